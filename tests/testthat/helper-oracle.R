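# Independent brute-force path-enumeration oracle.
#
# Written naively and directly from the textbook atom transitions as string
# manipulations -- deliberately NOT via the package's network machinery -- so
# it can serve as an independent check on supports and weights.

ob <- function(p) as.integer(strsplit(p, "")[[1]])
op <- function(b) paste(b, collapse = "")
orev <- function(p) op(rev(ob(p)))
omass <- function(p) vapply(p, function(q) sum(ob(q) == 1L), integer(1L))

# glycolysis: glucose C1-C3 -> DHAP C1-C3; C4-C6 -> GAP C1-C3
oracle_dhap <- function(glc) substr(glc, 1, 3)
oracle_gap_direct <- function(glc) substr(glc, 4, 6)
# TPI reverses the triose carbon order
oracle_tpi <- function(triose) orev(triose)
# GAP -> pyruvate carbons 1:1
oracle_pyr_from_gap <- function(gap) gap
# PDH: pyruvate C1 -> CO2, C2 -> acetyl C1, C3 -> acetyl C2
oracle_pdh <- function(pyr) substr(pyr, 2, 3)
# PC: pyruvate C1-C3 -> OAA C1-C3; unlabelled CO2 -> OAA C4
oracle_pc <- function(pyr) paste0(pyr, "0")
# oxidative PPP: glucose C1 lost, C2-C6 -> pentose C1-C5
oracle_pentose <- function(glc) substr(glc, 2, 6)

# one TCA round: citrate = (OAA4, OAA3, OAA2, Ac2, Ac1, OAA1);
# IDH releases citrate C6 (OAA C1); AKGDH releases aKG C1 (OAA C4);
# succinate = (OAA3, OAA2, Ac2, Ac1), scrambled 50/50 with its reverse.
oracle_turn_patterns <- function(oaa, ac) {
  o <- ob(oaa); a <- ob(ac)
  suc <- op(c(o[3], o[2], a[2], a[1]))
  unique(c(suc, orev(suc)))
}

# aspartate support after exactly `turns` rounds, given sets of possible OAA
# entry patterns and acetyl-CoA patterns (well-mixed pool each round)
oracle_asp_support <- function(oaa_entry, ac_set, turns) {
  cur <- unique(oaa_entry)
  for (k in seq_len(turns)) {
    nxt <- character()
    for (o4 in cur) for (a2 in ac_set) {
      nxt <- c(nxt, oracle_turn_patterns(o4, a2))
    }
    cur <- unique(nxt)
  }
  sort(cur)
}

# glutamine -> glutamate -> aKG carbons 1:1; aKG C1 lost; succinate =
# aKG C2-C5, scrambled; identity to OAA
oracle_oaa_from_gln <- function(gln) {
  suc <- substr(gln, 2, 5)
  sort(unique(c(suc, orev(suc))))
}

# labelled pyruvate patterns reachable from [1,2-13C]glucose by glycolysis
oracle_glyc_pyr_support <- function(glc = "110000") {
  unique(c(oracle_pyr_from_gap(oracle_gap_direct(glc)),
           oracle_pyr_from_gap(oracle_tpi(oracle_dhap(glc)))))
}

# F6P patterns reachable: forward = glucose carbons 1:1; PPP recombination
# F6P1 = (a1,a2,b1,a3,a4,a5), F6P2 = (c1,c2,b2,b3,b4,b5) over pentoses a,b,c;
# reverse = any (DHAP pattern, GAP pattern) pair from the triose pool
oracle_f6p_forward_support <- function(glc = "110000", pentoses = NULL) {
  if (is.null(pentoses)) {
    pentoses <- unique(c(oracle_pentose(glc), oracle_pentose("000000")))
  }
  f6p <- glc
  for (a in pentoses) for (b in pentoses) for (cc in pentoses) {
    av <- ob(a); bv <- ob(b); cv <- ob(cc)
    f6p <- c(f6p,
             op(c(av[1], av[2], bv[1], av[3], av[4], av[5])),
             op(c(cv[1], cv[2], bv[2], bv[3], bv[4], bv[5])))
  }
  sort(unique(f6p))
}

oracle_triose_pool <- function(glc = "110000") {
  dh <- oracle_dhap(glc); gp <- oracle_gap_direct(glc)
  gap_frame <- unique(c(gp, oracle_tpi(dh), "000"))
  dhap_frame <- unique(sapply(gap_frame, oracle_tpi))
  list(gap = gap_frame, dhap = dhap_frame)
}

oracle_f6p_reverse_support <- function(glc = "110000") {
  tp <- oracle_triose_pool(glc)
  out <- character()
  for (d in tp$dhap) for (g in tp$gap) out <- c(out, paste0(d, g))
  sort(unique(out))
}
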