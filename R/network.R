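# Atom-transition network for central carbon metabolism.
#
# Carbon numbering follows the standard biochemical convention throughout:
# glucose C1 is the aldehyde carbon, pyruvate C1 the carboxyl carbon,
# aspartate C1 the alpha-carboxyl carbon, glutamate/alpha-ketoglutarate C1 the
# alpha-carboxyl carbon. The full convention is auditable via the metabolite
# table (`network$metabolites`) and the reaction maps themselves.

#' Define a metabolite
#'
#' @param name unique metabolite identifier.
#' @param n_carbons number of backbone carbons tracked.
#' @param note free-text note documenting the numbering convention.
#' @return a one-row data frame.
#' @keywords internal
metabolite <- function(name, n_carbons, note = "") {
  stopifnot(n_carbons >= 1)
  data.frame(name = name, n_carbons = as.integer(n_carbons), note = note,
             stringsAsFactors = FALSE)
}

#' Define a reaction with an explicit carbon atom map
#'
#' The atom map is written as tokens `s<i>.c<j>>p<k>.c<l>`: carbon `j` of the
#' `i`-th substrate slot becomes carbon `l` of the `k`-th product slot.
#' Every substrate carbon must map to exactly one product carbon and vice
#' versa (a bijection), so label is conserved; carbons released as CO2 map to
#' a CO2 product slot.
#'
#' @param name reaction identifier.
#' @param substrates character vector of substrate metabolite names (slots;
#'   a metabolite may occupy several slots).
#' @param products character vector of product metabolite names.
#' @param map character vector of atom-map tokens.
#' @param reversible logical; reversible reactions can be inverted with
#'   [invert_reaction()].
#' @return an object of class `atom_map`.
#' @export
reaction <- function(name, substrates, products, map, reversible = FALSE) {
  tok <- regmatches(map, regexec("^s(\\d+)\\.c(\\d+)>p(\\d+)\\.c(\\d+)$", map))
  bad <- vapply(tok, length, integer(1L)) != 5L
  if (any(bad)) stop("malformed atom-map token(s): ",
                     paste(map[bad], collapse = ", "), call. = FALSE)
  m <- t(vapply(tok, function(x) as.integer(x[-1L]), integer(4L)))
  colnames(m) <- c("sub_slot", "sub_carbon", "prod_slot", "prod_carbon")
  rx <- structure(list(name = name, substrates = substrates,
                       products = products, map = m, reversible = reversible),
                  class = "atom_map")
  rx
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("%s: %s -> %s%s\n", x$name,
              paste(x$substrates, collapse = " + "),
              paste(x$products, collapse = " + "),
              if (x$reversible) "  (reversible)" else ""))
  invisible(x)
}

validate_reaction <- function(rx, metabolites) {
  nsub <- vapply(rx$substrates, function(m)
    metabolites$n_carbons[metabolites$name == m], integer(1L))
  nprod <- vapply(rx$products, function(m)
    metabolites$n_carbons[metabolites$name == m], integer(1L))
  m <- rx$map
  subkey <- paste(m[, "sub_slot"], m[, "sub_carbon"])
  prodkey <- paste(m[, "prod_slot"], m[, "prod_carbon"])
  if (anyDuplicated(subkey) || anyDuplicated(prodkey)) {
    stop(sprintf("reaction %s: atom map is not a bijection", rx$name),
         call. = FALSE)
  }
  want_sub <- unlist(lapply(seq_along(nsub), function(i) paste(i, seq_len(nsub[i]))))
  want_prod <- unlist(lapply(seq_along(nprod), function(i) paste(i, seq_len(nprod[i]))))
  if (!setequal(subkey, want_sub) || !setequal(prodkey, want_prod) ||
      length(subkey) != length(want_sub)) {
    stop(sprintf("reaction %s: atom map does not account for every carbon",
                 rx$name), call. = FALSE)
  }
  invisible(rx)
}

#' Invert a reversible reaction's atom map
#'
#' @param rx an `atom_map` with `reversible = TRUE`.
#' @return the reverse `atom_map` (products become substrates).
#' @export
invert_reaction <- function(rx) {
  stopifnot(inherits(rx, "atom_map"))
  if (!rx$reversible) stop("reaction ", rx$name, " is not reversible", call. = FALSE)
  m <- rx$map[, c("prod_slot", "prod_carbon", "sub_slot", "sub_carbon"), drop = FALSE]
  colnames(m) <- c("sub_slot", "sub_carbon", "prod_slot", "prod_carbon")
  structure(list(name = paste0(rx$name, "_rev"), substrates = rx$products,
                 products = rx$substrates, map = m, reversible = TRUE),
            class = "atom_map")
}

#' Build the default central-carbon-metabolism network
#'
#' Contains, with explicit atom maps: glycolysis from glucose to pyruvate
#' (aldolase and the triose steps reversible), the glycerol-3-phosphate
#' branch, the oxidative pentose phosphate pathway (glucose C1 released as
#' CO2) with the canonical transketolase/transaldolase recombination of three
#' pentoses into two F6P and one GAP, lactate dehydrogenase and alanine
#' transaminase, pyruvate dehydrogenase and pyruvate carboxylase entries into
#' the TCA cycle, the full cycle with both decarboxylations, the malic-enzyme
#' (malate to pyruvate) recycling route, and the aspartate / glutamate /
#' glutamine exchange reactions. Succinate and fumarate are flagged as
#' symmetric: their carbon order is randomised 50/50 on formation.
#'
#' @return an object of class `atom_network` with elements `metabolites`
#'   (data frame), `reactions` (named list of `atom_map`s) and `symmetric`
#'   (character vector of symmetric metabolites).
#' @examples
#' net <- build_default_network()
#' apply_reaction(net, "PDH", "011")
#' @export
build_default_network <- function() {
  mets <- rbind(
    metabolite("glucose",     6, "C1 = aldehyde carbon"),
    metabolite("G6P",         6, "numbering as glucose"),
    metabolite("F6P",         6, "C1 = hydroxymethyl of the ketose"),
    metabolite("FBP",         6, "numbering as F6P"),
    metabolite("DHAP",        3, "C1 = phosphorylated carbon (from FBP C1-C3)"),
    metabolite("GAP",         3, "C1 = aldehyde carbon (from FBP C4)"),
    metabolite("glycerol3P",  3, "numbering as DHAP"),
    metabolite("PG3",         3, "3-phosphoglycerate; C1 = carboxyl"),
    metabolite("pyruvate",    3, "C1 = carboxyl"),
    metabolite("lactate",     3, "C1 = carboxyl"),
    metabolite("alanine",     3, "C1 = carboxyl"),
    metabolite("acetylCoA",   2, "C1 = carbonyl (from pyruvate C2)"),
    metabolite("pentoseP",    5, "lumped pentose-5-phosphate pool; C1 from glucose C2"),
    metabolite("S7P",         7, "sedoheptulose-7-phosphate"),
    metabolite("E4P",         4, "erythrose-4-phosphate"),
    metabolite("citrate",     6, "C1-C3 from oxaloacetate C4-C2; C4,C5 from acetyl-CoA; C6 from OAA C1"),
    metabolite("aKG",         5, "alpha-ketoglutarate; C1 = alpha-carboxyl"),
    metabolite("succinate",   4, "symmetric"),
    metabolite("fumarate",    4, "symmetric"),
    metabolite("malate",      4, "C1 = carboxyl adjacent to hydroxyl carbon"),
    metabolite("OAA",         4, "oxaloacetate; C1 = keto-side carboxyl"),
    metabolite("aspartate",   4, "C1 = alpha-carboxyl; carbons 1:1 with OAA"),
    metabolite("glutamate",   5, "C1 = alpha-carboxyl; carbons 1:1 with aKG"),
    metabolite("glutamine",   5, "carbons 1:1 with glutamate"),
    metabolite("CO2",         1, "")
  )

  identity_map <- function(n, sub_slot = 1L, prod_slot = 1L) {
    sprintf("s%d.c%d>p%d.c%d", sub_slot, 1:n, prod_slot, 1:n)
  }

  rxs <- list(
    reaction("HK",  "glucose", "G6P", identity_map(6)),
    reaction("PGI", "G6P", "F6P", identity_map(6), reversible = TRUE),
    reaction("PFK", "F6P", "FBP", identity_map(6), reversible = TRUE),
    # aldolase: FBP C1-C3 -> DHAP, C4-C6 -> GAP (C4 becomes the GAP aldehyde)
    reaction("ALD", "FBP", c("DHAP", "GAP"),
             c("s1.c1>p1.c1", "s1.c2>p1.c2", "s1.c3>p1.c3",
               "s1.c4>p2.c1", "s1.c5>p2.c2", "s1.c6>p2.c3"),
             reversible = TRUE),
    # triose phosphate isomerase: DHAP C1 -> GAP C3, C2 -> C2, C3 -> C1
    reaction("TPI", "DHAP", "GAP",
             c("s1.c1>p1.c3", "s1.c2>p1.c2", "s1.c3>p1.c1"),
             reversible = TRUE),
    reaction("G3PDH", "DHAP", "glycerol3P", identity_map(3), reversible = TRUE),
    reaction("GAPDH", "GAP", "PG3", identity_map(3), reversible = TRUE),
    reaction("PK", "PG3", "pyruvate", identity_map(3)),
    reaction("LDH", "pyruvate", "lactate", identity_map(3), reversible = TRUE),
    reaction("ALT", "pyruvate", "alanine", identity_map(3), reversible = TRUE),
    # pyruvate dehydrogenase: C1 lost as CO2; C2 -> acetyl C1, C3 -> acetyl C2
    reaction("PDH", "pyruvate", c("acetylCoA", "CO2"),
             c("s1.c1>p2.c1", "s1.c2>p1.c1", "s1.c3>p1.c2")),
    # pyruvate carboxylase: pyruvate C1-C3 -> OAA C1-C3, fixed CO2 -> OAA C4
    reaction("PC", c("pyruvate", "CO2"), "OAA",
             c("s1.c1>p1.c1", "s1.c2>p1.c2", "s1.c3>p1.c3", "s2.c1>p1.c4")),
    # oxidative PPP, lumped: glucose C1 lost as CO2, C2-C6 -> pentose C1-C5
    reaction("oxPPP", "G6P", c("pentoseP", "CO2"),
             c("s1.c1>p2.c1", "s1.c2>p1.c1", "s1.c3>p1.c2", "s1.c4>p1.c3",
               "s1.c5>p1.c4", "s1.c6>p1.c5")),
    # transketolase 1: C1,C2 of the donor pentose onto the acceptor pentose
    reaction("TK1", c("pentoseP", "pentoseP"), c("S7P", "GAP"),
             c("s1.c1>p1.c1", "s1.c2>p1.c2",
               "s2.c1>p1.c3", "s2.c2>p1.c4", "s2.c3>p1.c5",
               "s2.c4>p1.c6", "s2.c5>p1.c7",
               "s1.c3>p2.c1", "s1.c4>p2.c2", "s1.c5>p2.c3"),
             reversible = TRUE),
    # transaldolase: S7P C1-C3 onto GAP
    reaction("TA", c("S7P", "GAP"), c("F6P", "E4P"),
             c("s1.c1>p1.c1", "s1.c2>p1.c2", "s1.c3>p1.c3",
               "s2.c1>p1.c4", "s2.c2>p1.c5", "s2.c3>p1.c6",
               "s1.c4>p2.c1", "s1.c5>p2.c2", "s1.c6>p2.c3", "s1.c7>p2.c4"),
             reversible = TRUE),
    # transketolase 2: pentose C1,C2 onto E4P
    reaction("TK2", c("pentoseP", "E4P"), c("F6P", "GAP"),
             c("s1.c1>p1.c1", "s1.c2>p1.c2",
               "s2.c1>p1.c3", "s2.c2>p1.c4", "s2.c3>p1.c5", "s2.c4>p1.c6",
               "s1.c3>p2.c1", "s1.c4>p2.c2", "s1.c5>p2.c3"),
             reversible = TRUE),
    # citrate synthase; citrate handled prochirally (asymmetric) by aconitase
    reaction("CS", c("OAA", "acetylCoA"), "citrate",
             c("s1.c1>p1.c6", "s1.c2>p1.c3", "s1.c3>p1.c2", "s1.c4>p1.c1",
               "s2.c1>p1.c5", "s2.c2>p1.c4")),
    # isocitrate dehydrogenase: citrate C6 (OAA C1) released as CO2
    reaction("IDH", "citrate", c("aKG", "CO2"),
             c("s1.c1>p1.c1", "s1.c2>p1.c2", "s1.c3>p1.c3",
               "s1.c4>p1.c4", "s1.c5>p1.c5", "s1.c6>p2.c1")),
    # aKG dehydrogenase + succinyl-CoA synthetase: aKG C1 (OAA C4) as CO2
    reaction("AKGDH", "aKG", c("succinate", "CO2"),
             c("s1.c1>p2.c1", "s1.c2>p1.c1", "s1.c3>p1.c2",
               "s1.c4>p1.c3", "s1.c5>p1.c4")),
    reaction("SDH", "succinate", "fumarate", identity_map(4), reversible = TRUE),
    reaction("FUM", "fumarate", "malate", identity_map(4), reversible = TRUE),
    reaction("MDH", "malate", "OAA", identity_map(4), reversible = TRUE),
    # malic enzyme: malate C4 released as CO2, C1-C3 -> pyruvate
    reaction("ME", "malate", c("pyruvate", "CO2"),
             c("s1.c1>p1.c1", "s1.c2>p1.c2", "s1.c3>p1.c3", "s1.c4>p2.c1")),
    reaction("GOT", "OAA", "aspartate", identity_map(4), reversible = TRUE),
    reaction("GDH", "aKG", "glutamate", identity_map(5), reversible = TRUE),
    reaction("GLS", "glutamine", "glutamate", identity_map(5))
  )
  names(rxs) <- vapply(rxs, `[[`, character(1L), "name")
  net <- structure(list(metabolites = mets, reactions = rxs,
                        symmetric = c("succinate", "fumarate")),
                   class = "atom_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  if (anyDuplicated(net$metabolites$name)) {
    stop("metabolite names must be unique", call. = FALSE)
  }
  for (rx in net$reactions) validate_reaction(rx, net$metabolites)
  invisible(net)
}

#' @export
print.atom_network <- function(x, ...) {
  cat(sprintf("Atom-transition network: %d metabolites, %d reactions\n",
              nrow(x$metabolites), length(x$reactions)))
  cat("Symmetric metabolites:", paste(x$symmetric, collapse = ", "), "\n")
  for (rx in x$reactions) print(rx)
  invisible(x)
}

n_carbons_of <- function(net, met) {
  i <- match(met, net$metabolites$name)
  if (is.na(i)) stop("unknown metabolite: ", met, call. = FALSE)
  net$metabolites$n_carbons[i]
}

# 50/50 head-to-tail scrambling of a symmetric molecule's pattern.
symmetrise_pattern <- function(pattern) {
  rev_p <- paste(rev(strsplit(pattern, "", fixed = TRUE)[[1L]]), collapse = "")
  if (rev_p == pattern) stats::setNames(1, pattern)
  else stats::setNames(c(0.5, 0.5), c(pattern, rev_p))
}

#' Apply one reaction step to labelled substrate molecules
#'
#' Deterministic for reactions whose products are orientation-specific; for
#' symmetric products (succinate, fumarate) both carbon orientations are
#' returned with weight 0.5 each.
#'
#' @param net an `atom_network` (supplies carbon counts and symmetry flags).
#' @param rx a reaction name in `net` or an `atom_map` object.
#' @param substrate_patterns character vector of pattern strings, one per
#'   substrate slot.
#' @return a list of outcomes; each outcome has `products` (named character
#'   vector of product patterns, names `<metabolite>.<slot>`) and `weight`.
#'   Weights sum to 1.
#' @examples
#' net <- build_default_network()
#' apply_reaction(net, "ALD", "110000")
#' @export
apply_reaction <- function(net, rx, substrate_patterns) {
  if (is.character(rx)) {
    if (!rx %in% names(net$reactions)) stop("unknown reaction: ", rx, call. = FALSE)
    rx <- net$reactions[[rx]]
  }
  stopifnot(inherits(rx, "atom_map"))
  if (length(substrate_patterns) != length(rx$substrates)) {
    stop(sprintf("reaction %s expects %d substrate pattern(s)", rx$name,
                 length(rx$substrates)), call. = FALSE)
  }
  for (i in seq_along(rx$substrates)) {
    check_pattern(substrate_patterns[i], n_carbons_of(net, rx$substrates[i]))
  }
  bits <- lapply(substrate_patterns, pattern_bits)
  prod_bits <- lapply(rx$products, function(m)
    integer(n_carbons_of(net, m)))
  m <- rx$map
  for (r in seq_len(nrow(m))) {
    prod_bits[[m[r, "prod_slot"]]][m[r, "prod_carbon"]] <-
      bits[[m[r, "sub_slot"]]][m[r, "sub_carbon"]]
  }
  prods <- vapply(prod_bits, paste, character(1L), collapse = "")
  names(prods) <- paste0(rx$products, ".", seq_along(rx$products))
  # expand symmetric products into both orientations
  outcomes <- list(list(products = prods, weight = 1))
  for (j in seq_along(rx$products)) {
    if (!rx$products[j] %in% net$symmetric) next
    new <- list()
    for (o in outcomes) {
      sp <- symmetrise_pattern(o$products[j])
      for (k in seq_along(sp)) {
        pr <- o$products; pr[j] <- names(sp)[k]
        new[[length(new) + 1L]] <- list(products = pr,
                                        weight = o$weight * sp[[k]])
      }
    }
    outcomes <- new
  }
  # merge identical outcomes (symmetric input patterns)
  key <- vapply(outcomes, function(o) paste(o$products, collapse = "|"),
                character(1L))
  if (anyDuplicated(key)) {
    agg <- tapply(vapply(outcomes, `[[`, numeric(1L), "weight"), key, sum)
    outcomes <- lapply(names(agg), function(k) {
      i <- match(k, key)
      list(products = outcomes[[i]]$products, weight = as.numeric(agg[[k]]))
    })
  }
  outcomes
}

# Concatenated-bit permutation view of a reaction's atom map: product bit i
# equals substrate bit perm[i] of the concatenated substrate pattern.
rx_perm <- function(net, rx) {
  ns <- vapply(rx$substrates, function(m) n_carbons_of(net, m), integer(1L))
  np <- vapply(rx$products, function(m) n_carbons_of(net, m), integer(1L))
  sub_off <- cumsum(c(0L, ns)); prod_off <- cumsum(c(0L, np))
  perm <- integer(sum(np))
  m <- rx$map
  perm[prod_off[m[, "prod_slot"]] + m[, "prod_carbon"]] <-
    sub_off[m[, "sub_slot"]] + m[, "sub_carbon"]
  list(ns = ns, np = np, perm = perm, prod_off = prod_off)
}

# Vectorised reaction application to rows of joint substrate patterns.
# sub_mat: character matrix, one column per substrate slot; weights: one per
# row. Returns list(prod = pattern matrix with "<met>.<slot>" columns,
# weight = numeric) with symmetric products scrambled 50/50.
fast_apply_rows <- function(net, rx, sub_mat, weights) {
  if (is.character(rx)) rx <- net$reactions[[rx]]
  pp <- rx_perm(net, rx)
  concat <- do.call(paste0, asplit(sub_mat, 2L))
  chars <- matrix(unlist(strsplit(concat, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(concat), byrow = TRUE)
  pb <- chars[, pp$perm, drop = FALSE]
  nprod <- length(rx$products)
  prod_pat <- matrix("", length(concat), nprod,
                     dimnames = list(NULL, paste0(rx$products, ".",
                                                  seq_len(nprod))))
  for (k in seq_len(nprod)) {
    rng <- (pp$prod_off[k] + 1L):(pp$prod_off[k] + pp$np[k])
    prod_pat[, k] <- do.call(paste0, asplit(pb[, rng, drop = FALSE], 2L))
  }
  for (k in seq_len(nprod)) {
    if (!rx$products[k] %in% net$symmetric) next
    rng <- (pp$prod_off[k] + 1L):(pp$prod_off[k] + pp$np[k])
    alt <- prod_pat
    alt[, k] <- do.call(paste0, asplit(pb[, rev(rng), drop = FALSE], 2L))
    prod_pat <- rbind(prod_pat, alt)
    pb <- rbind(pb, pb)
    weights <- c(weights / 2, weights / 2)
  }
  list(prod = prod_pat, weight = weights)
}

joint_from_independent <- function(substrate_dists) {
  grids <- lapply(substrate_dists, names)
  idx <- as.matrix(expand.grid(lapply(grids, seq_along)))
  sub_mat <- matrix("", nrow(idx), length(substrate_dists))
  w <- rep(1, nrow(idx))
  for (j in seq_along(substrate_dists)) {
    sub_mat[, j] <- grids[[j]][idx[, j]]
    w <- w * as.numeric(substrate_dists[[j]])[idx[, j]]
  }
  keep <- w > 0
  list(sub_mat = sub_mat[keep, , drop = FALSE], weight = w[keep])
}

marginals_of_rows <- function(rx, rows) {
  slots <- colnames(rows$prod)
  out <- stats::setNames(vector("list", length(slots)), slots)
  for (s in seq_along(slots)) {
    agg <- rowsum(rows$weight, rows$prod[, s])
    out[[s]] <- iso_dist(stats::setNames(as.numeric(agg), rownames(agg)),
                         metabolite = rx$products[s])
  }
  out
}

# Joint outcome rows of a reaction over independent substrate distributions.
dist_apply_joint <- function(net, rx, substrate_dists) {
  if (is.character(rx)) rx <- net$reactions[[rx]]
  jt <- joint_from_independent(substrate_dists)
  fast_apply_rows(net, rx, jt$sub_mat, jt$weight)
}

# Marginal product distributions of a reaction applied to independent
# substrate distributions. Returns a named list of iso_dist keyed
# "<metabolite>.<slot>".
dist_apply <- function(net, rx, substrate_dists) {
  if (is.character(rx)) rx <- net$reactions[[rx]]
  marginals_of_rows(rx, dist_apply_joint(net, rx, substrate_dists))
}

#' Read and write networks as plain-text reaction files
#'
#' Grammar, one record per line, `#` comments and blank lines ignored:
#' \preformatted{
#' metabolite <name> <n_carbons> [symmetric] [# note]
#' reaction <name> | <sub1>+<sub2> > <prod1>+<prod2> | <tok>,<tok>,... [| reversible]
#' }
#' where each `<tok>` is an atom-map token `s1.c1>p1.c3` (see [reaction()]).
#' Round-trips exactly through [write_network()].
#'
#' @param path file path.
#' @return `read_network()`: an `atom_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  mets <- list(); rxs <- list(); symmetric <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s*\\|\\s*")[[1L]]
    head <- strsplit(trimws(parts[1L]), "\\s+")[[1L]]
    if (head[1L] == "metabolite") {
      mets[[length(mets) + 1L]] <- metabolite(head[2L], as.integer(head[3L]))
      if (length(head) >= 4L && head[4L] == "symmetric") {
        symmetric <- c(symmetric, head[2L])
      }
    } else if (head[1L] == "reaction") {
      nm <- head[2L]
      sp <- strsplit(trimws(parts[2L]), "\\s*>\\s*")[[1L]]
      subs <- strsplit(sp[1L], "\\s*\\+\\s*")[[1L]]
      prods <- strsplit(sp[2L], "\\s*\\+\\s*")[[1L]]
      toks <- strsplit(trimws(parts[3L]), "\\s*,\\s*")[[1L]]
      rev <- length(parts) >= 4L && trimws(parts[4L]) == "reversible"
      rxs[[nm]] <- reaction(nm, subs, prods, toks, reversible = rev)
    } else stop("unrecognised network record: ", ln, call. = FALSE)
  }
  net <- structure(list(metabolites = do.call(rbind, mets), reactions = rxs,
                        symmetric = symmetric), class = "atom_network")
  validate_network(net)
  net
}

#' @rdname read_network
#' @param net an `atom_network`.
#' @return `write_network()`: `path`, invisibly.
#' @export
write_network <- function(net, path) {
  lines <- character()
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    lines <- c(lines, paste("metabolite", m$name, m$n_carbons,
                            if (m$name %in% net$symmetric) "symmetric" else ""))
  }
  for (rx in net$reactions) {
    toks <- apply(rx$map, 1L, function(r)
      sprintf("s%d.c%d>p%d.c%d", r[1L], r[2L], r[3L], r[4L]))
    lines <- c(lines, paste("reaction", rx$name, "|",
                            paste(rx$substrates, collapse = "+"), ">",
                            paste(rx$products, collapse = "+"), "|",
                            paste(toks, collapse = ","),
                            if (rx$reversible) "| reversible" else ""))
  }
  writeLines(trimws(lines), path)
  invisible(path)
}
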