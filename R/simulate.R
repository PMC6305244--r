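# Deterministic label propagation: tracer -> positional isotopomer
# distributions under pathway-usage fractions. All arithmetic is mixture
# algebra over pattern supports; no random numbers are used here.

#' Tracer specification
#'
#' @param metabolite name of the labelled nutrient (`"glucose"` or
#'   `"glutamine"` in the default network).
#' @param positions integer carbon positions carrying 13C.
#' @param enrichment fraction in `[0, 1]` of input molecules carrying the
#'   label (the rest are fully unlabelled).
#' @return an object of class `tracer_spec`.
#' @examples
#' tracer_glc12()   # [1,2-13C]glucose
#' tracer_glnU()    # [U-13C]glutamine
#' @export
tracer_spec <- function(metabolite, positions, enrichment = 1) {
  if (enrichment < 0 || enrichment > 1) {
    stop("enrichment must be in [0, 1]", call. = FALSE)
  }
  if (any(positions < 1) || anyDuplicated(positions)) {
    stop("labelled positions must be distinct indices >= 1", call. = FALSE)
  }
  structure(list(metabolite = metabolite,
                 positions = sort(as.integer(positions)),
                 enrichment = enrichment),
            class = "tracer_spec")
}

#' @rdname tracer_spec
#' @export
tracer_glc12 <- function(enrichment = 1) tracer_spec("glucose", c(1L, 2L), enrichment)

#' @rdname tracer_spec
#' @export
tracer_glnU <- function(enrichment = 1) tracer_spec("glutamine", 1:5, enrichment)

tracer_dist <- function(tracer, n, metabolite) {
  if (max(tracer$positions) > n) {
    stop("tracer positions exceed the metabolite's carbon count", call. = FALSE)
  }
  b <- integer(n); b[tracer$positions] <- 1L
  lab <- paste(b, collapse = "")
  e <- tracer$enrichment
  if (e == 0) return(unlabelled_dist(n, metabolite))
  if (e == 1) return(iso_dist(stats::setNames(1, lab), metabolite))
  iso_dist(stats::setNames(c(1 - e, e), c(strrep("0", n), lab)), metabolite)
}

#' Pathway-usage fractions
#'
#' The dials of the simulator; all in `[0, 1]`.
#'
#' @param f_oxppp fraction of glucose flux routed through the oxidative
#'   pentose phosphate pathway (the rest proceeds by upper glycolysis).
#' @param f_reverse fraction of the F6P pool formed by reverse aldolase/TPI
#'   from the triose phosphate pool (reverse glycolysis above GAPDH).
#' @param f_pc fraction of the anaplerotic pyruvate-derived TCA entry that
#'   uses pyruvate carboxylase; acetyl units always enter via PDH.
#' @param turn_exit per-turn probability that cycle oxaloacetate exits to
#'   aspartate, giving a (truncated) geometric number of TCA rounds.
#' @param f_gln fraction of the anaplerotic OAA pool derived from glutamine
#'   (via glutamate, alpha-ketoglutarate and the span of the cycle).
#' @param f_pyr_cycle fraction of the pyruvate pool regenerated from cycle
#'   malate by malic enzyme (pyruvate recycling); routes glutamine carbon
#'   into acetyl-CoA and is what produces m+3 aspartate from [U-13C]glutamine
#'   over multiple rounds.
#' @return an object of class `pathway_fractions`.
#' @export
pathway_fractions <- function(f_oxppp = 0, f_reverse = 0, f_pc = 0,
                              turn_exit = 0.5, f_gln = 0, f_pyr_cycle = 0) {
  x <- list(f_oxppp = f_oxppp, f_reverse = f_reverse, f_pc = f_pc,
            turn_exit = turn_exit, f_gln = f_gln, f_pyr_cycle = f_pyr_cycle)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a single number in [0, 1]", call. = FALSE)
    }
  }
  structure(x, class = "pathway_fractions")
}

#' @export
print.pathway_fractions <- function(x, ...) {
  cat("Pathway fractions:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %.3f\n", nm, x[[nm]]))
  invisible(x)
}

# marginal of one product slot, by metabolite name (first matching slot)
prod_of <- function(applied, met) {
  i <- grep(paste0("^", met, "\\."), names(applied))[1L]
  applied[[i]]
}

# relabel a distribution's metabolite attribute
as_met <- function(dist, metabolite) {
  attr(dist, "metabolite") <- metabolite
  dist
}

#' Simulate tracer label propagation through central carbon metabolism
#'
#' Propagates the tracer through upper glycolysis, the (lumped) pentose
#' phosphate pathway, the reverse-aldolase route, and `n_max_turns` rounds of
#' the TCA cycle. The acetyl-CoA fed to each round is drawn from the same
#' pyruvate-derived distribution (well-mixed pool); succinate and fumarate
#' scramble 50/50; the number of rounds before oxaloacetate exits to
#' aspartate is geometric with per-round probability `fractions$turn_exit`,
#' truncated at `n_max_turns` with the residual mass folded into the final
#' round. Exit at round 0 (anaplerotic OAA leaving before any condensation)
#' is what makes the pyruvate-carboxylase pattern visible in aspartate.
#'
#' @param net an `atom_network`; default [build_default_network()].
#' @param tracer a [tracer_spec()].
#' @param fractions a [pathway_fractions()].
#' @param n_max_turns maximum number of TCA rounds propagated (>= 1).
#' @return an object of class `iso_sim`: a named list of [iso_dist()]
#'   objects (glucose, G6P, F6P, FBP, DHAP, GAP, glycerol3P, PG3, pyruvate,
#'   lactate, alanine, acetylCoA, citrate, aKG, succinate, fumarate, malate,
#'   OAA, aspartate, glutamate, glutamine), with attributes `oaa_by_turn`
#'   (list of OAA distributions after 0..n_max_turns rounds), `turn_weights`,
#'   `fractions` and `tracer`.
#' @examples
#' sim <- simulate_labelling(tracer = tracer_glc12(),
#'                           fractions = pathway_fractions(turn_exit = 1, f_pc = 1))
#' sim$aspartate   # pyruvate-carboxylase first-pass pattern "0110"
#' @export
simulate_labelling <- function(net = build_default_network(),
                               tracer = tracer_glc12(),
                               fractions = pathway_fractions(),
                               n_max_turns = 4L) {
  stopifnot(inherits(tracer, "tracer_spec"),
            inherits(fractions, "pathway_fractions"), n_max_turns >= 1)
  K <- as.integer(n_max_turns)
  f <- fractions

  glc <- if (tracer$metabolite == "glucose") {
    tracer_dist(tracer, 6L, "glucose")
  } else unlabelled_dist(6L, "glucose")
  gln <- if (tracer$metabolite == "glutamine") {
    tracer_dist(tracer, 5L, "glutamine")
  } else unlabelled_dist(5L, "glutamine")

  g6p <- as_met(prod_of(dist_apply(net, "HK", list(glc)), "G6P"), "G6P")

  ## ---- pentose phosphate pathway (lumped) --------------------------------
  oxp <- dist_apply(net, "oxPPP", list(g6p))
  pentose <- prod_of(oxp, "pentoseP")
  # TK1 couples the donor's C1,C2 *and* C3-C5 into downstream products, so the
  # S7P/GAP pair must be tracked jointly before transaldolase.
  tk1 <- dist_apply_joint(net, "TK1", list(pentose, pentose))
  ta_rows <- fast_apply_rows(net, "TA",
                             tk1$prod[, c("S7P.1", "GAP.2"), drop = FALSE],
                             tk1$weight)
  ta_marg <- marginals_of_rows(net$reactions$TA, ta_rows)
  f6p_ta <- as_met(ta_marg[["F6P.1"]], "F6P")
  e4p <- as_met(ta_marg[["E4P.2"]], "E4P")
  tk2 <- dist_apply(net, "TK2", list(pentose, e4p))
  f6p_tk2 <- prod_of(tk2, "F6P")
  gap_ppp <- prod_of(tk2, "GAP")
  f6p_ppp <- mix_dists(list(f6p_ta, f6p_tk2), c(0.5, 0.5), "F6P")

  ## ---- upper glycolysis and the triose pool ------------------------------
  f6p_direct <- as_met(prod_of(dist_apply(net, "PGI", list(g6p)), "F6P"), "F6P")
  # molar accounting per unit glucose: 3 glucose -> 3 pentose -> 2 F6P + 1 GAP
  w_direct <- 1 - f$f_oxppp
  w_ppp_f6p <- (2 / 3) * f$f_oxppp
  w_ppp_gap <- (1 / 3) * f$f_oxppp
  M <- w_direct + w_ppp_f6p   # molar F6P formed per glucose (forward)
  f6p_fwd <- if (M > 0) {
    mix_dists(list(f6p_direct, f6p_ppp), c(w_direct, w_ppp_f6p), "F6P")
  } else unlabelled_dist(6L, "F6P")
  fbp_fwd <- as_met(prod_of(dist_apply(net, "PFK", list(f6p_fwd)), "FBP"), "FBP")
  ald <- dist_apply(net, "ALD", list(fbp_fwd))
  dhap_raw <- prod_of(ald, "DHAP")
  gap_raw <- prod_of(ald, "GAP")
  gap_from_dhap <- prod_of(dist_apply(net, "TPI", list(dhap_raw)), "GAP")
  # flux-weighted triose pool, GAP frame (TPI assumed fully equilibrated)
  gap_pool <- mix_dists(list(gap_from_dhap, gap_raw, gap_ppp),
                        c(M, M, w_ppp_gap), "GAP")
  tpi_rev <- invert_reaction(net$reactions$TPI)
  dhap_pool <- as_met(prod_of(dist_apply(net, tpi_rev, list(gap_pool)), "DHAP"),
                      "DHAP")
  glycerol3p <- as_met(prod_of(dist_apply(net, "G3PDH", list(dhap_pool)),
                               "glycerol3P"), "glycerol3P")

  ## ---- reverse glycolysis above GAPDH ------------------------------------
  ald_rev <- invert_reaction(net$reactions$ALD)
  fbp_rev <- as_met(prod_of(dist_apply(net, ald_rev, list(dhap_pool, gap_pool)),
                            "FBP"), "FBP")
  pfk_rev <- invert_reaction(net$reactions$PFK)
  f6p_rev <- as_met(prod_of(dist_apply(net, pfk_rev, list(fbp_rev)), "F6P"), "F6P")
  f6p <- mix_dists(list(f6p_fwd, f6p_rev), c(1 - f$f_reverse, f$f_reverse), "F6P")
  fbp <- mix_dists(list(fbp_fwd, fbp_rev), c(1 - f$f_reverse, f$f_reverse), "FBP")

  pg3 <- as_met(prod_of(dist_apply(net, "GAPDH", list(gap_pool)), "PG3"), "PG3")
  pyr_glyc <- as_met(prod_of(dist_apply(net, "PK", list(pg3)), "pyruvate"),
                     "pyruvate")

  ## ---- glutamine entry ----------------------------------------------------
  glu_gln <- as_met(prod_of(dist_apply(net, "GLS", list(gln)), "glutamate"),
                    "glutamate")
  gdh_rev <- invert_reaction(net$reactions$GDH)
  akg_gln <- as_met(prod_of(dist_apply(net, gdh_rev, list(glu_gln)), "aKG"), "aKG")
  suc_gln <- prod_of(dist_apply(net, "AKGDH", list(akg_gln)), "succinate")
  fum_gln <- prod_of(dist_apply(net, "SDH", list(suc_gln)), "fumarate")
  mal_gln <- as_met(prod_of(dist_apply(net, "FUM", list(fum_gln)), "malate"),
                    "malate")
  oaa_gln <- as_met(prod_of(dist_apply(net, "MDH", list(mal_gln)), "OAA"), "OAA")

  co2_free <- unlabelled_dist(1L, "CO2")  # CO2 pool treated as unlabelled
  unl_oaa <- unlabelled_dist(4L, "OAA")

  ## ---- TCA rounds with pyruvate recycling fixed point ---------------------
  # exit weights over rounds 0..K (geometric, residual folded into round K)
  te <- f$turn_exit
  w_exit <- te * (1 - te)^(0:K)
  w_exit[K + 1L] <- (1 - te)^K
  if (te == 0) { w_exit[] <- 0; w_exit[K + 1L] <- 1 }
  # cycle-intermediate occupancy over rounds 1..K
  u_occ <- (1 - te)^(0:(K - 1L))
  u_occ <- u_occ / sum(u_occ)

  pyr <- pyr_glyc
  mal_pool <- unlabelled_dist(4L, "malate")
  turn_state <- NULL
  for (iter in 1:50) {
    accoa <- as_met(prod_of(dist_apply(net, "PDH", list(pyr)), "acetylCoA"),
                    "acetylCoA")
    oaa_pc <- as_met(prod_of(dist_apply(net, "PC", list(pyr, co2_free)), "OAA"),
                     "OAA")
    oaa0 <- mix_dists(
      list(oaa_gln, oaa_pc, unl_oaa),
      c(f$f_gln, (1 - f$f_gln) * f$f_pc, (1 - f$f_gln) * (1 - f$f_pc)), "OAA")
    oaa_by_turn <- vector("list", K + 1L)
    cit_t <- akg_t <- suc_t <- mal_t <- vector("list", K)
    oaa_by_turn[[1L]] <- oaa0
    cur <- oaa0
    for (k in 1:K) {
      cit <- as_met(prod_of(dist_apply(net, "CS", list(cur, accoa)), "citrate"),
                    "citrate")
      akg <- as_met(prod_of(dist_apply(net, "IDH", list(cit)), "aKG"), "aKG")
      suc <- prod_of(dist_apply(net, "AKGDH", list(akg)), "succinate")
      fum <- prod_of(dist_apply(net, "SDH", list(suc)), "fumarate")
      mal <- as_met(prod_of(dist_apply(net, "FUM", list(fum)), "malate"), "malate")
      cur <- as_met(prod_of(dist_apply(net, "MDH", list(mal)), "OAA"), "OAA")
      cit_t[[k]] <- cit; akg_t[[k]] <- akg; suc_t[[k]] <- suc; mal_t[[k]] <- mal
      oaa_by_turn[[k + 1L]] <- cur
    }
    mal_cycle <- mix_dists(mal_t, u_occ, "malate")
    mal_new <- mix_dists(list(mal_gln, mal_cycle), c(f$f_gln, 1 - f$f_gln),
                         "malate")
    pyr_me <- as_met(prod_of(dist_apply(net, "ME", list(mal_new)), "pyruvate"),
                     "pyruvate")
    pyr_new <- mix_dists(list(pyr_glyc, pyr_me),
                         c(1 - f$f_pyr_cycle, f$f_pyr_cycle), "pyruvate")
    turn_state <- list(accoa = accoa, oaa_by_turn = oaa_by_turn, cit_t = cit_t,
                       akg_t = akg_t, suc_t = suc_t, mal_t = mal_t,
                       mal_pool = mal_new)
    delta <- dist_l1(pyr_new, pyr)
    pyr <- pyr_new
    if (f$f_pyr_cycle == 0 || delta < 1e-12) break
  }

  lac <- as_met(prod_of(dist_apply(net, "LDH", list(pyr)), "lactate"), "lactate")
  ala <- as_met(prod_of(dist_apply(net, "ALT", list(pyr)), "alanine"), "alanine")
  oaa_pool <- mix_dists(turn_state$oaa_by_turn, w_exit, "OAA")
  asp <- as_met(prod_of(dist_apply(net, "GOT", list(oaa_pool)), "aspartate"),
                "aspartate")
  cit_pool <- mix_dists(turn_state$cit_t, u_occ, "citrate")
  akg_cycle <- mix_dists(turn_state$akg_t, u_occ, "aKG")
  akg_pool <- mix_dists(list(akg_gln, akg_cycle), c(f$f_gln, 1 - f$f_gln), "aKG")
  suc_pool <- mix_dists(c(list(suc_gln), turn_state$suc_t),
                        c(f$f_gln, (1 - f$f_gln) * u_occ), "succinate")
  glu <- as_met(prod_of(dist_apply(net, "GDH", list(akg_pool)), "glutamate"),
                "glutamate")

  dists <- list(
    glucose = glc, G6P = g6p, F6P = f6p, FBP = fbp,
    DHAP = dhap_pool, GAP = gap_pool, glycerol3P = glycerol3p, PG3 = pg3,
    pyruvate = pyr, lactate = lac, alanine = ala,
    acetylCoA = turn_state$accoa, citrate = cit_pool, aKG = akg_pool,
    succinate = as_met(suc_pool, "succinate"),
    fumarate = as_met(suc_pool, "fumarate"),
    malate = turn_state$mal_pool, OAA = oaa_pool, aspartate = asp,
    glutamate = glu, glutamine = gln)
  structure(dists, class = "iso_sim",
            oaa_by_turn = turn_state$oaa_by_turn, turn_weights = w_exit,
            fractions = f, tracer = tracer)
}

dist_l1 <- function(a, b) {
  pats <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(pats)), pats); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(pats)), pats); bv[names(b)] <- b
  sum(abs(av - bv))
}

#' @export
print.iso_sim <- function(x, ...) {
  tr <- attr(x, "tracer")
  cat(sprintf("Isotopomer simulation: tracer %s at positions %s (enrichment %.2f)\n",
              tr$metabolite, paste(tr$positions, collapse = ","), tr$enrichment))
  cat("Metabolites:", paste(names(x), collapse = ", "), "\n")
  cat("Use $<metabolite> for distributions; mid_of()/multiplets_of() for observables.\n")
  invisible(x)
}
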