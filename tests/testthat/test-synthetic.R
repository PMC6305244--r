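sc <- default_scenario()

test_that("default scenario validates and encodes the study effect structure", {
  expect_silent(validate_scenario(sc))
  expect_equal(sc$conditions$FK866_48h$mult[["NAD"]], 0.05)
  expect_gt(sc$conditions$FK866_48h_NR_4h$mult[["NAD"]], 1)
  expect_equal(sc$conditions$NR_4h$mult[["NAM"]], 9)
  expect_equal(sc$conditions$NMN_4h$mult[["NAM"]], 1.8)
  expect_equal(sc$conditions$FK866_24h$fractions$f_reverse, 0)
  expect_gt(sc$conditions$FK866_48h$fractions$f_reverse, 0)
  # deeper TCA engagement under depletion: more PC, more rounds, glutamine use
  ctl <- sc$conditions$control$fractions
  fk <- sc$conditions$FK866_48h$fractions
  expect_gt(fk$f_pc, ctl$f_pc)
  expect_lt(fk$turn_exit, ctl$turn_exit)
  expect_gt(fk$f_gln, ctl$f_gln)
  expect_equal(unname(sc$replicates), c(6L, 4L))
})

test_that("scenario invariants reject bad configurations", {
  bad <- sc; bad$cv <- -0.1
  expect_error(validate_scenario(bad), "CV")
  bad2 <- sc; bad2$conditions$control$mult <- c(NAD = -1)
  expect_error(validate_scenario(bad2), "positive")
  bad3 <- sc; bad3$control <- "nope"
  expect_error(validate_scenario(bad3), "control")
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(sc, 42)
  d2 <- generate_dataset(sc, 42)
  expect_identical(d1$concentrations, d2$concentrations)
  expect_identical(d1$mids, d2$mids)
  expect_identical(d1$multiplets, d2$multiplets)
  d3 <- generate_dataset(sc, 43)
  expect_false(identical(d1$concentrations$raw_value,
                         d3$concentrations$raw_value))
})

test_that("zero noise reproduces the noiseless simulate output exactly", {
  sc0 <- sc
  sc0$cv <- 0; sc0$pellet_cv <- 0; sc0$na_abundance <- 0
  sc0$replicates <- c(C2C12 = 2L, primary = 1L)
  ds <- generate_dataset(sc0, 5)
  sim <- simulate_labelling(tracer = sc0$tracers$glc12,
                            fractions = sc0$conditions$FK866_48h$fractions,
                            n_max_turns = sc0$n_max_turns)
  m <- ds$mids[ds$mids$condition == "FK866_48h" & ds$mids$tracer == "glc12" &
                 ds$mids$metabolite == "aspartate" & ds$mids$replicate == 1 &
                 ds$mids$cell_line == "C2C12", ]
  expect_equal(m$fraction[order(m$mass)], as.numeric(mid_of(sim$aspartate)))
  # concentrations collapse to mean * multiplier
  cc <- ds$concentrations
  nad <- cc[cc$metabolite == "NAD" & cc$condition == "FK866_48h", "raw_value"]
  expect_equal(unique(round(nad, 12)), 0.05 * sc0$control_conc[["NAD"]])
})

test_that("noisy simplex observables remain on the simplex", {
  ds <- generate_dataset(sc, 7)
  sums <- tapply(ds$mids$fraction,
                 interaction(ds$mids$cell_line, ds$mids$condition,
                             ds$mids$replicate, ds$mids$tracer,
                             ds$mids$metabolite, drop = TRUE), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(ds$mids$fraction >= 0))
  msum <- tapply(ds$multiplets$fraction,
                 interaction(ds$multiplets$cell_line, ds$multiplets$condition,
                             ds$multiplets$replicate, ds$multiplets$tracer,
                             ds$multiplets$metabolite, ds$multiplets$carbon,
                             drop = TRUE), sum)
  expect_true(all(abs(msum - 1) < 1e-9))
})

test_that("mean NAD+ depletion across seeds matches the scenario parameter", {
  ratios <- vapply(1:40, function(s) {
    ds <- generate_dataset(sc, s)
    cc <- ds$concentrations[ds$concentrations$cell_line == "C2C12" &
                              ds$concentrations$metabolite == "NAD", ]
    v <- normalize_to_pellet(cc$raw_value, cc$pellet_weight)
    mean(v[cc$condition == "FK866_48h"]) / mean(v[cc$condition == "control"])
  }, numeric(1L))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.05), 3 * se + 1e-3)
})

test_that("dataset round-trips through the CSV directory format", {
  ds <- generate_dataset(sc, 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- read_dataset(dir)
  expect_equal(back$seed, 3L)
  expect_equal(nrow(back$mids), nrow(ds$mids))
  expect_equal(back$concentrations$raw_value, ds$concentrations$raw_value)
  expect_error(read_dataset(withr::local_tempdir()), "missing dataset file")
})

test_that("end-to-end attribution recovers the depletion-induced pathway shifts", {
  ds <- generate_dataset(sc, 11)
  rules <- build_default_rulesets()$aspartate_glc12
  class_means <- function(cond) {
    mids <- ds$mids[ds$mids$tracer == "glc12" & ds$mids$cell_line == "C2C12" &
                      ds$mids$metabolite == "aspartate" &
                      ds$mids$condition == cond, ]
    mps <- ds$multiplets[ds$multiplets$tracer == "glc12" &
                           ds$multiplets$cell_line == "C2C12" &
                           ds$multiplets$metabolite == "aspartate" &
                           ds$multiplets$condition == cond, ]
    w <- sapply(sort(unique(mids$replicate)), function(r) {
      m <- mids[mids$replicate == r, ]
      mid <- nat_abundance_correct(m$fraction[order(m$mass)],
                                   sc$na_abundance)
      p <- mps[mps$replicate == r, ]
      pr <- matrix(0, 4, 5,
                   dimnames = list(paste0("C", 1:4), multiplet_components()))
      for (i in seq_len(nrow(p))) pr[p$carbon[i], p$component[i]] <- p$fraction[i]
      pr <- pr / rowSums(pr)
      fit <- resolve_isotopomers(mid, pr, "aspartate", tol = 0.05)
      attribute_patterns(coef(fit), rules)
    })
    rowMeans(w)
  }
  truth <- function(cond) {
    sim <- simulate_labelling(tracer = sc$tracers$glc12,
                              fractions = sc$conditions[[cond]]$fractions,
                              n_max_turns = sc$n_max_turns)
    attribute_patterns(sim$aspartate, rules)
  }
  ctl <- class_means("control"); ctl_true <- truth("control")
  fk <- class_means("FK866_48h"); fk_true <- truth("FK866_48h")
  # estimated class means track the generator's noiseless truth
  expect_lt(max(abs(ctl - unclass(ctl_true))), 0.08)
  expect_lt(max(abs(fk - unclass(fk_true))), 0.08)
  # and the depletion-induced shifts come out with the correct sign for
  # every materially shifted class (deeper TCA engagement, less unlabelled
  # dilution of the labelled pool, more multi-round patterns)
  shift_true <- unclass(fk_true) - unclass(ctl_true)
  shift_est <- fk - ctl
  big <- abs(shift_true) > 0.03
  expect_true(any(big))
  expect_true(all(sign(shift_est[big]) == sign(shift_true[big])))
  expect_gt(fk[["tca_rounds_ppp"]], ctl[["tca_rounds_ppp"]])
  # reverse-glycolysis marker: absent in control, present at 48 h
  f6p_mid <- function(cond) {
    m <- ds$multiplets[ds$multiplets$metabolite == "F6P" &
                         ds$multiplets$cell_line == "C2C12" &
                         ds$multiplets$condition == cond &
                         ds$multiplets$carbon == 5 &
                         ds$multiplets$component == "unlabelled", ]
    mean(1 - m$fraction)   # carbon-5 labelled fraction, straight off the HSQC
  }
  expect_lt(f6p_mid("control"), 0.02)
  expect_gt(f6p_mid("FK866_48h"), 0.05)
})

test_that("Dunnett flags the scenario's headline effects at study size", {
  ds <- generate_dataset(sc, 13)
  cc <- ds$concentrations[ds$concentrations$cell_line == "C2C12", ]
  cc$value <- normalize_to_pellet(cc$raw_value, cc$pellet_weight)
  for (met in c("NAD", "aspartate", "GAP")) {
    d <- cc[cc$metabolite == met, ]
    res <- anova_dunnett(d$value, d$condition, "control")
    p <- res$comparisons$p_adj[res$comparisons$comparison == "FK866_48h - control"]
    expect_lt(p, 0.05)
  }
})

test_that("power for the 95% NAD+ depletion exceeds 0.9 at n = 6, CV = 0.15", {
  hits <- vapply(1:200, function(s) {
    ds <- generate_dataset(sc, 1000L + s)
    cc <- ds$concentrations[ds$concentrations$cell_line == "C2C12" &
                              ds$concentrations$metabolite == "NAD", ]
    cc$value <- normalize_to_pellet(cc$raw_value, cc$pellet_weight)
    res <- anova_dunnett(cc$value, cc$condition, "control")
    res$comparisons$p_adj[
      res$comparisons$comparison == "FK866_48h - control"] < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})
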