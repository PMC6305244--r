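rules <- build_default_rulesets()
net <- build_default_network()

test_that("default rule sets carry the printed pattern classes", {
  asp <- rules$aspartate_glc12
  expect_setequal(asp$classes$glycolysis, c("1100", "0011"))
  expect_setequal(asp$classes$tca_rounds_ppp,
                  c("0100", "0010", "1111", "0111", "1110", "1000", "0001"))
  expect_equal(asp$classes$pc, "0110")
  lac <- rules$lactate_glc12
  expect_equal(lac$classes$glycolysis, "011")
  expect_equal(lac$classes$ppp, "001")
})

test_that("rule-set invariants hold and violations are rejected", {
  for (rs in rules) {
    all_pat <- unlist(rs$classes)
    expect_false(anyDuplicated(all_pat) > 0)
    expect_false(strrep("0", rs$n_carbons) %in% all_pat)
  }
  expect_error(pattern_ruleset("x", list(a = "110", b = "110")), "disjoint")
  expect_error(pattern_ruleset("x", list(a = c("110", "000"))), "all-zero")
  expect_error(pattern_ruleset("x", list(other = "110")), "collides")
})

test_that("glutamine multi-round class equals the oracle enumeration", {
  # independent enumeration: entry OAA 1111; acetyl pool gains glutamine-
  # derived species via malic enzyme each round
  oracle_multiround <- local({
    oaa <- "1111"; acc <- "00"; seen <- character()
    for (k in 1:2) {
      acc <- unique(c(acc, vapply(oaa, function(m)
        oracle_pdh(substr(m, 1, 3)), character(1L))))
      nxt <- character()
      for (o4 in oaa) for (a2 in acc) {
        nxt <- c(nxt, oracle_turn_patterns(o4, a2))
      }
      oaa <- unique(nxt); seen <- unique(c(seen, oaa))
    }
    sort(seen[omass(seen) %in% c(2, 3)])
  })
  expect_setequal(rules$aspartate_glnU$classes$multi_round, oracle_multiround)
  expect_true(all(c("0111", "1110") %in% oracle_multiround))
})

test_that("attribution sums class weights, never dropping patterns", {
  d <- iso_dist(c("1100" = 0.3, "0011" = 0.3, "0110" = 0.2, "0000" = 0.2))
  a <- attribute_patterns(d, rules$aspartate_glc12)
  expect_equal(a[["glycolysis"]], 0.6)
  expect_equal(a[["pc"]], 0.2)
  expect_equal(a[["unlabelled"]], 0.2)
  expect_equal(sum(a), 1)

  a0 <- attribute_patterns(iso_dist(c("0000" = 1)), rules$aspartate_glc12)
  expect_equal(a0[["unlabelled"]], 1)

  # a pattern outside every class lands in "other"
  a1 <- attribute_patterns(iso_dist(c("1010" = 0.4, "0000" = 0.6)),
                           rules$aspartate_glc12)
  expect_equal(a1[["other"]], 0.4)
  expect_equal(sum(a1), 1)
})

test_that("attribution weights are nonnegative and sum to 1 on random input", {
  set.seed(52)
  for (rep in 1:20) {
    ps <- sample(all_patterns(4), sample(2:16, 1))
    w <- stats::rgamma(length(ps), 1); w <- w / sum(w)
    a <- attribute_patterns(iso_dist(stats::setNames(w, ps)),
                            rules$aspartate_glc12)
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1)
  }
})

test_that("lactate classes recover the glycolysis/PPP split of a simulation", {
  e <- 0.8
  sim <- simulate_labelling(net, tracer_glc12(e), pathway_fractions())
  a <- attribute_patterns(sim$lactate, rules$lactate_glc12)
  # from [1,2-13C]glucose only the DHAP-derived triose carries label, so the
  # glycolytic m+2 lactate fraction is enrichment/2
  expect_equal(a[["glycolysis"]], e / 2, tolerance = 1e-12)
  expect_equal(a[["ppp"]], 0)
  simp <- simulate_labelling(net, tracer_glc12(1),
                             pathway_fractions(f_oxppp = 0.5))
  ap <- attribute_patterns(simp$lactate, rules$lactate_glc12)
  expect_gt(ap[["ppp"]], 0)
})

test_that("reverse-glycolysis marker reads carbon 5", {
  expect_equal(detect_reverse_glycolysis(iso_dist(c("000010" = 1))), 1)
  sim0 <- simulate_labelling(net, tracer_glc12(), pathway_fractions())
  expect_equal(detect_reverse_glycolysis(sim0$F6P), 0)
  simr <- simulate_labelling(net, tracer_glc12(),
                             pathway_fractions(f_reverse = 0.2))
  expect_gt(detect_reverse_glycolysis(simr$F6P), 0)
  expect_error(detect_reverse_glycolysis(iso_dist(c("0110" = 1))), "6-carbon")
})

test_that("marker response is monotone in reverse flux at random settings", {
  set.seed(61)
  for (rep in 1:8) {
    fr0 <- stats::runif(1, 0, 0.45)
    fr1 <- fr0 + stats::runif(1, 0.05, 0.5)
    base <- list(f_oxppp = stats::runif(1, 0, 0.3), f_pc = stats::runif(1),
                 turn_exit = stats::runif(1, 0.1, 1))
    s0 <- simulate_labelling(net, tracer_glc12(),
                             do.call(pathway_fractions,
                                     c(base, f_reverse = fr0)))
    s1 <- simulate_labelling(net, tracer_glc12(),
                             do.call(pathway_fractions,
                                     c(base, f_reverse = fr1)))
    expect_gte(detect_reverse_glycolysis(s1$F6P),
               detect_reverse_glycolysis(s0$F6P))
  }
})

test_that("noiseless round trips recover the exact distribution", {
  d <- iso_dist(c("0110" = 1), "aspartate")
  fit <- resolve_isotopomers(mid_of(d), multiplets_of(d), "aspartate")
  expect_equal(coef(fit)[["0110"]], 1, tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-8)
  expect_false(fit$non_unique)

  d2 <- iso_dist(c("1100" = 0.5, "0011" = 0.5))
  fit2 <- resolve_isotopomers(mid_of(d2), multiplets_of(d2))
  expect_equal(coef(fit2)[["1100"]], 0.5, tolerance = 1e-9)
  expect_equal(coef(fit2)[["0011"]], 0.5, tolerance = 1e-9)
  expect_lt(fit2$residual_norm, 1e-8)
})

test_that("resolve residual vanishes on any forward-generated observables", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(3:4, 1)
    ps <- sample(all_patterns(n), sample(2:6, 1))
    w <- stats::rgamma(length(ps), 1); w <- w / sum(w)
    d <- iso_dist(stats::setNames(w, ps))
    fit <- resolve_isotopomers(mid_of(d), multiplets_of(d))
    expect_lt(fit$residual_norm, 1e-8)
  }
})

test_that("unidentifiable observables raise the non-uniqueness flag", {
  # the 4-carbon design has a 3-dimensional nullspace; an interior
  # distribution admits feasible flat directions
  u <- iso_dist(stats::setNames(rep(1 / 16, 16), all_patterns(4)))
  fit <- resolve_isotopomers(mid_of(u), multiplets_of(u))
  expect_equal(fit$nullspace_dim, 3L)
  expect_true(fit$non_unique)
  # and pathway-class weights are nonetheless invariant: any exact solution
  # attributes identically
  a_true <- attribute_patterns(u, rules$aspartate_glc12)
  a_fit <- attribute_patterns(coef(fit), rules$aspartate_glc12)
  expect_equal(unclass(a_fit), unclass(a_true), tolerance = 1e-8)
})

test_that("class functionals are orthogonal to the observability nullspace", {
  A <- observable_design(4)
  sv <- svd(rbind(A, 1))
  null_dim <- sum(sv$d < 1e-9 * sv$d[1])
  expect_equal(null_dim, 3L)
  N <- sv$v[, seq(ncol(sv$v) - null_dim + 1, ncol(sv$v)), drop = FALSE]
  ps <- all_patterns(4)
  classes <- c(rules$aspartate_glc12$classes,
               list(unlabelled = "0000",
                    other = setdiff(ps, c(unlist(rules$aspartate_glc12$classes),
                                          "0000"))))
  for (nm in names(classes)) {
    ind <- as.numeric(ps %in% classes[[nm]])
    expect_lt(max(abs(t(ind) %*% N)), 1e-9)
  }
})

test_that("infeasible observables produce explicit errors", {
  d <- iso_dist(c("0110" = 1))
  m <- mid_of(d); mp <- multiplets_of(d)
  bad_mid <- as.numeric(m); bad_mid[1] <- bad_mid[1] + 0.2
  expect_error(resolve_isotopomers(bad_mid, mp), "sum to 1")
  neg_mid <- as.numeric(m); neg_mid[1] <- -0.2; neg_mid[3] <- 1.2
  expect_error(resolve_isotopomers(neg_mid, mp), "negative")
  bad_mp <- unclass(mp); bad_mp[1, "doublet_lower"] <- 0.5
  bad_mp[1, "unlabelled"] <- 0.5
  expect_error(resolve_isotopomers(as.numeric(m), bad_mp), "terminal")
})

test_that("rule sets round-trip through the text format", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_ruleset(rules$aspartate_glc12, f)
  back <- read_ruleset(f)
  expect_equal(back$metabolite, "aspartate")
  expect_equal(back$classes, rules$aspartate_glc12$classes)
  expect_error(read_ruleset(tempfile()), "not found")
})
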