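# Inversion of observables (GC-MS MID + NMR multiplet profile) back to
# positional isotopomers, and assignment of patterns to pathway classes.

#' Pathway pattern rule set
#'
#' A rule set partitions the labelled patterns of one metabolite into named
#' pathway classes. Patterns in no class are counted under `residual_class`;
#' the all-zero pattern is always its own "unlabelled" class and may not
#' appear in any labelled class.
#'
#' @param metabolite metabolite name.
#' @param classes named list; each element a character vector of pattern
#'   strings. Classes must be pairwise disjoint.
#' @param residual_class name under which unclassified labelled patterns are
#'   reported (default `"other"`).
#' @return an object of class `pattern_ruleset`.
#' @examples
#' pattern_ruleset("aspartate",
#'                 list(glycolysis = c("1100", "0011"), pc = "0110"))
#' @export
pattern_ruleset <- function(metabolite, classes, residual_class = "other") {
  stopifnot(is.list(classes), !is.null(names(classes)), all(nzchar(names(classes))))
  n <- unique(nchar(unlist(classes)))
  if (length(n) != 1L) stop("all patterns in a rule set must have equal length",
                            call. = FALSE)
  all <- unlist(classes)
  if (anyDuplicated(all)) {
    stop("pattern classes must be pairwise disjoint; duplicated: ",
         paste(unique(all[duplicated(all)]), collapse = ", "), call. = FALSE)
  }
  if (strrep("0", n) %in% all) {
    stop("the all-zero pattern belongs to the implicit 'unlabelled' class",
         call. = FALSE)
  }
  if (residual_class %in% c(names(classes), "unlabelled")) {
    stop("residual class name collides with a class name", call. = FALSE)
  }
  for (p in all) check_pattern(p, n)
  structure(list(metabolite = metabolite, n_carbons = n, classes = classes,
                 residual_class = residual_class), class = "pattern_ruleset")
}

#' @export
print.pattern_ruleset <- function(x, ...) {
  cat(sprintf("Pattern rule set for %s (%d carbons)\n", x$metabolite, x$n_carbons))
  for (nm in names(x$classes)) {
    cat(sprintf("  %-16s %s\n", nm, paste(x$classes[[nm]], collapse = " ")))
  }
  cat(sprintf("  (+ 'unlabelled' and residual '%s')\n", x$residual_class))
  invisible(x)
}

#' Serialise rule sets to a small text format
#'
#' One class per line: `class name: pattern, pattern, ...`; a header line
#' `metabolite: <name>`. Round-trips through [read_ruleset()].
#'
#' @param rules a [pattern_ruleset()].
#' @param path file path.
#' @export
write_ruleset <- function(rules, path) {
  lines <- c(paste0("metabolite: ", rules$metabolite),
             paste0("residual: ", rules$residual_class),
             vapply(names(rules$classes), function(nm)
               paste0(nm, ": ", paste(rules$classes[[nm]], collapse = ", ")),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop("rule-set file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*:\\s*")
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", character(1L))
  met <- vals[keys == "metabolite"]
  res <- if ("residual" %in% keys) vals[keys == "residual"] else "other"
  cls <- keys != "metabolite" & keys != "residual"
  classes <- lapply(vals[cls], function(v) strsplit(v, "\\s*,\\s*")[[1L]])
  names(classes) <- keys[cls]
  pattern_ruleset(met, classes, residual_class = res)
}

#' Default pathway rule sets for the [1,2-13C]glucose and [U-13C]glutamine arms
#'
#' Ships three rule sets keyed `aspartate_glc12`, `lactate_glc12` and
#' `aspartate_glnU`:
#' \itemize{
#' \item aspartate / [1,2-13C]glucose: glycolysis `1100 + 0011` (PDH acetyl
#'   units through one round with succinate/fumarate scrambling); TCA rounds +
#'   PPP `0100 + 0010, 1111, 0111 + 1110, 1000 + 0001`; pyruvate carboxylase
#'   `0110`.
#' \item lactate / [1,2-13C]glucose: glycolysis = carbons 2,3 labelled
#'   (`011`); oxidative PPP = carbon 3 only (`001`), the standard
#'   [1,2-13C]glucose logic (loss of glucose C1 as CO2 leaves a single label
#'   that ends on lactate C3).
#' \item aspartate / [U-13C]glutamine: first pass `1111`; multi-round = the
#'   m+2 and m+3 patterns reachable after two or more rounds (enumerated from
#'   the atom maps; includes the scrambling pairs `1100/0011`, `0101/1010`,
#'   `0110/1001` and the m+3 sets `0111/1110`, `1011/1101`).
#' }
#' @return named list of [pattern_ruleset()] objects.
#' @export
build_default_rulesets <- function() {
  list(
    aspartate_glc12 = pattern_ruleset(
      "aspartate",
      list(glycolysis = c("1100", "0011"),
           tca_rounds_ppp = c("0100", "0010", "1111", "0111", "1110",
                              "1000", "0001"),
           pc = "0110")),
    lactate_glc12 = pattern_ruleset(
      "lactate",
      list(glycolysis = "011", ppp = "001")),
    aspartate_glnU = pattern_ruleset(
      "aspartate",
      list(first_pass = "1111",
           multi_round = enumerate_gln_multiround_patterns()))
  )
}

#' Enumerate multi-round aspartate patterns under [U-13C]glutamine
#'
#' Support-level enumeration from the default atom maps: starting from the
#' glutamine-derived oxaloacetate (`1111` after the first span of the cycle),
#' propagates two further rounds in which the acetyl-CoA pool may be either
#' unlabelled (glucose-derived) or glutamine-derived via malic-enzyme
#' pyruvate recycling, and collects the mass-2 and mass-3 aspartate patterns.
#'
#' @param net an `atom_network`.
#' @param turns number of additional rounds enumerated (default 2).
#' @return sorted character vector of patterns with mass 2 or 3.
#' @export
enumerate_gln_multiround_patterns <- function(net = build_default_network(),
                                              turns = 2L) {
  # acetyl-CoA supports: unlabelled, and glutamine-derived via ME recycling
  oaa_support <- "1111"
  acc_support <- "00"
  seen <- character()
  for (k in seq_len(turns)) {
    nxt <- character()
    # malic-enzyme recycling: this round's OAA-equivalent malate feeds pyruvate
    acc_new <- acc_support
    for (m in oaa_support) {
      pyr <- vapply(apply_reaction(net, "ME", m),
                    function(o) o$products[["pyruvate.1"]], character(1L))
      for (p in pyr) {
        acc_new <- c(acc_new, vapply(apply_reaction(net, "PDH", p),
                                     function(o) o$products[["acetylCoA.1"]],
                                     character(1L)))
      }
    }
    acc_support <- unique(acc_new)
    for (o4 in oaa_support) for (a2 in acc_support) {
      for (oc in apply_reaction(net, "CS", c(o4, a2))) {
        cit <- oc$products[["citrate.1"]]
        for (oi in apply_reaction(net, "IDH", cit)) {
          akg <- oi$products[["aKG.1"]]
          for (oa in apply_reaction(net, "AKGDH", akg)) {
            nxt <- c(nxt, oa$products[["succinate.1"]])
          }
        }
      }
    }
    oaa_support <- unique(nxt)   # succinate/fumarate/malate/OAA: carbons 1:1
    seen <- unique(c(seen, oaa_support))
  }
  sort(seen[pattern_mass(seen) %in% c(2L, 3L)])
}

#' Attribute an isotopomer distribution to pathway classes
#'
#' Each class weight is the summed fraction of its patterns; the all-zero
#' pattern is reported as `unlabelled` and labelled patterns outside every
#' class under the rule set's residual class (never silently dropped).
#' Weights sum to 1.
#'
#' @param dist an [iso_dist()].
#' @param rules a [pattern_ruleset()] for the same metabolite size.
#' @return named numeric vector of class weights, class `pathway_attribution`.
#' @examples
#' d <- iso_dist(c("1100" = 0.3, "0011" = 0.3, "0110" = 0.2, "0000" = 0.2))
#' attribute_patterns(d, build_default_rulesets()$aspartate_glc12)
#' @export
attribute_patterns <- function(dist, rules) {
  stopifnot(inherits(dist, "iso_dist"), inherits(rules, "pattern_ruleset"))
  n <- dist_n_carbons(dist)
  if (n != rules$n_carbons) {
    stop(sprintf("rule set is for %d carbons, distribution has %d",
                 rules$n_carbons, n), call. = FALSE)
  }
  out <- stats::setNames(numeric(length(rules$classes) + 2L),
                         c(names(rules$classes), "unlabelled",
                           rules$residual_class))
  zero <- strrep("0", n)
  for (p in names(dist)) {
    w <- dist[[p]]
    if (p == zero) { out["unlabelled"] <- out["unlabelled"] + w; next }
    hit <- FALSE
    for (nm in names(rules$classes)) {
      if (p %in% rules$classes[[nm]]) {
        out[nm] <- out[nm] + w; hit <- TRUE; break
      }
    }
    if (!hit) out[rules$residual_class] <- out[rules$residual_class] + w
  }
  structure(out, metabolite = rules$metabolite, class = "pathway_attribution")
}

#' @export
print.pathway_attribution <- function(x, digits = 4, ...) {
  cat("Pathway attribution",
      if (!is.null(attr(x, "metabolite"))) paste0("for ", attr(x, "metabolite")),
      "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Reverse-glycolysis marker: label in fructose-6-phosphate carbon 5
#'
#' Under forward-only flux from [1,2-13C]glucose no route places 13C on F6P
#' carbon 5; label there can only arrive by labelled triose phosphates running
#' aldolase/TPI backwards (the signature of an NAD+-dependent GAPDH block).
#'
#' @param f6p_dist a 6-carbon [iso_dist()].
#' @param carbon marker carbon position (default 5).
#' @return total weight of patterns with the marker carbon labelled.
#' @export
detect_reverse_glycolysis <- function(f6p_dist, carbon = 5L) {
  stopifnot(inherits(f6p_dist, "iso_dist"))
  if (dist_n_carbons(f6p_dist) != 6L) {
    stop("expected a 6-carbon fructose-6-phosphate distribution", call. = FALSE)
  }
  lab <- vapply(names(f6p_dist),
                function(p) substr(p, carbon, carbon) == "1", logical(1L))
  sum(f6p_dist[lab])
}

## --------------------------------------------------------------------------
## Constrained least-squares inversion

#' Forward design matrix mapping isotopomer fractions to observables
#'
#' Rows are the stacked observables (MID entries `m+0..m+n`, then the five
#' multiplet components per carbon); columns are the `2^n` patterns from
#' [all_patterns()]. Both [mid_of()] and [multiplets_of()] are linear in the
#' distribution, so observables equal `A %*% x`.
#'
#' @param n number of carbons.
#' @return a `(n + 1 + 5 n) x 2^n` matrix.
#' @export
observable_design <- function(n) {
  ps <- all_patterns(n)
  comp <- multiplet_components()
  A <- matrix(0, (n + 1L) + 5L * n, length(ps),
              dimnames = list(c(paste0("m+", 0:n),
                                paste0(rep(paste0("C", 1:n), each = 5L), ".",
                                       rep(comp, n))), ps))
  for (j in seq_along(ps)) {
    b <- pattern_bits(ps[j])
    A[sum(b) + 1L, j] <- 1
    for (k in 1:n) {
      if (b[k] == 0L) { A[(n + 1L) + (k - 1L) * 5L + 1L, j] <- 1; next }
      lo <- if (k > 1L) b[k - 1L] else 0L
      hi <- if (k < n) b[k + 1L] else 0L
      c_i <- if (lo == 0L && hi == 0L) 2L else if (lo == 1L && hi == 0L) 3L
             else if (lo == 0L && hi == 1L) 4L else 5L
      A[(n + 1L) + (k - 1L) * 5L + c_i, j] <- 1
    }
  }
  A
}

check_simplex <- function(x, what, tol = 1e-6) {
  if (any(x < -tol)) {
    stop(what, " has negative entries beyond tolerance", call. = FALSE)
  }
  if (abs(sum(x) - 1) > max(tol, 1e-6)) {
    stop(what, " does not sum to 1 (got ", format(sum(x)), ")", call. = FALSE)
  }
  invisible(x)
}

#' Resolve positional isotopomers from combined MID and multiplet data
#'
#' Finds the isotopomer distribution minimising the squared residual against
#' both observables jointly (forward maps [mid_of()] and [multiplets_of()]),
#' subject to nonnegativity and sum-to-one, by Lawson-Hanson nonnegative
#' least squares with an augmented sum-to-one row. When the observables admit
#' more than one exact solution (the design matrix has feasible nullspace
#' directions at the optimum) the fit is flagged non-unique rather than
#' hidden; for 4-carbon metabolites the pathway-class weights of
#' [build_default_rulesets()] are invariant along every such direction, so
#' attribution remains well defined.
#'
#' @param mid numeric MID vector (`m+0..m+n`), natural-abundance corrected.
#' @param multiplets an `n x 5` multiplet profile matrix with columns
#'   [multiplet_components()] (rows may be any carbon order `C1..Cn`).
#' @param metabolite optional name carried through to the result.
#' @param tol feasibility tolerance on the input simplex constraints.
#' @return an object of class `isotopomer_fit` with methods `print`,
#'   `summary`, `coef` (the fitted [iso_dist()]), `fitted` (reproduced
#'   observables) and `residuals`. Fields: `distribution`, `residual_norm`,
#'   `non_unique`, `nullspace_dim`.
#' @examples
#' d <- iso_dist(c("0110" = 1), "aspartate")
#' fit <- resolve_isotopomers(mid_of(d), multiplets_of(d), "aspartate")
#' coef(fit)
#' @export
resolve_isotopomers <- function(mid, multiplets, metabolite = NULL,
                                tol = 1e-6) {
  mid <- as.numeric(mid)
  n <- length(mid) - 1L
  mp <- unclass(multiplets)
  if (!is.matrix(mp) || nrow(mp) != n || ncol(mp) != 5L) {
    stop("multiplet profile must be an n x 5 matrix matching the MID length",
         call. = FALSE)
  }
  check_simplex(mid, "MID", tol)
  for (k in 1:n) check_simplex(mp[k, ], paste0("multiplet row C", k), tol)
  if (n > 1L) {
    if (mp[1L, "doublet_lower"] > tol || mp[1L, "doublet_of_doublets"] > tol ||
        mp[n, "doublet_higher"] > tol || mp[n, "doublet_of_doublets"] > tol) {
      stop("terminal carbons cannot show the inner doublet components",
           call. = FALSE)
    }
  }
  y <- c(mid, as.numeric(t(mp)))
  A <- observable_design(n)
  lambda <- 10
  C <- rbind(A, lambda)
  d <- c(y, lambda)
  sol <- pracma::lsqnonneg(C, d)
  x <- pmax(sol$x, 0)
  if (sum(x) <= 0) stop("inversion failed: empty solution", call. = FALSE)
  x <- x / sum(x)
  resid <- as.numeric(A %*% x) - y
  names(resid) <- rownames(A)
  # nullspace of the constrained forward operator
  sv <- svd(rbind(A, 1))
  null_dim <- sum(sv$d < 1e-9 * sv$d[1L])
  non_unique <- FALSE
  if (null_dim > 0L) {
    N <- sv$v[, seq(ncol(sv$v) - null_dim + 1L, ncol(sv$v)), drop = FALSE]
    active <- which(x < 1e-9)
    non_unique <- if (length(active) == 0L) TRUE else {
      feasible_null_direction(N, active)
    }
  }
  names(x) <- colnames(A)
  dist <- iso_dist(x[x > 0], metabolite = metabolite)
  structure(list(distribution = dist,
                 residual_norm = sqrt(sum(resid^2)),
                 residuals = resid,
                 non_unique = non_unique,
                 nullspace_dim = null_dim,
                 observed = y, design = A, metabolite = metabolite),
            class = "isotopomer_fit")
}

# Is there a nonzero v in span(N) with v >= 0 on the active (zero) coords?
# Maximises min(v[active]) / max|v| over the nullspace by quasi-Newton from
# deterministic starts; conservative within ~1e-8.
feasible_null_direction <- function(N, active) {
  d <- ncol(N)
  obj <- function(z) {
    v <- as.numeric(N %*% z)
    s <- max(abs(v))
    if (s < 1e-12) return(1)           # degenerate direction: penalise
    -min(v[active]) / s
  }
  starts <- rbind(diag(d), -diag(d))
  if (d > 1L) {
    extra <- matrix(sin(seq_len(20L * d) * 1.7), ncol = d)  # fixed spread
    starts <- rbind(starts, extra)
  }
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- try(stats::optim(starts[i, ], obj, method = "BFGS",
                          control = list(maxit = 200)), silent = TRUE)
    if (!inherits(r, "try-error")) best <- min(best, r$value)
    if (best < -1e-8) break
  }
  best < 1e-10   # min(v[active]) >= -1e-10 * scale => feasible direction
}

#' @export
print.isotopomer_fit <- function(x, digits = 4, ...) {
  cat("Isotopomer fit",
      if (!is.null(x$metabolite)) paste0("for ", x$metabolite), "\n")
  cat(sprintf("  residual norm: %.3e   non-unique: %s (nullspace dim %d)\n",
              x$residual_norm, x$non_unique, x$nullspace_dim))
  print(x$distribution, digits = digits)
  invisible(x)
}

#' @export
summary.isotopomer_fit <- function(object, ...) {
  cat("Constrained least-squares isotopomer fit\n")
  print(object)
  cat("Largest absolute observable residuals:\n")
  r <- sort(abs(object$residuals), decreasing = TRUE)
  print(round(utils::head(r, 5L), 8))
  invisible(object)
}

#' @export
coef.isotopomer_fit <- function(object, ...) object$distribution

#' @export
fitted.isotopomer_fit <- function(object, ...) {
  x <- stats::setNames(numeric(ncol(object$design)), colnames(object$design))
  x[names(object$distribution)] <- object$distribution
  stats::setNames(as.numeric(object$design %*% x), rownames(object$design))
}

#' @export
residuals.isotopomer_fit <- function(object, ...) object$residuals
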