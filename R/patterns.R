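# Positional isotopomer patterns are binary strings, carbon 1 first:
# "1" = 13C, "0" = 12C.  "0110" is a 4-carbon molecule labelled at C2 and C3.

#' Enumerate all labelling patterns of an n-carbon molecule
#'
#' @param n number of carbons.
#' @return character vector of the `2^n` binary pattern strings, carbon 1
#'   first, ordered by their binary value.
#' @examples
#' all_patterns(2)
#' @export
all_patterns <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  g <- expand.grid(rep(list(0:1), n))[, n:1, drop = FALSE]
  apply(g, 1L, paste, collapse = "")
}

#' @rdname all_patterns
#' @param pattern a pattern string such as `"0110"`.
#' @return `pattern_bits()`: integer vector of 0/1 bits; `pattern_mass()`:
#'   the number of labelled carbons.
#' @export
pattern_bits <- function(pattern) {
  as.integer(strsplit(pattern, "", fixed = TRUE)[[1L]])
}

#' @rdname all_patterns
#' @export
pattern_mass <- function(pattern) {
  vapply(strsplit(pattern, "", fixed = TRUE),
         function(b) sum(b == "1"), integer(1L))
}

check_pattern <- function(pattern, n = NULL) {
  if (!is.character(pattern) || length(pattern) != 1L ||
      grepl("[^01]", pattern)) {
    stop("a carbon pattern must be a single string of 0s and 1s", call. = FALSE)
  }
  if (!is.null(n) && nchar(pattern) != n) {
    stop(sprintf("pattern '%s' has %d carbons, expected %d",
                 pattern, nchar(pattern), n), call. = FALSE)
  }
  invisible(pattern)
}

#' Positional isotopomer distribution
#'
#' An isotopomer distribution assigns a fraction of a metabolite pool to each
#' positional labelling pattern. Weights below `prune` are dropped and the
#' remainder renormalised, which keeps supports small during simulation.
#'
#' @param weights named numeric vector; names are pattern strings of equal
#'   length, values are nonnegative and sum to 1 (within `1e-9` before
#'   pruning).
#' @param metabolite optional metabolite name, kept as an attribute.
#' @param prune weights strictly below this are removed (default `1e-12`).
#' @return an object of class `iso_dist`: a named numeric vector summing to 1.
#' @examples
#' iso_dist(c("1100" = 0.5, "0011" = 0.5), "aspartate")
#' @export
iso_dist <- function(weights, metabolite = NULL, prune = 1e-12) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("isotopomer weights must be named by pattern strings", call. = FALSE)
  }
  nc <- unique(nchar(names(weights)))
  if (length(nc) != 1L) stop("all patterns must have equal length", call. = FALSE)
  if (any(grepl("[^01]", names(weights)))) {
    stop("patterns may contain only 0 and 1", call. = FALSE)
  }
  if (any(weights < -1e-12)) stop("isotopomer weights must be nonnegative", call. = FALSE)
  weights <- pmax(weights, 0)
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("isotopomer weights must sum to 1 (got %.12f)", s), call. = FALSE)
  }
  weights <- tapply(weights, names(weights), sum)   # merge duplicate patterns
  weights <- weights[weights >= prune]
  weights <- weights / sum(weights)
  w <- as.numeric(weights)
  names(w) <- names(weights)
  w <- w[order(names(w))]
  structure(w, metabolite = metabolite, class = "iso_dist")
}

#' @export
print.iso_dist <- function(x, digits = 4, ...) {
  met <- attr(x, "metabolite")
  cat("Isotopomer distribution",
      if (!is.null(met)) paste0("for ", met), "\n")
  df <- data.frame(pattern = names(x), mass = pattern_mass(names(x)),
                   fraction = round(as.numeric(x), digits))
  print(df, row.names = FALSE)
  invisible(x)
}

dist_n_carbons <- function(dist) nchar(names(dist)[1L])

# Mix several iso_dists (same metabolite size) with the given weights.
mix_dists <- function(dists, weights, metabolite = NULL) {
  stopifnot(length(dists) == length(weights))
  keep <- weights > 0
  dists <- dists[keep]; weights <- weights[keep]
  weights <- weights / sum(weights)
  acc <- list()
  for (i in seq_along(dists)) {
    d <- dists[[i]]
    for (p in names(d)) acc[[p]] <- (acc[[p]] %||% 0) + weights[i] * d[[p]]
  }
  iso_dist(unlist(acc), metabolite = metabolite)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unlabelled_dist <- function(n, metabolite = NULL) {
  iso_dist(stats::setNames(1, strrep("0", n)), metabolite = metabolite)
}

#' Mass isotopomer distribution of an isotopomer distribution
#'
#' Collapses positional information to the GC-MS observable: `fractions[k+1]`
#' is the total weight of patterns carrying `k` labelled carbons.
#'
#' @param dist an [iso_dist()].
#' @return an object of class `mid`: numeric vector of length `n + 1` named
#'   `m+0 ... m+n`, summing to 1.
#' @examples
#' mid_of(iso_dist(c("1100" = 0.5, "0000" = 0.5)))
#' @export
mid_of <- function(dist) {
  stopifnot(inherits(dist, "iso_dist"))
  n <- dist_n_carbons(dist)
  out <- numeric(n + 1L)
  m <- pattern_mass(names(dist))
  for (i in seq_along(dist)) out[m[i] + 1L] <- out[m[i] + 1L] + dist[[i]]
  names(out) <- paste0("m+", 0:n)
  structure(out, metabolite = attr(dist, "metabolite"), class = "mid")
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  met <- attr(x, "metabolite")
  cat("MID", if (!is.null(met)) paste0("for ", met), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Multiplet components reported by the profile
#'
#' Column order used by [multiplets_of()] and [resolve_isotopomers()]:
#' a carbon is either unlabelled, or (conditional on being 13C) classified by
#' the labelling of its chain neighbours into singlet, doublet with the
#' lower-numbered neighbour, doublet with the higher-numbered neighbour, or
#' doublet of doublets.
#' @export
multiplet_components <- function() {
  c("unlabelled", "singlet", "doublet_lower", "doublet_higher",
    "doublet_of_doublets")
}

#' NMR multiplet profile of an isotopomer distribution
#'
#' Pattern-level bookkeeping of the 2D-1H,13C-HSQC observable: for every
#' carbon position, the fractions of the pool in which that carbon is
#' unlabelled, or labelled with 0/1/2 labelled chain neighbours (13C-13C
#' one-bond coupling splits the signal into a singlet, a doublet towards the
#' lower- or higher-numbered neighbour, or a doublet of doublets). Fractions
#' are of the total pool, so each carbon's row sums to 1. Terminal carbons
#' have structural zeros in the impossible doublet component.
#'
#' @param dist an [iso_dist()].
#' @return an object of class `multiplet_profile`: an `n x 5` matrix, rows
#'   `C1..Cn`, columns [multiplet_components()].
#' @examples
#' multiplets_of(iso_dist(c("011" = 1)))
#' @export
multiplets_of <- function(dist) {
  stopifnot(inherits(dist, "iso_dist"))
  n <- dist_n_carbons(dist)
  comp <- multiplet_components()
  prof <- matrix(0, n, 5L, dimnames = list(paste0("C", 1:n), comp))
  for (i in seq_along(dist)) {
    b <- pattern_bits(names(dist)[i])
    w <- dist[[i]]
    for (k in 1:n) {
      if (b[k] == 0L) { prof[k, "unlabelled"] <- prof[k, "unlabelled"] + w; next }
      lo <- if (k > 1L) b[k - 1L] else 0L
      hi <- if (k < n) b[k + 1L] else 0L
      j <- if (lo == 0L && hi == 0L) "singlet"
           else if (lo == 1L && hi == 0L) "doublet_lower"
           else if (lo == 0L && hi == 1L) "doublet_higher"
           else "doublet_of_doublets"
      prof[k, j] <- prof[k, j] + w
    }
  }
  structure(prof, metabolite = attr(dist, "metabolite"),
            class = c("multiplet_profile", "matrix"))
}

#' @export
print.multiplet_profile <- function(x, digits = 4, ...) {
  met <- attr(x, "metabolite")
  cat("HSQC multiplet profile", if (!is.null(met)) paste0("for ", met), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write simulated observables to tidy CSV
#'
#' Shared schemas: distributions have columns `metabolite,pattern,fraction`;
#' MIDs `metabolite,mass,fraction`; multiplet profiles
#' `metabolite,carbon,component,fraction`.
#'
#' @param dists named list of [iso_dist()] objects.
#' @param path output file.
#' @return the data frame written, invisibly.
#' @export
write_distributions_csv <- function(dists, path) {
  rows <- lapply(names(dists), function(m) {
    d <- dists[[m]]
    data.frame(metabolite = m, pattern = names(d),
               fraction = as.numeric(d), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' @rdname write_distributions_csv
#' @export
write_mids_csv <- function(dists, path) {
  rows <- lapply(names(dists), function(m) {
    v <- mid_of(dists[[m]])
    data.frame(metabolite = m, mass = 0:(length(v) - 1L),
               fraction = as.numeric(v), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' @rdname write_distributions_csv
#' @export
write_multiplets_csv <- function(dists, path) {
  rows <- lapply(names(dists), function(m) {
    pr <- multiplets_of(dists[[m]])
    data.frame(metabolite = m,
               carbon = rep(seq_len(nrow(pr)), each = ncol(pr)),
               component = rep(colnames(pr), nrow(pr)),
               fraction = as.numeric(t(pr)), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}
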