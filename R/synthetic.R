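# Synthetic study generator: emulates the NAD+ depletion/repletion design
# (control / NR 4 h / NMN 4 h / NR 24 h / FK866 24 h / FK866 48 h /
# FK866 48 h + NR 4 h) in C2C12 and primary myotubes, producing concentration
# tables, GC-MS ion counts and MIDs, and HSQC multiplet tables per replicate.

#' Default synthetic study scenario
#'
#' Encodes the study's effect structure relative to control:
#' \itemize{
#' \item NAD+ multiplied by 0.05 at FK866 48 h (a 95\% reduction), restored
#'   above control (x1.2) by 4 h NR co-treatment; partial depletion (x0.25,
#'   an assumption) at 24 h.
#' \item NAM fold changes of 9 (NR) and 1.8 (NMN); MeNAM elevated with NR in
#'   the C2C12 arm only.
#' \item PCr/Cr reduced under FK866 (phosphocreatine x0.5 at 48 h), restored
#'   with NR.
#' \item GAP and glycerol-3-phosphate elevated (x2) at 48 h but not 24 h;
#'   citrate, alpha-ketoglutarate and malate reduced (x0.5) at 48 h, restored
#'   with NR; aspartate elevated (x2) at 48 h; pyruvate reduced (x0.6) at
#'   48 h, raising the m+2 lactate/pyruvate ratio.
#' \item pathway fractions: reverse glycolysis appears only at 48 h
#'   (`f_reverse = 0.3`, 0 at 24 h), together with more pyruvate-carboxylase
#'   entry, more TCA rounds (lower `turn_exit`), glutamine anaplerosis and
#'   malic-enzyme pyruvate recycling.
#' }
#' Replicates default to 6 (C2C12) and 4 (primary myotubes); measurement
#' noise is lognormal with CV 0.15 on positive observables and a matched
#' Dirichlet perturbation on simplex observables. Control concentrations are
#' seeded from the printed control means where available (pyruvate, citrate,
#' alanine in mM/mg protein; GC-MS ion counts for the printed panel);
#' everything else defaults to 1 arbitrary unit.
#'
#' @return an object of class `tracer_scenario`.
#' @export
default_scenario <- function() {
  ctl_frac <- pathway_fractions(f_oxppp = 0.06, f_reverse = 0, f_pc = 0.15,
                                turn_exit = 0.6, f_gln = 0.05, f_pyr_cycle = 0)
  fk48_frac <- pathway_fractions(f_oxppp = 0.06, f_reverse = 0.3, f_pc = 0.3,
                                 turn_exit = 0.4, f_gln = 0.25,
                                 f_pyr_cycle = 0.2)
  cond <- function(label, fractions = ctl_frac, mult = numeric(),
                   mult_primary = numeric()) {
    list(label = label, fractions = fractions, mult = mult,
         mult_primary = mult_primary)
  }
  conditions <- list(
    control = cond("control"),
    NR_4h = cond("NR_4h",
                 mult = c(NAD = 1.5, NAM = 9, MeNAM = 3),
                 mult_primary = c(MeNAM = 1)),
    NMN_4h = cond("NMN_4h", mult = c(NAD = 1.5, NAM = 1.8)),
    NR_24h = cond("NR_24h",
                  mult = c(NAD = 1.3, NAM = 9, MeNAM = 3),
                  mult_primary = c(MeNAM = 1)),
    FK866_24h = cond("FK866_24h",
                     mult = c(NAD = 0.25, NADP = 0.6, PCr = 0.7)),
    FK866_48h = cond("FK866_48h", fractions = fk48_frac,
                     mult = c(NAD = 0.05, NADP = 0.3, PCr = 0.5,
                              aspartate = 2, GAP = 2, glycerol3P = 2,
                              citrate = 0.5, aKG = 0.5, malate = 0.5,
                              pyruvate = 0.6)),
    FK866_48h_NR_4h = cond("FK866_48h_NR_4h",
                           mult = c(NAD = 1.2, NAM = 2))
  )
  # control levels: printed means where the tables give a nonzero control
  # value; 1.0 arbitrary units otherwise (documented assumption)
  conc <- c(NAD = 1, NADP = 1, NAM = 1, MeNAM = 1, PCr = 2, Cr = 1, ATP = 1,
            aspartate = 1, lactate = 1, alanine = 0.07, citrate = 0.01,
            aKG = 1, malate = 1, GAP = 1, glycerol3P = 1, F6P = 1,
            pyruvate = 0.01, glutamine = 1, glutamate = 1)
  ions <- c(pyruvate = 255065, malate = 147186, lactate = 8345878,
            GAP = 1174906, glutamine = 942572, fumarate = 81303,
            alanine = 1541322, PG3 = 11227, aspartate = 1e6,
            citrate = 5e5, aKG = 2e5, glutamate = 2e6)
  structure(list(
    conditions = conditions, control = "control",
    replicates = c(C2C12 = 6L, primary = 4L),
    cv = 0.15, pellet_cv = 0.1, na_abundance = 0.011,
    tracers = list(glc12 = tracer_glc12(), glnU = tracer_glnU()),
    mid_metabolites = list(
      glc12 = c("lactate", "pyruvate", "aspartate", "glutamate", "alanine", "F6P"),
      glnU = c("aspartate", "glutamate")),
    multiplet_metabolites = list(glc12 = c("aspartate", "lactate", "F6P"),
                                 glnU = "aspartate"),
    control_conc = conc, control_ions = ions, n_max_turns = 4L),
    class = "tracer_scenario")
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "tracer_scenario"))
  if (sc$cv < 0 || sc$pellet_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (!sc$control %in% names(sc$conditions)) {
    stop("control condition missing from the scenario", call. = FALSE)
  }
  if (any(sc$replicates < 1L)) stop("replicate counts must be >= 1", call. = FALSE)
  for (cd in sc$conditions) {
    stopifnot(inherits(cd$fractions, "pathway_fractions"))
    if (any(cd$mult <= 0) || any(cd$mult_primary <= 0)) {
      stop("concentration multipliers must be positive", call. = FALSE)
    }
  }
  invisible(sc)
}

#' @export
print.tracer_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic tracer scenario: %d conditions, replicates C2C12=%d primary=%d, CV=%.2f\n",
    length(x$conditions), x$replicates[["C2C12"]], x$replicates[["primary"]],
    x$cv))
  cat("Conditions:", paste(names(x$conditions), collapse = ", "), "\n")
  invisible(x)
}

# simulate_labelling() on the default network is a pure function of
# (tracer, fractions, n_max_turns); cache results across generate() calls
.sim_cache <- new.env(parent = emptyenv())

simulate_cached <- function(tracer, fractions, n_max_turns) {
  key <- paste(tracer$metabolite, paste(tracer$positions, collapse = ","),
               tracer$enrichment, paste(unlist(fractions), collapse = ","),
               n_max_turns, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    if (is.null(.sim_cache[["..net"]])) {
      .sim_cache[["..net"]] <- build_default_network()
    }
    .sim_cache[[key]] <- simulate_labelling(.sim_cache[["..net"]], tracer,
                                            fractions, n_max_turns)
  }
  .sim_cache[[key]]
}

# mean-preserving lognormal noise: E[x] = mean
rlnorm_mean <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet perturbation of a probability vector; zero entries stay zero.
# Concentration 1/cv^2 gives a relative sd of roughly cv on mid-sized bins.
rdirichlet_about <- function(p, cv) {
  if (cv == 0 || sum(p > 0) < 2L) return(p)
  alpha <- p * (1 / cv^2)
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  g / sum(g)
}

mult_for <- function(cd, metabolite, cell_line) {
  m <- 1
  if (metabolite %in% names(cd$mult)) m <- cd$mult[[metabolite]]
  if (cell_line == "primary" && metabolite %in% names(cd$mult_primary)) {
    m <- cd$mult_primary[[metabolite]]
  }
  m
}

#' Generate a complete synthetic study dataset
#'
#' Deterministic given `seed`. Noiseless observables come from
#' [simulate_labelling()] under each condition's pathway fractions (computed
#' once per condition and tracer arm); lognormal noise is applied to positive
#' observables (concentrations, ion counts, pellet weights) and Dirichlet
#' perturbation to simplex observables (MIDs, multiplet rows), after which
#' MIDs are convolved with natural 13C abundance
#' (`scenario$na_abundance`). Raw concentration/ion values scale with the
#' replicate's pellet weight, so [normalize_to_pellet()] removes that factor.
#'
#' @param scenario a `tracer_scenario`, default [default_scenario()].
#' @param seed integer seed controlling all randomness.
#' @return an object of class `tracer_dataset`: list of tidy data frames
#'   `concentrations` (cell_line, condition, replicate, metabolite,
#'   raw_value, pellet_weight), `ion_counts` (same shape), `mids`
#'   (cell_line, condition, replicate, tracer, metabolite, mass, fraction)
#'   and `multiplets` (cell_line, condition, replicate, tracer, metabolite,
#'   carbon, component, fraction), plus the `scenario` and `seed`.
#' @export
generate_dataset <- function(scenario = default_scenario(), seed = 1L) {
  validate_scenario(scenario)
  set.seed(as.integer(seed))
  sc <- scenario
  # noiseless simulate per condition x tracer arm (deterministic, memoised)
  sims <- lapply(sc$conditions, function(cd) {
    lapply(sc$tracers, function(tr) {
      simulate_cached(tr, cd$fractions, sc$n_max_turns)
    })
  })
  # replicate grid: one pellet weight per (cell line, condition, replicate)
  grid <- do.call(rbind, lapply(names(sc$replicates), function(cl) {
    expand.grid(cell_line = cl, condition = names(sc$conditions),
                replicate = seq_len(sc$replicates[[cl]]),
                stringsAsFactors = FALSE)
  }))
  grid <- grid[order(grid$cell_line, grid$condition, grid$replicate), ]
  rownames(grid) <- NULL
  grid$pellet_weight <- rlnorm_mean(nrow(grid), 1, sc$pellet_cv)

  tidy_positive <- function(panel) {
    # one block per metabolite over the full replicate grid
    out <- do.call(rbind, lapply(names(panel), function(met) {
      mult <- mapply(function(cn, cl) mult_for(sc$conditions[[cn]], met, cl),
                     grid$condition, grid$cell_line)
      cbind(grid[c("cell_line", "condition", "replicate")],
            metabolite = met,
            raw_value = panel[[met]] * mult * grid$pellet_weight *
              rlnorm_mean(nrow(grid), 1, sc$cv),
            pellet_weight = grid$pellet_weight)
    }))
    rownames(out) <- NULL
    out
  }
  concentrations <- tidy_positive(as.list(sc$control_conc))
  ion_counts <- tidy_positive(as.list(sc$control_ions))

  mid_blocks <- list(); mp_blocks <- list()
  comp <- multiplet_components()
  for (arm in names(sc$tracers)) {
    for (met in sc$mid_metabolites[[arm]]) {
      base <- lapply(sims, function(s)
        as.numeric(reconvolve_mid(as.numeric(mid_of(s[[arm]][[met]])),
                                  sc$na_abundance)))
      n1 <- length(base[[1L]])
      frac <- vapply(seq_len(nrow(grid)), function(i)
        rdirichlet_about(base[[grid$condition[i]]], sc$cv), numeric(n1))
      mid_blocks[[paste(arm, met)]] <- cbind(
        grid[rep(seq_len(nrow(grid)), each = n1),
             c("cell_line", "condition", "replicate")],
        tracer = arm, metabolite = met, mass = rep(0:(n1 - 1L), nrow(grid)),
        fraction = as.numeric(frac))
    }
    for (met in sc$multiplet_metabolites[[arm]]) {
      base <- lapply(sims, function(s) unclass(multiplets_of(s[[arm]][[met]])))
      nr <- nrow(base[[1L]])
      frac <- vapply(seq_len(nrow(grid)), function(i) {
        pr <- base[[grid$condition[i]]]
        for (k in seq_len(nr)) pr[k, ] <- rdirichlet_about(pr[k, ], sc$cv)
        as.numeric(t(pr))
      }, numeric(nr * 5L))
      mp_blocks[[paste(arm, met)]] <- cbind(
        grid[rep(seq_len(nrow(grid)), each = nr * 5L),
             c("cell_line", "condition", "replicate")],
        tracer = arm, metabolite = met,
        carbon = rep(rep(seq_len(nr), each = 5L), nrow(grid)),
        component = rep(comp, nr * nrow(grid)),
        fraction = as.numeric(frac))
    }
  }
  mids <- do.call(rbind, mid_blocks); rownames(mids) <- NULL
  multiplets <- do.call(rbind, mp_blocks); rownames(multiplets) <- NULL
  structure(list(concentrations = concentrations,
                 ion_counts = ion_counts,
                 mids = mids,
                 multiplets = multiplets,
                 scenario = sc, seed = as.integer(seed)),
            class = "tracer_dataset")
}

#' @export
print.tracer_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic tracer dataset (seed %d): %d concentration rows, %d ion-count rows,\n  %d MID rows, %d multiplet rows\n",
    x$seed, nrow(x$concentrations), nrow(x$ion_counts), nrow(x$mids),
    nrow(x$multiplets)))
  invisible(x)
}

#' Write or read a dataset as a CSV directory
#'
#' Writes `concentrations.csv`, `ion_counts.csv`, `mids.csv`,
#' `multiplets.csv` and a `manifest.txt` recording the seed, noise settings
#' and package version.
#'
#' @param ds a `tracer_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "tracer_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("concentrations", "ion_counts", "mids", "multiplets")) {
    utils::write.csv(ds[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  ver <- tryCatch(as.character(utils::packageVersion("carbontrace")),
                  error = function(e) "devel")
  writeLines(c(paste0("seed: ", ds$seed),
               paste0("cv: ", ds$scenario$cv),
               paste0("na_abundance: ", ds$scenario$na_abundance),
               paste0("conditions: ",
                      paste(names(ds$scenario$conditions), collapse = ",")),
               paste0("package_version: ", ver)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param dir directory written by [write_dataset()].
#' @export
read_dataset <- function(dir) {
  parts <- lapply(c("concentrations", "ion_counts", "mids", "multiplets"),
                  function(nm) {
                    f <- file.path(dir, paste0(nm, ".csv"))
                    if (!file.exists(f)) stop("missing dataset file: ", f,
                                              call. = FALSE)
                    utils::read.csv(f, stringsAsFactors = FALSE)
                  })
  names(parts) <- c("concentrations", "ion_counts", "mids", "multiplets")
  manifest <- file.path(dir, "manifest.txt")
  seed <- NA_integer_
  if (file.exists(manifest)) {
    ln <- grep("^seed:", readLines(manifest), value = TRUE)
    if (length(ln)) seed <- as.integer(sub("^seed:\\s*", "", ln[1L]))
  }
  structure(c(parts, list(scenario = NULL, seed = seed)),
            class = "tracer_dataset")
}
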