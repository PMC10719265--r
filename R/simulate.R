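#' Ground-truth scenario for the synthetic incubation generator
#'
#' The defaults describe one eutrophied upstream estuarine station under the
#' standard incubation design: tracer additions of 5, 5 and 20 umol L-1
#' (15NH4+, 15NO2-, 15NO3-) onto ambient pools sized so the tracer makes up
#' 38, 31 and 14 percent of the final pools (the campaign means), three
#' timepoints (0, 6, 12 h) in triplicate, and Gaussian noise at 5 percent of
#' each analyte's full-scale signal. True transformation rates (AO 1000,
#' NO 400, NR 900 nmol N L-1 d-1) and N2O pathway rates (0.9, 0.5 and
#' 2.0 nmol N L-1 d-1 from NH4+, NO2- and NO3-) put the N2O yields at the
#' reported medians (about 0.09 percent for ammonia oxidation, 0.22 percent
#' for nitrate reduction) with a reductive share of about 74 percent.
#'
#' @param true_rates named vector: `AO`, `NO`, `NR`, `N2O-NH4`, `N2O-NO2`,
#'   `N2O-NO3`, all nmol N L-1 d-1.
#' @param tracer_add named vector of tracer additions, umol L-1.
#' @param ambient named vector of ambient pool concentrations, umol L-1.
#'   Defaults are derived from `tracer_add` and the target atom fractions
#'   0.38 / 0.31 / 0.14.
#' @param timepoints incubation sampling times, hours.
#' @param replicates bottles per timepoint.
#' @param noise list with `rel` (sd as a fraction of the full-scale true
#'   signal of each analyte; homoskedastic within a series, matching the
#'   unweighted slope inference) and `floor` (absolute sd floor, in the
#'   analyte's own units: umol L-1 for products, nmol L-1 for N2O).
#' @param hybrid_fraction fraction of N2O molecules formed by hybrid pairing
#'   (one atom from the labelled pool, one from an unlabelled pool);
#'   0 = single-pool binomial.
#' @param seed integer seed; all generator randomness flows through it.
#' @return object of class `n2o_scenario`.
#' @export
scenario <- function(true_rates = c("AO" = 1000, "NO" = 400, "NR" = 900,
                                    "N2O-NH4" = 0.9, "N2O-NO2" = 0.5,
                                    "N2O-NO3" = 2.0),
                     tracer_add = c(NH4 = 5, NO2 = 5, NO3 = 20),
                     ambient = NULL,
                     timepoints = c(0, 6, 12),
                     replicates = 3,
                     noise = list(rel = 0.05, floor = c(product = 0, n2o = 0)),
                     hybrid_fraction = 0,
                     seed = 1L) {
  f_target <- c(NH4 = 0.38, NO2 = 0.31, NO3 = 0.14)
  if (is.null(ambient)) {
    ambient <- tracer_add * (1 / f_target - 1)
  }
  procs <- c("AO", "NO", "NR", "N2O-NH4", "N2O-NO2", "N2O-NO3")
  if (!all(procs %in% names(true_rates))) {
    stop("`true_rates` must name all six processes", call. = FALSE)
  }
  if (any(true_rates < 0)) stop("true rates must be >= 0", call. = FALSE)
  if (length(timepoints) < 2L || any(diff(sort(timepoints)) <= 0)) {
    stop("need >= 2 distinct timepoints", call. = FALSE)
  }
  if (!is.numeric(noise$rel) || noise$rel < 0) {
    stop("infeasible noise: `rel` must be >= 0", call. = FALSE)
  }
  if (any(noise$floor < 0)) stop("infeasible noise: floors must be >= 0", call. = FALSE)
  if (hybrid_fraction < 0 || hybrid_fraction > 1) {
    stop("`hybrid_fraction` must lie in [0, 1]", call. = FALSE)
  }
  pools <- list(
    NH4 = pool_composition(ambient[["NH4"]], tracer_add[["NH4"]], "NH4"),
    NO2 = pool_composition(ambient[["NO2"]], tracer_add[["NO2"]], "NO2"),
    NO3 = pool_composition(ambient[["NO3"]], tracer_add[["NO3"]], "NO3"))
  structure(
    list(true_rates = true_rates[procs], tracer_add = tracer_add,
         ambient = ambient, pools = pools,
         timepoints = sort(timepoints), replicates = as.integer(replicates),
         noise = noise, hybrid_fraction = hybrid_fraction,
         seed = as.integer(seed)),
    class = "n2o_scenario"
  )
}

#' @export
print.n2o_scenario <- function(x, ...) {
  cat("<n2o_scenario>\n  true rates (nmol N L-1 d-1):\n")
  print(x$true_rates)
  cat(sprintf("  F: NH4 %.3f, NO2 %.3f, NO3 %.3f | t = %s h x %d reps | rel noise %.3g | hybrid %.2f | seed %d\n",
              atom_fraction(x$pools$NH4), atom_fraction(x$pools$NO2),
              atom_fraction(x$pools$NO3),
              paste(x$timepoints, collapse = "/"), x$replicates,
              x$noise$rel, x$hybrid_fraction, x$seed))
  invisible(x)
}

# expected (noise-free) isotopologue slopes, nmol N2O L-1 d-1, for a pathway
# with total rate `rate_n` (nmol N L-1 d-1) at substrate atom fraction f.
# A hybrid molecule pairs one labelled-pool atom (P(15N) = f) with one atom
# from an unlabelled pool, contributing to mass 45 with probability f and
# never to mass 46.
.iso_slopes <- function(rate_n, f, hybrid = 0) {
  mol <- rate_n / 2
  pp <- pairing_probabilities(f)
  c(s45 = mol * ((1 - hybrid) * pp[["p45"]] + hybrid * f),
    s46 = mol * (1 - hybrid) * pp[["p46"]])
}

.noise_floor <- function(noise, class) {
  fl <- noise$floor
  if (is.null(fl)) return(0)
  if (!is.null(names(fl)) && class %in% names(fl)) return(fl[[class]])
  fl[[1]]
}

#' Simulate the six labelled incubation experiments of one station
#'
#' Forward model of the slope-based inference: 15N products accumulate
#' linearly at `true_rate x F_substrate` (umol L-1), N2O isotopologues at the
#' binomial split of the molecule rate (optionally blended toward hybrid
#' pairing), with homoskedastic Gaussian noise per analyte (sd = `rel` x
#' full-scale signal + floor) and truncation at zero (flagged via the
#' `truncated` attribute).
#'
#' @param sc an [scenario()].
#' @return named list of six [incubation_series()]: `AO`, `NO`, `NR`
#'   (transformation series) and `N2O-NH4`, `N2O-NO2`, `N2O-NO3`.
#' @export
simulate_incubation <- function(sc) {
  stopifnot(inherits(sc, "n2o_scenario"))
  set.seed(sc$seed)
  tt <- rep(sc$timepoints, each = sc$replicates)
  rep_id <- rep(seq_len(sc$replicates), times = length(sc$timepoints))
  n_trunc <- 0L
  noisy <- function(true_vals, class) {
    sdv <- sc$noise$rel * max(true_vals) + .noise_floor(sc$noise, class)
    v <- true_vals + stats::rnorm(length(true_vals), 0, sdv)
    n_trunc <<- n_trunc + sum(v < 0)
    pmax(v, 0)
  }
  out <- list()
  for (i in seq_len(nrow(.process_map))) {
    m <- .process_map[i, ]
    species <- sub("^15", "", m$substrate)
    f <- atom_fraction(sc$pools[[species]])
    # transformation series: product 15N in umol L-1
    slope_umol_h <- sc$true_rates[[m$process]] * f / 1000 / 24
    prod_vals <- noisy(slope_umol_h * tt, "product")
    out[[m$process]] <- incubation_series(
      m$substrate, tt, rep_id, rep(m$product, length(tt)), prod_vals,
      pools = sc$pools, metadata = list(truth = sc$true_rates[[m$process]]))
    # N2O series: isotopologues in nmol N2O L-1
    s <- .iso_slopes(sc$true_rates[[m$n2o_process]], f, sc$hybrid_fraction) / 24
    v45 <- noisy(s[["s45"]] * tt, "n2o")
    v46 <- noisy(s[["s46"]] * tt, "n2o")
    out[[m$n2o_process]] <- incubation_series(
      m$substrate, c(tt, tt), c(rep_id, rep_id),
      c(rep("45N2O", length(tt)), rep("46N2O", length(tt))),
      c(v45, v46), pools = sc$pools,
      metadata = list(truth = sc$true_rates[[m$n2o_process]]))
  }
  attr(out, "truncated") <- n_trunc
  out
}

#' Simulate station hydrography, surface records and a rate profile
#'
#' Draws stations across the estuarine gradients the study spans (salinity
#' 0-35, temperature 15-30 degC, DO 16-300 umol L-1, N2O 5-60 nmol L-1,
#' wind 2-10 m s-1) and builds a depth profile of total N2O production for
#' depth-integration tests.
#'
#' @param n_stations number of stations.
#' @param n_depths depths per station profile.
#' @param x_air atmospheric N2O mole fraction, ppb.
#' @param seed integer seed.
#' @return list with data.frames `stations` (one surface row per station)
#'   and `profile` (station, depth_m, rate_n2o nmol N L-1 d-1).
#' @export
simulate_station_profile <- function(n_stations = 12, n_depths = 4,
                                     x_air = 332, seed = 1L) {
  set.seed(seed)
  st <- data.frame(
    station = sprintf("S%02d", seq_len(n_stations)),
    temperature = stats::runif(n_stations, 15, 30),
    salinity = stats::runif(n_stations, 0, 35),
    do_umol = stats::runif(n_stations, 16, 300),
    c_obs = stats::runif(n_stations, 5, 60),
    wind_u10 = stats::runif(n_stations, 2, 10),
    x_air = x_air,
    stringsAsFactors = FALSE)
  prof <- do.call(rbind, lapply(seq_len(n_stations), function(i) {
    depth <- sort(stats::runif(n_depths, 1, 30))
    data.frame(station = st$station[i], depth_m = depth,
               rate_n2o = stats::runif(n_depths, 0.1, 20),
               stringsAsFactors = FALSE)
  }))
  list(stations = st, profile = prof)
}

#' Brute-force molecule-pairing oracle
#'
#' Simulates each N2O molecule as two independent atoms that are 15N with
#' probability `f` and tabulates the empirical mass 44/45/46 frequencies.
#' Used as an independent check of [pairing_probabilities()].
#'
#' @param f 15N atom fraction in `[0, 1]` (the boundaries are allowed here:
#'   they give degenerate single-isotopologue output).
#' @param n_molecules number of molecules to draw (>= 1).
#' @param seed integer seed.
#' @return named empirical frequencies `c(p44, p45, p46)`.
#' @export
pairing_oracle <- function(f, n_molecules = 1e6, seed = 1L) {
  stopifnot(n_molecules >= 1, f >= 0, f <= 1)
  set.seed(seed)
  a1 <- stats::runif(n_molecules) < f
  a2 <- stats::runif(n_molecules) < f
  mass <- a1 + a2
  c(p44 = mean(mass == 0L), p45 = mean(mass == 1L), p46 = mean(mass == 2L))
}
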