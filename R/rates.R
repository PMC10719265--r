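#' A replicated tracer incubation time course
#'
#' Holds the measured analyte concentrations of one labelled-substrate
#' experiment: either a transformation series (accumulation of the 15N
#' product, umol L-1) or an N2O series (accumulation of the 45/46 N2O
#' isotopologues, nmol L-1), together with the t0 pool composition of the
#' labelled substrate.
#'
#' @param substrate_label one of `"15NH4"`, `"15NO2"`, `"15NO3"`.
#' @param time_h elapsed incubation time in hours, one per measurement.
#' @param replicate replicate identifier per measurement.
#' @param analyte analyte name per measurement: `"15NO2"`, `"15NO3"`
#'   (products, umol L-1) or `"45N2O"`, `"46N2O"` (nmol L-1).
#' @param value measured concentration, same length as `time_h`.
#' @param pools named list of [pool_composition()] objects (at least the
#'   labelled substrate species).
#' @param metadata optional named list (station, depth, size fraction, ...).
#' @return object of class `incubation_series`.
#' @export
incubation_series <- function(substrate_label = c("15NH4", "15NO2", "15NO3"),
                              time_h, replicate, analyte, value,
                              pools, metadata = list()) {
  substrate_label <- match.arg(substrate_label)
  n <- length(time_h)
  if (length(value) != n || length(analyte) != n || length(replicate) != n) {
    stop("time_h, replicate, analyte and value must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("incubation times must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  ok <- analyte %in% c("15NO2", "15NO3", "45N2O", "46N2O")
  if (!all(ok)) {
    stop("unknown analyte(s): ", paste(unique(analyte[!ok]), collapse = ", "),
         call. = FALSE)
  }
  for (a in unique(analyte)) {
    if (length(unique(time_h[analyte == a])) < 2L) {
      stop("insufficient design: analyte ", a, " needs >= 2 distinct timepoints",
           call. = FALSE)
    }
  }
  if (!is.list(pools) || !all(vapply(pools, inherits, TRUE, "pool_composition"))) {
    stop("`pools` must be a named list of pool_composition objects", call. = FALSE)
  }
  species <- sub("^15", "", substrate_label)
  if (!species %in% names(pools)) {
    stop("`pools` must contain the labelled substrate species ", species, call. = FALSE)
  }
  structure(
    list(substrate_label = substrate_label,
         data = data.frame(time_h = as.numeric(time_h),
                           replicate = replicate,
                           analyte = as.character(analyte),
                           value = as.numeric(value),
                           stringsAsFactors = FALSE),
         pools = pools,
         metadata = metadata),
    class = "incubation_series"
  )
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf("<incubation_series> %s label: %d measurements of {%s} at %d timepoints\n",
              x$substrate_label, nrow(x$data),
              paste(unique(x$data$analyte), collapse = ", "),
              length(unique(x$data$time_h))))
  invisible(x)
}

# substrate -> (process, product analyte) for the transformation series
.process_map <- data.frame(
  substrate = c("15NH4", "15NO2", "15NO3"),
  process   = c("AO", "NO", "NR"),
  product   = c("15NO2", "15NO3", "15NO2"),
  n2o_process = c("N2O-NH4", "N2O-NO2", "N2O-NO3"),
  stringsAsFactors = FALSE
)

#' Ordinary least-squares slope of a concentration time course
#'
#' Pools all replicates as independent points and regresses concentration on
#' time. Replicate scatter therefore informs the slope standard error. The
#' slope is converted from per hour to per day (x 24 exactly).
#'
#' @param series an [incubation_series()].
#' @param analyte which analyte column to fit.
#' @return list with `slope` (conc d-1), `se`, `p` (two-sided p-value for
#'   slope = 0), `n` (points used), `df`.
#' @export
fit_timecourse <- function(series, analyte) {
  stopifnot(inherits(series, "incubation_series"))
  d <- series$data[series$data$analyte == analyte, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("analyte ", analyte, " not present in series", call. = FALSE)
  }
  if (length(unique(d$time_h)) < 2L) {
    stop("insufficient design: need >= 2 distinct timepoints", call. = FALSE)
  }
  if (stats::sd(d$value) == 0) {
    # constant concentrations: slope exactly 0, nothing to detect
    return(list(slope = 0, se = 0, p = 1, n = nrow(d), df = nrow(d) - 2L))
  }
  fit <- stats::lm(value ~ time_h, data = d)
  # noiseless series trip summary.lm's "essentially perfect fit" warning;
  # exact fits are legitimate here (synthetic round-trips)
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  slope <- cf["time_h", "Estimate"]
  se <- cf["time_h", "Std. Error"]
  p <- cf["time_h", "Pr(>|t|)"]
  if (fit$df.residual == 0L) {
    # saturated fit (e.g. two single points): slope exact, uncertainty
    # unassessable
    se <- NA_real_
    p <- NA_real_
  } else if (!is.finite(p)) {
    # exact fit through > 2 points: se = 0, t undefined
    p <- if (abs(slope) > 0) 0 else 1
  }
  list(slope = 24 * slope, se = 24 * se, p = p,
       n = nrow(d), df = fit$df.residual)
}

#' A rate with uncertainty and detection flag
#'
#' @param value rate estimate.
#' @param se standard error, same units.
#' @param p_slope two-sided p-value of the underlying slope.
#' @param below_detection logical; when `TRUE` the reported value is 0 and
#'   `se` is retained.
#' @param n_points number of measurements used.
#' @param process one of `"AO"`, `"NO"`, `"NR"`, `"N2O-NH4"`, `"N2O-NO2"`,
#'   `"N2O-NO3"`.
#' @param units unit string, e.g. `"nmol N L-1 d-1"`.
#' @param notes character vector of qualifications (e.g. consumption warning).
#' @export
rate_estimate <- function(value, se, p_slope, below_detection = FALSE,
                          n_points = NA_integer_, process = NA_character_,
                          units = "nmol N L-1 d-1", notes = character()) {
  stopifnot(is.numeric(value), is.numeric(se), is.na(se) || se >= 0)
  structure(
    list(value = as.numeric(value), se = as.numeric(se),
         p_slope = as.numeric(p_slope),
         below_detection = isTRUE(below_detection),
         n_points = as.integer(n_points), process = process,
         units = units, notes = notes),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s: %.4g +/- %.4g %s (p = %.3g%s)\n",
              x$process, x$value, x$se, x$units, x$p_slope,
              if (x$below_detection) ", below detection" else ""))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Gross N transformation rate from a labelled time course
#'
#' Divides the 15N-product accumulation slope by the substrate 15N atom
#' fraction: ammonia oxidation from a 15NH4+ series (product 15NO2-), nitrite
#' oxidation from 15NO2- (product 15NO3-), nitrate reduction from 15NO3-
#' (product 15NO2-). Product concentrations are in umol L-1, so the rate is
#' reported in nmol N L-1 d-1 (x 1000).
#'
#' A slope whose two-sided p-value is at or above `alpha` is below detection:
#' the rate is reported as 0 with its standard error retained. A significant
#' negative slope is reported as negative with a consumption warning rather
#' than silently zeroed.
#'
#' @param series an [incubation_series()] containing the product analyte.
#' @param alpha detection significance level (default 0.05).
#' @return a [rate_estimate()] in nmol N L-1 d-1.
#' @export
transformation_rate <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "incubation_series"))
  m <- .process_map[.process_map$substrate == series$substrate_label, ]
  if (!m$product %in% series$data$analyte) {
    stop("configuration error: ", series$substrate_label,
         " series lacks its product analyte ", m$product, call. = FALSE)
  }
  f <- atom_fraction(series$pools[[sub("^15", "", series$substrate_label)]])
  fit <- fit_timecourse(series, m$product)
  value <- fit$slope / f * 1000   # umol L-1 d-1 -> nmol N L-1 d-1
  se <- fit$se / f * 1000
  notes <- character()
  below <- is.finite(fit$p) && fit$p >= alpha
  if (below) {
    value <- 0
  } else if (value < 0) {
    notes <- "significant negative slope: consumption-dominated time course"
  }
  rate_estimate(value, se, fit$p, below_detection = below,
                n_points = fit$n, process = m$process,
                units = "nmol N L-1 d-1", notes = notes)
}

#' Gross N2O production rate from isotopologue time courses
#'
#' Fits independent slopes to the 45N2O and 46N2O channels (nmol N2O L-1,
#' converted to per day), clamps negative below-detection slopes to zero,
#' infers the mass-44 rate from the binomial pairing model and sums the
#' three (see [total_n2o_rate()]). The standard error is propagated to first
#' order: `se_mol^2 = se45^2 + (1 + ((1-F)/F)^2)^2 * se46^2`, then doubled
#' into nitrogen units.
#'
#' When mass 46 is below detection but mass 45 is not, an alternative
#' estimate `r45 / p45` is also reported (`r45_scaled`); the primary value
#' then omits the unmeasurable mass-46 and inferred mass-44 terms.
#'
#' @param series an [incubation_series()] containing both `45N2O` and
#'   `46N2O` analytes.
#' @param alpha detection significance level (default 0.05).
#' @return list with `rate` (a [rate_estimate()], nmol N L-1 d-1), `iso`
#'   (an `isotopologue_rates`), `consistency` (diagnostic ratio) and
#'   `r45_scaled` (alternative estimate, `NA` unless the fallback applies).
#' @export
n2o_production_rate <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "incubation_series"))
  present <- unique(series$data$analyte)
  if (!all(c("45N2O", "46N2O") %in% present)) {
    stop("series must contain both 45N2O and 46N2O channels", call. = FALSE)
  }
  m <- .process_map[.process_map$substrate == series$substrate_label, ]
  f <- atom_fraction(series$pools[[sub("^15", "", series$substrate_label)]])
  f45 <- fit_timecourse(series, "45N2O")
  f46 <- fit_timecourse(series, "46N2O")
  det45 <- is.finite(f45$p) && f45$p < alpha
  det46 <- is.finite(f46$p) && f46$p < alpha
  s45 <- if (f45$slope < 0 && !det45) 0 else f45$slope
  s46 <- if (f46$slope < 0 && !det46) 0 else f46$slope
  # detection handling for the summed estimate: an undetected channel
  # contributes its (noisy) point estimate unless negative; the flags decide
  # the below-detection status of the total
  s45 <- max(s45, 0)
  s46 <- max(s46, 0)
  iso <- total_n2o_rate(s45, s46, f)
  amp <- ((1 - f) / f)^2
  se_mol <- sqrt(f45$se^2 + (1 + amp)^2 * f46$se^2)
  below <- !det45 && !det46
  value <- if (below) 0 else iso$r_total_n
  notes <- character()
  r45_scaled <- NA_real_
  if (det45 && !det46) {
    p45 <- pairing_probabilities(f)[["p45"]]
    r45_scaled <- 2 * s45 / p45
    notes <- "mass-46 below detection: r45-scaled alternative reported"
  }
  rate <- rate_estimate(value, 2 * se_mol, min(f45$p, f46$p),
                        below_detection = below,
                        n_points = f45$n + f46$n, process = m$n2o_process,
                        units = "nmol N L-1 d-1", notes = notes)
  consistency <- if (s46 > 0) (s45 / s46) / (2 * (1 - f) / f) else NA_real_
  list(rate = rate, iso = iso, consistency = consistency,
       r45_scaled = r45_scaled)
}

#' Assemble the per-station table of the six measured processes
#'
#' @param rates a list of [rate_estimate()] objects (any subset of the six
#'   processes); entries from [n2o_production_rate()] may be passed directly
#'   (their `$rate` element is used).
#' @return data.frame with one row per process (AO, NO, NR, N2O-NH4,
#'   N2O-NO2, N2O-NO3): `value`, `se`, `p_slope`, `below_detection`,
#'   `present`. Missing processes have `present = FALSE` and `NA` values
#'   (never zero).
#' @export
station_rate_table <- function(rates) {
  procs <- c("AO", "NO", "NR", "N2O-NH4", "N2O-NO2", "N2O-NO3")
  rates <- lapply(rates, function(r) if (!inherits(r, "rate_estimate") &&
                                         is.list(r) && inherits(r$rate, "rate_estimate"))
    r$rate else r)
  if (!all(vapply(rates, inherits, TRUE, "rate_estimate"))) {
    stop("`rates` must be a list of rate_estimate objects", call. = FALSE)
  }
  got <- vapply(rates, function(r) r$process, character(1))
  if (anyDuplicated(got)) {
    stop("duplicate process entries: ", paste(got[duplicated(got)], collapse = ", "),
         call. = FALSE)
  }
  if (!all(got %in% procs)) {
    stop("unknown process: ", paste(setdiff(got, procs), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(process = procs,
                    value = NA_real_, se = NA_real_, p_slope = NA_real_,
                    below_detection = NA, present = FALSE,
                    units = "nmol N L-1 d-1",
                    stringsAsFactors = FALSE)
  if (length(rates) == 0L) return(out[0L, , drop = FALSE])
  for (r in rates) {
    i <- match(r$process, procs)
    out$value[i] <- r$value
    out$se[i] <- r$se
    out$p_slope[i] <- r$p_slope
    out$below_detection[i] <- r$below_detection
    out$present[i] <- TRUE
  }
  out
}
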