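#' N2O yield of a nitrite-producing pathway
#'
#' Yield is defined as N2O-N produced per NO2--N produced by the paired
#' transformation: N2O-from-NH4+ over ammonia oxidation, or N2O-from-NO3-
#' over nitrate reduction. Both rates must be in the same units. Uncertainty
#' is first-order (delta-method) ratio propagation assuming independence.
#'
#' @param rate_n2o a [rate_estimate()] (numerator, N units).
#' @param rate_no2_production a [rate_estimate()] (denominator): the NO2-
#'   production rate (AO or NR).
#' @return list with `yield_pct`, `se_pct` and logical `defined`. When the
#'   denominator is non-positive or below detection the yield is undefined
#'   and reported as `NA` (never 0).
#' @export
n2o_yield <- function(rate_n2o, rate_no2_production) {
  stopifnot(inherits(rate_n2o, "rate_estimate"),
            inherits(rate_no2_production, "rate_estimate"))
  num <- rate_n2o$value; sn <- rate_n2o$se
  den <- rate_no2_production$value; sd_ <- rate_no2_production$se
  if (rate_no2_production$below_detection || den <= 0) {
    return(list(yield_pct = NA_real_, se_pct = NA_real_, defined = FALSE))
  }
  y <- 100 * num / den
  se <- 100 * sqrt(sn^2 / den^2 + num^2 * sd_^2 / den^4)
  list(yield_pct = y, se_pct = se, defined = TRUE)
}

#' Fractional contribution of oxidative vs. reductive N2O pathways
#'
#' Splits total N2O production into the share from ammonia oxidation
#' (`f_ao`, from the 15NH4+ incubation) and from the reductive pathways
#' (`f_red`, NO2- plus NO3- reduction). `f_ao + f_red = 1` exactly whenever
#' defined. The standard deviation uses first-order propagation treating the
#' three rates as independent; a Monte-Carlo mode (Gaussian draws on each
#' rate) exists for validating the delta method.
#'
#' @param rate_table a [station_rate_table()] (the three `N2O-*` rows must
#'   be present), or a named numeric vector/list with elements `N2O-NH4`,
#'   `N2O-NO2`, `N2O-NO3` and optional ses via `se`.
#' @param se optional numeric vector of standard errors (same order) when
#'   `rate_table` is a plain vector.
#' @param method `"delta"` (default) or `"mc"`.
#' @param n_draws Monte-Carlo draws (default 10000).
#' @return list with `f_ao`, `f_red`, `sd_f_ao`, `sd_f_red`, `total`.
#' @export
fractional_contributions <- function(rate_table, se = NULL,
                                     method = c("delta", "mc"),
                                     n_draws = 10000) {
  method <- match.arg(method)
  procs <- c("N2O-NH4", "N2O-NO2", "N2O-NO3")
  if (is.data.frame(rate_table)) {
    i <- match(procs, rate_table$process)
    if (anyNA(i) || !all(rate_table$present[i])) {
      stop("rate table must contain all three N2O pathway rates", call. = FALSE)
    }
    r <- rate_table$value[i]
    s <- rate_table$se[i]
  } else {
    r <- as.numeric(rate_table[procs])
    s <- if (is.null(se)) rep(0, 3) else as.numeric(se)
  }
  if (anyNA(r)) stop("missing pathway rates", call. = FALSE)
  total <- sum(r)
  if (total <= 0) {
    return(list(f_ao = NA_real_, f_red = NA_real_,
                sd_f_ao = NA_real_, sd_f_red = NA_real_, total = total))
  }
  f_ao <- r[1] / total
  if (method == "delta") {
    # f_ao = a/(a+b+c): d/da = (b+c)/T^2, d/db = d/dc = -a/T^2
    v <- ((r[2] + r[3])^2 * s[1]^2 + r[1]^2 * (s[2]^2 + s[3]^2)) / total^4
    sd_f <- sqrt(v)
  } else {
    draws <- matrix(stats::rnorm(3L * n_draws, mean = r, sd = s),
                    nrow = 3L)
    tot <- colSums(draws)
    ok <- tot > 0
    sd_f <- stats::sd(draws[1, ok] / tot[ok])
  }
  list(f_ao = f_ao, f_red = 1 - f_ao, sd_f_ao = sd_f, sd_f_red = sd_f,
       total = total)
}

#' One particle size class with rates, mass and gene copies
#'
#' @param size_class label, e.g. `"0.2-3"` (um); classes are compared by
#'   their lower bound when ordering.
#' @param rates named numeric vector of process rates (nmol N L-1 d-1), any
#'   subset of AO, NO, NR, N2O-NH4, N2O-NO2, N2O-NO3.
#' @param pn_mass particulate nitrogen, umol N L-1 (> 0 for normalization).
#' @param tsm total suspended matter, mg L-1 (optional).
#' @param gene_copies named numeric vector with elements among
#'   `amoA_archaeal`, `amoA_bacterial`, `nirS`, `nirK` (copies L-1).
#' @param enrichment_factor particle enrichment relative to in situ
#'   (1, 5, 10, 50, ...).
#' @return object of class `size_fraction_set`.
#' @export
size_fraction_set <- function(size_class, rates, pn_mass, tsm = NA_real_,
                              gene_copies = c(amoA_archaeal = 0, amoA_bacterial = 0,
                                              nirS = 0, nirK = 0),
                              enrichment_factor = 1) {
  stopifnot(is.numeric(rates), !is.null(names(rates)),
            is.numeric(pn_mass), length(pn_mass) == 1L)
  if (any(gene_copies < 0, na.rm = TRUE)) {
    stop("gene copies must be >= 0", call. = FALSE)
  }
  structure(list(size_class = size_class, rates = rates, pn_mass = pn_mass,
                 tsm = tsm, gene_copies = gene_copies,
                 enrichment_factor = enrichment_factor),
            class = "size_fraction_set")
}

#' PN-normalized rates along a particle size spectrum
#'
#' Divides each process rate by the particulate-nitrogen mass of its size
#' class, giving nmol N (umol PN)-1 d-1. Classes with zero PN are skipped
#' with a warning.
#'
#' @param fractions list of [size_fraction_set()] objects.
#' @return long data.frame: `size_class`, `process`, `rate`,
#'   `rate_per_pn`.
#' @export
pn_normalized_rates <- function(fractions) {
  stopifnot(all(vapply(fractions, inherits, TRUE, "size_fraction_set")))
  out <- list()
  for (fr in fractions) {
    if (!is.finite(fr$pn_mass) || fr$pn_mass <= 0) {
      warning("size class ", fr$size_class, " has non-positive PN: skipped")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      size_class = fr$size_class,
      process = names(fr$rates),
      rate = as.numeric(fr$rates),
      rate_per_pn = as.numeric(fr$rates) / fr$pn_mass,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(size_class = character(), process = character(),
                                      rate = numeric(), rate_per_pn = numeric()))
  do.call(rbind, out)
}

#' nir:amoA gene copy ratio of a size fraction
#'
#' `(nirS + nirK) / (archaeal amoA + bacterial amoA)`: an index of
#' denitrifier relative to nitrifier abundance.
#'
#' @param fraction a [size_fraction_set()].
#' @return the ratio, or `NA_real_` (with a message) when no amoA copies
#'   were detected.
#' @export
nir_amoa_ratio <- function(fraction) {
  stopifnot(inherits(fraction, "size_fraction_set"))
  g <- fraction$gene_copies
  pick <- function(nm) if (nm %in% names(g)) g[[nm]] else 0
  amoa <- pick("amoA_archaeal") + pick("amoA_bacterial")
  nir <- pick("nirS") + pick("nirK")
  if (amoa <= 0) {
    message("no amoA copies in size class ", fraction$size_class,
            ": nir:amoA undefined")
    return(NA_real_)
  }
  nir / amoa
}

#' Pairwise Pearson correlation screen
#'
#' Correlates every column of `x` against every column of `y` with
#' pairwise-complete observations and two-sided p-values. Cells with
#' p >= `alpha` (after optional Benjamini-Hochberg adjustment), fewer than 3
#' complete pairs, or a constant column are masked (`NA` in `r_masked`).
#'
#' @param x,y data.frames or matrices of numeric columns (`y` defaults to
#'   `x`).
#' @param alpha significance threshold (default 0.05; no multiplicity
#'   correction by default, matching the screening convention).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list of matrices `r`, `p`, `n`, and `r_masked`.
#' @export
pearson_screen <- function(x, y = x, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- as.data.frame(x); y <- as.data.frame(y)
  r <- p <- n <- matrix(NA_real_, ncol(x), ncol(y),
                        dimnames = list(names(x), names(y)))
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(y))) {
      xi <- x[[i]]; yj <- y[[j]]
      ok <- is.finite(xi) & is.finite(yj)
      n[i, j] <- sum(ok)
      if (sum(ok) < 3L || stats::sd(xi[ok]) == 0 || stats::sd(yj[ok]) == 0) next
      ct <- stats::cor.test(xi[ok], yj[ok], method = "pearson",
                            alternative = "two.sided")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  p_used <- p
  if (adjust == "BH") {
    p_used[] <- stats::p.adjust(p, method = "BH")
  }
  r_masked <- r
  r_masked[!(is.finite(p_used) & p_used < alpha)] <- NA_real_
  list(r = r, p = p, n = n, r_masked = r_masked)
}

#' Two-sample Student's t-test on replicate rates
#'
#' Two-sided comparison at the 0.05 convention. Degenerate input (zero
#' variance in both groups) returns p = 1 for equal means and p = 0
#' otherwise instead of erroring.
#'
#' @param bulk,treated numeric vectors of replicate rates (>= 2 each).
#' @param var.equal pooled-variance (classical Student) test by default.
#' @return list with `p`, `t`, `df`, `mean_bulk`, `mean_treated`.
#' @export
compare_rates_ttest <- function(bulk, treated, var.equal = TRUE) {
  bulk <- as.numeric(bulk); treated <- as.numeric(treated)
  if (length(bulk) < 2L || length(treated) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  if (stats::sd(bulk) == 0 && stats::sd(treated) == 0) {
    eq <- isTRUE(all.equal(mean(bulk), mean(treated)))
    return(list(p = if (eq) 1 else 0, t = NA_real_, df = NA_real_,
                mean_bulk = mean(bulk), mean_treated = mean(treated)))
  }
  ht <- stats::t.test(bulk, treated, var.equal = var.equal,
                      alternative = "two.sided")
  list(p = ht$p.value, t = unname(ht$statistic), df = unname(ht$parameter),
       mean_bulk = mean(bulk), mean_treated = mean(treated))
}

#' Depth-integrated volumetric N2O production (areal rate)
#'
#' Trapezoidal integration of a rate profile over depth. The shallowest
#' value is extended unchanged to 0 m and the deepest to `depth_limit`.
#' With rates in nmol N L-1 d-1 (= umol m-3 d-1) and depths in m the
#' integral is in umol N m-2 d-1.
#'
#' @param depth depths, m, strictly increasing, >= 2 values.
#' @param rate volumetric rates at those depths, nmol N L-1 d-1.
#' @param depth_limit bottom of the integration, m (>= max depth).
#' @return areal production, umol m-2 d-1.
#' @export
depth_integrated_production <- function(depth, rate, depth_limit = max(depth)) {
  stopifnot(length(depth) == length(rate), length(depth) >= 2L)
  if (any(diff(depth) <= 0) || any(depth < 0)) {
    stop("depths must be non-negative and strictly increasing", call. = FALSE)
  }
  if (depth_limit < max(depth)) {
    stop("`depth_limit` must be at or below the deepest sample", call. = FALSE)
  }
  z <- c(0, depth, depth_limit)
  r <- c(rate[1], rate, rate[length(rate)])
  sum(diff(z) * (utils::head(r, -1) + utils::tail(r, -1)) / 2)
}

#' Depth-integrated production as a percentage of the air-sea flux
#'
#' @inheritParams depth_integrated_production
#' @param flux air-sea flux, umol m-2 d-1, or a `flux_result`; must be
#'   positive, otherwise the ratio is undefined (`NA`).
#' @return percent of the flux sustained by water-column production.
#' @export
depth_integrated_ratio <- function(depth, rate, flux, depth_limit = max(depth)) {
  if (inherits(flux, "flux_result")) flux <- flux$flux
  if (!is.finite(flux) || flux <= 0) {
    return(NA_real_)
  }
  100 * depth_integrated_production(depth, rate, depth_limit) / flux
}
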