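#' Substrate pool composition after tracer addition
#'
#' Describes a dissolved inorganic nitrogen pool (NH4+, NO2- or NO3-) as the
#' sum of its ambient (14N) concentration and the added 15N tracer. The 15N
#' atom fraction of the amended pool is the dilution factor that converts
#' labelled-product accumulation into a gross transformation rate.
#'
#' @param ambient_14n ambient (pre-addition) concentration, umol L-1; >= 0.
#' @param tracer_15n added 15N tracer concentration, umol L-1; > 0.
#' @param species one of `"NH4"`, `"NO2"`, `"NO3"`.
#' @return an object of class `pool_composition`.
#' @examples
#' pool_composition(8.1, 5, "NH4")
#' @export
pool_composition <- function(ambient_14n, tracer_15n, species = c("NH4", "NO2", "NO3")) {
  species <- match.arg(species)
  if (!is.numeric(ambient_14n) || length(ambient_14n) != 1L || is.na(ambient_14n) ||
      ambient_14n < 0) {
    stop("invalid pool: `ambient_14n` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(tracer_15n) || length(tracer_15n) != 1L || is.na(tracer_15n) ||
      tracer_15n <= 0) {
    stop("invalid pool: `tracer_15n` must be a single positive number", call. = FALSE)
  }
  structure(
    list(ambient_14n = as.numeric(ambient_14n),
         tracer_15n = as.numeric(tracer_15n),
         species = species),
    class = "pool_composition"
  )
}

#' @export
print.pool_composition <- function(x, ...) {
  cat(sprintf("<pool_composition> %s: ambient %.4g + tracer %.4g umol L-1 (F = %.4f)\n",
              x$species, x$ambient_14n, x$tracer_15n, atom_fraction(x)))
  invisible(x)
}

#' 15N atom fraction of an amended pool
#'
#' `F = tracer / (ambient + tracer)`. A pure-tracer pool (ambient = 0, so
#' F = 1) is rejected: the mass-44 inference divides by `F` and multiplies by
#' `(1 - F)`, so the method is undefined without an ambient pool.
#'
#' @param pool a [pool_composition()], or a plain numeric atom fraction in
#'   (0, 1) which is validated and returned (convenience for downstream
#'   functions that accept either form).
#' @return atom fraction in (0, 1).
#' @examples
#' atom_fraction(pool_composition(5, 5, "NH4")) # 0.5
#' @export
atom_fraction <- function(pool) {
  if (is.numeric(pool) && length(pool) == 1L) {
    f <- as.numeric(pool)
    if (is.na(f) || f <= 0 || f >= 1) {
      stop("atom fraction must lie strictly in (0, 1)", call. = FALSE)
    }
    return(f)
  }
  if (!inherits(pool, "pool_composition")) {
    stop("`pool` must be a pool_composition or a numeric atom fraction", call. = FALSE)
  }
  if (pool$ambient_14n == 0) {
    stop("pure-tracer pool: ambient 14N is zero so F = 1; rate inference undefined",
         call. = FALSE)
  }
  pool$tracer_15n / (pool$ambient_14n + pool$tracer_15n)
}

#' Binomial isotopologue pairing probabilities
#'
#' Under single-pool production, each N2O molecule combines two N atoms drawn
#' independently from a pool with 15N atom fraction `F`, so the expected
#' proportions of the mass 44/45/46 isotopologues are binomial:
#' `p44 = (1-F)^2`, `p45 = 2F(1-F)`, `p46 = F^2`.
#'
#' @param f 15N atom fraction, strictly in (0, 1).
#' @return named numeric vector `c(p44, p45, p46)` summing to 1.
#' @examples
#' pairing_probabilities(0.5)
#' @export
pairing_probabilities <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f >= 1) {
    stop("`f` must be a single atom fraction strictly in (0, 1)", call. = FALSE)
  }
  c(p44 = (1 - f)^2, p45 = 2 * f * (1 - f), p46 = f^2)
}

#' Infer the unlabelled (mass 44) N2O production rate
#'
#' The mass-44 rate cannot be measured against the large ambient N2O
#' background; under the binomial pairing model it is inferred from the
#' mass-46 rate as `r44 = r46 * ((1 - F) / F)^2`, which equals the squared
#' ratio of the 14N to 15N substrate concentrations.
#'
#' @param r46 mass-46 N2O production rate (nmol N2O L-1 d-1); negative values
#'   (below-detection slopes) are clamped to zero with a warning.
#' @param pool [pool_composition()] of the labelled substrate, or a numeric
#'   atom fraction.
#' @return inferred mass-44 rate, same units as `r46`.
#' @export
infer_mass44_rate <- function(r46, pool) {
  f <- atom_fraction(pool)
  if (!is.numeric(r46) || length(r46) != 1L || is.na(r46)) {
    stop("`r46` must be a single finite number", call. = FALSE)
  }
  if (r46 < 0) {
    warning("negative mass-46 rate (below-detection isotopologue) clamped to 0")
    r46 <- 0
  }
  r46 * ((1 - f) / f)^2
}

#' Total gross N2O production rate from measured isotopologue rates
#'
#' Sums the measured mass-45 and mass-46 accumulation rates with the inferred
#' mass-44 rate. The total is reported both in molecule units
#' (nmol N2O L-1 d-1) and in nitrogen units (nmol N L-1 d-1, twice the
#' molecule rate, the convention used for reporting).
#'
#' When the mass-46 channel is below detection but mass 45 is not, the total
#' can alternatively be estimated as `r45 / p45`; see
#' [n2o_production_rate()], which exposes that fallback. Here negative inputs
#' are clamped to zero (below-detection slopes) and a total of zero is
#' flagged `below_detection`.
#'
#' @param r45,r46 measured isotopologue production rates (nmol N2O L-1 d-1).
#' @param pool [pool_composition()] of the labelled substrate (or numeric F).
#' @return object of class `isotopologue_rates` with fields `r44`, `r45`,
#'   `r46`, `r_total_molecules`, `r_total_n`, `below_detection`.
#' @examples
#' total_n2o_rate(0.4712, 0.1444, 0.38)
#' @export
total_n2o_rate <- function(r45, r46, pool) {
  f <- atom_fraction(pool)
  stopifnot(is.numeric(r45), length(r45) == 1L, is.finite(r45),
            is.numeric(r46), length(r46) == 1L, is.finite(r46))
  if (r45 < 0) {
    warning("negative mass-45 rate (below-detection isotopologue) clamped to 0")
    r45 <- 0
  }
  r44 <- infer_mass44_rate(r46, f)  # warns and clamps if r46 < 0
  r46 <- max(r46, 0)
  total <- r44 + r45 + r46
  structure(
    list(r44 = r44, r45 = r45, r46 = r46,
         r_total_molecules = total,
         r_total_n = 2 * total,
         below_detection = (r45 == 0 && r46 == 0)),
    class = "isotopologue_rates"
  )
}

#' @export
print.isotopologue_rates <- function(x, ...) {
  cat(sprintf(paste0("<isotopologue_rates> r44 %.4g (inferred), r45 %.4g, r46 %.4g",
                     " | total %.4g nmol N2O L-1 d-1 = %.4g nmol N L-1 d-1%s\n"),
              x$r44, x$r45, x$r46, x$r_total_molecules, x$r_total_n,
              if (x$below_detection) " [below detection]" else ""))
  invisible(x)
}

#' Single-pool binomial consistency diagnostic
#'
#' Ratio of the observed `r45 / r46` to its binomial expectation
#' `2 (1 - F) / F`. Values near 1 support the single-pool pairing assumption
#' behind the mass-44 inference; departures indicate hybrid formation or
#' multiple differently-labelled pools. Purely diagnostic: never used to
#' adjust rates.
#'
#' @inheritParams total_n2o_rate
#' @return diagnostic ratio, or `NA_real_` when `r46` is zero (undefined).
#' @export
binomial_consistency <- function(r45, r46, pool) {
  f <- atom_fraction(pool)
  stopifnot(is.numeric(r45), length(r45) == 1L, is.finite(r45),
            is.numeric(r46), length(r46) == 1L, is.finite(r46))
  if (r46 <= 0) {
    message("mass-46 rate is zero: binomial consistency diagnostic undefined")
    return(NA_real_)
  }
  (r45 / r46) / (2 * (1 - f) / f)
}
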