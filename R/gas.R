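# Published coefficient tables, embedded as data.
#
# Weiss & Price (1980, Mar. Chem. 8, 347-359), Table 2: N2O solubility F'
# (mol L-1 atm-1) for moist air at 100% humidity,
#   ln F' = A1 + A2(100/T) + A3 ln(T/100) + A4 (T/100)^2
#           + S [B1 + B2 (T/100) + B3 (T/100)^2],  T in Kelvin.
# Fit range roughly 0-40 degC, S 0-40.
.wp1980_n2o <- c(a1 = -165.8806, a2 = 222.8743, a3 = 92.0792, a4 = -1.48425,
                 b1 = -0.056235, b2 = 0.031619, b3 = -0.0048472)

# Wanninkhof (2014, Limnol. Oceanogr. Methods 12, 351-362), Table 1:
# Schmidt number polynomials Sc = A + Bt + Ct^2 + Dt^3 + Et^4 (t in degC,
# 0-40) for N2O in seawater (S = 35) and fresh water (S = 0).
.w2014_n2o_sea   <- c(2356.2, -166.38, 6.3952, -0.13422, 0.0011506)
.w2014_n2o_fresh <- c(2141.2, -152.56, 5.8963, -0.12411, 0.0010655)

#' A surface-water record for air-sea flux computation
#'
#' @param temperature water temperature, degC (within the solubility fit
#'   range, 0-40).
#' @param salinity practical salinity (0-42).
#' @param c_obs observed dissolved N2O, nmol L-1.
#' @param x_air atmospheric N2O dry mole fraction, ppb (e.g. the monthly
#'   Mauna Loa value for the sampling month).
#' @param wind_u10 wind speed at 10 m, m s-1.
#' @param pressure total pressure, atm (default 1).
#' @return object of class `surface_record`.
#' @export
surface_record <- function(temperature, salinity, c_obs, x_air, wind_u10,
                           pressure = 1) {
  stopifnot(is.numeric(temperature), is.numeric(salinity), is.numeric(c_obs),
            is.numeric(x_air), is.numeric(wind_u10), is.numeric(pressure))
  if (temperature < -2 || temperature > 40) {
    stop("temperature out of range [-2, 40] degC", call. = FALSE)
  }
  if (salinity < 0 || salinity > 42) stop("salinity out of range [0, 42]", call. = FALSE)
  if (c_obs < 0) stop("`c_obs` must be >= 0", call. = FALSE)
  if (x_air < 0) stop("`x_air` must be >= 0", call. = FALSE)
  if (wind_u10 < 0) stop("`wind_u10` must be >= 0", call. = FALSE)
  structure(list(temperature = temperature, salinity = salinity, c_obs = c_obs,
                 x_air = x_air, wind_u10 = wind_u10, pressure = pressure),
            class = "surface_record")
}

#' N2O solubility function (moist air)
#'
#' Weiss & Price (1980) solubility `F'` such that the air-equilibrium
#' concentration is `F' * x_air * pressure`. Evaluated outside the published
#' fit range this errors rather than extrapolating silently.
#'
#' @param temperature degC, in `[0, 40]`.
#' @param salinity practical salinity, in `[0, 40]`.
#' @return solubility in mol L-1 atm-1.
#' @export
n2o_solubility <- function(temperature, salinity) {
  if (any(temperature < 0 | temperature > 40)) {
    stop("temperature outside the solubility fit range [0, 40] degC", call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 40)) {
    stop("salinity outside the solubility fit range [0, 40]", call. = FALSE)
  }
  tk <- temperature + 273.15
  k <- .wp1980_n2o
  exp(k[["a1"]] + k[["a2"]] * (100 / tk) + k[["a3"]] * log(tk / 100) +
        k[["a4"]] * (tk / 100)^2 +
        salinity * (k[["b1"]] + k[["b2"]] * (tk / 100) + k[["b3"]] * (tk / 100)^2))
}

#' Air-equilibrium N2O concentration
#'
#' @param record a [surface_record()].
#' @return equilibrium concentration, nmol L-1. (With solubility in
#'   mol L-1 atm-1 and the atmospheric mole fraction in ppb, the product is
#'   numerically in nmol L-1.)
#' @export
equilibrium_concentration <- function(record) {
  stopifnot(inherits(record, "surface_record"))
  n2o_solubility(record$temperature, record$salinity) * record$x_air * record$pressure
}

#' Percent saturation of dissolved N2O
#'
#' @param c_obs observed concentration, nmol L-1.
#' @param c_eq equilibrium concentration, nmol L-1; must be positive.
#' @return saturation, percent.
#' @export
saturation <- function(c_obs, c_eq) {
  if (any(c_eq <= 0)) stop("`c_eq` must be positive", call. = FALSE)
  100 * c_obs / c_eq
}

#' Schmidt number for N2O
#'
#' Fourth-order polynomial in temperature (Wanninkhof 2014); salinity is
#' handled by linear interpolation between the freshwater (S = 0) and
#' seawater (S = 35) polynomials, extended linearly for brackish-to-
#' hypersaline values up to 42.
#'
#' @param temperature degC, in `[0, 40]`.
#' @param salinity practical salinity (default 35).
#' @return dimensionless Schmidt number.
#' @export
schmidt_number <- function(temperature, salinity = 35) {
  if (any(temperature < 0 | temperature > 40)) {
    stop("temperature outside the Schmidt-number fit range [0, 40] degC",
         call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 42)) {
    stop("salinity out of range [0, 42]", call. = FALSE)
  }
  poly4 <- function(k, t) k[1] + k[2] * t + k[3] * t^2 + k[4] * t^3 + k[5] * t^4
  sc_f <- poly4(.w2014_n2o_fresh, temperature)
  sc_s <- poly4(.w2014_n2o_sea, temperature)
  sc_f + (salinity / 35) * (sc_s - sc_f)
}

#' Gas transfer velocity
#'
#' Quadratic wind-speed parameterization `k = 0.251 u^2 (Sc/660)^-0.5`
#' (Wanninkhof 2014), with 660 the Schmidt number of CO2 in seawater at
#' 20 degC.
#'
#' @param wind_u10 wind speed at 10 m, m s-1.
#' @param sc Schmidt number (> 0).
#' @return transfer velocity, cm h-1.
#' @export
transfer_velocity <- function(wind_u10, sc) {
  if (any(sc <= 0)) stop("Schmidt number must be positive", call. = FALSE)
  if (any(wind_u10 < 0)) stop("wind speed must be >= 0", call. = FALSE)
  0.251 * wind_u10^2 * (sc / 660)^-0.5
}

#' Air-sea N2O flux for a surface record
#'
#' Composes solubility, saturation, Schmidt number and transfer velocity
#' into the bulk flux `F = k (C_obs - C_eq)`. The unit conversion
#' cm h-1 x nmol L-1 -> umol m-2 d-1 is the exact factor 0.24.
#'
#' @param record a [surface_record()].
#' @return object of class `flux_result` with `c_eq` (nmol L-1),
#'   `saturation_pct`, `schmidt`, `k` (cm h-1) and `flux` (umol m-2 d-1;
#'   positive = outgassing).
#' @export
air_sea_flux <- function(record) {
  stopifnot(inherits(record, "surface_record"))
  c_eq <- equilibrium_concentration(record)
  sc <- schmidt_number(record$temperature, record$salinity)
  k <- transfer_velocity(record$wind_u10, sc)
  structure(
    list(c_eq = c_eq,
         saturation_pct = saturation(record$c_obs, c_eq),
         schmidt = sc, k = k,
         flux = k * (record$c_obs - c_eq) * 0.24),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> c_eq %.3g nmol L-1, saturation %.1f%%, Sc %.0f, k %.3g cm h-1, flux %.3g umol m-2 d-1\n",
              x$c_eq, x$saturation_pct, x$schmidt, x$k, x$flux))
  invisible(x)
}

#' Convert dissolved oxygen from mg L-1 to umol L-1 and flag hypoxia
#'
#' Uses a molar mass of 32.00 g mol-1 for O2 (the rounding conventional in
#' hypoxia thresholds), so 2 mg L-1 converts to exactly 62.5 umol L-1.
#'
#' @param do_mgl dissolved oxygen, mg L-1 (vectorized).
#' @param threshold_umol hypoxia threshold, umol L-1 (default 62.5).
#' @return data.frame with `do_umol` and logical `hypoxic`
#'   (`do_umol < threshold_umol`).
#' @export
oxygen_mgl_to_umol <- function(do_mgl, threshold_umol = 62.5) {
  if (any(!is.finite(do_mgl)) || any(do_mgl < 0)) {
    stop("`do_mgl` must be finite and >= 0", call. = FALSE)
  }
  do_umol <- do_mgl * 1000 / 32.00
  data.frame(do_umol = do_umol, hypoxic = do_umol < threshold_umol)
}
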