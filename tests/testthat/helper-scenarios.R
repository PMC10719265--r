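# shared fixture builders (everything is generated in code; no data files)

pool38 <- function() pool_composition(8.1579, 5, "NH4")   # F very close to 0.38

# exact noise-free series with a known slope (units per day) for one analyte
exact_series <- function(slope_per_day, times_h = c(0, 12, 24),
                         analyte = "15NO2", substrate = "15NH4",
                         pools = list(NH4 = pool_composition(5, 5, "NH4"))) {
  incubation_series(substrate,
                    time_h = times_h,
                    replicate = rep(1, length(times_h)),
                    analyte = rep(analyte, length(times_h)),
                    value = slope_per_day * times_h / 24,
                    pools = pools)
}

# noise-free N2O series for a given total rate (nmol N L-1 d-1) and pool
exact_n2o_series <- function(rate_n, pool, times_h = c(0, 6, 12), reps = 3) {
  f <- atom_fraction(pool)
  pp <- pairing_probabilities(f)
  mol <- rate_n / 2
  tt <- rep(times_h, each = reps)
  pools <- list(pool)
  names(pools) <- pool$species
  incubation_series(paste0("15", pool$species),
                    time_h = c(tt, tt),
                    replicate = rep(seq_len(reps), times = 2 * length(times_h)),
                    analyte = c(rep("45N2O", length(tt)), rep("46N2O", length(tt))),
                    value = c(mol * pp[["p45"]] * tt / 24,
                              mol * pp[["p46"]] * tt / 24),
                    pools = pools)
}
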