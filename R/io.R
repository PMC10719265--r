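# Tidy CSV dialects (UTF-8, header row, '.' decimal).
#
# incubation table: station, depth, substrate_label, time_h, replicate,
#   analyte, value, pool_ambient, pool_tracer
#   (pool columns describe the labelled substrate at t0; products in
#   umol L-1, N2O isotopologues in nmol L-1)
# station table: station, temperature, salinity, do_umol, c_obs, wind_u10,
#   x_air [, pressure]
# profile table: station, depth_m, rate_n2o

.user_error <- function(...) {
  stop(structure(class = c("n2o_user_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Write incubation series to the documented CSV dialect
#'
#' @param series_list named list of [incubation_series()] (e.g. the output
#'   of [simulate_incubation()]).
#' @param path output CSV path.
#' @param station,depth identifiers written into each row (overridden by a
#'   series' own metadata when present).
#' @return `path`, invisibly.
#' @export
write_incubation_csv <- function(series_list, path, station = "S01", depth = 0) {
  rows <- lapply(series_list, function(s) {
    sp <- sub("^15", "", s$substrate_label)
    pool <- s$pools[[sp]]
    md <- s$metadata
    data.frame(station = if (!is.null(md$station)) md$station else station,
               depth = if (!is.null(md$depth)) md$depth else depth,
               substrate_label = s$substrate_label,
               time_h = s$data$time_h, replicate = s$data$replicate,
               analyte = s$data$analyte, value = s$data$value,
               pool_ambient = pool$ambient_14n, pool_tracer = pool$tracer_15n,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an incubation CSV into series objects
#'
#' Rows failing validation (negative or missing time/value, unknown analyte)
#' are rejected individually and reported with their line numbers; the
#' remainder is parsed. A missing required column is a schema error. Series
#' are keyed by station, depth, substrate label and analyte class
#' (transformation product vs. N2O isotopologues), so row order is
#' irrelevant.
#'
#' @param path CSV path.
#' @return named list of [incubation_series()]; names are
#'   `station/depth/process`.
#' @export
read_incubation_table <- function(path) {
  if (!file.exists(path)) .user_error("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("station", "depth", "substrate_label", "time_h", "replicate",
           "analyte", "value", "pool_ambient", "pool_tracer")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    .user_error("schema error: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  bad <- !is.finite(d$time_h) | d$time_h < 0 |
    !is.finite(d$value) | d$value < 0 |
    !d$analyte %in% c("15NO2", "15NO3", "45N2O", "46N2O") |
    !d$substrate_label %in% c("15NH4", "15NO2", "15NO3")
  if (any(bad)) {
    message(sum(bad), " row(s) rejected (line ",
            paste(which(bad) + 1L, collapse = ", "), ")")
    d <- d[!bad, , drop = FALSE]
  }
  if (!nrow(d)) .user_error("no valid rows in ", path)
  d$class <- ifelse(d$analyte %in% c("45N2O", "46N2O"), "n2o", "product")
  key <- interaction(d$station, d$depth, d$substrate_label, d$class, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    g <- d[key == k, , drop = FALSE]
    sp <- sub("^15", "", g$substrate_label[1])
    pools <- list(pool_composition(g$pool_ambient[1], g$pool_tracer[1], sp))
    names(pools) <- sp
    m <- .process_map[.process_map$substrate == g$substrate_label[1], ]
    proc <- if (g$class[1] == "n2o") m$n2o_process else m$process
    ser <- incubation_series(g$substrate_label[1], g$time_h, g$replicate,
                             g$analyte, g$value, pools,
                             metadata = list(station = g$station[1],
                                             depth = g$depth[1]))
    out[[paste(g$station[1], g$depth[1], proc, sep = "/")]] <- ser
  }
  out
}

#' Read a station table CSV
#'
#' @param path CSV path with columns station, temperature, salinity,
#'   do_umol, c_obs, wind_u10, x_air and optionally pressure.
#' @return validated data.frame.
#' @export
read_station_table <- function(path) {
  if (!file.exists(path)) .user_error("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("station", "temperature", "salinity", "c_obs", "wind_u10", "x_air")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    .user_error("schema error: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  if (is.null(d$pressure)) d$pressure <- 1
  d
}

#' Read a rate-profile table CSV
#'
#' @param path CSV with columns station, depth_m, rate_n2o.
#' @return validated data.frame.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) .user_error("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("station", "depth_m", "rate_n2o")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    .user_error("schema error: missing column(s) ",
                paste(missing_cols, collapse = ", "))
  }
  d
}
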