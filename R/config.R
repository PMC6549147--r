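#' Pipeline configuration
#'
#' Assembles the full set of tunable constants used across the pipeline, with
#' defaults reproducing the published processing settings: 0.03 kg m^-3
#' mixed-layer density threshold referenced to 10 m, annual cycles starting
#' 1 July with a 1 Nov - end Feb bloom window requiring at least 8 profiles,
#' 20-day bins, 1-degree deep-EKE boxes kept only above 5 samples and smoothed
#' with a 100 km Gaussian radius, 550 km optimal-interpolation scale on a
#' 0.5-degree grid with 25 m vertical spacing, 6-hourly fourth-order
#' Runge-Kutta advection seeded at 1/4 degree, iron-source disks of 1-degree
#' radius centered at (30E, 50S) and (30.5E, 49.5S), and a 500 m
#' shallow-bathymetry source cutoff.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class \code{vb_config}: a validated named list.
#' @details Fields (units): \code{cal_dark} (counts), \code{cal_slope}
#'   (mg m^-3 per count), \code{f490} (dimensionless, in (0,1]),
#'   \code{mld_threshold} (kg m^-3), \code{mld_ref_depth} (m),
#'   \code{bloom_window_start}/\code{bloom_window_end} ("MM-DD"),
#'   \code{cycle_start} ("MM-DD"), \code{bin_days}, \code{min_profiles},
#'   \code{eke_bin_deg}, \code{eke_min_count}, \code{eke_radius_km},
#'   \code{eke_high_threshold} (cm^2 s^-2), \code{oi_scale_km}, \code{dz_m},
#'   \code{rk4_dt_h}, \code{scavenging_efold_days}, \code{lookback_days},
#'   \code{seed_resolution_deg}, \code{source_disks} (data.frame lon/lat/
#'   radius_deg), \code{shallow_source_max_depth} (m), \code{zeu_coefs}
#'   (log10 Zeu cubic in log10 surface Chl), \code{rng_seed}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cal_dark = 50,
    cal_slope = 0.007,
    f490 = 0.3,
    mld_threshold = 0.03,
    mld_ref_depth = 10,
    bloom_window_start = "11-01",
    bloom_window_end = "02-28",
    cycle_start = "07-01",
    bin_days = 20,
    min_profiles = 8,
    eke_bin_deg = 1,
    eke_min_count = 5,
    eke_radius_km = 100,
    eke_high_threshold = 150,
    oi_scale_km = 550,
    oi_neff_floor = 0.2,
    dz_m = 25,
    rk4_dt_h = 6,
    scavenging_efold_days = 90,
    lookback_days = 150,
    seed_resolution_deg = 0.25,
    source_disks = data.frame(lon = c(30, 30.5), lat = c(-50, -49.5),
                              radius_deg = c(1, 1)),
    shallow_source_max_depth = 500,
    zeu_coefs = c(1.524, -0.436, -0.0145, 0.0186),
    rng_seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "vb_config")
}

validate_config <- function(cfg) {
  pos <- c("cal_slope", "mld_threshold", "mld_ref_depth", "bin_days",
           "eke_bin_deg", "eke_radius_km", "oi_scale_km", "dz_m", "rk4_dt_h",
           "scavenging_efold_days", "lookback_days", "seed_resolution_deg",
           "shallow_source_max_depth")
  for (k in pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]]) ||
        cfg[[k]] <= 0)
      stop("configuration field '", k, "' must be a single positive number")
  if (cfg$min_profiles < 1) stop("min_profiles must be >= 1")
  if (cfg$f490 <= 0 || cfg$f490 > 1) stop("f490 must lie in (0, 1]")
  for (k in c("bloom_window_start", "bloom_window_end", "cycle_start"))
    if (!grepl("^[01][0-9]-[0-3][0-9]$", cfg[[k]]))
      stop("configuration field '", k, "' must be 'MM-DD'")
  invisible(cfg)
}

#' @export
print.vb_config <- function(x, ...) {
  cat("<ventbloom pipeline configuration>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.data.frame(v))
      v <- paste(apply(v, 1, function(r) paste0("(", paste(r, collapse = ", "), ")")),
                 collapse = " ")
    cat(sprintf("  %-26s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' The on-disk format is one \code{key = value} pair per line; vectors are
#' comma-separated, source disks are written as \code{lon/lat/radius} triples
#' separated by semicolons, and \code{#} starts a comment.
#'
#' @param path file path.
#' @return \code{read_config}: a \code{vb_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  over <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed configuration line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    over[[key]] <- parse_config_value(key, val)
  }
  do.call(pipeline_config, over)
}

parse_config_value <- function(key, val) {
  if (key == "source_disks") {
    trip <- strsplit(strsplit(val, ";")[[1]], "/")
    m <- do.call(rbind, lapply(trip, function(t) as.numeric(trimws(t))))
    return(data.frame(lon = m[, 1], lat = m[, 2], radius_deg = m[, 3]))
  }
  if (key %in% c("bloom_window_start", "bloom_window_end", "cycle_start"))
    return(val)
  out <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
  if (anyNA(out)) stop("non-numeric value for configuration key '", key, "'")
  out
}

#' @rdname read_config
#' @param cfg a \code{vb_config}.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.data.frame(v))
      v <- paste(apply(v, 1, paste, collapse = "/"), collapse = "; ")
    else v <- paste(format(v, digits = 15), collapse = ", ")
    sprintf("%s = %s", k, v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
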