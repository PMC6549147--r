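# Readers and writers for the pipeline's file formats. Every format is plain
# text: long-form CSV with a small "# key: value" metadata header, so fixtures
# diff cleanly and round-trip losslessly at full double precision.

TIME_ORIGIN <- "2000-01-01"

#' Convert timestamps to/from pipeline time (days since 2000-01-01 UTC)
#' @param t POSIXct, Date, or ISO-8601 character.
#' @return numeric days since 2000-01-01 00:00 UTC.
#' @export
days_since_2000 <- function(t) {
  if (inherits(t, "Date")) t <- as.POSIXct(as.character(t), tz = "UTC")
  if (is.character(t)) t <- as.POSIXct(t, tz = "UTC")
  as.numeric(difftime(t, as.POSIXct(TIME_ORIGIN, tz = "UTC"), units = "days"))
}

#' @rdname days_since_2000
#' @param d numeric days since 2000-01-01 UTC.
#' @export
time_from_days <- function(d) {
  as.POSIXct(TIME_ORIGIN, tz = "UTC") + d * 86400
}

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# ---- metadata-header CSV primitives ----------------------------------------

write_meta_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (!length(body) || all(!nzchar(trimws(body))))
    return(list(data = data.frame(), meta = meta))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(data = df, meta = meta)
}

# ---- float profiles ---------------------------------------------------------

#' Read a float profile series
#'
#' Reads bio-optical float casts in the packaged CSV dialect (one row per
#' vertical level). Levels with \code{qc_flag != 1} are dropped; casts are
#' returned sorted by time with pressure strictly increasing.
#'
#' @param path file path.
#' @param dialect input dialect; only \code{"fixture_csv"} is supported.
#'   (Native Argo NetCDF ingestion is out of scope of this build.)
#' @return a list of \code{vb_profile} objects, each with fields
#'   \code{float_id}, \code{cycle}, \code{time}, \code{lat}, \code{lon},
#'   \code{day_flag}, and level vectors \code{pres} (dbar), \code{temp}
#'   (deg C), \code{psal}, \code{fluo} (counts), \code{bbp700} (m^-1).
#' @export
read_profile_series <- function(path, dialect = "fixture_csv") {
  if (!identical(dialect, "fixture_csv"))
    stop("unsupported profile dialect: '", dialect, "'")
  r <- read_meta_csv(path)
  df <- r$data
  if (!nrow(df)) {
    warning("empty profile file: ", path)
    return(list())
  }
  need <- c("float_id", "cycle", "time", "lat", "lon", "day_flag",
            "pres_dbar", "temp_C", "psal", "fluo_counts", "bbp700_m1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed profile file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if ("qc_flag" %in% names(df)) df <- df[df$qc_flag == 1, , drop = FALSE]
  df$lon <- normalize_lon(df$lon)
  key <- paste(df$float_id, df$cycle, sep = "\r")
  profs <- lapply(split(df, key), function(d) {
    d <- d[order(d$pres_dbar), , drop = FALSE]
    if (any(diff(d$pres_dbar) <= 0))
      stop("malformed profile file ", path, ": non-increasing pressure in float ",
           d$float_id[1], " cycle ", d$cycle[1])
    new_profile(float_id = as.character(d$float_id[1]),
                cycle = as.integer(d$cycle[1]),
                time = parse_time(d$time[1]),
                lat = d$lat[1], lon = d$lon[1],
                day_flag = as.logical(d$day_flag[1]),
                pres = d$pres_dbar, temp = d$temp_C, psal = d$psal,
                fluo = d$fluo_counts, bbp700 = d$bbp700_m1)
  })
  profs <- unname(profs)
  profs[order(vapply(profs, function(p) as.numeric(p$time), numeric(1)))]
}

new_profile <- function(float_id, cycle, time, lat, lon, day_flag,
                        pres, temp, psal, fluo, bbp700) {
  n <- length(pres)
  stopifnot(length(temp) == n, length(psal) == n, length(fluo) == n,
            length(bbp700) == n)
  structure(list(float_id = float_id, cycle = cycle, time = time,
                 lat = lat, lon = lon, day_flag = day_flag,
                 pres = pres, temp = temp, psal = psal,
                 fluo = fluo, bbp700 = bbp700),
            class = "vb_profile")
}

#' @export
print.vb_profile <- function(x, ...) {
  cat(sprintf("<vb_profile %s cycle %d  %s  (%.3f, %.3f)  %d levels %s>\n",
              x$float_id, x$cycle, fmt_time(x$time), x$lat, x$lon,
              length(x$pres), if (x$day_flag) "day" else "night"))
  invisible(x)
}

#' @rdname read_profile_series
#' @param profiles list of \code{vb_profile}.
#' @export
write_profile_series <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(float_id = p$float_id, cycle = p$cycle, time = fmt_time(p$time),
               lat = p$lat, lon = p$lon, day_flag = as.integer(p$day_flag),
               pres_dbar = p$pres, temp_C = p$temp, psal = p$psal,
               fluo_counts = p$fluo, bbp700_m1 = p$bbp700, qc_flag = 1L)
  })
  write_meta_csv(do.call(rbind, rows), path,
                 meta = list(format = "ventbloom profile fixture v1"))
}

# ---- gridded velocity series ------------------------------------------------

#' Construct a gridded velocity series
#'
#' @param lon,lat strictly increasing regular coordinate vectors, degrees.
#' @param time strictly increasing times, days since 2000-01-01 UTC.
#' @param u,v arrays dim (lon, lat, time), m s^-1; NA marks land/missing.
#' @return object of class \code{vb_velocity}.
#' @export
velocity_series <- function(lon, lat, time, u, v) {
  check_regular <- function(x, nm) {
    if (length(x) > 1 && any(diff(x) <= 0))
      stop(nm, " coordinate must be regular and strictly increasing")
    if (length(x) > 2 && max(abs(diff(diff(x)))) > 1e-6 * mean(diff(x)))
      stop(nm, " coordinate must be regular and strictly increasing")
  }
  check_regular(lon, "lon"); check_regular(lat, "lat")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time coordinate must be strictly increasing")
  dm <- c(length(lon), length(lat), length(time))
  u <- array(u, dm); v <- array(v, dm)
  structure(list(lon = lon, lat = lat, time = time, u = u, v = v),
            class = "vb_velocity")
}

#' @export
print.vb_velocity <- function(x, ...) {
  cat(sprintf("<vb_velocity %d x %d grid, %d time slice(s), lon %.2f..%.2f, lat %.2f..%.2f>\n",
              length(x$lon), length(x$lat), length(x$time),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' Read / write a gridded velocity series
#'
#' Long-form CSV (\code{time_days, lat, lon, u, v}) with metadata header.
#' A \code{units} header of \code{cm s-1} is converted to m s^-1 on read.
#'
#' @param path file path.
#' @return \code{read_velocity_series}: a \code{vb_velocity}.
#' @export
read_velocity_series <- function(path) {
  r <- read_meta_csv(path)
  df <- r$data
  need <- c("time_days", "lat", "lon", "u", "v")
  if (!all(need %in% names(df)))
    stop("malformed velocity file ", path, ": need columns ",
         paste(need, collapse = ", "))
  fac <- 1
  if (!is.null(r$meta$units)) {
    un <- gsub("[^a-z]", "", tolower(r$meta$units))
    fac <- switch(un, ms = 1, cms = 0.01,
                  stop("unknown velocity units '", r$meta$units, "'"))
  }
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  tim <- sort(unique(df$time_days))
  if (nrow(df) != length(lon) * length(lat) * length(tim))
    stop("malformed velocity file ", path, ": irregular or incomplete grid")
  i <- match(df$lon, lon); j <- match(df$lat, lat); k <- match(df$time_days, tim)
  dm <- c(length(lon), length(lat), length(tim))
  u <- array(NA_real_, dm); v <- array(NA_real_, dm)
  idx <- cbind(i, j, k)
  u[idx] <- df$u * fac
  v[idx] <- df$v * fac
  velocity_series(lon, lat, tim, u, v)
}

#' @rdname read_velocity_series
#' @param vel a \code{vb_velocity}.
#' @export
write_velocity_series <- function(vel, path) {
  g <- expand.grid(lon = vel$lon, lat = vel$lat, time_days = vel$time,
                   KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(time_days = g$time_days, lat = g$lat, lon = g$lon,
                   u = as.vector(vel$u), v = as.vector(vel$v))
  write_meta_csv(df, path, meta = list(format = "ventbloom velocity v1",
                                       units = "m s-1"))
}

# ---- scalar lon/lat grids (bathymetry, dynamic height, masks) ---------------

#' Construct / read / write a scalar lon-lat grid
#'
#' Carrier for bathymetry (depth in m, positive down), dynamic height, and
#' gridded classification masks. On disk: long CSV \code{lat, lon, <name>}.
#'
#' @param lon,lat strictly increasing coordinate vectors, degrees.
#' @param z matrix dim (lon, lat).
#' @param name value-column name used on disk (e.g. \code{"depth_m"}).
#' @return a \code{vb_grid} with fields \code{lon}, \code{lat}, \code{z}.
#' @export
field_grid <- function(lon, lat, z, name = "value") {
  z <- matrix(z, length(lon), length(lat))
  structure(list(lon = lon, lat = lat, z = z, name = name), class = "vb_grid")
}

#' @rdname field_grid
#' @param path file path.
#' @export
read_field_grid <- function(path) {
  r <- read_meta_csv(path)
  df <- r$data
  if (!all(c("lat", "lon") %in% names(df)) || ncol(df) < 3)
    stop("malformed grid file ", path)
  name <- setdiff(names(df), c("lat", "lon"))[1]
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  z <- matrix(NA_real_, length(lon), length(lat))
  z[cbind(match(df$lon, lon), match(df$lat, lat))] <- df[[name]]
  field_grid(lon, lat, z, name)
}

#' @rdname field_grid
#' @param grid a \code{vb_grid}.
#' @export
write_field_grid <- function(grid, path) {
  g <- expand.grid(lon = grid$lon, lat = grid$lat, KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(lat = g$lat, lon = g$lon, value = as.vector(grid$z))
  names(df)[3] <- grid$name
  write_meta_csv(df, path, meta = list(format = "ventbloom grid v1"))
}

# bilinear sample of a vb_grid at points; outside -> NA
grid_lookup <- function(grid, lon, lat, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (method == "nearest") {
    i <- pmin(pmax(round(approx(grid$lon, seq_along(grid$lon), lon, rule = 1)$y), 1),
              length(grid$lon))
    j <- pmin(pmax(round(approx(grid$lat, seq_along(grid$lat), lat, rule = 1)$y), 1),
              length(grid$lat))
    out <- rep(NA_real_, length(lon))
    ok <- !is.na(i) & !is.na(j)
    out[ok] <- grid$z[cbind(i[ok], j[ok])]
    return(out)
  }
  bilinear_sample(grid$lon, grid$lat, grid$z, lon, lat)
}

bilinear_sample <- function(gx, gy, z, x, y) {
  n <- length(x)
  out <- rep(NA_real_, n)
  fi <- approx(gx, seq_along(gx), x, rule = 1)$y
  fj <- approx(gy, seq_along(gy), y, rule = 1)$y
  ok <- !is.na(fi) & !is.na(fj)
  if (!any(ok)) return(out)
  i0 <- pmin(floor(fi[ok]), length(gx) - 1); j0 <- pmin(floor(fj[ok]), length(gy) - 1)
  if (length(gx) == 1) i0 <- rep(1, sum(ok))
  if (length(gy) == 1) j0 <- rep(1, sum(ok))
  wx <- fi[ok] - i0; wy <- fj[ok] - j0
  i1 <- pmin(i0 + 1, length(gx)); j1 <- pmin(j0 + 1, length(gy))
  z00 <- z[cbind(i0, j0)]; z10 <- z[cbind(i1, j0)]
  z01 <- z[cbind(i0, j1)]; z11 <- z[cbind(i1, j1)]
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy; w11 <- wx * wy
  num <- ifelse(is.na(z00), 0, z00 * w00) + ifelse(is.na(z10), 0, z10 * w10) +
    ifelse(is.na(z01), 0, z01 * w01) + ifelse(is.na(z11), 0, z11 * w11)
  den <- ifelse(is.na(z00), 0, w00) + ifelse(is.na(z10), 0, w10) +
    ifelse(is.na(z01), 0, w01) + ifelse(is.na(z11), 0, w11)
  out[ok] <- ifelse(den > 0, num / den, NA_real_)
  out
}

# ---- displacement records ---------------------------------------------------

#' Read / write deep-displacement records
#'
#' Park-depth float displacement records, one per float cycle: endpoints and
#' times of the deep drift between two surfacings.
#'
#' @param path file path.
#' @return \code{read_displacements}: data.frame with columns \code{float_id},
#'   \code{cycle}, \code{park_pres_dbar}, \code{t0}, \code{lon0}, \code{lat0},
#'   \code{t1}, \code{lon1}, \code{lat1} (times POSIXct UTC).
#' @export
read_displacements <- function(path) {
  df <- read_meta_csv(path)$data
  need <- c("float_id", "cycle", "park_pres_dbar", "t0", "lon0", "lat0",
            "t1", "lon1", "lat1")
  if (!all(need %in% names(df)))
    stop("malformed displacement file ", path)
  df$t0 <- parse_time(df$t0); df$t1 <- parse_time(df$t1)
  df$lon0 <- normalize_lon(df$lon0); df$lon1 <- normalize_lon(df$lon1)
  if (any(df$t1 <= df$t0)) stop("malformed displacement file ", path,
                                ": t1 <= t0 in record ",
                                which(df$t1 <= df$t0)[1])
  df
}

#' @rdname read_displacements
#' @param df displacement data.frame.
#' @export
write_displacements <- function(df, path) {
  df$t0 <- fmt_time(df$t0); df$t1 <- fmt_time(df$t1)
  write_meta_csv(df, path, meta = list(format = "ventbloom displacements v1"))
}

# ---- hydrographic profiles --------------------------------------------------

#' Read / write hydrographic T/S profile sets
#'
#' Long CSV, one row per level: \code{profile_id, source, qc_flag, time, lat,
#' lon, pres_dbar, temp_C, psal}. Only \code{qc_flag == 1} profiles enter the
#' climatology downstream.
#'
#' @param path file path.
#' @return \code{read_hydrography}: the long data.frame (times POSIXct).
#' @export
read_hydrography <- function(path) {
  df <- read_meta_csv(path)$data
  need <- c("profile_id", "source", "qc_flag", "time", "lat", "lon",
            "pres_dbar", "temp_C", "psal")
  if (!all(need %in% names(df))) stop("malformed hydrography file ", path)
  df$time <- parse_time(df$time)
  df$lon <- normalize_lon(df$lon)
  df
}

#' @rdname read_hydrography
#' @param df hydrography data.frame.
#' @export
write_hydrography <- function(df, path) {
  df$time <- fmt_time(df$time)
  write_meta_csv(df, path, meta = list(format = "ventbloom hydrography v1"))
}

# ---- tracer stations --------------------------------------------------------

#' Read / write helium-isotope tracer stations
#'
#' GLODAP-style long CSV: \code{cruise, station, lat, lon, depth_m,
#' delta3He_pct}.
#'
#' @param path file path.
#' @return \code{read_tracer_stations}: list of station objects, each with
#'   \code{cruise}, \code{station}, \code{lat}, \code{lon}, and depth-ordered
#'   vectors \code{depth}, \code{delta3he}.
#' @export
read_tracer_stations <- function(path) {
  df <- read_meta_csv(path)$data
  need <- c("cruise", "station", "lat", "lon", "depth_m", "delta3He_pct")
  if (!all(need %in% names(df))) stop("malformed tracer file ", path)
  df$lon <- normalize_lon(df$lon)
  sts <- lapply(split(df, paste(df$cruise, df$station, sep = "\r")), function(d) {
    d <- d[order(d$depth_m), , drop = FALSE]
    list(cruise = as.character(d$cruise[1]), station = as.character(d$station[1]),
         lat = d$lat[1], lon = d$lon[1],
         depth = d$depth_m, delta3he = d$delta3He_pct)
  })
  unname(sts)
}

#' @rdname read_tracer_stations
#' @param stations list of station objects.
#' @export
write_tracer_stations <- function(stations, path) {
  rows <- lapply(stations, function(s)
    data.frame(cruise = s$cruise, station = s$station, lat = s$lat,
               lon = s$lon, depth_m = s$depth, delta3He_pct = s$delta3he))
  write_meta_csv(do.call(rbind, rows), path,
                 meta = list(format = "ventbloom tracer v1"))
}
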