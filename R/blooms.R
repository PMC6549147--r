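# Bloom phenology: annual-cycle splitting, qualification against the bloom
# window, 20-day binning, bloom magnitude, type classification, and
# between-type comparison.

season_start_date <- function(time, cycle_start = "07-01") {
  d <- as.Date(time, tz = "UTC")
  y <- as.integer(format(d, "%Y"))
  anchor <- as.Date(paste0(y, "-", cycle_start))
  y <- ifelse(d < anchor, y - 1L, y)
  as.Date(paste0(y, "-", cycle_start))
}

#' Split processed profiles into annual cycles
#'
#' Each cast is assigned to the half-open austral year starting on
#' \code{cycle_start} (default 1 July): a cast on 30 June belongs to the
#' previous cycle, a cast on 1 July opens a new one.
#'
#' @param processed data.frame from [process_profiles()] (or any frame with a
#'   POSIXct \code{time} column), time-sorted.
#' @param cycle_start season anchor, \code{"MM-DD"}.
#' @return named list of data.frames, one per (float, season), each carrying
#'   a \code{season_start} Date column; ordered by float then season.
#' @export
split_annual_cycles <- function(processed, cycle_start = "07-01") {
  if (!nrow(processed)) return(list())
  processed$season_start <- season_start_date(processed$time, cycle_start)
  key <- paste(processed$float_id, processed$season_start, sep = "|")
  groups <- split(processed, key)
  groups[order(names(groups))]
}

# end of the bloom window in season starting year y; an end day of 28/29 Feb
# means the last day of February (leap-aware)
window_dates <- function(season_start, window_start, window_end) {
  y <- as.integer(format(season_start, "%Y"))
  ws <- as.Date(paste0(y, "-", window_start))
  if (ws < season_start) ws <- as.Date(paste0(y + 1L, "-", window_start))
  ye <- y + 1L
  if (window_end %in% c("02-28", "02-29")) {
    last_feb <- as.Date(paste0(ye, "-03-01")) - 1
    we <- last_feb
  } else {
    we <- as.Date(paste0(ye, "-", window_end))
    if (we < ws) we <- as.Date(paste0(ye + 1L, "-", window_end))
  }
  c(ws, we)
}

#' Qualify an annual cycle against the bloom window
#'
#' A cycle qualifies when at least \code{min_profiles} casts fall inside the
#' theoretical bloom period, 1 November to the last day of February of the
#' next year (both inclusive; leap Februaries end on the 29th).
#'
#' @param group one element of [split_annual_cycles()].
#' @param window_start,window_end window bounds, \code{"MM-DD"}.
#' @param min_profiles minimum cast count (default 8).
#' @return logical.
#' @export
qualify_cycle <- function(group, window_start = "11-01", window_end = "02-28",
                          min_profiles = 8) {
  if (!nrow(group)) return(FALSE)
  w <- window_dates(group$season_start[1], window_start, window_end)
  d <- as.Date(group$time, tz = "UTC")
  sum(d >= w[1] & d <= w[2]) >= min_profiles
}

#' Bin a cycle and compute bloom magnitude
#'
#' Casts are binned into fixed \code{bin_days} periods anchored at the season
#' start (so bin edges reproduce across floats); the bloom magnitude is the
#' maximum over non-empty bins of the per-bin mean depth-integrated
#' chlorophyll, with the date at the center of the maximizing bin and the
#' position the mean cast position within it.
#'
#' @param group one element of [split_annual_cycles()], with
#'   \code{int_chl_mg_m2} present.
#' @param bin_days bin width, days (default 20).
#' @param qualified qualification status carried onto the result.
#' @return one-row data.frame: \code{float_id, season_start, magnitude,
#'   magnitude_date, magnitude_lat, magnitude_lon, n_bins, n_profiles,
#'   qualified}; with an attribute \code{"bins"} holding the per-bin table.
#' @export
bin_and_magnitude <- function(group, bin_days = 20, qualified = TRUE) {
  g <- group[is.finite(group$int_chl_mg_m2), , drop = FALSE]
  s0 <- group$season_start[1]
  base <- data.frame(float_id = group$float_id[1], season_start = s0,
                     magnitude = NA_real_, magnitude_date = as.Date(NA),
                     magnitude_lat = NA_real_, magnitude_lon = NA_real_,
                     n_bins = 0L, n_profiles = nrow(g),
                     qualified = FALSE, stringsAsFactors = FALSE)
  if (!nrow(g)) return(base)
  day <- as.numeric(as.Date(g$time, tz = "UTC") - s0)
  bin <- floor(day / bin_days)
  agg <- lapply(split(seq_len(nrow(g)), bin), function(ix) {
    data.frame(bin_start = s0 + min(bin[ix]) * bin_days,
               mean_int_chl = mean(g$int_chl_mg_m2[ix]),
               n = length(ix),
               lat = mean(g$lat[ix]), lon = mean(g$lon[ix]))
  })
  bins <- do.call(rbind, agg)
  k <- which.max(bins$mean_int_chl)
  base$magnitude <- bins$mean_int_chl[k]
  base$magnitude_date <- bins$bin_start[k] + bin_days / 2
  base$magnitude_lat <- bins$lat[k]
  base$magnitude_lon <- bins$lon[k]
  base$n_bins <- nrow(bins)
  base$qualified <- isTRUE(qualified)
  attr(base, "bins") <- bins
  base
}

#' Build the bloom-cycle table for a processed profile set
#'
#' Splits into annual cycles, qualifies each against the bloom window, and
#' computes binned bloom magnitudes for the qualified cycles.
#'
#' @param processed data.frame from [process_profiles()].
#' @param config a \code{vb_config}.
#' @param keep_unqualified keep rows for discarded cycles (default FALSE,
#'   mirroring the discard rule).
#' @return data.frame of bloom cycles (see [bin_and_magnitude()]).
#' @export
bloom_cycles <- function(processed, config = pipeline_config(),
                         keep_unqualified = FALSE) {
  groups <- split_annual_cycles(processed, config$cycle_start)
  rows <- lapply(groups, function(g) {
    q <- qualify_cycle(g, config$bloom_window_start, config$bloom_window_end,
                       config$min_profiles)
    if (!q && !keep_unqualified) return(NULL)
    bin_and_magnitude(g, config$bin_days, qualified = q)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- bin_and_magnitude(data.frame(float_id = character(0),
                                        season_start = as.Date(character(0)),
                                        time = as.POSIXct(character(0)),
                                        int_chl_mg_m2 = numeric(0),
                                        lat = numeric(0), lon = numeric(0)))[0, ]
  rownames(out) <- NULL
  out
}

#' Classify a bloom by iron-supply regime
#'
#' Assigns each bloom position one of four types with fixed precedence:
#' \code{island_plateau} (inside the shallow-source downstream-delivery
#' zone), else \code{ice} (seasonal sea-ice zone), else \code{ridge}
#' (configured ridge-influence zone), else \code{HNLC}. Positions outside
#' the mask domain are \code{unclassified}.
#'
#' @param lat,lon bloom positions, degrees.
#' @param masks named list of \code{vb_grid} 0/1 masks:
#'   \code{shallow_delivery}, \code{ice}, \code{ridge} (any may be NULL).
#' @return character vector of types.
#' @export
classify_bloom <- function(lat, lon, masks) {
  lon <- normalize_lon(lon)
  inmask <- function(g) {
    if (is.null(g)) return(rep(FALSE, length(lat)))
    v <- grid_lookup(g, lon, lat, method = "nearest")
    !is.na(v) & v > 0.5
  }
  covered <- function(g) {
    if (is.null(g)) return(rep(FALSE, length(lat)))
    !is.na(grid_lookup(g, lon, lat, method = "nearest"))
  }
  type <- rep("HNLC", length(lat))
  type[inmask(masks$ridge)] <- "ridge"
  type[inmask(masks$ice)] <- "ice"
  type[inmask(masks$shallow_delivery)] <- "island_plateau"
  anycov <- covered(masks$shallow_delivery) | covered(masks$ice) |
    covered(masks$ridge)
  type[!anycov] <- "unclassified"
  type
}

#' Compare bloom magnitudes across bloom types
#'
#' Kruskal-Wallis rank test (tie-corrected H) on bloom magnitude by type,
#' with per-type summary statistics.
#'
#' @param magnitude bloom magnitudes, mg m^-2.
#' @param bloom_type type labels.
#' @return list: \code{H}, \code{df}, \code{p_value}, and \code{summary}
#'   data.frame (n, mean, median, quartiles per type).
#' @export
compare_types <- function(magnitude, bloom_type) {
  keep <- is.finite(magnitude) & !is.na(bloom_type) &
    bloom_type != "unclassified"
  magnitude <- magnitude[keep]
  bloom_type <- factor(bloom_type[keep])
  tab <- table(bloom_type)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least 2 types with at least 2 blooms each")
  kt <- stats::kruskal.test(magnitude, bloom_type)
  sm <- do.call(rbind, lapply(levels(bloom_type), function(tp) {
    x <- magnitude[bloom_type == tp]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(bloom_type = tp, n = length(x), mean = mean(x),
               q25 = q[1], median = q[2], q75 = q[3])
  }))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, summary = sm)
}
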