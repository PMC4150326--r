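#' Quality-filter and gap-fill an NDVI composite series
#'
#' Drops composites whose quality flag is non-zero and fills the resulting
#' gaps by linear interpolation between the nearest retained composites, so
#' that every date on the original composite grid carries a value.  Leading
#' and trailing gaps (no retained neighbour on one side) are filled by
#' constant extension of the nearest retained value.
#'
#' @param series a data.frame with columns `date` (Date, strictly
#'   increasing), `ndvi` (numeric in \[-1, 1\]) and `qa` (integer, 0 = good),
#'   optionally `site_id`.
#' @return the series with every `ndvi` value filled and an added logical
#'   column `interpolated` marking dates whose value was reconstructed.
#' @examples
#' s <- data.frame(date = as.Date("2005-01-01") + c(0, 16, 32),
#'                 ndvi = c(0.5, 0.9, 0.7), qa = c(0L, 1L, 0L))
#' filter_and_interpolate(s)$ndvi  # 0.5 0.6 0.7
#' @export
filter_and_interpolate <- function(series) {
  stopifnot(all(c("date", "ndvi", "qa") %in% names(series)))
  d <- as.numeric(series$date)
  if (is.unsorted(d, strictly = TRUE))
    stop("composite dates must be strictly increasing")
  good <- series$qa == 0 & !is.na(series$ndvi)
  if (sum(good) < 2) {
    site <- if (!is.null(series$site_id)) series$site_id[1] else "<unknown>"
    stop(sprintf("site %s: fewer than 2 usable (qa = 0) composites", site))
  }
  out <- series
  # rule = 2: constant extension beyond the first/last retained composite
  out$ndvi <- stats::approx(d[good], series$ndvi[good], xout = d,
                            method = "linear", rule = 2)$y
  out$interpolated <- !good
  out
}

#' Integrated NDVI above the window minimum (iNDVI)
#'
#' Integrates, by the trapezoidal rule on the composite grid, the excess of
#' the NDVI series over its minimum within a multi-year window ending at
#' `window_end`.  The result, in NDVI x days, is a proxy for vegetation
#' offtake: flat series score 0, series with deep excursions below their
#' typical level score high.  Day gaps are taken from the calendar dates, so
#' leap years are honoured.  Values at the exact window boundaries are
#' obtained by linear interpolation when the grid does not align.
#'
#' @param series a gap-free series (see [filter_and_interpolate()]) with
#'   columns `date` and `ndvi`.
#' @param window_end Date, last day of the integration window.
#' @param window_years number of calendar years the window spans (default 3:
#'   the window starts on 1 January two years before `window_end`'s year
#'   when `window_end` is 31 December).
#' @param window_start optional explicit first day of the window, overriding
#'   the calendar computation from `window_years`.
#' @return iNDVI in NDVI x days (non-negative scalar).
#' @export
compute_indvi <- function(series, window_end, window_years = 3,
                          window_start = NULL) {
  stopifnot(all(c("date", "ndvi") %in% names(series)))
  window_end <- as.Date(window_end)
  if (is.null(window_start))
    window_start <- seq(window_end, length.out = 2,
                        by = sprintf("-%d years", window_years))[2] + 1
  window_start <- as.Date(window_start)
  d <- as.numeric(series$date)
  v <- series$ndvi
  if (anyNA(v)) stop("series has missing values; run filter_and_interpolate first")
  t0 <- as.numeric(window_start)
  t1 <- as.numeric(window_end)
  # tolerate a boundary shortfall of one composite interval, extended constantly
  if (min(d) > t0 + 16 || max(d) < t1 - 16)
    stop(sprintf("series does not cover the window %s to %s",
                 window_start, window_end))
  inside <- d > t0 & d < t1
  tt <- c(t0, d[inside], t1)
  vv <- stats::approx(d, v, xout = tt, method = "linear", rule = 2)$y
  dev <- vv - min(vv)
  sum(diff(tt) * (dev[-length(dev)] + dev[-1]) / 2)
}

#' Flag isolated low spikes consistent with unflagged cloud contamination
#'
#' A composite is flagged when it sits anomalously far below the series
#' median -- more than `k` median absolute deviations -- while both of its
#' neighbours lie within one MAD of the median.  Sustained depressions
#' (droughts, harvests) are therefore never flagged: their neighbours are
#' low too.  The MAD is the usual scaled MAD ([stats::mad()]), consistent
#' with a normal noise SD.
#'
#' @param series gap-free series with columns `date` and `ndvi`.
#' @param k spike threshold in MADs (default 5).
#' @return integer vector of flagged composite indices (possibly empty).
#' @export
screen_influential <- function(series, k = 5) {
  v <- series$ndvi
  n <- length(v)
  if (n < 3) return(integer(0))
  med <- stats::median(v)
  s <- stats::mad(v)
  if (s == 0) return(integer(0))
  low <- (med - v) > k * s
  quiet <- abs(v - med) <= s
  flagged <- logical(n)
  for (i in which(low)) {
    nb <- c(if (i > 1) i - 1L, if (i < n) i + 1L)
    if (all(quiet[nb])) flagged[i] <- TRUE
  }
  which(flagged)
}

#' NDVI integration window for a study
#'
#' The offtake window ends on 31 December of the study's final sampling
#' year, floored at 2002: studies sampled in 2000-2002 all use the window
#' ending in 2002 (the earliest years with complete composite coverage).
#'
#' @param study_years integer vector of sampling years (one or more).
#' @return Date, the last day of the 3-year window.
#' @examples
#' window_for_study(2001)        # 2002-12-31
#' window_for_study(2005:2007)   # 2007-12-31
#' @export
window_for_study <- function(study_years) {
  stopifnot(is.numeric(study_years), length(study_years) >= 1)
  yr <- max(max(study_years), 2002)
  as.Date(sprintf("%d-12-31", yr))
}

#' Assemble the per-site pressure table
#'
#' Runs the full offtake workflow per site -- QA filtering, interpolation,
#' optional spike screening (screened composites are treated as qa != 0 and
#' re-interpolated; `drop_site = TRUE` instead discards the whole site, the
#' more conservative response to suspected contamination) -- and joins the
#' result with the static pressures.
#'
#' @param sites site table with `site_id`, `study_id`, `forest_cover`,
#'   `hpd`, and `sample_year_last`.
#' @param ndvi_long long NDVI table: `site_id`, `date`, `ndvi`, `qa`.
#' @param screen whether to screen for isolated unflagged low spikes.
#' @param k spike threshold passed to [screen_influential()].
#' @param drop_site if `TRUE`, sites with any screened spike are dropped
#'   (their row is removed) instead of re-interpolated.
#' @return data.frame: `site_id`, `forest_cover`, `hpd`, `indvi`,
#'   `n_flagged`.
#' @export
site_pressures <- function(sites, ndvi_long, screen = TRUE, k = 5,
                           drop_site = FALSE) {
  stopifnot(all(c("site_id", "study_id", "forest_cover", "hpd",
                  "sample_year_last") %in% names(sites)))
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    ser <- ndvi_long[ndvi_long$site_id == sid, , drop = FALSE]
    ser <- ser[order(ser$date), , drop = FALSE]
    ser$date <- as.Date(ser$date)
    filled <- filter_and_interpolate(ser)
    idx <- if (screen) screen_influential(filled, k = k) else integer(0)
    if (length(idx) > 0) {
      if (drop_site) next
      ser$qa[match(filled$date[idx], ser$date)] <- 999L
      filled <- filter_and_interpolate(ser)
    }
    wend <- window_for_study(sites$sample_year_last[i])
    out[[i]] <- data.frame(
      site_id = sid,
      forest_cover = sites$forest_cover[i],
      hpd = sites$hpd[i],
      indvi = compute_indvi(filled, wend),
      n_flagged = length(idx)
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
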