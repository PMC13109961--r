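# Summary metrics: cover areas, new-cover anomaly, thermal disequilibrium,
# and community composition by latitude band.

.class_cols <- function(class_filter = c("all", "reef", "nonreef")) {
  class_filter <- match.arg(class_filter)
  switch(class_filter, all = 1:4, reef = 1:2, nonreef = 3:4)
}

#' Total coral cover area
#'
#' \eqn{\sum_i \sum_{j \in class} C_{ij}\, r_f A_i}, in km^2: fractional
#' cover scaled by each site's reef-occupiable area. The `all` area equals
#' `reef + nonreef` exactly.
#'
#' @param state a [reef_state()]. @param sites a [site_table()].
#' @param class_filter `"all"`, `"reef"` or `"nonreef"`.
#' @return area in km^2.
#' @export
total_cover_area <- function(state, sites, class_filter = "all") {
  cols <- .class_cols(class_filter)
  sum(state$C[, cols, drop = FALSE] * (sites$A * sites$rf)) / 1e6
}

#' New cover area relative to a baseline state
#'
#' Positive-part cover anomaly versus a baseline mean state, scaled to area:
#' \eqn{\sum \max(0, C - \bar C_{base})\, r_f A_i}. Losses elsewhere do not
#' offset gains — this isolates genuinely new cover (e.g. range expansion)
#' from redistribution.
#'
#' @param state a [reef_state()]. @param baseline_C sites x 4 mean cover
#'   over the baseline window. @param sites a [site_table()].
#' @inheritParams total_cover_area
#' @return area in km^2.
#' @export
new_cover_area <- function(state, baseline_C, sites, class_filter = "all") {
  cols <- .class_cols(class_filter)
  gain <- pmax(0, state$C[, cols, drop = FALSE] -
                  baseline_C[, cols, drop = FALSE])
  sum(gain * (sites$A * sites$rf)) / 1e6
}

#' Cover-weighted thermal disequilibrium
#'
#' Cover-weighted mean of (annual-mean temperature - thermal optimum) across
#' the reef assemblages and all sites. At the model's seasonal equilibrium
#' the trait sits about 1 deg C above the annual mean, so the equilibrium
#' reference value is -1 deg C; departures from -1 measure disequilibrium
#' (e.g. lag behind warming).
#'
#' @param state a [reef_state()]. @param series a [forcing_series()].
#' @param window month indices of `series` over which to average T
#'   (>= 1 year; default the final 12 months).
#' @return degrees C, or `NA` if reef cover is zero.
#' @export
disequilibrium <- function(state, series,
                           window = seq(ncol(series$T) - 11L,
                                        ncol(series$T))) {
  if (length(window) < 12) stop("disequilibrium window must cover >= 1 year")
  Tann <- rowMeans(series$T[, window, drop = FALSE])
  Cr <- state$C[, 1:2, drop = FALSE]
  w <- sum(Cr)
  if (w == 0) return(NA_real_)
  sum(Cr * (Tann - state$z[, 1:2, drop = FALSE])) / w
}

#' Disequilibrium time series over run snapshots
#'
#' @param snapshots list of [reef_state()]s (e.g. from [run_phases()]).
#' @param series the [forcing_series()] covering the snapshots' months,
#'   aligned so that series column `state$t - t0` is the snapshot month.
#' @param t0 absolute month of the series' first column.
#' @param running_mean optional window (years) of a trailing running mean to
#'   remove subdecadal variability (e.g. 10).
#' @return data.frame `(t, diseq)`.
#' @export
disequilibrium_series <- function(snapshots, series, t0, running_mean = NULL) {
  d <- vapply(snapshots, function(st) {
    kend <- st$t - t0
    win <- seq(max(1, kend - 11), kend)
    disequilibrium(st, series, win)
  }, 0)
  out <- data.frame(t = vapply(snapshots, `[[`, 0L, "t"), diseq = d)
  if (!is.null(running_mean)) {
    k <- running_mean
    out$diseq_filtered <- stats::filter(out$diseq, rep(1 / k, k),
                                        sides = 1)
  }
  out
}

#' Community composition by latitude band
#'
#' Within each latitude band, the fraction of total (area-weighted) cover
#' held by each assemblage; sums to 1 where the band holds any cover. Empty
#' bands are excluded.
#'
#' @param state a [reef_state()]. @param sites a [site_table()].
#' @param band_width band width in degrees latitude (> 0).
#' @return data.frame: band mid-latitude, one fraction column per
#'   assemblage, and the band's total cover area (km^2).
#' @export
composition_by_band <- function(state, sites, band_width = 5) {
  if (band_width <= 0) stop("band_width must be > 0")
  band <- floor(sites$lat / band_width) * band_width + band_width / 2
  w <- sites$A * sites$rf
  rows <- lapply(sort(unique(band)), function(b) {
    sel <- band == b
    ca <- colSums(state$C[sel, , drop = FALSE] * w[sel])
    tot <- sum(ca)
    if (tot == 0) return(NULL)
    cbind(data.frame(band = b), as.data.frame(as.list(ca / tot)),
          data.frame(area_km2 = tot / 1e6))
  })
  do.call(rbind, rows)
}

#' Poleward reef front latitude
#'
#' The highest absolute latitude at which reef-class cover is at least
#' `threshold` — the range-expansion signal.
#'
#' @param state a [reef_state()]. @param sites a [site_table()].
#' @param threshold reef-class fractional cover threshold (default 0.05).
#' @return degrees latitude (absolute), or `NA` if no site qualifies.
#' @export
reef_front_latitude <- function(state, sites, threshold = 0.05) {
  reef_cov <- rowSums(state$C[, 1:2, drop = FALSE])
  sel <- reef_cov >= threshold
  if (!any(sel)) return(NA_real_)
  max(abs(sites$lat[sel]))
}

#' Write a yearly run summary as CSV with units metadata
#'
#' @param run a `"reef_run"`. @param path CSV path.
#' @param baseline_note free-text note on the baseline window (written into
#'   the header comment).
#' @export
write_summary <- function(run, path, baseline_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: area_* km^2; z_* degC; t months since run start",
               if (!is.null(baseline_note)) paste("# baseline:",
                                                  baseline_note)), con)
  utils::write.csv(run$summary, con, row.names = FALSE)
  invisible(path)
}
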