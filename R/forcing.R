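# Monthly environmental drivers: synthetic scenario generator, delta-method
# bias correction, post-scenario stabilized extension, and CSV I/O.

#' Forcing series constructor
#'
#' Monthly sea-surface temperature (deg C), pH (total scale) and benthic PAR
#' (mol m-2 day-1) per site, with a gap-free month calendar.
#'
#' @param T,P,R sites x months matrices.
#' @param calendar data.frame `(year, month)`, one row per column of `T`.
#' @return list of class `"forcing_series"`.
#' @export
forcing_series <- function(T, P, R, calendar) {
  T <- as.matrix(T); P <- as.matrix(P); R <- as.matrix(R)
  k <- ncol(T)
  if (ncol(P) != k || ncol(R) != k || nrow(calendar) != k)
    stop("forcing variables and calendar must cover the same months")
  if (any(!is.finite(T)) || any(!is.finite(P)) || any(!is.finite(R)))
    stop("forcing must be finite everywhere")
  if (any(R < 0)) stop("PAR must be non-negative")
  idx <- calendar$year * 12 + calendar$month
  if (k > 1 && any(diff(idx) != 1))
    stop("forcing calendar has gaps or is out of order")
  structure(list(T = T, P = P, R = R,
                 calendar = as.data.frame(calendar)[, c("year", "month")]),
            class = "forcing_series")
}

#' Climate-scenario specification for the synthetic forcing generator
#'
#' Encodes the study conditions for an idealized latitudinal domain: a linear
#' latitudinal gradient in mean SST (28 deg C at the equator to 16 deg C at
#' 45 degrees) and in seasonal amplitude (2 to 6 deg C), hemisphere-aware
#' seasonal phase (warmest month August north / February south), a secular
#' warming/acidification trajectory given as piecewise-linear phase
#' endpoints, AR(1) interannual noise, and depth-attenuated benthic PAR from
#' a seasonal surface-insolation curve (monthly climatological, repeating
#' year to year).
#'
#' @param phases list of phases, each `list(name, years, dT_end, dpH_end)`;
#'   trajectories are linear within a phase and continuous across phases,
#'   starting from offset 0.
#' @param sst_mean_eq,sst_mean_pole mean SST at 0 and 45 degrees latitude.
#' @param amp_eq,amp_pole seasonal SST amplitude at 0 and 45 degrees.
#' @param ph_ref reference pH.
#' @param par_surface mean surface PAR (mol m-2 day-1).
#' @param par_amp_eq,par_amp_pole fractional seasonal PAR amplitude at 0 and
#'   45 degrees.
#' @param par_k diffuse attenuation coefficient, 1/m.
#' @param noise_sd,noise_rho AR(1) SST noise standard deviation (deg C) and
#'   lag-1 autocorrelation; pH noise is `noise_sd_ph`.
#' @param noise_sd_ph pH AR(1) noise standard deviation.
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(phases = list(list(name = "control", years = 50,
                                             dT_end = 0, dpH_end = 0)),
                          sst_mean_eq = 28, sst_mean_pole = 16,
                          amp_eq = 2, amp_pole = 6, ph_ref = 8.1,
                          par_surface = 40, par_amp_eq = 0.1,
                          par_amp_pole = 0.35, par_k = 0.08,
                          noise_sd = 0.3, noise_rho = 0.6,
                          noise_sd_ph = 0.01) {
  for (ph in phases) {
    if (is.null(ph$years) || ph$years <= 0)
      stop("phase durations must be positive")
  }
  structure(as.list(environment()), class = "scenario_spec")
}

#' Generate a synthetic monthly forcing series
#'
#' Deterministic given `(spec, seed)`. SST is latitudinal mean + seasonal
#' cycle + piecewise-linear trend + AR(1) noise; pH is reference + trend +
#' AR(1) noise (no seasonality by default); PAR is a repeating seasonal
#' surface-insolation climatology attenuated exponentially with site depth.
#'
#' @param sites a [site_table()].
#' @param spec a [scenario_spec()].
#' @param seed integer seed for the AR(1) noise (0 disables noise entirely).
#' @param start_year first calendar year label.
#' @return a [forcing_series()].
#' @export
synth_forcing <- function(sites, spec = scenario_spec(), seed = 1L,
                          start_year = 1L) {
  n <- nrow(sites)
  years <- sum(vapply(spec$phases, `[[`, 0, "years"))
  K <- 12L * years
  month <- rep(1:12, years)
  year <- start_year + rep(seq_len(years) - 1L, each = 12L)
  lat <- sites$lat
  frac <- pmin(1, abs(lat) / 45)
  meanT <- spec$sst_mean_eq + (spec$sst_mean_pole - spec$sst_mean_eq) * frac
  amp <- spec$amp_eq + (spec$amp_pole - spec$amp_eq) * frac
  peak <- ifelse(lat >= 0, 8, 2)
  seas <- cos(2 * pi * outer(peak, month, function(p, m) (m - p)) / 12)
  trendT <- phase_trajectory(spec$phases, "dT_end", K)
  trendP <- phase_trajectory(spec$phases, "dpH_end", K)

  noiseT <- matrix(0, n, K); noiseP <- matrix(0, n, K)
  if (seed != 0) {
    noiseT <- ar1_noise(n, K, spec$noise_sd, spec$noise_rho, seed)
    noiseP <- ar1_noise(n, K, spec$noise_sd_ph, spec$noise_rho, seed + 1L)
  }
  T <- meanT + amp * seas + rep(trendT, each = n) + noiseT
  P <- spec$ph_ref + rep(trendP, each = n) + noiseP
  par_amp <- spec$par_amp_eq + (spec$par_amp_pole - spec$par_amp_eq) * frac
  R <- spec$par_surface * (1 + par_amp * seas) * exp(-spec$par_k * sites$depth)
  R <- pmax(R, 0)
  forcing_series(T, P, R, data.frame(year = year, month = month))
}

# Piecewise-linear offset trajectory across phases, evaluated per month.
phase_trajectory <- function(phases, field, K) {
  out <- numeric(0)
  v0 <- 0
  for (ph in phases) {
    kph <- 12L * ph$years
    v1 <- ph[[field]] %||% v0
    out <- c(out, v0 + (v1 - v0) * seq_len(kph) / kph)
    v0 <- v1
  }
  stopifnot(length(out) == K)
  out
}

# Seeded AR(1) noise matrix; leaves the caller's RNG state untouched.
ar1_noise <- function(n, K, sd, rho, seed) {
  if (sd <= 0) return(matrix(0, n, K))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- matrix(stats::rnorm(n * K, sd = innov_sd), n, K)
  x <- matrix(0, n, K)
  x[, 1] <- stats::rnorm(n, sd = sd)
  for (k in 2:K) x[, k] <- rho * x[, k - 1] + e[, k]
  x
}

#' Monthly climatology of a forcing series
#'
#' @param series a [forcing_series()]. @param window optional month indices
#'   over which to average (default all).
#' @return list with sites x 12 matrices `T`, `P`, `R`.
#' @export
forcing_climatology <- function(series, window = NULL) {
  idx <- window %||% seq_len(ncol(series$T))
  mo <- series$calendar$month[idx]
  clim1 <- function(X) {
    out <- sapply(1:12, function(m) rowMeans(X[, idx[mo == m], drop = FALSE]))
    matrix(out, nrow(X), 12)
  }
  list(T = clim1(series$T), P = clim1(series$P), R = clim1(series$R))
}

#' Delta-method bias correction
#'
#' Adds the month-matched difference between an observed and a modelled
#' monthly climatology to every timestep of SST and pH, so the corrected
#' series' climatology over the reference window equals the observed one.
#' Idempotent when re-applied with the corrected series' own climatology.
#'
#' @param series a [forcing_series()].
#' @param model_clim,obs_clim lists with sites x 12 matrices `T` and `P`
#'   (as from [forcing_climatology()]).
#' @return corrected [forcing_series()].
#' @export
delta_correct <- function(series, model_clim, obs_clim) {
  n <- nrow(series$T)
  if (nrow(model_clim$T) != n || nrow(obs_clim$T) != n)
    stop("climatology site sets do not match the series")
  mo <- series$calendar$month
  dT <- obs_clim$T - model_clim$T
  dP <- obs_clim$P - model_clim$P
  series$T <- series$T + dT[, mo, drop = FALSE]
  series$P <- series$P + dP[, mo, drop = FALSE]
  series
}

#' Stabilized post-scenario forcing extension
#'
#' Builds an equilibrium-climate extension: the mean SST and pH anomaly of
#' the scenario over a reference window (e.g. its final decade), relative to
#' the control mean, is added to the looped control series. Seasonal and
#' interannual variability are the control's, with the mean shifted; PAR is
#' taken from the control unchanged.
#'
#' @param control a [forcing_series()] (e.g. preindustrial control).
#' @param scenario a [forcing_series()] sharing the site set.
#' @param window month indices into `scenario` defining the anomaly window.
#' @param years output length in years (control is looped as needed;
#'   default = control length).
#' @return a [forcing_series()].
#' @export
stabilize_post2100 <- function(control, scenario, window,
                               years = ncol(control$T) / 12) {
  if (length(window) == 0) stop("anomaly window is empty")
  if (max(window) > ncol(scenario$T)) stop("window outside scenario series")
  aT <- rowMeans(scenario$T[, window, drop = FALSE]) - rowMeans(control$T)
  aP <- rowMeans(scenario$P[, window, drop = FALSE]) - rowMeans(control$P)
  K <- as.integer(12 * years)
  loop <- rep_len(seq_len(ncol(control$T)), K)
  y0 <- max(scenario$calendar$year) + 1L
  forcing_series(control$T[, loop, drop = FALSE] + aT,
                 control$P[, loop, drop = FALSE] + aP,
                 control$R[, loop, drop = FALSE],
                 data.frame(year = y0 + (seq_len(K) - 1L) %/% 12L,
                            month = rep(1:12, length.out = K)))
}

#' Write / read a forcing series as long-format CSV
#'
#' Columns: `site_id, year, month, sst, ph, par`. Reading validates a
#' gap-free monthly calendar shared by all sites and errors on missing
#' months rather than filling silently.
#'
#' @param series a [forcing_series()]. @param path CSV path.
#' @param site_id site identifiers (defaults to row index).
#' @export
write_forcing <- function(series, path, site_id = NULL) {
  n <- nrow(series$T); K <- ncol(series$T)
  site_id <- site_id %||% as.character(seq_len(n))
  df <- data.frame(
    site_id = rep(site_id, K),
    year = rep(series$calendar$year, each = n),
    month = rep(series$calendar$month, each = n),
    sst = as.vector(series$T), ph = as.vector(series$P),
    par = as.vector(series$R))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "month", "sst", "ph", "par")
  if (!all(need %in% names(df)))
    stop("forcing CSV must have columns ", paste(need, collapse = ", "))
  sid <- unique(df$site_id)
  key <- df$year * 12 + df$month
  months <- sort(unique(key))
  if (length(months) > 1 && any(diff(months) != 1))
    stop("forcing CSV has gap months")
  if (nrow(df) != length(sid) * length(months))
    stop("forcing CSV is not a complete site x month grid")
  ord <- order(match(df$site_id, sid), key)
  df <- df[ord, ]
  key <- key[ord]
  shape <- function(v) matrix(v, length(sid), length(months), byrow = TRUE)
  cal <- data.frame(year = df$year[match(months, key)],
                    month = df$month[match(months, key)])
  forcing_series(shape(df$sst), shape(df$ph), shape(df$par), cal)
}
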