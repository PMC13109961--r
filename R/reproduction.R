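# Annual spawning: competency-weighted connectivity, larval supply,
# analytic free-space-limited settlement, and trait admixture by
# immigration; plus synthetic kernel and competency-curve generators.

KERNEL_LAGS <- seq(2, 60, by = 2)

#' Connectivity kernel constructor
#'
#' Per-lag site-to-site transport probabilities: `M[h, i, m]` is the
#' probability that a larva released at site `h` is at site `i` at lag
#' `lags[m]` days after spawning. Rows may lose mass (larval loss) but never
#' gain: `sum_i M[h, i, m] <= 1` for every source and lag.
#'
#' @param M numeric array, sites x sites x lags.
#' @param lags lag axis in days (default 2,4,...,60).
#' @param month_tag which calendar month's circulation the kernel represents.
#' @return list of class `"connectivity_kernel"`.
#' @export
connectivity_kernel <- function(M, lags = KERNEL_LAGS, month_tag = NA_integer_) {
  M <- as.array(M)
  if (length(dim(M)) != 3L) stop("kernel must be a 3-d array [h, i, lag]")
  if (dim(M)[3] != length(lags)) stop("lag axis length mismatch")
  if (any(M < 0) || any(M > 1)) stop("kernel entries must lie in [0, 1]")
  rs <- apply(M, c(1, 3), sum)
  if (any(rs > 1 + 1e-9))
    stop("kernel row sums exceed 1 (larval mass gain) at some (source, lag)")
  structure(list(M = M, lags = lags, month_tag = as.integer(month_tag)),
            class = "connectivity_kernel")
}

#' Larval competency curve
#'
#' Proportion of larvae alive and competent to settle at each lag, modelled
#' as exponential survival times a competence window: competence is acquired
#' after `t_min` days at rate `rate_acq` (1/day) and subsequently lost at
#' rate `rate_loss` (1/day), while larvae die at rate `mort` (1/day). The
#' default parameter sets labelled `"AM"` (broadcast-spawning, long
#' competency; used by the fast-growing assemblages) and `"GR"` (shorter
#' competency and dispersal; slow-growing assemblages) are synthetic
#' calibrations of this standard larval model, not published species curves.
#'
#' @param kernel_id `"AM"` or `"GR"`, or `NULL` with explicit parameters.
#' @param lags lag axis, days.
#' @param t_min,rate_acq,rate_loss,mort curve parameters (days, 1/day).
#' @return data.frame `(lag_days, p)` of class `"competency_curve"`.
#' @export
competency_curve <- function(kernel_id = c("AM", "GR"), lags = KERNEL_LAGS,
                             t_min = NULL, rate_acq = NULL, rate_loss = NULL,
                             mort = NULL) {
  if (is.null(t_min)) {
    kernel_id <- match.arg(kernel_id)
    def <- switch(kernel_id,
      AM = list(t_min = 4, rate_acq = 0.4, rate_loss = 0.02, mort = 0.05),
      GR = list(t_min = 2, rate_acq = 0.8, rate_loss = 0.12, mort = 0.09))
    t_min <- def$t_min; rate_acq <- def$rate_acq
    rate_loss <- def$rate_loss; mort <- def$mort
  }
  tau <- pmax(0, lags - t_min)
  p <- exp(-mort * lags) * (1 - exp(-rate_acq * tau)) * exp(-rate_loss * tau)
  out <- data.frame(lag_days = lags, p = p)
  class(out) <- c("competency_curve", "data.frame")
  validate_competency_curve(out)
}

validate_competency_curve <- function(cc) {
  if (any(cc$p < 0 | cc$p > 1)) stop("competency values must lie in [0, 1]")
  if (sum(cc$p) <= 0) stop("competency curve must have positive total mass")
  cc
}

#' Competency-weighted effective connectivity
#'
#' Averages the per-lag kernel over lags, weighted by the proportion of
#' larvae alive and competent:
#' \deqn{M_{hi} = \sum_m M'_{him} p_m / \sum_m p_m}
#' Invariant to rescaling the competency curve by a positive constant.
#'
#' @param kernel a [connectivity_kernel()].
#' @param cc a [competency_curve()] on the same lag axis.
#' @return sites x sites effective transport matrix.
#' @export
effective_connectivity <- function(kernel, cc) {
  if (!isTRUE(all.equal(kernel$lags, cc$lag_days)))
    stop("kernel and competency curve lag axes differ")
  if (sum(cc$p) <= 0) stop("competency curve has zero total mass")
  w <- cc$p / sum(cc$p)
  dm <- dim(kernel$M)
  out <- matrix(0, dm[1], dm[2])
  for (m in seq_len(dm[3])) out <- out + kernel$M[, , m] * w[m]
  out
}

#' Larval supply and immigrant mean trait
#'
#' Area-weighted larval input per destination site and assemblage:
#' \deqn{I_{ij} = (f_j / A_i) \sum_h M_{hi} C_{hj} A_h}
#' and the cover-area-weighted mean trait of the immigrants. When no larvae
#' arrive the immigrant trait is undefined (`NaN` marker) and admixture is a
#' no-op (supply is then zero too).
#'
#' @param C,z state matrices (sites x 4). `C` may be pre-masked to the
#'   sites spawning this month.
#' @param M_eff list of 4 effective-connectivity matrices (one per
#'   assemblage) or a single matrix shared by all.
#' @param params assemblage parameter table (uses `f`).
#' @param A effective habitable area per site (m^2), already including the
#'   habitable fraction `rf`.
#' @return list `I` (sites x 4) and `z_imm` (sites x 4, `NaN` where
#'   undefined).
#' @export
larval_supply <- function(C, z, M_eff, params, A) {
  if (any(A <= 0)) stop("areas must be > 0")
  n <- nrow(C)
  I <- matrix(0, n, 4, dimnames = dimnames(C))
  z_imm <- matrix(NaN, n, 4, dimnames = dimnames(C))
  for (j in seq_len(4)) {
    M <- if (is.list(M_eff)) M_eff[[j]] else M_eff
    src <- C[, j] * A
    arr <- drop(crossprod(M, src))           # sum_h M[h,i] C[h] A[h]
    I[, j] <- params$f[j] * arr / A
    num <- drop(crossprod(M, src * z[, j]))
    pos <- arr > 0
    z_imm[pos, j] <- num[pos] / arr[pos]
  }
  list(I = I, z_imm = z_imm)
}

#' Free-space-limited settlement (analytic)
#'
#' Closed-form change in cover from a pulse of settling larvae filling a
#' share of the free space: with per-site totals \eqn{\mathbb{I} = \sum_j
#' I_j} and \eqn{\mathbb{C} = \sum_j C_j},
#' \deqn{\Delta C_j = (I_j / \mathbb{I}) (1 - \mathbb{C}) (1 -
#' e^{-\mathbb{I}})}
#' — the exact solution of \eqn{dC_j/dt = I_j (1 - \sum_f C_f)} over unit
#' settling time. Total settlement never exceeds the free space, the
#' partition across assemblages is exactly proportional to supply, and the
#' \eqn{\mathbb{I} \to 0} limit is continuous (zero settlement).
#'
#' @param C cover matrix (sites x 4) with row sums at most 1.
#' @param I supply matrix from [larval_supply()].
#' @return settled cover `dC` (sites x 4).
#' @export
settle <- function(C, I) {
  if (any(I < 0)) stop("larval supply must be non-negative")
  Itot <- rowSums(I)
  Ctot <- rowSums(C)
  if (any(Ctot > 1 + 1e-9)) stop("total cover exceeds 1")
  fac <- ifelse(Itot > 0, (1 - pmin(Ctot, 1)) * (1 - exp(-Itot)) / Itot, 0)
  I * fac
}

#' Trait admixture by immigration
#'
#' Cover-weighted mean of the resident and immigrant trait:
#' `z_new = (C z + dC z_imm) / (C + dC)`; an empty site colonized by
#' immigrants inherits the immigrant trait exactly, and with no settlement
#' the resident trait is unchanged.
#'
#' @param C resident cover. @param z resident trait. @param dC settled
#'   cover. @param z_imm immigrant mean trait (`NaN` allowed where `dC` is 0).
#' @return post-admixture trait matrix.
#' @export
admix_trait <- function(C, z, dC, z_imm) {
  if (any(dC < 0)) stop("settled cover must be non-negative")
  tot <- C + dC
  upd <- dC > 0 & tot > 0
  z_new <- z
  z_new[upd] <- (C[upd] * z[upd] + dC[upd] * z_imm[upd]) / tot[upd]
  z_new
}

#' One spawning event
#'
#' Draws one month-tagged kernel from the bank (counter-based seeded draw:
#' identical `(seed, event_index)` always selects the same kernel, which
#' keeps checkpoint-resume exact), computes each assemblage's effective
#' connectivity with its competency curve, then supply, settlement and
#' admixture, and finally applies the `C_min` clamp.
#'
#' @param state a [reef_state()]. @param bank a list of
#'   [connectivity_kernel()]s (or a precomputed effective bank from
#'   [precompute_effective_bank()]).
#' @param params assemblage parameter table.
#' @param sites a [site_table()] (areas and habitable fraction).
#' @param cfg a [reef_config()] (seed, `C_min`).
#' @param event_index spawning-event counter used with `cfg$seed` for the
#'   kernel draw.
#' @param source_mask logical per-site vector: which sites release larvae in
#'   this event (default all). Settlement can occur anywhere larvae arrive.
#' @return list `state`, and `outcome` with `dC`, `z_imm`, `z_new`,
#'   `kernel_index`.
#' @export
spawn_event <- function(state, bank, params, sites, cfg, event_index = 0L,
                        source_mask = NULL) {
  if (length(bank) == 0) stop("kernel bank is empty")
  ki <- 1L + counter_draw(cfg$seed, event_index, length(bank))
  eff <- if (inherits(bank, "effective_bank")) bank[[ki]]
         else precompute_effective_bank(bank[ki], params)[[1]]
  A_eff <- sites$A * sites$rf
  Csrc <- state$C
  if (!is.null(source_mask)) Csrc <- Csrc * source_mask
  sup <- larval_supply(Csrc, state$z, eff, params, A_eff)
  dC <- settle(state$C, sup$I)
  z_new <- admix_trait(state$C, state$z, dC, sup$z_imm)
  C_new <- state$C + dC
  C_new[C_new < cfg$C_min] <- 0
  list(state = reef_state(C_new, z_new, state$t),
       outcome = list(dC = dC, z_imm = sup$z_imm, z_new = z_new,
                      kernel_index = ki))
}

#' Precompute per-assemblage effective connectivity for a kernel bank
#'
#' @param bank list of [connectivity_kernel()]s.
#' @param params assemblage parameter table (uses `kernel_id`).
#' @return list (one element per kernel) of lists of 4 effective matrices,
#'   classed `"effective_bank"`.
#' @export
precompute_effective_bank <- function(bank, params) {
  curves <- lapply(unique(params$kernel_id), function(id)
    competency_curve(id, lags = bank[[1]]$lags))
  names(curves) <- unique(params$kernel_id)
  out <- lapply(bank, function(k) {
    effs <- lapply(curves, function(cc) effective_connectivity(k, cc))
    lapply(params$kernel_id, function(id) effs[[id]])
  })
  class(out) <- "effective_bank"
  out
}

# Counter-based pseudo-random integer in 0..(n-1): a splitmix-style hash of
# (seed, counter). Independent of R's global RNG so that resuming a run from
# a checkpoint reproduces the same kernel draws bit-for-bit.
counter_draw <- function(seed, counter, n) {
  x <- (as.double(seed) * 2654435761 + as.double(counter) * 40503 + 12345) %%
    2147483647
  x <- (x * 48271) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x %% n)
}

#' Synthetic dispersal kernel for an idealized coastline
#'
#' Stands in for an ocean-model-derived larval transport product on a 1-D
#' coastline: sites are laid out along a coastline coordinate (cumulative
#' great-circle distance in site order), and larvae released at `h` spread
#' as a Gaussian plume centred `advection_bias * lag` downstream with spread
#' `decay_scale * sqrt(lag)`, losing mass at `loss_rate` per 2-day lag step.
#' Site masses are exact integrals of the plume over disjoint coastline
#' segments, so row sums never exceed the surviving mass (no larval gain).
#'
#' @param sites a [site_table()] whose row order traces the coastline.
#' @param advection_bias alongshore drift, km/day (signed; 0 = symmetric).
#' @param decay_scale diffusive spread, km/sqrt(day).
#' @param loss_rate larval loss per 2-day interval, in `[0, 1)`.
#' @param lags lag axis, days. @param month_tag calendar month label.
#' @param seasonal_phase optional multiplier on the advection bias (used by
#'   [synth_kernel_bank()] to vary circulation by month).
#' @return a [connectivity_kernel()].
#' @export
synth_kernel <- function(sites, advection_bias = 2, decay_scale = 8,
                         loss_rate = 0.05, lags = KERNEL_LAGS,
                         month_tag = NA_integer_, seasonal_phase = 1) {
  if (decay_scale <= 0) stop("decay_scale must be > 0")
  if (loss_rate < 0 || loss_rate >= 1) stop("loss_rate must be in [0, 1)")
  s <- coast_coordinate(sites)
  n <- length(s)
  edges <- segment_edges(s)
  M <- array(0, c(n, n, length(lags)))
  for (m in seq_along(lags)) {
    tau <- lags[m]
    mass <- (1 - loss_rate)^(tau / 2)
    mu <- s + seasonal_phase * advection_bias * tau
    sd <- decay_scale * sqrt(tau)
    for (h in seq_len(n)) {
      M[h, , m] <- mass * (stats::pnorm(edges[-1], mu[h], sd) -
                           stats::pnorm(edges[-(n + 1)], mu[h], sd))
    }
  }
  connectivity_kernel(M, lags, month_tag)
}

#' Bank of monthly synthetic kernels
#'
#' Twelve kernels whose advection bias varies sinusoidally over the year,
#' emulating seasonal circulation; spawning draws uniformly among them.
#'
#' @inheritParams synth_kernel
#' @param seasonal_amplitude fractional modulation of the advection bias.
#' @return list of 12 [connectivity_kernel()]s.
#' @export
synth_kernel_bank <- function(sites, advection_bias = 2, decay_scale = 8,
                              loss_rate = 0.05, lags = KERNEL_LAGS,
                              seasonal_amplitude = 0.3) {
  lapply(1:12, function(mo)
    synth_kernel(sites, advection_bias, decay_scale, loss_rate, lags,
                 month_tag = mo,
                 seasonal_phase = 1 + seasonal_amplitude *
                   cos(2 * pi * (mo - 2) / 12)))
}

#' Self-connectivity-only kernel (closed single population)
#'
#' @param n_sites number of sites. @param retention per-lag self-retention.
#' @param lags lag axis.
#' @return a [connectivity_kernel()] with diagonal transport only.
#' @export
identity_kernel <- function(n_sites, retention = 1, lags = KERNEL_LAGS) {
  M <- array(0, c(n_sites, n_sites, length(lags)))
  for (m in seq_along(lags)) M[, , m] <- diag(retention, n_sites)
  connectivity_kernel(M, lags, 1L)
}

# Coastline coordinate: cumulative haversine distance (km) along site order.
coast_coordinate <- function(sites) {
  n <- nrow(sites)
  if (n == 1) return(0)
  lat <- sites$lat * pi / 180; lon <- sites$lon * pi / 180
  dlat <- diff(lat); dlon <- diff(lon)
  a <- sin(dlat / 2)^2 + cos(lat[-n]) * cos(lat[-1]) * sin(dlon / 2)^2
  d <- 2 * 6371 * asin(pmin(1, sqrt(a)))
  c(0, cumsum(d))
}

# Disjoint segment edges: midpoints between consecutive coastline
# coordinates, end segments mirrored.
segment_edges <- function(s) {
  n <- length(s)
  if (n == 1) return(c(s - 5, s + 5))
  mid <- (s[-1] + s[-n]) / 2
  c(s[1] - (mid[1] - s[1]), mid, s[n] + (s[n] - mid[n - 1]))
}

#' Write / read a kernel bank as Matrix Market sparse files
#'
#' One `.mtx` file per (kernel, lag) plus a CSV manifest with the lag axis
#' and month tags.
#'
#' @param bank list of [connectivity_kernel()]s. @param dir directory.
#' @return `dir` (write) or the reconstructed bank (read).
#' @export
write_kernel_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(kernel = integer(), lag_days = integer(),
                         month_tag = integer(), file = character())
  for (k in seq_along(bank)) {
    kn <- bank[[k]]
    for (m in seq_along(kn$lags)) {
      f <- sprintf("kernel%02d_lag%02d.mtx", k, kn$lags[m])
      Matrix::writeMM(Matrix::Matrix(kn$M[, , m], sparse = TRUE),
                      file.path(dir, f))
      manifest <- rbind(manifest,
                        data.frame(kernel = k, lag_days = kn$lags[m],
                                   month_tag = kn$month_tag, file = f))
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_kernel_bank
#' @export
read_kernel_bank <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(split(man, man$kernel), function(mk) {
    mk <- mk[order(mk$lag_days), ]
    mats <- lapply(file.path(dir, mk$file), function(f)
      as.matrix(Matrix::readMM(f)))
    M <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
    connectivity_kernel(M, mk$lag_days, mk$month_tag[1])
  })
}
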