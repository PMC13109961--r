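# Monthly eco-evolutionary stepping. Cover and trait are advanced jointly by
# a deterministic fixed-step classical RK4 scheme with configurable substeps,
# forcing held constant within the month. Cover is integrated in log space,
# which makes C = 0 an exact absorbing state for growth and guarantees
# non-negativity under arbitrary forcing.

# Precompute per-(site, assemblage) parameter matrices so the derivative
# evaluation is a handful of dense matrix operations.
make_deriv_context <- function(n_sites, params, alpha, cfg) {
  rep_row <- function(v) matrix(v, n_sites, 4, byrow = TRUE)
  list(
    n = n_sites,
    g0 = rep_row(params$g0), w2 = rep_row(params$w^2),
    zH = rep_row(params$zH), wH2 = rep_row(params$wH^2),
    zC = rep_row(params$zC), wC2 = rep_row(params$wC^2),
    zA = rep_row(params$zA), wA2 = rep_row(params$wA^2),
    V = rep_row(params$V), m0 = rep_row(params$m0),
    mN = rep_row(params$mN),
    r_pH = params$r_pH, pH0 = params$pH0, R_sat = params$R_sat,
    alpha = alpha[ASSEMBLAGES, ASSEMBLAGES],
    C_throttle = cfg$C_throttle
  )
}

# Month-constant environmental part: temperature broadcast plus the
# (z, C)-independent modifier sum G_pH + G_I.
make_month_env <- function(ctx, T, P, R) {
  Tm <- matrix(T, ctx$n, 4)
  GpHI <- matrix(0, ctx$n, 4)
  for (j in 1:4) {
    GpHI[, j] <- ctx$r_pH[j] * (P - ctx$pH0[j]) + tanh(R / ctx$R_sat[j]) - 1
  }
  list(Tm = Tm, GpHI = GpHI)
}

# Joint tendency of (log C, z). Returns per-capita cover rate (growth plus
# genetic load) and the throttled selection response.
deriv_uz <- function(C, z, me, ctx) {
  d <- me$Tm - z
  E <- exp(-d * d / (2 * ctx$w2))
  G <- E - 1 + me$GpHI - C %*% ctx$alpha
  gz  <- ctx$g0 * d / ctx$w2 * E
  gzz <- ctx$g0 * E * (d * d - ctx$w2) / (ctx$w2 * ctx$w2)
  hH <- d - ctx$zH
  onH <- hH > 0
  M <- ctx$mN + (hH * hH * onH) / (2 * ctx$wH2)
  gz  <- gz + ctx$m0 * (hH * onH) / ctx$wH2
  gzz <- gzz - ctx$m0 * onH / ctx$wH2
  hC <- d + ctx$zC
  onC <- hC < 0
  M <- M + (hC * hC * onC) / (2 * ctx$wC2)
  gz  <- gz + ctx$m0 * (hC * onC) / ctx$wC2
  gzz <- gzz - ctx$m0 * onC / ctx$wC2
  hA <- me$Tm - ctx$zA
  onA <- hA < 0
  M <- M + (hA * hA * onA) / (2 * ctx$wA2)
  g <- ctx$g0 * (1 + G) - ctx$m0 * M
  q <- pmax(0, 1 - ctx$C_throttle / pmax(ctx$C_throttle, 2 * C))
  list(du = g + 0.5 * ctx$V * gzz, dz = q * ctx$V * gz)
}

#' Cover tendency with genetic load
#'
#' Between spawning events cover obeys
#' \deqn{dC/dt = (g + \tfrac12 V \, \partial^2 g/\partial z^2)\, C}
#' where the second term is the genetic load from trait variance around the
#' population mean.
#'
#' @param C cover. @param z thermal optimum. @param env list with `T`, `P`,
#'   `R`, optional `C_others`. @param p single-row assemblage parameters.
#' @param alpha competition matrix.
#' @return dC/dt, 1/yr.
#' @export
cover_tendency <- function(C, z, env, p, alpha = default_competition_matrix()) {
  g <- growth_rate(env, z, p, alpha)$g
  load <- 0.5 * p$V * growth_gradient_z(env, z, p, alpha)$d2g_dz2
  (g + load) * C
}

#' Throttled selection tendency of the thermal optimum
#'
#' \deqn{dz/dt = q V \, \partial g/\partial z}, with throttle
#' `q = max(0, 1 - C_throttle / max(C_throttle, 2 C))`: selection is fully
#' suppressed for `2 C <= C_throttle` (bottleneck/founder regime) and
#' approaches the full response as cover grows.
#'
#' @inheritParams cover_tendency
#' @param C_throttle throttling threshold on cover.
#' @return dz/dt, deg C / yr.
#' @export
selection_tendency <- function(C, z, env, p, C_throttle = 1e-3,
                               alpha = default_competition_matrix()) {
  q <- pmax(0, 1 - C_throttle / pmax(C_throttle, 2 * C))
  q * p$V * growth_gradient_z(env, z, p, alpha)$dg_dz
}

#' Advance the model state through one non-spawning month
#'
#' Jointly integrates cover and trait over 1/12 yr with fixed-step RK4 and
#' `cfg$substeps` substeps, forcing held constant within the month; then
#' applies the clamps: cells below `C_min` are zeroed (extinction), and any
#' site whose total cover exceeds 1 is rescaled proportionally (with a
#' warning; under default parameters competition keeps totals well below 1
#' and this clamp should never fire).
#'
#' @param state a [reef_state()].
#' @param env_month list with site vectors `T`, `P`, `R` for the month.
#' @param params assemblage parameter table. @param alpha competition matrix.
#' @param cfg a [reef_config()].
#' @param ctx optional precomputed context (internal reuse across months).
#' @return list `state` (advanced [reef_state()]) and `report` with `dC`,
#'   `dz`, `extinctions`, `clamp_events`.
#' @export
step_month <- function(state, env_month, params, alpha, cfg,
                       ctx = NULL) {
  n <- nrow(state$C)
  if (is.null(ctx)) ctx <- make_deriv_context(n, params, alpha, cfg)
  me <- make_month_env(ctx, env_month$T, env_month$P, env_month$R)
  res <- .advance_month(state$C, state$z, me, ctx, cfg)
  C0 <- state$C; z0 <- state$z
  st <- reef_state(res$C, res$z, state$t + 1L)
  list(state = st,
       report = list(dC = st$C - C0, dz = st$z - z0,
                     extinctions = res$extinctions,
                     clamp_events = res$clamp_events))
}

# Inner month advance on raw matrices (no validation); shared by step_month
# and the run loop.
.advance_month <- function(C, z, me, ctx, cfg) {
  h <- (1 / 12) / cfg$substeps
  u <- log(C)                          # -Inf where extinct: exact absorber
  for (s in seq_len(cfg$substeps)) {
    Cc <- exp(u)
    k1 <- deriv_uz(Cc, z, me, ctx)
    k2 <- deriv_uz(exp(u + (h / 2) * k1$du), z + (h / 2) * k1$dz, me, ctx)
    k3 <- deriv_uz(exp(u + (h / 2) * k2$du), z + (h / 2) * k2$dz, me, ctx)
    k4 <- deriv_uz(exp(u + h * k3$du), z + h * k3$dz, me, ctx)
    u <- u + (h / 6) * (k1$du + 2 * k2$du + 2 * k3$du + k4$du)
    z <- z + (h / 6) * (k1$dz + 2 * k2$dz + 2 * k3$dz + k4$dz)
  }
  C <- exp(u)
  if (any(!is.finite(C)) || any(!is.finite(z))) {
    bad <- which(!is.finite(C) | !is.finite(z), arr.ind = TRUE)[1, ]
    stop("non-finite state after monthly step at site ", bad[1],
         ", assemblage ", ASSEMBLAGES[bad[2]])
  }
  ext <- C > 0 & C < cfg$C_min
  C[ext] <- 0
  tot <- rowSums(C)
  over <- tot > 1
  if (any(over)) {
    warning("total cover exceeded 1 at ", sum(over),
            " site(s); rescaled proportionally")
    C[over, ] <- C[over, , drop = FALSE] / tot[over]
  }
  list(C = C, z = z, extinctions = sum(ext), clamp_events = sum(over))
}
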