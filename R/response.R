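# Physiological response surfaces: growth-rate modifiers, mortality terms,
# size-structure conversion, and the analytic trait-derivatives of growth.
# The net growth rate of assemblage j at a site is
#   g = g0 * (1 + G_SST + G_pH + G_I + G_C) - m0 * (M_N + M_H + M_C + M_A)
# The modifier sum may fall below -1: the negative value acts as additional
# mortality and is deliberately not clamped.

#' Cover growth-rate coefficient from colony size structure
#'
#' Converts the maximum colony linear extension rate into a fractional-cover
#' growth rate, assuming log-normal colony size structure with shape
#' parameters `mu`, `sigma`:
#' \deqn{g_0 = 2\pi\, s_0\, c_0\, \exp(-\tfrac12 \mu - \tfrac38 \sigma^2)}
#' Strictly linear in `s0` and independent of environment.
#'
#' @param p assemblage parameter table (or any list with `s0`,`c0`,`mu`,
#'   `sigma`); vectorized over rows.
#' @return growth-rate coefficient(s), 1/yr.
#' @export
#' @examples
#' g0_from_size_structure(default_assemblage_params())  # 0.663, 0.133, ...
g0_from_size_structure <- function(p) {
  2 * pi * p$s0 * p$c0 * exp(-0.5 * p$mu - 0.375 * p$sigma^2)
}

#' Gaussian thermal growth modifier
#'
#' `exp(-(T - z)^2 / (2 w^2)) - 1`: zero at the thermal optimum `T = z`,
#' symmetric in `T - z`, approaching -1 far from the optimum.
#'
#' @param T temperature, deg C. @param z thermal optimum, deg C.
#' @param w tolerance breadth, deg C (> 0).
#' @export
thermal_term <- function(T, z, w) {
  stopifnot(all(w > 0))
  exp(-(T - z)^2 / (2 * w^2)) - 1
}

#' Linear pH growth modifier
#'
#' `r_pH * (P - pH0)`: with the default sensitivity 0.5, a drop of one pH
#' unit from the reference halves the linear extension rate.
#'
#' @param P pH (total scale). @param pH0 reference pH. @param r_pH
#'   extension-rate sensitivity per pH unit.
#' @export
ph_term <- function(P, pH0, r_pH) r_pH * (P - pH0)

#' Saturating light growth modifier
#'
#' `tanh(R / R_sat) - 1`: -1 in darkness (no growth without light, the light
#' deficit cancels the baseline), approaching 0 as PAR saturates.
#'
#' @param R benthic PAR, mol m-2 day-1 (>= 0).
#' @param R_sat saturation PAR, mol m-2 day-1.
#' @export
light_term <- function(R, R_sat) {
  if (any(R < 0)) stop("PAR must be non-negative")
  tanh(R / R_sat) - 1
}

#' Linear competition growth modifier
#'
#' `-sum_f alpha[f, j] * C[f]` over all competitor assemblages `f`,
#' including the self term.
#'
#' @param j focal assemblage (name or index).
#' @param C_all cover vector (length 4, one site) or sites x 4 matrix.
#' @param alpha 4x4 competition matrix, `alpha[f, j]` = effect of `f` on `j`.
#' @return scalar/vector of modifiers for the focal assemblage.
#' @export
competition_term <- function(j, C_all, alpha) {
  if (is.matrix(C_all)) -drop(C_all %*% alpha[, j]) else -sum(C_all * alpha[, j])
}

#' Stress mortality terms
#'
#' Quadratic one-sided penalties, continuous (value 0) at their activation
#' thresholds: heat stress above `z + zH`, cold stress below `z - zC`, and an
#' absolute lower limit below `zA` independent of the evolving trait.
#' Natural mortality `mN` is constant.
#'
#' @param T temperature. @param z thermal optimum. @param p assemblage
#'   parameters (single row or list of scalars).
#' @return list with components `M_N`, `M_H`, `M_C`, `M_A` (dimensionless;
#'   multiplied by `m0` in the growth rate).
#' @export
mortality_terms <- function(T, z, p) {
  hH <- T - (z + p$zH)
  hC <- T - (z - p$zC)
  hA <- T - p$zA
  list(M_N = p$mN + 0 * T,
       M_H = ifelse(hH > 0, hH^2 / (2 * p$wH^2), 0),
       M_C = ifelse(hC < 0, hC^2 / (2 * p$wC^2), 0),
       M_A = ifelse(hA < 0, hA^2 / (2 * p$wA^2), 0))
}

#' Net growth rate with full term breakdown
#'
#' @param env list with `T`, `P`, `R`, and optional `C_others` (length-4
#'   cover vector used for the competition term; default all zero).
#' @param z thermal optimum of the focal assemblage.
#' @param p single-row assemblage parameters.
#' @param alpha competition matrix.
#' @return list of class `"growth_breakdown"`: `g` (net, 1/yr), `g0`, the
#'   four growth modifiers and the four mortality terms.
#' @export
#' @examples
#' p <- default_assemblage_params()["fast_reef", ]
#' growth_rate(list(T = 27, P = 8.1, R = 1e6), z = 27, p,
#'             default_competition_matrix())$g  # = g0
growth_rate <- function(env, z, p, alpha = default_competition_matrix()) {
  C_others <- env$C_others %||% numeric(4)
  G_SST <- thermal_term(env$T, z, p$w)
  G_pH  <- ph_term(env$P, p$pH0, p$r_pH)
  G_I   <- light_term(env$R, p$R_sat)
  G_C   <- competition_term(p$name, C_others, alpha)
  M <- mortality_terms(env$T, z, p)
  g0 <- p$g0 %||% g0_from_size_structure(p)
  g <- g0 * (1 + G_SST + G_pH + G_I + G_C) -
    p$m0 * (M$M_N + M$M_H + M$M_C + M$M_A)
  structure(list(g = g, g0 = g0, G_SST = G_SST, G_pH = G_pH, G_I = G_I,
                 G_C = G_C, M_N = M$M_N, M_H = M$M_H, M_C = M$M_C,
                 M_A = M$M_A),
            class = "growth_breakdown")
}

#' Analytic trait-derivatives of the growth rate
#'
#' First and second derivatives of `g` with respect to the thermal optimum
#' `z`, used for the selection gradient and the genetic load. The Gaussian
#' thermal term contributes everywhere; heat- and cold-stress mortality
#' contribute only where active; the absolute-limit term and all non-thermal
#' modifiers are independent of `z`. At an activation threshold the one-sided
#' (stress-free) value applies.
#'
#' @inheritParams growth_rate
#' @return list with `dg_dz` and `d2g_dz2`.
#' @export
growth_gradient_z <- function(env, z, p, alpha = default_competition_matrix()) {
  g0 <- p$g0 %||% g0_from_size_structure(p)
  d <- env$T - z
  E <- exp(-d^2 / (2 * p$w^2))
  dg <- g0 * d / p$w^2 * E
  d2g <- g0 * E * (d^2 - p$w^2) / p$w^4
  hH <- d - p$zH                       # T - (z + zH)
  on <- hH > 0
  dg <- dg + ifelse(on, p$m0 * hH / p$wH^2, 0)
  d2g <- d2g - ifelse(on, p$m0 / p$wH^2, 0)
  hC <- d + p$zC                       # T - (z - zC)
  on <- hC < 0
  dg <- dg + ifelse(on, p$m0 * hC / p$wC^2, 0)
  d2g <- d2g - ifelse(on, p$m0 / p$wC^2, 0)
  list(dg_dz = dg, d2g_dz2 = d2g)
}

#' Growth response surface over temperature and thermal optimum
#'
#' Evaluates the net growth rate of each assemblage on a `(T, z)` grid under
#' otherwise optimal conditions (reference pH, saturating light, no
#' competitors), the parameterization view of the model: bounded
#' positive-growth regions, wider for the nonreef class, with no positive
#' growth below the absolute-limit temperature floor.
#'
#' @param params assemblage parameter table.
#' @param T_range,z_range grid limits, deg C. @param n grid points per axis.
#' @return list of class `"growth_surface"`: `T`, `z` axes and `g`, an
#'   n x n x 4 array of growth rates (1/yr).
#' @export
growth_surface <- function(params = default_assemblage_params(),
                           T_range = c(10, 36), z_range = c(14, 34),
                           n = 121) {
  Tg <- seq(T_range[1], T_range[2], length.out = n)
  zg <- seq(z_range[1], z_range[2], length.out = n)
  g <- array(NA_real_, c(n, n, 4), dimnames = list(NULL, NULL, params$name))
  alpha <- default_competition_matrix()
  for (j in seq_len(4)) {
    p <- params[j, ]
    for (iz in seq_len(n)) {
      env <- list(T = Tg, P = p$pH0, R = 1e9)
      g[, iz, j] <- growth_rate(env, zg[iz], p, alpha)$g
    }
  }
  structure(list(T = Tg, z = zg, g = g), class = "growth_surface")
}

#' @export
print.growth_breakdown <- function(x, ...) {
  cat("growth rate:", format(x$g), "yr^-1  (g0 =", format(x$g0), ")\n")
  cat("  modifiers: G_SST =", format(x$G_SST), " G_pH =", format(x$G_pH),
      " G_I =", format(x$G_I), " G_C =", format(x$G_C), "\n")
  cat("  mortality: M_N =", format(x$M_N), " M_H =", format(x$M_H),
      " M_C =", format(x$M_C), " M_A =", format(x$M_A), "\n")
  invisible(x)
}

#' Plot a growth response surface
#'
#' @param x a `"growth_surface"`. @param assemblage which panel(s) to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.growth_surface <- function(x, assemblage = dimnames(x$g)[[3]], ...) {
  assemblage <- match.arg(assemblage, dimnames(x$g)[[3]], several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(assemblage)))
  on.exit(graphics::par(op))
  for (a in assemblage) {
    gi <- x$g[, , a]
    graphics::image(x$T, x$z, gi, xlab = "temperature (deg C)",
                    ylab = "thermal optimum z (deg C)", main = a,
                    col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE), ...)
    graphics::contour(x$T, x$z, gi, levels = 0, add = TRUE, lwd = 2)
    graphics::abline(0, 1, col = "white", lwd = 1.5)
  }
  invisible(x)
}

#' Export a growth surface as a long-format CSV grid
#'
#' @param x a `"growth_surface"`. @param path output CSV path.
#' @export
write_growth_surface <- function(x, path) {
  long <- expand.grid(T = x$T, z = x$z,
                      assemblage = dimnames(x$g)[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$g <- as.vector(x$g)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
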