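# Programmatic fixtures shared across the suite.

# Evenly spaced coastal sites from the equator toward the pole.
make_sites <- function(n, lat_max = 45, A = 8e6, depth = 10) {
  lat <- seq(lat_max / (2 * n), lat_max - lat_max / (2 * n), length.out = n)
  site_table(paste0("s", seq_len(n)), lat = lat, lon = rep(150, n),
             A = rep(A, n), depth = depth)
}

# Noise-free repeating tropical seasonal forcing (single phase).
tropical_spec <- function(years = 30, mean_sst = 27, amp = 2.5) {
  scenario_spec(phases = list(list(name = "ctl", years = years,
                                   dT_end = 0, dpH_end = 0)),
                sst_mean_eq = mean_sst, sst_mean_pole = mean_sst,
                amp_eq = amp, amp_pole = amp, noise_sd = 0)
}

# One tropical site with self-connectivity only — a closed population.
make_single_site_model <- function(mean_sst = 27, amp = 2.5, years = 30,
                                   config = reef_config(seed = 1)) {
  sites <- make_sites(1, lat_max = 20)
  forcing <- synth_forcing(sites, tropical_spec(years, mean_sst, amp),
                           seed = 0)
  list(sites = sites, forcing = forcing,
       model = reef_model(sites, config = config))
}

.class_area_pair <- function(state, sites) {
  c(reef = total_cover_area(state, sites, "reef"),
    nonreef = total_cover_area(state, sites, "nonreef"))
}

# Reference multi-group growth ODE built from the scalar user-facing
# functions (independent of the vectorized stepping internals).
reference_rhs <- function(params, alpha, C_throttle, T, P, R) {
  function(t, y, parms) {
    C <- y[1:4]; z <- y[5:8]
    dC <- numeric(4); dz <- numeric(4)
    for (j in 1:4) {
      p <- params[j, ]
      env <- list(T = T, P = P, R = R, C_others = C)
      g <- growth_rate(env, z[j], p, alpha)$g
      gr <- growth_gradient_z(env, z[j], p, alpha)
      dC[j] <- (g + 0.5 * p$V * gr$d2g_dz2) * C[j]
      q <- max(0, 1 - C_throttle / max(C_throttle, 2 * C[j]))
      dz[j] <- q * p$V * gr$dg_dz
    }
    list(c(dC, dz))
  }
}
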