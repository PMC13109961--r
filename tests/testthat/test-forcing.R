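test_that("synthetic forcing is deterministic and exactly seasonal without
          trend or noise", {
  sites <- make_sites(5)
  spec <- scenario_spec(noise_sd = 0, noise_sd_ph = 0)
  a <- synth_forcing(sites, spec, seed = 3)
  b <- synth_forcing(sites, spec, seed = 3)
  expect_identical(a, b)
  K <- ncol(a$T)
  expect_equal(a$T[, 1:12], a$T[, 13:24])          # period 12
  expect_equal(a$R[, 1:12], a$R[, (K - 11):K])     # PAR climatological
  # noise on: same seed identical, different seed different
  spec2 <- scenario_spec()
  expect_identical(synth_forcing(sites, spec2, seed = 5),
                   synth_forcing(sites, spec2, seed = 5))
  expect_false(identical(synth_forcing(sites, spec2, seed = 5),
                         synth_forcing(sites, spec2, seed = 6)))
})

test_that("latitude controls mean, amplitude, phase; depth attenuates PAR", {
  eq <- site_table("eq", 0, 150, 1e6, depth = 5)
  po <- site_table("po", -44, 150, 1e6, depth = 15)
  spec <- scenario_spec(noise_sd = 0)
  f_eq <- synth_forcing(eq, spec, seed = 0)
  f_po <- synth_forcing(po, spec, seed = 0)
  expect_gt(mean(f_eq$T), mean(f_po$T))
  expect_lt(diff(range(f_eq$T)), diff(range(f_po$T)))
  # southern-hemisphere warm peak in February, northern in August
  expect_equal(which.max(f_po$T[1, 1:12]), 2)
  nh <- synth_forcing(site_table("n", 44, 150, 1e6, 15), spec, seed = 0)
  expect_equal(which.max(nh$T[1, 1:12]), 8)
  expect_gt(mean(f_eq$R), mean(f_po$R))            # shallower = brighter
  # amplitude 0 at the equator with equal ends: constant plus trend
  spec3 <- scenario_spec(amp_eq = 0, amp_pole = 0, noise_sd = 0,
                         phases = list(list(name = "w", years = 10,
                                            dT_end = 1)))
  f3 <- synth_forcing(eq, spec3, seed = 0)
  expect_equal(f3$T[1, ], sort(f3$T[1, ]))         # monotone ramp
})

test_that("phase trajectories reach their endpoint offsets", {
  sites <- make_sites(3)
  spec <- scenario_spec(phases = list(
    list(name = "hist", years = 20, dT_end = 1, dpH_end = -0.1),
    list(name = "ssp", years = 80, dT_end = 2.5, dpH_end = -0.3)),
    noise_sd = 0, noise_sd_ph = 0)
  fo <- synth_forcing(sites, spec, seed = 0)
  K <- ncol(fo$T)
  warming <- mean(fo$T[, (K - 119):K]) - mean(fo$T[, 1:120])
  # hand-computed ramp means: first decade of the 20-yr 0->1 ramp, last
  # decade of the 80-yr 1->2.5 ramp
  expect_equal(warming,
               (1 + 1.5 * mean(841:960) / 960) - mean(1:120) / 240,
               tolerance = 1e-6)
  expect_equal(mean(fo$P[, (K - 11):K]) - 8.1, -0.3, tolerance = 0.01)
  expect_error(scenario_spec(phases = list(list(name = "x", years = 0))),
               "positive")
})

test_that("delta correction is month-matched, exact and idempotent", {
  sites <- make_sites(4)
  fo <- synth_forcing(sites, scenario_spec(), seed = 2)
  clim <- forcing_climatology(fo)
  same <- delta_correct(fo, clim, clim)
  expect_equal(same$T, fo$T)
  obs <- clim; obs$T <- clim$T + 1
  shifted <- delta_correct(fo, clim, obs)
  expect_equal(shifted$T, fo$T + 1)
  # seasonal offset: +1 applied to January columns, -1 to July
  obs <- clim; obs$T[, 1] <- clim$T[, 1] + 1; obs$T[, 7] <- clim$T[, 7] - 1
  seas <- delta_correct(fo, clim, obs)
  jan <- fo$calendar$month == 1; jul <- fo$calendar$month == 7
  expect_equal(seas$T[, jan], fo$T[, jan] + 1)
  expect_equal(seas$T[, jul], fo$T[, jul] - 1)
  expect_equal(seas$T[, !jan & !jul], fo$T[, !jan & !jul])
  # corrected climatology equals the observed one; re-correcting is a no-op
  expect_equal(forcing_climatology(seas)$T, obs$T)
  again <- delta_correct(seas, forcing_climatology(seas), obs)
  expect_equal(again$T, seas$T)
  expect_error(delta_correct(fo, clim, forcing_climatology(
    synth_forcing(make_sites(3), scenario_spec(), seed = 2))), "site")
})

test_that("stabilized extension shifts the mean and preserves variability", {
  sites <- make_sites(3)
  # noise-free control: the anomaly window mean equals the series mean
  ctl0 <- synth_forcing(sites, scenario_spec(noise_sd = 0,
                                             noise_sd_ph = 0), seed = 0)
  win <- seq(ncol(ctl0$T) - 119, ncol(ctl0$T))
  same <- stabilize_post2100(ctl0, ctl0, win)
  expect_equal(same$T, ctl0$T, ignore_attr = TRUE)  # zero anomaly
  warm <- ctl0; warm$T <- ctl0$T + 2
  out <- stabilize_post2100(ctl0, warm, win, years = 100)
  expect_equal(ncol(out$T), 1200)
  expect_equal(rowMeans(out$T), rowMeans(ctl0$T) + 2)

  # with interannual noise: month-wise variance of the loop equals the
  # control variance exactly when the output spans whole control cycles
  ctl <- synth_forcing(sites, scenario_spec(), seed = 4)
  warm <- ctl; warm$T <- ctl$T + 2
  out <- stabilize_post2100(ctl, warm, seq(ncol(ctl$T) - 119, ncol(ctl$T)))
  expect_equal(ncol(out$T), ncol(ctl$T))
  for (m in c(1, 7)) {
    vo <- apply(out$T[, out$calendar$month == m], 1, var)
    vc <- apply(ctl$T[, ctl$calendar$month == m], 1, var)
    expect_equal(vo, vc, tolerance = 1e-10)
  }
  expect_error(stabilize_post2100(ctl, warm, integer(0)), "empty")
  expect_error(stabilize_post2100(ctl, warm, 10^6), "outside")
})

test_that("forcing round-trips through long-format CSV and rejects gaps", {
  sites <- make_sites(3)
  fo <- synth_forcing(sites, scenario_spec(phases = list(
    list(name = "c", years = 3, dT_end = 0, dpH_end = 0))), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_forcing(fo, path, site_id = sites$site_id)
  got <- read_forcing(path)
  expect_equal(got$T, fo$T, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$P, fo$P, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$R, fo$R, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$calendar, fo$calendar, ignore_attr = TRUE)

  df <- read.csv(path)
  df <- df[!(df$year == 1 & df$month == 5), ]      # drop one month: a gap
  write.csv(df, path, row.names = FALSE)
  expect_error(read_forcing(path), "gap")
  df <- df[df$month %in% c(1, 2), ]
  write.csv(df, path, row.names = FALSE)
  expect_error(read_forcing(path), "gap|complete")
})
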