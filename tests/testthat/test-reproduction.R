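p4 <- default_assemblage_params()

two_lag_kernel <- function(m1, m2, n = 1) {
  M <- array(0, c(n, n, 2))
  M[, , 1] <- m1; M[, , 2] <- m2
  connectivity_kernel(M, lags = c(2, 4), month_tag = 1)
}

test_that("kernel construction enforces probability invariants", {
  expect_error(connectivity_kernel(array(1.5, c(1, 1, 2)), lags = c(2, 4)),
               "\\[0, 1\\]")
  M <- array(0.6, c(2, 2, 1))           # row sums 1.2: mass gain
  expect_error(connectivity_kernel(M, lags = 2), "row sums")
  k <- two_lag_kernel(0.2, 0.6)
  expect_equal(dim(k$M), c(1L, 1L, 2L))
})

test_that("competency weighting averages lags and ignores curve scale", {
  cc <- data.frame(lag_days = c(2, 4), p = c(1, 1))
  class(cc) <- c("competency_curve", "data.frame")
  k <- two_lag_kernel(0.2, 0.6)
  expect_equal(effective_connectivity(k, cc)[1, 1], 0.4)   # plain mean
  cc$p <- c(0, 1)
  expect_equal(effective_connectivity(k, cc)[1, 1], 0.6)   # lag selector
  cc$p <- c(1, 3)
  expect_equal(effective_connectivity(k, cc)[1, 1], (0.2 + 3 * 0.6) / 4)
  cc$p <- 10 * cc$p                                        # scale invariance
  expect_equal(effective_connectivity(k, cc)[1, 1], 0.5)
  cc$p <- c(0, 0)
  expect_error(effective_connectivity(k, cc))
  cc <- data.frame(lag_days = c(2, 6), p = c(1, 1))
  expect_error(effective_connectivity(k, cc), "lag axes")
})

test_that("parametric competency curves are valid and class-distinct", {
  am <- competency_curve("AM")
  gr <- competency_curve("GR")
  expect_true(all(am$p >= 0 & am$p <= 1))
  expect_gt(sum(am$p), 0)
  # slow-growing curve concentrates at short lags: lower mean competent lag
  expect_lt(sum(gr$lag_days * gr$p) / sum(gr$p),
            sum(am$lag_days * am$p) / sum(am$p))
})

test_that("larval supply weights sources by cover area and averages traits", {
  z <- matrix(c(26, 28), 2, 4)
  A <- c(1e6, 1e6)
  M <- matrix(0, 2, 2)
  sup <- larval_supply(matrix(0, 2, 4), z, M, p4, A)
  expect_equal(sup$I, matrix(0, 2, 4), ignore_attr = TRUE)
  expect_true(all(is.nan(sup$z_imm)))

  # identity transport, equal areas: I = f C, trait carried through
  C <- matrix(0.3, 2, 4)
  sup <- larval_supply(C, z, diag(2), p4, A)
  expect_equal(sup$I, matrix(p4$f * 0.3, 2, 4, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(sup$z_imm, z, ignore_attr = TRUE)

  # two equal-cover sources with traits 26 and 28 mix to 27
  M <- matrix(c(0, 0, 0.5, 0.5), 2, 2)   # both sources feed site 2
  sup <- larval_supply(C, z, M, p4, A)
  expect_equal(unname(sup$z_imm[2, ]), rep(27, 4))
})

test_that("settlement closed form fills free space proportionally", {
  expect_equal(settle(matrix(c(1, 0, 0, 0), 1), matrix(0.3, 1, 4)),
               matrix(0, 1, 4), ignore_attr = TRUE)   # no free space
  dC <- settle(matrix(0, 1, 4), matrix(c(0.1, 0, 0, 0), 1))
  expect_equal(dC[1, 1], 1 - exp(-0.1))
  expect_equal(settle(matrix(0, 1, 4), matrix(0, 1, 4)),
               matrix(0, 1, 4), ignore_attr = TRUE)   # continuous limit
  expect_error(settle(matrix(0, 1, 4), matrix(-0.1, 1, 4)), "non-negative")
  # partition exactly proportional to supply, total bounded by free space
  set.seed(3)
  for (i in 1:25) {
    C <- matrix(runif(4, 0, 0.2), 1); I <- matrix(runif(4, 0, 2), 1)
    dC <- settle(C, I)
    expect_lte(sum(dC), 1 - sum(C) + 1e-12)
    expect_equal(dC / sum(dC), I / sum(I), tolerance = 1e-12)
  }
})

test_that("settlement matches the multi-group free-space ODE oracle", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, I) list(I * (1 - sum(y)))
  set.seed(4)
  for (i in 1:50) {
    C <- runif(4, 0, 0.24); I <- runif(4, 0, 2)
    dC <- settle(matrix(C, 1), matrix(I, 1))
    ref <- deSolve::ode(C, c(0, 1), rhs, I, rtol = 1e-12, atol = 1e-14)
    expect_equal(unname(dC[1, ]), unname(ref[2, -1] - C), tolerance = 1e-8)
  }
})

test_that("trait admixture is a cover-weighted mean with exact limits", {
  C <- matrix(c(0.2, 0, 0, 0), 1); z <- matrix(28, 1, 4)
  dC <- matrix(c(0.05, 0, 0, 0), 1); zi <- matrix(26, 1, 4)
  expect_equal(admix_trait(C, z, dC, zi)[1, 1], 27.6)
  expect_equal(admix_trait(C, z, matrix(0, 1, 4), zi), z)  # no immigration
  expect_equal(admix_trait(matrix(0, 1, 4), z, dC, zi)[1, 1],
               26)                      # colonization inherits immigrant trait
  zi_na <- matrix(NaN, 1, 4)
  expect_equal(admix_trait(C, z, matrix(0, 1, 4), zi_na), z)
  set.seed(5)
  for (i in 1:25) {                    # admixture bounds
    C <- matrix(runif(4), 1); z <- matrix(runif(4, 24, 30), 1)
    dC <- matrix(runif(4), 1); zi <- matrix(runif(4, 24, 30), 1)
    zn <- admix_trait(C, z, dC, zi)
    expect_true(all(zn >= pmin(z, zi) - 1e-12 & zn <= pmax(z, zi) + 1e-12))
  }
})

test_that("spawning events are deterministic and inert when fecundity is 0", {
  sites <- make_sites(3)
  st <- reef_state(matrix(0.1, 3, 4), matrix(27, 3, 4))
  bank1 <- list(synth_kernel(sites, month_tag = 1))
  cfg <- reef_config(seed = 9)
  a <- spawn_event(st, bank1, p4, sites, cfg, event_index = 5L)
  b <- spawn_event(st, bank1, p4, sites, cfg, event_index = 123L)
  expect_identical(a$state, b$state)    # one kernel: draw cannot matter
  expect_true(all(a$outcome$dC >= 0))
  expect_true(all(rowSums(a$state$C) <= 1 + 1e-12))

  p0 <- p4; p0$f <- rep(0, 4)
  z0 <- spawn_event(st, bank1, p0, sites, cfg)
  expect_equal(z0$state$C, st$C)
  expect_equal(z0$state$z, st$z)

  bank12 <- synth_kernel_bank(sites)
  r1 <- spawn_event(st, bank12, p4, sites, cfg, event_index = 7L)
  r2 <- spawn_event(st, bank12, p4, sites, cfg, event_index = 7L)
  expect_identical(r1, r2)              # fixed seed: bit-identical
  expect_error(spawn_event(st, list(), p4, sites, cfg), "empty")
})

test_that("synthetic kernels conserve larval mass and respect symmetry", {
  sites <- make_sites(12)
  k <- synth_kernel(sites, advection_bias = 0, decay_scale = 15,
                    loss_rate = 0.05)
  rs <- apply(k$M, c(1, 3), sum)
  expect_true(all(rs <= (1 - 0.05)^(rep(k$lags, each = 12) / 2) + 1e-12))
  # bias 0: transport h -> i equals i -> h
  for (m in c(1, 15, 30))
    expect_equal(k$M[, , m], t(k$M[, , m]), tolerance = 1e-10)
  # interior sources lose only to the domain edges: lag-60 surviving mass
  mid <- 6
  expect_equal(sum(k$M[mid, , 30]), (1 - 0.05)^30, tolerance = 0.05)
  k2 <- synth_kernel(sites, loss_rate = 0.999)
  expect_lt(max(k2$M), 2e-3)            # only the shortest lag retains mass
  expect_lt(sum(k2$M[, , 30]), 1e-80)
  kb <- synth_kernel(sites, advection_bias = 3)
  down <- sum(kb$M[mid, (mid + 1):12, 30])
  up <- sum(kb$M[mid, 1:(mid - 1), 30])
  expect_gt(down, up)                   # advection biases downstream
  expect_error(synth_kernel(sites, decay_scale = 0), "decay_scale")
  expect_error(synth_kernel(sites, loss_rate = 1), "loss_rate")
})

test_that("kernel banks round-trip through Matrix Market files", {
  sites <- make_sites(4)
  bank <- list(synth_kernel(sites, month_tag = 1, lags = c(2, 4, 6)),
               synth_kernel(sites, month_tag = 2, lags = c(2, 4, 6),
                            advection_bias = -1))
  dir <- withr::local_tempdir()
  write_kernel_bank(bank, dir)
  got <- read_kernel_bank(dir)
  expect_equal(length(got), 2)
  for (i in 1:2) {
    expect_equal(got[[i]]$M, bank[[i]]$M, tolerance = 1e-12)
    expect_equal(got[[i]]$lags, bank[[i]]$lags)
    expect_equal(got[[i]]$month_tag, bank[[i]]$month_tag)
  }
})
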