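# Experiment orchestration: model assembly, trait/cover initialization,
# spin-up under looped control forcing with a convergence check, transient
# scenario phases, and exact checkpoint-resume.

#' Assemble a runnable coral metacommunity model
#'
#' Bundles the site table, assemblage parameters, competition matrix, run
#' configuration and dispersal-kernel bank, and precomputes the per-
#' assemblage competency-weighted effective connectivity.
#'
#' @param sites a [site_table()].
#' @param params assemblage parameter table
#'   (default [default_assemblage_params()]).
#' @param alpha competition matrix (default [default_competition_matrix()]).
#' @param config a [reef_config()].
#' @param kernels list of [connectivity_kernel()]s (default: a single
#'   self-connectivity kernel — a closed population).
#' @param spawn_month optional per-site spawning month (1..12); default is
#'   derived hemisphere-aware from the control forcing at initialization
#'   (month after the climatological warmest month), or fixed globally by
#'   `config$spawning_month`.
#' @return list of class `"reef_model"`.
#' @export
reef_model <- function(sites, params = default_assemblage_params(),
                       alpha = default_competition_matrix(),
                       config = reef_config(),
                       kernels = list(identity_kernel(nrow(sites))),
                       spawn_month = NULL) {
  stopifnot(inherits(sites, "site_table"))
  validate_assemblage_params(params)
  alpha <- validate_competition_matrix(alpha)
  if (length(kernels) == 0) stop("kernel bank is empty")
  if (dim(kernels[[1]]$M)[1] != nrow(sites))
    stop("kernel dimension does not match the site table")
  if (!is.null(spawn_month)) spawn_month <- rep_len(spawn_month, nrow(sites))
  structure(list(sites = sites, params = params, alpha = alpha,
                 config = config, bank = kernels,
                 bank_eff = precompute_effective_bank(kernels, params),
                 spawn_month = spawn_month),
            class = "reef_model")
}

#' Hemisphere-aware spawning months
#'
#' Default spawning month per site: the calendar month after the site's
#' climatological warmest month (or `config$spawning_month` globally when
#' set).
#'
#' @param model a [reef_model()]. @param series control [forcing_series()].
#' @return integer vector, one month (1..12) per site.
#' @export
spawning_months <- function(model, series) {
  if (!is.null(model$config$spawning_month))
    return(rep(model$config$spawning_month, nrow(model$sites)))
  clim <- forcing_climatology(series)
  warmest <- max.col(clim$T, ties.method = "first")
  warmest %% 12L + 1L
}

#' Initialize the model state
#'
#' Thermal optimum: the 90th percentile of the monthly control SST
#' distribution at each site (all assemblages alike) — the convergent state
#' is insensitive to this choice, it only accelerates convergence. Cover: a
#' supplied site x assemblage map, or a uniform small cover in every group.
#'
#' @param model a [reef_model()].
#' @param control a control [forcing_series()].
#' @param init_cover scalar (default 0.01) or sites x 4 matrix.
#' @return a [reef_state()].
#' @export
initialize_state <- function(model, control, init_cover = 0.01) {
  n <- nrow(model$sites)
  z90 <- apply(control$T, 1, stats::quantile, probs = 0.9, names = FALSE)
  z <- matrix(z90, n, 4)
  C <- if (is.matrix(init_cover)) init_cover else matrix(init_cover, n, 4)
  if (all(C == 0))
    warning("initial cover is zero everywhere: ",
            "nothing can colonize without a seeded source")
  reef_state(C, z, t = 0L)
}

# Shared monthly driver: advances one month including any spawning, using
# precomputed contexts. `t_abs` (months since simulation start) keys the
# kernel draw, which makes resumed runs bit-identical.
.month_tick <- function(C, z, t_abs, k, series, model, ctx, sm, counters) {
  me <- make_month_env(ctx, series$T[, k], series$P[, k], series$R[, k])
  adv <- .advance_month(C, z, me, ctx, model$config)
  C <- adv$C; z <- adv$z
  counters$extinctions <- counters$extinctions + adv$extinctions
  counters$clamp_events <- counters$clamp_events + adv$clamp_events
  mo <- series$calendar$month[k]
  src <- sm == mo
  if (any(src)) {
    ki <- 1L + counter_draw(model$config$seed, t_abs, length(model$bank_eff))
    A_eff <- model$sites$A * model$sites$rf
    sup <- larval_supply(C * src, z, model$bank_eff[[ki]], model$params, A_eff)
    dC <- settle(C, sup$I)
    z <- admix_trait(C, z, dC, sup$z_imm)
    C <- C + dC
    C[C < model$config$C_min] <- 0
  }
  list(C = C, z = z, counters = counters)
}

.class_areas <- function(C, sites) {
  w <- sites$A * sites$rf / 1e6          # km^2
  reef <- colnames(C) %in% names(REEF_CLASS)[REEF_CLASS == "reef"]
  c(reef = sum(C[, reef, drop = FALSE] * w),
    nonreef = sum(C[, !reef, drop = FALSE] * w))
}

.cw_trait <- function(C, z, cols) {
  w <- sum(C[, cols]); if (w == 0) return(NA_real_)
  sum(C[, cols] * z[, cols]) / w
}

#' Spin up the model under looped control forcing
#'
#' Loops the control series for up to `years` model years, recording
#' century-block mean class-total cover areas. Convergence: the first
#' century whose class-total cover differs by less than `tol` (relative,
#' default 1%) from the previous century for every class with nonzero
#' cover.
#'
#' @param state initial [reef_state()]. @param control control
#'   [forcing_series()]. @param model a [reef_model()].
#' @param years total spin-up years (default 5000).
#' @param tol relative per-century convergence tolerance (default 0.01).
#' @param stop_after_convergence stop looping once convergence is detected
#'   (the reported convergence year is unaffected).
#' @return list `state` (final), `report` (a `"convergence_report"`:
#'   per-century class areas, trait drift, `converged_year` or `NA`), and
#'   stress counters.
#' @export
spin_up <- function(state, control, model, years = 5000, tol = 0.01,
                    stop_after_convergence = FALSE) {
  if (years == 0)
    return(list(state = state,
                report = structure(list(centuries = data.frame(),
                                        converged_year = NA_integer_),
                                   class = "convergence_report"),
                extinctions = 0L, clamp_events = 0L))
  ctx <- make_deriv_context(nrow(state$C), model$params, model$alpha,
                            model$config)
  sm <- model$spawn_month %||% spawning_months(model, control)
  Kc <- ncol(control$T)
  C <- state$C; z <- state$z; t_abs <- state$t
  counters <- list(extinctions = 0L, clamp_events = 0L)
  yearly <- matrix(NA_real_, years, 3,
                   dimnames = list(NULL, c("reef", "nonreef", "z_reef")))
  cent <- list(); converged <- NA_integer_
  prev <- NULL
  for (yr in seq_len(years)) {
    for (mo in 1:12) {
      k <- (t_abs %% Kc) + 1L           # loop the control series
      tk <- .month_tick(C, z, t_abs, k, control, model, ctx, sm, counters)
      C <- tk$C; z <- tk$z; counters <- tk$counters
      t_abs <- t_abs + 1L
    }
    ar <- .class_areas(C, model$sites)
    yearly[yr, ] <- c(ar, .cw_trait(C, z, 1:2))
    if (yr %% 100 == 0) {
      blk <- colMeans(yearly[(yr - 99):yr, , drop = FALSE])
      cent[[length(cent) + 1]] <-
        data.frame(century = yr / 100, year = yr, area_reef = blk[1],
                   area_nonreef = blk[2], z_reef = blk[3])
      if (!is.null(prev) && is.na(converged)) {
        rel <- abs(blk[1:2] - prev[1:2]) / pmax(prev[1:2], 1e-12)
        rel <- rel[prev[1:2] > 0 | blk[1:2] > 0]
        if (length(rel) == 0 || all(rel < tol)) converged <- yr
      }
      prev <- blk
      if (stop_after_convergence && !is.na(converged)) break
    }
  }
  cent <- do.call(rbind, cent)
  cent$z_drift <- c(NA, diff(cent$z_reef))
  report <- structure(list(centuries = cent, converged_year = converged,
                           tol = tol),
                      class = "convergence_report")
  list(state = reef_state(C, z, t_abs), report = report,
       extinctions = counters$extinctions,
       clamp_events = counters$clamp_events)
}

#' Run a sequence of forcing phases
#'
#' Advances the state through an ordered list of phases (each a named
#' [forcing_series()]), stepping monthly with annual spawning, emitting a
#' yearly summary and optional state snapshots, and optionally writing a
#' checkpoint. Fully deterministic given the model seed; a run resumed from
#' the checkpoint is bit-identical to the uninterrupted run.
#'
#' @param model a [reef_model()]. @param plan list of phases, each
#'   `list(name, forcing)`. @param state starting [reef_state()].
#' @param snapshot_every store full state snapshots every this many months
#'   (0 = none).
#' @param checkpoint_path,checkpoint_month write the state after this many
#'   plan months to this RDS path.
#' @param .skip_months internal (resume): months of the plan already done.
#' @return list of class `"reef_run"`: `summary` (yearly data.frame),
#'   `snapshots`, `state` (final), counters, and the phase table.
#' @export
run_phases <- function(model, plan, state, snapshot_every = 0,
                       checkpoint_path = NULL, checkpoint_month = NULL,
                       .skip_months = 0L) {
  ctx <- make_deriv_context(nrow(state$C), model$params, model$alpha,
                            model$config)
  sm <- model$spawn_month %||% spawning_months(model, plan[[1]]$forcing)
  C <- state$C; z <- state$z; t_abs <- state$t
  counters <- list(extinctions = 0L, clamp_events = 0L)
  rows <- list(); snaps <- list()
  g <- 0L
  for (ph in plan) {
    series <- ph$forcing
    K <- ncol(series$T)
    for (k in seq_len(K)) {
      g <- g + 1L
      if (g <= .skip_months) next
      tk <- .month_tick(C, z, t_abs, k, series, model, ctx, sm, counters)
      C <- tk$C; z <- tk$z; counters <- tk$counters
      t_abs <- t_abs + 1L
      if (!is.null(checkpoint_month) && g == checkpoint_month) {
        saveRDS(list(format = "reefevo-checkpoint-1",
                     state = reef_state(C, z, t_abs), plan_month = g,
                     seed = model$config$seed),
                checkpoint_path)
      }
      if (series$calendar$month[k] == 12L || k == K) {
        ar <- .class_areas(C, model$sites)
        rows[[length(rows) + 1]] <- data.frame(
          t = t_abs, phase = ph$name, year = series$calendar$year[k],
          area_reef = ar[1], area_nonreef = ar[2],
          area_all = ar[1] + ar[2],
          z_reef = .cw_trait(C, z, 1:2), z_nonreef = .cw_trait(C, z, 3:4))
      }
      if (snapshot_every > 0 && g %% snapshot_every == 0) {
        snaps[[length(snaps) + 1]] <- reef_state(C, z, t_abs)
      }
    }
  }
  out <- list(summary = do.call(rbind, rows), snapshots = snaps,
              state = reef_state(C, z, t_abs),
              extinctions = counters$extinctions,
              clamp_events = counters$clamp_events,
              phases = data.frame(
                name = vapply(plan, `[[`, "", "name"),
                months = vapply(plan, function(p) ncol(p$forcing$T), 0)))
  class(out) <- "reef_run"
  out
}

#' Resume a phased run from a checkpoint
#'
#' @param model,plan as passed to the original [run_phases()] call.
#' @param checkpoint_path RDS checkpoint written by [run_phases()].
#' @inheritParams run_phases
#' @return a `"reef_run"` covering the remainder of the plan.
#' @export
resume_run <- function(model, plan, checkpoint_path, snapshot_every = 0) {
  ck <- readRDS(checkpoint_path)
  if (!identical(ck$format, "reefevo-checkpoint-1"))
    stop("unrecognized checkpoint format")
  if (!identical(ck$seed, model$config$seed))
    stop("checkpoint seed does not match the model configuration")
  run_phases(model, plan, ck$state, snapshot_every = snapshot_every,
             .skip_months = ck$plan_month)
}

#' Simulate a coral metacommunity model
#'
#' Convenience front end to the experiment protocol: initialize (90th
#' percentile trait, uniform cover), spin up under the control forcing, then
#' run the transient phases.
#'
#' @param object a [reef_model()].
#' @param nsim unused (the model is deterministic given the seed).
#' @param seed overrides the model seed when non-`NULL`.
#' @param control control [forcing_series()] for spin-up.
#' @param plan transient phases for [run_phases()] (may be empty).
#' @param spinup_years spin-up length.
#' @param init_cover initial cover.
#' @param ... passed to [run_phases()].
#' @return a `"reef_run"` with the spin-up report attached as
#'   `$spinup_report`.
#' @export
simulate.reef_model <- function(object, nsim = 1, seed = NULL, control,
                                plan = list(), spinup_years = 1000,
                                init_cover = 0.01, ...) {
  model <- object
  if (!is.null(seed)) model$config$seed <- as.integer(seed)
  if (is.null(model$spawn_month))
    model$spawn_month <- spawning_months(model, control)
  st <- initialize_state(model, control, init_cover)
  sp <- spin_up(st, control, model, years = spinup_years)
  if (length(plan) == 0) {
    run <- list(summary = NULL, snapshots = list(), state = sp$state,
                extinctions = sp$extinctions,
                clamp_events = sp$clamp_events,
                phases = data.frame(name = character(), months = numeric()))
    class(run) <- "reef_run"
  } else {
    run <- run_phases(model, plan, sp$state, ...)
  }
  run$spinup_report <- sp$report
  run
}

#' @export
print.reef_model <- function(x, ...) {
  cat("coral metacommunity model:", nrow(x$sites), "sites, 4 assemblages\n")
  cat("  latitude range:", paste(round(range(x$sites$lat), 2),
                                 collapse = " .. "), "deg\n")
  cat("  kernel bank:", length(x$bank), "monthly kernel(s)\n")
  cat("  seed:", x$config$seed, " substeps:", x$config$substeps, "\n")
  invisible(x)
}

#' @export
print.reef_run <- function(x, ...) {
  cat("coral metacommunity run:", sum(x$phases$months), "plan months,",
      length(x$snapshots), "snapshots\n")
  if (!is.null(x$summary) && nrow(x$summary)) {
    last <- x$summary[nrow(x$summary), ]
    cat(sprintf("  final areas (km^2): all %.4g, reef %.4g, nonreef %.4g\n",
                last$area_all, last$area_reef, last$area_nonreef))
  }
  if (!is.null(x$spinup_report))
    cat("  spin-up converged year:", x$spinup_report$converged_year, "\n")
  invisible(x)
}

#' @export
summary.reef_run <- function(object, ...) {
  s <- object$summary
  cat("phases:\n"); print(object$phases)
  if (!is.null(s) && nrow(s)) {
    cat("\nclass-total cover area (km^2), first/last year per phase:\n")
    for (ph in unique(s$phase)) {
      sp <- s[s$phase == ph, ]
      print(sp[c(1, nrow(sp)), c("year", "area_all", "area_reef",
                                 "area_nonreef", "z_reef")],
            row.names = FALSE)
    }
  }
  cat("\nextinction clamps:", object$extinctions,
      " total-cover rescales:", object$clamp_events, "\n")
  invisible(object)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("spin-up convergence (<", 100 * (x$tol %||% 0.01),
      "% class-total change per century)\n", sep = "")
  cat("converged year:", x$converged_year, "\n")
  if (nrow(x$centuries)) print(utils::tail(x$centuries, 5), row.names = FALSE)
  invisible(x)
}

#' Plot the class-total cover trajectory of a run
#'
#' @param x a `"reef_run"`. @param ... passed to [graphics::matplot()].
#' @export
plot.reef_run <- function(x, ...) {
  s <- x$summary
  if (is.null(s) || !nrow(s)) stop("run has no summary rows to plot")
  graphics::matplot(s$year, s[, c("area_all", "area_reef", "area_nonreef")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "darkorange", "seagreen"),
                    xlab = "model year", ylab = expression(area ~ (km^2)),
                    ...)
  graphics::legend("topright", c("all", "reef", "nonreef"), lty = 1, lwd = 2,
                   col = c("steelblue", "darkorange", "seagreen"), bty = "n")
  invisible(x)
}
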