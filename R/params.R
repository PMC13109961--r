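ASSEMBLAGES <- c("fast_reef", "slow_reef", "fast_nonreef", "slow_nonreef")
REEF_CLASS <- c(fast_reef = "reef", slow_reef = "reef",
                fast_nonreef = "nonreef", slow_nonreef = "nonreef")

#' Default assemblage parameter table
#'
#' One row per assemblage (fast/slow x reef/nonreef) holding every
#' physiological, demographic and dispersal constant of the model:
#' maximum linear extension rate `s0` (m/yr), thermal tolerance breadth `w`
#' (deg C), heat/cold/absolute-limit stress tolerances and thresholds
#' (`wH`,`zH`,`wC`,`zC`,`wA`,`zA`, deg C), additive genetic variance `V`
#' (deg C^2), effective fecundity `f`, pH sensitivity `r_pH` and reference
#' `pH0`, saturation PAR `R_sat` (mol m-2 day-1), log-normal colony-size
#' shape `mu`,`sigma`, natural mortality `mN` (1/yr), mortality rate
#' coefficient `m0` (1/yr), unit-fixing constant `c0` (1/m) and the
#' competency-curve identifier `kernel_id`. The derived cover growth-rate
#' coefficient `g0` (1/yr) is attached as a column.
#'
#' @param fecundity `"table"` (defaults 0.008 fast / 0.1 slow) or
#'   `"conservative"` (4e-4 / 5e-3), an alternative preset reflecting more
#'   conservative egg-to-recruit conversion assumptions.
#' @return A `data.frame` of class `"assemblage_params"`, 4 rows.
#' @export
#' @examples
#' p <- default_assemblage_params()
#' p[, c("name", "s0", "w", "zH", "g0")]
default_assemblage_params <- function(fecundity = c("table", "conservative")) {
  fecundity <- match.arg(fecundity)
  f <- if (fecundity == "table") c(0.008, 0.1, 0.008, 0.1)
       else c(4e-4, 5e-3, 4e-4, 5e-3)
  p <- data.frame(
    name  = ASSEMBLAGES,
    s0    = c(0.05, 0.01, 0.05, 0.01),
    w     = c(6, 6, 8, 8),
    wH    = c(0.5, 1.0, 0.5, 1.0),
    zH    = c(1.5, 1.5, 3.5, 3.5),
    wC    = c(0.75, 1.5, 0.75, 1.5),
    zC    = c(8, 8, 10, 10),
    wA    = c(6, 6, 8, 8),
    zA    = c(24.2, 21.3, 22.9, 19.1),
    V     = c(0.05, 0.05, 0.05, 0.05),
    f     = f,
    r_pH  = c(0.5, 0.5, 0.5, 0.5),
    pH0   = c(8.1, 8.1, 8.1, 8.1),
    R_sat = c(15, 15, 15, 15),
    mu    = c(-4.2, -4.2, -4.2, -4.2),
    sigma = c(1.9, 1.9, 1.9, 1.9),
    mN    = c(0, 0, 0, 0),
    m0    = c(1, 1, 1, 1),
    c0    = c(1, 1, 1, 1),
    kernel_id = c("AM", "GR", "AM", "GR"),
    stringsAsFactors = FALSE
  )
  p$g0 <- g0_from_size_structure(p)
  rownames(p) <- p$name
  class(p) <- c("assemblage_params", "data.frame")
  validate_assemblage_params(p)
  p
}

validate_assemblage_params <- function(p) {
  stopifnot(is.data.frame(p), nrow(p) == 4)
  if (!identical(sort(p$name), sort(ASSEMBLAGES)))
    stop("assemblage names must be exactly ",
         paste(ASSEMBLAGES, collapse = ", "))
  chk <- function(cond, msg, val) {
    if (!all(cond)) stop("invalid assemblage parameter: ", msg,
                         " (got ", paste(val[!cond], collapse = ", "), ")")
  }
  chk(p$s0 >= 0, "s0 must be >= 0", p$s0)
  chk(p$w > 0, "w must be > 0", p$w)
  chk(p$wH > 0, "wH must be > 0", p$wH)
  chk(p$wC > 0, "wC must be > 0", p$wC)
  chk(p$wA > 0, "wA must be > 0", p$wA)
  chk(p$zC > p$zH, "zC must exceed zH", p$zC)
  chk(p$V >= 0, "V must be >= 0", p$V)
  chk(p$f >= 0 & p$f <= 1, "f must be in [0,1]", p$f)
  chk(p$R_sat > 0, "R_sat must be > 0", p$R_sat)
  chk(p$sigma > 0, "sigma must be > 0", p$sigma)
  chk(p$mN >= 0, "mN must be >= 0", p$mN)
  chk(p$m0 > 0, "m0 must be > 0", p$m0)
  invisible(p)
}

#' Default competition matrix
#'
#' Linear competition coefficients `alpha[f, j]`: the effect of competitor
#' assemblage `f`'s cover on the growth of focal assemblage `j`. Class-level
#' defaults: reef-on-nonreef 1.2, nonreef-on-reef 0.8, within the reef class 2,
#' within the nonreef class 10 (reef corals hold the competitive advantage;
#' strong within-class self-limitation keeps nonreef cover low).
#'
#' @return 4x4 numeric matrix with assemblage dimnames (rows = source
#'   competitor `f`, columns = focal `j`).
#' @export
default_competition_matrix <- function() {
  a <- matrix(0, 4, 4, dimnames = list(ASSEMBLAGES, ASSEMBLAGES))
  for (f in ASSEMBLAGES) for (j in ASSEMBLAGES) {
    cf <- REEF_CLASS[[f]]; cj <- REEF_CLASS[[j]]
    a[f, j] <- if (cf == cj) { if (cf == "reef") 2 else 10 }
               else if (cf == "reef") 1.2 else 0.8
  }
  a
}

validate_competition_matrix <- function(a) {
  if (!is.matrix(a) || !identical(dim(a), c(4L, 4L)))
    stop("competition matrix must be 4x4")
  if (any(a < 0)) stop("competition coefficients must be >= 0")
  if (is.null(dimnames(a)))
    dimnames(a) <- list(ASSEMBLAGES, ASSEMBLAGES)
  a[ASSEMBLAGES, ASSEMBLAGES, drop = FALSE]
}

#' Global run configuration
#'
#' @param C_min minimum nonzero cover: cells below it are clamped to 0 after
#'   each monthly step (default 1e-9).
#' @param C_throttle cover threshold below which the selection response is
#'   throttled, emulating founder effects (default 1e-3).
#' @param spawning_month `NULL` for hemisphere-aware default (the calendar
#'   month after each site's climatological warmest month), or an integer
#'   1..12 fixing a global spawning month.
#' @param substeps integration substeps per month for the fixed-step RK4
#'   scheme (default 4).
#' @param seed integer seed governing kernel sampling (and any other
#'   stochastic component of a run).
#' @param output_every diagnostic output cadence in months (default 12).
#' @return list of class `"reef_config"`.
#' @export
reef_config <- function(C_min = 1e-9, C_throttle = 1e-3,
                        spawning_month = NULL, substeps = 4L,
                        seed = 1L, output_every = 12L) {
  if (!(C_min > 0 && C_min < C_throttle && C_throttle < 1))
    stop("require 0 < C_min < C_throttle < 1; got C_min=", C_min,
         ", C_throttle=", C_throttle)
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be >= 1")
  if (!is.null(spawning_month)) {
    spawning_month <- as.integer(spawning_month)
    if (spawning_month < 1L || spawning_month > 12L)
      stop("spawning_month must be in 1..12")
  }
  structure(list(C_min = C_min, C_throttle = C_throttle,
                 spawning_month = spawning_month, substeps = substeps,
                 seed = as.integer(seed),
                 output_every = as.integer(output_every)),
            class = "reef_config")
}

#' Site table constructor
#'
#' Geography and habitable area of the model's subpopulations. Habitability
#' limits follow the model's definition of potential shallow-water coral
#' habitat: within 45 degrees of the equator and no deeper than 20 m mean
#' depth. `rf` is the fraction of the habitable area that reef can occupy at
#' most; it enters area reporting and the settlement area weights, not as a
#' cap on fractional cover.
#'
#' @param site_id character or integer identifiers (unique).
#' @param lat,lon coordinates in degrees.
#' @param A habitable area, m^2 (> 0).
#' @param depth mean depth, m (<= 20).
#' @param rf habitable fraction in (0, 1]; default 0.125 (1/8).
#' @return `data.frame` of class `"site_table"`.
#' @export
site_table <- function(site_id, lat, lon, A, depth = 10, rf = 0.125) {
  s <- data.frame(site_id = as.character(site_id), lat = lat, lon = lon,
                  A = A, depth = depth, rf = rf, stringsAsFactors = FALSE)
  if (anyDuplicated(s$site_id)) stop("site_id must be unique")
  if (any(s$A <= 0)) stop("habitable area A must be > 0")
  if (any(abs(s$lat) > 45))
    stop("sites must lie within 45 degrees of the equator")
  if (any(s$depth > 20)) stop("site mean depth must be <= 20 m")
  if (any(s$rf <= 0 | s$rf > 1)) stop("rf must be in (0, 1]")
  class(s) <- c("site_table", "data.frame")
  s
}

#' Model state constructor
#'
#' The two prognostic fields: fractional cover `C` and mean thermal-optimum
#' trait `z` (deg C), site x assemblage, plus model time in months.
#'
#' @param C,z numeric matrices, sites x 4 assemblages.
#' @param t months since simulation start.
#' @return list of class `"reef_state"`.
#' @export
reef_state <- function(C, z, t = 0L) {
  C <- as.matrix(C); z <- as.matrix(z)
  if (!identical(dim(C), dim(z))) stop("C and z must have identical shape")
  if (ncol(C) != 4L) stop("state must have 4 assemblage columns")
  colnames(C) <- colnames(z) <- ASSEMBLAGES
  if (any(C < 0)) stop("cover must be non-negative")
  if (any(rowSums(C) > 1 + 1e-12)) stop("total cover exceeds 1 at some site")
  if (any(!is.finite(z[C > 0]))) stop("z must be finite wherever C > 0")
  structure(list(C = C, z = z, t = as.integer(t)), class = "reef_state")
}

#' Load model configuration from a YAML file
#'
#' Unspecified fields take the package defaults (the standard four-assemblage
#' parameterization). Recognised top-level sections: `assemblages` (a map of
#' assemblage name to field overrides), `competition` (entries like
#' `reef_reef`, `reef_nonreef`, `nonreef_reef`, `nonreef_nonreef`, or a full
#' 4x4 `matrix`), and `global` (fields of [reef_config()]). The fully
#' resolved configuration is echoed via `message()` for reproducibility.
#'
#' @param path path to a YAML config file.
#' @param quiet suppress the configuration echo.
#' @return list with elements `params` ([default_assemblage_params()] shape),
#'   `alpha` (4x4 matrix), `config` ([reef_config()]).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  params <- default_assemblage_params()
  num_fields <- setdiff(names(params), c("name", "kernel_id", "g0"))
  for (nm in names(raw$assemblages)) {
    if (!nm %in% ASSEMBLAGES)
      stop("unknown assemblage in config: ", nm)
    for (fld in names(raw$assemblages[[nm]])) {
      if (!fld %in% c(num_fields, "kernel_id"))
        stop("unknown assemblage field in config: ", fld)
      params[nm, fld] <- raw$assemblages[[nm]][[fld]]
    }
  }
  params$g0 <- g0_from_size_structure(params)
  validate_assemblage_params(params)

  alpha <- default_competition_matrix()
  comp <- raw$competition
  if (!is.null(comp)) {
    if (!is.null(comp$matrix)) {
      alpha <- validate_competition_matrix(
        matrix(unlist(comp$matrix), 4, 4, byrow = TRUE,
               dimnames = list(ASSEMBLAGES, ASSEMBLAGES)))
    } else {
      cls <- list(reef = c("fast_reef", "slow_reef"),
                  nonreef = c("fast_nonreef", "slow_nonreef"))
      for (key in names(comp)) {
        src <- sub("_(reef|nonreef)$", "", key)
        dst <- sub(".*_", "", key)
        if (!src %in% names(cls) || !dst %in% names(cls))
          stop("unknown competition entry in config: ", key)
        alpha[cls[[src]], cls[[dst]]] <- comp[[key]]
      }
    }
  }
  alpha <- validate_competition_matrix(alpha)

  cfg <- do.call(reef_config, as.list(raw$global %||% list()))

  if (!quiet) {
    message("resolved configuration:")
    message(paste(utils::capture.output({
      print(as.data.frame(params)[, c("name", "s0", "w", "zH", "zC", "zA",
                                      "V", "f", "g0")])
      print(alpha)
      utils::str(unclass(cfg))
    }), collapse = "\n"))
  }
  list(params = params, alpha = alpha, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
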