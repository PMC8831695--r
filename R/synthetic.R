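#' Default 24-well synthetic plate layout
#'
#' A compact layout exercising every well role the kinetics pipeline
#' expects: 3 medium blanks, 3 autofluorescence-control wells
#' (non-fluorescent host strain), 3 + 3 reference wells for the RFP and GFP
#' reference strains (J101R, J101G), and 4 sample strains in triplicate at
#' different HSL inducer levels. True per-cell synthesis rates are chosen so
#' the sample strains span S_cell ratios 0.25--2.5 relative to the
#' reference, with a constitutive GFP capacity monitor in every sample.
#' Growth parameters emulate E. coli in M9 medium in a 96-well reader:
#' doubling time about 70 min, carrying capacity OD 0.7, 60 min lag.
#'
#' @return A data.frame, one row per well, with the per-well truth fields
#'   consumed by [plate_truth()].
#' @export
default_plate_layout <- function() {
  mk <- function(well, strain, role, inducer, conc_nM, mu, s_rfp, s_gfp) {
    data.frame(well = well, strain = strain, role = role, inducer = inducer,
               conc_nM = conc_nM, mu_true = mu, capacity = 0.7, lag_min = 60,
               s_true_RFP = s_rfp, s_true_GFP = s_gfp,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    mk(paste0("B", 1:3), "none", "blank_medium", "none", 0, 0, 0, 0),
    mk(paste0("C", 1:3), "TOP10", "autofluorescence_control", "none", 0,
       0.6, 0, 0),
    mk(paste0("R", 1:3), "J101R", "reference", "none", 0, 0.6, 20, 0),
    mk(paste0("G", 1:3), "J101G", "reference", "none", 0, 0.6, 0, 18)
  )
  strains <- c("circuitA", "circuitB", "circuitC", "circuitD")
  s_rfp <- c(5, 12.5, 25, 50)     # S_cell truth 0.25, 0.625, 1.25, 2.5
  conc <- c(0, 1, 10, 100)
  for (k in seq_along(strains)) {
    rows[[length(rows) + 1L]] <-
      mk(paste0("S", k, 1:3), strains[k], "sample", "HSL", conc[k],
         0.6, s_rfp[k], 15)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground truth for a synthetic microplate experiment
#'
#' Bundles the per-well truth table with the plate-level noise and
#' background settings that [generate_plate()] consumes. With the same
#' `seed` and configuration the generated files are byte-identical.
#'
#' @param wells Per-well truth data.frame (see [default_plate_layout()] for
#'   the required columns).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise, in `[0, 0.2]`. Default 0.02, a typical plate-reader
#'   repeatability.
#' @param background_od Additive medium/plate absorbance. Default 0.09.
#' @param background_fluo Named additive fluorescence backgrounds per
#'   channel, AU. Default `c(RFP = 30, GFP = 50)`.
#' @param od0 Initial biomass OD after dilution into the plate.
#'   Default 0.01.
#' @param seed Integer RNG seed. Default 1.
#' @return An object of class `"plate_truth"`.
#' @export
plate_truth <- function(wells = default_plate_layout(), noise_cv = 0.02,
                        background_od = 0.09,
                        background_fluo = c(RFP = 30, GFP = 50),
                        od0 = 0.01, seed = 1L) {
  need <- c("well", "strain", "role", "inducer", "conc_nM", "mu_true",
            "capacity", "lag_min", "s_true_RFP", "s_true_GFP")
  if (!all(need %in% names(wells)))
    stop("wells must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  num <- c("mu_true", "capacity", "lag_min", "s_true_RFP", "s_true_GFP")
  if (any(sapply(wells[num], function(v) any(!is.finite(v) | v < 0))))
    stop("per-well rates and growth parameters must be finite and >= 0",
         call. = FALSE)
  if (!is.finite(noise_cv) || noise_cv < 0 || noise_cv > 0.2)
    stop("noise_cv must be in [0, 0.2]", call. = FALSE)
  structure(list(wells = wells, noise_cv = noise_cv,
                 background_od = background_od,
                 background_fluo = background_fluo,
                 od0 = od0, seed = as.integer(seed)),
            class = "plate_truth")
}

# Batch-growth curve: flat lag, true exponential phase, then logistic
# deceleration once the culture passes sat_frac of its carrying capacity
# (substrate-limited growth is exponential until nutrients run short, unlike
# a pure logistic which decelerates from the first doubling). The two
# branches match in value and slope at the handover.
growth_od <- function(t_min, mu_per_h, capacity, lag_min, od0,
                      sat_frac = 0.5) {
  if (mu_per_h == 0 || capacity == 0) return(rep(od0, length(t_min)))
  te <- pmax(t_min - lag_min, 0) / 60
  od <- od0 * exp(mu_per_h * te)
  xstar <- sat_frac * capacity
  if (od0 < xstar) {
    t_star <- log(xstar / od0) / mu_per_h        # hours after lag
    hi <- te > t_star
    if (any(hi)) {
      mu2 <- mu_per_h / (1 - sat_frac)           # slope-matching rate
      e2 <- exp(mu2 * (te[hi] - t_star))
      od[hi] <- capacity * xstar * e2 / (capacity + xstar * (e2 - 1))
    }
  } else {
    e2 <- exp(mu_per_h * te / (1 - sat_frac))
    od <- capacity * od0 * e2 / (capacity + od0 * (e2 - 1))
  }
  od
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

lognorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # unit mean
}

#' Generate a synthetic microplate kinetic data set
#'
#' Emulates a 96-well-reader kinetic assay with a 5-min sampling cycle:
#' biomass follows a lag / exponential / logistic-deceleration batch-growth
#' curve (exponential at rate `mu_true` until half the carrying capacity,
#' then a slope-matched logistic approach to the plateau), each fluorescence
#' channel
#' accumulates as the running integral of (true per-cell synthesis rate x
#' OD) — so the derivative-based pipeline recovers the per-cell rate
#' exactly in the noise-free case — and every measurement gets an additive
#' background plus mean-one multiplicative lognormal noise. Blank wells
#' carry background only.
#'
#' What this emulates about real data: growth saturation, signal
#' accumulation, instrument background, multiplicative read noise. What it
#' does not: burden feedback of expression on growth, fluorophore
#' maturation delay, evaporation drift, cell-to-cell variability.
#'
#' @param truth A [plate_truth()].
#' @param duration_min Assay length in minutes (>= 360). Default 900.
#' @param sample_min Sampling interval, minutes. Default 5.
#' @param dir Optional output directory; if given, writes `plate.csv`,
#'   `wellmap.csv` and `truth.json` there.
#' @return Invisibly (visibly when `dir` is NULL) a list with `plate`
#'   (tidy data.frame), `wellmap` and `truth`.
#' @export
generate_plate <- function(truth, duration_min = 900, sample_min = 5,
                           dir = NULL) {
  stopifnot(inherits(truth, "plate_truth"))
  if (duration_min < 360)
    stop("assay must cover at least 6 h to resolve the growth phases",
         call. = FALSE)
  set.seed(truth$seed)
  t_min <- seq(0, duration_min, by = sample_min)
  nt <- length(t_min)
  channels <- c("OD600", names(truth$background_fluo))
  pieces <- vector("list", nrow(truth$wells) * length(channels))
  k <- 0L
  for (i in seq_len(nrow(truth$wells))) {
    w <- truth$wells[i, ]
    od_bio <- if (w$role == "blank_medium") rep(0, nt)
              else growth_od(t_min, w$mu_true, w$capacity, w$lag_min,
                             truth$od0)
    for (ch in channels) {
      bio <- if (ch == "OD600") od_bio
             else cumtrapz(t_min, w[[paste0("s_true_", ch)]] * od_bio)
      bg <- if (ch == "OD600") truth$background_od
            else truth$background_fluo[[ch]]
      val <- (bio + bg) * lognorm_mult(nt, truth$noise_cv)
      k <- k + 1L
      pieces[[k]] <- data.frame(time_min = t_min, well = w$well,
                                channel = ch, value = val,
                                stringsAsFactors = FALSE)
    }
  }
  plate <- do.call(rbind, pieces)
  wellmap <- truth$wells[c("well", "strain", "role", "inducer", "conc_nM")]
  out <- list(plate = plate, wellmap = wellmap, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(plate, file.path(dir, "plate.csv"), row.names = FALSE)
    utils::write.csv(wellmap, file.path(dir, "wellmap.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Ground truth for a synthetic transfer curve
#'
#' Describes how [generate_curve()] should produce a dose-response data
#' set: either from a Hill stage or from the full binding equilibrium
#' (sweeping one species total), with mean-one multiplicative lognormal
#' noise per replicate.
#'
#' @param generator `"hill"` or `"equilibrium"`.
#' @param stage A [hill_stage()] (hill generator).
#' @param params,totals,sweep_field [binding_params()], [species_totals()]
#'   and the swept field (equilibrium generator).
#' @param output Equilibrium output: `"D_over_Dtot"` or `"R"`.
#' @param noise_cv Lognormal noise CV, in `[0, 0.2]`. Default 0.1.
#' @param replicates Replicates per grid point. Default 3.
#' @param seed Integer RNG seed. Default 1.
#' @return An object of class `"curve_truth"`.
#' @export
curve_truth <- function(generator = c("hill", "equilibrium"), stage = NULL,
                        params = NULL, totals = NULL, sweep_field = "gtot",
                        output = "D_over_Dtot", noise_cv = 0.1,
                        replicates = 3, seed = 1L) {
  generator <- match.arg(generator)
  if (!is.finite(noise_cv) || noise_cv < 0 || noise_cv > 0.2)
    stop("noise_cv must be in [0, 0.2]", call. = FALSE)
  if (generator == "hill") {
    stopifnot(inherits(stage, "hill_stage"))
  } else {
    params <- as_binding_params(params)
    totals <- as_species_totals(totals)
  }
  structure(list(generator = generator, stage = stage, params = params,
                 totals = totals, sweep_field = sweep_field, output = output,
                 noise_cv = noise_cv, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "curve_truth")
}

#' Default inducer grids
#'
#' Log-spaced assay grids matching the characterization ranges of the lux
#' and lac induction systems — HSL 0.1--500 nM, IPTG 0.1--100 uM — plus a
#' zero point.
#'
#' @param inducer `"HSL"` or `"IPTG"`.
#' @param points Number of non-zero log-spaced points. Default 8.
#' @return Numeric grid including 0 (nM for HSL, uM for IPTG).
#' @export
default_inducer_grid <- function(inducer = c("HSL", "IPTG"), points = 8) {
  inducer <- match.arg(inducer)
  rng <- if (inducer == "HSL") c(0.1, 500) else c(0.1, 100)
  c(0, 10^seq(log10(rng[1]), log10(rng[2]), length.out = points))
}

#' Generate a noisy synthetic transfer curve
#'
#' Evaluates the chosen generator on the input grid and applies mean-one
#' multiplicative lognormal noise independently per replicate. Identical
#' seed and configuration give byte-identical output.
#'
#' @param truth A [curve_truth()].
#' @param grid Input grid; defaults to the HSL grid of
#'   [default_inducer_grid()] for the hill generator, or a 25-point
#'   log-grid over 0.01--1e4 nM for the equilibrium generator.
#' @param dir Optional output directory; writes `curve.csv` and
#'   `truth.json`.
#' @return A list with `curve` (data.frame `input_value`, `output_value`,
#'   `replicate`), `noiseless` (the generator evaluated on the grid) and
#'   `truth`.
#' @export
generate_curve <- function(truth, grid = NULL, dir = NULL) {
  stopifnot(inherits(truth, "curve_truth"))
  if (is.null(grid)) {
    grid <- if (truth$generator == "hill") default_inducer_grid("HSL")
            else 10^seq(-2, 4, length.out = 25)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  mu <- if (truth$generator == "hill") {
    hill_eval(truth$stage, grid)
  } else {
    sweep_transfer_curve(truth$params, truth$totals, truth$sweep_field,
                         grid, output = truth$output)$output_value
  }
  set.seed(truth$seed)
  reps <- lapply(seq_len(truth$replicates), function(r)
    data.frame(input_value = grid,
               output_value = mu * lognorm_mult(length(grid),
                                                truth$noise_cv),
               replicate = r))
  curve <- do.call(rbind, reps)
  out <- list(curve = curve, noiseless = mu, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(curve, file.path(dir, "curve.csv"), row.names = FALSE)
    tr <- unclass(truth)
    tr$stage <- if (!is.null(tr$stage)) unclass(tr$stage)
    tr$params <- if (!is.null(tr$params)) unclass(tr$params)
    tr$totals <- if (!is.null(tr$totals)) unclass(tr$totals)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
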