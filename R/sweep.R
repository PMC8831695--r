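#' Construct a transfer curve
#'
#' A transfer curve is the common currency between the equilibrium model,
#' Hill fits and synthetic data: an ordered input grid with aligned outputs.
#' Typical pairings are sgRNA level vs free-promoter fraction (`D_over_Dtot`),
#' inducer concentration vs reporter output (`R`), or inducer vs measured
#' per-cell synthesis rate (`S_cell`).
#'
#' @param input_values Strictly increasing numeric grid.
#' @param output_values Numeric outputs aligned with `input_values`.
#' @param input_name Label for the input axis (e.g. `"gtot"`, `"HSL"`).
#' @param output_name One of the conventional labels `"D_over_Dtot"`, `"R"`,
#'   `"S_cell"`, or any other descriptive string.
#' @param metadata Optional list snapshotting the generating parameters.
#' @return An object of class `"transfer_curve"`: a data.frame with columns
#'   `input_value`, `output_value`, plus attributes `input_name`,
#'   `output_name` and `metadata`.
#' @export
transfer_curve <- function(input_values, output_values,
                           input_name = "input", output_name = "output",
                           metadata = list()) {
  if (length(input_values) != length(output_values))
    stop("input and output grids must be the same length", call. = FALSE)
  if (length(input_values) >= 2 && any(diff(input_values) <= 0))
    stop("input grid must be strictly increasing", call. = FALSE)
  if (!all(is.finite(input_values)) || !all(is.finite(output_values)))
    stop("transfer curve values must be finite", call. = FALSE)
  if (identical(output_name, "D_over_Dtot") &&
      (any(output_values < -1e-12) || any(output_values > 1 + 1e-12)))
    stop("D_over_Dtot outputs must lie in [0, 1]", call. = FALSE)
  structure(data.frame(input_value = input_values,
                       output_value = output_values),
            input_name = input_name, output_name = output_name,
            metadata = metadata,
            class = c("transfer_curve", "data.frame"))
}

#' Sweep the binding equilibrium along one species total
#'
#' Solves the full equilibrium at every point of a grid over one of the
#' species totals, holding the other two fixed, and returns the repression
#' transfer curve. This reproduces the simulated repression-curve panels:
#' free-promoter fraction `D/Dtot` against sgRNA (or dCas9, or DNA) level.
#' `D/Dtot` is monotone non-increasing when sweeping `gtot` or `Ctot` and the
#' curve's half-repression point shifts to higher sgRNA levels as the DNA
#' copy number grows.
#'
#' @inheritParams solve_equilibrium
#' @param sweep_field Which total to sweep: `"gtot"`, `"Ctot"` or `"Dtot"`.
#' @param grid Strictly increasing numeric grid (>= 2 points) for the swept
#'   total, nM.
#' @param output `"D_over_Dtot"` (default) or `"R"` (reporter units,
#'   `theta * D`).
#' @return A [transfer_curve()] whose `metadata` holds the fixed totals,
#'   binding parameters and the full per-point equilibrium table
#'   (`metadata$states`: columns `input_value`, `C`, `g`, `D`, `Cg`, `CgD`,
#'   `D_over_Dtot`, `R`).
#' @examples
#' tc <- sweep_transfer_curve(binding_params(),
#'                            species_totals(Ctot = 100, gtot = 0, Dtot = 10),
#'                            sweep_field = "gtot",
#'                            grid = 10^seq(-2, 4, length.out = 25))
#' head(as.data.frame(tc))
#' @export
sweep_transfer_curve <- function(params, totals, sweep_field, grid,
                                 output = c("D_over_Dtot", "R"),
                                 tol = 1e-9, max_iter = 1e5) {
  params <- as_binding_params(params)
  totals <- as_species_totals(totals)
  output <- match.arg(output)
  sweep_field <- match.arg(sweep_field, c("gtot", "Ctot", "Dtot"))
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 2 points", call. = FALSE)

  states <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    tt <- unclass(totals)
    tt[[sweep_field]] <- grid[i]
    tt <- species_totals(tt$Ctot, tt$gtot, tt$Dtot)
    st <- tryCatch(solve_equilibrium(params, tt,
                                     tol = tol, max_iter = max_iter),
                   error = function(e)
                     stop(sprintf("equilibrium solve failed at %s = %g: %s",
                                  sweep_field, grid[i], conditionMessage(e)),
                          call. = FALSE))
    states[[i]] <- cbind(input_value = grid[i], as.data.frame(st))
  }
  states <- do.call(rbind, states)
  out <- if (output == "D_over_Dtot") states$D_over_Dtot else states$R
  transfer_curve(grid, out, input_name = sweep_field, output_name = output,
                 metadata = list(params = params, fixed = totals,
                                 sweep_field = sweep_field, states = states))
}

#' Locate the switch point of a repression curve
#'
#' The switch point is the input level at which a repression (or induction)
#' curve crosses a given fraction of its output range — by default 0.5,
#' i.e. the half-repression point `min(y) + 0.5 * (max(y) - min(y))`.
#' Defining the level relative to the curve's own range keeps the switch
#' point meaningful for incompletely repressed curves whose floor never
#' approaches zero. The crossing is located by log-linear interpolation
#' between the two bracketing grid points (linear in the output, linear in
#' log-input), matching the log-spaced grids these curves are computed on;
#' it falls back to linear interpolation in the input when a bracketing
#' input is not positive.
#'
#' @param curve A [transfer_curve()] (e.g. `D_over_Dtot` against sgRNA).
#' @param level Fraction of the output range to cross, usually in (0, 1).
#'   Default 0.5.
#' @return The interpolated input value, or `NA_real_` (with attribute
#'   `reason = "no switch point in range"`) when the curve never crosses
#'   the level within the grid.
#' @examples
#' tc <- transfer_curve(c(1, 10, 100), c(1, 0.5, 0))
#' switch_point(tc)          # exactly 10
#' switch_point(tc, 1.5)     # NA: level above the curve's range
#' @export
switch_point <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "transfer_curve"))
  if (!is.finite(level)) stop("level must be finite", call. = FALSE)
  x <- curve$input_value
  y <- curve$output_value
  level <- min(y) + level * (max(y) - min(y))
  no_cross <- structure(NA_real_, reason = "no switch point in range")
  hit <- which(y == level)
  if (length(hit) > 0) return(x[hit[1]])
  for (i in seq_len(length(x) - 1)) {
    if ((y[i] - level) * (y[i + 1] - level) < 0) {
      if (x[i] > 0 && x[i + 1] > 0) {
        lx <- log10(x[i]) + (level - y[i]) *
          (log10(x[i + 1]) - log10(x[i])) / (y[i + 1] - y[i])
        return(10^lx)
      }
      return(x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i]))
    }
  }
  no_cross
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat(sprintf("Transfer curve: %s -> %s (%d points, input range [%g, %g])\n",
              attr(x, "input_name"), attr(x, "output_name"), nrow(x),
              min(x$input_value), max(x$input_value)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Plot a transfer curve
#'
#' Log-x line plot of the curve, the usual presentation for repression and
#' induction transfer functions.
#'
#' @param x A [transfer_curve()].
#' @param add Logical; add to an existing plot.
#' @param ... Further arguments passed to [graphics::lines()] /
#'   [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.transfer_curve <- function(x, add = FALSE, ...) {
  xv <- x$input_value
  logx <- if (all(xv > 0)) "x" else ""
  if (add) {
    graphics::lines(xv, x$output_value, ...)
  } else {
    graphics::plot(xv, x$output_value, type = "l", log = logx,
                   xlab = attr(x, "input_name"),
                   ylab = attr(x, "output_name"), ...)
  }
  invisible(x)
}

#' Panel grid of repression curves over dCas9 and DNA levels
#'
#' Draws a matrix of sgRNA-sweep repression curves, one panel per
#' (Dtot row, Ctot column) combination, the standard way to visualize how
#' DNA copy number shifts the switch point and how limited sgRNA leaves
#' repression incomplete.
#'
#' @param params A [binding_params()].
#' @param Ctot_values dCas9 totals, one column per value (nM).
#' @param Dtot_values DNA totals, one row per value (nM).
#' @param gtot_grid Strictly increasing sgRNA grid (nM).
#' @return Invisibly, a list of [transfer_curve()]s in row-major panel order.
#' @export
plot_repression_panels <- function(params = binding_params(),
                                   Ctot_values = c(1, 10, 100, 1000),
                                   Dtot_values = c(1, 10, 100),
                                   gtot_grid = 10^seq(-2, 4, length.out = 40)) {
  oldpar <- graphics::par(mfrow = c(length(Dtot_values), length(Ctot_values)),
                          mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(oldpar))
  curves <- list()
  for (Dtot in Dtot_values) {
    for (Ctot in Ctot_values) {
      tc <- sweep_transfer_curve(params,
                                 species_totals(Ctot = Ctot, gtot = 0, Dtot = Dtot),
                                 sweep_field = "gtot", grid = gtot_grid)
      plot(tc, ylim = c(0, 1),
           main = sprintf("Ctot=%g, Dtot=%g nM", Ctot, Dtot))
      curves[[length(curves) + 1L]] <- tc
    }
  }
  invisible(curves)
}
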