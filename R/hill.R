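#' Construct a Hill stage
#'
#' A single regulatory stage of a genetic circuit, modelled with a
#' four-parameter Hill equation. Activation:
#' `y = basal + range * x^n / (Km^n + x^n)`; repression:
#' `y = basal + range / (1 + (x/Km)^n)`. `basal` is the output floor,
#' `range` the output span, `Km` the half-effect input and `n` the Hill
#' coefficient (steepness).
#'
#' @param kind `"activation"` or `"repression"`.
#' @param basal Output floor, AU (>= 0).
#' @param range Output span, AU (>= 0).
#' @param Km Half-effect input, input units (> 0).
#' @param n Hill coefficient, dimensionless (> 0).
#' @return An object of class `"hill_stage"`.
#' @examples
#' st <- hill_stage("repression", basal = 10, range = 100, Km = 5, n = 2)
#' hill_eval(st, c(0, 5, 1e6))   # basal+range, basal+range/2, ~basal
#' @export
hill_stage <- function(kind = c("activation", "repression"),
                       basal, range, Km, n) {
  kind <- match.arg(kind)
  for (v in list(basal = basal, range = range, Km = Km, n = n)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("Hill parameters must be finite scalars", call. = FALSE)
  }
  if (basal < 0 || range < 0) stop("basal and range must be >= 0", call. = FALSE)
  if (Km <= 0 || n <= 0) stop("Km and n must be > 0", call. = FALSE)
  structure(list(kind = kind, basal = basal, range = range, Km = Km, n = n),
            class = "hill_stage")
}

#' Evaluate a Hill stage
#'
#' Vectorized over `x`. Both branches are computed through the ratio form
#' `1 / (1 + (x/Km)^±n)`, which is numerically safe at `x = 0` and for large
#' `x^n`.
#'
#' @param stage A [hill_stage()].
#' @param x Input values (>= 0).
#' @return Output values, AU.
#' @export
hill_eval <- function(stage, x) {
  stopifnot(inherits(stage, "hill_stage"))
  if (any(x < 0)) stop("Hill input must be >= 0", call. = FALSE)
  frac <- if (stage$kind == "repression") {
    1 / (1 + (x / stage$Km)^stage$n)
  } else {
    ifelse(x == 0, 0, 1 / (1 + (stage$Km / x)^stage$n))
  }
  stage$basal + stage$range * frac
}

#' @export
print.hill_stage <- function(x, ...) {
  cat(sprintf("Hill %s stage: basal = %g, range = %g, Km = %g, n = %g\n",
              x$kind, x$basal, x$range, x$Km, x$n))
  invisible(x)
}

# deterministic multi-start grid: Km spans the positive input range,
# n cycles through typical cooperativities
hill_starts <- function(x, y, n_starts = 8) {
  xp <- x[x > 0]
  if (length(xp) == 0) xp <- 1
  km0 <- exp(seq(log(min(xp)), log(max(xp)), length.out = n_starts))
  n0 <- rep(c(1, 2, 0.5, 4), length.out = n_starts)
  basal0 <- max(min(y), 1e-6 * max(y))
  range0 <- max(max(y) - min(y), 1e-6 * max(y))
  lapply(seq_len(n_starts), function(i)
    c(basal = basal0, range = range0, Km = km0[i], n = n0[i]))
}

#' Fit a Hill stage to a transfer curve
#'
#' Least-squares fit of a four-parameter Hill stage on the log scale:
#' residuals are `log(y + eps) - log(yhat + eps)` with
#' `eps = 1e-6 * max(y)`, since circuit outputs span decades and a linear
#' scale would let the ON state dominate. Parameters are optimized on the
#' log scale (so positivity is structural) with the Levenberg-Marquardt
#' algorithm, restarted from 8 deterministic initial guesses whose `Km`
#' values span the observed input decades; the best residual wins, with ties
#' broken toward the smaller Hill coefficient. Replicate measurements are
#' fitted as independent points.
#'
#' @param data A [transfer_curve()], or a data.frame with columns
#'   `input_value`, `output_value` and optionally `replicate`.
#' @param kind `"activation"` or `"repression"`.
#' @param bounds Optional list with numeric vectors `lower` and/or `upper`,
#'   named subsets of `c("basal", "range", "Km", "n")`, on the natural scale.
#' @param seed Unused by the fit itself (the multi-start grid is
#'   deterministic); accepted so callers can thread one value through data
#'   generation and fitting.
#' @return An object of class `"hill_fit"`: `estimates` (basal, range, Km,
#'   n), `kind`, `stage` (a [hill_stage()]), `residual_norm` (sum of squared
#'   log-scale residuals), `n_points`, `converged`, and the fitting `data`.
#'   Supports `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()` and `plot()`.
#' @examples
#' x <- 10^seq(-1, 2, length.out = 8)
#' y <- hill_eval(hill_stage("repression", 10, 100, 5, 2), x)
#' fit <- fit_stage(data.frame(input_value = x, output_value = y), "repression")
#' coef(fit)   # recovers basal = 10, range = 100, Km = 5, n = 2
#' @export
fit_stage <- function(data, kind = c("activation", "repression"),
                      bounds = NULL, seed = NULL) {
  kind <- match.arg(kind)
  df <- as.data.frame(data)
  if (!all(c("input_value", "output_value") %in% names(df)))
    stop("data must have columns input_value and output_value", call. = FALSE)
  x <- df$input_value
  y <- df$output_value
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct input values to fit 4 parameters", call. = FALSE)
  if (all(y == 0)) stop("all outputs are zero; nothing to fit", call. = FALSE)
  if (any(y < 0)) stop("outputs must be >= 0", call. = FALSE)

  eps <- 1e-6 * max(y)
  obj <- function(logp) {
    p <- exp(logp)
    st <- list(kind = kind, basal = p[1], range = p[2], Km = p[3], n = p[4])
    class(st) <- "hill_stage"
    log(hill_eval(st, x) + eps) - log(y + eps)
  }
  lower <- c(basal = -Inf, range = -Inf, Km = -Inf, n = log(1e-3))
  upper <- c(basal = Inf, range = Inf, Km = Inf, n = log(50))
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower))
      lower[names(bounds$lower)] <- log(pmax(bounds$lower, 1e-300))
    if (!is.null(bounds$upper))
      upper[names(bounds$upper)] <- log(bounds$upper)
  }
  # log-scale parameters cannot be -Inf in nls.lm; use a deep finite floor
  lower[!is.finite(lower)] <- -60
  upper[!is.finite(upper)] <- 60

  best <- NULL
  for (start in hill_starts(x, y)) {
    p0 <- pmin(pmax(log(start), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = obj, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sum(fit$fvec^2)
    nval <- exp(fit$par[4])
    if (is.null(best) || rn < best$rn * (1 - 1e-8) ||
        (abs(rn - best$rn) <= 1e-8 * max(best$rn, 1e-300) &&
         nval < best$nval)) {
      best <- list(fit = fit, rn = rn, nval = nval)
    }
  }
  if (is.null(best)) stop("all Hill fits failed", call. = FALSE)
  p <- exp(best$fit$par)
  names(p) <- c("basal", "range", "Km", "n")
  stage <- hill_stage(kind, basal = p[["basal"]], range = p[["range"]],
                      Km = p[["Km"]], n = p[["n"]])
  structure(list(estimates = p, kind = kind, stage = stage,
                 residual_norm = best$rn,
                 n_points = length(y),
                 converged = best$fit$info %in% 1:4,
                 data = df, eps = eps),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Hill %s fit (%d points)\n", x$kind, x$n_points))
  print(signif(x$estimates, digits))
  cat(sprintf("log-scale residual norm: %.4g; converged: %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$estimates

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$input_value
       else if (is.data.frame(newdata)) newdata$input_value
       else newdata
  hill_eval(object$stage, x)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object,
                               type = c("log", "response"), ...) {
  type <- match.arg(type)
  yhat <- fitted(object)
  y <- object$data$output_value
  if (type == "log") log(y + object$eps) - log(yhat + object$eps)
  else y - yhat
}

#' @export
summary.hill_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(estimates = object$estimates, kind = object$kind,
                 residual_norm = object$residual_norm,
                 rmse_log = sqrt(mean(r^2)),
                 n_points = object$n_points,
                 converged = object$converged),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat(sprintf("Hill %s fit: %d points, log-scale RMSE %.4g%s\n",
              x$kind, x$n_points, x$rmse_log,
              if (x$converged) "" else " (NOT converged)"))
  print(signif(x$estimates, 5))
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, n_grid = 200, ...) {
  df <- x$data
  xp <- df$input_value
  pos <- xp[xp > 0]
  grid <- if (length(pos) >= 2)
    10^seq(log10(min(pos)), log10(max(pos)), length.out = n_grid)
  else seq(min(xp), max(xp), length.out = n_grid)
  graphics::plot(pmax(xp, min(grid)), df$output_value, log = "x",
                 xlab = "input", ylab = "output", ...)
  graphics::lines(grid, hill_eval(x$stage, grid), col = "firebrick")
  invisible(x)
}

#' Simulate noisy observations from a fitted Hill stage
#'
#' Draws multiplicative lognormal noise around the fitted curve at the
#' fitted input values, one data.frame per simulation.
#'
#' @param object A [fit_stage()] result.
#' @param nsim Number of simulated data sets.
#' @param seed Optional RNG seed.
#' @param cv Coefficient of variation of the lognormal noise. Default 0.1.
#' @param ... Ignored.
#' @return A list of `nsim` data.frames with columns `input_value`,
#'   `output_value`.
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, cv = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  x <- object$data$input_value
  mu <- hill_eval(object$stage, x)
  sdlog <- sqrt(log(1 + cv^2))
  lapply(seq_len(nsim), function(i)
    data.frame(input_value = x,
               output_value = mu * stats::rlnorm(length(x), -sdlog^2 / 2,
                                                 sdlog)))
}
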