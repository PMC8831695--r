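#' Steady-state dCas9:sgRNA:promoter binding equilibrium
#'
#' Solves the mass-action equilibrium of the two-step repression pathway
#'
#' \deqn{C + g \rightleftharpoons C{:}g, \qquad C{:}g + D \rightleftharpoons C{:}g{:}D}
#'
#' where dCas9 (`C`) loads an sgRNA (`g`) to form the repressor complex
#' (`C:g`), which occupies the target promoter (`D`) to form the repressed
#' promoter (`C:g:D`). Binding is assumed much faster than expression and
#' dilution, so only the dissociation constants `K1` and `K2` and the
#' conserved totals enter. The free concentrations satisfy the implicit
#' system
#'
#' \deqn{C = \frac{C_{tot}}{1 + g/K_1 + gD/(K_1 K_2)}, \quad
#'       g = \frac{g_{tot}}{1 + C/K_1 + CD/(K_1 K_2)}, \quad
#'       D = \frac{D_{tot}}{1 + gC/(K_1 K_2)}}
#'
#' which is solved by sequential fixed-point iteration (update order C, g, D,
#' each using the latest values) starting from the all-free state. If the
#' undamped iteration oscillates, it is restarted with a damping factor of
#' 0.5; if it still fails to converge within `max_iter`, the nested-bisection
#' solver [solve_equilibrium_oracle()] is used as a fallback and the result is
#' flagged with `converged = FALSE`. The reporter output is `R = theta * D`,
#' assuming no residual transcription from the repressed promoter.
#'
#' @param params A [binding_params()] object (or a list with `K1`, `K2`,
#'   `theta`).
#' @param totals A [species_totals()] object (or a list with `Ctot`, `gtot`,
#'   `Dtot`), nM.
#' @param tol Relative convergence tolerance on the maximum change across
#'   (C, g, D) per iteration. Default `1e-9`.
#' @param max_iter Maximum number of fixed-point iterations. Default `1e5`.
#' @return An object of class `"crispri_eq"`: a list with free concentrations
#'   `C`, `g`, `D` (nM), complexes `Cg`, `CgD` (nM), reporter output `R`
#'   (AU), `converged`, `iterations`, `damped`, `method`, and the input
#'   `params`/`totals`.
#' @seealso [solve_equilibrium_oracle()], [explicit_output()],
#'   [sweep_transfer_curve()]
#' @examples
#' eq <- solve_equilibrium(binding_params(), species_totals(100, 1000, 10))
#' eq$D / 10   # fraction of promoter left free
#' @export
solve_equilibrium <- function(params = binding_params(), totals,
                              tol = 1e-9, max_iter = 1e5) {
  params <- as_binding_params(params)
  totals <- as_species_totals(totals)
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)

  # degenerate cases: one binding partner absent, no iteration needed
  if (totals$gtot == 0 || totals$Ctot == 0) {
    return(new_eq_state(C = totals$Ctot, g = totals$gtot, D = totals$Dtot,
                        Cg = 0, CgD = 0, params = params, totals = totals,
                        converged = TRUE, iterations = 0L,
                        method = "analytic"))
  }

  st <- fixed_point_iterate(params, totals, tol, max_iter, damping = 0)
  if (!st$converged && st$oscillated) {
    st <- fixed_point_iterate(params, totals, tol, max_iter, damping = 0.5)
    st$damped <- TRUE
  }
  if (!st$converged) {
    warning("fixed-point iteration did not converge; falling back to ",
            "nested-bisection solver", call. = FALSE)
    out <- solve_equilibrium_oracle(params, totals)
    out$converged <- FALSE
    out$iterations <- st$iterations
    out$method <- "bisection_fallback"
    return(out)
  }
  new_eq_state(C = st$C, g = st$g, D = st$D,
               Cg = st$C * st$g / params$K1,
               CgD = st$C * st$g * st$D / (params$K1 * params$K2),
               params = params, totals = totals, converged = TRUE,
               iterations = st$iterations, damped = isTRUE(st$damped),
               method = "fixed_point")
}

fixed_point_iterate <- function(params, totals, tol, max_iter, damping) {
  K1 <- params$K1; K2 <- params$K2
  Ctot <- totals$Ctot; gtot <- totals$gtot; Dtot <- totals$Dtot
  C <- Ctot; g <- gtot; D <- Dtot
  delta_prev <- Inf
  growing <- 0L
  oscillated <- FALSE
  for (it in seq_len(max_iter)) {
    C_new <- Ctot / (1 + g / K1 + g * D / (K1 * K2))
    if (damping > 0) C_new <- damping * C + (1 - damping) * C_new
    g_new <- gtot / (1 + C_new / K1 + C_new * D / (K1 * K2))
    if (damping > 0) g_new <- damping * g + (1 - damping) * g_new
    D_new <- Dtot / (1 + g_new * C_new / (K1 * K2))
    if (damping > 0) D_new <- damping * D + (1 - damping) * D_new
    delta <- max(abs(C_new - C) / max(C_new, 1e-300),
                 abs(g_new - g) / max(g_new, 1e-300),
                 abs(D_new - D) / max(D_new, 1e-300))
    C <- C_new; g <- g_new; D <- D_new
    if (delta < tol) {
      return(list(C = C, g = g, D = D, converged = TRUE, iterations = it,
                  oscillated = oscillated, damped = damping > 0))
    }
    # oscillation heuristic: relative step repeatedly fails to contract
    if (delta > delta_prev) {
      growing <- growing + 1L
      if (growing >= 3L && damping == 0) {
        oscillated <- TRUE
        return(list(C = C, g = g, D = D, converged = FALSE, iterations = it,
                    oscillated = TRUE, damped = FALSE))
      }
    }
    delta_prev <- delta
  }
  list(C = C, g = g, D = D, converged = FALSE, iterations = as.integer(max_iter),
       oscillated = oscillated, damped = damping > 0)
}

new_eq_state <- function(C, g, D, Cg, CgD, params, totals, converged,
                         iterations, damped = FALSE, method) {
  structure(list(C = C, g = g, D = D, Cg = Cg, CgD = CgD,
                 R = params$theta * D,
                 converged = converged, iterations = as.integer(iterations),
                 damped = damped, method = method,
                 params = params, totals = totals),
            class = "crispri_eq")
}

#' Independent nested-bisection equilibrium solver
#'
#' Solves the same binding equilibrium as [solve_equilibrium()] through an
#' independent route, for verification. With `x = [C:g]` and `y = [C:g:D]`
#' the system reduces to two polynomial equations
#'
#' \deqn{K_1 x = (C_{tot}-x-y)(g_{tot}-x-y), \qquad K_2 y = x (D_{tot}-y)}
#'
#' For fixed `y` the first equation is a quadratic in `x` whose physical
#' (smaller) root has the numerically stable closed form
#' `x = 2ab / (s + sqrt(s^2 - 4ab))` with `a = Ctot - y`, `b = gtot - y`,
#' `s = a + b + K1`. The residual `K2*y - x(y)*(Dtot - y)` is strictly
#' increasing in `y`, so the outer equation is solved by bisection on
#' `y` in `[0, min(Ctot, gtot, Dtot)]` to near machine precision.
#'
#' @inheritParams solve_equilibrium
#' @return An object of class `"crispri_eq"` (see [solve_equilibrium()]),
#'   with `method = "bisection"`.
#' @examples
#' a <- solve_equilibrium(binding_params(), species_totals(1000, 1000, 10))
#' b <- solve_equilibrium_oracle(binding_params(), species_totals(1000, 1000, 10))
#' abs(a$D - b$D) / b$D   # should be < 1e-6
#' @export
solve_equilibrium_oracle <- function(params = binding_params(), totals) {
  params <- as_binding_params(params)
  totals <- as_species_totals(totals)
  K1 <- params$K1; K2 <- params$K2
  Ctot <- totals$Ctot; gtot <- totals$gtot; Dtot <- totals$Dtot

  if (gtot == 0 || Ctot == 0) {
    return(new_eq_state(C = Ctot, g = gtot, D = Dtot, Cg = 0, CgD = 0,
                        params = params, totals = totals, converged = TRUE,
                        iterations = 0L, method = "analytic"))
  }

  # physical root of K1*x = (Ctot - x - y)(gtot - x - y) at fixed y
  x_of_y <- function(y) {
    a <- Ctot - y; b <- gtot - y
    if (a <= 0 || b <= 0) return(0)
    s <- a + b + K1
    2 * a * b / (s + sqrt(s * s - 4 * a * b))
  }
  resid <- function(y) K2 * y - x_of_y(y) * (Dtot - y)

  ymax <- min(Ctot, gtot, Dtot)
  if (ymax == 0 || resid(ymax) <= 0) {
    y <- ymax
  } else {
    lo <- 0; hi <- ymax
    for (i in 1:300) {
      mid <- (lo + hi) / 2
      if (resid(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-16 * max(hi, 1e-300)) break
    }
    y <- (lo + hi) / 2
  }
  x <- x_of_y(y)
  new_eq_state(C = Ctot - x - y, g = gtot - x - y, D = Dtot - y,
               Cg = x, CgD = y, params = params, totals = totals,
               converged = TRUE, iterations = 0L, method = "bisection")
}

#' Explicit reporter output under the g >> C >> D regime
#'
#' Closed-form Michaelis-Menten-style approximation of the reporter output,
#' valid when sgRNA is in large excess over dCas9 and dCas9 over promoter
#' DNA:
#'
#' \deqn{R = \frac{\theta D_{tot}}{1 + \dfrac{C_{tot}/K_2}{1 + \dfrac{1}{g_{tot}/K_1}}}}
#'
#' The nested fraction is evaluated as
#' `theta*Dtot / (1 + (Ctot/K2) * gtot/(gtot + K1))`, which handles the
#' `gtot = 0` limit (no repression, `R = theta*Dtot`) without a 0/0. Outside
#' the stated regime this expression can deviate badly from the full
#' equilibrium solution; use [solve_equilibrium()] there.
#'
#' @inheritParams solve_equilibrium
#' @return Reporter output `R` in arbitrary units (a scalar).
#' @examples
#' p <- binding_params(theta = 1)
#' explicit_output(p, species_totals(100, 1e4, 0.1))
#' solve_equilibrium(p, species_totals(100, 1e4, 0.1))$R  # close to the above
#' @export
explicit_output <- function(params = binding_params(), totals) {
  params <- as_binding_params(params)
  totals <- as_species_totals(totals)
  params$theta * totals$Dtot /
    (1 + (totals$Ctot / params$K2) * totals$gtot / (totals$gtot + params$K1))
}

#' @export
print.crispri_eq <- function(x, digits = 6, ...) {
  cat("CRISPRi binding equilibrium (", x$method, ")\n", sep = "")
  cat(sprintf("  totals (nM):  Ctot = %g, gtot = %g, Dtot = %g\n",
              x$totals$Ctot, x$totals$gtot, x$totals$Dtot))
  cat(sprintf("  free (nM):    C = %.*g, g = %.*g, D = %.*g\n",
              digits, x$C, digits, x$g, digits, x$D))
  cat(sprintf("  bound (nM):   C:g = %.*g, C:g:D = %.*g\n",
              digits, x$Cg, digits, x$CgD))
  if (x$totals$Dtot > 0)
    cat(sprintf("  free promoter fraction D/Dtot = %.*g\n",
                digits, x$D / x$totals$Dtot))
  cat(sprintf("  reporter output R = %.*g AU  (theta = %g)\n",
              digits, x$R, x$params$theta))
  if (!x$converged)
    cat("  note: fixed-point iteration did not converge; bisection fallback used\n")
  invisible(x)
}

#' @export
as.data.frame.crispri_eq <- function(x, ...) {
  data.frame(C = x$C, g = x$g, D = x$D, Cg = x$Cg, CgD = x$CgD,
             D_over_Dtot = if (x$totals$Dtot > 0) x$D / x$totals$Dtot else NA_real_,
             R = x$R, converged = x$converged, iterations = x$iterations)
}
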