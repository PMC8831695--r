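#' Compose Hill stages into a circuit model
#'
#' Two topologies are supported. A **cascade** is an ordered chain of stages:
#' each stage's output is the next stage's input (e.g. an inducible device
#' feeding one or two NOT gates). A **NOR** gate is a pair of repression
#' stages acting in parallel on one promoter; because the two repressors
#' have mutually exclusive binding, the output is modelled multiplicatively:
#' `out = basal + range * f1(in1) * f2(in2)` with
#' `fi = 1 / (1 + (x/Km_i)^(n_i))`, where `basal` and `range` are shared by
#' the promoter (taken as the mean of the stages' own values unless given).
#'
#' A cascade stage may be replaced by a mechanistic CRISPRi inverter: supply
#' `crispri_stage` as a list with an `activation` [hill_stage()] mapping
#' inducer to total sgRNA (nM), plus `params` ([binding_params()]) and
#' `totals` ([species_totals()]; its `gtot` is overwritten per input). The
#' stage output is then the equilibrium reporter `R = theta * D` from
#' [solve_equilibrium()] rather than a phenomenological Hill repression.
#'
#' @param stages List of [hill_stage()] objects (cascade order, or the two
#'   parallel repression stages of a NOR gate).
#' @param topology `"cascade"` or `"nor"`.
#' @param crispri_stage Optional CRISPRi inverter description (see Details);
#'   cascade topology only. It replaces the *first* stage position.
#' @param basal,range Shared promoter floor and span for NOR topology;
#'   default to the means of the stages' values.
#' @return An object of class `"circuit_model"`.
#' @seealso [cascade_predict()], [nor_predict()], [crispri_not_predict()]
#' @export
circuit_model <- function(stages = list(), topology = c("cascade", "nor"),
                          crispri_stage = NULL, basal = NULL, range = NULL) {
  topology <- match.arg(topology)
  if (!all(vapply(stages, inherits, logical(1), "hill_stage")))
    stop("stages must be hill_stage objects", call. = FALSE)
  if (topology == "nor") {
    if (length(stages) != 2)
      stop("a NOR gate has exactly 2 parallel repression stages",
           call. = FALSE)
    if (!all(vapply(stages, `[[`, character(1), "kind") == "repression"))
      stop("NOR stages must both be repression stages", call. = FALSE)
    if (is.null(basal)) basal <- mean(vapply(stages, `[[`, numeric(1), "basal"))
    if (is.null(range)) range <- mean(vapply(stages, `[[`, numeric(1), "range"))
  } else {
    if (length(stages) == 0 && is.null(crispri_stage))
      stop("a cascade needs at least one stage", call. = FALSE)
  }
  if (!is.null(crispri_stage)) {
    if (topology != "cascade")
      stop("crispri_stage is only supported in cascade topology",
           call. = FALSE)
    stopifnot(inherits(crispri_stage$activation, "hill_stage"))
    crispri_stage$params <- as_binding_params(crispri_stage$params)
    crispri_stage$totals <- as_species_totals(crispri_stage$totals)
  }
  structure(list(stages = stages, topology = topology,
                 crispri_stage = crispri_stage,
                 basal = basal, range = range),
            class = "circuit_model")
}

#' Predict the output of a cascade
#'
#' Feeds the inducer through the stage chain: each stage's output becomes
#' the next stage's input. If the model carries a `crispri_stage`, that
#' mechanistic inverter is evaluated first (inducer -> sgRNA -> equilibrium
#' reporter) and its output feeds the remaining Hill stages. Two chained
#' repressions give a monotone increasing overall response (an inverter of
#' an inverter).
#'
#' @param model A cascade [circuit_model()].
#' @param inducer Input value(s), inducer units of the first stage.
#' @return Output AU, vectorized over `inducer`.
#' @export
cascade_predict <- function(model, inducer) {
  stopifnot(inherits(model, "circuit_model"))
  if (model$topology != "cascade")
    stop("cascade_predict needs a cascade model", call. = FALSE)
  if (length(model$stages) == 0 && is.null(model$crispri_stage))
    stop("cascade model has no stages", call. = FALSE)
  x <- inducer
  if (!is.null(model$crispri_stage)) x <- crispri_not_predict(model, x)
  for (st in model$stages) x <- hill_eval(st, x)
  x
}

#' Predict the output of a CRISPRi NOT gate
#'
#' Mechanistic inverter: the inducer drives sgRNA expression through an
#' activation Hill stage (`inducer -> gtot`, nM), and the sgRNA represses
#' the target promoter through the full binding equilibrium. The returned
#' output is the equilibrium reporter `R = theta * D`.
#'
#' @param model A [circuit_model()] carrying a `crispri_stage`.
#' @param inducer Input value(s).
#' @return Reporter output AU, vectorized over `inducer`.
#' @export
crispri_not_predict <- function(model, inducer) {
  stopifnot(inherits(model, "circuit_model"))
  cs <- model$crispri_stage
  if (is.null(cs))
    stop("model has no crispri_stage", call. = FALSE)
  gtot <- hill_eval(cs$activation, inducer)
  vapply(gtot, function(g) {
    tt <- species_totals(Ctot = cs$totals$Ctot, gtot = g,
                         Dtot = cs$totals$Dtot)
    solve_equilibrium(cs$params, tt)$R
  }, numeric(1))
}

#' Predict the output of a hybrid NOR gate
#'
#' `out = basal + range * f1(in1) * f2(in2)` with the normalized repression
#' terms `fi = 1 / (1 + (x/Km_i)^(n_i))`: the output is high only when both
#' inputs are low.
#'
#' @param model A NOR [circuit_model()].
#' @param in1,in2 The two input values (vectorized, recycled together).
#' @return Output AU.
#' @export
nor_predict <- function(model, in1, in2) {
  stopifnot(inherits(model, "circuit_model"))
  if (model$topology != "nor")
    stop("nor_predict needs a NOR model", call. = FALSE)
  s1 <- model$stages[[1]]; s2 <- model$stages[[2]]
  f1 <- 1 / (1 + (in1 / s1$Km)^s1$n)
  f2 <- 1 / (1 + (in2 / s2$Km)^s2$n)
  model$basal + model$range * f1 * f2
}

#' Fit a circuit stage-by-stage
#'
#' Fits each stage independently from its own transfer-curve data set
#' (component-wise characterization: each stage is measured in isolation
#' with its own input/output proxy) and composes the fitted stages into a
#' [circuit_model()]. No joint end-to-end refit is performed.
#'
#' @param stage_datasets List of per-stage data sets (each a
#'   [transfer_curve()] or data.frame with `input_value`, `output_value`).
#' @param topology Either `"nor"` (requires exactly 2 repression data sets)
#'   or a character vector of stage kinds in cascade order, e.g.
#'   `c("activation", "repression", "repression")`.
#' @param bounds,seed Passed to [fit_stage()].
#' @return A [circuit_model()] whose `fits` attribute holds the individual
#'   [fit_stage()] results.
#' @export
fit_cascade <- function(stage_datasets, topology, bounds = NULL, seed = NULL) {
  if (identical(topology, "nor")) {
    kinds <- c("repression", "repression")
    topo <- "nor"
  } else {
    kinds <- match.arg(topology, c("activation", "repression"),
                       several.ok = TRUE)
    topo <- "cascade"
  }
  if (length(stage_datasets) != length(kinds))
    stop(sprintf("topology expects %d stage data sets, got %d",
                 length(kinds), length(stage_datasets)), call. = FALSE)
  fits <- mapply(function(d, k) fit_stage(d, k, bounds = bounds, seed = seed),
                 stage_datasets, kinds, SIMPLIFY = FALSE)
  model <- circuit_model(stages = lapply(fits, `[[`, "stage"),
                         topology = topo)
  attr(model, "fits") <- fits
  model
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("Circuit model: %s topology\n", x$topology))
  if (!is.null(x$crispri_stage)) {
    cat("  [mechanistic CRISPRi inverter stage]\n   ")
    print(x$crispri_stage$activation)
    cat("   ")
    print(x$crispri_stage$params)
  }
  for (st in x$stages) { cat("  "); print(st) }
  if (x$topology == "nor")
    cat(sprintf("  shared promoter: basal = %g, range = %g\n",
                x$basal, x$range))
  invisible(x)
}

#' @export
predict.circuit_model <- function(object, inducer, in2 = NULL, ...) {
  if (object$topology == "nor") {
    if (is.null(in2)) stop("NOR prediction needs two inputs", call. = FALSE)
    nor_predict(object, inducer, in2)
  } else {
    cascade_predict(object, inducer)
  }
}
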