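#' Write a circuit model to JSON
#'
#' Serializes a [circuit_model()] (topology, stages, shared promoter
#' parameters, optional CRISPRi stage) with an explicit `schema_version`
#' field so files remain readable across package versions.
#'
#' @param model A [circuit_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_circuit_model <- function(model, path) {
  stopifnot(inherits(model, "circuit_model"))
  obj <- list(
    schema_version = 1L,
    topology = model$topology,
    stages = lapply(model$stages, unclass),
    basal = model$basal, range = model$range)
  if (!is.null(model$crispri_stage)) {
    cs <- model$crispri_stage
    obj$crispri_stage <- list(activation = unclass(cs$activation),
                              params = unclass(cs$params),
                              totals = unclass(cs$totals))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a circuit model from JSON
#'
#' @param path JSON path written by [write_circuit_model()].
#' @return A [circuit_model()].
#' @export
read_circuit_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported circuit model schema version", call. = FALSE)
  stages <- lapply(obj$stages, function(s)
    hill_stage(s$kind, s$basal, s$range, s$Km, s$n))
  cs <- NULL
  if (!is.null(obj$crispri_stage)) {
    a <- obj$crispri_stage$activation
    cs <- list(activation = hill_stage(a$kind, a$basal, a$range, a$Km, a$n),
               params = as_binding_params(obj$crispri_stage$params),
               totals = as_species_totals(obj$crispri_stage$totals))
  }
  circuit_model(stages = stages, topology = obj$topology,
                crispri_stage = cs, basal = obj$basal, range = obj$range)
}

#' Write / read tidy transfer-curve CSV files
#'
#' The tidy dialect used throughout: columns `input_value`, `output_value`
#' and optionally `replicate`.
#'
#' @param curve A data.frame (or [transfer_curve()]).
#' @param path CSV path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  keep <- intersect(c("input_value", "output_value", "replicate"), names(df))
  utils::write.csv(df[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("input_value", "output_value") %in% names(df)))
    stop("curve file must have columns input_value and output_value",
         call. = FALSE)
  df
}
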