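#' Binding parameters of the dCas9:sgRNA:promoter system
#'
#' Bundles the two dissociation constants of the repression pathway and the
#' lumped output gain. `K1` governs dCas9 + sgRNA -> dCas9:sgRNA binding and
#' `K2` governs dCas9:sgRNA + promoter DNA -> repressed-promoter binding, both
#' in nM. `theta` maps free promoter DNA (nM) to reporter output (arbitrary
#' units), absorbing transcription, translation, fluorophore maturation,
#' degradation and dilution; with the default `theta = 1` the reporter output
#' equals the free-DNA concentration. Only the ratios of the forward and
#' reverse binding rates matter at steady state, so the rates themselves are
#' never stored.
#'
#' @param K1 Dissociation constant of dCas9--sgRNA binding, nM (> 0).
#'   Default 0.3 nM, a biologically plausible affinity for sgRNA loading.
#' @param K2 Dissociation constant of complex--DNA binding, nM (> 0).
#'   Default 2 nM.
#' @param theta Lumped gain from free promoter DNA to reporter output,
#'   AU/nM (>= 0). Default 1, i.e. report free DNA itself.
#' @return An object of class `"binding_params"`.
#' @examples
#' binding_params()              # defaults K1 = 0.3, K2 = 2, theta = 1
#' binding_params(K1 = 1, K2 = 5, theta = 100)
#' @export
binding_params <- function(K1 = 0.3, K2 = 2, theta = 1) {
  for (v in list(K1 = K1, K2 = K2, theta = theta)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("binding parameters must be finite scalars", call. = FALSE)
  }
  if (K1 <= 0 || K2 <= 0) stop("K1 and K2 must be > 0", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  structure(list(K1 = K1, K2 = K2, theta = theta), class = "binding_params")
}

#' Total species concentrations
#'
#' Total (free + bound) intracellular concentrations of dCas9 (`Ctot`), sgRNA
#' (`gtot`) and target promoter DNA (`Dtot`), all in nM. In E. coli roughly
#' 1 nM corresponds to one molecule per cell, so plasmid copy numbers can be
#' used directly as `Dtot` values. Typical exploration ranges are 1--100 nM
#' for DNA and 1 nM -- 10 uM for dCas9 and sgRNA.
#'
#' @param Ctot Total dCas9, nM (>= 0).
#' @param gtot Total sgRNA, nM (>= 0).
#' @param Dtot Total target promoter DNA, nM (>= 0).
#' @return An object of class `"species_totals"`.
#' @examples
#' species_totals(Ctot = 100, gtot = 1000, Dtot = 10)
#' @export
species_totals <- function(Ctot, gtot, Dtot) {
  for (v in list(Ctot = Ctot, gtot = gtot, Dtot = Dtot)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("species totals must be finite scalars", call. = FALSE)
  }
  if (Ctot < 0 || gtot < 0 || Dtot < 0)
    stop("species totals must be >= 0", call. = FALSE)
  structure(list(Ctot = Ctot, gtot = gtot, Dtot = Dtot),
            class = "species_totals")
}

as_binding_params <- function(x) {
  if (inherits(x, "binding_params")) return(x)
  binding_params(K1 = x$K1, K2 = x$K2,
                 theta = if (is.null(x$theta)) 1 else x$theta)
}

as_species_totals <- function(x) {
  if (inherits(x, "species_totals")) return(x)
  species_totals(Ctot = x$Ctot, gtot = x$gtot, Dtot = x$Dtot)
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("CRISPRi binding parameters: K1 = %g nM, K2 = %g nM, theta = %g AU/nM\n",
              x$K1, x$K2, x$theta))
  invisible(x)
}

#' @export
print.species_totals <- function(x, ...) {
  cat(sprintf("Species totals (nM): dCas9 = %g, sgRNA = %g, promoter DNA = %g\n",
              x$Ctot, x$gtot, x$Dtot))
  invisible(x)
}
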