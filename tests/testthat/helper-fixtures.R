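# Shared fixtures: default binding parameters and a log-uniform sampler of
# species totals over the standard exploration box (0.01 -- 1e4 nM).
default_params <- function(theta = 1) binding_params(K1 = 0.3, K2 = 2,
                                                     theta = theta)

random_totals <- function(n, lo = 0.01, hi = 1e4) {
  m <- 10^matrix(stats::runif(n * 3, log10(lo), log10(hi)), ncol = 3)
  lapply(seq_len(n), function(i)
    species_totals(Ctot = m[i, 1], gtot = m[i, 2], Dtot = m[i, 3]))
}

# largest relative violation of the three conservation sums
conservation_residual <- function(eq) {
  tt <- eq$totals
  max(abs(eq$C + eq$Cg + eq$CgD - tt$Ctot) / max(1, tt$Ctot),
      abs(eq$g + eq$Cg + eq$CgD - tt$gtot) / max(1, tt$gtot),
      abs(eq$D + eq$CgD - tt$Dtot) / max(1, tt$Dtot))
}

# largest relative mass-action residual of the two binding steps
mass_action_residual <- function(eq) {
  p <- eq$params
  max(abs(p$K1 * eq$Cg - eq$C * eq$g) / max(1, p$K1 * eq$Cg),
      abs(p$K2 * eq$CgD - eq$Cg * eq$D) / max(1, p$K2 * eq$CgD))
}
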