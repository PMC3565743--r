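# Independent two-state partition-function oracle for the MWC activity.
# Physical free energies (kT): methylation lowers the active-state energy
# by alpha per unit above m0; ligand binding contributes -N log(1 + L/K)
# per conformation with its own dissociation constant.
boltzmannActivityOracle <- function(m, L, par) {
  E_A <- -par@N * par@alpha * (m - par@m0) - par@N * log1p(L / par@K_A)
  E_I <- -par@N * log1p(L / par@K_I)
  # energies are defined up to a common offset; anchor at the ground
  # state so the Boltzmann weights cannot overflow
  E0 <- min(E_A, E_I)
  wA <- exp(-(E_A - E0))
  wA / (wA + exp(-(E_I - E0)))
}

# Default truth values of the six fitted parameters.
fitTruth <- function() {
  v <- c(0.02, 0.02, 0.01, 0.01, 0.02, 12)
  names(v) <- c("methylation.kR", "methylation.kRt", "methylation.kB1",
                "methylation.kB2", "methylation.kB2t", "flagellar.q")
  v
}
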