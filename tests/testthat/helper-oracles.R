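# Independent brute-force oracles for the transfer-matrix core. These
# enumerate residue-state sequences directly, sharing no code path with
# the package's matrix route.

# log partition function by explicit state enumeration
oracle_ln_Z <- function(q, sigma, nu) {
  total <- 0
  for (s in 0:(2^nu - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(nu)]
    n_u <- sum(bits)
    n_blocks <- sum(bits == 1L & c(0L, bits[-nu]) == 0L)
    total <- total + sigma^n_blocks * q^n_u
  }
  log(total)
}

# Boltzmann-weighted mean fraction of unfolded residues
oracle_theta <- function(q, sigma, nu) {
  z <- 0
  acc <- 0
  for (s in 0:(2^nu - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(nu)]
    n_u <- sum(bits)
    n_blocks <- sum(bits == 1L & c(0L, bits[-nu]) == 0L)
    w <- sigma^n_blocks * q^n_u
    z <- z + w
    acc <- acc + w * n_u / nu
  }
  acc / z
}

# default lysozyme-like parameter set used across tests
lysozyme_params <- function(K_D = 0.25, sigma = 1e-3, nu = 129,
                            temperature_K = 298.15) {
  unfolding_params(K_D, sigma, nu, temperature_K)
}
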