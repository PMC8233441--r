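# Small in-code fixtures shared across test files.

# A tiny collection: 2 spectra on a 3-channel grid.
toy_collection <- function() {
  spectra_collection(
    wavenumber = c(600, 604, 608),
    intensity = cbind(a1 = c(1, 2, 3), a2 = c(3, 2, 1)),
    meta = data.frame(acquisition_id = c("a1", "a2"),
                      sample_id = c("s1", "s1"),
                      scan_setting = c(10L, 10L),
                      replicate = c(1L, 2L)))
}

# A small but realistic stability design (fast to generate).
small_stability <- function(seed = 11, ...) {
  generate_stability_dataset(n_samples = 3, settings = c(10, 40, 100),
                             replicates = 4, seed = seed, ...)
}

# Brute-force per-term moment distances: the independent oracle, written as
# a plain loop over channels, never vectorized.
brute_md <- function(rho, offsets) {
  total <- 0
  for (p in seq_along(rho)) total <- total + sqrt(rho[p]^2 + offsets[p]^2)
  total
}

brute_mdi <- function(rho, x = seq_along(rho) - 1) {
  x <- x - x[1]
  brute_md(rho, x[length(x)] - x) - brute_md(rho, x)
}

# Closed-form OLS predictions via the normal equations (independent of pls1).
ols_predict <- function(X, y, Xnew) {
  Z <- cbind(1, X)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  drop(cbind(1, Xnew) %*% beta)
}
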