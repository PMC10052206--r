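# Independent numerical oracles used by the test suite. These deliberately
# avoid the code paths under test: the spectral oracle goes through the
# characteristic polynomial (Faddeev-LeVerrier recursion + polyroot), not
# through svd()/eigen() on the same matrix product.

# coefficients of det(lambda I - A) = lambda^n + c1 lambda^(n-1) + ... + cn
charpoly_coefficients <- function(A) {
  n <- nrow(A)
  M <- diag(n)
  cs <- numeric(n)
  for (k in seq_len(n)) {
    AM <- A %*% M
    cs[k] <- -sum(diag(AM)) / k
    M <- AM + cs[k] * diag(n)
  }
  cs
}

# spectral norm of a real symmetric matrix = max |eigenvalue|, obtained as
# the largest root modulus of the characteristic polynomial
spectral_norm_oracle <- function(A) {
  if (nrow(A) == 1) return(abs(A[1, 1]))
  cs <- charpoly_coefficients(A)
  roots <- polyroot(c(rev(cs), 1))
  max(Mod(roots))
}

# plug-in Shannon entropy by explicit summation (no vector tricks)
entropy_by_summation <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base = 2)
  h
}

# shared subject used across the simulation-based tests
test_subject <- function() qct_subject(weight = 80, height = 180, sex = "male")
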