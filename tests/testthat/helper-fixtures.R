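# Small in-code fixtures shared across tests.

# all compositions of `total` into `parts` non-negative integers
compositionsOf <- function(total, parts) {
  if (parts == 1) return(matrix(total, 1, 1))
  out <- list()
  for (k in 0:total) {
    rest <- compositionsOf(total - k, parts - 1)
    out[[k + 1]] <- cbind(k, rest)
  }
  unname(do.call(rbind, out))
}

# a small DMExperiment with known dimensions
makeToyExperiment <- function(n = 12, J = 4, P = 3, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * P), n, P, dimnames = list(NULL, paste0("x", 1:P)))
  alpha <- runif(J, -1, 1)
  beta <- matrix(0, P, J)
  gam <- computeGamma(alpha, beta, X)
  Y <- t(vapply(seq_len(n), function(i)
    as.integer(rmultinom(1, 300, gam[i, ] / sum(gam[i, ]))), integer(J)))
  colnames(Y) <- paste0("taxon", 1:J)
  rownames(Y) <- paste0("s", 1:n)
  DMExperiment(Y, X)
}

# brute-force DM log pmf straight from the definition (independent oracle)
oracleDmLogPmf <- function(y, gamma) {
  yp <- sum(y); gp <- sum(gamma)
  log(factorial(yp)) + lgamma(gp) - lgamma(yp + gp) +
    sum(lgamma(y + gamma) - lgamma(gamma) - log(factorial(y)))
}
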