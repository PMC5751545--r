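# Independent scalar (double-loop) oracles for every closed-form quantity.
# These deliberately avoid matrix algebra so they cannot share a bug with
# the vectorised implementation.

oracle_bandwidth <- function(profiles, gamma_prime = 1) {
  total <- 0
  for (i in seq_len(nrow(profiles))) total <- total + sum(profiles[i, ]^2)
  gamma_prime / (total / nrow(profiles))
}

oracle_kernel <- function(profiles, gamma) {
  n <- nrow(profiles)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  K
}

oracle_ncp_d <- function(KD, A) {
  out <- matrix(NA_real_, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      nrm <- sqrt(sum(A[, j]^2))
      out[i, j] <- if (nrm == 0) 0 else sum(KD[i, ] * A[, j]) / nrm
    }
  }
  out
}

oracle_ncp_m <- function(A, KM) {
  out <- matrix(NA_real_, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      nrm <- sqrt(sum(A[i, ]^2))
      out[i, j] <- if (nrm == 0) 0 else sum(A[i, ] * KM[, j]) / nrm
    }
  }
  out
}

oracle_combine <- function(ncp_d, ncp_m, KD, KM) {
  out <- matrix(NA_real_, nrow(ncp_d), ncol(ncp_d))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- (ncp_d[i, j] + ncp_m[i, j]) /
        (sqrt(sum(KD[i, ]^2)) + sqrt(sum(KM[, j]^2)))
    }
  }
  out
}

# full scoring pipeline through the scalar oracles only
oracle_predict <- function(A, gamma_prime_d = 1, gamma_prime_m = 1) {
  KD <- oracle_kernel(A, oracle_bandwidth(A, gamma_prime_d))
  KM <- oracle_kernel(t(A), oracle_bandwidth(t(A), gamma_prime_m))
  oracle_combine(oracle_ncp_d(KD, A), oracle_ncp_m(A, KM), KD, KM)
}

# brute-force Mann-Whitney over all (test, candidate) pairs
oracle_auc <- function(test, cand) {
  wins <- 0
  for (t in test) for (c in cand) {
    wins <- wins + (t > c) + 0.5 * (t == c)
  }
  wins / (length(test) * length(cand))
}

# random binary matrix guaranteed to contain at least one 1
rand_binary <- function(nd, nm, p = 0.3) {
  A <- matrix(rbinom(nd * nm, 1, p), nd, nm)
  if (sum(A) == 0) A[sample(length(A), 1)] <- 1
  A
}

make_net <- function(A) association_network(A)

# bare numeric matrix from a gip_kernel (drops class and provenance attributes)
kmat <- function(K) {
  K <- unclass(K)
  attributes(K) <- attributes(K)[c("dim", "dimnames")]
  K
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

write_edges <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
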