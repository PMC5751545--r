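#' Gaussian interaction profile (GIP) kernel bandwidth
#'
#' The GIP bandwidth is a raw bandwidth `gamma_prime` normalised by the mean
#' squared norm of the interaction profiles:
#' \deqn{\gamma = \gamma' / \left(\frac{1}{n}\sum_i \|IP_i\|^2\right)}
#' For binary profiles \eqn{\|IP_i\|^2} is simply the number of known
#' associations of entity `i`, so the normaliser is the average association
#' count over all entities on that axis. Entities with empty profiles
#' contribute 0 to the sum but still count in `n`.
#'
#' @param profiles An `n x p` binary matrix, one interaction profile per row.
#' @param gamma_prime Positive raw bandwidth; 1 is the conventional default.
#' @return The normalised bandwidth, a non-negative scalar.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  check_binary_matrix(profiles, "profiles")
  check_scalar_number(gamma_prime, "gamma_prime", positive = TRUE)
  mean_sq <- mean(rowSums(profiles))
  if (mean_sq == 0) {
    stop_degenerate(paste(
      "all interaction profiles are empty: the bandwidth normaliser is zero.",
      "Supply a matrix with at least one association."
    ))
  }
  gamma_prime / mean_sq
}

#' Gaussian interaction profile kernel matrix
#'
#' Pairwise similarity between interaction profiles:
#' \deqn{K(i, j) = \exp(-\gamma \, \|IP_i - IP_j\|^2)}
#' For binary profiles the squared Euclidean distance is the Hamming
#' distance, computed here in integer arithmetic via one cross-product
#' before the single `exp` call.
#'
#' @param profiles An `n x p` binary matrix, one profile per row.
#' @param gamma Non-negative bandwidth (see [gip_bandwidth()]).
#' @return An `n x n` symmetric matrix of class `gip_kernel` with unit
#'   diagonal and entries in (0, 1]; attributes `gamma` and `axis` record
#'   its provenance.
#' @export
gip_kernel <- function(profiles, gamma, axis = NA_character_, gamma_prime = NA_real_) {
  check_binary_matrix(profiles, "profiles")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0) {
    stop_contract("`gamma` must be a single non-negative number")
  }
  G <- tcrossprod(profiles)
  ones <- diag(G)
  d2 <- outer(ones, ones, "+") - 2 * G # Hamming distance between binary rows
  K <- exp(-gamma * d2)
  # exact symmetry and unit diagonal despite floating-point round-off
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  structure(K, class = c("gip_kernel", class(K)),
            gamma = gamma, gamma_prime = gamma_prime, axis = axis)
}

#' @param axis,gamma_prime Provenance tags stored on the result.
#' @rdname gip_kernel
#' @export
disease_kernel <- function(net, gamma_prime_d = 1) {
  profiles <- net$A # disease profiles are the rows of A
  gamma <- gip_bandwidth(profiles, gamma_prime_d)
  gip_kernel(profiles, gamma, axis = "disease", gamma_prime = gamma_prime_d)
}

#' @param net An [association_network()].
#' @param gamma_prime_d,gamma_prime_m Raw bandwidths for the disease and
#'   microbe axes (default 1).
#' @rdname gip_kernel
#' @export
microbe_kernel <- function(net, gamma_prime_m = 1) {
  profiles <- t(net$A) # microbe profiles are the columns of A
  gamma <- gip_bandwidth(profiles, gamma_prime_m)
  gip_kernel(profiles, gamma, axis = "microbe", gamma_prime = gamma_prime_m)
}

#' @export
print.gip_kernel <- function(x, ...) {
  cat(sprintf("<gip_kernel> %d x %d (%s axis), gamma = %.6g\n",
              nrow(x), ncol(x),
              attr(x, "axis") %||% "?", attr(x, "gamma")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
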