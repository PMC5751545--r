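#' Generate a planted-block bipartite association network
#'
#' Draws a binary disease-microbe matrix from a bipartite stochastic block
#' model: diseases and microbes are assigned to `n_blocks` communities
#' round-robin (so block sizes are reproducible), and a pair is associated
#' with probability `p_in` when disease and microbe share a block and
#' `p_out` otherwise. This is the minimal generator for the guilt-by-
#' association assumption behind the method — functionally related microbes
#' sharing association patterns with phenotypically related diseases — and
#' its defaults emulate the shape and sparsity of the curated human
#' microbe-disease association catalogue (39 diseases, 292 microbes, about
#' 450 associations, ~4% fill).
#'
#' @param nd,nm Numbers of diseases and microbes (defaults 39 and 292).
#' @param n_blocks Number of planted communities (default 8).
#' @param p_in,p_out Within- and cross-block association probabilities
#'   (defaults 0.30 and 0.01; `p_out < p_in` required).
#' @param seed Integer seed; the same parameters and seed reproduce the
#'   matrix bit for bit. The caller's RNG state is untouched.
#' @return An object of class `synthetic_truth`: list with `net`
#'   (an [association_network()]), `disease_blocks`, `microbe_blocks`,
#'   `p_in`, `p_out`, `seed` and an (initially empty) `held_out` tibble.
#' @export
generate_block_network <- function(nd = 39, nm = 292, n_blocks = 8,
                                   p_in = 0.30, p_out = 0.01, seed = 1) {
  check_scalar_number(nd, "nd", positive = TRUE, integerish = TRUE)
  check_scalar_number(nm, "nm", positive = TRUE, integerish = TRUE)
  check_scalar_number(n_blocks, "n_blocks", positive = TRUE, integerish = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (n_blocks > min(nd, nm)) {
    stop_contract("`n_blocks` cannot exceed the smaller of `nd` and `nm`")
  }
  if (!is.numeric(p_in) || !is.numeric(p_out) ||
      p_out < 0 || p_in > 1 || p_out >= p_in) {
    stop_contract("need 0 <= p_out < p_in <= 1")
  }
  disease_blocks <- (seq_len(nd) - 1L) %% n_blocks + 1L
  microbe_blocks <- (seq_len(nm) - 1L) %% n_blocks + 1L
  prob <- ifelse(outer(disease_blocks, microbe_blocks, "=="), p_in, p_out)
  A <- withr::with_seed(as.integer(seed), {
    repeat {
      draw <- matrix(stats::rbinom(nd * nm, 1L, prob), nd, nm)
      if (sum(draw) > 0) break # reject the (rare) all-zero draw
    }
    draw
  })
  dimnames(A) <- list(sprintf("D%02d", seq_len(nd)), sprintf("M%03d", seq_len(nm)))
  structure(
    list(net = association_network(A),
         disease_blocks = disease_blocks, microbe_blocks = microbe_blocks,
         p_in = p_in, p_out = p_out, seed = as.integer(seed),
         held_out = tibble(disease = character(0), microbe = character(0))),
    class = "synthetic_truth"
  )
}

#' Remove a random sample of known associations as recoverable truth
#'
#' Moves a seeded random fraction of the positives out of the adjacency
#' matrix and records them in `held_out`, so downstream code can check
#' whether the method re-ranks them above never-associated pairs. Positives
#' are conserved: ones before = ones after + held-out count.
#'
#' @param truth A `synthetic_truth` from [generate_block_network()].
#' @param fraction Fraction of current positives to remove, in (0, 1);
#'   at least one pair is removed and at least one must remain.
#' @param seed Integer seed for the sample.
#' @return The modified `synthetic_truth`.
#' @export
hold_out_positives <- function(truth, fraction, seed = 1) {
  if (!inherits(truth, "synthetic_truth")) {
    stop_contract("`truth` must be a synthetic_truth object")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop_contract("`fraction` must lie strictly between 0 and 1")
  }
  check_scalar_number(seed, "seed", integerish = TRUE)
  A <- truth$net$A
  pos <- which(A == 1)
  n_remove <- max(1L, as.integer(round(fraction * length(pos))))
  if (n_remove >= length(pos)) {
    stop_contract("holding out that fraction would remove every positive")
  }
  removed <- withr::with_seed(as.integer(seed), sample(pos, n_remove))
  A[removed] <- 0
  nd <- nrow(A)
  i <- (removed - 1L) %% nd + 1L
  j <- (removed - 1L) %/% nd + 1L
  truth$net <- association_network(A)
  truth$held_out <- dplyr::bind_rows(
    truth$held_out,
    tibble(disease = rownames(A)[i], microbe = colnames(A)[j])
  )
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d x %d, %d blocks, p_in = %.3g, p_out = %.3g, seed = %d\n",
    length(x$net$diseases), length(x$net$microbes),
    max(x$disease_blocks), x$p_in, x$p_out, x$seed
  ))
  print(x$net)
  if (nrow(x$held_out)) cat(sprintf("  %d positives held out\n", nrow(x$held_out)))
  invisible(x)
}

#' One-row summary of a synthetic network and its planted structure
#'
#' @param x A `synthetic_truth`.
#' @param ... Unused.
#' @method glance synthetic_truth
#' @export
glance.synthetic_truth <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$net),
    tibble(n_blocks = max(x$disease_blocks), p_in = x$p_in, p_out = x$p_out,
           seed = x$seed, n_held_out = nrow(x$held_out))
  )
}
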