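#' Network consistency projection in disease space
#'
#' Projects each disease's similarity vector onto each microbe's association
#' vector:
#' \deqn{NCP_d(i, j) = \frac{KD_i \cdot A_j}{|A_j|}}
#' where \eqn{KD_i} is row `i` of the disease kernel, \eqn{A_j} is column `j`
#' of the adjacency matrix and \eqn{|\cdot|} the Euclidean norm. The score
#' grows with the number of diseases associated with microbe `j` that are
#' similar to disease `i` (a smaller angle between the two vectors). Columns
#' with no associations get a 0 score by convention, the limit of the
#' projection as the vector vanishes.
#'
#' @param KD Disease-axis [gip_kernel()] (`nd x nd`).
#' @param net An [association_network()].
#' @return An `nd x nm` numeric matrix.
#' @export
disease_space_projection <- function(KD, net) {
  A <- net$A
  if (!is.matrix(KD) || nrow(KD) != ncol(KD) || nrow(KD) != nrow(A)) {
    stop_contract("`KD` must be a square matrix matching the disease axis of `net`")
  }
  col_norm <- sqrt(colSums(A * A))
  P <- unclass(KD) %*% A
  sweep(P, 2L, ifelse(col_norm > 0, col_norm, Inf), "/")
}

#' Network consistency projection in microbe space
#'
#' The mirror image of [disease_space_projection()]:
#' \deqn{NCP_m(i, j) = \frac{A_i \cdot KM_j}{|A_i|}}
#' with \eqn{A_i} the association vector of disease `i` and \eqn{KM_j} the
#' similarity vector of microbe `j`. Diseases with no associations get a 0
#' row, so a cold-start disease is still scoreable through disease space.
#'
#' @param net An [association_network()].
#' @param KM Microbe-axis [gip_kernel()] (`nm x nm`).
#' @return An `nd x nm` numeric matrix.
#' @export
microbe_space_projection <- function(net, KM) {
  A <- net$A
  if (!is.matrix(KM) || nrow(KM) != ncol(KM) || nrow(KM) != ncol(A)) {
    stop_contract("`KM` must be a square matrix matching the microbe axis of `net`")
  }
  row_norm <- sqrt(rowSums(A * A))
  P <- A %*% unclass(KM)
  sweep(P, 1L, ifelse(row_norm > 0, row_norm, Inf), "/")
}

#' Combine the two projections into the final score matrix
#'
#' \deqn{NCP(i, j) = \frac{NCP_d(i, j) + NCP_m(i, j)}{|KD_i| + |KM_j|}}
#' The denominator is strictly positive (kernel diagonals are 1), and by
#' Cauchy-Schwarz each numerator term is bounded by the corresponding kernel
#' vector norm, so every combined score lies in [0, 1].
#'
#' @param ncp_d,ncp_m Projection matrices from the two spaces (`nd x nm`).
#' @param KD,KM The kernels used to build them.
#' @return An `nd x nm` matrix of scores in [0, 1].
#' @export
combine_projections <- function(ncp_d, ncp_m, KD, KM) {
  if (!identical(dim(ncp_d), dim(ncp_m)) ||
      nrow(ncp_d) != nrow(KD) || ncol(ncp_d) != ncol(KM)) {
    stop_contract("projection and kernel dimensions are inconsistent")
  }
  kd_norm <- sqrt(rowSums(unclass(KD)^2))
  km_norm <- sqrt(colSums(unclass(KM)^2))
  (ncp_d + ncp_m) / outer(kd_norm, km_norm, "+")
}

#' Score every disease-microbe pair of a network
#'
#' Runs the whole closed-form pipeline: GIP kernels on both axes
#' ([disease_kernel()], [microbe_kernel()]), both space projections, and the
#' combined, normalised score. Scoring is fully deterministic; there is no
#' randomness and no iteration anywhere.
#'
#' @param object An [association_network()] with at least one association.
#' @param gamma_prime_d,gamma_prime_m Raw kernel bandwidths (default 1).
#' @param ... Unused.
#' @return An object of class `ncp_scores`: list with the score matrix `S`
#'   (in [0, 1]), the label lists, the bandwidths actually used, and the
#'   adjacency matrix the scores were computed from.
#' @examples
#' truth <- generate_block_network(nd = 8, nm = 20, n_blocks = 2, seed = 1)
#' scores <- predict(truth$net)
#' head(tidy(scores))
#' @export
predict.assoc_network <- function(object, gamma_prime_d = 1, gamma_prime_m = 1, ...) {
  KD <- disease_kernel(object, gamma_prime_d)
  KM <- microbe_kernel(object, gamma_prime_m)
  project_with_kernels(object, KD, KM)
}

# projection given precomputed kernels; shared with the CV module, where the
# no-recompute convention reuses full-data kernels across folds
project_with_kernels <- function(net, KD, KM) {
  ncp_d <- disease_space_projection(KD, net)
  ncp_m <- microbe_space_projection(net, KM)
  S <- combine_projections(ncp_d, ncp_m, KD, KM)
  structure(
    list(S = S, diseases = net$diseases, microbes = net$microbes,
         gamma_prime_d = attr(KD, "gamma_prime"),
         gamma_prime_m = attr(KM, "gamma_prime"),
         gamma_d = attr(KD, "gamma"), gamma_m = attr(KM, "gamma"),
         A = net$A),
    class = "ncp_scores"
  )
}

#' @export
print.ncp_scores <- function(x, ...) {
  cat(sprintf(
    "<ncp_scores> %d diseases x %d microbes, scores in [%.4f, %.4f]\n",
    length(x$diseases), length(x$microbes), min(x$S), max(x$S)
  ))
  invisible(x)
}

#' Tidy NCP scores into a ranked long table
#'
#' @param x An `ncp_scores` object.
#' @param ... Unused.
#' @return A tibble with columns `disease`, `microbe`, `score`,
#'   `known` (1 for pairs already in the network), sorted by descending
#'   score within each disease with ties broken by microbe label. For
#'   discovery, rank the rows with `known == 0`; known pairs are reported
#'   but flagged.
#' @method tidy ncp_scores
#' @export
tidy.ncp_scores <- function(x, ...) {
  net <- new_assoc_network(x$A, sum(x$A), 0L)
  score_table(net, x$S)
}

#' One-row summary of an NCP score matrix
#'
#' @param x An `ncp_scores` object.
#' @param ... Unused.
#' @method glance ncp_scores
#' @export
glance.ncp_scores <- function(x, ...) {
  tibble(
    n_diseases = length(x$diseases),
    n_microbes = length(x$microbes),
    gamma_d = x$gamma_d,
    gamma_m = x$gamma_m,
    min_score = min(x$S),
    max_score = max(x$S)
  )
}

#' Heatmap of an NCP score matrix
#'
#' @param object An `ncp_scores` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ncp_scores
#' @export
autoplot.ncp_scores <- function(object, ...) {
  df <- tidy(object)
  df$disease <- factor(df$disease, levels = rev(object$diseases))
  df$microbe <- factor(df$microbe, levels = object$microbes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$microbe, y = .data$disease,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "microbe", y = "disease", fill = "NCP score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
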