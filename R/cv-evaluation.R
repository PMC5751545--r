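#' Rank-based ROC curve and AUC
#'
#' Sweeps a decision threshold over the pooled score values: at each
#' threshold the true-positive rate is the fraction of test scores strictly
#' above it, counting scores tied with the threshold as one half (the
#' mid-rank convention), and the false-positive rate is computed the same
#' way over the candidate scores. Under this convention the area under the
#' curve equals the Mann-Whitney statistic
#' \eqn{P(\mathrm{test} > \mathrm{cand}) + \frac12 P(\mathrm{test} = \mathrm{cand})},
#' which is how `auc` is computed (exactly, via mid-ranks).
#'
#' @param test_scores Scores of the held-out true associations.
#' @param candidate_scores Scores of the candidate (unknown) pairs.
#' @return A list with `roc` (tibble of `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @examples
#' rank_based_roc(c(0.9, 0.8), c(0.1, 0.2))$auc # 1: perfect separation
#' @export
rank_based_roc <- function(test_scores, candidate_scores) {
  if (length(test_scores) == 0L || length(candidate_scores) == 0L) {
    stop_contract("`test_scores` and `candidate_scores` must both be non-empty")
  }
  if (anyNA(test_scores) || anyNA(candidate_scores)) {
    stop_contract("scores must not contain missing values")
  }
  nt <- length(test_scores)
  nc <- length(candidate_scores)
  r <- rank(c(test_scores, candidate_scores)) # mid-ranks on ties
  auc <- (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (as.numeric(nt) * nc)
  vals <- sort(unique(c(test_scores, candidate_scores)), decreasing = TRUE)
  cnt_t <- tabulate(match(test_scores, vals), length(vals))
  cnt_c <- tabulate(match(candidate_scores, vals), length(vals))
  # inclusive-threshold step curve: scores tied with the threshold are called
  # positive, so tied groups become diagonal segments and the trapezoidal
  # area reproduces the mid-rank Mann-Whitney statistic exactly
  tpr <- cumsum(cnt_t) / nt
  fpr <- cumsum(cnt_c) / nc
  roc <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc = roc, auc = auc)
}

new_cv_result <- function(mode, auc, roc, ranks, folds = NULL, seed = NULL,
                          repeats = 1L, auc_mean = NULL, auc_sd = NULL,
                          fold_aucs = NULL, skipped = 0L, params = list()) {
  structure(
    list(mode = mode, auc = auc, roc = roc, ranks = ranks, folds = folds,
         seed = seed, repeats = as.integer(repeats), auc_mean = auc_mean,
         auc_sd = auc_sd, fold_aucs = fold_aucs, skipped = as.integer(skipped),
         params = params),
    class = "cv_result"
  )
}

# kernels for one (possibly masked) matrix; `cache` carries full-data kernels
# under the no-recompute convention
fold_kernels <- function(net, gamma_prime_d, gamma_prime_m, recompute, cache) {
  if (recompute) {
    list(KD = disease_kernel(net, gamma_prime_d),
         KM = microbe_kernel(net, gamma_prime_m))
  } else {
    cache
  }
}

mask_one <- function(net, i, j) {
  net$A[i, j] <- 0
  net
}

# mid-rank of the test score within {test} union {candidates}; 1 = best
test_rank <- function(test, candidates) {
  1 + sum(candidates > test) + 0.5 * sum(candidates == test)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is removed in turn; by default the GIP kernels are
#' recomputed from the masked matrix so no information about the held-out
#' pair leaks into the similarities (set `recompute_kernels = FALSE` to reuse
#' full-data kernels across folds, the leaky but historically common
#' convention). The held-out pair is then ranked against every pair that is
#' unknown in the original matrix, with candidates re-scored by that fold's
#' model. All folds are pooled into one rank-based ROC/AUC.
#'
#' @param net An [association_network()] with at least two associations.
#' @param gamma_prime_d,gamma_prime_m Raw kernel bandwidths (default 1).
#' @param recompute_kernels Recompute kernels from each masked matrix
#'   (default `TRUE`).
#' @return A `cv_result` with mode `"global_loocv"`.
#' @export
global_loocv <- function(net, gamma_prime_d = 1, gamma_prime_m = 1,
                         recompute_kernels = TRUE) {
  pos <- which(net$A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop_contract("global LOOCV needs at least 2 known associations")
  zeros <- which(net$A == 0)
  cache <- if (!recompute_kernels) {
    list(KD = disease_kernel(net, gamma_prime_d),
         KM = microbe_kernel(net, gamma_prime_m))
  }
  n_fold <- nrow(pos)
  tests <- numeric(n_fold)
  ranks <- integer(0)
  cand_scores <- vector("list", n_fold)
  rank_rows <- vector("list", n_fold)
  for (f in seq_len(n_fold)) {
    i <- pos[f, 1L]; j <- pos[f, 2L]
    masked <- mask_one(net, i, j)
    k <- fold_kernels(masked, gamma_prime_d, gamma_prime_m, recompute_kernels, cache)
    S <- project_with_kernels(masked, k$KD, k$KM)$S
    tests[f] <- S[i, j]
    cand_scores[[f]] <- S[zeros]
    rank_rows[[f]] <- tibble(
      disease = net$diseases[i], microbe = net$microbes[j],
      score = tests[f],
      rank = test_rank(tests[f], cand_scores[[f]]),
      candidate_set_size = length(zeros) + 1L
    )
  }
  pooled <- rank_based_roc(tests, unlist(cand_scores))
  new_cv_result(
    mode = "global_loocv", auc = pooled$auc, roc = pooled$roc,
    ranks = dplyr::bind_rows(rank_rows),
    params = list(gamma_prime_d = gamma_prime_d, gamma_prime_m = gamma_prime_m,
                  recompute_kernels = recompute_kernels)
  )
}

#' Local leave-one-out cross-validation
#'
#' Same per-association masking as [global_loocv()], but the held-out pair is
#' ranked only against the unknown microbes of its own disease. Each fold
#' contributes one rank-based AUC against its local candidate set; the
#' overall AUC is the unweighted mean over folds. Folds whose disease has no
#' unknown microbe are skipped with a warning and counted in `skipped`.
#'
#' @inheritParams global_loocv
#' @return A `cv_result` with mode `"local_loocv"`; `auc` is the mean
#'   per-fold AUC and `roc` the pooled rank-percentile curve.
#' @export
local_loocv <- function(net, gamma_prime_d = 1, gamma_prime_m = 1,
                        recompute_kernels = TRUE) {
  pos <- which(net$A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop_contract("local LOOCV needs at least 2 known associations")
  cache <- if (!recompute_kernels) {
    list(KD = disease_kernel(net, gamma_prime_d),
         KM = microbe_kernel(net, gamma_prime_m))
  }
  fold_aucs <- numeric(0)
  rank_rows <- list()
  skipped <- 0L
  for (f in seq_len(nrow(pos))) {
    i <- pos[f, 1L]; j <- pos[f, 2L]
    cand_j <- which(net$A[i, ] == 0)
    if (length(cand_j) == 0L) {
      warn(sprintf("disease '%s' has no candidate microbes; fold skipped",
                   net$diseases[i]))
      skipped <- skipped + 1L
      next
    }
    masked <- mask_one(net, i, j)
    k <- fold_kernels(masked, gamma_prime_d, gamma_prime_m, recompute_kernels, cache)
    S <- project_with_kernels(masked, k$KD, k$KM)$S
    fold <- rank_based_roc(S[i, j], S[i, cand_j])
    fold_aucs <- c(fold_aucs, fold$auc)
    rank_rows[[length(rank_rows) + 1L]] <- tibble(
      disease = net$diseases[i], microbe = net$microbes[j],
      score = S[i, j],
      rank = test_rank(S[i, j], S[i, cand_j]),
      candidate_set_size = length(cand_j) + 1L
    )
  }
  if (length(fold_aucs) == 0L) stop_degenerate("every local LOOCV fold was skipped")
  new_cv_result(
    mode = "local_loocv", auc = mean(fold_aucs),
    roc = percentile_roc(fold_aucs),
    ranks = dplyr::bind_rows(rank_rows),
    fold_aucs = fold_aucs, skipped = skipped,
    params = list(gamma_prime_d = gamma_prime_d, gamma_prime_m = gamma_prime_m,
                  recompute_kernels = recompute_kernels)
  )
}

# ROC over folds ranked by their within-disease percentile: accepting the top
# fraction t of each disease's candidate list recovers the folds whose test
# percentile exceeds 1 - t, so TPR(t) steps at the observed (1 - AUC_f)
percentile_roc <- function(fold_aucs) {
  q <- sort(unique(1 - fold_aucs))
  cnt <- tabulate(match(1 - fold_aucs, q), length(q))
  tpr <- cumsum(cnt) / length(fold_aucs)
  tibble(fpr = c(0, q, 1), tpr = c(0, tpr, 1))
}

#' Repeated k-fold cross-validation
#'
#' The known associations are shuffled and split into `k` groups of
#' near-equal size (differing by at most one); each group is zeroed out in
#' turn, the model retrained on the rest (kernels recomputed by default) and
#' the group's pairs ranked against the originally-unknown pairs. The whole
#' division is repeated `repeats` times under one seeded generator, and the
#' result reports the mean and standard deviation over all `k * repeats`
#' fold-level AUCs.
#'
#' @inheritParams global_loocv
#' @param k Number of folds (default 5).
#' @param repeats Number of random re-divisions (default 100).
#' @param seed Integer seed for the fold shuffling (R's default Mersenne
#'   Twister, scoped so the caller's RNG state is untouched).
#' @return A `cv_result` with mode `"kfold"`; `auc`/`auc_mean` is the mean
#'   fold AUC, `auc_sd` the standard deviation, `roc` the pooled curve.
#' @export
kfold_cv <- function(net, k = 5, repeats = 100, seed = 1,
                     gamma_prime_d = 1, gamma_prime_m = 1,
                     recompute_kernels = TRUE) {
  check_scalar_number(k, "k", positive = TRUE, integerish = TRUE)
  check_scalar_number(repeats, "repeats", positive = TRUE, integerish = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  k <- as.integer(k)
  if (k < 2L) stop_contract("`k` must be at least 2")
  pos <- which(net$A == 1)
  if (length(pos) < k) {
    stop_contract(sprintf("%d known associations cannot be split into %d folds",
                          length(pos), k))
  }
  zeros <- which(net$A == 0)
  cache <- if (!recompute_kernels) {
    list(KD = disease_kernel(net, gamma_prime_d),
         KM = microbe_kernel(net, gamma_prime_m))
  }
  fold_aucs <- numeric(0)
  fold_rows <- list()
  tests_all <- list()
  cands_all <- list()
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(repeats)) {
      shuffled <- sample(pos)
      group <- rep(seq_len(k), length.out = length(pos)) # sizes differ by <= 1
      for (g in seq_len(k)) {
        test_idx <- shuffled[group == g]
        masked <- net
        masked$A[test_idx] <- 0
        kk <- fold_kernels(masked, gamma_prime_d, gamma_prime_m,
                           recompute_kernels, cache)
        S <- project_with_kernels(masked, kk$KD, kk$KM)$S
        fr <- rank_based_roc(S[test_idx], S[zeros])
        fold_aucs <- c(fold_aucs, fr$auc)
        tests_all[[length(tests_all) + 1L]] <- S[test_idx]
        cands_all[[length(cands_all) + 1L]] <- S[zeros]
        fold_rows[[length(fold_rows) + 1L]] <- tibble(
          repeat_id = r, fold = g, n_test = length(test_idx), auc = fr$auc
        )
      }
    }
  })
  pooled <- rank_based_roc(unlist(tests_all), unlist(cands_all))
  new_cv_result(
    mode = "kfold", auc = mean(fold_aucs), roc = pooled$roc,
    ranks = NULL, folds = dplyr::bind_rows(fold_rows),
    seed = as.integer(seed), repeats = repeats,
    auc_mean = mean(fold_aucs), auc_sd = sd(fold_aucs),
    fold_aucs = fold_aucs,
    params = list(k = k, gamma_prime_d = gamma_prime_d,
                  gamma_prime_m = gamma_prime_m,
                  recompute_kernels = recompute_kernels)
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mode = %s, AUC = %.4f", x$mode, x$auc))
  if (!is.null(x$auc_sd)) cat(sprintf(" +/- %.4f (%d fold AUCs)", x$auc_sd,
                                      length(x$fold_aucs)))
  cat("\n")
  if (x$skipped > 0) cat(sprintf("  %d folds skipped\n", x$skipped))
  invisible(x)
}

#' Tidy a cross-validation result into its ROC points
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with columns `fpr`, `tpr`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$roc

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    mode = x$mode,
    auc = x$auc,
    auc_sd = if (is.null(x$auc_sd)) NA_real_ else x$auc_sd,
    n_folds = if (!is.null(x$fold_aucs)) length(x$fold_aucs)
              else if (!is.null(x$ranks)) nrow(x$ranks) else NA_integer_,
    skipped = x$skipped,
    repeats = x$repeats,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' ROC curve of a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s: AUC = %.4f", object$mode, object$auc)
    ) +
    ggplot2::theme_minimal()
}
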