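#' Complete-block score table
#'
#' Arranges goodness-of-fit scores as a blocks x treatments matrix for the
#' nonparametric layer. Treatments are the factor under test (typically cost
#' levels); blocks are the matched units (the levels of the crossed cost
#' factor, or subjects/replicates). No missing cells are allowed.
#'
#' @param values numeric matrix, blocks x treatments.
#' @param treatment_labels,block_labels optional dimension labels.
#' @return a `score_block_table` (matrix with class attribute).
#' @export
score_block_table <- function(values, treatment_labels = NULL,
                              block_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("score table has missing cells; blocks must be complete")
  if (ncol(values) < 2L) stop("need at least 2 treatments")
  if (nrow(values) < 2L) stop("need at least 2 blocks")
  if (is.null(treatment_labels)) treatment_labels <- colnames(values)
  if (is.null(treatment_labels)) treatment_labels <- paste0("T", seq_len(ncol(values)))
  if (is.null(block_labels)) block_labels <- rownames(values)
  if (is.null(block_labels)) block_labels <- paste0("B", seq_len(nrow(values)))
  dimnames(values) <- list(block_labels, treatment_labels)
  structure(values, class = c("score_block_table", "matrix", "array"))
}

#' Pivot a sweep result into a score table
#'
#' For the signed-threshold factorial, tests of the positive-cost factor use
#' the negative-cost levels as blocks and vice versa.
#'
#' @param result a `sweep_result` from a signed-scheme sweep.
#' @param treatment `"positive_cost"` or `"negative_cost"`.
#' @return a [score_block_table()].
#' @export
sweep_score_table <- function(result, treatment = c("positive_cost", "negative_cost")) {
  treatment <- match.arg(treatment)
  block <- setdiff(c("positive_cost", "negative_cost"), treatment)
  tr <- sort(unique(result[[treatment]]))
  bl <- sort(unique(result[[block]]))
  m <- matrix(NA_real_, length(bl), length(tr),
              dimnames = list(paste0(block, "=", bl), paste0(treatment, "=", tr)))
  for (k in seq_len(nrow(result)))
    m[match(result[[block]][k], bl), match(result[[treatment]][k], tr)] <-
      result$mean_r[k]
  score_block_table(m)
}

# Within-block mid-ranks and the tie-correction sum Sum(t^3 - t).
block_ranks <- function(x) {
  ranks <- t(apply(x, 1L, rank))  # rank() uses mid-ranks for ties
  tie_sum <- sum(apply(x, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  list(ranks = ranks, tie_sum = tie_sum)
}

#' Friedman rank test
#'
#' Tests for a treatment effect across matched blocks using within-block
#' mid-ranks, with the standard tie correction. The statistic is
#' `chi2 = [12 / (b k (k+1)) * sum_j (R_j - b(k+1)/2)^2] / C` with
#' `C = 1 - sum(t^3 - t) / (b k (k^2 - 1))`, referred to a chi-square with
#' `k - 1` degrees of freedom. A table whose blocks are all constant has no
#' rank information: the statistic is 0 and p = 1.
#'
#' @param table a [score_block_table()] (or coercible matrix).
#' @return a `friedman_test` list: `chi2`, `df`, `p`, `rank_means`,
#'   `n_blocks`, `n_treatments`.
#' @export
friedman_rank_test <- function(table) {
  x <- score_block_table(table)
  b <- nrow(x); k <- ncol(x)
  br <- block_ranks(x)
  Rj <- colSums(br$ranks)
  C <- 1 - br$tie_sum / (b * k * (k^2 - 1))
  raw <- 12 / (b * k * (k + 1)) * sum((Rj - b * (k + 1) / 2)^2)
  if (C <= 0) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- raw / C
    p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  }
  structure(list(chi2 = chi2, df = k - 1L, p = p,
                 rank_means = stats::setNames(Rj / b, colnames(x)),
                 n_blocks = b, n_treatments = k),
            class = "friedman_test")
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi2 = %.3f, df = %d, p = %.4g (%d blocks x %d treatments)\n",
              x$chi2, x$df, x$p, x$n_blocks, x$n_treatments))
  invisible(x)
}

#' Tukey-Kramer post hoc on Friedman rank means
#'
#' Compares every treatment pair on within-block rank means using the
#' studentized-range distribution. Under the null the rank mean of one
#' treatment has standard deviation `sqrt(k (k+1) / (12 b))`, so a pair
#' differs at level `alpha` when `|R_i - R_j|` exceeds
#' `qtukey(1 - alpha, k, Inf) * sqrt(k (k+1) / (12 b))`.
#'
#' @param table a [score_block_table()].
#' @param alpha familywise significance level.
#' @return a `tukey_kramer` data.frame with one row per pair: rank means,
#'   difference, adjusted p-value and significance flag; the critical
#'   difference is in the `crit_diff` attribute.
#' @export
tukey_kramer_posthoc <- function(table, alpha = 0.05) {
  x <- score_block_table(table)
  b <- nrow(x); k <- ncol(x)
  rank_means <- colMeans(block_ranks(x)$ranks)
  se <- sqrt(k * (k + 1) / (12 * b))
  crit <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) * se
  pairs <- utils::combn(k, 2)
  d <- rank_means[pairs[1, ]] - rank_means[pairs[2, ]]
  p_adj <- stats::ptukey(abs(d) / se, nmeans = k, df = Inf, lower.tail = FALSE)
  out <- data.frame(treatment_i = colnames(x)[pairs[1, ]],
                    treatment_j = colnames(x)[pairs[2, ]],
                    rank_mean_i = unname(rank_means[pairs[1, ]]),
                    rank_mean_j = unname(rank_means[pairs[2, ]]),
                    diff = unname(d),
                    p_adj = unname(p_adj),
                    significant = unname(abs(d) > crit),
                    row.names = NULL)
  structure(out, crit_diff = crit, alpha = alpha,
            class = c("tukey_kramer", "data.frame"))
}
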