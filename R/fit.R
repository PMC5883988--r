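#' Simulated connectivity from an activity raster
#'
#' Column-wise Pearson correlation of the binary activity record, giving the
#' simulated region-by-region connectivity. Constant columns (a node that
#' never or always fired) have undefined correlations; their entries are set
#' to 0 so matrix dimensions stay fixed across replicates, and the count of
#' such columns is recorded in the `n_constant` attribute (with a warning
#' when any occur).
#'
#' @param raster a `ser_raster` or any numeric steps x regions matrix with
#'   at least 3 rows.
#' @return a [conn_matrix()] with attribute `n_constant`.
#' @export
raster_connectivity <- function(raster) {
  x <- unclass(raster)
  if (nrow(x) < 3L) stop("raster needs at least 3 steps to correlate")
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  n_const <- sum(sds == 0)
  if (n_const > 0)
    warning(n_const, " constant column(s) in raster; their correlations set to 0")
  C <- suppressWarnings(stats::cor(x))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  out <- conn_matrix(C, colnames(x))
  attr(out, "n_constant") <- n_const
  out
}

upper_vec <- function(m) unclass(m)[upper.tri(m)]

#' Goodness-of-fit between simulated and target connectivity
#'
#' Pearson correlation between the vectorized upper-triangle (diagonal
#' excluded) entries of the two matrices. By default the target is its
#' positive part (negative entries zeroed), matching the protocol of
#' reproducing the empirical positive connectivity; `target_part = "signed"`
#' scores against the full signed target. If either vector has zero
#' variance the score is undefined and `NA` is returned with a warning.
#'
#' @param sim,target [conn_matrix()] objects with matching labels.
#' @param target_part `"positive"` (default) or `"signed"`.
#' @return a single correlation, or `NA_real_` if undefined.
#' @export
goodness_of_fit <- function(sim, target, target_part = c("positive", "signed")) {
  target_part <- match.arg(target_part)
  if (!identical(dim(sim), dim(target)))
    stop("simulated and target matrices have different dimensions")
  if (!identical(rownames(sim), rownames(target)))
    stop("simulated and target matrices have different region labels")
  a <- upper_vec(sim)
  b <- upper_vec(target)
  if (target_part == "positive") b <- pmax(b, 0)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("goodness-of-fit undefined: zero variance in upper-triangle vector")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Replicate goodness-of-fit protocol
#'
#' Runs `simulate -> raster_connectivity -> goodness_of_fit` for
#' `n_replicates` independent replicates, replicate `k` using seed
#' `base_seed + k - 1`, and aggregates the scores. Undefined scores are
#' excluded from the mean (not zero-filled) and their count reported.
#'
#' @param network a `signed_network` background.
#' @param params a [ser_params()].
#' @param target target [conn_matrix()].
#' @param n_replicates number of replicates (standard protocol: 100).
#' @param n_steps steps per simulation (standard protocol: 200).
#' @param base_seed seed of the first replicate.
#' @param target_part passed to [goodness_of_fit()].
#' @param strict passed to [local_fields()].
#' @return a `fit_score` list: `mean_r`, `sd_r`, `n_replicates` (scores
#'   used), `n_undefined`.
#' @export
replicate_fit <- function(network, params, target,
                          n_replicates = 100L, n_steps = 200L,
                          base_seed = 1L, target_part = "positive",
                          strict = FALSE) {
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L)
  scores <- vapply(seq_len(n_replicates), function(k) {
    raster <- ser_simulate(network, params, n_steps = n_steps,
                           seed = base_seed + k - 1L, strict = strict)
    sim <- suppressWarnings(raster_connectivity(raster))
    suppressWarnings(goodness_of_fit(sim, target, target_part = target_part))
  }, numeric(1))
  ok <- scores[!is.na(scores)]
  if (!length(ok))
    stop("all ", n_replicates, " replicates produced undefined goodness-of-fit")
  structure(list(mean_r = mean(ok),
                 sd_r = if (length(ok) > 1L) stats::sd(ok) else 0,
                 n_replicates = length(ok),
                 n_undefined = n_replicates - length(ok)),
            class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat(sprintf("<fit_score> mean r = %.4f (sd %.4f, n = %d, %d undefined)\n",
              x$mean_r, x$sd_r, x$n_replicates, x$n_undefined))
  invisible(x)
}

#' Sweep grids mirroring the three simulation series
#'
#' `sweep_grid_series1()`: absolute-threshold backgrounds over the 20-level
#' cost grid, with coarse dynamics (`sop`, `nep` in \{0.25, 0.5, 0.75\} and
#' the locked threshold couple `pi_p = pi_n` from 0.1 to 1 in 0.1 steps).
#' `sweep_grid_series2()`: the refinement around the low-excitability corner
#' (`sop`, `nep` 0.025-0.25 step 0.025; thresholds 0.025-0.1 step 0.025).
#' `sweep_grid_series3()`: dynamics locked at the optimum (`sop = 0.025`,
#' `nep = 0.225`, thresholds 0.1) while the background varies over the
#' 15 x 7 signed-threshold factorial.
#'
#' @param costs cost levels for the absolute-threshold series.
#' @param sop,nep,pi values for the locked parameters of series 3.
#' @return data.frame with columns `scheme`, `cost`, `positive_cost`,
#'   `negative_cost`, `sop`, `nep`, `pi_p`, `pi_n`, one row per combination.
#' @export
sweep_grid_series1 <- function(costs = cost_grid_absolute()) {
  g <- expand.grid(cost = costs, sop = c(0.25, 0.5, 0.75),
                   nep = c(0.25, 0.5, 0.75), pi = seq(0.1, 1, by = 0.1),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(scheme = "absolute", cost = g$cost,
             positive_cost = NA_real_, negative_cost = NA_real_,
             sop = g$sop, nep = g$nep, pi_p = g$pi, pi_n = g$pi)
}

#' @rdname sweep_grid_series1
#' @export
sweep_grid_series2 <- function(costs = cost_grid_absolute()) {
  g <- expand.grid(cost = costs, sop = seq(0.025, 0.25, by = 0.025),
                   nep = seq(0.025, 0.25, by = 0.025),
                   pi = seq(0.025, 0.1, by = 0.025), KEEP.OUT.ATTRS = FALSE)
  data.frame(scheme = "absolute", cost = g$cost,
             positive_cost = NA_real_, negative_cost = NA_real_,
             sop = g$sop, nep = g$nep, pi_p = g$pi, pi_n = g$pi)
}

#' @rdname sweep_grid_series1
#' @export
sweep_grid_series3 <- function(sop = 0.025, nep = 0.225, pi = 0.1) {
  g <- expand.grid(positive_cost = cost_grid_positive(),
                   negative_cost = cost_grid_negative(),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(scheme = "signed", cost = NA_real_,
             positive_cost = g$positive_cost,
             negative_cost = g$negative_cost,
             sop = sop, nep = nep, pi_p = pi, pi_n = pi)
}

# Background network for one sweep row. A row with zero total cost has an
# empty background (uncoupled dynamics), which is legal.
sweep_row_network <- function(conn, row) {
  if (row$scheme == "absolute") {
    threshold_absolute(conn, row$cost)
  } else {
    suppressWarnings(threshold_signed(conn, row$positive_cost, row$negative_cost))
  }
}

#' Run a goodness-of-fit sweep
#'
#' Evaluates [replicate_fit()] for every row of a sweep grid, thresholding
#' `conn` into the row's background network. Row `i` uses seeds
#' `base_seed + (i-1) * n_replicates ...`, so every combination owns a
#' disjoint seed range and results are identical whether rows are run
#' serially, resumed, or in any order. If `checkpoint` names a CSV file,
#' finished rows are appended there and an interrupted sweep resumes past
#' them.
#'
#' @param conn background source [conn_matrix()].
#' @param target target [conn_matrix()].
#' @param grid data.frame as produced by the `sweep_grid_series*()`
#'   constructors (columns `scheme`, `cost`, `positive_cost`,
#'   `negative_cost`, `sop`, `nep`, `pi_p`, `pi_n`).
#' @param n_replicates,n_steps,base_seed,target_part,strict protocol
#'   settings, see [replicate_fit()].
#' @param checkpoint optional CSV path for streaming/resuming results.
#' @param verbose print progress every 50 rows.
#' @return a `sweep_result`: the grid with `mean_r`, `sd_r`,
#'   `n_replicates`, `n_undefined` columns appended, and an `argmax`
#'   attribute holding the best row.
#' @export
sweep_fit <- function(conn, target, grid, n_replicates = 100L,
                      n_steps = 200L, base_seed = 1L,
                      target_part = "positive", strict = FALSE,
                      checkpoint = NULL, verbose = FALSE) {
  stopifnot(nrow(grid) >= 1L)
  need <- c("scheme", "cost", "positive_cost", "negative_cost",
            "sop", "nep", "pi_p", "pi_n")
  if (!all(need %in% names(grid)))
    stop("grid is missing columns: ",
         paste(setdiff(need, names(grid)), collapse = ", "))
  res <- grid
  res$mean_r <- NA_real_
  res$sd_r <- NA_real_
  res$n_replicates <- NA_integer_
  res$n_undefined <- NA_integer_

  done <- integer(0)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- utils::read.csv(checkpoint)
    done <- prev$row
    res[done, c("mean_r", "sd_r", "n_replicates", "n_undefined")] <-
      prev[, c("mean_r", "sd_r", "n_replicates", "n_undefined")]
  }
  for (i in setdiff(seq_len(nrow(grid)), done)) {
    row <- grid[i, ]
    net <- sweep_row_network(conn, row)
    params <- ser_params(row$sop, row$nep, row$pi_p, row$pi_n)
    fs <- replicate_fit(net, params, target,
                        n_replicates = n_replicates, n_steps = n_steps,
                        base_seed = base_seed + (i - 1L) * n_replicates,
                        target_part = target_part, strict = strict)
    res[i, c("mean_r", "sd_r")] <- c(fs$mean_r, fs$sd_r)
    res[i, c("n_replicates", "n_undefined")] <- c(fs$n_replicates, fs$n_undefined)
    if (!is.null(checkpoint)) {
      line <- cbind(row = i, res[i, c("mean_r", "sd_r", "n_replicates", "n_undefined")])
      utils::write.table(line, checkpoint, sep = ",", row.names = FALSE,
                         col.names = !file.exists(checkpoint), append = file.exists(checkpoint))
    }
    if (verbose && i %% 50L == 0L)
      message("sweep: ", i, "/", nrow(grid), " combinations done")
  }
  best <- which.max(res$mean_r)
  structure(res, argmax = res[best, ], class = c("sweep_result", "data.frame"))
}

#' Best combination of a sweep
#' @param result a `sweep_result`.
#' @return the argmax row (a one-row data.frame).
#' @export
sweep_argmax <- function(result) attr(result, "argmax")
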