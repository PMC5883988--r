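#' Region-by-time panel
#'
#' Container for one subject's activity panel: rows are timepoints, columns
#' are regions. Panels are the raw input from which signed Pearson
#' connectivity is estimated.
#'
#' @param values numeric matrix, timepoints x regions.
#' @param region_labels character vector of region names; defaults to the
#'   matrix column names or `R1..Rn`.
#' @param subject_id single string identifying the subject.
#' @return an object of class `ts_panel`.
#' @export
ts_panel <- function(values, region_labels = NULL, subject_id = "subject") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 3L)
    stop("a panel needs at least 3 timepoints, got ", nrow(values))
  if (ncol(values) < 2L)
    stop("a panel needs at least 2 regions, got ", ncol(values))
  if (anyNA(values))
    stop("panel for subject '", subject_id, "' contains missing values")
  if (is.null(region_labels)) region_labels <- colnames(values)
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values))
    stop("region_labels length (", length(region_labels),
         ") does not match region count (", ncol(values), ")")
  colnames(values) <- region_labels
  structure(list(values = values,
                 region_labels = as.character(region_labels),
                 subject_id = as.character(subject_id)),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("<ts_panel> subject '", x$subject_id, "': ",
      nrow(x$values), " timepoints x ", ncol(x$values), " regions\n", sep = "")
  invisible(x)
}

#' Signed connectivity matrix
#'
#' A symmetric region-by-region matrix of signed Pearson correlations, with
#' unit diagonal. The diagonal is ignored by all downstream operations.
#'
#' @param values numeric square matrix with entries in `[-1, 1]`.
#' @param region_labels character vector of region names.
#' @param tol symmetry tolerance.
#' @return an object of class `conn_matrix` (a matrix with a class attribute).
#' @export
conn_matrix <- function(values, region_labels = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square")
  if (anyNA(values))
    stop("connectivity matrix contains missing values")
  if (max(abs(values - t(values))) > tol)
    stop("connectivity matrix is not symmetric within tolerance ", tol)
  values <- (values + t(values)) / 2
  off <- values[upper.tri(values)]
  if (any(off < -1 - tol | off > 1 + tol))
    stop("off-diagonal correlations outside [-1, 1]")
  diag(values) <- 1
  if (is.null(region_labels)) region_labels <- colnames(values)
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(values)))
  dimnames(values) <- list(region_labels, region_labels)
  structure(values, class = c("conn_matrix", "matrix", "array"))
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat("<conn_matrix> ", nrow(x), " regions; off-diagonal range [",
      sprintf("%.3f", min(x[upper.tri(x)])), ", ",
      sprintf("%.3f", max(x[upper.tri(x)])), "]\n", sep = "")
  invisible(x)
}

region_labels <- function(x) {
  if (inherits(x, "ts_panel")) x$region_labels else rownames(x)
}

#' Signed Pearson connectivity from a panel
#'
#' Correlates every pair of region time series, keeping both correlation
#' signs. Columns with zero variance cannot be correlated and raise an error
#' naming the offending region.
#'
#' @param panel a [ts_panel()].
#' @return a [conn_matrix()].
#' @export
pearson_connectivity <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  sds <- apply(panel$values, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s) in subject '", panel$subject_id, "': ",
         paste(panel$region_labels[sds == 0], collapse = ", "))
  conn_matrix(stats::cor(panel$values), panel$region_labels)
}

#' Group-average connectivity
#'
#' Entry-wise arithmetic mean of per-subject connectivity matrices, the
#' group-level background used for simulation and fitting.
#'
#' @param matrices list of [conn_matrix()] objects sharing labels/dimensions.
#' @return a [conn_matrix()].
#' @export
group_average <- function(matrices) {
  if (!length(matrices)) stop("no matrices to average")
  if (!all(vapply(matrices, inherits, logical(1), "conn_matrix")))
    stop("all elements must be conn_matrix objects")
  ref <- rownames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(rownames(m), ref))
      stop("matrices have mismatched region labels or dimensions")
  }
  acc <- Reduce(`+`, lapply(matrices, unclass))
  conn_matrix(acc / length(matrices), ref)
}

# Round-half-up with a tiny relative guard: cost grids are multiples of 0.05
# whose product with the pair count may land a hair under x.5 in binary
# floating point (e.g. 0.35 * 5460).
round_half_up <- function(x) as.integer(floor(x + 0.5 + 1e-9))

# All unordered off-diagonal pairs (i < j) with their correlation, in
# lexicographic (i, j) order -- the documented deterministic tie-break.
upper_pairs <- function(conn) {
  n <- nrow(conn)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  data.frame(i = i, j = j, r = conn[cbind(i, j)])
}

new_signed_network <- function(adjacency, labels, scheme,
                               positive_cost, negative_cost) {
  dimnames(adjacency) <- list(labels, labels)
  structure(adjacency,
            scheme = scheme,
            positive_cost = positive_cost,
            negative_cost = negative_cost,
            class = c("signed_network", "matrix", "array"))
}

#' @export
print.signed_network <- function(x, ...) {
  P <- nrow(x) * (nrow(x) - 1L) / 2
  np <- sum(x[upper.tri(x)] > 0); nn <- sum(x[upper.tri(x)] < 0)
  cat("<signed_network> ", nrow(x), " regions, scheme '", attr(x, "scheme"),
      "': ", np, " positive / ", nn, " negative links (density ",
      sprintf("%.3f", (np + nn) / P), ")\n", sep = "")
  invisible(x)
}

#' Absolute-value proportional threshold
#'
#' Keeps the `cost` fraction of region pairs with the largest absolute
#' correlation, each link carrying the sign of its correlation. `cost` is the
#' network density: the number of retained links is `round(cost * P)` with
#' `P = R(R-1)/2` (round half up). Ties in `|r|` are broken by lexicographic
#' pair order so networks are reproducible.
#'
#' @param conn a [conn_matrix()].
#' @param cost fraction of pairs to keep, in `(0, 1]`.
#' @return a `signed_network`: integer matrix in `{-1, 0, +1}` with
#'   attributes `scheme = "absolute"` and the realized `positive_cost` /
#'   `negative_cost` fractions.
#' @export
threshold_absolute <- function(conn, cost) {
  stopifnot(inherits(conn, "conn_matrix"))
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0 || cost > 1)
    stop("cost must be a single value in (0, 1]")
  pairs <- upper_pairs(conn)
  P <- nrow(pairs)
  k <- min(round_half_up(cost * P), P)
  sel <- pairs[order(-abs(pairs$r), pairs$i, pairs$j)[seq_len(k)], , drop = FALSE]
  adj <- matrix(0L, nrow(conn), ncol(conn))
  if (k > 0L) {
    s <- ifelse(sel$r >= 0, 1L, -1L)
    adj[cbind(sel$i, sel$j)] <- s
    adj[cbind(sel$j, sel$i)] <- s
  }
  new_signed_network(adj, rownames(conn), "absolute",
                     positive_cost = sum(sel$r >= 0) / P,
                     negative_cost = sum(sel$r < 0) / P)
}

#' Signed-value proportional threshold
#'
#' Selects the strongest positive and the strongest negative correlations
#' independently: `round(positive_cost * P)` pairs with the largest positive
#' `r` become `+1` links and `round(negative_cost * P)` pairs with the most
#' negative `r` become `-1` links. The two selections are disjoint by
#' construction. A cost of 0 on either sign yields no links of that sign.
#' If the matrix holds fewer pairs of the requested sign than the cost
#' demands, all available pairs are taken and a warning is issued.
#'
#' @param conn a [conn_matrix()].
#' @param positive_cost,negative_cost fractions in `[0, 1]`, summing to at
#'   most 1.
#' @return a `signed_network` with `scheme = "signed"`.
#' @export
threshold_signed <- function(conn, positive_cost, negative_cost) {
  stopifnot(inherits(conn, "conn_matrix"))
  for (cc in c(positive_cost, negative_cost))
    if (!is.numeric(cc) || length(cc) != 1L || cc < 0 || cc > 1)
      stop("costs must be single values in [0, 1]")
  if (positive_cost + negative_cost > 1 + 1e-9)
    stop("positive_cost + negative_cost must not exceed 1")
  pairs <- upper_pairs(conn)
  P <- nrow(pairs)
  kp <- round_half_up(positive_cost * P)
  kn <- round_half_up(negative_cost * P)

  pos <- pairs[pairs$r > 0, , drop = FALSE]
  neg <- pairs[pairs$r < 0, , drop = FALSE]
  if (kp > nrow(pos)) {
    warning("requested ", kp, " positive links but only ", nrow(pos),
            " positive correlations available; taking all")
    kp <- nrow(pos)
  }
  if (kn > nrow(neg)) {
    warning("requested ", kn, " negative links but only ", nrow(neg),
            " negative correlations available; taking all")
    kn <- nrow(neg)
  }
  adj <- matrix(0L, nrow(conn), ncol(conn))
  if (kp > 0L) {
    sp <- pos[order(-pos$r, pos$i, pos$j)[seq_len(kp)], , drop = FALSE]
    adj[cbind(sp$i, sp$j)] <- 1L
    adj[cbind(sp$j, sp$i)] <- 1L
  }
  if (kn > 0L) {
    sn <- neg[order(neg$r, neg$i, neg$j)[seq_len(kn)], , drop = FALSE]
    stopifnot(all(adj[cbind(sn$i, sn$j)] == 0L))  # signs partition the pairs
    adj[cbind(sn$i, sn$j)] <- -1L
    adj[cbind(sn$j, sn$i)] <- -1L
  }
  new_signed_network(adj, rownames(conn), "signed",
                     positive_cost = kp / P, negative_cost = kn / P)
}

#' Cost grids for proportional thresholding
#'
#' The three standard density grids: the absolute-value series spans 5% to
#' 100% in 5% steps (20 non-empty networks), while the signed series include
#' the empty 0% level: positive costs 0-70% (15 levels) and negative costs
#' 0-30% (7 levels), giving a 15 x 7 = 105 combined factorial.
#'
#' @return numeric vector of cost fractions.
#' @export
cost_grid_absolute <- function() seq(0.05, 1, by = 0.05)

#' @rdname cost_grid_absolute
#' @export
cost_grid_positive <- function() seq(0, 0.70, by = 0.05)

#' @rdname cost_grid_absolute
#' @export
cost_grid_negative <- function() seq(0, 0.30, by = 0.05)

#' Number of links in a signed network
#' @param network a `signed_network`.
#' @return named integer vector with `positive`, `negative`, `total` counts
#'   of unordered linked pairs.
#' @export
link_count <- function(network) {
  ut <- network[upper.tri(network)]
  c(positive = sum(ut > 0L), negative = sum(ut < 0L), total = sum(ut != 0L))
}
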