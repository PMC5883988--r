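test_that("raster_connectivity handles degenerate and regular rasters", {
  r <- matrix(c(0, 1, 0, 1, 0, 1,
                0, 1, 0, 1, 0, 1,
                1, 0, 1, 0, 1, 0), 6, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  cm <- raster_connectivity(r)
  expect_equal(cm["a", "b"], 1.0)
  expect_equal(cm["a", "c"], -1.0)

  expect_warning(z <- raster_connectivity(matrix(0L, 10, 4)), "constant")
  expect_equal(unclass(z)[upper.tri(z)], rep(0, 6))
  expect_equal(attr(z, "n_constant"), 4L)

  expect_error(raster_connectivity(matrix(0L, 2, 3)), "3 steps")

  set.seed(8)
  x <- matrix(rbinom(200, 1, 0.4), 50, 4)
  expect_equal(unclass(raster_connectivity(x)), oracle_pearson(x),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("goodness_of_fit is the upper-triangle Pearson correlation", {
  tgt <- random_conn(6, 3)
  pos <- conn_matrix(abs(unclass(tgt)))   # all-positive target
  expect_equal(goodness_of_fit(pos, pos), 1.0)
  negated <- conn_matrix(-unclass(pos) + 2 * diag(1, 6))
  expect_equal(goodness_of_fit(negated, pos), -1.0)

  sim <- random_conn(6, 4)
  a <- unclass(sim)[upper.tri(sim)]
  b <- pmax(unclass(tgt)[upper.tri(tgt)], 0)
  sxy <- sum(a * b) - 15 * mean(a) * mean(b)      # textbook formula
  expect_equal(goodness_of_fit(sim, tgt),
               sxy / sqrt((sum(a^2) - 15 * mean(a)^2) * (sum(b^2) - 15 * mean(b)^2)),
               tolerance = 1e-12)
  # the signed switch uses the raw target and differs when negatives exist
  expect_false(isTRUE(all.equal(goodness_of_fit(sim, tgt),
                                goodness_of_fit(sim, tgt, target_part = "signed"))))

  flat <- conn_matrix(matrix(0, 6, 6) + diag(1, 6))
  expect_warning(expect_true(is.na(goodness_of_fit(flat, tgt))), "undefined")
  expect_error(goodness_of_fit(random_conn(5, 1), tgt), "dimensions")
})

test_that("replicate_fit aggregates seeded replicates as documented", {
  st <- tiny_study()
  net <- threshold_absolute(st$group, 0.2)
  p <- ser_params(0.1, 0.2, 0.1)

  one <- replicate_fit(net, p, st$group, n_replicates = 1, n_steps = 100,
                       base_seed = 21)
  manual <- goodness_of_fit(
    suppressWarnings(raster_connectivity(ser_simulate(net, p, 100, seed = 21))),
    st$group)
  expect_equal(one$mean_r, manual)
  expect_equal(one$sd_r, 0)
  expect_equal(one$n_replicates, 1L)

  # replicate k uses base_seed + k - 1: the two-replicate mean is the mean
  # of the two manually seeded scores
  two <- replicate_fit(net, p, st$group, n_replicates = 2, n_steps = 100,
                       base_seed = 21)
  manual2 <- goodness_of_fit(
    suppressWarnings(raster_connectivity(ser_simulate(net, p, 100, seed = 22))),
    st$group)
  expect_equal(two$mean_r, mean(c(manual, manual2)))

  # all-undefined replicates error out (sop = 0 on an empty network never fires)
  empty <- threshold_signed(st$group, 0, 0)
  expect_error(
    suppressWarnings(replicate_fit(empty, ser_params(0, 0.5, 0.5), st$group,
                                   n_replicates = 2, n_steps = 10, base_seed = 1)),
    "undefined")
})

test_that("standard error of the replicate mean shrinks like 1/sqrt(n)", {
  st <- tiny_study()
  net <- threshold_absolute(st$group, 0.2)
  p <- ser_params(0.1, 0.2, 0.1)
  # disjoint-seed batches: sd of batch means at n=4 vs n=16 should shrink
  # by about 2 (checked within a loose factor; sampling theory only)
  batch_means <- function(n_rep, n_batch)
    vapply(seq_len(n_batch), function(b)
      replicate_fit(net, p, st$group, n_replicates = n_rep, n_steps = 80,
                    base_seed = 1000 + (b - 1) * n_rep)$mean_r, numeric(1))
  s4 <- stats::sd(batch_means(4, 8))
  s16 <- stats::sd(batch_means(16, 8))
  expect_lt(s16, s4)
  expect_gt(s16, s4 / 6)
})

test_that("sweep_fit covers the grid deterministically and finds the argmax", {
  st <- tiny_study()
  grid1 <- sweep_grid_series3(sop = 0.1, nep = 0.2, pi = 0.1)[50, ]
  res1 <- sweep_fit(st$group, st$group, grid1, n_replicates = 3, n_steps = 80,
                    base_seed = 11)
  net <- suppressWarnings(threshold_signed(st$group, grid1$positive_cost,
                                           grid1$negative_cost))
  direct <- replicate_fit(net, ser_params(0.1, 0.2, 0.1), st$group,
                          n_replicates = 3, n_steps = 80, base_seed = 11)
  expect_equal(res1$mean_r, direct$mean_r)
  expect_equal(res1$sd_r, direct$sd_r)

  grid <- sweep_grid_series3(sop = 0.1, nep = 0.2, pi = 0.1)[c(1, 40, 80), ]
  resA <- sweep_fit(st$group, st$group, grid, n_replicates = 2, n_steps = 60,
                    base_seed = 5)
  resB <- sweep_fit(st$group, st$group, grid, n_replicates = 2, n_steps = 60,
                    base_seed = 5)
  expect_identical(as.data.frame(resA), as.data.frame(resB))
  expect_equal(sweep_argmax(resA)$mean_r, max(resA$mean_r))
  expect_true(all(resA$mean_r >= -1 & resA$mean_r <= 1))
  expect_true(all(resA$sd_r >= 0))

  expect_error(sweep_fit(st$group, st$group, grid[, 1:3]), "missing columns")
})

test_that("checkpointed sweeps resume to identical results", {
  st <- tiny_study()
  grid <- sweep_grid_series3(sop = 0.1, nep = 0.2, pi = 0.1)[c(10, 60, 100), ]
  ck <- tempfile(fileext = ".csv")
  full <- sweep_fit(st$group, st$group, grid, n_replicates = 2, n_steps = 60,
                    base_seed = 9)
  # simulate an interruption after row 1: keep only its checkpoint line
  sweep_fit(st$group, st$group, grid[1, ], n_replicates = 2, n_steps = 60,
            base_seed = 9, checkpoint = ck)
  resumed <- sweep_fit(st$group, st$group, grid, n_replicates = 2, n_steps = 60,
                       base_seed = 9, checkpoint = ck)
  expect_equal(as.data.frame(resumed), as.data.frame(full))
})

test_that("a shuffled target carries no information", {
  st <- tiny_study()
  net <- threshold_absolute(st$group, 0.2)
  p <- ser_params(0.1, 0.2, 0.1)
  set.seed(13)
  shuf <- unclass(st$group)[upper.tri(st$group)]
  shuf <- sample(shuf)
  m <- diag(1, 30)
  m[upper.tri(m)] <- shuf
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  target <- conn_matrix(m, rownames(st$group))
  fs <- replicate_fit(net, p, target, n_replicates = 20, n_steps = 100,
                      base_seed = 77)
  expect_lt(abs(fs$mean_r), 3 * fs$sd_r / sqrt(fs$n_replicates) + 0.05)
})

test_that("series grid constructors enumerate the printed designs", {
  g1 <- sweep_grid_series1()
  expect_equal(nrow(g1), 20 * 3 * 3 * 10)
  expect_true(all(g1$pi_p == g1$pi_n))  # threshold couple locked
  g2 <- sweep_grid_series2()
  expect_equal(nrow(g2), 20 * 10 * 10 * 4)
  expect_equal(range(g2$sop), c(0.025, 0.25))
  expect_equal(range(g2$pi_p), c(0.025, 0.1))
  g3 <- sweep_grid_series3()
  expect_equal(nrow(g3), 105)
  expect_equal(unique(g3$sop), 0.025)
  expect_equal(unique(g3$nep), 0.225)
})
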