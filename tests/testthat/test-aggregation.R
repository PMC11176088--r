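## small regular array fixture built through the extraction path
fix <- two_chrom_store(seed = 55)
qs <- bins_to_pairset(fix$cs, 1000, "chrA", c(10, 20, 30), c(20, 32, 44))
arr <- pull_submatrices(fix$store,
                        suppressMessages(drop_out_of_range(expand_pixels(qs, 1))),
                        extraction_config())

test_that("aggregation reductions match brute-force accumulation", {
  x <- counts(arr)                          # 3 x 3 x 3 x 1
  want_sum <- x[, , 1, 1] + x[, , 2, 1] + x[, , 3, 1]
  ag <- agg_matrices(arr, by = "both", fn = "sum")
  expect_equal(ag$values, want_sum)
  expect_true(all(ag$n_contributing == 3))
  expect_equal(agg_matrices(arr, by = "both", fn = "mean")$values, want_sum / 3)
  med <- agg_matrices(arr, by = "both", fn = "median")$values
  expect_equal(med, apply(x[, , , 1], c(1, 2), stats::median))
  ## by files: one matrix per interaction, equal to its own slice
  byf <- agg_matrices(arr, by = "files", fn = "mean")
  for (p in 1:3) expect_equal(byf[, , p], x[, , p, 1])
  ## a single-matrix aggregate is the matrix itself
  one <- pull_submatrices(fix$store,
                          suppressMessages(drop_out_of_range(expand_pixels(qs[1, ], 1))),
                          extraction_config())
  expect_equal(agg_matrices(one, "both", "mean")$values, submatrix(one, 1))
})

test_that("missing cells are excluded with contribution tracking", {
  w <- rep(1, 80); w[21] <- NA      # bin 20 (0-based) unweighted
  fw <- two_chrom_store(seed = 55, weights = w)
  ar <- pull_submatrices(fw$store,
                         suppressMessages(drop_out_of_range(expand_pixels(qs, 1))),
                         extraction_config("balanced"))
  ag <- agg_matrices(ar, by = "both", fn = "mean")
  ## the missing row/col of pair 1 reduces contributions there
  expect_true(any(ag$n_contributing < 3))
  expect_true(all(is.finite(ag$values[ag$n_contributing > 0])))
  ## mean over the one contributing value equals that value
  x <- counts(ar)
  cellwise <- apply(x, c(1, 2), function(v) mean(v, na.rm = TRUE))
  expect_equal(ag$values, cellwise)
})

test_that("jagged stacks must be regularized before aggregation", {
  bp <- bins_to_pairset(fix$cs, 1000, "chrA", c(10, 30), c(10, 30))
  bp$r1 <- bp$bin1; bp$r2 <- bp$bin1 + c(3L, 5L)
  bp$c1 <- bp$bin2; bp$c2 <- bp$bin2 + c(3L, 5L)
  ja <- pull_submatrices(fix$store, bp, extraction_config())
  expect_error(agg_matrices(ja), "regularize")
  reg <- regularize(ja, ndim = 4)
  expect_s3_class(reg, "SubmatrixArray")
  expect_equal(reg$dims, c(4L, 4L))
  expect_s3_class(agg_matrices(reg, "both", "mean"), "AggregateMatrix")
})

test_that("bilinear regularization is exact on known cases", {
  ## native size passes through unchanged
  reg <- regularize(arr, ndim = 3)
  for (p in 1:3) expect_equal(submatrix(reg, p), submatrix(arr, p))
  ## the 2x2 -> 3x3 midpoint case
  expect_equal(hicblocks:::.resample_bilinear(matrix(c(0, 2, 2, 4), 2), 3),
               matrix(c(0, 1, 2, 1, 2, 3, 2, 3, 4), 3))
  ## agreement with the independent nearest-4-neighbour oracle
  set.seed(8)
  for (dims in list(c(2, 2), c(3, 5), c(7, 4), c(6, 6))) {
    m <- matrix(stats::runif(prod(dims)), dims[1], dims[2])
    for (nd in c(2, 3, 5, 8))
      expect_equal(hicblocks:::.resample_bilinear(m, nd), bilinear_oracle(m, nd),
                   tolerance = 1e-12)
  }
  ## sum preservation on demand
  bp <- bins_to_pairset(fix$cs, 1000, "chrA", 10, 25)
  bp$r1 <- bp$bin1; bp$r2 <- bp$bin1 + 4L
  bp$c1 <- bp$bin2; bp$c2 <- bp$bin2 + 6L
  ja <- pull_submatrices(fix$store, bp, extraction_config())
  sc <- regularize(ja, ndim = 9, scale_to_sum = TRUE)
  expect_equal(sum(submatrix(sc, 1)), sum(submatrix(ja, 1)),
               tolerance = 1e-9)
})

test_that("APA pileups center on planted loops and match pixel pulls", {
  lm <- loop_map(n_loops = 30, depth = 400, fold = 5, seed = 37)
  calls <- truth_loop_calls(lm$truth)
  aggs <- suppressMessages(pileup_pixels(lm$store, calls, buffer_bins = 5))
  apa <- aggs[[1]]
  expect_equal(which.max(apa$values), 61L)        # center of the 11x11 grid
  ## center equals the mean of pull_pixels over the same surviving pairs
  bp <- snap_to_bins(calls, lm$binsize)
  ex <- suppressMessages(remove_short_pairs(
    drop_out_of_range(expand_pixels(bp, 5)), 5))
  ctr <- mean(counts(pull_pixels(lm$store, ex[, setdiff(names(ex),
                                                        c("r1", "r2", "c1", "c2"))])))
  expect_equal(apa$values[6, 6], ctr)
  ## singleton pileup equals the single submatrix
  one <- suppressMessages(pileup_pixels(lm$store, calls[1, ], buffer_bins = 3))
  sub <- fetch_block(lm$store, c(bp$bin1[1] - 3, bp$bin1[1] + 4),
                     c(bp$bin2[1] - 3, bp$bin2[1] + 4))$values
  expect_equal(one[[1]]$values, sub)
  expect_error(suppressMessages(pileup_pixels(lm$store, calls[0, ])), "no pairs|empty|0")
})

test_that("domain pileups concentrate signal inside planted domains", {
  cs <- chrom_sizes("chrT", 3e6)
  tads <- data.frame(chrom = "chrT", start_bin = c(40, 120, 200),
                     end_bin = c(70, 160, 230), fold = 3)
  sim <- simulate_contact_map(map_spec(cs, 1e4, depth = 200, tads = tads,
                                       seed = 41))
  doms <- data.frame(chrom = "chrT", start = tads$start_bin * 1e4,
                     end = tads$end_bin * 1e4)
  aggs <- pileup_domains(sim$store, doms, ndim = 60)
  v <- aggs[[1]]$values
  ## window = domain +/- half its width: the domain occupies the middle half
  inside <- mean(v[16:45, 16:45])
  corner <- mean(v[1:10, 51:60])
  expect_gt(inside, corner)
  ## identity chain: one domain, no per-matrix norm, native size
  d1 <- data.frame(chrom = "chrT", start = 50e4, end = 60e4)
  a1 <- pileup_domains(sim$store, d1, buffer_frac = 0, ndim = 10,
                       per_matrix_norm = "none")
  raw <- fetch_block(sim$store, c(50, 60), c(50, 60))$values
  expect_equal(a1[[1]]$values, raw)
  ## expansion arithmetic: 100 kb domain with buffer_frac 0.5 -> 200 kb window
  a2 <- pileup_domains(sim$store, d1, buffer_frac = 0.5, ndim = 20,
                       per_matrix_norm = "none")
  expect_equal(dim(a2[[1]]$values), c(20L, 20L))
  raw2 <- fetch_block(sim$store, c(45, 65), c(45, 65))$values
  expect_equal(a2[[1]]$values, hicblocks:::.resample_bilinear(raw2, 20))
})

test_that("boundary pileups are centered, odd-sided, and quadrant-asymmetric", {
  cs <- chrom_sizes("chrT", 3e6)
  tads <- data.frame(chrom = "chrT", start_bin = c(40, 80, 120, 160),
                     end_bin = c(80, 120, 160, 200), fold = 3)
  sim <- simulate_contact_map(map_spec(cs, 1e4, depth = 200, tads = tads,
                                       seed = 43))
  bnd <- data.frame(chrom = "chrT", pos = c(40, 80, 120, 160, 200) * 1e4)
  aggs <- pileup_boundaries(sim$store, bnd, flank_bp = 1e5)
  v <- aggs[[1]]$values
  expect_equal(dim(v), c(21L, 21L))               # 2*10 + 1 bins
  ul <- mean(v[1:10, 1:10]); lr <- mean(v[12:21, 12:21]); ur <- mean(v[1:10, 12:21])
  expect_gt(mean(c(ul, lr)), ur)
  ## a single boundary equals its own block
  one <- pileup_boundaries(sim$store, bnd[2, , drop = FALSE], flank_bp = 5e4)
  raw <- fetch_block(sim$store, c(75, 86), c(75, 86))$values
  expect_equal(one[[1]]$values, raw)
})

test_that("pileups are invariant to input order", {
  lm <- loop_map(n_loops = 20, depth = 300, fold = 4, seed = 47)
  calls <- truth_loop_calls(lm$truth)
  perm <- sample(nrow(calls))
  a1 <- suppressMessages(pileup_pixels(lm$store, calls, buffer_bins = 4))
  a2 <- suppressMessages(pileup_pixels(lm$store, calls[perm, ], buffer_bins = 4))
  expect_equal(a1[[1]]$values, a2[[1]]$values)
})
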