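fix <- two_chrom_store(seed = 21)
qset <- bins_to_pairset(fix$cs, 1000, "chrA", c(2, 10, 25, 30), c(8, 20, 40, 44),
                        qid = 1:4)

test_that("block plans cover every query exactly once", {
  plan <- plan_blocks(qset, fix$store, extraction_config(block_span_bp = 10000))
  members <- sort(unlist(lapply(plan$blocks, `[[`, "members")))
  expect_equal(members, 1:4)
  ## pixels at 0.1, 0.2, 9.8 Mb with 1 Mb span: two share a tile
  cs <- chrom_sizes("chr1", 1e7)
  st1 <- {
    set.seed(5)
    n <- 1000
    simulate_contact_map(map_spec(cs, 1e4, depth = 5, seed = 5))$store
  }
  bp <- bins_to_pairset(cs, 1e4, "chr1", c(10, 20, 980), c(12, 22, 982))
  plan <- plan_blocks(bp, st1, extraction_config(block_span_bp = 1e6))
  expect_equal(plan$n_blocks, 2L)
  ## a single pixel always yields one block
  expect_equal(plan_blocks(bp[1, ], st1, extraction_config())$n_blocks, 1L)
  ## footprints larger than the block span are rejected with advice
  ex <- expand_pixels(bp, 2)
  expect_error(plan_blocks(ex, st1, extraction_config(block_span_bp = 4e4)),
               "block_span_bp")
})

test_that("pulled pixels equal dense-matrix lookups for every block span", {
  expect_ref <- dense_lookup(fix$full, qset$bin1, qset$bin2)
  for (span in c(1000, 10000, 50000)) {
    px <- pull_pixels(fix$store, qset, extraction_config(block_span_bp = span))
    expect_identical(as.vector(counts(px)), as.numeric(expect_ref))
  }
  ## shuffled query order lands in shuffled rows (order restored by input row)
  perm <- c(3, 1, 4, 2)
  px <- pull_pixels(fix$store, qset[perm, ], extraction_config())
  expect_identical(as.vector(counts(px)), as.numeric(expect_ref[perm]))
})

test_that("multi-file queries equal column-stacked single-file queries", {
  fix2 <- two_chrom_store(seed = 99, path = tempfile(fileext = ".cool"))
  px12 <- pull_pixels(list(a = fix$store, b = fix2$store), qset,
                      extraction_config())
  pxa <- pull_pixels(fix$store, qset, extraction_config())
  pxb <- pull_pixels(fix2$store, qset, extraction_config())
  expect_identical(unname(counts(px12)),
                   unname(cbind(counts(pxa), counts(pxb))))
  ## duplicated file gives duplicated columns
  pxd <- pull_pixels(list(x = fix$store, y = fix$store), qset,
                     extraction_config())
  expect_identical(counts(pxd)[, 1], counts(pxd)[, 2],
                   ignore_attr = TRUE)
})

test_that("submatrix extraction matches fetch_block and keeps orientation", {
  ex <- suppressMessages(drop_out_of_range(expand_pixels(qset, 2)))
  sa <- pull_submatrices(fix$store, ex, extraction_config(block_span_bp = 20000))
  expect_s3_class(sa, "SubmatrixArray")
  for (p in seq_len(nrow(ex))) {
    direct <- fetch_block(fix$store, c(ex$r1[p], ex$r2[p]),
                          c(ex$c1[p], ex$c2[p]))$values
    expect_identical(submatrix(sa, p), direct)
  }
  ## center cell equals the un-expanded pixel pull
  px <- pull_pixels(fix$store, qset, extraction_config())
  expect_identical(vapply(seq_len(nrow(ex)), function(p) submatrix(sa, p)[3, 3], 0),
                   as.vector(counts(px))[match(ex$qid, qset$qid)])
})

test_that("jagged extraction mirrors the regular path on square footprints", {
  ## domains of widths 3 and 5 bins -> dims (3,3) and (5,5)
  bp <- bins_to_pairset(fix$cs, 1000, "chrA", c(10, 30), c(10, 30))
  bp$r1 <- bp$bin1; bp$r2 <- bp$bin1 + c(3L, 5L)
  bp$c1 <- bp$bin2; bp$c2 <- bp$bin2 + c(3L, 5L)
  ja <- pull_submatrices(fix$store, bp, extraction_config())
  expect_s3_class(ja, "JaggedSubmatrixArray")
  expect_equal(unname(ja$dims), cbind(c(3L, 5L), c(3L, 5L)), ignore_attr = TRUE)
  for (p in 1:2)
    expect_identical(submatrix(ja, p),
                     fetch_block(fix$store, c(bp$r1[p], bp$r2[p]),
                                 c(bp$c1[p], bp$c2[p]))$values)
  ## equal square footprints through the jagged path = regular path values
  ex <- suppressMessages(drop_out_of_range(expand_pixels(qset, 1)))
  reg <- pull_submatrices(fix$store, ex, extraction_config())
  jag <- pull_submatrices(fix$store, ex, extraction_config(),
                          force_jagged = TRUE)
  expect_s3_class(jag, "JaggedSubmatrixArray")
  for (p in seq_len(nrow(ex)))
    expect_identical(submatrix(jag, p), submatrix(reg, p))
})

test_that("balanced extraction honours the missing policy", {
  w <- rep(1, 80); w[12] <- NA
  fixw <- two_chrom_store(seed = 4, weights = w)
  bp <- bins_to_pairset(fixw$cs, 1000, "chrA", c(5, 11), c(20, 30))
  pxm <- pull_pixels(fixw$store, bp, extraction_config("balanced"))
  expect_true(is.na(counts(pxm)[2, 1]))       # bin 11 has no weight
  expect_false(is.na(counts(pxm)[1, 1]))
  pxz <- pull_pixels(fixw$store, bp,
                     extraction_config("balanced", missing_policy = "zero"))
  expect_equal(counts(pxz)[2, 1], 0, ignore_attr = TRUE)
})

test_that("results persist, reload bit-exactly, and slice lazily", {
  px <- pull_pixels(fix$store, qset, extraction_config())
  dest <- tempfile(fileext = ".h5")
  px2 <- load_result(persist(px, dest)$h5)
  expect_identical(counts(px2), counts(px))
  expect_identical(counts(px2, pairs = 2:3), counts(px)[2:3, , drop = FALSE])
  expect_identical(as.data.frame(interactions(px2))$qid, qset$qid)
  ## submatrices round-trip too
  ex <- suppressMessages(drop_out_of_range(expand_pixels(qset, 2)))
  sa <- pull_submatrices(fix$store, ex, extraction_config())
  sa2 <- load_result(persist(sa, tempfile(fileext = ".h5"))$h5)
  expect_identical(counts(sa2), counts(sa))
  ## foreign layouts are rejected with a versioned error
  bogus <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(bogus)
  rhdf5::h5write(1:3, bogus, "counts")
  rhdf5::h5closeAll()
  expect_error(load_result(bogus), "layout version")
})

test_that("peak working set is bounded by one block, not the query count", {
  cs <- chrom_sizes("chr1", 5e6)
  sim <- simulate_contact_map(map_spec(cs, 1e4, depth = 20, seed = 31))
  set.seed(31)
  n <- 400
  b1 <- sample(5:430, n, TRUE)
  bp <- bins_to_pairset(cs, 1e4, "chr1", b1, b1 + sample(6:50, n, TRUE))
  ex <- suppressMessages(drop_out_of_range(expand_pixels(bp, 2)))
  span_bins <- 50
  sa <- pull_submatrices(sim$store, ex,
                         extraction_config(block_span_bp = span_bins * 1e4))
  ## a block may be enlarged by at most one footprint width per side
  expect_lte(sa$stats$max_block_cells, (span_bins + 2 * 5)^2)
  ## far below the total cells touched by the query set
  expect_lt(sa$stats$max_block_cells, nrow(ex) * 25 / 2)
})
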