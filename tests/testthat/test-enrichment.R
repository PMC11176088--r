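test_that("mask geometries enumerate the documented cells", {
  expect_equal(sum(make_mask("focal", 5)), 1L)
  expect_true(make_mask("focal", 5)[3, 3])
  ## donut(1,2) on 5x5: 24 ring cells minus 8 on the center row/column
  expect_equal(sum(make_mask("donut", 5, inner = 1, outer = 2)), 16L)
  expect_equal(sum(make_mask("donut", 5, inner = 1, outer = 2,
                             include_axes = TRUE)), 24L)
  expect_equal(sum(make_mask("inner_square", 5, k = 1)), 9L)
  expect_equal(sum(make_mask("top_left", 5, k = 2)), 4L)
  expect_equal(sum(make_mask("rows_cols", 5)), 8L)
  expect_equal(sum(mask_union(make_mask("top_left", 5, k = 2),
                              make_mask("bottom_right", 5, k = 2))), 8L)
  expect_error(make_mask("donut", 5, inner = 2, outer = 1), "geometry")
  expect_error(make_mask("inner_square", 5, k = 3), "exceeds")
  expect_error(make_mask("focal", 4), "odd")
})

test_that("mask algebra satisfies inclusion-exclusion", {
  set.seed(3)
  kinds <- list(make_mask("focal", 7),
                make_mask("donut", 7, inner = 1, outer = 3),
                make_mask("inner_square", 7, k = 2),
                make_mask("rows_cols", 7),
                make_mask("top_left", 7, k = 3))
  for (a in kinds) for (b in kinds) {
    expect_equal(sum(mask_union(a, b)) + sum(mask_intersect(a, b)),
                 sum(a) + sum(b))
    expect_equal(sum(mask_complement(a)), 49 - sum(a))
  }
})

## store whose chrA block holds a hand-crafted window: all ones except a
## center pixel of 9 at (20, 40) (0-based bins)
window_store <- function(center = 9, base = 1) {
  cs <- chrom_sizes("chrW", 8e4)
  m <- matrix(0, 80, 80)
  m[16:26, 36:46] <- base
  m[36:46, 16:26] <- base
  m[21, 41] <- m[41, 21] <- center
  list(store = write_contacts(list(chrW = m), cs, 1000,
                              path = tempfile(fileext = ".cool")),
       cs = cs, dense = m)
}

test_that("median-ratio enrichment reproduces hand-worked examples", {
  fx <- window_store()
  bp <- bins_to_pairset(fx$cs, 1000, "chrW", 20, 40)
  en <- calc_loop_enrichment(fx$store, bp, buffer_bins = 2,
                             fg = make_mask("focal", 5),
                             bg = make_mask("donut", 5, inner = 1, outer = 2))
  expect_equal(unname(en$scores[1, 1]), 5.0)     # (9+1)/(1+1)
  ## constant window scores exactly 1 for any disjoint masks
  flat <- window_store(center = 4, base = 4)
  en1 <- calc_loop_enrichment(flat$store, bp, buffer_bins = 2,
                              fg = make_mask("inner_square", 5, k = 1),
                              bg = make_mask("donut", 5, inner = 2, outer = 2))
  expect_equal(unname(en1$scores[1, 1]), 1.0)
})

test_that("overlapping masks and mismatched sides are rejected", {
  fx <- window_store()
  bp <- bins_to_pairset(fx$cs, 1000, "chrW", 20, 40)
  expect_error(calc_loop_enrichment(fx$store, bp, buffer_bins = 2,
                                    fg = make_mask("inner_square", 5, k = 1),
                                    bg = make_mask("rows_cols", 5)),
               "overlap")
  expect_error(calc_loop_enrichment(fx$store, bp, buffer_bins = 3,
                                    fg = make_mask("focal", 5),
                                    bg = make_mask("donut", 5, 1, 2)),
               "side")
})

test_that("pseudocounted score is scale-covariant and center-monotone", {
  cs <- chrom_sizes("chrW", 8e4)
  base <- sym_count_matrix(80, 4, 44)
  bp <- bins_to_pairset(cs, 1000, "chrW", 20, 40)
  score_of <- function(m) {
    st <- write_contacts(list(chrW = m), cs, 1000,
                         path = tempfile(fileext = ".cool"))
    unname(calc_loop_enrichment(st, bp, buffer_bins = 2)$scores[1, 1])
  }
  s1 <- score_of(base)
  for (c_scale in c(2, 10)) {
    m <- base * c_scale
    ## medians scale with c: score maps to (c*m_fg + 1) / (c*m_bg + 1)
    fg_med <- stats::median(base[21, 41]) * c_scale
    w <- base[19:23, 39:43] * c_scale
    bg_med <- stats::median(w[which(make_mask("donut", 5, 2, 2))])  # default bg at buffer 2
    expect_equal(score_of(m), (fg_med + 1) / (bg_med + 1), tolerance = 1e-12)
  }
  ## raising only the center never lowers the focal-vs-donut score
  up <- base; up[21, 41] <- up[41, 21] <- up[21, 41] + 25
  expect_gte(score_of(up), s1)
})

test_that("scores agree with a brute-force dense-window scorer", {
  fix <- two_chrom_store(seed = 77)
  set.seed(77)
  b1 <- sample(8:35, 12); b2 <- pmin(b1 + sample(8:12, 12, TRUE), 44)
  bp <- bins_to_pairset(fix$cs, 1000, "chrA", b1, b2)
  buf <- 2
  fg <- make_mask("focal", 5); bg <- make_mask("donut", 5, 1, 2)
  en <- suppressWarnings(calc_loop_enrichment(fix$store, bp, buf, fg, bg))
  kept <- en$kept
  for (i in seq_along(kept)) {
    p <- kept[i]
    w <- fix$full[(bp$bin1[p] - buf):(bp$bin1[p] + buf) + 1,
                  (bp$bin2[p] - buf):(bp$bin2[p] + buf) + 1]
    want <- (stats::median(w[which(fg)]) + 1) / (stats::median(w[which(bg)]) + 1)
    expect_equal(unname(en$scores[i, 1]), want, tolerance = 1e-12)
  }
  ## user-defined score functions are applied verbatim
  en2 <- suppressWarnings(calc_loop_enrichment(
    fix$store, bp, buf, fg, bg, score = function(f, b) mean(f) - mean(b)))
  expect_equal(en2$score_definition, "user function")
})

test_that("planted loop folds are recovered within the expected ratio", {
  lm <- loop_map(n_loops = 60, depth = 1500, fold = 5, seed = 23)
  calls <- truth_loop_calls(lm$truth)
  bp <- snap_to_bins(calls, lm$binsize)
  en <- calc_loop_enrichment(lm$store, bp)
  ## expected score per loop from the noiseless intensity matrix
  fg <- make_mask("focal", 11); bg <- make_mask("donut", 11, 2, 5)
  lam <- lm$truth$lambda$chrL
  expected <- vapply(seq_len(nrow(lm$loops)), function(k) {
    w <- lam[lm$loops$bin1[k] + 1 + (-5:5), lm$loops$bin2[k] + 1 + (-5:5)]
    (stats::median(w[which(fg)]) + 1) / (stats::median(w[which(bg)]) + 1)
  }, 0)
  ## median window count must be deep enough for a stable median
  expect_gte(stats::median(counts(pull_pixels(lm$store, bp))), 20)
  rec <- stats::median(en$scores[, 1]) / stats::median(expected)
  expect_gt(rec, 0.8)
  expect_lt(rec, 1.2)
  ## scores track planted fold across a fold gradient
  lm2 <- loop_map(n_loops = 40, depth = 1500, fold = 5, seed = 29,
                  dist_bins = rep(20, 40))
  lm2$loops$fold <- seq(1.5, 8, length.out = 40)
  spec <- map_spec(lm2$cs, lm2$binsize, depth = 1500, loops = lm2$loops, seed = 29)
  sim <- simulate_contact_map(spec)
  en2 <- calc_loop_enrichment(sim$store,
                              snap_to_bins(truth_loop_calls(sim$truth),
                                           lm2$binsize))
  expect_gte(stats::cor(en2$scores[, 1], lm2$loops$fold, method = "spearman"),
             0.8)
})
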