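## Fixtures and independent oracles, built in code at test time.

## symmetric non-negative integer count matrix
sym_count_matrix <- function(n, lambda = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

## two-chromosome store + dense genome-wide oracle matrix (block diagonal)
two_chrom_store <- function(binsize = 1000, lenA = 50000, lenB = 30000,
                            weights = NULL, seed = 1,
                            path = tempfile(fileext = ".cool")) {
  cs <- chrom_sizes(c("chrA", "chrB"), c(lenA, lenB))
  nA <- ceiling(lenA / binsize); nB <- ceiling(lenB / binsize)
  mA <- sym_count_matrix(nA, 3, seed)
  mB <- sym_count_matrix(nB, 2, seed + 1)
  st <- write_contacts(list(chrA = mA, chrB = mB), cs, binsize,
                       weights = weights, path = path)
  full <- matrix(0, nA + nB, nA + nB)
  full[1:nA, 1:nA] <- mA
  full[nA + 1:nB, nA + 1:nB] <- mB
  list(store = st, cs = cs, full = full, binsize = binsize, nA = nA, nB = nB,
       weights = weights)
}

## build a snapped BinnedPairSet straight from bin coordinates
bins_to_pairset <- function(cs, binsize, chrom, b1, b2, ...) {
  df <- data.frame(chrom1 = chrom, start1 = b1 * binsize, end1 = (b1 + 1) * binsize,
                   chrom2 = chrom, start2 = b2 * binsize, end2 = (b2 + 1) * binsize,
                   ..., stringsAsFactors = FALSE)
  snap_to_bins(pair_set(df, cs), binsize)
}

## dense-matrix lookup oracle for pixel queries (0-based global bins)
dense_lookup <- function(full, b1, b2) full[cbind(b1 + 1, b2 + 1)]

## union-find transitive closure: connected components of the <= eps graph,
## labels canonical by first appearance (independent of the DBSCAN code path)
cc_partition <- function(coords, eps, metric = "manhattan") {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    dx <- abs(coords[i, 1] - coords[j, 1]); dy <- abs(coords[i, 2] - coords[j, 2])
    d <- if (metric == "chebyshev") max(dx, dy) else dx + dy
    if (d <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

## canonical first-appearance labels; two partitions are equal iff these match
canon_labels <- function(x) match(x, unique(x))

## independent bilinear oracle: per-cell nearest-4-neighbour interpolation,
## coded without the weight-matrix product used by the package
bilinear_oracle <- function(m, ndim) {
  out <- matrix(0, ndim, ndim)
  for (i in seq_len(ndim)) for (j in seq_len(ndim)) {
    u <- min(max(((i - 0.5) / ndim) * nrow(m) - 0.5, 0), nrow(m) - 1)
    v <- min(max(((j - 0.5) / ndim) * ncol(m) - 0.5, 0), ncol(m) - 1)
    i0 <- floor(u); j0 <- floor(v)
    i1 <- min(i0 + 1, nrow(m) - 1); j1 <- min(j0 + 1, ncol(m) - 1)
    fu <- u - i0; fv <- v - j0
    out[i, j] <- (1 - fu) * (1 - fv) * m[i0 + 1, j0 + 1] +
      (1 - fu) * fv * m[i0 + 1, j1 + 1] +
      fu * (1 - fv) * m[i1 + 1, j0 + 1] +
      fu * fv * m[i1 + 1, j1 + 1]
  }
  out
}

## simulated map with many well-separated planted loops on one chromosome
loop_map <- function(n_loops = 50, binsize = 1e4, len = 1e7, depth = 1000,
                     fold = 5, width = 1, dist_bins = NULL, seed = 11,
                     bias = NULL, alpha = 1) {
  cs <- chrom_sizes("chrL", len)
  nb <- ceiling(len / binsize)
  b1 <- seq(15, nb - 60, by = max(12, (nb - 80) %/% n_loops))[seq_len(n_loops)]
  if (is.null(dist_bins)) dist_bins <- 15 + (seq_len(n_loops) %% 5) * 5
  loops <- data.frame(chrom = "chrL", bin1 = b1, bin2 = b1 + dist_bins,
                      fold = fold, width_bins = width)
  spec <- map_spec(cs, binsize, alpha = alpha, depth = depth, loops = loops,
                   bias = bias, seed = seed)
  sim <- simulate_contact_map(spec)
  c(sim, list(cs = cs, loops = loops, binsize = binsize, nb = nb))
}

## the reference simulation used by the extraction acceptance checks:
## two chromosomes (5 Mb + 3 Mb) at 10 kb bins, biased, with loops
acceptance_map <- function(seed = 101, depth = 60, bias_sd = 0.25) {
  cs <- chrom_sizes(c("chr1", "chr2"), c(5e6, 3e6))
  set.seed(seed)
  bias <- exp(stats::rnorm(800, 0, bias_sd))
  loops <- data.frame(chrom = "chr1", bin1 = seq(20, 420, by = 40),
                      bin2 = seq(20, 420, by = 40) + 25, fold = 5, width_bins = 1)
  spec <- map_spec(cs, 1e4, alpha = 1, depth = depth, loops = loops,
                   bias = bias, seed = seed)
  sim <- simulate_contact_map(spec)
  n <- 800
  full <- matrix(0, n, n)
  full[1:500, 1:500] <- sim$truth$counts$chr1
  full[501:800, 501:800] <- sim$truth$counts$chr2
  w <- sim$truth$weights
  list(store = sim$store, truth = sim$truth, cs = cs, full = full,
       full_bal = full * outer(w, w), w = w, binsize = 1e4)
}

## random intra-chromosomal pixel queries over both chromosomes (0-based bins)
random_queries <- function(cs, binsize, n, seed, min_gap = 6, max_gap = 60) {
  set.seed(seed)
  nb <- ceiling(cs$length / binsize)
  ci <- sample(seq_len(nrow(cs)), n, replace = TRUE, prob = nb / sum(nb))
  g <- pmin(min_gap + stats::rgeom(n, 2 / (max_gap - min_gap)), max_gap)
  b1 <- vapply(seq_len(n), function(i) sample.int(nb[ci[i]] - max_gap - 1L, 1L) - 1L, 0L)
  df <- data.frame(chrom1 = cs$chrom[ci], start1 = b1 * binsize,
                   end1 = (b1 + 1) * binsize,
                   chrom2 = cs$chrom[ci], start2 = (b1 + g) * binsize,
                   end2 = (b1 + g + 1) * binsize,
                   qid = seq_len(n), stringsAsFactors = FALSE)
  snap_to_bins(pair_set(df, cs), binsize)
}
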