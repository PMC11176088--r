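## Deterministic contact-map simulator.
##
## Intra-chromosomal intensity model, per chromosome:
##   Lambda[i, j] = depth * (|i - j| + 1)^(-alpha) * L[i, j] * T[i, j] * b_i * b_j
## where L multiplies a Gaussian bump (in Chebyshev radius, peak `fold`,
## scale `width_bins`) at each planted loop, T multiplies `fold` inside each
## planted domain block, and b is a multiplicative per-bin bias. Counts are
## Poisson(Lambda) sampled on the upper triangle and mirrored; stored
## balancing weights are 1/b, so balanced counts have bias-free expectation.

#' Specify a synthetic contact map
#'
#' @param chromsizes A [chrom_sizes] table.
#' @param binsize_bp Bin size in bp.
#' @param alpha Distance-decay exponent (> 0): expected counts fall off as
#'   `(d + 1)^-alpha` with bin separation `d`.
#' @param depth Expected count at distance 0 before loop/domain/bias factors.
#' @param loops Optional data.frame: `chrom`, `bin1`, `bin2` (chromosome-local
#'   bin indices, `bin1 <= bin2`), `fold` (>= 1), `width_bins` (> 0).
#' @param tads Optional data.frame: `chrom`, `start_bin`, `end_bin`
#'   (half-open, chromosome-local), `fold` (>= 1).
#' @param bias Per-bin positive multiplicative biases (length = total bins),
#'   or `NULL` for none.
#' @param seed Integer seed; all simulator outputs are pure functions of
#'   (spec, seed).
#' @return A `MapSpec` list.
#' @export
map_spec <- function(chromsizes, binsize_bp, alpha = 1, depth = 100,
                     loops = NULL, tads = NULL, bias = NULL, seed = 1L) {
  cs <- .validate_chromsizes(chromsizes)
  n_bins <- .n_bins(cs, binsize_bp)
  nb <- .bins_per_chrom(cs, binsize_bp)
  if (alpha <= 0) .stopf("alpha must be positive")
  if (depth <= 0) .stopf("depth must be positive")
  if (!is.null(loops)) {
    stopifnot(all(c("chrom", "bin1", "bin2", "fold") %in% names(loops)))
    if (is.null(loops$width_bins)) loops$width_bins <- 1
    ci <- match(loops$chrom, cs$chrom)
    if (anyNA(ci)) .stopf("loop on unknown chromosome")
    if (any(loops$fold < 1)) .stopf("loop folds must be >= 1")
    if (any(loops$bin1 < 0 | loops$bin2 >= nb[ci])) .stopf("loop bins out of range")
    if (any(loops$bin1 > loops$bin2)) .stopf("loops need bin1 <= bin2")
  }
  if (!is.null(tads)) {
    stopifnot(all(c("chrom", "start_bin", "end_bin", "fold") %in% names(tads)))
    ci <- match(tads$chrom, cs$chrom)
    if (anyNA(ci)) .stopf("domain on unknown chromosome")
    if (any(tads$fold < 1)) .stopf("domain folds must be >= 1")
    if (any(tads$start_bin < 0 | tads$end_bin > nb[ci] |
            tads$end_bin <= tads$start_bin)) .stopf("domain bins out of range")
  }
  if (!is.null(bias)) {
    if (length(bias) != n_bins) .stopf("bias must have one value per bin (%d)", n_bins)
    if (any(!is.finite(bias)) || any(bias <= 0)) .stopf("bias must be finite positive")
  }
  structure(list(chromsizes = cs, binsize_bp = binsize_bp, alpha = alpha,
                 depth = depth, loops = loops, tads = tads, bias = bias,
                 seed = as.integer(seed)),
            class = "MapSpec")
}

## noiseless intensity matrix for one chromosome (chromosome-local bins)
.lambda_chrom <- function(spec, chrom_i) {
  cs <- spec$chromsizes
  nb <- .bins_per_chrom(cs, spec$binsize_bp)[chrom_i]
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  lam <- spec$depth * (d + 1)^(-spec$alpha)
  chrom <- cs$chrom[chrom_i]
  if (!is.null(spec$loops)) {
    lp <- spec$loops[spec$loops$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(lp))) {
      i <- seq_len(nb) - 1L
      dc <- outer(abs(i - lp$bin1[k]), abs(i - lp$bin2[k]), pmax)
      bump <- 1 + (lp$fold[k] - 1) * exp(-dc^2 / (2 * lp$width_bins[k]^2))
      lam <- lam * bump
      dc2 <- outer(abs(i - lp$bin2[k]), abs(i - lp$bin1[k]), pmax)  # mirror
      lam <- lam * (1 + (lp$fold[k] - 1) * exp(-dc2^2 / (2 * lp$width_bins[k]^2)))
    }
  }
  if (!is.null(spec$tads)) {
    td <- spec$tads[spec$tads$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(td))) {
      sel <- (td$start_bin[k] + 1L):td$end_bin[k]
      lam[sel, sel] <- lam[sel, sel] * td$fold[k]
    }
  }
  if (!is.null(spec$bias)) {
    off <- .chrom_offsets(cs, spec$binsize_bp)[chrom_i]
    b <- spec$bias[(off + 1):(off + nb)]
    lam <- lam * outer(b, b)
  }
  lam
}

#' Simulate a contact map with known ground truth
#'
#' Builds the noiseless intensity matrix per chromosome, samples Poisson
#' counts on the upper triangle (mirrored for symmetry), writes a
#' cooler-dialect file with balancing weights `1/bias`, and returns both the
#' opened store and the ground truth. The same (spec, seed) always produces
#' an identical pixel table.
#'
#' @param spec A [map_spec()].
#' @param path Output `.cool` path (default: temporary file).
#' @return A list `(store, truth)`; `truth` holds `lambda` (list of dense
#'   intensity matrices per chromosome), `counts` (sampled dense matrices),
#'   `loops`, `tads`, `weights`, `chromsizes`, `binsize_bp`.
#' @export
simulate_contact_map <- function(spec, path = tempfile(fileext = ".cool")) {
  stopifnot(inherits(spec, "MapSpec"))
  cs <- spec$chromsizes
  lam <- lapply(seq_len(nrow(cs)), function(i) .lambda_chrom(spec, i))
  names(lam) <- cs$chrom
  counts <- .with_seed(spec$seed, lapply(lam, function(L) {
    n <- nrow(L)
    up <- upper.tri(L, diag = TRUE)
    m <- matrix(0, n, n)
    m[up] <- stats::rpois(sum(up), L[up])
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }))
  weights <- if (is.null(spec$bias)) rep(1, .n_bins(cs, spec$binsize_bp))
             else 1 / spec$bias
  store <- write_contacts(counts, cs, spec$binsize_bp, weights = weights,
                          path = path)
  loops_global <- NULL
  if (!is.null(spec$loops)) {
    loops_global <- spec$loops
    loops_global$gbin1 <- .global_bin(cs, spec$binsize_bp, spec$loops$chrom,
                                      spec$loops$bin1)
    loops_global$gbin2 <- .global_bin(cs, spec$binsize_bp, spec$loops$chrom,
                                      spec$loops$bin2)
  }
  truth <- structure(list(lambda = lam, counts = counts, loops = loops_global,
                          tads = spec$tads, weights = weights,
                          chromsizes = cs, binsize_bp = spec$binsize_bp,
                          spec = spec),
                     class = "GroundTruth")
  list(store = store, truth = truth)
}

#' Loop calls of a ground truth as a PairSet
#'
#' @param truth A `GroundTruth` from [simulate_contact_map()].
#' @return A `PairSet` with one pair per planted loop (anchors are the loop
#'   bins) and metadata `fold`.
#' @export
truth_loop_calls <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  lp <- truth$loops
  if (is.null(lp)) .stopf("ground truth has no planted loops")
  bs <- truth$binsize_bp
  df <- data.frame(chrom1 = lp$chrom, start1 = lp$bin1 * bs,
                   end1 = (lp$bin1 + 1) * bs,
                   chrom2 = lp$chrom, start2 = lp$bin2 * bs,
                   end2 = (lp$bin2 + 1) * bs,
                   fold = lp$fold, stringsAsFactors = FALSE)
  pair_set(df, truth$chromsizes)
}

#' Simulate jittered replicate loop-call files
#'
#' Emulates the same loop being assigned to slightly different pixels across
#' datasets: each replicate contains each true loop with probability
#' `1 - fnr`, displaced by independent uniform integer offsets in
#' `[-jitter, +jitter]^2` bins (clamped to the chromosome), with a `count`
#' metadata column read from the sampled map at the jittered pixel.
#'
#' @param truth A `GroundTruth` from [simulate_contact_map()].
#' @param n_replicates Number of replicate call sets.
#' @param jitter_bins Maximum absolute displacement per axis, in bins.
#' @param fnr False-negative rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return A named list of `PairSet`s (`rep1`, `rep2`, ...), each
#'   BEDPE-writable with [write_bedpe()].
#' @export
simulate_loop_calls <- function(truth, n_replicates, jitter_bins = 1L,
                                fnr = 0, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (fnr < 0 || fnr >= 1) .stopf("fnr must be in [0, 1)")
  lp <- truth$loops
  if (is.null(lp) || !nrow(lp)) .stopf("ground truth has no planted loops")
  cs <- truth$chromsizes
  bs <- truth$binsize_bp
  nb <- .bins_per_chrom(cs, bs)
  .with_seed(seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      keep <- stats::runif(nrow(lp)) >= fnr
      sub <- lp[keep, , drop = FALSE]
      n <- nrow(sub)
      j1 <- sample.int(2L * jitter_bins + 1L, n, replace = TRUE) - jitter_bins - 1L
      j2 <- sample.int(2L * jitter_bins + 1L, n, replace = TRUE) - jitter_bins - 1L
      ci <- match(sub$chrom, cs$chrom)
      b1 <- pmin(pmax(sub$bin1 + j1, 0L), nb[ci] - 1L)
      b2 <- pmin(pmax(sub$bin2 + j2, 0L), nb[ci] - 1L)
      cnt <- vapply(seq_len(n), function(i)
        truth$counts[[sub$chrom[i]]][b1[i] + 1L, b2[i] + 1L], 0)
      df <- data.frame(chrom1 = sub$chrom, start1 = b1 * bs, end1 = (b1 + 1) * bs,
                       chrom2 = sub$chrom, start2 = b2 * bs, end2 = (b2 + 1) * bs,
                       count = cnt, true_loop = which(keep),
                       stringsAsFactors = FALSE)
      if (n) df <- df[order(seq_len(n)), , drop = FALSE]
      pair_set(df, cs)
    })
    names(reps) <- paste0("rep", seq_len(n_replicates))
    reps
  })
}

#' Write ground truth as a JSON sidecar
#'
#' Stores the planted loops, domains, weights and simulation parameters
#' (not the dense matrices) next to a simulated map.
#'
#' @param truth A `GroundTruth`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  x <- list(binsize_bp = truth$binsize_bp,
            chromsizes = as.data.frame(truth$chromsizes),
            alpha = truth$spec$alpha, depth = truth$spec$depth,
            seed = truth$spec$seed,
            loops = if (!is.null(truth$loops)) as.data.frame(truth$loops),
            tads = if (!is.null(truth$tads)) as.data.frame(truth$tads),
            weights = truth$weights)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
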