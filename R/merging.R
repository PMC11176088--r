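## Density-based merging of redundant loop calls.
##
## The same loop is often assigned to slightly different pixels across
## datasets and callers. Calls are snapped to a common bin grid and clustered
## per chromosome pair with DBSCAN (Manhattan distance on (bin1, bin2) scaled
## to base pairs, minPts = 2, eps = radius_bp); one representative pixel per
## cluster is selected while every original call and all its metadata are
## retained.

## Generic DBSCAN on a coordinate matrix. minPts counts the point itself.
## Returns integer labels; 0 = noise. O(n^2) region queries -- loop-call sets
## are small relative to contact matrices.
.dbscan <- function(coords, eps, min_pts, metric = "manhattan") {
  n <- nrow(coords)
  labels <- integer(n)            # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  neighbors <- function(i) {
    dx <- abs(coords[, 1] - coords[i, 1])
    dy <- abs(coords[, 2] - coords[i, 2])
    d <- if (metric == "chebyshev") pmax(dx, dy) else dx + dy
    which(d <= eps)
  }
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbors(i)
    if (length(nb) < min_pts) next    # noise (may be claimed as border later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbors(j)
        if (length(nbj) >= min_pts) queue <- c(queue, setdiff(nbj, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Merge redundant loop calls across files or callers
#'
#' Concatenates the given call sets (keeping a per-pair source label), snaps
#' them to `binsize_bp`, clusters pixel coordinates per chromosome pair with
#' DBSCAN (Manhattan distance in bp, `minPts = 2`, `eps = radius_bp`), and
#' picks one representative pixel per cluster. With `minPts = 2` an isolated
#' call is never discarded as noise -- it becomes its own singleton cluster --
#' and clusters coincide with the connected components of the graph joining
#' calls at distance `<= radius_bp`.
#'
#' Representative selection: `"max_metric"` takes the member maximizing
#' `metric_column` (ties: first in concatenation order); `"most_frequent"`
#' takes the modal pixel coordinate (ties: higher metric when given, else
#' first); `"mean_position"` takes the member nearest the coordinate-wise
#' mean (ties: first). Default: `"max_metric"` when a metric column is
#' supplied, else `"most_frequent"`.
#'
#' @param pair_lists A `PairSet` or (optionally named) list of them; names
#'   become source labels.
#' @param binsize_bp Bin size used for snapping and clustering.
#' @param radius_bp Non-negative DBSCAN eps, in base pairs.
#' @param metric_column Optional metadata column (must exist in every list
#'   when `selection = "max_metric"`).
#' @param selection Representative rule (see above).
#' @param metric `"manhattan"` (default) or `"chebyshev"` distance on the
#'   snapped bin coordinates, scaled to bp. Chebyshev makes the merge radius
#'   directly comparable to a per-axis pixel jitter: calls of one loop
#'   jittered by at most `j` bins per axis always fall within Chebyshev
#'   distance `2j` of each other, so `radius_bp = 2j * binsize_bp` merges
#'   them deterministically, while loops separated by more than `2j + radius`
#'   bins on every axis can never be linked.
#' @param anchor_point Snapping rule passed to [snap_to_bins()].
#' @return A `MergedPairSet`: list with `representatives` (a `BinnedPairSet`
#'   with `cluster_id`, `cluster_size` and the selection metric),
#'   `membership` (cluster id -> original indices), `originals` (the full
#'   concatenated snapped input with source labels and `cluster_id`), and
#'   `selection_record`.
#' @export
merge_pairs <- function(pair_lists, binsize_bp, radius_bp,
                        metric_column = NULL,
                        selection = c("max_metric", "mean_position",
                                      "most_frequent"),
                        metric = c("manhattan", "chebyshev"),
                        anchor_point = "center") {
  metric <- match.arg(metric)
  if (inherits(pair_lists, "PairSet")) pair_lists <- list(pair_lists)
  if (!length(pair_lists) || !all(vapply(pair_lists, inherits, TRUE, "PairSet")))
    .stopf("pair_lists must be a PairSet or a list of them")
  if (radius_bp < 0) .stopf("radius_bp must be non-negative")
  selection <- if (missing(selection)) {
    if (is.null(metric_column)) "most_frequent" else "max_metric"
  } else match.arg(selection)
  if (selection == "max_metric" && is.null(metric_column))
    .stopf("selection = 'max_metric' needs a metric_column")
  if (!is.null(metric_column)) {
    lacking <- !vapply(pair_lists, function(p) metric_column %in% names(p), TRUE)
    if (any(lacking))
      .stopf("metric column '%s' missing from input list %d", metric_column,
             which(lacking)[1])
  }
  labs <- names(pair_lists)
  if (is.null(labs)) labs <- paste0("set", seq_along(pair_lists))
  labs[!nzchar(labs)] <- paste0("set", which(!nzchar(labs)))

  snapped <- lapply(seq_along(pair_lists), function(i) {
    s <- snap_to_bins(pair_lists[[i]], binsize_bp, anchor_point)
    s$source <- if (is.null(s$source)) labs[i] else s$source
    as.data.frame(s)
  })
  all_cols <- unique(unlist(lapply(snapped, names)))
  snapped <- lapply(snapped, function(d) {
    for (nm in setdiff(all_cols, names(d))) d[[nm]] <- NA
    d[, all_cols, drop = FALSE]
  })
  df <- do.call(rbind, snapped)
  rownames(df) <- NULL
  n <- nrow(df)
  if (!n) .stopf("no pairs to merge")
  cs <- attr(snap_to_bins(pair_lists[[1]], binsize_bp, anchor_point), "chromsizes")

  cluster_id <- integer(n)
  next_id <- 0L
  for (idx in split(seq_len(n), paste(df$chrom1, df$chrom2))) {
    coords <- cbind(df$bin1[idx], df$bin2[idx]) * binsize_bp
    lab <- .dbscan(coords, radius_bp, min_pts = 2L, metric = metric)
    noise <- lab == 0L
    lab[noise] <- max(lab) + seq_len(sum(noise))      # singleton clusters
    cluster_id[idx] <- next_id + lab
    next_id <- next_id + max(lab)
  }
  ## renumber clusters in order of first appearance
  first <- match(unique(cluster_id), cluster_id)
  remap <- integer(max(cluster_id))
  remap[cluster_id[sort(first)]] <- seq_along(first)
  cluster_id <- remap[cluster_id]
  df$cluster_id <- cluster_id

  metric <- if (!is.null(metric_column)) as.numeric(df[[metric_column]]) else NULL
  membership <- split(seq_len(n), cluster_id)
  rep_idx <- vapply(membership, function(m) {
    if (length(m) == 1L) return(m[1])
    switch(selection,
      max_metric = m[which.max(metric[m])],
      mean_position = {
        ctr <- c(mean(df$bin1[m]), mean(df$bin2[m]))
        d <- abs(df$bin1[m] - ctr[1]) + abs(df$bin2[m] - ctr[2])
        m[which.min(d)]
      },
      most_frequent = {
        key <- paste(df$bin1[m], df$bin2[m])
        tab <- table(key)
        modal <- m[key %in% names(tab)[tab == max(tab)]]
        if (!is.null(metric) && length(modal) > 1L)
          modal[which.max(metric[modal])] else modal[1]
      })
  }, 0L)
  sel_value <- if (!is.null(metric)) metric[rep_idx]
               else vapply(seq_along(membership), function(k) {
                 m <- membership[[k]]
                 key <- paste(df$bin1[m], df$bin2[m])
                 max(table(key))
               }, 0)

  reps <- df[rep_idx, , drop = FALSE]
  reps$cluster_id <- as.integer(names(membership))
  reps$cluster_size <- lengths(membership)
  reps$selection_value <- sel_value
  rownames(reps) <- NULL
  reps <- structure(reps, chromsizes = cs, binsize = binsize_bp,
                    class = c("BinnedPairSet", "PairSet", "data.frame"))
  originals <- structure(df, chromsizes = cs, binsize = binsize_bp,
                         class = c("BinnedPairSet", "PairSet", "data.frame"))
  structure(list(representatives = reps, membership = membership,
                 originals = originals,
                 selection_record = data.frame(
                   cluster_id = as.integer(names(membership)),
                   metric = if (is.null(metric_column)) "detection_frequency"
                            else metric_column,
                   value = sel_value,
                   representative_index = rep_idx)),
            class = "MergedPairSet")
}

#' @export
print.MergedPairSet <- function(x, ...) {
  cat(sprintf("MergedPairSet: %d clusters from %d calls (%d sources)\n",
              nrow(x$representatives), nrow(x$originals),
              length(unique(x$originals$source))))
  cat(sprintf("  selection metric: %s\n", x$selection_record$metric[1]))
  invisible(x)
}

#' Representatives of a merged set as a PairSet
#'
#' @param x A `MergedPairSet`.
#' @return The representative `BinnedPairSet` (one pair per cluster, with
#'   `cluster_id`, `cluster_size`, `source` and `selection_value` columns),
#'   BEDPE-writable via [write_bedpe()].
#' @export
merged_representatives <- function(x) {
  stopifnot(inherits(x, "MergedPairSet"))
  x$representatives
}

#' Original calls of one cluster
#'
#' @param x A `MergedPairSet`.
#' @param cluster_id Cluster identifier.
#' @return The original (snapped) calls of that cluster with all metadata.
#' @export
cluster_members <- function(x, cluster_id) {
  stopifnot(inherits(x, "MergedPairSet"))
  m <- x$membership[[as.character(cluster_id)]]
  if (is.null(m)) .stopf("no cluster %s", cluster_id)
  x$originals[m, , drop = FALSE]
}
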