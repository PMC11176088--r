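#' Chromosome sizes
#'
#' A chromosome-sizes table is the authoritative genome order for every
#' operation in the package: bin grids, genome-wide bin ids and all sorting
#' follow the order of its rows.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in base pairs (> 0).
#' @return A `data.frame` with columns `chrom` and `length`, class
#'   `chrom_sizes`.
#' @examples
#' chrom_sizes(c("chr1", "chr2"), c(5e6, 3e6))
#' @export
chrom_sizes <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) .stopf("chromosome names must be unique")
  if (length(chrom) != length(length)) .stopf("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0))
    .stopf("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("chrom_sizes", "data.frame"))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab- or space-separated columns: chromosome name and length in bp.
#'
#' @param path Path to the text file.
#' @return A [chrom_sizes] table in file order.
#' @export
read_chromsizes <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chrom_sizes(df$chrom, df$length)
}

.validate_chromsizes <- function(cs) {
  if (!is.data.frame(cs) || !all(c("chrom", "length") %in% names(cs)))
    .stopf("expected a chrom_sizes table with columns chrom, length")
  cs
}

## --- bin-grid arithmetic (0-based genome-wide bin ids, cooler convention) ---

.bins_per_chrom <- function(cs, binsize) {
  as.integer(ceiling(cs$length / binsize))
}

## offsets[i] = first global bin id of chromosome i; length nchrom + 1
.chrom_offsets <- function(cs, binsize) {
  nb <- .bins_per_chrom(cs, binsize)
  c(0L, cumsum(nb))
}

.n_bins <- function(cs, binsize) sum(.bins_per_chrom(cs, binsize))

## full bin table (chrom, start, end) in genome order; last bin may be short
.bin_table <- function(cs, binsize) {
  nb <- .bins_per_chrom(cs, binsize)
  chrom <- rep(cs$chrom, nb)
  k <- unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- k * binsize
  end <- pmin(start + binsize, rep(cs$length, nb))
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

## chromosome index (into cs rows) of each global bin id (0-based ids)
.bin_chrom_index <- function(cs, binsize, bin_ids) {
  off <- .chrom_offsets(cs, binsize)
  findInterval(bin_ids, off[-length(off)])
}

## global bin id from chromosome name + chromosome-local bin index
.global_bin <- function(cs, binsize, chrom, local_bin) {
  off <- .chrom_offsets(cs, binsize)
  ci <- match(chrom, cs$chrom)
  if (anyNA(ci)) .stopf("unknown chromosome: %s",
                        paste(unique(chrom[is.na(ci)]), collapse = ", "))
  off[ci] + as.integer(local_bin)
}
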