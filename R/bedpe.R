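## BEDPE / BED text I/O. Hand-parsed line by line so contract violations can
## name the offending line; loop/domain call files are small.

#' Read paired anchors from a BEDPE file
#'
#' Tab-separated, >= 6 columns (`chrom1 start1 end1 chrom2 start2 end2`),
#' 0-based half-open. An optional header line starting with `#` may name the
#' columns; extra columns become named metadata (numeric where possible).
#' Intra-chromosomal pairs are canonically oriented so
#' `start1 <= start2`.
#'
#' @param path Path to the BEDPE file.
#' @param genome A [chrom_sizes] table; chromosomes are validated against it.
#' @return A `PairSet` in file order.
#' @export
read_bedpe <- function(path, genome) {
  cs <- .validate_chromsizes(genome)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  header <- NULL
  is_head <- startsWith(lines, "#")
  if (any(is_head)) header <- sub("^#\\s*", "", lines[which(is_head)[1]])
  keep <- which(!is_head & nzchar(trimws(lines)))
  if (!length(keep)) {
    empty <- data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                        chrom2 = character(), start2 = numeric(), end2 = numeric(),
                        stringsAsFactors = FALSE)
    return(pair_set(empty, cs))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6))
    .stopf("line %d: fewer than 6 tab-separated columns", keep[which(ncol < 6)[1]])
  nmax <- max(ncol)
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, nmax - length(f))),
                  character(nmax)))
  cn <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra_names <- if (nmax > 6) paste0("V", 7:nmax) else character()
  if (!is.null(header)) {
    hn <- strsplit(header, "\t", fixed = TRUE)[[1]]
    if (length(hn) >= nmax) extra_names <- hn[seq(7, length.out = nmax - 6)]
  }
  df <- data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- c(cn, extra_names)
  for (col in c("start1", "end1", "start2", "end2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) .stopf("line %d: non-numeric %s", keep[which(is.na(v))[1]], col)
    df[[col]] <- v
  }
  for (col in extra_names)
    df[[col]] <- utils::type.convert(df[[col]], as.is = TRUE)
  ## validate with line numbers before delegating to pair_set
  for (cc in c(1, 2)) {
    bad <- !(df[[paste0("chrom", cc)]] %in% cs$chrom)
    if (any(bad)) .stopf("line %d: unknown chromosome '%s'", keep[which(bad)[1]],
                         df[[paste0("chrom", cc)]][which(bad)[1]])
    bad <- df[[paste0("end", cc)]] <= df[[paste0("start", cc)]]
    if (any(bad)) .stopf("line %d: end <= start", keep[which(bad)[1]])
  }
  pair_set(df, cs)
}

#' Write a PairSet (or merged representatives) as BEDPE
#'
#' Writes the six anchor columns plus every metadata column, preceded by a
#' `#`-prefixed header line naming all columns.
#'
#' @param pairs A `PairSet` (any subclass).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pairs, path) {
  df <- as.data.frame(pairs)
  cols <- c(.pair_core_cols,
            intersect("source", names(df)), pair_metadata_cols(pairs))
  df <- df[, cols, drop = FALSE]
  for (col in c("start1", "end1", "start2", "end2"))
    df[[col]] <- format(df[[col]], scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED3 file
#'
#' @param path Path to a tab-separated BED file (first three columns used),
#'   0-based half-open, optional `#` header lines.
#' @param genome A [chrom_sizes] table for validation.
#' @return A data.frame with columns `chrom`, `start`, `end`, in file order.
#' @export
read_bed <- function(path, genome) {
  cs <- .validate_chromsizes(genome)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    .stopf("line %d: fewer than 3 columns", keep[which(lengths(fields) < 3)[1]])
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                   start = as.numeric(vapply(fields, `[[`, "", 2)),
                   end = as.numeric(vapply(fields, `[[`, "", 3)),
                   stringsAsFactors = FALSE)
  bad <- !(df$chrom %in% cs$chrom)
  if (any(bad)) .stopf("line %d: unknown chromosome '%s'",
                       keep[which(bad)[1]], df$chrom[which(bad)[1]])
  if (any(df$end <= df$start))
    .stopf("line %d: end <= start", keep[which(df$end <= df$start)[1]])
  df
}
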