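#' Build a fixed-resolution genomic bin table
#'
#' Tiles each chromosome with consecutive bins of `resolution` bp. Coordinates
#' are 0-based, half-open (BED convention); the last bin of a chromosome may be
#' shorter than `resolution`. Bin ids are dense 0-based integers ordered by
#' (chromosome, start), and are the indices used in sparse triplet files.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param resolution Bin width in bp.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `bin_id` and
#'   attribute `resolution`.
#' @export
make_bins <- function(chrom_sizes, resolution) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (resolution <= 0) stop("resolution must be positive")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0L, len - 1L, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin_id <- seq_len(nrow(bins)) - 1L
  attr(bins, "resolution") <- resolution
  bins
}

#' Read a bin table from a BED4 file
#'
#' Expects tab-separated columns chrom, start, end, bin_id (no header).
#'
#' @param path Path to the BED4 file.
#' @return Bin table `data.frame` as produced by [make_bins()].
#' @export
read_bins <- function(path) {
  bins <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "bin_id"),
                            colClasses = c("character", "integer", "integer",
                                           "integer"),
                            stringsAsFactors = FALSE)
  validate_bins(bins)
  attr(bins, "resolution") <- stats::median(bins$end - bins$start)
  bins
}

#' Write a bin table as BED4
#'
#' @param bins Bin table.
#' @param path Output path.
#' @export
write_bins <- function(bins, path) {
  out <- bins[, c("chrom", "start", "end", "bin_id")]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_bins <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "bin_id") %in% names(bins)))
  if (!identical(as.integer(bins$bin_id), seq_len(nrow(bins)) - 1L))
    stop("bin_id must be dense, 0-based and ordered by (chrom, start)")
  if (any(bins$end <= bins$start)) stop("bins must have end > start")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stop("bins must tile each chromosome without gaps or overlaps")
  }
  invisible(bins)
}

#' Assign genes to bins by midpoint
#'
#' The midpoint `floor((start + end) / 2)` decides the bin. A midpoint that
#' falls exactly on a bin boundary is assigned to the lower (left) bin.
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @param bins Bin table.
#' @return `genes` with an added `bin_id` column (`NA` for genes outside the
#'   bin table, with a warning).
#' @export
assign_genes_to_bins <- function(genes, bins) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  mid <- floor((genes$start + genes$end) / 2)
  bin_id <- rep(NA_integer_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) == 0) next
    # (start, end] intervals so a midpoint on a boundary goes to the left bin;
    # midpoint 0 stays in the first bin
    idx <- findInterval(mid[gi], b$start, left.open = TRUE) # 0..nrow(b)
    idx[mid[gi] == 0] <- 1L
    ok <- idx >= 1L & idx <= nrow(b) & mid[gi] <= b$end[pmax(idx, 1L)]
    bin_id[gi[ok]] <- b$bin_id[idx[ok]]
  }
  if (anyNA(bin_id))
    warning(sum(is.na(bin_id)), " gene(s) fall outside the bin table")
  genes$bin_id <- bin_id
  genes
}

#' Count gene midpoints per bin
#'
#' @param genes Gene annotation (see [assign_genes_to_bins()]).
#' @param bins Bin table.
#' @return Integer vector of length `nrow(bins)` with gene counts.
#' @export
gene_density <- function(genes, bins) {
  g <- assign_genes_to_bins(genes, bins)
  tab <- table(factor(g$bin_id, levels = bins$bin_id))
  as.integer(tab)
}
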