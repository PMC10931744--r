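#' Directionality index track
#'
#' For each bin, `A` is the sum of balanced contacts to the upstream window
#' and `B` to the downstream window (each `window_bp` wide). With
#' `E = (A + B) / 2`, the directionality index is
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`;
#' `DI = 0` when `A == B` or `E == 0`. Bins whose window is cut by a
#' chromosome end use the truncated window and are flagged.
#'
#' @param m Balanced [contact_matrix()] (typically at 40 kb).
#' @param window_bp Window span in bp; must be a positive multiple of the bin
#'   resolution.
#' @return A `di_track` `data.frame`: `chrom`, `start`, `end`, `bin_id`,
#'   `di`, `truncated`; `di` is `NA` on masked bins.
#' @export
directionality_index <- function(m, window_bp = 2e6) {
  stopifnot(inherits(m, "contact_matrix"))
  res <- attr(m$bins, "resolution")
  w <- window_bp / res
  if (w < 1 || w != round(w))
    stop("window_bp must be a positive multiple of the resolution")
  w <- as.integer(w)
  track <- m$bins[, c("chrom", "start", "end", "bin_id")]
  track$di <- NA_real_
  track$truncated <- FALSE
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    B <- m$counts[idx, idx, drop = FALSE]
    k <- length(idx)
    for (i in seq_len(k)) {
      if (m$mask[idx[i]]) next
      up_rng <- seq.int(max(1L, i - w), i - 1L)
      dn_rng <- seq.int(i + 1L, min(k, i + w))
      if (i == 1L) up_rng <- integer(0)
      if (i == k) dn_rng <- integer(0)
      a <- sum(B[i, up_rng])
      b <- sum(B[i, dn_rng])
      e <- (a + b) / 2
      di <- if (a == b || e == 0) 0 else
        sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
      track$di[idx[i]] <- di
      track$truncated[idx[i]] <- (i - w < 1L) || (i + w > k)
    }
  }
  attr(track, "window_bp") <- window_bp
  class(track) <- c("di_track", "data.frame")
  track
}

running_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  sapply(seq_len(n), function(i) {
    rng <- max(1, i - (k %/% 2)):min(n, i + (k %/% 2))
    mean(x[rng])
  })
}

#' Call TADs from a directionality-index track
#'
#' The DI track is smoothed with a centered running mean, and a boundary is
#' placed wherever a sustained-negative run (length >= `persistence`) is
#' followed by a sustained-positive run (length >= `persistence`); short
#' flicker runs (length < `persistence`) of any sign between the two flanks
#' are tolerated. Because the running mean lags the true sign change by up
#' to half the smoothing window, the boundary is refined to the start of the
#' contiguous positive run of the *raw* DI track containing (or nearest
#' right of) the smoothed transition. Domains are the intervals between
#' consecutive boundaries (and chromosome ends); domains shorter than
#' `min_tad_bins` are dropped.
#'
#' @param di A `di_track` (see [directionality_index()]).
#' @param min_tad_bins Minimum domain size in bins.
#' @param persistence Minimum run length of each sign flank.
#' @param smooth Running-mean window in bins (1 = no smoothing).
#' @return A `tad_set` `data.frame` (`chrom`, `start`, `end` in bp) with
#'   attributes `sample` and `boundaries` (`data.frame(chrom, bin)`, 1-based
#'   bin offset within the chromosome of each internal boundary).
#' @export
call_tads <- function(di, min_tad_bins = 5L, persistence = 3L, smooth = 3L) {
  stopifnot(inherits(di, "di_track"))
  doms <- list()
  bnds <- list()
  for (ch in unique(di$chrom)) {
    d <- di[di$chrom == ch, ]
    x <- d$di
    x[is.na(x)] <- 0
    raw <- d$di
    raw[is.na(raw)] <- 0
    x <- running_mean(x, smooth)
    sgn <- sign(x)
    r <- rle(sgn)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    chrom_bnd <- integer(0)
    i <- 1
    while (i <= length(r$lengths)) {
      if (r$values[i] == -1 && r$lengths[i] >= persistence) {
        # skip flicker runs shorter than the persistence requirement
        j <- i + 1
        while (j <= length(r$lengths) &&
               (r$values[j] == 0 || r$lengths[j] < persistence)) j <- j + 1
        if (j <= length(r$lengths) && r$values[j] == 1 &&
            r$lengths[j] >= persistence) {
          b <- starts[j]
          # undo the running-mean lag: snap to the raw-DI sign change
          while (b > 1L && raw[b - 1L] > 0) b <- b - 1L
          while (b < length(raw) && raw[b] <= 0) b <- b + 1L
          chrom_bnd <- c(chrom_bnd, b)
          i <- j - 1L
        }
      }
      i <- i + 1
    }
    chrom_bnd <- sort(unique(chrom_bnd))
    k <- nrow(d)
    seg_start <- c(1L, chrom_bnd)
    seg_end <- c(chrom_bnd - 1L, k)
    keep <- (seg_end - seg_start + 1L) >= min_tad_bins
    if (any(keep))
      doms[[ch]] <- data.frame(chrom = ch,
                               start = d$start[seg_start[keep]],
                               end = d$end[seg_end[keep]],
                               stringsAsFactors = FALSE)
    if (length(chrom_bnd))
      bnds[[ch]] <- data.frame(chrom = ch, bin = chrom_bnd,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(doms)) do.call(rbind, doms) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rownames(out) <- NULL
  attr(out, "sample") <- attr(di, "sample")
  attr(out, "boundaries") <- if (length(bnds)) do.call(rbind, bnds) else
    data.frame(chrom = character(0), bin = integer(0))
  class(out) <- c("tad_set", "data.frame")
  out
}

#' Compare two TAD sets: conserved vs specific domains
#'
#' A reference domain is conserved iff some domain of the other sample (same
#' chromosome) has both boundaries within `tol_bins` bins; otherwise it is
#' specific. Symmetric counts are reported for a Venn-style summary.
#'
#' @param ref,other `tad_set` objects on the same bin resolution.
#' @param tol_bins Boundary tolerance in bins.
#' @param resolution_bp Bin size in bp used to convert `tol_bins`.
#' @return `list(domains, counts)`: `domains` is `ref` with a `status`
#'   column; `counts` has `n_conserved`, `n_specific_ref`,
#'   `n_specific_other`.
#' @export
compare_tads <- function(ref, other, tol_bins = 1L, resolution_bp = 4e4) {
  tol <- tol_bins * resolution_bp
  match_status <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      cand <- b[b$chrom == a$chrom[i], , drop = FALSE]
      any(abs(cand$start - a$start[i]) <= tol &
            abs(cand$end - a$end[i]) <= tol)
    }, logical(1))
  }
  ref_cons <- if (nrow(ref)) match_status(ref, other) else logical(0)
  oth_cons <- if (nrow(other)) match_status(other, ref) else logical(0)
  domains <- as.data.frame(ref)
  domains$status <- ifelse(ref_cons, "conserved", "specific")
  list(domains = domains,
       counts = c(n_conserved = sum(ref_cons),
                  n_specific_ref = sum(!ref_cons),
                  n_specific_other = sum(!oth_cons)))
}

#' Classify conserved TADs as activated / repressed / other
#'
#' Genes are assigned to domains by midpoint. Per conserved domain with at
#' least one gene carrying a fold change, the mean log2 fold change
#' (parent relative to F1, F1 as reference) and the fraction of member genes
#' with fold change > 1 are computed. Domains are ranked by mean log2 fold
#' change, descending, ties broken by genomic order; the top
#' `floor(frac * n)` are activated, the bottom `floor(frac * n)` repressed,
#' the rest other. Domains without genes, and specific domains, get `NA`.
#'
#' @param cmp Result of [compare_tads()].
#' @param deg DEG table for the parent-vs-F1 contrast (`gene_id`, `log2fc`).
#' @param genes Gene annotation.
#' @param frac Tail fraction for each class.
#' @return `cmp$domains` with `n_genes`, `fc_fraction`, `mean_log2fc`,
#'   `activity` columns added (inside the returned `cmp` list).
#' @export
classify_tad_activity <- function(cmp, deg, genes, frac = 0.10) {
  dom <- cmp$domains
  dom$n_genes <- 0L
  dom$fc_fraction <- NA_real_
  dom$mean_log2fc <- NA_real_
  dom$activity <- NA_character_
  if (nrow(dom)) {
    mid <- floor((genes$start + genes$end) / 2)
    lfc <- deg$log2fc[match(genes$gene_id, deg$gene_id)]
    for (i in seq_len(nrow(dom))) {
      inside <- genes$chrom == dom$chrom[i] & mid >= dom$start[i] &
        mid < dom$end[i] & is.finite(lfc)
      if (any(inside)) {
        dom$n_genes[i] <- sum(inside)
        dom$fc_fraction[i] <- mean(lfc[inside] > 0)
        dom$mean_log2fc[i] <- mean(lfc[inside])
      }
    }
  }
  rankable <- which(dom$status == "conserved" & dom$n_genes > 0)
  if (length(rankable) > 0) {
    if (length(rankable) < 10L) {
      warning("fewer than 10 rankable TADs; all classified as other")
      dom$activity[rankable] <- "other"
    } else {
      ord <- rankable[order(-dom$mean_log2fc[rankable],
                            dom$chrom[rankable], dom$start[rankable])]
      k <- floor(frac * length(rankable))
      dom$activity[ord] <- "other"
      if (k > 0) {
        dom$activity[ord[seq_len(k)]] <- "activated"
        dom$activity[ord[seq.int(length(ord) - k + 1L, length(ord))]] <-
          "repressed"
      }
    }
  }
  cmp$domains <- dom
  cmp
}

#' Shared vs specific TAD boundaries by DI-window correlation
#'
#' For each boundary, the two samples' DI values over the boundary's
#' `+/- window_bins` bins are correlated (Pearson); the boundary is shared
#' iff `r >= r_min`. Boundaries whose window extends outside the chromosome
#' are excluded (status `out_of_range`); zero-variance windows are flagged
#' `unclassifiable`.
#'
#' @param di_ref,di_other `di_track`s on the same bins.
#' @param boundaries `data.frame(chrom, bin)` with 1-based bin offsets within
#'   the chromosome (as produced by [call_tads()]).
#' @param window_bins Half-window in bins.
#' @param r_min Correlation threshold for a shared boundary.
#' @return `list(boundaries, summary)`: per-boundary `r` and `status` in
#'   `{shared, specific, unclassifiable, out_of_range}`; `summary` has counts
#'   and the fraction specific among classifiable boundaries.
#' @export
boundary_specificity <- function(di_ref, di_other, boundaries,
                                 window_bins = 12L, r_min = 0.75) {
  if (!identical(di_ref$bin_id, di_other$bin_id))
    stop("DI tracks must share the same bins")
  res <- data.frame(chrom = boundaries$chrom, bin = boundaries$bin,
                    r = NA_real_, status = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[i]
    idx <- which(di_ref$chrom == ch)
    k <- length(idx)
    b <- boundaries$bin[i]
    if (b - window_bins < 1 || b + window_bins > k) {
      res$status[i] <- "out_of_range"
      next
    }
    rng <- idx[(b - window_bins):(b + window_bins)]
    x <- di_ref$di[rng]
    y <- di_other$di[rng]
    if (anyNA(x) || anyNA(y) || stats::sd(x) == 0 || stats::sd(y) == 0) {
      res$status[i] <- "unclassifiable"
      next
    }
    r <- stats::cor(x, y)
    res$r[i] <- r
    res$status[i] <- if (r >= r_min) "shared" else "specific"
  }
  classifiable <- res$status %in% c("shared", "specific")
  list(boundaries = res,
       summary = c(n_shared = sum(res$status == "shared", na.rm = TRUE),
                   n_specific = sum(res$status == "specific", na.rm = TRUE),
                   frac_specific = if (any(classifiable))
                     mean(res$status[classifiable] == "specific") else NA_real_))
}

#' Per-sample TAD count and length statistics
#'
#' @param t A `tad_set`.
#' @return `list(n, mean_length_bp, covered_bp)`; `NA` statistics for an
#'   empty set.
#' @export
tad_length_stats <- function(t) {
  if (nrow(t) == 0)
    return(list(n = 0L, mean_length_bp = NA_real_, covered_bp = NA_real_))
  len <- t$end - t$start
  list(n = nrow(t), mean_length_bp = mean(len), covered_bp = sum(len))
}
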