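#' Construct a contact matrix object
#'
#' A `contact_matrix` couples a symmetric non-negative count matrix with its
#' bin table. Matrix row/column `i` corresponds to `bin_id == i - 1`.
#'
#' @param counts Symmetric non-negative numeric matrix.
#' @param bins Bin table covering the same bins (see [make_bins()]).
#' @param state `"raw"` or `"balanced"`.
#' @param mask Logical vector of masked (excluded) bins; defaults to none.
#' @param converged Logical; meaningful for balanced matrices.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bins, state = c("raw", "balanced"),
                           mask = NULL, converged = NA) {
  state <- match.arg(state)
  counts <- as.matrix(counts)
  validate_bins(bins)
  if (nrow(counts) != nrow(bins))
    stop("matrix dimension must equal the number of bins")
  if (any(counts < 0)) stop("contact counts must be non-negative")
  if (!isSymmetric(unname(counts), tol = 1e-8))
    stop("contact matrix must be symmetric")
  if (is.null(mask)) mask <- rep(FALSE, nrow(bins))
  structure(list(counts = unname(counts), bins = bins, state = state,
                 mask = mask, converged = converged),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins, %d chromosome(s), state=%s, %d masked\n",
              nrow(x$bins), length(unique(x$bins$chrom)), x$state,
              sum(x$mask)))
  invisible(x)
}

#' Read a contact matrix from a sparse triplet file
#'
#' The triplet file holds tab-separated rows `bin1_id  bin2_id  count`
#' (0-based bin ids, no header), each unordered pair listed at most once.
#' Unlisted pairs are zero; the matrix is symmetrized on read.
#'
#' @param triplet_path Path to the triplet TSV.
#' @param bins Bin table, or a path to a BED4 bins file.
#' @return A raw [contact_matrix()].
#' @export
read_contact_matrix <- function(triplet_path, bins) {
  if (is.character(bins)) bins <- read_bins(bins)
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  info <- file.info(triplet_path)
  if (is.na(info$size)) stop("triplet file not found: ", triplet_path)
  if (info$size > 0) {
    tr <- utils::read.table(triplet_path, sep = "\t", header = FALSE,
                            col.names = c("bin1", "bin2", "count"))
    if (nrow(tr) > 0) {
      if (any(tr$count < 0)) stop("negative contact count in triplet file")
      if (any(tr$bin1 < 0 | tr$bin1 >= n | tr$bin2 < 0 | tr$bin2 >= n))
        stop("bin id out of range in triplet file")
      key <- paste(pmin(tr$bin1, tr$bin2), pmax(tr$bin1, tr$bin2))
      if (anyDuplicated(key))
        stop("duplicate bin pair in triplet file (e.g. both (i,j) and (j,i))")
      i <- tr$bin1 + 1L
      j <- tr$bin2 + 1L
      counts[cbind(i, j)] <- tr$count
      counts[cbind(j, i)] <- tr$count
    }
  }
  contact_matrix(counts, bins, state = "raw")
}

#' Write a contact matrix as a sparse triplet file
#'
#' Writes the upper triangle (including the diagonal) of non-zero entries as
#' `bin1_id  bin2_id  count`.
#'
#' @param m A [contact_matrix()].
#' @param path Output path.
#' @export
write_contact_matrix <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  tr <- data.frame(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                   count = m$counts[idx])
  tr <- tr[order(tr$bin1, tr$bin2), ]
  utils::write.table(tr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Balance a contact matrix by iterative correction
#'
#' Standardizes the raw observed matrix by ICE-style iterative correction:
#' each round divides the matrix by the outer product of its (active-bin) row
#' sums scaled to mean 1, until all active row sums agree to within `tol`
#' (relative). Bins with a zero raw marginal are masked and excluded from the
#' iteration and from all downstream statistics.
#'
#' @param m Raw [contact_matrix()].
#' @param tol Relative convergence tolerance on row sums.
#' @param max_iter Maximum number of correction rounds.
#' @return Balanced `contact_matrix`; `converged` is `FALSE` (with a warning)
#'   if `max_iter` rounds did not reach `tol`, in which case the best iterate
#'   is returned.
#' @export
balance_matrix <- function(m, tol = 1e-5, max_iter = 200L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$state != "raw") stop("balance_matrix expects a raw matrix")
  n <- nrow(m$counts)
  mask <- m$mask | rowSums(m$counts) == 0
  active <- !mask
  W <- m$counts
  converged <- FALSE
  if (sum(active) > 0) {
    for (it in seq_len(max_iter)) {
      s <- rowSums(W[active, active, drop = FALSE])
      s <- s / mean(s)
      if (max(abs(s - 1)) < tol) {
        converged <- TRUE
        break
      }
      f <- rep(1, n)
      f[active] <- s
      W <- W / outer(f, f)
    }
    if (!converged)
      warning("balancing did not converge within ", max_iter, " iterations")
  } else {
    converged <- TRUE
  }
  W[mask, ] <- 0
  W[, mask] <- 0
  contact_matrix(W, m$bins, state = "balanced", mask = mask,
                 converged = converged)
}

#' Distance-decay expected contact value per chromosome
#'
#' For each chromosome and each diagonal offset `d` (in bins), the expected
#' value is the mean of the matrix entries at that offset over pairs of
#' unmasked bins. Offsets whose entries are all zero (or fully masked) get
#' `expected = 0` and are flagged.
#'
#' @param m Balanced (or raw) [contact_matrix()].
#' @return `data.frame` with `chrom`, `distance` (bins), `expected`,
#'   `n_pairs`, `flagged`.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  out <- lapply(unique(m$bins$chrom), function(ch) {
    idx <- which(m$bins$chrom == ch)
    B <- m$counts[idx, idx, drop = FALSE]
    ok <- !m$mask[idx]
    k <- length(idx)
    exp_d <- numeric(k)
    npair <- integer(k)
    for (d in 0:(k - 1)) {
      i <- seq_len(k - d)
      keep <- ok[i] & ok[i + d]
      npair[d + 1] <- sum(keep)
      exp_d[d + 1] <- if (any(keep)) mean(B[cbind(i[keep], i[keep] + d)]) else 0
    }
    data.frame(chrom = ch, distance = 0:(k - 1), expected = exp_d,
               n_pairs = npair, flagged = exp_d == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Observed/expected matrix (cis blocks)
#'
#' Divides each intra-chromosomal entry by the distance-decay expected value
#' for its chromosome and offset. Entries with a zero expected value, and all
#' inter-chromosomal entries, are set to `NA`.
#'
#' @param m Balanced [contact_matrix()].
#' @param expected Optional precomputed [expected_by_distance()] table.
#' @return Numeric matrix of the same dimension as `m$counts`.
#' @export
oe_matrix <- function(m, expected = NULL) {
  if (is.null(expected)) expected <- expected_by_distance(m)
  n <- nrow(m$counts)
  oe <- matrix(NA_real_, n, n)
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    B <- m$counts[idx, idx, drop = FALSE]
    e <- expected$expected[expected$chrom == ch]
    k <- length(idx)
    D <- abs(outer(seq_len(k), seq_len(k), "-"))
    E <- matrix(e[D + 1], k, k)
    blk <- ifelse(E > 0, B / E, NA_real_)
    oe[idx, idx] <- blk
  }
  oe[m$mask, ] <- NA_real_
  oe[, m$mask] <- NA_real_
  oe
}

#' Cis/trans contact totals and trans/cis ratio
#'
#' Cis totals sum intra-chromosomal counts over the upper triangle including
#' the diagonal (each unordered pair, and the diagonal, counted once); trans
#' totals sum inter-chromosomal pairs.
#'
#' @param m Raw [contact_matrix()].
#' @return `list(cis_total, trans_total, trans_cis_ratio)`.
#' @export
contact_summary <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  chrom <- m$bins$chrom
  ut <- upper.tri(m$counts, diag = TRUE)
  same <- outer(chrom, chrom, "==")
  cis_total <- sum(m$counts[ut & same])
  trans_total <- sum(m$counts[ut & !same])
  if (cis_total == 0) stop("cis total is zero; trans/cis ratio undefined")
  list(cis_total = cis_total, trans_total = trans_total,
       trans_cis_ratio = trans_total / cis_total)
}
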