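# Shared fixture builders; everything is generated in code.

toy_bins <- function(n_per_chrom, chroms = "chr1", res = 100L) {
  make_bins(stats::setNames(rep(n_per_chrom * res, length(chroms)), chroms),
            res)
}

toy_cm <- function(counts, chroms = "chr1", res = 100L,
                   state = "raw", ...) {
  n <- nrow(counts) / length(chroms)
  contact_matrix(counts, toy_bins(n, chroms, res), state = state, ...)
}

write_triplets <- function(rows, path) {
  if (length(rows) == 0) {
    file.create(path)
  } else {
    df <- do.call(rbind, lapply(rows, function(r) data.frame(r[1], r[2], r[3])))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  path
}

random_symmetric <- function(n, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# independent brute-force DI: plain window sums and the chi-square-style score
brute_di <- function(block, w) {
  k <- nrow(block)
  vapply(seq_len(k), function(i) {
    a <- if (i > 1) sum(block[i, max(1, i - w):(i - 1)]) else 0
    b <- if (i < k) sum(block[i, (i + 1):min(k, i + w)]) else 0
    e <- (a + b) / 2
    if (a == b || e == 0) 0 else sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e)
  }, numeric(1))
}

# independent per-diagonal mean
brute_expected <- function(block) {
  k <- nrow(block)
  vapply(0:(k - 1), function(d) {
    mean(block[cbind(seq_len(k - d), seq_len(k - d) + d)])
  }, numeric(1))
}

# deterministic checkerboard contact matrix with genes denser in A
checkerboard_fixture <- function(n = 60, block = 10, contrast = 2,
                                 res = 1e5, genes_per_a_bin = 3) {
  lab <- rep(rep(c("A", "B"), length.out = ceiling(n / block)),
             each = block)[seq_len(n)]
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- 100 * (1 + D)^-1
  same <- outer(lab, lab, "==")
  lam[same] <- lam[same] * contrast
  counts <- round(lam * 10)
  bins <- toy_bins(n, res = res)
  gene_rows <- list()
  for (i in which(lab == "A"))
    for (j in seq_len(genes_per_a_bin))
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(chrom = "chr1", start = bins$start[i] + j * 1000,
                   end = bins$start[i] + j * 1000 + 500)
  for (i in which(lab == "B"))
    gene_rows[[length(gene_rows) + 1L]] <-
      data.frame(chrom = "chr1", start = bins$start[i] + 1000,
                 end = bins$start[i] + 1500)
  genes <- do.call(rbind, gene_rows)
  genes$gene_id <- sprintf("G%03d", seq_len(nrow(genes)))
  list(cm = contact_matrix(counts, bins, state = "raw"), labels = lab,
       genes = genes[, c("gene_id", "chrom", "start", "end")], bins = bins)
}

# minimal compartment track built by hand
manual_track <- function(labels, sample = "S", res = 1e5) {
  bins <- toy_bins(length(labels), res = res)
  tr <- bins[, c("chrom", "start", "end", "bin_id")]
  tr$pc1 <- ifelse(labels == "A", 1, ifelse(labels == "B", -1, NA))
  tr$label <- labels
  attr(tr, "sample") <- sample
  class(tr) <- c("compartment_track", "data.frame")
  tr
}

manual_di <- function(di_values, chroms = "chr1", res = 4e4,
                      sample = "S") {
  bins <- toy_bins(length(di_values) / length(chroms), chroms, res)
  tr <- bins[, c("chrom", "start", "end", "bin_id")]
  tr$di <- di_values
  tr$truncated <- FALSE
  attr(tr, "sample") <- sample
  attr(tr, "window_bp") <- 2e6
  class(tr) <- c("di_track", "data.frame")
  tr
}

manual_expr <- function(fpkm_matrix, gene_ids = NULL) {
  df <- as.data.frame(fpkm_matrix)
  names(df) <- as.vector(t(outer(c("P1", "P2", "F1"), 1:3, paste, sep = "_")))
  df$gene_id <- if (is.null(gene_ids)) sprintf("G%03d", seq_len(nrow(df)))
  else gene_ids
  expression_table(df)
}
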