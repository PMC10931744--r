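#' Construct / validate an expression table
#'
#' An expression table holds FPKM values for three samples (P1, P2, F1) with
#' `n_reps` replicates each, in columns named `<sample>_<rep>`
#' (e.g. `P1_1`, ..., `F1_3`) plus a `gene_id` column.
#'
#' @param df `data.frame` with `gene_id` and the 9 replicate columns.
#' @param samples Sample ids.
#' @param n_reps Replicates per sample.
#' @return The validated `data.frame` with class `expression_table`.
#' @export
expression_table <- function(df, samples = c("P1", "P2", "F1"), n_reps = 3L) {
  cols <- as.vector(t(outer(samples, seq_len(n_reps), paste, sep = "_")))
  if (!all(c("gene_id", cols) %in% names(df)))
    stop("missing replicate columns: expected ", paste(cols, collapse = ", "))
  vals <- as.matrix(df[, cols])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("FPKM values must be finite and non-negative")
  attr(df, "samples") <- samples
  attr(df, "n_reps") <- n_reps
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Read an expression table from TSV
#'
#' @param path TSV with header `gene_id` plus replicate columns.
#' @inheritParams expression_table
#' @export
read_expression_table <- function(path, samples = c("P1", "P2", "F1"),
                                  n_reps = 3L) {
  expression_table(utils::read.table(path, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE),
                   samples = samples, n_reps = n_reps)
}

rep_cols <- function(expr, sample) {
  n_reps <- attr(expr, "n_reps")
  if (is.null(n_reps)) n_reps <- 3L
  paste(sample, seq_len(n_reps), sep = "_")
}

#' Mean FPKM per gene for one sample
#'
#' @param expr Expression table.
#' @param sample Sample id.
#' @return Numeric vector of per-gene replicate-mean FPKM.
#' @export
sample_mean_fpkm <- function(expr, sample) {
  rowMeans(as.matrix(expr[, rep_cols(expr, sample)]))
}

#' Actively expressed genes of one sample
#'
#' A gene is active when its replicate-mean FPKM is >= `threshold`
#' (boundary inclusive).
#'
#' @param expr Expression table.
#' @param sample Sample id.
#' @param threshold FPKM threshold.
#' @return Character vector of gene ids.
#' @export
active_genes <- function(expr, sample, threshold = 1) {
  expr$gene_id[sample_mean_fpkm(expr, sample) >= threshold]
}

#' Specifically expressed genes and pairwise Venn counts
#'
#' A sample's SEGs are the genes active in that sample and inactive in both
#' other samples. Pairwise counts report, per sample pair, the common active
#' genes and each side's specific ones.
#'
#' @param expr Expression table.
#' @param threshold Active-gene FPKM threshold.
#' @return `list(active, seg, pairwise)`; `active` and `seg` are named lists
#'   of gene-id vectors, `pairwise` a `data.frame` with `sample1`, `sample2`,
#'   `common`, `specific1`, `specific2`.
#' @export
specific_genes <- function(expr, threshold = 1) {
  samples <- attr(expr, "samples")
  act <- lapply(samples, function(s) active_genes(expr, s, threshold))
  names(act) <- samples
  seg <- lapply(samples, function(s) {
    others <- setdiff(samples, s)
    setdiff(act[[s]], union(act[[others[1]]], act[[others[2]]]))
  })
  names(seg) <- samples
  prs <- utils::combn(samples, 2)
  pairwise <- data.frame(sample1 = prs[1, ], sample2 = prs[2, ],
                         common = NA_integer_, specific1 = NA_integer_,
                         specific2 = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(prs))) {
    a <- act[[prs[1, i]]]
    b <- act[[prs[2, i]]]
    pairwise$common[i] <- length(intersect(a, b))
    pairwise$specific1[i] <- length(setdiff(a, b))
    pairwise$specific2[i] <- length(setdiff(b, a))
  }
  list(active = act, seg = seg, pairwise = pairwise)
}

#' Pairwise squared Pearson correlation of expression profiles
#'
#' Computed on `log2(FPKM + 1)` over all genes, for every replicate pair and
#' for sample-level replicate means.
#'
#' @param expr Expression table.
#' @return `list(replicate_r2, sample_r2)`, both squared-correlation
#'   matrices; zero-variance columns give `NA` with a warning.
#' @export
sample_correlation <- function(expr) {
  samples <- attr(expr, "samples")
  cols <- unlist(lapply(samples, function(s) rep_cols(expr, s)))
  x <- log2(as.matrix(expr[, cols]) + 1)
  if (any(apply(x, 2, stats::sd) == 0))
    warning("zero-variance replicate column; correlations are NA")
  r2 <- suppressWarnings(stats::cor(x))^2
  means <- sapply(samples, function(s) sample_mean_fpkm(expr, s))
  sm <- suppressWarnings(stats::cor(log2(means + 1)))^2
  list(replicate_r2 = r2, sample_r2 = sm)
}

#' Percentages from category counts (report layer)
#'
#' @param counts Named (or unnamed) non-negative counts.
#' @param digits Decimal places.
#' @return Percentages of the total, rounded.
#' @export
category_percentages <- function(counts, digits = 2) {
  round(100 * counts / sum(counts), digits)
}

#' Differential-expression flag
#'
#' A gene is a DEG when `padj < p_max` and `|log2fc| > lfc_min` (strict).
#'
#' @param deg DEG table with `log2fc` and `padj`.
#' @param p_max Adjusted-p threshold.
#' @param lfc_min Absolute log2 fold-change threshold (excluded boundary).
#' @return Logical vector.
#' @export
is_deg <- function(deg, p_max = 0.05, lfc_min = 1) {
  deg$padj < p_max & abs(deg$log2fc) > lfc_min
}

#' Trio DEG categories (Up / Down / B2P) and per-contrast report
#'
#' Trio DEGs are genes flagged as DEGs in both F1-vs-parent contrasts. With
#' parent and hybrid replicate-mean FPKM: `Up` = F1 above both parents,
#' `Down` = below both, `B2P` = strictly between the parent means. When the
#' parent means are equal a gene cannot be B2P and is assigned Up or Down by
#' comparison with that common value. Pairwise contrast rows report Up/Down
#' relative to the reference sample (the one after "vs.").
#'
#' @param degs Named list of DEG tables: `P1_vs_P2`, `F1_vs_P1`, `F1_vs_P2`,
#'   each with `gene_id`, `log2fc`, `padj` (`log2fc` is log2 of the first
#'   sample over the reference).
#' @param expr Expression table.
#' @return `list(report, trio_genes, trio_category)`: `report` is a
#'   Table-1-style `data.frame` (contrast, up, down, b2p, total plus
#'   percentage columns, 2 dp); `trio_category` is a named vector over the
#'   trio DEG set.
#' @export
classify_trio_degs <- function(degs, expr) {
  stopifnot(all(c("P1_vs_P2", "F1_vs_P1", "F1_vs_P2") %in% names(degs)))
  pair_row <- function(deg) {
    d <- deg[is_deg(deg), ]
    c(up = sum(d$log2fc > 0), down = sum(d$log2fc < 0))
  }
  r12 <- pair_row(degs$P1_vs_P2)
  rf1 <- pair_row(degs$F1_vs_P1)
  rf2 <- pair_row(degs$F1_vs_P2)
  trio <- intersect(degs$F1_vs_P1$gene_id[is_deg(degs$F1_vs_P1)],
                    degs$F1_vs_P2$gene_id[is_deg(degs$F1_vs_P2)])
  mP1 <- sample_mean_fpkm(expr, "P1")[match(trio, expr$gene_id)]
  mP2 <- sample_mean_fpkm(expr, "P2")[match(trio, expr$gene_id)]
  mF1 <- sample_mean_fpkm(expr, "F1")[match(trio, expr$gene_id)]
  lo <- pmin(mP1, mP2)
  hi <- pmax(mP1, mP2)
  cat_trio <- ifelse(mF1 >= hi, "Up", ifelse(mF1 <= lo, "Down", "B2P"))
  names(cat_trio) <- trio
  tri <- c(up = sum(cat_trio == "Up"), down = sum(cat_trio == "Down"),
           b2p = sum(cat_trio == "B2P"))
  mk_row <- function(contrast, up, down, b2p = NA_integer_) {
    total <- sum(c(up, down, b2p), na.rm = TRUE)
    pct <- if (total > 0)
      category_percentages(c(up, down, if (!is.na(b2p)) b2p)) else
        rep(NA_real_, 2 + !is.na(b2p))
    data.frame(contrast = contrast, up = up, down = down, b2p = b2p,
               total = total, up_pct = pct[1], down_pct = pct[2],
               b2p_pct = if (!is.na(b2p)) pct[3] else NA_real_,
               stringsAsFactors = FALSE)
  }
  report <- rbind(mk_row("P1_vs_P2", r12["up"], r12["down"]),
                  mk_row("F1_vs_P1", rf1["up"], rf1["down"]),
                  mk_row("F1_vs_P2", rf2["up"], rf2["down"]),
                  mk_row("F1_vs_both", tri["up"], tri["down"], tri["b2p"]))
  rownames(report) <- NULL
  list(report = report, trio_genes = trio, trio_category = cat_trio)
}

#' Mid-parent and high-parent heterosis
#'
#' `MPH = 100 * (mean(F1) - mid-parent) / mid-parent`, with the mid-parent
#' value the average of the two parent means;
#' `HPH = 100 * (mean(F1) - best parent) / best parent`, with the best
#' (optimal) parent the larger parent mean.
#'
#' @param pheno `data.frame(trait, sample, value)` with per-replicate trait
#'   values; samples `P1`, `P2`, `F1`.
#' @return `data.frame(trait, mph_percent, hph_percent)`.
#' @export
heterosis_stats <- function(pheno) {
  stopifnot(all(c("trait", "sample", "value") %in% names(pheno)))
  out <- lapply(unique(pheno$trait), function(tr) {
    p <- pheno[pheno$trait == tr, ]
    m <- tapply(p$value, p$sample, mean)
    if (anyNA(m[c("P1", "P2", "F1")]))
      stop("trait ", tr, " lacks replicates for some sample")
    if (m[["P1"]] <= 0 || m[["P2"]] <= 0)
      stop("non-positive parent mean for trait ", tr)
    mid <- (m[["P1"]] + m[["P2"]]) / 2
    best <- max(m[["P1"]], m[["P2"]])
    data.frame(trait = tr,
               mph_percent = 100 * (m[["F1"]] - mid) / mid,
               hph_percent = 100 * (m[["F1"]] - best) / best,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simple two-group differential-expression test (synthetic data)
#'
#' A Welch two-sample t-test per gene on `log2(FPKM + 1)` replicate values
#' with Benjamini-Hochberg adjustment. `log2fc` is the log2 ratio of the
#' group FPKM means (group A over group B, i.e. B as reference). This is a
#' convenience test for synthetic data; it does not reproduce a count-based
#' negative-binomial test, and real DEG tables should be supplied as input
#' where available.
#'
#' @param expr Expression table.
#' @param groupA,groupB Sample ids (A is the numerator of the fold change).
#' @return DEG table `data.frame(gene_id, log2fc, pvalue, padj, is_deg)`.
#' @export
simple_de_test <- function(expr, groupA, groupB) {
  xa <- log2(as.matrix(expr[, rep_cols(expr, groupA)]) + 1)
  xb <- log2(as.matrix(expr[, rep_cols(expr, groupB)]) + 1)
  ma <- sample_mean_fpkm(expr, groupA)
  mb <- sample_mean_fpkm(expr, groupB)
  pv <- vapply(seq_len(nrow(expr)), function(i) {
    a <- xa[i, ]
    b <- xb[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
  }, numeric(1))
  eps <- 1e-9
  lfc <- log2((ma + eps) / (mb + eps))
  lfc[ma == 0 & mb == 0] <- 0
  out <- data.frame(gene_id = expr$gene_id, log2fc = lfc, pvalue = pv,
                    padj = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE)
  out$is_deg <- is_deg(out)
  attr(out, "contrast") <- paste0(groupA, "_vs_", groupB)
  out
}

#' Flip a DEG table's contrast direction
#'
#' Negates `log2fc` so a `A_vs_B` table becomes `B_vs_A`; p-values are
#' unchanged.
#'
#' @param deg DEG table.
#' @return DEG table with the opposite contrast.
#' @export
flip_contrast <- function(deg) {
  deg$log2fc <- -deg$log2fc
  ctr <- attr(deg, "contrast")
  if (!is.null(ctr)) {
    parts <- strsplit(ctr, "_vs_")[[1]]
    if (length(parts) == 2) attr(deg, "contrast") <- paste0(parts[2], "_vs_",
                                                            parts[1])
  }
  deg
}
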