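#' Call A/B compartments by PCA of the O/E correlation matrix
#'
#' Per chromosome: the balanced matrix is converted to an observed/expected
#' matrix, the Pearson correlation matrix over unmasked bins is computed, and
#' its first principal component (leading eigenvector) is the compartment
#' score. The sign is oriented per chromosome so that positive-score bins
#' (compartment A) have the higher mean gene density, reflecting that A
#' compartments are gene-dense euchromatin. Bins are labelled `A` when
#' `pc1 > 0`, `B` otherwise.
#'
#' Bins with no O/E variance are masked. A chromosome with fewer than
#' `min_bins` usable bins is fully masked with a warning, as is a chromosome
#' whose correlation matrix is degenerate (constant).
#'
#' @param m Balanced [contact_matrix()] (typically at 100 kb).
#' @param genes Gene annotation `data.frame` (`gene_id`, `chrom`, `start`,
#'   `end`) used for orientation.
#' @param sample Sample id stored on the track.
#' @param min_bins Minimum unmasked bins per chromosome.
#' @return A `compartment_track` `data.frame`: `chrom`, `start`, `end`,
#'   `bin_id`, `pc1`, `label` in `{A, B, masked}`, with attribute `sample`.
#' @export
call_compartments <- function(m, genes, sample = "sample", min_bins = 10L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$state != "balanced") stop("call_compartments expects a balanced matrix")
  oe <- oe_matrix(m)
  dens <- gene_density(genes, m$bins)
  track <- m$bins[, c("chrom", "start", "end", "bin_id")]
  track$pc1 <- NA_real_
  track$label <- "masked"
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    blk <- oe[idx, idx, drop = FALSE]
    # usable bins: unmasked with non-degenerate O/E profile
    vr <- apply(blk, 1, function(x) stats::var(x, na.rm = TRUE))
    ok <- !m$mask[idx] & is.finite(vr) & vr > 1e-12
    if (sum(ok) < min_bins) {
      warning("chromosome ", ch, " has fewer than ", min_bins,
              " usable bins; masked")
      next
    }
    sub <- blk[ok, ok, drop = FALSE]
    sub[is.na(sub)] <- 0
    C <- suppressWarnings(stats::cor(sub))
    C[!is.finite(C)] <- 0
    if (stats::var(as.vector(C)) < 1e-12) {
      warning("degenerate correlation matrix on chromosome ", ch, "; masked")
      next
    }
    eg <- eigen(C, symmetric = TRUE)
    pc1 <- eg$vectors[, 1]
    d <- dens[idx][ok]
    m_pos <- if (any(pc1 > 0)) mean(d[pc1 > 0]) else NA_real_
    m_neg <- if (any(pc1 < 0)) mean(d[pc1 < 0]) else NA_real_
    if (is.finite(m_pos) && is.finite(m_neg)) {
      if (m_pos < m_neg) pc1 <- -pc1
      else if (m_pos == m_neg)
        warning("gene-density tie on chromosome ", ch,
                "; keeping PCA's native sign")
    } else {
      warning("one-sided PC1 on chromosome ", ch,
              "; keeping PCA's native sign")
    }
    track$pc1[idx][ok] <- pc1
    track$label[idx][ok] <- ifelse(pc1 > 0, "A", "B")
  }
  attr(track, "sample") <- sample
  class(track) <- c("compartment_track", "data.frame")
  track
}

#' Compare gene expression between A and B compartments
#'
#' Genes are assigned to bins by midpoint and inherit the bin's label; per
#' label the gene count and mean `log2(FPKM + 1)` (mean FPKM over the sample's
#' replicates) are reported, with a Wilcoxon rank-sum test of A vs B.
#'
#' @param track A `compartment_track`.
#' @param expr Expression table (see [expression_table()]).
#' @param genes Gene annotation.
#' @param sample Sample whose replicates are averaged; defaults to the
#'   track's sample attribute.
#' @return `list(summary = data.frame(label, n_genes, mean_log2_fpkm),
#'   p_value)`; statistics are `NA` when a label has no genes.
#' @export
compartment_expression_contrast <- function(track, expr, genes,
                                            sample = attr(track, "sample")) {
  g <- assign_genes_to_bins(genes, as.data.frame(track))
  lab <- track$label[match(g$bin_id, track$bin_id)]
  fpkm <- sample_mean_fpkm(expr, sample)
  x <- log2(fpkm[match(g$gene_id, expr$gene_id)] + 1)
  vals <- split(x[lab %in% c("A", "B")], lab[lab %in% c("A", "B")])
  summ <- data.frame(label = c("A", "B"),
                     n_genes = c(length(vals[["A"]]), length(vals[["B"]])),
                     mean_log2_fpkm = c(mean_or_na(vals[["A"]]),
                                        mean_or_na(vals[["B"]])))
  p <- if (summ$n_genes[1] > 0 && summ$n_genes[2] > 0) {
    if (stats::var(c(vals[["A"]], vals[["B"]])) == 0) 1 # all tied: no signal
    else suppressWarnings(stats::wilcox.test(vals[["A"]],
                                             vals[["B"]])$p.value)
  } else NA_real_
  list(summary = summ, p_value = p)
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

all_trio_states <- function() {
  g <- expand.grid(P2 = c("A", "B"), F1 = c("A", "B"), P1 = c("A", "B"),
                   stringsAsFactors = FALSE)
  sprintf("%s-to-%s-to-%s", g$P1, g$F1, g$P2)
}

#' Classify trio compartment states and shifts
#'
#' Combines three compartment tracks on an identical bin table into a per-bin
#' trio state. State strings read in the order P1 -> F1 -> P2 (e.g.
#' `"B-to-A-to-B"` is a bin that is B in both parents and A in the hybrid).
#' Percentages are computed over bins unmasked in all three samples.
#'
#' Aggregates reported alongside the 8 per-state percentages:
#' * `unchanged`: both `A-to-A-to-A` and `B-to-B-to-B`;
#' * `a_gain_split` / `b_gain_split`: parents disagree and F1 is A / B;
#' * `a_flip` / `b_flip`: parents agree and F1 takes the opposite label;
#' * `a_gain_total`: any bin where F1 is A and at least one parent is B
#'   (`a_gain_split + a_flip`), and symmetrically `b_gain_total`.
#'
#' @param tracks Named list with elements `P1`, `F1`, `P2`, each a
#'   `compartment_track` on the same bins.
#' @return `list(table, percentages, aggregates, n_unmasked)`; `table` has
#'   per-bin states, the trio state and pairwise parent->F1 shifts;
#'   `percentages` is the named 8-state percentage vector (unrounded; round
#'   to 2 dp for reporting).
#' @export
classify_shifts <- function(tracks) {
  stopifnot(all(c("P1", "F1", "P2") %in% names(tracks)))
  b1 <- tracks$P1[, c("chrom", "start", "end", "bin_id")]
  for (s in c("F1", "P2"))
    if (!identical(b1, tracks[[s]][, c("chrom", "start", "end", "bin_id")]))
      stop("compartment tracks must share an identical bin table")
  tab <- b1
  tab$state_P1 <- tracks$P1$label
  tab$state_F1 <- tracks$F1$label
  tab$state_P2 <- tracks$P2$label
  unmasked <- tab$state_P1 %in% c("A", "B") &
    tab$state_F1 %in% c("A", "B") & tab$state_P2 %in% c("A", "B")
  tab$trio_state <- ifelse(unmasked,
                           sprintf("%s-to-%s-to-%s", tab$state_P1,
                                   tab$state_F1, tab$state_P2),
                           "masked")
  tab$shift_P1_F1 <- ifelse(unmasked,
                            sprintf("%s-to-%s", tab$state_P1, tab$state_F1),
                            "masked")
  tab$shift_P2_F1 <- ifelse(unmasked,
                            sprintf("%s-to-%s", tab$state_P2, tab$state_F1),
                            "masked")
  n_unmasked <- sum(unmasked)
  states <- all_trio_states()
  counts <- table(factor(tab$trio_state[unmasked], levels = states))
  pct <- 100 * as.numeric(counts) / max(n_unmasked, 1L)
  names(pct) <- states
  list(table = tab, percentages = pct,
       aggregates = aggregate_shift_percentages(pct),
       n_unmasked = n_unmasked)
}

#' Aggregate trio-state percentages
#'
#' Report-layer addition over the 8 trio-state percentages (states read
#' P1 -> F1 -> P2). See [classify_shifts()] for the aggregate definitions.
#'
#' @param pct Named numeric vector over the 8 trio states (percentages).
#' @return Named numeric vector of aggregates.
#' @export
aggregate_shift_percentages <- function(pct) {
  stopifnot(all(all_trio_states() %in% names(pct)))
  g <- function(...) sum(pct[c(...)])
  c(unchanged = g("A-to-A-to-A", "B-to-B-to-B"),
    a_gain_split = g("A-to-A-to-B", "B-to-A-to-A"),
    b_gain_split = g("A-to-B-to-B", "B-to-B-to-A"),
    a_flip = g("B-to-A-to-B"),
    b_flip = g("A-to-B-to-A"),
    a_gain_total = g("A-to-A-to-B", "B-to-A-to-A", "B-to-A-to-B"),
    b_gain_total = g("A-to-B-to-B", "B-to-B-to-A", "A-to-B-to-A"))
}

#' Genes located in pairwise compartment shifts
#'
#' Returns, for one parent vs F1, the genes whose midpoint bin changed label
#' (`A-to-B` or `B-to-A`, read parent -> F1).
#'
#' @param shifts Result of [classify_shifts()].
#' @param genes Gene annotation.
#' @param parent `"P1"` or `"P2"`.
#' @return `data.frame(gene_id, chrom, bin_id, shift)` restricted to shifted
#'   bins.
#' @export
shift_gene_lists <- function(shifts, genes, parent = c("P1", "P2")) {
  parent <- match.arg(parent)
  tab <- shifts$table
  col <- paste0("shift_", parent, "_F1")
  g <- assign_genes_to_bins(genes, tab)
  sh <- tab[[col]][match(g$bin_id, tab$bin_id)]
  keep <- !is.na(g$bin_id) & sh %in% c("A-to-B", "B-to-A")
  data.frame(gene_id = g$gene_id[keep], chrom = g$chrom[keep],
             bin_id = g$bin_id[keep], shift = sh[keep],
             stringsAsFactors = FALSE)
}
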