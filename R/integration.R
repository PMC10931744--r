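#' Candidate genes from compartment shifts
#'
#' Intersects a parent-vs-F1 DEG contrast with the genes located in pairwise
#' A-to-B / B-to-A compartment shifts (parent -> F1). A candidate is
#' concordant when the expression direction matches the structural change:
#' B-to-A with up-regulation in F1, A-to-B with down-regulation in F1.
#' Discordant candidates are retained and flagged.
#'
#' @param deg DEG table for the F1-vs-parent contrast (`log2fc > 0` means
#'   up-regulated in F1).
#' @param shift_genes Gene-level shift list from [shift_gene_lists()].
#' @param contrast Label recorded on the candidates (e.g. `"F1_vs_P1"`).
#' @return Candidate `data.frame(gene_id, source, contrast,
#'   structure_change, log2fc, padj, expression_direction, concordant)`.
#' @export
integrate_shifts <- function(deg, shift_genes, contrast = "F1_vs_P1") {
  d <- deg[is_deg(deg), ]
  keep <- shift_genes$gene_id %in% d$gene_id
  sg <- shift_genes[keep, , drop = FALSE]
  i <- match(sg$gene_id, d$gene_id)
  up <- d$log2fc[i] > 0
  data.frame(gene_id = sg$gene_id, source = "compartment_shift",
             contrast = contrast, structure_change = sg$shift,
             log2fc = d$log2fc[i], padj = d$padj[i],
             expression_direction = ifelse(up, "up_in_F1", "down_in_F1"),
             concordant = (sg$shift == "B-to-A" & up) |
               (sg$shift == "A-to-B" & !up),
             stringsAsFactors = FALSE)
}

#' Candidate genes from TAD activity classes
#'
#' DEGs (parent-vs-F1 contrast, F1 as reference) whose midpoint lies inside
#' an activated or repressed conserved TAD. Concordance follows the
#' fold-change convention used to rank the TADs: a repressed TAD should hold
#' genes down-regulated in the parent relative to F1 (`log2fc < 0`), an
#' activated TAD up-regulated ones. DEGs in "other" TADs are not candidates.
#'
#' @param deg DEG table for the parent-vs-F1 contrast (`log2fc` is parent
#'   over F1).
#' @param cmp Result of [classify_tad_activity()].
#' @param genes Gene annotation.
#' @param contrast Label recorded on the candidates (e.g. `"P1_vs_F1"`).
#' @return Candidate `data.frame` (same columns as [integrate_shifts()]).
#' @export
integrate_tads <- function(deg, cmp, genes, contrast = "P1_vs_F1") {
  dom <- cmp$domains
  dom <- dom[!is.na(dom$activity) & dom$activity %in%
               c("activated", "repressed"), , drop = FALSE]
  d <- deg[is_deg(deg), ]
  mid <- floor((genes$start + genes$end) / 2)
  rows <- list()
  for (i in seq_len(nrow(dom))) {
    inside <- genes$chrom == dom$chrom[i] & mid >= dom$start[i] &
      mid < dom$end[i]
    gid <- intersect(genes$gene_id[inside], d$gene_id)
    if (!length(gid)) next
    j <- match(gid, d$gene_id)
    parent_up <- d$log2fc[j] > 0
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, source = "tad_activity", contrast = contrast,
      structure_change = dom$activity[i], log2fc = d$log2fc[j],
      padj = d$padj[j],
      # parent-vs-F1 fold change: parent up means F1 down
      expression_direction = ifelse(parent_up, "down_in_F1", "up_in_F1"),
      concordant = (dom$activity[i] == "activated" & parent_up) |
        (dom$activity[i] == "repressed" & !parent_up),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), source = character(0),
                      contrast = character(0), structure_change = character(0),
                      log2fc = numeric(0), padj = numeric(0),
                      expression_direction = character(0),
                      concordant = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Merge compartment and TAD candidate lists
#'
#' Deduplicated union by gene id; genes carried by both evidence tracks get
#' `source = "both"`. Per-gene records from each track are retained in the
#' detail table.
#'
#' @param comp_list Candidates from [integrate_shifts()].
#' @param tad_list Candidates from [integrate_tads()].
#' @return `list(candidates, detail, summary)`: `candidates` is one row per
#'   gene with the merged source; `summary` counts genes by source and
#'   concordance.
#' @export
final_candidates <- function(comp_list, tad_list) {
  detail <- rbind(comp_list, tad_list)
  genes_comp <- unique(comp_list$gene_id)
  genes_tad <- unique(tad_list$gene_id)
  all_genes <- union(genes_comp, genes_tad)
  source <- ifelse(all_genes %in% genes_comp & all_genes %in% genes_tad,
                   "both",
                   ifelse(all_genes %in% genes_comp, "compartment_shift",
                          "tad_activity"))
  conc <- vapply(all_genes, function(g)
    any(detail$concordant[detail$gene_id == g]), logical(1))
  candidates <- data.frame(gene_id = all_genes, source = source,
                           concordant = conc, stringsAsFactors = FALSE)
  summary <- c(n_candidates = length(all_genes),
               n_compartment_only = sum(source == "compartment_shift"),
               n_tad_only = sum(source == "tad_activity"),
               n_both = sum(source == "both"),
               n_concordant = sum(conc))
  list(candidates = candidates, detail = detail, summary = summary)
}
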