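#' Simulation configuration for a synthetic trio
#'
#' Defines the generating model for a parent/parent/hybrid Hi-C +
#' expression dataset with planted, recorded structure. Cis contact
#' intensity decays as a power law with bin distance and is boosted
#' multiplicatively for bin pairs sharing a compartment label
#' (checkerboard blocks) or a TAD; trans contacts are uniform. Counts are
#' Poisson. Genes are placed with higher density in A bins and expressed
#' from a lognormal model with an A-compartment boost, so the canonical
#' compartment/expression relationships hold by construction.
#'
#' @param n_chroms Number of chromosomes.
#' @param bins_per_chrom Bins per chromosome.
#' @param resolution Bin size in bp.
#' @param base_count Expected count at distance 0 before structure factors.
#' @param decay_exponent Power-law distance-decay exponent (> 0).
#' @param compartment_block_len Checkerboard block length in bins; the
#'   default corresponds to 2 Mb at the chosen resolution, since
#'   compartment blocks are a genomic-scale feature that must not shrink
#'   with the analysis resolution.
#' @param compartment_contrast Multiplicative boost for same-label pairs
#'   (> 1; 1 disables compartment structure).
#' @param tad_bins_range Length-2 range of TAD sizes in bins; the default
#'   corresponds to roughly 0.5-1 Mb domains at the chosen resolution.
#' @param tad_contrast Multiplicative boost for same-TAD pairs (> 1; 1
#'   disables TADs).
#' @param tad_boundaries Optional named list (per chromosome) of fixed TAD
#'   start bins (1-based, excluding bin 1); overrides random TAD sizes.
#' @param f1_split_min_bins If finite, parental TADs of at least this many
#'   bins are candidates for being split in two in F1 (more, smaller TADs
#'   in the hybrid, while most domains stay conserved).
#' @param f1_split_frac Fraction of candidate TADs actually split in F1.
#' @param trans_weight Named vector (`P1`, `P2`, `F1`) of trans intensity
#'   relative to `base_count`.
#' @param planted_shifts List of planted compartment shifts, each
#'   `list(chrom =, bins =, pattern = c(P1 =, F1 =, P2 =))` with `bins`
#'   1-based offsets within the chromosome; `NULL` uses a default set
#'   covering ~11% of bins with a net B-to-A gain in F1.
#' @param n_genes Number of genes.
#' @param a_density_ratio Gene-placement weight of A bins relative to B.
#' @param expr_base_meanlog,expr_sdlog_gene Natural-log mean/sd of the
#'   gene-level baseline FPKM.
#' @param a_expr_boost Multiplicative FPKM boost for genes in A bins
#'   (per sample, following that sample's labels).
#' @param sdlog_rep Replicate-level lognormal noise (natural-log sd).
#' @param planted_degs `data.frame(gene_id, sample, log2fc)` of explicit
#'   expression effects, or `NULL` for a default planted set.
#' @param pheno_means Named list of per-trait sample means (defaults mimic
#'   strong biomass heterosis: fresh-weight MPH 159.28%, HPH 150.11%).
#' @param pheno_cv Replicate coefficient of variation for phenotypes.
#' @param seed Integer seed; a fixed seed makes the bundle byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, bins_per_chrom = 200L,
                       resolution = 1e5, base_count = 300,
                       decay_exponent = 1.0,
                       compartment_block_len = max(2L,
                                                   round(2e6 / resolution)),
                       compartment_contrast = 2.0,
                       tad_bins_range = pmax(2L, round(c(5e5, 1e6) /
                                                         resolution)),
                       tad_contrast = 1.8,
                       tad_boundaries = NULL, f1_split_min_bins = Inf,
                       f1_split_frac = 0.5,
                       trans_weight = c(P1 = 0.01, P2 = 0.01, F1 = 0.01),
                       planted_shifts = NULL,
                       n_genes = 600L, a_density_ratio = 3,
                       expr_base_meanlog = log(3), expr_sdlog_gene = 0.8,
                       a_expr_boost = 6, sdlog_rep = 0.15,
                       planted_degs = NULL,
                       pheno_means = list(
                         fresh_weight = c(P1 = 2.78776, P2 = 3, F1 = 7.5033),
                         dry_weight = c(P1 = 0.30, P2 = 0.28, F1 = 0.52)),
                       pheno_cv = 0.03, seed = 1L) {
  if (compartment_contrast < 1 || tad_contrast < 1)
    stop("structure contrasts must be >= 1")
  if (is.null(tad_boundaries) && tad_bins_range[1] > bins_per_chrom)
    stop("infeasible config: minimum TAD size exceeds the chromosome")
  cfg <- list(n_chroms = n_chroms, bins_per_chrom = bins_per_chrom,
              resolution = resolution, base_count = base_count,
              decay_exponent = decay_exponent,
              compartment_block_len = compartment_block_len,
              compartment_contrast = compartment_contrast,
              tad_bins_range = tad_bins_range, tad_contrast = tad_contrast,
              tad_boundaries = tad_boundaries,
              f1_split_min_bins = f1_split_min_bins,
              f1_split_frac = f1_split_frac,
              trans_weight = trans_weight,
              planted_shifts = planted_shifts, n_genes = n_genes,
              a_density_ratio = a_density_ratio,
              expr_base_meanlog = expr_base_meanlog,
              expr_sdlog_gene = expr_sdlog_gene,
              a_expr_boost = a_expr_boost, sdlog_rep = sdlog_rep,
              planted_degs = planted_degs, pheno_means = pheno_means,
              pheno_cv = pheno_cv, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

default_planted_shifts <- function(cfg) {
  if (cfg$bins_per_chrom < 160L) return(list())
  out <- list()
  for (c_i in seq_len(cfg$n_chroms)) {
    ch <- paste0("chr", c_i)
    out <- c(out, list(
      list(chrom = ch, bins = 55:60,
           pattern = c(P1 = "A", F1 = "A", P2 = "B")),
      list(chrom = ch, bins = 115:120,
           pattern = c(P1 = "B", F1 = "A", P2 = "A")),
      list(chrom = ch, bins = 147:152,
           pattern = c(P1 = "B", F1 = "A", P2 = "B")),
      list(chrom = ch, bins = 35:38,
           pattern = c(P1 = "A", F1 = "B", P2 = "B"))))
  }
  out
}

base_checkerboard <- function(cfg) {
  lab <- rep(rep(c("A", "B"), length.out = ceiling(cfg$bins_per_chrom /
                                                    cfg$compartment_block_len)),
             each = cfg$compartment_block_len)[seq_len(cfg$bins_per_chrom)]
  lab
}

draw_tad_starts <- function(cfg) {
  # TAD start bins (1-based) per chromosome, first TAD starting at bin 1
  sizes <- integer(0)
  total <- 0L
  while (total < cfg$bins_per_chrom) {
    s <- sample(seq.int(cfg$tad_bins_range[1], cfg$tad_bins_range[2]), 1L)
    sizes <- c(sizes, s)
    total <- total + s
  }
  starts <- cumsum(c(1L, sizes))
  starts[starts <= cfg$bins_per_chrom - cfg$tad_bins_range[1] + 1L]
}

split_tads <- function(starts, n_bins, min_bins, frac = 1) {
  bounds <- c(starts, n_bins + 1L)
  sizes <- diff(bounds)
  cand <- which(sizes >= min_bins)
  n_split <- ceiling(frac * length(cand))
  chosen <- if (n_split > 0 && length(cand) > 0)
    sort(sample(cand, min(n_split, length(cand)))) else integer(0)
  new_starts <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]
    new_starts <- c(new_starts, s)
    if (i %in% chosen)
      new_starts <- c(new_starts, s + sizes[i] %/% 2L)
  }
  sort(unique(new_starts))
}

tad_id_vector <- function(starts, n_bins) {
  findInterval(seq_len(n_bins), sort(unique(c(1L, starts))))
}

#' Simulate a parent/parent/hybrid dataset with recorded truth
#'
#' Generates, for each of P1, P2 and F1, a genome-wide Poisson contact
#' matrix with planted distance decay, compartment checkerboard and TAD
#' blocks; a gene annotation with A-enriched density; a replicate FPKM
#' table coupled to each sample's compartment labels plus explicit planted
#' differential effects; and a phenotype table. All planted structure is
#' returned as truth tables.
#'
#' @param cfg A [sim_config()].
#' @return `list(matrices, bins, genes, expr, pheno, truth, config)`;
#'   `matrices` holds one raw [contact_matrix()] per sample and `truth`
#'   records labels, TAD starts, trio shift states and planted effects.
#' @export
simulate_trio <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- c("P1", "P2", "F1")
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$bins_per_chrom * cfg$resolution,
                                     cfg$n_chroms), chroms)
  bins <- make_bins(chrom_sizes, cfg$resolution)
  nb <- cfg$bins_per_chrom

  # --- compartment labels ----------------------------------------------
  shifts <- if (is.null(cfg$planted_shifts)) default_planted_shifts(cfg)
  else cfg$planted_shifts
  base_lab <- base_checkerboard(cfg)
  labels <- lapply(samples, function(s) {
    lab <- lapply(chroms, function(ch) base_lab)
    names(lab) <- chroms
    for (sh in shifts) lab[[sh$chrom]][sh$bins] <- sh$pattern[[s]]
    lab
  })
  names(labels) <- samples

  # --- TAD structure ----------------------------------------------------
  parent_starts <- lapply(chroms, function(ch) {
    if (!is.null(cfg$tad_boundaries)) sort(unique(c(1L,
                                                    cfg$tad_boundaries[[ch]])))
    else draw_tad_starts(cfg)
  })
  names(parent_starts) <- chroms
  tad_starts <- list(P1 = parent_starts, P2 = parent_starts,
                     F1 = if (is.finite(cfg$f1_split_min_bins))
                       lapply(parent_starts, split_tads, n_bins = nb,
                              min_bins = cfg$f1_split_min_bins,
                              frac = cfg$f1_split_frac)
                     else parent_starts)

  # --- contact matrices -------------------------------------------------
  tw <- cfg$trans_weight
  if (length(tw) == 1L) tw <- stats::setNames(rep(tw, 3), samples)
  matrices <- list()
  for (s in samples) {
    n <- nrow(bins)
    lam <- matrix(cfg$base_count * tw[[s]], n, n)
    for (ch in chroms) {
      idx <- which(bins$chrom == ch)
      k <- length(idx)
      D <- abs(outer(seq_len(k), seq_len(k), "-"))
      block <- cfg$base_count * (1 + D)^(-cfg$decay_exponent)
      lab <- labels[[s]][[ch]]
      same_comp <- outer(lab, lab, "==")
      block[same_comp] <- block[same_comp] * cfg$compartment_contrast
      tid <- tad_id_vector(tad_starts[[s]][[ch]], k)
      same_tad <- outer(tid, tid, "==")
      block[same_tad] <- block[same_tad] * cfg$tad_contrast
      lam[idx, idx] <- block
    }
    counts <- matrix(0, n, n)
    ut <- upper.tri(lam, diag = TRUE)
    counts[ut] <- stats::rpois(sum(ut), lam[ut])
    counts <- counts + t(counts) - diag(diag(counts))
    matrices[[s]] <- contact_matrix(counts, bins, state = "raw")
  }

  # --- genes ------------------------------------------------------------
  w <- ifelse(unlist(lapply(chroms, function(ch) base_lab)) == "A",
              cfg$a_density_ratio, 1)
  gene_bins <- sample(seq_len(nrow(bins)), cfg$n_genes, replace = TRUE,
                      prob = w)
  offset <- floor(stats::runif(cfg$n_genes, 0, cfg$resolution - 2000))
  genes <- data.frame(chrom = bins$chrom[gene_bins],
                      start = bins$start[gene_bins] + offset,
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 1500L
  genes <- genes[order(match(genes$chrom, chroms), genes$start), ]
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end")]
  rownames(genes) <- NULL
  gb <- assign_genes_to_bins(genes, bins)

  # --- planted expression effects --------------------------------------
  bin_offset <- gb$bin_id + 1L - (match(gb$chrom, chroms) - 1L) * nb
  shifted_bins <- lapply(chroms, function(ch)
    unlist(lapply(shifts[vapply(shifts, function(x) x$chrom == ch,
                                logical(1))], `[[`, "bins")))
  names(shifted_bins) <- chroms
  in_shift <- mapply(function(ch, b) b %in% shifted_bins[[ch]],
                     gb$chrom, bin_offset)
  planted <- cfg$planted_degs
  if (is.null(planted)) {
    pool <- genes$gene_id[!in_shift]
    pool <- pool[seq(1, length(pool), by = 7)]
    planted <- data.frame(gene_id = character(0), sample = character(0),
                          log2fc = numeric(0), stringsAsFactors = FALSE)
    if (length(pool) >= 60) {
      planted <- rbind(
        data.frame(gene_id = pool[1:25], sample = "F1", log2fc = 2.5),
        data.frame(gene_id = pool[26:40], sample = "F1", log2fc = -2.5),
        data.frame(gene_id = pool[41:60], sample = "P1", log2fc = 2.0))
    }
  }

  # --- expression table -------------------------------------------------
  base_g <- stats::rnorm(nrow(genes), cfg$expr_base_meanlog,
                         cfg$expr_sdlog_gene)
  expr <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (s in samples) {
    lab_s <- mapply(function(ch, b) labels[[s]][[ch]][b], gb$chrom,
                    bin_offset)
    mu <- base_g + ifelse(lab_s == "A", log(cfg$a_expr_boost), 0)
    pl <- planted[planted$sample == s, , drop = FALSE]
    if (nrow(pl)) {
      i <- match(pl$gene_id, genes$gene_id)
      mu[i] <- mu[i] + pl$log2fc * log(2)
    }
    for (r in 1:3)
      expr[[paste(s, r, sep = "_")]] <-
        exp(mu + stats::rnorm(length(mu), 0, cfg$sdlog_rep))
  }
  expr <- expression_table(expr, samples = c("P1", "P2", "F1"))

  # --- phenotypes -------------------------------------------------------
  pheno <- do.call(rbind, lapply(names(cfg$pheno_means), function(tr) {
    m <- cfg$pheno_means[[tr]]
    do.call(rbind, lapply(names(m), function(s)
      data.frame(trait = tr, sample = s, replicate = 1:3,
                 value = m[[s]] * exp(stats::rnorm(3, 0, cfg$pheno_cv)),
                 stringsAsFactors = FALSE)))
  }))

  # --- truth ------------------------------------------------------------
  lab_df <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample = s, chrom = bins$chrom, bin_id = bins$bin_id,
               label = unlist(labels[[s]])[seq_len(nrow(bins))],
               stringsAsFactors = FALSE)))
  truth_states <- data.frame(
    chrom = bins$chrom, bin_id = bins$bin_id,
    state_P1 = unlist(labels$P1), state_F1 = unlist(labels$F1),
    state_P2 = unlist(labels$P2), stringsAsFactors = FALSE)
  truth_states$trio_state <- sprintf("%s-to-%s-to-%s",
                                     truth_states$state_P1,
                                     truth_states$state_F1,
                                     truth_states$state_P2)
  truth <- list(labels = lab_df, states = truth_states,
                tad_starts = tad_starts, planted_shifts = shifts,
                planted_degs = planted, trans_weight = tw,
                gene_bins = gb)
  list(matrices = matrices, bins = bins, genes = genes, expr = expr,
       pheno = pheno, truth = truth, config = cfg)
}

#' Paper-like trio preset
#'
#' Convenience wrapper around [simulate_trio()] whose hybrid has a boosted
#' trans weight, split (more, smaller) TADs, and the default net B-to-A
#' compartment gain, so the hallmark qualitative trio findings (higher
#' trans/cis ratio in F1, more and smaller F1 TADs, ~90% stable compartments
#' with a net A gain) hold on synthetic data.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A [simulate_trio()] result.
#' @export
make_paper_like_trio <- function(seed = 1L, ...) {
  cfg <- sim_config(trans_weight = c(P1 = 0.01, P2 = 0.01, F1 = 0.016),
                    f1_split_min_bins = 16L, seed = seed, ...)
  simulate_trio(cfg)
}

#' Write a simulated bundle to disk
#'
#' Emits the file formats the pipeline consumes: per-sample sparse triplet
#' matrices, a BED4 bin table, a BED-like gene annotation, the FPKM TSV,
#' the phenotype TSV, truth TSVs, and a plain-text manifest recording the
#' seed and key parameters.
#'
#' @param sim Result of [simulate_trio()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bins(sim$bins, file.path(dir, "bins.bed"))
  for (s in names(sim$matrices))
    write_contact_matrix(sim$matrices[[s]],
                         file.path(dir, paste0(s, ".matrix.tsv")))
  genes_out <- sim$genes
  genes_out$start <- as.integer(genes_out$start)
  genes_out$end <- as.integer(genes_out$end)
  utils::write.table(genes_out, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$expr), file.path(dir, "fpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$pheno, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$labels, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$states, file.path(dir, "truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$planted_degs,
                     file.path(dir, "truth_planted_degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  keys <- c("seed", "n_chroms", "bins_per_chrom", "resolution", "base_count",
            "decay_exponent", "compartment_block_len", "compartment_contrast",
            "tad_contrast", "n_genes", "a_density_ratio")
  manifest <- data.frame(key = keys,
                         value = vapply(keys, function(k)
                           paste(format(cfg[[k]]), collapse = ","),
                           character(1)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
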