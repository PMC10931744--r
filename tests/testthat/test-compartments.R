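test_that("a planted checkerboard is recovered exactly and oriented by gene density", {
  fx <- checkerboard_fixture(n = 60, block = 10, contrast = 2)
  bal <- balance_matrix(fx$cm)
  track <- call_compartments(bal, fx$genes, sample = "P1")
  expect_equal(track$label, fx$labels)
  dens <- gene_density(fx$genes, fx$bins)
  expect_gte(mean(dens[track$label == "A"]), mean(dens[track$label == "B"]))
  # A labels iff positive score
  expect_true(all((track$pc1 > 0) == (track$label == "A")))
})

test_that("pipeline PC1 matches an independent eigendecomposition up to sign", {
  fx <- checkerboard_fixture(n = 40, block = 8)
  bal <- balance_matrix(fx$cm)
  track <- call_compartments(bal, fx$genes)
  # independent route: brute-force O/E, correlation, leading eigenvector
  blk <- bal$counts
  e <- brute_expected(blk)
  n <- nrow(blk)
  oe <- blk / outer(rep(1, n), rep(1, n)) # placeholder shape
  for (i in seq_len(n)) for (j in seq_len(n))
    oe[i, j] <- if (e[abs(i - j) + 1] > 0) blk[i, j] / e[abs(i - j) + 1] else 0
  v <- eigen(stats::cor(oe), symmetric = TRUE)$vectors[, 1]
  r <- abs(stats::cor(track$pc1, v))
  expect_gt(r, 0.999999)
})

test_that("degenerate chromosomes are masked with a warning", {
  # constant matrix: no O/E variance anywhere
  m <- balance_matrix(toy_cm(matrix(5, 20, 20), res = 1e5))
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 10, end = 600)
  expect_warning(tr <- call_compartments(m, genes), "masked")
  expect_true(all(tr$label == "masked"))

  # too few bins
  m2 <- balance_matrix(toy_cm(random_symmetric(5, seed = 2) + 1, res = 1e5))
  expect_warning(tr2 <- call_compartments(m2, genes, min_bins = 10L),
                 "fewer than")
  expect_true(all(tr2$label == "masked"))
})

test_that("A-compartment genes are expressed higher when an A effect is planted", {
  fx <- checkerboard_fixture(n = 60, block = 10)
  track <- manual_track(fx$labels)
  set.seed(1)
  g <- assign_genes_to_bins(fx$genes, fx$bins)
  in_a <- fx$labels[g$bin_id + 1] == "A"
  base <- matrix(rlnorm(nrow(g) * 9, log(3), 0.2), ncol = 9)
  base[in_a, ] <- base[in_a, ] * 4  # ~ +2 on the log2 scale
  expr <- manual_expr(base, gene_ids = g$gene_id)
  res <- compartment_expression_contrast(track, expr, fx$genes, sample = "P1")
  s <- res$summary
  expect_gt(s$mean_log2_fpkm[s$label == "A"], s$mean_log2_fpkm[s$label == "B"])
  expect_lt(res$p_value, 0.05)

  # identical expression: no difference
  expr0 <- manual_expr(matrix(2, nrow(g), 9), gene_ids = g$gene_id)
  res0 <- compartment_expression_contrast(track, expr0, fx$genes,
                                          sample = "P1")
  expect_gt(res0$p_value, 0.9)
})

test_that("gene-to-bin assignment sends boundary midpoints to the left bin", {
  bins <- toy_bins(3, res = 100L)
  genes <- data.frame(gene_id = c("mid_in_bin", "mid_on_border"),
                      chrom = "chr1",
                      start = c(120, 50), end = c(160, 150))
  g <- assign_genes_to_bins(genes, bins)
  expect_equal(g$bin_id, c(1L, 0L)) # midpoints 140 -> bin 1; 100 -> bin 0
})

test_that("trio states, percentages and aggregates are consistent", {
  labs_P1 <- c("A", "B", "A", "B", "A", "masked")
  labs_F1 <- c("A", "A", "A", "B", "B", "A")
  labs_P2 <- c("A", "B", "B", "B", "A", "A")
  sh <- classify_shifts(list(P1 = manual_track(labs_P1, "P1"),
                             F1 = manual_track(labs_F1, "F1"),
                             P2 = manual_track(labs_P2, "P2")))
  expect_equal(sh$n_unmasked, 5L)
  expect_equal(sh$table$trio_state[1], "A-to-A-to-A")
  expect_equal(sh$table$trio_state[6], "masked")
  expect_equal(sum(sh$percentages), 100)
  # (B,A,B) bin 2 counts toward the total A gain in F1
  expect_equal(unname(sh$aggregates["a_flip"]), 20)
  expect_true(sh$aggregates["a_gain_total"] >= sh$aggregates["a_flip"])
  # unchanged = A-A-A (bin 1) + B-B-B (bin 4) = 40%
  expect_equal(unname(sh$aggregates["unchanged"]), 40)

  # mismatched bin tables are rejected
  bad <- manual_track(labs_P2[1:5], "P2")
  expect_error(classify_shifts(list(P1 = manual_track(labs_P1, "P1"),
                                    F1 = manual_track(labs_F1, "F1"),
                                    P2 = bad)),
               "identical bin table")
})

test_that("printed component percentages add at the report layer", {
  pct <- stats::setNames(rep(0, 8), hictrio:::all_trio_states())
  pct["A-to-A-to-B"] <- 3.14
  pct["B-to-A-to-A"] <- 0.90
  pct["A-to-A-to-A"] <- 95.96
  agg <- aggregate_shift_percentages(pct)
  expect_equal(unname(agg["a_gain_split"]), 4.04)
})

test_that("gene-level shift lists equal the brute-force bin lookup", {
  labs_P1 <- rep(c("A", "B"), each = 5)
  labs_F1 <- c(rep("A", 3), rep("B", 4), rep("A", 3))
  labs_P2 <- labs_P1
  sh <- classify_shifts(list(P1 = manual_track(labs_P1, "P1", res = 100L),
                             F1 = manual_track(labs_F1, "F1", res = 100L),
                             P2 = manual_track(labs_P2, "P2", res = 100L)))
  set.seed(4)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:30), chrom = "chr1",
                      start = sort(sample(0:990, 30)), stringsAsFactors = FALSE)
  genes$end <- genes$start + 8
  lst <- shift_gene_lists(sh, genes, parent = "P1")
  # brute force: per gene, find its midpoint bin and compare labels
  for (i in seq_len(nrow(genes))) {
    mid <- floor((genes$start[i] + genes$end[i]) / 2)
    b <- min(max(ceiling(mid / 100), 1), 10)
    expected_shift <- paste0(labs_P1[b], "-to-", labs_F1[b])
    in_list <- genes$gene_id[i] %in% lst$gene_id
    expect_equal(in_list, expected_shift %in% c("A-to-B", "B-to-A"))
    if (in_list)
      expect_equal(lst$shift[lst$gene_id == genes$gene_id[i]], expected_shift)
  }
})
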