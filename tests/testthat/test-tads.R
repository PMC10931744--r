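test_that("directionality index matches hand values and the symmetry oracle", {
  # balanced upstream/downstream: DI is exactly 0
  m <- matrix(c(0, 2, 0,
                2, 0, 2,
                0, 2, 0), 3, 3)
  di <- directionality_index(toy_cm(m, res = 4e4, state = "balanced"),
                             window_bp = 4e4)
  expect_equal(di$di[2], 0)

  # A = 10, B = 30 gives E = 20 and DI = +10
  m2 <- matrix(c(0, 10, 0,
                 10, 0, 30,
                 0, 30, 0), 3, 3)
  di2 <- directionality_index(toy_cm(m2, res = 4e4, state = "balanced"),
                              window_bp = 4e4)
  expect_equal(di2$di[2], 10)

  # mirroring the genome negates and reverses the track
  cnt <- random_symmetric(20, seed = 8)
  d_fwd <- directionality_index(toy_cm(cnt, res = 4e4, state = "balanced"),
                                window_bp = 2e5)
  rev_cnt <- cnt[20:1, 20:1]
  d_rev <- directionality_index(toy_cm(rev_cnt, res = 4e4,
                                       state = "balanced"),
                                window_bp = 2e5)
  expect_equal(d_rev$di, -rev(d_fwd$di))
})

test_that("DI equals the brute-force window sums on random matrices", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:30, 1)
    w <- sample(1:5, 1)
    cnt <- random_symmetric(n, seed = seed + 1000)
    di <- directionality_index(toy_cm(cnt, res = 4e4, state = "balanced"),
                               window_bp = w * 4e4)
    expect_equal(di$di, brute_di(cnt, w))
  }
})

test_that("windows cut by chromosome ends are flagged as truncated", {
  cnt <- random_symmetric(12, seed = 3)
  di <- directionality_index(toy_cm(cnt, res = 4e4, state = "balanced"),
                             window_bp = 3 * 4e4)
  expect_true(all(di$truncated[c(1:3, 10:12)]))
  expect_false(any(di$truncated[4:9]))
  expect_error(directionality_index(toy_cm(cnt, res = 4e4,
                                           state = "balanced"),
                                    window_bp = 2e4),
               "multiple of the resolution")
})

test_that("boundary caller follows the sign-run rule", {
  di <- manual_di(c(1, 1, 1, -1, -1, -1, 1, 1, 1))
  tads <- call_tads(di, min_tad_bins = 1L, persistence = 2L, smooth = 1L)
  b <- attr(tads, "boundaries")
  expect_equal(b$bin, 7L)
  expect_equal(nrow(tads), 2L)
  expect_equal(tads$start, c(0, 6 * 4e4))

  # all-positive DI: one whole-chromosome domain, no internal boundary
  di_pos <- manual_di(rep(1, 9))
  t_pos <- call_tads(di_pos, min_tad_bins = 1L, persistence = 2L,
                     smooth = 1L)
  expect_equal(nrow(t_pos), 1L)
  expect_equal(nrow(attr(t_pos, "boundaries")), 0L)
  expect_equal(t_pos$end - t_pos$start, 9 * 4e4)
})

test_that("TAD calls are invariant to positive scaling of the matrix", {
  cfg <- sim_config(n_chroms = 1L, bins_per_chrom = 100L, resolution = 4e4,
                    compartment_contrast = 1, tad_contrast = 2,
                    tad_boundaries = list(chr1 = c(21L, 41L, 61L, 81L)),
                    planted_shifts = list(), n_genes = 50L, seed = 7L)
  sim <- simulate_trio(cfg)
  bal <- balance_matrix(sim$matrices$P1)
  t1 <- call_tads(directionality_index(bal, window_bp = 6e5))
  scaled <- contact_matrix(bal$counts * 3.7, bal$bins, state = "balanced",
                           mask = bal$mask)
  t2 <- call_tads(directionality_index(scaled, window_bp = 6e5))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("five planted TADs are recovered within one bin", {
  cfg <- sim_config(n_chroms = 1L, bins_per_chrom = 100L, resolution = 4e4,
                    compartment_contrast = 1, tad_contrast = 2,
                    tad_boundaries = list(chr1 = c(21L, 41L, 61L, 81L)),
                    planted_shifts = list(), n_genes = 50L, seed = 7L)
  sim <- simulate_trio(cfg)
  bal <- balance_matrix(sim$matrices$P1)
  tads <- call_tads(directionality_index(bal, window_bp = 6e5))
  called <- attr(tads, "boundaries")$bin
  hits <- vapply(c(21L, 41L, 61L, 81L),
                 function(b) any(abs(called - b) <= 1), logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("conserved/specific status matches the all-pairs oracle", {
  mk_tads <- function(starts, ends, chrom = "chr1") {
    out <- data.frame(chrom = chrom, start = starts, end = ends)
    class(out) <- c("tad_set", "data.frame")
    out
  }
  a <- mk_tads(c(0, 10, 25) * 4e4, c(8, 20, 33) * 4e4)
  expect_true(all(compare_tads(a, a)$domains$status == "conserved"))

  # one boundary off by tol + 1 bins
  b <- mk_tads(c(0, 10, 25 + 2) * 4e4, c(8, 20, 33) * 4e4)
  st <- compare_tads(a, b, tol_bins = 1L)$domains$status
  expect_equal(st, c("conserved", "conserved", "specific"))

  # randomized sets against an independently coded O(n^2) check
  set.seed(11)
  rs <- sort(sample(0:200, 20)) * 4e4
  re <- rs + sample(5:9, 20, replace = TRUE) * 4e4
  ref <- mk_tads(rs, re)
  os <- rs + sample(-3:3, 20, replace = TRUE) * 4e4
  other <- mk_tads(sort(os), sort(os) + sample(5:9, 20, replace = TRUE) * 4e4)
  got <- compare_tads(ref, other, tol_bins = 1L)$domains$status
  want <- vapply(seq_len(20), function(i) {
    hit <- FALSE
    for (j in seq_len(20))
      if (abs(other$start[j] - ref$start[i]) <= 4e4 &&
          abs(other$end[j] - ref$end[i]) <= 4e4) hit <- TRUE
    if (hit) "conserved" else "specific"
  }, character(1))
  expect_equal(got, want)
})

test_that("activity classes take exactly the 10% tails of rankable TADs", {
  # 20 conserved one-gene TADs with known fold changes
  n <- 20
  starts <- (0:(n - 1)) * 10 * 4e4
  dom <- data.frame(chrom = "chr1", start = starts, end = starts + 8 * 4e4,
                    status = "conserved", stringsAsFactors = FALSE)
  cmp <- list(domains = dom, counts = c(n_conserved = n))
  genes <- data.frame(gene_id = sprintf("G%02d", 1:n), chrom = "chr1",
                      start = starts + 4e4, end = starts + 4e4 + 1000,
                      stringsAsFactors = FALSE)
  lfc <- seq(3, -3, length.out = n)
  deg <- data.frame(gene_id = genes$gene_id, log2fc = lfc,
                    padj = rep(0.001, n), stringsAsFactors = FALSE)
  out <- classify_tad_activity(cmp, deg, genes)$domains
  expect_equal(sum(out$activity == "activated", na.rm = TRUE), 2L)
  expect_equal(sum(out$activity == "repressed", na.rm = TRUE), 2L)
  expect_equal(sum(out$activity == "other", na.rm = TRUE), 16L)
  # the top/bottom of the ranking carry the labels
  expect_equal(out$activity[1:2], c("activated", "activated"))
  expect_equal(out$activity[19:20], c("repressed", "repressed"))
  # fc_fraction is the share of genes with fold change > 1
  expect_equal(out$fc_fraction, as.numeric(lfc > 0))

  # all-tied fold changes: classes still assigned, broken by genomic order
  deg0 <- transform(deg, log2fc = 0)
  out0 <- classify_tad_activity(cmp, deg0, genes)$domains
  expect_equal(sum(out0$activity == "activated", na.rm = TRUE), 2L)
  expect_equal(out0$activity[1:2], c("activated", "activated"))

  # fewer than 10 rankable TADs: everything is "other" with a warning
  small <- list(domains = dom[1:5, ], counts = c(n_conserved = 5))
  expect_warning(o5 <- classify_tad_activity(small, deg, genes)$domains,
                 "fewer than 10")
  expect_true(all(o5$activity == "other"))
})

test_that("boundary specificity classifies by DI-window correlation", {
  set.seed(2)
  di1 <- manual_di(stats::rnorm(60), res = 4e4)
  bnd <- data.frame(chrom = "chr1", bin = 30L)
  same <- boundary_specificity(di1, di1, bnd, window_bins = 10L)
  expect_equal(same$boundaries$status, "shared")
  expect_equal(same$boundaries$r, 1)

  neg <- manual_di(-di1$di, res = 4e4)
  opp <- boundary_specificity(di1, neg, bnd, window_bins = 10L)
  expect_equal(opp$boundaries$status, "specific")
  expect_equal(opp$boundaries$r, -1)

  flat <- manual_di(rep(0, 60), res = 4e4)
  z <- boundary_specificity(di1, flat, bnd, window_bins = 10L)
  expect_equal(z$boundaries$status, "unclassifiable")

  # window outside the chromosome is excluded
  edge <- boundary_specificity(di1, di1, data.frame(chrom = "chr1", bin = 3L),
                               window_bins = 10L)
  expect_equal(edge$boundaries$status, "out_of_range")
})

test_that("TAD length statistics are exact and handle empty sets", {
  t2 <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(4e5, 1.6e6))
  class(t2) <- c("tad_set", "data.frame")
  st <- tad_length_stats(t2)
  expect_equal(st$n, 2L)
  expect_equal(st$mean_length_bp, 5e5)
  expect_equal(st$covered_bp, 1e6)

  t0 <- t2[0, ]
  st0 <- tad_length_stats(t0)
  expect_equal(st0$n, 0L)
  expect_true(is.na(st0$mean_length_bp))
})
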