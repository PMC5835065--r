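test_that("tetranucleotide frequencies are canonical and normalised", {
  v <- tetranucleotide_freqs("AAAA")
  expect_length(v, 136L)
  expect_equal(unname(v[["AAAA"]]), 1)
  expect_equal(sum(v), 1)

  # reverse-complement canonicalisation: TTTT counts as AAAA
  expect_identical(tetranucleotide_freqs("TTTT"), tetranucleotide_freqs("AAAA"))

  # a long random ACGT sequence: sums to 1 to machine precision
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  v2 <- tetranucleotide_freqs(s)
  expect_equal(sum(v2), 1, tolerance = 1e-12)
  expect_true(all(v2 >= 0))

  # windows containing N are skipped, not counted
  v3 <- tetranucleotide_freqs("AAAANGGGG")
  expect_equal(unname(v3[["AAAA"]]), 0.5)
  expect_equal(unname(v3[["CCCC"]]), 0.5)  # GGGG canonicalises to CCCC
  expect_error(tetranucleotide_freqs("NNNNNN", id = "c9"), "c9")
})

test_that("GC content ignores ambiguous symbols", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("GGNNCC"), 1)
  expect_error(gc_content("NNN"), "no A/C/G/T")
})

test_that("vectorised contig features agree with the scalar operations", {
  set.seed(4)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"), 500,
                                         replace = TRUE), collapse = ""),
           ""),
    paste0("c", 1:5)))
  feats <- contig_features(seqs)
  expect_equal(unname(feats$gc["c3"]), gc_content(as.character(seqs[["c3"]])))
  expect_equal(feats$tnf["c3", ],
               tetranucleotide_freqs(as.character(seqs[["c3"]])))
  expect_equal(unname(rowSums(feats$tnf)), rep(1, 5))
})

test_that("coverage preparation equalises sample depth then logs", {
  cov <- matrix(c(10, 30, 20, 60), 2, 2,
                dimnames = list(c("c1", "c2"), c("t1", "t2")))
  out <- prepare_coverage(cov, pseudocount = 1)
  # columns of the rescaled matrix share the maximum original column sum
  back <- 10^out - 1
  expect_equal(unname(colSums(back)), c(80, 80))
  # row ratios within each column are untouched by the per-column scaling
  expect_equal(back[2, ] / back[1, ], c(t1 = 3, t2 = 3))

  # all-zero contig row maps to log10(pseudocount)
  cov2 <- rbind(cov, c3 = c(0, 0))
  expect_equal(unname(prepare_coverage(cov2, 1)["c3", ]), c(0, 0))

  # equal column sums in: value 9 with pseudocount 1 gives exactly 1
  cov3 <- matrix(c(9, 1, 9, 1), 2, 2)
  expect_equal(prepare_coverage(cov3, 1)[1, 1], 1)

  expect_error(prepare_coverage(matrix(c(1, 2, 0, 0), 2, 2)), "all-zero")
  expect_error(prepare_coverage(cov, pseudocount = 0), "pseudocount")
  expect_error(prepare_coverage(cov[, 1, drop = FALSE]), "2 samples")
})

test_that("classical MDS reproduces exact Euclidean configurations", {
  # equilateral triangle: all pairwise distances 1
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  emb <- classical_mds(eq, d = 2)
  expect_equal(as.vector(dist(emb$coords)), rep(1, 3), tolerance = 1e-9)

  # 3-4-5 right triangle
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  emb2 <- classical_mds(tri, d = 2)
  expect_equal(sort(as.vector(dist(emb2$coords))), c(3, 4, 5),
               tolerance = 1e-9)
  expect_true(all(diff(emb2$eigenvalues) <= 0))
  expect_equal(unname(colMeans(emb2$coords)), c(0, 0), tolerance = 1e-9)

  # random Euclidean configurations are reproduced at 1e-9
  set.seed(42)
  for (i in 1:5) {
    X <- matrix(rnorm(30), 10, 3)
    e <- classical_mds(X, d = 3)
    expect_equal(as.vector(dist(e$coords)), as.vector(dist(X)),
                 tolerance = 1e-9)
  }

  # collinear points: the second eigenvalue vanishes but the requested
  # dimensionality is always honoured
  line <- cbind(seq(0, 9), seq(0, 9) * 2)
  e3 <- classical_mds(line, d = 2)
  expect_lte(e3$eigenvalues[2], 1e-9 * e3$eigenvalues[1])
  expect_equal(ncol(e3$coords), 2L)

  expect_error(classical_mds(eq, d = 0), "at least 1")
  expect_error(classical_mds(eq, d = 3), "rows")
})

test_that("adjusted Rand index follows the contingency-table formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)

  # one bin against two equal genomes: chance level
  expect_equal(adjusted_rand_index(rep(1, 8), rep(c("a", "b"), each = 4)), 0)

  # contingency [[2,1],[1,2]] over 6 items: hand-evaluated formula gives
  # (2 - 2.4) / (6 - 2.4) = -1/9
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), -1 / 9, tolerance = 1e-12)

  # independent cross-check against mclust
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)

  # symmetry and label-permutation invariance over random labelings
  set.seed(7)
  for (i in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    relab <- c(3, 1, 4, 2)[x]
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(relab, y))
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("marker quality reports completeness and contamination", {
  ids <- paste0("c", 1:10)
  bins <- make_bins(ids, rep(c(1L, 2L), each = 5))

  # bin 1 holds 90 of 100 markers once each
  m1 <- data.frame(contig_id = rep(ids[1:5], length.out = 90),
                   marker_id = 1:90)
  q <- marker_quality(bins, m1, n_markers = 100)
  expect_equal(q$completeness[q$bin == 1], 90)
  expect_equal(q$contamination[q$bin == 1], 0)

  # all 100 present, five of them twice
  m2 <- data.frame(contig_id = rep(ids[1:5], length.out = 105),
                   marker_id = c(1:100, 1:5))
  q2 <- marker_quality(bins, m2, n_markers = 100)
  expect_equal(q2$completeness[q2$bin == 1], 100)
  expect_equal(q2$contamination[q2$bin == 1], 5)

  # a bin whose contigs carry no markers scores 0 / 0
  expect_equal(q$completeness[q$bin == 2], 0)
  expect_equal(q$contamination[q$bin == 2], 0)

  expect_error(marker_quality(bins, m1, n_markers = 0), "n_markers")
})
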