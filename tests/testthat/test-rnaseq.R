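test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  set.seed(81)
  for (i in 1:10) {
    m3 <- matrix(stats::rpois(60, 50) + 1, ncol = 4)
    colnames(m3) <- paste0("s", 1:4)
    sf <- size_factors(m3)
    pseudo <- exp(rowMeans(log(m3)))
    oracle <- apply(m3, 2, function(col) stats::median(col / pseudo))
    expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
  }
  zero <- matrix(c(0, 1, 1, 0), 2)
  expect_error(size_factors(zero), class = "rfl_parameter_error")
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(82)
  # odd gene count: the median ratio is a single element, so the median of
  # ratios and DESeq2's exp(median(log ratios)) coincide exactly
  m <- matrix(stats::rnbinom(51 * 8, mu = 80, size = 5) + 1, ncol = 8)
  colnames(m) <- paste0("s", 1:8)
  sf <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("TPM normalises by length and sums to one million", {
  cm1 <- count_matrix(matrix(5, 1, 2, dimnames = list("t", c("a", "b"))),
                      1000)
  expect_equal(unname(tpm(cm1)[1, ]), c(1e6, 1e6))

  cm2 <- count_matrix(matrix(c(10, 10), 2, 1,
                             dimnames = list(c("t1", "t2"), "s")),
                      c(1000, 2000))
  expect_equal(unname(tpm(cm2)[, 1]), c(2e6 / 3, 1e6 / 3))

  set.seed(83)
  cm3 <- count_matrix(matrix(stats::rpois(50, 20), 10, 5),
                      sample(200:2000, 10))
  expect_true(all(abs(colSums(tpm(cm3)) - 1e6) < 1e-6))
})

test_that("fertile/sterile ratio clustering orders planted blocks together", {
  sim <- simulate_counts(84, n_genes = 120)
  fertile <- sim$design$sample[sim$design$fertile]
  sterile <- sim$design$sample[!sim$design$fertile]
  contrasts <- data.frame(fertile = fertile,
                          sterile = rep(sterile, length.out =
                                          length(fertile)))
  cc <- contrast_cluster(sim$counts, contrasts)
  up_pos <- which(rownames(cc$ratios) %in% sim$truth$up_genes)
  down_pos <- which(rownames(cc$ratios) %in% sim$truth$down_genes)
  # planted blocks are contiguous in the clustered order
  expect_lte(diff(range(up_pos)), length(up_pos) + 2)
  expect_lte(diff(range(down_pos)), length(down_pos) + 2)
  expect_true(mean(cc$ratios[up_pos, ]) > 0)
  expect_true(mean(cc$ratios[down_pos, ]) < 0)

  # all-equal counts give all-zero ratios
  m <- matrix(7, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  cc0 <- contrast_cluster(count_matrix(m, rep(100, 4)),
                          data.frame(fertile = c("s1", "s2"),
                                     sterile = c("s3", "s4")))
  expect_true(all(cc0$ratios == 0))

  # row permutation leaves ratio values and the partition unchanged
  perm <- sample(nrow(sim$counts$counts))
  cmp <- count_matrix(sim$counts$counts[perm, ], sim$counts$lengths[perm])
  cc2 <- contrast_cluster(cmp, contrasts)
  common <- rownames(cc$ratios)
  expect_equal(cc2$ratios[common, ], cc$ratios[common, ])

  expect_error(contrast_cluster(sim$counts,
                                data.frame(fertile = "nope",
                                           sterile = sterile[1])),
               class = "rfl_config_error")
})

test_that("sample PCA separates planted groups and is well-formed", {
  sim <- simulate_counts(85, n_genes = 200, effect_size = 6)
  p <- pca_samples(sim$counts)
  f <- sim$design$fertile
  expect_true(min(p$coordinates[f, 1]) > max(p$coordinates[!f, 1]) ||
                max(p$coordinates[f, 1]) < min(p$coordinates[!f, 1]))
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  expect_lte(sum(p$variance_fractions), 1 + 1e-9)

  m <- sim$counts$counts
  m2 <- cbind(m, dup = m[, 1])
  p2 <- pca_samples(count_matrix(m2, sim$counts$lengths))
  expect_equal(p2$coordinates["dup", ], p2$coordinates[1, ],
               ignore_attr = TRUE)

  const <- count_matrix(matrix(5, 4, 3), rep(100, 4))
  expect_equal(sum(pca_samples(const)$variance_fractions), 0)
})

test_that("coverage normalisation scales by the unmasked mean only", {
  tr <- coverage_track("r", "+", rep(8, 100))
  n <- normalize_coverage(tr)
  expect_equal(n$depth, rep(1, 100))
  expect_equal(n$scale, 8)
  expect_identical(normalize_coverage(n), n)      # idempotent

  tr2 <- coverage_track("r", "+", c(rep(10, 50), rep(0, 50)))
  expect_equal(unique(normalize_coverage(tr2)$depth), c(2, 0))

  # a masked high-coverage block must not affect the scaling
  d <- c(rep(1000, 20), rep(10, 80))
  masked <- coverage_track("r", "+", d, masks = matrix(c(0L, 20L), 1))
  expect_equal(normalize_coverage(masked)$depth[21:100], rep(1, 80))
  all_masked <- coverage_track("r", "+", d, masks = matrix(c(0L, 100L), 1))
  expect_error(normalize_coverage(all_masked),
               class = "rfl_parameter_error")
})

test_that("cleavage detection finds planted transitions and rejects noise", {
  flat <- simulate_coverage(86, cleavage_pos = c(x = 3000), fold = 1)
  cl <- detect_cleavage(normalize_coverage(flat$x$fertile),
                        normalize_coverage(flat$x$sterile))
  expect_false(cl$passed)

  sim <- simulate_coverage(87, cleavage_pos = c(x = 3000))
  cl2 <- detect_cleavage(normalize_coverage(sim$x$fertile),
                         normalize_coverage(sim$x$sterile))
  expect_true(cl2$passed)
  expect_lte(abs(cl2$position - 3000), 2)

  expect_error(detect_cleavage(normalize_coverage(sim$x$fertile),
                               normalize_coverage(sim$x$sterile),
                               cleavage_params(window_w = 50,
                                               search_region = c(0, 60))),
               class = "rfl_parameter_error")
  expect_error(detect_cleavage(sim$x$fertile, sim$x$sterile),
               class = "rfl_parameter_error")
})

test_that("reverse-strand transcripts are scanned 5' to 3'", {
  sim <- simulate_coverage(88, cleavage_pos = c(x = 2500), strand = "-")
  cl <- detect_cleavage(normalize_coverage(sim$x$fertile),
                        normalize_coverage(sim$x$sterile),
                        transcript_strand = "-")
  expect_true(cl$passed)
  expect_lte(abs(cl$position - 2500), 2)
})
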