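models <- load_motif_models()
pmod <- models[["P"]]

test_that("motif scanning finds planted consensus repeats, not shuffles", {
  expect_equal(nrow(scan_motifs(seq_record("e", "", "protein"), models)), 0L)

  planted <- paste(rep(pmod$consensus, 18), collapse = "")
  hits <- scan_motifs(planted, models["P"])
  expect_gte(sum(hits$aa_start %% 35 == 0), 18L)
  # aa5/aa35 are the residues at motif positions 5 and 35 (1-based)
  h1 <- hits[hits$aa_start == 0, ][1, ]
  expect_equal(h1$aa5, substr(pmod$consensus, 5, 5))
  expect_equal(h1$aa35, substr(pmod$consensus, 35, 35))

  set.seed(9)
  shuffled <- paste(sample(strsplit(planted, "")[[1]]), collapse = "")
  score_all <- function(p) {
    aa <- strsplit(p, "")[[1]]
    idx <- match(aa, rownames(pmod$log_odds))
    nw <- length(aa) - 35 + 1
    tot <- numeric(nw)
    for (j in 1:35) tot <- tot + pmod$log_odds[cbind(idx[j:(j + nw - 1)], j)]
    tot
  }
  expect_gt(mean(score_all(planted)), mean(score_all(shuffled)))
  expect_equal(nrow(scan_motifs(shuffled, models["P"])), 0L)
})

test_that("chaining picks the optimal non-overlapping subset", {
  two <- data.frame(model = "P", aa_start = c(0L, 10L), aa_end = c(35L, 45L),
                    score = c(5, 7), aa5 = "T", aa35 = "N")
  arch <- chain_motifs(two, adjacency_bonus = 0)
  expect_equal(arch$hits$score, 7)

  abc <- data.frame(model = "P", aa_start = c(0L, 20L, 40L),
                    aa_end = c(35L, 55L, 75L), score = c(5, 5, 5),
                    aa5 = "T", aa35 = "N")
  arch <- chain_motifs(abc, adjacency_bonus = 0)
  expect_equal(arch$hits$aa_start, c(0L, 40L))
  expect_equal(arch$total_score, 10)

  expect_equal(chain_motifs(abc[0, ])$p_count, 0L)

  set.seed(13)
  for (i in 1:40) {
    hits <- random_hit_set(sample(1:12, 1))
    arch <- chain_motifs(hits, adjacency_bonus = 2)
    expect_equal(arch$total_score, oracle_chain_score(hits, 2))
  }
})

test_that("chain ties break toward more hits then smaller start sum", {
  # one 70-aa hit vs two 35-aa hits, equal total score, no adjacency bonus
  hits <- data.frame(model = "P", aa_start = c(0L, 0L, 35L),
                     aa_end = c(70L, 35L, 70L), score = c(8, 4, 4),
                     aa5 = "T", aa35 = "N")
  arch <- chain_motifs(hits, adjacency_bonus = 0)
  expect_equal(nrow(arch$hits), 2L)
})

test_that("RFL classification boundaries are exact", {
  mk_arch <- function(p) structure(
    list(hits = data.frame(model = rep("P", p),
                           aa_start = 35L * (seq_len(p) - 1L) + 40L,
                           aa_end = 35L * seq_len(p) + 40L,
                           score = 50, aa5 = "T", aa35 = "N"),
         p_count = p, total_score = 50 * p, is_rfl = p >= 10,
         tandem_max = p), class = "ppr_architecture")
  long_prot <- paste0("M", random_prot_str(779))
  set.seed(2)
  expect_true(classify_rfl(mk_arch(10L), long_prot)$is_rfl)
  expect_false(classify_rfl(mk_arch(9L), long_prot)$is_rfl)
  expect_equal(classify_rfl(mk_arch(18L), long_prot)$status, "full_length")
  expect_equal(classify_rfl(mk_arch(12L),
                            substr(long_prot, 1, 450))$status, "partial")
  expect_equal(classify_rfl(mk_arch(12L),
                            substr(long_prot, 1, 499))$status, "partial")
  expect_equal(classify_rfl(mk_arch(12L),
                            substr(long_prot, 1, 500))$status, "full_length")
  # no initiator M -> not full length
  expect_equal(classify_rfl(mk_arch(12L),
                            sub("^M", "K", long_prot))$status, "truncated")
  expect_equal(classify_rfl(mk_arch(12L), long_prot,
                            frameshifted = TRUE)$status, "frameshifted")
  # premature end relative to the orthogroup, C-terminal motif at the edge
  short <- substr(long_prot, 1, 560)
  expect_equal(classify_rfl(mk_arch(14L), short,
                            orthogroup_max_codons = 780L)$status, "truncated")
})

test_that("code pairs come out in N-to-C order and match the protein", {
  prot <- random_prot_str(40)
  arch <- structure(
    list(hits = data.frame(model = "P", aa_start = 0L, aa_end = 35L,
                           score = 50, aa5 = substr(prot, 5, 5),
                           aa35 = substr(prot, 35, 35)),
         p_count = 1L, total_score = 50, is_rfl = FALSE, tandem_max = 1L),
    class = "ppr_architecture")
  cp <- extract_code_pairs(arch, prot)
  expect_equal(cp$aa5, substr(prot, 5, 5))
  expect_equal(cp$aa35, substr(prot, 35, 35))
  arch$hits$aa_start <- 20L; arch$hits$aa_end <- 55L
  expect_error(extract_code_pairs(arch, substr(prot, 1, 30)),
               class = "rfl_bounds_error")
})

test_that("planted-motif proteins yield p_count equal to the plant", {
  for (k in c(5L, 10L, 20L)) {
    sim <- simulate_ppr_target(100 + k, pairs_n = k)
    ann <- annotate_protein(sim$protein, models)
    expect_equal(ann$p_count, k)
    expect_equal(ann$code_pairs$aa5, sim$truth$pairs$aa5)
    expect_equal(ann$code_pairs$aa35, sim$truth$pairs$aa35)
  }
})

test_that("motif models survive a TSV round trip", {
  td <- withr::local_tempfile(fileext = ".tsv")
  m <- build_motif_model("Q", strrep("VTYNT", 4), hit_threshold = 12)
  write_motif_model(m, td)
  back <- read_motif_model(td)
  expect_equal(back$name, "Q")
  expect_equal(back$n_cols, 20L)
  expect_equal(back$hit_threshold, 12)
  expect_equal(back$log_odds, m$log_odds, tolerance = 1e-5)
})
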