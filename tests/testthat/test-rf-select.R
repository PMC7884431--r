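mini_panel <- data.frame(
  genotype = c("A", "B", "C", "Ttimo"),
  carries_Rf1 = c(TRUE, TRUE, FALSE, TRUE),
  carries_Rf3 = FALSE,
  maintainer = c(FALSE, FALSE, TRUE, FALSE),
  is_timopheevii = c(FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

mk_group <- function(gid, genotypes, statuses, codons) {
  data.frame(group_id = gid, representative = paste0(gid, "_rep"),
             id = paste0(gid, "_", genotypes), genotype = genotypes,
             status = statuses, codons = codons, stringsAsFactors = FALSE)
}

test_that("a group passing every rule is a candidate; one violation rejects", {
  g1 <- mk_group("g1", c("A", "B", "Ttimo"), "full_length", 760L)
  rep1 <- select_candidates(g1, mini_panel, c(g1 = "in"), mode = "Rf1")
  expect_equal(rep1$verdict, "candidate")
  expect_true(all(unlist(rep1[, c("restorer_fulllength", "nonrestorer_absent",
                                  "in_interval", "provenance_ok",
                                  "length_ok")])))

  g1c <- rbind(g1, mk_group("g1", "C", "full_length", 760L))
  rep2 <- select_candidates(g1c, mini_panel, c(g1 = "in"), mode = "Rf1")
  expect_equal(rep2$verdict, "rejected")
  expect_false(rep2$nonrestorer_absent)

  rep3 <- select_candidates(g1, mini_panel, c(g1 = "out"), mode = "Rf1")
  expect_equal(rep3$verdict, "rejected")
  # timopheevii member required for Rf1 provenance
  g2 <- mk_group("g2", c("A", "B"), "full_length", 760L)
  rep4 <- select_candidates(g2, mini_panel, c(g2 = "in"), mode = "Rf1")
  expect_false(rep4$provenance_ok)
  # verdict is a pure function of the rules
  for (r in list(rep1, rep2, rep3, rep4)) {
    rules <- unlist(r[, c("restorer_fulllength", "nonrestorer_absent",
                          "in_interval", "provenance_ok", "length_ok")])
    expect_equal(r$verdict == "candidate", all(rules))
  }
  expect_error(select_candidates(mk_group("g", "nope", "full_length", 700L),
                                 mini_panel, c(g = "in"), mode = "Rf1"),
               class = "rfl_config_error")
})

test_that("the published Rf1 screen outcome is reproduced", {
  # groups 79 and 104: full-length in all Rf1 accessions, timopheevii
  # member, inside the chr1A interval; groups 185 and 268: the frameshift
  # halves, present only as <500 aa partial proteins
  panel <- default_panel()
  rf1_gt <- panel$genotype[panel$carries_Rf1]
  groups <- rbind(
    mk_group("g079", rf1_gt, "full_length", 770L),
    mk_group("g104", rf1_gt, "full_length", 755L),
    mk_group("g185", rf1_gt, "partial", 430L),
    mk_group("g268", rf1_gt, "partial", 320L),
    mk_group("g900", panel$genotype, "full_length", 760L))   # decoy
  placements <- c(g079 = "in", g104 = "in", g185 = "in", g268 = "in",
                  g900 = "in")
  rep_ <- select_candidates(groups, panel, placements, mode = "Rf1")
  expect_setequal(rep_$group_id[rep_$verdict == "candidate"],
                  c("g079", "g104"))
  expect_false(rep_$length_ok[rep_$group_id == "g185"])
  expect_false(rep_$length_ok[rep_$group_id == "g268"])
  expect_false(rep_$nonrestorer_absent[rep_$group_id == "g900"])
})

test_that("the Rf3 provenance rule only rejects identical timopheevii copies", {
  panel <- default_panel()
  rf3_gt <- panel$genotype[panel$carries_Rf3]
  g <- rbind(mk_group("g29", rf3_gt, "full_length", 760L),
             mk_group("g29", "Ttimopheevii", "partial", 430L))
  seqs <- stats::setNames(as.list(c(rep(random_prot_str(300), 3), "")),
                          g$id)
  p <- random_prot_str(300)
  seqs[g$genotype %in% rf3_gt] <- p
  # near-identical timopheevii member: one substitution
  aa <- strsplit(p, "")[[1]]; aa[100] <- setdiff(AAS, aa[100])[1]
  seqs[[g$id[g$genotype == "Ttimopheevii"]]] <- substr(
    paste(aa, collapse = ""), 1, 300)
  rep_ <- select_candidates(g, panel, c(g29 = "in"), mode = "Rf3",
                            sequences = seqs)
  expect_true(rep_$provenance_ok)
  # identical full-coverage timopheevii member disqualifies
  seqs[[g$id[g$genotype == "Ttimopheevii"]]] <- p
  rep2 <- select_candidates(g, panel, c(g29 = "in"), mode = "Rf3",
                            sequences = seqs)
  expect_false(rep2$provenance_ok)
})

test_that("selection is monotone in maintainer full-length members", {
  set.seed(51)
  for (i in 1:20) {
    gt <- sample(mini_panel$genotype, sample(2:4, 1))
    g <- mk_group("g", gt, sample(c("full_length", "partial"), length(gt),
                                  TRUE), sample(c(300L, 760L), length(gt),
                                                TRUE))
    pl <- c(g = sample(c("in", "out", "unknown"), 1))
    before <- select_candidates(g, mini_panel, pl, mode = "Rf1")
    g2 <- rbind(g, mk_group("g", "C", "full_length", 760L))
    after <- select_candidates(g2, mini_panel, pl, mode = "Rf1")
    if (before$verdict == "rejected") expect_equal(after$verdict, "rejected")
  }
})

test_that("in silico placement maps genes in, out, or unknown", {
  set.seed(52)
  chrom <- random_dna_str(16000)
  gene <- substr(chrom, 4001, 4800)
  contigs <- list(seq_record("c1", substr(chrom, 1, 8000)),
                  seq_record("c2", substr(chrom, 8001, 16000)))
  info <- data.frame(id = c("c1", "c2"), chrom = "chr1A",
                     offset = c(0, 8000))
  iv <- list(chrom = "chr1A", start = 3000, end = 6000)
  expect_equal(place_in_interval(gene, contigs, info, iv), "in")
  iv_far <- list(chrom = "chr1A", start = 9000, end = 12000)
  expect_equal(place_in_interval(gene, contigs, info, iv_far), "out")
  # identical copies at two loci cannot be placed
  dup <- list(seq_record("c1", paste0(gene, random_dna_str(1000))),
              seq_record("c2", paste0(random_dna_str(1000), gene)))
  expect_equal(place_in_interval(gene, dup, info, iv), "unknown")
  expect_equal(place_in_interval(gene, list(), info, iv), "unknown")
})

test_that("frameshift halves on one contig are flagged, others are not", {
  g <- data.frame(group_id = c("gA", "gB", "gC"),
                  representative = "r", id = c("x", "y", "z"),
                  genotype = "A", status = "partial",
                  codons = c(300L, 310L, 280L), stringsAsFactors = FALSE)
  cc <- data.frame(id = c("x", "y", "z"),
                   contig = c("ctg1", "ctg1", "ctg9"),
                   start = c(0L, 1400L, 0L), end = c(1200L, 2300L, 900L),
                   strand = "+", stringsAsFactors = FALSE)
  fp <- flag_frameshift_pairs(g, cc)
  expect_equal(nrow(fp), 1L)
  expect_setequal(c(fp$group_a, fp$group_b), c("gA", "gB"))
  cc$strand <- c("+", "-", "+")
  expect_equal(nrow(flag_frameshift_pairs(g, cc)), 0L)

  pan <- simulate_rfl_panel(53, n_families = 4L, panel = small_panel(),
                            frameshift_family = 3L)
  g2 <- greedy_cluster(pan$proteins, pan$meta)
  g2$status <- pan$meta$status_truth[match(g2$id, pan$meta$id)]
  fp2 <- flag_frameshift_pairs(g2, pan$contig_coords)
  expect_gt(nrow(fp2), 0L)
})
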