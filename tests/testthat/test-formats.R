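test_that("FASTA parsing canonicalises and round-trips exactly", {
  td <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc here", "ac", "gu"), td)
  recs <- read_fasta(td)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$description, "desc here")
  expect_equal(recs[[1]]$sequence, "ACGT")

  set.seed(11)
  recs <- lapply(seq_len(100), function(i)
    seq_record(sprintf("r%03d", i), random_dna_str(sample(50:2000, 1))))
  write_fasta(recs, td)
  back <- read_fasta(td)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  expect_equal(vapply(back, `[[`, "", "id"), vapply(recs, `[[`, "", "id"))
})

test_that("FASTA errors are typed and empty input is empty output", {
  td <- withr::local_tempfile(fileext = ".fa")
  file.create(td)
  expect_length(read_fasta(td), 0L)
  writeLines(c("ACGT", ">late"), td)
  expect_error(read_fasta(td), class = "rfl_format_error")
  writeLines(c(">a", "ACGT", ">a", "GG"), td)
  expect_error(read_fasta(td), class = "rfl_format_error")
  expect_error(seq_record("", "ACGT"), class = "rfl_format_error")
  expect_error(seq_record("x", "AB%", "dna"), class = "rfl_format_error")
})

test_that("bedGraph parsing paints depth per base with last-wins overlaps", {
  td <- withr::local_tempfile(fileext = ".bg")
  writeLines("m\t0\t5\t2.0", td)
  tr <- read_bedgraph(td, 8L, "+")
  expect_equal(tr$depth, c(2, 2, 2, 2, 2, 0, 0, 0))

  file.create(td); writeLines(character(), td)
  expect_equal(read_bedgraph(td, 5L, "+")$depth, rep(0, 5))

  writeLines(c("m\t0\t4\t1", "m\t2\t6\t3"), td)
  expect_warning(tr <- read_bedgraph(td, 8L, "+"), "last")
  expect_equal(tr$depth, c(1, 1, 3, 3, 3, 3, 0, 0))

  writeLines("m\t0\t5\t-1", td)
  expect_error(read_bedgraph(td, 8L, "+"), class = "rfl_format_error")
  writeLines("m\t0\t9\t1", td)
  expect_error(read_bedgraph(td, 8L, "+"), class = "rfl_bounds_error")
})

test_that("bedGraph reconstruction matches brute-force painting", {
  td <- withr::local_tempfile(fileext = ".bg")
  set.seed(5)
  for (rep_i in 1:20) {
    L <- sample(50:200, 1)
    n <- sample(1:10, 1)
    s <- sample(0:(L - 2), n, TRUE)
    e <- pmin(L, s + sample(1:30, n, TRUE))
    v <- round(stats::runif(n, 0, 50), 3)
    writeLines(sprintf("m\t%d\t%d\t%s", s, e, v), td)
    expected <- numeric(L)
    for (i in seq_len(n)) expected[(s[i] + 1):e[i]] <- v[i]
    tr <- suppressWarnings(read_bedgraph(td, L, "+"))
    expect_equal(tr$depth, expected)
    write_bedgraph(tr, td)
    expect_equal(read_bedgraph(td, L, "+")$depth, expected)
  }
})

test_that("GFF3 coordinates convert 1-based inclusive <-> 0-based half-open", {
  td <- withr::local_tempfile(fileext = ".gff3")
  writeLines("m\t.\tgene\t1\t9\t.\t+\t.\tID=atp8", td)
  f <- read_gff3(td)[[1]]
  expect_equal(f$start, 0L)
  expect_equal(f$end, 9L)
  expect_equal(f$strand, "+")
  expect_equal(unname(f$attributes["ID"]), "atp8")

  writeLines(c("# a comment", "## another"), td)
  expect_length(read_gff3(td), 0L)

  set.seed(7)
  feats <- lapply(1:50, function(i) {
    s <- sample(0:1000, 1)
    feature("chr", s, s + sample(1:500, 1),
            strand = sample(c("+", "-"), 1), type = "CDS",
            attributes = c(ID = sprintf("f%02d", i)))
  })
  write_gff3(feats, td)
  back <- read_gff3(td)
  expect_equal(vapply(back, `[[`, 0L, "start"),
               vapply(feats, `[[`, 0L, "start"))
  expect_equal(vapply(back, `[[`, 0L, "end"), vapply(feats, `[[`, 0L, "end"))
  expect_equal(vapply(back, `[[`, "", "strand"),
               vapply(feats, `[[`, "", "strand"))

  writeLines("m\t.\tgene\t9\t2\t.\t+\t.\t.", td)
  expect_error(read_gff3(td), class = "rfl_format_error")
  writeLines("m\t.\tgene\t1\t9\t.\t?\t.\t.", td)
  expect_error(read_gff3(td), class = "rfl_format_error")
})

test_that("coverage tracks and masks enforce their invariants", {
  expect_error(coverage_track("r", "x", c(1, 2)), class = "rfl_format_error")
  expect_error(coverage_track("r", "+", c(-1, 2)), class = "rfl_format_error")
  expect_error(coverage_track("r", "+", 1:5, masks = matrix(c(0L, 9L), 1)),
               class = "rfl_bounds_error")
  tr <- coverage_track("r", "+", 1:5, masks = matrix(c(1L, 3L), 1))
  expect_equal(nrow(tr$masks), 1L)
})

test_that("count matrices validate dimensions and lengths", {
  m <- matrix(1:6, 2, dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  cm <- count_matrix(m, c(100, 200))
  expect_equal(unname(cm$lengths), c(100, 200))
  expect_error(count_matrix(m, c(100, 0)), class = "rfl_format_error")
  expect_error(count_matrix(m, 100), class = "rfl_format_error")
  expect_error(count_matrix(-m, c(1, 1)), class = "rfl_format_error")
})

test_that("counts TSV reader builds a count matrix with lengths", {
  td <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript\tlength\ts1\ts2", "t1\t1000\t5\t8",
               "t2\t500\t0\t2"), td)
  cm <- read_counts(td)
  expect_equal(dim(cm$counts), c(2L, 2L))
  expect_equal(unname(cm$lengths), c(1000, 500))
  expect_equal(cm$counts["t1", "s2"], 8)
  writeLines(c("transcript\ts1", "t1\t5"), td)
  expect_error(read_counts(td), class = "rfl_format_error")
})
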