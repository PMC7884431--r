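# Independent oracles used across the suite. Each re-derives a quantity by
# the most transparent method available (per-codon lookup, brute-force
# enumeration, an external alignment engine) and stays separate from the
# package code paths it checks.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
random_prot_str <- function(n) paste(sample(AAS, n, TRUE), collapse = "")

# codon-by-codon translation using the standard-code lookup table
oracle_translate <- function(dna, frame = 0L) {
  tab <- Biostrings::GENETIC_CODE
  out <- character()
  i <- frame + 1L
  while (i + 2L <= nchar(dna)) {
    codon <- substr(dna, i, i + 2L)
    aa <- tab[[codon]]
    out <- c(out, if (is.null(aa) || is.na(aa)) "X" else aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# brute-force six-frame between-stops ORF enumeration
oracle_orfs <- function(seq, min_nt) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  L <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 0:2) {
      prot <- oracle_translate(s, frame)
      if (!nchar(prot)) next
      aa <- strsplit(prot, "")[[1]]
      i <- 1L
      while (i <= length(aa)) {
        if (aa[i] == "*") { i <- i + 1L; next }
        j <- i
        while (j < length(aa) && aa[j + 1L] != "*") j <- j + 1L
        nt0 <- frame + 3L * (i - 1L); nt1 <- frame + 3L * j
        if (nt1 - nt0 >= min_nt) {
          g <- if (strand == "+") c(nt0, nt1) else c(L - nt1, L - nt0)
          rows[[length(rows) + 1L]] <-
            sprintf("%s/%d/%d/%d", strand, g[1], g[2], frame)
        }
        i <- j + 1L
      }
    }
  }
  sort(unlist(rows))
}

orf_keys <- function(orfs) {
  sort(sprintf("%s/%d/%d/%d", orfs$strand, orfs$start, orfs$end, orfs$frame))
}

# exhaustive enumeration of the chained-motif objective over all
# non-overlapping hit subsets (vectorised over bitmasks)
oracle_chain_score <- function(hits, bonus) {
  n <- nrow(hits)
  if (n == 0L) return(0)
  stopifnot(n <= 15L)
  hits <- hits[order(hits$aa_start, hits$aa_end), , drop = FALSE]
  masks <- 0:(2^n - 1L)
  valid <- rep(TRUE, length(masks))
  score <- rep(0, length(masks))
  for (i in seq_len(n))
    score <- score + hits$score[i] * (bitwAnd(masks, 2^(i - 1L)) > 0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hits$aa_end[i] > hits$aa_start[j]) {
      both <- bitwAnd(masks, 2^(i - 1L) + 2^(j - 1L)) == 2^(i - 1L) + 2^(j - 1L)
      valid <- valid & !both
    }
  }
  # adjacency bonus: hits i and j (in start order) are consecutive in a
  # chain when both are chosen and nothing between them is
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hits$aa_end[i] > hits$aa_start[j]) next
    if (hits$aa_start[j] - hits$aa_end[i] > 2L) next
    bmask <- if (j - i > 1L) sum(2^(((i + 1L):(j - 1L)) - 1L)) else 0L
    both <- bitwAnd(masks, 2^(i - 1L) + 2^(j - 1L)) == 2^(i - 1L) + 2^(j - 1L)
    free <- bitwAnd(masks, bmask) == 0L
    score <- score + bonus * (both & free)
  }
  max(score[valid])
}

# external alignment engine as score oracle
oracle_align_score <- function(a, b, alphabet = "protein") {
  if (alphabet == "protein") {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62; m["X", ] <- 0; m[, "X"] <- 0
    go <- 10; ge <- 1
  } else {
    bs <- c("A", "C", "G", "T", "N")
    m <- matrix(-2, 5, 5, dimnames = list(bs, bs)); diag(m) <- 1
    m["N", ] <- 0; m[, "N"] <- 0
    go <- 5; ge <- 2
  }
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = m, gapOpening = go,
                                gapExtension = ge, scoreOnly = TRUE)
}

# naive per-position lookup-sum for binding-window scores
oracle_window_score <- function(pairs, window, table) {
  bases <- strsplit(gsub("U", "T", toupper(window)), "")[[1]]
  tot <- 0
  for (i in seq_len(nrow(pairs))) {
    if (bases[i] == "N") next
    key <- paste0(pairs$aa5[i], pairs$aa35[i])
    aff <- table$scores[[key]]
    if (is.null(aff)) aff <- rep(table$pseudo, 4)
    names(aff) <- c("A", "C", "G", "U")
    b <- if (bases[i] == "T") "U" else bases[i]
    tot <- tot + log2(4 * aff[[b]])
  }
  tot
}

# small genotype subset used for the repeated-simulation loops
small_panel <- function() {
  p <- default_panel()
  p[p$genotype %in% c("R197", "R0932E", "Anapurna", "Ttimopheevii"), ]
}

# random insert with guarded boundary bases, so exact-match anchor
# extension cannot absorb a coincidentally matching first/last base and
# the planted interval is the unique measurable answer
planted_insert <- function(b, p, U) {
  ins <- strsplit(random_dna_str(U), "")[[1]]
  right_base <- substr(b, p + 1, p + 1)
  left_base <- substr(b, p, p)
  if (ins[1] == right_base)
    ins[1] <- setdiff(c("A", "C", "G", "T"), right_base)[1]
  if (ins[U] == left_base)
    ins[U] <- setdiff(c("A", "C", "G", "T"), left_base)[1]
  paste0(substr(b, 1, p), paste(ins, collapse = ""),
         substr(b, p + 1, nchar(b)))
}

# random non-overlapping-ish motif hit sets for chaining tests
random_hit_set <- function(n, span = 200L) {
  starts <- sort(sample(0:span, n, TRUE))
  data.frame(model = "P", aa_start = starts,
             aa_end = starts + sample(20:40, n, TRUE),
             score = round(stats::runif(n, 1, 10), 3),
             aa5 = "T", aa35 = "N", stringsAsFactors = FALSE)
}
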