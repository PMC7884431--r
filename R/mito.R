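#' Find regions of one genome absent from another
#'
#' k-mer mode: a position of `genome_a` is unique iff no k-mer window
#' containing it occurs anywhere in `genome_b` (either strand); maximal
#' runs of unique positions at least `min_len` long are reported. On a
#' genome that differs from `genome_b` only by an inserted segment, these
#' runs recover the insert exactly. Anchor mode (the precise default for
#' length claims) additionally refines each run by locating the flanking
#' shared k-mers in `genome_b` and extending exact matches inward from both
#' sides; the inter-anchor gap on `genome_a` is the reported insert. When a
#' flanking anchor is not unique in `genome_b` (repeats), the run falls
#' back to its k-mer boundaries with a warning.
#'
#' @param genome_a,genome_b dna [seq_record()]s or strings.
#' @param k k-mer size (odd, 15-63).
#' @param min_len Minimum reported region length (nt).
#' @param mode `"anchor"` or `"kmer"`.
#' @return data.frame with columns `start`, `end` (0-based half-open on
#'   `genome_a`), `length`, `anchored`.
#' @export
unique_regions <- function(genome_a, genome_b, k = 31L, min_len = 50L,
                           mode = c("anchor", "kmer")) {
  mode <- match.arg(mode)
  if (k %% 2L == 0L || k < 15L || k > 63L)
    rfl_parameter_error("k must be odd and in [15, 63]")
  a <- as_seq_record(genome_a, "dna", "a")$sequence
  b <- as_seq_record(genome_b, "dna", "b")$sequence
  La <- nchar(a)
  if (La < k || nchar(b) < k)
    rfl_parameter_error("genome shorter than k")
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), anchored = logical())
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) character() else substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  bk <- unique(c(kmers(b), kmers(revcomp(b))))
  ak <- kmers(a)
  shared <- ak %in% bk
  covered <- logical(La)
  r <- rle(shared)
  ends_w <- cumsum(r$lengths); starts_w <- ends_w - r$lengths + 1L
  for (i in which(r$values))
    covered[starts_w[i]:(ends_w[i] + k - 1L)] <- TRUE
  ru <- rle(!covered)
  ends_p <- cumsum(ru$lengths); starts_p <- ends_p - ru$lengths + 1L
  runs <- which(ru$values & ru$lengths >= min_len)
  if (!length(runs)) return(empty)
  out <- data.frame(start = starts_p[runs] - 1L, end = ends_p[runs],
                    length = ru$lengths[runs], anchored = FALSE)
  if (mode == "kmer") return(out)
  brc <- revcomp(b)
  locate_unique <- function(kmer) {
    hf <- gregexpr(kmer, b, fixed = TRUE)[[1]]
    hr <- gregexpr(kmer, brc, fixed = TRUE)[[1]]
    nf <- if (hf[1] == -1L) 0L else length(hf)
    nr <- if (hr[1] == -1L) 0L else length(hr)
    if (nf + nr != 1L) return(NULL)
    if (nf == 1L) list(seq = b, pos = hf[1]) else list(seq = brc, pos = hr[1])
  }
  extend_right <- function(sa, ia, sb, ib) {   # 1-based starts of matched kmer
    ia <- ia + k; ib <- ib + k
    while (ia <= nchar(sa) && ib <= nchar(sb) &&
           substr(sa, ia, ia) == substr(sb, ib, ib)) { ia <- ia + 1L; ib <- ib + 1L }
    ia                                          # first non-matching a position
  }
  extend_left <- function(sa, ia, sb, ib) {    # 1-based starts of matched kmer
    ia <- ia - 1L; ib <- ib - 1L
    while (ia >= 1L && ib >= 1L &&
           substr(sa, ia, ia) == substr(sb, ib, ib)) { ia <- ia - 1L; ib <- ib - 1L }
    ia                                          # last non-matching a position
  }
  for (i in seq_len(nrow(out))) {
    s0 <- out$start[i]; e0 <- out$end[i]       # 0-based half-open
    ls <- s0 - k + 1L                           # 1-based start of left flank kmer
    rs <- e0 + 1L                               # 1-based start of right flank kmer
    lhit <- if (ls >= 1L) locate_unique(substr(a, ls, ls + k - 1L)) else NULL
    rhit <- if (rs + k - 1L <= La) locate_unique(substr(a, rs, rs + k - 1L))
            else NULL
    if ((ls >= 1L && is.null(lhit)) || (rs + k - 1L <= La && is.null(rhit))) {
      warning("non-unique flanking anchor; keeping k-mer boundaries")
      next
    }
    new_s <- if (is.null(lhit)) s0 else extend_right(a, ls, lhit$seq, lhit$pos) - 1L
    new_e <- if (is.null(rhit)) e0 else extend_left(a, rs, rhit$seq, rhit$pos)
    if (new_e >= new_s) {
      out$start[i] <- new_s; out$end[i] <- new_e
      out$length[i] <- new_e - new_s
      out$anchored[i] <- TRUE
    }
  }
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ORFs specific to one genome of a pair
#'
#' An ORF of `genome_a` is species-specific iff no single local alignment
#' against `genome_b` (either strand) covers at least `cover_t` of the ORF
#' at `identity_t` identity or better — i.e. the intact ORF is absent even
#' when sub-fragments are shared. A chimeric ORF whose 5' half matches a
#' conserved gene is therefore still specific, which is exactly the
#' situation of a CMS-associated chimera.
#'
#' @param orfs A [find_orfs()] result for `genome_a`.
#' @param genome_a,genome_b dna [seq_record()]s or strings.
#' @param identity_t,cover_t Identity and ORF-coverage thresholds.
#' @return The subset of `orfs` rows that are specific to `genome_a`.
#' @export
species_specific_orfs <- function(orfs, genome_a, genome_b,
                                  identity_t = 0.95, cover_t = 0.95) {
  a <- as_seq_record(genome_a, "dna", "a")
  b <- as_seq_record(genome_b, "dna", "b")
  brc <- seq_record("b_rc", revcomp(b$sequence))
  keep <- vapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    s <- orf_sequence(o, a)
    for (target in list(b, brc)) {
      r <- align_identity(seq_record("orf", s), target, alphabet = "dna")
      cover <- (r$span_a[2] - r$span_a[1]) / nchar(s)
      if (r$identity >= identity_t && cover >= cover_t) return(FALSE)
    }
    TRUE
  }, TRUE)
  out <- orfs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a chimeric ORF against candidate donor genes
#'
#' Chimeric mitochondrial ORFs typically fuse the 5' part of a conserved
#' gene (the donor, often an ATP-synthase subunit) to novel sequence. This
#' function identifies the donor as the CDS sharing the longest run of
#' identical leading codons with the ORF (ties broken toward the longest
#' CDS), measures that shared prefix in codons, optionally measures the
#' identical 5'-flank extension upstream of the start codons, and
#' delimits the ORF's unique region.
#'
#' Codon bookkeeping: `orf_codons` counts sense codons (stop excluded, as
#' reported by [find_orfs()]); `unique_codons` counts reading-frame
#' triplets lying fully inside the unique region, *including* the stop
#' triplet when the region covers it. A 279-sense-codon chimera with a
#' 96-codon donor prefix and a 552-nt unique region therefore reports 184
#' unique codons (183 sense + stop); the two tallies deliberately overlap
#' by the stop codon and both are returned.
#'
#' @param orf One row of a [find_orfs()] result.
#' @param genome The dna [seq_record()] the ORF lives on.
#' @param donor_cds List of dna [seq_record()]s of candidate donor CDSs
#'   (sense strand, in frame, stop codon optional).
#' @param donor_flanks Optional named character vector of genomic sequence
#'   immediately 5' of each donor's start codon, used with the ORF's own
#'   genomic flank to measure `shared_5prime_flank_nt`.
#' @param unique_intervals Optional [unique_regions()] result (genome
#'   coordinates); when supplied, the unique region reported is the
#'   intersecting interval from this set, which may extend past the ORF's
#'   stop (e.g. to include the stop codon itself).
#' @param flank_window How much genomic 5' flank of the ORF to consider.
#' @return An object of class `chimera_annotation`: `orf_id`, `donor_gene`,
#'   `shared_prefix_codons`, `shared_5prime_flank_nt`, `unique_start`,
#'   `unique_end`, `unique_len_nt`, `unique_codons`, `orf_codons`.
#' @export
annotate_chimera <- function(orf, genome, donor_cds, donor_flanks = NULL,
                             unique_intervals = NULL, flank_window = 500L) {
  genome <- as_seq_record(genome, "dna")
  orf_nt <- orf_sequence(orf, genome)
  n_codons <- nchar(orf_nt) %/% 3L
  orf_codon_v <- substring(orf_nt, 3L * (seq_len(n_codons) - 1L) + 1L,
                           3L * seq_len(n_codons))
  best_donor <- NULL; best_prefix <- 0L; best_len <- -1L
  for (d in donor_cds) {
    dn <- as_seq_record(d, "dna")
    nc <- nchar(dn$sequence) %/% 3L
    dc <- substring(dn$sequence, 3L * (seq_len(nc) - 1L) + 1L,
                    3L * seq_len(nc))
    nmax <- min(n_codons, nc)
    run <- 0L
    while (run < nmax && orf_codon_v[run + 1L] == dc[run + 1L])
      run <- run + 1L
    if (run > best_prefix ||
        (run == best_prefix && run > 0L && nchar(dn$sequence) > best_len)) {
      best_prefix <- run; best_donor <- dn$id; best_len <- nchar(dn$sequence)
    }
  }
  flank_nt <- 0L
  if (!is.null(best_donor) && best_prefix > 0L && !is.null(donor_flanks) &&
      best_donor %in% names(donor_flanks)) {
    dflank <- toupper(donor_flanks[[best_donor]])
    oflank <- if (orf$strand == "+")
      substr(genome$sequence, max(1L, orf$start - flank_window + 1L),
             orf$start)
    else revcomp(substr(genome$sequence, orf$end + 1L,
                        min(nchar(genome$sequence), orf$end + flank_window)))
    i <- nchar(oflank); j <- nchar(dflank)
    while (i >= 1L && j >= 1L &&
           substr(oflank, i, i) == substr(dflank, j, j)) {
      flank_nt <- flank_nt + 1L; i <- i - 1L; j <- j - 1L
    }
  }
  # unique region: ORF minus shared prefix, in genome forward coordinates
  if (orf$strand == "+") {
    u <- c(orf$start + 3L * best_prefix, orf$end)
  } else {
    u <- c(orf$start, orf$end - 3L * best_prefix)
  }
  if (!is.null(unique_intervals) && nrow(unique_intervals)) {
    ov <- unique_intervals[unique_intervals$end > u[1] &
                             unique_intervals$start < u[2], , drop = FALSE]
    if (nrow(ov)) u <- c(min(ov$start), max(ov$end))
  }
  # reading-frame triplets (stop included) fully inside the unique region
  total_triplets <- n_codons + 1L   # sense codons + stop
  tri_idx <- seq_len(total_triplets) - 1L
  if (orf$strand == "+") {
    tri_s <- orf$start + 3L * tri_idx
    tri_e <- tri_s + 3L
  } else {
    tri_e <- orf$end - 3L * tri_idx
    tri_s <- tri_e - 3L
  }
  unique_codons <- sum(tri_s >= u[1] & tri_e <= u[2])
  structure(list(
    orf_id = rownames(orf) %||% "orf",
    donor_gene = if (best_prefix > 0L) best_donor else NA_character_,
    shared_prefix_codons = best_prefix,
    shared_5prime_flank_nt = flank_nt,
    unique_start = u[1], unique_end = u[2],
    unique_len_nt = u[2] - u[1],
    unique_codons = unique_codons,
    orf_codons = n_codons), class = "chimera_annotation")
}

#' @export
print.chimera_annotation <- function(x, ...) {
  cat(sprintf(paste0(
    "<chimera_annotation: %d-codon ORF, donor %s, %d-codon shared prefix,\n",
    "  %d-nt unique region [%d, %d) holding %d codon triplets>\n"),
    x$orf_codons, if (is.na(x$donor_gene)) "none" else x$donor_gene,
    x$shared_prefix_codons,
    x$unique_len_nt, x$unique_start, x$unique_end, x$unique_codons))
  invisible(x)
}
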