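#' Translate a DNA sequence in a given frame
#'
#' Standard genetic code (translation table 1). Stops are rendered as `*`,
#' a trailing partial codon is dropped, and any codon containing `N`
#' translates to `X`.
#'
#' @param dna A [seq_record()] with dna alphabet, or a DNA string.
#' @param frame Frame offset, 0, 1 or 2.
#' @return The translated protein string.
#' @examples
#' translate_dna("ATGGCC")  # "MA"
#' @export
translate_dna <- function(dna, frame = 0L) {
  if (inherits(dna, "seq_record")) {
    if (dna$alphabet != "dna") rfl_type_error("dna record required")
    dna <- dna$sequence
  } else {
    dna <- as_seq_record(dna, "dna")$sequence
  }
  if (!frame %in% 0:2) rfl_parameter_error("frame must be 0, 1 or 2")
  L <- nchar(dna)
  n_codons <- (L - frame) %/% 3L
  if (n_codons <= 0L) return("")
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(dna, starts, starts + 2L)
  aa <- GENETIC_CODE_1[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

# Standard code (table 1), from Biostrings.
GENETIC_CODE_1 <- stats::setNames(as.character(Biostrings::GENETIC_CODE),
                                  names(Biostrings::GENETIC_CODE))

#' Six-frame open reading frame discovery
#'
#' Finds ORFs in the getorf style: in `between_stops` mode (the default,
#' getorf's `-find 0`) every maximal stop-free translated stretch between two
#' stop codons (or the sequence ends) is an ORF; in `atg_to_stop` mode each
#' ORF runs from the first ATG of such a stretch to its stop. Both strands
#' are scanned by default and coordinates are always reported on the forward
#' strand (0-based half-open). ORFs touching a sequence end are included and
#' flagged `open_ended`, since truncated contigs truncate genes.
#'
#' `min_nt` is in nucleotides (the default 279 nt equals 93 codons). To keep
#' only ORFs of more than `n` codons, set `min_codons` to `n + 1` (codon
#' counts are sense codons, stop excluded; the filter keeps
#' `codons >= min_codons`).
#'
#' @param seq A dna [seq_record()] or string.
#' @param min_nt Minimum ORF length in nucleotides (>= 3).
#' @param mode `"between_stops"` or `"atg_to_stop"`.
#' @param both_strands Scan the reverse strand too.
#' @param min_codons Optional additional filter on sense-codon count.
#' @param circular Treat the sequence as circular: the first `min_nt - 1`
#'   bases are appended before scanning and wrapped duplicates are removed.
#' @return A data.frame with columns `genome_id`, `start`, `end`, `strand`,
#'   `frame`, `nt_len`, `codons`, `protein`, `open_ended`, sorted by
#'   (start, strand, frame).
#' @export
find_orfs <- function(seq, min_nt = 279L, mode = c("between_stops",
                      "atg_to_stop"), both_strands = TRUE,
                      min_codons = NULL, circular = FALSE) {
  mode <- match.arg(mode)
  rec <- as_seq_record(seq, "dna")
  if (rec$alphabet != "dna") rfl_type_error("dna record required")
  if (min_nt < 3L) rfl_parameter_error("min_nt must be >= 3")
  s <- rec$sequence
  L <- nchar(s)
  scan_len <- L
  if (circular && L > min_nt) {
    s <- paste0(s, substr(s, 1L, min_nt - 1L))
    scan_len <- nchar(s)
  }
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    work <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      prot <- translate_dna(work, frame)
      nc <- nchar(prot)
      if (nc == 0L) next
      is_stop <- strsplit(prot, "")[[1]] == "*"
      r <- rle(!is_stop)
      ends_c <- cumsum(r$lengths)
      starts_c <- ends_c - r$lengths + 1L
      for (k in which(r$values)) {
        i0 <- starts_c[k]; i1 <- ends_c[k]
        open_start <- i0 == 1L
        open_end <- i1 == nc
        pp <- substr(prot, i0, i1)
        nt0 <- frame + 3L * (i0 - 1L)          # 0-based on working strand
        nt1 <- frame + 3L * i1
        if (mode == "atg_to_stop") {
          m <- regexpr("M", pp, fixed = TRUE)
          if (m < 0L) next
          pp <- substr(pp, m, nchar(pp))
          nt0 <- nt0 + 3L * (as.integer(m) - 1L)
          open_start <- FALSE
        }
        nt_len <- nt1 - nt0
        if (nt_len < min_nt) next
        if (strand == "+") {
          g0 <- nt0; g1 <- nt1
        } else {
          g0 <- nchar(work) - nt1; g1 <- nchar(work) - nt0
        }
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = rec$id, start = g0, end = g1, strand = strand,
          frame = frame, nt_len = nt_len, codons = nt_len %/% 3L,
          protein = pp, open_ended = open_start || open_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), start = integer(), end = integer(),
               strand = character(), frame = integer(), nt_len = integer(),
               codons = integer(), protein = character(),
               open_ended = logical(), stringsAsFactors = FALSE)
  if (circular && nrow(out)) {
    # drop ORFs living entirely in the appended copy, then wrapped duplicates
    out <- out[out$start < L, , drop = FALSE]
    key <- sprintf("%s/%d/%d", out$strand, out$start %% L, out$nt_len)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(min_codons)) out <- out[out$codons >= min_codons, , drop = FALSE]
  out <- out[order(out$start, out$strand, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract an ORF's nucleotide sequence from its genome
#'
#' @param orf One row of a [find_orfs()] result.
#' @param genome The genome [seq_record()] the ORF was found on.
#' @return The sense-strand nucleotide string of the ORF.
#' @export
orf_sequence <- function(orf, genome) {
  genome <- as_seq_record(genome, "dna")
  s <- substr(genome$sequence, orf$start + 1L, orf$end)
  if (orf$strand == "-") s <- revcomp(s)
  s
}

#' Write ORFs as GFF3
#' @param orfs A [find_orfs()] result.
#' @param path Output path.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  feats <- lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    feature(o$genome_id, o$start, o$end, strand = o$strand, type = "ORF",
            source = "rflscan",
            attributes = c(ID = sprintf("orf_%d", i),
                           codons = as.character(o$codons),
                           frame = as.character(o$frame)))
  })
  write_gff3(feats, path)
}
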