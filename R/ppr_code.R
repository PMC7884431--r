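#' PPR code tables
#'
#' A code table maps a (position-5, position-35) amino-acid pair to a
#' 4-vector of base affinities over A, C, G, U. The shipped default table
#' (`default_code_table()`) encodes the canonical qualitative PPR code —
#' T5/N35 and S5/N35 favour A, T5/D35 and S5/D35 favour G, N5/D35 favours
#' U (then C), N5/S35 favours C, N5/N35 favours pyrimidines — as
#' probabilities; the quantitative in vitro affinities behind such tables
#' are not redistributable here, so every value can be overridden from a
#' TSV via `read_code_table()`. Combinations absent from the table score
#' the uniform `pseudo` affinity (0.25), i.e. they are uninformative.
#'
#' @param path TSV with header `aa5 aa35 A C G U`.
#' @param pseudo Affinity assigned to every base for unseen combinations.
#' @return An object of class `ppr_code_table`.
#' @export
read_code_table <- function(path, pseudo = 0.25) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("aa5", "aa35", "A", "C", "G", "U")
  if (!all(need %in% names(df)))
    rfl_format_error("code table needs columns aa5, aa35, A, C, G, U")
  scores <- lapply(seq_len(nrow(df)), function(i)
    c(A = df$A[i], C = df$C[i], G = df$G[i], U = df$U[i]))
  names(scores) <- paste0(toupper(df$aa5), toupper(df$aa35))
  if (any(!is.finite(unlist(scores))) || any(unlist(scores) <= 0))
    rfl_format_error("code table affinities must be finite and positive")
  structure(list(scores = scores, pseudo = pseudo,
                 provenance = path), class = "ppr_code_table")
}

#' @rdname read_code_table
#' @export
default_code_table <- function() {
  read_code_table(system.file("extdata", "ppr_code_default.tsv",
                              package = "rflscan"))
}

# affinity lookup for one pair; unseen pairs are uniform at pseudo
code_affinity <- function(table, aa5, aa35) {
  v <- table$scores[[paste0(aa5, aa35)]]
  if (is.null(v))
    v <- c(A = table$pseudo, C = table$pseudo, G = table$pseudo,
           U = table$pseudo)
  v
}

# pairs argument normaliser: data.frame(aa5, aa35) or "T:N"-style strings
as_code_pairs <- function(pairs) {
  if (is.data.frame(pairs)) {
    data.frame(aa5 = toupper(pairs$aa5), aa35 = toupper(pairs$aa35),
               stringsAsFactors = FALSE)
  } else {
    sp <- strsplit(toupper(pairs), ":", fixed = TRUE)
    data.frame(aa5 = vapply(sp, `[[`, "", 1L),
               aa35 = vapply(sp, `[[`, "", 2L), stringsAsFactors = FALSE)
  }
}

#' Score one RNA window against an ordered list of code pairs
#'
#' Motif i (N- to C-terminal) scores base i (5' to 3'): each per-motif
#' score is `log2(4 * affinity)` of that pair for that base, so an
#' uninformative pairing scores 0 and the maximum-affinity base of a
#' canonical pair scores positively. `N` bases score 0. T and U are
#' equivalent.
#'
#' @param pairs data.frame with `aa5`, `aa35` (e.g. from
#'   [extract_code_pairs()]) or character vector like `"T:N"`.
#' @param window RNA/DNA window of the same length as `pairs`.
#' @param table A [read_code_table()] table.
#' @return List with `total` and `per_motif`.
#' @export
score_window <- function(pairs, window, table = default_code_table()) {
  pairs <- as_code_pairs(pairs)
  w <- gsub("U", "T", toupper(window), fixed = TRUE)
  if (nchar(w) != nrow(pairs))
    rfl_contract_error("window length must equal number of code pairs")
  if (nrow(pairs) == 0L) return(list(total = 0, per_motif = numeric()))
  bases <- strsplit(w, "")[[1]]
  per <- vapply(seq_len(nrow(pairs)), function(i) {
    if (bases[i] == "N") return(0)
    aff <- code_affinity(table, pairs$aa5[i], pairs$aa35[i])
    b <- if (bases[i] == "T") "U" else bases[i]
    log2(4 * aff[[b]])
  }, 0)
  list(total = sum(per), per_motif = per)
}

#' Scan a transcript for the best-scoring binding windows
#'
#' Scores every window of length `length(pairs)` (a 20-motif protein thus
#' predicts a 20-nt site), ranks by total descending with ties broken
#' toward the smaller start. Orientation is fixed: motif N-terminus pairs
#' with the RNA 5' end.
#'
#' @inheritParams score_window
#' @param transcript A [seq_record()] or string (5' to 3').
#' @param top_n Number of ranked windows to return.
#' @return data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open on the transcript), `total`, `rank`.
#' @export
scan_transcript <- function(pairs, transcript, table = default_code_table(),
                            top_n = 5L) {
  pairs <- as_code_pairs(pairs)
  rec <- as_seq_record(transcript, "dna", "transcript")
  n <- nrow(pairs)
  L <- nchar(rec$sequence)
  if (L < n || n == 0L) {
    warning("transcript shorter than the code-pair list")
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), total = numeric(), rank = integer()))
  }
  # lookup matrix: motif x base (DNA letters; T column holds the U affinity)
  M <- t(vapply(seq_len(n), function(i)
    log2(4 * code_affinity(table, pairs$aa5[i], pairs$aa35[i])), numeric(4)))
  colnames(M) <- c("A", "C", "G", "T")
  base_idx <- match(strsplit(rec$sequence, "")[[1]], c("A", "C", "G", "T"))
  nw <- L - n + 1L
  tot <- numeric(nw)
  for (i in seq_len(n)) {
    sc <- M[cbind(i, base_idx[i:(i + nw - 1L)])]
    sc[is.na(sc)] <- 0     # N bases
    tot <- tot + sc
  }
  ord <- order(-tot, seq_len(nw))
  top <- ord[seq_len(min(top_n, nw))]
  data.frame(transcript_id = rec$id, start = top - 1L, end = top - 1L + n,
             total = tot[top], rank = seq_along(top),
             stringsAsFactors = FALSE)
}

#' Offset between a predicted binding site and a cleavage position
#'
#' Restorer PPR proteins induce endonucleolytic cleavage a short distance
#' 3' of where they bind; an offset strictly between 0 and 100 nt is
#' classified as consistent with that mechanism.
#'
#' @param site_end Binding-site end (0-based half-open, transcript coords).
#' @param cleavage_pos Cleavage position on the same transcript.
#' @return List with `offset` (positive = cleavage 3' of the site end) and
#'   `consistent`.
#' @export
site_cleavage_offset <- function(site_end, cleavage_pos) {
  offset <- cleavage_pos - site_end
  list(offset = offset, consistent = offset > 0 && offset < 100)
}
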