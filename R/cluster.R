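# Scoring constants shared by align_identity and the pipeline's placement
# and specificity checks. DNA: +1 match / -2 mismatch, N neutral; protein:
# BLOSUM62 with X made neutral. Affine gap penalties per alphabet; a gap of
# length L costs gap_open + gap_ext * L.
aln_scoring <- function(alphabet) {
  if (alphabet == "dna") {
    b <- c("A", "C", "G", "T", "N")
    m <- matrix(-2, 5, 5, dimnames = list(b, b))
    diag(m) <- 1
    m["N", ] <- 0; m[, "N"] <- 0
    list(mat = m, gap_open = 5, gap_ext = 2)
  } else {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
    m["X", ] <- 0; m[, "X"] <- 0
    list(mat = m, gap_open = 10, gap_ext = 1)
  }
}

#' Local-alignment identity between two sequences
#'
#' Smith-Waterman local alignment with affine gaps (BLOSUM62 for protein;
#' +1/-2 with gap open 5 / extend 2 for DNA). Identity is matches divided
#' by alignment columns (gap columns included). `unaligned_short` is the
#' number of residues of the shorter sequence outside the aligned span —
#' the quantity CD-HIT's `-AS` option bounds. The alignment runs in
#' compiled code; the test suite checks its scores against
#' `Biostrings::pairwiseAlignment` as an independent oracle.
#'
#' @param a,b [seq_record()]s or strings of the same alphabet.
#' @param alphabet `"protein"` or `"dna"` (used when `a`, `b` are strings).
#' @return A list with `identity`, `aln_len`, `unaligned_short`, `score`,
#'   and the 0-based half-open aligned spans `span_a`, `span_b`.
#' @export
align_identity <- function(a, b, alphabet = "protein") {
  a <- as_seq_record(a, alphabet, "a"); b <- as_seq_record(b, alphabet, "b")
  if (a$alphabet != b$alphabet) rfl_type_error("alphabet mismatch")
  sa <- sub("\\*$", "", a$sequence); sb <- sub("\\*$", "", b$sequence)
  if (!nchar(sa) || !nchar(sb))
    return(list(identity = 0, aln_len = 0L,
                unaligned_short = min(nchar(sa), nchar(sb)), score = 0,
                span_a = c(0L, 0L), span_b = c(0L, 0L)))
  sc <- aln_scoring(a$alphabet)
  align_coded(encode_seq(sa, sc), encode_seq(sb, sc), sc)
}

# integer-code a sequence for the compiled kernel; unknown residues
# (internal '*') map to the matrix's neutral last letter (X / N)
encode_seq <- function(s, sc) {
  code <- match(strsplit(s, "")[[1]], rownames(sc$mat))
  code[is.na(code)] <- nrow(sc$mat)
  code
}

align_coded <- function(ca, cb, sc) {
  r <- .rfl_align_c(ca, cb, sc$mat, sc$gap_open, sc$gap_ext)
  span_a <- if (r$a_end >= r$a_start) r$a_end - r$a_start + 1L else 0L
  span_b <- if (r$b_end >= r$b_start) r$b_end - r$b_start + 1L else 0L
  span_short <- if (length(ca) <= length(cb)) span_a else span_b
  list(identity = if (r$cols > 0) r$matches / r$cols else 0,
       aln_len = as.integer(r$cols),
       unaligned_short = min(length(ca), length(cb)) - span_short,
       score = r$score,
       span_a = c(r$a_start - 1L, r$a_end), span_b = c(r$b_start - 1L, r$b_end))
}

#' Greedy identity clustering of RFL sequences into orthogroups
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length
#' (descending, ties broken by id) and each sequence joins the first
#' existing cluster whose representative it matches at
#' `identity >= identity_c` with alignment length `>= min_aln_len` and at
#' most `max_unaligned_short` unaligned residues on the shorter sequence;
#' otherwise it founds a new cluster. Representatives are therefore always
#' the longest member. The defaults mirror a 96% identity threshold with
#' a 105-aa minimum alignment and 60-aa unaligned allowance. Word-filter
#' heuristics are not reproduced: every comparison is a full local
#' alignment, which keeps the procedure deterministic and oracle-testable
#' at panel scale. Output is invariant to input order.
#'
#' @param proteins List of protein [seq_record()]s.
#' @param meta Optional data.frame with columns `id`, `genotype`, `status`
#'   (and any extra columns), joined onto the members.
#' @param identity_c Identity threshold (inclusive).
#' @param min_aln_len Minimum alignment length (aa).
#' @param max_unaligned_short Maximum unaligned length of the shorter
#'   sequence (aa).
#' @param match_mode `"first"` joins the first qualifying cluster in
#'   founding order (CD-HIT-like greedy); `"best"` joins the qualifying
#'   cluster with the highest identity.
#' @return data.frame with columns `group_id`, `representative`, `id`,
#'   plus any `meta` columns; one row per member.
#' @export
greedy_cluster <- function(proteins, meta = NULL, identity_c = 0.96,
                           min_aln_len = 105L, max_unaligned_short = 60L,
                           match_mode = c("first", "best")) {
  match_mode <- match.arg(match_mode)
  if (!length(proteins)) rfl_parameter_error("at least one sequence required")
  if (identity_c <= 0 || identity_c > 1)
    rfl_parameter_error("identity_c must be in (0, 1]")
  ids <- vapply(proteins, `[[`, "", "id")
  seqs <- vapply(proteins, function(r) sub("\\*$", "", r$sequence), "")
  lens <- nchar(seqs)
  sc <- aln_scoring("protein")
  codes <- lapply(seqs, encode_seq, sc = sc)
  ord <- order(-lens, ids)
  reps <- integer()          # index of each cluster's representative
  assign <- integer(length(proteins))
  for (i in ord) {
    joined <- 0L
    best_ident <- -1
    for (ci in seq_along(reps)) {
      r <- align_coded(codes[[i]], codes[[reps[ci]]], sc)
      ok <- r$identity >= identity_c && r$aln_len >= min_aln_len &&
        r$unaligned_short <= max_unaligned_short
      if (!ok) next
      if (match_mode == "first") { joined <- ci; break }
      if (r$identity > best_ident) { best_ident <- r$identity; joined <- ci }
    }
    if (joined == 0L) {
      reps <- c(reps, i)
      joined <- length(reps)
    }
    assign[i] <- joined
  }
  out <- data.frame(
    group_id = sprintf("g%03d", assign),
    representative = ids[reps[assign]],
    id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    mi <- match(out$id, meta$id)
    for (col in setdiff(names(meta), "id")) out[[col]] <- meta[[col]][mi]
  }
  out <- out[order(out$group_id, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tile capture baits along target sequences
#'
#' Probes of length `probe_max` are placed at starts 0, `step`, 2*`step`,
#' ... while they fit; if the last tiled probe stops short of the target
#' end, a final probe flush with the end is added. Targets shorter than
#' `probe_max` (but at least `probe_min`) get a single full-length probe.
#' Probes overlapping a mask are trimmed to their longest unmasked part and
#' kept if still at least `probe_min` long, otherwise dropped.
#'
#' @param targets List of dna [seq_record()]s.
#' @param masks Optional named list (by target id) of two-column
#'   (start, end) 0-based half-open mask matrices.
#' @param probe_min,probe_max Probe length bounds (nt).
#' @param step Tiling step (nt).
#' @return data.frame with columns `target`, `start`, `end` (0-based
#'   half-open probe coordinates).
#' @export
design_capture_baits <- function(targets, masks = NULL, probe_min = 50L,
                                 probe_max = 95L, step = 36L) {
  if (probe_min > probe_max) rfl_parameter_error("probe_min > probe_max")
  if (step < 1L) rfl_parameter_error("step must be >= 1")
  rows <- list()
  for (rec in targets) {
    L <- nchar(rec$sequence)
    if (L < probe_min) {
      warning(sprintf("target %s shorter than probe_min: no probes", rec$id))
      next
    }
    if (L < probe_max) {
      probes <- matrix(c(0L, L), ncol = 2L)
    } else {
      starts <- seq.int(0L, L - probe_max, by = step)
      probes <- cbind(starts, starts + probe_max)
      if (probes[nrow(probes), 2L] < L)
        probes <- rbind(probes, c(L - probe_max, L))
    }
    msk <- normalize_masks(if (!is.null(masks)) masks[[rec$id]] else NULL, L)
    if (nrow(msk)) {
      masked <- logical(L)
      for (i in seq_len(nrow(msk))) masked[(msk[i, 1] + 1L):msk[i, 2]] <- TRUE
      trimmed <- list()
      for (i in seq_len(nrow(probes))) {
        s <- probes[i, 1L]; e <- probes[i, 2L]
        free <- !masked[(s + 1L):e]
        if (all(free)) { trimmed[[length(trimmed) + 1L]] <- c(s, e); next }
        r <- rle(free)
        ends <- cumsum(r$lengths); starts_r <- ends - r$lengths
        runs <- which(r$values)
        if (!length(runs)) next
        best <- runs[which.max(r$lengths[runs])]
        ns <- s + starts_r[best]; ne <- s + ends[best]
        if (ne - ns >= probe_min)
          trimmed[[length(trimmed) + 1L]] <- c(ns, ne)
      }
      probes <- if (length(trimmed)) do.call(rbind, trimmed) else
        matrix(integer(), ncol = 2L)
    }
    if (nrow(probes))
      rows[[length(rows) + 1L]] <- data.frame(
        target = rec$id, start = as.integer(probes[, 1L]),
        end = as.integer(probes[, 2L]), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(target = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
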