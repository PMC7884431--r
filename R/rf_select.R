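#' Place a gene inside or outside a genetic interval by in silico mapping
#'
#' Aligns the gene against reference contigs (both strands) and converts the
#' best hit's midpoint to chromosome coordinates. Returns `"in"` when the
#' midpoint lies inside the interval, `"out"` when it does not, and
#' `"unknown"` when the placement is unreliable: best-hit identity below
#' `min_identity`, or a second contig scoring within `ambiguity_frac` of
#' the best on a different chromosome or locus (multi-copy genes cannot be
#' placed).
#'
#' @param gene_dna A dna [seq_record()] (or string) for the gene.
#' @param contigs List of dna [seq_record()]s for the reference.
#' @param contig_info data.frame with columns `id`, `chrom`, `offset`
#'   (0-based chromosome offset of each contig's first base).
#' @param interval List or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open chromosome coordinates).
#' @param min_identity Minimum best-hit identity for a confident placement.
#' @param ambiguity_frac Relative score margin under which a second locus
#'   makes the placement ambiguous.
#' @return `"in"`, `"out"` or `"unknown"`.
#' @export
place_in_interval <- function(gene_dna, contigs, contig_info, interval,
                              min_identity = 0.90, ambiguity_frac = 0.01) {
  if (!length(contigs)) return("unknown")
  gene <- as_seq_record(gene_dna, "dna", "gene")
  hits <- lapply(contigs, function(ct) {
    fwd <- align_identity(gene, ct, alphabet = "dna")
    rev_ <- align_identity(
      gene, seq_record(ct$id, revcomp(ct$sequence)), alphabet = "dna")
    best <- if (fwd$score >= rev_$score) list(r = fwd, strand = "+")
            else list(r = rev_, strand = "-")
    L <- nchar(ct$sequence)
    span <- if (best$strand == "+") best$r$span_b
            else c(L - best$r$span_b[2], L - best$r$span_b[1])
    list(id = ct$id, score = best$r$score, identity = best$r$identity,
         mid = mean(span))
  })
  scores <- vapply(hits, `[[`, 0, "score")
  if (max(scores) <= 0) return("unknown")
  best <- which.max(scores)
  if (hits[[best]]$identity < min_identity) return("unknown")
  if (length(hits) > 1L) {
    second <- max(scores[-best])
    if (second >= (1 - ambiguity_frac) * scores[best]) return("unknown")
  }
  ci <- contig_info[match(hits[[best]]$id, contig_info$id), ]
  if (is.na(ci$id[1])) rfl_config_error("contig missing from contig_info")
  pos <- ci$offset + hits[[best]]$mid
  if (ci$chrom == interval$chrom && pos >= interval$start &&
      pos < interval$end) "in" else "out"
}

#' Select candidate restorer orthogroups from a genotype panel
#'
#' Applies the restorer-gene selection logic to clustered RFL orthogroups:
#' a candidate group must (1) have a full-length member in the restoring
#' genotypes (`restorer_fulllength`; all restorers by default, any restorer
#' with `require_all_restorers = FALSE` — the published Rf1 screen started
#' from groups with at least one sequence from an Rf1 accession), (2) have
#' no full-length member in any non-restoring genotype
#' (`nonrestorer_absent`: absent from, or only partial in, maintainers),
#' (3) map inside the genetic interval (`in_interval`), (4) satisfy the
#' provenance rule (`provenance_ok`: an Rf1 group must contain a
#' *T. timopheevii* member, since Rf1 introgressed from that species; an
#' Rf3 group must not contain a *T. timopheevii* member identical to a
#' restorer member, since Rf3 is native to *T. aestivum*), and (5) have at
#' least one restorer member reaching `full_length_min_aa` codons
#' (`length_ok` — the rule that excludes frameshift fragments shorter than
#' 500 aa). The verdict is `"candidate"` iff all rules hold.
#'
#' @param groups data.frame from [greedy_cluster()] with columns
#'   `group_id`, `id`, `genotype`, `status`, `codons`.
#' @param panel data.frame with columns `genotype`, `carries_Rf1`,
#'   `carries_Rf3`, `maintainer`, `is_timopheevii`.
#' @param placements Named character vector `group_id -> in/out/unknown`.
#' @param mode `"Rf1"` or `"Rf3"`.
#' @param sequences Optional named list/character of member protein
#'   sequences, needed for the Rf3 identity-by-descent check.
#' @param full_length_min_aa Codon threshold for `length_ok`.
#' @param require_all_restorers Strict (default) vs any-restorer presence.
#' @return data.frame with one row per group: the five rule columns,
#'   `verdict`, and a semicolon-joined `reasons` column for rejections.
#' @export
select_candidates <- function(groups, panel, placements,
                              mode = c("Rf1", "Rf3"), sequences = NULL,
                              full_length_min_aa = 500L,
                              require_all_restorers = TRUE) {
  mode <- match.arg(mode)
  missing_gt <- setdiff(unique(groups$genotype), panel$genotype)
  if (length(missing_gt))
    rfl_config_error(paste("genotype(s) missing from panel:",
                           paste(missing_gt, collapse = ", ")))
  carries <- panel[[paste0("carries_", mode)]]
  restorers <- panel$genotype[carries]
  nonrestorers <- panel$genotype[!carries & !panel$is_timopheevii]
  timo <- panel$genotype[panel$is_timopheevii]
  out <- lapply(split(groups, groups$group_id), function(g) {
    fl <- g[g$status == "full_length", , drop = FALSE]
    present_fl <- unique(fl$genotype)
    rule_restorer <- if (require_all_restorers)
      all(restorers %in% present_fl) else any(restorers %in% present_fl)
    rule_absent <- !any(nonrestorers %in% present_fl)
    placement <- placements[[g$group_id[1]]] %||% "unknown"
    rule_interval <- identical(placement, "in")
    has_timo <- any(g$genotype %in% timo)
    rule_prov <- if (mode == "Rf1") has_timo else {
      if (!has_timo || is.null(sequences)) TRUE else {
        # disqualify only on a timopheevii member identical (100% over the
        # full shorter length) to a restorer member
        tseq <- sequences[g$id[g$genotype %in% timo]]
        rseq <- sequences[g$id[g$genotype %in% restorers]]
        !any(vapply(tseq, function(ts) any(vapply(rseq, function(rs) {
          r <- align_identity(ts, rs)
          r$identity == 1 && r$unaligned_short == 0L
        }, TRUE)), TRUE))
      }
    }
    rule_length <- any(g$codons[g$genotype %in% restorers] >=
                         full_length_min_aa)
    rules <- c(restorer_fulllength = rule_restorer,
               nonrestorer_absent = rule_absent,
               in_interval = rule_interval,
               provenance_ok = rule_prov,
               length_ok = isTRUE(rule_length))
    data.frame(group_id = g$group_id[1], t(rules),
               verdict = if (all(rules)) "candidate" else "rejected",
               reasons = paste(names(rules)[!rules], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag pairs of partial RFL genes that may be one frameshift-split gene
#'
#' Two partial members of different orthogroups lying on the same contig,
#' on the same strand and within `max_gap` bp of each other are reported as
#' a putative frameshift pair — two pieces of a single broken reading
#' frame, to be treated as one non-functional gene.
#'
#' @param groups data.frame from [greedy_cluster()] with `status`.
#' @param contig_coords data.frame with columns `id`, `contig`, `start`,
#'   `end`, `strand` for (at least) the partial members.
#' @param max_gap Maximum genomic gap in bp.
#' @return data.frame with columns `group_a`, `group_b`, `id_a`, `id_b`,
#'   `contig`.
#' @export
flag_frameshift_pairs <- function(groups, contig_coords, max_gap = 1000L) {
  empty <- data.frame(group_a = character(), group_b = character(),
                      id_a = character(), id_b = character(),
                      contig = character(), stringsAsFactors = FALSE)
  part <- groups[groups$status %in% c("partial", "frameshifted"), ,
                 drop = FALSE]
  part <- merge(part, contig_coords, by = "id")
  if (nrow(part) < 2L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(part) - 1L)) for (j in (i + 1L):nrow(part)) {
    a <- part[i, ]; b <- part[j, ]
    if (a$group_id == b$group_id) next
    if (a$contig != b$contig || a$strand != b$strand) next
    gap <- max(a$start, b$start) - min(a$end, b$end)
    if (gap > max_gap) next
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = a$group_id, group_b = b$group_id, id_a = a$id, id_b = b$id,
      contig = a$contig, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
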