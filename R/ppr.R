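AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# conservative substitution groups used when spreading emission probability
AA_GROUPS <- list(c("I", "L", "V", "M"), c("F", "Y", "W"), c("K", "R"),
                  c("D", "E"), c("S", "T"), c("N", "Q"), c("A", "G"),
                  "C", "H", "P")

#' Build an ungapped log-odds motif model from a consensus
#'
#' Pentatricopeptide-repeat motifs are fixed-length tandem repeats, so the
#' package scans with ungapped position-specific scoring matrices rather
#' than profile HMMs. A model is built from a consensus string by a simple
#' emission mixture: the consensus residue receives probability
#' `p_consensus`, `p_similar` is spread over its conservative substitution
#' group, and the remainder is spread uniformly over all twenty residues.
#' Scores are log2 odds against a uniform background. The shipped default
#' models (see [load_motif_models()]) are synthetic models built this way.
#'
#' @param name Model name (e.g. `"P"`).
#' @param consensus Consensus amino-acid string; its length sets `n_cols`.
#' @param hit_threshold Bit-score threshold for reporting a window.
#' @param p_consensus,p_similar Emission mixture weights.
#' @return An object of class `motif_model` with fields `name`, `n_cols`,
#'   `log_odds` (20 x n_cols), `emission` (20 x n_cols probabilities) and
#'   `hit_threshold`.
#' @export
build_motif_model <- function(name, consensus, hit_threshold = 30,
                              p_consensus = 0.55, p_similar = 0.25) {
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (!all(cons %in% AA20)) rfl_parameter_error("non-standard consensus residue")
  n_cols <- length(cons)
  if (n_cols < 15L) rfl_parameter_error("motif must have >= 15 columns")
  emission <- matrix(0, 20L, n_cols, dimnames = list(AA20, NULL))
  for (j in seq_len(n_cols)) {
    p <- rep((1 - p_consensus - p_similar) / 20, 20)
    names(p) <- AA20
    grp <- AA_GROUPS[[which(vapply(AA_GROUPS, function(g) cons[j] %in% g,
                                   TRUE))]]
    sim <- setdiff(grp, cons[j])
    if (length(sim)) p[sim] <- p[sim] + p_similar / length(sim)
    else p[cons[j]] <- p[cons[j]] + p_similar
    p[cons[j]] <- p[cons[j]] + p_consensus
    emission[, j] <- p / sum(p)
  }
  structure(list(name = name, n_cols = n_cols,
                 log_odds = log2(emission / 0.05),
                 emission = emission,
                 hit_threshold = hit_threshold,
                 consensus = paste(cons, collapse = "")),
            class = "motif_model")
}

#' Write / read a motif model as TSV
#'
#' The matrix is residues x columns with a header row of column indices;
#' model name and threshold travel in `#` comment lines.
#'
#' @param model A `motif_model`.
#' @param path File path.
#' @export
write_motif_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name\t%s", model$name),
               sprintf("# hit_threshold\t%.6g", model$hit_threshold),
               sprintf("# consensus\t%s", model$consensus),
               paste(c("residue", seq_len(model$n_cols)), collapse = "\t")),
             con)
  for (a in AA20)
    writeLines(paste(c(a, sprintf("%.6f", model$log_odds[a, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_motif_model
#' @export
read_motif_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default = NA) {
    hit <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (length(hit)) strsplit(hit[[1]], "\t")[[1]][2] else default
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m <- m[AA20, , drop = FALSE]
  colnames(m) <- NULL
  structure(list(name = get_meta("name", basename(path)),
                 n_cols = ncol(m), log_odds = m,
                 emission = 0.05 * 2^m,
                 hit_threshold = as.numeric(get_meta("hit_threshold", "30")),
                 consensus = get_meta("consensus", "")),
            class = "motif_model")
}

#' Load the shipped PPR motif models
#'
#' Returns the package's default P-, L- and S-class models: synthetic
#' ungapped 35/36/31-column log-odds profiles built with
#' [build_motif_model()] from PPR-style consensus strings. Only the P model
#' matters for RFL classification and code extraction; L and S are provided
#' so PLS-class architectures can be screened.
#'
#' @param dir Directory of model TSVs; defaults to the files shipped with
#'   the package.
#' @return A named list of `motif_model` objects.
#' @export
load_motif_models <- function(dir = system.file("extdata", "ppr_models",
                                                package = "rflscan")) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  models <- lapply(files, read_motif_model)
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Scan a protein for motif-model hits
#'
#' Every window whose summed log-odds reaches the model's threshold is
#' reported, for every model; the list may contain overlapping hits (use
#' [chain_motifs()] to resolve them). `X` residues score 0.
#'
#' The `aa5`/`aa35` columns carry the residues at motif positions 5 and 35
#' (1-based within the motif) — the two positions of the PPR code that
#' determine which RNA base the motif binds. For models shorter than 35
#' columns the final column stands in for position 35.
#'
#' @param protein A protein [seq_record()] or string.
#' @param models A list of `motif_model`s (default: shipped models).
#' @return data.frame with columns `model`, `aa_start`, `aa_end` (0-based
#'   half-open), `score`, `aa5`, `aa35`.
#' @export
scan_motifs <- function(protein, models = load_motif_models()) {
  rec <- as_seq_record(protein, "protein")
  if (inherits(models, "motif_model")) models <- list(models)
  if (length(models) == 0L) rfl_parameter_error("at least one model required")
  aa <- strsplit(rec$sequence, "")[[1]]
  L <- length(aa)
  idx <- match(aa, AA20)            # NA for X / *
  rows <- list()
  for (model in models) {
    n <- model$n_cols
    if (L < n) next
    nw <- L - n + 1L
    tot <- numeric(nw)
    for (j in seq_len(n)) {
      sc <- model$log_odds[cbind(idx[j:(j + nw - 1L)], j)]
      sc[is.na(sc)] <- 0
      tot <- tot + sc
    }
    hit <- which(tot >= model$hit_threshold)
    if (!length(hit)) next
    p5 <- aa[hit + 4L]
    p35 <- aa[hit + min(n, 35L) - 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      model = model$name, aa_start = hit - 1L, aa_end = hit - 1L + n,
      score = tot[hit], aa5 = p5, aa35 = p35, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), aa_start = integer(),
               aa_end = integer(), score = numeric(), aa5 = character(),
               aa35 = character(), stringsAsFactors = FALSE)
  out <- out[order(out$aa_start, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain motif hits into a repeat architecture
#'
#' Selects the non-overlapping subset of hits maximising
#' `sum(score) + adjacency_bonus * n_adjacent`, where `n_adjacent` counts
#' pairs of consecutive chosen hits separated by at most 2 aa. Solved by
#' dynamic programming over hits sorted by start; ties are broken toward the
#' chain with more hits, then toward the smaller total start-coordinate sum.
#' The adjacency bonus reflects that PPR motifs occur in tandem arrays, so
#' runs of adjacent motifs are favoured over isolated high scorers.
#'
#' @param hits A [scan_motifs()] result for one protein.
#' @param adjacency_bonus Bonus (bits) per adjacent chosen pair.
#' @param rfl_min_p Minimum P-motif count for RFL status.
#' @return An object of class `ppr_architecture`: `hits` (chosen subset, in
#'   order), `p_count`, `total_score` (the maximised objective), `is_rfl`,
#'   `tandem_max` (longest run of adjacent chosen P motifs).
#' @export
chain_motifs <- function(hits, adjacency_bonus = 2.0, rfl_min_p = 10L) {
  empty <- function() structure(
    list(hits = hits[0, , drop = FALSE], p_count = 0L, total_score = 0,
         is_rfl = FALSE, tandem_max = 0L),
    class = "ppr_architecture")
  if (is.null(hits) || nrow(hits) == 0L) return(empty())
  hits <- hits[order(hits$aa_start, hits$aa_end), , drop = FALSE]
  n <- nrow(hits)
  # state per hit: best chain ending in that hit
  val <- hits$score
  nh <- rep(1L, n)
  ssum <- hits$aa_start
  parent <- rep(0L, n)
  better <- function(v1, n1, s1, v2, n2, s2) {
    if (v1 != v2) return(v1 > v2)
    if (n1 != n2) return(n1 > n2)
    s1 < s2
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (hits$aa_end[j] > hits$aa_start[i]) next
      bonus <- if (hits$aa_start[i] - hits$aa_end[j] <= 2L) adjacency_bonus else 0
      v <- val[j] + hits$score[i] + bonus
      k <- nh[j] + 1L
      s <- ssum[j] + hits$aa_start[i]
      if (better(v, k, s, val[i], nh[i], ssum[i])) {
        val[i] <- v; nh[i] <- k; ssum[i] <- s; parent[i] <- j
      }
    }
  }
  best <- 1L
  for (i in seq_len(n))
    if (better(val[i], nh[i], ssum[i], val[best], nh[best], ssum[best]))
      best <- i
  chain <- integer()
  i <- best
  while (i > 0L) { chain <- c(i, chain); i <- parent[i] }
  chosen <- hits[chain, , drop = FALSE]
  rownames(chosen) <- NULL
  p_count <- sum(chosen$model == "P")
  # longest run of adjacent P motifs
  tandem_max <- 0L
  run <- 0L
  for (i in seq_len(nrow(chosen))) {
    adj <- i > 1L && chosen$model[i - 1L] == "P" &&
      chosen$aa_start[i] - chosen$aa_end[i - 1L] <= 2L
    run <- if (chosen$model[i] == "P") { if (adj) run + 1L else 1L } else 0L
    tandem_max <- max(tandem_max, run)
  }
  structure(list(hits = chosen, p_count = p_count,
                 total_score = val[best],
                 is_rfl = p_count >= rfl_min_p, tandem_max = tandem_max),
            class = "ppr_architecture")
}

#' @export
print.ppr_architecture <- function(x, ...) {
  cat(sprintf("<ppr_architecture %d motif(s), %d P, score %.1f, %s>\n",
              nrow(x$hits), x$p_count, x$total_score,
              if (x$is_rfl) "RFL" else "not RFL"))
  invisible(x)
}

#' Classify an annotated protein as an RFL gene
#'
#' A protein with at least `rfl_min_p` P-class motifs is an RFL. Status is
#' `full_length` when the protein starts with M, has no internal stop, and
#' reaches `full_length_min_aa` sense codons; `partial` when shorter than
#' `full_length_min_aa`; `truncated` when long enough but failing the
#' full-length requirements, or when orthogroup context
#' (`orthogroup_max_codons`) shows the protein ends at least 35 aa short of
#' its group's longest member with its C-terminal motif running into the
#' premature end; `frameshifted` when the caller flags the gene as one half
#' of a split reading frame (see [flag_frameshift_pairs()]).
#'
#' @param arch The [chain_motifs()] architecture of `protein`.
#' @param protein The protein [seq_record()] or string.
#' @param rfl_min_p Minimum P-motif count for RFL status.
#' @param full_length_min_aa Minimum codon count for full-length status.
#' @param orthogroup_max_codons Optional codon count of the longest
#'   orthogroup member, enabling relative truncation calls.
#' @param frameshifted Set `TRUE` when external evidence marks the gene as a
#'   frameshift fragment.
#' @return A list with `is_rfl`, `status`, `codons`, `p_count`.
#' @export
classify_rfl <- function(arch, protein, rfl_min_p = 10L,
                         full_length_min_aa = 500L,
                         orthogroup_max_codons = NULL,
                         frameshifted = FALSE) {
  rec <- as_seq_record(protein, "protein")
  p <- sub("\\*$", "", rec$sequence)
  codons <- nchar(p)
  internal_stop <- grepl("*", p, fixed = TRUE)
  is_rfl <- arch$p_count >= rfl_min_p
  status <- if (frameshifted) "frameshifted"
  else if (codons < full_length_min_aa) "partial"
  else if (internal_stop || !startsWith(p, "M") || !is_rfl) "truncated"
  else {
    premature <- !is.null(orthogroup_max_codons) &&
      codons <= orthogroup_max_codons - 35L
    cterm_cut <- nrow(arch$hits) > 0L &&
      max(arch$hits$aa_end) >= codons - 35L
    if (premature && cterm_cut) "truncated" else "full_length"
  }
  list(is_rfl = is_rfl, status = status, codons = codons,
       p_count = arch$p_count)
}

#' Extract the PPR code pairs of an architecture
#'
#' One (aa5, aa35) pair per P-class motif, N-terminal to C-terminal. These
#' two residues per repeat constitute the PPR code that determines RNA-base
#' recognition; position indexing is 1-based within the motif (off-by-one
#' here would corrupt all downstream binding-site predictions).
#'
#' @param arch A [chain_motifs()] architecture.
#' @param protein The protein it came from.
#' @return data.frame with columns `motif` (1-based index among P motifs),
#'   `aa5`, `aa35`.
#' @export
extract_code_pairs <- function(arch, protein) {
  rec <- as_seq_record(protein, "protein")
  hp <- arch$hits[arch$hits$model == "P", , drop = FALSE]
  if (nrow(hp) && max(hp$aa_end) > nchar(rec$sequence))
    rfl_bounds_error("motif hit extends past protein end")
  aa <- strsplit(rec$sequence, "")[[1]]
  data.frame(motif = seq_len(nrow(hp)),
             aa5 = aa[hp$aa_start + 5L],
             aa35 = aa[hp$aa_start + pmin(hp$aa_end - hp$aa_start, 35L)],
             stringsAsFactors = FALSE)
}

#' Annotate one protein end-to-end
#'
#' Convenience wrapper: [scan_motifs()] then [chain_motifs()] then
#' [classify_rfl()] and [extract_code_pairs()].
#'
#' @inheritParams scan_motifs
#' @inheritParams classify_rfl
#' @param adjacency_bonus Passed to [chain_motifs()].
#' @return A list with `architecture`, `is_rfl`, `status`, `codons`,
#'   `p_count`, `code_pairs`.
#' @export
annotate_protein <- function(protein, models = load_motif_models(),
                             adjacency_bonus = 2.0, rfl_min_p = 10L,
                             full_length_min_aa = 500L,
                             orthogroup_max_codons = NULL) {
  rec <- as_seq_record(protein, "protein")
  arch <- chain_motifs(scan_motifs(rec, models), adjacency_bonus, rfl_min_p)
  cls <- classify_rfl(arch, rec, rfl_min_p, full_length_min_aa,
                      orthogroup_max_codons)
  c(list(architecture = arch, code_pairs = extract_code_pairs(arch, rec)),
    cls)
}
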