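# Seed hygiene: every generator evaluates under its own seed and restores
# the caller's RNG state, so generators are pure functions of (params, seed)
# and never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
# one fixed codon per amino acid, for deterministic back-translation
CODON1 <- vapply(split(SENSE_CODONS,
                       as.character(Biostrings::GENETIC_CODE[SENSE_CODONS])),
                 `[[`, "", 1L)

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(CODON1[aa], collapse = "")
}

sample_motif <- function(model) {
  paste(vapply(seq_len(model$n_cols), function(j)
    sample(AA20, 1L, prob = model$emission[, j]), ""), collapse = "")
}

# Substitution-only mutation with an exact substitution count, so
# within-family identity is controlled (guaranteed), not merely expected:
# two members mutated at floor(rate * n) sites each sit at pairwise
# identity >= 1 - 2 * rate deterministically. The generator passes half
# the divergence budget per member to honour a within-family identity
# target.
mutate_protein <- function(p, rate) {
  aa <- strsplit(p, "")[[1]]
  n_mut <- min(length(aa) - 1L, floor(rate * length(aa)))
  hit <- sample(2:length(aa), n_mut)    # keep the initiator M
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

#' The default genotype panel
#'
#' Eight wheat accessions and one *T. timopheevii* line with their
#' restorer phenotypes: Rf1 carriers (R197, R0932E, R0934F and
#' *T. timopheevii*, the Rf1 donor species), Rf3 carriers (Primepi,
#' R0946E, R0934F) and maintainers (Anapurna, Fielder). Weak-restorer
#' accessions are deliberately not included by default; users deciding how
#' to treat them can pass their own panel table.
#'
#' @return data.frame with columns `genotype`, `carries_Rf1`,
#'   `carries_Rf3`, `maintainer`, `is_timopheevii`.
#' @export
default_panel <- function() {
  data.frame(
    genotype = c("R197", "R0932E", "R0934F", "R0946E", "Primepi",
                 "Anapurna", "Fielder", "Ttimopheevii"),
    carries_Rf1 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    carries_Rf3 = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    maintainer = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    is_timopheevii = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                       TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-genotype RFL capture panel with planted orthogroups
#'
#' Builds `n_families` RFL paralog families. Each family founder is a
#' PPR-array protein: an initiator M, a random N-terminal leader, 17-20
#' planted 35-aa P-motifs drawn from the shipped P model, and a C-tail,
#' totalling 741-790 codons — the size and repeat count of full-length
#' RFL proteins. Genotype members are substitution-only mutated copies of
#' the founder at `1 - within_id` per-residue rate, so within-family
#' identity stays above the clustering threshold while independent
#' founders keep between-family identity far below it. The
#' `restorer_specific` family is full-length only in genotypes carrying
#' the restorer gene for `mode` (it is the planted Rf candidate); in other
#' genotypes it is absent or, with probability `truncation_rate`, present
#' as a truncated fragment. Setting `frameshift_family` replaces that
#' family's full-length members by two partial halves placed 200 bp apart
#' on one contig, emulating a reading frame split by a frameshift.
#'
#' @param seed Integer seed; outputs are a pure function of (params, seed).
#' @param n_families Number of paralog families (the planted one included).
#' @param panel Genotype phenotype table, as [default_panel()].
#' @param mode Which restorer gene the planted family restores.
#' @param within_id Within-family protein identity (must exceed
#'   `identity_threshold`).
#' @param between_id Upper bound on between-family identity (must be below
#'   `identity_threshold`; independent founders land far below it).
#' @param identity_threshold The clustering threshold the panel is built
#'   around.
#' @param restorer_specific Index of the planted restorer-specific family.
#' @param truncation_rate Probability that a non-restorer genotype carries
#'   a truncated (rather than absent) copy of the planted family.
#' @param frameshift_family Optional family index to emit as a frameshift
#'   pair.
#' @param models Motif models used to build the founders.
#' @return List with `proteins` (list of [seq_record()]), `dna`, `meta`
#'   (id, genotype, family, codons, status_truth), `panel`,
#'   `contig_coords` (for frameshift halves), and `truth` (`partition`,
#'   `restorer_family`, `motif_counts`).
#' @export
simulate_rfl_panel <- function(seed, n_families = 21L,
                               panel = default_panel(),
                               mode = c("Rf1", "Rf3"),
                               within_id = 0.98, between_id = 0.90,
                               identity_threshold = 0.96,
                               restorer_specific = 1L,
                               truncation_rate = 0.3,
                               frameshift_family = NULL,
                               models = load_motif_models()) {
  mode <- match.arg(mode)
  if (!(within_id > identity_threshold && identity_threshold > between_id))
    rfl_parameter_error("need within_id > identity_threshold > between_id")
  pmod <- models[["P"]]
  restorers <- panel$genotype[panel[[paste0("carries_", mode)]]]
  with_seed(seed, {
    proteins <- list(); dna <- list(); meta_rows <- list(); cc_rows <- list()
    motif_counts <- integer(n_families)
    for (f in seq_len(n_families)) {
      n_mot <- sample(17:20, 1L)
      target <- sample(max(741L, 35L * n_mot + 40L):790L, 1L)
      extras <- target - 35L * n_mot
      leader_len <- max(10L, round(0.45 * extras)) - 1L
      tail_len <- target - 1L - leader_len - 35L * n_mot
      founder <- paste0(
        "M", paste(sample(AA20, leader_len, TRUE), collapse = ""),
        paste(vapply(seq_len(n_mot), function(i) sample_motif(pmod), ""),
              collapse = ""),
        paste(sample(AA20, tail_len, TRUE), collapse = ""))
      motif_counts[f] <- n_mot
      fam <- sprintf("fam%02d", f)
      for (g in panel$genotype) {
        is_restorer <- g %in% restorers
        planted <- f == restorer_specific
        if (planted && !is_restorer) {
          if (stats::runif(1) >= truncation_rate) next    # absent
          frag_len <- sample(300:450, 1L)
          p <- substr(mutate_protein(founder, (1 - within_id) / 2), 1L, frag_len)
          status <- "partial"
          id <- sprintf("%s_%s", fam, g)
          proteins[[id]] <- seq_record(id, p, "protein")
          dna[[id]] <- seq_record(id, back_translate(p), "dna")
          meta_rows[[id]] <- data.frame(
            id = id, genotype = g, family = fam, codons = nchar(p),
            status_truth = status, stringsAsFactors = FALSE)
          next
        }
        p <- mutate_protein(founder, (1 - within_id) / 2)
        if (!is.null(frameshift_family) && f == frameshift_family) {
          half <- nchar(p) %/% 2L
          parts <- c(substr(p, 1L, half),
                     paste0("M", substr(p, half + 1L, nchar(p))))
          contig <- sprintf("%s_ctg_%s", g, fam)
          for (h in 1:2) {
            id <- sprintf("%s%s_%s", fam, c("a", "b")[h], g)
            proteins[[id]] <- seq_record(id, parts[h], "protein")
            dna[[id]] <- seq_record(id, back_translate(parts[h]), "dna")
            s <- if (h == 1L) 0L else 3L * half + 200L
            cc_rows[[id]] <- data.frame(
              id = id, contig = contig, start = s,
              end = s + 3L * nchar(parts[h]), strand = "+",
              stringsAsFactors = FALSE)
            meta_rows[[id]] <- data.frame(
              id = id, genotype = g, family = paste0(fam, c("a", "b")[h]),
              codons = nchar(parts[h]), status_truth = "frameshifted",
              stringsAsFactors = FALSE)
          }
          next
        }
        id <- sprintf("%s_%s", fam, g)
        proteins[[id]] <- seq_record(id, p, "protein")
        dna[[id]] <- seq_record(id, back_translate(p), "dna")
        meta_rows[[id]] <- data.frame(
          id = id, genotype = g, family = fam, codons = nchar(p),
          status_truth = "full_length", stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, meta_rows)
    rownames(meta) <- NULL
    contig_coords <- if (length(cc_rows)) do.call(rbind, cc_rows) else
      data.frame(id = character(), contig = character(), start = integer(),
                 end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    rownames(contig_coords) <- NULL
    list(proteins = proteins, dna = dna, meta = meta, panel = panel,
         contig_coords = contig_coords,
         truth = list(partition = stats::setNames(meta$family, meta$id),
                      restorer_family = sprintf("fam%02d", restorer_specific),
                      motif_counts = motif_counts,
                      seed = seed))
  })
}

#' Simulate a genome pair differing by a chimeric ORF
#'
#' Builds a random mitochondrial-like base genome carrying a donor CDS
#' (an atp8-like conserved gene). `genome_b` keeps the donor intact;
#' `genome_a` replaces everything from codon `prefix_codons + 1` onward
#' with a unique, hydrophobic-biased extension ending in a stop, forming a
#' single chimeric ORF of `prefix_codons + unique_len_nt/3 - 1` sense
#' codons. All other positions are identical, so the 5' flank (promoter /
#' UTR context) of the chimera matches the donor's. An in-frame stop is
#' planted immediately upstream of the start codon so the between-stop ORF
#' is exactly the CDS. Defaults reproduce the geometry of a 96-codon
#' donor prefix plus a 552-nt unique region (a 279-sense-codon chimera).
#'
#' @param seed Integer seed.
#' @param base_len Genome length (nt).
#' @param donor_codons Sense codons of the donor CDS.
#' @param prefix_codons Donor codons shared by the chimera.
#' @param unique_len_nt Length of the chimera-specific region, including
#'   its stop codon; must be a positive multiple of 3.
#' @param strand Strand the genes are placed on in genome coordinates.
#' @return List with `genome_a`, `genome_b`, `donor_cds`, `donor_flank`
#'   and `truth` (`prefix_codons`, `unique_start`, `unique_end`,
#'   `orf_start`, `orf_end`, `orf_codons`, `strand`).
#' @export
simulate_chimeric_genomes <- function(seed, base_len = 12000L,
                                      donor_codons = 147L,
                                      prefix_codons = 96L,
                                      unique_len_nt = 552L,
                                      strand = "+") {
  if (unique_len_nt %% 3L != 0L || unique_len_nt < 3L)
    rfl_parameter_error("unique_len_nt must be a positive multiple of 3")
  if (prefix_codons > donor_codons)
    rfl_parameter_error("prefix longer than the donor CDS")
  orf_codons <- prefix_codons + unique_len_nt %/% 3L - 1L
  need <- 3L + 3L * max(donor_codons + 1L, orf_codons + 1L) + 200L
  if (need > base_len)
    rfl_parameter_error("genes do not fit in base_len")
  with_seed(seed, {
    sense <- function(n) paste(sample(SENSE_CODONS, n, TRUE), collapse = "")
    hydrophobic <- c("A", "V", "L", "I", "F", "M", "W")
    hydro_codons <- SENSE_CODONS[
      as.character(Biostrings::GENETIC_CODE[SENSE_CODONS]) %in% hydrophobic]
    donor <- paste0("ATG", sense(donor_codons - 1L))
    # the chimera ends in its own stop codon, distinct from the donor's
    # (TAG vs TAA), so the whole extension including the stop is genuinely
    # absent from genome_b; the first unique base is forced to differ from
    # the donor's next base so the planted boundary is unambiguous under
    # exact-match anchor extension
    unique_seq <- paste0(
      paste(sample(c(hydro_codons, SENSE_CODONS), unique_len_nt %/% 3L - 1L,
                   TRUE), collapse = ""), "TAG")
    donor_next <- substr(donor, 3L * prefix_codons + 1L,
                         3L * prefix_codons + 1L)
    if (donor_next == "") donor_next <- "T"      # donor stop follows
    if (substr(unique_seq, 1L, 1L) == donor_next) {
      repl <- sample(SENSE_CODONS[substr(SENSE_CODONS, 1L, 1L) !=
                                    donor_next], 1L)
      unique_seq <- paste0(repl, substr(unique_seq, 4L, nchar(unique_seq)))
    }
    chimera <- paste0(substr(donor, 1L, 3L * prefix_codons), unique_seq)
    donor_full <- paste0(donor, "TAA")
    pos <- round(base_len * 0.4)             # 0-based insertion point
    left <- random_dna(pos - 3L)
    right <- random_dna(base_len - pos - max(nchar(donor_full),
                                             nchar(chimera)))
    mk <- function(cds) paste0(left, "TAG", cds, right)
    ga <- mk(chimera); gb <- mk(donor_full)
    donor_flank <- substr(gb, max(1L, pos - 499L), pos)
    orf_start <- pos; orf_end <- pos + 3L * orf_codons
    u_start <- pos + 3L * prefix_codons
    u_end <- orf_end + 3L                    # includes the stop codon
    if (strand == "-") {
      La <- nchar(ga)
      ga <- revcomp(ga); gb <- revcomp(gb)
      tmp <- c(La - orf_end, La - orf_start)
      orf_start <- tmp[1]; orf_end <- tmp[2]
      tmp <- c(La - u_end, La - u_start)
      u_start <- tmp[1]; u_end <- tmp[2]
    }
    list(genome_a = seq_record("mt_A", ga),
         genome_b = seq_record("mt_B", gb),
         donor_cds = seq_record("atp8", donor_full),
         donor_flank = donor_flank,
         truth = list(prefix_codons = prefix_codons,
                      unique_start = u_start, unique_end = u_end,
                      unique_len_nt = u_end - u_start,
                      orf_start = orf_start, orf_end = orf_end,
                      orf_codons = orf_codons, strand = strand,
                      seed = seed))
  })
}

#' Simulate a PPR protein / target transcript pair
#'
#' Samples `pairs_n` code pairs from the table's known combinations,
#' plants them at positions 5 and 35 of `pairs_n` tandem P motifs in a
#' synthetic protein, and embeds the pairs' argmax base string — the
#' highest-scoring possible window — at a random position in an otherwise
#' random transcript.
#'
#' @param seed Integer seed.
#' @param pairs_n Number of motifs / site length in nt.
#' @param transcript_len Transcript length (nt).
#' @param table A [read_code_table()] table.
#' @param models Motif models for the protein construction.
#' @return List with `protein`, `transcript` ([seq_record()]s), and
#'   `truth` (`pairs`, `site_start`, `site_end`).
#' @export
simulate_ppr_target <- function(seed, pairs_n = 20L, transcript_len = 1000L,
                                table = default_code_table(),
                                models = load_motif_models()) {
  pmod <- models[["P"]]
  with_seed(seed, {
    combos <- names(table$scores)
    pick <- sample(combos, pairs_n, TRUE)
    pairs <- data.frame(aa5 = substr(pick, 1L, 1L),
                        aa35 = substr(pick, 2L, 2L),
                        stringsAsFactors = FALSE)
    motifs <- vapply(seq_len(pairs_n), function(i) {
      m <- strsplit(sample_motif(pmod), "")[[1]]
      m[5L] <- pairs$aa5[i]; m[35L] <- pairs$aa35[i]
      paste(m, collapse = "")
    }, "")
    protein <- paste0(
      "M", paste(sample(AA20, 59L, TRUE), collapse = ""),
      paste(motifs, collapse = ""),
      paste(sample(AA20, 50L, TRUE), collapse = ""))
    site <- paste(vapply(seq_len(pairs_n), function(i) {
      aff <- code_affinity(table, pairs$aa5[i], pairs$aa35[i])
      c("A", "C", "G", "T")[which.max(aff)]
    }, ""), collapse = "")
    for (attempt in 1:20) {
      start <- sample(100:(transcript_len - pairs_n - 100L), 1L)
      tx <- paste0(random_dna(start), site,
                   random_dna(transcript_len - start - pairs_n))
      top <- scan_transcript(pairs, tx, table, top_n = 2L)
      if (top$start[1] == start &&
          (nrow(top) < 2L || top$total[1] > top$total[2])) break
    }
    list(protein = seq_record("rfl_sim", protein, "protein"),
         transcript = seq_record("target_sim", tx),
         truth = list(pairs = pairs, site_start = start,
                      site_end = start + pairs_n, seed = seed))
  })
}

#' Simulate strand-specific coverage with a planted cleavage transition
#'
#' For each genotype the fertile (restored) track has Poisson-distributed
#' depth with mean `depth / fold` 5' of the planted cleavage position and
#' `depth` 3' of it — the signature of transcript cleavage followed by
#' degradation of the 5' product — while the sterile track is flat
#' Poisson at `depth`.
#'
#' @param seed Integer seed.
#' @param ref_len Reference length (nt).
#' @param cleavage_pos Named vector of planted positions (0-based genome
#'   coordinates), one per genotype; the default plants two restorer
#'   classes 110 nt apart.
#' @param depth Mean sterile / 3'-fertile depth.
#' @param fold Depth ratio across the transition.
#' @param masks Optional mask matrix applied to all tracks.
#' @param strand Transcript strand (5'/3' orientation in genome coords).
#' @return List of per-genotype lists (`fertile`, `sterile` raw
#'   [coverage_track()]s) plus `truth`.
#' @export
simulate_coverage <- function(seed, ref_len = 6000L,
                              cleavage_pos = c(Rf1 = 2800L, Rf3 = 2910L),
                              depth = 100, fold = 5, masks = NULL,
                              strand = "+") {
  with_seed(seed, {
    out <- list()
    for (g in names(cleavage_pos)) {
      p <- cleavage_pos[[g]]
      mean_f <- rep(depth, ref_len)
      if (strand == "+") {
        if (p > 0L) mean_f[seq_len(p)] <- depth / fold        # 5' low
      } else {
        if (p < ref_len) mean_f[(p + 1L):ref_len] <- depth / fold
      }
      out[[g]] <- list(
        fertile = coverage_track("ref", strand,
                                 stats::rpois(ref_len, mean_f), masks),
        sterile = coverage_track("ref", strand,
                                 stats::rpois(ref_len, depth), masks))
    }
    out$truth <- list(cleavage_pos = as.list(cleavage_pos),
                      strand = strand, depth = depth, fold = fold,
                      seed = seed)
    out
  })
}

#' Simulate an expression count matrix with genotype x stage structure
#'
#' Negative-binomial counts for a fertile/sterile anther time course:
#' baseline means are log-normal, planted gene blocks are up- or
#' down-regulated in fertile samples by `effect_size`, and per-sample
#' library-size multipliers are planted for size-factor recovery tests.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param design data.frame with columns `sample`, `fertile` (logical) and
#'   optionally `stage`; defaults to three fertile restorer genotypes and
#'   one sterile line across three anther stages.
#' @param effect_size Fold change of the planted blocks (1 = no effect).
#' @param dispersion Negative-binomial dispersion.
#' @param frac_up,frac_down Fractions of genes planted up/down in fertile.
#' @param lib_range Range of planted library-size multipliers.
#' @return List with `counts` (a [count_matrix()]), `design`, and `truth`
#'   (`lib_factors`, `up_genes`, `down_genes`).
#' @export
simulate_counts <- function(seed, n_genes = 500L, design = NULL,
                            effect_size = 4, dispersion = 0.1,
                            frac_up = 0.1, frac_down = 0.1,
                            lib_range = c(0.5, 2)) {
  if (is.null(design)) {
    gt <- c("Rf1", "Rf3", "Rf1Rf3", "CMS")
    design <- expand.grid(genotype = gt, stage = c("A", "B", "C"),
                          stringsAsFactors = FALSE)
    design$sample <- paste(design$genotype, design$stage, sep = "_")
    design$fertile <- design$genotype != "CMS"
  }
  with_seed(seed, {
    base <- exp(stats::rnorm(n_genes, mean = 4, sd = 1.2))
    n_up <- round(frac_up * n_genes); n_down <- round(frac_down * n_genes)
    up <- seq_len(n_up)
    down <- seq.int(n_up + 1L, n_up + n_down)
    lib <- stats::runif(nrow(design), lib_range[1], lib_range[2])
    m <- matrix(0, n_genes, nrow(design))
    for (j in seq_len(nrow(design))) {
      mu <- base
      if (design$fertile[j]) {
        mu[up] <- mu[up] * effect_size
        mu[down] <- mu[down] / effect_size
      }
      m[, j] <- stats::rnbinom(n_genes, mu = mu * lib[j],
                               size = 1 / dispersion)
    }
    rownames(m) <- sprintf("gene%04d", seq_len(n_genes))
    colnames(m) <- design$sample
    lens <- sample(500:3000, n_genes, TRUE)
    list(counts = count_matrix(m, lens), design = design,
         truth = list(lib_factors = stats::setNames(lib, design$sample),
                      up_genes = rownames(m)[up],
                      down_genes = rownames(m)[down], seed = seed))
  })
}

#' Write a generator's planted-truth sidecar as JSON
#'
#' @param truth The `truth` element of any generator's output.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
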