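#' Sequence records
#'
#' A `seq_record` is the package's light container for a single nucleotide or
#' protein sequence: an id, an optional free-text description, the sequence
#' string and its alphabet. Sequences are canonicalised on construction:
#' lowercase is folded to uppercase and, for DNA, `U` becomes `T` so that
#' transcript (RNA) input and genomic input behave identically everywhere
#' downstream. `N` is allowed in DNA and `X`/`*` in protein; both score
#' neutrally in motif and alignment code.
#'
#' @param id Non-empty record identifier.
#' @param sequence Sequence string.
#' @param alphabet `"dna"` or `"protein"`.
#' @param description Optional description (text after the id on the FASTA
#'   header line).
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("a", "acgu")$sequence  # "ACGT"
#' @export
seq_record <- function(id, sequence, alphabet = c("dna", "protein"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    rfl_format_error("record id must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  if (alphabet == "dna") {
    sequence <- gsub("U", "T", sequence, fixed = TRUE)
    bad <- gsub("[ACGTN]", "", sequence)
  } else {
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX*]", "", sequence)
  }
  if (nzchar(bad))
    rfl_format_error(sprintf(
      "invalid %s characters in record '%s': %s", alphabet, id,
      paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  structure(
    list(id = id, description = as.character(description),
         sequence = sequence, alphabet = alphabet),
    class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<seq_record %s [%s, %d %s] %s>\n", x$id, x$alphabet,
              nchar(x$sequence), if (x$alphabet == "dna") "nt" else "aa", s))
  invisible(x)
}

#' @keywords internal
as_seq_record <- function(x, alphabet = "dna", id = "seq") {
  if (inherits(x, "seq_record")) return(x)
  seq_record(id, x, alphabet)
}

#' Read a multi-record FASTA file
#'
#' Sequences are canonicalised as in [seq_record()]. An empty file yields an
#' empty list; sequence data appearing before any `>` header is a format
#' error.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list of [seq_record()] objects, one per header.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) rfl_format_error(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  if (!startsWith(lines[[1]], ">"))
    rfl_format_error("sequence data before any FASTA header")
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- ids[[i]]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    out[[i]] <- seq_record(id, as.character(set[[i]]), alphabet, desc)
  }
  dup <- duplicated(vapply(out, `[[`, "", "id"))
  if (any(dup))
    rfl_format_error(paste("duplicate record ids:",
                           paste(vapply(out[dup], `[[`, "", "id"),
                                 collapse = ", ")))
  out
}

#' Write sequence records to FASTA
#'
#' Output is bit-stable given identical inputs. Round-trips with
#' [read_fasta()] preserve sequence content exactly.
#'
#' @param records A list of [seq_record()] objects (or a single record).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, `[[`, "", "sequence")
  hdr <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Strand-specific per-base coverage tracks
#'
#' Holds one strand's read depth along a reference, together with mask
#' intervals (e.g. rRNA or plastid-identical regions excluded from
#' normalisation). Coordinates are 0-based half-open throughout. When
#' `normalised` is `TRUE` the mean depth over unmasked positions is 1 and
#' `scale` retains the pre-normalisation mean so raw-depth checks remain
#' possible downstream.
#'
#' @param ref_id Reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param depth Numeric vector of non-negative per-base depths, one entry per
#'   reference position.
#' @param masks A two-column matrix (start, end) of 0-based half-open mask
#'   intervals, or `NULL`.
#' @param normalised Whether the track has been normalised to unmasked mean 1.
#' @param scale Pre-normalisation unmasked mean depth (`NA` for raw tracks).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(ref_id, strand, depth, masks = NULL,
                           normalised = FALSE, scale = NA_real_) {
  if (!strand %in% c("+", "-")) rfl_format_error("strand must be '+' or '-'")
  depth <- as.numeric(depth)
  if (any(depth < 0)) rfl_format_error("negative depth value")
  masks <- normalize_masks(masks, length(depth))
  structure(list(ref_id = ref_id, strand = strand, depth = depth,
                 masks = masks, normalised = normalised, scale = scale),
            class = "coverage_track")
}

#' @keywords internal
normalize_masks <- function(masks, ref_len) {
  if (is.null(masks) || (is.matrix(masks) && nrow(masks) == 0L))
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  masks <- matrix(as.integer(masks), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(masks[, 1] < 0L) || any(masks[, 2] > ref_len) ||
      any(masks[, 1] >= masks[, 2]))
    rfl_bounds_error("mask interval out of bounds")
  masks
}

#' @keywords internal
mask_logical <- function(track) {
  m <- rep(FALSE, length(track$depth))
  msk <- track$masks
  if (nrow(msk)) for (i in seq_len(nrow(msk)))
    m[(msk[i, 1] + 1L):msk[i, 2]] <- TRUE
  m
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track %s(%s) %d bp, %d mask(s), %s>\n",
              x$ref_id, x$strand, length(x$depth), nrow(x$masks),
              if (x$normalised) "normalised" else "raw"))
  invisible(x)
}

#' Read a 4-column bedGraph file into a coverage track
#'
#' Positions not covered by any interval get depth 0. Overlapping intervals
#' are resolved last-wins with a warning. Intervals extending past `ref_len`
#' are a bounds error; negative values are a format error.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value; 0-based
#'   half-open).
#' @param ref_len Reference length in bp.
#' @param strand Strand the track describes.
#' @param ref_id Reference name; defaults to the first chrom in the file.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, ref_len, strand, ref_id = NULL) {
  if (!file.exists(path)) rfl_format_error(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) &
                 !startsWith(trimws(lines), "#") &
                 !startsWith(trimws(lines), "track")]
  depth <- numeric(ref_len)
  if (length(lines) == 0L)
    return(coverage_track(ref_id %||% "ref", strand, depth))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    rfl_format_error("bedGraph line with fewer than 4 columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end   <- as.integer(vapply(parts, `[[`, "", 3L))
  value <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (anyNA(start) || anyNA(end) || anyNA(value))
    rfl_format_error("unparseable bedGraph coordinates or value")
  if (any(value < 0)) rfl_format_error("negative bedGraph value")
  if (any(end > ref_len) || any(start < 0L))
    rfl_bounds_error("bedGraph interval outside [0, ref_len)")
  if (any(start >= end)) rfl_format_error("bedGraph interval with start >= end")
  covered <- logical(ref_len)
  overlapped <- FALSE
  for (i in seq_along(start)) {
    idx <- (start[i] + 1L):end[i]
    if (any(covered[idx])) overlapped <- TRUE
    covered[idx] <- TRUE
    depth[idx] <- value[i]       # last-wins
  }
  if (overlapped) warning("overlapping bedGraph intervals: last value wins")
  coverage_track(ref_id %||% chrom[[1L]], strand, depth)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted (they are implied by [read_bedgraph()]'s
#' uncovered-means-zero rule), so write/read round-trips reproduce the depth
#' vector exactly. Output is bit-stable.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", track$ref_id, start[keep], end[keep],
                   vapply(r$values[keep], function(v) sprintf("%.10g", v), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Genomic features
#'
#' Internal feature representation: 0-based half-open coordinates on the
#' forward strand plus a strand flag. [read_gff3()]/[write_gff3()] convert
#' to and from GFF3's 1-based inclusive convention; the conversion is an
#' exact bijection.
#'
#' @param seq_id Reference sequence name.
#' @param start,end 0-based half-open span.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param type Feature type (e.g. `"gene"`, `"CDS"`).
#' @param attributes Named character vector of GFF3 attributes.
#' @param source,score,frame Remaining GFF3 columns.
#' @return An object of class `feature`.
#' @export
feature <- function(seq_id, start, end, strand = ".", type = "region",
                    attributes = character(), source = ".", score = ".",
                    frame = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    rfl_format_error("feature requires 0 <= start < end")
  if (!strand %in% c("+", "-", "."))
    rfl_format_error(paste("unknown strand symbol:", strand))
  if (type %in% c("gene", "CDS") && strand == ".")
    rfl_format_error(paste("strand required for", type, "features"))
  structure(list(seq_id = seq_id, source = source, type = type,
                 start = start, end = end, score = score, strand = strand,
                 frame = frame, attributes = attributes),
            class = "feature")
}

#' Read a GFF3 feature table
#'
#' Only the 9-column tabular subset is supported; `##` directives and
#' comments are skipped. 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A list of [feature()] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) rfl_format_error(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      rfl_format_error(sprintf("GFF3 line %d does not have 9 columns", i))
    start1 <- suppressWarnings(as.integer(f[4])); end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1))
      rfl_format_error(sprintf("GFF3 line %d: unparseable coordinates", i))
    if (start1 > end1)
      rfl_format_error(sprintf("GFF3 line %d: start > end", i))
    attrs <- character()
    if (f[9] != ".") {
      kv <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      kv <- kv[lengths(kv) == 2L]
      attrs <- stats::setNames(vapply(kv, `[[`, "", 2L),
                               vapply(kv, `[[`, "", 1L))
    }
    out[[i]] <- feature(seq_id = f[1], source = f[2], type = f[3],
                        start = start1 - 1L, end = end1, score = f[6],
                        strand = f[7], frame = f[8], attributes = attrs)
  }
  out
}

#' Write features as GFF3
#'
#' @param features List of [feature()] objects.
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3", vapply(features, function(f) {
    attrs <- if (length(f$attributes))
      paste(names(f$attributes), f$attributes, sep = "=", collapse = ";")
    else "."
    sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s", f$seq_id, f$source, f$type,
            f$start + 1L, f$end, f$score, f$strand, f$frame, attrs)
  }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Expression count matrices
#'
#' @param counts Non-negative numeric matrix, transcripts in rows (named),
#'   samples in columns (named).
#' @param lengths Per-transcript lengths in nt, positive, in row order.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `lengths`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  lengths <- as.numeric(lengths)
  if (length(lengths) != nrow(counts))
    rfl_format_error("one length per transcript required")
  if (any(counts < 0)) rfl_format_error("negative counts")
  if (any(lengths <= 0)) rfl_format_error("transcript lengths must be > 0")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  names(lengths) <- rownames(counts)
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' Read a counts TSV (genes x samples plus a length column)
#'
#' @param path TSV with header; first column transcript id, a `length`
#'   column, remaining columns samples.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"length" %in% names(df))
    rfl_format_error("counts table requires a 'length' column")
  ids <- df[[1]]
  lens <- df[["length"]]
  samp <- setdiff(names(df)[-1], "length")
  m <- as.matrix(df[, samp, drop = FALSE])
  rownames(m) <- ids
  count_matrix(m, lens)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
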