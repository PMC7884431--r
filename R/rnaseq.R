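#' Median-of-ratios (pseudoreference) size factors
#'
#' For each gene with all-positive counts the pseudoreference is the
#' geometric mean of its counts across samples; each sample's size factor
#' is the median over those genes of count / pseudoreference. This is the
#' pseudoreference normalisation popularised by DESeq2; the test suite
#' cross-checks the implementation against
#' `DESeq2::estimateSizeFactorsForMatrix`.
#'
#' @param cm A [count_matrix()] (or plain counts matrix).
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(m) < 2L) rfl_parameter_error("at least two samples required")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    rfl_parameter_error(
      "no gene has positive counts in every sample; filter low-count genes")
  lg <- log(m[pos, , drop = FALSE])
  pseudo <- exp(rowMeans(lg))
  apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / pseudo))
}

#' Transcripts-per-million normalisation
#'
#' `rate = count / length`; TPM is the rate rescaled so each sample column
#' sums to one million.
#'
#' @param cm A [count_matrix()] with per-transcript lengths.
#' @return Matrix of TPM values, same dimensions as the counts.
#' @export
tpm <- function(cm) {
  if (!inherits(cm, "count_matrix"))
    rfl_type_error("a count_matrix (with lengths) is required")
  rate <- cm$counts / cm$lengths
  sweep(rate, 2, colSums(rate), function(r, s) 1e6 * r / s)
}

#' Fertile/sterile log-ratio matrix with hierarchical gene ordering
#'
#' For each (fertile sample, sterile sample) contrast — typically matched
#' by developmental stage — computes
#' `log2((norm_fertile + c) / (norm_sterile + c))` on size-factor
#' normalised counts with pseudocount `c = 0.5`, then orders genes by
#' average-linkage hierarchical clustering of the ratio rows (Euclidean
#' distance). The pseudocount stabilises ratios for genes with zero
#' counts.
#'
#' @param cm A [count_matrix()].
#' @param contrasts data.frame with columns `fertile`, `sterile` (sample
#'   names) and optionally `label`.
#' @param pseudocount Ratio pseudocount.
#' @return List with `ratios` (genes x contrasts, rows in clustered
#'   order), `order` (row permutation applied) and `hclust`.
#' @export
contrast_cluster <- function(cm, contrasts, pseudocount = 0.5) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  miss <- setdiff(c(contrasts$fertile, contrasts$sterile), colnames(m))
  if (length(miss))
    rfl_config_error(paste("samples missing from counts:",
                           paste(miss, collapse = ", ")))
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  ratios <- vapply(seq_len(nrow(contrasts)), function(k)
    log2((norm[, contrasts$fertile[k]] + pseudocount) /
           (norm[, contrasts$sterile[k]] + pseudocount)),
    numeric(nrow(m)))
  colnames(ratios) <- if ("label" %in% names(contrasts)) contrasts$label
                      else paste(contrasts$fertile, contrasts$sterile,
                                 sep = "_vs_")
  rownames(ratios) <- rownames(m)
  hc <- stats::hclust(stats::dist(ratios), method = "average")
  list(ratios = ratios[hc$order, , drop = FALSE], order = hc$order,
       hclust = hc)
}

#' Principal components analysis of samples
#'
#' Samples are projected on the principal components of
#' `log2(normalised count + 1)`, feature-centred, via singular value
#' decomposition.
#'
#' @param cm A [count_matrix()] or counts matrix.
#' @param normalise Apply [size_factors()] first.
#' @return List with `coordinates` (samples x components) and
#'   `variance_fractions` (non-increasing, summing to at most 1).
#' @export
pca_samples <- function(cm, normalise = TRUE) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(m) < 3L) rfl_parameter_error("at least three samples required")
  if (normalise) m <- sweep(m, 2, size_factors(m), "/")
  x <- t(log2(m + 1))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  frac <- if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  list(coordinates = p$x, variance_fractions = frac)
}

#' Normalise a coverage track to unmasked mean depth 1
#'
#' Divides the depth by its mean over unmasked positions, so masked
#' regions (rRNA, plastid-identical sequence) cannot distort the scaling.
#' Idempotent; the pre-normalisation mean is kept in `scale`.
#'
#' @param track A raw [coverage_track()].
#' @return The normalised track.
#' @export
normalize_coverage <- function(track) {
  if (track$normalised) return(track)
  unmasked <- !mask_logical(track)
  if (!any(unmasked)) rfl_parameter_error("track is entirely masked")
  m <- mean(track$depth[unmasked])
  if (m == 0) rfl_parameter_error("zero mean coverage on unmasked positions")
  coverage_track(track$ref_id, track$strand, track$depth / m, track$masks,
                 normalised = TRUE, scale = m)
}

#' Cleavage parameters
#'
#' @param window_w Half-window width in nt (>= 5).
#' @param min_fold Minimum right/left ratio-of-ratios fold for a call.
#' @param min_depth Minimum pre-normalisation sterile depth in both
#'   windows.
#' @param search_region Optional c(start, end) 0-based half-open genome
#'   interval to scan.
#' @return List of validated parameters.
#' @export
cleavage_params <- function(window_w = 50L, min_fold = 3.0, min_depth = 10,
                            search_region = NULL) {
  if (window_w < 5L) rfl_parameter_error("window_w must be >= 5")
  list(window_w = as.integer(window_w), min_fold = min_fold,
       min_depth = min_depth, search_region = search_region)
}

#' Localise a restorer-induced cleavage site from coverage
#'
#' In restored (fertile) plants the CMS transcript is cut and the 5' piece
#' degraded, so fertile/sterile coverage shows a sharp low-to-high
#' transition at the cleavage site when read 5' to 3'. On the per-base
#' ratio `(fertile + c) / (sterile + c)` with `c = 0.05`, the statistic
#' at position i is the mean of `r` over the `w` bases 3' of i divided by
#' the mean over the `w` bases 5' of i, evaluated in transcript
#' orientation. The call is the argmax (ties: 5'-most); it passes when the
#' fold reaches `min_fold` and the sterile track's raw depth averages at
#' least `min_depth` in both windows.
#'
#' The returned `position` is the transition boundary in genome
#' coordinates: the first base of the 3' (high) segment for a `+`
#' transcript, and the half-open mirror of that boundary for a `-`
#' transcript.
#'
#' @param fertile,sterile Normalised [coverage_track()]s on the same
#'   reference and strand.
#' @param params A [cleavage_params()] list.
#' @param transcript_strand Orientation in which 5'/3' are evaluated.
#' @param pseudocount Ratio pseudocount `c`.
#' @return An object of class `cleavage_call`: `ref_id`, `strand`,
#'   `position` (0-based), `fold`, `direction`, `passed`.
#' @export
detect_cleavage <- function(fertile, sterile, params = cleavage_params(),
                            transcript_strand = "+", pseudocount = 0.05) {
  if (!fertile$normalised || !sterile$normalised)
    rfl_parameter_error("both tracks must be normalised first")
  L <- length(fertile$depth)
  if (length(sterile$depth) != L)
    rfl_contract_error("tracks have different lengths")
  w <- params$window_w
  r <- (fertile$depth + pseudocount) / (sterile$depth + pseudocount)
  raw_sterile <- sterile$depth * (if (is.na(sterile$scale)) 1 else
                                    sterile$scale)
  if (transcript_strand == "-") {
    r <- rev(r); raw_sterile <- rev(raw_sterile)
  }
  reg <- params$search_region %||% c(0L, L)
  if (transcript_strand == "-") reg <- c(L - reg[2], L - reg[1])
  if (reg[2] - reg[1] < 2L * w)
    rfl_parameter_error("search region shorter than two windows")
  lo <- max(reg[1], w)               # candidate boundaries, 0-based
  hi <- min(reg[2], L - w)
  if (hi <= lo) rfl_parameter_error("no candidate position fits the windows")
  cs <- c(0, cumsum(r))
  css <- c(0, cumsum(raw_sterile))
  i <- lo:(hi - 1L)                  # boundary before oriented position i
  right <- (cs[i + w + 1L] - cs[i + 1L]) / w
  left <- (cs[i + 1L] - cs[i - w + 1L]) / w
  stat <- right / left
  k <- which.max(stat)               # first max = 5'-most
  call_i <- i[k]
  depth_right <- (css[call_i + w + 1L] - css[call_i + 1L]) / w
  depth_left <- (css[call_i + 1L] - css[call_i - w + 1L]) / w
  passed <- stat[k] >= params$min_fold &&
    depth_right >= params$min_depth && depth_left >= params$min_depth
  position <- if (transcript_strand == "+") call_i else L - call_i
  structure(list(ref_id = fertile$ref_id, strand = fertile$strand,
                 position = as.integer(position), fold = stat[k],
                 direction = "low_to_high", passed = passed),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat(sprintf("<cleavage_call %s(%s) position %d, fold %.2f, %s>\n",
              x$ref_id, x$strand, x$position, x$fold,
              if (x$passed) "PASSED" else "not passed"))
  invisible(x)
}
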