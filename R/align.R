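# Alignment of a candidate sequence against a collapsed (reduced-alphabet)
# scoring matrix: optimal semi-global alignment with affine gap penalties,
# position-specific match scores, and deterministic tie-breaking (fewer gap
# events, then leftmost placement).

#' Align a candidate sequence to a collapsed scoring matrix
#'
#' The segment is the short query (it must be fully explained, with
#' deletion runs penalized wherever they fall); the candidate sequence is
#' the long reference, so sequence overhangs before the first and after the
#' last matched position are free. Internal gaps in either direction cost
#' `gap_open + (len - 1) * gap_extend`.
#'
#' @param collapsed A [collapse_matrix()] result.
#' @param sequence Candidate amino-acid sequence (full 20-letter string).
#' @param alphabet The [reduced_alphabet()] the matrix was collapsed with.
#' @param gap_open,gap_extend Affine gap penalties in Z-score units
#'   (defaults 2.0 and 0.5, sized so the roughly one-per-ten-residue indel
#'   rate of automated chain tracing is tolerated).
#' @param mask Optional logical vector over sequence positions; `TRUE`
#'   positions may not be matched (used to forbid reusing residues).
#' @param seq_id Identifier carried into the result.
#' @return List of class `segment_alignment`: `segment_id`, `seq_id`,
#'   `pairs` (k x 2 matrix of segment/sequence positions, both strictly
#'   increasing), `raw_score`, `n_gaps`, `start`.
#' @export
align_segment <- function(collapsed, sequence, alphabet = reduced_alphabet(),
                          gap_open = 2.0, gap_extend = 0.5, mask = NULL,
                          seq_id = NA_character_) {
  stopifnot(inherits(collapsed, "collapsed_matrix"))
  if (!nzchar(sequence)) stop("empty candidate sequence", call. = FALSE)
  seqg <- .seq_groups(sequence, alphabet)
  if (is.null(mask)) mask <- rep(FALSE, length(seqg))
  stopifnot(length(mask) == length(seqg))
  r <- .align_pssm_cpp(collapsed$g, seqg, gap_open, gap_extend, mask)
  structure(list(segment_id = collapsed$segment_id, seq_id = seq_id,
                 pairs = r$pairs, raw_score = r$score, n_gaps = r$n_gaps,
                 start = r$start),
            class = "segment_alignment")
}

#' @export
print.segment_alignment <- function(x, ...) {
  cat("<segment_alignment> ", x$segment_id, " vs ", x$seq_id, ": score ",
      signif(x$raw_score, 5), ", ", nrow(x$pairs), " matched, ",
      x$n_gaps, " gap event(s)\n", sep = "")
  invisible(x)
}

# Batch score-only alignment (shared score model) for the null adjustment.
.align_scores_batch <- function(collapsed, group_seqs, gap_open, gap_extend) {
  .align_pssm_scores_cpp(collapsed$g, group_seqs, gap_open, gap_extend)
}
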