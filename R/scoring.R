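# Per-segment side-chain scoring: best-rotamer map-model correlation for
# each of the 20 residue types at each backbone position, converted to a
# non-negative Z-score matrix (the segment's position-specific scoring
# matrix), plus the derived pseudo-sequence and optional trimming.

#' Score a backbone segment against a map
#'
#' For every position of a break-free backbone segment and each of the 20
#' residue types, correlates every rotamer template with the map density in
#' the residue's standard frame and keeps the best-correlating rotamer. Per
#' residue type, the correlations over positions are then standardized to
#' Z-scores (value minus the column mean, divided by the column population
#' SD) and clipped at zero, so each column has pre-clip mean 0 and SD 1 by
#' construction. Columns whose correlations are constant across positions
#' get all-zero Z with a warning.
#'
#' @param map A [density_map].
#' @param segment Backbone tibble rows for one segment (>= 2 residues).
#' @param library A `template_library`.
#' @return Object of class `scoring_matrix` with fields `segment_id`, `L`,
#'   `z` and `corr` (L x 20 matrices, columns in [AA_ORDER]),
#'   `best_rotamer` (L x 20 rotamer ids), and the segment `backbone`.
#' @export
score_segment <- function(map, segment, library) {
  stopifnot(inherits(map, "density_map"), inherits(library, "template_library"))
  L <- nrow(segment)
  if (L < 2) stop("segment too short to score (need >= 2 residues)", call. = FALSE)
  pack <- .pack_library(library)
  n_tmpl <- length(pack$tcn)
  corr_rot <- matrix(0, L, n_tmpl)
  grp <- pack$tmpl_of
  n_off <- pack$n_off
  for (i in seq_len(L)) {
    fr <- build_frame(c(segment$n_x[i], segment$n_y[i], segment$n_z[i]),
                      c(segment$ca_x[i], segment$ca_y[i], segment$ca_z[i]),
                      c(segment$c_x[i], segment$c_y[i], segment$c_z[i]))
    pts <- .frame_apply(fr, pack$offsets)
    v <- .interp(map, pts)$values
    s1 <- rowsum(v, grp)[, 1]
    s2 <- rowsum(v * v, grp)[, 1]
    sp <- rowsum(v * pack$tc, grp)[, 1]
    obs_ss <- s2 - s1^2 / n_off
    denom <- pack$tcn * sqrt(pmax(obs_ss, 0))
    r <- ifelse(denom > 1e-12, sp / denom, 0)
    corr_rot[i, ] <- pmin(1, pmax(-1, r))
  }
  type1 <- pack$type_one
  corr <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA_ORDER))
  best_rot <- matrix(NA_character_, L, 20, dimnames = list(NULL, AA_ORDER))
  for (aa in AA_ORDER) {
    cols <- which(type1 == aa)
    sub <- corr_rot[, cols, drop = FALSE]
    pick <- max.col(sub, ties.method = "first")
    corr[, aa] <- sub[cbind(seq_len(L), pick)]
    best_rot[, aa] <- pack$rot_ids[cols][pick]
  }
  z <- .z_from_corr(corr)
  structure(list(segment_id = segment$segment_id[1], L = L, z = z,
                 corr = corr, best_rotamer = best_rot, backbone = segment),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("<scoring_matrix> segment ", x$segment_id, ": ", x$L,
      " positions x 20 residue types\n", sep = "")
  invisible(x)
}

#' Pseudo-sequence of a scoring matrix
#'
#' The best-fitting residue at each position: the highest-Z residue type,
#' reported as its residue-group representative when `by_groups` is set
#' (the default). Ties go to the first residue in the fixed [AA_ORDER].
#'
#' @param matrix A [score_segment()] result.
#' @param alphabet A [reduced_alphabet()].
#' @param by_groups Report group representatives (default) or raw residues.
#' @return Single string of length `L`.
#' @export
pseudo_sequence <- function(matrix, alphabet = reduced_alphabet(),
                            by_groups = TRUE) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  idx <- max.col(matrix$z, ties.method = "first")
  letters1 <- AA_ORDER[idx]
  if (by_groups) letters1 <- unname(alphabet$map[letters1])
  paste(letters1, collapse = "")
}

#' Trim and split a scored segment
#'
#' Optional model trimming: positions where the discrimination between the
#' most and least probable side chain (max Z minus min Z) falls below
#' `minimum_discrimination` are removed and the segment is split there;
#' then `trim_models` residues are removed from each end of every resulting
#' piece. Both are off (`NULL`) by default. Pieces shorter than 2 residues
#' are dropped.
#'
#' @param matrix A `scoring_matrix`.
#' @param minimum_discrimination Optional threshold (Z units).
#' @param trim_models Optional residue count to trim from each end.
#' @return List of `scoring_matrix` pieces (possibly empty).
#' @export
apply_trims <- function(matrix, minimum_discrimination = NULL,
                        trim_models = NULL) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  keep <- rep(TRUE, matrix$L)
  if (!is.null(minimum_discrimination)) {
    disc <- apply(matrix$z, 1, max) - apply(matrix$z, 1, min)
    keep <- disc >= minimum_discrimination
  }
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pieces <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    if (!is.null(trim_models) && trim_models > 0) {
      if (length(idx) <= 2 * trim_models) next
      idx <- idx[(trim_models + 1):(length(idx) - trim_models)]
    }
    if (length(idx) < 2) next
    piece <- matrix
    piece$L <- length(idx)
    piece$z <- matrix$z[idx, , drop = FALSE]
    piece$corr <- matrix$corr[idx, , drop = FALSE]
    piece$best_rotamer <- matrix$best_rotamer[idx, , drop = FALSE]
    piece$backbone <- matrix$backbone[idx, , drop = FALSE]
    piece$segment_id <- if (sum(runs$values) > 1) {
      sprintf("%s/%d", matrix$segment_id, sum(runs$values[seq_len(k)]))
    } else {
      matrix$segment_id
    }
    pieces[[length(pieces) + 1L]] <- piece
  }
  pieces
}

#' Collapse a scoring matrix to residue groups
#'
#' Group score at each position is the maximum Z over the group's member
#' residues; the member attaining the maximum is recorded as the position's
#' representative (so the true residue is never penalized for its group
#' assignment).
#'
#' @param matrix A `scoring_matrix`.
#' @param alphabet A [reduced_alphabet()] (any partition of the 20 residues;
#'   an identity partition gives per-residue scoring).
#' @return Object of class `collapsed_matrix`: fields `segment_id`, `L`,
#'   `g` (L x n-groups score matrix), `rep_member` (attaining members),
#'   `backbone`.
#' @export
collapse_matrix <- function(matrix, alphabet = reduced_alphabet()) {
  stopifnot(inherits(matrix, "scoring_matrix"),
            inherits(alphabet, "reduced_alphabet"))
  reps <- alphabet$representatives
  L <- matrix$L
  g <- matrix(0, L, length(reps), dimnames = list(NULL, reps))
  rep_member <- matrix(NA_character_, L, length(reps),
                       dimnames = list(NULL, reps))
  for (r in reps) {
    members <- alphabet$groups[[r]]
    sub <- matrix$z[, members, drop = FALSE]
    pick <- max.col(sub, ties.method = "first")
    g[, r] <- sub[cbind(seq_len(L), pick)]
    rep_member[, r] <- members[pick]
  }
  structure(list(segment_id = matrix$segment_id, L = L, g = g,
                 rep_member = rep_member, backbone = matrix$backbone),
            class = "collapsed_matrix")
}

# Z-score construction: per column (residue type), value minus the column
# mean divided by the column population SD, clipped at zero. Columns with
# zero SD across positions become all-zero with a warning.
.z_from_corr <- function(corr) {
  L <- nrow(corr)
  z <- matrix(0, L, ncol(corr), dimnames = dimnames(corr))
  flat <- character(0)
  for (aa in colnames(corr)) {
    m <- mean(corr[, aa])
    s <- sqrt(mean((corr[, aa] - m)^2))
    if (s < 1e-12) {
      flat <- c(flat, aa)
    } else {
      z[, aa] <- pmax(0, (corr[, aa] - m) / s)
    }
  }
  if (length(flat)) {
    warning("constant correlation across positions for type(s) ",
            paste(flat, collapse = ","), "; Z column set to 0")
  }
  z
}

# Identity partition (each residue its own class) used when
# score_by_residue_groups is off.
.identity_alphabet <- function() {
  reduced_alphabet(stats::setNames(as.list(AA_ORDER), AA_ORDER))
}
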