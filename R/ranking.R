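# Candidate ranking: configuration, random-sequence null adjustment,
# greedy segment assignment per candidate, database Z-scores, and the
# end-to-end identification driver.

#' Identification configuration
#'
#' Defaults mirror the method's stated defaults: up to three longest chains
#' are used; residue-group scoring is on; model trimming, positive-only
#' scoring and too-short rejection are off; duplicate use of sequence
#' residues by different segments is allowed.
#'
#' @param max_chains Number of longest segments used (default 3).
#' @param score_by_residue_groups Align in the six-letter reduced alphabet
#'   (default `TRUE`); when `FALSE` the full 20-letter alphabet is used.
#' @param residue_groups The [reduced_alphabet()] used when grouping is on.
#' @param minimum_discrimination,trim_models Optional trimming controls,
#'   see [apply_trims()]; both off (`NULL`) by default.
#' @param allow_duplicates Allow different segments to align to overlapping
#'   sequence windows (default `TRUE`).
#' @param skip_if_too_short Reject candidate sequences shorter than the
#'   model (default `FALSE`).
#' @param positive_only Count negative per-segment adjusted scores as zero
#'   (default `FALSE`).
#' @param default_sequence Residue frequencies (length 20, [AA_ORDER]
#'   order, summing to 1) for the random sequences of the null adjustment;
#'   defaults to eukaryotic frequencies ([kj_frequencies]).
#' @param n_null Random sequences per segment/length pair for the null
#'   mean (default 100; cached by sequence length).
#' @param gap_open,gap_extend Affine gap penalties, see [align_segment()].
#' @param seed Integer seed governing the null draws.
#' @return List of class `seqid_config`.
#' @export
seqid_config <- function(max_chains = 3,
                         score_by_residue_groups = TRUE,
                         residue_groups = reduced_alphabet(),
                         minimum_discrimination = NULL,
                         trim_models = NULL,
                         allow_duplicates = TRUE,
                         skip_if_too_short = FALSE,
                         positive_only = FALSE,
                         default_sequence = kj_frequencies,
                         n_null = 100,
                         gap_open = 2.0,
                         gap_extend = 0.5,
                         seed = 1) {
  stopifnot(max_chains >= 1, n_null >= 1)
  default_sequence <- as.numeric(default_sequence)
  if (length(default_sequence) != 20 || any(default_sequence < 0) ||
      abs(sum(default_sequence) - 1) > 1e-9) {
    stop("default_sequence must be 20 non-negative frequencies summing to 1",
         call. = FALSE)
  }
  structure(list(max_chains = as.integer(max_chains),
                 score_by_residue_groups = isTRUE(score_by_residue_groups),
                 residue_groups = residue_groups,
                 minimum_discrimination = minimum_discrimination,
                 trim_models = trim_models,
                 allow_duplicates = isTRUE(allow_duplicates),
                 skip_if_too_short = isTRUE(skip_if_too_short),
                 positive_only = isTRUE(positive_only),
                 default_sequence = stats::setNames(default_sequence, AA_ORDER),
                 n_null = as.integer(n_null),
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed = as.integer(seed)),
            class = "seqid_config")
}

# Small deterministic mix of a seed with integer keys, kept below 2^31.
.mix_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483629
  for (k in keys) h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  as.integer(h)
}

#' Null mean of segment-sequence alignment scores
#'
#' Mean raw alignment score of `n_null` random sequences of a given length
#' (i.i.d. letters from `freqs`) against a collapsed matrix. Subtracted
#' from a candidate's raw segment score, this centres random-sequence
#' scores at zero so that candidates of different lengths are comparable.
#'
#' @param collapsed A [collapse_matrix()] result.
#' @param seq_length Length of the random sequences.
#' @param freqs Residue frequencies over [AA_ORDER] summing to 1.
#' @param n_null Number of random sequences.
#' @param seed Integer seed (deterministic result for a given seed).
#' @param gap_open,gap_extend Gap penalties, as in [align_segment()].
#' @param alphabet Alphabet defining the matrix's groups.
#' @return Scalar null mean.
#' @export
null_mean <- function(collapsed, seq_length, freqs = kj_frequencies,
                      n_null = 100, seed = 1, gap_open = 2.0,
                      gap_extend = 0.5, alphabet = reduced_alphabet()) {
  stopifnot(n_null >= 1, seq_length >= 1)
  if (max(freqs) >= 1 - 1e-12) {
    warning("degenerate residue frequencies: null collapses to one sequence")
  }
  grp_of_aa <- match(alphabet$map[AA_ORDER], alphabet$representatives)
  rng <- .local_rng(seed)
  seqs <- lapply(seq_len(n_null), function(i) {
    grp_of_aa[rng$sample(20L, seq_length, replace = TRUE, prob = freqs)]
  })
  mean(.align_scores_batch(collapsed, seqs, gap_open, gap_extend))
}

# Cached null mean: environment keyed on (segment index, length).
.null_cache_fun <- function(collapsed_list, cfg, alphabet) {
  cache <- new.env(parent = emptyenv())
  function(seg_idx, seq_length) {
    key <- sprintf("%d_%d", seg_idx, seq_length)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- null_mean(collapsed_list[[seg_idx]], seq_length,
                   freqs = cfg$default_sequence, n_null = cfg$n_null,
                   seed = .mix_seed(cfg$seed, seg_idx, seq_length),
                   gap_open = cfg$gap_open, gap_extend = cfg$gap_extend,
                   alphabet = alphabet)
    cache[[key]] <- v
    v
  }
}

#' Score one candidate sequence against all segments
#'
#' Greedy assignment: every remaining segment is aligned to the candidate,
#' the single best segment-sequence alignment (by null-adjusted score) is
#' committed, the segment is removed, and the process repeats until no
#' segments remain. The candidate total is the sum of committed per-segment
#' adjusted scores (raw minus the random-sequence null mean for that
#' segment and sequence length). With `allow_duplicates = FALSE`, committed
#' alignments may not reuse a sequence position; with `positive_only`,
#' negative per-segment adjusted scores contribute zero.
#'
#' @param collapsed_list List of [collapse_matrix()] results.
#' @param seq_record List or one-row tibble with `seq_id`, `sequence`.
#' @param cfg A [seqid_config()].
#' @param null_fun Optional cached null function (internal use).
#' @return List of class `candidate_score`: `seq_id`, `raw_score`,
#'   `null_mean`, `adjusted_score`, `alignments`, `rejected`, `reason`.
#' @export
score_candidate <- function(collapsed_list, seq_record, cfg = seqid_config(),
                            null_fun = NULL) {
  stopifnot(length(collapsed_list) >= 1)
  alphabet <- if (cfg$score_by_residue_groups) cfg$residue_groups else .identity_alphabet()
  if (is.null(null_fun)) null_fun <- .null_cache_fun(collapsed_list, cfg, alphabet)
  seq_id <- seq_record$seq_id
  sequence <- seq_record$sequence
  n_model <- sum(vapply(collapsed_list, `[[`, 0L, "L"))
  if (cfg$skip_if_too_short && nchar(sequence) < n_model) {
    return(structure(list(seq_id = seq_id, raw_score = NA_real_,
                          null_mean = NA_real_, adjusted_score = NA_real_,
                          alignments = list(), rejected = TRUE,
                          reason = sprintf("sequence length %d < model size %d",
                                           nchar(sequence), n_model)),
                     class = "candidate_score"))
  }
  mask <- rep(FALSE, nchar(sequence))
  remaining <- seq_along(collapsed_list)
  committed <- list()
  total_raw <- 0; total_null <- 0; total_adj <- 0
  while (length(remaining)) {
    best <- NULL; best_adj <- -Inf; best_k <- NA_integer_; best_null <- NA_real_
    for (k in remaining) {
      al <- align_segment(collapsed_list[[k]], sequence, alphabet = alphabet,
                          gap_open = cfg$gap_open, gap_extend = cfg$gap_extend,
                          mask = if (cfg$allow_duplicates) NULL else mask,
                          seq_id = seq_id)
      nm <- null_fun(k, nchar(sequence))
      adj <- al$raw_score - nm
      if (adj > best_adj + 1e-12 ||
          (adj > best_adj - 1e-12 && !is.na(best_k) && k < best_k)) {
        best <- al; best_adj <- adj; best_k <- k; best_null <- nm
      }
    }
    committed[[length(committed) + 1L]] <- best
    contrib <- if (cfg$positive_only) max(0, best_adj) else best_adj
    total_raw <- total_raw + best$raw_score
    total_null <- total_null + best_null
    total_adj <- total_adj + contrib
    if (!cfg$allow_duplicates && nrow(best$pairs)) {
      mask[best$pairs[, 2]] <- TRUE
    }
    remaining <- setdiff(remaining, best_k)
  }
  structure(list(seq_id = seq_id, raw_score = total_raw,
                 null_mean = total_null, adjusted_score = total_adj,
                 alignments = committed, rejected = FALSE, reason = NA_character_),
            class = "candidate_score")
}

#' Rank a database of candidate scores
#'
#' Computes each candidate's database Z-score (adjusted score minus the
#' database mean, divided by the population SD over candidates) and ranks
#' by descending adjusted score with ties broken by `seq_id`.
#'
#' @param scores List of [score_candidate()] results (>= 2 candidates).
#' @return Tibble: `seq_id`, `raw_score`, `null_mean`, `adjusted_score`,
#'   `db_z`, `rank`, `n_segments`, `rejected`.
#' @export
rank_database <- function(scores) {
  if (length(scores) < 2) {
    stop("need at least 2 candidates to define a database Z-score", call. = FALSE)
  }
  tab <- tibble::tibble(
    seq_id = vapply(scores, `[[`, "", "seq_id"),
    raw_score = vapply(scores, `[[`, 0, "raw_score"),
    null_mean = vapply(scores, `[[`, 0, "null_mean"),
    adjusted_score = vapply(scores, `[[`, 0, "adjusted_score"),
    n_segments = vapply(scores, function(s) length(s$alignments), 0L),
    rejected = vapply(scores, `[[`, TRUE, "rejected"))
  ok <- !tab$rejected
  m <- mean(tab$adjusted_score[ok])
  s <- sqrt(mean((tab$adjusted_score[ok] - m)^2))
  if (!is.finite(s) || s < 1e-12) {
    warning("all candidate scores identical; database Z set to 0")
    tab$db_z <- ifelse(ok, 0, NA_real_)
  } else {
    tab$db_z <- ifelse(ok, (tab$adjusted_score - m) / s, NA_real_)
  }
  tab <- tab[order(tab$rejected, -ifelse(ok, tab$adjusted_score, -Inf),
                   tab$seq_id), ]
  tab$rank <- seq_len(nrow(tab))
  dplyr::relocate(tab, "seq_id", "raw_score", "null_mean", "adjusted_score",
                  "db_z", "rank", "n_segments", "rejected")
}

#' Identify the protein in a map
#'
#' End-to-end driver: keeps the `max_chains` longest backbone segments,
#' scores each against the map, applies optional trimming, collapses to the
#' alignment alphabet, scores every database candidate with the greedy
#' segment assignment and null adjustment, and ranks the database by
#' Z-score.
#'
#' @param map A [density_map].
#' @param backbone Backbone tibble ([read_backbone()] /
#'   [backbone_from_model()]).
#' @param database Tibble with `seq_id`, `sequence` ([read_fasta()]).
#' @param cfg A [seqid_config()].
#' @param library A `template_library`; defaults to the idealized library
#'   at 3 Angstrom.
#' @return Object of class `seqid_result`: `ranking` (tibble), `winner`
#'   (top `seq_id`), `alignments` (winner's committed alignments),
#'   `matrices` (collapsed matrices used), `config`.
#' @export
identify_protein <- function(map, backbone, database, cfg = seqid_config(),
                             library = idealized_template_library()) {
  if (!nrow(database)) stop("empty candidate database", call. = FALSE)
  segs <- split(backbone, backbone$segment_id)
  segs <- segs[vapply(segs, nrow, 0L) >= 2]
  if (!length(segs)) stop("no scoreable segments (all shorter than 2 residues)",
                          call. = FALSE)
  lens <- vapply(segs, nrow, 0L)
  keep <- names(sort(lens, decreasing = TRUE))[seq_len(min(cfg$max_chains, length(segs)))]
  segs <- segs[keep]
  matrices <- lapply(segs, function(s) score_segment(map, s, library))
  if (!is.null(cfg$minimum_discrimination) || !is.null(cfg$trim_models)) {
    matrices <- unlist(lapply(matrices, apply_trims,
                              minimum_discrimination = cfg$minimum_discrimination,
                              trim_models = cfg$trim_models),
                       recursive = FALSE)
    if (!length(matrices)) stop("trimming removed all segments", call. = FALSE)
  }
  alphabet <- if (cfg$score_by_residue_groups) cfg$residue_groups else .identity_alphabet()
  collapsed <- lapply(matrices, collapse_matrix, alphabet = alphabet)
  null_fun <- .null_cache_fun(collapsed, cfg, alphabet)
  scores <- lapply(seq_len(nrow(database)), function(i) {
    score_candidate(collapsed, database[i, ], cfg, null_fun = null_fun)
  })
  ranking <- rank_database(scores)
  winner <- ranking$seq_id[1]
  win_aln <- scores[[match(winner, vapply(scores, `[[`, "", "seq_id"))]]$alignments
  structure(list(ranking = ranking, winner = winner, alignments = win_aln,
                 matrices = collapsed, scoring = matrices, config = cfg,
                 library = library),
            class = "seqid_result")
}

#' @export
print.seqid_result <- function(x, ...) {
  cat("<seqid_result> ", nrow(x$ranking), " candidates over ",
      length(x$matrices), " segment(s)\n", sep = "")
  top <- utils::head(x$ranking, 3)
  cat(sprintf("  #%d %s  adjusted %.2f  Z %.2f\n", top$rank, top$seq_id,
              top$adjusted_score, top$db_z), sep = "")
  invisible(x)
}
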