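# Broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy an identification result
#'
#' @param x A `seqid_result`.
#' @param ... Unused.
#' @return The ranking tibble (one row per candidate): `seq_id`,
#'   `raw_score`, `null_mean`, `adjusted_score`, `db_z`, `rank`,
#'   `n_segments`, `rejected`.
#' @method tidy seqid_result
#' @export
tidy.seqid_result <- function(x, ...) x$ranking

#' Glance at an identification result
#'
#' @param x A `seqid_result`.
#' @param ... Unused.
#' @return One-row tibble: winner, its Z-score, the runner-up margin, and
#'   problem sizes.
#' @method glance seqid_result
#' @export
glance.seqid_result <- function(x, ...) {
  r <- x$ranking
  tibble::tibble(
    winner = r$seq_id[1],
    winner_db_z = r$db_z[1],
    runner_up_db_z = r$db_z[2],
    z_margin = r$db_z[1] - r$db_z[2],
    n_candidates = nrow(r),
    n_segments = length(x$matrices),
    n_positions = sum(vapply(x$matrices, `[[`, 0L, "L")))
}

#' Tidy a scoring matrix
#'
#' @param x A `scoring_matrix`.
#' @param ... Unused.
#' @return Long tibble: `segment_id`, `position`, `residue`, `z`, `corr`,
#'   `best_rotamer`.
#' @method tidy scoring_matrix
#' @export
tidy.scoring_matrix <- function(x, ...) {
  tibble::tibble(
    segment_id = x$segment_id,
    position = rep(seq_len(x$L), times = 20),
    residue = rep(AA_ORDER, each = x$L),
    z = as.numeric(x$z),
    corr = as.numeric(x$corr),
    best_rotamer = as.character(x$best_rotamer))
}

#' Plot a scoring matrix as a position-by-residue heat map
#'
#' @param object A `scoring_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scoring_matrix
#' @export
autoplot.scoring_matrix <- function(object, ...) {
  d <- tidy.scoring_matrix(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = factor(.data$residue, rev(AA_ORDER)),
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Z") +
    ggplot2::labs(x = "segment position", y = NULL,
                  title = paste("Side-chain scoring matrix:", object$segment_id)) +
    ggplot2::theme_minimal()
}

#' Plot the candidate Z-score distribution of an identification
#'
#' Shows every candidate's database Z-score with the top candidate
#' highlighted; a well-identified protein stands several SD clear of the
#' decoy bulk.
#'
#' @param object A `seqid_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seqid_result
#' @export
autoplot.seqid_result <- function(object, ...) {
  d <- object$ranking
  d$top <- d$rank == 1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$db_z, fill = .data$top)) +
    ggplot2::geom_histogram(bins = 40, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "database Z-score", y = "candidates",
                  title = paste0("Top candidate: ", d$seq_id[1],
                                 " (Z = ", signif(d$db_z[1], 3), ")")) +
    ggplot2::theme_minimal()
}
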