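# Side-chain refit: once the winning sequence is known, assign its residues
# to the aligned backbone positions and place the best-correlating rotamer
# of each assigned type in the residue's standard frame. Torsion-space
# placement only; no coordinate refinement.

#' Refit side chains for the identified sequence
#'
#' At every backbone position matched by a winning alignment, the residue
#' type is taken from the aligned sequence position and the rotamer with the
#' highest template-map correlation is placed via the residue frame.
#' Unaligned positions keep an alanine placeholder and are flagged.
#'
#' @param result A [identify_protein()] result, or a list of
#'   `segment_alignment`s via `alignments` with matching `matrices`.
#' @param map The [density_map] used for identification.
#' @param sequence The winning sequence string (the full 20-letter sequence
#'   of the top-ranked candidate).
#' @param library Template library; defaults to the one used in `result`.
#' @return Object of class `fitted_model`: `model` (atom tibble),
#'   `assignments` (tibble: segment_id, position, resno, assigned residue,
#'   rotamer, aligned flag).
#' @export
refit_side_chains <- function(result, map, sequence, library = NULL) {
  stopifnot(inherits(result, "seqid_result"))
  if (is.null(library)) library <- result$library
  alignments <- result$alignments
  matrices <- result$matrices
  seg_ids <- vapply(matrices, `[[`, "", "segment_id")
  rows <- list()
  assign_rows <- list()
  templates_by_type <- split(library$templates,
                             vapply(library$templates, `[[`, "", "residue_type"))
  for (al in alignments) {
    cm <- matrices[[match(al$segment_id, seg_ids)]]
    bb <- cm$backbone
    aligned_pos <- if (nrow(al$pairs)) al$pairs[, 1] else integer(0)
    seq_pos <- if (nrow(al$pairs)) al$pairs[, 2] else integer(0)
    for (i in seq_len(nrow(bb))) {
      hit <- match(i, aligned_pos)
      if (!is.na(hit)) {
        aa1 <- substr(sequence, seq_pos[hit], seq_pos[hit])
        res3 <- AA_THREE[[aa1]]
        aligned <- TRUE
      } else {
        res3 <- "ALA"
        aligned <- FALSE
      }
      n <- c(bb$n_x[i], bb$n_y[i], bb$n_z[i])
      ca <- c(bb$ca_x[i], bb$ca_y[i], bb$ca_z[i])
      cc <- c(bb$c_x[i], bb$c_y[i], bb$c_z[i])
      fr <- build_frame(n, ca, cc)
      tl <- templates_by_type[[res3]]
      rot_id <- NA_character_
      chis <- numeric(0)
      if (is.null(tl)) {
        warning("no template for ", res3, "; alanine placeholder used")
        res3 <- "ALA"
        tl <- templates_by_type[["ALA"]]
        aligned <- FALSE
      }
      if (length(tl) > 1) {
        cors <- vapply(tl, function(t) correlate_template(map, fr, t), 0)
        best <- which.max(cors)
      } else {
        best <- 1L
      }
      rot_id <- tl[[best]]$rotamer_id
      chis <- tl[[best]]$chis
      bb_atoms <- list(N = n, CA = ca, C = cc)
      atoms <- bb_atoms
      if (!all(is.na(c(bb$o_x[i], bb$o_y[i], bb$o_z[i])))) {
        atoms$O <- c(bb$o_x[i], bb$o_y[i], bb$o_z[i])
      }
      if (res3 != "GLY") {
        sc_std <- .std_sidechain(res3, chis)
        sc_world <- .frame_apply(fr, sc_std)
        for (k in seq_len(nrow(sc_std))) {
          atoms[[rownames(sc_std)[k]]] <- sc_world[k, ]
        }
      }
      for (a in names(atoms)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chain = bb$chain[i], resno = bb$resno[i], resname = res3,
          atom = a, x = atoms[[a]][1], y = atoms[[a]][2], z = atoms[[a]][3],
          element = substr(a, 1, 1))
      }
      assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
        segment_id = al$segment_id, position = i, resno = bb$resno[i],
        assigned = AA_ONE[[res3]], rotamer = rot_id, aligned = aligned)
    }
  }
  structure(list(model = dplyr::bind_rows(rows),
                 assignments = dplyr::bind_rows(assign_rows)),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> ", nrow(x$assignments), " residues (",
      sum(x$assignments$aligned), " aligned, ",
      sum(!x$assignments$aligned), " placeholder)\n", sep = "")
  invisible(x)
}
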