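# Structural model and sequence I/O: backbone segments from PDB/mmCIF,
# model output as PDB, FASTA sequence databases.

#' Convert an atom-level model to a backbone-segment table
#'
#' Collapses an atom table (one row per atom) to one row per residue with
#' wide coordinate columns for N, CA, C (and CB, O when present), assigning
#' `segment_id` by splitting each chain wherever consecutive CA-CA distance
#' exceeds `break_threshold` Angstrom. Residues missing any of N, CA or C
#' are dropped with a warning (no local frame can be built for them).
#'
#' @param model Tibble with columns `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`.
#' @param break_threshold CA-CA distance (Angstrom) above which a chain is
#'   split into separate segments. Default 5.0, a generous upper bound on
#'   the CA separation of a trans or cis peptide.
#' @return Backbone tibble: `segment_id`, `chain`, `resno`, `resname`,
#'   `n_x`..`c_z` (+ `cb_*`, `o_*`, possibly NA).
#' @export
backbone_from_model <- function(model, break_threshold = 5.0) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(model)))
  mc <- dplyr::filter(model, .data$atom %in% c("N", "CA", "C", "CB", "O"))
  wide <- mc |>
    dplyr::distinct(.data$chain, .data$resno, .data$atom, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = c("chain", "resno", "resname"),
                       names_from = "atom", values_from = c("x", "y", "z"),
                       names_glue = "{tolower(atom)}_{.value}") |>
    dplyr::arrange(.data$chain, .data$resno)
  for (col in c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z", "c_x", "c_y",
                "c_z", "cb_x", "cb_y", "cb_z", "o_x", "o_y", "o_z")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  ok <- stats::complete.cases(wide[, c("n_x", "n_y", "n_z", "ca_x", "ca_y",
                                       "ca_z", "c_x", "c_y", "c_z")])
  if (any(!ok)) {
    warning(sum(!ok), " residue(s) missing main-chain atoms were skipped")
    wide <- wide[ok, ]
  }
  if (!nrow(wide)) stop("no usable residues with complete main chain", call. = FALSE)
  pieces <- wide |>
    dplyr::group_by(.data$chain) |>
    dplyr::group_split()
  out <- list()
  seg_counter <- 0L
  for (p in pieces) {
    dca <- sqrt(diff(p$ca_x)^2 + diff(p$ca_y)^2 + diff(p$ca_z)^2)
    brk <- c(0, cumsum(dca > break_threshold))
    for (b in split(seq_len(nrow(p)), brk)) {
      seg_counter <- seg_counter + 1L
      q <- p[b, ]
      q$segment_id <- sprintf("%s_%03d", q$chain[1], seg_counter)
      out[[seg_counter]] <- q
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("segment_id") |>
    dplyr::select("segment_id", "chain", "resno", "resname",
                  dplyr::starts_with("n_"), dplyr::starts_with("ca_"),
                  dplyr::starts_with("c_"), dplyr::starts_with("cb_"),
                  dplyr::starts_with("o_"))
}

#' Read a backbone model from PDB or mmCIF
#'
#' Reads main-chain atoms and returns break-free segments (chains split at
#' CA-CA gaps above `break_threshold`). mmCIF is accepted on input; PDB is
#' the canonical output dialect of [write_model()].
#'
#' @inheritParams backbone_from_model
#' @param path Path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @return Backbone tibble as in [backbone_from_model()].
#' @export
read_backbone <- function(path, break_threshold = 5.0) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("no ATOM records in ", path, call. = FALSE)
  model <- tibble::tibble(chain = a$chain, resno = a$resno,
                          resname = a$resid, atom = a$elety,
                          x = a$x, y = a$y, z = a$z)
  backbone_from_model(model, break_threshold = break_threshold)
}

#' Write an atom-level model as PDB
#'
#' @param model Tibble with `chain`, `resno`, `resname`, `atom`, `x`, `y`,
#'   `z` (one row per atom).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(nrow(model) > 0)
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = model$resno, resid = model$resname,
                   eleno = seq_len(nrow(model)), elety = model$atom,
                   chain = model$chain)
  invisible(path)
}

#' Read a FASTA sequence database
#'
#' @param path FASTA file (multi-record, wrapped lines).
#' @param policy `"strict"` rejects records with letters outside the 20
#'   standard one-letter codes; `"lenient"` maps such letters to `G`, the
#'   representative of the most frequent residue group.
#' @return Tibble with `seq_id`, `sequence`.
#' @export
read_fasta <- function(path, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  bad <- vapply(strsplit(seqs, ""), function(s) any(!s %in% AA_ORDER), logical(1))
  if (any(bad)) {
    if (policy == "strict") {
      stop("non-standard letters in record(s): ",
           paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
    }
    seqs[bad] <- vapply(strsplit(seqs[bad], ""), function(s) {
      s[!s %in% AA_ORDER] <- "G"
      paste(s, collapse = "")
    }, character(1))
  }
  if (any(!nzchar(seqs))) stop("empty sequence record in FASTA", call. = FALSE)
  tibble::tibble(seq_id = ids, sequence = unname(seqs))
}

#' Write sequences as FASTA
#'
#' @param db Tibble with `seq_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  ss <- Biostrings::AAStringSet(stats::setNames(db$sequence, db$seq_id))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}
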