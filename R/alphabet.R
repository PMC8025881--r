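# Reduced six-letter amino-acid alphabet: side chains grouped into
# size/shape classes that are hard to tell apart in density, so that
# alignment operates over classes rather than the full 20-letter alphabet.

#' Reduced amino-acid alphabet
#'
#' Partition of the 20 standard amino acids into six size/shape classes,
#' each named by a representative letter. The default grouping is
#' G = VGASCTI, P = P, L = LDNEQM, K = KR, Y = FHY, W = W.
#'
#' @param groups Named list of character strings; names are the
#'   representative letters, values the member residues (one-letter).
#' @return Object of class `reduced_alphabet` with fields `groups`,
#'   `representatives`, and `map` (named vector residue -> representative).
#' @export
reduced_alphabet <- function(groups = list(G = "VGASCTI", P = "P",
                                           L = "LDNEQM", K = "KR",
                                           Y = "FHY", W = "W")) {
  members <- lapply(groups, function(s) strsplit(s, "")[[1]])
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members)) stop("groups overlap", call. = FALSE)
  if (!setequal(all_members, AA_ORDER)) {
    stop("groups must cover exactly the 20 standard amino acids", call. = FALSE)
  }
  map <- stats::setNames(rep(names(groups), lengths(members)), all_members)
  structure(list(groups = members,
                 representatives = names(groups),
                 map = map[AA_ORDER]),
            class = "reduced_alphabet")
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat("<reduced_alphabet> ", length(x$groups), " classes: ",
      paste(sprintf("%s=%s", x$representatives,
                    vapply(x$groups, paste, "", collapse = "")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reduce a sequence to group representatives
#'
#' @param seq One-letter amino-acid string (or character vector of them).
#' @param alphabet A [reduced_alphabet()].
#' @return Character of the same length/shape with each residue replaced by
#'   its group representative.
#' @export
reduce_sequence <- function(seq, alphabet = reduced_alphabet()) {
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    letters1 <- strsplit(s, "")[[1]]
    rep <- alphabet$map[letters1]
    if (anyNA(rep)) stop("sequence contains letters outside the 20-letter alphabet",
                         call. = FALSE)
    paste(rep, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer group index (1-based, in representative order) for each letter of
# a plain sequence; used by the alignment core.
.seq_groups <- function(seq, alphabet) {
  letters1 <- strsplit(seq, "")[[1]]
  idx <- match(alphabet$map[letters1], alphabet$representatives)
  if (anyNA(idx)) stop("sequence contains letters outside the 20-letter alphabet",
                       call. = FALSE)
  idx
}
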