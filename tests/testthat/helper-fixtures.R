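# Shared fixtures, built once per test run. All synthetic and generated in
# code; nothing is read from disk.

.fix_env <- new.env(parent = emptyenv())

test_library <- function(resolution = 3.0) {
  key <- sprintf("lib_%s", resolution)
  if (is.null(.fix_env[[key]])) {
    .fix_env[[key]] <- idealized_template_library(resolution = resolution)
  }
  .fix_env[[key]]
}

# A small clean fixture: 60 residues, no noise, default trace errors.
test_fixture <- function() {
  if (is.null(.fix_env$fx)) {
    .fix_env$fx <- simulate_identification_fixture(seed = 42, n_res = 60,
                                                   n_decoys = 20)
  }
  .fix_env$fx
}

# An unperturbed scored segment of the clean fixture (ground truth known).
test_scored_segment <- function() {
  if (is.null(.fix_env$sm)) {
    fx <- test_fixture()
    bb <- backbone_from_model(fx$model)
    .fix_env$sm <- score_segment(fx$map, bb, test_library())
  }
  .fix_env$sm
}

# Hand-construct a scoring_matrix from a z matrix (columns AA_ORDER).
fake_scoring_matrix <- function(z, segment_id = "T_001") {
  colnames(z) <- AA_ORDER
  bb <- tibble::tibble(segment_id = segment_id, chain = "T",
                       resno = seq_len(nrow(z)), resname = "UNK",
                       n_x = 0, n_y = 0, n_z = 0, ca_x = 0, ca_y = 0,
                       ca_z = 0, c_x = 0, c_y = 0, c_z = 0,
                       cb_x = NA_real_, cb_y = NA_real_, cb_z = NA_real_,
                       o_x = NA_real_, o_y = NA_real_, o_z = NA_real_)
  structure(list(segment_id = segment_id, L = nrow(z), z = z, corr = z,
                 best_rotamer = matrix(NA_character_, nrow(z), 20,
                                       dimnames = list(NULL, AA_ORDER)),
                 backbone = bb),
            class = "scoring_matrix")
}

# Hand-construct a collapsed matrix (columns = group representatives).
fake_collapsed <- function(g, segment_id = "T_001") {
  ab <- reduced_alphabet()
  colnames(g) <- ab$representatives
  structure(list(segment_id = segment_id, L = nrow(g), g = g,
                 rep_member = matrix(NA_character_, nrow(g), 6,
                                     dimnames = list(NULL, ab$representatives)),
                 backbone = NULL),
            class = "collapsed_matrix")
}

# One-hot collapsed matrix whose per-position best groups spell `groups`
# (a string over G P L K Y W), with `hi` on the spelled group and 0 elsewhere.
spelled_collapsed <- function(groups, hi = 2) {
  reps <- reduced_alphabet()$representatives
  letters1 <- strsplit(groups, "")[[1]]
  g <- matrix(0, length(letters1), 6)
  g[cbind(seq_along(letters1), match(letters1, reps))] <- hi
  fake_collapsed(g)
}
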