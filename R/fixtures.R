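# Synthetic fixtures: Gaussian-atom density maps rendered from coordinates
# at a nominal resolution, trace-like backbone perturbations (insertions /
# deletions at a set per-residue rate plus coordinate jitter), and decoy
# sequence databases. All fixtures are reproducible bit-for-bit from their
# arguments and seed.

#' Simulate a density map from an atomic model
#'
#' Renders each atom as an isotropic Gaussian of width
#' sigma = resolution / (pi * sqrt(2)), weighted by an approximate electron
#' count per element, on a regular grid enclosing the model with `margin`
#' Angstrom on every side, plus optional i.i.d. Gaussian noise with SD
#' `noise_sd` times the peak density.
#'
#' @param model Atom tibble (`chain`, `resno`, `resname`, `atom`, `x`, `y`,
#'   `z`, optionally `element`).
#' @param resolution Nominal resolution in Angstrom (must be >= 2 * voxel).
#' @param voxel Voxel spacing in Angstrom.
#' @param noise_sd Noise SD as a fraction of the peak density (default 0).
#' @param margin Box margin around the model, Angstrom.
#' @param seed Seed for the noise draw.
#' @return A [density_map].
#' @export
simulate_density_map <- function(model, resolution = 3.0, voxel = 1.0,
                                 noise_sd = 0, margin = 4.0, seed = 1) {
  stopifnot(nrow(model) > 0)
  if (resolution < 2 * voxel) {
    stop("resolution must be at least twice the voxel size", call. = FALSE)
  }
  sigma <- .res_sigma(resolution)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  el <- if ("element" %in% names(model)) model$element else substr(model$atom, 1, 1)
  w <- .element_weight[el]
  w[is.na(w)] <- 6
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  d <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  grid <- array(0, dim = d)
  cutoff <- 4 * sigma
  cut_vox <- ceiling(cutoff / voxel)
  ax1 <- lo[1] + voxel * (0:(d[1] - 1))
  ax2 <- lo[2] + voxel * (0:(d[2] - 1))
  ax3 <- lo[3] + voxel * (0:(d[3] - 1))
  for (i in seq_len(nrow(xyz))) {
    ctr <- round((xyz[i, ] - lo) / voxel)
    i1 <- max(0, ctr[1] - cut_vox):min(d[1] - 1, ctr[1] + cut_vox)
    i2 <- max(0, ctr[2] - cut_vox):min(d[2] - 1, ctr[2] + cut_vox)
    i3 <- max(0, ctr[3] - cut_vox):min(d[3] - 1, ctr[3] + cut_vox)
    if (!length(i1) || !length(i2) || !length(i3)) {
      stop("atom outside the map box: row ", i, call. = FALSE)
    }
    g1 <- exp(-(ax1[i1 + 1] - xyz[i, 1])^2 / (2 * sigma^2))
    g2 <- exp(-(ax2[i2 + 1] - xyz[i, 2])^2 / (2 * sigma^2))
    g3 <- exp(-(ax3[i3 + 1] - xyz[i, 3])^2 / (2 * sigma^2))
    blk <- w[i] * (g1 %o% g2 %o% g3)
    grid[i1 + 1, i2 + 1, i3 + 1] <- grid[i1 + 1, i2 + 1, i3 + 1] + blk
  }
  if (noise_sd > 0) {
    rng <- .local_rng(seed)
    grid <- grid + rng$rnorm(length(grid), sd = noise_sd * max(grid))
  }
  density_map(grid, origin = lo, voxel = rep(voxel, 3))
}

#' Perturb a backbone like an automated chain trace
#'
#' Strips side chains, then draws an indel event per residue at rate
#' `indel_rate` (default 0.10, the rough one-per-ten-residue error rate of
#' automated tracing). Deletion events remove the residue and split the
#' chain there; insertion events locally resample a three-residue window
#' into four evenly spaced residues (emulating a spurious extra residue in
#' the trace). All coordinates are jittered with i.i.d. Gaussian noise of
#' SD `coord_jitter`.
#'
#' @param model Atom tibble of the ground-truth structure.
#' @param indel_rate Events per residue in `[0, 0.5]`.
#' @param coord_jitter Coordinate noise SD in Angstrom.
#' @param seed Integer seed.
#' @return Backbone tibble (as [backbone_from_model()]); attribute
#'   `n_indels` records the number of events drawn.
#' @export
perturb_backbone <- function(model, indel_rate = 0.10, coord_jitter = 0.1,
                             seed = 1) {
  stopifnot(indel_rate >= 0, indel_rate <= 0.5)
  mc <- dplyr::filter(model, .data$atom %in% c("N", "CA", "C")) |>
    dplyr::arrange(.data$chain, .data$resno)
  res <- mc |>
    tidyr::pivot_wider(id_cols = c("chain", "resno", "resname"),
                       names_from = "atom", values_from = c("x", "y", "z"),
                       names_glue = "{tolower(atom)}_{.value}") |>
    dplyr::arrange(.data$chain, .data$resno)
  L <- nrow(res)
  rng <- .local_rng(seed)
  ev <- rng$runif(L) < indel_rate
  kind <- ifelse(rng$runif(L) < 0.5, "del", "ins")
  kind[!ev] <- "none"
  # insertions need a 3-residue window starting at the event position
  kind[kind == "ins" & seq_len(L) > L - 2] <- "del"
  coord_cols <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                  "c_x", "c_y", "c_z")
  out <- list()
  cur <- list()
  flush <- function(out, cur) {
    if (length(cur)) out[[length(out) + 1L]] <- dplyr::bind_rows(cur)
    out
  }
  i <- 1L
  while (i <= L) {
    k <- kind[i]
    if (k == "del") {
      out <- flush(out, cur)
      cur <- list()
      i <- i + 1L
    } else if (k == "ins") {
      win <- res[i:(i + 2), ]
      t_new <- c(0, 2 / 3, 4 / 3, 2)
      resampled <- lapply(t_new, function(t) {
        lo <- min(floor(t) + 1, 2)
        fr <- t - (lo - 1)
        row <- win[lo, ]
        for (cc in coord_cols) {
          row[[cc]] <- (1 - fr) * win[[cc]][lo] + fr * win[[cc]][lo + 1]
        }
        row$resname <- "UNK"
        row
      })
      cur <- c(cur, resampled)
      i <- i + 3L
    } else {
      row <- res[i, ]
      row$resname <- "UNK"
      cur <- c(cur, list(row))
      i <- i + 1L
    }
  }
  out <- flush(out, cur)
  out <- out[vapply(out, nrow, 0L) > 0]
  segs <- list()
  for (sidx in seq_along(out)) {
    q <- out[[sidx]]
    q$segment_id <- sprintf("%s_%03d", q$chain[1], sidx)
    segs[[sidx]] <- q
  }
  bb <- dplyr::bind_rows(segs)
  if (coord_jitter > 0) {
    for (cc in coord_cols) {
      bb[[cc]] <- bb[[cc]] + rng$rnorm(nrow(bb), sd = coord_jitter)
    }
  }
  for (cc in c("cb_x", "cb_y", "cb_z", "o_x", "o_y", "o_z")) bb[[cc]] <- NA_real_
  bb <- dplyr::relocate(bb, "segment_id")
  # renumber within segments to keep residue numbering monotone
  bb <- bb |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::mutate(resno = dplyr::row_number()) |>
    dplyr::ungroup()
  attr(bb, "n_indels") <- sum(ev)
  bb
}

#' Generate a decoy sequence database
#'
#' I.i.d. sequences from the given residue frequencies, with optional
#' composition-preserving shuffles of a true sequence.
#'
#' @param n Number of i.i.d. decoys.
#' @param length_range Integer length range (inclusive) to draw decoy
#'   lengths from.
#' @param freqs Residue frequencies over [AA_ORDER] summing to 1.
#' @param seed Integer seed.
#' @param shuffles_of Optional sequence; adds `n_shuffles` shuffled copies.
#' @param n_shuffles Number of shuffles when `shuffles_of` is given.
#' @return Tibble with `seq_id`, `sequence`.
#' @export
make_decoys <- function(n, length_range = c(80, 120), freqs = kj_frequencies,
                        seed = 1, shuffles_of = NULL, n_shuffles = 0) {
  stopifnot(n >= 1)
  rng <- .local_rng(seed)
  lens <- length_range[1] + floor(rng$runif(n) * (length_range[2] - length_range[1] + 1))
  lens <- pmin(lens, length_range[2])
  seqs <- vapply(lens, function(l) {
    paste(AA_ORDER[rng$sample(20L, l, replace = TRUE, prob = freqs)],
          collapse = "")
  }, character(1))
  db <- tibble::tibble(seq_id = sprintf("decoy_%03d", seq_len(n)),
                       sequence = seqs)
  if (!is.null(shuffles_of) && n_shuffles > 0) {
    sh <- vapply(seq_len(n_shuffles), function(i) {
      s <- strsplit(shuffles_of, "")[[1]]
      paste(s[rng$sample(length(s), length(s))], collapse = "")
    }, character(1))
    db <- dplyr::bind_rows(db, tibble::tibble(
      seq_id = sprintf("shuffle_%03d", seq_len(n_shuffles)), sequence = sh))
  }
  db
}

#' Build a complete identification fixture
#'
#' Draws a random true sequence, builds its ideal full-atom model, renders
#' a map at the requested resolution, perturbs the backbone like an
#' automated trace, and assembles a candidate database of the true sequence
#' plus decoys. The returned ground truth makes rank-1 recovery an
#' assertable end-to-end test.
#'
#' @param seed Integer seed controlling every random choice.
#' @param n_res Length of the true protein.
#' @param resolution,voxel,noise_sd Map rendering controls
#'   ([simulate_density_map()]); the voxel defaults to `resolution / 3`,
#'   the usual ~3x oversampling of cryo-EM deposition.
#' @param indel_rate,coord_jitter Trace perturbation controls
#'   ([perturb_backbone()]).
#' @param n_decoys Number of i.i.d. decoys in the database (default 99,
#'   plus the true sequence).
#' @return List: `map`, `backbone`, `database`, `true_id`, `sequence`,
#'   `model`.
#' @export
simulate_identification_fixture <- function(seed = 1, n_res = 120,
                                            resolution = 3.0,
                                            voxel = resolution / 3,
                                            noise_sd = 0, indel_rate = 0.10,
                                            coord_jitter = 0.1,
                                            n_decoys = 99) {
  rng <- .local_rng(.mix_seed(seed, 11))
  true_seq <- paste(AA_ORDER[rng$sample(20L, n_res, replace = TRUE,
                                        prob = kj_frequencies)],
                    collapse = "")
  model <- build_polypeptide(true_seq, seed = .mix_seed(seed, 23))
  map <- simulate_density_map(model, resolution = resolution, voxel = voxel,
                              noise_sd = noise_sd, seed = .mix_seed(seed, 37))
  backbone <- perturb_backbone(model, indel_rate = indel_rate,
                               coord_jitter = coord_jitter,
                               seed = .mix_seed(seed, 53))
  decoys <- make_decoys(n_decoys,
                        length_range = c(round(0.7 * n_res), round(1.3 * n_res)),
                        seed = .mix_seed(seed, 71))
  database <- dplyr::bind_rows(
    tibble::tibble(seq_id = "true_protein", sequence = true_seq), decoys)
  list(map = map, backbone = backbone, database = database,
       true_id = "true_protein", sequence = true_seq, model = model)
}

#' Run one seeded identification replicate
#'
#' Convenience wrapper for validation studies: builds a fixture at the
#' given seed and resolution, runs the full identification against the
#' matched idealized library, and reports where the true sequence landed.
#'
#' @param seed Integer replicate seed.
#' @param resolution Simulated resolution in Angstrom.
#' @param n_res,n_decoys,noise_sd,indel_rate,coord_jitter Fixture controls,
#'   see [simulate_identification_fixture()].
#' @param cfg A [seqid_config()]; its seed is replaced by `seed`.
#' @return One-row tibble: `seed`, `resolution`, `true_rank`, `true_db_z`,
#'   `runner_up_db_z`, `n_candidates`.
#' @export
evaluate_fixture_identification <- function(seed, resolution = 3.0,
                                            n_res = 120, n_decoys = 99,
                                            noise_sd = 0, indel_rate = 0.10,
                                            coord_jitter = 0.1,
                                            cfg = seqid_config()) {
  fx <- simulate_identification_fixture(seed = seed, n_res = n_res,
                                        resolution = resolution,
                                        noise_sd = noise_sd,
                                        indel_rate = indel_rate,
                                        coord_jitter = coord_jitter,
                                        n_decoys = n_decoys)
  cfg$seed <- as.integer(seed)
  lib <- idealized_template_library(resolution = resolution)
  res <- identify_protein(fx$map, fx$backbone, fx$database, cfg, lib)
  r <- res$ranking
  true_row <- which(r$seq_id == fx$true_id)
  runner <- r$db_z[r$seq_id != fx$true_id][1]
  tibble::tibble(seed = seed, resolution = resolution,
                 true_rank = r$rank[true_row], true_db_z = r$db_z[true_row],
                 runner_up_db_z = runner, n_candidates = nrow(r))
}
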