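# Brute-force alignment oracle: enumerates every monotone set of matched
# (segment position, sequence position) pairs and scores it under the same
# cost model as the package's dynamic program — matched cells add
# S[i, group(seq[j])], every maximal run of unmatched segment positions
# costs open + (len-1)*extend wherever it falls, unmatched sequence runs
# strictly between matches cost the same, sequence overhangs are free.
# Enumeration is cached per (L, M) shape; completely independent of the
# DP implementation.

.oracle_cache <- new.env(parent = emptyenv())

run_penalty <- function(positions, open, ext) {
  # positions: sorted indices of unmatched slots to penalize
  if (!length(positions)) return(0)
  grp <- cumsum(c(1, diff(positions) != 1))
  lens <- tabulate(grp)
  sum(open + (lens - 1) * ext)
}

oracle_combos <- function(L, M) {
  key <- sprintf("%d_%d", L, M)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  out <- list()
  for (k in seq_len(min(L, M))) {
    rows <- utils::combn(L, k)
    cols <- utils::combn(M, k)
    out[[k]] <- list(rows = t(rows), cols = t(cols))
  }
  .oracle_cache[[key]] <- out
  out
}

# Best score over all alignments. S is L x G, seqg integer groups (1..G),
# forbidden: optional logical over sequence positions that may not match.
bf_align_score <- function(S, seqg, open, ext, forbidden = NULL) {
  L <- nrow(S)
  M <- length(seqg)
  best <- -(open + (L - 1) * ext)   # empty alignment: whole segment deleted
  combos <- oracle_combos(L, M)
  for (k in seq_len(min(L, M))) {
    rows <- combos[[k]]$rows
    cols <- combos[[k]]$cols
    col_ok <- rep(TRUE, nrow(cols))
    if (!is.null(forbidden)) {
      col_ok <- !apply(cols, 1, function(cc) any(forbidden[cc]))
    }
    # matched sums for every (row choice, col choice) pair
    for (ri in seq_len(nrow(rows))) {
      rsel <- rows[ri, ]
      unmatched_rows <- setdiff(seq_len(L), rsel)
      rpen <- run_penalty(unmatched_rows, open, ext)
      for (ci in which(col_ok)) {
        csel <- cols[ci, ]
        matched <- sum(S[cbind(rsel, seqg[csel])])
        inner <- setdiff(seq(csel[1], csel[k]), csel)
        cpen <- run_penalty(inner, open, ext)
        sc <- matched - rpen - cpen
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Random alignment instance generator (small integer-ish scores so exact
# float ties are well defined).
random_align_instance <- function(rng_seed, max_L = 6, max_M = 8, G = 6) {
  set.seed(rng_seed)
  L <- sample(2:max_L, 1)
  M <- sample(2:max_M, 1)
  S <- matrix(sample(0:6, L * G, replace = TRUE) / 2, L, G)
  seqg <- sample(seq_len(G), M, replace = TRUE)
  list(S = S, seqg = seqg, L = L, M = M)
}
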