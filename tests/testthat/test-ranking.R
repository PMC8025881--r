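# Null adjustment, greedy candidate scoring, database ranking, and the
# end-to-end driver.

test_that("configuration defaults and validation", {
  cfg <- seqid_config()
  expect_equal(cfg$max_chains, 3L)
  expect_true(cfg$score_by_residue_groups)
  expect_null(cfg$minimum_discrimination)
  expect_null(cfg$trim_models)
  expect_true(cfg$allow_duplicates)
  expect_false(cfg$skip_if_too_short)
  expect_false(cfg$positive_only)
  expect_equal(sum(cfg$default_sequence), 1, tolerance = 1e-12)
  expect_error(seqid_config(default_sequence = rep(0.1, 20)), "summing")
  expect_error(seqid_config(max_chains = 0))
})

test_that("null mean is zero for an all-zero matrix and collapses for point-mass frequencies", {
  cm0 <- fake_collapsed(matrix(0, 4, 6))
  expect_equal(null_mean(cm0, seq_length = 9, n_null = 5, seed = 1), 0)
  # point mass on W: the null is the deterministic all-W alignment score
  g <- matrix(0, 3, 6); g[, 6] <- c(1, 2, 3)
  cmW <- fake_collapsed(g)
  fW <- stats::setNames(as.numeric(AA_ORDER == "W"), AA_ORDER)
  det_score <- align_segment(cmW, "WWWWW")$raw_score
  expect_warning(
    nm <- null_mean(cmW, seq_length = 5, freqs = fW, n_null = 7, seed = 3),
    "degenerate")
  expect_equal(nm, det_score)
  # determinism
  cm <- fake_collapsed(matrix(runif(24), 4, 6))
  expect_identical(null_mean(cm, 10, n_null = 50, seed = 9),
                   null_mean(cm, 10, n_null = 50, seed = 9))
})

test_that("the Monte-Carlo null agrees with an independent enumeration-based oracle", {
  set.seed(8)
  S <- matrix(sample(0:4, 18, replace = TRUE) / 2, 3, 6)
  cm <- fake_collapsed(S)
  nm <- null_mean(cm, seq_length = 4, n_null = 2000, seed = 11)
  # oracle: 20000 draws scored by brute-force enumeration (no DP involved)
  set.seed(999)
  grp_of_aa <- match(reduced_alphabet()$map[AA_ORDER],
                     reduced_alphabet()$representatives)
  draws <- replicate(20000, {
    seqg <- grp_of_aa[sample(20, 4, replace = TRUE, prob = kj_frequencies)]
    bf_align_score(S, seqg, 2, 0.5)
  })
  se <- sd(draws) / sqrt(20000) + sd(draws) / sqrt(2000)
  expect_lt(abs(nm - mean(draws)), 3 * se)
})

test_that("single-segment candidate score is that segment's adjusted score", {
  cm <- spelled_collapsed("GKYW", hi = 2)
  cfg <- seqid_config(n_null = 50, seed = 4)
  sc <- score_candidate(list(cm), list(seq_id = "s", sequence = "VRFW"), cfg)
  al <- align_segment(cm, "VRFW")
  nm <- null_mean(cm, 4, n_null = 50,
                  seed = cryoseqid:::.mix_seed(4, 1, 4))
  expect_equal(sc$raw_score, al$raw_score)
  expect_equal(sc$adjusted_score, al$raw_score - nm)
})

test_that("skip_if_too_short rejects short candidates with a recorded reason", {
  cm <- spelled_collapsed("GKYWPL")
  cfg <- seqid_config(skip_if_too_short = TRUE, n_null = 5)
  sc <- score_candidate(list(cm), list(seq_id = "s", sequence = "VRF"), cfg)
  expect_true(sc$rejected)
  expect_match(sc$reason, "length")
  cfg2 <- seqid_config(n_null = 5)
  sc2 <- score_candidate(list(cm), list(seq_id = "s", sequence = "VRF"), cfg2)
  expect_false(sc2$rejected)
})

test_that("duplicate restriction only matters when best windows overlap, and matches exhaustive search", {
  # disjoint best windows: identical totals either way
  cm1 <- spelled_collapsed("GKY", hi = 2)
  cm2 <- spelled_collapsed("WPL", hi = 2)
  seqrec <- list(seq_id = "s", sequence = "VRFWPM")
  cfg_dup <- seqid_config(n_null = 30, seed = 6)
  cfg_nodup <- seqid_config(allow_duplicates = FALSE, n_null = 30, seed = 6)
  s1 <- score_candidate(list(cm1, cm2), seqrec, cfg_dup)
  s2 <- score_candidate(list(cm1, cm2), seqrec, cfg_nodup)
  expect_equal(s1$adjusted_score, s2$adjusted_score, tolerance = 1e-9)
  # overlapping best windows: the second segment must move off the window
  cmA <- spelled_collapsed("GKY", hi = 2)
  cmB <- spelled_collapsed("GKY", hi = 1)
  seq2 <- list(seq_id = "s", sequence = "VRFVRF")
  sdup <- score_candidate(list(cmA, cmB), seq2, cfg_dup)
  snod <- score_candidate(list(cmA, cmB), seq2, cfg_nodup)
  expect_gt(sum(sdup$alignments[[1]]$pairs[, 2] %in%
                  sdup$alignments[[2]]$pairs[, 2]), 0L)   # duplicates allowed: windows collide
  expect_equal(sum(snod$alignments[[1]]$pairs[, 2] %in%
                     snod$alignments[[2]]$pairs[, 2]), 0L)
  # greedy with masking equals exhaustive search over joint assignments here
  grp <- cryoseqid:::.seq_groups(seq2$sequence, reduced_alphabet())
  best_joint <- -Inf
  for (first in 1:2) {
    Sa <- if (first == 1) cmA$g else cmB$g
    Sb <- if (first == 1) cmB$g else cmA$g
    # enumerate all window placements for the first, mask, then best second
    for (startj in 0:3) {
      mask <- rep(FALSE, 6)
      mask[startj + 1:3] <- TRUE
      sc_first <- bf_align_score(Sa, grp, 2, 0.5, forbidden = !mask)
      sc_second <- bf_align_score(Sb, grp, 2, 0.5, forbidden = mask)
      best_joint <- max(best_joint, sc_first + sc_second)
    }
  }
  expect_equal(snod$raw_score, best_joint, tolerance = 1e-9)
})

test_that("database ranking standardizes scores and is deterministic under ties", {
  mk <- function(id, adj) structure(list(seq_id = id, raw_score = adj,
                                         null_mean = 0, adjusted_score = adj,
                                         alignments = list(), rejected = FALSE,
                                         reason = NA_character_),
                                    class = "candidate_score")
  r <- rank_database(list(mk("a", 10), mk("b", 0), mk("c", -10)))
  expect_equal(r$db_z, c(10, 0, -10) / sqrt(200 / 3), tolerance = 1e-9)
  expect_equal(r$rank, 1:3)
  expect_equal(mean(r$db_z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(r$db_z^2)), 1, tolerance = 1e-9)
  r2 <- rank_database(list(mk("b", 5), mk("a", 5), mk("c", 1)))
  expect_equal(r2$seq_id[1:2], c("a", "b"))   # tie broken by id
  expect_error(rank_database(list(mk("a", 1))), "at least 2")
  expect_warning(r3 <- rank_database(list(mk("a", 2), mk("b", 2))), "identical")
  expect_equal(r3$db_z, c(0, 0))
})

test_that("end-to-end identification ranks the true sequence first on a clean fixture", {
  fx <- test_fixture()
  res <- identify_protein(fx$map, fx$backbone, fx$database,
                          seqid_config(seed = 42), test_library())
  expect_s3_class(res, "seqid_result")
  expect_equal(res$ranking$seq_id[1], fx$true_id)
  expect_gt(res$ranking$db_z[1], res$ranking$db_z[2])
  td <- tidy(res)
  expect_equal(nrow(td), nrow(fx$database))
  expect_equal(sort(td$rank), seq_len(nrow(td)))
  g <- glance(res)
  expect_equal(g$winner, fx$true_id)
  expect_gt(g$z_margin, 0)
})

test_that("duplicated candidate ids get identical scores and deterministic order", {
  fx <- test_fixture()
  db <- tibble::tibble(seq_id = c("dup_b", "dup_a"),
                       sequence = rep(fx$database$sequence[5], 2))
  suppressWarnings(
    res <- identify_protein(fx$map, fx$backbone, db, seqid_config(seed = 1),
                            test_library()))
  expect_equal(res$ranking$adjusted_score[1], res$ranking$adjusted_score[2])
  expect_equal(res$ranking$seq_id, c("dup_a", "dup_b"))
})

test_that("a database without the true sequence still ranks, with a weaker top score", {
  fx <- test_fixture()
  cfg <- seqid_config(seed = 42)
  with_true <- identify_protein(fx$map, fx$backbone, fx$database, cfg,
                                test_library())
  without <- identify_protein(fx$map, fx$backbone,
                              dplyr::filter(fx$database, seq_id != fx$true_id),
                              cfg, test_library())
  expect_equal(nrow(without$ranking), nrow(fx$database) - 1)
  true_adj <- with_true$ranking$adjusted_score[
    with_true$ranking$seq_id == fx$true_id]
  expect_lt(without$ranking$adjusted_score[1], true_adj)
})
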