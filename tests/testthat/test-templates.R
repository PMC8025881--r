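# Residue frames and the rotamer template library.

test_that("frame construction is exact for the standard pose and inverts known rotations", {
  std <- cryoseqid:::.std_backbone
  fr <- build_frame(std$N, std$CA, std$C)
  expect_equal(fr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fr$translation, c(0, 0, 0))
  # rigidly transformed residue: recovered rotation equals the applied one
  th <- 0.83
  ax <- c(1, 2, -0.5) / sqrt(sum(c(1, 2, -0.5)^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- c(4, -2, 7)
  fr2 <- build_frame(R %*% std$N + tr, R %*% std$CA + tr, R %*% std$C + tr)
  expect_equal(fr2$rotation, R, tolerance = 1e-6)
  expect_equal(fr2$translation, as.numeric(R %*% std$CA + tr), tolerance = 1e-9)
  expect_error(build_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "degenerate")
})

test_that("frame rotation is always orthonormal with determinant +1 (equivariance property)", {
  set.seed(5)
  for (i in 1:25) {
    n <- rnorm(3); ca <- rnorm(3); cc <- rnorm(3)
    if (cryoseqid:::.vnorm(cryoseqid:::.cross3(n - ca, cc - ca)) < 1e-3) next
    fr <- build_frame(n, ca, cc)
    expect_equal(t(fr$rotation) %*% fr$rotation, diag(3), tolerance = 1e-8)
    expect_equal(det(fr$rotation), 1, tolerance = 1e-8)
  }
})

test_that("idealized library has the topology-forced rotamer counts and is deterministic", {
  lib <- test_library()
  types <- vapply(lib$templates, `[[`, "", "residue_type")
  expect_setequal(unique(types), unname(AA_THREE))
  counts <- table(types)
  expect_equal(unname(counts[["ALA"]]), 1L)   # no chi angles
  expect_equal(unname(counts[["GLY"]]), 1L)   # CB probe only
  expect_equal(unname(counts[["LEU"]]),
               unname(rotamer_counts()[["LEU"]]))
  # every template region is usable for correlation
  expect_true(all(vapply(lib$templates, function(t) nrow(t$offsets) >= 8, NA)))
  lib2 <- idealized_template_library()
  expect_identical(lib, lib2)
})

test_that("learning from a single noise-free example reproduces its normalized density with zero variance", {
  # one LEU residue exactly on a canonical rotamer
  model <- build_polypeptide("GLG", seed = 1)
  map <- simulate_density_map(model, resolution = 3.0, voxel = 0.5)
  lib <- suppressWarnings(learn_template_library(list(list(map = map, model = model)),
                                                 n_min = 1))
  learned <- Filter(function(t) t$provenance == "learned" &&
                      t$residue_type == "LEU", lib$templates)
  expect_length(learned, 1)
  t1 <- learned[[1]]
  expect_equal(t1$n_examples, 1L)
  expect_equal(t1$var_density, rep(0, length(t1$var_density)), tolerance = 1e-12)
  # oracle: interpolate the map at the frame-carried offsets and z-normalize
  bb <- backbone_from_model(model)
  i <- 2
  fr <- build_frame(c(bb$n_x[i], bb$n_y[i], bb$n_z[i]),
                    c(bb$ca_x[i], bb$ca_y[i], bb$ca_z[i]),
                    c(bb$c_x[i], bb$c_y[i], bb$c_z[i]))
  pts <- cryoseqid:::.frame_apply(fr, t1$offsets)
  v <- interpolate_density(map, data.frame(x = pts[, 1], y = pts[, 2],
                                           z = pts[, 3]))$density
  expect_equal(t1$mean_density, (v - mean(v)) / sd(v), tolerance = 1e-9)
})

test_that("learned per-offset variance tracks injected map noise", {
  model <- build_polypeptide("GMG", seed = 2)
  base <- simulate_density_map(model, resolution = 3.0, voxel = 0.5)
  # oracle scale: the noise-free region SD seen by the learner
  clean <- suppressWarnings(learn_template_library(
    list(list(map = base, model = model)), n_min = 1))
  tref <- Filter(function(t) t$provenance == "learned" &&
                   t$residue_type == "MET", clean$templates)[[1]]
  bb <- backbone_from_model(model)
  fr <- build_frame(c(bb$n_x[2], bb$n_y[2], bb$n_z[2]),
                    c(bb$ca_x[2], bb$ca_y[2], bb$ca_z[2]),
                    c(bb$c_x[2], bb$c_y[2], bb$c_z[2]))
  pts <- cryoseqid:::.frame_apply(fr, tref$offsets)
  v0 <- interpolate_density(base, data.frame(x = pts[, 1], y = pts[, 2],
                                             z = pts[, 3]))$density
  S <- sd(v0)
  sigma <- 0.1 * S
  # trilinear interpolation averages 8 voxels, shrinking i.i.d. voxel noise
  # by the sum of squared weights at each point's fractional offset
  frac <- sweep(sweep(pts, 2, base$origin, "-"), 2, base$voxel, "/")
  tt <- frac - floor(frac)
  w2 <- apply((1 - tt)^2 + tt^2, 1, prod)
  examples <- lapply(1:100, function(s) {
    m <- base
    set.seed(1000 + s)
    m$grid <- m$grid + array(rnorm(length(m$grid), sd = sigma), dim(m$grid))
    list(map = m, model = model)
  })
  lib <- suppressWarnings(learn_template_library(examples, n_min = 3))
  tl <- Filter(function(t) t$provenance == "learned" &&
                 t$residue_type == "MET", lib$templates)[[1]]
  expect_equal(tl$n_examples, 100L)
  # normalization divides each example by its region SD ~ S, so the
  # expected per-offset variance is (sigma/S)^2 times the interpolation
  # shrinkage factor; Monte-Carlo agreement within 20% on the region mean
  expected_var <- (sigma / S)^2 * w2
  ratio <- mean(tl$var_density) / mean(expected_var)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("template correlation has the Pearson identities", {
  lib <- test_library()
  tmpl <- Filter(function(t) t$residue_type == "TRP", lib$templates)[[1]]
  # build a map whose interpolated values at the offsets equal the template
  # mean exactly: a fine grid rendered from the same Gaussian field
  model_df <- tibble::tibble(chain = "A", resno = 1, resname = "TRP",
                             atom = "CA", x = 0, y = 0, z = 0)
  fr <- list(rotation = diag(3), translation = c(0, 0, 0))
  # map on a fine lattice storing the template field itself
  pad <- 3
  lo <- apply(tmpl$offsets, 2, min) - pad
  hi <- apply(tmpl$offsets, 2, max) + pad
  vox <- 1.0
  d <- as.integer(ceiling((hi - lo) / vox)) + 1L
  ax <- lapply(1:3, function(k) lo[k] + vox * (0:(d[k] - 1)))
  # trick: template offsets lie on a 1 A lattice, so choose the map lattice
  # to coincide with it and write the template values into those voxels
  g <- array(0, d)
  idx <- sweep(tmpl$offsets, 2, lo, "-") / vox
  g[cbind(idx[, 1], idx[, 2], idx[, 3]) + 1] <- tmpl$mean_density
  m <- density_map(g, origin = lo, voxel = rep(vox, 3))
  expect_equal(correlate_template(m, fr, tmpl), 1.0, tolerance = 1e-9)
  m_neg <- density_map(-g, origin = lo, voxel = rep(vox, 3))
  expect_equal(correlate_template(m_neg, fr, tmpl), -1.0, tolerance = 1e-9)
  m_aff <- density_map(3.7 * g + 11, origin = lo, voxel = rep(vox, 3))
  expect_equal(correlate_template(m_aff, fr, tmpl), 1.0, tolerance = 1e-9)
  m_const <- density_map(array(5, d), origin = lo, voxel = rep(vox, 3))
  expect_equal(correlate_template(m_const, fr, tmpl), 0)
})
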