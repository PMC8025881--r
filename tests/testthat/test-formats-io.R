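# Map, model and sequence I/O.

test_that("MRC round trip preserves grid, origin and voxel", {
  set.seed(7)
  m <- density_map(array(rnorm(4 * 3 * 5), c(4, 3, 5)),
                   origin = c(-1.5, 2, 0.25), voxel = c(0.8, 1, 1.2))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_density_map(m, f)
  r1 <- read_density_map(f)
  # values pass through float32 once; a second round trip must be bitwise
  write_density_map(r1, f)
  r2 <- read_density_map(f)
  expect_identical(r2$grid, r1$grid)
  expect_equal(r1$grid, m$grid, tolerance = 1e-6)
  expect_equal(r1$origin, m$origin, tolerance = 1e-6)
  expect_equal(r1$voxel, m$voxel, tolerance = 1e-6)
})

test_that("permuted-axis MRC files are reordered to canonical x,y,z", {
  # hand-crafted file with MAPC,MAPR,MAPS = 3,2,1 (columns run along z)
  v <- array(seq_len(2 * 3 * 4), c(2, 3, 4))   # canonical x,y,z truth
  f <- withr::local_tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  d_file <- c(4, 3, 2)                         # counts along file axes z,y,x
  wi(d_file); wi(2); wi(c(0, 0, 0)); wi(c(2, 3, 4))
  wf(c(2, 3, 4)); wf(c(90, 90, 90))
  wi(c(3, 2, 1))
  wf(c(0, 0, 0)); wi(c(1, 0)); wi(rep(0, 25)); wf(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0); writeBin(raw(800), con)
  # file data: index (c=z, r=y, s=x) fastest-first
  arr_file <- aperm(v, c(3, 2, 1))             # oracle: direct index remap
  writeBin(as.numeric(arr_file), con, size = 4, endian = "little")
  close(con)
  m <- read_density_map(f)
  expect_identical(dim(m$grid), dim(v))
  expect_equal(m$grid, v + 0, tolerance = 1e-7)
})

test_that("corrupt and truncated map files raise format errors", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(1:100), f)
  expect_error(read_density_map(f), "corrupt")
  m <- density_map(array(1:8 + 0, c(2, 2, 2)))
  write_density_map(m, f)
  raw_all <- readBin(f, "raw", file.size(f))
  writeBin(raw_all[1:1040], f)
  expect_error(read_density_map(f), "truncated")
})

test_that("interpolation is exact at voxel centers, midpoints, and linear ramps", {
  set.seed(11)
  g <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  m <- density_map(g, origin = c(1, -2, 0.5), voxel = c(0.7, 1.1, 0.9))
  # voxel center
  p <- c(1 + 2 * 0.7, -2 + 1 * 1.1, 0.5 + 3 * 0.9)
  expect_equal(interpolate_density(m, rbind(p))$density, g[3, 2, 4])
  # midpoint along x
  pm <- p + c(0.35, 0, 0)
  expect_equal(interpolate_density(m, rbind(pm))$density,
               (g[3, 2, 4] + g[4, 2, 4]) / 2)
  # linear ramp f(x,y,z) = x recovered exactly anywhere inside
  ramp <- array(rep(1 + 0.7 * (0:4), 4 * 6), c(5, 4, 6))
  mr <- density_map(ramp, origin = c(1, -2, 0.5), voxel = c(0.7, 1.1, 0.9))
  pts <- cbind(runif(50, 1.01, 1 + 4 * 0.7 - 0.01),
               runif(50, -1.99, -2 + 3 * 1.1 - 0.01),
               runif(50, 0.51, 0.5 + 5 * 0.9 - 0.01))
  expect_equal(interpolate_density(mr, pts)$density, pts[, 1],
               tolerance = 1e-10)
  # outside point: zero and flagged
  out <- interpolate_density(m, rbind(c(-100, 0, 0)))
  expect_equal(out$density, 0)
  expect_false(out$inside)
})

test_that("backbone reading splits chains at CA-CA gaps and rejects side-chain-only input", {
  model <- build_polypeptide(strrep("A", 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(model, f)
  bb <- read_backbone(f)
  expect_equal(length(unique(bb$segment_id)), 1L)
  expect_equal(nrow(bb), 10L)
  # deleting residue 5 leaves a > 5 A CA gap in the extended chain
  write_model(dplyr::filter(model, resno != 5), f)
  bb2 <- read_backbone(f)
  expect_equal(as.integer(sort(table(bb2$segment_id))), c(4L, 5L))
  # only side-chain atoms: no usable residue
  write_model(dplyr::filter(model, atom == "CB"), f)
  expect_error(suppressWarnings(read_backbone(f)), "usable")
})

test_that("model write -> backbone read round-trips coordinates at PDB precision", {
  model <- build_polypeptide("ACDEFGHIKLMNPQRSTVWY", seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(model, f)
  bb <- read_backbone(f)
  truth <- backbone_from_model(model)
  expect_equal(nrow(bb), nrow(truth))
  expect_equal(bb$ca_x, truth$ca_x, tolerance = 1e-3)
  expect_equal(bb$ca_y, truth$ca_y, tolerance = 1e-3)
  expect_equal(bb$n_z, truth$n_z, tolerance = 1e-3)
})

test_that("FASTA reading handles wrapped records and the non-standard-letter policies", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first", "ACDEF", "GHIKL", ">s2", "WWPK"), f)
  db <- read_fasta(f)
  expect_equal(db$seq_id, c("s1", "s2"))
  expect_equal(db$sequence, c("ACDEFGHIKL", "WWPK"))
  writeLines(c(">s1", "ACXDE"), f)
  expect_error(read_fasta(f, policy = "strict"), "non-standard")
  expect_equal(read_fasta(f, policy = "lenient")$sequence, "ACGDE")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})
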