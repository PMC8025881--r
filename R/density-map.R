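# Density map container, trilinear interpolation, and MRC/CCP4 2014 file
# input/output. The map is stored with a canonical x,y,z axis order, a
# 0-based grid whose index (0,0,0) sits at `origin` (Angstrom), and voxel
# spacings in Angstrom per voxel.

#' Construct a density map
#'
#' @param grid 3D numeric array of density values (arbitrary units).
#' @param origin Length-3 numeric, position (Angstrom) of grid index (0,0,0).
#' @param voxel Length-3 numeric, voxel spacings in Angstrom (> 0).
#' @return Object of class `density_map`.
#' @export
density_map <- function(grid, origin = c(0, 0, 0), voxel = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array", call. = FALSE)
  if (any(dim(grid) < 2L)) stop("all grid dimensions must be >= 2", call. = FALSE)
  voxel <- rep_len(as.numeric(voxel), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(voxel <= 0)) stop("voxel spacings must be > 0", call. = FALSE)
  if (!all(is.finite(grid))) stop("grid contains non-finite values", call. = FALSE)
  structure(list(grid = grid, origin = origin, voxel = voxel),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", paste(dim(x$grid), collapse = " x "),
      " voxels; voxel ", paste(signif(x$voxel, 4), collapse = "/"),
      " A; origin ", paste(signif(x$origin, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Fast internal trilinear interpolation. `pts` is an n x 3 matrix in
# Angstrom. Out-of-box points get value 0; returns list(values, inside).
.interp <- function(map, pts) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(map$grid)
  f1 <- (pts[, 1] - map$origin[1]) / map$voxel[1]
  f2 <- (pts[, 2] - map$origin[2]) / map$voxel[2]
  f3 <- (pts[, 3] - map$origin[3]) / map$voxel[3]
  i1 <- floor(f1); i2 <- floor(f2); i3 <- floor(f3)
  inside <- i1 >= 0 & i2 >= 0 & i3 >= 0 &
    i1 <= d[1] - 2 & i2 <= d[2] - 2 & i3 <= d[3] - 2
  vals <- numeric(nrow(pts))
  if (any(inside)) {
    j1 <- i1[inside]; j2 <- i2[inside]; j3 <- i3[inside]
    t1 <- f1[inside] - j1; t2 <- f2[inside] - j2; t3 <- f3[inside] - j3
    base <- 1 + j1 + d[1] * (j2 + d[2] * j3)
    g <- map$grid
    s1 <- 1; s2 <- d[1]; s3 <- d[1] * d[2]
    v000 <- g[base];             v100 <- g[base + s1]
    v010 <- g[base + s2];        v110 <- g[base + s1 + s2]
    v001 <- g[base + s3];        v101 <- g[base + s1 + s3]
    v011 <- g[base + s2 + s3];   v111 <- g[base + s1 + s2 + s3]
    c00 <- v000 * (1 - t1) + v100 * t1
    c10 <- v010 * (1 - t1) + v110 * t1
    c01 <- v001 * (1 - t1) + v101 * t1
    c11 <- v011 * (1 - t1) + v111 * t1
    c0 <- c00 * (1 - t2) + c10 * t2
    c1 <- c01 * (1 - t2) + c11 * t2
    vals[inside] <- c0 * (1 - t3) + c1 * t3
  }
  list(values = vals, inside = inside)
}

#' Interpolate map density at points
#'
#' Trilinear interpolation, exact at voxel centers. Points outside the grid
#' bounding box return density 0 and are flagged `inside = FALSE`.
#'
#' @param map A [density_map].
#' @param points Data frame or matrix with columns/cols x, y, z (Angstrom).
#' @return Tibble with `x`, `y`, `z`, `density`, `inside`.
#' @export
interpolate_density <- function(map, points) {
  stopifnot(inherits(map, "density_map"))
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  r <- .interp(map, points)
  tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3],
                 density = r$values, inside = r$inside)
}

# ---- MRC/CCP4 2014 ----------------------------------------------------

#' Read an MRC/CCP4 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32) and arbitrary axis
#' permutations, which are reordered to the canonical x,y,z storage. The
#' working origin is the ORIGIN record plus NX/NY/NZSTART offsets times the
#' voxel size.
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A [density_map].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("corrupt MRC header: file truncated", call. = FALSE)
  ints <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = "little")
  flts <- readBin(hdr_raw, "numeric", n = 256, size = 4, endian = "little")
  magic <- rawToChar(hdr_raw[209:212])
  if (!startsWith(magic, "MAP")) stop("corrupt MRC header: missing MAP magic", call. = FALSE)
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]
  m_xyz <- ints[8:10]
  cella <- flts[11:13]
  mapcrs <- ints[17:19]
  orig <- flts[50:52]
  if (any(c(nc, nr, ns) < 1) || any(c(nc, nr, ns) > 1e5)) {
    stop("corrupt MRC header: implausible dimensions", call. = FALSE)
  }
  if (!all(sort(mapcrs) == 1:3)) {
    stop("unsupported axis correspondence in MRC header", call. = FALSE)
  }
  nvox <- as.numeric(nc) * nr * ns
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode, call. = FALSE))
  if (length(dat) < nvox) stop("corrupt MRC file: data truncated", call. = FALSE)
  arr <- array(dat, dim = c(nc, nr, ns))
  perm <- match(1:3, mapcrs)   # result axis k comes from file axis perm[k]
  arr <- aperm(arr, perm)
  if (any(m_xyz < 1)) m_xyz <- dim(arr)
  voxel <- cella / m_xyz
  voxel[!is.finite(voxel) | voxel <= 0] <- 1
  origin <- orig + nstart[perm] * voxel
  density_map(arr, origin = origin, voxel = voxel)
}

#' Write a density map as MRC2014
#'
#' Writes mode-2 (float32) data in canonical x,y,z axis order with the map
#' origin in the ORIGIN header record.
#'
#' @param map A [density_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  g <- as.numeric(map$grid)
  wi(d)                     # NX NY NZ
  wi(2)                     # MODE float32
  wi(c(0, 0, 0))            # NXSTART..
  wi(d)                     # MX MY MZ
  wf(d * map$voxel)         # CELLA
  wf(c(90, 90, 90))         # CELLB
  wi(1:3)                   # MAPC MAPR MAPS
  wf(c(min(g), max(g), mean(g)))  # DMIN DMAX DMEAN
  wi(c(1, 0))               # ISPG NSYMBT
  wi(rep(0, 25))            # EXTRA (words 25-49)
  wf(map$origin)            # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(g))          # RMS
  wi(1)                     # NLABL
  lab <- charToRaw(formatC("cryoseqid", width = -80))
  writeBin(lab[1:80], con)
  writeBin(raw(800 - 80), con)
  writeBin(g, con, size = 4, endian = "little")
  invisible(path)
}
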