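# 3D geometry: residue frames, internal-coordinate atom placement (NeRF),
# ideal polypeptide construction, torsion measurement.

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed torsion angle p1-p2-p3-p4 in degrees.
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Natural-extension-reference-frame placement: position of atom D at `bond`
# from C, with angle D-C-B and torsion D-C-B-A (degrees).
.nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build the standard main-chain frame of a residue
#'
#' Constructs the rigid transform mapping the residue standard frame (CA at
#' the origin, C on +x, N in the xy-plane with positive y) onto the world
#' coordinates of a residue, from its N, CA and C atoms. The rotation columns
#' are the Gram-Schmidt frame: x along CA->C, y the component of CA->N
#' orthogonal to x, z = x cross y.
#'
#' @param n,ca,c Numeric length-3 coordinates (Angstrom) of the main-chain
#'   N, CA and C atoms.
#' @return List with `rotation` (3x3, orthonormal, det +1) and
#'   `translation` (the CA position); world = rotation %*% standard + translation.
#' @export
build_frame <- function(n, ca, c) {
  n <- as.numeric(n); ca <- as.numeric(ca); c <- as.numeric(c)
  v_c <- c - ca
  v_n <- n - ca
  if (.vnorm(v_c) < 1e-6 || .vnorm(v_n) < 1e-6) {
    stop("degenerate frame: coincident main-chain atoms", call. = FALSE)
  }
  x <- .unit(v_c)
  y0 <- v_n - sum(v_n * x) * x
  if (.vnorm(y0) < 1e-4) {
    stop("degenerate frame: collinear N, CA, C", call. = FALSE)
  }
  y <- .unit(y0)
  z <- .cross3(x, y)
  list(rotation = cbind(x, y, z, deparse.level = 0), translation = ca)
}

# Apply a frame to an n x 3 matrix of standard-frame points.
.frame_apply <- function(frame, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(frame$rotation), 2, frame$translation, "+")
}

# Place the side-chain heavy atoms of `resname` with the given chi vector,
# in an arbitrary frame defined by the backbone atom coordinates (a named
# list with N, CA, C). Returns a named list of length-3 coordinates.
.place_sidechain <- function(resname, chis, backbone) {
  zm <- .sidechain_zmat[[resname]]
  if (is.null(zm)) stop("unknown residue type: ", resname, call. = FALSE)
  atoms <- backbone
  for (r in zm) {
    tor <- if (r$ref == "none") r$off else chis[[r$ref]] + r$off
    atoms[[r$atom]] <- .nerf(atoms[[r$p3]], atoms[[r$p2]], atoms[[r$p1]],
                             r$bond, r$angle, tor)
  }
  atoms[setdiff(names(atoms), c("N", "CA", "C", "O"))]
}

# Standard-frame side-chain coordinates for one rotamer, as an n x 3 matrix
# with atom-name rownames. For glycine returns the pseudo-CB probe position.
.std_sidechain <- function(resname, chis) {
  bb <- .std_backbone
  if (resname == "GLY") {
    r <- .cb_row()
    cb <- .nerf(bb[[r$p3]], bb[[r$p2]], bb[[r$p1]], r$bond, r$angle, r$off)
    return(matrix(cb, nrow = 1, dimnames = list("CB*", NULL)))
  }
  sc <- .place_sidechain(resname, as.list(chis), bb)
  do.call(rbind, sc)
}

# Measure the rotameric chi angles of a full-atom residue given as a named
# list of coordinates; returns numeric vector (possibly length 0) or NULL
# when a defining atom is missing.
.measure_chis <- function(resname, atoms) {
  defs <- .chi_atoms[[resname]]
  if (is.null(defs)) return(NULL)
  out <- numeric(0)
  for (chi in names(defs)) {
    nm <- defs[[chi]]
    if (!all(nm %in% names(atoms))) return(NULL)
    out[chi] <- .torsion(atoms[[nm[1]]], atoms[[nm[2]]], atoms[[nm[3]]],
                         atoms[[nm[4]]])
  }
  out
}

# Nearest canonical rotamer (row index of .rotamer_chis[[resname]]) within
# `window` degrees on every chi, or NA when unbinnable.
.bin_rotamer <- function(resname, chis, window = 40) {
  tab <- .rotamer_chis[[resname]]
  if (nrow(tab) == 1 && ncol(tab) == 0) return(1L)
  if (is.null(chis) || length(chis) < ncol(tab)) return(NA_integer_)
  d <- abs(sweep(tab, 2, chis[seq_len(ncol(tab))], "-")) %% 360
  d <- pmin(d, 360 - d)
  ok <- apply(d, 1, max) <= window
  if (!any(ok)) return(NA_integer_)
  which.min(ifelse(ok, rowSums(d), Inf))
}

#' Build an ideal polypeptide model
#'
#' Generates a full-atom model of a linear polypeptide with the given
#' sequence and backbone torsions, with side chains placed on canonical
#' rotamers (sampled uniformly per residue under `seed`). Used as ground
#' truth by the synthetic-fixture generator.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi Backbone torsions in degrees (defaults give an extended
#'   beta-like conformation so that consecutive side chains stay resolved).
#' @param seed Integer seed controlling the per-residue rotamer draw.
#' @return Tibble with columns `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`, `element`.
#' @export
build_polypeptide <- function(sequence, phi = -140, psi = 135, seed = 1) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (!length(letters1)) stop("empty sequence", call. = FALSE)
  if (!all(letters1 %in% AA_ORDER)) {
    stop("sequence contains non-standard letters", call. = FALSE)
  }
  res3 <- AA_THREE[letters1]
  g <- .bb_geom
  omega <- 180
  # first residue backbone
  n1 <- c(0, 0, 0)
  ca1 <- c(g$n_ca, 0, 0)
  c1 <- .nerf(c(0, 1, 0), n1, ca1, g$ca_c, g$ang_n_ca_c, 60)
  bb <- vector("list", length(res3))
  bb[[1]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_along(res3)[-1]) {
    prev <- bb[[i - 1]]
    ni <- .nerf(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi)
    cai <- .nerf(prev$CA, prev$C, ni, g$n_ca, g$ang_c_n_ca, omega)
    ci <- .nerf(prev$C, ni, cai, g$ca_c, g$ang_n_ca_c, phi)
    bb[[i]] <- list(N = ni, CA = cai, C = ci)
  }
  # carbonyl O from the next residue's N (trans peptide); last residue gets
  # psi-based placement.
  rows <- list()
  rng <- .local_rng(seed)
  for (i in seq_along(res3)) {
    atoms <- bb[[i]]
    if (i < length(res3)) {
      atoms$O <- .nerf(bb[[i + 1]]$N, atoms$CA, atoms$C, g$c_o,
                       g$ang_ca_c_o, 180)
    } else {
      atoms$O <- .nerf(atoms$N, atoms$CA, atoms$C, g$c_o, g$ang_ca_c_o,
                       psi + 180)
    }
    tab <- .rotamer_chis[[res3[i]]]
    k <- if (nrow(tab) <= 1) 1L else rng$int(nrow(tab))
    chis <- if (ncol(tab)) as.list(tab[k, , drop = TRUE]) else list()
    if (res3[i] != "GLY") {
      atoms <- c(atoms, .place_sidechain(res3[i], chis,
                                         atoms[c("N", "CA", "C")]))
    }
    for (a in names(atoms)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chain = "A", resno = i, resname = res3[i], atom = a,
        x = atoms[[a]][1], y = atoms[[a]][2], z = atoms[[a]][3],
        element = substr(a, 1, 1))
    }
  }
  dplyr::bind_rows(rows)
}

# Small deterministic RNG helper that does not disturb the global RNG state.
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    int = function(n) with_state(function() sample.int(n, 1L)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      with_state(function() sample(x, size, replace = replace, prob = prob))
  )
}
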