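# Rotamer density template library: expected side-chain density (mean and
# variance) at grid offsets in the residue standard frame, one template per
# rotamer per residue type. Templates can be rendered from ideal geometry
# ("idealized") or accumulated from example map/model pairs ("learned").
# Rotamers are used unweighted: no frequency enters scoring.

.TEMPLATE_REGION_RADIUS <- 2.5  # Angstrom around side-chain atoms

# Gaussian width for a nominal resolution: a single-Gaussian atom model
# with sigma = resolution / (pi * sqrt(2)).
.res_sigma <- function(resolution) resolution / (pi * sqrt(2))

# Grid offsets (n x 3) at `spacing` within `radius` of any row of `atoms`.
.region_offsets <- function(atoms, spacing, radius = .TEMPLATE_REGION_RADIUS) {
  atoms <- matrix(atoms, ncol = 3)
  lo <- floor((apply(atoms, 2, min) - radius) / spacing)
  hi <- ceiling((apply(atoms, 2, max) + radius) / spacing)
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  g <- g * spacing
  d2min <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(atoms))) {
    d2 <- (g[, 1] - atoms[i, 1])^2 + (g[, 2] - atoms[i, 2])^2 +
      (g[, 3] - atoms[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  g[d2min <= radius^2, , drop = FALSE]
}

# Render Gaussian-atom density at points for atoms (n x 3) with weights.
.render_density <- function(points, atoms, weights, sigma) {
  atoms <- matrix(atoms, ncol = 3)
  v <- numeric(nrow(points))
  for (i in seq_len(nrow(atoms))) {
    d2 <- (points[, 1] - atoms[i, 1])^2 + (points[, 2] - atoms[i, 2])^2 +
      (points[, 3] - atoms[i, 3])^2
    v <- v + weights[i] * exp(-d2 / (2 * sigma^2))
  }
  v
}

.znorm <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Idealized rotamer template library
#'
#' Renders the expected side-chain density for every canonical rotamer of
#' every residue type from ideal geometry, as Gaussian atoms of width
#' sigma = resolution / (pi * sqrt(2)), at standard-frame grid offsets
#' within 2.5 Angstrom of the side-chain atoms. The residue's own N, CA, C
#' and CB contribute to the expected density; each template is normalized
#' to zero mean and unit SD over its region, so scoring is scale-free.
#' Glycine carries a pseudo-CB probe region (no side-chain atoms), which is
#' what distinguishes it from alanine.
#'
#' @param resolution Nominal map resolution in Angstrom (default 3.0).
#' @param grid_spacing Offset grid spacing in Angstrom; defaults to
#'   `resolution / 3` so template sampling tracks the feature scale, the
#'   usual cryo-EM convention of ~3x oversampling.
#' @return Object of class `template_library`.
#' @export
idealized_template_library <- function(resolution = 3.0,
                                       grid_spacing = resolution / 3) {
  sigma <- .res_sigma(resolution)
  bb <- .std_backbone
  templates <- list()
  for (res in names(.sidechain_zmat)) {
    tab <- .rotamer_chis[[res]]
    nrot <- nrow(tab)
    for (k in seq_len(nrot)) {
      chis <- if (ncol(tab)) tab[k, , drop = TRUE] else numeric(0)
      sc <- .std_sidechain(res, chis)
      offs <- .region_offsets(sc, grid_spacing)
      # density from real atoms: side chain (glycine has none) + N, CA, C, CB
      real_sc <- if (res == "GLY") NULL else sc
      atoms <- rbind(real_sc, do.call(rbind, bb))
      anames <- c(if (!is.null(real_sc)) rownames(sc), names(bb))
      w <- .element_weight[substr(anames, 1, 1)]
      mean_d <- .znorm(.render_density(offs, atoms, w, sigma))
      templates[[length(templates) + 1L]] <- list(
        residue_type = res,
        rotamer_id = sprintf("%s_%d", res, k),
        chis = chis,
        offsets = offs,
        mean_density = mean_d,
        var_density = rep(0, length(mean_d)),
        n_examples = 0L,
        provenance = "idealized")
    }
  }
  structure(list(templates = templates, grid_spacing = grid_spacing,
                 resolution = resolution, provenance = "idealized"),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  types <- vapply(x$templates, `[[`, "", "residue_type")
  cat("<template_library> ", length(x$templates), " rotamer templates over ",
      length(unique(types)), " residue types; spacing ", x$grid_spacing,
      " A; ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Learn a rotamer template library from examples
#'
#' Accumulates, for each canonical rotamer bin, the per-offset mean and
#' variance of observed density around full-atom example residues. Each
#' example residue is assigned to the nearest canonical rotamer by its chi
#' angles (within a +/-40 degree window; unbinnable residues are skipped),
#' its density is interpolated at the idealized template offsets carried
#' into the residue's standard frame, and z-normalized over the region
#' before accumulation (maps have arbitrary scale). Bins with fewer than
#' `n_min` examples fall back to the idealized template, with a warning.
#'
#' @param examples List of `list(map = density_map, model = atom tibble)`
#'   pairs; models must carry full side chains.
#' @param resolution,grid_spacing Passed to the idealized scaffold library.
#' @param n_min Minimum example count for "learned" status (default 3).
#' @return A `template_library` with per-template provenance.
#' @export
learn_template_library <- function(examples, resolution = 3.0,
                                   grid_spacing = resolution / 3, n_min = 3) {
  lib <- idealized_template_library(resolution, grid_spacing)
  acc <- lapply(lib$templates, function(t)
    list(s = numeric(length(t$mean_density)),
         s2 = numeric(length(t$mean_density)), n = 0L))
  rot_index <- stats::setNames(seq_along(lib$templates),
                               vapply(lib$templates, `[[`, "", "rotamer_id"))
  for (ex in examples) {
    stopifnot(inherits(ex$map, "density_map"))
    resids <- ex$model |>
      dplyr::group_by(.data$chain, .data$resno) |>
      dplyr::group_split()
    for (r in resids) {
      res <- r$resname[1]
      if (!res %in% names(.sidechain_zmat)) next
      atoms <- stats::setNames(
        lapply(seq_len(nrow(r)), function(i) c(r$x[i], r$y[i], r$z[i])),
        r$atom)
      if (!all(c("N", "CA", "C") %in% names(atoms))) next
      chis <- .measure_chis(res, atoms)
      bin <- .bin_rotamer(res, chis)
      if (is.na(bin)) next
      id <- sprintf("%s_%d", res, bin)
      ti <- rot_index[[id]]
      tmpl <- lib$templates[[ti]]
      fr <- build_frame(atoms$N, atoms$CA, atoms$C)
      pts <- .frame_apply(fr, tmpl$offsets)
      v <- .znorm(.interp(ex$map, pts)$values)
      acc[[ti]]$s <- acc[[ti]]$s + v
      acc[[ti]]$s2 <- acc[[ti]]$s2 + v^2
      acc[[ti]]$n <- acc[[ti]]$n + 1L
    }
  }
  n_fallback <- 0L
  for (ti in seq_along(lib$templates)) {
    n <- acc[[ti]]$n
    if (n >= n_min) {
      m <- acc[[ti]]$s / n
      lib$templates[[ti]]$mean_density <- m
      lib$templates[[ti]]$var_density <- pmax(0, acc[[ti]]$s2 / n - m^2)
      lib$templates[[ti]]$n_examples <- n
      lib$templates[[ti]]$provenance <- "learned"
    } else {
      n_fallback <- n_fallback + 1L
    }
  }
  if (n_fallback > 0) {
    warning(n_fallback,
            " rotamer bin(s) had fewer than n_min examples; idealized ",
            "templates kept for them")
  }
  lib$provenance <- "learned"
  lib
}

#' Correlate a rotamer template with map density
#'
#' Pearson correlation between a template's expected density and the map
#' density interpolated at the template offsets carried into a residue's
#' world frame. Returns 0 when the observed density is constant over the
#' region (correlation undefined).
#'
#' @param map A [density_map].
#' @param frame A frame from [build_frame()].
#' @param template One element of `template_library$templates`.
#' @return Correlation in `[-1, 1]`.
#' @export
correlate_template <- function(map, frame, template) {
  m <- template$mean_density
  if (length(m) < 8 || stats::sd(m) < 1e-12) {
    stop("degenerate template: too few offsets or constant expected density",
         call. = FALSE)
  }
  pts <- .frame_apply(frame, template$offsets)
  obs <- .interp(map, pts)$values
  if (stats::sd(obs) < 1e-12) return(0)
  stats::cor(m, obs)
}

# Pack a library for fast per-position scoring: concatenated offsets with
# per-offset template index, centered template vectors and their norms,
# and template -> residue-type bookkeeping.
.pack_library <- function(library) {
  tl <- library$templates
  n_off <- vapply(tl, function(t) nrow(t$offsets), integer(1))
  idx <- rep(seq_along(tl), n_off)
  offs <- do.call(rbind, lapply(tl, `[[`, "offsets"))
  tc <- unlist(lapply(tl, function(t) t$mean_density - mean(t$mean_density)),
               use.names = FALSE)
  tcn <- vapply(tl, function(t) {
    v <- t$mean_density - mean(t$mean_density)
    sqrt(sum(v^2))
  }, numeric(1))
  types <- vapply(tl, `[[`, "", "residue_type")
  list(offsets = offs, tmpl_of = idx, tc = tc, tcn = tcn, n_off = n_off,
       types = types, type_one = AA_ONE[types],
       rot_ids = vapply(tl, `[[`, "", "rotamer_id"))
}
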