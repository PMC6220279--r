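#' Virtually section a phantom into serial histological sections
#'
#' Cuts the label volume into consecutive slabs of uniform thickness `T`
#' along one axis, with a systematic-uniform-random start in `[0, T)`.
#' Every cell is assigned to exactly one slab by its reference point (the
#' nucleus centroid); slabs partition the whole grid extent, so partial
#' end slabs are kept. For each section and region an exact equivalent
#' area is recorded: the voxel-slab intersection volume divided by `T`,
#' so that `sum(area) * T` reproduces the voxelized region volume exactly
#' for any start.
#'
#' @param vol a `label_volume`.
#' @param cells optional `cell_population` to assign to sections.
#' @param thickness_um section thickness T in micrometres.
#' @param axis sectioning axis (1, 2 or 3; default 3, the coronal axis of
#'   the phantom frame).
#' @param start random start in `[0, T)`; drawn uniformly when `NULL`.
#' @param seed optional RNG seed for the start.
#' @return a `section_series` list: `sections` (index, z_lo, z_hi),
#'   `areas_um2` (sections x regions matrix of equivalent areas),
#'   `cells` (with a `section` column), plus the generating metadata.
#' @export
section_phantom <- function(vol, cells = NULL, thickness_um, axis = 3,
                            start = NULL, seed = NULL) {
  stopifnot_scalar_pos(thickness_um, "thickness_um")
  Tz <- thickness_um
  dz <- vol$voxel_size[axis]
  extent <- dim(vol$grid)[axis] * dz
  with_seed(seed, {
    if (is.null(start)) start <- stats::runif(1, 0, Tz)
  })
  stopifnot(start >= 0, start < Tz)
  single <- Tz >= extent
  if (single) warning("section thickness exceeds object extent; single section")

  # slab lower boundaries covering [0, extent)
  first <- if (start > 0) start - Tz else 0
  nsec <- max(1L, ceiling((extent - first) / Tz - 1e-12))
  lows <- first + Tz * (seq_len(nsec) - 1)
  highs <- lows + Tz

  # per-voxel-layer region counts along the axis
  labs <- vol$label_map
  other <- setdiff(1:3, axis)
  a_xy <- prod(vol$voxel_size[other])
  nz <- dim(vol$grid)[axis]
  counts <- vapply(seq_along(labs), function(l) {
    apply(vol$grid == l, axis, sum)
  }, numeric(nz)) # nz x nregions

  # overlap of voxel layer k ([ (k-1)dz, k dz )) with each slab
  zlo <- (seq_len(nz) - 1) * dz
  zhi <- zlo + dz
  ov <- pmax(outer(zhi, highs, pmin) - outer(zlo, lows, pmax), 0) # nz x nsec
  areas <- t(ov) %*% counts * a_xy / Tz # nsec x nregions
  colnames(areas) <- names(labs)

  if (!is.null(cells) && nrow(cells) > 0) {
    z <- cells[[c("x_um", "y_um", "z_um")[axis]]]
    sec <- floor((z - lows[1]) / Tz) + 1L
    sec[sec < 1L] <- 1L; sec[sec > nsec] <- nsec
    cells$section <- sec
  } else if (!is.null(cells)) cells$section <- integer(0)

  structure(list(sections = data.frame(index = seq_len(nsec),
                                       z_lo = lows, z_hi = highs),
                 areas_um2 = areas, cells = cells,
                 thickness_um = Tz, start = start, axis = axis,
                 volume = vol, single = single),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("Section series: %d sections of %g um (start %.2f um, axis %d)\n",
              nrow(x$sections), x$thickness_um, x$start, x$axis))
  invisible(x)
}

#' Binary region mask of one section
#'
#' Returns the 2D region profile at the mid-plane of a section (the voxel
#' layer containing the slab midpoint), as seen on a stained section.
#'
#' @param series a `section_series`.
#' @param s section index.
#' @param region region name.
#' @return logical matrix over the in-plane axes, with attribute
#'   `pixel_size` (micrometres per in-plane axis).
#' @export
section_mask <- function(series, s, region) {
  vol <- series$volume
  lab <- region_label(vol, region)
  zmid <- (series$sections$z_lo[s] + series$sections$z_hi[s]) / 2
  k <- min(max(1L, ceiling(zmid / vol$voxel_size[series$axis])), dim(vol$grid)[series$axis])
  ax <- series$axis
  m <- switch(ax,
              vol$grid[k, , ] == lab,
              vol$grid[, k, ] == lab,
              vol$grid[, , k] == lab)
  attr(m, "pixel_size") <- vol$voxel_size[setdiff(1:3, ax)]
  m
}
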