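#' Unbiased counting-frame rule
#'
#' Applies the Gundersen counting frame to a set of cell reference points:
#' a cell is accepted iff it lies inside the frame or on the inclusion
#' edges (top `y = y0 + h`, right `x = x0 + w`) and touches neither
#' exclusion edge (left `x = x0`, bottom `y = y0`) nor their infinite
#' extensions. Implemented as the half-open intervals
#' `x in (x0, x0+w]`, `y in (y0, y0+h]`, which is exactly the rule that
#' lets a complete tiling of the plane count every point once.
#' Coordinates are compared exactly; there is no epsilon.
#'
#' @param cells data frame with `x_um`, `y_um` columns.
#' @param origin frame lower-left corner `c(x0, y0)` in micrometres.
#' @param width,height frame edge lengths in micrometres.
#' @return logical acceptance vector.
#' @export
apply_counting_frame <- function(cells, origin, width, height) {
  x <- cells$x_um; y <- cells$y_um
  x > origin[1] & x <= origin[1] + width &
    y > origin[2] & y <= origin[2] + height
}

#' Optical disector count at one site
#'
#' Counts cells whose reference point passes the counting-frame rule and
#' whose depth within the section lies in the half-open disector window
#' `[z_lo, z_hi)` (micrometres below the section's upper cut surface,
#' leaving guard zones at both faces).
#'
#' @param cells cells of one section slab with `x_um`, `y_um` and local
#'   depth column `depth_um` (or `z_um` with `z_top` given).
#' @param origin,width,height counting-frame geometry, see
#'   [apply_counting_frame()].
#' @param z_window `c(z_lo, z_hi)` disector window, `z_lo < z_hi`.
#' @param z_top absolute z of the section's upper face, used to derive
#'   depth from `z_um` when no `depth_um` column is present.
#' @return a `disector_count` list with `q` (the count) and `v_dis_um3`.
#' @export
optical_disector <- function(cells, origin, width, height, z_window,
                             z_top = NULL) {
  if (z_window[2] <= z_window[1]) stop("inverted disector window")
  depth <- cells$depth_um
  if (is.null(depth)) {
    if (is.null(z_top)) stop("need 'depth_um' column or 'z_top'")
    depth <- cells$z_um - z_top
  }
  ok <- apply_counting_frame(cells, origin, width, height) &
    depth >= z_window[1] & depth < z_window[2]
  structure(list(q = sum(ok), v_dis_um3 = width * height * diff(z_window),
                 origin = origin, z_window = z_window),
            class = "disector_count")
}

#' Stereological sampling design
#'
#' Bundles the sampling fractions of the optical fractionator: the section
#' sampling fraction `ssf = 1/period`, the area sampling fraction
#' `asf = frame area / (step_x * step_y)` and the height sampling fraction
#' `hsf = disector height / section thickness`.
#'
#' @param period section period k (every k-th section; ssf = 1/k).
#' @param step x-y grid step lengths in micrometres (length 1 or 2).
#' @param frame counting-frame width and height in micrometres.
#' @param z_window disector window `c(z_lo, z_hi)` within the section
#'   (micrometres below the upper face).
#' @param n_rays ray count of the 2D nucleator used for Cavalieri areas.
#' @return a `sampling_design` list with derived fractions.
#' @export
sampling_design <- function(period = 6, step = c(400, 400),
                            frame = c(50, 40), z_window = c(5, 15),
                            n_rays = 4) {
  step <- rep(step, length.out = 2)
  stopifnot(period >= 1, all(step > 0), all(frame > 0),
            z_window[2] > z_window[1], n_rays >= 2)
  if (any(frame > step)) stop("frame must fit inside one step cell")
  structure(list(period = as.integer(period), step = step, frame = frame,
                 z_window = z_window, n_rays = n_rays,
                 ssf = 1 / period,
                 asf = prod(frame) / prod(step),
                 hsf = NA_real_), # depends on section thickness
            class = "sampling_design")
}

new_stereo_estimate <- function(kind, estimate, ce, design, tallies) {
  structure(list(kind = kind, estimate = estimate, ce = ce,
                 design = design, tallies = tallies),
            class = "stereo_estimate")
}

#' @export
print.stereo_estimate <- function(x, ...) {
  unit <- if (x$kind == "volume") " mm^3" else " cells"
  cat(sprintf("Stereological %s estimate: %s%s (CE %.3f)\n", x$kind,
              format(signif(x$estimate, 6)), unit, x$ce))
  invisible(x)
}

#' Optical-fractionator total-number estimate
#'
#' Samples every k-th section (uniform random offset), tiles each sampled
#' section with counting frames on a systematic x-y grid with uniform
#' random phase, applies the optical disector in a fixed z-window, and
#' expands the summed count by the reciprocal sampling fractions:
#' `N = sum(Q-) / (ssf * asf * hsf)`.
#'
#' @param series a `section_series` carrying cells.
#' @param design a [sampling_design()].
#' @param class_filter cell class to count (default `"neuron"`);
#'   `NULL` counts all cells.
#' @param marker optional marker filter: `"pv"`, `"vva"`, `"pv_vva"`.
#' @param offset section offset in `1..period`; random when `NULL`.
#' @param phase grid phase in `[0, step)`; random when `NULL`.
#' @param seed optional RNG seed for offset/phase.
#' @return a `stereo_estimate` (kind `"number"`) with per-section counts
#'   in `tallies`.
#' @export
fractionator_count <- function(series, design, class_filter = "neuron",
                               marker = NULL, offset = NULL, phase = NULL,
                               seed = NULL) {
  cells <- series$cells
  if (is.null(cells)) stop("section series carries no cells")
  Tz <- series$thickness_um
  hsf <- diff(design$z_window) / Tz
  if (design$z_window[2] > Tz)
    stop("disector window must lie strictly inside the section slab")
  if (any(c(design$ssf, design$asf, hsf) <= 0))
    stop("all sampling fractions must be positive")

  with_seed(seed, {
    if (is.null(offset)) offset <- sample.int(design$period, 1)
    if (is.null(phase)) phase <- stats::runif(2) * design$step
  })

  # vector-level hot path: study-scale populations run through here
  x <- cells$x_um; y <- cells$y_um; z <- cells$z_um; sec <- cells$section
  keep <- rep(TRUE, length(x))
  if (!is.null(class_filter)) {
    keep <- keep & (if (length(class_filter) == 1) cells$class == class_filter
                    else cells$class %in% class_filter)
  }
  if (!is.null(marker)) {
    keep <- keep & switch(marker, pv = cells$pv, vva = cells$vva,
                          pv_vva = cells$pv & cells$vva,
                          stop("unknown marker filter"))
  }

  nsec <- nrow(series$sections)
  sampled <- seq(offset, nsec, by = design$period)
  q_sec <- integer(length(sampled))
  if (any(keep)) {
    in_sec <- keep & (sec - offset) %% design$period == 0L &
      sec >= offset & sec <= max(sampled)
    xs <- x[in_sec]; ys <- y[in_sec]; zs <- z[in_sec]; ss <- sec[in_sec]
    # frame tiling with SUR phase: local position within the step cell
    lx <- (xs - phase[1]) %% design$step[1]
    ly <- (ys - phase[2]) %% design$step[2]
    depth <- zs - series$sections$z_lo[ss]
    hit <- lx > 0 & lx <= design$frame[1] &
      ly > 0 & ly <= design$frame[2] &
      depth >= design$z_window[1] & depth < design$z_window[2]
    q_sec <- tabulate((ss[hit] - offset) %/% design$period + 1L,
                      nbins = length(sampled))
  }
  q <- sum(q_sec)
  est <- q / (design$ssf * design$asf * hsf)
  ce <- count_ce(q_sec)
  d <- design; d$hsf <- hsf
  new_stereo_estimate("number", est, ce, d,
                      data.frame(section = sampled, q = q_sec))
}

#' Cavalieri volume estimate from systematic sections
#'
#' Estimates a region's volume as `V = k * T * sum(A_i)` over every k-th
#' section with uniform random offset. Section areas come either from the
#' exact voxel-slab intersection (`"pixel"`) or from the 2D nucleator
#' applied to the section's mid-plane mask (`"nucleator"`).
#'
#' @param series a `section_series`.
#' @param region region name.
#' @param design a [sampling_design()] (supplies the period and, for the
#'   nucleator, the ray count).
#' @param area_method `"pixel"` or `"nucleator"`.
#' @param offset section offset in `1..period`; random when `NULL`.
#' @param seed optional RNG seed (offset and nucleator ray phases).
#' @return a `stereo_estimate` (kind `"volume"`, mm^3) with the sampled
#'   per-section areas in `tallies`.
#' @export
cavalieri_volume <- function(series, region, design,
                             area_method = c("pixel", "nucleator"),
                             offset = NULL, seed = NULL) {
  area_method <- match.arg(area_method)
  k <- design$period
  with_seed(seed, {
    if (is.null(offset)) offset <- sample.int(k, 1)
    nsec <- nrow(series$sections)
    sampled <- seq(offset, nsec, by = k)
    areas <- if (area_method == "pixel") {
      series$areas_um2[sampled, region]
    } else {
      vapply(sampled, function(s) {
        m <- section_mask(series, s, region)
        if (!any(m)) return(0)
        nucleator_area(m, n_rays = design$n_rays)
      }, 0)
    }
  })
  if (all(areas == 0)) warning(sprintf("region '%s' absent from all sampled sections", region))
  est <- k * series$thickness_um * sum(areas) / 1e9
  ce <- cavalieri_ce(areas)
  new_stereo_estimate("volume", est, ce, design,
                      data.frame(section = sampled, area_um2 = areas))
}

#' 2D nucleator area estimate
#'
#' Estimates a plane profile's area from the intercept lengths of `n_rays`
#' systematically rotated rays (uniform random phase) emitted from a seed
#' point inside the profile: `A = pi * mean(l^2)`. Unbiased over the
#' rotation phase for profiles star-shaped about the seed. Input may be a
#' radial function `r(theta)`, a polygon (matrix of vertices, exact
#' ray-segment intersection) or a binary mask (subpixel ray marching).
#'
#' @param profile radial function, two-column vertex matrix (closed
#'   polygon, micrometres), or logical mask with `pixel_size` attribute.
#' @param seed_point seed `c(x, y)`; defaults to the mask/polygon centroid.
#' @param n_rays number of rays (>= 2), spread systematically over 2*pi.
#' @param phase rotation phase in radians; uniform random when `NULL`.
#' @param step_px ray-marching step for masks, in pixels.
#' @return area estimate (squared micrometres; squared pixels for a mask
#'   without `pixel_size`).
#' @export
nucleator_area <- function(profile, seed_point = NULL, n_rays = 4,
                           phase = NULL, step_px = 0.25) {
  if (n_rays < 2) stop("n_rays must be >= 2")
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi / n_rays)
  theta <- phase + 2 * pi * (seq_len(n_rays) - 1) / n_rays

  if (is.function(profile)) {
    l <- profile(theta)
    return(pi * mean(l^2))
  }
  if (is.matrix(profile) && !is.logical(profile)) {
    poly <- profile
    if (is.null(seed_point)) seed_point <- colMeans(poly)
    l <- vapply(theta, function(th) ray_polygon_intercept(seed_point, th, poly), 0)
    return(pi * mean(l^2))
  }
  # binary mask
  m <- profile
  px <- attr(m, "pixel_size") %||% c(1, 1)
  if (!any(m)) stop("empty profile mask")
  idx <- which(m, arr.ind = TRUE)
  cx <- (colMeans(idx) - 0.5) * px # centroid in physical units
  if (is.null(seed_point)) seed_point <- cx
  ij <- c((seed_point[1] / px[1]) + 0.5, (seed_point[2] / px[2]) + 0.5)
  if (ij[1] < 1 || ij[1] > nrow(m) || ij[2] < 1 || ij[2] > ncol(m) ||
      !m[round(ij[1]), round(ij[2])])
    stop("seed point lies outside the profile")
  rmax <- sqrt(sum((dim(m) * px)^2))
  steps <- seq(0, rmax / min(px), by = step_px)
  l <- vapply(theta, function(th) {
    # march in physical units, look up pixel membership
    xs <- seed_point[1] + cos(th) * steps * min(px)
    ys <- seed_point[2] + sin(th) * steps * min(px)
    i <- round(xs / px[1] + 0.5); j <- round(ys / px[2] + 0.5)
    ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
    inside <- ok
    inside[ok] <- m[cbind(i[ok], j[ok])]
    first_out <- which(!inside)[1]
    if (is.na(first_out)) rmax else (steps[first_out] - step_px / 2) * min(px)
  }, 0)
  pi * mean(l^2)
}

# farthest intersection of a ray with a closed polygon boundary
ray_polygon_intercept <- function(origin, theta, poly) {
  d <- c(cos(theta), sin(theta))
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  # solve origin + t*d = a + u*(b-a), t>=0, 0<=u<=1
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- d[1] * (-ey) - d[2] * (-ex)
  rx <- a[, 1] - origin[1]; ry <- a[, 2] - origin[2]
  t <- (rx * (-ey) - ry * (-ex)) / den
  u <- (d[1] * ry - d[2] * rx) / den
  ok <- is.finite(t) & t >= 0 & u >= -1e-12 & u <= 1 + 1e-12
  if (!any(ok)) return(0)
  max(t[ok])
}

#' Disector-density total-number estimate
#'
#' Estimates a total from disector stacks and a reference volume:
#' `N = sum(Q-) / sum(v_dis) * V_ref` (numerical density times reference
#' volume).
#'
#' @param stacks list of `disector_count` objects, or a data frame with
#'   columns `q` and `v_dis_um3`.
#' @param v_ref_mm3 reference region volume in mm^3.
#' @return a `stereo_estimate` (kind `"number"`).
#' @export
density_count <- function(stacks, v_ref_mm3) {
  df <- as_stack_df(stacks)
  if (nrow(df) < 1) stop("need at least one disector stack")
  if (v_ref_mm3 <= 0) stop("reference volume must be positive")
  sv <- sum(df$v_dis_um3)
  if (sv == 0) stop("total disector volume is zero")
  est <- sum(df$q) / sv * v_ref_mm3 * 1e9
  ce <- count_ce(df$q)
  new_stereo_estimate("number", est, ce, NULL, df)
}

as_stack_df <- function(stacks) {
  if (is.data.frame(stacks)) return(stacks)
  do.call(rbind, lapply(stacks, function(s)
    data.frame(q = s$q, v_dis_um3 = s$v_dis_um3,
               layer = attr(s, "layer") %||% NA_character_,
               stringsAsFactors = FALSE)))
}

#' Layer-wise disector-density estimates
#'
#' Applies [density_count()] within laminar bands. When the bands
#' partition the region and share the stack design, the band estimates
#' add up to the whole-region estimate computed from the pooled stacks
#' with band-volume weighting.
#'
#' @param stacks data frame (or list of `disector_count`s) with a `layer`
#'   assignment per stack.
#' @param v_ref_mm3 named per-band reference volumes (mm^3).
#' @return data frame of per-band estimates (band, q, v_dis, estimate, ce).
#' @export
layerwise_counts <- function(stacks, v_ref_mm3) {
  df <- as_stack_df(stacks)
  if (any(is.na(df$layer))) stop("every stack must be assigned to a layer band")
  bad <- setdiff(unique(df$layer), names(v_ref_mm3))
  if (length(bad)) stop(sprintf("no reference volume for band '%s'", bad[1]))
  out <- lapply(names(v_ref_mm3), function(b) {
    d <- df[df$layer == b, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    e <- density_count(d, v_ref_mm3[[b]])
    data.frame(layer = b, q = sum(d$q), v_dis_um3 = sum(d$v_dis_um3),
               estimate = e$estimate, ce = e$ce, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample disector stacks across cortical layers of a phantom
#'
#' Emulates confocal z-stack sampling: on each of `n_sections`
#' systematically sampled sections, `layout` stacks per hemisphere are
#' placed uniformly at random within each laminar band of the region, and
#' the optical disector is applied to each.
#'
#' @param series a `section_series` over a laminar phantom (cells carry a
#'   `layer` column).
#' @param region region name.
#' @param layout named integer vector: stacks per hemisphere per band,
#'   e.g. `c("I-III" = 3, "V" = 3, "VI" = 1)`.
#' @param layer_widths named depth fractions of the bands along axis 1.
#' @param stack_xy stack field edge lengths in micrometres.
#' @param z_window disector window within the section.
#' @param n_sections number of sections to sample systematically.
#' @param marker optional marker filter as in [fractionator_count()].
#' @param seed optional RNG seed.
#' @return data frame of stacks (section, layer, q, v_dis_um3).
#' @export
sample_stacks <- function(series, region, layout, layer_widths,
                          stack_xy = c(135, 135), z_window = c(5, 15),
                          n_sections = 4, marker = NULL, seed = NULL) {
  vol <- series$volume
  lab <- region_label(vol, region)
  idx <- which(vol$grid == lab)
  sub <- arrayInd(idx, dim(vol$grid))
  xr <- range((sub[, 1] - 0.5) * vol$voxel_size[1]) + c(-0.5, 0.5) * vol$voxel_size[1]
  yr <- range((sub[, 2] - 0.5) * vol$voxel_size[2]) + c(-0.5, 0.5) * vol$voxel_size[2]
  ymid <- mean(yr)
  breaks <- xr[1] + cumsum(c(0, layer_widths)) * diff(xr)

  cells <- series$cells
  with_seed(seed, {
    nsec <- nrow(series$sections)
    # sections where the region fills the whole slab thickness (partial
    # end slabs would put disectors into empty space), sampled systematically
    amax <- max(series$areas_um2[, region])
    present <- which(series$areas_um2[, region] > 0.99 * amax)
    secs <- present[unique(round(seq(1, length(present), length.out = n_sections)))]
    out <- list()
    for (s in secs) {
      sc <- cells[cells$section == s, , drop = FALSE]
      sc$depth_um <- sc$z_um - series$sections$z_lo[s]
      if (!is.null(marker)) {
        sc <- sc[switch(marker, pv = sc$pv, vva = sc$vva,
                        pv_vva = sc$pv & sc$vva), , drop = FALSE]
      }
      for (b in seq_along(layout)) {
        band <- names(layout)[b]
        for (hemi in c(0, 1)) {
          ylo <- if (hemi == 0) yr[1] else ymid
          yhi <- if (hemi == 0) ymid else yr[2]
          for (r in seq_len(layout[[b]])) {
            x0 <- stats::runif(1, breaks[b], max(breaks[b], breaks[b + 1] - stack_xy[1]))
            y0 <- stats::runif(1, ylo, max(ylo, yhi - stack_xy[2]))
            dc <- optical_disector(sc, c(x0, y0), stack_xy[1], stack_xy[2],
                                   z_window, z_top = series$sections$z_lo[s])
            out[[length(out) + 1L]] <-
              data.frame(section = s, layer = band, q = dc$q,
                         v_dis_um3 = dc$v_dis_um3, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  do.call(rbind, out)
}
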