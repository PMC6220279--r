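#' Describe one generating shape of a phantom region
#'
#' Regions of a phantom are built from simple solids with closed-form
#' volumes: ellipsoids, spherical shells and axis-aligned boxes. Several
#' shapes may share one region name (e.g. bilateral structures); their
#' analytic volumes add. If `target_volume_mm3` is given the shape is
#' rescaled isotropically so that its analytic volume matches the target.
#'
#' @param name region name.
#' @param type one of `"ellipsoid"`, `"shell"`, `"box"`.
#' @param center shape center in micrometres (length 3).
#' @param semiaxes ellipsoid semi-axes / box half-lengths in micrometres
#'   (length 3; ignored for shells).
#' @param radii for shells, `c(r_inner, r_outer)` in micrometres.
#' @param target_volume_mm3 optional analytic volume to rescale to.
#' @param structure,group optional hierarchy labels (region belongs to a
#'   structure, structure to a super-group), mirroring how regional volumes
#'   are usually tabulated.
#' @return a `region_shape` list.
#' @export
region_shape <- function(name, type = c("ellipsoid", "shell", "box"),
                         center, semiaxes = NULL, radii = NULL,
                         target_volume_mm3 = NULL,
                         structure = NULL, group = NULL) {
  type <- match.arg(type)
  stopifnot(length(center) == 3, is.numeric(center))
  s <- list(name = name, type = type, center = as.numeric(center),
            semiaxes = semiaxes, radii = radii,
            structure = structure %||% name, group = group %||% "brain")
  if (type == "shell") {
    stopifnot(length(radii) == 2, radii[1] >= 0, radii[2] > radii[1])
  } else {
    stopifnot(length(semiaxes) == 3, all(semiaxes > 0))
  }
  if (!is.null(target_volume_mm3)) {
    f <- (target_volume_mm3 / shape_volume_mm3(s))^(1 / 3)
    if (type == "shell") s$radii <- s$radii * f else s$semiaxes <- s$semiaxes * f
  }
  class(s) <- "region_shape"
  s
}

#' Analytic volume of a generating shape (mm^3)
#' @param s a `region_shape`.
#' @return volume in mm^3.
#' @export
shape_volume_mm3 <- function(s) {
  v_um3 <- switch(s$type,
    ellipsoid = 4 / 3 * pi * prod(s$semiaxes),
    shell = 4 / 3 * pi * (s$radii[2]^3 - s$radii[1]^3),
    box = 8 * prod(s$semiaxes))
  v_um3 / 1e9
}

# squared/normalized membership of voxel-center coordinates in a shape;
# coordinates are matrices with columns x, y, z in micrometres
shape_contains <- function(s, xyz) {
  d <- sweep(xyz, 2, s$center)
  switch(s$type,
    ellipsoid = rowSums(sweep(d, 2, s$semiaxes, "/")^2) <= 1,
    shell = {
      r <- sqrt(rowSums(d^2))
      r > s$radii[1] & r <= s$radii[2]
    },
    box = apply(abs(sweep(d, 2, s$semiaxes, "/")) <= 1, 1, all))
}

# bounding box of a shape in micrometres (2 x 3 matrix lo/hi)
shape_bbox <- function(s) {
  half <- switch(s$type,
    ellipsoid = s$semiaxes, box = s$semiaxes,
    shell = rep(s$radii[2], 3))
  rbind(s$center - half, s$center + half)
}

#' Voxelize generating shapes into a labeled phantom volume
#'
#' Builds a 3D integer label volume on a regular grid (voxel centers at
#' `(i - 0.5) * voxel_size`, 1-based indexing) together with the analytic
#' ground truth. A voxel belongs to a shape when its center does.
#' Overlapping regions are rejected with the offending pair named.
#'
#' @param shapes list of [region_shape()] objects.
#' @param voxel_size voxel edge length(s) in micrometres (length 1 or 3).
#' @param grid_dim grid dimensions; defaults to the joint bounding box plus
#'   a margin. Shapes are expected to lie inside the grid.
#' @param margin_um margin added around the bounding box when `grid_dim`
#'   is derived (default two voxels).
#' @return a list with components `volume` (a `label_volume`) and `truth`
#'   (a `ground_truth` holding the analytic region volumes).
#' @export
make_phantom <- function(shapes, voxel_size, grid_dim = NULL,
                         margin_um = NULL) {
  if (inherits(shapes, "region_shape")) shapes <- list(shapes)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  margin_um <- margin_um %||% (2 * max(voxel_size))

  bb <- sapply(shapes, shape_bbox, simplify = "array") # 2 x 3 x nshape
  lo <- apply(bb[1, , , drop = FALSE], 2, min) - margin_um
  if (any(lo < 0)) {
    # shift all shapes into the positive octant
    shapes <- lapply(shapes, function(s) { s$center <- s$center - pmin(lo, 0); s })
    bb <- sapply(shapes, shape_bbox, simplify = "array")
  }
  hi <- apply(bb[2, , , drop = FALSE], 2, max) + margin_um
  if (is.null(grid_dim)) grid_dim <- ceiling(hi / voxel_size)
  grid_dim <- as.integer(grid_dim)

  region_names <- unique(vapply(shapes, `[[`, "", "name"))
  labels <- stats::setNames(seq_along(region_names), region_names)
  grid <- array(0L, dim = grid_dim)
  owner <- character(length(region_names)) # region owning each label

  axes <- lapply(1:3, function(a) (seq_len(grid_dim[a]) - 0.5) * voxel_size[a])
  for (s in shapes) {
    # resolution guard: smallest half-extent should span >= 5 voxels
    half <- if (s$type == "shell") (s$radii[2] - s$radii[1]) / 2 else min(s$semiaxes)
    if (half / max(voxel_size) < 5)
      warning(sprintf("region '%s' resolved by fewer than 10 voxels per axis", s$name))
    bbx <- shape_bbox(s)
    ir <- lapply(1:3, function(a) {
      which(axes[[a]] >= bbx[1, a] - voxel_size[a] & axes[[a]] <= bbx[2, a] + voxel_size[a])
    })
    if (any(lengths(ir) == 0)) next
    xyz <- as.matrix(expand.grid(x = axes[[1]][ir[[1]]],
                                 y = axes[[2]][ir[[2]]],
                                 z = axes[[3]][ir[[3]]]))
    inside <- shape_contains(s, xyz)
    if (!any(inside)) next
    sub <- as.matrix(expand.grid(i = ir[[1]], j = ir[[2]], k = ir[[3]]))[inside, , drop = FALSE]
    lin <- sub[, 1] + grid_dim[1] * (sub[, 2] - 1L) + grid_dim[1] * grid_dim[2] * (sub[, 3] - 1L)
    lab <- labels[[s$name]]
    clash <- grid[lin] != 0L & grid[lin] != lab
    if (any(clash)) {
      other <- region_names[grid[lin][clash][1]]
      stop(sprintf("regions '%s' and '%s' overlap", other, s$name))
    }
    grid[lin] <- lab
  }

  hier <- unique(do.call(rbind, lapply(shapes, function(s)
    data.frame(region = s$name, structure = s$structure, group = s$group,
               stringsAsFactors = FALSE))))
  if (anyDuplicated(hier$region))
    stop("hierarchy is not a tree: a region maps to more than one structure")

  vol <- structure(list(grid = grid, voxel_size = voxel_size,
                        label_map = labels, hierarchy = hier,
                        shapes = shapes),
                   class = "label_volume")
  vols <- tapply(vapply(shapes, shape_volume_mm3, 0),
                 vapply(shapes, `[[`, "", "name"), sum)
  truth <- structure(list(volumes_mm3 = vols[region_names],
                          counts = data.frame(region = character(), class = character(),
                                              count = numeric()),
                          layer_counts = data.frame(region = character(), class = character(),
                                                    layer = character(), count = numeric())),
                     class = "ground_truth")
  list(volume = vol, truth = truth)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume:", paste(dim(x$grid), collapse = " x "),
      "voxels @", paste(signif(x$voxel_size, 4), collapse = " x "), "um\n")
  cat("Regions:", paste(names(x$label_map), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-counting volume of a region (mm^3)
#' @param vol a `label_volume`.
#' @param region region name.
#' @return voxelized volume in mm^3.
#' @export
voxel_volume_mm3 <- function(vol, region) {
  lab <- region_label(vol, region)
  sum(vol$grid == lab) * prod(vol$voxel_size) / 1e9
}

#' Populate a phantom region with a cellular point pattern
#'
#' Places exactly `n` cells uniformly inside the voxels carrying the
#' region's label (uniform voxel choice plus a uniform jitter within the
#' voxel, so every cell lies inside a voxel of its region). Cell classes
#' are assigned per cell from `classes`; marker flags (parvalbumin,
#' Vicia Villosa Agglutinin lectin) are thinned binomially and only ever
#' set on neurons. An optional laminar profile partitions the region into
#' cortical-layer bands along one axis and draws exact per-layer totals.
#'
#' @param vol a `label_volume`.
#' @param region region name.
#' @param n total number of cells (realized exactly); a named vector
#'   (e.g. `c(neuron = 666016, glia = 300000)`) fixes per-class totals
#'   exactly and overrides `classes`.
#' @param classes named probability vector over cell classes
#'   (default all neurons).
#' @param marker_probs named vector `c(pv_only=, vva_only=, both=)` of
#'   per-neuron marker probabilities (remainder unlabeled).
#' @param layers optional `list(axis =, profile = named fractions)` giving
#'   layer bands of equal status along `axis` over the region's extent;
#'   band widths follow `widths` (defaults to `profile`'s names' share of
#'   extent = expected share of cells unless `widths` given).
#' @param widths optional named band width fractions (must sum to 1).
#' @param seed optional RNG seed.
#' @return a `cell_population` data frame with columns
#'   `x_um, y_um, z_um, class, pv, vva, layer, region` and attributes
#'   `class_counts` and `layer_counts` recording the generative truth.
#' @export
populate_cells <- function(vol, region, n, classes = c(neuron = 1),
                           marker_probs = c(pv_only = 0, vva_only = 0, both = 0),
                           layers = NULL, widths = NULL, seed = NULL) {
  lab <- region_label(vol, region)
  class_totals <- NULL
  if (!is.null(names(n))) { # exact per-class totals
    class_totals <- n
    n <- sum(n)
  }
  if (n < 0) stop("requested total must be >= 0")
  stopifnot(abs(sum(classes) - 1) < 1e-8)
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      class = character(), pv = logical(), vva = logical(),
                      layer = character(), region = character())
  if (n == 0) return(structure(empty, class = c("cell_population", "data.frame"),
                               class_counts = numeric(), layer_counts = numeric()))

  with_seed(seed, {
    idx <- which(vol$grid == lab)
    if (length(idx) == 0) stop(sprintf("region '%s' has no voxels", region))
    sub <- arrayInd(idx, dim(vol$grid))
    centers <- sweep(sub - 0.5, 2, vol$voxel_size, "*")

    if (!is.null(layers)) {
      ax <- layers$axis %||% 1L
      prof <- layers$profile
      stopifnot(abs(sum(prof) - 1) < 1e-8)
      w <- widths %||% layers$widths %||% prof
      stopifnot(abs(sum(w) - 1) < 1e-8, identical(names(w), names(prof)))
      ext <- range(centers[, ax]) + c(-0.5, 0.5) * vol$voxel_size[ax]
      breaks <- ext[1] + cumsum(c(0, w)) * diff(ext)
      band <- findInterval(centers[, ax], breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
      n_layer <- if (!is.null(layers$counts)) {
        stopifnot(identical(names(layers$counts), names(prof)),
                  sum(layers$counts) == n)
        as.numeric(layers$counts)
      } else drop(stats::rmultinom(1, n, prof))
      pick <- unlist(lapply(seq_along(prof), function(b) {
        cand <- which(band == b)
        if (length(cand) == 0 && n_layer[b] > 0)
          stop(sprintf("layer band '%s' contains no voxels", names(prof)[b]))
        cand[sample.int(length(cand), n_layer[b], replace = TRUE)]
      }))
      layer <- rep(names(prof), n_layer)
    } else {
      pick <- sample.int(length(idx), n, replace = TRUE)
      layer <- rep(NA_character_, n)
      n_layer <- NULL
    }

    jitter <- matrix(stats::runif(3 * n, -0.5, 0.5), ncol = 3)
    xyz <- centers[pick, , drop = FALSE] + sweep(jitter, 2, vol$voxel_size, "*")
    cls <- if (!is.null(class_totals)) {
      if (length(class_totals) == 1) rep(names(class_totals), n)
      else sample(rep(names(class_totals), class_totals))
    } else if (length(classes) == 1) rep(names(classes), n)
    else sample(names(classes), n, replace = TRUE, prob = classes)

    pv <- vva <- logical(n)
    neu <- cls == "neuron"
    if (any(neu) && sum(marker_probs) > 0) {
      mp <- c(marker_probs[c("pv_only", "vva_only", "both")],
              none = 1 - sum(marker_probs))
      m <- sample(names(mp), sum(neu), replace = TRUE, prob = mp)
      pv[neu] <- m %in% c("pv_only", "both")
      vva[neu] <- m %in% c("vva_only", "both")
    }

    cells <- structure(list(x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
                            class = cls, pv = pv, vva = vva,
                            layer = layer, region = rep(region, n)),
                       row.names = c(NA_integer_, -n),
                       class = c("cell_population", "data.frame"))
    lc <- if (is.null(n_layer)) numeric() else stats::setNames(n_layer, names(layers$profile))
    cc <- if (!is.null(class_totals)) class_totals
      else if (length(classes) == 1) stats::setNames(n, names(classes))
      else c(table(cls))
    structure(cells, class_counts = cc, layer_counts = lc)
  })
}
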