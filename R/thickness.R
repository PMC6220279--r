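#' Build a concentric spherical-shell phantom for thickness validation
#'
#' Labels a cubic grid with 1 = inside (core), 2 = cortex ribbon,
#' 0 = outside, based on the distance of voxel centers (in voxel units)
#' from the grid center. The closed-form thickness is
#' `r_outer - r_inner` and the closed-form Laplace potential on the
#' ribbon is `phi(r) = (1/r_in - 1/r) / (1/r_in - 1/r_out)`.
#'
#' @param r_inner,r_outer shell radii in voxel units.
#' @param margin voxels of outside padding around the shell.
#' @return list with `labels` (3D integer array), `center`, `radii`.
#' @export
shell_phantom <- function(r_inner = 20, r_outer = 28, margin = 3) {
  n <- ceiling(2 * (r_outer + margin))
  ctr <- rep((n + 1) / 2, 3)
  ax <- seq_len(n) - ctr[1]
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  r <- sqrt(r2)
  lab <- array(0L, dim = rep(n, 3))
  lab[r <= r_inner] <- 1L
  lab[r > r_inner & r <= r_outer] <- 2L
  list(labels = lab, center = ctr, radii = c(r_inner, r_outer))
}

#' Laplace-equation cortical thickness
#'
#' Solves Laplace's equation on the cortical ribbon (label 2) with
#' Dirichlet boundary values 0 on the inner surface (label 1) and 1 on
#' the outer surface (label 0 / grid boundary), by a direct sparse
#' factorization of the 7-point Laplacian. Thickness at each
#' outer-boundary cortex voxel is the length of the streamline through
#' the normalized potential gradient, integrated by RK4 in both
#' directions (down to the inner surface and up to the outer surface)
#' and summed.
#'
#' @param labels 3D integer array: 1 inside, 2 cortex, 0 outside.
#' @param voxel_size_um isotropic voxel edge length (micrometres).
#' @param step RK4 step in voxel units (default 0.2).
#' @param tol residual tolerance the solve is checked against.
#' @param max_steps streamline step cap (default generous).
#' @return a `thickness_field` list: `points` (voxel indices of
#'   outer-surface cortex voxels), `thickness_um`, `potential`
#'   (3D array, NA outside cortex), `residual`, `iterations`.
#' @export
laplace_thickness <- function(labels, voxel_size_um = 1, step = 0.2,
                              tol = 1e-5, max_steps = NULL) {
  dm <- dim(labels)
  cortex <- which(labels == 2L)
  if (length(cortex) == 0) stop("no cortex voxels (label 2)")
  sub <- arrayInd(cortex, dm)
  id <- array(0L, dm) # equation index per cortex voxel
  id[cortex] <- seq_along(cortex)

  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb_lab <- function(s) {
    p <- sweep(sub, 2, s, "+")
    out <- p[, 1] < 1 | p[, 1] > dm[1] | p[, 2] < 1 | p[, 2] > dm[2] |
      p[, 3] < 1 | p[, 3] > dm[3]
    p[out, ] <- 1L
    l <- labels[p]
    l[out] <- 0L # off-grid treated as outside
    list(lab = l, id = ifelse(l == 2L & !out, id[p], 0L))
  }

  trip_i <- trip_j <- list(); b <- numeric(length(cortex))
  for (k in seq_len(nrow(shifts))) {
    nb <- nb_lab(shifts[k, ])
    inr <- nb$lab == 2L
    trip_i[[k]] <- which(inr)
    trip_j[[k]] <- nb$id[inr]
    b <- b + (nb$lab == 0L) # outer boundary value 1; inner contributes 0
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_along(cortex), unlist(trip_i)),
    j = c(seq_along(cortex), unlist(trip_j)),
    x = c(rep(6, length(cortex)), rep(-1, length(unlist(trip_i)))),
    dims = rep(length(cortex), 2))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  phi <- as.numeric(Matrix::solve(ch, b))
  residual <- max(abs(A %*% phi - b))
  if (residual > tol) {
    # ribbon fails to separate the boundaries or the system is singular
    stop(sprintf("Laplace solve residual %.3g exceeds tolerance %.3g", residual, tol))
  }

  # potential on the full grid for finite differences: inside 0, outside 1
  phi_full <- array(NA_real_, dm)
  phi_full[labels == 1L] <- 0
  phi_full[labels == 0L] <- 1
  phi_full[cortex] <- phi
  if (!any(is.na(phi))) {
    # boundary layers (off-ribbon) already set; nothing else needed
  }

  # outer-surface cortex voxels: at least one outside neighbor
  outer_pt <- rep(FALSE, length(cortex))
  inner_nb <- rep(FALSE, length(cortex))
  for (k in seq_len(nrow(shifts))) {
    nb <- nb_lab(shifts[k, ])
    outer_pt <- outer_pt | nb$lab == 0L
    inner_nb <- inner_nb | nb$lab == 1L
  }
  if (!any(outer_pt) || !any(inner_nb))
    stop("cortex ribbon does not separate inner and outer boundaries")

  pts <- sub[outer_pt, , drop = FALSE]
  len_dn <- trace_streamlines(phi_full, pts, direction = -1, step = step,
                              max_steps = max_steps)
  len_up <- trace_streamlines(phi_full, pts, direction = +1, step = step,
                              max_steps = max_steps)
  structure(list(points = pts, thickness_um = (len_dn + len_up) * voxel_size_um,
                 potential = phi_full, residual = residual,
                 iterations = NA_integer_, voxel_size_um = voxel_size_um),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  cat(sprintf("Thickness field: %d surface points, mean %.2f um (residual %.2g)\n",
              nrow(x$points), mean(x$thickness_um), x$residual))
  invisible(x)
}

# vectorized trilinear interpolation of a 3D array at fractional voxel
# coordinates (voxel centers at integer coordinates); NAs treated via
# clamped nearest defined value fallback
interp3 <- function(arr, p) {
  dm <- dim(arr)
  p[, 1] <- pmin(pmax(p[, 1], 1), dm[1] - 1e-9)
  p[, 2] <- pmin(pmax(p[, 2], 1), dm[2] - 1e-9)
  p[, 3] <- pmin(pmax(p[, 3], 1), dm[3] - 1e-9)
  i0 <- pmin(floor(p[, 1]), dm[1] - 1); fx <- p[, 1] - i0
  j0 <- pmin(floor(p[, 2]), dm[2] - 1); fy <- p[, 2] - j0
  k0 <- pmin(floor(p[, 3]), dm[3] - 1); fz <- p[, 3] - k0
  g <- function(di, dj, dk) arr[cbind(i0 + di, j0 + dj, k0 + dk)]
  v <- g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    g(1, 1, 0) * fx * fy * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 0, 1) * fx * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy * fz +
    g(1, 1, 1) * fx * fy * fz
  v
}

# integrate streamlines of the normalized potential gradient from the
# given voxel centers; direction +1 ascends phi (towards outer surface),
# -1 descends (towards inner). Returns path lengths in voxel units.
trace_streamlines <- function(phi_full, pts, direction, step = 0.2,
                              max_steps = NULL) {
  dm <- dim(phi_full)
  # gradient arrays by central differences on a boundary-padded copy
  ph <- phi_full
  ph[is.na(ph)] <- 0.5 # far-field fill; never reached by traces
  gx <- array(0, dm); gy <- array(0, dm); gz <- array(0, dm)
  gx[2:(dm[1] - 1), , ] <- (ph[3:dm[1], , ] - ph[1:(dm[1] - 2), , ]) / 2
  gy[, 2:(dm[2] - 1), ] <- (ph[, 3:dm[2], ] - ph[, 1:(dm[2] - 2), ]) / 2
  gz[, , 2:(dm[3] - 1)] <- (ph[, , 3:dm[3]] - ph[, , 1:(dm[3] - 2)]) / 2

  dirfield <- function(p) {
    v <- cbind(interp3(gx, p), interp3(gy, p), interp3(gz, p))
    nrm <- sqrt(rowSums(v^2))
    nrm[nrm < 1e-12] <- 1
    v / nrm * direction
  }
  target <- if (direction < 0) 0 else 1
  eps <- 0.02
  n <- nrow(pts)
  pos <- pts * 1.0
  len <- numeric(n)
  active <- rep(TRUE, n)
  if (is.null(max_steps)) max_steps <- ceiling(4 * max(dm) / step)
  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    pa <- pos[active, , drop = FALSE]
    k1 <- dirfield(pa)
    k2 <- dirfield(pa + step / 2 * k1)
    k3 <- dirfield(pa + step / 2 * k2)
    k4 <- dirfield(pa + step * k3)
    pa2 <- pa + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    pos[active, ] <- pa2
    len[active] <- len[active] + step
    val <- interp3(ph, pa2)
    done <- abs(val - target) < eps
    active[active] <- !done
  }
  len
}

#' Pointwise thickness t-map between genotype groups
#'
#' Two-sample pooled t test at every shared surface point, with the
#' significance mask thresholded at uncorrected p < 0.05 (deliberately
#' uncorrected; the map is exploratory).
#'
#' @param thickness matrix, points x animals (all fields on one shared
#'   point set), or list of `thickness_field`s with identical `points`.
#' @param genotype per-animal genotype vector (`"WT"`/`"MUT"`).
#' @param alpha mask threshold (default 0.05).
#' @return a `tmap` list: `t`, `p`, `mask` per point.
#' @export
thickness_tmap <- function(thickness, genotype, alpha = 0.05) {
  if (is.list(thickness) && inherits(thickness[[1]], "thickness_field")) {
    pts <- thickness[[1]]$points
    for (f in thickness) {
      if (!identical(f$points, pts)) stop("thickness fields are on different point sets")
    }
    thickness <- do.call(cbind, lapply(thickness, `[[`, "thickness_um"))
  }
  thickness <- as.matrix(thickness)
  stopifnot(ncol(thickness) == length(genotype))
  g1 <- thickness[, genotype == "WT", drop = FALSE]
  g2 <- thickness[, genotype == "MUT", drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, stats::var); v2 <- apply(g2, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m2 - m1) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), n1 + n2 - 2), 1)
  structure(list(t = t, p = p, mask = p < alpha, alpha = alpha),
            class = "tmap")
}
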