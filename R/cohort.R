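#' Template phantoms emulating the study's tissue blocks
#'
#' Three stock geometries are provided. `cpu_template()` is a single
#' ellipsoidal caudate-putamen (left CPu) used for the stereology arm:
#' default analytic volume 10.90 mm^3, the wild-type group mean of the
#' emulated study, with a coronal extent well inside the 4.4 mm sectioned
#' range. `acc_template()` is a box-shaped anterior cingulate cortex with
#' laminar bands (layers I-III, V, VI) stacked along the depth axis.
#' `brain_template()` is a bilateral multi-region phantom carrying a small
#' region/structure hierarchy for volumetric tabulation.
#'
#' @param volume_mm3 target analytic volume of the region.
#' @param voxel_size_um voxel edge length in micrometres.
#' @name templates
NULL

#' @rdname templates
#' @export
cpu_template <- function(volume_mm3 = 10.90, voxel_size_um = 50) {
  sh <- region_shape("CPu", "ellipsoid", center = c(0, 0, 0),
                     semiaxes = c(1.5, 1.0, 1.3), # ratios; rescaled below
                     target_volume_mm3 = volume_mm3,
                     structure = "Striatum", group = "Cerebral grey")
  make_phantom(list(sh), voxel_size_um)
}

#' @rdname templates
#' @param layer_widths named fractions of cortical depth per laminar band.
#' @export
acc_template <- function(volume_mm3 = 3.0, voxel_size_um = 50,
                         layer_widths = c("I-III" = 0.45, "V" = 0.35, "VI" = 0.20)) {
  sh <- region_shape("aCC", "box", center = c(0, 0, 0),
                     semiaxes = c(600, 700, 900),
                     target_volume_mm3 = volume_mm3,
                     structure = "Cingulate cortex", group = "Cerebral grey")
  ph <- make_phantom(list(sh), voxel_size_um)
  ph$layer_widths <- layer_widths
  ph
}

#' @rdname templates
#' @param volumes_mm3 named bilateral region volumes (mm^3); defaults mirror
#'   a typical wild-type mouse volumetric table.
#' @export
brain_template <- function(voxel_size_um = 50,
                           volumes_mm3 = c("Caudate Nucleus/Putamen" = 20.5,
                                           "Fundus of Striatum" = 0.2,
                                           "Nucleus Accumbens" = 4.4,
                                           "Amygdala" = 16.3,
                                           "Globus Pallidus" = 3.2,
                                           "Thalamus" = 18.4)) {
  structures <- c("Caudate Nucleus/Putamen" = "Striatum",
                  "Fundus of Striatum" = "Striatum",
                  "Nucleus Accumbens" = "Striatum",
                  "Amygdala" = "Amygdala",
                  "Globus Pallidus" = "Globus Pallidus",
                  "Thalamus" = "Thalamus")
  nms <- names(volumes_mm3)
  r <- (3 * volumes_mm3 / 2 / (4 * pi))^(1 / 3) * 1000 # hemisphere radius, um
  gap <- 500
  zc <- cumsum(2 * r + gap) - r # stack regions along z
  xoff <- r + 400
  shapes <- list()
  for (i in seq_along(nms)) {
    for (sgn in c(-1, 1)) {
      shapes[[length(shapes) + 1L]] <-
        region_shape(nms[i], "ellipsoid",
                     center = c(sgn * xoff[i], 0, zc[i]),
                     semiaxes = rep(r[i], 3),
                     structure = structures[[nms[i]]],
                     group = "Cerebral grey")
    }
  }
  ph <- make_phantom(shapes, voxel_size_um)
  # midplane: shapes were shifted into the positive octant; recover it
  ph$midplane_um <- mean(vapply(ph$volume$shapes, function(s) s$center[1], 0))
  ph
}

#' Specify a two-genotype cohort
#'
#' Describes group sizes, per-region fractional volume effects in the
#' mutant group, cell-count effects (overall and per layer), and
#' between-animal coefficients of variation. Animal-level true values are
#' drawn log-normal by default (volumes and counts are positive with CVs
#' up to ~0.25); a Gaussian alternative is available.
#'
#' @param n_wt,n_mut group sizes (>= 2).
#' @param volume_effect named fractional change of mutant region-volume
#'   means (e.g. `c(CPu = -0.11)`).
#' @param volume_cv between-animal CV of region volumes.
#' @param count_mean,count_cv,count_effect mean, CV and fractional effect
#'   for the cell count of `count_region` (class `count_class`).
#' @param count_region,count_class region/class the count refers to.
#' @param layer_profile optional named wild-type laminar profile of the
#'   counted cells (fractions summing to 1).
#' @param layer_effect optional named per-layer fractional effects in the
#'   mutant group (overrides `count_effect` within those layers).
#' @param marker_probs per-neuron marker probabilities, see
#'   [populate_cells()].
#' @param classes cell class mixture, see [populate_cells()].
#' @param distribution `"lognormal"` (default) or `"gaussian"`.
#' @param seed RNG seed; a fixed seed makes the cohort byte-identical.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_wt, n_mut, volume_effect = numeric(),
                        volume_cv = 0.06,
                        count_mean = NULL, count_cv = 0.15, count_effect = 0,
                        count_region = NULL, count_class = "neuron",
                        layer_profile = NULL, layer_effect = NULL,
                        marker_probs = c(pv_only = 0, vva_only = 0, both = 0),
                        classes = c(neuron = 1),
                        distribution = c("lognormal", "gaussian"),
                        seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_wt >= 2, n_mut >= 2)
  if (volume_cv <= 0 || volume_cv >= 1) stop("CVs must lie in (0, 1)")
  if (!is.null(count_mean) && (count_cv <= 0 || count_cv >= 1))
    stop("CVs must lie in (0, 1)")
  structure(list(n_wt = n_wt, n_mut = n_mut,
                 volume_effect = volume_effect, volume_cv = volume_cv,
                 count_mean = count_mean, count_cv = count_cv,
                 count_effect = count_effect, count_region = count_region,
                 count_class = count_class,
                 layer_profile = layer_profile, layer_effect = layer_effect,
                 marker_probs = marker_probs, classes = classes,
                 distribution = distribution, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_positive <- function(n, mean, cv, distribution) {
  if (distribution == "lognormal") rlnorm_mean_cv(n, mean, cv)
  else pmax(stats::rnorm(n, mean, cv * mean), mean * 1e-6)
}

#' Generate a two-genotype phantom cohort
#'
#' Draws animal-level true region volumes and cell counts around the
#' template's analytic means (wild type) and around effect-scaled means
#' (mutant), then records them as the cohort's ground truth. Phantoms and
#' cellular point patterns for individual animals are materialized on
#' demand with [animal_phantom()] and [animal_cells()]; materialization is
#' deterministic given the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @param template a template phantom (list with `volume` and `truth`),
#'   e.g. [cpu_template()].
#' @return a `phantom_cohort` with `animals` (id, genotype), `volumes`
#'   (animals x regions matrix of true volumes, mm^3), `counts` (true
#'   totals) and `layer_counts` (true per-layer totals) when counts are
#'   requested.
#' @export
make_cohort <- function(spec, template) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_wt + spec$n_mut
  genotype <- rep(c("WT", "MUT"), c(spec$n_wt, spec$n_mut))
  regions <- names(template$truth$volumes_mm3)
  wt_means <- template$truth$volumes_mm3

  with_seed(spec$seed, {
    vols <- matrix(NA_real_, n, length(regions), dimnames = list(NULL, regions))
    for (r in regions) {
      eff <- spec$volume_effect[r]
      eff <- if (is.na(eff) || is.null(eff)) 0 else eff
      mu <- ifelse(genotype == "MUT", wt_means[[r]] * (1 + eff), wt_means[[r]])
      vols[, r] <- draw_positive(n, 1, spec$volume_cv, spec$distribution) * mu
    }

    counts <- layer_counts <- NULL
    if (!is.null(spec$count_mean)) {
      if (is.null(spec$layer_profile)) {
        mu <- ifelse(genotype == "MUT",
                     spec$count_mean * (1 + spec$count_effect), spec$count_mean)
        counts <- round(draw_positive(n, 1, spec$count_cv, spec$distribution) * mu)
      } else {
        prof <- spec$layer_profile
        layer_counts <- matrix(NA_real_, n, length(prof),
                               dimnames = list(NULL, names(prof)))
        for (l in names(prof)) {
          eff_l <- if (!is.null(spec$layer_effect) && l %in% names(spec$layer_effect))
            spec$layer_effect[[l]] else spec$count_effect
          mu <- spec$count_mean * prof[[l]] *
            ifelse(genotype == "MUT", 1 + eff_l, 1)
          layer_counts[, l] <-
            round(draw_positive(n, 1, spec$count_cv, spec$distribution) * mu)
        }
        counts <- rowSums(layer_counts)
      }
    }
  })

  structure(list(spec = spec, template = template,
                 animals = data.frame(id = seq_len(n), genotype = genotype,
                                      stringsAsFactors = FALSE),
                 volumes = vols, counts = counts, layer_counts = layer_counts),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort: %d WT + %d MUT animals, regions: %s\n",
              x$spec$n_wt, x$spec$n_mut,
              paste(colnames(x$volumes), collapse = ", ")))
  invisible(x)
}

#' Materialize one animal's label volume
#'
#' Rescales every template shape isotropically so its analytic volume
#' matches the animal's drawn true region volume, then voxelizes on the
#' template grid settings (self-similar anatomy; no registration).
#'
#' @param cohort a `phantom_cohort`.
#' @param i animal id.
#' @return list with `volume` (a `label_volume`) and `truth`.
#' @export
animal_phantom <- function(cohort, i) {
  tmpl <- cohort$template$volume
  target <- cohort$volumes[i, ]
  cur <- cohort$template$truth$volumes_mm3
  shapes <- lapply(tmpl$shapes, function(s) {
    f <- (target[[s$name]] / cur[[s$name]])^(1 / 3)
    if (s$type == "shell") s$radii <- s$radii * f else s$semiaxes <- s$semiaxes * f
    s
  })
  ph <- make_phantom(shapes, tmpl$voxel_size, grid_dim = dim(tmpl$grid))
  ph$layer_widths <- cohort$template$layer_widths
  ph
}

#' Materialize one animal's cellular point pattern
#'
#' Draws the animal's cells inside its phantom with the cohort's class
#' mixture, marker probabilities and (optionally) laminar profile, at the
#' animal's true total count. Deterministic given the cohort seed.
#'
#' @param cohort a `phantom_cohort`.
#' @param i animal id.
#' @param phantom optionally a pre-materialized [animal_phantom()] result.
#' @return a `cell_population`.
#' @export
animal_cells <- function(cohort, i, phantom = NULL) {
  spec <- cohort$spec
  if (is.null(spec$count_mean)) stop("cohort carries no cell counts")
  if (is.null(phantom)) phantom <- animal_phantom(cohort, i)
  seed_i <- (spec$seed + 77003L * i) %% .Machine$integer.max
  if (is.null(spec$layer_profile)) {
    populate_cells(phantom$volume, spec$count_region, cohort$counts[i],
                   classes = spec$classes, marker_probs = spec$marker_probs,
                   seed = seed_i)
  } else {
    lc <- cohort$layer_counts[i, ]
    populate_cells(phantom$volume, spec$count_region, sum(lc),
                   classes = spec$classes, marker_probs = spec$marker_probs,
                   layers = list(axis = 1L, profile = lc / sum(lc),
                                 counts = lc),
                   widths = phantom$layer_widths %||% (lc * 0 + 1 / length(lc)),
                   seed = seed_i)
  }
}
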