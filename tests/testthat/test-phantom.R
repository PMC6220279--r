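test_that("analytic shape volumes are exact and voxelization tracks them", {
  sp <- sphere_phantom(1000, 50)
  expect_equal(unname(sp$truth$volumes_mm3["ball"]), 4 / 3 * pi, tolerance = 1e-12)
  expect_lt(abs(voxel_volume_mm3(sp$volume, "ball") - 4 / 3 * pi) / (4 / 3 * pi), 0.02)

  # rescaling to a target volume is exact on the analytic record
  el <- region_shape("CPu", "ellipsoid", center = c(0, 0, 0),
                     semiaxes = c(3000, 1500, 1500), target_volume_mm3 = 20.5)
  expect_equal(shape_volume_mm3(el), 20.5, tolerance = 1e-12)
  expect_equal(el$semiaxes[1] / el$semiaxes[2], 2, tolerance = 1e-12)
})

test_that("voxelization error shrinks monotonically under grid refinement", {
  errs <- vapply(c(100, 50, 25), function(vx) {
    sp <- sphere_phantom(1000, vx)
    abs(voxel_volume_mm3(sp$volume, "ball") - 4 / 3 * pi) / (4 / 3 * pi)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("disjoint regions get distinct labels; overlaps are rejected by name", {
  two <- make_phantom(list(
    region_shape("a", "ellipsoid", center = c(0, 0, 0), semiaxes = rep(400, 3)),
    region_shape("b", "ellipsoid", center = c(2000, 0, 0), semiaxes = rep(400, 3))),
    50)
  expect_length(unique(as.vector(two$volume$grid)), 3) # background + 2
  expect_error(make_phantom(list(
    region_shape("a", "ellipsoid", center = c(0, 0, 0), semiaxes = rep(400, 3)),
    region_shape("b", "ellipsoid", center = c(300, 0, 0), semiaxes = rep(400, 3))),
    50), "'a' and 'b' overlap")
})

test_that("populate_cells realizes totals exactly and keeps cells in-region", {
  sp <- sphere_phantom(1000, 50)
  expect_equal(nrow(populate_cells(sp$volume, "ball", 0)), 0)

  cells <- populate_cells(sp$volume, "ball", c(neuron = 5000, glia = 1000), seed = 1)
  expect_identical(sum(cells$class == "neuron"), 5000L)
  expect_identical(sum(cells$class == "glia"), 1000L)

  # every cell lies inside a voxel carrying its region label
  vs <- sp$volume$voxel_size
  ijk <- cbind(ceiling(cells$x_um / vs[1]), ceiling(cells$y_um / vs[2]),
               ceiling(cells$z_um / vs[3]))
  expect_true(all(sp$volume$grid[ijk] == sp$volume$label_map[["ball"]]))

  expect_error(populate_cells(sp$volume, "nope", 10), "'nope'")
})

test_that("marker flags follow their probabilities and stay on neurons", {
  sp <- sphere_phantom(800, 50)
  cells <- populate_cells(sp$volume, "ball", 2000, classes = c(neuron = 0.5, glia = 0.5),
                          marker_probs = c(pv_only = 1, vva_only = 0, both = 0),
                          seed = 2)
  neu <- cells$class == "neuron"
  expect_true(all(cells$pv[neu]))        # degenerate probability 1
  expect_false(any(cells$pv[!neu]))      # markers only on neurons
  expect_false(any(cells$vva))
})

test_that("laminar placement conserves totals and honors exact layer counts", {
  ac <- acc_template()
  prof <- c("I-III" = 0.45, "V" = 0.40, "VI" = 0.15)
  cells <- populate_cells(ac$volume, "aCC", 3000,
                          layers = list(axis = 1, profile = prof),
                          widths = ac$layer_widths, seed = 3)
  lc <- attr(cells, "layer_counts")
  expect_equal(sum(lc), 3000)
  expect_equal(c(table(cells$layer)[names(prof)]), stats::setNames(c(lc), names(prof)))

  exact <- c("I-III" = 1000, "V" = 1500, "VI" = 500)
  cells2 <- populate_cells(ac$volume, "aCC", 3000,
                           layers = list(axis = 1, profile = prof, counts = exact),
                           widths = ac$layer_widths, seed = 4)
  expect_equal(c(table(cells2$layer)[names(exact)]), exact)
})

test_that("cohorts reproduce generating means, scale mutants, and are deterministic", {
  tmpl <- cpu_template(10.90)
  spec <- cohort_spec(7, 6, volume_effect = c(CPu = -0.11), volume_cv = 0.06,
                      seed = 5)
  co1 <- make_cohort(spec, tmpl)
  co2 <- make_cohort(spec, tmpl)
  expect_identical(co1$volumes, co2$volumes) # fixed seed, byte-identical

  # mutant generating mean: 10.90 * (1 - 0.11) = 9.70; check by Monte Carlo
  # over many cohorts that group means of draws match the generating means
  wt_means <- mut_means <- numeric(500)
  for (s in seq_len(500)) {
    co <- make_cohort(cohort_spec(7, 6, volume_effect = c(CPu = -0.11),
                                  volume_cv = 0.06, seed = 1000L + s), tmpl)
    g <- co$animals$genotype
    wt_means[s] <- mean(co$volumes[g == "WT", "CPu"])
    mut_means[s] <- mean(co$volumes[g == "MUT", "CPu"])
  }
  expect_lt(abs(mean(wt_means) - 10.90) / 10.90, 0.01)
  expect_lt(abs(mean(mut_means) - 9.701) / 9.701, 0.01)

  # degenerate variance: all animals collapse onto the group mean
  expect_error(cohort_spec(3, 3, volume_cv = 0), "CVs")
  co0 <- make_cohort(cohort_spec(3, 3, volume_cv = 1e-6, seed = 6,
                                 distribution = "gaussian"), tmpl)
  expect_lt(max(abs(co0$volumes[, "CPu"] - 10.90)), 1e-3)
})

test_that("per-layer cohort truths sum to the animal totals", {
  ac <- acc_template()
  spec <- cohort_spec(4, 4, count_mean = 10000, count_cv = 0.2,
                      count_effect = -0.1,
                      layer_profile = c("I-III" = 0.45, "V" = 0.40, "VI" = 0.15),
                      layer_effect = c("V" = -0.45),
                      count_region = "aCC", seed = 7)
  co <- make_cohort(spec, ac)
  expect_equal(unname(rowSums(co$layer_counts)), unname(co$counts))
  cells <- animal_cells(co, 1)
  expect_equal(nrow(cells), unname(co$counts[1]))
  expect_equal(c(table(cells$layer)[colnames(co$layer_counts)]),
               stats::setNames(co$layer_counts[1, ], colnames(co$layer_counts)))
})
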