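test_that("region volumes are exact, hemisphere-symmetric, and roll up", {
  shapes <- list(
    region_shape("CPu", "ellipsoid", center = c(-1200, 0, 0), semiaxes = rep(500, 3),
                 structure = "Striatum"),
    region_shape("CPu", "ellipsoid", center = c(1200, 0, 0), semiaxes = rep(500, 3),
                 structure = "Striatum"),
    region_shape("Accumbens", "ellipsoid", center = c(-1200, 0, 2000), semiaxes = rep(300, 3),
                 structure = "Striatum"),
    region_shape("Accumbens", "ellipsoid", center = c(1200, 0, 2000), semiaxes = rep(300, 3),
                 structure = "Striatum"))
  ph <- make_phantom(shapes, 50)
  mid <- mean(vapply(ph$volume$shapes, function(s) s$center[1], 0))
  tab <- region_volumes(ph$volume, midplane_um = mid)

  both <- tab[tab$hemisphere == "both" & tab$level == "region", ]
  for (r in c("CPu", "Accumbens"))
    expect_equal(both$volume_mm3[both$region == r], voxel_volume_mm3(ph$volume, r))

  left <- tab[tab$hemisphere == "left" & tab$region == "CPu", "volume_mm3"]
  right <- tab[tab$hemisphere == "right" & tab$region == "CPu", "volume_mm3"]
  expect_equal(left, right) # mirrored phantom

  striatum <- tab[tab$level == "structure" & tab$hemisphere == "both", ]
  expect_equal(striatum$volume_mm3, sum(both$volume_mm3))

  # conservation: labeled volume + background = grid volume
  grid_mm3 <- prod(dim(ph$volume$grid)) * prod(ph$volume$voxel_size) / 1e9
  bg <- sum(ph$volume$grid == 0) * prod(ph$volume$voxel_size) / 1e9
  expect_equal(sum(both$volume_mm3) + bg, grid_mm3, tolerance = 1e-12)
})

test_that("percent change matches the group-mean definition and its fixtures", {
  tab <- data.frame(animal = 1:13,
                    genotype = rep(c("WT", "MUT"), c(7, 6)),
                    region = "CPu",
                    volume_mm3 = c(rep(10.90, 7), rep(9.70, 6)))
  pc <- percent_change(tab)
  expect_equal(pc$pct_change, 100 * (9.70 - 10.90) / 10.90, tolerance = 1e-12)
  expect_equal(round(pc$pct_change, 1), -11.0)

  same <- tab; same$volume_mm3 <- 10
  expect_equal(percent_change(same)$pct_change, 0)
})

test_that("injected volume effects are recovered across simulated cohorts", {
  tmpl <- cpu_template(10.90)
  changes <- vapply(1:200, function(s) {
    co <- make_cohort(cohort_spec(9, 10, volume_effect = c(CPu = -0.10),
                                  volume_cv = 0.06, seed = 40000 + s), tmpl)
    tab <- data.frame(animal = co$animals$id, genotype = co$animals$genotype,
                      region = "CPu", volume_mm3 = co$volumes[, "CPu"])
    percent_change(tab)$pct_change
  }, 0)
  expect_lt(abs(mean(changes) - (-10)), 1)
})

test_that("volume correlations recover latent structure and stay PSD", {
  set.seed(20)
  n <- 40
  latent <- rnorm(n, 1, 0.1)
  tab <- do.call(rbind, lapply(c("A", "B", "C"), function(r) {
    noise <- if (r == "C") rnorm(n, 0, 0.2) else rnorm(n, 0, 0.005)
    data.frame(animal = 1:n, genotype = "WT", region = r,
               volume_mm3 = latent * ifelse(r == "C", 0, 1) + 1 + noise)
  }))
  cm <- volume_correlations(tab)
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_gt(cm["A", "B"], 0.95)        # shared latent size factor
  expect_lt(abs(cm["A", "C"]), 0.5)    # independent region
  expect_true(all(eigen(cm, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  expect_equal(cm, t(cm))
})

test_that("zero-variance regions are flagged, not silently zeroed", {
  tab <- data.frame(animal = rep(1:5, 2), genotype = "WT",
                    region = rep(c("A", "B"), each = 5),
                    volume_mm3 = c(rnorm(5, 10), rep(2, 5)))
  expect_warning(cm <- volume_correlations(tab), "zero-variance")
  expect_true(is.na(cm["A", "B"]))
})

test_that("Laplace thickness is exact on a flat slab", {
  dm <- c(24, 24, 24)
  lab <- array(0L, dm)
  lab[, , 3:8] <- 1L       # inner compartment
  lab[, , 9:16] <- 2L      # cortex ribbon, 8 voxels thick
  tf <- laplace_thickness(lab, voxel_size_um = 1)
  expect_lt(tf$residual, 1e-5)
  # central points (away from the open lateral faces) see the flat answer;
  # Dirichlet data sit at neighbor voxel centers, so the discrete ribbon is
  # up to half a voxel wider per face (error < 1.5 voxels)
  ctr <- tf$points[, 1] > 8 & tf$points[, 1] < 17 & tf$points[, 2] > 8 & tf$points[, 2] < 17
  expect_lt(max(abs(tf$thickness_um[ctr] - 8)), 1.5)
})

test_that("a ribbon that does not separate its boundaries is rejected", {
  lab <- array(0L, c(10, 10, 10))
  lab[4:6, 4:6, 4:6] <- 2L # cortex with no inner compartment at all
  expect_error(laplace_thickness(lab), "separate")
})

test_that("thickness t-maps are empty on identical groups and calibrated on null data", {
  pts <- 1000
  th0 <- matrix(rep(c(8, 8, 8, 8, 8, 8), each = pts), pts) # zero variance
  tm0 <- thickness_tmap(th0, rep(c("WT", "MUT"), each = 3))
  expect_false(any(tm0$mask))

  set.seed(21)
  frac <- replicate(60, {
    th <- matrix(rnorm(pts * 12, 100, 5), pts)
    mean(thickness_tmap(th, rep(c("WT", "MUT"), each = 6))$mask)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.015)

  expect_error(thickness_tmap(th0, rep("WT", 6)))
})

test_that("focal thinning is detected at effect size d >= 2", {
  set.seed(22)
  pts <- 500; patch <- 1:50
  hits <- replicate(100, {
    th <- matrix(rnorm(pts * 13, 100, 5), pts)
    mut <- 8:13
    th[patch, mut] <- th[patch, mut] - 10 # d = 2 in patch
    tm <- thickness_tmap(th, rep(c("WT", "MUT"), c(7, 6)))
    mean(tm$mask[patch]) > 0.5
  })
  expect_gt(mean(hits), 0.9)
})
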