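test_that("counting-frame edge rules follow the Gundersen convention", {
  cells <- data.frame(x_um = c(0, 5, 5, 10, 0, 5), y_um = c(5, 0, 10, 5, 10, 5))
  acc <- apply_counting_frame(cells, origin = c(0, 0), width = 10, height = 10)
  expect_false(acc[1]) # on the left (exclusion) edge
  expect_false(acc[2]) # on the bottom (exclusion) edge
  expect_true(acc[3])  # on the top (inclusion) edge, x strictly inside
  expect_true(acc[4])  # on the right (inclusion) edge
  expect_false(acc[5]) # corner of both exclusion extensions
  expect_true(acc[6])  # interior
})

test_that("a complete frame tiling counts every point exactly once", {
  set.seed(10)
  for (rep in 1:5) {
    pts <- data.frame(x_um = runif(400, 0, 1000), y_um = runif(400, 0, 1000))
    # snap a few points onto frame edges to exercise the tie rule
    pts$x_um[1:10] <- seq(0, 900, by = 100)[1:10]
    w <- 100; h <- 125
    hits <- 0
    for (x0 in seq(-w, 1000, by = w)) {
      for (y0 in seq(-h, 1000, by = h)) {
        hits <- hits + sum(apply_counting_frame(pts, c(x0, y0), w, h))
      }
    }
    expect_equal(hits, 400)
  }
})

test_that("the optical disector counts reference points in the z-window only", {
  cells <- data.frame(x_um = rep(5, 4), y_um = rep(5, 4),
                      depth_um = c(2, 5, 14.99, 15))
  dc <- optical_disector(cells, c(0, 0), 10, 10, c(5, 15))
  expect_equal(dc$q, 2L) # 5 in, 14.99 in; 2 and 15 out
  expect_equal(dc$v_dis_um3, 10 * 10 * 10)
  expect_equal(optical_disector(cells[0, ], c(0, 0), 10, 10, c(5, 15))$q, 0L)
  expect_error(optical_disector(cells, c(0, 0), 10, 10, c(15, 5)), "inverted")
})

test_that("disector spanning the full slab and frame recovers every cell", {
  sp <- sphere_phantom(500, 50)
  cells <- populate_cells(sp$volume, "ball", 1000, seed = 11)
  ser <- section_phantom(sp$volume, cells, 40, start = 0)
  k <- which.max(table(ser$cells$section))
  slab <- ser$cells[ser$cells$section == as.integer(names(k)), ]
  slab$depth_um <- slab$z_um - ser$sections$z_lo[as.integer(names(k))]
  dc <- optical_disector(slab, c(0, 0), 1e5, 1e5, c(0, 40))
  expect_equal(dc$q, nrow(slab))
})

test_that("fractionator with all sampling fractions 1 is an exhaustive count", {
  sp <- sphere_phantom(600, 50)
  cells <- populate_cells(sp$volume, "ball", c(neuron = 3000, glia = 500), seed = 12)
  ser <- section_phantom(sp$volume, cells, 40, start = 0)
  d <- sampling_design(period = 1, step = c(200, 200), frame = c(200, 200),
                       z_window = c(0, 40))
  fr <- fractionator_count(ser, d, class_filter = "neuron", seed = 13)
  expect_equal(fr$estimate, 3000)
  expect_equal(fractionator_count(ser, d, class_filter = NULL, seed = 13)$estimate, 3500)
})

test_that("fractionator is unbiased at the study design and scale-equivariant", {
  ph <- cpu_template(10.90)
  cells <- populate_cells(ph$volume, "CPu", 66602, seed = 14)
  d <- sampling_design(period = 6, step = c(400, 400), frame = c(50, 40),
                       z_window = c(5, 15))
  est <- vapply(1:150, function(s) {
    ser <- section_phantom(ph$volume, cells, 40, seed = 7000 + s)
    fractionator_count(ser, d, seed = 8000 + s)$estimate
  }, 0)
  expect_lt(abs(mean(est) - 66602) / 66602, 0.03)

  # doubling step_x halves asf but leaves the expectation unchanged
  d2 <- sampling_design(period = 6, step = c(800, 400), frame = c(50, 40),
                        z_window = c(5, 15))
  expect_equal(d2$asf, d$asf / 2)
  est2 <- vapply(1:150, function(s) {
    ser <- section_phantom(ph$volume, cells, 40, seed = 7000 + s)
    fractionator_count(ser, d2, seed = 8000 + s)$estimate
  }, 0)
  expect_lt(abs(mean(est2) - 66602) / 66602, 0.05)

  # scaling all coordinates by s: counts unchanged, volumes scale by s^3
  s <- 2
  vol2 <- ph$volume
  vol2$voxel_size <- vol2$voxel_size * s
  cells2 <- cells
  cells2$x_um <- cells2$x_um * s; cells2$y_um <- cells2$y_um * s
  cells2$z_um <- cells2$z_um * s
  ds <- sampling_design(period = 6, step = c(400, 400) * s, frame = c(50, 40) * s,
                        z_window = c(5, 15) * s)
  ser1 <- section_phantom(ph$volume, cells, 40, start = 11)
  ser2 <- section_phantom(vol2, cells2, 40 * s, start = 11 * s)
  f1 <- fractionator_count(ser1, d, offset = 2, phase = c(90, 250))
  f2 <- fractionator_count(ser2, ds, offset = 2, phase = c(90, 250) * s)
  expect_equal(f2$estimate, f1$estimate)
  c1 <- cavalieri_volume(ser1, "CPu", d, offset = 3)
  c2 <- cavalieri_volume(ser2, "CPu", ds, offset = 3)
  expect_equal(c2$estimate, c1$estimate * s^3, tolerance = 1e-12)
})

test_that("Cavalieri at period 1 with pixel areas is the voxel volume", {
  sp <- sphere_phantom(700, 50)
  ser <- section_phantom(sp$volume, NULL, 40, start = 0)
  d <- sampling_design(period = 1)
  cav <- cavalieri_volume(ser, "ball", d, area_method = "pixel", offset = 1)
  expect_equal(cav$estimate, voxel_volume_mm3(sp$volume, "ball"), tolerance = 1e-12)
  expect_warning(cavalieri_volume(
    section_phantom(sp$volume, NULL, 40, start = 0), "ball",
    sampling_design(period = 50), offset = 40), "absent")
})

test_that("estimates are reproducible under a fixed design and seed", {
  sp <- sphere_phantom(700, 50)
  cells <- populate_cells(sp$volume, "ball", 2000, seed = 15)
  ser <- section_phantom(sp$volume, cells, 40, start = 5)
  d <- sampling_design()
  f1 <- fractionator_count(ser, d, seed = 16)
  f2 <- fractionator_count(ser, d, seed = 16)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$tallies, f2$tallies)
})

test_that("nucleator is exact on circles and unbiased on ellipses and polygons", {
  circle <- function(theta) rep(300, length(theta))
  expect_equal(nucleator_area(circle, n_rays = 3, phase = 0.7), pi * 300^2,
               tolerance = 1e-12)

  # 2:1 ellipse, 4 rays, averaged over random phases: within 1% of pi*a*b
  a <- 400; b <- 200
  ell <- function(theta) a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  set.seed(17)
  est <- vapply(1:1000, function(i) nucleator_area(ell, n_rays = 4), 0)
  expect_lt(abs(mean(est) - pi * a * b) / (pi * a * b), 0.01)

  # dense rays on a star-shaped polygon approach the shoelace area
  poly <- cbind(c(0, 400, 500, 200, -100), c(0, -50, 300, 500, 250))
  shoelace <- abs(sum(poly[, 1] * poly[c(2:5, 1), 2] -
                        poly[c(2:5, 1), 1] * poly[, 2])) / 2
  dense <- nucleator_area(poly, n_rays = 4000, phase = 0)
  expect_lt(abs(dense - shoelace) / shoelace, 0.005)

  expect_error(nucleator_area(matrix(FALSE, 5, 5)), "empty profile")
})

test_that("Cavalieri with nucleator areas is unbiased on the sphere phantom", {
  sp <- sphere_phantom(1000, 50)
  truth <- 4 / 3 * pi
  d <- sampling_design(period = 6, n_rays = 4)
  est <- vapply(1:300, function(s) {
    ser <- section_phantom(sp$volume, NULL, 40, seed = 20000 + s)
    cavalieri_volume(ser, "ball", d, area_method = "nucleator",
                     seed = 21000 + s)$estimate
  }, 0)
  expect_lt(abs(mean(est) - truth) / truth, 0.02)
})

test_that("density estimates recover a uniform generating density", {
  sp <- sphere_phantom(800, 50)
  v_ref <- voxel_volume_mm3(sp$volume, "ball")
  n_true <- 20000
  set.seed(18)
  est <- vapply(1:40, function(i) {
    cells <- populate_cells(sp$volume, "ball", n_true)
    ser <- section_phantom(sp$volume, cells, 40)
    # stacks at random in-region positions on full-thickness sections
    amax <- max(ser$areas_um2[, "ball"])
    secs <- which(ser$areas_um2[, "ball"] > 0.99 * amax)
    stacks <- do.call(rbind, lapply(secs[1:4], function(s) {
      sc <- ser$cells[ser$cells$section == s, ]
      sc$depth_um <- sc$z_um - ser$sections$z_lo[s]
      do.call(rbind, lapply(1:10, function(j) {
        org <- c(runif(1, 600, 900), runif(1, 600, 900))
        dc <- optical_disector(sc, org, 135, 135, c(5, 15))
        data.frame(q = dc$q, v_dis_um3 = dc$v_dis_um3)
      }))
    }))
    density_count(stacks, v_ref)$estimate
  }, 0)
  expect_lt(abs(mean(est) - n_true) / n_true, 0.05)
  expect_equal(density_count(data.frame(q = 0, v_dis_um3 = 100), 1)$estimate, 0)
  expect_error(density_count(data.frame(q = 1, v_dis_um3 = 0), 1), "zero")
})

test_that("layer-wise estimates localize deficits and add up over a partition", {
  ac <- acc_template()
  lw <- ac$layer_widths
  v_ref <- voxel_volume_mm3(ac$volume, "aCC")
  prof_def <- c("I-III" = 0.45, "V" = 0.40, "VI" = 0.15)
  prof_hit <- prof_def * c(1, 0.5, 1); prof_hit <- prof_hit / sum(prof_hit)
  set.seed(19)
  runs <- replicate(12, {
    base <- populate_cells(ac$volume, "aCC", 40000,
                           layers = list(axis = 1, profile = prof_def), widths = lw)
    hit <- populate_cells(ac$volume, "aCC", round(40000 * sum(prof_def * c(1, 0.5, 1))),
                          layers = list(axis = 1, profile = prof_hit), widths = lw)
    sb <- sample_stacks(section_phantom(ac$volume, base, 40), "aCC",
                        c("I-III" = 3, "V" = 3, "VI" = 1), lw)
    sh <- sample_stacks(section_phantom(ac$volume, hit, 40), "aCC",
                        c("I-III" = 3, "V" = 3, "VI" = 1), lw)
    lb <- layerwise_counts(sb, v_ref * lw)
    lh <- layerwise_counts(sh, v_ref * lw)
    c(lb$estimate, lh$estimate)
  })
  base_mean <- rowMeans(runs)[1:3]; hit_mean <- rowMeans(runs)[4:6]
  ratio <- hit_mean / base_mean
  expect_lt(ratio[2], 0.75)          # layer V carries the deficit
  expect_gt(min(ratio[c(1, 3)]), 0.8) # spared layers stay near 1

  # proportional allocation: band estimates sum to the pooled estimate
  st <- sample_stacks(section_phantom(ac$volume, populate_cells(
    ac$volume, "aCC", 30000, layers = list(axis = 1, profile = prof_def),
    widths = lw), 40), "aCC", c("I-III" = 2, "V" = 2, "VI" = 2),
    stats::setNames(rep(1 / 3, 3), names(lw)))
  v_bands <- stats::setNames(rep(v_ref / 3, 3), names(lw))
  ly <- layerwise_counts(st, v_bands)
  pooled <- density_count(st, v_ref)
  expect_equal(sum(ly$estimate), pooled$estimate, tolerance = 1e-9)

  bad <- data.frame(q = 1, v_dis_um3 = 10, layer = NA_character_)
  expect_error(layerwise_counts(bad, v_bands), "assigned")
})

test_that("error prediction behaves like the noise term on flat sequences", {
  q <- rep(20, 12)
  # the open-ended 3A-4B+C form leaves only the end-term remnant
  # sqrt(2/240)/n on a flat sequence; the total CE is noise-dominated
  expect_equal(ce_surs(q, m = 1), sqrt(2 / 240) / 12, tolerance = 1e-12)
  expect_lt(abs(count_ce(q) - sqrt(1 / sum(q))) / sqrt(1 / sum(q)), 0.01)
  expect_true(is.na(ce_surs(c(1, 2), m = 1)))
})

test_that("predicted Cavalieri CE is calibrated within a factor 2 of the truth", {
  sp <- sphere_phantom(1000, 50)
  d <- sampling_design(period = 6)
  res <- vapply(1:300, function(s) {
    ser <- section_phantom(sp$volume, NULL, 40, seed = 30000 + s)
    cav <- cavalieri_volume(ser, "ball", d, area_method = "pixel",
                            seed = 31000 + s)
    c(cav$estimate, cav$ce)
  }, numeric(2))
  emp_cv <- stats::sd(res[1, ]) / mean(res[1, ])
  pred <- mean(res[2, ])
  expect_gt(pred / emp_cv, 0.5)
  expect_lt(pred / emp_cv, 2)
})
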