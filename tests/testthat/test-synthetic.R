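test_that("feature grids are rescaled, deterministic, and autocorrelated", {
  g <- generate_feature_grid(8, 8, 16, correlation_length = 0, seed = 1)
  for (f in seq_len(16)) {
    expect_lt(abs(mean(g$values[, , f])), 1e-6)
    expect_lt(abs(sd(g$values[, , f]) - 1), 1e-6)
  }
  g2 <- generate_feature_grid(8, 8, 16, correlation_length = 0, seed = 7)
  g3 <- generate_feature_grid(8, 8, 16, correlation_length = 0, seed = 7)
  expect_identical(g2$values, g3$values)

  # smoothing raises lag-1 spatial autocorrelation
  gw <- generate_feature_grid(24, 24, 1, correlation_length = 0, seed = 5)
  gs <- generate_feature_grid(24, 24, 1, correlation_length = 4, seed = 5)
  expect_gt(lag1_autocor(gs$values[, , 1]), lag1_autocor(gw$values[, , 1]))

  expect_error(generate_feature_grid(0, 4, 16, 0, seed = 1), "dimensions")
})

test_that("district partitions cover the lattice exactly once", {
  g <- generate_feature_grid(8, 8, 4, 0, seed = 2)
  p1 <- generate_districts(g, 1, seed = 1)
  expect_true(all(p1$assignment == 1))

  p4 <- generate_districts(g, 4, seed = 3)
  expect_equal(sort(unique(as.vector(p4$assignment))), 1:4)
  expect_equal(length(p4$assignment), 64)
  expect_true(all(table(p4$assignment) >= 1))
  expect_identical(p4$assignment,
                   generate_districts(g, 4, seed = 3)$assignment)

  pall <- generate_districts(g, 64, seed = 1)
  expect_equal(sort(as.vector(pall$assignment)), 1:64)

  expect_error(generate_districts(g, 65, seed = 1), "pixel count")
})

test_that("truth weight correlation tracks the cross-crop knob", {
  t1 <- define_truth(2, 16, cross_crop_correlation = 1, seed = 4)
  expect_equal(t1$weights[, 1], t1$weights[, 2], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(t1$offsets[1], t1$offsets[2])))

  t0 <- define_truth(40, 16, cross_crop_correlation = 0, seed = 4)
  cors <- cor(t0$weights)
  mean_off <- mean(cors[upper.tri(cors)])
  expect_lt(abs(mean_off), 0.1)  # Monte-Carlo tolerance

  g <- generate_feature_grid(16, 16, 16, 2, seed = 9)
  expect_true(all(true_yield(t0, g) >= 0))

  expect_error(define_truth(2, 16, cross_crop_correlation = 1.5, seed = 1),
               "\\[0, 1\\]")
})

test_that("crop placement respects fraction, uniformity, and sharpness", {
  g <- generate_feature_grid(110, 110, 8, 0, seed = 3)
  tr <- define_truth(3, 8, selection_sharpness = 0, seed = 3)
  a0 <- assign_crops(g, tr, cultivated_fraction = 0, seed = 1)
  expect_true(all(is.na(a0$assignment)))

  a <- assign_crops(g, tr, cultivated_fraction = 0.9, seed = 1)
  ncult <- sum(!is.na(a$assignment))
  expect_gt(ncult, 1e4)
  shares <- table(a$assignment) / ncult
  expect_true(all(abs(shares - 1 / 3) < 0.02))

  # very sharp selection picks the argmax-yield crop everywhere
  trs <- define_truth(3, 8, selection_sharpness = 1e3, seed = 3)
  as_ <- assign_crops(g, trs, cultivated_fraction = 0.5, seed = 1)
  yt <- true_yield(trs, g)
  am <- apply(matrix(yt, 110 * 110, 3), 1, which.max)
  cult <- which(!is.na(as_$assignment))
  expect_true(all(as_$assignment[cult] == am[cult]))

  expect_error(assign_crops(g, tr, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("district labels equal brute-force group means when noiseless", {
  b <- tiny_bundle(seed = 17)
  for (yr in names(b$grids)) {
    yt <- true_yield(b$truth, b$grids[[yr]])
    tab <- b$yields[b$yields$year == as.integer(yr), ]
    for (i in seq_len(nrow(tab))) {
      ci <- match(tab$crop[i], b$truth$crop_names)
      px <- which(!is.na(b$assignments[[yr]]$assignment) &
                    b$assignments[[yr]]$assignment == ci &
                    b$partition$assignment == tab$district[i])
      expect_gte(length(px), 1)
      expect_equal(tab$yield[i], mean(yt[, , ci][px]), tolerance = 1e-9)
    }
  }
  # no record for (crop, district) combinations with no cultivated pixel
  yr <- names(b$grids)[1]
  combos <- expand.grid(crop = b$truth$crop_names,
                        district = b$partition$district_ids,
                        stringsAsFactors = FALSE)
  tab <- b$yields[b$yields$year == as.integer(yr), ]
  for (i in seq_len(nrow(combos))) {
    ci <- match(combos$crop[i], b$truth$crop_names)
    px <- sum(!is.na(b$assignments[[yr]]$assignment) &
                b$assignments[[yr]]$assignment == ci &
                b$partition$assignment == combos$district[i])
    has_rec <- any(tab$crop == combos$crop[i] &
                     tab$district == combos$district[i])
    expect_equal(has_rec, px > 0)
  }
})

test_that("single-crop-per-pixel constraint and bundle determinism hold", {
  b1 <- tiny_bundle(seed = 5)
  b2 <- tiny_bundle(seed = 5)
  expect_identical(b1$yields, b2$yields)
  expect_identical(b1$grids[["2013"]]$values, b2$grids[["2013"]]$values)
  expect_identical(b1$assignments[["2014"]]$assignment,
                   b2$assignments[["2014"]]$assignment)
  # one crop index (or NA) per pixel-year by construction of the raster
  a <- b1$assignments[["2013"]]$assignment
  expect_true(all(is.na(a) | (a >= 1 & a <= 3)))
})

test_that("mean assigned true yield is nondecreasing in selection sharpness", {
  g <- generate_feature_grid(40, 40, 8, 0, seed = 21)
  means <- vapply(c(0, 0.2, 2), function(sh) {
    tr <- define_truth(3, 8, selection_sharpness = sh, seed = 13)
    a <- assign_crops(g, tr, cultivated_fraction = 0.6, seed = 2)
    yt <- matrix(true_yield(tr, g), 1600, 3)
    cult <- which(!is.na(a$assignment))
    mean(yt[cbind(cult, a$assignment[cult])] -
           rowMeans(yt[cult, , drop = FALSE]))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
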