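test_that("polytope primitives carry exact analytic ground truth", {
  b <- make_primitive_segment("box", c(0.1, 0.2, 0.3), center = c(1, 2, 3))
  expect_equal(b$volume, 0.006, tolerance = 1e-15)
  h <- convex_hull(b$points)
  expect_equal(h$volume, b$volume, tolerance = 1e-12)
  expect_equal(h$centroid, b$centroid, tolerance = 1e-12)

  fr <- make_primitive_segment("frustum", c(1, 2, 3), sides = 96)
  hf <- convex_hull(fr$points)
  expect_equal(hf$volume, fr$volume, tolerance = 1e-12)
  expect_equal(hf$centroid, fr$centroid, tolerance = 1e-10)
  # polygonal volume converges to the circular closed form 7*pi from below
  expect_lt(fr$volume, frustum_volume(1, 2, 3))
  fine <- make_primitive_segment("frustum", c(1, 2, 3), sides = 2048)
  expect_equal(fine$volume, 7 * pi, tolerance = 1e-5)
  expect_equal(frustum_volume(1, 2, 3), 7 * pi, tolerance = 1e-12)
  # cone limit (one zero radius) still hulls correctly
  cone <- make_primitive_segment("frustum", c(1.5, 0, 2), sides = 64)
  expect_equal(convex_hull(cone$points)$volume, cone$volume, tolerance = 1e-12)

  expect_error(make_primitive_segment("box", c(1, -1, 1)), "positive")
  expect_error(make_primitive_segment("sphere", 1))
})

test_that("ellipsoid clouds inscribe the ellipsoid tightly from below", {
  e <- make_primitive_segment("ellipsoid_cloud", c(1, 1, 1), n_points = 5000,
                              seed = 3)
  h <- convex_hull(e$points)
  expect_lt(h$volume, 4 * pi / 3)
  expect_gt(h$volume, 0.99 * 4 * pi / 3)
  ab <- make_primitive_segment("ellipsoid_cloud", c(0.5, 0.2, 0.1),
                               n_points = 4000, seed = 5)
  hab <- convex_hull(ab$points)
  expect_lt(hab$volume, ab$volume)
  expect_gt(hab$volume, 0.98 * ab$volume)
  expect_error(make_primitive_segment("ellipsoid_cloud", c(1, 1, 1),
                                      n_points = 10), "n_points")
})

test_that("generated bodies match their analytic ground truth end to end", {
  for (tpl in c("mammal_like", "crocodylian_like", "fossil_like")) {
    b <- make_body(synthetic_body_spec(tpl))
    m <- body_from_synthetic(b)
    expect_equal(body_volume(m), b$truth$body_volume, tolerance = 1e-9)
    expect_equal(center_of_mass(m), b$truth$com, tolerance = 1e-9)
    cm <- com_metrics(m)
    expect_equal(cm$pct_AG, b$truth$pct_AG, tolerance = 1e-9)
    expect_equal(cm$dca_fl, b$truth$dca_fl, tolerance = 1e-9)
    expect_equal(cm$log10_skull_tail, b$truth$log10_skull_tail,
                 tolerance = 1e-9)
  }
  # template constraints and the exact ratio hit
  croc <- make_body(synthetic_body_spec("crocodylian_like"))
  expect_lt(croc$truth$log10_skull_tail, 0)
  mam <- make_body(synthetic_body_spec("mammal_like"))
  expect_gt(mam$truth$log10_skull_tail, 0)
  custom <- make_body(synthetic_body_spec("fossil_like",
                                          skull_tail_ratio = 0.42))
  expect_equal(10^custom$truth$log10_skull_tail, 0.42, tolerance = 0.02)
  expect_error(make_body(synthetic_body_spec("mammal_like",
                                             skull_tail_ratio = 500)),
               "infeasible")
})

test_that("noise-free populations invert to the generating laws exactly", {
  spec <- synthetic_population_spec(
    n = 60, n_volumetric = 30,
    mch_law = masshull:::law(0.968, 0.215, 0),
    ss_law = masshull:::law(2.716, -4.078, 0),
    robustness_laws = list(mammal = masshull:::law(1.038, -0.605, 0),
                           crocodylian = masshull:::law(0.985, -0.347, 0),
                           other_reptile = masshull:::law(1.127, -0.759, 0)),
    seed = 11)
  pop <- make_population(spec)
  cal <- suppressWarnings(calibrate(pop))
  expect_equal(cal$mch_fit$slope, 0.968, tolerance = 1e-8)
  expect_equal(cal$mch_fit$intercept, 0.215, tolerance = 1e-8)
  expect_equal(cal$ss_fit$slope, 2.716, tolerance = 1e-8)
  expect_equal(cal$ss_fit$intercept, -4.078, tolerance = 1e-8)
})

test_that("populations are seeded-deterministic with the stated scatter", {
  spec <- synthetic_population_spec(seed = 21)
  expect_identical(make_population(spec), make_population(spec))
  expect_false(identical(
    make_population(spec),
    make_population(synthetic_population_spec(seed = 22))))

  # empirical residual SD converges to the specified sigma
  big <- synthetic_population_spec(n = 10000, n_volumetric = 100, seed = 31)
  pop <- make_population(big)
  f <- fit_loglog(pop$humerus_circ_mm + pop$femur_circ_mm, pop$known_mass_kg)
  resid_sd <- sd(residuals(f$lm))
  expect_lt(abs(resid_sd - 0.15), 3 * 0.15 / sqrt(2 * 10000))
})

test_that("mean PPE decreases with generator noise and hits 0 at sigma 0", {
  mean_ppe_at <- function(sig) {
    spec <- synthetic_population_spec(
      n = 120, n_volumetric = 40,
      mch_law = masshull:::law(0.968, 0.215, sig),
      ss_law = masshull:::law(2.716, -4.078, sig),
      seed = 41)
    pop <- make_population(spec)
    cal <- suppressWarnings(calibrate(pop))
    rep <- accuracy_report(pop, cal$mch_fit, cal$ss_fit, iterations = 10,
                           seed = 1)
    rep$summary$mean_ppe[rep$summary$group == "total"]
  }
  p0 <- mean_ppe_at(0)
  p1 <- mean_ppe_at(0.05)
  p2 <- mean_ppe_at(0.15)
  expect_equal(p0, c(0, 0), tolerance = 1e-8)
  expect_true(all(p1 < p2))
})

test_that("fossil sets reproduce the stylopodial overestimation pattern", {
  fos <- make_fossil_set(n = 12, seed = 3)
  expect_identical(fos, make_fossil_set(n = 12, seed = 3))
  est <- estimate_fossils(fos)
  big <- est[est$mch_kg > 50, ]
  expect_true(all(big$ratio_ss_mch > 1))
  # discrepancy grows with volumetric mass: slope of SS on MCH above 1
  expect_gt(method_discrepancy_fit(est)$slope, 1)

  # null construction: identical robustness laws give ratios near 1
  ext <- synthetic_population_spec()
  null_fos <- make_fossil_set(
    n = 12, fossil_robustness = ext$robustness_laws$mammal,
    extant_spec = ext, seed = 3)
  null_est <- estimate_fossils(null_fos)
  expect_lt(abs(mean(log10(null_est$ratio_ss_mch))), 0.1)
})

test_that("seed splitting gives distinct reproducible streams", {
  expect_identical(split_seed(7, 1), split_seed(7, 1))
  expect_false(split_seed(7, 1) == split_seed(7, 2))
  expect_false(split_seed(7, 1) == split_seed(8, 1))
  s <- vapply(0:1000, function(k) split_seed(123456, k), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
})
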