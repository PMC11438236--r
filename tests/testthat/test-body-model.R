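full_16 <- function() {
  nms <- masshull:::canonical_segments()
  tibble::tibble(name = nms, volume = seq_along(nms) * 1e-4,
                 cx = seq_along(nms) * 0.1, cy = 0, cz = 0)
}

test_that("assemble_body validates the segment vocabulary", {
  m <- assemble_body(full_16(), clade = "mammal")
  expect_s3_class(m, "body_model")

  with_sail <- dplyr::bind_rows(
    full_16(), tibble::tibble(name = "sail", volume = 1e-4, cx = 0.5, cy = 0,
                              cz = 0.3))
  expect_s3_class(assemble_body(with_sail, clade = "fossil"), "body_model")

  dup <- dplyr::bind_rows(full_16()[1, ], full_16())
  expect_error(assemble_body(dup, clade = "mammal"), "duplicate")
  bad <- tibble::tibble(name = "thorax", volume = 1, cx = 0, cy = 0, cz = 0)
  expect_error(assemble_body(bad, clade = "mammal"), "unknown segment")
  expect_warning(
    assemble_body(full_16()[1:3, ], clade = "mammal"), "canonical")
  # subdivided tails are allowed alongside each other
  tails <- tibble::tibble(name = c("trunk", "tail_sub_1", "tail_sub_2"),
                          volume = c(3, 1, 1) * 1e-3,
                          cx = c(0, -0.2, -0.4), cy = 0, cz = 0)
  expect_s3_class(suppress_canonical_warning(
    assemble_body(tails, clade = "crocodylian")), "body_model")
})

test_that("body volume is the exact segment sum; mass applies EF and density", {
  m <- two_segment_body(0.01, 0.02, clade = "mammal")
  expect_equal(body_volume(m), 0.03)
  one <- two_segment_body(0.005, 0.001, names = c("trunk", "tail"),
                          clade = "mammal")
  expect_equal(body_volume(one), 0.006)

  withr::local_seed(4)
  vols <- runif(16, 1e-4, 1e-2)
  segs <- full_16(); segs$volume <- vols
  expect_equal(body_volume(assemble_body(segs, clade = "mammal")),
               Reduce(`+`, as.list(vols)), tolerance = 1e-12)

  # mass: 0.002*1000 + 0.003*2*1000 = 8 kg
  m2 <- two_segment_body(0.002, 0.003, names = c("skull", "trunk"),
                         clade = "mammal")
  expect_equal(body_mass_direct(m2), 5)
  m2e <- apply_expansion(m2, masshull:::new_expansion_table(
    tibble::tibble(segment = "trunk", factor = 2), "test"))
  expect_equal(body_mass_direct(m2e), 8)
  expect_equal(body_volume(m2e), 0.005)  # hull volume untouched by EF

  m0 <- m2; m0$expansion_factor <- 0
  expect_equal(body_mass_direct(m0), 0)
})

test_that("expansion factors average skin:hull ratios and default to 1", {
  hull <- tibble::tibble(specimen = c("a", "b"), segment = "trunk",
                         volume = c(1, 2))
  skin <- tibble::tibble(specimen = c("a", "b"), segment = "trunk",
                         volume = c(1.2, 2.6))
  ef <- compute_expansion_factors(hull, skin, label = "MEF")
  expect_equal(ef$factor[ef$segment == "trunk"], mean(c(1.2, 1.3)))
  expect_identical(attr(ef, "label"), "MEF")

  same <- compute_expansion_factors(hull, hull)
  expect_equal(same$factor, 1)
  single <- compute_expansion_factors(hull[1, ], skin[1, ])
  expect_equal(single$factor, 1.2)
  expect_error(compute_expansion_factors(hull, skin[1, ]), "unpaired")

  m <- two_segment_body(0.01, 0.02, clade = "mammal")
  ident <- masshull:::new_expansion_table(
    tibble::tibble(segment = c("skull", "trunk"), factor = 1), "id")
  expect_equal(body_mass_direct(apply_expansion(m, ident)),
               body_mass_direct(m))
  # table missing a segment leaves its factor at 1
  partial <- masshull:::new_expansion_table(
    tibble::tibble(segment = "skull", factor = 1.5), "p")
  mp <- apply_expansion(m, partial)
  expect_equal(mp$expansion_factor[mp$name == "trunk"], 1)
  # single-segment factor f changes total mass by exactly (f-1)*V*rho
  expect_equal(body_mass_direct(mp) - body_mass_direct(m),
               0.5 * 0.01 * 1000, tolerance = 1e-12)
})

test_that("expanding the tail pulls the center of mass toward it", {
  m <- two_segment_body(0.01, 0.01, x1 = 0, x2 = 2,
                        names = c("skull", "tail"), clade = "crocodylian")
  com0 <- center_of_mass(m)
  tail_up <- apply_expansion(m, masshull:::new_expansion_table(
    tibble::tibble(segment = "tail", factor = 1.5), "t"))
  com1 <- center_of_mass(tail_up)
  expect_gt(com1[1], com0[1])  # tail sits at larger x
  # hand recomputation of the weighted mean
  expect_equal(com1[1], (0.01 * 0 + 0.015 * 2) / 0.025, tolerance = 1e-12)
})

test_that("trunk deflation scales trunk mass and shifts the CoM away", {
  m <- two_segment_body(0.01, 0.02, names = c("skull", "trunk"),
                        clade = "mammal")
  expect_equal(body_mass_direct(deflate_trunk(m, 1)), body_mass_direct(m))
  trunk_only <- suppress_canonical_warning(assemble_body(
    tibble::tibble(name = "trunk", volume = 0.01, cx = 0, cy = 0, cz = 0),
    clade = "mammal"))
  expect_equal(body_mass_direct(deflate_trunk(trunk_only, 0.7)),
               0.7 * body_mass_direct(trunk_only), tolerance = 1e-12)

  trunk_x <- 2
  dist_from_trunk <- vapply(c(1, 0.9, 0.8, 0.7), function(fr) {
    abs(center_of_mass(deflate_trunk(m, fr))[1] - trunk_x)
  }, numeric(1))
  expect_true(all(diff(dist_from_trunk) > 0))  # strictly monotone shift

  expect_error(deflate_trunk(m, 0), "fraction")
  expect_error(deflate_trunk(m, 1.2), "fraction")
  no_trunk <- two_segment_body(names = c("skull", "tail"), clade = "mammal")
  expect_error(deflate_trunk(no_trunk, 0.9), "no trunk")
})

test_that("center of mass is the mass-weighted mean and density-scale free", {
  m <- two_segment_body(0.01, 0.01, x1 = 0, x2 = 2, clade = "mammal")
  expect_equal(center_of_mass(m), c(1, 0, 0))
  w <- two_segment_body(0.001, 0.003, x1 = 0, x2 = 4, clade = "mammal")
  expect_equal(center_of_mass(w)[1], 3)
  w2 <- w; w2$density <- w$density * 1.08
  expect_identical(center_of_mass(w2), center_of_mass(w))
  z <- w; z$expansion_factor <- 0
  expect_error(center_of_mass(z), "zero")
})

landmarked_body <- function() {
  lm <- list(acetabulum = c(0, 0, 0), glenoid = c(2, 0, 0), femur_length = 1)
  segs <- tibble::tibble(
    name = c("skull", "trunk", "tail"),
    volume = c(0.01, 0.02, 0.005),
    cx = c(3, 1, -1), cy = 0, cz = 0)
  suppress_canonical_warning(
    assemble_body(segs, landmarks = lm, clade = "fossil"))
}

test_that("positional metrics follow the acetabulum-glenoid projection", {
  lm <- list(acetabulum = c(0, 0, 0), glenoid = c(2, 0, 0), femur_length = 1)
  at_acet <- suppress_canonical_warning(assemble_body(
    tibble::tibble(name = "trunk", volume = 0.01, cx = 0, cy = 0, cz = 0),
    landmarks = lm, clade = "mammal"))
  expect_equal(com_metrics(at_acet)$pct_AG, 0)
  at_glen <- suppress_canonical_warning(assemble_body(
    tibble::tibble(name = "trunk", volume = 0.01, cx = 2, cy = 0, cz = 0),
    landmarks = lm, clade = "mammal"))
  expect_equal(com_metrics(at_glen)$pct_AG, 100)
  # CoM at the midpoint, femur length |AG|/2: pct 50, dca_fl exactly 1
  mid <- suppress_canonical_warning(assemble_body(
    tibble::tibble(name = "trunk", volume = 0.01, cx = 1, cy = 0, cz = 0),
    landmarks = lm, clade = "mammal"))
  cm <- com_metrics(mid)
  expect_equal(cm$pct_AG, 50)
  expect_equal(cm$dca_fl, 1)
  expect_equal(cm$pct_AG, 100 * cm$dca_fl * lm$femur_length / 2)
})

test_that("positional metrics are rigid-motion invariant and density-robust", {
  m <- landmarked_body()
  base <- com_metrics(m)
  rot <- random_rotation(seed = 42)
  shift <- c(5, -3, 2)
  moved <- m
  moved[, c("cx", "cy", "cz")] <-
    sweep(as.matrix(m[, c("cx", "cy", "cz")]) %*% t(rot), 2, shift, "+")
  lm0 <- masshull:::model_landmarks(m)
  attr(moved, "landmarks") <- list(
    acetabulum = as.vector(rot %*% lm0$acetabulum) + shift,
    glenoid = as.vector(rot %*% lm0$glenoid) + shift,
    femur_length = lm0$femur_length)
  movd <- com_metrics(moved)
  expect_equal(movd$pct_AG, base$pct_AG, tolerance = 1e-9)
  expect_equal(movd$dca_fl, base$dca_fl, tolerance = 1e-9)

  # any uniform density in the measured 893-1080 kg/m^3 range is irrelevant
  for (rho in c(893, 1000, 1080)) {
    md <- m; md$density <- rho
    expect_identical(com_metrics(md)$pct_AG, base$pct_AG)
    expect_identical(com_metrics(md)$dca_fl, base$dca_fl)
  }
})

test_that("skull:tail ratio needs both segments; tail sub-hulls sum", {
  m <- landmarked_body()
  expect_equal(com_metrics(m)$log10_skull_tail, log10(0.01 / 0.005))
  lm <- masshull:::model_landmarks(m)
  no_tail <- suppress_canonical_warning(assemble_body(
    tibble::tibble(name = c("skull", "trunk"), volume = c(0.01, 0.02),
                   cx = c(3, 1), cy = 0, cz = 0),
    landmarks = lm, clade = "mammal"))
  expect_true(is.na(com_metrics(no_tail)$log10_skull_tail))
  subdiv <- suppress_canonical_warning(assemble_body(
    tibble::tibble(name = c("skull", "tail_sub_1", "tail_sub_2"),
                   volume = c(0.01, 0.003, 0.002),
                   cx = c(3, -1, -2), cy = 0, cz = 0),
    landmarks = lm, clade = "crocodylian"))
  expect_equal(com_metrics(subdiv)$log10_skull_tail, log10(0.01 / 0.005))
})

test_that("landmark JSON and expansion-table files round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(acetabulum = c(0, 0, 0), glenoid = c(1.5, 0, 0.2),
                            femur_length_m = 0.4),
                       f, auto_unbox = TRUE, digits = NA)
  lm <- read_landmarks(f)
  expect_equal(lm$glenoid, c(1.5, 0, 0.2))
  expect_equal(lm$femur_length, 0.4)

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(segment = c("trunk", "tail"),
                                  factor = c(1.1, 1.4)), csv)
  et <- read_expansion_table(csv, label = "SEF")
  expect_identical(attr(et, "label"), "SEF")
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "MEF", factors = list(trunk = 1.1)),
                       jf, auto_unbox = TRUE, digits = NA)
  expect_equal(read_expansion_table(jf)$factor, 1.1)
})
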