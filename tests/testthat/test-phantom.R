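test_that("phantom truth is analytic and matches the generated grid", {
  ph <- make_phantom(phantom_spec("plate_stack", pitch_mm = 1,
                                  element_width_mm = 0.2,
                                  extent_mm = c(4, 4, 4),
                                  base_spacing_mm = 0.05))
  expect_equal(ph$truth$bvtv, 0.2)
  expect_equal(ph$truth$tb_th_mm, 0.2)
  expect_equal(ph$truth$tb_sp_mm, 0.8)
  expect_equal(ph$truth$tb_sc_mm, 1.0)
  expect_equal(mean(ph$truth_mask$data), 0.2)  # exact voxel-count agreement
  expect_identical(sort(unique(as.vector(ph$volume$data))), c(100, 1000))

  rods <- make_phantom(phantom_spec("rod_lattice", pitch_mm = 1,
                                    element_width_mm = 0.2,
                                    extent_mm = c(4, 4, 4),
                                    base_spacing_mm = 0.05))
  expect_equal(rods$truth$bvtv, pi * 0.01)
  expect_lte(abs(mean(rods$truth_mask$data) - rods$truth$bvtv),
             0.2 * rods$truth$bvtv)
})

test_that("phantom generation is deterministic and validates geometry", {
  spec <- phantom_spec("mixed", pitch_mm = 0.6, element_width_mm = 0.15,
                       extent_mm = rep(1.2, 3), base_spacing_mm = 0.03,
                       rng_seed = 5)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_error(phantom_spec(pitch_mm = 0.2, element_width_mm = 0.2),
               "unresolvable")
  expect_error(phantom_spec(element_width_mm = 0.1, base_spacing_mm = 0.05),
               "unresolvable")
})

test_that("degradation with null parameters is the identity", {
  ph <- small_plate_phantom(extent = 1)
  out <- degrade(ph$volume, degradation_spec(0, ph$volume$spacing_mm, 0))
  expect_equal(out$data, ph$volume$data)
  expect_equal(out$spacing_mm, ph$volume$spacing_mm)
  expect_error(degrade(ph$volume,
                       degradation_spec(0, ph$volume$spacing_mm / 2, 0)),
               "finer")
})

test_that("Gaussian blur conserves total intensity and reduces CNR at fixed noise", {
  ph <- small_plate_phantom(spacing = 0.04, extent = 2)
  blur <- degrade(ph$volume, degradation_spec(0.05, 0.04, 0))
  expect_equal(mean(blur$data), mean(ph$volume$data), tolerance = 1e-6)

  cnr_of <- function(psf) {
    deg <- degrade(ph$volume, degradation_spec(psf, 0.04, 30, rng_seed = 8))
    skel <- skeletonize(ph$truth_mask$data, 0.04)
    cnr(deg, skel, !ph$truth_mask$data)
  }
  expect_gt(cnr_of(0.02), cnr_of(0.06))
})

test_that("degradation resampling coarsens the lattice correctly", {
  ph <- small_plate_phantom(spacing = 0.05, extent = 2)
  d2 <- degrade(ph$volume, degradation_spec(0, 0.1, 0))   # integer: block mean
  expect_equal(d2$spacing_mm, 0.1)
  expect_identical(dim(d2$data), dim(ph$volume$data) %/% 2L)
  expect_equal(mean(d2$data), mean(ph$volume$data), tolerance = 1e-9)
  d3 <- degrade(ph$volume, degradation_spec(0, 0.061, 0))  # trilinear
  expect_equal(d3$spacing_mm, 0.061)
  expect_identical(dim(d3$data), as.integer(floor(dim(ph$volume$data) / 1.22)))
  expect_gte(min(d3$data), min(ph$volume$data) - 1e-9)
  expect_lte(max(d3$data), max(ph$volume$data) + 1e-9)
})

test_that("noise calibration hits device CNR anchors on a reference phantom", {
  ph <- make_phantom(phantom_spec("plate_stack", pitch_mm = 1.0496,
                                  element_width_mm = 0.1968,
                                  extent_mm = rep(3.1488, 3),
                                  base_spacing_mm = 0.0328))
  deg <- degrade_with_preset(ph, "microct32", rng_seed = 7)
  res <- analyze(deg$volume, method = "otsu")
  expect_lt(abs(res$cnr - 12.57) / 12.57, 0.15)

  deg61 <- degrade_with_preset(ph, "hr61", rng_seed = 7)
  res61 <- analyze(deg61$volume, method = "otsu")
  expect_lt(abs(res61$cnr - 6.98) / 6.98, 0.3)
  expect_gt(res$cnr, res61$cnr)  # micro-CT is the high-CNR device
})

test_that("degradation is reproducible from its seed", {
  ph <- small_plate_phantom(extent = 1)
  a <- degrade(ph$volume, degradation_spec(0.03, 0.061, 25, rng_seed = 3))
  b <- degrade(ph$volume, degradation_spec(0.03, 0.061, 25, rng_seed = 3))
  d <- degrade(ph$volume, degradation_spec(0.03, 0.061, 25, rng_seed = 4))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, d$data))
})

test_that("specimen cohorts are reproducible and respect the stated ranges", {
  coh <- specimen_cohort(n = 4, width_range = c(0.12, 0.2),
                         pitch_range = c(0.5, 0.7), kind = "mixed",
                         base_spacing_mm = 0.04, extent_mm = 1.2,
                         preset = "hr61", rng_seed = 2)
  expect_length(coh, 4)
  widths <- sapply(coh, `[[`, "width_mm")
  expect_true(all(widths >= 0.12 & widths <= 0.2))
  truths <- sapply(coh, function(s) s$truth$bvtv)
  expect_true(all(truths > 0 & truths < 1))
  coh2 <- specimen_cohort(n = 4, width_range = c(0.12, 0.2),
                          pitch_range = c(0.5, 0.7), kind = "mixed",
                          base_spacing_mm = 0.04, extent_mm = 1.2,
                          preset = "hr61", rng_seed = 2)
  expect_identical(coh[[3]]$degraded$volume$data,
                   coh2[[3]]$degraded$volume$data)
  expect_warning(
    specimen_cohort(n = 3, width_range = c(0.18, 0.18),
                    pitch_range = c(0.6, 0.6), kind = "plate_stack",
                    base_spacing_mm = 0.05, extent_mm = 1.2, rng_seed = 1),
    "degenerate"
  )
})
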