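test_that("measure_loop: circle, scaling law, rotation invariance", {
  loop <- circle_loop(256)
  meas <- measure_loop(loop)
  expect_identical(round(meas$perimeter_cm, 2), 6.28)
  expect_identical(round(meas$area_cm2, 2), 3.14)
  expect_equal(meas$axial_diameter_cm, 2, tolerance = 1e-3)

  big <- measure_loop(loop * 1.2)
  expect_equal(big$perimeter_cm, meas$perimeter_cm * 1.2)
  expect_equal(big$area_cm2, meas$area_cm2 * 1.44)

  # unit square rotated into a tilted plane keeps area 1 and perimeter 4
  sq <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(10, 5, 0),
              c(10, 10, 0), c(5, 10, 0), c(0, 10, 0), c(0, 5, 0))
  th <- 0.7; ph <- 0.3
  R1 <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  R2 <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  tilted <- sq %*% t(R2 %*% R1) + matrix(c(3, -2, 5), 8, 3, byrow = TRUE)
  mt <- measure_loop(tilted)
  expect_equal(mt$area_cm2, 1, tolerance = 1e-10)
  expect_equal(mt$perimeter_cm, 4, tolerance = 1e-10)
})

test_that("measure_loop rejects degenerate input", {
  expect_error(measure_loop(circle_loop(6)), "at least 8")
  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(measure_loop(line), "zero-area|non-simple")
  bowtie <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0),
                  c(0.5, 1, 0), c(2, 1, 0), c(1.4, 0.25, 0), c(0.6, 0.75, 0))
  expect_error(measure_loop(bowtie), "non-simple")
})

test_that("enlargement reproduces the printed percent columns", {
  ref <- measure_loop(circle_loop(256))           # 3.14 cm^2, 6.28 cm
  same <- enlargement(ref, ref)
  expect_identical(same$percent_area_increase, 0)
  expect_identical(same$percent_perimeter_increase, 0)

  printed <- function(area, per) {
    tibble::tibble(perimeter_cm = per, area_cm2 = area,
                   axial_diameter_cm = NA_real_, sagittal_diameter_cm = NA_real_,
                   percent_area_increase = NA_real_,
                   percent_perimeter_increase = NA_real_)
  }
  base <- printed(3.14, 6.28)
  lateral <- enlargement(base, printed(5.82, 9.05))
  expect_identical(round(lateral$percent_area_increase), 85)
  expect_identical(round(lateral$percent_perimeter_increase), 44)
  midline <- enlargement(base, printed(3.76, 6.93))
  expect_identical(round(midline$percent_area_increase), 20)
  expect_identical(round(midline$percent_perimeter_increase), 10)
})

test_that("extract_trephine_loop honours displacement and orientation", {
  m <- small_phantom("s21")
  ref <- extract_trephine_loop(m, "trephine_inner_loop")
  shift <- c(1, 2, 3)
  u <- matrix(shift, nrow(m$nodes), 3L, byrow = TRUE)
  moved <- extract_trephine_loop(m, "trephine_inner_loop", u = u)
  expect_equal(moved, ref + matrix(shift, nrow(ref), 3L, byrow = TRUE))
  mm <- measure_loop(moved)
  mr <- measure_loop(ref)
  expect_equal(mm$area_cm2, mr$area_cm2)
  expect_equal(mm$perimeter_cm, mr$perimeter_cm)

  # counter-clockwise about the outward normal regardless of stored order
  flipped <- m
  flipped$loops$trephine_inner_loop <- rev(m$loops$trephine_inner_loop)
  ref2 <- extract_trephine_loop(flipped, "trephine_inner_loop")
  expect_gt(sum(wallfem:::newell_vector(ref2) *
                wallfem:::newell_vector(ref)), 0)

  expect_error(extract_trephine_loop(m, "nope"), "unknown loop")
  expect_error(extract_trephine_loop(small_phantom(), "trephine_inner_loop"),
               "unknown loop")
})

test_that("isoperimetric inequality holds for measured loops", {
  m <- small_phantom("s21")
  meas <- measure_loop(extract_trephine_loop(m, "trephine_inner_loop"))
  expect_gte(meas$perimeter_cm^2 * (1 + 1e-9), 4 * pi * meas$area_cm2)
  mt <- measure_loop(t(t(circle_loop(64)) * c(2, 0.5, 1)))  # 4:1 ellipse
  expect_gte(mt$perimeter_cm^2 * (1 + 1e-9), 4 * pi * mt$area_cm2)
})

test_that("summarize_by_position groups the labelling scheme correctly", {
  # the printed per-stoma area increases of the three vertical lines
  printed <- tibble::tibble(
    position = c("s0", paste0("s1", 1:6), paste0("s2", 1:6), paste0("s3", 1:4)),
    percent_area_increase = c(20, 14, 16, 33, 33, 35, 30,
                              51, 53, 71, 78, 38, 25, 36, 85, 38, 56),
    percent_perimeter_increase = c(10, 9, 11, 20, 19, 19, 16,
                                   23, 28, 38, 43, 20, 14, 19, 44, 21, 29))
  sm <- summarize_by_position(printed)
  expect_setequal(sm$group, c("s0", "s1j", "s2j", "s3j"))
  # recomputed from printed integers; the published averages (28, 53, 54)
  # used unrounded values, so agree within 2 points
  expect_equal(sm$mean_percent_area_increase[sm$group == "s1j"], 28,
               tolerance = 2 / 28)
  expect_equal(sm$mean_percent_area_increase[sm$group == "s2j"], 53,
               tolerance = 2 / 53)
  expect_equal(sm$mean_percent_area_increase[sm$group == "s3j"], 54,
               tolerance = 2 / 54)
  expect_identical(sm$mean_percent_area_increase[sm$group == "s0"], 20)

  single <- summarize_by_position(printed[2, ])
  expect_identical(nrow(single), 1L)
  expect_identical(single$mean_percent_area_increase,
                   printed$percent_area_increase[2])

  expect_error(summarize_by_position(tibble::tibble(
    position = "s77", percent_area_increase = 1,
    percent_perimeter_increase = 1)), "unknown position")
})
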