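test_that("component labelling respects the requested connectivity", {
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L; m[3, 3] <- 1L   # touch only diagonally
  expect_identical(max(label_components(m, 8L)), 1L)
  expect_identical(max(label_components(m, 4L)), 2L)
  # two separate blobs
  m2 <- matrix(0L, 8, 8)
  m2[1:2, 1:2] <- 1L; m2[6:8, 6:8] <- 1L
  lab <- label_components(m2)
  expect_identical(max(lab), 2L)
  expect_identical(sort(unique(tabulate(lab[lab > 0]))), c(4L, 9L))
})

test_that("hole filling closes interior holes only", {
  ring <- matrix(0L, 9, 9)
  ring[3:7, 3:7] <- 1L
  ring[4:6, 4:6] <- 0L
  filled <- fill_holes(ring)
  expect_identical(sum(filled), 25L)
  # a bay open to the border is not a hole
  bay <- matrix(0L, 9, 9)
  bay[3:7, 3:7] <- 1L
  bay[1:5, 5] <- 0L
  expect_identical(fill_holes(bay), bay == 1L)
})

test_that("nucleus mask applies range threshold, size filter and filling", {
  px <- 1  # 1 um pixels
  expect_identical(sum(mask_nuclei(matrix(0, 30, 30), px)), 0L)
  # ring of outer area ~80 um^2 becomes a solid disk
  ring <- matrix(0, 40, 40)
  ring <- paint_disk(ring, 20, 20, 5, 200)
  ring <- paint_disk(ring, 20, 20, 2, 0)
  m <- mask_nuclei(ring, px)
  expect_equal(sum(m), sum(paint_disk(matrix(0, 40, 40), 20, 20, 5, 1)))
  # a 40 um^2 disk falls under the 50 um^2 minimum
  small <- paint_disk(matrix(0, 30, 30), 15, 15, sqrt(40 / pi), 200)
  expect_identical(sum(mask_nuclei(small, px)), 0L)
  big <- paint_disk(matrix(0, 40, 40), 20, 20, sqrt(60 / pi), 200)
  expect_gt(sum(mask_nuclei(big, px)), 0)
  # threshold is a percentage of the dynamic range: 13% of 255 = 33.15
  lvl <- matrix(0, 20, 20)
  lvl[5:15, 5:15] <- 33   # below
  expect_identical(sum(mask_nuclei(lvl, px, min_area = 1)), 0L)
  lvl[5:15, 5:15] <- 34   # above
  expect_gt(sum(mask_nuclei(lvl, px, min_area = 1)), 0)
  expect_warning(mask_nuclei(big, pixel_size = 10, min_area = 50),
                 "smaller than one pixel")
})

test_that("whole-cell mask has inclusive absolute thresholds", {
  px <- 1
  m <- matrix(0, 30, 30)
  m <- paint_disk(m, 15, 15, 10, 6)
  m[15, 15] <- 5
  mask <- mask_total(m, px)
  expect_false(mask[15, 15])        # intensity 5 excluded
  expect_true(mask[15, 16])         # intensity 6 included
  # 99 vs 101 um^2 at the 100 um^2 minimum
  d99 <- paint_disk(matrix(0, 30, 30), 15, 15, sqrt(99 / pi), 100)
  d101 <- paint_disk(matrix(0, 30, 30), 15, 15, sqrt(101 / pi), 100)
  expect_identical(sum(mask_total(d99, px)), 0L)
  expect_gt(sum(mask_total(d101, px)), 0)
  # uniform frame -> single full-frame component
  uni <- matrix(200, 25, 25)
  mu <- mask_total(uni, px)
  expect_true(all(mu))
  expect_identical(max(label_components(mu)), 1L)
})

test_that("raising the lower Cy5 threshold never grows the mask", {
  set.seed(5)
  img <- matrix(sample(0:255, 50 * 50, TRUE), 50, 50)
  prev <- mask_total(img, 1, intensity_low = 0, min_area = 0)
  for (lo in c(6, 60, 150)) {
    cur <- mask_total(img, 1, intensity_low = lo, min_area = 0)
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("mask combination follows the exclusive-combine algebra", {
  nuc <- matrix(FALSE, 6, 6); tot <- matrix(FALSE, 6, 6)
  tot[2:5, 2:5] <- TRUE
  nuc[3:4, 3:4] <- TRUE
  ms <- combine_masks(nuc, tot)
  expect_identical(ms$cytoplasm, tot & !nuc)
  expect_identical(ms$cy5_nuclei, tot & nuc)
  # nuclei == total degenerates to all-nuclei
  ms2 <- combine_masks(tot, tot)
  expect_identical(sum(ms2$cytoplasm), 0L)
  expect_identical(ms2$cy5_nuclei, tot)
  # a nucleus pixel outside total lands in the symmetric difference and is
  # excluded from the stained-nuclei mask (3x3 toy, worked by hand)
  n3 <- matrix(FALSE, 3, 3); t3 <- matrix(FALSE, 3, 3)
  t3[1:2, 1:2] <- TRUE
  n3[1, 1] <- TRUE; n3[3, 3] <- TRUE
  ms3 <- combine_masks(n3, t3)
  expect_true(ms3$cytoplasm[3, 3])
  expect_false(ms3$cy5_nuclei[3, 3])
  expect_true(ms3$cy5_nuclei[1, 1])
  expect_error(combine_masks(n3, matrix(FALSE, 3, 3)), "empty")
})

test_that("mask-set invariants hold on generated fields", {
  for (s in 1:3) {
    sim <- gen_fish_images(n_cells = 6, nc_ratio = 2, noise_sd = 3, seed = s)
    ms <- altcbc:::image_masks(sim$image)
    expect_false(any(ms$cytoplasm & ms$cy5_nuclei))
    if (!any(ms$nuclei & !ms$total))  # nuclei contained in total
      expect_identical(ms$cytoplasm | ms$cy5_nuclei, ms$total)
  }
})

test_that("uniform and constructed density ratios are recovered", {
  sim1 <- gen_fish_images(n_cells = 6, nc_ratio = 1, noise_sd = 0, seed = 2)
  s1 <- measure_nc_ratio(sim1$image, min_cells = 5)
  expect_equal(s1$mean, 1, tolerance = 1e-12)
  sim2 <- gen_fish_images(n_cells = 6, nc_ratio = 2, noise_sd = 0, seed = 2)
  s2 <- measure_nc_ratio(sim2$image, min_cells = 5)
  expect_equal(s2$mean, 2, tolerance = 1e-9)
})

test_that("an undersized field triggers the minimum-cell-count warning", {
  sim <- gen_fish_images(n_cells = 5, nc_ratio = 2, seed = 1)
  expect_warning(measure_nc_ratio(sim$image, min_cells = 125),
                 "minimum expected")
  expect_error(measure_nc_ratio(sim$image, min_cells = 125,
                                on_undercount = "error"),
               "minimum expected")
})

test_that("per-image mode and pixel-size rescaling agree with per-cell", {
  sim <- gen_fish_images(n_cells = 4, nc_ratio = 3, noise_sd = 0, seed = 6)
  pc <- measure_nc_ratio(sim$image, per_cell = TRUE, min_cells = 3)
  pi_ <- measure_nc_ratio(sim$image, per_cell = FALSE, min_cells = 1)
  expect_equal(pc$mean, pi_$mean, tolerance = 1e-9)
  # doubling pixel size with matched areas leaves masks/ratios unchanged
  img2 <- cell_image_set(sim$image$dapi, sim$image$cy5, pixel_size = 1,
                         condition = "x")
  s2 <- measure_nc_ratio(img2, min_cells = 3,
                         mask_params = list(nucleus_min_area = 50 * 4,
                                            total_min_area = 100 * 4))
  expect_equal(s2$mean, pc$mean, tolerance = 1e-9)
})

test_that("additive noise below the Cy5 threshold perturbs the ratio mildly", {
  # the protocol's absolute lower threshold is 6 counts; once the background
  # noise sd exceeds it, background floods the whole-cell mask by design, so
  # robustness is asserted for noise up to ~2% of the dynamic range
  clean <- gen_fish_images(n_cells = 9, nc_ratio = 2, noise_sd = 0, seed = 4)
  r0 <- measure_nc_ratio(clean$image, min_cells = 5)$mean
  for (ns in c(0.01, 0.02) * 255) {
    noisy <- gen_fish_images(n_cells = 9, nc_ratio = 2, noise_sd = ns,
                             seed = 4)
    r1 <- measure_nc_ratio(noisy$image, min_cells = 5)$mean
    expect_lt(abs(r1 - r0) / r0, 0.10)
  }
})

test_that("one-way ANOVA matches a sums-of-squares oracle and Tukey behaves", {
  set.seed(12)
  vals <- list(a = rnorm(5, 1), b = rnorm(5, 1.5), c = rnorm(5, 3))
  res <- anova_tukey(vals)
  f_oracle <- oracle_anova_f(unlist(vals), rep(names(vals), each = 5))
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  # extreme separation: adjusted p < 0.001
  res2 <- anova_tukey(list(a = rnorm(50, 1, 0.1), b = rnorm(50, 5, 0.1)))
  expect_lt(res2$tukey$p_adj, 0.001)
  # identical constant conditions: F = 0, p = 1, no significant pairs
  res3 <- anova_tukey(list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4)))
  expect_identical(res3$F, 0)
  expect_identical(res3$p, 1)
  expect_true(all(res3$tukey$p_adj == 1))
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(anova_tukey(list(a = c(1, 2))), "at least 2 conditions")
})

test_that("TIFF round trip preserves channel data", {
  sim <- gen_fish_images(n_cells = 4, nc_ratio = 2, seed = 9)
  dir <- tempfile(); dir.create(dir)
  dp <- file.path(dir, "d.tiff"); cp <- file.path(dir, "c.tiff")
  tiff::writeTIFF(sim$image$dapi / 255, dp)
  tiff::writeTIFF(sim$image$cy5 / 255, cp)
  img <- read_cell_images(dp, cp, pixel_size = 0.5, condition = "rt")
  expect_equal(img$dapi, sim$image$dapi, tolerance = 1e-9)
  expect_equal(img$cy5, sim$image$cy5, tolerance = 1e-9)
})
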