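test_that("raw Rayleigh envelope has the closed-form mean sigma*sqrt(pi/2)", {
  sigma <- 2.5
  env <- echotex:::rayleigh_envelope(200, 200, sigma, seed = 99L)
  n <- length(env)
  true_mean <- sigma * sqrt(pi / 2)
  true_sd <- sigma * sqrt(2 - pi / 2)
  expect_lt(abs(mean(env) - true_mean), 3 * true_sd / sqrt(n))
})

test_that("make_speckle is deterministic under the seed and hits its target mean", {
  spec <- phantom_spec(shape = c(64L, 64L), smoothing_radius = 0, seed = 5L)
  img1 <- make_speckle(spec)
  img2 <- make_speckle(spec)
  expect_identical(img1$pixels, img2$pixels)
  img3 <- make_speckle(phantom_spec(shape = c(64L, 64L),
                                    smoothing_radius = 0, seed = 6L))
  expect_gt(sum(img1$pixels != img3$pixels), 0)
  expect_lt(abs(mean(img1$pixels) - 120), 5)
  expect_error(phantom_spec(speckle_scale = 0), "speckle_scale")
  expect_error(phantom_spec(smoothing_radius = -1), "smoothing_radius")
})

test_that("insert_microliths places bright non-overlapping foci at reported coordinates", {
  bg <- gray_image(matrix(50L, 64, 64), 256L)
  one <- insert_microliths(bg, count = 1, radius_px = 2,
                           intensity_gain = 120, seed = 3)
  bright <- one$image$pixels > 50L
  expect_equal(sum(bright), sum(echotex:::disk_mask(64, 64, one$foci$x[1],
                                                    one$foci$y[1], 2)))
  expect_equal(unique(one$image$pixels[bright]), 170L)

  ten <- insert_microliths(bg, count = 10, seed = 4)
  expect_equal(nrow(ten$foci), 10)
  px <- ten$image$pixels
  for (k in 1:10) {
    # each reported center is a local intensity maximum
    cx <- ten$foci$x[k]; cy <- ten$foci$y[k]
    centre <- px[cy + 1, cx + 1]
    nb <- px[max(1, cy - 4):min(64, cy + 6), max(1, cx - 4):min(64, cx + 6)]
    expect_equal(centre, max(nb))
    expect_gt(centre, 50L)
  }
  expect_error(insert_microliths(bg, count = 500, seed = 1),
               "fewer foci")
  expect_error(insert_microliths(bg, count = 3, radius_px = 30, seed = 1),
               "radius too large")
})

test_that("microlith foci shift texture features in the lesion direction", {
  spec <- phantom_spec(shape = c(64L, 64L), seed = 21L)
  bg <- make_speckle(spec)
  ml <- insert_microliths(bg, count = 12, intensity_gain = 120, seed = 22)
  f0 <- image_features(bg)
  f1 <- image_features(ml$image)
  expect_gt(f1["entropy"], f0["entropy"])
  expect_gt(f1["contrast"], f0["contrast"])
  expect_gt(f1["dissimilarity"], f0["dissimilarity"])
  expect_lt(f1["asm"], f0["asm"])
  expect_lt(f1["energy"], f0["energy"])
})

test_that("insert_cyst darkens the interior and draws bright septa", {
  spec <- phantom_spec(shape = c(64L, 64L), seed = 31L)
  bg <- make_speckle(spec)
  plain <- insert_cyst(bg, center = c(31, 31), axes = c(14, 10),
                       septa_count = 0, seed = 1)
  inside <- outer(((0:63) - 31)^2 / 100, ((0:63) - 31)^2 / 196, `+`) <= 1
  expect_lt(mean(plain$pixels[inside]), mean(bg$pixels[!inside]))

  septated <- insert_cyst(bg, center = c(31, 31), axes = c(14, 10),
                          septa_count = 2, septa_intensity = 180, seed = 2)
  interior_vals <- septated$pixels[inside]
  expect_gt(sum(interior_vals >= 145L), 10)       # septa pixels present
  expect_lt(stats::median(interior_vals), 30)     # interior near-anechoic
  expect_identical(
    insert_cyst(bg, center = c(31, 31), axes = c(14, 10), seed = 2)$pixels,
    insert_cyst(bg, center = c(31, 31), axes = c(14, 10), seed = 2)$pixels)
  f0 <- image_features(bg); f1 <- image_features(septated)
  expect_gt(f1["entropy"], f0["entropy"])
  expect_gt(f1["contrast"], f0["contrast"])
  expect_error(insert_cyst(bg, center = c(5, 5), axes = c(14, 10)),
               "out of bounds")
})

test_that("heterogeneous gain field changes texture but respects gray range", {
  spec <- phantom_spec(shape = c(64L, 64L), seed = 41L)
  bg <- make_speckle(spec)
  het <- apply_heterogeneity(bg, patch_scale = 10,
                             gain_range = c(0.5, 1.5), seed = 42)
  expect_true(all(het$pixels >= 0L & het$pixels <= 255L))
  expect_gt(sum(het$pixels != bg$pixels), 100)
  expect_identical(
    apply_heterogeneity(bg, patch_scale = 10, seed = 42)$pixels,
    apply_heterogeneity(bg, patch_scale = 10, seed = 42)$pixels)
  expect_error(apply_heterogeneity(bg, gain_range = c(2, 1)), "gain_range")
})

test_that("make_phantom is a pure function of spec + seed", {
  for (lesion in c("none", "microliths", "cyst", "heterogeneous")) {
    s <- phantom_spec(shape = c(48L, 48L), lesion = lesion, seed = 77L)
    expect_identical(make_phantom(s)$pixels, make_phantom(s)$pixels)
  }
})

test_that("make_cohort writes matching PNGs and labels, byte-identically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- cohort_spec(n_normal = 5, n_microlith = 3, n_other = 2,
                      shape = c(48L, 48L), seed = 19)
  rois1 <- make_cohort(spec, d1)
  expect_equal(nrow(rois1), 10L)
  expect_equal(sum(rois1$lesion_label == "normal"), 5L)
  expect_equal(sum(rois1$lesion_label == "microlith"), 3L)
  expect_equal(sum(rois1$lesion_label == "other"), 2L)
  expect_true(all(rois1$mineralization == (rois1$lesion_label == "microlith")))
  expect_true(all(rois1$nodule == (rois1$lesion_label == "other")))
  pngs <- list.files(d1, pattern = "\\.png$")
  expect_equal(length(pngs), 10L)

  make_cohort(spec, d2)
  for (f in c(pngs, "rois.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
})

test_that("cohort group sizes follow the study-scale default composition", {
  spec <- cohort_spec()
  expect_equal(spec$n_normal + spec$n_microlith + spec$n_other, 280L)
  expect_equal(c(spec$n_normal, spec$n_microlith, spec$n_other),
               c(245L, 16L, 19L))
})
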