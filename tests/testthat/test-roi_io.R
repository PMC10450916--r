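test_that("crop_roi follows the 0-based half-open convention", {
  set.seed(3)
  px <- random_gray_matrix(10, 10, 256L)
  img <- gray_image(px, 256L)
  full <- crop_roi(img, roi_spec("a.png", 0, 0, 10, 10))
  expect_equal(full$pixels, img$pixels)
  one <- crop_roi(img, roi_spec("a.png", 4, 2, 5, 3))
  expect_equal(one$pixels, px[3, 5, drop = FALSE])
  # index-arithmetic oracle for [2,7) x [3,9)
  crop <- crop_roi(img, roi_spec("a.png", 2, 3, 7, 9))
  expect_equal(dim(crop$pixels), c(6L, 5L))
  for (r in 0:5) for (cc in 0:4)
    expect_equal(crop$pixels[r + 1, cc + 1], px[3 + r + 1, 2 + cc + 1])
  expect_error(crop_roi(img, roi_spec("a.png", 5, 5, 12, 8)),
               "out of bounds")
  expect_error(roi_spec("a.png", 5, 5, 5, 8), "invalid ROI")
})

test_that("extract_record composes crop + GLCM + features and keeps labels", {
  set.seed(8)
  px <- random_gray_matrix(40, 40, 256L)
  img <- gray_image(px, 256L)
  roi <- roi_spec("img1.png", 4, 6, 36, 38, plane = "sagittal",
                  side = "left")
  params <- glcm_params()
  rec <- extract_record(img, roi, params, mineralization = TRUE,
                        lesion_label = "microlith",
                        metadata = list(age_group = "8-10"))
  manual <- glcm_features(compute_glcm(crop_roi(img, roi), params))
  expect_equal(unlist(rec[feature_names()]), manual)
  expect_equal(rec$lesion_label, "microlith")
  expect_true(rec$mineralization)
  expect_equal(rec$age_group, "8-10")
  expect_equal(names(rec)[1:17],
               c("image_id", "x0", "y0", "x1", "y1", "plane", "side",
                 "mineralization", "nodule", "lesion_label",
                 feature_names()))

  const <- gray_image(matrix(3L, 20, 20), levels = 256)
  rc <- extract_record(const, roi_spec("c.png", 0, 0, 20, 20))
  expect_equal(rc$entropy, 0); expect_equal(rc$asm, 1)

  expect_error(extract_record(img, roi, lesion_label = "microlith"),
               "mineralization")
  expect_error(extract_record(img, roi, lesion_label = "other"),
               "nodule")
  tiny <- roi_spec("img1.png", 0, 0, 3, 3)
  expect_error(extract_record(img, tiny, params),
               "ROI too small for offset.*img1.png")
})

test_that("feature CSV round-trips losslessly with labels and row order", {
  set.seed(21)
  img <- gray_image(random_gray_matrix(64, 64, 256L), 256L)
  recs <- rbind(
    extract_record(img, roi_spec("a.png", 0, 0, 32, 32)),
    extract_record(img, roi_spec("a.png", 32, 0, 64, 32),
                   mineralization = TRUE, lesion_label = "microlith"),
    extract_record(img, roi_spec("b.png", 0, 0, 40, 40,
                                 plane = "transverse", side = "right"),
                   nodule = TRUE, lesion_label = "other"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(recs, path)
  back <- read_feature_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
  expect_equal(back$lesion_label, c("normal", "microlith", "other"))
  for (nm in feature_names())
    expect_equal(back[[nm]], recs[[nm]], tolerance = 1e-13)
})

test_that("CSV reader rejects schema mismatches and duplicate keys", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(foo = 1, bar = 2), path)
  expect_error(read_feature_csv(path), "schema mismatch")

  img <- gray_image(matrix(5L, 30, 30), 256L)
  rec <- extract_record(img, roi_spec("dup.png", 0, 0, 30, 30))
  two <- rbind(rec, rec)
  expect_error(write_feature_csv(two, path), "duplicate.*row 2")
  expect_error(read_feature_csv(tempfile()), "cannot read")
})

test_that("PNG images round-trip through load_grayscale_image", {
  dir <- withr::local_tempdir()
  vals <- matrix(c(0L, 255L, 0L, 255L), 1, 4)
  p1 <- file.path(dir, "strip.png")
  png::writePNG(vals / 255, p1)
  img <- load_grayscale_image(p1)
  expect_equal(img$pixels, vals)
  expect_equal(img$levels, 256L)

  # channel-equal RGB equals its grayscale twin
  set.seed(13)
  g <- matrix(sample(0:255, 64, TRUE), 8, 8) / 255
  rgb <- array(g, dim = c(8, 8, 3))
  p2 <- file.path(dir, "rgb.png"); p3 <- file.path(dir, "gray.png")
  png::writePNG(rgb, p2); png::writePNG(g, p3)
  expect_equal(load_grayscale_image(p2)$pixels,
               load_grayscale_image(p3)$pixels)

  # true color collapses by Rec. 709 luminance
  col <- array(0, dim = c(2, 2, 3)); col[, , 1] <- 1  # pure red
  p4 <- file.path(dir, "red.png")
  png::writePNG(col, p4)
  expect_equal(unique(as.vector(load_grayscale_image(p4)$pixels)),
               as.integer(round(0.2126 * 255)))
  expect_error(load_grayscale_image(file.path(dir, "missing.png")),
               "missing.png")
})

test_that("16-bit TIFF is rescaled by the fixed-range map; odd depths error", {
  dir <- withr::local_tempdir()
  t1 <- file.path(dir, "deep.tif")
  tiff::writeTIFF(matrix(c(0, 1), 1, 2), t1, bits.per.sample = 16)
  img <- load_grayscale_image(t1)
  expect_equal(as.vector(img$pixels), c(0L, 255L))
  # mid-range value maps through v * 255 / 65535
  t2 <- file.path(dir, "mid.tif")
  tiff::writeTIFF(matrix(30000 / 65535, 1, 1), t2, bits.per.sample = 16)
  expect_equal(as.vector(load_grayscale_image(t2)$pixels),
               as.integer(ceiling(30000 * 255 / 65535 - 0.5)))

  t3 <- file.path(dir, "float.tif")
  tiff::writeTIFF(matrix(0.5, 2, 2), t3, bits.per.sample = 32)
  expect_error(load_grayscale_image(t3), "unsupported bit depth")
})

test_that("feature extraction is invariant to joint image/ROI translation", {
  set.seed(31)
  inner <- random_gray_matrix(30, 30, 256L)
  big <- random_gray_matrix(50, 50, 256L)
  big2 <- big
  big[6:35, 11:40] <- inner
  big2[11:40, 16:45] <- inner
  params <- glcm_params()
  f1 <- glcm_features(compute_glcm(
    crop_roi(gray_image(big, 256L), roi_spec("a", 10, 5, 40, 35)), params))
  f2 <- glcm_features(compute_glcm(
    crop_roi(gray_image(big2, 256L), roi_spec("a", 15, 10, 45, 40)), params))
  expect_equal(f1, f2)
})

test_that("batch extraction is record-wise and order-independent", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_normal = 3, n_microlith = 2, n_other = 1,
                      shape = c(48L, 48L), seed = 5)
  rois <- make_cohort(spec, dir)
  tbl <- extract_features(dir, rois)
  expect_equal(nrow(tbl), 6L)
  perm <- c(4, 1, 6, 2, 5, 3)
  tbl2 <- extract_features(dir, rois[perm, ])
  expect_equal(as.data.frame(tbl2), as.data.frame(tbl[perm, ]),
               ignore_attr = TRUE)
})
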