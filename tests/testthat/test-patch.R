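test_that("landmark deltas follow the sign convention", {
  d <- compute_deltas(500, 100, 700, 300)
  expect_equal(d$delta_x, 400)
  expect_equal(d$delta_y, 400)
  expect_equal(compute_deltas(101, 100, 700, 300)$delta_x, 1)
  expect_error(compute_deltas(100, 500, 700, 300), "landmark convention")
})

test_that("patch size is the rounded-up maximum of the deltas", {
  expect_identical(compute_psize(423, 439), 439L)
  expect_identical(compute_psize(100, 100), 100L)
  expect_identical(compute_psize(460.2, 100), 461L)
  expect_error(compute_psize(-1, 5), "positive")
  # symmetric and equal to a brute-force max
  set.seed(11)
  for (k in 1:200) {
    a <- runif(1, 1, 500); b <- runif(1, 1, 500)
    expect_identical(compute_psize(a, b), compute_psize(b, a))
    expect_identical(compute_psize(a, b), as.integer(ceiling(max(a, b))))
  }
})

test_that("dataset-level size covers the requested quantile", {
  mk <- function(p_sizes) record_set(lapply(seq_along(p_sizes), function(k)
    hand_record(paste0("s", k), x1 = p_sizes[k], x2 = 0,
                y1 = p_sizes[k] - 5, y2 = -5, label_m = 0, label_p = 0,
                image_path = "x.png")))
  st <- dataset_psize_stats(mk(c(430, 440, 455)))
  expect_identical(st$chosen_global_size, 455L)
  expect_true(all(st$p_sizes <= st$chosen_global_size))
  expect_identical(dataset_psize_stats(mk(437))$chosen_global_size, 437L)
  expect_error(dataset_psize_stats(record_set(list())), "empty")

  # cohort mimicking the clinical landmark statistics, capped at 460
  set.seed(97)
  dx <- rnorm(500, 423, 16.26); dy <- rnorm(500, 439, 27.15)
  ps <- pmax(dx, dy)
  expect_gt(max(ps), 460)   # the cap is what limits the choice
  st <- dataset_psize_stats(mk(ps), hard_limit = 460)
  expect_identical(st$chosen_global_size, 460L)
})

test_that("patch cropping zero-pads against a brute-force oracle", {
  set.seed(4)
  img <- array(runif(10 * 10 * 3), c(10, 10, 3))
  lm <- list(x1 = 4, x2 = 2, y1 = 5, y2 = 2)   # palm near top-left corner
  size <- 8
  patch <- extract_patch(img, lm, size)
  off <- attr(patch, "offset")
  # oracle: loop every patch pixel
  ref <- array(0, c(size, size, 3))
  for (i in seq_len(size)) for (j in seq_len(size)) {
    r <- i + off["row"]; c <- j + off["col"]
    if (r >= 1 && r <= 10 && c >= 1 && c <= 10) ref[i, j, ] <- img[r, c, ]
  }
  expect_equal(patch, ref, ignore_attr = TRUE)
  expect_true(any(patch == 0))               # padding happened
  # the landmark-box center maps to the patch center
  expect_equal((lm$y1 + lm$y2) / 2 - off[["row"]], (size + 1) / 2,
               tolerance = 0.51)
})

test_that("a size-1 patch picks the rounded center pixel", {
  img <- array(seq_len(49) / 49, c(7, 7, 1))
  dim(img) <- c(7, 7)
  p <- extract_patch(img, list(x1 = 5, x2 = 3, y1 = 6, y2 = 4), 1)
  expect_equal(p[1, 1], img[5, 4])
})

test_that("cropping is translation-equivariant away from borders", {
  set.seed(8)
  base <- array(runif(30 * 30 * 3), c(30, 30, 3))
  shifted <- array(0, c(30, 30, 3))
  shifted[4:30, 6:30, ] <- base[1:27, 1:25, ]
  lm <- list(x1 = 14, x2 = 6, y1 = 15, y2 = 5)
  lm2 <- list(x1 = 14 + 5, x2 = 6 + 5, y1 = 15 + 3, y2 = 5 + 3)
  p1 <- extract_patch(base, lm, 9)
  p2 <- extract_patch(shifted, lm2, 9)
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("landmarks fall inside the patch extent when size covers them", {
  set.seed(21)
  for (k in 1:50) {
    x2 <- runif(1, 10, 30); dx <- runif(1, 5, 25)
    y2 <- runif(1, 10, 30); dy <- runif(1, 5, 25)
    lm <- list(x1 = x2 + dx, x2 = x2, y1 = y2 + dy, y2 = y2)
    size <- compute_psize(dx, dy)
    # at size = p_size, containment up to the half-pixel grid rounding
    cb <- patch_spec(lm$x1, lm$x2, lm$y1, lm$y2, size = size)$crop_box
    expect_gte(lm$y2, cb[["row_min"]] - 1)
    expect_lte(lm$y1, cb[["row_max"]])
    expect_gte(lm$x2, cb[["col_min"]] - 1)
    expect_lte(lm$x1, cb[["col_max"]])
    # one extra pixel absorbs the rounding: exact containment in the
    # patch extent [row_min - 0.5, row_max - 0.5]
    cb <- patch_spec(lm$x1, lm$x2, lm$y1, lm$y2, size = size + 1)$crop_box
    expect_gte(lm$y2, cb[["row_min"]] - 0.5)
    expect_lte(lm$y1, cb[["row_max"]] - 0.5)
    expect_gte(lm$x2, cb[["col_min"]] - 0.5)
    expect_lte(lm$x1, cb[["col_max"]] - 0.5)
  }
})

test_that("landmarks outside the image are an error", {
  img <- array(0, c(10, 10, 3))
  expect_error(extract_patch(img, list(x1 = 30, x2 = 20, y1 = 8, y2 = 2), 5),
               "outside")
})

test_that("per-record p_size never exceeds the full-coverage choice", {
  rs <- generate_dataset(tiny_generator(n = 12, seed = 3))
  st <- dataset_psize_stats(rs, coverage = 1)
  expect_true(all(st$p_sizes <= st$chosen_global_size))
})

test_that("bilinear resize preserves identity and constants", {
  set.seed(2)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_equal(resize_image(img, 12), img)
  flat <- array(0.37, c(9, 9, 3))
  expect_equal(resize_image(flat, 5), array(0.37, c(5, 5, 3)))
})
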