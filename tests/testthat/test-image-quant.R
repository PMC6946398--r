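test_that("stack generation honours ground-truth labelling and seeds", {
  cfg0 <- image_config(n_nuclei = 40, labeled_fraction = 0,
                       dim_vox = c(80, 60, 16))
  st0 <- generate_stack(cfg0, seed = 1)
  expect_false(any(st0$truth$labeled))

  cfg_ex <- image_config(n_nuclei = 40, labeled_fraction = 0.5,
                         exact_count = TRUE, dim_vox = c(80, 60, 16))
  st_ex <- generate_stack(cfg_ex, seed = 2)
  expect_equal(sum(st_ex$truth$labeled), 20L)

  cfg <- image_config(n_nuclei = 30, dim_vox = c(80, 60, 16))
  a <- generate_stack(cfg, seed = 5)
  b <- generate_stack(cfg, seed = 5)
  expect_identical(a$nuclear, b$nuclear)
  expect_identical(a$label, b$label)

  # minimum spacing is respected
  d <- dist(as.matrix(a$truth[, c("x_um", "y_um", "z_um")]))
  expect_gte(min(d), cfg$min_spacing_um)

  # infeasible packing errors out
  tiny <- image_config(n_nuclei = 500, dim_vox = c(40, 30, 8),
                       max_retries = 2000)
  expect_error(generate_stack(tiny, seed = 1), "retry budget")
})

test_that("segmentation recovers the default synthetic stack", {
  cfg <- image_config()
  st <- generate_stack(cfg, seed = 7)
  surf <- segment_nuclei(st)
  expect_lt(abs(nrow(surf) - nrow(st$truth)) / nrow(st$truth), 0.05)
  m <- match_nuclei(surf, st$truth, gate_um = 1)
  expect_gte(m$f1, 0.95)
  # voxel sets are disjoint
  vox <- unlist(surf$voxels)
  expect_equal(anyDuplicated(vox), 0L)
})

test_that("ground-truth fractions are recovered across labelling levels", {
  for (lf in c(0.1, 0.75)) {
    cfg <- image_config(labeled_fraction = lf, exact_count = TRUE)
    st <- generate_stack(cfg, seed = round(100 * lf))
    surf <- segment_nuclei(st)
    fit <- fit_label_threshold(surf$mean_label)
    fr <- quantify_clone_fraction(surf, fit$threshold)
    expect_lte(abs(fr$labeled_fraction - lf), 0.02)
  }
})

test_that("blank images yield zero surfaces with a warning", {
  set.seed(3)
  blank <- structure(list(
    nuclear = array(pmax(rnorm(60 * 40 * 12, 10, 5), 0), c(60, 40, 12)),
    label = array(10, c(60, 40, 12)),
    voxel_size_um = c(0.2, 0.2, 0.5), truth = NULL),
    class = "image_stack")
  expect_warning(s0 <- segment_nuclei(blank), "blank")
  expect_equal(nrow(s0), 0L)
})

test_that("touching nuclei at 1.2x diameter spacing are split", {
  st <- two_blob_stack(spacing_um = 1.2 * 2.1)
  surf <- segment_nuclei(st, diameter_um = 2.1)
  expect_equal(nrow(surf), 2L)
  m <- match_nuclei(surf, st$truth, gate_um = 1)
  expect_equal(m$n_matched, 2L)
})

test_that("segmentation quality does not improve with more noise", {
  cfg_lo <- image_config(n_nuclei = 120, noise_sd = 5)
  cfg_hi <- image_config(n_nuclei = 120, noise_sd = 10)
  f1 <- function(cfg) {
    st <- generate_stack(cfg, seed = 17)
    match_nuclei(segment_nuclei(st), st$truth, gate_um = 1)$f1
  }
  expect_gte(f1(cfg_lo), f1(cfg_hi))
})

test_that("label thresholding separates bimodal intensities", {
  fit <- fit_label_threshold(c(1, 1, 1, 10, 10, 10))
  expect_gt(fit$threshold, 1)
  expect_lt(fit$threshold, 10)
  expect_false(fit$unimodal)
  expect_equal(as.integer(table(fit$class)), c(3L, 3L))

  same <- fit_label_threshold(rep(4, 10))
  expect_true(same$unimodal)
  expect_true(all(is.na(same$class)))

  expect_error(fit_label_threshold(5), "at least 2")
})

test_that("threshold classification agrees with ground truth", {
  cfg <- image_config(n_nuclei = 150)
  st <- generate_stack(cfg, seed = 23)
  surf <- segment_nuclei(st)
  fit <- fit_label_threshold(surf$mean_label)
  m <- match_nuclei(surf, st$truth, gate_um = 1)
  agree <- mean((surf$mean_label[m$matches$nucleus] < fit$threshold) ==
                  st$truth$labeled[m$matches$truth])
  expect_gte(agree, 0.98)
})

test_that("clone fractions count below/above threshold in the region", {
  surf <- tibble::tibble(
    nucleus = 1:20, x_um = seq(1, 20), y_um = 5, z_um = 5,
    n_voxels = 50L, volume_um3 = 1,
    mean_nuclear = 50, mean_label = rep(c(5, 100), 10),
    voxels = replicate(20, integer(), simplify = FALSE))
  fr <- quantify_clone_fraction(surf, threshold = 30)
  expect_equal(fr$labeled_fraction, 0.5)
  expect_equal(fr$n_negative, 10L)
  # positive marking counts the other side
  fp <- quantify_clone_fraction(surf, 30, positive_marking = TRUE)
  expect_equal(fp$labeled_fraction, 0.5)
  # raising the threshold never decreases the negative count
  n_neg <- vapply(c(2, 30, 150),
                  function(t) quantify_clone_fraction(surf, t)$n_negative, 0L)
  expect_true(all(diff(n_neg) >= 0))

  expect_error(quantify_clone_fraction(surf, 30, c(100, 200)),
               "no surfaces")
})

test_that("stacks round-trip through multi-page TIFF", {
  cfg <- image_config(n_nuclei = 10, dim_vox = c(60, 40, 12))
  st <- generate_stack(cfg, seed = 2)
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$nuclear, st$nuclear, tolerance = 1e-4)
  expect_equal(back$label, st$label, tolerance = 1e-4)
  expect_equal(back$truth$x_um, st$truth$x_um, tolerance = 1e-9)
  unlink(c(path, paste0(path, ".json")))
})
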