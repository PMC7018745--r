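test_that("cluster detection recovers planted puncta and their intensities", {
  gen <- gen_puncta_image(n_puncta = 50, seed = 3)
  det <- detect_clusters(gen$image, psf_fwhm = 0.25)
  expect_equal(det$n, 50)
  # planted-footprint quantification recovers the amplitude within 10%
  tm <- truth_cluster_mask(gen$truth)
  rec <- intensity_in_mask(gen$image, tm)
  rel <- (rec$per_object$mean_intensity - gen$truth$background) /
    gen$truth$amplitudes - 1
  expect_true(all(abs(rel) < 0.10))
  # constant image: no clusters
  flat <- image_plane(matrix(500, 128, 128), pixel_size = 0.1)
  expect_equal(detect_clusters(flat, psf_fwhm = 0.25)$n, 0)
  expect_error(detect_clusters(flat, psf_fwhm = 0.05), "at least 2 pixels")
  # density arithmetic: objects per 100 um^2
  expect_close(det$density_per_100um2,
               100 * 50 / (256 * 256 * 0.1^2), 1e-9)
})

test_that("detection is translation invariant and background independent", {
  # plant on a jittered grid away from the frame edge so a cyclic shift
  # never cuts an object at the seam
  set.seed(90)
  grid_pts <- as.matrix(expand.grid(seq(30, 212, by = 26),
                                    seq(30, 212, by = 26)))[1:50, ]
  grid_pts <- grid_pts + matrix(runif(100, -4, 4), ncol = 2)
  gen <- gen_puncta_image(positions = grid_pts, seed = 9)
  det0 <- detect_clusters(gen$image, psf_fwhm = 0.25)
  # whole-pixel shift (cyclic, so no content is lost) shifts detections
  # identically
  sh <- 7
  shifted <- rbind(gen$image$data[(256 - sh + 1):256, ],
                   gen$image$data[1:(256 - sh), ])
  det1 <- detect_clusters(image_plane(shifted, 0.1), psf_fwhm = 0.25)
  expect_equal(det1$n, det0$n)
  rows_expected <- sort(round(((det0$objects$row + sh - 1) %% 256) + 1))
  expect_equal(sort(round(det1$objects$row)), rows_expected)
  # a smooth low-frequency gradient (~20% of punctum peak) changes the
  # count by under 2%
  grad <- outer(seq(0, 1, length.out = 256), seq(0, 1, length.out = 256),
                function(a, b) 160 * (a + b) / 2)
  det2 <- detect_clusters(image_plane(pmin(gen$image$data + grad, 4095), 0.1),
                          psf_fwhm = 0.25)
  expect_lt(abs(det2$n - det0$n) / det0$n, 0.02)
})

test_that("doubling punctum density doubles detected density", {
  g1 <- gen_puncta_image(n_puncta = 30, seed = 15)
  g2 <- gen_puncta_image(n_puncta = 60, seed = 16)
  d1 <- detect_clusters(g1$image, psf_fwhm = 0.25)
  d2 <- detect_clusters(g2$image, psf_fwhm = 0.25)
  expect_lt(abs(d2$density_per_100um2 / d1$density_per_100um2 - 2), 0.05 * 2)
})

test_that("mask intensity statistics behave on whole-frame and disjoint masks", {
  gen <- gen_puncta_image(n_puncta = 10, seed = 4)
  det <- detect_clusters(gen$image, psf_fwhm = 0.25)
  # whole-frame mask: overall mean equals the image mean
  full <- det
  full$mask <- matrix(TRUE, 256, 256)
  full$labels <- matrix(1L, 256, 256)
  full$n <- 1L
  expect_close(intensity_in_mask(gen$image, full)$overall_mean,
               mean(gen$image$data), 1e-9)
  # disjoint masks overlap 0%; identical masks overlap 100%
  other <- det
  other$mask <- !det$mask
  expect_equal(intensity_in_mask(gen$image, det, other)$overlap_pct, 0)
  expect_equal(intensity_in_mask(gen$image, det, det)$overlap_pct, 100)
  wrong <- image_plane(matrix(1, 10, 10), 0.1)
  expect_error(intensity_in_mask(wrong, det), "mismatch")
})

test_that("membrane profile finds the planted diameter and averages idempotently", {
  cells <- data.frame(row = c(80, 180), col = c(80, 180),
                      radius_px = c(25, 25))
  g <- gen_membrane_image(cells, seed = 5)
  segs <- list(list(from = c(80, 40), to = c(80, 120)),
               list(from = c(180, 140), to = c(180, 220)))
  mp <- membrane_profile(g$image, segs)
  # peak separation = planted diameter within one pixel
  planted_um <- 2 * 25 * g$image$pixel_size
  expect_true(all(abs(mp$peak_separation_um - planted_um) <=
                  g$image$pixel_size + 1e-9))
  # averaging two identical cells reproduces the single-cell profile shape
  expect_equal(length(mp$profiles), 2)
  # flat image: all segments rejected
  flat <- image_plane(matrix(200, 256, 256), 0.2)
  expect_error(membrane_profile(flat, segs), "no segment")
})

test_that("membrane index isolates the planted contrast and ignores offsets", {
  cells <- data.frame(row = 80, col = 80, radius_px = 25)
  g <- gen_membrane_image(cells, ring_px = 5, seed = 5)
  ring <- gabakcc2:::disc_indices(c(256, 256), c(80, 80), 26) &
    !gabakcc2:::disc_indices(c(256, 256), c(80, 80), 24)
  intra <- gabakcc2:::disc_indices(c(256, 256), c(80, 80), 15)
  bg <- matrix(FALSE, 256, 256); bg[1:25, 1:25] <- TRUE
  idx <- membrane_index(g$image, ring, intra, bg)
  planted <- g$truth$membrane_level - g$truth$intracellular_level
  expect_lt(abs(idx - planted) / planted, 0.15)
  # equal membrane and intracellular levels: index near zero
  g0 <- gen_membrane_image(cells, membrane_level = 400,
                           intracellular_level = 400, ring_px = 5, seed = 6)
  expect_lt(abs(membrane_index(g0$image, ring, intra, bg)), 15)
  # adding a constant to the whole image leaves the index unchanged
  shifted <- image_plane(pmin(g$image$data + 200, 4095), 0.2)
  # (clip cannot bite: max is well under 12-bit range here)
  expect_close(membrane_index(shifted, ring, intra, bg), idx, 1e-9)
  expect_error(membrane_index(g$image, matrix(FALSE, 256, 256), intra, bg),
               "non-empty")
})

test_that("relative difference map reproduces planted ratios", {
  a <- image_plane(matrix(200, 64, 64) + outer(1:64, 1:64, "+") / 10, 1)
  same <- relative_difference_map(a, a, gaussian_sigma_um = 5)
  expect_lt(max(abs(same$delta), na.rm = TRUE), 1e-9)
  half <- image_plane(a$data * 0.5, 1)
  dm <- relative_difference_map(a, half, gaussian_sigma_um = 5)
  expect_true(all(abs(dm$delta + 0.5) < 1e-9, na.rm = TRUE))
  # sigma 0 reduces to the raw pixelwise relative difference
  raw <- relative_difference_map(a, half, gaussian_sigma_um = 0)
  expect_equal(raw$delta, (half$data - a$data) / a$data, tolerance = 1e-12)
  # near-zero reference pixels are masked, not divided
  z <- a; z$data[1, 1] <- 0
  masked <- relative_difference_map(z, half, gaussian_sigma_um = 0)
  expect_true(is.na(masked$delta[1, 1]))
})

test_that("soma detection applies the area and eccentricity rules exactly", {
  mk_ellipse_img <- function(semi_major, ecc) {
    img <- matrix(100, 256, 256)
    b <- semi_major * sqrt(1 - ecc^2)
    sel <- gabakcc2:::ellipse_indices(c(256, 256), c(128, 128), semi_major, b)
    img[sel] <- 900
    image_plane(img, 0.2)
  }
  # area just above 500 px with modest eccentricity: detected
  big <- mk_ellipse_img(16, 0.5)          # pi*16*13.9 ~ 698 px
  expect_equal(detect_somata(big)$n, 1)
  # same shape scaled below 500 px: rejected
  small <- mk_ellipse_img(12, 0.5)        # pi*12*10.4 ~ 392 px
  expect_equal(detect_somata(small)$n, 0)
  # elongated beyond eccentricity 0.98: rejected
  thin <- mk_ellipse_img(60, 0.995)
  expect_equal(detect_somata(thin)$n, 0)
  # empty image allowed
  flat <- image_plane(matrix(100, 256, 256), 0.2)
  expect_equal(detect_somata(flat)$n, 0)
  expect_error(detect_somata(big, soma_detection_params(kernel_px = 500)),
               "fit")
})

test_that("transcript counting matches planted dot ground truth", {
  som <- data.frame(row = c(60, 180), col = c(70, 170),
                    semi_major_px = c(18, 20), eccentricity = c(0.5, 0.3),
                    angle = c(0, 1), intensity = c(900, 800))
  g <- gen_rnascope_image(som, dots_per_cell = list(
    gabra2 = c(5, 2), slc32a1 = c(1, 0), slc17a6 = c(0, 3)), seed = 4)
  det_som <- detect_somata(g$soma_image)
  expect_equal(det_som$n, 2)
  dots <- lapply(g$dot_images, function(di)
    detect_clusters(di, psf_fwhm = 0.6)$objects[, c("row", "col")])
  ct <- count_transcripts_per_cell(dots, det_som)
  # order somata by planted position
  ord <- order(ct$counts$cell_id)
  byrow <- ct$counts[order(det_som$somata$row), ]
  expect_equal(byrow$gabra2, c(5, 2))
  expect_equal(byrow$type, c("inhibitory", "excitatory"))
  expect_true(all(ct$extracellular == 0))
  # a soma with no marker dots stays unclassified
  g2 <- gen_rnascope_image(som[1, ], dots_per_cell = list(gabra2 = 2),
                           seed = 5)
  s2 <- detect_somata(g2$soma_image)
  ct2 <- count_transcripts_per_cell(
    list(gabra2 = detect_clusters(g2$dot_images$gabra2,
                                  psf_fwhm = 0.6)$objects[, c("row", "col")]),
    s2)
  expect_equal(ct2$counts$type, "unclassified")
})

test_that("scalar helpers compute their closed forms", {
  expect_equal(subunit_total_count(10, 4), 18)
  expect_equal(subunit_total_count(0, 0), 0)
  expect_equal(subunit_total_count(2 * 3, 2 * 5), 2 * subunit_total_count(3, 5))
  expect_error(subunit_total_count(-1, 0), ">= 0")
  expect_equal(deconvolve_bead_fwhm(500, 300), 400)
  expect_equal(deconvolve_bead_fwhm(250, 0), 250)
  expect_equal(deconvolve_bead_fwhm(300, 300), 0)
  expect_error(deconvolve_bead_fwhm(200, 300), "below")
})
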