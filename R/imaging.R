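#' A 2-D fluorescence image plane with physical pixel size
#'
#' Thin wrapper holding a numeric intensity matrix together with its
#' pixel size (micrometres) and bit depth. Matrices are indexed
#' `[row, col]`; positions are in pixel units unless stated otherwise.
#'
#' @param data numeric matrix of non-negative intensities.
#' @param pixel_size pixel edge length, um.
#' @param bit_depth acquisition bit depth (12 by default, matching
#'   confocal acquisitions).
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(data, pixel_size, bit_depth = 12) {
  data <- as.matrix(data)
  if (any(data < 0) || any(data > 2^bit_depth - 1))
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(data = data, pixel_size = pixel_size, bit_depth = bit_depth),
            class = "image_plane")
}

# Zero-mean disc matched filter sized to the PSF: a positive disc of the
# given radius inside a window twice its diameter, normalized so the disc
# weights sum to 1 and the whole kernel to 0 (the surround is uniformly
# negative). Low-frequency background therefore cancels exactly.
disc_kernel <- function(radius_px) {
  r <- max(1L, round(radius_px))
  win <- 4L * r + 1L
  disc <- matrix(0, win, win)
  ctr <- (win + 1) / 2
  disc[(row(disc) - ctr)^2 + (col(disc) - ctr)^2 <= r^2] <- 1
  inside <- disc == 1
  k <- matrix(0, win, win)
  k[inside] <- 1 / sum(inside)
  k[!inside] <- -1 / sum(!inside)
  k
}

#' Detect PSF-scale puncta with a disc matched filter
#'
#' Realizes object-based punctum ("cluster") segmentation: the image is
#' convolved with a zero-mean disc kernel whose diameter equals the PSF
#' FWHM, so that structures at the PSF scale are amplified while diffuse
#' low-frequency background cancels out; the filtered image is then
#' thresholded at a robust z-score (median + `z_thresh` * MAD of the
#' filtered values) and connected components are labelled. The result is
#' therefore independent of slowly varying background and of any global
#' raw-intensity threshold.
#'
#' @param image an [image_plane()].
#' @param psf_fwhm PSF full width at half maximum, um; must span at least
#'   2 pixels.
#' @param z_thresh robust z-score threshold on the filtered image.
#' @param min_area_px discard components smaller than this, px.
#' @return list of class `cluster_mask` with `mask` (binary matrix),
#'   `labels` (integer matrix), `objects` (data.frame: `id`, `row`,
#'   `col` centroid, `area_px`, `area_um2`, `mean_intensity`,
#'   `on_border`), `n`, and `density_per_100um2`.
#' @export
detect_clusters <- function(image, psf_fwhm, z_thresh = 4,
                            min_area_px = 2) {
  stopifnot(inherits(image, "image_plane"))
  fwhm_px <- psf_fwhm / image$pixel_size
  if (fwhm_px < 2) stop("PSF FWHM must be at least 2 pixels")
  img <- image$data
  filt <- as.matrix(EBImage::filter2(EBImage::Image(img), disc_kernel(fwhm_px / 2),
                                     boundary = "replicate"))
  med <- stats::median(filt)
  madv <- stats::mad(filt)
  if (madv < .Machine$double.eps) madv <- stats::sd(filt)
  mask <- filt > med + z_thresh * madv
  if (madv < .Machine$double.eps) mask[] <- FALSE   # constant image
  labels <- label_components(mask)
  objects <- summarize_labels(labels, img, image$pixel_size)
  keep <- objects$area_px >= min_area_px
  labels <- relabel(labels, objects$id[keep])
  objects <- summarize_labels(labels, img, image$pixel_size)
  area_um2 <- prod(dim(img)) * image$pixel_size^2
  structure(list(mask = labels > 0, labels = labels, objects = objects,
                 n = nrow(objects),
                 density_per_100um2 = 100 * nrow(objects) / area_um2),
            class = "cluster_mask")
}

# component connectivity is fixed at 8-connected throughout
label_components <- function(mask) {
  as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
}

relabel <- function(labels, keep_ids) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep_ids)) out[labels == keep_ids[i]] <- i
  out
}

summarize_labels <- function(labels, img, pixel_size) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      area_px = integer(), area_um2 = numeric(),
                      mean_intensity = numeric(), on_border = logical()))
  rows <- row(labels); cols <- col(labels)
  out <- lapply(ids, function(i) {
    sel <- labels == i
    data.frame(id = i,
               row = mean(rows[sel]), col = mean(cols[sel]),
               area_px = sum(sel),
               area_um2 = sum(sel) * pixel_size^2,
               mean_intensity = mean(img[sel]),
               on_border = any(rows[sel] %in% c(1, nrow(labels))) ||
                 any(cols[sel] %in% c(1, ncol(labels))))
  })
  do.call(rbind, out)
}

#' Channel intensity inside a binary mask
#'
#' Pixelwise product statistics of a channel with a cluster mask (e.g. a
#' receptor-subunit channel inside the gephyrin mask): overall mean of
#' the channel over mask pixels, per-object means, and optionally the
#' overlap fraction of a second mask with the first.
#'
#' @param channel an [image_plane()] (same shape as the mask).
#' @param mask a `cluster_mask` from [detect_clusters()].
#' @param second_mask optional second `cluster_mask`; its overlap with
#'   `mask` is reported as `100 * |A and B| / |A|`.
#' @return list with `overall_mean`, `per_object` (data.frame `id`,
#'   `mean_intensity`), `overlap_pct` (or `NA`).
#' @export
intensity_in_mask <- function(channel, mask, second_mask = NULL) {
  stopifnot(inherits(channel, "image_plane"), inherits(mask, "cluster_mask"))
  if (!all(dim(channel$data) == dim(mask$mask))) stop("shape mismatch")
  img <- channel$data
  per <- vapply(seq_len(mask$n),
                function(i) mean(img[mask$labels == i]), numeric(1))
  overlap <- NA_real_
  if (!is.null(second_mask)) {
    if (!all(dim(second_mask$mask) == dim(mask$mask))) stop("shape mismatch")
    denom <- sum(mask$mask)
    overlap <- if (denom == 0) 0 else
      100 * sum(mask$mask & second_mask$mask) / denom
  }
  list(overall_mean = if (any(mask$mask)) mean(img[mask$mask]) else NA_real_,
       per_object = data.frame(id = seq_len(mask$n), mean_intensity = per),
       overlap_pct = overlap)
}

#' Intensity profile across cell membranes
#'
#' For each user-supplied crossing segment (3-pixel-thick line across a
#' cell), extracts the averaged intensity profile, locates the two
#' membrane maxima, and aligns the profiles on the first membrane peak
#' before averaging. Segments without two clear maxima are rejected.
#'
#' @param image an [image_plane()].
#' @param segments list of segments, each `list(from = c(row, col),
#'   to = c(row, col))` in pixel coordinates.
#' @param thickness averaging thickness across the segment, px.
#' @param min_prominence minimum peak height over the profile median, as
#'   a fraction of the profile range, for a maximum to count as membrane.
#' @return list of class `membrane_profile` with `profiles` (list of
#'   per-segment data.frames `distance_um`, `intensity`),
#'   `peak_separation_um` per segment, and `average` (aligned mean
#'   profile).
#' @export
membrane_profile <- function(image, segments, thickness = 3,
                             min_prominence = 0.2) {
  stopifnot(inherits(image, "image_plane"))
  img <- image$data
  res <- list(); seps <- numeric(0)
  for (seg in segments) {
    p0 <- seg$from; p1 <- seg$to
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2))))
    tt <- seq(0, 1, length.out = n + 1)
    dir <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    nrm <- c(-dir[2], dir[1])
    offs <- seq(-(thickness - 1) / 2, (thickness - 1) / 2)
    prof <- vapply(tt, function(a) {
      pts <- lapply(offs, function(o) p0 + a * (p1 - p0) + o * nrm)
      mean(vapply(pts, function(p) {
        r <- round(p[1]); c0 <- round(p[2])
        if (r < 1 || c0 < 1 || r > nrow(img) || c0 > ncol(img)) NA_real_
        else img[r, c0]
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    pk <- find_two_peaks(prof, min_prominence)
    if (is.null(pk)) next
    d_um <- tt * sqrt(sum((p1 - p0)^2)) * image$pixel_size
    res[[length(res) + 1]] <- data.frame(
      distance_um = d_um - d_um[pk[1]], intensity = prof)
    seps <- c(seps, d_um[pk[2]] - d_um[pk[1]])
  }
  if (length(res) == 0) stop("no segment showed two membrane maxima")
  # average on a common grid centered on the first peak
  grid <- seq(min(vapply(res, function(p) min(p$distance_um), numeric(1))),
              max(vapply(res, function(p) max(p$distance_um), numeric(1))),
              by = image$pixel_size)
  avg <- rowMeans(vapply(res, function(p)
    stats::approx(p$distance_um, p$intensity, xout = grid, rule = 2)$y,
    numeric(length(grid))))
  structure(list(profiles = res, peak_separation_um = seps,
                 average = data.frame(distance_um = grid, intensity = avg)),
            class = "membrane_profile")
}

find_two_peaks <- function(prof, min_prominence) {
  n <- length(prof)
  if (n < 5) return(NULL)
  rng <- diff(range(prof))
  if (rng < .Machine$double.eps) return(NULL)
  is_pk <- which(diff(sign(diff(prof))) == -2) + 1
  is_pk <- is_pk[prof[is_pk] - stats::median(prof) > min_prominence * rng]
  if (length(is_pk) < 2) return(NULL)
  # the two most prominent maxima, in spatial order
  top2 <- is_pk[order(prof[is_pk], decreasing = TRUE)[1:2]]
  sort(top2)
}

#' Membrane fluorescence index
#'
#' Global membrane-expression index for dense tissue where single cells
#' cannot be delineated: after subtracting the non-specific background
#' (estimated in a signal-free region), the mean intensity of identified
#' intracellular regions is subtracted from the mean intensity of the
#' analysis region. Because intracellular signal bleeds into any membrane
#' measurement at optical resolution, this difference isolates the
#' membrane-associated component. Adding a constant to the whole image
#' leaves the index unchanged.
#'
#' @param image an [image_plane()].
#' @param roi logical matrix: the large analysis region.
#' @param intracellular logical matrix: unambiguous intracellular regions.
#' @param background logical matrix: signal-free region for background
#'   estimation.
#' @return Index in intensity units.
#' @export
membrane_index <- function(image, roi, intracellular, background) {
  stopifnot(inherits(image, "image_plane"))
  for (m in list(roi, intracellular, background))
    if (!any(m)) stop("all regions must be non-empty")
  img <- image$data - mean(image$data[background])
  mean(img[roi]) - mean(img[intracellular])
}

#' Smoothed relative difference map between two mean images
#'
#' Both images are Gaussian-smoothed (default 20 um standard deviation,
#' removing high-frequency fluctuation), then the pixelwise relative
#' difference `(B - A) / A` is computed inside the region mask. Pixels
#' where the reference falls below `noise_floor` are masked out rather
#' than divided.
#'
#' @param img_a,img_b [image_plane()] objects (reference A, comparison B),
#'   co-registered.
#' @param gaussian_sigma_um smoothing SD, um (0 = no smoothing).
#' @param region logical matrix restricting the analysis.
#' @param noise_floor reference intensities at or below this are masked.
#' @param breaks histogram breaks for the summary.
#' @return list with `delta` (matrix, NA outside the valid region) and
#'   `histogram` (a [graphics::hist()] object computed without plotting).
#' @export
relative_difference_map <- function(img_a, img_b, gaussian_sigma_um = 20,
                                    region = NULL, noise_floor = 1e-6,
                                    breaks = 50) {
  stopifnot(inherits(img_a, "image_plane"), inherits(img_b, "image_plane"))
  if (!all(dim(img_a$data) == dim(img_b$data))) stop("shape mismatch")
  sm <- function(m) {
    if (gaussian_sigma_um <= 0) return(m)
    as.matrix(EBImage::gblur(EBImage::Image(m),
                             sigma = gaussian_sigma_um / img_a$pixel_size))
  }
  a <- sm(img_a$data); b <- sm(img_b$data)
  if (is.null(region)) region <- matrix(TRUE, nrow(a), ncol(a))
  valid <- region & a > noise_floor
  delta <- matrix(NA_real_, nrow(a), ncol(a))
  delta[valid] <- (b[valid] - a[valid]) / a[valid]
  h <- graphics::hist(delta[valid], breaks = breaks, plot = FALSE)
  list(delta = delta, histogram = h)
}

#' Parameters for adaptive soma detection
#'
#' @param kernel_px side of the local-average box kernel, px.
#' @param k threshold multiplier in SD units over the offset-image mean
#'   (stated working range 0.5-1; default the midpoint 0.75).
#' @param min_area_px minimum soma area, px (strictly more than this).
#' @param max_eccentricity maximum allowed ellipse eccentricity.
#' @return list of class `soma_detection_params`.
#' @export
soma_detection_params <- function(kernel_px = 50, k = 0.75,
                                  min_area_px = 500, max_eccentricity = 0.98) {
  if (k <= 0 || k > 2) stop("k must be in (0, 2]")
  if (min_area_px <= 0) stop("min_area_px must be > 0")
  if (max_eccentricity <= 0 || max_eccentricity >= 1)
    stop("max_eccentricity must be in (0, 1)")
  structure(list(kernel_px = kernel_px, k = k, min_area_px = min_area_px,
                 max_eccentricity = max_eccentricity),
            class = "soma_detection_params")
}

#' Adaptive-threshold detection of neuronal somata
#'
#' A local-average image (box kernel, sum 1) is computed and subtracted
#' from the original so that bright cell bodies stand out as positive
#' offsets (the subtraction is oriented original-minus-local-average so
#' somata are bright-positive). Candidate pixels exceed the offset-image
#' mean plus `k` standard deviations; connected components are filled
#' (holes closed) and kept when their area exceeds `min_area_px` and
#' their ellipse eccentricity is at most `max_eccentricity`.
#'
#' @param image an [image_plane()] (Nissl-type soma channel).
#' @param params a [soma_detection_params()].
#' @return list of class `soma_labels` with `labels` (integer matrix),
#'   `somata` (data.frame: `id`, centroid `row`/`col`, `area_px`,
#'   `eccentricity`), and `n`.
#' @export
detect_somata <- function(image, params = soma_detection_params()) {
  stopifnot(inherits(image, "image_plane"))
  img <- image$data
  if (params$kernel_px > min(dim(img))) stop("kernel does not fit in image")
  ksz <- params$kernel_px + (1 - params$kernel_px %% 2)  # odd-padded
  box <- matrix(1 / ksz^2, ksz, ksz)
  local_avg <- as.matrix(EBImage::filter2(EBImage::Image(img), box,
                                          boundary = "replicate"))
  offset <- img - local_avg
  thr <- mean(offset) + params$k * stats::sd(offset)
  cand <- offset > thr
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(cand * 1))) > 0
  labels <- as.matrix(EBImage::bwlabel(EBImage::Image(filled * 1)))
  feats <- EBImage::computeFeatures.moment(labels)
  if (is.null(feats) || nrow(as.matrix(feats)) == 0) {
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          somata = data.frame(), n = 0L),
                     class = "soma_labels"))
  }
  feats <- as.data.frame(feats)
  areas <- tabulate(labels[labels > 0])
  ecc <- feats$m.eccentricity
  keep <- which(areas > params$min_area_px & ecc <= params$max_eccentricity)
  labels_out <- relabel(labels, keep)
  somata <- data.frame(id = seq_along(keep),
                       row = feats$m.cy[keep], col = feats$m.cx[keep],
                       area_px = areas[keep],
                       eccentricity = ecc[keep])
  structure(list(labels = labels_out, somata = somata, n = length(keep)),
            class = "soma_labels")
}

#' Count transcript dots per detected soma and classify cell type
#'
#' Assigns detected fluorescent dots (e.g. RNAscope spots) to labelled
#' somata and counts them per cell and channel. A cell is labelled
#' `inhibitory` if it holds at least one dot of the inhibitory marker
#' channel, `excitatory` if at least one of the excitatory marker
#' channel (inhibitory takes precedence when both are present), else
#' `unclassified`. Dots falling outside all somata are tallied as
#' extracellular per channel.
#'
#' @param dots named list of data.frames, one per channel, each with
#'   pixel columns `row`, `col`. Channel names are free; see
#'   `inhibitory_marker` / `excitatory_marker`.
#' @param somata a `soma_labels` object from [detect_somata()].
#' @param inhibitory_marker,excitatory_marker names of the marker
#'   channels in `dots` used for typing (may be absent).
#' @return list with `counts` (data.frame: `cell_id`, one column per
#'   channel, `type`) and `extracellular` (named counts).
#' @export
count_transcripts_per_cell <- function(dots, somata,
                                       inhibitory_marker = "slc32a1",
                                       excitatory_marker = "slc17a6") {
  stopifnot(inherits(somata, "soma_labels"))
  labs <- somata$labels
  chan_counts <- lapply(dots, function(df) {
    ids <- vapply(seq_len(nrow(df)), function(i) {
      r <- round(df$row[i]); c0 <- round(df$col[i])
      if (r < 1 || c0 < 1 || r > nrow(labs) || c0 > ncol(labs)) 0L
      else labs[r, c0]
    }, integer(1))
    ids
  })
  n <- somata$n
  counts <- data.frame(cell_id = seq_len(n))
  extracellular <- integer(length(dots)); names(extracellular) <- names(dots)
  for (ch in names(dots)) {
    ids <- chan_counts[[ch]]
    counts[[ch]] <- tabulate(ids[ids > 0], nbins = n)
    extracellular[ch] <- sum(ids == 0)
  }
  inh <- if (inhibitory_marker %in% names(dots))
    counts[[inhibitory_marker]] > 0 else rep(FALSE, n)
  exc <- if (excitatory_marker %in% names(dots))
    counts[[excitatory_marker]] > 0 else rep(FALSE, n)
  counts$type <- ifelse(inh, "inhibitory",
                        ifelse(exc, "excitatory", "unclassified"))
  list(counts = counts, extracellular = extracellular)
}

#' Total subunit count from monomer and dimer counts
#'
#' Oligomer-state decomposition reports monomers and dimers; the total
#' number of subunits is one per monomer plus two per dimer.
#'
#' @param monomers,dimers non-negative counts.
#' @return Total subunit count.
#' @export
subunit_total_count <- function(monomers, dimers) {
  if (any(monomers < 0) || any(dimers < 0)) stop("counts must be >= 0")
  monomers + 2 * dimers
}

#' Deconvolve a bead diameter from a fitted FWHM
#'
#' Optical resolution estimated from sub-resolution beads:
#' \eqn{\omega = \sqrt{\omega_{fit}^2 - D_{bead}^2}}.
#'
#' @param fwhm_fit fitted FWHM of the bead profile, nm.
#' @param bead_diameter manufacturer bead diameter, nm.
#' @return Resolution, nm.
#' @export
deconvolve_bead_fwhm <- function(fwhm_fit, bead_diameter) {
  if (any(fwhm_fit < bead_diameter)) stop("fitted FWHM below bead diameter")
  sqrt(fwhm_fit^2 - bead_diameter^2)
}
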