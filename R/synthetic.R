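# Run code under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Ground truth for a synthetic behavioral dose-response experiment
#'
#' @param hill a [hill_params()] object (the true dose-response, % MPA).
#' @param collapse optional [collapse_params()] for a high-dose collapse.
#' @param wd50_prepni pre-injury baseline withdrawal threshold, g.
#' @param wd50_predrug post-injury pre-drug threshold, g (must be below
#'   the baseline).
#' @param n_animals animals per dose.
#' @param noise_sd per-measurement Gaussian noise on the MPA scale, %.
#' @param seed RNG seed.
#' @return An object of class `behavioral_truth`.
#' @export
behavioral_truth <- function(hill, collapse = NULL,
                             wd50_prepni = 26, wd50_predrug = 2,
                             n_animals = 8, noise_sd = 5, seed = 1) {
  stopifnot(inherits(hill, "hill_params"))
  if (!is.null(collapse)) stopifnot(inherits(collapse, "collapse_params"))
  if (!(wd50_predrug > 0 && wd50_predrug < wd50_prepni))
    stop("need 0 < wd50_predrug < wd50_prepni")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(hill = hill, collapse = collapse,
                 wd50_prepni = wd50_prepni, wd50_predrug = wd50_predrug,
                 n_animals = n_animals, noise_sd = noise_sd, seed = seed),
            class = "behavioral_truth")
}

#' Generate a synthetic behavioral withdrawal-threshold table
#'
#' Per-animal 50% withdrawal thresholds are generated so that the exact
#' MPA transform of the emitted columns reproduces the Hill (optionally
#' times collapse) model value plus additive Gaussian noise on the MPA
#' scale; thresholds are then clipped to `[0, prePNI]`. With
#' `noise_sd = 0` the round trip through [compute_mpa()] returns the
#' model curve to machine precision. Optionally thresholds can be
#' snapped to the 12 von Frey filament values (off by default, since
#' snapping breaks exact invertibility).
#'
#' @param truth a [behavioral_truth()].
#' @param doses dose vector, mg/kg (at least one).
#' @param timepoints measurement times, h: the hourly tests of the
#'   post-injection observation window (default 1-4 h). The model value
#'   is the same at every timepoint; each measurement gets independent
#'   noise, and downstream reductions (see [mpa_by_animal()]) collapse
#'   the window to one value per animal.
#' @param snap_filaments snap thresholds to the standard 0.04-60 g
#'   filament set.
#' @return list with `table` (data.frame: `animal_id`, `group`,
#'   `dose_mgkg`, `time_h`, `wd50_g`, `mpa`) and `truth` (the generating
#'   `behavioral_truth`, serving as the ground-truth bundle).
#' @export
gen_behavioral <- function(truth, doses, timepoints = 1:4,
                           snap_filaments = FALSE) {
  stopifnot(inherits(truth, "behavioral_truth"))
  if (length(doses) == 0) stop("at least one dose required")
  if (any(doses < 0)) stop("doses must be >= 0")
  filaments <- c(0.04, 0.07, 0.16, 0.4, 0.6, 1, 1.4, 2, 4, 6, 8, 15)
  filaments <- c(filaments, 26, 60)
  tab <- with_seed(truth$seed, {
    grid <- expand.grid(animal = seq_len(truth$n_animals),
                        dose = doses, time = timepoints)
    model <- hill_response(grid$dose, truth$hill, truth$collapse)
    mpa <- model + stats::rnorm(nrow(grid), 0, truth$noise_sd)
    wd <- wd50_from_mpa(mpa, truth$wd50_predrug, truth$wd50_prepni)
    wd <- pmin(pmax(wd, 0), truth$wd50_prepni)
    if (snap_filaments)
      wd <- vapply(wd, function(w) filaments[which.min(abs(filaments - w))],
                   numeric(1))
    data.frame(animal_id = sprintf("a%02d_d%g", grid$animal, grid$dose),
               group = ifelse(grid$dose == 0, "vehicle", "drug"),
               dose_mgkg = grid$dose, time_h = grid$time, wd50_g = wd,
               mpa = compute_mpa(wd, truth$wd50_predrug, truth$wd50_prepni))
  })
  list(table = tab, truth = truth)
}

#' Generate a synthetic mIPSC trace from the gating model
#'
#' Events occur as a Poisson process at `event_rate`; each event's
#' waveform is the open-fraction time course of [simulate_gating()] under
#' the given preset, normalized to unit peak and scaled by a lognormal
#' amplitude. Gaussian baseline noise is added. With a zero rate and zero
#' noise the trace is identically zero.
#'
#' @param preset a [gating_params()] object.
#' @param event_rate events per second (>= 0).
#' @param amplitude_mean,amplitude_cv mean (pA) and coefficient of
#'   variation of event amplitudes.
#' @param noise_sd baseline Gaussian noise SD, pA.
#' @param duration_ms trace duration, ms.
#' @param dt_ms sampling step, ms.
#' @param pulse transmitter pulse shaping each event.
#' @param seed RNG seed.
#' @return list with `trace` (data.frame `time_ms`, `pa`), `event_times`
#'   (ms) and `truth` (generating parameters).
#' @export
gen_mipsc_trace <- function(preset, event_rate = 5, amplitude_mean = 50,
                            amplitude_cv = 0.3, noise_sd = 2,
                            duration_ms = 2000, dt_ms = 0.1,
                            pulse = transmitter_pulse(), seed = 1) {
  stopifnot(inherits(preset, "gating_params"))
  if (event_rate < 0) stop("event_rate must be >= 0")
  if (duration_ms <= 0) stop("duration must be > 0")
  tgrid <- seq(0, duration_ms, by = dt_ms)
  # event template: open fraction, unit peak, truncated at 1e-4 of peak
  traj <- simulate_gating(preset, pulse, duration = 150, dt = dt_ms)
  tmpl <- traj$o / max(traj$o)
  tmpl <- tmpl[seq_len(max(which(tmpl > 1e-4)))]
  out <- with_seed(seed, {
    n_ev <- stats::rpois(1, event_rate * duration_ms / 1000)
    ev_t <- sort(stats::runif(n_ev, 0, duration_ms))
    sdlog <- sqrt(log(1 + amplitude_cv^2))
    amps <- stats::rlnorm(n_ev, log(amplitude_mean) - sdlog^2 / 2, sdlog)
    trace <- numeric(length(tgrid))
    for (i in seq_len(n_ev)) {
      i0 <- floor(ev_t[i] / dt_ms) + 1
      idx <- i0:min(length(tgrid), i0 + length(tmpl) - 1)
      trace[idx] <- trace[idx] + amps[i] * tmpl[seq_along(idx)]
    }
    if (noise_sd > 0) trace <- trace + stats::rnorm(length(trace), 0, noise_sd)
    list(trace = data.frame(time_ms = tgrid, pa = trace), event_times = ev_t,
         amplitudes = amps)
  })
  list(trace = out$trace, event_times = out$event_times,
       truth = list(preset = preset, event_rate = event_rate,
                    amplitude_mean = amplitude_mean,
                    amplitude_cv = amplitude_cv, noise_sd = noise_sd,
                    amplitudes = out$amplitudes, seed = seed))
}

# render additive discs on a canvas, gaussian-blur, add noise, clip
render_field <- function(canvas, pixel_size, psf_sigma_um, background,
                         poisson_noise, read_noise_sd, bit_depth = 12) {
  sig <- canvas
  if (psf_sigma_um > 0)
    sig <- as.matrix(EBImage::gblur(EBImage::Image(sig),
                                    sigma = psf_sigma_um / pixel_size))
  img <- sig + background
  if (poisson_noise) img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                                   nrow(img), ncol(img))
  if (read_noise_sd > 0) img <- img + stats::rnorm(length(img), 0, read_noise_sd)
  img <- pmin(pmax(img, 0), 2^bit_depth - 1)
  img
}

disc_indices <- function(dim, center, radius) {
  rr <- row(matrix(0, dim[1], dim[2])); cc <- col(matrix(0, dim[1], dim[2]))
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

ellipse_indices <- function(dim, center, semi_major, semi_minor, angle = 0) {
  rr <- row(matrix(0, dim[1], dim[2])) - center[1]
  cc <- col(matrix(0, dim[1], dim[2])) - center[2]
  u <- cc * cos(angle) + rr * sin(angle)
  v <- -cc * sin(angle) + rr * cos(angle)
  (u / semi_major)^2 + (v / semi_minor)^2 <= 1
}

#' Generate a synthetic punctate immunofluorescence image
#'
#' Puncta are discs of given radius and amplitude placed at the given
#' (or random non-overlapping) positions, blurred with an isotropic
#' Gaussian PSF, set over a constant background, and corrupted with
#' Poisson shot noise plus Gaussian read noise before 12-bit clipping.
#' The default PSF sigma corresponds to an FWHM of about 0.25 um
#' (high-NA oil objective).
#'
#' @param n_puncta number of puncta (ignored if `positions` given).
#' @param dim image dimensions, px.
#' @param pixel_size pixel size, um.
#' @param psf_sigma_um PSF Gaussian sigma, um.
#' @param amplitude punctum peak amplitude(s) above background
#'   (recycled).
#' @param radius_um punctum disc radius, um.
#' @param background constant background level.
#' @param positions optional n x 2 matrix (row, col) of centers; all must
#'   lie inside the frame.
#' @param poisson_noise,read_noise_sd noise model controls.
#' @param min_separation_px minimum center separation when sampling
#'   random positions.
#' @param seed RNG seed.
#' @return list with `image` (an [image_plane()]) and `truth` (positions,
#'   amplitudes, radius, background, noise settings, seed).
#' @export
gen_puncta_image <- function(n_puncta = 50, dim = c(256, 256),
                             pixel_size = 0.1, psf_sigma_um = 0.106,
                             amplitude = 800, radius_um = 0.3,
                             background = 100, positions = NULL,
                             poisson_noise = TRUE, read_noise_sd = 5,
                             min_separation_px = 12, seed = 1) {
  if (psf_sigma_um <= 0) stop("psf_sigma_um must be > 0")
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  out <- with_seed(seed, {
    if (is.null(positions)) {
      positions <- matrix(NA_real_, 0, 2)
      margin <- ceiling(radius_um / pixel_size) + 5
      tries <- 0
      while (nrow(positions) < n_puncta && tries < 20000) {
        p <- c(stats::runif(1, margin, dim[1] - margin),
               stats::runif(1, margin, dim[2] - margin))
        if (nrow(positions) == 0 ||
            min(sqrt((positions[, 1] - p[1])^2 + (positions[, 2] - p[2])^2)) >=
              min_separation_px)
          positions <- rbind(positions, p)
        tries <- tries + 1
      }
      if (nrow(positions) < n_puncta)
        stop("could not place the requested number of separated puncta")
    } else {
      positions <- as.matrix(positions)
      if (any(positions[, 1] < 1) || any(positions[, 2] < 1) ||
          any(positions[, 1] > dim[1]) || any(positions[, 2] > dim[2]))
        stop("punctum positions must lie inside the frame")
    }
    amps <- rep_len(amplitude, nrow(positions))
    canvas <- matrix(0, dim[1], dim[2])
    r_px <- radius_um / pixel_size
    # `amplitude` is defined as the mean in-footprint brightness of a
    # punctum after blurring, so quantification against the planted disc
    # recovers it directly; pre-compensate the PSF edge loss on a unit disc
    side <- 2 * ceiling(r_px + 6 * psf_sigma_um / pixel_size) + 1
    unit <- matrix(0, side, side)
    ctr_ij <- c((side + 1) / 2, (side + 1) / 2)
    foot <- disc_indices(c(side, side), ctr_ij, r_px)
    unit[foot] <- 1
    blurred <- as.matrix(EBImage::gblur(EBImage::Image(unit),
                                        sigma = psf_sigma_um / pixel_size))
    loss <- mean(blurred[foot])
    for (i in seq_len(nrow(positions)))
      canvas[disc_indices(dim, positions[i, ], r_px)] <-
        canvas[disc_indices(dim, positions[i, ], r_px)] + amps[i] / loss
    img <- render_field(canvas, pixel_size, psf_sigma_um, background,
                        poisson_noise, read_noise_sd)
    list(img = img, positions = positions, amps = amps)
  })
  list(image = image_plane(out$img, pixel_size),
       truth = list(positions = out$positions, amplitudes = out$amps,
                    radius_um = radius_um, psf_sigma_um = psf_sigma_um,
                    background = background, poisson_noise = poisson_noise,
                    read_noise_sd = read_noise_sd, pixel_size = pixel_size,
                    seed = seed))
}

#' Generate a synthetic membrane-ring cell image
#'
#' Cells are rendered as a bright membrane ring (1-2 px annulus at the
#' planted diameter) around a dimmer intracellular disc, on a
#' background, then PSF-blurred and noised. The planted
#' membrane-minus-intracellular contrast and geometry are returned as
#' ground truth for membrane-profile and membrane-index recovery tests.
#'
#' @param cells data.frame with `row`, `col`, `radius_px` per cell.
#' @param dim image dimensions, px.
#' @param pixel_size um per pixel.
#' @param membrane_level,intracellular_level,background intensity levels
#'   (must be ordered membrane >= intracellular >= background >= 0).
#' @param ring_px membrane annulus thickness, px.
#' @param psf_sigma_um PSF sigma, um.
#' @param poisson_noise,read_noise_sd noise controls.
#' @param seed RNG seed.
#' @return list with `image` ([image_plane()]) and `truth`.
#' @export
gen_membrane_image <- function(cells, dim = c(256, 256), pixel_size = 0.2,
                               membrane_level = 900,
                               intracellular_level = 400, background = 100,
                               ring_px = 3, psf_sigma_um = 0.25,
                               poisson_noise = TRUE, read_noise_sd = 5,
                               seed = 1) {
  if (!(membrane_level >= intracellular_level &&
        intracellular_level >= background && background >= 0))
    stop("need membrane >= intracellular >= background >= 0")
  for (i in seq_len(nrow(cells)))
    for (j in seq_len(nrow(cells)))
      if (i < j) {
        d <- sqrt((cells$row[i] - cells$row[j])^2 +
                  (cells$col[i] - cells$col[j])^2)
        if (d < cells$radius_px[i] + cells$radius_px[j])
          stop("cells overlap beyond tolerance")
      }
  out <- with_seed(seed, {
    canvas <- matrix(0, dim[1], dim[2])
    for (i in seq_len(nrow(cells))) {
      # annulus centered on the planted radius, so the intensity maxima sit
      # at the nominal membrane position and peak separation = 2 * radius
      ctr <- c(cells$row[i], cells$col[i]); r <- cells$radius_px[i]
      inner <- disc_indices(dim, ctr, r - ring_px / 2)
      outer <- disc_indices(dim, ctr, r + ring_px / 2)
      canvas[outer & !inner] <- membrane_level - background
      canvas[inner] <- intracellular_level - background
    }
    render_field(canvas, pixel_size, psf_sigma_um, background,
                 poisson_noise, read_noise_sd)
  })
  list(image = image_plane(out, pixel_size),
       truth = list(cells = cells, membrane_level = membrane_level,
                    intracellular_level = intracellular_level,
                    background = background, ring_px = ring_px,
                    psf_sigma_um = psf_sigma_um, pixel_size = pixel_size,
                    seed = seed))
}

#' Generate a synthetic in-situ hybridization (soma + dots) image set
#'
#' Produces a Nissl-like soma channel (filled ellipses of given size,
#' eccentricity and intensity) and one dot channel per requested marker,
#' with a planted number of PSF-scale dots inside each soma. Ground truth
#' stores per-cell dot counts per channel, so transcript-counting and
#' cell-typing can be validated exactly.
#'
#' @param somata data.frame with `row`, `col`, `semi_major_px`,
#'   `eccentricity`, `angle` (radians), `intensity` per soma.
#' @param dots_per_cell named list: per channel, an integer vector of dot
#'   counts per soma (same order as `somata` rows).
#' @param dim image dimensions, px.
#' @param pixel_size um per pixel.
#' @param dot_amplitude,dot_radius_px dot rendering parameters.
#' @param background,psf_sigma_um,read_noise_sd rendering controls
#'   (Poisson noise is applied to the soma channel only; dot channels are
#'   near-noiseless so counts are exact at high SNR).
#' @param seed RNG seed.
#' @return list with `soma_image` ([image_plane()]), `dot_images` (named
#'   list of [image_plane()]), `dot_positions` (named list of
#'   data.frames), `truth`.
#' @export
gen_rnascope_image <- function(somata, dots_per_cell, dim = c(256, 256),
                               pixel_size = 0.2, dot_amplitude = 1500,
                               dot_radius_px = 1.5, background = 50,
                               psf_sigma_um = 0.25, read_noise_sd = 3,
                               seed = 1) {
  if (any(somata$eccentricity < 0) || any(somata$eccentricity >= 1))
    stop("eccentricity must be in [0, 1)")
  out <- with_seed(seed, {
    soma_canvas <- matrix(0, dim[1], dim[2])
    masks <- vector("list", nrow(somata))
    for (i in seq_len(nrow(somata))) {
      a <- somata$semi_major_px[i]
      b <- a * sqrt(1 - somata$eccentricity[i]^2)
      m <- ellipse_indices(dim, c(somata$row[i], somata$col[i]), a, b,
                           somata$angle[i])
      masks[[i]] <- m
      soma_canvas[m] <- somata$intensity[i] - background
    }
    soma_img <- render_field(soma_canvas, pixel_size, psf_sigma_um,
                             background, TRUE, read_noise_sd)
    dot_imgs <- list(); dot_pos <- list()
    for (ch in names(dots_per_cell)) {
      canvas <- matrix(0, dim[1], dim[2])
      pos <- data.frame(row = numeric(0), col = numeric(0), cell = integer(0))
      for (i in seq_len(nrow(somata))) {
        k <- dots_per_cell[[ch]][i]
        if (k == 0) next
        cand <- which(masks[[i]], arr.ind = TRUE)
        # keep dots away from the soma edge so blur cannot move them out
        ctr <- c(somata$row[i], somata$col[i])
        d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
        cand <- cand[d2 <= stats::quantile(d2, 0.6), , drop = FALSE]
        # enforce separation so each dot is a distinct object
        sel <- matrix(NA_real_, 0, 2)
        while (nrow(sel) < k) {
          p <- cand[sample(nrow(cand), 1), ]
          if (nrow(sel) == 0 ||
              min(sqrt((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2)) >
                4 * dot_radius_px)
            sel <- rbind(sel, p)
        }
        for (j in seq_len(k))
          canvas[disc_indices(dim, sel[j, ], dot_radius_px)] <- dot_amplitude
        pos <- rbind(pos, data.frame(row = sel[, 1], col = sel[, 2], cell = i))
      }
      dot_imgs[[ch]] <- render_field(canvas, pixel_size, psf_sigma_um,
                                     background / 5, FALSE, read_noise_sd / 3)
      dot_pos[[ch]] <- pos
    }
    list(soma = soma_img, dots = dot_imgs, pos = dot_pos)
  })
  list(soma_image = image_plane(out$soma, pixel_size),
       dot_images = lapply(out$dots, image_plane, pixel_size = pixel_size),
       dot_positions = out$pos,
       truth = list(somata = somata, dots_per_cell = dots_per_cell,
                    pixel_size = pixel_size, seed = seed))
}

#' Cluster mask built from planted punctum ground truth
#'
#' Converts the ground-truth record of [gen_puncta_image()] into the same
#' labelled-mask structure returned by [detect_clusters()], with one disc
#' label per planted punctum. Useful to quantify intensity recovery
#' against the known footprints independently of the detector.
#'
#' @param truth the `truth` element returned by [gen_puncta_image()].
#' @param dim image dimensions, px.
#' @return A `cluster_mask` object.
#' @export
truth_cluster_mask <- function(truth, dim = c(256, 256)) {
  labels <- matrix(0L, dim[1], dim[2])
  r_px <- truth$radius_um / truth$pixel_size
  for (i in seq_len(nrow(truth$positions)))
    labels[disc_indices(dim, truth$positions[i, ], r_px)] <- i
  objects <- summarize_labels(labels, matrix(0, dim[1], dim[2]),
                              truth$pixel_size)
  area_um2 <- prod(dim) * truth$pixel_size^2
  structure(list(mask = labels > 0, labels = labels, objects = objects,
                 n = nrow(truth$positions),
                 density_per_100um2 = 100 * nrow(truth$positions) / area_um2),
            class = "cluster_mask")
}

#' Write a behavioral table, trace or image to disk
#'
#' Behavioral tables and traces go to CSV; images to 16-bit TIFF with a
#' JSON sidecar holding the pixel size and the ground-truth record.
#'
#' @param x object from a generator.
#' @param path output file path (`.csv` or `.tif`).
#' @name synthetic-io
#' @export
write_behavioral_csv <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic-io
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(x$trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic-io
#' @param image an [image_plane()].
#' @param truth optional ground-truth list for the sidecar.
#' @export
write_image_tiff <- function(image, path, truth = NULL) {
  stopifnot(inherits(image, "image_plane"))
  tiff::writeTIFF(image$data / (2^16 - 1), path, bits.per.sample = 16)
  sidecar <- list(pixel_size_um = image$pixel_size,
                  bit_depth = image$bit_depth,
                  scale = "stored as value/65535")
  if (!is.null(truth))
    sidecar$truth <- truth[!vapply(truth, is.function, logical(1))]
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname synthetic-io
#' @export
read_image_tiff <- function(path) {
  raw <- tiff::readTIFF(path)
  sidecar_path <- paste0(path, ".json")
  ps <- 1; bd <- 16
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    ps <- sc$pixel_size_um; bd <- sc$bit_depth
  }
  image_plane(raw * (2^16 - 1), pixel_size = ps, bit_depth = bd)
}
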