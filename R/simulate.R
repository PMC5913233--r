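#' Binding-kinetics model of imager / docking-site hybridization
#'
#' DNA-PAINT blinking is an alternating renewal process: a docking site waits
#' an exponentially distributed dark time for an imager strand to bind, stays
#' bright for an exponentially distributed bright time, and repeats. The mean
#' dark time defaults to the simulation value of 12.5 s; when not given it is
#' derived from the association rate and imager concentration as
#' 1 / (k_on * c).
#'
#' @param tau_dark mean dark time (s), or `NULL` to derive from `k_on` and
#'   `imager_nM`.
#' @param tau_bright mean bright time (s).
#' @param k_on association rate (per molar per second).
#' @param imager_nM imager strand concentration (nanomolar).
#' @export
kinetic_model <- function(tau_dark = 12.5, tau_bright = 0.5,
                          k_on = 1.6e6, imager_nM = 5) {
  if (is.null(tau_dark)) tau_dark <- 1 / (k_on * imager_nM * 1e-9)
  stopifnot(tau_dark > 0, tau_bright > 0, k_on > 0, imager_nM > 0)
  structure(list(tau_dark = tau_dark, tau_bright = tau_bright,
                 k_on = k_on, imager_nM = imager_nM),
            class = "kinetic_model")
}

#' Camera / photophysics model of the imaging experiment
#'
#' Defaults reproduce the in-silico imaging conditions: 15,000 frames of
#' 200 ms on a 128 x 128 px camera with 160 nm pixels, a detection rate of
#' 35 photons per ms per kW/cm^2 at 1.5 kW/cm^2 power density (10,500 photons
#' for a fully bright frame), a photon budget of 1.5e6 per binding event, and
#' a PSF of 309 nm FWHM. The localization error per axis is
#' psf_sigma / sqrt(photons); localizations below `min_photons` are discarded,
#' mimicking the detection floor of spot-fitting software.
#'
#' @param n_frames number of camera frames.
#' @param integration_ms frame integration time (ms).
#' @param pixel_size_nm camera pixel size (nm).
#' @param detection_rate photons per ms per kW/cm^2.
#' @param power_density excitation power density (kW/cm^2).
#' @param photon_budget maximum photons emitted per binding event.
#' @param psf_fwhm_nm point-spread-function full width at half maximum (nm).
#' @param image_size_px camera width/height in pixels.
#' @param min_photons localizations with fewer photons are dropped.
#' @export
imaging_model <- function(n_frames = 15000L, integration_ms = 200,
                          pixel_size_nm = 160, detection_rate = 35,
                          power_density = 1.5, photon_budget = 1.5e6,
                          psf_fwhm_nm = 309, image_size_px = 128L,
                          min_photons = 100) {
  stopifnot(n_frames > 0, integration_ms > 0, pixel_size_nm > 0,
            detection_rate > 0, power_density > 0, photon_budget > 0,
            psf_fwhm_nm > 0, image_size_px > 0, min_photons >= 0)
  structure(list(n_frames = as.integer(n_frames), integration_ms = integration_ms,
                 pixel_size_nm = pixel_size_nm, detection_rate = detection_rate,
                 power_density = power_density, photon_budget = photon_budget,
                 psf_fwhm_nm = psf_fwhm_nm,
                 psf_sigma_nm = psf_fwhm_nm / (2 * sqrt(2 * log(2))),
                 image_size_px = as.integer(image_size_px),
                 min_photons = min_photons),
            class = "imaging_model")
}

#' Sample binding intervals for one docking site
#'
#' Alternating renewal process starting in the dark state: dark durations are
#' Exponential(mean `tau_dark`), bright durations Exponential(mean
#' `tau_bright`); intervals are truncated at `total_time`. The expected number
#' of binding events is approximately `total_time / (tau_dark + tau_bright)`.
#'
#' @param kinetics a [kinetic_model()].
#' @param total_time acquisition length (s).
#' @return data frame with columns `start`, `duration` (s), ordered and
#'   non-overlapping.
#' @export
sample_binding_intervals <- function(kinetics, total_time) {
  stopifnot(total_time >= 0)
  if (total_time == 0) return(data.frame(start = numeric(0), duration = numeric(0)))
  mu <- kinetics$tau_dark + kinetics$tau_bright
  starts <- numeric(0); durs <- numeric(0); t0 <- 0
  repeat {
    n <- max(16L, ceiling(1.5 * (total_time - t0) / mu + 10))
    d <- stats::rexp(n, 1 / kinetics$tau_dark)
    b <- stats::rexp(n, 1 / kinetics$tau_bright)
    s <- t0 + cumsum(d + b) - b
    keep <- s < total_time
    starts <- c(starts, s[keep]); durs <- c(durs, b[keep])
    if (!all(keep)) break
    t0 <- s[n] + b[n]
  }
  durs <- pmin(durs, total_time - starts)
  data.frame(start = starts, duration = durs)
}

#' Convert binding intervals into localization records
#'
#' Each bright interval is discretized into camera frames; every overlapped
#' frame yields one localization with photons proportional to the overlap time
#' (capped so that cumulative photons per event stay within the photon
#' budget). The localization position is the site position plus isotropic
#' Gaussian error of sd `psf_sigma / sqrt(photons)` per axis, which is also
#' recorded as the localization precision. Localizations below the photon
#' floor are dropped.
#'
#' @param intervals data frame from [sample_binding_intervals()].
#' @param site_xy numeric length-2: site position (nm).
#' @param imaging an [imaging_model()].
#' @return data frame with columns `frame` (0-based), `x`, `y` (nm),
#'   `photons`, `sd_nm`.
#' @export
events_to_localizations <- function(intervals, site_xy, imaging) {
  if (nrow(intervals) == 0L)
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      photons = numeric(0), sd_nm = numeric(0)))
  dt <- imaging$integration_ms / 1000
  start <- intervals$start
  end <- start + intervals$duration
  f0 <- floor(start / dt)
  f1 <- floor((end - 1e-12) / dt)        # end exactly on a boundary stays in the previous frame
  f1 <- pmax(f1, f0)
  k <- as.integer(f1 - f0 + 1)
  ev <- rep.int(seq_along(k), k)
  frame <- unlist(lapply(seq_along(k), function(i) f0[i] + 0:(k[i] - 1L)), use.names = FALSE)
  ov <- pmin(end[ev], (frame + 1) * dt) - pmax(start[ev], frame * dt)
  photons <- imaging$detection_rate * imaging$power_density * (ov * 1000)
  # photon budget: cap cumulative photons within each event
  cs <- cumsum(photons)
  base <- rep.int(c(0, cs[cumsum(k)])[seq_along(k)], k)
  within <- cs - base
  photons <- pmax(0, pmin(photons, imaging$photon_budget - (within - photons)))
  keep <- frame >= 0 & frame < imaging$n_frames & photons >= imaging$min_photons
  frame <- frame[keep]; photons <- photons[keep]
  sd_nm <- imaging$psf_sigma_nm / sqrt(photons)
  n <- length(frame)
  data.frame(frame = as.integer(frame),
             x = site_xy[1] + stats::rnorm(n, 0, sd_nm),
             y = site_xy[2] + stats::rnorm(n, 0, sd_nm),
             photons = photons, sd_nm = sd_nm)
}

#' Simulate a full DNA-PAINT field of view with ground truth
#'
#' Places `n_structures` copies of `pattern` at uniform random positions and
#' orientations in the camera field (with a minimum separation), draws per-site
#' presence as Bernoulli(`presence`) for probed sites (alignment sites are
#' always present; absent-by-design sites never), simulates every present site
#' independently with the given kinetics, and returns the pooled localization
#' table (sorted by frame) together with the ground truth. Deterministic given
#' `seed`: each structure uses its own child RNG stream derived from the
#' master seed.
#'
#' @param pattern a [site_pattern()].
#' @param n_structures number of structures to place.
#' @param presence per-site presence probability in `[0, 1]` (scalar or one
#'   value per probed site).
#' @param kinetics a [kinetic_model()].
#' @param imaging an [imaging_model()].
#' @param seed master RNG seed.
#' @param exclusion_nm minimum distance between structure centers (nm).
#' @param mirror_prob probability that a structure adsorbs mirrored (default 0:
#'   one attachment face).
#' @return list with `table` (a localization table, see [loc_table()]) and
#'   `truth` (list: `structures` data frame with id, position (px), angle
#'   (degrees), mirror; `presence` logical matrix structures x sites;
#'   `pattern`).
#' @export
simulate_field <- function(pattern, n_structures, presence = 1,
                           kinetics = kinetic_model(), imaging = imaging_model(),
                           seed = 1L, exclusion_nm = 400, mirror_prob = 0) {
  stopifnot(all(presence >= 0), all(presence <= 1), n_structures >= 1)
  set.seed(seed)
  field_nm <- imaging$image_size_px * imaging$pixel_size_nm
  pat_r <- max(sqrt(rowSums(pattern$sites^2)))
  margin <- pat_r + 50
  if (field_nm <= 2 * margin) stop("field too small for this pattern")
  centers <- matrix(NA_real_, n_structures, 2)
  placed <- 0L; tries <- 0L
  while (placed < n_structures) {
    tries <- tries + 1L
    if (tries > 200L * n_structures)
      stop("field too crowded to place structures with the requested exclusion radius")
    cand <- stats::runif(2, margin, field_nm - margin)
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < exclusion_nm^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  angles <- stats::runif(n_structures, 0, 360)
  mirrors <- stats::runif(n_structures) < mirror_prob
  n_sites <- nrow(pattern$sites)
  probed_idx <- which(pattern$probed)
  pres_p <- rep_len(presence, length(probed_idx))
  presence_mat <- matrix(FALSE, n_structures, n_sites,
                         dimnames = list(NULL, pattern$labels))
  presence_mat[, pattern$alignment] <- TRUE
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_structures)
  total_time <- imaging$n_frames * imaging$integration_ms / 1000
  px <- imaging$pixel_size_nm
  rows <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    set.seed(child_seeds[i])
    pres <- stats::runif(length(probed_idx)) < pres_p
    presence_mat[i, probed_idx] <- pres
    th <- angles[i] * pi / 180
    loc_i <- vector("list", n_sites)
    for (s in which(presence_mat[i, ])) {
      iv <- sample_binding_intervals(kinetics, total_time)
      ll <- events_to_localizations(iv, c(pattern$sites[s, ]), imaging)
      loc_i[[s]] <- ll
    }
    loc_i <- do.call(rbind, loc_i)
    if (is.null(loc_i) || nrow(loc_i) == 0L) next
    sx <- if (mirrors[i]) -loc_i$x else loc_i$x
    gx <- centers[i, 1] + sx * cos(th) - loc_i$y * sin(th)
    gy <- centers[i, 2] - (sx * sin(th) + loc_i$y * cos(th)) # camera y points down
    rows[[i]] <- data.frame(frame = loc_i$frame, x = gx / px, y = gy / px,
                            photons = loc_i$photons,
                            lpx = loc_i$sd_nm / px, lpy = loc_i$sd_nm / px)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(frame = integer(0), x = numeric(0),
                                      y = numeric(0), photons = numeric(0),
                                      lpx = numeric(0), lpy = numeric(0))
  tab <- tab[order(tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  table <- loc_table(tab, pixel_size_nm = px, n_frames = imaging$n_frames,
                     width = imaging$image_size_px, height = imaging$image_size_px)
  truth <- list(
    structures = data.frame(id = seq_len(n_structures),
                            x_px = centers[, 1] / px, y_px = centers[, 2] / px,
                            angle_deg = angles, mirror = mirrors),
    presence = presence_mat, pattern = pattern)
  list(table = table, truth = truth)
}
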