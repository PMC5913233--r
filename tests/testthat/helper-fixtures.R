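# Shared fixtures and independent oracles for the test suite.

# Reduced acquisition for fast unit tests: same kinetics and photophysics as
# the full model, fewer frames. ~35 binding events per site instead of ~230.
fast_imaging <- function(n_frames = 2250L) imaging_model(n_frames = n_frames)

# Closed-form renewal oracle for the expected number of localizations per
# present site, independent of the simulator's code path. A site binds on
# average T / (tau_d + tau_b) times; a bright interval of duration d starting
# at a uniform phase within a frame overlaps E[d]/dt + 1 frames; edge frames
# with overlap below the photon floor (min_photons / (rate * power) ms) are
# dropped, each with probability ~ t_floor/dt per edge.
expected_locs_per_site <- function(kin = kinetic_model(), img = imaging_model()) {
  total_time <- img$n_frames * img$integration_ms / 1000
  n_events <- total_time / (kin$tau_dark + kin$tau_bright)
  dt <- img$integration_ms / 1000
  t_floor_ms <- img$min_photons / (img$detection_rate * img$power_density)
  locs_per_event <- kin$tau_bright / dt + 1 - 2 * (t_floor_ms / img$integration_ms)
  n_events * locs_per_event
}

# ideal localization set of a pattern: m localizations exactly at every
# rendered (probed or alignment) site
ideal_locs <- function(pattern, m = 20) {
  keep <- pattern$probed | pattern$alignment
  s <- pattern$sites[keep, , drop = FALSE]
  out <- data.frame(x = rep(s[, 1], each = m), y = rep(s[, 2], each = m),
                    frame = 0L, photons = 1000, sd_nm = 1.3)
  class(out) <- c("structure_locs", "data.frame")
  out
}

# apply a rotation (degrees, counterclockwise) and optional mirror/shift to a
# localization set -- written independently of transform_locs()
rotate_locs <- function(locs, angle_deg, mirror = FALSE, shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  x <- if (mirror) -locs$x else locs$x
  out <- locs
  out$x <- x * cos(th) - locs$y * sin(th) + shift[1]
  out$y <- x * sin(th) + locs$y * cos(th) + shift[2]
  out
}

# match picked regions to ground-truth structures by nearest center
match_picks <- function(picks, truth, max_dist_px = 2) {
  vapply(seq_len(nrow(picks)), function(i) {
    d2 <- (truth$structures$x_px - picks$x_px[i])^2 +
          (truth$structures$y_px - picks$y_px[i])^2
    k <- which.min(d2)
    if (d2[k] <= max_dist_px^2) k else NA_integer_
  }, integer(1))
}
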