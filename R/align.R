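#' Render a picked structure as a 2D localization histogram
#'
#' Computes the 2D histogram of localization positions on the given bin grid,
#' optionally blurred with a Gaussian. Total counts are preserved before
#' blurring (localizations outside the grid are dropped).
#'
#' @param structure_locs a `structure_locs` from [extract_structure()].
#' @param bin_size nm per bin.
#' @param extent image side length (nm).
#' @param blur_sigma optional Gaussian blur (nm); 0 disables.
#' @return numeric matrix indexed `[ix, iy]` (x rightward, y upward) with
#'   attributes `bin_size` and `centers` (bin center coordinates, nm).
#' @export
render_structure <- function(structure_locs, bin_size = 1, extent = NULL,
                             blur_sigma = 0) {
  if (nrow(structure_locs) == 0L) stop("cannot render an empty localization set")
  if (is.null(extent))
    extent <- 2 * (max(abs(c(structure_locs$x, structure_locs$y))) + 2 * bin_size)
  n <- stats::nextn(ceiling(extent / bin_size), c(2, 3, 5))
  h <- bin_points(structure_locs$x, structure_locs$y, n, bin_size)
  if (blur_sigma > 0) h <- gaussian_blur(h, blur_sigma / bin_size)
  attr(h, "bin_size") <- bin_size
  attr(h, "centers") <- (seq_len(n) - (n + 1) / 2) * bin_size
  h
}

# 2D histogram of points on an n x n grid of `bin` nm centred at the origin
bin_points <- function(x, y, n, bin) {
  ix <- round(x / bin + (n + 1) / 2)
  iy <- round(y / bin + (n + 1) / 2)
  ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
  h <- matrix(tabulate((ix[ok] - 1) + (iy[ok] - 1) * n + 1, n * n), n, n)
  h
}

# separable Gaussian blur by banded kernel matrices
gaussian_blur <- function(h, sigma_bins) {
  n <- nrow(h)
  k <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-(i - j)^2 / (2 * sigma_bins^2)))
  k <- k / rowSums(k)
  k %*% h %*% t(k)
}

#' Align a picked structure to a template by rotational cross-correlation
#'
#' The structure's localizations are rotated stepwise through a full circle
#' (step `step_deg`); at each step a 2D histogram on the template's bin grid
#' is cross-correlated with the template image in the frequency domain, which
#' searches all translations at once. Correlations are normalized by the image
#' norms so scores are comparable across templates. The transform with the
#' global correlation maximum wins; ties break to the smallest angle, then to
#' the non-mirrored orientation.
#'
#' @param structure_locs a `structure_locs` from [extract_structure()].
#' @param template a `template_image` from [render_template()].
#' @param step_deg rotation step (degrees).
#' @param try_mirror also search the mirrored (x-flipped) orientation.
#' @return An `alignment_result`: list with `angle` (degrees in `[0, 360)`,
#'   the rotation applied to the structure), `shift` (dx, dy in nm, applied
#'   after rotation), `mirror`, `correlation` and `template` (name).
#' @export
align_to_template <- function(structure_locs, template, step_deg = 1,
                              try_mirror = FALSE) {
  if (nrow(structure_locs) == 0L) stop("cannot align an empty localization set")
  tf <- template_fft(template)
  angles <- seq(0, 360 - step_deg, by = step_deg)
  best <- list(score = -Inf)
  for (mir in if (try_mirror) c(FALSE, TRUE) else FALSE) {
    for (th in angles) {
      sc <- score_rotation(structure_locs, th, mir, tf)
      if (sc$score > best$score)
        best <- c(sc, list(angle = th, mirror = mir))
    }
  }
  if (!is.finite(best$score)) stop("degenerate (all-zero) structure image")
  structure(list(angle = best$angle, shift = best$shift, mirror = best$mirror,
                 correlation = best$score, template = template$name),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment: template '%s', angle %.1f deg, shift (%.1f, %.1f) nm, %scorrelation %.3f>\n",
    x$template, x$angle, x$shift[1], x$shift[2],
    if (x$mirror) "mirrored, " else "", x$correlation))
  invisible(x)
}

# precompute what the correlation search needs from a template
template_fft <- function(template) {
  tp <- template$pixels
  list(n = nrow(tp), bin = template$bin_size,
       fft = stats::fft(tp), norm = sqrt(sum(tp^2)), name = template$name)
}

# normalized cross-correlation of one rotated/mirrored copy of the structure
# against one (or more) prepared templates; returns best score and shift
score_rotation <- function(structure_locs, angle, mirror, tf) {
  th <- angle * pi / 180
  x <- if (mirror) -structure_locs$x else structure_locs$x
  y <- structure_locs$y
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  h <- bin_points(xr, yr, tf$n, tf$bin)
  nh <- sqrt(sum(h^2))
  if (nh == 0) return(list(score = -Inf, shift = c(0, 0)))
  cc <- Re(stats::fft(Conj(stats::fft(h)) * tf$fft, inverse = TRUE)) / (tf$n^2)
  i <- arrayInd(which.max(cc), dim(cc))
  list(score = max(cc) / (nh * tf$norm),
       shift = c(wrap_shift(i[1], tf$n), wrap_shift(i[2], tf$n)) * tf$bin)
}

# circular correlation peak index -> signed shift in bins
wrap_shift <- function(idx, n) {
  d <- idx - 1L
  if (d > n / 2) d - n else d
}

#' Classify a structure against a template library
#'
#' Runs the rotational alignment against every template and returns the best
#' by correlation. Structures whose best correlation falls below
#' `min_correlation` are flagged unassigned (`template = NA`), the automated
#' analogue of discarding structures without a recognizable alignment pattern.
#' All templates must share the same bin grid (render them from patterns in a
#' common design frame with one [template_spec()]).
#'
#' @param structure_locs a `structure_locs`.
#' @param templates named list of `template_image`s.
#' @param step_deg rotation step (degrees).
#' @param try_mirror also search mirrored orientations.
#' @param min_correlation assignment threshold on the normalized correlation;
#'   the default was calibrated on simulated uniform-noise picks (see the
#'   package vignette).
#' @return An `alignment_result` with an extra `scores` field (best
#'   correlation per template); `template` is `NA` if unassigned.
#' @export
classify_template <- function(structure_locs, templates, step_deg = 1,
                              try_mirror = FALSE, min_correlation = 0.35) {
  stopifnot(length(templates) >= 1)
  tfs <- lapply(templates, template_fft)
  n0 <- tfs[[1]]$n; b0 <- tfs[[1]]$bin
  if (!all(vapply(tfs, function(t) t$n == n0 && t$bin == b0, TRUE)))
    stop("all templates must share the same bin grid")
  angles <- seq(0, 360 - step_deg, by = step_deg)
  nt <- length(tfs)
  best <- rep(-Inf, nt)
  best_fit <- vector("list", nt)
  for (mir in if (try_mirror) c(FALSE, TRUE) else FALSE) {
    for (th in angles) {
      # one histogram + forward FFT per angle, reused across all templates
      thr <- th * pi / 180
      x <- if (mir) -structure_locs$x else structure_locs$x
      y <- structure_locs$y
      h <- bin_points(x * cos(thr) - y * sin(thr),
                      x * sin(thr) + y * cos(thr), n0, b0)
      nh <- sqrt(sum(h^2))
      if (nh == 0) next
      hf <- Conj(stats::fft(h))
      for (k in seq_len(nt)) {
        cc <- Re(stats::fft(hf * tfs[[k]]$fft, inverse = TRUE)) / (n0^2)
        sc <- max(cc) / (nh * tfs[[k]]$norm)
        if (sc > best[k]) {
          i <- arrayInd(which.max(cc), dim(cc))
          best[k] <- sc
          best_fit[[k]] <- list(angle = th, mirror = mir,
                                shift = c(wrap_shift(i[1], n0),
                                          wrap_shift(i[2], n0)) * b0)
        }
      }
    }
  }
  names(best) <- names(templates)
  if (!any(is.finite(best))) stop("degenerate (all-zero) structure image")
  w <- which.max(best)
  fit <- best_fit[[w]]
  assigned <- best[w] >= min_correlation
  structure(list(angle = fit$angle, shift = fit$shift, mirror = fit$mirror,
                 correlation = unname(best[w]),
                 template = if (assigned) names(templates)[w] else NA_character_,
                 scores = best),
            class = "alignment_result")
}

#' Apply an alignment transform to localization coordinates
#'
#' Applies, in order: the mirror flip (if set), the rotation by `angle` about
#' the pick center, and the translation by `shift` -- i.e. maps the structure
#' into its template's frame. Invertible via [invert_alignment()].
#'
#' @param structure_locs a `structure_locs`.
#' @param alignment an `alignment_result`.
#' @return The transformed `structure_locs`.
#' @export
transform_locs <- function(structure_locs, alignment) {
  th <- alignment$angle * pi / 180
  x <- if (alignment$mirror) -structure_locs$x else structure_locs$x
  y <- structure_locs$y
  out <- structure_locs
  out$x <- x * cos(th) - y * sin(th) + alignment$shift[1]
  out$y <- x * sin(th) + y * cos(th) + alignment$shift[2]
  attr(out, "aligned_to") <- alignment$template
  out
}

#' @rdname transform_locs
#' @export
invert_alignment <- function(alignment) {
  ang <- if (alignment$mirror) alignment$angle else -alignment$angle
  th <- ang * pi / 180
  s <- alignment$shift
  sx <- if (alignment$mirror) -s[1] else s[1]
  inv_shift <- -c(sx * cos(th) - s[2] * sin(th),
                  sx * sin(th) + s[2] * cos(th))
  structure(list(angle = (ang + 360) %% 360, shift = inv_shift,
                 mirror = alignment$mirror,
                 correlation = alignment$correlation,
                 template = alignment$template),
            class = "alignment_result")
}
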