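#' Per-figure analysis presets
#'
#' Bundles the per-use-case numeric parameters: counting-disc diameter,
#' template rendering sigma, histogram bin size of the alignment images and
#' rotation step.
#'
#' * `grid20`    -- 20-nm grid: 20 nm discs, sigma 3 nm, 2 nm bins.
#' * `excess`    -- staple-excess series on the grid: 18 nm discs, sigma 2 nm.
#' * `bs3bs6`    -- 3 BS / 6 BS single-site measurements: 5 nm discs, sigma 1 nm.
#' * `variants18`-- 18-variant rectangle library: 6 nm discs, sigma 1 nm.
#'
#' @param name preset name.
#' @return list of parameters accepted by [analyze_structures()].
#' @export
analysis_preset <- function(name = c("grid20", "excess", "bs3bs6", "variants18")) {
  name <- match.arg(name)
  switch(name,
    grid20     = list(count_diameter_nm = 20, render_sigma = 3, bin_size = 2, step_deg = 1),
    excess     = list(count_diameter_nm = 18, render_sigma = 2, bin_size = 2, step_deg = 1),
    bs3bs6     = list(count_diameter_nm = 5,  render_sigma = 1, bin_size = 1, step_deg = 1),
    variants18 = list(count_diameter_nm = 6,  render_sigma = 1, bin_size = 1, step_deg = 1))
}

#' Run the full single-design analysis pipeline
#'
#' pick -> extract -> align -> transform -> count -> threshold -> call ->
#' efficiency. Structures whose alignment correlation falls below
#' `min_correlation` are discarded (the automated analogue of removing picks
#' without a recognizable alignment pattern). The detection threshold is
#' fitted on the pooled counts of probed and absent-by-design sites via
#' [determine_threshold()] unless supplied explicitly (to e.g. share one
#' threshold across several conditions of an experiment, pool the `counts`
#' of all runs, fit once, and pass the result as `threshold`).
#'
#' @param table a [loc_table()].
#' @param pattern the [site_pattern()] the structures were built from.
#' @param preset preset name (see [analysis_preset()]) or a parameter list.
#' @param threshold optional fixed threshold (counts or `threshold_fit`).
#' @param min_correlation minimum alignment correlation to keep a structure.
#' @param try_mirror search mirrored orientations during alignment.
#' @param min_locs minimum localizations per pick.
#' @param pick_radius_nm pick radius; default: pattern radius plus 40 nm,
#'   covering the tails of the localization error (low-photon localizations
#'   from partial frames can sit tens of nm off their site).
#' @return An `origami_analysis`: list with `counts` (structures x sites
#'   matrix, roles in attribute `role`), `calls` (`site_calls`, `NULL` if no
#'   threshold could be fitted and none was given), `threshold_fit`,
#'   `efficiency`, `fp_rate` (if the design has absent sites), `alignments`,
#'   `picks`, `n_discarded`, `pattern` and `params`.
#' @export
analyze_structures <- function(table, pattern, preset = "grid20",
                               threshold = NULL, min_correlation = 0.35,
                               try_mirror = FALSE, min_locs = 50,
                               pick_radius_nm = NULL) {
  params <- if (is.character(preset)) analysis_preset(preset) else preset
  if (is.null(pick_radius_nm))
    pick_radius_nm <- max(sqrt(rowSums(pattern$sites^2))) + 40
  if (nrow(table) == 0L) stop("localization table is empty; nothing to analyze")
  picks <- pick_structures(table, expected_radius_nm = pick_radius_nm,
                           min_locs = min_locs)
  if (nrow(picks) == 0L) stop("no structures found by automated picking")
  template <- render_template(pattern,
                              template_spec(render_sigma = params$render_sigma,
                                            bin_size = params$bin_size))
  cfg <- site_count_config(params$count_diameter_nm)
  counts <- matrix(0L, nrow(picks), nrow(pattern$sites),
                   dimnames = list(NULL, pattern$labels))
  alignments <- vector("list", nrow(picks))
  keep <- logical(nrow(picks))
  for (i in seq_len(nrow(picks))) {
    locs <- extract_structure(table, picks[i, ])
    if (nrow(locs) == 0L) next
    al <- align_to_template(locs, template, step_deg = params$step_deg,
                            try_mirror = try_mirror)
    alignments[[i]] <- al
    if (al$correlation < min_correlation) next
    keep[i] <- TRUE
    counts[i, ] <- count_sites(transform_locs(locs, al), pattern, cfg)
  }
  counts <- counts[keep, , drop = FALSE]
  roles <- site_roles(pattern)
  attr(counts, "role") <- roles
  scored <- roles != "alignment"
  pooled <- as.vector(counts[, scored, drop = FALSE])
  tf <- NULL
  if (is.null(threshold)) {
    tf <- determine_threshold(pooled)
    threshold <- tf$threshold
  } else if (inherits(threshold, "threshold_fit")) {
    tf <- threshold
    threshold <- tf$threshold
  }
  calls <- call_sites(counts, threshold, roles = roles)
  out <- list(counts = counts, calls = calls, threshold_fit = tf,
              threshold = threshold,
              efficiency = detection_efficiency(calls),
              fp_rate = if (any(roles == "absent")) false_positive_rate(calls) else NULL,
              alignments = alignments[keep], picks = picks[keep, , drop = FALSE],
              n_discarded = sum(!keep), pattern = pattern, params = params)
  class(out) <- "origami_analysis"
  out
}

#' @export
print.origami_analysis <- function(x, ...) {
  cat(sprintf("<origami_analysis '%s': %d structures (%d discarded), threshold %.1f>\n",
              x$pattern$name, nrow(x$counts), x$n_discarded, x$threshold))
  cat(sprintf("  grand detection efficiency: %.1f%%\n", 100 * x$efficiency$grand_mean))
  if (!is.null(x$fp_rate))
    cat(sprintf("  false-positive rate (absent sites): %.1f%%\n", 100 * x$fp_rate))
  invisible(x)
}

#' Two-color coincidence analysis of paired call sets
#'
#' Tallies the joint detection categories of the two channels and derives the
#' incorporation estimate under channel independence.
#'
#' @param detected3,detected5 per-instance logical detection calls (see
#'   [coincidence_tally()]).
#' @return list with `tally` (`two_color_tally`) and `estimate`
#'   (`incorporation_estimate`).
#' @export
run_two_color <- function(detected3, detected5) {
  tally <- coincidence_tally(detected3, detected5)
  list(tally = tally, estimate = independence_estimate(tally))
}
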