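#' Two-color coincidence tally
#'
#' For docking sites probed simultaneously through orthogonal 3'- and 5'-end
#' extensions imaged in two colors, tallies every site instance into the four
#' joint categories: detected in both channels, only the 3' channel, only the
#' 5' channel, or neither.
#'
#' @param detected3,detected5 logical vectors or matrices (structures x sites)
#'   of per-instance detection calls for the 3'-end and 5'-end channels; must
#'   cover the same instances (equal dimensions and dimnames).
#' @return A `two_color_tally`: list with fractions `f_both`, `f_only3`,
#'   `f_only5`, `f_none` (summing to 1) and `n_sites`.
#' @export
coincidence_tally <- function(detected3, detected5) {
  if (!identical(dim(detected3), dim(detected5)) ||
      length(detected3) != length(detected5) ||
      !identical(dimnames(detected3), dimnames(detected5)))
    stop("the two channels must cover the same structures and sites")
  d3 <- as.logical(detected3); d5 <- as.logical(detected5)
  if (anyNA(d3) || anyNA(d5)) stop("detection calls must not contain NA")
  n <- length(d3)
  if (n == 0L) stop("empty call matrices")
  two_color_tally(sum(d3 & d5) / n, sum(d3 & !d5) / n,
                  sum(!d3 & d5) / n, sum(!d3 & !d5) / n, n)
}

#' @rdname coincidence_tally
#' @param f_both,f_only3,f_only5,f_none category fractions.
#' @param n_sites number of site instances behind the fractions.
#' @export
two_color_tally <- function(f_both, f_only3, f_only5, f_none, n_sites = NA_integer_) {
  f <- c(f_both, f_only3, f_only5, f_none)
  stopifnot(all(f >= 0))
  if (abs(sum(f) - 1) > 1e-9) stop("tally fractions must sum to 1")
  structure(list(f_both = f_both, f_only3 = f_only3, f_only5 = f_only5,
                 f_none = f_none, n_sites = n_sites),
            class = "two_color_tally")
}

#' @export
print.two_color_tally <- function(x, ...) {
  cat(sprintf("<two_color_tally: both %.1f%%, only-3' %.1f%%, only-5' %.1f%%, none %.1f%% (n=%s)>\n",
              100 * x$f_both, 100 * x$f_only3, 100 * x$f_only5, 100 * x$f_none,
              format(x$n_sites)))
  invisible(x)
}

#' Decouple incorporation from accessibility under channel independence
#'
#' Detection of the 3'- and 5'-end docking sites of one staple are independent
#' given that the staple is incorporated. The total miss fractions per channel
#' are `miss3 = f_only5 + f_none` and `miss5 = f_only3 + f_none`; their
#' product `chance_none = miss3 * miss5` estimates the probability that
#' neither end of an actually incorporated staple is detected. When
#' `chance_none` is much smaller than `f_none`, the no-signal category is
#' attributed to staples that were never incorporated, so
#' `incorporated = 1 - f_none`. The offset `incorporated - det3` (with
#' `det3 = f_both + f_only3`) translates a 3'-end detection efficiency into an
#' absolute incorporation efficiency.
#'
#' @param tally a `two_color_tally`.
#' @return An `incorporation_estimate`: list with `miss3`, `miss5`,
#'   `chance_none`, `incorporated`, `det3`, `det5` and `offset`.
#' @export
independence_estimate <- function(tally) {
  stopifnot(inherits(tally, "two_color_tally"))
  miss3 <- tally$f_only5 + tally$f_none
  miss5 <- tally$f_only3 + tally$f_none
  structure(list(miss3 = miss3, miss5 = miss5,
                 chance_none = miss3 * miss5,
                 incorporated = 1 - tally$f_none,
                 det3 = tally$f_both + tally$f_only3,
                 det5 = tally$f_both + tally$f_only5,
                 offset = (1 - tally$f_none) - (tally$f_both + tally$f_only3)),
            class = "incorporation_estimate")
}

#' @export
print.incorporation_estimate <- function(x, ...) {
  cat(sprintf(paste0("<incorporation_estimate: incorporated %.1f%%, ",
                     "chance-none %.2f%%, 3' offset +%.1f%%>\n"),
              100 * x$incorporated, 100 * x$chance_none, 100 * x$offset))
  invisible(x)
}

#' Translate detection efficiency into incorporation efficiency
#'
#' Adds the two-color-derived offset to a measured detection (accessibility)
#' efficiency and clamps to `[0, 1]`. The default offset of 0.07 is the
#' experimentally determined value for 3'-end docking sites; supply the
#' `offset` field of an [independence_estimate()] when two-color data are
#' available.
#'
#' @param efficiency detection efficiency in `[0, 1]` (vectorized).
#' @param offset additive offset in `[0, 1]`.
#' @export
detection_to_incorporation <- function(efficiency, offset = 0.07) {
  stopifnot(all(efficiency >= 0 & efficiency <= 1), offset >= 0, offset <= 1)
  pmin(1, pmax(0, efficiency + offset))
}

#' Michaelis-Menten fit of detection efficiency versus staple excess
#'
#' Least-squares fit of `E(x) = vmax * x / (km + x)` to detection efficiencies
#' measured at different molar excesses of the docking staple over the
#' scaffold. Unweighted raw pairs.
#'
#' @param excess molar excess values (> 0, at least 3 points).
#' @param efficiency detection efficiencies (same length; any consistent
#'   units, e.g. percent).
#' @return An `mm_fit`: list with `vmax` (saturation), `km`, `residuals` and
#'   `degenerate` (TRUE when the fit collapsed to a constant, km ~ 0).
#' @export
fit_michaelis_menten <- function(excess, efficiency) {
  if (length(excess) != length(efficiency))
    stop("excess and efficiency must have the same length")
  if (length(excess) < 3L) stop("need at least 3 points to fit vmax and km")
  stopifnot(all(excess > 0))
  df <- data.frame(x = excess, y = efficiency)
  if (stats::sd(df$y) < 1e-12 * max(abs(df$y), 1)) {
    # constant efficiencies: the km -> 0 limit, flagged rather than fitted
    return(structure(list(vmax = mean(df$y), km = 0,
                          residuals = df$y - mean(df$y), degenerate = TRUE),
                     class = "mm_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ vmax * x / (km + x), data = df,
                      start = list(vmax = max(df$y),
                                   km = max(stats::median(df$x) / 4, 1e-6)),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  structure(list(vmax = unname(p["vmax"]), km = unname(p["km"]),
                 residuals = unname(stats::resid(fit)),
                 degenerate = unname(p["km"]) < 1e-6 * max(df$x)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit: vmax %.4g, km %.4g%s>\n", x$vmax, x$km,
              if (x$degenerate) " (degenerate: km ~ 0)" else ""))
  invisible(x)
}

#' Assemble per-staple efficiencies into the rectangle heatmap
#'
#' Merges per-variant site efficiencies into one map keyed by staple label on
#' the rectangle layout. Labels probed in several variants are averaged
#' weighted by the number of structures behind each estimate. Layout positions
#' not probed by any variant (e.g. biotin-adjacent staples excluded from the
#' designs) carry `NA` and are flagged excluded.
#'
#' @param per_variant named list (by variant) of data frames with columns
#'   `label`, `value` (efficiency in `[0, 1]`) and `n` (structure count).
#' @param layout data frame mapping `label` to `row`/`col` (e.g. the `layout`
#'   attribute of [build_variant_library()]).
#' @return A data frame `label`, `row`, `col`, `value`, `n`, `excluded`.
#' @export
build_heatmap <- function(per_variant, layout) {
  all <- do.call(rbind, lapply(names(per_variant), function(v) {
    df <- per_variant[[v]]
    stopifnot(all(c("label", "value", "n") %in% names(df)))
    if (any(df$value < 0 | df$value > 1, na.rm = TRUE))
      stop("efficiencies must lie in [0, 1]")
    unknown <- setdiff(df$label, layout$label)
    if (length(unknown))
      stop("variant ", v, " probes labels absent from the layout: ",
           paste(unknown, collapse = ", "))
    df
  }))
  agg <- lapply(split(all, all$label), function(d)
    c(value = sum(d$value * d$n) / sum(d$n), n = sum(d$n)))
  m <- do.call(rbind, agg)
  out <- layout[, c("label", "row", "col")]
  i <- match(out$label, rownames(m))
  out$value <- ifelse(is.na(i), NA_real_, m[ifelse(is.na(i), 1L, i), "value"])
  out$n <- ifelse(is.na(i), 0L, m[ifelse(is.na(i), 1L, i), "n"])
  out$excluded <- is.na(i)
  rownames(out) <- NULL
  out
}

#' Simulate a two-color detection experiment
#'
#' Generative model behind the coincidence analysis: each of `n_sites` staple
#' instances is incorporated with probability `incorporation`; given
#' incorporation, the 3'- and 5'-end docking sites are missed independently
#' with probabilities `miss3` and `miss5`; a staple that is not incorporated
#' is never detected in either channel.
#'
#' @param n_sites number of site instances.
#' @param incorporation probability a staple is physically incorporated.
#' @param miss3,miss5 per-channel miss probabilities given incorporation.
#' @param seed RNG seed.
#' @return list of logical vectors `detected3`, `detected5`.
#' @export
simulate_two_color <- function(n_sites, incorporation, miss3, miss5, seed = 1L) {
  stopifnot(n_sites > 0, incorporation >= 0, incorporation <= 1,
            miss3 >= 0, miss3 <= 1, miss5 >= 0, miss5 <= 1)
  set.seed(seed)
  inc <- stats::runif(n_sites) < incorporation
  list(detected3 = inc & stats::runif(n_sites) >= miss3,
       detected5 = inc & stats::runif(n_sites) >= miss5)
}
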