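#' Site patterns: designed docking-site geometries of DNA origami structures
#'
#' A `site_pattern` describes one origami design as a set of 2D site
#' coordinates (nm, design frame, y up) together with the role of every site:
#'
#' * `probed`    -- the site carries a docking strand in this variant and is
#'                  scored for detection;
#' * `absent`    -- the position exists in the design family but carries no
#'                  docking strand in this variant (scored for false positives);
#' * `alignment` -- part of the always-present arrowhead + line pattern used
#'                  for orientation and template assignment, never scored.
#'
#' @param sites numeric matrix with columns `x`, `y` (nm).
#' @param labels character vector of unique site identifiers.
#' @param probed logical vector: does the site carry a docking strand?
#' @param alignment logical vector: is the site part of the alignment pattern?
#' @param name variant identifier.
#' @return An object of class `site_pattern`.
#' @export
site_pattern <- function(sites, labels, probed, alignment, name = "pattern") {
  sites <- as.matrix(sites)
  if (ncol(sites) != 2L) stop("`sites` must have two columns (x, y)")
  storage.mode(sites) <- "double"
  colnames(sites) <- c("x", "y")
  n <- nrow(sites)
  if (n == 0L) stop("pattern must contain at least one site")
  if (!all(is.finite(sites))) stop("all site positions must be finite")
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("`labels` must be unique and match the number of sites")
  probed <- rep_len(as.logical(probed), n)
  alignment <- rep_len(as.logical(alignment), n)
  if (any(probed & alignment))
    stop("alignment sites are never scored as detection sites")
  rownames(sites) <- labels
  structure(
    list(sites = sites, labels = labels, probed = probed,
         alignment = alignment, name = name),
    class = "site_pattern")
}

#' @export
print.site_pattern <- function(x, ...) {
  cat(sprintf("<site_pattern '%s': %d sites (%d probed, %d absent, %d alignment)>\n",
              x$name, nrow(x$sites), sum(x$probed),
              sum(!x$probed & !x$alignment), sum(x$alignment)))
  invisible(x)
}

#' Site roles of a pattern
#'
#' @param pattern a [site_pattern()].
#' @return character vector `"probed"`, `"absent"` or `"alignment"` per site.
#' @export
site_roles <- function(pattern) {
  ifelse(pattern$alignment, "alignment", ifelse(pattern$probed, "probed", "absent"))
}

#' Minimum pairwise distance between sites (nm)
#'
#' @param pattern a [site_pattern()].
#' @param roles optional subset of site roles to consider.
#' @export
min_site_spacing <- function(pattern, roles = NULL) {
  keep <- if (is.null(roles)) rep(TRUE, nrow(pattern$sites)) else site_roles(pattern) %in% roles
  s <- pattern$sites[keep, , drop = FALSE]
  if (nrow(s) < 2L) return(Inf)
  min(stats::dist(s))
}

# Shared arrowhead + line alignment fixture (nm, design frame). A five-site
# chevron pointing along -x plus a four-site row below the structure: the
# combination has neither rotational nor mirror symmetry, which is what makes
# orientation recovery and template assignment unambiguous. Placed outside the
# staple lattice of the rectangle so that 6-nm counting discs never overlap.
alignment_fixture <- function() {
  arrow <- cbind(x = c(-68, -60, -60, -52, -52), y = c(0, 8, -8, 16, -16))
  line  <- cbind(x = c(-10, 2, 14, 26),          y = rep(-36, 4))
  list(sites = rbind(arrow, line),
       labels = c(paste0("arrow_", 1:5), paste0("line_", 1:4)))
}

recenter <- function(sites, center = colMeans(sites)) {
  sweep(sites, 2, center)
}

#' The 20-nm grid: 12 docking sites on a 4 x 3 lattice with 20 nm pitch
#'
#' The standard benchmark structure: a 2D rectangular origami displaying 12
#' docking sites arranged in 4 rows and 3 columns, 20 nm apart, all probed,
#' with no separate alignment pattern (the grid itself is used for alignment).
#'
#' @return A [site_pattern()] with 12 probed sites, centroid at the origin.
#' @export
build_grid_20nm <- function() {
  g <- expand.grid(x = c(-20, 0, 20), y = c(-30, -10, 10, 30))
  site_pattern(as.matrix(g), labels = sprintf("grid_%02d", seq_len(12)),
               probed = TRUE, alignment = FALSE, name = "grid20")
}

#' The 3 BS / 6 BS design pair for false-positive scoring
#'
#' Two structures sharing identical site positions and the arrowhead + line
#' alignment pattern. The 6 BS variant probes docking sites 1-6; the 3 BS
#' variant probes only sites 1-3 and retains sites 4-6 as absent-by-design
#' positions, so that any localization signal called "detected" there is a
#' false positive.
#'
#' @return A list with elements `bs3` and `bs6`, both [site_pattern()]s
#'   expressed in a common frame (shared alignment sites are bit-identical).
#' @export
build_bs_pair <- function() {
  al <- alignment_fixture()
  bs <- cbind(x = rep(c(6, 26), each = 3), y = rep(c(28, 12, -4), 2))
  sites <- rbind(al$sites, bs)
  labels <- c(al$labels, sprintf("bs_%d", 1:6))
  ctr <- colMeans(sites)            # one shared frame for both variants
  sites <- recenter(sites, ctr)
  n_al <- nrow(al$sites)
  is_al <- c(rep(TRUE, n_al), rep(FALSE, 6))
  bs6 <- site_pattern(sites, labels, probed = !is_al, alignment = is_al, name = "bs6")
  probed3 <- !is_al & labels %in% sprintf("bs_%d", 1:3)
  bs3 <- site_pattern(sites, labels, probed = probed3, alignment = is_al, name = "bs3")
  list(bs3 = bs3, bs6 = bs6)
}

#' Default 18-variant configuration for the rectangle staple library
#'
#' Generates the default probing plan: staple positions on a 14 x 12 lattice
#' (7 nm x 5 nm pitch; 168 labels), each variant probing 12 positions laid out
#' along a wrapped diagonal so that within-variant spacing stays above the 6-nm
#' counting disc. Variants 1-14 follow a slope-1 diagonal and together cover
#' every position exactly once; variants 15-18 follow a slope-5 diagonal and
#' re-probe 48 of the positions, giving cross-variant consistency checks.
#'
#' @return A list with one element per variant: `name` and `labels` (the 12
#'   probed staple labels), plus attribute `layout`, a data frame mapping each
#'   of the 168 labels to lattice row/column and nm coordinates.
#' @export
default_variant_config <- function() {
  n_row <- 12L; n_col <- 14L
  rows <- rep(seq_len(n_row) - 1L, times = n_col)
  cols <- rep(seq_len(n_col) - 1L, each = n_row)
  layout <- data.frame(
    label = sprintf("staple_r%02d_c%02d", rows, cols),
    row = rows, col = cols,
    x = (cols - (n_col - 1) / 2) * 7,
    y = (rows - (n_row - 1) / 2) * 5,
    stringsAsFactors = FALSE)
  slot <- function(slope, shift) {
    r <- seq_len(n_row) - 1L
    c <- (slope * r + shift) %% n_col
    sprintf("staple_r%02d_c%02d", r, c)
  }
  cfg <- c(
    lapply(0:13, function(b) list(name = sprintf("variant_%02d", b + 1L),
                                  labels = slot(1L, b))),
    lapply(c(0L, 3L, 6L, 9L), function(b) list(name = sprintf("variant_%02d", 15L + b %/% 3L),
                                               labels = slot(5L, b))))
  attr(cfg, "layout") <- layout
  cfg
}

#' Build the library of origami design variants
#'
#' Each variant consists of the shared arrowhead + line alignment pattern plus
#' the probed staple positions named in `config`. All variants are expressed in
#' one common design frame (centroid of alignment pattern + full staple lattice
#' at the origin) so that alignment sites are identical across variants and a
#' structure can be classified by template cross-correlation.
#'
#' @param config a list as returned by [default_variant_config()]: per variant
#'   a `name` and the probed staple `labels`; must carry a `layout` attribute
#'   mapping labels to coordinates.
#' @return Named list of [site_pattern()]s, with the `layout` data frame
#'   attached as an attribute.
#' @export
build_variant_library <- function(config = default_variant_config()) {
  layout <- attr(config, "layout")
  if (is.null(layout)) stop("`config` must carry a `layout` attribute")
  nms <- vapply(config, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate variant names in config")
  sets <- lapply(config, function(v) sort(v$labels))
  if (anyDuplicated(vapply(sets, paste, "", collapse = ",")))
    stop("two variants probe identical site sets and cannot be distinguished")
  al <- alignment_fixture()
  full <- rbind(al$sites, as.matrix(layout[, c("x", "y")]))
  ctr <- colMeans(full)
  al_sites <- recenter(al$sites, ctr)
  lay_xy <- recenter(as.matrix(layout[, c("x", "y")]), ctr)
  rownames(lay_xy) <- layout$label
  lib <- lapply(config, function(v) {
    miss <- setdiff(v$labels, layout$label)
    if (length(miss)) stop("unknown staple labels: ", paste(miss, collapse = ", "))
    sites <- rbind(al_sites, lay_xy[v$labels, , drop = FALSE])
    site_pattern(sites,
                 labels = c(al$labels, v$labels),
                 probed = c(rep(FALSE, nrow(al_sites)), rep(TRUE, length(v$labels))),
                 alignment = c(rep(TRUE, nrow(al_sites)), rep(FALSE, length(v$labels))),
                 name = v$name)
  })
  names(lib) <- nms
  attr(lib, "layout") <- layout
  lib
}

#' Template rendering specification
#'
#' @param render_sigma Gaussian spot width (nm) used when rendering designed
#'   site positions to a template image. The per-analysis presets use
#'   3 nm (20-nm grid), 2 nm (staple-excess series) and 1 nm (single-site
#'   measurements).
#' @param bin_size nm per rendered pixel.
#' @param extent image side length in nm; `NULL` (default) sizes the image
#'   automatically to cover all sites plus a 3-sigma + padding margin, rounded
#'   up to an FFT-friendly bin count.
#' @param pad extra margin (nm) beyond the 3-sigma rule, to leave room for the
#'   translation search during alignment.
#' @export
template_spec <- function(render_sigma = 3, bin_size = 1, extent = NULL, pad = 16) {
  stopifnot(render_sigma > 0, bin_size > 0, pad >= 0)
  structure(list(render_sigma = render_sigma, bin_size = bin_size,
                 extent = extent, pad = pad), class = "template_spec")
}

template_n_bins <- function(pattern, spec) {
  r <- max(abs(pattern$sites))
  need <- 2 * (r + 3 * spec$render_sigma + spec$pad)
  if (!is.null(spec$extent)) {
    if (spec$extent < 2 * (r + 3 * spec$render_sigma))
      stop("extent too small: sites plus 3*render_sigma margin do not fit")
    need <- spec$extent
  }
  stats::nextn(ceiling(need / spec$bin_size), c(2, 3, 5))
}

#' Render a site pattern to a template image
#'
#' Places a unit-amplitude isotropic Gaussian (sd `render_sigma`) at every
#' probed and alignment site (absent-by-design sites are not rendered) and
#' samples the sum on a square pixel grid. The template encodes the design
#' geometry, not binding kinetics, hence equal amplitudes.
#'
#' @param pattern a [site_pattern()].
#' @param spec a [template_spec()].
#' @return A `template_image`: list with `pixels` (matrix indexed `[ix, iy]`,
#'   x rightward, y upward), `bin_size` (nm), `centers_x`/`centers_y` (nm
#'   coordinates of pixel centers) and `name`.
#' @export
render_template <- function(pattern, spec = template_spec()) {
  n <- template_n_bins(pattern, spec)
  ctr <- ((seq_len(n)) - (n + 1) / 2) * spec$bin_size
  keep <- pattern$probed | pattern$alignment
  sites <- pattern$sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) stop("pattern has no probed or alignment sites to render")
  px <- matrix(0, n, n)
  s2 <- 2 * spec$render_sigma^2
  for (k in seq_len(nrow(sites))) {
    gx <- exp(-(ctr - sites[k, 1])^2 / s2)
    gy <- exp(-(ctr - sites[k, 2])^2 / s2)
    px <- px + outer(gx, gy)
  }
  structure(list(pixels = px, bin_size = spec$bin_size,
                 centers_x = ctr, centers_y = ctr,
                 render_sigma = spec$render_sigma, name = pattern$name),
            class = "template_image")
}

#' @export
print.template_image <- function(x, ...) {
  cat(sprintf("<template_image '%s': %d x %d px, %.2g nm/px, sigma %.2g nm>\n",
              x$name, nrow(x$pixels), ncol(x$pixels), x$bin_size, x$render_sigma))
  invisible(x)
}

#' Read / write design specifications as YAML
#'
#' The on-disk design format stores, per variant, the site list in nm with the
#' probed and alignment flags, so designs can be exchanged and inspected.
#'
#' @param patterns a [site_pattern()] or list of them.
#' @param path file path.
#' @export
write_design_yaml <- function(patterns, path) {
  if (inherits(patterns, "site_pattern")) patterns <- list(patterns)
  doc <- lapply(patterns, function(p) list(
    name = p$name,
    sites = lapply(seq_len(nrow(p$sites)), function(i) list(
      label = p$labels[i], x = p$sites[i, 1], y = p$sites[i, 2],
      probed = p$probed[i], alignment = p$alignment[i]))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @return `read_design_yaml()` returns a named list of [site_pattern()]s.
#' @export
read_design_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(d) {
    s <- do.call(rbind, lapply(d$sites, function(x) c(x$x, x$y)))
    site_pattern(s,
                 labels = vapply(d$sites, `[[`, "", "label"),
                 probed = vapply(d$sites, `[[`, TRUE, "probed"),
                 alignment = vapply(d$sites, `[[`, TRUE, "alignment"),
                 name = d$name)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
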