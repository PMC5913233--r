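#' Localization tables
#'
#' The interchange unit of the pipeline: one row per localization with the
#' Picasso-style fields `frame` (0-based), `x`, `y` (camera pixels, origin
#' top-left, y downward), `photons`, `lpx`, `lpy` (localization precision in
#' pixels), plus camera metadata carried as attributes (`pixel_size_nm`,
#' `n_frames`, `width`, `height`). All downstream analysis works in nm with
#' the y axis pointing up; [extract_structure()] is the single place where the
#' conversion happens.
#'
#' @param df data frame with the required record fields.
#' @param pixel_size_nm camera pixel size (nm).
#' @param n_frames number of frames in the acquisition.
#' @param width,height camera image size (pixels).
#' @return A `loc_table` (data frame subclass).
#' @export
loc_table <- function(df, pixel_size_nm, n_frames, width, height) {
  req <- c("frame", "x", "y", "photons", "lpx", "lpy")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required localization fields: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    stopifnot(all(df$frame >= 0), all(df$frame < n_frames), all(df$photons > 0))
  }
  out <- as.data.frame(df)[req]
  attr(out, "pixel_size_nm") <- pixel_size_nm
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "width") <- as.integer(width)
  attr(out, "height") <- as.integer(height)
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Metadata of a localization table
#' @param table a [loc_table()].
#' @export
loc_meta <- function(table) {
  list(pixel_size_nm = attr(table, "pixel_size_nm"),
       n_frames = attr(table, "n_frames"),
       width = attr(table, "width"), height = attr(table, "height"))
}

#' Read and write localization tables
#'
#' Tables are stored as a CSV file with the Picasso field names plus a YAML
#' metadata sidecar (`<path>.yaml`) holding the camera metadata, so that a
#' write/read round trip is lossless including metadata. Floats are written
#' with 17 significant digits, which round-trips IEEE doubles exactly.
#'
#' @param table a [loc_table()].
#' @param path CSV file path.
#' @export
write_locs <- function(table, path) {
  meta <- loc_meta(table)
  df <- as.data.frame(table)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_locs
#' @export
read_locs <- function(path) {
  df <- utils::read.csv(path)
  req <- c("frame", "x", "y", "photons", "lpx", "lpy")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("localization file ", path,
                         " is missing required column(s): ",
                         paste(miss, collapse = ", "))
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  loc_table(df, pixel_size_nm = meta$pixel_size_nm, n_frames = meta$n_frames,
            width = meta$width, height = meta$height)
}

#' Automatically pick individual structures from a field of view
#'
#' Density-based grouping that replaces interactive structure selection:
#' localizations are binned into square cells of side `expected_radius_nm`,
#' occupied cells are merged into connected components (8-neighborhood), and
#' each component becomes one candidate pick. Candidates with fewer than
#' `min_locs` localizations, or whose spatial extent (max distance from the
#' centroid) exceeds `expected_radius_nm` (e.g. two merged structures), are
#' dropped. Deterministic.
#'
#' @param table a [loc_table()].
#' @param expected_radius_nm expected structure radius (nm); also the
#'   clustering cell size and the pick radius.
#' @param min_locs minimum localizations per structure.
#' @return data frame of pick regions: `id`, `x_px`, `y_px` (center),
#'   `radius_px`, `n_locs`.
#' @export
pick_structures <- function(table, expected_radius_nm, min_locs = 50) {
  empty <- data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      radius_px = numeric(0), n_locs = integer(0))
  if (nrow(table) == 0L) return(empty)
  px <- attr(table, "pixel_size_nm")
  x <- table$x * px; y <- table$y * px
  cell <- expected_radius_nm
  cx <- floor(x / cell); cy <- floor(y / cell)
  span <- max(cx) - min(cx) + 3
  key <- (cx - min(cx)) + (cy - min(cy)) * span
  cells <- sort(unique(key))
  comp <- union_find_components(cells, span)
  loc_comp <- comp[match(key, cells)]
  out <- lapply(split(seq_along(x), loc_comp), function(idx) {
    mx <- mean(x[idx]); my <- mean(y[idx])
    ext <- sqrt(max((x[idx] - mx)^2 + (y[idx] - my)^2))
    c(mx, my, ext, length(idx))
  })
  m <- do.call(rbind, out)
  keep <- m[, 4] >= min_locs & m[, 3] <= expected_radius_nm
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(id = seq_len(nrow(m)), x_px = m[, 1] / px, y_px = m[, 2] / px,
             radius_px = expected_radius_nm / px, n_locs = as.integer(m[, 4]))
}

# connected components over occupied grid cells (keys on a row-major grid of
# width `span`), 8-neighborhood; plain union-find with path halving
union_find_components <- function(cells, span) {
  n <- length(cells)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (off in c(1, span - 1, span, span + 1)) {
    j <- match(cells + off, cells)
    for (i in which(!is.na(j))) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Extract the localizations of one picked structure
#'
#' Subsets the table to localizations within the pick radius and converts
#' coordinates to nm relative to the pick center, flipping the y axis so that
#' analysis coordinates point up.
#'
#' @param table a [loc_table()].
#' @param region one row of the data frame returned by [pick_structures()]
#'   (or any list with `x_px`, `y_px`, `radius_px`, `id`).
#' @return A `structure_locs`: data frame with `x`, `y` (nm, y up), `frame`,
#'   `photons`, `sd_nm`; attributes `id`, `center_px`, `pixel_size_nm`.
#' @export
extract_structure <- function(table, region) {
  px <- attr(table, "pixel_size_nm")
  dx <- (table$x - region$x_px) * px
  dy <- (table$y - region$y_px) * px
  keep <- dx^2 + dy^2 <= (region$radius_px * px)^2
  out <- data.frame(x = dx[keep], y = -dy[keep], frame = table$frame[keep],
                    photons = table$photons[keep], sd_nm = table$lpx[keep] * px)
  rownames(out) <- NULL
  attr(out, "id") <- region$id
  attr(out, "center_px") <- c(region$x_px, region$y_px)
  attr(out, "pixel_size_nm") <- px
  class(out) <- c("structure_locs", "data.frame")
  out
}
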