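test_that("20-nm grid has 12 sites on a centered 20-nm lattice", {
  g <- build_grid_20nm()
  expect_equal(nrow(g$sites), 12)
  expect_true(all(g$probed))
  expect_equal(colMeans(g$sites), c(x = 0, y = 0))
  # nearest-neighbor distance of every site is the 20 nm pitch
  d <- as.matrix(dist(g$sites))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(20, 12))
})

test_that("3 BS / 6 BS pair shares geometry and differs only in probing", {
  pair <- build_bs_pair()
  expect_equal(sum(pair$bs3$probed), 3)
  expect_equal(sum(pair$bs6$probed), 6)
  # identical alignment sites and site positions
  expect_identical(pair$bs3$sites[pair$bs3$alignment, ],
                   pair$bs6$sites[pair$bs6$alignment, ])
  expect_identical(pair$bs3$sites, pair$bs6$sites)
  # absent sites of 3 BS = probed in 6 BS minus probed in 3 BS
  absent3 <- pair$bs3$labels[!pair$bs3$probed & !pair$bs3$alignment]
  expect_setequal(absent3,
                  setdiff(pair$bs6$labels[pair$bs6$probed],
                          pair$bs3$labels[pair$bs3$probed]))
  # shared frame is centered
  expect_equal(colMeans(pair$bs6$sites), c(x = 0, y = 0))
})

test_that("variant library: 18 designs covering 168 staples, identifiable", {
  lib <- build_variant_library()
  expect_length(lib, 18)
  probed_labels <- lapply(lib, function(p) p$labels[p$probed])
  expect_true(all(lengths(probed_labels) == 12))
  expect_equal(length(unique(unlist(probed_labels))), 168)
  # shared alignment pattern, bit-identical across variants
  al1 <- lib[[1]]$sites[lib[[1]]$alignment, ]
  for (p in lib) expect_identical(p$sites[p$alignment, ], al1)
  # within-variant spacing supports the 6-nm counting disc
  expect_true(all(vapply(lib, min_site_spacing, 0) > 6))
})

test_that("variant configs with duplicate names or probed sets are rejected", {
  cfg <- default_variant_config()
  bad <- cfg; bad[[2]]$name <- bad[[1]]$name
  attr(bad, "layout") <- attr(cfg, "layout")
  expect_error(build_variant_library(bad), "duplicate")
  bad2 <- cfg; bad2[[2]]$labels <- bad2[[1]]$labels
  attr(bad2, "layout") <- attr(cfg, "layout")
  expect_error(build_variant_library(bad2), "identical")
  # a toy config with disjoint probed sets is accepted
  toy <- list(list(name = "a", labels = cfg[[1]]$labels),
              list(name = "b", labels = cfg[[2]]$labels))
  attr(toy, "layout") <- attr(cfg, "layout")
  expect_length(build_variant_library(toy), 2)
})

test_that("template rendering places Gaussians at sites", {
  p1 <- site_pattern(cbind(0, 0), "s", TRUE, FALSE)
  img <- render_template(p1, template_spec(render_sigma = 3, bin_size = 1))
  i <- arrayInd(which.max(img$pixels), dim(img$pixels))
  expect_lt(abs(img$centers_x[i[1]]), 1)
  expect_lt(abs(img$centers_y[i[2]]), 1)
  # integral proportional to the number of rendered sites (within 1%)
  g <- build_grid_20nm()
  img12 <- render_template(g, template_spec(render_sigma = 2, bin_size = 1))
  expect_equal(sum(img12$pixels) / sum(img$pixels) * (3 / 2)^2, 12,
               tolerance = 0.01)
})

test_that("rendered 20-nm grid shows 12 local maxima at lattice positions", {
  g <- build_grid_20nm()
  img <- render_template(g, template_spec(render_sigma = 2, bin_size = 1))
  px <- img$pixels
  n <- nrow(px)
  inner <- 2:(n - 1)
  is_max <- matrix(FALSE, n, n)
  is_max[inner, inner] <-
    px[inner, inner] > 1e-3 &
    px[inner, inner] >= px[inner - 1, inner] & px[inner, inner] >= px[inner + 1, inner] &
    px[inner, inner] >= px[inner, inner - 1] & px[inner, inner] >= px[inner, inner + 1]
  peaks <- which(is_max, arr.ind = TRUE)
  xy <- cbind(img$centers_x[peaks[, 1]], img$centers_y[peaks[, 2]])
  # sites fall between bin centers, so each peak is a small plateau; cluster
  # plateau bins and compare cluster centroids
  cl <- cutree(hclust(dist(xy), method = "single"), h = 5)
  expect_equal(max(cl), 12)
  cxy <- do.call(rbind, lapply(split(seq_len(nrow(xy)), cl),
                               function(i) colMeans(xy[i, , drop = FALSE])))
  d <- as.matrix(dist(cxy)); diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(20, 12), tolerance = 0.06)
})

test_that("rendering is translation-equivariant up to one bin", {
  p <- site_pattern(cbind(c(-10, 8), c(4, -6)), c("a", "b"), TRUE, FALSE)
  spec <- template_spec(render_sigma = 2, bin_size = 1, extent = 64)
  base <- render_template(p, spec)
  shifted <- site_pattern(p$sites + matrix(c(5, 5, 0, 0), 2), p$labels,
                          TRUE, FALSE)
  img <- render_template(shifted, spec)
  n <- nrow(base$pixels)
  expect_equal(img$pixels[6:n, ], base$pixels[1:(n - 5), ], tolerance = 1e-12)
})

test_that("ideal site sets score highest against their own variant template", {
  lib <- build_variant_library()[c(1, 2, 7, 15)]
  tmpls <- lapply(lib, render_template,
                  spec = template_spec(render_sigma = 1, bin_size = 2))
  for (v in seq_along(lib)) {
    cl <- classify_template(ideal_locs(lib[[v]]), tmpls, step_deg = 10)
    expect_identical(cl$template, names(lib)[v])
    own <- cl$scores[names(lib)[v]]
    expect_gt(own, max(cl$scores[-match(names(lib)[v], names(cl$scores))]))
  }
})

test_that("design YAML round-trips patterns", {
  pair <- build_bs_pair()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_design_yaml(pair, f)
  back <- read_design_yaml(f)
  expect_equal(back$bs3$sites, pair$bs3$sites)
  expect_identical(back$bs6$probed, pair$bs6$probed)
  expect_identical(back$bs3$labels, pair$bs3$labels)
})

test_that("degenerate patterns are rejected", {
  expect_error(site_pattern(cbind(c(0, NA), c(0, 1)), c("a", "b"), TRUE, FALSE),
               "finite")
  expect_error(site_pattern(cbind(c(0, 1), c(0, 1)), c("a", "a"), TRUE, FALSE),
               "unique")
  expect_error(site_pattern(cbind(0, 0), "a", TRUE, TRUE), "never scored")
})
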