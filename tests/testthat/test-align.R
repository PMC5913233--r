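test_that("structure rendering conserves counts and localizes mass", {
  locs <- data.frame(x = rep(0, 100), y = rep(0, 100), frame = 0L,
                     photons = 1000, sd_nm = 1)
  class(locs) <- c("structure_locs", "data.frame")
  h <- render_structure(locs, bin_size = 1, extent = 32)
  expect_equal(sum(h), 100)
  expect_equal(sum(h > 0), 1)            # all mass in a single bin
  hb <- render_structure(locs, bin_size = 1, extent = 32, blur_sigma = 2)
  expect_gt(sum(hb > 1e-6), 1)
  expect_error(render_structure(locs[0, ], 1), "empty")
})

test_that("self-alignment is optimal with identity transform", {
  pair <- build_bs_pair()
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  al <- align_to_template(ideal_locs(pair$bs6), tmpl, step_deg = 2)
  expect_equal(al$angle, 0)
  expect_equal(al$shift, c(0, 0))
  expect_false(al$mirror)
  # no tested transform beats the identity on the own template
  rot <- align_to_template(rotate_locs(ideal_locs(pair$bs6), 90), tmpl,
                           step_deg = 2)
  expect_lte(abs(rot$correlation - al$correlation), 1e-9)
})

test_that("a known rotation is recovered as its inverse", {
  pair <- build_bs_pair()
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  moved <- rotate_locs(ideal_locs(pair$bs6), 37, shift = c(6, -4))
  al <- align_to_template(moved, tmpl, step_deg = 1)
  expect_lte(min(abs(al$angle - 323), abs(al$angle - 323 + 360)), 1.5)
  back <- transform_locs(moved, al)
  keep <- pair$bs6$probed | pair$bs6$alignment
  # residual = rotation-step + 1-bin shift quantization
  expect_lt(max(abs(back$x - rep(pair$bs6$sites[keep, 1], each = 20))), 2.5)
  expect_lt(max(abs(back$y - rep(pair$bs6$sites[keep, 2], each = 20))), 2.5)
})

test_that("mirrored structures are found only when the mirror search is on", {
  pair <- build_bs_pair()
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  mirrored <- rotate_locs(ideal_locs(pair$bs6), 20, mirror = TRUE)
  with_m <- align_to_template(mirrored, tmpl, step_deg = 2, try_mirror = TRUE)
  no_m <- align_to_template(mirrored, tmpl, step_deg = 2, try_mirror = FALSE)
  expect_true(with_m$mirror)
  expect_gt(with_m$correlation, no_m$correlation)
  ref <- align_to_template(ideal_locs(pair$bs6), tmpl, step_deg = 2)
  expect_equal(with_m$correlation, ref$correlation, tolerance = 0.05)
})

test_that("identity alignment and inverse transform round-trip", {
  locs <- ideal_locs(build_bs_pair()$bs3)
  ident <- structure(list(angle = 0, shift = c(0, 0), mirror = FALSE,
                          correlation = 1, template = "t"),
                     class = "alignment_result")
  expect_equal(transform_locs(locs, ident)$x, locs$x)
  for (mir in c(FALSE, TRUE)) {
    al <- structure(list(angle = 123, shift = c(5, -8), mirror = mir,
                         correlation = 1, template = "t"),
                    class = "alignment_result")
    fwd <- transform_locs(locs, al)
    back <- transform_locs(fwd, invert_alignment(al))
    expect_equal(back$x, locs$x, tolerance = 1e-12)
    expect_equal(back$y, locs$y, tolerance = 1e-12)
  }
})

test_that("aligned simulated structures land on their design sites", {
  pair <- build_bs_pair()
  sim <- simulate_field(pair$bs6, 3, presence = 1, imaging = fast_imaging(),
                        seed = 31)
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  picks <- pick_structures(sim$table, expected_radius_nm = 98, min_locs = 50)
  expect_gte(nrow(picks), 3)
  locs <- extract_structure(sim$table, picks[1, ])
  al <- align_to_template(locs, tmpl, step_deg = 1)
  aligned <- transform_locs(locs, al)
  # mean position of localizations near each site within 2 nm of the design
  for (k in which(pair$bs6$probed)) {
    s <- pair$bs6$sites[k, ]
    near <- (aligned$x - s[1])^2 + (aligned$y - s[2])^2 < 5^2
    expect_gt(sum(near), 10)
    expect_lt(sqrt((mean(aligned$x[near]) - s[1])^2 +
                   (mean(aligned$y[near]) - s[2])^2), 2)
  }
})

test_that("classification reduces to plain alignment for one template", {
  pair <- build_bs_pair()
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  locs <- rotate_locs(ideal_locs(pair$bs6), 75)
  one <- classify_template(locs, list(bs6 = tmpl), step_deg = 5)
  ref <- align_to_template(locs, tmpl, step_deg = 5)
  expect_equal(one$angle, ref$angle)
  expect_equal(one$correlation, ref$correlation)
  expect_identical(one$template, "bs6")
})

test_that("uniform noise stays unassigned under the default correlation cut", {
  pair <- build_bs_pair()
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  set.seed(33)
  r <- 75 * sqrt(runif(800)); a <- runif(800, 0, 2 * pi)
  noise <- data.frame(x = r * cos(a), y = r * sin(a), frame = 0L,
                      photons = 1000, sd_nm = 1.3)
  class(noise) <- c("structure_locs", "data.frame")
  cl <- classify_template(noise, list(bs6 = tmpl), step_deg = 4)
  expect_true(is.na(cl$template))
  expect_lt(cl$correlation, 0.35)
})

test_that("degenerate inputs raise errors", {
  pair <- build_bs_pair()
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  empty <- ideal_locs(pair$bs6)[0, ]
  class(empty) <- c("structure_locs", "data.frame")
  expect_error(align_to_template(empty, tmpl), "empty")
  # localizations entirely outside the template grid give an all-zero image
  far <- ideal_locs(pair$bs6)
  far$x <- far$x + 1e5
  expect_error(align_to_template(far, tmpl, step_deg = 90), "degenerate")
})
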