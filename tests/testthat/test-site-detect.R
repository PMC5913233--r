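make_locs <- function(x, y) {
  out <- data.frame(x = x, y = y, frame = 0L, photons = 1000, sd_nm = 1)
  class(out) <- c("structure_locs", "data.frame")
  out
}

test_that("counting uses closed discs with nearest-site assignment", {
  g <- build_grid_20nm()
  cfg <- site_count_config(20)
  # exactly at a site center
  counts <- count_sites(make_locs(0, -30), g, cfg)
  expect_equal(unname(counts[g$sites[, 1] == 0 & g$sites[, 2] == -30]), 1)
  expect_equal(sum(counts), 1)
  # on the boundary (closed disc) vs just outside
  on <- count_sites(make_locs(10, -30), g, cfg)
  expect_equal(sum(on), 1)
  off <- count_sites(make_locs(0, 30 + 10.001), g, cfg)
  expect_equal(sum(off), 0)
  # equidistant overlap region: contributes to exactly one site
  mid <- count_sites(make_locs(10, -10), g, cfg)  # between two 20-nm sites
  expect_equal(sum(mid), 1)
})

test_that("count diameters wider than the site spacing are rejected", {
  g <- build_grid_20nm()
  expect_error(count_sites(make_locs(0, 0), g, site_count_config(21)),
               "exceeds the minimum site spacing")
  expect_silent(count_sites(make_locs(0, 0), g, site_count_config(20)))
})

test_that("per-site counts are conserved against the total", {
  pair <- build_bs_pair()
  sim <- simulate_field(pair$bs6, 2, presence = 1, imaging = fast_imaging(750L),
                        seed = 41)
  picks <- pick_structures(sim$table, 98, min_locs = 30)
  tmpl <- render_template(pair$bs6, template_spec(render_sigma = 1, bin_size = 1))
  locs <- extract_structure(sim$table, picks[1, ])
  aligned <- transform_locs(locs, align_to_template(locs, tmpl, step_deg = 2))
  counts <- count_sites(aligned, pair$bs6, site_count_config(5))
  expect_lte(sum(counts), nrow(aligned))
  expect_gt(sum(counts), 0.5 * nrow(aligned))
})

test_that("threshold fit recovers the lower half-maximum of a Gaussian", {
  set.seed(42)
  x <- rnorm(1e4, 200, 30)
  tf <- fit_threshold(x)
  expect_equal(tf$threshold, 200 - 30 * sqrt(2 * log(2)), tolerance = 0.03)
  expect_equal(tf$mu, 200, tolerance = 0.03)
  expect_equal(tf$sigma, 30, tolerance = 0.10)
})

test_that("zero-inflated bimodal counts exclude the spike from the fit", {
  set.seed(43)
  x <- c(rep(0, 4000), rnorm(1e4, 200, 30))
  tf <- fit_threshold(x)
  expect_gt(tf$threshold, 100)
  expect_lt(tf$threshold, 180)
})

test_that("degenerate count sets produce explicit errors", {
  expect_error(fit_threshold(rep(100, 200)), "identical")
  expect_error(fit_threshold(c(1, 2, 3)), "at least 50")
})

test_that("the valley rule fires only on cleanly separated populations", {
  set.seed(44)
  sep <- c(rep(0, 150), rnorm(450, 600, 50))
  tf <- determine_threshold(sep)
  expect_identical(tf$method, "gap")
  expect_gt(tf$threshold, max(sep[sep < 300]))
  expect_lt(tf$threshold, min(sep[sep > 300]))
  # broad experimental-like counts reaching down to zero: no clean valley,
  # the Gaussian half-maximum value is used unchanged
  cont <- pmax(0, rnorm(5000, 150, 70))
  tf2 <- determine_threshold(cont)
  expect_identical(tf2$method, "half_max")
  expect_equal(tf2$threshold, tf2$mu - tf2$sigma * sqrt(2 * log(2)),
               tolerance = 1e-9)
})

test_that("site calls use an inclusive threshold", {
  roles <- c("probed", "probed", "absent")
  counts <- rbind(c(10, 9, 0), c(10, 30, 12))
  calls <- call_sites(counts, 10, roles = roles)
  expect_identical(calls$detected,
                   rbind(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE)))
})

test_that("efficiency report averages per site and per structure", {
  roles <- rep("probed", 2)
  # 10 structures: site 1 detected in 8 of them, site 2 in all
  det <- cbind(c(rep(TRUE, 8), FALSE, FALSE), rep(TRUE, 10))
  calls <- call_sites(det * 100, 50, roles = roles)
  eff <- detection_efficiency(calls)
  expect_equal(unname(eff$per_site), c(0.8, 1))
  expect_equal(eff$grand_mean, 0.9)
  expect_equal(eff$per_structure[9], 0.5)
  all_det <- call_sites(matrix(100, 4, 2), 50, roles = roles)
  expect_equal(unname(detection_efficiency(all_det)$per_site), c(1, 1))
})

test_that("bootstrap spread matches the binomial oracle", {
  set.seed(45)
  det <- matrix(runif(500 * 3) < 0.8, 500, 3)
  calls <- call_sites(det * 100, 50, roles = rep("probed", 3))
  s <- bootstrap_std(calls, subset_size = 250, reps = 10, seed = 46)
  oracle <- sqrt(0.8 * 0.2 / 250)
  expect_true(all(s > oracle / 2 & s < oracle * 2))
  # perfectly detected site has zero spread
  sure <- call_sites(matrix(100, 300, 1), 50, roles = "probed")
  expect_equal(unname(bootstrap_std(sure, 250, 10, seed = 1)), 0)
  expect_warning(std1 <- bootstrap_std(calls, 250, reps = 1, seed = 1), "0 by convention")
  expect_equal(unname(std1), rep(0, 3))
  expect_error(bootstrap_std(calls, subset_size = 501), "exceeds")
})

test_that("false-positive rate scores absent-by-design sites only", {
  roles <- c("probed", "absent")
  counts <- cbind(rep(100, 50), c(60, rep(0, 49)))
  calls <- call_sites(counts, 50, roles = roles)
  expect_equal(false_positive_rate(calls), 1 / 50)
  clean <- call_sites(cbind(rep(100, 50), rep(0, 50)), 50, roles = roles)
  expect_equal(false_positive_rate(clean), 0)
  no_absent <- call_sites(cbind(rep(100, 5)), 50, roles = "probed")
  expect_error(false_positive_rate(no_absent), "no absent")
})
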