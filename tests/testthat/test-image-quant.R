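test_that("segmentation recovers the planted cell count on clean fields", {
  f <- simulate_microscopy_field(field_sim_config(n_cells = 20, noise_sd = 2,
                                                  seed = 3))
  m <- segment_cells(f)
  expect_equal(max(m), 20)
})

test_that("a blank field segments to zero labels with a warning", {
  blank <- list(gfp = matrix(0, 64, 64), cmac = matrix(0, 64, 64),
                tb = matrix(0, 64, 64))
  expect_warning(m <- segment_cells(blank), "empty field")
  expect_equal(max(m), 0L)
})

test_that("segmentation stays within one cell of truth under moderate noise", {
  hits <- vapply(1:10, function(s) {
    f <- simulate_microscopy_field(field_sim_config(
      n_cells = 15, image_shape = c(256, 256), noise_sd = 10, seed = s))
    abs(max(segment_cells(f)) - 15) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("border-cell removal drops exactly the edge-touching labels", {
  f <- simulate_microscopy_field(field_sim_config(
    n_cells = 5, border_fraction = 0.2, image_shape = c(256, 256), seed = 8))
  kept <- remove_border_cells(f$labels)
  expect_equal(max(kept), 4)
  # interior-only masks are unchanged up to relabeling
  g <- small_field(seed = 3)
  expect_equal(sum(remove_border_cells(g$labels) > 0), sum(g$labels > 0))
  # idempotence
  expect_identical(remove_border_cells(kept), kept)
  # all labels on the border leaves an empty mask
  edge_only <- matrix(0L, 32, 32); edge_only[1, 5:10] <- 1L
  expect_equal(max(remove_border_cells(edge_only)), 0L)
})

test_that("whole-cell means reproduce constructed and planted intensities", {
  mask <- matrix(0L, 10, 10); mask[3:6, 3:6] <- 1L
  img <- matrix(100, 10, 10)
  expect_equal(whole_cell_intensities(mask, img)$mean_gfp, 100)
  img[3:6, 3:4] <- 0; img[3:6, 5:6] <- 200
  expect_equal(whole_cell_intensities(mask, img)$mean_gfp, 100)
  expect_error(whole_cell_intensities(mask, matrix(0, 5, 5)), "shape")
  # planted values are exact on a noise-free field
  f <- small_field(seed = 5, gfp_levels = gfp_model(c(30, 90), sdlog = 0.3,
                                                    weights = c(0.5, 0.5)))
  rec <- whole_cell_intensities(f$labels, f$gfp)
  expect_equal(rec$mean_gfp, f$truth$true_mean_gfp)
})

test_that("surface and vacuole masks match the planted compartments when noise-free", {
  f <- small_field(pm_vac_ratio_true = 2, seed = 4)
  cm <- surface_and_vacuole_masks(f, f$labels)
  expect_equal(mask_jaccard(cm$surface, f$wall_labels), 1)
  expect_equal(mask_jaccard(cm$vacuole, f$vacuole_labels), 1)
  expect_true(all(cm$flags$vacuole_defined))
  # masks disjoint per construction
  expect_equal(sum(cm$surface > 0 & cm$vacuole > 0), 0L)
})

test_that("cells without CMAC signal are flagged vacuole-undefined", {
  f <- small_field(seed = 4)
  f$cmac[] <- 0
  cm <- surface_and_vacuole_masks(f, f$labels)
  expect_true(all(!cm$flags$vacuole_defined))
  q <- quantify_cells(f, f$labels, compartments = TRUE)
  expect_true(all(is.na(q$pm_vac_ratio)))
  expect_equal(attr(q, "n_excluded"), nrow(q))
})

test_that("compartment masks stay accurate under moderate noise", {
  js <- jv <- numeric(5)
  for (s in 1:5) {
    f <- simulate_microscopy_field(field_sim_config(
      n_cells = 12, image_shape = c(256, 256), pm_vac_ratio_true = 2,
      noise_sd = 10, seed = s))
    cm <- surface_and_vacuole_masks(f, f$labels)
    js[s] <- mask_jaccard(cm$surface, f$wall_labels)
    jv[s] <- mask_jaccard(cm$vacuole, f$vacuole_labels)
  }
  expect_gte(mean(js), 0.8)
  expect_gte(mean(jv), 0.8)
})

test_that("PM/vacuole ratios follow the compartment means and their invariances", {
  rec <- tibble::tibble(cell_id = 1:2, surface_mean = c(200, 50),
                        vacuole_mean = c(100, 50))
  out <- pm_vacuole_ratio(rec)
  expect_equal(out$pm_vac_ratio, c(2, 1))
  # zero vacuole mean excluded and counted
  rec$vacuole_mean[2] <- 0
  out <- pm_vacuole_ratio(rec)
  expect_true(is.na(out$pm_vac_ratio[2]))
  expect_equal(attr(out, "n_excluded"), 1L)
  # planted ratio is exact on a noise-free field, and invariant to a
  # global rescaling of the GFP channel
  f <- small_field(pm_vac_ratio_true = 2, seed = 4)
  q1 <- quantify_cells(f, f$labels, compartments = TRUE)
  expect_equal(q1$pm_vac_ratio, rep(2, nrow(q1)))
  f$gfp <- f$gfp * 7.3
  q2 <- quantify_cells(f, f$labels, compartments = TRUE)
  expect_equal(q2$pm_vac_ratio, q1$pm_vac_ratio, tolerance = 1e-12)
})

test_that("population summaries give the median and a seeded bootstrap CI", {
  s <- population_summary(1:9, n_boot = 200, seed = 1)
  expect_equal(s$median, 5)
  expect_lte(s$ci_lower, s$median); expect_gte(s$ci_upper, s$median)
  cs <- population_summary(rep(4.2, 10), n_boot = 100, seed = 1)
  expect_equal(c(cs$ci_lower, cs$ci_upper), c(4.2, 4.2))
  expect_error(population_summary(c(1, 2)), "insufficient")
  # same seed, same CI
  set.seed(99); v <- rlnorm(50)
  a <- population_summary(v, n_boot = 200, seed = 3)
  b <- population_summary(v, n_boot = 200, seed = 3)
  expect_identical(a, b)
})

test_that("the bootstrap CI of the median covers the true median", {
  true_med <- 50
  covered <- vapply(1:100, function(s) {
    set.seed(s + 300)
    v <- rlnorm(500, log(true_med), 0.3)
    ci <- population_summary(v, n_boot = 400, seed = s)
    ci$ci_lower <= true_med && true_med <= ci$ci_upper
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("subpopulation splitting recovers planted fractions and flags unimodal data", {
  set.seed(9)
  comp <- sample(1:2, 1000, replace = TRUE, prob = c(0.4, 0.6))
  v <- exp(log(c(40, 80))[comp] + rnorm(1000, 0, 0.2))
  sp <- split_subpopulations(v, seed = 9)
  expect_lt(abs(sp$fractions[1] - 0.4), 0.05)
  expect_lt(abs(sp$fractions[2] - 0.6), 0.05)
  expect_true(sp$split_warranted)
  expect_equal(sum(sp$fractions), 1, tolerance = 1e-9)
  # components sorted by mean: dim first
  expect_lt(sp$means[1], sp$means[2])
  expect_equal(sp$assignment[which.min(v)], 1L)
  # unimodal data: split not warranted
  set.seed(10)
  u <- rlnorm(1000, log(50), 0.2)
  su <- split_subpopulations(u, seed = 10)
  expect_false(su$split_warranted)
  expect_error(split_subpopulations(c(-1, rep(2, 30))), "positive")
  expect_error(split_subpopulations(1:10), "at least 20")
})

test_that("the full pipeline recovers population medians within 5%", {
  errs <- vapply(1:5, function(s) {
    f <- simulate_microscopy_field(field_sim_config(
      n_cells = 15, image_shape = c(256, 256), noise_sd = 10, seed = s))
    q <- quantify_cells(f)
    tm <- median(f$truth$true_mean_gfp[!f$truth$border])
    abs(median(q$mean_gfp) - tm) / tm
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})
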