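test_that("replicate summaries use the sample SD and count replicates", {
  tbl <- tibble::tibble(plate = "p1", gene = rep(c("g1", "g2"), each = 3),
                        plasmid = "vector", condition = "control",
                        replicate = rep(1:3, 2), day = 1,
                        colony_px = c(10, 20, 30, 7, 7, 7))
  out <- summarize_replicates(tbl)
  expect_equal(out$mean_px, c(20, 7))
  expect_equal(out$sd_px, c(10, 0))
  expect_equal(out$n_reps, c(3L, 3L))
})

test_that("single-replicate keys warn and record an undefined SD", {
  tbl <- tibble::tibble(plate = "p1", gene = c("g1", "g1", "g2"),
                        plasmid = "vector", condition = "control",
                        replicate = c(1, 2, 1), day = 1,
                        colony_px = c(10, 20, 5))
  expect_warning(out <- summarize_replicates(tbl), "single replicate")
  expect_true(is.na(out$sd_px[out$gene == "g2"]))
})

test_that("the latest imaging day is scored by default", {
  tbl <- tidyr::crossing(plate = "p1", gene = c("g1", "g2"),
                         plasmid = "vector", condition = "control",
                         replicate = 1:2, day = c(1, 3))
  tbl$colony_px <- ifelse(tbl$day == 3, 100, 1)
  out <- summarize_replicates(tbl)
  expect_true(all(out$mean_px == 100))
  expect_true(all(summarize_replicates(tbl, day = 1)$mean_px == 1))
})

test_that("plate Z-scores center and scale within the stratum", {
  expect_equal(plate_zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_warning(z <- plate_zscore(c(5, 5, 5, 5)), "zero-SD")
  expect_true(all(is.na(z)))
  # normalization identity on arbitrary strata
  for (s in 1:5) {
    set.seed(s)
    z <- plate_zscore(rlnorm(50, 5, 0.4))
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
})

test_that("deltaV is the arrestin-minus-vector difference and is antisymmetric", {
  expect_equal(unname(compute_delta_v(c(g = 0.8), c(g = 0.8))), 0)
  expect_equal(unname(compute_delta_v(c(g = -0.5), c(g = 1.0))), -1.5)
  set.seed(3)
  a <- stats::setNames(rnorm(10), paste0("g", 1:10))
  v <- stats::setNames(rnorm(10), paste0("g", 1:10))
  expect_equal(compute_delta_v(a, v), -compute_delta_v(v, a))
  expect_warning(dv <- compute_delta_v(c(g1 = 1, gX = 2), c(g1 = 0)),
                 "missing from vector")
  expect_true(is.na(dv["gX"]))
})

test_that("candidate calls follow strict cutoffs on Z(dV) and plate Z", {
  sc <- tibble::tibble(
    plate = "p1", gene = c("A", "B", "C"), plasmid = "ALY1",
    condition = "control", mean_px = 1, sd_px = 0, n_reps = 3,
    plate_z = c(2, 2, 2), delta_v = 1,
    delta_v_z = c(1.3, -0.5, -1.6))
  out <- call_condition_candidates(sc, require_size_deviation = FALSE)
  expect_setequal(out$gene[out$candidate], c("A", "C"))
  # size filter removes candidates whose colony size is unremarkable
  sc$plate_z <- c(2, 2, 1.0)
  out2 <- call_condition_candidates(sc)
  expect_setequal(out2$gene[out2$candidate], "A")
  # all |Z| below cutoff: nothing called; ties at the cutoff are excluded
  sc$delta_v_z <- c(0.3, 1.2, -1.1)
  expect_equal(sum(call_condition_candidates(sc)$candidate), 0)
})

test_that("raising either cutoff never adds a candidate", {
  sim <- tiny_screen(seed = 11)
  scored <- score_screen(sim$measurements)
  loose <- call_condition_candidates(scored, z_cutoff = 1.2, size_cutoff = 1.25)
  for (zc in c(1.5, 2)) {
    tight <- call_condition_candidates(scored, z_cutoff = zc, size_cutoff = 1.25)
    expect_true(all(!tight$candidate | loose$candidate))
  }
  tight <- call_condition_candidates(scored, z_cutoff = 1.2, size_cutoff = 2)
  expect_true(all(!tight$candidate | loose$candidate))
})

test_that("scoring is invariant to rescaling colony sizes within a stratum", {
  sim <- tiny_screen(seed = 13)
  m <- sim$measurements
  scored <- score_screen(m)
  m2 <- m
  pick <- m2$plate == "plate1" & m2$condition == "control"
  m2$colony_px[pick] <- m2$colony_px[pick] * 37.5
  scored2 <- score_screen(m2)
  expect_equal(scored2$plate_z, scored$plate_z, tolerance = 1e-12)
  expect_equal(scored2$delta_v, scored$delta_v, tolerance = 1e-12)
  expect_equal(scored2$delta_v_z, scored$delta_v_z, tolerance = 1e-12)
})

test_that("aggregation keeps genes hit in enough conditions", {
  sets <- list(control = "a", salt = c("a", "b"), rapamycin = "b")
  expect_setequal(aggregate_candidates(sets, 2), c("a", "b"))
  expect_equal(aggregate_candidates(list(c1 = "x", c2 = "y", c3 = "z"), 2),
               character(0))
  expect_setequal(aggregate_candidates(sets, 1), c("a", "b"))
  expect_error(aggregate_candidates(list(c1 = "a"), 2), "min_conditions")
  # monotone non-increasing in min_conditions
  expect_true(all(aggregate_candidates(sets, 3) %in%
                    aggregate_candidates(sets, 2)))
})

test_that("Venn regions partition the union and match brute force", {
  r <- venn_regions(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(r$count[r$pattern == "A"]), 1L)
  expect_equal(unname(r$count[r$pattern == "A&B"]), 1L)
  expect_equal(unname(r$count[r$pattern == "B"]), 1L)

  same <- venn_regions(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(nrow(same), 1L)
  expect_equal(same$pattern, "X&Y")

  # brute-force oracle over all membership patterns of three random sets
  set.seed(2)
  genes <- paste0("g", 1:50)
  sets <- lapply(1:3, function(i) sample(genes, sample(10:30, 1)))
  names(sets) <- c("s1", "s2", "s3")
  r3 <- venn_regions(sets)
  for (g in genes) {
    member <- vapply(sets, function(s) g %in% s, logical(1))
    if (!any(member)) next
    pat <- paste(names(sets)[member], collapse = "&")
    expect_true(g %in% r3$members[[which(r3$pattern == pat)]])
  }
  expect_equal(sum(r3$count), length(unique(unlist(sets))))
  # region counts containing a set sum to that set's cardinality
  for (nm in names(sets)) {
    in_set <- grepl(nm, r3$pattern, fixed = TRUE)
    expect_equal(sum(r3$count[in_set]), length(unique(sets[[nm]])))
  }
})

test_that("two-arm Venn partition reports per-condition overlaps", {
  v <- venn_partition(list(c1 = c("a", "b")), list(c1 = c("b", "c")))
  expect_equal(v$overlap$arm1_only, 1L)
  expect_equal(v$overlap$both, 1L)
  expect_equal(v$overlap$arm2_only, 1L)
})

test_that("the candidate report pools arms and collapses the salt arms", {
  sc <- tidyr::crossing(plate = "p1",
                        gene = c("hit2", "hitsalt", "null"),
                        plasmid = c("ALY1", "ALY2"),
                        condition = names(default_condition_map()))
  sc$mean_px <- 1; sc$sd_px <- 0; sc$n_reps <- 3L
  sc$plate_z <- 2; sc$delta_v <- 1
  # hit2: candidate in control (ALY1) and rapamycin (ALY2) -> 2 groups
  # hitsalt: candidate in both NaCl arms (one group) -> 1 group
  sc$delta_v_z <- 0
  sc$delta_v_z[sc$gene == "hit2" & sc$plasmid == "ALY1" &
                 sc$condition == "control"] <- 2
  sc$delta_v_z[sc$gene == "hit2" & sc$plasmid == "ALY2" &
                 sc$condition == "rapamycin_50ng_mL"] <- -2
  sc$delta_v_z[sc$gene == "hitsalt" &
                 sc$condition %in% c("NaCl_0.8M", "NaCl_1.5M")] <- 2
  report <- candidate_report(call_condition_candidates(sc))
  expect_equal(report$aggregated, "hit2")
  expect_setequal(names(report$pooled_grouped),
                  c("control", "salt", "rapamycin"))
  expect_equal(report$pooled_grouped$salt, "hitsalt")
})

test_that("a summarized simulated screen has one row per strain and arm", {
  sim <- simulate_screen_plates(screen_sim_config(seed = 1))
  expect_equal(nrow(summarize_replicates(sim$measurements)), 187 * 3 * 4)
})
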