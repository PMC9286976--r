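test_that("simulate_fly is deterministic under a fixed seed", {
  a <- simulate_fly(get_preset("control"), 600, seed = 42)
  b <- simulate_fly(get_preset("control"), 600, seed = 42)
  expect_identical(a$trajectory$heights_mm, b$trajectory$heights_mm)
  expect_identical(a$truth, b$truth)
  c <- simulate_fly(get_preset("control"), 600, seed = 43)
  expect_false(identical(a$trajectory$heights_mm, c$trajectory$heights_mm))
})

test_that("a zero climb-initiation rate gives a fly resting at the bottom", {
  p <- phenotype_preset(climb_initiation_rate_per_min = 0)
  s <- simulate_fly(p, 300, seed = 1)
  expect_equal(s$trajectory$heights_mm, rep(3, 300))
  m <- compute_metrics(s$trajectory)
  expect_equal(m$n_climb_events, 0)
  expect_equal(m$total_height_climbed_mm, 0)
  expect_equal(m$n_movements, 0)
})

test_that("preset validation rejects bad probabilities", {
  expect_error(phenotype_preset(peak_height_probs = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(phenotype_preset(prob_descent_is_drop = 1.2), "\\[0, 1\\]")
  expect_error(phenotype_preset(bottom_bias = -0.1), "\\[0, 1\\]")
})

test_that("ground-truth events tile the timeline with continuous heights", {
  s <- simulate_fly(get_preset("park25"), 900, seed = 5)
  tr <- s$truth
  expect_equal(tr$t_start[1], 0)
  expect_equal(tr$t_end[nrow(tr)], 900)
  expect_equal(tr$t_start[-1], tr$t_end[-nrow(tr)])
  expect_equal(tr$h_start[-1], tr$h_end[-nrow(tr)])
})

test_that("sampled heights stay within 3 mm of the continuous truth", {
  for (seed in 1:5) {
    s <- simulate_fly(get_preset("control"), 600, seed = seed)
    tr <- s$truth
    cont <- approx(c(0, tr$t_end), c(3, tr$h_end),
                   xout = 0:599, rule = 2, ties = "ordered")$y
    expect_true(all(abs(s$trajectory$heights_mm - cont) < 3))
  }
})

test_that("climbing events recover ground-truth ascents within +/- 1", {
  for (seed in 1:8) {
    s <- simulate_fly(get_preset("control"), 1200, seed = 100 + seed)
    n_true <- sum(s$truth$type == "ascent")
    n_seg <- nrow(segment_climbs(s$trajectory, count_terminal_ascent = TRUE))
    expect_lte(abs(n_seg - n_true), 1)
  }
})

test_that("simulate_cohort labels groups, derives per-fly substreams", {
  design <- list(a = list(preset = "control", n = 3, genotype = "control"),
                 b = list(preset = "park25", n = 3, genotype = "park25",
                          dose_ug_per_ml = 9))
  co <- simulate_cohort(design, duration_s = 120, seed = 9)
  expect_length(co$trajectories, 6)
  expect_setequal(unique(co$truth$group), c("a", "b"))
  expect_equal(co$trajectories$b_001$genotype, "park25")
  expect_equal(co$trajectories$b_001$dose_ug_per_ml, 9)
  # reproducible independent of construction order
  co2 <- simulate_cohort(design, duration_s = 120, seed = 9)
  expect_identical(co$trajectories$a_002$heights_mm, co2$trajectories$a_002$heights_mm)
  # schema stable under a different master seed
  co3 <- simulate_cohort(design, duration_s = 120, seed = 10)
  expect_identical(names(co3$trajectories), names(co$trajectories))
  expect_false(identical(co$trajectories$a_001$heights_mm,
                         co3$trajectories$a_001$heights_mm))

  expect_error(simulate_cohort(list(a = list(preset = "control", n = 0))), "n >= 1")
  expect_error(simulate_cohort(setNames(list(list(preset = "control", n = 1),
                                             list(preset = "control", n = 1)),
                                        c("a", "a"))), "duplicate")
  expect_error(simulate_cohort(list(a = list(preset = "nope", n = 1))),
               "unknown preset")
})

test_that("simulate_flight honours probabilities and seeds", {
  expect_false(any(simulate_flight(0, 50, seed = 1)$flew))
  expect_true(all(simulate_flight(1, 50, seed = 1)$flew))
  fl <- simulate_flight(0.5, 1000, seed = 2)
  expect_lt(abs(mean(fl$flew) - 0.5), 0.05)
  expect_identical(simulate_flight(0.3, 40, seed = 5)$flew,
                   simulate_flight(0.3, 40, seed = 5)$flew)
  expect_error(simulate_flight(1.5, 10), "probability")
})

test_that("control preset out-climbs the park25 preset (directional only)", {
  n <- 15
  ctrl <- simulate_cohort(list(c = list(preset = "control", n = n)),
                          duration_s = 1200, seed = 500)
  park <- simulate_cohort(list(p = list(preset = "park25", n = n,
                                        genotype = "park25")),
                          duration_s = 1200, seed = 900)
  mc <- compute_metrics_table(ctrl$trajectories)
  mp <- compute_metrics_table(park$trajectories)
  expect_gt(mean(mc$n_climbs_to_top), mean(mp$n_climbs_to_top))
  expect_gt(mean(mc$dwell_top_s), mean(mp$dwell_top_s))
  expect_lt(mean(mc$dwell_lower_s), mean(mp$dwell_lower_s))
  dc <- descent_summary(ctrl$trajectories)
  dp <- descent_summary(park$trajectories)
  expect_gt(mean(dc$n_descending_climbs), mean(dp$n_descending_climbs))
})
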