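# Balanced 2x2 fixture with integer values; SS decomposition is hand-checked
# in the acceptance suite against a closed-form oracle.
balanced_fixture <- function() {
  data.frame(
    genotype = rep(c("control", "park25"), each = 6),
    dose = rep(rep(c(0, 9), each = 3), 2),
    y = c(10, 12, 14, 16, 18, 20, 4, 6, 8, 16, 14, 18))
}

test_that("no-effect configurations give F near 0", {
  set.seed(31)
  d <- data.frame(a = rep(c("x", "y"), each = 20),
                  b = rep(rep(c("u", "v"), each = 10), 2))
  d$y <- rnorm(40)
  # force all cell means to be identical
  d$y <- d$y - ave(d$y, d$a, d$b) + 5
  res <- two_way_anova_tukey(d, "y", "a", "b")
  expect_lt(max(res$anova$F[1:3]), 1e-20)
  expect_equal(res$anova$sum_sq[1:3], rep(0, 3), tolerance = 1e-12)
})

test_that("balanced ANOVA reproduces stats::aov sums of squares", {
  d <- balanced_fixture()
  res <- two_way_anova_tukey(d, "y", "genotype", "dose")
  ref <- summary(aov(y ~ genotype * dose, transform(d, dose = factor(dose))))[[1]]
  expect_equal(res$anova$sum_sq, unname(ref[["Sum Sq"]]), tolerance = 1e-10)
  expect_equal(res$anova$F[1:3], unname(ref[["F value"]][1:3]), tolerance = 1e-10)
  expect_equal(res$anova$p[1:3], unname(ref[["Pr(>F)"]][1:3]), tolerance = 1e-10)
  # SS decomposition: total == A + B + AB + residual on balanced data
  expect_equal(sum(res$anova$sum_sq), sum((d$y - mean(d$y))^2), tolerance = 1e-10)
})

test_that("Type III agrees with Type II on balanced data", {
  d <- balanced_fixture()
  r2 <- two_way_anova_tukey(d, "y", "genotype", "dose", ss_type = "II")
  r3 <- two_way_anova_tukey(d, "y", "genotype", "dose", ss_type = "III")
  expect_equal(r2$anova$sum_sq, r3$anova$sum_sq, tolerance = 1e-10)
})

test_that("Tukey on identical groups gives diff 0 and p near 1", {
  d <- data.frame(a = rep(c("x", "y"), each = 10),
                  b = rep(c("u", "v"), 10),
                  y = rep(c(1, 2, 3, 4, 5), 4))
  res <- two_way_anova_tukey(d, "y", "a", "b", tukey = "margins")
  row_a <- res$tukey[res$tukey$factor == "a", ]
  expect_equal(row_a$diff, 0)
  expect_gt(row_a$p_adj, 0.99)
})

test_that("ANOVA errors are informative", {
  d <- balanced_fixture()
  d2 <- d[!(d$genotype == "park25" & d$dose == 9), ]
  expect_error(two_way_anova_tukey(d2, "y", "genotype", "dose"), "empty cell")
  d3 <- d[c(1, 4, 7, 10), ]  # one observation per cell
  expect_error(two_way_anova_tukey(d3, "y", "genotype", "dose"),
               "residual degrees of freedom")
  expect_error(two_way_anova_tukey(d, "nope", "genotype", "dose"), "not found")
  d$y[1] <- NA
  expect_message(two_way_anova_tukey(d, "y", "genotype", "dose"), "dropped")
})

test_that("fisher_exact matches hand-enumerated values", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "zero margin")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  set.seed(33)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    p <- fisher_exact(tab)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, oracle_fisher_p(tab))
  }
})

test_that("marascuilo flags only clearly different proportions", {
  # two identical groups
  r <- marascuilo(c(10, 10), c(50, 50))
  expect_false(any(r$pairs$significant))
  expect_equal(r$pairs$abs_diff, 0)
  # degenerate variance: 0/100 vs 100/100 has critical range 0
  r2 <- marascuilo(c(0, 100), c(100, 100), bonferroni_m = 1L)
  expect_equal(r2$pairs$critical_range, 0)
  expect_true(r2$pairs$significant)
  expect_false(is.na(r2$fisher_p))
  # hand-evaluated three-group case (alpha 0.05, m = 1):
  # chi2_{0.95, 2} = 5.9915, ranges ~ 0.1080 / 0.1406 / 0.1439
  r3 <- marascuilo(c(10, 12, 60), c(100, 100, 100), bonferroni_m = 1L)
  expect_equal(r3$pairs$critical_range,
               c(0.10800, 0.14064, 0.14392), tolerance = 1e-3)
  expect_equal(r3$pairs$significant, c(FALSE, TRUE, TRUE))
  # same pattern under the default Bonferroni m = 3
  r3b <- marascuilo(c(10, 12, 60), c(100, 100, 100))
  expect_equal(r3b$bonferroni_m, 3L)
  expect_equal(r3b$pairs$significant, c(FALSE, TRUE, TRUE))
})

test_that("marascuilo control mode compares control to each treatment", {
  r <- marascuilo(c(44, 10, 30), c(50, 50, 50),
                  labels = c("ctrl", "t1", "t2"), control = "ctrl")
  expect_identical(nrow(r$pairs), 2L)
  expect_true(all(r$pairs$group_i == "ctrl"))
  expect_equal(r$bonferroni_m, 2L)
  expect_error(marascuilo(c(1, 2), c(10, 10), control = "nope"), "not found")
  expect_error(marascuilo(c(5), c(10)), "at least 2 groups")
})

test_that("marascuilo significance is monotone in the proportion gap", {
  n <- c(80, 80)
  prev <- FALSE
  for (k2 in seq(10, 80, by = 5)) {
    sig <- marascuilo(c(10, k2), n)$pairs$significant
    if (prev) expect_true(sig)  # once significant, stays significant
    prev <- sig
  }
  expect_true(prev)
})

test_that("window_analysis recovers a known benefit window", {
  fl <- simulate_window_cohort(seed = 1000)
  res <- window_analysis(fl)
  expect_equal(unname(res$edges["park25"]), 5L)
  # inside the window the benefit is detected with a positive direction
  inside <- res$table$genotype == "park25" & res$table$start_day <= 5
  expect_true(all(res$table$significant[inside]))
  expect_true(all(res$table$direction[inside] > 0))
  # the control arm shows the opposite (harmful) direction from day 0
  ctrl0 <- res$table$genotype == "control" & res$table$start_day == 0
  expect_true(res$table$significant[ctrl0])
  expect_true(res$table$direction[ctrl0] < 0)
  expect_false(is.na(res$edges["control"]))
})

test_that("window_analysis handles degenerate inputs", {
  # all days at baseline: no significant day, edge is none
  rows <- do.call(rbind, lapply(0:3, function(d) rbind(
    simulate_flight(0.1, 40, seed = 50 + d, genotype = "park25",
                    dose_ug_per_ml = 4.5, start_day = d),
    simulate_flight(0.1, 40, seed = 150 + d, genotype = "park25",
                    dose_ug_per_ml = 0, start_day = d))))
  res <- window_analysis(rows)
  expect_true(is.na(res$edges["park25"]))
  # single start day violates the precondition
  one <- simulate_flight(0.5, 20, seed = 1, dose_ug_per_ml = 4.5, start_day = 0L)
  expect_error(window_analysis(one), "at least 2 start days")
  expect_error(window_analysis(data.frame(flew = TRUE)), "missing columns")
})
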