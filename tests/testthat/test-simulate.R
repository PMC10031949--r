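test_that("generators are pure functions of their seed", {
  d <- study_design(4)
  p <- truth_params()
  expect_identical(simulate_mn(p, d, seed = 9), simulate_mn(p, d, seed = 9))
  expect_false(identical(simulate_mn(p, d, seed = 9), simulate_mn(p, d, seed = 10)))
  prof <- lymphocyte_profile(cv = 0.2)
  expect_identical(simulate_hematology(list(prof), "A1", hema_days, seed = 3),
                   simulate_hematology(list(prof), "A1", hema_days, seed = 3))
  des <- overlap_design(500, 50, 20, c(1, 3, 7))
  expect_identical(simulate_molecule_lists(des, seed = 5),
                   simulate_molecule_lists(des, seed = 5))
  expect_identical(simulate_expression_matrix(100, 4, 10, 1, 0.5, seed = 2),
                   simulate_expression_matrix(100, 4, 10, 1, 0.5, seed = 2))
  # and the caller's RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_mn(p, d, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("without production every MN sample has expected ratio C", {
  p <- kinetic_params(C = 0.04, Kprod = 0)
  tab <- simulate_mn(p, study_design(8, bn = 5000), seed = 1)
  expect_equal(mean(tab$mn / tab$bn), 0.04, tolerance = 0.01)
  # per-day means stay flat
  expect_lt(diff(range(tapply(tab$mn / tab$bn, tab$day, mean))), 0.01)
})

test_that("empirical MN/BN agrees with the closed-form curve", {
  # binomial family under a curve that stays below 1
  p <- truth_params()
  day <- 3
  des <- mn_design(sprintf("A%03d", 1:200), day, bn_range = c(1000, 1000))
  tab <- simulate_mn(p, des, dispersion_spec("binomial"), seed = 21)
  expected <- model_mn(p, day)
  mc_sd <- sqrt(expected * (1 - expected) / 1000) / sqrt(200)
  expect_lt(abs(mean(tab$mn / tab$bn) - expected), 3 * mc_sd)

  # per-cell Poisson permits ratios above 1
  p2 <- kinetic_params(C = 0.05, Kprod = 0.2, Kdec1 = 0.1, Kdec2 = 0.001, P = 0.5)
  des2 <- mn_design(sprintf("A%03d", 1:200), 10, bn_range = c(1e5, 1e5))
  tab2 <- simulate_mn(p2, des2, dispersion_spec("poisson-per-cell"), seed = 22)
  expected2 <- model_mn(p2, 10)
  mc_sd2 <- sqrt(expected2 / 1e5) / sqrt(200)
  expect_gt(expected2, 1)  # binomial could not represent this day
  expect_lt(abs(mean(tab2$mn / tab2$bn) - expected2), 3 * mc_sd2)
})

test_that("binomial noise is rejected when the curve exceeds one", {
  p2 <- kinetic_params(C = 0.05, Kprod = 0.2, Kdec1 = 0.1, Kdec2 = 0.001, P = 0.5)
  des <- mn_design("A1", c(0, 10), bn_range = c(100, 100))
  expect_error(simulate_mn(p2, des, dispersion_spec("binomial")), "exceeds 1")
  expect_error(simulate_mn(p2, des, dispersion_spec("beta-binomial", 0.1)),
               "exceeds 1")
})

test_that("count-noise variance behaves across dispersion families", {
  p <- kinetic_params(C = 0.1, Kprod = 0)
  des <- mn_design(sprintf("A%03d", 1:400), 0, bn_range = c(500, 500))
  props <- function(noise, seed) {
    tab <- simulate_mn(p, des, noise, seed = seed)
    tab$mn / tab$bn
  }
  v_bin <- var(props(dispersion_spec("binomial"), 1))
  expect_lt(v_bin, 1.5 * 0.1 * 0.9 / 500)
  # beta-binomial variance strictly increases with rho
  v_rho <- vapply(c(0.01, 0.05, 0.2), function(r)
    var(props(dispersion_spec("beta-binomial", r), 1)), numeric(1))
  expect_true(all(diff(v_rho) > 0))
  expect_gt(v_rho[1], v_bin)
  # rho = 0 reduces exactly to the binomial draw
  expect_identical(props(dispersion_spec("beta-binomial", 0), 4),
                   props(dispersion_spec("binomial"), 4))
})

test_that("noiseless hematology reproduces its trajectory exactly", {
  prof <- lymphocyte_profile(cv = 0)
  tab <- simulate_hematology(list(prof), sprintf("A%d", 1:8), hema_days, seed = 1)
  mu <- as.numeric(tapply(tab$count, tab$day, mean))
  days <- sort(unique(tab$day))
  expect_equal(unname(mu[days <= 0]), rep(4, sum(days <= 0)))
  expect_equal(unname(mu[days == 15]), 4 * 0.2, tolerance = 1e-12)
  expect_equal(unname(mu[days >= 27]), rep(4, sum(days >= 27)))
  expect_equal(days[which.min(mu)], 15)
  # piecewise log-linear between the anchors
  expect_equal(unname(mu[days == 6]), 4 * 0.2^(6 / 15), tolerance = 1e-12)
})

test_that("lognormal noise is mean-corrected", {
  prof <- hema_profile("wbc", baseline_mean = 6, nadir_day = 15,
                       nadir_fraction = 0.3, recovery_day = 27, cv = 0.2)
  tab <- simulate_hematology(list(prof), sprintf("A%d", 1:8),
                             rep(-3, 250), seed = 8)  # 2000 baseline draws
  expect_lt(abs(mean(tab$count) / 6 - 1), 0.02)
})

test_that("invalid hematology profiles are rejected", {
  expect_error(hema_profile("x", -1, 15, 0.5, 27), "baseline_mean")
  expect_error(hema_profile("x", 4, 27, 0.5, 15), "precede")
  expect_error(hema_profile("x", 4, 15, 1.5, 27), "nadir_fraction")
})

test_that("molecule lists have the designed size and core structure", {
  des <- overlap_design(1000, 100, 50, c(1, 3, 5, 7))
  for (mode in c("random", "disjoint")) {
    ll <- simulate_molecule_lists(des, seed = 3, extras = mode)
    expect_true(all(vapply(ll, nrow, integer(1)) == 150L))
    ov <- intersect_lists(ll)
    expect_equal(ov$intersection_size, 100L)
    if (mode == "disjoint") {
      off <- ov$pairwise[upper.tri(ov$pairwise)]
      expect_true(all(off == 100L))
      expect_equal(ov$union_size, 100L + 4L * 50L)
    }
  }
  # per_day_extra = 0: every list is exactly the core
  ll0 <- simulate_molecule_lists(overlap_design(1000, 100, 0, c(1, 3)), seed = 1)
  expect_equal(intersect_lists(ll0)$union_size, 100L)
  expect_equal(intersect_lists(ll0)$intersection_size, 100L)
})

test_that("random extras overlap at the hypergeometric expectation", {
  des <- overlap_design(260, 10, 50, c(1, 3))
  expected_extra <- 50^2 / (260 - 10)  # = 10 extra molecules shared on average
  extra_overlap <- vapply(1:300, function(s) {
    ll <- simulate_molecule_lists(des, seed = s, extras = "random")
    intersect_lists(ll)$pairwise[1, 2] - 10L
  }, numeric(1))
  se <- sd(extra_overlap) / sqrt(length(extra_overlap))
  expect_lt(abs(mean(extra_overlap) - expected_extra), 4 * se)
})

test_that("expression matrices plant the promised effects", {
  sim <- simulate_expression_matrix(1000, 8, 50, effect = 2, sigma = 0.5,
                                    seed = 5)
  expect_equal(dim(sim$x), c(1000L, 16L))
  expect_equal(sum(sim$truth), 50L)
  shift <- rowMeans(sim$x[1:50, sim$group == "g2"]) -
           rowMeans(sim$x[1:50, sim$group == "g1"])
  expect_equal(mean(shift), 2, tolerance = 0.15)
  # null case: no truth labels at zero effect
  sim0 <- simulate_expression_matrix(200, 4, 50, effect = 0, sigma = 1, seed = 1)
  expect_false(any(sim0$truth))
  expect_error(simulate_expression_matrix(10, 4, 20, 1, 1), "n_true")
  expect_error(simulate_expression_matrix(10, 4, 2, 1, 0), "sigma")
})
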