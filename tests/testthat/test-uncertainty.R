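# printed reference parameterization: medians and 5-95% intervals, with the
# number of printed decimals for each entry
ref_priors <- list(
  list(d = param_dist("length_to_width_ratio", "normal", 2.35, 0.3),
       med = 2.35, lo = 1.86, hi = 2.84, dig = 2),
  list(d = param_dist("viscosity", "lognormal", -2.3, 1),
       med = 0.1, lo = 0.019, hi = 0.52, dig = c(1, 3, 2)),
  list(d = param_dist("surface_tension", "lognormal", 2.7, 1),
       med = 14.88, lo = 2.87, hi = 77.1, dig = c(2, 2, 1)),
  list(d = param_dist("viscosity", "lognormal", 0, 1),
       med = 1, lo = 0.19, hi = 5.18, dig = 2),
  # surface tension of swimbladdered fish: the printed upper bound is
  # internally inconsistent with its own mu/SD (see dedicated test below)
  list(d = param_dist("length_to_radius", "normal", 5.5, 1),
       med = 5.5, lo = 3.86, hi = 7.15, dig = 2),
  list(d = param_dist("g", "normal", 0.96, 0.0075),
       med = 0.96, lo = 0.948, hi = NA, dig = 3),
  list(d = param_dist("h", "normal", 0.99, 0.0075),
       med = 0.99, lo = 0.978, hi = 1.002, dig = 3),
  list(d = param_dist("length_to_radius", "normal", 10, 1.5),
       med = 10, lo = 7.53, hi = 12.47, dig = 2),
  list(d = param_dist("g", "normal", 1.016, 0.0075),
       med = 1.016, lo = 1.004, hi = 1.028, dig = 3),
  list(d = param_dist("h", "normal", 1.019, 0.0075),
       med = 1.019, lo = 1.007, hi = 1.031, dig = 3),
  list(d = param_dist("length_to_radius", "normal", 8, 1.5),
       med = 8, lo = 5.53, hi = 10.47, dig = 2),
  list(d = param_dist("g", "normal", 1.01, 0.0075),
       med = 1.01, lo = NA, hi = 1.022, dig = 3),
  list(d = param_dist("h", "normal", 1.025, 0.0075),
       med = 1.025, lo = 1.0127, hi = 1.037, dig = c(3, 4, 3)),
  list(d = param_dist("R", "lognormal", -0.69, 0.4),
       med = 0.50, lo = 0.26, hi = 0.97, dig = 2))

test_that("analytic quantiles reproduce the tabulated priors at printed precision", {
  for (e in ref_priors) {
    dig <- if (length(e$dig) == 1) rep(e$dig, 3) else e$dig
    q <- quantile(e$d, c(0.5, 0.05, 0.95))
    expect_equal(round_half_up(q[1], dig[1]), e$med,
                 info = paste(e$d$name, e$d$mu))
    if (!is.na(e$lo))
      expect_equal(round_half_up(q[2], dig[2]), e$lo,
                   info = paste(e$d$name, e$d$mu, "lower"))
    if (!is.na(e$hi))
      expect_equal(round_half_up(q[3], dig[3]), e$hi,
                   info = paste(e$d$name, e$d$mu, "upper"))
  }
})

test_that("quantile arithmetic is analytic and symmetric", {
  d <- param_dist("x", "normal", 3.2, 0.7)
  expect_equal(quantile(d, 0.5), 3.2)                 # normal median is mu
  expect_equal(quantile(d, 0.95) - 3.2, 3.2 - quantile(d, 0.05))
  dl <- param_dist("y", "lognormal", -2.3, 1)
  expect_equal(quantile(dl, 0.5), exp(-2.3))
  expect_equal(round_half_up(quantile(dl, 0.5), 3), 0.1)
  dl2 <- param_dist("z", "lognormal", 2.7, 1)
  expect_equal(round_half_up(quantile(dl2, 0.5), 2), 14.88)
  expect_error(quantile(d, 0), "inside")
  expect_error(quantile(d, 1), "inside")
  # the three tabulated entries that are inconsistent with their own mu/SD
  # must still be analytic: mu + z * sd exactly
  expect_equal(quantile(param_dist("g", "normal", 0.96, 0.0075), 0.95),
               0.96 + 1.645 * 0.0075)
  expect_equal(quantile(param_dist("g", "normal", 1.01, 0.0075), 0.05),
               1.01 - 1.645 * 0.0075)
  expect_equal(quantile(param_dist("tau", "lognormal", 5.3, 1), 0.95),
               exp(5.3 + 1.645))
})

test_that("Latin hypercube designs are stratified and reproducible", {
  dists <- list(v = param_dist("v", "lognormal", -2.3, 1),
                r = param_dist("r", "normal", 2.35, 0.3))
  for (n in c(10, 100, 1000)) {
    des <- lhs_sample(dists, n, seed = 99)
    # exactly one draw per probability stratum, for every parameter
    for (j in 1:2) {
      counts <- table(findInterval(des$probs[, j],
                                   seq(0, 1, length.out = n + 1),
                                   rightmost.closed = TRUE))
      expect_true(all(counts == 1))
      expect_equal(length(counts), n)
    }
    # reproducibility
    des2 <- lhs_sample(dists, n, seed = 99)
    expect_identical(des$draws, des2$draws)
  }
  expect_error(lhs_sample(dists, 0, seed = 1), "at least 1")
})

test_that("LHS sample medians are close to the analytic medians", {
  dists <- list(v = param_dist("v", "lognormal", -2.3, 1))
  des <- lhs_sample(dists, 1000, seed = 5)
  expect_gt(median(des$draws[, "v"]), 0.085)
  expect_lt(median(des$draws[, "v"]), 0.115)
  # n = 1: a single draw anywhere in (0, 1); stratification vacuous
  d1 <- lhs_sample(dists, 1, seed = 5)
  expect_equal(nrow(d1$draws), 1)
  expect_true(d1$probs[1, 1] > 0 && d1$probs[1, 1] < 1)
})

test_that("degenerate priors collapse the envelope onto the reference", {
  f <- seq(18, 120, 2)
  dists <- list(
    length_to_width_ratio = param_dist("length_to_width_ratio", "normal",
                                       2.35, 0),
    viscosity = param_dist("viscosity", "lognormal", log(0.1), 0))
  env <- ts_envelope("gas_bearing", dists, lengths = 1.23,
                     medium = medium(depth = 83), frequencies = f, n = 20,
                     seed = 2, base = list(surface_tension = 15))
  ref <- ts_gas_bearing(1.23, gas_params(2.35, 0.1, 15), medium(depth = 83),
                        f)
  e <- env$envelopes[[1]]
  expect_equal(e$q05, ref$ts, tolerance = 1e-9)
  expect_equal(e$q50, ref$ts, tolerance = 1e-9)
  expect_equal(e$q95, ref$ts, tolerance = 1e-9)
})

test_that("envelopes are ordered and widen with prior spread", {
  f <- seq(18, 220, 2)
  mk <- function(sd_v) list(
    viscosity = param_dist("viscosity", "lognormal", -2.3, sd_v),
    length_to_width_ratio = param_dist("length_to_width_ratio", "normal",
                                       2.35, 0.3))
  base <- list(surface_tension = 15)
  e1 <- ts_envelope("gas_bearing", mk(0.5), 1.23, medium(depth = 83), f,
                    n = 200, seed = 31, base = base)$envelopes[[1]]
  e2 <- ts_envelope("gas_bearing", mk(1.0), 1.23, medium(depth = 83), f,
                    n = 200, seed = 31, base = base)$envelopes[[1]]
  expect_true(all(e1$q05 <= e1$q50 + 1e-12) && all(e1$q50 <= e1$q95 + 1e-12))
  pk <- which.max(e1$q50)
  expect_gte((e2$q95 - e2$q05)[pk], (e1$q95 - e1$q05)[pk])
})

test_that("envelope quantiles are stable across seeds at n = 1000", {
  f <- seq(18, 420, 10)
  dists <- list(
    viscosity = param_dist("viscosity", "lognormal", -2.3, 1),
    surface_tension = param_dist("surface_tension", "lognormal", 2.7, 1),
    length_to_width_ratio = param_dist("length_to_width_ratio", "normal",
                                       2.35, 0.3))
  ea <- ts_envelope("gas_bearing", dists, 1.23, medium(depth = 83), f,
                    n = 1000, seed = 1)$envelopes[[1]]
  eb <- ts_envelope("gas_bearing", dists, 1.23, medium(depth = 83), f,
                    n = 1000, seed = 2)$envelopes[[1]]
  expect_lt(max(abs(ea$q05 - eb$q05)), 0.5)
  expect_lt(max(abs(ea$q95 - eb$q95)), 0.5)
})

test_that("priors that match no tunable model parameter are a hard error", {
  dists <- list(orientation_sd = param_dist("orientation_sd", "normal", 20, 5))
  expect_error(
    ts_envelope("gas_bearing", dists, 1.23, medium(), c(38, 120), n = 5,
                seed = 1),
    "tunable")
})
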