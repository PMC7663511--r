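# Kinetic fitters: exact round trips at the twelve standard sampling
# minutes, oracle equivalence, breakpoint search, and model selection.

expect_rel_equal <- function(got, want, tol = 1e-6) {
  expect_lt(abs(got - want) / abs(want), tol)
}

test_that("pseudo-first-order fit recovers integrated-form parameters", {
  d <- gen_kinetics("pseudo_first", KIN_PARAMS$pseudo_first, noise_sd = 0)
  f <- fit_pseudo_first(d, qe_exp = 2290)
  expect_rel_equal(f$parameters[["qe"]], 2290)
  expect_rel_equal(f$parameters[["k1"]], 0.0110)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("pseudo-first-order handles flat data and exclusions", {
  d <- kinetic_dataset(c(1, 3, 5, 10), rep(0, 4))
  f <- fit_pseudo_first(d, qe_exp = 100)
  expect_equal(f$parameters[["k1"]], 0)
  expect_equal(f$parameters[["qe"]], 100)
  # points at/above qe_exp are excluded with a message
  d <- kinetic_dataset(c(1, 3, 5, 10, 20), c(10, 20, 30, 55, 60))
  expect_message(f <- fit_pseudo_first(d, qe_exp = 55), "excluded 2")
  expect_equal(f$details$n_excluded, 2)
  expect_error(
    suppressMessages(fit_pseudo_first(
      kinetic_dataset(c(1, 3, 5), c(10, 60, 70)), qe_exp = 55)),
    "fewer than 3")
  expect_error(fit_pseudo_first(kinetic_dataset(c(1, 3), c(1, 2))),
               "qe_exp")
})

test_that("pseudo-second-order fit and predictor match the closed form", {
  d <- gen_kinetics("pseudo_second", KIN_PARAMS$pseudo_second, noise_sd = 0)
  f <- fit_pseudo_second(d)
  expect_rel_equal(f$parameters[["qe"]], 4029)
  expect_rel_equal(f$parameters[["k2"]], 6.92e-5)
  # hand-derived oracle value at t = 10 min (computed before the fit:
  # 4029^2 * 6.92e-5 * 10 / (1 + 4029 * 6.92e-5 * 10))
  pred <- f$details$predict
  expect_equal(pred(10), 2965.3971290906075, tolerance = 1e-9)
  expect_equal(pseudo_second_qt(4029, 6.92e-5)(10), 2965.3971290906075,
               tolerance = 1e-9)
})

test_that("pseudo-second predictor is monotone and asymptotes to qe", {
  pred <- pseudo_second_qt(4029, 6.92e-5)
  tt <- exp(seq(log(0.01), log(1e6), length.out = 200))
  qt <- pred(tt)
  expect_true(all(diff(qt) > 0))
  expect_true(all(qt < 4029))
  expect_equal(pred(1e9), 4029, tolerance = 1e-3)
})

test_that("t/qt regression equals hand OLS on exact points", {
  t <- c(2, 5, 9)
  qt <- c(30, 55, 70)
  f <- fit_pseudo_second(kinetic_dataset(t, qt))
  orc <- ols_oracle(t, t / qt)
  expect_equal(f$parameters[["qe"]], 1 / orc$slope, tolerance = 1e-12)
  expect_equal(f$parameters[["k2"]], orc$slope^2 / orc$intercept,
               tolerance = 1e-12)
  expect_error(fit_pseudo_second(kinetic_dataset(c(1, 2, 3), c(0, 1, 2))),
               "undefined")
})

test_that("two-segment diffusion fit recovers both segments and the breakpoint", {
  d <- gen_kinetics("intraparticle",
                    c(KIN_PARAMS$intraparticle, t_break = IPD_TSTAR),
                    t_points = IPD_GRID, noise_sd = 0)
  f <- fit_intraparticle(d, n_segments = 2)
  expect_rel_equal(f$parameters[["k1"]], 1058.6)
  expect_rel_equal(f$parameters[["C1"]], 82.59)
  expect_rel_equal(f$parameters[["k2"]], 77.12)
  expect_rel_equal(f$parameters[["C2"]], 317.0)
  expect_equal(f$details$breakpoint_time, IPD_TSTAR, tolerance = 1e-9)
})

test_that("one-segment diffusion fit is plain OLS in sqrt(t)", {
  t <- c(1, 4, 9, 16, 25)
  qt <- 12 * sqrt(t) + 7
  f <- fit_intraparticle(kinetic_dataset(t, qt), n_segments = 1)
  expect_equal(f$parameters[["k1"]], 12, tolerance = 1e-10)
  expect_equal(f$parameters[["C1"]], 7, tolerance = 1e-9)
  expect_error(fit_intraparticle(kinetic_dataset(c(1, 2, 3, 4, 5),
                                                 1:5), 2),
               "at least 6")
})

test_that("breakpoint search equals brute-force split enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    t <- sort(runif(12, 0.5, 90))
    qt <- cumsum(runif(12, 0, 50))
    d <- kinetic_dataset(t, qt)
    f <- fit_intraparticle(d, 2)
    x <- sqrt(t)
    best_sse <- Inf; best_i <- NA
    for (i in 3:(12 - 3)) {
      o1 <- ols_oracle(x[1:i], qt[1:i])
      o2 <- ols_oracle(x[(i + 1):12], qt[(i + 1):12])
      if (o1$sse + o2$sse < best_sse) {
        best_sse <- o1$sse + o2$sse; best_i <- i
      }
    }
    expect_equal(f$details$breakpoint_index, best_i)
    expect_equal(f$details$total_sse, best_sse, tolerance = 1e-9)
  }
})

test_that("two-segment SSE never exceeds the one-segment SSE", {
  set.seed(32)
  for (rep in 1:5) {
    t <- sort(runif(10, 1, 90))
    qt <- 100 * sqrt(t) + rnorm(10, 0, 20) + 200
    qt <- pmax(qt, 0)
    d <- kinetic_dataset(t, qt)
    f2 <- fit_intraparticle(d, 2)
    o1 <- ols_oracle(sqrt(t), qt)
    expect_lte(f2$details$total_sse, o1$sse + 1e-9)
  }
})

test_that("fractional power fit recovers parameters and flags v < 1", {
  d <- gen_kinetics("fractional_power", KIN_PARAMS$fractional_power,
                    noise_sd = 0)
  f <- fit_fractional_power(d)
  expect_rel_equal(f$parameters[["v"]], 0.283)
  expect_rel_equal(f$parameters[["KFP"]], 1264.4)
  expect_true(f$details$v_below_unity)
  # constant qt: exponent zero
  f0 <- fit_fractional_power(kinetic_dataset(c(1, 5, 20, 60), rep(7, 4)))
  expect_equal(f0$parameters[["v"]], 0, tolerance = 1e-12)
  # seeded noise vs OLS oracle
  d <- gen_kinetics("fractional_power", KIN_PARAMS$fractional_power,
                    noise_sd = 0.01, seed = 41)
  f <- fit_fractional_power(d)
  orc <- ols_oracle(log(d$t), log(d$qt))
  expect_equal(f$parameters[["v"]], orc$slope, tolerance = 1e-12)
  expect_equal(f$parameters[["KFP"]], exp(orc$intercept), tolerance = 1e-12)
})

test_that("Elovich fit recovers the simplified-form parameters", {
  d <- gen_kinetics("elovich", KIN_PARAMS$elovich, noise_sd = 0)
  f <- fit_elovich(d)
  expect_rel_equal(f$parameters[["alpha"]], 4136.2)
  expect_rel_equal(f$parameters[["beta"]], 0.001537)
  # slope on 3 exact points vs hand OLS; beta positive when qt rises in ln t
  t <- c(2, 6, 18)
  qt <- 40 + 11 * log(t)
  f3 <- fit_elovich(kinetic_dataset(t, qt))
  orc <- ols_oracle(log(t), qt)
  expect_equal(1 / f3$parameters[["beta"]], orc$slope, tolerance = 1e-10)
  expect_gt(f3$parameters[["beta"]], 0)
})

test_that("every kinetic linearization is exact on its own noise-free data", {
  cases <- list(
    list(model = "pseudo_first", fit = function(d) fit_pseudo_first(d, 2290)),
    list(model = "pseudo_second", fit = fit_pseudo_second),
    list(model = "fractional_power", fit = fit_fractional_power),
    list(model = "elovich", fit = fit_elovich)
  )
  for (cs in cases) {
    d <- gen_kinetics(cs$model, KIN_PARAMS[[cs$model]], noise_sd = 0)
    f <- cs$fit(d)
    truth <- unlist(KIN_PARAMS[[cs$model]])
    for (nm in names(truth))
      expect_rel_equal(f$parameters[[nm]], truth[[nm]])
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("estimates converge to generating values as noise decreases", {
  errs <- vapply(c(0.05, 0.01, 0.002), function(ns) {
    d <- gen_kinetics("pseudo_second", KIN_PARAMS$pseudo_second,
                      noise_sd = ns, seed = 8)
    f <- fit_pseudo_second(d)
    abs(f$parameters[["qe"]] - 4029) / 4029
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("model selection ranks PSO first and flags the PFO capacity gap", {
  d <- gen_kinetics("pseudo_second", KIN_PARAMS$pseudo_second,
                    noise_sd = 0.01, seed = 51, qe_exp = 4029)
  fits <- list(suppressMessages(fit_pseudo_first(d)),
               fit_pseudo_second(d),
               fit_fractional_power(d),
               fit_elovich(d))
  sel <- select_kinetic_model(fits, qe_exp = 4029)
  expect_equal(sel$model[1], "pseudo_second")
  expect_false(sel$flagged[sel$model == "pseudo_second"])

  # the tabulated rejection: fitted qe 2290 vs experimental 3900 (41% off)
  pfo <- model_fit("pseudo_first", c(qe = 2290, k1 = 0.011),
                   c(qe = 0, k1 = 0), r_squared = 0.915, "linearized")
  pso <- model_fit("pseudo_second", c(qe = 4029, k2 = 6.92e-5),
                   c(qe = 0, k2 = 0), r_squared = 0.999, "linearized")
  sel <- select_kinetic_model(list(pfo, pso), qe_exp = 3900)
  expect_true(sel$flagged[sel$model == "pseudo_first"])
  expect_false(sel$flagged[sel$model == "pseudo_second"])
  expect_equal(sel$qe_rel_dev[sel$model == "pseudo_first"],
               abs(2290 - 3900) / 3900, tolerance = 1e-12)

  # empty fit list: empty report
  sel0 <- select_kinetic_model(list(), qe_exp = 3900)
  expect_equal(nrow(sel0), 0)
})
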