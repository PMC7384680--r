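test_that("the lag adjustment function has the right limits and shape", {
  gp_nolag <- growth_params(K = 8e12, N0 = 1e11, mu_max = 0.005,
                            v = 10, m = 1, lambda = 0)
  expect_true(all(baranyi_adjustment(c(0, 10, 100), gp_nolag) == 1))
  expect_equal(baranyi_adjustment(20 * fx_gp[["lambda"]], fx_gp), 1,
               tolerance = 1e-9)
  # alpha starts near zero for a long lag
  expect_lt(baranyi_adjustment(0, fx_gp), 0.01)
  # monotone non-decreasing over random parameter draws
  set.seed(3)
  for (i in 1:15) {
    gp <- growth_params(K = 8e12, N0 = 1e11, mu_max = 0.005,
                        v = stats::runif(1, 0.002, 0.5), m = 1,
                        lambda = stats::runif(1, 100, 900))
    a <- baranyi_adjustment(seq(0, 3600, by = 10), gp)
    expect_true(all(diff(a) >= -1e-12))
    expect_true(all(a > 0 & a <= 1))
  }
})

test_that("population dynamics: initial condition, plateau, logistic limit", {
  pop <- baranyi_population(c(0, 1e7), fx_gp)
  expect_equal(pop$N[1], fx_gp[["N0"]], tolerance = 1e-9)
  expect_equal(pop$N[2], fx_gp[["K"]], tolerance = 1e-6)

  # m = 1, no lag: closed-form logistic
  gp <- growth_params(K = 8e12, N0 = 1e11, mu_max = 0.005,
                      v = 50, m = 1, lambda = 0)
  t <- seq(0, 3600, by = 60)
  N <- baranyi_population(t, gp)$N
  logistic <- function(t) {
    K <- 8e12; N0 <- 1e11; mu <- 0.005
    K * N0 * exp(mu * t) / (K + N0 * (exp(mu * t) - 1))
  }
  expect_equal(N, logistic(t), tolerance = 1e-8)
})

test_that("closed-form population matches numeric integration of the ODE", {
  for (seed in 1:5) {
    set.seed(seed)
    gp <- growth_params(K = stats::runif(1, 7.14e12, 9e12),
                        N0 = stats::runif(1, 5e10, 2e11),
                        mu_max = stats::runif(1, 0.0034, 0.0075),
                        v = stats::runif(1, 0.0015, 0.58),
                        m = stats::runif(1, 0.47, 2.46),
                        lambda = stats::runif(1, 330, 883))
    t <- seq(0, 3600, by = 120)
    rhs <- function(tt, y, parms) {
      a <- baranyi_adjustment(tt, gp)
      list(gp[["mu_max"]] * a * y * (1 - (y / gp[["K"]])^gp[["m"]]))
    }
    num <- deSolve::ode(y = gp[["N0"]], times = t, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-2)[, 2]
    expect_equal(baranyi_population(t, gp)$N, unname(num), tolerance = 1e-6)
  }
})

test_that("population is non-decreasing and mu bounded by mu_max", {
  set.seed(9)
  for (i in 1:10) {
    gp <- growth_params(K = 8e12, N0 = stats::runif(1, 5e10, 2e11),
                        mu_max = stats::runif(1, 0.0034, 0.0075),
                        v = stats::runif(1, 0.0015, 0.58),
                        m = stats::runif(1, 0.47, 2.46),
                        lambda = stats::runif(1, 330, 883))
    pop <- baranyi_population(seq(0, 3600, by = 30), gp)
    expect_true(all(diff(pop$N) >= -1e-9 * gp[["K"]]))
    expect_true(all(pop$mu <= gp[["mu_max"]] + 1e-12))
    expect_true(all(pop$mu >= 0))
  }
})

test_that("fit_growth recovers known parameters from 11 noiseless points", {
  obs <- gen_growth_obs(fx_gp, n_points = 11, noise_sd = 0)
  expect_identical(nrow(obs), 11L)
  fit <- fit_growth(obs, n_starts = 40, seed = 5)
  expect_lt(abs(fit$best[["K"]] / fx_gp[["K"]] - 1), 0.02)
  expect_lt(abs(fit$best[["lambda"]] / fx_gp[["lambda"]] - 1), 0.10)
  # refit on noiseless model output: residuals essentially zero
  expect_lt(fit$sse, 1e-6)
  expect_gte(nrow(fit$confidence_set), 1)
})

test_that("fit_growth rejects degenerate or insufficient input", {
  flat <- data.frame(time = seq(0, 3600, length.out = 11), N = rep(8e12, 11))
  expect_error(fit_growth(flat), "degenerate")
  few <- gen_growth_obs(fx_gp, n_points = 7, noise_sd = 0)[1:6, ]
  expect_error(fit_growth(few), "at least 7")
})

test_that("growth observations round-trip through delimited text", {
  obs <- gen_growth_obs(fx_gp, n_points = 11, noise_sd = 0.05, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_growth_obs(obs, path)
  back <- read_growth_obs(path)
  expect_equal(back$time, obs$time)
  expect_equal(back$N, obs$N, tolerance = 1e-12)
})
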