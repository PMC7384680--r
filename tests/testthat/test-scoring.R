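# small helper: a fake ok-simulation whose r/a trajectories are given
fake_sim <- function(times, r, a, C = NULL, OA_free = NULL) {
  traj <- matrix(0, nrow = length(times), ncol = length(species_names),
                 dimnames = list(NULL, species_names))
  traj[, "r"] <- r; traj[, "a"] <- a
  of <- if (is.null(OA_free)) rep(1, length(times)) else OA_free
  traj[, "OA_free"] <- of
  traj[, "OA_1"] <- 1 - of  # occupied fraction, so the operator total is 1
  if (!is.null(C)) traj[, "C"] <- C
  structure(list(status = "ok", times = times, trajectory = traj,
                 scenario = "C", diagnostics = NULL), class = "scb_sim")
}

simple_targets <- function(times, r, a, thr = 5, thr_sd = 1, scale = "none") {
  target_features(
    scbR = data.frame(time = times, value = r, sd = rep(0.5, length(times))),
    scbA = data.frame(time = times, value = a, sd = rep(0.5, length(times))),
    threshold = thr, threshold_sd = thr_sd, scale = scale)
}

test_that("a zero-residual fit attains the sum of normalisation constants", {
  times <- seq(0, 3600, by = 600)
  r <- 1 + sin(times / 800); a <- 2 + cos(times / 900)
  # OA_free dips below 0.5 then recovers exactly where C = 5
  frac <- c(1, 0.4, 0.2, 0.3, 0.6, 0.8, 1)
  C <- c(0, 1, 2, 3, 5, 7, 8)
  sim <- fake_sim(times, r, a, C = C, OA_free = frac)
  tgt <- simple_targets(times, r, a, thr = activation_threshold(sim))
  tll <- total_log_likelihood(sim, tgt)
  const <- 2 * length(times) * stats::dnorm(0, 0, 0.5, log = TRUE) +
    stats::dnorm(0, 0, 1, log = TRUE)
  expect_equal(tll, const, tolerance = 1e-9)
})

test_that("TLL equals a brute-force point-by-point summation", {
  set.seed(21)
  times <- seq(0, 3600, by = 300)
  sim <- fake_sim(times, r = stats::runif(length(times), 0, 10),
                  a = stats::runif(length(times), 0, 5),
                  C = seq(0, 10, length.out = length(times)),
                  OA_free = seq(0.9, 0.95, length.out = length(times)))
  tgt <- simple_targets(times, stats::runif(length(times), 0, 10),
                        stats::runif(length(times), 0, 5))
  # brute force, including the no-activation penalty at 10 sd
  brute <- 0
  for (i in seq_along(times)) {
    brute <- brute +
      stats::dnorm(sim$trajectory[i, "r"], tgt$scbR$value[i], 0.5, log = TRUE) +
      stats::dnorm(sim$trajectory[i, "a"], tgt$scbA$value[i], 0.5, log = TRUE)
  }
  brute <- brute + stats::dnorm(10 * 1, 0, 1, log = TRUE)
  expect_equal(total_log_likelihood(sim, tgt), unname(brute),
               tolerance = 1e-10)
})

test_that("TLL is monotone: growing any single residual lowers it", {
  times <- seq(0, 3600, by = 600)
  base_r <- rep(2, length(times))
  tgt <- simple_targets(times, base_r, base_r, thr = 1e9, thr_sd = 1e9)
  tll0 <- total_log_likelihood(fake_sim(times, base_r, base_r), tgt)
  for (k in c(2, 5)) {
    r <- base_r; r[k] <- r[k] + 1
    expect_lt(total_log_likelihood(fake_sim(times, r, base_r), tgt), tll0)
  }
})

test_that("failed simulations score -Inf and never pass", {
  failed <- structure(list(status = "solver_failed", times = fx_times,
                           trajectory = NULL, scenario = "C",
                           diagnostics = "x"), class = "scb_sim")
  tgt <- simple_targets(c(0, 100), c(1, 1), c(1, 1))
  expect_identical(total_log_likelihood(failed, tgt), -Inf)
})

test_that("the pass criterion is strictly greater than the threshold", {
  scores <- data.frame(member = c("1", "2", "3"), scenario = "C",
                       tll = c(-139.5, -140.0, -150), rank = c(1L, 2L, 3L),
                       pass = c(TRUE, FALSE, FALSE))
  rc <- rank_and_count(scores, threshold = -140)
  expect_identical(unname(rc$counts), 1)
  # and the score_ensemble path agrees
  expect_true(-139.5 > -140 && !(-140 > -140))
})

test_that("rank_and_count: failures, permutation invariance, identical profiles", {
  sc <- data.frame(member = as.character(1:6), scenario = rep(c("A", "B"), each = 3),
                   tll = c(-Inf, -Inf, -Inf, -10, -200, -90))
  rc <- rank_and_count(sc, threshold = -140)
  expect_identical(unname(rc$counts), c(0, 2))
  perm <- sc[sample(nrow(sc)), ]
  expect_identical(rank_and_count(perm, -140)$counts[order(names(rc$counts))],
                   rc$counts[order(names(rc$counts))])
  # two scenarios with identical trajectories give identical profiles
  sc2 <- data.frame(member = as.character(rep(1:3, 2)),
                    scenario = rep(c("G", "H"), each = 3),
                    tll = rep(c(-1, -2, -3), 2))
  p <- rank_and_count(sc2, -140)$profiles
  expect_identical(p$G, p$H)
})

test_that("predictive density: unit, zero and log-sum-exp oracle cases", {
  one <- data.frame(member = "1", scenario = "X", tll = 0)
  expect_equal(predictive_density(one)$predictive_density, 1)
  dead <- data.frame(member = c("1", "2"), scenario = "X", tll = c(-Inf, -Inf))
  expect_equal(predictive_density(dead)$predictive_density, 0)

  set.seed(5)
  tll <- stats::runif(100, -30, 0)
  df <- data.frame(member = as.character(1:100), scenario = "Y", tll = tll)
  naive <- mean(exp(tll))  # safe at this magnitude: the brute-force oracle
  expect_equal(predictive_density(df)$predictive_density, naive,
               tolerance = 1e-12)
})

test_that("logsumexp is overflow-safe and matches naive summation", {
  x <- c(-1000, -1001, -999)
  expect_equal(logsumexp(x), -999 + log(sum(exp(x + 999))), tolerance = 1e-12)
  expect_identical(logsumexp(c(-Inf, -Inf)), -Inf)
  expect_identical(logsumexp(numeric(0)), -Inf)
  big <- c(800, 801)
  expect_equal(logsumexp(big), 801 + log1p(exp(-1)), tolerance = 1e-12)
})

test_that("activation threshold picks the last upward de-repression crossing", {
  times <- seq(0, 600, by = 100)
  frac <- c(1, 0.3, 0.6, 0.3, 0.4, 0.7, 0.9)  # two upward crossings
  C <- 1:7
  sim <- fake_sim(times, rep(1, 7), rep(1, 7), C = C, OA_free = frac)
  thr <- activation_threshold(sim)
  # last crossing is between the 5th (0.4) and 6th (0.7) points
  w <- (0.5 - 0.4) / (0.7 - 0.4)
  expect_equal(thr, 5 + w * (6 - 5), tolerance = 1e-12)
  # monotonically free operator: no crossing
  sim2 <- fake_sim(times, rep(1, 7), rep(1, 7), C = C, OA_free = rep(1, 7))
  expect_true(is.na(activation_threshold(sim2)))
})

test_that("targets validate their inputs and round-trip through text files", {
  expect_error(target_features(
    data.frame(time = 0, value = 1, sd = 0),
    data.frame(time = 0, value = 1, sd = 1), 1, 1), "uncertainties")
  expect_error(target_features(
    data.frame(time = 4000, value = 1, sd = 1),
    data.frame(time = 0, value = 1, sd = 1), 1, 1), "horizon")
  tgt <- simple_targets(seq(0, 3600, by = 720), 1:6, 6:1)
  path <- tempfile(fileext = ".tsv")
  write_targets(tgt, path)
  back <- read_targets(path, scale = "none")
  expect_equal(back$scbR$value, tgt$scbR$value)
  expect_equal(back$threshold, tgt$threshold)
})
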