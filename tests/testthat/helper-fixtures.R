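# Shared fixtures: built once per test run, in code (no stored data).

fx_gp <- default_growth_params()
fx_truth <- true_parameter_set()

# coarse grid for cheap simulations (2 h steps still resolve the pulse)
fx_times <- seq(0, 3600, by = 120)

# a parameter set guaranteed valid but dynamically dull (prior medians)
fx_median_params <- default_params()

# random positive state over all species, operators summing to their copies
random_state <- function(seed) {
  set.seed(seed)
  y <- stats::setNames(stats::runif(18, 0, 50), species_names)
  o <- function(nms) {
    w <- stats::runif(length(nms)); w <- w / sum(w)
    y[nms] <<- w
  }
  o(c("OR_free", "OR_1", "OR_2"))
  o(c("OA_free", "OA_1", "OA_2"))
  o(c("OAp_free", "OAp_AR"))
  y
}

# random parameter set: log-normal jitter around the prior medians
random_params <- function(seed, sd = 0.5) {
  set.seed(seed)
  pr <- default_priors()
  parameter_set(stats::setNames(
    exp(pr$location + stats::rnorm(nrow(pr), 0, sd)), pr$parameter))
}

expect_sim_ok <- function(sim) {
  expect_s3_class(sim, "scb_sim")
  expect_identical(sim$status, "ok")
}
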