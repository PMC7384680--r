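test_that("K-S enrichment runs one test per sampled parameter (44) and is calibrated", {
  ens <- sample_ensemble(default_priors(), 400, seed = 17)
  set.seed(31)
  random_sel <- sample(400, 40)
  res <- ks_enrichment(ens, random_sel)
  expect_identical(nrow(res), 44L)
  expect_identical(attr(res, "n_tests"), 44L)
  # a uniformly random selection should show no Bonferroni-significant
  # parameter in a typical run (expected false positives ~ alpha)
  expect_identical(sum(res$significant), 0L)
})

test_that("K-S enrichment flags a constructed biased selection", {
  ens <- sample_ensemble(default_priors(), 400, seed = 17)
  biased <- which(ens$draws[, "d_A"] > stats::median(ens$draws[, "d_A"]))
  res <- ks_enrichment(ens, biased)
  expect_true(res$significant[res$parameter == "d_A"])
})

test_that("K-S enrichment validates its selection argument", {
  ens <- sample_ensemble(default_priors(), 50, seed = 1)
  expect_error(ks_enrichment(ens, integer(0)), "empty")
  expect_error(ks_enrichment(ens, 1:50), "strict subset")
  expect_error(ks_enrichment(ens, c(1, 99)), "outside")
})

test_that("type-I error of the Bonferroni procedure is controlled under random selection", {
  ens <- sample_ensemble(default_priors(), 200, seed = 5)
  set.seed(77)
  n_rep <- 200
  any_hit <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sel <- sample(200, 20)
    any_hit[i] <- any(ks_enrichment(ens, sel)$significant)
  }
  alpha <- 0.05
  mc_sd <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lte(mean(any_hit), alpha + 3 * mc_sd)
})

test_that("bin enrichment: self-comparison is null, extremes are flagged", {
  set.seed(4)
  prior_vals <- stats::rlnorm(2000, log(0.01), 1)
  # selected identical to the prior sample: all log-ratios 0, nothing flagged
  null_res <- bin_enrichment(prior_vals, prior_vals, n_bins = 10)
  expect_true(all(abs(null_res$log_ratio) < 1e-12))
  expect_false(any(null_res$significant))
  expect_equal(sum(null_res$expected), length(prior_vals))

  # all selected values concentrated in a narrow quantile window
  win <- stats::quantile(prior_vals, c(0.50, 0.55))
  sel <- prior_vals[prior_vals >= win[1] & prior_vals < win[2]]
  ext <- bin_enrichment(prior_vals, sel, n_bins = 8)
  hot <- ext$observed > 0
  expect_lte(sum(hot), 2)  # a 5% quantile window spans at most two log bins
  expect_true(all(ext$log_ratio[hot] > 0))
  expect_true(all(ext$significant[hot]))
  cold <- ext$observed == 0 & ext$expected > 5
  expect_true(any(cold))
  expect_true(all(ext$log_ratio[cold] == -Inf))
  expect_true(all(ext$significant[cold]))
})

test_that("bin enrichment detects enrichment of fast ScbA degradation (d_A > 0.01/min)", {
  ens <- sample_ensemble(default_priors(), 1000, seed = 23)
  dA <- ens$draws[, "d_A"]
  set.seed(6)
  # selection biased towards fast degradation, mirroring high-TLL models
  keep <- dA > 0.01 | stats::runif(1000) < 0.1
  res <- bin_enrichment(dA, dA[keep], n_bins = 12)
  hi_bins <- res$bin_lo >= 0.01
  lo_bins <- res$bin_hi <= 0.005
  expect_true(any(res$significant[hi_bins] & res$log_ratio[hi_bins] > 0))
  expect_true(any(res$significant[lo_bins] & res$log_ratio[lo_bins] < 0))
})

test_that("bin log-ratios are antisymmetric under swapping the two roles", {
  set.seed(9)
  pool <- stats::rlnorm(3000, 0, 1)
  a <- pool[1:1500]; b <- pool[1501:3000]
  # evaluate on the pooled support so bins match in both directions
  res_ab <- bin_enrichment(pool, a, n_bins = 8)
  res_ba <- bin_enrichment(pool, b, n_bins = 8)
  # a-vs-pool enrichment must mirror b-vs-pool depletion: each bin's pool
  # count splits between a and b (expected is scaled to n_sel = half pool)
  expect_equal(res_ab$observed + res_ba$observed, 2 * res_ab$expected,
               tolerance = 1e-12)
  # so a finite positive log-ratio in a implies depletion in b and vice versa
  fin <- is.finite(res_ab$log_ratio) & is.finite(res_ba$log_ratio) &
    abs(res_ab$log_ratio) > 1e-9
  expect_true(all(sign(res_ab$log_ratio[fin]) == -sign(res_ba$log_ratio[fin])))
})

test_that("BH step-up agrees with a brute-force implementation on random p-values", {
  brute_bh <- function(p, q) {
    n <- length(p); o <- order(p); flag <- logical(n)
    thresh <- 0
    for (k in seq_len(n)) if (p[o[k]] <= q * k / n) thresh <- k
    if (thresh > 0) flag[o[seq_len(thresh)]] <- TRUE
    flag
  }
  set.seed(13)
  for (i in 1:20) {
    p <- stats::runif(30)^stats::runif(1, 0.5, 3)
    q <- 0.05
    expect_identical(stats::p.adjust(p, "BH") < q, brute_bh(p, q))
  }
})

test_that("growth-parameter enrichment: null self-comparison and positive control", {
  set.seed(2)
  fits <- data.frame(K = stats::rlnorm(120, log(8e12), 0.05),
                     N0 = stats::rlnorm(120, log(1e11), 0.3),
                     mu_max = stats::rlnorm(120, log(0.005), 0.2),
                     v = stats::rlnorm(120, log(0.03), 0.5),
                     m = stats::rlnorm(120, log(1.2), 0.2),
                     lambda = stats::rlnorm(120, log(600), 0.25))
  null_res <- growth_param_enrichment(fits, fits)
  expect_identical(nrow(null_res), 6L)
  expect_identical(attr(null_res, "n_tests"), 6L)
  expect_false(any(null_res$significant))
  expect_true(all(null_res$p > 0.99))

  sel <- fits[fits$lambda > stats::quantile(fits$lambda, 0.75), ]
  pos <- growth_param_enrichment(fits, sel)
  expect_true(pos$significant[pos$parameter == "lambda"])
  expect_error(growth_param_enrichment(fits, fits[1, ]), "at least 2")
})
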