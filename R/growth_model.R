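#' Six-parameter Baranyi-Roberts growth model
#'
#' Culture growth over the 60 h experiment is described by the
#' Baranyi-Roberts model
#'
#'   dN/dt = mu_max * alpha(t) * N * (1 - (N/K)^m),   N(0) = N0,
#'
#' where `alpha(t)` is the lag-phase adjustment function (see
#' [baranyi_adjustment()]), `K` the carrying capacity, `mu_max` the maximum
#' specific growth rate, `v` the lag-to-exponential curvature, `m` the
#' exponential-to-stationary (Richards) curvature, and `lambda` the lag
#' time. Times are in minutes, populations in cells.
#'
#' @param K carrying capacity, cells.
#' @param N0 initial population, cells (`N0 < K`).
#' @param mu_max maximum specific growth rate, 1/min.
#' @param v lag-to-exponential curvature, 1/min.
#' @param m exponential-to-stationary curvature (dimensionless).
#' @param lambda lag phase, min (>= 0).
#' @return named numeric vector of class `growth_params`.
#' @examples
#' gp <- growth_params(K = 8e12, N0 = 1e11, mu_max = 0.005,
#'                     v = 0.03, m = 1.2, lambda = 600)
#' baranyi_population(c(0, 1800, 3600), gp)
#' @export
growth_params <- function(K, N0, mu_max, v, m, lambda) {
  x <- vapply(list(K = K, N0 = N0, mu_max = mu_max, v = v, m = m,
                   lambda = lambda), function(z) as.numeric(z)[1], numeric(1))
  lambda <- x[["lambda"]]
  if (any(!is.finite(x)) || any(x[c("K", "N0", "mu_max", "v", "m")] <= 0) ||
      lambda < 0)
    stop("growth parameters must be finite and positive (lambda >= 0)",
         call. = FALSE)
  if (N0 >= K) stop("N0 must be smaller than the carrying capacity K",
                    call. = FALSE)
  structure(x, class = c("growth_params", "numeric"))
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  x <- unlist(x)
  do.call(growth_params, as.list(x[c("K", "N0", "mu_max", "v", "m", "lambda")]))
}

#' Baranyi lag-phase adjustment function
#'
#' `alpha(t) = q(t) / (1 + q(t))` with `q(t) = q0 * exp(v t)` and
#' `q0 = 1 / (exp(v lambda) - 1)`, so that `alpha` rises from ~0 during the
#' lag phase to 1 for `t >> lambda`, with sharpness controlled by `v`.
#' For `lambda = 0` the adjustment is identically 1 (no lag).
#'
#' @param t time, min (vector, >= 0).
#' @param gp [growth_params()].
#' @return `alpha(t)` in (0, 1].
#' @export
baranyi_adjustment <- function(t, gp) {
  gp <- as_growth_params(gp)
  v <- gp[["v"]]; lam <- gp[["lambda"]]
  if (lam <= 0) return(rep(1, length(t)))
  # alpha = e^{vt} / (e^{v lambda} - 1 + e^{vt}), computed on log scale
  log_denom_part <- v * lam + log1p(-exp(-v * lam))  # log(e^{v lam} - 1)
  a <- exp(v * t - .logadd(log_denom_part, v * t))
  unname(pmin(a, 1))
}

# log(exp(a) + exp(b)), elementwise, overflow-safe
.logadd <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# integral of alpha from 0 to t (Baranyi's adjusted time A(t))
.baranyi_A <- function(t, gp) {
  v <- gp[["v"]]; lam <- gp[["lambda"]]
  if (lam <= 0) return(t)
  q0 <- 1 / expm1(v * lam)
  # A(t) = t + (1/v) log((e^{-vt} + q0) / (1 + q0))
  t + (log(exp(-v * t) + q0) - log1p(q0)) / v
}

#' Population size and specific growth rate
#'
#' Closed-form solution of the Baranyi-Roberts ODE (log-space Richards
#' growth on the adjusted time scale `A(t)`):
#'
#'   `N(t) = K / (1 + ((K/N0)^m - 1) * exp(-m mu_max A(t)))^(1/m)`
#'
#' and `mu(t) = (dN/dt)/N = mu_max * alpha(t) * (1 - (N/K)^m)`.
#'
#' @inheritParams baranyi_adjustment
#' @return data.frame with columns `time`, `N` (cells), `mu` (1/min).
#' @export
baranyi_population <- function(t, gp) {
  gp <- as_growth_params(gp)
  K <- gp[["K"]]; N0 <- gp[["N0"]]; mu_max <- gp[["mu_max"]]; m <- gp[["m"]]
  A <- .baranyi_A(t, gp)
  # log-scale evaluation keeps (K/N0)^m finite for large m
  x <- m * mu_max * A
  log_gap <- m * log(K / N0)                       # log((K/N0)^m), > 0
  log_term <- log_gap + log1p(-exp(-log_gap)) - x  # log(((K/N0)^m - 1) e^{-x})
  log_one_plus <- .logadd(rep(0, length(x)), log_term)
  N <- K * exp(-log_one_plus / m)
  alpha <- baranyi_adjustment(t, gp)
  mu <- mu_max * alpha * (1 - (N / K)^m)
  data.frame(time = t, N = unname(N), mu = unname(pmax(mu, 0)))
}

#' Fit the Baranyi-Roberts model to growth observations
#'
#' Multi-start nonlinear least squares (Levenberg-Marquardt on
#' log-transformed parameters, residuals on log10 cell counts, matching the
#' multiplicative error structure of biomass-derived counts). All starts
#' whose SSE is within `sse_tol` of the best constitute the returned
#' confidence set - with few observations (the reference experiment has 11)
#' many distinct parameter sets fit the curve comparably well.
#'
#' @param obs data.frame with columns `time` (min) and `N` (cells); at least
#'   7 observations (more observations than parameters).
#' @param n_starts number of random starting points.
#' @param seed integer seed for start generation.
#' @param sse_tol retain fits with `SSE <= sse_tol * min(SSE)` (default 1.05).
#' @param start_ranges optional named list of `c(lo, hi)` ranges for the six
#'   parameters; defaults span the plausible culture-growth ranges.
#' @return list of class `growth_fit`: `best` ([growth_params()]),
#'   `confidence_set` (data.frame, one row per retained fit + `sse`),
#'   `sse`, `residuals`, `n_converged`.
#' @export
fit_growth <- function(obs, n_starts = 40, seed = 1, sse_tol = 1.05,
                       start_ranges = NULL) {
  stopifnot(is.data.frame(obs), all(c("time", "N") %in% names(obs)))
  obs <- obs[is.finite(obs$time) & is.finite(obs$N) & obs$N > 0, ]
  if (nrow(obs) < 7)
    stop("need at least 7 observations to fit 6 growth parameters",
         call. = FALSE)
  if (stats::sd(log(obs$N)) < 1e-6)
    stop("degenerate observations: no growth signal (all counts equal)",
         call. = FALSE)
  if (is.null(start_ranges)) {
    start_ranges <- list(
      K      = c(max(obs$N), 3 * max(obs$N)),
      N0     = c(min(obs$N) / 3, 3 * min(obs$N)),
      mu_max = c(1e-3, 1e-2),
      v      = c(1e-3, 0.6),
      m      = c(0.4, 2.5),
      lambda = c(60, 1200)
    )
  }
  par_names <- c("K", "N0", "mu_max", "v", "m", "lambda")
  resid_fun <- function(logp) {
    p <- exp(logp); names(p) <- par_names
    if (p["N0"] >= p["K"]) return(rep(1e3, nrow(obs)))
    N <- tryCatch(baranyi_population(obs$time, growth_params(
      p["K"], p["N0"], p["mu_max"], p["v"], p["m"], p["lambda"]))$N,
      error = function(e) NULL)
    if (is.null(N) || any(!is.finite(N)) || any(N <= 0))
      return(rep(1e3, nrow(obs)))
    log10(N) - log10(obs$N)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    start <- vapply(start_ranges, function(r)
      exp(stats::runif(1, log(r[1]), log(r[2]))), numeric(1))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(start), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- exp(fit$par); names(p) <- par_names
      fits[[i]] <- c(p, sse = sum(fit$fvec^2))
    }
  }
  fits <- do.call(rbind, fits)
  fits <- fits[is.finite(fits[, "sse"]) & fits[, "sse"] < 1e5, , drop = FALSE]
  if (is.null(fits) || nrow(fits) == 0)
    stop("no start converged; inspect the observations or widen start_ranges",
         call. = FALSE)
  fits <- fits[order(fits[, "sse"]), , drop = FALSE]
  keep <- fits[, "sse"] <= sse_tol * fits[1, "sse"] + 1e-12
  conf <- as.data.frame(fits[keep, , drop = FALSE])
  best <- growth_params(conf$K[1], conf$N0[1], conf$mu_max[1],
                        conf$v[1], conf$m[1], conf$lambda[1])
  structure(list(best = best, confidence_set = conf,
                 sse = conf$sse[1],
                 residuals = resid_fun(log(unclass(best))),
                 n_converged = nrow(fits)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: best SSE %.4g, %d fit(s) in confidence set>\n",
              x$sse, nrow(x$confidence_set)))
  print(round(unclass(x$best), 6))
  invisible(x)
}

#' Read/write growth observations as 2-column delimited text
#' @param path file path; tab-separated with header `time`, `N`.
#' @param obs data.frame with columns `time`, `N`.
#' @return `read_growth_obs` returns the data.frame.
#' @export
read_growth_obs <- function(path) {
  obs <- utils::read.delim(path)
  stopifnot(all(c("time", "N") %in% names(obs)))
  obs
}

#' @rdname read_growth_obs
#' @export
write_growth_obs <- function(obs, path) {
  utils::write.table(obs[, c("time", "N")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# RNG bookkeeping: restore the caller's RNG state after seeded internals
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
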