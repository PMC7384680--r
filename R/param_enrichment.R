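#' Kolmogorov-Smirnov enrichment of sampled parameters
#'
#' For each sampled parameter, compares its distribution among a selected
#' member subset (typically the members with TLL above the pass threshold)
#' against the full ensemble draws with a two-sample K-S test. The
#' family-wise error rate is controlled by a strict Bonferroni correction:
#' significance at `alpha` divided by the number of tested parameters (44
#' in the default configuration).
#'
#' @param ens [sample_ensemble()] result.
#' @param selected integer indices of the selected members (non-empty,
#'   strict subset).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame: `parameter`, `statistic`, `p`, `significant`
#'   (Bonferroni at `alpha / n_tests`); attribute `n_tests`.
#' @export
ks_enrichment <- function(ens, selected, alpha = 0.05) {
  stopifnot(inherits(ens, "scb_ensemble"))
  selected <- unique(as.integer(selected))
  if (!length(selected)) stop("empty selection", call. = FALSE)
  if (any(selected < 1 | selected > ens$n))
    stop("selection indices outside the ensemble", call. = FALSE)
  if (length(selected) >= ens$n)
    stop("selection must be a strict subset of the ensemble", call. = FALSE)
  pars <- colnames(ens$draws)
  n_tests <- length(pars)
  res <- do.call(rbind, lapply(pars, function(pn) {
    kt <- suppressWarnings(
      stats::ks.test(ens$draws[selected, pn], ens$draws[, pn]))
    data.frame(parameter = pn, statistic = unname(kt$statistic),
               p = kt$p.value)
  }))
  res$significant <- res$p < alpha / n_tests
  attr(res, "n_tests") <- n_tests
  attr(res, "alpha") <- alpha
  res
}

#' Bin-wise enrichment with two-tailed binomial tests
#'
#' Divides a parameter's sampled range into bins (log-spaced by default,
#' appropriate for rate parameters), computes the expected per-bin
#' probability from the full ensemble's empirical distribution, the
#' observed counts from the selected members, the log-ratio
#' `log2(observed / expected count)`, and a two-tailed binomial test per
#' bin. P-values are corrected across the bins of the parameter by
#' Benjamini-Hochberg at FDR `fdr` (Bonferroni available via `method`).
#' Bins with zero expected probability are merged into their left
#' neighbour.
#'
#' @param prior_values parameter values of the full ensemble.
#' @param selected_values values among the selected members.
#' @param n_bins number of bins (>= 3).
#' @param log_bins log-spaced bin edges (default TRUE).
#' @param fdr false discovery rate for BH (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return data.frame: `bin_lo`, `bin_hi`, `expected`, `observed`,
#'   `log_ratio` (log2; `-Inf`/`Inf` for empty cells), `p`, `p_adj`,
#'   `significant`.
#' @export
bin_enrichment <- function(prior_values, selected_values, n_bins = 20,
                           log_bins = TRUE, fdr = 0.05,
                           method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(n_bins >= 3, length(prior_values) > 0, length(selected_values) > 0)
  rng <- range(prior_values)
  if (log_bins) {
    stopifnot(rng[1] > 0)
    edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  edges[1] <- edges[1] * (1 - 1e-12) - 1e-300
  edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-12)
  exp_counts <- as.numeric(table(cut(prior_values, edges)))
  # merge empty-expectation bins leftwards so every kept bin is testable
  keep_lo <- edges[-length(edges)]; keep_hi <- edges[-1]
  while (any(exp_counts == 0) && length(exp_counts) > 1) {
    i <- which(exp_counts == 0)[1]
    j <- if (i == 1) 2 else i - 1
    exp_counts[j] <- exp_counts[j] + exp_counts[i]
    keep_lo[j] <- min(keep_lo[j], keep_lo[i])
    keep_hi[j] <- max(keep_hi[j], keep_hi[i])
    exp_counts <- exp_counts[-i]; keep_lo <- keep_lo[-i]; keep_hi <- keep_hi[-i]
  }
  p_exp <- exp_counts / length(prior_values)
  n_sel <- length(selected_values)
  obs <- vapply(seq_along(p_exp), function(i)
    sum(selected_values >= keep_lo[i] & selected_values < keep_hi[i]),
    numeric(1))
  expected_n <- p_exp * n_sel
  log_ratio <- log2(obs / expected_n)
  p <- vapply(seq_along(obs), function(i)
    stats::binom.test(obs[i], n_sel, p_exp[i],
                      alternative = "two.sided")$p.value, numeric(1))
  p_adj <- stats::p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
  data.frame(bin_lo = keep_lo, bin_hi = keep_hi,
             expected = expected_n, observed = obs,
             log_ratio = log_ratio, p = p, p_adj = p_adj,
             significant = p_adj < fdr)
}

#' Two-sample K-S comparison of growth-parameter sets
#'
#' The growth parameters are not sampled from priors but fitted to the
#' growth data, so enrichment among high-TLL members is assessed by a
#' two-sample K-S test between the initially assigned fits and the fits of
#' the selected members, Bonferroni-corrected over the six growth
#' parameters.
#'
#' @param initial_fits data.frame of growth parameters, one row per member
#'   (columns `K`, `N0`, `mu_max`, `v`, `m`, `lambda`).
#' @param selected_fits subset data.frame for the selected members.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: `parameter`, `statistic`, `p`, `significant`.
#' @export
growth_param_enrichment <- function(initial_fits, selected_fits, alpha = 0.05) {
  pars <- c("K", "N0", "mu_max", "v", "m", "lambda")
  initial_fits <- as.data.frame(initial_fits)
  selected_fits <- as.data.frame(selected_fits)
  stopifnot(all(pars %in% names(initial_fits)),
            all(pars %in% names(selected_fits)))
  if (nrow(initial_fits) < 2 || nrow(selected_fits) < 2)
    stop("need at least 2 parameter vectors in each set", call. = FALSE)
  res <- do.call(rbind, lapply(pars, function(pn) {
    kt <- suppressWarnings(
      stats::ks.test(selected_fits[[pn]], initial_fits[[pn]]))
    data.frame(parameter = pn, statistic = unname(kt$statistic),
               p = kt$p.value)
  }))
  res$significant <- res$p < alpha / length(pars)
  attr(res, "n_tests") <- length(pars)
  res
}

#' Full enrichment report for a scored run
#'
#' Combines the K-S parameter tests, the per-parameter bin-wise binomial
#' enrichment, and (when per-member growth parameters were used) the
#' growth-parameter K-S comparison.
#'
#' @param ens [sample_ensemble()] result.
#' @param scores `score_table` restricted to one scenario (or with a
#'   `scenario` argument below).
#' @param scenario scenario label to report on.
#' @param growth optional data.frame of per-member growth parameters.
#' @param n_bins bins per parameter for [bin_enrichment()].
#' @param alpha,fdr significance settings.
#' @return list of class `enrichment_report`: `ks` (data.frame), `bins`
#'   (named list of data.frames per parameter), `growth` (data.frame or
#'   NULL), `selected` (member indices), `scenario`.
#' @export
enrichment_report <- function(ens, scores, scenario, growth = NULL,
                              n_bins = 20, alpha = 0.05, fdr = 0.05) {
  stopifnot(inherits(ens, "scb_ensemble"))
  sc <- scores[scores$scenario == scenario, ]
  if (!nrow(sc)) stop("no scores for scenario ", scenario, call. = FALSE)
  # only numeric member ids index the ensemble (injected members excluded)
  idx <- suppressWarnings(as.integer(sc$member))
  sel <- idx[!is.na(idx) & sc$pass]
  if (!length(sel))
    stop("no passing members in scenario ", scenario,
         "; nothing to enrich", call. = FALSE)
  ks <- ks_enrichment(ens, sel, alpha = alpha)
  bins <- lapply(colnames(ens$draws), function(pn)
    bin_enrichment(ens$draws[, pn], ens$draws[sel, pn],
                   n_bins = n_bins, fdr = fdr))
  names(bins) <- colnames(ens$draws)
  gr <- NULL
  if (!is.null(growth)) {
    growth <- as.data.frame(growth)
    if (nrow(growth) >= max(sel))
      gr <- tryCatch(
        growth_param_enrichment(growth, growth[sel, , drop = FALSE],
                                alpha = alpha),
        error = function(e) NULL)
  }
  structure(list(ks = ks, bins = bins, growth = gr, selected = sel,
                 scenario = scenario),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report scenario %s: %d selected members>\n",
              x$scenario, length(x$selected)))
  sig <- x$ks$parameter[x$ks$significant]
  cat("K-S significant (Bonferroni): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write an enrichment report to CSV files
#' @param report [enrichment_report()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_enrichment <- function(report, dir) {
  stopifnot(inherits(report, "enrichment_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$ks, file.path(dir, "ks_tests.csv"),
                   row.names = FALSE)
  bins <- do.call(rbind, lapply(names(report$bins), function(pn)
    cbind(parameter = pn, report$bins[[pn]])))
  utils::write.csv(bins, file.path(dir, "bin_enrichment.csv"),
                   row.names = FALSE)
  if (!is.null(report$growth))
    utils::write.csv(report$growth, file.path(dir, "growth_ks.csv"),
                     row.names = FALSE)
  invisible(dir)
}
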