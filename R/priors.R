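#' Log-normal prior specification helpers
#'
#' Each sampled parameter carries an independent log-normal prior specified
#' by `location` (log of the median) and `scale` (log-scale standard
#' deviation). Priors are elicited from a most-plausible value (the median)
#' and a plausible range interpreted as the central 95% interval, so
#' `scale = (log(hi) - log(lo)) / (2 * 1.96)`.
#'
#' @param parameter parameter id.
#' @param median most plausible value (prior median, > 0).
#' @param lo,hi bounds of the central 95% plausible range (`lo < hi`).
#' @param units unit string.
#' @param note free-text provenance note.
#' @return one-row data.frame with columns `parameter`, `location`,
#'   `scale`, `units`, `note`.
#' @export
prior_from_range <- function(parameter, median, lo, hi, units = "", note = "") {
  stopifnot(median > 0, lo > 0, hi > lo)
  data.frame(parameter = parameter, location = log(median),
             scale = (log(hi) - log(lo)) / (2 * stats::qnorm(0.975)),
             units = units, note = note, stringsAsFactors = FALSE)
}

#' Default prior table for the 44 sampled parameters
#'
#' Reconstructed defaults spanning literature-plausible ranges for
#' actinomycete transcription, translation, protein/mRNA turnover and
#' TetR-operator binding kinetics; every entry can be overridden via
#' [read_priors()]. Rate-parameter ranges are deliberately wide (typically
#' two orders of magnitude, 95% central mass) so that enrichment analyses
#' have signal to detect: e.g. the ScbA degradation rate `d_A` spans
#' 1e-3 - 1e-1 /min and the GBL synthesis rate `k_C` spans 1e-3 - 10 /min.
#'
#' @return data.frame with one row per sampled parameter: `parameter`,
#'   `location`, `scale`, `units`, `note`.
#' @export
default_priors <- function() {
  pr <- rbind(
    prior_from_range("k_FA", 1, 0.1, 10, "1/min", "scbA promoter firing"),
    prior_from_range("chi", 1, 0.1, 10, "-", "promoter strength ratio k_FR/k_FA"),
    prior_from_range("aspect_R", 1, 0.2, 5, "-", "interference susceptibility, scbR"),
    prior_from_range("aspect_A", 1, 0.2, 5, "-", "interference susceptibility, scbA"),
    prior_from_range("k_elong", 10, 1, 100, "1/min", "RNAP clearance of the 53 bp overlap"),
    prior_from_range("f_rep1_R", 0.1, 0.01, 1, "-", "residual transcription, 1 dimer on O_R"),
    prior_from_range("f_rep2_R", 0.01, 0.001, 0.1, "-", "residual transcription, 2 dimers on O_R"),
    prior_from_range("f_rep1_A", 0.1, 0.01, 1, "-", "residual transcription, 1 dimer on O_A"),
    prior_from_range("f_rep2_A", 0.01, 0.001, 0.1, "-", "residual transcription, 2 dimers on O_A"),
    prior_from_range("k_leak_r", 0.01, 0.001, 0.1, "1/min", "basal scbR initiation"),
    prior_from_range("k_leak_a", 0.01, 0.001, 0.1, "1/min", "basal scbA initiation"),
    prior_from_range("k_on1", 0.01, 0.001, 0.1, "1/(nM min)", "R2 on free O_R"),
    prior_from_range("K_d1", 10, 1, 100, "nM", "first dimer on O_R"),
    prior_from_range("k_on7", 0.01, 0.001, 0.1, "1/(nM min)", "R2 on occupied O_R"),
    prior_from_range("K_d7", 20, 2, 200, "nM", "second dimer on O_R"),
    prior_from_range("k_on2", 0.01, 0.001, 0.1, "1/(nM min)", "R2 on free O_A"),
    prior_from_range("K_d2", 5, 0.5, 50, "nM", "first dimer on O_A"),
    prior_from_range("k_on8", 0.01, 0.001, 0.1, "1/(nM min)", "R2 on occupied O_A"),
    prior_from_range("K_d8", 10, 1, 100, "nM", "second dimer on O_A"),
    prior_from_range("k_TL_r", 0.3, 0.03, 3, "1/min", "ScbR synthesis per r"),
    prior_from_range("k_TL_a", 0.3, 0.03, 3, "1/min", "ScbA synthesis per a"),
    prior_from_range("k_dim", 0.001, 1e-4, 0.01, "1/(molec min)", "ScbR dimerisation"),
    prior_from_range("k_undim", 0.01, 0.001, 0.1, "1/min", "dimer dissociation"),
    prior_from_range("k_C", 0.1, 0.001, 10, "1/min", "GBL synthesis per A"),
    prior_from_range("k_CR_on", 1e-4, 1e-5, 1e-3, "1/(nM^2 min)", "C2R2 formation"),
    prior_from_range("k_CR_off", 0.01, 0.001, 0.1, "1/min", "C2R2 dissociation"),
    prior_from_range("k_diff", 0.1, 0.01, 1, "1/min", "membrane diffusion of C"),
    prior_from_range("d_r", 0.1, 0.02, 0.5, "1/min", "r mRNA turnover (t1/2 ~ 7 min)"),
    prior_from_range("d_a", 0.1, 0.02, 0.5, "1/min", "a mRNA turnover"),
    prior_from_range("d_R", 0.003, 3e-4, 0.03, "1/min", "ScbR monomer turnover"),
    prior_from_range("d_R2", 0.003, 3e-4, 0.03, "1/min", "ScbR dimer turnover"),
    prior_from_range("d_A", 0.01, 0.001, 0.1, "1/min", "ScbA turnover (dA)"),
    prior_from_range("d_C", 0.001, 1e-4, 0.01, "1/min", "GBL degradation (both compartments)"),
    prior_from_range("d_C2R2", 0.003, 3e-4, 0.03, "1/min", "C2R2 turnover"),
    prior_from_range("k_as", 0.002, 2e-4, 0.02, "1/(molec min)", "duplex formation"),
    prior_from_range("k_as_off", 0.01, 0.001, 0.1, "1/min", "duplex dissociation"),
    prior_from_range("d_ra", 0.5, 0.1, 2.5, "1/min", "duplex degradation (fast)"),
    prior_from_range("k_AR_on", 0.001, 1e-4, 0.01, "1/(molec min)", "AR formation"),
    prior_from_range("k_AR_off", 0.01, 0.001, 0.1, "1/min", "AR dissociation"),
    prior_from_range("d_AR", 0.01, 0.001, 0.1, "1/min", "AR turnover"),
    prior_from_range("k_OAp_on", 0.01, 0.001, 0.1, "1/(molec min)", "AR on O_A'"),
    prior_from_range("k_OAp_off", 0.1, 0.01, 1, "1/min", "AR off O_A'"),
    prior_from_range("f_RA", 5, 1, 25, "-", "scbA activation fold via O_A'"),
    prior_from_range("f_Ract", 5, 1, 25, "-", "scbA activation fold via R2-bound O_A")
  )
  stopifnot(identical(sort(pr$parameter), sort(parameter_names("sampled"))))
  pr
}

#' Draw a reproducible ensemble of parameter sets
#'
#' Independent log-normal draws per parameter (no cross-parameter
#' correlation), shared across all scenarios of a study. The same seed and
#' prior table reproduce the ensemble bitwise.
#'
#' @param priors prior table as from [default_priors()].
#' @param n number of parameter sets (>= 1).
#' @param seed integer seed.
#' @return object of class `scb_ensemble`: list with `draws` (n x p matrix,
#'   columns in prior-table order), `priors`, `n`, `seed`.
#' @export
sample_ensemble <- function(priors = default_priors(), n, seed) {
  n <- as.integer(n)
  stopifnot(n >= 1, nrow(priors) >= 1)
  need <- parameter_names("sampled")
  missing <- setdiff(need, priors$parameter)
  if (length(missing))
    stop("no prior defined for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(priors$scale < 0))
    stop("prior scales must be >= 0", call. = FALSE)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(nrow(priors)), function(j)
    stats::rlnorm(n, meanlog = priors$location[j], sdlog = priors$scale[j]),
    numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, priors$parameter))
  structure(list(draws = draws, priors = priors, n = n,
                 seed = as.integer(seed)),
            class = "scb_ensemble")
}

#' @export
print.scb_ensemble <- function(x, ...) {
  cat(sprintf("<scb_ensemble: %d draws x %d parameters (seed %d)>\n",
              x$n, ncol(x$draws), x$seed))
  invisible(x)
}

#' Constrain the ratio of two parameters in an ensemble
#'
#' Rejection-resamples the ensemble until all members satisfy
#' `lo <= param_a / param_b <= hi`, preserving the conditional joint
#' distribution (marginals of unrelated parameters are untouched). Used to
#' realise promoter-strength sweep arms such as `k_FR > k_FA` (chi in
#' (1, 10]) versus `k_FR < k_FA`.
#'
#' @param ens [sample_ensemble()] result.
#' @param param_a,param_b column names; `param_b = NULL` constrains
#'   `param_a` itself to the range.
#' @param ratio_range numeric `c(lo, hi)`.
#' @param max_tries resampling batches before giving up.
#' @return new `scb_ensemble` with the same `n`.
#' @export
constrain_ratio <- function(ens, param_a, param_b = NULL,
                            ratio_range, max_tries = 1000) {
  stopifnot(inherits(ens, "scb_ensemble"), length(ratio_range) == 2)
  lo <- ratio_range[1]; hi <- ratio_range[2]
  cols <- colnames(ens$draws)
  if (!param_a %in% cols || (!is.null(param_b) && !param_b %in% cols))
    stop("parameter not present in the ensemble", call. = FALSE)
  if (lo == hi) {
    # degenerate range: enforce the ratio exactly
    draws <- ens$draws
    draws[, param_a] <- if (is.null(param_b)) lo else lo * draws[, param_b]
    out <- ens
    out$draws <- draws
    out$constraint <- list(param_a = param_a, param_b = param_b,
                           range = ratio_range)
    return(out)
  }
  ratio_of <- function(m)
    if (is.null(param_b)) m[, param_a] else m[, param_a] / m[, param_b]
  ok <- function(m) ratio_of(m) >= lo & ratio_of(m) <= hi
  acc <- ens$draws[ok(ens$draws), , drop = FALSE]
  tries <- 0; subseed <- ens$seed
  while (nrow(acc) < ens$n && tries < max_tries) {
    tries <- tries + 1
    subseed <- (subseed + 7919 * tries) %% .Machine$integer.max
    extra <- sample_ensemble(ens$priors, ens$n, seed = subseed)$draws
    acc <- rbind(acc, extra[ok(extra), , drop = FALSE])
  }
  if (nrow(acc) < ens$n)
    stop(sprintf("feasible set for %s in [%g, %g] is (near-)empty",
                 if (is.null(param_b)) param_a
                 else paste0(param_a, "/", param_b), lo, hi), call. = FALSE)
  structure(list(draws = acc[seq_len(ens$n), , drop = FALSE],
                 priors = ens$priors, n = ens$n, seed = ens$seed,
                 constraint = list(param_a = param_a, param_b = param_b,
                                   range = ratio_range)),
            class = "scb_ensemble")
}

#' Complete one ensemble member to a full parameter set
#'
#' @param ens [sample_ensemble()] result.
#' @param i member index.
#' @return [parameter_set()] for member `i` (fixed structural constants and
#'   derived entries added).
#' @export
member_params <- function(ens, i) {
  stopifnot(inherits(ens, "scb_ensemble"), i >= 1, i <= ens$n)
  parameter_set(ens$draws[i, ])
}

#' Read and write prior tables as delimited text
#'
#' Tab-separated with columns `parameter`, `median`, `lo`, `hi`, `units`,
#' `note`; the 95% plausible range (`lo`, `hi`) is converted to the
#' log-normal scale on reading. Round-trips exactly through
#' [write_priors()].
#'
#' @param path file path.
#' @param priors prior table (`location`/`scale` form).
#' @return `read_priors` returns a prior table like [default_priors()].
#' @export
read_priors <- function(path) {
  tb <- utils::read.delim(path)
  stopifnot(all(c("parameter", "median", "lo", "hi") %in% names(tb)))
  do.call(rbind, lapply(seq_len(nrow(tb)), function(i)
    prior_from_range(tb$parameter[i], tb$median[i], tb$lo[i], tb$hi[i],
                     if ("units" %in% names(tb)) tb$units[i] else "",
                     if ("note" %in% names(tb)) tb$note[i] else "")))
}

#' @rdname read_priors
#' @export
write_priors <- function(priors, path) {
  z <- stats::qnorm(0.975)
  out <- data.frame(
    parameter = priors$parameter,
    median = exp(priors$location),
    lo = exp(priors$location - z * priors$scale),
    hi = exp(priors$location + z * priors$scale),
    units = priors$units, note = priors$note
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
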