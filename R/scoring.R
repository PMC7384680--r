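#' Target features for the prior predictive check
#'
#' The features a simulated ensemble member is compared against: the time
#' profiles of the *scbR* and *scbA* transcripts and the activation
#' threshold of the GBL system (the butyrolactone concentration at which
#' the *scbA* operator is de-repressed).
#'
#' Transcript targets are compared as normalised profiles: both target and
#' simulated profiles are scaled to a maximum of 1 per observable
#' (`scale = "max"`, the default), mirroring how array-style transcript
#' intensities are related to absolute per-cell copy numbers only up to an
#' observable-specific factor. `scale = "none"` compares raw values.
#'
#' @param scbR,scbA data.frames with columns `time` (min), `value`, `sd`
#'   (uncertainty, > 0).
#' @param threshold GBL activation threshold target, nM.
#' @param threshold_sd its uncertainty, nM (> 0).
#' @param scale `"max"` or `"none"` (see above).
#' @return object of class `target_features`.
#' @export
target_features <- function(scbR, scbA, threshold, threshold_sd,
                            scale = c("max", "none")) {
  scale <- match.arg(scale)
  check <- function(tb, nm) {
    stopifnot(is.data.frame(tb), all(c("time", "value", "sd") %in% names(tb)))
    if (any(tb$sd <= 0)) stop(nm, ": uncertainties must be > 0", call. = FALSE)
    if (any(tb$time < 0 | tb$time > 3600))
      stop(nm, ": target times must lie within the simulation horizon",
           call. = FALSE)
    tb[order(tb$time), c("time", "value", "sd")]
  }
  stopifnot(is.finite(threshold), threshold_sd > 0)
  structure(list(scbR = check(scbR, "scbR"), scbA = check(scbA, "scbA"),
                 threshold = threshold, threshold_sd = threshold_sd,
                 species_map = c(scbR = "r", scbA = "a"), scale = scale),
            class = "target_features")
}

#' Read/write target features as delimited text
#'
#' Tab-separated, columns `observable` (`scbR`, `scbA` or `threshold`),
#' `time_min` (NA for the threshold row), `value`, `sd`.
#' @param path file path.
#' @param targets [target_features()] object.
#' @param ... passed to [target_features()] (e.g. `scale`).
#' @return `read_targets` returns a [target_features()] object.
#' @export
read_targets <- function(path, ...) {
  tb <- utils::read.delim(path)
  stopifnot(all(c("observable", "time_min", "value", "sd") %in% names(tb)))
  grab <- function(obs) {
    z <- tb[tb$observable == obs, ]
    data.frame(time = z$time_min, value = z$value, sd = z$sd)
  }
  th <- tb[tb$observable == "threshold", ]
  if (nrow(th) != 1) stop("exactly one threshold row required", call. = FALSE)
  target_features(grab("scbR"), grab("scbA"), th$value, th$sd, ...)
}

#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  stopifnot(inherits(targets, "target_features"))
  rows <- rbind(
    data.frame(observable = "scbR", time_min = targets$scbR$time,
               value = targets$scbR$value, sd = targets$scbR$sd),
    data.frame(observable = "scbA", time_min = targets$scbA$time,
               value = targets$scbA$value, sd = targets$scbA$sd),
    data.frame(observable = "threshold", time_min = NA,
               value = targets$threshold, sd = targets$threshold_sd)
  )
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Activation threshold of a simulated trajectory
#'
#' The GBL concentration at which the system switches on: the intracellular
#' butyrolactone concentration `C` at the time the unrepressed fraction of
#' the *scbA* operator (`OA_free / total O_A`) crosses 0.5 from below (the
#' last such upward crossing, i.e. the de-repression event after the
#' repressed phase). Returns `NA` if the operator never recovers past 0.5
#' after having been repressed below it.
#'
#' @param sim an `scb_sim` with `status == "ok"`.
#' @return threshold concentration, nM, or `NA`.
#' @export
activation_threshold <- function(sim) {
  stopifnot(inherits(sim, "scb_sim"))
  if (sim$status != "ok") return(NA_real_)
  tr <- sim$trajectory
  tot <- tr[, "OA_free"] + tr[, "OA_1"] + tr[, "OA_2"]
  frac <- ifelse(tot > 0, tr[, "OA_free"] / tot, NA_real_)
  up <- which(frac[-length(frac)] < 0.5 & frac[-1] >= 0.5)
  if (!length(up)) return(NA_real_)
  i <- up[length(up)]
  # linear interpolation of C at the crossing
  w <- (0.5 - frac[i]) / (frac[i + 1] - frac[i])
  unname(tr[i, "C"] + w * (tr[i + 1, "C"] - tr[i, "C"]))
}

.profile_at <- function(sim, species, at_times) {
  j <- match(at_times, sim$times)
  if (any(is.na(j)))
    return(stats::approx(sim$times, sim$trajectory[, species],
                         xout = at_times, rule = 2)$y)
  sim$trajectory[j, species]
}

.scale_profile <- function(x, mode) {
  if (mode == "none") return(x)
  m <- max(x)
  if (m <= 0) x else x / m
}

#' Total log-likelihood of one simulation against the targets
#'
#' Sum of independent Gaussian log-densities over every transcript target
#' point plus the activation-threshold term. Normalisation constants are
#' included, so TLL is an absolute quantity comparable across members and
#' scenarios. Failed simulations score `-Inf`; a missing activation event
#' is penalised deterministically at 10 target uncertainties.
#'
#' @param sim an `scb_sim`.
#' @param targets a [target_features()] object.
#' @return total log-likelihood (finite real or `-Inf`).
#' @export
total_log_likelihood <- function(sim, targets) {
  stopifnot(inherits(sim, "scb_sim"), inherits(targets, "target_features"))
  if (sim$status != "ok") return(-Inf)
  tll <- 0
  for (obs in c("scbR", "scbA")) {
    tb <- targets[[obs]]
    y_sim <- .scale_profile(
      .profile_at(sim, targets$species_map[[obs]], tb$time), targets$scale)
    y_tgt <- .scale_profile(tb$value, targets$scale)
    sd <- tb$sd / if (targets$scale == "max") max(max(tb$value), 1e-12) else 1
    tll <- tll + sum(stats::dnorm(y_sim, y_tgt, sd, log = TRUE))
  }
  thr <- activation_threshold(sim)
  dev <- if (is.na(thr)) 10 * targets$threshold_sd else thr - targets$threshold
  tll + stats::dnorm(dev, 0, targets$threshold_sd, log = TRUE)
}

#' Score a simulated ensemble
#'
#' @param simset [run_ensemble()] result.
#' @param targets [target_features()].
#' @param threshold pass criterion: member passes if `TLL > threshold`
#'   (strict). Default -140.
#' @return data.frame of class `score_table`: `member`, `scenario`, `tll`,
#'   `rank` (within scenario, 1 = best), `pass`.
#' @export
score_ensemble <- function(simset, targets, threshold = -140) {
  stopifnot(inherits(simset, "scb_simset"))
  rows <- list()
  for (sc in simset$scenarios) {
    tll <- vapply(simset$results[[sc]],
                  function(s) total_log_likelihood(s, targets), numeric(1))
    rows[[sc]] <- data.frame(
      member = simset$member_ids, scenario = sc, tll = unname(tll),
      rank = rank(-tll, ties.method = "min"),
      pass = unname(tll > threshold)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("score_table", "data.frame")
  out
}

#' Per-scenario pass counts and sorted likelihood profiles
#'
#' Because every scenario is run on the identical parameter sets, the pass
#' counts are directly comparable across scenarios (the ensemble-robustness
#' comparison of the prior predictive check).
#'
#' @param scores a `score_table` (from [score_ensemble()]).
#' @param threshold pass criterion, strict (`TLL > threshold`); defaults to
#'   the threshold stored in the score table, or -140.
#' @return list: `counts` (named vector, passing members per scenario),
#'   `profiles` (list of descending TLL vectors per scenario), `threshold`.
#' @export
rank_and_count <- function(scores, threshold = NULL) {
  stopifnot(is.data.frame(scores), all(c("scenario", "tll") %in% names(scores)))
  if (is.null(threshold))
    threshold <- if (!is.null(attr(scores, "threshold")))
      attr(scores, "threshold") else -140
  sc_levels <- unique(scores$scenario)
  counts <- vapply(sc_levels, function(sc)
    sum(scores$tll[scores$scenario == sc] > threshold), numeric(1))
  profiles <- lapply(sc_levels, function(sc)
    sort(scores$tll[scores$scenario == sc], decreasing = TRUE))
  names(profiles) <- sc_levels
  list(counts = counts, profiles = profiles, threshold = threshold)
}

#' Predictive density (ensemble-average likelihood) per scenario
#'
#' The mean of `exp(TLL)` over all members of a scenario's ensemble,
#' computed with overflow-safe log-sum-exp; failed members (TLL `-Inf`)
#' contribute zero likelihood but stay in the denominator.
#'
#' @param scores a `score_table`.
#' @return data.frame: `scenario`, `log_predictive_density`,
#'   `predictive_density`.
#' @export
predictive_density <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("scenario", "tll") %in% names(scores)))
  sc_levels <- unique(scores$scenario)
  lpd <- vapply(sc_levels, function(sc) {
    tll <- scores$tll[scores$scenario == sc]
    logsumexp(tll) - log(length(tll))
  }, numeric(1))
  data.frame(scenario = sc_levels, log_predictive_density = unname(lpd),
             predictive_density = exp(unname(lpd)))
}

#' Overflow-safe log(sum(exp(x)))
#' @param x numeric vector (may contain `-Inf`).
#' @return scalar; `-Inf` for an empty or all-`-Inf` input.
#' @export
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Write a score table as CSV
#' @param scores `score_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
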