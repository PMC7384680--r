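#' Simulate one parameter set under one scenario
#'
#' Integrates the scenario ODEs over the culture horizon (default 60 h,
#' `0..3600` min) with a stiff implicit solver (deSolve's BDF family).
#' Solver failures and non-physical excursions never raise: they are
#' recorded in the result `status` so downstream scoring can assign a
#' non-calculable likelihood.
#'
#' @param params [parameter_set()] (or named vector of sampled values).
#' @param scenario scenario label or [scb_scenario()].
#' @param gp [growth_params()].
#' @param times output time grid, min; must be non-empty, within the
#'   simulation horizon and start at 0.
#' @param rtol,atol solver tolerances.
#' @param method deSolve method; `"bdf"` (default) or any [deSolve::ode()]
#'   method string.
#' @return object of class `scb_sim`: list with `status` (`"ok"`,
#'   `"solver_failed"` or `"nonphysical"`), `times`, `trajectory`
#'   (time x species matrix, clipped to >= 0 on output), `scenario`,
#'   `diagnostics`.
#' @examples
#' gp <- default_growth_params()
#' sim <- simulate_member(default_params(), "C", gp, times = seq(0, 3600, 60))
#' sim$status
#' @export
simulate_member <- function(params, scenario, gp, times = seq(0, 3600, by = 60),
                            rtol = 1e-6, atol = 1e-9, method = "bdf") {
  if (length(times) < 2 || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be an increasing grid with at least two points",
         call. = FALSE)
  params <- if (inherits(params, "scb_params")) params else parameter_set(params)
  sc <- as_scenario(scenario)
  net <- build_network(sc)
  y0 <- initial_state(net, params)
  rhs <- make_rhs(params, sc, gp)
  # capture.output: the Fortran cores report step failures on the console
  invisible(utils::capture.output(
    out <- tryCatch(
      suppressWarnings(
        deSolve::ode(y = unname(y0), times = times, func = rhs, parms = NULL,
                     method = method, rtol = rtol, atol = atol)),
      error = function(e) e
    ), type = "output"))
  fail <- function(status, msg) structure(
    list(status = status, times = times, trajectory = NULL,
         scenario = sc$label, diagnostics = msg), class = "scb_sim")
  if (inherits(out, "error")) return(fail("solver_failed", conditionMessage(out)))
  if (nrow(out) < length(times) || any(!is.finite(out[, -1])))
    return(fail("solver_failed", "integration did not span the grid"))
  traj <- out[, -1, drop = FALSE]
  colnames(traj) <- species_names
  if (min(traj) < -1e-6 * max(1, max(abs(traj))))
    return(fail("nonphysical", sprintf("negative excursion %.3g", min(traj))))
  traj[traj < 0] <- 0
  structure(list(status = "ok", times = times, trajectory = traj,
                 scenario = sc$label, diagnostics = NULL),
            class = "scb_sim")
}

#' @export
print.scb_sim <- function(x, ...) {
  cat(sprintf("<scb_sim scenario %s: %s, %d time points>\n",
              x$scenario, x$status, length(x$times)))
  invisible(x)
}

#' Simulate an ensemble across scenarios
#'
#' Runs every (member, scenario) pair with the identical parameter sets, so
#' cross-scenario comparisons are paired by member. Per-member growth
#' parameters may be supplied (one row of a growth-fit confidence set per
#' member); results are independent of execution order.
#'
#' @param ens [sample_ensemble()] result.
#' @param scenarios character vector of scenario labels (subset of A-H).
#' @param gp a single [growth_params()], or a data.frame /matrix with one
#'   row per member (columns `K`, `N0`, `mu_max`, `v`, `m`, `lambda`).
#' @param times output grid, min.
#' @param members optional integer subset of members to run.
#' @param extra_members optional named list of additional full parameter
#'   sets (e.g. an injected ground-truth member); they are appended after
#'   the ensemble members with the supplied names as member ids.
#' @param ... passed to [simulate_member()].
#' @return list of class `scb_simset`: `results` (nested list
#'   `[[scenario]][[member]]` of `scb_sim`), `member_ids`, `scenarios`,
#'   `growth` (the per-member growth parameters actually used).
#' @export
run_ensemble <- function(ens, scenarios, gp, times = seq(0, 3600, by = 60),
                         members = NULL, extra_members = NULL, ...) {
  stopifnot(inherits(ens, "scb_ensemble"))
  scenarios <- vapply(scenarios, function(s) as_scenario(s)$label, "",
                      USE.NAMES = FALSE)
  if (is.null(members)) members <- seq_len(ens$n)
  member_ids <- c(as.character(members), names(extra_members))
  psets <- c(lapply(members, function(i) member_params(ens, i)),
             lapply(extra_members, parameter_set))
  n_tot <- length(psets)
  gp_rows <- .growth_per_member(gp, n_tot)
  results <- lapply(scenarios, function(sc) {
    sims <- lapply(seq_len(n_tot), function(k)
      simulate_member(psets[[k]], sc, gp_rows[[k]], times = times, ...))
    names(sims) <- member_ids
    sims
  })
  names(results) <- scenarios
  structure(list(results = results, member_ids = member_ids,
                 scenarios = scenarios, growth = gp_rows, times = times),
            class = "scb_simset")
}

.growth_per_member <- function(gp, n) {
  if (inherits(gp, "growth_params")) return(rep(list(gp), n))
  gp <- as.data.frame(gp)
  need <- c("K", "N0", "mu_max", "v", "m", "lambda")
  stopifnot(all(need %in% names(gp)))
  if (nrow(gp) == 1) return(rep(list(as_growth_params(gp[1, need])), n))
  if (nrow(gp) != n)
    stop("per-member growth parameters must have one row per member",
         call. = FALSE)
  lapply(seq_len(n), function(i) as_growth_params(gp[i, need]))
}

#' @export
print.scb_simset <- function(x, ...) {
  n_ok <- sum(vapply(unlist(x$results, recursive = FALSE),
                     function(s) s$status == "ok", logical(1)))
  cat(sprintf("<scb_simset: %d members x %d scenario(s), %d/%d ok>\n",
              length(x$member_ids), length(x$scenarios), n_ok,
              length(x$member_ids) * length(x$scenarios)))
  invisible(x)
}

#' Write simulated trajectories as tidy CSV
#'
#' Long format: `member`, `scenario`, `time_min`, `species`, `value`.
#' @param simset [run_ensemble()] result.
#' @param path output CSV path.
#' @param species optional subset of species columns.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(simset, path, species = NULL) {
  stopifnot(inherits(simset, "scb_simset"))
  rows <- list()
  for (sc in simset$scenarios) for (id in simset$member_ids) {
    sim <- simset$results[[sc]][[id]]
    if (sim$status != "ok") next
    sp <- if (is.null(species)) colnames(sim$trajectory) else species
    for (s in sp) rows[[length(rows) + 1L]] <- data.frame(
      member = id, scenario = sc, time_min = sim$times,
      species = s, value = sim$trajectory[, s])
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
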