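#' @title Species and reaction catalogue of the GBL circuit meta-model
#' @name reaction_network
#' @description
#' The meta-model tracks 18 species in two compartments. Intracellular
#' molecular species are in molecules/cell, the intracellular GBL pool `C`
#' and the extracellular pool `Ce` in nM (conversion via the fixed cell
#' volume), operator states in copies/cell:
#'
#' * `r`, `a` - full-length *scbR* / *scbA* mRNA; `ra` - their
#'   sense-antisense duplex (AS mechanism only)
#' * `R`, `R2` - ScbR monomer and homodimer; `A` - ScbA protein
#' * `C`, `Ce` - intra-/extracellular gamma-butyrolactone
#' * `C2R2` - SCB-bound (deactivated) ScbR dimer; `AR` - ScbA-ScbR complex
#'   (RA mechanism only)
#' * `OR_free/OR_1/OR_2`, `OA_free/OA_1/OA_2` - the scbR and scbA operators
#'   with 0, 1 or 2 bound ScbR dimers
#' * `OAp_free/OAp_AR` - the hypothetical O_A' activator operator (RA only)
#'
#' The full meta-model (scenario H) has 41 reactions and 51 parameters;
#' disabling a mechanism removes its reactions (and thereby the production
#' routes of its species, which stay at zero).
NULL

species_names <- c("r", "a", "ra", "R", "R2", "A", "C", "Ce", "C2R2", "AR",
                   "OR_free", "OR_1", "OR_2", "OA_free", "OA_1", "OA_2",
                   "OAp_free", "OAp_AR")

#' Species table of the meta-model
#' @return data.frame: `species`, `compartment` (`cell`/`environment`),
#'   `units`, `mechanism` (`core`, `AS` or `RA` for mechanism-specific
#'   species).
#' @export
species_table <- function() {
  data.frame(
    species = species_names,
    compartment = ifelse(species_names == "Ce", "environment", "cell"),
    units = ifelse(species_names %in% c("C", "Ce"), "nM",
                   ifelse(grepl("^O", species_names), "copies/cell",
                          "molecules/cell")),
    mechanism = ifelse(species_names == "ra", "AS",
                       ifelse(species_names %in% c("AR", "OAp_free", "OAp_AR"),
                              "RA", "core")),
    stringsAsFactors = FALSE
  )
}

# Reaction catalogue. `stoich` is the net change in each species' native
# units per reaction event; the compiled stoichiometry matrix scales the C
# row by the molecules->nM conversion (C-involving rates are per-cell
# molecular events; C_mol = C/conv appears where C reacts in molecule
# terms). Rate expressions reference species, parameters, the precomputed
# escape probabilities esc_r/esc_a and the mechanism flags as_f/ra_f/ract_f.
.reaction_catalogue <- function() {
  rx <- function(id, name, mech, stoich, rate, params)
    list(id = id, name = name, mechanism = mech, stoich = stoich,
         rate = rate, params = params)
  list(
    rx(1, "tx_r_free", "core", c(r = 1),
       quote((k_FR + k_leak_r) * esc_r * OR_free),
       c("k_FR", "k_leak_r", "chi", "k_FA", "aspect_R", "k_elong")),
    rx(2, "tx_r_one", "core", c(r = 1),
       quote((k_FR * f_rep1_R + k_leak_r) * esc_r * OR_1),
       c("k_FR", "f_rep1_R", "k_leak_r")),
    rx(3, "tx_r_two", "core", c(r = 1),
       quote((k_FR * f_rep2_R + k_leak_r) * esc_r * OR_2),
       c("k_FR", "f_rep2_R", "k_leak_r")),
    rx(4, "tx_a_free", "core", c(a = 1),
       quote((k_FA + k_leak_a) * esc_a * OA_free),
       c("k_FA", "k_leak_a", "aspect_A", "k_elong")),
    rx(5, "tx_a_one", "core", c(a = 1),
       quote((k_FA * f_rep1_A + k_leak_a) * esc_a * OA_1),
       c("k_FA", "f_rep1_A", "k_leak_a")),
    rx(6, "tx_a_two", "core", c(a = 1),
       quote((k_FA * f_rep2_A + k_leak_a) * esc_a * OA_2),
       c("k_FA", "f_rep2_A", "k_leak_a")),
    rx(7, "bind_OR_1", "core", c(R2 = -1, OR_free = -1, OR_1 = 1),
       quote(k_on1 * R2_nM * OR_free), c("k_on1", "V_cell")),
    rx(8, "unbind_OR_1", "core", c(R2 = 1, OR_free = 1, OR_1 = -1),
       quote(k_on1 * K_d1 * OR_1), c("k_on1", "K_d1")),
    rx(9, "bind_OR_2", "core", c(R2 = -1, OR_1 = -1, OR_2 = 1),
       quote(k_on7 * R2_nM * OR_1), c("k_on7")),
    rx(10, "unbind_OR_2", "core", c(R2 = 1, OR_1 = 1, OR_2 = -1),
       quote(k_on7 * K_d7 * OR_2), c("k_on7", "K_d7")),
    rx(11, "bind_OA_1", "core", c(R2 = -1, OA_free = -1, OA_1 = 1),
       quote(k_on2 * R2_nM * OA_free), c("k_on2")),
    rx(12, "unbind_OA_1", "core", c(R2 = 1, OA_free = 1, OA_1 = -1),
       quote(k_on2 * K_d2 * OA_1), c("k_on2", "K_d2")),
    rx(13, "bind_OA_2", "core", c(R2 = -1, OA_1 = -1, OA_2 = 1),
       quote(k_on8 * R2_nM * OA_1), c("k_on8")),
    rx(14, "unbind_OA_2", "core", c(R2 = 1, OA_1 = 1, OA_2 = -1),
       quote(k_on8 * K_d8 * OA_2), c("k_on8", "K_d8")),
    rx(15, "translate_r", "core", c(R = 1), quote(k_TL_r * r), c("k_TL_r")),
    rx(16, "translate_a", "core", c(A = 1), quote(k_TL_a * a), c("k_TL_a")),
    rx(17, "dimerise", "core", c(R = -2, R2 = 1),
       quote(k_dim * R * R), c("k_dim")),
    rx(18, "undimerise", "core", c(R = 2, R2 = -1),
       quote(k_undim * R2), c("k_undim")),
    rx(19, "synthesise_C", "core", c(C = 1),
       quote(k_C * A), c("k_C")),
    rx(20, "bind_C2R2", "core", c(C = -2, R2 = -1, C2R2 = 1),
       quote(k_CR_on * C * C * R2), c("k_CR_on")),
    rx(21, "unbind_C2R2", "core", c(C = 2, R2 = 1, C2R2 = -1),
       quote(k_CR_off * C2R2), c("k_CR_off")),
    rx(22, "export_C", "core", c(C = -1),
       quote(k_diff * C_mol), c("k_diff", "V_env")),
    rx(23, "import_C", "core", c(C = 1),
       quote(k_diff * Ce_mol), c("k_diff")),
    rx(24, "deg_r", "core", c(r = -1), quote(d_r * r), c("d_r")),
    rx(25, "deg_a", "core", c(a = -1), quote(d_a * a), c("d_a")),
    rx(26, "deg_R", "core", c(R = -1), quote(d_R * R), c("d_R")),
    rx(27, "deg_R2", "core", c(R2 = -1), quote(d_R2 * R2), c("d_R2")),
    rx(28, "deg_A", "core", c(A = -1), quote(d_A * A), c("d_A")),
    rx(29, "deg_C", "core", c(C = -1), quote(d_C * C_mol), c("d_C")),
    rx(30, "deg_Ce", "core", c(Ce = -1), quote(d_Ce * Ce), c("d_Ce")),
    rx(31, "deg_C2R2", "core", c(C2R2 = -1),
       quote(d_C2R2 * C2R2), c("d_C2R2")),
    rx(32, "duplex_form", "AS", c(r = -1, a = -1, ra = 1),
       quote(as_f * k_as * r * a), c("k_as")),
    rx(33, "duplex_dissociate", "AS", c(r = 1, a = 1, ra = -1),
       quote(as_f * k_as_off * ra), c("k_as_off")),
    rx(34, "deg_duplex", "AS", c(ra = -1),
       quote(as_f * d_ra * ra), c("d_ra")),
    rx(35, "AR_form", "RA", c(A = -1, R2 = -1, AR = 1),
       quote(ra_f * k_AR_on * A * R2), c("k_AR_on")),
    rx(36, "AR_dissociate", "RA", c(A = 1, R2 = 1, AR = -1),
       quote(ra_f * k_AR_off * AR), c("k_AR_off")),
    rx(37, "deg_AR", "RA", c(AR = -1), quote(ra_f * d_AR * AR), c("d_AR")),
    rx(38, "bind_OAp", "RA", c(AR = -1, OAp_free = -1, OAp_AR = 1),
       quote(ra_f * k_OAp_on * AR * OAp_free), c("k_OAp_on", "n_OAp")),
    rx(39, "unbind_OAp", "RA", c(AR = 1, OAp_free = 1, OAp_AR = -1),
       quote(ra_f * k_OAp_off * OAp_AR), c("k_OAp_off")),
    rx(40, "tx_a_RA_act", "RA", c(a = 1),
       quote(ra_f * fx_RA * k_FA * esc_a * OAp_AR), c("f_RA")),
    rx(41, "tx_a_Ract", "Ract", c(a = 1),
       quote(ract_f * fx_Ract * k_FA * f_rep1_A * esc_a * OA_1),
       c("f_Ract"))
  )
}

#' Assemble the reaction network for one scenario
#'
#' Starts from the 41-reaction meta-model and removes the reactions of
#' disabled mechanisms (AS duplex kinetics; RA complex, O_A' binding and
#' RA-activated transcription; the R_act activated-transcription channel),
#' together with their parameters. Removing a mechanism removes the only
#' production routes of its species, which therefore remain at zero.
#'
#' @param scenario a [scb_scenario()] or a label `"A"`-`"H"`.
#' @return object of class `scb_network`: list with `scenario`, `species`
#'   (see [species_table()]), `reactions` (list; each has `id`, `name`,
#'   `mechanism`, `stoich`, `rate` expression, `params`), `parameters`
#'   (character), `n_reactions`, `n_parameters`.
#' @examples
#' net <- build_network("H")
#' net$n_reactions    # 41
#' net$n_parameters   # 51
#' @export
build_network <- function(scenario) {
  sc <- as_scenario(scenario)
  keep_mech <- c("core", if (sc$AS) "AS", if (sc$RA) "RA", if (sc$Ract) "Ract")
  rxns <- Filter(function(r) r$mechanism %in% keep_mech, .reaction_catalogue())
  pcat <- parameter_catalogue()
  pars <- pcat$parameter[pcat$mechanism %in% keep_mech]
  structure(list(
    scenario = sc,
    species = species_table(),
    reactions = rxns,
    parameters = pars,
    n_reactions = length(rxns),
    n_parameters = length(pars)
  ), class = "scb_network")
}

#' @export
print.scb_network <- function(x, ...) {
  cat(sprintf("<scb_network scenario %s: %d reactions, %d parameters, %d species>\n",
              x$scenario$label, x$n_reactions, x$n_parameters,
              nrow(x$species)))
  invisible(x)
}

#' Initial state of a scenario network
#'
#' All species start at zero except the operators: one copy of each gene
#' per cell, hence one free copy of each operator (and of O_A' in RA
#' scenarios).
#'
#' @param network an [build_network()] result.
#' @param params optional [parameter_set()] supplying operator copy numbers
#'   (`n_OR`, `n_OA`, `n_OAp`); defaults to 1 copy each.
#' @return named numeric state vector over all 18 meta-model species.
#' @export
initial_state <- function(network, params = NULL) {
  stopifnot(inherits(network, "scb_network"))
  n <- if (is.null(params)) c(n_OR = 1, n_OA = 1, n_OAp = 1)
       else params[c("n_OR", "n_OA", "n_OAp")]
  y <- stats::setNames(numeric(length(species_names)), species_names)
  y["OR_free"] <- n[["n_OR"]]
  y["OA_free"] <- n[["n_OA"]]
  if (network$scenario$RA) y["OAp_free"] <- n[["n_OAp"]]
  y
}

# Compile the full meta-model stoichiometry matrix (species x 41).
# The C row is scaled by conv (rates of C-involving reactions are per-cell
# molecular events, C itself is carried in nM).
.stoich_matrix <- function(conv) {
  rxns <- .reaction_catalogue()
  S <- matrix(0, nrow = length(species_names), ncol = length(rxns),
              dimnames = list(species_names, vapply(rxns, `[[`, "", "name")))
  for (j in seq_along(rxns))
    S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich
  S["C", ] <- S["C", ] * conv
  S
}

.CELL_IDX <- which(species_names != "Ce")
.OP_IDX <- which(grepl("^O", species_names))
.CE_IDX <- which(species_names == "Ce")

# fast scalar N(t)/mu(t) closure for the RHS
.growth_fun <- function(gp) {
  gp <- as_growth_params(gp)
  K <- gp[["K"]]; N0 <- gp[["N0"]]; mu_max <- gp[["mu_max"]]
  v <- gp[["v"]]; m <- gp[["m"]]; lam <- gp[["lambda"]]
  q0 <- if (lam > 0) 1 / expm1(v * lam) else Inf
  log_gap <- m * log(K / N0)
  lg1 <- log_gap + log1p(-exp(-log_gap))
  ld <- if (lam > 0) v * lam + log1p(-exp(-v * lam)) else -Inf
  function(t) {
    A <- if (lam <= 0) t else t + (log(exp(-v * t) + q0) - log1p(q0)) / v
    lt <- lg1 - m * mu_max * A
    lop <- if (lt > 30) lt else log1p(exp(lt))
    N <- K * exp(-lop / m)
    alpha <- if (lam <= 0) 1 else {
      mx <- max(ld, v * t)
      exp(v * t - (mx + log1p(exp(min(ld, v * t) - mx))))
    }
    c(N = N, mu = max(mu_max * alpha * (1 - (N / K)^m), 0))
  }
}

#' Compile a scenario's ODE right-hand side
#'
#' Builds a fast derivative function for [deSolve::ode()]. The dynamics
#' combine (i) the mass-action reaction fluxes of the meta-model
#' (mechanism flags zero the rates of disabled mechanisms, so all scenarios
#' share one stoichiometry matrix and scenario-nesting equivalences hold
#' exactly), (ii) transcription initiation modulated by operator occupancy
#' and mutual transcriptional interference (see [interference_escape()]),
#' (iii) growth coupling: dilution of every intracellular species at the
#' instantaneous specific growth rate `mu(t)`, operator replication (DNA
#' duplication) at the same rate so operator copies per cell are conserved,
#' and (iv) accumulation of exported GBL in the medium, scaled by the cell
#' number `N(t)` and the volume ratio.
#'
#' @param params [parameter_set()].
#' @param scenario [scb_scenario()] or label.
#' @param gp [growth_params()].
#' @return function `(t, y, parms)` returning `list(dy)`, suitable for
#'   deSolve; `y` must be the 18-species state vector of [initial_state()].
#' @export
make_rhs <- function(params, scenario, gp) {
  params <- if (inherits(params, "scb_params")) params else parameter_set(params)
  sc <- as_scenario(scenario)
  p <- as.list(unclass(params))
  conv <- molecules_to_nM(p$V_cell)
  S <- .stoich_matrix(conv)
  as_f <- as.numeric(sc$AS); ra_f <- as.numeric(sc$RA)
  ract_f <- as.numeric(sc$Ract)
  fx_RA <- max(p$f_RA, 1) - 1      # activation folds below 1 act as neutral
  fx_Ract <- max(p$f_Ract, 1) - 1
  convE <- conv * p$V_cell / p$V_env  # molecules/cell/min -> nM/min in medium
  growth <- .growth_fun(gp)
  cell_idx <- .CELL_IDX; op_idx <- .OP_IDX; ce <- .CE_IDX

  env <- list2env(p, parent = baseenv())
  env$as_f <- as_f; env$ra_f <- ra_f; env$ract_f <- ract_f
  env$fx_RA <- fx_RA; env$fx_Ract <- fx_Ract; env$conv <- conv

  rates <- .compile_rates(env)

  function(t, y, parms = NULL) {
    y <- pmax(y, 0)  # solver hygiene: clip transient negative excursions
    v <- rates(y)
    dy <- as.vector(S %*% v)
    g <- growth(t)
    mu <- g[[2]]
    dy[cell_idx] <- dy[cell_idx] - mu * y[cell_idx]  # dilution by growth
    dy[op_idx] <- dy[op_idx] + mu * y[op_idx]        # DNA duplication
    dy[ce] <- dy[ce] + convE * g[[1]] * (v[[22]] - v[[23]])
    list(dy)
  }
}

# Build the 41-rate evaluator from the catalogue expressions (single source
# of truth for the dynamics); parameters and flags are pre-bound in `env`.
.compile_rates <- function(env) {
  rxns <- .reaction_catalogue()
  idx <- lapply(seq_along(species_names), function(i) bquote(y[.(i)]))
  names(idx) <- species_names
  pre <- c(
    idx,
    list(
      R2_nM = quote(conv * y[5]),
      C_mol = quote(y[7] / conv),
      Ce_mol = quote(y[8] / conv),
      OR_tot = quote(y[11] + y[12] + y[13]),
      OA_tot = quote(y[14] + y[15] + y[16]),
      f_R_fire = quote(
        if (OR_tot > 0)
          k_FR * (OR_free + f_rep1_R * OR_1 + f_rep2_R * OR_2) / OR_tot +
            k_leak_r else 0),
      f_A_fire = quote(
        if (OA_tot > 0)
          (k_FA * (OA_free + f_rep1_A * OA_1 + f_rep2_A * OA_2) +
             ract_f * fx_Ract * k_FA * f_rep1_A * OA_1 +
             ra_f * fx_RA * k_FA * OAp_AR) / OA_tot + k_leak_a else 0),
      esc_r = quote(1 / (1 + aspect_R * f_A_fire / k_elong)),
      esc_a = quote(1 / (1 + aspect_A * f_R_fire / k_elong))
    )
  )
  assigns <- mapply(function(nm, ex) call("<-", as.name(nm), ex),
                    names(pre), pre, SIMPLIFY = FALSE)
  vcall <- as.call(c(quote(c), lapply(rxns, `[[`, "rate")))
  body <- as.call(c(quote(`{`), unname(assigns), vcall))
  f <- function(y) NULL
  body(f) <- body
  environment(f) <- env
  f
}

#' Evaluate the ODE right-hand side at one state
#'
#' Contract-level wrapper around [make_rhs()] for inspection and testing:
#' validates the state (negative components beyond numerical noise are
#' rejected - they indicate a solver excursion to be handled by the
#' integrator wrapper) and returns the named derivative vector.
#'
#' @param t time, min.
#' @param state named 18-species state vector.
#' @param params [parameter_set()].
#' @param gp [growth_params()].
#' @param scenario scenario label or [scb_scenario()].
#' @return named numeric derivative d(state)/dt.
#' @export
scb_rhs <- function(t, state, params, gp, scenario) {
  if (any(state < -1e-9))
    stop("negative state components: ",
         paste(names(state)[state < -1e-9], collapse = ", "), call. = FALSE)
  state <- pmax(state, 0)
  state <- state[species_names]
  f <- make_rhs(params, scenario, gp)
  stats::setNames(f(t, unname(state))[[1]], species_names)
}

#' Dump a scenario network to JSON
#'
#' Introspection export: species, reactions with stoichiometry and
#' deparsed rate laws, parameter bindings, and the growth-coupling terms
#' applied outside the stoichiometry matrix.
#'
#' @param network [build_network()] result.
#' @param path output file; `NULL` returns the JSON string.
#' @return path (invisibly) or JSON string.
#' @export
network_to_json <- function(network, path = NULL) {
  stopifnot(inherits(network, "scb_network"))
  obj <- list(
    scenario = network$scenario$label,
    mechanisms = list(TI = TRUE, RA = network$scenario$RA,
                      AS = network$scenario$AS, Ract = network$scenario$Ract),
    species = network$species,
    reactions = lapply(network$reactions, function(r)
      list(id = r$id, name = r$name, mechanism = r$mechanism,
           stoichiometry = as.list(r$stoich),
           rate_law = paste(deparse(r$rate), collapse = " "),
           parameters = r$params)),
    parameters = network$parameters,
    growth_coupling = list(
      dilution = "-mu(t) * x for every intracellular species",
      dna_duplication = "+mu(t) * x for every operator state (copies/cell conserved)",
      medium_accumulation = "dCe/dt += (export - import) * conv * V_cell/V_env * N(t)"
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
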