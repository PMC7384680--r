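#' @title Kinetic parameter catalogue of the GBL circuit meta-model
#' @description
#' The full meta-model (scenario H) carries 51 parameters. They fall into
#' three groups:
#'
#' * 44 *sampled* parameters, drawn from log-normal priors for ensemble runs;
#' * 5 *fixed* structural constants (compartment volumes and operator copy
#'   numbers);
#' * 2 *derived* parameters: `k_FR = chi * k_FA` (the promoter heterogeneity
#'   factor chi is defined as the ratio of the *scbR* over the *scbA* firing
#'   rate) and `d_Ce = d_C` (intracellular and extracellular GBL degrade at
#'   the same rate).
#'
#' The six growth-curve parameters (see [growth_params()]) are fitted to
#' culture data, not sampled from priors, and are counted outside the 51.
#'
#' @return `parameter_catalogue()` returns a data.frame with one row per
#'   parameter: `parameter`, `role` (`sampled`/`fixed`/`derived`),
#'   `mechanism` (`core`, `AS`, `RA`, `Ract`), `units`, `description`.
#' @export
parameter_catalogue <- function() {
  p <- function(parameter, role, mechanism, units, description)
    data.frame(parameter = parameter, role = role, mechanism = mechanism,
               units = units, description = description,
               stringsAsFactors = FALSE)
  rbind(
    p("k_FA",     "sampled", "core", "1/min", "scbA promoter firing rate"),
    p("chi",      "sampled", "core", "-",     "promoter heterogeneity factor k_FR/k_FA"),
    p("k_FR",     "derived", "core", "1/min", "scbR promoter firing rate (= chi * k_FA)"),
    p("aspect_R", "sampled", "core", "-",     "scbR promoter aspect ratio (interference susceptibility)"),
    p("aspect_A", "sampled", "core", "-",     "scbA promoter aspect ratio"),
    p("k_elong",  "sampled", "core", "1/min", "RNAP clearance rate of the overlap region"),
    p("f_rep1_R", "sampled", "core", "-",     "residual scbR transcription with one ScbR dimer bound"),
    p("f_rep2_R", "sampled", "core", "-",     "residual scbR transcription with two dimers bound"),
    p("f_rep1_A", "sampled", "core", "-",     "residual scbA transcription with one dimer bound"),
    p("f_rep2_A", "sampled", "core", "-",     "residual scbA transcription with two dimers bound"),
    p("k_leak_r", "sampled", "core", "1/min", "basal (occupancy-independent) scbR initiation"),
    p("k_leak_a", "sampled", "core", "1/min", "basal scbA initiation"),
    p("k_on1",    "sampled", "core", "1/(nM min)", "R2 association with free O_R"),
    p("K_d1",     "sampled", "core", "nM",    "dissociation constant, first R2 on O_R"),
    p("k_on7",    "sampled", "core", "1/(nM min)", "R2 association with singly occupied O_R"),
    p("K_d7",     "sampled", "core", "nM",    "dissociation constant, second R2 on O_R"),
    p("k_on2",    "sampled", "core", "1/(nM min)", "R2 association with free O_A"),
    p("K_d2",     "sampled", "core", "nM",    "dissociation constant, first R2 on O_A"),
    p("k_on8",    "sampled", "core", "1/(nM min)", "R2 association with singly occupied O_A"),
    p("K_d8",     "sampled", "core", "nM",    "dissociation constant, second R2 on O_A"),
    p("k_TL_r",   "sampled", "core", "1/min", "translation rate of r (ScbR synthesis)"),
    p("k_TL_a",   "sampled", "core", "1/min", "translation rate of a (ScbA synthesis)"),
    p("k_dim",    "sampled", "core", "1/(molec min)", "ScbR dimerisation"),
    p("k_undim",  "sampled", "core", "1/min", "ScbR dimer dissociation"),
    p("k_C",      "sampled", "core", "1/min", "GBL synthesis rate (C production proportional to A)"),
    p("k_CR_on",  "sampled", "core", "1/(nM^2 min)", "C2R2 complex formation (2 C + R2, collapsed step)"),
    p("k_CR_off", "sampled", "core", "1/min", "C2R2 complex dissociation"),
    p("k_diff",   "sampled", "core", "1/min", "passive membrane diffusion rate of C"),
    p("d_r",      "sampled", "core", "1/min", "degradation of r mRNA"),
    p("d_a",      "sampled", "core", "1/min", "degradation of a mRNA"),
    p("d_R",      "sampled", "core", "1/min", "degradation of ScbR monomer"),
    p("d_R2",     "sampled", "core", "1/min", "degradation of ScbR dimer"),
    p("d_A",      "sampled", "core", "1/min", "degradation of ScbA protein (dA)"),
    p("d_C",      "sampled", "core", "1/min", "degradation of intracellular GBL"),
    p("d_Ce",     "derived", "core", "1/min", "degradation of extracellular GBL (= d_C)"),
    p("d_C2R2",   "sampled", "core", "1/min", "degradation of the C2R2 complex"),
    p("k_as",     "sampled", "AS",   "1/(molec min)", "sense-antisense duplex formation"),
    p("k_as_off", "sampled", "AS",   "1/min", "duplex dissociation"),
    p("d_ra",     "sampled", "AS",   "1/min", "duplex degradation (fast)"),
    p("k_AR_on",  "sampled", "RA",   "1/(molec min)", "AR complex formation (A + R2)"),
    p("k_AR_off", "sampled", "RA",   "1/min", "AR complex dissociation"),
    p("d_AR",     "sampled", "RA",   "1/min", "AR complex degradation"),
    p("k_OAp_on", "sampled", "RA",   "1/(molec min)", "AR binding to the hypothetical O_A' operator"),
    p("k_OAp_off","sampled", "RA",   "1/min", "AR unbinding from O_A'"),
    p("f_RA",     "sampled", "RA",   "-",     "scbA activation fold via AR-bound O_A' (neutral = 1)"),
    p("f_Ract",   "sampled", "Ract", "-",     "scbA activation fold via R2-bound O_A (neutral = 1)"),
    p("V_cell",   "fixed",   "core", "L",     "cell (hyphal compartment) volume"),
    p("V_env",    "fixed",   "core", "L",     "culture medium volume"),
    p("n_OR",     "fixed",   "core", "copies/cell", "scbR operator copy number"),
    p("n_OA",     "fixed",   "core", "copies/cell", "scbA operator copy number"),
    p("n_OAp",    "fixed",   "core", "copies/cell", "O_A' operator copy number")
  )
}

#' Names of parameters by role or mechanism
#' @param role optional filter: `"sampled"`, `"fixed"` or `"derived"`.
#' @param mechanism optional filter: `"core"`, `"AS"`, `"RA"`, `"Ract"`.
#' @return character vector of parameter names.
#' @export
parameter_names <- function(role = NULL, mechanism = NULL) {
  cat_ <- parameter_catalogue()
  if (!is.null(role)) cat_ <- cat_[cat_$role %in% role, ]
  if (!is.null(mechanism)) cat_ <- cat_[cat_$mechanism %in% mechanism, ]
  cat_$parameter
}

# structural constants: one genome copy per cell, typical hyphal compartment
# volume ~1 fL, bench-scale culture volume 1 L
.fixed_parameter_values <- c(
  V_cell = 1e-15, V_env = 1, n_OR = 1, n_OA = 1, n_OAp = 1
)

# nM per (molecule / cell): 1e9 / (N_Avogadro * V_cell[L])
molecules_to_nM <- function(V_cell) 1e9 / (6.02214076e23 * V_cell)

#' Construct and validate a full parameter set
#'
#' Completes a named vector of sampled parameter values with the fixed
#' structural constants and the derived entries (`k_FR`, `d_Ce`), then
#' validates the result: all entries non-negative, divisor-type parameters
#' (dissociation constants, volumes, `k_elong`, copy numbers) strictly
#' positive, `chi == k_FR / k_FA` and `d_Ce == d_C` enforced.
#'
#' Zero is a legal value for rate constants: setting a mechanism's rate to
#' zero is how scenario-nesting equivalences (e.g. scenario C with duplex
#' rate 0 equals scenario A) are expressed.
#'
#' @param x named numeric vector covering at least the 44 sampled parameters
#'   (extra entries for fixed/derived parameters are allowed and checked).
#' @return named numeric vector of all 51 parameters, class `scb_params`.
#' @export
parameter_set <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("parameter values must be named", call. = FALSE)
  sampled <- parameter_names("sampled")
  missing <- setdiff(sampled, names(x))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  fixed <- .fixed_parameter_values
  for (nm in names(fixed)) if (!nm %in% names(x)) x[nm] <- fixed[nm]
  # derived entries: recompute, but reject inconsistent explicit values
  k_FR <- unname(x["chi"] * x["k_FA"])
  if ("k_FR" %in% names(x) && !isTRUE(all.equal(unname(x["k_FR"]), k_FR)))
    stop("inconsistent parameter set: chi must equal k_FR / k_FA",
         call. = FALSE)
  x["k_FR"] <- k_FR
  if ("d_Ce" %in% names(x) && !isTRUE(all.equal(unname(x["d_Ce"]), unname(x["d_C"]))))
    stop("inconsistent parameter set: internal and external GBL degrade at ",
         "the same rate (d_Ce must equal d_C)", call. = FALSE)
  x["d_Ce"] <- unname(x["d_C"])
  all_names <- parameter_catalogue()$parameter
  unknown <- setdiff(names(x), all_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  x <- x[all_names]
  if (any(!is.finite(x)) || any(x < 0))
    stop("all parameters must be finite and non-negative", call. = FALSE)
  strict <- c("K_d1", "K_d2", "K_d7", "K_d8", "k_elong",
              "V_cell", "V_env", "n_OR", "n_OA", "n_OAp")
  if (any(x[strict] <= 0))
    stop("parameters ", paste(strict[x[strict] <= 0], collapse = ", "),
         " must be strictly positive", call. = FALSE)
  structure(x, class = c("scb_params", "numeric"))
}

#' A plausible default parameter set
#'
#' The prior medians of [default_priors()], completed to a full validated
#' set. Used as a convenient starting point in examples and as the basis of
#' the synthetic study's ground truth.
#' @return `scb_params` vector.
#' @export
default_params <- function() {
  pr <- default_priors()
  parameter_set(stats::setNames(exp(pr$location), pr$parameter))
}
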