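#' Scenario configurations for the GBL circuit meta-model
#'
#' The meta-model contains four candidate regulatory mechanisms that can be
#' switched on and off individually:
#'
#' * `TI`  - transcriptional interference between the convergent, overlapping
#'   *scbR* / *scbA* promoters (always on: it is a consequence of the gene
#'   topology, not a hypothesis).
#' * `RA`  - formation of a ScbA-ScbR (AR) complex that sequesters the ScbR
#'   dimer and activates *scbA* transcription through a hypothetical O_A'
#'   operator.
#' * `AS`  - antisense interaction: the complementary *scbR* / *scbA*
#'   transcripts form a fast-degrading sense-antisense duplex, inhibiting
#'   translation.
#' * `Ract` - a dual role of ScbR: repressor of its own gene while acting as
#'   an activator of *scbA*.
#'
#' The eight combinations are labelled `A` through `H`:
#' A = TI; B = TI+RA; C = TI+AS; D = TI+Ract; E = TI+RA+AS; F = TI+RA+Ract;
#' G = TI+AS+Ract; H = TI+RA+AS+Ract.
#'
#' @param label scenario label, one of `"A"` to `"H"`.
#' @return An object of class `scb_scenario`: a list with logical flags
#'   `TI`, `RA`, `AS`, `Ract` and the `label`.
#' @examples
#' scb_scenario("C")          # TI + antisense
#' scenario_flags("H")        # all four mechanisms
#' @export
scb_scenario <- function(label) {
  label <- match.arg(toupper(label), LETTERS[1:8])
  flags <- .scenario_table[[label]]
  structure(
    list(TI = TRUE, RA = flags[["RA"]], AS = flags[["AS"]],
         Ract = flags[["Ract"]], label = label),
    class = "scb_scenario"
  )
}

# label -> optional-mechanism flags (TI implicit, always TRUE)
.scenario_table <- list(
  A = c(RA = FALSE, AS = FALSE, Ract = FALSE),
  B = c(RA = TRUE,  AS = FALSE, Ract = FALSE),
  C = c(RA = FALSE, AS = TRUE,  Ract = FALSE),
  D = c(RA = FALSE, AS = FALSE, Ract = TRUE),
  E = c(RA = TRUE,  AS = TRUE,  Ract = FALSE),
  F = c(RA = TRUE,  AS = FALSE, Ract = TRUE),
  G = c(RA = FALSE, AS = TRUE,  Ract = TRUE),
  H = c(RA = TRUE,  AS = TRUE,  Ract = TRUE)
)

#' @rdname scb_scenario
#' @export
scenario_flags <- function(label) {
  sc <- scb_scenario(label)
  c(TI = sc$TI, RA = sc$RA, AS = sc$AS, Ract = sc$Ract)
}

#' Build a scenario configuration from explicit mechanism flags
#'
#' @param RA,AS,Ract logical mechanism flags (see [scb_scenario()]).
#' @param TI must be `TRUE`; transcriptional interference is structural and
#'   cannot be switched off.
#' @return `scb_scenario` object with the matching `A`-`H` label.
#' @export
scenario_config <- function(RA = FALSE, AS = FALSE, Ract = FALSE, TI = TRUE) {
  if (!isTRUE(TI)) {
    stop("TI cannot be disabled: transcriptional interference follows from ",
         "the overlapping convergent promoter topology and is present in ",
         "all scenarios.", call. = FALSE)
  }
  for (lab in LETTERS[1:8]) {
    fl <- .scenario_table[[lab]]
    if (identical(unname(fl), c(RA, AS, Ract))) return(scb_scenario(lab))
  }
  stop("no scenario label matches the given flags", call. = FALSE) # unreachable
}

#' @export
print.scb_scenario <- function(x, ...) {
  on <- c("TI", if (x$RA) "RA", if (x$AS) "AS", if (x$Ract) "Ract")
  cat(sprintf("<scb_scenario %s: %s>\n", x$label, paste(on, collapse = " + ")))
  invisible(x)
}

is_scb_scenario <- function(x) inherits(x, "scb_scenario")

as_scenario <- function(x) {
  if (is_scb_scenario(x)) x else scb_scenario(x)
}
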