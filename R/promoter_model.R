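#' Equilibrium occupancy of a two-site operator
#'
#' Two ScbR homodimers can bind sequentially to each operator. With free
#' dimer concentration `R2` and dissociation constants `Kd_first` (first
#' site) and `Kd_second` (second site, binding to the already-occupied
#' operator), the partition function over the three occupancy classes is
#' `1 : R2/Kd_first : R2^2/(Kd_first*Kd_second)`.
#'
#' This quasi-equilibrium view backs the reduced oracle network and the
#' promoter-level API; the full simulator tracks the operator states as
#' explicit species with binding/unbinding reactions instead.
#'
#' @param R2 free ScbR dimer concentration, nM (scalar or vector, >= 0).
#' @param Kd_first,Kd_second dissociation constants, nM (> 0).
#' @return matrix with columns `p_free`, `p_one`, `p_two`; rows sum to 1.
#' @examples
#' occupancy_fractions(0, 10, 5)          # (1, 0, 0)
#' occupancy_fractions(1e9, 10, 5)        # ~(0, 0, 1)
#' @export
occupancy_fractions <- function(R2, Kd_first, Kd_second) {
  stopifnot(all(R2 >= 0), Kd_first > 0, Kd_second > 0)
  w1 <- R2 / Kd_first
  w2 <- w1 * R2 / Kd_second
  z <- 1 + w1 + w2
  cbind(p_free = 1 / z, p_one = w1 / z, p_two = w2 / z)
}

#' Probability of escaping transcriptional interference
#'
#' The *scbR* and *scbA* promoters are convergent and overlap, so an RNA
#' polymerase elongating from the opposing promoter across the shared region
#' can collide with (and abort) an initiating polymerase. The escape
#' probability for gene *i* decreases with the opposing promoter's effective
#' initiation frequency `f_opp` and with the time an opposing polymerase
#' occupies the shared region (set by the aspect ratio of promoter *i* and
#' the RNAP clearance rate of the overlap):
#'
#'   `escape_i = 1 / (1 + aspect_i * f_opp / k_elong)`
#'
#' The coupling vanishes as `aspect -> 0` or `k_elong -> Inf`, in which case
#' the two promoters factorise into independent repressible promoters.
#'
#' @param f_opp effective initiation rate of the opposing promoter, 1/min.
#' @param aspect promoter aspect-ratio parameter (dimensionless, >= 0).
#' @param k_elong RNAP clearance rate of the overlap region, 1/min (> 0).
#' @return escape probability in (0, 1].
#' @export
interference_escape <- function(f_opp, aspect, k_elong) {
  stopifnot(all(f_opp >= 0), all(aspect >= 0), all(k_elong > 0))
  1 / (1 + aspect * f_opp / k_elong)
}

#' Promoter state container
#'
#' @param occ_R,occ_A occupancy class of O_R and O_A: `"free"`, `"one"` or
#'   `"two"` (number of bound ScbR dimers).
#' @param k_FR,k_FA promoter firing rates, 1/min (> 0).
#' @param aspect_R,aspect_A promoter aspect ratios.
#' @param k_elong RNAP clearance rate of the overlap, 1/min.
#' @param rep1_R,rep2_R,rep1_A,rep2_A residual-transcription (repression)
#'   factors for single and double dimer occupancy; must satisfy
#'   `rep2 <= rep1 <= 1`.
#' @return list of class `promoter_state`.
#' @export
promoter_state <- function(occ_R = "free", occ_A = "free",
                           k_FR = 1, k_FA = 1,
                           aspect_R = 1, aspect_A = 1, k_elong = 10,
                           rep1_R = 0.1, rep2_R = 0.01,
                           rep1_A = 0.1, rep2_A = 0.01) {
  occ_R <- match.arg(occ_R, c("free", "one", "two"))
  occ_A <- match.arg(occ_A, c("free", "one", "two"))
  if (k_FR <= 0 || k_FA <= 0)
    stop("promoter firing rates must be positive", call. = FALSE)
  if (!(rep2_R <= rep1_R && rep1_R <= 1 && rep2_A <= rep1_A && rep1_A <= 1))
    stop("repression factors must satisfy rep2 <= rep1 <= 1", call. = FALSE)
  structure(list(occ_R = occ_R, occ_A = occ_A, k_FR = k_FR, k_FA = k_FA,
                 chi = k_FR / k_FA,
                 aspect_R = aspect_R, aspect_A = aspect_A, k_elong = k_elong,
                 rep1_R = rep1_R, rep2_R = rep2_R,
                 rep1_A = rep1_A, rep2_A = rep2_A),
            class = "promoter_state")
}

.occ_factor <- function(occ, rep1, rep2)
  switch(occ, free = 1, one = rep1, two = rep2)

#' Effective full-length transcription rates of the convergent gene pair
#'
#' Each gene's rate is its occupancy-modulated firing rate times the
#' probability of escaping interference from the opposing promoter. The
#' interference is mutual: the opposing promoter enters through its own
#' occupancy-modulated (pre-interference) firing rate.
#'
#' @param ps a [promoter_state()].
#' @return named numeric vector `c(rate_r=, rate_a=)`, 1/min; both are
#'   bounded above by their interference-free values.
#' @export
transcription_rates <- function(ps) {
  stopifnot(inherits(ps, "promoter_state"))
  f_R <- ps$k_FR * .occ_factor(ps$occ_R, ps$rep1_R, ps$rep2_R)
  f_A <- ps$k_FA * .occ_factor(ps$occ_A, ps$rep1_A, ps$rep2_A)
  c(rate_r = f_R * interference_escape(f_A, ps$aspect_R, ps$k_elong),
    rate_a = f_A * interference_escape(f_R, ps$aspect_A, ps$k_elong))
}
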