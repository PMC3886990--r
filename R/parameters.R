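#' Division-type probabilities of a cancer stem cell
#'
#' A CSC division is symmetric self-renewal (two CSCs, probability `p_s`),
#' asymmetric (one CSC and one NSCC, probability `p_a`), or symmetric
#' differentiation (two NSCCs, probability `p_d`). The three probabilities
#' must sum to one. Defaults are the in-situ immunofluorescence estimates
#' for CD133+/CD133- SW620 colon cancer cells.
#'
#' @param p_s probability of self-renewal (two CSC daughters).
#' @param p_a probability of asymmetric division (one CSC, one NSCC).
#' @param p_d probability of differentiation (two NSCC daughters).
#' @return an object of class `division_probs`.
#' @examples
#' dp <- division_probs()
#' effective_e(dp)
#' @export
division_probs <- function(p_s = 0.777, p_a = 0.164, p_d = 0.059) {
  stopifnot(is.numeric(p_s), is.numeric(p_a), is.numeric(p_d),
            length(p_s) == 1L, length(p_a) == 1L, length(p_d) == 1L)
  p <- c(p_s = p_s, p_a = p_a, p_d = p_d)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("division probabilities must all lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("division probabilities must sum to 1 (got %.10f)", sum(p)),
         call. = FALSE)
  }
  structure(as.list(p), class = "division_probs")
}

#' Effective division parameter e = P_S - P_D
#'
#' The division probabilities enter the population dynamics only through the
#' combination `e = p_s - p_d`: the expected net number of CSC daughters per
#' CSC division minus one. `e = 1` is pure self-renewal, `e = -1` pure
#' differentiation, `e = 0` a balanced divider.
#'
#' @param probs a [division_probs()] object.
#' @return a single number in `[-1, 1]`.
#' @export
effective_e <- function(probs) {
  if (!inherits(probs, "division_probs")) probs <- do.call(division_probs, as.list(probs))
  probs$p_s - probs$p_d
}

#' Kinetic parameters of the CSC/NSCC interconversion model
#'
#' Collects every rate of the deterministic model: the CSC division-type
#' probabilities, the CSC mitosis rate `k_c`, the NSCC proliferation rate
#' `k_n`, the mitosis-independent NSCC-to-CSC transition rate `k_t` (all per
#' day), the NSCC replicative lifespan `m_gen` (generations before
#' senescence), and the senescent death rate `d`. Defaults are the
#' experimentally estimated values for SW620 cells with the conventional
#' lifespan `m_gen = 50`, `d = 1`.
#'
#' @param probs a [division_probs()] object.
#' @param k_t NSCC-to-CSC transition rate (per day).
#' @param k_n NSCC proliferation rate (per day).
#' @param k_c CSC mitosis rate (per day).
#' @param m_gen NSCC lifespan in generations (positive integer).
#' @param d death rate of generation-`m_gen` (senescent) NSCCs, per day.
#' @return an object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params()
#' kp
#' @export
kinetic_params <- function(probs = division_probs(), k_t = 0.269,
                           k_n = 0.659, k_c = 0.849, m_gen = 50L, d = 1) {
  if (!inherits(probs, "division_probs")) probs <- do.call(division_probs, as.list(probs))
  rates <- c(k_t = k_t, k_n = k_n, k_c = k_c, d = d)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates k_t, k_n, k_c and d must be finite and non-negative",
         call. = FALSE)
  }
  m_gen <- as.integer(m_gen)
  if (is.na(m_gen) || m_gen < 1L) stop("m_gen must be a positive integer", call. = FALSE)
  structure(list(probs = probs, k_t = k_t, k_n = k_n, k_c = k_c,
                 m_gen = m_gen, d = d),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("CSC/NSCC kinetic parameters\n")
  cat(sprintf("  division probabilities: P_S=%.3f P_A=%.3f P_D=%.3f (e=%.3f)\n",
              x$probs$p_s, x$probs$p_a, x$probs$p_d, effective_e(x$probs)))
  cat(sprintf("  rates/day: K_T=%.3f K_N=%.3f K_C=%.3f d=%.3f\n",
              x$k_t, x$k_n, x$k_c, x$d))
  cat(sprintf("  NSCC lifespan: %d generations\n", x$m_gen))
  invisible(x)
}

#' Radiation-response parameters
#'
#' Parameters of the double-strand-break (DSB) kill model: a dose `dose_gy`
#' instantaneously induces `k_dsb * dose_gy` DSBs per cell, which are removed
#' by repair at rate `r_csc` (CSC) or `r_nscc` (NSCC); unrepaired DSB pairs
#' are lethally mis-repaired at rate `m_csc` / `m_nscc` per pair per day.
#' Survival fractions `s_csc` and `s_nscc` are the measured clonogenic
#' survivals after the reference 2 Gy dose. Defaults are the published values
#' for SW620 subpopulations.
#'
#' The default mis-repair rates are the tabulated ones. For CSCs the
#' tabulated value coincides with [misrepair_from_survival()] applied to
#' `s_csc`; for NSCCs it does not (see the package vignette), so the
#' tabulated `m_nscc` is used as-is for simulation.
#'
#' @param k_dsb DSBs induced per Gy.
#' @param dose_gy radiation dose in Gy.
#' @param r_csc,r_nscc DSB repair rates (per day).
#' @param m_csc,m_nscc lethal mis-repair rates (per DSB pair per day).
#' @param s_csc,s_nscc survival fractions after `dose_gy`, in (0, 1].
#' @return an object of class `radiation_params`.
#' @export
radiation_params <- function(k_dsb = 25, dose_gy = 2, r_csc = 15, r_nscc = 10,
                             m_csc = 0.0012, m_nscc = 0.0092,
                             s_csc = 0.95, s_nscc = 0.43) {
  vals <- c(k_dsb = k_dsb, dose_gy = dose_gy, r_csc = r_csc, r_nscc = r_nscc,
            m_csc = m_csc, m_nscc = m_nscc)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("radiation parameters must be finite and non-negative", call. = FALSE)
  }
  for (s in c(s_csc, s_nscc)) {
    if (!is.finite(s) || s <= 0 || s > 1) {
      stop("survival fractions must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(k_dsb = k_dsb, dose_gy = dose_gy, r_csc = r_csc,
                 r_nscc = r_nscc, m_csc = m_csc, m_nscc = m_nscc,
                 s_csc = s_csc, s_nscc = s_nscc),
            class = "radiation_params")
}

#' @export
print.radiation_params <- function(x, ...) {
  cat("Radiation-response parameters\n")
  cat(sprintf("  k=%.3g DSB/Gy, D=%.3g Gy; repair r_C=%.3g r_N=%.3g /day\n",
              x$k_dsb, x$dose_gy, x$r_csc, x$r_nscc))
  cat(sprintf("  mis-repair m_C=%.3g m_N=%.3g /pair/day; survival S_C=%.3g S_N=%.3g\n",
              x$m_csc, x$m_nscc, x$s_csc, x$s_nscc))
  invisible(x)
}
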