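#' Flow-sorting scenario with contamination
#'
#' Describes a FACS-sorted starting culture of `total_cells` cells that is
#' nominally pure CSC or pure NSCC but carries `theta` percent of the
#' opposite phenotype (sorter purity is typically 98\%, i.e. `theta <= 2`).
#'
#' @param nominal_type `"CSC"` or `"NSCC"`.
#' @param total_cells number of cells plated.
#' @param theta percent contamination by the opposite phenotype, in
#'   `[0, 100]`.
#' @return an object of class `sorting_scenario`.
#' @export
sorting_scenario <- function(nominal_type = c("CSC", "NSCC"),
                             total_cells = 1000, theta = 2) {
  nominal_type <- match.arg(nominal_type)
  if (!is.finite(theta) || theta < 0 || theta > 100) {
    stop("theta must lie in [0, 100]", call. = FALSE)
  }
  if (total_cells <= 0) stop("total_cells must be positive", call. = FALSE)
  structure(list(nominal_type = nominal_type, total_cells = total_cells,
                 theta = theta),
            class = "sorting_scenario")
}

#' Initial population state of an imperfectly sorted culture
#'
#' A fraction `1 - theta/100` of the cells is of the nominal type and
#' `theta/100` of the opposite type. All NSCCs (nominal or contaminating)
#' start at generation 1.
#'
#' @param scenario a [sorting_scenario()].
#' @param m_gen number of NSCC generations for the paired model.
#' @return a [population_state()].
#' @examples
#' apply_sorting_error(sorting_scenario("CSC", 1000, theta = 2), m_gen = 50)
#' @export
apply_sorting_error <- function(scenario, m_gen) {
  stopifnot(inherits(scenario, "sorting_scenario"))
  frac <- scenario$theta / 100
  n <- scenario$total_cells
  if (scenario$nominal_type == "CSC") {
    csc <- n * (1 - frac); n1 <- n * frac
  } else {
    csc <- n * frac; n1 <- n * (1 - frac)
  }
  population_state(csc = csc, nscc = c(n1, rep(0, m_gen - 1L)))
}

#' Sum-of-squares objective for proportion time-course fitting
#'
#' Integrates the full generation-structured model from the scenario's
#' (contaminated) initial state under a candidate `(k_c, k_n, e)` with the
#' remaining parameters fixed, and returns the sum of squared residuals
#' between the simulated and observed CSC proportions at the data times.
#'
#' @param candidate named list or vector with elements `k_c`, `k_n`, `e`.
#' @param data a data frame with columns `time_days` and `csc_proportion`.
#' @param scenario the [sorting_scenario()] defining the initial state.
#' @param fixed named list of fixed parameters: `k_t` (0 for the pure
#'   hierarchy test), `m_gen`, `d`.
#' @return the non-negative sum of squared proportion residuals.
#' @export
fit_objective <- function(candidate, data, scenario,
                          fixed = list(k_t = 0, m_gen = 50L, d = 1)) {
  cand <- as.list(candidate)
  params <- candidate_params(cand$k_c, cand$k_n, cand$e, fixed)
  initial <- apply_sorting_error(scenario, params$m_gen)
  sim <- proportion_on_grid(params, initial, data$time_days)
  sum((sim - data$csc_proportion)^2)
}

# division probabilities enter only through e; realise a valid triple
candidate_params <- function(k_c, k_n, e, fixed) {
  if (abs(e) > 1) stop("e must lie in [-1, 1]", call. = FALSE)
  p_a <- min(0.164, 1 - abs(e))
  probs <- division_probs((1 - p_a + e) / 2, p_a, (1 - p_a - e) / 2)
  kinetic_params(probs, k_t = fixed$k_t, k_n = k_n, k_c = k_c,
                 m_gen = fixed$m_gen, d = fixed$d)
}

#' Simulated-annealing schedule
#'
#' Defaults: the initial temperature is the objective value at the chain's
#' random starting point; geometric cooling by `cooling` every `block`
#' proposals; Gaussian proposals with per-parameter standard deviation
#' `step_frac` of the bound width; `n_proposals` Metropolis proposals per
#' chain. A fit is accepted when its best objective falls below
#' `n_timepoints * sigma^2`, the residual floor implied by an assumed
#' per-point measurement noise `sigma` (proportion units).
#'
#' @param n_proposals proposals per chain.
#' @param cooling geometric cooling factor in (0, 1).
#' @param block proposals between cooling steps.
#' @param step_frac proposal scale as a fraction of each bound width.
#' @param bounds named list of `c(lo, hi)` for `k_c`, `k_n`, `e`.
#' @param sigma assumed measurement noise used for the acceptance threshold.
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n_proposals = 10000L, cooling = 0.95,
                            block = 50L, step_frac = 0.05,
                            bounds = list(k_c = c(1e-6, 3),
                                          k_n = c(1e-6, 3),
                                          e = c(-1, 1)),
                            sigma = 0.03) {
  if (cooling <= 0 || cooling >= 1) stop("cooling must be in (0, 1)", call. = FALSE)
  stopifnot(n_proposals >= 1L, block >= 1L, step_frac > 0, sigma > 0,
            all(c("k_c", "k_n", "e") %in% names(bounds)))
  structure(list(n_proposals = as.integer(n_proposals), cooling = cooling,
                 block = as.integer(block), step_frac = step_frac,
                 bounds = bounds, sigma = sigma),
            class = "anneal_schedule")
}

#' Fit (k_c, k_n, e) to a proportion time course by simulated annealing
#'
#' Runs `n_fits` independent annealing chains. Each chain starts from
#' uniform-random parameters within the schedule bounds and performs
#' Metropolis moves on [fit_objective()]: a worse candidate is accepted with
#' probability `exp(-delta / temperature)` and the temperature cools
#' geometrically. The transition rate `k_t` stays fixed (0 to test the pure
#' hierarchy model), as do `m_gen` and `d`.
#'
#' @param data a data frame with columns `time_days`, `csc_proportion`.
#' @param scenario the [sorting_scenario()] of the fitted culture.
#' @param schedule an [anneal_schedule()].
#' @param fixed fixed parameters, see [fit_objective()].
#' @param n_fits number of independent chains.
#' @param seed optional RNG seed for reproducibility.
#' @return a `data.frame` of class `fit_results`, one row per chain, with
#'   columns `k_c`, `k_n`, `e`, `objective`, `accepted`, `chain`; the
#'   acceptance threshold is stored in `attr(, "threshold")`.
#' @export
simulated_annealing_fit <- function(data, scenario,
                                    schedule = anneal_schedule(),
                                    fixed = list(k_t = 0, m_gen = 50L, d = 1),
                                    n_fits = 50L, seed = NULL) {
  stopifnot(inherits(schedule, "anneal_schedule"), n_fits >= 1L,
            nrow(data) > 0)
  if (!is.null(seed)) set.seed(seed)
  threshold <- nrow(data) * schedule$sigma^2
  lo <- vapply(schedule$bounds, `[`, numeric(1), 1L)[c("k_c", "k_n", "e")]
  hi <- vapply(schedule$bounds, `[`, numeric(1), 2L)[c("k_c", "k_n", "e")]
  width <- hi - lo
  obj <- function(p) fit_objective(list(k_c = p[1], k_n = p[2], e = p[3]),
                                   data, scenario, fixed)
  run_chain <- function(chain) {
    p <- lo + runif(3) * width
    f <- obj(p)
    best_p <- p; best_f <- f
    temp <- max(f, 1e-8)
    for (i in seq_len(schedule$n_proposals)) {
      q <- pmin(pmax(p + rnorm(3, 0, schedule$step_frac * width), lo), hi)
      fq <- obj(q)
      if (fq <= f || runif(1) < exp(-(fq - f) / temp)) {
        p <- q; f <- fq
        if (f < best_f) { best_f <- f; best_p <- p }
      }
      if (i %% schedule$block == 0L) temp <- temp * schedule$cooling
    }
    data.frame(k_c = best_p[1], k_n = best_p[2], e = best_p[3],
               objective = best_f, accepted = best_f < threshold,
               chain = chain)
  }
  out <- do.call(rbind, lapply(seq_len(n_fits), run_chain))
  if (!any(out$accepted)) {
    warning("no annealing chain reached the acceptance threshold",
            call. = FALSE)
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("fit_results", "data.frame")
  out
}

#' Cross-evaluate hierarchy-model fits on the opposite sorted culture
#'
#' Evaluates each accepted fit (obtained from the nominally-CSC culture with
#' `k_t = 0`) on the nominally-NSCC culture's time course. If even the best
#' fit's objective exceeds `factor` times the acceptance threshold, the
#' verdict is `"hierarchy-insufficient"`: no contamination-only parameter
#' set explains both cultures, so NSCC-to-CSC transitions are required.
#'
#' @param fits a `fit_results` object from [simulated_annealing_fit()].
#' @param nscc_data proportion time course of the nominally-NSCC culture.
#' @param scenario the NSCC-sorted [sorting_scenario()].
#' @param fixed fixed parameters used during fitting.
#' @param threshold acceptance threshold; defaults to the one stored in
#'   `fits`.
#' @param factor multiple of the threshold that the best cross objective
#'   must exceed for the insufficiency verdict.
#' @return a list with `objectives` (per accepted fit), `verdict`
#'   (`"hierarchy-insufficient"` or `"hierarchy-consistent"`), and
#'   `threshold`.
#' @export
cross_evaluate <- function(fits, nscc_data, scenario,
                           fixed = list(k_t = 0, m_gen = 50L, d = 1),
                           threshold = attr(fits, "threshold"), factor = 1) {
  stopifnot(inherits(fits, "fit_results"))
  acc <- fits[fits$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) stop("no accepted fits to cross-evaluate", call. = FALSE)
  objs <- vapply(seq_len(nrow(acc)), function(i) {
    fit_objective(list(k_c = acc$k_c[i], k_n = acc$k_n[i], e = acc$e[i]),
                  nscc_data, scenario, fixed)
  }, numeric(1))
  verdict <- if (min(objs) > factor * threshold) "hierarchy-insufficient"
             else "hierarchy-consistent"
  list(objectives = objs, verdict = verdict, threshold = threshold)
}
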