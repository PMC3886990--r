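#' Sample in-situ division-event counts
#'
#' Emulates the immunofluorescence scoring of `n` CSC divisions: each
#' division is self-renewal, asymmetric, or differentiation with the true
#' probabilities, giving trinomial counts. Plug-in frequency estimates and
#' their binomial standard errors are attached.
#'
#' @param probs true [division_probs()].
#' @param n number of scored divisions.
#' @param seed optional RNG seed.
#' @return a list of class `division_event_counts` with elements `n`,
#'   `counts` (named integer vector), `estimates`, `se`.
#' @examples
#' sample_division_events(division_probs(), n = 1000, seed = 1)
#' @export
sample_division_events <- function(probs, n, seed = NULL) {
  if (!inherits(probs, "division_probs")) probs <- do.call(division_probs, as.list(probs))
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cnt <- drop(rmultinom(1, n, c(probs$p_s, probs$p_a, probs$p_d)))
  names(cnt) <- c("self_renewal", "asymmetric", "differentiation")
  est <- cnt / n
  structure(list(n = n, counts = cnt, estimates = est,
                 se = sqrt(est * (1 - est) / n)),
            class = "division_event_counts")
}

#' Simulate one-day counts of a sorted population
#'
#' Emulates the one-day quantity-change measurement used to estimate the
#' rates: a purified population of `n0` cells is cultured for one day and
#' recounted. Totals come from the full structured model. For an NSCC sort
#' the per-cell transition is also scored, emulating the in-situ tracking of
#' individual NSCCs: each of the `n0` founder cells converts within the day
#' with probability `1 - exp(-k_t)`, scored binomially (or exactly when
#' `noise = "none"`).
#'
#' @param params true [kinetic_params()].
#' @param sorted_type `"CSC"` or `"NSCC"`.
#' @param n0 cells plated at day 0.
#' @param seed optional RNG seed.
#' @param noise `"none"` for expected values, `"poisson"` for Poisson
#'   counting noise on the total (and binomial noise on the transition
#'   fraction).
#' @return a list of class `one_day_counts` with elements `sorted_type`,
#'   `count_day0`, `count_day1_total`, and `transitioned_fraction` (NSCC
#'   sorts only, otherwise `NA`).
#' @export
simulate_one_day_counts <- function(params, sorted_type = c("CSC", "NSCC"),
                                    n0 = 1000, seed = NULL,
                                    noise = c("none", "poisson")) {
  stopifnot(inherits(params, "kinetic_params"))
  sorted_type <- match.arg(sorted_type)
  noise <- match.arg(noise)
  if (n0 < 1) stop("n0 must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  initial <- if (sorted_type == "CSC") {
    population_state(csc = n0, nscc = 0, m_gen = params$m_gen)
  } else {
    population_state(csc = 0, nscc = c(n0, rep(0, params$m_gen - 1L)))
  }
  y <- propagate_linear(kinetic_matrix(params), as_state_vector(initial),
                        c(0, 1))
  total1 <- sum(y[2, ])
  trans <- NA_real_
  if (sorted_type == "NSCC") {
    p_tr <- 1 - exp(-params$k_t)
    trans <- if (noise == "none") p_tr else rbinom(1, n0, p_tr) / n0
  }
  if (noise == "poisson") total1 <- rpois(1, total1)
  structure(list(sorted_type = sorted_type, count_day0 = n0,
                 count_day1_total = total1, transitioned_fraction = trans),
            class = "one_day_counts")
}

#' Estimate the kinetic rates from one-day counts
#'
#' Inverts the one-day measurements under the approximation that divisions
#' of newly born cells of the opposite type contribute negligibly within a
#' day: `k_c = log(total1 / n0)` from the CSC sort, `k_n = log(total1 / n0)`
#' from the NSCC sort, and `k_t = -log(1 - f)` from the scored transition
#' fraction `f` (exponential-waiting-time inversion; `method = "naive"`
#' returns `k_t = f` instead).
#'
#' @param csc_obs a `one_day_counts` from a CSC sort.
#' @param nscc_obs a `one_day_counts` from an NSCC sort.
#' @param method transition-fraction inversion, `"exponential"` or
#'   `"naive"`.
#' @return named numeric vector with elements `k_t`, `k_n`, `k_c`.
#' @examples
#' kp <- kinetic_params()
#' est <- estimate_rates_one_day(simulate_one_day_counts(kp, "CSC"),
#'                               simulate_one_day_counts(kp, "NSCC"))
#' @export
estimate_rates_one_day <- function(csc_obs, nscc_obs,
                                   method = c("exponential", "naive")) {
  method <- match.arg(method)
  stopifnot(inherits(csc_obs, "one_day_counts"),
            inherits(nscc_obs, "one_day_counts"),
            csc_obs$sorted_type == "CSC", nscc_obs$sorted_type == "NSCC")
  if (csc_obs$count_day1_total <= 0 || nscc_obs$count_day1_total <= 0) {
    stop("day-1 totals must be positive", call. = FALSE)
  }
  f <- nscc_obs$transitioned_fraction
  if (is.na(f) || f < 0 || f >= 1) {
    stop("NSCC observation must carry a transitioned fraction in [0, 1)",
         call. = FALSE)
  }
  c(k_t = if (method == "exponential") -log(1 - f) else f,
    k_n = log(nscc_obs$count_day1_total / nscc_obs$count_day0),
    k_c = log(csc_obs$count_day1_total / csc_obs$count_day0))
}

#' Generate a noisy CSC-proportion time course
#'
#' Integrates the full model (optionally through a radiation pulse at time
#' 0) from an imperfectly sorted initial state and samples the CSC
#' proportion at the requested times with observation noise: Gaussian with
#' standard deviation `noise_sigma`, clipped to `[0, 1]` (default), or
#' binomial scoring of `n_scored` cells per time point.
#'
#' @param params true [kinetic_params()].
#' @param scenario a [sorting_scenario()] (use `theta = 0` for a perfectly
#'   pure culture).
#' @param sample_times strictly increasing sampling times in days.
#' @param noise_sigma Gaussian noise SD in proportion units.
#' @param seed optional RNG seed.
#' @param rad optional [radiation_params()]; when supplied a single pulse is
#'   delivered at time 0.
#' @param noise_model `"gaussian"` or `"binomial"`.
#' @param n_scored cells scored per time point for the binomial model.
#' @return a list of class `synthetic_time_course` with elements `data` (a
#'   data frame `time_days`, `csc_proportion`), `truth_proportion` (the
#'   noiseless series), `params`, `scenario`, `noise_sigma`, `seed`.
#' @export
generate_time_course <- function(params, scenario, sample_times,
                                 noise_sigma = 0.02, seed = NULL, rad = NULL,
                                 noise_model = c("gaussian", "binomial"),
                                 n_scored = 500) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(scenario, "sorting_scenario"))
  noise_model <- match.arg(noise_model)
  if (any(diff(sample_times) <= 0) || any(sample_times < 0)) {
    stop("sample_times must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  initial <- apply_sorting_error(scenario, params$m_gen)
  truth <- if (is.null(rad)) {
    proportion_on_grid(params, initial, sample_times)
  } else {
    tr <- integrate_irradiated(params, rad, initial,
                               t_end = max(sample_times) + 1e-6,
                               dt_out = min(0.05, min(diff(c(0, sample_times)))))
    stats::approx(tr$time_days, tr$csc_proportion, xout = sample_times)$y
  }
  observed <- switch(noise_model,
    gaussian = pmin(pmax(truth + rnorm(length(truth), 0, noise_sigma), 0), 1),
    binomial = rbinom(length(truth), n_scored, truth) / n_scored)
  structure(list(data = data.frame(time_days = sample_times,
                                   csc_proportion = observed),
                 truth_proportion = truth, params = params,
                 scenario = scenario, noise_sigma = noise_sigma, seed = seed),
            class = "synthetic_time_course")
}

#' End-to-end parameter recovery from one synthetic replicate
#'
#' Generates the three synthetic measurement types from a known truth —
#' 1000 scored division events, noisy one-day counts of CSC and NSCC sorts,
#' and a 26-day proportion time course (sigma = 0.02) — and runs the
#' estimation pipeline: plug-in division probabilities, one-day rate
#' inversion, and the equilibrium proportion read from the late time-course
#' samples.
#'
#' @param seed RNG seed for the replicate.
#' @param truth true [kinetic_params()].
#' @param n_events scored divisions.
#' @param n0 plated cells per one-day sort.
#' @param sample_times time-course sampling days.
#' @param noise_sigma time-course noise SD.
#' @return named numeric vector of estimates: `p_s`, `p_a`, `p_d`, `k_t`,
#'   `k_n`, `k_c`, `equilibrium_R`.
#' @export
recover_parameters <- function(seed, truth = kinetic_params(),
                               n_events = 1000, n0 = 1000,
                               sample_times = seq(2, 26, by = 2),
                               noise_sigma = 0.02) {
  set.seed(seed)
  ev <- sample_division_events(truth$probs, n_events)
  csc1 <- simulate_one_day_counts(truth, "CSC", n0, noise = "poisson")
  nscc1 <- simulate_one_day_counts(truth, "NSCC", n0, noise = "poisson")
  rates <- estimate_rates_one_day(csc1, nscc1)
  tc <- generate_time_course(truth, sorting_scenario("NSCC", n0, theta = 0),
                             sample_times, noise_sigma)
  late <- tc$data$csc_proportion[tc$data$time_days >= max(sample_times) - 6]
  c(p_s = unname(ev$estimates["self_renewal"]),
    p_a = unname(ev$estimates["asymmetric"]),
    p_d = unname(ev$estimates["differentiation"]),
    rates,
    equilibrium_R = mean(late))
}
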