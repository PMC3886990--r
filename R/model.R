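#' Population state of the structured model
#'
#' A snapshot of the population: the CSC count `csc` and the NSCC counts
#' `nscc[i]` stratified by generation `i = 1..m_gen`. Counts are continuous
#' (the deterministic model tracks expected cell numbers).
#'
#' @param csc CSC count (non-negative).
#' @param nscc numeric vector of NSCC counts by generation; a scalar is
#'   interpreted as generation-1 cells with `m_gen - 1` empty older
#'   generations.
#' @param m_gen number of NSCC generations; defaults to `length(nscc)` when
#'   `nscc` has length > 1.
#' @param time time of the snapshot in days.
#' @return an object of class `population_state`.
#' @examples
#' population_state(csc = 100, nscc = 0, m_gen = 50)
#' @export
population_state <- function(csc, nscc = 0, m_gen = NULL, time = 0) {
  if (length(nscc) == 1L) {
    if (is.null(m_gen)) stop("m_gen is required when nscc is scalar", call. = FALSE)
    nscc <- c(nscc, rep(0, m_gen - 1L))
  }
  if (!is.null(m_gen) && length(nscc) != m_gen) {
    stop(sprintf("nscc has %d generations but m_gen = %d", length(nscc), m_gen),
         call. = FALSE)
  }
  if (!is.finite(csc) || csc < 0 || any(!is.finite(nscc)) || any(nscc < 0)) {
    stop("cell counts must be finite and non-negative", call. = FALSE)
  }
  structure(list(time = time, csc = as.numeric(csc), nscc = as.numeric(nscc)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state at t=%.3g d: C=%.4g, sum(N)=%.4g over %d generations\n",
              x$time, x$csc, sum(x$nscc), length(x$nscc)))
  invisible(x)
}

as_state_vector <- function(state) c(state$csc, state$nscc)

#' CSC proportion of a population state
#'
#' `R = C / (C + sum(N_i))`, the fraction of cancer stem cells in the whole
#' population.
#'
#' @param state a [population_state()], or a numeric vector whose first
#'   element is the CSC count and remaining elements the NSCC generations.
#' @return a fraction in `[0, 1]`.
#' @export
csc_proportion <- function(state) {
  v <- if (inherits(state, "population_state")) as_state_vector(state) else as.numeric(state)
  tot <- sum(v)
  if (tot <= 0) stop("CSC proportion is undefined for an empty population", call. = FALSE)
  v[1] / tot
}

#' System matrix of the structured linear model
#'
#' The model is linear, `dx/dt = A x` with `x = (C, N_1, ..., N_M)`. The
#' matrix encodes: CSC net self-amplification `k_c * e`; CSC output into
#' generation-1 NSCCs at `k_c * (1 - e)` (one NSCC daughter per asymmetric
#' division, two per differentiation); NSCC division moving one cell of
#' generation `i` into two of generation `i + 1` at rate `k_n`; senescent
#' death of generation `M` at rate `d`; and NSCC-to-CSC transition at `k_t`
#' from every generation.
#'
#' @param params a [kinetic_params()] object.
#' @return a dense `(m_gen + 1) x (m_gen + 1)` matrix.
#' @export
kinetic_matrix <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  M <- params$m_gen
  e <- effective_e(params$probs)
  n <- M + 1L
  A <- matrix(0, n, n)
  A[1, 1] <- params$k_c * e
  A[1, 2:n] <- params$k_t
  A[2, 1] <- params$k_c * (1 - e)
  A[2, 2] <- -(if (M == 1L) params$d else params$k_n) - params$k_t
  if (M >= 2L) {
    for (i in 2:M) {
      A[i + 1L, i] <- 2 * params$k_n
      A[i + 1L, i + 1L] <- -(if (i == M) params$d else params$k_n) - params$k_t
    }
  }
  A
}

#' Time derivatives of the structured model
#'
#' Right-hand side of the ODE system:
#' \deqn{dC/dt = k_c e C + k_t \sum_i N_i}
#' \deqn{dN_1/dt = k_c (1 - e) C - (k_n + k_t) N_1}
#' \deqn{dN_i/dt = 2 k_n N_{i-1} - (k_n + k_t) N_i, \quad 2 \le i < M}
#' \deqn{dN_M/dt = 2 k_n N_{M-1} - (d + k_t) N_M}
#'
#' @param state a [population_state()] consistent with `params`.
#' @param params a [kinetic_params()] object.
#' @return a numeric vector of derivatives, `c(dC, dN_1, ..., dN_M)`.
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  v <- if (inherits(state, "population_state")) as_state_vector(state) else as.numeric(state)
  if (length(v) != params$m_gen + 1L) {
    stop(sprintf("state has %d compartments but the model needs %d",
                 length(v), params$m_gen + 1L), call. = FALSE)
  }
  drop(kinetic_matrix(params) %*% v)
}

#' Integrate the structured model
#'
#' Solves the linear system from `initial` up to `t_end` days with an
#' adaptive implicit-capable solver (`deSolve::lsoda`) at tight tolerances
#' (rtol 1e-8, atol 1e-10), sampling every `dt_out` days.
#'
#' @param params a [kinetic_params()] object.
#' @param initial a [population_state()].
#' @param t_end final time in days (must exceed `initial$time`).
#' @param dt_out output sampling interval in days.
#' @param keep_generations if `TRUE`, include one column per NSCC generation.
#' @param hazard optional function of time returning `c(h_csc, h_nscc)`
#'   additional per-capita death rates (used by the radiation extension).
#' @return a `data.frame` of class `csc_trajectory` with columns
#'   `time_days`, `csc_count`, `nscc_total`, `csc_proportion` (and
#'   `nscc_gen_1..M` if requested).
#' @examples
#' tr <- integrate_model(kinetic_params(),
#'                       population_state(100, 0, m_gen = 50),
#'                       t_end = 30)
#' tail(tr, 2)
#' @export
integrate_model <- function(params, initial, t_end, dt_out = 0.5,
                            keep_generations = FALSE, hazard = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(initial, "population_state"))
  if (length(initial$nscc) != params$m_gen) {
    stop("initial state and params disagree on the number of generations",
         call. = FALSE)
  }
  if (t_end <= initial$time) stop("t_end must exceed the initial time", call. = FALSE)
  if (dt_out <= 0) stop("dt_out must be positive", call. = FALSE)
  A <- kinetic_matrix(params)
  times <- seq(initial$time, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  deriv <- if (is.null(hazard)) {
    function(t, y, p) list(drop(A %*% y))
  } else {
    function(t, y, p) {
      h <- hazard(t)
      list(drop(A %*% y) - c(h[1] * y[1], h[2] * y[-1]))
    }
  }
  sol <- deSolve::lsoda(y = as_state_vector(initial), times = times,
                        func = deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed to converge; see deSolve diagnostics above",
         call. = FALSE)
  }
  sol_to_trajectory(sol, params$m_gen, keep_generations)
}

sol_to_trajectory <- function(sol, m_gen, keep_generations) {
  y <- unname(as.matrix(sol[, -1, drop = FALSE]))
  csc <- y[, 1]
  nscc <- rowSums(y[, -1, drop = FALSE])
  out <- data.frame(time_days = sol[, 1],
                    csc_count = csc,
                    nscc_total = nscc,
                    csc_proportion = csc / pmax(csc + nscc, .Machine$double.xmin))
  if (keep_generations) {
    gen <- y[, -1, drop = FALSE]
    colnames(gen) <- paste0("nscc_gen_", seq_len(m_gen))
    out <- cbind(out, as.data.frame(gen))
  }
  class(out) <- c("csc_trajectory", "data.frame")
  out
}

# Exact propagation of the linear system on a time grid via the matrix
# exponential; one Pade expm per distinct time gap, reused across steps.
# Much faster than adaptive stepping inside tight fitting loops.
propagate_linear <- function(A, x0, times) {
  stopifnot(length(x0) == nrow(A))
  gaps <- diff(times)
  if (any(gaps <= 0)) stop("times must be strictly increasing", call. = FALSE)
  keys <- signif(gaps, 12)
  cache <- new.env(parent = emptyenv())
  out <- matrix(NA_real_, nrow = length(times), ncol = length(x0))
  out[1, ] <- x0
  x <- x0
  for (i in seq_along(gaps)) {
    key <- format(keys[i], digits = 15)
    E <- cache[[key]]
    if (is.null(E)) {
      E <- as.matrix(Matrix::expm(A * gaps[i]))
      cache[[key]] <- E
    }
    x <- drop(E %*% x)
    out[i + 1L, ] <- x
  }
  out
}

# Fast CSC-proportion series on arbitrary times (exact for the linear model).
proportion_on_grid <- function(params, initial, times) {
  A <- kinetic_matrix(params)
  x0 <- as_state_vector(initial)
  t0 <- initial$time
  full <- if (isTRUE(all.equal(times[1], t0))) times else c(t0, times)
  y <- propagate_linear(A, x0, full)
  if (length(full) != length(times)) y <- y[-1, , drop = FALSE]
  y[, 1] / rowSums(y)
}
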