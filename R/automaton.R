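#' Configuration of the lattice cellular automaton
#'
#' A bounded rectangular lattice (default 200 x 200 sites of 10 um; no
#' wraparound) holding at most one cell per site. The automaton is the
#' stochastic, spatial counterpart of the structured ODE model: CSCs divide
#' at rate `k_c` choosing a division type from `(p_s, p_a, p_d)`, NSCCs
#' divide at `k_n` with both daughters one generation older, NSCCs convert
#' to CSCs at `k_t`, and generation-`m_gen` NSCCs die at `d`. A
#' division-ready cell with no vacant von Neumann neighbour is quiescent.
#'
#' Two cell-cycle models are available. The default, `"exponential"`, draws
#' each cell's division in a step with probability `1 - exp(-K dt)`, so
#' inter-division times are exponential and the ensemble mean obeys the
#' mass-action ODE. `"timer"` accumulates cycle progress `K dt` per step and
#' divides on crossing 1 (near-deterministic cycle length `1/K`); it is
#' provided for comparison but its population growth rate is `K log(2)`,
#' not `K`, so it does not correspond to the ODE (see the vignette).
#'
#' @param rows,cols lattice dimensions.
#' @param dt time step in days; per-step event probabilities are
#'   `1 - exp(-rate * dt)`.
#' @param params a [kinetic_params()] object.
#' @param cycle_model `"exponential"` (ODE-matching, default) or `"timer"`.
#' @param site_um site edge length in micrometres (metadata only).
#' @param seed optional RNG seed applied by [init_lattice()].
#' @return an object of class `automaton_config`.
#' @export
automaton_config <- function(rows = 200L, cols = 200L, dt = 0.05,
                             params = kinetic_params(),
                             cycle_model = c("exponential", "timer"),
                             site_um = 10, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  cycle_model <- match.arg(cycle_model)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("lattice dimensions must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (cycle_model == "timer" && dt * max(params$k_c, params$k_n) > 1) {
    stop("dt too large: cycle progress per step must not exceed 1", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, dt = dt, params = params,
                 cycle_model = cycle_model, site_um = site_um,
                 boundary = "bounded", seed = seed),
            class = "automaton_config")
}

#' Seed a lattice with an initial cell population
#'
#' Places cells on uniformly sampled vacant sites. The composition is given
#' either as explicit counts (`n_csc`, `n_nscc`) or as a total and a CSC
#' proportion. NSCCs start at generation 1; cycle progress is initialised
#' uniformly in `[0, 1)` (used by the `"timer"` cycle model).
#'
#' @param config an [automaton_config()].
#' @param n_csc,n_nscc numbers of CSCs and generation-1 NSCCs to place.
#' @param total,prop_csc alternative seeding: `total` cells of which
#'   `prop_csc` are CSCs (counts rounded to integers).
#' @return an object of class `automaton_state`.
#' @examples
#' st <- init_lattice(automaton_config(rows = 50, cols = 50, seed = 1),
#'                    n_csc = 0, n_nscc = 100)
#' @export
init_lattice <- function(config, n_csc = 0L, n_nscc = 0L,
                         total = NULL, prop_csc = NULL) {
  stopifnot(inherits(config, "automaton_config"))
  if (!is.null(total)) {
    stopifnot(!is.null(prop_csc), prop_csc >= 0, prop_csc <= 1)
    n_csc <- round(total * prop_csc)
    n_nscc <- total - n_csc
  }
  n_csc <- as.integer(n_csc); n_nscc <- as.integer(n_nscc)
  n <- n_csc + n_nscc
  cap <- config$rows * config$cols
  if (n > cap) {
    stop(sprintf("cannot seed %d cells on a %d-site lattice", n, cap),
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  type <- matrix(0L, config$rows, config$cols)
  gen <- matrix(0L, config$rows, config$cols)
  prog <- matrix(0, config$rows, config$cols)
  if (n > 0L) {
    sites <- sample.int(cap, n)
    type[sites] <- rep(c(1L, 2L), c(n_csc, n_nscc))
    gen[sites[type[sites] == 2L]] <- 1L
    prog[sites] <- runif(n)
  }
  structure(list(type = type, gen = gen, prog = prog, time = 0,
                 config = config),
            class = "automaton_state")
}

#' @export
print.automaton_state <- function(x, ...) {
  cat(sprintf("automaton_state %dx%d at t=%.3g d: %d CSC, %d NSCC, %d vacant\n",
              nrow(x$type), ncol(x$type), x$time,
              sum(x$type == 1L), sum(x$type == 2L), sum(x$type == 0L)))
  invisible(x)
}

#' Advance the automaton
#'
#' `ca_step()` applies one time step; `ca_run()` applies `n_steps` steps and
#' records the subpopulation counts every `record_every` steps.
#'
#' @param state an [init_lattice()] state.
#' @param n_steps number of steps to run.
#' @param record_every recording stride (steps).
#' @return `ca_run()` returns a list with `counts` (a data frame with
#'   columns `time_days`, `csc_count`, `nscc_count`, `csc_proportion`) and
#'   `state` (the final `automaton_state`). `ca_step()` returns the advanced
#'   state.
#' @export
ca_run <- function(state, n_steps, record_every = 1L) {
  stopifnot(inherits(state, "automaton_state"), n_steps >= 1L)
  cfg <- state$config
  p <- cfg$params
  type <- state$type + 0L  # force copies: the C++ kernel updates in place
  gen <- state$gen + 0L
  prog <- state$prog + 0
  rec <- ca_run_cpp(type, gen, prog, cfg$dt, as.integer(n_steps),
                    as.integer(record_every),
                    p$probs$p_s, p$probs$p_a, p$k_t, p$k_n, p$k_c,
                    p$m_gen, p$d, cfg$cycle_model == "timer", state$time)
  tot <- rec$csc + rec$nscc
  counts <- data.frame(time_days = rec$time,
                       csc_count = rec$csc,
                       nscc_count = rec$nscc,
                       csc_proportion = ifelse(tot > 0, rec$csc / tot, NA_real_))
  new_state <- state
  new_state$type <- type; new_state$gen <- gen; new_state$prog <- prog
  new_state$time <- state$time + n_steps * cfg$dt
  list(counts = counts, state = new_state)
}

#' @rdname ca_run
#' @export
ca_step <- function(state) {
  ca_run(state, n_steps = 1L)$state
}

#' Run the automaton under a serial-passage culture protocol
#'
#' Real multi-week cultures of a daily-doubling line are repeatedly
#' passaged: once cells amass, a random aliquot is replated on a fresh
#' dish. This runner emulates that protocol so the automaton can be
#' followed for weeks without hitting confluence: it advances the lattice
#' in chunks of `passage_interval` days and after each chunk re-seeds a
#' uniform random subsample of `n_reseed` cells (types, generations and
#' cycle progress preserved) onto an empty lattice.
#'
#' An unpassaged lattice grown to confluence behaves differently: blocked
#' cells stop dividing while NSCC-to-CSC conversion continues, so the
#' composition drifts CSC-ward (see the vignette). Passaging keeps the
#' population in the dilute regime where the automaton ensemble mean obeys
#' the mass-action ODE.
#'
#' @param state an [init_lattice()] state (also defines the lattice size).
#' @param t_end total simulated time in days.
#' @param passage_interval days between passages.
#' @param n_reseed cells replated at each passage (at most the cells
#'   available).
#' @return a data frame with the end-of-chunk counts (`time_days`,
#'   `csc_count`, `nscc_count`, `csc_proportion`).
#' @export
ca_run_passaged <- function(state, t_end, passage_interval = 1,
                            n_reseed = NULL) {
  stopifnot(inherits(state, "automaton_state"), t_end > state$time)
  cfg <- state$config
  if (is.null(n_reseed)) n_reseed <- sum(state$type != 0L)
  steps <- max(1L, round(passage_interval / cfg$dt))
  out <- NULL
  repeat {
    res <- ca_run(state, n_steps = steps, record_every = steps)
    out <- rbind(out, res$counts[nrow(res$counts), ])
    state <- res$state
    if (state$time >= t_end - 1e-9) break
    occ <- which(state$type != 0L)
    keep <- if (length(occ) > n_reseed) sample(occ, n_reseed) else occ
    fresh <- state
    fresh$type <- matrix(0L, cfg$rows, cfg$cols)
    fresh$gen <- matrix(0L, cfg$rows, cfg$cols)
    fresh$prog <- matrix(0, cfg$rows, cfg$cols)
    sites <- sample.int(cfg$rows * cfg$cols, length(keep))
    fresh$type[sites] <- state$type[keep]
    fresh$gen[sites] <- state$gen[keep]
    fresh$prog[sites] <- state$prog[keep]
    state <- fresh
  }
  rownames(out) <- NULL
  out
}

#' Render a lattice as text
#'
#' One character per site: `'.'` vacant, `'C'` CSC, `'N'` NSCC. Useful for
#' plain-text snapshots.
#'
#' @param state an `automaton_state`.
#' @return a character vector, one element per lattice row.
#' @export
format_lattice <- function(state) {
  stopifnot(inherits(state, "automaton_state"))
  chars <- c(".", "C", "N")[state$type + 1L]
  apply(matrix(chars, nrow(state$type), ncol(state$type)), 1, paste0,
        collapse = "")
}
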