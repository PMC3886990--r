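#' Default run configuration
#'
#' The baseline configuration: kinetic and radiation blocks preset to the
#' experimentally measured values, plus automaton and annealing defaults.
#' Keys follow the conventional symbols (`P_S`, `K_T`, `r_C`, ...).
#'
#' @return a nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    kinetics = list(P_S = 0.777, P_A = 0.164, P_D = 0.059,
                    K_T = 0.269, K_N = 0.659, K_C = 0.849, M = 50L, d = 1),
    radiation = list(k = 25, D = 2, r_C = 15, r_N = 10,
                     m_C = 0.0012, m_N = 0.0092, S_C = 0.95, S_N = 0.43),
    automaton = list(rows = 200L, cols = 200L, dt = 0.05,
                     cycle_model = "exponential"),
    anneal = list(n_proposals = 10000L, cooling = 0.95, block = 50L,
                  step_frac = 0.05, sigma = 0.03),
    output_dir = ".", seed = 1L, log_level = "info"),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration and merges it over [default_config()], so an
#' empty file yields the measured baseline parameters. Unknown keys are
#' rejected; every validation failure is collected and reported in one
#' message.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("config file does not parse as YAML: ", conditionMessage(e),
           call. = FALSE)
    })
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    problems <- character(0)
    top_unknown <- setdiff(names(user), names(cfg))
    if (length(top_unknown)) {
      problems <- c(problems, paste0("unknown top-level key(s): ",
                                     paste(top_unknown, collapse = ", ")))
    }
    for (block in intersect(names(user), c("kinetics", "radiation",
                                           "automaton", "anneal"))) {
      unknown <- setdiff(names(user[[block]]), names(cfg[[block]]))
      if (length(unknown)) {
        problems <- c(problems, paste0("unknown key(s) in '", block, "': ",
                                       paste(unknown, collapse = ", ")))
      }
    }
    if (length(problems)) {
      stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
           call. = FALSE)
    }
    for (block in names(user)) {
      cfg[[block]] <- if (is.list(cfg[[block]])) {
        modifyList(cfg[[block]], user[[block]])
      } else user[[block]]
    }
  }
  # constructing the parameter objects runs every invariant check; collect
  # the failures so a bad file is diagnosed in one pass
  problems <- character(0)
  for (expr in list(function() config_kinetics(cfg),
                    function() config_radiation(cfg))) {
    tryCatch(expr(), error = function(e) {
      problems <<- c(problems, conditionMessage(e))
    })
  }
  if (length(problems)) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

#' Materialise model objects from a run configuration
#'
#' @param cfg a `run_config` list.
#' @return `config_kinetics()` a [kinetic_params()]; `config_radiation()` a
#'   [radiation_params()].
#' @export
config_kinetics <- function(cfg) {
  k <- cfg$kinetics
  kinetic_params(division_probs(k$P_S, k$P_A, k$P_D),
                 k_t = k$K_T, k_n = k$K_N, k_c = k$K_C,
                 m_gen = k$M, d = k$d)
}

#' @rdname config_kinetics
#' @export
config_radiation <- function(cfg) {
  r <- cfg$radiation
  radiation_params(k_dsb = r$k, dose_gy = r$D, r_csc = r$r_C, r_nscc = r$r_N,
                   m_csc = r$m_C, m_nscc = r$m_N, s_csc = r$S_C,
                   s_nscc = r$S_N)
}

#' Write / read a proportion time course as CSV
#'
#' The on-disk schema has columns `time_days`, `csc_count`, `nscc_total`,
#' `csc_proportion` (trajectories) or at minimum `time_days` and
#' `csc_proportion` (observed courses). Reading validates the schema and
#' that times are strictly increasing.
#'
#' @param x a `csc_trajectory` or any data frame with the schema columns.
#' @param path file path.
#' @return `read_timecourse()` returns the validated data frame.
#' @export
write_timecourse <- function(x, path) {
  if (inherits(x, "synthetic_time_course")) x <- x$data
  stopifnot(is.data.frame(x), "time_days" %in% names(x))
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("time-course file is empty: ", path, call. = FALSE)
  df <- read.csv(path)
  if (nrow(df) == 0) stop("time-course file has no rows: ", path, call. = FALSE)
  needed <- "time_days"
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("time-course file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("csc_proportion" %in% names(df)) &&
      !all(c("csc_count", "nscc_total") %in% names(df))) {
    stop("time-course file needs csc_proportion or csc_count + nscc_total",
         call. = FALSE)
  }
  if (any(diff(df$time_days) <= 0)) {
    stop("time_days must be strictly increasing", call. = FALSE)
  }
  df
}
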