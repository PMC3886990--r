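# Baseline parameter sets used throughout the suite: the measured SW620
# values with the conventional lifespan M = 50, d = 1.
table1_params <- function(...) kinetic_params(...)

table2_params <- function(...) radiation_params(...)

# mixed initial state with a given CSC proportion
mixed_state <- function(prop, n = 1000, m_gen = 50L) {
  population_state(csc = n * prop,
                   nscc = c(n * (1 - prop), rep(0, m_gen - 1L)))
}
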