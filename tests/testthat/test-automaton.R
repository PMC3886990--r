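test_that("lattice seeding places the requested composition on vacant sites", {
  cfg <- automaton_config(rows = 200, cols = 200, seed = 3)
  st <- init_lattice(cfg, n_csc = 0, n_nscc = 100)
  expect_equal(sum(st$type != 0), 100)
  expect_true(all(st$gen[st$type == 2] == 1))

  st2 <- init_lattice(cfg, total = 1000, prop_csc = 0.7)
  expect_equal(sum(st2$type == 1), 700)
  expect_equal(sum(st2$type == 2), 300)

  # determinism under a fixed seed
  st3 <- init_lattice(cfg, total = 1000, prop_csc = 0.7)
  expect_identical(st2$type, st3$type)

  expect_error(init_lattice(automaton_config(rows = 5, cols = 5), n_nscc = 26),
               "cannot seed")
})

test_that("identical config and seed give bit-identical trajectories", {
  run_once <- function() {
    st <- init_lattice(automaton_config(rows = 60, cols = 60, seed = 11),
                       n_csc = 20, n_nscc = 80)
    ca_run(st, n_steps = 60, record_every = 10)$counts
  }
  expect_identical(run_once(), run_once())
})

test_that("a lone self-renewing CSC doubles after completing its cycle", {
  probs <- division_probs(1, 0, 0)
  kp <- kinetic_params(probs, k_t = 0, k_n = 0)
  cfg <- automaton_config(rows = 11, cols = 11, dt = 0.5, params = kp,
                          seed = 2)
  st <- init_lattice(cfg, n_csc = 1)
  for (i in 1:40) st <- ca_step(st)   # 20 days: division essentially certain
  expect_gte(sum(st$type == 1), 2)
  expect_equal(sum(st$type == 2), 0)  # pure self-renewal makes only CSCs
})

test_that("a full lattice cannot divide; only composition changes", {
  kp <- table1_params()
  cfg <- automaton_config(rows = 12, cols = 12, dt = 0.05, params = kp,
                          seed = 5)
  st <- init_lattice(cfg, total = 144, prop_csc = 0.3)
  res <- ca_run(st, n_steps = 40, record_every = 5)
  total <- res$counts$csc_count + res$counts$nscc_count
  # no vacancies were ever created (d reaches only generation 50), so the
  # population cannot grow; transitions still shift NSCCs into CSCs
  expect_true(all(total == 144))
  expect_gt(res$counts$csc_count[nrow(res$counts)], res$counts$csc_count[1])
})

test_that("NSCC divisions age both daughters by one generation", {
  kp <- kinetic_params(k_t = 0, k_n = 3, k_c = 0)
  cfg <- automaton_config(rows = 31, cols = 31, dt = 0.05, params = kp,
                          seed = 7)
  st <- init_lattice(cfg, n_nscc = 1)
  res <- ca_run(st, n_steps = 100)
  st2 <- res$state
  gens <- st2$gen[st2$type == 2]
  expect_gt(length(gens), 1)          # it divided
  expect_true(all(gens >= 2))         # founder generation 1 is gone
  expect_lte(max(gens), 50)           # within the replicative lifespan
})

test_that("without transitions an all-NSCC lattice never produces a CSC", {
  kp <- kinetic_params(k_t = 0)
  st <- init_lattice(automaton_config(rows = 50, cols = 50, params = kp,
                                      seed = 9), n_nscc = 50)
  res <- ca_run(st, n_steps = 100, record_every = 20)
  expect_true(all(res$counts$csc_count == 0))
})

test_that("occupancy never exceeds capacity and counts match the lattice", {
  st <- init_lattice(automaton_config(rows = 30, cols = 30, seed = 13),
                     total = 200, prop_csc = 0.5)
  res <- ca_run(st, n_steps = 100, record_every = 25)
  expect_true(all(res$counts$csc_count + res$counts$nscc_count <= 900))
  final <- res$counts[nrow(res$counts), ]
  expect_equal(sum(res$state$type == 1), final$csc_count)
  expect_equal(sum(res$state$type == 2), final$nscc_count)
})

test_that("dilute-regime ensemble mean tracks the ODE proportion", {
  kp <- table1_params()
  tr <- integrate_model(kp, population_state(0, c(200, rep(0, 49))),
                        t_end = 2, dt_out = 1)
  props <- sapply(1:8, function(s) {
    st <- init_lattice(automaton_config(rows = 150, cols = 150, seed = s),
                       n_nscc = 200)
    ca_run(st, n_steps = 40, record_every = 20)$counts$csc_proportion
  })
  m <- rowMeans(props)
  se <- apply(props, 1, stats::sd) / sqrt(ncol(props))
  expect_true(all(abs(m[-1] - tr$csc_proportion[-1]) < 3 * se[-1] + 0.01))
})

test_that("colony growth clusters same-type cells beyond the well-mixed null", {
  # join-count statistic: fraction of like-type neighbour pairs, compared
  # with a permutation null that shuffles types over the occupied sites
  st <- init_lattice(automaton_config(rows = 100, cols = 100, seed = 21),
                     total = 60, prop_csc = 0.5)
  res <- ca_run(st, n_steps = 120)
  type <- res$state$type
  like_frac <- function(type) {
    h_a <- type[-nrow(type), ]; h_b <- type[-1, ]
    v_a <- type[, -ncol(type)]; v_b <- type[, -1]
    pairs_ok <- (h_a != 0 & h_b != 0); pairs_same <- (h_a == h_b & pairs_ok)
    vpairs_ok <- (v_a != 0 & v_b != 0); vpairs_same <- (v_a == v_b & vpairs_ok)
    sum(pairs_same + 0) + sum(vpairs_same + 0)
  }
  obs <- like_frac(type)
  occ <- which(type != 0)
  set.seed(99)
  null <- replicate(200, {
    t2 <- type; t2[occ] <- sample(type[occ]); like_frac(t2)
  })
  expect_gt(obs, stats::quantile(null, 0.95))
})

test_that("serial passaging keeps the lattice dilute and preserves cells", {
  st <- init_lattice(automaton_config(rows = 100, cols = 100, seed = 31),
                     n_nscc = 150)
  out <- ca_run_passaged(st, t_end = 6, passage_interval = 1, n_reseed = 150)
  expect_equal(nrow(out), 6)
  total <- out$csc_count + out$nscc_count
  expect_true(all(total < 0.2 * 100 * 100))
  expect_true(all(diff(out$time_days) > 0))
})

test_that("lattice text rendering round-trips the occupancy", {
  st <- init_lattice(automaton_config(rows = 8, cols = 10, seed = 1),
                     n_csc = 5, n_nscc = 7)
  txt <- format_lattice(st)
  expect_length(txt, 8)
  expect_true(all(nchar(txt) == 10))
  chars <- unlist(strsplit(txt, ""))
  expect_equal(sum(chars == "C"), 5)
  expect_equal(sum(chars == "N"), 7)
})
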