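# Single-neuron and synapse dynamics of the network integrator, against
# closed-form and root-finding oracles.

cfg <- model_config()

test_that("subthreshold EIF relaxes to rest without spiking", {
  r <- simulate_single_eif("exc", cfg, v0 = cfg$neuron$exc$e_l + 5,
                           duration_ms = 200)
  expect_length(r$spike_times_ms, 0)
  expect_lt(abs(tail(r$vm, 1) - cfg$neuron$exc$e_l), 0.5)
  expect_true(all(diff(r$vm[1:1000]) <= 1e-12))  # monotone decay
})

test_that("EIF rheobase conductance from root-finding matches the simulated boundary", {
  p <- cfg$neuron$exc
  # stationary equation 0 = -(V-EL) + DT exp((V-VT)/DT) + R g (Eexc - V);
  # the rheobase is the largest g for which a stable fixed point remains
  has_fixed_point <- function(g) {
    f <- function(v) -(v - p$e_l) + cfg$neuron$delta_t *
      exp((v - p$v_t) / cfg$neuron$delta_t) +
      p$r_mohm * 1e-3 * g * (cfg$neuron$e_exc - v)
    any(f(seq(p$e_l - 5, cfg$neuron$v_spike, by = 0.001)) < 0)
  }
  lo <- 0; hi <- 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (has_fixed_point(mid)) lo <- mid else hi <- mid
  }
  g_rheo <- (lo + hi) / 2
  # simulated spiking/non-spiking boundary by bisection on g
  spikes_at <- function(g) length(simulate_single_eif(
    "exc", cfg, g_exc_ns = g, duration_ms = 600, dt_ms = 0.01)$spike_times_ms) > 0
  lo <- 0.5 * g_rheo; hi <- 2 * g_rheo
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  g_sim <- (lo + hi) / 2
  expect_lt(abs(g_sim - g_rheo) / g_rheo, 0.01)
})

test_that("with a tiny slope factor the EIF f-I curve approaches the LIF closed form", {
  p <- cfg$neuron$exc
  for (i_na in c(0.12, 0.16, 0.24)) {
    r <- simulate_single_eif("exc", cfg, i_ext_na = i_na,
                             duration_ms = 2000, dt_ms = 0.01,
                             delta_t_override = 8e-4)
    ri <- p$r_mohm * i_na
    pred <- 1000 / (p$t_ref + p$tau_m *
                      log((ri + p$e_l - cfg$neuron$v_reset) /
                            (ri + p$e_l - p$v_t)))
    expect_equal(r$rate_hz, pred, tolerance = 0.02)
  }
})

test_that("a single spike leaves an exponentially decaying conductance trace", {
  # passive neuron, one EPSP: after the peak, the synaptic current decays
  # with tau_syn, so ln(g) reconstructed from the Vm ODE is linear in t
  r <- simulate_epsp_train(100, weight_ns = 2, stp_u = 1, tau_rec = 1e9,
                           duration_ms = 300, dt_ms = 0.01)
  p <- cfg$neuron$exc
  v <- r$vm
  dv <- (v[-1] - v[-length(v)]) / 0.01
  vm <- v[-length(v)]
  g <- (p$tau_m * dv + (vm - p$e_l)) / (p$r_mohm * 1e-3 * (0 - vm))
  idx <- which(r$t_ms[-length(v)] > 101 & r$t_ms[-length(v)] < 106)
  fit <- lm(log(g[idx]) ~ r$t_ms[idx])
  expect_equal(-1 / coef(fit)[[2]], cfg$synapse$tau_exc, tolerance = 0.02)
  # and the increment is weight * u * x = 2 * 1 * 1 nS at onset
  expect_equal(max(g, na.rm = TRUE), 2, tolerance = 0.02)
})

test_that("TM depression matches its closed-form steady state to 1e-6", {
  u <- 0.75; tau_rec <- 125; T <- 50
  spikes <- seq(0, by = T, length.out = 60)
  rel <- tm_release(spikes, u, tau_rec)
  x <- rel / u
  e <- exp(-T / tau_rec)
  x_ss <- (1 - e) / (1 - (1 - u) * e)
  expect_equal(x[60], x_ss, tolerance = 1e-6)
  # u = 0 disables depression: every release fraction identical
  rel0 <- tm_release(spikes, 0, tau_rec)
  expect_true(all(rel0 == 0))
  r1 <- simulate_epsp_train(spikes + 10, weight_ns = 0.5, stp_u = 0,
                            duration_ms = 1000)
  # with u = 0 nothing is ever released; Vm stays at rest
  expect_lt(max(abs(r1$vm - cfg$neuron$exc$e_l)), 1e-9)
})

test_that("successive EPSPs depress along the network code path like tm_release", {
  T <- 60
  spikes <- seq(20, by = T, length.out = 8)
  r <- simulate_epsp_train(spikes, weight_ns = 0.4, tau_rec = 125,
                           duration_ms = 700, dt_ms = 0.1)
  base <- cfg$neuron$exc$e_l
  amps <- vapply(spikes, function(s) {
    win <- r$t_ms >= s & r$t_ms < s + T / 2
    max(r$vm[win]) - base
  }, 1)
  rel <- tm_release(spikes, 0.75, 125)
  expect_equal(amps / amps[1], rel / rel[1], tolerance = 0.02)
  # amplitudes strictly decreasing towards the periodic steady state
  expect_true(all(diff(amps) < 0))
})

test_that("network runs are deterministic and Vm stays within conductance bounds", {
  cfg_s <- make_scaled_config(0.06, overrides = list(
    geometry = list(sheet_mm = c(1.2, 1.2), lgn_field_deg = 1.44),
    protocol = list(disk_diameters_deg = c(0, 0.6), ring_outer_deg = 0.7,
                    duration_ms = 400, trials = 1),
    sim = list(record_ecc_deg = 0.25, lgn_dt_ms = 0.5)))
  cfg_s$counts$lgn <- 800
  cfg_s <- sparsify_config(cfg_s, 0.25)
  con <- build_connectome(cfg_s, seed = 2)
  a <- run_protocol(con, cfg_s, seed = 5, trials = 1)
  b <- run_protocol(con, cfg_s, seed = 5, trials = 1)
  expect_identical(a$vm, b$vm)
  expect_identical(a$spikes, b$spikes)
  vm <- do.call(cbind, a$vm[[2]])
  expect_gte(min(vm), cfg_s$neuron$e_inh - 1e-9)  # bounded below by E_inh
  expect_lte(max(vm), cfg_s$neuron$v_spike + 1e-9)
  # refractory contract: no ISI below t_ref for any recorded cell
  isi_ok <- vapply(seq_len(nrow(a$cells)), function(j) {
    s <- a$spikes[[2]][[1]][[j]]
    length(s) < 2 || min(diff(s)) >= ifelse(a$cells$cell_class[j] == "exc",
                                            2, 0.5) - 1e-9
  }, TRUE)
  expect_true(all(isi_ok))
  # population activity is bounded (no runaway) under a blank stimulus
  blank_rate <- mean(lengths(a$spikes[[1]][[1]])) / 0.4
  expect_lt(blank_rate, 100)
})
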