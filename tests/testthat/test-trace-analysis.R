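# Cyclegram construction, response measures, spike removal, classification.

test_that("cyclegram averaging is exact on constant and periodic traces", {
  cg <- build_cyclegram(vm = rep(-65, 1000), period_ms = 250, dt_ms = 1)
  expect_equal(cg$vm, rep(-65, 250))
  expect_equal(cg$n_cycles, 4)
  # two identical concatenated cycles average to either cycle
  one <- sin(2 * pi * (0:249) / 250) - 60
  cg2 <- build_cyclegram(vm = c(one, one), period_ms = 250, dt_ms = 1)
  expect_equal(cg2$vm, one)
  # partial cycles are discarded
  cg3 <- build_cyclegram(vm = c(one, one, one[1:100]), period_ms = 250,
                         dt_ms = 1)
  expect_equal(cg3$n_cycles, 2)
  expect_error(build_cyclegram(vm = one[1:100], period_ms = 250, dt_ms = 1),
               "complete cycle")
})

test_that("quantify recovers DC and F1 of a sinusoid for any phase", {
  t <- 0:499
  for (phi in c(0, 0.7, 2.1, 4.5)) {
    y <- -62 + 3.5 * sin(2 * pi * t / 250 + phi)
    cg <- build_cyclegram(vm = y, period_ms = 250, dt_ms = 1)
    q <- quantify_cyclegram(cg)
    expect_equal(q$VmDC, -62, tolerance = 1e-10)
    expect_equal(q$VmF1, 3.5, tolerance = 1e-10)
  }
})

test_that("least-squares F1 equals the DFT fundamental on integer-cycle traces", {
  set.seed(7)
  n <- 500  # one cycle, arbitrary trace
  y <- rnorm(n) + 2 * sin(2 * pi * (0:(n - 1)) / n) + 5
  cg <- build_cyclegram(vm = y, period_ms = n, dt_ms = 1)
  f1_dft <- 2 / n * Mod(stats::fft(y)[2])
  expect_equal(quantify_cyclegram(cg)$VmF1, f1_dft, tolerance = 1e-10)
  # and the DC term equals the mean
  expect_equal(quantify_cyclegram(cg)$VmDC, mean(y), tolerance = 1e-12)
})

test_that("quantify is linear in the trace for DC and F1", {
  set.seed(11)
  y <- rnorm(500, -60)
  q1 <- quantify_cyclegram(build_cyclegram(vm = y, period_ms = 250, dt_ms = 1))
  q3 <- quantify_cyclegram(build_cyclegram(vm = 3 * y, period_ms = 250,
                                           dt_ms = 1))
  expect_equal(q3$VmDC, 3 * q1$VmDC)
  expect_equal(q3$VmF1, 3 * q1$VmF1)
})

test_that("PSTH measures: flat rate gives MFR = r and spikesF1 ~ 0", {
  set.seed(3)
  r <- 40  # Hz, regular train so the PSTH is exactly flat at bin width 1/64
  period <- 320
  spk <- seq(2.5, 1600, by = 1000 / r)
  cg <- build_cyclegram(spikes = spk, period_ms = period, dt_ms = 1,
                        duration_ms = 1600, n_bins = 64)
  q <- quantify_cyclegram(cg)
  expect_equal(q$MFR, r, tolerance = 1e-10)
  expect_lt(q$spikesF1, 1e-8)
})

test_that("spike removal recovers the subthreshold trace under both conventions", {
  dt <- 0.1
  t <- seq(0, 999.9, by = dt)
  clean <- -65 + 6 * sin(2 * pi * t / 250)
  spk_times <- c(100, 230, 480, 720)
  dirty <- clean
  for (s in spk_times) {
    i0 <- as.integer(s / dt) + 1L
    idx <- i0:(i0 + 19L)  # 2 ms stereotyped spike, 45 mV peak
    dirty[idx] <- dirty[idx] + 45 * exp(-((seq_along(idx) - 6) / 4)^2)
  }
  for (m in c("onset", "window")) {
    out <- remove_spikes(dirty, dt, method = m, spike_times_ms = spk_times)
    expect_lt(sqrt(mean((out - running_mean5(clean))^2)), 0.5)
  }
  # removal is invariant to spike amplitude above threshold
  dirty2 <- clean
  for (s in spk_times) {
    i0 <- as.integer(s / dt) + 1L
    idx <- i0:(i0 + 19L)
    dirty2[idx] <- dirty2[idx] + 90 * exp(-((seq_along(idx) - 6) / 4)^2)
  }
  expect_equal(remove_spikes(dirty, dt, method = "onset"),
               remove_spikes(dirty2, dt, method = "onset"), tolerance = 0.2)
  # spikeless trace passes through (only smoothed)
  expect_equal(remove_spikes(clean, dt, method = "onset"),
               running_mean5(clean))
  expect_error(remove_spikes(clean[1:3], dt), "smoothing window")
})

test_that("VmSD recovers a known noise SD in both modes and handles F1 subtraction", {
  set.seed(5)
  sigma <- 2
  seg <- matrix(rnorm(500 * 30, -70, sigma), nrow = 500)
  expect_equal(vm_sd(seg, 1, mode = "three_part"), sigma, tolerance = 0.05)
  expect_equal(vm_sd(seg, 1, mode = "sliding_100ms"), sigma, tolerance = 0.05)
  # pure sinusoid with F1 subtraction leaves ~zero residual SD
  t <- 0:499
  sine <- matrix(rep(-60 + 4 * sin(2 * pi * t / 500), 3), ncol = 3)
  expect_lt(vm_sd(sine, 1, mode = "three_part", f1_subtract = TRUE,
                  period_ms = 500), 1e-10)
  # without subtraction the per-third SD of a sine matches the closed form
  got <- vm_sd(sine, 1, mode = "three_part")
  thirds <- split(sine[, 1], rep(1:3, times = diff(floor(500 * 0:3 / 3))))
  expect_equal(got, mean(vapply(thirds, sd, 1)))
  expect_gt(got, 0)
  # the two modes agree within 20% on stationary noise
  a <- vm_sd(seg, 1, mode = "three_part")
  b <- vm_sd(seg, 1, mode = "sliding_100ms")
  expect_lt(abs(a - b) / a, 0.2)
})

test_that("simple/complex classification flips exactly at F1/F0 = 1", {
  expect_equal(classify_cell(spikes_f1 = 12, mfr = 8)$class, "simple")
  expect_equal(classify_cell(spikes_f1 = 0, mfr = 8)$class, "complex")
  expect_true(is.na(classify_cell(0, 0)$class))
  for (ratio in c(0.8, 0.99, 1.01, 1.3)) {
    cls <- classify_cell(spikes_f1 = ratio * 10, mfr = 10)$class
    expect_equal(cls, if (ratio > 1) "simple" else "complex")
  }
  # simple cells with DC depolarisation exceeding F1 are flagged
  cc <- classify_cell(12, 8, vm_dc_depol = 9, vm_f1 = 5)
  expect_true(cc$excluded)
  ok <- classify_cell(12, 8, vm_dc_depol = 3, vm_f1 = 5)
  expect_false(ok$excluded)
})

test_that("cell selection applies the eccentricity and strict rate criteria", {
  cells <- data.frame(cell = 1:4,
                      ecc_deg = c(0.1, 0.5, 0.3, 0.39),
                      max_disk_rate_hz = c(5, 50, 1.0, 0))
  sel <- select_cells(cells)
  expect_equal(sel$cell, 1L)
  ex <- attr(sel, "excluded")
  expect_equal(ex$reason[ex$cell == 2], "outside eccentricity window")
  expect_equal(nrow(ex), 3)
})
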