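# Spatial-integration indices on hand-built size-tuning curves.

# curve used in several blocks: rest -70, saturating then suppressed disks,
# rings declining from the full-disk value
ex_curve <- function() {
  size_tuning_curve(
    diameters = c(0, 1, 2, 4, 8),
    disk = c(-70, -60, -56, -57, -58),
    ring = c(-58, -61, -64, -68, -70),
    baseline = -70)
}

test_that("suppression index handles flat, fully suppressed and example curves", {
  flat <- size_tuning_curve(c(0, 1, 2), disk = c(0, 5, 5), ring = c(5, 3, 0),
                            baseline = 0)
  expect_equal(suppression_index(flat), 0)
  full <- size_tuning_curve(c(0, 1, 2), disk = c(0, 5, 0), ring = c(0, 3, 0),
                            baseline = 0)
  expect_equal(suppression_index(full), 100)
  # supragranular example: rest -77.3, peak -59.0, largest-disk -61 -> ~11%
  sgc <- size_tuning_curve(c(0, 1.8, 10), disk = c(-77.3, -59.0, -61),
                           baseline = -77.3)
  expect_equal(round(suppression_index(sgc)), 11)
  # same cell's firing rate: rest 0, peak 10.5, largest 2.3 -> ~78%
  mfr <- size_tuning_curve(c(0, 1.5, 10), disk = c(0, 10.5, 2.3),
                           baseline = 0, measure = "MFR")
  expect_equal(round(suppression_index(mfr)), 78)
  # simple-cell modulation amplitudes quoted raw: 6.8 -> 5.5 is 19%
  f1 <- size_tuning_curve(c(0, 1.9, 16.5), disk = c(0.6, 6.8, 5.5),
                          baseline = 0.6, measure = "VmF1")
  expect_equal(round(suppression_index(f1, subtract_baseline = FALSE)), 19)
})

test_that("suppression index is undefined when the peak sits at the noise floor", {
  cv <- size_tuning_curve(c(0, 1, 2), disk = c(0, 0.5, 0.2), ring = c(0, 0, 0),
                          baseline = 0, baseline_sem = 0.3)
  expect_true(is.na(suppression_index(cv)))
})

test_that("residual matches direct arithmetic on printed example values", {
  # infragranular cell: rest -70.4, peak -56.8, matched ring -71.7
  cv <- size_tuning_curve(c(0, 10.3, 16), disk = c(-70.4, -56.8, -58),
                          ring = c(-58, -71.7, -70.4), baseline = -70.4)
  expect_equal(residual_index(cv), (-71.7 + 70.4) / (-56.8 + 70.4))
  expect_equal(round(residual_index(cv), 2), -0.10)
  # boundary cases
  z <- size_tuning_curve(c(0, 1, 2), disk = c(0, 10, 8), ring = c(8, 0, 0),
                         baseline = 0)
  expect_equal(residual_index(z), 0)
  one <- size_tuning_curve(c(0, 1, 2), disk = c(0, 10, 8), ring = c(8, 10, 0),
                           baseline = 0)
  expect_equal(residual_index(one), 1)
})

test_that("NLI follows the prediction-minus-peak convention and its identities", {
  # perfectly tiling linear cell without suppression: D_i + R_i = Dpeak
  lin <- size_tuning_curve(c(0, 1, 2), disk = c(0, 6, 10),
                           ring = c(10, 4, 0), baseline = 0)
  expect_equal(as.numeric(nonlinearity_index(lin)), 0)
  # no suppression, matched-ring residual 0.5 -> NLI = 0.5
  r5 <- size_tuning_curve(c(0, 1, 2), disk = c(0, 10, 10),
                          ring = c(10, 5, 0), baseline = 0)
  expect_equal(as.numeric(nonlinearity_index(r5)), 0.5)
  # linear tiling cell with suppression s: NLI = -s (rings complement Dlargest)
  s <- 0.3
  D <- c(0, 10, 10 * (1 - s))
  sup <- size_tuning_curve(c(0, 1, 2), disk = D, ring = D[3] - D, baseline = 0)
  expect_equal(as.numeric(nonlinearity_index(sup)), -s)
  expect_equal(suppression_index(sup), 100 * s)
})

test_that("LI profile is zero for tiling-linear cells and signed as deviation", {
  lin <- size_tuning_curve(c(0, 1, 2, 3), disk = c(0, 4, 9, 10),
                           ring = c(10, 6, 1, 0), baseline = 0)
  li <- linearity_index(lin)
  expect_equal(li$per_pair, rep(0, 4))
  expect_equal(li$mean, 0)
  # a pair summing to 1.2x the largest disk scores -20%
  ov <- size_tuning_curve(c(0, 1, 2), disk = c(0, 6, 10),
                          ring = c(10, 6, 0), baseline = 0)
  expect_equal(linearity_index(ov)$per_pair[2], -20)
  # the i = 1 pair (blank + full disk) is always exactly 0
  expect_equal(linearity_index(ex_curve())$per_pair[1], 0)
})

test_that("for nonnegative curves NLI >= -SI/100 (the i=1 pair bounds the sum)", {
  set.seed(42)
  d <- c(0, 0.5, 1, 2, 3, 4, 6)
  for (k in 1:25) {
    s <- runif(1, 0, 0.5)
    prof <- disk_ring_profiles(
      d, peak_diameter_deg = runif(1, 0.8, 3), peak_amp = runif(1, 5, 15),
      suppression = s, residual = runif(1, 0, 0.8 * (1 - s)))
    cv <- size_tuning_curve(d, prof$D, prof$R, baseline = 0)
    nli <- as.numeric(nonlinearity_index(cv))
    si <- suppression_index(cv)
    expect_gte(nli, -si / 100 - 1e-12)
  }
})

test_that("metrics are invariant to uniform rescaling of the measure", {
  cv <- ex_curve()
  sc <- size_tuning_curve(cv$diameters, -70 + 3 * (cv$disk + 70),
                          -70 + 3 * (cv$ring + 70), baseline = -70)
  expect_equal(suppression_index(sc), suppression_index(cv))
  expect_equal(residual_index(sc), residual_index(cv))
  expect_equal(as.numeric(nonlinearity_index(sc)),
               as.numeric(nonlinearity_index(cv)))
  expect_equal(linearity_index(sc)$mean, linearity_index(cv)$mean)
})

test_that("population comparison matches brute-force U counting and KS extremes", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(0.5, 2.9, 1.1)
  res <- compare_populations(list(g1 = a, g2 = b))
  # Mann-Whitney U = number of (a_i > b_j) pairs (+0.5 per tie)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(res$tests$U, U)
  same <- compare_populations(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$tests$U, 9 / 2)
  expect_equal(same$tests$ks_D, 0)
  disj <- compare_populations(list(x = c(1, 2, 3), y = c(10, 11, 12)))
  expect_equal(disj$tests$ks_D, 1)
  expect_equal(res$summary$median[1], median(a))
  expect_equal(res$summary$sem[2], sd(b) / sqrt(3))
})
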