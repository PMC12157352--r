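# Connectivity kernels and statistical audits of the sampled wiring.

test_that("Gabor weight matches direct evaluation and phase conventions", {
  # at the origin with zero phase: envelope 1, carrier 1, pedestal G
  expect_equal(gabor_weight(0, 0, theta = 0, psi = 0), 1.085)
  # independent scalar re-evaluation at (0.17, 0), theta 0, psi 0
  x <- 0.17
  by_hand <- exp(-x^2 / (2 * 0.17^2)) * (0.085 + cos(2 * pi * 0.8 * x))
  expect_equal(gabor_weight(0.17, 0, 0, 0), by_hand)
  # psi -> psi + pi negates the carrier but keeps the envelope
  xs <- runif(20, -0.5, 0.5); ys <- runif(20, -0.2, 0.2)
  w0 <- gabor_weight(xs, ys, 0.7, 0)
  wpi <- gabor_weight(xs, ys, 0.7, pi)
  env <- exp(-((xs * cos(0.7) + ys * sin(0.7))^2 +
                 2.5^2 * (-xs * sin(0.7) + ys * cos(0.7))^2) / (2 * 0.17^2))
  expect_equal(w0 + wpi, 2 * env * 0.085, tolerance = 1e-12)
})

test_that("hyperbolic distance profile: value, monotonicity, asymptote", {
  expect_equal(p_dist_hyperbolic(0, 0.0139, 207.7), exp(-0.0139 * 207.7))
  x <- seq(0, 3000, by = 10)
  cfg <- model_config()
  for (r in seq_len(nrow(cfg$table1))) {
    p <- p_dist_hyperbolic(x, cfg$table1$alpha[r], cfg$table1$theta[r])
    expect_true(all(diff(p) < 0))
  }
  # large-x: log p + alpha x ~ -alpha theta^2 / (2x) -> 0
  a <- 0.0139; th <- 207.7
  for (xx in c(3e3, 1e4, 3e4))
    expect_equal(log(p_dist_hyperbolic(xx, a, th)) + a * xx,
                 -a * th^2 / (2 * xx), tolerance = 1e-2)
})

test_that("push-pull bias peaks at the class-specific mode and mirrors", {
  cs <- seq(-1, 1, by = 0.01)
  pe <- p_func_pushpull(cs, "exc")
  expect_equal(cs[which.max(pe)], 1)
  expect_equal(p_func_pushpull(0.3, "exc"), p_func_pushpull(-0.3, "inh"))
  expect_equal(max(pe), dnorm(0, sd = 1.3))
})

test_that("identical Gabors in antiphase have RF correlation near -1", {
  cfg <- audit_config()
  pop4 <- data.frame(id = 1:2, pop = "l4_exc", layer = "L4",
                     cell_class = "exc", x_mm = 0, y_mm = 0,
                     psi = c(0, pi), pref_or = 0.4,
                     rf_x_deg = 0, rf_y_deg = 0, ecc_deg = 0)
  cc <- l4_rf_correlation(pop4, cfg)
  # the Gaussian pedestal keeps the overlap from reaching exactly -1
  expect_lt(cc[1, 2], -0.9)
  expect_equal(cc[1, 1], 1, tolerance = 1e-9)
  pop4$psi <- c(0.8, 0.8)
  cc2 <- l4_rf_correlation(pop4, cfg)
  expect_equal(cc2[1, 2], 1, tolerance = 1e-9)
})

test_that("orientation bias: peak, closed-form ratio, variant ordering", {
  expect_equal(p_func_orientation(0, 1.3), 1 / (1.3 * sqrt(2 * pi)))
  ratio <- function(s) p_func_orientation(pi / 2, s) / p_func_orientation(0, s)
  expect_equal(ratio(1.3), exp(-(pi / 2)^2 / (2 * 1.3^2)))
  # weak bias (3.5 rad) is flatter than strong bias (0.7 rad)
  expect_gt(ratio(3.5), ratio(0.7))
  expect_gt(ratio(3.5), 0.85)
})

test_that("layer 2/3 mixture profile: peak composition and long-range dominance", {
  expect_equal(l23_excitatory_pdf(0, 0),
               1 + 4 * p_func_orientation(0, 1.3))
  # at 2 mm the local Gaussian is numerically dead; the long-range times
  # functional product carries everything
  lr_only <- 4 * exp(-2000^2 / (2 * 1000^2)) * p_func_orientation(0.3, 1.3)
  expect_equal(l23_excitatory_pdf(2000, 0.3), lr_only, tolerance = 1e-6)
  expect_lt(exp(-2000^2 / (2 * 270^2)), 1e-11)
})

test_that("realized in-degrees equal the configured table exactly", {
  con <- audit_connectome()
  cfg <- audit_config()
  pj <- cfg$projections
  pop <- con$populations
  for (r in which(pj$kernel != "gabor")) {
    nm <- paste0(pj$src[r], "->", pj$tgt[r])
    got <- tabulate(con$edges[[nm]]$tgt, nbins = nrow(pop))
    tgt_ids <- pop$id[pop$pop == pj$tgt[r]]
    if (!is.na(pj$in_degree[r])) {
      expect_true(all(got[tgt_ids] == pj$in_degree[r]), info = nm)
    } else {
      tot <- if (pj$tgt[r] == "l4_exc") cfg$thalamic$l4_exc_total_exc
             else cfg$thalamic$l4_inh_total_exc
      expect_equal(got[tgt_ids] + con$lgn_afferents_per_target[tgt_ids],
                   rep(tot, length(tgt_ids)), info = nm,
                   ignore_attr = TRUE)
    }
  }
})

test_that("thalamic afferent counts fall in the configured uniform ranges", {
  con <- audit_connectome()
  cfg <- audit_config()
  pop <- con$populations
  n_aff <- con$lgn_afferents_per_target
  exc <- pop$id[pop$pop == "l4_exc"]; inh <- pop$id[pop$pop == "l4_inh"]
  expect_true(all(n_aff[exc] >= 2 * cfg$thalamic$n_exc_per_polarity[1] &
                    n_aff[exc] <= 2 * cfg$thalamic$n_exc_per_polarity[2]))
  expect_true(all(n_aff[inh] >= 2 * cfg$thalamic$n_inh_per_polarity[1] &
                    n_aff[inh] <= 2 * cfg$thalamic$n_inh_per_polarity[2]))
})

test_that("laminar excitatory input fractions: 22% feedforward, 20% feedback", {
  con <- audit_connectome()
  ff <- nrow(con$edges[["l4_exc->l23_exc"]])
  rec <- nrow(con$edges[["l23_exc->l23_exc"]])
  expect_equal(ff / (ff + rec), 0.22, tolerance = 0.005)
  pop <- con$populations
  fb <- nrow(con$edges[["l23_exc->l4_exc"]])
  r4 <- nrow(con$edges[["l4_exc->l4_exc"]])
  nl <- sum(con$lgn_afferents_per_target[pop$id[pop$pop == "l4_exc"]])
  expect_equal(fb / (fb + r4 + nl), 0.20, tolerance = 0.005)
})

test_that("ON afferents of layer 4 cells sit on Gabor-positive subfields", {
  con <- audit_connectome()
  cfg <- audit_config()
  th <- con$edges[["lgn->l4"]]
  pop <- con$populations
  p4 <- pop[pop$layer == "L4", ]
  set.seed(1)
  for (id in sample(p4$id, 25)) {
    cell <- p4[p4$id == id, ]
    for (pol in c("ON", "OFF")) {
      e <- th[th$tgt == id & th$polarity == pol, ]
      g <- gabor_weight(con$lgn$x_deg[e$src] - cell$rf_x_deg,
                        con$lgn$y_deg[e$src] - cell$rf_y_deg,
                        cell$pref_or, cell$psi)
      if (pol == "ON") expect_gt(mean(g), 0) else expect_lt(mean(g), 0)
    }
  }
})

test_that("empirical ON-afferent sampling matches the normalised positive lobe", {
  con <- audit_connectome()
  cfg <- audit_config()
  pop <- con$populations
  cell <- pop[pop$pop == "l4_exc", ][1, ]
  g <- gabor_weight(con$lgn$x_deg - cell$rf_x_deg,
                    con$lgn$y_deg - cell$rf_y_deg, cell$pref_or, cell$psi)
  on <- which(con$lgn$polarity == "ON" & g > 0)
  p_theory <- g[on] / sum(g[on])
  set.seed(9)
  draws <- v1rings:::sample_by_weight(g[on], 1e5)
  p_emp <- tabulate(draws, nbins = length(on)) / 1e5
  # total-variation distance between empirical and target distributions
  expect_lt(0.5 * sum(abs(p_emp - p_theory)), 0.02)
})

test_that("push-pull sign segregation holds in the realized layer 4 wiring", {
  con <- audit_connectome()
  cfg <- audit_config()
  pop <- con$populations
  p4 <- pop[pop$layer == "L4", ]
  corr <- l4_rf_correlation(p4, cfg)
  row_of <- match(seq_len(nrow(pop)), p4$id)
  mean_edge_corr <- function(nm) {
    e <- con$edges[[nm]]
    i <- row_of[e$src]; j <- row_of[e$tgt]
    set.seed(2)
    pick <- sample(length(i), min(20000, length(i)))
    mean(corr[cbind(i[pick], j[pick])])
  }
  expect_gt(mean_edge_corr("l4_exc->l4_exc"), 0.05)
  expect_lt(mean_edge_corr("l4_inh->l4_exc"), -0.05)
})

test_that("sampled distances follow the generative pdf (KS against discrete CDF)", {
  cfg <- audit_config()
  set.seed(31)
  n_src <- 1500
  src <- data.frame(
    id = seq_len(n_src), pop = "l23_inh", layer = "L23", cell_class = "inh",
    x_mm = runif(n_src, -0.8, 0.8), y_mm = runif(n_src, -0.8, 0.8),
    psi = 0, pref_or = runif(n_src, 0, pi), rf_x_deg = 0, rf_y_deg = 0,
    ecc_deg = 0)
  tgt <- src[1, ]; tgt$id <- n_src + 1L; tgt$pop <- "l23_exc"
  tgt$cell_class <- "exc"; tgt$x_mm <- 0.05; tgt$y_mm <- -0.02
  e <- sample_projection(src, tgt, "dist_only", 5e4, cfg, seed = 7)
  d_um <- sqrt((src$x_mm - tgt$x_mm)^2 + (src$y_mm - tgt$y_mm)^2)[e$src] * 1000
  # discrete theoretical CDF over the candidate set
  all_d <- sqrt((src$x_mm - tgt$x_mm)^2 + (src$y_mm - tgt$y_mm)^2) * 1000
  t1 <- cfg$table1[cfg$table1$src == "l23_inh" & cfg$table1$tgt == "l23_exc", ]
  w <- p_dist_hyperbolic(all_d, t1$alpha, t1$theta)
  ord <- order(all_d)
  cdf_th <- stats::approxfun(all_d[ord], cumsum(w[ord]) / sum(w),
                             method = "constant", yleft = 0, yright = 1)
  grid <- sort(unique(all_d))
  cdf_emp <- ecdf(d_um)
  expect_lt(max(abs(cdf_emp(grid) - cdf_th(grid))), 0.02)
})

test_that("long-range excitatory edges are iso-orientation biased vs a shuffled null", {
  con <- audit_connectome()
  pop <- con$populations
  e <- con$edges[["l23_exc->l23_exc"]]
  px <- pop$x_mm; py <- pop$y_mm; por <- pop$pref_or
  d <- sqrt((px[e$src] - px[e$tgt])^2 + (py[e$src] - py[e$tgt])^2)
  lr <- which(d > 0.5)  # beyond the local Gaussian's reach
  dor <- orientation_diff(por[e$src[lr]], por[e$tgt[lr]])
  # distance-matched null: same targets, sources shuffled among the
  # long-range edge set (preserves the distance mix by construction)
  set.seed(4)
  null <- replicate(40, {
    sh <- sample(e$src[lr])
    mean(orientation_diff(por[sh], por[e$tgt[lr]]))
  })
  expect_lt(mean(dor), min(null))
})

test_that("cortical delays are the class constant plus 0.33 ms per mm", {
  con <- audit_connectome()
  pop <- con$populations
  for (nm in c("l4_exc->l4_exc", "l4_exc->l4_inh", "l23_inh->l23_exc")) {
    e <- con$edges[[nm]][1:500, ]
    d <- sqrt((pop$x_mm[e$src] - pop$x_mm[e$tgt])^2 +
                (pop$y_mm[e$src] - pop$y_mm[e$tgt])^2)
    const <- switch(nm, "l4_exc->l4_exc" = 1.4, "l4_exc->l4_inh" = 0.5, 1)
    expect_equal(e$delay_ms, const + 0.33 * d, tolerance = 1e-9)
  }
  # thalamic delays: distance-independent, uniform in [1.4, 2.4]
  th <- con$edges[["lgn->l4"]]
  expect_true(all(th$delay_ms >= 1.4 & th$delay_ms <= 2.4))
  # an exc->exc edge at exactly 3 mm would get 1.4 + 3 * 0.33 = 2.39 ms
  expect_equal(v1rings:::cortical_delay("exc", "exc", 3,
                                        model_config()$synapse), 2.39)
})

test_that("connectome construction is deterministic under the seed", {
  cfg <- make_scaled_config(0.06, overrides = list(
    geometry = list(sheet_mm = c(1.2, 1.2), lgn_field_deg = 1.44)))
  cfg$counts$lgn <- 500
  a <- build_connectome(cfg, seed = 11)
  b <- build_connectome(cfg, seed = 11)
  expect_identical(a$edges, b$edges)
  expect_identical(a$populations, b$populations)
  expect_equal(a$provenance$config_hash, b$provenance$config_hash)
})

test_that("variant configs differ from base by exactly one parameter", {
  base <- model_config()
  expect_length(config_diff(base, make_variant_config("base", base)), 0)
  expect_equal(config_diff(base, make_variant_config("broad_EE", base)),
               "l23.sigma_lr_ee_um")
  expect_equal(config_diff(base, make_variant_config("narrow_EE", base)),
               "l23.sigma_lr_ee_um")
  expect_equal(config_diff(base, make_variant_config("low_bias_EE", base)),
               "l23.sigma_or_ee")
  v <- make_variant_config("broad_EE", base)
  expect_equal(v$l23$sigma_lr_ee_um, 1250)
  expect_equal(v$l23$sigma_lr_ei_um, 1000)
  expect_equal(make_variant_config("high_bias_EE", base)$l23$sigma_or_ee, 0.7)
})

test_that("scaled configs preserve in-degrees and reproduce full counts at s = 1", {
  full <- make_scaled_config(1)
  expect_equal(full$counts$l4_exc, 37500)
  expect_equal(full$counts$l4_inh, 9375)
  expect_equal(full$counts$lgn, 14400)
  ten <- make_scaled_config(0.1)
  expect_equal(ten$counts$l4_exc, 3750)
  expect_equal(ten$counts$l4_inh, 937)
  expect_identical(ten$projections$in_degree, full$projections$in_degree)
  expect_error(make_scaled_config(0.02), "scale too small")
  expect_equal(config_hash(make_scaled_config(0.1)),
               config_hash(make_scaled_config(0.1)))
})

test_that("sparsified configs scale in-degrees down and weights up in proportion", {
  cfg <- model_config()
  sp <- sparsify_config(cfg, 0.4)
  keep <- !is.na(cfg$projections$in_degree)
  expect_equal(sp$projections$in_degree[keep],
               as.integer(round(cfg$projections$in_degree[keep] * 0.4)))
  expect_equal(sp$projections$weight_ns * sp$projections$in_degree,
               cfg$projections$weight_ns * cfg$projections$in_degree,
               tolerance = 0.02)
})
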