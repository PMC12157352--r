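#' Thalamocortical Gabor weighting function
#'
#' Signed weight of the Gabor profile that distributes LGN afferents onto a
#' layer 4 cell: a Gaussian envelope times an offset cosine carrier,
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * (G + cos(2 pi f x' + psi))`,
#' with `x', y'` the coordinates rotated by the cell's preferred
#' orientation.  Positive values attract ON afferents, negative values OFF
#' afferents.
#'
#' @param x_deg,y_deg offsets from the RF centre (visual degrees).
#' @param theta preferred orientation (rad).
#' @param psi spatial phase (rad).
#' @param freq_cpd carrier spatial frequency (cycles/degree, default 0.8).
#' @param sigma_deg envelope size (default 0.17 deg).
#' @param gamma envelope aspect ratio (default 2.5).
#' @param G weight of the Gaussian pedestal relative to the carrier
#'   (default 0.085).
#' @return signed weights, same shape as `x_deg`.
#' @export
gabor_weight <- function(x_deg, y_deg, theta, psi, freq_cpd = 0.8,
                         sigma_deg = 0.17, gamma = 2.5, G = 0.085) {
  xp <- x_deg * cos(theta) + y_deg * sin(theta)
  yp <- -x_deg * sin(theta) + y_deg * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma_deg^2)) *
    (G + cos(2 * pi * freq_cpd * xp + psi))
}

#' Hyperbolic distance profile for local cortical connectivity
#'
#' Unnormalised connection probability `exp(-alpha * sqrt(theta^2 + x^2))`
#' as a function of intersomatic distance, the profile fitted to cat
#' axonal/dendritic overlap data.
#'
#' @param x_um distance in micrometres (>= 0).
#' @param alpha,theta profile parameters for the (source, target) pair.
#' @return unnormalised probabilities.
#' @export
p_dist_hyperbolic <- function(x_um, alpha, theta) {
  exp(-alpha * sqrt(theta^2 + x_um^2))
}

#' Push-pull functional bias for layer 4 recurrent connectivity
#'
#' Gaussian in the receptive-field correlation c between the pair, centred
#' on +1 for excitatory presynaptic cells (excitation between correlated
#' RFs) and -1 for inhibitory ones (inhibition between anti-correlated
#' RFs).
#'
#' @param c RF correlation(s) in `[-1, 1]`.
#' @param presyn_class `"exc"` or `"inh"`.
#' @param sigma Gaussian width (default 1.3).
#' @return unnormalised probabilities.
#' @export
p_func_pushpull <- function(c, presyn_class = c("exc", "inh"), sigma = 1.3) {
  mu <- if (match.arg(presyn_class) == "exc") 1 else -1
  stats::dnorm(c, mean = mu, sd = sigma)
}

#' Iso-orientation bias for connections onto/within layer 2/3
#'
#' Gaussian density in the circular orientation-preference difference
#' (`[0, pi/2]`), favouring connections between similarly tuned neurons.
#'
#' @param delta_or orientation differences (rad, from [orientation_diff()]).
#' @param sigma bias width (rad; 1.3 at base, 0.7/3.5 in the high/low-bias
#'   variants).
#' @return unnormalised probabilities.
#' @export
p_func_orientation <- function(delta_or, sigma = 1.3) {
  stats::dnorm(delta_or, mean = 0, sd = sigma)
}

#' Layer 2/3 excitatory connectivity profile
#'
#' Mixture of a local Gaussian with no functional bias and a long-range
#' Gaussian modulated by the iso-orientation bias:
#' `p = exp(-x^2/(2 sigma_local^2)) +
#'    alpha_lr * exp(-x^2/(2 sigma_lr^2)) * p_or(delta_or)`.
#'
#' @param dist_um intersomatic distance (micrometres).
#' @param delta_or orientation difference (rad).
#' @param sigma_local_um,sigma_lr_um Gaussian widths (default 270 and
#'   1000 um).
#' @param alpha_lr long-range weight relative to local (default 4).
#' @param sigma_or orientation-bias width (rad, default 1.3).
#' @return unnormalised probabilities.
#' @export
l23_excitatory_pdf <- function(dist_um, delta_or, sigma_local_um = 270,
                               sigma_lr_um = 1000, alpha_lr = 4,
                               sigma_or = 1.3) {
  exp(-dist_um^2 / (2 * sigma_local_um^2)) +
    alpha_lr * exp(-dist_um^2 / (2 * sigma_lr_um^2)) *
      p_func_orientation(delta_or, sigma_or)
}

# ---- population construction -----------------------------------------------

#' Lay out the cortical populations on the sheet
#'
#' Positions are drawn uniformly over the sheet; preferred orientations are
#' read from the orientation map; layer 4 cells get a random spatial phase;
#' retinotopy is uniform linear (position / magnification).
#'
#' @param cfg a [model_config()].
#' @param map an [generate_orientation_map()] covering the sheet.
#' @param seed RNG seed.
#' @return data.frame: `id`, `pop`, `layer`, `cell_class`, `x_mm`, `y_mm`,
#'   `pref_or`, `psi`, `rf_x_deg`, `rf_y_deg`, `ecc_deg`.
#' @export
build_populations <- function(cfg, map, seed = 1) {
  set.seed(seed)
  pops <- c("l4_exc", "l4_inh", "l23_exc", "l23_inh")
  half <- cfg$geometry$sheet_mm / 2
  out <- lapply(pops, function(p) {
    n <- cfg$counts[[p]]
    data.frame(
      pop = p,
      layer = if (startsWith(p, "l4")) "L4" else "L23",
      cell_class = if (endsWith(p, "exc")) "exc" else "inh",
      x_mm = stats::runif(n, -half[1], half[1]),
      y_mm = stats::runif(n, -half[2], half[2]),
      psi = stats::runif(n, 0, 2 * pi))
  })
  out <- do.call(rbind, out)
  out <- cbind(id = seq_len(nrow(out)), out)
  out$pref_or <- orientation_at(map, cbind(out$x_mm, out$y_mm))
  mag <- cfg$geometry$magnification_mm_per_deg
  out$rf_x_deg <- out$x_mm / mag
  out$rf_y_deg <- out$y_mm / mag
  out$ecc_deg <- sqrt(out$rf_x_deg^2 + out$rf_y_deg^2)
  out
}

# sparse L2-normalised Gabor field matrix for all layer 4 cells on a common
# visual grid; tcrossprod of this gives the pairwise RF correlations
l4_field_matrix <- function(pop4, cfg, grid_deg = NULL) {
  g <- cfg$gabor
  if (is.null(grid_deg)) grid_deg <- cfg$pushpull$corr_grid_deg
  halff <- cfg$geometry$lgn_field_deg / 2 + 1
  gx <- seq(-halff, halff, by = grid_deg)
  support <- 3.2 * g$sigma_deg
  ii <- jj <- vv <- vector("list", nrow(pop4))
  for (k in seq_len(nrow(pop4))) {
    xi <- which(abs(gx - pop4$rf_x_deg[k]) <= support)
    yi <- which(abs(gx - pop4$rf_y_deg[k]) <= support)
    w <- gabor_weight(
      outer(gx[xi] - pop4$rf_x_deg[k], rep(1, length(yi))),
      outer(rep(1, length(xi)), gx[yi] - pop4$rf_y_deg[k]),
      pop4$pref_or[k], pop4$psi[k], g$freq_cpd, g$sigma_deg, g$gamma, g$G)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) next
    pix <- outer(xi, (yi - 1) * length(gx), "+")
    ii[[k]] <- rep.int(k, length(pix))
    jj[[k]] <- as.integer(pix)
    vv[[k]] <- as.numeric(w) / nrm
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(nrow(pop4), length(gx)^2))
}

#' Pairwise receptive-field correlations of the layer 4 population
#'
#' Normalised inner products of the cells' Gabor fields evaluated on a
#' shared visual grid; cells with non-overlapping fields have correlation
#' zero.  Used by the push-pull wiring rule.
#'
#' @param pop4 layer 4 rows of [build_populations()].
#' @param cfg a [model_config()].
#' @return sparse symmetric matrix of correlations in `[-1, 1]`.
#' @export
l4_rf_correlation <- function(pop4, cfg) {
  Fm <- l4_field_matrix(pop4, cfg)
  cc <- methods::as(methods::as(Matrix::tcrossprod(Fm), "generalMatrix"),
                    "CsparseMatrix")
  cc@x <- pmin(pmax(cc@x, -1), 1)
  cc
}

# ---- edge sampling ---------------------------------------------------------

# dense column j of a dgCMatrix, via direct slot access (fast in loops)
.sparse_col <- function(M, j) {
  out <- numeric(nrow(M))
  p <- M@p
  if (p[j + 1L] > p[j]) {
    rng <- (p[j] + 1L):p[j + 1L]
    out[M@i[rng] + 1L] <- M@x[rng]
  }
  out
}

# k draws (with replacement) from unnormalised weights, via the cumulative
# distribution; returns integer indices
sample_by_weight <- function(w, k) {
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  if (!is.finite(tot) || tot <= 0) stop("degenerate sampling weights")
  findInterval(stats::runif(k) * tot, cw) + 1L
}

cortical_delay <- function(src_class, tgt_class, dist_mm, syn) {
  const <- ifelse(src_class == "inh", syn$delay_const_inh,
                  ifelse(tgt_class == "exc", syn$delay_const_ee,
                         syn$delay_const_ei))
  const + syn$delay_ms_per_mm * dist_mm
}

#' Sample the thalamocortical projection
#'
#' Per layer 4 target: the per-polarity afferent count is drawn uniformly
#' from the configured interval ([45, 95] per polarity for excitatory
#' targets, [56, 84] for inhibitory); ON afferents are then sampled (with
#' replacement) proportionally to the positive part of the target's Gabor
#' profile at the LGN cell positions, OFF afferents to the negative part.
#' Weights are constant (1.2 nS) and delays uniform in [1.4, 2.4] ms,
#' independent of distance.
#'
#' @param pop4 layer 4 rows of [build_populations()].
#' @param lgn an [lgn_mosaic()] data.frame.
#' @param cfg a [model_config()].
#' @param seed RNG seed.
#' @return data.frame of edges: `src` (LGN id), `tgt` (cortical id),
#'   `weight_ns`, `delay_ms`, `polarity`.
#' @export
sample_thalamocortical <- function(pop4, lgn, cfg, seed = 1) {
  set.seed(seed)
  g <- cfg$gabor
  w_ns <- cfg$projections$weight_ns[cfg$projections$kernel == "gabor"][1]
  dl <- cfg$synapse$thalamic_delay_ms
  on_idx <- which(lgn$polarity == "ON")
  off_idx <- which(lgn$polarity == "OFF")
  support <- 3.5 * g$sigma_deg
  e_src <- vector("list", nrow(pop4))
  e_non <- integer(nrow(pop4))
  for (k in seq_len(nrow(pop4))) {
    rng <- if (pop4$cell_class[k] == "exc") cfg$thalamic$n_exc_per_polarity
           else cfg$thalamic$n_inh_per_polarity
    n_on <- sample(rng[1]:rng[2], 1)
    n_off <- sample(rng[1]:rng[2], 1)
    near <- abs(lgn$x_deg - pop4$rf_x_deg[k]) <= support &
      abs(lgn$y_deg - pop4$rf_y_deg[k]) <= support
    pick <- function(idx, sign) {
      lobe <- function(ix) {
        gv <- sign * gabor_weight(lgn$x_deg[ix] - pop4$rf_x_deg[k],
                                  lgn$y_deg[ix] - pop4$rf_y_deg[k],
                                  pop4$pref_or[k], pop4$psi[k],
                                  g$freq_cpd, g$sigma_deg, g$gamma, g$G)
        pmax(gv, 0)
      }
      cand <- idx[near[idx]]
      gv <- lobe(cand)
      if (!length(cand) || sum(gv) <= 0) {
        # edge cells: the local support box can miss the requested lobe
        # entirely; fall back to the full mosaic of this polarity
        cand <- idx
        gv <- lobe(cand)
        if (sum(gv) <= 0) stop("Gabor has no lobe of the requested sign here")
      }
      cand[sample_by_weight(gv, if (sign > 0) n_on else n_off)]
    }
    e_src[[k]] <- c(pick(on_idx, 1), pick(off_idx, -1))
    e_non[k] <- n_on
  }
  lens <- lengths(e_src)
  src <- unlist(e_src)
  data.frame(
    src = src, tgt = rep.int(pop4$id, lens), weight_ns = w_ns,
    delay_ms = stats::runif(length(src), dl[1], dl[2]),
    polarity = unlist(lapply(seq_along(lens), function(k)
      rep(c("ON", "OFF"), c(e_non[k], lens[k] - e_non[k])))))
}

# table1 lookup
.t1 <- function(cfg, src, tgt) {
  r <- cfg$table1[cfg$table1$src == src & cfg$table1$tgt == tgt, ]
  if (nrow(r) != 1) stop("no hyperbolic parameters for ", src, "->", tgt)
  r
}

#' Sample one cortico-cortical projection
#'
#' Per target neuron, draws exactly `in_degree` presynaptic partners (with
#' replacement, duplicates kept as separate synapses, self-connections
#' excluded) from the kernel-specific probability over all candidate
#' sources:
#' \describe{
#'   \item{push / pull}{hyperbolic distance profile times the push-pull
#'     Gaussian in RF correlation (or their sum when
#'     `cfg$combine = "sum"`).}
#'   \item{ff_orient}{hyperbolic distance profile times the iso-orientation
#'     bias (layer 4 to layer 2/3 feedforward).}
#'   \item{lr_mixture / fb_orient}{the layer 2/3 excitatory local +
#'     long-range mixture with orientation-biased long-range component
#'     (intralaminar, and the feedback to layer 4 which travels in the same
#'     axon system).}
#'   \item{dist_only}{hyperbolic distance profile alone (layer 2/3
#'     inhibition).}
#' }
#' Delays are the class-pair constant plus 0.33 ms/mm of distance.
#'
#' @param src_pop,tgt_pop population data.frames (rows of
#'   [build_populations()]).
#' @param kernel kernel name (see above).
#' @param in_degree integer vector (recycled) of per-target draw counts.
#' @param cfg a [model_config()].
#' @param corr sparse RF-correlation matrix over the layer 4 population
#'   (required for push/pull); `corr_rows`/`corr_cols` give the row/column
#'   indices of `src_pop`/`tgt_pop` cells within it.
#' @param seed RNG seed.
#' @return edge data.frame: `src`, `tgt` (global ids), `weight_ns` = NA
#'   (filled by the caller), `delay_ms`, `dist_mm`.
#' @export
sample_projection <- function(src_pop, tgt_pop, kernel, in_degree, cfg,
                              corr = NULL, corr_rows = NULL,
                              corr_cols = NULL, seed = 1) {
  set.seed(seed)
  n_src <- nrow(src_pop)
  in_degree <- rep_len(in_degree, nrow(tgt_pop))
  sx <- src_pop$x_mm; sy <- src_pop$y_mm
  src_or <- src_pop$pref_or
  same_pop <- identical(src_pop$id, tgt_pop$id)
  combine <- if (identical(cfg$combine, "sum")) `+` else `*`
  l23 <- cfg$l23
  if (kernel %in% c("push", "pull") && is.null(corr))
    stop("push-pull kernels need the RF correlation matrix")
  if (kernel %in% c("push", "pull", "ff_orient", "dist_only"))
    t1 <- .t1(cfg, src_pop$pop[1], tgt_pop$pop[1])
  total <- sum(in_degree)
  e_src <- integer(total); e_tgt <- integer(total); e_dist <- numeric(total)
  pos <- 0L
  for (k in seq_len(nrow(tgt_pop))) {
    if (in_degree[k] <= 0) next
    dx <- sx - tgt_pop$x_mm[k]; dy <- sy - tgt_pop$y_mm[k]
    dist_um <- sqrt(dx^2 + dy^2) * 1000
    p <- switch(kernel,
      push = , pull = {
        cc <- .sparse_col(corr, corr_cols[k])[corr_rows]
        combine(p_dist_hyperbolic(dist_um, t1$alpha, t1$theta),
                p_func_pushpull(cc, src_pop$cell_class[1],
                                cfg$pushpull$sigma))
      },
      ff_orient = combine(
        p_dist_hyperbolic(dist_um, t1$alpha, t1$theta),
        p_func_orientation(orientation_diff(src_or, tgt_pop$pref_or[k]),
                           l23$sigma_or_ff)),
      lr_mixture = , fb_orient = {
        s_or <- if (tgt_pop$cell_class[1] == "exc") l23$sigma_or_ee
                else l23$sigma_or_ei
        s_lr <- if (tgt_pop$cell_class[1] == "exc") l23$sigma_lr_ee_um
                else l23$sigma_lr_ei_um
        l23_excitatory_pdf(dist_um,
                           orientation_diff(src_or, tgt_pop$pref_or[k]),
                           l23$sigma_local_um, s_lr, l23$alpha_lr, s_or)
      },
      dist_only = p_dist_hyperbolic(dist_um, t1$alpha, t1$theta),
      stop("unknown kernel ", kernel))
    if (same_pop) p[k] <- 0  # no self-connections
    si <- sample_by_weight(p, in_degree[k])
    idx <- pos + seq_along(si)
    e_src[idx] <- si
    e_tgt[idx] <- k
    e_dist[idx] <- dist_um[si]
    pos <- pos + length(si)
  }
  data.frame(
    src = src_pop$id[e_src], tgt = tgt_pop$id[e_tgt],
    delay_ms = cortical_delay(src_pop$cell_class[1], tgt_pop$cell_class[1],
                              e_dist / 1000, cfg$synapse),
    dist_mm = e_dist / 1000)
}

#' Build the full connectome
#'
#' Generates the orientation map, lays out the LGN mosaic and cortical
#' populations, computes layer 4 RF correlations, and samples every
#' projection: thalamocortical Gabor sampling, layer 4 push-pull
#' recurrence, feedforward L4 to L2/3 with orientation bias, layer 2/3
#' local + long-range excitation and local inhibition, and the L2/3 to L4
#' feedback.  Realised in-degrees match the configuration exactly: fixed
#' counts for most projections, and for the layer 4 recurrent excitation
#' the configured total minus the cell's thalamic afferent count.
#'
#' @param cfg a [model_config()] (typically [make_scaled_config()]).
#' @param seed master seed; per-stage child seeds are derived
#'   deterministically and logged in the provenance.
#' @return list of class `"connectome"`: `populations`, `lgn`, `map`,
#'   `edges` (named list of per-projection data.frames with `src`, `tgt`,
#'   `weight_ns`, `delay_ms`, `tau_rec`, `lgn_source` flag), `provenance`.
#' @export
build_connectome <- function(cfg, seed = 1) {
  seeds <- seed + seq(0, 40)
  map <- generate_orientation_map(cfg$geometry$sheet_mm, cfg$map$resolution_mm,
                                  cfg$map$hypercolumn_mm, seed = seeds[1])
  pop <- build_populations(cfg, map, seed = seeds[2])
  lgn <- lgn_mosaic(cfg$counts$lgn, cfg$geometry$lgn_field_deg,
                    cfg$counts$lgn_on_fraction, seed = seeds[3])
  p4 <- pop[pop$layer == "L4", ]
  corr <- l4_rf_correlation(p4, cfg)
  corr_idx <- match(pop$id, p4$id)  # cortical id -> row of corr (NA for L23)

  th <- sample_thalamocortical(p4, lgn, cfg, seed = seeds[4])
  th$lgn_count <- 1
  n_lgn <- tapply(th$lgn_count, th$tgt, sum)
  lgn_per_tgt <- rep(0L, nrow(pop))
  lgn_per_tgt[as.integer(names(n_lgn))] <- as.integer(n_lgn)

  pj <- cfg$projections
  sub <- function(p) pop[pop$pop == p, ]
  edges <- list()
  th_row <- which(pj$kernel == "gabor")[1]
  edges[["lgn->l4"]] <- data.frame(
    src = th$src, tgt = th$tgt, weight_ns = th$weight_ns,
    delay_ms = th$delay_ms, tau_rec = pj$tau_rec[th_row], lgn_source = TRUE,
    polarity = th$polarity)

  si <- 5L
  for (r in which(pj$kernel != "gabor")) {
    src_pop <- sub(pj$src[r]); tgt_pop <- sub(pj$tgt[r])
    indeg <- if (!is.na(pj$in_degree[r])) pj$in_degree[r] else {
      tot <- if (pj$tgt[r] == "l4_exc") cfg$thalamic$l4_exc_total_exc
             else cfg$thalamic$l4_inh_total_exc
      pmax(0L, tot - lgn_per_tgt[tgt_pop$id])
    }
    e <- sample_projection(src_pop, tgt_pop, pj$kernel[r], indeg, cfg,
                           corr = corr, corr_rows = corr_idx[src_pop$id],
                           corr_cols = corr_idx[tgt_pop$id],
                           seed = seeds[si])
    si <- si + 1L
    e$weight_ns <- pj$weight_ns[r]
    e$tau_rec <- pj$tau_rec[r]
    e$lgn_source <- FALSE
    e$dist_mm <- NULL
    edges[[paste0(pj$src[r], "->", pj$tgt[r])]] <- e
  }
  structure(list(
    populations = pop, lgn = lgn, map = map, edges = edges,
    lgn_afferents_per_target = lgn_per_tgt,
    provenance = list(seed = seed, child_seeds = seeds,
                      config_hash = config_hash(cfg),
                      scale = cfg$provenance$scale,
                      variant = cfg$provenance$variant)),
    class = "connectome")
}

#' Re-wire only the long-range E-to-E projection for a variant
#'
#' The connectivity variants modify only the layer 2/3
#' excitatory-to-excitatory long-range parameters, so the rest of the
#' connectome (map, populations, all other projections) can be reused
#' unchanged; this resamples the `l23_exc->l23_exc` edges under the variant
#' configuration with the same projection seed lineage.
#'
#' @param con a [build_connectome()] result.
#' @param variant_cfg the [make_variant_config()] configuration.
#' @return the connectome with replaced `l23_exc->l23_exc` edges.
#' @export
apply_variant <- function(con, variant_cfg) {
  pj <- variant_cfg$projections
  r <- which(pj$src == "l23_exc" & pj$tgt == "l23_exc")
  pop <- con$populations
  src_pop <- pop[pop$pop == "l23_exc", ]
  rows <- which(pj$kernel != "gabor")
  seed <- con$provenance$child_seeds[5L + match(r, rows) - 1L]
  e <- sample_projection(src_pop, src_pop, pj$kernel[r], pj$in_degree[r],
                         variant_cfg, seed = seed)
  e$weight_ns <- pj$weight_ns[r]
  e$tau_rec <- pj$tau_rec[r]
  e$lgn_source <- FALSE
  e$dist_mm <- NULL
  con$edges[["l23_exc->l23_exc"]] <- e
  con$provenance$variant <- variant_cfg$provenance$variant
  con
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d cortical cells, %d LGN cells, %d projections, %s edges (variant %s)\n",
              nrow(x$populations), nrow(x$lgn), length(x$edges),
              format(sum(vapply(x$edges, nrow, 1L)), big.mark = ","),
              x$provenance$variant))
  invisible(x)
}
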