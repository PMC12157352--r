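#' Size-tuning curve for one cell and one response measure
#'
#' Bundles the responses of a single cell to drifting-grating disks of
#' increasing diameter and to the complementary rings (annuli) whose inner
#' diameters equal the disk diameters and whose outer diameter equals the
#' largest disk.  By construction each matched disk/ring pair tiles the
#' largest disk, so the algebraic sum of the pair responses is the linear
#' prediction for the largest-disk response.
#'
#' Index 1 of `diameters` must be 0: for disks this is the blank (uniform
#' grey) condition, for rings the zero-inner-diameter ring, i.e. the largest
#' solid disk.  Responses are stored raw; metrics subtract `baseline` (the
#' blank-condition value of the measure) unless told otherwise.
#'
#' @param diameters numeric vector of disk diameters / ring inner diameters
#'   (visual degrees), increasing, starting at 0.
#' @param disk raw responses to the disks, same length as `diameters`.
#' @param ring raw responses to the rings, same length, or `NULL` if only
#'   disk-based metrics are needed.  `ring[1]` is the full-disk response.
#' @param baseline raw blank-condition value of the measure (e.g. resting Vm
#'   in mV, spontaneous rate in Hz).  Defaults to `disk[1]`.
#' @param baseline_sem standard error of the baseline estimate, used for the
#'   undefined-metric guard (metrics are `NA` when the peak response does not
#'   exceed `3 * baseline_sem`).
#' @param measure label of the response measure ("VmDC", "VmF1", "VmSD",
#'   "MFR", "spikesF1").
#' @return an object of class `"size_tuning"`.
#' @export
size_tuning_curve <- function(diameters, disk, ring = NULL,
                              baseline = disk[1], baseline_sem = 0,
                              measure = "VmDC") {
  stopifnot(is.numeric(diameters), length(diameters) >= 2,
            !is.unsorted(diameters), length(disk) == length(diameters))
  if (abs(diameters[1]) > .Machine$double.eps^0.5)
    stop("first diameter must be 0 (blank disk / zero-inner-diameter ring)")
  if (!is.null(ring) && length(ring) != length(diameters))
    stop("ring responses must match the disk diameters index-for-index")
  structure(
    list(diameters = as.numeric(diameters), disk = as.numeric(disk),
         ring = if (is.null(ring)) NULL else as.numeric(ring),
         baseline = baseline, baseline_sem = baseline_sem, measure = measure),
    class = "size_tuning")
}

#' @export
print.size_tuning <- function(x, ...) {
  cat(sprintf("<size_tuning> %s over %d diameters (%.2g-%.2g deg), baseline %.3g\n",
              x$measure, length(x$diameters), min(x$diameters),
              max(x$diameters), x$baseline))
  invisible(x)
}

# baseline-subtracted disk/ring responses, with the near-zero-peak guard
.st_responses <- function(curve, subtract_baseline = TRUE) {
  b <- if (subtract_baseline) curve$baseline else 0
  list(D = curve$disk - b,
       R = if (is.null(curve$ring)) NULL else curve$ring - b)
}

.st_defined <- function(peak, curve) {
  is.finite(peak) && abs(peak) > 3 * curve$baseline_sem && peak != 0
}

#' Suppression index
#'
#' Percent reduction of the response from the best disk to the largest disk:
#' `SI = 100 * (Dpeak - Dlargest) / Dpeak`, on baseline-subtracted responses
#' by default.  An SI of 0 means no surround suppression; 100 means the
#' largest disk evokes no response above baseline.
#'
#' @param curve a [size_tuning_curve()].
#' @param subtract_baseline subtract the blank-condition baseline before
#'   forming the ratio (the standard convention).  Set `FALSE` to operate on
#'   raw amplitudes, e.g. for modulation amplitudes quoted without a resting
#'   reference.
#' @return SI in percent, or `NA` (with attribute `reason`) when the peak
#'   response is indistinguishable from baseline.
#' @export
suppression_index <- function(curve, subtract_baseline = TRUE) {
  r <- .st_responses(curve, subtract_baseline)
  peak <- max(r$D)
  if (!.st_defined(peak, curve))
    return(structure(NA_real_, reason = "peak response at noise floor"))
  100 * (peak - r$D[length(r$D)]) / peak
}

#' Residual ring response
#'
#' Baseline-subtracted response to the ring whose inner diameter equals the
#' best disk diameter, divided by the best disk response.  0 means the
#' suppressive-surround region drives no input on its own; 1 means it drives
#' as much as the best disk; negative values indicate hyperpolarisation
#' below rest.
#'
#' @inheritParams suppression_index
#' @return unitless ratio, or `NA` when undefined.
#' @export
residual_index <- function(curve) {
  if (is.null(curve$ring)) stop("residual requires ring responses")
  r <- .st_responses(curve, TRUE)
  ipk <- which.max(r$D)
  peak <- r$D[ipk]
  if (!.st_defined(peak, curve))
    return(structure(NA_real_, reason = "peak response at noise floor"))
  r$R[ipk] / peak
}

#' Non-linearity index
#'
#' `NLI = (max_i(D_i + R_i) - Dpeak) / Dpeak` on baseline-subtracted
#' responses.  Each matched disk/ring pair tiles the largest disk, so
#' `D_i + R_i` is the linear prediction of the largest-disk response; the NLI
#' compares the largest such prediction with the best measured disk response.
#' Positive values mean some pair sums to more than the cell ever produced
#' (sublinear integration of the joint stimulus); for a linearly summating
#' cell with surround suppression s the NLI equals `-s/100`.
#'
#' @inheritParams suppression_index
#' @return unitless index, or `NA` when undefined.  The sign convention
#'   (prediction minus response) is recorded in attribute `convention`.
#' @export
nonlinearity_index <- function(curve) {
  if (is.null(curve$ring)) stop("NLI requires ring responses")
  r <- .st_responses(curve, TRUE)
  peak <- max(r$D)
  if (!.st_defined(peak, curve))
    return(structure(NA_real_, reason = "peak response at noise floor"))
  structure((max(r$D + r$R) - peak) / peak,
            convention = "max-pair-sum minus peak, over peak")
}

#' Linearity index profile
#'
#' For every matched disk/ring pair, the percent deviation of the measured
#' largest-disk response from the pair's linear prediction:
#' `LI_i = 100 * (Dlargest - (D_i + R_i)) / Dlargest`.  0 is perfect linear
#' summation, negative values sublinear (prediction exceeds the measured
#' response).  The per-cell summary is the mean of `LI_i` over all pairs,
#' including the degenerate i = 1 pair (blank + full disk), which is 0 by
#' construction.
#'
#' @inheritParams suppression_index
#' @return list with `per_pair` (percent, one per diameter) and `mean`.
#' @export
linearity_index <- function(curve) {
  if (is.null(curve$ring)) stop("LI requires ring responses")
  r <- .st_responses(curve, TRUE)
  dl <- r$D[length(r$D)]
  if (!.st_defined(dl, curve))
    return(list(per_pair = rep(NA_real_, length(r$D)), mean = NA_real_))
  li <- 100 * (dl - (r$D + r$R)) / dl
  list(per_pair = li, mean = mean(li))
}

#' Compare metric distributions between cell groups
#'
#' Per-group location/spread summaries plus the two standard two-sample
#' tests used for laminar comparisons: Mann-Whitney (Wilcoxon rank-sum) and
#' Kolmogorov-Smirnov.
#'
#' @param groups named list of numeric vectors (one per cell group), each of
#'   length >= 2; `NA`s are dropped.
#' @return list with `summary` (data.frame: n, median, iqr, mean, sem per
#'   group) and `tests` (data.frame of pairwise U/KS statistics and p-values).
#' @export
compare_populations <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 finite values")
  summ <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    median = vapply(groups, stats::median, 1),
    iqr = vapply(groups, stats::IQR, 1),
    mean = vapply(groups, mean, 1),
    sem = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), 1),
    row.names = NULL)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- groups[[p[1]]]; b <- groups[[p[2]]]
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    k <- suppressWarnings(stats::ks.test(a, b))
    data.frame(group1 = p[1], group2 = p[2],
               U = unname(w$statistic), p_mw = w$p.value,
               ks_D = unname(k$statistic), p_ks = k$p.value)
  }))
  list(summary = summ, tests = tests)
}
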