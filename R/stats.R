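#' Fugl-Meyer scoring-system maxima
#'
#' The maximum possible scores of the (slightly modified) Fugl-Meyer
#' sensorimotor assessment used throughout the package: five domain
#' maxima summing to the grand total of 226, and the upper-extremity
#' (UE, 130) / lower-extremity (LE, 96) component breakdowns. Lower
#' scores indicate greater impairment.
#'
#' @return nested list with elements `domains`, `ue`, `ue_motor`,
#'   `le`, `le_motor`, and `totals`.
#' @export
fm_maxima <- function() {
  list(
    domains = c(motor = 100, balance = 14, sensation = 24,
                rom = 44, pain = 44),
    ue = c(motor = 66, parachute = 4, light_touch = 4,
           proprioception = 8, rom = 24, pain = 24),
    ue_motor = c(reflexes = 6, synergy = 30, wrist_hand = 24,
                 coordination = 6),
    le = c(motor = 34, standing_balance = 8, sit_without_support = 2,
           light_touch = 4, proprioception = 8, rom = 20, pain = 20),
    le_motor = c(reflexes = 6, synergy = 22, coordination = 6),
    totals = c(grand = 226, ue = 130, le = 96)
  )
}

check_subscores <- function(scores, maxima, what) {
  unknown <- setdiff(names(scores), names(maxima))
  if (length(unknown))
    stop("unknown ", what, " subscore(s): ",
         paste(unknown, collapse = ", "))
  if (any(scores < 0))
    stop(what, " subscores must be non-negative")
  over <- names(scores)[scores > maxima[names(scores)]]
  if (length(over))
    stop(what, " subscore exceeds its maximum: ",
         paste(over, collapse = ", "))
  invisible(TRUE)
}

#' Fugl-Meyer totals
#'
#' Sums validated subscores into totals. Scores may be supplied at the
#' domain level (`motor`, `balance`, `sensation`, `rom`, `pain`, grand
#' maximum 226) and/or at the limb-component level (`ue`, `le`; maxima
#' 130 and 96). Every subscore is checked against its scoring-table
#' maximum, and an out-of-range value raises an error naming the
#' offending domain. When both limbs are given, the grand total equals
#' `ue_total + le_total`.
#'
#' @param domains named numeric of domain subscores.
#' @param ue,le named numerics of limb component subscores.
#' @return An object of class `fm_score`: list with any of `grand`,
#'   `ue_total`, `le_total` and the validated inputs.
#' @export
#' @examples
#' mx <- fm_maxima()
#' fm_totals(domains = mx$domains)$grand            # 226
#' fm_totals(ue = mx$ue, le = mx$le)[c("ue_total", "le_total")]
fm_totals <- function(domains = NULL, ue = NULL, le = NULL) {
  mx <- fm_maxima()
  out <- list()
  if (!is.null(domains)) {
    check_subscores(domains, mx$domains, "domain")
    out$grand <- sum(domains)
    out$domains <- domains
  }
  if (!is.null(ue)) {
    check_subscores(ue, mx$ue, "UE")
    out$ue_total <- sum(ue)
    out$ue <- ue
  }
  if (!is.null(le)) {
    check_subscores(le, mx$le, "LE")
    out$le_total <- sum(le)
    out$le <- le
  }
  if (is.null(out$grand) && !is.null(out$ue_total) &&
      !is.null(out$le_total))
    out$grand <- out$ue_total + out$le_total
  if (!length(out)) stop("no subscores supplied")
  structure(out, class = "fm_score")
}

#' @export
print.fm_score <- function(x, ...) {
  cat("<fm_score>",
      if (!is.null(x$grand)) paste0(" grand ", x$grand, "/226"),
      if (!is.null(x$ue_total)) paste0(" UE ", x$ue_total, "/130"),
      if (!is.null(x$le_total)) paste0(" LE ", x$le_total, "/96"),
      "\n", sep = "")
  invisible(x)
}

#' Bundled example score and correlation tables
#'
#' `load_fm_scores()` returns per-subject Fugl-Meyer scores for a
#' ten-subject chronic stroke cohort (domain subscores plus UE/LE
#' totals); `load_fa_r2()` returns per-subject coefficients of
#' determination between FA and three tractography-derived metrics
#' (fiber count, mean fiber length, VISC at alpha = 1) for a
#' nineteen-subject sample. Both ship as plain TSV under
#' `inst/extdata/` and are used by the worked examples and the
#' acceptance checks.
#'
#' @return a `data.frame`.
#' @export
load_fm_scores <- function() {
  read.table(system.file("extdata", "fugl_meyer_scores.tsv",
                         package = "viscdti"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname load_fm_scores
#' @export
load_fa_r2 <- function() {
  read.table(system.file("extdata", "fa_metric_r2.tsv",
                         package = "viscdti"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Voxel-wise one-tailed t-test of one subject against controls
#'
#' At each voxel the per-control differences `d_c = control_c -
#' subject` are tested against a zero-mean null with a one-sample
#' Student's t-test, `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`,
#' one-tailed in the stated direction. At zero-variance voxels the
#' statistic is `+/-Inf` by the sign of the mean difference (p = 0 or
#' 1); zero mean and zero variance give p = 1. The default tail per
#' metric follows lesion physiology: FA and VISC drop inside and
#' around a lesion (test controls > subject) while diffusivity rises
#' (test subject > controls).
#'
#' @param subject a [scalar_map()] or 3D array.
#' @param controls list (length >= 2) of maps/arrays on the same grid.
#' @param tail `"controls-greater"` or `"subject-greater"`.
#' @param alpha voxel-wise significance level. The study protocol never
#'   fixes this; the default is 0.05 uncorrected — set it explicitly
#'   for anything beyond exploration.
#' @param mask optional logical array restricting the tested voxels.
#' @return An object of class `voxel_test_result`: arrays `t`, `p`,
#'   `sig`, plus `tail`, `df`, `alpha`, `n`.
#' @export
voxelwise_ttest <- function(subject, controls,
                            tail = c("controls-greater",
                                     "subject-greater"),
                            alpha = 0.05, mask = NULL) {
  tail <- match.arg(tail)
  s <- as.numeric(map_values(subject))
  C <- vapply(controls, function(x) as.numeric(map_values(x)),
              numeric(length(s)))
  n <- ncol(C)
  if (n < 2L) stop("need at least 2 control maps")
  d <- C - s
  m <- rowMeans(d)
  sdv <- sqrt(pmax(rowSums((d - m)^2) / (n - 1), 0))
  tstat <- ifelse(sdv > 0, m / (sdv / sqrt(n)),
                  ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)))
  df <- n - 1
  p <- if (tail == "controls-greater")
    pt(tstat, df, lower.tail = FALSE) else pt(tstat, df)
  p[sdv == 0 & m == 0] <- 1
  dm <- dim(map_values(subject))
  sig <- p < alpha
  if (!is.null(mask)) sig <- sig & as.logical(mask)
  structure(list(t = array(tstat, dm), p = array(p, dm),
                 sig = array(sig, dm), tail = tail, df = df,
                 alpha = alpha, n = n),
            class = "voxel_test_result")
}

#' @export
print.voxel_test_result <- function(x, ...) {
  cat("<voxel_test_result> one-tailed (", x$tail, "), df = ", x$df,
      ", alpha = ", x$alpha, "; ", sum(x$sig),
      " significant voxels\n", sep = "")
  invisible(x)
}

#' Difference volume and its logarithm (LDV)
#'
#' `difference_volume` counts significant voxels, optionally restricted
#' to a region; `ldv` is its natural logarithm, the logarithmic
#' difference volume. A zero count propagates as `NA` (not `-Inf`) so
#' that it is excluded from downstream regressions, mirroring how
#' all-zero control-vs-control difference volumes are handled.
#'
#' @param x a `voxel_test_result` or a logical significance array.
#' @param region optional logical array.
#' @param count a voxel count.
#' @return integer count; `ldv` returns a numeric (or `NA`).
#' @export
difference_volume <- function(x, region = NULL) {
  sig <- if (inherits(x, "voxel_test_result")) x$sig else as.logical(x)
  if (!is.null(region)) sig <- sig & as.logical(region)
  sum(sig)
}

#' @rdname difference_volume
#' @export
ldv <- function(count) {
  ifelse(count >= 1, log(count), NA_real_)
}

#' Simple linear regression with slope F-test
#'
#' Ordinary least squares of `y` on a single predictor; the slope is
#' tested with the regression F-test.
#'
#' @param x predictor (must not be constant).
#' @param y response.
#' @param xname,yname labels for reporting.
#' @return An object of class `regression_result`: `coefficients`,
#'   `r_squared`, `f_statistic`, `p_value`, `n`, `predictors`.
#' @export
simple_regression <- function(x, y, xname = deparse(substitute(x)),
                              yname = deparse(substitute(y))) {
  # resolve the default labels before the arguments are reassigned
  xname <- paste(as.character(xname), collapse = "")[1]
  yname <- paste(as.character(yname), collapse = "")[1]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(coefficients = setNames(stats::coef(fit),
                                         c("(Intercept)", xname)),
                 r_squared = sm$r.squared,
                 f_statistic = unname(fs[1]),
                 p_value = unname(pf(fs[1], fs[2], fs[3],
                                     lower.tail = FALSE)),
                 n = length(x), predictors = xname, response = yname),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), ": R^2 = ",
      signif(x$r_squared, 4), ", F = ", signif(x$f_statistic, 4),
      ", p = ", format.pval(x$p_value, digits = 3), ", n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

#' Multiple linear regression with per-metric corrected significance
#'
#' OLS of `y` on several predictors; each coefficient is judged at the
#' Bonferroni-corrected level `alpha / m`, with `m` defaulting to 3
#' (the number of DTI metrics compared: VISC, FA, MD).
#'
#' @param X data.frame or matrix of predictors (no constants).
#' @param y response.
#' @param m_corrections Bonferroni divisor.
#' @param alpha nominal level.
#' @return a `regression_result` with an extra `terms` data.frame
#'   (estimate, p, significant flag at `alpha / m`).
#' @export
multiple_regression <- function(X, y, m_corrections = 3, alpha = 0.05) {
  X <- as.data.frame(X)
  keep <- stats::complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) <= ncol(X) + 1L)
    stop("need more observations than predictors + 1")
  if (any(vapply(X, var, numeric(1)) == 0)) stop("constant predictor")
  fit <- lm(y ~ ., data = X)
  sm <- summary(fit)
  fs <- sm$fstatistic
  ct <- sm$coefficients[-1, , drop = FALSE]
  terms <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      p_value = ct[, 4],
                      significant = ct[, 4] < alpha / m_corrections,
                      row.names = NULL)
  structure(list(coefficients = stats::coef(fit),
                 r_squared = sm$r.squared,
                 f_statistic = unname(fs[1]),
                 p_value = unname(pf(fs[1], fs[2], fs[3],
                                     lower.tail = FALSE)),
                 n = length(y), predictors = colnames(X),
                 response = "y", terms = terms,
                 corrected_alpha = alpha / m_corrections),
            class = "regression_result")
}

#' Voxel-wise correlation of a metric with FA
#'
#' Coefficient of determination (R^2) of an OLS fit between a derived
#' metric and FA, across voxels with FA strictly above a floor (default
#' 0.15, the tractography stopping criterion).
#'
#' @param metric_map,fa_map maps/arrays on a common grid.
#' @param fa_floor FA floor (strict).
#' @return R^2 (scalar). Fewer than 3 qualifying voxels is an error.
#' @export
metric_fa_correlation <- function(metric_map, fa_map, fa_floor = 0.15) {
  mv <- as.numeric(map_values(metric_map))
  fv <- as.numeric(map_values(fa_map))
  sel <- fv > fa_floor
  if (sum(sel) < 3L) stop("fewer than 3 voxels with FA above the floor")
  simple_regression(fv[sel], mv[sel])$r_squared
}

#' Per-subject LDV table against a control group
#'
#' Runs [voxelwise_ttest()] for each subject map against the control
#' maps, counts significant voxels (optionally within a region) and
#' returns the logarithmic difference volume per subject.
#'
#' @param subject_maps list of subject maps/arrays.
#' @param control_maps list of control maps/arrays.
#' @param tail,alpha passed to [voxelwise_ttest()].
#' @param region optional logical array.
#' @return data.frame with `subject`, `count`, `ldv`.
#' @export
ldv_table <- function(subject_maps, control_maps,
                      tail = "controls-greater", alpha = 0.05,
                      region = NULL) {
  rows <- lapply(seq_along(subject_maps), function(i) {
    tt <- voxelwise_ttest(subject_maps[[i]], control_maps, tail = tail,
                          alpha = alpha)
    cnt <- difference_volume(tt, region)
    data.frame(subject = i, count = cnt, ldv = ldv(cnt))
  })
  do.call(rbind, rows)
}

#' Region-of-interest analysis of DTI metrics against clinical scores
#'
#' For every ROI of an integer-coded label image and every metric, the
#' whole-brain analyses are repeated regionally: the per-subject
#' logarithmic difference volume restricted to the ROI is regressed
#' against the clinical score, and so is the per-subject regional mean
#' of the metric (over all ROI voxels and, when a restriction mask such
#' as the nonzero-VISC support is supplied, over restricted voxels as
#' well). Significance is flagged at two Bonferroni-corrected levels
#' mirroring the usual star convention (`p < 0.05/m` and `p < 0.01/m`);
#' because it is ambiguous whether the divisor should also count ROIs,
#' a flag corrected by `m * n_roi` is reported alongside.
#'
#' @param metric_maps named list (one per metric) of per-subject
#'   maps/arrays.
#' @param sig_masks named list (one per metric) of per-subject logical
#'   significance arrays (from [voxelwise_ttest()]).
#' @param label_image integer-coded ROI image (0 = background).
#' @param scores numeric clinical score per subject.
#' @param restrict_masks optional list of per-subject logical arrays
#'   restricting the regional means (e.g. nonzero-VISC voxels).
#' @param alpha nominal level; `m` Bonferroni divisor (metrics).
#' @param m number of metrics corrected for.
#' @return data.frame with one row per ROI x metric x analysis.
#' @export
roi_analysis <- function(metric_maps, sig_masks, label_image, scores,
                         restrict_masks = NULL, alpha = 0.05, m = 3) {
  lab <- as.integer(round(as.numeric(map_values(label_image))))
  rois <- sort(unique(lab[lab > 0]))
  n_roi <- length(rois)
  if (!n_roi) stop("label image contains no ROI")
  metrics <- union(names(metric_maps), names(sig_masks))
  rows <- list()
  reg_row <- function(roi, metric, analysis, x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3L && var(x[ok]) > 0) {
      r <- simple_regression(x[ok], y[ok])
      data.frame(roi = roi, metric = metric, analysis = analysis,
                 n = r$n, r_squared = r$r_squared, p_value = r$p_value,
                 sig_05 = r$p_value < alpha / m,
                 sig_01 = r$p_value < 0.01 / m,
                 sig_05_all = r$p_value < alpha / (m * n_roi))
    } else {
      data.frame(roi = roi, metric = metric, analysis = analysis,
                 n = sum(ok), r_squared = NA_real_, p_value = NA_real_,
                 sig_05 = NA, sig_01 = NA, sig_05_all = NA)
    }
  }
  for (roi in rois) {
    rmask <- lab == roi
    for (metric in metrics) {
      if (!is.null(sig_masks[[metric]])) {
        cnts <- vapply(sig_masks[[metric]], function(s)
          sum(as.logical(map_values(s)) & rmask), numeric(1))
        rows[[length(rows) + 1L]] <-
          reg_row(roi, metric, "ldv", ldv(cnts), scores)
      }
      if (!is.null(metric_maps[[metric]])) {
        mns <- vapply(metric_maps[[metric]], function(mp)
          mean(as.numeric(map_values(mp))[rmask]), numeric(1))
        rows[[length(rows) + 1L]] <-
          reg_row(roi, metric, "mean", mns, scores)
        if (!is.null(restrict_masks)) {
          mnr <- vapply(seq_along(metric_maps[[metric]]), function(i) {
            sel <- rmask & as.logical(map_values(restrict_masks[[i]]))
            if (any(sel))
              mean(as.numeric(map_values(metric_maps[[metric]][[i]]))[sel])
            else NA_real_
          }, numeric(1))
          rows[[length(rows) + 1L]] <-
            reg_row(roi, metric, "mean_restricted", mnr, scores)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' FA-threshold sensitivity sweep
#'
#' Re-runs tractography and the connectivity graph for a series of FA
#' stopping thresholds (default 0.10 to 0.40 in steps of 0.05, 7
#' settings), reporting the mean VISC over an ROI, its natural log, the
#' union penetrated-voxel volume, and the correlation of log mean VISC
#' with threshold (expected negative: raising the stopping threshold
#' shrinks the volume occupied by reconstructed fibers).
#'
#' @param field a `tensor_field`.
#' @param thresholds ascending FA stopping thresholds.
#' @param roi logical array (or voxel index vector) over the grid.
#' @param params base [tracking_params()].
#' @param alpha VISC contrast exponent.
#' @return list with `table` (threshold, mean_visc, log_mean_visc,
#'   n_penetrated) and `correlation` (log mean VISC vs threshold).
#' @export
fa_threshold_sweep <- function(field, thresholds = seq(0.10, 0.40, 0.05),
                               roi, params = tracking_params(),
                               alpha = 1) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  grid <- field$grid
  roi_idx <- if (is.logical(roi) || is.array(roi))
    which(as.logical(roi)) else as.integer(roi)
  if (!length(roi_idx)) stop("empty ROI")
  fa_map <- compute_fa(field)
  seeds <- generate_seeds(fa_map, params)
  rows <- lapply(thresholds, function(thr) {
    p <- params; p$fa_stop <- thr
    fibers <- track_fibers(field, p, seeds = seeds)
    graph <- build_connectivity(fibers, grid)
    v <- compute_visc(graph, alpha = alpha)$values
    pen <- length(unique(unlist(graph$voxel_sets)))
    mv <- mean(v[roi_idx])
    data.frame(threshold = thr, mean_visc = mv,
               log_mean_visc = ifelse(mv > 0, log(mv), NA_real_),
               n_penetrated = pen)
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$log_mean_visc)
  corr <- if (sum(ok) >= 3 && var(tab$log_mean_visc[ok]) > 0)
    stats::cor(tab$threshold[ok], tab$log_mean_visc[ok]) else NA_real_
  list(table = tab, correlation = corr)
}
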