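#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the processing chain on a synthetic cohort: phantom
#' generation, diffusion simulation and tensor fitting, FA/MD maps,
#' tractography, the voxel-wise connectivity graph and VISC map per
#' subject, voxel-based one-tailed t-tests of each lesioned subject
#' against the control group for VISC, FA and MD, difference volumes
#' and their logs, and (when several lesioned subjects with clinical
#' scores are configured) the LDV-versus-score regressions. All
#' randomness derives from `config$phantom$seed`, so a rerun with the
#' same configuration is bit-identical.
#'
#' The configuration is a plain list (serialisable with
#' [write_config()]):
#' \describe{
#'   \item{phantom}{`type` (`"bundles"`, the default, or `"tract"` for
#'     [make_tract_phantom()] geometry), `dim`, `vsize`, `bundles`
#'     (list of lists with `centerline`, `radius`, `lambdas`,
#'     `taper`), `radius` (tract type), `background_adc`,
#'     `noise_sigma`, `seed`.}
#'   \item{cohort}{`n_controls`, `n_directions`, `bval`, `s0`.}
#'   \item{subjects}{list of lesioned subjects, each with `lesion`
#'     (box/sphere spec in voxel indices) and optionally `score` (an
#'     impairment score; lower = more impaired).}
#'   \item{tracking}{any [tracking_params()] fields.}
#'   \item{visc}{`alpha`.}
#'   \item{stats}{`alpha` (voxel-wise level), `tails` (named,
#'     per-metric).}
#' }
#'
#' @param config configuration list.
#' @param out_dir optional directory; when given, maps, t-maps, the
#'   LDV table and the regression report are written there.
#' @return list with `maps` (per subject and metric), `tests`, the
#'   `ldv_table` data.frame and `regressions` (or `NULL`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  ph <- config$phantom
  dirs <- gradient_scheme(config$cohort$n_directions)
  tp <- do.call(tracking_params, config$tracking)
  alpha <- config$visc$alpha
  base_field <- if (identical(ph$type, "tract")) {
    make_tract_phantom(n_x = ph$dim[1], n_yz = ph$dim[2],
                       radius = if (is.null(ph$radius)) 3 else ph$radius,
                       background_adc = ph$background_adc,
                       vsize = ph$vsize)$field
  } else {
    bundles <- lapply(ph$bundles, function(b)
      bundle_spec(if (is.matrix(b$centerline)) b$centerline
                  else do.call(rbind, lapply(b$centerline, unlist)),
                  radius = b$radius,
                  lambdas = if (is.null(b$lambdas)) c(1.7e-3, 3e-4, 3e-4)
                            else unlist(b$lambdas),
                  taper = isTRUE(b$taper)))
    generate_phantom(
      phantom_spec(unlist(ph$dim), vsize = ph$vsize, bundles = bundles,
                   background_adc = ph$background_adc,
                   noise_sigma = ph$noise_sigma, seed = ph$seed))$field
  }
  # one noise seed per acquisition: controls first, then subjects
  set.seed(ph$seed)
  nsub <- length(config$subjects)
  nctl <- config$cohort$n_controls
  acq_seeds <- sample.int(.Machine$integer.max - 1L, nctl + nsub)
  acquire <- function(field, seed) {
    dwi <- synthesize_dwi(field, dirs, config$cohort$bval,
                          config$cohort$s0,
                          noise_sigma = ph$noise_sigma, seed = seed)
    fit_tensor(dwi)
  }
  control_fields <- lapply(seq_len(nctl), function(i)
    acquire(base_field, acq_seeds[i]))
  subject_fields <- lapply(seq_len(nsub), function(i) {
    les <- insert_lesion(base_field, config$subjects[[i]]$lesion,
                         md = 2 * ph$background_adc)
    acquire(les$field, acq_seeds[nctl + i])
  })
  metric_maps <- function(field) {
    fa <- compute_fa(field)
    md <- compute_md(field)
    fibers <- track_fibers(field, tp)
    graph <- build_connectivity(fibers, field$grid)
    list(FA = fa, MD = md, VISC = compute_visc(graph, alpha = alpha))
  }
  ctrl_maps <- lapply(control_fields, metric_maps)
  subj_maps <- lapply(subject_fields, metric_maps)
  tails <- config$stats$tails
  a <- config$stats$alpha
  tests <- lapply(subj_maps, function(sm)
    lapply(setNames(names(sm), names(sm)), function(metric)
      voxelwise_ttest(sm[[metric]],
                      lapply(ctrl_maps, `[[`, metric),
                      tail = tails[[metric]], alpha = a)))
  ldv_tab <- do.call(rbind, lapply(seq_along(tests), function(i)
    do.call(rbind, lapply(names(tests[[i]]), function(metric) {
      cnt <- difference_volume(tests[[i]][[metric]])
      data.frame(subject = i, metric = metric, count = cnt,
                 ldv = ldv(cnt))
    }))))
  scores <- vapply(config$subjects, function(s)
    if (is.null(s$score)) NA_real_ else s$score, numeric(1))
  regressions <- NULL
  if (sum(is.finite(scores)) >= 3L) {
    regressions <- lapply(setNames(unique(ldv_tab$metric),
                                   unique(ldv_tab$metric)),
                          function(metric) {
      sub <- ldv_tab[ldv_tab$metric == metric, ]
      tryCatch(simple_regression(sub$ldv, scores[sub$subject],
                                 xname = paste0("LDV_", metric),
                                 yname = "score"),
               error = function(e) NULL)
    })
  }
  result <- list(control_maps = ctrl_maps, subject_maps = subj_maps,
                 tests = tests, ldv_table = ldv_tab,
                 regressions = regressions, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

validate_config <- function(config) {
  for (field in c("phantom", "cohort", "subjects"))
    if (is.null(config[[field]]))
      stop("config is missing required section '", field, "'")
  ph <- config$phantom
  req <- if (identical(ph$type, "tract")) c("dim", "seed")
         else c("dim", "bundles", "seed")
  for (field in req)
    if (is.null(ph[[field]]))
      stop("config$phantom is missing '", field, "'")
  if (is.null(ph$vsize)) config$phantom$vsize <- 1
  if (is.null(ph$background_adc)) config$phantom$background_adc <- 7e-4
  if (is.null(ph$noise_sigma)) config$phantom$noise_sigma <- 0
  if (is.null(config$cohort$n_controls)) config$cohort$n_controls <- 9L
  if (is.null(config$cohort$n_directions))
    config$cohort$n_directions <- 25L
  if (is.null(config$cohort$bval)) config$cohort$bval <- 1000
  if (is.null(config$cohort$s0)) config$cohort$s0 <- 1000
  if (is.null(config$tracking)) config$tracking <- list()
  if (is.null(config$visc)) config$visc <- list()
  if (is.null(config$visc$alpha)) config$visc$alpha <- 1
  if (is.null(config$stats)) config$stats <- list()
  if (is.null(config$stats$alpha)) config$stats$alpha <- 0.05
  if (is.null(config$stats$tails))
    config$stats$tails <- list(FA = "controls-greater",
                               VISC = "controls-greater",
                               MD = "subject-greater")
  if (!length(config$subjects)) stop("config has no subjects")
  config
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(result$subject_maps))
    for (metric in names(result$subject_maps[[i]])) {
      write_map(result$subject_maps[[i]][[metric]],
                file.path(out_dir, sprintf("sub%02d_%s.nii", i, metric)))
      write_map(scalar_map(result$tests[[i]][[metric]]$t, "t",
                           result$subject_maps[[i]][[metric]]$grid),
                file.path(out_dir, sprintf("sub%02d_%s_t.nii", i, metric)))
    }
  write.table(result$ldv_table, file.path(out_dir, "ldv_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$regressions)) {
    rep_df <- do.call(rbind, lapply(names(result$regressions),
                                    function(metric) {
      r <- result$regressions[[metric]]
      if (is.null(r)) return(NULL)
      data.frame(metric = metric, slope = r$coefficients[2],
                 r_squared = r$r_squared, p_value = r$p_value, n = r$n)
    }))
    if (!is.null(rep_df))
      write.table(rep_df, file.path(out_dir, "regressions.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}
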