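test_that("Fugl-Meyer maxima and totals add up", {
  mx <- fm_maxima()
  expect_identical(sum(mx$domains), 226)
  expect_identical(sum(mx$ue), 130)
  expect_identical(sum(mx$le), 96)
  expect_identical(sum(mx$ue_motor), unname(mx$ue["motor"]))
  expect_identical(sum(mx$le_motor), unname(mx$le["motor"]))
  full <- fm_totals(domains = mx$domains, ue = mx$ue, le = mx$le)
  expect_identical(full$grand, 226)
  expect_identical(full$ue_total, 130)
  expect_identical(full$le_total, 96)
  zero <- fm_totals(domains = mx$domains * 0)
  expect_identical(zero$grand, 0)
  expect_error(fm_totals(domains = c(motor = 101)), "motor")
  expect_error(fm_totals(ue = c(light_touch = 5)), "light_touch")
})

test_that("bundled cohort table is internally consistent", {
  fm <- load_fm_scores()
  expect_identical(nrow(fm), 10L)
  # domain subscores sum to the printed totals for every subject
  expect_identical(fm$motor + fm$balance + fm$sensation + fm$rom +
                     fm$pain, fm$total)
  # UE + LE totals reproduce the grand totals
  expect_identical(fm$ue_total + fm$le_total, fm$total)
  # first subject as a spot check through the validator
  s01 <- fm[1, ]
  tot <- fm_totals(domains = c(motor = s01$motor, balance = s01$balance,
                               sensation = s01$sensation, rom = s01$rom,
                               pain = s01$pain))
  expect_equal(tot$grand, 170)
})

test_that("voxelwise t statistic matches the closed form", {
  g <- c(1, 1, 3)
  controls <- lapply(1:3, function(i) array(i, g))   # {1,2,3} per voxel
  r <- voxelwise_ttest(array(0, g), controls)
  expect_equal(unique(as.numeric(r$t)), 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(r$df, 2)
  expect_equal(unique(as.numeric(r$p)), pt(2 * sqrt(3), 2,
                                           lower.tail = FALSE))
  # zero-variance, positive mean difference: significant by convention
  same <- lapply(1:4, function(i) array(2, g))
  rz <- voxelwise_ttest(array(1, g), same)
  expect_true(all(is.infinite(rz$t) & rz$t > 0))
  expect_true(all(rz$sig))
  # zero mean and zero variance: not significant
  rn <- voxelwise_ttest(array(2, g), same)
  expect_true(all(rn$p == 1))
  # opposite tail flips significance
  rs <- voxelwise_ttest(array(3, g), same, tail = "subject-greater")
  expect_true(all(rs$sig))
  expect_error(voxelwise_ttest(array(1, g), same[1]), "at least 2")
})

test_that("type-I error of the voxelwise test is calibrated", {
  # The paired design conditions on the subject map (the 9 differences
  # all share it), so calibration is assessed with the pseudo-subject
  # at the control population mean; an independently noisy subject
  # inflates the statistic by construction.
  set.seed(2024)
  dm <- c(10, 10, 10)
  controls <- lapply(1:9, function(i) array(rnorm(1000), dm))
  subject <- array(0, dm)               # population mean of the controls
  r <- voxelwise_ttest(subject, controls, alpha = 0.05)
  frac <- mean(r$sig)
  ci <- 2.58 * sqrt(0.05 * 0.95 / 1000)   # binomial 99% interval
  expect_lt(abs(frac - 0.05), ci + 0.01)
})

test_that("difference volume and LDV handle zero counts as missing", {
  expect_identical(ldv(1), 0)
  expect_true(is.na(ldv(0)))
  expect_equal(ldv(c(0, 1, 10)), c(NA, 0, log(10)))
  mask <- array(FALSE, c(3, 3, 1)); mask[1:9] <- rep(c(TRUE, FALSE), length.out = 9)
  region <- array(FALSE, c(3, 3, 1)); region[1:3, 1, 1] <- TRUE
  expect_identical(difference_volume(mask, region),
                   sum(mask & region))
})

test_that("regression engine matches closed-form OLS", {
  r <- simple_regression(c(1, 2, 3), c(1, 2, 2))
  expect_equal(r$r_squared, 0.75, tolerance = 1e-12)
  expect_equal(unname(r$coefficients), c(2 / 3, 0.5), tolerance = 1e-12)
  # exact data: lm warns about the perfect fit, which is the point here
  ex <- suppressWarnings(simple_regression(1:5, 2 * (1:5) + 1))
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)
  expect_lt(ex$p_value, 1e-10)
  expect_error(simple_regression(rep(2, 5), 1:5), "constant")
  # multiple regression flags at the corrected level
  set.seed(1)
  X <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  y <- 3 * X$a + rnorm(20, sd = 0.1)
  mr <- multiple_regression(X, y, m_corrections = 3)
  expect_true(mr$terms$significant[mr$terms$term == "a"])
  expect_equal(mr$corrected_alpha, 0.05 / 3)
})

test_that("slope F-test is calibrated under the null", {
  set.seed(99)
  rej <- mean(replicate(1000, {
    simple_regression(rnorm(10), rnorm(10))$p_value < 0.05
  }))
  ci <- 2.58 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), ci + 0.01)
})

test_that("metric-FA correlation respects the FA floor", {
  set.seed(8)
  dm <- c(12, 12, 8)
  fa <- array(runif(prod(dm)), dm)
  expect_equal(suppressWarnings(metric_fa_correlation(fa, fa)), 1,
               tolerance = 1e-12)
  indep <- array(5 + rnorm(prod(dm)), dm)
  expect_lt(metric_fa_correlation(indep, fa), 0.02)
  low <- array(0.05, dm)
  expect_error(metric_fa_correlation(indep, low), "fewer than 3")
})

test_that("bundled per-subject R^2 column summarises correctly", {
  r2 <- load_fa_r2()
  expect_identical(nrow(r2), 18L)
  expect_equal(round(mean(r2$visc), 3), 0.184)
  expect_equal(round(sd(r2$visc), 3), 0.033)
  expect_equal(round(mean(r2$fiber_count), 3), 0.140)
  expect_equal(round(mean(r2$fiber_length), 4), 0.1984)
})

test_that("ROI analysis is consistent with whole-volume analysis", {
  set.seed(10)
  dm <- c(8, 8, 4)
  n <- 8
  scores <- seq(100, 226, length.out = n)
  # significance masks whose counts shrink with score, plus noise maps
  masks <- lapply(seq_len(n), function(i) {
    m <- array(FALSE, dm)
    m[seq_len(4 * (n - i + 1))] <- TRUE
    m
  })
  maps <- lapply(seq_len(n), function(i)
    array(0.5 - 0.001 * scores[i] + rnorm(prod(dm), sd = 0.001), dm))
  whole <- array(1L, dm)
  tab <- roi_analysis(metric_maps = list(FA = maps),
                      sig_masks = list(FA = masks),
                      label_image = whole, scores = scores)
  ld <- ldv(vapply(masks, sum, numeric(1)))
  ref <- simple_regression(ld, scores)
  row <- tab[tab$analysis == "ldv", ]
  expect_equal(row$r_squared, ref$r_squared, tolerance = 1e-12)
  expect_equal(row$p_value, ref$p_value, tolerance = 1e-12)
  # ROI disjoint from significance: missing LDV row
  lab2 <- array(0L, dm); lab2[dm[1], dm[2], dm[3]] <- 2L
  masks0 <- lapply(masks, function(m) { m[] <- FALSE; m[1] <- TRUE; m })
  tab2 <- roi_analysis(list(FA = maps), list(FA = masks0), lab2, scores)
  expect_true(is.na(tab2$r_squared[tab2$analysis == "ldv"]))
  # a lesion confined to ROI 1 drives its regression, not ROI 2's
  lab3 <- array(2L, dm); lab3[1:4, , ] <- 1L
  masks3 <- lapply(seq_len(n), function(i) {
    m <- array(FALSE, dm)
    m[seq_len(3 * i)] <- TRUE            # grows with i, inside ROI 1
    m
  })
  tab3 <- roi_analysis(list(), list(VISC = masks3), lab3,
                       scores = rev(scores))
  r1 <- tab3[tab3$roi == 1 & tab3$analysis == "ldv", "r_squared"]
  r2b <- tab3[tab3$roi == 2 & tab3$analysis == "ldv", "r_squared"]
  expect_true(is.na(r2b) || r1 > r2b)
})

test_that("constructed lesion-severity cohorts yield the LDV-score link", {
  # end-to-end power check on the statistical chain: maps with a
  # lesion effect scaling inversely with an impairment score
  set.seed(77)
  dm <- c(10, 10, 4)
  nvox <- prod(dm)
  lesion <- array(FALSE, dm); lesion[3:8, 3:8, 2:3] <- TRUE
  n_sub <- 10
  reps <- 100
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    controls <- lapply(1:9, function(i)
      array(0.5 + rnorm(nvox, sd = 0.05), dm))
    severity <- runif(n_sub, 0.5, 3)
    score <- 226 - 60 * severity        # lower score = worse
    ld <- vapply(seq_len(n_sub), function(s) {
      subj <- array(0.5 + rnorm(nvox, sd = 0.05), dm)
      subj[lesion] <- subj[lesion] - 0.05 * severity[s]
      tt <- voxelwise_ttest(subj, controls)
      ldv(difference_volume(tt))
    }, numeric(1))
    fit <- tryCatch(simple_regression(ld, score),
                    error = function(e) NULL)
    hits[r] <- !is.null(fit) && fit$p_value < 0.05 &&
      fit$coefficients[2] < 0
  }
  expect_gte(mean(hits), 0.8)
})

test_that("FA threshold sweep reports 7 rows and a negative trend", {
  tr <- make_tract_phantom(n_x = 30, n_yz = 7, radius = 2.5)
  tp <- tracking_params(min_length = 3, max_length = 10)
  sw <- fa_threshold_sweep(tr$field, roi = tr$tract_mask, params = tp)
  expect_identical(nrow(sw$table), 7L)
  expect_identical(sw$table$threshold, seq(0.10, 0.40, 0.05))
  expect_lt(sw$correlation, 0)
  expect_true(all(diff(sw$table$n_penetrated) <= 0))
  expect_error(fa_threshold_sweep(tr$field, roi = array(FALSE, tr$grid$dim),
                                  params = tp), "empty ROI")
  # threshold above the phantom's peak FA leaves no VISC
  sw2 <- fa_threshold_sweep(tr$field, thresholds = c(0.85, 0.9),
                            roi = tr$tract_mask, params = tp)
  expect_true(all(sw2$table$mean_visc == 0))
})
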