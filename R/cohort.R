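#' Specify a simulated elderly cohort
#'
#' Describes a cohort of elderly subjects with repeated supine BP and pulse
#' measurements, anthropometry, vascular history flags, per-artery stenosis
#' scores, and a binary cognitive-impairment outcome drawn from a logistic
#' model in the subject's *true* features:
#' `logit P(CI) = intercept + b_pp * PP + b_lpca * leftPCA +
#'  b_diabetes * diabetes + b_mi * MI + b_stroke * stroke`.
#' Default effect sizes mirror the directions of the reference association
#' table (PP odds ratio about 1.04 per mmHg, left-PCA score about 1.02 per
#' percent, positive history effects); demographic defaults describe a
#' mostly male cohort in the mid-80s.
#'
#' @param n_subjects number of subjects (> 0).
#' @param seed integer seed.
#' @param age_mean,age_sd,age_min age distribution (years), truncated below.
#' @param male_fraction fraction of male subjects.
#' @param bmi_mean,bmi_sd body-mass index distribution (kg/m^2).
#' @param n_meas_mean,n_meas_size measurement count per subject:
#'   `1 + NegBinom(mu = n_meas_mean - 1, size = n_meas_size)`.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,pulse_mean,pulse_sd between-subject
#'   distribution of the true (long-run mean) SBP/DBP (mmHg) and pulse
#'   (beats/min).
#' @param meas_noise_sbp,meas_noise_dbp,meas_noise_pulse within-subject
#'   measurement noise SDs.
#' @param min_pp floor on SBP - DBP (mmHg), enforced for the true values and
#'   for every measurement.
#' @param sten_ba_shape,sten_ba_scale,sten_pca_shape,sten_pca_scale gamma
#'   parameters of the per-artery stenosis-score distributions (percent,
#'   capped at 95).
#' @param prev_diabetes,prev_hypertension,prev_mi,prev_postural_hypotension,prev_hyperlipidaemia,prev_stroke
#'   history-flag prevalences.
#' @param coef named list of logistic outcome coefficients: `intercept`,
#'   `pp` (per mmHg), `lpca` (per percent), `diabetes`, `mi`, `stroke`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1L,
                        age_mean = 84.5, age_sd = 6.5, age_min = 65,
                        male_fraction = 0.894,
                        bmi_mean = 24.3, bmi_sd = 3.2,
                        n_meas_mean = 12, n_meas_size = 1.2,
                        sbp_mean = 131, sbp_sd = 9,
                        dbp_mean = 70, dbp_sd = 6,
                        pulse_mean = 70, pulse_sd = 5,
                        meas_noise_sbp = 8, meas_noise_dbp = 5,
                        meas_noise_pulse = 4,
                        min_pp = 10,
                        sten_ba_shape = 8, sten_ba_scale = 2.2,
                        sten_pca_shape = 2.2, sten_pca_scale = 14,
                        prev_diabetes = 0.30, prev_hypertension = 0.72,
                        prev_mi = 0.055, prev_postural_hypotension = 0.034,
                        prev_hyperlipidaemia = 0.195, prev_stroke = 0.23,
                        coef = list(intercept = -3.96, pp = log(1.04),
                                    lpca = log(1.021), diabetes = log(1.75),
                                    mi = log(2), stroke = log(2))) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects <= 0)
    stop("`n_subjects` must be a positive count")
  stopifnot(all(c("intercept", "pp", "lpca", "diabetes", "mi", "stroke") %in% names(coef)))
  spec <- as.list(environment())
  spec$n_subjects <- as.integer(n_subjects)
  structure(spec, class = "cohort_spec")
}

#' Generate a simulated cohort
#'
#' Draws subjects and their repeated measurements per the specification.
#' Every measurement satisfies `SBP - DBP >= min_pp`; generation is
#' bit-reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: list with `subjects` (one row per
#'   subject: demographics, history flags, true BP means, stenosis scores,
#'   `ci_label`) and `measurements` (long format: `subject_id`,
#'   `date_index`, `sbp`, `dbp`, `pulse`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  local_seed(spec$seed, {
    age <- round(pmax(spec$age_min, rnorm(n, spec$age_mean, spec$age_sd)))
    sex <- ifelse(runif(n) < spec$male_fraction, "M", "F")
    height <- ifelse(sex == "M", rnorm(n, 1.68, 0.06), rnorm(n, 1.58, 0.055))
    bmi <- rnorm(n, spec$bmi_mean, spec$bmi_sd)
    weight <- round(bmi * height^2, 1)
    height <- round(height, 2)
    bmi <- compute_bmi(height, weight)

    true_sbp <- rnorm(n, spec$sbp_mean, spec$sbp_sd)
    true_dbp <- pmin(rnorm(n, spec$dbp_mean, spec$dbp_sd), true_sbp - spec$min_pp)
    true_pulse <- rnorm(n, spec$pulse_mean, spec$pulse_sd)
    true_pp <- true_sbp - true_dbp

    ba_score <- pmin(rgamma(n, spec$sten_ba_shape, scale = spec$sten_ba_scale), 95)
    rpca_score <- pmin(rgamma(n, spec$sten_pca_shape, scale = spec$sten_pca_scale), 95)
    lpca_score <- pmin(rgamma(n, spec$sten_pca_shape, scale = spec$sten_pca_scale), 95)

    diabetes <- rbinom(n, 1, spec$prev_diabetes)
    hypertension <- rbinom(n, 1, spec$prev_hypertension)
    mi <- rbinom(n, 1, spec$prev_mi)
    postural_hypotension <- rbinom(n, 1, spec$prev_postural_hypotension)
    hyperlipidaemia <- rbinom(n, 1, spec$prev_hyperlipidaemia)
    stroke <- rbinom(n, 1, spec$prev_stroke)

    cf <- spec$coef
    logit <- cf$intercept + cf$pp * true_pp + cf$lpca * lpca_score +
      cf$diabetes * diabetes + cf$mi * mi + cf$stroke * stroke
    ci_label <- rbinom(n, 1, plogis(logit))

    n_meas <- 1L + rnbinom(n, mu = max(spec$n_meas_mean - 1, 0.01),
                           size = spec$n_meas_size)

    subjects <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, height = height, weight = weight, bmi = bmi,
      diabetes = diabetes, hypertension = hypertension, mi = mi,
      postural_hypotension = postural_hypotension,
      hyperlipidaemia = hyperlipidaemia, stroke = stroke,
      ba_score = ba_score, rpca_score = rpca_score, lpca_score = lpca_score,
      true_sbp = true_sbp, true_dbp = true_dbp, true_pp = true_pp,
      true_pulse = true_pulse, n_measurements = n_meas,
      ci_label = ci_label,
      stringsAsFactors = FALSE
    )

    total <- sum(n_meas)
    sid <- rep(subjects$subject_id, n_meas)
    sbp <- rep(true_sbp, n_meas) + rnorm(total, 0, spec$meas_noise_sbp)
    dbp <- rep(true_dbp, n_meas) + rnorm(total, 0, spec$meas_noise_dbp)
    dbp <- pmin(dbp, sbp - spec$min_pp)
    pulse <- rep(true_pulse, n_meas) + rnorm(total, 0, spec$meas_noise_pulse)
    measurements <- data.frame(
      subject_id = sid,
      date_index = unlist(lapply(n_meas, seq_len), use.names = FALSE),
      sbp = round(sbp, 1), dbp = round(dbp, 1), pulse = round(pulse, 1),
      stringsAsFactors = FALSE
    )
    # rounding must not break the pulse-pressure floor
    measurements$dbp <- pmin(measurements$dbp, measurements$sbp - 0.5)

    structure(list(subjects = subjects, measurements = measurements,
                   spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects, ", nrow(x$measurements),
      " BP measurements, CI prevalence ",
      signif(mean(x$subjects$ci_label), 3), "\n", sep = "")
  invisible(x)
}

#' Write / read a cohort as CSV pair
#'
#' Long-format measurements (`measurements.csv`: subject_id, date_index,
#' sbp, dbp, pulse) and one-row-per-subject covariates
#' (`subjects.csv`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$measurements, file.path(dir, "measurements.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  measurements <- read.csv(file.path(dir, "measurements.csv"), stringsAsFactors = FALSE)
  structure(list(subjects = subjects, measurements = measurements, spec = NULL),
            class = "cohort")
}
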