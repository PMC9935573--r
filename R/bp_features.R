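#' Body-mass index
#'
#' `BMI = weight / height^2` in kg/m^2.
#'
#' @param height_m height in meters (> 0).
#' @param weight_kg weight in kilograms (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(height_m, weight_kg) {
  if (any(height_m <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  weight_kg / height_m^2
}

#' Derive per-subject blood-pressure features
#'
#' Measurements are averaged first; the derived pressures are then computed
#' from the means: pulse pressure `PP = SBP - DBP`, mean arterial pressure
#' `MAP = DBP + PP/3`, and pulse pressure index `PPI = PP / SBP`.
#' Measurements with `sbp <= dbp` are physiologically invalid and are
#' rejected with a warning reporting the count.
#'
#' @param measurements data frame with columns `sbp`, `dbp`, `pulse` (one
#'   row per measurement of one subject).
#' @return a list of class `bp_features`: `sbp`, `dbp`, `pulse`, `pp`,
#'   `map`, `ppi`, `n_used`, `n_rejected`.
#' @export
derive_bp_features <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("sbp", "dbp", "pulse") %in% names(measurements)))
  ok <- measurements$sbp > measurements$dbp & measurements$dbp > 0
  n_rej <- sum(!ok)
  if (n_rej > 0)
    warning(n_rej, " measurement(s) with SBP <= DBP (or DBP <= 0) rejected")
  m <- measurements[ok, , drop = FALSE]
  if (nrow(m) == 0L) stop("no valid measurements: cannot derive BP features")
  sbp <- mean(m$sbp); dbp <- mean(m$dbp); pulse <- mean(m$pulse)
  pp <- sbp - dbp
  structure(list(sbp = sbp, dbp = dbp, pulse = pulse,
                 pp = pp, map = dbp + pp / 3, ppi = pp / sbp,
                 n_used = nrow(m), n_rejected = n_rej),
            class = "bp_features")
}

#' @export
print.bp_features <- function(x, ...) {
  cat(sprintf("<bp_features> SBP %.1f / DBP %.1f mmHg, PP %.1f, MAP %.2f, PPI %.3f, pulse %.1f (n = %d)\n",
              x$sbp, x$dbp, x$pp, x$map, x$ppi, x$pulse, x$n_used))
  invisible(x)
}

#' Category boundaries for BP parameters
#'
#' The `"guideline"` preset reproduces the reference staging: SBP < 120 /
#' 120-135 / >= 135 mmHg, DBP < 70 / 70-80 / >= 80 mmHg, and the published
#' cohort tertiles PP 58/66, MAP 88/93, PPI 0.45/0.49, pulse 68/72. All
#' intervals are `[lower, upper)` with the top interval closed above by
#' infinity, and the middle category is the modelling reference.
#'
#' @param preset currently `"guideline"`.
#' @return named list of length-2 increasing boundary vectors.
#' @export
bp_boundaries <- function(preset = "guideline") {
  if (!identical(preset, "guideline")) stop("unknown preset: ", preset)
  list(sbp = c(120, 135), dbp = c(70, 80), pp = c(58, 66),
       map = c(88, 93), ppi = c(0.45, 0.49), pulse = c(68, 72))
}

#' Empirical tertile boundaries
#'
#' @param x numeric vector.
#' @return length-2 vector of the 1/3 and 2/3 quantiles.
#' @export
empirical_tertiles <- function(x) {
  as.numeric(quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, type = 7))
}

#' Categorize a BP parameter into three levels
#'
#' Levels are `first` (`< lower`), `second` (`[lower, upper)`, the reference
#' group) and `third` (`>= upper`); the lower bound of each interval is
#' inclusive.
#'
#' @param x numeric vector of parameter values.
#' @param boundaries increasing length-2 numeric vector of cut points, e.g.
#'   one entry of [bp_boundaries()], or the output of [empirical_tertiles()].
#' @return factor with levels `first`, `second`, `third` and attribute
#'   `reference = "second"`.
#' @export
categorize_bp <- function(x, boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    stop("`boundaries` must be two strictly increasing cut points")
  lv <- c("first", "second", "third")
  f <- factor(lv[findInterval(x, boundaries) + 1L], levels = lv)
  attr(f, "reference") <- "second"
  f
}

#' Assemble the per-subject analysis table
#'
#' Joins averaged BP features (means first, then PP/MAP/PPI from the means)
#' onto the subject covariates, attaches stenosis scores (the cohort's own
#' by default, or externally supplied, e.g. pipeline output) and the
#' `< 50\%` / `>= 50\%` grades, and the three-level categories of each BP
#' parameter.
#'
#' @param cohort a [generate_cohort()] (or [read_cohort()]) result.
#' @param stenosis optional data frame `subject_id`, `ba_score`,
#'   `rpca_score`, `lpca_score` overriding the cohort's scores.
#' @param boundaries `"guideline"` for the shipped preset, `"empirical"` for
#'   sample tertiles of every parameter.
#' @return data frame, one row per subject, with BP features, categories,
#'   covariates, stenosis scores and grades, and `ci_label`.
#' @export
assemble_analysis_table <- function(cohort, stenosis = NULL,
                                    boundaries = c("guideline", "empirical")) {
  stopifnot(inherits(cohort, "cohort"))
  boundaries <- match.arg(boundaries)
  m <- cohort$measurements
  ok <- m$sbp > m$dbp & m$dbp > 0
  if (any(!ok))
    warning(sum(!ok), " measurement(s) with SBP <= DBP (or DBP <= 0) rejected")
  m <- m[ok, , drop = FALSE]
  # means first, then the derived pressures from the means (vectorized
  # equivalent of derive_bp_features() per subject)
  sums <- rowsum(m[c("sbp", "dbp", "pulse")], m$subject_id)
  cnt <- as.vector(table(m$subject_id)[rownames(sums)])
  fdf <- data.frame(subject_id = rownames(sums), sums / cnt,
                    row.names = NULL, stringsAsFactors = FALSE)
  fdf$pp <- fdf$sbp - fdf$dbp
  fdf$map <- fdf$dbp + fdf$pp / 3
  fdf$ppi <- fdf$pp / fdf$sbp
  tab <- merge(cohort$subjects, fdf, by = "subject_id")
  if (!is.null(stenosis)) {
    tab$ba_score <- NULL; tab$rpca_score <- NULL; tab$lpca_score <- NULL
    tab <- merge(tab, stenosis, by = "subject_id")
  }
  tab$ba_ge50 <- as.integer(tab$ba_score >= 50)
  tab$rpca_ge50 <- as.integer(tab$rpca_score >= 50)
  tab$lpca_ge50 <- as.integer(tab$lpca_score >= 50)
  bnd <- if (boundaries == "guideline") bp_boundaries() else
    lapply(tab[c("sbp", "dbp", "pp", "map", "ppi", "pulse")], empirical_tertiles)
  for (p in c("sbp", "dbp", "pp", "map", "ppi", "pulse"))
    tab[[paste0(p, "_cat")]] <- categorize_bp(tab[[p]], bnd[[p]])
  tab[order(tab$subject_id), ]
}

#' 1:1 nested case-control matching
#'
#' Pairs each case with at most one unused control of identical sex and age
#' within `age_caliper` years, by a greedy nearest-age pass over the cases
#' in seeded random order. Ties on age difference break to the
#' lexicographically smallest control id, so the match is deterministic
#' under a fixed seed. Unmatched cases are reported, not an error.
#'
#' @param subjects data frame with the id, age, sex and case columns.
#' @param case_col binary case indicator column (1 = case).
#' @param id_col,age_col,sex_col column names.
#' @param age_caliper maximum |age difference| in years.
#' @param seed shuffle seed for the greedy pass.
#' @return an object of class `matched_set`: `pairs` (case_id, control_id,
#'   ages, sex), `unmatched` case ids, and `data` (the matched subjects,
#'   stacked).
#' @export
match_case_control <- function(subjects, case_col = "ci_label",
                               id_col = "subject_id", age_col = "age",
                               sex_col = "sex", age_caliper = 1, seed = 1L) {
  stopifnot(all(c(case_col, id_col, age_col, sex_col) %in% names(subjects)))
  cases <- subjects[subjects[[case_col]] == 1, , drop = FALSE]
  pool <- subjects[subjects[[case_col]] == 0, , drop = FALSE]
  ord <- local_seed(seed, sample.int(nrow(cases)))
  used <- logical(nrow(pool))
  pairs <- list()
  unmatched <- character(0)
  for (i in ord) {
    ca <- cases[i, ]
    elig <- which(!used &
                    pool[[sex_col]] == ca[[sex_col]] &
                    abs(pool[[age_col]] - ca[[age_col]]) <= age_caliper)
    if (length(elig) == 0L) {
      unmatched <- c(unmatched, ca[[id_col]])
      next
    }
    dd <- abs(pool[[age_col]][elig] - ca[[age_col]])
    elig <- elig[order(dd, pool[[id_col]][elig])]
    j <- elig[1]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      case_id = ca[[id_col]], control_id = pool[[id_col]][j],
      case_age = ca[[age_col]], control_age = pool[[age_col]][j],
      sex = ca[[sex_col]], stringsAsFactors = FALSE)
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               case_age = numeric(0), control_age = numeric(0),
               sex = character(0))
  # post-hoc balance assertion: exact on sex, within caliper on age
  stopifnot(all(abs(pairs_df$case_age - pairs_df$control_age) <= age_caliper))
  matched_ids <- c(pairs_df$case_id, pairs_df$control_id)
  structure(list(pairs = pairs_df, unmatched = unmatched,
                 data = subjects[subjects[[id_col]] %in% matched_ids, ,
                                 drop = FALSE]),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("<matched_set> ", nrow(x$pairs), " pairs, ", length(x$unmatched),
      " unmatched case(s)\n", sep = "")
  invisible(x)
}
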