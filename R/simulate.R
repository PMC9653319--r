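#' Group measurement profiles for the simulated cohort
#'
#' Per-group means and standard deviations of the clinical measurements
#' used throughout the pipeline, for the three diagnostic groups: healthy,
#' glaucoma suspect (GS), and preperimetric glaucoma (PPG). The defaults
#' are the reference cohort summaries the simulator emulates (age in
#' years, ARNFLT in um, Mag/MagD in uV, MD in dB, IOP in mmHg).
#'
#' @return data frame with one row per group (`healthy`, `GS`, `PPG`) and
#'   `<var>_mean` / `<var>_sd` columns for age, arnflt, mag, magd, md, iop,
#'   plus `ergc_csfi_mean` (the group-level CSFI-scale count).
#' @export
group_profiles <- function() {
  data.frame(
    group = c("healthy", "GS", "PPG"),
    age_mean = c(49, 50, 73),           age_sd = c(12, 19, 16),
    arnflt_mean = c(96.80, 85.00, 79.2), arnflt_sd = c(7.95, 5.75, 5.35),
    mag_mean = c(1.95, 1.35, 1.25),     mag_sd = c(0.64, 0.32, 0.28),
    magd_mean = c(1.72, 1.09, 0.79),    magd_sd = c(1.06, 0.34, 0.67),
    md_mean = c(0.10, -0.45, -1.06),    md_sd = c(1.06, 0.94, 1.72),
    iop_mean = c(17.13, 17.70, 16.80),  iop_sd = c(3.85, 4.14, 3.12),
    ergc_csfi_mean = c(1076635, 912667, 702679),
    stringsAsFactors = FALSE
  )
}

#' Reference group means of the model-based RGC estimates
#'
#' Group means of the two affine eRGC estimators over the reference cohort
#' (healthy / GS / PPG), used as the denominators of proportional-loss and
#' per-year loss summaries.
#'
#' @return data frame with columns `group`, `ergc_mag`, `ergc_magd`.
#' @export
ergc_reference_means <- function() {
  data.frame(group = c("healthy", "GS", "PPG"),
             ergc_mag = c(1068581, 924701, 723352),
             ergc_magd = c(1070825, 927134, 718722),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic bilateral cohort
#'
#' @param n_subjects named integer vector: subjects whose primary group is
#'   healthy / GS / PPG. The default (15, 5, 5) gives 50 eyes in a
#'   30/10/10 group split when no subject is discordant; discordant
#'   subjects move one eye to an adjacent group.
#' @param rho target within-subject inter-eye correlation for each
#'   measurement, in [0, 1).
#' @param fraction_discordant proportion of subjects whose two eyes fall in
#'   adjacent diagnostic groups (healthy/GS or GS/PPG).
#' @param outcome_model [rgc_model] generating the latent true RGC count
#'   (default: the built-in Mag estimator).
#' @param sd_subject,sd_eye standard deviations (counts) of the
#'   subject-level and eye-level noise added to the latent count.
#' @param profiles group profiles, see [group_profiles()].
#' @param seed optional integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = c(healthy = 15, GS = 5, PPG = 5),
                          rho = 0.6, fraction_discordant = 0.2,
                          outcome_model = builtin_rgc_models()$mag,
                          sd_subject = 50000, sd_eye = 40000,
                          profiles = group_profiles(), seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (fraction_discordant < 0 || fraction_discordant > 1)
    stop("fraction_discordant must lie in [0, 1]", call. = FALSE)
  if (any(n_subjects < 0) || sum(n_subjects) == 0)
    stop("n_subjects must be non-negative with a positive total", call. = FALSE)
  structure(list(n_subjects = n_subjects, rho = rho,
                 fraction_discordant = fraction_discordant,
                 outcome_model = outcome_model,
                 sd_subject = sd_subject, sd_eye = sd_eye,
                 profiles = profiles, seed = seed),
            class = "cohort_config")
}

# physiologic truncation bounds applied to simulated measurements
.measure_bounds <- list(
  arnflt = c(40, 130), mag = c(0, Inf), magd = c(0, Inf),
  md = c(-35, 3), iop = c(5, Inf)
)

#' Simulate a bilateral clinical cohort
#'
#' Generates two eyes per subject. Each measurement is drawn from its eye's
#' group profile as mean + sd * (sqrt(rho) z_subject + sqrt(1 - rho) z_eye),
#' so the two eyes of a subject share the subject-level deviate and their
#' measurements correlate at rho; values are truncated to physiologic
#' bounds (ARNFLT 40-130 um, Mag/MagD >= 0, MD in [-35, 3] dB). Age is
#' subject-level and identical in both eyes. A configurable fraction of
#' subjects is discordant: one eye is assigned to the adjacent diagnostic
#' group. The latent true RGC count is the outcome model's prediction plus
#' subject- and eye-level Gaussian noise and is exposed both as
#' `latent_true_rgc` and as the working outcome column `ergc_csfi`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed overriding `config$seed`; given a seed the
#'   cohort is fully reproducible.
#' @param ... convenience overrides passed to [cohort_config()] when
#'   `config` is missing.
#' @return data frame with one row per eye: `subject_id`, `eye`, `group`,
#'   `age_years`, `arnflt_um`, `mag_uv`, `magd_uv`, `md_db`, `iop_mmhg`,
#'   `latent_true_rgc`, `ergc_csfi`.
#' @examples
#' co <- simulate_cohort(seed = 1)
#' table(co$group)
#' @export
simulate_cohort <- function(config = cohort_config(...), seed = config$seed, ...) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  prof <- config$profiles
  groups <- prof$group
  n_sub <- config$n_subjects
  primary <- rep(names(n_sub), n_sub)
  n <- length(primary)
  subject_id <- sprintf("S%03d", seq_len(n))

  # discordant subjects: one eye moves to an adjacent group
  disc <- stats::runif(n) < config$fraction_discordant
  adjacent <- function(g) {
    i <- match(g, groups)
    opts <- c(i - 1, i + 1)
    opts <- opts[opts >= 1 & opts <= length(groups)]
    groups[if (length(opts) == 1) opts else sample(opts, 1)]
  }

  rho <- config$rho
  vars <- c("arnflt", "mag", "magd", "md", "iop")
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    g1 <- primary[s]
    g2 <- if (disc[s]) adjacent(g1) else g1
    eye_groups <- c(OD = g1, OS = g2)
    p1 <- prof[match(g1, groups), ]
    age <- min(max(stats::rnorm(1, p1$age_mean, p1$age_sd), 20), 80)

    z_sub <- stats::rnorm(length(vars))
    names(z_sub) <- vars
    u_sub <- stats::rnorm(1, 0, config$sd_subject)

    eye_rows <- lapply(c("OD", "OS"), function(e) {
      pg <- prof[match(eye_groups[[e]], groups), ]
      vals <- vapply(vars, function(v) {
        mu <- pg[[paste0(v, "_mean")]]
        sd <- pg[[paste0(v, "_sd")]]
        x <- mu + sd * (sqrt(rho) * z_sub[[v]] + sqrt(1 - rho) * stats::rnorm(1))
        b <- .measure_bounds[[v]]
        min(max(x, b[1]), b[2])
      }, numeric(1))
      data.frame(subject_id = subject_id[s], eye = e,
                 group = eye_groups[[e]], age_years = age,
                 arnflt_um = vals[["arnflt"]], mag_uv = vals[["mag"]],
                 magd_uv = vals[["magd"]], md_db = vals[["md"]],
                 iop_mmhg = vals[["iop"]], stringsAsFactors = FALSE)
    })
    rows[[s]] <- do.call(rbind, eye_rows)
    rows[[s]]$.u_sub <- u_sub
  }
  co <- do.call(rbind, rows)
  mu <- predict(config$outcome_model, co)
  co$latent_true_rgc <- mu + co$.u_sub + stats::rnorm(nrow(co), 0, config$sd_eye)
  co$.u_sub <- NULL
  co$ergc_csfi <- co$latent_true_rgc
  rownames(co) <- NULL
  co
}

# normative 24-2 sensitivity surface: linear decline with eccentricity,
# 33 dB at the innermost ring (4.24 deg) to 27 dB at the far nasal edge (27 deg)
vf_normative <- function(ecc_deg) {
  33 - (33 - 27) / (27 - sqrt(18)) * (ecc_deg - sqrt(18))
}

#' Mean deviation of a field from the normative surface
#'
#' @param field a [vf24] field.
#' @return mean of (sensitivity - normative sensitivity) over locations, dB.
#' @export
vf_mean_deviation <- function(field) {
  mean(field$sensitivity_db - vf_normative(field$ecc_deg))
}

#' Simulate a 24-2 visual field with a target mean deviation
#'
#' Draws 52 sensitivities from an eccentricity-declining normative surface
#' plus Gaussian noise, then shifts the whole field so its mean deviation
#' from the surface equals `target_md`. Values are clipped to [0, 50] dB;
#' if clipping moves the achieved MD more than 0.05 dB from the target the
#' target is unreachable and an error is raised.
#'
#' @param target_md desired mean deviation, in [-35, 3] dB.
#' @param eye laterality.
#' @param noise_sd per-location noise SD (dB), default 1.5.
#' @param seed optional integer seed.
#' @return a [vf24] field whose [vf_mean_deviation()] is within 0.05 dB of
#'   `target_md`.
#' @examples
#' f <- simulate_visual_field(-3, seed = 2)
#' vf_mean_deviation(f)
#' @export
simulate_visual_field <- function(target_md, eye = c("OD", "OS"),
                                  noise_sd = 1.5, seed = NULL) {
  eye <- match.arg(eye)
  if (target_md < -35 || target_md > 3)
    stop("target_md must lie in [-35, 3] dB", call. = FALSE)
  g <- vf24_grid(eye)
  norm <- vf_normative(g$ecc_deg)
  s <- with_seed(seed, norm + stats::rnorm(nrow(g), 0, noise_sd))
  s <- s + (target_md - mean(s - norm))   # exact MD before clipping
  s <- pmin(pmax(s, 0), 50)
  achieved <- mean(s - norm)
  if (abs(achieved - target_md) > 0.05)
    stop(sprintf("target MD %.2f dB unreachable within the [0, 50] dB range (achieved %.2f)",
                 target_md, achieved), call. = FALSE)
  vf24(g$x_deg, g$y_deg, s, eye = eye)
}
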