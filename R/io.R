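cohort_required_cols <- c("subject_id", "eye", "group", "age_years",
                          "arnflt_um", "mag_uv", "magd_uv", "md_db")

validate_cohort <- function(co, source = "cohort") {
  miss <- setdiff(cohort_required_cols, names(co))
  if (length(miss))
    stop(source, " lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(co$subject_id, co$eye, sep = ":")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate (subject, eye) record: %s (rows %s)", d,
                 paste(which(key == d), collapse = ", ")), call. = FALSE)
  }
  checks <- list(
    list("eye", !co$eye %in% c("OD", "OS"), "eye must be OD or OS"),
    list("group", !co$group %in% c("healthy", "GS", "PPG"),
         "group must be healthy, GS or PPG"),
    list("age_years", !is.finite(co$age_years) | co$age_years <= 0,
         "age must be positive"),
    list("arnflt_um", !is.finite(co$arnflt_um) | co$arnflt_um < 40 | co$arnflt_um > 130,
         "ARNFLT must lie in [40, 130] um"),
    list("mag_uv", !is.finite(co$mag_uv) | co$mag_uv < 0, "Mag must be >= 0"),
    list("magd_uv", !is.finite(co$magd_uv) | co$magd_uv < 0, "MagD must be >= 0"),
    list("md_db", !is.finite(co$md_db) | co$md_db < -35 | co$md_db > 3,
         "MD must lie in [-35, 3] dB")
  )
  for (ck in checks) {
    if (any(ck[[2]]))
      stop(sprintf("invalid %s at row(s) %s: %s", ck[[1]],
                   paste(utils::head(which(ck[[2]]), 5), collapse = ", "),
                   ck[[3]]), call. = FALSE)
  }
  # age shared within subject
  ages <- tapply(co$age_years, co$subject_id, function(a) length(unique(a)))
  if (any(ages > 1))
    stop("both eyes of a subject must share one age: subject(s) ",
         paste(names(ages)[ages > 1], collapse = ", "), call. = FALSE)
  invisible(co)
}

#' Read and validate a per-eye cohort CSV
#'
#' Expects comma-separated UTF-8 with a header row and one row per eye.
#' Required columns: `subject_id`, `eye` (OD/OS), `group`
#' (healthy/GS/PPG), `age_years`, `arnflt_um`, `mag_uv`, `magd_uv`,
#' `md_db`; optional `iop_mmhg`, `ergc_csfi`. Violations (duplicate
#' subject/eye pairs, out-of-range measurements) are reported with the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @return validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(co, source = path)
  co
}

#' Write a cohort to CSV
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-location visual field records from CSV
#'
#' Columns: `subject_id`, `eye`, `x_deg`, `y_deg`, `sensitivity_db`; one
#' row per test location.
#'
#' @param path CSV file path.
#' @return named list of [vf24] fields, keyed `"subject:eye"`.
#' @export
read_vf_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "x_deg", "y_deg", "sensitivity_db")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(path, " lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  keys <- paste(d$subject_id, d$eye, sep = ":")
  out <- lapply(split(d, keys), function(x)
    vf24(x$x_deg, x$y_deg, x$sensitivity_db, eye = x$eye[1]))
  out
}

group_summary_table <- function(cohort, variables) {
  rows <- lapply(names(variables), function(v) {
    col <- variables[[v]]
    av <- one_way_anova(cohort[[col]], cohort$group)
    means <- tapply(cohort[[col]], factor(cohort$group, c("healthy", "GS", "PPG")), mean)
    sds <- tapply(cohort[[col]], factor(cohort$group, c("healthy", "GS", "PPG")), stats::sd)
    data.frame(variable = v,
               healthy_mean = means[["healthy"]], healthy_sd = sds[["healthy"]],
               gs_mean = means[["GS"]], gs_sd = sds[["GS"]],
               ppg_mean = means[["PPG"]], ppg_sd = sds[["PPG"]],
               f = av$f, p_value = av$p_value, eta_sq = av$eta_sq)
  })
  do.call(rbind, rows)
}

#' Proportional-loss and per-year loss table
#'
#' For each measurement and RGC estimate, the GS and PPG group means are
#' expressed as percent losses relative to the healthy mean
#' ([proportional_loss()]); the two model rows also report the age
#' coefficient as a per-year percent of the healthy model mean
#' ([annual_loss_rate()]).
#'
#' @param cohort cohort data frame carrying `ergc_mag` and `ergc_magd`
#'   prediction columns (added by [run_study()], or supply your own).
#' @param models named list with `mag` and `magd` [rgc_model]s (used for
#'   the per-year rows).
#' @return data frame with one row per quantity: healthy/GS/PPG means,
#'   integer percent losses, and per-year loss percents for the model rows.
#' @export
loss_table <- function(cohort, models = builtin_rgc_models()) {
  vars <- c(ergc_mag = "ergc_mag", ergc_magd = "ergc_magd",
            arnflt_um = "arnflt_um", mag_uv = "mag_uv", magd_uv = "magd_uv")
  g <- factor(cohort$group, c("healthy", "GS", "PPG"))
  rows <- lapply(names(vars), function(v) {
    m <- tapply(cohort[[vars[[v]]]], g, mean)
    data.frame(variable = v, healthy_mean = m[["healthy"]],
               gs_mean = m[["GS"]], ppg_mean = m[["PPG"]],
               gs_loss_pct = as.numeric(proportional_loss(m[["healthy"]], m[["GS"]])),
               ppg_loss_pct = as.numeric(proportional_loss(m[["healthy"]], m[["PPG"]])),
               per_year_count = NA_real_, per_year_pct = NA_real_)
  })
  tab <- do.call(rbind, rows)
  for (p in c("mag", "magd")) {
    i <- match(paste0("ergc_", p), tab$variable)
    tab$per_year_count[i] <- abs(models[[p]]$coef_age)
    tab$per_year_pct[i] <- as.numeric(annual_loss_rate(models[[p]], tab$healthy_mean[i]))
  }
  tab
}

#' Run the full structure-function study pipeline
#'
#' Orchestrates the analysis end-to-end on a per-eye cohort: optional CSFI
#' computation from supplied visual fields (otherwise the `ergc_csfi`
#' column is used as-is); random training/validation split; two
#' mixed-model fits (Mag and MagD) on the training set, or the built-in
#' estimators when `use_builtin = TRUE`; cross-validation R-squared on both
#' sets; group summaries with ANOVA and eta-squared; Welch t comparisons of
#' training vs validation; Games-Howell pairwise comparisons; ROC analysis
#' (healthy vs GS and GS vs PPG); and the proportional-loss table.
#'
#' @param cohort validated cohort data frame (see [read_cohort_csv()]).
#' @param seed integer seed controlling the split.
#' @param variant CSFI formula variant, used only when `fields` is given.
#' @param fields optional named list of [vf24] fields keyed
#'   `"subject:eye"`; when present, `ergc_csfi` is recomputed by [csfi()].
#' @param fraction training fraction for [split_cohort()].
#' @param split_unit `"eye"` or `"subject"`.
#' @param use_builtin if `TRUE`, skip fitting and evaluate the built-in
#'   estimators.
#' @return object of class `rgc_study`: list of tables (`groups`, `split`,
#'   `models`, `pairwise`, `roc`, `losses`), the fitted models, the split,
#'   and a `header` recording seed, variant and split settings.
#' @export
run_study <- function(cohort, seed = 1, variant = c("corrected", "as_printed"),
                      fields = NULL, fraction = 0.6,
                      split_unit = c("eye", "subject"), use_builtin = FALSE) {
  variant <- csfi_variant(variant)
  split_unit <- match.arg(split_unit)
  validate_cohort(cohort)

  if (!is.null(fields)) {
    key <- paste(cohort$subject_id, cohort$eye, sep = ":")
    miss <- setdiff(key, names(fields))
    if (length(miss))
      stop("stage csfi: no visual field for ", paste(miss, collapse = ", "),
           call. = FALSE)
    cohort$ergc_csfi <- vapply(seq_len(nrow(cohort)), function(i)
      csfi(fields[[key[i]]], cohort$age_years[i], cohort$arnflt_um[i],
           cohort$md_db[i], variant)$ergc_csfi, numeric(1))
  } else if (is.null(cohort$ergc_csfi)) {
    stop("stage csfi: cohort has no ergc_csfi column and no fields were supplied",
         call. = FALSE)
  }

  sp <- split_cohort(cohort, fraction = fraction, unit = split_unit, seed = seed)

  if (use_builtin) {
    models <- builtin_rgc_models()
  } else {
    models <- list(mag = fit_rgc_glmm(sp$training, "mag"),
                   magd = fit_rgc_glmm(sp$training, "magd"))
  }
  cohort$ergc_mag <- predict(models$mag, cohort)
  cohort$ergc_magd <- predict(models$magd, cohort)

  r2 <- lapply(models, function(m) list(
    training = cross_validate(m, sp$training),
    validation = if (nrow(sp$validation)) cross_validate(m, sp$validation) else NA_real_))

  model_tab <- do.call(rbind, lapply(names(models), function(p) {
    cf <- coef(models[[p]])
    data.frame(model = p, term = names(cf), coefficient = unname(cf),
               se = if (!is.null(models[[p]]$se)) unname(models[[p]]$se) else NA_real_,
               r2_training = r2[[p]]$training, r2_validation = r2[[p]]$validation)
  }))

  stat_vars <- c(age_years = "age_years", iop_mmhg = "iop_mmhg",
                 md_db = "md_db", arnflt_um = "arnflt_um", mag_uv = "mag_uv",
                 magd_uv = "magd_uv", ergc_csfi = "ergc_csfi",
                 ergc_mag = "ergc_mag", ergc_magd = "ergc_magd")
  stat_vars <- stat_vars[stat_vars %in% names(cohort)]
  groups_tab <- group_summary_table(cohort, as.list(stat_vars))

  in_train <- paste(cohort$subject_id, cohort$eye, sep = ":") %in%
    paste(sp$training$subject_id, sp$training$eye, sep = ":")
  split_tab <- if (any(!in_train)) do.call(rbind, lapply(names(stat_vars), function(v) {
    w <- welch_t(cohort[[stat_vars[[v]]]][in_train], cohort[[stat_vars[[v]]]][!in_train])
    data.frame(variable = v, training_mean = w$mean_a, validation_mean = w$mean_b,
               t = w$t, df = w$df, p_value = w$p_value)
  })) else NULL

  pairwise_tab <- do.call(rbind, lapply(names(stat_vars), function(v) {
    gh <- games_howell(cohort[[stat_vars[[v]]]], cohort$group)
    gh$variable <- v
    gh
  }))

  roc_pairs <- list(healthy_vs_gs = c("healthy", "GS"), gs_vs_ppg = c("GS", "PPG"))
  roc_vars <- stat_vars[!names(stat_vars) %in% c("age_years", "iop_mmhg", "md_db")]
  roc_tab <- do.call(rbind, lapply(names(roc_pairs), function(cmp) {
    keep <- cohort$group %in% roc_pairs[[cmp]]
    do.call(rbind, lapply(names(roc_vars), function(v) {
      r <- roc_auc(cohort[[roc_vars[[v]]]][keep], cohort$group[keep],
                   positive = roc_pairs[[cmp]][2])
      data.frame(comparison = cmp, variable = v, auc = r$auc,
                 p_value = r$p_value, direction = r$direction)
    }))
  }))

  losses <- loss_table(cohort, models)

  structure(list(
    header = list(seed = seed, variant = variant, fraction = fraction,
                  split_unit = split_unit, use_builtin = use_builtin,
                  n_eyes = nrow(cohort),
                  n_subjects = length(unique(cohort$subject_id))),
    groups = groups_tab, split = split_tab, models = model_tab,
    pairwise = pairwise_tab, roc = roc_tab, losses = losses,
    fitted_models = models, split_spec = sp, cohort = cohort),
    class = "rgc_study")
}

#' @export
print.rgc_study <- function(x, ...) {
  h <- x$header
  cat(sprintf("Structure-function study: %d eyes / %d subjects (seed %s, variant %s, split by %s)\n\n",
              h$n_eyes, h$n_subjects, h$seed, h$variant, h$split_unit))
  cat("Group summaries (ANOVA):\n")
  print(format(x$groups, digits = 4), row.names = FALSE)
  cat("\nModels:\n")
  print(format(x$models, digits = 6), row.names = FALSE)
  cat("\nProportional losses vs healthy:\n")
  print(format(x$losses, digits = 4), row.names = FALSE)
  cat("\nPairwise (Games-Howell) and ROC tables available in $pairwise, $roc\n")
  invisible(x)
}

#' Write the study report tables to CSV files
#'
#' @param study an `rgc_study` from [run_study()].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_study_report <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("groups", "split", "models", "pairwise", "roc", "losses")
  paths <- character()
  for (t in tabs) {
    if (is.null(study[[t]])) next
    p <- file.path(dir, paste0(t, ".csv"))
    utils::write.csv(study[[t]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
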