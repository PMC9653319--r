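#' Construct an affine RGC estimator
#'
#' An eRGC model is affine in age, average RNFL thickness, and one ssPERG
#' amplitude parameter (Mag or MagD):
#' \deqn{eRGC = \beta_0 + \beta_{age}\,age + \beta_{ARNFLT}\,ARNFLT +
#'       \beta_{PERG}\,PERG}
#'
#' @param intercept,coef_age,coef_arnflt,coef_perg model coefficients
#'   (counts; counts/year; counts/um; counts/uV).
#' @param perg which ssPERG parameter the model uses: `"mag"` or `"magd"`.
#' @param se optional named numeric of standard errors
#'   (`intercept`, `age`, `arnflt`, `perg`).
#' @param var_subject,var_resid optional variance components (subject-level
#'   random intercept; eye-level residual).
#' @return object of class `rgc_model`.
#' @seealso [builtin_rgc_models()], [fit_rgc_glmm()]
#' @export
rgc_model <- function(intercept, coef_age, coef_arnflt, coef_perg,
                      perg = c("mag", "magd"), se = NULL,
                      var_subject = NA_real_, var_resid = NA_real_) {
  perg <- match.arg(perg)
  stopifnot(is.finite(intercept), is.finite(coef_age),
            is.finite(coef_arnflt), is.finite(coef_perg))
  structure(list(intercept = intercept, coef_age = coef_age,
                 coef_arnflt = coef_arnflt, coef_perg = coef_perg,
                 perg = perg, se = se,
                 var_subject = var_subject, var_resid = var_resid),
            class = "rgc_model")
}

#' Built-in eRGC estimators
#'
#' The two published estimators of CSFI-scale RGC count from age, ARNFLT
#' and one ssPERG amplitude, stored at full reported precision (rounded
#' display forms are derived, not stored):
#' \deqn{eRGC_{Mag} = 401{,}341.71 - 6268.04\,age + 8899.32\,ARNFLT +
#'       58{,}610.30\,Mag}
#' \deqn{eRGC_{MagD} = 405{,}528.50 - 6091.65\,age + 9018.93\,ARNFLT +
#'       53{,}492.96\,MagD}
#'
#' @return named list with elements `mag` and `magd`, each an [rgc_model].
#' @examples
#' m <- builtin_rgc_models()$mag
#' predict(m, data.frame(age_years = 49, arnflt_um = 96.8, mag_uv = 1.95))
#' @export
builtin_rgc_models <- function() {
  list(
    mag = rgc_model(401341.71, -6268.04, 8899.32, 58610.30, perg = "mag",
                    se = c(intercept = 155818.98, age = 991.91,
                           arnflt = 1615.10, perg = 24744.92)),
    magd = rgc_model(405528.50, -6091.65, 9018.93, 53492.96, perg = "magd",
                     se = c(intercept = 157900.55, age = 998.26,
                            arnflt = 1631.04, perg = 24090.70))
  )
}

perg_column <- function(perg) c(mag = "mag_uv", magd = "magd_uv")[[perg]]

#' @export
coef.rgc_model <- function(object, ...) {
  c(intercept = object$intercept, age = object$coef_age,
    arnflt = object$coef_arnflt, perg = object$coef_perg)
}

#' Predict RGC counts from an affine estimator
#'
#' @param object an [rgc_model].
#' @param newdata data frame with columns `age_years`, `arnflt_um` and the
#'   ssPERG column the model uses (`mag_uv` or `magd_uv`).
#' @param ... unused.
#' @return numeric vector of predicted counts.
#' @export
predict.rgc_model <- function(object, newdata, ...) {
  pc <- perg_column(object$perg)
  need <- c("age_years", "arnflt_um", pc)
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("newdata lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  with(newdata, object$intercept + object$coef_age * age_years +
         object$coef_arnflt * arnflt_um) + object$coef_perg * newdata[[pc]]
}

#' @export
print.rgc_model <- function(x, digits = 2, ...) {
  lab <- c(mag = "Mag", magd = "MagD")[[x$perg]]
  cat(sprintf("eRGC_%s = %s %s %s*Age + %s*ARNFLT + %s*%s\n", lab,
              format(round_half_away(x$intercept), big.mark = ","),
              if (x$coef_age < 0) "-" else "+",
              format(abs(round_half_away(x$coef_age)), big.mark = ","),
              format(round_half_away(x$coef_arnflt), big.mark = ","),
              format(round_half_away(x$coef_perg), big.mark = ","), lab))
  if (!is.na(x$var_subject))
    cat(sprintf("  variance components: subject %.4g, residual %.4g\n",
                x$var_subject, x$var_resid))
  invisible(x)
}

#' Fit an eRGC estimator by linear mixed model
#'
#' Regresses a CSFI-scale RGC count on age, ARNFLT and one ssPERG amplitude
#' with a per-subject random intercept, estimated by REML. Both eyes of a
#' subject enter as repeated measures sharing the intercept, which absorbs
#' within-subject inter-eye correlation.
#'
#' @param data data frame of eye records with columns `subject_id`,
#'   `age_years`, `arnflt_um`, the ssPERG column, and the outcome.
#' @param perg `"mag"` or `"magd"`.
#' @param outcome name of the outcome column (default `"ergc_csfi"`).
#' @return object of class `c("rgc_glmm", "rgc_model")`; the lme4 fit is
#'   kept in `$fit`, convergence/singularity messages in `$messages`.
#' @examples
#' co <- simulate_cohort(seed = 7)
#' fit <- fit_rgc_glmm(co, perg = "mag")
#' coef(fit)
#' @export
fit_rgc_glmm <- function(data, perg = c("mag", "magd"), outcome = "ergc_csfi") {
  perg <- match.arg(perg)
  pc <- perg_column(perg)
  need <- c("subject_id", "age_years", "arnflt_um", pc, outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(data$subject_id)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(data[need]))
    stop("missing values in outcome or covariates", call. = FALSE)

  X <- cbind(1, data$age_years, data$arnflt_um, data[[pc]])
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effects design (collinear covariates)", call. = FALSE)

  fml <- stats::as.formula(sprintf("%s ~ age_years + arnflt_um + %s + (1 | subject_id)",
                                   outcome, pc))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )

  beta <- lme4::fixef(fit)
  ses <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_subj <- vc$vcov[vc$grp == "subject_id"][1]
  v_res <- vc$vcov[vc$grp == "Residual"][1]

  out <- rgc_model(beta[[1]], beta[["age_years"]], beta[["arnflt_um"]], beta[[pc]],
                   perg = perg,
                   se = c(intercept = ses[[1]], age = ses[[2]],
                          arnflt = ses[[3]], perg = ses[[4]]),
                   var_subject = v_subj, var_resid = v_res)
  out$fit <- fit
  out$outcome <- outcome
  out$n_eyes <- nrow(data)
  out$n_subjects <- length(unique(data$subject_id))
  out$messages <- msgs
  class(out) <- c("rgc_glmm", class(out))
  out
}

#' @export
summary.rgc_glmm <- function(object, ...) {
  est <- coef(object)
  se <- object$se
  f <- (est / se)^2          # Wald F on 1 numerator df
  tab <- data.frame(coefficient = est, se = se, F = f,
                    p_value = stats::pchisq(f, df = 1, lower.tail = FALSE),
                    row.names = names(est))
  out <- list(coefficients = tab, var_subject = object$var_subject,
              var_resid = object$var_resid, n_eyes = object$n_eyes,
              n_subjects = object$n_subjects, perg = object$perg,
              messages = object$messages)
  class(out) <- "summary.rgc_glmm"
  out
}

#' @export
print.summary.rgc_glmm <- function(x, ...) {
  cat(sprintf("Linear mixed eRGC model (%s), %d eyes / %d subjects\n",
              toupper(x$perg), x$n_eyes, x$n_subjects))
  print(format(x$coefficients, digits = 6))
  cat(sprintf("Random intercept variance %.4g, residual variance %.4g\n",
              x$var_subject, x$var_resid))
  if (length(x$messages)) cat("Fit messages:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' @export
residuals.rgc_glmm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
fitted.rgc_glmm <- function(object, ...) stats::fitted(object$fit, ...)

#' Simulate outcomes from a fitted or specified eRGC model
#'
#' Draws new outcome values at the covariates in `newdata`: fixed-effect
#' prediction plus a shared normal deviate per subject (variance
#' `var_subject`) plus an independent eye-level deviate (variance
#' `var_resid`).
#'
#' @param object an [rgc_model] with variance components.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param newdata data frame with covariates and `subject_id`.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated outcomes.
#' @export
simulate.rgc_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (is.na(object$var_subject) || is.na(object$var_resid))
    stop("model has no variance components to simulate from", call. = FALSE)
  mu <- predict(object, newdata)
  ids <- as.character(newdata$subject_id)
  uid <- unique(ids)
  sim1 <- function() {
    b <- stats::rnorm(length(uid), 0, sqrt(object$var_subject))
    names(b) <- uid
    mu + b[ids] + stats::rnorm(length(mu), 0, sqrt(object$var_resid))
  }
  out <- with_seed(seed, as.data.frame(replicate(nsim, sim1())))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.rgc_glmm <- function(x, ...) {
  obs <- stats::model.frame(x$fit)[[1]]
  fit <- stats::fitted(x$fit)
  plot(fit, obs, xlab = "Fitted eRGC", ylab = "Observed outcome",
       main = sprintf("eRGC_%s mixed model", toupper(x$perg)), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Random training/validation split of a cohort
#'
#' Randomly partitions eyes (or whole subjects) into training and
#' validation sets. The default unit is the eye, which reproduces the
#' 30/20 split of a 50-eye cohort at fraction 0.6; splitting by subject
#' avoids placing the two eyes of one subject on opposite sides.
#'
#' @param data cohort data frame with `subject_id` and `eye` columns.
#' @param fraction proportion assigned to training, in (0, 1]; 1 gives a
#'   degenerate all-training split.
#' @param unit `"eye"` or `"subject"`.
#' @param seed optional integer; the split is deterministic given a seed.
#' @return object of class `cohort_split`: list with `training` and
#'   `validation` data frames, `training_ids`, `validation_ids`, and the
#'   split parameters.
#' @export
split_cohort <- function(data, fraction = 0.6, unit = c("eye", "subject"),
                         seed = NULL) {
  unit <- match.arg(unit)
  if (nrow(data) == 0) stop("empty cohort", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  keys <- if (unit == "eye") paste(data$subject_id, data$eye, sep = ":")
          else as.character(data$subject_id)
  units <- unique(keys)
  n_train <- round(fraction * length(units))
  train_units <- with_seed(seed, sample(units, n_train))
  in_train <- keys %in% train_units
  structure(list(training = data[in_train, , drop = FALSE],
                 validation = data[!in_train, , drop = FALSE],
                 training_ids = sort(unique(keys[in_train])),
                 validation_ids = sort(unique(keys[!in_train])),
                 unit = unit, fraction = fraction, seed = seed),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("Cohort split by %s (fraction %.2f%s): %d training / %d validation rows\n",
              x$unit, x$fraction,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed),
              nrow(x$training), nrow(x$validation)))
  invisible(x)
}

#' Cross-validate an eRGC model
#'
#' Squared Pearson correlation between model predictions and the observed
#' outcome on a held-out record set.
#'
#' @param model an [rgc_model].
#' @param data validation records (non-empty).
#' @param outcome outcome column name.
#' @return R-squared (scalar).
#' @export
cross_validate <- function(model, data, outcome = "ergc_csfi") {
  if (nrow(data) == 0) stop("validation set is empty", call. = FALSE)
  pred <- predict(model, data)
  obs <- data[[outcome]]
  if (stats::var(pred) == 0 || stats::var(obs) == 0)
    stop("undefined correlation: zero variance in predictions or outcomes",
         call. = FALSE)
  stats::cor(pred, obs)^2
}

# half-away-from-zero rounding (the convention of the reported tables;
# base round() is half-to-even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Proportional loss relative to a reference group
#'
#' `100 * (reference - group) / reference`, reported as an integer percent
#' rounded half-away-from-zero; the unrounded value is kept in the
#' `"unrounded"` attribute.
#'
#' @param reference_mean healthy-group mean (> 0).
#' @param group_mean comparison-group mean.
#' @return integer percent with attribute `unrounded`.
#' @examples
#' proportional_loss(1.95, 1.35)  # 31
#' @export
proportional_loss <- function(reference_mean, group_mean) {
  if (any(reference_mean <= 0)) stop("reference mean must be positive", call. = FALSE)
  raw <- 100 * (reference_mean - group_mean) / reference_mean
  structure(round_half_away(raw, 0), unrounded = raw)
}

#' Annual age-related RGC loss rate
#'
#' The model's age coefficient expressed as a percentage of the healthy
#' reference count: `100 * |coef_age| / reference_mean`, reported to two
#' decimals (unrounded value in the `"unrounded"` attribute).
#'
#' @param model an [rgc_model], or a bare numeric age coefficient.
#' @param reference_mean healthy-group model mean (> 0).
#' @return percent per year, rounded to 2 decimals.
#' @examples
#' annual_loss_rate(builtin_rgc_models()$mag, 1068581)  # 0.59
#' @export
annual_loss_rate <- function(model, reference_mean) {
  if (any(reference_mean <= 0)) stop("reference mean must be positive", call. = FALSE)
  coef_age <- if (inherits(model, "rgc_model")) model$coef_age else model
  raw <- 100 * abs(coef_age) / reference_mean
  structure(round_half_away(raw, 2), unrounded = raw)
}

#' Write / read an eRGC model as a flat YAML file
#'
#' @param model an [rgc_model].
#' @param path file path.
#' @return `read_rgc_model` returns an [rgc_model]; `write_rgc_model`
#'   returns `path` invisibly.
#' @export
write_rgc_model <- function(model, path) {
  x <- list(intercept = model$intercept, coef_age = model$coef_age,
            coef_arnflt = model$coef_arnflt, coef_perg = model$coef_perg,
            perg = model$perg,
            var_subject = model$var_subject, var_resid = model$var_resid)
  if (!is.null(model$se)) x$se <- as.list(model$se)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_rgc_model
#' @export
read_rgc_model <- function(path) {
  x <- yaml::read_yaml(path)
  rgc_model(x$intercept, x$coef_age, x$coef_arnflt, x$coef_perg,
            perg = x$perg,
            se = if (!is.null(x$se)) unlist(x$se),
            var_subject = x$var_subject %||% NA_real_,
            var_resid = x$var_resid %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
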