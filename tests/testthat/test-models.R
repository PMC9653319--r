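test_that("built-in estimators carry the full-precision published coefficients", {
  m <- builtin_rgc_models()
  expect_equal(unname(coef(m$mag)), c(401341.71, -6268.04, 8899.32, 58610.30))
  expect_equal(unname(coef(m$magd)), c(405528.50, -6091.65, 9018.93, 53492.96))
  expect_equal(unname(m$mag$se), c(155818.98, 991.91, 1615.10, 24744.92))
  expect_equal(unname(m$magd$se), c(157900.55, 998.26, 1631.04, 24090.70))
  # rounded display constants (half-away-from-zero) derive from the stored
  # full-precision values and match the published display formulas
  expect_equal(rgcest:::round_half_away(coef(m$mag)),
               c(intercept = 401342, age = -6268, arnflt = 8899, perg = 58610))
  expect_equal(rgcest:::round_half_away(coef(m$magd)),
               c(intercept = 405529, age = -6092, arnflt = 9019, perg = 53493))
  expect_output(print(m$magd), "405,529 - 6,092\\*Age \\+ 9,019\\*ARNFLT \\+ 53,493\\*MagD")
  expect_identical(m$mag$perg, "mag")
  expect_identical(m$magd$perg, "magd")
})

test_that("affine prediction reproduces hand arithmetic and linearity", {
  rounded <- rgc_model(401342, -6268, 8899, 58610, perg = "mag")
  nd <- data.frame(age_years = 49, arnflt_um = 96.80, mag_uv = 1.95)
  expect_equal(predict(rounded, nd), 1069922.7, tolerance = 1e-9)
  # full-precision model lands within 0.2% of the healthy-group model mean
  full <- builtin_rgc_models()$mag
  expect_equal(predict(full, nd), 1068581, tolerance = 2e-3)
  # intercept at the origin; unit PERG increment adds exactly coef_perg
  z <- data.frame(age_years = 0, arnflt_um = 0, mag_uv = 0)
  expect_equal(predict(full, z), 401341.71)
  nd2 <- nd; nd2$mag_uv <- nd$mag_uv + 1
  expect_equal(predict(full, nd2) - predict(full, nd), full$coef_perg)
  expect_error(predict(full, data.frame(age_years = 1)), "lacks columns")
})

test_that("mean of affine predictions equals prediction at covariate means", {
  set.seed(31)
  m <- builtin_rgc_models()$magd
  d <- data.frame(age_years = runif(40, 25, 80), arnflt_um = runif(40, 60, 120),
                  magd_uv = runif(40, 0.2, 2.5))
  at_means <- data.frame(age_years = mean(d$age_years),
                         arnflt_um = mean(d$arnflt_um),
                         magd_uv = mean(d$magd_uv))
  expect_equal(mean(predict(m, d)), predict(m, at_means))
})

test_that("mixed-model fit recovers an exact affine outcome to 1e-6", {
  d <- affine_cohort(n_subjects = 20, seed = 42)
  fit <- fit_rgc_glmm(d, perg = "mag")
  gen <- coef(builtin_rgc_models()$mag)
  expect_equal(unname(coef(fit)), unname(gen), tolerance = 1e-6)
})

test_that("mixed-model fit recovers generating coefficients within 2 SE under noise", {
  gen <- builtin_rgc_models()$mag
  cfg <- cohort_config(n_subjects = c(healthy = 70, GS = 65, PPG = 65),
                       outcome_model = gen, sd_subject = 50000, sd_eye = 40000)
  co <- simulate_cohort(cfg, seed = 2024)
  fit <- fit_rgc_glmm(co, perg = "mag")
  expect_true(all(abs(coef(fit) - coef(gen)) <= 2 * fit$se))
  # variance components land on the right scale
  expect_gt(sqrt(fit$var_subject), 25000)
  expect_lt(sqrt(fit$var_subject), 80000)
  expect_gt(sqrt(fit$var_resid), 20000)
  expect_lt(sqrt(fit$var_resid), 65000)
})

test_that("collinear designs are rejected before fitting", {
  d <- affine_cohort(n_subjects = 10)
  d$mag_uv <- d$arnflt_um   # duplicate covariate
  expect_error(fit_rgc_glmm(d, perg = "mag"), "singular")
  expect_error(fit_rgc_glmm(d[0, ], perg = "mag"), "subjects")
})

test_that("training and validation R-squared agree on homogeneous cohorts", {
  cfg <- cohort_config(n_subjects = c(healthy = 70, GS = 65, PPG = 65))
  co <- simulate_cohort(cfg, seed = 88)
  sp <- split_cohort(co, fraction = 0.6, seed = 88)
  fit <- fit_rgc_glmm(sp$training, perg = "mag")
  r2_tr <- cross_validate(fit, sp$training)
  r2_va <- cross_validate(fit, sp$validation)
  expect_lt(abs(r2_tr - r2_va), 0.05)
})

test_that("cohort splits are exhaustive, disjoint, seed-deterministic", {
  co <- simulate_cohort(seed = 5)   # 50 eyes
  sp <- split_cohort(co, fraction = 0.6, unit = "eye", seed = 9)
  expect_equal(nrow(sp$training), 30)
  expect_equal(nrow(sp$validation), 20)
  expect_length(intersect(sp$training_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$training_ids, sp$validation_ids),
                  paste(co$subject_id, co$eye, sep = ":"))
  sp2 <- split_cohort(co, fraction = 0.6, unit = "eye", seed = 9)
  expect_identical(sp$training_ids, sp2$training_ids)
  sp3 <- split_cohort(co, fraction = 0.6, unit = "eye", seed = 10)
  expect_false(identical(sp$training_ids, sp3$training_ids))

  all_tr <- split_cohort(co, fraction = 1, seed = 1)
  expect_equal(nrow(all_tr$training), 50)
  expect_equal(nrow(all_tr$validation), 0)

  by_subj <- split_cohort(co, fraction = 0.6, unit = "subject", seed = 3)
  both_eyes_together <- !any(by_subj$training$subject_id %in%
                               by_subj$validation$subject_id)
  expect_true(both_eyes_together)
  expect_error(split_cohort(co[0, ], 0.6), "empty")
  expect_error(split_cohort(co, 0), "fraction")
})

test_that("cross-validation R-squared is squared Pearson correlation", {
  m <- rgc_model(0, 0, 0, 1, perg = "mag")  # predicts mag_uv itself
  d <- data.frame(age_years = 0, arnflt_um = 0, mag_uv = c(1, 2, 3, 4),
                  ergc_csfi = c(1, 2, 3, 4))
  expect_equal(cross_validate(m, d), 1)
  # 4-point set with hand-computed correlation
  d$ergc_csfi <- c(2, 1, 4, 6)
  r_hand <- sum((d$mag_uv - 2.5) * (d$ergc_csfi - 3.25)) /
    sqrt(sum((d$mag_uv - 2.5)^2) * sum((d$ergc_csfi - 3.25)^2))
  expect_equal(cross_validate(m, d), r_hand^2, tolerance = 1e-9)
  d$mag_uv <- rep(1, 4)
  expect_error(cross_validate(m, d), "undefined correlation")
  expect_error(cross_validate(m, d[0, ]), "empty")
})

test_that("proportional losses round half-away-from-zero to integer percent", {
  expect_equal(as.numeric(proportional_loss(1.95, 1.35)), 31)
  expect_equal(as.numeric(proportional_loss(96.80, 85.00)), 12)
  expect_equal(as.numeric(proportional_loss(7, 7)), 0)
  expect_equal(attr(proportional_loss(1.95, 1.35), "unrounded"),
               100 * 0.6 / 1.95)
  expect_error(proportional_loss(0, 1), "positive")
})

test_that("annual loss rate is the age coefficient as percent of the reference", {
  expect_equal(as.numeric(annual_loss_rate(-6268, 1068581)), 0.59)
  expect_equal(as.numeric(annual_loss_rate(-6092, 1070825)), 0.57)
  expect_equal(as.numeric(annual_loss_rate(builtin_rgc_models()$mag, 1068581)), 0.59)
  expect_equal(as.numeric(annual_loss_rate(0, 1e6)), 0)
})

test_that("model serialization round-trips through YAML", {
  d <- affine_cohort(n_subjects = 15, seed = 7)
  d$ergc_csfi <- d$ergc_csfi + rnorm(nrow(d), 0, 1000)
  fit <- fit_rgc_glmm(d, perg = "mag")
  path <- tempfile(fileext = ".yaml")
  write_rgc_model(fit, path)
  back <- read_rgc_model(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$var_subject, fit$var_subject)
  expect_equal(unname(back$se), unname(fit$se), tolerance = 1e-8)
})

test_that("simulation from a model is seed-deterministic with the right location", {
  m <- builtin_rgc_models()$mag
  m$var_subject <- 50000^2; m$var_resid <- 40000^2
  nd <- data.frame(subject_id = rep(1:100, each = 2),
                   age_years = 50, arnflt_um = 95, mag_uv = 1.8)
  s1 <- simulate(m, nsim = 2, seed = 4, newdata = nd)
  s2 <- simulate(m, nsim = 2, seed = 4, newdata = nd)
  expect_identical(s1, s2)
  mu <- predict(m, nd)[1]
  expect_lt(abs(mean(s1$sim_1) - mu), 4 * sqrt(50000^2 + 40000^2) / sqrt(100))
  # both eyes of a subject share the subject-level deviate
  eye1 <- s1$sim_1[seq(1, 199, 2)] - mu
  eye2 <- s1$sim_1[seq(2, 200, 2)] - mu
  expect_gt(cor(eye1, eye2), 0.3)
})
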