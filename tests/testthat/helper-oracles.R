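# Independent scalar oracles used across the suite. These re-derive the
# quantities under test by a different route (per-location loops, exhaustive
# enumeration, numeric quadrature) and must stay free of package internals.

# per-location loop evaluation of the perimetry count chain
sap_count_loop <- function(field, variant) {
  total <- 0
  for (i in seq_len(nrow(field))) {
    ec <- sqrt(field$x_deg[i]^2 + field$y_deg[i]^2)
    if (variant == "corrected") {
      m <- 0.054 * ec^1.32 + 0.9
      b <- -1.5 * ec^1.32 - 14.8
    } else {
      m <- 0.54 * (ec * 1.32) + 0.9
      b <- -1.5 * (ec + 1.32) - 14.8
    }
    gc <- ((field$sensitivity_db[i] - 1) - b) / m + 4.7
    total <- total + 10^(gc * 0.1)
  }
  total
}

# exhaustive between-class pair counting (concordant + half-weight ties)
auc_pair_oracle <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# upper tail of the studentized range distribution by double quadrature:
# scale mixture of the range of k standard normals over a chi-distributed
# denominator with df degrees of freedom
ptukey_quadrature <- function(q, k, df) {
  range_cdf <- function(w) {
    vapply(w, function(wi) {
      if (wi <= 0) return(0)
      stats::integrate(function(z)
        k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - wi))^(k - 1),
        -Inf, Inf, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  chi_density <- function(u)
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(u) - df * u^2 / 2)
  1 - stats::integrate(function(u) chi_density(u) * range_cdf(q * u),
                       0, Inf, rel.tol = 1e-8)$value
}

# small complete cohort with exact affine outcome (no noise)
affine_cohort <- function(n_subjects = 20, model = builtin_rgc_models()$mag,
                          seed = 42) {
  set.seed(seed)
  n <- 2 * n_subjects
  d <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2),
    eye = rep(c("OD", "OS"), n_subjects),
    group = "healthy",
    age_years = rep(runif(n_subjects, 30, 75), each = 2),
    arnflt_um = runif(n, 75, 110),
    mag_uv = runif(n, 0.8, 2.6),
    magd_uv = runif(n, 0.5, 2.2),
    md_db = runif(n, -2, 1)
  )
  d$ergc_csfi <- predict(model, d)
  d
}
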