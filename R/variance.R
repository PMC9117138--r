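# Decomposition of per-child DNM count variance.
#
# Counts are Poisson-noisy even at a fully known rate, so only the
# super-Poisson part of Var(Y) is explainable. The fraction of explainable
# variance attributed to a model is
#   F = pseudoR2 * Var(Y) / (Var(Y) - mean(Y)) = pseudoR2 / (1 - mean/Var),
# i.e. the McFadden pseudo-R2 rescaled to the non-Poisson variance. An OLS
# variant uses R^2 in place of the pseudo-R2.

#' Poisson-corrected fraction of variance explained
#'
#' @param fit An \code{nb_fit} (or \code{lm} when \code{method = "ols"})
#'   fitted to \code{counts}.
#' @param counts The response counts.
#' @param method \code{"pseudo_r2"} (McFadden, for NB fits) or \code{"ols"}
#'   (uses \code{summary(fit)$r.squared}).
#' @param clip Clip the result to \[0, 1\] (with a warning when outside).
#' @return F, the fraction of super-Poisson variance explained;
#'   \code{NA} (with a warning) when \code{Var(Y) <= mean(Y)} so no
#'   super-Poisson variance exists.
#' @export
fraction_variance_explained <- function(fit, counts,
                                        method = c("pseudo_r2", "ols"),
                                        clip = TRUE) {
  method <- match.arg(method)
  v <- stats::var(counts)
  m <- mean(counts)
  if (v <= m) {
    warning("Var(Y) <= mean(Y): no super-Poisson variance, F undefined")
    return(NA_real_)
  }
  r2 <- if (method == "pseudo_r2") {
    stopifnot(inherits(fit, "nb_fit"))
    fit$pseudo_r2
  } else {
    summary(fit)$r.squared
  }
  f <- r2 * v / (v - m)
  if (clip && (f < 0 || f > 1)) {
    warning("F outside [0,1]; clipped")
    f <- min(max(f, 0), 1)
  }
  f
}

#' Decompose count variance into age, quality and hypermutation components
#'
#' Fits three nested identity-link NB models: (1) parental age only,
#' (2) age plus data-quality covariates, (3) age, quality and the
#' hypermutation-excess covariate (observed count minus cohort median for
#' flagged children, 0 otherwise). Component contributions are the
#' increments of the Poisson-corrected F between successive models, which
#' telescope exactly to the full-model F; the residual fraction is
#' 1 - F_full.
#'
#' The R-squared entering F can be the McFadden pseudo-R2 of the NB fits
#' (\code{method = "pseudo_r2"}) or the ordinary R-squared of OLS fits of
#' the same three mean models (\code{method = "ols"}). The OLS R-squared is
#' a variance ratio, so with it F consistently estimates the share of
#' super-Poisson variance carried by the covariates; the likelihood-based
#' McFadden ratio is systematically smaller on NB data (see the methods
#' vignette).
#'
#' @param counts Per-child DNM counts.
#' @param ages Data frame with \code{father_age}, \code{mother_age}.
#' @param qc Data frame of quality covariates (standardized internally).
#' @param hm_flags Logical vector marking hypermutated children.
#' @param standardize_qc Standardize QC columns.
#' @param method R-squared flavour for F: \code{"ols"} (default; variance
#'   ratio) or \code{"pseudo_r2"} (McFadden on the NB fits).
#' @return Object of class \code{variance_report}: per-model F and
#'   pseudo-R2, \code{increments} (age, quality, hypermutation),
#'   \code{residual_fraction}, cohort \code{mean} and \code{var}, and the
#'   three fits.
#' @export
attribute_variance_components <- function(counts, ages, qc, hm_flags,
                                          standardize_qc = TRUE,
                                          method = c("ols", "pseudo_r2")) {
  method <- match.arg(method)
  qc <- as.data.frame(qc)
  if (standardize_qc) {
    keep <- vapply(qc, function(v) stats::sd(v) > 0, logical(1))
    if (any(!keep)) {
      warning("dropping constant QC columns: ",
              paste(names(qc)[!keep], collapse = ", "))
      qc <- qc[, keep, drop = FALSE]
    }
    qc[] <- lapply(qc, function(v) as.numeric(scale(v)))
    # drop exactly collinear columns
    qr_ <- qr(as.matrix(qc))
    if (qr_$rank < ncol(qc)) {
      drop_i <- qr_$pivot[seq(qr_$rank + 1, ncol(qc))]
      warning("dropping collinear QC columns: ",
              paste(names(qc)[drop_i], collapse = ", "))
      qc <- qc[, -drop_i, drop = FALSE]
    }
  }
  med <- stats::median(counts)
  hm_excess <- ifelse(hm_flags, counts - med, 0)
  cv1 <- data.frame(father_age = ages$father_age,
                    mother_age = ages$mother_age)
  cv2 <- cbind(cv1, qc)
  cv3 <- cbind(cv2, hm_excess = hm_excess)
  f1 <- fit_nb_identity(counts, cv1)
  f2 <- fit_nb_identity(counts, cv2)
  f3 <- fit_nb_identity(counts, cv3)
  if (method == "ols") {
    o1 <- stats::lm(counts ~ ., data = cv1)
    o2 <- stats::lm(counts ~ ., data = cv2)
    o3 <- stats::lm(counts ~ ., data = cv3)
    F1 <- fraction_variance_explained(o1, counts, "ols", clip = FALSE)
    F2 <- fraction_variance_explained(o2, counts, "ols", clip = FALSE)
    F3 <- fraction_variance_explained(o3, counts, "ols", clip = FALSE)
  } else {
    F1 <- fraction_variance_explained(f1, counts, clip = FALSE)
    F2 <- fraction_variance_explained(f2, counts, clip = FALSE)
    F3 <- fraction_variance_explained(f3, counts, clip = FALSE)
  }
  out <- list(
    F = c(age = F1, age_qc = F2, full = F3),
    pseudo_r2 = c(f1$pseudo_r2, f2$pseudo_r2, f3$pseudo_r2),
    increments = c(
      age = F1, quality = F2 - F1, hypermutation = F3 - F2
    ),
    residual_fraction = 1 - F3,
    method = method,
    mean = mean(counts), var = stats::var(counts),
    hm_excess = hm_excess, cohort_median = med,
    fits = list(age = f1, age_qc = f2, full = f3)
  )
  class(out) <- "variance_report"
  out
}

#' @export
print.variance_report <- function(x, ...) {
  cat("Variance decomposition (Poisson-corrected F)\n")
  cat(sprintf("  parental age:   %5.1f%%\n", 100 * x$increments["age"]))
  cat(sprintf("  data quality:   %5.1f%%\n", 100 * x$increments["quality"]))
  cat(sprintf(
    "  hypermutation:  %5.1f%%\n",
    100 * x$increments["hypermutation"]
  ))
  cat(sprintf("  unexplained:    %5.1f%%\n", 100 * x$residual_fraction))
  invisible(x)
}

#' Case-resampling bootstrap percentile interval
#'
#' Resamples trios with replacement, recomputes a statistic, and returns
#' the 2.5th and 97.5th percentiles. Replicates in which the statistic
#' fails are dropped and counted.
#'
#' @param data Data frame of per-trio rows.
#' @param statistic Function of a resampled data frame returning a scalar.
#' @param reps Bootstrap replicates.
#' @param seed Seed.
#' @param probs Interval percentiles.
#' @return List with \code{ci}, \code{replicates}, \code{n_failed}.
#' @export
bootstrap_ci <- function(data, statistic, reps = 1000, seed = 1,
                         probs = c(0.025, 0.975)) {
  stopifnot(reps >= 2)
  set.seed(seed)
  vals <- rep(NA_real_, reps)
  n <- nrow(data)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[r] <- tryCatch(
      statistic(data[idx, , drop = FALSE]),
      error = function(e) NA_real_
    )
  }
  failed <- sum(is.na(vals))
  list(
    ci = stats::quantile(vals, probs, na.rm = TRUE, names = FALSE),
    replicates = vals, n_failed = failed
  )
}

#' Small-cohort resampling of the age-explained variance fraction
#'
#' Repeatedly subsamples \code{n} trios without replacement, fits ordinary
#' least squares of count on paternal age, and computes the
#' Poisson-corrected F from the OLS R-squared — the estimator used by small
#' early trio studies. Summarizes how unstable small-cohort estimates of
#' the age-explained fraction are.
#'
#' @param counts Per-child DNM counts.
#' @param father_age Paternal ages.
#' @param n Subsample size (classically 78 trios).
#' @param reps Number of resamplings.
#' @param seed Seed.
#' @return List with \code{median}, \code{sd}, \code{ci} (2.5/97.5
#'   percentiles), \code{frac_ge} (fraction of estimates at or above
#'   \code{ge_threshold}), \code{estimates}.
#' @param ge_threshold Threshold for \code{frac_ge} (default 0.95).
#' @export
resampling_experiment <- function(counts, father_age, n = 78, reps = 10000,
                                  seed = 1, ge_threshold = 0.95) {
  stopifnot(length(counts) >= n)
  set.seed(seed)
  N <- length(counts)
  est <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(N, n)
    y <- counts[idx]
    x <- father_age[idx]
    v <- stats::var(y)
    m <- mean(y)
    if (v <= m) next
    fit <- stats::lm.fit(cbind(1, x), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - m)^2)
    est[r] <- min(max(r2 * v / (v - m), 0), 1)
  }
  ok <- est[!is.na(est)]
  list(
    median = stats::median(ok),
    sd = stats::sd(ok),
    ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
    frac_ge = mean(ok >= ge_threshold),
    estimates = est
  )
}
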