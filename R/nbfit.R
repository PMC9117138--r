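# Identity-link negative-binomial regression.
#
# The mean model is E(Y_i) = x_i' beta (additive in covariates, no log
# link), with NB variance Var(Y_i) = mu_i + mu_i^2 / theta. Standard GLM
# stacks do not fit this reliably because the linear predictor must be kept
# strictly positive, so the likelihood is maximized directly over
# (beta, log theta) from a feasible least-squares start, with a feasibility
# guard on the line search.

.nb_negll <- function(par, y, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  mu <- drop(X %*% beta)
  if (any(mu <= 0) || !is.finite(theta)) {
    return(1e10 + 1e10 * sum(pmax(-mu, 0)))
  }
  -sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

.nb_negll_grad <- function(par, y, X) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1])
  mu <- drop(X %*% beta)
  if (any(mu <= 0)) {
    # push back toward feasibility
    g <- -drop(crossprod(X, as.numeric(mu <= 0)))
    return(c(1e10 * g, 0))
  }
  dmu <- y / mu - (y + theta) / (mu + theta)
  gbeta <- -drop(crossprod(X, dmu))
  dth <- sum(digamma(y + theta) - digamma(theta) + log(theta) + 1 -
    log(mu + theta) - (y + theta) / (mu + theta))
  c(gbeta, -dth * theta)
}

# a feasible starting beta: least squares, shrunk toward the grand mean
# until every fitted mean is positive
.nb_start <- function(y, X) {
  beta_ls <- tryCatch(
    stats::lm.fit(X, y)$coefficients,
    error = function(e) NULL
  )
  has_int <- all(X[, 1] == 1)
  beta_mean <- c(if (has_int) max(mean(y), 0.5) else 0.5,
                 rep(0, ncol(X) - 1))
  if (is.null(beta_ls) || any(is.na(beta_ls))) {
    return(beta_mean)
  }
  for (t in c(1, 0.8, 0.6, 0.4, 0.2, 0.05, 0)) {
    beta <- t * beta_ls + (1 - t) * beta_mean
    if (all(X %*% beta > 1e-6)) {
      return(beta)
    }
  }
  beta_mean
}

#' Fit an identity-link negative-binomial regression
#'
#' Maximum-likelihood fit of \eqn{E(Y) = X\beta} with NB variance
#' \eqn{\mu + \mu^2/\theta} (so \eqn{\theta \to \infty} is the Poisson
#' limit). \eqn{\beta} and \eqn{\log\theta} are estimated jointly by
#' quasi-Newton optimization with a feasibility guard keeping all fitted
#' means positive; standard errors come from the inverse observed
#' information at the optimum, and two-sided Wald p-values from the
#' asymptotic normal.
#'
#' @param counts Nonnegative integer response vector.
#' @param covariates Data frame or matrix of covariates (no intercept
#'   column; one is added). May have zero columns for an intercept-only fit.
#' @param theta Optional fixed dispersion; if \code{NULL} (default) it is
#'   estimated by ML.
#' @return An object of class \code{nb_fit}: coefficients, standard errors,
#'   Wald \code{p}, dispersion \code{theta}, \code{loglik},
#'   \code{null_loglik} (intercept-only), McFadden \code{pseudo_r2}, fitted
#'   means, Pearson residuals, leverages, \code{n}, \code{p} (number of mean
#'   parameters) and a convergence flag.
#' @export
fit_nb_identity <- function(counts, covariates = NULL, theta = NULL) {
  y <- counts
  stopifnot(all(y >= 0), all(y == round(y)))
  if (is.null(covariates)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.data.frame(covariates)
    stopifnot(nrow(cv) == length(y))
    X <- cbind("(Intercept)" = 1, as.matrix(cv))
    if (any(!is.finite(X))) stop("covariates must be finite")
  }
  p <- ncol(X)
  if (length(y) <= p) stop("need more observations than parameters")
  if (stats::var(y) == 0) {
    warning("constant response: degenerate fit")
  }

  beta0 <- .nb_start(y, X)
  mu0 <- drop(X %*% beta0)
  # moment start for theta
  ex <- mean((y - mu0)^2 - mu0)
  th0 <- if (ex > 0) min(max(mean(mu0)^2 / ex, 0.1), 1e6) else 1e4

  fixed_theta <- !is.null(theta)
  if (fixed_theta) {
    negll <- function(b) .nb_negll(c(b, log(theta)), y, X)
    grad <- function(b) .nb_negll_grad(c(b, log(theta)), y, X)[seq_len(p)]
    opt <- stats::optim(beta0, negll, grad,
      method = "BFGS",
      control = list(maxit = 500, reltol = 1e-12)
    )
    par <- c(opt$par, log(theta))
  } else {
    opt <- stats::optim(c(beta0, log(th0)), .nb_negll, .nb_negll_grad,
      y = y, X = X, method = "BFGS",
      control = list(maxit = 1000, reltol = 1e-12)
    )
    if (opt$convergence != 0) {
      opt2 <- stats::optim(opt$par, .nb_negll,
        y = y, X = X,
        method = "Nelder-Mead", control = list(maxit = 5000)
      )
      if (opt2$value <= opt$value) opt <- opt2
    }
    par <- opt$par
  }
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  theta_hat <- exp(par[p + 1])
  mu <- drop(X %*% beta)
  if (any(mu <= 0)) {
    stop("identity-link NB fit ended with a nonpositive fitted mean")
  }
  boundary <- any(mu < 1e-6 * mean(mu))
  ll <- -.nb_negll(par, y, X)

  # observed information for SEs (beta block; theta profiled out)
  hess <- tryCatch(
    stats::optimHess(par, .nb_negll, .nb_negll_grad, y = y, X = X),
    error = function(e) NULL
  )
  se <- rep(NA_real_, p)
  if (!is.null(hess)) {
    vb <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vb)) {
      d <- diag(vb)[seq_len(p)]
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  # null (intercept-only) loglik, same dispersion handling
  if (p > 1) {
    null_fit <- fit_nb_identity(y, NULL, theta = if (fixed_theta) theta)
    ll0 <- null_fit$loglik
  } else {
    ll0 <- ll
  }
  pseudo_r2 <- if (ll0 != 0) 1 - ll / ll0 else NA_real_

  # leverages from the weighted hat matrix, W = 1/Var(Y_i)
  vfun <- mu + mu^2 / theta_hat
  Xw <- X / sqrt(vfun)
  XtWX <- crossprod(Xw)
  lev <- tryCatch(
    rowSums((Xw %*% solve(XtWX)) * Xw),
    error = function(e) rep(NA_real_, length(y))
  )
  pearson <- (y - mu) / sqrt(vfun)

  out <- list(
    coefficients = beta, se = se, p_values = pval,
    theta = theta_hat, theta_fixed = fixed_theta,
    loglik = ll, null_loglik = ll0, pseudo_r2 = pseudo_r2,
    fitted = mu, pearson_residuals = pearson, leverage = lev,
    n = length(y), p = p,
    converged = opt$convergence == 0, boundary = boundary,
    X = X, y = y
  )
  class(out) <- "nb_fit"
  if (!out$converged) {
    warning("identity-link NB fit did not converge; inspect diagnostics")
  }
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Identity-link negative-binomial fit\n")
  cat("  n =", x$n, " theta =", format(x$theta, digits = 4), "\n")
  tab <- data.frame(
    estimate = x$coefficients, se = x$se,
    p = format.pval(x$p_values)
  )
  print(tab, digits = 4)
  cat(
    "  loglik:", format(x$loglik, digits = 6),
    " McFadden pseudo-R2:", format(x$pseudo_r2, digits = 3), "\n"
  )
  invisible(x)
}

#' Studentized residuals of an identity-link NB fit
#'
#' Leverage-scaled residuals \eqn{r_i / \sqrt{1 - h_i}} used for outlier
#' screening. The default residual is the NB deviance residual — the
#' construction behind \code{rstudent()} for GLMs in R — whose distribution
#' is close to normal even for skewed counts; Pearson residuals are
#' available but are right-skew-inflated on NB data and anti-conservative
#' in tail tests (see the methods vignette).
#'
#' @param fit An \code{nb_fit}.
#' @param type \code{"deviance"} (default) or \code{"pearson"}.
#' @return Numeric vector.
#' @export
studentized_residuals <- function(fit, type = c("deviance", "pearson")) {
  stopifnot(inherits(fit, "nb_fit"))
  type <- match.arg(type)
  r <- if (type == "pearson") {
    fit$pearson_residuals
  } else {
    y <- fit$y
    mu <- fit$fitted
    th <- fit$theta
    d2 <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
      (y + th) * log((y + th) / (mu + th)))
    sign(y - mu) * sqrt(pmax(d2, 0))
  }
  r / sqrt(pmax(1 - fit$leverage, 1e-8))
}

#' Fit the single-parent phased count models
#'
#' Fits \eqn{E(Y_{pat}) = \beta_0 + \beta_1 f} to paternally phased counts
#' against paternal age, and \eqn{E(Y_{mat}) = \beta_0 + \beta_1 m} to
#' maternally phased counts against maternal age, each as an identity-link
#' NB regression.
#'
#' @param paternal_counts,paternal_ages Paternally phased DNM counts and
#'   paternal ages (years).
#' @param maternal_counts,maternal_ages Maternally phased counts and
#'   maternal ages.
#' @return List with elements \code{paternal} and \code{maternal}, each an
#'   \code{nb_fit}.
#' @export
fit_phased_models <- function(paternal_counts, paternal_ages,
                              maternal_counts, maternal_ages) {
  list(
    paternal = fit_nb_identity(
      paternal_counts,
      data.frame(paternal_age = paternal_ages)
    ),
    maternal = fit_nb_identity(
      maternal_counts,
      data.frame(maternal_age = maternal_ages)
    )
  )
}

#' Paternal-to-maternal slope ratio
#'
#' Ratio of the per-year paternal age coefficient to the per-year maternal
#' age coefficient, conventionally reported to one decimal place.
#'
#' @param fit_pat,fit_mat Phased \code{nb_fit}s (or bare slope numbers).
#' @param digits Decimal places for the reported ratio.
#' @return Numeric ratio (rounded).
#' @export
slope_ratio <- function(fit_pat, fit_mat, digits = 1) {
  sl <- function(f) {
    if (inherits(f, "nb_fit")) f$coefficients[2] else f
  }
  b_pat <- sl(fit_pat)
  b_mat <- sl(fit_mat)
  if (!(b_mat > 0)) stop("maternal slope must be positive")
  if (!(b_pat > 0)) stop("paternal slope must be positive")
  round(unname(b_pat / b_mat), digits)
}

#' Identity-link NB fit with parental carrier covariates
#'
#' Extends the parental-age model with per-trio binary indicators for a
#' paternal and a maternal rare-variant carrier (e.g. in DNA-repair genes),
#' plus optional data-quality covariates and the hypermutation-excess
#' covariate. Quality covariates are standardized by default. When several
#' such regressions are run (one per gene set / variant class), a Bonferroni
#' threshold of \code{alpha / n_regressions} applies to the carrier
#' coefficients.
#'
#' @param counts Per-trio DNM counts.
#' @param ages Data frame with \code{father_age} and \code{mother_age}.
#' @param paternal_carrier,maternal_carrier 0/1 vectors.
#' @param qc Optional data frame of quality covariates.
#' @param hm_excess Optional per-trio hypermutation excess covariate.
#' @param standardize_qc Standardize QC columns to mean 0, sd 1.
#' @param n_regressions Number of regressions in the family (for the
#'   Bonferroni threshold recorded in the result).
#' @param alpha Family-wise level.
#' @return An \code{nb_fit} with extra fields \code{carrier_tests} (carrier
#'   coefficients, SEs, p, and whether each passes Bonferroni) and
#'   \code{bonferroni_threshold}.
#' @export
fit_with_carrier_covariates <- function(counts, ages,
                                        paternal_carrier, maternal_carrier,
                                        qc = NULL, hm_excess = NULL,
                                        standardize_qc = TRUE,
                                        n_regressions = 8, alpha = 0.05) {
  cv <- data.frame(
    father_age = ages$father_age,
    mother_age = ages$mother_age
  )
  if (!is.null(qc)) {
    qc <- as.data.frame(qc)
    if (standardize_qc) qc[] <- lapply(qc, function(v) as.numeric(scale(v)))
    cv <- cbind(cv, qc)
  }
  if (!is.null(hm_excess)) cv$hm_excess <- hm_excess
  inestimable <- c(
    paternal_carrier = all(paternal_carrier == 0),
    maternal_carrier = all(maternal_carrier == 0)
  )
  if (!inestimable["paternal_carrier"]) cv$paternal_carrier <- paternal_carrier
  if (!inestimable["maternal_carrier"]) cv$maternal_carrier <- maternal_carrier
  fit <- fit_nb_identity(counts, cv)
  thr <- alpha / n_regressions
  nm <- c("paternal_carrier", "maternal_carrier")
  tests <- data.frame(
    term = nm,
    estimate = NA_real_, se = NA_real_, p = NA_real_,
    significant = NA, estimable = !unname(inestimable)
  )
  for (i in seq_along(nm)) {
    if (nm[i] %in% names(fit$coefficients)) {
      tests$estimate[i] <- fit$coefficients[[nm[i]]]
      tests$se[i] <- fit$se[[which(names(fit$coefficients) == nm[i])]]
      tests$p[i] <- fit$p_values[[which(names(fit$coefficients) == nm[i])]]
      tests$significant[i] <- tests$p[i] < thr
    }
  }
  fit$carrier_tests <- tests
  fit$bonferroni_threshold <- thr
  fit
}

#' Binomial regression of paternal phase fraction on paternal age
#'
#' Identity-link binomial regression of the per-trio paternal count out of
#' phased count against paternal age, mirroring an additive
#' change-per-year statement; a logit-link fit is available as an option.
#'
#' @param paternal Per-trio paternally phased counts.
#' @param phased Per-trio total phased counts (> 0 rows are used).
#' @param father_age Paternal ages.
#' @param link \code{"identity"} (default) or \code{"logit"}.
#' @return List with \code{intercept}, \code{slope}, \code{se} (slope SE),
#'   \code{p} (slope Wald p) and the underlying \code{glm} fit.
#' @export
fit_paternal_fraction <- function(paternal, phased, father_age,
                                  link = c("identity", "logit")) {
  link <- match.arg(link)
  keep <- phased > 0
  if (!any(keep)) stop("no trios with phased DNMs")
  pat <- paternal[keep]
  n <- phased[keep]
  age <- father_age[keep]
  if (all(pat == n) || all(pat == 0)) {
    # boundary: every phased DNM from one parent; proportion is constant
    return(list(
      intercept = if (all(pat == n)) 1 else 0, slope = 0,
      se = NA_real_, p = NA_real_, glm = NULL
    ))
  }
  if (link == "identity") {
    p0 <- sum(pat) / sum(n)
    fit <- tryCatch(
      stats::glm(cbind(pat, n - pat) ~ age,
        family = stats::binomial(link = "identity"),
        start = c(p0, 0)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) {
      # direct ML fallback with a feasibility guard
      nll <- function(b) {
        pr <- b[1] + b[2] * age
        if (any(pr <= 0 | pr >= 1)) {
          return(1e10)
        }
        -sum(stats::dbinom(pat, n, pr, log = TRUE))
      }
      op <- stats::optim(c(p0, 0), nll, control = list(maxit = 2000))
      h <- stats::optimHess(op$par, nll)
      v <- tryCatch(solve(h), error = function(e) matrix(NA, 2, 2))
      se <- sqrt(pmax(diag(v), 0))
      z <- op$par[2] / se[2]
      return(list(
        intercept = op$par[1], slope = op$par[2], se = se[2],
        p = 2 * stats::pnorm(-abs(z)), glm = NULL
      ))
    }
  } else {
    fit <- stats::glm(cbind(pat, n - pat) ~ age, family = stats::binomial())
  }
  cf <- summary(fit)$coefficients
  list(
    intercept = unname(cf[1, 1]), slope = unname(cf[2, 1]),
    se = unname(cf[2, 2]), p = unname(cf[2, 4]), glm = fit
  )
}
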