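# independent oracle: brute-force refinement grid search of the
# identity-link NB likelihood over (beta0, beta1, log theta)
grid_oracle <- function(y, x, passes = 4) {
  ll <- function(b0, b1, th) {
    mu <- b0 + b1 * x
    if (any(mu <= 0)) {
      return(-Inf)
    }
    sum(stats::dnbinom(y, size = th, mu = mu, log = TRUE))
  }
  c0 <- c(mean(y) * 0.2, mean(y) * 2)
  c1 <- c(-2, 5)
  cl <- c(log(0.5), log(5e4))
  best <- NULL
  for (p in seq_len(passes)) {
    g0 <- seq(c0[1], c0[2], length.out = 21)
    g1 <- seq(c1[1], c1[2], length.out = 21)
    gl <- seq(cl[1], cl[2], length.out = 21)
    vals <- expand.grid(b0 = g0, b1 = g1, lt = gl)
    vals$ll <- mapply(function(b0, b1, lt) ll(b0, b1, exp(lt)),
      vals$b0, vals$b1, vals$lt
    )
    best <- vals[which.max(vals$ll), ]
    st0 <- diff(c0) / 20
    st1 <- diff(c1) / 20
    stl <- diff(cl) / 20
    c0 <- c(best$b0 - st0, best$b0 + st0)
    c1 <- c(best$b1 - st1, best$b1 + st1)
    cl <- c(best$lt - stl, best$lt + stl)
  }
  list(beta = c(best$b0, best$b1), theta = exp(best$lt), loglik = best$ll)
}

test_that("constant counts give zero slopes and the mean as intercept", {
  y <- rep(50L, 40)
  ages <- data.frame(
    father_age = seq(20, 50, length.out = 40),
    mother_age = seq(19, 45, length.out = 40)
  )
  fit <- suppressWarnings(fit_nb_identity(y, ages))
  expect_equal(unname(fit$coefficients[1]), 50, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[3]), 0, tolerance = 1e-3)
})

test_that("ML solution matches the grid-search oracle on a tiny dataset", {
  # 6 observations, single covariate
  x <- c(20, 25, 30, 35, 40, 45)
  y <- c(44, 52, 57, 64, 66, 79)
  fit <- fit_nb_identity(y, data.frame(age = x))
  orc <- grid_oracle(y, x)
  # agreement to 3 significant figures on the coefficients
  expect_equal(unname(fit$coefficients[1]), orc$beta[1],
    tolerance = 5e-3
  )
  expect_equal(unname(fit$coefficients[2]), orc$beta[2],
    tolerance = 5e-3
  )
  expect_gte(fit$loglik, orc$loglik - 1e-4)
})

test_that("the reported optimum dominates a surrounding grid", {
  set.seed(4)
  x <- stats::runif(30, 20, 45)
  y <- stats::rnbinom(30, size = 50, mu = 15 + 1.2 * x)
  fit <- fit_nb_identity(y, data.frame(age = x))
  b <- fit$coefficients
  th <- fit$theta
  ll <- function(b0, b1, theta) {
    mu <- b0 + b1 * x
    if (any(mu <= 0)) {
      return(-Inf)
    }
    sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  for (d0 in c(-0.5, 0, 0.5)) {
    for (d1 in c(-0.02, 0, 0.02)) {
      for (f in c(0.8, 1, 1.25)) {
        expect_lte(ll(b[1] + d0, b[2] + d1, th * f), fit$loglik + 1e-6)
      }
    }
  }
})

test_that("parameters are recovered within 3 SE on a simulated cohort", {
  cfg <- sim_config(n_trios = 5000, seed = 31)
  co <- simulate_cohort(cfg, include_dnms = FALSE)
  fit <- fit_nb_identity(
    co$trios$dn_snv_count,
    data.frame(
      father_age = co$trios$father_age,
      mother_age = co$trios$mother_age
    )
  )
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[1] - 20), 3 * fit$se[1])
  expect_lt(abs(fit$coefficients[2] - 1.28), 3 * fit$se[2])
  expect_lt(abs(fit$coefficients[3] - 0.35), 3 * fit$se[3])
  expect_true(all(fit$fitted > 0))
  expect_gte(fit$pseudo_r2, 0)
  expect_lte(fit$pseudo_r2, 1)
})

test_that("large fixed dispersion reproduces the identity-link Poisson fit", {
  set.seed(9)
  x <- stats::runif(200, 20, 45)
  y <- stats::rpois(200, 10 + x)
  nb <- fit_nb_identity(y, data.frame(age = x), theta = 1e8)
  pois <- stats::glm(y ~ x,
    family = stats::poisson(link = "identity"),
    start = c(10, 1)
  )
  expect_equal(unname(nb$coefficients),
    unname(stats::coef(pois)),
    tolerance = 1e-4
  )
})

test_that("adding a covariate never decreases the log-likelihood", {
  co <- simulate_cohort(sim_config(n_trios = 400, seed = 8),
    include_dnms = FALSE
  )
  y <- co$trios$dn_snv_count
  f1 <- fit_nb_identity(y, data.frame(father_age = co$trios$father_age))
  f2 <- fit_nb_identity(y, data.frame(
    father_age = co$trios$father_age,
    mother_age = co$trios$mother_age
  ))
  f3 <- fit_nb_identity(y, data.frame(
    father_age = co$trios$father_age,
    mother_age = co$trios$mother_age,
    noise = stats::rnorm(400)
  ))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_gte(f3$loglik, f2$loglik - 1e-6)
})

test_that("phased single-parent models recover their slopes", {
  # direct generative check: NB counts with known single-covariate means
  set.seed(13)
  n <- 3000
  fa <- stats::runif(n, 22, 48)
  ma <- stats::runif(n, 20, 42)
  pat <- stats::rnbinom(n, size = 150, mu = 10 + 1.23 * fa)
  mat <- stats::rnbinom(n, size = 150, mu = 4 + 0.38 * ma)
  fits <- fit_phased_models(pat, fa, mat, ma)
  expect_lt(abs(fits$paternal$coefficients[2] - 1.23),
            3 * fits$paternal$se[2])
  expect_lt(abs(fits$maternal$coefficients[2] - 0.38),
            3 * fits$maternal$se[2])
  # recovered slope ratio close to the configured ratio
  expect_equal(
    unname(fits$paternal$coefficients[2] / fits$maternal$coefficients[2]),
    1.23 / 0.38,
    tolerance = 0.15
  )
  # degenerate input flagged
  expect_warning(
    fit_phased_models(pat[1:50], fa[1:50], rep(0L, 50), ma[1:50]),
    "constant|degenerate|converge"
  )
})

test_that("slope ratio reporting matches the printed convention", {
  expect_equal(slope_ratio(1.28, 0.35), 3.7)
  expect_equal(slope_ratio(1, 1), 1.0)
  expect_equal(slope_ratio(0.071, 0.019), 3.7)
  expect_error(slope_ratio(1.2, 0), "maternal slope")
})

test_that("carrier covariates are estimated and Bonferroni-thresholded", {
  cfg <- sim_config(n_trios = 2500, seed = 17)
  co <- simulate_cohort(cfg, include_dnms = FALSE)
  set.seed(1)
  carrier <- stats::rbinom(2500, 1, 0.05)
  y <- co$trios$dn_snv_count + stats::rpois(2500, 10) * carrier
  fit <- fit_with_carrier_covariates(
    y, data.frame(
      father_age = co$trios$father_age,
      mother_age = co$trios$mother_age
    ),
    paternal_carrier = carrier,
    maternal_carrier = stats::rbinom(2500, 1, 0.05)
  )
  tst <- fit$carrier_tests
  est <- tst$estimate[tst$term == "paternal_carrier"]
  se <- tst$se[tst$term == "paternal_carrier"]
  expect_lt(abs(est - 10), 3 * se)
  expect_equal(fit$bonferroni_threshold, 0.05 / 8)
  # all-zero carrier column reported inestimable, fit unchanged
  base <- fit_nb_identity(y, data.frame(
    father_age = co$trios$father_age,
    mother_age = co$trios$mother_age,
    paternal_carrier = carrier
  ))
  fit0 <- fit_with_carrier_covariates(
    y, data.frame(
      father_age = co$trios$father_age,
      mother_age = co$trios$mother_age
    ),
    paternal_carrier = carrier,
    maternal_carrier = rep(0, 2500)
  )
  expect_false(
    fit0$carrier_tests$estimable[
      fit0$carrier_tests$term == "maternal_carrier"
    ]
  )
  expect_equal(fit0$loglik, base$loglik, tolerance = 1e-6)
})
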