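test_that("empty and degenerate configs are handled", {
  co <- simulate_cohort(sim_config(n_trios = 0))
  expect_s3_class(co, "trio_cohort")
  expect_equal(nrow(co$trios), 0)
  expect_equal(nrow(co$dnms), 0)
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(beta_pat = -1), "nonnegative")
  expect_error(
    sim_config(paternal_fraction_base = 0.99,
               paternal_fraction_slope = 0.01),
    "paternal fraction"
  )
})

test_that("counts follow the configured additive age model", {
  # fixed ages: compare the empirical mean with the closed-form mean
  cfg <- sim_config(
    n_trios = 5000, beta0 = 20, beta_pat = 1.28, beta_mat = 0.35,
    mother_age_mean = 30, mother_age_sd = 1e-8,
    father_age_offset_mean = 0, father_age_offset_sd = 1e-8,
    dispersion = 200, seed = 11
  )
  co <- simulate_cohort(cfg, include_dnms = FALSE)
  mu_true <- 20 + 1.28 * 30 + 0.35 * 30 # 68.9
  v <- mu_true + mu_true^2 / 200
  mc_se <- sqrt(v / 5000)
  expect_lt(abs(mean(co$trios$dn_snv_count) - mu_true), 3 * mc_se)
})

test_that("large dispersion approaches the Poisson limit", {
  cfg <- sim_config(
    n_trios = 4000, dispersion = 1e9,
    mother_age_sd = 1e-8, father_age_offset_sd = 1e-8, seed = 3
  )
  co <- simulate_cohort(cfg, include_dnms = FALSE)
  ratio <- stats::var(co$trios$dn_snv_count) /
    mean(co$trios$dn_snv_count)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("fixed seed fixes every simulated value", {
  cfg <- sim_config(n_trios = 30, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trios, b$trios)
  expect_identical(a$dnms, b$dnms)
  expect_identical(a$hethom, b$hethom)
})

test_that("per-trio DNM tables are consistent with count-level truth", {
  co <- small_cohort()
  expect_equal(nrow(co$dnms), sum(co$trios$dn_snv_count))
  tab <- table(factor(co$dnms$trio_id, levels = co$trios$trio_id))
  expect_equal(as.integer(tab), co$trios$dn_snv_count)
  expect_equal(
    co$trios$true_paternal + co$trios$true_maternal,
    co$trios$dn_snv_count
  )
  expect_true(all(co$dnms$pos >= 1))
  expect_true(all(co$dnms$pos <= sim_genome()[co$dnms$chrom]))
  expect_true(all(co$dnms$ref != co$dnms$alt))
  # VAF equals alt reads / depth
  expect_equal(co$dnms$vaf_child,
    co$dnms$altreads_child / co$dnms$rd_child,
    tolerance = 1e-12
  )
})

test_that("hypermutator injection scales counts as specified", {
  co <- small_cohort()
  # fold 1 repair_defect leaves everything unchanged
  co1 <- inject_hypermutators(
    co, list(list(trio = 3, etiology = "repair_defect", fold_or_extra = 1))
  )
  expect_equal(co1$trios$dn_snv_count, co$trios$dn_snv_count)
  expect_equal(nrow(co1$dnms), nrow(co$dnms))

  # fold 4 multiplies the paternal count: expected total 4*pat + mat
  i <- 5
  pat <- co$trios$true_paternal[i]
  mat <- co$trios$true_maternal[i]
  co4 <- inject_hypermutators(
    co, list(list(trio = i, etiology = "repair_defect", fold_or_extra = 4))
  )
  expect_equal(co4$trios$dn_snv_count[i], 4 * pat + mat)
  expect_equal(co4$trios$true_paternal[i], 4 * pat)
  expect_equal(co4$trios$etiology[i], "repair_defect")
  # other trios untouched
  expect_equal(
    co4$trios$dn_snv_count[-i], co$trios$dn_snv_count[-i]
  )

  # postzygotic injections have mosaic-like VAF truth
  cop <- inject_hypermutators(
    co, list(list(trio = 2, etiology = "postzygotic", fold_or_extra = 120))
  )
  inj <- cop$dnms[cop$dnms$etiology == "postzygotic", ]
  expect_equal(nrow(inj), 120)
  expect_lt(mean(inj$true_vaf), 0.4)
  expect_gt(mean(inj$true_parent == "father"), 0.25)
  expect_lt(mean(inj$true_parent == "father"), 0.75)

  expect_error(
    inject_hypermutators(co, list(list(
      trio = 1, etiology = "chemo_signature", fold_or_extra = 10,
      signature = "nope"
    ))),
    "unknown signature"
  )
})

test_that("lota artifact injection is confined and depresses parental het", {
  co <- small_cohort()
  region <- list(chrom = "chr5", start = 2e5, end = 3e5)
  before_het <- sum(co$hethom$n_het[
    co$hethom$trio_id == "trio00007" & co$hethom$parent == "father" &
      co$hethom$chrom == "chr5" & co$hethom$start >= 2e5 &
      co$hethom$start < 3e5
  ])
  co0 <- inject_lota_artifact(co, 7, region, 0)
  expect_equal(co0$trios$dn_snv_count, co$trios$dn_snv_count)
  col <- inject_lota_artifact(co, 7, region, 600)
  inj <- col$dnms[col$dnms$etiology == "lota_artifact", ]
  expect_equal(nrow(inj), 600)
  expect_true(all(inj$chrom == "chr5"))
  expect_true(all(inj$pos >= 2e5 & inj$pos <= 3e5))
  expect_equal(col$trios$dn_snv_count[7], co$trios$dn_snv_count[7] + 600)
  after_het <- sum(col$hethom$n_het[
    col$hethom$trio_id == "trio00007" & col$hethom$parent == "father" &
      col$hethom$chrom == "chr5" & col$hethom$start >= 2e5 &
      col$hethom$start < 3e5
  ])
  expect_lt(after_het, 0.3 * before_het)
  expect_error(
    inject_lota_artifact(co, 7, list(chrom = "chr99", start = 1, end = 2), 5),
    "chromosome"
  )
})

test_that("cohorts round-trip losslessly through write/read", {
  co <- simulate_cohort(sim_config(n_trios = 12, seed = 5))
  co <- inject_hypermutators(
    co, list(list(trio = 2, etiology = "chemo_signature", fold_or_extra = 30))
  )
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$trios, co$trios, tolerance = 1e-9)
  expect_equal(
    back$dnms[, names(co$dnms)], co$dnms,
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_equal(back$hethom, co$hethom, tolerance = 1e-9)
  expect_equal(
    back$config[setdiff(names(back$config), "catalogue")],
    co$config[setdiff(names(co$config), "catalogue")],
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_equal(back$config$catalogue, co$config$catalogue, tolerance = 1e-12)
  # truth table row count equals total true count
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(co$dnms))

  # empty cohort: valid headers, zero rows
  dir2 <- tempfile("empty")
  write_cohort(simulate_cohort(sim_config(n_trios = 0)), dir2)
  d <- utils::read.delim(file.path(dir2, "dnms.tsv"))
  expect_equal(nrow(d), 0)
  expect_true(all(c("trio_id", "chrom", "pos", "vaf_child") %in% names(d)))
})

test_that("age model parameters are recoverable from large cohorts", {
  cfg <- sim_config(n_trios = 3000, seed = 21)
  co <- simulate_cohort(cfg, include_dnms = FALSE)
  fit <- fit_nb_identity(
    co$trios$dn_snv_count,
    data.frame(
      father_age = co$trios$father_age,
      mother_age = co$trios$mother_age
    )
  )
  expect_lt(abs(fit$coefficients["father_age"] - 1.28), 3 * fit$se[2])
  expect_lt(abs(fit$coefficients["mother_age"] - 0.35), 3 * fit$se[3])
  # configured paternal fraction recovered within binomial MC error
  pf <- sum(co$trios$true_paternal) / sum(co$trios$dn_snv_count)
  n <- sum(co$trios$dn_snv_count)
  expect_lt(abs(pf - 0.77), 4 * sqrt(0.77 * 0.23 / n) + 0.01)
})
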