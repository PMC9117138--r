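test_that("autosomal rules keep a clean call and reject each violation", {
  ok <- apply_autosomal_filters(valid_call())
  expect_equal(nrow(ok$kept), 1)
  expect_equal(sum(ok$tally), 0)

  cases <- list(
    list(mod = list(altreads_father = 2L), rule = "parental-alt"),
    list(mod = list(rd_child = 20L), rule = "read-depth"), # strict >
    list(mod = list(rd_mother = 20L), rule = "read-depth"),
    list(mod = list(rd_child = 99L), rule = "max-depth"),
    list(mod = list(vaf_child = 0.3), rule = "vaf"), # endpoints excluded
    list(mod = list(vaf_child = 0.7), rule = "vaf"),
    list(mod = list(gt_child = "1/1"), rule = "genotype"),
    list(mod = list(gt_father = "0/1"), rule = "genotype")
  )
  for (cs in cases) {
    call <- do.call(valid_call, cs$mod)
    res <- apply_autosomal_filters(call)
    expect_equal(nrow(res$kept), 0)
    expect_gte(res$tally[[cs$rule]], 1)
  }
  # boundary passes: RD 21, VAF just inside
  res <- apply_autosomal_filters(valid_call(
    rd_child = 21L, rd_father = 21L,
    rd_mother = 21L, vaf_child = 0.31
  ))
  expect_equal(nrow(res$kept), 1)
  # RD 98 is kept ("removed if > 98")
  expect_equal(nrow(apply_autosomal_filters(valid_call(rd_child = 98L))$kept), 1)
})

test_that("missing required fields are rejected, never silently passed", {
  call <- valid_call()
  call$rd_mother <- NA_integer_
  res <- apply_autosomal_filters(call)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$tally[["incomplete-record"]], 1)
  call2 <- valid_call()
  call2$vaf_child <- NULL
  res2 <- apply_autosomal_filters(call2)
  expect_equal(nrow(res2$kept), 0)
  expect_equal(res2$tally[["incomplete-record"]], 1)
})

test_that("mask overlap uses BED half-open convention", {
  bed <- write_bed(data.frame(chrom = "chr1", start = 999L, end = 1100L))
  mask <- read_mask_bed(bed, "segdup")
  # 1-based position 1000 is the first base of [999, 1100)
  expect_equal(
    nrow(apply_autosomal_filters(valid_call(), segdup_mask = mask)$kept), 0
  )
  # 1-based 1100 is the last covered base; 1101 is outside
  expect_equal(
    nrow(apply_autosomal_filters(valid_call(pos = 1100L),
      segdup_mask = mask
    )$kept), 0
  )
  expect_equal(
    nrow(apply_autosomal_filters(valid_call(pos = 1101L),
      segdup_mask = mask
    )$kept), 1
  )
  # 1-based 999 precedes the interval
  expect_equal(
    nrow(apply_autosomal_filters(valid_call(pos = 999L),
      segdup_mask = mask
    )$kept), 1
  )
})

test_that("SNV cluster rule removes all members transitively", {
  mk <- function(pos) {
    do.call(rbind, lapply(pos, function(p) valid_call(pos = as.integer(p))))
  }
  expect_equal(nrow(cluster_filter(mk(c(100, 115)))), 0)
  expect_equal(nrow(cluster_filter(mk(c(100, 121)))), 2) # distance 21
  expect_equal(nrow(cluster_filter(mk(c(100, 120)))), 0) # inclusive at 20
  expect_equal(nrow(cluster_filter(mk(c(100, 118, 136)))), 0) # chain
  # different children or chromosomes do not cluster
  two <- mk(c(100, 110))
  two$child_id <- c("c1", "c2")
  expect_equal(nrow(cluster_filter(two)), 2)
  two2 <- mk(c(100, 110))
  two2$chrom <- c("chr1", "chr2")
  expect_equal(nrow(cluster_filter(two2)), 2)
})

test_that("filters are order-independent and idempotent", {
  co <- small_cohort()
  calls <- co$dnms[1:400, ]
  # inject violations
  calls$rd_child[5] <- 10L
  calls$vaf_child[9] <- 0.2
  calls$pos[12] <- calls$pos[11] + 3L
  calls$chrom[12] <- calls$chrom[11]
  calls$child_id[12] <- calls$child_id[11]
  res <- apply_autosomal_filters(calls)
  # permuting the input rows yields the same kept set
  perm <- sample(nrow(calls))
  res_p <- apply_autosomal_filters(calls[perm, ])
  expect_setequal(
    paste(res$kept$chrom, res$kept$pos),
    paste(res_p$kept$chrom, res_p$kept$pos)
  )
  # idempotence
  res2 <- apply_autosomal_filters(res$kept)
  expect_equal(nrow(res2$kept), nrow(res$kept))
  expect_equal(sum(res2$tally), 0)
})

test_that("simulated true DNMs pass the filters at >= 99%", {
  co <- small_cohort()
  res <- apply_autosomal_filters(co$dnms)
  expect_gte(nrow(res$kept) / nrow(co$dnms), 0.99)
})

test_that("X-chromosome rules are sex-specific", {
  xm <- valid_call(
    chrom = "chrX", gt_child = "1", gt_father = "./.",
    rd_father = 3L
  )
  # male non-PAR: hemizygous child, mother 0/0, no father depth rule
  res <- apply_x_filters(xm, child_sex = "M")
  expect_equal(nrow(res$kept), 1)
  # male heterozygous call removed
  xm2 <- xm
  xm2$gt_child <- "0/1"
  expect_equal(nrow(apply_x_filters(xm2, child_sex = "M")$kept), 0)
  # female: father RD 11 kept, RD 10 removed
  xf <- valid_call(chrom = "chrX", rd_father = 11L)
  expect_equal(nrow(apply_x_filters(xf, child_sex = "F")$kept), 1)
  xf$rd_father <- 10L
  expect_equal(nrow(apply_x_filters(xf, child_sex = "F")$kept), 0)
  # unknown sex excluded with its own rule
  res_u <- apply_x_filters(xf, child_sex = NA_character_)
  expect_equal(nrow(res_u$kept), 0)
  expect_equal(res_u$tally[["sex-unknown"]], 1)
  # PAR: male hemizygous allowed under otherwise autosomal rules
  par_bed <- write_bed(data.frame(chrom = "chrX", start = 0L, end = 5000L))
  par_mask <- read_mask_bed(par_bed, "PAR")
  xp <- valid_call(chrom = "chrX", gt_child = "1", pos = 100L)
  expect_equal(
    nrow(apply_x_filters(xp, child_sex = "M", par_mask = par_mask)$kept), 1
  )
  # but in PAR the father depth rule applies again
  xp$rd_father <- 3L
  expect_equal(
    nrow(apply_x_filters(xp, child_sex = "M", par_mask = par_mask)$kept), 0
  )
})

ddd_call <- function(...) {
  args <- utils::modifyList(
    list(
      altreads_child = 10L, gnomad_af = 0.0001,
      vaf_father = 0.0, vaf_mother = 0.0,
      dng_posterior = 0.5, site_error_rate = 0.001,
      alt_fwd_child = 5L, alt_rev_child = 5L,
      alt_fwd_parents = 30L, alt_rev_parents = 30L
    ),
    list(...)
  )
  do.call(valid_call, args)
}

test_that("the 11-rule exome-cohort filter set applies each threshold", {
  expect_equal(nrow(apply_ddd_filters(ddd_call())$kept), 1)
  # child alt reads: strictly more than 2 required
  expect_equal(nrow(apply_ddd_filters(ddd_call(altreads_child = 2L))$kept), 0)
  expect_equal(nrow(apply_ddd_filters(ddd_call(altreads_child = 3L))$kept), 1)
  # posterior threshold
  expect_equal(nrow(apply_ddd_filters(ddd_call(dng_posterior = 0.005))$kept), 0)
  expect_equal(nrow(apply_ddd_filters(ddd_call(dng_posterior = 0.01))$kept), 1)
  # strand bias: keep requires p > 0.001
  skew <- ddd_call(
    alt_fwd_child = 30L, alt_rev_child = 0L,
    alt_fwd_parents = 5L, alt_rev_parents = 60L
  )
  res <- apply_ddd_filters(skew)
  expect_equal(nrow(res$kept), 0)
  expect_gte(res$tally[["strand-bias"]], 1)
  # both parents > 1 alt read removed; one parent is fine
  expect_equal(nrow(apply_ddd_filters(
    ddd_call(altreads_father = 2L, altreads_mother = 2L)
  )$kept), 0)
  expect_equal(nrow(apply_ddd_filters(
    ddd_call(altreads_father = 2L, altreads_mother = 0L)
  )$kept), 1)
  # depth window 10 < RD <= 200
  expect_equal(nrow(apply_ddd_filters(ddd_call(rd_child = 10L))$kept), 0)
  expect_equal(nrow(apply_ddd_filters(ddd_call(rd_child = 201L))$kept), 0)
  # error-site test: VAF must clearly exceed the site error rate
  noisy <- ddd_call(site_error_rate = 0.45)
  expect_equal(nrow(apply_ddd_filters(noisy)$kept), 0)
})

test_that("missing optional columns make rules not-evaluable, call removed", {
  call <- ddd_call()
  call$dng_posterior <- NA_real_
  res <- apply_ddd_filters(call)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$tally[["not-evaluable"]], 1)
})
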