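# Cohort-style DNM call filters, with per-rule accounting.
#
# Thresholds follow the printed inequalities literally: ">" excludes
# equality everywhere (child RD > 20 removes RD == 20; VAF must satisfy
# 0.3 < VAF < 0.7 exclusive). A call may fail several rules; the tally
# counts every failure. All thresholds are overridable.

#' Read a BED mask into a region mask
#'
#' Reads a standard BED file (0-based half-open) via
#' \code{rtracklayer::import} into a \code{GRanges} used as an exclusion
#' mask. Intervals are reduced (sorted, merged) on import.
#'
#' @param path BED file path.
#' @param label Mask label (e.g. "segdup", "repeat", "PAR").
#' @return A \code{GRanges} with a \code{label} metadata kept as an
#'   attribute.
#' @export
read_mask_bed <- function(path, label = "mask") {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(gr)
  attr(gr, "mask_label") <- label
  gr
}

# TRUE where a 1-based call position falls inside the mask
.in_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || length(mask) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, mask)
}

.need <- function(calls, cols) {
  miss <- !cols %in% names(calls)
  if (any(miss)) {
    # represent wholly absent columns as NA so the incomplete-record rule
    # catches them uniformly
    for (cn in cols[miss]) calls[[cn]] <- NA
  }
  calls
}

#' Apply the autosomal whole-genome DNM filters
#'
#' The rules (all must pass for a call to be kept):
#' genotypes child 0/1, both parents 0/0; read depth > 20 in child, mother
#' and father; at most one alternative read in each parent; child VAF
#' strictly between 0.3 and 0.7; child read depth not above 98; outside the
#' segmental-duplication and simple-repeat masks. SNV cluster removal
#' (\code{\link{cluster_filter}}) is applied to SNVs per child. Calls with a
#' missing required field fail rule \code{"incomplete-record"}.
#'
#' @param calls DNM call data frame (the simulator's table dialect).
#' @param segdup_mask,repeat_mask Optional \code{GRanges} masks.
#' @param thresholds Named list overriding \code{rd_min} (20),
#'   \code{parent_alt_max} (1), \code{vaf_lo} (0.3), \code{vaf_hi} (0.7),
#'   \code{rd_max} (98), \code{cluster_bp} (20).
#' @return List with \code{kept} (the surviving calls), \code{tally} (named
#'   failure counts per rule) and \code{fail} (logical matrix call x rule).
#' @export
apply_autosomal_filters <- function(calls, segdup_mask = NULL,
                                    repeat_mask = NULL,
                                    thresholds = list()) {
  th <- utils::modifyList(
    list(
      rd_min = 20, parent_alt_max = 1, vaf_lo = 0.3, vaf_hi = 0.7,
      rd_max = 98, cluster_bp = 20
    ),
    thresholds
  )
  req <- c(
    "chrom", "pos", "gt_child", "gt_father", "gt_mother",
    "rd_child", "rd_father", "rd_mother",
    "altreads_father", "altreads_mother", "vaf_child"
  )
  calls <- .need(calls, req)
  n <- nrow(calls)
  incomplete <- Reduce(`|`, lapply(req, function(cn) is.na(calls[[cn]])))
  fail <- cbind(
    `genotype` = !(calls$gt_child %in% c("0/1", "1/0") &
      calls$gt_father == "0/0" & calls$gt_mother == "0/0"),
    `read-depth` = !(calls$rd_child > th$rd_min &
      calls$rd_mother > th$rd_min & calls$rd_father > th$rd_min),
    `parental-alt` = !(calls$altreads_father <= th$parent_alt_max &
      calls$altreads_mother <= th$parent_alt_max),
    `vaf` = !(calls$vaf_child > th$vaf_lo & calls$vaf_child < th$vaf_hi),
    `max-depth` = !(calls$rd_child <= th$rd_max),
    `segdup-mask` = .in_mask(calls$chrom, calls$pos, segdup_mask),
    `repeat-mask` = .in_mask(calls$chrom, calls$pos, repeat_mask)
  )
  fail[is.na(fail)] <- TRUE
  fail <- cbind(fail, `incomplete-record` = incomplete)

  # SNV cluster rule among calls from the same child
  is_snv <- if ("vartype" %in% names(calls)) {
    calls$vartype == "SNV"
  } else {
    nchar(calls$ref) == 1 & nchar(calls$alt) == 1
  }
  clustered <- rep(FALSE, n)
  if (any(is_snv, na.rm = TRUE)) {
    snv_idx <- which(is_snv & !is.na(calls$pos))
    cl <- .cluster_members(
      calls$child_id[snv_idx], calls$chrom[snv_idx],
      calls$pos[snv_idx], th$cluster_bp
    )
    clustered[snv_idx] <- cl
  }
  fail <- cbind(fail, `snv-cluster` = clustered)

  kept <- calls[rowSums(fail) == 0, , drop = FALSE]
  list(kept = kept, tally = colSums(fail), fail = fail)
}

# TRUE for every SNV with another SNV from the same child within `bp`
# (inclusive) on the same chromosome; clustering is transitive but the
# pairwise rule alone marks every member of any chain
.cluster_members <- function(child, chrom, pos, bp) {
  key <- paste(child, chrom, sep = "\r")
  out <- logical(length(pos))
  for (k in unique(key)) {
    i <- which(key == k)
    if (length(i) < 2) next
    o <- order(pos[i])
    p <- pos[i][o]
    d <- diff(p)
    near <- d <= bp
    memb <- logical(length(p))
    memb[which(near)] <- TRUE
    memb[which(near) + 1L] <- TRUE
    out[i[o]] <- memb
  }
  out
}

#' Remove clustered SNVs
#'
#' Removes every SNV that has another SNV from the same child within a
#' given distance (default 20 bp, inclusive) on the same chromosome. All
#' members of a cluster are removed, and the rule chains transitively
#' (calls at 100, 118, 136 are all removed).
#'
#' @param calls SNV call data frame with \code{child_id}, \code{chrom},
#'   \code{pos}.
#' @param bp Clustering distance in bp (inclusive).
#' @return The calls with clustered SNVs removed.
#' @export
cluster_filter <- function(calls, bp = 20) {
  if (nrow(calls) == 0) {
    return(calls)
  }
  memb <- .cluster_members(calls$child_id, calls$chrom, calls$pos, bp)
  calls[!memb, , drop = FALSE]
}

#' Apply the X-chromosome DNM filters
#'
#' Pseudoautosomal (PAR) calls use the autosomal rules, additionally
#' allowing hemizygous ("1") child genotypes in males. Non-PAR calls use
#' sex-specific rules: males must be hemizygous with a homozygous-reference
#' mother, read depth > 20 in child and mother with no paternal depth
#' filter; females use the autosomal genotype rule with depth > 20 in child
#' and mother and > 10 in the father. Calls from children of unknown sex
#' fail rule \code{"sex-unknown"}.
#'
#' @param calls Calls on the X chromosome.
#' @param child_sex Named character vector mapping \code{child_id} to
#'   \code{"M"}/\code{"F"}, or a vector along \code{calls}.
#' @param par_mask Optional \code{GRanges} of PAR intervals.
#' @param thresholds As in \code{\link{apply_autosomal_filters}}.
#' @return List with \code{kept}, \code{tally}, \code{fail}.
#' @export
apply_x_filters <- function(calls, child_sex, par_mask = NULL,
                            thresholds = list()) {
  th <- utils::modifyList(
    list(
      rd_min = 20, rd_min_father_female = 10, parent_alt_max = 1,
      vaf_lo = 0.3, vaf_hi = 0.7, rd_max = 98
    ),
    thresholds
  )
  n <- nrow(calls)
  sex <- if (!is.null(names(child_sex))) {
    unname(child_sex[calls$child_id])
  } else {
    rep_len(child_sex, n)
  }
  in_par <- .in_mask(calls$chrom, calls$pos, par_mask)
  male <- sex == "M"
  female <- sex == "F"
  unknown <- is.na(sex) | !(male | female)

  gt_ok <- rep(FALSE, n)
  rd_ok <- rep(FALSE, n)
  # PAR: autosomal rules, hemizygous allowed for males
  gt_par <- (calls$gt_child %in% c("0/1", "1/0") |
    (male & calls$gt_child == "1")) &
    calls$gt_father == "0/0" & calls$gt_mother == "0/0"
  rd_par <- calls$rd_child > th$rd_min & calls$rd_mother > th$rd_min &
    calls$rd_father > th$rd_min
  # non-PAR males: hemizygous child, hom-ref mother, no father depth rule
  gt_m <- calls$gt_child == "1" & calls$gt_mother == "0/0"
  rd_m <- calls$rd_child > th$rd_min & calls$rd_mother > th$rd_min
  # non-PAR females
  gt_f <- calls$gt_child %in% c("0/1", "1/0") &
    calls$gt_father == "0/0" & calls$gt_mother == "0/0"
  rd_f <- calls$rd_child > th$rd_min & calls$rd_mother > th$rd_min &
    calls$rd_father > th$rd_min_father_female

  gt_ok[in_par] <- gt_par[in_par]
  rd_ok[in_par] <- rd_par[in_par]
  i <- !in_par & male
  gt_ok[i] <- gt_m[i]
  rd_ok[i] <- rd_m[i]
  i <- !in_par & female
  gt_ok[i] <- gt_f[i]
  rd_ok[i] <- rd_f[i]

  fail <- cbind(
    `genotype` = !gt_ok,
    `read-depth` = !rd_ok,
    `parental-alt` = !(calls$altreads_father <= th$parent_alt_max &
      calls$altreads_mother <= th$parent_alt_max),
    `vaf` = !(calls$vaf_child > th$vaf_lo & calls$vaf_child < th$vaf_hi),
    `max-depth` = !(calls$rd_child <= th$rd_max),
    `sex-unknown` = unknown
  )
  fail[is.na(fail)] <- TRUE
  kept <- calls[rowSums(fail) == 0, , drop = FALSE]
  list(kept = kept, tally = colSums(fail), fail = fail)
}

#' Apply the exome-cohort (11-rule) WGS DNM filters
#'
#' The rule set used for the whole-genome follow-up of exome-ascertained
#' trios: read depth > 10 in all three members; child alternative-allele
#' reads > 2; Fisher strand-bias p > 0.001 (forward/reverse alternative
#' reads, child versus both parents combined); outside segmental-duplication
#' and repeat masks; population allele frequency < 0.01; parental VAF < 0.1
#' in both parents; not both parents with > 1 alternative read; child VAF
#' significantly above the per-site error rate (one-sided binomial test);
#' caller posterior > 0.00781; child read depth not above 200. A rule whose
#' input column is missing is recorded as \code{"not-evaluable"} and the
#' call is removed (conservative).
#'
#' @param calls Call data frame carrying the extended columns:
#'   \code{gnomad_af}, \code{vaf_father}, \code{vaf_mother},
#'   \code{dng_posterior}, \code{site_error_rate}, and strand counts
#'   \code{alt_fwd_child}, \code{alt_rev_child}, \code{alt_fwd_parents},
#'   \code{alt_rev_parents}.
#' @param segdup_mask,repeat_mask Optional \code{GRanges} masks.
#' @param error_test_alpha Level for the one-sided binomial error-site test.
#' @param thresholds Named list overriding defaults.
#' @return List with \code{kept}, \code{tally}, \code{fail}.
#' @export
apply_ddd_filters <- function(calls, segdup_mask = NULL, repeat_mask = NULL,
                              error_test_alpha = 0.05, thresholds = list()) {
  th <- utils::modifyList(
    list(
      rd_min = 10, child_alt_min = 2, strand_p_min = 0.001,
      gnomad_af_max = 0.01, parent_vaf_max = 0.1, parent_alt_max = 1,
      posterior_min = 0.00781, rd_max = 200
    ),
    thresholds
  )
  opt <- c(
    "gnomad_af", "vaf_father", "vaf_mother", "dng_posterior",
    "site_error_rate", "alt_fwd_child", "alt_rev_child",
    "alt_fwd_parents", "alt_rev_parents"
  )
  calls <- .need(calls, c(
    "rd_child", "rd_father", "rd_mother",
    "altreads_child", "altreads_father", "altreads_mother", opt
  ))
  n <- nrow(calls)

  strand_p <- rep(NA_real_, n)
  ok <- !(is.na(calls$alt_fwd_child) | is.na(calls$alt_rev_child) |
    is.na(calls$alt_fwd_parents) | is.na(calls$alt_rev_parents))
  if (any(ok)) {
    strand_p[ok] <- vapply(which(ok), function(i) {
      stats::fisher.test(matrix(
        c(
          calls$alt_fwd_child[i], calls$alt_rev_child[i],
          calls$alt_fwd_parents[i], calls$alt_rev_parents[i]
        ),
        nrow = 2
      ))$p.value
    }, numeric(1))
  }

  err_p <- rep(NA_real_, n)
  ok <- !(is.na(calls$site_error_rate) | is.na(calls$altreads_child) |
    is.na(calls$rd_child))
  if (any(ok)) {
    err_p[ok] <- vapply(which(ok), function(i) {
      stats::binom.test(
        calls$altreads_child[i], calls$rd_child[i],
        p = max(calls$site_error_rate[i], 1e-12),
        alternative = "greater"
      )$p.value
    }, numeric(1))
  }

  fail <- cbind(
    `read-depth` = !(calls$rd_child > th$rd_min &
      calls$rd_mother > th$rd_min & calls$rd_father > th$rd_min),
    `child-alt-reads` = !(calls$altreads_child > th$child_alt_min),
    `strand-bias` = !(strand_p > th$strand_p_min),
    `segdup-mask` = .in_mask(calls$chrom, calls$pos, segdup_mask),
    `repeat-mask` = .in_mask(calls$chrom, calls$pos, repeat_mask),
    `gnomad-af` = !(calls$gnomad_af < th$gnomad_af_max),
    `parent-vaf` = !(calls$vaf_father < th$parent_vaf_max &
      calls$vaf_mother < th$parent_vaf_max),
    `both-parents-alt` = (calls$altreads_father > th$parent_alt_max &
      calls$altreads_mother > th$parent_alt_max),
    `error-site` = !(err_p < error_test_alpha),
    `posterior` = !(calls$dng_posterior > th$posterior_min),
    `max-depth` = !(calls$rd_child <= th$rd_max)
  )
  not_eval <- is.na(fail)
  fail[not_eval] <- TRUE
  fail <- cbind(fail, `not-evaluable` = rowSums(not_eval) > 0)
  kept <- calls[rowSums(fail[, colnames(fail) != "not-evaluable",
    drop = FALSE
  ]) == 0, , drop = FALSE]
  list(kept = kept, tally = colSums(fail), fail = fail)
}
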