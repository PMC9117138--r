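# Hypermutation outlier detection and per-individual characterization.
#
# A child is a hypermutation candidate when its studentized residual from
# the identity-link NB parental-age model is extreme under a t distribution
# with N - 3 degrees of freedom, Bonferroni-corrected across the analyzed
# children. Known artifact trios (clustered calls with regional parental
# loss of heterozygosity) are screened out and the model refit without
# them.

#' Detect hypermutated individuals
#'
#' Fits (or refits) the identity-link NB parental-age model on all
#' non-excluded children, studentizes the residuals, and flags children
#' whose two-sided t p-value (df = N - 3, N counted after exclusions)
#' falls below \code{alpha / N}. Whenever \code{exclusions} is non-empty the
#' fit is recomputed without those children before residuals are taken.
#'
#' @param counts Data frame with \code{child_id}, \code{count},
#'   \code{father_age}, \code{mother_age} (one row per analyzed child);
#'   a \code{trio_cohort} is also accepted.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param exclusions Character vector of \code{child_id}s removed as
#'   artifacts before fitting.
#' @return List of class \code{hm_scan}: \code{reports} (per-child data
#'   frame with observed, expected, studentized residual, p, flag, excess
#'   and fold relative to the cohort median), \code{fit} (the \code{nb_fit}),
#'   \code{threshold}, \code{n_tests}, \code{cohort_median}.
#' @export
detect_hypermutators <- function(counts, alpha = 0.05,
                                 exclusions = character(0)) {
  if (inherits(counts, "trio_cohort")) {
    counts <- data.frame(
      child_id = counts$trios$child_id,
      count = counts$trios$dn_snv_count,
      father_age = counts$trios$father_age,
      mother_age = counts$trios$mother_age
    )
  }
  keep <- !(counts$child_id %in% exclusions)
  d <- counts[keep, , drop = FALSE]
  n <- nrow(d)
  if (n <= 3) stop("need more than 3 children after exclusions")
  fit <- fit_nb_identity(
    d$count,
    data.frame(father_age = d$father_age, mother_age = d$mother_age)
  )
  stud <- studentized_residuals(fit)
  df <- n - 3
  p <- 2 * stats::pt(-abs(stud), df = df)
  thr <- alpha / n
  med <- stats::median(d$count)
  reports <- data.frame(
    child_id = d$child_id,
    observed = d$count,
    expected = fit$fitted,
    studentized_residual = stud,
    p = p,
    flag = p < thr,
    excess = d$count - med,
    fold = round(d$count / med, 1),
    stringsAsFactors = FALSE
  )
  out <- list(
    reports = reports, fit = fit, threshold = thr, n_tests = n,
    df = df, cohort_median = med, exclusions = exclusions
  )
  class(out) <- "hm_scan"
  out
}

#' @export
print.hm_scan <- function(x, ...) {
  nf <- sum(x$reports$flag)
  cat(
    "hypermutation scan:", x$n_tests, "children, threshold",
    format(x$threshold, digits = 3), "->", nf, "flagged\n"
  )
  if (nf > 0) {
    print(x$reports[x$reports$flag, c(
      "child_id", "observed", "expected",
      "p", "excess", "fold"
    )], digits = 3)
  }
  invisible(x)
}

#' Screen children for the loss-of-transmitted-allele artifact
#'
#' Flags a child when (a) a large fraction of its DNM calls concentrates in
#' a single genomic window of one chromosome (cluster sub-flag) and (b) a
#' parent's heterozygous/homozygous site-count ratio in that window falls
#' well below that parent's genome-wide ratio (LOH sub-flag). The two
#' sub-flags are reported separately; the artifact flag requires both.
#'
#' @param dnms DNM call table with \code{child_id}, \code{chrom},
#'   \code{pos}.
#' @param hethom Parental het/hom window counts with \code{trio_id},
#'   \code{parent}, \code{chrom}, \code{start}, \code{end}, \code{n_het},
#'   \code{n_hom}; the child-to-trio map is taken from \code{trio_map}.
#' @param trio_map Data frame with \code{child_id}, \code{trio_id}.
#' @param cluster_frac Minimum fraction of the child's calls inside one
#'   window to raise the cluster sub-flag.
#' @param window_bp Clustering window length in bp (default 1e5, a 10-Mb
#'   window at the simulator's 1/100 genome scale).
#' @param loh_ratio_frac LOH sub-flag when regional het/hom ratio is below
#'   this fraction of the genome-wide ratio.
#' @return Data frame per child: \code{cluster_flag}, \code{loh_flag},
#'   \code{artifact}, implicated \code{chrom}, \code{region_start},
#'   \code{region_end}, \code{parent}, \code{max_window_frac}.
#' @export
artifact_screen <- function(dnms, hethom = NULL, trio_map = NULL,
                            cluster_frac = 0.5, window_bp = 1e5,
                            loh_ratio_frac = 0.5) {
  children <- unique(dnms$child_id)
  out <- lapply(children, function(cid) {
    calls <- dnms[dnms$child_id == cid, , drop = FALSE]
    ntot <- nrow(calls)
    best_frac <- 0
    best <- list(chrom = NA_character_, start = NA_real_, end = NA_real_)
    for (cn in unique(calls$chrom)) {
      p <- sort(calls$pos[calls$chrom == cn])
      # max count of calls inside any window of window_bp anchored at a call
      j <- findInterval(p + window_bp, p)
      cnt <- j - seq_along(p) + 1L
      k <- which.max(cnt)
      frac <- cnt[k] / ntot
      if (frac > best_frac) {
        best_frac <- frac
        best <- list(chrom = cn, start = p[k], end = p[k] + window_bp)
      }
    }
    cluster_flag <- best_frac >= cluster_frac
    loh_flag <- FALSE
    parent <- NA_character_
    if (cluster_flag && !is.null(hethom) && !is.null(trio_map)) {
      tid <- trio_map$trio_id[match(cid, trio_map$child_id)]
      hh <- hethom[hethom$trio_id == tid, , drop = FALSE]
      for (pp in unique(hh$parent)) {
        hp <- hh[hh$parent == pp, , drop = FALSE]
        genome_ratio <- sum(hp$n_het) / max(sum(hp$n_hom), 1)
        # overlap-weighted regional counts, so windows straddling the
        # region boundary do not dilute the signal
        ov <- pmax(
          0,
          pmin(hp$end, best$end) - pmax(hp$start, best$start)
        ) / (hp$end - hp$start)
        ov[hp$chrom != best$chrom] <- 0
        if (sum(ov) == 0) next
        reg_ratio <- sum(ov * hp$n_het) / max(sum(ov * hp$n_hom), 1e-9)
        if (reg_ratio < loh_ratio_frac * genome_ratio) {
          loh_flag <- TRUE
          parent <- pp
        }
      }
    }
    data.frame(
      child_id = cid, n_calls = ntot,
      cluster_flag = cluster_flag, loh_flag = loh_flag,
      artifact = cluster_flag && loh_flag,
      chrom = best$chrom, region_start = best$start,
      region_end = best$end, parent = parent,
      max_window_frac = best_frac,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Exact two-sided Poisson test (minimum-likelihood method)
#'
#' The two-sided p-value is the sum of probabilities of all outcomes whose
#' Poisson likelihood under the null mean does not exceed that of the
#' observed count. This matches \code{stats::poisson.test}; the wrapper
#' exists so the construction used throughout the characterization tests is
#' explicit and testable in one place.
#'
#' @param observed Observed count.
#' @param expected Null mean (> 0).
#' @return Two-sided p-value.
#' @export
poisson_test_two_sided <- function(observed, expected) {
  if (!(expected > 0)) stop("null mean must be positive")
  stats::poisson.test(observed, r = expected)$p.value
}

#' Characterize a hypermutation candidate
#'
#' Runs the per-individual follow-up tests against cohort references:
#' per-mutation-type enrichment (two-sided Poisson test of the child's
#' count in each of the 7 types C>A, C>G, C>T, T>A, T>C, T>G, indel against
#' the cohort per-child mean), parental phase bias (two-sided binomial test
#' of the maternal count among phased DNMs against the cohort phased
#' paternal fraction), VAF shift (two-sided binomial test of the number of
#' DNMs with VAF < 0.4 against the cohort proportion) and transcriptional
#' strand bias (two-sided Poisson test of the transcribed-strand count
#' against half the stranded total).
#'
#' @param calls The child's DNM calls (columns \code{context96},
#'   \code{vartype}, \code{vaf_child}, \code{tx_strand}).
#' @param phased List/row with \code{n_paternal}, \code{n_maternal}.
#' @param cohort_ref List with \code{type_means} (named per-type per-child
#'   means), \code{vaf_lt04_prop}, \code{paternal_fraction}.
#' @param n_individuals,n_types Multiplicity for the per-type Bonferroni
#'   threshold reported alongside (defaults 12 x 7).
#' @param alpha Family-wise level.
#' @return List with \code{types} (per-type observed, expected, enrichment,
#'   p), \code{type_threshold}, \code{phase_bias_p}, \code{vaf_shift_p},
#'   \code{strand_bias_p}.
#' @export
characterize_hypermutator <- function(calls, phased, cohort_ref,
                                      n_individuals = 12, n_types = 7,
                                      alpha = 0.05) {
  cls6 <- sbs6_classes()
  snv <- calls[calls$vartype == "SNV", , drop = FALSE]
  obs <- c(
    table(factor(substr(snv$context96, 3, 5), levels = cls6)),
    indel = sum(calls$vartype != "SNV")
  )
  expd <- cohort_ref$type_means[names(obs)]
  types <- data.frame(
    type = names(obs), observed = as.integer(obs),
    expected = as.numeric(expd),
    enrichment = ifelse(expd > 0, as.numeric(obs) / as.numeric(expd), NA),
    p = NA_real_, stringsAsFactors = FALSE
  )
  ok <- !is.na(types$expected) & types$expected > 0
  types$p[ok] <- vapply(
    which(ok),
    function(i) poisson_test_two_sided(types$observed[i], types$expected[i]),
    numeric(1)
  )
  n_phased <- phased$n_paternal + phased$n_maternal
  phase_p <- if (n_phased > 0) {
    stats::binom.test(phased$n_maternal, n_phased,
      p = 1 - cohort_ref$paternal_fraction
    )$p.value
  } else {
    NA_real_
  }
  n_lo <- sum(snv$vaf_child < 0.4)
  vaf_p <- if (nrow(snv) > 0) {
    stats::binom.test(n_lo, nrow(snv), p = cohort_ref$vaf_lt04_prop)$p.value
  } else {
    NA_real_
  }
  n_t <- sum(snv$tx_strand == "T", na.rm = TRUE)
  n_u <- sum(snv$tx_strand == "U", na.rm = TRUE)
  strand_p <- if (n_t + n_u > 0) {
    poisson_test_two_sided(n_t, (n_t + n_u) / 2)
  } else {
    NA_real_
  }
  list(
    types = types,
    type_threshold = alpha / (n_individuals * n_types),
    phase_bias_p = phase_p,
    vaf_shift_p = vaf_p,
    strand_bias_p = strand_p,
    n_vaf_lt04 = n_lo, n_phased = n_phased
  )
}

#' Excess and fold relative to the cohort median
#'
#' @param observed Observed DNM count.
#' @param cohort_median Cohort median DNM count (> 0).
#' @param digits Decimal places for the reported fold.
#' @return List with \code{excess} (observed - median, exact) and
#'   \code{fold} (observed / median, rounded).
#' @export
excess_and_fold <- function(observed, cohort_median, digits = 1) {
  if (!(cohort_median > 0)) stop("cohort median must be positive")
  list(
    excess = observed - cohort_median,
    fold = round(observed / cohort_median, digits)
  )
}

#' Absolute disease risk implied by a mutation-rate fold increase
#'
#' Scales the baseline risk that a child carries a disease-causing DNM
#' (about 1 in 300 births for severe developmental disorders) by the fold
#' increase in DNM count: a fourfold increase gives about 1.3\%.
#'
#' @param fold Fold increase in DNM count (>= 0).
#' @param baseline Baseline absolute risk per birth.
#' @return Absolute risk as a probability.
#' @export
disease_risk <- function(fold, baseline = 1 / 300) {
  stopifnot(fold >= 0)
  fold * baseline
}

#' Iterative hypermutation scan with artifact exclusion
#'
#' Runs the detection scan, screens flagged children for the
#' loss-of-transmitted-allele artifact, and—if any artifact is found—
#' excludes those children and refits once, mirroring the two-pass
#' screen-then-refit procedure.
#'
#' @param cohort A \code{trio_cohort} with DNM calls.
#' @param alpha Family-wise level.
#' @param ... Passed to \code{\link{artifact_screen}}.
#' @return List with \code{scan} (final \code{hm_scan}), \code{screen}
#'   (artifact screen of first-pass hits), \code{excluded} (child ids).
#' @export
scan_with_artifact_exclusion <- function(cohort, alpha = 0.05, ...) {
  scan1 <- detect_hypermutators(cohort, alpha = alpha)
  hits <- scan1$reports$child_id[scan1$reports$flag &
    scan1$reports$studentized_residual > 0]
  screen <- NULL
  excluded <- character(0)
  if (length(hits) > 0 && !is.null(cohort$dnms)) {
    screen <- artifact_screen(
      cohort$dnms[cohort$dnms$child_id %in% hits, , drop = FALSE],
      hethom = cohort$hethom,
      trio_map = cohort$trios[, c("child_id", "trio_id")],
      ...
    )
    excluded <- screen$child_id[screen$artifact]
  }
  scan <- if (length(excluded) > 0) {
    detect_hypermutators(cohort, alpha = alpha, exclusions = excluded)
  } else {
    scan1
  }
  list(scan = scan, screen = screen, excluded = excluded)
}
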