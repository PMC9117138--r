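# Read-backed parent-of-origin phasing.
#
# A DNM is phased by finding nearby heterozygous sites in the child whose
# alleles can each be attributed to a unique parent, then counting on how
# many sequencing fragments the DNM's alternative allele co-occurs with
# each parent's allele. A DNM is called paternal or maternal only when all
# fragment evidence points to one parent; mixed evidence is a conflict.

.split_gt <- function(gt) strsplit(gt, "/", fixed = TRUE)

#' Find informative heterozygous sites near a DNM
#'
#' A site is informative when the child is heterozygous and exactly one
#' assignment of the two child alleles to the two parents is consistent
#' with Mendelian transmission. Sites heterozygous in both parents and the
#' child are never informative. Only sites within \code{window} bp of the
#' DNM (inclusive) on the same chromosome are considered.
#'
#' @param dnm List or one-row data frame with \code{chrom}, \code{pos}.
#' @param trio_variants Data frame of nearby variants with \code{chrom},
#'   \code{pos} and allele-level genotypes \code{gt_child},
#'   \code{gt_father}, \code{gt_mother} written as e.g. \code{"A/G"}.
#' @param window Maximum distance in bp (inclusive).
#' @return Data frame with \code{chrom}, \code{pos}, \code{distance},
#'   \code{father_allele}, \code{mother_allele}; zero rows if none.
#' @export
find_informative_sites <- function(dnm, trio_variants, window = 500) {
  tv <- trio_variants
  empty <- data.frame(
    chrom = character(0), pos = integer(0), distance = integer(0),
    father_allele = character(0), mother_allele = character(0),
    stringsAsFactors = FALSE
  )
  if (is.null(tv) || nrow(tv) == 0) {
    return(empty)
  }
  tv <- tv[tv$chrom == dnm$chrom & abs(tv$pos - dnm$pos) <= window &
    tv$pos != dnm$pos, , drop = FALSE]
  if (nrow(tv) == 0) {
    return(empty)
  }
  ch <- .split_gt(tv$gt_child)
  fa <- .split_gt(tv$gt_father)
  mo <- .split_gt(tv$gt_mother)
  rows <- lapply(seq_len(nrow(tv)), function(i) {
    a <- ch[[i]]
    if (length(a) != 2 || a[1] == a[2]) {
      return(NULL) # child not heterozygous
    }
    # exclude triple-heterozygous sites
    if (fa[[i]][1] != fa[[i]][2] && mo[[i]][1] != mo[[i]][2]) {
      return(NULL)
    }
    asg1 <- a[1] %in% fa[[i]] && a[2] %in% mo[[i]] # a1 from father
    asg2 <- a[2] %in% fa[[i]] && a[1] %in% mo[[i]] # a2 from father
    if (asg1 == asg2) {
      return(NULL) # ambiguous or inconsistent
    }
    f_allele <- if (asg1) a[1] else a[2]
    m_allele <- if (asg1) a[2] else a[1]
    data.frame(
      chrom = tv$chrom[i], pos = tv$pos[i],
      distance = abs(tv$pos[i] - dnm$pos),
      father_allele = f_allele, mother_allele = m_allele,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Phase a single DNM from read evidence
#'
#' Counts sequencing fragments on which the DNM's alternative allele
#' co-occurs with a paternally versus maternally attributed allele at any
#' informative site, and calls the parent of origin only when the evidence
#' is exclusive.
#'
#' @param dnm List/one-row data frame with \code{chrom}, \code{pos},
#'   \code{alt} (and optionally \code{dnm_id}).
#' @param sites Informative sites from \code{\link{find_informative_sites}}.
#' @param reads Read-evidence table with columns \code{read_id},
#'   \code{locus_a}, \code{allele_a} (observation at the DNM) and
#'   \code{locus_b}, \code{allele_b} (observation at a nearby site). Each
#'   fragment contributes at most one observation per site.
#' @return List with \code{result} in \code{paternal}, \code{maternal},
#'   \code{unphased_no_data}, \code{unphased_conflict}; and support counts
#'   \code{n_paternal}, \code{n_maternal}.
#' @export
phase_dnm <- function(dnm, sites, reads) {
  n_pat <- 0L
  n_mat <- 0L
  if (!is.null(reads) && nrow(reads) > 0 && nrow(sites) > 0) {
    r <- reads[reads$locus_a == dnm$pos & reads$allele_a == dnm$alt, ,
      drop = FALSE
    ]
    if (nrow(r) > 0) {
      # one observation per fragment per site
      r <- r[!duplicated(paste(r$read_id, r$locus_b)), , drop = FALSE]
      m <- match(r$locus_b, sites$pos)
      ok <- !is.na(m)
      n_pat <- sum(r$allele_b[ok] == sites$father_allele[m[ok]])
      n_mat <- sum(r$allele_b[ok] == sites$mother_allele[m[ok]])
    }
  }
  result <- if (n_pat == 0 && n_mat == 0) {
    "unphased_no_data"
  } else if (n_pat > 0 && n_mat > 0) {
    "unphased_conflict"
  } else if (n_pat > 0) {
    "paternal"
  } else {
    "maternal"
  }
  list(result = result, n_paternal = n_pat, n_maternal = n_mat)
}

#' Simulate read evidence over a DNM and one informative site
#'
#' Generates fragment observations covering a DNM and a nearby informative
#' heterozygous site. The haplotype carrying the DNM also carries the true
#' parent's site allele; the other haplotype carries the reference and the
#' other parent's allele. Each allele observation is flipped independently
#' with probability \code{error_rate}. If the site lies beyond the fragment
#' span no co-covering reads are produced (valid, unphaseable evidence).
#'
#' @param dnm List with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{true_parent} ("father"/"mother").
#' @param site List with \code{offset} (bp from the DNM),
#'   \code{father_allele}, \code{mother_allele}.
#' @param n_reads Number of fragments.
#' @param error_rate Per-allele observation error probability.
#' @param span Maximum fragment span in bp.
#' @param seed Optional seed.
#' @return Read-evidence data frame (possibly zero rows) with columns
#'   \code{read_id}, \code{locus_a}, \code{allele_a}, \code{locus_b},
#'   \code{allele_b}.
#' @export
simulate_phasing_reads <- function(dnm, site, n_reads, error_rate = 0,
                                   span = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(
    read_id = character(0), locus_a = integer(0), allele_a = character(0),
    locus_b = integer(0), allele_b = character(0), stringsAsFactors = FALSE
  )
  if (n_reads == 0 || abs(site$offset) > span) {
    return(empty)
  }
  hap_dnm <- stats::runif(n_reads) < 0.5 # fragment from the DNM haplotype
  allele_a <- ifelse(hap_dnm, dnm$alt, dnm$ref)
  true_site <- if (dnm$true_parent == "father") {
    site$father_allele
  } else {
    site$mother_allele
  }
  other_site <- if (dnm$true_parent == "father") {
    site$mother_allele
  } else {
    site$father_allele
  }
  allele_b <- ifelse(hap_dnm, true_site, other_site)
  if (error_rate > 0) {
    flip_a <- stats::runif(n_reads) < error_rate
    allele_a[flip_a] <- ifelse(allele_a[flip_a] == dnm$alt, dnm$ref, dnm$alt)
    flip_b <- stats::runif(n_reads) < error_rate
    allele_b[flip_b] <- ifelse(allele_b[flip_b] == site$father_allele,
      site$mother_allele, site$father_allele
    )
  }
  data.frame(
    read_id = sprintf("r%04d", seq_len(n_reads)),
    locus_a = dnm$pos, allele_a = allele_a,
    locus_b = dnm$pos + site$offset, allele_b = allele_b,
    stringsAsFactors = FALSE
  )
}

#' Simulate phasing evidence for a whole cohort
#'
#' For each DNM in the cohort, with probability \code{informative_prob} an
#' informative heterozygous site exists nearby and fragment evidence is
#' generated for it (vectorized across the cohort).
#'
#' @param cohort A \code{trio_cohort} with DNM calls.
#' @param informative_prob Probability a DNM has an informative site.
#' @param n_reads Fragments per phaseable DNM.
#' @param error_rate Per-allele observation error probability.
#' @param seed Seed.
#' @return List with \code{sites} (dnm_id, site position and parent allele
#'   map) and \code{reads} (dnm_id keyed fragment observations).
#' @export
simulate_cohort_reads <- function(cohort, informative_prob = 0.6,
                                  n_reads = 8, error_rate = 0, seed = 1) {
  stopifnot(inherits(cohort, "trio_cohort"), !is.null(cohort$dnms))
  set.seed(seed)
  d <- cohort$dnms
  has_site <- stats::runif(nrow(d)) < informative_prob
  ds <- d[has_site, , drop = FALSE]
  ns <- nrow(ds)
  if (ns == 0) {
    return(list(
      sites = data.frame(), reads = data.frame()
    ))
  }
  offset <- sample(c(-1, 1), ns, TRUE) * sample(50:500, ns, TRUE)
  sites <- data.frame(
    dnm_id = ds$dnm_id, trio_id = ds$trio_id, chrom = ds$chrom,
    pos = ds$pos + offset,
    father_allele = "A", mother_allele = "G",
    stringsAsFactors = FALSE
  )
  idx <- rep(seq_len(ns), each = n_reads)
  total <- ns * n_reads
  hap_dnm <- stats::runif(total) < 0.5
  allele_a <- ifelse(hap_dnm, ds$alt[idx], ds$ref[idx])
  pat <- ds$true_parent[idx] == "father"
  allele_b <- ifelse(hap_dnm == pat, "A", "G")
  if (error_rate > 0) {
    flip_a <- stats::runif(total) < error_rate
    allele_a[flip_a] <- ifelse(allele_a[flip_a] == ds$alt[idx][flip_a],
      ds$ref[idx][flip_a], ds$alt[idx][flip_a]
    )
    flip_b <- stats::runif(total) < error_rate
    allele_b[flip_b] <- ifelse(allele_b[flip_b] == "A", "G", "A")
  }
  reads <- data.frame(
    read_id = sprintf("r%08d", seq_len(total)),
    dnm_id = ds$dnm_id[idx], trio_id = ds$trio_id[idx],
    locus_a = ds$pos[idx], allele_a = allele_a,
    locus_b = sites$pos[idx], allele_b = allele_b,
    stringsAsFactors = FALSE
  )
  list(sites = sites, reads = reads)
}

#' Phase every DNM in a cohort and model the paternal fraction
#'
#' Phases each DNM from the fragment-evidence tables, aggregates per-trio
#' paternal/maternal/unphased counts, and fits an identity-link binomial
#' regression of the paternal proportion on paternal age. The four phase
#' outcomes partition the DNMs exactly.
#'
#' @param cohort A \code{trio_cohort} with DNM calls.
#' @param evidence List with \code{sites} and \code{reads} as produced by
#'   \code{\link{simulate_cohort_reads}} (or equivalent real-data tables
#'   keyed by \code{dnm_id}).
#' @param link Link for the paternal-fraction regression.
#' @return List with \code{per_dnm} (dnm_id, result, support counts),
#'   \code{per_trio} (n_paternal, n_maternal, n_unphased, father_age) and
#'   \code{fraction_fit} (see \code{\link{fit_paternal_fraction}}).
#' @export
phase_cohort <- function(cohort, evidence, link = "identity") {
  stopifnot(inherits(cohort, "trio_cohort"), !is.null(cohort$dnms))
  d <- cohort$dnms
  reads <- evidence$reads
  n_pat <- n_mat <- stats::setNames(integer(nrow(d)), d$dnm_id)
  if (!is.null(reads) && nrow(reads) > 0) {
    alt_of <- stats::setNames(d$alt, d$dnm_id)
    r <- reads[reads$allele_a == alt_of[reads$dnm_id], , drop = FALSE]
    if (nrow(r) > 0) {
      s <- evidence$sites
      fa_of <- stats::setNames(s$father_allele, s$dnm_id)
      mo_of <- stats::setNames(s$mother_allele, s$dnm_id)
      pat_tab <- table(r$dnm_id[r$allele_b == fa_of[r$dnm_id]])
      mat_tab <- table(r$dnm_id[r$allele_b == mo_of[r$dnm_id]])
      n_pat[names(pat_tab)] <- as.integer(pat_tab)
      n_mat[names(mat_tab)] <- as.integer(mat_tab)
    }
  }
  result <- ifelse(n_pat == 0 & n_mat == 0, "unphased_no_data",
    ifelse(n_pat > 0 & n_mat > 0, "unphased_conflict",
      ifelse(n_pat > 0, "paternal", "maternal")
    )
  )
  per_dnm <- data.frame(
    dnm_id = d$dnm_id, trio_id = d$trio_id,
    result = unname(result),
    n_paternal = unname(n_pat), n_maternal = unname(n_mat),
    true_parent = d$true_parent,
    stringsAsFactors = FALSE
  )
  agg <- function(res) {
    t <- table(factor(per_dnm$trio_id[per_dnm$result == res],
      levels = cohort$trios$trio_id
    ))
    as.integer(t)
  }
  per_trio <- data.frame(
    trio_id = cohort$trios$trio_id,
    father_age = cohort$trios$father_age,
    n_paternal = agg("paternal"),
    n_maternal = agg("maternal"),
    n_conflict = agg("unphased_conflict"),
    n_no_data = agg("unphased_no_data"),
    stringsAsFactors = FALSE
  )
  per_trio$n_phased <- per_trio$n_paternal + per_trio$n_maternal
  fit <- fit_paternal_fraction(
    per_trio$n_paternal, per_trio$n_phased, per_trio$father_age,
    link = link
  )
  list(per_dnm = per_dnm, per_trio = per_trio, fraction_fit = fit)
}
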