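# Parental pre-conception cancer/chemotherapy exposure analysis from coded
# hospital records (ICD10-like), and its effect on offspring DNM counts.

#' Classify a parent's pre-conception cancer history from coded records
#'
#' A parent is \emph{eligible} for comparison when at least one record is
#' dated at least two years before the child's birth year (a year-level
#' proxy for "before conception"). A cancer diagnosis before conception is
#' any qualifying code — ICD10 'C' prefix (malignant neoplasm) or 'Z85'
#' prefix (personal history of malignant neoplasm) — dated >= 2 years
#' before the birth year; 'Z511' (antineoplastic chemotherapy encounter)
#' sets the chemotherapy flag under the same dating rule. Malformed codes
#' are ignored and tallied.
#'
#' @param records Data frame with \code{parent_id}, \code{icd10_code},
#'   \code{year} for one parent (rows for other parents are ignored if
#'   \code{parent_id} is supplied).
#' @param child_birth_year Integer birth year.
#' @param parent_id Optionally restrict \code{records} to this parent.
#' @return Object of class \code{parental_history}: flags
#'   \code{eligible}, \code{cancer_before_conception}, \code{chemo_code},
#'   \code{qualifying} (the qualifying records) and \code{n_malformed}.
#' @export
classify_parental_history <- function(records, child_birth_year,
                                      parent_id = NULL) {
  if (!is.null(parent_id)) {
    records <- records[records$parent_id == parent_id, , drop = FALSE]
  }
  ok <- grepl("^[A-Z][0-9]", records$icd10_code) &
    !is.na(records$year) & records$year == round(records$year)
  n_malformed <- sum(!ok)
  rec <- records[ok, , drop = FALSE]
  pre <- rec[rec$year <= child_birth_year - 2, , drop = FALSE]
  eligible <- nrow(pre) > 0
  is_cancer <- startsWith(pre$icd10_code, "C") |
    startsWith(pre$icd10_code, "Z85")
  is_chemo <- startsWith(pre$icd10_code, "Z511")
  out <- list(
    parent_id = if (!is.null(parent_id)) {
      parent_id
    } else if (nrow(records) > 0) records$parent_id[1] else NA_character_,
    eligible = eligible,
    cancer_before_conception = eligible && any(is_cancer),
    chemo_code = eligible && any(is_chemo),
    qualifying = pre[is_cancer | is_chemo, , drop = FALSE],
    n_malformed = n_malformed
  )
  class(out) <- "parental_history"
  out
}

#' Test exposed versus unexposed children on model residuals
#'
#' Two-sided Wilcoxon rank-sum test of the age/quality/hypermutation-
#' corrected model residuals between children of exposed and unexposed
#' parents.
#'
#' @param residuals Per-child residuals from the full NB fit (Pearson or
#'   raw; the test is rank-based).
#' @param exposed Logical vector along \code{residuals}.
#' @return List with \code{p}, \code{median_exposed},
#'   \code{median_unexposed}, \code{n_exposed}, \code{n_unexposed}.
#' @export
exposure_group_test <- function(residuals, exposed) {
  stopifnot(length(residuals) == length(exposed))
  if (!any(exposed) || all(exposed)) stop("both groups must be non-empty")
  wt <- stats::wilcox.test(residuals[exposed], residuals[!exposed],
    exact = FALSE
  )
  list(
    p = wt$p.value,
    median_exposed = stats::median(residuals[exposed]),
    median_unexposed = stats::median(residuals[!exposed]),
    n_exposed = sum(exposed), n_unexposed = sum(!exposed)
  )
}

#' Age-matched control comparison of case DNM counts
#'
#' For each case child, draws \code{k} control children (with replacement)
#' matched on both paternal and maternal age — exact year match first,
#' widening to a +/- 2 year caliper if needed — then compares case counts
#' with matched-control counts by a two-sided Wilcoxon test. Cases with no
#' control inside the widest caliper are dropped with a warning.
#'
#' @param cases Data frame of cases: \code{count}, \code{father_age},
#'   \code{mother_age}.
#' @param cohort Data frame of candidate controls (same columns).
#' @param k Controls per case.
#' @param caliper_widths Successive age calipers tried (years).
#' @param seed Seed for the control draw.
#' @return List with \code{p}, \code{median_case}, \code{median_control},
#'   \code{median_difference}, \code{n_cases_used}, \code{controls}.
#' @export
matched_cohort_test <- function(cases, cohort, k = 20,
                                caliper_widths = c(0, 1, 2), seed = 1) {
  set.seed(seed)
  ctrl_counts <- NULL
  used <- 0
  for (i in seq_len(nrow(cases))) {
    pool <- integer(0)
    for (w in caliper_widths) {
      pool <- which(
        abs(round(cohort$father_age) - round(cases$father_age[i])) <= w &
          abs(round(cohort$mother_age) - round(cases$mother_age[i])) <= w
      )
      if (length(pool) > 0) break
    }
    if (length(pool) == 0) {
      warning("no control within caliper for case ", i, "; dropped")
      next
    }
    used <- used + 1
    ctrl_counts <- c(
      ctrl_counts,
      cohort$count[sample(pool, k, replace = TRUE)]
    )
  }
  if (used == 0) stop("no case could be matched")
  wt <- stats::wilcox.test(cases$count, ctrl_counts, exact = FALSE)
  list(
    p = wt$p.value,
    median_case = stats::median(cases$count),
    median_control = stats::median(ctrl_counts),
    median_difference = stats::median(cases$count) -
      stats::median(ctrl_counts),
    n_cases_used = used,
    controls = ctrl_counts
  )
}

#' Enrichment of hypermutation among exposed parents
#'
#' Exact two-sided Fisher test of the 2x2 table of hypermutated children
#' among exposed versus unexposed parents (p is the sum of hypergeometric
#' probabilities no larger than the observed table's).
#'
#' @param exposed Vector or list \code{c(n_hyper, n_total)} for the exposed
#'   group.
#' @param unexposed Same for the unexposed group.
#' @return List with \code{p}, \code{odds_ratio}, \code{table}.
#' @export
hypermutation_enrichment_test <- function(exposed, unexposed) {
  e <- as.numeric(exposed)
  u <- as.numeric(unexposed)
  stopifnot(length(e) == 2, length(u) == 2, e[1] <= e[2], u[1] <= u[2])
  tab <- matrix(
    c(e[1], e[2] - e[1], u[1], u[2] - u[1]),
    nrow = 2,
    dimnames = list(
      c("hyper", "not_hyper"),
      c("exposed", "unexposed")
    )
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in 2x2 table")
  }
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}
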