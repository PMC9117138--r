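#' Scaled simulated genome
#'
#' A desk-scale genome: the 22 autosomes plus X with lengths at 1/100 of the
#' human assembly, used to place simulated DNMs. Positions are 1-based.
#'
#' @return Named integer vector of chromosome lengths in bp.
#' @export
sim_genome <- function() {
  mb <- c(
    chr1 = 248.96, chr2 = 242.19, chr3 = 198.30, chr4 = 190.21,
    chr5 = 181.54, chr6 = 170.81, chr7 = 159.35, chr8 = 145.14,
    chr9 = 138.39, chr10 = 133.80, chr11 = 135.09, chr12 = 133.28,
    chr13 = 114.36, chr14 = 107.04, chr15 = 101.99, chr16 = 90.34,
    chr17 = 83.26, chr18 = 80.37, chr19 = 58.62, chr20 = 64.44,
    chr21 = 46.71, chr22 = 50.82, chrX = 156.04
  )
  round(mb * 1e6 / 100)
}

#' Configuration for the trio-cohort simulator
#'
#' Defines the generative model for a whole-genome trio cohort. Expected
#' de novo SNV counts follow an additive (identity-link) parental-age model
#' \eqn{E(Y) = \beta_0 + \beta_{pat} f + \beta_{mat} m} for paternal age
#' \eqn{f} and maternal age \eqn{m} (years), with negative-binomial noise
#' (\eqn{Var = \mu + \mu^2/\theta}). Each DNM is paternal with an
#' age-dependent probability, is assigned a 96-channel substitution class
#' from its etiology's signature mixture, and gets read support drawn
#' binomially around a heterozygous allele fraction of 0.5.
#'
#' Defaults reflect a large rare-disease whole-genome cohort: slopes of 1.28
#' dnSNVs per paternal year and 0.35 per maternal year, paternal/maternal
#' ages centred at 33/30 years, a paternal phase fraction of 0.77 at the
#' reference paternal age rising by 0.0017 per year, and ~35x sequencing
#' depth. The dispersion default (theta = 200) makes parental age account
#' for roughly 70\% of the super-Poisson count variance and gives a
#' variance/mean ratio of about 2.
#'
#' @param n_trios Number of trios.
#' @param beta0 Baseline expected dnSNV count (age-independent term).
#' @param beta_pat Expected extra dnSNVs per year of paternal age.
#' @param beta_mat Expected extra dnSNVs per year of maternal age.
#' @param dispersion NB dispersion theta (> 0); \code{Inf} gives Poisson counts.
#' @param paternal_fraction_base Probability a DNM is paternal at the
#'   reference paternal age.
#' @param paternal_fraction_slope Change in paternal fraction per year of
#'   paternal age.
#' @param paternal_reference_age Paternal age (years) at which
#'   \code{paternal_fraction_base} applies.
#' @param mother_age_mean,mother_age_sd,mother_age_range Maternal age
#'   distribution (truncated normal).
#' @param father_age_offset_mean,father_age_offset_sd Paternal age is
#'   maternal age plus a normal offset, truncated to
#'   \code{father_age_range}.
#' @param father_age_range Allowed paternal age range.
#' @param signature_mix Named list mapping each etiology to a named numeric
#'   vector of catalogue-signature weights (each summing to 1).
#' @param catalogue Signature catalogue matrix (k x 96, unit row sums).
#' @param vaf_depth Mean sequencing depth for binomial VAF sampling.
#' @param seed Integer seed; fixing it fixes every simulated value.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_trios = 1000,
                       beta0 = 20,
                       beta_pat = 1.28,
                       beta_mat = 0.35,
                       dispersion = 200,
                       paternal_fraction_base = 0.77,
                       paternal_fraction_slope = 0.0017,
                       paternal_reference_age = 33,
                       mother_age_mean = 30,
                       mother_age_sd = 4.5,
                       mother_age_range = c(18, 45),
                       father_age_offset_mean = 3,
                       father_age_offset_sd = 2.5,
                       father_age_range = c(18, 60),
                       signature_mix = NULL,
                       catalogue = signature_catalogue(),
                       vaf_depth = 35,
                       seed = 1L) {
  if (is.null(signature_mix)) {
    base_mix <- c(sig_clock = 0.16, sig_flat = 0.84)
    signature_mix <- list(
      baseline = base_mix,
      repair_defect = c(sig_tc = 1),
      chemo_signature = c(sig_platinum = 1),
      postzygotic = base_mix,
      lota_artifact = base_mix
    )
  }
  cfg <- list(
    n_trios = as.integer(n_trios), beta0 = beta0, beta_pat = beta_pat,
    beta_mat = beta_mat, dispersion = dispersion,
    paternal_fraction_base = paternal_fraction_base,
    paternal_fraction_slope = paternal_fraction_slope,
    paternal_reference_age = paternal_reference_age,
    mother_age_mean = mother_age_mean, mother_age_sd = mother_age_sd,
    mother_age_range = mother_age_range,
    father_age_offset_mean = father_age_offset_mean,
    father_age_offset_sd = father_age_offset_sd,
    father_age_range = father_age_range,
    signature_mix = signature_mix, catalogue = catalogue,
    vaf_depth = vaf_depth, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A \code{sim_config} object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (n_trios < 0) stop("n_trios must be nonnegative")
    if (beta0 < 0 || beta_pat < 0 || beta_mat < 0) {
      stop("rate parameters must be nonnegative")
    }
    if (!(dispersion > 0)) stop("dispersion must be > 0")
    .check_catalogue(catalogue)
    for (nm in names(signature_mix)) {
      w <- signature_mix[[nm]]
      if (abs(sum(w) - 1) > 1e-9) {
        stop("signature_mix weights for '", nm, "' must sum to 1")
      }
      if (!all(names(w) %in% rownames(catalogue))) {
        stop("unknown signature id in mix for '", nm, "'")
      }
    }
    # expected count must be positive over the whole configured age range
    mu_min <- beta0 + beta_pat * father_age_range[1] +
      beta_mat * mother_age_range[1]
    if (mu_min <= 0) stop("expected count nonpositive at minimum ages")
    # paternal fraction must stay a probability over the age range
    pf <- paternal_fraction_base + paternal_fraction_slope *
      (father_age_range - paternal_reference_age)
    if (any(pf < 0 | pf > 1)) {
      stop("paternal fraction leaves [0,1] over the configured age range")
    }
  })
  invisible(config)
}

# Poisson truncated to values strictly above `lo`
.rpois_gt <- function(n, lambda, lo) {
  x <- stats::rpois(n, lambda)
  bad <- which(x <= lo)
  while (length(bad) > 0) {
    x[bad] <- stats::rpois(length(bad), lambda)
    bad <- bad[x[bad] <= lo]
  }
  x
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

.paternal_fraction <- function(config, father_age) {
  pmin(pmax(config$paternal_fraction_base + config$paternal_fraction_slope *
    (father_age - config$paternal_reference_age), 0), 1)
}

# channel sampling probabilities for one etiology
.mix_probs <- function(config, etiology) {
  w <- config$signature_mix[[etiology]]
  if (is.null(w)) stop("unknown etiology: ", etiology)
  p <- drop(w %*% config$catalogue[names(w), , drop = FALSE])
  p / sum(p)
}

# vectorized construction of DNM call rows
.gen_dnm_rows <- function(config, trio_id, child_id, n_per, etiology,
                          true_parent = NULL, true_vaf = 0.5,
                          region = NULL) {
  n <- sum(n_per)
  if (n == 0) {
    return(.empty_dnm_table())
  }
  genome <- sim_genome()
  probs <- .mix_probs(config, etiology)
  ch <- sbs96_channels()[sample.int(96, n, replace = TRUE, prob = probs)]
  if (is.null(region)) {
    chrom <- names(genome)[sample.int(
      length(genome), n,
      replace = TRUE, prob = genome
    )]
    pos <- 1L + as.integer(floor(stats::runif(n) * (genome[chrom] - 1)))
  } else {
    chrom <- rep(region$chrom, n)
    pos <- as.integer(floor(stats::runif(n, region$start, region$end + 1)))
  }
  ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5)
  # depths emulate a coverage-QC'd cohort (upstream pipelines release calls
  # only where trio depth is adequate), so the depth filter is satisfiable
  rd_child <- .rpois_gt(n, config$vaf_depth, 20L)
  vaf_true <- rep_len(true_vaf, n)
  alt_child <- stats::rbinom(n, rd_child, vaf_true)
  # constitutive het calls mimic a released call set: observed allele
  # balance inside the callable (0.3, 0.7) band; mosaic calls (true VAF
  # below 0.5) keep their raw binomial draw — the shift is the signal
  het <- vaf_true == 0.5
  bad <- het & (alt_child / rd_child <= 0.3 | alt_child / rd_child >= 0.7)
  while (any(bad)) {
    alt_child[bad] <- stats::rbinom(sum(bad), rd_child[bad], 0.5)
    bad <- het & (alt_child / rd_child <= 0.3 | alt_child / rd_child >= 0.7)
  }
  data.frame(
    trio_id = rep(trio_id, n_per),
    child_id = rep(child_id, n_per),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vartype = "SNV",
    gt_child = "0/1", gt_father = "0/0", gt_mother = "0/0",
    rd_child = rd_child,
    rd_father = .rpois_gt(n, config$vaf_depth, 20L),
    rd_mother = .rpois_gt(n, config$vaf_depth, 20L),
    altreads_father = 0L, altreads_mother = 0L,
    altreads_child = alt_child,
    vaf_child = alt_child / rd_child,
    context96 = ch,
    tx_strand = sample(c("T", "U", NA), n,
      replace = TRUE,
      prob = c(0.2, 0.2, 0.6)
    ),
    true_parent = if (is.null(true_parent)) NA_character_ else
      rep_len(true_parent, n),
    true_signature = ch,
    true_vaf = vaf_true,
    etiology = etiology,
    stringsAsFactors = FALSE
  )
}

.empty_dnm_table <- function() {
  data.frame(
    trio_id = character(0), child_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    vartype = character(0), gt_child = character(0),
    gt_father = character(0), gt_mother = character(0),
    rd_child = integer(0), rd_father = integer(0), rd_mother = integer(0),
    altreads_father = integer(0), altreads_mother = integer(0),
    altreads_child = integer(0), vaf_child = numeric(0),
    context96 = character(0), tx_strand = character(0),
    true_parent = character(0), true_signature = character(0),
    true_vaf = numeric(0), etiology = character(0),
    stringsAsFactors = FALSE
  )
}

# baseline parental het/hom site counts in fixed windows, per chromosome
.gen_hethom <- function(trio_ids, window = 2e5) {
  genome <- sim_genome()
  win <- lapply(names(genome), function(cn) {
    starts <- seq(0L, genome[[cn]] - 1L, by = window)
    data.frame(
      chrom = cn, start = starts,
      end = pmin(starts + window, genome[[cn]])
    )
  })
  win <- do.call(rbind, win)
  nwin <- nrow(win)
  out <- do.call(rbind, lapply(trio_ids, function(tid) {
    do.call(rbind, lapply(c("father", "mother"), function(p) {
      cbind(
        data.frame(trio_id = tid, parent = p, stringsAsFactors = FALSE),
        win,
        n_het = stats::rpois(nwin, 0.0008 * (win$end - win$start)),
        n_hom = stats::rpois(nwin, 0.0005 * (win$end - win$start))
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a trio cohort
#'
#' Draws parental ages, NB-distributed dnSNV counts with the configured
#' additive age model, per-DNM parent-of-origin labels, 96-channel
#' substitution classes, genomic positions and binomial read support. All
#' trios start with etiology \code{"baseline"}; use
#' \code{\link{inject_hypermutators}} and \code{\link{inject_lota_artifact}}
#' to add outliers and the clustered-call artifact mode.
#'
#' @param config A \code{\link{sim_config}}.
#' @param include_dnms If \code{FALSE}, only per-trio counts are generated
#'   (fast path for large count-level simulations); the DNM call table and
#'   parental het/hom table are omitted.
#' @return A \code{trio_cohort}: list with \code{trios} (one row per trio
#'   with ages, QC metrics, observed and truth counts), \code{dnms} (one row
#'   per DNM call, with truth labels), \code{hethom} (parental het/hom site
#'   counts in genomic windows) and \code{config}.
#' @export
simulate_cohort <- function(config, include_dnms = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_trios
  if (n == 0) {
    cohort <- list(
      trios = data.frame(), dnms = .empty_dnm_table(),
      hethom = NULL, config = config
    )
    class(cohort) <- "trio_cohort"
    return(cohort)
  }
  ma <- .rtruncnorm(
    n, config$mother_age_mean, config$mother_age_sd,
    config$mother_age_range[1], config$mother_age_range[2]
  )
  fa <- pmin(
    pmax(
      ma + stats::rnorm(
        n, config$father_age_offset_mean,
        config$father_age_offset_sd
      ),
      config$father_age_range[1]
    ),
    config$father_age_range[2]
  )
  mu <- config$beta0 + config$beta_pat * fa + config$beta_mat * ma
  if (any(mu <= 0)) stop("negative expected count for simulated ages")
  counts <- if (is.infinite(config$dispersion)) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, size = config$dispersion, mu = mu)
  }
  pfrac <- .paternal_fraction(config, fa)

  trio_id <- sprintf("trio%05d", seq_len(n))
  trios <- data.frame(
    trio_id = trio_id,
    child_id = paste0(trio_id, "_c"),
    father_id = paste0(trio_id, "_f"),
    mother_id = paste0(trio_id, "_m"),
    child_sex = sample(c("M", "F"), n, replace = TRUE),
    father_age = fa, mother_age = ma,
    dn_snv_count = counts,
    true_paternal = NA_integer_, true_maternal = NA_integer_,
    etiology = "baseline",
    # data-quality covariates (independent noise by default: no real effect)
    mean_rd_child = stats::rnorm(n, 35, 2),
    mean_rd_father = stats::rnorm(n, 35, 2),
    mean_rd_mother = stats::rnorm(n, 35, 2),
    prop_aligned_child = pmin(stats::rnorm(n, 0.97, 0.01), 1),
    prop_aligned_father = pmin(stats::rnorm(n, 0.97, 0.01), 1),
    prop_aligned_mother = pmin(stats::rnorm(n, 0.97, 0.01), 1),
    snvs_child = round(stats::rnorm(n, 4.6e6, 5e4)),
    snvs_father = round(stats::rnorm(n, 4.6e6, 5e4)),
    snvs_mother = round(stats::rnorm(n, 4.6e6, 5e4)),
    median_vaf = stats::rnorm(n, 0.5, 0.01),
    median_bf = stats::rnorm(n, 40, 5),
    stringsAsFactors = FALSE
  )

  if (include_dnms) {
    dnms <- .gen_dnm_rows(config, trio_id, trios$child_id, counts, "baseline")
    # per-DNM parent-of-origin truth: Bernoulli with the trio's fraction
    dnms$true_parent <- ifelse(
      stats::runif(nrow(dnms)) < rep(pfrac, counts), "father", "mother"
    )
    dnms$dnm_id <- sprintf("d%07d", seq_len(nrow(dnms)))
    pat <- tapply(dnms$true_parent == "father", dnms$trio_id, sum)
    trios$true_paternal <- as.integer(pat[trios$trio_id])
    trios$true_paternal[is.na(trios$true_paternal)] <- 0L
    trios$true_maternal <- trios$dn_snv_count - trios$true_paternal
    hethom <- .gen_hethom(trio_id)
  } else {
    # count-level truth only
    trios$true_paternal <- stats::rbinom(n, counts, pfrac)
    trios$true_maternal <- counts - trios$true_paternal
    dnms <- NULL
    hethom <- NULL
  }

  cohort <- list(trios = trios, dnms = dnms, hethom = hethom, config = config)
  class(cohort) <- "trio_cohort"
  cohort
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(
    "trio_cohort:", nrow(x$trios), "trios,",
    if (is.null(x$dnms)) "counts only" else paste(nrow(x$dnms), "DNM calls"),
    "\n"
  )
  invisible(x)
}

.next_dnm_id <- function(cohort) {
  if (is.null(cohort$dnms) || nrow(cohort$dnms) == 0) {
    return(1L)
  }
  max(as.integer(sub("^d", "", cohort$dnms$dnm_id))) + 1L
}

#' Inject hypermutated individuals into a simulated cohort
#'
#' Adds excess DNMs to selected trios according to an etiology:
#' \describe{
#'   \item{repair_defect}{The trio's paternal DNM count is multiplied by
#'     \code{fold_or_extra} (a fold >= 1); the excess calls carry paternal
#'     truth labels and the etiology's signature.}
#'   \item{chemo_signature}{\code{fold_or_extra} extra DNMs drawn from the
#'     named signature are added with paternal truth labels.}
#'   \item{postzygotic}{\code{fold_or_extra} extra DNMs are added with
#'     ~50/50 parental truth and true VAF drawn below 0.5 (mosaic-like).}
#' }
#'
#' @param cohort A \code{trio_cohort} with DNM calls.
#' @param specs A list of specs, each a list with \code{trio} (index or id),
#'   \code{etiology}, \code{fold_or_extra}, and optionally \code{signature}
#'   (a catalogue row name overriding the etiology's configured mixture).
#' @return The modified cohort with updated counts and truth labels.
#' @export
inject_hypermutators <- function(cohort, specs) {
  stopifnot(inherits(cohort, "trio_cohort"), !is.null(cohort$dnms))
  config <- cohort$config
  for (spec in specs) {
    idx <- if (is.character(spec$trio)) {
      match(spec$trio, cohort$trios$trio_id)
    } else {
      spec$trio
    }
    if (is.na(idx) || idx < 1 || idx > nrow(cohort$trios)) {
      stop("unknown trio in hypermutator spec")
    }
    et <- match.arg(
      spec$etiology,
      c("repair_defect", "chemo_signature", "postzygotic")
    )
    if (!is.null(spec$signature)) {
      if (!spec$signature %in% rownames(config$catalogue)) {
        stop("unknown signature id: ", spec$signature)
      }
      config$signature_mix[[et]] <- stats::setNames(1, spec$signature)
    }
    tr <- cohort$trios[idx, ]
    if (et == "repair_defect") {
      if (spec$fold_or_extra < 1) stop("fold must be >= 1")
      extra <- round(tr$true_paternal * (spec$fold_or_extra - 1))
      parent <- "father"
      vaf <- 0.5
    } else if (et == "chemo_signature") {
      extra <- round(spec$fold_or_extra)
      parent <- "father"
      vaf <- 0.5
    } else {
      extra <- round(spec$fold_or_extra)
      parent <- NULL # drawn 50/50 below
      vaf <- NULL
    }
    if (extra <= 0) next
    if (et == "postzygotic") {
      parent <- sample(c("father", "mother"), extra, replace = TRUE)
      vaf <- stats::runif(extra, 0.10, 0.35)
    }
    new <- .gen_dnm_rows(
      config, tr$trio_id, tr$child_id, extra, et,
      true_parent = parent, true_vaf = vaf
    )
    new$dnm_id <- sprintf("d%07d", .next_dnm_id(cohort) + seq_len(extra) - 1L)
    cohort$dnms <- rbind(cohort$dnms, new)
    cohort$trios$dn_snv_count[idx] <- tr$dn_snv_count + extra
    npat <- sum(new$true_parent == "father")
    cohort$trios$true_paternal[idx] <- tr$true_paternal + npat
    cohort$trios$true_maternal[idx] <- tr$true_maternal + (extra - npat)
    cohort$trios$etiology[idx] <- et
  }
  cohort
}

#' Inject a loss-of-transmitted-allele artifact
#'
#' Emulates the known false-positive mode in which a parental somatic
#' deletion in blood produces a burst of apparent DNM calls clustered in one
#' genomic region of a single chromosome, together with a regional loss of
#' heterozygosity in that parent's genotype calls. The injected calls carry
#' truth etiology \code{"lota_artifact"} (they are not real DNMs) and the
#' parent's het/hom site counts in the region are depressed.
#'
#' @param cohort A \code{trio_cohort} with DNM calls.
#' @param trio Trio index or id.
#' @param region List with \code{chrom}, \code{start}, \code{end} (1-based).
#' @param n_calls Number of pseudo-DNM calls to add.
#' @param parent Which parent carries the somatic event.
#' @return The modified cohort.
#' @export
inject_lota_artifact <- function(cohort, trio, region, n_calls,
                                 parent = "father") {
  stopifnot(inherits(cohort, "trio_cohort"), !is.null(cohort$dnms))
  genome <- sim_genome()
  if (!region$chrom %in% names(genome)) {
    stop("region chromosome not in simulated genome")
  }
  region$end <- min(region$end, genome[[region$chrom]])
  if (region$start > region$end) stop("empty region")
  idx <- if (is.character(trio)) match(trio, cohort$trios$trio_id) else trio
  if (is.na(idx)) stop("unknown trio")
  if (n_calls == 0) {
    return(cohort)
  }
  tr <- cohort$trios[idx, ]
  new <- .gen_dnm_rows(
    cohort$config, tr$trio_id, tr$child_id, n_calls,
    "lota_artifact",
    true_parent = parent, region = region
  )
  new$dnm_id <- sprintf("d%07d", .next_dnm_id(cohort) + seq_len(n_calls) - 1L)
  cohort$dnms <- rbind(cohort$dnms, new)
  cohort$trios$dn_snv_count[idx] <- tr$dn_snv_count + n_calls
  cohort$trios$etiology[idx] <- "lota_artifact"
  # depress the parent's regional heterozygosity
  if (!is.null(cohort$hethom)) {
    hh <- cohort$hethom
    sel <- hh$trio_id == tr$trio_id & hh$parent == parent &
      hh$chrom == region$chrom & hh$end > region$start - 1 &
      hh$start < region$end
    hh$n_het[sel] <- stats::rbinom(sum(sel), hh$n_het[sel], 0.05)
    cohort$hethom <- hh
  }
  cohort
}

#' Write a simulated cohort to plain-text tables
#'
#' Emits \code{dnms.tsv} (the DNM call table in the package's tabular
#' dialect), \code{pedigree.tsv} (PED-like columns plus parental ages and QC
#' metrics), \code{truth.tsv} (per-DNM truth labels keyed by \code{dnm_id}),
#' \code{hethom.tsv} (parental het/hom window counts) and
#' \code{config.json}. \code{\link{read_cohort}} reverses the operation.
#'
#' @param cohort A \code{trio_cohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trio_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE, na = "NA"
    )
  }
  truth_cols <- c("dnm_id", "true_parent", "true_signature", "true_vaf",
                  "etiology")
  dnms <- cohort$dnms
  if (is.null(dnms)) dnms <- .empty_dnm_table()
  if (!"dnm_id" %in% names(dnms)) dnms$dnm_id <- character(0)
  wt(dnms[, setdiff(names(dnms), setdiff(truth_cols, "dnm_id"))], "dnms.tsv")
  wt(dnms[, intersect(truth_cols, names(dnms)), drop = FALSE], "truth.tsv")
  wt(cohort$trios, "pedigree.tsv")
  if (!is.null(cohort$hethom)) wt(cohort$hethom, "hethom.tsv")
  cfg <- cohort$config
  cfg$catalogue <- NULL # catalogue stored separately, row-major
  jsonlite::write_json(
    list(
      config = unclass(cfg),
      catalogue = list(
        ids = rownames(cohort$config$catalogue),
        values = cohort$config$catalogue
      )
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#' @param dir Directory containing the cohort tables.
#' @return A \code{trio_cohort}.
#' @export
read_cohort <- function(dir) {
  rd <- function(f, ...) {
    utils::read.delim(file.path(dir, f),
      stringsAsFactors = FALSE,
      na.strings = "NA", ...
    )
  }
  js <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- js$config
  cfg$signature_mix <- lapply(cfg$signature_mix, unlist)
  cat <- js$catalogue$values
  rownames(cat) <- js$catalogue$ids
  colnames(cat) <- sbs96_channels()
  cfg$catalogue <- cat
  class(cfg) <- "sim_config"
  dnms <- rd("dnms.tsv", colClasses = c(chrom = "character"))
  truth <- rd("truth.tsv")
  if (nrow(dnms) > 0) {
    dnms <- merge(dnms, truth, by = "dnm_id", sort = FALSE)
    dnms <- dnms[order(dnms$dnm_id), c(names(.empty_dnm_table()), "dnm_id")]
    rownames(dnms) <- NULL
  } else {
    dnms <- .empty_dnm_table()
    dnms$dnm_id <- character(0)
  }
  hethom <- if (file.exists(file.path(dir, "hethom.tsv"))) {
    rd("hethom.tsv")
  } else {
    NULL
  }
  cohort <- list(
    trios = rd("pedigree.tsv"), dnms = dnms, hethom = hethom,
    config = cfg
  )
  class(cohort) <- "trio_cohort"
  cohort
}
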