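# 96-channel mutational spectra: construction, NNLS refitting against a
# reference catalogue, and small-scale de novo NMF extraction.

#' Build a 96-channel mutational spectrum
#'
#' Counts SNVs into the 96 pyrimidine-strand trinucleotide channels.
#' Purine-reference context labels are folded by reverse complement; SNV
#' counts are conserved. Calls with an ambiguous context (N base or
#' malformed label) are excluded and tallied.
#'
#' @param calls Data frame with \code{context96} (and optionally
#'   \code{vartype}; non-SNVs are ignored), or a character vector of
#'   context labels.
#' @return Object of class \code{spectrum96}: named integer vector of
#'   length 96 with attributes \code{total} (contributing SNVs) and
#'   \code{n_excluded}.
#' @export
build_spectrum <- function(calls) {
  ctx <- if (is.character(calls)) {
    calls
  } else {
    cc <- calls$context96
    if ("vartype" %in% names(calls)) cc <- cc[calls$vartype == "SNV"]
    cc
  }
  folded <- fold_context96(ctx)
  excluded <- sum(is.na(folded))
  folded <- folded[!is.na(folded)]
  ch <- sbs96_channels()
  counts <- table(factor(folded, levels = ch))
  out <- stats::setNames(as.integer(counts), ch)
  attr(out, "total") <- sum(out)
  attr(out, "n_excluded") <- excluded
  class(out) <- "spectrum96"
  out
}

#' Collapse a 96-channel spectrum to the six substitution classes
#' @param spectrum A \code{spectrum96} or named 96-vector.
#' @return Named vector of six class counts.
#' @export
collapse_spectrum <- function(spectrum) {
  cls <- substr(sbs96_channels(), 3, 5)
  tapply(as.numeric(spectrum), cls, sum)[sbs6_classes()]
}

#' Refit a spectrum onto a signature catalogue by NNLS
#'
#' Nonnegative least-squares decomposition of an observed 96-channel
#' spectrum onto catalogue signatures. Signatures whose fitted exposure
#' falls below \code{sparsity} (as a proportion of the total) are pruned
#' and the remainder refit, a standard guard against spreading counts over
#' irrelevant signatures.
#'
#' @param spectrum A \code{spectrum96} or numeric 96-vector of counts.
#' @param catalogue k x 96 matrix with unit row sums.
#' @param sparsity Minimum exposure proportion to retain a signature.
#' @return List with \code{exposures} (counts scale), \code{proportions},
#'   \code{residual_norm} (Euclidean), \code{reconstruction} and
#'   \code{relative_residual} (residual norm / spectrum norm).
#' @export
fit_exposures_nnls <- function(spectrum, catalogue, sparsity = 0.01) {
  .check_catalogue(catalogue)
  y <- as.numeric(spectrum)
  if (length(y) != 96) stop("spectrum must have 96 channels")
  if (sum(y) == 0) stop("empty spectrum")
  A <- t(catalogue) # 96 x k
  sol <- pracma::lsqnonneg(A, y)
  x <- sol$x
  names(x) <- rownames(catalogue)
  tot <- sum(x)
  if (tot > 0 && sparsity > 0) {
    keep <- x / tot >= sparsity
    if (any(!keep) && any(keep)) {
      x2 <- rep(0, length(x))
      names(x2) <- names(x)
      sol2 <- pracma::lsqnonneg(A[, keep, drop = FALSE], y)
      x2[keep] <- sol2$x
      x <- x2
    }
  }
  recon <- drop(A %*% x)
  rn <- sqrt(sum((y - recon)^2))
  list(
    exposures = x,
    proportions = if (sum(x) > 0) x / sum(x) else x,
    residual_norm = rn,
    relative_residual = rn / sqrt(sum(y^2)),
    reconstruction = recon
  )
}

# one NMF run: multiplicative updates for the Frobenius objective;
# the objective is non-increasing per update by construction
.nmf_once <- function(V, k, maxit, tol) {
  n <- nrow(V)
  m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- 1e-12
  obj <- Inf
  for (it in seq_len(maxit)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    if (it %% 10 == 0 || it == maxit) {
      newobj <- sum((V - W %*% H)^2)
      if (is.finite(obj) && (obj - newobj) < tol * (obj + eps)) {
        obj <- newobj
        break
      }
      obj <- newobj
    }
  }
  # normalize signatures (rows of H) to unit sum, push scale into W
  s <- rowSums(H)
  s[s == 0] <- 1
  list(W = W * rep(s, each = n), H = H / s, objective = obj)
}

#' Match two signature sets by best one-to-one assignment
#'
#' Finds the permutation of rows of \code{B} maximizing the mean cosine
#' similarity to the rows of \code{A} (exhaustive over permutations; meant
#' for small k).
#'
#' @param A,B Matrices with the same number of rows (signatures x channels).
#' @return List with \code{order} (rows of B matched to rows of A),
#'   \code{cosines}, \code{mean_cosine}.
#' @export
match_signatures <- function(A, B) {
  k <- nrow(A)
  stopifnot(nrow(B) == k, k <= 8)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      sim[i, j] <- cosine_similarity(A[i, ], B[j, ])
    }
  }
  perms <- .permutations(k)
  scores <- apply(perms, 1, function(p) mean(sim[cbind(seq_len(k), p)]))
  best <- perms[which.max(scores), ]
  list(
    order = best,
    cosines = sim[cbind(seq_len(k), best)],
    mean_cosine = max(scores)
  )
}

.permutations <- function(k) {
  if (k == 1) {
    return(matrix(1))
  }
  sub <- .permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Extract de novo signatures by NMF with restarts
#'
#' Small-scale nonnegative matrix factorization (multiplicative updates,
#' Frobenius objective) of a samples x 96 count matrix, with multiple
#' random restarts per k. For each k the best-objective factorization is
#' kept and a stability score is reported: the mean matched cosine
#' similarity of each restart's signatures to the best run's. The choice
#' of k is left to the caller, guided by the stability/error report.
#'
#' @param spectra Samples x 96 matrix of counts.
#' @param k_range Integer vector of ranks to scan.
#' @param restarts Random restarts per k.
#' @param seed Seed; the same seed reproduces the factorization exactly.
#' @param maxit,tol Update iteration controls.
#' @return List of class \code{nmf_scan}: per-k list with
#'   \code{signatures} (k x 96, unit row sums), \code{exposures}
#'   (samples x k), \code{objective}, \code{stability}; plus a
#'   \code{report} data frame.
#' @export
extract_signatures_nmf <- function(spectra, k_range = 1:5, restarts = 20,
                                   seed = 1, maxit = 2000, tol = 1e-9) {
  V <- as.matrix(spectra)
  if (any(V < 0)) stop("spectra must be nonnegative")
  if (max(k_range) > nrow(V)) stop("k exceeds the number of samples")
  set.seed(seed)
  fits <- list()
  report <- NULL
  for (k in k_range) {
    runs <- lapply(seq_len(restarts), function(r) .nmf_once(V, k, maxit, tol))
    objs <- vapply(runs, `[[`, numeric(1), "objective")
    best <- runs[[which.min(objs)]]
    stab <- if (restarts > 1 && k <= 8) {
      mean(vapply(runs, function(r) {
        match_signatures(best$H, r$H)$mean_cosine
      }, numeric(1)))
    } else {
      NA_real_
    }
    rownames(best$H) <- paste0("denovo", seq_len(k))
    colnames(best$H) <- colnames(V)
    fits[[as.character(k)]] <- list(
      signatures = best$H, exposures = best$W,
      objective = min(objs), stability = stab
    )
    report <- rbind(report, data.frame(
      k = k, objective = min(objs),
      rel_error = sqrt(min(objs)) / sqrt(sum(V^2)), stability = stab
    ))
  }
  out <- list(fits = fits, report = report)
  class(out) <- "nmf_scan"
  out
}

#' Compare paternally and maternally phased spectra by substitution class
#'
#' Collapses each phased spectrum to the six substitution classes and tests
#' each class count in one parent's set against the proportion observed in
#' the other with a two-sided binomial test. Since the choice of null side
#' is arbitrary, the test is run in both directions and the two p-values
#' averaged (symmetric construction); both one-sided-null p-values are also
#' returned.
#'
#' @param paternal,maternal \code{spectrum96} objects or 96-vectors.
#' @return Data frame per class: proportions in each set, p-values.
#' @export
compare_phased_spectra <- function(paternal, maternal) {
  cp <- collapse_spectrum(paternal)
  cm <- collapse_spectrum(maternal)
  np <- sum(cp)
  nm <- sum(cm)
  if (np == 0 || nm == 0) stop("both spectra must be non-empty")
  out <- data.frame(
    class = sbs6_classes(),
    paternal_count = as.integer(cp), maternal_count = as.integer(cm),
    paternal_prop = as.numeric(cp) / np,
    maternal_prop = as.numeric(cm) / nm,
    p_vs_paternal = NA_real_, p_vs_maternal = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(6)) {
    if (cp[i] == 0 && cm[i] == 0) {
      out$p_vs_paternal[i] <- out$p_vs_maternal[i] <- 1
      next
    }
    # maternal count tested against the paternal proportion, and vice versa
    out$p_vs_paternal[i] <- stats::binom.test(
      out$maternal_count[i], nm,
      p = out$paternal_prop[i]
    )$p.value
    out$p_vs_maternal[i] <- stats::binom.test(
      out$paternal_count[i], np,
      p = out$maternal_prop[i]
    )$p.value
  }
  out$p <- (out$p_vs_paternal + out$p_vs_maternal) / 2
  out
}
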