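#' The 96 single-base-substitution channels
#'
#' Returns the canonical ordering of the 96 pyrimidine-strand trinucleotide
#' substitution channels used throughout the package: the six substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G in alphabetical order, each crossed
#' with the 16 flanking contexts in alphabetical order (A, C, G, T on either
#' side). Channel labels have the form \code{"A[C>T]G"}. This layout is the
#' conventional one used by published signature catalogues, so user-supplied
#' catalogues in that layout can be used directly.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (cl in classes) {
    for (b5 in bases) {
      for (b3 in bases) {
        out <- c(out, paste0(b5, "[", cl, "]", b3))
      }
    }
  }
  out
}

#' The six collapsed substitution classes
#' @return Character vector \code{c("C>A","C>G","C>T","T>A","T>C","T>G")}.
#' @export
sbs6_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.revcomp_base <- function(x) {
  m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(m[x])
}

#' Fold a substitution-context label onto the pyrimidine strand
#'
#' Labels whose reference (central) base is a purine (A or G) are
#' reverse-complemented so that every mutation is expressed with a C or T
#' reference, the convention under which signature catalogues are defined.
#' Pyrimidine-reference labels are returned unchanged. Labels containing an
#' ambiguous base (N) yield \code{NA}.
#'
#' @param context Character vector of labels of the form \code{"X[R>A]Y"}.
#' @return Character vector of pyrimidine-strand labels (NA where ambiguous).
#' @export
fold_context96 <- function(context) {
  stopifnot(is.character(context))
  up <- substr(context, 1, 1)
  ref <- substr(context, 3, 3)
  alt <- substr(context, 5, 5)
  dn <- substr(context, 7, 7)
  bad <- !grepl("^[ACGTN]\\[[ACGTN]>[ACGTN]\\][ACGTN]$", context)
  hasN <- up == "N" | ref == "N" | alt == "N" | dn == "N"
  purine <- ref %in% c("A", "G")
  out <- context
  idx <- purine & !bad & !hasN
  if (any(idx)) {
    out[idx] <- paste0(
      .revcomp_base(dn[idx]), "[",
      .revcomp_base(ref[idx]), ">", .revcomp_base(alt[idx]), "]",
      .revcomp_base(up[idx])
    )
  }
  out[bad | hasN] <- NA_character_
  out
}

#' Cosine similarity between two nonnegative profiles
#'
#' @param a,b Numeric vectors of equal length, elementwise nonnegative.
#' @return Cosine similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("profiles must be nonnegative")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Synthetic reference signature catalogue
#'
#' Builds a small catalogue of 96-channel mutational signatures with the
#' qualitative shapes relevant to germline mutagenesis studies. These are
#' synthetic stand-ins constructed in code (no published catalogue is
#' bundled); any user-supplied catalogue in the standard 96-row layout can
#' be used instead wherever a catalogue argument is accepted.
#'
#' The five profiles are:
#' \describe{
#'   \item{sig_clock}{CpG-deamination clock-like: mass concentrated on
#'     \code{N[C>T]G} channels, mimicking spontaneous 5mC deamination.}
#'   \item{sig_flat}{A near-flat background over all 96 channels.}
#'   \item{sig_platinum}{C>A/C>T rich with strong context preference,
#'     emulating a platinum-chemotherapy-like profile.}
#'   \item{sig_alkyl}{T>A rich, emulating an alkylating-agent-like profile.}
#'   \item{sig_tc}{T>C dominated, emulating a repair-defect profile.}
#' }
#'
#' @return Matrix with signatures in rows (rownames are signature ids),
#'   96 columns named by channel; each row sums to 1.
#' @export
signature_catalogue <- function() {
  ch <- sbs96_channels()
  cls <- substr(ch, 3, 5)
  up <- substr(ch, 1, 1)
  dn <- substr(ch, 7, 7)

  mk <- function(w) w / sum(w)

  clock <- rep(0.05, 96)
  clock[cls == "C>T" & dn == "G"] <- 12
  clock[cls == "C>T" & dn != "G"] <- 1

  flat <- rep(1, 96) + 0.15 * sin(seq_len(96) / 7)

  platinum <- rep(0.1, 96)
  platinum[cls == "C>A"] <- 4
  platinum[cls == "C>A" & up == "C"] <- 9
  platinum[cls == "C>T" & up == "C"] <- 5

  alkyl <- rep(0.1, 96)
  alkyl[cls == "T>A"] <- 6
  alkyl[cls == "T>A" & up == "C"] <- 12
  alkyl[cls == "C>T" & dn == "T"] <- 2

  tcsig <- rep(0.05, 96)
  tcsig[cls == "T>C"] <- 8
  tcsig[cls == "T>C" & up == "A"] <- 16

  out <- rbind(
    sig_clock = mk(clock),
    sig_flat = mk(flat),
    sig_platinum = mk(platinum),
    sig_alkyl = mk(alkyl),
    sig_tc = mk(tcsig)
  )
  colnames(out) <- ch
  out
}

# validate a catalogue: k x 96 with unit row sums
.check_catalogue <- function(catalogue) {
  if (is.null(dim(catalogue)) || ncol(catalogue) != 96) {
    stop("catalogue must be a k x 96 matrix")
  }
  if (any(catalogue < 0)) stop("catalogue entries must be nonnegative")
  if (any(abs(rowSums(catalogue) - 1) > 1e-6)) {
    stop("catalogue rows must each sum to 1")
  }
  invisible(TRUE)
}
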