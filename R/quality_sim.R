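# Quality channel: draws per-base quality characters from uniform or Gaussian
# distributions over arbitrary (possibly sparse) subsets of the printable
# ASCII range 33..126, with rank-even quantization and the rule that N bases
# carry the lowest configured score.

#' Quality-score alphabet and distribution
#'
#' Quality characters are drawn from an ordered set of ASCII codes restricted
#' to the printable range 33..126. Sparse sets (e.g. codes 33-35 plus 100)
#' are allowed. The Gaussian distribution is parameterized by a mean and
#' standard deviation expressed in raw ASCII-code units (no Phred offset is
#' subtracted).
#'
#' @param codes Integer vector of allowed ASCII codes (deduplicated, sorted).
#' @param distribution `"uniform"` or `"gaussian"`.
#' @param mean,sd Gaussian parameters in ASCII-code units (`sd > 0`).
#' @return An object of class `quality_alphabet`.
#' @export
quality_alphabet <- function(codes = 33:126,
                             distribution = c("uniform", "gaussian"),
                             mean = 70, sd = 5) {
  distribution <- match.arg(distribution)
  codes <- sort(unique(as.integer(codes)))
  if (length(codes) == 0L) stop("quality alphabet must contain at least one code")
  if (any(codes < 33L) || any(codes > 126L))
    stop("quality ASCII codes must lie in [33, 126]")
  if (distribution == "gaussian" && (!is.numeric(sd) || sd <= 0))
    stop("gaussian quality distribution requires sd > 0")
  structure(list(codes = codes, distribution = distribution,
                 mean = mean, sd = sd),
            class = "quality_alphabet")
}

#' Parse a sparse ASCII-range specification
#'
#' Expands a comma-separated list of codes and hyphen ranges (en-dashes are
#' accepted too) into a validated, sorted, deduplicated code set, e.g.
#' `"33,34,35,40-45,100,102,110-120"` yields 22 codes.
#'
#' @param spec Specification string.
#' @return Integer vector of ASCII codes in `[33, 126]`.
#' @export
parse_ascii_ranges <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub("–|—", "-", spec)
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty ASCII range specification")
  codes <- unlist(lapply(tokens, function(tok) {
    if (grepl("^[0-9]+$", tok)) return(as.integer(tok))
    m <- regmatches(tok, regexec("^([0-9]+)-([0-9]+)$", tok))[[1]]
    if (length(m) == 0L) stop("malformed ASCII range token: '", tok, "'")
    lo <- as.integer(m[2]); hi <- as.integer(m[3])
    if (lo > hi) stop("descending ASCII range: '", tok, "'")
    lo:hi
  }))
  if (any(codes < 33L) || any(codes > 126L))
    stop("ASCII codes must lie in [33, 126]")
  sort(unique(codes))
}

# split a single string of quality characters into per-read strings
split_lengths <- function(s, lengths) {
  ends <- cumsum(lengths)
  substring(s, c(1L, ends[-length(ends)] + 1L), ends)
}

#' Sample quality strings with equal symbol probability
#'
#' Each character is drawn i.i.d. uniformly over the alphabet's codes.
#'
#' @param lengths Integer vector of per-read quality-string lengths.
#' @param alphabet A [quality_alphabet()].
#' @return Character vector of quality strings, one per length.
#' @export
sample_qualities_uniform <- function(lengths, alphabet = quality_alphabet()) {
  stopifnot(inherits(alphabet, "quality_alphabet"), all(lengths >= 1))
  total <- sum(lengths)
  codes <- alphabet$codes[sample.int(length(alphabet$codes), total, replace = TRUE)]
  split_lengths(intToUtf8(codes), lengths)
}

#' Sample quality strings from a Gaussian over the alphabet
#'
#' Each position draws a normal variate (mean/sd in ASCII-code units), rounds
#' it to the nearest integer and maps it to the nearest code in the alphabet,
#' with ties broken toward the lower code. Out-of-range draws clamp to the
#' nearest extreme code, so the output always stays inside the alphabet.
#'
#' @param lengths Integer vector of per-read quality-string lengths.
#' @param alphabet A [quality_alphabet()].
#' @param mean,sd Override the alphabet's Gaussian parameters.
#' @return Character vector of quality strings.
#' @export
sample_qualities_gaussian <- function(lengths, alphabet = quality_alphabet(),
                                      mean = alphabet$mean, sd = alphabet$sd) {
  stopifnot(inherits(alphabet, "quality_alphabet"), all(lengths >= 1), sd > 0)
  total <- sum(lengths)
  draws <- round(stats::rnorm(total, mean, sd))
  codes <- alphabet$codes
  if (length(codes) == 1L) {
    out <- rep(codes, total)
  } else {
    mids <- (codes[-length(codes)] + codes[-1]) / 2
    # left-open intervals send a draw landing exactly on a midpoint to the
    # lower code (fixed tie-break, reproducible streams)
    out <- codes[findInterval(draws, mids, left.open = TRUE) + 1L]
  }
  split_lengths(intToUtf8(out), lengths)
}

#' Sample quality strings using the alphabet's configured distribution
#'
#' @inheritParams sample_qualities_uniform
#' @return Character vector of quality strings.
#' @export
sample_qualities <- function(lengths, alphabet = quality_alphabet()) {
  if (alphabet$distribution == "uniform")
    sample_qualities_uniform(lengths, alphabet)
  else
    sample_qualities_gaussian(lengths, alphabet)
}

#' Force the lowest quality score at N positions
#'
#' Positions where the base is `N` carry the alphabet's lowest code; all
#' other positions are unchanged. Base and quality strings must have equal
#' lengths element-wise.
#'
#' @param quals Character vector of quality strings.
#' @param seq Character vector of base strings (same lengths as `quals`).
#' @param alphabet A [quality_alphabet()]; its first code is the lowest score.
#' @return Character vector of masked quality strings.
#' @examples
#' mask_n_positions("IIII", "ACNT", quality_alphabet(33:74))  # "II!I"
#' @export
mask_n_positions <- function(quals, seq, alphabet = quality_alphabet()) {
  stopifnot(length(quals) == length(seq))
  if (any(nchar(quals) != nchar(seq)))
    stop("quality and base strings must have equal lengths")
  lowest <- intToUtf8(alphabet$codes[1])
  mapply(function(q, s) {
    n_at <- gregexpr("N", s, fixed = TRUE)[[1]]
    if (n_at[1] == -1L) return(q)
    qc <- strsplit(q, "")[[1]]
    qc[n_at] <- lowest
    paste(qc, collapse = "")
  }, quals, seq, USE.NAMES = FALSE)
}

#' Quantize a quality alphabet to fewer levels
#'
#' Selects `n_levels` codes evenly spaced by rank from the alphabet (always
#' keeping the extremes for `n_levels >= 2`), so quantization composes with
#' sparse alphabets. Sampling through the reduced alphabet lowers the symbol
#' entropy of the quality stream and hence its post-compression size.
#'
#' @param alphabet A [quality_alphabet()].
#' @param n_levels Number of retained codes, `1 <= n_levels <= length(codes)`.
#' @return A new `quality_alphabet` with the reduced code set.
#' @export
quantize_alphabet <- function(alphabet, n_levels) {
  stopifnot(inherits(alphabet, "quality_alphabet"))
  m <- length(alphabet$codes)
  if (n_levels < 1 || n_levels > m)
    stop("n_levels must lie in [1, ", m, "]")
  idx <- unique(round(seq(1, m, length.out = n_levels)))
  quality_alphabet(alphabet$codes[idx], alphabet$distribution,
                   alphabet$mean, alphabet$sd)
}
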