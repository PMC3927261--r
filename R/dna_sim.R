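# DNA channel: i.i.d. composition sampling over {A,C,G,T,N}, optional planting
# of exact / approximate / reverse-complement repeats copied from the
# already-generated prefix, and SOLiD color-space conversion.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Nucleotide composition profile
#'
#' Per-symbol probabilities for the 5-symbol alphabet A, C, G, T, N used by
#' the composition-only sampler and for the novel segments between planted
#' repeats. Probabilities must sum to 1 (tolerance 1e-9).
#'
#' @param p_A,p_C,p_G,p_T,p_N Symbol probabilities.
#' @return An object of class `composition_profile` (named probability vector).
#' @export
composition_profile <- function(p_A = 0.25, p_C = 0.25, p_G = 0.25,
                                p_T = 0.25, p_N = 0) {
  p <- c(A = p_A, C = p_C, G = p_G, T = p_T, N = p_N)
  if (any(p < 0) || any(p > 1))
    stop("composition probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("composition probabilities must sum to 1 (got ", sum(p), ")")
  structure(p, class = "composition_profile")
}

#' Repeat model parameters
#'
#' Controls the planted-repeat extension of the DNA sampler: how many copy
#' events occur, their size range, the per-base substitution rate applied to
#' each copy (0 = exact repeats), and the probability that a copy is the
#' reverse complement of its source.
#'
#' @param n_repeats Number of copy events (0 recovers composition-only sampling).
#' @param min_size,max_size Repeat size bounds (sizes drawn uniformly).
#' @param mutation_rate Per-base substitution probability in `[0, 1]`.
#' @param p_reverse_complement Probability a copy is reverse complemented.
#' @return An object of class `repeat_model`.
#' @export
repeat_model <- function(n_repeats = 0L, min_size = 1L, max_size = 3000L,
                         mutation_rate = 0, p_reverse_complement = 0) {
  n_repeats <- as.integer(n_repeats)
  stopifnot(n_repeats >= 0, min_size >= 1, min_size <= max_size,
            mutation_rate >= 0, mutation_rate <= 1,
            p_reverse_complement >= 0, p_reverse_complement <= 1)
  structure(list(n_repeats = n_repeats, min_size = as.integer(min_size),
                 max_size = as.integer(max_size), mutation_rate = mutation_rate,
                 p_reverse_complement = p_reverse_complement),
            class = "repeat_model")
}

new_dna_stream <- function(chars, annotations) {
  structure(list(seq = paste(chars, collapse = ""),
                 annotations = annotations),
            class = "dna_stream")
}

empty_annotations <- function() {
  data.frame(source_start = integer(0), dest_start = integer(0),
             length = integer(0), is_reverse_complement = logical(0))
}

#' @export
print.dna_stream <- function(x, ...) {
  cat("DNA stream:", nchar(x$seq), "bases,", nrow(x$annotations),
      "planted repeat(s)\n")
  invisible(x)
}

#' Sample an i.i.d. DNA stream from a composition profile
#'
#' Composition-only simulation mode: every symbol is drawn independently with
#' the configured probabilities; no repeat structure is planted.
#'
#' @param length Number of symbols to generate.
#' @param comp A [composition_profile()].
#' @return A `dna_stream` with empty `annotations`.
#' @export
sample_sequence <- function(length, comp = composition_profile()) {
  stopifnot(length >= 1)
  if (!inherits(comp, "composition_profile")) comp <- do.call(composition_profile, as.list(comp))
  new_dna_stream(sample(DNA_ALPHABET, length, replace = TRUE, prob = comp),
                 empty_annotations())
}

#' Reverse complement of a DNA string
#'
#' Complements A<->T, C<->G (N maps to N) and reverses the order. Applying it
#' twice returns the input.
#'
#' @param seq Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequence contains symbols outside {A,C,G,T,N}")
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# per-character mutation on a character vector; substitutes to a uniformly
# chosen *different* base from {A,C,G,T} so the expected mismatch fraction
# equals `rate` exactly (N positions go to any of the four bases)
mutate_chars <- function(chars, rate) {
  if (rate == 0 || length(chars) == 0L) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) == 0L) return(chars)
  cur <- match(chars[hit], DNA_ALPHABET[1:4])   # NA for N
  shift <- sample.int(3L, length(hit), replace = TRUE)
  new <- DNA_ALPHABET[((cur - 1L + shift) %% 4L) + 1L]
  is_n <- is.na(cur)
  if (any(is_n)) new[is_n] <- sample(DNA_ALPHABET[1:4], sum(is_n), replace = TRUE)
  chars[hit] <- new
  chars
}

#' Apply per-base substitution mutations
#'
#' Each position is independently substituted with probability `rate` to a
#' uniformly chosen different base from `{A,C,G,T}`; length is preserved. The
#' expected mismatch fraction therefore equals `rate` exactly.
#'
#' @param seq A DNA string.
#' @param rate Substitution probability in `[0, 1]`.
#' @return The mutated DNA string.
#' @export
mutate <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1, length(seq) == 1L)
  paste(mutate_chars(strsplit(seq, "")[[1]], rate), collapse = "")
}

#' Generate a DNA stream with planted repeats
#'
#' Extends composition sampling with `n_repeats` copy events: generation runs
#' left to right, and at uniformly spread trigger points the stream is
#' extended by a copy of a window drawn uniformly from the already-generated
#' prefix. Each copy is reverse complemented with probability
#' `p_reverse_complement` and then passed through the substitution process at
#' `mutation_rate`. Sampled sizes are truncated to the available prefix and
#' to the remaining stream capacity (never discarded), so exactly `n_repeats`
#' events occur. Every event is recorded in `annotations` for verification.
#'
#' @param length Total stream length (must be >= 2 when repeats are requested).
#' @param comp A [composition_profile()] for the novel segments.
#' @param model A [repeat_model()].
#' @return A `dna_stream`; `annotations` has one row per copy event with
#'   columns `source_start`, `dest_start`, `length`, `is_reverse_complement`.
#' @export
plant_repeats <- function(length, comp = composition_profile(),
                          model = repeat_model()) {
  stopifnot(inherits(model, "repeat_model"), length >= 1)
  if (model$n_repeats == 0L) return(sample_sequence(length, comp))
  if (length < 2)
    stop("stream too short to host a repeat: need at least 1 novel symbol before the first copy")
  if (!inherits(comp, "composition_profile")) comp <- do.call(composition_profile, as.list(comp))
  R <- model$n_repeats
  triggers <- sort(sample(2:length, R, replace = TRUE))
  sizes <- sample.int(model$max_size - model$min_size + 1L, R, replace = TRUE) +
    model$min_size - 1L
  is_rc <- stats::runif(R) < model$p_reverse_complement
  sym <- character(length)
  ann <- vector("list", R)
  pos <- 1L
  for (j in seq_len(R)) {
    cur <- min(max(pos, triggers[j]), length + 1L)
    if (cur > pos)
      sym[pos:(cur - 1L)] <- sample(DNA_ALPHABET, cur - pos, replace = TRUE, prob = comp)
    size <- max(0L, min(sizes[j], length - cur + 1L, cur - 1L))
    if (size > 0L) {
      src <- sample.int(cur - size, 1L)
      copy <- sym[src:(src + size - 1L)]
      if (is_rc[j]) {
        copy <- rev(chartr("ACGT", "TGCA", copy))
      }
      sym[cur:(cur + size - 1L)] <- mutate_chars(copy, model$mutation_rate)
    } else {
      src <- NA_integer_
    }
    ann[[j]] <- c(src, cur, size)
    pos <- cur + size
  }
  if (pos <= length)
    sym[pos:length] <- sample(DNA_ALPHABET, length - pos + 1L, replace = TRUE, prob = comp)
  ann <- do.call(rbind, ann)
  # exactly n_repeats rows; events truncated to zero length (capacity ran out)
  # keep an NA source_start
  annotations <- data.frame(source_start = ann[, 1], dest_start = ann[, 2],
                            length = ann[, 3], is_reverse_complement = is_rc)
  new_dna_stream(sym, annotations)
}

#' Estimate the substitution rate from a stream's repeat annotations
#'
#' Compares every annotated destination window against its (possibly
#' reverse-complemented) source window and returns the pooled mismatch
#' fraction — an unbiased estimate of the configured `mutation_rate`.
#'
#' @param stream A `dna_stream` produced by [plant_repeats()].
#' @return Estimated per-base substitution rate (NaN if no repeat bases).
#' @export
estimate_mutation_rate <- function(stream) {
  stopifnot(inherits(stream, "dna_stream"))
  chars <- strsplit(stream$seq, "")[[1]]
  ann <- stream$annotations
  mism <- 0; total <- 0
  for (j in seq_len(nrow(ann))) {
    if (is.na(ann$source_start[j]) || ann$length[j] == 0L) next
    src <- chars[ann$source_start[j]:(ann$source_start[j] + ann$length[j] - 1L)]
    dst <- chars[ann$dest_start[j]:(ann$dest_start[j] + ann$length[j] - 1L)]
    if (ann$is_reverse_complement[j]) src <- rev(chartr("ACGT", "TGCA", src))
    mism <- mism + sum(src != dst)
    total <- total + ann$length[j]
  }
  mism / total
}

# SOLiD di-base equivalence matrix: bases A,C,G,T map to 0..3 and the color
# call for a transition is the bitwise XOR of the two codes, i.e.
# {AA,CC,GG,TT}->0, {AC,CA,GT,TG}->1, {AG,GA,CT,TC}->2, {AT,TA,CG,GC}->3.

#' Convert a DNA string to SOLiD color space
#'
#' Encodes base transitions as digits 0-3 via the standard di-base
#' equivalence matrix. By default a known anchor base (`"T"`) is prepended and
#' every base yields one color call, as in SOLiD csfasta reads; with
#' `anchor = NULL` the first sequence base itself serves as the anchor and
#' `len - 1` transition digits follow. Transitions involving `N` emit the
#' missing-call character `"."`.
#'
#' @param seq Character vector of DNA strings.
#' @param anchor Single anchor base prepended to each read, or `NULL` to use
#'   the first base of the sequence as the anchor.
#' @return Character vector: anchor base followed by color digits.
#' @examples
#' to_color_space("AAAA", anchor = NULL)  # "A000"
#' to_color_space("A")                    # "T3"
#' @export
to_color_space <- function(seq, anchor = "T") {
  if (!is.null(anchor))
    stopifnot(length(anchor) == 1L, anchor %in% DNA_ALPHABET[1:4])
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- strsplit(s, "")[[1]]
    if (!is.null(anchor)) chars <- c(anchor, chars)
    code <- match(chars, DNA_ALPHABET[1:4]) - 1L   # NA for N
    calls <- bitwXor(code[-length(code)], code[-1])
    digits <- ifelse(is.na(calls), ".", as.character(calls))
    paste(c(chars[1], digits), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
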