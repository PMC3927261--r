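# Assembly of the three simulated channels (headers, bases, qualities) into
# four-line FASTQ records, the top-level simulation driver, and a structural
# validator used as the generator's own closure oracle.

#' A single FASTQ read record
#'
#' @param header Header string without the leading `@`.
#' @param bases DNA (or color-space) string for line 2.
#' @param qualities Quality string for line 4; must match `bases` in length.
#' @return An object of class `read_record`.
#' @export
read_record <- function(header, bases, qualities) {
  if (nchar(bases) != nchar(qualities))
    stop("lines 2 and 4 must have equal length (got ", nchar(bases),
         " bases, ", nchar(qualities), " quality characters)")
  structure(list(header = header, bases = bases, qualities = qualities),
            class = "read_record")
}

#' Full simulation configuration
#'
#' Bundles every parameter of one run: read geometry, the per-channel
#' configurations, record-layout options and the RNG seed. The seed fully
#' determines the output byte stream.
#'
#' @param n_reads Number of reads to simulate.
#' @param read_length_min,read_length_max Per-read length bounds; lengths are
#'   drawn uniformly in `[min, max]` (equal values give fixed-length reads).
#' @param header A [header_config()].
#' @param composition A [composition_profile()].
#' @param repeats A [repeat_model()].
#' @param quality A [quality_alphabet()].
#' @param color_space Emit line 2 in SOLiD color space (anchor base + digits).
#' @param plus3_repeats_header Repeat the header after `+` on line 3.
#' @param lines_excluded Subset of `c(1, 3, 4)` to omit from every record;
#'   excluding lines 1, 3 and 4 turns the tool into a bare DNA simulator.
#' @param seed Integer RNG seed.
#' @param run_mode `"repeat_buffered"` holds the whole DNA stream in memory so
#'   copy events can reference any earlier position; `"low_memory"` generates
#'   reads in bounded chunks and supports composition-only simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1000L,
                       read_length_min = 100L, read_length_max = 100L,
                       header = header_config("illumina", append_length = TRUE),
                       composition = composition_profile(),
                       repeats = repeat_model(),
                       quality = quality_alphabet(),
                       color_space = FALSE,
                       plus3_repeats_header = FALSE,
                       lines_excluded = integer(0),
                       seed = 1L,
                       run_mode = c("repeat_buffered", "low_memory")) {
  run_mode <- match.arg(run_mode)
  lines_excluded <- as.integer(lines_excluded)
  stopifnot(n_reads >= 1, read_length_min >= 1,
            read_length_min <= read_length_max,
            inherits(header, "header_config"),
            inherits(composition, "composition_profile"),
            inherits(repeats, "repeat_model"),
            inherits(quality, "quality_alphabet"))
  if (2L %in% lines_excluded)
    stop("line 2 (the bases) cannot be excluded from a record")
  if (!all(lines_excluded %in% c(1L, 3L, 4L)))
    stop("'lines_excluded' must be a subset of {1, 3, 4}")
  if (plus3_repeats_header && 1L %in% lines_excluded)
    stop("line 3 cannot repeat the header when line 1 is excluded")
  if (run_mode == "low_memory" && repeats$n_repeats > 0L)
    stop("planted repeats require run_mode = 'repeat_buffered'")
  structure(list(n_reads = as.integer(n_reads),
                 read_length_min = as.integer(read_length_min),
                 read_length_max = as.integer(read_length_max),
                 header = header, composition = composition,
                 repeats = repeats, quality = quality,
                 color_space = color_space,
                 plus3_repeats_header = plus3_repeats_header,
                 lines_excluded = sort(lines_excluded),
                 seed = as.integer(seed), run_mode = run_mode),
            class = "sim_config")
}

#' Render a read record as FASTQ text lines
#'
#' Applies the four-line rules: `@header`, bases, `+` (optionally followed by
#' the line-1 header), qualities — omitting any lines excluded in the config.
#'
#' @param rec A [read_record()].
#' @param cfg A [sim_config()] (only layout fields are used).
#' @return Character vector of 1-4 output lines.
#' @export
build_record <- function(rec, cfg = sim_config()) {
  stopifnot(inherits(rec, "read_record"))
  lines <- c(paste0("@", rec$header),
             rec$bases,
             if (cfg$plus3_repeats_header) paste0("+", rec$header) else "+",
             rec$qualities)
  keep <- setdiff(1:4, cfg$lines_excluded)
  lines[keep]
}

# draw the bases channel for all reads; returns list(reads=<chr>, stream=<dna_stream or NULL>)
simulate_bases <- function(lens, cfg) {
  if (cfg$run_mode == "repeat_buffered") {
    stream <- plant_repeats(sum(lens), cfg$composition, cfg$repeats)
    reads <- split_lengths(stream$seq, lens)
    list(reads = reads, stream = stream)
  } else {
    # bounded chunks of ~1 Mbase: constant memory in n_reads
    total <- sum(lens)
    chunk <- 1048576L
    parts <- character(0)
    done <- 0L
    while (done < total) {
      take <- min(chunk, total - done)
      parts <- c(parts, sample_sequence(take, cfg$composition)$seq)
      done <- done + take
    }
    list(reads = split_lengths(paste(parts, collapse = ""), lens), stream = NULL)
  }
}

#' Simulate a FASTQ file
#'
#' Top-level driver: draws per-read lengths once (shared by lines 2 and 4),
#' generates the three channels independently — headers for the configured
#' platform, the DNA stream (partitioned into reads; planted repeats may span
#' read boundaries), quality strings from the configured distribution — masks
#' N positions to the lowest quality score, and assembles four-line records.
#' The same seed and configuration always produce byte-identical output.
#'
#' @param cfg A [sim_config()].
#' @param file Optional output path (or connection); lines are written
#'   LF-terminated. If `NULL` the lines are returned only.
#' @param quiet Suppress the one-line run summary on stderr.
#' @return Invisibly, a list with `lines` (the output text), `stream` (the
#'   underlying `dna_stream` in repeat-buffered mode) and `read_lengths`.
#' @export
simulate_fastq <- function(cfg = sim_config(), file = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  t0 <- proc.time()[["elapsed"]]
  set.seed(cfg$seed)
  n <- cfg$n_reads
  lens <- if (cfg$read_length_min == cfg$read_length_max) {
    rep(cfg$read_length_min, n)
  } else {
    sample(cfg$read_length_min:cfg$read_length_max, n, replace = TRUE)
  }
  ch <- simulate_bases(lens, cfg)
  bases <- ch$reads
  if (cfg$color_space) bases <- to_color_space(bases)
  out_lens <- nchar(bases)
  headers <- sub("^@", "", make_headers(seq_len(n), out_lens, cfg$header))
  quals <- sample_qualities(out_lens, cfg$quality)
  quals <- mask_n_positions(quals, bases, cfg$quality)
  blocks <- rbind(paste0("@", headers),
                  bases,
                  if (cfg$plus3_repeats_header) paste0("+", headers) else rep("+", n),
                  quals)
  lines <- as.vector(blocks[setdiff(1:4, cfg$lines_excluded), , drop = FALSE])
  if (!is.null(file)) writeLines(lines, file, sep = "\n")
  if (!quiet)
    message(sprintf("simulated %d reads / %d bases in %.2f s",
                    n, sum(out_lens), proc.time()[["elapsed"]] - t0))
  invisible(list(lines = lines, stream = ch$stream, read_lengths = lens))
}

#' Validate FASTQ text against the four-line rules
#'
#' Structural oracle for simulator output (assumes no lines were excluded):
#' checks the `@` and `+` prefixes, equality of line-2 and line-4 lengths,
#' quality codes within the printable range 33..126, and — when the header
#' carries a `length=` appendix — its consistency with the actual line-2
#' length. Malformed records are reported, not raised.
#'
#' @param x Character vector of FASTQ lines, or a path to a FASTQ file.
#' @return A list of class `fastq_validation` with `n_records`,
#'   `n_violations` and a `violations` data frame (record, check, message).
#' @export
validate_fastq <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else x
  viol <- list()
  flag <- function(rec, check, msg)
    viol[[length(viol) + 1L]] <<- data.frame(record = rec, check = check,
                                             message = msg)
  n_rec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L)
    flag(NA_integer_, "line_count", sprintf(
      "line count %d is not a multiple of 4", length(lines)))
  for (r in seq_len(n_rec)) {
    h <- lines[4L * r - 3L]; b <- lines[4L * r - 2L]
    p <- lines[4L * r - 1L]; q <- lines[4L * r]
    if (!startsWith(h, "@")) flag(r, "at_prefix", "line 1 does not begin with '@'")
    if (!startsWith(p, "+")) flag(r, "plus_prefix", "line 3 does not begin with '+'")
    if (nchar(b) != nchar(q))
      flag(r, "length_equal", sprintf("line 2 has %d chars but line 4 has %d",
                                      nchar(b), nchar(q)))
    if (nchar(q) > 0L) {
      cq <- utf8ToInt(q)
      if (min(cq) < 33L || max(cq) > 126L)
        flag(r, "quality_range", "quality code outside printable ASCII 33..126")
    }
    m <- regmatches(h, regexec("length=([0-9]+)", h))[[1]]
    if (length(m) == 2L && as.integer(m[2]) != nchar(b))
      flag(r, "declared_length", sprintf(
        "header declares length=%s but line 2 has %d chars", m[2], nchar(b)))
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(record = integer(0), check = character(0), message = character(0))
  structure(list(n_records = n_rec, n_violations = nrow(violations),
                 violations = violations),
            class = "fastq_validation")
}

#' @export
print.fastq_validation <- function(x, ...) {
  cat("FASTQ validation:", x$n_records, "records,", x$n_violations,
      "violation(s)\n")
  if (x$n_violations > 0) print(utils::head(x$violations, 10))
  invisible(x)
}
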