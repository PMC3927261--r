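# Per-read header generation for the four supported platforms. All stochastic
# header fields are drawn from uniform distributions; run-constant fields
# (454 timestamp, Ion Torrent run ID, SOLiD run name) are drawn once per call,
# so one vectorized call corresponds to one sequencing run.

#' Ion Torrent chip coordinate bounds
#'
#' Coordinates in Ion Torrent headers are addressable well positions whose
#' maxima depend on the chip. The P1 chip bounds (x <= 15456, y <= 10656) are
#' fixed; the smaller chips default to plausible well-grid sizes and can be
#' overridden.
#'
#' @param name Chip name: one of `"314"`, `"316"`, `"318"`, `"P1"`.
#' @param x_max,y_max Optional overrides for the coordinate maxima.
#' @return An object of class `iontorrent_chip` with fields `name`, `x_max`, `y_max`.
#' @export
iontorrent_chip <- function(name = c("P1", "314", "316", "318"),
                            x_max = NULL, y_max = NULL) {
  name <- match.arg(name)
  defaults <- list(`314` = c(1280L, 1152L), `316` = c(2772L, 2284L),
                   `318` = c(3392L, 3792L), P1 = c(15456L, 10656L))
  d <- defaults[[name]]
  x_max <- if (is.null(x_max)) d[1] else as.integer(x_max)
  y_max <- if (is.null(y_max)) d[2] else as.integer(y_max)
  stopifnot(x_max >= 0, y_max >= 0)
  structure(list(name = name, x_max = x_max, y_max = y_max),
            class = "iontorrent_chip")
}

#' Header generation configuration
#'
#' Selects the platform dialect and the optional header suffix. Headers can
#' carry either a `length=<L>` appendix or a `/1` `/2` mate suffix
#' (alternating across consecutive reads), but not both.
#'
#' @param platform One of `"illumina"`, `"solid"`, `"roche454"`, `"iontorrent"`.
#' @param instrument_tag Tag used in the `@<tag>.<index>` prefix.
#' @param paired_mode `"none"` or `"pair_suffix"` (`/1`, `/2` alternating).
#' @param append_length Append `length=<read length>` to the header.
#' @param chip [iontorrent_chip()] spec (Ion Torrent only).
#' @param illumina_instrument Instrument field of Illumina headers.
#' @param illumina_max Named integer vector with uniform-sampling maxima for
#'   `lane`, `tile`, `x`, `y` (minima are 1, 1, 0, 0).
#' @param solid_max Named integer vector with maxima for the trailing
#'   `panel`, `x`, `y` numeric tokens of SOLiD headers.
#' @return An object of class `header_config`.
#' @export
header_config <- function(platform = c("illumina", "solid", "roche454", "iontorrent"),
                          instrument_tag = "FILEOUT",
                          paired_mode = c("none", "pair_suffix"),
                          append_length = FALSE,
                          chip = iontorrent_chip("P1"),
                          illumina_instrument = "HWUSI-EAS100R",
                          illumina_max = c(lane = 8L, tile = 120L, x = 2047L, y = 2047L),
                          solid_max = c(panel = 2000L, x = 3000L, y = 3000L)) {
  platform <- match.arg(platform)
  paired_mode <- match.arg(paired_mode)
  if (append_length && paired_mode == "pair_suffix")
    stop("'append_length' and paired_mode = 'pair_suffix' are mutually exclusive")
  stopifnot(inherits(chip, "iontorrent_chip"),
            all(c("lane", "tile", "x", "y") %in% names(illumina_max)),
            all(c("panel", "x", "y") %in% names(solid_max)))
  structure(list(platform = platform, instrument_tag = instrument_tag,
                 paired_mode = paired_mode, append_length = append_length,
                 chip = chip, illumina_instrument = illumina_instrument,
                 illumina_max = illumina_max, solid_max = solid_max),
            class = "header_config")
}

# length= / mate suffix shared by Illumina, SOLiD and Roche-454 headers
header_suffix <- function(read_index, read_length, cfg) {
  if (cfg$paired_mode == "pair_suffix") {
    paste0("/", 2L - read_index %% 2L)
  } else if (cfg$append_length) {
    paste0(" length=", read_length)
  } else {
    rep("", length(read_index))
  }
}

#' Generate Roche-454 headers
#'
#' Produces `@<tag>.<index> <accession> length=<L>` headers. The 14-character
#' accession is a 6-character base-36 run timestamp (constant within the
#' call), a randomizing hash character, the 2-digit PTP region (01-16) and
#' the 5-character base-36 well code encoding `x * 4096 + y`.
#'
#' @param read_index Integer vector of read indices.
#' @param read_length Integer vector of read lengths (recycled).
#' @param cfg A [header_config()].
#' @return Character vector of headers, one per read.
#' @export
make_roche454_header <- function(read_index, read_length,
                                 cfg = header_config("roche454", append_length = TRUE)) {
  n <- length(read_index)
  read_length <- rep_len(read_length, n)
  timestamp <- paste(sample(B36_ALPHABET, 6, replace = TRUE), collapse = "")
  hash <- sample(B36_ALPHABET, n, replace = TRUE)
  region <- sample.int(16L, n, replace = TRUE)
  # x bounded so x*4096 + y always fits in 5 base-36 digits (36^5 = 60466176)
  x <- sample.int(14762L, n, replace = TRUE) - 1L
  y <- sample.int(4096L, n, replace = TRUE) - 1L
  accession <- paste0(timestamp, hash, sprintf("%02d", region),
                      encode_well_location(x, y))
  paste0("@", cfg$instrument_tag, ".", read_index, " ", accession,
         " length=", read_length)
}

#' Generate Ion Torrent headers
#'
#' Produces `@<run ID>:<X>:<Y>` headers: a 5-character alphanumeric run ID
#' (constant within the call) and zero-padded 5-digit well coordinates drawn
#' uniformly within the chip bounds.
#'
#' @param n Number of headers to generate.
#' @param cfg A [header_config()] with its `chip` field set.
#' @return Character vector of headers.
#' @export
make_iontorrent_header <- function(n, cfg = header_config("iontorrent")) {
  chip <- cfg$chip
  run_id <- paste(sample(c(LETTERS, 0:9), 5, replace = TRUE), collapse = "")
  x <- sample.int(chip$x_max + 1L, n, replace = TRUE) - 1L
  y <- sample.int(chip$y_max + 1L, n, replace = TRUE) - 1L
  sprintf("@%s:%05d:%05d", run_id, x, y)
}

#' Generate Illumina headers
#'
#' Produces `@<tag>.<index> <instrument>:<lane>:<tile>:<x>:<y>` headers with
#' lane, tile and cluster coordinates drawn uniformly from the configured
#' ranges, plus an optional `length=` or `/mate` suffix.
#'
#' @inheritParams make_roche454_header
#' @return Character vector of headers.
#' @export
make_illumina_header <- function(read_index, read_length,
                                 cfg = header_config("illumina")) {
  n <- length(read_index)
  read_length <- rep_len(read_length, n)
  m <- cfg$illumina_max
  lane <- sample.int(m[["lane"]], n, replace = TRUE)
  tile <- sample.int(m[["tile"]], n, replace = TRUE)
  x <- sample.int(m[["x"]] + 1L, n, replace = TRUE) - 1L
  y <- sample.int(m[["y"]] + 1L, n, replace = TRUE) - 1L
  paste0("@", cfg$instrument_tag, ".", read_index, " ",
         cfg$illumina_instrument, ":", lane, ":", tile, ":", x, ":", y,
         header_suffix(read_index, read_length, cfg))
}

#' Generate ABI-SOLiD headers
#'
#' Produces underscore-joined SOLiD run architecture headers of the shape
#' `@<tag>.<index><run name>_<date>_<run tokens>_<panel>_<x>_<y>` (no space
#' after the index), with a date-like token and run-constant name tokens, and
#' uniformly sampled trailing panel/x/y numeric tokens.
#'
#' @inheritParams make_roche454_header
#' @return Character vector of headers.
#' @export
make_solid_header <- function(read_index, read_length,
                              cfg = header_config("solid")) {
  n <- length(read_index)
  read_length <- rep_len(read_length, n)
  run_name <- paste(sample(LETTERS, 4, replace = TRUE), collapse = "")
  run_date <- format(as.Date("2008-01-01") + sample.int(2500L, 1L), "%Y%m%d")
  slide <- sample.int(8L, 1L)
  center <- sample(c("Broad", "Baylor", "WashU", "Sanger"), 1L)
  grid <- paste0(sample.int(9L, 1L), sample(letters[1:6], 1L))
  m <- cfg$solid_max
  panel <- sample.int(m[["panel"]], n, replace = TRUE)
  x <- sample.int(m[["x"]] + 1L, n, replace = TRUE) - 1L
  y <- sample.int(m[["y"]] + 1L, n, replace = TRUE) - 1L
  paste0("@", cfg$instrument_tag, ".", read_index,
         "VAB_", run_name, "_", run_date, "_", slide, "_", center, "_", grid,
         "_", panel, "_", x, "_", y,
         header_suffix(read_index, read_length, cfg))
}

#' Generate headers for any configured platform
#'
#' Dispatches to the platform-specific generator named in `cfg$platform`.
#'
#' @param read_index Integer vector of read indices.
#' @param read_length Integer vector of read lengths.
#' @param cfg A [header_config()].
#' @return Character vector of headers.
#' @export
make_headers <- function(read_index, read_length, cfg) {
  stopifnot(inherits(cfg, "header_config"))
  switch(cfg$platform,
         illumina   = make_illumina_header(read_index, read_length, cfg),
         solid      = make_solid_header(read_index, read_length, cfg),
         roche454   = make_roche454_header(read_index, read_length, cfg),
         iontorrent = make_iontorrent_header(length(read_index), cfg))
}
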