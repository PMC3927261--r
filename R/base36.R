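# Base-36 positional encoding used by Roche-454 accessions (timestamp and
# well-location fields). Digit alphabet is 0-9 then A-Z, most-significant first.

B36_ALPHABET <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]

#' Encode non-negative integers as fixed-width base-36 strings
#'
#' Roche-454 read accessions store the run timestamp and the flow-cell well
#' location as fixed-width base-36 fields over the digit alphabet
#' \code{0-9A-Z}, most-significant digit first.
#'
#' @param value Vector of non-negative integers (each must be < 36^width).
#' @param width Number of base-36 digits to emit (positive integer).
#' @return Character vector of `width`-character base-36 strings.
#' @examples
#' encode_base36(0, 5)         # "00000"
#' encode_base36(20712422, 5)  # "CBXT2"
#' @export
encode_base36 <- function(value, width) {
  if (length(width) != 1L || is.na(width) || width < 1)
    stop("'width' must be a single positive integer")
  value <- as.numeric(value)
  if (any(is.na(value)) || any(value < 0))
    stop("base-36 values must be non-negative")
  if (any(value >= 36^width))
    stop("value out of range: does not fit in ", width, " base-36 digits")
  digits <- matrix("", nrow = length(value), ncol = width)
  rem <- floor(value)
  for (i in width:1) {
    digits[, i] <- B36_ALPHABET[rem %% 36 + 1]
    rem <- rem %/% 36
  }
  do.call(paste0, as.data.frame(digits, stringsAsFactors = FALSE))
}

#' Decode base-36 strings to integers
#'
#' Inverse of [encode_base36()]: `encode_base36(decode_base36(s), nchar(s))`
#' returns `s` for any valid code.
#'
#' @param code Character vector of base-36 strings (digits `0-9A-Z` only).
#' @return Numeric vector of decoded non-negative integers.
#' @export
decode_base36 <- function(code) {
  if (any(is.na(code)) || any(nchar(code) == 0L))
    stop("base-36 codes must be non-empty strings")
  vapply(strsplit(code, ""), function(ch) {
    v <- match(ch, B36_ALPHABET)
    if (anyNA(v)) stop("invalid base-36 character in '", paste(ch, collapse = ""), "'")
    sum((v - 1) * 36^(rev(seq_along(v)) - 1))
  }, numeric(1))
}

#' Encode a Roche-454 well location as a 5-character base-36 code
#'
#' The (x, y) well coordinates on the Pico Titer Plate are combined into the
#' single total `x * 4096 + y` and rendered as five base-36 digits.
#' `y` must be below 4096 so the code decodes uniquely.
#'
#' @param x,y Integer vectors of well coordinates; `0 <= y < 4096`, `x >= 0`,
#'   and `x * 4096 + y < 36^5`.
#' @return Character vector of 5-character base-36 well codes.
#' @examples
#' encode_well_location(5056, 3046)  # "CBXT2"
#' @export
encode_well_location <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(x < 0)) stop("well x coordinate must be non-negative")
  if (any(y < 0) || any(y >= 4096))
    stop("well y coordinate must lie in [0, 4095] for unique decoding")
  encode_base36(x * 4096 + y, 5L)
}

#' Decode a 5-character well code back to (x, y)
#'
#' @param code Character vector of 5-character base-36 well codes.
#' @return List with integer vectors `x` (total div 4096) and `y` (total mod 4096).
#' @export
decode_well_location <- function(code) {
  if (any(nchar(code) != 5L)) stop("well codes must be exactly 5 characters")
  total <- decode_base36(code)
  list(x = total %/% 4096, y = total %% 4096)
}
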