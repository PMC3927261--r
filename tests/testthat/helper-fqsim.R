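# shared test utilities

deflate_size <- function(s) length(memCompress(charToRaw(s), type = "gzip"))

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# pull the 14-char accession out of a Roche-454 header
accession_of <- function(headers) {
  vapply(strsplit(headers, " ", fixed = TRUE), `[`, character(1), 2)
}
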