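test_that("records render under the four-line rules with optional variations", {
  rec <- read_record("H", "ACGT", "IIII")
  cfg <- sim_config()
  expect_identical(build_record(rec, cfg), c("@H", "ACGT", "+", "IIII"))
  plus_cfg <- sim_config(plus3_repeats_header = TRUE)
  expect_identical(build_record(rec, plus_cfg)[3], "+H")
  dna_cfg <- sim_config(lines_excluded = c(1, 3, 4))
  expect_identical(build_record(rec, dna_cfg), "ACGT")
  expect_error(read_record("H", "ACGT", "III"), "equal length")
})

test_that("config invariants forbid impossible record layouts", {
  expect_error(sim_config(lines_excluded = 2), "cannot be excluded")
  expect_error(sim_config(lines_excluded = c(1, 5)), "subset")
  expect_error(sim_config(lines_excluded = 1, plus3_repeats_header = TRUE),
               "line 1 is excluded")
  expect_error(sim_config(repeats = repeat_model(10), run_mode = "low_memory"),
               "repeat_buffered")
})

test_that("simulated files satisfy the structural contract", {
  cfg <- sim_config(n_reads = 3, read_length_min = 5, read_length_max = 5,
                    seed = 42)
  out <- simulate_fastq(cfg, quiet = TRUE)
  expect_length(out$lines, 12L)
  v <- validate_fastq(out$lines)
  expect_identical(v$n_records, 3L)
  expect_identical(v$n_violations, 0L)
  # variable lengths with a declared length= appendix stay consistent
  cfg2 <- sim_config(n_reads = 500, read_length_min = 20, read_length_max = 180,
                     header = header_config("roche454"), seed = 43)
  out2 <- simulate_fastq(cfg2, quiet = TRUE)
  expect_identical(validate_fastq(out2$lines)$n_violations, 0L)
  lens <- nchar(out2$lines[seq(2, length(out2$lines), by = 4)])
  declared <- as.integer(sub(".*length=", "", out2$lines[seq(1, length(out2$lines), by = 4)]))
  expect_identical(declared, lens)
})

test_that("identical seed and config give byte-identical FASTQ files", {
  cfg <- sim_config(n_reads = 200, read_length_min = 50, read_length_max = 120,
                    repeats = repeat_model(10, 1, 500, 0.1, 0.5), seed = 7)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_fastq(cfg, f1, quiet = TRUE)
  simulate_fastq(cfg, f2, quiet = TRUE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("generated FASTQ round-trips through the Biostrings parser", {
  cfg <- sim_config(n_reads = 250, read_length_min = 36, read_length_max = 36,
                    composition = composition_profile(0.3, 0.2, 0.2, 0.28, 0.02),
                    seed = 11)
  f <- tempfile(fileext = ".fastq")
  out <- simulate_fastq(cfg, f, quiet = TRUE)
  parsed <- Biostrings::readDNAStringSet(f, format = "fastq", with.qualities = TRUE)
  expect_length(parsed, 250L)
  expect_identical(unname(as.character(parsed)),
                   out$lines[seq(2, length(out$lines), by = 4)])
  # N bases carry the lowest configured quality score
  quals <- unname(as.character(S4Vectors::mcols(parsed)$qualities))
  bases <- strsplit(paste(as.character(parsed), collapse = ""), "")[[1]]
  qchars <- strsplit(paste(quals, collapse = ""), "")[[1]]
  expect_true(all(qchars[bases == "N"] == "!"))
  unlink(f)
})

test_that("low-memory and repeat-buffered modes agree without repeats", {
  base_freq <- function(mode, seed) {
    cfg <- sim_config(n_reads = 400, read_length_min = 250, read_length_max = 250,
                      seed = seed, run_mode = mode)
    s <- simulate_fastq(cfg, quiet = TRUE)$lines
    table(factor(strsplit(paste(s[seq(2, length(s), 4)], collapse = ""), "")[[1]],
                 levels = c("A", "C", "G", "T")))
  }
  tab <- rbind(base_freq("low_memory", 21), base_freq("repeat_buffered", 22))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("color-space mode emits anchored digit reads with matching qualities", {
  cfg <- sim_config(n_reads = 50, read_length_min = 35, read_length_max = 35,
                    header = header_config("solid", append_length = TRUE),
                    color_space = TRUE, seed = 13)
  out <- simulate_fastq(cfg, quiet = TRUE)
  l2 <- out$lines[seq(2, length(out$lines), 4)]
  l4 <- out$lines[seq(4, length(out$lines), 4)]
  expect_true(all(grepl("^T[0123]{35}$", l2)))
  expect_identical(nchar(l4), nchar(l2))  # 36: anchor + one call per base
  expect_identical(validate_fastq(out$lines)$n_violations, 0L)
})

test_that("the validator flags malformed hand-made records", {
  bad <- c("@ok", "ACGT", "+", "III",            # length mismatch
           "Xbad", "ACGT", "+", "IIII",          # missing @
           "@ok2", "ACGT", "-", "IIII",          # missing +
           "@ok3 length=9", "ACGT", "+", "IIII", # wrong declared length
           "@ok4", "ACGT", "+", paste0("II", intToUtf8(32), "I"))  # code 32
  v <- validate_fastq(bad)
  expect_identical(v$n_records, 5L)
  expect_setequal(v$violations$check,
                  c("length_equal", "at_prefix", "plus_prefix",
                    "declared_length", "quality_range"))
  expect_identical(v$n_violations, 5L)
  # truncated stream is reported, not raised
  expect_identical(validate_fastq(c("@h", "ACGT"))$violations$check, "line_count")
})

test_that("excluded lines leave a parseable single-channel stream", {
  cfg <- sim_config(n_reads = 30, read_length_min = 40, read_length_max = 40,
                    lines_excluded = c(1, 3, 4), seed = 17)
  out <- simulate_fastq(cfg, quiet = TRUE)
  expect_length(out$lines, 30L)
  expect_true(all(grepl("^[ACGTN]{40}$", out$lines)))
})
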