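test_that("composition-only sampling honors the configured probabilities", {
  set.seed(301)
  expect_identical(sample_sequence(10, composition_profile(1, 0, 0, 0, 0))$seq,
                   "AAAAAAAAAA")
  s <- sample_sequence(1e5, composition_profile())$seq
  expect_false(grepl("N", s, fixed = TRUE))  # p_N = 0 by default
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # skewed profile recovers its own frequencies
  s2 <- sample_sequence(1e5, composition_profile(0.5, 0.2, 0.2, 0.05, 0.05))$seq
  freq <- table(factor(strsplit(s2, "")[[1]], levels = c("A", "C", "G", "T", "N"))) / 1e5
  expect_equal(as.numeric(freq), c(0.5, 0.2, 0.2, 0.05, 0.05), tolerance = 0.05)
})

test_that("composition profile validates probabilities", {
  expect_error(composition_profile(0.5, 0.5, 0.5, 0, 0), "sum to 1")
  expect_error(composition_profile(-0.1, 0.6, 0.25, 0.25, 0), "\\[0, 1\\]")
})

test_that("reverse complement is correct and an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")  # RC palindrome
  expect_identical(reverse_complement("AAAC"), "GTTT")
  expect_identical(reverse_complement("N"), "N")
  expect_error(reverse_complement("ACGU"), "outside")
  set.seed(302)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1), bases = c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("reverse complement agrees with the Biostrings oracle", {
  set.seed(303)
  s <- replicate(25, random_dna(sample(1:100, 1)))
  oracle <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  expect_identical(reverse_complement(s), unname(oracle))
})

test_that("mutation substitutes at the configured rate to different bases", {
  set.seed(304)
  s <- random_dna(1e5)
  expect_identical(mutate(s, 0), s)
  m1 <- mutate(s, 1)
  expect_identical(nchar(m1), nchar(s))
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  # rate 0.1: observed fraction within the 99.99% binomial interval
  m <- mutate(s, 0.1)
  frac <- mean(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  expect_gt(frac, 0.094)
  expect_lt(frac, 0.106)
})

test_that("planted repeats copy exactly from their annotated sources", {
  set.seed(305)
  st <- plant_repeats(1e5, model = repeat_model(50, 1, 3000, 0, 0))
  expect_identical(nchar(st$seq), 1e5L)
  expect_identical(nrow(st$annotations), 50L)
  chars <- strsplit(st$seq, "")[[1]]
  for (j in seq_len(nrow(st$annotations))) {
    a <- st$annotations[j, ]
    if (is.na(a$source_start) || a$length == 0L) next
    src <- chars[a$source_start:(a$source_start + a$length - 1L)]
    dst <- chars[a$dest_start:(a$dest_start + a$length - 1L)]
    expect_identical(dst, src)
    # brute-force oracle: the dest window occurs at the annotated source
    expect_identical(substr(st$seq, a$source_start, a$source_start + a$length - 1L),
                     paste(dst, collapse = ""))
  }
})

test_that("reverse-complement repeats match the reverse complement of their source", {
  set.seed(306)
  st <- plant_repeats(5e4, model = repeat_model(30, 5, 500, 0, 1))
  chars <- strsplit(st$seq, "")[[1]]
  expect_true(all(st$annotations$is_reverse_complement))
  for (j in seq_len(nrow(st$annotations))) {
    a <- st$annotations[j, ]
    if (is.na(a$source_start) || a$length == 0L) next
    src <- paste(chars[a$source_start:(a$source_start + a$length - 1L)], collapse = "")
    dst <- paste(chars[a$dest_start:(a$dest_start + a$length - 1L)], collapse = "")
    expect_identical(dst, reverse_complement(src))
  }
})

test_that("mutated copies sit at the configured Hamming distance", {
  set.seed(307)
  st <- plant_repeats(2e5, model = repeat_model(60, 500, 2000, 0.1, 0.3))
  est <- estimate_mutation_rate(st)
  total <- sum(st$annotations$length, na.rm = TRUE)
  ci <- 4 * sqrt(0.1 * 0.9 / total)  # ~99.99% binomial interval
  expect_gt(est, 0.1 - ci)
  expect_lt(est, 0.1 + ci)
})

test_that("degenerate repeat models reduce to composition-only sampling", {
  set.seed(308)
  st <- plant_repeats(1000, model = repeat_model(0))
  expect_identical(nrow(st$annotations), 0L)
  expect_error(plant_repeats(1, model = repeat_model(1)), "too short")
})

test_that("color-space conversion emits digits 0-3 under the di-base matrix", {
  # first-base anchoring: same-base transitions all map to 0
  expect_identical(to_color_space("AAAA", anchor = NULL), "A000")
  expect_identical(to_color_space("A", anchor = NULL), "A")
  # fixed anchor T prepended: one call per base
  expect_identical(to_color_space("A"), "T3")
  expect_identical(to_color_space(""), "")
  # adopted matrix: complements map to 3, transitions within pair groups
  expect_identical(to_color_space("ACGT", anchor = NULL), "A131")
  expect_identical(to_color_space("TGCA", anchor = NULL), "T131")
  expect_identical(to_color_space("AN", anchor = NULL), "A.")
  set.seed(309)
  calls <- to_color_space(replicate(200, random_dna(100)))
  expect_true(all(grepl("^[ACGT][0123]{100}$", calls)))
})

test_that("same seed reproduces the identical DNA stream", {
  model <- repeat_model(20, 1, 500, 0.05, 0.5)
  set.seed(310); a <- plant_repeats(2e4, model = model)
  set.seed(310); b <- plant_repeats(2e4, model = model)
  expect_identical(a, b)
})
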