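---
title: "Simulating FASTQ reads without a reference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating FASTQ reads without a reference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqsim)
```

## The model

A FASTQ file interleaves three statistically unrelated channels — headers,
DNA bases and quality scores — under a rigid four-line frame: line 1 is
`@` + header, line 2 the bases, line 3 `+` (optionally repeating the
header), line 4 the qualities, with lines 2 and 4 equal in length and `N`
bases carrying the lowest quality score. fqsim treats simulation as
modeling + generation and simulates each channel independently with its own
stochastic model, assembling records at the end. No reference genome is
involved anywhere: the point is to produce files with the *statistical
shape* of sequencing output — including a tunable amount of repetitive
structure, and hence a tunable post-compression ratio — for load-testing
storage and compute infrastructure and for exercising FASTQ compressors.
Everything is driven by R's RNG, so one integer seed fully determines the
output bytes.

### Headers

All stochastic header fields are drawn from uniform distributions: uniform
draws are cheap and minimize accidental field collisions. Four dialects are
generated:

* **Illumina**: `@<tag>.<i> <instrument>:<lane>:<tile>:<x>:<y>` with
  configurable field maxima (defaults: lane ≤ 8, tile ≤ 120, x,y ≤ 2047).
* **ABI-SOLiD**: the underscore-joined run architecture
  (`...VAB_<name>_<YYYYMMDD>_<slide>_<center>_<grid>_<panel>_<x>_<y>`), with
  run-constant name/date tokens and per-read numeric tokens.
* **Roche-454**: a 14-character accession = 6-char base-36 run timestamp +
  1 randomizing hash char + 2-digit PTP region (01–16) + 5-char base-36
  well code encoding `x * 4096 + y`. The timestamp is drawn uniformly from
  all 6-char base-36 strings once per run rather than from the wall clock,
  so runs are reproducible under seeding. `y < 4096` is enforced so the
  well code decodes uniquely.
* **Ion Torrent**: `@<run ID>:<X>:<Y>`, zero-padded to five digits, with
  coordinates bounded by the chip. The P1 bounds (15456, 10656) are fixed;
  the 314/316/318 bounds are documented, overridable defaults
  (1280×1152, 2772×2284, 3392×3792), since only P1's are pinned down.

Headers may end in a ` length=<L>` appendix or an alternating `/1` `/2`
mate suffix — one or the other, never both. Read indices count up from 1.
No attempt is made to chase any specific instrument-software version's
header grammar; formats vary too much for that to be useful.

### DNA bases

Two modes. *Composition-only*: i.i.d. draws over `{A,C,G,T,N}` with
configurable probabilities — fast and constant-memory. *Repeat-planting*:
generation still runs left to right, but at `n_repeats` trigger points
(uniform over the stream, so events spread evenly) the stream is extended
by a copy of a window drawn uniformly from the already-generated prefix.
Copy sizes are uniform in `[min_size, max_size]`, truncated (never
discarded) to the available prefix and remaining capacity, so exactly
`n_repeats` events always occur. Each copy is reverse-complemented with
probability `p_reverse_complement` and then passed through a substitution
process: every base independently mutates with probability `mutation_rate`
to a uniformly chosen *different* base, which makes the expected mismatch
fraction exactly equal the configured rate — a deliberately testable
choice. Because the source may be any earlier position, copies of copies
are allowed. Every event is recorded in an annotation table
(`source_start`, `dest_start`, `length`, `is_reverse_complement`) so tests
can verify the planted structure by brute force, and
`estimate_mutation_rate()` can recover the configured rate.

Repeats are planted in one global stream that is then partitioned into
reads, so repeats span read boundaries — this is what gives whole files
long-range structure a compressor can (or cannot) exploit.

Color-space output encodes base transitions as digits 0–3 via the standard
di-base matrix (equivalently, XOR of the 2-bit codes A=0, C=1, G=2, T=3):
`{AA,CC,GG,TT}→0`, `{AC,CA,GT,TG}→1`, `{AG,GA,CT,TC}→2`,
`{AT,TA,CG,GC}→3`. By default a known anchor base `T` is prepended and
every base yields one call, as in csfasta reads; `anchor = NULL` instead
uses the first sequence base as the anchor with `len − 1` calls. Both
conventions are exposed because both are in circulation; transitions
involving `N` emit the missing-call character `.`.

### Quality scores

Qualities are position-independent draws over an arbitrary, possibly
sparse, subset of printable ASCII 33–126 (`parse_ascii_ranges("33,40-45,100")`).
Two distributions: uniform (fast), and Gaussian with mean and standard
deviation expressed in **raw ASCII-code units** — no Phred offset is
subtracted. Gaussian draws are rounded to the nearest integer and mapped
to the nearest alphabet code, ties toward the lower code (fixed, so streams
reproduce); clamping rather than rejection guarantees termination and exact
output length. `quantize_alphabet()` keeps `n_levels` codes evenly spaced
by *rank* — rank spacing composes with sparse alphabets where value-even
binning would not — and fewer levels means lower symbol entropy and smaller
compressed output. `N` positions always receive the alphabet's lowest code.

### The information profiler

`information_profile()` is the package's verification instrument: an
adaptive order-k finite-context model assigns symbol \(s_i\) the code
length \(-\log_2 \frac{c + \alpha}{C + 4\alpha}\) bits, where \(c\) counts
earlier occurrences of (context, symbol) and \(C\) of the context, counts
updating online after every symbol. Defaults k = 8, α = 1/16. Planted
repeats make symbols predictable once the model has seen their source, so
repeat destinations show up as low-information zones; `smooth_profile()`
(centered moving average, truncated at boundaries, default window 5) makes
the zones visible, and `mean_information()` summarizes a whole stream.
A single order-k model is used rather than a mixture of models of several
orders: for detecting planted repeats one high-order model suffices, and it
keeps the per-symbol cost exactly checkable against a direct product of
predictive probabilities (the test suite does exactly that with an
independent count-table implementation).

Numerical conventions: the first k symbols have no full context and are
charged the flat 2-bit uniform cost without updating counts; `N` symbols
are skipped in context formation and also charged 2 bits.

A caution on expectations: the mean adaptive code length of an i.i.d.
uniform sequence is 2 bits *asymptotically per context*. At order 8 there
are 4^8 = 65536 contexts, so even a 10^6-symbol sequence gives each context
only ~15 observations and the measured mean is ≈ 2.6 bits — model
redundancy, not a bug. Comparisons between streams (with vs without
repeats) at the same order are meaningful; the absolute level approaches
2 bits only when the order is small relative to log4(n) (order 2 at 10^5
symbols measures 2.004 bits).

## What the tests do and do not show

The test suite generates all data in code. Structural claims (accession
shape, chip bounds, four-line rules, closure of quality codes and color
digits) are checked exactly over 10^4–10^6 draws. Statistical claims use
pre-computed oracles: chi-square goodness-of-fit at α = 0.001 for
uniformity, ~4-sigma binomial/CLT intervals for rate and moment recovery,
an independent slow count-table coder for the profiler, and
`Biostrings` as a third-party cross-check for reverse complementation and
FASTQ parsing. Compressibility claims use base R's deflate
(`memCompress(type = "gzip")`).

Problem sizes in the routine suite and acceptance checks: 10^5-draw header
batches, 10^6-character quality streams, and five-seed batteries of
10^6-symbol DNA streams for the profiler and compressibility comparisons
(the profiler analysis mirrors, at one tenth the length, the 10-Mbp setting
with 350 repeats, sizes 1–3000 and mutation rate 0.1).

Two honest limitations surfaced by the five-seed deflate battery: deflate's
32 KB window cannot see a copy whose source is further back, and repeat
sources here are uniform over the whole prefix; with only 10 planted
repeats (~15 k copied bases in 10^6) the expected size reduction (~130
bytes) is below deflate's per-stream noise (±230 bytes), so a strict
non-increasing chain over repeat counts {0, 10, 100, 350} holds in only
about half of seeds. The decrease is reliable from ~100 repeats up, and
reverse-complement repeats reliably shrink output versus none. A
long-window compressor, or an order-k model like the profiler, sees the
effect at all counts.

What passing tests do *not* show: real reads are not position-independent
in quality, have platform-specific error structure (homopolymers,
position-dependent decay), diploid variation, and non-stationary base
composition. None of these are modeled — deliberately. fqsim emulates the
*format* and the *complexity profile* of sequencing data, not any
instrument's error physics; conclusions about tools that depend on
realistic error models need an empirical-model simulator instead.

## Other design choices worth recording

* Output uses LF newlines and no trailing blank line: byte-exact
  reproducibility under a seed is part of the contract.
* `repeat_buffered` mode keeps the whole DNA stream in memory to serve
  repeat sources; `low_memory` generates in ~1 Mbase chunks, is constant
  memory in the read count, and therefore refuses repeat planting. With
  `n_repeats = 0` the two modes are distributionally identical.
* Excluding line 2 is forbidden (a record must have bases); excluding
  lines 1, 3 and 4 turns the tool into a bare DNA simulator. Line 3 cannot
  repeat the header when line 1 is excluded — there is no header to repeat.
* Ion Torrent reads are not length-capped; their headers carry no
  length appendix or mate suffix.
* Read-length variability is uniform over `[min, max]`; lengths are drawn
  once per read and shared by lines 2 and 4, and a `length=` appendix
  always reports the emitted line-2 length (in color space, anchor
  included).
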