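---
title: "Evaluating scaffolders with unique sequence tags: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating scaffolders with unique sequence tags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaftag)
```

## The evaluation model

A scaffolder's task is to order and orient contigs into scaffolds using
paired reads whose fragment length constrains the distance between the
contigs each pair links. Evaluating a scaffolder honestly requires knowing
the truth: where every contig really belongs on the genome. `scaftag`
manufactures that truth and then tracks it.

The central device is the *unique sequence tag*: a substring cut from the
middle of each contig that occurs exactly once in the whole contig set and
exactly once in the reference genome, counting both strands. Because the
tag is unique, finding it in a scaffold pins down its contig's position and
orientation unambiguously — even after the scaffolder has reordered,
flipped, padded, or partially rewritten its input. The *truth layout* is
the list of tagged contigs ordered along each reference sequence; each pair
of consecutive tags on one sequence is a *potential join*, so a layout of
`n_tags` tags over `n_sequences` sequences has
`n_tags - n_sequences` potential joins.

Every consecutive pair of located tags in a scaffold implies a join, judged
by four rules applied in a fixed order:

1. tags from different reference sequences → **incorrect
   (different_sequence)**;
2. tags on different scaffold strands → **incorrect (orientation)**;
3. on shared strand `+` the truth layout index must increase along the
   scaffold, on `-` decrease → otherwise **incorrect (order)**;
4. the midpoint-to-midpoint distance between the tags in the scaffold must
   differ from their true reference distance by *less than* the fragment
   length → otherwise **incorrect (distance)**.

A surviving pair of layout-adjacent tags is a **correct join**; a surviving
pair jumping k intermediate tags is a **skipping join** with k **skipped
tags**. A tag with no exact occurrence in any scaffold is a **lost tag** —
data loss, treated as the most serious error. These counts give the five
key metrics (correct joins, incorrect joins, skipped tags, lost tags, CPU
time) plus N50 and a *corrected* N50 recomputed after breaking each
scaffold at the midpoint between the flanking tags of every incorrect
join — discounting the continuity a tool "buys" with wrong joins.

Two classification choices deserve emphasis, because the rules above leave
them genuinely open:

* **Skipping joins must satisfy the distance rule against the
  skip-inclusive true distance.** A scaffolder that omits a contig but
  leaves a correctly sized gap has made a defensible (if lossy) join; one
  that simply concatenates the flanking contigs has also misjudged the
  distance and is counted incorrect. This is the stricter reading, and it
  keeps "skipping" from absorbing distance errors.
* **Order violations are incorrect joins**, not a class of their own: a
  join whose tags are on one strand but in reversed layout order misplaces
  sequence exactly as an orientation error does.

## Tag search

The candidate tag of length l is centered: offset `floor((len - l) / 2)`,
left-biased on odd remainders, so the tag sits as far as possible from the
contig ends that scaffolders are most likely to trim or overlap. The length
ladder is 50, 100, 200, 400, 600, 1000, 2000, 5000 bp; the first rung whose
candidate is unique wins, so the chosen length is minimal on the ladder.
Uniqueness counts both strands; consequently a reverse-complement-
palindromic candidate matches its own locus twice and escalates — a rare
but safe outcome. Rungs longer than the contig are skipped, and only a
contig shorter than the first rung is tried whole. A contig with no unique
tag at any rung is excluded from the evaluation set, with a warning,
*before* scaffolding input is written, which keeps potential-join
accounting consistent; exclusion is this package's policy for an otherwise
undefined corner.

Tag location in scaffolds uses exact search in which N (the gap character)
never matches a pattern base, so a tag bridging a gap is not found — by
design, since its sequence is no longer intact in the output. A tag found
more than once (possible when a scaffolder duplicates sequence) is placed
deterministically at its leftmost occurrence in the lexicographically
smallest scaffold id, mirroring single-best-hit read mapping; treating
multi-hit tags as lost is available by ignoring the warning's hits.

## Synthetic data

Three generators produce truth-known inputs.

**Random test cases** (`build_testcase()`) emulate small scaffolding-graph
problems: contigs of random sequence (default 5 kb, uniform base
composition) arranged into paths, each path concatenated into a template
from which perfect read pairs are sampled, with per-path pair counts
`round(multiplier × coverage × template_length / (2 × read_length))` so a
path given multiplier 9 carries nine times the read-pair evidence of a
multiplier-1 alternative. The contigs are then trimmed (default 40 bp; both
ends) so every junction is a real sequence gap that read pairs must bridge.
Trimming both ends, rather than one, makes the gaps symmetric at every
junction; a single-end mode is available. Each test is generated
independently `replicates` times (default 5, seeds `seed + r`) to expose
nondeterminism in the tools under test.

**Reference tiling** (`tile_reference()`) cuts perfect contigs of length c
at starts 0, c+g, 2(c+g), … per reference sequence, dropping a trailing
partial contig. The join count is therefore a pure function of sequence
length: `floor((L + g) / (c + g))` contigs, and one fewer potential joins,
per sequence. The standard configurations are 3 kb/50 bp and 10 kb/300 bp;
on a 2.87 Mb chromosome these give 940 and 277 potential joins
respectively.

**Read simulation** (`simulate_read_pairs()`) draws a fragment start
uniformly over the template and a length from Normal(μ, σ) rounded to the
nearest integer, redrawing both when the length falls below the read length
or the fragment overruns the template — the simplest rejection scheme that
preserves near-uniform coverage. Read 1 is the fragment's first
`read_length` bases, read 2 the reverse complement of its last
`read_length` bases (FR), every base at one fixed quality (default Q40,
written Sanger-encoded). Defaults are 500 ± 30 bp fragments and 76 bp
reads; the long-fragment library is 3000 ± 200 bp. Seeded runs are
byte-reproducible.

What the generators deliberately do **not** model: sequencing errors,
quality decay by cycle, coverage bias, chimeric or circularisation-failed
mate pairs, heterozygosity, and repeats beyond those the genome sequence
itself contains. Perfect input isolates the scaffolding algorithm from the
mapper and library artefacts, so a tool's failures here are algorithmic;
conversely, success on these datasets bounds real-data performance from
above and says little about robustness to noisy libraries.

**Artificial contigs** (`artificial_contigs()`) bring real assemblies into
the truth-known frame: each assembly contig is aligned to the reference
(externally, e.g. nucmer with stringent filtering; the package consumes the
`show-coords -T` coordinate table), its overlapping reference hits are
merged transitively, and each merged interval is re-cut from the reference
forward strand. The result resembles the assembler's contigs but is
error-free and placeable. Merging unions intervals sharing at least one
base; bookended intervals stay separate, since nothing aligned across the
boundary. Hits of one contig to different reference sequences yield
separate artificial contigs, and artificial contigs from *different*
assembly contigs are never merged or deduplicated — if two end up
near-identical, the tag ladder escalates or excludes them, which is the
consistent remedy. Contigs with no hit cannot be placed and are dropped
with a warning.

## Scoring

Within one dataset, each metric is min–max scaled across tools: the best
tool scores 1, the worst 0, the rest linearly between (correct joins
higher-better; the other four lower-better). When every tool ties, all
score 1 — no tool is "worst" when none differ. Scoring consumes raw counts,
never derived percentages, so a tool that made no joins at all scores 1 on
the incorrect/lost/skipped columns and 0 on correct joins: inactivity
flatters the error metrics, visibly, rather than producing undefined rates
(its percent-incorrect is reported as NA, since the denominator — joins
made — is zero).

The summary score under weight vector w is `sum(w * s) / sum(w)`; with
equal weights this is the plain mean of the five scaled scores. Because the
relative importance of the metrics is a judgement call, the package scores
every combination from the grids — correct 10/20/40/80/160, incorrect
10/20/40/80/160, lost 20/40/80/160, skipped 10/20/40/80/160, CPU 1–5 —
subject to three accuracy-emphasising constraints: incorrect ≥ correct,
incorrect ≥ 2 × skipped, lost ≥ correct. Scalar multiples of a weight
vector give identical summaries, so vectors are normalised by their gcd and
deduplicated; over the default grids 625 valid combinations reduce to 527
canonical weightings. Normalising by gcd keeps the arithmetic exact in
integers. Each tool is reported as the distribution (min, quartiles, max)
of its 527 summaries, plus the single reference weighting
(80, 160, 160, 40, 1) that heavily penalises errors. A summary of 1 means
"not outperformed", not "ideal output".

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere inside the package; the
  only 1-based inclusive coordinates are those of the `show-coords` table
  boundary, converted on entry by `start - 1`.
* Join distances are measured midpoint-to-midpoint between tags, which is
  invariant to tag-length asymmetry and strand.
* The distance test is strict (`error < fragment length` passes); with
  several libraries in one run the default tolerance is the largest
  fragment mean — the most permissive choice consistent with a per-library
  bound.
* Exact-search hit lists are sorted by (subject, position, strand), making
  every downstream choice (e.g. the multi-hit tie-break) deterministic.
* Degenerate inputs fail loudly: empty patterns, zero-length sequences,
  tiling that yields no contigs, scaling with fewer than two tools, and
  summaries over a layout with no potential joins are all errors rather
  than silent zeros.

## Problem sizes

The test suite and the acceptance script run entirely on generated data,
sized so the full battery completes in well under a minute: a 200 kb
reference for the tile–tag–evaluate identity round trip (65 contigs, 64
potential joins), a chromosome-length (2.87 Mb) synthetic stand-in for the
tiling arithmetic, exhaustive 3-of-4-contig scaffolds (192 configurations)
against an independently coded rule oracle, 10,000 read pairs for
fragment-length recovery, and the full 527-weighting score space. These
scales exercise every code path at full fidelity because the method's
arithmetic — join counts, verdicts, scores — is size-exact, not
asymptotic.

## Known limitations

* Tag uniqueness is exact-match uniqueness; a tag duplicated with one
  mismatch elsewhere in the genome is still "unique" here, though a
  permissive read mapper might not agree.
* Artificial contigs inherit the aligner's view of the assembly: alignment
  filtering choices (minimum length and identity) change the contig set
  and hence the potential-join denominator.
* CPU time is an externally supplied number; the package does not run or
  benchmark scaffolders itself.
* The join classification assumes each located tag is a point pair; a
  scaffolder that rearranges sequence *within* a contig without destroying
  its tag is invisible to this evaluation.
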