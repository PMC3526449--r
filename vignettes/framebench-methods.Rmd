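---
title: "Reading-frame-aware evaluation of metagenomic gene callers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading-frame-aware evaluation of metagenomic gene callers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framebench)
```

## The evaluation problem

Ab initio gene callers for shotgun metagenomic reads are usually scored on
whether they call a gene at all. On short, error-containing reads that
misses the failure mode that matters most downstream: a gene called in the
**wrong reading frame** translates to nonsense protein. framebench scores
predictions at the reading-frame level, on simulated reads whose provenance
is exactly known, so that every prediction can be checked against a single
unambiguous truth.

The design rests on three ideas:

1. **One label per read, taken at the center.** Each fragment receives one
   of seven labels — F1–F3 (the three frames read in the fragment's own
   orientation), R1–R3 (the three reverse frames), or NC (noncoding) — from
   the first annotated gene overlapping the fragment's *center base*. The
   center is where the evidence available to a caller is strongest, and a
   single label gives every read a single correct answer.
2. **Indel-aware frame comparison.** Simulated insertions and deletions
   shift the apparent reading frame of everything downstream. A predicted
   frame is referenced to the beginning of the read; the annotated frame
   lives in template coordinates. The two are made comparable by the
   *cumulative indel correction*: with `s = insertions − deletions`
   occurring before the center, forward phases shift by `−s (mod 3)` and
   reverse phases by `+s (mod 3)`. Skipping this correction produces an
   artefactual decay of apparent accuracy with read length on indel data,
   because the naive frame is only valid up to the first indel.
3. **Wrong-frame calls are their own error class.** True-by-predicted
   labels are tallied into a 7×7 matrix; its cells aggregate to TP (coding,
   same frame), TN (NC/NC), FP (NC called coding), FN (coding called NC)
   and WF (coding called in a different frame), with
   `N_tot = TP + TN + FP + FN + WF` and

   - sensitivity `Sn = TP / (TP + FN + WF)`,
   - specificity `Sp = TN / (TN + FP)`,
   - positive predictive value `PPV = TP / (TP + FP + WF)`,
   - overall accuracy `(TP + TN) / N_tot`, the class-incidence-weighted
     combination of Sn and Sp.

   Ratios with an empty denominator are reported as `NA`, never coerced to
   0 or 1, and `NA` species are dropped (with a warning) from equal-weight
   species averages — coercion would silently bias the averages.

## Coordinate and tie-break conventions

Ambiguities that the frame arithmetic cannot tolerate are fixed once:

* All internal coordinates are 0-based, half-open; GFF3 and the caller
  dialects convert at the I/O boundary. This removes off-by-one ambiguity
  from every overlap and center computation.
* The center of a read of length L is `floor(L / 2)`, 0-based
  (left-of-middle for even lengths). Any fixed convention works as long as
  truth and prediction share it.
* "First annotated gene" at a position: ascending start coordinate, `+`
  strand before `-` on ties. Opposite-strand gene overlap is permitted;
  same-strand overlap is rejected.
* Reverse-strand phase is anchored at the gene's rightmost template base
  (its 5′ end on the minus strand), matching translation order.
* A deletion is logged at the read position of the next surviving base; at
  equal read positions insertions sort before deletions before
  substitutions. With these rules the error log *replays*: applying it to
  the template substring must reconstruct the read byte-exactly, and the
  test suite enforces this for every simulated fragment.
* If the center base is itself an inserted base, its label comes from the
  nearest template-derived base to its left, so every read is labelable.
  The indel tally counts insertions at or before the center and deletions
  up to that last template-derived base: this is the unique boundary for
  which `ins − del` equals the center's read-to-template offset shift
  exactly, including centers inside inserted runs.

The signs in the correction and the reverse-phase anchor were treated as
provisional until validated by the **oracle-closure test**: a
perfect-knowledge caller (emitting every true gene's indel-aware read
footprint, with the frame encoded in the start — forward — or end —
reverse — coordinate mod 3, referenced to the read beginning) must score
`Sn = Sp = PPV = accuracy = 1.0` exactly on every simulated dataset,
including 2.8% indel rates, both strands and all fragment lengths. This
single invariant pins every coordinate convention and sign in the package;
it is asserted over a 12-cell length-by-error grid with 2000 fragments per
cell in the test suite. One consequence worth noting: because a prediction
carries no separate frame field, the oracle trims a gene footprint's anchor
coordinate by up to two bases to encode the frame, exactly as real callers
trim partial codons, and footprints extend through inserted bases that
immediately follow a gene so that "prediction covers the center" coincides
exactly with "center maps into the gene".

## The simulator

The synthetic-genome generator emulates the features of prokaryotic
chromosomes that this evaluation depends on, and nothing more:

* coding fraction defaults to 0.87 (prokaryotic genomes are typically
  85–90% coding), realized within ±5 percentage points;
* mean gene length defaults to 900 bp (typical bacterial mean), gene
  lengths Poisson-distributed around it in whole codons, one stop codon
  appended;
* coding sequence is a codon-weight multinomial (default: a fixed,
  GC-biased table) with internal stop codons excluded; intergenic sequence
  is i.i.d. uniform; genes fall on either strand at random.

There is deliberately no start-codon, ribosome-binding-site or operon
structure: the *evaluation layer*, not caller realism, is under test, and a
perfect-knowledge oracle does not need realistic coding statistics. For
benchmarking real callers the same machinery accepts real genomes as
FASTA + GFF3.

Fragments are sampled uniformly (position and orientation) from the
template. The error model injects, per template base, a deletion and —
if not deleted — a substitution, and per inter-base gap an insertion, at
the configured rates; the named presets follow the standard benchmark
conditions (total indel rates 0, 0.2%, 0.5%, 2.8% split equally between
insertions and deletions; substitution rates 0, 1.5×10⁻⁵, 1.5×10⁻⁴,
1.5×10⁻³, 1.5×10⁻²). A `linear_ramp` positional profile scales all rates
along the read to emulate the rising error rates of pyrosequencing.
Calibration is verified against the closed form: at a 0.5% indel rate and
315 bp, the fraction of reads with at least one indel must match
`1 − (1 − 0.005)^315 ≈ 0.79` within three binomial standard errors over
10,000 reads.

What the simulator does **not** emulate — homopolymer-context 454 errors,
quality scores, chimeras, community abundance structure — bounds what
passing tests show: they validate the evaluation arithmetic and its
conventions on reads with known, independently drawn errors, not the
behavior of real callers on real platform-specific error spectra.

## Mock callers and parameter recovery

`oracle_caller()` is the closure fixture described above. `noisy_caller()`
degrades the oracle output with three independent, planted error rates —
miss probability, wrong-frame probability, spurious-call probability on
gene-free fragments — plus optional truncation of predictions at the first
downstream injected error. The planted rates are recovered by the metrics
(`Sn = (1−miss)(1−wrongframe)`, `Sp = 1 − fp`, WF fraction
`= (1−miss)·wrongframe`) within three binomial standard errors, which tests
the whole pipeline's calibration, not just its conventions. True
predictions score uniformly on [0.55, 1], spurious ones on [0, 0.45], so
score thresholds separate them cleanly; ROC sweeps re-run the full
center-selection pipeline per threshold (implemented via the equivalent
per-fragment score masking, since center selection always prefers the
highest-scoring covering prediction) and must be monotone, with the
unthresholded point equal to the default metrics.

## Caller output parsing

The supported interchange format is a bit-specified TSV
(`fragment_id start end strand score caller indels`, 0-based half-open,
`.` for absent values). Adapters for FragGeneScan, MetaGeneAnnotator,
MetaGeneMark (GFF), Orphelia and Prodigal (GFF3) normalize 1-based
inclusive coordinates and strand, drop scores for the tools that emit no
confidence score (MetaGeneMark, Orphelia), and carry FragGeneScan's
reported indels through to the frame computation (insertions shift the
phase by −1, deletions by +1, between the anchor and the center); a switch
(`use_reported_indels = FALSE`) ignores them. Tool output formats drift
across versions, so the adapters are best-effort and the generic TSV is the
stable contract. Malformed records are skipped, warned about and counted,
never silently dropped.

When several predictions cover the center, the highest score wins, then the
longest interval, then the smallest start. Fragments with no covering
prediction are predicted NC.

## The coding-fraction profile

`coding_fraction_profile()` reports, for each position n (1-based in
reports), the fraction of reads at least n bases long whose nth base lies
inside at least one predicted gene, together with the read-length
histogram. Overlapping predictions are unioned and strand is ignored —
the profile measures predicted coding *coverage*, not frames. The
implementation is verified against a brute-force per-read boolean mask.
With a ramped error model and the truncating noisy caller the profile
declines toward the read end, reproducing the qualitative signature of
error-disrupted gene calling near read ends; the package makes no claim
about the numeric profiles of real platforms, which require real callers
and data.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 30 kb synthetic genome
(about 29 genes), 2000 fragments per grid cell for closure checks, 5000
each of all-coding and all-noncoding fragments for parameter recovery, and
10,000 fragments for simulator calibration — sizes at which every
stochastic assertion has a comfortable (three-standard-error) margin while
a full run stays within a couple of minutes on one CPU. All randomness
flows through one seeded generator per operation call, with sub-seeds
derived deterministically from the master seed, so identical
configurations are byte-identical.

One assertion deserves a caveat. Without the indel correction, apparent
oracle accuracy at a 2.8% indel rate decays with fragment length toward the
chance plateau (the probability that the net frame shift is ≡ 0 mod 3
approaches 1/3). By 315 bp the expected number of indels before the center
(≈4.4) has already saturated the randomization, so the *expected*
difference between 315 bp and 1000 bp (~10⁻³) is far below sampling noise
at 2000 fragments; the decay is therefore asserted from 75 bp to the
plateau, and the plateau values are asserted to sit below 0.6, rather than
asserting a strict ordering between two statistically indistinguishable
points.

## Known limitations

* Single-genome runs; community structure is out of scope (multi-genome
  experiments are concatenations of runs, with species tracked through
  `species_id` for equal-weight averaging).
* Fragment sampling is linear; the origin of circular chromosomes is never
  spanned.
* The reverse-frame anchor (5′ end of the minus-strand gene) is internally
  consistent and closure-validated, but an external label set anchored at
  the other end would differ by a fixed permutation of R1–R3.
* Gene-boundary accuracy, amino-acid-level sensitivity and statistical
  comparison between callers are out of scope.

## A minimal run

```{r example, eval = FALSE}
genome <- generate_genome(30000, coding_fraction = 0.87, seed = 1)
frags <- sample_fragments(genome, 2000, 315, seed = 2)
frags <- inject_errors(frags, error_preset("indel_05"), seed = 3)
preds <- noisy_caller(frags, genome, miss_prob = 0.2,
                      wrongframe_prob = 0.1, fp_noncoding_prob = 0.3,
                      seed = 4)
ev <- evaluate_frames(frags, genome, preds)
frame_metrics(ev)
roc_curve(ev)
coding_fraction_profile(frags, preds)
```
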