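---
title: "Models and methods behind legoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind legoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legoscreen)
```

`legoscreen` models a pooled shRNA suppressor screen whose library is built
enzymatically from a subtracted transcriptome. This vignette documents the
models, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical and design choices made where the
design was genuinely open.

## 1. Enzymatic library construction

AluI cuts the blunt palindrome AG^CT. Coordinates are 0-based half-open
throughout, and a cut is recorded as the index of the C, so every
cut-flanked fragment starts with `CT` and/or ends with `AG`. Digestion is a
partition: fragment lengths always sum to the transcript length.

Each AluI site can seed **two** vectors: the right-side guide is the first
`stem_len` nt of the downstream fragment on the top strand, and the
left-side guide is the first `stem_len` nt of the reverse complement of the
upstream fragment — both therefore begin `CT`, and the extra G supplied by
the recipient vector makes the transcribed hairpin start `GCT`. Guides whose
source fragment is shorter than `stem_len` are *unrealizable* but still
count toward the theoretical maximum of `2 × sites`, because the final
ranking percentage divides by the maximally-usable-site denominator.
Transcript termini that are not AluI cuts never yield vectors: adapters
ligate at cut ends only.

The default guide length is 20 nt, the MmeI arithmetic (18 bp of cDNA plus
a 2-nt overhang); 19 nt is accepted for the shorter inverted-repeat variant.
The double-stranded insert released by the simulated BpmI step is

```
[arm] [stem 20] [adapter-C core 51, incl. 9-nt loop] [revcomp stem 20] [arm]
```

with AG overhangs (the ligation partners of the CT overhangs on the
prepared recipient backbone). Published adapter base sequences are not part
of the model; the adapter arms are free parameters constrained by the
91-bp insert identity `2·arm + 2·stem + core = 91`. The default residual
arm is 0 — BpmI cuts exactly at the cDNA–adapter junction — which fixes the
adapter-C core at 51 nt; the core beyond the loop is the portion a later
BsgI step (16-bp offset) trims from the final vector. Synthetic core/arm
filler uses an A/C alphabet so no spurious AluI site or loop match can
arise. The loop defaults to the classic 9-nt hairpin loop `TTCAAGAGA`.

## 2. Hybridization kinetics

Re-annealing of melted cDNA follows second-order kinetics. Writing `u` for
the total single-stranded concentration of one species (tester + excess
driver, `c = t + E·d`), `du/dτ = −k·u²`, and the adapter-ligated tester is
the constant fraction `t/c` of it, giving the closed form

`s(τ) = t / (1 + k·c·τ)`.

The tests integrate the underlying ODE system numerically (deSolve) and
require agreement with the closed form to a relative tolerance of 1e-6 over
a 100-point grid. Two qualitative consequences are also asserted: the
coefficient of variation of `s` across equally expressed species is
non-increasing in time (normalization), and the enrichment of a
tester-specific species grows with driver excess across 1 → 35 → 60.

Choices made where the protocol is silent:

* **Rate constant `k`** has no published value. The default `k = 0.25` per
  concentration-unit per hour makes `k·c·τ₁ ≈ 10` for a unit-abundance
  species over the 45-h first hybridization: abundant shared fragments are
  strongly, but not completely, removed.
* **PEG** enters purely as a rate multiplier in the 24-h second
  hybridization (crowding raises the effective concentration); multiplier 0
  reproduces the no-PEG failure (no amplifiable material). No
  volume-exclusion physics is modeled.
* **Cross-hybridization** between distinct fragments is ignored; the kinetic
  argument is per fragment.
* **Suppression PCR** is composition-preserving exponential amplification of
  A–B duplexes only; polymerase saturation is not modeled. The second-order
  A+B→AB closed form is evaluated with an equal-concentration series branch
  and an overflow-safe limit for large rate·time.

## 3. The synthetic screen generator

`screen_scenario()` fixes the study conditions; its defaults are the
conditions the rest of the package is tested under:

| parameter | default | rationale |
|---|---|---|
| transcripts | 200 | desk-scale transcriptome |
| transcript length | uniform 2000–4000 nt | mean ~3 kb ⇒ ~23 theoretical vectors per transcript, matching the ~25 vectors/transcript complexity of enzymatic libraries |
| planted suppressors | 10 | |
| suppressor repression in drivers | uniform 2–6 fold | comfortably above the 1.66-fold flag threshold |
| knockdown of functional vectors | uniform 40–80 % | the measured efficacy range |
| nonfunctional vector fraction | 2/11 | 9 of 11 calibration vectors worked |
| transformation threshold | 50 % knockdown | a vector transforms only if it silences its suppressor target at least this far |
| library complexity | 150,000 cells | colony count of the cloned library |
| growth boost | 50× per round | free parameter: colony growth vs single-cell carryover; the protocol does not quantify it |
| rounds | 2 | a mobilized library is re-screened |
| reads per sample | 100,000 | desk-scale deep sequencing |
| per-base error rate | 0.002 | typical short-read substitution rate |
| driver excess | 60 | optimum found in the calibration series |

Sequences are uniform ACGT, so AluI sites arrive at the binomial rate
(1/256 per position) — verified against the analytic expectation. Reads are
`flank + G + guide + loop + revcomp(G + guide) + flank` with independent
substitution errors; counts are multinomial (overdispersion is not modeled
— a negative-binomial option would be the natural extension).
Off-target transformation is a per-vector Bernoulli, default 0, so the
false-positive behavior of the dual-library criterion can be studied
separately. All randomness flows from the single scenario seed; runs are
byte-reproducible.

What the generator does **not** emulate: retroviral multiplicity of
infection, colony geometry and size variation, PCR duplicates and chimeras,
quality-score structure, real transcriptome homology families (beyond what
clustering tests construct explicitly), and genome-scale transcript counts.
Passing tests therefore demonstrate internal consistency of the method
under its own model, not performance on real screening data.

## 4. Deconvolution and calling

Tag extraction finds the 9-nt loop — exactly via a fast fixed-pattern
search, else by a positional scan allowing one loop mismatch — and accepts
a read iff total mismatches across loop and stem/revcomp-stem comparison
are ≤ 1 (the *joint* reading of the one-mismatch allowance; the allowance
is configurable). The informative span is thus `2·stem + loop` = 49 nt, and
observed acceptance matches the binomial ≤1-error probability at the
configured error rate within 3σ at a depth of 100,000 reads. With two
stems as the only evidence, a single stem disagreement is a 1–1 tie, which
the upstream base wins: the canonical tag is the upstream stem read 5'→3'.
Tags within Hamming distance 1 of a ≥10×-more-abundant tag are absorbed
into it (disable with `ratio = Inf`); tags absent from the expected catalog
are retained — the stage is reference-free.

Counts are normalized to 1e6 per sample. The enrichment ratio uses a
0.5-cpm pseudocount so vectors appearing from zero remain callable, and the
transforming call is strictly `> 3`. Both selection rounds are computed;
the default contrast is pre-selection vs the final round.

## 5. Mapping, clustering, set cover

The transcript database drops entries with more than 500 AluI sites
(repetitive sequences) and indexes every realizable guide for exact O(1)
lookup; a mismatch-tolerant scan (both strands, optionally not requiring
the AluI-cut context) covers degraded inputs. Pairwise transcript identity
is computed by local alignment (Biostrings); sequences with ≥95 % identity
over the aligned span covering ≥90 % of the *shorter* sequence
(single-sided coverage) are linked, clusters are connected components, the
representative is the longest member (ties by id), and clusters whose
members carry ≥2 distinct gene labels are flagged ambiguous and later
removed, since multiple gene copies defeat unambiguous target
identification.

The minimal explaining cluster set is an exact minimum set cover found
breadth-first over subset sizes 1, 2, …; ties prefer more total explained
tags, then the lexicographically smallest id vector. Above 24 candidate
clusters the exact search is replaced by a greedy cover with a warning —
in practice the candidate set after mapping is far smaller. Correctness is
tested against exhaustive enumeration on 1,000 random instances of up to 12
clusters.

The AluI-coverage filter runs *after* the cover (the order the procedure
lists its steps; configurable in principle): a cluster survives iff
`distinct transforming tags / (2 × AluI sites of the representative)`
strictly exceeds 15 %. The theoretical denominator is the default; the hit
table also reports the realizable-vector denominator, because for some
transcripts a published percentage is only consistent with counting
realizable vectors.

## 6. Hit calling and ranking

A suppressor needs ≥3 distinct transforming vectors — distinct
(site, side) pairs, not distinct read sequences — in *each* of the two
libraries. The percentage is rounded half-up to an integer *before*
multiplication, because the published scores are exact integer products of
the printed columns (e.g. 14 × 78 = 1092). Sorting is by descending score,
then descending percentage, then stable input order; a stable sort is what
reproduces the published ordering of the three equal-score rows, which an
alphabetical tie-break would not. Expression flags (repressed in either
transformed genotype, induced on anchor loss) use the strict >1.66-fold
rule; a fold of exactly 1.66 is not flagged.

## 7. Problem sizes and determinism

The test suite runs the full pipeline at 30–50 transcripts and
15,000–30,000 reads per sample, plus one default-scale run (200
transcripts, 6 × 100,000 reads) for the recovery property; these sizes keep
the suite comfortably within a few minutes while exercising every stage at
realistic per-transcript vector counts. Every stochastic stage consumes the
single scenario seed; identical configuration yields byte-identical FASTA,
FASTQ and hit tables, which the tests assert.

## 8. Known limitations

* Kinetics are per-species; sequence-dependent melting, mismatch hybrids
  and fragment-length effects are not modeled.
* Multinomial counting understates overdispersion of real selection.
* The mismatch-tolerant mapping path is a linear scan — adequate for
  desk-scale databases, not for a full transcriptome with mismatches.
* Exact set cover is exponential in the worst case; the >24-cluster greedy
  fallback trades optimality for boundedness and warns when it engages.
* The generator's uniform-composition transcripts underrepresent repeat
  structure, so the >500-AluI-site database filter is exercised by
  constructed cases rather than arising naturally.
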