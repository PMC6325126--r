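---
title: "EndoV cleavage scoring: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EndoV cleavage scoring: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endovseq)
```

## The assay and the signal

Adenine base editors (ABEs) deaminate adenine to inosine inside a narrow,
PAM-distal "deamination window" of the protospacer (modelled here as
positions 4–8, counted from the PAM-distal end). When genomic DNA is
treated in vitro with an ABE and then with Endonuclease V — which cleaves
the phosphodiester backbone just 3′ of deoxyinosine — every deaminated
target acquires two nicks on opposite strands:

* the EndoV nick on the **edited strand**, immediately 3′ of the inosine
  (inter-base coordinate `protospacer_start + edited_A_offset + 1`, with
  `edited_A_offset` 0-based), and
* the nCas9 (D10A) nick on the **opposite strand**, between protospacer
  positions 17 and 18, i.e. 3 bp from the PAM.

The pair of nicks is a staggered double-strand break. For a 20-nt
protospacer and window positions 4–8 the stagger is
`16 − edited_A_offset` = 9–13 bp. After fragmentation and blunt-end
repair, both cut coordinates surface in whole-genome sequencing as
columns of reads with identical 5′ ends: forward reads all starting at
the lower cut coordinate, reverse reads all ending at the higher one.

## The cleavage score

For every genomic position *i* the package tallies sequencing depth
`D[i]`, forward-strand read starts `F[i]`, and reverse-strand read 5′
ends `R[i]`. The per-position score is

$$
\sum_{\alpha=1}^{5} \frac{F_i-1}{D_i}\,\frac{R_{i+8+\alpha}-1}{D_i}
  \,(F_i+R_{i+8+\alpha}-2)
\;+\;
\sum_{\alpha=1}^{5} \frac{R_{i+11}-1}{D_{i+11}}\,
  \frac{F_{i-3+\alpha}-1}{D_{i-3+\alpha}}\,(R_{i+11}+F_{i-3+\alpha}-2)
$$

implemented exactly as printed, with two numerical conventions:

* an α-term with a zero denominator contributes 0 (an uncovered position
  carries no evidence), and
* with the default clamping (`min_start_reads = 2`), an α-term whose
  start counts do not both reach 2 contributes 0 — a lone read end is
  noise, and the negative "evidence" the raw algebra assigns to counts of
  0 or 1 is an artifact.

The α window pairs pileups 9–13 bp apart, which is exactly the stagger
range of a 20-nt protospacer. For an 18-nt guide the stagger is
`14 − edited_A_offset` = 7–11 bp, so edits at window positions 7–8 are
structurally invisible to the printed equation; this is a property of
the score, not of the implementation, and it is why the bundled
validation worlds use 20-nt guides.

### The reverse-read coordinate convention

The score's offsets only cohere if `R` is recorded at the *half-open end
coordinate* of a reverse read (the inter-base cut position 3′ of the
rightmost aligned base): a blunt fragment boundary at cut coordinate *c*
then places forward starts and reverse ends at the same *c*, and the
F/R pileups of one cleavage event sit exactly one stagger (9–13 bp)
apart, matching the α window. This is the package default
(`reverse_five_prime = "nick"`). The alternative of recording the
rightmost covered base (`"base"`) shifts every separation to 8–12 bp,
systematically missing the widest window position; it is kept as an
option for comparison only.

A consequence worth knowing: with the `"nick"` convention
`R[i] ≤ D[i−1]` rather than `R[i] ≤ D[i]` (a read ending at nick *i*
covers base *i − 1*).

### Scan strategy

With clamping on, only positions where `F[i] ≥ min_start_reads` or
`R[i + 11] ≥ min_start_reads` can score positive, so only those are
evaluated; the result is provably identical to a dense scan (the test
suite checks this against a naive loop transcription of the equation on
random count arrays). Without clamping the package falls back to a dense
scan over covered positions.

## Site calling and annotation

Above-threshold positions within `merge_window` (default 20 bp, one
protospacer+PAM footprint) merge into one site, represented by the
maximum-scoring position (ties leftmost). The two summations peak at the
forward-pileup coordinate and ~2 bp away, so one cleavage event yields
one merged site whose representative lies within 2 bp of the
lower-coordinate nick. The published analysis used thresholds of 2.5
(stringent) and 0.1 (sensitive); calling at 0.1 always yields a superset
of the 2.5 calls.

Annotation scans all protospacer+PAM windows on both strands within
`search_radius` (default 25 bp — stagger plus merge slack) of a site,
preferring PAM-bearing windows (IUPAC patterns, so NG or GAA-style PAMs
are expressible) and minimising Hamming mismatches, with ties broken by
distance to the site and then the forward strand.

## Multiplex allocation

In a multiplex digestion one library carries several guides; captured
sites are attributed afterwards by Levenshtein edit distance (unit
costs) between the site's matched protospacer and each guide's target
string, smallest distance wins, ties flagged and broken by guide order.
Distances default to protospacer-only comparison; `include_pam = TRUE`
appends each target's concrete genomic PAM. The matrix summary reports
the maximum and the mean over the 15 distinct off-diagonal pairs — the
zero diagonal ("each site against itself") is excluded, which is how the
published mean of 13.1 alongside an explicit "0 on the diagonal" reads.

The six bundled multiplex guides are a **reconstruction from the primary
literature** of these much-used target sites (the authoritative
per-experiment strings were published only as supplementary material and
are not redistributed here; the file is named `*_synthetic.tsv`
accordingly). With PAMs included the reconstruction reproduces the
identity of the published maximum pair (HBG–FANCF) but not its magnitude
(15 vs 17.0; mean 12.13 vs 13.1) — a known, documented gap that would
close by replacing the TSV with the authoritative sequences.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults restate the wet protocol: 400–500 bp fragments
(Normal(450, 30), truncated at 50 bp), 30–40× coverage (default 35×),
150 bp reads, and a human-like GC content of 0.41 for the random
reference. `plant_and_simulate()` writes one exact on-target plus
mismatched off-targets per guide into the reference (mismatch positions
biased PAM-distal, linearly weighted, matching the observed off-target
motif structure), assigns each site an edited A among the window
adenines, and derives both nick coordinates from the geometry above.

Molecules are fragmented at random; a fraction `cleavage_fraction` of
molecules spanning a planted site is split there. The two staggered
nicks leave 5′ overhangs, and end repair fills them in, so the upstream
fragment ends at the *higher* cut coordinate and the downstream fragment
starts at the *lower* one — both fragments retain the 9–13 bp between
the nicks, and each cut surfaces as one forward-start and one
reverse-end pileup. `cleavage_fraction` defaults to 1.0: the published
in vitro digestion is described as essentially complete (the Sanger G
peak at deaminated sites disappears after EndoV treatment). It is a free
parameter because per-molecule efficiency was never quantified.

Deliberately **not** modelled: sequencing errors and base qualities
(the score consumes only coordinates), PCR duplicates, GC bias,
real-genome repeat structure, and partial/resected overhang processing.
A green planted-site recovery test therefore establishes that the
scoring chain detects ideal staggered-break pileups over Poisson-like
background at the stated depth — not that it is robust to mapping
artifacts or library chemistry quirks.

`mix_datasets()` reproduces the dilution control: treated reads are
subsampled to `1/dilution_factor` of the library and topped up with
untreated reads. Planted-site scores fall monotonically with dilution
(roughly quadratically, since both the F and R factors shrink while
depth is constant), remaining comfortably above the 0.1 sensitive
threshold at 2.5-fold and collapsing towards it by 5–10-fold, which
mirrors the published dilution behaviour qualitatively.

## Validation worlds and their parameters

* **Recovery**: 1 Mb genome, 35×, 20 planted sites (five 20-nt guides ×
  (1 on-target + 3 off-targets, 1–3 mismatches)), cleavage 1.0,
  threshold 2.5, 10 seeds. Expected: ≥95% of planted sites called
  within 25 bp, zero calls elsewhere. Measured in the suite: 100%, 0.
* **Dilution**: 0.5 Mb, 35×, dilutions 1/2.5/5/10, 3 seeds; the median
  planted-site score must be strictly decreasing.
* **Scoring oracle**: 500 random small count arrays against a naive
  transcription of the equation, plus the hand-computed single-pileup
  value `(9/20)·(9/20)·18 = 3.645`.

Genome sizes were chosen to keep the whole suite under a minute while
leaving ≥50 fragments per planted site; they scale the published
experiment down (30–40× human WGS) without changing any rate, depth or
fragment-length parameter.

## Degenerate inputs and tie-breaks

* Empty SAM, empty track, empty site list: empty results, never errors.
* Reads beyond chromosome bounds or on undeclared chromosomes: errors
  naming the offending read.
* Duplicate guide names: error; identical guide sequences: allowed,
  produce flagged allocation ties.
* `which.max` semantics give the leftmost maximum everywhere a
  representative must be chosen.
* PAM degeneracy in distance comparisons is resolved to a fixed
  representative base, so distances stay deterministic.

## Known limitations

* The cleavage score is used exactly as printed, including the
  `D_i · D_i` denominator of the first summation (a `use_offset_depth`
  toggle provides the plausible `D_{i+8+α}` alternative).
* Scores are not normalised across samples; thresholds are absolute.
* The allocator is winner-takes-all; no probabilistic assignment.
* The bundled guide set is a reconstruction (see above); conclusions
  about the published matrix magnitudes should not be drawn from it.
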