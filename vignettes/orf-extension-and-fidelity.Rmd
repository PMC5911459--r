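---
title: "Upstream start-codon re-annotation and lacZα fidelity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upstream start-codon re-annotation and lacZα fidelity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfex)
```

## The problem

Automated prokaryotic gene annotation usually selects the start codon that
gives the longest ATG-initiated frame. In many archaea this is wrong often
enough to matter: in *Aeropyrum pernix*, proteome-scale work has shown TTG
to be the most frequently used initiator (more than half of detected
proteins), ahead of ATG and GTG. A misplaced start truncates the predicted
protein's N-terminus, and the missing residues can be functionally
decisive — the *A. pernix* replicase PolB3 gains its remarkable
thermostability only with its 19 upstream residues restored, and PolB1's
database annotation is 58 residues short of the protein detected in cell
extracts.

`orfex` implements the two quantitative procedures behind such a
re-annotation study as reusable, tested components: the upstream in-frame
start scan with Shine–Dalgarno (SD) evidence, and the lacZα blue/white PCR
fidelity statistics used to benchmark the resulting enzymes.

## The upstream scan

For a gene with annotated start position $s$ on its coding strand, the
scanner inspects codons at $s-3k$ for $k = 1, 2, \dots$ in the same frame.
Walking upstream, it:

* records every codon in the allowed initiator set (default
  `ATG, GTG, TTG`; the polB-style analysis uses `TTG, GTG` upstream of an
  annotated ATG);
* terminates at the first in-frame stop codon (TAA/TAG/TGA), at the window
  limit `max_extension_codons` (default 200 codons — larger than any
  plausible missed N-terminus, while keeping runtime bounded), or at the
  edge of a linear genome;
* treats any codon containing `N` as unknown: it matches neither the start
  nor the stop set, never terminates the scan, and is surfaced as a
  warning. This is deliberately conservative for draft assemblies.

A candidate at extension $k$ adds $k$ codons to the open reading frame,
the candidate initiator itself counted as one residue; this is the
counting under which the polB1 TTG/GTG candidates measure 58 and 36 added
amino acids and the polB3 TTG candidate measures 19. Candidates at the
annotated start itself are never emitted — the annotated form is the
baseline. The scan is purely sequence-based: overlapping upstream gene
annotations do not stop it (a design choice that mirrors how the original
candidates were found), and minus-strand genes are handled by the exact
strand-symmetry contract tested in the suite: scanning a minus-strand gene
equals scanning the plus-strand gene on the reverse-complemented genome
with mirrored coordinates.

The "chosen" form of a gene is its most upstream candidate, by analogy
with the long (L) recombinant constructs; its translation uses the
standard genetic code with the initiator reported as methionine (initiator
tRNA delivers Met regardless of whether the codon reads ATG, GTG or TTG),
and the literal translation of the initiator codon is retained in a
separate field.

### Coordinates

Internally, all features live on 0-based half-open plus-strand intervals
with a strand flag; GFF3 (1-based inclusive) and GenBank
(`complement(a..b)`) locations are converted at the boundary, and TSV
reports print 1-based positions. One internal convention eliminates the
usual off-by-one error classes, and the round-trip (write GFF3, read it
back, identical coordinates) is tested. FASTA genomes default to linear;
circularity must be declared (or come from a GenBank LOCUS line), because
silently wrapping coordinates would manufacture phantom upstream
extensions. On declared-circular genomes upstream extraction wraps
modulo the genome length.

GenBank flat files are read by a minimal parser scoped to exactly what
the pipeline needs — LOCUS topology, ORIGIN sequence, and CDS
location/locus_tag — since the package's remit excludes general feature
handling; `join()` locations are skipped with a warning.

## Shine–Dalgarno evidence

*A. pernix* structural genes typically carry an SD box between positions
−15 and −4 relative to the initiation codon (position −1 being the base
immediately 5′ of it), and show a distinct enrichment of G at position −3.
For every candidate start — not merely per gene, since each proposed
initiation site has its own ribosome-binding context — the package scores:

* `find_sd()`: the best ungapped alignment of a consensus (default
  `GGAGG`) within −15..−4, scored as the longest run of consecutive
  identities, ties broken toward the more upstream alignment; matches
  below `min_score` (default 4) are reported as absent.
* `g_at_minus3()`: whether position −3 is G.

The scoring function is a design choice: no standard definition exists
for calling a "putative SD" by eye from a figure, and a 16S rRNA
anti-SD hybridisation free-energy model would be unverifiable against the
motivating annotations. The longest-identity-run scheme is the simplest
deterministic scheme that behaves sensibly for short purine-rich boxes,
and both the consensus and the threshold are configurable. Upstream
windows shorter than 15 bases (genes near a linear genome's edge) are
scored over what exists and flagged `truncated`.

## The fidelity statistics

In the lacZα assay, a 483-bp fragment containing the lacZα gene is
amplified, re-cloned, and plated on X-gal/IPTG; mutations within the
345 bp required for α-complementation turn colonies white or pale blue.
With mutant count $m$ out of $N$ colonies:

$$\mathrm{mf} = \frac{m \cdot c}{N}, \qquad
  2^d = \frac{\text{product}}{\text{input}}, \qquad
  \mathrm{ER} = \frac{\mathrm{mf}_{\text{sample}} -
  \mathrm{mf}_{\text{background}}}{\mathrm{bp} \times d}$$

where $c$ is the fraction of white colonies confirmed (by colony PCR) to
carry an insert, `bp = 345`, and `d = 12` template doublings for the
benchmark conditions. The background row — re-ligated unamplified vector —
is subtracted to remove cloning and plating artefacts. Replicate groups
are summarised as mean ± **population** standard deviation (divisor $n$):
this is the convention under which the published group spreads
(0.5 × 10⁻⁵ and 1.6 × 10⁻⁶) are reproduced from the per-replicate rates;
the sample SD (divisor $n-1$) does not reproduce them.

Two reporting choices deserve mention:

* **Published mf values versus raw counts.** In the packaged benchmark
  table, the per-replicate mutant frequencies printed for the polymerase
  samples are systematically below the raw ratios (e.g. 966/9810 = 0.0985
  against a printed 0.0896), implying a confirmed-insert correction whose
  exact per-row value is not recoverable. The package therefore never
  invents it: `confirmed_fraction` is exposed for users who know it, the
  table's `mf_override` column feeds the published values through
  unchanged, and downstream error rates are reconstructed from those
  published frequencies. One consequence is visible in the two smallest
  PfuPolB rates, where the published values were evidently computed from
  unrounded frequencies: reconstruction from the rounded mf column gives
  2.4 × 10⁻⁷ and 1.7 × 10⁻⁷ against published 2.5 × 10⁻⁷ and 1.9 × 10⁻⁷ —
  rounding propagation, which the test suite documents rather than hides.
* **Negative error rates** (sample mf below background) are returned
  as-is with a warning, never clamped: they are a quality-control signal.

Display rounding follows assay convention — mf to 4 decimals, ER to 2
significant figures — while JSON outputs keep full precision.

## What the synthetic generator emulates

`generate_genome()` plants gene cassettes in random background sequence
(uniform base composition with a GC knob; a GC of 0.56 approximates the
GC-rich *A. pernix* genome). Each cassette is built so the truth is
unambiguous by construction:

* codons inside a planted extension are drawn from the 58 codons that are
  neither stops nor initiators, so the planted candidates are exactly the
  candidates present;
* an in-frame stop barrier sits just beyond the most upstream planted
  candidate (or immediately upstream of the annotated ATG for "no
  extension" genes), so scans terminate where the truth says they should;
* an SD consensus can be overlaid at a chosen offset in the −15..−4
  window of the planted candidate, with rejection-resampling so the
  overlay never creates an accidental start or stop in frame.

`simulate_colony_counts()` draws each colony as an independent Bernoulli
trial with success probability
$\mathrm{ER}_{\text{true}} \times \mathrm{bp} \times d +
\mathrm{mf}_{\text{background}}$ — exactly the model under which the point
estimator is unbiased. Parameter-recovery tests (200 simulated assays at
2.6 × 10⁻⁵, five replicates of 10,000 colonies each, estimate within three
Monte-Carlo standard errors of truth) therefore validate the estimator's
implementation, not the biology: no transformation bottlenecks, ligation
biases, plaque-size effects or mutation spectra are modelled, and passing
them says nothing about such effects in real assays.

The same honesty applies to `synthetic_polb_loci()`: it reconstructs the
*architecture* of the two re-annotated *A. pernix* polymerase loci (TTG at
−58 and GTG at −36 codons for the polB1-like gene; TTG at −19, on the
minus strand, for the polB3-like gene; SD boxes in window) in random
background, because the study genome itself is not bundled. Tests against
it validate the scanner and the extension-counting convention, not the
real assembly; to analyse the real genome, point `cmd_extend()` at a
downloaded copy of the assembly and its annotations. For traceability,
every pipeline run records the md5 checksums of its input files in
`run_record.json`, so results can always be tied to one assembly revision.

## Numerical and degenerate-input choices

* Scan window 200 codons by default; enlarging it can only add candidates
  (a tested monotonicity property).
* Extraction short of the requested window (linear edge) is legal and
  returns what exists; an incomplete upstream codon ends the scan.
* SD ties break toward the more upstream alignment; identical inputs give
  identical output, including tie-breaks.
* A CDS whose length is not a multiple of 3 is flagged and kept — dropping
  it would hide the annotation problem the package exists to find. An
  internal stop in the annotated frame is a per-gene error, reported with
  the offending codon index; in batch mode the gene is flagged and the
  batch continues.
* All generator and simulator outputs are pure functions of their seed.
* Test problem sizes — 300-gene oracle sweeps in the unit suite, a
  1000-gene sweep plus 200 simulated assays in the end-to-end checks —
  were chosen to make the binomial comparisons decisive while keeping the
  default suite fast.

## Known limitations

* Start-codon evidence here is purely sequence-based. Homology support
  (alignment of N-terminal regions across related genomes), ribosome
  profiling, and proteomics are out of scope, as are leaderless
  transcripts and non-SD initiation mechanisms.
* The SD detector is a consensus matcher, not an energy model, and its
  default consensus is a configurable convention, not a fitted motif.
* The fidelity statistics are the assay's point estimates; a binomial
  confidence interval on mf can be had from standard tools, but no
  Poisson/Bayesian error modelling is attempted beyond them.
* Colony classification (white versus pale versus blue) is wet-lab work;
  counts are taken as given.
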