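---
title: "Interdomain linker analysis for CDH-like flavocytochromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interdomain linker analysis for CDH-like flavocytochromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkerscape)
```

## The problem

Cellobiose dehydrogenase (CDH) carries its catalytic FAD in a
flavodehydrogenase (DH) domain and shuttles electrons out through a mobile,
heme-*b*-binding cytochrome (CYT) domain. The two domains are connected by a
flexible interdomain linker, and the rate of interdomain electron transfer —
and of direct electron transfer to electrodes — depends on how freely the CYT
domain can swing between a docked, closed state and an open state. The linker
is therefore an engineering target, but "the linker" first has to be defined
reproducibly across a diverse sequence family.

`linkerscape` implements a *function-based* linker definition and the
analyses built on top of it:

* the linker starts at the conserved Tyr that initiates the last C-terminal
  helix of the CYT domain (the **anchor**; Tyr195 in *N. crassa* CDH IIA
  numbering) and ends with the conserved **Tyr/Phe-Asp-Tyr** motif that packs
  against the DH domain (229–231);
* inside that span, three segments are distinguished: the **N-attached**
  segment (anchor helix through the conserved CYT-attachment Cys, Cys211 in
  reference numbering), the **mobile** segment (Gly/Ser/Thr-rich, the part
  that actually stretches), and the **C-attached** segment (from the
  Pro-Val-Pro or Cys DH-attachment motif to the end motif).

## Annotation procedure and its tunables

`annotate_linker()` runs five deterministic steps: anchor propagation from a
trusted reference by pairwise alignment, end-motif search in a window, Cys
search, DH-attachment search, segmentation. The tunables live in
`annotation_params()`:

* **End-motif window `c(15, 80)`** (offsets from the anchor, residues).
  Observed linkers measured anchor-to-motif-end almost all fall between 30
  and 60 residues; the window pads that range on both sides so unusual but
  real linkers are still found while unrelated downstream `[YF]DY` hits are
  excluded.
* **Cys search depth 20.** The CYT-attachment Cys sits at anchor+16 in the
  reference; 20 covers it with slack without reaching into typical mobile
  segments.
* **N-attached fallback 6.** When a family lacks the CYT Cys, the N-attached
  segment defaults to the anchor helix, which comprises the anchor plus four
  or five residues; 6 is used as the upper bound. The exact C-terminal extent
  of that helix is not defined by sequence alone — this constant is a package
  choice, exposed as a parameter.
* **Anchor rescue ±3.** If the alignment-mapped column is not a Tyr, the
  nearest Tyr within three positions is accepted; beyond that the annotation
  fails loudly rather than guessing.
* All motif scans take the *first* (leftmost) occurrence, matching the
  definition of the attachment motif as the *start* of the next segment.

Failures (no anchor, no end motif, degenerate segmentation — e.g. when a
sequence lacking the CYT Cys would yield an empty mobile segment) are encoded
in the annotation's `status`, never thrown, so one bad record cannot abort a
set.

### The bundled reference is synthetic

Anchor propagation needs one trusted, annotated sequence. The package ships
`cdh_reference()`, a deterministic **synthetic** NcCDHIIA-like construct: it
places every landmark documented for *N. crassa* CDH IIA in wild-type
numbering (Tyr195, Cys211, Thr215–217, Ile218, Pro-Val-Pro at 222–224,
Tyr-Asp-Tyr at 229–231, Asn459, Val806) inside domain cores made of fixed,
pseudo-random, motif-free filler (no Cys/Tyr/Phe/Pro, so the filler can never
forge an anchor, attachment or end motif, and no repeats that would make
alignment registers ambiguous). It is *not* the natural sequence: landmark
positions are real, domain content is not. Everything the package reports
about it — and about the matching synthetic closed-state structure from
`gen_cdh_structure()` — is a statement about the machinery recovering planted
landmarks, not a measurement on the crystal structures. Users with the real
4QI6/4QI7 entries can build a `reference_annotation()` from them and pass it
everywhere a reference is accepted.

```{r}
ann <- annotate_linker(cdh_reference()$record)
ann
```

## Composition statistics and logo matrices

`profile_composition()` uses the three-way residue partition: hydrophilic
(S, T, E, D, N, Q, H, K, R), hydrophobic (A, V, L, I, Y, F, W, M) and
potentially structural (G, P, C). An alternative convention omits Met from
the hydrophobic set, but that leaves a 19-residue partition; the package uses
the complete 20-residue partition. `X` is excluded from denominators and
tallied separately.

`frequency_matrix_with_ic()` computes per-column frequencies over non-gap
residues and the information content `IC = log2(20) − H` in bits, with
stacked-letter heights `f · IC`. No small-sample correction is applied by
default (the intended inputs are large family alignments); pass
`small_sample_correction = TRUE` for small sets. Columns with under 50%
coverage are flagged rather than dropped. Histogram bin edges default to
`seq(20, 80, 10)` — source figures do not state their bin widths, so the
edges are a package choice covering the observed 30–60 range with margin.

## Similarity-network grouping

`build_network_and_group()` scores all pairs by optimal local alignment
(BLOSUM62, affine gaps open 11 / extend 1 — a gap of length *k* costs
11 + *k*), converts scores to E-values with the standard gapped-BLOSUM62
Karlin–Altschul constants (λ = 0.267, K = 0.041) over the pairwise search
space *m·n*, draws an edge when `E ≤ threshold` (default `1e-10`, the
documented grouping threshold, read as an E-value in the convention of SSN
tools), and labels connected components of size ≥ `min_group_size` in
descending size order, ties broken by smallest member id. Local alignment is
used for scoring because similarity networks score shared segments; global
alignment is reserved for coordinate propagation during annotation. Unknown
residues (`X`) score 0 against everything. `threshold_sweep()` re-thresholds
a computed edge table without re-aligning; raising the threshold can only
merge components, never split them, which the tests assert.

The original group memberships of the published family snapshot are not
reproducible without that database snapshot; the package reproduces the
*procedure* and validates it on synthetic families with known group truth.

## Variant design

`apply_variant()` takes edits in wild-type numbering, validates all of them
against the wild-type sequence before applying any (substitutions name their
expected wild-type residue; overlapping edits are rejected), and returns the
edited sequence with a wild-type→variant coordinate map and the theoretical
average-isotopic mass (standard residue masses + 18.0153 Da; the ProtParam
convention). `invert_variant()` reverses any edit set through the coordinate
map; round-tripping every catalog variant back to the wild type is part of
the test suite.

The built-in `variant_catalog()` holds the seven engineering variants:
LNK−1 deletes Thr215; LNK−2 and LNK−4 delete 215–216 and 215–218 (the
single-residue site is documented, the longer deletions are taken as
contiguous mobile-linker deletions anchored there — an assumption, flagged
here); LNK+4/LNK+8 insert two/four Ala-Thr repeats at the Thr216/Thr217
junction; LNK_S=S introduces I218C + N459C; LNK_S=S+4 combines both. Under
the +4 insertion, wild-type 218 maps to variant 222; the catalog keeps this
arithmetic consistently (a published mention of "I223/N464" in a homology
model implies +5 and is treated as a typo).

`design_disulfide_pairs()` screens cross-region Cα–Cα distances (cutoff
7 Å). Cα rather than Cβ/Sγ keeps the screen robust to missing side-chain
atoms; it is a geometric pre-filter, not an energy model.

## Pull-trajectory metrics

Steered-pull simulations stretch the linker until the pulled CYT domain
itself starts to deform; distances measured after that point reflect domain
unfolding, not linker extension. `analyze_pull()` therefore smooths each
channel (Savitzky–Golay, window 101, order 2), finds the first frame where
the smoothed CYT distortion (distance from the CYT center of geometry to the
Cα of the attachment Cys) reaches the cutoff (default 11 Å), and reports the
maximum interdomain COG distance and tracked-pair distance range strictly
before that crossing. Crossing detection runs on the smoothed series — the
distance data are filtered before analysis, and the cutoff itself was
originally chosen by visual inspection of smoothed traces, so applying it to
raw noisy samples would trigger spuriously early.

Numerical choices: COG is the unweighted mean of the selected atoms;
selections default to Cα-only (robust to hydrogens/glycans; all-atom mode is
available — the two conventions differ by well under the ±1 Å tolerance used
for closed-state distance checks). Default domain selections exclude the
linker from both domains (CYT = residues before the anchor, DH = residues
after the end motif). Savitzky–Golay edge samples are produced by evaluating
the polynomial fitted to the first/last window (the transient handling of
the reference scipy implementation), so an order-2 filter reproduces
quadratic series exactly, edges included. Series shorter than the window
shrink it to the largest odd length with a warning.

## Kinetic fitting

`fit_single_exponential()` fits `A(t) = offset + amplitude·exp(−k t)` by
Levenberg–Marquardt least squares on the *raw* trace (smoothing before
fitting biases the rate), with starting values from the endpoint offset and
a log-linearised slope. Rising (reduction) traces fit via a negative
amplitude, so both the 449 nm FAD and 563 nm heme-*b* channels are covered
without mode switches. The fit window starts at the first sample; dead-time
correction is instrument-specific and out of scope. A trace whose amplitude
is within ~3× the point-to-point noise raises "no decay detected" instead of
returning a spurious rate. `activity_from_slope()` is the Beer–Lambert
quotient (e.g. ε = 6.9 /mM/cm for DCIP at 520 nm, 19.6 /mM/cm for
cytochrome *c* at 550 nm), returning mM/min ≡ µmol·min⁻¹·mL⁻¹.

## What the synthetic generators emulate — and what they do not

`gen_linker_families()` renders sequences from six group templates that
mirror the documented group architectures: Pro-Val-Pro C-attachment in
groups 1–3 versus Cys in 4–6; the N-terminal Cys present in groups 1–4,
in about half of group 5 sequences, and absent in group 6; `[YF]DY` end
motifs; Gly/Ser/Thr-rich mobile segments whose lengths span 15–30 residues.
Each group couples the shared GST background with a group-specific pair of
seasoning residues so that groups are homologous within and effectively
unrelated across — the separation condition the network benchmarks assume.
Substitution noise never touches the anchor motifs (and draws replacements
from an alphabet without C/Y/F/P/V, so it cannot forge them either):
annotation failure rates therefore measure window and segmentation logic,
not motif destruction. `hostile = TRUE` lifts this protection for negative
tests. Indels are confined to the mobile segment, where natural length
variation lives.

What passing these benchmarks does *not* show: real CDH linkers carry
glycosylation, genuinely shared inter-group homology, alignment ambiguity
near segment boundaries, and database redundancy structure; template
rendering has none of these. The benchmarks validate the machinery, not the
published family statistics (the 190/501 linker counts and the
150-sequence/6-group result depend on a 2021 database snapshot and are out
of scope).

`gen_pull_series()` emulates the post-processing inputs only — linear COG
ramps with a delayed distortion ramp and Gaussian noise — with the analytic
cutoff crossing stored as truth. `gen_exponential_trace()` produces
stopped-flow-like traces at user-set rates (the wild-type-scale default used
in the acceptance script is 15.6 s⁻¹). `gen_cdh_structure()` builds a
Cα-only two-domain toy structure numbered like the reference, with the
closed-state COG separation (35.6 Å) and the 218–459 contact geometry
planted exactly; it is a recovery target for the geometry code, not a model
of CDH.

## Problem sizes used by tests and the acceptance script

Annotation benchmarks use 60 clean and 300 noisy sequences (6 × 50 at 5%
substitutions); network benchmarks 30–60 linkers plus 100 random graphs
against a union-find oracle; smoothing/crossing benchmarks 1500-frame ramps
over 50 seeds; kinetic recovery 10 seeded replicates at each of
k ∈ {0.5, 5, 50} s⁻¹. These sizes give stable pass/fail behaviour for the
stated thresholds (e.g. ≥95% recall, ≤5% median rate error) while keeping a
full run in the minutes range on one core.

## Known limitations

* Anchor propagation is pairwise-alignment-based; a profile/HMM approach
  would be more robust for remote homologs (Class III/IV CDHs are out of
  scope).
* The star alignment used for per-group logos projects every member onto the
  longest member and drops insertions relative to it; it approximates a full
  multiple alignment and can understate variability at indel-rich columns.
* Whether group-5-like sequences lacking the CYT Cys should segment via the
  fallback helix length or the DH attachment alone is not settled by the
  definition; the package applies the fallback, and such sequences fail
  loudly if that yields a degenerate segmentation.
* E-value calibration uses fixed gapped-BLOSUM62 Karlin–Altschul constants;
  they are conventional, not fitted to the scoring engine.
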