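# linkerscape

Analysis of the interdomain linker in cellobiose dehydrogenase (CDH) and
related multidomain flavocytochromes.

CDH couples a catalytic flavodehydrogenase (DH) domain to a mobile,
electron-shuttling cytochrome (CYT) domain through a flexible linker; the
linker governs the open/closed conformational switch and with it the
interdomain electron transfer rate. `linkerscape` implements a
function-based linker definition — from the conserved CYT anchor Tyr
(Tyr195 in *Neurospora crassa* CDH IIA numbering) through the conserved
Tyr/Phe-Asp-Tyr motif (229–231) that docks onto the DH domain — and the
analyses built on it:

* **Annotation and segmentation** — anchor propagation by pairwise
  alignment against a trusted reference, `[YF]DY` end-motif search, and
  tripartite segmentation into N-attached (anchor helix through the
  CYT-attachment Cys), mobile (Gly/Ser/Thr-rich) and C-attached
  (Pro-Val-Pro or Cys attachment through the end motif) segments.
* **Composition and logos** — hydrophilic / hydrophobic / structural
  residue-class profiles, length histograms, and per-column frequency
  matrices with information content `IC = log2(20) − H` (bits) for
  sequence logos.
* **Similarity-network grouping** — all-vs-all local alignment
  (BLOSUM62, affine gaps 11/1), Karlin–Altschul E-values
  (`bit = (λ·raw − ln K)/ln 2`, `E = m·n·2^−bit`), edges at `E ≤ 1e-10`,
  groups as connected components labelled by descending size.
* **Variant design** — deletions, Ala-Thr insertions and engineered
  disulfides (I218C/N459C) in wild-type numbering, with coordinate maps,
  theoretical average masses, and Cα-distance disulfide screening.
* **Pull-trajectory metrics** — center-of-geometry distances,
  Savitzky–Golay smoothing (window 101, order 2), and the maximum linker
  extension before the CYT distortion reaches the 11 Å cutoff.
* **Kinetics** — single-exponential fits of stopped-flow traces
  (`A(t) = offset + amplitude·e^−kt`) and Beer–Lambert activity
  conversion.
* **Synthetic data** — seeded generators for CDH-like sequence families
  (six group templates with planted motifs and ground truth), pull series
  with analytic crossings, exponential traces, and a toy closed-state
  Cα structure, so every stage is testable offline. The bundled
  NcCDHIIA-like reference sequence and closed-state structure are
  *synthetic* constructs carrying the documented landmark coordinates;
  they are recovery targets for the machinery, not the natural data.

## Worked example

```r
library(linkerscape)

# six noisy synthetic families with ground truth, through the full pipeline
fam <- gen_linker_families(n_per_group = 5, sub_rate = 0.03, seed = 7)
res <- run_analysis(pipeline_config(records = fam$records,
                                    out_dir = "linker_out",
                                    min_group_size = 2, verbose = FALSE))
res$summary
#>   n_in n_annotated n_failed n_unique_linkers n_grouped n_groups
#> 1   30          30        0               30        30        6

annotate_linker(cdh_reference()$record)
#> <linker_annotation> NcCDHIIA_synthetic status: ok
#>   anchor Y195, end motif 229-231, linker 195-231
#>   segments: N-attached 195-211 | mobile 212-221 | C-attached 222-231
#>   CYT Cys: 211, DH attachment: pvp at 222

fit_single_exponential(gen_exponential_trace(k = 15.6, noise_sd = 0.001,
                                             seed = 3)$trace)
#> <exp_fit> k_obs = 15.53 1/s (se 0.1), amplitude 0.09965, offset 0.01999
```

All 30 sequences annotate successfully, the network recovers the six
planted groups, the annotator locates the documented linker boundaries
(195–231) and CYT Cys (211) on the bundled reference, and the fitted rate
recovers the simulated wild-type-scale rate of 15.6 s⁻¹ within its
standard error. `run_analysis()` writes annotation, linker FASTA,
composition, histogram, edge/group and per-group logo tables to
`out_dir`.

A thin command-line wrapper ships at `inst/scripts/linkerscape`
(subcommands `run`, `annotate`, `pull`, `kinetics`, `simulate`).

## Package layout

```
R/                  annotation, composition, network, variants,
                    structure metrics, kinetics, generators, pipeline
tests/testthat/     unit + property tests, with independent oracles
                    (Gotoh DP, union-find, windowed least squares)
vignettes/          methods vignette: model, parameters, design choices
scripts/acceptance.R   headline-quantity reproduction (JSON output)
inst/scripts/linkerscape  thin CLI wrapper
```
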