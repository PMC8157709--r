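---
title: "Methods: screening, trigger design and effect calling in an allotetraploid suppression study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, trigger design and effect calling in an allotetraploid suppression study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suckerscreen)
```

This vignette documents the statistical and algorithmic choices behind
`suckerscreen`, module by module, with the rationale for every default.

## 1. Expression screen

Expression is quantified as RPKM,
$\mathrm{RPKM} = c \cdot 10^9 / (L \cdot N)$, for read count $c$,
transcript length $L$ (nt) and library size $N$ (mapped reads)
(`compute_rpkm()`). Candidate genes must satisfy three criteria
(`select_candidates()`):

* **(a) enrichment**: fold change of the EA or VE axillary-meristem zone
  over the control zone at least `min_fold = 10`;
* **(b) length**: assembled length strictly greater than
  `min_length_nt = 200`, removing short assembly artifacts;
* **(c) annotation**: class in `transcription_factor` or `unknown` —
  developmental regulators are the biological targets, and unknowns are
  retained as possible novel regulators.

**Not-detectable handling.** ND is below-detection, not zero. A gene ND
in the tissue cannot be enriched there (fold 0). A gene expressed in the
tissue but ND in the control is biologically the strongest kind of
candidate, so the control is floored at `nd_epsilon = 0.1` RPKM: any
tissue RPKM of at least 1 then clears a 10-fold screen. Measured zeros
are kept distinct: 0/0 is fold 0 and $x/0$ for $x > 0$ is infinite fold.
A selected gene is assigned to the passing tissue with the larger RPKM;
exact ties go to EA. Applied to the bundled `axillary_expression()`
table, this reproduces the published 11 EA / 13 VE split exactly.

## 2. Pairwise alignment

Global (Needleman–Wunsch) alignment with affine gaps, delegated to the
Biostrings engine (`align_pair()`). Scoring defaults are megablast-style:
match $+2$, mismatch $-3$, gap open $-5$, gap extend $-2$, where a gap
run of length $\ell$ costs $5 + 2\ell$. `N` never matches anything,
including another `N` — an unknown base should never *support* a trigger.
Percent identity (`percent_identity()`) defaults to excluding terminal
gap columns, so a short fragment aligned inside a longer transcript is
judged on the aligned region. All coordinates in the package are
1-based and inclusive, the native R string convention.

## 3. Trigger design

For each homoeolog family the designer (`design_triggers()`) profiles
every window start (default step 1 nt) of length `trigger_length`
(default 430 nt, the study-scale average construct length) along the
ungapped S-subgenome sequence, scoring the S/T identity of the alignment
columns the window spans (`windowed_identity()`). The selected window
maximises S/T identity subject to:

* `min_st_identity = 90`%: both homoeologs must be silenced by one
  hairpin, which needs near-perfect shared identity;
* `max_paralog_identity = 70`% (strict `<`): the best *ungapped sliding*
  identity of the window against every same-family paralog — on either
  strand, since hairpin processing yields small RNAs from both strands —
  must stay below the cap, keeping relatives unsilenced. The ungapped
  diagonal scan is deliberate: siRNA-mediated silencing acts through
  contiguous complementarity, for which gapped alignment identity is the
  wrong risk measure, and the scan admits an $O((L_1+L_2)\,L_1)$
  vectorised implementation that keeps a 36-family design under a
  minute.

Ties go to the leftmost window, making the design deterministic. An
infeasible family is reported as `no_valid_trigger` together with a
per-window table of which constraint binds where.

## 4. Off-target scan

Small-RNA silencing requires (as a conservative screening rule) at least
`k = 22` consecutive identical nucleotides. `scan_offtargets()` finds
*every* maximal exact match of length ≥ k between each trigger and any
transcript: all k-mers of the transcriptome are indexed
(`kmer_index()`; k-mers containing `N` are skipped), trigger k-mers are
joined against the index, and runs of consecutive seeds on one
(transcript, diagonal) are collapsed — a run of $m$ consecutive seeds is
exactly one maximal match of length $k + m - 1$. Both strands are
scanned and antisense coordinates are mapped back to the trigger's own
orientation. Every reported hit is re-verified character by character;
the triggers' own target genes are removed via explicit exclusions.

## 5. Effect statistics

For construct $g$, line $i$ and trait $t$, the per-line relative effect
is $r_{git} = \bar{y}^{\mathrm{tg}}_{git} / \bar{y}^{\mathrm{null}}_{git}$,
the ratio of transgenic to null-segregant plant means within the line —
null segregants are the genetically matched control
(`relative_effects()`). Construct-level summaries are the arithmetic
mean and sample SD over the (default 3) independent single-locus lines.
Significance is a one-sample two-sided Student t-test of
$H_0\!: \mu_r = 1$ with $n - 1 = 2$ degrees of freedom at
$\alpha = 0.01$ (`test_effects()`). Modelling choices:

* **Reduction-only flagging**: a cell is marked only when $p < \alpha$
  *and* $\bar r < 1$; a significant increase in suckering is not
  suppression.
* **Degenerate SD 0**: complete suppression in every line (e.g.
  $0.00 \pm 0.00$) leaves the t statistic undefined. By the limit of the
  statistic the convention is $p = 0$ when $\bar r \ne \mu$ and $p = 1$
  when $\bar r = \mu$ — the fully-suppressed construct is (correctly)
  called effective.
* **Effective gene**: significant reduction in secondary lateral-shoot
  number and/or weight (`call_effective_genes()`). Applied to the
  bundled `rnai_effects()` table this flags exactly 9 cells and the five
  constructs NtLs, NtBl1, NtREV, VE7, VE12.

With n = 3 the two-sided 1% critical value is $|t| > 9.92$, so only very
large, consistent reductions are called — near-misses like $0.28 \pm
0.30$ ($p = 0.053$) stay unflagged.

## 6. Synthetic data generator

The simulator provides ground-truth instances at a scale where every
result can be verified:

* **Transcriptome** (`simulate_transcriptome()`): per family an ancestral
  random sequence is diverged into S and T copies by placing exactly
  $\mathrm{round}((1-\mathrm{identity}) L)$ substitutions at distinct
  positions split between the branches, so the realized identity is
  exact and (with the default `indel_rate = 0`) coincides with alignment
  identity. Defaults: 36 families at S/T identity 0.954, two paralogs
  per family at identity 0.50–0.68 (below the 70% cap), 100 background
  transcripts of 500–2000 nt.
* **Expression** (`simulate_expression()`): log-normal control RPKM,
  a planted `enriched_fraction` of eligible genes whose tissue counts
  are raised so the *recomputed* fold is ≥ 10 even after count rounding,
  short-contig contaminants (50–199 nt) that criterion (b) must remove,
  and per-cell ND knockouts with probability `nd_probability`.
* **Phenotypes** (`simulate_phenotypes()`): shoot counts are negative
  binomial with extra-Poisson coefficient of variation `noise_cv`
  (Poisson at 0), weights log-normal with the same CV, around wild-type
  baselines scaled by per-construct multipliers. A multiplier of 0
  (complete suppression) is legal and produces exact zeros — the
  degenerate-SD case above.
* **Seeding**: one master seed; each stage draws from its own sub-stream
  `(seed + 1009 * stage_index) mod (2^31 - 1)`, so runs are bit-identical
  and stages independently reproducible. `plant_offtarget()` plants
  known exact matches (optionally with mismatching flanks, for boundary
  cases at $k - 1$) as scanner positives.

Problem sizes in examples and tests are deliberately smaller than a real
transcriptome assembly (tens of families, hundreds of transcripts); the
algorithms are the same and the scaling is documented per function. The
simulator emulates screening-relevant structure (homoeology, paralogy,
enrichment, ND, noise) but not read-level artifacts such as mapping
bias, chimeric contigs or indel divergence (available via `indel_rate`,
off by default to keep identities exact).

## 7. Pipeline

`run_pipeline()` chains simulate → screen → design → off-target →
phenostats on one `sim_config()`, writing FASTA/TSV artifacts, an md5
manifest and a report whose numbers are recomputed from the files on
disk (`pipeline_report()`). The pipeline is a set of composable
functions rather than a shell entry point: every stage is callable,
testable and seedable on its own, and a rerun of the same configuration
reproduces identical digests.

```{r example}
cfg <- sim_config(seed = 1, n_target_pairs = 3, n_background = 10,
                  transcript_length_range = c(400, 600),
                  effect_table = default_effect_table(3, n_effective = 1))
outdir <- file.path(tempdir(), "demo_run")
run <- run_pipeline(cfg, outdir, trigger_length = 150, step = 5)
writeLines(run$report)
```
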