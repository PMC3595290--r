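---
title: "Digital gene expression from 3'-tags: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital gene expression from 3'-tags: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tagdge)
library(dplyr)
```

## The assay and the quantities it measures

Tag-based digital gene expression (DGE) is a SAGE-style protocol: mRNA is
captured on oligo-dT beads, reverse-transcribed, and digested with NlaIII,
which cuts at every `CATG`. A type IIS enzyme (MmeI) then releases a short
fragment — the *tag* — anchored at the `CATG` closest to the 3' end of the
transcript, extending about 17 nt downstream. Sequencing millions of such
tags and counting identical copies gives an absolute, length-independent
readout of transcript abundance: one expressed transcript molecule
contributes one tag, always from the same position.

Three consequences shape everything in this package:

* a transcript with no `CATG` followed by a full tag window is invisible to
  the assay, no matter how highly it is expressed;
* observed tags come from the 3'-most usable anchor, but *mapping* must
  consider every anchor of every transcript, because RNA degradation and
  incomplete digestion produce internal tags, and because two genes can
  share a window;
* abundance is a pure count, so comparing libraries is a problem of
  comparing Poisson-like counts at known sequencing depths — no
  length normalisation, no dispersion estimation from replicates (the
  classic design has none).

## Pipeline model

The pipeline mirrors the standard analysis of a three-strain fungal design:
two homokaryotic parents (`p1`, `p2`) and their hybrid heterokaryon (`h`).

1. **Virtual tag index** (`extract_virtual_tags()`): every sense-strand
   `CATG` with at least `tag_length - 4` nt downstream contributes one
   index entry. Tag length defaults to 21 nt (`CATG` + 17), the canonical
   NlaIII/MmeI geometry; it is configurable because the protocol's release
   length varies by a base between kit versions.
2. **QC** (`filter_tags()`): raw tags are removed in a fixed cascade —
   N-containing ("low quality"), adaptor-matching, then copy-number-1
   tags. Order matters for the ledger: a tag is attributed to the *first*
   class that catches it, and singleton status is evaluated only after the
   first two removals. The ledger reports raw, each removal class, clean,
   and survival at copy-number thresholds (>= 2, > 5, > 10, > 20, > 50,
   > 100), reproducing the conventional library-characteristics table.
   Adaptor matching is exact full-tag equality by default, with a prefix
   mode; real pipelines differ and the choice only moves counts between
   the adaptor and singleton rows.
3. **Quantification** (`count_genes()`, `tpm_normalize()`): each clean tag
   is assigned with strict exact-hit priority, then a Hamming-distance-1
   search; tags whose winning gene set has two or more members are
   *ambiguous* and contribute to no gene. Per-gene counts ("raw
   intensity") are normalised to tags per million **clean** tags — the
   denominator is the clean total, not the mapped total, so ambiguous and
   unmapped copies still count toward depth.
4. **Differential expression** (`ac_probability()`,
   `ac_pvalue_two_sided()`, `bh_fdr()`, `call_de()`): the exact
   two-library test for tag counts. Conditional on observing `x` tags in a
   library of depth `N1`, the probability of `y` tags at depth `N2` is

   $$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
     \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

   the posterior predictive of a Poisson rate under a flat prior. It
   equals a negative binomial with size $x+1$ and success probability
   $N_1/(N_1+N_2)$, which is how the tails are evaluated (through the
   regularised incomplete beta function) without explicit summation.
5. **Strain comparison** (`venn_partition()`, `fold_classify()`,
   `complementation_classify()`): detection patterns across the triad,
   descriptive fold classification, and the three complementation
   categories (silent in one parent, silent in the other, low in both but
   boosted in the heterokaryon).
6. **CAZyme profiling** (`class_totals()`, `lineage_average()`,
   `rank_by_total()`, `max_in_lineage()`, `bicluster()`): repertoire
   arithmetic over genome-by-family count matrices and the double
   hierarchical clustering used to present them.

`run_pipeline()` chains stages 1–5 (optionally 6) over a single
configuration object and writes every table with an MD5 manifest, so a
rerun with the same seed is byte-identical.

## Thresholds and parameters

| Parameter | Default | Why |
|---|---|---|
| `tag_length` | 21 nt | CATG anchor + 17 nt, the standard NlaIII/MmeI release length |
| TPM floor | 0.01 | conventional reporting value for zero-count genes; keeps fold changes finite |
| `intensity_floor` | 40 | genes with raw count <= 40 in *both* libraries are excluded before testing |
| `p_threshold` | 0.005 | significance calling |
| `fdr_threshold` | 0.001 | Benjamini–Hochberg, computed over the tested set only |
| `fc_threshold_log2` | 2 | significance calls use 4-fold; descriptive comparisons conventionally use 3-fold (`fold_k = 3`) |
| `detect_min` | 1 tag | weakest count-based definition of "expressed"; anything stronger is arbitrary without replicates |
| `comp_low_tpm` / `comp_high_tpm` / `comp_min_fold` | 20 / 50 / 3 | calibrated so the canonical worked examples of each category classify correctly; they are configuration values, not measured facts |

Two fold thresholds coexist deliberately: strict significance calling uses
$|\log_2 \mathrm{FC}| > 2$, while descriptive "at least 3 times"
comparisons use a plain TPM ratio of 3. Both are exposed; neither is
derived from the other.

The TPM floor is applied at reporting and fold-change time only; raw zero
counts stay zeros internally, and the `detected` flag keeps them
distinguishable. Whether the floor is applied before or after
normalisation is a genuinely open convention; applying it after (as here)
means a floored value never depends on library depth.

## Numerical choices

* **Tails and sidedness.** The two-sided p-value doubles the smaller of
  the two inclusive tails and caps at 1 — the conservative standard for
  discrete exact tests, and provably super-uniform under the null.
  A doubled-tail construction on a discrete distribution cannot be exactly
  symmetric under swapping $(x, N_1) \leftrightarrow (y, N_2)$: the swap
  maps an inclusive tail onto a strict one, so the two directions differ
  by up to twice the observed-point masses. The suite asserts symmetry at
  exactly that discreteness bound; at genome-scale counts the bound is
  negligible.
* **Stability.** The mass is evaluated in log space via `lgamma`; tails go
  through `pbeta` with `lower.tail = FALSE` for the upper side, avoiding
  the catastrophic cancellation of `1 - pbeta(...)` (which silently
  returns 0 for p-values below ~1e-16).
* **BH over the tested set.** Prefiltered genes receive no p-value and do
  not enter the multiple-testing correction; including them would dilute
  the adjustment with tests that were never performed.
* **Rounding.** Lineage averages round half away from zero
  (160.75 → 161), not banker's rounding.
* **Clustering.** `bicluster()` defaults to Euclidean distance on raw
  counts with average linkage. No metric is canonical for family-count
  heatmaps; raw counts match the usual clipped (0 to >20) colour scale.
  Exact dendrogram reproduction of any published figure is explicitly not
  a goal — tie-breaks and linkage conventions differ across tools.
* **Degenerate inputs.** Constant matrices cluster with an arbitrary,
  flagged order; single-row/column dimensions return a single leaf without
  a dendrogram; empty libraries yield all-zero ledgers rather than errors.

## The synthetic world

`simulation_params()` + `simulate_genes()` + `simulate_triad()` generate a
triad with known ground truth. The defaults are a scaled-down but
structurally faithful version of a real mushroom DGE experiment: 1,000
genes and 200,000 tags per library rather than ~11,500 genes and ~5.9
million tags — full scale would add nothing to the logic of any test while
multiplying runtimes ~30-fold. The generator emulates:

* transcript lengths ~ Normal(1500, 500) truncated at 25 nt; 95% of
  transcripts carry a guaranteed usable anchor, the rest are scrubbed of
  anchors entirely (the assay-invisible minority);
* allele divergence between the parents at 1 SNP/kb (the observed
  genome-wide scale for two such homokaryons is ~35k SNPs over ~37 Mb),
  which makes a small fraction of emission tags parent-diagnostic;
* negative-binomial counts with dispersion 0.1 (a generator knob, not a
  fitted quantity — single-replicate libraries cannot estimate it),
  collapsing to Poisson at 0;
* base-call errors at 0.005/nt, N-replacement at 0.002/tag, adaptor
  contamination at 5e-4/tag, and 5,000 planted copy-number-1 junk tags.
  No instrument figures exist for these rates; they are chosen to make
  every ledger row non-trivially exercised;
* planted biology: 5% of genes silent in each parent (expressed at 500
  TPM in the other — category A/B material, and at 200k tags exactly the
  depth where expected counts hit 100); 2% "complementation boost" genes
  with both parents at U(0.5, 10) TPM and the heterokaryon boosted 40-fold
  over the parental mean. The 40x default reflects the canonical published
  examples of the phenomenon, where heterokaryon TPM of 51–3285 arises
  from parents below 20 TPM; boosts much below ~30x would plant "boosted"
  genes that no threshold-based classifier should be expected to find.
  All other genes have equal parental rates, and the heterokaryon default
  is the additive parental mean — the simplest null for complementation.

What the generator does **not** emulate: 3' bias and RNA degradation
producing internal tags, sequence-dependent error profiles, PCR
duplication structure, and real adaptor sequences. A green planted-recovery
test therefore establishes that the *logic* of QC → mapping →
quantification → classification is correct under the stated noise model,
not that the thresholds are optimal for any particular instrument.
Category-C recovery sits closest to its 0.9 test threshold across seeds,
precisely because planted boosts landing near the 50-TPM detection bound
are genuinely ambiguous cases.

## Worked example

```{r example}
p <- simulation_params(n_genes = 300, library_size = 60000,
                       singleton_noise = 1000, seed = 42)
genes <- simulate_genes(p)
triad <- simulate_triad(genes, p)
index <- extract_virtual_tags(genes)

qc <- filter_tags(triad$libraries$p1,
                  adaptor_sequences = p$adaptor_sequences)
qc$accounting

expr <- lapply(triad$libraries, function(lib) {
  clean <- filter_tags(lib, adaptor_sequences = p$adaptor_sequences)$clean
  quantify_library(clean, index, gene_ids = genes$gene_id)
})

de <- call_de(
  tibble::tibble(gene_id = expr$p1$gene_id,
                 x = expr$p1$raw_count, y = expr$p2$raw_count),
  N1 = attr(expr$p1, "clean_total"), N2 = attr(expr$p2, "clean_total")
)
glance(de)
```

```{r comp}
comp <- complementation_classify(tibble::tibble(
  gene_id = expr$p1$gene_id,
  raw_p1 = expr$p1$raw_count, raw_p2 = expr$p2$raw_count,
  tpm_p1 = expr$p1$tpm, tpm_p2 = expr$p2$tpm, tpm_h = expr$h$tpm
))
table(planted = triad$truth$category, called = comp$category)
```

## Known limitations

* The exact test assumes a single tag count per gene per library; genes
  whose tags are all ambiguous are structurally zero and indistinguishable
  from unexpressed genes.
* Antisense tags are not indexed (oligo-dT selection implies sense-strand
  tags); protocols with antisense leakage would need the index doubled.
* The mapper is transcript-level only; no genome-coordinate mapping.
* The Hamming-1 fallback can rescue a tag onto the wrong gene when the
  true source gene is absent from the gene models; with a complete gene
  set this is rare, with a fragmented one it is not.
* BH control is nominal per comparison; the three pairwise comparisons of
  a triad are not jointly corrected, matching standard practice for this
  design.
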