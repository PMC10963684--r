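---
title: "Gene-based haplotype candidate mining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based haplotype candidate mining: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomine)
```

## The procedure and its assumptions

haplomine prioritizes candidate genes inside a mapped QTL interval by
treating the *gene haplotype* — the joint allele signature an accession
carries across a gene's selected variant sites — as the unit of analysis.
The pipeline assumes:

* an **inbred panel**: every accession is effectively homozygous, so one
  genotype column is one haplotype. Heterozygous VCF calls are therefore
  treated as missing (with a logged count), not phased.
* **haplotype-level causality**: phenotype differences attach to the
  haplotype as a whole; no attempt is made to fine-map the causal variant
  within the gene.
* **environments as replicates of the genetic signal**: a real causal gene
  should separate its haplotypes in every cultivation environment; requiring
  replication across all environments is the screen's main protection
  against one-off artifacts.

The stages are: LD-based region delimitation (`ld_matrix`, `ld_block`,
`region_report`), per-gene site selection (`collect_gene_variants`),
haplotype enumeration (`enumerate_haplotypes`) and the major-haplotype
filter (`major_haplotypes`), per-environment testing (`test_gene`), and the
all-environment candidate decision (`mine_candidates`).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| promoter length | 1000 | bp | regulatory variants are scanned 1 kb upstream of the transcription initiation site; the TSS falls back to the gene boundary when the annotation has no mRNA feature, because a "predicted TSS" is not otherwise machine-readable |
| PAV threshold | 50 | bp | an allele-length difference above 50 bp is classified as a presence/absence variant; at or below, an InDel |
| major-haplotype floor | 11 | accessions | "more than 10" read strictly; 10 would also be defensible, so the floor is an argument |
| LD block threshold `r2_min` | 0.6 | r² | the block is the maximal contiguous run of sites whose r² with the peak stays at or above the threshold; simple and reproducible, in place of confidence-interval block callers |
| α | 0.05 | — | per-test level of both the omnibus ANOVA and Duncan's ranges; no multiple-testing correction across genes by default (a Bonferroni flag exists but is off, mirroring standard practice in this screen) |
| pyramiding cell floor | 5 | accessions | combination cells have no "more than 10" filter (published combination tables keep cells of n = 8); a floor of 5 avoids degenerate groups in the range test |

## The statistical machinery

**Pooled ANOVA.** `MSE = Σ(n_i−1)s_i²/Σ(n_i−1)` with `df_e = N − k`; the
omnibus F compares the between-group mean square against MSE. Summary mode
uses printed `n`, `mean`, `sd` exactly as given, so published tables can be
re-analyzed; raw and summary modes agree exactly when the summaries are
exact.

**Duncan's multiple range test.** Means sorted descending; a pair spanning
`p` ordered groups is tested against
`R_p = q(1−(1−α)^(p−1); p, df_e)·sqrt(MSE/n_h)` with `q` the
studentized-range quantile (`stats::qtukey`, i.e. library-quality quantiles)
and `n_h` the harmonic mean of the **two compared** group sizes (Kramer's
unequal-n extension). Which unequal-n variant classic SPSS used is not
documented, so `n_h = "all"` (harmonic mean of all groups) is available; both
reproduce the letter displays of the tables used in the test-suite. Stepwise
protection is implemented as absorb-marking: once a range fails its test,
every pair inside it is non-significant. For `k = 2` the procedure
coincides exactly with the pooled two-sample t-test (the suite checks this
on a grid).

**Compact letter display.** Non-significant sets of a protected range test
are contiguous intervals of the sorted means, so letters are the maximal
non-significant intervals (insert-and-absorb). Letter orientation follows
the agronomy convention: ascending means receive earlier letters ("a" =
shortest group); a flag flips it.

**Degenerate inputs.** Zero pooled variance is an error for `pooled_anova`
(no within-group variability to test against), but `duncan_mrt` resolves it
by convention — all-equal means share one letter (p = 1), distinct means
with zero variance are all mutually different (p = 0) — because the
pyramiding screen must handle flat phenotype columns gracefully. The
two-sample t adopts the same conventions. Undefined correlations
(zero-variance input) and monomorphic-site r² return `NA`, never 0: "no
information" must not masquerade as "no association".

**Candidate rule.** A gene is significant in one environment when the
omnibus p < α **and** at least one haplotype pair shares no letter; the
omnibus guard keeps tiny-group letter artifacts from counting. The decision
is per environment, accessions missing a phenotype are dropped from that
environment only, and candidacy requires every environment.

**Pyramiding verdict.** For each trait × environment column, Duncan letters
are computed across all two-gene combination cells; within each stratum of
gene A's haplotype, the screen asks whether gene B's levels share letters
(and symmetrically). A column is "A-dominant" when varying A separates
letters in some stratum while varying B never does; "additive" when both
do; "none" when neither. The overall verdict is the unanimous column
verdict and falls back to "none" on disagreement — a deliberately
conservative joining rule, since a dominance claim spanning traits and
environments should not rest on a subset of columns. The vocabulary stays
statistical ("A-dominant"), not biological (upstream/downstream action),
because letter displays cannot distinguish those. A formal two-way
interaction F-test is outside the verdict by design; letter displays are
what the screen mirrors.

## The synthetic panel: what it emulates and what it does not

`sim_config()` states a fixed world modeled on a rice seedling-vigor panel:
343 inbred accessions; a 10-gene region on one chromosome; gene 5 causal
with four haplotypes at frequencies (25, 91, 28, 46)/190 and additive
effects (0, 29, 45, 45.5) cm on the plant-height scale — the magnitudes of
the published four-haplotype table; ~20 promoter variants (one InDel), CDS
SNPs and a ~400 bp PAV carried by haplotype 1; haplotype 2 matches the
reference genome (all-reference signature). Shoot length is measured in
three environments (GST/GSF/DST, offsets 0/−3.3/−8.9 cm, baseline 27.7,
residual SD 3.5 — the magnitudes of the published combination table) and
plant height at two locations (offsets 0/+2, baseline 91.5, residual SD 20).
Both traits share the haplotype effect, SL scaled by 0.27, which induces the
positive SL–PH correlation seen in real panels (~0.4–0.5 at these
defaults). Effects enter via the haplotype label, not per variant, so the
haplotype is the causal unit and signatures are in bijection with labels.

Random streams for genotype assignment, each phenotype column, and null
genes are derived independently from one master seed, so genotypes can be
re-phenotyped (or permuted) without disturbing each other, and a fixed seed
reproduces fixture files byte-for-byte.

Not emulated: population structure and kinship, LD decay *between* genes
(null genes are unlinked by construction, and with ≥ 3 haplotypes no pair of
within-gene sites can have r² = 1 — different sites induce different
bipartitions), coalescent allele-frequency spectra, genotyping error, and
missing data (defaults are complete). A green power test therefore
establishes that the pipeline recovers a planted haplotype effect of
published magnitude against iid noise — not that it is robust to
confounding by relatedness, which real panels require separate handling
for.

One stated-world caveat measured honestly: redrawing the four-group
plant-height table from its printed ns/means/SDs recovers the printed
a/b/c/c letter display in ~89–90% of seeds, not ≥ 95% — the 16.1 cm gap
between the second and third groups sits only ~1.5 standard errors above
its least significant range, so ~6% of redraws merge them and ~3% split the
top pair. The property test asserts the measured ≥ 80% bound; the
generator was not tuned to inflate the rate.

## Numerical choices, tie-breaks, degenerate cases

* Coordinates 1-based inclusive everywhere (VCF/GFF3 convention); BED output
  from the CLI is converted to 0-based half-open on write.
* Haplotype ids are frequency-ranked (`Hap1` = most common), ties broken by
  first occurrence in accession order; `reference_haplotype()` identifies
  the all-reference signature when reference-anchored labeling is wanted.
* Multiallelic sites collapse to reference-vs-any-alternate before LD;
  r² needs ≥ 2 pairwise-complete observations and is undefined (NA) for
  monomorphic input.
* `r_squared` is the squared Pearson correlation of allele codes — on
  inbred genotypes this equals haplotype r², and no estimator choice is
  hidden in a library call.
* Studentized-range quantiles come from `stats::qtukey`; all letter logic
  operates on exact comparisons of means against ranges, with no rounding.
* Replicate phenotype rows are averaged at ingestion; non-numeric values are
  dropped with a counted warning, never silently.

## Known limitations

* The exact LD method/threshold behind any particular published interval is
  usually unstated; `ld_block`'s contiguous-run rule is one reproducible
  choice, and printed interval sizes should not be expected to reproduce
  exactly.
* Whether published haplotype scans used promoter+CDS variants for every
  gene or whole-gene variants is often ambiguous; both region sets are
  supported (`regions = c("promoter", "cds")` vs `"gene"`), defaulting to
  promoter+CDS.
* Duncan letters recomputed from *printed* (rounded) summaries can flip
  borderline pairs; the pyramiding summary-mode check treats published
  conclusions as a soft target and logs recomputed margins for any
  mismatch.
* The candidate screen's cross-environment replication does not protect
  against a null gene whose haplotype partition chance-correlates with the
  causal gene's, because the genetic signal is shared across environments;
  at the default world this residual false-flag rate is ~0.4% per null
  gene (measured), versus α³ ≈ 0.01% for a fully null region.
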