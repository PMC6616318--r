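---
title: "Detecting immediate dosage compensation from Y-deletion mutant panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting immediate dosage compensation from Y-deletion mutant panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xydosage)
```

## The scientific problem

In dioecious plants with young sex chromosomes, such as *Silene latifolia*,
Y-linked gene copies (gametologs) degenerate after recombination stops.
Whether and how expression of the X copy is adjusted to compensate the
failing Y copy — dosage compensation — is a central question in sex
chromosome evolution. A deletion-mutant panel offers an unusually direct
experiment: irradiation mutants carrying contiguous Y deletions remove a
gene's Y copy *immediately*, within one generation, so any upregulation of
the X partner ("immediate dosage compensation", IDC) must be a direct
regulatory response rather than the product of long-term evolution.

`xydosage` implements the full analysis chain for such a panel:

1. **Deletion map** — order PCR-genotyped STS markers so every mutant's
   deletion becomes contiguous (`cluster_markers()`, `order_markers()`,
   `order_within_clusters()`, `build_deletion_map()`).
2. **Deletion calling** — identify deleted Y gametologs from expression
   evidence and hemizygous autosomal genes from read-coverage ratios
   (`call_y_deletions()`, `call_autosomal_hemizygous()`, `region_span()`).
3. **Relative expression** — per-gene mutant/control ratios by category
   (`X_del`, `X_nondel`, `Y_nondel`, `Aut`, `A_del`, `A_nondel`), rank
   tests, dS and degeneration strata, per-gene t tests with FDR control,
   PCA of mutant profiles, kernel-density bimodality detection
   (`relative_expression()`, `category_test()`, `stratify()`,
   `per_gene_de_test()`, `pca_mutants()`, `density_peaks()`).
4. **Factor localization** — classify mutants as IDC-positive and
   intersect their deletions (`classify_idc()`, `localize_factor()`).
5. **Companion analyses** — bisulfite methylation comparison
   (`filter_sites()`, `methylation_percentage()`, `compare_methylation()`)
   and parent-of-origin allele-specific expression
   (`allele_expression()`, `summarize_origin()`, `imprinting_test()`).
6. **Synthetic data with planted truth** (`simulation_config()`,
   `simulate_all()`) so that every stage is testable closed-loop.

The exported functions, `run_pipeline()` and this vignette are the
package's interface; there is no shell executable because the natural user
is an R analyst working from tables.

## The deletion map: breakpoint minimisation

The raw genotyping data is a mutants × markers presence/absence matrix.
Markers sharing a deletion pattern are grouped into *virtual markers*
(exact pattern identity first; if more groups than requested, the closest
patterns under a missing-aware normalised Hamming distance are merged by
average-linkage clustering). Ordering then minimises the total number of
*breakpoints*: cells where consecutive non-missing calls along the order
differ within a mutant. The map ends are treated as continuing the status
of the adjacent marker, so only internal transitions count; a mutant with
one interior deletion contributes two breakpoints, one if the deletion
touches an end. Minimising breakpoints is the consecutive-ones relaxation:
when an order exists that makes every deletion contiguous, it attains the
minimum.

Missing calls are bridged — a missing run between equal calls contributes
nothing, between different calls exactly one breakpoint — so ungenotyped
cells are never penalised.

Exhaustive search enumerates orders up to whole-map reversal (reversal
cannot change the objective) and reports *all* co-optimal orders,
canonicalised so the lexicographically smaller end comes first; the count
of co-optima is an honest statement of how much the data actually
constrain the order. The default heuristic is greedy nearest-neighbour
construction from every start followed by local search with 2-opt segment
reversals and or-opt relocation of one- and two-marker segments, always
evaluated on the true breakpoint objective. The test suite checks the
heuristic against exhaustive enumeration on hundreds of random instances
of up to 8 virtual markers. Within each cluster, member markers are
re-ordered by the same objective with the flanking clusters' consensus
patterns as fixed context; members with identical patterns are flagged
uninformative and left in input order.

## Deletion calling

**Y gametologs.** Because the Y is hemizygous, a deleted Y copy has no
second allele to mask it: the call is *deleted* exactly when the Y copy's
summed FPKM across the mutant's technical replicates is zero
(criterion i). To protect against genes that are simply silent, the gene
must be testable: its X copy expressed above a floor in at least one mutant
(ii) and both copies expressed in non-irradiated controls (iii). Genes
failing (ii) or (iii) are reported *unclassifiable*, never *not deleted*.
The expression floor defaults to FPKM 0.5; synthetic recovery tests lower
it beneath the simulated baseline so every planted deletion is
classifiable.

**Autosomal hemizygosity.** A heterozygous deletion halves copy number, so
the mutant/control RPKM ratio (RPKM = reads / (kb × million mapped reads))
is expected at 0.5. Genes with a ratio inside `[0.3, 0.7]` and adequate
control RPKM are flagged. Because a heterozygous deletion is contiguous on
the genetic map, an optional contiguity filter keeps the largest run of
flagged genes on one linkage group and calls the *whole span* of that run
hemizygous, rescuing interior genes whose ratio left the window by
counting noise. The run tolerates up to `gap = 3` consecutive unflagged
genes: under Poisson counting at a control depth of ~50 reads per gene,
a truly hemizygous gene leaves the window with probability ≈ 0.10, so a
tolerance of 1 would split a ~50-gene block in roughly a third of
panels, whereas 3 makes splits negligible while spurious extension stays
vanishingly rare (a diploid gene's ratio falls below 0.7 with probability
≈ 0.001). `region_span()` reports the block's extent in centimorgans.

## Relative expression and category statistics

Technical replicates (up to three per individual) are combined by
arithmetic mean; at the default replicate CV of 0.1 simulated replicates
correlate above 0.8, matching the quality regime expected of real data.
Ratios are mutant/control per gene, with the control a phenotype-matched
individual or a pooled mean; genes whose control value is below the floor
(default FPKM 0.5) are dropped and counted. Categories follow the
deletion calls: an X-linked gene is `X_del` in a mutant exactly when its Y
partner is called deleted there, `X_nondel` otherwise; surviving Y copies
are `Y_nondel`; deleted Y copies are excluded from ratio analysis.

Category location tests use the two-sided Wilcoxon rank sum test against
the same mutant's autosomal ratios, exact when both groups have at most 25
values and the pooled data are tie-free, otherwise the normal
approximation with continuity and tie correction. One-group signed-rank
mode tests a median against a null value (e.g. hemizygous ratios against
0.5). Per-gene differential tests are Welch t tests across replicates with
Benjamini–Hochberg adjustment over the tested set, feeding volcano-style
tables (log2 ratio, −log10 q).

Stratification bins are: dS < 0.04 (young stratum), 0.04–0.08, > 0.08
(old stratum); and control Yc/Xc expression ratio < 0.3 (highly
degenerate), 0.3–0.7 (partially degenerated), > 0.7 (non-degenerate). The
middle bins are closed on both ends — the boundary convention the source
wording leaves open.

PCA operates on the mutants × genes matrix of log2 ratios (log so up- and
down-regulation are symmetric; genes centred), keeping genes observed in
every mutant, followed by k-means (default k = 3) on the leading scores.
Bimodality detection uses a Gaussian kernel density (Silverman's
rule-of-thumb bandwidth by default) and reports local maxima above 10% of
the global maximum.

## IDC classification and factor localization

A mutant is IDC-positive when the medians of *all* its available X
categories reach the threshold (default 1.3) and the primary category
(X_del when present) is significant against the autosomal category at
α = 0.01. Requiring both X_del and X_nondel reflects the biology being
modelled: a trans-acting compensation trigger upregulates X-linked genes
generally, not only those whose Y partner happens to be deleted.

The factor region is the marker set deleted in every positive mutant and
in no negative mutant. Missing calls are permissive in positives (a
missing call cannot veto membership) and conservative in negatives
(treated as non-deleted) — mirroring how PCR genotyping failures are
interpreted in practice. The candidate set is checked for contiguity on
the map order and reported whole with a warning if non-contiguous or
empty; adding negatives can only shrink it (anti-monotone), which the test
suite checks as a property.

## Methylation and imprinting companions

Methylation: per-site calls are filtered to coverage ≥ 5, and genes whose
mean site coverage is below 3 are removed entirely; per-gene percentages
are pooled methylated reads over pooled coverage, per context (CpG, CHG,
CHH) and region (coding vs 5 kb upstream). Comparison reports both the
rank-sum test of mutant vs control percentage distributions and the
signed-rank test of per-gene ratios against 1, since either reading of
"compared by Wilcoxon" is defensible; genes with zero control percentage
are excluded from ratios and counted.

Imprinting: allelic expression is E = r/(n·l) — reads over one parental
origin's alleles, divided by the SNP count of the gene and the library
size. Library size is carried in millions of reads for readable
magnitudes; any consistent unit cancels in the maternal/paternal ratios
that are actually tested. E values are averaged per origin across progeny
of the same sex (four values per gene) and tested per Y/X degeneration
bin (> 0.75, 0.25–0.75, < 0.25, autosomal) by signed-rank of log ratios
against 0. Genes with a zero E on either side are excluded from the log
test and counted.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study design: ~100
mutants × 160 ordered markers with zero, one or two contiguous deletion
runs of up to ~40 markers; five mutants deleting a planted 13-marker
factor interval (runs of other mutants are truncated at the interval
boundary, so negatives flank it — the configuration that makes its borders
identifiable); log-normal baseline FPKM (median 20, log-sd 1, matching
the right skew of real FPKM); all-or-nothing per-gene compensation (a
responding gene is multiplied by the fold in every triggered mutant),
which is what produces the observed *bimodal* X_del ratio distribution
rather than a smeared mean shift; Poisson genome coverage at depth ×
copy-number/2; binomially split allelic counts with a configurable
maternal/paternal bias on X-linked genes (in males the paternal "allele"
is the Y copy at its Yc/Xc level); CpG-dominant methylation with ~2%
CHG/CHH rates.

They do **not** emulate: read-level artifacts (mapping bias, positional
coverage, GC effects), biological replicates or genotype background
variation, partial deletions or copy-number states other than 0/1/2,
linked compensation responses (each gene responds independently), or
inter-gene correlation. Passing closed-loop tests therefore demonstrates
that the *algorithms* recover what was planted under the stated noise
model — not that real data meet that model.

Two identifiability limits are worth naming. First, with the compensated
fraction at exactly 0.5 the X_del median sits on the boundary between the
two modes, so per-mutant median classification is undecidable by design;
integration tests of classification use a clearly identifiable fraction
(0.85), while bimodality tests use 0.5, where the two modes are
best balanced. Second, the factor region is recovered exactly only when
the panel's other deletions trim every marker adjacent to the interval;
the generator's truncated-run design makes this overwhelmingly likely at
the study's panel size, and the localization tests verify the planted
interval against a truth-side oracle.

## Numerical and reproducibility choices

- One global seed is fanned out to fixed per-stage child seeds
  (`seed × 1000 + stage offset`, reduced modulo 2³¹), so identical
  (seed, config) pairs give bit-identical outputs and any stage can be
  re-run in isolation; generators restore the caller's RNG state.
- Exhaustive ordering is capped at 10 virtual markers (about 1.8 million
  orders after reversal deduplication); above that the heuristic is
  required. Ties among co-optimal orders break lexicographically after
  reversal canonicalisation.
- Consensus patterns use per-mutant majority with missing ignored and
  ties resolved to *present* (the conservative call for a deletion map).
- Ratio denominators use a control floor rather than pseudo-counts, so a
  reported ratio is always a ratio of observed expression.
- Degenerate inputs error early and by name: empty groups, unpaired
  mutants, markers with all calls missing, single-gene spans.

## Problem sizes in the test suite

The suite runs the full pipeline at reduced but structurally faithful
sizes (20–100 mutants, 30–163 markers, 120–1000 genes, 3 technical
replicates), the ordering oracle on 200+ random instances of up to 8
virtual markers, the Wilcoxon engine against brute-force enumeration on
1000 random small-sample cases, FDR calibration over 100 simulated null
panels, and imprinting calibration over 200 simulated crosses — sizes
chosen so the whole suite completes in well under a minute per module
while keeping every estimate's Monte Carlo error far below the asserted
tolerances.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1, n_mutants = 40, n_expression_mutants = 10,
                         compensated_fraction = 0.7)
report <- run_pipeline(run_config(sim = cfg, k = 14))
report$summaries          # per-mutant category medians, SDs and rank tests
report$idc_classification # which mutants trigger compensation
report$factor_region      # markers deleted in all positives, no negatives
```

## Known limitations

- The deletion map's heuristic has no optimality certificate above the
  exhaustive cap; co-optima are only enumerated exhaustively.
- Hemizygosity calling assumes a single dominant deletion per genome; two
  comparable blocks on different linkage groups would compete for the
  "largest run".
- The methylation module compares one mutant against one control sample;
  replicate-level methylation designs are out of scope.
- Classification sensitivity degrades as the compensated fraction
  approaches 0.5 from above, as discussed.
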