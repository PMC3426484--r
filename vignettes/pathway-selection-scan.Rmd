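---
title: "Scanning a metabolic pathway for differentiation and selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a metabolic pathway for differentiation and selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and their defaults, what the synthetic
data do and do not emulate, and the numerical decisions taken where the
underlying protocol left them open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The question the pipeline answers

A metabolic pathway whose parts face different functional constraints —
here, asparagine N-glycosylation, with an upstream part that builds the
single N-glycan precursor consumed by the calnexin/calreticulin
protein-folding checkpoint and a downstream part that diversifies glycans
on membrane proteins — lets one ask whether population differentiation
and recent positive selection concentrate in one part. The pipeline
quantifies, per gene, two complementary per-SNP signals, aggregates them
over gene regions against a genomic background, and then compares the
parts and relates the signals to the gene's position in the pathway
graph.

## Per-SNP statistics

**F~ST~, one group versus the rest.** Each continental group is
contrasted against all remaining haplotypes pooled. Inputs are phased, so
counting is haploid. The default estimator is the Weir–Cockerham
variance-component θ̂ specialized to two haploid subsamples,

$$\hat\theta = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG},$$

with $MSP = \sum_i n_i(p_i-\bar p)^2$, $MSG = \sum_i n_i p_i(1-p_i) /
(n_T - 2)$ and $n_c = n_T - (n_1^2+n_2^2)/n_T$. Nei's
$G_{ST} = (H_T - H_S)/H_T$ and the unbiased Hudson form are selectable
(`estimator`); downstream stages consume ranks, which are robust to the
choice. Negative estimates are clamped to 0 by default (`clamp`), so
empirical p-values are monotone in differentiation; the clamp puts a
point mass of tied zeros at the null that is visible in the empirical
p-value distribution (see *Calibration* below). Monomorphic sites and
subsamples below 2 haplotypes return missing values.

**EHH and iHS.** For a core SNP and allele, EHH at position $x$ is the
probability that two random distinct carriers are identical at every
site from the core to $x$ — computed by refining a partition of the
carriers column by column, $EHH = \sum_h \binom{n_h}{2} / \binom{n_c}{2}$,
which the test suite proves equal to an $O(n^2 m)$ pairwise-comparison
oracle. iHH integrates each curve by trapezoid out to the point where EHH
first drops below the cutoff, summed over both directions;
iHS~unstd~ = ln(iHH~A~/iHH~D~); scores are standardized to mean 0 / sd 1
within derived-allele-frequency bins and reported in absolute value,
since only the presence of selection, not the swept allele, is of
interest.

Parameters, all in `ihs_params()`:

* `cutoff = 0.05` — the conventional EHH truncation level.
* `n_bins = 20` equal-width frequency bins, merged with their nearest
  occupied neighbor below `min_bin_count = 10` SNPs. The binning operates
  on derived frequency; the original scan software's binning is not
  documented, so these are declared defaults, not inferred ones.
* `freq_range = c(0.05, 0.95)` — SNPs outside it are not scored
  (unstable integrals), consistent with the global MAF filter.
* `boundary = "exclude"` — a SNP whose EHH has not decayed below the
  cutoff at a chromosome end is flagged `edge` and dropped, the common
  scan practice; `"keep"` truncates and keeps instead.
* `distance_mode = "bp"` — physical distance; a `genetic_pos_cM` column
  switches integration to the genetic map.

iHS requires ancestral orientation and missing-free haplotypes; the VCF
reader enforces orientation from the `AA` INFO tag (dropping sites whose
ancestral call matches neither allele) and the scan refuses panels with
missing genotypes rather than imputing them, since phasing/imputation is
upstream of this package by design. Sites without an ancestral call can
be retained for F~ST~, which is orientation-invariant.

## From scores to gene-level calls

Empirical p-values contextualize each score among SNPs of similar minor
allele frequency: SNPs are sorted by MAF and chunked into bins of
`snps_per_bin` (default 10,000, the genome-scale value; scaled runs use a
value from their configuration), and
$p = (\#\{\text{strictly greater}\} + 1)/(n + 1)$. The +1 correction is a
deliberate deviation from the literal "proportion greater", which would
assign the top SNP p = 0 and break the logarithm in Fisher's
combination; it preserves ranking exactly and bounds p in (0, 1). Bins
are computed per group × statistic — each track is its own genome
context.

Gene regions are the gene body ± `flank_bp` (default 100,000 bp, both
bounds inclusive, 1-based coordinates; BED input is converted at the
boundary). Fisher's combination $Z_F = -2\sum_i \ln p_i$ is referred to
the upper tail of χ²(2k). Genes whose flanks overlap share SNPs and are
scored independently, matching the region-wise construction. The same
machinery applied to a catalog of non-overlapping background regions
yields the genomic null; a gene's empirical rank
$(\#\{\text{background} \le \text{gene}\} + 1)/(N_{bg}+1)$ must fall at
or below $\alpha/(n_{groups} \times n_{methods})$ — 0.05/14 at the
defaults — for a significance call. Background ranking uses the χ² tail
p rather than raw $Z_F$ so regions with different SNP counts are
comparable. The *printed* per-gene p-value is the χ² tail (and its
Bonferroni multiple), which is why a reported p can be many orders of
magnitude below the $1/(N_{bg}+1)$ resolution of the empirical rank that
actually drives the call.

## Part comparison and network analysis

A gene is an *event* for a statistic if significant in at least one
continental group. Only upstream and downstream genes enter part
comparisons; substrate-synthesis genes (their product feeds both parts)
and unplaced genes are scored but excluded. Three tests are run: an
observed-versus-expected goodness-of-fit χ² with expectations
proportional to part size (df = 1); Mann–Whitney on the genes' $Z_F$
values per group; and hypergeometric enrichment of each part against the
background event rate. The Mann–Whitney implementation uses midranks,
$U = \min(U_1, U_2)$, a Z computed from group 1's U with tie-corrected
variance, and the normal approximation — the exact layout of the
published rank-sum tables, which the test suite reconstructs.

Centralities on the pathway graph (nodes = genes, edges = shared
metabolites) follow the CentiScaPe conventions by default: eccentricity
and closeness as reciprocals (larger = more central), raw unnormalized
betweenness over unordered pairs, and centroid
$\min_w[\gamma_v(w) - \gamma_w(v)]$ where $\gamma_v(w)$ counts vertices
strictly closer to $v$ than to $w$ (ties count for neither; the count
runs over all vertices including $v$ and $w$). A `convention = "classical"`
flag exposes the textbook definitions. Distances and betweenness come
from igraph; centroid is computed from the distance matrix directly, and
all five are verified against brute-force path-enumeration oracles on
exhaustively enumerated small graphs. The set of genes entering the
association tests is taken explicitly (default: all graph nodes), since
protocols differ on whether excluded genes keep their network position.

## The synthetic study generator

`simulate_study()` produces an HGDP-like study with known ground truth:

* **Structure.** Balding–Nichols per-group derived-allele frequencies,
  Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$, around an array-like, roughly uniform
  ancestral frequency spectrum. `wright_F = 0.1` by default, in the range
  typical of continental-scale human differentiation.
* **Linkage.** A Markov copying pass rebuilds each haplotype as a mosaic
  of its group's site-wise-independent base haplotypes, switching
  template at `copy_switch_rate = 1e-5`/bp. This produces realistic
  local LD decay without a coalescent simulator and keeps the generator
  desk-scale and dependency-free; a coalescent backend could be slotted
  in later.
* **Sweeps.** Constructed, not forward-simulated: a target fraction of
  haplotypes (default derived frequency 0.6) receives the derived core
  allele and is rebuilt as a mosaic of one founder haplotype with one-way
  recombination escapes at 5 × 10⁻⁸/bp within ±100 kb of the core. The
  carrier set, founder and decay rate are therefore exact and
  assertable.
* **Scale.** Defaults: 7 labelled groups × 30 diploids, 5,000 SNPs on a
  24 Mb chromosome (≈ 1 SNP / 4.8 kb, matching the ~1 SNP / 5 kb density
  of the motivating array data), 57 pathway genes annotated
  25 upstream / 21 downstream / 10 substrates / 1 excluded — the
  composition of the real pathway — and 500 background regions. Region
  widths are scaled (gene 4 kb, flank 10 kb) so that all 557 regions tile
  one chromosome without overlap; the analysis default `flank_bp = 1e5`
  applies to real-scale input, while synthetic runs pass the generator's
  own flank. The global MAF floor (0.05) is enforced by construction:
  violating columns are dropped, so a panel may hold slightly fewer than
  `n_snps` sites.
* **Determinism.** Every stage (positions/frequencies, copying, sweep,
  fixture) draws from its own substream of the master seed, so toggling
  the sweep leaves the neutral background bit-identical.

What the generator does **not** emulate: demographic history
(bottlenecks, expansions, migration), recombination-map heterogeneity,
array ascertainment bias beyond the uniform MAF spectrum, and selection
acting through allele-frequency change (sweeps alter haplotype structure
only). Passing tests therefore certify the statistical machinery —
estimator identities, calibration under exchangeability, power against a
constructed haplotype signal — not robustness to the demographic
confounders that complicate real scans.

## Calibration, numerical choices, degenerate inputs

* The test suite and acceptance script verify: Weir–Cockerham against an
  independent transcription of the variance-component formulas (1e-12);
  EHH against the pairwise oracle (1e-12); Fisher's p against the
  closed-form even-df χ² tail (1e-12); empirical p against direct
  counting; recovery of Wright's F = 0.15 by mean F~ST~ within ±0.03 at
  2,000 SNPs × 100 haplotypes/group; per-bin iHS moments exact to 1e-12;
  a neutral |iHS| > 2 fraction near the two-sided normal tail; sweep
  detection (core above the panel's 95th percentile) in ≥ 9/10 seeds;
  and, under the global null, a significant-call fraction within
  binomial error of the nominal rate with uniform empirical p-values
  (KS at the 1% critical value). The calibration run uses 7 × 12
  diploids, 2,500 SNPs and 300 background regions; the property runs use
  the sizes just quoted — sizes chosen so the whole suite stays
  desk-scale while the Monte-Carlo bands remain tight.
* Uniformity of empirical p-values holds for continuous scores. The
  clamped F~ST~ default places an atom of tied zeros under the null, so
  the uniformity check is run on |iHS| and on the unclamped F~ST~ track;
  the clamp stays on by default because the ranking of positive
  estimates — all that downstream stages use — is unaffected.
* Ties in empirical p use the strictly-greater rule, so duplicated
  maxima share the smallest p of their bin. Ties in ranks use midranks
  with tie-corrected variance (toggleable). γ-ties in centroid
  centrality count for neither node.
* Degenerate inputs error loudly rather than silently: unphased
  genotypes (named sample and site), alleles too rare for EHH, frequency
  bins with zero variance, all-tied rank tests, empty pathway parts,
  overlapping background regions, unreachable sweep frequencies.
* The Bonferroni multiplier is `n_groups × n_methods` (14 at the
  defaults) and the empirical threshold is applied inclusively.

## Known limitations

Only two-population (focal versus pooled rest) F~ST~ contrasts; no
XP-EHH/nSL; no LD-aware effective-SNP correction in Fisher's combination
(tag-SNP sparsity is assumed); the normal approximation of the
Mann–Whitney p is inaccurate below ~8 observations per group; no
phasing, imputation or liftover — inputs must arrive phased and
ancestral-annotated; and the centrality association treats the
significance call as binary, discarding effect sizes.
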