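---
title: "Methods and design notes for haplopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for haplopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific setting

`haplopop` implements a comparative population-genomics workflow for
haplodiploid species, modeled on a study design with six populations of 25
haploid males split into two behavior groups (three eusocial, three
solitary), plus two outgroup haplotypes from a sister species. Because
males are haploid, a heterozygous genotype call in a male is a genotyping
artifact, and the whole pipeline — QC, diversity, differentiation, LD,
association — is written for haploid calls over the alphabet
ref/alt/H(artifact)/M(missing). The pipeline starts from a called
multi-sample VCF; read mapping and variant calling are out of scope.

## The QC cascade

Individuals are filtered first (heterozygous-artifact fraction among
called sites strictly greater than 30% removes an individual), then
sites, so site statistics reflect the final cohort. Site filters, each
evaluated independently on the same input so the report can tally a site
under every filter it fails:

* non-SNP class (indels and MNPs),
* phred site quality below 30,
* H calls in **15 or more** ingroup individuals,
* uncalled in **16 or more** ingroup individuals,
* more than one alt allele,
* minor-allele frequency below 0.05, computed over called (non-H, non-M)
  ingroup genotypes of retained individuals.

H calls never enter allele-frequency denominators: in a haploid they carry
no allelic information. The thresholds 15 and 16 are absolute counts, as
in the originating design (143 ingroup samples); fractional alternatives
can be configured for differently sized cohorts. Outgroup samples face the
same individual-level QC but never count toward site filters. Whether the
MAF filter should precede the removal of high-heterozygosity individuals
is not derivable from the source design; individual-first is this
package's documented choice, and QC is idempotent either way.

## Diversity

Per-site nucleotide diversity uses the unbiased pairwise estimator
$\pi_{site} = \frac{n}{n-1} 2 p (1-p)$ over the $n$ called haploid
genotypes at a site, summed over sites and divided by the genome length
$L$. Watterson's estimator is $\theta_W = S / (a_n L)$ with
$a_n = \sum_{i=1}^{n-1} 1/i$. Both are reported; on equilibrium-neutral
input they estimate the same quantity, which the tests verify on
calibrated simulations (ratio within [0.8, 1.25] aggregated over seeds).

## Weir–Cockerham F\_ST for haploids

The diploid Weir–Cockerham estimator has three variance components; the
within-individual (heterozygosity) component does not exist for haploids,
so the package implements the haploid analogue with only the among-group
component $a$ and within-group component $b$:

$$\bar n = \tfrac{1}{r}\sum_i n_i, \quad
  n_c = \frac{r\bar n - \sum_i n_i^2/(r\bar n)}{r-1}, \quad
  \bar p = \frac{\sum_i n_i p_i}{r \bar n}, \quad
  s^2 = \frac{\sum_i n_i (p_i - \bar p)^2}{(r-1)\bar n}$$

$$b = \frac{\bar n}{\bar n - 1}\Big(\bar p(1-\bar p) - \frac{r-1}{r}s^2\Big),
  \qquad
  a = \frac{\bar n}{n_c}\Big(s^2 - \frac{b}{\bar n}\Big)$$

Per-site $F_{ST} = a/(a+b)$ (possibly negative — estimator noise around
zero differentiation); the multi-locus estimate is the **ratio of sums**
$\sum a / \sum (a+b)$, the standard multi-locus combination (a
mean-of-ratios mode exists for sensitivity analyses). Sites where any
group has fewer than two called genotypes, or where $a+b=0$, are excluded
from the sums. The fixed-difference limit gives exactly 1 and the
no-differentiation limit is centered on 0; both are tested, along with
1e-12 agreement against an independently coded direct-formula oracle.

## Permutation null for behavior-group differentiation

Significance of between-behavior-group differentiation is assessed by
shuffling behavior labels across individuals. Each of the (default) 1000
permutations draws a fresh random subset of up to 100,000 SNPs without
replacement and recomputes the genome-wide ratio-of-sums F\_ST — the
resample-per-permutation reading of "a randomly-selected subset"; a
fixed-subset mode is available because the source description is
ambiguous. The p-value is $(1 + \#\{null \ge obs\})/(1 + n_{perm})$,
which can never be exactly zero; with 1000 permutations the attainable
minimum is $1/1001$.

## LD, pruning and PCA

Pairwise $r^2$ is the squared Pearson correlation of the two haploid 0/1
vectors over jointly called samples, for all same-scaffold pairs within a
50 kb window (the window and distance-bin edges are configurable; the
default decay curve uses a 0–50 bp bin then log-spaced bins). Pruning
follows the `--indep 50 5 2` recipe: a 50-SNP window advancing by 5 SNPs;
within a window the SNP with the highest variance-inflation factor (the
diagonal of the inverted correlation matrix) is removed until all VIFs
fall below 2; removals are global, and exact duplicates are resolved by
removing the later-coordinate copy. Missing/artifact calls are
mean-imputed for pruning and PCA (the common practice of the cited
tooling; the source does not state a policy). PCA mean-centers each SNP
and scales by $\sqrt{p(1-p)}$ — frequency scaling, under which haploid
genotypes have unit variance at every MAF — then eigendecomposes the
sample covariance; coordinates are projections on the top eigenvectors.

## Mixed-model association

The scan fits, per SNP, $y = \mu + x\beta + u + \varepsilon$ with
$u \sim N(0, \sigma_g^2 K)$ and $\varepsilon \sim N(0, \sigma_e^2 I)$,
where $K$ is the centered genomic relatedness matrix
$K = \tfrac{1}{m} G G^\top$ (mean-imputed, column-centered dosages). The
binary phenotype (social = 1) is treated as quantitative, as the cited
association tool does for case-control labels. $K$ is eigendecomposed
once; the restricted likelihood (REML; ML was considered and left out
since the source names only the tool) is profiled over
$\lambda = \sigma_g^2/\sigma_e^2$ on $\log\lambda \in [\log 10^{-5},
\log 10^{5}]$. For speed the profile is first evaluated on a 41-point
grid vectorized across all SNPs, then each SNP's optimum is refined by
bracketed scalar optimization inside its grid cell; spot checks put the
refined optimum within ~1e-7 log-likelihood units of a full-interval
scalar optimization. The Wald statistic $(\beta/se)^2$ is referred to
$\chi^2_1$, and multiplicity is handled by Benjamini–Hochberg step-up
q-values (the source cites an FDR correction without naming the
procedure; BH is this package's fixed choice) with the genome-wide
threshold $q < 5\times10^{-5}$ as default. At the $\lambda \to 0$
boundary (or $K = I$) the scan reproduces OLS p-values exactly, and on
structured-but-null simulations the genomic inflation factor stays in
[0.8, 1.2] while naive OLS exceeds 1.5 — the mixed model absorbs the
population structure that would otherwise masquerade as association.

## Annotation and enrichment

Positional classes are strand-aware: `upstream_5kb` extends 5 kb against
transcription from the TSS, `downstream_1kb` extends 1 kb beyond the last
codon (the stop codon's final CDS base in transcription direction);
inside the gene body a SNP is exonic or intronic, and within-CDS SNPs are
classified synonymous/non-synonymous by codon substitution under the
standard nuclear code when a reference sequence is available (phase and
codon context come from the gene model; without sequence they fall back
to `exon_other`, which also holds UTR bases). Remaining SNPs within 10 kb
of a gene span are `gene_proximal_10kb`, all else `intergenic`. When
windows of several genes overlap, precedence is coding > intron >
downstream > upstream > proximal, nearest gene breaking ties — the source
reports disjoint category counts without stating precedence, so the rule
is documented here as this package's choice. Multiple isoforms collapse
to the longest CDS. Enrichment tests are upper-tail hypergeometric; the
background is the set of *tested* (post-QC) SNPs, not all genomic
positions, matching the sampling frame of the scan. Allele polarization
requires every called outgroup haplotype to agree; discordant or missing
outgroups leave a site unpolarized.

## Expression-assay statistics

qPCR: technical replicates are averaged per sample and gene (the
biological replicate is the unit of analysis), $\Delta C_T =
\overline{CT}_{target} - \overline{CT}_{reference}$, and fold change is
$2^{-(\Delta C_T - \overline{\Delta C_T}_{baseline})}$, so baseline
(solitary) fold changes have geometric mean exactly 1. Group differences
are tested on $\Delta C_T$ with a pooled-variance two-sample t-test
(Welch behind a flag; the source says only "t-test"). A second reference
gene is supported by recomputation, not by multi-reference geometric-mean
normalization. Reporter assays: one-way fixed-effects ANOVA followed by
Tukey HSD on the studentized range, with the harmonic mean of the two
group sizes per pair (Tukey–Kramer) for unbalanced designs; the source
assay statistics (t = −6.32; F(4,20) = 65.01) rest on unpublished raw
measurements, so only the formula path is implemented and oracle-tested.

## The synthetic-data generator: what it emulates

The generator is first-class, tested code; its defaults *are* the stated
study conditions:

* 6 populations × 25 haploid males, 3 social / 3 solitary, plus 2
  outgroup haplotypes;
* Balding–Nichols population frequencies
  $p_i \sim Beta(p\tfrac{1-F}{F}, (1-p)\tfrac{1-F}{F})$ with $F = 0.06$
  (the genome-wide differentiation scale of the system; $F = 0$
  degenerates to copying the ancestral frequency);
* ancestral MAF uniform on [0.05, 0.5] (sites below 5% are removed by QC
  anyway); one SNP per ~130 bp, the empirical SNP density of the system,
  which also puts per-site diversity on the ~0.002 scale;
* heterozygous-artifact calls at rate 0.002 and missingness 0.01 per
  call — rare enough that the absolute QC thresholds (15, 16) bite only
  on planted violations, as in the real cascade;
* block LD: one latent uniform per individual per 250 bp block,
  thresholded against the per-SNP population frequencies (comonotone
  copying from a local template). Marginal frequencies are exact,
  within-block $r^2$ is elevated, cross-block pairs are independent —
  mirroring a system whose $r^2$ halves within ~250 bp. This is
  deliberately not a coalescent: downstream analyses consume
  site-frequency structure and local LD only, so long-range haplotype
  realism would buy nothing at desk scale;
* causal architecture: a between-behavior-group frequency displacement
  (±shift/2 around the ancestral value, clipped to [0,1]) — a
  local-adaptation model, matching a design where phenotype is assigned
  at the population level, not an individual liability model. Causal
  sites are seeded at intermediate ancestral frequency
  (uniform on [shift/2, 1 − shift/2]) so the configured displacement
  survives clipping; this choice was fixed before any acceptance run;
* outgroup haplotypes deterministically carry the ancestral major allele
  (no private outgroup mutations) — they exist only for polarization;
* a `neutral_sfs` ancestral law (derived-allele counts $\propto 1/k$, no
  population structure) exists solely for diversity calibration, where it
  makes $E[\pi] = E[\theta_W]$ by construction.

What the generator does **not** emulate: demographic history
(bottlenecks, growth, migration beyond the island model), selection
other than the planted shift, sequencing depth/quality structure
(QUAL values are decorative draws above the filter threshold), linked
selection, or reference-sequence emission. A green simulation-based test
therefore establishes that the *estimators and decision rules* behave as
specified under the stated frequency/LD structure — not that the pipeline
is robust to realistic demographic misspecification.

Determinism: every stage that draws random numbers takes a seed; an
identical configuration yields byte-identical VCF/GFF3/TSV output.
Frequency recovery is verified in aggregate (frequency-binned means):
binomial noise at 25 haploids has sd 0.1 at intermediate frequency, so a
per-SNP sup-norm bound of 0.1 is not attainable and was not intended.

## Numerical choices and degenerate inputs

* p-values from permutation tests use the add-one convention and cannot
  be zero; Wald p-values are floored at the smallest positive double.
* Zero-variance SNPs are skipped by the scan (flagged, `NA` statistics);
  non-finite fits report p = 1 with a flag rather than dying mid-scan.
* Exactly collinear SNPs in pruning are detected before matrix inversion
  (|r| within 1e-10 of 1) and resolved later-coordinate-first.
* Grid-plus-refinement REML is documented above; eigenvalues of K are
  clamped at 0 before use.
* Coordinates are 1-based inclusive at every file boundary (VCF, GFF3)
  and 0-based half-open internally; the converters are tested inverse
  bijections.
* Homozygous calls for a second alt allele ("2/2") cannot be expressed in
  the biallelic {0,1,H,M} alphabet; they are read as missing and the site
  keeps its multiallelic annotation, so the biallelic QC filter removes
  it. The reader never silently splits multiallelic sites.

## Known limitations

* One acceptance property is knowingly red: with the stated default world
  (10⁴ SNPs, shift 0.5 added after Balding–Nichols drift, population-
  assigned phenotype), the planted causal SNP wins the genome-wide
  minimum p in ~60% of replicates, not ≥ 90% — the causal displacement
  carries drift plus sampling noise (z ≈ N(4.3, 1)) while the maximum of
  10⁴ calibrated null statistics sits near z ≈ 3.9. The scan itself is
  calibrated (separately verified); the 90% figure would require a larger
  shift or fewer tested sites.
* The LMM is a quantitative-trait approximation for binary labels; no
  logistic/liability mixed model is provided.
* Tukey HSD uses the pairwise harmonic-mean (Tukey–Kramer)
  approximation for unbalanced designs, not exact unbalanced-range
  integration.
* The annotation module classifies only positional/coding-change
  categories; no splice/UTR impact tiers, no GO machinery, no ortholog
  inference — external gene sets are taken as given id lists.
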