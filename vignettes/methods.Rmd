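---
title: "Methods: strain-resolved population genetics from pooled metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-resolved population genetics from pooled metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpop)
```

## The setting

A shotgun metagenome of one host individual pools reads from its entire
within-host symbiont population. At a core-genome site the data are
therefore nucleotide counts, not genotypes, and "population" quantities
must be estimated directly from those pooled counts. strainpop covers the
path from such count tables — together with strain haplotypes produced by
a deconvolution tool, a strain tree, per-sample strain frequencies, gene
coverage matrices and in-frame gene sequences — to diversity,
differentiation, selection and community-structure statistics.

## Estimators on pooled counts

**Intra-sample nucleotide diversity.** At site $i$ with counts $X_{i,B}$
and coverage $C_i$, the probability that two reads drawn *without
replacement* differ is
$\sum_{B_1 \ne B_2} \frac{X_{i,B_1}}{C_i}\frac{X_{i,B_2}}{C_i-1}$;
$\pi(S,G)$ averages this over the genome. Division by $C_i(C_i-1)$ makes
the single-site estimator unbiased for $2f(1-f)$ under binomial read
sampling at true frequency $f$ — the suite verifies this to three Monte
Carlo standard errors at coverages 10 and 100 ($10^4$ replicate sites).

**Inter-sample diversity and $F_{ST}$.** $\pi(S_1,S_2,G)$ draws one read
from each sample (independent draws, denominators $C_{i,S_1} C_{i,S_2}$),
and $F_{ST} = 1 - \pi_{within}/\pi_{between}$. Two conventions matter:

- $|G|$ is the **full core-genome length**, monomorphic sites included.
  Sites absent from the count table contribute zero, so a table restricted
  to SNV sites plus the true $|G|$ gives the same value as a whole-genome
  table. Per-site $\pi$ values are then small (order $10^{-3}$ and below),
  as expected for low-diversity intracellular symbionts.
- Sites with $C_i < 2$ (intra) or $C_i < 1$ (either sample, inter)
  contribute zero rather than being renormalized; `n_sites_used` reports
  how many sites actually entered. This is the plainest reading of the
  sums and keeps estimates comparable across samples with ragged
  coverage.

$F_{ST}$ is reported as `NA` with a warning when $\pi_{between} = 0$
(0/0), and small negative values are possible and documented as estimator
noise. Fixed differences at every site give exactly 1.

**Correctness strategy.** Both $\pi$ estimators are checked against
independent oracles — exhaustive enumeration of read pairs, and summation
over ordered allele pairs — on $10^3$ random low-coverage sites to
$10^{-10}$.

## pN/pS and the Neutrality Index

The mutational opportunity of a gene is obtained by enumerating all nine
single-nucleotide changes of every codon with equal weight (no
transition/transversion bias; the source procedure is plain enumeration)
and classifying each under the standard genetic code. Changes to or from
stop codons are counted as nonsynonymous — they are not silent; internal
stop codons in a supplied frame raise a warning but do not abort, and
codons containing non-ACGT characters are skipped with a warning.

Observed counts use biallelic SNVs mapped onto reference codons. Per gene,
$pN/pS = \frac{obsN/(obsS+1)}{expN/expS}$: the $+1$ pseudocount keeps
genes without synonymous SNVs defined. Genome-wide, observed and expected
counts are pooled and no pseudocount is applied (both modes are
available; the pooled counts are large enough not to need one).

The Neutrality Index $NI = (pN/pS)/(dN/dS)$ needs each SNV labelled
divergent or polymorphic from the strain haplotype matrix:

- *strain level*: divergent iff the SNV distinguishes at least two
  strains; polymorphic iff it is invariant in the strain alignment (a
  population-wide variant no strain explains);
- *clade level*: additionally requires divergent SNVs to be uniform
  within every clade; SNVs still segregating inside a clade are treated
  as (possibly transient) polymorphism.

On simulated data, where substitutions are placed uniformly without
regard to codon position, both SNV classes share one expected N:S ratio;
the suite checks that the resulting NI's 95% confidence interval (log-odds
normal approximation) covers 1, and that genome-wide pN/pS is consistent
with the mutational opportunity by a binomial test.

## SNV handling

**Coverage normalization** thins deeper samples to the smallest median
site coverage by per-count binomial sampling with retention probability
target/median. Thinning keeps counts integral, matches the read-level
downsampling used in production pipelines at the count level, and leaves
expected allele frequencies untouched (verified over $10^4$ sites).

**Hard filtering** follows GATK-style keep directions: keep when
QD $\ge$ 2, FS $\le$ 60, MQ $\ge$ 40, base-quality RMS $\ge$ 30,
MQRankSum $\ge -12.5$, ReadPosRankSum $\ge -8$. The base-quality keep
direction is genuinely ambiguous in prose descriptions of this filter
set; it defaults to "keep $\ge$ 30" here and, like every threshold, is
configurable. Missing annotations pass vacuously (with a message), and
the filter is idempotent and order-independent.

**Classification**: a SNV is polymorphic in a sample when its frequency
lies in $[0.05, 0.95]$ — bounds inclusive, reading "between" inclusively —
fixed above, absent below; zero-coverage sites are excluded with a
warning. Multi-state SNVs (three or more observed alleles) remain in
$\pi$/$F_{ST}$, whose sums run over all nucleotide pairs, but are excluded
from the allele-frequency spectra and from observed pN/pS counts, which
are defined on biallelic sites.

## Strain utilities

Distances between strains are Hamming counts over SNV sites; percent
identity is $100(1 - d/L)$ at two decimals with $L$ the strain alignment
length. Clades are read off the distance matrix by single-linkage
components under a threshold; since the source of truth for clades is a
splits network read by eye, the default threshold is the midpoint of the
largest gap in the sorted pairwise distances, and it can be set
explicitly. Presence ($\ge 5\%$) and dominance ($\ge 90\%$) calls use
inclusive bounds.

Dominant haplotypes take the allele with frequency $\ge 0.9$ per site,
undefined otherwise; differential-SNV counts between two haplotypes
exclude sites undefined in either (the number excluded is reported — the
conservative choice, since an undefined site is evidence of residual
mixture, not of difference). Ancestral states for the unfolded AFS are
majority-rule across strains with ties resolved by a designated tree tip;
derived frequency is one minus the ancestral allele's read frequency, and
the spectrum uses 20 equal-width right-closed bins by default (a
presentation choice).

## Canopy binning and the core-genome filter

The canopy algorithm is specified by its published behaviour, not by a
reference implementation, so the iteration details are fixed here as:
genes are visited in seeded random order; an unclaimed gene seeds a
canopy whose profile is the per-sample median of its members; membership
(Pearson $> 0.9$ to the profile) and profile are alternated to a fixed
point (at most 100 rounds). Canopies are then merged while any pair of
median profiles correlates above 0.97 (merging precedes member pruning,
following the order in which the steps are described); canopies with
signal (profile $> 0$) in fewer than three samples are removed; members
with Spearman $< 0.7$ to the bin median are pruned; overlapping genes are
kept only in the largest bin (ties by bin id), making the result a
partition; and groups below three genes are dropped. Bins with $\ge 700$
genes are metagenomic species (MGS, candidate core genomes), 3-699 genes
are co-abundant gene groups (CAGs). Zero-variance genes are excluded up
front with a warning because their correlations are undefined.

The core-genome filter removes genes at least $24 \times$ MAD from the
member median in any sample, with MAD **unscaled** (no 1.4826 normal
consistency factor — the rule is stated in raw MADs). When a sample's MAD
is zero, only exact-median genes pass that sample's criterion, with a
warning.

## Diversity measures

Phylogenetic species evenness is computed from the tree's correlation
matrix $C$ (shared root-to-tip branch length, standardized to unit
diagonal — strain trees are generally not ultrametric, and
standardization makes $C$ a correlation structure), restricted to present
strains:
$PSE = \frac{N\,\mathrm{diag}(C)^\top m - m^\top C m}{N^2 - N\bar m}$.
This is the form used by the picante implementation; the suite checks the
numerical identity with PSV at equal abundances and agreement with
`picante::pse` directly. A single present strain yields `NA` (denominator
zero).

Weighted UniFrac is the normalized form: branch-length-weighted absolute
difference of descending community fractions over the branch-length
weighted sum, computed by postorder accumulation from the tree's given
root. It is checked against an independent traversal (per-edge descendant
sets) on random six-tip trees, along with its semimetric properties.

Rank associations use Spearman's correlation (reported with $\rho^2$, the
convention for these comparisons); matrix associations use a Mantel-style
permutation test with Spearman correlation (9,999 permutations by
default), since no specific procedure is named by the source analysis for
the host-symbiont comparison — this choice is flagged as such.

## The gene catalog step

Similarity hits (BLAST outfmt-6-like tables) are filtered — identity
$\ge 95\%$, alignment covering $\ge 90\%$ of the shorter gene, e-value
$\le 10^{-6}$, length ratio $\le 4$, equal partial status, self-hits
dropped — and clustered by single linkage (connected components; cluster
id = lexicographically smallest member, making the partition
order-independent). Identity and coverage are applied in nucleotide
units, since the clustering operates on nucleotide genes. Consensus
representatives vote per position among members sharing the modal length;
members of other lengths are excluded from the vote and counted, which
avoids embedding a multiple-aligner in a plumbing step; ties are broken
by a seeded uniform choice. The two-stage (within-sample, then
cross-sample) procedure is provided and is checked to coincide with
one-stage clustering away from borderline hits, a consequence of
single-linkage transitivity.

## The synthetic community simulator

The simulator generates what the analysis assumes and nothing more:

- A strain tree (clade ancestors under the root, strains under their
  ancestor) with Poisson substitution counts per branch: expectation
  $d_{between}/2$ on root-clade branches, $d_{within}/2$ on clade-strain
  branches, so within-clade pairs differ by $\sim d_{within}$ SNVs and
  between-clade pairs by $\sim d_{between} + d_{within}$. Substitutions
  occupy distinct genome positions (no back-mutation), which makes
  Hamming distances exactly additive along the tree; configurations whose
  expected substitution load exceeds 10% of the genome are rejected
  because that approximation would break down.
- Invariant SNVs at positions untouched by strain substitutions, each
  with one alternative-allele frequency drawn once from $U(0.05, 0.95)$
  and shared across samples — these emulate population-wide variants that
  deconvolution cannot assign to a strain.
- Per-sample strain mixtures from a Dirichlet with concentration 0.3,
  which produces the dominant-strain samples seen in real hosts. An
  optional founder scenario (off by default) instead passes a common pool
  through per-host serial multinomial bottlenecks, a deliberately
  qualitative emulation of self-infection; the real environmental pool
  composition is unknown.
- Pileup counts at SNV sites: depth Poisson with the configured mean
  (mimicking pileup dispersion without read-level simulation), reads
  multinomial at the sample's true allele frequencies, and per-base error
  $e$ moving mass $p \mapsto p(1-e) + (1-p)e/3$. Optional truly
  monomorphic background sites exercise error and filtering code.
- Gene abundance matrices: planted groups share a latent log-normal
  per-sample profile times multiplicative log-normal noise
  (`noise_sd` on the log scale). Coverage outliers are displaced by
  $30 \times$ MAD $+ 1\%$ of the median in one low-coverage sample —
  mapping-artifact-like displacements that leave the gene's overall
  covariation (and hence its bin membership) intact, so they isolate the
  MAD rule rather than re-testing canopy membership.

Default generator settings mirror the sulfur-oxidizer data regime: 11
strains in clades of 4+3+3+1, a 1.27 Mbp core genome split into
whole-codon genes, 19 samples, 482x mean coverage, error rate $10^{-3}$
(typical for quality-filtered short reads), invariant-SNV fraction 4.7%,
and $d_{between} = 6000$, $d_{within} = 1200$, which place pairwise strain
differences in the published several-hundred-to-8000 SNV range.

What the simulator does **not** emulate: read-level artifacts (mapping
bias, indels, chimeras), recombination, gene content variation between
strains, compositional noise in coverage, or linkage decay. Passing tests
therefore demonstrate correctness of the estimators and procedures under
the model's assumptions, not robustness to the full messiness of real
metagenomes.

## Determinism and numerical conventions

Every stochastic step takes an explicit integer seed; internal substream
seeds are derived arithmetically (stage offsets below $2^{31}$) so stages
are decoupled. Reruns with the same seed produce byte-identical output
files, including the pipeline's TSV tables and JSON manifest (which
records inputs, package version, seed and thresholds, and deliberately no
timestamps). Ties are always broken deterministically or by the seeded
generator: consensus ties by seeded choice, overlap removal by bin id,
cluster ids lexicographically.

Test problem sizes were chosen so the default suite completes in well
under a minute of compute per module: 30-120 kb genomes, 6-19 samples,
coverages 100-800 for simulation-based checks; $10^3$-site oracle
comparisons at tolerance $10^{-10}$; $10^4$-replicate calibration checks
at three standard errors; binning recovery at 750-800 core genes with 19
samples. These sizes are the package's own validation choices; all
generator defaults remain at the data-regime values above.

## Known limitations

- pN/pS classifies each SNV against the reference codon independently;
  double substitutions within one codon are not modelled.
- The Neutrality Index is computed from count tables; it does not model
  the sampling dependence between the divergent and polymorphic classes.
- The canopy implementation targets correctness and determinism at
  desk scale (up to ~$10^4$ genes); it recomputes full correlation
  vectors per iteration and is not tuned for millions of genes.
- The clade-threshold default (largest distance gap) assumes clade
  separation exceeds within-clade spread; for weakly structured strain
  sets the threshold should be set explicitly.
- VCF support covers biallelic SNVs with AD/DP fields and the standard
  hard-filter INFO keys only.
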