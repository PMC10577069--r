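---
title: "Scanning genomes for reproductive character displacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for reproductive character displacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The question and the design

When two hybridising species meet along a contact zone, selection against
hybrids can strengthen prezygotic barriers where the species co-occur —
reinforcement. Its genomic footprint is *reproductive character
displacement*: genomic windows where divergence between the **parapatric**
populations of the two species exceeds divergence between their
**allopatric** populations. `rcdscan` implements a window-based scan for
this signature in a four-population design — allopatric and parapatric
populations of a donor species (labelled `MUL`, after the macaque system
in which introgression flows from *M. mulatta*) and of a recipient
species (`FAS`, *M. fascicularis*-like), with introgression assumed
asymmetric into the parapatric recipient population.

A window is a candidate when three signatures co-occur:

1. **Elevated parapatric divergence.** For each divergence statistic
   (Hudson F~ST~ and D~XY~), the window's difference
   $D_d = D_p - D_a$ between the parapatric-pair and allopatric-pair
   divergence must exceed more than 95% of the values obtained under
   permutations of individuals across the four populations.
2. **Directional selection specific to the parapatric recipient.** The
   averaged Tajima's D contrast
   $TD_d = \tfrac{1}{2}\left[(TD_{pf}-TD_{pm}) + (TD_{pf}-TD_{af})\right]$
   must be strictly below −1. The contrast excludes the allopatric donor
   population: the hybridising donor and the allopatric conspecifics are
   the relevant demographic controls.
3. **Reduced introgression.** Mean donor-component ancestry among
   parapatric recipient individuals, from a two-component admixture
   model, must be strictly below 2.5%.

A candidate must pass (1) for F~ST~ *or* D~XY~, and (2) *and* (3). All
three cutoffs are strict inequalities: $TD_d = -1$ exactly, mean
ancestry exactly 2.5%, or 95 of 100 permutation exceedances are all
non-significant. Candidate windows are intersected with a gene
annotation (half-open intervals; ≥1 bp overlap) to produce the candidate
gene list.

## Windows from spline inflection points

Fixed-width windows ignore the fact that linkage blocks vary in size.
Following the GenWin idea, `define_windows()` fits a cubic smoothing
spline of per-site minor allele frequency (the one statistic defined at
single sites) against position, with the penalty chosen by generalised
cross-validation, and places boundaries at sign changes of the second
derivative evaluated at the observed site positions — each boundary at
the midpoint between the two flanking sites, since a boundary between
observed sites is the finest meaningful resolution. Windows tile the
span from the first to the last variant site, every window contains at
least one site, and a constant signal yields a single window. Windowing
is per contig; splines across chromosome boundaries would be
meaningless. A `fixed_windows()` fallback exists for degenerate inputs
and testing. On the whole-genome data this procedure is modelled after,
windows average roughly 10 kb; at the simulation scales used in this
package's tests only the partition and breakpoint-recovery properties
are asserted.

## The statistics

**Hudson F~ST~, ratio of sums.** Per site,
$N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $D = p_1(1-p_2) + p_2(1-p_1)$, with allele frequencies computed from
called alleles only; a window's F~ST~ is $\sum N / \sum D$ over
comparable sites. The finite-sample correction requires at least two
called alleles per population; windows with zero summed denominator
return `NA`, and negative estimates are reported unclamped — clamping
would bias the $D_d$ difference.

**D~XY~ with invariant sites.** The per-site between-population mean
difference $p_1(1-p_2)+p_2(1-p_1)$ is averaged over *all* sites with at
least one called allele in both populations — including invariant
sites, which is why the input VCF must retain them. Dropping invariant
sites would inflate D~XY~ by orders of magnitude; this is the
missing-data-aware convention of all-sites divergence calculators.

**Tajima's D.** Computed per population per window from complete-case
sites (any missing call within the focal population excludes the site),
with the standard constants derived from the haplotype count and the
unbiased per-site pairwise diversity $2j(n-j)/(n(n-1))$. `D` is `NA`
when a window has no segregating sites. All three statistics are tested
against brute-force loop-over-pairs oracles to 10^−12^.

**Permutation null.** One set of `n_perm` (default 100) size-preserving
relabelings of individuals is drawn once and reused for every window and
both divergence statistics, so that window-to-window comparisons share
the same null draws and the empirical run is just the identity
relabeling through the same code path. Undefined permuted values (for
instance a zero F~ST~ denominator after reshuffling) are dropped from
that window's comparison; the >95% rule then applies to the defined
subset. With exchangeable data the realised per-window level is
5/101 ≈ 4.95%.

## Two-component ancestry: two estimators, one ridge

The admixture model treats each of an individual's two allele copies at
a site as drawn from the donor component with probability $q$ and from
the recipient component otherwise, giving the binomial log-likelihood
$\sum_s g_s \log m_s + (2-g_s)\log(1-m_s)$ with
$m_s = q\,p^M_s + (1-q)\,p^F_s$. Two estimators are provided because no
single per-window estimator can be simultaneously unbiased under the
pure mixture model and robust to local drift:

- `mode = "supervised"` (default, used by the scan): supervised
  admixture semantics. Labelled individuals' ancestries are fixed (both
  donor populations at $q=1$, allopatric recipients at $q=0$) and the
  component frequencies are re-estimated from **all** samples by a
  deterministic EM, followed by a bounded one-dimensional maximisation
  of each query's $q$ at the converged frequencies. Because the query
  population helps estimate its own background component, window-local
  drift or selection in the recipient population is not misread as donor
  ancestry — essential, since the scan's low-introgression gate is
  evaluated precisely in windows selected for strong local drift.
- `mode = "fixed_panel"`: component frequencies fixed at the allopatric
  panel estimates with a pseudocount of 1 per allele class (no
  log-of-zero at fixed sites), then the same 1-D maximisation. Unbiased
  exactly when the panels coincide with the ancestral components.

The trade-off is structural, not numerical: with free component
frequencies the window likelihood is invariant under
$q_i \mapsto (q_i-\delta)/(1-\delta)$ with the recipient frequencies
moved $\delta$ of the way towards the donor's — a flat ridge that only
the labelled recipients' data penalise. Consequently the EM estimator
shrinks all $q$ by roughly the smallest true $q$ in the window (a few
percent in practice), while the fixed-panel estimator converts any
drift of the query population away from its allopatric panel into
phantom ancestry (an upward bias that can exceed 10% in strongly
drifted windows). The scan therefore defaults to the EM; parameter
recovery under the mixture model is demonstrated with `fixed_panel`.
Label switching cannot occur in either supervised mode; the
unsupervised K = 2 EM (`mode = "unsupervised"`, provided for fidelity
to genome-wide admixture runs) resolves it by assigning the donor label
to the component favoured by allopatric donor samples.

## The synthetic-data generator

`simulate_genotypes()` draws allele frequencies under a hierarchical
Balding–Nichols model chosen to match the admixture likelihood exactly:
ancestral $p \sim U(0.05, 0.95)$ at variant sites, species frequencies
$\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ at $F =$
`F_species`, population frequencies likewise at `F_pop`. Non-admixed
individuals draw dosages $\mathrm{Binomial}(2, p_{pop})$; parapatric
recipient individuals draw each allele copy's ancestry
$\mathrm{Bernoulli}(q_i)$ with $q_i$ Beta-distributed around `q_intro`
(concentration 30), then the allele at the corresponding parapatric
population's frequency. Planted windows add `F_boost` to the recipient
population's drift (elevated parapatric divergence), force ancestry to
`q_planted` (reduced introgression), and convert a fraction of variant
sites to singletons private to one recipient parapatric individual —
a mechanical, deterministic way to push Tajima's D negative without
simulating sweeps. `generate_dataset()` emits the full file bundle
(all-sites VCF, popmap, reference FASTA consistent with every REF base,
GTF with one gene inside each planted window and genes tiling alternate
null windows, SIFT table covering both alleles of every variant, MEME
motif library, truth tables), byte-identical under a fixed seed.

Default study conditions (`default_sim_params()`): 10 samples per
population (the real design this emulates used 9–11), 50 windows of
1,000 sites (10% variant, mirroring the low SNP density of all-sites
primate VCFs at desk scale), `F_species = 0.2` (between-species panel
F~ST~ ≈ 0.2), `F_pop = 0.05`, `q_intro = 0.06` (real per-individual
donor ancestry spans 0–18%), and 5 planted windows with
`F_boost = 0.5`, `q_planted = 0`, `singleton_fraction = 0.3`. What the
generator does *not* emulate: linkage and recombination (sites are
exchangeable within windows), coalescent variance in window-to-window
relatedness, sequencing error, and sex chromosomes. Passing tests
therefore certify the estimators and the decision rule, not robustness
to LD or call-quality artefacts in real data.

## Candidate-gene annotation

Within candidate genes, sites whose non-reference allele segregates
only in the parapatric recipient population are extracted (missing
genotypes count nothing, and a site where others are fixed for the
alternate while the recipient holds the reference is deliberately not
"unique"). Each site is classified against every overlapping transcript
— codon-level translation for CDS sites (strand-aware), UTR side by
position relative to the CDS, splice donor/acceptor as the first/last
two intronic bases with a splice region out to 8 bases, and a 5 kb
upstream/downstream radius (common variant-annotator defaults; exonic
positions of non-coding transcripts fall back to `intron` since the
class vocabulary has no non-coding-exon category). 13-base flank pairs
centred on each variant (reference vs alternate-consensus) feed two
analyses: B-SIFT, the difference `sift(alt) − sift(ref)` in \[−1, 1\]
with any positive value classed adaptive, zero neutral, negative
deleterious, after excluding low-confidence scores; and motif
uniqueness, where each position weight matrix is slid over both strands
of both flanks, scored as log-odds against a uniform background, and
declared a match at ≥ 85% of its maximum achievable score — motifs
matching the alternate but not the reference flank are the candidate
gained binding sites. The relative-threshold PWM scan is a transparent
stand-in for motif-to-motif comparison tools; the deliverable quantity
(motifs unique to the alternate allele) is the same. Sites within 6
bases of a contig end are skipped rather than truncated: a fixed window
width is what makes reference/alternate scores comparable.

## Numerical and policy choices

- Internal coordinates are 0-based half-open everywhere; conversions
  happen only at I/O boundaries (VCF and GTF are 1-based, BED is
  0-based). Window BED lines are therefore emitted verbatim.
- Biallelic SNPs only; multiallelic and indel records are skipped and
  counted. Half-calls are missing. No imputation anywhere.
- The spline windowing treats a fit whose second derivative never
  exceeds 10^−12^ in absolute value as inflection-free (single window).
- Permutations require ≥ 20 draws (the 95% exceedance rule is
  meaningless below that) and every population needs ≥ 2 samples.
- The EM ancestry estimator is deterministic (fixed initialisation at
  panel frequencies and query $q = 0.5$); only the unsupervised mode
  consumes a seed.
- Undefined window statistics are `NA` sentinels, never zeros, and any
  undefined input makes the corresponding significance flag `FALSE`.

## Problem sizes used in the tests

The test-suite simulations are sized for a desk machine: estimator
oracles run on 200 random matrices of ≤ 20 sites × 8 samples; the
permutation-calibration experiment uses 1,000 windows × 20 sites with
100 permutations; planted-window recovery uses 550 windows × 250 sites
(50 planted); ancestry recovery uses 100 replicate windows × 600 sites
per true ancestry value; the end-to-end determinism check runs the full
pipeline twice on a 12-window dataset. The acceptance script repeats
these computations from scratch at the same sizes plus one run under
the full default conditions (50,000 sites).

## Limitations

Per-window ancestry with few informative sites is intrinsically noisy;
below ~50 informative sites the 2.5% gate is dominated by estimator
variance. The permutation null assumes exchangeability of individuals
under the no-displacement hypothesis; systematic within-species
structure beyond the four-population labels would inflate the type-I
error. The scan applies no multiple-testing correction beyond the
per-window permutation criterion, by design — downstream gene lists are
screening output, not confirmatory inference. Tajima's D windows with
very few segregating sites are unstable; the planted singleton fraction
in the simulator deliberately concentrates the signal instead of
relying on sweep dynamics.
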