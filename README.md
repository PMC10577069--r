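# rcdscan

Window-based genome scans for **reinforcement speciation** via
**reproductive character displacement** in a two-species,
four-population contact-zone design.

## The problem

When two hybridising species meet along a contact zone, selection
against hybrids can strengthen reproductive barriers where they
co-occur. The genomic footprint is reproductive character displacement:
windows where divergence between the *parapatric* populations of the
two species exceeds divergence between their *allopatric* populations.
`rcdscan` is for population geneticists who have an all-sites VCF
(variant **and** invariant sites) for four populations — allopatric and
parapatric samples of a donor species (`ALLO_MUL`, `PARA_MUL`) and of a
recipient species (`ALLO_FAS`, `PARA_FAS`), with introgression flowing
asymmetrically into the parapatric recipient — and want the candidate
windows and genes carrying all three reinforcement signatures.

## The method

Windows are defined per contig by a cubic smoothing spline of per-site
minor allele frequency (GCV penalty), with boundaries at the sign
changes of the spline's second derivative. For each window the scan
computes:

- **Hudson F_ST** (ratio of sums, finite-sample corrected) and **D_XY**
  (invariant sites in the denominator) for the parapatric and allopatric
  species pairs, and the divergence difference

  `D_d = D_p − D_a`

  whose significance is assessed against `D_d` recomputed under 100
  size-preserving permutations of individuals across the four
  populations (significant iff the empirical value strictly exceeds
  >95% of a window's permuted values);

- the averaged **Tajima's D contrast** for the introgression recipient

  `TD_d = ((TD_pf − TD_pm) + (TD_pf − TD_af)) / 2`,

  significant iff strictly below −1;

- mean donor-component **ancestry** of parapatric recipient individuals
  under a two-component binomial admixture model (supervised EM;
  donor populations fixed at q = 1, allopatric recipients at q = 0),
  significant iff strictly below 2.5%.

A window is a **candidate** iff `(F_ST-sig OR D_XY-sig) AND TD-sig AND
ancestry-sig`; candidates are intersected with a GTF gene annotation.
Candidate genes feed a variant-annotation stage: sites with alleles
unique to the parapatric recipient, codon-level effect classes, 13-bp
reference/alternate flank pairs, B-SIFT scores
(`sift(alt) − sift(ref)`; positive = candidate adaptive) and PWM-scan
motifs unique to the alternate allele.

A synthetic-data module (`sim_params()`, `simulate_genotypes()`,
`generate_dataset()`) generates the full four-population design under a
hierarchical Balding–Nichols model with planted reinforcement windows,
so every stage is testable with no external data.

## Worked example

```r
library(rcdscan)
library(dplyr)

p <- sim_params(
  n_windows = 12L, sites_per_window = 200L, variant_fraction = 0.5,
  planted = tibble::tibble(window = c(3L, 8L), F_boost = 0.5,
                           q_planted = 0, singleton_fraction = 0.3),
  seed = 42L
)
sim <- simulate_genotypes(p)
sim$geno
#> <genotype_matrix> chr1: 2400 sites (1186 variant) x 40 samples

scan <- rcd_scan(sim$geno, sim$popmap, sim$windows,
                 n_perm = 100L, seed = 1L)
scan
#> <rcd_scan> 12 windows: 4 F_ST-sig, 4 D_XY-sig, 2 TajimaD-sig,
#>            4 low-ancestry, 2 candidates

tidy(scan) |>
  filter(candidate) |>
  select(chrom, start, end, dd_fst, dd_dxy, td_d, mean_para_fas_q)
#> # A tibble: 2 x 7
#>   chrom start   end dd_fst dd_dxy  td_d mean_para_fas_q
#> 1 chr1  12000 18000  0.181 0.0127 -1.98               0
#> 2 chr1  42000 48000  0.122 0.0160 -2.15               0
```

The two recovered windows are exactly the two planted ones (windows 3
and 8 of the 6-kb grid): parapatric F_ST elevated by ~0.12–0.18 over
the allopatric pair, recipient-specific Tajima's D contrast near −2
from the planted private singletons, and zero introgressed ancestry.
`glance(scan)` gives the one-row count summary and `autoplot(scan)`
plots all four per-window statistics with candidates highlighted.

For file-based work, `run_pipeline()` chains
windows → statistics → ancestry → scan → gene overlap → annotation from
a config list or YAML file and writes per-stage TSV/BED outputs plus a
JSON manifest:

```r
paths <- generate_dataset(default_sim_params(seed = 1L), "simdata")
res <- run_pipeline(list(
  vcf = paths$vcf, popmap = paths$popmap, gtf = paths$gtf,
  fasta = paths$fasta, sift = paths$sift, motifs = paths$motifs,
  out_dir = "run1", n_perm = 100L, seed = 1L
))
```

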