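#' Per-population allele counts
#'
#' Internal workhorse: alternate-allele counts and called-allele counts per
#' site for an arbitrary set of population columns, computed by matrix
#' multiplication so the permutation null can reuse it cheaply.
#'
#' @param g A [genotype_matrix()].
#' @param membership Numeric samples x pops 0/1 indicator matrix.
#' @return List with `alt` and `called` (sites x pops matrices); `called`
#'   counts alleles (2 per non-missing diploid call).
#' @keywords internal
allele_counts <- function(g, membership) {
  d <- g$dosage
  dz <- d
  dz[is.na(dz)] <- 0L
  list(
    alt = dz %*% membership,
    called = (!is.na(d)) %*% membership * 2
  )
}

#' Per-site Hudson F_ST and D_XY components
#'
#' For two populations with alternate-allele frequencies `p1`, `p2`
#' estimated from `n1`, `n2` called alleles, the Hudson estimator with the
#' Bhatia et al. finite-sample correction has per-site numerator
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`; the denominator is also the per-site contribution
#' to D_XY (mean between-population difference). A site is comparable for
#' F_ST only when both populations have at least 2 called alleles (the
#' correction is undefined below that) and for D_XY when both have at least
#' 1. Invariant sites yield numerator = denominator = 0 but remain
#' comparable, which is how they enter the D_XY denominator.
#'
#' @param alt1,called1,alt2,called2 Per-site allele counts for the two
#'   populations.
#' @return Tibble with `p1`, `p2`, `n1`, `n2`, `fst_num`, `fst_den`,
#'   `dxy_site`, `fst_ok`, `dxy_ok`.
#' @export
site_divergence_components <- function(alt1, called1, alt2, called2) {
  p1 <- ifelse(called1 > 0, alt1 / called1, NA_real_)
  p2 <- ifelse(called2 > 0, alt2 / called2, NA_real_)
  fst_ok <- called1 >= 2 & called2 >= 2
  dxy_ok <- called1 >= 1 & called2 >= 1
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (called1 - 1) -
    p2 * (1 - p2) / (called2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble(
    p1 = p1, p2 = p2, n1 = called1, n2 = called2,
    fst_num = ifelse(fst_ok, num, NA_real_),
    fst_den = ifelse(fst_ok, den, NA_real_),
    dxy_site = ifelse(dxy_ok, den, NA_real_),
    fst_ok = fst_ok, dxy_ok = dxy_ok
  )
}

# Sums per window of F_ST numerator/denominator, D_XY numerator and
# comparable-site counts. win: window index per site (NA = unassigned).
window_divergence_sums <- function(comp, win, n_windows) {
  keep <- !is.na(win)
  acc <- function(x, ok) {
    v <- ifelse(ok, x, 0)
    out <- numeric(n_windows)
    s <- rowsum(v[keep], win[keep])
    out[as.integer(rownames(s))] <- s[, 1L]
    out
  }
  fst_num <- acc(comp$fst_num, comp$fst_ok)
  fst_den <- acc(comp$fst_den, comp$fst_ok)
  dxy_sum <- acc(comp$dxy_site, comp$dxy_ok)
  n_dxy <- acc(rep(1, nrow(comp)), comp$dxy_ok)
  n_fst <- acc(rep(1, nrow(comp)), comp$fst_ok)
  tibble(
    fst = ifelse(fst_den > 0, fst_num / fst_den, NA_real_),
    dxy = ifelse(n_dxy > 0, dxy_sum / n_dxy, NA_real_),
    n_comparable = n_dxy, n_fst_sites = n_fst
  )
}

#' Windowed Hudson F_ST and D_XY for a population pair
#'
#' F_ST aggregates per-site Hudson numerators and denominators as a ratio
#' of sums over comparable sites ("ratio of averages"); windows whose
#' summed denominator is zero get `NA`, not 0. D_XY averages the per-site
#' between-population difference over all comparable sites — variant and
#' invariant — so the genotype matrix must retain invariant sites for an
#' absolute-divergence denominator. Negative F_ST values are reported, not
#' clamped.
#'
#' @param g A [genotype_matrix()].
#' @param popmap Popmap tibble.
#' @param pop_a,pop_b Population labels (see [population_labels()]).
#' @param windows Window tibble (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return Tibble with one row per window: `fst`, `dxy`, `n_comparable`,
#'   `n_fst_sites`.
#' @export
window_divergence <- function(g, popmap, pop_a, pop_b, windows) {
  m <- pop_membership(g, validate_popmap(popmap))
  ac <- allele_counts(g, m[, c(pop_a, pop_b), drop = FALSE])
  comp <- site_divergence_components(ac$alt[, 1L], ac$called[, 1L],
                                     ac$alt[, 2L], ac$called[, 2L])
  win <- assign_positions(g$pos, windows)
  bind_cols(windows[, c("chrom", "start", "end")],
            window_divergence_sums(comp, win, nrow(windows)))
}

#' Tajima's D normalising constants
#'
#' The standard constants of the D statistic for `n` sampled haplotypes:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n Haplotype count (>= 4 for a defined D).
#' @return Named list of the constants.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D for one population
#'
#' Within the focal population, sites carrying any missing call are
#' excluded from both the segregating-site count `S` and the pairwise
#' diversity `pi` (complete-case policy). Per-site pi uses the unbiased
#' mean pairwise difference `2 j (n - j) / (n (n - 1))` for derived count
#' `j` among `n` haplotypes. `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`;
#' windows with `S = 0` get `NA`.
#'
#' @param g A [genotype_matrix()].
#' @param popmap Popmap tibble.
#' @param pop Population label.
#' @param windows Window tibble.
#' @return Tibble per window: `n_hap`, `S`, `pi`, `theta_w`, `D`.
#' @export
window_tajima_d <- function(g, popmap, pop, windows) {
  idx <- pop_samples(g, validate_popmap(popmap), pop)
  if (length(idx) < 2L) abort("Tajima's D needs >= 2 diploid samples")
  d <- g$dosage[, idx, drop = FALSE]
  n <- 2L * length(idx)
  complete <- rowSums(is.na(d)) == 0L
  j <- rowSums(d)
  seg <- complete & !is.na(j) & j > 0L & j < n
  pi_site <- ifelse(seg, 2 * j * (n - j) / (n * (n - 1)), 0)
  pi_site[!complete] <- 0

  win <- assign_positions(g$pos, windows)
  keep <- !is.na(win)
  nw <- nrow(windows)
  acc <- function(x) {
    out <- numeric(nw)
    s <- rowsum(x[keep], win[keep])
    out[as.integer(rownames(s))] <- s[, 1L]
    out
  }
  S <- acc(as.numeric(seg))
  pi <- acc(pi_site)
  k <- tajima_constants(n)
  theta_w <- S / k$a1
  varD <- k$e1 * S + k$e2 * S * (S - 1)
  D <- ifelse(S > 0 & varD > 0, (pi - theta_w) / sqrt(varD), NA_real_)
  bind_cols(
    windows[, c("chrom", "start", "end")],
    tibble(n_hap = n, S = S, pi = pi, theta_w = theta_w, D = D)
  )
}
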