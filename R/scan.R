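#' Divergence difference between parapatric and allopatric pairs
#'
#' The character-displacement statistic: `D_d = D_p - D_a`, where `D_p` is
#' divergence (F_ST or D_XY) between the parapatric populations of the two
#' species and `D_a` the divergence between the allopatric populations.
#' Windows under reinforcement are expected to show `D_d > 0`.
#'
#' @param d_p,d_a Divergence values (vectors allowed); `NA` propagates.
#' @return `d_p - d_a`.
#' @export
divergence_difference <- function(d_p, d_a) d_p - d_a

#' Averaged Tajima's D contrast for the introgression recipient
#'
#' `TD_d = ((TD_pf - TD_pm) + (TD_pf - TD_af)) / 2`: the parapatric
#' recipient population's Tajima's D contrasted against the hybridising
#' parapatric donor population and against its allopatric conspecifics,
#' averaged. Strongly negative values indicate directional selection
#' specific to the recipient population; the significance rule is
#' `TD_d < cutoff` with a strict inequality (the default cutoff is -1, so
#' `TD_d = -1` exactly is NOT significant).
#'
#' @param td_pf,td_pm,td_af Tajima's D in parapatric recipient, parapatric
#'   donor, allopatric recipient populations.
#' @param cutoff Significance cutoff (default -1).
#' @return Tibble with `td_d` and logical `td_sig` (`FALSE` when any input
#'   is undefined).
#' @export
tajima_difference <- function(td_pf, td_pm, td_af, cutoff = -1) {
  td_d <- ((td_pf - td_pm) + (td_pf - td_af)) / 2
  tibble(td_d = td_d,
         td_sig = !is.na(td_d) & td_d < cutoff)
}

#' Strict permutation-exceedance significance rule
#'
#' A window is significant iff the empirical value strictly exceeds more
#' than `frac` of the defined permuted values: `n_exceed > frac *
#' n_defined`. With 100 defined permutations and `frac = 0.95`, 96
#' exceedances are required; 95 of 100 is NOT significant. Ties between
#' the empirical and a permuted value do not count as exceedances.
#'
#' @param n_exceed Number of permuted values strictly below the empirical.
#' @param n_defined Number of defined permuted values.
#' @param frac Required exceedance fraction (default 0.95).
#' @return Logical.
#' @export
exceedance_significant <- function(n_exceed, n_defined, frac = 0.95) {
  !is.na(n_exceed) & n_defined > 0 & n_exceed > frac * n_defined
}

#' Low-introgression (reduced-ancestry) significance rule
#'
#' Strict inequality: mean donor ancestry in the recipient parapatric
#' population must be below the cutoff; a window at exactly the cutoff
#' (e.g. 2.5%) is NOT significant, and an undefined mean is never
#' significant.
#'
#' @param mean_q Mean donor-component ancestry per window.
#' @param cutoff Ancestry cutoff (default 0.025).
#' @return Logical.
#' @export
ancestry_significance <- function(mean_q, cutoff = 0.025) {
  !is.na(mean_q) & mean_q < cutoff
}

#' Combine per-window significance flags into candidate calls
#'
#' A window is a candidate for reproductive character displacement iff it
#' is significant for the divergence difference in either F_ST or D_XY,
#' significant for the Tajima's D contrast, and passes the low-ancestry
#' (reduced introgression) criterion:
#' `candidate = (fst_sig | dxy_sig) & td_sig & adm_sig`.
#'
#' @param flags Tibble/data frame with logical columns `fst_sig`,
#'   `dxy_sig`, `td_sig`, `adm_sig` (`NA` treated as `FALSE`).
#' @return `flags` with an added logical `candidate` column.
#' @export
call_candidates <- function(flags) {
  f <- function(x) !is.na(x) & x
  mutate(as_tibble(flags),
         candidate = (f(.data$fst_sig) | f(.data$dxy_sig)) &
           f(.data$td_sig) & f(.data$adm_sig))
}

# D_d per window for both statistics from allele-count matrices.
# alt/called: sites x 4 (POP_LEVELS order); win: window index per site.
scan_dd <- function(alt, called, win, n_windows) {
  pair <- function(i, j) {
    comp <- site_divergence_components(alt[, i], called[, i],
                                       alt[, j], called[, j])
    window_divergence_sums(comp, win, n_windows)
  }
  para <- pair(2L, 4L) # PARA_MUL vs PARA_FAS
  allo <- pair(1L, 3L) # ALLO_MUL vs ALLO_FAS
  tibble(
    fst_para = para$fst, fst_allo = allo$fst,
    dxy_para = para$dxy, dxy_allo = allo$dxy,
    dd_fst = divergence_difference(para$fst, allo$fst),
    dd_dxy = divergence_difference(para$dxy, allo$dxy),
    n_comparable = pmin(para$n_comparable, allo$n_comparable)
  )
}

#' Permutation null for the divergence difference
#'
#' Generates `n_perm` relabelings of samples to populations, preserving the
#' original group sizes, and recomputes `D_d` for both divergence
#' statistics per window with the same estimator code path as the
#' empirical run. The same relabelings are reused for every window and
#' both statistics. A window is significant for a statistic iff its
#' empirical `D_d` is strictly greater than more than `perm_frac` (default
#' 95%) of that window's defined permuted values; with 100 permutations
#' this requires at least 96 exceedances, and a window where exactly 95 of
#' 100 permuted values are exceeded is NOT significant. Permuted values
#' that are undefined (e.g. zero F_ST denominator after reshuffling) are
#' dropped from that window's comparison and counted.
#'
#' @param g A [genotype_matrix()].
#' @param popmap Popmap tibble.
#' @param windows Window tibble.
#' @param n_perm Number of permutations (>= 20; default 100).
#' @param seed RNG seed for the relabelings.
#' @param perm_frac Required exceedance fraction (strict; default 0.95).
#' @param empirical Optional precomputed empirical `scan_dd` tibble;
#'   computed from the identity labeling when `NULL`.
#' @return List: `empirical` (per-window tibble), `exceed` (tibble with
#'   exceedance and defined-permutation counts and `fst_sig`/`dxy_sig`
#'   flags), `perm_dd_fst` and `perm_dd_dxy` (windows x n_perm matrices).
#' @export
permutation_null <- function(g, popmap, windows, n_perm = 100L, seed = 1L,
                             perm_frac = 0.95, empirical = NULL) {
  if (n_perm < 20L) abort("n_perm < 20 makes the exceedance threshold meaningless")
  popmap <- validate_popmap(popmap)
  m <- pop_membership(g, popmap)
  if (any(colSums(m) < 2)) {
    abort("every population needs >= 2 samples for the permutation null")
  }
  win <- assign_positions(g$pos, windows)
  nw <- nrow(windows)
  if (is.null(empirical)) {
    ac <- allele_counts(g, m)
    empirical <- scan_dd(ac$alt, ac$called, win, nw)
  }
  set.seed(seed)
  ns <- nrow(m)
  perm_fst <- matrix(NA_real_, nw, n_perm)
  perm_dxy <- matrix(NA_real_, nw, n_perm)
  for (b in seq_len(n_perm)) {
    mp <- m[sample.int(ns), , drop = FALSE]
    ac <- allele_counts(g, mp)
    dd <- scan_dd(ac$alt, ac$called, win, nw)
    perm_fst[, b] <- dd$dd_fst
    perm_dxy[, b] <- dd$dd_dxy
  }
  exceed <- function(emp, pm) {
    n_def <- rowSums(!is.na(pm))
    n_exc <- rowSums(sweep(pm, 1L, emp, function(p, e) !is.na(p) & p < e))
    sig <- !is.na(emp) & exceedance_significant(n_exc, n_def, perm_frac)
    tibble(n_exceed = n_exc, n_defined = n_def, sig = sig)
  }
  ef <- exceed(empirical$dd_fst, perm_fst)
  ed <- exceed(empirical$dd_dxy, perm_dxy)
  list(
    empirical = empirical,
    exceed = tibble(
      fst_exceed = ef$n_exceed, fst_defined = ef$n_defined,
      fst_sig = ef$sig,
      dxy_exceed = ed$n_exceed, dxy_defined = ed$n_defined,
      dxy_sig = ed$sig
    ),
    perm_dd_fst = perm_fst, perm_dd_dxy = perm_dxy,
    n_perm = n_perm, perm_frac = perm_frac, seed = seed
  )
}

#' Run the full reinforcement window scan
#'
#' Computes, for every window: Hudson F_ST and D_XY for the parapatric and
#' allopatric species pairs and their differences (`dd_fst`, `dd_dxy`);
#' Tajima's D for the parapatric recipient, parapatric donor and
#' allopatric recipient populations and the averaged contrast `td_d`; mean
#' donor-component ancestry in the parapatric recipient population; the
#' permutation-null significance flags; and the final candidate call
#' `(fst_sig | dxy_sig) & td_sig & adm_sig`.
#'
#' @param g A [genotype_matrix()].
#' @param popmap Popmap tibble (labels in [population_labels()]).
#' @param windows Window tibble (0-based half-open), e.g. from
#'   [define_windows()].
#' @param n_perm Permutations for the divergence-difference null.
#' @param seed RNG seed (permutations; unsupervised EM if selected).
#' @param perm_frac Strict exceedance fraction for significance.
#' @param tajima_cut Cutoff for `td_d` (strict `<`).
#' @param ancestry_cut Cutoff for mean recipient ancestry (strict `<`).
#' @param ancestry_mode `"supervised"` or `"unsupervised"`.
#' @return An object of class `rcd_scan`; see [tidy.rcd_scan()],
#'   [glance.rcd_scan()], [autoplot.rcd_scan()].
#' @export
rcd_scan <- function(g, popmap, windows, n_perm = 100L, seed = 1L,
                     perm_frac = 0.95, tajima_cut = -1,
                     ancestry_cut = 0.025,
                     ancestry_mode = c("supervised", "unsupervised")) {
  ancestry_mode <- match.arg(ancestry_mode)
  popmap <- validate_popmap(popmap)
  windows <- as_tibble(windows)

  null <- permutation_null(g, popmap, windows, n_perm = n_perm,
                           seed = seed, perm_frac = perm_frac)
  td_pf <- window_tajima_d(g, popmap, "PARA_FAS", windows)$D
  td_pm <- window_tajima_d(g, popmap, "PARA_MUL", windows)$D
  td_af <- window_tajima_d(g, popmap, "ALLO_FAS", windows)$D
  td <- tajima_difference(td_pf, td_pm, td_af, cutoff = tajima_cut)
  anc <- estimate_window_ancestry(g, popmap, windows, mode = ancestry_mode,
                                  seed = seed)
  mean_q <- anc$windows$mean_para_fas_q

  tab <- bind_cols(
    windows[, c("chrom", "start", "end")],
    null$empirical,
    tibble(td_pf = td_pf, td_pm = td_pm, td_af = td_af,
           td_d = td$td_d, mean_para_fas_q = mean_q),
    null$exceed[, c("fst_exceed", "fst_defined", "fst_sig",
                    "dxy_exceed", "dxy_defined", "dxy_sig")]
  )
  tab$td_sig <- td$td_sig
  tab$adm_sig <- ancestry_significance(mean_q, ancestry_cut)
  tab <- call_candidates(tab)

  structure(
    list(
      windows = tab, ancestry = anc, null = null,
      params = list(n_perm = n_perm, seed = seed, perm_frac = perm_frac,
                    tajima_cut = tajima_cut, ancestry_cut = ancestry_cut,
                    ancestry_mode = ancestry_mode)
    ),
    class = "rcd_scan"
  )
}

#' @export
print.rcd_scan <- function(x, ...) {
  w <- x$windows
  cat("<rcd_scan> ", nrow(w), " windows: ",
      sum(w$fst_sig), " F_ST-sig, ", sum(w$dxy_sig), " D_XY-sig, ",
      sum(w$td_sig), " TajimaD-sig, ", sum(w$adm_sig), " low-ancestry, ",
      sum(w$candidate), " candidates\n", sep = "")
  invisible(x)
}

#' Tidy and summarise a reinforcement scan
#'
#' `tidy()` returns the per-window statistics table; `glance()` a one-row
#' summary of window counts per criterion and candidate totals.
#'
#' @param x An `rcd_scan` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_rcd_scan
NULL

#' @rdname tidy_rcd_scan
#' @export
tidy.rcd_scan <- function(x, ...) x$windows

#' @rdname tidy_rcd_scan
#' @export
glance.rcd_scan <- function(x, ...) {
  w <- x$windows
  tibble(
    n_windows = nrow(w),
    n_fst_sig = sum(w$fst_sig), n_dxy_sig = sum(w$dxy_sig),
    n_td_sig = sum(w$td_sig), n_adm_sig = sum(w$adm_sig),
    n_candidates = sum(w$candidate),
    n_perm = x$params$n_perm, seed = x$params$seed
  )
}

#' Genes overlapped by candidate windows
#'
#' Reports every gene whose span is overlapped by at least one candidate
#' window by at least one base (half-open intervals: a window ending where
#' a gene starts does not overlap). Each gene is listed once, with all its
#' supporting windows.
#'
#' @param candidates Window tibble (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. `dplyr::filter(tidy(scan), candidate)`.
#' @param annotation A `gene_annotation` from [read_gene_annotation()].
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `n_windows`,
#'   `windows` (comma-separated `start-end` list).
#' @export
overlap_genes <- function(candidates, annotation) {
  genes <- annotation$genes
  if (nrow(candidates) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_windows = integer(), windows = character()))
  }
  missing_contigs <- setdiff(unique(candidates$chrom), unique(genes$chrom))
  if (length(missing_contigs)) {
    abort(paste0("window contig(s) absent from gene annotation: ",
                 paste(missing_contigs, collapse = ", ")))
  }
  wr <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(start = candidates$start + 1L, end = candidates$end)
  )
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(gr, wr, minoverlap = 1L)
  if (!length(hits)) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_windows = integer(), windows = character()))
  }
  tibble(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    chrom = genes$chrom[S4Vectors::queryHits(hits)],
    start = genes$start[S4Vectors::queryHits(hits)],
    end = genes$end[S4Vectors::queryHits(hits)],
    win = paste0(candidates$start[S4Vectors::subjectHits(hits)], "-",
                 candidates$end[S4Vectors::subjectHits(hits)])
  ) |>
    group_by(.data$gene_id, .data$chrom, .data$start, .data$end) |>
    summarise(n_windows = dplyr::n(),
              windows = paste(.data$win, collapse = ","),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start)
}
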