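#' Per-site minor allele frequency
#'
#' Computes, for every variant site, the minor allele frequency over all
#' samples pooled: `maf = min(f, 1 - f)` with `f` the alternate-allele count
#' divided by the called-allele count. Sites with zero called alleles are
#' dropped. This is the "fundamental statistic" fed to the smoothing-spline
#' window definition — unlike window-level statistics it exists per site.
#'
#' @param g A [genotype_matrix()].
#' @return Tibble with `position` (1-based) and `maf` in \[0, 0.5\].
#' @export
per_site_maf <- function(g) {
  idx <- which(g$is_variant)
  d <- g$dosage[idx, , drop = FALSE]
  alt <- rowSums(d, na.rm = TRUE)
  called <- 2L * rowSums(!is.na(d))
  keep <- called > 0L
  f <- alt[keep] / called[keep]
  tibble(position = g$pos[idx][keep], maf = pmin(f, 1 - f))
}

#' Define genomic windows from spline inflection points
#'
#' Fits a cubic smoothing spline (penalty chosen by generalised
#' cross-validation) of minor allele frequency against site position, then
#' places window boundaries at sign changes of the spline's second
#' derivative evaluated at the observed site positions — each boundary at
#' the midpoint between the two flanking sites. The resulting variable-width
#' windows approximate independently evolving blocks of the contig; they
#' tile the span from the first to the last site with no gaps or overlaps,
#' and every window contains at least one variant site.
#'
#' With fewer than `min_sites` sites, or an (all but) constant signal, a
#' single window spanning all sites is returned.
#'
#' @param sites Tibble from [per_site_maf()] (`position`, `maf`).
#' @param chrom Contig name recorded in the output.
#' @param min_sites Minimum site count for spline fitting (default 4).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default `NULL` lets GCV choose.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites`.
#' @export
define_windows <- function(sites, chrom = "chr1", min_sites = 4L,
                           spar = NULL) {
  sites <- arrange(as_tibble(sites), .data$position)
  pos <- sites$position
  if (!length(pos)) abort("no variant sites: cannot define windows")
  span <- function(starts, ends) {
    tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends))
  }
  single <- span(pos[1L] - 1L, pos[length(pos)])
  if (length(pos) < min_sites || length(unique(sites$maf)) == 1L) {
    single$n_sites <- length(pos)
    return(single)
  }

  fit <- if (is.null(spar)) {
    smooth.spline(pos, sites$maf, cv = FALSE) # GCV
  } else {
    smooth.spline(pos, sites$maf, spar = spar)
  }
  d2 <- predict(fit, x = pos, deriv = 2L)$y
  if (max(abs(d2)) < 1e-12) { # numerically flat fit
    single$n_sites <- length(pos)
    return(single)
  }
  flip <- which(d2[-length(d2)] * d2[-1L] < 0)
  if (!length(flip)) {
    single$n_sites <- length(pos)
    return(single)
  }
  # boundary between site i and i+1: midpoint, as a 0-based coordinate
  bounds <- unique(as.integer(floor((pos[flip] + pos[flip + 1L]) / 2)))
  starts <- c(pos[1L] - 1L, bounds)
  ends <- c(bounds, pos[length(pos)])
  out <- span(starts, ends)
  out$n_sites <- count_sites_in_windows(pos, out)
  out[out$n_sites > 0L, , drop = FALSE]
}

# number of 1-based positions falling in each 0-based half-open window
count_sites_in_windows <- function(pos, windows) {
  idx <- assign_positions(pos, windows)
  tabulate(idx, nbins = nrow(windows))
}

#' Assign site positions to windows
#'
#' @param pos Integer vector of 1-based positions.
#' @param windows Tibble with `start`, `end` (0-based half-open), sorted,
#'   non-overlapping.
#' @return Integer window index per position (`NA` outside all windows).
#' @export
assign_positions <- function(pos, windows) {
  z <- pos - 1L # 0-based
  idx <- findInterval(z, windows$start)
  idx[idx == 0L] <- NA_integer_
  inside <- !is.na(idx) & z < windows$end[pmax(idx, 1L)]
  idx[!inside] <- NA_integer_
  idx
}

#' Fixed-width window fallback
#'
#' Tiles the span of the sites with windows of constant width; used for
#' degenerate inputs and as a testing aid.
#'
#' @param sites Tibble with `position` (1-based), or a numeric vector.
#' @param width Window width in bases.
#' @param chrom Contig name.
#' @return Tibble with `chrom`, `start`, `end`, `n_sites`; windows without
#'   sites are dropped.
#' @export
fixed_windows <- function(sites, width, chrom = "chr1") {
  pos <- if (is.numeric(sites)) sites else sites$position
  pos <- sort(as.integer(pos))
  first <- pos[1L] - 1L
  starts <- seq(first, pos[length(pos)] - 1L, by = width)
  out <- tibble(chrom = chrom, start = as.integer(starts),
                end = as.integer(pmin(starts + width, pos[length(pos)])))
  out$n_sites <- count_sites_in_windows(pos, out)
  out[out$n_sites > 0L, , drop = FALSE]
}
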