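#' Sites-by-samples genotype dosage container
#'
#' `genotype_matrix()` builds the substrate of every statistic in the scan: a
#' sites x samples matrix of alternate-allele dosages (0, 1, 2 for diploids;
#' `NA` = missing call) together with 1-based site positions, per-site
#' reference/alternate alleles, and a per-site flag distinguishing variant
#' sites from invariant sites retained for absolute-divergence (D_XY)
#' denominators.
#'
#' @param chrom Single contig name.
#' @param pos Integer vector of strictly increasing 1-based site positions.
#' @param ref Character vector of reference alleles (one base per site).
#' @param alt Character vector of alternate alleles; `NA` at invariant sites.
#' @param dosage Integer matrix, `length(pos)` rows x samples columns, values
#'   in `0:2` or `NA` for missing genotypes.
#' @param sample_ids Character vector of unique sample names (column order).
#' @param is_variant Logical per-site flag; `FALSE` marks invariant sites.
#'
#' @return An object of class `genotype_matrix`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   chrom = "chr1", pos = c(10L, 20L), ref = c("A", "C"), alt = c("G", NA),
#'   dosage = matrix(c(0L, 1L, 0L, 0L), nrow = 2),
#'   sample_ids = c("s1", "s2"), is_variant = c(TRUE, FALSE)
#' )
#' g
genotype_matrix <- function(chrom, pos, ref, alt, dosage, sample_ids,
                            is_variant) {
  if (length(chrom) != 1L) abort("`chrom` must be a single contig name.")
  pos <- as.integer(pos)
  n_sites <- length(pos)
  if (n_sites > 1L && any(diff(pos) <= 0L)) {
    abort("site positions must be strictly increasing within the contig")
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != n_sites) abort("`dosage` must have one row per site.")
  if (ncol(dosage) != length(sample_ids)) {
    abort("`dosage` must have one column per sample.")
  }
  if (anyDuplicated(sample_ids)) abort("`sample_ids` must be unique.")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must lie in 0..2 or be NA")
  }
  is_variant <- as.logical(is_variant)
  alt <- as.character(alt)
  alt[!is_variant] <- NA_character_
  if (any(is_variant & (is.na(alt) | alt == ""))) {
    abort("variant sites must carry a non-empty alternate allele")
  }
  colnames(dosage) <- sample_ids
  structure(
    list(
      chrom = chrom, pos = pos, ref = as.character(ref), alt = alt,
      dosage = dosage, sample_ids = as.character(sample_ids),
      is_variant = is_variant
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "<genotype_matrix> ", x$chrom, ": ", length(x$pos), " sites (",
    sum(x$is_variant), " variant) x ", length(x$sample_ids), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of sites / samples in a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(g) length(g$pos)

#' @rdname n_sites
#' @export
n_samples <- function(g) length(g$sample_ids)

#' Subset a genotype matrix by site index and/or samples
#'
#' @param g A `genotype_matrix`.
#' @param sites Integer or logical site index (default all).
#' @param samples Character sample names or index (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(g$pos)
  if (is.null(samples)) samples <- g$sample_ids
  if (is.character(samples)) {
    missing <- setdiff(samples, g$sample_ids)
    if (length(missing)) {
      abort(paste0("samples not in matrix: ", paste(missing, collapse = ", ")))
    }
  }
  genotype_matrix(
    chrom = g$chrom, pos = g$pos[sites], ref = g$ref[sites],
    alt = g$alt[sites],
    dosage = g$dosage[sites, samples, drop = FALSE],
    sample_ids = colnames(g$dosage[, samples, drop = FALSE]),
    is_variant = g$is_variant[sites]
  )
}

# sample column indices for a population label, via a popmap tibble
pop_samples <- function(g, popmap, label) {
  ids <- popmap$sample_id[popmap$population == label]
  which(g$sample_ids %in% ids)
}

# samples x 4 membership indicator in POP_LEVELS order
pop_membership <- function(g, popmap) {
  m <- matrix(0, nrow = length(g$sample_ids), ncol = 4L,
              dimnames = list(g$sample_ids, POP_LEVELS))
  idx <- match(g$sample_ids, popmap$sample_id)
  lab <- popmap$population[idx]
  keep <- !is.na(lab)
  m[cbind(which(keep), match(lab[keep], POP_LEVELS))] <- 1
  m
}
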