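#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads biallelic SNPs and invariant reference records from a
#' coordinate-sorted VCF (which may interleave invariant sites with SNPs, as
#' produced by all-sites genotyping). Multiallelic records and indels are
#' skipped and counted. Genotype dosage is the number of alternate alleles in
#' the call; half-calls (e.g. `./1`) and missing calls are treated as missing.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param popmap Optional population map tibble (see
#'   [read_population_map()]); when given, every mapped sample must be
#'   present in the VCF header and the matrix is restricted to mapped
#'   samples, in popmap order.
#' @param region Optional `c(start, end)` 1-based inclusive position range.
#'
#' @return A [genotype_matrix()]; attribute `skipped` carries the count of
#'   multiallelic/indel records dropped.
#' @export
read_genotype_vcf <- function(path, popmap = NULL, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) != 1L) {
    abort(paste0(
      "expected a single contig per genotype matrix, found: ",
      paste(chroms, collapse = ", ")
    ))
  }
  pos <- as.integer(fix[, "POS"])
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("input VCF is not coordinate-sorted (positions must increase)")
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."

  invariant <- alt == "." | alt == ""
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- nchar(ref) != 1L | (!invariant & !multi & nchar(alt) != 1L)
  keep <- !multi & !indel
  n_skipped <- sum(!keep)
  if (!is.null(region)) {
    keep <- keep & pos >= region[[1]] & pos <= region[[2]]
  }

  gt <- v@gt[keep, -1L, drop = FALSE] # drop FORMAT column
  samples <- colnames(gt)
  if (!is.null(popmap)) {
    missing <- setdiff(popmap$sample_id, samples)
    if (length(missing)) {
      abort(paste0(
        "samples in population map absent from VCF: ",
        paste(missing, collapse = ", ")
      ))
    }
    gt <- gt[, popmap$sample_id, drop = FALSE]
    samples <- popmap$sample_id
  }

  calls <- sub(":.*$", "", gt)
  dosage <- gt_to_dosage(calls)

  g <- genotype_matrix(
    chrom = chroms, pos = pos[keep], ref = ref[keep],
    alt = ifelse(invariant[keep], NA_character_, alt[keep]),
    dosage = dosage, sample_ids = samples,
    is_variant = !invariant[keep]
  )
  attr(g, "skipped") <- n_skipped
  if (n_skipped > 0L) {
    inform(paste0("read_genotype_vcf: skipped ", n_skipped,
                  " multiallelic/indel record(s)"))
  }
  g
}

# "0/1", "1|1", "./.", "./1" ... -> alt dosage or NA; half-calls are missing
gt_to_dosage <- function(calls) {
  lut <- c(
    "0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
    "1/1" = 2L, "1|1" = 2L
  )
  d <- matrix(lut[calls], nrow = nrow(calls), ncol = ncol(calls))
  colnames(d) <- colnames(calls)
  d
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype fields. Invariant sites are
#' written with `ALT = "."` so that downstream readers retain them for D_XY
#' denominators. Used by the synthetic-data generator; round-trips through
#' [read_genotype_vcf()].
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param contig_length Optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path, contig_length = NULL) {
  if (is.null(contig_length)) contig_length <- max(g$pos)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rcdscan",
    sprintf("##contig=<ID=%s,length=%d>", g$chrom, as.integer(contig_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L],
                   nrow = nrow(g$dosage))
  gt_str[is.na(g$dosage)] <- "./."
  body <- paste(
    g$chrom, g$pos, ".", g$ref,
    ifelse(g$is_variant, g$alt, "."),
    ".", "PASS", ".", "GT",
    apply(gt_str, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
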