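#' Read a two-column population map
#'
#' The population map assigns each sample to one of the four populations of
#' the contact-zone design (see [population_labels()]): allopatric and
#' parapatric populations of the donor (`MUL`) and recipient (`FAS`) species.
#'
#' @param path TSV with two columns (no header): sample_id, population.
#' @return Tibble with columns `sample_id`, `population`.
#' @export
read_population_map <- function(path) {
  pm <- readr::read_tsv(path, col_names = c("sample_id", "population"),
                        col_types = "cc", progress = FALSE)
  validate_popmap(pm)
}

#' Validate a population map tibble
#'
#' @param pm Tibble with columns `sample_id`, `population`.
#' @return `pm`, invisibly validated (returned as a tibble).
#' @export
validate_popmap <- function(pm) {
  pm <- as_tibble(pm)
  if (anyDuplicated(pm$sample_id)) {
    dup <- unique(pm$sample_id[duplicated(pm$sample_id)])
    abort(paste0("duplicate sample_id in population map: ",
                 paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(pm$population), POP_LEVELS)
  if (length(bad)) {
    abort(paste0(
      "unknown population label(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(POP_LEVELS, collapse = ", "), ")"
    ))
  }
  pm
}

#' Write a population map
#' @param pm Popmap tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(pm, path) {
  readr::write_tsv(pm[, c("sample_id", "population")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a SIFT score table
#'
#' A lookup of per-allele SIFT tolerance scores for coding variants:
#' `score` in \[0,1\] (0 = intolerant/deleterious, 1 = tolerated) plus a
#' low-confidence flag from the scorer.
#'
#' @param path TSV with header columns `chrom`, `pos`, `allele`, `score`,
#'   `low_confidence` (logical).
#' @return Tibble keyed by (chrom, pos, allele).
#' @export
read_sift_table <- function(path) {
  st <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", allele = "c", score = "d", low_confidence = "l"
  ), progress = FALSE)
  if (any(st$score < 0 | st$score > 1, na.rm = TRUE)) {
    bad <- st[which(st$score < 0 | st$score > 1)[1L], ]
    abort(sprintf("SIFT score out of [0,1] at %s:%d allele %s (score %g)",
                  bad$chrom, bad$pos, bad$allele, bad$score))
  }
  st
}

#' Look up a SIFT score
#'
#' @param sift Tibble from [read_sift_table()].
#' @param chrom,pos,allele Key of the query.
#' @return One-row tibble with `score` and `low_confidence`, or `NA` entries
#'   when the key has no score (a distinguished "no score" result, not an
#'   error).
#' @export
sift_lookup <- function(sift, chrom, pos, allele) {
  hit <- sift[sift$chrom == chrom & sift$pos == pos & sift$allele == allele, ]
  if (nrow(hit) == 0L) {
    return(tibble(score = NA_real_, low_confidence = NA))
  }
  tibble(score = hit$score[[1L]], low_confidence = hit$low_confidence[[1L]])
}

#' Write windows as BED3
#'
#' Window intervals are kept 0-based half-open internally, so they are
#' emitted verbatim as BED.
#'
#' @param windows Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_bed <- function(windows, path) {
  readr::write_tsv(windows[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a BED3 file of windows
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_window_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", progress = FALSE)
}

#' Write a statistics table as TSV with header
#'
#' Deterministic column order (as given); round-trips losslessly through
#' [read_scan_table()]. An empty record set yields a header-only file.
#'
#' @param records A data frame / tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(records, path) {
  readr::write_tsv(as_tibble(records), path, col_names = TRUE)
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
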