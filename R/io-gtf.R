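#' Read gene annotation from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based closed coordinates) and converts
#' all intervals to the package's internal 0-based half-open convention.
#' Genes are grouped from exon/CDS lines by `gene_id`; a transcript without
#' any CDS line is flagged non-coding.
#'
#' @param path GTF path.
#' @return A `gene_annotation` list with tibbles `genes` (gene_id, chrom,
#'   start, end, strand), `transcripts` (transcript_id, gene_id, chrom,
#'   start, end, strand, coding), `exons` and `cds` (transcript_id, start,
#'   end), all 0-based half-open.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  df$start0 <- df$start - 1L # to 0-based half-open; end stays (closed end == open end)
  feat <- as.character(df$type)

  tx_rows <- df[feat %in% c("exon", "CDS"), ]
  if (!nrow(tx_rows)) abort("GTF contains no exon/CDS features")

  ex_rows <- df[feat == "exon", ]
  exons <- tibble(transcript_id = ex_rows$transcript_id,
                  start = ex_rows$start0, end = ex_rows$end)
  cds_rows <- df[feat == "CDS", ]
  cds <- tibble(transcript_id = cds_rows$transcript_id,
                start = cds_rows$start0, end = cds_rows$end)

  transcripts <- tx_rows |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[[1L]],
      chrom = as.character(.data$seqnames[[1L]]),
      start = min(.data$start0), end = max(.data$end),
      strand = as.character(.data$strand[[1L]]),
      .groups = "drop"
    ) |>
    mutate(coding = .data$transcript_id %in% cds$transcript_id)

  genes <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[[1L]],
      start = min(.data$start), end = max(.data$end),
      strand = .data$strand[[1L]], .groups = "drop"
    )
  # prefer explicit gene lines for the gene span when present
  gene_lines <- df[feat == "gene", ]
  if (nrow(gene_lines)) {
    gl <- tibble(
      gene_id = gene_lines$gene_id,
      chrom = as.character(gene_lines$seqnames),
      start = gene_lines$start0, end = gene_lines$end,
      strand = as.character(gene_lines$strand)
    )
    genes <- bind_rows(gl, genes[!genes$gene_id %in% gl$gene_id, ])
  }
  stopifnot(all(genes$start <= genes$end))

  structure(
    list(genes = arrange(genes, .data$chrom, .data$start),
         transcripts = transcripts, exons = exons, cds = cds),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts (",
      sum(x$transcripts$coding), " coding)\n", sep = "")
  invisible(x)
}

#' Write a gene annotation as GTF
#'
#' Inverse of [read_gene_annotation()] for simulator output: internal
#' 0-based half-open intervals are converted back to GTF 1-based closed.
#'
#' @param ann A `gene_annotation`.
#' @param path Output GTF path.
#' @param source Source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path, source = "rcdscan") {
  line <- function(chrom, feature, start0, end, strand, attrs) {
    paste(chrom, source, feature, start0 + 1L, end, ".", strand, ".",
          attrs, sep = "\t")
  }
  out <- character(0)
  for (i in seq_len(nrow(ann$genes))) {
    gn <- ann$genes[i, ]
    out <- c(out, line(gn$chrom, "gene", gn$start, gn$end, gn$strand,
                       sprintf('gene_id "%s";', gn$gene_id)))
    txs <- ann$transcripts[ann$transcripts$gene_id == gn$gene_id, ]
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j, ]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       gn$gene_id, tx$transcript_id)
      out <- c(out, line(tx$chrom, "transcript", tx$start, tx$end,
                         tx$strand, attrs))
      ex <- ann$exons[ann$exons$transcript_id == tx$transcript_id, ]
      for (k in seq_len(nrow(ex))) {
        out <- c(out, line(tx$chrom, "exon", ex$start[k], ex$end[k],
                           tx$strand, attrs))
      }
      cd <- ann$cds[ann$cds$transcript_id == tx$transcript_id, ]
      for (k in seq_len(nrow(cd))) {
        out <- c(out, line(tx$chrom, "CDS", cd$start[k], cd$end[k],
                           tx$strand, attrs))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
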