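# Hand-built two-gene toy annotation with a reference engineered so every
# effect class is reachable by a single substitution, plus the hand truth.

toy_reference <- function() {
  len <- 7100L
  s <- rep("C", len)
  s[131:220] <- "A" # CDS piece 1 of plus gene, 0-based [130,220): AAA codons
  s[281:370] <- "A" # CDS piece 2, 0-based [280,370)
  s[601:609] <- "T" # minus-strand gene CDS, 0-based [600,609)
  fa <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(fa) <- "chr1"
  fa
}

toy_annotation <- function() {
  structure(list(
    genes = tibble::tibble(
      gene_id = c("GPLUS", "GMINUS"), chrom = "chr1",
      start = c(100L, 600L), end = c(400L, 609L),
      strand = c("+", "-")
    ),
    transcripts = tibble::tibble(
      transcript_id = c("GPLUS.t1", "GMINUS.t1"),
      gene_id = c("GPLUS", "GMINUS"), chrom = "chr1",
      start = c(100L, 600L), end = c(400L, 609L),
      strand = c("+", "-"), coding = c(TRUE, TRUE)
    ),
    exons = tibble::tibble(
      transcript_id = c("GPLUS.t1", "GPLUS.t1", "GMINUS.t1"),
      start = c(100L, 280L, 600L), end = c(220L, 400L, 609L)
    ),
    cds = tibble::tibble(
      transcript_id = c("GPLUS.t1", "GPLUS.t1", "GMINUS.t1"),
      start = c(130L, 280L, 600L), end = c(220L, 370L, 609L)
    )
  ), class = "gene_annotation")
}

# 12 variants on the plus-strand gene covering every effect class
# (positions are 1-based; zero-based position = pos - 1)
toy_variants <- function() {
  tibble::tribble(
    ~pos, ~ref, ~alt, ~expect,
    131L, "A", "T", "stop_gained",     # codon 1: AAA -> TAA
    135L, "A", "G", "missense",        # codon 2: AAA -> AGA
    139L, "A", "G", "synonymous",      # codon 3: AAA -> AAG
    221L, "C", "G", "splice_donor",    # intron base 1
    280L, "C", "A", "splice_acceptor", # intron base -1
    226L, "C", "T", "splice_region",   # intron base 6
    251L, "C", "T", "intron",
    111L, "C", "T", "5_prime_UTR",
    381L, "C", "T", "3_prime_UTR",
    51L,  "C", "T", "upstream_gene",
    451L, "C", "T", "downstream_gene",
    6001L, "C", "T", "intergenic"
  ) |>
    dplyr::mutate(chrom = "chr1", .before = 1)
}
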