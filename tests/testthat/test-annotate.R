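# Candidate-gene variant annotation: unique sites, effect classes,
# flank pairs, B-SIFT, motif uniqueness.

test_that("population-unique sites require alt copies only in the recipient parapatric group", {
  # columns: 2 ALLO_MUL, 2 PARA_MUL, 2 ALLO_FAS, 2 PARA_FAS
  dos <- rbind(
    c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 1L), # 3 copies in PARA_FAS only -> yes
    c(0L, 0L, 0L, 0L, 1L, 0L, 2L, 1L), # also 1 copy in ALLO_FAS -> no
    c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), # alt absent in PARA_FAS -> no
    c(0L, NA, 0L, 0L, NA, 0L, 1L, 0L)  # missing elsewhere counts nothing
  )
  g <- make_geno(dos)
  pm <- make_popmap(g$sample_ids)
  u <- unique_parapatric_sites(g, pm)
  expect_equal(u$pos, g$pos[c(1, 4)])
  expect_equal(u$alt_copies_para_fas, c(3, 1))

  # removing a non-recipient carrier can only grow the set
  dos2 <- dos
  dos2[2, 5] <- 0L
  u2 <- unique_parapatric_sites(make_geno(dos2), pm)
  expect_true(all(u$pos %in% u2$pos))
  expect_gte(nrow(u2), nrow(u))

  # region restriction
  region <- tibble::tibble(chrom = "chr1", start = 0L, end = 15L)
  u3 <- unique_parapatric_sites(g, pm, regions = region)
  expect_equal(u3$pos, g$pos[1])
})

test_that("effect classifier matches the hand-annotated toy gene exactly", {
  fa <- toy_reference()
  ann <- toy_annotation()
  variants <- toy_variants()
  eff <- classify_effect(variants, ann, fa)
  plus <- eff[is.na(eff$transcript_id) | eff$transcript_id == "GPLUS.t1", ]
  got <- setNames(plus$effect, plus$pos)
  expect_equal(unname(got[as.character(variants$pos)]), variants$expect)
})

test_that("strand-aware coding classification and flank distances", {
  fa <- toy_reference()
  ann <- toy_annotation()
  # minus-strand CDS of T's: substituting the last base changes the first
  # codon of the reverse-complemented frame -> missense
  eff <- classify_effect(
    tibble::tibble(chrom = "chr1", pos = 609L, ref = "T", alt = "C"),
    ann, fa
  )
  minus <- eff[eff$transcript_id == "GMINUS.t1", ]
  expect_equal(minus$effect, "missense")

  # positions flanking a minus-strand gene flip upstream/downstream
  eff2 <- classify_effect(
    tibble::tibble(chrom = "chr1", pos = c(551L, 701L), ref = "C",
                   alt = "T"),
    ann, fa
  )
  m2 <- eff2[eff2$transcript_id == "GMINUS.t1", ]
  expect_equal(m2$effect[m2$pos == 551L], "downstream_gene")
  expect_equal(m2$effect[m2$pos == 701L], "upstream_gene")
})

test_that("transcripts with out-of-frame CDS are skipped with a warning", {
  fa <- toy_reference()
  ann <- toy_annotation()
  ann$cds$end[3] <- 608L # 8 bases, not divisible by 3
  expect_warning(
    eff <- classify_effect(
      tibble::tibble(chrom = "chr1", pos = 605L, ref = "T", alt = "C"),
      ann, fa
    ),
    "multiple of 3"
  )
  expect_false("GMINUS.t1" %in% eff$transcript_id)
})

test_that("flank pairs are 13 bases with the variant at the centre", {
  fa <- toy_reference()
  sites <- tibble::tibble(chrom = "chr1", pos = 1000L, ref = "C",
                          alt = "T")
  fl <- flank_sequences(sites, fa)
  expect_equal(nchar(fl$ref_seq), 13L)
  expect_equal(fl$ref_seq,
               as.character(Biostrings::subseq(fa[[1]], 994, 1006)))
  diffs <- which(strsplit(fl$ref_seq, "")[[1]] !=
                   strsplit(fl$alt_seq, "")[[1]])
  expect_equal(diffs, 7L) # 1-based centre position
  expect_equal(substr(fl$alt_seq, 7, 7), "T")

  # near-edge site skipped with a warning
  expect_warning(
    fl2 <- flank_sequences(
      tibble::tibble(chrom = "chr1", pos = c(4L, 1000L), ref = "C",
                     alt = "A"), fa),
    "skipped"
  )
  expect_equal(fl2$pos, 1000L)

  # REF mismatch is an error naming the site
  expect_error(
    flank_sequences(tibble::tibble(chrom = "chr1", pos = 1000L,
                                   ref = "G", alt = "T"), fa),
    "1000"
  )

  # FASTA emission
  fr <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  write_flank_fasta(fl, fr, fa2)
  ref_out <- Biostrings::readDNAStringSet(fr)
  expect_equal(names(ref_out), "chr1:1000:C")
  expect_equal(as.character(ref_out[[1]]), fl$ref_seq)
})

test_that("B-SIFT classes on a 10-row toy table match hand counts", {
  # 5 scored sites (2 adaptive, 1 neutral, 2 deleterious),
  # 1 low-confidence, 1 with a missing allele score
  keys <- tibble::tibble(
    chrom = "chr1", pos = 1:7 * 100L,
    ref = rep("A", 7), alt = rep("G", 7)
  )
  sift <- tibble::tibble(
    chrom = "chr1",
    pos = rep(1:7 * 100L, each = 2)[-14], # drop alt score at pos 700
    allele = rep(c("A", "G"), 7)[-14],
    score = c(0.3, 0.8,  0.2, 0.9,  0.5, 0.5,  0.9, 0.1,  1.0, 0.0,
              0.1, 0.6,  0.4),
    low_confidence = c(rep(FALSE, 10), TRUE, FALSE, FALSE)
  )
  res <- bsift_score(keys, sift)
  expect_equal(sum(res$class == "adaptive", na.rm = TRUE), 2L)
  expect_equal(sum(res$class == "neutral", na.rm = TRUE), 1L)
  expect_equal(sum(res$class == "deleterious", na.rm = TRUE), 2L)
  expect_equal(res$status[res$pos == 600L], "low_confidence")
  expect_equal(res$status[res$pos == 700L], "no_score")
  expect_equal(res$bsift[res$pos == 100L], 0.5)
  expect_equal(res$bsift[res$pos == 500L], -1)
  expect_true(all(res$bsift >= -1 & res$bsift <= 1, na.rm = TRUE))
})

test_that("a one-hot motif of the alternate flank is unique to the alternate allele", {
  alt_13 <- "ACGTACGTACGTA"
  ref_13 <- alt_13
  substr(ref_13, 7, 7) <- "A" # centre differs: ref A, alt G
  one_hot <- function(s) {
    m <- matrix(1e-9, 4, nchar(s),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    ch <- strsplit(s, "")[[1]]
    for (k in seq_along(ch)) m[ch[k], k] <- 1
    sweep(m, 2, colSums(m), "/")
  }
  lib <- structure(list(
    list(motif_id = "HOT", width = 13L, mat = one_hot(alt_13)),
    # matches a segment untouched by the variant (first 4 bases)
    list(motif_id = "EDGE", width = 4L, mat = one_hot("ACGT"))
  ), class = "motif_library")
  flanks <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "G",
                           alt = "T", ref_seq = ref_13, alt_seq = alt_13)
  mm <- motif_uniqueness(flanks, lib, threshold_frac = 1.0)
  expect_equal(mm$unique_to_alt, "HOT")
  expect_true(grepl("EDGE", mm$motifs_ref) && grepl("EDGE", mm$motifs_alt))
})

test_that("PWM scanning agrees with the exhaustive oracle and is strand-symmetric", {
  lib <- random_motifs(6, 8, seed = 33)
  set.seed(44)
  for (rep in 1:10) {
    seqs <- random_dna(13)
    for (m in lib) {
      expect_equal(
        motif_best_score(seqs, m) >=
          0.85 * sum(log(apply(m$mat, 2, max) / 0.25)) - 1e-9,
        oracle_motif_matches(seqs, m, 0.85)
      )
    }
  }
  # reverse-complementing both flanks leaves match sets unchanged
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))
  )
  fl <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "C",
                       ref_seq = random_dna(13, seed = 1),
                       alt_seq = random_dna(13, seed = 2))
  fl_rc <- dplyr::mutate(fl, ref_seq = rc(ref_seq), alt_seq = rc(alt_seq))
  m1 <- motif_uniqueness(fl, lib, 0.7)
  m2 <- motif_uniqueness(fl_rc, lib, 0.7)
  expect_equal(m1$motifs_ref, m2$motifs_ref)
  expect_equal(m1$motifs_alt, m2$motifs_alt)
  expect_equal(m1$unique_to_alt, m2$unique_to_alt)
})

test_that("motifs wider than the flank are skipped with a warning", {
  lib <- random_motifs(1, 20, seed = 3)
  fl <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "C",
                       ref_seq = random_dna(13, seed = 5),
                       alt_seq = random_dna(13, seed = 6))
  expect_warning(mm <- motif_uniqueness(fl, lib, 0.8), "wider")
  expect_equal(mm$motifs_ref, "")
})
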