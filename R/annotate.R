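#' Sites carrying alleles unique to the parapatric recipient population
#'
#' A site qualifies iff some non-reference allele has at least one called
#' copy among parapatric recipient-species (`PARA_FAS`) samples and zero
#' called copies among all other samples. Missing genotypes contribute
#' nothing to either count. Optionally restricted to candidate gene
#' regions.
#'
#' @param g A [genotype_matrix()].
#' @param popmap Popmap tibble.
#' @param regions Optional tibble of 0-based half-open intervals (`chrom`,
#'   `start`, `end`) to restrict to.
#' @return Tibble of qualifying sites: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_copies_para_fas`.
#' @export
unique_parapatric_sites <- function(g, popmap, regions = NULL) {
  popmap <- validate_popmap(popmap)
  pf <- pop_samples(g, popmap, "PARA_FAS")
  others <- setdiff(
    which(g$sample_ids %in% popmap$sample_id), pf
  )
  d <- g$dosage
  alt_pf <- rowSums(d[, pf, drop = FALSE], na.rm = TRUE)
  alt_other <- rowSums(d[, others, drop = FALSE], na.rm = TRUE)
  sel <- g$is_variant & alt_pf >= 1 & alt_other == 0
  if (!is.null(regions)) {
    win <- assign_positions(g$pos, regions[regions$chrom == g$chrom, ])
    sel <- sel & !is.na(win)
  }
  tibble(
    chrom = g$chrom, pos = g$pos[sel], ref = g$ref[sel], alt = g$alt[sel],
    alt_copies_para_fas = alt_pf[sel]
  )
}

# effect classes ordered most to least severe; classification reports the
# most severe class per (site, transcript)
EFFECT_CLASSES <- c(
  "stop_gained", "missense", "synonymous", "splice_donor",
  "splice_acceptor", "splice_region", "5_prime_UTR", "3_prime_UTR",
  "intron", "upstream_gene", "downstream_gene", "intergenic"
)

#' Classify the effect of a substitution on overlapping transcripts
#'
#' SnpEff-style single-class effect annotation against a transcript model:
#' CDS variants are translated in frame (strand-aware) and classified
#' synonymous / missense / stop_gained; non-CDS exonic positions become
#' 5'/3' UTR by their side of the CDS in transcript orientation; the first
#' and last two intronic bases of an intron are splice_donor /
#' splice_acceptor and intronic bases 3-8 from a junction splice_region;
#' positions within `flank` bases outside a transcript are upstream /
#' downstream by strand; everything else is intron or intergenic. One
#' most-severe class is reported per transcript; a site overlapping no
#' transcript (and no flank) yields a single `intergenic` record.
#'
#' Transcripts whose CDS length is not a multiple of 3 are skipped with a
#' warning. Exonic positions of non-coding transcripts are reported as
#' `intron` (the class vocabulary has no non-coding-exon category).
#'
#' @param sites Tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param annotation A `gene_annotation`.
#' @param ref_fasta A [Biostrings::DNAStringSet] reference (names =
#'   contigs).
#' @param flank Upstream/downstream radius in bases (default 5000).
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `transcript_id` (`NA` for
#'   intergenic), `gene_id`, `effect`.
#' @export
classify_effect <- function(sites, annotation, ref_fasta, flank = 5000L) {
  tx <- annotation$transcripts
  out <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    z <- s$pos - 1L # 0-based
    cand <- tx[tx$chrom == s$chrom &
                 z >= tx$start - flank & z < tx$end + flank, ]
    if (!nrow(cand)) {
      out[[length(out) + 1L]] <- tibble(
        chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
        transcript_id = NA_character_, gene_id = NA_character_,
        effect = "intergenic"
      )
      next
    }
    for (j in seq_len(nrow(cand))) {
      t1 <- cand[j, ]
      eff <- classify_one(z, s$ref, s$alt, t1, annotation, ref_fasta)
      if (is.na(eff)) next # transcript skipped (bad CDS)
      out[[length(out) + 1L]] <- tibble(
        chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
        transcript_id = t1$transcript_id, gene_id = t1$gene_id,
        effect = eff
      )
    }
  }
  res <- bind_rows(out)
  res$effect <- factor(res$effect, levels = EFFECT_CLASSES)
  arrange(res, .data$pos, .data$transcript_id) |>
    mutate(effect = as.character(.data$effect))
}

# classify a single 0-based position against one transcript row
classify_one <- function(z, ref, alt, t1, annotation, ref_fasta) {
  plus <- t1$strand != "-"
  if (z < t1$start || z >= t1$end) {
    # flanking region
    before <- z < t1$start
    if (plus) {
      return(if (before) "upstream_gene" else "downstream_gene")
    }
    return(if (before) "downstream_gene" else "upstream_gene")
  }
  ex <- annotation$exons[annotation$exons$transcript_id == t1$transcript_id, ]
  ex <- ex[order(ex$start), ]
  cds <- annotation$cds[annotation$cds$transcript_id == t1$transcript_id, ]
  cds <- cds[order(cds$start), ]
  in_exon <- any(z >= ex$start & z < ex$end)

  if (!in_exon) {
    # intronic: distance to nearest junction in transcript orientation.
    # donor = intron side adjacent to the upstream exon (5' of intron)
    lefts <- z - ex$end[ex$end <= z]
    rights <- ex$start[ex$start > z] - z
    d_left <- if (length(lefts)) min(lefts) + 1L else Inf
    d_right <- if (length(rights)) min(rights) else Inf
    don <- if (plus) d_left else d_right
    acc <- if (plus) d_right else d_left
    if (don <= 2L) return("splice_donor")
    if (acc <= 2L) return("splice_acceptor")
    if (min(don, acc) <= 8L) return("splice_region")
    return("intron")
  }
  if (!nrow(cds)) return("intron") # non-coding transcript, exonic
  in_cds <- any(z >= cds$start & z < cds$end)
  if (!in_cds) {
    cds_lo <- min(cds$start); cds_hi <- max(cds$end)
    if (z < cds_lo) return(if (plus) "5_prime_UTR" else "3_prime_UTR")
    return(if (plus) "3_prime_UTR" else "5_prime_UTR")
  }
  # coding: build CDS sequence, substitute, translate the affected codon
  cds_len <- sum(cds$end - cds$start)
  if (cds_len %% 3L != 0L) {
    warn(paste0("transcript ", t1$transcript_id,
                " CDS length not a multiple of 3; skipped"))
    return(NA_character_)
  }
  contig <- ref_fasta[[t1$chrom]]
  pieces <- lapply(seq_len(nrow(cds)), function(k) {
    as.character(Biostrings::subseq(contig, cds$start[k] + 1L, cds$end[k]))
  })
  cds_seq <- paste(pieces, collapse = "")
  # position of z within the concatenated (genome-forward) CDS
  off <- 0L
  for (k in seq_len(nrow(cds))) {
    if (z >= cds$start[k] && z < cds$end[k]) {
      pos_fwd <- off + (z - cds$start[k]) + 1L
      break
    }
    off <- off + (cds$end[k] - cds$start[k])
  }
  ref_seq <- cds_seq
  alt_seq <- cds_seq
  substr(alt_seq, pos_fwd, pos_fwd) <- alt
  if (substr(ref_seq, pos_fwd, pos_fwd) != ref) {
    abort(sprintf("reference base mismatch at 0-based %d in transcript %s",
                  z, t1$transcript_id))
  }
  if (!plus) {
    ref_seq <- revcomp(ref_seq)
    alt_seq <- revcomp(alt_seq)
    pos_fwd <- cds_len - pos_fwd + 1L
  }
  codon_i <- (pos_fwd - 1L) %/% 3L
  ref_codon <- substr(ref_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- substr(alt_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  aa <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                       no.init.codon = TRUE))
  }
  ref_aa <- aa(ref_codon)
  alt_aa <- aa(alt_codon)
  if (alt_aa == "*" && ref_aa != "*") return("stop_gained")
  if (alt_aa == ref_aa) return("synonymous")
  "missense"
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Reference/alternate flank pairs around variants
#'
#' For each site, extracts the 13-base window with the variant at its
#' centre (1-based position 7 of 13) from the reference and from an
#' alternate consensus in which every selected site's reference base is
#' replaced by its population-unique allele. In internal 0-based
#' coordinates a variant at position `p` spans `[p - 6, p + 7)`. Sites
#' closer than 6 bases to a contig end are skipped with a warning (the
#' fixed-width invariant beats coverage).
#'
#' @param sites Tibble with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param ref_fasta A [Biostrings::DNAStringSet].
#' @param width Flank window width (odd; default 13).
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `ref_seq`, `alt_seq`.
#' @export
flank_sequences <- function(sites, ref_fasta, width = 13L) {
  half <- (width - 1L) %/% 2L
  out <- list()
  consensus <- lapply(unique(sites$chrom), function(ch) {
    contig <- ref_fasta[[ch]]
    ss <- sites[sites$chrom == ch, ]
    seq_chr <- as.character(contig)
    for (i in seq_len(nrow(ss))) {
      have <- substr(seq_chr, ss$pos[i], ss$pos[i])
      if (have != ss$ref[i]) {
        abort(sprintf(
          "reference base at %s:%d is %s but VCF REF is %s",
          ch, ss$pos[i], have, ss$ref[i]
        ))
      }
      substr(seq_chr, ss$pos[i], ss$pos[i]) <- ss$alt[i]
    }
    seq_chr
  })
  names(consensus) <- unique(sites$chrom)
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    contig_len <- Biostrings::width(ref_fasta[s$chrom])
    lo <- s$pos - half
    hi <- s$pos + half
    if (lo < 1L || hi > contig_len) {
      n_skipped <- n_skipped + 1L
      next
    }
    ref_seq <- as.character(Biostrings::subseq(ref_fasta[[s$chrom]], lo, hi))
    alt_seq <- substr(consensus[[s$chrom]], lo, hi)
    out[[length(out) + 1L]] <- tibble(
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      ref_seq = ref_seq, alt_seq = alt_seq
    )
  }
  if (n_skipped > 0L) {
    warn(paste0("flank_sequences: skipped ", n_skipped,
                " site(s) within ", half, " bases of a contig end"))
  }
  bind_rows(out)
}

#' Write flank pairs as FASTA
#'
#' Headers are `chrom:pos:allele`; reference flanks and alternate flanks
#' go to separate files.
#'
#' @param flanks Tibble from [flank_sequences()].
#' @param ref_path,alt_path Output FASTA paths.
#' @return Invisibly, `c(ref_path, alt_path)`.
#' @export
write_flank_fasta <- function(flanks, ref_path, alt_path) {
  mk <- function(seqs, alleles) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste(flanks$chrom, flanks$pos, alleles, sep = ":")
    x
  }
  Biostrings::writeXStringSet(mk(flanks$ref_seq, flanks$ref), ref_path)
  Biostrings::writeXStringSet(mk(flanks$alt_seq, flanks$alt), alt_path)
  invisible(c(ref_path, alt_path))
}

#' B-SIFT scoring of population-unique coding variants
#'
#' `bsift = sift(alt) - sift(ref)` per site, in \[-1, 1\]: a positive
#' difference marks the derived allele as better tolerated than the
#' reference (candidate adaptive), zero neutral, negative deleterious.
#' Records with a low-confidence flag on either allele keep their score
#' but get no class; records missing a score for either allele are
#' emitted with `status = "no_score"` and are excluded from class counts.
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param sift SIFT table from [read_sift_table()].
#' @return Tibble: site key plus `sift_ref`, `sift_alt`, `bsift`,
#'   `low_confidence`, `class` (`adaptive`/`neutral`/`deleterious` or
#'   `NA`), `status` (`scored`/`no_score`/`low_confidence`).
#' @export
bsift_score <- function(sites, sift) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    r <- sift_lookup(sift, s$chrom, s$pos, s$ref)
    a <- sift_lookup(sift, s$chrom, s$pos, s$alt)
    if (is.na(r$score) || is.na(a$score)) {
      return(tibble(
        chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
        sift_ref = r$score, sift_alt = a$score, bsift = NA_real_,
        low_confidence = NA, class = NA_character_, status = "no_score"
      ))
    }
    lowc <- isTRUE(r$low_confidence) || isTRUE(a$low_confidence)
    b <- a$score - r$score
    cls <- if (lowc) NA_character_
           else if (b > 0) "adaptive" else if (b < 0) "deleterious"
           else "neutral"
    tibble(
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      sift_ref = r$score, sift_alt = a$score, bsift = b,
      low_confidence = lowc, class = cls,
      status = if (lowc) "low_confidence" else "scored"
    )
  })
  bind_rows(rows)
}

#' Motifs matching a flank and motifs unique to the alternate allele
#'
#' Scores every motif of the library against the reference and alternate
#' flank sequences by sliding the position weight matrix over all
#' alignments on both strands and taking the best log-odds score against a
#' uniform 0.25 background. A motif matches a sequence iff its best score
#' reaches `threshold_frac` of that motif's maximum achievable score.
#' `unique_to_alt` is the set difference `motifs_alt \ motifs_ref`: the
#' putative transcription-factor motifs created by the derived allele.
#' Motifs wider than the flank are skipped with a warning.
#'
#' @param flanks Tibble from [flank_sequences()].
#' @param motifs A `motif_library`.
#' @param threshold_frac Fraction of the per-motif maximum score required
#'   for a match, in (0, 1\] (default 0.85).
#' @return Tibble: site key, `motifs_ref`, `motifs_alt`, `unique_to_alt`
#'   (comma-separated id lists), `n_unique_to_alt`.
#' @export
motif_uniqueness <- function(flanks, motifs, threshold_frac = 0.85) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  widths <- vapply(motifs, function(m) as.integer(m$width), integer(1))
  seq_len_f <- nchar(flanks$ref_seq[1] %||% "")
  skip <- widths > seq_len_f
  if (any(skip)) {
    warn(paste0("motif_uniqueness: skipping ", sum(skip),
                " motif(s) wider than the flank"))
  }
  lib <- motifs[!skip]
  rows <- lapply(seq_len(nrow(flanks)), function(i) {
    fr <- flanks[i, ]
    m_ref <- vapply(lib, function(m) motif_matches(fr$ref_seq, m,
                                                   threshold_frac),
                    logical(1))
    m_alt <- vapply(lib, function(m) motif_matches(fr$alt_seq, m,
                                                   threshold_frac),
                    logical(1))
    ids <- vapply(lib, `[[`, character(1), "motif_id")
    uniq <- setdiff(ids[m_alt], ids[m_ref])
    tibble(
      chrom = fr$chrom, pos = fr$pos, ref = fr$ref, alt = fr$alt,
      motifs_ref = paste(ids[m_ref], collapse = ","),
      motifs_alt = paste(ids[m_alt], collapse = ","),
      unique_to_alt = paste(uniq, collapse = ","),
      n_unique_to_alt = length(uniq)
    )
  })
  bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Best PWM log-odds score of a motif over a sequence (both strands)
#'
#' @param seq Character scalar (ACGT).
#' @param motif One motif (`motif_id`, `width`, `mat`).
#' @param background Background base probability (uniform 0.25).
#' @return Best score over all offsets and both strands (`-Inf` if the
#'   motif does not fit).
#' @export
motif_best_score <- function(seq, motif, background = 0.25) {
  score_one <- function(s) {
    n <- nchar(s)
    w <- motif$width
    if (w > n) return(-Inf)
    chars <- strsplit(s, "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T"))
    lods <- log(pmax(motif$mat, 0) / background)
    best <- -Inf
    for (off in 0:(n - w)) {
      sc <- sum(lods[cbind(idx[(off + 1):(off + w)], seq_len(w))])
      if (!is.na(sc) && sc > best) best <- sc
    }
    best
  }
  max(score_one(seq), score_one(revcomp(seq)))
}

# maximum achievable log-odds score for a motif
motif_max_score <- function(motif, background = 0.25) {
  sum(log(apply(motif$mat, 2L, max) / background))
}

motif_matches <- function(seq, motif, threshold_frac, background = 0.25) {
  best <- motif_best_score(seq, motif, background)
  best >= threshold_frac * motif_max_score(motif, background) - 1e-9
}
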