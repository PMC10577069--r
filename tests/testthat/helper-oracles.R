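# Independent brute-force oracles and fixture builders. These deliberately
# use explicit loops over sites, alleles and haplotype pairs so they share
# no code path with the vectorised estimators they check.

# genotype_matrix from a dosage matrix; alleles auto-filled
make_geno <- function(dosage, pos = NULL, chrom = "chr1",
                      is_variant = NULL) {
  dosage <- as.matrix(dosage)
  ns <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(is_variant)) is_variant <- rep(TRUE, ns)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  }
  genotype_matrix(
    chrom = chrom, pos = pos,
    ref = rep("A", ns),
    alt = ifelse(is_variant, "G", NA_character_),
    dosage = dosage, sample_ids = colnames(dosage),
    is_variant = is_variant
  )
}

# popmap for column blocks of sizes n (POP_LEVELS order)
make_popmap <- function(sample_ids, sizes = c(2L, 2L, 2L, 2L)) {
  stopifnot(length(sample_ids) == sum(sizes))
  tibble::tibble(
    sample_id = sample_ids,
    population = rep(population_labels(), times = sizes)
  )
}

# whole-window span as a one-row window table
whole_window <- function(g) {
  tibble::tibble(chrom = g$chrom, start = min(g$pos) - 1L,
                 end = max(g$pos))
}

# --- Hudson F_ST oracle: explicit per-site arithmetic, ratio of sums ----
oracle_fst <- function(dosage, a_cols, b_cols) {
  num_sum <- 0; den_sum <- 0; any_site <- FALSE
  for (s in seq_len(nrow(dosage))) {
    da <- dosage[s, a_cols]; db <- dosage[s, b_cols]
    da <- da[!is.na(da)]; db <- db[!is.na(db)]
    n1 <- 2 * length(da); n2 <- 2 * length(db)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(da) / n1; p2 <- sum(db) / n2
    num_sum <- num_sum + (p1 - p2)^2 -
      p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den_sum <- den_sum + p1 * (1 - p2) + p2 * (1 - p1)
    any_site <- TRUE
  }
  if (!any_site || den_sum == 0) return(NA_real_)
  num_sum / den_sum
}

# --- D_XY oracle: double loop over inter-population allele pairs --------
oracle_dxy <- function(dosage, a_cols, b_cols) {
  total <- 0; n_sites_cmp <- 0
  for (s in seq_len(nrow(dosage))) {
    da <- dosage[s, a_cols]; db <- dosage[s, b_cols]
    da <- da[!is.na(da)]; db <- db[!is.na(db)]
    if (!length(da) || !length(db)) next
    # expand genotypes to allele lists (diploid, unphased)
    al_a <- unlist(lapply(da, function(g) c(rep(1, g), rep(0, 2 - g))))
    al_b <- unlist(lapply(db, function(g) c(rep(1, g), rep(0, 2 - g))))
    diff <- 0
    for (x in al_a) for (y in al_b) if (x != y) diff <- diff + 1
    total <- total + diff / (length(al_a) * length(al_b))
    n_sites_cmp <- n_sites_cmp + 1
  }
  if (n_sites_cmp == 0) return(NA_real_)
  total / n_sites_cmp
}

# --- Tajima's D oracle: pairwise haplotype differences per site ---------
oracle_tajima <- function(dosage, cols) {
  n <- 2 * length(cols)
  S <- 0; pi_sum <- 0
  for (s in seq_len(nrow(dosage))) {
    d <- dosage[s, cols]
    if (any(is.na(d))) next # complete-case within the population
    alleles <- unlist(lapply(d, function(g) c(rep(1, g), rep(0, 2 - g))))
    j <- sum(alleles)
    if (j > 0 && j < n) S <- S + 1
    diff_pairs <- 0
    for (x in seq_len(n - 1)) {
      for (y in (x + 1):n) if (alleles[x] != alleles[y]) {
        diff_pairs <- diff_pairs + 1
      }
    }
    pi_sum <- pi_sum + diff_pairs / choose(n, 2)
  }
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- exhaustive PWM match oracle: all offsets, both strands -------------
oracle_motif_matches <- function(seq, motif, threshold_frac) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  score_at <- function(s, off) {
    tot <- 0
    for (k in seq_len(motif$width)) {
      base <- substr(s, off + k, off + k)
      tot <- tot + log(motif$mat[base, k] / 0.25)
    }
    tot
  }
  best <- -Inf
  for (s in c(seq, rc(seq))) {
    n_off <- nchar(s) - motif$width
    if (n_off < 0) next
    for (off in 0:n_off) {
      sc <- score_at(s, off)
      if (sc > best) best <- sc
    }
  }
  max_score <- 0
  for (k in seq_len(motif$width)) {
    max_score <- max_score + log(max(motif$mat[, k]) / 0.25)
  }
  unname(best >= threshold_frac * max_score - 1e-9)
}

# random motif library for oracle comparisons
random_motifs <- function(n, width, seed) {
  set.seed(seed)
  structure(lapply(seq_len(n), function(i) {
    mat <- matrix(stats::rgamma(4 * width, 1), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    mat <- sweep(mat, 2, colSums(mat), "/")
    list(motif_id = paste0("R", i), width = width, mat = mat)
  }), class = "motif_library")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
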