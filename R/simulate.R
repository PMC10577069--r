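#' Parameters for the four-population simulator
#'
#' The generator draws allele frequencies under a hierarchical
#' Balding-Nichols model that mirrors the scan's admixture likelihood: an
#' ancestral frequency `p ~ Uniform(0.05, 0.95)` at variant sites splits
#' into two species-level frequencies via `Beta(p(1-F)/F, (1-p)(1-F)/F)`
#' with `F = F_species`, and each species frequency splits into two
#' population frequencies with `F = F_pop`. Parapatric recipient-species
#' (`PARA_FAS`) individuals are admixed: each of their two allele copies
#' takes donor ancestry with probability `q_i` (drawn per individual and
#' window around `q_intro`) and is then sampled at the corresponding
#' parapatric population's frequency.
#'
#' Planted windows carry the three reinforcement signatures: extra drift
#' `F_boost` in the recipient parapatric population (elevated parapatric
#' divergence), ancestry forced to `q_planted` (reduced introgression),
#' and a fraction `singleton_fraction` of their variant sites converted to
#' singletons private to the recipient parapatric population (negative
#' Tajima's D, planted mechanically rather than via simulated sweeps so
#' the signature is under deterministic control).
#'
#' @param n_per_pop Samples per population, named or in
#'   [population_labels()] order (default 10 each, close to real
#'   contact-zone study designs of 9-11 per group).
#' @param n_windows Number of windows laid end-to-end on the contig.
#' @param sites_per_window Sites per window (total sites =
#'   `n_windows * sites_per_window`).
#' @param variant_fraction Fraction of sites polymorphic in the ancestor
#'   (default 0.1; the rest are invariant reference sites, emulating the
#'   roughly 2% SNP density of all-sites primate VCFs at desk scale).
#' @param F_species,F_pop Balding-Nichols drift coefficients between
#'   species and between populations within species.
#' @param q_intro Mean donor ancestry of recipient parapatric individuals
#'   in null windows (default 0.06; real per-individual values range
#'   0-0.18).
#' @param q_concentration Beta concentration for per-individual ancestry
#'   draws around the window mean.
#' @param planted Tibble with `window` (index), `F_boost`, `q_planted`,
#'   `singleton_fraction`; `NULL` for none.
#' @param spacing Base-pair spacing between adjacent sites (default 30).
#' @param missing_rate Per-call missingness probability (default 0).
#' @param chrom Contig name.
#' @param seed RNG seed; identical parameters + seed give byte-identical
#'   outputs.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_per_pop = c(ALLO_MUL = 10L, PARA_MUL = 10L,
                                     ALLO_FAS = 10L, PARA_FAS = 10L),
                       n_windows = 50L, sites_per_window = 100L,
                       variant_fraction = 0.1,
                       F_species = 0.2, F_pop = 0.05,
                       q_intro = 0.06, q_concentration = 30,
                       planted = NULL, spacing = 30L,
                       missing_rate = 0, chrom = "chr1", seed = 1L) {
  if (is.null(names(n_per_pop))) names(n_per_pop) <- POP_LEVELS
  stopifnot(
    all(POP_LEVELS %in% names(n_per_pop)),
    F_species > 0, F_species < 1, F_pop > 0, F_pop < 1,
    q_intro >= 0, q_intro <= 1,
    variant_fraction >= 0, variant_fraction <= 1
  )
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(
      all(planted$window >= 1), all(planted$window <= n_windows),
      !anyDuplicated(planted$window),
      all(planted$q_planted >= 0 & planted$q_planted <= 1),
      all(planted$singleton_fraction >= 0 & planted$singleton_fraction <= 1)
    )
  }
  structure(
    list(
      n_per_pop = n_per_pop[POP_LEVELS], n_windows = as.integer(n_windows),
      sites_per_window = as.integer(sites_per_window),
      variant_fraction = variant_fraction, F_species = F_species,
      F_pop = F_pop, q_intro = q_intro,
      q_concentration = q_concentration, planted = planted,
      spacing = as.integer(spacing), missing_rate = missing_rate,
      chrom = chrom, seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Default study conditions for the simulator
#'
#' The reference configuration used by the end-to-end examples: 10 samples
#' per population, 50 windows of 1,000 sites (50,000 sites total), 10%
#' variant sites, and 5 planted reinforcement windows (extra recipient
#' drift `F_boost = 0.5`, zero introgressed ancestry, 30% private
#' singletons) evenly spaced along the contig.
#'
#' @param seed RNG seed.
#' @return A [sim_params()] object.
#' @export
default_sim_params <- function(seed = 1L) {
  sim_params(
    n_windows = 50L, sites_per_window = 1000L, variant_fraction = 0.1,
    planted = tibble(window = c(5L, 15L, 25L, 35L, 45L), F_boost = 0.5,
                     q_planted = 0, singleton_fraction = 0.3),
    seed = seed
  )
}

# Balding-Nichols draw: offspring frequency around p with drift F
bn_draw <- function(p, f) {
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Draw per-population allele frequencies for one window
#'
#' @param params A [sim_params()].
#' @param window Window index (1-based); decides planted settings.
#' @return List: `p_anc`, `freq` (sites x 4 matrix, columns in
#'   [population_labels()] order), `is_variant`, `is_singleton`.
#' @export
draw_window_frequencies <- function(params, window) {
  ns <- params$sites_per_window
  is_variant <- runif(ns) < params$variant_fraction
  p_anc <- ifelse(is_variant, runif(ns, 0.05, 0.95), 0)

  plant <- planted_row(params, window)
  f_boost <- if (is.null(plant)) 0 else plant$F_boost
  singleton <- rep(FALSE, ns)
  if (!is.null(plant) && plant$singleton_fraction > 0) {
    vi <- which(is_variant)
    n_sing <- round(plant$singleton_fraction * length(vi))
    if (n_sing > 0) singleton[sample(vi, n_sing)] <- TRUE
  }

  p_mul <- ifelse(is_variant, bn_draw(p_anc, params$F_species), p_anc)
  p_fas <- ifelse(is_variant, bn_draw(p_anc, params$F_species), p_anc)
  freq <- cbind(
    ALLO_MUL = ifelse(is_variant, bn_draw(p_mul, params$F_pop), p_anc),
    PARA_MUL = ifelse(is_variant, bn_draw(p_mul, params$F_pop), p_anc),
    ALLO_FAS = ifelse(is_variant, bn_draw(p_fas, params$F_pop), p_anc),
    PARA_FAS = ifelse(is_variant,
                      bn_draw(p_fas, min(params$F_pop + f_boost, 0.999)),
                      p_anc)
  )
  # singleton sites: all populations fixed ancestral; the single derived
  # copy is injected at genotype-sampling time
  freq[singleton, ] <- 0
  list(p_anc = p_anc, freq = freq, is_variant = is_variant,
       is_singleton = singleton)
}

planted_row <- function(params, window) {
  if (is.null(params$planted)) return(NULL)
  hit <- params$planted[params$planted$window == window, ]
  if (nrow(hit)) hit else NULL
}

#' Sample a genotype block for one window
#'
#' Non-admixed populations draw each individual's dosage
#' `Binomial(2, p_pop)`. Recipient parapatric individuals draw each of
#' their two allele copies independently: donor ancestry with probability
#' `q_i`, then a Bernoulli at the corresponding parapatric population's
#' frequency. `q_i` is Beta-distributed around `q_intro`
#' (`q_planted` in planted windows; exactly 0 or 1 when the mean is 0
#' or 1).
#'
#' @param freqs Output of [draw_window_frequencies()].
#' @param params A [sim_params()].
#' @param window Window index.
#' @return List: `dosage` (sites x samples), `q_true` (per recipient
#'   parapatric individual).
#' @export
sample_genotypes <- function(freqs, params, window) {
  np <- params$n_per_pop
  ns <- params$sites_per_window
  plant <- planted_row(params, window)
  q_mean <- if (is.null(plant)) params$q_intro else plant$q_planted

  blocks <- list()
  for (popk in c("ALLO_MUL", "PARA_MUL", "ALLO_FAS")) {
    p <- freqs$freq[, popk]
    blocks[[popk]] <- matrix(
      rbinom(ns * np[[popk]], 2L, rep(p, np[[popk]])), nrow = ns
    )
  }
  n_pf <- np[["PARA_FAS"]]
  q_i <- if (q_mean <= 0) rep(0, n_pf)
         else if (q_mean >= 1) rep(1, n_pf)
         else rbeta(n_pf, params$q_concentration * q_mean,
                    params$q_concentration * (1 - q_mean))
  p_pm <- freqs$freq[, "PARA_MUL"]
  p_pf <- freqs$freq[, "PARA_FAS"]
  pf_block <- matrix(0L, nrow = ns, ncol = n_pf)
  for (i in seq_len(n_pf)) {
    for (copy in 1:2) {
      anc_mul <- runif(ns) < q_i[i]
      p_copy <- ifelse(anc_mul, p_pm, p_pf)
      pf_block[, i] <- pf_block[, i] + as.integer(runif(ns) < p_copy)
    }
  }
  blocks[["PARA_FAS"]] <- pf_block
  dosage <- do.call(cbind, blocks[POP_LEVELS])

  # inject planted singletons: exactly one derived copy, private to a
  # recipient parapatric individual
  sing <- which(freqs$is_singleton)
  if (length(sing)) {
    offset <- sum(np[c("ALLO_MUL", "PARA_MUL", "ALLO_FAS")])
    dosage[sing, ] <- 0L
    carrier <- offset + sample.int(n_pf, length(sing), replace = TRUE)
    dosage[cbind(sing, carrier)] <- 1L
  }
  if (params$missing_rate > 0) {
    miss <- runif(length(dosage)) < params$missing_rate
    dosage[miss] <- NA_integer_
  }
  list(dosage = dosage, q_true = q_i)
}

#' Simulate a four-population genotype matrix with planted windows
#'
#' Runs [draw_window_frequencies()] and [sample_genotypes()] over all
#' windows and assembles a [genotype_matrix()], the popmap, the window
#' grid and a truth table.
#'
#' @param params A [sim_params()].
#' @return List: `geno` ([genotype_matrix()]), `popmap`, `windows`
#'   (0-based half-open grid of simulation windows), `truth` (per-window
#'   planted flag and settings), `ancestry_truth` (per window x recipient
#'   individual true `q`).
#' @export
simulate_genotypes <- function(params) {
  set.seed(params$seed)
  np <- params$n_per_pop
  # readable ids: AMUL_01.., PMUL_.., AFAS_.., PFAS_..
  sample_ids <- unlist(lapply(POP_LEVELS, function(p) {
    tag <- c(ALLO_MUL = "AMUL", PARA_MUL = "PMUL",
             ALLO_FAS = "AFAS", PARA_FAS = "PFAS")[[p]]
    sprintf("%s_%02d", tag, seq_len(np[[p]]))
  }))
  popmap <- tibble(
    sample_id = sample_ids,
    population = rep(POP_LEVELS, times = np[POP_LEVELS])
  )

  nw <- params$n_windows
  spw <- params$sites_per_window
  dosage <- matrix(NA_integer_, nrow = nw * spw, ncol = sum(np))
  is_variant <- logical(nw * spw)
  truth <- list()
  anc_truth <- list()
  pf_ids <- popmap$sample_id[popmap$population == "PARA_FAS"]
  for (w in seq_len(nw)) {
    fr <- draw_window_frequencies(params, w)
    gs <- sample_genotypes(fr, params, w)
    rows <- ((w - 1L) * spw + 1L):(w * spw)
    dosage[rows, ] <- gs$dosage
    iv <- fr$is_variant
    iv[fr$is_singleton] <- TRUE
    is_variant[rows] <- iv
    plant <- planted_row(params, w)
    truth[[w]] <- tibble(
      window = w, planted = !is.null(plant),
      F_boost = if (is.null(plant)) 0 else plant$F_boost,
      q_window = if (is.null(plant)) params$q_intro else plant$q_planted,
      singleton_fraction = if (is.null(plant)) 0
                           else plant$singleton_fraction
    )
    anc_truth[[w]] <- tibble(window = w, sample_id = pf_ids,
                             q_true = gs$q_true)
  }
  pos <- seq.int(params$spacing, by = params$spacing,
                 length.out = nw * spw)
  # alleles: REF random base; ALT a different base, for variant sites
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nw * spw, replace = TRUE)
  alt_shift <- sample.int(3L, nw * spw, replace = TRUE)
  alt <- bases[((match(ref, bases) - 1L + alt_shift) %% 4L) + 1L]
  alt[!is_variant] <- NA_character_

  # sites simulated as variant but monomorphic-reference in the sample are
  # still flagged variant records (maf 0), matching all-sites VCF output
  geno <- genotype_matrix(
    chrom = params$chrom, pos = pos, ref = ref, alt = alt,
    dosage = dosage, sample_ids = sample_ids, is_variant = is_variant
  )
  win_bp <- params$spacing * spw
  windows <- tibble(
    chrom = params$chrom,
    start = as.integer((seq_len(nw) - 1L) * win_bp),
    end = as.integer(seq_len(nw) * win_bp)
  )
  list(
    geno = geno, popmap = popmap, windows = windows,
    truth = bind_rows(truth), ancestry_truth = bind_rows(anc_truth),
    params = params
  )
}

#' Generate a complete on-disk dataset for the pipeline
#'
#' Writes everything the pipeline reads: an all-sites VCF (invariant sites
#' included), popmap TSV, reference FASTA (matching every VCF REF base),
#' GTF (one gene fully inside each planted window, genes tiling a subset
#' of null windows), a SIFT table covering the ref and alt alleles of all
#' variant sites, a motif library in MEME minimal format, and truth
#' tables. Identical `params` (including seed) give byte-identical files.
#'
#' @param params A [sim_params()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of file paths plus the in-memory simulation.
#' @export
generate_dataset <- function(params, out_dir) {
  sim <- simulate_genotypes(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "sim.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    fasta = file.path(out_dir, "reference.fa"),
    gtf = file.path(out_dir, "genes.gtf"),
    sift = file.path(out_dir, "sift.tsv"),
    motifs = file.path(out_dir, "motifs.meme"),
    truth_windows = file.path(out_dir, "truth_windows.tsv"),
    truth_ancestry = file.path(out_dir, "truth_ancestry.tsv")
  )
  g <- sim$geno
  contig_len <- max(g$pos) + params$spacing
  write_genotype_vcf(g, paths$vcf, contig_length = contig_len)
  write_population_map(sim$popmap, paths$popmap)

  # reference FASTA consistent with VCF REF columns (seeded off the main
  # stream so file emission does not perturb the genotype draw)
  set.seed(params$seed + 1000003L)
  seq_chr <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  seq_chr[g$pos] <- g$ref
  fa <- Biostrings::DNAStringSet(paste(seq_chr, collapse = ""))
  names(fa) <- params$chrom
  Biostrings::writeXStringSet(fa, paths$fasta)

  ann <- sim_annotation(sim, params)
  write_gene_annotation(ann, paths$gtf)

  vi <- which(g$is_variant)
  sift <- tibble(
    chrom = params$chrom,
    pos = rep(g$pos[vi], 2L),
    allele = c(g$ref[vi], g$alt[vi]),
    score = round(runif(2L * length(vi)), 3),
    low_confidence = runif(2L * length(vi)) < 0.05
  ) |> arrange(.data$pos, .data$allele)
  readr::write_tsv(sift, paths$sift)

  motifs <- sim_motif_library(n = 4L, width = 8L)
  write_motif_database(motifs, paths$motifs)

  readr::write_tsv(sim$truth, paths$truth_windows)
  readr::write_tsv(sim$ancestry_truth, paths$truth_ancestry)
  invisible(c(paths, list(sim = sim, annotation = ann, motifs = motifs)))
}

# one gene inside each planted window; genes tiling every other null window
sim_annotation <- function(sim, params) {
  win <- sim$windows
  planted <- sim$truth$planted
  keep <- planted | (seq_len(nrow(win)) %% 2L == 1L)
  genes <- list(); txs <- list(); exons <- list(); cds <- list()
  for (k in which(keep)) {
    w <- win[k, ]
    width <- w$end - w$start
    g_start <- w$start + as.integer(width * 0.2)
    g_len <- as.integer(width * 0.6)
    g_len <- g_len - (g_len %% 3L) # single-exon CDS in frame
    g_end <- g_start + g_len
    gid <- sprintf("GENE_W%04d", k)
    tid <- paste0(gid, ".t1")
    strand <- if (k %% 2L == 0L) "-" else "+"
    genes[[length(genes) + 1L]] <- tibble(
      gene_id = gid, chrom = w$chrom, start = g_start, end = g_end,
      strand = strand
    )
    txs[[length(txs) + 1L]] <- tibble(
      transcript_id = tid, gene_id = gid, chrom = w$chrom,
      start = g_start, end = g_end, strand = strand, coding = TRUE
    )
    exons[[length(exons) + 1L]] <- tibble(transcript_id = tid,
                                          start = g_start, end = g_end)
    cds[[length(cds) + 1L]] <- tibble(transcript_id = tid,
                                      start = g_start, end = g_end)
  }
  structure(
    list(genes = bind_rows(genes), transcripts = bind_rows(txs),
         exons = bind_rows(exons), cds = bind_rows(cds)),
    class = "gene_annotation"
  )
}

# small random motif library (used by the generated dataset)
sim_motif_library <- function(n = 4L, width = 8L) {
  motifs <- lapply(seq_len(n), function(i) {
    mat <- matrix(stats::rgamma(4L * width, shape = 0.5), nrow = 4L)
    mat <- sweep(mat, 2L, colSums(mat), "/")
    rownames(mat) <- c("A", "C", "G", "T")
    list(motif_id = sprintf("SIM_MOTIF_%d", i), width = width, mat = mat)
  })
  structure(motifs, class = "motif_library")
}
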