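# Four-population Balding-Nichols simulator with planted reinforcement
# windows.

test_that("identical parameters and seed give byte-identical datasets", {
  p <- sim_params(n_windows = 4L, sites_per_window = 40L,
                  variant_fraction = 0.3,
                  planted = tibble::tibble(window = 2L, F_boost = 0.4,
                                           q_planted = 0,
                                           singleton_fraction = 0.2),
                  seed = 7L)
  d1 <- tempfile("simA"); d2 <- tempfile("simB")
  generate_dataset(p, d1)
  generate_dataset(p, d2)
  for (f in c("sim.vcf", "popmap.tsv", "reference.fa", "genes.gtf",
              "sift.tsv", "motifs.meme", "truth_windows.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("invariant sites are fixed reference and variant flags are consistent", {
  p <- sim_params(n_windows = 3L, sites_per_window = 100L,
                  variant_fraction = 0.2, seed = 3L)
  sim <- simulate_genotypes(p)
  g <- sim$geno
  inv <- !g$is_variant
  expect_true(all(g$dosage[inv, ] == 0L))
  expect_true(all(is.na(g$alt[inv])))
  expect_true(all(!is.na(g$alt[g$is_variant])))
  expect_true(all(diff(g$pos) > 0))
})

test_that("vanishing drift keeps population frequencies near the ancestral value", {
  p <- sim_params(n_windows = 1L, sites_per_window = 2000L,
                  variant_fraction = 1, F_species = 1e-4, F_pop = 1e-4,
                  seed = 5L)
  set.seed(p$seed)
  fr <- draw_window_frequencies(p, 1L)
  expect_lt(mean(abs(fr$freq[, "ALLO_MUL"] - fr$p_anc)), 0.02)
  expect_lt(mean(abs(fr$freq[, "PARA_FAS"] - fr$p_anc)), 0.02)
})

test_that("planted drift boost raises expected parapatric F_ST (Monte Carlo)", {
  p <- sim_params(n_windows = 2L, sites_per_window = 1500L,
                  variant_fraction = 1, q_intro = 0,
                  planted = tibble::tibble(window = 2L, F_boost = 0.5,
                                           q_planted = 0,
                                           singleton_fraction = 0),
                  seed = 13L)
  sim <- simulate_genotypes(p)
  div <- window_divergence(sim$geno, sim$popmap, "PARA_MUL", "PARA_FAS",
                           sim$windows)
  expect_gt(div$fst[2], div$fst[1])
})

test_that("singleton planting drives recipient-population Tajima's D negative", {
  planted <- tibble::tibble(window = 1:100, F_boost = 0, q_planted = 0,
                            singleton_fraction = 0.3)
  p <- sim_params(n_windows = 100L, sites_per_window = 40L,
                  variant_fraction = 0.5, q_intro = 0, planted = planted,
                  seed = 17L)
  sim <- simulate_genotypes(p)
  td <- window_tajima_d(sim$geno, sim$popmap, "PARA_FAS", sim$windows)
  expect_lt(mean(td$D, na.rm = TRUE), 0)
})

test_that("ancestry boundaries behave: q = 1 draws from the donor parapatric pool", {
  # q_planted = 1: recipient parapatric genotypes should match the donor
  # parapatric frequency in law (z-test on the summed alt count)
  p <- sim_params(n_windows = 1L, sites_per_window = 2000L,
                  variant_fraction = 1, F_species = 0.3, F_pop = 0.05,
                  planted = tibble::tibble(window = 1L, F_boost = 0,
                                           q_planted = 1,
                                           singleton_fraction = 0),
                  seed = 23L)
  set.seed(p$seed)
  fr <- draw_window_frequencies(p, 1L)
  gs <- sample_genotypes(fr, p, 1L)
  expect_true(all(gs$q_true == 1))
  pf_cols <- 31:40
  obs <- sum(gs$dosage[, pf_cols])
  expected <- sum(2 * 10 * fr$freq[, "PARA_MUL"])
  sd_tot <- sqrt(sum(2 * 10 * fr$freq[, "PARA_MUL"] *
                       (1 - fr$freq[, "PARA_MUL"])))
  expect_lt(abs(obs - expected) / sd_tot, 4)
})

test_that("q = 0 makes the recipient parapatric population purely recipient-like", {
  p <- sim_params(n_windows = 1L, sites_per_window = 2000L,
                  variant_fraction = 1, F_species = 0.3, F_pop = 0.05,
                  q_intro = 0, seed = 29L)
  set.seed(p$seed)
  fr <- draw_window_frequencies(p, 1L)
  gs <- sample_genotypes(fr, p, 1L)
  obs <- sum(gs$dosage[, 31:40])
  expected <- sum(2 * 10 * fr$freq[, "PARA_FAS"])
  sd_tot <- sqrt(sum(2 * 10 * fr$freq[, "PARA_FAS"] *
                       (1 - fr$freq[, "PARA_FAS"])))
  expect_lt(abs(obs - expected) / sd_tot, 4)
})

test_that("fixed frequencies give fixed genotypes", {
  p <- sim_params(n_windows = 1L, sites_per_window = 50L,
                  variant_fraction = 1, seed = 1L)
  fr <- list(p_anc = rep(1, 50),
             freq = matrix(1, 50, 4,
                           dimnames = list(NULL, population_labels())),
             is_variant = rep(TRUE, 50), is_singleton = rep(FALSE, 50))
  gs <- sample_genotypes(fr, p, 1L)
  expect_true(all(gs$dosage == 2L))
})

test_that("truth tables track planted windows and per-individual ancestry", {
  planted <- tibble::tibble(window = c(2L, 5L), F_boost = 0.5,
                            q_planted = 0, singleton_fraction = 0.3)
  p <- sim_params(n_windows = 6L, sites_per_window = 30L,
                  planted = planted, seed = 41L)
  sim <- simulate_genotypes(p)
  expect_equal(sim$truth$planted, seq_len(6) %in% c(2L, 5L))
  expect_equal(nrow(sim$ancestry_truth), 6L * 10L)
  expect_true(all(sim$ancestry_truth$q_true[
    sim$ancestry_truth$window %in% c(2L, 5L)] == 0))

  p0 <- sim_params(n_windows = 3L, sites_per_window = 20L, seed = 42L)
  expect_false(any(simulate_genotypes(p0)$truth$planted))
})

test_that("generated dataset round-trips through the readers", {
  p <- sim_params(n_windows = 4L, sites_per_window = 50L,
                  variant_fraction = 0.3,
                  planted = tibble::tibble(window = 3L, F_boost = 0.5,
                                           q_planted = 0,
                                           singleton_fraction = 0.2),
                  seed = 11L)
  out <- tempfile("ds")
  paths <- generate_dataset(p, out)
  pm <- read_population_map(paths$popmap)
  expect_equal(nrow(pm), 40L)
  expect_equal(unname(table(pm$population)[population_labels()]),
               rep(10L, 4), ignore_attr = TRUE)

  g <- read_genotype_vcf(paths$vcf, popmap = pm)
  expect_equal(g$pos, paths$sim$geno$pos)
  expect_equal(g$is_variant, paths$sim$geno$is_variant)
  expect_equal(g$dosage, paths$sim$geno$dosage, ignore_attr = TRUE)

  # reference FASTA agrees with every VCF REF base
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  seq_chr <- as.character(fa[[1]])
  expect_equal(substring(seq_chr, g$pos, g$pos), g$ref)

  ann <- read_gene_annotation(paths$gtf)
  expect_true(all(paste0("GENE_W", sprintf("%04d", 3)) %in%
                    ann$genes$gene_id))
  sift <- read_sift_table(paths$sift)
  expect_true(all(sift$score >= 0 & sift$score <= 1))
  motifs <- read_motif_database(paths$motifs)
  expect_length(motifs, 4L)
})
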