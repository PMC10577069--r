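#' Run the full reinforcement scan pipeline
#'
#' One-command orchestration: windows -> divergence/selection statistics ->
#' ancestry -> permutation scan -> gene overlap -> candidate-gene variant
#' annotation, with per-stage outputs and a JSON run manifest. Identical
#' configuration + seed produces byte-identical outputs.
#'
#' @param config Either a named list or a path to a YAML file with fields:
#'   `vcf`, `popmap` (required); `gtf`, `fasta`, `sift`, `motifs`
#'   (optional; annotation stages run only when their inputs are present);
#'   `out_dir` (required); `n_perm` (default 100), `seed` (default 1),
#'   `perm_frac` (0.95), `tajima_cut` (-1), `ancestry_cut` (0.025),
#'   `ancestry_mode` ("supervised"), `fixed_window` (optional width to
#'   bypass spline windowing), `motif_threshold` (0.85).
#' @return Invisibly, a list with the scan object, per-stage tibbles and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_perm = 100L, seed = 1L, perm_frac = 0.95,
                   tajima_cut = -1, ancestry_cut = 0.025,
                   ancestry_mode = "supervised", fixed_window = NULL,
                   motif_threshold = 0.85)
  cfg <- utils::modifyList(defaults, config)
  for (req in c("vcf", "popmap", "out_dir")) {
    if (is.null(cfg[[req]])) abort(paste0("config field missing: ", req))
  }
  stopifnot(cfg$perm_frac > 0, cfg$perm_frac < 1,
            cfg$ancestry_cut >= 0, cfg$ancestry_cut <= 1)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # stage 1: inputs
  popmap <- run_stage("inputs", read_population_map(cfg$popmap))
  g <- run_stage("inputs", read_genotype_vcf(cfg$vcf, popmap = popmap))
  stage_counts$sites <- n_sites(g)
  stage_counts$samples <- n_samples(g)

  # stage 2: windows
  windows <- run_stage("windows", {
    maf <- per_site_maf(g)
    if (!is.null(cfg$fixed_window)) {
      fixed_windows(maf, cfg$fixed_window, chrom = g$chrom)
    } else {
      define_windows(maf, chrom = g$chrom)
    }
  })
  p_windows <- file.path(cfg$out_dir, "windows.bed")
  write_window_bed(windows, p_windows)
  stage_counts$windows <- nrow(windows)

  # stage 3: statistics + permutation scan (+ ancestry)
  scan <- run_stage("scan", rcd_scan(
    g, popmap, windows, n_perm = cfg$n_perm, seed = cfg$seed,
    perm_frac = cfg$perm_frac, tajima_cut = cfg$tajima_cut,
    ancestry_cut = cfg$ancestry_cut, ancestry_mode = cfg$ancestry_mode
  ))
  tab <- tidy(scan)
  p_scan <- file.path(cfg$out_dir, "scan.windows.tsv")
  write_scan_table(tab, p_scan)
  cand <- tab[tab$candidate, c("chrom", "start", "end")]
  p_cand <- file.path(cfg$out_dir, "scan.candidates.bed")
  write_window_bed(cand, p_cand)
  stage_counts$fst_sig <- sum(tab$fst_sig)
  stage_counts$dxy_sig <- sum(tab$dxy_sig)
  stage_counts$td_sig <- sum(tab$td_sig)
  stage_counts$adm_sig <- sum(tab$adm_sig)
  stage_counts$candidates <- nrow(cand)

  # stage 4: gene overlap
  genes_tbl <- NULL
  annotation <- NULL
  if (!is.null(cfg$gtf)) {
    annotation <- run_stage("genes", read_gene_annotation(cfg$gtf))
    genes_tbl <- run_stage("genes", overlap_genes(cand, annotation))
    write_scan_table(genes_tbl, file.path(cfg$out_dir, "scan.genes.tsv"))
    stage_counts$candidate_genes <- nrow(genes_tbl)
  }

  # stage 5: candidate-gene variant annotation
  annot <- NULL
  if (!is.null(genes_tbl) && nrow(genes_tbl) > 0 &&
      !is.null(cfg$fasta) && !is.null(cfg$sift)) {
    annot <- run_stage("annotate", {
      fa <- Biostrings::readDNAStringSet(cfg$fasta)
      names(fa) <- sub("\\s.*$", "", names(fa))
      sift <- read_sift_table(cfg$sift)
      regions <- genes_tbl[, c("chrom", "start", "end")] |>
        arrange(.data$start)
      usites <- unique_parapatric_sites(g, popmap, regions = regions)
      effects <- classify_effect(usites, annotation, fa)
      flanks <- flank_sequences(usites, fa)
      coding <- effects[effects$effect %in%
                          c("missense", "synonymous", "stop_gained"), ]
      bsift <- bsift_score(distinct(coding[, c("chrom", "pos", "ref",
                                               "alt")]), sift)
      write_scan_table(usites,
                       file.path(cfg$out_dir, "annot.unique_sites.tsv"))
      write_scan_table(effects, file.path(cfg$out_dir, "annot.effects.tsv"))
      write_scan_table(bsift, file.path(cfg$out_dir, "annot.bsift.tsv"))
      if (nrow(flanks)) {
        write_flank_fasta(flanks,
                          file.path(cfg$out_dir, "annot.flanks_ref.fa"),
                          file.path(cfg$out_dir, "annot.flanks_alt.fa"))
      }
      motifs_tbl <- NULL
      if (!is.null(cfg$motifs) && nrow(flanks)) {
        lib <- read_motif_database(cfg$motifs)
        motifs_tbl <- motif_uniqueness(flanks, lib,
                                       threshold_frac = cfg$motif_threshold)
        write_scan_table(motifs_tbl,
                         file.path(cfg$out_dir, "annot.motifs.tsv"))
      }
      list(unique_sites = usites, effects = effects, flanks = flanks,
           bsift = bsift, motifs = motifs_tbl)
    })
    stage_counts$unique_sites <- nrow(annot$unique_sites)
  } else if (!is.null(cfg$sift) && is.null(cfg$fasta)) {
    abort("pipeline stage 'annotate' failed: annotation requested (sift given) but `fasta` input is missing")
  }

  manifest <- list(
    package = "rcdscan",
    version = as.character(utils::packageVersion("rcdscan")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    stages = c("inputs", "windows", "scan", "genes", "annotate"),
    counts = stage_counts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(scan = scan, windows = windows, candidates = cand,
                 genes = genes_tbl, annotation = annot,
                 manifest = manifest, out_dir = cfg$out_dir))
}
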