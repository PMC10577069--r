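#' Per-window two-component ancestry estimation
#'
#' Estimates, for each window and each query individual, the proportion `q`
#' of its alleles drawn from the donor-species ("mulatta") ancestral
#' component under a two-component binomial admixture model, maximising per
#' individual
#' `sum_s [ g log(q pM + (1-q) pF) + (2-g) log(1 - q pM - (1-q) pF) ]`
#' over `q` in \[0,1\] by bounded one-dimensional optimisation.
#'
#' The default supervised mode follows supervised ADMIXTURE semantics:
#' ancestry is fixed for the labelled reference individuals (both
#' donor-species populations at `q = 1`, allopatric recipient-species
#' samples at `q = 0`) while the two component allele frequencies are
#' re-estimated from all samples — labelled and query — by a deterministic
#' EM, initialised at the panel estimates with a pseudocount of 1 per
#' allele class (which keeps likelihoods finite at fixed sites). Letting
#' the query individuals contribute to the recipient component's
#' frequencies is essential: windows under strong local drift or selection
#' in the query population would otherwise inflate `q` purely because the
#' query no longer matches the allopatric panel, defeating the
#' low-introgression criterion exactly where it matters.
#'
#' `fixed_panel` mode instead fixes the component frequencies at the
#' allopatric panels' estimates (same pseudocount) and only optimises each
#' individual's `q`. The two modes trade assumptions: with free component
#' frequencies the window likelihood carries an exact reparameterisation
#' ridge — a uniform shift of every query's `q` can be absorbed into the
#' recipient component — so estimates lean on the labelled samples and
#' shrink towards zero by roughly the smallest true `q`; with fixed
#' frequencies the estimate is unbiased exactly when the allopatric panels
#' coincide with the ancestral components, but any window-specific drift
#' of the query population away from its allopatric panel is misread as
#' donor ancestry. The scan uses `supervised` because its low-introgression
#' gate must not fire spuriously in windows under strong local drift or
#' selection — which are precisely the windows the scan is looking for.
#'
#' Unsupervised mode runs a K = 2 EM block relaxation on all samples
#' jointly with no fixed labels and resolves label switching by assigning
#' the "mulatta" label to the component with the larger mean `q` among
#' allopatric donor-species samples.
#'
#' Windows with no ancestry-informative variant sites (component
#' frequencies identical everywhere) return `NA` for every individual.
#'
#' @param g A [genotype_matrix()].
#' @param popmap Popmap tibble.
#' @param windows Window tibble (0-based half-open).
#' @param mode `"supervised"` (default) or `"unsupervised"`.
#' @param query Population label(s) whose individuals are estimated;
#'   defaults to the introgression recipient `PARA_FAS`.
#' @param em_iter,em_tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param seed Seed for the unsupervised EM initialisation (the supervised
#'   EM is deterministic).
#' @param keep_freqs Keep the per-window component allele frequencies in
#'   the returned object (`component_freqs`).
#' @return List of class `ancestry_estimate`: `q` (tibble window x
#'   sample_id x q) and `windows` (per-window `mean_para_fas_q`, the mean
#'   over recipient-population individuals with defined estimates);
#'   optionally `component_freqs`.
#' @export
estimate_window_ancestry <- function(g, popmap, windows,
                                     mode = c("supervised", "fixed_panel",
                                              "unsupervised"),
                                     query = "PARA_FAS",
                                     em_iter = 200L, em_tol = 1e-6,
                                     seed = 1L, keep_freqs = FALSE) {
  mode <- match.arg(mode)
  popmap <- validate_popmap(popmap)
  win <- assign_positions(g$pos, windows)
  variant <- g$is_variant
  q_rows <- list()
  freqs_out <- if (keep_freqs) vector("list", nrow(windows)) else NULL
  query_idx <- which(g$sample_ids %in%
                       popmap$sample_id[popmap$population %in% query])
  if (!length(query_idx)) abort("no query individuals found in popmap")

  if (mode %in% c("supervised", "fixed_panel")) {
    am <- pop_samples(g, popmap, "ALLO_MUL")
    af <- pop_samples(g, popmap, "ALLO_FAS")
    pm_don <- pop_samples(g, popmap, "PARA_MUL")
    if (length(am) < 2L || length(af) < 2L) {
      abort("supervised mode needs >= 2 samples in each allopatric panel")
    }
    donor_idx <- setdiff(union(am, pm_don), query_idx)
    recip_idx <- setdiff(af, query_idx)
    for (w in seq_len(nrow(windows))) {
      s <- which(win == w & variant)
      if (!length(s)) {
        for (i in query_idx) {
          q_rows[[length(q_rows) + 1L]] <-
            tibble(window = w, sample_id = g$sample_ids[i], q = NA_real_)
        }
        next
      }
      block <- g$dosage[s, , drop = FALSE]
      fit <- if (mode == "supervised") {
        supervised_em(block, donor_idx, recip_idx, query_idx,
                      em_iter, em_tol)
      } else {
        fixed_panel_fit(block, am, af, query_idx)
      }
      informative <- max(abs(fit$p1 - fit$p2)) > 1e-12
      if (keep_freqs) {
        freqs_out[[w]] <- tibble(window = w, pos = g$pos[s],
                                 p_donor = fit$p1, p_recipient = fit$p2)
      }
      for (k in seq_along(query_idx)) {
        i <- query_idx[k]
        qhat <- if (!informative) NA_real_ else fit$q[k]
        q_rows[[length(q_rows) + 1L]] <-
          tibble(window = w, sample_id = g$sample_ids[i], q = qhat)
      }
    }
  } else {
    set.seed(seed)
    am <- pop_samples(g, popmap, "ALLO_MUL")
    for (w in seq_len(nrow(windows))) {
      s <- which(win == w & variant)
      if (!length(s)) {
        for (i in query_idx) {
          q_rows[[length(q_rows) + 1L]] <-
            tibble(window = w, sample_id = g$sample_ids[i], q = NA_real_)
        }
        next
      }
      em <- admixture_em(g$dosage[s, , drop = FALSE], em_iter, em_tol)
      qv <- em$q
      # label switching: "mulatta" = component 1 favoured by ALLO_MUL
      if (length(am) && mean(qv[am]) < 0.5) qv <- 1 - qv
      for (i in query_idx) {
        q_rows[[length(q_rows) + 1L]] <-
          tibble(window = w, sample_id = g$sample_ids[i], q = qv[i])
      }
    }
  }

  q_tbl <- bind_rows(q_rows)
  para_ids <- popmap$sample_id[popmap$population == "PARA_FAS"]
  win_tbl <- q_tbl |>
    filter(.data$sample_id %in% para_ids) |>
    group_by(.data$window) |>
    summarise(
      mean_para_fas_q = if (all(is.na(.data$q))) NA_real_
                        else mean(.data$q, na.rm = TRUE),
      n_defined = sum(!is.na(.data$q)), .groups = "drop"
    )
  if (any(win_tbl$n_defined > 0 &
          win_tbl$n_defined < length(para_ids))) {
    warn("some windows have undefined ancestry for a subset of individuals; means use the defined subset")
  }
  win_tbl <- bind_cols(windows[win_tbl$window, c("chrom", "start", "end")],
                       win_tbl)
  structure(list(q = q_tbl, windows = win_tbl, mode = mode,
                 component_freqs = if (keep_freqs) bind_rows(freqs_out)),
            class = "ancestry_estimate")
}

# fixed-panel estimator: component frequencies taken from the
# allopatric panels (pseudocount 1 per allele class), q by bounded 1-D ML
fixed_panel_fit <- function(d, donor_idx, recip_idx, query_idx) {
  pf <- function(idx) {
    dd <- d[, idx, drop = FALSE]
    (rowSums(dd, na.rm = TRUE) + 1) / (2 * rowSums(!is.na(dd)) + 2)
  }
  p1 <- pf(donor_idx)
  p2 <- pf(recip_idx)
  q <- vapply(query_idx, function(i) fit_q(d[, i], p1, p2), numeric(1))
  list(q = q, p1 = p1, p2 = p2)
}

# supervised ADMIXTURE-style EM on one window block: ancestry fixed for
# labelled individuals (donor pops q=1, allopatric recipients q=0);
# component frequencies re-estimated from all samples; deterministic.
supervised_em <- function(d, donor_idx, recip_idx, query_idx,
                          max_iter, tol) {
  panel_counts <- function(idx) {
    dd <- d[, idx, drop = FALSE]
    list(alt = rowSums(dd, na.rm = TRUE),
         called = 2 * rowSums(!is.na(dd)))
  }
  don <- panel_counts(donor_idx)
  rec <- panel_counts(recip_idx)
  p1 <- (don$alt + 1) / (don$called + 2) # pseudocount per allele class
  p2 <- (rec$alt + 1) / (rec$called + 2)
  dq <- d[, query_idx, drop = FALSE]
  obs <- !is.na(dq)
  gz <- dq
  gz[!obs] <- 0
  nq <- length(query_idx)
  q <- rep(0.5, nq)
  for (iter in seq_len(max_iter)) {
    m <- outer(p1, q) + outer(p2, 1 - q)
    m <- pmin(pmax(m, 1e-12), 1 - 1e-12)
    r_alt <- outer(p1, q) / m
    r_ref <- outer(1 - p1, q) / (1 - m)
    a1 <- gz * r_alt          # expected donor-component alt copies
    r1 <- (2 - gz) * r_ref    # expected donor-component ref copies
    a1[!obs] <- 0; r1[!obs] <- 0
    a2 <- gz - a1; r2 <- (2 - gz) - r1
    a2[!obs] <- 0; r2[!obs] <- 0
    q_new <- colSums(a1 + r1) / pmax(2 * colSums(obs), 1)
    p1 <- (don$alt + rowSums(a1) + 1) /
      (don$called + rowSums(a1 + r1) + 2)
    p2 <- (rec$alt + rowSums(a2) + 1) /
      (rec$called + rowSums(a2 + r2) + 2)
    delta <- max(abs(q_new - q))
    q <- pmin(pmax(q_new, 1e-9), 1 - 1e-9)
    if (delta < tol) break
  }
  # final per-individual bounded maximisation at the converged frequencies
  q_final <- vapply(seq_len(nq), function(k) fit_q(dq[, k], p1, p2),
                    numeric(1))
  list(q = q_final, p1 = p1, p2 = p2)
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat("<ancestry_estimate> mode=", x$mode, ", ", nrow(x$windows),
      " windows, ", length(unique(x$q$sample_id)), " individuals\n",
      sep = "")
  invisible(x)
}

# maximum-likelihood q for one individual: dosages g (0..2, NA allowed)
# against fixed component frequencies pM, pF
fit_q <- function(gdos, p_m, p_f) {
  ok <- !is.na(gdos)
  if (!any(ok)) return(NA_real_)
  gdos <- gdos[ok]; p_m <- p_m[ok]; p_f <- p_f[ok]
  ll <- function(q) {
    m <- q * p_m + (1 - q) * p_f
    m <- pmin(pmax(m, 1e-12), 1 - 1e-12)
    sum(gdos * log(m) + (2 - gdos) * log(1 - m))
  }
  opt <- optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-9)
  cand <- c(0, opt$maximum, 1)
  cand[which.max(vapply(cand, ll, numeric(1)))]
}

# unsupervised K=2 EM on a sites x samples dosage block (complete or NA)
admixture_em <- function(d, max_iter, tol) {
  ns <- ncol(d)
  q <- runif(ns, 0.2, 0.8)
  p1 <- pmin(pmax(rowMeans(d, na.rm = TRUE) / 2 +
                    runif(nrow(d), -0.1, 0.1), 1e-3), 1 - 1e-3)
  p2 <- pmin(pmax(rowMeans(d, na.rm = TRUE) / 2 +
                    runif(nrow(d), -0.1, 0.1), 1e-3), 1 - 1e-3)
  obs <- !is.na(d)
  dz <- d; dz[!obs] <- 0
  last <- -Inf
  for (iter in seq_len(max_iter)) {
    m <- outer(p1, q) + outer(p2, 1 - q) # sites x samples mean alt freq
    m <- pmin(pmax(m, 1e-12), 1 - 1e-12)
    # responsibilities for alt and ref allele copies
    r_alt <- outer(p1, q) / m
    r_ref <- outer(1 - p1, q) / (1 - m)
    ll <- sum((dz * log(m) + (2 - dz) * log(1 - m))[obs])
    a1 <- dz * r_alt          # expected alt copies from component 1
    r1 <- (2 - dz) * r_ref    # expected ref copies from component 1
    a1[!obs] <- 0; r1[!obs] <- 0
    n_called <- 2 * colSums(obs)
    q <- pmin(pmax(colSums(a1 + r1) / pmax(n_called, 1), 1e-9), 1 - 1e-9)
    p1 <- pmin(pmax(rowSums(a1) / pmax(rowSums(a1 + r1), 1e-12),
                    1e-6), 1 - 1e-6)
    a2 <- dz * (1 - r_alt); r2 <- (2 - dz) * (1 - r_ref)
    a2[!obs] <- 0; r2[!obs] <- 0
    p2 <- pmin(pmax(rowSums(a2) / pmax(rowSums(a2 + r2), 1e-12),
                    1e-6), 1 - 1e-6)
    if (is.finite(ll) && abs(ll - last) < tol) break
    last <- ll
  }
  list(q = q, p1 = p1, p2 = p2, loglik = ll)
}

#' Mean recipient-population ancestry per window
#'
#' Arithmetic mean of the donor-component proportion over parapatric
#' recipient-species individuals, the quantity compared against the
#' introgression cutoff (default 2.5%) in candidate calling.
#'
#' @param est An `ancestry_estimate`.
#' @return Tibble of per-window `mean_para_fas_q`.
#' @export
mean_parapatric_ancestry <- function(est) {
  est$windows[, c("chrom", "start", "end", "mean_para_fas_q", "n_defined")]
}
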