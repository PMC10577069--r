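# Windowed Hudson F_ST, D_XY and Tajima's D against hand values and
# brute-force pairwise/site-loop oracles.

test_that("Hudson per-site components match the hand-evaluated formula", {
  # p1 = 0.75 (n1 = 4 alleles), p2 = 0.25 (n2 = 4)
  comp <- site_divergence_components(3, 4, 1, 4)
  expect_equal(comp$fst_num, 0.125, tolerance = 1e-12)
  expect_equal(comp$fst_den, 0.625, tolerance = 1e-12)

  # invariant site, both populations fixed reference
  inv <- site_divergence_components(0, 4, 0, 4)
  expect_equal(inv$fst_num, 0)
  expect_equal(inv$fst_den, 0)
  expect_equal(inv$dxy_site, 0)
  expect_true(inv$fst_ok && inv$dxy_ok)

  # fewer than 2 called alleles: F_ST correction undefined
  expect_false(site_divergence_components(1, 1, 1, 4)$fst_ok)
})

test_that("single-site window F_ST equals the 0.125/0.625 hand value", {
  # two diploids per population: dosages give p = 0.75 vs 0.25
  g <- make_geno(matrix(c(2L, 1L, 1L, 0L), nrow = 1))
  pm <- tibble::tibble(sample_id = g$sample_ids,
                       population = c("PARA_MUL", "PARA_MUL",
                                      "PARA_FAS", "PARA_FAS"))
  div <- window_divergence(g, pm, "PARA_MUL", "PARA_FAS", whole_window(g))
  expect_equal(div$fst, 0.2, tolerance = 1e-12)
})

test_that("F_ST is 1 for fixed opposite alleles and <= 0 for identical populations", {
  g <- make_geno(rbind(c(2L, 2L, 0L, 0L), c(2L, 2L, 0L, 0L)))
  pm <- tibble::tibble(sample_id = g$sample_ids,
                       population = rep(c("ALLO_MUL", "ALLO_FAS"),
                                        each = 2))
  div <- window_divergence(g, pm, "ALLO_MUL", "ALLO_FAS", whole_window(g))
  expect_equal(div$fst, 1, tolerance = 1e-12)

  # the same individuals duplicated into both populations
  g2 <- make_geno(rbind(c(1L, 2L, 1L, 2L), c(0L, 1L, 0L, 1L)))
  div2 <- window_divergence(g2, pm, "ALLO_MUL", "ALLO_FAS",
                            whole_window(g2))
  expect_lte(div2$fst, 0)
})

test_that("D_XY counts invariant sites in the denominator and F_ST ignores them", {
  # 1 fixed-difference site + 9 invariant sites -> dxy = 0.1
  dos <- rbind(c(2L, 2L, 0L, 0L),
               matrix(0L, nrow = 9, ncol = 4))
  g <- make_geno(dos, is_variant = c(TRUE, rep(FALSE, 9)))
  pm <- tibble::tibble(sample_id = g$sample_ids,
                       population = rep(c("PARA_MUL", "PARA_FAS"),
                                        each = 2))
  div <- window_divergence(g, pm, "PARA_MUL", "PARA_FAS", whole_window(g))
  expect_equal(div$dxy, 0.1, tolerance = 1e-12)
  expect_equal(div$n_comparable, 10)

  # dropping the invariant sites changes dxy but not fst
  g1 <- make_geno(dos[1, , drop = FALSE])
  div1 <- window_divergence(g1, pm, "PARA_MUL", "PARA_FAS",
                            whole_window(g1))
  expect_equal(div1$fst, div$fst)
  expect_equal(div1$dxy, 1)

  # single site with p1 = p2 = 0.5 -> dxy = 0.5
  g3 <- make_geno(matrix(c(1L, 1L, 1L, 1L), nrow = 1))
  div3 <- window_divergence(g3, pm, "PARA_MUL", "PARA_FAS",
                            whole_window(g3))
  expect_equal(div3$dxy, 0.5, tolerance = 1e-12)
})

test_that("empty or undefined windows give NA, not zero", {
  g <- make_geno(matrix(0L, nrow = 2, ncol = 4),
                 is_variant = c(FALSE, FALSE))
  pm <- tibble::tibble(sample_id = g$sample_ids,
                       population = rep(c("PARA_MUL", "PARA_FAS"),
                                        each = 2))
  div <- window_divergence(g, pm, "PARA_MUL", "PARA_FAS", whole_window(g))
  expect_true(is.na(div$fst)) # summed denominator 0
  expect_equal(div$dxy, 0)    # comparable invariant sites exist

  # window with no sites at all
  far <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10100L)
  div2 <- window_divergence(g, pm, "PARA_MUL", "PARA_FAS", far)
  expect_true(is.na(div2$fst) && is.na(div2$dxy))
})

test_that("Tajima's D reproduces the hand-derived worked example", {
  # n = 4 haplotypes (2 diploids), 3 singleton sites:
  # pi = 1.5, theta_w = 18/11, D = -0.7544511 from the 1989 constants
  k <- tajima_constants(4)
  expect_equal(k$a1, 11 / 6, tolerance = 1e-14)
  expect_equal(k$b2, 46 / 108, tolerance = 1e-14)
  expect_equal(k$c1, 1 / 99, tolerance = 1e-14)

  g <- make_geno(matrix(c(1L, 0L, 1L, 0L, 1L, 0L), nrow = 3, byrow = TRUE))
  pm <- tibble::tibble(sample_id = g$sample_ids,
                       population = rep("PARA_FAS", 2))
  td <- window_tajima_d(g, pm, "PARA_FAS", whole_window(g))
  expect_equal(td$pi, 1.5, tolerance = 1e-12)
  expect_equal(td$theta_w, 18 / 11, tolerance = 1e-12)
  expect_equal(td$D, -0.7544511, tolerance = 1e-6)
})

test_that("Tajima's D is NA for monomorphic windows and positive for intermediate-frequency excess", {
  pm4 <- tibble::tibble(sample_id = sprintf("s%02d", 1:4),
                        population = rep("PARA_FAS", 4))
  mono <- make_geno(matrix(0L, nrow = 3, ncol = 4))
  expect_true(is.na(window_tajima_d(mono, pm4, "PARA_FAS",
                                    whole_window(mono))$D))

  # every site at frequency n/2 maximises pi relative to theta_w
  mid <- make_geno(matrix(1L, nrow = 6, ncol = 4))
  expect_gt(window_tajima_d(mid, pm4, "PARA_FAS", whole_window(mid))$D, 0)
})

test_that("windowed estimators equal brute-force oracles on random matrices", {
  set.seed(101)
  sizes <- c(2L, 2L, 2L, 2L)
  for (rep in 1:40) {
    ns <- sample(5:20, 1)
    dos <- matrix(sample(0:2, ns * 8, replace = TRUE), nrow = ns)
    dos[stats::runif(length(dos)) < 0.08] <- NA_integer_ # some missingness
    iv <- stats::runif(ns) < 0.8
    dos[!iv, ] <- 0L
    g <- make_geno(dos, is_variant = iv)
    pm <- make_popmap(g$sample_ids, sizes)
    win <- whole_window(g)

    div <- window_divergence(g, pm, "PARA_MUL", "PARA_FAS", win)
    expect_equal(div$fst, oracle_fst(dos, 3:4, 7:8), tolerance = 1e-12)
    expect_equal(div$dxy, oracle_dxy(dos, 3:4, 7:8), tolerance = 1e-12)

    td <- window_tajima_d(g, pm, "ALLO_FAS", win)
    expect_equal(td$D, oracle_tajima(dos, 5:6), tolerance = 1e-12)
  }
})

test_that("statistics are invariant to sample order", {
  set.seed(7)
  dos <- matrix(sample(0:2, 15 * 8, replace = TRUE), nrow = 15)
  g <- make_geno(dos)
  pm <- make_popmap(g$sample_ids, c(2L, 2L, 2L, 2L))
  win <- whole_window(g)
  shuffle <- sample(ncol(dos))
  g2 <- make_geno(dos[, shuffle])
  colnames(g2$dosage) <- g$sample_ids[shuffle]
  g2$sample_ids <- g$sample_ids[shuffle]

  for (pair in list(c("PARA_MUL", "PARA_FAS"), c("ALLO_MUL", "ALLO_FAS"))) {
    d1 <- window_divergence(g, pm, pair[1], pair[2], win)
    d2 <- window_divergence(g2, pm, pair[1], pair[2], win)
    expect_equal(d1$fst, d2$fst, tolerance = 1e-14)
    expect_equal(d1$dxy, d2$dxy, tolerance = 1e-14)
  }
  expect_equal(window_tajima_d(g, pm, "PARA_FAS", win)$D,
               window_tajima_d(g2, pm, "PARA_FAS", win)$D,
               tolerance = 1e-14)
})

test_that("D_XY against a duplicated copy of a population equals its plugin diversity", {
  set.seed(11)
  dos <- matrix(sample(0:2, 12 * 2, replace = TRUE), nrow = 12)
  dupl <- cbind(dos, dos) # same individuals twice
  g <- make_geno(dupl)
  pm <- tibble::tibble(sample_id = g$sample_ids,
                       population = rep(c("ALLO_FAS", "PARA_FAS"),
                                        each = 2))
  div <- window_divergence(g, pm, "ALLO_FAS", "PARA_FAS", whole_window(g))
  expect_equal(div$dxy, oracle_dxy(dupl, 1:2, 3:4), tolerance = 1e-12)
  # closed form: mean over sites of 2 p (1 - p)
  p <- rowSums(dos) / 4
  expect_equal(div$dxy, mean(2 * p * (1 - p)), tolerance = 1e-12)
})
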