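log2_fixture <- function(values) {
  expr_matrix(values, rownames(values)[1], "log2_normalized")
}

test_that("Pearson track matches the textbook formula to 1e-10", {
  esr <- setNames(c(10, 25, 40, 60, 81), paste0("S", 1:5))
  v <- rbind(
    HK = rep(0, 5),
    LIN = 2 * esr + 1,                       # exact linear function of ESR
    G1 = c(2, 1, 4, 3, 6),
    FLAT = rep(1.5, 5)
  )
  colnames(v) <- names(esr)
  res <- pearson_track(log2_fixture(v), esr)
  expect_equal(res$statistic[res$gene == "LIN"], 1.0, tolerance = 1e-12)
  # frozen hand evaluation on x = 1..5 (ESR is a linear transform of rank here? no:
  # use the classic fixture directly)
  x5 <- setNames(c(1, 2, 3, 4, 5), paste0("S", 1:5))
  res2 <- pearson_track(log2_fixture(v), x5)
  expect_equal(res2$statistic[res2$gene == "G1"], 10 / sqrt(148), tolerance = 1e-10)
  expect_equal(res2$statistic[res2$gene == "G1"], 0.8219949, tolerance = 1e-6)
  # constant gene flagged undefined, not dropped
  expect_true(is.na(res$statistic[res$gene == "FLAT"]))
  expect_match(res$note[res$gene == "FLAT"], "undefined")
  # constant covariate errors
  expect_error(pearson_track(log2_fixture(v), setNames(rep(3, 5), names(esr))),
               "constant")

  set.seed(10)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  cov <- setNames(rnorm(10), colnames(X))
  res3 <- pearson_track(log2_fixture(X), cov)
  for (i in seq_len(20)) {
    r_o <- oracle_pearson(X[i, ], cov)
    expect_equal(res3$statistic[i], r_o, tolerance = 1e-10)
    expect_equal(res3$p_value[i], oracle_pearson_p(r_o, 10), tolerance = 1e-10)
  }
})

test_that("t-test track matches the pooled-variance oracle to 1e-10", {
  v <- rbind(HK = rep(0, 6), G1 = c(1, 2, 3, 4, 5, 6), SAME = rep(c(1, 2, 3), 2))
  colnames(v) <- paste0("S", 1:6)
  x <- log2_fixture(v)
  res <- ttest_track(x, group_high = paste0("S", 1:3), group_low = paste0("S", 4:6))
  expect_equal(res$statistic[res$gene == "G1"], -3.674235, tolerance = 1e-6)
  expect_equal(res$p_value[res$gene == "G1"], 0.02131164, tolerance = 1e-6)
  expect_equal(res$direction[res$gene == "G1"], "lower")
  # identical groups: t = 0, p = 1
  expect_equal(res$statistic[res$gene == "SAME"], 0)
  expect_equal(res$p_value[res$gene == "SAME"], 1)
  # group of size 1 errors
  expect_error(ttest_track(x, "S1", paste0("S", 2:6)), ">= 2 samples")
  # zero pooled variance with unequal means flagged undefined
  v2 <- rbind(HK = rep(0, 4), CONST = c(1, 1, 2, 2))
  colnames(v2) <- paste0("S", 1:4)
  res2 <- ttest_track(log2_fixture(v2), paste0("S", 1:2), paste0("S", 3:4))
  expect_true(is.na(res2$statistic[res2$gene == "CONST"]))
  expect_match(res2$note[res2$gene == "CONST"], "zero pooled variance")

  set.seed(20)
  X <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("G", 1:30), paste0("S", 1:10)))
  res3 <- ttest_track(log2_fixture(X), paste0("S", 1:4), paste0("S", 5:10))
  for (i in seq_len(30)) {
    o <- oracle_student_t(X[i, 1:4], X[i, 5:10])
    expect_equal(res3$statistic[i], o$t, tolerance = 1e-10)
    expect_equal(res3$p_value[i], o$p, tolerance = 1e-10)
  }
})

test_that("permutation null is deterministic and matches exhaustive enumeration", {
  set.seed(30)
  X <- matrix(rnorm(50), 10, 5,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:5)))
  x <- log2_fixture(X)
  cov <- setNames(c(2, 5, 1, 9, 4), colnames(X))
  n1 <- build_null(x, covariate = cov, n_permutations = 50, seed = 99)
  n2 <- build_null(x, covariate = cov, n_permutations = 50, seed = 99)
  expect_identical(n1$stats, n2$stats)
  expect_equal(dim(n1$stats), c(10L, 50L))
  expect_error(build_null(x, covariate = cov, n_permutations = 0), "n_permutations")

  # exhaustive oracle at n = 5: all 120 covariate orderings
  perms <- all_perms(5L)
  for (g in c(1L, 7L)) {
    exact <- mean(abs(apply(perms, 1L, function(p) oracle_pearson(X[g, ], cov[p]))))
    big <- build_null(x, covariate = cov, n_permutations = 3000, seed = 5)
    expect_lt(abs(mean(abs(big$stats[g, ])) - exact), 0.03)
  }
})

test_that("gFDR curve reproduces the direct exceedance count", {
  obs <- c(0.9, 0.5, 0.1)
  null <- matrix(c(0.2, 0.4, 0.6, 0.1, 0.3, 0.5), ncol = 2)
  curve <- gfdr_curve(obs, null)
  expect_equal(curve$gfdr[curve$threshold == 0.5], 0.5)
  expect_equal(curve$gfdr[curve$threshold == 0.9], 0)   # empty null exceedance
  expect_equal(curve$gfdr[curve$threshold == 0.1], 1.0)
  # monotone non-increasing when observed counts are fixed along thresholds
  expect_true(all(diff(curve$mean_n_null) <= 0))
})

test_that("local FDR is calibrated on null data and separates planted effects", {
  # observed drawn from the null itself
  set.seed(7)
  n_genes <- 2000
  obs <- rnorm(n_genes, 0, 0.15)
  null <- matrix(rnorm(n_genes * 100, 0, 0.15), n_genes, 100)
  fit <- local_fdr(obs, null)
  expect_gte(median(fit$lfdr), 0.9)
  expect_lt(mean(fit$lfdr < 0.05), 0.05)
  expect_true(all(fit$lfdr >= 0 & fit$lfdr <= 1))

  # two-component mixture: 10% strong effects
  planted <- c(rnorm(200, 0.7, 0.05), rnorm(1800, 0, 0.15))
  fit2 <- local_fdr(planted, null)
  expect_lt(mean(fit2$lfdr[1:200]), mean(fit2$lfdr[201:2000]))

  expect_error(local_fdr(obs, matrix(rnorm(30), 30, 1)), ">= 50 pooled null")
  expect_error(local_fdr(rep(1, 100), matrix(1, 100, 2)), "degenerate")
})

test_that("track combination uses union semantics with provenance", {
  mk <- function(genes, sel, dir) {
    data.frame(gene = genes, track = "x", statistic = 1, p_value = 0.01,
               direction = dir, note = "", lfdr = ifelse(sel, 0.01, 0.5),
               selected = sel, stringsAsFactors = FALSE)
  }
  p <- mk(c("A", "B", "C"), c(TRUE, TRUE, FALSE), c("higher", "higher", "lower"))
  t <- mk(c("A", "B", "C"), c(FALSE, TRUE, TRUE), c("higher", "lower", "lower"))
  comb <- combine_tracks(p, t, "ESR")
  expect_setequal(comb$gene, c("A", "B", "C"))
  expect_equal(comb$selected_by[comb$gene == "B"], "pearson+ttest")
  expect_equal(comb$selected_by[comb$gene == "A"], "pearson")
  expect_true(comb$direction_conflict[comb$gene == "B"])
  expect_false(comb$direction_conflict[comb$gene == "A"])
  # inclusion-exclusion on the union size
  expect_equal(nrow(comb), 2 + 2 - 1)
  # both tracks empty -> empty combined list (the POLY joint-count outcome shape)
  empty <- combine_tracks(mk("A", FALSE, "higher"), mk("A", FALSE, "higher"))
  expect_equal(nrow(empty), 0L)
})

test_that("statistics are invariant to sample column order", {
  co <- generate_cohort(simulation_design(seed = 21))
  g <- sample_grouping(co$clinical)
  cfg <- run_config(rng_seed = 4, n_permutations_gene = 20)
  a1 <- associate(co$expression, co$clinical, g, "esr", "SJIA", cfg)
  # permute expression columns
  perm <- sample(colnames(co$expression$values))
  x2 <- subset_expr(co$expression, samples = perm)
  a2 <- associate(x2, co$clinical, g, "esr", "SJIA", cfg)
  expect_equal(a1$pearson$statistic, a2$pearson$statistic, tolerance = 1e-9)
  expect_equal(a1$ttest$statistic, a2$ttest$statistic, tolerance = 1e-9)
})
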