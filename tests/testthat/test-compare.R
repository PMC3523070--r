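profile_pair <- function(a, b, ids = paste0("P", seq_along(a))) {
  pathway_comparison(setNames(a, ids), setNames(b, ids))
}

test_that("profile correlation matches the hand-computed Pearson value", {
  expect_equal(profile_pair(c(1, 2, 3), c(1, 2, 3))$profile_correlation, 1.0)
  # frozen oracle value for the first three rows of the ESR/JC worked example
  cmp <- profile_pair(c(5.68, 1.27, 4.43), c(3.07, 3.73, 4.43))
  expect_equal(cmp$profile_correlation, -0.2586166, tolerance = 1e-6)
  expect_equal(cmp$profile_correlation,
               oracle_pearson(c(5.68, 1.27, 4.43), c(3.07, 3.73, 4.43)),
               tolerance = 1e-12)
  # disjoint single-hit profiles anticorrelate (hand value for n = 3: -1/2)
  cmp2 <- pathway_comparison(setNames(c(1, 0, 0), paste0("P", 1:3)),
                             setNames(c(0, 1, 0), paste0("P", 1:3)))
  expect_equal(cmp2$profile_correlation, -0.5)
  expect_error(profile_correlation(setNames(c(1, 1, 1), paste0("P", 1:3)),
                                   setNames(c(2, 2, 2), paste0("P", 1:3))),
               "constant")
})

test_that("pathways scored in one condition only are imputed zero in the other", {
  a <- setNames(c(3.74, 2.0, 1.0), c("Th", "X", "Y"))
  b <- setNames(c(0.51, 4.0), c("X", "Z"))
  cmp <- pathway_comparison(a, b)
  expect_setequal(cmp$pathway_ids, c("Th", "X", "Y", "Z"))
  i <- match("Th", cmp$pathway_ids)
  expect_equal(cmp$neglogp_b[i], 0)
  expect_equal(cmp$signed_diff[i], 3.74)
  j <- match("Z", cmp$pathway_ids)
  expect_equal(cmp$signed_diff[j], -4.0)
})

test_that("profile permutation null is deterministic and enumeration-exact", {
  a <- c(5.68, 1.27, 4.43)
  b <- c(3.07, 3.73, 4.43)
  cmp <- profile_pair(a, b)
  n1 <- simulate_null(cmp, 500, seed = 3)
  n2 <- simulate_null(cmp, 500, seed = 3)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(3L, 500L))
  expect_error(simulate_null(cmp, 0), "n_simulations")

  # per-pathway null = uniform over all |a_i - b_j| pairs; compare total
  # variation of the Monte-Carlo frequencies against the enumeration
  support <- round(abs(outer(a, b, "-")), 10)
  exact <- table(support) / length(support)
  for (p in 1:3) {
    mc <- table(factor(round(n1[p, ], 10), levels = names(exact))) / ncol(n1)
    tv <- sum(abs(mc - exact)) / 2
    expect_lt(tv, 0.1)
  }

  # constant profiles: every null difference equals the constant gap
  cmpc <- pathway_comparison(setNames(c(2, 2, 2), paste0("P", 1:3)),
                             setNames(c(0.5, 0.5, 0.5), paste0("P", 1:3)),
                             "A", "B")
  expect_true(all(simulate_null(cmpc, 20, 1) == 1.5))
})

test_that("percentile summaries use type-7 interpolation and order correctly", {
  cmp <- profile_pair(c(1, 2, 3), c(3, 2, 1))
  null <- matrix(rep(1:500, each = 3), nrow = 3)
  rownames(null) <- cmp$pathway_ids
  ps <- percentile_summaries(cmp, null, c(20, 50, 80))
  expect_equal(unname(ps$percentile_values[1, "p80"]), 400.2)
  expect_equal(unname(ps$percentile_values[1, "p50"]), 250.5)
  expect_true(all(ps$percentile_values[, "p20"] <= ps$percentile_values[, "p50"]))
  expect_true(all(ps$percentile_values[, "p50"] <= ps$percentile_values[, "p80"]))
  # identical null values collapse every percentile onto that value
  nullc <- matrix(7, 3, 10, dimnames = list(cmp$pathway_ids, NULL))
  psc <- percentile_summaries(cmp, nullc, c(20, 50, 80))
  expect_true(all(psc$percentile_values == 7))
  # observed + three percentile density curves come back
  expect_setequal(names(ps$curves), c("observed", "p20", "p50", "p80"))
})

test_that("differentiating report reproduces worked-example differences exactly", {
  t5 <- read.delim(system.file("extdata", "pathway_profiles_sjia_esr_vs_jc.tsv",
                               package = "jiaassoc"), check.names = FALSE)
  cmp <- pathway_comparison(setNames(t5$neglogp_sjia_esr, t5$pathway),
                            setNames(t5$neglogp_sjia_jc, t5$pathway),
                            "SJIA_ESR", "SJIA_JC")
  null <- simulate_null(cmp, 500, seed = 2)
  rep5 <- differentiating_report(cmp, null)
  # internally consistent printed rows reproduce exactly
  consistent <- abs(round(t5$neglogp_sjia_esr - t5$neglogp_sjia_jc, 2) -
                      t5$reported_difference) < 1e-9
  got <- rep5$signed_diff[match(t5$pathway, rep5$pathway)]
  expect_true(all(abs(round(got[consistent], 2) -
                        t5$reported_difference[consistent]) < 1e-9))
  expect_equal(got[t5$pathway == "Glucocorticoid receptor signaling"], 2.61)
  # shared zero-difference block is reported separately at the bottom
  n_shared <- sum(rep5$shared)
  expect_equal(n_shared, sum(t5$reported_difference == 0))
  expect_true(all(rep5$shared[seq(nrow(rep5) - n_shared + 1, nrow(rep5))]))

  t6 <- read.delim(system.file("extdata", "pathway_profiles_sjia_vs_poly_esr.tsv",
                               package = "jiaassoc"), check.names = FALSE)
  cmp6 <- pathway_comparison(setNames(t6$neglogp_sjia_esr, t6$pathway),
                             setNames(t6$neglogp_poly_esr, t6$pathway))
  rep6 <- differentiating_report(cmp6, simulate_null(cmp6, 500, seed = 2))
  il10 <- rep6$signed_diff[rep6$pathway == "IL-10 signaling"]
  expect_equal(il10, 4.34)
})

test_that("identical profiles yield no differentiating pathways", {
  a <- setNames(c(4.4, 2.2, 1.1, 0.5), paste0("P", 1:4))
  cmp <- pathway_comparison(a, a)
  expect_true(all(cmp$observed_absdiff == 0))
  null <- simulate_null(cmp, 500, seed = 8)
  rep <- differentiating_report(cmp, null)
  expect_false(any(rep$differentiating))
  repp <- differentiating_report(cmp, null, mode = "per_pathway")
  expect_false(any(repp$differentiating))
})

test_that("comparison results are invariant to pathway row order", {
  a <- setNames(c(5, 3, 1, 0.2), paste0("P", 1:4))
  b <- setNames(c(1, 2, 3, 4), paste0("P", 1:4))
  cmp1 <- pathway_comparison(a, b)
  perm <- c(3, 1, 4, 2)
  cmp2 <- pathway_comparison(a[perm], b[perm])
  expect_equal(cmp1$profile_correlation, cmp2$profile_correlation)
  ps1 <- percentile_summaries(cmp1, simulate_null(cmp1, 400, 9))
  ps2 <- percentile_summaries(cmp2, simulate_null(cmp2, 400, 9))
  # per-pathway percentiles are exchangeable across pathways under the null;
  # the pooled percentile distribution must agree closely
  expect_equal(sort(colMeans(ps1$percentile_values)),
               sort(colMeans(ps2$percentile_values)), tolerance = 0.15)
})
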