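test_that("default design reproduces the study cohort structure", {
  co <- generate_cohort(simulation_design(seed = 1))
  expect_equal(nrow(co$clinical), 71L)
  expect_equal(nrow(co$expression$values), 181L)
  expect_length(co$expression$housekeeping, 4L)
  expect_setequal(co$expression$housekeeping, c("EEF1A1", "PPP1CC", "RPL12", "RPL41"))
  grp <- table(co$clinical$disease, co$clinical$state)
  expect_equal(grp["SJIA", "F"], 22L, ignore_attr = TRUE)
  expect_equal(grp["SJIA", "Q"], 24L, ignore_attr = TRUE)
  expect_equal(grp["POLY", "F"], 17L, ignore_attr = TRUE)
  expect_equal(grp["POLY", "Q"], 8L, ignore_attr = TRUE)
  # truth covers every gene exactly once, aligned with the panel
  expect_identical(co$truth$gene, rownames(co$expression$values))
  expect_identical(colnames(co$expression$values), co$clinical$sample_id)
  expect_equal(sum(co$truth$mechanism == "low_variance"), 75L)
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(simulation_design(seed = 17))
  b <- generate_cohort(simulation_design(seed = 17))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  c2 <- generate_cohort(simulation_design(seed = 18))
  expect_false(identical(a$expression$values, c2$expression$values))
})

test_that("clinical covariates respect the per-group ranges and flare rules", {
  for (seed in 1:5) {
    co <- generate_cohort(simulation_design(seed = seed))
    cl <- co$clinical
    rng <- default_clinical_ranges()
    grp <- paste0(tolower(cl$disease), "_", tolower(cl$state))
    for (g in unique(grp)) {
      r <- rng[[if (g == "sjia_f") "sjia_f" else g]]
      esr <- cl$esr[grp == g]
      jc <- cl$joint_count[grp == g]
      expect_true(all(esr >= r$esr_range[1] & esr <= r$esr_range[2]))
      expect_true(median(esr) >= r$esr_range[1] && median(esr) <= r$esr_range[2])
      expect_true(all(jc >= r$jc_range[1] & jc <= r$jc_range[2]))
    }
    # flares all have >= 1 active joint, quiescent SJIA at most 1, POLY 0
    expect_true(all(cl$joint_count[cl$state == "F"] >= 1))
    expect_true(all(cl$joint_count[cl$state == "Q" & cl$disease == "SJIA"] <= 1))
    expect_true(all(cl$joint_count[cl$state == "Q" & cl$disease == "POLY"] == 0))
  }
})

test_that("derived states match generator truth on every sample", {
  for (seed in c(3, 9, 13, 27, 40)) {
    co <- generate_cohort(simulation_design(seed = seed))
    derived <- classify_state(co$clinical)
    expect_identical(derived$state_derived, co$clinical$state)
    expect_false(any(derived$state_discrepancy))
  }
})

test_that("low-variance genes stay within 2-fold of their mean in every replicate", {
  for (seed in 1:5) {
    co <- generate_cohort(simulation_design(seed = seed))
    lv <- co$truth$gene[co$truth$mechanism == "low_variance"]
    v <- co$expression$values[lv, , drop = FALSE]
    m <- rowMeans(v)
    expect_true(all(v >= m / 2 - 1e-12))
    expect_true(all(v <= 2 * m + 1e-12))
  }
})

test_that("planted linear genes hit the target correlation with ESR", {
  rs <- vapply(1:50, function(seed) {
    co <- generate_cohort(simulation_design(seed = seed, n_low_variance = 0,
                                            n_flare_shift = 0, n_jc_linear = 0))
    sjia <- co$clinical$sample_id[co$clinical$disease == "SJIA"]
    esr <- co$clinical$esr[match(sjia, co$clinical$sample_id)]
    planted <- co$truth$gene[co$truth$mechanism == "esr_linear"]
    X <- log2(co$expression$values[planted, sjia])
    mean(abs(apply(X, 1L, function(row) cor(row, esr))))
  }, 0)
  expect_lt(abs(mean(rs) - 0.6), 0.1)
})

test_that("flare-shift genes recover the designed log2 fold change at large n", {
  d <- simulation_design(n_sjia_f = 300, n_sjia_q = 300, seed = 8,
                         n_low_variance = 0, n_esr_linear = 0, n_jc_linear = 0,
                         n_flare_shift = 30, shift_log2fc = 1.0)
  co <- generate_cohort(d)
  cl <- co$clinical
  f2 <- cl$sample_id[cl$disease == "SJIA" & cl$state == "F" & cl$esr >= 20]
  rest <- setdiff(cl$sample_id[cl$disease == "SJIA"], f2)
  tr <- co$truth[co$truth$mechanism == "flare_shift", ]
  lfc <- log2(rowMeans(co$expression$values[tr$gene, f2])) -
    log2(rowMeans(co$expression$values[tr$gene, rest]))
  # signed estimate should recover the planted shift direction and size
  expect_lt(mean(abs(lfc * tr$sign - 1.0)), 0.35)
  expect_true(all(sign(lfc) == tr$sign))
})

test_that("infeasible designs and bad set requests error", {
  expect_error(simulation_design(n_genes = 50), "infeasible design")
  co <- generate_cohort(simulation_design(seed = 1))
  expect_error(generate_gene_sets(co, n_sets = 0), "n_sets")
  null_co <- generate_cohort(simulation_design(seed = 1, n_esr_linear = 0,
                                               n_flare_shift = 0, n_jc_linear = 0))
  expect_error(generate_gene_sets(null_co, n_sets = 5, enriched_fraction = 0.5),
               "no planted genes")
})

test_that("gene-set generation is deterministic and honours enriched_fraction", {
  co <- generate_cohort(simulation_design(seed = 5))
  a <- generate_gene_sets(co, n_sets = 10, enriched_fraction = 0.4, seed = 7)
  b <- generate_gene_sets(co, n_sets = 10, enriched_fraction = 0.4, seed = 7)
  expect_identical(a$sets, b$sets)
  expect_equal(sum(a$descriptions == "enriched"), 4L)
  all_null <- generate_gene_sets(co, n_sets = 6, enriched_fraction = 0, seed = 3)
  expect_true(all(all_null$descriptions == "background"))
})
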