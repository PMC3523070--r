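# Synthetic JIA kPCR cohort generator. Emulates the cohort structure the
# analysis assumes -- SJIA/POLY flare and quiescence groups with clinical
# covariates matching the published medians and ranges, a 181-gene panel
# with 4 housekeeping and 75 low-variation genes, and planted
# covariate-linear and flare-shift expression effects with known truth --
# so every downstream stage can be tested for parameter recovery without
# patient data.

#' Default per-group clinical ranges
#'
#' Medians and ranges per disease/state group: SJIA flare ESR 81 (11-121)
#' mm/h with 9 (1-28) active joints, SJIA quiescence ESR 5.5 (0-18) with
#' 0-1 joints, POLY flare ESR 31 (7-78) with 25 (3-62) joints, POLY
#' quiescence ESR 9 (2-15) with 0 joints.
#'
#' @return nested list keyed by group (`sjia_f`, `sjia_q`, `poly_f`,
#'   `poly_q`), each with `esr_median`, `esr_range`, `jc_median`, `jc_range`.
#' @export
default_clinical_ranges <- function() {
  list(
    sjia_f = list(esr_median = 81, esr_range = c(11, 121), jc_median = 9, jc_range = c(1, 28)),
    sjia_q = list(esr_median = 5.5, esr_range = c(0, 18), jc_median = 0, jc_range = c(0, 1)),
    poly_f = list(esr_median = 31, esr_range = c(7, 78), jc_median = 25, jc_range = c(3, 62)),
    poly_q = list(esr_median = 9, esr_range = c(2, 15), jc_median = 0, jc_range = c(0, 0))
  )
}

#' Simulation design for a synthetic cohort
#'
#' Defaults reproduce the study conditions: 22 SJIA flare, 24 SJIA
#' quiescence, 17 POLY flare and 8 POLY quiescence samples over a
#' 181-gene panel with 4 housekeeping genes and 75 low-variation genes.
#' Planted mechanisms: `n_esr_linear` genes correlated with ESR at
#' `esr_effect_r` (both diseases), `n_jc_linear` genes correlated with
#' joint count (SJIA only, emulating the published SJIA/POLY asymmetry),
#' and `n_flare_shift` genes shifted by `shift_log2fc` log2 units in
#' high-ESR (F2) SJIA flare samples. Remaining genes are null.
#'
#' @param n_sjia_f,n_sjia_q,n_poly_f,n_poly_q per-group sample counts.
#' @param n_genes panel size.
#' @param n_housekeeping number of reference genes (near-constant).
#' @param n_low_variance genes bounded within a 2-fold band of their mean.
#' @param n_esr_linear,n_flare_shift,n_jc_linear planted gene counts.
#' @param esr_effect_r target |Pearson r| of planted linear genes, in (0,1).
#' @param shift_log2fc log2 fold-change of flare-shift genes (F2 vs rest).
#' @param noise_sd_log2 per-gene log2 noise standard deviation.
#' @param esr_jc_copula_rho Gaussian-copula rank dependence between ESR and
#'   joint count within flare groups.
#' @param clinical_ranges per-group medians/ranges, see
#'   [default_clinical_ranges()].
#' @param seed integer seed.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n_sjia_f = 22L, n_sjia_q = 24L, n_poly_f = 17L,
                              n_poly_q = 8L, n_genes = 181L,
                              n_housekeeping = 4L, n_low_variance = 75L,
                              n_esr_linear = 40L, n_flare_shift = 20L,
                              n_jc_linear = 30L, esr_effect_r = 0.6,
                              shift_log2fc = 1.0, noise_sd_log2 = 1.0,
                              esr_jc_copula_rho = 0.5,
                              clinical_ranges = default_clinical_ranges(),
                              seed = 1L) {
  stopifnot(
    n_sjia_f >= 1, n_sjia_q >= 1, n_poly_f >= 1, n_poly_q >= 1,
    n_genes >= 1, n_housekeeping >= 1, n_low_variance >= 0,
    n_esr_linear >= 0, n_flare_shift >= 0, n_jc_linear >= 0,
    esr_effect_r > 0, esr_effect_r < 1, noise_sd_log2 > 0,
    esr_jc_copula_rho >= -1, esr_jc_copula_rho <= 1
  )
  planted <- n_housekeeping + n_low_variance + n_esr_linear + n_flare_shift + n_jc_linear
  if (planted > n_genes) {
    stop_with("infeasible design: %d mechanism genes exceed panel size %d",
              planted, n_genes)
  }
  for (g in c("sjia_f", "sjia_q", "poly_f", "poly_q")) {
    cr <- clinical_ranges[[g]]
    if (is.null(cr)) stop_with("clinical_ranges missing group '%s'", g)
    if (cr$esr_median < cr$esr_range[1] || cr$esr_median > cr$esr_range[2] ||
        cr$jc_median < cr$jc_range[1] || cr$jc_median > cr$jc_range[2]) {
      stop_with("clinical_ranges['%s']: median outside range", g)
    }
  }
  structure(as.list(environment())[c(
    "n_sjia_f", "n_sjia_q", "n_poly_f", "n_poly_q", "n_genes",
    "n_housekeeping", "n_low_variance", "n_esr_linear", "n_flare_shift",
    "n_jc_linear", "esr_effect_r", "shift_log2fc", "noise_sd_log2",
    "esr_jc_copula_rho", "clinical_ranges", "seed"
  )], class = "simulation_design")
}

# Median-matched scaled Beta draw on [lo, hi]: shape alpha fixed at 2, beta
# solved so the Beta median sits at the target; degenerate ranges collapse
# to the constant.
rbeta_median <- function(n, median, range, u = stats::runif(n)) {
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) return(rep(lo, n))
  m <- (median - lo) / (hi - lo)
  m <- min(max(m, 0.02), 0.98)
  a <- 2
  b <- max((a - 1 / 3) / m - a + 2 / 3, 0.05)
  lo + (hi - lo) * stats::qbeta(u, a, b)
}

housekeeping_gene_names <- c("EEF1A1", "PPP1CC", "RPL12", "RPL41")

#' Generate a synthetic cohort with known truth
#'
#' Draws clinical covariates per group from median-matched scaled Beta
#' distributions (ESR and joint count rank-coupled within flare groups by
#' a Gaussian copula), assigns systemic-feature tokens consistent with the
#' flare/quiescence scoring rules, and builds a housekeeping-normalized
#' expression matrix of baseline log2-normal genes plus planted effects.
#' Planted linear genes use covariate-orthogonalized noise, so their
#' within-disease sample correlation with the covariate equals the design
#' target exactly; flare-shift genes receive an additive log2 shift in
#' high-ESR flare (F2) samples. Low-variance genes are contracted until
#' every value lies within 2-fold of the gene's mean. Deterministic given
#' the design seed.
#'
#' @param design a [simulation_design()].
#' @return list of class `synthetic_cohort`: `clinical` (a `jia_clinical`),
#'   `expression` (an `expr_matrix`, normalized scale), `truth` (data frame
#'   gene/mechanism/sign), `design`.
#' @export
generate_cohort <- function(design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, generate_cohort_impl(design))
}

generate_cohort_impl <- function(design) {
  groups <- data.frame(
    group = c("sjia_f", "sjia_q", "poly_f", "poly_q"),
    disease = c("SJIA", "SJIA", "POLY", "POLY"),
    state = c("F", "Q", "F", "Q"),
    n = c(design$n_sjia_f, design$n_sjia_q, design$n_poly_f, design$n_poly_q),
    stringsAsFactors = FALSE
  )
  clin_list <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    cr <- design$clinical_ranges[[g$group]]
    n <- g$n
    if (g$state == "F") {
      z1 <- stats::rnorm(n)
      z2 <- design$esr_jc_copula_rho * z1 +
        sqrt(1 - design$esr_jc_copula_rho^2) * stats::rnorm(n)
      esr <- rbeta_median(n, cr$esr_median, cr$esr_range, u = stats::pnorm(z1))
      jc <- round(rbeta_median(n, cr$jc_median, cr$jc_range, u = stats::pnorm(z2)))
      jc <- pmax(jc, max(1, cr$jc_range[1])) # all flare samples have >= 1 active joint
    } else {
      esr <- rbeta_median(n, cr$esr_median, cr$esr_range)
      jc <- if (g$disease == "SJIA") stats::rbinom(n, 1L, 0.3) else rep(0L, n)
    }
    feats <- character(n)
    if (g$disease == "SJIA") {
      for (j in seq_len(n)) {
        f <- character()
        if (g$state == "F") {
          if (esr[j] > 90) f <- c(f, "esr_gt90")
          else if (esr[j] >= 40) f <- c(f, "esr_40_90")
          if (stats::runif(1) < 0.45) f <- c(f, "rash")
          if (stats::runif(1) < 0.30) f <- c(f, "fever_lt10d")
          if (stats::runif(1) < 0.15) f <- c(f, "fever_gt10d")
          if (stats::runif(1) < 0.35) f <- c(f, "plt_gt450k")
          if (stats::runif(1) < 0.10) f <- c(f, sample(c("pericarditis", "pleural_effusion", "MAS"), 1L))
          # keep the sample a flare under the scoring rules: single moderate
          # features (e.g. fever > 10 d alone) score 0, so check the score
          if (jc[j] < 5 && score_systemic(unique(f)) == 0L) f <- c(f, "rash")
        }
        feats[j] <- paste(sort(unique(f)), collapse = ";")
      }
    }
    rf <- if (g$disease == "POLY") sample(c("negative", "positive"), n, TRUE, c(2 / 3, 1 / 3)) else NA_character_
    data.frame(group = g$group, disease = g$disease, state = g$state,
               esr = esr, joint_count = jc, systemic_features = feats,
               rf_status = rf, stringsAsFactors = FALSE)
  })
  clin <- do.call(rbind, clin_list)
  clin$sample_id <- sprintf("S%03d", seq_len(nrow(clin)))
  clinical <- clinical_table(
    sample_id = clin$sample_id, patient_id = sprintf("P%03d", seq_len(nrow(clin))),
    disease = clin$disease, esr = clin$esr, joint_count = clin$joint_count,
    systemic_features = clin$systemic_features, rf_status = clin$rf_status,
    state = clin$state
  )

  # --- gene panel and mechanisms -------------------------------------------
  n_hk <- design$n_housekeeping
  hk_names <- if (n_hk <= length(housekeeping_gene_names)) {
    housekeeping_gene_names[seq_len(n_hk)]
  } else {
    c(housekeeping_gene_names, sprintf("HK%02d", seq_len(n_hk - length(housekeeping_gene_names))))
  }
  n_rest <- design$n_genes - n_hk
  gene_ids <- c(hk_names, sprintf("G%03d", seq_len(n_rest)))
  mech <- rep("null", design$n_genes)
  mech[seq_len(n_hk)] <- "housekeeping"
  idx <- n_hk
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  lv_idx <- take(design$n_low_variance)
  esr_idx <- take(design$n_esr_linear)
  shift_idx <- take(design$n_flare_shift)
  jc_idx <- take(design$n_jc_linear)
  mech[lv_idx] <- "low_variance"
  mech[esr_idx] <- "esr_linear"
  mech[shift_idx] <- "flare_shift"
  mech[jc_idx] <- "jc_linear"
  sign_vec <- integer(design$n_genes)
  planted <- c(esr_idx, shift_idx, jc_idx)
  sign_vec[planted] <- sample(c(-1L, 1L), length(planted), TRUE)

  n_samp <- nrow(clin)
  mu <- stats::runif(design$n_genes, -2, 6)
  log2v <- matrix(mu, design$n_genes, n_samp) +
    matrix(stats::rnorm(design$n_genes * n_samp, 0, design$noise_sd_log2),
           design$n_genes, n_samp)
  dimnames(log2v) <- list(gene_ids, clin$sample_id)

  # housekeeping: near-constant around log2 = 0
  log2v[seq_len(n_hk), ] <- matrix(stats::rnorm(n_hk * n_samp, 0, 0.05), n_hk, n_samp)

  # low-variance genes: contract noise until every linear value is within
  # 2-fold of the gene's linear mean
  for (g in lv_idx) {
    dev <- stats::rnorm(n_samp, 0, 0.3)
    repeat {
      lin <- 2^(mu[g] + dev)
      m <- mean(lin)
      if (all(lin >= m / 2) && all(lin <= 2 * m)) break
      dev <- dev * 0.8
    }
    log2v[g, ] <- mu[g] + dev
  }

  # planted linear effects: exact within-disease correlation with covariate
  plant_linear <- function(gi, covariate, block) {
    v <- covariate[block]
    if (stats::sd(v) == 0) return()
    z <- as.numeric(scale(v))
    r <- design$esr_effect_r
    for (g in gi) {
      e <- stats::rnorm(length(block))
      e <- stats::residuals(stats::lm(e ~ z))
      e <- as.numeric(scale(e))
      log2v[g, block] <<- mu[g] + design$noise_sd_log2 *
        sign_vec[g] * (r * z + sqrt(1 - r^2) * e)
    }
  }
  sjia_block <- which(clin$disease == "SJIA")
  poly_block <- which(clin$disease == "POLY")
  plant_linear(esr_idx, clin$esr, sjia_block)
  plant_linear(esr_idx, clin$esr, poly_block)
  plant_linear(jc_idx, clin$joint_count, sjia_block)

  # flare-shift genes: additive log2 shift in SJIA F2 samples
  f2 <- which(clin$disease == "SJIA" & clin$state == "F" & clin$esr >= 20)
  for (g in shift_idx) {
    log2v[g, f2] <- log2v[g, f2] + sign_vec[g] * design$shift_log2fc
  }

  expression <- expr_matrix(2^log2v, hk_names, "normalized")
  truth <- data.frame(gene = gene_ids, mechanism = mech, sign = sign_vec,
                      stringsAsFactors = FALSE)
  structure(list(clinical = clinical, expression = expression, truth = truth,
                 design = design),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d genes\n",
              nrow(x$clinical), nrow(x$expression$values)))
  print(table(mechanism = x$truth$mechanism))
  invisible(x)
}

#' Generate gene-set fixtures with known enrichment
#'
#' Builds a gene-set collection over a cohort's panel in which a fraction
#' of the sets preferentially sample planted (non-null mechanism) genes and
#' the remainder sample the panel uniformly; the truth is recorded in each
#' set's description (`enriched` / `background`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_sets number of sets (>= 1).
#' @param enriched_fraction fraction of sets drawn from planted genes.
#' @param set_size size of every set (default 10).
#' @param planted_weight fraction of an enriched set drawn from planted
#'   genes (default 1: all members planted).
#' @param seed integer seed.
#' @return a `gene_set_collection` with the panel as universe.
#' @export
generate_gene_sets <- function(cohort, n_sets, enriched_fraction = 0.3,
                               set_size = 10L, planted_weight = 1,
                               seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (n_sets < 1L) stop_with("n_sets must be >= 1")
  panel <- cohort$truth$gene
  planted <- cohort$truth$gene[cohort$truth$mechanism %in%
                                 c("esr_linear", "flare_shift", "jc_linear")]
  if (enriched_fraction > 0 && !length(planted)) {
    stop_with("cohort has no planted genes; cannot build enriched sets")
  }
  n_enriched <- round(n_sets * enriched_fraction)
  with_seed(seed, {
    sets <- list()
    desc <- character()
    for (i in seq_len(n_sets)) {
      if (i <= n_enriched) {
        k_p <- min(length(planted), max(1L, round(set_size * planted_weight)))
        members <- c(sample(planted, k_p),
                     sample(setdiff(panel, planted), set_size - k_p))
        desc[i] <- "enriched"
      } else {
        members <- sample(panel, min(set_size, length(panel)))
        desc[i] <- "background"
      }
      sets[[sprintf("SET%03d", i)]] <- members
    }
    gene_set_collection(sets, desc, universe = panel)
  })
}

#' Generate an SAF/AF subgroup scenario
#'
#' A focused SJIA-flare design for the subgroup correlation analysis:
#' `n_saf` systemic-plus-arthritis flare samples (systemic score >= 1) and
#' `n_af` arthritis-only flare samples (systemic score 0, joint count
#' >= 5), with `n_af_negative` genes planted to correlate negatively with
#' joint count within the AF subgroup at exactly `af_target_r`, and one
#' `IL10`-like gene planted to correlate positively with joint count
#' within SAF. All other genes are noise.
#'
#' @param n_saf,n_af subgroup sizes (AF needs >= 4).
#' @param n_genes panel size (4 housekeeping genes included).
#' @param n_af_negative number of planted AF-negative genes (default 12).
#' @param af_target_r magnitude of the planted AF correlation (default 0.7).
#' @param noise_sd_log2 baseline log2 noise sd.
#' @param seed integer seed.
#' @return a `synthetic_cohort` (truth mechanisms `af_negative`,
#'   `saf_positive`, `housekeeping`, `null`).
#' @export
generate_subgroup_scenario <- function(n_saf = 10L, n_af = 12L, n_genes = 181L,
                                       n_af_negative = 12L, af_target_r = 0.7,
                                       noise_sd_log2 = 1.0, seed = 1L) {
  stopifnot(n_af >= 4L, n_saf >= 4L, n_af_negative + 5L <= n_genes)
  with_seed(seed, {
    n <- n_saf + n_af
    subgroup <- c(rep("SAF", n_saf), rep("AF", n_af))
    jc <- pmax(1L, c(stats::rbinom(n_saf, 12, 0.5) + 1L,
                     stats::rbinom(n_af, 20, 0.5) + 5L))
    esr <- c(rbeta_median(n_saf, 81, c(40, 121)), rbeta_median(n_af, 25, c(11, 39)))
    feats <- ifelse(subgroup == "SAF", "rash", "")
    clinical <- clinical_table(
      sample_id = sprintf("S%03d", seq_len(n)), disease = "SJIA", esr = esr,
      joint_count = jc, systemic_features = feats, state = "F"
    )
    hk <- housekeeping_gene_names
    gene_ids <- c(hk, sprintf("G%03d", seq_len(n_genes - length(hk) - 1L)), "IL10")
    mech <- rep("null", n_genes)
    mech[seq_along(hk)] <- "housekeeping"
    af_idx <- length(hk) + seq_len(n_af_negative)
    mech[af_idx] <- "af_negative"
    mech[n_genes] <- "saf_positive"
    sign_vec <- integer(n_genes)
    sign_vec[af_idx] <- -1L
    sign_vec[n_genes] <- 1L
    mu <- stats::runif(n_genes, -2, 6)
    log2v <- matrix(mu, n_genes, n) +
      matrix(stats::rnorm(n_genes * n, 0, noise_sd_log2), n_genes, n)
    dimnames(log2v) <- list(gene_ids, clinical$sample_id)
    log2v[seq_along(hk), ] <- matrix(stats::rnorm(length(hk) * n, 0, 0.05),
                                     length(hk), n)
    plant_exact <- function(g, block, target_r) {
      z <- as.numeric(scale(jc[block]))
      e <- stats::rnorm(length(block))
      e <- as.numeric(scale(stats::residuals(stats::lm(e ~ z))))
      log2v[g, block] <<- mu[g] + noise_sd_log2 *
        (target_r * z + sqrt(1 - target_r^2) * e)
    }
    af_block <- which(subgroup == "AF")
    saf_block <- which(subgroup == "SAF")
    for (g in af_idx) plant_exact(g, af_block, -af_target_r)
    plant_exact(n_genes, saf_block, af_target_r)
    expression <- expr_matrix(2^log2v, hk, "normalized")
    truth <- data.frame(gene = gene_ids, mechanism = mech, sign = sign_vec,
                        stringsAsFactors = FALSE)
    structure(list(clinical = clinical, expression = expression, truth = truth,
                   design = list(n_saf = n_saf, n_af = n_af,
                                 af_target_r = af_target_r, seed = seed)),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression matrix, clinical table and truth table as TSVs
#' (the io formats of the pipeline) into a directory.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression(cohort$expression, paths[["expression"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (inherits(cohort$design, "simulation_design")) {
    paths <- c(paths, design = file.path(dir, "design.yaml"))
    d <- unclass(cohort$design)
    yaml::write_yaml(d, paths[["design"]])
  }
  invisible(paths)
}
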