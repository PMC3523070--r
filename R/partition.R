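# Clinical scoring rules and sample groupings.
#
# Severity scoring follows the published flare/quiescence scheme for JIA:
# a 0-3 systemic score for SJIA driven by feature tokens, and
# disease-specific arthritis scores (SJIA A-D, POLY 0-3) driven by the
# active joint count.

severe_features <- c("pneumonitis", "pericarditis", "pleural_effusion", "MAS")
moderate_features <- c("rash", "fever_gt10d", "wbc_gt20k", "esr_gt90",
                       "plt_gt550k", "ddimer_250_500", "elevated_fibrinogen")
mild_features <- c("rash", "fever_lt10d", "esr_40_90", "plt_gt450k")

#' Systemic severity score for an SJIA sample
#'
#' 3 if any severe feature (pneumonitis, pericarditis, pleural effusion,
#' MAS); else 2 if at least three moderate features (rash, fever > 10 d,
#' WBC > 20k, ESR > 90, platelets > 550k, d-dimer 250-500, elevated
#' fibrinogen); else 1 if any mild feature (rash, fever < 10 d, ESR 40-90,
#' platelets > 450k); else 0.
#'
#' @param features character vector of feature tokens, or a semicolon-joined
#'   string as stored in the clinical table.
#' @param disease disease label; must be `"SJIA"` (the score is not defined
#'   for POLY).
#' @return integer score 0-3.
#' @export
score_systemic <- function(features, disease = "SJIA") {
  if (!identical(disease, "SJIA")) {
    stop_with("systemic score is defined for SJIA records only (got '%s')", disease)
  }
  if (length(features) == 1L && (is.na(features) || grepl(";", features) || !features %in% systemic_feature_tokens)) {
    features <- parse_features(features)
  }
  unknown <- setdiff(features, systemic_feature_tokens)
  if (length(unknown)) {
    stop_with("unknown systemic feature token(s): %s", paste(unknown, collapse = ", "))
  }
  if (any(features %in% severe_features)) return(3L)
  if (sum(moderate_features %in% features) >= 3L) return(2L)
  if (any(features %in% mild_features)) return(1L)
  0L
}

#' Arthritis severity score
#'
#' SJIA: A (0 joints), B (1-4), C (5-10), D (> 10). POLY: 0 (0 joints),
#' 1 (1-10), 2 (11-20), 3 (> 20).
#'
#' @param joint_count non-negative integer active-joint count.
#' @param disease `"SJIA"` or `"POLY"`.
#' @return character score (`"A"`-`"D"` or `"0"`-`"3"`).
#' @export
score_arthritis <- function(joint_count, disease) {
  stopifnot(length(joint_count) == 1L)
  if (is.na(joint_count)) return(NA_character_)
  if (joint_count < 0 || joint_count != round(joint_count)) {
    stop_with("joint_count must be a non-negative integer")
  }
  if (identical(disease, "SJIA")) {
    if (joint_count == 0) "A" else if (joint_count < 5) "B" else if (joint_count <= 10) "C" else "D"
  } else if (identical(disease, "POLY")) {
    if (joint_count == 0) "0" else if (joint_count <= 10) "1" else if (joint_count <= 20) "2" else "3"
  } else {
    stop_with("unknown disease '%s'", disease)
  }
}

#' Classify samples as flare (F) or quiescence (Q)
#'
#' SJIA samples flare when the systemic score is >= 1 or (default rule)
#' the active joint count is >= 5; POLY samples flare when the arthritis
#' score is >= 1 (>= 1 active joint). A pre-assigned `state` column in the
#' clinical table overrides the derived state; any discrepancy is reported
#' with a warning and recorded in the output.
#'
#' @param clinical a `jia_clinical` data frame.
#' @param sjia_flare_rule `"jc5"` (joint count >= 5 qualifies an SJIA flare)
#'   or `"literal_b"` (>= 1 active joint qualifies).
#' @return data frame: sample_id, disease, systemic_score, arthritis_score,
#'   state_derived, state (effective), state_discrepancy.
#' @export
classify_state <- function(clinical, sjia_flare_rule = c("jc5", "literal_b")) {
  sjia_flare_rule <- match.arg(sjia_flare_rule)
  stopifnot(inherits(clinical, "jia_clinical"))
  jc_floor <- if (sjia_flare_rule == "jc5") 5 else 1
  n <- nrow(clinical)
  sys_score <- integer(n)
  arth <- character(n)
  derived <- character(n)
  for (i in seq_len(n)) {
    dis <- clinical$disease[i]
    jc <- clinical$joint_count[i]
    arth[i] <- score_arthritis(jc, dis)
    if (dis == "SJIA") {
      sys_score[i] <- score_systemic(parse_features(clinical$systemic_features[i]))
      derived[i] <- if (sys_score[i] >= 1L || (!is.na(jc) && jc >= jc_floor)) "F" else "Q"
    } else {
      sys_score[i] <- NA_integer_
      derived[i] <- if (!is.na(jc) && jc >= 1) "F" else "Q"
    }
  }
  state <- derived
  pre <- clinical$state
  has_pre <- !is.na(pre)
  state[has_pre] <- pre[has_pre]
  disagree <- has_pre & pre != derived
  if (any(disagree)) {
    warning(sprintf(
      "pre-assigned state overrides derived state for sample(s): %s",
      paste(clinical$sample_id[disagree], collapse = ", ")), call. = FALSE)
  }
  data.frame(sample_id = clinical$sample_id, disease = clinical$disease,
             systemic_score = sys_score, arthritis_score = arth,
             state_derived = derived, state = state,
             state_discrepancy = disagree, stringsAsFactors = FALSE)
}

#' Partition samples by ESR around the flare split point
#'
#' Flare samples with ESR below the cutoff (default 20 mm/h) form F1, flare
#' samples at or above it form F2, quiescent samples form Q. The matching
#' two-group comparison downstream is F2 versus F1 together with Q, since
#' low-ESR flares and quiescent samples were indistinguishable on this
#' panel. Flare samples missing ESR are excluded with a warning (label NA).
#'
#' @param clinical a `jia_clinical` data frame.
#' @param state per-sample `"F"`/`"Q"` vector aligned with `clinical`.
#' @param cutoff ESR cutoff, mm/h.
#' @return character vector of `"F1"`, `"F2"`, `"Q"` (or `NA`), named by
#'   sample id.
#' @export
partition_by_esr <- function(clinical, state, cutoff = 20) {
  stopifnot(nrow(clinical) == length(state))
  out <- ifelse(state == "Q", "Q",
                ifelse(is.na(clinical$esr), NA_character_,
                       ifelse(clinical$esr < cutoff, "F1", "F2")))
  if (anyNA(out)) {
    warning(sprintf("flare sample(s) missing ESR excluded from partition: %s",
                    paste(clinical$sample_id[is.na(out)], collapse = ", ")),
            call. = FALSE)
  }
  stats::setNames(out, clinical$sample_id)
}

#' Split SJIA flare samples into SAF and AF subgroups
#'
#' SAF (systemic plus arthritis flare) = flare with systemic score >= 1 and
#' >= 1 active joint; AF (arthritis-only flare) = flare with systemic score
#' 0 and >= 1 active joint. All other samples (quiescent, POLY, or no
#' active joints) are `not_applicable`.
#'
#' @param clinical a `jia_clinical` data frame.
#' @param state per-sample `"F"`/`"Q"` vector.
#' @param systemic_score per-sample integer systemic score (NA for POLY).
#' @return character vector (`"SAF"`, `"AF"`, `"not_applicable"`), named by
#'   sample id.
#' @export
partition_saf_af <- function(clinical, state, systemic_score) {
  stopifnot(nrow(clinical) == length(state), nrow(clinical) == length(systemic_score))
  jc <- clinical$joint_count
  eligible <- clinical$disease == "SJIA" & state == "F" & !is.na(jc) & jc >= 1 &
    !is.na(systemic_score)
  out <- rep("not_applicable", nrow(clinical))
  out[eligible & systemic_score >= 1L] <- "SAF"
  out[eligible & systemic_score == 0L] <- "AF"
  stats::setNames(out, clinical$sample_id)
}

#' Derive every sample grouping used by the pipeline
#'
#' Applies the scoring rules, flare/quiescence classification, ESR
#' partition and SAF/AF subgrouping in one pass.
#'
#' @param clinical a `jia_clinical` data frame.
#' @param config a [run_config()].
#' @return data frame of class `sample_grouping`: sample_id, disease,
#'   systemic_score, arthritis_score, state, esr_partition, saf_af.
#' @export
sample_grouping <- function(clinical, config = run_config()) {
  cs <- classify_state(clinical, config$sjia_flare_rule)
  esr_part <- partition_by_esr(clinical, cs$state, config$esr_partition_cutoff)
  saf <- partition_saf_af(clinical, cs$state, cs$systemic_score)
  out <- data.frame(
    sample_id = cs$sample_id, disease = cs$disease,
    systemic_score = cs$systemic_score, arthritis_score = cs$arthritis_score,
    state = cs$state, esr_partition = unname(esr_part),
    saf_af = unname(saf), stringsAsFactors = FALSE
  )
  class(out) <- c("sample_grouping", "data.frame")
  out
}

#' Read / write a sample grouping table
#'
#' @param grouping a `sample_grouping` data frame.
#' @param path TSV path.
#' @return `write_grouping()` returns `path` invisibly; `read_grouping()`
#'   returns a `sample_grouping` data frame.
#' @export
write_grouping <- function(grouping, path) {
  utils::write.table(as.data.frame(grouping), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grouping
#' @export
read_grouping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "disease", "systemic_score", "arthritis_score",
            "state", "esr_partition", "saf_af")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_with("grouping table missing column(s): %s",
                              paste(miss, collapse = ", "))
  df$arthritis_score <- as.character(df$arthritis_score)
  class(df) <- c("sample_grouping", "data.frame")
  df
}
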