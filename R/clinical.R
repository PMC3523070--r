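#' Systemic-feature vocabulary
#'
#' Pre-judged boolean tokens used by the systemic severity score. Tokens mix
#' clinical findings (rash, fever duration bins, serositis, MAS) with
#' lab-threshold indicators (ESR and platelet bins, WBC, d-dimer,
#' fibrinogen); the pipeline scores these tokens, it does not derive them
#' from raw labs.
#'
#' @format character vector of valid tokens.
#' @export
systemic_feature_tokens <- c(
  "rash", "fever_lt10d", "fever_gt10d", "esr_40_90", "esr_gt90",
  "plt_gt450k", "plt_gt550k", "wbc_gt20k", "ddimer_250_500",
  "elevated_fibrinogen", "pneumonitis", "pericarditis",
  "pleural_effusion", "MAS"
)

#' Build a validated clinical metadata table
#'
#' One row per sample. `systemic_features` is a per-sample semicolon-joined
#' string of tokens from [systemic_feature_tokens]. Optional fields
#' (`rf_status`, `state`, `prednisone_dose`) may be `NA`.
#'
#' @param sample_id,patient_id character identifiers.
#' @param disease `"SJIA"` or `"POLY"`.
#' @param esr non-negative erythrocyte sedimentation rate, mm/h (`NA` allowed).
#' @param joint_count non-negative integer active-joint count (`NA` allowed).
#' @param systemic_features character, semicolon-joined feature tokens
#'   (empty string = none).
#' @param rf_status optional `"positive"`, `"negative"`, `"unknown"` or `NA`.
#' @param state optional pre-assigned `"F"`/`"Q"` disease state or `NA`.
#' @param prednisone_dose optional non-negative mg/kg/day or `NA`.
#' @return a `data.frame` of class `jia_clinical`.
#' @export
clinical_table <- function(sample_id, patient_id = sample_id, disease, esr,
                           joint_count, systemic_features = "",
                           rf_status = NA_character_, state = NA_character_,
                           prednisone_dose = NA_real_) {
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    patient_id = rep_len(as.character(patient_id), n),
    disease = rep_len(as.character(disease), n),
    esr = rep_len(as.numeric(esr), n),
    joint_count = rep_len(as.numeric(joint_count), n),
    systemic_features = rep_len(as.character(systemic_features), n),
    rf_status = rep_len(as.character(rf_status), n),
    state = rep_len(as.character(state), n),
    prednisone_dose = rep_len(as.numeric(prednisone_dose), n),
    stringsAsFactors = FALSE
  )
  validate_clinical(df)
}

validate_clinical <- function(df) {
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop_with("duplicate sample ids: %s", paste(dup, collapse = ", "))
  bad_dis <- setdiff(unique(df$disease), c("SJIA", "POLY"))
  if (length(bad_dis)) {
    stop_with("unknown disease token(s): %s (expected SJIA or POLY)",
              paste(bad_dis, collapse = ", "))
  }
  if (any(df$esr < 0, na.rm = TRUE)) {
    stop_with("negative ESR for sample(s): %s",
              paste(df$sample_id[which(df$esr < 0)], collapse = ", "))
  }
  jc <- df$joint_count
  if (any(jc < 0, na.rm = TRUE) || any(jc[!is.na(jc)] != round(jc[!is.na(jc)]))) {
    bad <- df$sample_id[which(jc < 0 | jc != round(jc))]
    stop_with("joint_count must be a non-negative integer; bad sample(s): %s",
              paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    toks <- parse_features(df$systemic_features[i])
    unknown <- setdiff(toks, systemic_feature_tokens)
    if (length(unknown)) {
      stop_with("unknown systemic feature token(s) for sample '%s': %s",
                df$sample_id[i], paste(unknown, collapse = ", "))
    }
  }
  bad_rf <- setdiff(stats::na.omit(unique(df$rf_status)),
                    c("positive", "negative", "unknown", ""))
  if (length(bad_rf)) stop_with("invalid rf_status value(s): %s", paste(bad_rf, collapse = ", "))
  bad_state <- setdiff(stats::na.omit(unique(df$state)), c("F", "Q", ""))
  if (length(bad_state)) stop_with("invalid state value(s): %s (expected F or Q)", paste(bad_state, collapse = ", "))
  df$state[!is.na(df$state) & df$state == ""] <- NA_character_
  df$rf_status[!is.na(df$rf_status) & df$rf_status == ""] <- NA_character_
  if (any(df$prednisone_dose < 0, na.rm = TRUE)) {
    stop_with("negative prednisone_dose")
  }
  class(df) <- c("jia_clinical", "data.frame")
  df
}

parse_features <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
}

#' Read a clinical metadata table
#'
#' TSV or CSV (chosen by file extension) with one row per sample and the
#' columns of [clinical_table]. Empty cells in optional columns are read as
#' missing; samples missing the covariate under analysis are dropped
#' per-analysis downstream, never imputed.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv` comma-separated).
#' @return a validated `jia_clinical` data frame.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", na.strings = c("NA", ""))
  need <- c("sample_id", "disease", "esr", "joint_count")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stop_with("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  clinical_table(
    sample_id = raw$sample_id,
    patient_id = raw$patient_id %||% raw$sample_id,
    disease = raw$disease,
    esr = suppressWarnings(as.numeric(raw$esr)),
    joint_count = suppressWarnings(as.numeric(raw$joint_count)),
    systemic_features = {
      sf <- raw$systemic_features %||% ""
      sf[is.na(sf)] <- ""
      sf
    },
    rf_status = raw$rf_status %||% NA_character_,
    state = raw$state %||% NA_character_,
    prednisone_dose = suppressWarnings(as.numeric(raw$prednisone_dose %||% NA))
  )
}

#' Write a clinical metadata table
#'
#' @param clinical a `jia_clinical` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- as.data.frame(clinical)
  out$esr <- format_full(out$esr)
  out$prednisone_dose <- format_full(out$prednisone_dose)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
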