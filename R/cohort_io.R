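#' Read an AIRR rearrangement table
#'
#' Reads one patient-visit rearrangement file in the AIRR Rearrangement TSV
#' dialect (tab-separated, header row, AIRR v1 field names;
#' `consensus_count` carries the number of distinct UMIs behind each
#' consensus sequence). Non-productive rows are dropped at read time so that
#' every downstream metric sees only functional rearrangements.
#'
#' @param path TSV file path.
#' @param patient_id,visit_month identifiers attached to every record.
#' @return tibble of rearrangement records, row order preserved.
#' @export
read_rearrangements <- function(path, patient_id, visit_month) {
  required <- c("sequence_id", "v_call", "d_call", "j_call", "junction",
                "sequence_alignment", "germline_alignment", "consensus_count",
                "productive")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_bcd(sprintf("AIRR file %s lacks required column(s): %s",
                     path, paste(missing_cols, collapse = ", ")),
             "bcelldyn_format_error")
  }
  df$consensus_count <- as.integer(df$consensus_count)
  df$productive <- toupper(df$productive) %in% c("T", "TRUE", "1")
  bad_len <- nchar(df$sequence_alignment) != nchar(df$germline_alignment)
  if (any(bad_len)) {
    stop_bcd(sprintf("sequence/germline alignment lengths differ for record(s): %s",
                     paste(head(df$sequence_id[bad_len], 3), collapse = ", ")),
             "bcelldyn_validation_error")
  }
  if (any(!is.na(df$consensus_count) & df$consensus_count < 1)) {
    stop_bcd("consensus_count must be >= 1", "bcelldyn_validation_error")
  }
  df <- df[df$productive, , drop = FALSE]
  df$patient_id <- patient_id
  df$visit_month <- as.integer(visit_month)
  tibble::as_tibble(df)
}

#' Write rearrangement records as an AIRR TSV
#'
#' @param records rearrangement tibble (columns beyond the AIRR set, such as
#'   `patient_id`/`visit_month`, are not written).
#' @param path output file.
#' @export
write_rearrangements <- function(records, path) {
  airr_cols <- c("sequence_id", "v_call", "d_call", "j_call", "junction",
                 "sequence_alignment", "germline_alignment", "consensus_count",
                 "productive")
  out <- records[, intersect(airr_cols, names(records)), drop = FALSE]
  out$productive <- ifelse(out$productive, "T", "F")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

VALID_SAMPLE_STATUS <- c("ok", "failed_amplification", "not_collected")

#' Read the clinical visit table
#'
#' CSV with columns `patient_id, visit_month, das28, das28_basis,
#' sample_status, retreated, ada_positive_within_12m`; empty cells are
#' missing values (missing DAS28 stays missing — it is excluded per
#' analysis, never imputed).
#'
#' @param path CSV file path.
#' @return tibble of visits grouped by patient and sorted by month.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          visit_month = readr::col_integer(),
                          das28 = readr::col_double(),
                          das28_basis = readr::col_character(),
                          sample_status = readr::col_character(),
                          retreated = readr::col_logical(),
                          ada_positive_within_12m = readr::col_logical()
                        ))
  dup <- duplicated(df[, c("patient_id", "visit_month")])
  if (any(dup)) {
    stop_bcd(sprintf("duplicate (patient_id, visit_month) row(s): %s",
                     paste(unique(df$patient_id[dup]), collapse = ", ")),
             "bcelldyn_validation_error")
  }
  if (any(!df$sample_status %in% VALID_SAMPLE_STATUS)) {
    stop_bcd(sprintf("unknown sample_status value(s): %s",
                     paste(setdiff(unique(df$sample_status), VALID_SAMPLE_STATUS),
                           collapse = ", ")),
             "bcelldyn_validation_error")
  }
  if (any(!is.na(df$das28) & (df$das28 < 0 | df$das28 > 10))) {
    stop_bcd("das28 must lie in [0, 10]", "bcelldyn_validation_error")
  }
  dplyr::arrange(df, .data$patient_id, .data$visit_month)
}

#' Assemble the cohort data model
#'
#' Joins the clinical visit table with per-visit AIRR rearrangement files.
#' Patients with no baseline (month 0) repertoire are excluded, with the
#' reason logged in the returned `exclusions` table; all other missing
#' repertoires are retained as absent alongside their `sample_status`.
#'
#' @param clinical tibble from [read_clinical_table()].
#' @param rearrangement_files tibble with columns `patient_id`,
#'   `visit_month`, `path` mapping visits to AIRR TSV files.
#' @param baseline_month visit month defining baseline (default 0).
#' @return a `bcr_cohort` list with elements `clinical`, `repertoires`
#'   (named list keyed `"<patient>|<month>"`), and `exclusions`.
#' @export
assemble_cohort <- function(clinical, rearrangement_files, baseline_month = 0L) {
  files <- tibble::as_tibble(rearrangement_files)
  key <- function(p, m) paste(p, m, sep = "|")
  visit_key <- key(clinical$patient_id, clinical$visit_month)
  fkey <- key(files$patient_id, files$visit_month)
  unmatched <- setdiff(fkey, visit_key)
  if (length(unmatched)) {
    stop_bcd(sprintf("rearrangement file(s) without a clinical visit: %s",
                     paste(unmatched, collapse = ", ")),
             "bcelldyn_validation_error")
  }
  status <- clinical$sample_status[match(fkey, visit_key)]
  if (any(status == "not_collected")) {
    stop_bcd(sprintf("repertoire supplied for visit(s) marked not_collected: %s",
                     paste(fkey[status == "not_collected"], collapse = ", ")),
             "bcelldyn_consistency_error")
  }
  repertoires <- stats::setNames(
    lapply(seq_len(nrow(files)), function(i) {
      read_rearrangements(files$path[i], files$patient_id[i], files$visit_month[i])
    }),
    fkey
  )
  patients <- unique(clinical$patient_id)
  has_baseline <- patients %in% files$patient_id[files$visit_month == baseline_month]
  excluded <- patients[!has_baseline]
  exclusions <- tibble::tibble(
    patient_id = excluded,
    reason = rep("baseline repertoire not available", length(excluded))
  )
  keep <- clinical$patient_id %in% patients[has_baseline]
  structure(
    list(clinical = clinical[keep, , drop = FALSE],
         repertoires = repertoires[files$patient_id %in% patients[has_baseline]],
         exclusions = exclusions),
    class = "bcr_cohort"
  )
}
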