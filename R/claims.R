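#' Claim sets
#'
#' A `claim_set` is a validated tibble with one row per claim:
#'
#' * `claim_id` — opaque unique identifier
#' * `year` — calendar year of service
#' * `specialty_code` — attending-physician specialty code
#' * `procedure_codes` — list column of 7-character ICD-10-PCS codes
#' * `diagnosis_codes` — list column of ICD-10-CM codes (3-7 alphanumeric
#'   characters, starting with a letter)
#' * `truth` — list column of ground-truth annotations (synthetic corpora
#'   only; `NULL` per row otherwise), each a list with fields `is_error`,
#'   `error_kind`, `nonerror_kind`, `justifying_diagnosis_index`
#'
#' The claim is the unit of analysis: it carries every procedure and
#' diagnosis documented together.
#'
#' @param claims A data frame with the columns above (`truth` optional).
#' @param provenance Free-text source tag stored as an attribute.
#' @return A validated `claim_set`.
#' @export
claim_set <- function(claims, provenance = "unspecified") {
  claims <- as_tibble(claims)
  required <- c("claim_id", "year", "specialty_code", "procedure_codes", "diagnosis_codes")
  missing_cols <- setdiff(required, names(claims))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("claim table is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "lateraleye_schema_error"
    )
  }
  if (!"truth" %in% names(claims)) {
    claims$truth <- vector("list", nrow(claims))
  }
  claims$claim_id <- as.character(claims$claim_id)
  claims$year <- as.integer(claims$year)
  claims$specialty_code <- as.character(claims$specialty_code)

  dup <- unique(claims$claim_id[duplicated(claims$claim_id)])
  if (length(dup) > 0) {
    abort(
      sprintf(
        "duplicate claim_id(s): %s",
        paste(head(dup, 5L), collapse = ", ")
      ),
      class = "lateraleye_validation_error"
    )
  }

  problems <- validate_claim_rows(claims)
  if (nrow(problems) > 0) {
    keep <- !seq_len(nrow(claims)) %in% problems$row
    warn(
      sprintf(
        "%d malformed claim row(s) rejected (see attr(x, \"rejected\")); e.g. row %d: %s",
        nrow(problems), problems$row[1], problems$reason[1]
      ),
      class = "lateraleye_rejected_rows"
    )
    claims <- claims[keep, , drop = FALSE]
  }
  out <- claims[, c(required, "truth")]
  attr(out, "provenance") <- provenance
  attr(out, "rejected") <- problems
  class(out) <- c("claim_set", class(out))
  out
}

# Row-level validation is total: every input row is either accepted or listed
# here with its reason, so accepted + rejected = input rows.
validate_claim_rows <- function(claims) {
  n_proc <- lengths(claims$procedure_codes)
  n_dx <- lengths(claims$diagnosis_codes)
  ok_pcs <- vapply(
    claims$procedure_codes,
    function(p) all(grepl("^[A-Za-z0-9]{7}$", p)), logical(1)
  )
  ok_cm <- vapply(
    claims$diagnosis_codes,
    function(d) all(grepl("^[A-Za-z][A-Za-z0-9]{2,6}$", d)), logical(1)
  )
  reasons <- list(
    "empty procedure_codes" = n_proc == 0,
    "empty diagnosis_codes" = n_dx == 0,
    "PCS code not 7 alphanumeric characters" = n_proc > 0 & !ok_pcs,
    "CM code not 3-7 alphanumeric characters starting with a letter" = n_dx > 0 & !ok_cm,
    "missing year" = is.na(claims$year),
    "missing claim_id" = is.na(claims$claim_id) | claims$claim_id == ""
  )
  out <- purrr::imap(reasons, function(bad, why) {
    tibble(row = which(bad), claim_id = claims$claim_id[bad], reason = why)
  })
  arrange(bind_rows(out), .data$row)
}

#' @export
print.claim_set <- function(x, ...) {
  cat(sprintf(
    "<claim_set> %d claims, years %s, provenance: %s\n",
    nrow(x),
    if (nrow(x) > 0) paste(range(x$year), collapse = "-") else "-",
    attr(x, "provenance") %||% "unspecified"
  ))
  NextMethod()
}

truth_to_json <- function(truth) {
  vapply(truth, function(t) {
    if (is.null(t)) "" else as.character(jsonlite::toJSON(t, auto_unbox = TRUE, null = "null"))
  }, character(1))
}

truth_from_json <- function(js) {
  lapply(js, function(s) {
    if (is.na(s) || s == "") NULL else jsonlite::fromJSON(s, simplifyVector = TRUE)
  })
}

#' Read and write claim tables
#'
#' CSV stores the code lists as pipe-delimited strings (hand-editable
#' fixtures); Parquet uses native list columns (requires the arrow package).
#' Ground-truth annotations round-trip through a `truth_json` column in both
#' formats.
#'
#' @param path File path.
#' @param format `"csv"` or `"parquet"`; inferred from the file extension
#'   when omitted.
#' @param provenance Source tag attached to the returned set.
#' @return `read_claims()` returns a [claim_set]; `write_claims()` returns
#'   `path` invisibly.
#' @export
read_claims <- function(path, format = c("auto", "csv", "parquet"),
                        provenance = path) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) {
    abort(sprintf("claim file not found: %s", path), class = "lateraleye_io_error")
  }
  if (format == "csv") {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    required <- c("claim_id", "year", "specialty_code", "procedure_codes", "diagnosis_codes")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0) {
      abort(
        sprintf("claim CSV is missing column(s): %s", paste(missing_cols, collapse = ", ")),
        class = "lateraleye_schema_error"
      )
    }
    raw$procedure_codes <- strsplit(dplyr::coalesce(raw$procedure_codes, ""), "|", fixed = TRUE)
    raw$diagnosis_codes <- strsplit(dplyr::coalesce(raw$diagnosis_codes, ""), "|", fixed = TRUE)
    raw$year <- suppressWarnings(as.integer(raw$year))
    raw$truth <- if ("truth_json" %in% names(raw)) {
      truth_from_json(raw$truth_json)
    } else {
      vector("list", nrow(raw))
    }
    raw$truth_json <- NULL
  } else {
    require_arrow()
    raw <- as_tibble(arrow::read_parquet(path))
    if ("truth_json" %in% names(raw)) {
      raw$truth <- truth_from_json(raw$truth_json)
      raw$truth_json <- NULL
    }
    raw$procedure_codes <- lapply(raw$procedure_codes, as.character)
    raw$diagnosis_codes <- lapply(raw$diagnosis_codes, as.character)
  }
  claim_set(raw, provenance = provenance)
}

#' @param claims A [claim_set].
#' @rdname read_claims
#' @export
write_claims <- function(claims, path, format = c("auto", "csv", "parquet")) {
  stopifnot(inherits(claims, "claim_set"))
  format <- resolve_format(path, match.arg(format))
  flat <- as_tibble(unclass(claims)[c(
    "claim_id", "year", "specialty_code", "procedure_codes", "diagnosis_codes", "truth"
  )])
  flat$truth_json <- truth_to_json(flat$truth)
  flat$truth <- NULL
  if (format == "csv") {
    flat$procedure_codes <- vapply(flat$procedure_codes, paste, character(1), collapse = "|")
    flat$diagnosis_codes <- vapply(flat$diagnosis_codes, paste, character(1), collapse = "|")
    readr::write_csv(flat, path, progress = FALSE)
  } else {
    require_arrow()
    arrow::write_parquet(flat, path)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") {
    return(format)
  }
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv"
}

require_arrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("Parquet support requires the 'arrow' package", class = "lateraleye_dependency_error")
  }
}
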