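#' Code metadata maps
#'
#' A `code_map` translates ICD-10-PCS procedure codes and ICD-10-CM diagnosis
#' codes into the per-code metadata the analysis needs: a canonical body-part
#' identifier, a laterality, whether the code is a general (no-body-part)
#' diagnosis that can by itself justify a procedure, and whether a PCS code is
#' an infusion-device insertion. Lookup is by longest matching prefix, because
#' in both coding systems the characters that carry body part and side depend
#' on the code family (for PCS the fourth character encodes body part and
#' side jointly, conditional on the first three).
#'
#' Two symmetric, irreflexive relations over body-part identifiers ride along:
#'
#' * `same_site`: identifiers that name the same anatomical site at different
#'   granularity (e.g. `knee` vs `knee_joint`); used when deciding whether a
#'   diagnosis and a procedure refer to the same body part.
#' * `proximity`: anatomically adjacent sites (e.g. `shoulder_joint` and
#'   `humerus`) that can justify one another's procedures when sides agree.
#'
#' An optional `stem` column names the laterality-free family of a code
#' (e.g. left and right knee replacement share one stem); the association
#' model uses stems as its intermediate backoff level. Codes without a stem
#' default to `part:<body_part>` when lateralized, otherwise to the code
#' itself.
#'
#' @param entries Tibble with columns `code_or_prefix`, `system` ("PCS" or
#'   "CM"), `body_part` (`NA` for none), `laterality` (one of `LEFT`, `RIGHT`,
#'   `BILATERAL`, `UNSPECIFIED_SIDE`, `NO_LATERALITY`), `is_general`,
#'   `is_infusion_device_insertion`, and optionally `stem`.
#' @param relations Tibble with columns `body_part_a`, `body_part_b` and
#'   optionally `relation` (`"proximity"`, the default, or `"same_site"`).
#' @return A `code_map` object.
#' @seealso [load_code_map()], [default_code_map()], [resolve_code()]
#' @export
code_map <- function(entries, relations = NULL) {
  required <- c(
    "code_or_prefix", "system", "body_part", "laterality",
    "is_general", "is_infusion_device_insertion"
  )
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("code map is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "lateraleye_schema_error"
    )
  }
  entries <- as_tibble(entries)
  entries$system <- toupper(entries$system)
  entries$laterality <- normalize_laterality(entries$laterality)
  entries$body_part <- normalize_body_part(entries$body_part)
  if (!"stem" %in% names(entries)) entries$stem <- NA_character_
  entries$stem <- if_else(
    is.na(entries$stem) | entries$stem == "",
    if_else(
      entries$laterality %in% c("LEFT", "RIGHT", "BILATERAL") & !is.na(entries$body_part),
      paste0("part:", entries$body_part),
      entries$code_or_prefix
    ),
    entries$stem
  )
  validate_map_entries(entries)

  if (is.null(relations) || nrow(as_tibble(relations)) == 0) {
    relations <- tibble(
      body_part_a = character(), body_part_b = character(),
      relation = character()
    )
  } else {
    relations <- as_tibble(relations)
    if (!"relation" %in% names(relations)) relations$relation <- "proximity"
    relations$relation <- tolower(relations$relation)
    bad_rel <- setdiff(unique(relations$relation), c("proximity", "same_site"))
    if (length(bad_rel) > 0) {
      abort(sprintf("unknown relation type(s): %s", paste(bad_rel, collapse = ", ")))
    }
    reflexive <- relations$body_part_a == relations$body_part_b
    if (any(reflexive)) {
      abort(
        sprintf(
          "body-part relations must be irreflexive; offending part(s): %s",
          paste(unique(relations$body_part_a[reflexive]), collapse = ", ")
        ),
        class = "lateraleye_validation_error"
      )
    }
    # store the symmetric closure so lookup is order-free
    relations <- distinct(bind_rows(
      relations[, c("body_part_a", "body_part_b", "relation")],
      tibble(
        body_part_a = relations$body_part_b,
        body_part_b = relations$body_part_a,
        relation = relations$relation
      )
    ))
  }

  structure(list(entries = entries, relations = relations), class = "code_map")
}

validate_map_entries <- function(entries) {
  dup <- entries$code_or_prefix[duplicated(entries$code_or_prefix)]
  if (length(dup) > 0) {
    abort(
      sprintf("conflicting duplicate code prefix(es): %s", paste(unique(dup), collapse = ", ")),
      class = "lateraleye_validation_error"
    )
  }
  bad_lat <- !entries$laterality %in% LATERALITIES
  if (any(bad_lat)) {
    abort(sprintf(
      "invalid laterality value(s): %s",
      paste(unique(entries$laterality[bad_lat]), collapse = ", ")
    ), class = "lateraleye_validation_error")
  }
  sided <- entries$laterality %in% c("LEFT", "RIGHT", "BILATERAL")
  if (any(sided & is.na(entries$body_part))) {
    abort(
      sprintf(
        "lateralized codes must name a body part: %s",
        paste(entries$code_or_prefix[sided & is.na(entries$body_part)], collapse = ", ")
      ),
      class = "lateraleye_validation_error"
    )
  }
  bad_gen <- entries$is_general &
    (!is.na(entries$body_part) | entries$laterality != "NO_LATERALITY")
  if (any(bad_gen)) {
    abort(
      sprintf(
        "general codes must have no body part and no laterality: %s",
        paste(entries$code_or_prefix[bad_gen], collapse = ", ")
      ),
      class = "lateraleye_validation_error"
    )
  }
  bad_inf <- entries$is_infusion_device_insertion & entries$system != "PCS"
  if (any(bad_inf)) {
    abort(
      sprintf(
        "infusion-device insertion is a PCS-only attribute: %s",
        paste(entries$code_or_prefix[bad_inf], collapse = ", ")
      ),
      class = "lateraleye_validation_error"
    )
  }
  invisible(entries)
}

normalize_laterality <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c("", "NONE", "NO_LATERALITY", "NA") | is.na(x)] <- "NO_LATERALITY"
  x[x %in% c("UNSPECIFIED", "UNSPECIFIED_SIDE")] <- "UNSPECIFIED_SIDE"
  x
}

normalize_body_part <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | tolower(x) == "none")] <- NA_character_
  x
}

#' Load a code map from CSV files
#'
#' @param path CSV with columns `code_or_prefix`, `system`, `body_part`,
#'   `laterality`, `is_general`, `is_infusion_device_insertion` and optional
#'   `stem`. Empty/`none` cells mean "no body part" / "no laterality".
#' @param relations_path Optional CSV of body-part relations with columns
#'   `body_part_a`, `body_part_b` and optional `relation`.
#' @return A [code_map] object.
#' @export
load_code_map <- function(path, relations_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("code map file not found: %s", path), class = "lateraleye_io_error")
  }
  entries <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("is_general", "is_infusion_device_insertion")) {
    if (col %in% names(entries)) entries[[col]] <- as.logical(entries[[col]])
  }
  relations <- NULL
  if (!is.null(relations_path)) {
    if (!file.exists(relations_path)) {
      abort(sprintf("relations file not found: %s", relations_path),
        class = "lateraleye_io_error"
      )
    }
    relations <- readr::read_csv(relations_path, show_col_types = FALSE, progress = FALSE)
  }
  code_map(entries, relations)
}

#' Packaged default code map
#'
#' Covers the worked orthopedic code examples used in the documentation and
#' tests (knee/hip/shoulder replacements, lower-leg detachment, femur
#' fixation, the matching ICD-10-CM diagnoses, general justifying diagnoses
#' such as gangrene and bone metastasis, and common comorbidity codes),
#' together with same-site and proximity relations. It is a small extensible
#' mapping, not the official ICD-10 dictionaries.
#'
#' @return A [code_map] object.
#' @export
default_code_map <- function() {
  load_code_map(
    system.file("extdata", "default-code-map.csv", package = "lateraleye"),
    system.file("extdata", "default-code-relations.csv", package = "lateraleye")
  )
}

#' Resolve codes to metadata
#'
#' Longest-prefix lookup of each code against the map. Codes that match no
#' entry resolve to the permissive fallback (no body part, no laterality,
#' `is_general = TRUE`) with a warning: real claims always contain codes
#' outside any dictionary, and an unknown diagnosis must not be treated as
#' evidence of error.
#'
#' @param map A [code_map].
#' @param codes Character vector of code strings.
#' @param quiet Suppress the unknown-code warning.
#' @return A tibble with one row per element of `codes`, columns `code`,
#'   `system`, `body_part`, `laterality`, `is_general`,
#'   `is_infusion_device_insertion`, `stem`.
#' @export
resolve_code <- function(map, codes, quiet = FALSE) {
  stopifnot(inherits(map, "code_map"))
  codes <- as.character(codes)
  keys <- map$entries$code_or_prefix
  idx <- match(codes, keys)
  max_len <- max(nchar(codes), 0L)
  len <- max_len - 1L
  while (len >= 1L && anyNA(idx)) {
    open <- which(is.na(idx) & nchar(codes) > len)
    if (length(open) > 0) {
      idx[open] <- match(substr(codes[open], 1L, len), keys)
    }
    len <- len - 1L
  }
  unknown <- is.na(idx)
  if (any(unknown) && !quiet) {
    shown <- head(unique(codes[unknown]), 5L)
    warn(sprintf(
      "%d code(s) not in the code map resolved to the permissive fallback (e.g. %s)",
      length(unique(codes[unknown])), paste(shown, collapse = ", ")
    ), class = "lateraleye_unknown_code")
  }
  out <- map$entries[idx, c(
    "system", "body_part", "laterality", "is_general",
    "is_infusion_device_insertion", "stem"
  )]
  out$code <- codes
  if (any(unknown)) {
    out$system[unknown] <- if_else(nchar(codes[unknown]) == 7L, "PCS", "CM")
    out$body_part[unknown] <- NA_character_
    out$laterality[unknown] <- "NO_LATERALITY"
    out$is_general[unknown] <- TRUE
    out$is_infusion_device_insertion[unknown] <- FALSE
    out$stem[unknown] <- codes[unknown]
  }
  out[, c(
    "code", "system", "body_part", "laterality", "is_general",
    "is_infusion_device_insertion", "stem"
  )]
}

relation_lookup <- function(map, a, b, type) {
  rel <- map$relations[map$relations$relation == type, , drop = FALSE]
  key <- paste(a, b, sep = "\r")
  have <- paste(rel$body_part_a, rel$body_part_b, sep = "\r")
  out <- key %in% have
  out[is.na(a) | is.na(b)] <- FALSE
  out
}

#' Body-part relations
#'
#' `in_proximity()` tests anatomical adjacency; `same_site()` tests whether
#' two identifiers denote the same site (equality or a declared `same_site`
#' pair). Both are vectorized and symmetric; `NA` body parts never relate.
#'
#' @param map A [code_map].
#' @param a,b Character vectors of body-part identifiers.
#' @return Logical vector.
#' @export
in_proximity <- function(map, a, b) {
  relation_lookup(map, a, b, "proximity")
}

#' @rdname in_proximity
#' @export
same_site <- function(map, a, b) {
  eq <- !is.na(a) & !is.na(b) & a == b
  eq | relation_lookup(map, a, b, "same_site")
}

#' @export
print.code_map <- function(x, ...) {
  cat(sprintf(
    "<code_map> %d entries (%d PCS, %d CM), %d relation pairs\n",
    nrow(x$entries), sum(x$entries$system == "PCS"), sum(x$entries$system == "CM"),
    nrow(x$relations) / 2L
  ))
  invisible(x)
}
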