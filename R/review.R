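#' Automated clinical-style review of flagged claims
#'
#' Deterministic implementation of the review criteria used to adjudicate
#' discordant-laterality claims. For each procedure the engine searches the
#' claim's diagnoses for a justification, in priority order:
#'
#' 1. a diagnosis on the same site with a matching (or bilateral) side —
#'    plain nonerror;
#' 2. same site, side documented as unspecified — `UNSPECIFIED_SIDE`;
#' 3. same site, code carries no laterality — `NO_LATERALITY`;
#' 4. a general diagnosis (no body part) that can explain procedures —
#'    `GENERAL_DIAGNOSIS`;
#' 5. a diagnosis on a proximate body part with a compatible (or
#'    unspecified) side — `PROXIMITY`;
#' 6. failing all of those, a concurrent procedure that is itself justified
#'    and whose site is the same as or proximate to this procedure's, with
#'    compatible side — `COMBINATION` (one level deep; no recursion).
#'
#' A claim is a confirmed error when at least one procedure has no
#' justification; the error kind is `SAME_BODY_PART` when some diagnosis
#' names the same site on the opposite side, otherwise
#' `DIFFERENT_BODY_PART`. A nonerror claim's kind is the weakest
#' justification any of its procedures needed (the rationale that clears
#' the claim).
#'
#' @param claims A [claim_set], normally the output of
#'   [filter_study_population()].
#' @param map A [code_map].
#' @return Tibble with `claim_id`, `is_error`, `error_kind`,
#'   `nonerror_kind`, `rationale` (the explanation trace).
#' @export
auto_review <- function(claims, map) {
  stopifnot(inherits(claims, "claim_set"))
  pm <- explode_codes(claims, "procedure_codes", map)
  dm <- explode_codes(claims, "diagnosis_codes", map)
  pm <- distinct(tibble(
    claim = pm$claim_id, p_code = pm$code, p_part = pm$body_part,
    p_lat = pm$laterality
  ))
  dm <- distinct(tibble(
    claim = dm$claim_id, d_code = dm$code, d_part = dm$body_part,
    d_lat = dm$laterality, d_general = dm$is_general
  ))
  pairs <- inner_join(pm, dm, by = "claim", relationship = "many-to-many")

  same <- same_site(map, pairs$p_part, pairs$d_part)
  prox <- in_proximity(map, pairs$p_part, pairs$d_part)
  compat <- sides_compatible(pairs$p_lat, pairs$d_lat)
  d_sided <- pairs$d_lat %in% c("LEFT", "RIGHT", "BILATERAL")

  cat <- rep(7L, nrow(pairs)) # 7 = no justification from this diagnosis
  cat[prox & (compat | pairs$d_lat == "UNSPECIFIED_SIDE")] <- 5L
  cat[pairs$d_general] <- 4L
  cat[same & pairs$d_lat == "NO_LATERALITY" & !is.na(pairs$d_part)] <- 3L
  cat[same & pairs$d_lat == "UNSPECIFIED_SIDE"] <- 2L
  cat[same & d_sided & compat] <- 1L
  pairs$cat <- cat
  # opposite-side same-site diagnosis: the wrong-site signature
  pairs$opposite <- same &
    pairs$p_lat %in% c("LEFT", "RIGHT") & pairs$d_lat %in% c("LEFT", "RIGHT") &
    pairs$p_lat != pairs$d_lat

  per_proc <- summarise(
    group_by(pairs, .data$claim, .data$p_code, .data$p_part, .data$p_lat),
    cat = min(.data$cat),
    via = .data$d_code[which.min(.data$cat)],
    any_opposite = any(.data$opposite),
    .groups = "drop"
  )

  # one-deep combination pass: an unjustified procedure inherits
  # justification from a justified concurrent procedure at a compatible site
  unjust <- per_proc[per_proc$cat == 7L, , drop = FALSE]
  just <- per_proc[per_proc$cat < 7L, , drop = FALSE]
  if (nrow(unjust) > 0 && nrow(just) > 0) {
    cand <- inner_join(
      unjust[, c("claim", "p_code", "p_part", "p_lat")],
      tibble(
        claim = just$claim, q_code = just$p_code,
        q_part = just$p_part, q_lat = just$p_lat
      ),
      by = "claim", relationship = "many-to-many"
    )
    cand <- cand[
      (same_site(map, cand$p_part, cand$q_part) |
        in_proximity(map, cand$p_part, cand$q_part)) &
        sides_compatible(cand$p_lat, cand$q_lat),
      ,
      drop = FALSE
    ]
    if (nrow(cand) > 0) {
      combo <- distinct(cand[, c("claim", "p_code")])
      combo$combo_via <- cand$q_code[match(
        paste(combo$claim, combo$p_code),
        paste(cand$claim, cand$p_code)
      )]
      hit <- match(
        paste(per_proc$claim, per_proc$p_code),
        paste(combo$claim, combo$p_code)
      )
      per_proc$cat[!is.na(hit)] <- 6L
      per_proc$via[!is.na(hit)] <- combo$combo_via[hit[!is.na(hit)]]
    }
  }

  kind_names <- c(
    "NONE", "UNSPECIFIED_SIDE", "NO_LATERALITY", "GENERAL_DIAGNOSIS",
    "PROXIMITY", "COMBINATION"
  )
  per_proc$note <- if_else(
    per_proc$cat == 7L,
    paste0(per_proc$p_code, ": unjustified"),
    paste0(
      per_proc$p_code, ": ",
      c(kind_names, "")[per_proc$cat], " via ", per_proc$via
    )
  )

  by_claim <- summarise(
    group_by(per_proc, .data$claim),
    is_error = any(.data$cat == 7L),
    weakest = max(.data$cat[.data$cat < 7L], -Inf),
    same_part_conflict = any(.data$cat == 7L & .data$any_opposite),
    rationale = paste(.data$note, collapse = "; "),
    .groups = "drop"
  )
  by_claim$error_kind <- if_else(
    by_claim$is_error,
    if_else(by_claim$same_part_conflict, "SAME_BODY_PART", "DIFFERENT_BODY_PART"),
    "NONE"
  )
  by_claim$nonerror_kind <- if_else(
    by_claim$is_error | !is.finite(by_claim$weakest),
    "NONE",
    kind_names[pmax(by_claim$weakest, 1)]
  )

  idx <- match(claims$claim_id, by_claim$claim)
  tibble(
    claim_id = claims$claim_id,
    is_error = by_claim$is_error[idx],
    error_kind = by_claim$error_kind[idx],
    nonerror_kind = by_claim$nonerror_kind[idx],
    rationale = by_claim$rationale[idx]
  )
}

sides_compatible <- function(a, b) {
  lr <- c("LEFT", "RIGHT")
  (a %in% lr & b %in% lr & a == b) | a == "BILATERAL" | b == "BILATERAL"
}

#' Compare the rule-based method with the association model
#'
#' Restricted to the two discordant subgroups (`LR`, `RL`), builds the
#' evaluation contingency structure: per method and subgroup, the flagged
#' count, confirmed-error and nonerror counts with subcategory breakdown,
#' per-subgroup precision (confirmed errors / flagged) and pooled precision.
#' The rule-based method flags every claim in the discordant subgroups by
#' definition; the association model flags the subset scoring below the
#' threshold.
#'
#' @param claims Filtered [claim_set] (see [filter_study_population()]).
#' @param map A [code_map].
#' @param model An `association_table`.
#' @param threshold An `aop_threshold` or numeric threshold.
#' @param labels `"auto_review"` (label with [auto_review()]) or
#'   `"ground_truth"` (use the generator's annotations).
#' @return A `comparison_report` with elements `cells`, `summary`, `pooled`.
#' @export
compare_methods <- function(claims, map, model, threshold,
                            labels = c("auto_review", "ground_truth")) {
  stopifnot(inherits(claims, "claim_set"))
  labels <- match.arg(labels)
  subgroup <- assign_subgroup(claims, map)
  keep <- subgroup %in% c("LR", "RL")
  sub <- claims[keep, , drop = FALSE]
  sub_lab <- as.character(subgroup[keep])

  if (nrow(sub) == 0) {
    lab <- tibble(
      claim_id = character(), is_error = logical(),
      error_kind = character(), nonerror_kind = character()
    )
    aop_flag <- logical()
  } else if (labels == "auto_review") {
    lab <- auto_review(sub, map)
    aop_flag <- score_claims(sub, model, threshold)$flagged
  } else {
    if (any(vapply(sub$truth, is.null, logical(1)))) {
      abort("labels = 'ground_truth' requires truth annotations on every claim",
        class = "lateraleye_validation_error"
      )
    }
    lab <- tibble(
      claim_id = sub$claim_id,
      is_error = claim_truth_field(sub, "is_error", NA),
      error_kind = claim_truth_field(sub, "error_kind", NA_character_),
      nonerror_kind = claim_truth_field(sub, "nonerror_kind", NA_character_)
    )
    aop_flag <- score_claims(sub, model, threshold)$flagged
  }

  base <- tibble(
    subgroup = sub_lab,
    is_error = lab$is_error,
    error_kind = lab$error_kind,
    nonerror_kind = lab$nonerror_kind,
    rule = TRUE,
    aop = aop_flag
  )
  cells <- bind_rows(
    method_cells(base[base$rule, , drop = FALSE], "rule"),
    method_cells(base[base$aop, , drop = FALSE], "aop")
  )
  new_comparison_report(cells, n_subgroup = count(base, .data$subgroup, name = "n"))
}

# contingency cells for the claims one method flagged
method_cells <- function(flagged, method) {
  if (nrow(flagged) == 0) {
    return(tibble(
      method = character(), subgroup = character(), category = character(),
      subcategory = character(), n = integer()
    ))
  }
  flagged$category <- if_else(flagged$is_error, "confirmed_error", "confirmed_nonerror")
  flagged$subcategory <- if_else(
    flagged$is_error,
    if_else(flagged$error_kind == "SAME_BODY_PART", "same_body_part", "not_same_body_part"),
    tolower(flagged$nonerror_kind)
  )
  out <- count(flagged, .data$subgroup, .data$category, .data$subcategory, name = "n")
  out$method <- method
  out[, c("method", "subgroup", "category", "subcategory", "n")]
}

new_comparison_report <- function(cells, n_subgroup = NULL) {
  cells$masked <- FALSE
  summary <- summarise(
    group_by(cells, .data$method, .data$subgroup),
    n_flagged = sum(.data$n),
    n_error = sum(.data$n[.data$category == "confirmed_error"]),
    n_nonerror = sum(.data$n[.data$category == "confirmed_nonerror"]),
    .groups = "drop"
  )
  summary$precision <- if_else(
    summary$n_flagged > 0, summary$n_error / summary$n_flagged, NA_real_
  )
  pooled <- summarise(
    group_by(cells, .data$method),
    n_flagged = sum(.data$n),
    n_error = sum(.data$n[.data$category == "confirmed_error"]),
    .groups = "drop"
  )
  pooled$precision <- if_else(
    pooled$n_flagged > 0, pooled$n_error / pooled$n_flagged, NA_real_
  )
  structure(
    list(
      cells = cells, summary = summary, pooled = pooled,
      n_subgroup = n_subgroup, min_reportable = NA_integer_, pr_points = NULL
    ),
    class = "comparison_report"
  )
}

#' Build a comparison report from printed counts
#'
#' Reconstructs a `comparison_report` from an already-tabulated contingency
#' table (columns `method`, `subgroup`, `category`, `subcategory`, `n`), so
#' published count tables can be re-analyzed without claim-level data.
#'
#' @param counts Count tibble or path to a CSV with the columns above.
#' @return A `comparison_report`.
#' @export
comparison_from_counts <- function(counts) {
  if (is.character(counts)) {
    counts <- readr::read_csv(counts, show_col_types = FALSE, progress = FALSE)
  }
  counts <- as_tibble(counts)
  required <- c("method", "subgroup", "category", "subcategory", "n")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("count table is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "lateraleye_schema_error"
    )
  }
  counts$n <- as.integer(counts$n)
  new_comparison_report(counts[, required])
}

#' Reference review counts (CMS-LDS 2020 orthopedic laterality evaluation)
#'
#' The published contingency counts from a clinical review of the 2020
#' CMS-LDS orthopedic discordant-laterality subgroups (left-procedure/
#' right-diagnosis n = 1106; right-procedure/left-diagnosis n = 1064),
#' for the rule-based method and the association-outlier model. Shipped as
#' a plain-text fixture so the headline precision arithmetic can be
#' reproduced without access to the restricted claims data.
#'
#' @return A `comparison_report` built from the packaged counts.
#' @export
reference_review_counts <- function() {
  comparison_from_counts(
    system.file("extdata", "reference-review-counts.csv", package = "lateraleye")
  )
}

#' Mask small cells for disclosure control
#'
#' CMS reporting rules prohibit publishing result cells of 10 or fewer
#' observations. Marks every cell with `0 < n < min_reportable` as masked;
#' totals stay exact internally and masking is flag-based, not destructive.
#' Zero cells stay visible (no disclosure risk).
#'
#' @param report A `comparison_report`.
#' @param min_reportable Smallest publishable cell count (default 11, i.e.
#'   mask cells of 10 or fewer).
#' @return The report with masking flags set.
#' @export
suppress_small_cells <- function(report, min_reportable = 11L) {
  stopifnot(inherits(report, "comparison_report"))
  report$cells$masked <- report$cells$n > 0L & report$cells$n < min_reportable
  report$min_reportable <- as.integer(min_reportable)
  report
}

#' Write a comparison report to disk
#'
#' Emits `comparison_report.csv` (cells; masked cells show a sentinel, never
#' the count), `summary.txt` (human-readable), and `pr_points.csv` when the
#' report carries precision-recall points.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- report$cells
  cells$n_display <- if_else(cells$masked, "suppressed", as.character(cells$n))
  cells$n <- NULL
  cells_path <- file.path(dir, "comparison_report.csv")
  readr::write_csv(cells, cells_path, progress = FALSE)

  summary_path <- file.path(dir, "summary.txt")
  writeLines(format_report_summary(report), summary_path)

  paths <- c(cells_path, summary_path)
  if (!is.null(report$pr_points)) {
    pr_path <- file.path(dir, "pr_points.csv")
    readr::write_csv(report$pr_points, pr_path, progress = FALSE)
    paths <- c(paths, pr_path)
  }
  invisible(paths)
}

format_report_summary <- function(report) {
  lines <- c("Method comparison (discordant laterality subgroups)", "")
  for (i in seq_len(nrow(report$summary))) {
    s <- report$summary[i, ]
    lines <- c(lines, sprintf(
      "%-5s %-3s flagged=%d errors=%d nonerrors=%d precision=%s",
      s$method, s$subgroup, s$n_flagged, s$n_error, s$n_nonerror,
      if (is.na(s$precision)) "undefined" else sprintf("%.1f%%", 100 * s$precision)
    ))
  }
  lines <- c(lines, "")
  for (i in seq_len(nrow(report$pooled))) {
    p <- report$pooled[i, ]
    lines <- c(lines, sprintf(
      "%-5s pooled flagged=%d errors=%d precision=%s",
      p$method, p$n_flagged, p$n_error,
      if (is.na(p$precision)) "undefined" else sprintf("%.1f%%", 100 * p$precision)
    ))
  }
  if (!is.na(report$min_reportable)) {
    lines <- c(lines, "", sprintf(
      "Cells below %d suppressed in rendered output.", report$min_reportable
    ))
  }
  lines
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(paste(format_report_summary(x), collapse = "\n"), "\n")
  invisible(x)
}
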