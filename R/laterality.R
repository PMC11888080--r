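#' Per-code laterality
#'
#' Thin wrapper over [resolve_code()] for a single vector of codes: returns
#' the code metadata (body part, laterality, flags) the map assigns. Total
#' function — unknown codes get the permissive fallback.
#'
#' @param codes Character vector of PCS or CM codes.
#' @param map A [code_map].
#' @return Tibble of code metadata, one row per code.
#' @export
code_laterality <- function(codes, map) {
  resolve_code(map, codes, quiet = TRUE)
}

side_of <- function(laterality) {
  # collapse a set of code lateralities into a claim-level side
  has_b <- any(laterality == "BILATERAL")
  has_l <- any(laterality == "LEFT")
  has_r <- any(laterality == "RIGHT")
  if (has_b || (has_l && has_r)) {
    "BOTH"
  } else if (has_l) {
    "LEFT"
  } else if (has_r) {
    "RIGHT"
  } else {
    "INDETERMINATE"
  }
}

#' Claim-level procedure and diagnosis sides
#'
#' A claim's procedure side is `LEFT` when every lateralized procedure is
#' left-sided (and at least one exists), `RIGHT` symmetrically, `BOTH` when a
#' bilateral code is present or both left and right procedures were
#' performed, and `INDETERMINATE` when no procedure carries laterality.
#' The diagnosis side is computed identically over the diagnosis codes.
#' Codes with `UNSPECIFIED_SIDE` or `NO_LATERALITY` are ignored for side
#' determination: an unspecified-side diagnosis coexisting with lateralized
#' ones does not create a conflict.
#'
#' @param claims A [claim_set].
#' @param map A [code_map].
#' @return Tibble with `claim_id`, `procedure_side`, `diagnosis_side`.
#' @export
claim_sides <- function(claims, map) {
  stopifnot(inherits(claims, "claim_set"))
  proc_lat <- code_lat_per_claim(claims$procedure_codes, map)
  dx_lat <- code_lat_per_claim(claims$diagnosis_codes, map)
  tibble(
    claim_id = claims$claim_id,
    procedure_side = unname(vapply(proc_lat, side_of, character(1))),
    diagnosis_side = unname(vapply(dx_lat, side_of, character(1)))
  )
}

code_lat_per_claim <- function(code_lists, map) {
  lens <- lengths(code_lists)
  meta <- resolve_code(map, unlist(code_lists, use.names = FALSE), quiet = TRUE)
  split(meta$laterality, rep(seq_along(code_lists), lens))[as.character(seq_along(code_lists))]
}

side_pair_to_subgroup <- function(procedure_side, diagnosis_side) {
  abbrev <- c(LEFT = "L", RIGHT = "R", BOTH = "B")
  ok <- procedure_side %in% names(abbrev) & diagnosis_side %in% names(abbrev)
  out <- rep("INDETERMINATE", length(procedure_side))
  out[ok] <- paste0(abbrev[procedure_side[ok]], abbrev[diagnosis_side[ok]])
  factor(out, levels = SUBGROUPS)
}

#' Laterality subgroup assignment
#'
#' Crosses the claim's procedure side with its diagnosis side into the nine
#' subgroups `RR, RL, RB, LR, LL, LB, BR, BL, BB` (procedure side first).
#' Claims where either side is indeterminate get `INDETERMINATE`; the ten
#' labels partition all claims. The two discordant subgroups `LR` and `RL`
#' are the wrong-site screening targets.
#'
#' @inheritParams claim_sides
#' @return Factor of subgroup labels, one per claim, levels [SUBGROUPS].
#' @export
assign_subgroup <- function(claims, map) {
  sides <- claim_sides(claims, map)
  side_pair_to_subgroup(sides$procedure_side, sides$diagnosis_side)
}

#' Rule-based laterality-conflict flag
#'
#' The baseline screening rule: flag a claim if and only if its subgroup is
#' `LR` (left-side procedures, right-side diagnoses) or `RL`.
#'
#' @inheritParams claim_sides
#' @return Logical vector, one per claim.
#' @export
rule_flag <- function(claims, map) {
  assign_subgroup(claims, map) %in% c("LR", "RL")
}

#' Select the study population
#'
#' Applies the test-set selection filters in order:
#'
#' 1. attending-physician specialty equals `specialty` (orthopedic surgery
#'    in the motivating setting; the code value is configuration because CMS
#'    specialty tables vary by file vintage);
#' 2. identifiable laterality: at least one procedure code and one diagnosis
#'    code resolve to a body part with side `LEFT`, `RIGHT` or `BILATERAL`;
#' 3. claims whose only procedures are infusion-device insertions are
#'    excluded (the insertion site is clinician-determined and rarely
#'    documented).
#'
#' A selection-flow count report (population-flow style) is attached as
#' `attr(x, "selection_flow")`.
#'
#' @inheritParams claim_sides
#' @param specialty Specialty code string to retain.
#' @return The filtered [claim_set] with a `selection_flow` attribute.
#' @export
filter_study_population <- function(claims, map, specialty = "20") {
  stopifnot(inherits(claims, "claim_set"))
  n_input <- nrow(claims)

  keep_spec <- claims$specialty_code == specialty
  step1 <- claims[keep_spec, , drop = FALSE]

  proc_meta <- explode_codes(step1, "procedure_codes", map)
  dx_meta <- explode_codes(step1, "diagnosis_codes", map)
  lateralized <- function(meta) {
    meta$laterality %in% c("LEFT", "RIGHT", "BILATERAL") & !is.na(meta$body_part)
  }
  proc_ok <- unique(proc_meta$claim_id[lateralized(proc_meta)])
  dx_ok <- unique(dx_meta$claim_id[lateralized(dx_meta)])
  keep_lat <- step1$claim_id %in% proc_ok & step1$claim_id %in% dx_ok
  step2 <- step1[keep_lat, , drop = FALSE]

  proc_meta2 <- proc_meta[proc_meta$claim_id %in% step2$claim_id, , drop = FALSE]
  infusion_only <- tapply(
    proc_meta2$is_infusion_device_insertion, proc_meta2$claim_id, all
  )
  drop_inf <- names(infusion_only)[infusion_only]
  step3 <- step2[!step2$claim_id %in% drop_inf, , drop = FALSE]

  flow <- tibble(
    step = c(
      "input", "specialty_match", "identifiable_laterality",
      "infusion_only_excluded"
    ),
    n_retained = c(n_input, nrow(step1), nrow(step2), nrow(step3)),
    n_dropped = c(
      0L, n_input - nrow(step1), nrow(step1) - nrow(step2),
      nrow(step2) - nrow(step3)
    )
  )
  attr(step3, "selection_flow") <- flow
  attr(step3, "provenance") <- attr(claims, "provenance")
  step3
}

# long form: one row per (claim, code) with metadata
explode_codes <- function(claims, column, map) {
  lens <- lengths(claims[[column]])
  codes <- unlist(claims[[column]], use.names = FALSE)
  meta <- resolve_code(map, codes, quiet = TRUE)
  meta$claim_id <- rep(claims$claim_id, lens)
  meta
}
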