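# Shared fixtures: built in code, no stored data.

# quick claim_set constructor from parallel lists of code vectors
make_claims <- function(procs, dxs, specialty = "20", year = 2020L, truth = NULL) {
  n <- length(procs)
  claim_set(tibble::tibble(
    claim_id = sprintf("F%04d", seq_len(n)),
    year = year,
    specialty_code = specialty,
    procedure_codes = procs,
    diagnosis_codes = dxs,
    truth = truth %||% vector("list", n)
  ), provenance = "test fixture")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal laterality-free map for hand-computed association examples
toy_map <- function() {
  code_map(tibble::tibble(
    code_or_prefix = c("P100000", "P200000", "D10", "D20", "D30"),
    system = c("PCS", "PCS", "CM", "CM", "CM"),
    body_part = NA_character_,
    laterality = "none",
    is_general = FALSE,
    is_infusion_device_insertion = FALSE
  ))
}

# small default synthetic study conditions, scaled down for unit tests
small_config <- function(n = 2000L, seed = 42L, ...) {
  generator_config(n_claims = n, seed = seed, ...)
}

# mirror a synthetic-universe code list left<->right (grammar-aware)
swap_universe_sides <- function(codes) {
  vapply(codes, function(code) {
    if (grepl("^(0SR|0JH0)", code)) {
      side <- substr(code, 5, 5)
      if (side %in% c("R", "L")) {
        substr(code, 5, 5) <- c(R = "L", L = "R")[side]
      }
    } else if (grepl("^M[0-9]{3}$", code)) {
      digit <- substr(code, 4, 4)
      if (digit %in% c("1", "2")) {
        substr(code, 4, 4) <- c(`1` = "2", `2` = "1")[digit]
      }
    }
    code
  }, character(1), USE.NAMES = FALSE)
}

truth_field <- function(claims, field, default = NA) {
  vapply(claims$truth, function(t) {
    if (is.null(t) || is.null(t[[field]]) || length(t[[field]]) == 0) default else t[[field]]
  }, default)
}
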