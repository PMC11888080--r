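#' Generator configuration
#'
#' Parameters of the condition-first synthetic claims generator. Each claim
#' starts from a latent condition (a body part and a side); the condition
#' emits a justifying diagnosis and the matching procedure, so
#' procedure-diagnosis association is a real statistical property of the
#' corpus rather than an artifact of the scorer. Documentation noise,
#' general-diagnosis justifications, proximity substitutions and planted
#' wrong-site errors then perturb what is written down.
#'
#' @param n_claims Number of claims to generate.
#' @param n_body_parts Number of synthetic body parts; consecutive pairs
#'   (1,2), (3,4), ... are anatomically proximate.
#' @param conditions_per_claim Mean number of extra comorbidity diagnoses
#'   (Poisson).
#' @param p_wrong_site Probability a claim is a planted wrong-site error.
#'   Errors are planted only as lateralized documentation of the true
#'   condition (a wrong-site case is, by definition, one where an
#'   opposite-side lateralized diagnosis is on record).
#' @param p_unspecified_side,p_no_laterality Documentation-noise
#'   probabilities: the justifying diagnosis is written with an unspecified
#'   side, or as a body-part code without laterality.
#' @param p_general_justification Probability the procedure is justified
#'   only by a general diagnosis with no body part (gangrene-style).
#' @param p_proximity_pair Probability the justifying diagnosis names the
#'   proximate partner part (same side).
#' @param p_secondary_condition Probability of one extra lateralized
#'   diagnosis on an unrelated body part (a condition that is documented but
#'   not treated); these are what place non-error claims in the discordant
#'   subgroups.
#' @param p_different_body_part Among planted errors, probability the error
#'   is a different-body-part error (procedure moved to a non-proximate part
#'   on the opposite side) rather than a same-part side flip.
#' @param p_infusion_only Probability the claim's only procedure is an
#'   infusion-device insertion.
#' @param p_other_specialty Probability the attending specialty is not the
#'   configured surgical specialty.
#' @param n_comorbidity_codes Size of the shared comorbidity code pool.
#' @param specialty_code,other_specialty_codes Specialty code values.
#' @param years Calendar years to sample claim years from.
#' @param seed Integer seed; every stochastic operation takes an explicit
#'   seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_claims = 100000L,
                             n_body_parts = 12L,
                             conditions_per_claim = 2,
                             p_wrong_site = 0.02,
                             p_unspecified_side = 0.05,
                             p_no_laterality = 0.10,
                             p_general_justification = 0.10,
                             p_proximity_pair = 0.02,
                             p_secondary_condition = 0.15,
                             p_different_body_part = 0.30,
                             p_infusion_only = 0.01,
                             p_other_specialty = 0.02,
                             n_comorbidity_codes = 30L,
                             specialty_code = "20",
                             other_specialty_codes = c("11", "50"),
                             years = 2017:2019,
                             seed = 20170101L) {
  cfg <- list(
    n_claims = as.integer(n_claims),
    n_body_parts = as.integer(n_body_parts),
    conditions_per_claim = conditions_per_claim,
    p_wrong_site = p_wrong_site,
    p_unspecified_side = p_unspecified_side,
    p_no_laterality = p_no_laterality,
    p_general_justification = p_general_justification,
    p_proximity_pair = p_proximity_pair,
    p_secondary_condition = p_secondary_condition,
    p_different_body_part = p_different_body_part,
    p_infusion_only = p_infusion_only,
    p_other_specialty = p_other_specialty,
    n_comorbidity_codes = as.integer(n_comorbidity_codes),
    specialty_code = as.character(specialty_code),
    other_specialty_codes = as.character(other_specialty_codes),
    years = as.integer(years),
    seed = as.integer(seed)
  )
  probs <- cfg[grepl("^p_", names(cfg))]
  bad <- names(probs)[vapply(probs, function(p) p < 0 || p > 1, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("probabilities must be in [0,1]: %s", paste(bad, collapse = ", ")),
      class = "lateraleye_config_error"
    )
  }
  if (cfg$n_claims < 1L) {
    abort("n_claims must be >= 1", class = "lateraleye_config_error")
  }
  mode_sum <- p_unspecified_side + p_no_laterality + p_general_justification + p_proximity_pair
  if (mode_sum > 1) {
    abort("documentation-mode probabilities must sum to at most 1",
      class = "lateraleye_config_error"
    )
  }
  if (cfg$n_body_parts < 2L && p_proximity_pair > 0) {
    abort("proximity pairs require at least 2 body parts",
      class = "lateraleye_config_error"
    )
  }
  structure(cfg, class = "generator_config")
}

part_char <- function(i) substr("123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", i, i)

#' Build the synthetic code universe
#'
#' Constructs a [code_map] over `n_body_parts` synthetic parts following a
#' fixed grammar:
#'
#' * PCS replacement codes `0SR<part><side>JZ` with side characters `R`, `L`
#'   and `B` (bilateral);
#' * infusion-device insertion codes `0JH0<side>WZ`;
#' * CM diagnosis codes `M<part:2 digits><side digit>` with the ICD-style
#'   side digits 1 = right, 2 = left, 3 = bilateral, 9 = unspecified;
#' * no-laterality body-part codes `Z<part>0`, general justifying codes
#'   `E<part>5` (no body part, `is_general`), and a shared comorbidity pool
#'   `I<k>9`.
#'
#' Left and right variants share a stem, so the association model's backoff
#' levels are meaningful. Consecutive parts form the proximity relation.
#' Construction is deterministic.
#'
#' @param config A [generator_config].
#' @return A [code_map] whose `"universe"` attribute carries the generator's
#'   bookkeeping tables.
#' @export
build_code_universe <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  B <- config$n_body_parts
  if (B > 35L) {
    abort("the synthetic grammar supports at most 35 body parts",
      class = "lateraleye_config_error"
    )
  }
  parts <- sprintf("part%02d", seq_len(B))
  pp <- sprintf("%02d", seq_len(B))
  pc <- vapply(seq_len(B), part_char, character(1))

  side_tbl <- expand.grid(
    part = seq_len(B), side = c("R", "L", "B"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  lat_name <- c(R = "right", L = "left", B = "bilateral")
  digit <- c(R = "1", L = "2", B = "3")

  pcs <- tibble(
    code_or_prefix = paste0("0SR", pc[side_tbl$part], side_tbl$side, "JZ"),
    system = "PCS",
    body_part = parts[side_tbl$part],
    laterality = lat_name[side_tbl$side],
    is_general = FALSE,
    is_infusion_device_insertion = FALSE,
    stem = paste0("repl_", parts[side_tbl$part])
  )
  infusion <- tibble(
    code_or_prefix = paste0("0JH0", c("R", "L"), "WZ"),
    system = "PCS",
    body_part = "vascular_access",
    laterality = c("right", "left"),
    is_general = FALSE,
    is_infusion_device_insertion = TRUE,
    stem = "infusion_device_insertion"
  )
  cm_sided <- tibble(
    code_or_prefix = paste0("M", pp[side_tbl$part], digit[side_tbl$side]),
    system = "CM",
    body_part = parts[side_tbl$part],
    laterality = lat_name[side_tbl$side],
    is_general = FALSE,
    is_infusion_device_insertion = FALSE,
    stem = paste0("dx_", parts[side_tbl$part])
  )
  cm_unspec <- tibble(
    code_or_prefix = paste0("M", pp, "9"),
    system = "CM", body_part = parts, laterality = "unspecified",
    is_general = FALSE, is_infusion_device_insertion = FALSE,
    stem = paste0("dx_", parts)
  )
  cm_nolat <- tibble(
    code_or_prefix = paste0("Z", pp, "0"),
    system = "CM", body_part = parts, laterality = "none",
    is_general = FALSE, is_infusion_device_insertion = FALSE,
    stem = paste0("aftercare_", parts)
  )
  cm_general <- tibble(
    code_or_prefix = paste0("E", pp, "5"),
    system = "CM", body_part = NA_character_, laterality = "none",
    is_general = TRUE, is_infusion_device_insertion = FALSE,
    stem = paste0("E", pp, "5")
  )
  comorb <- tibble(
    code_or_prefix = paste0("I", sprintf("%02d", seq_len(config$n_comorbidity_codes)), "9"),
    system = "CM", body_part = NA_character_, laterality = "none",
    is_general = FALSE, is_infusion_device_insertion = FALSE,
    stem = NA_character_
  )

  partner <- ifelse(seq_len(B) %% 2L == 1L, seq_len(B) + 1L, seq_len(B) - 1L)
  partner[partner > B] <- NA_integer_
  pairs <- which(seq_len(B) %% 2L == 1L & !is.na(partner))
  relations <- tibble(
    body_part_a = parts[pairs],
    body_part_b = parts[partner[pairs]],
    relation = "proximity"
  )

  map <- code_map(
    bind_rows(pcs, infusion, cm_sided, cm_unspec, cm_nolat, cm_general, comorb),
    relations
  )
  attr(map, "universe") <- list(
    config = config,
    parts = parts,
    partner = partner,
    pcs_code = function(part, side) paste0("0SR", pc[part], side, "JZ"),
    cm_lat_code = function(part, side) paste0("M", pp[part], digit[side]),
    cm_unspec_code = function(part) paste0("M", pp[part], "9"),
    cm_nolat_code = function(part) paste0("Z", pp[part], "0"),
    cm_general_code = function(part) paste0("E", pp[part], "5"),
    infusion_codes = infusion$code_or_prefix,
    comorbidity_codes = comorb$code_or_prefix
  )
  map
}

# sample one integer per row from 1..n_options excluding the (sorted) columns
# of `excluded`; vectorized shift trick
sample_excluding <- function(n_options, excluded) {
  excluded <- as.matrix(excluded)
  k <- ncol(excluded)
  n <- nrow(excluded)
  excluded <- t(apply(excluded, 1L, sort))
  if (n == 1L) excluded <- matrix(excluded, nrow = 1L)
  draw <- sample.int(n_options - k, n, replace = TRUE)
  for (j in seq_len(k)) {
    draw <- draw + (draw >= excluded[, j])
  }
  draw
}

#' Simulate a claims corpus
#'
#' Generates `config$n_claims` claims from the universe map, with full ground
#' truth on every claim. See [generator_config()] for the generative story.
#' Identical `(config, map, seed)` give identical output.
#'
#' @param config A [generator_config].
#' @param map Universe from [build_code_universe()]; built from `config` when
#'   omitted.
#' @param seed Seed for this corpus (defaults to `config$seed`); train and
#'   test corpora are two calls with different seeds over the same universe.
#' @param years Years to stamp on claims (defaults to `config$years`).
#' @param id_prefix Claim-id prefix, to keep ids distinct across corpora.
#' @return A [claim_set] with `truth` filled in.
#' @export
simulate_claims <- function(config, map = NULL, seed = config$seed,
                            years = config$years, id_prefix = "C") {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(map)) map <- build_code_universe(config)
  uni <- attr(map, "universe")
  if (is.null(uni)) {
    abort("map must come from build_code_universe()", class = "lateraleye_config_error")
  }
  B <- config$n_body_parts
  n <- config$n_claims

  withr::with_seed(as.integer(seed), {
    cond_part <- sample.int(B, n, replace = TRUE)
    cond_side <- sample(c("R", "L"), n, replace = TRUE)
    flip <- c(R = "L", L = "R")

    specialty <- rep(config$specialty_code, n)
    other <- runif(n) < config$p_other_specialty
    if (any(other)) {
      specialty[other] <- sample(config$other_specialty_codes, sum(other), replace = TRUE)
    }

    infusion_only <- runif(n) < config$p_infusion_only
    is_error <- runif(n) < config$p_wrong_site & !infusion_only
    err_dbp <- is_error & runif(n) < config$p_different_body_part

    # documentation mode of the justifying diagnosis; errors are always
    # documented lateralized (see generator_config)
    u <- runif(n)
    p1 <- config$p_general_justification
    p2 <- p1 + config$p_proximity_pair
    p3 <- p2 + config$p_unspecified_side
    p4 <- p3 + config$p_no_laterality
    mode <- rep("lateral", n)
    mode[u < p4] <- "nolat"
    mode[u < p3] <- "unspec"
    mode[u < p2] <- "prox"
    mode[u < p1] <- "general"
    mode[is_error | infusion_only] <- "lateral"
    mode[mode == "prox" & is.na(uni$partner[cond_part])] <- "lateral"

    justifier <- character(n)
    justifier[mode == "lateral"] <-
      uni$cm_lat_code(cond_part[mode == "lateral"], cond_side[mode == "lateral"])
    justifier[mode == "unspec"] <- uni$cm_unspec_code(cond_part[mode == "unspec"])
    justifier[mode == "nolat"] <- uni$cm_nolat_code(cond_part[mode == "nolat"])
    justifier[mode == "general"] <- uni$cm_general_code(cond_part[mode == "general"])
    justifier[mode == "prox"] <-
      uni$cm_lat_code(uni$partner[cond_part[mode == "prox"]], cond_side[mode == "prox"])

    proc_part <- cond_part
    proc_side <- cond_side
    proc_side[is_error] <- flip[cond_side[is_error]]
    if (any(err_dbp)) {
      excl <- cbind(cond_part[err_dbp], uni$partner[cond_part[err_dbp]])
      excl[is.na(excl)] <- 0L # parts without a partner exclude a dummy slot
      has_partner <- !is.na(uni$partner[cond_part[err_dbp]])
      sub <- integer(sum(err_dbp))
      if (any(has_partner)) {
        sub[has_partner] <- sample_excluding(B, excl[has_partner, , drop = FALSE])
      }
      if (any(!has_partner)) {
        sub[!has_partner] <- sample_excluding(
          B, cbind(excl[!has_partner, 1, drop = FALSE])
        )
      }
      proc_part[err_dbp] <- sub
    }
    procedure <- uni$pcs_code(proc_part, proc_side)
    procedure[infusion_only] <- sample(uni$infusion_codes, sum(infusion_only), replace = TRUE)

    # secondary documented-but-untreated condition on an unrelated part
    has_sec <- runif(n) < config$p_secondary_condition
    sec_code <- rep(NA_character_, n)
    if (any(has_sec)) {
      idx <- which(has_sec)
      excl4 <- cbind(
        cond_part[idx], uni$partner[cond_part[idx]],
        proc_part[idx], uni$partner[proc_part[idx]]
      )
      excl4[infusion_only[idx], ] <- NA_integer_ # infusion claims exclude nothing
      sec_part <- integer(length(idx))
      for (i in seq_along(idx)) {
        ex <- unique(excl4[i, !is.na(excl4[i, ])])
        if (length(ex) >= B) {
          sec_part[i] <- NA_integer_
          next
        }
        pool <- setdiff(seq_len(B), ex)
        sec_part[i] <- pool[sample.int(length(pool), 1L)]
      }
      sec_side <- sample(c("R", "L"), length(idx), replace = TRUE)
      ok <- !is.na(sec_part)
      sec_code[idx[ok]] <- uni$cm_lat_code(sec_part[ok], sec_side[ok])
    }

    n_com <- rpois(n, config$conditions_per_claim)
    com_flat <- sample(uni$comorbidity_codes, sum(n_com), replace = TRUE)
    com_split <- split(com_flat, rep.int(seq_len(n), n_com))
    comorbs <- vector("list", n)
    comorbs[as.integer(names(com_split))] <- lapply(com_split, unique)

    diagnosis_codes <- vector("list", n)
    for (i in seq_len(n)) {
      dx <- c(
        if (!infusion_only[i]) justifier[i],
        if (!is.na(sec_code[i])) sec_code[i],
        comorbs[[i]]
      )
      if (is.null(dx)) dx <- uni$comorbidity_codes[1L] # never emit an empty list
      diagnosis_codes[[i]] <- dx
    }

    nonerror_kind <- c(
      lateral = "NONE", unspec = "UNSPECIFIED_SIDE", nolat = "NO_LATERALITY",
      general = "GENERAL_DIAGNOSIS", prox = "PROXIMITY"
    )[mode]
    nonerror_kind[is_error | infusion_only] <- "NONE"
    error_kind <- rep("NONE", n)
    error_kind[is_error] <- if_else(err_dbp[is_error], "DIFFERENT_BODY_PART", "SAME_BODY_PART")

    truth <- purrr::pmap(
      list(is_error, error_kind, nonerror_kind, infusion_only),
      function(e, ek, nk, inf) {
        list(
          is_error = e, error_kind = ek, nonerror_kind = nk,
          justifying_diagnosis_index = if (e || inf) NA_integer_ else 1L
        )
      }
    )

    claims <- tibble(
      claim_id = sprintf("%s%08d", id_prefix, seq_len(n)),
      year = sample(rep(years, 2L), n, replace = TRUE),
      specialty_code = specialty,
      procedure_codes = as.list(procedure),
      diagnosis_codes = diagnosis_codes,
      truth = truth
    )
    claim_set(claims, provenance = sprintf("synthetic (seed %d)", as.integer(seed)))
  })
}

#' Tabulate ground truth
#'
#' Exact counts of claims by laterality subgroup (when a map is supplied),
#' error status and error/nonerror kind. Marginals sum to the number of
#' claims.
#'
#' @param claims A [claim_set] where every claim carries truth.
#' @param map Optional [code_map] for the subgroup dimension.
#' @return A count tibble.
#' @export
truth_summary <- function(claims, map = NULL) {
  stopifnot(inherits(claims, "claim_set"))
  if (any(vapply(claims$truth, is.null, logical(1)))) {
    abort("every claim must carry a truth annotation", class = "lateraleye_validation_error")
  }
  tab <- tibble(
    is_error = vapply(claims$truth, function(t) isTRUE(t$is_error), logical(1)),
    error_kind = vapply(claims$truth, function(t) t$error_kind, character(1)),
    nonerror_kind = vapply(claims$truth, function(t) t$nonerror_kind, character(1))
  )
  if (!is.null(map)) {
    tab$subgroup <- as.character(assign_subgroup(claims, map))
    count(tab, .data$subgroup, .data$is_error, .data$error_kind, .data$nonerror_kind,
      name = "n"
    )
  } else {
    count(tab, .data$is_error, .data$error_kind, .data$nonerror_kind, name = "n")
  }
}

claim_truth_field <- function(claims, field, default = NA) {
  vapply(claims$truth, function(t) {
    if (is.null(t) || is.null(t[[field]])) default else t[[field]]
  }, default)
}
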