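#' Association-outlier scoring of procedure-diagnosis pairs
#'
#' The association model learns, from a training corpus, how strongly each
#' procedure is substantiated by each diagnosis, and flags claims containing
#' a procedure that no recorded diagnosis substantiates. Counting is at the
#' claim level: each distinct (procedure key, diagnosis key) pair is counted
#' once per claim, and marginals count claims containing the key.
#'
#' Counts are kept at three backoff levels:
#'
#' 1. `code` — the full procedure and diagnosis codes;
#' 2. `stem` — laterality-stripped code families. Because stripping side
#'    from both codes would make a left-procedure/right-diagnosis pair
#'    indistinguishable from a correct one, the stripped procedure key
#'    carries the pairwise side relation: `=` (sides agree), `x` (sides
#'    conflict) or `.` (at least one code has no usable side). Codes without
#'    a body part (general diagnoses, comorbidities) keep their own code.
#' 3. `body_part` — body-part keys, again with the side relation on the
#'    procedure key.
#'
#' The final score of a pair is the maximum over levels, so a rare full-code
#' pair can still be substantiated by a well-attested stem or body-part
#' association (this is what lets unspecified-side and general diagnoses
#' clear lateralized procedures), while a side-conflicting pair stays rare
#' at every level.
#'
#' Two score modes, both mapped into \[0, 1\] so a probability-style
#' threshold applies:
#'
#' * `confidence` (default): the Laplace-smoothed conditional probability of
#'   the procedure key among pairs involving the diagnosis key,
#'   `s = (c(p,d) + alpha) / (C(d) + alpha * |P|)`, where `C(d)` is the total
#'   pair count for `d` and `|P|` the number of distinct procedure keys at
#'   that level. Scores over the procedure universe sum to one for every
#'   diagnosis key.
#' * `lift`: `lambda = (c(p,d)+alpha) * (n+alpha) /
#'   ((c(p)+alpha) * (c(d)+alpha))` with claim-containment marginals,
#'   reported as `s = lambda / (lambda + 1)` (independence maps to 0.5).
#'
#' @param claims Training [claim_set] (nonempty).
#' @param map A [code_map].
#' @param alpha Positive Laplace smoothing constant. The smoothing floor is
#'   what ranks never-seen pairs below seen ones without degeneracy.
#' @param mode `"confidence"` or `"lift"`.
#' @return An `association_table` holding per-level pair counts, marginals,
#'   the smoothing constant, the mode and the code map used for key
#'   resolution.
#' @export
train_associations <- function(claims, map, alpha = 1, mode = c("confidence", "lift")) {
  stopifnot(inherits(claims, "claim_set"))
  mode <- match.arg(mode)
  if (nrow(claims) == 0) {
    abort("cannot train on an empty claim set", class = "lateraleye_validation_error")
  }
  if (!is.numeric(alpha) || alpha <= 0) {
    abort("alpha must be a positive real", class = "lateraleye_config_error")
  }

  pairs <- claim_pairs(claims, map)
  levels <- lapply(BACKOFF_LEVELS, function(lv) {
    keyed <- distinct(tibble(
      claim = pairs$claim,
      p_key = pairs[[paste0("p_", lv)]],
      d_key = pairs[[paste0("d_", lv)]]
    ))
    counts <- count(keyed, .data$p_key, .data$d_key, name = "n")
    d_totals <- summarise(
      group_by(counts, .data$d_key),
      pair_total = sum(.data$n), .groups = "drop"
    )
    d_claims <- count(distinct(keyed[, c("claim", "d_key")]), .data$d_key, name = "n_claims")
    p_claims <- count(distinct(keyed[, c("claim", "p_key")]), .data$p_key, name = "n_claims")
    list(
      counts = counts,
      d_totals = left_join(d_totals, d_claims, by = "d_key"),
      p_claims = p_claims,
      n_p_keys = nrow(p_claims)
    )
  })
  names(levels) <- BACKOFF_LEVELS

  structure(
    list(
      levels = levels,
      alpha = alpha,
      mode = mode,
      backoff_levels = BACKOFF_LEVELS,
      n_claims_trained = nrow(claims),
      map = map
    ),
    class = "association_table"
  )
}

BACKOFF_LEVELS <- c("code", "stem", "body_part")

side_relation <- function(p_lat, d_lat) {
  out <- rep(".", length(p_lat))
  both <- p_lat %in% c("LEFT", "RIGHT") & d_lat %in% c("LEFT", "RIGHT")
  out[both & p_lat == d_lat] <- "="
  out[both & p_lat != d_lat] <- "x"
  out
}

# Backoff keys for a long table of procedure/diagnosis code pairs with
# resolved metadata. Input needs columns p_code, d_code, p_body_part,
# d_body_part, p_laterality, d_laterality, p_stem_raw, d_stem_raw; adds the
# key columns p_stem, d_stem, p_body_part_key, d_body_part_key.
pair_keys <- function(df) {
  rel <- side_relation(df$p_laterality, df$d_laterality)
  p_sited <- !is.na(df$p_body_part)
  d_sited <- !is.na(df$d_body_part)
  df$p_stem <- if_else(p_sited, paste0(df$p_stem_raw, "|", rel), df$p_code)
  df$d_stem <- if_else(d_sited, df$d_stem_raw, df$d_code)
  df$p_body_part_key <- if_else(p_sited, paste0("bp:", df$p_body_part, "|", rel), df$p_code)
  df$d_body_part_key <- if_else(d_sited, paste0("bp:", df$d_body_part), df$d_code)
  df
}

# one row per claim x distinct procedure code x distinct diagnosis code,
# with key columns named p_<level>/d_<level> for each backoff level
claim_pairs <- function(claims, map) {
  pm <- explode_codes(claims, "procedure_codes", map)
  dm <- explode_codes(claims, "diagnosis_codes", map)
  pm <- distinct(tibble(
    claim = pm$claim_id, p_code = pm$code, p_body_part = pm$body_part,
    p_laterality = pm$laterality, p_stem_raw = pm$stem
  ))
  dm <- distinct(tibble(
    claim = dm$claim_id, d_code = dm$code, d_body_part = dm$body_part,
    d_laterality = dm$laterality, d_stem_raw = dm$stem
  ))
  df <- inner_join(pm, dm, by = "claim", relationship = "many-to-many")
  df <- pair_keys(df)
  # level-key columns: p_code/d_code already are the "code" level keys
  df$p_body_part <- df$p_body_part_key
  df$d_body_part <- df$d_body_part_key
  df$p_body_part_key <- NULL
  df$d_body_part_key <- NULL
  df
}

# smoothed score for aligned key vectors at one backoff level
level_score <- function(table, level, p_key, d_key) {
  lv <- table$levels[[level]]
  alpha <- table$alpha
  q <- tibble(p_key = p_key, d_key = d_key)
  q <- left_join(q, lv$counts, by = c("p_key", "d_key"))
  q$n[is.na(q$n)] <- 0
  if (table$mode == "confidence") {
    q <- left_join(q, lv$d_totals[, c("d_key", "pair_total")], by = "d_key")
    q$pair_total[is.na(q$pair_total)] <- 0
    (q$n + alpha) / (q$pair_total + alpha * lv$n_p_keys)
  } else {
    q <- left_join(q, rename(lv$p_claims, p_n = "n_claims"), by = "p_key")
    q <- left_join(q, rename(lv$d_totals[, c("d_key", "n_claims")], d_n = "n_claims"),
      by = "d_key"
    )
    q$p_n[is.na(q$p_n)] <- 0
    q$d_n[is.na(q$d_n)] <- 0
    n <- table$n_claims_trained
    lambda <- ((q$n + alpha) * (n + alpha)) / ((q$p_n + alpha) * (q$d_n + alpha))
    lambda / (lambda + 1)
  }
}

# scores for a prepared pair table (from claim_pairs); max over backoff levels
score_pairs <- function(table, pairs) {
  per_level <- vapply(
    table$backoff_levels,
    function(lv) {
      level_score(table, lv, pairs[[paste0("p_", lv)]], pairs[[paste0("d_", lv)]])
    },
    numeric(nrow(pairs))
  )
  if (nrow(pairs) == 1L) per_level <- matrix(per_level, nrow = 1L)
  do.call(pmax, as.data.frame(per_level))
}

#' Score a single procedure-diagnosis pair
#'
#' Evaluates the trained association score for given code pairs (vectorized
#' over `p_code` / `d_code`). Keys unseen at a level fall through to its
#' smoothing floor; the returned score is the maximum over backoff levels
#' and always lies in \[0, 1\].
#'
#' @param table An `association_table` from [train_associations()].
#' @param p_code,d_code Procedure and diagnosis code strings (recycled to a
#'   common length).
#' @return Numeric vector of association scores.
#' @export
association_score <- function(table, p_code, d_code) {
  stopifnot(inherits(table, "association_table"))
  k <- max(length(p_code), length(d_code))
  p_code <- rep_len(as.character(p_code), k)
  d_code <- rep_len(as.character(d_code), k)
  pm <- resolve_code(table$map, p_code, quiet = TRUE)
  dm <- resolve_code(table$map, d_code, quiet = TRUE)
  df <- tibble(
    p_code = p_code, d_code = d_code,
    p_body_part = pm$body_part, d_body_part = dm$body_part,
    p_laterality = pm$laterality, d_laterality = dm$laterality,
    p_stem_raw = pm$stem, d_stem_raw = dm$stem
  )
  df <- pair_keys(df)
  df$p_body_part <- df$p_body_part_key
  df$d_body_part <- df$d_body_part_key
  score_pairs(table, df)
}

#' Score claims for unsubstantiated procedures
#'
#' Each procedure's substantiation score is the maximum association score
#' over the claim's diagnoses; the claim score is the minimum over its
#' procedures (one unexplained procedure is enough to make the claim
#' suspect). A claim is flagged when its score falls strictly below the
#' threshold, so never-seen pairs at the smoothing floor flag at any
#' threshold above the floor.
#'
#' @param claims A [claim_set].
#' @param table An `association_table`.
#' @param threshold Optional threshold object from [select_threshold()] or a
#'   bare number; without it, `flagged` is `NA`.
#' @return A tibble with `claim_id`, `claim_score`, `flagged`, and a
#'   `procedure_scores` list column holding the per-procedure explanation
#'   trace (procedure code, its score, and the best-supporting diagnosis).
#' @export
score_claims <- function(claims, table, threshold = NULL) {
  stopifnot(inherits(claims, "claim_set"), inherits(table, "association_table"))
  thr_value <- if (is.null(threshold)) {
    NA_real_
  } else if (is.numeric(threshold)) {
    threshold
  } else {
    threshold$value
  }
  pairs <- claim_pairs(claims, table$map)
  pairs$score <- score_pairs(table, pairs)

  per_proc <- summarise(
    group_by(pairs, .data$claim, .data$p_code),
    score = max(.data$score),
    best_diagnosis = .data$d_code[which.max(.data$score)],
    .groups = "drop"
  )
  per_claim <- summarise(
    group_by(per_proc, .data$claim),
    claim_score = min(.data$score),
    .groups = "drop"
  )
  trace <- split(
    per_proc[, c("p_code", "score", "best_diagnosis")],
    per_proc$claim
  )
  out <- tibble(
    claim_id = claims$claim_id,
    claim_score = per_claim$claim_score[match(claims$claim_id, per_claim$claim)],
    procedure_scores = unname(trace[claims$claim_id])
  )
  out$flagged <- if (is.na(thr_value)) NA else out$claim_score < thr_value
  out
}

#' Precision-recall operating points
#'
#' Sweeps the flagging threshold over every distinct claim score (plus a
#' flag-everything point) and computes precision and recall of `score < t`
#' against the error labels. Points that flag nothing are dropped
#' (precision is undefined there). Recall is nondecreasing in the
#' threshold.
#'
#' @param scores Numeric claim scores.
#' @param labels Logical error labels, same length, at least one `TRUE`.
#' @return Tibble with `threshold`, `n_flagged`, `precision`, `recall`,
#'   `f1`, ordered by threshold.
#' @export
precision_recall_points <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length", class = "lateraleye_validation_error")
  }
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) {
    abort("scores and labels must not contain NA", class = "lateraleye_validation_error")
  }
  n_pos <- sum(labels)
  if (n_pos == 0) {
    abort("at least one positive label is required (recall undefined)",
      class = "lateraleye_validation_error"
    )
  }
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  cum_flagged <- seq_along(s)
  cum_pos <- cumsum(l)
  # thresholds: strictly-below flagging at each distinct score captures the
  # prefix ending just before that score's first occurrence
  first_idx <- which(!duplicated(s))
  thresholds <- c(s[first_idx], Inf)
  flagged <- c(first_idx - 1L, length(s))
  pos <- c(ifelse(first_idx == 1L, 0L, cum_pos[pmax(first_idx - 1L, 1L)]), n_pos)
  keep <- flagged > 0L
  precision <- pos[keep] / flagged[keep]
  recall <- pos[keep] / n_pos
  f1 <- if_else(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  tibble(
    threshold = thresholds[keep],
    n_flagged = flagged[keep],
    precision = precision,
    recall = recall,
    f1 = f1
  )
}

#' Select an operating threshold
#'
#' * `max_f1` (default): the point maximizing F1; ties break toward higher
#'   precision, then toward the lower threshold.
#' * `precision_floor`: the highest-recall point with precision at or above
#'   `precision_floor` (the high-precision operating stance); errors if no
#'   point attains the floor, naming the best attainable precision.
#'
#' @param points PR points from [precision_recall_points()].
#' @param rule `"max_f1"` or `"precision_floor"`.
#' @param precision_floor Required for rule `"precision_floor"`.
#' @return An `aop_threshold` object with fields `value`, `selection_rule`,
#'   `precision`, `recall`.
#' @export
select_threshold <- function(points, rule = c("max_f1", "precision_floor"),
                             precision_floor = NULL) {
  rule <- match.arg(rule)
  if (nrow(points) == 0) {
    abort("no candidate operating points", class = "lateraleye_validation_error")
  }
  eps <- 1e-12
  if (rule == "max_f1") {
    best <- points[points$f1 >= max(points$f1) - eps, , drop = FALSE]
    best <- best[best$precision >= max(best$precision) - eps, , drop = FALSE]
    chosen <- best[which.min(best$threshold), , drop = FALSE]
  } else {
    if (is.null(precision_floor)) {
      abort("precision_floor is required for rule 'precision_floor'",
        class = "lateraleye_config_error"
      )
    }
    ok <- points[points$precision >= precision_floor, , drop = FALSE]
    if (nrow(ok) == 0) {
      abort(
        sprintf(
          "no operating point attains precision %.3f; best attainable is %.3f",
          precision_floor, max(points$precision)
        ),
        class = "lateraleye_threshold_error"
      )
    }
    best <- ok[ok$recall >= max(ok$recall) - eps, , drop = FALSE]
    best <- best[best$precision >= max(best$precision) - eps, , drop = FALSE]
    chosen <- best[which.min(best$threshold), , drop = FALSE]
  }
  structure(
    list(
      value = chosen$threshold,
      selection_rule = rule,
      precision = chosen$precision,
      recall = chosen$recall
    ),
    class = "aop_threshold"
  )
}

#' @export
print.aop_threshold <- function(x, ...) {
  cat(sprintf(
    "<aop_threshold> %.4g (%s; precision %.3f, recall %.3f)\n",
    x$value, x$selection_rule, x$precision, x$recall
  ))
  invisible(x)
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf(
    "<association_table> mode=%s alpha=%g, trained on %d claims; %d code pairs\n",
    x$mode, x$alpha, x$n_claims_trained, nrow(x$levels$code$counts)
  ))
  invisible(x)
}

#' Persist and restore a trained association table
#'
#' The model is stored as a documented JSON artifact: per-level pair counts
#' and marginals, the smoothing constant, mode, training size, a version
#' tag, and the code map (entries and relations) used for key resolution.
#'
#' @param table An `association_table`.
#' @param path JSON file path.
#' @return `write_association_table()` returns `path` invisibly;
#'   `read_association_table()` returns the restored `association_table`.
#' @export
write_association_table <- function(table, path) {
  stopifnot(inherits(table, "association_table"))
  payload <- list(
    format = "lateraleye-association-table",
    version = 1L,
    alpha = table$alpha,
    mode = table$mode,
    backoff_levels = table$backoff_levels,
    n_claims_trained = table$n_claims_trained,
    levels = lapply(table$levels, function(lv) {
      list(
        counts = lv$counts, d_totals = lv$d_totals,
        p_claims = lv$p_claims, n_p_keys = lv$n_p_keys
      )
    }),
    map = list(
      entries = table$map$entries,
      relations = table$map$relations
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "lateraleye-association-table")) {
    abort("not a lateraleye association-table file", class = "lateraleye_io_error")
  }
  map <- code_map(as_tibble(payload$map$entries), as_tibble(payload$map$relations))
  levels <- lapply(payload$levels, function(lv) {
    list(
      counts = as_tibble(lv$counts),
      d_totals = as_tibble(lv$d_totals),
      p_claims = as_tibble(lv$p_claims),
      n_p_keys = lv$n_p_keys
    )
  })
  structure(
    list(
      levels = levels,
      alpha = payload$alpha,
      mode = payload$mode,
      backoff_levels = payload$backoff_levels,
      n_claims_trained = payload$n_claims_trained,
      map = map
    ),
    class = "association_table"
  )
}
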