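test_that("claim-level counting and the smoothed confidence formula are exact", {
  # corpus {P1,D1} x3, {P2,D2} x1; alpha=1; universe of 2 procedure keys:
  # score(P1|D1) = (3+1)/(3+1*2) = 0.8
  map <- toy_map()
  claims <- make_claims(
    procs = list("P100000", "P100000", "P100000", "P200000"),
    dxs = list("D10", "D10", "D10", "D20")
  )
  table <- train_associations(claims, map, alpha = 1, mode = "confidence")
  lv <- table$levels$code
  expect_equal(lv$counts$n[lv$counts$p_key == "P100000" & lv$counts$d_key == "D10"], 3L)
  expect_equal(lv$n_p_keys, 2L)
  expect_equal(association_score(table, "P100000", "D10"), 0.8)
  expect_equal(association_score(table, "P200000", "D10"), 0.2) # (0+1)/(3+2)
  expect_equal(association_score(table, "P200000", "D20"), 2 / 3)

  # duplicate codes inside one claim count once for that claim
  dup <- make_claims(
    procs = list(c("P100000", "P100000")),
    dxs = list(c("D10", "D10"))
  )
  t2 <- train_associations(dup, map, alpha = 1)
  expect_equal(t2$levels$code$counts$n, 1L)

  expect_error(
    train_associations(make_claims(procs = list(), dxs = list()), map),
    class = "lateraleye_validation_error"
  )
})

test_that("confidence scores normalize over the procedure universe", {
  cfg <- small_config(n = 3000L, seed = 61L)
  uni <- build_code_universe(cfg)
  table <- train_associations(simulate_claims(cfg, map = uni), uni, alpha = 1)
  for (level in table$backoff_levels) {
    lv <- table$levels[[level]]
    d_key <- lv$d_totals$d_key[which.max(lv$d_totals$pair_total)]
    p_keys <- lv$p_claims$p_key
    s <- lateraleye:::level_score(table, level, p_keys, rep(d_key, length(p_keys)))
    # observed keys plus the alpha floor for the (zero) unobserved remainder
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("scores are monotone in the pair count with marginals held fixed", {
  map <- toy_map()
  total <- 8L
  scores <- vapply(0:total, function(k) {
    # k pairs (P1,D1), 8-k pairs (P2,D1); side claims keep both procedure
    # keys observed and the D1 pair total fixed at 8
    procs <- c(rep("P100000", k), rep("P200000", total - k), "P100000", "P200000")
    dxs <- c(rep("D10", total), "D30", "D20")
    claims <- make_claims(procs = as.list(procs), dxs = as.list(dxs))
    table <- train_associations(claims, map, alpha = 1)
    association_score(table, "P100000", "D10")
  }, numeric(1))
  expect_equal(scores, (0:total + 1) / (total + 2))
  expect_true(all(diff(scores) > 0))
})

test_that("lift mode has the independence fixed point and stays in (0,1)", {
  map <- toy_map()
  # c(p,d) = c(p) c(d) / n exactly: the 2x2 balanced corpus
  claims <- make_claims(
    procs = list("P100000", "P100000", "P200000", "P200000"),
    dxs = list("D10", "D20", "D10", "D20")
  )
  table <- train_associations(claims, map, alpha = 1e-9, mode = "lift")
  expect_equal(association_score(table, "P100000", "D10"), 0.5, tolerance = 1e-6)
  # dependence pushes the score off 0.5 in the expected direction
  dep <- train_associations(make_claims(
    procs = list("P100000", "P100000", "P200000"),
    dxs = list("D10", "D10", "D20")
  ), map, alpha = 0.5, mode = "lift")
  expect_gt(association_score(dep, "P100000", "D10"), 0.5)
  expect_lt(association_score(dep, "P100000", "D20"), 0.5)
})

test_that("unseen pairs score at the smoothing floor", {
  cfg <- small_config(n = 2000L, seed = 71L)
  uni <- build_code_universe(cfg)
  table <- train_associations(simulate_claims(cfg, map = uni), uni, alpha = 1)
  floor_value <- max(vapply(
    table$levels, function(lv) 1 / lv$n_p_keys, numeric(1)
  ))
  got <- suppressWarnings(association_score(table, "YYYYYYY", "Y99"))
  expect_equal(got, floor_value)
  # a well-attested pair sits far above the floor
  expect_gt(association_score(table, "0SR1RJZ", "M011"), 10 * floor_value)
})

test_that("claim scoring is max over diagnoses then min over procedures", {
  map <- toy_map()
  claims <- make_claims(
    procs = list("P100000", "P200000"),
    dxs = list("D10", "D20")
  )
  table <- train_associations(make_claims(
    procs = list("P100000", "P100000", "P100000", "P200000"),
    dxs = list(c("D10", "D30"), "D10", "D10", "D20")
  ), map, alpha = 1)

  mixed <- make_claims(
    procs = list(c("P100000", "P200000")),
    dxs = list(c("D10", "D30"))
  )
  scored <- score_claims(mixed, table, threshold = 0.5)
  per_proc <- scored$procedure_scores[[1]]
  expect_setequal(per_proc$p_code, c("P100000", "P200000"))
  manual <- vapply(per_proc$p_code, function(p) {
    max(association_score(table, p, "D10"), association_score(table, p, "D30"))
  }, numeric(1))
  expect_equal(sort(per_proc$score), sort(unname(manual)))
  expect_equal(scored$claim_score, min(manual))
  # one unjustified procedure flags the whole claim (min rule)
  expect_true(scored$flagged)

  solo <- score_claims(
    make_claims(procs = list("P100000"), dxs = list("D10")),
    table, threshold = 0.5
  )
  expect_gt(solo$claim_score, 0.5)
  expect_false(solo$flagged)
})

test_that("precision-recall points match a quadratic brute-force oracle", {
  brute <- function(scores, labels) {
    out <- NULL
    for (t in c(sort(unique(scores)), Inf)) {
      flag <- scores < t
      if (!any(flag)) next
      out <- rbind(out, data.frame(
        threshold = t,
        n_flagged = sum(flag),
        precision = sum(labels[flag]) / sum(flag),
        recall = sum(labels[flag]) / sum(labels)
      ))
    }
    out
  }
  withr::with_seed(404L, {
    for (i in seq_len(200L)) {
      n <- sample(5:60, 1)
      scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force ties sometimes
      labels <- runif(n) < runif(1, 0.1, 0.9)
      if (!any(labels)) labels[sample.int(n, 1)] <- TRUE
      got <- precision_recall_points(scores, labels)
      want <- brute(scores, labels)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$n_flagged, want$n_flagged)
      expect_equal(got$precision, want$precision)
      expect_equal(got$recall, want$recall)
      expect_true(all(diff(got$recall) >= 0))
    }
  })
  expect_error(
    precision_recall_points(c(0.1, 0.2), c(FALSE, FALSE)),
    class = "lateraleye_validation_error"
  )
})

test_that("degenerate PR points behave as documented", {
  # perfectly separated scores contain a precision=1, recall=1 point
  pts <- precision_recall_points(
    c(0.1, 0.2, 0.8, 0.9),
    c(TRUE, TRUE, FALSE, FALSE)
  )
  expect_true(any(pts$precision == 1 & pts$recall == 1))
  # the flag-everything point has recall 1 and precision = prevalence
  last <- pts[nrow(pts), ]
  expect_equal(last$recall, 1)
  expect_equal(last$precision, 0.5)
})

test_that("threshold selection follows the F1 rule with precision tie-break", {
  pt <- function(threshold, precision, recall) {
    tibble::tibble(
      threshold = threshold, n_flagged = 10L, precision = precision,
      recall = recall, f1 = 2 * precision * recall / (precision + recall)
    )
  }
  # F1(0.9, 0.5) == F1(0.5, 0.9): tie resolves to the higher-precision point
  two <- dplyr::bind_rows(pt(0.2, 0.9, 0.5), pt(0.8, 0.5, 0.9))
  chosen <- select_threshold(two, "max_f1")
  expect_equal(chosen$value, 0.2)
  expect_equal(chosen$precision, 0.9)

  single <- pt(0.3, 0.7, 0.6)
  expect_equal(select_threshold(single, "max_f1")$value, 0.3)

  expect_error(
    select_threshold(single[0, ], "max_f1"),
    class = "lateraleye_validation_error"
  )
})

test_that("precision-floor selection maximizes recall subject to the floor", {
  withr::with_seed(17L, {
    scores <- runif(300)
    labels <- scores < 0.35 | runif(300) < 0.1
    pts <- precision_recall_points(scores, labels)
    chosen <- select_threshold(pts, "precision_floor", precision_floor = 0.8)
    expect_gte(chosen$precision, 0.8)
    # brute-force: no candidate with precision >= 0.8 has higher recall
    ok <- pts[pts$precision >= 0.8, ]
    expect_equal(chosen$recall, max(ok$recall))

    unattainable <- tibble::tibble(
      threshold = c(0.2, 0.5), n_flagged = c(4L, 9L),
      precision = c(0.6, 0.5), recall = c(0.3, 0.7), f1 = c(0.4, 0.58)
    )
    expect_error(
      select_threshold(unattainable, "precision_floor", precision_floor = 0.8),
      class = "lateraleye_threshold_error"
    )
    expect_error(
      select_threshold(unattainable, "precision_floor", precision_floor = 0.8),
      "best attainable"
    )
    expect_error(
      select_threshold(pts, "precision_floor"),
      class = "lateraleye_config_error"
    )
  })
})

test_that("association tables persist losslessly through JSON", {
  cfg <- small_config(n = 500L, seed = 88L)
  uni <- build_code_universe(cfg)
  claims <- simulate_claims(cfg, map = uni)
  table <- train_associations(claims, uni, alpha = 0.5, mode = "confidence")
  path <- withr::local_tempfile(fileext = ".json")
  write_association_table(table, path)
  back <- read_association_table(path)
  expect_equal(back$alpha, table$alpha)
  expect_equal(back$n_claims_trained, table$n_claims_trained)
  probe_p <- c("0SR1RJZ", "0SR1LJZ", "0SR2RJZ")
  probe_d <- c("M011", "M012", "I019")
  expect_equal(
    association_score(back, probe_p, probe_d),
    association_score(table, probe_p, probe_d)
  )
})
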