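dmap <- default_code_map()

test_that("review reproduces the worked orthopedic adjudications", {
  claims <- make_claims(
    procs = list(
      "0SRC0J9", # right knee replacement
      "0Y6H0Z2", # right lower-leg detachment
      "0PR80JZ", # left glenoid cavity replacement
      "0RRJ0J6", # right shoulder joint replacement
      c("0LS40ZZ", "0RRK0JZ"), # left arm tendon + left shoulder
      c("0SPD08Z", "0SRD0J9"), # left knee removal + replacement
      "0SRB02A" # left hip replacement
    ),
    dxs = list(
      c("M1712", "F17210"), # left knee OA only -> error, same part
      c("E1152", "I96", "N186", "E785"), # gangrene justifies detachment
      c("M75120", "G8918", "M109"), # unspecified-side rotator cuff tear
      c("S42242A", "Z85528"), # left humerus fracture vs right shoulder
      c("M19021", "E785", "I10"), # right elbow OA only
      c("Z4733", "E785", "I10"), # knee aftercare, no laterality
      c("M1611", "I10", "F329") # right hip OA only
    )
  )
  got <- auto_review(claims, dmap)
  expect_equal(
    got$is_error,
    c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  expect_equal(
    got$error_kind,
    c(
      "SAME_BODY_PART", "NONE", "NONE", "DIFFERENT_BODY_PART",
      "DIFFERENT_BODY_PART", "NONE", "SAME_BODY_PART"
    )
  )
  expect_equal(
    got$nonerror_kind,
    c("NONE", "GENERAL_DIAGNOSIS", "UNSPECIFIED_SIDE", "NONE", "NONE", "NO_LATERALITY", "NONE")
  )
  # rationale traces name the deciding diagnosis
  expect_match(got$rationale[2], "E1152|I96")
  expect_match(got$rationale[3], "M75120")
})

test_that("proximity with a compatible side justifies; opposite side does not", {
  claims <- make_claims(
    procs = list("0RRJ0J6", "0RRJ0J6"),
    dxs = list("S42241A", "S42242A") # right vs left humerus fracture
  )
  got <- auto_review(claims, dmap)
  expect_equal(got$is_error, c(FALSE, TRUE))
  expect_equal(got$nonerror_kind[1], "PROXIMITY")
  expect_equal(got$error_kind[2], "DIFFERENT_BODY_PART")
})

test_that("a concurrent justified procedure clears its neighbor one level deep", {
  # left hip osteoarthritis justifies the hip replacement directly; the
  # upper-femur fixation has no diagnosis of its own (hip OA is neither the
  # same site as nor proximate to the upper femur in the map) and is cleared
  # only through the justified concurrent hip procedure
  combo <- make_claims(
    procs = list(c("0SRB049", "0QH706Z")),
    dxs = list(c("M1612", "I10"))
  )
  got <- auto_review(combo, dmap)
  expect_false(got$is_error)
  expect_equal(got$nonerror_kind, "COMBINATION")

  # without the anchoring diagnosis both procedures are unjustified
  bare <- make_claims(
    procs = list(c("0SRB049", "0QH706Z")),
    dxs = list("I10")
  )
  expect_true(auto_review(bare, dmap)$is_error)
})

test_that("review agrees exactly with ground truth on generated corpora", {
  cfg <- small_config(n = 4000L, seed = 202L)
  uni <- build_code_universe(cfg)
  claims <- simulate_claims(cfg, map = uni)
  pop <- filter_study_population(claims, uni, specialty = "20")
  got <- auto_review(pop, uni)
  expect_equal(got$is_error, truth_field(pop, "is_error"))
  expect_equal(got$error_kind, truth_field(pop, "error_kind", NA_character_))
  expect_equal(got$nonerror_kind, truth_field(pop, "nonerror_kind", NA_character_))
})

test_that("comparison reports conserve counts and handle empty flags", {
  cfg <- small_config(n = 8000L, seed = 303L)
  uni <- build_code_universe(cfg)
  train <- simulate_claims(cfg, map = uni, seed = 303L, id_prefix = "TR")
  test <- simulate_claims(cfg, map = uni, seed = 304L, id_prefix = "TE")
  pop <- filter_study_population(test, uni, specialty = "20")
  model <- train_associations(train, uni)
  report <- compare_methods(pop, uni, model, threshold = 0.2, labels = "ground_truth")

  # conservation: subcategories sum to category totals, categories to flagged
  for (i in seq_len(nrow(report$summary))) {
    s <- report$summary[i, ]
    cells <- report$cells[
      report$cells$method == s$method & report$cells$subgroup == s$subgroup,
    ]
    expect_equal(sum(cells$n), s$n_flagged)
    expect_equal(sum(cells$n[cells$category == "confirmed_error"]), s$n_error)
    expect_equal(sum(cells$n[cells$category == "confirmed_nonerror"]), s$n_nonerror)
    expect_equal(s$n_error + s$n_nonerror, s$n_flagged)
  }
  # the rule method flags every discordant claim
  rule_total <- sum(report$summary$n_flagged[report$summary$method == "rule"])
  expect_equal(rule_total, sum(report$n_subgroup$n))

  # labels from the automated review give the same report shape
  report2 <- compare_methods(pop, uni, model, threshold = 0.2, labels = "auto_review")
  expect_equal(sort(unique(report2$cells$method)), c("aop", "rule"))

  # a corpus with no discordant claims yields an empty report with
  # undefined (not zero) precisions
  clean_cfg <- generator_config(
    n_claims = 500L, p_wrong_site = 0, p_secondary_condition = 0,
    p_unspecified_side = 0, p_no_laterality = 0,
    p_general_justification = 0, p_proximity_pair = 0,
    p_infusion_only = 0, p_other_specialty = 0, seed = 7L
  )
  clean_uni <- build_code_universe(clean_cfg)
  clean <- simulate_claims(clean_cfg, map = clean_uni)
  clean_pop <- filter_study_population(clean, clean_uni, specialty = "20")
  empty <- compare_methods(
    clean_pop, clean_uni,
    train_associations(clean, clean_uni),
    threshold = 0.2, labels = "ground_truth"
  )
  expect_equal(nrow(empty$cells), 0L)
  expect_false(any(empty$pooled$precision %in% 0))
})

test_that("small-cell suppression masks 1-10 but shows 0 and 11", {
  counts <- tibble::tibble(
    method = "rule", subgroup = "LR", category = "confirmed_nonerror",
    subcategory = c("proximity", "no_laterality", "combination", "unspecified_side"),
    n = c(10L, 11L, 0L, 1L)
  )
  report <- suppress_small_cells(comparison_from_counts(counts))
  expect_equal(report$cells$masked, c(TRUE, FALSE, FALSE, TRUE))
  # totals stay exact internally
  expect_equal(report$summary$n_flagged, 22L)

  dir <- withr::local_tempdir()
  render_report(report, dir)
  rendered <- readr::read_csv(
    file.path(dir, "comparison_report.csv"),
    show_col_types = FALSE
  )
  expect_equal(rendered$n_display, c("suppressed", "11", "0", "suppressed"))
  expect_false(any(grepl("^10$|^1$", rendered$n_display)))
  expect_true(file.exists(file.path(dir, "summary.txt")))
})

test_that("rendered reports reproduce the cell counts they were built from", {
  report <- reference_review_counts()
  dir <- withr::local_tempdir()
  report$pr_points <- tibble::tibble(
    threshold = c(0.1, 0.2), n_flagged = c(5L, 9L),
    precision = c(1, 0.9), recall = c(0.4, 0.8), f1 = c(0.57, 0.85)
  )
  paths <- render_report(report, dir)
  rendered <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(rendered), nrow(report$cells))
  expect_equal(as.integer(rendered$n_display), report$cells$n)
  expect_true(file.exists(file.path(dir, "pr_points.csv")))
})
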