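cfg <- ckd_config()

test_that("the default risk matrix is total, monotone and has the expected cell counts", {
  m <- risk_matrix(cfg)
  expect_equal(dim(m), c(6, 3))
  expect_false(anyNA(m))
  expect_true(all(m %in% c("low", "moderate", "high", "very_high")))
  expect_silent(validate_risk_matrix(m))
  counts <- table(factor(m, levels = c("low", "moderate", "high", "very_high")))
  expect_equal(as.integer(counts), c(2L, 3L, 4L, 9L))
  # pinned worked cell: stage 3a + microalbuminuria -> high
  expect_equal(m["3a", "microalbuminuria"], "high")
})

test_that("a non-monotone or partial matrix is rejected unless overridden", {
  m <- risk_matrix(cfg)
  m["5", "albuminuria"] <- "low"
  expect_error(validate_risk_matrix(m), "monotone")
  expect_warning(validate_risk_matrix(m, override = TRUE), "monotone")
  m2 <- risk_matrix(cfg)
  m2["1", "normal"] <- NA
  expect_error(validate_risk_matrix(m2), "total")
})

test_that("the worked simulation example classifies as microalbuminuria, stage 3a, high risk", {
  res <- evaluate_risk_values(200.0, 50.0, cfg)
  expect_equal(res$category, "microalbuminuria")
  expect_equal(res$stage, "3a")
  expect_equal(res$risk, "high")
})

test_that("best- and worst-case panels land in the corner cells", {
  best <- evaluate_risk_values(5, 120, cfg)
  expect_equal(c(best$category, best$stage, best$risk), c("normal", "1", "low"))
  worst <- evaluate_risk_values(400, 10, cfg)
  expect_equal(c(worst$category, worst$stage, worst$risk),
               c("albuminuria", "5", "very_high"))
})

test_that("evaluating a full record composes GFR estimation, classification and matrix lookup", {
  recs <- load_records(chart_fixture())
  ev <- evaluate_risk(recs[[2]], cfg)  # male 79 y, 61 kg, creatinine 0.81, ACR 77.5
  expect_s3_class(ev, "risk_evaluation")
  expect_equal(ev$gfr_displayed, 63.8)
  expect_equal(ev$category, "microalbuminuria")
  expect_equal(ev$stage, "2")
  expect_equal(ev$risk, "moderate")
  expect_true(nzchar(ev$advice))
  expect_named(ev$comorbidities, c("sah", "dm"))
})

test_that("exactly one risk level is produced and it equals the composed classification (oracle sweep)", {
  set.seed(47)
  m <- risk_matrix(cfg)
  for (i in 1:1000) {
    prot <- runif(1, 0, 600)
    gfr <- runif(1, 1, 160)
    res <- evaluate_risk_values(prot, gfr, cfg)
    expect_length(res$risk, 1)
    expect_true(res$risk %in% c("low", "moderate", "high", "very_high"))
    expect_identical(res$category, oracle_proteinuria(prot))
    expect_identical(res$stage, oracle_stage(gfr))
    expect_identical(res$risk, m[res$stage, res$category])
  }
})

test_that("an incomplete panel yields an explicit refusal, never a partial evaluation", {
  rec <- make_complete_record(proteinuria = NA_real_)
  out <- evaluate_risk(rec, cfg)
  expect_s3_class(out, "incomplete_panel")
  expect_match(out$message, "incomplete panel")
  expect_match(out$message, "proteinuria")
  expect_null(out$risk)
  # advice text accompanies every moderate-or-worse evaluation
  ev <- evaluate_risk(make_complete_record(creatinine = 2.2, proteinuria = 500), cfg)
  expect_true(ev$risk %in% c("moderate", "high", "very_high"))
  expect_gt(nchar(ev$advice), 0)
})

test_that("the terminal-state enumeration is a bijection onto the 6 x 3 grid", {
  states <- enumerate_terminal_states(cfg)
  expect_equal(nrow(states), 18)
  expect_equal(nrow(unique(states[, c("category", "stage")])), 18)
  expect_setequal(unique(states$stage), c("1", "2", "3a", "3b", "4", "5"))
  expect_setequal(unique(states$category),
                  c("normal", "microalbuminuria", "albuminuria"))
  expect_true(all(states$risk %in% c("low", "moderate", "high", "very_high")))
  expect_equal(length(unique(states$risk)), 4)
})

test_that("screening reminders shorten as risk rises and respect the configured intervals", {
  mk <- function(risk) structure(list(risk = risk, time = "2024-03-01T09:00:00"),
                                 class = "risk_evaluation")
  due_low <- next_screening_due(mk("low"), as.Date("2024-03-01"), cfg)
  due_vh <- next_screening_due(mk("very_high"), as.Date("2024-03-01"), cfg)
  expect_equal(as.Date(due_low), as.Date("2025-03-01"),
               ignore_attr = TRUE)   # +12 months
  expect_equal(as.Date(due_vh), as.Date("2024-06-01"),
               ignore_attr = TRUE)   # +3 months
  dues <- vapply(c("low", "moderate", "high", "very_high"),
                 function(r) as.numeric(next_screening_due(mk(r), config = cfg)),
                 numeric(1))
  expect_true(all(diff(dues) <= 0))
  # a zero interval is due the same day
  cfg0 <- cfg
  cfg0$screening_intervals_months$very_high <- 0
  expect_equal(as.Date(next_screening_due(mk("very_high"), config = cfg0)),
               as.Date("2024-03-01"), ignore_attr = TRUE)
})

test_that("the evaluation history is append-only and re-readable", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  ev1 <- evaluate_risk(make_complete_record(), cfg,
                       time = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"))
  ev2 <- evaluate_risk(make_complete_record(creatinine = 2.5, proteinuria = 400), cfg,
                       time = as.POSIXct("2024-06-01 08:00:00", tz = "UTC"))
  append_evaluation_history(ev1, tmp)
  append_evaluation_history(ev2, tmp)
  hist <- read_evaluation_history(tmp)
  expect_length(hist, 2)
  expect_equal(hist[[1]]$risk, ev1$risk)
  expect_equal(hist[[2]]$risk, ev2$risk)
  expect_equal(hist[[2]]$stage, ev2$stage)
})
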