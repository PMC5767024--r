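test_that("a complete adult record yields no findings and violations are each flagged", {
  expect_equal(nrow(validate_record(make_complete_record())), 0)
  f <- validate_record(make_complete_record(age = 17))
  expect_true(any(grepl("adult scope", f$message)))
  f <- validate_record(make_complete_record(weight = -5))
  expect_true(any(grepl("non-positive", f$message)))
})

test_that("seeded invariant violations are all reported in a record fuzz", {
  set.seed(31)
  for (i in 1:50) {
    rec <- random_record(i)
    expect_equal(nrow(validate_record(rec)), 0)
    bad <- rec
    broken <- sample(c("age", "weight", "gender", "lab"), 1)
    if (broken == "age") bad$age <- sample(0:17, 1)
    if (broken == "weight") bad$weight <- -runif(1, 0, 50)
    if (broken == "gender") bad$gender <- "other"
    if (broken == "lab") bad$labs$creatinine <- -1
    f <- validate_record(bad)
    expect_gt(nrow(f), 0)
  }
})

test_that("the chart-dialect CSV fixture loads six records with absent optionals", {
  recs <- load_records(chart_fixture())
  expect_length(recs, 6)
  # second fixture row: male, 79 y, 61 kg, creatinine 0.81, comorbidity X marks
  r3 <- recs[[2]]
  expect_equal(r3$gender, "male")
  expect_equal(r3$age, 79)
  expect_true(r3$sah); expect_false(r3$dm)
  expect_equal(r3$labs$creatinine, 0.81)
  # blank proteinuria cell becomes an absent optional
  expect_true(is.na(recs[[5]]$labs$proteinuria))
  expect_false(is.na(recs[[1]]$labs$proteinuria))
})

test_that("an empty chart CSV with header loads zero records and malformed rows name row and column", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("ID,SAH,DM,Creatinine,Urea,Microalbuminuria,Potassium,Weight,Age,Gender,GFR", tmp)
  expect_length(load_records(tmp), 0)
  writeLines(c("ID,SAH,DM,Creatinine,Urea,Microalbuminuria,Potassium,Weight,Age,Gender,GFR",
               "1,X,,abc,20,,4.0,70,40,F,"), tmp)
  expect_error(load_records(tmp), "row 1, column Creatinine")
  writeLines("Wrong,Header", tmp)
  expect_error(load_records(tmp), "header")
})

test_that("save then load round-trips records through both CSV and JSON", {
  recs <- load_records(chart_fixture())
  for (fmt in c("csv", "json")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", fmt))
    save_records(recs, tmp)
    back <- load_records(tmp)
    expect_length(back, length(recs))
    for (i in seq_along(recs)) {
      expect_equal(back[[i]]$labs, recs[[i]]$labs, info = fmt)
      expect_equal(back[[i]][c("id", "gender", "age", "weight", "sah", "dm")],
                   recs[[i]][c("id", "gender", "age", "weight", "sah", "dm")],
                   info = fmt)
    }
  }
  # JSON keeps medications and allergies too
  rec <- make_complete_record(medications = list(medication("enalapril", "10 mg")),
                              allergies = list(allergy("dipyrone", "urticaria")))
  tmp <- withr::local_tempfile(fileext = ".json")
  save_records(list(rec), tmp)
  back <- load_records(tmp)[[1]]
  expect_equal(back$medications[[1]]$substance, "enalapril")
  expect_equal(back$allergies[[1]]$reaction, "urticaria")
})

test_that("medication alerts match allergies case-insensitively and interactions symmetrically", {
  a <- check_medication_alerts(list(medication("Ibuprofen")),
                               list(allergy("ibuprofen")), NULL)
  expect_equal(nrow(a), 1)
  expect_equal(a$type, "allergy")

  b <- check_medication_alerts(list(medication("A"), medication("B")),
                               list(), data.frame(x = "B", y = "A"))
  expect_equal(nrow(b), 1)
  expect_equal(b$type, "interaction")

  cc <- check_medication_alerts(
    list(medication("A"), medication("B"), medication("C")),
    list(allergy("C")),
    data.frame(x = c("A", "A"), y = c("B", "C")))
  expect_equal(nrow(cc), 3)
  expect_equal(sort(cc$type), c("allergy", "interaction", "interaction"))
})

test_that("alerts are order-independent in medications and duplicate-free", {
  meds <- list(medication("A"), medication("B"), medication("C"))
  algs <- list(allergy("b"))
  inter <- data.frame(x = c("C", "a"), y = c("a", "C"))  # same pair twice
  fwd <- check_medication_alerts(meds, algs, inter)
  rev <- check_medication_alerts(base::rev(meds), algs, inter)
  expect_equal(nrow(fwd), 2)
  expect_equal(fwd[order(fwd$type), c("type", "message")],
               rev[order(rev$type), c("type", "message")])
})

test_that("the monitoring log is append-only JSON lines", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  r1 <- blood_pressure_reading(120, 80, time = "2024-01-01T08:00:00")
  r2 <- glucose_reading(95, "fasting", time = "2024-01-01T08:05:00")
  append_monitoring_log(r1, tmp)
  append_monitoring_log(r2, tmp)
  log <- read_monitoring_log(tmp)
  expect_length(log, 2)
  expect_equal(log[[1]]$systolic, 120)
  expect_equal(log[[2]]$context, "fasting")
})
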