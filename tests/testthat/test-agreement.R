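ratings6 <- read_ratings(ratings_fixture())

test_that("Cohen's kappa reproduces hand-derived values on the six printed control-group rows", {
  k1 <- cohen_kappa(ratings6[, "Nephro 1"], ratings6[, "App"])
  expect_equal(k1$k, 7 / 13, tolerance = 1e-12)
  expect_equal(k1$po, 4 / 6, tolerance = 1e-12)
  expect_equal(k1$pe, 10 / 36, tolerance = 1e-12)
  k2 <- cohen_kappa(ratings6[, "Nephro 2"], ratings6[, "App"])
  expect_equal(k2$k, 17 / 23, tolerance = 1e-12)
})

test_that("kappa is 1 iff observed agreement is 1, and 0 when observed equals expected", {
  same <- cohen_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c"))
  expect_equal(same$k, 1)
  expect_equal(same$po, 1)
  # po == pe: independent-looking split
  r1 <- c("a", "a", "b", "b")
  r2 <- c("a", "b", "a", "b")
  res <- cohen_kappa(r1, r2)
  expect_equal(res$po, res$pe)
  expect_equal(res$k, 0)
})

test_that("kappa matches a brute-force contingency oracle to 1e-12 on random matrices", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    ncat <- sample(2:4, 1)
    cats <- letters[seq_len(ncat)]
    r1 <- sample(cats, n, replace = TRUE)
    r2 <- sample(cats, n, replace = TRUE)
    want <- oracle_cohen_kappa(r1, r2, cats)
    if (is.na(want)) {
      expect_error(cohen_kappa(r1, r2, categories = cats),
                   class = "undefined_kappa")
    } else {
      expect_equal(cohen_kappa(r1, r2, categories = cats)$k, want,
                   tolerance = 1e-12)
    }
  }
})

test_that("kappa is symmetric under rater exchange and invariant to category relabeling", {
  set.seed(5)
  for (i in 1:50) {
    cats <- c("low", "moderate", "high", "very_high")
    r1 <- sample(cats, 20, replace = TRUE)
    r2 <- sample(cats, 20, replace = TRUE)
    expect_equal(cohen_kappa(r1, r2, categories = cats)$k,
                 cohen_kappa(r2, r1, categories = cats)$k)
    relabel <- c(low = "W", moderate = "X", high = "Y", very_high = "Z")
    expect_equal(cohen_kappa(relabel[r1], relabel[r2],
                             categories = unname(relabel))$k,
                 cohen_kappa(r1, r2, categories = cats)$k)
  }
})

test_that("constant identical raters raise a typed undefined-kappa signal, never NaN", {
  expect_error(cohen_kappa(rep("a", 5), rep("a", 5)), class = "undefined_kappa")
  m <- matrix("a", nrow = 4, ncol = 3)
  expect_error(global_kappa(rating_matrix(m, categories = c("a", "b"))),
               class = "undefined_kappa")
  expect_error(global_kappa(rating_matrix(m, categories = c("a", "b"))),
               "rater pair")
})

test_that("per-category kappa collapses to binary and averages rater pairs", {
  res <- per_category_kappa(ratings6, "Low risk")
  # Nephro 1 and App have identical Low-vs-rest indicator columns
  pair <- cohen_kappa(ifelse(ratings6[, "Nephro 1"] == "Low risk", "y", "n"),
                      ifelse(ratings6[, "App"] == "Low risk", "y", "n"))
  expect_equal(pair$k, 1)
  ks <- numeric(0)
  cols <- colnames(ratings6)
  for (i in 1:3) for (j in (i + 1):4) {
    b1 <- ifelse(ratings6[, cols[i]] == "Low risk", "y", "n")
    b2 <- ifelse(ratings6[, cols[j]] == "Low risk", "y", "n")
    ks <- c(ks, oracle_cohen_kappa(b1, b2, c("n", "y")))
  }
  expect_equal(res$k, mean(ks), tolerance = 1e-12)
  # total agreement on a category gives kappa 1
  tot <- matrix(rep(c("s4", "s1", "s4", "s1"), 3), ncol = 3)
  expect_equal(per_category_kappa(rating_matrix(tot), "s4")$k, 1)
  # a category one rater never uses cannot beat chance
  m <- cbind(r1 = c("a", "a", "b", "b"), r2 = c("b", "b", "b", "b"))
  expect_lte(per_category_kappa(rating_matrix(m), "a")$k, 0)
  expect_error(per_category_kappa(ratings6, "Absent risk"), "not declared")
  all_rest <- matrix("x", 3, 2)
  expect_error(per_category_kappa(rating_matrix(all_rest, c("x", "y")), "y"),
               class = "undefined_kappa")
})

test_that("global kappa averages all pairwise kappas and degenerates to Cohen for 2 raters", {
  g <- global_kappa(ratings6)
  cols <- colnames(ratings6)
  ks <- numeric(0)
  for (i in 1:3) for (j in (i + 1):4)
    ks <- c(ks, oracle_cohen_kappa(ratings6[, cols[i]], ratings6[, cols[j]],
                                   attr(ratings6, "categories")))
  expect_equal(g$k, mean(ks), tolerance = 1e-12)
  expect_equal(nrow(g$pairwise), 6)
  two <- ratings6[, c("Nephro 1", "App")]
  expect_equal(global_kappa(rating_matrix(two))$k,
               cohen_kappa(ratings6[, "Nephro 1"], ratings6[, "App"])$k)
  ident <- matrix(rep(c("a", "b", "c"), 4), ncol = 4)
  expect_equal(global_kappa(rating_matrix(ident))$k, 1)
  # Fleiss alternative is labeled and also 1 under total agreement
  f <- global_kappa(rating_matrix(ident), method = "fleiss")
  expect_equal(f$k, 1)
  expect_equal(f$method, "fleiss")
})

test_that("the Wald interval uses SE = sqrt(po(1-po)/(n(1-pe)^2)) and is never clipped", {
  res <- cohen_kappa(ratings6[, "Nephro 1"], ratings6[, "App"])
  se <- sqrt(res$po * (1 - res$po) / (res$n * (1 - res$pe)^2))
  ci <- kappa_confidence_interval(res)
  expect_equal(unname(ci["high"] - ci["low"]), 2 * 1.96 * se, tolerance = 1e-3)
  expect_lte(ci["low"], res$k); expect_gte(ci["high"], res$k)
  # near-perfect agreement at modest n: upper bound exceeds 1, retained
  r1 <- c(rep("a", 20), rep("b", 14), "a")
  r2 <- c(rep("a", 20), rep("b", 14), "b")
  near <- cohen_kappa(r1, r2)
  expect_gt(near$k, 0.9)
  expect_gt(near$ci_high, 1)
  # degenerate po = 1 collapses the interval to a point
  perfect <- cohen_kappa(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$se, 0)
  expect_equal(perfect$ci_low, perfect$ci_high)
})

test_that("the Wald half-width matches a bootstrap oracle within Monte-Carlo error", {
  set.seed(88)
  n <- 60
  truth <- sample(c("low", "moderate", "high"), n, replace = TRUE)
  flip <- function(x) ifelse(runif(n) < 0.15,
                             sample(c("low", "moderate", "high"), n, replace = TRUE), x)
  r1 <- flip(truth); r2 <- flip(truth)
  res <- cohen_kappa(r1, r2)
  boot <- vapply(1:10000, function(b) {
    idx <- sample(n, replace = TRUE)
    oracle_cohen_kappa(r1[idx], r2[idx], sort(unique(c(r1, r2))))
  }, numeric(1))
  expect_equal(1.96 * stats::sd(boot, na.rm = TRUE),
               (res$ci_high - res$ci_low) / 2, tolerance = 0.25)
})

test_that("the interpretation scale labels the conventional bands", {
  expect_equal(interpret_kappa(0.7119), "substantial")
  expect_equal(interpret_kappa(0.8375), "almost_perfect")
  expect_equal(interpret_kappa(0.2920), "fair")
  expect_equal(interpret_kappa(1.0), "almost_perfect")
  expect_equal(interpret_kappa(c(-0.2, 0, 0.01, 0.20, 0.41, 0.60, 0.80, 0.81)),
               c("absence", "absence", "slight", "slight", "moderate",
                 "moderate", "substantial", "almost_perfect"))
})

test_that("the agreement report has one row per category plus a global row", {
  rep6 <- agreement_report(ratings6)
  expect_equal(nrow(rep6), 5)  # 4 categories + Global Kappa
  expect_equal(rep6$Category[5], "Global Kappa")
  expect_named(rep6, c("Category", "Kappa", "CI_low", "CI_high", "Interpretation"))
  tot <- matrix(rep(c("a", "b", "a", "b"), 3), ncol = 3)
  rep_tot <- agreement_report(rating_matrix(tot))
  expect_true(all(rep_tot$Kappa == 1))
  # optional merge map collapses categories before analysis
  merged <- agreement_report(ratings6,
                             merge_map = c("High risk" = "Elevated",
                                           "Very high risk" = "Elevated"))
  expect_equal(nrow(merged), 4)  # 3 merged categories + global
  expect_true("Elevated" %in% merged$Category)
})

test_that("simulated rater panels at a design kappa recover it on average", {
  # scaled-down recovery sweep; the full 500-replicate study runs in the
  # acceptance suite
  marg <- c(0.3, 0.3, 0.25, 0.15)
  for (k0 in c(0.3, 0.9)) {
    conf <- confusion_for_kappa(k0, marg)
    set.seed(123)
    ks <- vapply(1:120, function(r) {
      truth <- sample(c("low", "moderate", "high", "very_high"), 60,
                      replace = TRUE, prob = marg)
      global_kappa(simulate_raters(truth, raters = 4, confusion = conf,
                                   seed = 5000 + r))$k
    }, numeric(1))
    expect_lt(abs(mean(ks) - k0), 0.05)
  }
})
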