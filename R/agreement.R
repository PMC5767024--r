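#' Build a rating matrix of categorical evaluations
#'
#' Agreement between independent observers (e.g. several nephrologists and
#' a decision-support tool rating the same subjects) is analyzed on a
#' subjects-by-raters grid of categorical labels drawn from a declared
#' category set.
#'
#' @param x Matrix or data frame of labels, one column per rater, one row
#'   per subject.
#' @param categories Declared category set; defaults to the sorted unique
#'   labels observed. Every cell must belong to this set.
#' @return Character matrix of class `rating_matrix` with a `categories`
#'   attribute.
#' @export
rating_matrix <- function(x, categories = NULL) {
  m <- as.matrix(as.data.frame(x, stringsAsFactors = FALSE))
  storage.mode(m) <- "character"
  if (ncol(m) < 2) stop("a rating matrix needs at least 2 raters")
  if (nrow(m) < 1) stop("a rating matrix needs at least 1 subject")
  if (anyNA(m)) stop("rating matrix must not contain missing labels")
  if (is.null(categories)) categories <- sort(unique(as.vector(m)))
  extra <- setdiff(unique(as.vector(m)), categories)
  if (length(extra) > 0)
    stop("labels outside the declared category set: ",
         paste(extra, collapse = ", "))
  structure(m, categories = categories, class = c("rating_matrix", "matrix"))
}

#' Read ratings from a CSV of subject-by-rater evaluations
#'
#' Expects a CSV whose first column is the subject `ID` and whose remaining
#' columns are raters (e.g. `Nephro 1, Nephro 2, Nephro 3, App`).
#'
#' @param path CSV file.
#' @param categories Optional declared category set.
#' @return A [rating_matrix()] with subject ids as rownames.
#' @export
read_ratings <- function(path, categories = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 3) stop("ratings CSV needs an ID column and >= 2 raters")
  m <- rating_matrix(df[, -1, drop = FALSE], categories)
  rownames(m) <- df[[1]]
  m
}

# Typed signal for the degenerate case p_e = 1 (all mass on one agreeing
# cell), where kappa's denominator vanishes.
undefined_kappa <- function(detail) {
  stop(errorCondition(paste0("kappa is undefined (expected agreement = 1): ",
                             detail),
                      class = c("undefined_kappa", "error")))
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement
#' \deqn{k = \frac{p_o - p_e}{1 - p_e}}
#' where \eqn{p_o} is the observed proportion of subjects with identical
#' labels and \eqn{p_e} the agreement expected by chance from the two
#' raters' marginal label distributions. When both raters assign a single
#' identical label to every subject, \eqn{p_e = 1} and kappa is undefined;
#' this raises a typed `undefined_kappa` condition rather than returning
#' `NaN`.
#'
#' @param ratings A [rating_matrix()] (restricted to 2 raters unless `r1`,
#'   `r2` select a pair), or a vector of labels for rater 1.
#' @param r2 Labels for rater 2 when `ratings` is a vector.
#' @param categories Optional declared category set.
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `agreement_result`: list with `k`, `po`,
#'   `pe`, `se`, `ci_low`, `ci_high`, `n`, `interpretation`, `method`.
#' @examples
#' cohen_kappa(c("a", "b", "a"), c("a", "b", "b"))
#' @export
cohen_kappa <- function(ratings, r2 = NULL, categories = NULL,
                        conf_level = 0.95) {
  if (!is.null(r2)) {
    ratings <- rating_matrix(cbind(r1 = as.character(ratings),
                                   r2 = as.character(r2)), categories)
  } else {
    if (!inherits(ratings, "rating_matrix")) ratings <- rating_matrix(ratings, categories)
    if (ncol(ratings) != 2)
      stop("cohen_kappa needs exactly 2 raters; use global_kappa for more")
  }
  cats <- attr(ratings, "categories")
  n <- nrow(ratings)
  po <- mean(ratings[, 1] == ratings[, 2])
  m1 <- tabulate(factor(ratings[, 1], levels = cats), nbins = length(cats)) / n
  m2 <- tabulate(factor(ratings[, 2], levels = cats), nbins = length(cats)) / n
  pe <- sum(m1 * m2)
  if (pe >= 1) undefined_kappa("both raters assign the same constant label")
  k <- (po - pe) / (1 - pe)
  new_agreement_result(k, po, pe, n, conf_level, method = "cohen")
}

# Shared constructor: Wald CI from the large-sample standard error
# SE = sqrt(po (1 - po) / (n (1 - pe)^2)); bounds deliberately unclipped
# (an upper bound above 1 is reported as-is).
new_agreement_result <- function(k, po, pe, n, conf_level = 0.95,
                                 method = "cohen") {
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(k = k, po = po, pe = pe, se = se,
         ci_low = k - z * se, ci_high = k + z * se,
         conf_level = conf_level, n = n,
         interpretation = interpret_kappa(k), method = method),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Kappa = %.4f (%s agreement), %.0f%% CI [%.4f, %.4f]\n",
              x$k, gsub("_", " ", x$interpretation), 100 * x$conf_level,
              x$ci_low, x$ci_high))
  cat(sprintf("  observed agreement %.4f, expected %.4f, n = %d, method = %s\n",
              x$po, x$pe, x$n, x$method))
  invisible(x)
}

#' Confidence interval for a kappa estimate
#'
#' Large-sample Wald interval \eqn{k \pm z \cdot SE} with
#' \eqn{SE = \sqrt{p_o (1 - p_o) / (n (1 - p_e)^2)}}, with no adjustment
#' for bias or prevalence. Bounds are not clipped to [-1, 1]: near-perfect
#' agreement at modest n legitimately yields an upper bound above 1.
#'
#' @param result An `agreement_result` (uses its `po`, `pe`, `k`).
#' @param n Number of subjects; defaults to the result's own `n`.
#' @param conf_level Confidence level.
#' @return Named numeric vector `c(low, high)`.
#' @export
kappa_confidence_interval <- function(result, n = result$n, conf_level = 0.95) {
  stopifnot(n >= 2)
  if (result$pe >= 1) undefined_kappa("expected agreement is 1")
  se <- sqrt(result$po * (1 - result$po) / (n * (1 - result$pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(low = result$k - z * se, high = result$k + z * se)
}

#' Per-category kappa (one category versus the rest)
#'
#' Collapses the labels to a binary indicator of the given category, then
#' computes Cohen's kappa for every unordered rater pair and averages the
#' pairwise kappas. A pair in which neither rater ever uses the category is
#' vacuous after the collapse (both indicator columns are constantly "no",
#' so expected agreement is 1): such pairs carry no information about the
#' category and are excluded from the average. The confidence interval uses
#' the means of the pairwise observed and expected agreements in the Wald
#' standard error.
#'
#' @param ratings A [rating_matrix()] (any number of raters >= 2).
#' @param category The category of interest; must be declared.
#' @param conf_level Confidence level.
#' @return An `agreement_result` (method `"mean_pairwise_binary"`). Raises
#'   `undefined_kappa` when the category is absent from all ratings.
#' @export
per_category_kappa <- function(ratings, category, conf_level = 0.95) {
  if (!inherits(ratings, "rating_matrix")) ratings <- rating_matrix(ratings)
  cats <- attr(ratings, "categories")
  if (!category %in% cats)
    stop("category '", category, "' is not declared in the rating matrix")
  if (!any(ratings == category))
    undefined_kappa(sprintf("category '%s' absent from all ratings", category))
  bin <- matrix(ifelse(ratings == category, "yes", "no"), nrow = nrow(ratings))
  colnames(bin) <- colnames(ratings)
  combine_pairwise(rating_matrix(bin, c("no", "yes")), conf_level,
                   method = "mean_pairwise_binary", skip_vacuous = TRUE)
}

#' Global kappa across all raters
#'
#' Pools agreement across more than two raters. The default combination is
#' the mean of all pairwise Cohen's kappas; Fleiss' kappa is available as a
#' labeled alternative (the `method` field of the result records which rule
#' produced the value).
#'
#' @param ratings A [rating_matrix()].
#' @param method `"mean_pairwise"` or `"fleiss"`.
#' @param conf_level Confidence level.
#' @return An `agreement_result`. With exactly 2 raters, the
#'   `mean_pairwise` method reduces to [cohen_kappa()] exactly. Any
#'   undefined pairwise kappa propagates as an `undefined_kappa` condition
#'   naming the rater pair.
#' @export
global_kappa <- function(ratings, method = c("mean_pairwise", "fleiss"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  if (!inherits(ratings, "rating_matrix")) ratings <- rating_matrix(ratings)
  if (method == "fleiss") return(fleiss_kappa(ratings, conf_level))
  combine_pairwise(ratings, conf_level, method = "mean_pairwise")
}

combine_pairwise <- function(ratings, conf_level, method,
                             skip_vacuous = FALSE) {
  cats <- attr(ratings, "categories")
  raters <- colnames(ratings) %||% paste0("rater", seq_len(ncol(ratings)))
  pairs <- utils::combn(ncol(ratings), 2)
  ks <- pos <- pes <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- tryCatch(
      cohen_kappa(ratings[, i1], ratings[, i2], categories = cats,
                  conf_level = conf_level),
      undefined_kappa = function(e) {
        if (skip_vacuous) return(NULL)
        stop(errorCondition(
          sprintf("kappa undefined for rater pair (%s, %s)",
                  raters[i1], raters[i2]),
          class = c("undefined_kappa", "error")))
      })
    if (is.null(res)) {
      ks[j] <- pos[j] <- pes[j] <- NA_real_
      next
    }
    ks[j] <- res$k; pos[j] <- res$po; pes[j] <- res$pe
  }
  if (all(is.na(ks)))
    undefined_kappa("every rater pair is degenerate after collapsing")
  if (anyNA(ks)) {
    keep <- !is.na(ks)
    ks <- ks[keep]; pos <- pos[keep]; pes <- pes[keep]
    pairs <- pairs[, keep, drop = FALSE]
  }
  # Headline kappa is the mean of pairwise kappas; the Wald SE uses the
  # mean observed/expected agreements at the common n.
  out <- new_agreement_result(mean(ks), mean(pos), mean(pes), nrow(ratings),
                              conf_level, method = method)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out$ci_low <- out$k - z * out$se
  out$ci_high <- out$k + z * out$se
  out$pairwise <- data.frame(rater_a = raters[pairs[1, ]],
                             rater_b = raters[pairs[2, ]], k = ks)
  out
}

# Fleiss' kappa for m raters: per-subject agreement P_i over label counts,
# chance agreement from pooled category proportions.
fleiss_kappa <- function(ratings, conf_level = 0.95) {
  cats <- attr(ratings, "categories")
  n <- nrow(ratings); m <- ncol(ratings)
  counts <- t(apply(ratings, 1, function(row)
    tabulate(factor(row, levels = cats), nbins = length(cats))))
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  po <- mean(p_i)
  pj <- colSums(counts) / (n * m)
  pe <- sum(pj^2)
  if (pe >= 1) undefined_kappa("all raters assign the same constant label")
  k <- (po - pe) / (1 - pe)
  new_agreement_result(k, po, pe, n, conf_level, method = "fleiss")
}

#' Interpret a kappa value on the conventional agreement scale
#'
#' Labels: below or equal to 0, absence of agreement; up to 0.20 slight;
#' up to 0.40 fair; up to 0.60 moderate; up to 0.80 substantial; above
#' 0.80 (including exactly 1) almost perfect. The published scale leaves
#' tiny gaps (below 0.01, and exactly 1.0); the bands here are closed on
#' the right so every finite value gets a label.
#'
#' @param k Kappa value(s), finite.
#' @return Character vector of scale labels.
#' @examples
#' interpret_kappa(c(0.7119, 0.8375, 0.2920))
#' @export
interpret_kappa <- function(k) {
  stopifnot(is.numeric(k), all(is.finite(k)))
  cut_labels <- c("absence", "slight", "fair", "moderate", "substantial",
                  "almost_perfect")
  idx <- findInterval(k, c(-Inf, 0, 0.20, 0.40, 0.60, 0.80),
                      left.open = TRUE, rightmost.closed = FALSE)
  cut_labels[idx]
}

#' Tabulate per-category and global agreement
#'
#' Produces the standard agreement report: one row per category with its
#' per-category kappa and confidence interval, plus a final `Global Kappa`
#' row, in a CSV-renderable data frame
#' (`Category | Kappa | CI_low | CI_high | Interpretation`).
#'
#' @param ratings A [rating_matrix()].
#' @param merge_map Optional named character vector collapsing categories
#'   before analysis (e.g. `c("3a" = "3", "3b" = "3")` to merge CKD
#'   sub-stages).
#' @param method Global combination rule, see [global_kappa()].
#' @param conf_level Confidence level.
#' @return Data frame with one row per category plus the global row.
#' @export
agreement_report <- function(ratings, merge_map = NULL,
                             method = c("mean_pairwise", "fleiss"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  if (!inherits(ratings, "rating_matrix")) ratings <- rating_matrix(ratings)
  if (!is.null(merge_map)) {
    m <- matrix(ifelse(ratings %in% names(merge_map),
                       merge_map[as.vector(ratings)], as.vector(ratings)),
                nrow = nrow(ratings), dimnames = dimnames(ratings))
    ratings <- rating_matrix(m)
  }
  cats <- attr(ratings, "categories")
  rows <- lapply(cats, function(cat) {
    res <- per_category_kappa(ratings, cat, conf_level)
    data.frame(Category = cat, Kappa = res$k,
               CI_low = res$ci_low, CI_high = res$ci_high,
               Interpretation = res$interpretation)
  })
  g <- global_kappa(ratings, method, conf_level)
  rows[[length(rows) + 1]] <- data.frame(Category = "Global Kappa", Kappa = g$k,
                                         CI_low = g$ci_low, CI_high = g$ci_high,
                                         Interpretation = g$interpretation)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
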