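#' Sequential two-group comparison
#'
#' Applies the sequential decision ladder used for all univariate group
#' comparisons: (1) Lilliefors-corrected Kolmogorov-Smirnov normality test
#' on each group (alpha = 0.05); if either group is non-normal, a
#' rank-based Wilcoxon test; otherwise (2) Levene's test (mean-centered)
#' for equal variances; equal variances give the independent-samples
#' t-test, unequal give Welch's t-test.
#'
#' The rank branch defaults to the Wilcoxon rank-sum (Mann-Whitney) test,
#' which is the valid choice for two independent groups;
#' `rank_test = "signed-rank"` instead pairs the groups by sorted order
#' (equal group sizes only) and applies the signed-rank test literally.
#'
#' @param values_a,values_b Numeric samples, each of size >= 3.
#' @param alpha Gate level for the normality and variance tests (0.05).
#' @param rank_test `"rank-sum"` (default) or `"signed-rank"`.
#' @return A one-row data frame (`stat_result`): `test_used`
#'   (`independent-t`, `welch-t` or `wilcoxon`), `statistic`, `p_raw`,
#'   `normality_p` (minimum of the two groups' normality p-values),
#'   `variance_p` (NA when the rank branch was taken).
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           rank_test = c("rank-sum", "signed-rank")) {
  rank_test <- match.arg(rank_test)
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("each sample must have size >= 3", call. = FALSE)
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    stop("both samples are constant; no test applicable", call. = FALSE)
  }
  norm_p <- suppressWarnings(
    min(lilliefors_p(values_a), lilliefors_p(values_b)))
  if (norm_p < alpha) {
    if (rank_test == "rank-sum") {
      ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE))
    } else {
      if (length(values_a) != length(values_b)) {
        stop("signed-rank mode requires equal group sizes", call. = FALSE)
      }
      ht <- suppressWarnings(
        wilcox.test(sort(values_a), sort(values_b), paired = TRUE,
                    exact = FALSE))
    }
    return(stat_row("wilcoxon", unname(ht$statistic), ht$p.value, norm_p,
                    NA_real_))
  }
  grp <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  lev <- car::leveneTest(c(values_a, values_b), grp, center = mean)
  var_p <- lev[["Pr(>F)"]][1]
  ht <- t.test(values_a, values_b, var.equal = var_p >= alpha)
  test <- if (var_p >= alpha) "independent-t" else "welch-t"
  stat_row(test, unname(ht$statistic), ht$p.value, norm_p, var_p)
}

lilliefors_p <- function(x) {
  if (sd(x) == 0) return(0)      # constant sample is maximally non-normal
  nortest::lillie.test(x)$p.value
}

stat_row <- function(test, statistic, p, norm_p, var_p) {
  data.frame(test_used = test, statistic = statistic, p_raw = p,
             normality_p = norm_p, variance_p = var_p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: monotone in the sorted order
#' and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Compare every feature of a table between the two groups
#'
#' Runs [compare_groups()] per feature column and adjusts p-values with
#' [bh_adjust()] within the supplied family (call it once per family, e.g.
#' once for behavioral and once for neurological features, to reproduce
#' per-analysis correction).
#'
#' @param table Feature table with a `group` factor column (levels
#'   `hc`, `amci`) as produced by [simulate_cohort()].
#' @param features Character vector of feature columns; defaults to every
#'   numeric column except identifiers.
#' @param ... Passed to [compare_groups()].
#' @return Data frame: one row per feature with group means/SDs, the test
#'   chosen, statistic, `p_raw` and `p_adjusted`.
#' @export
compare_feature_table <- function(table, features = NULL, ...) {
  stopifnot("group" %in% names(table))
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("subject_id"))
  }
  a <- table$group == levels(factor(table$group))[1]
  rows <- lapply(features, function(f) {
    r <- compare_groups(table[[f]][a], table[[f]][!a], ...)
    cbind(data.frame(feature = f,
                     mean_a = mean(table[[f]][a]), sd_a = sd(table[[f]][a]),
                     mean_b = mean(table[[f]][!a]),
                     sd_b = sd(table[[f]][!a])), r)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out
}

#' Cross-modal Pearson correlation grid
#'
#' Pearson correlation between every behavioral and every neurological
#' column, with p-values Benjamini-Hochberg adjusted jointly over the
#' whole grid.
#'
#' @param behavioral,neurological Data frames (or matrices) of paired
#'   observations; rows are the same subjects.
#' @return List with matrices `r`, `p_raw` and `p_adjusted`
#'   (behavioral features in rows, neurological in columns).
#' @export
cross_modal_correlations <- function(behavioral, neurological) {
  behavioral <- as.data.frame(behavioral)
  neurological <- as.data.frame(neurological)
  if (nrow(behavioral) != nrow(neurological) || nrow(behavioral) < 3) {
    stop("need >= 3 paired complete observations", call. = FALSE)
  }
  if (any(vapply(behavioral, sd, numeric(1)) == 0) ||
      any(vapply(neurological, sd, numeric(1)) == 0)) {
    stop("zero-variance column", call. = FALSE)
  }
  nb <- ncol(behavioral); nn <- ncol(neurological)
  r <- p <- matrix(NA_real_, nb, nn,
                   dimnames = list(names(behavioral), names(neurological)))
  for (i in seq_len(nb)) {
    for (j in seq_len(nn)) {
      ct <- cor.test(behavioral[[i]], neurological[[j]])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  p_adj <- matrix(bh_adjust(as.vector(p)), nb, nn, dimnames = dimnames(p))
  list(r = r, p_raw = p, p_adjusted = p_adj)
}
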