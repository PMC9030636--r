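# Multi-rater agreement statistics: Fleiss' kappa (overall and per
# category), bootstrap/asymptotic confidence intervals, and the chi-squared
# comparison of intermediate-electrode proportions between array models.

#' Rater-by-electrode count table
#'
#' @param counts items x categories matrix of rater counts; every row must
#'   sum to the (constant) number of raters.
#' @param categories Category labels; defaults to the matrix column names or
#'   `ST`/`INT`/`SV`.
#' @param item_labels Optional electrode identifiers.
#' @return Object of class `rater_table`.
#' @export
rater_table <- function(counts, categories = NULL, item_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1L)
    stop("every item must be rated by the same number of raters")
  n_raters <- rs[1]
  if (n_raters < 2L) stop("need at least 2 raters")
  if (is.null(categories))
    categories <- colnames(counts) %||% paste0("C", seq_len(ncol(counts)))
  if (length(categories) != ncol(counts)) stop("one label per category column required")
  colnames(counts) <- categories
  if (is.null(item_labels)) item_labels <- paste0("e", seq_len(nrow(counts)))
  rownames(counts) <- item_labels
  structure(list(counts = counts, n_raters = as.integer(n_raters),
                 categories = categories, item_labels = item_labels),
            class = "rater_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a rater table from long-format ratings
#'
#' @param ratings data.frame with columns `electrode_id`, `rater_id`,
#'   `category`.
#' @param categories Valid category labels (default `ST`, `INT`, `SV`).
#' @return A `rater_table`.
#' @export
rater_table_from_long <- function(ratings, categories = c("ST", "INT", "SV")) {
  need <- c("electrode_id", "rater_id", "category")
  if (!all(need %in% names(ratings)))
    stop("long ratings need columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(as.character(ratings$category)), categories)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(categories, collapse = ", "))
  items <- unique(as.character(ratings$electrode_id))
  tab <- table(factor(as.character(ratings$electrode_id), levels = items),
               factor(as.character(ratings$category), levels = categories))
  rater_table(unclass(tab), categories = categories, item_labels = items)
}

fleiss_components <- function(counts, n_raters) {
  n <- n_raters
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  pj <- colSums(counts) / (nrow(counts) * n)
  list(Pi = Pi, p_bar = mean(Pi), p_e = sum(pj^2), pj = pj)
}

#' Fleiss' kappa for multiple raters
#'
#' The 1971 fixed-marginal statistic: per-item agreement
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, observed agreement
#' `Pbar = mean(P_i)`, chance agreement `Pe = sum_j p_j^2`, and
#' `kappa = (Pbar - Pe) / (1 - Pe)`.
#'
#' @param table A [rater_table()].
#' @return Object of class `kappa_result`: `kappa`, `ci_low`/`ci_high`
#'   (`NA` until [kappa_ci()] is used), `scope`, `n_items`, plus `p_bar`,
#'   `p_e`.
#' @export
fleiss_kappa <- function(table) {
  stopifnot(inherits(table, "rater_table"))
  counts <- table$counts
  if (nrow(counts) < 2L) stop("need at least 2 items")
  comp <- fleiss_components(counts, table$n_raters)
  if (comp$p_e >= 1 - 1e-12)
    stop("undefined kappa: all ratings fall in a single category")
  structure(list(kappa = (comp$p_bar - comp$p_e) / (1 - comp$p_e),
                 ci_low = NA_real_, ci_high = NA_real_,
                 scope = "overall", n_items = nrow(counts),
                 p_bar = comp$p_bar, p_e = comp$p_e),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  ci <- if (is.finite(x$ci_low)) sprintf(" (%.2f-%.2f)", x$ci_low, x$ci_high) else ""
  cat(sprintf("Fleiss' kappa [%s]: %.3f%s over %d items\n",
              x$scope, x$kappa, ci, x$n_items))
  invisible(x)
}

collapse_binary <- function(table, category) {
  if (!category %in% table$categories)
    stop("category not present in table: ", category)
  counts <- cbind(table$counts[, category],
                  rowSums(table$counts[, setdiff(table$categories, category), drop = FALSE]))
  rater_table(counts, categories = c(category, "other"),
              item_labels = table$item_labels)
}

#' Category-wise Fleiss' kappa
#'
#' Collapses the table to the given category versus the rest and computes
#' Fleiss' kappa on the binary table (the standard category-wise kappa).
#'
#' @inheritParams fleiss_kappa
#' @param category Category label to isolate.
#' @return A `kappa_result` with scope `per_category:<label>`.
#' @export
per_category_kappa <- function(table, category) {
  out <- fleiss_kappa(collapse_binary(table, category))
  out$scope <- paste0("per_category:", category)
  out
}

#' Confidence interval for Fleiss' kappa
#'
#' Default: seeded nonparametric bootstrap over items (percentile interval).
#' The asymptotic alternative uses the Fleiss-Nee-Landis large-sample
#' standard error.
#'
#' @inheritParams fleiss_kappa
#' @param alpha Two-sided miss probability (default 0.05).
#' @param method `"bootstrap"` or `"asymptotic"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return A `kappa_result` with `ci_low`/`ci_high` filled in; with fewer
#'   than 5 items the interval is refused with a warning (`NA` bounds).
#' @export
kappa_ci <- function(table, alpha = 0.05, method = c("bootstrap", "asymptotic"),
                     n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(table, "rater_table"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  method <- match.arg(method)
  out <- fleiss_kappa(table)
  N <- nrow(table$counts)
  if (N < 5L) {
    warning("too few items (< 5) for a confidence interval; returning NA bounds")
    return(out)
  }
  n <- table$n_raters
  if (method == "bootstrap") {
    counts <- table$counts
    Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
    ks <- with_seed(seed, {
      idx <- matrix(sample.int(N, N * n_boot, replace = TRUE), nrow = n_boot)
      p_bar <- rowMeans(matrix(Pi[idx], nrow = n_boot))
      p_e <- numeric(n_boot)
      for (j in seq_len(ncol(counts))) {
        cj <- matrix(counts[, j][idx], nrow = n_boot)
        p_e <- p_e + (rowSums(cj) / (N * n))^2
      }
      ifelse(p_e >= 1 - 1e-12, NA_real_, (p_bar - p_e) / (1 - p_e))
    })
    ks <- ks[is.finite(ks)]
    ci <- unname(stats::quantile(ks, c(alpha / 2, 1 - alpha / 2), type = 7))
  } else {
    pj <- colSums(table$counts) / (N * n)
    spj2 <- sum(pj^2)
    num <- spj2 - (2 * n - 3) * spj2^2 + 2 * (n - 2) * sum(pj^3)
    se <- sqrt(2 / (N * n * (n - 1)) * num / (1 - spj2)^2)
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(out$kappa - z * se, out$kappa + z * se)
  }
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out
}

#' Compare intermediate-electrode proportions between two array models
#'
#' Pearson chi-squared test (1 df, no continuity correction by default) on
#' the 2 x 2 table of intermediate versus other electrodes.
#'
#' @param a,n1 Intermediate count and total for the first group.
#' @param b,n2 Same for the second group.
#' @param correct Apply Yates continuity correction.
#' @return List with `chi2`, `p_value`, `proportions`, `expected_min`; a
#'   `low_expected` warning flag is attached when any expected cell < 1.
#' @export
compare_intermediate_proportions <- function(a, n1, b, n2, correct = FALSE) {
  if (any(!is.finite(c(a, n1, b, n2)))) stop("counts must be finite")
  if (n1 <= 0 || n2 <= 0 || a < 0 || b < 0 || a > n1 || b > n2)
    stop("need 0 <= a <= n1 and 0 <= b <= n2 with positive totals")
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2L, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  out <- list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value),
              proportions = c(a / n1, b / n2), expected_min = min(expected),
              low_expected = min(expected) < 1)
  if (out$low_expected)
    warning("expected cell count below 1; chi-squared approximation is unreliable")
  out
}
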