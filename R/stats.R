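#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration with the
#' probability-mass ordering: the p-value sums the probabilities of all
#' tables with the observed margins whose probability does not exceed
#' that of the observed table (the convention of R's `fisher.test`).
#'
#' @param table a 2x2 matrix of non-negative integer counts (rows =
#'   group, columns = outcome), or a length-4 vector `c(a, b, c, d)`
#'   filled by row.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(8, 14, 41, 34), 2, byrow = TRUE)) # ~0.15
fisher_exact_2x2 <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, 2, byrow = TRUE)
  }
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table))) {
    stop("validation error: counts must be non-negative integers",
         call. = FALSE)
  }
  if (sum(table) == 0) stop("validation error: empty table", call. = FALSE)
  a <- table[1, 1]
  row1 <- sum(table[1, ])
  row2 <- sum(table[2, ])
  col1 <- sum(table[, 1])
  if (row1 == 0 || row2 == 0 || col1 == 0 || sum(table[, 2]) == 0) {
    return(1) # degenerate margin: only one table possible
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- stats::dhyper(support, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  # relative tolerance guards against ties broken by rounding error
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Kruskal-Wallis rank test
#'
#' Ranks all observations jointly (mid-ranks for ties) and computes
#' `H = (12 / (N (N + 1))) * sum n_i (Rbar_i - (N + 1) / 2)^2`, divided
#' by the tie correction `1 - sum(t^3 - t) / (N^3 - N)`. The p-value
#' uses the chi-square approximation with k - 1 degrees of freedom,
#' standard at the group sizes of case-control cohorts.
#'
#' @param samples_by_group a list of numeric vectors, one per group.
#' @return a list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(samples_by_group) {
  if (any(lengths(samples_by_group) == 0)) {
    stop("validation error: empty group", call. = FALSE)
  }
  k <- length(samples_by_group)
  x <- unlist(samples_by_group, use.names = FALSE)
  g <- rep(seq_len(k), lengths(samples_by_group))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g, k)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) {
    # all observations identical: no evidence against the null
    return(list(statistic = 0, df = k - 1, p_value = 1))
  }
  h <- h / correction
  list(statistic = h, df = k - 1,
       p_value = stats::pchisq(h, k - 1, lower.tail = FALSE))
}

#' Group comparison report for a feature table
#'
#' Compares every requested variable between the two groups with the
#' test appropriate to its type: binary variables (0/1 or logical) by
#' two-sided Fisher exact test with counts and within-group percentages;
#' numeric variables by Kruskal-Wallis with group means and SDs.
#'
#' @param data a data frame with one row per subject.
#' @param group name of the grouping column (two levels).
#' @param variables variables to compare; defaults to every column except
#'   the group and any `subject_id`.
#' @param digits significant digits for the formatted p-value column
#'   (full precision is kept in `p_value`).
#' @return a tibble with one row per variable: per-group summaries,
#'   `test`, `p_value`, `p_formatted`.
#' @export
compare_groups <- function(data, group = "group", variables = NULL,
                           digits = 2) {
  g <- data[[group]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) {
    stop("`group` must have exactly two levels", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data), c(group, "subject_id"))
  }
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]]
    in1 <- g == lev[1]
    is_binary <- is.logical(x) ||
      (is.numeric(x) && all(x %in% c(0, 1)))
    if (is_binary) {
      x <- as.numeric(x)
      a <- sum(x[in1]); b <- sum(in1) - a
      c_ <- sum(x[!in1]); d <- sum(!in1) - c_
      p <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      tibble::tibble(
        variable = v, test = "fisher",
        summary_1 = sprintf("%d (%.0f%%)", a, 100 * a / sum(in1)),
        summary_2 = sprintf("%d (%.0f%%)", c_, 100 * c_ / sum(!in1)),
        mean_1 = NA_real_, sd_1 = NA_real_,
        mean_2 = NA_real_, sd_2 = NA_real_,
        p_value = p
      )
    } else {
      sd1 <- stats::sd(x[in1]); sd2 <- stats::sd(x[!in1])
      kw <- kruskal_wallis(list(x[in1], x[!in1]))
      tibble::tibble(
        variable = v, test = "kruskal-wallis",
        summary_1 = sprintf("%.4g (%.4g)", mean(x[in1]), sd1),
        summary_2 = sprintf("%.4g (%.4g)", mean(x[!in1]), sd2),
        mean_1 = mean(x[in1]), sd_1 = sd1,
        mean_2 = mean(x[!in1]), sd_2 = sd2,
        p_value = kw$p_value
      )
    }
  })
  out <- purrr::list_rbind(rows)
  out$p_formatted <- signif(out$p_value, digits)
  attr(out, "group_levels") <- lev
  out
}
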