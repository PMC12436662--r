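# Shared statistics: Grubbs outlier removal and the normality-gated
# two-group comparison used throughout the imaging quantifications.

#' Iterative Grubbs outlier removal
#'
#' Repeatedly applies Grubbs' test for a single outlier (two-sided) at
#' level `alpha`, removing the most extreme value while the test rejects.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level per step.
#' @return list with `kept`, `removed`, `is_outlier`.
#' @export
remove_outliers_grubbs <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  is_out <- rep(FALSE, length(values))
  repeat {
    idx <- which(!is_out)
    x <- values[idx]
    n <- length(x)
    if (n < 3 || sd(x) == 0) break
    g <- abs(x - mean(x)) / sd(x)
    i_max <- which.max(g)
    tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g[i_max] > gcrit) {
      is_out[idx[i_max]] <- TRUE
    } else break
  }
  list(kept = values[!is_out], removed = values[is_out],
       is_outlier = is_out)
}

#' Two-group comparison with outlier removal and a normality gate
#'
#' Outliers are removed per group (iterative Grubbs at alpha 0.05, ROUT,
#' or none), each group is tested for normality (Shapiro-Wilk at alpha
#' 0.05), and the groups are compared with a two-sided Mann-Whitney U test
#' if either normality test rejects, otherwise with Welch's t-test (equal
#' variances not assumed). The routing is deterministic given the inputs.
#'
#' Mann-Whitney p-values use exact enumeration when both groups have at
#' most 20 observations and no ties are present, and the normal
#' approximation with tie and continuity correction otherwise (so two
#' identical samples give p = 1).
#'
#' @param a,b numeric samples (>= 3 each after outlier removal).
#' @param outlier_method `"grubbs"`, `"rout"`, or `"none"`.
#' @param alpha normality-gate level.
#' @param rout_q ROUT false-discovery rate, percent, when
#'   `outlier_method = "rout"`.
#' @return list with `test` (`"mann-whitney"` or `"welch-t"`), `statistic`,
#'   `p_value`, `n` (per-group sizes after removal), `normality_p`,
#'   `removed` (values dropped per group).
#' @export
compare_groups <- function(a, b, outlier_method = c("grubbs", "rout",
                                                    "none"),
                           alpha = 0.05, rout_q = 1) {
  outlier_method <- match.arg(outlier_method)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values", call. = FALSE)
  clean <- switch(outlier_method,
    grubbs = list(remove_outliers_grubbs(a, alpha = 0.05),
                  remove_outliers_grubbs(b, alpha = 0.05)),
    rout = list(remove_outliers_rout(a, Q = rout_q),
                remove_outliers_rout(b, Q = rout_q)),
    none = list(list(kept = a, removed = a[0]),
                list(kept = b, removed = b[0])))
  ka <- clean[[1]]$kept; kb <- clean[[2]]$kept
  if (length(ka) < 3 || length(kb) < 3)
    stop("fewer than 3 values left after outlier removal", call. = FALSE)
  norm_p <- c(a = shapiro_safe(ka), b = shapiro_safe(kb))
  nonnormal <- any(norm_p < alpha, na.rm = TRUE)
  if (nonnormal) {
    exact <- length(ka) <= 20 && length(kb) <= 20 &&
      !any(duplicated(c(ka, kb)))
    ht <- suppressWarnings(wilcox.test(ka, kb, exact = exact,
                                       correct = TRUE))
    test <- "mann-whitney"
  } else {
    ht <- t.test(ka, kb, var.equal = FALSE)
    test <- "welch-t"
  }
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value,
       n = c(a = length(ka), b = length(kb)),
       normality_p = norm_p,
       removed = list(a = clean[[1]]$removed, b = clean[[2]]$removed))
}

# Shapiro-Wilk p-value; NA (treated as "cannot reject") for degenerate
# samples the test cannot handle.
shapiro_safe <- function(x) {
  if (length(x) < 3 || length(x) > 5000 || sd(x) == 0) return(NA_real_)
  tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
}
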