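#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-mass rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of every table no more probable than the observed one (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `(a b / c d)`.
#' @return the two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_2x2(4, 7, 20, 2)   # 0.002 to 3 decimals
#' fisher_exact_2x2(0, 11, 9, 13)  # 0.015 to 3 decimals
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0) stop("need at least one positive margin")
  stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
}

#' Compare a continuous variable between two groups
#'
#' Implements the distribution-gated dispatch used for cohort tables:
#' Shapiro-Wilk is run on each group at `normality_alpha`; if both groups
#' pass, a two-sided pooled-variance Student's t-test is used and groups
#' are summarised as mean +/- SD, otherwise a two-sided Mann-Whitney U test
#' with median (25th-75th percentile) summaries. A group of identical
#' values (on which Shapiro-Wilk is undefined) falls to the Mann-Whitney
#' branch with a warning.
#'
#' @param x case-group values (>= 3, non-missing values are used).
#' @param y control-group values (>= 3).
#' @param normality_alpha significance level of the normality gate
#'   (default 0.05).
#' @param variable variable name carried into the output row.
#' @return one-row data.frame: `variable`, `test_used` (`"t"` or `"mwu"`),
#'   `statistic`, `p_value`, `case_summary`, `control_summary`.
#' @export
compare_continuous <- function(x, y, normality_alpha = 0.05,
                               variable = "") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 non-missing values per group")
  normal_p <- function(v) {
    if (length(unique(v)) == 1) {
      warning("all values identical in one group; ",
              "using Mann-Whitney with ties")
      return(0)
    }
    shapiro.test(v)$p.value
  }
  normal <- normal_p(x) > normality_alpha && normal_p(y) > normality_alpha
  fmt <- function(v, digits = 3) signif(v, digits)
  if (normal) {
    ht <- t.test(x, y, var.equal = TRUE)
    data.frame(variable = variable, test_used = "t",
               statistic = unname(ht$statistic),
               p_value = ht$p.value,
               case_summary = paste0(fmt(mean(x)), " ± ", fmt(sd(x))),
               control_summary = paste0(fmt(mean(y)), " ± ", fmt(sd(y))),
               stringsAsFactors = FALSE)
  } else {
    p <- mwu_p(x, y, "two.sided")
    u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    qs <- function(v) {
      q <- quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
      paste0(fmt(q[1]), " (", fmt(q[2]), "–", fmt(q[3]), ")")
    }
    data.frame(variable = variable, test_used = "mwu",
               statistic = u, p_value = p,
               case_summary = qs(x), control_summary = qs(y),
               stringsAsFactors = FALSE)
  }
}

#' Group comparison of every column of a sample table
#'
#' Applies [compare_continuous()] to each variable (column) of a numeric
#' samples x variables table, splitting samples by the cohort design.
#'
#' @param values numeric matrix or data.frame (samples x variables) with
#'   sample ids as rownames, e.g. metabolite concentrations or
#'   [derive_panels()] output.
#' @param design a [cohort_design()].
#' @param normality_alpha normality-gate level, see [compare_continuous()].
#' @return data.frame, one row per variable.
#' @export
cohort_comparison <- function(values, design, normality_alpha = 0.05) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.data.frame(values)) {
    if ("sample_id" %in% colnames(values)) {
      rownames(values) <- values$sample_id
      values$sample_id <- NULL
    }
    values <- as.matrix(values)
  }
  check_design_covers(design, rownames(values))
  cs <- group_samples(design, "case", rownames(values))
  ct <- group_samples(design, "control", rownames(values))
  out <- lapply(colnames(values), function(v)
    compare_continuous(values[cs, v], values[ct, v],
                       normality_alpha = normality_alpha, variable = v))
  do.call(rbind, out)
}
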