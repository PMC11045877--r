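#' @include AllClasses.R
NULL

#' Group comparison result
#'
#' @slot testName \code{"t_test_two_tailed_unpaired"} or
#'   \code{"anova_tukey"}.
#' @slot groupLabels,groupMeans Labels and arithmetic means of the groups.
#' @slot statistic t statistic or ANOVA F.
#' @slot pValue Two-sided p-value (omnibus p for ANOVA).
#' @slot pairwise For ANOVA: data frame of Tukey HSD pairwise contrasts
#'   (\code{pair}, \code{diff}, \code{lwr}, \code{upr}, \code{p_adj});
#'   \code{NULL} otherwise.
#' @export
setClass("GroupComparison",
         representation(testName = "character", groupLabels = "character",
                        groupMeans = "numeric", statistic = "numeric",
                        pValue = "numeric", pairwise = "ANY"),
         prototype(pairwise = NULL))

setValidity("GroupComparison", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("p-value must lie in [0, 1]")
  if (object@testName == "anova_tukey" && is.null(object@pairwise))
    return("ANOVA results must carry Tukey pairwise contrasts")
  if (object@testName != "anova_tukey" && !is.null(object@pairwise))
    return("pairwise contrasts are only defined for ANOVA results")
  TRUE
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s]\n", object@testName))
  cat(sprintf("  groups: %s\n  means:  %s\n",
              paste(object@groupLabels, collapse = ", "),
              paste(signif(object@groupMeans, 4), collapse = ", ")))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", object@statistic,
              object@pValue))
  if (!is.null(object@pairwise)) {
    cat("  Tukey HSD:\n")
    for (i in seq_len(nrow(object@pairwise)))
      cat(sprintf("    %s: p_adj = %.4g\n", object@pairwise$pair[i],
                  object@pairwise$p_adj[i]))
  }
})

#' P-value accessor
#' @param x A \linkS4class{GroupComparison}.
#' @return Numeric p-value (omnibus p for ANOVA results).
#' @export
pValue <- function(x) {
  stopifnot(is(x, "GroupComparison"))
  x@pValue
}

#' Tukey pairwise contrasts accessor
#' @param x A \linkS4class{GroupComparison} from
#'   \code{\link{compareMultiGroups}}.
#' @return Data frame of pairwise contrasts with adjusted p-values.
#' @export
pairwiseContrasts <- function(x) {
  stopifnot(is(x, "GroupComparison"))
  x@pairwise
}

#' Two-tailed unpaired t test between two cell populations
#'
#' Per-cell values (one mean relative BiAD signal per cell) are the
#' statistical unit. Default is Welch's unequal-variance form; Student's
#' equal-variance form is available via \code{variant}.
#'
#' @param a,b Numeric vectors of per-cell values (length >= 2 each).
#' @param variant \code{"welch"} or \code{"student"}.
#' @param labels Group labels recorded in the result.
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' compareTwoGroups(c(0.5, 0.6, 0.55), c(0.01, 0.02, 0.015))
#' @export
compareTwoGroups <- function(a, b, variant = c("welch", "student"),
                             labels = c("a", "b")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    stop("degenerate input: both groups constant and equal", call. = FALSE)
  tt <- stats::t.test(a, b, alternative = "two.sided",
                      var.equal = (variant == "student"))
  new("GroupComparison", testName = "t_test_two_tailed_unpaired",
      groupLabels = labels, groupMeans = c(mean(a), mean(b)),
      statistic = unname(tt$statistic), pValue = unname(tt$p.value))
}

#' One-way ANOVA with Tukey's post test
#'
#' Omnibus one-way ANOVA over three or more cell populations followed by
#' Tukey HSD adjusted pairwise comparisons.
#'
#' @param groups Named list of numeric per-cell value vectors (>= 3 groups,
#'   each of length >= 2).
#' @return A \linkS4class{GroupComparison} with the omnibus F and p plus a
#'   pairwise contrast table.
#' @export
compareMultiGroups <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use compareTwoGroups()", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL,
                         stringsAsFactors = FALSE)
  new("GroupComparison", testName = "anova_tukey",
      groupLabels = names(groups),
      groupMeans = vapply(groups, mean, numeric(1L)),
      statistic = an[["F value"]][1L],
      pValue = an[["Pr(>F)"]][1L], pairwise = pairwise)
}

#' Boxplot summary with 1.5 IQR whiskers
#'
#' Median and quartiles by linear-interpolation (type 7) quantiles, the box
#' from the first to the third quartile, whiskers at the most extreme
#' observed values within 1.5 times the interquartile range of the box.
#'
#' @param values Numeric per-cell values.
#' @param replicate_ids Optional replicate label per value, carried with
#'   the points for replicate-colored plotting.
#' @return List: \code{median}, \code{q1}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}, \code{points} (data frame of values with
#'   replicate ids).
#' @export
summarizeBoxplot <- function(values, replicate_ids = NULL) {
  stopifnot(length(values) >= 1L, is.numeric(values))
  if (is.null(replicate_ids)) replicate_ids <- rep(NA_character_,
                                                   length(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7L, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[values >= lo_fence]),
       whisker_high = max(values[values <= hi_fence]),
       points = data.frame(value = values, replicate = replicate_ids,
                           stringsAsFactors = FALSE))
}

#' Replicate-colored boxplot of per-cell signals
#'
#' The figure convention of the assay: one box per group, whiskers at 1.5
#' IQR, one point per cell colored by replicate.
#'
#' @param cells Experiment table (per-cell data frame).
#' @param value Column plotted on y.
#' @param group Grouping column on x.
#' @param replicate Column coloring the points.
#' @return A ggplot object.
#' @export
plotGroupComparison <- function(cells, value = "mean_relative_biad",
                                group = "condition",
                                replicate = "replicate") {
  stopifnot(is.data.frame(cells),
            all(c(value, group) %in% names(cells)))
  p <- ggplot2::ggplot(cells, ggplot2::aes(
    x = .data[[group]], y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 1.5) +
    ggplot2::labs(x = NULL, y = "relative BiAD signal") +
    ggplot2::theme_classic()
  if (replicate %in% names(cells)) {
    p <- p + ggplot2::geom_jitter(
      ggplot2::aes(color = .data[[replicate]]), width = 0.15, size = 1.5,
      alpha = 0.8) +
      ggplot2::scale_color_brewer(palette = "Dark2", name = "replicate")
  } else {
    p <- p + ggplot2::geom_jitter(width = 0.15, size = 1.5, alpha = 0.8)
  }
  p
}
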