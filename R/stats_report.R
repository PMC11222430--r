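#' Group comparison with automatic test selection
#'
#' Implements the test-selection decision tree used for all group
#' comparisons. Two groups: Shapiro-Wilk normality on each sample; when both
#' pass (p > alpha), an F-test decides between Student's t (equal variances)
#' and Welch's t; when normality fails, Welch's t is used by default
#' (\code{nonparametric = TRUE} switches to Mann-Whitney). Three or more
#' groups: one-way ANOVA with Tukey HSD when every sample is normal and
#' Bartlett's test finds homoscedasticity, Kruskal-Wallis otherwise. The
#' full decision path is recorded in the result.
#'
#' @param values numeric vector of measurements.
#' @param groups factor or character vector of group labels (>= 2 levels,
#'   each with n >= 3).
#' @param alpha significance level, also used for the normality/variance
#'   screening (default 0.05).
#' @param nonparametric use Mann-Whitney instead of Welch's t when normality
#'   fails in a two-group design (default FALSE).
#' @return An object of class \code{stat_result}: list with \code{test}
#'   (name), \code{statistic}, \code{p_value}, \code{stars},
#'   \code{decision_path} (named list: per-group Shapiro p's, variance-test
#'   p, branch taken), and \code{posthoc} (Tukey table, multi-group ANOVA
#'   only).
#' @export
#' @examples
#' set.seed(1)
#' r <- select_and_run(c(rnorm(10), rnorm(10, 2)), rep(c("a", "b"), each = 10))
#' r$test
select_and_run <- function(values, groups, alpha = 0.05,
                           nonparametric = FALSE) {
  stopifnot(is.numeric(values), length(values) == length(groups),
            alpha > 0, alpha < 1)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  ns <- table(groups)
  if (any(ns < 3))
    stop("insufficient sample: every group needs n >= 3 (got ",
         paste(ns, collapse = ", "), ")")
  if (stats::var(values) == 0) {
    # degenerate input: every measurement identical; no test can reject
    return(structure(list(test = "none (no variance)", statistic = NA_real_,
                          p_value = 1, stars = "ns",
                          decision_path = list(branch = "degenerate: all values identical",
                                               alpha = alpha),
                          posthoc = NULL),
                     class = "stat_result"))
  }
  samples <- split(values, groups)
  sw <- vapply(samples, function(s) {
    if (length(unique(s)) == 1) return(NA_real_)  # Shapiro undefined
    stats::shapiro.test(s)$p.value
  }, numeric(1))
  all_normal <- all(!is.na(sw) & sw > alpha)
  path <- list(shapiro_p = sw, alpha = alpha)
  if (nlevels(groups) == 2) {
    if (all_normal) {
      ft <- stats::var.test(samples[[1]], samples[[2]])
      path$variance_p <- ft$p.value
      if (ft$p.value > alpha) {
        path$branch <- "normal, homoscedastic -> Student t"
        tt <- stats::t.test(samples[[1]], samples[[2]], var.equal = TRUE)
        test <- "Student t"
      } else {
        path$branch <- "normal, heteroscedastic -> Welch t"
        tt <- stats::t.test(samples[[1]], samples[[2]], var.equal = FALSE)
        test <- "Welch t"
      }
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else if (nonparametric) {
      path$branch <- "non-normal -> Mann-Whitney"
      tt <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
      test <- "Mann-Whitney U"
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      res <- tryCatch({
        tt <- stats::t.test(samples[[1]], samples[[2]], var.equal = FALSE)
        list(branch = "non-normal -> Welch t", test = "Welch t",
             stat = unname(tt$statistic), p = tt$p.value)
      }, error = function(e) {
        # e.g. both samples internally constant: t is undefined, ranks are not
        tt <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
        list(branch = "non-normal, t undefined -> Mann-Whitney",
             test = "Mann-Whitney U", stat = unname(tt$statistic),
             p = tt$p.value)
      })
      path$branch <- res$branch
      test <- res$test
      stat <- res$stat
      p <- res$p
    }
    posthoc <- NULL
  } else {
    bt <- stats::bartlett.test(values, groups)
    path$variance_p <- bt$p.value
    if (all_normal && bt$p.value > alpha) {
      path$branch <- "normal, homoscedastic -> one-way ANOVA + Tukey"
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      test <- "one-way ANOVA"
      stat <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      posthoc <- as.data.frame(stats::TukeyHSD(fit)$groups)
    } else {
      path$branch <- "non-normal or heteroscedastic -> Kruskal-Wallis"
      kt <- stats::kruskal.test(values, groups)
      test <- "Kruskal-Wallis"
      stat <- unname(kt$statistic)
      p <- kt$p.value
      posthoc <- NULL
    }
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 stars = star_annotation(p), decision_path = path,
                 posthoc = posthoc),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g %s\n  path: %s\n",
              x$test, x$statistic, x$p_value, x$stars,
              x$decision_path$branch))
  invisible(x)
}

#' Significance star annotation
#'
#' The conventional ladder with strict inequalities: \code{****} p < 0.0001,
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, otherwise
#' \code{ns}.
#'
#' @param p p-value in \[0, 1\].
#' @return character label.
#' @export
#' @examples
#' star_annotation(0.03)   # "*"
#' star_annotation(0.05)   # "ns" (strict threshold)
star_annotation <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Run grouped comparisons over a tidy readout table
#'
#' @param data data frame with columns \code{value}, \code{group} and
#'   optionally \code{readout} (one comparison per readout level).
#' @param alpha significance level (default 0.05).
#' @param ... passed to [select_and_run()].
#' @return data frame with one row per readout: test, statistic, p, stars,
#'   branch. No multiplicity correction is applied across readouts (Tukey
#'   adjusts within an ANOVA only).
#' @export
compare_readouts <- function(data, alpha = 0.05, ...) {
  stopifnot(all(c("value", "group") %in% names(data)))
  if (!"readout" %in% names(data)) data$readout <- "value"
  res <- lapply(split(data, data$readout), function(d) {
    r <- select_and_run(d$value, d$group, alpha = alpha, ...)
    data.frame(readout = d$readout[1], test = r$test,
               statistic = r$statistic, p_value = r$p_value,
               stars = r$stars, branch = r$decision_path$branch)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
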