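# Group statistics: two-group t-tests (raw samples or published
# mean ± SD summaries), two-way ANOVA over treatment × compartment with
# Bonferroni-corrected per-compartment comparisons, and the significance
# star convention *p<0.05, **p<0.01, ***p<0.001.

#' Summarize a group as n / mean / SD
#'
#' Used to reproduce tests from published "average ± standard deviation"
#' values when raw measurements are not available.
#'
#' @param n sample size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param label optional group label.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd, label = NULL) {
  if (!is.finite(n) || n < 2) abort("group `n` must be >= 2")
  if (!is.finite(sd) || sd < 0) abort("group `sd` must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 label = label %||% "group"),
            class = "group_summary")
}

as_group_summary <- function(x, label) {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  if (length(x) < 2L) abort("each group needs at least 2 observations")
  group_summary(length(x), mean(x), sd(x), label)
}

#' Significance stars
#'
#' @param p p-value(s) in \[0, 1\].
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `""` otherwise.
#' @export
stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Two-group t-test from raw samples or summary statistics
#'
#' Student's (pooled-variance) t-test by default, matching the convention
#' for two-group comparisons of image-derived readouts; Welch's variant is
#' available and suggested (with a message) when the group SDs differ by
#' more than a factor of two. Raw-sample inputs go through
#' [stats::t.test()]; `group_summary` inputs use the textbook formulas,
#' which agree with the raw path to numerical precision.
#'
#' @param a,b numeric vectors of raw measurements, or [group_summary()]
#'   objects.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A one-row tibble of class `comparison_result`: `comparison`,
#'   `method`, `statistic` (t), `df`, `p_value`, `stars`.
#' @export
two_group_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  ga <- as_group_summary(a, "a")
  gb <- as_group_summary(b, "b")
  if (variant == "student" && min(ga$sd, gb$sd) > 0 &&
      max(ga$sd, gb$sd) / min(ga$sd, gb$sd) > 2) {
    inform("group SDs differ by more than 2x; consider variant = \"welch\"")
  }
  raw <- is.numeric(a) && is.numeric(b)
  if (raw) {
    ht <- stats::t.test(a, b, var.equal = (variant == "student"))
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  } else {
    n1 <- ga$n; n2 <- gb$n; s1 <- ga$sd; s2 <- gb$sd
    if (variant == "student") {
      sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se <- sqrt(s1^2 / n1 + s2^2 / n2)
      df <- (s1^2 / n1 + s2^2 / n2)^2 /
        ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    }
    if (se == 0) abort("zero standard error; groups have no variance")
    t_stat <- (ga$mean - gb$mean) / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  out <- tibble(
    comparison = paste(ga$label, "vs", gb$label),
    method = paste0(if (variant == "student") "Student" else "Welch",
                    " two-sample t-test"),
    statistic = t_stat, df = df, p_value = p, stars = stars(p)
  )
  structure(out, class = c("comparison_result", class(out)))
}

#' Two-way ANOVA with Bonferroni-corrected per-compartment comparisons
#'
#' Fits `value ~ treatment * compartment`, reports the overall F-tests for
#' both factors and their interaction (classical sequential sums of squares
#' for balanced designs, Type II via [car::Anova()] for unbalanced ones),
#' and compares the two treatment levels within every compartment using the
#' pooled residual variance, Bonferroni-corrected over the number of
#' compartments — the per-compartment asterisks of a grouped bar panel.
#'
#' @param data a data frame in long format.
#' @param value,treatment,compartment column names (tidy-eval) holding the
#'   measurement, the treatment factor (exactly 2 levels for the
#'   per-compartment comparisons) and the compartment factor.
#' @return An object of class `two_way_anova` with components `anova`
#'   (tibble of F-tests) and `comparisons` (tibble of per-compartment
#'   results with `adjusted_p` and `stars`); see [tidy()] and [glance()]
#'   methods.
#' @export
two_way_anova_bonferroni <- function(data, value, treatment, compartment) {
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    treatment = factor(dplyr::pull(data, {{ treatment }})),
    compartment = factor(dplyr::pull(data, {{ compartment }}))
  )
  if (nlevels(df$treatment) < 2L || nlevels(df$compartment) < 2L) {
    abort("both factors need at least 2 levels")
  }
  counts <- table(df$treatment, df$compartment)
  if (any(counts == 0L)) {
    bad <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    abort(sprintf("empty cell: treatment '%s' x compartment '%s'",
                  rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  if (any(counts < 2L)) abort("every cell needs at least 2 replicates")
  balanced <- length(unique(as.vector(counts))) == 1L

  fit <- stats::lm(value ~ treatment * compartment, data = df)
  if (balanced) {
    at <- stats::anova(fit)
  } else {
    at <- car::Anova(fit, type = 2)
  }
  an <- as_tibble(at, rownames = "term")
  names(an) <- sub("^Sum Sq$", "sumsq", names(an))
  names(an) <- sub("^Df$", "df", names(an))
  names(an) <- sub("^F value$", "statistic", names(an))
  names(an) <- sub("^Pr\\(>F\\)$", "p_value", names(an))
  an$term <- sub("^treatment:compartment$", "interaction", an$term)
  an <- an[, intersect(c("term", "df", "sumsq", "statistic", "p_value"),
                       names(an))]

  mse <- sum(stats::resid(fit)^2) / fit$df.residual
  comparisons <- NULL
  if (nlevels(df$treatment) == 2L) {
    lv <- levels(df$treatment)
    m <- nlevels(df$compartment)
    comparisons <- purrr::map_dfr(levels(df$compartment), function(cl) {
      sub <- df[df$compartment == cl, ]
      n1 <- sum(sub$treatment == lv[1L])
      n2 <- sum(sub$treatment == lv[2L])
      diff <- mean(sub$value[sub$treatment == lv[1L]]) -
        mean(sub$value[sub$treatment == lv[2L]])
      se <- sqrt(mse * (1 / n1 + 1 / n2))
      t_stat <- diff / se
      p <- 2 * pt(-abs(t_stat), fit$df.residual)
      tibble(compartment = cl,
             comparison = paste(lv[1L], "vs", lv[2L]),
             estimate = diff, statistic = t_stat,
             df = fit$df.residual, p_value = p,
             adjusted_p = min(1, m * p))
    })
    comparisons$stars <- stars(comparisons$adjusted_p)
  } else {
    inform("per-compartment comparisons need exactly 2 treatment levels; skipped")
  }
  structure(list(anova = an, comparisons = comparisons,
                 n_comparisons = nlevels(df$compartment),
                 balanced = balanced, fit = fit),
            class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (%s, %s sums of squares)\n",
              if (x$balanced) "balanced" else "unbalanced",
              if (x$balanced) "sequential" else "Type II"))
  print(x$anova)
  if (!is.null(x$comparisons)) {
    cat(sprintf("\nPer-compartment comparisons (Bonferroni m = %d):\n",
                x$n_comparisons))
    print(x$comparisons)
  }
  invisible(x)
}

#' @rdname two_way_anova_bonferroni
#' @param x a `two_way_anova` object.
#' @param ... unused.
#' @export
tidy.two_way_anova <- function(x, ...) {
  if (is.null(x$comparisons)) x$anova else x$comparisons
}

#' @rdname two_way_anova_bonferroni
#' @export
glance.two_way_anova <- function(x, ...) {
  an <- x$anova[x$anova$term != "Residuals", ]
  out <- list()
  for (i in seq_len(nrow(an))) {
    nm <- gsub("[^a-z]+", "_", tolower(an$term[i]))
    out[[paste0("f_", nm)]] <- an$statistic[i]
    out[[paste0("p_", nm)]] <- an$p_value[i]
  }
  out$df_residual <- x$fit$df.residual
  as_tibble(out)
}

#' @export
tidy.comparison_result <- function(x, ...) {
  as_tibble(unclass(x))
}
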