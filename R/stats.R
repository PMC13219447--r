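#' Two-tailed unpaired t-test
#'
#' Student's pooled-variance two-sample t-test (the default for two-group
#' comparisons here), two-sided. Welch's unequal-variance form is
#' available behind `var_equal = FALSE`.
#'
#' @param x,y numeric vectors, each with at least 2 values.
#' @param var_equal pooled-variance Student test if `TRUE` (default),
#'   Welch otherwise.
#' @return one-row tibble: `mean_x`, `mean_y`, `estimate` (difference of
#'   means), `statistic`, `df`, `p_value`, `stars`.
#' @export
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
unpaired_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs at least 2 values")
  pooled_sd <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                      (length(x) + length(y) - 2))
  if (pooled_sd == 0) {
    # degenerate: both groups constant
    equal <- mean(x) == mean(y)
    stat <- if (equal) 0 else sign(mean(x) - mean(y)) * Inf
    p <- if (equal) 1 else 0
    return(tibble::tibble(mean_x = mean(x), mean_y = mean(y),
                          estimate = mean(x) - mean(y), statistic = stat,
                          df = length(x) + length(y) - 2, p_value = p,
                          stars = signif_stars(p)))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(mean_x = mean(x), mean_y = mean(y),
                 estimate = mean(x) - mean(y),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stars = signif_stars(tt$p.value))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' For three or more groups: the omnibus F test followed by Tukey's
#' honestly-significant-difference all-pairs comparisons (studentized
#' range distribution).
#'
#' @param data a data frame in tidy form, or a named list of numeric
#'   vectors (one per group).
#' @param value,group column names (unquoted) when `data` is a data
#'   frame; defaults `value` and `group`.
#' @return object of class `anova_tukey`; use [generics::tidy()] for the
#'   pairwise table (`comparison`, `estimate`, `conf_low`, `conf_high`,
#'   `adj_p_value`, `stars`) and [generics::glance()] for the omnibus row
#'   (`statistic`, `df_between`, `df_within`, `p_value`).
#' @export
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 4),
#'                 value = c(1, 2, 2, 3, 4, 5, 5, 6, 1, 1, 2, 2))
#' tidy(anova_tukey(d))
anova_tukey <- function(data, value = value, group = group) {
  if (is.list(data) && !is.data.frame(data)) {
    stopifnot(!is.null(names(data)))
    data <- tibble::tibble(
      group = rep(names(data), lengths(data)),
      value = unlist(data, use.names = FALSE)
    )
    df <- data
  } else {
    df <- tibble::tibble(
      value = dplyr::pull(data, {{ value }}),
      group = as.character(dplyr::pull(data, {{ group }}))
    )
  }
  df <- dplyr::filter(df, is.finite(.data$value))
  k <- dplyr::n_distinct(df$group)
  if (k < 3) abort("fewer than 3 groups; use `unpaired_t_test()` for two-group comparisons")
  if (any(table(df$group) < 2)) abort("each group needs at least 2 values")
  df$group <- factor(df$group)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- tibble::tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"],
    stars = signif_stars(tk[, "p adj"])
  )
  structure(list(
    fit = fit,
    omnibus = tibble::tibble(statistic = an["group", "F value"],
                             df_between = an["group", "Df"],
                             df_within = an["Residuals", "Df"],
                             p_value = an["group", "Pr(>F)"],
                             stars = signif_stars(an["group", "Pr(>F)"])),
    pairwise = pairwise
  ), class = "anova_tukey")
}

#' Competitive-growth fitness
#'
#' Relative fitness of knockout vs wild-type cells in a co-culture:
#' the knockout efficiency after co-culture normalized to the initial
#' knockout efficiency.
#'
#' @param ko_d0 initial KO fraction(s), in (0, 1].
#' @param ko_d10 end-of-interval KO fraction(s), in \[0, 1\].
#' @return tibble: `ko_d0`, `ko_d10`, `fitness` (`ko_d10 / ko_d0`; NA
#'   with `defined = FALSE` where `ko_d0` is 0).
#' @export
#' @examples
#' competitive_fitness(0.5, 0.25) # fitness 0.5
competitive_fitness <- function(ko_d0, ko_d10) {
  stopifnot(length(ko_d0) == length(ko_d10),
            all(ko_d0 >= 0 & ko_d0 <= 1), all(ko_d10 >= 0 & ko_d10 <= 1))
  undefined <- ko_d0 == 0
  if (any(undefined)) warn("`ko_d0` of 0: fitness undefined for those entries")
  tibble::tibble(ko_d0 = ko_d0, ko_d10 = ko_d10,
                 fitness = ifelse(undefined, NA_real_, ko_d10 / ko_d0),
                 defined = !undefined)
}

#' Per-group mean and standard deviation
#'
#' Group summaries in the conventional mean ± SD form (sample SD, n - 1
#' denominator; NA for singleton groups).
#'
#' @inheritParams anova_tukey
#' @return tibble: `group`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' summarize_groups(data.frame(group = c("a", "a", "b"), value = 1:3))
summarize_groups <- function(data, value = value, group = group) {
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = dplyr::pull(data, {{ group }})
  )
  if (nrow(df) == 0) abort("no data")
  dplyr::summarise(dplyr::group_by(df, .data$group),
                   n = dplyr::n(),
                   mean = mean(.data$value),
                   sd = sd(.data$value),
                   .groups = "drop")
}
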