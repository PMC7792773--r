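## Between-population statistics for estimated membrane parameters:
## one-way ANOVA with Tukey post hoc, plus Kruskal-Wallis for data at risk
## of non-normality. Deliberately thin wrappers over the standard routines.

#' Compare parameter populations across groups
#'
#' One-way ANOVA (significance level `alpha`), Tukey's HSD as the post-hoc
#' test (applied when the ANOVA rejects), and the Kruskal-Wallis test, for
#' e.g. per-vesicle bending-rigidity estimates across peptide treatments.
#'
#' @param data A data frame in long format.
#' @param value,group Column names (tidy-eval) holding the numeric samples
#'   and the group labels.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `population_comparison`: list with
#'   `group_summary` (n, mean, sd per group), `anova` (F, p), `kruskal`
#'   (H, p), `tukey` (pairwise tibble with adjusted p and `significant`),
#'   `alpha`, and `significant_pairs` (character vector, empty when the
#'   ANOVA does not reject).
#' @export
#' @examples
#' df <- data.frame(kappa = c(rnorm(10, 10), rnorm(10, 3)),
#'                  system = rep(c("POPC", "AB40"), each = 10))
#' compare_populations(df, kappa, system)
compare_populations <- function(data, value, group, alpha = 0.05) {
  v <- rlang::enquo(value); g <- rlang::enquo(group)
  df <- tibble(value = dplyr::pull(data, !!v),
               group = as.character(dplyr::pull(data, !!g)))
  df <- filter(df, is.finite(.data$value))
  counts <- count(df, .data$group)
  if (nrow(counts) < 2) abort("need at least 2 groups")
  if (any(counts$n < 3)) abort("every group needs at least 3 observations")
  zero_var <- summarise(group_by(df, .data$group), v = var(.data$value),
                        .groups = "drop")
  if (all(zero_var$v == 0)) {
    abort("all groups have zero variance; comparison is degenerate")
  }
  gs <- summarise(group_by(df, .data$group),
                  n = n(), mean = mean(.data$value), sd = sd(.data$value),
                  .groups = "drop")
  df$group <- factor(df$group)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  anova_res <- tibble(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                      df_between = an[["Df"]][1], df_within = an[["Df"]][2])
  kw <- kruskal.test(value ~ group, data = df)
  kruskal_res <- tibble(H = unname(kw$statistic), p = kw$p.value,
                        df = unname(kw$parameter))
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- tibble(
    pair = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  anova_rejects <- is.finite(anova_res$p) && anova_res$p < alpha
  sig_pairs <- if (anova_rejects) tukey$pair[tukey$significant] else character(0)
  structure(list(
    group_summary = gs, anova = anova_res, kruskal = kruskal_res,
    tukey = tukey, alpha = alpha, anova_rejects = anova_rejects,
    significant_pairs = sig_pairs
  ), class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf(
    "<population_comparison> %d groups; ANOVA F = %.3f, p = %.3g; Kruskal-Wallis H = %.3f, p = %.3g\n",
    nrow(x$group_summary), x$anova$F, x$anova$p, x$kruskal$H, x$kruskal$p))
  if (x$anova_rejects) {
    cat("  Tukey-significant pairs:",
        if (length(x$significant_pairs)) paste(x$significant_pairs, collapse = "; ")
        else "none", "\n")
  } else {
    cat(sprintf("  ANOVA does not reject at alpha = %g; post hoc not applied\n",
                x$alpha))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.population_comparison <- function(x, ...) x$tukey

#' @exportS3Method generics::glance
glance.population_comparison <- function(x, ...) {
  tibble(n_groups = nrow(x$group_summary),
         anova_F = x$anova$F, anova_p = x$anova$p,
         kruskal_H = x$kruskal$H, kruskal_p = x$kruskal$p,
         n_significant_pairs = length(x$significant_pairs),
         alpha = x$alpha)
}
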