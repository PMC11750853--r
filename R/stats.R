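prep_groups <- function(values, group) {
  stopifnot(length(values) == length(group))
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 observations")
  list(values = values, group = group)
}

#' Classical one-way fixed-effects ANOVA
#'
#' F statistic with (k - 1, N - k) degrees of freedom, computed by base
#' `aov`. Zero total variance leaves F undefined; that case is reported as
#' `NA` with a note rather than an error.
#'
#' @param values numeric outcome vector.
#' @param group group labels (coerced to factor); every group needs
#'   n >= 2.
#' @return a list with `F`, `df1`, `df2`, `p`, `msw` (within-group mean
#'   square), and per-group `means`, `sds`, `ns`. Class `ov_anova`.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(c("a", "b", "c"), each = 3))
#' @export
one_way_anova <- function(values, group) {
  g <- prep_groups(values, group)
  means <- tapply(g$values, g$group, mean)
  sds <- tapply(g$values, g$group, stats::sd)
  ns <- as.integer(table(g$group))
  k <- nlevels(g$group); N <- length(g$values)
  out <- list(F = NA_real_, df1 = k - 1L, df2 = N - k, p = NA_real_,
              msw = NA_real_, means = means, sds = sds, ns = ns,
              note = NULL)
  if (stats::var(g$values) == 0) {
    out$note <- "zero total variance: F undefined"
    class(out) <- "ov_anova"
    return(out)
  }
  fit <- stats::aov(g$values ~ g$group)
  tab <- summary(fit)[[1]]
  out$F <- tab[["F value"]][1]
  out$p <- tab[["Pr(>F)"]][1]
  out$msw <- tab[["Mean Sq"]][2]
  class(out) <- "ov_anova"
  out
}

#' @export
print.ov_anova <- function(x, ...) {
  if (is.na(x$F)) {
    cat(sprintf("<one-way ANOVA> %s\n", x$note %||% "F undefined"))
  } else {
    cat(sprintf("<one-way ANOVA> F(%d, %d) = %.4f, p = %.4g\n",
                x$df1, x$df2, x$F, x$p))
  }
  invisible(x)
}

#' Variance-homogeneity test (Levene, centred on the mean)
#'
#' The gate that decides between LSD and Games-Howell post hoc tests.
#' Degenerate input (all groups constant) is reported as `NA` with a
#' `"not applicable"` note.
#'
#' @inheritParams one_way_anova
#' @return the Levene test p value (possibly `NA`).
#' @export
homogeneity_test <- function(values, group) {
  g <- prep_groups(values, group)
  within_sds <- tapply(g$values, g$group, stats::sd)
  if (all(within_sds == 0)) {
    out <- NA_real_
    attr(out, "note") <- "not applicable: zero variance in every group"
    return(out)
  }
  # Levene regresses |y - group mean| on group; degenerate deviation
  # patterns leave its ANOVA undefined
  z <- abs(g$values - stats::ave(g$values, g$group))
  if (stats::var(z) == 0) {
    out <- 1
    attr(out, "note") <- "degenerate: identical absolute deviations everywhere"
    return(out)
  }
  if (all(tapply(z, g$group, stats::sd) == 0)) {
    out <- 0
    attr(out, "note") <- "degenerate: deviations constant within each group"
    return(out)
  }
  tab <- car::leveneTest(g$values ~ g$group, center = mean)
  tab[1, "Pr(>F)"]
}

#' Pairwise post hoc tests: LSD or Games-Howell
#'
#' * **LSD** (least significant difference): unadjusted pairwise t tests
#'   using the pooled within-group mean square from the overall ANOVA,
#'   with N - k degrees of freedom. Appropriate when variances are
#'   homogeneous.
#' * **Games-Howell**: pairwise Welch-type statistics
#'   `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#'   Welch-Satterthwaite degrees of freedom, referred to the studentized
#'   range distribution (`p = ptukey(|t| * sqrt(2), k, df)`). Appropriate
#'   under unequal variances.
#'
#' @inheritParams one_way_anova
#' @param method `"LSD"` or `"Games-Howell"`.
#' @return data frame with one row per group pair: `group1`, `group2`,
#'   `estimate` (mean difference), `statistic`, `df`, `p.value`,
#'   `method`.
#' @export
pairwise_posthoc <- function(values, group, method = c("LSD", "Games-Howell")) {
  method <- match.arg(method)
  g <- prep_groups(values, group)
  lev <- levels(g$group)
  k <- length(lev)
  means <- tapply(g$values, g$group, mean)
  vars <- tapply(g$values, g$group, stats::var)
  ns <- tapply(g$values, g$group, length)
  N <- length(g$values)

  msw <- df_pooled <- NULL
  if (method == "LSD") {
    fit <- stats::aov(g$values ~ g$group)
    msw <- stats::deviance(fit) / stats::df.residual(fit)
    df_pooled <- N - k
  }

  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- means[[a]] - means[[b]]
    if (method == "LSD") {
      se <- sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
      tt <- est / se
      p <- if (se == 0) {
        if (est == 0) 1 else 0
      } else 2 * stats::pt(-abs(tt), df_pooled)
      data.frame(group1 = a, group2 = b, estimate = est, statistic = tt,
                 df = df_pooled, p.value = p, method = method,
                 stringsAsFactors = FALSE)
    } else {
      va <- vars[[a]] / ns[[a]]; vb <- vars[[b]] / ns[[b]]
      se <- sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (ns[[a]] - 1) + vb^2 / (ns[[b]] - 1))
      tt <- est / se
      p <- if (se == 0) {
        if (est == 0) 1 else 0
      } else stats::ptukey(abs(tt) * sqrt(2), nmeans = k, df = df,
                           lower.tail = FALSE)
      data.frame(group1 = a, group2 = b, estimate = est, statistic = tt,
                 df = df, p.value = p, method = method,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Full three-group comparison for one parameter
#'
#' One-way ANOVA, Levene homogeneity gate, and the gated pairwise post hoc
#' battery: LSD when the Levene p value is at least `alpha_levene`,
#' Games-Howell otherwise. Normality (Shapiro-Wilk per group) is reported
#' for information but never gates the analysis. Missing values are
#' dropped listwise for this parameter.
#'
#' @inheritParams one_way_anova
#' @param parameter name recorded in the result.
#' @param alpha significance level for the overall and pairwise calls.
#' @param alpha_levene level of the homogeneity gate.
#' @return a list of class `vessel_anova`: `parameter`, `anova`
#'   (an `ov_anova`), `homogeneity_p`, `posthoc_method`, `posthoc`
#'   (pairwise table), `significant` (overall, at `alpha`),
#'   `shapiro_p` (per group, `NA` where not computable), `alpha`.
#' @export
compare_groups <- function(values, group, parameter = NA_character_,
                           alpha = 0.05, alpha_levene = 0.05) {
  an <- one_way_anova(values, group)
  hom <- homogeneity_test(values, group)
  g <- prep_groups(values, group)
  shapiro_p <- vapply(levels(g$group), function(lv) {
    v <- g$values[g$group == lv]
    if (length(v) >= 3 && length(v) <= 5000 && stats::sd(v) > 0) {
      stats::shapiro.test(v)$p.value
    } else NA_real_
  }, numeric(1))
  if (is.na(an$F)) {
    method <- NA_character_
    ph <- NULL
  } else {
    method <- if (!is.na(hom) && hom < alpha_levene) "Games-Howell" else "LSD"
    ph <- pairwise_posthoc(values, group, method = method)
    ph$significant <- ph$p.value < alpha
  }
  structure(
    list(parameter = parameter, anova = an, homogeneity_p = as.numeric(hom),
         posthoc_method = method, posthoc = ph,
         significant = !is.na(an$p) && an$p < alpha,
         shapiro_p = shapiro_p, alpha = alpha),
    class = "vessel_anova"
  )
}

#' @export
print.vessel_anova <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$parameter %||% "parameter"))
  print(x$anova)
  cat(sprintf("  Levene p = %.4g -> %s post hoc\n",
              x$homogeneity_p, x$posthoc_method))
  if (!is.null(x$posthoc)) {
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf("  %s vs %s: p = %.4g%s\n",
                  x$posthoc$group1[i], x$posthoc$group2[i],
                  x$posthoc$p.value[i],
                  if (x$posthoc$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

vessel_parameters <- function() {
  c("RAOD", "RALD", "RVOD", "RVLD", "AWT", "VWT", "AWLR", "VWLR",
    "AWCSA", "VWCSA", "AVR")
}

#' Compare all vessel parameters across the cohort groups
#'
#' Runs [compare_groups()] for each requested parameter of a cohort table
#' and renders a mean +- SD summary table (four decimals) with a P-value
#' column, one row per parameter.
#'
#' @param cohort a `cohort_table` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param parameters character vector of parameter column names; defaults
#'   to all eleven. Unknown names are an error.
#' @param alpha,alpha_levene forwarded to [compare_groups()].
#' @return a list of class `cohort_comparison`: `results` (named list of
#'   `vessel_anova`) and `table` (the rendered data frame).
#' @examples
#' coh <- generate_cohort(reference_group_specs(), seed = 7)
#' cmp <- run_table(coh, parameters = c("VWT", "AVR"))
#' cmp$table
#' @export
run_table <- function(cohort, parameters = NULL, alpha = 0.05,
                      alpha_levene = 0.05) {
  parameters <- parameters %||% vessel_parameters()
  unknown <- setdiff(parameters, names(cohort))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  grp <- factor(cohort$group)
  results <- lapply(parameters, function(p) {
    compare_groups(cohort[[p]], grp, parameter = p,
                   alpha = alpha, alpha_levene = alpha_levene)
  })
  names(results) <- parameters

  lev <- levels(grp)
  tab <- do.call(rbind, lapply(results, function(r) {
    cells <- vapply(seq_along(lev), function(i) {
      sprintf("%s ± %s", fmt4(r$anova$means[[lev[i]]]),
              fmt4(r$anova$sds[[lev[i]]]))
    }, character(1))
    p <- r$anova$p
    df <- data.frame(parameter = r$parameter, t(cells),
                     P = if (is.na(p)) "NA" else if (p < 1e-4) "<0.0001"
                         else fmt4(p),
                     stringsAsFactors = FALSE)
    names(df)[2:(1 + length(lev))] <- lev
    df
  }))
  rownames(tab) <- NULL
  structure(list(results = results, table = tab),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a cohort comparison to CSV
#'
#' @param comparison a `cohort_comparison` from [run_table()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "cohort_comparison"))
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}
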