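#' Normalize values to a reference group's mean
#'
#' Divides every value by the mean of the reference group, the convention
#' used when presenting per-cell readouts relative to the young or untreated
#' control group. The reference group's normalized mean is exactly 1.
#'
#' @param data Data frame with one row per cell.
#' @param reference Label of the reference group.
#' @param value,group Columns holding the measurement and the group label
#'   (unquoted; default `value` and `group`).
#' @return `data` with an added `normalized` column.
#' @examples
#' df <- tibble::tibble(group = c("young", "young", "aged", "aged"),
#'                      value = c(4, 4, 2, 6))
#' normalize_to_reference(df, "young")
#' @export
normalize_to_reference <- function(data, reference, value = value,
                                   group = group) {
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  if (!reference %in% g) abort("reference group not present in `group`.")
  ref_mean <- mean(v[g == reference])
  if (ref_mean == 0) abort("reference group mean is zero; cannot normalize.")
  mutate(data, normalized = v / ref_mean)
}

#' Two-group comparison (unpaired t-test with reference normalization)
#'
#' Classical unpaired two-tailed Student's t-test (equal variances by
#' default; set `var_equal = FALSE` for the Welch variant). Summaries report
#' per-group n, mean, SEM (`sd/sqrt(n)`), and means normalized to the
#' reference group.
#'
#' @param data Data frame, one row per cell.
#' @param value,group Measurement and group columns (unquoted).
#' @param reference Reference group label (default: first group in the
#'   data's order).
#' @param var_equal Use the pooled-variance Student's test (default `TRUE`).
#' @return A `group_result` object; see [tidy.group_result()] and
#'   [glance.group_result()].
#' @export
compare_two_groups <- function(data, value = value, group = group,
                               reference = NULL, var_equal = TRUE) {
  v <- eval_tidy(enquo(value), data)
  g <- as.character(eval_tidy(enquo(group), data))
  lev <- unique(g)
  if (length(lev) != 2L) abort("exactly two groups are required.")
  if (any(tabulate(factor(g, lev)) < 2L)) {
    abort("each group needs at least two observations.")
  }
  if (is.null(reference)) reference <- lev[1]
  tt <- t.test(v[g == lev[1]], v[g == lev[2]], var.equal = var_equal,
               alternative = "two.sided")
  new_group_result(
    summary = group_summary(v, g, lev, reference),
    test = if (var_equal) "t_test" else "welch_t_test",
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    posthoc = NULL,
    reference = reference)
}

#' Multi-group comparison (one-way ANOVA with Tukey HSD)
#'
#' One-way ANOVA across three or more groups followed by a multiple
#' comparisons test: Tukey HSD by default (the standard companion to one-way
#' ANOVA), Bonferroni-adjusted pairwise t-tests optionally. Groups sharing no
#' significant pairwise difference receive the same significance letter, so
#' groups "indicated by different letters" differ at the chosen alpha.
#'
#' Two groups are accepted (the ANOVA then reproduces the equal-variance
#' t-test, `F = t^2`); the usual entry point for two groups is
#' [compare_two_groups()].
#'
#' @inheritParams compare_two_groups
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `group_result` with a `posthoc` tibble
#'   (`comparison`, `estimate`, `p_adj`).
#' @export
compare_many_groups <- function(data, value = value, group = group,
                                reference = NULL,
                                posthoc = c("tukey", "bonferroni"),
                                alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  v <- eval_tidy(enquo(value), data)
  g <- as.character(eval_tidy(enquo(group), data))
  lev <- unique(g)
  if (length(lev) < 2L) abort("need at least two groups.")
  if (any(tabulate(factor(g, lev)) < 2L)) {
    abort("each group needs at least two observations.")
  }
  if (is.null(reference)) reference <- lev[1]
  gf <- factor(g, levels = lev)
  fit <- aov(v ~ gf)
  an <- summary(fit)[[1]]
  ph <- if (posthoc == "tukey") {
    tk <- TukeyHSD(fit)$gf
    tibble(comparison = rownames(tk), estimate = tk[, "diff"],
           p_adj = tk[, "p adj"])
  } else {
    pairs <- utils::combn(lev, 2)
    raw <- apply(pairs, 2, function(pr) {
      t.test(v[g == pr[1]], v[g == pr[2]], var.equal = TRUE)$p.value
    })
    est <- apply(pairs, 2, function(pr) mean(v[g == pr[2]]) - mean(v[g == pr[1]]))
    tibble(comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
           estimate = est, p_adj = p.adjust(raw, "bonferroni"))
  }
  new_group_result(
    summary = group_summary(v, g, lev, reference,
                            letters = significance_letters(lev, ph, alpha)),
    test = "anova",
    statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    posthoc = ph,
    reference = reference)
}

group_summary <- function(v, g, lev, reference, letters = NULL) {
  ref_mean <- mean(v[g == reference])
  out <- bind_rows(lapply(lev, function(l) {
    x <- v[g == l]
    tibble(group = l, n = length(x), mean = mean(x),
           sem = sd(x) / sqrt(length(x)),
           normalized_mean = if (ref_mean != 0) mean(x) / ref_mean
                             else NA_real_)
  }))
  if (!is.null(letters)) out$letters <- unname(letters[out$group])
  out
}

# compact letter display via insert-and-absorb over the pairwise p matrix
significance_letters <- function(lev, posthoc, alpha) {
  k <- length(lev)
  differ <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(posthoc))) {
    pr <- strsplit(posthoc$comparison[i], "-", fixed = TRUE)[[1]]
    if (posthoc$p_adj[i] < alpha) {
      differ[pr[1], pr[2]] <- differ[pr[2], pr[1]] <- TRUE
    }
  }
  groups <- list()  # each element: set of levels sharing a letter
  for (l in lev) {
    placed <- FALSE
    for (j in seq_along(groups)) {
      if (!any(differ[l, groups[[j]]])) {
        groups[[j]] <- c(groups[[j]], l); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- l
  }
  # drop letter-sets wholly contained in another
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a != b && keep[a] && all(groups[[a]] %in% groups[[b]]) &&
        length(groups[[a]]) < length(groups[[b]])) keep[a] <- FALSE
  }
  groups <- groups[keep]
  out <- setNames(rep("", k), lev)
  for (j in seq_along(groups)) {
    out[groups[[j]]] <- paste0(out[groups[[j]]], letters[j])
  }
  out
}

new_group_result <- function(summary, test, statistic, p_value, df, posthoc,
                             reference) {
  structure(list(summary = summary, test = test, statistic = statistic,
                 p_value = p_value, df = df, posthoc = posthoc,
                 reference = reference),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s n = %-3d mean +/- SEM = %.4g +/- %.4g (norm %.3g)%s%s\n",
                s$group[i], s$n[i], s$mean[i], s$sem[i],
                s$normalized_mean[i],
                if ("letters" %in% names(s)) paste0("  ", s$letters[i]) else "",
                significance_marker(x$p_value)))
  }
  invisible(x)
}

significance_marker <- function(p) {
  if (!is.finite(p)) "" else if (p <= 0.01) " **" else if (p < 0.05) " *"
  else ""
}

#' Tidy a group comparison
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @return Per-group tibble: `group`, `n`, `mean`, `sem`,
#'   `normalized_mean` (reference = 1), and significance `letters` for ANOVA
#'   results.
#' @export
tidy.group_result <- function(x, ...) as_tibble(x$summary)

#' One-row summary of a group comparison
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @return Tibble with `test`, `statistic`, `p_value`, degrees of freedom
#'   and the reference group.
#' @export
glance.group_result <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         reference = x$reference)
}

#' Plot a group comparison
#'
#' Normalized mean +/- SEM per group with per-cell points, the standard
#' presentation for reference-normalized readouts.
#'
#' @param object A `group_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_result <- function(object, ...) {
  s <- as_tibble(object$summary)
  sem_norm <- s$sem / ifelse(s$normalized_mean == 0, 1,
                             s$mean / s$normalized_mean)
  s$sem_norm <- sem_norm
  ggplot(s, aes(x = .data$group, y = .data$normalized_mean)) +
    geom_col(fill = "grey70", width = 0.6) +
    geom_errorbar(aes(ymin = .data$normalized_mean - .data$sem_norm,
                      ymax = .data$normalized_mean + .data$sem_norm),
                  width = 0.2) +
    labs(y = sprintf("normalized to %s (mean +/- SEM)", object$reference),
         x = NULL,
         subtitle = sprintf("%s: p = %.3g", object$test, object$p_value)) +
    theme_minimal()
}

#' Dose-response summary
#'
#' Per-dose means of area, count, and viability, flagging dose levels whose
#' viability falls below a cutoff as excluded from statistics (with the
#' reason recorded), the convention used when a top dose is overtly toxic.
#'
#' @param data Data frame with one row per cell/replicate.
#' @param dose,area,count,viability Columns (unquoted): dose level (uM),
#'   mean vesicle area (um^2), vesicle count, and viability as a fraction in
#'   `[0, 1]`.
#' @param min_viability Doses with mean viability below this fraction are
#'   excluded from statistics (default 0.5).
#' @return Tibble: `dose_um`, `n`, `mean_area_um2`, `mean_count`,
#'   `viability`, `excluded`, `exclusion_reason`.
#' @export
dose_response_summary <- function(data, dose = dose, area = area,
                                  count = count, viability = viability,
                                  min_viability = 0.5) {
  d <- eval_tidy(enquo(dose), data)
  a <- eval_tidy(enquo(area), data)
  k <- eval_tidy(enquo(count), data)
  vb <- eval_tidy(enquo(viability), data)
  if (any(vb < 0 | vb > 1, na.rm = TRUE)) {
    abort("`viability` must be a fraction in [0, 1].")
  }
  lev <- sort(unique(d))
  out <- bind_rows(lapply(lev, function(l) {
    sel <- d == l
    tibble(dose_um = l, n = sum(sel), mean_area_um2 = mean(a[sel]),
           mean_count = mean(k[sel]), viability = mean(vb[sel]))
  }))
  out$excluded <- out$viability < min_viability
  out$exclusion_reason <- ifelse(
    out$excluded,
    sprintf("low viability (%.0f%% < %.0f%%)", 100 * out$viability,
            100 * min_viability),
    NA_character_)
  out
}
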