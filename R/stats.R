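#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Classical one-way ANOVA on one measurement of a long-format cohort
#' table, followed by Tukey's honestly-significant-difference test on all
#' group pairs using the studentized-range distribution (the Tukey-Kramer
#' form, valid for unequal group sizes such as 6/8/4). Group summaries are
#' reported as mean +/- sample SD.
#'
#' @param table Data frame with columns `animal`, `group`, `measurement`,
#'   `value` (the layout produced by [simulate_cohort()]).
#' @param measurement Name of the measurement to compare.
#' @param alpha Significance level (default 0.05).
#' @return List of class `comparison_result`: `measurement`, `F`,
#'   `p_anova`, `df`, `pairwise` (data.frame: group_a, group_b, diff, lwr,
#'   upr, p_adj, significant), `summaries` (group, n, mean, sd), `alpha`,
#'   and `degenerate` (TRUE when within-group variance is zero, leaving F
#'   undefined).
#' @examples
#' tab <- data.frame(animal = paste0("a", 1:6),
#'                   group = rep(c("g1", "g2"), each = 3),
#'                   measurement = "m",
#'                   value = c(1, 2, 3, 2, 3, 4))
#' anova_tukey(tab, "m")$F  # 1.5
#' @export
anova_tukey <- function(table, measurement, alpha = 0.05) {
  d <- table[table$measurement == measurement, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for measurement '", measurement, "'")
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2L) stop("need at least 2 groups")
  cnt <- tapply(d$value, d$group, length)
  cnt[is.na(cnt)] <- 0L
  small <- names(cnt)[cnt < 2]
  if (length(small))
    stop("group(s) with fewer than 2 values: ",
         paste(small, collapse = ", "))

  # zero within-group variance leaves F undefined (floating dust aside):
  # detect it by exact constancy rather than trusting aov's 0/0
  degenerate <- all(tapply(d$value, d$group,
                           function(v) max(v) == min(v)))

  if (degenerate) {
    means <- tapply(d$value, d$group, mean)
    grand <- mean(d$value)
    cnt_n <- tapply(d$value, d$group, length)
    between <- sum(cnt_n * (means - grand)^2)
    Fval <- if (between == 0) 0 else Inf
    pval <- NA_real_
    an <- NULL
    dfs <- c(between = nlevels(d$group) - 1L,
             within = nrow(d) - nlevels(d$group))
  } else {
    fit <- aov(value ~ group, data = d)
    an <- summary(fit)[[1]]
    Fval <- an$`F value`[1]
    pval <- an$`Pr(>F)`[1]
    dfs <- c(between = an$Df[1], within = an$Df[2])
  }

  pw <- if (degenerate) {
    lv <- levels(d$group)
    means <- tapply(d$value, d$group, mean)
    combs <- utils::combn(lv, 2)
    data.frame(group_a = combs[2, ], group_b = combs[1, ],
               diff = unname(means[combs[2, ]] - means[combs[1, ]]),
               lwr = NA_real_, upr = NA_real_, p_adj = NA_real_,
               significant = NA)
  } else {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
    # TukeyHSD names rows "a-b"; split against the known level names so
    # group labels that themselves contain hyphens parse correctly
    lv <- levels(d$group)
    pairs_ab <- t(vapply(rownames(tk), function(rn) {
      for (a in lv) for (b in lv)
        if (a != b && rn == paste0(a, "-", b)) return(c(a, b))
      c(NA_character_, NA_character_)
    }, character(2)))
    data.frame(group_a = pairs_ab[, 1],
               group_b = pairs_ab[, 2],
               diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
               p_adj = tk[, "p adj"],
               significant = tk[, "p adj"] < alpha)
  }
  rownames(pw) <- NULL

  summ <- do.call(rbind, lapply(levels(d$group), function(g) {
    v <- d$value[d$group == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v))
  }))

  structure(
    list(measurement = measurement, F = Fval, p_anova = pval,
         df = dfs,
         pairwise = pw, summaries = summ, alpha = alpha,
         degenerate = degenerate),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: F(%d, %d) = %.4g, p = %.3g\n",
              x$measurement, x$df[1], x$df[2], x$F, x$p_anova))
  for (i in seq_len(nrow(x$summaries)))
    cat(sprintf("  %-10s n = %d  %.4g +/- %.4g\n",
                x$summaries$group[i], x$summaries$n[i],
                x$summaries$mean[i], x$summaries$sd[i]))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Fold change against an endogenous control (here 18S rRNA in the
#' emulated study) and a calibrator group:
#' \deqn{\Delta\Delta Ct = (Ct_{target,s} - Ct_{ref,s}) -
#'       (Ct_{target,c} - Ct_{ref,c}), \quad fold = 2^{-\Delta\Delta Ct}.}
#' Vectors of technical replicates are averaged before differencing.
#'
#' @param ct_target_sample,ct_ref_sample Sample Ct values (target and
#'   endogenous-control genes).
#' @param ct_target_calib,ct_ref_calib Calibrator-group Ct values.
#' @return Fold change (unitless), with attribute `ddct`.
#' @examples
#' ddct_fold_change(25, 20, 24, 20)  # ddCt 1 -> fold 0.5
#' ddct_fold_change(22, 20, 24, 20)  # ddCt -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calib, ct_ref_calib) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calib, ct_ref_calib)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (mean(ct_target_sample) - mean(ct_ref_sample)) -
    (mean(ct_target_calib) - mean(ct_ref_calib))
  structure(2^(-ddct), ddct = ddct)
}

#' Average Mac-1-positive cell counts over microscope fields
#'
#' Per-sample immune-infiltration score: the arithmetic mean of
#' Mac-1-positive cell counts over separate 40x field views (three per
#' sample in the emulated protocol).
#'
#' @param field_counts Non-negative counts, one per field.
#' @param n_required Expected number of fields (default 3); set NULL to
#'   accept any count.
#' @return Mean cells per field.
#' @examples
#' mac1_average(c(18, 20, 20))  # 19.33
#' @export
mac1_average <- function(field_counts, n_required = 3L) {
  if (length(field_counts) == 0L) stop("empty field-count list")
  if (any(field_counts < 0)) stop("counts must be >= 0")
  if (!is.null(n_required) && length(field_counts) != n_required)
    stop("expected ", n_required, " field counts, got ",
         length(field_counts))
  mean(field_counts)
}
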