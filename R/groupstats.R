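#' Kruskal-Wallis dose test for one region's VoA
#'
#' Rank-based H statistic (with tie correction, via [stats::kruskal.test()])
#' comparing per-subject VoA counts across dose groups, with the chi-square
#' p on k - 1 df and an omega-squared effect size. The default effect size
#' is `(H - k + 1) / (n - k)`; `effect = "epsilon"` gives the
#' epsilon-squared variant `H (n + 1) / (n^2 - 1)`. Effect sizes can be
#' slightly negative under the null; they are reported as computed, with a
#' floored-at-zero display column.
#'
#' @param voa_by_group named list of numeric vectors, one per dose group
#'   (>= 2 groups of >= 2 subjects each).
#' @param region_id,name optional identifiers copied into the row.
#' @param effect `"omega"` (default) or `"epsilon"`.
#' @return one-row data.frame: ids, per-group `mean_<group>` / `se_<group>`,
#'   `H`, `df`, `p`, `omega_squared`, `omega_squared_display`.
#' @export
kruskal_dose_test <- function(voa_by_group, region_id = NA, name = NA,
                              effect = c("omega", "epsilon")) {
  effect <- match.arg(effect)
  k <- length(voa_by_group)
  if (k < 2L || any(vapply(voa_by_group, length, 1L) < 2L))
    stop("need >= 2 groups with >= 2 subjects each")
  x <- unlist(voa_by_group, use.names = FALSE)
  grp <- factor(rep(names(voa_by_group), vapply(voa_by_group, length, 1L)),
                levels = names(voa_by_group))
  n <- length(x)
  if (length(unique(x)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, grp)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  om <- if (effect == "omega") (H - k + 1) / (n - k) else H * (n + 1) / (n^2 - 1)
  row <- data.frame(region_id = region_id, name = name,
                    stringsAsFactors = FALSE)
  for (gname in names(voa_by_group)) {
    v <- voa_by_group[[gname]]
    row[[paste0("mean_", gname)]] <- mean(v)
    row[[paste0("se_", gname)]] <- stats::sd(v) / sqrt(length(v))
  }
  row$H <- H
  row$df <- k - 1L
  row$p <- p
  row$omega_squared <- om
  row$omega_squared_display <- max(om, 0)
  row
}

#' Two-group comparison: rank or Welch t
#'
#' `mode = "rank"` runs the Mann-Whitney/Wilcoxon rank-sum test (exact
#' where n permits, without continuity quibbles left to [stats::wilcox.test()]);
#' `mode = "t"` runs Welch's unequal-variance two-sample t, two-tailed.
#' A zero-variance degenerate t comparison is flagged rather than silently
#' producing `NaN`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param mode `"rank"` or `"t"`.
#' @return list: `statistic`, `p`, `mode`, `degenerate` flag.
#' @export
two_group_compare <- function(a, b, mode = c("rank", "t")) {
  mode <- match.arg(mode)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (mode == "rank") {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    list(statistic = unname(wt$statistic), p = wt$p.value, mode = mode,
         degenerate = FALSE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(list(statistic = if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b)),
                  p = if (mean(a) == mean(b)) 1 else 0, mode = mode,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(tt$statistic), p = tt$p.value, mode = mode,
         degenerate = FALSE)
  }
}

#' Dose comparison of macro-region VoA fractions
#'
#' The regional dose analysis: per-subject VoA fractions for one
#' macro-region compared across dose groups. `method = "anova"` fits a
#' subject-blocked one-way ANOVA (`fraction ~ subject + dose`, the matched
#' design) and reports the dose F with Tukey HSD pairwise comparisons;
#' `method = "friedman"` runs the nonparametric matched-blocks variant
#' (used for the whole-brain comparison). Both require complete blocks:
#' every subject rank observed at every dose.
#'
#' @param df data.frame with columns `subject`, `dose`, `fraction`;
#'   `subject` codes the matched block (e.g. subject rank within group).
#' @param method `"anova"` or `"friedman"`.
#' @return list: `statistic` (F or Friedman chi-square), `df`, `p`, and for
#'   ANOVA a `tukey` data.frame of pairwise dose contrasts.
#' @export
region_group_anova <- function(df, method = c("anova", "friedman")) {
  method <- match.arg(method)
  req <- c("subject", "dose", "fraction")
  if (!all(req %in% names(df))) stop("df needs columns subject, dose, fraction")
  df$subject <- factor(df$subject)
  df$dose <- factor(df$dose)
  cells <- table(df$subject, df$dose)
  if (any(cells == 0L)) {
    miss <- which(cells == 0L, arr.ind = TRUE)
    stop(sprintf("missing subject x dose cell(s): %s",
                 paste(sprintf("%s@%s", rownames(cells)[miss[, 1]],
                               colnames(cells)[miss[, 2]]), collapse = ", ")))
  }
  if (any(tapply(df$fraction, df$dose, length) < 2L))
    stop("each dose group needs >= 2 observations")
  if (method == "anova") {
    fit <- stats::aov(fraction ~ subject + dose, data = df)
    tab <- summary(fit)[[1]]
    i <- which(trimws(rownames(tab)) == "dose")
    tk <- stats::TukeyHSD(fit, which = "dose")$dose
    list(statistic = tab[i, "F value"],
         df = c(tab[i, "Df"], tab[nrow(tab), "Df"]),
         p = tab[i, "Pr(>F)"],
         tukey = data.frame(contrast = rownames(tk), tk, row.names = NULL),
         method = method)
  } else {
    ft <- stats::friedman.test(fraction ~ dose | subject, data = df)
    list(statistic = unname(ft$statistic), df = unname(ft$parameter),
         p = ft$p.value, method = method)
  }
}

#' Rank regions by significance and flag the FDR pass set
#'
#' Orders Kruskal-Wallis (or any) test rows by ascending p, applies the
#' same Benjamini-Hochberg step-up filter used at the voxel level across
#' regions, flags the passing rows, and reports the largest passing
#' p-value — the single "the FDR was p = x" summary number for a ranked
#' table.
#'
#' @param rows data.frame with a `p` column (one row per region).
#' @param q target FDR across regions (default 0.05).
#' @param c_V the constant c(V).
#' @return list: `table` (rows sorted by p with `rank` and `fdr_flag`
#'   columns), `fdr` (the [fdr_filter()] result), `p_cutoff` (largest
#'   passing p, `NA` if none pass).
#' @export
rank_and_flag <- function(rows, q = 0.05, c_V = 1) {
  if (!nrow(rows)) stop("need at least one row")
  f <- fdr_filter(rows$p, q = q, c_V = c_V)
  rows$fdr_flag <- f$pass
  ord <- order(rows$p)
  out <- rows[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(table = out, fdr = f, p_cutoff = f$p_cutoff)
}

#' Two-factor repeated-measures ANOVA for group time courses
#'
#' Time x treatment ANOVA on per-subject region time courses with subject
#' as the error stratum for the within-subject time factor — the standard
#' group test behind a time-course figure. Kept deliberately plain: factors
#' in, the summary table of the within-stratum effects out.
#'
#' @param df data.frame with columns `subject`, `time`, `treatment`,
#'   `value`; `time` and `treatment` are coerced to factors.
#' @return data.frame of effects (`effect`, `df1`, `df2`, `F`, `p`) for
#'   treatment, time and the time x treatment interaction.
#' @export
timecourse_anova <- function(df) {
  req <- c("subject", "time", "treatment", "value")
  if (!all(req %in% names(df)))
    stop("df needs columns subject, time, treatment, value")
  df$subject <- factor(df$subject)
  df$time <- factor(df$time)
  df$treatment <- factor(df$treatment)
  fit <- stats::aov(value ~ treatment * time + Error(subject / time), data = df)
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm == "Residuals") next
      rows[[nm]] <- data.frame(effect = nm, df1 = tab[i, "Df"],
                               df2 = tab[nrow(tab), "Df"],
                               F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
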