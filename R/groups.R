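# Group comparison: per-metric z-scores versus control, one-way ANOVA with
# Bonferroni or resampling-based many-to-one (Dunnett-style) correction, and
# heatmap export.

#' z-score of a treatment group against its control
#'
#' `z = (mean(treatment) - mean(control)) / sd(control)`. The control-only
#' standard deviation is used (not pooled) so the score reads as "how many
#' control standard deviations the treatment moved", preserving
#' directionality across metrics.
#'
#' @param treatment,control Numeric vectors (each dendrite is one
#'   observation).
#' @return A single z value. A zero-variance control is flagged with an
#'   error (`"degenerate control"`).
#' @export
zscore_vs_control <- function(treatment, control) {
  if (length(control) < 2L) stop("control needs >= 2 values")
  s <- stats::sd(control)
  if (!is.finite(s) || s == 0) stop("degenerate control: zero variance")
  (mean(treatment) - mean(control)) / s
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F statistic with its F-distribution p-value.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), n))
  fit <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  Fv <- unname(fit$statistic)
  # identical groups: 0/0 mean squares
  if (!is.finite(Fv)) Fv <- 0
  p <- unname(fit$p.value)
  if (!is.finite(p)) p <- 1
  list(F = Fv, p = p, df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]))
}

#' Multiple-comparison adjustment
#'
#' `bonferroni` multiplies each p-value by the family size (capped at 1).
#' `dunnett_approx` is the many-to-one design: it ignores `p` and instead
#' recomputes adjusted p-values from the group data via
#' [dunnett_compare()]'s seeded permutation approximation of the Dunnett
#' null, so `groups` (control first) must be supplied.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"dunnett_approx"`.
#' @param groups For `dunnett_approx`: list of numeric vectors, control
#'   first.
#' @param ... Passed to [dunnett_compare()].
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "dunnett_approx"),
                           groups = NULL, ...) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  method <- match.arg(method)
  if (method == "bonferroni") {
    stats::p.adjust(p, method = "bonferroni")
  } else {
    if (is.null(groups)) {
      stop("dunnett_approx recomputes p-values from the data; ",
           "supply `groups` (control first)")
    }
    dunnett_compare(groups, ...)$p_adj
  }
}

#' Permutation approximation of Dunnett's many-to-one comparison
#'
#' Compares every treatment group against the control with pooled-variance
#' t statistics and adjusts for the family by referencing each |t| to the
#' permutation distribution of the maximum |t| across comparisons (labels
#' permuted jointly, preserving group sizes), a seeded resampling
#' approximation of the multivariate-t Dunnett null.
#'
#' @param groups List of numeric vectors, control first.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @return Data frame with one row per treatment: `t`, `p_adj`.
#' @export
dunnett_compare <- function(groups, n_perm = 999L, seed = 1L) {
  k <- length(groups) - 1L
  if (k < 1L) stop("need a control and at least one treatment group")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), n)
  tstats <- function(v, g) {
    means <- tapply(v, g, mean)
    vars <- tapply(v, g, stats::var)
    s2 <- sum((n - 1) * vars) / (sum(n) - length(n))
    (means[-1] - means[1]) / sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  }
  t_obs <- tstats(values, idx)
  t_max <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    max(abs(tstats(values[sample.int(length(values))], idx)))
  }, numeric(1)))
  p_adj <- vapply(abs(t_obs), function(t0)
    (1 + sum(t_max >= t0)) / (n_perm + 1), numeric(1))
  data.frame(treatment = seq_len(k), t = as.numeric(t_obs),
             p_adj = p_adj)
}

#' Compare metric distributions across exposure groups
#'
#' Joins a metric report with a group assignment (`image_id`, `group`,
#' `control` flag), and for every one of the 19 metrics computes per-group
#' summaries (n, mean, sd), the z-score of each treatment against the
#' control, the one-way ANOVA p-value across all groups, and adjusted
#' p-values. Each dendrite row (aggregate rows excluded) counts as one
#' observation.
#'
#' @param report A `"metric_report"` data frame (see [read_report()]).
#' @param groups Data frame with columns `image_id`, `group`, `control`
#'   (logical; exactly one group flagged).
#' @param method `"bonferroni"` (within-metric family across treatments) or
#'   `"dunnett_approx"`.
#' @param alpha Significance level for the `significant` flag.
#' @param metrics Metric columns to compare (default: all except the
#'   categorical score).
#' @param ... Passed to [dunnett_compare()].
#' @return List of class `"group_comparison"`: `summaries` (group x metric),
#'   `comparisons` (metric x treatment: z, p_raw, p_adj, significant),
#'   `control` (group label).
#' @export
compare_groups <- function(report, groups, method = "bonferroni",
                           alpha = 0.05,
                           metrics = setdiff(metric_schema(),
                                             "degeneration_category"),
                           ...) {
  stopifnot(all(c("image_id", "group", "control") %in% names(groups)))
  df <- report[report$dendrite_index != "all", , drop = FALSE]
  df <- merge(df, groups, by = "image_id")
  if (!nrow(df)) stop("no report rows match the group assignment")
  ctrl_label <- unique(groups$group[as.logical(groups$control)])
  if (length(ctrl_label) != 1L) stop("exactly one group must be the control")
  trt_labels <- setdiff(unique(df$group), ctrl_label)
  summaries <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(unique(df$group), function(g) {
      v <- df[[m]][df$group == g]
      v <- v[is.finite(v)]
      data.frame(group_label = g, metric_name = m, n = length(v),
                 mean = mean(v), sd = stats::sd(v))
    }))
  }))
  comparisons <- do.call(rbind, lapply(metrics, function(m) {
    ctrl <- df[[m]][df$group == ctrl_label]
    ctrl <- ctrl[is.finite(ctrl)]
    vals <- lapply(trt_labels, function(g) {
      v <- df[[m]][df$group == g]
      v[is.finite(v)]
    })
    usable <- vapply(vals, function(v) length(v) >= 2L, logical(1))
    if (length(ctrl) < 2L || stats::sd(ctrl) == 0 || !any(usable)) {
      return(data.frame(metric_name = m, group_label = trt_labels,
                        z_score = NA_real_, p_raw = NA_real_,
                        p_adj = NA_real_, significant = NA,
                        flag = "degenerate control or group"))
    }
    z <- vapply(vals, function(v)
      if (length(v)) zscore_vs_control(v, ctrl) else NA_real_, numeric(1))
    glist <- c(list(ctrl), vals[usable])
    p_raw <- rep(NA_real_, length(trt_labels))
    p_raw[usable] <- vapply(which(usable), function(i)
      anova_oneway(list(ctrl, vals[[i]]))$p, numeric(1))
    if (method == "dunnett_approx") {
      p_adj <- rep(NA_real_, length(trt_labels))
      p_adj[usable] <- dunnett_compare(glist, ...)$p_adj
    } else {
      p_adj <- adjust_pvalues(p_raw, "bonferroni")
    }
    data.frame(metric_name = m, group_label = trt_labels, z_score = z,
               p_raw = p_raw, p_adj = p_adj,
               significant = !is.na(p_adj) & p_adj < alpha, flag = "")
  }))
  structure(list(summaries = summaries, comparisons = comparisons,
                 control = ctrl_label, alpha = alpha, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison vs control '", x$control, "' (", x$method,
      ", alpha = ", x$alpha, ")\n", sep = "")
  sig <- x$comparisons[!is.na(x$comparisons$significant) &
                         x$comparisons$significant, ]
  cat(nrow(sig), "significant metric x group effects\n")
  invisible(x)
}

#' Export comparison heatmaps
#'
#' Writes the two comparison panels as CSV matrices (signed z-scores and a
#' boolean `p_adj < alpha` matrix, metrics x groups) and renders them as a
#' two-panel PNG heatmap.
#'
#' @param cmp A [compare_groups()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
export_heatmaps <- function(cmp, dir, prefix = "comparison") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- cmp$comparisons
  zmat <- stats::xtabs(z_score ~ metric_name + group_label, data = cc,
                       na.action = stats::na.pass)
  smat <- stats::xtabs(significant ~ metric_name + group_label, data = cc,
                       na.action = stats::na.pass)
  zcsv <- file.path(dir, paste0(prefix, "_zscores.csv"))
  scsv <- file.path(dir, paste0(prefix, "_significant.csv"))
  utils::write.csv(as.data.frame.matrix(zmat), zcsv)
  utils::write.csv(as.data.frame.matrix(smat) > 0, scsv)
  pngf <- file.path(dir, paste0(prefix, "_heatmap.png"))
  grDevices::png(pngf, width = 1200, height = 700)
  op <- graphics::par(mfrow = c(1, 2), mar = c(10, 10, 3, 2))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  draw <- function(m, main, col) {
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    graphics::image(t(m), axes = FALSE, main = main, col = col)
    graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                   labels = colnames(m), las = 2)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                   labels = rownames(m), las = 2)
  }
  zl <- max(abs(zmat), na.rm = TRUE)
  zdraw <- pmax(pmin(zmat, zl), -zl)
  draw(zdraw, "z-score vs control",
       grDevices::hcl.colors(64, "Blue-Red 2"))
  draw(smat, sprintf("adjusted p < %g", cmp$alpha),
       c("grey90", "firebrick"))
  invisible(c(zcsv, scsv, pngf))
}
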