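# Group-level statistics: pooled-variance two-sample t-tests on per-bin
# VLD and plaque density, mirroring a two-phenotype imaging study.

#' Unpaired pooled-variance Student's t-test
#'
#' Two-sided Student's t with the pooled variance estimate and
#' `df = n_a + n_b - 2` (not Welch; see [compare_cohort()] for the
#' Welch option).
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @param welch use the Welch-Satterthwaite variant instead.
#' @param metric,label_a,label_b labels carried into the result.
#' @return list of class `group_comparison` with `t_statistic`, `df`,
#'   `p_value`, per-group means, s.d., s.e. and n.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE, metric = "",
                            label_a = "A", label_b = "B") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 finite values")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (ma == mb) { tstat <- 0; df <- na + nb - 2 }
      else stop("zero variance with unequal means: t undefined")
    } else {
      tstat <- (ma - mb) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    if (sp2 == 0) {
      if (ma == mb) tstat <- 0
      else stop("zero pooled variance with unequal means: t undefined")
    } else {
      tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    }
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(metric = metric, group_a = label_a, group_b = label_b,
                 t_statistic = tstat, df = df, p_value = p,
                 mean_a = ma, mean_b = mb,
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 se_a = stats::sd(a) / sqrt(na),
                 se_b = stats::sd(b) / sqrt(nb),
                 n_a = na, n_b = nb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: %s (%.3g +/- %.3g, n=%d) vs %s (%.3g +/- %.3g, n=%d)\n  t = %.4g, df = %.3g, p = %.4g\n",
    x$metric, x$group_a, x$mean_a, x$sd_a, x$n_a,
    x$group_b, x$mean_b, x$sd_b, x$n_b, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare per-subject metrics between groups
#'
#' Runs one unpaired t-test per (metric, group pair): each VLD diameter
#' bin, total VLD, and plaque density when supplied.  Reports raw
#' p-values (per-bin, uncorrected) plus a clearly-labeled Holm-corrected
#' column as an extension.  Groups with fewer than 2 subjects are
#' skipped with a warning.
#'
#' @param vld list of `vld_profile` objects, one per subject (or `NULL`
#'   entries to skip).
#' @param labels group label per subject.
#' @param plaque_density optional numeric vector, plaques per mm^2 per
#'   subject.
#' @param welch use Welch's t instead of the pooled Student's t.
#' @return data.frame: metric, bin, group_a, group_b, n_a, n_b, mean_a,
#'   mean_b, sd_a, sd_b, se_a, se_b, t, df, p, p_holm.
#' @export
compare_cohort <- function(vld, labels, plaque_density = NULL,
                           welch = FALSE) {
  stopifnot(length(vld) == length(labels))
  groups <- unique(labels)
  rows <- list()
  metrics <- list()
  if (length(vld) && !is.null(vld[[1]])) {
    bins <- vld[[1]]$profile$bin
    for (b in seq_along(bins)) {
      metrics[[paste0("vld_", bins[b])]] <-
        vapply(vld, function(v) v$profile$vld[b], numeric(1))
    }
    metrics[["vld_total"]] <- vapply(vld, function(v) v$total_vld,
                                     numeric(1))
  }
  if (!is.null(plaque_density))
    metrics[["plaque_density"]] <- plaque_density
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  for (mname in names(metrics)) {
    vals <- metrics[[mname]]
    for (pr in pairs) {
      ia <- labels == pr[1]; ib <- labels == pr[2]
      if (sum(ia) < 2 || sum(ib) < 2) {
        warning("skipping ", mname, " for ", pr[1], " vs ", pr[2],
                ": group with n < 2")
        next
      }
      ct <- unpaired_t_test(vals[ia], vals[ib], welch = welch,
                            metric = mname, label_a = pr[1],
                            label_b = pr[2])
      is_bin <- grepl("^vld_", mname) && mname != "vld_total"
      rows[[length(rows) + 1L]] <- data.frame(
        metric = if (is_bin) "vld" else mname,
        bin = if (is_bin) sub("^vld_", "", mname) else "",
        group_a = ct$group_a, group_b = ct$group_b,
        n_a = ct$n_a, n_b = ct$n_b,
        mean_a = ct$mean_a, mean_b = ct$mean_b,
        sd_a = ct$sd_a, sd_b = ct$sd_b,
        se_a = ct$se_a, se_b = ct$se_b,
        t = ct$t_statistic, df = ct$df, p = ct$p_value)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out))
    out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
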