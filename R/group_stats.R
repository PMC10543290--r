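# Group-comparison layer: 2-SD inclusion filter, pooled-variance two-tailed
# t tests, two-way (optionally repeated-measures) ANOVA and Sidak-family
# post hoc adjustments. Applies to any metric table produced upstream.

#' Two-standard-deviation inclusion filter
#'
#' Single pass per group: mean and SD are computed on the full group and
#' values farther than 2 SD from the mean are excluded; the filter is not
#' re-iterated on the retained values. Groups with fewer than 3 values are
#' passed through unfiltered with a warning.
#'
#' @param values numeric vector.
#' @param group optional grouping factor (one group when NULL).
#' @return list: `retained` (data.frame value/group), `excluded` (data.frame
#'   value/group/reason).
#' @export
filter_2sd <- function(values, group = NULL) {
  if (is.null(group)) group <- rep("all", length(values))
  group <- as.character(group)
  ret <- list(); exc <- list()
  for (g in unique(group)) {
    v <- values[group == g]
    ok <- !is.na(v)
    if (sum(ok) < 3) {
      warning("group '", g, "' has n < 3; 2-SD filter skipped")
      keep <- ok
    } else {
      m <- mean(v[ok]); s <- stats::sd(v[ok])
      keep <- ok & abs(v - m) <= 2 * s
      keep[is.na(keep)] <- FALSE
    }
    ret[[g]] <- data.frame(value = v[keep], group = g)
    if (any(!keep))
      exc[[g]] <- data.frame(
        value = v[!keep], group = g,
        reason = ifelse(is.na(v[!keep]), "missing value",
                        sprintf("beyond mean +/- 2 SD (%.4g +/- %.4g)",
                                mean(v[ok]), 2 * stats::sd(v[ok]))))
  }
  list(
    retained = do.call(rbind, c(ret, list(make.row.names = FALSE))),
    excluded = if (length(exc))
      do.call(rbind, c(exc, list(make.row.names = FALSE)))
    else data.frame(value = numeric(0), group = character(0),
                    reason = character(0))
  )
}

#' Pooled-variance two-tailed t test between two groups
#'
#' Student's t with pooled variance (the classical equal-variance form),
#' df = nA + nB - 2. Degenerate inputs with zero pooled variance return
#' p = 1 when the means are equal and p = 0 (flagged) when they differ.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return one-row data.frame: `test`, `statistic`, `df`, `p_value`,
#'   `mean_a`, `mean_b`, `direction` ("a>b", "a<b" or "a=b").
#' @export
group_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  pooled_var <- ((length(a) - 1) * stats::var(a) +
                   (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (pooled_var == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(data.frame(
      test = "student_t", statistic = if (eq) 0 else Inf, df = df,
      p_value = if (eq) 1 else 0, mean_a = mean(a), mean_b = mean(b),
      direction = if (eq) "a=b" else if (mean(a) > mean(b)) "a>b" else "a<b"
    ))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  data.frame(
    test = "student_t", statistic = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value,
    mean_a = mean(a), mean_b = mean(b),
    direction = if (mean(a) > mean(b)) "a>b"
      else if (mean(a) < mean(b)) "a<b" else "a=b"
  )
}

#' Two-way ANOVA on a long metric table
#'
#' Fits `value ~ between * within` with [stats::aov()]. With
#' `repeated = TRUE` the within factor is treated as repeated measures: an
#' `Error(id/within)` stratum removes subject variance from the error term,
#' and subjects missing any within level are dropped (complete case) with a
#' warning.
#'
#' @param table data.frame with columns `id`, `value`, plus the two factor
#'   columns named by `between` and `within`.
#' @param between name of the between-subjects factor column.
#' @param within name of the second (or within-subjects) factor column.
#' @param repeated logical; repeated-measures variant.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p_value`.
#' @export
two_way_anova <- function(table, between = "group_label", within = "div",
                          repeated = FALSE) {
  stopifnot(all(c("id", "value", between, within) %in% names(table)))
  d <- data.frame(
    id = factor(table$id), value = table$value,
    B = factor(table[[between]]), W = factor(table[[within]])
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (repeated) {
    full <- table(d$id)
    n_lev <- nlevels(d$W)
    bad <- names(full)[full < n_lev]
    if (length(bad)) {
      warning("dropping ", length(bad),
              " subject(s) missing a within-factor level")
      d <- d[!(as.character(d$id) %in% bad), , drop = FALSE]
      d$id <- droplevels(d$id)
    }
    fit <- stats::aov(value ~ B * W + Error(id / W), data = d)
    # each Error stratum tests its effects against its own residual term
    out <- do.call(rbind, lapply(summary(fit), function(s) {
      s <- s[[1]]
      eff <- trimws(rownames(s))
      resid_df <- s$Df[eff == "Residuals"]
      keep <- eff != "Residuals" & !is.na(s$`F value`)
      if (!any(keep)) return(NULL)
      data.frame(effect = eff[keep], df1 = s$Df[keep],
                 df2 = if (length(resid_df)) resid_df else NA_real_,
                 F = s$`F value`[keep], p_value = s$`Pr(>F)`[keep])
    }))
  } else {
    # a single-level factor collapses the design to a one-way ANOVA
    form <- if (nlevels(d$W) < 2) value ~ B
      else if (nlevels(d$B) < 2) value ~ W
      else value ~ B * W
    fit <- stats::aov(form, data = d)
    s <- summary(fit)[[1]]
    eff <- trimws(rownames(s))
    resid_df <- s$Df[eff == "Residuals"]
    keep <- eff != "Residuals"
    out <- data.frame(effect = eff[keep], df1 = s$Df[keep], df2 = resid_df,
                      F = s$`F value`[keep], p_value = s$`Pr(>F)`[keep])
  }
  out$effect <- sub("^B$", between, out$effect)
  out$effect <- sub("^W$", within, out$effect)
  out$effect <- sub("^B:W$", paste0(between, ":", within), out$effect)
  rownames(out) <- NULL
  out
}

#' Post hoc multiple-comparison adjustment
#'
#' Methods: `sidak` (1 - (1-p)^m), `bonferroni_dunn` (min(1, m p)) and
#' `holm_sidak` (step-down Sidak with monotonicity enforced). Adjusted
#' values are always >= the raw p and monotone in it.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param method one of "sidak", "holm_sidak", "bonferroni_dunn".
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
posthoc_adjust <- function(p, method = c("sidak", "holm_sidak",
                                         "bonferroni_dunn")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  switch(method,
    sidak = 1 - (1 - p)^m,
    bonferroni_dunn = pmin(1, m * p),
    holm_sidak = {
      o <- order(p)
      adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
      adj <- cummax(adj)
      out <- numeric(m); out[o] <- pmin(1, adj)
      out
    }
  )
}
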