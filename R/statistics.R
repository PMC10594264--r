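#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Two degenerate samples with zero variance and
#' equal means return t = 0, p = 1 by convention.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return one-row data.frame: effect, statistic, df, p, n1, n2.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(data.frame(effect = "welch", statistic = 0,
                        df = length(a) + length(b) - 2, p = 1,
                        n1 = length(a), n2 = length(b)))
    stop("both variances are zero with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(effect = "welch", statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             n1 = length(a), n2 = length(b))
}

# Greenhouse-Geisser epsilon from the pooled within-subject covariance
gg_epsilon <- function(wide) {
  # wide: subjects x within-levels matrix of residuals (group means removed)
  S <- stats::cov(wide)
  k <- ncol(S)
  mbar <- mean(S)
  rowm <- rowMeans(S)
  num <- (k * (mean(diag(S)) - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mbar^2)
  if (den <= 0) return(1)
  min(max(num / den, 1 / (k - 1)), 1)
}

#' Two-way repeated-measures (mixed-design) ANOVA
#'
#' One between-subjects factor (group) and one within-subjects factor
#' (timepoint/bin). Sums of squares are partitioned with the subject stratum
#' as the error for the between effect and the within x subject residual as
#' the error for the within and interaction effects (via `aov` with an
#' `Error(subject)` stratum). Subjects missing any within level are dropped
#' and recorded in attribute `dropped_subjects`. When the within factor has
#' more than two levels a Greenhouse-Geisser corrected p-value (`p_gg`) is
#' reported alongside the uncorrected one.
#'
#' @param table data.frame with columns subject, group, within, value.
#' @return data.frame: effect (group, within, group:within), df1, df2, F, p,
#'   p_gg.
#' @export
rm_anova_2way <- function(table) {
  stopifnot(all(c("subject", "group", "within", "value") %in% names(table)))
  table$subject <- factor(table$subject)
  table$group <- factor(table$group)
  table$within <- factor(table$within)
  if (nlevels(table$group) < 2 || nlevels(table$within) < 2)
    stop("need >= 2 levels per factor", call. = FALSE)
  if (any(duplicated(table[c("subject", "within")])))
    stop("duplicated (subject, within) observation", call. = FALSE)
  k <- nlevels(table$within)
  cnt <- table(table$subject)
  keep <- names(cnt)[cnt == k]
  dropped <- setdiff(levels(table$subject), keep)
  table <- droplevels(table[table$subject %in% keep, ])
  gs <- unique(table[c("subject", "group")])
  if (any(table(gs$group) < 2))
    stop("need >= 2 complete subjects per group", call. = FALSE)
  if (stats::var(table$value) == 0) { # constant response: no effects
    out <- data.frame(effect = c("group", "within", "group:within"),
                      df1 = NA_real_, df2 = NA_real_, F = 0, p = 1,
                      p_gg = NA_real_)
    attr(out, "dropped_subjects") <- dropped
    return(out)
  }

  fit <- stats::aov(value ~ group * within + Error(subject), data = table)
  sm <- summary(fit)
  bt <- sm[["Error: subject"]][[1]]
  wt <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(df = tab[i, "Df"], f = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  g <- pick(bt, "group")
  w <- pick(wt, "within")
  gw <- pick(wt, "group:within")
  df_bt_err <- bt[trimws(rownames(bt)) == "Residuals", "Df"]
  df_wt_err <- wt[trimws(rownames(wt)) == "Residuals", "Df"]

  p_gg <- c(NA_real_, NA_real_, NA_real_)
  if (k > 2) {
    wide <- stats::reshape(table[order(table$subject, table$within), ],
                           idvar = "subject", timevar = "within",
                           direction = "wide",
                           drop = setdiff(names(table), c("subject", "within", "value")))
    mat <- as.matrix(wide[, -1])
    # remove group x within cell means before pooling the covariance
    grp <- gs$group[match(wide$subject, gs$subject)]
    for (lev in levels(grp)) {
      rows <- grp == lev
      mat[rows, ] <- sweep(mat[rows, , drop = FALSE], 2,
                           colMeans(mat[rows, , drop = FALSE]))
    }
    eps <- gg_epsilon(mat)
    p_gg <- c(NA_real_,
              stats::pf(w["f"], eps * w["df"], eps * df_wt_err, lower.tail = FALSE),
              stats::pf(gw["f"], eps * gw["df"], eps * df_wt_err, lower.tail = FALSE))
  }
  out <- data.frame(
    effect = c("group", "within", "group:within"),
    df1 = c(g["df"], w["df"], gw["df"]),
    df2 = c(df_bt_err, df_wt_err, df_wt_err),
    F = c(g["f"], w["f"], gw["f"]),
    p = c(g["p"], w["p"], gw["p"]),
    p_gg = p_gg)
  rownames(out) <- NULL
  attr(out, "dropped_subjects") <- dropped
  out
}

#' Bonferroni-corrected post-hoc pairwise t-tests
#'
#' Compares groups at each within level (unpaired t) or within levels inside
#' each group (paired t), adjusting every p-value by the total number of
#' comparisons m: `p_adj = min(1, m * p)`.
#'
#' @param table data.frame with columns subject, group, within, value.
#' @param contrast "between" (groups at each within level, unpaired) or
#'   "within" (within levels pairwise inside each group, paired).
#' @param var_equal use the pooled-variance t for unpaired comparisons
#'   (default FALSE = Welch).
#' @return data.frame: comparison, level, statistic, df, p, p_adj, m.
#' @export
bonferroni_posthoc <- function(table, contrast = c("between", "within"),
                               var_equal = FALSE) {
  contrast <- match.arg(contrast)
  table$group <- factor(table$group)
  table$within <- factor(table$within)
  rows <- list()
  if (contrast == "between") {
    gl <- levels(table$group)
    pairs <- utils::combn(gl, 2, simplify = FALSE)
    for (lev in levels(table$within)) {
      sub <- table[table$within == lev, ]
      for (pr in pairs) {
        a <- sub$value[sub$group == pr[1]]
        b <- sub$value[sub$group == pr[2]]
        tt <- stats::t.test(a, b, var.equal = var_equal)
        rows[[length(rows) + 1]] <- data.frame(
          comparison = paste(pr, collapse = " vs "), level = lev,
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value)
      }
    }
  } else {
    wl <- levels(table$within)
    pairs <- utils::combn(wl, 2, simplify = FALSE)
    for (g in levels(table$group)) {
      sub <- table[table$group == g, ]
      for (pr in pairs) {
        a <- sub[sub$within == pr[1], c("subject", "value")]
        b <- sub[sub$within == pr[2], c("subject", "value")]
        mrg <- merge(a, b, by = "subject")
        tt <- stats::t.test(mrg$value.x, mrg$value.y, paired = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          comparison = paste(pr, collapse = " vs "), level = g,
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p)
  out$m <- m
  out
}

# least-squares R^2 of y on x (size-vs-distance trend reporting)
ols_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  summary(stats::lm(y[ok] ~ x[ok]))$r.squared
}
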