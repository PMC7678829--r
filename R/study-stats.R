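# Repeated-measures statistics: one- and two-way within-subject ANOVA
# (classical univariate partitions, no sphericity correction by default),
# Bonferroni-corrected pairwise post-hoc tests, and linear / quadratic
# trend fits with r^2.

as_long <- function(values, factor_names) {
  stopifnot(is.matrix(values) || is.array(values))
  if (anyNA(values)) stop("design contains missing cells; repeated-measures ANOVA requires a complete table")
  dn <- dimnames(values)
  dims <- dim(values)
  idx <- expand.grid(lapply(dims, seq_len))
  lv <- lapply(seq_along(dims), function(d) {
    labs <- if (!is.null(dn[[d]])) dn[[d]] else as.character(seq_len(dims[d]))
    factor(labs[idx[[d]]], levels = labs)
  })
  names(lv) <- factor_names
  cbind(data.frame(y = as.numeric(values)), lv)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject partition of a complete participant x
#' condition table: `F = MS_condition / MS_error` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`; no sphericity correction.
#'
#' @param values numeric matrix, participants in rows, condition levels in
#'   columns (no missing cells).
#' @return object of class `rm_anova_result` with an `effects` data frame
#'   (`effect, df1, df2, ss, F, p`).
#' @export
rm_anova_one_way <- function(values) {
  stopifnot(is.matrix(values), nrow(values) >= 2, ncol(values) >= 2)
  d <- as_long(values, c("subject", "condition"))
  tot_var <- sum((d$y - mean(d$y))^2)
  if (tot_var <= .Machine$double.eps * length(d$y)) {
    eff <- data.frame(effect = "condition", df1 = ncol(values) - 1,
                      df2 = (ncol(values) - 1) * (nrow(values) - 1),
                      ss = 0, F = 0, p = 1)
    return(structure(list(effects = eff, factors = "condition"),
                     class = "rm_anova_result"))
  }
  fit <- aov(y ~ condition + Error(subject), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  eff <- data.frame(effect = "condition",
                    df1 = s["condition", "Df"], df2 = s["Residuals", "Df"],
                    ss = s["condition", "Sum Sq"],
                    F = s["condition", "F value"], p = s["condition", "Pr(>F)"])
  if (s["condition", "Sum Sq"] < 1e-12 * tot_var) { eff$F <- 0; eff$p <- 1 }
  structure(list(effects = eff, factors = "condition"), class = "rm_anova_result")
}

#' Two-way repeated-measures ANOVA
#'
#' Both factors within-subject; each main effect is tested against its own
#' subject-by-factor interaction error term (classical univariate
#' convention), and the interaction against the subject-by-both term. The
#' interaction row is reported, but significance decisions rest on the
#' main effects.
#'
#' @param values 3-D numeric array `participant x factor_a x factor_b`
#'   (complete, no missing cells).
#' @param factor_names length-2 character, names of the two within-subject
#'   factors (default `c("region", "condition")`).
#' @return object of class `rm_anova_result` with one `effects` row per
#'   main effect and the interaction.
#' @export
rm_anova_two_way <- function(values, factor_names = c("region", "condition")) {
  stopifnot(length(dim(values)) == 3, dim(values)[1] >= 2,
            dim(values)[2] >= 2, dim(values)[3] >= 2,
            length(factor_names) == 2)
  d <- as_long(values, c("subject", "A", "B"))
  fit <- aov(y ~ A * B + Error(subject / (A * B)), data = d)
  s <- summary(fit)
  pick <- function(stratum, term) {
    tb <- s[[stratum]][[1]]
    row <- trimws(rownames(tb)) == term
    err <- trimws(rownames(tb)) == "Residuals"
    ss <- tb[row, "Sum Sq"]
    data.frame(df1 = tb[row, "Df"], df2 = tb[err, "Df"], ss = ss,
               F = tb[row, "F value"], p = tb[row, "Pr(>F)"])
  }
  eff <- rbind(cbind(effect = factor_names[1], pick("Error: subject:A", "A")),
               cbind(effect = factor_names[2], pick("Error: subject:B", "B")),
               cbind(effect = paste(factor_names, collapse = ":"),
                     pick("Error: subject:A:B", "A:B")))
  # zero-variance effects: report F = 0, p = 1 rather than NaN
  degenerate <- !is.finite(eff$F) & eff$ss < 1e-12 * max(sum((d$y - mean(d$y))^2), 1e-300)
  zero_ss <- eff$ss < 1e-12 * max(sum((d$y - mean(d$y))^2), .Machine$double.xmin)
  eff$F[zero_ss | degenerate] <- 0
  eff$p[zero_ss | degenerate] <- 1
  rownames(eff) <- NULL
  structure(list(effects = eff, factors = factor_names), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("repeated-measures ANOVA\n")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc tests
#'
#' All pairwise paired t-tests between the factor levels; adjusted
#' `p = min(1, raw p * m)` with `m` the number of pairs. A zero-variance
#' difference vector is reported with `p = 1` when its mean difference is
#' also zero, and flagged degenerate otherwise.
#'
#' @param values numeric matrix, participants in rows, factor levels in
#'   columns.
#' @param alpha significance level (default 0.05).
#' @return data frame `level_1, level_2, mean_diff, p_raw, p_adjusted,
#'   significant, degenerate`.
#' @export
bonferroni_posthoc <- function(values, alpha = 0.05) {
  stopifnot(is.matrix(values), ncol(values) >= 2)
  levels <- colnames(values)
  if (is.null(levels)) levels <- as.character(seq_len(ncol(values)))
  pairs <- combn(ncol(values), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dif <- values[, a] - values[, b]
    degenerate <- FALSE
    if (sd(dif) <= .Machine$double.eps * max(abs(dif), 1)) {
      if (abs(mean(dif)) <= .Machine$double.eps * max(abs(values))) {
        p <- 1
      } else {
        p <- NA_real_; degenerate <- TRUE
      }
    } else {
      p <- t.test(values[, a], values[, b], paired = TRUE)$p.value
    }
    data.frame(level_1 = levels[a], level_2 = levels[b], mean_diff = mean(dif),
               p_raw = p, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out[, c("level_1", "level_2", "mean_diff", "p_raw", "p_adjusted",
          "significant", "degenerate")]
}

#' Polynomial trend fit with r-squared
#'
#' Least-squares fit of `y` on `x` of the given degree, with
#' `r^2 = 1 - SS_res / SS_tot`. Used for peak power or cumulative
#' frequency as a function of input frequency.
#'
#' @param x predictor (e.g. input frequency, Hz).
#' @param y response (e.g. peak power, mm^2).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return object of class `trend_fit`: `degree`, `coefficients`
#'   (intercept first), `r_squared`, `fitted`, `residuals`.
#' @export
fit_trend <- function(x, y, degree = 1L) {
  stopifnot(degree %in% c(1L, 2L), length(x) == length(y))
  if (length(x) < degree + 2) stop("need at least degree + 2 points")
  if (sd(x) == 0) stop("degenerate predictor: all x values are equal")
  fit <- lm(y ~ stats::poly(x, degree, raw = TRUE))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(degree = as.integer(degree),
                 coefficients = unname(coef(fit)),
                 r_squared = r2, fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  terms <- c("", "x", "x^2")[seq_len(x$degree + 1)]
  eq <- paste(sprintf("%.4g%s", x$coefficients, terms), collapse = " + ")
  cat(sprintf("trend_fit (degree %d): y = %s, r^2 = %.3f\n", x$degree, eq, x$r_squared))
  invisible(x)
}
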