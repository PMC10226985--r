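#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized skewness (D'Agostino 1970) and kurtosis
#' (Anscombe-Glynn 1983) statistics into `K2 = Zg1^2 + Zg2^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric vector, n >= 8 (the kurtosis approximation is unstable
#'   below that).
#' @return list: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness -> Z (D'Agostino)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis -> Z (Anscombe-Glynn)
  eb2 <- -6 / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Mann-Whitney U test with mid-rank ties and exact small-sample enumeration
#'
#' Two-tailed, unpaired. The U statistic uses mid-ranks for ties. For small
#' samples (`choose(n1 + n2, n1)` combinations up to `max_exact`) the null
#' distribution of U is enumerated exactly over all group assignments of the
#' observed values (valid with ties); larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param max_exact largest number of combinations to enumerate.
#' @return list: `U` (for the first sample), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, max_exact = 40000) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  u_stat <- function(take, pooled_ranks) {
    sum(pooled_ranks[take]) - n1 * (n1 + 1) / 2
  }
  pooled <- c(x, y)
  rk <- rank(pooled)              # mid-ranks
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- min(U1, n1 * n2 - U1)
  if (choose(n1 + n2, n1) <= max_exact) {
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2, function(take) {
      u <- sum(rk[take]) - n1 * (n1 + 1) / 2
      min(u, n1 * n2 - u)
    })
    p <- mean(us <= U + 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (nt * (nt - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nt + 1 - tie_corr))
    z <- (abs(U1 - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U1, p_value = p, method = method)
}

# Dunn's post-hoc z-tests on pooled ranks after Kruskal-Wallis,
# Bonferroni-adjusted within the comparison family.
dunn_posthoc <- function(values, groups, control = NULL) {
  rk <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- unique(groups)
  mean_rk <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  pairs <- if (is.null(control)) combn(lev, 2, simplify = FALSE)
           else lapply(setdiff(lev, control), function(g) c(control, g))
  rows <- lapply(pairs, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    z <- (mean_rk[[pr[1]]] - mean_rk[[pr[2]]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_value = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

# Dunnett or Tukey-free post-hoc after ANOVA via multcomp.
dunnett_posthoc <- function(values, groups) {
  g <- factor(groups)
  fit <- aov(values ~ g, data = data.frame(values = values, g = g))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  data.frame(comparison = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             p_adjusted = as.numeric(sm$test$pvalues))
}

#' Normality-routed group comparison
#'
#' Routes the comparison through the reporting rule: every group is tested
#' for normality with the D'Agostino-Pearson omnibus test at
#' `alpha_normality`; if all groups pass, a parametric branch is used
#' (unpaired two-tailed t-test for 2 groups, one-way ANOVA with Dunnett's
#' post hoc against the first group for more); otherwise a non-parametric
#' branch (two-tailed Mann-Whitney U for 2 groups, Kruskal-Wallis with
#' Dunn's post hoc for more). Groups too small for the normality test
#' (n < 8) route directly to the non-parametric branch, flagged.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha_normality significance level of the normality gate.
#' @return a `group_comparison` list: `groups`, `normality_p` (per group, NA
#'   when skipped), `test_used`, `statistic`, `p_value`, `posthoc` (NULL for
#'   2 groups), `flags`.
#' @export
route_and_test <- function(groups, alpha_normality = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 3)) {
    stop("every group needs n >= 3; got: ",
         paste(sizes, collapse = ", "))
  }
  flags <- character(0)
  small <- sizes < 8
  if (any(small)) {
    flags <- c(flags, paste0("group_too_small_for_normality_test:",
                             paste(names(groups)[small], collapse = ",")))
    norm_p <- rep(NA_real_, length(groups))
    normal <- FALSE
  } else {
    norm_p <- vapply(groups, function(g) dagostino_pearson(g)$p_value,
                     numeric(1))
    normal <- all(norm_p > alpha_normality)
  }
  values <- unlist(groups, use.names = FALSE)
  glab <- rep(names(groups), sizes)
  posthoc <- NULL
  if (normal) {
    if (length(groups) == 2) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      test_used <- "t"; statistic <- unname(ht$statistic); p <- ht$p.value
    } else {
      fit <- aov(values ~ factor(glab))
      sm <- summary(fit)[[1]]
      test_used <- "anova_dunnett"
      statistic <- sm[["F value"]][1]; p <- sm[["Pr(>F)"]][1]
      posthoc <- dunnett_posthoc(values, glab)
    }
  } else {
    if (length(groups) == 2) {
      ht <- mann_whitney_u(groups[[1]], groups[[2]])
      test_used <- "mann_whitney"; statistic <- ht$U; p <- ht$p_value
    } else {
      kw <- kruskal.test(values, factor(glab))
      test_used <- "kruskal_wallis_dunn"
      statistic <- unname(kw$statistic); p <- kw$p.value
      posthoc <- dunn_posthoc(values, glab)
    }
  }
  structure(list(groups = groups, normality_p = setNames(norm_p, names(groups)),
                 test_used = test_used, statistic = statistic, p_value = p,
                 posthoc = posthoc, flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s, statistic = %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Per-group summary table (median, IQR, mean, SD)
#'
#' Quartiles use linear interpolation (R type 7), so `{1,2,3,4}` gives
#' median 2.5 and IQR 1.5. Empty groups are dropped with a warning.
#'
#' @param records data.frame of per-object records.
#' @param by grouping column name (e.g. `"position_class"`).
#' @param metrics character vector of numeric column names to summarize.
#' @return data.frame with one row per group x metric: `n`, `median`,
#'   `iqr`, `q25`, `q75`, `mean`, `sd`.
#' @export
summarize_groups <- function(records, by, metrics) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  missing_m <- setdiff(metrics, names(records))
  if (length(missing_m) > 0) {
    stop("unknown metric(s): ", paste(missing_m, collapse = ", "))
  }
  if (!by %in% names(records)) stop("unknown grouping column: ", by)
  out <- list()
  for (g in unique(records[[by]])) {
    sub <- records[records[[by]] == g, , drop = FALSE]
    for (mname in metrics) {
      v <- sub[[mname]][is.finite(sub[[mname]])]
      if (length(v) == 0) {
        warning("group '", g, "' has no finite values for ", mname,
                "; dropped")
        next
      }
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = mname, n = length(v),
        median = q[2], iqr = q[3] - q[1], q25 = q[1], q75 = q[3],
        mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
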