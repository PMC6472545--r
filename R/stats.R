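#' Six-statistic distribution summary
#'
#' Minimum, 25th percentile, mean, 75th percentile, maximum and
#' coefficient of variation (percent, sample standard deviation).
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param x Numeric vector, length >= 2.
#' @return A one-row tibble: `n`, `min`, `p25`, `mean`, `p75`, `max`,
#'   `cv_percent`.
#' @export
summarize_distribution <- function(x) {
  if (length(x) < 2) {
    stop("need at least 2 values to summarise a distribution", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  m <- mean(x)
  tibble::tibble(
    n = length(x),
    min = min(x),
    p25 = q[1],
    mean = m,
    p75 = q[2],
    max = max(x),
    cv_percent = 100 * stats::sd(x) / m
  )
}

#' One-way ANOVA with LSD mean separation
#'
#' Fits a one-way ANOVA and compares group means with Fisher's least
#' significant difference test:
#' `LSD(i, j) = t(1 - alpha/2, df_err) * sqrt(MSE * (1/n_i + 1/n_j))`.
#' Compact letters are assigned by descending mean; groups that do not
#' differ share a letter. No correction beyond LSD is applied.
#'
#' @param values Numeric response.
#' @param groups Grouping vector (coerced to factor), >= 2 groups with
#'   >= 2 observations each.
#' @param alpha Significance level (default 0.05).
#' @return A list: `f_value`, `p_value`, `df` (c(between, error)), `mse`,
#'   `alpha`, `groups` (tibble with `group`, `n`, `mean`, `letter`,
#'   ordered by descending mean) and `pairwise` (tibble with the pairwise
#'   mean differences, LSD thresholds and significance flags).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n_i <- table(g)
  if (any(n_i < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  means <- tapply(values, g, mean)
  ord <- order(means, decreasing = TRUE)
  lv <- levels(g)[ord]
  means <- means[ord]
  n_i <- n_i[ord]

  k <- length(lv)
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  nonsig <- matrix(TRUE, k, k, dimnames = list(lv, lv))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      lsd <- tcrit * sqrt(mse * (1 / n_i[i] + 1 / n_i[j]))
      diff_ij <- abs(means[i] - means[j])
      sig <- diff_ij > lsd
      nonsig[i, j] <- nonsig[j, i] <- !sig
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        group1 = lv[i], group2 = lv[j],
        difference = unname(diff_ij), lsd = unname(lsd),
        significant = unname(sig)
      )
    }
  }
  letters_out <- cld_letters(nonsig)
  list(
    f_value = an["g", "F value"],
    p_value = an["g", "Pr(>F)"],
    df = c(between = an["g", "Df"], error = df_err),
    mse = mse,
    alpha = alpha,
    groups = tibble::tibble(
      group = lv, n = as.integer(n_i), mean = unname(means),
      letter = letters_out
    ),
    pairwise = dplyr::bind_rows(pairs)
  )
}

# compact letter display over a symmetric non-significance matrix whose
# rows/cols are ordered by descending mean: each maximal interval of
# mutually non-different groups gets one letter
cld_letters <- function(nonsig) {
  k <- nrow(nonsig)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nonsig[i:(j + 1), i:(j + 1)])) {
      j <- j + 1
    }
    intervals[[i]] <- c(i, j)
  }
  # drop intervals nested inside an earlier one
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (h in seq_len(k)) {
      if (h != i && intervals[[h]][1] <= intervals[[i]][1] &&
          intervals[[h]][2] >= intervals[[i]][2] && keep[h] &&
          !identical(intervals[[h]], intervals[[i]])) {
        keep[i] <- FALSE
      }
    }
  }
  iv <- unique(intervals[keep])
  iv <- iv[order(vapply(iv, `[`, numeric(1), 1))]
  out <- character(k)
  for (m in seq_along(iv)) {
    rng <- iv[[m]][1]:iv[[m]][2]
    out[rng] <- paste0(out[rng], letters[m])
  }
  out
}

#' Simple linear regression fit
#'
#' Ordinary least squares of `y` on `x` with the slope t-test.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`,
#'   `slope_p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("need at least 3 points", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("x has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    slope_p_value = sm$coefficients["x", "Pr(>|t|)"],
    n = length(x)
  )
}

#' Per-system distribution summaries with LSD letters
#'
#' Builds the per-indicator, per-system six-statistic summary and attaches
#' the compact letters of the LSD comparison across systems.
#'
#' @param indicators Per-field indicator table (see
#'   [compute_indicators()]).
#' @param vars Character vector of indicator columns to summarise;
#'   defaults to all numeric indicator columns.
#' @param alpha Significance level for the LSD letters.
#' @return A tibble with one row per indicator x system.
#' @export
summarize_systems <- function(indicators,
                              vars = NULL,
                              alpha = 0.05) {
  if (is.null(vars)) {
    vars <- setdiff(names(indicators)[vapply(indicators, is.numeric,
                                             logical(1))],
                    c("field_id"))
  }
  out <- list()
  for (v in vars) {
    ok <- is.finite(indicators[[v]])
    vals <- indicators[[v]][ok]
    sys <- indicators$system[ok]
    cmp <- anova_lsd(vals, sys, alpha = alpha)
    smry <- dplyr::bind_rows(lapply(split(vals, sys), summarize_distribution),
                             .id = "system")
    smry$indicator <- v
    smry <- dplyr::left_join(smry, cmp$groups[c("group", "letter")],
                             by = c(system = "group"))
    smry$f_value <- cmp$f_value
    smry$p_value <- cmp$p_value
    out[[v]] <- smry
  }
  dplyr::bind_rows(out)[, c("indicator", "system", "n", "min", "p25",
                            "mean", "p75", "max", "cv_percent", "letter",
                            "f_value", "p_value")]
}
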