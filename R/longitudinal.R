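#' Normalize longitudinal series to the day-1 baseline average
#'
#' For each modality, the baseline is the mean of the baseline-day values
#' across all animals; every value of that modality is divided by it. The
#' cross-animal mean of normalized baseline-day values is therefore exactly
#' 1. Day 1 — the first post-operative day — is the study's reference point;
#' no pre-surgery measurement exists.
#'
#' @param series Tidy data frame with columns `animal`, `modality`, `day`,
#'   `value`.
#' @param baseline_day Baseline day (default 1).
#' @return The same data frame with `value` replaced by the normalized value.
#' @export
normalize_to_baseline <- function(series, baseline_day = 1) {
  req <- c("animal", "modality", "day", "value")
  if (!all(req %in% names(series))) stop("series must have columns ",
                                         paste(req, collapse = ", "))
  out <- series
  for (mod in unique(series$modality)) {
    sel <- series$modality == mod
    base <- series[sel & series$day == baseline_day, ]
    missing <- setdiff(unique(series$animal[sel]), unique(base$animal))
    if (length(missing) > 0)
      stop("no baseline-day value for animal(s): ",
           paste(missing, collapse = ", "), " in modality ", mod)
    b <- mean(base$value)
    if (b == 0) stop("zero baseline average in modality ", mod)
    out$value[sel] <- series$value[sel] / b
  }
  out
}

#' Linear interpolation of a day series to daily resolution
#'
#' Piecewise-linear interpolation between consecutive measured days onto the
#' integer-day grid. Measured days keep their values exactly; no
#' extrapolation is performed outside the first/last measured day.
#'
#' @param days Measured days (integers, strictly increasing after sorting;
#'   duplicates are an error).
#' @param values Measured values.
#' @param range Length-2 day range to interpolate over (default `c(1, 56)`),
#'   clipped to the measured span.
#' @return An object of class `daily_series`: data frame with columns `day`,
#'   `value`, `measured` (logical).
#' @examples
#' interpolate_daily(c(1, 4), c(1, 4))   # days 2, 3 filled linearly
#' @export
interpolate_daily <- function(days, values, range = c(1, 56)) {
  if (anyDuplicated(days)) stop("duplicate measured days")
  if (length(days) < 2) stop("need at least 2 measured days")
  o <- order(days)
  days <- days[o]; values <- values[o]
  lo <- max(range[1], min(days)); hi <- min(range[2], max(days))
  grid <- seq(ceiling(lo), floor(hi))
  v <- stats::approx(days, values, xout = grid)$y
  out <- data.frame(day = grid, value = v, measured = grid %in% days)
  # knot exactness, immune to interpolation rounding
  out$value[out$measured] <- values[match(out$day[out$measured], days)]
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Sliding-window lag correlation between two daily series
#'
#' For each window width `w` and lag `L`, correlates the fixed series over
#' days `1...w` with the sliding series over days `1+L ... w+L` (equal
#' lengths). Two-sided p-values come from the t transform of Pearson's R
#' with `n = w`; since interpolated days are not independent measurements,
#' the effective sample size is overstated — the result carries a caveat
#' flag recording the fraction of interpolated days used.
#'
#' @param fixed,sliding `daily_series` objects (see [interpolate_daily()])
#'   or data frames with `day` and `value` columns.
#' @param widths Window widths in days (default `c(7, 14, 21, 28, 35)`).
#' @param max_lag Largest lag to scan (default 20 days; lags are `0:max_lag`).
#' @return An object of class `lag_correlation`: list with `grid` (data
#'   frame: `width`, `lag`, `r`, `p`, `n`, `available`), `best` (row of the
#'   grid maximizing `r`; ties broken by smallest lag, then smallest width),
#'   and `interpolated_fraction`.
#' @examples
#' f <- interpolate_daily(1:56, sin(1:56 / 5))
#' s <- interpolate_daily(1:56, sin((1:56 - 5) / 5))
#' best_lag(lag_correlation(f, s))$lag   # 5
#' @export
lag_correlation <- function(fixed, sliding,
                            widths = c(7, 14, 21, 28, 35), max_lag = 20) {
  fval <- stats::setNames(fixed$value, fixed$day)
  sval <- stats::setNames(sliding$value, sliding$day)
  grid <- expand.grid(width = widths, lag = 0:max_lag)
  grid <- grid[order(grid$width, grid$lag), ]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    w <- grid$width[i]; L <- grid$lag[i]
    fd <- as.character(1:w); sd_ <- as.character((1 + L):(w + L))
    if (!all(fd %in% names(fval)) || !all(sd_ %in% names(sval)))
      return(c(r = NA_real_, p = NA_real_, n = w, available = 0))
    r <- stats::cor(fval[fd], sval[sd_])
    p <- if (is.na(r) || abs(r) >= 1) {
      if (is.na(r)) NA_real_ else 0
    } else {
      tt <- r * sqrt((w - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = w - 2)
    }
    c(r = r, p = p, n = w, available = 1)
  })
  res <- as.data.frame(do.call(rbind, res))
  grid <- cbind(grid, res)
  grid$available <- grid$available == 1
  if (!any(grid$available)) stop("entire lag-correlation grid unavailable")
  avail <- grid[grid$available & !is.na(grid$r), ]
  # round for ordering only, so exact ties (e.g. several perfect windows)
  # break by smallest lag then smallest width instead of fp noise
  avail <- avail[order(-round(avail$r, 10), avail$lag, avail$width), ]
  interp_frac <- if (is.null(fixed$measured) || is.null(sliding$measured))
    NA_real_ else mean(c(!fixed$measured, !sliding$measured))
  structure(list(grid = grid, best = avail[1, ],
                 interpolated_fraction = interp_frac),
            class = "lag_correlation")
}

#' Best lag of a lag-correlation grid
#'
#' @param result A [lag_correlation()] result.
#' @return List with `lag` (days), `r`, `p`, `width`.
#' @export
best_lag <- function(result) {
  stopifnot(inherits(result, "lag_correlation"))
  b <- result$best
  list(lag = b$lag, r = b$r, p = b$p, width = b$width)
}

#' Compare a metric across post-operative timepoints
#'
#' Implements the test-selection logic for longitudinal comparisons: per-day
#' Shapiro-Wilk normality at `alpha`; if every day passes, repeated-measures
#' one-way ANOVA with Tukey's post hoc (paired) or one-way ANOVA with Tukey
#' (unpaired); otherwise the Friedman test with Dunn's post hoc and
#' Bonferroni correction (paired) or Kruskal-Wallis with Bonferroni-adjusted
#' pairwise Wilcoxon tests (unpaired).
#'
#' @param values Data frame with columns `animal`, `day`, `value`, or a
#'   matrix with animals in rows and days in columns.
#' @param paired Repeated measures on the same animals (default `TRUE`);
#'   requires a complete animal x day table.
#' @param alpha Significance level for the normality decision and stars.
#' @return An object of class `stats_report`: list with `test` (name of the
#'   route taken), `statistic`, `df`, `p`, `posthoc` (data frame with
#'   pairwise comparisons, adjusted p-values and stars), `normality`
#'   (per-day Shapiro-Wilk results), `alpha`.
#' @export
compare_timepoints <- function(values, paired = TRUE, alpha = 0.05) {
  if (is.matrix(values)) {
    days <- colnames(values) %||% seq_len(ncol(values))
    values <- data.frame(
      animal = rep(rownames(values) %||% seq_len(nrow(values)),
                   times = ncol(values)),
      day = rep(days, each = nrow(values)),
      value = as.vector(values))
  }
  values$day <- factor(values$day, levels = unique(values$day))
  values$animal <- factor(values$animal)
  if (nlevels(values$day) < 2) stop("need at least 2 days")
  if (nlevels(values$animal) < 3) stop("need at least 3 animals")
  if (paired) {
    tab <- table(values$animal, values$day)
    if (any(tab != 1)) {
      miss <- which(tab == 0, arr.ind = TRUE)
      stop("incomplete paired table; missing cells: ",
           paste(sprintf("(%s, day %s)", rownames(tab)[miss[, 1]],
                         colnames(tab)[miss[, 2]]), collapse = ", "))
    }
  }
  norm <- do.call(rbind, lapply(levels(values$day), function(d) {
    v <- values$value[values$day == d]
    sw <- tryCatch(stats::shapiro.test(v),
                   error = function(e) list(statistic = NA, p.value = 0))
    data.frame(day = d, W = unname(sw$statistic), p = sw$p.value)
  }))
  norm$normal <- norm$p > alpha
  all_normal <- all(norm$normal)

  if (paired && all_normal) {
    # fit with sum-to-zero contrasts up front so the post hoc machinery
    # does not need to re-fit the model outside this scope
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    fit <- stats::aov(value ~ day + Error(animal), data = values)
    s <- summary(fit)[["Error: Within"]][[1]]
    row <- which(trimws(rownames(s)) == "day")
    ph <- summary(emmeans::contrast(
      emmeans::emmeans(fit, "day", data = values),
      method = "pairwise", adjust = "tukey"))
    posthoc <- data.frame(comparison = as.character(ph$contrast),
                          estimate = ph$estimate, p_adj = ph$p.value)
    test <- "RM-ANOVA + Tukey"
    statistic <- s[row, "F value"]
    df <- s[row, "Df"]; p <- s[row, "Pr(>F)"]
  } else if (paired) {
    m <- stats::xtabs(value ~ animal + day, data = values)
    fr <- stats::friedman.test(as.matrix(m))
    posthoc <- dunn_posthoc(as.matrix(m))
    test <- "Friedman + Dunn (Bonferroni)"
    statistic <- unname(fr$statistic)
    df <- unname(fr$parameter); p <- fr$p.value
  } else if (all_normal) {
    fit <- stats::aov(value ~ day, data = values)
    s <- summary(fit)[[1]]
    row <- which(trimws(rownames(s)) == "day")
    tk <- stats::TukeyHSD(fit)$day
    posthoc <- data.frame(comparison = rownames(tk),
                          estimate = tk[, "diff"], p_adj = tk[, "p adj"])
    test <- "one-way ANOVA + Tukey"
    statistic <- s[row, "F value"]
    df <- s[row, "Df"]; p <- s[row, "Pr(>F)"]
  } else {
    kw <- stats::kruskal.test(value ~ day, data = values)
    pw <- stats::pairwise.wilcox.test(values$value, values$day,
                                      p.adjust.method = "bonferroni",
                                      exact = FALSE)
    pm <- pw$p.value
    posthoc <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
      j <- which(!is.na(pm[i, ]))
      if (length(j) == 0) return(NULL)
      data.frame(comparison = paste(rownames(pm)[i], "-", colnames(pm)[j]),
                 estimate = NA_real_, p_adj = pm[i, j])
    }))
    test <- "Kruskal-Wallis + Wilcoxon (Bonferroni)"
    statistic <- unname(kw$statistic)
    df <- unname(kw$parameter); p <- kw$p.value
  }
  posthoc$stars <- p_stars(posthoc$p_adj, alpha)
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 posthoc = posthoc, normality = norm, alpha = alpha),
            class = "stats_report")
}

# Dunn's post hoc after a Friedman test: mean within-block ranks compared
# with z statistics, Bonferroni-adjusted
dunn_posthoc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  combs <- utils::combn(k, 2)
  n_comp <- ncol(combs)
  out <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    z <- (rbar[a] - rbar[b]) / se
    data.frame(
      comparison = paste(colnames(m)[a], "-", colnames(m)[b]),
      estimate = rbar[a] - rbar[b],
      p_adj = min(1, 2 * stats::pnorm(-abs(z)) * n_comp))
  }))
  rownames(out) <- NULL
  out
}

p_stars <- function(p, alpha = 0.05) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 0.0001) "****" else if (x < 0.001) "***" else
      if (x < 0.01) "**" else if (x < alpha) "*" else "ns"
  }, character(1))
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, paste(x$df, collapse = ","), x$p))
  invisible(x)
}

#' @export
print.lag_correlation <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<lag_correlation> best R = %.3f at lag %d d (width %d, p = %.3g)\n",
    b$r, b$lag, b$width, b$p))
  invisible(x)
}
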