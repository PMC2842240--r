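# Trend fitting, projection, dataset-feature regression and gene ranking.

#' Fit a polynomial (or exponential) trend to a yearly series
#'
#' Ordinary least squares on `value ~ poly(year - first_year)` of the given
#' order. For `order = 2` the fit also reports the nested-F test of the
#' quadratic term against the linear model,
#' F = ((RSS1 - RSS2)/1) / (RSS2/(n - 3)) on F(1, n - 3); a perfect linear
#' fit (both RSS zero) yields p = 1. `order = "exp"` fits log(value) on year
#' by OLS (values must be positive), as used for raw sequence-accumulation
#' counts.
#'
#' @param years Numeric years (distinct).
#' @param values Series values, one per year.
#' @param order 1, 2 or `"exp"`.
#' @return A `trend_fit`: list with `order`, `coefficients` (in powers of
#'   `year - first_year`), `r_squared`, `rss`, `n`, `p_improvement`
#'   (order-2 fits only), `first_year`.
#' @export
fit_trend <- function(years, values, order = 1) {
  if (length(years) != length(values)) stopf("years/values length mismatch")
  if (length(unique(years)) < 2L) stopf("degenerate series: constant year")
  ord_num <- if (identical(order, "exp")) 1L else as.integer(order)
  if (length(years) < ord_num + 2L) stopf("too few points for order %s", order)
  x <- years - min(years)
  y <- if (identical(order, "exp")) {
    if (any(values <= 0)) stopf("exponential fit needs positive values")
    log(values)
  } else values
  fits <- lapply(seq_len(max(ord_num, if (identical(order, "exp")) 1L else
                             as.integer(order))), function(k)
    stats::lm(y ~ stats::poly(x, k, raw = TRUE)))
  fit <- fits[[length(fits)]]
  rss <- sum(stats::residuals(fit)^2)
  # exact series are legitimate inputs; silence summary.lm's perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  p_imp <- NA_real_
  if (identical(order, 2) || identical(order, 2L)) {
    rss1 <- sum(stats::residuals(fits[[1L]])^2)
    n <- length(y)
    if (rss <= .Machine$double.eps^0.75 && rss1 <= .Machine$double.eps^0.75) {
      p_imp <- 1
    } else if (rss <= .Machine$double.eps^0.75) {
      p_imp <- 0
    } else {
      Fstat <- (rss1 - rss) / (rss / (n - 3))
      p_imp <- stats::pf(Fstat, 1, n - 3, lower.tail = FALSE)
    }
  }
  structure(list(order = order,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = r2, rss = rss, n = length(y),
                 p_improvement = p_imp, first_year = min(years)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit (order %s): r^2 = %.4f on %d points\n",
              as.character(x$order), x$r_squared, x$n))
  if (!is.na(x$p_improvement))
    cat(sprintf("  quadratic vs linear improvement p = %.3g\n",
                x$p_improvement))
  invisible(x)
}

# Evaluate a trend_fit at (possibly fractional) years.
predict_trend <- function(fit, years) {
  x <- years - fit$first_year
  co <- fit$coefficients
  v <- drop(outer(x, seq_along(co) - 1L, "^") %*% co)
  if (identical(fit$order, "exp")) exp(v) else v
}

#' Project the year a trend reaches a target
#'
#' Scans fitted values (proportions capped at 1) year by year from
#' `last_year` and returns the first integer year at which the fitted value
#' reaches `target`. Returns `NA` ("not reached") when the trend is
#' decreasing at `last_year` or the target is not met by `horizon`.
#'
#' @param fit A `trend_fit`.
#' @param target Target value (e.g. 1.0 for complete sampling).
#' @param last_year Final observed year; the scan starts here, so a target
#'   already met returns `last_year`.
#' @param horizon Last year scanned (default 2100).
#' @param cap Cap fitted values at this ceiling (default 1 for proportions;
#'   use `Inf` for unbounded series).
#' @return Integer year, or `NA_integer_` if not reached.
#' @export
project_trend <- function(fit, target, last_year, horizon = 2100, cap = 1) {
  stopifnot(inherits(fit, "trend_fit"))
  yrs <- seq(last_year, horizon)
  vals <- pmin(predict_trend(fit, yrs), cap)
  if (length(yrs) > 1L && vals[2L] < vals[1L] && vals[1L] < target)
    return(NA_integer_)
  hit <- which(vals >= target)
  if (!length(hit)) return(NA_integer_)
  as.integer(yrs[hit[1L]])
}

#' Multiple regression of resolution on dataset features
#'
#' Regresses clade resolution on the proportion of species sampled, clade
#' size (described species), mean characters per species and dataset
#' density. All variables are z-standardised so the coefficients are
#' comparable standardized (partial) regression coefficients.
#'
#' @param table Data frame with columns `prop_sampled`, `clade_size`,
#'   `chars_per_species`, `density` and `resolution` (one row per clade,
#'   >= 6 rows).
#' @return A `feature_regression` list: `betas` (named standardized
#'   coefficients), `r_squared`, `p_value` (overall F), `n`.
#' @export
feature_regression <- function(table) {
  preds <- c("prop_sampled", "clade_size", "chars_per_species", "density")
  if (!all(c(preds, "resolution") %in% names(table)))
    stopf("table must have columns %s",
          paste(c(preds, "resolution"), collapse = ", "))
  if (nrow(table) < 6L) stopf("need >= 6 clades for the regression")
  X <- as.matrix(table[, preds])
  if (any(apply(X, 2L, stats::sd) == 0))
    stopf("constant predictor: %s",
          preds[apply(X, 2L, stats::sd) == 0][1L])
  Z <- scale(X)
  kappa_z <- kappa(cbind(1, Z), exact = TRUE)
  if (kappa_z > 1e8) {
    cors <- abs(stats::cor(Z)); diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
    stopf("collinear predictors: %s and %s", preds[worst[1L]],
          preds[worst[2L]])
  }
  y <- as.numeric(scale(table$resolution))
  df <- data.frame(y = y, Z)
  fit <- stats::lm(y ~ ., data = df)
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  structure(list(
    betas = stats::setNames(stats::coef(fit)[-1L], preds),
    se = stats::setNames(sm$coefficients[-1L, "Std. Error"], preds),
    r_squared = sm$r.squared,
    p_value = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
    n = nrow(table)), class = "feature_regression")
}

#' @export
print.feature_regression <- function(x, ...) {
  cat(sprintf("feature_regression: r^2 = %.3f, p = %.3g (n = %d)\n",
              x$r_squared, x$p_value, x$n))
  print(round(x$betas, 3))
  invisible(x)
}

top5 <- function(genes, value) {
  ord <- order(-value, genes)
  genes[ord][seq_len(min(5L, length(genes)))]
}

#' Rank genes by sampling effort and by resolving power
#'
#' For every clade with at least `min_genes` informative gene analyses,
#' takes the five genes with the most taxa sampled and the five with the
#' highest single-gene resolution (ties: larger value, then gene id), and
#' reports each gene's frequency of appearing in either top-5 list across
#' the qualifying clades, plus the overall regression of single-gene
#' resolution on taxa sampled.
#'
#' @param gene_table Data frame with columns `clade`, `gene`, `n_taxa`,
#'   `resolution` (one row per clade-gene analysis).
#' @param min_genes Minimum gene analyses for a clade to qualify
#'   (default 20).
#' @return A `gene_ranking` list: `clades` (qualifying ids), `top_sampled`
#'   and `top_resolved` (per-clade top-5 lists), `freq_sampled` and
#'   `freq_resolved` (per-gene top-5 frequencies), `sampling_regression`
#'   (slope, r_squared, p of resolution ~ n_taxa).
#' @export
rank_genes <- function(gene_table, min_genes = 20L) {
  counts <- table(gene_table$clade)
  qual <- names(counts)[counts >= min_genes]
  if (!length(qual)) {
    warning("no clade qualifies for gene ranking", call. = FALSE)
    return(structure(list(clades = character(0), top_sampled = list(),
                          top_resolved = list(),
                          freq_sampled = numeric(0),
                          freq_resolved = numeric(0),
                          sampling_regression = NULL),
                     class = "gene_ranking"))
  }
  top_sampled <- lapply(qual, function(cl) {
    g <- gene_table[gene_table$clade == cl, ]
    top5(g$gene, g$n_taxa)
  })
  top_resolved <- lapply(qual, function(cl) {
    g <- gene_table[gene_table$clade == cl, ]
    top5(g$gene, g$resolution)
  })
  names(top_sampled) <- names(top_resolved) <- qual
  genes <- sort(unique(gene_table$gene))
  freq_of <- function(lists) stats::setNames(vapply(genes, function(g)
    mean(vapply(lists, function(l) g %in% l, TRUE)), 0), genes)
  fit <- stats::lm(resolution ~ n_taxa, data = gene_table)
  sm <- summary(fit)
  reg <- list(slope = unname(stats::coef(fit)[2L]),
              r_squared = sm$r.squared,
              p = stats::coef(sm)[2L, "Pr(>|t|)"])
  structure(list(clades = qual, top_sampled = top_sampled,
                 top_resolved = top_resolved,
                 freq_sampled = freq_of(top_sampled),
                 freq_resolved = freq_of(top_resolved),
                 sampling_regression = reg),
            class = "gene_ranking")
}
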