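#' Summarise activity metrics across recordings of one condition
#'
#' Descriptive statistics per metric: mean, standard deviation,
#' coefficient of variation \eqn{\sigma^* = \sigma / |\mu|}, quartiles
#' (Q1, median, Q3) and the 5th/95th percentiles — the quantities shown
#' in the field's box-and-whisker displays. Metrics are the scalar columns
#' of [as.data.frame.activity_metrics()].
#'
#' @param metrics List of `activity_metrics` objects (one per recording).
#' @param condition Condition label attached to the summary.
#' @return A `condition_summary`: data frame with one row per metric and
#'   columns `metric, n, mean, sd, cv, q1, q2, q3, p5, p95`, plus
#'   attribute `condition`. `cv` is `NA` where the mean is 0.
#' @examples
#' ev <- classify_intervals(c(0, 1, 2, 40), 80, detection_params())
#' summarize_metrics(list(compute_metrics(ev)), "demo")
#' @export
summarize_metrics <- function(metrics, condition = "condition") {
  if (inherits(metrics, "activity_metrics")) metrics <- list(metrics)
  stopifnot(length(metrics) >= 1L)
  df <- do.call(rbind, lapply(metrics, as.data.frame))
  cols <- setdiff(names(df), c("source_id"))
  rows <- lapply(cols, function(cn) {
    v <- df[[cn]]
    v <- v[is.finite(v)]
    if (!length(v))
      return(data.frame(metric = cn, n = 0L, mean = NA_real_, sd = NA_real_,
                        cv = NA_real_, q1 = NA_real_, q2 = NA_real_,
                        q3 = NA_real_, p5 = NA_real_, p95 = NA_real_))
    qs <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    mu <- mean(v)
    sdv <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(
      metric = cn, n = length(v), mean = mu, sd = sdv,
      cv = if (mu != 0) sdv / abs(mu) else NA_real_,
      q1 = qs[[2L]], q2 = qs[[3L]], q3 = qs[[4L]],
      p5 = qs[[1L]], p95 = qs[[5L]]
    )
  })
  out <- do.call(rbind, rows)
  structure(out, condition = condition,
            class = c("condition_summary", "data.frame"))
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition_summary: '%s'\n", attr(x, "condition")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare activity metrics between two conditions
#'
#' Thin reporting conveniences over standard routines: a per-metric
#' two-sample t-test (Welch by default; the unequal-variance form is the
#' safer default when electrode coupling differs between configurations)
#' and a principal component analysis over the recording-level variables
#' `ctime, etime, n_burst, n_cp` (standardised to unit variance by
#' default), reporting explained-variance fractions and loadings.
#'
#' @param a,b Lists of `activity_metrics` (one element per recording).
#' @param labels Character vector of two condition labels.
#' @param var_equal Pooled-variance t-test instead of Welch (default
#'   `FALSE`).
#' @param scale_pca Standardise variables before PCA (default `TRUE`,
#'   i.e. correlation PCA).
#' @param pca_vars Recording-level variables entering the PCA.
#' @return An object of class `condition_comparison`: `summaries` (two
#'   [summarize_metrics()] tables), `t_tests` (data frame with metric,
#'   group means, t, df, p; `NA` rows where a group has fewer than two
#'   finite values), `pca` (list with `explained` fractions summing to 1,
#'   `loadings`, `scores`, `condition` per row), `labels`.
#' @export
compare_conditions <- function(a, b, labels = c("A", "B"),
                               var_equal = FALSE, scale_pca = TRUE,
                               pca_vars = c("ctime", "etime", "n_burst", "n_cp")) {
  stopifnot(length(a) >= 1L, length(b) >= 1L, length(labels) == 2L)
  da <- do.call(rbind, lapply(a, as.data.frame))
  db <- do.call(rbind, lapply(b, as.data.frame))
  metrics <- c("ctime", "etime", "n_burst", "n_icbi", "n_cp", "hyai",
               "mean_cpi", "mean_icbi", "mean_burst_time")

  t_rows <- lapply(metrics, function(mn) {
    va <- da[[mn]][is.finite(da[[mn]])]
    vb <- db[[mn]][is.finite(db[[mn]])]
    if (length(va) < 2L || length(vb) < 2L) {
      message("t-test skipped for '", mn, "': fewer than 2 values in a group")
      return(data.frame(metric = mn, mean_a = mean(va), mean_b = mean(vb),
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- tryCatch(stats::t.test(va, vb, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # both groups essentially constant: no mean difference to test
      return(data.frame(metric = mn, mean_a = mean(va), mean_b = mean(vb),
                        t = if (isTRUE(all.equal(mean(va), mean(vb)))) 0
                            else NA_real_,
                        df = NA_real_,
                        p = if (isTRUE(all.equal(mean(va), mean(vb)))) 1
                            else NA_real_))
    }
    data.frame(metric = mn, mean_a = mean(va), mean_b = mean(vb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  t_tests <- do.call(rbind, t_rows)

  x <- rbind(da[, pca_vars, drop = FALSE], db[, pca_vars, drop = FALSE])
  cond <- rep(labels, c(nrow(da), nrow(db)))
  keep_var <- vapply(x, function(v) stats::var(v) > 0, logical(1))
  pca <- NULL
  if (nrow(x) >= 3L && sum(keep_var) >= 2L) {
    pr <- stats::prcomp(x[, keep_var, drop = FALSE], center = TRUE,
                        scale. = scale_pca)
    pca <- list(
      explained = pr$sdev^2 / sum(pr$sdev^2),
      loadings = pr$rotation,
      scores = pr$x,
      condition = cond,
      variables = names(x)[keep_var]
    )
  } else {
    message("PCA skipped: need >= 3 recordings and >= 2 non-constant variables")
  }

  structure(
    list(
      summaries = list(summarize_metrics(a, labels[[1L]]),
                       summarize_metrics(b, labels[[2L]])),
      t_tests = t_tests,
      pca = pca,
      labels = labels
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition_comparison: %s vs %s\n",
              x$labels[[1L]], x$labels[[2L]]))
  cat("\nPer-metric two-sample t-tests:\n")
  print.data.frame(x$t_tests, row.names = FALSE, digits = 4)
  if (!is.null(x$pca)) {
    cat("\nPCA explained variance fractions:\n")
    ev <- x$pca$explained
    names(ev) <- paste0("PC", seq_along(ev))
    print(round(ev, 4))
  }
  invisible(x)
}

#' Box plots and PCA biplot for a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param metrics Metrics to draw as per-condition box plots.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.condition_comparison <- function(x, metrics = c("ctime", "n_cp"), ...) {
  n_panel <- length(metrics) + !is.null(x$pca)
  old <- graphics::par(mfrow = c(1, n_panel))
  on.exit(graphics::par(old))
  sa <- x$summaries[[1L]]
  sb <- x$summaries[[2L]]
  for (mn in metrics) {
    ra <- sa[sa$metric == mn, ]
    rb <- sb[sb$metric == mn, ]
    bx <- list(
      stats = cbind(c(ra$p5, ra$q1, ra$q2, ra$q3, ra$p95),
                    c(rb$p5, rb$q1, rb$q2, rb$q3, rb$p95)),
      n = c(ra$n, rb$n), conf = NULL, out = numeric(0),
      names = x$labels
    )
    graphics::bxp(bx, main = mn, ylab = mn)
    graphics::points(1:2, c(ra$mean, rb$mean), pch = 0)
  }
  if (!is.null(x$pca)) {
    sc <- x$pca$scores
    cols <- ifelse(x$pca$condition == x$labels[[1L]], "red", "blue")
    graphics::plot(sc[, 1], sc[, 2], col = cols, pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained[[1L]]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained[[2L]]),
                   main = "PCA of activity metrics")
    graphics::legend("topright", legend = x$labels, col = c("red", "blue"),
                     pch = 19, bty = "n")
  }
  invisible(x)
}
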