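#' Align peak trains to their first event and standardise the window
#'
#' Each train is realigned so its first peak is at time 0 (the pre-peak
#' interval is discarded) and its record length becomes
#' `final_time - first_peak`. The common comparison window ends at
#' `t_last`, the minimum realigned length across trains; peaks beyond
#' `t_last` are dropped (counts reported for provenance). Trains with no
#' peaks are excluded with a warning.
#'
#' @param trains A list of `cp_train` objects from [detect_peaks()].
#' @return An object of class `aligned_trains`: `trains` (list of numeric
#'   relative peak-time vectors, first element 0), `t_last`, `source_ids`,
#'   `dropped_prefix` (seconds removed before the first peak, per train),
#'   `dropped_peaks` (peaks truncated beyond `t_last`, per train).
#' @examples
#' mk <- function(p, fin) structure(list(source_id = "r", peak_times = p,
#'   final_time = fin, params = detection_params()), class = "cp_train")
#' a <- align_trains(list(mk(c(12, 20), 600), mk(c(30, 44), 595.519)))
#' a$t_last  # 565.519
#' @export
align_trains <- function(trains) {
  if (inherits(trains, "cp_train")) trains <- list(trains)
  stopifnot(is.list(trains), length(trains) >= 1L)
  ok <- vapply(trains, function(tr) length(tr$peak_times) >= 1L, logical(1))
  if (!any(ok)) stop("all trains are empty: nothing to align")
  if (any(!ok)) {
    bad <- vapply(trains[!ok], `[[`, character(1), "source_id")
    warning("excluding ", sum(!ok), " train(s) with zero peaks: ",
            paste(bad, collapse = ", "))
    trains <- trains[ok]
  }
  first <- vapply(trains, function(tr) tr$peak_times[[1L]], numeric(1))
  fin <- vapply(trains, `[[`, numeric(1), "final_time")
  t_last <- min(fin - first)
  rel <- vector("list", length(trains))
  dropped <- integer(length(trains))
  for (i in seq_along(trains)) {
    p <- trains[[i]]$peak_times - first[[i]]
    keep <- p <= t_last
    dropped[[i]] <- sum(!keep)
    rel[[i]] <- p[keep]
  }
  structure(
    list(
      trains = rel,
      t_last = t_last,
      source_ids = vapply(trains, `[[`, character(1), "source_id"),
      dropped_prefix = first,
      dropped_peaks = dropped
    ),
    class = "aligned_trains"
  )
}

#' @export
print.aligned_trains <- function(x, ...) {
  cat(sprintf(
    "aligned_trains: %d trains on common window [0, %.3f] s\n",
    length(x$trains), x$t_last
  ))
  for (i in seq_along(x$trains)) {
    cat(sprintf("  %-20s %4d peaks (prefix %.2f s removed, %d truncated)\n",
                x$source_ids[[i]], length(x$trains[[i]]),
                x$dropped_prefix[[i]], x$dropped_peaks[[i]]))
  }
  invisible(x)
}

#' Classify inter-peak intervals and segment bursts
#'
#' Consecutive-peak differences \eqn{\delta_p = t_{p+1} - t_p}, plus the
#' terminal interval from the last peak to `t_last`, are each classified by
#' duration: a contraction-pulse (CP) interval if \eqn{\delta <}
#' `cp_threshold`, an inter-contraction burst interval (IcBI) if
#' \eqn{\delta \ge} `icbi_threshold`. With distinct thresholds any interval
#' falling between them is labelled `ambiguous` and excluded from burst
#' membership, with a warning; the default configuration keeps the two
#' equal so the split is exhaustive. Bursts are maximal runs of consecutive
#' CP intervals; `burst_index` numbers them from 1 in time order.
#'
#' The intervals tile `[0, t_last]` exactly: the first peak of an aligned
#' train sits at 0 and the terminal interval ends at `t_last`.
#'
#' @param train An aligned train: a numeric vector of strictly increasing
#'   peak times whose first element is 0 (one element of
#'   [align_trains()]`$trains`), or a `cp_train` whose first peak is at 0.
#' @param t_last End of the common comparison window, seconds.
#' @param params A [detection_params()] supplying `cp_threshold` and
#'   `icbi_threshold`.
#' @param source_id Identifier copied into the table (taken from the train
#'   if it is a `cp_train`).
#' @return A `cp_events` data frame with columns `source_id`,
#'   `event_index`, `t_start_s`, `t_end_s`, `duration_s`, `class` (factor
#'   CP/IcBI/ambiguous), `burst_index` (NA outside bursts), and attributes
#'   `t_last`, `n_peaks`.
#' @examples
#' p <- detection_params()
#' ev <- classify_intervals(c(0, 1, 2, 40), t_last = 80, params = p)
#' table(ev$class)        # 2 CP, 2 IcBI
#' sum(ev$duration_s)     # 80
#' @export
classify_intervals <- function(train, t_last, params = detection_params(),
                               source_id = "recording") {
  params <- as_detection_params(params)
  if (inherits(train, "cp_train")) {
    source_id <- train$source_id
    train <- train$peak_times
  }
  p <- as.numeric(train)
  if (length(p) < 1L) stop("train must contain at least one peak")
  if (abs(p[[1L]]) > 1e-12)
    stop("contract violation: train is not aligned (first peak must be 0)")
  if (is.unsorted(p, strictly = TRUE)) stop("peak times must strictly increase")
  if (t_last < p[[length(p)]])
    stop("t_last (", t_last, ") precedes the last peak (", p[[length(p)]], ")")

  starts <- p
  ends <- c(p[-1L], t_last)
  # terminal interval taken as the non-negative duration t_last - t_p,last
  durs <- ends - starts
  cls <- ifelse(durs < params$cp_threshold, "CP",
                ifelse(durs >= params$icbi_threshold, "IcBI", "ambiguous"))
  if (any(cls == "ambiguous"))
    warning(sum(cls == "ambiguous"), " interval(s) between cp_threshold and ",
            "icbi_threshold labelled 'ambiguous' and excluded from bursts")

  # bursts = maximal runs of consecutive CP intervals
  burst_index <- rep(NA_integer_, length(durs))
  r <- rle(cls == "CP")
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  b <- 0L
  for (k in seq_along(r$values)) {
    if (r$values[[k]]) {
      b <- b + 1L
      burst_index[run_starts[[k]]:run_ends[[k]]] <- b
    }
  }

  df <- data.frame(
    source_id = source_id,
    event_index = seq_along(durs),
    t_start_s = starts,
    t_end_s = ends,
    duration_s = durs,
    class = factor(cls, levels = c("CP", "IcBI", "ambiguous")),
    burst_index = burst_index
  )
  structure(df, t_last = t_last, n_peaks = length(p),
            params = params, class = c("cp_events", "data.frame"))
}

#' Compute per-recording activity metrics
#'
#' Summarises a classified event table into the standard metric suite:
#' \describe{
#'   \item{cpi}{durations of CP-classified intervals (contraction pulse
#'     intervals), seconds}
#'   \item{ctime}{total contraction time, `sum(cpi)`}
#'   \item{icbi}{durations of IcBI-classified intervals}
#'   \item{etime}{total elongation time, `sum(icbi)`}
#'   \item{burst_time}{per-burst sum of CPIs}
#'   \item{n_burst, n_icbi, n_cp, n_cp_burst}{burst count (maximal CP
#'     runs), IcBI count, CP count, and per-burst CP counts}
#'   \item{hyai}{Hydra Activity Index, `ctime / etime` — the balance of
#'     contractile versus elongation behaviour. When `etime` is 0 the index
#'     is undefined; it is reported as `Inf` with `hyai_defined = FALSE`
#'     rather than raising.}
#'   \item{cv}{coefficient of variation \eqn{\sigma^* = \sigma/|\mu|} of
#'     the per-recording lists (cpi, icbi, burst_time, n_cp_burst)}
#' }
#' With `count_convention = "intervals"` (default) `n_cp` counts
#' CP-classified intervals, so `n_cp = sum(n_cp_burst)` and
#' `ctime = sum(cpi)` are consistent; `"peaks"` counts the peaks bounding
#' each run instead (one more per burst).
#'
#' @param events A `cp_events` table from [classify_intervals()].
#' @param count_convention Overrides the convention recorded in the
#'   table's parameters; see [detection_params()].
#' @return An object of class `activity_metrics`.
#' @examples
#' ev <- classify_intervals(c(0, 1, 2, 40), 80, detection_params())
#' m <- compute_metrics(ev)
#' m$ctime + m$etime  # 80 = t_last
#' @export
compute_metrics <- function(events, count_convention = NULL) {
  stopifnot(inherits(events, "cp_events"))
  params <- attr(events, "params")
  conv <- count_convention %||% params$count_convention
  conv <- match.arg(conv, c("intervals", "peaks"))
  t_last <- attr(events, "t_last")

  cpi <- events$duration_s[events$class == "CP"]
  icbi <- events$duration_s[events$class == "IcBI"]
  ctime <- sum(cpi)
  etime <- sum(icbi)

  bidx <- events$burst_index[!is.na(events$burst_index)]
  n_burst <- if (length(bidx)) max(bidx) else 0L
  n_cp_burst <- if (n_burst > 0L) as.integer(table(factor(bidx, 1:n_burst)))
                else integer(0)
  burst_time <- if (n_burst > 0L)
    as.numeric(tapply(events$duration_s[!is.na(events$burst_index)],
                      factor(bidx, 1:n_burst), sum))
  else numeric(0)
  if (conv == "peaks") n_cp_burst <- n_cp_burst + 1L
  n_cp <- if (conv == "intervals") length(cpi) else sum(n_cp_burst)

  hyai_defined <- etime > 0
  hyai <- if (hyai_defined) ctime / etime else if (ctime > 0) Inf else NaN

  cv <- function(v) if (length(v) >= 1L && mean(v) != 0)
    stats::sd(v) / abs(mean(v)) else NA_real_

  structure(
    list(
      source_id = events$source_id[[1L]],
      t_last = t_last,
      cpi = cpi,
      icbi = icbi,
      burst_time = burst_time,
      ctime = ctime,
      etime = etime,
      n_burst = as.integer(n_burst),
      n_icbi = length(icbi),
      n_cp = as.integer(n_cp),
      n_cp_burst = n_cp_burst,
      hyai = hyai,
      hyai_defined = hyai_defined,
      count_convention = conv,
      cv = c(cpi = cv(cpi), icbi = cv(icbi), burst_time = cv(burst_time),
             n_cp_burst = cv(as.numeric(n_cp_burst)))
    ),
    class = "activity_metrics"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.activity_metrics <- function(x, ...) {
  cat(sprintf("activity_metrics for '%s' (window %.3f s)\n",
              x$source_id, x$t_last))
  cat(sprintf("  CTime %.3f s over %d CP intervals; ETime %.3f s over %d IcBI\n",
              x$ctime, x$n_cp, x$etime, x$n_icbi))
  cat(sprintf("  %d burst(s); CPs per burst: %s\n", x$n_burst,
              paste(x$n_cp_burst, collapse = " ")))
  if (x$hyai_defined) {
    cat(sprintf("  HyAI = %.4f\n", x$hyai))
  } else {
    cat("  HyAI undefined (ETime = 0): flagged as infinite activity\n")
  }
  invisible(x)
}

#' Flatten activity metrics to a one-row data frame
#'
#' Scalar summary used for cross-recording tables and the reporting
#' module: `source_id, t_last, ctime, etime, n_burst, n_icbi, n_cp, hyai,
#' mean_cpi, mean_icbi, mean_burst_time`.
#'
#' @param x An `activity_metrics` object.
#' @param ... Unused.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.activity_metrics <- function(x, ...) {
  data.frame(
    source_id = x$source_id,
    t_last = x$t_last,
    ctime = x$ctime,
    etime = x$etime,
    n_burst = x$n_burst,
    n_icbi = x$n_icbi,
    n_cp = x$n_cp,
    hyai = x$hyai,
    mean_cpi = if (length(x$cpi)) mean(x$cpi) else NA_real_,
    mean_icbi = if (length(x$icbi)) mean(x$icbi) else NA_real_,
    mean_burst_time = if (length(x$burst_time)) mean(x$burst_time) else NA_real_
  )
}

#' Raster of aligned peak trains
#'
#' One row per train, marks at the relative peak times over the common
#' window `[0, t_last]`.
#'
#' @param aligned An [align_trains()] result.
#' @return An object of class `cp_raster`: data frame with columns
#'   `train`, `source_id`, `time_s`, plus attribute `t_last`.
#' @export
raster <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_trains"))
  rows <- lapply(seq_along(aligned$trains), function(i) {
    ts <- aligned$trains[[i]]
    if (!length(ts))
      return(data.frame(train = integer(0), source_id = character(0),
                        time_s = numeric(0)))
    data.frame(train = i, source_id = aligned$source_ids[[i]], time_s = ts)
  })
  df <- do.call(rbind, rows)
  structure(df, t_last = aligned$t_last,
            n_trains = length(aligned$trains),
            class = c("cp_raster", "data.frame"))
}

#' @export
plot.cp_raster <- function(x, col = "black", ...) {
  n <- attr(x, "n_trains")
  graphics::plot(
    NULL, xlim = c(0, attr(x, "t_last")), ylim = c(0.5, n + 0.5),
    xlab = "time since first peak (s)", ylab = "recording",
    yaxt = "n", main = "Raster of detected contraction pulses", ...
  )
  graphics::axis(2, at = seq_len(n), labels = seq_len(n), las = 1)
  if (nrow(x))
    graphics::segments(x$time_s, x$train - 0.4, x$time_s, x$train + 0.4,
                       col = col)
  invisible(x)
}
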