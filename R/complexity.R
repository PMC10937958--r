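#' Ordinal pattern index of m consecutive values
#'
#' Identifies the rank permutation of a window of `m` consecutive samples by
#' its Lehmer code: digit i counts later values strictly smaller than value
#' i, weighted by (m-i)!. Strictly increasing values map to 0, strictly
#' decreasing to m!-1. Ties break stably (the earlier occurrence ranks
#' first).
#'
#' @param window Numeric vector of length m (finite).
#' @return Integer pattern id in `[0, factorial(m) - 1]`.
#' @export
ordinal_pattern_index <- function(window) {
  m <- length(window)
  stop_if(m < 2L, "need at least two values")
  stop_if(any(!is.finite(window)), "window contains non-finite values")
  fact <- factorial((m - 1L):0L)
  id <- 0
  for (i in 1:(m - 1L)) {
    id <- id + sum(window[(i + 1L):m] < window[i]) * fact[i]
  }
  as.integer(id)
}

# Vectorized Lehmer codes for all length-m windows of a series. Windows
# containing non-finite values return NA. Ties resolve stably, identical to
# ordinal_pattern_index().
ordinal_pattern_codes <- function(x, m = 6L) {
  n <- length(x) - m + 1L
  stop_if(n < 1L, "series shorter than one pattern")
  fact <- factorial((m - 1L):0L)
  code <- numeric(n)
  for (i in 1:(m - 1L)) {
    xi <- x[i:(i + n - 1L)]
    di <- numeric(n)
    for (j in (i + 1L):m) di <- di + (x[j:(j + n - 1L)] < xi)
    code <- code + di * fact[i]
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- !is.finite(x)
    badw <- which(stats::filter(as.numeric(bad), rep(1, m), sides = 1)[m:length(x)] > 0)
    code[badw] <- NA
  }
  code
}

#' Permutation entropy of one window
#'
#' Shannon entropy \eqn{-\sum p_i \ln p_i} of the ordinal-pattern frequency
#' distribution over all consecutive (delay 1) order-`m` patterns in the
#' window; optionally normalized by \eqn{\ln(m!)} to [0, 1]. An all-constant
#' window has a single pattern and entropy 0 (with a warning).
#'
#' @param x Window samples.
#' @param m Pattern order (default 6).
#' @param normalize Report entropy normalized to [0, 1] (default TRUE).
#' @return Permutation entropy value.
#' @export
permutation_entropy_window <- function(x, m = 6L, normalize = TRUE) {
  stop_if(m < 2L, "order must be >= 2")
  if (length(x) < factorial(m) * 5)
    warning("window shorter than 5 * m! samples; entropy estimate is coarse",
            call. = FALSE)
  code <- ordinal_pattern_codes(x, m)
  code <- code[!is.na(code)]
  stop_if(length(code) == 0L, "no valid patterns in window")
  p <- tabulate(code + 1L, nbins = factorial(m))
  p <- p / sum(p)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz])) + 0  # +0 normalizes signed zero
  if (h == 0) warning("single ordinal pattern; entropy 0", call. = FALSE)
  if (normalize) h / log(factorial(m)) else h
}

#' Sliding-window permutation entropy per condition epoch
#'
#' Computes the ordinal-pattern codes once per epoch and tabulates them in
#' sliding windows (default 30,000 samples = 15 s at 2 kHz, hop 2,000
#' samples), then averages into one representative entropy value per
#' condition. Windows never straddle epoch boundaries.
#'
#' @param x Signal (single channel).
#' @param fs Sampling rate (Hz).
#' @param epochs data.frame with `label`, `start_s`, `end_s`.
#' @param window_len Window length in samples (default 30000).
#' @param hop Hop in samples (default 2000).
#' @param m Pattern order (default 6).
#' @param normalize Normalize to [0, 1] (default TRUE); raw nats are always
#'   included in the per-window table.
#' @return Object of class `"entropy_result"`: `windows` (data.frame with
#'   condition, window start, pe, pe_nats), `summary` (per-condition mean,
#'   sd, n; conditions shorter than one window are `NA` with a reason).
#' @export
permutation_entropy_series <- function(x, fs, epochs, window_len = 30000L,
                                       hop = 2000L, m = 6L,
                                       normalize = TRUE) {
  stop_if(hop < 1L, "`hop` must be >= 1")
  stop_if(m < 2L, "order must be >= 2")
  win_rows <- list()
  sum_rows <- list()
  lw <- log(factorial(m))
  for (e in seq_len(nrow(epochs))) {
    i0 <- floor(epochs$start_s[e] * fs) + 1L
    i1 <- min(floor(epochs$end_s[e] * fs), length(x))
    lab <- epochs$label[e]
    if (i1 - i0 + 1L < window_len) {
      sum_rows[[e]] <- data.frame(condition = lab, pe_mean = NA_real_,
                                  pe_sd = NA_real_, n_windows = 0L,
                                  reason = "epoch shorter than one window")
      next
    }
    seg <- x[i0:i1]
    code <- ordinal_pattern_codes(seg, m)
    starts <- seq.int(1L, length(seg) - window_len + 1L, by = hop)
    pe <- vapply(starts, function(s) {
      cw <- code[s:(s + window_len - m)]
      cw <- cw[!is.na(cw)]
      if (!length(cw)) return(NA_real_)
      p <- tabulate(cw + 1L, nbins = factorial(m))
      p <- p / sum(p)
      nz <- p > 0
      -sum(p[nz] * log(p[nz]))
    }, numeric(1))
    win_rows[[e]] <- data.frame(
      condition = lab, start_s = epochs$start_s[e] + (starts - 1L) / fs,
      pe = if (normalize) pe / lw else pe, pe_nats = pe)
    sum_rows[[e]] <- data.frame(
      condition = lab,
      pe_mean = mean(if (normalize) pe / lw else pe, na.rm = TRUE),
      pe_sd = stats::sd(if (normalize) pe / lw else pe),
      n_windows = length(starts), reason = NA_character_)
  }
  structure(list(windows = do.call(rbind, win_rows),
                 summary = do.call(rbind, sum_rows),
                 normalized = normalize, m = m, window_len = window_len),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> order %d, window %d samples%s\n", x$m,
              x$window_len, if (x$normalized) " (normalized)" else ""))
  print(x$summary)
  invisible(x)
}
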