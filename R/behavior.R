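#' Read a pose-track CSV
#'
#' Accepts the common markerless-tracking export dialect with a 3-row header
#' (scorer / bodypart / coordinate) and a plain long format
#' (`frame,bodypart,x,y[,likelihood]`). Coordinates are assumed calibrated
#' to cm (an optional `scale` multiplies them).
#'
#' @param path CSV path.
#' @param fps Frames per second (default 25).
#' @param scale Optional coordinate scale factor.
#' @return A `pose_track`: data.frame `frame, bodypart, x, y, likelihood`
#'   with attributes `fps`.
#' @export
read_pose_track <- function(path, fps = 25, scale = 1) {
  first <- readLines(path, n = 3L)
  if (grepl("^scorer", first[1L]) || grepl("bodyparts", first[2L])) {
    parts <- strsplit(first[2L], ",")[[1L]][-1L]
    coords <- strsplit(first[3L], ",")[[1L]][-1L]
    raw <- utils::read.csv(path, skip = 3L, header = FALSE)
    frame <- raw[[1L]]
    rows <- list()
    for (bp in unique(parts)) {
      ix <- which(parts == bp & coords == "x") + 1L
      iy <- which(parts == bp & coords == "y") + 1L
      il <- which(parts == bp & coords == "likelihood") + 1L
      rows[[bp]] <- data.frame(
        frame = frame, bodypart = bp,
        x = raw[[ix[1L]]] * scale, y = raw[[iy[1L]]] * scale,
        likelihood = if (length(il)) raw[[il[1L]]] else 1,
        stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, rows)
  } else {
    tr <- utils::read.csv(path, stringsAsFactors = FALSE)
    stop_if(!all(c("frame", "bodypart", "x", "y") %in% names(tr)),
            "long format needs columns frame, bodypart, x, y")
    if (is.null(tr$likelihood)) tr$likelihood <- 1
    tr$x <- tr$x * scale
    tr$y <- tr$y * scale
  }
  tr <- tr[order(tr$frame, tr$bodypart), ]
  rownames(tr) <- NULL
  as_pose_track(tr, fps)
}

#' @rdname read_pose_track
#' @param track Long-format data.frame to tag as a pose track.
#' @export
as_pose_track <- function(track, fps = 25) {
  stop_if(fps <= 0, "`fps` must be > 0")
  attr(track, "fps") <- fps
  class(track) <- c("pose_track", "data.frame")
  track
}

#' Centroid trajectory by averaging body parts
#'
#' Per-frame mean of the available (finite) body-part coordinates; frames
#' where every part is missing are linearly interpolated and flagged.
#'
#' @param track A `pose_track`.
#' @return data.frame `frame, x, y, interpolated` with attribute `fps`.
#' @export
average_position <- function(track) {
  fps <- attr(track, "fps") %||% 25
  ok <- is.finite(track$x) & is.finite(track$y)
  t2 <- track[ok, , drop = FALSE]
  frames <- sort(unique(track$frame))
  agg_x <- tapply(t2$x, factor(t2$frame, levels = frames), mean)
  agg_y <- tapply(t2$y, factor(t2$frame, levels = frames), mean)
  cen <- data.frame(frame = frames, x = as.numeric(agg_x),
                    y = as.numeric(agg_y))
  cen$interpolated <- !is.finite(cen$x) | !is.finite(cen$y)
  if (any(cen$interpolated)) {
    good <- which(!cen$interpolated)
    stop_if(length(good) < 2L, "too few frames with any tracked part")
    cen$x <- stats::approx(cen$frame[good], cen$x[good], xout = cen$frame,
                           rule = 2)$y
    cen$y <- stats::approx(cen$frame[good], cen$y[good], xout = cen$frame,
                           rule = 2)$y
  }
  attr(cen, "fps") <- fps
  cen
}

#' Speed from a centroid trajectory
#'
#' Euclidean displacement between consecutive frames times fps. The first
#' frame has speed 0. Optional boxcar smoothing.
#'
#' @param centroid data.frame from [average_position()] (or with `x`, `y`).
#' @param fps Frames per second (taken from the centroid attribute when
#'   present).
#' @param smooth_frames Boxcar width in frames (0/1 = none).
#' @return Numeric speed series (cm/s), one value per frame.
#' @export
compute_speed <- function(centroid, fps = NULL, smooth_frames = 0L) {
  fps <- fps %||% attr(centroid, "fps") %||% 25
  stop_if(nrow(centroid) < 2L, "need at least two frames")
  d <- sqrt(diff(centroid$x)^2 + diff(centroid$y)^2) * fps
  v <- c(0, d)
  if (smooth_frames > 1L) {
    k <- rep(1 / smooth_frames, smooth_frames)
    v <- as.numeric(stats::filter(v, k, sides = 2))
    v[is.na(v)] <- 0
  }
  v
}

#' Bout detection configuration
#' @param min_speed Minimum speed (cm/s), default 2.
#' @param min_duration Minimum duration (s), default 0.5.
#' @param median_frames Median-filter width (frames) applied to the speed
#'   before thresholding (tracking-jitter suppression); default 5, 0
#'   disables.
#' @export
bout_config <- function(min_speed = 2, min_duration = 0.5,
                        median_frames = 5L) {
  stop_if(min_speed <= 0 || min_duration <= 0, "thresholds must be > 0")
  list(min_speed = min_speed, min_duration = min_duration,
       median_frames = as.integer(median_frames))
}

#' Detect locomotion bouts from a speed profile
#'
#' Maximal runs with (median-filtered) speed at or above `min_speed` lasting
#' at least `min_duration` (0.5 s at 25 fps = 12.5 frames, rounded up to
#' 13). Bouts are non-overlapping and ordered.
#'
#' @param speed Speed series (cm/s) at `fps`.
#' @param fps Frames per second.
#' @param config A [bout_config()].
#' @return data.frame: start_frame, end_frame, duration_s, mean_speed,
#'   distance_cm (zero rows when nothing qualifies).
#' @export
detect_bouts <- function(speed, fps = 25, config = bout_config()) {
  v <- speed
  if (config$median_frames > 1L) {
    k <- config$median_frames
    if (k %% 2L == 0L) k <- k + 1L
    v <- stats::runmed(v, k)
  }
  min_frames <- as.integer(ceiling(config$min_duration * fps))
  above <- v >= config$min_speed
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), mean_speed = numeric(0),
                      distance_cm = numeric(0)))
  }
  out <- data.frame(start_frame = starts[keep], end_frame = ends[keep])
  out$duration_s <- (out$end_frame - out$start_frame + 1L) / fps
  out$mean_speed <- vapply(seq_len(nrow(out)), function(i)
    mean(speed[out$start_frame[i]:out$end_frame[i]]), numeric(1))
  out$distance_cm <- vapply(seq_len(nrow(out)), function(i)
    sum(speed[out$start_frame[i]:out$end_frame[i]]) / fps, numeric(1))
  out
}

#' Summary statistics over detected bouts
#'
#' @param bouts data.frame from [detect_bouts()].
#' @param window_s Observation window length (s), > 0.
#' @return One-row data.frame: n_bouts, bout_rate_per_min, mean_speed,
#'   mean_duration_s, mean_distance_cm, locomotion_cm_per_s (total
#'   within-bout distance over the window). With no bouts the rate is 0 and
#'   the means are `NA` (missing, not zero).
#' @export
bout_statistics <- function(bouts, window_s) {
  stop_if(window_s <= 0, "`window_s` must be > 0")
  n <- nrow(bouts)
  data.frame(
    n_bouts = n,
    bout_rate_per_min = n / (window_s / 60),
    mean_speed = if (n) mean(bouts$mean_speed) else NA_real_,
    mean_duration_s = if (n) mean(bouts$duration_s) else NA_real_,
    mean_distance_cm = if (n) mean(bouts$distance_cm) else NA_real_,
    locomotion_cm_per_s = if (n) sum(bouts$distance_cm) / window_s else 0)
}

#' Cumulative signed turning angle
#'
#' Heading is the direction of centroid displacement; frames moving slower
#' than `min_speed` are excluded from the angle sums (heading is undefined
#' at rest). Wrapped frame-to-frame heading changes are summed; positive =
#' counterclockwise. By the ipsiversive convention for a right-hemisphere
#' lesion, positive sums indicate leftward (ipsiversive) rotation bias.
#'
#' @param centroid data.frame from [average_position()].
#' @param fps Frames per second.
#' @param min_speed Speed threshold for heading validity (cm/s), default 1.
#' @return Cumulative angle in degrees. Errors when heading is undefined
#'   for more than half of the frames.
#' @export
cumulative_turning <- function(centroid, fps = NULL, min_speed = 1) {
  fps <- fps %||% attr(centroid, "fps") %||% 25
  dx <- diff(centroid$x)
  dy <- diff(centroid$y)
  spd <- sqrt(dx^2 + dy^2) * fps
  ok <- spd > min_speed
  stop_if(mean(ok) < 0.5 && sum(ok) < 2L,
          "heading undefined for more than half of the frames")
  heading <- atan2(dy, dx)
  h <- heading[ok]
  if (length(h) < 2L) return(0)
  dh <- wrap_pi(diff(h))
  sum(dh) * 180 / pi
}

#' Generate a synthetic pose track with a known bout schedule
#'
#' The centroid rests between bouts and moves at the scheduled speed during
#' them, with optional constant-sign turning; body parts sit at zero-mean
#' offsets along the heading axis plus isotropic Gaussian jitter
#' (`noise_cm`). With zero noise the scheduled bouts are exactly
#' recoverable.
#'
#' @param bout_schedule data.frame `start_s, end_s` and optional `speed`
#'   (cm/s, default 5); non-overlapping.
#' @param duration_s Track duration (s).
#' @param fps Frames per second (default 25).
#' @param arena_diameter_cm Circular arena diameter (default 50).
#' @param turn_rate_deg_s Constant heading rotation during bouts (deg/s).
#' @param noise_cm Body-part jitter SD (cm).
#' @param n_parts Number of tracked body parts (default 3).
#' @param seed Optional integer seed.
#' @return A `pose_track` with attribute `bout_schedule`.
#' @export
generate_pose_track <- function(bout_schedule, duration_s, fps = 25,
                                arena_diameter_cm = 50, turn_rate_deg_s = 0,
                                noise_cm = 0, n_parts = 3L, seed = NULL) {
  stop_if(fps <= 0, "`fps` must be > 0")
  bs <- bout_schedule
  if (nrow(bs)) {
    bs <- bs[order(bs$start_s), , drop = FALSE]
    stop_if(any(bs$end_s <= bs$start_s), "bouts need end_s > start_s")
    stop_if(any(bs$end_s > duration_s + 1e-9), "bouts outside the track")
    if (nrow(bs) > 1L)
      stop_if(any(bs$start_s[-1L] < bs$end_s[-nrow(bs)]),
              "overlapping bouts")
    if (is.null(bs$speed)) bs$speed <- 5
  }
  if (!is.null(seed)) set.seed(seed)
  nfr <- as.integer(round(duration_s * fps))
  rmax <- arena_diameter_cm / 2 - 3
  x <- numeric(nfr)
  y <- numeric(nfr)
  heading <- 0
  pos <- c(-rmax / 2, 0)
  in_bout <- rep(FALSE, nfr)
  speed_of <- rep(0, nfr)
  for (b in seq_len(nrow(bs))) {
    f0 <- floor(bs$start_s[b] * fps) + 1L
    f1 <- min(floor(bs$end_s[b] * fps), nfr)
    in_bout[f0:f1] <- TRUE
    speed_of[f0:f1] <- bs$speed[b]
  }
  omega <- turn_rate_deg_s * pi / 180 / fps
  for (f in seq_len(nfr)) {
    if (in_bout[f]) {
      heading <- heading + omega
      step <- speed_of[f] / fps
      cand <- pos + step * c(cos(heading), sin(heading))
      if (sqrt(sum(cand^2)) > rmax) {
        # steer toward the center, keep the step length
        heading <- atan2(-pos[2L], -pos[1L])
        cand <- pos + step * c(cos(heading), sin(heading))
      }
      pos <- cand
    }
    x[f] <- pos[1L]
    y[f] <- pos[2L]
  }
  offsets <- seq(-1.5, 1.5, length.out = n_parts)
  offsets <- offsets - mean(offsets)  # zero-mean: centroid = position
  hx <- c(0, diff(x))
  hy <- c(0, diff(y))
  hn <- sqrt(hx^2 + hy^2)
  ux <- ifelse(hn > 0, hx / hn, 1)
  uy <- ifelse(hn > 0, hy / hn, 0)
  rows <- lapply(seq_len(n_parts), function(p) {
    data.frame(frame = seq_len(nfr) - 1L,
               bodypart = paste0("part", p),
               x = x + offsets[p] * ux + stats::rnorm(nfr, 0, noise_cm),
               y = y + offsets[p] * uy + stats::rnorm(nfr, 0, noise_cm),
               likelihood = 1, stringsAsFactors = FALSE)
  })
  tr <- as_pose_track(do.call(rbind, rows), fps)
  attr(tr, "bout_schedule") <- bs
  tr
}
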