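#' @title Freely-moving spatial analysis
#' @description Kinematics from tracked points, occupancy-normalized firing
#'   rate maps, the border score, and circular-shuffle significance testing.
#' @name spatial
NULL

#' Speed and head direction from tracked body points
#'
#' Points with likelihood at or below `likelihood_cut` are dropped and the
#' gaps closed by linear interpolation (also used for upsampling to
#' `rate_out`). Speed is the Euclidean distance between consecutive
#' positions divided by the inter-frame interval, smoothed with a moving
#' average of `smooth_s`. When left/right ear columns (`lx, ly, rx, ry`)
#' are present, head direction is the angle of the left-to-right ear
#' vector rotated 90 degrees counterclockwise.
#'
#' @param track data frame with `t_s`, `x_cm`, `y_cm` and optionally
#'   `likelihood`, `lx`, `ly`, `rx`, `ry`.
#' @param rate_out output rate (Hz); `NULL` keeps the native track rate.
#' @param likelihood_cut tracking-confidence threshold (default 0.7).
#' @param smooth_s speed smoothing kernel (default 0.5 s).
#' @return a `behavior_track` list: `t_s`, `x_cm`, `y_cm`, `speed_cms`,
#'   `head_dir_deg` (or NULL), `rate`.
#' @export
compute_kinematics <- function(track, rate_out = NULL,
                               likelihood_cut = 0.7, smooth_s = 0.5) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(track)))
  ok <- if ("likelihood" %in% names(track))
    track$likelihood > likelihood_cut else rep(TRUE, nrow(track))
  stopifnot(sum(ok) >= 2)
  t_in <- track$t_s[ok]
  if (is.null(rate_out)) {
    t_out <- track$t_s
  } else {
    t_out <- seq(min(track$t_s), max(track$t_s), by = 1 / rate_out)
  }
  x <- stats::approx(t_in, track$x_cm[ok], xout = t_out, rule = 2)$y
  y <- stats::approx(t_in, track$y_cm[ok], xout = t_out, rule = 2)$y
  dt <- diff(t_out)
  sp <- c(0, sqrt(diff(x)^2 + diff(y)^2) / dt)
  rate <- 1 / stats::median(dt)
  sp <- moving_average(sp, round(smooth_s * rate))
  hd <- NULL
  if (all(c("lx", "ly", "rx", "ry") %in% names(track))) {
    lx <- stats::approx(t_in, track$lx[ok], xout = t_out, rule = 2)$y
    ly <- stats::approx(t_in, track$ly[ok], xout = t_out, rule = 2)$y
    rx <- stats::approx(t_in, track$rx[ok], xout = t_out, rule = 2)$y
    ry <- stats::approx(t_in, track$ry[ok], xout = t_out, rule = 2)$y
    vx <- rx - lx; vy <- ry - ly
    # 90 deg counterclockwise rotation of the ear vector
    hd <- (atan2(vx, -vy) * 180 / pi) %% 360
  }
  structure(list(t_s = t_out, x_cm = x, y_cm = y, speed_cms = sp,
                 head_dir_deg = hd, rate = rate),
            class = "behavior_track")
}

# Gaussian smoothing on a masked grid: unvisited bins contribute nothing
# and the kernel is renormalized over visited bins.
masked_gauss_smooth <- function(m, visited, sigma_bins) {
  r <- ceiling(3 * sigma_bins)
  k <- outer(-r:r, -r:r, function(i, j)
    exp(-(i^2 + j^2) / (2 * sigma_bins^2)))
  mm <- m
  mm[!visited] <- 0
  w <- matrix(0, nrow(m), ncol(m)) + as.numeric(visited)
  conv2 <- function(a) {
    out <- matrix(0, nrow(a), ncol(a))
    for (di in -r:r) for (dj in -r:r) {
      wk <- k[di + r + 1, dj + r + 1]
      src_r <- seq_len(nrow(a)) - di
      src_c <- seq_len(ncol(a)) - dj
      ok_r <- src_r >= 1 & src_r <= nrow(a)
      ok_c <- src_c >= 1 & src_c <= ncol(a)
      out[ok_r, ok_c] <- out[ok_r, ok_c] +
        wk * a[src_r[ok_r], src_c[ok_c]]
    }
    out
  }
  num <- conv2(mm)
  den <- conv2(w)
  out <- num / den
  out[!visited] <- NA_real_
  out
}

#' Occupancy-normalized spatial firing rate map
#'
#' Positions and spikes are binned on a square grid (default 2.5 cm bins);
#' the rate in each bin is the spike count over the occupancy time,
#' computed only on bins visited for at least `min_occ_s` seconds, then
#' smoothed with a Gaussian kernel (default SD 3 cm) renormalized over
#' visited bins. Samples slower than `speed_cut_cms` are excluded first.
#'
#' @param track a `behavior_track` (or data frame with `t_s`, `x_cm`,
#'   `y_cm`; speed is then derived).
#' @param spike_times_s spike times aligned to the track clock.
#' @param arena_cm arena side length (default 80).
#' @param bin_cm bin size (default 2.5).
#' @param sigma_cm smoothing SD (default 3).
#' @param min_occ_s minimum occupancy for a visited bin (default 0.1 s).
#' @param speed_cut_cms exclude samples below this speed (default 2.5;
#'   `NULL` disables).
#' @return a `rate_map` list: `rate` (smoothed, Hz), `rate_raw`,
#'   `spike_count`, `occupancy_s`, `visited`, `bin_cm`, `arena_cm`,
#'   `n_spikes_used`.
#' @export
rate_map <- function(track, spike_times_s, arena_cm = 80, bin_cm = 2.5,
                     sigma_cm = 3, min_occ_s = 0.1, speed_cut_cms = 2.5) {
  if (!inherits(track, "behavior_track"))
    track <- compute_kinematics(track)
  nb <- ceiling(arena_cm / bin_cm)
  dt <- 1 / track$rate
  keep <- if (is.null(speed_cut_cms)) rep(TRUE, length(track$t_s))
          else track$speed_cms >= speed_cut_cms
  if (!any(keep)) stop("data error: zero occupancy everywhere",
                       call. = FALSE)
  bx <- pmin(pmax(ceiling(track$x_cm / bin_cm), 1), nb)
  by <- pmin(pmax(ceiling(track$y_cm / bin_cm), 1), nb)
  cell <- (bx - 1) * nb + by
  occ <- tabulate(cell[keep], nbins = nb * nb) * dt
  # map each spike to the nearest track sample; inherit its speed mask
  si <- pmin(pmax(findInterval(spike_times_s, track$t_s), 1),
             length(track$t_s))
  s_keep <- keep[si]
  cnt <- tabulate(cell[si[s_keep]], nbins = nb * nb)
  occ_m <- matrix(occ, nb, nb)
  cnt_m <- matrix(cnt, nb, nb)
  visited <- occ_m >= min_occ_s
  if (!any(visited)) stop("data error: zero occupancy everywhere",
                          call. = FALSE)
  raw <- matrix(NA_real_, nb, nb)
  raw[visited] <- cnt_m[visited] / occ_m[visited]
  sm <- masked_gauss_smooth(raw, visited, sigma_cm / bin_cm)
  structure(list(rate = sm, rate_raw = raw, spike_count = cnt_m,
                 occupancy_s = occ_m, visited = visited, bin_cm = bin_cm,
                 arena_cm = arena_cm, n_spikes_used = sum(cnt_m[visited])),
            class = "rate_map")
}

# 4-connected component labelling of a logical matrix (flood fill).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) &&
              q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            stack[[length(stack) + 1]] <- q
          }
        }
      }
    }
  }
  lab
}

#' Border score of a spatial rate map
#'
#' Firing fields are 4-connected regions of the smoothed map above
#' `field_frac` of the session peak with at least `field_min_bins` bins.
#' For each wall, coverage is the fraction of valid (visited) wall-edge
#' bins belonging to a firing field; the maximum coverage `c` across the
#' four walls is compared against the firing-rate-weighted mean distance
#' `d` of field bins to their nearest wall, normalized by half the arena
#' extent: `score = (c - d) / (c + d)`, ranging from -1 (central fields)
#' to 1 (fields hugging a wall).
#'
#' @param map a `rate_map`.
#' @param field_min_bins minimum field size in bins (default 9).
#' @param field_frac field threshold as a fraction of the peak (default
#'   0.3), applied to the smoothed map.
#' @return a `border_result` list: `score`, `fields` (label matrix),
#'   `wall_coverage` (per wall), `mean_dist_norm`, `undefined` flag.
#' @export
border_score <- function(map, field_min_bins = 9, field_frac = 0.3) {
  stopifnot(inherits(map, "rate_map"))
  r <- map$rate
  nb <- nrow(r)
  pk <- max(r, na.rm = TRUE)
  mask <- !is.na(r) & r >= field_frac * pk
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= field_min_bins)
  if (length(keep_ids) == 0)
    return(structure(list(score = NA_real_, fields = lab * 0L,
                          wall_coverage = rep(NA_real_, 4),
                          mean_dist_norm = NA_real_, undefined = TRUE),
                     class = "border_result"))
  field <- matrix(lab %in% keep_ids, nb, nb)
  lab[!field] <- 0L
  vis <- map$visited
  wall_cov <- c(
    left   = sum(field[, 1] & vis[, 1]) / max(sum(vis[, 1]), 1),
    right  = sum(field[, nb] & vis[, nb]) / max(sum(vis[, nb]), 1),
    bottom = sum(field[1, ] & vis[1, ]) / max(sum(vis[1, ]), 1),
    top    = sum(field[nb, ] & vis[nb, ]) / max(sum(vis[nb, ]), 1))
  cmax <- max(wall_cov)
  idx <- which(field, arr.ind = TRUE)
  dist_bins <- pmin(idx[, 1] - 1, nb - idx[, 1],
                    idx[, 2] - 1, nb - idx[, 2]) + 0.5
  dist_cm <- dist_bins * map$bin_cm
  w <- r[idx]
  dbar <- sum(w * dist_cm) / sum(w) / (map$arena_cm / 2)
  score <- (cmax - dbar) / (cmax + dbar)
  structure(list(score = score, fields = lab, wall_coverage = wall_cov,
                 mean_dist_norm = dbar, undefined = FALSE),
            class = "border_result")
}

#' Circular-shuffle significance test for spatial tuning
#'
#' The spike sequence is circularly time-shifted along the trajectory by a
#' random interval between `min_shift_s` and the session duration minus
#' `min_shift_s`, `n` times, building a null distribution of the tuning
#' score. The cell is flagged tuned if the observed score exceeds the 95th
#' percentile of the null and, when `score_floor` is given (0.5 for border
#' tuning), also exceeds that floor.
#'
#' @param track a `behavior_track`.
#' @param spike_times_s observed spike times.
#' @param score_fn function(track, spike_times) returning a scalar score.
#' @param n number of shuffles (default 200).
#' @param min_shift_s minimum circular shift (default 30 s; the session
#'   must be longer than twice this).
#' @param score_floor optional additional absolute threshold.
#' @param seed integer seed.
#' @return list with `observed`, `null` (length-n vector, NA where the
#'   score was undefined), `percentile`, `tuned`, `shifts_s`.
#' @export
shuffle_test <- function(track, spike_times_s, score_fn, n = 200,
                         min_shift_s = 30, score_floor = NULL, seed = 1) {
  duration <- max(track$t_s)
  stopifnot(duration > 2 * min_shift_s)
  observed <- score_fn(track, spike_times_s)
  shifts <- with_seed(seed,
                      stats::runif(n, min_shift_s, duration - min_shift_s))
  stopifnot(all(shifts >= min_shift_s),
            all(shifts <= duration - min_shift_s))
  null <- vapply(shifts, function(s) {
    shifted <- (spike_times_s + s) %% duration
    score_fn(track, sort(shifted))
  }, numeric(1))
  ok <- !is.na(null)
  pct <- if (is.na(observed) || !any(ok)) NA_real_
         else mean(null[ok] < observed)
  tuned <- !is.na(pct) && pct > 0.95 &&
    (is.null(score_floor) || observed > score_floor)
  list(observed = observed, null = null, percentile = pct, tuned = tuned,
       shifts_s = shifts)
}
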