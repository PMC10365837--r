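# Spot detection and frame-to-frame linking along an axon path.

# Re-join track fragments broken by crossings/occlusions: fragment B is
# appended to fragment A when B starts within `stitch_gap` frames of A's end
# and within `stitch_dist` um of A's end position extrapolated at A's recent
# velocity. Greedy, best (smallest extrapolation error) first.
stitch_fragments <- function(frag, dt, stitch_gap = 8L, stitch_dist = 1.0,
                             backward = TRUE) {
  repeat {
    n <- length(frag)
    if (n < 2L) return(frag)
    ends <- vapply(frag, function(m) m[nrow(m), 1], numeric(1))
    starts <- vapply(frag, function(m) m[1, 1], numeric(1))
    end_pos <- vapply(frag, function(m) m[nrow(m), 2], numeric(1))
    start_pos <- vapply(frag, function(m) m[1, 2], numeric(1))
    end_vel <- vapply(frag, function(m) {
      k <- min(10L, nrow(m) - 1L)
      if (k < 1L) return(0)
      tail_m <- m[(nrow(m) - k):nrow(m), , drop = FALSE]
      (tail_m[k + 1L, 2] - tail_m[1L, 2]) /
        ((tail_m[k + 1L, 1] - tail_m[1L, 1]) * dt)
    }, numeric(1))
    start_vel <- vapply(frag, function(m) {
      k <- min(10L, nrow(m) - 1L)
      if (k < 1L) return(0)
      (m[k + 1L, 2] - m[1L, 2]) / ((m[k + 1L, 1] - m[1L, 1]) * dt)
    }, numeric(1))
    best <- NULL; best_err <- Inf
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        gap <- starts[b] - ends[a]
        if (gap < 1L || gap > stitch_gap) next
        # extrapolate A forward and B backward across the gap; either end's
        # motion state may have changed during the occlusion, so take the
        # better of the two continuations, with a gap-scaled tolerance
        err_f <- abs(start_pos[b] - (end_pos[a] + end_vel[a] * gap * dt))
        err <- if (backward)
          min(err_f, abs(end_pos[a] - (start_pos[b] - start_vel[b] * gap * dt)))
        else err_f
        if (err <= stitch_dist + 0.04 * gap && err < best_err) {
          best <- c(a, b); best_err <- err
        }
      }
    }
    if (is.null(best)) return(frag)
    frag[[best[1L]]] <- rbind(frag[[best[1L]]], frag[[best[2L]]])
    frag <- frag[-best[2L]]
  }
}

# Undo identity swaps at track crossings. Wherever two tracks approach
# within `radius`, compare the velocity discontinuity of the current tail
# assignment against the swapped one and keep the smoother configuration.
repair_crossings <- function(frag, dt, radius = 0.7, window = 6L) {
  slope <- function(m, fmin, fmax) {
    r <- m[m[, 1] >= fmin & m[, 1] <= fmax, , drop = FALSE]
    if (nrow(r) < 2L) return(NA_real_)
    (r[nrow(r), 2] - r[1, 2]) / ((r[nrow(r), 1] - r[1, 1]) * dt)
  }
  for (pass in seq_len(25L)) {
    changed <- FALSE
    n <- length(frag)
    if (n < 2L) break
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        A <- frag[[a]]; B <- frag[[b]]
        common <- intersect(A[, 1], B[, 1])
        if (length(common) == 0L) next
        dist <- abs(A[match(common, A[, 1]), 2] - B[match(common, B[, 1]), 2])
        close_f <- common[dist < radius]
        if (length(close_f) == 0L) next
        # one decision per contiguous encounter
        groups <- split(close_f, cumsum(c(1, diff(close_f) > 3)))
        for (g in groups) {
          fstar <- stats::median(g)
          vA0 <- slope(A, fstar - window, fstar)
          vA1 <- slope(A, fstar, fstar + window)
          vB0 <- slope(B, fstar - window, fstar)
          vB1 <- slope(B, fstar, fstar + window)
          if (anyNA(c(vA0, vA1, vB0, vB1))) next
          cost_now <- abs(vA0 - vA1) + abs(vB0 - vB1)
          cost_swap <- abs(vA0 - vB1) + abs(vB0 - vA1)
          if (cost_swap + 0.1 < cost_now) {
            tailA <- A[, 1] > fstar
            tailB <- B[, 1] > fstar
            newA <- rbind(A[!tailA, , drop = FALSE], B[tailB, , drop = FALSE])
            newB <- rbind(B[!tailB, , drop = FALSE], A[tailA, , drop = FALSE])
            frag[[a]] <- A <- newA
            frag[[b]] <- B <- newB
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  frag
}

# DoG band-pass of one frame: gblur(sigma) - gblur(1.6 sigma).
dog_filter <- function(img, sigma, k = 1.6) {
  EBImage::gblur(img, sigma = sigma) - EBImage::gblur(img, sigma = k * sigma)
}

# Local maxima of a matrix above a threshold (8-neighbourhood, strict).
local_maxima <- function(img, threshold) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3L || nx < 3L) return(cbind(y = integer(), x = integer()))
  ok <- img > threshold
  core <- img[2:(ny - 1), 2:(nx - 1)]
  is_max <- ok[2:(ny - 1), 2:(nx - 1)] &
    core >= img[1:(ny - 2), 2:(nx - 1)] & core >= img[3:ny, 2:(nx - 1)] &
    core >= img[2:(ny - 1), 1:(nx - 2)] & core >= img[2:(ny - 1), 3:nx] &
    core >= img[1:(ny - 2), 1:(nx - 2)] & core >= img[3:ny, 3:nx] &
    core >= img[1:(ny - 2), 3:nx] & core >= img[3:ny, 1:(nx - 2)]
  w <- which(is_max, arr.ind = TRUE)
  cbind(y = w[, 1] + 1L, x = w[, 2] + 1L)
}

# Intensity-weighted 3x3 centroid refinement on the filtered image.
refine_centroid <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- max(1L, y - 1L):min(ny, y + 1L)
  xs <- max(1L, x - 1L):min(nx, x + 1L)
  w <- pmax(img[ys, xs, drop = FALSE], 0)
  if (sum(w) == 0) return(c(y = y, x = x))
  c(y = sum(ys * rowSums(w)) / sum(w), x = sum(xs * colSums(w)) / sum(w))
}

#' Detect vesicles per frame and link them into tracks along an axon
#'
#' Spots are detected on each frame as local maxima of a
#' difference-of-Gaussians response above `intensity_threshold`, refined to
#' sub-pixel centroids, and projected to arc length along the path. Linking is
#' nearest-neighbour with constant-velocity prediction, gated at
#' `max_link_step` micrometers per frame, tolerating up to `max_gap` missed
#' frames; tracks shorter than `min_track_frames` are discarded. Track
#' positions are lightly median-smoothed (3 frames) to suppress localization
#' noise before segmentation.
#'
#' @param movie Array `[y, x, frame]` with `pixel_size` / `frame_interval`
#'   attributes (defaults 0.1 um/px, 0.2 s otherwise).
#' @param path An [axon_path()].
#' @param detect_sigma DoG centre sigma, pixels (match the spot size).
#' @param intensity_threshold Minimum DoG response (photon units) for a
#'   detection; must be `> 0`.
#' @param max_link_step Maximum displacement per frame allowed when linking,
#'   micrometers; must be `> 0`.
#' @param max_gap Maximum number of consecutive missed frames inside a track.
#' @param min_track_frames Minimum number of detections to keep a track.
#'
#' @return Tibble `(track, frame, position_um)` of class `axq_tracks` with
#'   attributes `frame_interval` and `path_length_um`. May have zero rows.
#' @export
detect_and_link <- function(movie, path,
                            detect_sigma = 1.3,
                            intensity_threshold = 12,
                            max_link_step = 0.6,
                            max_gap = 2L,
                            min_track_frames = 10L,
                            stitch_gap = 10L,
                            stitch_dist = 0.45,
                            stitch_backward = TRUE,
                            repair_radius = 0.7,
                            coast_limit = 12L) {
  stopifnot(inherits(path, "axq_axon_path"))
  if (intensity_threshold <= 0 || max_link_step <= 0)
    stopf("detection/link thresholds must be > 0")
  px <- attr(movie, "pixel_size") %||% 0.1
  dt <- attr(movie, "frame_interval") %||% 0.2
  nf <- dim(movie)[3]
  rs <- resample_path(path, step = 1)

  detections <- vector("list", nf)
  for (f in seq_len(nf)) {
    resp <- dog_filter(movie[, , f], detect_sigma)
    pk <- local_maxima(resp, intensity_threshold)
    if (nrow(pk) == 0L) { detections[f] <- list(NULL); next }
    pos <- t(apply(pk, 1L, function(p) refine_centroid(resp, p[1], p[2])))
    # Project onto the path: nearest resampled point's arc length; drop
    # detections further than the extraction half-width from the path.
    d2 <- outer(pos[, "x"], rs$x, `-`)^2 + outer(pos[, "y"], rs$y, `-`)^2
    nearest <- max.col(-d2)
    keep <- sqrt(d2[cbind(seq_len(nrow(pos)), nearest)]) <=
      max(path$width / 2, 1.5)
    if (!any(keep)) { detections[f] <- list(NULL); next }
    n_k <- nearest[keep]
    # Sub-bin arc length: project the centroid offset onto the local tangent.
    ds_ref <- (pos[keep, "x"] - rs$x[n_k]) * rs$tx[n_k] +
      (pos[keep, "y"] - rs$y[n_k]) * rs$ty[n_k]
    detections[[f]] <- tibble::tibble(
      frame = f, s_um = (rs$s[n_k] + ds_ref) * px)
  }

  # --- linking ---
  # Tracks take one real detection per frame (greedy nearest-to-prediction).
  # A track left without a detection whose prediction still sits on top of
  # some detection is treated as occluded (two spots merged into one): it
  # coasts on its motion model for up to `coast_limit` frames instead of
  # dying, so crossings and co-travelling pairs do not break identities.
  merge_radius <- 0.45
  next_id <- 0L
  active <- list()  # id, pos, vel, last_frame, coast, rows = list(c(frame, pos, real))
  done <- list()
  close_track <- function(tr) {
    m <- do.call(rbind, tr$rows)
    # drop trailing coasted rows; interior ones are kept (flagged in col 3)
    # until repair/stitching is done -- they carry identity continuity but
    # are not measurements and are excluded from the returned tracks
    while (nrow(m) > 0L && m[nrow(m), 3] == 0) m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) > 0L) done[[length(done) + 1L]] <<- m
  }
  track_vel <- function(tr) if (is.na(tr$vel)) 0 else tr$vel
  update_vel <- function(tr, f, pos) {
    nlen <- length(tr$rows)
    w0 <- max(1L, nlen - 5L)
    r0 <- tr$rows[[w0]]
    if (f > r0[1]) (pos - r0[2]) / (f - r0[1]) else tr$vel
  }

  for (f in seq_len(nf)) {
    det <- detections[[f]]
    # retire stale / over-coasted tracks
    if (length(active)) {
      stale <- vapply(active, function(tr)
        f - tr$last_frame > max_gap + 1L || tr$coast > coast_limit,
        logical(1))
      for (tr in active[stale]) close_track(tr)
      active <- active[!stale]
    }
    if (is.null(det) || nrow(det) == 0L) next
    ds <- det$s_um
    assigned_det <- rep(FALSE, length(ds))
    used_tr <- rep(FALSE, length(active))
    if (length(active)) {
      pred <- vapply(active, function(tr)
        tr$pos + track_vel(tr) * (f - tr$last_frame), numeric(1))
      gapn <- vapply(active, function(tr) f - tr$last_frame, numeric(1))
      gate <- max_link_step * gapn
      cost <- abs(outer(pred, ds, `-`))
      ord <- order(cost)
      sel <- rep(NA_integer_, length(active))
      for (o in ord) {
        i <- (o - 1L) %% length(active) + 1L
        j <- (o - 1L) %/% length(active) + 1L
        if (!is.na(sel[i]) || assigned_det[j] || used_tr[i]) next
        if (cost[i, j] > gate[i]) next
        sel[i] <- j; assigned_det[j] <- TRUE
      }
      assigned_det[] <- FALSE
      assigned_det[stats::na.omit(sel)] <- TRUE
      for (i in which(!is.na(sel))) {
        j <- sel[i]
        tr <- active[[i]]
        tr$vel <- update_vel(tr, f, ds[j])
        tr$pos <- ds[j]; tr$last_frame <- f; tr$coast <- 0L
        tr$rows[[length(tr$rows) + 1L]] <- c(f, ds[j], 1)
        active[[i]] <- tr
        used_tr[i] <- TRUE; assigned_det[j] <- TRUE
      }
      # occluded tracks coast while their prediction overlaps a taken spot
      for (i in which(!used_tr)) {
        tr <- active[[i]]
        if (min(abs(ds - pred[i])) > merge_radius) next
        tr$pos <- pred[i]; tr$last_frame <- f
        tr$coast <- tr$coast + 1L
        tr$rows[[length(tr$rows) + 1L]] <- c(f, pred[i], 0)
        active[[i]] <- tr
        used_tr[i] <- TRUE
      }
    }
    for (j in which(!assigned_det)) {
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- list(
        id = next_id, pos = ds[j], vel = NA_real_, last_frame = f,
        coast = 0L, rows = list(c(f, ds[j], 1)))
    }
  }
  for (tr in active) close_track(tr)

  frag <- repair_crossings(done, dt, radius = repair_radius)
  frag <- frag[vapply(frag, nrow, integer(1)) >= 3L]
  frag <- stitch_fragments(frag, dt, stitch_gap = stitch_gap,
                           stitch_dist = stitch_dist,
                           backward = stitch_backward)

  rows <- purrr::imap_dfr(frag, function(m, id) {
    m <- m[m[, 3] == 1, , drop = FALSE]
    if (nrow(m) < min_track_frames) return(NULL)
    pos <- m[, 2]
    if (length(pos) >= 5L) pos <- stats::runmed(pos, 5L, endrule = "keep")
    tibble::tibble(track = id, frame = as.integer(m[, 1]),
                   position_um = as.numeric(pos))
  })
  if (nrow(rows) == 0L)
    rows <- tibble::tibble(track = integer(), frame = integer(),
                           position_um = numeric())
  rows <- dplyr::mutate(rows, track = match(.data$track, unique(.data$track)))
  attr(rows, "frame_interval") <- dt
  attr(rows, "path_length_um") <- path$length_px * px
  class(rows) <- c("axq_tracks", class(rows))
  rows
}
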