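#' Tracker configuration
#'
#' @param threshold_method \code{"automatic"} (Otsu) or \code{"fixed"}.
#' @param fixed_threshold Intensity threshold in [0, 255] when fixed.
#' @param polarity \code{"dark-fish"} (fish darker than background) or
#'   \code{"bright-fish"}.
#' @param min_blob_px Minimum connected-component area (px) accepted as a
#'   fish.
#' @param n_midline_points Output midline resolution (odd, >= 11).
#' @param smoothing_window Moving-average window (points) applied to the
#'   skeleton path before resampling.
#' @return A \code{track_config} list.
#' @export
track_config <- function(threshold_method = c("automatic", "fixed"),
                         fixed_threshold = 128,
                         polarity = c("dark-fish", "bright-fish"),
                         min_blob_px = 50, n_midline_points = 51,
                         smoothing_window = 5) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  stopifnot(n_midline_points >= 11, n_midline_points %% 2 == 1,
            min_blob_px >= 1)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, polarity = polarity,
                 min_blob_px = min_blob_px,
                 n_midline_points = n_midline_points,
                 smoothing_window = smoothing_window),
            class = "track_config")
}

#' Segment the fish silhouette in one frame
#'
#' Polarity-corrects the frame so the fish is bright, thresholds (Otsu or
#' fixed), keeps the largest connected component of sufficient area, and
#' fills holes.
#'
#' @param frame Integer/numeric matrix [y, x], intensities 0-255.
#' @param cfg A \code{track_config}.
#' @return Logical mask matrix of the fish.
#' @export
segment_fish <- function(frame, cfg = track_config()) {
  img <- frame / 255
  if (cfg$polarity == "dark-fish") img <- 1 - img
  thr <- if (cfg$threshold_method == "automatic") {
    EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  } else {
    t0 <- cfg$fixed_threshold / 255
    if (cfg$polarity == "dark-fish") 1 - t0 else t0
  }
  bw <- EBImage::Image(img > thr)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(lab))
  if (length(sizes) == 0 || max(sizes) < cfg$min_blob_px)
    stop("no-fish: no connected component of at least ", cfg$min_blob_px,
         " px")
  keep <- which.max(sizes)
  mask <- EBImage::fillHull(EBImage::Image(as.integer(lab) == keep,
                                           dim = dim(lab)))
  matrix(as.logical(as.matrix(mask)), nrow = nrow(frame))
}

# Zhang-Suen binary thinning. Pure-R vectorized implementation (no installed
# package provides 2-D skeletonization); operates on a padded logical
# matrix.
zhang_suen_thin <- function(mask) {
  M <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  M[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(M); nc <- ncol(M)
  sh <- function(A, dy, dx) {
    B <- matrix(FALSE, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    B[ys, xs] <- A[ys - dy, xs - dx]
    B
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- sh(M, -1, 0); p3 <- sh(M, -1, 1); p4 <- sh(M, 0, 1)
      p5 <- sh(M, 1, 1);  p6 <- sh(M, 1, 0);  p7 <- sh(M, 1, -1)
      p8 <- sh(M, 0, -1); p9 <- sh(M, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- M & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- M & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        M[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  M[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

#' Extract an (unoriented) midline from a fish mask
#'
#' Thins the mask to its morphological skeleton, prunes the skeleton to its
#' longest path (the graph diameter over 8-connected skeleton pixels,
#' weighted by Euclidean step length), smooths the path coordinates with a
#' moving average and resamples to \code{n_midline_points} equidistant
#' points.
#'
#' @param mask Logical matrix from [segment_fish()].
#' @param cfg A \code{track_config}.
#' @return A \code{midline} in pixel coordinates (x rightward, y downward),
#'   orientation arbitrary.
#' @export
extract_midline <- function(mask, cfg = track_config()) {
  skel <- zhang_suen_thin(mask)
  px <- which(skel, arr.ind = TRUE)         # [row=y, col=x]
  if (nrow(px) < 5) stop("degenerate-shape: skeleton shorter than 5 px")
  # 8-neighbour graph over skeleton pixels
  key <- px[, 1] + nrow(skel) * (px[, 2] - 1L)
  idx_of <- integer(nrow(skel) * ncol(skel))
  idx_of[key] <- seq_len(nrow(px))
  edges <- integer(0); wts <- numeric(0)
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    ny <- px[, 1] + d[1]; nx <- px[, 2] + d[2]
    ok <- ny >= 1 & ny <= nrow(skel) & nx >= 1 & nx <= ncol(skel)
    nk <- ny + nrow(skel) * (nx - 1L)
    ok[ok] <- skel[nk[ok]]
    from <- which(ok)
    to <- idx_of[nk[ok]]
    edges <- c(edges, rbind(from, to))
    wts <- c(wts, rep(sqrt(sum(d^2)), length(from)))
  }
  g <- igraph::make_graph(edges, n = nrow(px), directed = FALSE)
  igraph::E(g)$weight <- wts
  path <- igraph::get_diameter(g)
  if (length(path) < 5) stop("degenerate-shape: skeleton path shorter than 5 px")
  xy <- cbind(x = px[as.integer(path), 2], y = px[as.integer(path), 1])
  # skeleton endpoints are the noisiest pixels; drop a few before smoothing
  if (nrow(xy) > 30) xy <- xy[4:(nrow(xy) - 3), , drop = FALSE]
  w <- cfg$smoothing_window
  if (w > 1 && nrow(xy) > w) {
    xs <- smooth_ma(xy[, 1], w); ys <- smooth_ma(xy[, 2], w)
    xy <- cbind(x = xs, y = ys)
  }
  # penalized spline along arc length suppresses pixel-scale skeleton
  # jitter while keeping body-wave-scale curvature (df ~ a dozen basis
  # functions per coordinate over one body length)
  if (nrow(xy) >= 20) {
    cs <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
    keep <- c(TRUE, diff(cs) > 0)
    cs <- cs[keep]; xy <- xy[keep, , drop = FALSE]
    df <- min(12, max(4, floor(nrow(xy) / 4)))
    xs <- stats::smooth.spline(cs, xy[, 1], df = df)
    ys <- stats::smooth.spline(cs, xy[, 2], df = df)
    s_out <- seq(0, max(cs), length.out = 4 * cfg$n_midline_points)
    xy <- cbind(x = stats::predict(xs, s_out)$y,
                y = stats::predict(ys, s_out)$y)
  }
  xy <- extend_to_boundary(xy, mask)
  # refit over the joined path so the extension joins without a tangent
  # kink (equal-arc resampling then yields equal chords)
  if (nrow(xy) >= 20) {
    cs <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
    keep <- c(TRUE, diff(cs) > 0)
    cs <- cs[keep]; xy <- xy[keep, , drop = FALSE]
    df2 <- min(14, max(4, floor(nrow(xy) / 4)))
    xs2 <- stats::smooth.spline(cs, xy[, 1], df = df2)
    ys2 <- stats::smooth.spline(cs, xy[, 2], df = df2)
    s_out <- seq(0, max(cs), length.out = 4 * cfg$n_midline_points)
    xy <- cbind(x = stats::predict(xs2, s_out)$y,
                y = stats::predict(ys2, s_out)$y)
  }
  resample_midline(xy, cfg$n_midline_points)
}

# The medial axis of a tapered silhouette stops short of the snout and tail
# tips; extend the midline from both ends along the end tangents until it
# leaves the mask. The extension is capped near the local mask half-width
# (the medial-axis inset at a blunt end), so a wide head cannot grow a long
# wandering extension.
extend_to_boundary <- function(xy, mask, step = 0.5) {
  inside <- function(pt) {
    y <- round(pt[2]); x <- round(pt[1])
    y >= 1 && y <= nrow(mask) && x >= 1 && x <= ncol(mask) && mask[y, x]
  }
  dmm <- as.matrix(EBImage::distmap(EBImage::Image(mask)))
  local_w <- function(pt) {
    y <- min(max(1, round(pt[2])), nrow(dmm))
    x <- min(max(1, round(pt[1])), ncol(dmm))
    dmm[y, x]
  }
  n <- nrow(xy)
  k <- max(5, round(0.05 * n))
  ext_one <- function(end_pt, tangent) {
    tn <- sqrt(sum(tangent^2))
    if (tn == 0) return(NULL)
    tangent <- tangent / tn
    cap <- 2 * local_w(end_pt) + 2 * step
    pts <- NULL
    for (i in seq_len(max(1, ceiling(cap / step)))) {
      cand <- end_pt + i * step * tangent
      if (!inside(cand)) break
      pts <- rbind(pts, cand)
    }
    pts
  }
  head_ext <- ext_one(xy[1, ], xy[1, ] - xy[k, ])
  tail_ext <- ext_one(xy[n, ], xy[n, ] - xy[n - k + 1, ])
  out <- xy
  if (!is.null(head_ext)) out <- rbind(head_ext[rev(seq_len(nrow(head_ext))), ,
                                                drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  out
}

#' Orient midlines head-first using the motion direction
#'
#' The head is the endpoint whose displacement best aligns with the centroid
#' velocity over a sliding window; when the fish is too slow to vote, the
#' orientation is carried forward from the previous frame (flagged). A
#' majority filter enforces temporal consistency so single frames never
#' flip.
#'
#' @param midlines List of \code{midline} (unoriented), one per frame.
#' @param traj A \code{trajectory} (centroid path) with matching frames.
#' @param fps Frame rate.
#' @param window Sliding window (frames) for the velocity vote; defaults to
#'   half a second of frames.
#' @param speed_threshold Minimum centroid speed for a motion vote, in
#'   body lengths per second (arc length of the midline); below it the
#'   width fallback decides. Default 0.5 BL/s.
#' @param widths Optional per-frame two-element vector list
#'   \code{c(width_at_end1, width_at_end2)} used as fallback: the wider end
#'   is the head.
#' @return List: \code{seq} (head-first \code{midline_seq}, px units,
#'   scale NA), \code{flipped} (logical, frames stored reversed),
#'   \code{flagged} (frames with no direct motion vote).
#' @export
orient_head <- function(midlines, traj, fps, window = NULL,
                        speed_threshold = 0.5, widths = NULL) {
  nt <- length(midlines)
  stopifnot(nt >= 3, nrow(traj) == nt)
  n <- nrow(midlines[[1]])
  if (is.null(window)) window <- max(5, round(fps))
  # the skeleton path direction is arbitrary per frame: first make
  # consecutive frames point the same way, so votes are comparable and the
  # widths fallback tracks the canonical direction
  for (i in 2:nt) {
    a <- midlines[[i - 1]]; b <- midlines[[i]]
    same <- sum((b[1, ] - a[1, ])^2) + sum((b[n, ] - a[n, ])^2)
    crossed <- sum((b[1, ] - a[n, ])^2) + sum((b[n, ] - a[1, ])^2)
    if (crossed < same) {
      midlines[[i]] <- b[n:1, ]
      if (!is.null(widths)) widths[[i]] <- rev(widths[[i]])
    }
  }
  bl <- stats::median(vapply(midlines, arc_length, numeric(1)))
  vx <- c(0, diff(traj$x)) * fps
  vy <- c(0, diff(traj$y)) * fps
  vx <- smooth_ma(vx, window); vy <- smooth_ma(vy, window)
  speed <- sqrt(vx^2 + vy^2) / bl        # body lengths per second
  vote <- integer(nt)           # +1 keep, -1 flip, 0 abstain
  for (i in seq_len(nt)) {
    m <- midlines[[i]]
    cen <- colMeans(m)
    e1 <- m[1, ] - cen; e2 <- m[n, ] - cen
    if (speed[i] >= speed_threshold) {
      a1 <- e1[1] * vx[i] + e1[2] * vy[i]
      a2 <- e2[1] * vx[i] + e2[2] * vy[i]
      vote[i] <- if (a1 >= a2) 1L else -1L
    } else if (!is.null(widths)) {
      w <- widths[[i]]
      if (abs(w[1] - w[2]) > 1e-9) vote[i] <- if (w[1] > w[2]) 1L else -1L
    }
  }
  flagged <- vote == 0L
  # carry forward, then majority-smooth to suppress single-frame flips
  dir <- vote
  last <- if (any(vote != 0)) vote[which(vote != 0)[1]] else 1L
  for (i in seq_len(nt)) {
    if (dir[i] == 0L) dir[i] <- last else last <- dir[i]
  }
  half <- floor(window / 2)
  dir_s <- dir
  for (i in seq_len(nt)) {
    lo <- max(1, i - half); hi <- min(nt, i + half)
    dir_s[i] <- if (sum(dir[lo:hi]) >= 0) 1L else -1L
  }
  oriented <- lapply(seq_len(nt), function(i) {
    if (dir_s[i] == 1L) midlines[[i]] else midlines[[i]][n:1, ]
  })
  list(seq = midline_seq(oriented, fps = fps, units = "px",
                         scale_px_per_mm = NA_real_),
       flipped = dir_s == -1L, flagged = flagged)
}

#' Track a frame stack into midlines, trajectory and QC table
#'
#' Composes [segment_fish()], [extract_midline()] and [orient_head()] over a
#' stack of frames. The trajectory is the mask centroid per frame. Frames
#' whose segmentation or midline extraction fails are flagged in the QC
#' table and interpolated from neighbours; if more than
#' \code{max_fail_frac} of the frames fail, tracking aborts with a QC
#' report in the error.
#'
#' @param frames List of frame matrices, or a \code{frame_stack}.
#' @param cfg A \code{track_config}.
#' @param fps Frame rate (taken from the stack when available).
#' @param scale_px_per_mm Optional pixel scale; when given, outputs are
#'   converted to mm.
#' @param max_fail_frac Abort threshold for failed frames.
#' @return List: \code{seq} (head-first \code{midline_seq}),
#'   \code{trajectory}, \code{qc} (data.frame frame, ok, note).
#' @export
track_stack <- function(frames, cfg = track_config(), fps = NULL,
                        scale_px_per_mm = NULL, max_fail_frac = 0.2) {
  if (inherits(frames, "frame_stack")) {
    if (is.null(fps)) fps <- frames$fps
    if (is.null(scale_px_per_mm)) scale_px_per_mm <- frames$px_per_mm
    frames <- frames$frames
  }
  if (is.null(fps)) stop("fps required")
  nt <- length(frames)
  mids <- vector("list", nt)
  cx <- cy <- rep(NA_real_, nt)
  note <- character(nt)
  widths <- vector("list", nt)
  for (i in seq_len(nt)) {
    res <- tryCatch({
      mask <- segment_fish(frames[[i]], cfg)
      ml <- extract_midline(mask, cfg)
      cen <- which(mask, arr.ind = TRUE)
      list(ml = ml, cx = mean(cen[, 2]), cy = mean(cen[, 1]),
           w = endpoint_widths(mask, ml))
    }, error = function(e) conditionMessage(e))
    if (is.list(res)) {
      mids[[i]] <- res$ml; cx[i] <- res$cx; cy[i] <- res$cy
      widths[[i]] <- res$w
    } else {
      note[i] <- res
    }
  }
  failed <- which(is.na(cx))
  if (length(failed) / nt > max_fail_frac) {
    stop("tracking aborted: ", length(failed), "/", nt, " frames failed (",
         paste(utils::head(unique(note[failed]), 3), collapse = "; "), ")")
  }
  # interpolate failed frames from neighbours
  if (length(failed) > 0) {
    okf <- which(!is.na(cx))
    cx[failed] <- stats::approx(okf, cx[okf], xout = failed, rule = 2)$y
    cy[failed] <- stats::approx(okf, cy[okf], xout = failed, rule = 2)$y
    for (i in failed) {
      nb <- okf[which.min(abs(okf - i))]
      mids[[i]] <- mids[[nb]]
      widths[[i]] <- widths[[nb]]
    }
  }
  traj_px <- trajectory((seq_len(nt) - 1) / fps, cx, cy, fps)
  ori <- orient_head(mids, traj_px, fps, widths = widths)
  seq <- ori$seq
  seq$scale_px_per_mm <- scale_px_per_mm
  traj <- traj_px
  if (!is.null(scale_px_per_mm) && is.finite(scale_px_per_mm)) {
    seq <- midline_seq_to_mm(seq)
    traj <- trajectory(traj_px$times_s, cx / scale_px_per_mm,
                       cy / scale_px_per_mm, fps)
  }
  qc <- data.frame(frame = seq_len(nt), ok = !(seq_len(nt) %in% failed),
                   flagged_orientation = ori$flagged, note = note)
  list(seq = seq, trajectory = traj, qc = qc)
}

# Mask width near each midline endpoint (distance transform value), used as
# a head/tail fallback when the fish is stationary.
endpoint_widths <- function(mask, ml) {
  dm <- EBImage::distmap(EBImage::Image(mask))
  dmm <- as.matrix(dm)
  grab <- function(pt) {
    y <- min(max(1, round(pt[2])), nrow(dmm))
    x <- min(max(1, round(pt[1])), ncol(dmm))
    dmm[y, x]
  }
  n <- nrow(ml)
  # average over the inner 5-20% band of each end for a stable estimate
  i1 <- max(1, round(n * 0.05)):max(1, round(n * 0.2))
  i2 <- min(n, round(n * 0.8)):min(n, round(n * 0.95))
  c(mean(apply(ml[i1, , drop = FALSE], 1, grab)),
    mean(apply(ml[i2, , drop = FALSE], 1, grab)))
}
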