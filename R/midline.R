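#' Construct a midline
#'
#' An ordered head-first 2-D polyline describing the body axis in a single
#' frame. Consecutive points must be distinct so arc length is positive.
#'
#' @param points Two-column matrix (x, y) of ordered coordinates, head first.
#' @return Matrix of class \code{midline}.
#' @export
midline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2, all(is.finite(points)))
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0))
    stop("invalid-midline: consecutive points must be strictly distinct")
  colnames(points) <- c("x", "y")
  structure(points, class = c("midline", "matrix"))
}

#' Arc length of a midline
#' @param m A \code{midline} or plain two-column matrix.
#' @return Total polyline length.
#' @export
arc_length <- function(m) sum(sqrt(rowSums(diff(unclass(as.matrix(m)))^2)))

#' Resample a midline to equidistant arc-length spacing
#'
#' Linear interpolation along the polyline; the output has \code{n} points
#' whose consecutive spacings agree to within 1e-6 relative tolerance.
#'
#' @param m A \code{midline} or two-column matrix.
#' @param n Number of output points (>= 2).
#' @return A \code{midline} with \code{n} points.
#' @export
resample_midline <- function(m, n) {
  pts <- unclass(as.matrix(m))
  stopifnot(n >= 2)
  # two passes of parametric spline re-parameterization: the dense pass
  # recovers arc length of the smooth curve, the final pass places points
  # at equidistant arc length so consecutive spacings match to ~1e-6
  interp <- if (nrow(pts) >= 4) {
    function(cs, v, out) stats::spline(cs, v, xout = out)$y
  } else {
    function(cs, v, out) stats::approx(cs, v, xout = out)$y
  }
  for (n_out in c(50L * n, n)) {
    cs <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    keep <- c(TRUE, diff(cs) > 0)       # drop coincident vertices
    pts <- pts[keep, , drop = FALSE]
    cs <- cs[keep]
    target <- seq(0, cs[length(cs)], length.out = n_out)
    pts <- cbind(interp(cs, pts[, 1], target),
                 interp(cs, pts[, 2], target))
  }
  colnames(pts) <- c("x", "y")
  midline(pts)
}

#' Construct a midline sequence
#'
#' The common currency between the wave model, the renderer and the tracker:
#' one midline per frame, all with the same point count, at a fixed frame
#' rate. Coordinates are in mm, or in px with a px-per-mm scale.
#'
#' @param midlines List of midlines (or two-column matrices), one per frame.
#' @param fps Frame rate (> 0).
#' @param units \code{"mm"} or \code{"px"}.
#' @param scale_px_per_mm Pixel scale, required when \code{units = "px"}.
#' @return A \code{midline_seq} object.
#' @export
midline_seq <- function(midlines, fps, units = c("mm", "px"),
                        scale_px_per_mm = NULL) {
  units <- match.arg(units)
  stopifnot(fps > 0, length(midlines) >= 1)
  midlines <- lapply(midlines, function(m) unclass(as.matrix(m)))
  np <- vapply(midlines, nrow, integer(1))
  if (length(unique(np)) != 1)
    stop("all frames must have the same point count")
  if (units == "px" && is.null(scale_px_per_mm))
    stop("scale_px_per_mm required when units = 'px'")
  structure(list(midlines = midlines, fps = fps, units = units,
                 scale_px_per_mm = scale_px_per_mm),
            class = "midline_seq")
}

#' @export
print.midline_seq <- function(x, ...) {
  cat(sprintf("Midline sequence: %d frames x %d points, %.1f fps [%s]\n",
              length(x$midlines), nrow(x$midlines[[1]]), x$fps, x$units))
  invisible(x)
}

#' Convert a pixel-space midline sequence to mm
#' @param seq A \code{midline_seq} with \code{units = "px"}.
#' @return The sequence rescaled to mm.
#' @export
midline_seq_to_mm <- function(seq) {
  stopifnot(inherits(seq, "midline_seq"))
  if (seq$units == "mm") return(seq)
  s <- seq$scale_px_per_mm
  midline_seq(lapply(seq$midlines, function(m) m / s), fps = seq$fps,
              units = "mm")
}

#' Write / read a midline sequence as long-format CSV
#'
#' Columns \code{frame, point_idx, x, y}; frame rate, units and scale travel
#' in a JSON sidecar next to the CSV (\code{<path>.meta.json}).
#'
#' @param seq A \code{midline_seq}.
#' @param path CSV path.
#' @return \code{write_midline_seq}: the path, invisibly.
#'   \code{read_midline_seq}: the reconstructed \code{midline_seq}.
#' @export
write_midline_seq <- function(seq, path) {
  stopifnot(inherits(seq, "midline_seq"))
  np <- nrow(seq$midlines[[1]])
  df <- data.frame(
    frame = rep(seq_along(seq$midlines), each = np),
    point_idx = rep(seq_len(np), length(seq$midlines)),
    x = unlist(lapply(seq$midlines, function(m) m[, 1])),
    y = unlist(lapply(seq$midlines, function(m) m[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fps = seq$fps, units = seq$units,
               scale_px_per_mm = seq$scale_px_per_mm)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_midline_seq
#' @export
read_midline_seq <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  frames <- split(df[, c("x", "y")], df$frame)
  midline_seq(lapply(frames, as.matrix), fps = meta$fps, units = meta$units,
              scale_px_per_mm = meta$scale_px_per_mm)
}

#' Write / read a bending field as long-format CSV
#'
#' Columns \code{frame, s_frac, theta}; sample times reconstructed from the
#' sidecar frame rate.
#'
#' @param field A \code{bending_field}.
#' @param path CSV path.
#' @export
write_bending_field <- function(field, path) {
  stopifnot(inherits(field, "bending_field"))
  ns <- length(field$s_frac)
  df <- data.frame(frame = rep(seq_along(field$times_s), each = ns),
                   s_frac = rep(field$s_frac, length(field$times_s)),
                   theta = as.vector(t(field$theta)))
  utils::write.csv(df, path, row.names = FALSE)
  fps <- if (length(field$times_s) > 1) 1 / mean(diff(field$times_s)) else 1
  jsonlite::write_json(list(fps = fps, t0 = field$times_s[1]),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bending_field
#' @export
read_bending_field <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  s_frac <- sort(unique(df$s_frac))
  nt <- length(unique(df$frame))
  theta <- matrix(df$theta[order(df$frame, df$s_frac)], nrow = nt,
                  byrow = TRUE)
  times <- meta$t0 + (seq_len(nt) - 1) / meta$fps
  bending_field(theta, times, s_frac)
}
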