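#' Detect axon cross-sections in a micrograph ROI
#'
#' Thresholds the image, restricts to the region of interest, labels
#' connected components, discards specks below \code{min_area_px}, and
#' reports each axon's centroid and equivalent diameter
#' \eqn{2\sqrt{area/\pi}}. Intensity scaling above the threshold does not
#' change the result.
#'
#' @param image Numeric matrix [y, x] with intensities in [0, 1] (or any
#'   range when \code{threshold = "otsu"}).
#' @param roi_polygon Two-column matrix of ROI vertices (px).
#' @param threshold Numeric cut-off, or \code{"otsu"} for automatic.
#' @param min_area_px Minimum component area in px (default 5).
#' @param um_per_px Micron scale; diameters are also reported in um.
#' @return data.frame: \code{x}, \code{y} (centroid px), \code{area_px},
#'   \code{diameter_px}, \code{diameter_um}.
#' @export
detect_axons <- function(image, roi_polygon, threshold = "otsu",
                         min_area_px = 5, um_per_px = 1) {
  stopifnot(is.matrix(image), nrow(roi_polygon) >= 3)
  H <- nrow(image); W <- ncol(image)
  xg <- rep(seq_len(W), each = H)
  yg <- rep(seq_len(H), W)
  roi <- matrix(point_in_polygon(xg, yg, roi_polygon), H, W)
  if (!any(roi)) stop("empty ROI")
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(image)
    EBImage::otsu(EBImage::Image((image - rng[1]) / diff(rng)),
                  range = c(0, 1)) * diff(rng) + rng[1]
  } else threshold
  bw <- image > thr & roi
  if (!any(bw)) {
    return(data.frame(x = numeric(0), y = numeric(0), area_px = numeric(0),
                      diameter_px = numeric(0), diameter_um = numeric(0)))
  }
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bw)))
  areas <- tabulate(lab)
  keep <- which(areas >= min_area_px)
  out <- lapply(keep, function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    data.frame(x = mean(pix[, 2]), y = mean(pix[, 1]),
               area_px = nrow(pix))
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), area_px = numeric(0))
  out$diameter_px <- 2 * sqrt(out$area_px / pi)
  out$diameter_um <- out$diameter_px * um_per_px
  out[order(out$y, out$x), , drop = FALSE]
}

#' Blind sample identifiers for unbiased quantification
#'
#' Replaces sample identifiers with opaque sequential codes in a seeded
#' random order, so the operator scoring the images cannot infer genotype.
#' The inverse mapping is returned separately ("sealed") for unblinding
#' after quantification.
#'
#' @param sample_ids Unique character identifiers.
#' @param seed Integer seed (same seed, same mapping).
#' @param prefix Code prefix.
#' @return List: \code{map} (named vector id -> code) and \code{key}
#'   (named vector code -> id).
#' @export
blind_labels <- function(sample_ids, seed = 1, prefix = "S") {
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  set.seed(seed)
  codes <- sprintf("%s%03d", prefix, seq_along(sample_ids))
  perm <- sample(length(sample_ids))
  map <- stats::setNames(codes[perm], sample_ids)
  key <- stats::setNames(names(map), map)
  list(map = map, key = key)
}

#' Unblind coded identifiers
#'
#' @param codes Character codes produced by [blind_labels()].
#' @param key The sealed inverse mapping.
#' @return Original identifiers.
#' @export
unblind <- function(codes, key) {
  out <- unname(key[codes])
  if (any(is.na(out))) stop("unknown code(s): ",
                            paste(codes[is.na(out)], collapse = ", "))
  out
}

#' Summarize axon detections per group with permutation tests
#'
#' Per sample, the axon count and median diameter; per group, their
#' distributions; between two groups, Fisher permutation p-values
#' (difference of medians across samples) for count and diameter,
#' Benjamini-Hochberg corrected. Samples with no detections are flagged and
#' excluded with a log entry in the result.
#'
#' @param detections Named list of detection data.frames (one per sample,
#'   from [detect_axons()]).
#' @param groups Named group label per sample (same names as
#'   \code{detections}).
#' @param n_resamples,seed Permutation settings.
#' @return List: \code{per_sample} (data.frame sample, group, n_axons,
#'   median_diameter_um), \code{per_group} summary, \code{tests}
#'   (data.frame measure, p_value, p_adjusted; NULL for a single group),
#'   \code{excluded} (character).
#' @export
axon_summary <- function(detections, groups, n_resamples = 10000, seed = 1) {
  stopifnot(!is.null(names(detections)),
            all(names(detections) %in% names(groups)))
  n_ax <- vapply(detections, nrow, integer(1))
  excluded <- names(detections)[n_ax == 0]
  keep <- names(detections)[n_ax > 0]
  if (length(excluded))
    message("excluding sample(s) with no detections: ",
            paste(excluded, collapse = ", "))
  per_sample <- data.frame(
    sample = keep,
    group = unname(groups[keep]),
    n_axons = vapply(detections[keep], nrow, integer(1)),
    median_diameter_um = vapply(detections[keep], function(d)
      stats::median(d$diameter_um), numeric(1)),
    row.names = NULL)
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                     function(g) data.frame(
    group = g$group[1], n_samples = nrow(g),
    median_count = stats::median(g$n_axons),
    median_diameter_um = stats::median(g$median_diameter_um))))
  rownames(per_group) <- NULL
  tests <- NULL
  glev <- unique(per_sample$group)
  if (length(glev) == 2) {
    split_on <- function(col) {
      list(x = per_sample[[col]][per_sample$group == glev[1]],
           y = per_sample[[col]][per_sample$group == glev[2]])
    }
    cnt <- split_on("n_axons")
    dia <- split_on("median_diameter_um")
    p_cnt <- permutation_test(cnt$x, cnt$y, n_resamples = n_resamples,
                              seed = seed)$p_value
    p_dia <- permutation_test(dia$x, dia$y, n_resamples = n_resamples,
                              seed = seed + 1)$p_value
    tests <- data.frame(measure = c("count", "diameter"),
                        p_value = c(p_cnt, p_dia),
                        p_adjusted = bh_fdr(c(p_cnt, p_dia)))
  }
  list(per_sample = per_sample, per_group = per_group, tests = tests,
       excluded = excluded)
}
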