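#' Segmentation configuration
#'
#' @param threshold_method `"otsu"` (default; parameter-free threshold on the
#'   pooled intensity histogram of the stack) or `"fixed"`.
#' @param fixed_threshold Intensity threshold in \[0, 1\]; required if and
#'   only if `threshold_method = "fixed"`.
#' @param min_component_px Minimum connected-component size in px; smaller
#'   bright blobs are treated as noise speckles (default 20).
#' @param smoothing_radius_px Gaussian smoothing radius applied to each
#'   frame before thresholding (default 0 = none).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_component_px = 20L,
                                smoothing_radius_px = 0) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold)) {
      phono_abort("`fixed_threshold` is required when threshold_method = \"fixed\".",
                  class = "phonolab_error_validation", field = "fixed_threshold")
    }
    check_number(fixed_threshold, "fixed_threshold", min = 0, max = 1)
  } else if (!is.null(fixed_threshold)) {
    phono_abort("`fixed_threshold` must be NULL unless threshold_method = \"fixed\".",
                class = "phonolab_error_validation", field = "fixed_threshold")
  }
  min_component_px <- check_count(min_component_px, "min_component_px", min = 0L)
  check_number(smoothing_radius_px, "smoothing_radius_px", min = 0)
  structure(
    list(threshold_method = threshold_method, fixed_threshold = fixed_threshold,
         min_component_px = min_component_px, smoothing_radius_px = smoothing_radius_px),
    class = "segmentation_config"
  )
}

#' Segment a frame stack into a glottal area waveform
#'
#' Per frame: optional Gaussian smoothing, intensity thresholding (Otsu on
#' the pooled stack histogram by default), and selection of the largest
#' bright connected component above `min_component_px` as the glottal gap
#' (an empty frame yields zero areas). The glottal midline direction is the
#' first principal axis of the gap pixel coordinates pooled over the whole
#' stack, anchored at the line connecting the two glottal commissures (the
#' pooled extreme tips along that axis); pooling keeps the left/right
#' assignment stable even when the gap nearly closes, and the commissure
#' anchor keeps the split anatomically centred when the two folds
#' oscillate asymmetrically. Hemiglottal areas are the pixel counts on each
#' side of the midline (pixels on the midline are split evenly) and the
#' glottal length is the extent of the component along the midline.
#'
#' @param frames Numeric array `c(height, width, n_frames)` (a single matrix
#'   is treated as one frame), intensities in \[0, 1\].
#' @param config A [segmentation_config()].
#' @param fs_video Frame rate used to build the time axis (default 4000).
#' @return A `gaw_df` tibble (`t`, `area_total`, `area_left`, `area_right`,
#'   `length`).
#' @export
segment_frames <- function(frames, config = segmentation_config(), fs_video = 4000) {
  stopifnot(inherits(config, "segmentation_config"))
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L || any(dim(frames) == 0L)) {
    phono_abort("`frames` must be a non-empty height x width x n array of frames.",
                class = "phonolab_error_format")
  }
  h <- dim(frames)[1]; w <- dim(frames)[2]; nf <- dim(frames)[3]
  frames[] <- pmin(1, pmax(0, frames))
  if (config$smoothing_radius_px > 0) {
    for (i in seq_len(nf)) {
      frames[, , i] <- as.array(EBImage::gblur(
        EBImage::Image(frames[, , i]), sigma = config$smoothing_radius_px
      ))
    }
  }
  thr <- if (config$threshold_method == "otsu") {
    # pooled histogram over the whole stack keeps closed frames consistent
    EBImage::otsu(EBImage::Image(array(frames, dim = c(h, w * nf))))
  } else {
    config$fixed_threshold
  }
  empty <- tibble(
    t = (seq_len(nf) - 1L) / fs_video,
    area_total = 0, area_left = 0, area_right = 0, length = 0
  )
  # a glottal gap occupies a small part of the frame; when thresholding
  # lights up a large share of all pixels the "foreground" is just texture
  # noise (e.g. an all-background stack)
  if (mean(frames > thr) > 0.25) {
    rlang::warn("Thresholding selects a large share of all pixels; the stack appears to contain no glottal gap.",
                class = "phonolab_warning_empty_stack")
    return(new_gaw(empty, fs = fs_video))
  }

  pix <- vector("list", nf)
  for (i in seq_len(nf)) {
    mask <- frames[, , i] > thr
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(mask))
    lab <- as.array(lab)
    sizes <- tabulate(lab[lab > 0])
    best <- which.max(sizes)
    if (sizes[best] < max(1L, config$min_component_px)) next
    pix[[i]] <- which(lab == best, arr.ind = TRUE)
  }

  n_gap <- sum(!vapply(pix, is.null, logical(1)))
  if (n_gap == 0L) {
    rlang::warn("No glottal gap found in any frame; returning an all-zero waveform.",
                class = "phonolab_warning_empty_stack")
    return(new_gaw(empty, fs = fs_video))
  }
  pooled <- do.call(rbind, pix[!vapply(pix, is.null, logical(1))])
  if (nrow(pooled) / (as.numeric(h) * w * nf) > 0.5) {
    rlang::warn("Thresholding selected more than half of all pixels; treating the stack as gap-free.",
                class = "phonolab_warning_empty_stack")
    return(new_gaw(empty, fs = fs_video))
  }
  ctr <- colMeans(pooled)
  ev <- eigen(stats::cov(pooled), symmetric = TRUE)
  axis1 <- ev$vectors[, 1]                       # midline direction
  axis2 <- ev$vectors[, 2]                       # lateral direction
  # deterministic orientation so left/right labels never flip across frames
  if (axis2[2] < 0 || (axis2[2] == 0 && axis2[1] < 0)) axis2 <- -axis2
  # anchor the midline at the glottal commissures (the extreme tips along
  # the long axis, where the folds meet) rather than at the pixel centroid,
  # which shifts toward the stronger fold when the oscillation is asymmetric
  d1_all <- (pooled[, 1] - ctr[1]) * axis1[1] + (pooled[, 2] - ctr[2]) * axis1[2]
  q <- stats::quantile(d1_all, c(0.005, 0.995), names = FALSE)
  tip_lo <- colMeans(pooled[d1_all <= q[1], , drop = FALSE])
  tip_hi <- colMeans(pooled[d1_all >= q[2], , drop = FALSE])
  anchor <- (tip_lo + tip_hi) / 2
  tip_axis <- tip_hi - tip_lo
  tip_len <- sqrt(sum(tip_axis^2))
  if (tip_len > 0) {
    axis1 <- tip_axis / tip_len
    axis2 <- c(-axis1[2], axis1[1])
    if (axis2[2] < 0 || (axis2[2] == 0 && axis2[1] < 0)) axis2 <- -axis2
  }

  out <- empty
  for (i in seq_len(nf)) {
    p <- pix[[i]]
    if (is.null(p)) next
    d1 <- (p[, 1] - anchor[1]) * axis1[1] + (p[, 2] - anchor[2]) * axis1[2]
    d2 <- (p[, 1] - anchor[1]) * axis2[1] + (p[, 2] - anchor[2]) * axis2[2]
    n_left <- sum(d2 < 0) + sum(d2 == 0) / 2
    out$area_total[i] <- nrow(p)
    out$area_left[i] <- n_left
    out$area_right[i] <- nrow(p) - n_left
    out$length[i] <- diff(range(d1)) + 1
  }
  new_gaw(out, fs = fs_video)
}
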