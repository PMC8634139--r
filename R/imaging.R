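#' Circular pixel masks for recruitment regions
#'
#' `disc_mask` marks pixels within `radius` of the centre; `annulus_mask`
#' marks a surrounding ring. The default "nearby region" used for
#' recruitment scoring is an annulus of equal continuous area as the disc
#' (outer radius = radius * sqrt(2)).
#'
#' @param dim Image dimensions c(rows, cols).
#' @param center c(row, col) of the region centre.
#' @param radius Disc radius in pixels.
#' @param outer Outer radius of the annulus.
#' @return Logical matrix mask.
#' @export
disc_mask <- function(dim, center, radius) {
  r <- row(matrix(0, dim[1], dim[2])) - center[1]
  c <- col(matrix(0, dim[1], dim[2])) - center[2]
  r^2 + c^2 <= radius^2
}

#' @rdname disc_mask
#' @export
annulus_mask <- function(dim, center, radius, outer = radius * sqrt(2)) {
  r <- row(matrix(0, dim[1], dim[2])) - center[1]
  c <- col(matrix(0, dim[1], dim[2])) - center[2]
  d2 <- r^2 + c^2
  d2 > radius^2 & d2 <= outer^2
}

#' Recruitment score of one frame
#'
#' Recruitment is the difference between the average intensity in the
#' recruitment region and in a nearby region, multiplied by the total area
#' of recruitment: (mean(in) - mean(near)) * |in|.
#'
#' @param frame Numeric matrix.
#' @param in_region,near_region Disjoint, non-empty logical masks.
#' @return Scalar score (intensity x pixel units).
#' @export
recruit_score <- function(frame, in_region, near_region) {
  stopifnot(any(in_region), any(near_region), !any(in_region & near_region))
  (mean(frame[in_region]) - mean(frame[near_region])) * sum(in_region)
}

#' Recruitment kinetics from a time-lapse stack
#'
#' Quantifies micro-irradiation spot recruitment over time. Each frame is
#' smoothed with a 5x5 Gaussian blur to limit the impact of noise; the spot
#' centre is re-estimated per frame by an intensity-weighted centroid within
#' a search radius of the previous position (a light-weight stand-in for a
#' full spot tracker). When the tracked spot is lost (no excess intensity in
#' the search window), the trace falls back to the static initial ROI and is
#' flagged. Scores are reported raw, baseline-subtracted (pre-irradiation
#' frame maps to 0) and as fold over the pre-irradiation frame.
#'
#' @param stack T x H x W numeric array (or T x Z x H x W; Z is
#'   max-projected first).
#' @param center Initial spot centre c(row, col).
#' @param radius Spot ROI radius (pixels).
#' @param search_radius Tracking search radius (default 2 * radius).
#' @param pre_frames Number of leading pre-irradiation frames (default 1);
#'   their mean score is the baseline.
#' @param blur Apply the 5x5 Gaussian blur (default TRUE).
#' @param blur_sigma Gaussian sigma in pixels (default 1).
#' @param static Force static-ROI mode (no tracking).
#' @return Data frame (class `recruitment_trace`): frame, score,
#'   score_baseline_sub, fold_over_pre, center_row, center_col, tracked.
#' @export
recruitment_trace <- function(stack, center, radius, search_radius = 2 * radius,
                              pre_frames = 1L, blur = TRUE, blur_sigma = 1,
                              static = FALSE) {
  if (length(dim(stack)) == 4) stack <- apply(stack, c(1, 3, 4), max)
  stopifnot(length(dim(stack)) == 3)
  nt <- dim(stack)[1]
  dm <- dim(stack)[2:3]
  kern <- EBImage::makeBrush(5, shape = "gaussian", sigma = blur_sigma)
  cur <- center
  tracked_all <- TRUE
  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- stack[t, , ]
    if (blur) fr <- EBImage::filter2(fr, kern, boundary = "replicate")
    tracked <- FALSE
    if (!static && t > pre_frames) {
      win <- disc_mask(dm, cur, search_radius)
      excess <- pmax(fr - stats::median(fr), 0) * win
      w <- sum(excess)
      if (w > 0 && max(fr[win]) > stats::median(fr) + 3 * stats::mad(fr)) {
        ri <- row(fr); ci <- col(fr)
        cur <- c(sum(ri * excess) / w, sum(ci * excess) / w)
        tracked <- TRUE
      }
    }
    if (!tracked) {
      cur <- center  # static-ROI fallback (pre-irradiation frames always)
      if (t > pre_frames) tracked_all <- FALSE
    }
    inm <- disc_mask(dm, cur, radius)
    nearm <- annulus_mask(dm, cur, radius) & !inm
    rows[[t]] <- data.frame(frame = t,
                            score = recruit_score(fr, inm, nearm),
                            center_row = cur[1], center_col = cur[2],
                            tracked = tracked)
  }
  out <- do.call(rbind, rows)
  base <- mean(out$score[seq_len(min(pre_frames, nt))])
  out$score_baseline_sub <- out$score - base
  out$fold_over_pre <- if (abs(base) > .Machine$double.eps) out$score / base
                       else NA_real_
  attr(out, "static_fallback") <- !tracked_all || static
  class(out) <- c("recruitment_trace", class(out))
  out
}

#' Laser-track signal over nuclear background
#'
#' Per nucleus, subtracts the background nuclear intensity outside the
#' segmented irradiation tracks from the mean intensity within the tracks:
#' mean(image[track & nucleus]) - mean(image[nucleus & !track]). Optionally
#' only positive values are reported (negative set to NA), mirroring
#' plotting conventions for damage-track signal.
#'
#' @param image Numeric matrix.
#' @param track_mask,nucleus_mask Logical masks.
#' @param positive_only Report only values > 0 (default FALSE).
#' @return Scalar background-subtracted track intensity.
#' @export
track_quant <- function(image, track_mask, nucleus_mask,
                        positive_only = FALSE) {
  inside <- track_mask & nucleus_mask
  outside <- nucleus_mask & !track_mask
  stopifnot(any(inside), any(outside))
  val <- mean(image[inside]) - mean(image[outside])
  if (positive_only && val <= 0) NA_real_ else val
}

#' Masked mean with an exclusion region
#'
#' Mean intensity over `include_mask` minus the pixels of `exclude_mask`;
#' used e.g. for chromatin-retention signal in the DAPI region excluding
#' the nucleolar (fibrillarin) region.
#'
#' @param image Numeric matrix.
#' @param include_mask,exclude_mask Logical masks.
#' @return Scalar mean intensity.
#' @export
masked_mean_excluding <- function(image, include_mask, exclude_mask) {
  sel <- include_mask & !exclude_mask
  if (!any(sel)) stop("include mask minus exclude mask is empty")
  mean(image[sel])
}
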