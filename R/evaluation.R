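#' Extract per-frame reference kinematics from section states
#'
#' For every frame, the reference lateral and vertical displacements are
#' taken from the tape section with the highest absolute vertical
#' displacement, and the reference roll from the section with the highest
#' absolute roll (the two argmax sections may differ, since the foot can
#' touch several sections). Ties break to the lower section index for
#' determinism. The reference longitudinal position comes from the foot
#' marker centroid when supplied.
#'
#' @param sections Data.frame of per-frame section states with columns
#'   `time_s` (or `frame`), `section`, `y_mm`, `z_mm`, `roll_deg`
#'   (`y_center_mm`/`z_center_mm` from [section_angles()] are accepted).
#' @param foot_x Optional numeric vector (one per frame) of foot-centroid
#'   X positions, mm.
#' @return Data.frame keyed by frame with `x_mm` (NA unless `foot_x`
#'   given), `y_mm`, `z_mm`, `roll_deg`. Frames with no valid section are
#'   dropped.
#' @export
extract_reference <- function(sections, foot_x = NULL) {
  key <- if ("time_s" %in% names(sections)) "time_s" else "frame"
  if (!key %in% names(sections)) stop("sections needs a time_s or frame column")
  ycol <- if ("y_mm" %in% names(sections)) "y_mm" else "y_center_mm"
  zcol <- if ("z_mm" %in% names(sections)) "z_mm" else "z_center_mm"
  sp <- split(sections, sections[[key]])
  rows <- lapply(sp, function(df) {
    df <- df[order(df$section), ]
    okz <- which(!is.na(df[[zcol]]))
    okr <- which(!is.na(df$roll_deg))
    if (!length(okz) && !length(okr)) return(NULL)
    iz <- if (length(okz)) okz[which.max(abs(df[[zcol]][okz]))] else NA
    ir <- if (length(okr)) okr[which.max(abs(df$roll_deg[okr]))] else NA
    data.frame(key = df[[key]][1],
               y_mm = if (is.na(iz)) NA_real_ else df[[ycol]][iz],
               z_mm = if (is.na(iz)) NA_real_ else df[[zcol]][iz],
               roll_deg = if (is.na(ir)) NA_real_ else df$roll_deg[ir])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  names(out)[1] <- key
  rownames(out) <- NULL
  out$x_mm <- if (is.null(foot_x)) NA_real_ else
    foot_x[match(out[[key]], unique(sections[[key]]))]
  out[, c(key, "x_mm", "y_mm", "z_mm", "roll_deg")]
}

#' Root-mean-squared error over non-excluded frames
#'
#' @param pred,ref Numeric series of equal length.
#' @param mask Optional exclusion mask: a logical vector or a data.frame
#'   with an `excluded` column ([exclude_frames()]). Excluded frames do
#'   not contribute.
#' @return RMSE (same units as the inputs).
#' @export
rmse <- function(pred, ref, mask = NULL) {
  stopifnot(length(pred) == length(ref))
  keep <- rep(TRUE, length(pred))
  if (!is.null(mask)) {
    excl <- if (is.data.frame(mask)) mask$excluded else as.logical(mask)
    stopifnot(length(excl) == length(pred))
    keep <- !excl
  }
  r <- pred[keep] - ref[keep]
  if (!length(r)) stop("no frames left after exclusion")
  sqrt(mean(r^2))
}

#' Modified box-plot percentile statistics
#'
#' The five percentiles used in the accuracy summaries: whiskers at the
#' 2nd and 98th percentiles, box at the 25th/75th, and the median.
#' Percentiles interpolate linearly between order statistics (R quantile
#' type 7). Values outside `[p2, p98]` count as outliers.
#'
#' @param errors Numeric vector of (signed) prediction errors.
#' @return Named numeric vector `p2, p25, p50, p75, p98` with attribute
#'   `"n_outliers"`.
#' @export
box_stats <- function(errors) {
  errors <- errors[!is.na(errors)]
  q <- stats::quantile(errors, c(0.02, 0.25, 0.5, 0.75, 0.98),
                       type = 7, names = FALSE)
  out <- c(p2 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p98 = q[5])
  attr(out, "n_outliers") <- sum(errors < q[1] | errors > q[5])
  out
}

#' Percentile profiles conditioned on a reference quantity
#'
#' Bins the errors by a conditioning variable (typically the reference X
#' position or Z displacement) and reports [box_stats()] per bin. Empty
#' bins are reported as `NA` rows (gaps), not dropped.
#'
#' @param errors Numeric error vector.
#' @param conditioner Numeric vector of the same length.
#' @param breaks Bin edges, or a single integer bin count over the range
#'   of `conditioner` (default 10).
#' @return Data.frame with `bin_center`, `n`, `p2`, `p25`, `p50`, `p75`,
#'   `p98`.
#' @export
conditioned_profile <- function(errors, conditioner, breaks = 10) {
  stopifnot(length(errors) == length(conditioner))
  if (length(breaks) == 1L) {
    breaks <- seq(min(conditioner), max(conditioner), length.out = breaks + 1)
  }
  idx <- cut(conditioner, breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- lapply(seq_along(centers), function(b) {
    e <- errors[!is.na(idx) & idx == b]
    if (!length(e)) {
      data.frame(bin_center = centers[b], n = 0L, p2 = NA_real_,
                 p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                 p98 = NA_real_)
    } else {
      q <- box_stats(e)
      data.frame(bin_center = centers[b], n = length(e), p2 = q[["p2"]],
                 p25 = q[["p25"]], p50 = q[["p50"]], p75 = q[["p75"]],
                 p98 = q[["p98"]])
    }
  })
  do.call(rbind, rows)
}

#' Per-output accuracy summary of a trial
#'
#' Convenience wrapper computing RMSE and box percentiles of every model
#' output against the ground truth of a synthetic trial (or any aligned
#' reference with the same columns).
#'
#' @param est Estimates from [estimate_tape()].
#' @param truth Reference data.frame with `x_mm`, `y_mm`, `z_mm`,
#'   `roll_deg` aligned with `est`.
#' @param mask Optional exclusion mask (see [rmse()]).
#' @param z_output Which vertical output to score: `"zr_mm"` (default,
#'   segment-corrected) in addition to the always-reported raw `z_mm`.
#' @return Data.frame with one row per output (`xz`, `xy`, `y`, `z`, `zr`,
#'   `rm`, `rs`, `rws`, `ra`): `rmse`, `p2`, `p25`, `p50`, `p75`, `p98`.
#' @export
summarize_errors <- function(est, truth, mask = NULL, z_output = "zr_mm") {
  pairs <- list(
    xz = list(est$xz_mm, truth$x_mm),
    xy = list(est$xy_mm, truth$x_mm),
    y = list(est$y_mm, truth$y_mm),
    z = list(est$z_mm, truth$z_mm),
    zr = list(est[[z_output]], truth$z_mm),
    rm = list(est$roll_rm_deg, truth$roll_deg),
    rs = list(est$roll_rs_deg, truth$roll_deg),
    rws = list(est$roll_rws_deg, truth$roll_deg),
    ra = list(est$roll_ra_deg, truth$roll_deg)
  )
  keep <- if (is.null(mask)) rep(TRUE, nrow(est)) else
    !(if (is.data.frame(mask)) mask$excluded else as.logical(mask))
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]][[1]][keep]
    r <- pairs[[nm]][[2]][keep]
    q <- box_stats(p - r)
    data.frame(output = nm, rmse = sqrt(mean((p - r)^2)),
               p2 = q[["p2"]], p25 = q[["p25"]], p50 = q[["p50"]],
               p75 = q[["p75"]], p98 = q[["p98"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
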