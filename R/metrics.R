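#' Morphological skeleton of a binary mask
#'
#' Thins a binary mask to a 1-pixel-wide skeleton by Zhang-Suen-style
#' iterative thinning. An empty mask returns empty; a mask that is already a
#' 1-px curve is returned unchanged.
#'
#' @param mask binary (0/1) matrix.
#' @return integer 0/1 matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- check_binary(mask)
  cpp_thin(m)
}

check_binary <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary 0/1")
  storage.mode(mask) <- "integer"
  mask
}

mask_points <- function(mask) {
  which(mask != 0, arr.ind = TRUE)
}

#' Centerline Dice score
#'
#' Topology precision is the fraction of the prediction's skeleton lying
#' inside the label mask; topology sensitivity the fraction of the label's
#' skeleton inside the prediction mask. The centerline Dice is their
#' harmonic mean. Empty-mask conventions: both masks empty scores 1 (a
#' correctly empty detection); exactly one empty scores 0.
#'
#' @param pred binary prediction mask.
#' @param label binary label mask.
#' @return list with `cl_dice`, `t_prec`, `t_sens`, `n_pred_points`,
#'   `n_label_points`.
#' @export
cl_dice <- function(pred, label) {
  pred <- check_binary(pred); label <- check_binary(label)
  if (!identical(dim(pred), dim(label))) stop("shape mismatch")
  sp <- skeletonize(pred)
  sl <- skeletonize(label)
  np <- sum(sp); nl <- sum(sl)
  if (np == 0 && nl == 0)
    return(list(cl_dice = 1, t_prec = NA_real_, t_sens = NA_real_,
                n_pred_points = 0L, n_label_points = 0L))
  if (np == 0 || nl == 0)
    return(list(cl_dice = 0, t_prec = NA_real_, t_sens = NA_real_,
                n_pred_points = as.integer(np), n_label_points = as.integer(nl)))
  t_prec <- sum(sp * label) / np
  t_sens <- sum(sl * pred) / nl
  cd <- if (t_prec + t_sens == 0) 0 else 2 * t_prec * t_sens / (t_prec + t_sens)
  list(cl_dice = cd, t_prec = t_prec, t_sens = t_sens,
       n_pred_points = as.integer(np), n_label_points = as.integer(nl))
}

#' Directed mean surface distance and signed probe-axis offset
#'
#' Both masks are skeletonized; for each of the N label-skeleton points the
#' Euclidean distance (in mm, per-axis pixel spacing applied) to the nearest
#' predicted-skeleton point is taken, and the mean of these N minima is the
#' directed (label to prediction) mean surface distance. The signed offset
#' averages, over the same nearest pairs, the depth difference
#' `(label_row - pred_row) * row_spacing`: positive when the prediction lies
#' shallower than the label, i.e. closer to the transducer at row 0.
#'
#' @param pred binary prediction mask.
#' @param label binary label mask.
#' @param spacing mm per pixel; scalar or `c(row_mm, col_mm)`.
#' @return list with `msd_mm`, `signed_offset_mm`, `defined` (FALSE when
#'   either skeleton is empty, in which case both values are `NA`).
#' @export
mean_surface_distance <- function(pred, label, spacing = c(1, 1)) {
  pred <- check_binary(pred); label <- check_binary(label)
  if (!identical(dim(pred), dim(label))) stop("shape mismatch")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  stopifnot(all(spacing > 0))
  sp <- mask_points(skeletonize(pred))
  sl <- mask_points(skeletonize(label))
  if (nrow(sp) == 0 || nrow(sl) == 0)
    return(list(msd_mm = NA_real_, signed_offset_mm = NA_real_,
                defined = FALSE))
  r <- cpp_min_dists(matrix(as.numeric(sl), ncol = 2),
                     matrix(as.numeric(sp), ncol = 2),
                     as.numeric(spacing))
  nearest_rows <- sp[r$which, 1]
  list(msd_mm = mean(r$dist),
       signed_offset_mm = mean((sl[, 1] - nearest_rows) * spacing[1]),
       defined = TRUE)
}

#' Per-image segmentation scores
#'
#' @param pred binary prediction mask.
#' @param label binary label mask.
#' @param spacing mm per pixel, scalar or per-axis.
#' @return list combining [cl_dice()] and [mean_surface_distance()] fields.
#' @export
seg_scores <- function(pred, label, spacing = c(1, 1)) {
  c(cl_dice(pred, label), mean_surface_distance(pred, label, spacing))
}

#' Aggregate segmentation scores over an image set
#'
#' Computes per-image scores and mean +/- SD (sample SD, n - 1) of the
#' centerline Dice and directed mean surface distance, overall and per
#' stratum. Images whose mean surface distance is undefined (an empty label
#' or empty prediction skeleton) are excluded from the distance aggregation
#' and counted; an image where exactly one of the two is empty is counted as
#' a detection failure.
#'
#' @param pairs list; each element a list with elements `pred`, `label`,
#'   optionally `spacing` (mm/px) and further metadata fields.
#' @param strata_key optional name of a metadata field to stratify by.
#' @param spacing default spacing for pairs that carry none.
#' @return object of class `seg_report` with elements `per_image` (data
#'   frame) and `aggregate` (data frame, first row the overall summary).
#' @export
evaluate_set <- function(pairs, strata_key = NULL, spacing = c(1, 1)) {
  stopifnot(length(pairs) > 0)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sc <- seg_scores(p$pred, p$label, if (is.null(p$spacing)) spacing else p$spacing)
    data.frame(image = i,
               stratum = if (is.null(strata_key) || is.null(p[[strata_key]]))
                 "all" else as.character(p[[strata_key]]),
               cl_dice = sc$cl_dice, t_prec = sc$t_prec, t_sens = sc$t_sens,
               msd_mm = sc$msd_mm, signed_offset_mm = sc$signed_offset_mm,
               n_label_points = sc$n_label_points,
               n_pred_points = sc$n_pred_points,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  agg_one <- function(df, name) {
    det_fail <- sum((df$n_label_points == 0) != (df$n_pred_points == 0))
    data.frame(stratum = name,
               n = nrow(df),
               mean_cl_dice = mean(df$cl_dice),
               sd_cl_dice = stats::sd(df$cl_dice),
               mean_msd_mm = mean(df$msd_mm, na.rm = TRUE),
               sd_msd_mm = stats::sd(df$msd_mm[!is.na(df$msd_mm)]),
               mean_signed_offset_mm = mean(df$signed_offset_mm, na.rm = TRUE),
               n_msd_excluded = sum(is.na(df$msd_mm)),
               n_detection_failures = det_fail,
               stringsAsFactors = FALSE)
  }
  agg <- agg_one(per_image, "all")
  if (!is.null(strata_key)) {
    for (s in sort(unique(per_image$stratum)))
      agg <- rbind(agg, agg_one(per_image[per_image$stratum == s, ], s))
  }
  structure(list(per_image = per_image, aggregate = agg),
            class = "seg_report")
}

#' @export
print.seg_report <- function(x, ...) {
  cat("Segmentation performance (mean +/- sample SD)\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-12s n=%3d  clDice %.3f +/- %.3f   MSD %.3f +/- %.3f mm (offset %+.3f mm, %d excluded)\n",
                a$stratum[i], a$n[i], a$mean_cl_dice[i], a$sd_cl_dice[i],
                a$mean_msd_mm[i], a$sd_msd_mm[i],
                a$mean_signed_offset_mm[i], a$n_msd_excluded[i]))
  }
  invisible(x)
}
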