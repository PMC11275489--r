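# Classical stand-in detector for the synthetic renders.
#
# This module deliberately replaces a trained segmentation model with a
# fully specified classical detector (background-subtracted dark-blob
# response on the green channel, connected components, size gates) so that
# the downstream pipeline is exercisable end-to-end with no model weights.
# It is tuned for the package's own renders, not for real fundus
# photographs.

#' Detection parameters
#'
#' @param min_blob_um smallest accepted equivalent-circle diameter (um).
#' @param ma_max_diameter_um MA/HEM size cutoff: blobs at or below it are
#'   microaneurysms, larger ones hemorrhages (default 125 um, the
#'   conventional clinical upper bound for an MA).
#' @param max_blob_um largest accepted diameter; larger blobs are rejected.
#' @param response_threshold darkness-response threshold in [0, 1]; raising
#'   it makes the detector stricter.
#' @param channel color channel carrying red-lesion contrast (default
#'   `"green"`, standard for fundus imaging; `"red"`/`"blue"`/`"luminance"`
#'   also accepted).
#' @param smooth_sigma_px Gaussian pre-smoothing scale in pixels.
#' @param disc_mask_radius_um radius around the optic-disc center excluded
#'   from the lesion search.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(min_blob_um = 20, ma_max_diameter_um = 125,
                             max_blob_um = 1500, response_threshold = 0.15,
                             channel = c("green", "red", "blue", "luminance"),
                             smooth_sigma_px = 1,
                             disc_mask_radius_um = 1100) {
  channel <- match.arg(channel)
  if (!(min_blob_um < ma_max_diameter_um && ma_max_diameter_um < max_blob_um))
    stop("require min_blob_um < ma_max_diameter_um < max_blob_um")
  if (response_threshold <= 0) stop("response_threshold must be positive")
  structure(list(min_blob_um = min_blob_um,
                 ma_max_diameter_um = ma_max_diameter_um,
                 max_blob_um = max_blob_um,
                 response_threshold = response_threshold,
                 channel = channel, smooth_sigma_px = smooth_sigma_px,
                 disc_mask_radius_um = disc_mask_radius_um),
            class = "detection_params")
}

# pull the working channel as a matrix
.image_channel <- function(image, channel) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3) {
    idx <- switch(channel, red = 1, green = 2, blue = 3, luminance = NULL)
    if (is.null(idx)) {
      return(0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
               0.0722 * image[, , 3])
    }
    return(image[, , min(idx, dim(image)[3])])
  }
  stop("image must be a matrix or an h x w x 3 array")
}

#' Detect dark blob candidates
#'
#' Finds dark, roughly circular blobs in a fundus-like raster: the chosen
#' channel is inverted, the background level (median over the usable
#' pixels) subtracted, the response lightly Gaussian-smoothed, thresholded
#' and decomposed into connected components. Each component yields a
#' centroid, an equivalent-circle diameter (from its area) and a mean
#' contrast. Components outside the size gates are dropped. The procedure
#' is deterministic for a fixed input.
#'
#' @param image matrix (single channel) or `h x w x 3` RGB array, values
#'   in [0, 1].
#' @param params a [detection_params()].
#' @param um_per_px micrometres per pixel, used for the size gates.
#' @param mask optional logical matrix, `TRUE` where detection may look
#'   (e.g. inside the field and away from the optic disc).
#' @return data frame with columns `x_px`, `y_px`, `diameter_um`,
#'   `contrast`; empty for a flat image.
#' @export
detect_candidates <- function(image, params = detection_params(),
                              um_per_px, mask = NULL) {
  ch <- .image_channel(image, params$channel)
  inv <- 1 - ch
  usable <- if (is.null(mask)) rep(TRUE, length(inv)) else {
    stopifnot(identical(dim(mask), dim(inv)))
    as.vector(mask)
  }
  if (!any(usable)) return(.empty_candidates())
  bg <- median(inv[usable])
  resp <- inv - bg
  if (params$smooth_sigma_px > 0)
    resp <- gblur(resp, sigma = params$smooth_sigma_px)
  if (!is.null(mask)) resp[!mask] <- 0
  bw <- resp > params$response_threshold
  if (!any(bw)) return(.empty_candidates())
  lab <- bwlabel(bw)
  ids <- lab[lab > 0]
  area <- tabulate(ids)
  xs <- (col(lab) - 1)[lab > 0]
  ys <- (row(lab) - 1)[lab > 0]
  cx <- tapply(xs, ids, mean)
  cy <- tapply(ys, ids, mean)
  contrast <- tapply(resp[lab > 0], ids, mean)
  diam_um <- 2 * sqrt(area / pi) * um_per_px
  out <- data.frame(x_px = as.numeric(cx), y_px = as.numeric(cy),
                    diameter_um = diam_um,
                    contrast = as.numeric(contrast))
  out <- out[out$diameter_um >= params$min_blob_um &
               out$diameter_um <= params$max_blob_um, , drop = FALSE]
  row.names(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0),
             diameter_um = numeric(0), contrast = numeric(0))
}

#' Classify a blob as MA, HEM or reject
#'
#' Pure size rule: equivalent diameters at or below the MA cutoff are
#' microaneurysms, those between the cutoff and the upper gate are
#' hemorrhages, anything outside the gates is rejected. Contrast is
#' carried along for optional tuning but does not enter the default rule.
#'
#' @param diameter_um equivalent-circle diameter(s) in micrometres.
#' @param params a [detection_params()].
#' @return character vector in `{"MA", "HEM", "reject"}`.
#' @export
#' @examples
#' classify_lesion(c(60, 300, 2000))
classify_lesion <- function(diameter_um, params = detection_params()) {
  ifelse(diameter_um < params$min_blob_um, "reject",
         ifelse(diameter_um <= params$ma_max_diameter_um, "MA",
                ifelse(diameter_um <= params$max_blob_um, "HEM", "reject")))
}

#' Detect and classify lesions in a rendered fundus image
#'
#' Composes [detect_candidates()] and [classify_lesion()]: the search is
#' restricted to the 45-degree field circle minus a disc-shaped exclusion
#' zone around the optic nerve head (the bright disc is not lesion
#' territory), candidates are typed by size, and rejects are dropped.
#'
#' @param image RGB array or matrix matching the frame's dimensions.
#' @param frame a [fundus_frame()].
#' @param params a [detection_params()].
#' @return lesion marks data frame (`lesion_type`, `x_px`, `y_px`,
#'   `diameter_um`, `mean_intensity`).
#' @export
detect_lesions <- function(image, frame, params = detection_params()) {
  d <- dim(image)
  if (d[1] != frame$height_px || d[2] != frame$width_px)
    stop(sprintf("image is %d x %d but frame says %d x %d",
                 d[1], d[2], frame$height_px, frame$width_px))
  h <- frame$height_px; w <- frame$width_px
  xs <- outer(rep(1, h), 0:(w - 1))
  ys <- outer(0:(h - 1), rep(1, w))
  in_field <- sqrt((xs - (w - 1) / 2)^2 + (ys - (h - 1) / 2)^2) <=
    min(w, h) / 2
  disc_r_px <- params$disc_mask_radius_um / frame$um_per_px
  away_from_disc <- sqrt((xs - frame$disc_x)^2 + (ys - frame$disc_y)^2) >
    disc_r_px
  cand <- detect_candidates(image, params, um_per_px = frame$um_per_px,
                            mask = in_field & away_from_disc)
  if (!nrow(cand)) {
    return(data.frame(lesion_type = character(0), x_px = numeric(0),
                      y_px = numeric(0), diameter_um = numeric(0),
                      mean_intensity = numeric(0)))
  }
  type <- classify_lesion(cand$diameter_um, params)
  keep <- type != "reject"
  data.frame(lesion_type = type[keep], x_px = cand$x_px[keep],
             y_px = cand$y_px[keep], diameter_um = cand$diameter_um[keep],
             mean_intensity = cand$contrast[keep], row.names = NULL)
}

#' Score detections against ground truth
#'
#' Greedy nearest-centroid matching between detected marks and generator
#' ground truth: a detection is a true positive when a same-type truth
#' mark lies within `max_dist_px` (each truth mark is matched at most
#' once). Reports precision, recall and F1 overall and per lesion type.
#'
#' @param truth,detected lesion marks data frames (`lesion_type`, `x_px`,
#'   `y_px`).
#' @param max_dist_px matching radius in pixels.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, and a
#'   `by_type` data frame.
#' @export
evaluate_detections <- function(truth, detected, max_dist_px = 5) {
  score_one <- function(tr, de) {
    used <- rep(FALSE, nrow(tr))
    tp <- 0L
    if (nrow(de)) for (i in seq_len(nrow(de))) {
      if (!nrow(tr)) break
      dd <- sqrt((tr$x_px - de$x_px[i])^2 + (tr$y_px - de$y_px[i])^2)
      dd[used] <- Inf
      j <- which.min(dd)
      if (length(j) && dd[j] <= max_dist_px) {
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
    c(tp = tp, fp = nrow(de) - tp, fn = nrow(tr) - tp)
  }
  by_type <- do.call(rbind, lapply(.LESION_TYPES, function(ltype) {
    s <- score_one(truth[truth$lesion_type == ltype, , drop = FALSE],
                   detected[detected$lesion_type == ltype, , drop = FALSE])
    data.frame(lesion_type = ltype, tp = s["tp"], fp = s["fp"],
               fn = s["fn"], row.names = NULL)
  }))
  tp <- sum(by_type$tp); fp <- sum(by_type$fp); fn <- sum(by_type$fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, by_type = by_type)
}
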