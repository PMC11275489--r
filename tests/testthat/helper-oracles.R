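# Independent per-point oracles used to cross-check the vectorized
# implementations. Written deliberately as scalar if-chains.

# standard test frame: fovea at the image center, disc 500 px to the
# nasal side, 1440 x 960 px at 45 degrees (9 um/px)
test_frame <- function(laterality = c("right", "left"),
                       width = 1440, height = 960, id = "test") {
  laterality <- match.arg(laterality)
  fx <- (width - 1) / 2
  fy <- (height - 1) / 2
  dx <- if (laterality == "right") fx + 500 else fx - 500
  fundus_frame(width, height, fx, fy, dx, fy, image_id = id)
}

# scalar region oracle: explicit atan2 angle intervals
oracle_region <- function(x, y, frame, ring_um = 750) {
  dx <- x - frame$fovea_x
  dy <- y - frame$fovea_y
  if (sqrt(dx^2 + dy^2) * frame$um_per_px < ring_um) return("central_ring")
  cx <- (frame$width_px - 1) / 2
  cy <- (frame$height_px - 1) / 2
  if (sqrt((x - cx)^2 + (y - cy)^2) >
      min(frame$width_px, frame$height_px) / 2) return("outside_field")
  ang <- atan2(-dy, dx) * 180 / pi
  if (ang <= 0) ang <- ang + 360            # (0, 360]
  side <- if (ang > 45 && ang <= 135) {
    "superior"
  } else if (ang > 135 && ang <= 225) {
    "left"
  } else if (ang > 225 && ang <= 315) {
    "inferior"
  } else {
    "right"
  }
  if (side %in% c("superior", "inferior")) return(side)
  # disc side is nasal
  disc_right <- frame$disc_x > frame$fovea_x
  if (side == "right") {
    if (disc_right) "nasal" else "temporal"
  } else {
    if (disc_right) "temporal" else "nasal"
  }
}

# literal transcription of the MESSIDOR grading booleans, severe first
oracle_grade <- function(mu, h, nv) {
  if (mu >= 15 || h >= 5 || nv == 1) {
    3L
  } else if (((mu > 5 && mu < 15) || (h > 0 && h < 5)) && nv == 0) {
    2L
  } else if ((mu > 0 && mu <= 5) && h == 0) {
    1L
  } else {
    0L
  }
}

# brute-force sum-of-squares decomposition for the one-way F
oracle_anova_f <- function(groups) {
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups)
  n <- length(unlist(groups))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# quadrant x lesion count request table for place_lesions
count_request <- function(ma = c(0, 0, 0, 0), hem = c(0, 0, 0, 0)) {
  q <- region_labels(quadrants_only = TRUE)
  data.frame(lesion_type = rep(c("MA", "HEM"), each = 4),
             quadrant = rep(q, 2), count = c(ma, hem))
}
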