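#' Load a cohort preset
#'
#' Reads one of the shipped YAML presets describing per-grade stratum sizes
#' and per-quadrant lesion count distributions (mean and SD per lesion type
#' and quadrant), or any user YAML in the same dialect.
#'
#' @param preset `"messidor"`, `"miradataset"`, or a path to a YAML file.
#' @return list with `name`, `n` (named integer vector per grade) and
#'   `rates` (data frame: `lesion`, `grade`, `quadrant`, `mean`, `sd`).
#' @export
load_preset <- function(preset) {
  path <- if (file.exists(preset)) preset else
    system.file("extdata", "presets", paste0(preset, ".yaml"),
                package = "drquad")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown preset: ", preset)
  y <- read_yaml(path)
  grades <- names(y$grades)
  rates <- do.call(rbind, lapply(grades, function(g) {
    do.call(rbind, lapply(.LESION_TYPES, function(ltype) {
      cells <- y$grades[[g]][[ltype]]
      do.call(rbind, lapply(.QUADRANTS, function(q) {
        data.frame(lesion = ltype, grade = g, quadrant = q,
                   mean = cells[[q]]$mean, sd = cells[[q]]$sd)
      }))
    }))
  }))
  n <- vapply(y$grades, function(g) as.integer(g$n_images), integer(1))
  list(name = y$name, n = n, rates = rates)
}

#' Cohort simulation specification
#'
#' Collects everything [simulate_cohort()] needs: stratum sizes, the
#' per-quadrant count distributions, frame geometry, laterality mix and a
#' seed. Defaults reproduce the shipped presets; any field can be
#' overridden for custom designs.
#'
#' Two consistency modes exist. `"table_calibrated"` (default) draws
#' quadrant counts straight from the preset distributions; whole-image
#' totals then need not satisfy the MESSIDOR rules of the stratum (the
#' published mild-DR strata, for instance, report nonzero hemorrhage means
#' although the mild rule requires H = 0 — the presets reproduce the
#' tables, not the rules). `"rule_consistent"` instead minimally adjusts
#' each image's counts so that its grade under [grade_from_counts()]
#' matches its stratum, at the cost of distorting the calibrated moments.
#'
#' @param preset `"messidor"`, `"miradataset"`, a YAML path, or `"custom"`
#'   (then `n` and `rates` are required).
#' @param grades which strata to simulate (default: all in the preset).
#' @param n named integer vector of images per grade; overrides the preset.
#' @param rates data frame (`lesion`, `grade`, `quadrant`, `mean`, `sd`);
#'   overrides the preset.
#' @param laterality_mix fraction of right eyes (default 0.5).
#' @param mode `"table_calibrated"` or `"rule_consistent"`.
#' @param seed integer seed for reproducibility.
#' @param width_px,height_px,fov_deg frame geometry of the simulated
#'   photographs (defaults: 1440 x 960 px at 45 degrees, i.e. 9 um/px).
#' @param ma_diameter_um,hem_diameter_um diameter ranges (um) assigned to
#'   generated MA and HEM marks.
#' @return list of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec("messidor", grades = "Severe", seed = 7)
#' spec$n
cohort_spec <- function(preset = "messidor", grades = NULL, n = NULL,
                        rates = NULL, laterality_mix = 0.5,
                        mode = c("table_calibrated", "rule_consistent"),
                        seed = 1L, width_px = 1440, height_px = 960,
                        fov_deg = 45, ma_diameter_um = c(30, 110),
                        hem_diameter_um = c(150, 800)) {
  mode <- match.arg(mode)
  if (identical(preset, "custom")) {
    if (is.null(n) || is.null(rates))
      stop("custom preset requires n and rates")
    name <- "custom"
  } else {
    p <- load_preset(preset)
    name <- p$name
    if (is.null(n)) n <- p$n
    if (is.null(rates)) rates <- p$rates
  }
  if (is.null(grades)) grades <- names(n)
  n <- n[grades]
  if (any(is.na(n)) || any(n < 2))
    stop("need n >= 2 images for every requested grade")
  rates <- rates[rates$grade %in% grades, , drop = FALSE]
  need <- length(grades) * length(.LESION_TYPES) * length(.QUADRANTS)
  if (nrow(rates) != need || any(rates$mean < 0) || any(rates$sd < 0))
    stop("rates must cover every grade x lesion x quadrant cell with non-negative mean and sd")
  if (laterality_mix < 0 || laterality_mix > 1)
    stop("laterality_mix must be in [0, 1]")
  structure(list(name = name, grades = grades, n = n, rates = rates,
                 laterality_mix = laterality_mix, mode = mode,
                 seed = as.integer(seed), width_px = width_px,
                 height_px = height_px, fov_deg = fov_deg,
                 ma_diameter_um = ma_diameter_um,
                 hem_diameter_um = hem_diameter_um),
            class = "cohort_spec")
}

#' Draw overdispersed lesion counts
#'
#' Samples non-negative integer counts whose first two moments match a
#' target mean and SD. Published per-quadrant lesion counts are
#' overdispersed (SD > mean in every severe-DR cell), so when
#' `sd^2 > mean` a negative binomial with moment-matched size
#' `r = mean^2 / (sd^2 - mean)` is used; when `sd^2 <= mean` a Poisson
#' with the target mean (its variance then equals the mean); a zero mean
#' always yields zero.
#'
#' @param n number of draws.
#' @param mean,sd target mean and standard deviation, `mean >= 0`.
#' @return integer vector of `n` counts.
#' @export
#' @examples
#' set.seed(1)
#' x <- sample_count(1e4, mean = 5.50, sd = 6.52)
#' c(mean(x), sd(x))
sample_count <- function(n, mean, sd) {
  if (mean < 0) stop("mean must be non-negative")
  if (mean == 0) return(integer(n))
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    rnbinom(n, size = size, mu = mean)
  } else {
    rpois(n, mean)
  }
}

#' Place lesion marks inside their target quadrants
#'
#' Draws lesion positions uniformly at random within each requested
#' quadrant wedge — inside the 45-degree field circle and outside the
#' central ring — by rejection sampling against [assign_region()], so that
#' by construction every placed mark maps back to its target quadrant and
#' the central ring stays empty. Mark diameters are drawn uniformly from
#' the type's range.
#'
#' @param counts data frame with columns `lesion_type`, `quadrant`,
#'   `count` (non-negative integers; quadrants among
#'   `region_labels(TRUE)`).
#' @param frame a [fundus_frame()].
#' @param grid an [etdrs_grid()]; defaults to the grid of `frame`.
#' @param ma_diameter_um,hem_diameter_um diameter ranges (um).
#' @param min_separation_um if positive, marks are re-placed until all
#'   pairwise center distances exceed this separation (used for renders
#'   meant to contain non-overlapping lesions).
#' @param max_tries rejection-sampling guard.
#' @return data frame of lesion marks (`lesion_type`, `x_px`, `y_px`,
#'   `diameter_um`, `region`).
#' @export
place_lesions <- function(counts, frame, grid = etdrs_grid(frame),
                          ma_diameter_um = c(30, 110),
                          hem_diameter_um = c(150, 800),
                          min_separation_um = 0, max_tries = 200) {
  stopifnot(all(c("lesion_type", "quadrant", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  if (!all(counts$quadrant %in% .QUADRANTS))
    stop("quadrant must be one of: ", paste(.QUADRANTS, collapse = ", "))
  ring_px <- grid$central_ring_radius_um / frame$um_per_px
  if (ring_px >= grid$field_radius_px)
    stop("impossible placement: central ring covers the whole field")
  counts <- counts[counts$count > 0, , drop = FALSE]
  total <- sum(counts$count)
  empty <- data.frame(lesion_type = character(0), x_px = numeric(0),
                      y_px = numeric(0), diameter_um = numeric(0),
                      region = character(0))
  if (total == 0) return(empty)

  need <- setNames(rep(0L, length(.QUADRANTS)), .QUADRANTS)
  agg <- tapply(counts$count, counts$quadrant, sum)
  need[names(agg)] <- as.integer(agg)

  got <- list()
  tries <- 0
  while (any(need > 0)) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("impossible placement: could not fill quadrants ",
           paste(names(need)[need > 0], collapse = ", "))
    m <- max(500L, 20L * sum(need))
    # uniform over the field disc, then rejected into target wedges
    r <- grid$field_radius_px * sqrt(runif(m))
    a <- runif(m, 0, 2 * pi)
    x <- grid$field_center_x + r * cos(a)
    y <- grid$field_center_y + r * sin(a)
    reg <- as.character(assign_region(x, y, frame, grid))
    for (q in .QUADRANTS) {
      if (need[[q]] == 0) next
      idx <- which(reg == q)
      take <- head(idx, need[[q]])
      if (length(take)) {
        got[[q]] <- rbind(got[[q]], data.frame(x_px = x[take], y_px = y[take]))
        need[[q]] <- need[[q]] - length(take)
      }
    }
  }

  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    q <- counts$quadrant[i]
    k <- counts$count[i]
    pos <- got[[q]][seq_len(k), , drop = FALSE]
    got[[q]] <<- got[[q]][-seq_len(k), , drop = FALSE]
    rng <- if (counts$lesion_type[i] == "MA") ma_diameter_um else hem_diameter_um
    data.frame(lesion_type = counts$lesion_type[i],
               x_px = pos$x_px, y_px = pos$y_px,
               diameter_um = runif(k, rng[1], rng[2]),
               region = q)
  }))
  row.names(rows) <- NULL

  if (min_separation_um > 0 && nrow(rows) > 1) {
    sep_px <- min_separation_um / frame$um_per_px
    for (pass in seq_len(max_tries)) {
      d <- as.matrix(dist(rows[, c("x_px", "y_px")]))
      diag(d) <- Inf
      bad <- which(apply(d < sep_px, 1, any))
      if (!length(bad)) break
      if (pass == max_tries)
        stop("impossible placement: cannot satisfy min_separation_um")
      for (i in bad[-1]) {  # keep the first of each crowded pair
        repeat {
          r <- grid$field_radius_px * sqrt(runif(1))
          a <- runif(1, 0, 2 * pi)
          x <- grid$field_center_x + r * cos(a)
          y <- grid$field_center_y + r * sin(a)
          if (as.character(assign_region(x, y, frame, grid)) == rows$region[i]) {
            rows$x_px[i] <- x; rows$y_px[i] <- y
            break
          }
        }
      }
    }
  }
  rows
}

# Minimal count adjustment so an image's whole-image totals satisfy the
# MESSIDOR rule of its stratum (rule_consistent mode). cnt is the named
# 2 x 4 matrix of counts [lesion, quadrant].
.enforce_rules <- function(cnt, grade, rules = grade_rules()) {
  shrink_to <- function(v, target) {
    # remove counts from the largest cells until sum(v) == target
    while (sum(v) > target) {
      i <- which.max(v)
      v[i] <- v[i] - 1L
    }
    v
  }
  ma <- cnt["MA", ]; hem <- cnt["HEM", ]
  if (grade == "Mild") {
    hem[] <- 0L
    if (sum(ma) > rules$mild_ma_max) ma <- shrink_to(ma, rules$mild_ma_max)
    if (sum(ma) == 0) ma["temporal"] <- 1L
  } else if (grade == "Moderate") {
    if (sum(ma) >= rules$moderate_ma_max)
      ma <- shrink_to(ma, rules$moderate_ma_max - 1L)
    if (sum(hem) >= rules$moderate_hem_max)
      hem <- shrink_to(hem, rules$moderate_hem_max - 1L)
    if (sum(ma) <= rules$mild_ma_max && sum(hem) == 0)
      hem["temporal"] <- 1L
  } else if (grade == "Severe") {
    deficit <- rules$moderate_ma_max - sum(ma)
    if (deficit > 0 && sum(hem) < rules$moderate_hem_max)
      ma["temporal"] <- ma["temporal"] + deficit
  }
  cnt["MA", ] <- ma; cnt["HEM", ] <- hem
  cnt
}

#' Simulate a graded cohort of lesion maps
#'
#' Generates a full synthetic cohort: for every image in every requested
#' grade stratum, eye laterality is drawn from the laterality mix, a
#' [fundus_frame()] is built (fovea at the image center, optic disc 4500 um
#' to the nasal side), per-quadrant MA/HEM counts are drawn from the
#' stratum's calibrated distributions via [sample_count()], and lesions are
#' placed into their quadrants with [place_lesions()]. The whole procedure
#' is deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `dr_cohort` with elements `spec`, `frames` (named
#'   list of [fundus_frame()]), `marks` (one data frame of all lesion
#'   marks, keyed by `image_id`) and `strata` (data frame: `image_id`,
#'   `grade`, `laterality`).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec("messidor", grades = "Severe",
#'                                   n = c(Severe = 10), seed = 3))
#' nrow(co$strata)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  disc_offset_px <- 4500 / um_per_px(spec$width_px, spec$fov_deg)
  frames <- list()
  marks <- list()
  strata <- list()
  for (g in spec$grades) {
    n_img <- spec$n[[g]]
    rates_g <- spec$rates[spec$rates$grade == g, , drop = FALSE]
    # draw the whole stratum's count matrix cell by cell
    draws <- lapply(seq_len(nrow(rates_g)), function(i)
      sample_count(n_img, rates_g$mean[i], rates_g$sd[i]))
    right_eye <- runif(n_img) < spec$laterality_mix
    for (j in seq_len(n_img)) {
      id <- sprintf("%s_%s_%04d", spec$name, tolower(g), j)
      fov_x <- (spec$width_px - 1) / 2
      fov_y <- (spec$height_px - 1) / 2
      disc_x <- fov_x + if (right_eye[j]) disc_offset_px else -disc_offset_px
      fr <- fundus_frame(spec$width_px, spec$height_px, fov_x, fov_y,
                         disc_x, fov_y, fov_deg = spec$fov_deg,
                         image_id = id)
      cnt <- matrix(vapply(seq_len(nrow(rates_g)), function(i)
        draws[[i]][j], numeric(1)),
        nrow = 2, byrow = TRUE,
        dimnames = list(.LESION_TYPES, .QUADRANTS))
      if (spec$mode == "rule_consistent")
        cnt <- .enforce_rules(cnt, g)
      tab <- data.frame(
        lesion_type = rep(.LESION_TYPES, each = length(.QUADRANTS)),
        quadrant = rep(.QUADRANTS, 2),
        count = as.integer(t(cnt)))
      mk <- place_lesions(tab, fr,
                          ma_diameter_um = spec$ma_diameter_um,
                          hem_diameter_um = spec$hem_diameter_um)
      if (nrow(mk)) mk <- cbind(image_id = id, mk)
      frames[[id]] <- fr
      marks[[id]] <- mk
      strata[[id]] <- data.frame(
        image_id = id, grade = g,
        laterality = if (right_eye[j]) "right" else "left")
    }
  }
  all_marks <- do.call(rbind, marks[lengths(lapply(marks, nrow)) > 0])
  if (is.null(all_marks))
    all_marks <- data.frame(image_id = character(0), lesion_type = character(0),
                            x_px = numeric(0), y_px = numeric(0),
                            diameter_um = numeric(0), region = character(0))
  row.names(all_marks) <- NULL
  strata <- do.call(rbind, strata)
  row.names(strata) <- NULL
  structure(list(spec = spec, frames = frames, marks = all_marks,
                 strata = strata),
            class = "dr_cohort")
}

#' @export
print.dr_cohort <- function(x, ...) {
  cat(sprintf("<dr_cohort %s> %d images (%s), %d lesion marks\n",
              x$spec$name, nrow(x$strata),
              paste(sprintf("%s: %d", names(table(x$strata$grade)),
                            as.integer(table(x$strata$grade))),
                    collapse = ", "),
              nrow(x$marks)))
  invisible(x)
}

#' Per-image region counts for a simulated cohort
#'
#' Runs every image of a cohort through the grid-counting stage
#' ([count_by_region()]) and stacks the results. This is the pipeline's
#' measurement of the cohort, as opposed to the generator's target counts.
#'
#' @param cohort a `dr_cohort` from [simulate_cohort()].
#' @return data frame with columns `image_id`, `region`, `n_MA`, `n_HEM`.
#' @export
cohort_counts <- function(cohort) {
  stopifnot(inherits(cohort, "dr_cohort"))
  out <- do.call(rbind, lapply(names(cohort$frames), function(id) {
    mk <- cohort$marks[cohort$marks$image_id == id, , drop = FALSE]
    count_by_region(mk, cohort$frames[[id]])
  }))
  row.names(out) <- NULL
  out
}

#' Render specification for synthetic fundus images
#'
#' Parameters of the fundus-like renderer: background color, lesion
#' colors/diameter ranges, optic-disc and macula geometry, pixel noise.
#' The defaults keep MA diameters below and HEM diameters above the
#' detector's 125 um type cutoff.
#'
#' @param background RGB triple in [0, 1] of the fundus background.
#' @param ma_rgb,hem_rgb lesion colors (dark red; HEM darker).
#' @param disc_radius_um optic-disc radius (bright ellipse).
#' @param macula_radius_um radius of the slightly darker macular disc.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(background = c(0.82, 0.46, 0.26),
                        ma_rgb = c(0.55, 0.12, 0.10),
                        hem_rgb = c(0.42, 0.05, 0.06),
                        disc_radius_um = 750,
                        macula_radius_um = 750,
                        noise_sd = 0.004) {
  structure(list(background = background, ma_rgb = ma_rgb,
                 hem_rgb = hem_rgb, disc_radius_um = disc_radius_um,
                 macula_radius_um = macula_radius_um, noise_sd = noise_sd),
            class = "render_spec")
}

# paint a filled ellipse into the rgb array (h x w x 3); axes in px
.paint_ellipse <- function(img, cx, cy, rx, ry, angle, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(0, floor(cx - max(rx, ry))); x1 <- min(w - 1, ceiling(cx + max(rx, ry)))
  y0 <- max(0, floor(cy - max(rx, ry))); y1 <- min(h - 1, ceiling(cy + max(rx, ry)))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  gx <- outer(rep(1, length(ys)), xs) - cx
  gy <- outer(ys, rep(1, length(xs))) - cy
  ca <- cos(angle); sa <- sin(angle)
  u <- gx * ca + gy * sa
  v <- -gx * sa + gy * ca
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  for (ch in 1:3) {
    sl <- img[ys + 1, xs + 1, ch]
    sl[inside] <- rgb[ch]
    img[ys + 1, xs + 1, ch] <- sl
  }
  img
}

#' Render a synthetic fundus image
#'
#' Paints a simplified macula-centered fundus photograph as an RGB array
#' (`height x width x 3`, values in [0, 1]): uniform reddish background
#' inside the 45-degree field circle, black outside it, a bright optic
#' disc on the nasal side, a slightly darker macula, microaneurysms as
#' small dark-red discs and hemorrhages as larger, darker, mildly
#' elliptical blotches (equivalent-circle area preserved). Gaussian pixel
#' noise is added last; the render consumes the current RNG stream, so
#' seed before calling for reproducibility.
#'
#' @param frame a [fundus_frame()].
#' @param marks lesion marks data frame (`lesion_type`, `x_px`, `y_px`,
#'   `diameter_um`); all marks must lie inside the image.
#' @param spec a [render_spec()].
#' @return numeric array `height_px x width_px x 3`, suitable for
#'   [png::writePNG()] and [detect_lesions()].
#' @export
render_fundus <- function(frame, marks, spec = render_spec()) {
  validate_marks(marks, require_diameter = TRUE)
  if (nrow(marks) &&
      (any(marks$x_px < 0 | marks$x_px > frame$width_px - 1) ||
       any(marks$y_px < 0 | marks$y_px > frame$height_px - 1)))
    stop("marks outside the image")
  h <- frame$height_px; w <- frame$width_px
  img <- array(rep(spec$background, each = h * w), dim = c(h, w, 3))

  # macula: mild darkening around the fovea (kept under detection threshold)
  mac_r <- spec$macula_radius_um / frame$um_per_px
  img <- .paint_ellipse(img, frame$fovea_x, frame$fovea_y, mac_r, mac_r, 0,
                        spec$background * 0.88)
  # optic disc: bright ellipse, slightly taller than wide
  disc_r <- spec$disc_radius_um / frame$um_per_px
  img <- .paint_ellipse(img, frame$disc_x, frame$disc_y,
                        disc_r * 0.9, disc_r * 1.1, 0,
                        c(0.95, 0.82, 0.55))
  if (nrow(marks)) {
    for (i in seq_len(nrow(marks))) {
      r <- marks$diameter_um[i] / 2 / frame$um_per_px
      if (marks$lesion_type[i] == "MA") {
        img <- .paint_ellipse(img, marks$x_px[i], marks$y_px[i], r, r, 0,
                              spec$ma_rgb)
      } else {
        q <- runif(1, 0.75, 1)       # mild eccentricity, area preserved
        ang <- runif(1, 0, pi)
        img <- .paint_ellipse(img, marks$x_px[i], marks$y_px[i],
                              r / sqrt(q), r * sqrt(q), ang, spec$hem_rgb)
      }
    }
  }
  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
  # black outside the camera aperture (radius w/2: wider than the analysis
  # field circle, so the optic disc stays visible; corners go black as in
  # real retinographies)
  fx <- outer(rep(1, h), 0:(w - 1)) - (w - 1) / 2
  fy <- outer(0:(h - 1), rep(1, w)) - (h - 1) / 2
  outside <- sqrt(fx^2 + fy^2) > w / 2
  for (ch in 1:3) {
    sl <- img[, , ch]
    sl[outside] <- 0
    img[, , ch] <- sl
  }
  pmin(pmax(img, 0), 1)
}
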