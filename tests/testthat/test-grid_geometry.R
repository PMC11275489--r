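test_that("laterality follows the disc side and rejects degenerate landmarks", {
  expect_equal(infer_laterality(fundus_frame(1440, 960, 720, 480, 1050, 470)),
               "right")
  expect_equal(infer_laterality(fundus_frame(1440, 960, 720, 480, 390, 470)),
               "left")
  expect_error(fundus_frame(1440, 960, 720, 480, 720, 300),
               "degenerate")
})

test_that("um-per-pixel scale follows the field of view", {
  expect_equal(um_per_px(1440, fov_deg = 45), 9.0)
  expect_equal(um_per_px(2880, fov_deg = 45), 4.5)
  expect_error(um_per_px(0), "positive")
  fr <- fundus_frame(1440, 960, 720, 480, 1220, 480)
  expect_equal(um_per_px(fr), 9.0)
})

test_that("frame constructor enforces landmarks inside the image", {
  expect_error(fundus_frame(1440, 960, 2000, 480, 1220, 480), "fovea")
  expect_error(fundus_frame(1440, 960, 720, 480, 1500, 480), "disc")
  expect_error(fundus_frame(0, 960, 0, 0, 0, 0), "positive")
})

test_that("region assignment handles axis, ring and laterality cases", {
  fr_r <- test_frame("right")   # 9 um/px
  fr_l <- test_frame("left")
  px2000 <- 2000 / 9
  # straight above the fovea
  expect_equal(as.character(assign_region(fr_r$fovea_x,
                                          fr_r$fovea_y - px2000, fr_r)),
               "superior")
  # the fovea itself
  expect_equal(as.character(assign_region(fr_r$fovea_x, fr_r$fovea_y, fr_r)),
               "central_ring")
  # image-left of the fovea: temporal in a right eye, nasal in a left eye
  expect_equal(as.character(assign_region(fr_r$fovea_x - px2000,
                                          fr_r$fovea_y, fr_r)),
               "temporal")
  expect_equal(as.character(assign_region(fr_l$fovea_x - px2000,
                                          fr_l$fovea_y, fr_l)),
               "nasal")
  # far beyond the field circle
  expect_equal(as.character(assign_region(0, 0, fr_r)), "outside_field")
})

test_that("boundary rays are assigned deterministically to the clockwise wedge", {
  fr <- test_frame("right")
  d <- 1600 / 9  # outside the ring
  # exactly on the 45-degree ray (up-right): belongs to the horizontal wedge
  on45 <- assign_region(fr$fovea_x + d / sqrt(2), fr$fovea_y - d / sqrt(2), fr)
  expect_equal(as.character(on45), "nasal")
  # exactly on the 135-degree ray (up-left): belongs to superior
  on135 <- assign_region(fr$fovea_x - d / sqrt(2), fr$fovea_y - d / sqrt(2), fr)
  expect_equal(as.character(on135), "superior")
})

test_that("region assignment agrees with the scalar oracle on random points", {
  set.seed(101)
  for (side in c("right", "left")) {
    fr <- test_frame(side)
    n <- 2000
    x <- runif(n, 0, fr$width_px - 1)
    y <- runif(n, 0, fr$height_px - 1)
    got <- as.character(assign_region(x, y, fr))
    want <- vapply(seq_len(n), function(i) oracle_region(x[i], y[i], fr),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("laterality symmetry: flips swap temporal/nasal, full mirrors preserve labels", {
  set.seed(101)
  fr <- test_frame("right")
  w <- fr$width_px
  fr_m <- fundus_frame(w, fr$height_px, w - 1 - fr$fovea_x, fr$fovea_y,
                       w - 1 - fr$disc_x, fr$disc_y)
  expect_equal(fr_m$laterality, "left")
  n <- 2000
  x <- runif(n, 0, w - 1)
  y <- runif(n, 0, fr$height_px - 1)
  orig <- as.character(assign_region(x, y, fr))
  # same image positions, opposite eye: temporal and nasal swap, the
  # vertical wedges and ring/field status stay put
  flip <- as.character(assign_region(x, y, fr_m))
  swap <- c(superior = "superior", inferior = "inferior",
            temporal = "nasal", nasal = "temporal",
            central_ring = "central_ring", outside_field = "outside_field")
  expect_identical(flip, unname(swap[orig]))
  # mirroring frame AND marks together changes nothing anatomically: the
  # mirrored photo of a right eye reads as a left eye with identical labels
  mirr <- as.character(assign_region(w - 1 - x, y, fr_m))
  expect_identical(mirr, orig)
})

test_that("region counting partitions marks and matches per-point assignment", {
  fr <- test_frame("right")
  # empty input
  z <- count_by_region(data.frame(lesion_type = character(0),
                                  x_px = numeric(0), y_px = numeric(0)),
                       fr)
  expect_equal(sum(z$n_MA) + sum(z$n_HEM), 0)
  expect_equal(as.character(z$region), region_labels())

  # constructed placement: 3 MA superior, 1 HEM inferior
  px2000 <- 2000 / 9
  marks <- data.frame(
    lesion_type = c("MA", "MA", "MA", "HEM"),
    x_px = fr$fovea_x + c(0, 10, -10, 0),
    y_px = fr$fovea_y + c(-px2000, -px2000, -px2000, px2000))
  cc <- count_by_region(marks, fr)
  expect_equal(cc$n_MA[cc$region == "superior"], 3L)
  expect_equal(cc$n_HEM[cc$region == "inferior"], 1L)
  expect_equal(sum(cc$n_MA), 3L)
  expect_equal(sum(cc$n_HEM), 1L)

  # 500 uniform points agree with the brute-force oracle
  set.seed(101)
  n <- 500
  marks <- data.frame(lesion_type = sample(c("MA", "HEM"), n, replace = TRUE),
                      x_px = runif(n, 0, fr$width_px - 1),
                      y_px = runif(n, 0, fr$height_px - 1))
  cc <- count_by_region(marks, fr)
  expect_equal(sum(cc$n_MA) + sum(cc$n_HEM), n)
  want <- vapply(seq_len(n),
                 function(i) oracle_region(marks$x_px[i], marks$y_px[i], fr),
                 character(1))
  for (reg in region_labels()) {
    expect_equal(cc$n_MA[cc$region == reg],
                 sum(want == reg & marks$lesion_type == "MA"))
    expect_equal(cc$n_HEM[cc$region == reg],
                 sum(want == reg & marks$lesion_type == "HEM"))
  }
})

test_that("unknown lesion types are rejected with their row", {
  fr <- test_frame("right")
  marks <- data.frame(lesion_type = c("MA", "X"), x_px = c(1, 2),
                      y_px = c(1, 2))
  expect_error(count_by_region(marks, fr), "row\\(s\\) 2")
})

test_that("marks inside the central ring are never counted in a quadrant", {
  fr <- test_frame("right")
  set.seed(101)
  # points sprinkled within 750 um of the fovea
  r <- 750 / 9 * sqrt(runif(200))
  a <- runif(200, 0, 2 * pi)
  reg <- assign_region(fr$fovea_x + r * cos(a) * 0.999,
                       fr$fovea_y + r * sin(a) * 0.999, fr)
  expect_true(all(reg == "central_ring"))
})
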