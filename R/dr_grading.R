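.GRADE_LABELS <- c("NoDR", "Mild", "Moderate", "Severe")

#' MESSIDOR grading rule set
#'
#' Thresholds of the count-based MESSIDOR DR severity rules. With uA the
#' whole-image microaneurysm count, H the hemorrhage count and NV the
#' neovascularization flag:
#' \itemize{
#'   \item level 0 (NoDR): uA = 0 and H = 0
#'   \item level 1 (Mild): 0 < uA <= `mild_ma_max` and H = 0
#'   \item level 2 (Moderate): (`mild_ma_max` < uA < `moderate_ma_max` or
#'     0 < H < `moderate_hem_max`) and NV = 0
#'   \item level 3 (Severe): uA >= `moderate_ma_max` or
#'     H >= `moderate_hem_max` or NV = 1
#' }
#' The clauses overlap at their boundaries, so the severe clause is
#' evaluated first, then moderate, then mild.
#'
#' @param mild_ma_max largest uA still graded mild (default 5).
#' @param moderate_ma_max uA at which the grade becomes severe (default 15).
#' @param moderate_hem_max H at which the grade becomes severe (default 5).
#' @return list of class `grade_rules`.
#' @export
grade_rules <- function(mild_ma_max = 5, moderate_ma_max = 15,
                        moderate_hem_max = 5) {
  if (!(mild_ma_max > 0 && moderate_ma_max > mild_ma_max))
    stop("require 0 < mild_ma_max < moderate_ma_max")
  if (moderate_hem_max <= 0) stop("moderate_hem_max must be positive")
  structure(list(mild_ma_max = mild_ma_max,
                 moderate_ma_max = moderate_ma_max,
                 moderate_hem_max = moderate_hem_max),
            class = "grade_rules")
}

#' Grade DR severity from lesion counts
#'
#' Applies the MESSIDOR rules (see [grade_rules()]) to whole-image
#' microaneurysm and hemorrhage counts plus a neovascularization flag.
#' Severe is evaluated first, then moderate, then mild; anything left is
#' level 0. The function is total over non-negative integer inputs and
#' vectorized.
#'
#' @param mu_a microaneurysm count(s), non-negative integers.
#' @param h hemorrhage count(s), non-negative integers.
#' @param nv neovascularization flag(s), 0 or 1 (default 0).
#' @param rules a [grade_rules()] object.
#' @return data frame with columns `mu_a`, `h`, `nv`, `level` (integer
#'   0-3) and `label` (`NoDR`/`Mild`/`Moderate`/`Severe`).
#' @export
#' @examples
#' grade_from_counts(c(0, 5, 6, 15), c(0, 0, 0, 0))$level  # 0 1 2 3
#' grade_from_counts(0, 5)$label                           # "Severe"
grade_from_counts <- function(mu_a, h, nv = 0, rules = grade_rules()) {
  n <- max(length(mu_a), length(h), length(nv))
  mu_a <- rep_len(mu_a, n); h <- rep_len(h, n); nv <- rep_len(nv, n)
  if (any(mu_a < 0) || any(h < 0))
    stop("lesion counts must be non-negative")
  if (!all(nv %in% c(0, 1)))
    stop("nv must be 0 or 1")
  severe <- mu_a >= rules$moderate_ma_max | h >= rules$moderate_hem_max | nv == 1
  moderate <- !severe &
    ((mu_a > rules$mild_ma_max & mu_a < rules$moderate_ma_max) |
       (h > 0 & h < rules$moderate_hem_max)) & nv == 0
  mild <- !severe & !moderate &
    mu_a > 0 & mu_a <= rules$mild_ma_max & h == 0
  level <- integer(n)
  level[mild] <- 1L
  level[moderate] <- 2L
  level[severe] <- 3L
  data.frame(mu_a = mu_a, h = h, nv = nv, level = level,
             label = .GRADE_LABELS[level + 1L])
}

#' Grade one image from its lesion marks
#'
#' Totals the MA and HEM marks of an image (all regions inside the field —
#' the grading rules predate the quadrant division and use whole-image
#' counts) and applies [grade_from_counts()]. When a frame is supplied,
#' marks falling outside the 45-degree field circle are excluded from the
#' totals.
#'
#' @param marks data frame of lesion marks (`lesion_type`, `x_px`, `y_px`).
#' @param nv neovascularization flag, 0 or 1.
#' @param rules a [grade_rules()] object.
#' @param frame optional [fundus_frame()] used to drop out-of-field marks.
#' @return one-row data frame as returned by [grade_from_counts()].
#' @export
grade_image <- function(marks, nv = 0, rules = grade_rules(), frame = NULL) {
  validate_marks(marks, require_diameter = FALSE)
  if (!is.null(frame) && nrow(marks)) {
    region <- assign_region(marks$x_px, marks$y_px, frame)
    marks <- marks[region != "outside_field", , drop = FALSE]
  }
  grade_from_counts(sum(marks$lesion_type == "MA"),
                    sum(marks$lesion_type == "HEM"), nv, rules)
}
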