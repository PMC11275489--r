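#' Descriptive summary of a sample
#'
#' Sample size, mean, standard deviation (n - 1 denominator) and standard
#' error of the mean, the descriptive block reported per lesion type, DR
#' grade and quadrant.
#'
#' @param values numeric vector, length >= 2.
#' @return list of class `summary_stats` with fields `n`, `mean`, `sd`,
#'   `sem`.
#' @seealso [as_summary_stats()] to wrap printed summary statistics.
#' @export
#' @examples
#' summary_stats(c(1, 2, 3, 4, 5))
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (anyNA(values)) stop("values must not contain NA")
  as_summary_stats(mean(values), sd(values), length(values))
}

#' Wrap printed summary statistics
#'
#' Builds a `summary_stats` object from a reported mean, SD and n — the
#' form in which cohort tables print their cells — so that two-sample
#' t-tests can be recomputed from published numbers alone.
#'
#' @param mean,sd,n reported sample mean, standard deviation and size.
#' @return list of class `summary_stats`.
#' @export
#' @examples
#' as_summary_stats(5.50, 6.52, 261)
as_summary_stats <- function(mean, sd, n) {
  if (n < 2) stop("need n >= 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 sem = sd / sqrt(n)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g, sem = %.4g\n",
              x$n, x$mean, x$sd, x$sem))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the independent two-sample t statistic from two (mean, sd, n)
#' triples, either unpooled (Welch) or pooled. With equal group sizes the
#' two t values coincide; only the degrees of freedom (hence p) differ.
#' The p-value is two-sided.
#'
#' @param a,b `summary_stats` objects (see [summary_stats()],
#'   [as_summary_stats()]).
#' @param method `"welch"` (default) or `"pooled"`.
#' @return list of class `t_test_result` with fields `t`, `df`, `p`,
#'   `method`.
#' @export
#' @examples
#' # severe-DR temporal vs nasal microaneurysm counts, n = 261 per group
#' t_from_summary(as_summary_stats(5.50, 6.52, 261),
#'                as_summary_stats(1.86, 2.22, 261))
t_from_summary <- function(a, b, method = c("welch", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (method == "welch") {
    se <- sqrt(va + vb)
    df <- if (se > 0)
      (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1)) else NA_real_
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  delta <- a$mean - b$mean
  if (se == 0) {
    if (delta == 0)
      stop("t undefined: zero variance in both groups with equal means")
    t <- sign(delta) * Inf
    p <- 0
    if (method == "welch") df <- a$n + b$n - 2
  } else {
    t <- delta / se
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, method = method),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("two-sample t (%s): t = %.4g, df = %.4g, p = %.3g\n",
              x$method, x$t, x$df, x$p))
  invisible(x)
}

#' Two-sample t-test from raw values
#'
#' Summarizes each group with [summary_stats()] and delegates to
#' [t_from_summary()]; the two routes agree exactly (up to floating-point
#' round-off).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param method `"welch"` (default) or `"pooled"`.
#' @return list of class `t_test_result`.
#' @export
t_independent <- function(x, y, method = c("welch", "pooled")) {
  t_from_summary(summary_stats(x), summary_stats(y), method)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA across k independent groups
#' (F = MS_between / MS_within, upper-tail p). The fully degenerate case —
#' every value in every group identical — is reported as F = 0, p = 1 by
#' convention.
#'
#' @param groups list of numeric vectors, at least 2 groups of length
#'   >= 2 each.
#' @return list of class `anova_result` with fields `f`, `df_between`,
#'   `df_within`, `p`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(7, 8, 9)))
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 values")
  values <- as.numeric(unlist(groups, use.names = FALSE))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  n_tot <- length(values)
  if (all(values == values[1])) {
    return(structure(list(f = 0, df_between = k - 1L,
                          df_within = n_tot - k, p = 1),
                     class = "anova_result"))
  }
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  structure(list(f = unname(ow$statistic),
                 df_between = as.integer(unname(ow$parameter[1])),
                 df_within = as.integer(unname(ow$parameter[2])),
                 p = unname(ow$p.value)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

# Long lesion-count table (one row per image x quadrant x lesion type)
# from a quadrant_counts table plus a grade table. Internal reshaping used
# by build_report() and the pipeline.
counts_long <- function(counts, grades) {
  stopifnot(all(c("image_id", "region", "n_MA", "n_HEM") %in% names(counts)))
  stopifnot(all(c("image_id", "grade") %in% names(grades)))
  quad <- counts[counts$region %in% .QUADRANTS, , drop = FALSE]
  long <- rbind(
    data.frame(image_id = quad$image_id, region = quad$region,
               lesion = "MA", count = quad$n_MA),
    data.frame(image_id = quad$image_id, region = quad$region,
               lesion = "HEM", count = quad$n_HEM)
  )
  long$grade <- grades$grade[match(long$image_id, grades$image_id)]
  if (anyNA(long$grade))
    stop("every image in the counts table needs a grade")
  long$region <- factor(as.character(long$region), levels = .QUADRANTS)
  long$lesion <- factor(long$lesion, levels = .LESION_TYPES)
  long$grade <- factor(long$grade, levels = unique(grades$grade))
  long
}

#' Cohort report: per-grade per-quadrant statistics
#'
#' Builds the full statistical report for a graded cohort of per-image
#' quadrant counts: a summary grid (n, mean, SD, SEM per lesion type x DR
#' grade x quadrant), one-way ANOVA across the four quadrants within each
#' grade and across grades within each quadrant, and the pairwise
#' two-sample t table comparing a reference quadrant (temporal by default)
#' against each of the other three, per lesion type and grade. Quadrant
#' groups are treated as independent samples. No multiple-testing
#' correction is applied; p-values are raw.
#'
#' Grade x quadrant cells with no images are kept in the summary grid with
#' `n = 0` and `NA` statistics (explicit absence, not silent zeros) and are
#' skipped in the test tables.
#'
#' @param counts per-image region counts: data frame with columns
#'   `image_id`, `region`, `n_MA`, `n_HEM` (rows for all regions are
#'   accepted; only the four quadrants enter the report).
#' @param grades data frame with columns `image_id`, `grade` (character or
#'   factor; typically `Mild`/`Moderate`/`Severe`).
#' @param reference_quadrant quadrant used as reference in the pairwise
#'   t table (default `"temporal"`).
#' @param method t-test flavour, `"welch"` (default) or `"pooled"`; with
#'   the equal group sizes of quadrant comparisons the t value is identical
#'   for both.
#' @param database optional cohort name carried into the tables.
#' @return list of class `cohort_report` with elements `summary`,
#'   `anova_by_grade`, `anova_by_quadrant`, `pairwise_t`, plus the
#'   reference quadrant and method.
#' @export
build_report <- function(counts, grades, reference_quadrant = "temporal",
                         method = c("welch", "pooled"),
                         database = NA_character_) {
  method <- match.arg(method)
  reference_quadrant <- match.arg(reference_quadrant, .QUADRANTS)
  long <- counts_long(counts, grades)
  grade_levels <- levels(long$grade)

  cells <- expand.grid(lesion = .LESION_TYPES, grade = grade_levels,
                       quadrant = .QUADRANTS, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- long$count[long$lesion == cells$lesion[i] &
                      long$grade == cells$grade[i] &
                      long$region == cells$quadrant[i]]
    if (length(v) < 2) {
      data.frame(database = database, cells[i, ], n = length(v),
                 mean = NA_real_, sd = NA_real_, sem = NA_real_)
    } else {
      s <- summary_stats(v)
      data.frame(database = database, cells[i, ], n = s$n,
                 mean = s$mean, sd = s$sd, sem = s$sem)
    }
  }))
  row.names(summ) <- NULL

  grp <- function(lesion, grade, quadrant) {
    long$count[long$lesion == lesion & long$grade == grade &
                 long$region == quadrant]
  }

  anova_by_grade <- do.call(rbind, lapply(.LESION_TYPES, function(ltype) {
    do.call(rbind, lapply(grade_levels, function(g) {
      gs <- lapply(.QUADRANTS, grp, lesion = ltype, grade = g)
      if (any(lengths(gs) < 2)) return(NULL)
      a <- anova_oneway(gs)
      data.frame(database = database, lesion = ltype, grade = g,
                 f = a$f, df_between = a$df_between,
                 df_within = a$df_within, p = a$p)
    }))
  }))

  anova_by_quadrant <- do.call(rbind, lapply(.LESION_TYPES, function(ltype) {
    do.call(rbind, lapply(.QUADRANTS, function(q) {
      gs <- lapply(grade_levels, grp, lesion = ltype, quadrant = q)
      gs <- gs[lengths(gs) >= 2]
      if (length(gs) < 2) return(NULL)
      a <- anova_oneway(gs)
      data.frame(database = database, lesion = ltype, quadrant = q,
                 f = a$f, df_between = a$df_between,
                 df_within = a$df_within, p = a$p)
    }))
  }))

  others <- setdiff(.QUADRANTS, reference_quadrant)
  pairwise <- do.call(rbind, lapply(.LESION_TYPES, function(ltype) {
    do.call(rbind, lapply(grade_levels, function(g) {
      ref <- grp(ltype, g, reference_quadrant)
      if (length(ref) < 2) return(NULL)
      do.call(rbind, lapply(others, function(q) {
        other <- grp(ltype, g, q)
        if (length(other) < 2) return(NULL)
        tt <- if (sd(ref) == 0 && sd(other) == 0 &&
                  mean(ref) == mean(other)) {
          # fully degenerate comparison: identical constant groups
          list(t = 0, df = length(ref) + length(other) - 2, p = 1)
        } else {
          t_independent(ref, other, method)
        }
        data.frame(database = database, lesion = ltype, grade = g,
                   comparison = paste(reference_quadrant, "vs", q),
                   t = tt$t, df = tt$df, p = tt$p)
      }))
    }))
  }))

  structure(list(summary = summ,
                 anova_by_grade = anova_by_grade,
                 anova_by_quadrant = anova_by_quadrant,
                 pairwise_t = pairwise,
                 reference_quadrant = reference_quadrant,
                 method = method,
                 database = database),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Cohort report",
      if (!is.na(x$database)) paste0("(", x$database, ")"), "\n")
  cat("\nPer-grade per-quadrant summaries (mean +/- SD):\n")
  s <- x$summary
  for (ltype in unique(s$lesion)) {
    cat(" ", ltype, "\n")
    sub <- s[s$lesion == ltype, ]
    wide <- sapply(split(sub, sub$quadrant), function(d)
      ifelse(d$n < 2, "--",
             sprintf("%.2f +/- %.2f", d$mean, d$sd)))
    rownames(wide) <- unique(sub$grade)
    print(wide[, .QUADRANTS, drop = FALSE], quote = FALSE)
  }
  cat(sprintf("\nPairwise t (%s, reference %s):\n",
              x$method, x$reference_quadrant))
  print(format(x$pairwise_t, digits = digits), row.names = FALSE)
  invisible(x)
}
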