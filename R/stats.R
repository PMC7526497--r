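#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected Pearson chi-squared (1 df) on a 2x2 contingency table of
#' cohort (rows) versus in-category / not-in-category (columns). No Yates
#' continuity correction is applied: only the uncorrected statistic
#' reproduces the published per-category p-values from the published
#' junction counts. The statistic is computed in closed form,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param a,b,c,d Cell counts; alternatively `a` may be a 2x2 matrix.
#' @return An object of class `sj_test` with fields `statistic`, `df`,
#'   `p.value`, `method`, `table`. `tidy()` and `glance()` methods are
#'   provided.
#' @examples
#' chisq_2x2(4, 78, 34, 179)  # p = 0.0109
#' @export
chisq_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2L, 2L)
  }
  storage.mode(tab) <- "double"
  if (any(tab < 0) || anyNA(tab)) stop("cell counts must be non-negative",
                                       call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a row or column marginal is zero", call. = FALSE)
  }
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  stat <- num / den
  new_sj_test(statistic = stat, df = 1L,
              p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
              method = "Pearson chi-squared (2x2, no continuity correction)",
              table = tab)
}

#' Compare two cohorts per repair-pattern category
#'
#' For each junction category, builds the 2x2 table (in-category vs rest,
#' cohort a vs cohort b) and applies the uncorrected Pearson chi-squared
#' test ([chisq_2x2()]), mirroring per-category comparison of repair
#' patterns between patient and control cohorts. Categories with a zero
#' column marginal (absent from both cohorts) get `NA` results.
#'
#' No multiple-testing adjustment is applied by default, matching
#' per-category reporting; `adjust = "holm"` is available for new analyses.
#'
#' @param a,b Cohort tables from [summarize_cohort()]/[cohort_table()], or
#'   numeric count vectors of length 4 (direct, insertion, mh_1_6,
#'   mh_ge7).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble of class `sj_comparison`: `class`, `count_a`,
#'   `total_a`, `count_b`, `total_b`, `prop_a`, `prop_b`, `direction`
#'   (change in cohort a relative to b), `statistic`, `p_value` (and
#'   `p_adj` when adjusted).
#' @examples
#' icf2 <- cohort_table(c(4, 11, 34, 33), "ICF2")
#' ctrl <- cohort_table(c(34, 52, 77, 50), "controls")
#' compare_categories(icf2, ctrl)
#' @export
compare_categories <- function(a, b, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  ca <- as_counts(a); cb <- as_counts(b)
  ta <- sum(ca$count); tb <- sum(cb$count)
  stopifnot(identical(as.character(ca$class), as.character(cb$class)))
  rows <- purrr::map(seq_along(ca$count), function(i) {
    ka <- ca$count[i]; kb <- cb$count[i]
    res <- if (ka + kb == 0L || (ta - ka) + (tb - kb) == 0L) {
      list(statistic = NA_real_, p.value = NA_real_)
    } else {
      t <- chisq_2x2(ka, ta - ka, kb, tb - kb)
      list(statistic = t$statistic, p.value = t$p.value)
    }
    pa <- ka / ta; pb <- kb / tb
    tibble::tibble(
      class = as.character(ca$class)[i],
      count_a = ka, total_a = ta, count_b = kb, total_b = tb,
      prop_a = pa, prop_b = pb,
      direction = if (pa > pb) "up" else if (pa < pb) "down" else "none",
      statistic = res$statistic, p_value = res$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$class <- factor(out$class, levels = junction_classes)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p_value, "holm")
  class(out) <- c("sj_comparison", class(out))
  out
}

as_counts <- function(x) {
  if (inherits(x, "sj_cohort_table") ||
      (is.data.frame(x) && all(c("class", "count") %in% names(x)))) {
    stopifnot(identical(as.character(x$class), junction_classes))
    list(class = x$class, count = as.integer(x$count))
  } else if (is.numeric(x) && length(x) == 4L) {
    list(class = factor(junction_classes, levels = junction_classes),
         count = as.integer(x))
  } else {
    stop("expected a cohort table or a length-4 count vector", call. = FALSE)
  }
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples of junction characteristics (e.g.
#' deletion counts or N-nucleotide numbers). The statistic is the U of the
#' first sample. The p-value is exact (doubled one-sided tail of the exact
#' null distribution, capped at 1) when `m * n <= 400` and there are no
#' ties, and otherwise uses the normal approximation with tie correction
#' (no continuity correction).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return An `sj_test` object with fields `statistic` (U), `p.value`,
#'   `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && m * n <= 400) {
    p1 <- if (U > m * n / 2) {
      stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      stats::pwilcox(U, m, n)
    }
    p <- min(1, 2 * p1)
    method <- "Mann-Whitney U (exact, doubled one-sided tail)"
  } else {
    tt <- table(c(x, y))
    sigma2 <- m * n / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - m * n / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  new_sj_test(statistic = U, df = NA_integer_, p.value = p, method = method,
              table = NULL)
}

#' Plasmid-integration NHEJ efficiency
#'
#' Raw end-joining efficiency of a stable plasmid-integration assay:
#' `(cloning efficiency under selection) / ((cloning efficiency without
#' selection) * (transfection efficiency))`, optionally normalized to a
#' control condition measured the same way.
#'
#' @param selected,unselected,transfection Fractions in (0, 1]: cloning
#'   efficiency with selection, cloning efficiency without selection, and
#'   transfection efficiency. Vectorized.
#' @param control Either `NULL` (raw efficiency returned), a numeric
#'   length-3 vector `(selected, unselected, transfection)` for the control
#'   condition, or a single precomputed raw control efficiency.
#' @return Numeric efficiency (relative to control when given).
#' @examples
#' plasmid_integration_efficiency(0.05, 0.5, 0.8, control = 0.25)  # 0.5
#' @export
plasmid_integration_efficiency <- function(selected, unselected, transfection,
                                           control = NULL) {
  check_frac <- function(x, nm) {
    if (any(is.na(x)) || any(x <= 0) || any(x > 1)) {
      stop(nm, " must be in (0, 1]", call. = FALSE)
    }
  }
  check_frac(selected, "selected"); check_frac(unselected, "unselected")
  check_frac(transfection, "transfection")
  raw <- selected / (unselected * transfection)
  if (is.null(control)) return(raw)
  ctrl_raw <- if (length(control) == 3L) {
    check_frac(control, "control")
    control[[1]] / (control[[2]] * control[[3]])
  } else if (length(control) == 1L) {
    if (control <= 0) stop("control efficiency must be positive",
                           call. = FALSE)
    control
  } else {
    stop("control must be NULL, a length-3 triple, or a raw efficiency",
         call. = FALSE)
  }
  raw / ctrl_raw
}

#' Relative accumulation at laser-induced damage sites
#'
#' Background-corrected protein accumulation in a laser track expressed
#' relative to the nucleoplasmic level:
#' `(I_damage - I_background) / (I_nucleoplasm - I_background) - 1`.
#' Zero means no enrichment over the nucleoplasm.
#'
#' @param i_damage,i_nucleoplasm,i_background Mean pixel intensities
#'   (arbitrary units). Vectorized; requires
#'   `i_nucleoplasm > i_background`.
#' @return Numeric relative accumulation.
#' @examples
#' relative_accumulation(200, 100, 50)  # 2
#' @export
relative_accumulation <- function(i_damage, i_nucleoplasm, i_background) {
  if (any(i_nucleoplasm <= i_background)) {
    stop("invalid measurement: i_nucleoplasm must exceed i_background",
         call. = FALSE)
  }
  (i_damage - i_background) / (i_nucleoplasm - i_background) - 1
}

new_sj_test <- function(statistic, df, p.value, method, table = NULL) {
  structure(list(statistic = unname(statistic), df = df,
                 p.value = unname(p.value), method = method, table = table),
            class = "sj_test")
}

#' @export
print.sj_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("statistic =", format(x$statistic, digits = 6),
      if (!is.na(x$df)) paste0("(df = ", x$df, ")") else "",
      " p =", format(round(x$p.value, 4), nsmall = 4), "\n")
  invisible(x)
}

#' @rdname chisq_2x2
#' @param x An `sj_test` object.
#' @param ... Unused.
#' @export
tidy.sj_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 method = x$method)
}

#' @rdname chisq_2x2
#' @export
glance.sj_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n = if (is.null(x$table)) NA_integer_ else
                   as.integer(sum(x$table)),
                 method = x$method)
}

#' @rdname compare_categories
#' @param x An `sj_comparison` object.
#' @param ... Unused.
#' @export
glance.sj_comparison <- function(x, ...) {
  tibble::tibble(n_categories = nrow(x), total_a = x$total_a[1],
                 total_b = x$total_b[1],
                 min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}
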