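junction_classes <- c("direct", "insertion", "mh_1_6", "mh_ge7")

#' Classify a junction into the four repair-pattern categories
#'
#' Maps microhomology length and insertion content to the canonical
#' four-category scheme used to characterize CSR junctions: junctions with
#' untemplated inserted bases are `"insertion"`; otherwise zero
#' microhomology is `"direct"` (blunt end-joining), 1-6 bp is `"mh_1_6"`,
#' and 7 bp or more is `"mh_ge7"`. A junction with both an insertion and
#' incidental flanking homology counts as `"insertion"` (the categories
#' partition the calls; insertions sit under the 0 bp homology column).
#'
#' @param mh_len Integer vector of microhomology lengths.
#' @param insertion_seq Character vector of untemplated insertions (`""`
#'   when absent).
#' @return A factor with levels `direct`, `insertion`, `mh_1_6`, `mh_ge7`.
#' @examples
#' classify_junction(c(0, 9, 0), c("", "", "GA"))
#' @export
classify_junction <- function(mh_len, insertion_seq = "") {
  n <- max(length(mh_len), length(insertion_seq))
  mh_len <- rep_len(as.integer(mh_len), n)
  insertion_seq <- rep_len(as.character(insertion_seq), n)
  if (anyNA(mh_len) || anyNA(insertion_seq)) {
    stop("classify requires a successful call (no NA fields)", call. = FALSE)
  }
  stopifnot(all(mh_len >= 0))
  lab <- ifelse(nzchar(insertion_seq), "insertion",
                ifelse(mh_len == 0L, "direct",
                       ifelse(mh_len <= 6L, "mh_1_6", "mh_ge7")))
  factor(lab, levels = junction_classes)
}

#' Add repair-pattern classes to a calls table
#'
#' Uncallable reads are dropped with a message; callable calls receive a
#' `class` column via [classify_junction()].
#'
#' @param calls A calls tibble from [call_junctions()].
#' @return The callable subset of `calls` with a `class` factor column.
#' @export
classify_calls <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("mh_len", "insertion_seq") %in% names(calls)))
  if ("callable" %in% names(calls) && any(!calls$callable)) {
    message(sum(!calls$callable), " uncallable read(s) excluded from ",
            "classification")
    calls <- dplyr::filter(calls, .data$callable)
  }
  dplyr::mutate(calls,
                class = classify_junction(.data$mh_len, .data$insertion_seq))
}

# Round half away from zero; R's round() rounds half to even, which does
# not reproduce the printed cohort percentages.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize junction classes for one cohort
#'
#' Counts junctions per repair-pattern category and computes integer
#' percentages (rounded half away from zero) of the cohort total.
#'
#' @param classes A factor/character vector of class labels (see
#'   [classify_junction()]), or a data frame with a `class` column.
#' @param cohort Cohort label for the output.
#' @return A tibble of class `sj_cohort_table` with columns `cohort`,
#'   `class`, `count`, `percent`, `total` (one row per category; counts sum
#'   to `total`).
#' @export
summarize_cohort <- function(classes, cohort = "cohort") {
  if (is.data.frame(classes)) {
    stopifnot("class" %in% names(classes))
    classes <- classes$class
  }
  if (length(classes) == 0L) {
    stop("cannot summarize an empty cohort", call. = FALSE)
  }
  classes <- factor(as.character(classes), levels = junction_classes)
  if (anyNA(classes)) stop("unknown junction class label", call. = FALSE)
  counts <- as.integer(table(classes))
  total <- length(classes)
  out <- tibble::tibble(cohort = cohort,
                        class = factor(junction_classes,
                                       levels = junction_classes),
                        count = counts,
                        percent = as.integer(round_half_up(100 * counts / total)),
                        total = total)
  class(out) <- c("sj_cohort_table", class(out))
  out
}

#' Build a cohort table directly from category counts
#'
#' Convenience constructor for published count vectors (e.g. the packaged
#' CSR junction table, [csr_junction_table1()]).
#'
#' @param counts Numeric vector of length 4 in the order direct,
#'   insertion, mh_1_6, mh_ge7 (names, if present, are checked).
#' @param cohort Cohort label.
#' @return An `sj_cohort_table` tibble (see [summarize_cohort()]).
#' @examples
#' cohort_table(c(4, 11, 34, 33), "ICF2")
#' @export
cohort_table <- function(counts, cohort = "cohort") {
  stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) >= 1)
  if (!is.null(names(counts))) {
    stopifnot(identical(names(counts), junction_classes))
  }
  counts <- as.integer(counts)
  total <- sum(counts)
  out <- tibble::tibble(cohort = cohort,
                        class = factor(junction_classes,
                                       levels = junction_classes),
                        count = counts,
                        percent = as.integer(round_half_up(100 * counts / total)),
                        total = total)
  class(out) <- c("sj_cohort_table", class(out))
  out
}

#' Summarize junction classes for several cohorts
#'
#' @param calls A classified calls tibble (see [classify_calls()]) with a
#'   `cohort` column.
#' @return An `sj_cohort_table` tibble with one row per cohort and
#'   category.
#' @export
summarize_cohorts <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("class", "cohort") %in% names(calls)))
  out <- dplyr::bind_rows(lapply(split(calls, calls$cohort), function(g) {
    summarize_cohort(g$class, cohort = g$cohort[[1]])
  }))
  class(out) <- c("sj_cohort_table", class(out))
  out
}

#' Bin reporter-junction deletion sizes
#'
#' Counts deletion lengths into half-open bins `[e1, e2), [e2, e3), ...`
#' with the final bin open-ended. Default edges `c(0, 1, 11, 21)` give the
#' bins 0, 1-10, 11-20 and >= 21 nt.
#'
#' @param calls A reporter-calls tibble (see [call_reporter_junctions()])
#'   or a numeric vector of deletion lengths.
#' @param edges Strictly increasing integer bin edges, starting at 0.
#' @return A tibble of class `sj_del_bins` with columns `bin` (factor),
#'   `count`.
#' @export
bin_deletion_sizes <- function(calls, edges = c(0, 1, 11, 21)) {
  del <- if (is.data.frame(calls)) calls$deletion_len else calls
  del <- del[!is.na(del)]
  stopifnot(all(del >= 0), length(edges) >= 2L, edges[1] == 0,
            all(diff(edges) > 0))
  labs <- c(
    vapply(seq_len(length(edges) - 1L), function(i) {
      lo <- edges[i]; hi <- edges[i + 1L] - 1L
      if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
    }, character(1)),
    paste0(">=", edges[length(edges)]))
  b <- cut(del, breaks = c(edges, Inf), right = FALSE, labels = labs)
  out <- tibble::tibble(bin = factor(labs, levels = labs),
                        count = as.integer(table(b)))
  class(out) <- c("sj_del_bins", class(out))
  out
}

#' Microhomology usage among deletion-bearing reporter junctions
#'
#' Restricts to calls with `deletion_len > 0` and tabulates their
#' microhomology lengths — the deletion-associated microhomology-usage
#' signature of alternative end-joining.
#'
#' @param calls A reporter-calls tibble (see [call_reporter_junctions()]).
#' @return A tibble of class `sj_mh_usage` with columns `mh_len`, `count`
#'   (empty when no deletions are present).
#' @export
mh_usage_in_deletions <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("deletion_len", "mh_len") %in% names(calls)))
  dels <- dplyr::filter(calls, !is.na(.data$deletion_len),
                        .data$deletion_len > 0)
  out <- if (nrow(dels) == 0L) {
    tibble::tibble(mh_len = integer(0), count = integer(0))
  } else {
    dplyr::count(dels, mh_len = .data$mh_len, name = "count")
  }
  class(out) <- c("sj_mh_usage", class(out))
  out
}

#' Published characterization of CSR junctions (worked example)
#'
#' The packaged worked example: per-cohort counts of S-mu to S-alpha and
#' S-mu to S-gamma switch junctions in the four repair-pattern categories,
#' for ICF2 (ZBTB24-deficient), LIG4-deficient and Artemis-deficient
#' patients and healthy-children controls.
#'
#' @return A tibble with columns `region`, `cohort`, `class`, `count`.
#' @examples
#' t1 <- csr_junction_table1()
#' icf2 <- cohort_table(t1$count[t1$region == "Smu-Salpha" &
#'                               t1$cohort == "ICF2"], "ICF2")
#' @export
csr_junction_table1 <- function() {
  cls <- factor(junction_classes, levels = junction_classes)
  rows <- list(
    list("Smu-Salpha", "ICF2",     c(4L, 11L, 34L, 33L)),
    list("Smu-Salpha", "LIG4",     c(1L, 0L, 11L, 18L)),
    list("Smu-Salpha", "Artemis",  c(0L, 6L, 18L, 30L)),
    list("Smu-Salpha", "controls", c(34L, 52L, 77L, 50L)),
    list("Smu-Sgamma", "ICF2",     c(9L, 3L, 34L, 0L)),
    list("Smu-Sgamma", "LIG4",     c(4L, 11L, 19L, 0L)),
    list("Smu-Sgamma", "Artemis",  c(5L, 4L, 15L, 0L)),
    list("Smu-Sgamma", "controls", c(13L, 9L, 36L, 0L)))
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(region = r[[1]], cohort = r[[2]], class = cls,
                   count = r[[3]])
  }))
}
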