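#' Alignment and calling parameters
#'
#' Scoring and threshold parameters for the breakpoint caller. The flanks of
#' a junction read are aligned semi-globally (free at the junction side and
#' at the amplicon end) with affine gaps; a gap of length g costs
#' `gap_open + g * gap_extend`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch penalty (< 0). `N` scores as mismatch to
#'   everything.
#' @param gap_open Gap opening penalty (< 0), charged once per gap.
#' @param gap_extend Gap extension penalty (< 0), charged per gapped base.
#' @param min_flank Minimum aligned flank length in read bases; reads whose
#'   donor or acceptor flank would be shorter are called uncallable. Guards
#'   against spurious splits in repeat-rich switch regions.
#' @param footprint_min_len Minimum read-span (nt) of an intermediate
#'   switch-region segment for a sequential-switching footprint.
#' @param footprint_min_ident Minimum identity of the intermediate segment.
#' @param try_revcomp If `TRUE`, also try the reverse complement of each
#'   read (with donor/acceptor roles preserved) and keep the orientation
#'   with the better total score.
#' @return A list of class `sj_params`.
#' @export
caller_params <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                          gap_extend = -1L, min_flank = 15L,
                          footprint_min_len = 15L,
                          footprint_min_ident = 0.90,
                          try_revcomp = FALSE) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  min_flank <- as.integer(min_flank)
  footprint_min_len <- as.integer(footprint_min_len)
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            min_flank >= 1, footprint_min_len >= 1,
            footprint_min_ident > 0, footprint_min_ident <= 1,
            is.logical(try_revcomp))
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_flank = min_flank,
                 footprint_min_len = footprint_min_len,
                 footprint_min_ident = footprint_min_ident,
                 try_revcomp = try_revcomp),
            class = "sj_params")
}

#' Perfectly matched microhomology at a junction
#'
#' Computes the length of the perfectly matched short homology spanning a
#' junction: the maximal `l` such that `donor[donor_end - l, donor_end)`
#' equals `acceptor[acceptor_start - l, acceptor_start)` plus the maximal
#' `r` such that `donor[donor_end, donor_end + r)` equals
#' `acceptor[acceptor_start, acceptor_start + r)`. Matches must be perfect;
#' `N` never matches. The result is invariant to which equivalent junction
#' placement inside the homology window is supplied.
#'
#' @param donor,acceptor Reference sequences (character scalar or one-row
#'   data frame with `name`/`seq`).
#' @param donor_end 0-based index of the first donor base *not* used by the
#'   read.
#' @param acceptor_start 0-based index of the first acceptor base used.
#' @return Integer microhomology length (>= 0).
#' @examples
#' compute_microhomology("AACCGTGT", 8, "GTGTTTAA", 4) # 4
#' @export
compute_microhomology <- function(donor, donor_end, acceptor, acceptor_start) {
  d <- as_ref(donor, "donor"); a <- as_ref(acceptor, "acceptor")
  donor_end <- as.integer(donor_end)
  acceptor_start <- as.integer(acceptor_start)
  stopifnot(donor_end >= 0, donor_end <= nchar(d$seq),
            acceptor_start >= 0, acceptor_start <= nchar(a$seq))
  mh_len_cpp(d$seq, donor_end, a$seq, acceptor_start)
}

#' Call the breakpoint of a single junction read
#'
#' Splits the read into a donor prefix, an optional untemplated insertion,
#' and an acceptor suffix, maximizing the total alignment score. Each flank
#' is aligned semi-globally (global in the read flank, free at both ends in
#' the reference) with affine gaps; insertion bases at the junction are
#' unaligned and score 0, so a junction base is absorbed into a flank only
#' if it extends it by a matching base. Microhomology is computed post hoc
#' at the called coordinates with [compute_microhomology()]; a junction
#' carrying an insertion is recorded with `mh_len = 0` so that the four
#' repair-pattern categories partition the calls.
#'
#' Ties between equally scoring splits are broken by a total order: larger
#' microhomology first, then the donor-maximal junction placement (largest
#' `donor_end`, largest `acceptor_start`), then the shorter insertion —
#' making calls deterministic.
#'
#' A read is *uncallable* when no split with both flanks of at least
#' `min_flank` read bases achieves a positive alignment score on both
#' sides; such reads are flagged (`callable = FALSE`) and are excluded from
#' classification.
#'
#' @param read_seq Read sequence (character scalar).
#' @param donor,acceptor References (character scalar or one-row data frame
#'   with `name`/`seq`).
#' @param params A [caller_params()] object.
#' @param read_id,cohort Identifiers carried into the output row.
#' @return A one-row tibble: `read_id`, `cohort`, `callable`, `donor_name`,
#'   `donor_end`, `acceptor_name`, `acceptor_start`, `mh_len`,
#'   `insertion_seq`, `n_mismatch_flank`, `footprint_ref`, `score`,
#'   `strand`.
#' @examples
#' call_breakpoint("AACCGTGTTTAA", "AACCGTGT", "GTGTTTAA",
#'                 caller_params(min_flank = 2))
#' @export
call_breakpoint <- function(read_seq, donor, acceptor,
                            params = caller_params(), read_id = "read",
                            cohort = NA_character_) {
  d <- as_ref(donor, "donor"); a <- as_ref(acceptor, "acceptor")
  read_seq <- canonicalize_seq(read_seq, read_id)
  best <- call_core(read_seq, d$seq, a$seq, params)
  best$strand <- "+"
  if (isTRUE(params$try_revcomp)) {
    alt <- call_core(revcomp(read_seq), d$seq, a$seq, params)
    alt$strand <- "-"
    if ((alt$callable && !best$callable) ||
        (alt$callable && best$callable && alt$score > best$score)) {
      best <- alt
    }
  }
  tibble::tibble(
    read_id = read_id, cohort = cohort, callable = best$callable,
    donor_name = d$name, donor_end = best$donor_end,
    acceptor_name = a$name, acceptor_start = best$acceptor_start,
    mh_len = best$mh_len, insertion_seq = best$insertion_seq,
    n_mismatch_flank = best$n_mismatch_flank,
    footprint_ref = NA_character_, score = best$score,
    strand = if (is.null(best$strand)) "+" else best$strand
  )
}

# Core split search on canonical sequences. Returns a list; uncallable
# results carry NA coordinates.
call_core <- function(read_seq, donor_seq, acceptor_seq, params) {
  uncallable <- list(callable = FALSE, donor_end = NA_integer_,
                     acceptor_start = NA_integer_, mh_len = NA_integer_,
                     insertion_seq = NA_character_,
                     n_mismatch_flank = NA_integer_, score = NA_integer_)
  L <- nchar(read_seq)
  mf <- params$min_flank
  if (L < 2L * mf) return(uncallable)

  D <- flank_dp_cpp(read_seq, donor_seq, params$match, params$mismatch,
                    params$gap_open, params$gap_extend)
  Arev <- flank_dp_cpp(rev_str(read_seq), rev_str(acceptor_seq),
                       params$match, params$mismatch,
                       params$gap_open, params$gap_extend)

  # Dv[i]: donor flank = read[1..i]; Av[k]: acceptor flank = read[(k+1)..L]
  Dv <- rep(-Inf, L + 1L)
  idx_i <- mf:(L - mf)
  Dv[idx_i + 1L] <- D$score[idx_i + 1L]
  Dv[Dv <= 0] <- -Inf
  Av <- rep(-Inf, L + 1L)
  idx_k <- 0L:(L - mf)
  Av[idx_k + 1L] <- Arev$score[L - idx_k + 1L]
  Av[Av <= 0] <- -Inf
  Av[seq_len(mf)] <- -Inf  # k < min_flank would imply donor flank < min_flank

  # suffix maximum of Av over k >= i
  suf <- rev(cummax(rev(Av)))
  tot <- Dv + suf
  T_best <- max(tot)
  if (!is.finite(T_best)) return(uncallable)

  cand_i <- which(tot == T_best) - 1L
  cands <- list()
  for (i in cand_i) {
    need <- T_best - Dv[i + 1L]
    ks <- which(Av == need) - 1L
    ks <- ks[ks >= i]
    for (k in ks) {
      de <- D$ref_end[i + 1L]
      as_ <- nchar(acceptor_seq) - Arev$ref_end[L - k + 1L]
      ins <- if (k > i) substr(read_seq, i + 1L, k) else ""
      mh <- if (nzchar(ins)) 0L else mh_len_cpp(donor_seq, de, acceptor_seq, as_)
      cands[[length(cands) + 1L]] <- list(
        donor_end = de, acceptor_start = as_, mh_len = mh,
        insertion_seq = ins,
        n_mismatch_flank = D$n_mismatch[i + 1L] + Arev$n_mismatch[L - k + 1L])
      if (length(cands) >= 5000L) break
    }
    if (length(cands) >= 5000L) break
  }

  ord <- order(-vapply(cands, `[[`, integer(1), "mh_len"),
               -vapply(cands, `[[`, integer(1), "donor_end"),
               -vapply(cands, `[[`, integer(1), "acceptor_start"),
               nchar(vapply(cands, `[[`, character(1), "insertion_seq")))
  best <- cands[[ord[1L]]]
  c(list(callable = TRUE, score = as.integer(T_best)), best)
}

rev_str <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Detect a sequential-switching footprint
#'
#' Given a read with a successful two-part (donor + acceptor) call, attempts
#' a three-part segmentation donor -> intermediate -> acceptor for each
#' candidate intermediate switch region. The intermediate segment is the
#' best local alignment of the read against the intermediate reference; a
#' footprint is reported when that segment spans at least
#' `footprint_min_len` read bases with identity at least
#' `footprint_min_ident` and the three-part total score strictly exceeds
#' the two-part score.
#'
#' @inheritParams call_breakpoint
#' @param intermediates A data frame of intermediate references (columns
#'   `name`, `seq`), e.g. the S-gamma-3 region for S-mu to S-gamma-2
#'   junctions.
#' @param two_part_score Total score of the two-part call (from
#'   [call_breakpoint()]); computed internally when `NULL`.
#' @return A one-row tibble `footprint_ref`, `seg_start`, `seg_end`,
#'   `identity`, `three_part_score` (NA row when no footprint is detected).
#' @export
detect_sequential_footprint <- function(read_seq, donor, acceptor,
                                        intermediates,
                                        params = caller_params(),
                                        two_part_score = NULL) {
  d <- as_ref(donor, "donor"); a <- as_ref(acceptor, "acceptor")
  read_seq <- canonicalize_seq(read_seq, "read")
  stopifnot(is.data.frame(intermediates),
            all(c("name", "seq") %in% names(intermediates)))
  none <- tibble::tibble(footprint_ref = NA_character_, seg_start = NA_integer_,
                         seg_end = NA_integer_, identity = NA_real_,
                         three_part_score = NA_integer_)
  if (is.null(two_part_score)) {
    core <- call_core(read_seq, d$seq, a$seq, params)
    if (!core$callable) return(none)
    two_part_score <- core$score
  }
  L <- nchar(read_seq); mf <- params$min_flank
  if (L < 2L * mf) return(none)

  D <- flank_dp_cpp(read_seq, d$seq, params$match, params$mismatch,
                    params$gap_open, params$gap_extend)
  Arev <- flank_dp_cpp(rev_str(read_seq), rev_str(a$seq), params$match,
                       params$mismatch, params$gap_open, params$gap_extend)
  Dv <- rep(-Inf, L + 1L); Dv[(mf:L) + 1L] <- D$score[(mf:L) + 1L]
  Dv[Dv <= 0] <- -Inf
  Av <- rep(-Inf, L + 1L)
  Av[(0L:(L - mf)) + 1L] <- Arev$score[L - (0L:(L - mf)) + 1L]
  Av[Av <= 0] <- -Inf
  pre_max <- cummax(Dv)            # over donor flank length <= a
  suf_max <- rev(cummax(rev(Av)))  # over acceptor suffix start >= b

  best <- none; best_score <- -Inf
  for (r in seq_len(nrow(intermediates))) {
    iseq <- canonicalize_seq(intermediates$seq[[r]], intermediates$name[[r]])
    loc <- local_dp_cpp(read_seq, iseq, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
    seg_len <- loc$read_end - loc$read_start
    if (seg_len < params$footprint_min_len) next
    ident <- if (loc$n_col > 0) loc$n_match / loc$n_col else 0
    if (ident < params$footprint_min_ident) next
    left <- pre_max[loc$read_start + 1L]
    right <- suf_max[loc$read_end + 1L]
    if (!is.finite(left) || !is.finite(right)) next
    t3 <- left + loc$score + right
    if (t3 > two_part_score && t3 > best_score) {
      best_score <- t3
      best <- tibble::tibble(footprint_ref = intermediates$name[[r]],
                             seg_start = loc$read_start,
                             seg_end = loc$read_end, identity = ident,
                             three_part_score = as.integer(t3))
    }
  }
  best
}

#' Call breakpoints for a table of junction reads
#'
#' Data-frame-first wrapper around [call_breakpoint()] (and optionally
#' [detect_sequential_footprint()]): one call row per read.
#'
#' @param reads A data frame with columns `read_id`, `seq` and optionally
#'   `cohort`.
#' @param donor,acceptor References (character scalar or one-row data frame
#'   with `name`/`seq`).
#' @param intermediates Optional data frame of intermediate references for
#'   sequential-switching footprint detection.
#' @param params A [caller_params()] object.
#' @return A tibble of breakpoint calls, one row per read.
#' @export
call_junctions <- function(reads, donor, acceptor, intermediates = NULL,
                           params = caller_params()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  cohorts <- if ("cohort" %in% names(reads)) reads$cohort else
    rep(NA_character_, nrow(reads))
  calls <- purrr::map(seq_len(nrow(reads)), function(i) {
    row <- call_breakpoint(reads$seq[[i]], donor, acceptor, params,
                           read_id = reads$read_id[[i]],
                           cohort = cohorts[[i]])
    if (!is.null(intermediates) && row$callable) {
      fp <- detect_sequential_footprint(reads$seq[[i]], donor, acceptor,
                                        intermediates, params,
                                        two_part_score = row$score)
      row$footprint_ref <- fp$footprint_ref
    }
    row
  })
  dplyr::bind_rows(calls)
}

#' Call a repair junction in a cut reporter
#'
#' Treats `reporter[0, cut_left)` as the donor side and
#' `reporter[cut_right, end)` as the acceptor side of the reconstructed cut
#' reporter (the cassette between the two nuclease sites is excised), calls
#' the junction as in [call_breakpoint()], and reports the total deletion
#' relative to perfect religation:
#' `deletion_len = (cut_left - donor_end) + (acceptor_start_global -
#' cut_right)`. Junctions are labelled `"deletion"` when `deletion_len >
#' 0`, otherwise `"insertion"` when untemplated bases are present,
#' otherwise `"blunt"`.
#'
#' @param read_seq Read sequence.
#' @param reporter Reporter reference (character scalar or one-row data
#'   frame with `name`/`seq`).
#' @param cut_left,cut_right 0-based cut coordinates delimiting the excised
#'   cassette (`cut_left < cut_right`).
#' @inheritParams call_breakpoint
#' @return A one-row tibble: `read_id`, `callable`, `donor_end`,
#'   `acceptor_start_global`, `deletion_len`, `mh_len`, `insertion_seq`,
#'   `n_mismatch_flank`, `score`, `class_label`.
#' @export
call_reporter_junction <- function(read_seq, reporter, cut_left, cut_right,
                                   params = caller_params(),
                                   read_id = "read") {
  rep_ref <- as_ref(reporter, "reporter")
  cut_left <- as.integer(cut_left); cut_right <- as.integer(cut_right)
  n <- nchar(rep_ref$seq)
  stopifnot(cut_left >= 1, cut_right > cut_left, cut_right < n)
  donor_seq <- substr(rep_ref$seq, 1L, cut_left)
  acceptor_seq <- substr(rep_ref$seq, cut_right + 1L, n)
  read_seq <- canonicalize_seq(read_seq, read_id)
  core <- call_core(read_seq, donor_seq, acceptor_seq, params)
  if (!core$callable) {
    return(tibble::tibble(read_id = read_id, callable = FALSE,
                          donor_end = NA_integer_,
                          acceptor_start_global = NA_integer_,
                          deletion_len = NA_integer_, mh_len = NA_integer_,
                          insertion_seq = NA_character_,
                          n_mismatch_flank = NA_integer_,
                          score = NA_integer_, class_label = NA_character_))
  }
  acc_global <- cut_right + core$acceptor_start
  del <- (cut_left - core$donor_end) + (acc_global - cut_right)
  label <- if (del > 0L) "deletion" else if (nzchar(core$insertion_seq))
    "insertion" else "blunt"
  tibble::tibble(read_id = read_id, callable = TRUE,
                 donor_end = core$donor_end,
                 acceptor_start_global = acc_global,
                 deletion_len = as.integer(del), mh_len = core$mh_len,
                 insertion_seq = core$insertion_seq,
                 n_mismatch_flank = core$n_mismatch_flank,
                 score = core$score, class_label = label)
}

#' Call repair junctions for a table of reporter reads
#'
#' @param reads A data frame with columns `read_id` and `seq`.
#' @inheritParams call_reporter_junction
#' @return A tibble with one reporter call per read.
#' @export
call_reporter_junctions <- function(reads, reporter, cut_left, cut_right,
                                    params = caller_params()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  dplyr::bind_rows(purrr::map(seq_len(nrow(reads)), function(i) {
    call_reporter_junction(reads$seq[[i]], reporter, cut_left, cut_right,
                           params, read_id = reads$read_id[[i]])
  }))
}
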