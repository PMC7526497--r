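BASES <- c("A", "C", "G", "T")

#' Generate a repeat-rich switch-region reference
#'
#' Switch (S) regions are tandem arrays of short conserved motifs (e.g. the
#' S-mu pentamers GAGCT/GGGCT). The generator concatenates the supplied
#' motifs cyclically to the requested length and then applies per-base
#' substitutions at the given divergence rate, emulating the imperfect
#' tandem-repeat structure in which switch breakpoints occur.
#'
#' @param length Target length in nt (>= 200 for realistic use; shorter
#'   allowed for toy examples).
#' @param repeat_units Character vector of short motifs (A/C/G/T).
#' @param divergence Per-base substitution fraction in `[0, 1)`.
#' @param seed Optional integer seed; the result is deterministic per seed.
#' @param name,role Passed to [reference()].
#' @return A one-row reference tibble (`name`, `role`, `seq`).
#' @examples
#' make_switch_reference(20, "GAGCT", divergence = 0, name = "Smu")
#' @export
make_switch_reference <- function(length, repeat_units = c("GAGCT", "GGGCT"),
                                  divergence = 0.1, seed = NULL,
                                  name = "Sref", role = "donor") {
  stopifnot(length >= 1, length(repeat_units) >= 1,
            divergence >= 0, divergence < 1)
  repeat_units <- vapply(repeat_units, canonicalize_seq, character(1),
                         record = "repeat unit")
  build <- function() {
    units <- rep(repeat_units,
                 times = ceiling(length / min(nchar(repeat_units))))
    s <- substr(paste(units, collapse = ""), 1L, length)
    if (divergence > 0) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length) < divergence)
      for (p in hit) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
      s <- paste(ch, collapse = "")
    }
    s
  }
  s <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  reference(name, s, role)
}

#' Configuration of the junction simulator
#'
#' Defines the end-joining outcome spectrum and read geometry for
#' [simulate_junctions()] and [simulate_reporter_junctions()]. The outcome
#' law must satisfy `p_direct + p_insertion + sum(mh_law) = 1`.
#'
#' @param n_reads Number of junction reads to simulate.
#' @param p_direct Probability of a direct (blunt) join.
#' @param p_insertion Probability of an untemplated insertion at the
#'   junction.
#' @param mh_law Named numeric vector: probability mass per microhomology
#'   length (names are lengths 1..20).
#' @param insertion_len_law Geometric parameter p of the insertion-length
#'   law (length = 1 + Geom(p); mean 1/p).
#' @param flank_len_law Integer range `c(lo, hi)`: donor and acceptor flank
#'   lengths are uniform on it. The default 100-250 nt per flank gives
#'   200-500 nt reads, matching Sanger-sequenced junction fragments.
#' @param substitution_rate Per-base substitution noise applied to finished
#'   reads (Sanger-type point errors).
#' @param deletion_mean Mean of the shifted-geometric deletion-size law
#'   used in reporter mode (`deletion = 1 + Geom(1/mean)`).
#' @param plant_mh If `TRUE` (default), microhomology is planted by local
#'   reference editing so ground truth hits the sampled length; if `FALSE`,
#'   junction microhomology is whatever occurs naturally (recorded
#'   honestly in the truth table).
#' @param seed Optional integer seed; identical configurations (including
#'   seed) give byte-identical output.
#' @return A list of class `sj_sim_config`.
#' @export
sim_config <- function(n_reads = 200L, p_direct = 0.16, p_insertion = 0.24,
                       mh_law = NULL, insertion_len_law = 0.4,
                       flank_len_law = c(100L, 250L),
                       substitution_rate = 0.002, deletion_mean = 8,
                       plant_mh = TRUE, seed = NULL) {
  if (is.null(mh_law)) {
    mh_law <- stats::setNames(c(rep(0.36 / 6, 6), rep(0.24 / 6, 6)),
                              as.character(1:12))
  }
  stopifnot(n_reads >= 1, p_direct >= 0, p_insertion >= 0,
            all(mh_law >= 0), !is.null(names(mh_law)),
            insertion_len_law > 0, insertion_len_law <= 1,
            length(flank_len_law) == 2L,
            flank_len_law[1] >= 1, flank_len_law[2] >= flank_len_law[1],
            substitution_rate >= 0, substitution_rate <= 1,
            deletion_mean >= 1, is.logical(plant_mh))
  ks <- as.integer(names(mh_law))
  stopifnot(!anyNA(ks), all(ks >= 1), all(ks <= 20))
  total <- p_direct + p_insertion + sum(mh_law)
  if (abs(total - 1) > 1e-8) {
    stop("p_direct + p_insertion + sum(mh_law) must be 1 (got ",
         format(total), ")", call. = FALSE)
  }
  structure(list(n_reads = as.integer(n_reads), p_direct = p_direct,
                 p_insertion = p_insertion, mh_law = mh_law,
                 insertion_len_law = insertion_len_law,
                 flank_len_law = as.integer(flank_len_law),
                 substitution_rate = substitution_rate,
                 deletion_mean = deletion_mean, plant_mh = plant_mh,
                 seed = seed),
            class = "sj_sim_config")
}

#' Preset simulator regimes
#'
#' `"control-like"` carries the class spectrum typical of healthy-control
#' CSR junctions (direct 16%, insertions 24%, 1-6 bp microhomology 36%,
#' >= 7 bp 24%); `"ICF2-like"` carries the alternative-end-joining-shifted
#' spectrum of ZBTB24-deficient patients (5% / 13% / 42% / 40%). Within the
#' 1-6 bp and >= 7 bp classes, mass is spread uniformly over lengths 1-6
#' and 7-12 respectively.
#'
#' @param preset `"control-like"` or `"ICF2-like"`.
#' @param ... Overrides passed to [sim_config()].
#' @return An `sj_sim_config`.
#' @examples
#' cfg <- sim_preset("ICF2-like", n_reads = 100, seed = 1)
#' @export
sim_preset <- function(preset = c("control-like", "ICF2-like"), ...) {
  preset <- match.arg(preset)
  masses <- switch(preset,
    "control-like" = list(p_direct = 0.16, p_insertion = 0.24,
                          mh_law = stats::setNames(
                            c(rep(0.36 / 6, 6), rep(0.24 / 6, 6)),
                            as.character(1:12))),
    "ICF2-like" = list(p_direct = 0.05, p_insertion = 0.13,
                       mh_law = stats::setNames(
                         c(rep(0.42 / 6, 6), rep(0.40 / 6, 6)),
                         as.character(1:12))))
  do.call(sim_config, utils::modifyList(masses, list(...)))
}

# --- constraint engine ------------------------------------------------------
# Planting edits a reference through equality/inequality constraints on
# single positions. Once a position participates in a constraint it is
# frozen; later reads may reuse it only compatibly. Constraints are applied
# transactionally: a read whose constraints cannot all be satisfied leaves
# the reference untouched and its coordinates are resampled.
#
# st: list(chars = character vector, frozen = logical vector)
# ops: list of list(type = "eq"|"ne", pos = 0-based index, base = "A".."T")
# Positions out of range are treated as satisfied (no base, no extension).
apply_ops <- function(st, ops) {
  n <- length(st$chars)
  for (op in ops) {
    p <- op$pos + 1L
    if (p < 1L || p > n) next
    if (op$type == "eq") {
      if (st$frozen[p]) {
        if (st$chars[p] != op$base) return(list(ok = FALSE, st = NULL))
      } else {
        st$chars[p] <- op$base
        st$frozen[p] <- TRUE
      }
    } else {  # ne
      if (st$frozen[p]) {
        if (st$chars[p] == op$base) return(list(ok = FALSE, st = NULL))
      } else {
        if (st$chars[p] == op$base) {
          st$chars[p] <- sample(setdiff(BASES, op$base), 1L)
        }
        st$frozen[p] <- TRUE
      }
    }
  }
  list(ok = TRUE, st = st)
}

sample_int_range <- function(lo, hi) {
  if (lo > hi) return(NA_integer_)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_bases <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")

add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    L <- nchar(s)
    hit <- which(stats::runif(L) < rate)
    if (length(hit) == 0L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in hit) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sample_outcomes <- function(cfg, n) {
  labels <- c("direct", "insertion", paste0("mh:", names(cfg$mh_law)))
  probs <- c(cfg$p_direct, cfg$p_insertion, unname(cfg$mh_law))
  sample(labels, n, replace = TRUE, prob = probs)
}

sample_insertion <- function(cfg, forbid_first = NULL) {
  len <- 1L + stats::rgeom(1L, cfg$insertion_len_law)
  ins <- strsplit(random_bases(len), "", fixed = TRUE)[[1L]]
  if (!is.null(forbid_first) && ins[1L] == forbid_first) {
    ins[1L] <- sample(setdiff(BASES, forbid_first), 1L)
  }
  paste(ins, collapse = "")
}

# --- switch-region mode -----------------------------------------------------

#' Simulate switch-junction reads with ground truth
#'
#' Emulates Sanger-length CSR junction amplicons: each read is a donor
#' flank joined to an acceptor flank, with the sampled outcome (direct
#' join, untemplated insertion, or k bp of perfectly matched
#' microhomology), followed by per-base substitution noise. Microhomology
#' is planted by local, constraint-checked editing of the acceptor
#' reference (chance repeats in repeat-rich references cannot be relied on
#' for a specific length), and the truth table is recomputed from the
#' final references after all edits — every truth record is re-derivable
#' from its read and the returned references.
#'
#' @param donor,acceptor References (one-row tibble from
#'   [make_switch_reference()]/[reference()], or character scalars). The
#'   acceptor in the returned object may differ from the input at planted
#'   positions; downstream calling must use the returned references.
#' @param cfg An [sim_config()] object.
#' @param cohort Cohort label stamped on the reads.
#' @return A list of class `sj_sim`: `reads` (tibble `read_id`, `seq`,
#'   `cohort`), `truth` (tibble `read_id`, `true_donor_end`,
#'   `true_acceptor_start`, `true_mh_len`, `true_insertion_seq`,
#'   `true_class`, `regime`), `donor`, `acceptor` (reference tibbles).
#' @examples
#' don <- make_switch_reference(600, c("GAGCT", "GGGCT"), 0.1, seed = 1,
#'                              name = "Smu", role = "donor")
#' acc <- make_switch_reference(900, c("TGGGG", "TGAGC"), 0.1, seed = 2,
#'                              name = "Salpha", role = "acceptor")
#' sim <- simulate_junctions(don, acc, sim_preset("control-like",
#'                           n_reads = 20, seed = 3))
#' @export
simulate_junctions <- function(donor, acceptor, cfg, cohort = "sim") {
  stopifnot(inherits(cfg, "sj_sim_config"))
  d <- as_ref(donor, "donor"); a <- as_ref(acceptor, "acceptor")
  run <- function() simulate_junctions_impl(d, a, cfg, cohort)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

simulate_junctions_impl <- function(d, a, cfg, cohort) {
  n <- cfg$n_reads
  dch <- strsplit(d$seq, "", fixed = TRUE)[[1L]]
  nd <- length(dch)
  st <- list(chars = strsplit(a$seq, "", fixed = TRUE)[[1L]],
             frozen = rep(FALSE, nchar(a$seq)))
  na <- length(st$chars)

  outcome <- sample_outcomes(cfg, n)
  f1 <- sample_int_vec(cfg$flank_len_law, n)
  f2 <- sample_int_vec(cfg$flank_len_law, n)
  if (max(f1) > nd || max(f2) + 1L > na) {
    stop("references too short for the configured flank lengths",
         call. = FALSE)
  }

  de <- integer(n); as_ <- integer(n); ins <- character(n)
  donor_base <- function(p) if (p >= 0L && p < nd) dch[p + 1L] else NULL

  for (i in seq_len(n)) {
    k <- if (startsWith(outcome[i], "mh:")) {
      as.integer(sub("mh:", "", outcome[i]))
    } else 0L
    if (k > 0L && k > nd - f1[i]) {
      stop("unrealizable microhomology: length ", k,
           " exceeds donor beyond the largest breakpoint", call. = FALSE)
    }
    placed <- FALSE
    for (try in seq_len(200L)) {
      di <- sample_int_range(f1[i], nd - k)        # donor_end (0-based)
      ai <- sample_int_range(1L, na - max(f2[i], k))  # acceptor_start
      if (is.na(di) || is.na(ai)) break
      ops <- list(); ins_i <- ""
      if (outcome[i] == "direct") {
        if (!is.null(donor_base(di - 1L)))
          ops <- c(ops, list(list(type = "ne", pos = ai - 1L,
                                  base = donor_base(di - 1L))))
        if (!is.null(donor_base(di)))
          ops <- c(ops, list(list(type = "ne", pos = ai,
                                  base = donor_base(di))))
      } else if (outcome[i] == "insertion") {
        ins_i <- sample_insertion(cfg, forbid_first = donor_base(di))
        last <- substr(ins_i, nchar(ins_i), nchar(ins_i))
        ops <- c(ops, list(list(type = "ne", pos = ai - 1L, base = last)))
      } else {
        for (t in 0:(k - 1L)) {
          ops <- c(ops, list(list(type = "eq", pos = ai + t,
                                  base = donor_base(di + t))))
        }
        if (!is.null(donor_base(di - 1L)))
          ops <- c(ops, list(list(type = "ne", pos = ai - 1L,
                                  base = donor_base(di - 1L))))
        if (!is.null(donor_base(di + k)))
          ops <- c(ops, list(list(type = "ne", pos = ai + k,
                                  base = donor_base(di + k))))
      }
      res <- apply_ops(st, ops)
      if (res$ok) {
        st <- res$st
        de[i] <- di; as_[i] <- ai; ins[i] <- ins_i
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place junction ", i, " after 200 attempts; ",
           "use longer references or fewer reads", call. = FALSE)
    }
  }

  acc_final <- paste(st$chars, collapse = "")
  true_mh <- vapply(seq_len(n), function(i) {
    if (nzchar(ins[i])) 0L else mh_len_cpp(d$seq, de[i], acc_final, as_[i])
  }, integer(1))
  ids <- sprintf("sim_%05d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    paste0(substr(d$seq, de[i] - f1[i] + 1L, de[i]), ins[i],
           substr(acc_final, as_[i] + 1L, as_[i] + f2[i]))
  }, character(1))
  seqs <- add_substitutions(seqs, cfg$substitution_rate)

  structure(list(
    reads = tibble::tibble(read_id = ids, seq = seqs, cohort = cohort),
    truth = tibble::tibble(
      read_id = ids, true_donor_end = de, true_acceptor_start = as_,
      true_mh_len = true_mh, true_insertion_seq = ins,
      true_class = as.character(classify_junction(true_mh, ins)),
      regime = cohort),
    donor = tibble::tibble(name = d$name, role = "donor", seq = d$seq),
    acceptor = tibble::tibble(name = a$name, role = "acceptor",
                              seq = acc_final)),
    class = "sj_sim")
}

sample_int_vec <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

# --- reporter mode ----------------------------------------------------------

#' Simulate DSB-reporter repair junctions with ground truth
#'
#' Emulates sequencing of repair junctions in an integrated cut-and-rejoin
#' reporter: the cassette between the two nuclease sites is excised and the
#' ends are rejoined either precisely (blunt), with untemplated inserted
#' bases, or with further resection (a deletion). Deletion sizes follow a
#' shifted-geometric law (`1 + Geom(1/deletion_mean)`, mean
#' `deletion_mean`) split binomially between the two sides. With
#' `plant_mh = TRUE`, deletion junctions carry microhomology of the length
#' sampled from `mh_law`, planted by constraint-checked editing of the
#' reporter; a junction whose constraints cannot be satisfied falls back to
#' its natural (unplanted) microhomology. Truth is recomputed from the
#' final reporter sequence, so it is honest in all cases.
#'
#' @param cfg An [sim_config()] object.
#' @param reporter Optional reporter reference (one-row tibble or character
#'   scalar); a random 1600 nt reporter is generated when `NULL`.
#' @param cut_left,cut_right 0-based cut coordinates delimiting the excised
#'   cassette; defaults 750/850 for the generated reporter.
#' @param cohort Cohort label.
#' @return A list of class `sj_sim_reporter`: `reads`, `truth` (with
#'   `true_deletion_len`), `reporter` (reference tibble), `cut_left`,
#'   `cut_right`.
#' @export
simulate_reporter_junctions <- function(cfg, reporter = NULL,
                                        cut_left = NULL, cut_right = NULL,
                                        cohort = "sim") {
  stopifnot(inherits(cfg, "sj_sim_config"))
  run <- function() {
    if (is.null(reporter)) {
      reporter <- reference("reporter", random_bases(1600L), "reporter")
      if (is.null(cut_left)) cut_left <- 750L
      if (is.null(cut_right)) cut_right <- 850L
    }
    r <- as_ref(reporter, "reporter")
    stopifnot(!is.null(cut_left), !is.null(cut_right),
              cut_left >= 1, cut_right > cut_left,
              cut_right < nchar(r$seq))
    simulate_reporter_impl(r, as.integer(cut_left), as.integer(cut_right),
                           cfg, cohort)
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

simulate_reporter_impl <- function(r, cut_left, cut_right, cfg, cohort) {
  n <- cfg$n_reads
  st <- list(chars = strsplit(r$seq, "", fixed = TRUE)[[1L]],
             frozen = rep(FALSE, nchar(r$seq)))
  nr <- length(st$chars)
  na <- nr - cut_right  # acceptor-side length

  outcome <- sample_outcomes(cfg, n)
  f1 <- sample_int_vec(cfg$flank_len_law, n)
  f2 <- sample_int_vec(cfg$flank_len_law, n)
  stopifnot(max(f1) <= cut_left, max(f2) <= na)

  de <- integer(n); dr <- integer(n); ins <- character(n)
  rgeom_shift <- function(min_val) {
    repeat {
      v <- 1L + stats::rgeom(1L, 1 / cfg$deletion_mean)
      if (v >= min_val) return(v)
    }
  }

  for (i in seq_len(n)) {
    if (outcome[i] == "direct") {           # blunt religation
      de[i] <- cut_left; dr[i] <- 0L; ins[i] <- ""
      next
    }
    if (outcome[i] == "insertion") {
      de[i] <- cut_left; dr[i] <- 0L
      ins[i] <- sample_insertion(cfg)       # boundary extension impossible
      next
    }
    k <- as.integer(sub("mh:", "", outcome[i]))
    if (!cfg$plant_mh) k <- 0L
    placed <- FALSE
    for (try in seq_len(200L)) {
      D <- rgeom_shift(max(1L, k))
      dl_i <- if (k > 0L) k + stats::rbinom(1L, D - k, 0.5) else
        stats::rbinom(1L, D, 0.5)
      dr_i <- D - dl_i
      di <- cut_left - dl_i                 # global donor_end
      ag <- cut_right + dr_i                # global acceptor start
      if (di < f1[i] || dr_i + f2[i] > na || dr_i + k > na) next
      ops <- list()
      if (k > 0L) {
        for (t in 0:(k - 1L)) {
          # equality between two reporter positions: freeze source, copy
          ops <- c(ops, list(list(type = "eq2", pos = di + t,
                                  pos2 = ag + t)))
        }
        if (di - 1L >= 0L && dr_i >= 1L)
          ops <- c(ops, list(list(type = "ne2", pos = di - 1L,
                                  pos2 = ag - 1L)))
        if (di + k < cut_left && ag + k < nr)
          ops <- c(ops, list(list(type = "ne2", pos = di + k,
                                  pos2 = ag + k)))
      }
      res <- apply_ops2(st, ops)
      if (res$ok) {
        st <- res$st; de[i] <- di; dr[i] <- dr_i; ins[i] <- ""
        placed <- TRUE
        break
      }
    }
    if (!placed) {                          # honest fallback: unplanted
      D <- rgeom_shift(1L)
      dl_i <- stats::rbinom(1L, D, 0.5)
      dl_i <- min(dl_i, cut_left - f1[i])
      dr_i <- min(D - dl_i, na - f2[i])
      de[i] <- cut_left - dl_i; dr[i] <- dr_i; ins[i] <- ""
    }
  }

  rep_final <- paste(st$chars, collapse = "")
  donor_part <- substr(rep_final, 1L, cut_left)
  acceptor_part <- substr(rep_final, cut_right + 1L, nr)
  del <- (cut_left - de) + dr
  true_mh <- vapply(seq_len(n), function(i) {
    if (nzchar(ins[i])) 0L else
      mh_len_cpp(donor_part, de[i], acceptor_part, dr[i])
  }, integer(1))
  true_class <- ifelse(del > 0L, "deletion",
                       ifelse(nzchar(ins), "insertion", "blunt"))
  ids <- sprintf("rep_%05d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) {
    ag <- cut_right + dr[i]
    paste0(substr(rep_final, de[i] - f1[i] + 1L, de[i]), ins[i],
           substr(rep_final, ag + 1L, ag + f2[i]))
  }, character(1))
  seqs <- add_substitutions(seqs, cfg$substitution_rate)

  structure(list(
    reads = tibble::tibble(read_id = ids, seq = seqs, cohort = cohort),
    truth = tibble::tibble(
      read_id = ids, true_donor_end = de,
      true_acceptor_start = cut_right + dr, true_deletion_len = del,
      true_mh_len = true_mh, true_insertion_seq = ins,
      true_class = true_class, regime = cohort),
    reporter = tibble::tibble(name = r$name, role = "reporter",
                              seq = rep_final),
    cut_left = cut_left, cut_right = cut_right),
    class = "sj_sim_reporter")
}

# Position-position variant of the constraint engine (reporter mode):
# eq2 freezes both positions to a common base, ne2 to differing bases.
apply_ops2 <- function(st, ops) {
  n <- length(st$chars)
  for (op in ops) {
    p <- op$pos + 1L; q <- op$pos2 + 1L
    if (p < 1L || p > n || q < 1L || q > n) next
    fp <- st$frozen[p]; fq <- st$frozen[q]
    if (op$type == "eq2") {
      if (fp && fq) {
        if (st$chars[p] != st$chars[q]) return(list(ok = FALSE, st = NULL))
      } else if (fp) {
        st$chars[q] <- st$chars[p]; st$frozen[q] <- TRUE
      } else if (fq) {
        st$chars[p] <- st$chars[q]; st$frozen[p] <- TRUE
      } else {
        st$chars[q] <- st$chars[p]
        st$frozen[p] <- TRUE; st$frozen[q] <- TRUE
      }
    } else {  # ne2
      if (fp && fq) {
        if (st$chars[p] == st$chars[q]) return(list(ok = FALSE, st = NULL))
      } else if (fp || fq) {
        frozen_base <- if (fp) st$chars[p] else st$chars[q]
        free <- if (fp) q else p
        if (st$chars[free] == frozen_base) {
          st$chars[free] <- sample(setdiff(BASES, frozen_base), 1L)
        }
        st$frozen[p] <- TRUE; st$frozen[q] <- TRUE
      } else {
        if (st$chars[p] == st$chars[q]) {
          st$chars[q] <- sample(setdiff(BASES, st$chars[p]), 1L)
        }
        st$frozen[p] <- TRUE; st$frozen[q] <- TRUE
      }
    }
  }
  list(ok = TRUE, st = st)
}

#' Write a simulation to disk
#'
#' Writes `<prefix>_reads.fa`, `<prefix>_truth.tsv` and
#' `<prefix>_refs.fa` for an [simulate_junctions()] or
#' [simulate_reporter_junctions()] result.
#'
#' @param sim An `sj_sim` or `sj_sim_reporter` object.
#' @param out_prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, out_prefix) {
  stopifnot(inherits(sim, c("sj_sim", "sj_sim_reporter")))
  reads_fa <- paste0(out_prefix, "_reads.fa")
  truth_tsv <- paste0(out_prefix, "_truth.tsv")
  refs_fa <- paste0(out_prefix, "_refs.fa")
  write_fasta(sim$reads[, c("read_id", "seq")] |>
                stats::setNames(c("name", "seq")), reads_fa)
  utils::write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  refs <- if (inherits(sim, "sj_sim")) {
    dplyr::bind_rows(sim$donor, sim$acceptor)
  } else {
    sim$reporter
  }
  write_fasta(refs, refs_fa)
  invisible(c(reads = reads_fa, truth = truth_tsv, refs = refs_fa))
}
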