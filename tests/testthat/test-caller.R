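p2 <- caller_params(min_flank = 2)

test_that("breakpoint calling resolves blunt, microhomology and insertion splits", {
  cases <- list(
    # read, donor, acceptor, donor_end, mh, insertion
    list("AAAATTTT", "AAAACCCC", "GGGGTTTT", 4L, 0L, ""),
    list("AACCGTGTTTAA", "AACCGTGT", "GTGTTTAA", 8L, 4L, ""),
    list("AAAAGCTTTT", "AAAACCCC", "GGGGTTTT", 4L, 0L, "GC"))
  for (cs in cases) {
    call <- call_breakpoint(cs[[1]], cs[[2]], cs[[3]], p2)
    expect_true(call$callable)
    expect_equal(call$donor_end, cs[[4]])
    expect_equal(call$mh_len, cs[[5]])
    expect_equal(call$insertion_seq, cs[[6]])
  }
})

test_that("microhomology extension is perfect-match only and N never matches", {
  expect_equal(compute_microhomology("AACCGTGT", 8, "GTGTTTAA", 4), 4)
  expect_equal(compute_microhomology("AAAACCCC", 4, "GGGGTTTT", 4), 0)
  expect_equal(compute_microhomology("ACGTACGT", 0, "TGCATGCA", 0), 0)
  # N blocks extension even against another N
  expect_equal(compute_microhomology("TTTTNAAA", 4, "TTTTNAAA", 4), 4)
  expect_equal(compute_microhomology("AAANTTTT", 4, "AAANTTTT", 4), 4)
  expect_error(compute_microhomology("ACGT", 5, "ACGT", 0))
})

test_that("microhomology length is invariant to junction placement in the window", {
  # donor and acceptor share the window "GTGT" around the junction
  donor <- "AACCGTGT"; acceptor <- "GTGTTTAA"
  placements <- list(c(4, 0), c(5, 1), c(6, 2), c(7, 3), c(8, 4))
  mh <- vapply(placements, function(pl)
    compute_microhomology(donor, pl[1], acceptor, pl[2]), numeric(1))
  expect_true(all(mh == 4))
})

test_that("calls are deterministic and reverse-complement symmetric", {
  set.seed(21)
  refs <- demo_refs(400, 500)
  cfg <- sim_preset("control-like", n_reads = 30, seed = 22,
                    substitution_rate = 0, flank_len_law = c(40L, 70L))
  sim <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  pars <- caller_params(min_flank = 15)
  calls1 <- call_junctions(sim$reads, sim$donor, sim$acceptor, params = pars)
  calls2 <- call_junctions(sim$reads, sim$donor, sim$acceptor, params = pars)
  expect_identical(calls1, calls2)

  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in seq_len(10)) {
    fwd <- calls1[i, ]
    swapped <- call_breakpoint(rc(sim$reads$seq[[i]]),
                               rc(sim$acceptor$seq), rc(sim$donor$seq),
                               pars)
    expect_equal(swapped$mh_len, fwd$mh_len)
    expect_equal(nchar(swapped$insertion_seq), nchar(fwd$insertion_seq))
    expect_equal(swapped$score, fwd$score)
  }
})

test_that("reverse-complement rescue recovers antisense reads", {
  refs <- demo_refs(400, 500)
  cfg <- sim_preset("control-like", n_reads = 5, seed = 23,
                    substitution_rate = 0, flank_len_law = c(40L, 70L))
  sim <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  pars <- caller_params(min_flank = 15, try_revcomp = TRUE)
  fwd <- call_breakpoint(sim$reads$seq[[1]], sim$donor, sim$acceptor, pars)
  rev <- call_breakpoint(rc(sim$reads$seq[[1]]), sim$donor, sim$acceptor, pars)
  expect_equal(rev$strand, "-")
  expect_equal(rev$mh_len, fwd$mh_len)
  expect_equal(rev$score, fwd$score)
})

test_that("reads without a positive-scoring split on both flanks are uncallable", {
  set.seed(24)
  pars <- caller_params(min_flank = 15)
  # degenerate case: read shorter than twice the minimum flank
  short <- call_breakpoint("ACGTACGT", rand_seq(80), rand_seq(80), pars)
  expect_false(short$callable)
  expect_true(is.na(short$donor_end))
})

test_that("caller score and microhomology match exhaustive enumeration", {
  set.seed(25)
  agree <- oracle_agreement(60)
  expect_equal(agree, 1)
})

test_that("sequential-switching footprints require length, identity and score gain", {
  don <- make_switch_reference(500, c("GAGCT", "GGGCT"), 0.08, seed = 31,
                               name = "Smu", role = "donor")
  acc <- make_switch_reference(500, c("TGGGG", "TGAGC"), 0.08, seed = 32,
                               name = "Sg2", role = "acceptor")
  itm <- make_switch_reference(400, c("TACAT", "AATAC"), 0.08, seed = 33,
                               name = "Sg3", role = "intermediate")
  blockful <- paste0(substr(don$seq, 101, 180), substr(itm$seq, 201, 225),
                     substr(acc$seq, 51, 130))
  fp <- detect_sequential_footprint(blockful, don, acc, itm)
  expect_equal(fp$footprint_ref, "Sg3")
  expect_gte(fp$identity, 0.9)

  blockless <- paste0(substr(don$seq, 101, 180), substr(acc$seq, 51, 130))
  expect_true(is.na(detect_sequential_footprint(blockless, don, acc,
                                                itm)$footprint_ref))

  short_block <- paste0(substr(don$seq, 101, 180), substr(itm$seq, 201, 210),
                        substr(acc$seq, 51, 130))
  fp3 <- detect_sequential_footprint(short_block, don, acc, itm,
                                     caller_params(footprint_min_len = 15))
  expect_true(is.na(fp3$footprint_ref))

  calls <- call_junctions(tibble::tibble(read_id = c("a", "b"),
                                         seq = c(blockful, blockless)),
                          don, acc, intermediates = itm)
  expect_equal(calls$footprint_ref, c("Sg3", NA))
})

test_that("reporter junctions report deletion, insertion and blunt religation", {
  set.seed(41)
  rep_seq <- rand_seq(700)
  cl <- 320L; cr <- 380L
  pars <- caller_params(min_flank = 15)
  perfect <- paste0(substr(rep_seq, cl - 79, cl), substr(rep_seq, cr + 1, cr + 80))
  call <- call_reporter_junction(perfect, rep_seq, cl, cr, pars)
  expect_equal(call$deletion_len, 0L)
  expect_equal(call$class_label, "blunt")
  expect_equal(call$mh_len, 0L)

  resected <- paste0(substr(rep_seq, cl - 79, cl - 6),
                     substr(rep_seq, cr + 1, cr + 80))
  call6 <- call_reporter_junction(resected, rep_seq, cl, cr, pars)
  expect_equal(call6$deletion_len, 6L)
  expect_equal(call6$class_label, "deletion")

  ins_read <- paste0(substr(rep_seq, cl - 79, cl), "TTA",
                     substr(rep_seq, cr + 1, cr + 80))
  calli <- call_reporter_junction(ins_read, rep_seq, cl, cr, pars)
  expect_equal(nchar(calli$insertion_seq), 3L)
  expect_equal(calli$deletion_len, 0L)
  expect_equal(calli$class_label, "insertion")
})
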