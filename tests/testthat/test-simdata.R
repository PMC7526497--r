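test_that("switch-region references are tandem repeats with controlled divergence", {
  r <- make_switch_reference(20, "GAGCT", divergence = 0, name = "Smu")
  expect_equal(r$seq, "GAGCTGAGCTGAGCTGAGCT")
  a <- make_switch_reference(1000, c("GAGCT", "GGGCT"), divergence = 0.1,
                             seed = 71)
  b <- make_switch_reference(1000, c("GAGCT", "GGGCT"), divergence = 0.1,
                             seed = 71)
  expect_identical(a$seq, b$seq)
  pristine <- make_switch_reference(1000, c("GAGCT", "GGGCT"),
                                    divergence = 0)
  frac <- mean(strsplit(a$seq, "")[[1]] != strsplit(pristine$seq, "")[[1]])
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lte(abs(frac - 0.1), 3 * se)
  expect_error(make_switch_reference(100, "GAXCT"), "non-IUPAC")
})

test_that("simulator configurations validate the outcome law", {
  expect_error(sim_config(p_direct = 0.5, p_insertion = 0.6,
                          mh_law = c("1" = 0.5)), "must be 1")
  expect_error(sim_config(mh_law = c("0" = 0.6, "1" = 0.4),
                          p_direct = 0, p_insertion = 0))
  cfg <- sim_preset("ICF2-like")
  expect_equal(cfg$p_direct + cfg$p_insertion + sum(cfg$mh_law), 1)
})

test_that("a pure direct-joining regime is recovered perfectly without noise", {
  refs <- demo_refs(500, 900)
  cfg <- sim_config(n_reads = 40, p_direct = 1, p_insertion = 0,
                    mh_law = c("1" = 0), substitution_rate = 0,
                    flank_len_law = c(40L, 70L), seed = 72)
  sim <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  expect_true(all(sim$truth$true_mh_len == 0))
  expect_true(all(sim$truth$true_insertion_seq == ""))
  calls <- call_junctions(sim$reads, sim$donor, sim$acceptor,
                          params = caller_params(min_flank = 15))
  m <- merge(calls, sim$truth, by = "read_id")
  expect_true(all(m$callable))
  expect_true(all(m$mh_len == 0 & m$insertion_seq == ""))
})

test_that("a long-microhomology regime classifies as mh_ge7 nearly always", {
  refs <- demo_refs(600, 3000)
  cfg <- sim_config(n_reads = 120, p_direct = 0, p_insertion = 0,
                    mh_law = c("8" = 1), substitution_rate = 0,
                    flank_len_law = c(40L, 70L), seed = 73)
  sim <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  expect_true(all(sim$truth$true_mh_len == 8))
  calls <- call_junctions(sim$reads, sim$donor, sim$acceptor,
                          params = caller_params(min_flank = 15))
  cl <- classify_calls(calls)
  expect_gte(mean(cl$class == "mh_ge7"), 0.95)
})

test_that("simulation output is reproducible and truth records are realizable", {
  refs <- demo_refs(500, 1000)
  cfg <- sim_preset("control-like", n_reads = 60, seed = 74,
                    substitution_rate = 0, flank_len_law = c(40L, 70L))
  s1 <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  s2 <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$acceptor, s2$acceptor)

  # noise-free reads must reconstruct exactly from truth + final references
  for (i in seq_len(nrow(s1$reads))) {
    tr <- s1$truth[i, ]
    read <- s1$reads$seq[[i]]
    de <- tr$true_donor_end; as_ <- tr$true_acceptor_start
    prefix_ok <- FALSE
    for (fl in 40:70) {
      cand <- paste0(substr(s1$donor$seq, de - fl + 1, de),
                     tr$true_insertion_seq)
      if (startsWith(read, cand) &&
          endsWith(read, substr(s1$acceptor$seq, as_ + 1,
                                as_ + (nchar(read) - nchar(cand))))) {
        prefix_ok <- TRUE
        break
      }
    }
    expect_true(prefix_ok)
    if (tr$true_insertion_seq == "") {
      expect_equal(compute_microhomology(s1$donor$seq, de,
                                         s1$acceptor$seq, as_),
                   tr$true_mh_len)
    }
  }
})

test_that("reporter simulation honours its outcome and deletion laws", {
  # degenerate regime: everything religates precisely
  cfg0 <- sim_config(n_reads = 30, p_direct = 1, p_insertion = 0,
                     mh_law = c("1" = 0), substitution_rate = 0, seed = 75,
                     flank_len_law = c(40L, 70L))
  s0 <- simulate_reporter_junctions(cfg0)
  expect_true(all(s0$truth$true_deletion_len == 0))
  expect_true(all(s0$truth$true_class == "blunt"))

  # shifted-geometric deletion law, mean 8, unplanted microhomology
  cfg1 <- sim_config(n_reads = 500, p_direct = 0, p_insertion = 0,
                     mh_law = c("1" = 1), deletion_mean = 8,
                     plant_mh = FALSE, substitution_rate = 0, seed = 76,
                     flank_len_law = c(40L, 70L))
  s1 <- simulate_reporter_junctions(cfg1)
  se <- sqrt(8 * 7 / 500)  # sd of 1 + Geom(1/8) is sqrt(mean*(mean-1))
  expect_lte(abs(mean(s1$truth$true_deletion_len) - 8), 3 * se)
  expect_true(all(s1$truth$true_deletion_len >= 1))
})

test_that("planted microhomology dominates deletion-associated usage", {
  cfg <- sim_config(n_reads = 150, p_direct = 0.1, p_insertion = 0.1,
                    mh_law = c("4" = 0.8), substitution_rate = 0, seed = 77,
                    flank_len_law = c(40L, 70L))
  sim <- simulate_reporter_junctions(cfg)
  calls <- call_reporter_junctions(sim$reads, sim$reporter, sim$cut_left,
                                   sim$cut_right,
                                   caller_params(min_flank = 15))
  usage <- mh_usage_in_deletions(calls)
  expect_equal(usage$mh_len[which.max(usage$count)], 4L)
  m <- merge(calls, sim$truth, by = "read_id")
  expect_true(all(m$deletion_len == m$true_deletion_len))
  expect_gte(mean(m$mh_len == m$true_mh_len), 0.99)
})

test_that("simulations serialize to FASTA and TSV", {
  refs <- demo_refs(500, 900)
  cfg <- sim_preset("control-like", n_reads = 10, seed = 78,
                    flank_len_law = c(40L, 70L))
  sim <- simulate_junctions(refs$donor, refs$acceptor, cfg)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_sim(sim, prefix)
  expect_true(all(file.exists(paths)))
  reads_back <- read_fasta(paths[["reads"]])
  expect_equal(reads_back$seq, sim$reads$seq)
  refs_back <- read_fasta(paths[["refs"]])
  expect_equal(refs_back$seq[2], sim$acceptor$seq)
})
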