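#' Run the junction-analysis pipeline
#'
#' Wires the stages simulate -> call -> classify -> summarize -> compare
#' over a single configuration, writing all artifacts and a JSON run
#' manifest (parameters, package version, seed, input digests) so that any
#' run is reproducible from its manifest. Either simulate two cohorts
#' (`presets`) or supply FASTA inputs (`reads_fa`, `donor_fa`,
#' `acceptor_fa`).
#'
#' @param out_dir Output directory (created if missing).
#' @param presets Named character vector of simulator presets, e.g.
#'   `c(control = "control-like", ICF2 = "ICF2-like")`; ignored when
#'   `reads_fa` is given.
#' @param reads_fa,donor_fa,acceptor_fa Optional FASTA inputs for calling
#'   real reads instead of simulating.
#' @param n_reads Reads per simulated cohort.
#' @param ref_lengths Lengths of the simulated donor and acceptor
#'   references.
#' @param params A [caller_params()] object.
#' @param seed Integer seed controlling all randomness of the run.
#' @return A list with elements `calls`, `summary`, `comparison`,
#'   `manifest` (paths of artifacts in `manifest$artifacts`).
#' @export
run_pipeline <- function(out_dir, presets = c(control = "control-like",
                                              ICF2 = "ICF2-like"),
                         reads_fa = NULL, donor_fa = NULL,
                         acceptor_fa = NULL, n_reads = 200L,
                         ref_lengths = c(donor = 1200L, acceptor = 1600L),
                         params = caller_params(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()

  if (!is.null(reads_fa)) {
    stopifnot(!is.null(donor_fa), !is.null(acceptor_fa))
    reads <- read_fasta(reads_fa)
    reads <- tibble::tibble(read_id = reads$name, seq = reads$seq,
                            cohort = "input")
    donor <- read_fasta(donor_fa)[1, ]
    acceptor <- read_fasta(acceptor_fa)[1, ]
    inputs <- list(reads_fa = unname(tools::md5sum(reads_fa)),
                   donor_fa = unname(tools::md5sum(donor_fa)),
                   acceptor_fa = unname(tools::md5sum(acceptor_fa)))
    calls <- call_junctions(reads, donor, acceptor, params = params)
  } else {
    stopifnot(length(presets) >= 1, !is.null(names(presets)))
    donor <- make_switch_reference(ref_lengths[["donor"]],
                                   c("GAGCT", "GGGCT"), 0.1,
                                   seed = seed, name = "Smu",
                                   role = "donor")
    acceptor <- make_switch_reference(ref_lengths[["acceptor"]],
                                      c("TGGGG", "TGAGC"), 0.1,
                                      seed = seed + 1L, name = "Sacc",
                                      role = "acceptor")
    sims <- purrr::imap(presets, function(p, nm) {
      cfg <- sim_preset(p, n_reads = n_reads,
                        seed = seed + 10L + match(nm, names(presets)))
      simulate_junctions(donor, acceptor, cfg, cohort = nm)
    })
    calls <- dplyr::bind_rows(purrr::imap(sims, function(s, nm) {
      write_sim(s, file.path(out_dir, paste0("sim_", nm)))
      call_junctions(s$reads, s$donor, s$acceptor, params = params)
    }))
  }

  calls_path <- file.path(out_dir, "calls.tsv")
  write_calls_tsv(calls, calls_path)
  classified <- classify_calls(calls)
  summary <- summarize_cohorts(classified)
  summary_path <- file.path(out_dir, "summary.tsv")
  utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  comparison <- NULL
  cohorts <- unique(summary$cohort)
  if (length(cohorts) == 2L) {
    comparison <- compare_categories(
      summary[summary$cohort == cohorts[1], ],
      summary[summary$cohort == cohorts[2], ])
    utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "switchjxn",
    version = as.character(utils::packageVersion("switchjxn")),
    seed = seed,
    n_reads = n_reads,
    presets = as.list(presets),
    params = unclass(params),
    inputs = inputs,
    artifacts = list(calls = calls_path, summary = summary_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(calls = calls, summary = summary, comparison = comparison,
       manifest = manifest)
}
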