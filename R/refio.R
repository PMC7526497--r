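#' Read a FASTA file of switch-region references or junction reads
#'
#' Reads a FASTA file and canonicalizes every record: sequences are
#' uppercased, `U` is mapped to `T`, and multi-line sequences are
#' concatenated. Record names are the first whitespace-delimited token of
#' each header. Only the alphabet `A`, `C`, `G`, `T`, `N` is accepted;
#' anything else is a format error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `seq`, one row per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  nm <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate record name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(seq_along(set), function(i) {
    canonicalize_seq(as.character(set[[i]]), record = nm[i])
  }, character(1))
  tibble::tibble(name = nm, seq = seqs)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` is the
#' identity on canonical records.
#'
#' @param x A data frame with columns `name` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("name", "seq") %in% names(x)))
  set <- Biostrings::DNAStringSet(stats::setNames(x$seq, x$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Fixed column order of the breakpoint-call TSV. `class` and `footprint_ref`
# may be NA when classification / footprint detection has not been run.
calls_tsv_columns <- c(
  "read_id", "cohort", "donor_name", "donor_end", "acceptor_name",
  "acceptor_start", "mh_len", "insertion_seq", "n_mismatch_flank",
  "class", "footprint_ref", "score"
)

#' Write breakpoint calls to a TSV file
#'
#' Serializes a calls table to a tab-separated file with a fixed header
#' (`read_id, cohort, donor_name, donor_end, acceptor_name, acceptor_start,
#' mh_len, insertion_seq, n_mismatch_flank, class, footprint_ref, score`).
#' Missing columns are filled with `NA`; the file round-trips losslessly
#' through [read_calls_tsv()].
#'
#' @param calls A data frame of breakpoint calls (see [call_junctions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  out <- calls
  for (col in setdiff(calls_tsv_columns, names(out))) out[[col]] <- NA
  out <- out[, calls_tsv_columns, drop = FALSE]
  # "." encodes an empty insertion so that empty and missing stay distinct
  out$insertion_seq <- ifelse(is.na(out$insertion_seq), NA,
                              ifelse(out$insertion_seq == "", ".",
                                     out$insertion_seq))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read breakpoint calls from a TSV file
#'
#' @param path Path to a TSV written by [write_calls_tsv()].
#' @return A tibble of calls with typed columns.
#' @export
read_calls_tsv <- function(path) {
  if (!file.exists(path)) stop("calls TSV not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = c(
                           read_id = "character", cohort = "character",
                           donor_name = "character", donor_end = "integer",
                           acceptor_name = "character",
                           acceptor_start = "integer", mh_len = "integer",
                           insertion_seq = "character",
                           n_mismatch_flank = "integer", class = "character",
                           footprint_ref = "character", score = "integer"))
  if (!identical(names(x), calls_tsv_columns)) {
    stop("malformed calls TSV: expected columns ",
         paste(calls_tsv_columns, collapse = ", "), call. = FALSE)
  }
  x$insertion_seq[!is.na(x$insertion_seq) & x$insertion_seq == "."] <- ""
  tibble::as_tibble(x)
}

#' Construct a named reference sequence
#'
#' @param name Text identifier, unique within a reference set.
#' @param seq Nucleotide sequence over `A, C, G, T, N` (lowercase and `U`
#'   are canonicalized).
#' @param role One of `"donor"`, `"acceptor"`, `"intermediate"`,
#'   `"reporter"`.
#' @return A one-row tibble with columns `name`, `role`, `seq`.
#' @examples
#' reference("Smu", "GAGCTGAGCT", "donor")
#' @export
reference <- function(name, seq, role = c("donor", "acceptor",
                                          "intermediate", "reporter")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  tibble::tibble(name = name, role = role,
                 seq = canonicalize_seq(seq, record = name))
}

# Uppercase, map U->T, reject anything outside A/C/G/T/N. All downstream
# code assumes sequences have passed through here.
canonicalize_seq <- function(seq, record = "<sequence>") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  if (!nzchar(s)) stop("empty sequence in record '", record, "'", call. = FALSE)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    stop("non-IUPAC character(s) '", substr(bad, 1, 5), "' in record '",
         record, "'", call. = FALSE)
  }
  s
}

# Accept a reference as a one-row data frame (name/seq), a named or plain
# character scalar, and return list(name=, seq=) canonicalized.
as_ref <- function(x, default_name = "ref") {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(c("name", "seq") %in% names(x)))
    list(name = x$name[[1]], seq = canonicalize_seq(x$seq[[1]], x$name[[1]]))
  } else if (is.character(x) && length(x) == 1L) {
    nm <- if (!is.null(names(x)) && nzchar(names(x))) names(x) else default_name
    list(name = nm, seq = canonicalize_seq(unname(x), nm))
  } else {
    stop("expected a reference (one-row data frame with name/seq, or a ",
         "character scalar)", call. = FALSE)
  }
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
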