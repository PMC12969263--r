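# Sequence ingestion, result serialisation and deterministic fixtures.

#' Read peptide sequences
#'
#' Accepts either a path to a (multi-record) FASTA file or one or more bare
#' one-letter sequence strings. Sequences are uppercased and validated
#' against the 20 standard residues; errors name the offending record and
#' position.
#'
#' @param input Character vector: a FASTA file path, or literal sequences.
#' @return A named character vector of validated uppercase sequences
#'   (FASTA record names, or `seq1`, `seq2`, ... for literals).
#' @examples
#' read_sequences("PEPTIDE")
#' @export
read_sequences <- function(input) {
  if (!is.character(input) || length(input) < 1L) {
    abort_input("`input` must be a character vector")
  }
  if (length(input) == 1L && file.exists(input)) {
    recs <- tryCatch(
      seqinr::read.fasta(input, seqtype = "AA", as.string = TRUE,
                         seqonly = FALSE),
      error = function(e) abort_input("malformed FASTA '%s': %s",
                                      input, conditionMessage(e)))
    if (length(recs) == 0L) abort_input("no records in FASTA '%s'", input)
    seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
    names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  } else {
    seqs <- input
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  for (i in seq_along(seqs)) {
    seqs[i] <- tryCatch(peptide(seqs[i]), error = function(e) {
      abort_input("record '%s': %s", names(seqs)[i], conditionMessage(e))
    })
  }
  seqs
}

.unit_scale <- function(units = c("per-min", "per-sec", "per-hour")) {
  switch(match.arg(units), "per-min" = 1, "per-sec" = 1 / 60, "per-hour" = 60)
}

#' Write a per-residue rate table
#'
#' Serialises a [residue_profile()] to TSV or CSV, with `#` header comments
#' recording the solvent condition, reference standard, sequence-factor
#' table version and package version; rates are converted to the requested
#' unit. Numbers are printed with 6 significant digits.
#'
#' @param profile A [residue_profile()] data frame.
#' @param path Output file path ("" writes to stdout).
#' @param format `"tsv"` or `"csv"`.
#' @param units `"per-min"` (native), `"per-sec"` or `"per-hour"`.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(profile, path = "",
                             format = c("tsv", "csv"),
                             units = c("per-min", "per-sec", "per-hour")) {
  format <- match.arg(format)
  units <- match.arg(units)
  sep <- if (format == "tsv") "\t" else ","
  scale <- .unit_scale(units)
  cond <- attr(profile, "condition")
  out <- profile
  rate_cols <- c("tilde_forward", "tilde_backward", "k_forward",
                 "k_backward", "k_int")
  for (col in intersect(rate_cols, names(out))) {
    out[[col]] <- out[[col]] * scale
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  header <- c(
    sprintf("# hdxmix %s", as.character(utils::packageVersion("hdxmix"))),
    if (!is.null(cond)) sprintf(
      "# condition: x = %g, T = %g K, %s = %g",
      cond$x, cond$temperature, cond$acidity_mode, cond$acidity_value),
    sprintf("# standard: %s", attr(profile, "standard") %||% "PDLA"),
    sprintf("# sequence-factor table: %s",
            attr(profile, "table_version") %||% "unversioned"),
    sprintf("# units: %s", units))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(header, con)
  utils::write.table(out, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a rate table written by [write_rate_table()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`.
#' @return A data frame.
#' @export
read_rate_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (!file.exists(path)) abort_input("rate table '%s' not found", path)
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic peptide fixtures
#'
#' Generates reproducible random peptide sequences for property tests.
#' The canonical examples `AAAAAAA` and `PEPTIDE` are always prepended.
#' The caller's random-number state is left untouched.
#'
#' @param n Number of random sequences (in addition to the canonical two).
#' @param length_range Integer range `c(min, max)` of sequence lengths.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param alphabet Residue letters to draw from (default: the 20 standard
#'   residues).
#' @return A named character vector of sequences.
#' @examples
#' make_fixtures(3, seed = 42)
#' @export
make_fixtures <- function(n, length_range = c(5, 20), seed = 1,
                          alphabet = .AA20) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    abort_config("`n` must be a non-negative integer")
  }
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    abort_config("`length_range` must be c(min, max) with 1 <= min <= max")
  }
  bad <- setdiff(alphabet, .AA20)
  if (length(bad)) {
    abort_config("alphabet contains non-standard letters: %s",
                 paste(bad, collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  lens <- seq(length_range[1], length_range[2])
  random <- vapply(seq_len(n), function(i) {
    len <- lens[sample.int(length(lens), 1)]  # robust to length-1 ranges
    paste(alphabet[sample.int(length(alphabet), len, replace = TRUE)],
          collapse = "")
  }, character(1))
  out <- c(AAAAAAA = "AAAAAAA", PEPTIDE = "PEPTIDE")
  if (n > 0) {
    names(random) <- paste0("fixture", seq_len(n))
    out <- c(out, random)
  }
  out
}
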