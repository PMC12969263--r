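# Sequence-dependent (lambda/rho) multiplicative factors for base-catalysed
# exchange. The shipped table transcribes the published random-coil factors
# (see the header of inst/extdata/base_factors_bai1993.tsv for provenance
# and conventions); alanine defines the zero of the log scale, so PDLA-like
# contexts have a factor of exactly 1.

.AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load a sequence-factor table
#'
#' Reads a tab-separated table of per-residue log10 lambda (left-neighbour)
#' and rho (own-amide) factors for base-catalysed exchange, keyed by the
#' abstracting medium (`H_base` for OH-, `D_base` for OD-). With no
#' arguments the table shipped with the package is loaded.
#'
#' @param path Path to a TSV file with columns `residue_code`,
#'   `log_B_lambda`, `log_B_rho`, `medium`, `notes` (lines starting with
#'   `#` are comments). `NULL` loads the packaged table.
#' @return A data frame of class `sequence_factor_table` with an attribute
#'   `table_version` taken from the file header when present.
#' @examples
#' tab <- sequence_factors()
#' head(tab)
#' @export
sequence_factors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "base_factors_bai1993.tsv",
                        package = "hdxmix", mustWork = TRUE)
  }
  if (!file.exists(path)) abort_input("sequence-factor file '%s' not found", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character"))
  need <- c("residue_code", "log_B_lambda", "log_B_rho", "medium")
  if (!all(need %in% names(tab))) {
    abort_input("sequence-factor file '%s' lacks required columns", path)
  }
  for (med in unique(tab$medium)) {
    sub <- tab[tab$medium == med, ]
    missing <- setdiff(.AA20, sub$residue_code)
    if (length(missing)) {
      abort_input("sequence-factor table (medium %s) misses residues: %s",
                  med, paste(missing, collapse = ", "))
    }
  }
  version <- grep("Table version:", readLines(path, n = 30), value = TRUE)
  attr(tab, "table_version") <- if (length(version)) {
    sub(".*Table version:\\s*([^. ]+).*", "\\1", version[1])
  } else "unversioned"
  class(tab) <- c("sequence_factor_table", class(tab))
  tab
}

# single table lookup; kind is "log_B_lambda" or "log_B_rho"
.factor_lookup <- function(table, residue, medium, kind) {
  row <- table$residue_code == residue & table$medium == medium
  if (!any(row)) {
    abort_input("no %s entry for residue '%s' (medium %s)",
                kind, residue, medium)
  }
  table[[kind]][which(row)[1]]
}

#' Validate a peptide sequence
#'
#' Checks a one-letter amino-acid string against the 20 standard residues
#' (case-insensitive) and returns it uppercased.
#'
#' @param sequence One-letter amino-acid string.
#' @return The validated uppercase sequence.
#' @examples
#' peptide("peptide")
#' @export
peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort_input("`sequence` must be a single non-empty character string")
  }
  seq_up <- toupper(sequence)
  letters <- strsplit(seq_up, "")[[1]]
  bad <- which(!letters %in% .AA20)
  if (length(bad)) {
    abort_input("illegal residue letter '%s' at position %d",
                letters[bad[1]], bad[1])
  }
  seq_up
}

#' Sequence factor of a residue's amide
#'
#' Computes the multiplicative (B_lambda x B_rho) factor modulating the
#' base-catalysed exchange rate of the backbone amide of residue `index`:
#' on the log10 scale, the lambda factor of the left neighbour (residue
#' `index - 1`) plus the rho factor of the residue itself, with extra
#' terminal terms when the amide is adjacent to the free N-terminal amine
#' (residue 2) or to the C-terminal carboxylate (last residue). Residue 1
#' (no reported backbone amide hydrogen) and prolines have no exchangeable
#' amide and raise an error.
#'
#' @param sequence Peptide sequence (validated with [peptide()]).
#' @param index 1-based residue position (>= 2, not proline).
#' @param medium `"H_base"` (abstraction by OH-) or `"D_base"` (OD-).
#' @param table A [sequence_factors()] table.
#' @return The linear-scale factor `10^(log B_lambda + log B_rho + terminal terms)`.
#' @examples
#' sequence_factor("AAAAAAA", 4)   # interior Ala with Ala neighbours: 1
#' @export
sequence_factor <- function(sequence, index, medium = c("H_base", "D_base"),
                            table = sequence_factors()) {
  medium <- match.arg(medium)
  sequence <- peptide(sequence)
  n <- nchar(sequence)
  if (!is.numeric(index) || length(index) != 1L || index != round(index) ||
      index < 1 || index > n) {
    abort_input("`index` must be an integer position in 1..%d", n)
  }
  letters <- strsplit(sequence, "")[[1]]
  if (index == 1) {
    abort_no_amide("residue 1 carries no reported backbone amide hydrogen")
  }
  if (letters[index] == "P") {
    abort_no_amide("proline at position %d has no backbone amide hydrogen",
                   index)
  }
  log_sum <- .factor_lookup(table, letters[index - 1], medium, "log_B_lambda") +
    .factor_lookup(table, letters[index], medium, "log_B_rho")
  if (index == 2) {
    log_sum <- log_sum + .factor_lookup(table, "N_TERM", medium, "log_B_lambda")
  }
  if (index == n) {
    log_sum <- log_sum + .factor_lookup(table, "C_TERM", medium, "log_B_rho")
  }
  10^log_sum
}
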