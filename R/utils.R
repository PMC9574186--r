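#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids; linkers in synthetic proteins draw from
## this set minus C and H so that zinc-ligand positions are unambiguous.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_NO_CH <- setdiff(AA20, c("C", "H"))

#' Round half away from zero to a fixed number of decimals
#'
#' Matches the "round half up" convention used for printed percentages in
#' family reports (e.g. 378/549 -> 68.9), unlike [base::round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == trunc(x)
}

#' @noRd
.check_protein_seq <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    .stopf("%s must be a single character string", what)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad))
    .stopf("%s contains illegal residue(s): %s", what,
           paste(bad, collapse = ", "))
  chars
}

#' @noRd
.check_nt_seq <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    .stopf("%s must be a single character string", what)
  s <- toupper(sequence)
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), iupac)
  if (length(bad))
    .stopf("%s contains non-nucleotide character(s): %s", what,
           paste(bad, collapse = ", "))
  s
}

#' @noRd
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write named sequences to a FASTA file
#'
#' @param x named character vector of sequences (or an `XStringSet`).
#' @param path output file path.
#' @param type `"AA"` or `"DNA"`; ignored when `x` is already an XStringSet.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.character(x)) {
    x <- if (type == "AA") Biostrings::AAStringSet(x)
         else Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  ## keep only the identifier token of the header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a TSV report with a YAML front-matter header
#'
#' Reports carry their provenance (package version, seed, parameters) as
#' commented YAML lines so that every printed number can be audited from
#' the file alone.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, meta = list()) {
  meta <- c(list(package = "zfkit",
                 version = as.character(utils::packageVersion("zfkit")),
                 created = format(Sys.time(), "%Y-%m-%d")), meta)
  hdr <- c("# ---",
           paste0("# ", names(meta), ": ", vapply(meta, function(v)
             paste(format(v), collapse = ","), character(1))),
           "# ---")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
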