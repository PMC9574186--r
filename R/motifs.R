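## Promoter cis-acting element scanning: exact/IUPAC string matching with
## overlapping occurrences counted on both orientations.

MOTIF_CLASSES <- c("ABRE", "DRE", "MBS", "TC-rich", "LTR", "G-box",
                   "MeJA", "auxin")

#' Default cis-acting element dictionary
#'
#' Ships the elements whose strings the source analysis prints: the ABRE
#' core `ACGTG`, the composite ABREs `CGCACGTGTC`, `CGTACGTGCA` and
#' `GCAACGTGTC`, the G-box `CACGTG`, the MBS drought-inducibility motif
#' `CAACTG` and the MeJA-responsive `CGTCA`. DRE, TC-rich, LTR and
#' auxin (TGA-box) slots have no default strings and are supplied through
#' `extra`.
#'
#' @param extra optional data.frame with `name`, `class`, `sequence`
#'   columns appended to the defaults; classes must be among
#'   `r paste(MOTIF_CLASSES, collapse = ", ")`.
#' @return data.frame with `name`, `class` and `sequence` (uppercase,
#'   IUPAC codes allowed).
#' @export
default_motif_dictionary <- function(extra = NULL) {
  d <- data.frame(
    name = c("ABRE_core", "ABRE_CGCACGTGTC", "ABRE_CGTACGTGCA",
             "ABRE_GCAACGTGTC", "G_box", "MBS", "MeJA_CGTCA"),
    class = c("ABRE", "ABRE", "ABRE", "ABRE", "G-box", "MBS", "MeJA"),
    sequence = c("ACGTG", "CGCACGTGTC", "CGTACGTGCA", "GCAACGTGTC",
                 "CACGTG", "CAACTG", "CGTCA"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra),
              all(c("name", "class", "sequence") %in% names(extra)))
    bad <- setdiff(extra$class, MOTIF_CLASSES)
    if (length(bad))
      .stopf("unknown motif class(es): %s", paste(bad, collapse = ", "))
    extra$sequence <- toupper(extra$sequence)
    for (s in extra$sequence) .check_nt_seq(s, "motif sequence")
    d <- rbind(d, extra[, c("name", "class", "sequence")])
  }
  if (anyDuplicated(d$name)) .stopf("duplicate motif names in dictionary")
  d
}

#' Scan promoters for cis-acting elements
#'
#' Counts overlapping occurrences of each motif on the given strand
#' (`forward`) and of its reverse complement on the same strand
#' (`reverse`), reported separately. IUPAC codes in motifs expand to
#' character classes; IUPAC letters in the promoter are matched
#' literally. Palindromic motifs therefore count once in each column.
#'
#' @param promoters named character vector (or `DNAStringSet`) of
#'   uppercase promoter sequences; non-nucleotide characters are a
#'   validation error.
#' @param dictionary motif dictionary from [default_motif_dictionary()].
#' @return long data.frame: `gene_id`, `motif`, `class`, `forward`,
#'   `reverse`.
#' @export
scan_motifs <- function(promoters, dictionary = default_motif_dictionary()) {
  if (methods::is(promoters, "XStringSet")) promoters <- as.character(promoters)
  if (is.null(names(promoters)))
    names(promoters) <- paste0("gene", seq_along(promoters))
  for (p in promoters) if (nzchar(p)) .check_nt_seq(p, "promoter")
  rows <- lapply(names(promoters), function(id) {
    s <- promoters[[id]]
    subj <- if (nzchar(s)) Biostrings::DNAString(s) else NULL
    fwd <- integer(nrow(dictionary))
    rev <- integer(nrow(dictionary))
    for (k in seq_len(nrow(dictionary))) {
      motif <- dictionary$sequence[k]
      if (is.null(subj) || nchar(motif) > nchar(s)) next
      fwd[k] <- Biostrings::countPattern(motif, subj, fixed = "subject")
      rev[k] <- Biostrings::countPattern(.revcomp(motif), subj,
                                         fixed = "subject")
    }
    data.frame(gene_id = id, motif = dictionary$name,
               class = dictionary$class, forward = fwd, reverse = rev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-gene motif hit summary
#'
#' @param scan long scan table from [scan_motifs()].
#' @return data.frame with one row per gene: total hits per class
#'   (forward + reverse) in `<class>_hits` columns plus `has_abre` and
#'   `has_dre` flags.
#' @export
motif_hit_summary <- function(scan) {
  genes <- unique(scan$gene_id)
  classes <- unique(scan$class)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  tot <- scan$forward + scan$reverse
  for (cl in classes) {
    v <- vapply(genes, function(g)
      sum(tot[scan$gene_id == g & scan$class == cl]), numeric(1))
    out[[paste0(gsub("-", "_", cl), "_hits")]] <- as.integer(v)
  }
  out$has_abre <- if ("ABRE_hits" %in% names(out)) out$ABRE_hits > 0 else FALSE
  out$has_dre <- if ("DRE_hits" %in% names(out)) out$DRE_hits > 0 else FALSE
  out
}

#' Summarize cis-acting elements per species
#'
#' @param scan long scan table from [scan_motifs()].
#' @param species_map data.frame with `gene_id` and `species`.
#' @return list with `per_motif` (species x motif totals), `per_class`
#'   (species x class totals) and `abre_dre` (per species: promoter
#'   count, promoters with ABRE and/or DRE, percentage at 1 decimal,
#'   round half up).
#' @export
summarize_elements <- function(scan, species_map) {
  stopifnot(all(c("gene_id", "species") %in% names(species_map)))
  sp_of <- stats::setNames(species_map$species, species_map$gene_id)
  scan$species <- sp_of[scan$gene_id]
  tot <- scan$forward + scan$reverse
  per_motif <- as.data.frame.matrix(
    stats::xtabs(tot ~ scan$species + scan$motif))
  per_class <- as.data.frame.matrix(
    stats::xtabs(tot ~ scan$species + scan$class))
  hs <- motif_hit_summary(scan)
  hs$species <- sp_of[hs$gene_id]
  rows <- lapply(split(hs, hs$species), function(h) {
    n <- nrow(h)
    k <- sum(h$has_abre | h$has_dre)
    data.frame(species = h$species[[1]], n_promoters = n,
               n_abre_or_dre = k,
               pct_abre_or_dre = if (n) round_half_up(100 * k / n, 1) else 0,
               stringsAsFactors = FALSE)
  })
  abre_dre <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_all <- sum(abre_dre$n_promoters)
  k_all <- sum(abre_dre$n_abre_or_dre)
  abre_dre <- rbind(abre_dre, data.frame(
    species = "Total", n_promoters = n_all, n_abre_or_dre = k_all,
    pct_abre_or_dre = if (n_all) round_half_up(100 * k_all / n_all, 1) else 0))
  list(per_motif = per_motif, per_class = per_class, abre_dre = abre_dre)
}
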