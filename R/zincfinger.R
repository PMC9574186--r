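## C2H2 zinc-finger detection and Q/M/Z/D classification.
##
## A finger is a match of the scaffold C-X(2,4)-C-X(min,max)-H-X(3,5)-H,
## or the H2-less variant C-X(2,4)-C-X(min,max)-H with no further His 3-5
## residues after H1 (a D-type candidate). The internal P and L of the
## canonical consensus C-X2~4-C-X3-P-X5-L-X2-H-X3-H are deliberately not
## required: degenerate (M/Z/D) fingers violate them.

#' Detect C2H2 zinc-finger domains in a protein sequence
#'
#' Scans a single amino-acid sequence for all non-overlapping instances of
#' the C2H2 zinc-finger scaffold `C-X(2,4)-C-X(min_spacer,max_spacer)-H`
#' with an optional second His ligand 3-5 residues after the first
#' (absent in D-type candidates). `X` in the input is tolerated inside
#' spacers but never accepted as a ligand.
#'
#' Overlaps are resolved leftmost-first and greedily: the scan emits the
#' best parse at the leftmost possible start, then continues after its
#' end. Competing parses at the same start are ranked by (1) presence of
#' the second His (complete fingers beat H2-less candidates), (2)
#' Cys2-His1 spacer closest to the canonical 12, ties toward the smaller
#' spacer, then (3) smaller Cys1-Cys2 spacer and (4) smaller His1-His2
#' spacer.
#'
#' @param sequence single amino-acid string (20-letter alphabet, `X`
#'   tolerated in spacers).
#' @param protein_id identifier recorded in the output.
#' @param min_spacer,max_spacer bounds on the Cys2-His1 spacer
#'   (defaults 8 and 25, bracketing the 25-30 aa domain span).
#' @return data.frame with one row per finger: `protein_id`, 1-based
#'   ligand positions `c1`, `c2`, `h1`, `h2` (`NA` for D-type
#'   candidates), spacer lengths `c1c2_spacer`, `c2h1_spacer`,
#'   `h1h2_spacer`, the `six_mer` ending at H1 and its Hamming distance
#'   `qalggh_distance` to `QALGGH`.
#' @examples
#' detect_fingers("MSSCAACFAKSGYGQALGGHKKAHNN")
#' @export
detect_fingers <- function(sequence, protein_id = "protein",
                           min_spacer = 8L, max_spacer = 25L) {
  stopifnot(.is_count(min_spacer), .is_count(max_spacer),
            min_spacer <= max_spacer)
  empty <- data.frame(protein_id = character(), c1 = integer(),
                      c2 = integer(), h1 = integer(), h2 = integer(),
                      c1c2_spacer = integer(), c2h1_spacer = integer(),
                      h1h2_spacer = integer(), six_mer = character(),
                      qalggh_distance = integer(),
                      stringsAsFactors = FALSE)
  if (is.character(sequence) && length(sequence) == 1L &&
      !is.na(sequence) && nchar(sequence) == 0L)
    return(empty)
  chars <- .check_protein_seq(sequence)
  cpos <- which(chars == "C")
  hpos <- which(chars == "H")
  if (length(cpos) < 2L || length(hpos) < 1L) return(empty)

  ## enumerate every grammar-conformant parse
  cand <- vector("list", 64L); k <- 0L
  for (c1 in cpos) {
    for (c2 in cpos[cpos >= c1 + 3L & cpos <= c1 + 5L]) {
      for (h1 in hpos[hpos >= c2 + min_spacer + 1L &
                      hpos <= c2 + max_spacer + 1L]) {
        h2s <- hpos[hpos >= h1 + 4L & hpos <= h1 + 6L]
        if (length(h2s) == 0L) h2s <- NA_integer_
        for (h2 in h2s) {
          k <- k + 1L
          if (k > length(cand)) cand <- c(cand, vector("list", length(cand)))
          cand[[k]] <- c(c1, c2, h1, h2)
        }
      }
    }
  }
  if (k == 0L) return(empty)
  m <- do.call(rbind, cand[seq_len(k)])
  colnames(m) <- c("c1", "c2", "h1", "h2")
  sel <- .resolve_fingers(m)
  if (nrow(sel) == 0L) return(empty)

  six <- vapply(sel[, "h1"], function(h1)
    paste(chars[(h1 - 5L):h1], collapse = ""), character(1))
  data.frame(
    protein_id = protein_id,
    c1 = sel[, "c1"], c2 = sel[, "c2"],
    h1 = sel[, "h1"], h2 = sel[, "h2"],
    c1c2_spacer = sel[, "c2"] - sel[, "c1"] - 1L,
    c2h1_spacer = sel[, "h1"] - sel[, "c2"] - 1L,
    h1h2_spacer = sel[, "h2"] - sel[, "h1"] - 1L,
    six_mer = six,
    qalggh_distance = .hamming_qalggh(six),
    stringsAsFactors = FALSE)
}

#' @noRd
.hamming_qalggh <- function(six_mer) {
  ref <- strsplit("QALGGH", "")[[1]]
  vapply(strsplit(six_mer, ""), function(x)
    sum(x != ref), integer(1))
}

## Leftmost-first greedy selection among candidate parses (rows of a
## matrix with columns c1, c2, h1, h2). Ranking at a tied start: complete
## fingers first, then |c2h1 - 12| ascending, c2h1 ascending, c1c2
## ascending, h1h2 ascending.
#' @noRd
.resolve_fingers <- function(m) {
  c2h1 <- m[, "h1"] - m[, "c2"] - 1L
  c1c2 <- m[, "c2"] - m[, "c1"] - 1L
  h1h2 <- m[, "h2"] - m[, "h1"] - 1L
  ord <- order(m[, "c1"],
               is.na(m[, "h2"]),          # complete parses first
               abs(c2h1 - 12L), c2h1, c1c2,
               ifelse(is.na(h1h2), Inf, h1h2))
  m <- m[ord, , drop = FALSE]
  keep <- logical(0)
  pos <- 1L
  sel <- NULL
  i <- 1L
  while (i <= nrow(m)) {
    if (m[i, "c1"] >= pos) {
      sel <- rbind(sel, m[i, , drop = FALSE])
      pos <- max(m[i, c("h1", "h2")], na.rm = TRUE) + 1L
    }
    i <- i + 1L
  }
  if (is.null(sel))
    matrix(integer(0), ncol = 4, dimnames = list(NULL, colnames(m)))
  else sel
}

#' Detect fingers in many proteins
#'
#' @param proteins named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @inheritParams detect_fingers
#' @return row-bound data.frame of [detect_fingers()] results.
#' @export
scan_proteins <- function(proteins, min_spacer = 8L, max_spacer = 25L) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein", seq_along(proteins))
  res <- lapply(names(proteins), function(id)
    detect_fingers(proteins[[id]], protein_id = id,
                   min_spacer = min_spacer, max_spacer = max_spacer))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Classify detected fingers into Q/M/Z/D types
#'
#' Applies the decision tree: (1) second His absent -> `D`; (2)
#' Cys2-His1 spacer greater than 12 -> `Z1`, less than 12 -> `Z2`;
#' (3) spacer exactly 12: Hamming distance of the six residues ending at
#' His1 to `QALGGH` equal to 0 -> `Q`, distance d in 1..5 -> `Md`.
#' A spacer-12 finger is never labelled Z. An exact `QALGGH` found at a
#' spacer other than 12 classifies by the spacing rule (Z) and is flagged
#' in the `qalggh_offspacing` column for audit.
#'
#' @param fingers data.frame from [detect_fingers()]/[scan_proteins()].
#' @return the input with `type` (one of Q, M1..M5, Z1, Z2, D) and
#'   `qalggh_offspacing` columns appended.
#' @export
classify_fingers <- function(fingers) {
  stopifnot(is.data.frame(fingers),
            all(c("h2", "c2h1_spacer", "qalggh_distance") %in%
                  names(fingers)))
  sp <- fingers$c2h1_spacer
  d <- fingers$qalggh_distance
  type <- ifelse(is.na(fingers$h2), "D",
          ifelse(sp > 12L, "Z1",
          ifelse(sp < 12L, "Z2",
          ifelse(d == 0L, "Q", paste0("M", d)))))
  fingers$type <- type
  fingers$qalggh_offspacing <- d == 0L & sp != 12L
  fingers
}

#' Collapse a fine type label to its Q/M/Z/D coarse type
#'
#' @param type character vector of labels (Q, M1..M5, Z1, Z2, D).
#' @return character vector over Q, M, Z, D.
#' @export
coarse_type <- function(type) {
  out <- substr(type, 1, 1)
  bad <- !out %in% c("Q", "M", "Z", "D")
  if (any(bad)) .stopf("unknown type label(s): %s",
                       paste(unique(type[bad]), collapse = ", "))
  out
}

#' Per-protein finger inventory and pure/mixed category
#'
#' M subtypes (M1-M5) and Z subtypes (Z1/Z2) collapse to M and Z; a
#' protein is `mixed` when it carries two or more distinct coarse types,
#' otherwise `pure:<type>`. Proteins with zero detected fingers are not
#' part of the family: they are excluded and listed in the `excluded`
#' attribute rather than raising an error.
#'
#' @param fingers classified finger table from [classify_fingers()].
#' @param protein_ids optional universe of scanned protein ids, used to
#'   report fingerless proteins in the `excluded` attribute.
#' @return data.frame with `protein_id`, `n_fingers`, `types`
#'   (comma-separated fine labels), `coarse_types` (comma-separated,
#'   sorted, unique) and `category`.
#' @export
profile_proteins <- function(fingers, protein_ids = NULL) {
  stopifnot(is.data.frame(fingers), "type" %in% names(fingers))
  sp <- split(fingers, fingers$protein_id)
  rows <- lapply(sp, function(f) {
    ct <- sort(unique(coarse_type(f$type)))
    data.frame(protein_id = f$protein_id[[1]],
               n_fingers = nrow(f),
               types = paste(f$type, collapse = ","),
               coarse_types = paste(ct, collapse = ","),
               category = if (length(ct) >= 2L) "mixed"
                          else paste0("pure:", ct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(protein_id = character(), n_fingers = integer(),
                      types = character(), coarse_types = character(),
                      category = character(), stringsAsFactors = FALSE)
  excluded <- if (is.null(protein_ids)) character(0)
              else setdiff(protein_ids, out$protein_id)
  attr(out, "excluded") <- excluded
  out
}

FINE_TYPES <- c("Q", "M1", "M2", "M3", "M4", "M5", "Z1", "Z2", "D")

#' Summarize a C2H2-ZFP family across species
#'
#' @param profiles protein profile table from [profile_proteins()].
#' @param fingers classified finger table from [classify_fingers()].
#' @param species_map data.frame with `protein_id` and `species` columns.
#' @param annotations optional additional-domain table
#'   (`protein_id`, `domains` as comma-separated names); proteins absent
#'   from it count as containing only C2H2-ZF domains.
#' @return per-species data.frame with protein, C2H2-only, per-type
#'   domain, pure/mixed and total-domain counts; species with zero
#'   proteins yield all-zero rows.
#' @export
summarize_family <- function(profiles, fingers, species_map,
                             annotations = NULL) {
  stopifnot(is.data.frame(species_map),
            all(c("protein_id", "species") %in% names(species_map)))
  species <- unique(species_map$species)
  with_extra <- character(0)
  coiled <- character(0)
  if (!is.null(annotations) && nrow(annotations)) {
    with_extra <- annotations$protein_id[nzchar(annotations$domains)]
    coiled <- annotations$protein_id[
      grepl("coiled-coil", annotations$domains, fixed = TRUE)]
  }
  sp_of <- stats::setNames(species_map$species, species_map$protein_id)
  rows <- lapply(species, function(s) {
    pids <- profiles$protein_id[sp_of[profiles$protein_id] == s]
    p <- profiles[profiles$protein_id %in% pids, , drop = FALSE]
    f <- fingers[fingers$protein_id %in% pids, , drop = FALSE]
    tc <- table(factor(f$type, levels = FINE_TYPES))
    out <- data.frame(species = s,
                      n_proteins = nrow(p),
                      n_c2h2_only = sum(!p$protein_id %in% with_extra),
                      n_coiled_coil = sum(p$protein_id %in% coiled),
                      stringsAsFactors = FALSE)
    for (t in FINE_TYPES) out[[t]] <- as.integer(tc[[t]])
    out$n_domains <- nrow(f)
    out$n_pure <- sum(p$category != "mixed")
    out$n_mixed <- sum(p$category == "mixed")
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
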