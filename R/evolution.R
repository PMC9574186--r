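## Pairwise and codon-aware alignment, Nei-Gojobori (1986) Ka/Ks with
## Jukes-Cantor correction, concatenated-domain export and a small
## neighbor-joining tree. NG86 was chosen because the upstream analysis
## does not document its substitution model; numeric deltas against
## model-based estimators are expected.

#' Global pairwise alignment (Needleman-Wunsch, linear gap penalty)
#'
#' Thin wrapper over [Biostrings::pairwiseAlignment()] with identity
#' scoring: `match`/`mismatch` on the diagonal and a linear `gap`
#' penalty (gap opening 0).
#'
#' @param a,b sequences (single strings; amino acid or nucleotide).
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @return list of class `zf_alignment`: gapped strings `a_aln`/`b_aln`,
#'   `score`, `identity` (matches / aligned non-gap-pair columns) and
#'   `aligned_cols`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) .stopf("cannot align an empty sequence")
  stopifnot(gap <= 0)
  letters <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
  mat <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- match
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap)
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a_aln, "")[[1]]
  cb <- strsplit(b_aln, "")[[1]]
  aligned <- ca != "-" & cb != "-"
  structure(list(
    a_aln = a_aln, b_aln = b_aln,
    score = Biostrings::score(pa),
    identity = if (any(aligned)) mean(ca[aligned] == cb[aligned]) else 0,
    aligned_cols = sum(aligned)), class = "zf_alignment")
}

#' @export
print.zf_alignment <- function(x, ...) {
  cat("Global alignment: score", x$score,
      sprintf("identity %.3f over %d columns\n", x$identity,
              x$aligned_cols))
  cat(x$a_aln, "\n", x$b_aln, "\n", sep = "")
  invisible(x)
}

#' @noRd
.check_cds <- function(cds, what) {
  s <- .check_nt_seq(cds, what)
  if (nchar(s) %% 3 != 0)
    .stopf("%s length (%d) is not a multiple of 3", what, nchar(s))
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- .translate_codons(codons)
  internal <- which(aa == "*")
  internal <- internal[internal < length(codons)]
  if (length(internal))
    .stopf("%s has an internal stop codon at codon %d", what, internal[[1]])
  if (length(aa) && aa[[length(aa)]] == "*") codons <- codons[-length(codons)]
  codons
}

#' @noRd
.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  out <- gc[codons]
  out[is.na(out)] <- "X"  # codons with ambiguous bases
  unname(out)
}

#' Codon-aware alignment of two coding sequences
#'
#' Translates both CDS (terminal stop codons are trimmed; internal stops
#' are an error naming the sequence and codon), aligns the proteins with
#' [global_align()] and threads the codons onto the protein alignment.
#' Codon columns containing a gap or an ambiguous base are dropped and
#' counted.
#'
#' @param cds_a,cds_b coding sequences (lengths divisible by 3).
#' @param ... scoring parameters passed to [global_align()].
#' @return list: `codons_a`, `codons_b` (kept codon columns), `kept`,
#'   `dropped`; kept + dropped equals the number of protein alignment
#'   columns.
#' @export
codon_align <- function(cds_a, cds_b, ...) {
  ca <- .check_cds(cds_a, "cds_a")
  cb <- .check_cds(cds_b, "cds_b")
  al <- global_align(paste(.translate_codons(ca), collapse = ""),
                     paste(.translate_codons(cb), collapse = ""), ...)
  pa <- strsplit(al$a_aln, "")[[1]]
  pb <- strsplit(al$b_aln, "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0); dropped <- 0L
  for (k in seq_along(pa)) {
    codon_a <- if (pa[k] != "-") { ia <- ia + 1L; ca[ia] } else NA
    codon_b <- if (pb[k] != "-") { ib <- ib + 1L; cb[ib] } else NA
    ok <- !is.na(codon_a) && !is.na(codon_b) &&
      !grepl("[^ACGT]", codon_a) && !grepl("[^ACGT]", codon_b)
    if (ok) {
      keep_a <- c(keep_a, codon_a)
      keep_b <- c(keep_b, codon_b)
    } else dropped <- dropped + 1L
  }
  list(codons_a = keep_a, codons_b = keep_b,
       kept = length(keep_a), dropped = dropped)
}

## ---- NG86 machinery ----

## Site counts of one codon: over its 9 single-base changes, each change
## contributes 1/3 of a synonymous site when it preserves the amino acid
## and 1/3 of a nonsynonymous site otherwise. Changes creating a stop
## codon are excluded from both classes (they are not part of the
## mutable space of a coding sequence), so S + N <= 3 per codon.
#' @noRd
.site_counts_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0; n <- 0
  for (pos in 1:3) {
    for (alt in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (gc[[mut]] == "*") next
      if (gc[[mut]] == aa) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s = s, n = n)
}

## Pathway-averaged synonymous/nonsynonymous difference counts between
## two codons: enumerate all orders of the differing positions, exclude
## pathways passing through stop codons (renormalizing the weights);
## when every pathway is blocked, fall back to uniform weights over all.
#' @noRd
.codon_pair_diffs <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  gc <- Biostrings::GENETIC_CODE
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  perms <- .permutations(diff_pos)
  path_sd <- numeric(0); path_nd <- numeric(0); blocked <- logical(0)
  for (p in seq_len(nrow(perms))) {
    cur <- codon_a
    sd <- 0; nd <- 0; stop_hit <- FALSE
    for (pos in perms[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (gc[[nxt]] == "*") stop_hit <- TRUE
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
    blocked <- c(blocked, stop_hit)
  }
  use <- if (all(blocked)) rep(TRUE, length(blocked)) else !blocked
  c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
}

#' @noRd
.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

## memo caches, filled lazily
.ng86_cache <- new.env(parent = emptyenv())

#' @noRd
.site_counts <- function(codon) {
  key <- paste0("S_", codon)
  if (is.null(.ng86_cache[[key]]))
    .ng86_cache[[key]] <- .site_counts_codon(codon)
  .ng86_cache[[key]]
}

#' @noRd
.pair_diffs <- function(a, b) {
  key <- paste0("D_", a, b)
  if (is.null(.ng86_cache[[key]]))
    .ng86_cache[[key]] <- .codon_pair_diffs(a, b)
  .ng86_cache[[key]]
}

#' Jukes-Cantor distance correction
#'
#' @param p proportion of differing sites; must be below 3/4.
#' @return corrected distance `-(3/4) log(1 - (4/3) p)`.
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75)) .stopf("saturated: proportion %.3f >= 3/4", max(p))
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Synonymous sites per codon are the fraction of single-base changes
#' that preserve the amino acid, averaged over the two sequences;
#' nonsynonymous sites are the amino-acid-changing fraction. Changes
#' creating a stop codon belong to neither class: a coding sequence
#' cannot substitute into a stop, so counting such changes as
#' nonsynonymous sites would deflate Ka. Differences are averaged over
#' all substitution pathways between each codon pair, with pathways
#' through stop codons excluded and the weights renormalized (uniform
#' over all pathways when every one is blocked). Proportions are
#' Jukes-Cantor corrected; `p >= 3/4` is an error (`"saturated"`).
#'
#' @param alignment a [codon_align()] result, or a list with `codons_a`
#'   and `codons_b` character vectors of equal length.
#' @param neutral_tol half-width of the ratio band labelled `neutral`
#'   (default 1e-9).
#' @return list of class `zf_kaks`: `ka`, `ks`, `ratio` (`NA` when
#'   `ks = 0`), `selection_mode` (purifying / neutral / positive /
#'   undefined) and the intermediate `S`, `N`, `Sd`, `Nd`, `ps`, `pn`.
#' @export
ng86_kaks <- function(alignment, neutral_tol = 1e-9) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  stopifnot(length(ca) == length(cb))
  if (length(ca) == 0L) .stopf("codon alignment has no columns")
  sc_a <- vapply(ca, .site_counts, numeric(2))
  sc_b <- vapply(cb, .site_counts, numeric(2))
  S <- (sum(sc_a["s", ]) + sum(sc_b["s", ])) / 2
  N <- (sum(sc_a["n", ]) + sum(sc_b["n", ])) / 2
  d <- vapply(seq_along(ca), function(i) .pair_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  ps <- Sd / S
  pn <- Nd / N
  ka <- jukes_cantor(pn)
  ks <- jukes_cantor(ps)
  if (ks == 0) {
    ratio <- NA_real_
    mode <- "undefined"
  } else {
    ratio <- ka / ks
    mode <- if (abs(ratio - 1) <= neutral_tol) "neutral"
            else if (ratio < 1) "purifying" else "positive"
  }
  structure(list(ka = ka, ks = ks, ratio = ratio, selection_mode = mode,
                 S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn),
            class = "zf_kaks")
}

#' @export
print.zf_kaks <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f, Ks = %.4f, Ka/Ks = %s (%s)\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              x$selection_mode))
  invisible(x)
}

#' Ka/Ks table for a set of CDS pairs
#'
#' @param cds named character vector holding pairs as consecutive entries
#'   (`<pair>_1`, `<pair>_2`), or a list of two-element character vectors.
#' @param ... passed to [codon_align()].
#' @return data.frame: `pair`, `ka`, `ks`, `ratio`, `selection_mode`.
#' @export
kaks_pairs <- function(cds, ...) {
  if (is.character(cds)) {
    stopifnot(length(cds) %% 2 == 0)
    idx <- seq(1, length(cds), by = 2)
    pairs <- lapply(idx, function(i) cds[c(i, i + 1L)])
    names(pairs) <- sub("_1$", "", names(cds)[idx])
  } else pairs <- cds
  rows <- lapply(names(pairs), function(p) {
    r <- ng86_kaks(codon_align(pairs[[p]][[1]], pairs[[p]][[2]], ...))
    data.frame(pair = p, ka = r$ka, ks = r$ks, ratio = r$ratio,
               selection_mode = r$selection_mode, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Concatenate the zinc-finger domains of a protein
#'
#' Finger subsequences (C1..H2, or C1..H1 for D-type) joined in N-to-C
#' order, for export to external aligners.
#'
#' @param sequence protein sequence.
#' @param fingers finger table for this protein (rows of
#'   [detect_fingers()] output).
#' @return single concatenated string; `NA` with a warning when the
#'   protein has no fingers.
#' @export
concat_domains <- function(sequence, fingers) {
  if (nrow(fingers) == 0L) {
    warning("protein has no fingers; skipped", call. = FALSE)
    return(NA_character_)
  }
  fingers <- fingers[order(fingers$c1), , drop = FALSE]
  ends <- ifelse(is.na(fingers$h2), fingers$h1, fingers$h2)
  paste(substring(sequence, fingers$c1, ends), collapse = "")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch lengths
#' are clamped to zero and counted. Additive distance matrices are
#' reproduced exactly.
#'
#' @param d symmetric, non-negative distance matrix with zero diagonal
#'   (n >= 3); an asymmetric matrix is a validation error.
#' @param labels optional taxon labels (default: `dimnames`).
#' @return list of class `zf_njtree`: `tree` (`phylo`), `newick` string,
#'   `n_clamped`.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) .stopf("distance matrix must be square")
  if (nrow(d) < 3L) .stopf("need at least 3 taxa")
  if (any(d < 0)) .stopf("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-8)) .stopf("distance matrix must be symmetric")
  if (any(diag(d) != 0)) .stopf("diagonal must be zero")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 n_clamped = sum(neg)), class = "zf_njtree")
}

#' @export
print.zf_njtree <- function(x, ...) {
  cat("Neighbor-joining tree (", length(x$tree$tip.label), " taxa",
      if (x$n_clamped) sprintf(", %d branch(es) clamped to 0", x$n_clamped),
      "):\n", x$newick, "\n", sep = "")
  invisible(x)
}
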