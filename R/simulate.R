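## Synthetic-data generators. Every generator emits data plus a truth
## table and self-verifies by running the consuming stage (scanner, motif
## scan, DEG caller) on its own output, so downstream round-trip tests
## have exact oracles. Protein linkers and flanks draw from the 18
## residues excluding C and H, and promoter backgrounds from {A,C,T}
## (every shipped motif and its reverse complement contains a G), which
## keeps planted items unambiguous.

#' Build and validate a species manifest for the generators
#'
#' @param species_code short species label.
#' @param n_proteins number of proteins/genes to generate.
#' @param planted_fingers named integer vector of finger requests, e.g.
#'   `c(Q = 3, M1 = 2, Z1 = 1)`; names must be fine type labels.
#' @param frac_c2h2_only fraction of proteins carrying only C2H2-ZF
#'   domains (the rest get a coiled-coil entry in the annotation table).
#' @param chromosome_count number of chromosomes for the genome layout.
#' @param seed integer RNG seed; the same manifest and seed give
#'   byte-identical outputs.
#' @return list of class `zf_manifest`.
#' @export
species_manifest <- function(species_code, n_proteins, planted_fingers,
                             frac_c2h2_only = 1, chromosome_count = 1L,
                             seed = 1L) {
  if (!.is_count(n_proteins)) .stopf("n_proteins must be a count")
  if (!.is_count(chromosome_count) || chromosome_count < 1)
    .stopf("chromosome_count must be a positive count")
  if (!is.numeric(frac_c2h2_only) || frac_c2h2_only < 0 ||
      frac_c2h2_only > 1)
    .stopf("frac_c2h2_only must be in [0, 1]")
  pf <- planted_fingers
  if (length(pf)) {
    bad <- setdiff(names(pf), FINE_TYPES)
    if (length(bad)) .stopf("unknown finger type(s): %s",
                            paste(bad, collapse = ", "))
    if (any(pf < 0) || any(pf != trunc(pf)))
      .stopf("finger counts must be non-negative integers")
  }
  if (sum(pf) > 0 && n_proteins == 0)
    .stopf("impossible request: planted fingers but zero proteins")
  structure(list(species_code = species_code,
                 n_proteins = as.integer(n_proteins),
                 planted_fingers = pf,
                 frac_c2h2_only = frac_c2h2_only,
                 chromosome_count = as.integer(chromosome_count),
                 seed = as.integer(seed)),
            class = "zf_manifest")
}

#' @noRd
.linker <- function(n) paste(sample(AA_NO_CH, n, replace = TRUE),
                             collapse = "")

## One exact finger instance of a fine type. Returns the sequence plus
## ligand offsets (1-based within the instance).
#' @noRd
.finger_instance <- function(type) {
  has_h2 <- TRUE
  if (type == "Q") {
    spacer <- paste0(.linker(7), "QALGG"); h1h2 <- 3L
  } else if (grepl("^M[1-5]$", type)) {
    d <- as.integer(substr(type, 2, 2))
    motif <- strsplit("QALGG", "")[[1]]
    pos <- sample(5L, d)
    for (p in pos)
      motif[p] <- sample(setdiff(AA_NO_CH, motif[p]), 1)
    spacer <- paste0(.linker(7), paste(motif, collapse = ""))
    h1h2 <- sample(3:5, 1)
  } else if (type == "Z1") {
    spacer <- .linker(sample(13:25, 1)); h1h2 <- sample(3:5, 1)
  } else if (type == "Z2") {
    spacer <- .linker(sample(8:11, 1)); h1h2 <- sample(3:5, 1)
  } else if (type == "D") {
    spacer <- .linker(sample(8:25, 1)); has_h2 <- FALSE; h1h2 <- NA_integer_
  } else .stopf("unknown finger type: %s", type)
  c1c2 <- sample(2:4, 1)
  seq <- paste0("C", .linker(c1c2), "C", spacer, "H",
                if (has_h2) paste0(.linker(h1h2), "H") else "")
  c1 <- 1L
  c2 <- c1 + c1c2 + 1L
  h1 <- c2 + nchar(spacer) + 1L
  h2 <- if (has_h2) h1 + h1h2 + 1L else NA_integer_
  list(seq = seq, c1 = c1, c2 = c2, h1 = h1, h2 = h2)
}

#' Generate a synthetic proteome with planted fingers
#'
#' Planted fingers are exact instances of their type's pattern, separated
#' by C/H-free linkers (10-15 aa) and flanks (5-10 aa), so the scanner
#' and classifier must recover exactly the planted inventory; the
#' generator verifies this round trip before returning and resamples any
#' protein that fails it.
#'
#' @param manifest a [species_manifest()].
#' @return list: `proteins` (named character), `truth` (one row per
#'   planted finger: `protein_id`, `finger_index`, `type`, ligand
#'   positions), `annotations` (additional-domain table for proteins with
#'   `frac_c2h2_only` complement), `manifest`.
#' @export
generate_proteome <- function(manifest) {
  stopifnot(inherits(manifest, "zf_manifest"))
  set.seed(manifest$seed)
  n <- manifest$n_proteins
  ids <- sprintf("%s_p%03d", manifest$species_code, seq_len(n))
  types <- rep(names(manifest$planted_fingers), manifest$planted_fingers)
  if (length(types)) types <- sample(types)
  ## distribute fingers over proteins as evenly as possible
  owner <- if (length(types)) rep_len(seq_len(n), length(types)) else integer(0)

  proteins <- character(n)
  truth_rows <- list()
  for (i in seq_len(n)) {
    my_types <- types[owner == i]
    for (try in seq_len(20L)) {
      parts <- character(0)
      pos <- nchar(flank <- .linker(sample(5:10, 1)))
      parts <- flank
      rows <- list()
      if (length(my_types)) {
        for (k in seq_along(my_types)) {
          inst <- .finger_instance(my_types[k])
          rows[[k]] <- data.frame(
            protein_id = ids[i], finger_index = k, type = my_types[k],
            c1 = pos + inst$c1, c2 = pos + inst$c2,
            h1 = pos + inst$h1,
            h2 = if (is.na(inst$h2)) NA_integer_ else pos + inst$h2,
            stringsAsFactors = FALSE)
          link <- .linker(sample(10:15, 1))
          parts <- paste0(parts, inst$seq, link)
          pos <- pos + nchar(inst$seq) + nchar(link)
        }
      } else {
        parts <- paste0(parts, .linker(sample(25:50, 1)))
      }
      seq <- parts
      ## round-trip self-check: detected fingers must equal the plant
      det <- classify_fingers(detect_fingers(seq, protein_id = ids[i]))
      tr <- if (length(rows)) do.call(rbind, rows) else
        data.frame(c1 = integer(), type = character())
      ok <- nrow(det) == nrow(tr) &&
        (nrow(det) == 0L ||
           (all(det$c1 == tr$c1) && all(det$type == tr$type) &&
              all(det$h1 == tr$h1)))
      if (ok) break
    }
    if (!ok) .stopf("could not realize protein %s after 20 attempts", ids[i])
    proteins[i] <- seq
    truth_rows <- c(truth_rows, if (length(my_types)) list(do.call(rbind, rows)))
  }
  names(proteins) <- ids
  truth <- if (length(truth_rows))
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  else data.frame(protein_id = character(), finger_index = integer(),
                  type = character(), c1 = integer(), c2 = integer(),
                  h1 = integer(), h2 = integer(), stringsAsFactors = FALSE)
  n_extra <- round((1 - manifest$frac_c2h2_only) * n)
  extra_ids <- if (n_extra > 0) sample(ids, n_extra) else character(0)
  annotations <- data.frame(protein_id = extra_ids,
                            domains = rep("coiled-coil", length(extra_ids)),
                            stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth, annotations = annotations,
       manifest = manifest)
}

## ---- genome + annotation ----

## codons never containing a stop and starting from {A,C,T}-safe set is
## unnecessary; sample uniformly from the 61 sense codons.
#' @noRd
.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' @noRd
.bg_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
}

## Count overlapping occurrences of `motif` (IUPAC in the motif allowed)
## on the forward orientation of `s`.
#' @noRd
.count_fwd <- function(motif, s) {
  if (!nzchar(s) || nchar(motif) > nchar(s)) return(0L)
  Biostrings::countPattern(motif, Biostrings::DNAString(s),
                           fixed = "subject")
}

## Build one 2000-nt promoter holding the planted motif instances, with
## {A,C,T} background and 5-nt T buffers around each instance. The
## assembled promoter is re-scanned against `check_motifs` and must show
## exactly the expected counts (expected = plant counts plus occurrences
## of each motif inside the other planted strings), else it is resampled.
#' @noRd
.build_promoter <- function(plan, check_motifs, length_nt = 2000L,
                            max_tries = 50L) {
  insts <- character(0)
  if (!is.null(plan) && nrow(plan)) {
    for (k in seq_len(nrow(plan))) {
      s <- if (plan$strand[k] == "-") .revcomp(plan$motif[k]) else
        plan$motif[k]
      insts <- c(insts, rep(s, plan$count[k]))
    }
  }
  blocks <- if (length(insts)) paste0("TTTTT", insts, "TTTTT") else character(0)
  used <- sum(nchar(blocks))
  if (used > length_nt)
    .stopf("planted motifs (%d nt with buffers) do not fit in a %d nt promoter",
           used, length_nt)
  ## expected counts: plants plus containments inside planted strings
  expected <- vapply(check_motifs, function(m) {
    f <- sum(vapply(insts, function(s) .count_fwd(m, s), integer(1)))
    r <- sum(vapply(insts, function(s) .count_fwd(.revcomp(m), s),
                    integer(1)))
    c(f, r)
  }, numeric(2))
  for (try in seq_len(max_tries)) {
    blocks_t <- if (length(blocks)) sample(blocks) else character(0)
    free <- length_nt - used
    cuts <- sort(c(0, if (length(blocks_t))
      sample.int(free + 1L, length(blocks_t), replace = TRUE) - 1L, free))
    gaps <- diff(cuts)
    pieces <- character(0)
    for (k in seq_along(blocks_t))
      pieces <- c(pieces, .bg_nt(gaps[k]), blocks_t[k])
    pieces <- c(pieces, .bg_nt(gaps[length(gaps)]))
    prom <- paste(pieces, collapse = "")
    if (!length(check_motifs)) return(prom)
    got <- vapply(check_motifs, function(m)
      c(.count_fwd(m, prom), .count_fwd(.revcomp(m), prom)), numeric(2))
    if (all(got == expected)) return(prom)
  }
  .stopf("could not assemble a promoter with exactly the planted counts")
}

#' Generate a synthetic genome with GFF3 gene models and planted promoters
#'
#' Lays `n_proteins` genes over the manifest's chromosomes; each gene is
#' a 2000-nt promoter (immediately upstream of the ATG) followed by its
#' CDS, split over a chosen number of exons, on alternating strands.
#' Promoters carry the planted motif instances at exactly the requested
#' counts (verified by self-scan against the default dictionary plus the
#' planted motifs). Tandem arrays are planted as adjacent genes with
#' near-identical coding sequences.
#'
#' @param manifest a [species_manifest()].
#' @param motif_plan optional list, one entry per gene index, each a
#'   data.frame with `motif`, `count` and optionally `strand` (`"+"` by
#'   default: the instance is inserted in that orientation).
#' @param exon_counts optional integer vector (recycled) of exons per
#'   gene; default samples 1-4.
#' @param strands optional strand vector (recycled); default alternates.
#' @param tandem optional list of integer vectors of consecutive gene
#'   indices to plant as tandem arrays (>= 95% protein identity).
#' @param cds_codons codons per gene (default 40).
#' @return list: `genome` (named character, one contig per chromosome),
#'   `gff` (character vector of GFF3 lines), `proteins` (translations,
#'   named by mRNA id), `cds` (named by mRNA id), `truth` (list with
#'   `genes`, `promoters`, `tandem`), `manifest`.
#' @export
generate_genome_annotation <- function(manifest, motif_plan = NULL,
                                       exon_counts = NULL, strands = NULL,
                                       tandem = NULL, cds_codons = 40L) {
  stopifnot(inherits(manifest, "zf_manifest"))
  set.seed(manifest$seed + 1L)
  n <- manifest$n_proteins
  if (n == 0L)
    return(list(genome = character(0), gff = "##gff-version 3",
                proteins = character(0), cds = character(0),
                truth = list(genes = NULL, promoters = NULL,
                             tandem = list()),
                manifest = manifest))
  code <- manifest$species_code
  gids <- sprintf("%s_g%03d", code, seq_len(n))
  if (is.null(exon_counts)) exon_counts <- sample(1:4, n, replace = TRUE)
  exon_counts <- rep_len(as.integer(exon_counts), n)
  if (is.null(strands)) strands <- rep_len(c("+", "-"), n)
  strands <- rep_len(strands, n)
  if (!is.null(tandem)) {
    for (arr in tandem)
      if (!all(diff(sort(arr)) == 1L))
        .stopf("tandem array indices must be consecutive")
  }

  ## coding sequences (multiple of 3, no stops, leading ATG)
  codons <- .sense_codons()
  make_cds <- function() paste(c("ATG",
    sample(codons, cds_codons - 1L, replace = TRUE)), collapse = "")
  cds <- character(n)
  done <- logical(n)
  if (!is.null(tandem)) {
    for (arr in tandem) {
      base <- make_cds()
      for (j in seq_along(arr)) {
        s <- base
        if (j > 1L) {  # ~2% of codons substituted (never the ATG), stop-free
          mut <- sample(2:cds_codons, max(1L, round(0.02 * cds_codons)))
          for (p in mut)
            substr(s, 3 * p - 2, 3 * p) <- sample(codons, 1)
        }
        cds[arr[j]] <- s
        done[arr[j]] <- TRUE
      }
    }
  }
  cds[!done] <- replicate(sum(!done), make_cds())

  ## promoters with planted motifs
  dict <- default_motif_dictionary()
  prom <- character(n)
  prom_truth <- list()
  for (i in seq_len(n)) {
    plan <- NULL
    if (!is.null(motif_plan) && length(motif_plan) >= i &&
        !is.null(motif_plan[[i]])) {
      plan <- as.data.frame(motif_plan[[i]], stringsAsFactors = FALSE)
      if (is.null(plan$strand)) plan$strand <- "+"
      plan$motif <- toupper(plan$motif)
    }
    check <- unique(c(dict$sequence, plan$motif))
    prom[i] <- .build_promoter(plan, check)
    if (!is.null(plan) && nrow(plan))
      prom_truth[[length(prom_truth) + 1L]] <-
        cbind(gene_id = gids[i], plan)
  }
  prom_truth <- if (length(prom_truth))
    do.call(rbind, c(prom_truth, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(), motif = character(),
                  count = integer(), strand = character(),
                  stringsAsFactors = FALSE)

  ## chromosome assembly (block-wise, so consecutive indices are adjacent)
  chr_of <- sort(rep_len(seq_len(manifest$chromosome_count), n))
  if (!is.null(tandem)) {
    for (arr in tandem)
      if (length(unique(chr_of[arr])) != 1L)
        .stopf("tandem array %s straddles a chromosome boundary",
               paste(arr, collapse = ","))
  }
  chrom_names <- sprintf("%s_chr%02d", code, seq_len(manifest$chromosome_count))
  contigs <- stats::setNames(rep("", manifest$chromosome_count), chrom_names)
  gff <- c("##gff-version 3")
  gene_rows <- list()
  proteins <- character(n)

  for (i in seq_len(n)) {
    k <- exon_counts[i]
    s <- cds[i]
    L <- nchar(s)
    ## split CDS into k exon chunks (each >= 3 nt)
    if (k > 1L) {
      cuts <- sort(sample(seq(3L, L - 3L, by = 3L), k - 1L))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, L)
    } else { starts <- 1L; ends <- L }
    introns <- replicate(max(0L, k - 1L), .bg_nt(sample(50:120, 1)))
    ## sense cassette: [promoter][e1 i1 e2 ... ek]
    sense <- prom[i]
    exon_pos <- matrix(0L, k, 2)
    off <- nchar(sense)
    for (j in seq_len(k)) {
      exon_pos[j, ] <- c(off + 1L, off + (ends[j] - starts[j] + 1L))
      sense <- paste0(sense, substr(s, starts[j], ends[j]))
      off <- exon_pos[j, 2]
      if (j < k) { sense <- paste0(sense, introns[j]); off <- off + nchar(introns[j]) }
    }
    Lc <- nchar(sense)
    chr <- chrom_names[chr_of[i]]
    spacer <- .bg_nt(200L)
    o <- nchar(contigs[[chr]]) + nchar(spacer)   # cassette offset
    placed <- if (strands[i] == "-") .revcomp(sense) else sense
    contigs[[chr]] <- paste0(contigs[[chr]], spacer, placed)
    ## map sense positions to forward coordinates
    map <- function(a, b) {
      if (strands[i] == "-") c(o + (Lc - b) + 1L, o + (Lc - a) + 1L)
      else c(o + a, o + b)
    }
    segs <- t(apply(exon_pos, 1, function(e) map(e[1], e[2])))
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    gid <- gids[i]; mid <- paste0(gid, ".t1")
    g_start <- min(segs[, 1]); g_end <- max(segs[, 2])
    line <- function(type, st, en, id, parent = NULL)
      paste(chr, "zfkit", type, st, en, ".", strands[i], ".",
            paste0("ID=", id, if (!is.null(parent))
              paste0(";Parent=", parent)), sep = "\t")
    gff <- c(gff, line("gene", g_start, g_end, gid),
             line("mRNA", g_start, g_end, mid, gid))
    for (j in seq_len(nrow(segs)))
      gff <- c(gff,
               line("exon", segs[j, 1], segs[j, 2],
                    paste0(mid, ".e", j), mid),
               line("CDS", segs[j, 1], segs[j, 2],
                    paste0(mid, ".c", j), mid))
    proteins[i] <- as.character(Biostrings::translate(
      Biostrings::DNAString(s)))
    gene_rows[[i]] <- data.frame(
      gene_id = gid, protein_id = mid, chromosome = chr,
      strand = strands[i], exon_count = k, intron_count = k - 1L,
      translation_start = if (strands[i] == "-") max(segs[, 2])
                          else min(segs[, 1]),
      promoter = prom[i], stringsAsFactors = FALSE)
  }
  names(proteins) <- paste0(gids, ".t1")
  names(cds) <- paste0(gids, ".t1")
  genes_truth <- do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))
  list(genome = contigs, gff = gff, proteins = proteins, cds = cds,
       truth = list(genes = genes_truth, promoters = prom_truth,
                    tandem = if (is.null(tandem)) list() else
                      lapply(tandem, function(a) gids[a])),
       manifest = manifest)
}

#' Generate CDS pairs evolved from a common ancestor
#'
#' Each pair descends from one stop-free ancestor of `codons_per_gene`
#' codons by codon-wise substitution: per codon, one substitution
#' opportunity at a randomly chosen position (shared by the two
#' descendants, so the codons of a pair never differ at more than one
#' position and NG86 pathway averaging is exact). Each descendant
#' proposes a uniform alternative base there, accepted with probability
#' `syn_rate` when the change preserves the amino acid and `nonsyn_rate`
#' otherwise; proposals creating a stop codon are always rejected. The
#' truth table records realized counts. With `nonsyn_rate = 0` the
#' downstream Ka estimate is therefore exactly zero.
#'
#' @param n_pairs number of pairs.
#' @param codons_per_gene codons per sequence.
#' @param syn_rate,nonsyn_rate acceptance probabilities in \[0, 1\];
#'   keep them small enough that the expected proportion of differing
#'   sites stays below 3/4 (Jukes-Cantor domain).
#' @param seed RNG seed.
#' @return list: `cds` (named character, `pair<k>_1`/`pair<k>_2`),
#'   `truth` (`pair`, `syn_subs`, `nonsyn_subs`).
#' @export
generate_duplicate_pairs <- function(n_pairs, codons_per_gene, syn_rate,
                                     nonsyn_rate, seed = 1L) {
  stopifnot(.is_count(n_pairs), .is_count(codons_per_gene),
            codons_per_gene > 0)
  if (syn_rate < 0 || syn_rate > 1 || nonsyn_rate < 0 || nonsyn_rate > 1)
    .stopf("rates must be in [0, 1]")
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  codons <- .sense_codons()
  bases <- c("A", "C", "G", "T")
  evolve <- function(anc, pos_of) {
    cod <- anc
    syn <- 0L; nonsyn <- 0L
    for (ci in seq_along(cod)) {
      pos <- pos_of[ci]
      cur <- cod[ci]
      alt <- sample(setdiff(bases, substr(cur, pos, pos)), 1)
      mut <- cur
      substr(mut, pos, pos) <- alt
      if (gc[[mut]] == "*") next
      is_syn <- gc[[mut]] == gc[[cur]]
      if (stats::runif(1) < (if (is_syn) syn_rate else nonsyn_rate)) {
        cod[ci] <- mut
        if (is_syn) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      }
    }
    list(cod = cod, syn = syn, nonsyn = nonsyn)
  }
  out <- character(2 * n_pairs)
  truth <- data.frame(pair = sprintf("pair%03d", seq_len(n_pairs)),
                      syn_subs = integer(n_pairs),
                      nonsyn_subs = integer(n_pairs),
                      stringsAsFactors = FALSE)
  for (p in seq_len(n_pairs)) {
    anc <- sample(codons, codons_per_gene, replace = TRUE)
    pos_of <- sample(3L, codons_per_gene, replace = TRUE)
    a <- evolve(anc, pos_of); b <- evolve(anc, pos_of)
    out[2 * p - 1L] <- paste(a$cod, collapse = "")
    out[2 * p] <- paste(b$cod, collapse = "")
    truth$syn_subs[p] <- a$syn + b$syn
    truth$nonsyn_subs[p] <- a$nonsyn + b$nonsyn
  }
  names(out) <- paste0(rep(truth$pair, each = 2), c("_1", "_2"))
  list(cds = out, truth = truth)
}

#' Generate a five-stage expression data set with planted DEG patterns
#'
#' Differentially expressed genes follow one of the six
#' [pattern_templates()] with stage means `base * 2^(amp * template)`
#' (lognormal baseline, default amplitude 3 so planted fold changes
#' reach 8x) and three replicates per stage with lognormal noise of
#' log-sd `noise_sd`. The three per-method significance tables are
#' generated directly: true DEGs receive all three significances below
#' 0.05 on their strongly-changing contrasts, non-DEGs always fail the
#' third method, so the intersection caller recovers the truth exactly
#' (the generator verifies this before returning).
#'
#' @param n_genes total genes.
#' @param pattern_mix named or positional integer vector of DEG counts
#'   per pattern 1..6; `sum(pattern_mix) <= n_genes`.
#' @param noise_sd lognormal replicate noise, natural-log scale
#'   (default 0.2; 0 gives noise-free profiles).
#' @param seed RNG seed.
#' @param amp log2 amplitude applied to the templates (default 3).
#' @return list: `fpkm` (genes x 15 matrix, columns `HD_1..FRE_3`),
#'   `tables` (list of three DE tables: `gene_id`, `contrast`, `log2fc`,
#'   `sig`), `truth` (`gene_id`, `is_deg`, `pattern`).
#' @export
generate_expression <- function(n_genes, pattern_mix, noise_sd = 0.2,
                                seed = 1L, amp = 3) {
  stopifnot(.is_count(n_genes))
  pm <- as.integer(pattern_mix)
  if (is.null(names(pattern_mix))) {
    if (length(pm) > 6L) .stopf("pattern_mix has more than 6 entries")
    pat_ids <- seq_along(pm)
  } else {
    pat_ids <- as.integer(sub("^pattern", "", names(pattern_mix)))
  }
  if (any(is.na(pat_ids)) || any(pat_ids < 1L) || any(pat_ids > 6L))
    .stopf("pattern ids must be in 1..6")
  if (sum(pm) > n_genes)
    .stopf("more planted DEGs (%d) than genes (%d)", sum(pm), n_genes)
  set.seed(seed)
  tmpl <- pattern_templates()
  ids <- sprintf("gene%04d", seq_len(n_genes))
  pattern <- rep(NA_integer_, n_genes)
  deg_idx <- sample.int(n_genes, sum(pm))
  pattern[deg_idx] <- sample(rep(pat_ids, pm))
  is_deg <- !is.na(pattern)

  contrasts <- paste0(STAGES[-1], "_vs_HD")
  nrep <- 3L
  cols <- paste(rep(STAGES, each = nrep), seq_len(nrep), sep = "_")
  fpkm <- matrix(0, n_genes, length(cols), dimnames = list(ids, cols))
  lfc <- matrix(0, n_genes, 4, dimnames = list(ids, contrasts))

  base <- stats::rlnorm(n_genes, meanlog = log(20), sdlog = 0.5)
  for (g in seq_len(n_genes)) {
    t5 <- if (is_deg[g]) tmpl[pattern[g], ] else rep(0, 5)
    mu <- base[g] * 2^(amp * t5)
    qualifying <- which(abs(amp * (t5[-1] - t5[1])) >= 1)
    for (try in seq_len(20L)) {
      vals <- rep(mu, each = nrep) *
        exp(stats::rnorm(5 * nrep, 0, noise_sd))
      sm <- vapply(seq_len(5), function(s)
        mean(vals[(s - 1) * nrep + seq_len(nrep)]), numeric(1))
      l <- log2(sm[-1] / sm[1])
      ## a true DEG must clear the fold-change bar on a contrast whose
      ## significances will also pass, so the intersection rule recovers
      ## the planted truth exactly
      if (!is_deg[g] || any(abs(l[qualifying]) >= 1)) break
    }
    fpkm[g, ] <- vals
    lfc[g, ] <- l
  }

  make_table <- function(method) {
    rows <- expand.grid(gene_id = ids, contrast = contrasts,
                        stringsAsFactors = FALSE)
    rows$log2fc <- lfc[cbind(rows$gene_id, rows$contrast)]
    sig <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      g <- match(rows$gene_id[r], ids)
      ci <- match(rows$contrast[r], contrasts)
      qual <- is_deg[g] &&
        abs(amp * (tmpl[pattern[g], ci + 1L] - tmpl[pattern[g], 1L])) >= 1 &&
        abs(lfc[g, ci]) >= 1
      sig[r] <- if (qual) stats::runif(1, 1e-4, 0.049)
        else if (method < 3) stats::runif(1)
        else stats::runif(1, 0.06, 1)
    }
    rows$sig <- sig
    rows
  }
  tables <- lapply(1:3, make_table)
  names(tables) <- paste0("method", 1:3)
  truth <- data.frame(gene_id = ids, is_deg = is_deg,
                      pattern = ifelse(is_deg, paste0("pattern", pattern),
                                       NA_character_),
                      stringsAsFactors = FALSE)
  ## self-check: the intersection caller must recover the planted truth
  calls <- call_degs(tables)$calls
  if (!identical(calls$is_deg[match(ids, calls$gene_id)], is_deg))
    .stopf("internal error: generated tables do not reproduce the DEG truth")
  list(fpkm = fpkm, tables = tables, truth = truth)
}
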