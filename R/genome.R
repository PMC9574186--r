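## Gene models from GFF3: structure, chromosomal distribution, duplicate
## pairs (tandem vs segmental) and promoter extraction. Coordinates are
## GFF3 throughout: 1-based, inclusive.

#' Parse gene models from a GFF3 file
#'
#' One model is kept per gene, from its primary isoform: the mRNA
#' carrying a truthy `canonical` or `primary` attribute when present,
#' otherwise the lowest-sorting mRNA ID. Exon count comes from `exon`
#' features of the chosen mRNA (falling back to its CDS segments) and
#' intron count is exon count minus one. Genes without CDS are skipped
#' with a warning.
#'
#' @param gff3 path to a GFF3 file.
#' @return data.frame with `gene_id`, `protein_id` (the chosen mRNA ID),
#'   `chromosome`, `strand`, `exon_count`, `intron_count`,
#'   `translation_start` (genomic coordinate of the first CDS base,
#'   strand-aware), `cds_start`/`cds_end` (span) and a `cds_segments`
#'   list-column of two-column start/end matrices.
#' @export
parse_gene_models <- function(gff3) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  genes <- which(type == "gene")
  mrnas <- which(type == "mRNA")
  cds <- which(type == "CDS")
  exons <- which(type == "exon")

  pick_primary <- function(cand) {
    for (attr in c("canonical", "primary")) {
      if (!is.null(md[[attr]])) {
        v <- md[[attr]][cand]
        hit <- which(!is.na(v) & v %in% c("true", "TRUE", "1", "yes"))
        if (length(hit)) return(cand[hit[[1]]])
      }
    }
    cand[order(id[cand])][[1]]
  }

  rows <- list()
  for (g in genes) {
    gid <- id[[g]]
    cand <- mrnas[parent[mrnas] %in% gid]
    if (length(cand) == 0L) cand <- g  # CDS attached directly to the gene
    m <- pick_primary(cand)
    mid <- id[[m]]
    seg_idx <- cds[parent[cds] %in% mid]
    if (length(seg_idx) == 0L) {
      warning(sprintf("gene %s has no CDS; skipped", gid), call. = FALSE)
      next
    }
    segs <- cbind(start = GenomicRanges::start(gr)[seg_idx],
                  end = GenomicRanges::end(gr)[seg_idx])
    segs <- segs[order(segs[, "start"]), , drop = FALSE]
    exo_idx <- exons[parent[exons] %in% mid]
    n_exon <- if (length(exo_idx)) length(exo_idx) else nrow(segs)
    strand <- as.character(GenomicRanges::strand(gr)[m])
    rows[[length(rows) + 1L]] <- list(
      gene_id = gid, protein_id = mid,
      chromosome = as.character(GenomicRanges::seqnames(gr)[g]),
      strand = strand,
      exon_count = n_exon, intron_count = n_exon - 1L,
      translation_start = if (strand == "-") max(segs[, "end"])
                          else min(segs[, "start"]),
      cds_start = min(segs[, "start"]), cds_end = max(segs[, "end"]),
      cds_segments = segs)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), protein_id = character(),
                      chromosome = character(), strand = character(),
                      exon_count = integer(), intron_count = integer(),
                      translation_start = integer(), cds_start = integer(),
                      cds_end = integer()))
  out <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    chromosome = vapply(rows, `[[`, character(1), "chromosome"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    exon_count = vapply(rows, `[[`, integer(1), "exon_count"),
    intron_count = vapply(rows, `[[`, integer(1), "intron_count"),
    translation_start = vapply(rows, function(r)
      as.integer(r$translation_start), integer(1)),
    cds_start = vapply(rows, function(r)
      as.integer(r$cds_start), integer(1)),
    cds_end = vapply(rows, function(r)
      as.integer(r$cds_end), integer(1)),
    stringsAsFactors = FALSE)
  out$cds_segments <- lapply(rows, `[[`, "cds_segments")
  out
}

#' Per-chromosome gene counts
#'
#' @param models gene-model table from [parse_gene_models()].
#' @return data.frame with `chromosome` and `n`; counts sum to the number
#'   of models.
#' @export
chromosome_distribution <- function(models) {
  if (nrow(models) == 0L)
    return(data.frame(chromosome = character(), n = integer()))
  tc <- table(models$chromosome)
  data.frame(chromosome = names(tc), n = as.integer(tc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find duplicate (paralog) gene pairs by sequence similarity and position
#'
#' All-vs-all global protein alignment ([global_align()] with identity
#' scoring); pairs pass when alignment identity and coverage of the
#' shorter sequence reach the thresholds. A passing pair is `tandem` when
#' both genes sit on the same chromosome with at most `max_intervening`
#' family genes between them and within `max_bp`; otherwise it is a
#' (segmental) `duplicate`.
#'
#' @param proteins named character vector of protein sequences; names
#'   must match `models$protein_id`.
#' @param models gene-model table from [parse_gene_models()].
#' @param identity_min minimum alignment identity (default 0.70).
#' @param coverage_min minimum aligned fraction of the shorter sequence
#'   (default 0.70).
#' @param max_intervening,max_bp tandem criteria (defaults 10 genes,
#'   100 kb); the source method prints no thresholds, so these are
#'   package defaults.
#' @return data.frame of `ParalogPair` rows: `gene_a`, `gene_b`,
#'   `protein_identity`, `same_chromosome`, `intervening_genes`,
#'   `genomic_distance`, `relation`.
#' @export
find_duplicate_pairs <- function(proteins, models, identity_min = 0.70,
                                 coverage_min = 0.70, max_intervening = 10L,
                                 max_bp = 100000L) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  models <- models[models$protein_id %in% names(proteins), , drop = FALSE]
  n <- nrow(models)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      protein_identity = numeric(),
                      same_chromosome = logical(),
                      intervening_genes = integer(),
                      genomic_distance = integer(), relation = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ## rank genes along each chromosome for the intervening-gene count
  rank_on_chr <- stats::ave(models$translation_start, models$chromosome,
                            FUN = rank)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- proteins[[models$protein_id[i]]]
      b <- proteins[[models$protein_id[j]]]
      al <- global_align(a, b)
      if (al$identity < identity_min) next
      if (al$aligned_cols / min(nchar(a), nchar(b)) < coverage_min) next
      same_chr <- models$chromosome[i] == models$chromosome[j]
      if (same_chr) {
        interv <- as.integer(abs(rank_on_chr[i] - rank_on_chr[j]) - 1L)
        dist <- max(0L, max(models$cds_start[i], models$cds_start[j]) -
                         min(models$cds_end[i], models$cds_end[j]))
      } else {
        interv <- NA_integer_
        dist <- NA_integer_
      }
      tandem <- same_chr && interv <= max_intervening && dist <= max_bp
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = models$gene_id[i], gene_b = models$gene_id[j],
        protein_identity = al$identity,
        same_chromosome = same_chr,
        intervening_genes = interv,
        genomic_distance = dist,
        relation = if (tandem) "tandem" else "duplicate",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group tandem pairs into arrays
#'
#' Connected components over the `tandem` relation; an array is a
#' maximal set of genes linked by tandem pairs.
#'
#' @param pairs output of [find_duplicate_pairs()].
#' @return list of character vectors, one per array (size >= 2), sorted.
#' @export
tandem_arrays <- function(pairs) {
  tp <- pairs[pairs$relation == "tandem", , drop = FALSE]
  if (nrow(tp) == 0L) return(list())
  genes <- sort(unique(c(tp$gene_a, tp$gene_b)))
  ## simple union-find over gene indices
  parent <- seq_along(genes)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(tp))) {
    i <- root(match(tp$gene_a[k], genes))
    j <- root(match(tp$gene_b[k], genes))
    if (i != j) parent[j] <- i
  }
  comp_id <- vapply(seq_along(genes), root, integer(1))
  unname(lapply(split(genes, comp_id), sort))
}

#' Extract promoter sequences (upstream of ATG)
#'
#' The promoter is the `length` bases immediately upstream of the
#' translation start (first CDS base), not the transcription start: for
#' a plus-strand gene, bases `[translation_start - length,
#' translation_start - 1]`; for a minus-strand gene, the reverse
#' complement of `[translation_start + 1, translation_start + length]`.
#' Windows are truncated at contig edges and flagged.
#'
#' @param genome named character vector or `DNAStringSet` of contigs (or
#'   a FASTA path).
#' @param models gene-model table from [parse_gene_models()].
#' @param length promoter length in bp (default 2000).
#' @return named character vector of promoter sequences (one per gene);
#'   a data.frame attribute `"info"` records per-gene `truncated` flags.
#'   Genes with zero upstream bases yield an empty record with a warning.
#' @export
extract_promoters <- function(genome, models, length = 2000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome, type = "DNA")
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  missing <- setdiff(models$chromosome, names(genome))
  if (length(missing))
    .stopf("contig(s) not in genome: %s", paste(missing, collapse = ", "))
  out <- character(nrow(models))
  trunc <- logical(nrow(models))
  for (i in seq_len(nrow(models))) {
    contig <- genome[[models$chromosome[i]]]
    ts <- models$translation_start[i]
    if (models$strand[i] == "-") {
      from <- ts + 1L
      to <- min(nchar(contig), ts + length)
      trunc[i] <- to - from + 1L < length
      out[i] <- if (from > to) "" else .revcomp(substr(contig, from, to))
    } else {
      from <- max(1L, ts - length)
      to <- ts - 1L
      trunc[i] <- to - from + 1L < length
      out[i] <- if (from > to) "" else substr(contig, from, to)
    }
    if (!nzchar(out[i]))
      warning(sprintf("gene %s has no upstream sequence; empty promoter",
                      models$gene_id[i]), call. = FALSE)
  }
  names(out) <- models$gene_id
  attr(out, "info") <- data.frame(gene_id = models$gene_id,
                                  truncated = trunc,
                                  stringsAsFactors = FALSE)
  out
}
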