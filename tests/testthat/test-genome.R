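## A small hand-written GFF3/FASTA world for coordinate arithmetic.
make_toy_gff <- function() {
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t2001\t2300\t.\t+\t.\tID=gA",
    "chr1\ttoy\tmRNA\t2001\t2300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttoy\texon\t2001\t2300\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
    "chr1\ttoy\tCDS\t2001\t2300\t.\t+\t0\tID=gA.t1.c1;Parent=gA.t1",
    "chr1\ttoy\tgene\t3001\t3400\t.\t-\t.\tID=gB",
    "chr1\ttoy\tmRNA\t3001\t3400\t.\t-\t.\tID=gB.t2;Parent=gB",
    "chr1\ttoy\tmRNA\t3001\t3400\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\ttoy\texon\t3001\t3100\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1",
    "chr1\ttoy\texon\t3201\t3300\t.\t-\t.\tID=gB.t1.e2;Parent=gB.t1",
    "chr1\ttoy\texon\t3301\t3400\t.\t-\t.\tID=gB.t1.e3;Parent=gB.t1",
    "chr1\ttoy\tCDS\t3001\t3100\t.\t-\t0\tID=gB.t1.c1;Parent=gB.t1",
    "chr1\ttoy\tCDS\t3201\t3300\t.\t-\t0\tID=gB.t1.c2;Parent=gB.t1",
    "chr1\ttoy\tCDS\t3301\t3400\t.\t-\t0\tID=gB.t1.c3;Parent=gB.t1",
    "chr1\ttoy\tCDS\t3001\t3400\t.\t-\t0\tID=gB.t2.c1;Parent=gB.t2",
    "chr1\ttoy\tgene\t4000\t4100\t.\t+\t.\tID=gC",
    "chr1\ttoy\tmRNA\t4000\t4100\t.\t+\t.\tID=gC.t1;Parent=gC")
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

test_that("gene models come from the primary isoform with intron counts", {
  path <- make_toy_gff()
  expect_warning(models <- parse_gene_models(path), "no CDS")
  expect_equal(sort(models$gene_id), c("gA", "gB"))
  a <- models[models$gene_id == "gA", ]
  expect_equal(a$exon_count, 1L)
  expect_equal(a$intron_count, 0L)
  expect_equal(a$translation_start, 2001L)
  b <- models[models$gene_id == "gB", ]
  expect_equal(b$protein_id, "gB.t1")  # lowest-sorting mRNA wins
  expect_equal(b$exon_count, 3L)
  expect_equal(b$intron_count, 2L)
  expect_equal(b$translation_start, 3400L)  # minus strand: max CDS end
  unlink(path)
})

test_that("chromosome distribution counts sum to the model count", {
  path <- make_toy_gff()
  suppressWarnings(models <- parse_gene_models(path))
  cd <- chromosome_distribution(models)
  expect_equal(sum(cd$n), nrow(models))
  expect_equal(nrow(chromosome_distribution(models[0, ])), 0L)
  unlink(path)
})

test_that("promoters are the 2 kb upstream of ATG, strand-aware", {
  set.seed(5)
  contig <- random_dna(6000)
  genome <- c(chr1 = contig)
  path <- make_toy_gff()
  suppressWarnings(models <- parse_gene_models(path))
  prom <- extract_promoters(genome, models)
  ## plus strand, ATG at 2001: bases 1..2000
  expect_equal(prom[["gA"]], substr(contig, 1, 2000))
  ## minus strand: reverse complement of the 2000 nt right of the start
  expect_equal(prom[["gB"]], as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 3401, 5400)))))
  expect_false(any(attr(prom, "info")$truncated))
  ## truncation at the contig edge
  short <- c(chr1 = substr(contig, 1, 4500))
  prom2 <- extract_promoters(short, models)
  expect_equal(nchar(prom2[["gB"]]), 1100L)
  expect_true(attr(prom2, "info")$truncated[
    attr(prom2, "info")$gene_id == "gB"])
  unlink(path)
})

test_that("synthetic genome round-trips models and promoters exactly", {
  mf <- species_manifest("spG", 6, c(Q = 2), chromosome_count = 2, seed = 21)
  gen <- generate_genome_annotation(mf, exon_counts = c(1, 2, 3, 4, 1, 2))
  path <- tempfile(fileext = ".gff3")
  writeLines(gen$gff, path)
  models <- parse_gene_models(path)
  truth <- gen$truth$genes
  idx <- match(truth$gene_id, models$gene_id)
  expect_false(anyNA(idx))
  expect_equal(models$exon_count[idx], truth$exon_count)
  expect_equal(models$intron_count[idx], truth$intron_count)
  expect_equal(models$strand[idx], truth$strand)
  expect_equal(models$translation_start[idx], truth$translation_start)
  prom <- extract_promoters(gen$genome, models)
  expect_equal(unname(prom[truth$gene_id]), truth$promoter)
  unlink(path)
})

test_that("duplicate pairs split into tandem and segmental relations", {
  ## two identical adjacent genes + one identical gene on another contig
  mk_models <- function() data.frame(
    gene_id = c("g1", "g2", "g3"),
    protein_id = c("p1", "p2", "p3"),
    chromosome = c("c1", "c1", "c2"),
    strand = "+",
    exon_count = 1L, intron_count = 0L,
    translation_start = c(1000L, 6000L, 1000L),
    cds_start = c(1000L, 6000L, 1000L),
    cds_end = c(1300L, 6300L, 1300L),
    stringsAsFactors = FALSE)
  prot <- c(p1 = "MKVAWGNNNQRST", p2 = "MKVAWGNNNQRST", p3 = "MKVAWGNNNQRST")
  pairs <- find_duplicate_pairs(prot, mk_models())
  expect_equal(nrow(pairs), 3L)
  p12 <- pairs[pairs$gene_a == "g1" & pairs$gene_b == "g2", ]
  expect_equal(p12$relation, "tandem")
  expect_equal(p12$protein_identity, 1.0)
  expect_equal(p12$intervening_genes, 0L)
  p13 <- pairs[pairs$gene_a == "g1" & pairs$gene_b == "g3", ]
  expect_equal(p13$relation, "duplicate")
  expect_false(p13$same_chromosome)
  ## symmetry: reversing the input order finds the same relations
  m2 <- mk_models()[c(3, 2, 1), ]
  pairs2 <- find_duplicate_pairs(prot, m2)
  key <- function(p) sort(paste(pmin(p$gene_a, p$gene_b),
                                pmax(p$gene_a, p$gene_b), p$relation))
  expect_equal(key(pairs), key(pairs2))
  ## tandem pairs are always same-chromosome
  expect_true(all(pairs$same_chromosome[pairs$relation == "tandem"]))
})

test_that("planted tandem arrays are recovered as one array", {
  mf <- species_manifest("spT", 6, c(Q = 1), chromosome_count = 1, seed = 33)
  gen <- generate_genome_annotation(mf, tandem = list(2:4))
  path <- tempfile(fileext = ".gff3")
  writeLines(gen$gff, path)
  models <- parse_gene_models(path)
  pairs <- find_duplicate_pairs(gen$proteins, models)
  arrays <- tandem_arrays(pairs)
  expect_equal(length(arrays), 1L)
  expect_equal(arrays[[1]], sort(gen$truth$tandem[[1]]))
  expect_true(all(pairs$protein_identity >= 0.95))
  unlink(path)
})
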