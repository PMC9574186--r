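test_that("manifests validate their fields", {
  expect_error(species_manifest("x", -1, c(Q = 1)), "count")
  expect_error(species_manifest("x", 5, c(QQ = 1)), "unknown finger type")
  expect_error(species_manifest("x", 5, c(Q = 1), frac_c2h2_only = 1.2),
               "0, 1")
  expect_error(species_manifest("x", 0, c(Q = 1)), "impossible request")
  expect_s3_class(species_manifest("x", 5, c(Q = 2)), "zf_manifest")
})

test_that("generators are deterministic under a fixed seed", {
  mf <- species_manifest("spD", 8, c(Q = 3, Z1 = 2, D = 1), seed = 77)
  expect_identical(generate_proteome(mf), generate_proteome(mf))
  expect_identical(generate_genome_annotation(mf),
                   generate_genome_annotation(mf))
  expect_identical(generate_expression(40, c(2, 2, 2, 2, 2, 2), seed = 5),
                   generate_expression(40, c(2, 2, 2, 2, 2, 2), seed = 5))
  expect_identical(generate_duplicate_pairs(3, 50, 0.1, 0.05, seed = 5),
                   generate_duplicate_pairs(3, 50, 0.1, 0.05, seed = 5))
})

test_that("proteome truth is recovered by the scanner and classifier", {
  mf <- species_manifest("spR", 15, c(Q = 6, M1 = 3, M4 = 3, Z1 = 4,
                                      Z2 = 4, D = 4), seed = 13)
  pr <- generate_proteome(mf)
  expect_equal(nrow(pr$truth), 24L)
  fingers <- classify_fingers(scan_proteins(pr$proteins))
  expect_equal(nrow(fingers), nrow(pr$truth))
  key <- function(d) d[order(d$protein_id, d$c1),
                       c("protein_id", "c1", "c2", "h1", "h2")]
  expect_equal(key(fingers), key(pr$truth), ignore_attr = TRUE)
  expect_equal(fingers$type[order(fingers$protein_id, fingers$c1)],
               pr$truth$type[order(pr$truth$protein_id, pr$truth$c1)])
  ## linkers and flanks never contain the ligand residues
  stripped <- pr$proteins
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    end <- if (is.na(tr$h2)) tr$h1 else tr$h2
    s <- stripped[[tr$protein_id]]
    substr(s, tr$c1, end) <- strrep(".", end - tr$c1 + 1)
    stripped[[tr$protein_id]] <- s
  }
  expect_false(any(grepl("[CH]", stripped)))
})

test_that("zero-protein and zero-finger requests degrade gracefully", {
  mf0 <- species_manifest("spZ", 0, integer(0))
  pr0 <- generate_proteome(mf0)
  expect_equal(length(pr0$proteins), 0L)
  expect_equal(nrow(pr0$truth), 0L)
  ## proteins without planted fingers scan clean
  mf1 <- species_manifest("spO", 3, c(Q = 1), seed = 2)
  pr1 <- generate_proteome(mf1)
  fingers <- scan_proteins(pr1$proteins)
  expect_equal(nrow(fingers), 1L)
})

test_that("promoter planting is exact, both strands, with self-scan", {
  mf <- species_manifest("spM", 3, c(Q = 1), seed = 31)
  plan <- list(
    data.frame(motif = "ACGTG", count = 3),
    data.frame(motif = "CAACTG", count = 2, strand = "-"),
    NULL)
  gen <- generate_genome_annotation(mf, motif_plan = plan)
  path <- tempfile(fileext = ".gff3")
  writeLines(gen$gff, path)
  models <- parse_gene_models(path)
  prom <- extract_promoters(gen$genome, models)
  sc <- scan_motifs(prom)
  g <- gen$truth$genes$gene_id
  expect_equal(sc$forward[sc$gene_id == g[1] & sc$motif == "ABRE_core"], 3L)
  expect_equal(sc$reverse[sc$gene_id == g[1] & sc$motif == "ABRE_core"], 0L)
  ## reverse-oriented plants appear as reverse hits
  expect_equal(sc$reverse[sc$gene_id == g[2] & sc$motif == "MBS"], 2L)
  expect_equal(sc$forward[sc$gene_id == g[2] & sc$motif == "MBS"], 0L)
  ## unplanted promoter is clean for every dictionary motif
  expect_true(all(sc$forward[sc$gene_id == g[3]] == 0))
  expect_true(all(sc$reverse[sc$gene_id == g[3]] == 0))
  ## over-stuffed plans are rejected
  expect_error(generate_genome_annotation(mf, motif_plan = list(
    data.frame(motif = "CGCACGTGTC", count = 150))), "do not fit")
  unlink(path)
})

test_that("duplicate-pair truth records realized substitution counts", {
  ## nonsyn_rate = 0: no nonsynonymous substitutions happen, and at low
  ## divergence (codon pairs differing at <= 1 position) Ka is exactly 0
  dp <- generate_duplicate_pairs(10, 100, syn_rate = 0.02, nonsyn_rate = 0,
                                 seed = 3)
  expect_equal(dp$truth$nonsyn_subs, rep(0L, 10))
  kk <- kaks_pairs(dp$cds)
  expect_equal(kk$ka, rep(0, 10))
  ## syn_rate = 0 symmetric case: realized synonymous count is zero
  dp2 <- generate_duplicate_pairs(4, 60, syn_rate = 0, nonsyn_rate = 0.05,
                                  seed = 4)
  expect_equal(dp2$truth$syn_subs, rep(0L, 4))
  expect_error(generate_duplicate_pairs(2, 50, 1.5, 0), "rates")
})

test_that("expression generator honours its stated world", {
  expect_error(generate_expression(10, c(5, 4, 3, 2, 1, 1, 1)),
               "more than 6")
  expect_error(generate_expression(5, c(9, 0, 0, 0, 0, 0)), "more planted")
  ex <- generate_expression(30, c(1, 1, 1, 1, 1, 1), noise_sd = 0, seed = 8)
  expect_equal(dim(ex$fpkm), c(30L, 15L))
  expect_equal(sum(ex$truth$is_deg), 6L)
  ## noise-free replicates are identical within a stage
  sm <- stage_means(ex$fpkm)
  expect_equal(unname(ex$fpkm[, "HD_1"]), unname(sm[, "HD"]))
  ## DEG caller recovers the planted truth exactly
  degs <- call_degs(ex$tables)
  expect_equal(degs$calls$is_deg[match(ex$truth$gene_id,
                                       degs$calls$gene_id)],
               ex$truth$is_deg)
})
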