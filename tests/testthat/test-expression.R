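## Small hand-built DE tables for the intersection rule.
mk_tables <- function(rows) {
  ## rows: list of list(gene, lfc, s1, s2, s3)
  base <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene"),
    contrast = "SDH_vs_HD",
    log2fc = vapply(rows, `[[`, numeric(1), "lfc"),
    stringsAsFactors = FALSE)
  lapply(1:3, function(m) {
    t <- base
    t$sig <- vapply(rows, function(r) r[[paste0("s", m)]], numeric(1))
    t
  })
}

test_that("the three-method intersection rule is applied literally", {
  tabs <- mk_tables(list(
    list(gene = "g1", lfc = 1.2, s1 = 0.01, s2 = 0.03, s3 = 0.04),
    list(gene = "g2", lfc = 0.9, s1 = 0.001, s2 = 0.001, s3 = 0.001),
    list(gene = "g3", lfc = 3.0, s1 = 0.01, s2 = 0.01, s3 = 0.06),
    list(gene = "g4", lfc = -1.5, s1 = 0.01, s2 = 0.02, s3 = 0.03)))
  degs <- call_degs(tabs)
  got <- stats::setNames(degs$calls$is_deg, degs$calls$gene_id)
  expect_true(got[["g1"]])    # passes everything
  expect_false(got[["g2"]])   # fold change fails
  expect_false(got[["g3"]])   # one method fails
  expect_true(got[["g4"]])    # repression counts too
  dir <- degs$contrasts$direction[degs$contrasts$gene_id == "g4"]
  expect_equal(dir, "repressed")
})

test_that("genes missing from one table are non-significant there", {
  tabs <- mk_tables(list(list(gene = "g1", lfc = 2, s1 = 0.01, s2 = 0.01,
                              s3 = 0.01)))
  tabs[[2]] <- tabs[[2]][0, ]
  expect_warning(degs <- call_degs(tabs), "missing")
  expect_false(degs$calls$is_deg[degs$calls$gene_id == "g1"])
})

test_that("DEG set is monotone and nested within each method's set", {
  set.seed(15)
  rows <- lapply(seq_len(80), function(i)
    list(gene = sprintf("g%02d", i), lfc = stats::rnorm(1, 0, 2),
         s1 = stats::runif(1), s2 = stats::runif(1), s3 = stats::runif(1)))
  tabs <- mk_tables(rows)
  strict <- call_degs(tabs, fc_threshold = 2, alpha = 0.05)
  ## intersection is a subset of each single method's significant set
  for (m in 1:3) {
    single <- tabs[[m]]$gene_id[tabs[[m]]$sig < 0.05 &
                                  abs(tabs[[m]]$log2fc) >= 1]
    expect_true(all(strict$calls$gene_id[strict$calls$is_deg] %in% single))
  }
  ## relaxing alpha or the fold threshold never removes a DEG
  for (relax in list(c(2, 0.10), c(1.5, 0.05), c(1.2, 0.20))) {
    loose <- call_degs(tabs, fc_threshold = relax[1], alpha = relax[2])
    expect_true(all(strict$calls$gene_id[strict$calls$is_deg] %in%
                      loose$calls$gene_id[loose$calls$is_deg]))
  }
})

test_that("profile standardization is exact and excludes flat genes", {
  x <- rbind(g1 = 1:5, g2 = rep(4, 5), g3 = c(2, 8, 4, 1, 0))
  colnames(x) <- c("HD", "MDH", "SDH", "PRE", "FRE")
  z <- standardize_profiles(x, log2 = FALSE)
  expect_equal(attr(z, "excluded"), "g2")
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), c(1, 1))
  ## a linear profile has the fixed z-vector (x - 3)/sqrt(2.5)
  expect_equal(unname(z["g1", ]), (1:5 - 3) / sqrt(2.5))
  ## on the default log2 scale a gene with a zero stage mean is dropped
  zl <- standardize_profiles(x)
  expect_setequal(attr(zl, "excluded"), c("g2", "g3"))
  expect_equal(unname(zl["g1", ]), unname((log2(1:5) - mean(log2(1:5))) /
                                            stats::sd(log2(1:5))))
})

test_that("fuzzy c-means separates blobs and normalizes memberships", {
  set.seed(16)
  blob <- function(center, n) t(replicate(n, center + stats::rnorm(5, 0, 0.05)))
  x <- rbind(blob(c(2, 0, 0, 0, 0), 20), blob(c(0, 0, 0, 0, 2), 20))
  fit <- fuzzy_cmeans(x, centers = 2, seed = 1, templates = NULL)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(diff(fit$objective) <= 1e-9))
  top <- apply(fit$membership, 1, max)
  expect_true(all(top > 0.9))
  ## the two blobs land in different clusters
  h <- fit$hard
  expect_equal(length(unique(h[1:20])), 1L)
  expect_equal(length(unique(h[21:40])), 1L)
  expect_false(h[1] == h[40])
  expect_error(fuzzy_cmeans(x[1:3, ], centers = 6), "at least")
})

test_that("noise-free planted patterns are recovered with exact centroids", {
  ex <- generate_expression(12, rep(2, 6), noise_sd = 0, seed = 4)
  ids <- ex$truth$gene_id[ex$truth$is_deg]
  z <- standardize_profiles(ex$fpkm[ids, ])
  fit <- fuzzy_cmeans(z, seed = 2)
  truth <- ex$truth$pattern[match(rownames(z), ex$truth$gene_id)]
  expect_equal(unname(fit$hard), truth)
  ## centroids equal the standardized templates exactly at zero noise
  zt <- t(apply(pattern_templates(), 1, function(v)
    (v - mean(v)) / stats::sd(v)))
  expect_equal(fit$centroids, zt, tolerance = 1e-6)
})

test_that("integration yields one row per DEG and rolls up truthfully", {
  ex <- generate_expression(60, c(4, 4, 4, 4, 4, 4), seed = 6)
  degs <- call_degs(ex$tables)
  ids <- degs$calls$gene_id[degs$calls$is_deg]
  z <- standardize_profiles(ex$fpkm[ids, ])
  fit <- fuzzy_cmeans(z, seed = 3)
  profiles <- data.frame(protein_id = ids, n_fingers = 1L, types = "Q",
                         coarse_types = "Q", category = "pure:Q",
                         stringsAsFactors = FALSE)
  tab <- integrate_annotations(degs, fit, profiles, fpkm = ex$fpkm)
  expect_equal(sort(tab$gene_id), sort(ids))
  expect_equal(anyDuplicated(tab$gene_id), 0L)
  expect_true(all(c("pattern", "directions", "log2_fpkm_HD") %in% names(tab)))
  expect_equal(length(attr(tab, "rejects")), 0L)
  ## unmapped DEGs land in the reject report
  tab2 <- integrate_annotations(degs, fit, profiles[-1, ], fpkm = ex$fpkm)
  expect_equal(attr(tab2, "rejects"), ids[1])
  ## empty DEG set gives an empty table
  none <- call_degs(lapply(ex$tables, function(t) {
    t$sig <- 1; t
  }))
  expect_equal(nrow(integrate_annotations(none, fit, profiles)), 0L)
})
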