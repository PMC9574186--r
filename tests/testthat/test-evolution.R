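test_that("global alignment scores match exhaustive enumeration", {
  al <- global_align("AAA", "AAA")
  expect_equal(al$identity, 1)
  expect_equal(al$score, 3)
  expect_equal(global_align("A", "G")$identity, 0)
  set.seed(14)
  for (i in 1:30) {
    a <- paste(sample(c("A", "C"), sample(1:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C"), sample(1:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  expect_error(global_align("", "A"), "empty")
})

test_that("codon alignment threads and drops gap columns", {
  a <- "ATGAAAGGGTTT"
  ca <- codon_align(a, a)
  expect_equal(ca$dropped, 0L)
  expect_equal(ca$kept, 4L)
  ## one inserted codon: exactly one dropped column
  b <- "ATGAAACCCGGGTTT"
  cb <- codon_align(a, b)
  expect_equal(cb$dropped, 1L)
  expect_equal(cb$kept, 4L)  # the aligned codons of the shorter sequence
  expect_equal(cb$codons_a, cb$codons_b)
  ## terminal stops are trimmed, internal stops are named errors
  expect_equal(codon_align("ATGAAATAA", "ATGAAATAA")$kept, 2L)
  expect_error(codon_align("ATGTAAGGG", "ATGAAAGGG"),
               "cds_a has an internal stop codon at codon 2")
  expect_error(codon_align("ATGAA", "ATGAAA"), "multiple of 3")
})

test_that("NG86 reproduces hand-computed values", {
  ## identical sequences
  r0 <- ng86_kaks(codon_align(strrep("GGT", 100), strrep("GGT", 100)))
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_equal(r0$selection_mode, "undefined")
  ## one synonymous third-position change among 100 glycine codons:
  ## every GGN codon has 1 synonymous + 2 nonsynonymous sites, so
  ## S = 100, N = 200, Sd = 1, Nd = 0
  b <- paste0(strrep("GGT", 99), "GGC")
  r1 <- ng86_kaks(codon_align(strrep("GGT", 100), b))
  expect_equal(r1$S, 100)
  expect_equal(r1$N, 200)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$ks, -0.75 * log(1 - 4 * 0.01 / 3))
  expect_equal(r1$ka, 0)
  expect_equal(r1$ratio, 0)
  expect_equal(r1$selection_mode, "purifying")
  ## one nonsynonymous change, no synonymous: ratio undefined
  b2 <- paste0("GTT", strrep("GGT", 99))
  r2 <- ng86_kaks(codon_align(strrep("GGT", 100), b2))
  expect_gt(r2$ka, 0)
  expect_equal(r2$ks, 0)
  expect_true(is.na(r2$ratio))
  expect_equal(r2$selection_mode, "undefined")
})

test_that("pathway averaging excludes routes through stop codons", {
  ## TAC (Tyr) -> TTA (Leu): the pathway via TAA (stop) is excluded, so
  ## only TAC -> TTC -> TTA counts: two nonsynonymous steps
  pad <- strrep("GGT", 50)
  r <- ng86_kaks(codon_align(paste0("TAC", pad), paste0("TTA", pad)))
  expect_equal(r$Nd, 2)
  expect_equal(r$Sd, 0)
  ## TCA (Ser) -> TTG (Leu): both pathways open, one syn + one nonsyn
  ## step each, so the average is sd = 1, nd = 1
  r2 <- ng86_kaks(codon_align(paste0("TCA", pad), paste0("TTG", pad)))
  expect_equal(r2$Sd, 1)
  expect_equal(r2$Nd, 1)
})

test_that("Jukes-Cantor correction rejects saturated proportions", {
  expect_error(jukes_cantor(0.8), "saturated")
  expect_equal(jukes_cantor(0), 0)
})

test_that("domain concatenation preserves order and length", {
  seq <- "MSSCAACFAKSGYGQALGGHKKAHNNPCAACADEFGIKLMHKKAHQQ"
  f <- detect_fingers(seq)
  expect_equal(nrow(f), 2L)
  dom <- concat_domains(seq, f)
  ends <- ifelse(is.na(f$h2), f$h1, f$h2)
  expect_equal(nchar(dom), sum(ends - f$c1 + 1))
  expect_equal(dom, paste0(substring(seq, f$c1[1], ends[1]),
                           substring(seq, f$c1[2], ends[2])))
  one <- concat_domains(seq, f[1, ])
  expect_equal(one, substring(seq, f$c1[1], ends[1]))
  expect_warning(res <- concat_domains(seq, f[0, ]), "no fingers")
  expect_true(is.na(res))
})

test_that("neighbor joining solves the three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  cp <- ape::cophenetic.phylo(tr$tree)[rownames(d), colnames(d)]
  expect_equal(cp, d)
  ## branch lengths: x_a = (3 + 4 - 5)/2 = 1 etc.
  bl <- stats::setNames(tr$tree$edge.length,
                        tr$tree$tip.label[tr$tree$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("additive 4- and 5-taxon matrices are reproduced exactly", {
  d4 <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0),
               4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(tr4$tree)[letters[1:4], letters[1:4]],
               d4)
  expect_equal(tr4$n_clamped, 0L)
  ## 5 taxa from the tree ((a:1,b:2):1.5,(c:1,d:2.5):0.5,e:2)
  d5 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  d5["a", "b"] <- 3; d5["a", "c"] <- 4; d5["a", "d"] <- 5.5
  d5["a", "e"] <- 4.5; d5["b", "c"] <- 5; d5["b", "d"] <- 6.5
  d5["b", "e"] <- 5.5; d5["c", "d"] <- 3.5; d5["c", "e"] <- 3.5
  d5["d", "e"] <- 5
  d5 <- d5 + t(d5)
  tr5 <- nj_tree(d5)
  expect_equal(ape::cophenetic.phylo(tr5$tree)[letters[1:5], letters[1:5]],
               d5)
  ## the true split {a,b} is a clade in the unrooted topology
  expect_true(ape::is.monophyletic(tr5$tree, c("a", "b")))
  ## permuting labels permutes leaves only
  perm <- c(3, 1, 5, 2, 4)
  trp <- nj_tree(d5[perm, perm])
  expect_equal(ape::cophenetic.phylo(trp$tree)[letters[1:5], letters[1:5]],
               d5)
  ## validation
  bad <- d4; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d4[1:2, 1:2]), "3 taxa")
})
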