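## Independent brute-force oracles. These deliberately re-derive results
## from first principles (exhaustive enumeration, sliding windows,
## recursive search) and share no code with the package implementation.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                                    collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## Exhaustive finger enumeration + greedy resolution, written as literal
## nested loops over index tuples.
oracle_detect <- function(seq, min_spacer = 8, max_spacer = 25) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cand <- list()
  for (c1 in seq_len(n)) {
    if (chars[c1] != "C") next
    for (c2 in (c1 + 3):(c1 + 5)) {
      if (c2 > n || chars[c2] != "C") next
      for (h1 in (c2 + min_spacer + 1):(c2 + max_spacer + 1)) {
        if (h1 > n || chars[h1] != "H") next
        win <- (h1 + 4):(h1 + 6)
        win <- win[win <= n]
        h2s <- win[chars[win] == "H"]
        if (length(h2s) == 0) {
          cand[[length(cand) + 1]] <- c(c1, c2, h1, NA)
        } else {
          for (h2 in h2s) cand[[length(cand) + 1]] <- c(c1, c2, h1, h2)
        }
      }
    }
  }
  sel <- list()
  pos <- 1
  while (length(cand)) {
    cand <- Filter(function(x) x[1] >= pos, cand)
    if (!length(cand)) break
    starts <- vapply(cand, `[`, numeric(1), 1)
    atstart <- cand[starts == min(starts)]
    keys <- t(vapply(atstart, function(x) {
      sp <- x[3] - x[2] - 1
      c(as.numeric(is.na(x[4])), abs(sp - 12), sp, x[2] - x[1] - 1,
        if (is.na(x[4])) Inf else x[4] - x[3] - 1)
    }, numeric(5)))
    best <- atstart[[do.call(order, as.data.frame(keys))[1]]]
    sel[[length(sel) + 1]] <- best
    pos <- max(best, na.rm = TRUE) + 1
  }
  if (!length(sel))
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("c1", "c2", "h1", "h2"))))
  m <- do.call(rbind, sel)
  colnames(m) <- c("c1", "c2", "h1", "h2")
  m
}

## Sliding-window motif counter with IUPAC expansion in the pattern.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_count <- function(motif, seq) {
  m <- strsplit(motif, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  k <- length(m)
  n <- length(s)
  if (k > n || k == 0) return(0L)
  cnt <- 0L
  for (i in seq_len(n - k + 1)) {
    hit <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1] %in% IUPAC_SETS[[m[j]]]) { hit <- FALSE; break }
    }
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## Recursive enumeration of all global alignments (feasible for n <= 6).
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0) return(gap * nchar(b))
  if (nchar(b) == 0) return(gap * nchar(a))
  sub <- if (substr(a, 1, 1) == substr(b, 1, 1)) match else mismatch
  max(oracle_align_score(substring(a, 2), substring(b, 2),
                         match, mismatch, gap) + sub,
      oracle_align_score(substring(a, 2), b, match, mismatch, gap) + gap,
      oracle_align_score(a, substring(b, 2), match, mismatch, gap) + gap)
}

## Synthesize a finger-bearing peptide with the requested geometry, for
## exhaustive classifier checks. `distance` mutates the QALGG part of
## the six-mer ending at H1 (position 6 is H1 itself).
synth_finger <- function(spacer, distance = 0, has_h2 = TRUE) {
  filler <- function(n) paste(rep("S", n), collapse = "")
  six5 <- strsplit("QALGG", "")[[1]]
  if (distance > 0) six5[seq_len(distance)] <- "V"
  core <- if (spacer >= 5)
    paste0(filler(spacer - 5), paste(six5, collapse = ""))
  else filler(spacer)
  paste0("M", "C", filler(2), "C", core, "H",
         if (has_h2) paste0(filler(3), "H") else filler(8))
}

## Table 1 / Table 2 fixtures encoding the printed integers.
table1_fixture <- function() {
  data.frame(
    species = c("At", "Os", "Pp", "Sm", "Sf", "Mp"),
    n_proteins = c(158L, 168L, 112L, 53L, 41L, 17L),
    n_c2h2_only = c(108L, 136L, 63L, 38L, 19L, 14L),
    n_coiled_coil = c(20L, 15L, 10L, 3L, 1L, 1L),  # sums to the printed 50
    stringsAsFactors = FALSE)
}

table2_fixture <- function() {
  species <- c("At", "Os", "Pp", "Sf", "Sm", "Mp")
  counts <- list(
    list(group = "I", subgroup = "Ia", n = c(2, 1, 3, 2, 3, 1)),
    list(group = "I", subgroup = "Ib", n = c(3, 9, 0, 0, 0, 0)),
    list(group = "II", subgroup = "", n = c(22, 23, 20, 6, 5, 1)),
    list(group = "III", subgroup = "", n = c(48, 51, 57, 22, 28, 12)),
    list(group = "IV", subgroup = "IVa", n = c(11, 7, 0, 0, 0, 0)),
    list(group = "IV", subgroup = "IVb", n = c(38, 38, 13, 5, 7, 1)),
    list(group = "IV", subgroup = "IVc", n = c(34, 39, 19, 6, 10, 2)))
  rows <- do.call(rbind, lapply(counts, function(x)
    do.call(rbind, lapply(seq_along(species), function(i)
      if (x$n[i] > 0)
        data.frame(species = species[i], group = x$group,
                   subgroup = x$subgroup, n = x$n[i],
                   stringsAsFactors = FALSE)))))
  out <- rows[rep(seq_len(nrow(rows)), rows$n), c("species", "group",
                                                  "subgroup")]
  rownames(out) <- NULL
  out$angiosperm <- out$species %in% c("At", "Os")
  ## 198 of the 230 group-IV members carry only C2H2-ZF domains
  out$c2h2_only <- FALSE
  iv <- which(out$group == "IV")
  out$c2h2_only[iv[seq_len(198)]] <- TRUE
  out
}
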