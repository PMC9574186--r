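## Dehydration-rehydration expression analysis: three-method DEG
## intersection, z-scored stage profiles, fuzzy c-means clustering into
## six canonical patterns, and integration with family annotations.

STAGES <- c("HD", "MDH", "SDH", "PRE", "FRE")

#' Canonical five-stage expression pattern templates
#'
#' Fixed template profiles over the stages HD (hydrated control), MDH
#' (moderate dehydration), SDH (severe/deep dehydration), PRE (partial
#' rehydration) and FRE (full rehydration), anchoring the six cluster
#' labels: pattern 1 peaks at both ends (control and full rehydration),
#' pattern 2 at SDH, pattern 3 at full rehydration, pattern 4 at MDH,
#' pattern 5 is highest in the hydrated control and declines, pattern 6
#' peaks at PRE.
#'
#' @return 6 x 5 numeric matrix (rows `pattern1..pattern6`, columns the
#'   stages).
#' @export
pattern_templates <- function() {
  m <- rbind(
    pattern1 = c(1.0, 0.1, 0.0, 0.1, 1.0),
    pattern2 = c(0.0, 0.5, 1.0, 0.4, 0.1),
    pattern3 = c(0.2, 0.0, 0.0, 0.3, 1.0),
    pattern4 = c(0.2, 1.0, 0.4, 0.1, 0.0),
    pattern5 = c(1.0, 0.6, 0.3, 0.1, 0.0),
    pattern6 = c(0.0, 0.1, 0.3, 1.0, 0.4))
  colnames(m) <- STAGES
  m
}

#' Call DEGs by the three-method intersection rule
#'
#' A gene is differentially expressed when, for at least one contrast
#' (each treatment stage vs the hydrated control), its absolute fold
#' change reaches `fc_threshold` and all three methods report
#' significance below `alpha` at the same time. Genes missing from a
#' table are treated as non-significant there, with a warning.
#'
#' @param tables named list of three data.frames, each with columns
#'   `gene_id`, `contrast`, `log2fc`, `sig`.
#' @param fc_threshold fold-change threshold on the natural scale
#'   (default 2, i.e. |log2FC| >= 1).
#' @param alpha significance threshold applied to all three methods
#'   (default 0.05).
#' @return list of class `zf_degs`: `calls` (per gene: `gene_id`,
#'   `is_deg`, `n_passing_contrasts`) and `contrasts` (per gene x
#'   contrast: `log2fc`, `sig_method1..3`, `pass`, `direction`).
#' @export
call_degs <- function(tables, fc_threshold = 2, alpha = 0.05) {
  stopifnot(is.list(tables), length(tables) == 3L)
  for (t in tables)
    stopifnot(all(c("gene_id", "contrast", "log2fc", "sig") %in% names(t)))
  genes <- unique(unlist(lapply(tables, `[[`, "gene_id")))
  contrasts <- unique(unlist(lapply(tables, `[[`, "contrast")))
  lfc_min <- log2(fc_threshold)

  key <- function(t) paste(t$gene_id, t$contrast, sep = "\r")
  grid <- expand.grid(gene_id = genes, contrast = contrasts,
                      stringsAsFactors = FALSE)
  gkey <- paste(grid$gene_id, grid$contrast, sep = "\r")
  lfc <- matrix(NA_real_, nrow(grid), 3)
  sig <- matrix(NA_real_, nrow(grid), 3)
  for (m in 1:3) {
    idx <- match(gkey, key(tables[[m]]))
    lfc[, m] <- tables[[m]]$log2fc[idx]
    sig[, m] <- tables[[m]]$sig[idx]
  }
  n_missing <- sum(is.na(sig))
  if (n_missing > 0)
    warning(sprintf(
      "%d gene x contrast entries missing from a table; treated as non-significant",
      n_missing), call. = FALSE)
  pass <- rowSums(sig < alpha, na.rm = FALSE) == 3 &
    rowSums(abs(lfc) >= lfc_min, na.rm = FALSE) == 3
  pass[is.na(pass)] <- FALSE
  grid$log2fc <- lfc[, 1]
  grid$sig_method1 <- sig[, 1]
  grid$sig_method2 <- sig[, 2]
  grid$sig_method3 <- sig[, 3]
  grid$pass <- pass
  grid$direction <- ifelse(!pass, NA_character_,
                           ifelse(grid$log2fc > 0, "induced", "repressed"))
  npass <- tapply(grid$pass, grid$gene_id, sum)[genes]
  calls <- data.frame(gene_id = genes,
                      is_deg = as.vector(npass) > 0,
                      n_passing_contrasts = as.integer(npass),
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, contrasts = grid,
                 fc_threshold = fc_threshold, alpha = alpha),
            class = "zf_degs")
}

#' @export
print.zf_degs <- function(x, ...) {
  cat(sprintf(
    "DEG calls: %d of %d genes pass (|log2FC| >= %.2f and all 3 sigs < %g)\n",
    sum(x$calls$is_deg), nrow(x$calls), log2(x$fc_threshold), x$alpha))
  invisible(x)
}

#' Stage means from a replicate FPKM matrix
#'
#' @param fpkm numeric matrix, genes x (stage_replicate) with column
#'   names like `HD_1`; the stage is the token before the underscore.
#' @return genes x 5 matrix of stage means in the canonical stage order.
#' @export
stage_means <- function(fpkm) {
  st <- sub("_.*$", "", colnames(fpkm))
  miss <- setdiff(STAGES, st)
  if (length(miss)) .stopf("missing stage column(s): %s",
                           paste(miss, collapse = ", "))
  out <- sapply(STAGES, function(s)
    rowMeans(fpkm[, st == s, drop = FALSE]))
  rownames(out) <- rownames(fpkm)
  out
}

#' Z-score five-stage profiles gene-wise
#'
#' Reduces a replicate matrix to stage means, moves to the log2 scale
#' (the scale expression-pattern clustering conventionally runs on),
#' then subtracts each gene's mean and divides by the standard deviation
#' of its five values (Mfuzz-style standardization). Genes with zero
#' variance across stages, or with non-finite log values (zero FPKM with
#' `pseudocount = 0`), are excluded and reported.
#'
#' @param x genes x 5 stage-mean matrix (see [stage_means()]), or a
#'   replicate FPKM matrix which is first reduced to stage means.
#' @param log2 standardize log2 expression (default) rather than the
#'   natural scale.
#' @param pseudocount added before the log (default 0; supply a positive
#'   value when zero-FPKM genes must be retained).
#' @return z-scored matrix with an `excluded` attribute naming the
#'   dropped genes.
#' @export
standardize_profiles <- function(x, log2 = TRUE, pseudocount = 0) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != length(STAGES)) x <- stage_means(x)
  if (log2) x <- base::log2(x + pseudocount)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  keep <- is.finite(mu) & is.finite(sd) & sd > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  attr(z, "excluded") <- rownames(x)[!keep]
  z
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Standard fuzzy c-means on Euclidean distance with fuzzifier `m`:
#' random centroid initialization from `seed` (distinct data points),
#' alternating membership/centroid updates; the objective is
#' non-increasing and iteration stops when its decrease falls below
#' `tol`. When `templates` is supplied (default: the six canonical
#' patterns for `centers = 6`), cluster labels are canonicalized by the
#' total-distance-minimizing assignment of centroids to z-scored
#' templates, so "pattern k" is stable across runs.
#'
#' @param x numeric matrix of z-scored profiles (rows = genes).
#' @param centers number of clusters (default 6).
#' @param m fuzzifier (> 1; default 2).
#' @param tol,max_iter convergence controls.
#' @param seed RNG seed for centroid initialization.
#' @param templates optional template matrix for label canonicalization;
#'   `NULL` disables it.
#' @return list of class `zf_fcm`: `membership` (rows sum to 1),
#'   `centroids`, `hard` (named argmax pattern per gene), `objective`
#'   (trace), `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(x, centers = 6L, m = 2, tol = 1e-6,
                         max_iter = 1000L, seed = NULL,
                         templates = if (centers == 6L) pattern_templates()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < centers) .stopf("need at least %d profiles for %d clusters",
                          centers, centers)
  stopifnot(m > 1)
  if (!is.null(seed)) set.seed(seed)
  ## D^2-weighted random seeding (kmeans++ style): subsequent centroids
  ## are drawn proportional to the squared distance from the nearest
  ## chosen one, so (near-)duplicate profiles cannot absorb two seeds
  idx <- sample.int(n, 1)
  for (k in seq_len(centers - 1L)) {
    d2min <- apply(x, 1, function(r)
      min(colSums((t(x[idx, , drop = FALSE]) - r)^2)))
    if (sum(d2min) == 0) idx <- c(idx, sample.int(n, 1))
    else idx <- c(idx, sample.int(n, 1, prob = d2min))
  }
  cent <- x[idx, , drop = FALSE]
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  u <- NULL
  for (iter in seq_len(max_iter)) {
    ## squared Euclidean distances genes x centers
    d2 <- outer(rowSums(x^2), rep(1, centers)) +
      outer(rep(1, n), rowSums(cent^2)) - 2 * x %*% t(cent)
    d2[d2 < 0] <- 0
    u <- matrix(0, n, centers)
    zero <- d2 < 1e-12
    hit <- rowSums(zero) > 0
    if (any(hit)) u[hit, ] <- zero[hit, ] / rowSums(zero[hit, , drop = FALSE])
    if (any(!hit)) {
      r <- d2[!hit, , drop = FALSE]^(expo / 2)
      u[!hit, ] <- (1 / r) / rowSums(1 / r)
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    cent <- (t(um) %*% x) / colSums(um)
    if (iter > 1 && obj[iter - 1] - obj[iter] < tol) break
  }
  converged <- iter < max_iter
  labels <- paste0("pattern", seq_len(centers))
  if (!is.null(templates)) {
    stopifnot(nrow(templates) == centers)
    zt <- t(apply(templates, 1, function(v) (v - mean(v)) / stats::sd(v)))
    perm <- .best_assignment(cent, zt)
    ## reorder clusters so cluster k matches template k
    inv <- order(perm)
    u <- u[, inv, drop = FALSE]
    cent <- cent[inv, , drop = FALSE]
    labels <- rownames(templates)
  }
  colnames(u) <- labels
  rownames(u) <- rownames(x)
  rownames(cent) <- labels
  colnames(cent) <- colnames(x)
  hard <- labels[max.col(u, ties.method = "first")]
  names(hard) <- rownames(x)
  structure(list(membership = u, centroids = cent, hard = hard,
                 objective = obj, iterations = iter,
                 converged = converged, m = m),
            class = "zf_fcm")
}

## exhaustive assignment of centroids to templates minimizing total
## squared distance (c <= 8; factorial search is cheap and exact)
#' @noRd
.best_assignment <- function(cent, templates) {
  k <- nrow(cent)
  d2 <- outer(rowSums(cent^2), rep(1, k)) +
    outer(rep(1, k), rowSums(templates^2)) - 2 * cent %*% t(templates)
  if (k <= 8) {
    perms <- .permutations(seq_len(k))
    costs <- apply(perms, 1, function(p) sum(d2[cbind(seq_len(k), p)]))
    perms[which.min(costs), ]
  } else {
    ## greedy fallback for large k
    perm <- integer(k)
    free <- seq_len(k)
    for (i in order(apply(d2, 1, min))) {
      j <- free[which.min(d2[i, free])]
      perm[i] <- j
      free <- setdiff(free, j)
    }
    perm
  }
}

#' @export
print.zf_fcm <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means: %d profiles, %d clusters, m = %g, %d iteration(s)%s\n",
    nrow(x$membership), ncol(x$membership), x$m, x$iterations,
    if (x$converged) "" else " (not converged)"))
  print(table(x$hard))
  invisible(x)
}

#' Integrate DEG calls, patterns and family annotations
#'
#' One row per DEG, combining species, fuzzy pattern, phylogenetic group
#' (an external input), coarse C2H2-ZF type composition, promoter
#' ABRE/DRE/MBS counts, per-contrast direction and mean expression per
#' stage on a log2(FPKM + 1) display scale.
#'
#' @param degs [call_degs()] result.
#' @param fcm [fuzzy_cmeans()] result (or `NULL`).
#' @param profiles [profile_proteins()] table.
#' @param species_map data.frame `gene_id`, `species`.
#' @param id_map optional data.frame `gene_id`, `protein_id`; by default
#'   gene and protein ids are assumed identical.
#' @param groups optional data.frame `gene_id` (or `protein_id`),
#'   `group`.
#' @param motif_summary optional [motif_hit_summary()] table.
#' @param fpkm optional replicate FPKM matrix for the display columns.
#' @return data.frame (one row per DEG) with attributes `rejects`
#'   (DEG ids that could not be mapped to a protein profile), `by_group`
#'   and `by_type` roll-up tables.
#' @export
integrate_annotations <- function(degs, fcm = NULL, profiles,
                                  species_map = NULL, id_map = NULL,
                                  groups = NULL, motif_summary = NULL,
                                  fpkm = NULL) {
  deg_ids <- degs$calls$gene_id[degs$calls$is_deg]
  if (length(deg_ids) == 0L) {
    out <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    attr(out, "rejects") <- character(0)
    return(out)
  }
  to_protein <- if (is.null(id_map)) stats::setNames(deg_ids, deg_ids)
    else stats::setNames(id_map$protein_id, id_map$gene_id)[deg_ids]
  prot_idx <- match(to_protein, profiles$protein_id)
  rejects <- deg_ids[is.na(prot_idx)]
  keep <- !is.na(prot_idx)
  ids <- deg_ids[keep]
  out <- data.frame(
    gene_id = ids,
    protein_id = to_protein[keep],
    coarse_types = profiles$coarse_types[prot_idx[keep]],
    category = profiles$category[prot_idx[keep]],
    n_fingers = profiles$n_fingers[prot_idx[keep]],
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(species_map))
    out$species <- stats::setNames(species_map$species,
                                   species_map$gene_id)[ids]
  if (!is.null(fcm))
    out$pattern <- unname(fcm$hard[ids])
  if (!is.null(groups)) {
    gid_col <- if ("gene_id" %in% names(groups)) "gene_id" else "protein_id"
    out$group <- stats::setNames(groups$group, groups[[gid_col]])[ids]
  }
  if (!is.null(motif_summary)) {
    midx <- match(ids, motif_summary$gene_id)
    for (col in intersect(c("ABRE_hits", "DRE_hits", "MBS_hits"),
                          names(motif_summary)))
      out[[tolower(col)]] <- motif_summary[[col]][midx]
  }
  ## per-contrast direction summary
  ct <- degs$contrasts[degs$contrasts$pass, , drop = FALSE]
  dir_of <- function(id) {
    rows <- ct[ct$gene_id == id, , drop = FALSE]
    paste(paste0(rows$contrast, ":", rows$direction), collapse = ";")
  }
  out$directions <- vapply(ids, dir_of, character(1), USE.NAMES = FALSE)
  if (!is.null(fpkm)) {
    sm <- stage_means(fpkm)
    idx <- match(ids, rownames(sm))
    for (s in STAGES)
      out[[paste0("log2_fpkm_", s)]] <- log2(sm[idx, s] + 1)
  }
  attr(out, "rejects") <- rejects
  if (!is.null(fcm) && !is.null(out$group))
    attr(out, "by_group") <- as.data.frame(table(group = out$group,
                                                 pattern = out$pattern))
  attr(out, "by_type") <- as.data.frame(table(coarse_types =
                                                out$coarse_types))
  out
}
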