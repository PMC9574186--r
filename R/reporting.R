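## Family-level reports: per-species overview (protein counts, domain
## types, pure/mixed), phylogenetic group tables, and the end-to-end
## pipeline driver. Every printed percentage recomputes exactly from the
## integer cells in the same table (round half up, 1 decimal).

#' Build the family overview report
#'
#' Appends a `Total` row (column sums) to the per-species summary and
#' derives percentages from the integer cells: share of proteins with
#' only C2H2-ZF domains, share with a coiled-coil domain, mixed-type
#' share, and each species' share of the family.
#'
#' @param summaries per-species table from [summarize_family()] (or any
#'   data.frame with `species`, `n_proteins` and further integer
#'   columns).
#' @param element_summary optional `abre_dre` table from
#'   [summarize_elements()]; its percentage column is joined by species.
#' @return data.frame of class `zf_family_report` with the totals row
#'   last; percentage columns are rounded half up to 1 decimal.
#' @export
build_family_report <- function(summaries, element_summary = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("species", "n_proteins") %in% names(summaries)))
  num_cols <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  total <- summaries[1, , drop = FALSE]
  total$species <- "Total"
  for (cl in num_cols) total[[cl]] <- sum(summaries[[cl]])
  out <- rbind(summaries, total)
  grand <- total$n_proteins
  if (grand > 0) {
    out$pct_of_family <- round_half_up(100 * out$n_proteins / grand, 1)
    if ("n_c2h2_only" %in% names(out))
      out$pct_c2h2_only <- round_half_up(
        100 * out$n_c2h2_only / out$n_proteins, 1)
    if ("n_coiled_coil" %in% names(out))
      out$pct_coiled_coil <- round_half_up(
        100 * out$n_coiled_coil / out$n_proteins, 1)
    if (all(c("n_mixed") %in% names(out)))
      out$pct_mixed <- round_half_up(100 * out$n_mixed / out$n_proteins, 1)
  }
  if (!is.null(element_summary)) {
    idx <- match(out$species, element_summary$species)
    out$pct_abre_or_dre <- element_summary$pct_abre_or_dre[idx]
  }
  class(out) <- c("zf_family_report", class(out))
  out
}

#' Build the phylogenetic group report
#'
#' Counts proteins per group (and subgroup) and species from a
#' membership table, with a totals row, each group's share of the grand
#' total, and optional within-group shares for `c2h2_only` and
#' `angiosperm` flags when those columns are present. Subgroup sums that
#' disagree with their group total are flagged, not corrected.
#'
#' @param group_table data.frame with one row per protein: `species`,
#'   `group`, optional `subgroup` (empty string for none), optional
#'   logical `c2h2_only` and `angiosperm` columns.
#' @param valid_groups allowed group labels (default I-IV).
#' @return list of class `zf_group_report`: `groups` (per group/subgroup
#'   x species counts with derived shares), `total`, `inconsistent`
#'   (subgroup labels whose sums disagree with the group row).
#' @export
build_group_report <- function(group_table,
                               valid_groups = c("I", "II", "III", "IV")) {
  stopifnot(is.data.frame(group_table),
            all(c("species", "group") %in% names(group_table)))
  bad <- setdiff(unique(group_table$group), valid_groups)
  if (length(bad))
    .stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  gt <- group_table
  if (is.null(gt$subgroup)) gt$subgroup <- ""
  species <- unique(gt$species)
  grand <- nrow(gt)

  row_for <- function(sub) {
    n <- nrow(sub)
    counts <- vapply(species, function(s) sum(sub$species == s), integer(1))
    r <- data.frame(n = n, t(counts), stringsAsFactors = FALSE,
                    check.names = FALSE)
    r$pct_of_total <- round_half_up(100 * n / grand, 1)
    r$pct_c2h2_only <- if (!is.null(sub$c2h2_only) && n)
      round_half_up(100 * sum(sub$c2h2_only) / n, 1) else NA_real_
    r$pct_angiosperm <- if (!is.null(sub$angiosperm) && n)
      round_half_up(100 * sum(sub$angiosperm) / n, 1) else NA_real_
    r
  }
  rows <- list()
  inconsistent <- character(0)
  for (g in intersect(valid_groups, unique(gt$group))) {
    sub_g <- gt[gt$group == g, , drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(group = g, subgroup = "", stringsAsFactors = FALSE),
      row_for(sub_g))
    subs <- setdiff(unique(sub_g$subgroup), "")
    sub_total <- 0L
    for (s in sort(subs)) {
      sub_s <- sub_g[sub_g$subgroup == s, , drop = FALSE]
      sub_total <- sub_total + nrow(sub_s)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = g, subgroup = s, stringsAsFactors = FALSE),
        row_for(sub_s))
    }
    if (length(subs) && sub_total != nrow(sub_g))
      inconsistent <- c(inconsistent, g)
  }
  groups <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  total <- cbind(data.frame(group = "Total", subgroup = "",
                            stringsAsFactors = FALSE), row_for(gt))
  structure(list(groups = groups, total = total,
                 inconsistent = inconsistent),
            class = "zf_group_report")
}

#' @export
print.zf_group_report <- function(x, ...) {
  print(rbind(x$groups, x$total))
  if (length(x$inconsistent))
    cat("! subgroup sums disagree with group totals for:",
        paste(x$inconsistent, collapse = ", "), "\n")
  invisible(x)
}

#' Run the whole characterization pipeline on a synthetic world
#'
#' Generates one proteome and genome per manifest, round-trips the GFF3
#' and FASTA through files, then runs every stage: finger scan and
#' classification, physicochemistry, gene models, promoters, cis-element
#' scan, duplicate pairs, Ka/Ks on simulated duplicate pairs, DEG
#' calling, fuzzy pattern clustering, annotation integration and the
#' family report.
#'
#' @param manifests list of [species_manifest()] objects.
#' @param seed integer master seed for the expression and Ka/Ks
#'   simulations.
#' @param n_genes,n_degs_per_pattern expression world size (defaults 200
#'   genes, 8 DEGs per pattern).
#' @param kaks_pairs_n,kaks_codons Ka/Ks simulation size.
#' @param out_dir optional directory for TSV reports.
#' @return list with the per-species results and the integrated tables.
#' @export
run_pipeline <- function(manifests, seed = 1L, n_genes = 200L,
                         n_degs_per_pattern = 8L, kaks_pairs_n = 20L,
                         kaks_codons = 100L, out_dir = NULL) {
  per_species <- list()
  all_profiles <- list()
  all_fingers <- list()
  species_map <- list()
  gene_species <- list()
  motif_scans <- list()

  for (mf in manifests) {
    code <- mf$species_code
    prot <- generate_proteome(mf)
    gen <- generate_genome_annotation(mf)
    ## exercise the file formats
    tmp <- tempfile(fileext = ".gff3")
    writeLines(gen$gff, tmp)
    models <- parse_gene_models(tmp)
    unlink(tmp)
    promoters <- extract_promoters(gen$genome, models)
    scan <- scan_motifs(promoters)
    fingers <- classify_fingers(scan_proteins(prot$proteins))
    profiles <- profile_proteins(fingers,
                                 protein_ids = names(prot$proteins))
    pc <- physchem_profile(prot$proteins)
    dup <- find_duplicate_pairs(gen$proteins, models)
    per_species[[code]] <- list(
      proteome = prot, genome = gen, models = models,
      promoters = promoters, motif_scan = scan, fingers = fingers,
      profiles = profiles, physchem = pc, duplicates = dup,
      chromosomes = chromosome_distribution(models))
    all_profiles[[code]] <- profiles
    all_fingers[[code]] <- fingers
    species_map[[code]] <- data.frame(protein_id = names(prot$proteins),
                                      species = code,
                                      stringsAsFactors = FALSE)
    gene_species[[code]] <- data.frame(gene_id = models$gene_id,
                                       species = code,
                                       stringsAsFactors = FALSE)
    motif_scans[[code]] <- scan
  }
  profiles <- do.call(rbind, c(unname(all_profiles),
                               list(make.row.names = FALSE)))
  fingers <- do.call(rbind, c(unname(all_fingers),
                              list(make.row.names = FALSE)))
  smap <- do.call(rbind, c(unname(species_map), list(make.row.names = FALSE)))
  summaries <- summarize_family(profiles, fingers, smap,
                                annotations = do.call(rbind, c(
                                  lapply(unname(per_species), function(x)
                                    x$proteome$annotations),
                                  list(make.row.names = FALSE))))
  gmap <- do.call(rbind, c(unname(gene_species), list(make.row.names = FALSE)))
  scans <- do.call(rbind, c(unname(motif_scans), list(make.row.names = FALSE)))
  elements <- summarize_elements(scans, gmap)
  family_report <- build_family_report(summaries,
                                       element_summary = elements$abre_dre)

  ## molecular evolution on simulated duplicate pairs
  dp <- generate_duplicate_pairs(kaks_pairs_n, kaks_codons,
                                 syn_rate = 0.45, nonsyn_rate = 0.045,
                                 seed = seed)
  kaks <- kaks_pairs(dp$cds)

  ## NJ tree over concatenated domains of a few proteins per species
  reps <- lapply(per_species, function(x) {
    p <- x$profiles$protein_id[seq_len(min(2L, nrow(x$profiles)))]
    vapply(p, function(id) concat_domains(
      x$proteome$proteins[[id]],
      x$fingers[x$fingers$protein_id == id, , drop = FALSE]), character(1))
  })
  doms <- unlist(reps)
  doms <- doms[!is.na(doms)]
  tree <- NULL
  if (length(doms) >= 3L) {
    dm <- matrix(0, length(doms), length(doms),
                 dimnames = list(names(doms), names(doms)))
    for (i in seq_along(doms)) for (j in seq_along(doms)) if (i < j) {
      al <- global_align(doms[[i]], doms[[j]])
      dm[i, j] <- dm[j, i] <- 1 - al$identity
    }
    tree <- nj_tree(dm)
  }

  ## expression world
  expr <- generate_expression(n_genes,
                              pattern_mix = rep(n_degs_per_pattern, 6),
                              seed = seed)
  degs <- call_degs(expr$tables)
  deg_ids <- degs$calls$gene_id[degs$calls$is_deg]
  z <- standardize_profiles(expr$fpkm[deg_ids, , drop = FALSE])
  fcm <- fuzzy_cmeans(z, seed = seed)
  ## expression genes are their own "proteins" here: give each one Q-type
  ## placeholder profile so integration has a target
  expr_profiles <- data.frame(protein_id = deg_ids, n_fingers = 1L,
                              types = "Q", coarse_types = "Q",
                              category = "pure:Q", stringsAsFactors = FALSE)
  integrated <- integrate_annotations(degs, fcm, expr_profiles,
                                      fpkm = expr$fpkm)

  out <- list(per_species = per_species, summaries = summaries,
              elements = elements, family_report = family_report,
              kaks = kaks, tree = tree, expression = expr, degs = degs,
              fcm = fcm, integrated = integrated)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(as.data.frame(family_report),
                 file.path(out_dir, "family_report.tsv"),
                 meta = list(seed = seed))
    write_report(kaks, file.path(out_dir, "kaks.tsv"),
                 meta = list(seed = seed))
    write_report(integrated, file.path(out_dir, "integrated.tsv"),
                 meta = list(seed = seed))
  }
  out
}
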