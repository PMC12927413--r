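# Consensus extraction: support computation on the consensus-node HOGs,
# the retention rule, representative selection, assembly and reports.

#' Compute support records for the consensus-node HOGs
#'
#' One record per HOG at the consensus node. Source bits come from the
#' member species labels. The outgroup bit for species `s` is set iff a gene
#' of `s` co-occurs with the HOG's members in an ancestral HOG above the
#' consensus node (`outgroup_evidence = "hog"`, the default) or iff a direct
#' ortholog pair links a member gene to a gene of `s`
#' (`outgroup_evidence = "pairs"`; requires `pairs`).
#'
#' @param forest a `hog_forest` ([build_hogs()] or [read_orthoxml()]).
#' @param tree the [read_species_tree()] object.
#' @param pairs ortholog pairs data.frame (needed for `"pairs"` evidence).
#' @param outgroup_evidence `"hog"` or `"pairs"`.
#' @return List of `support_record` objects: `hog_id`, `sources` (named
#'   logical), `outgroups` (named logical), `members` (data.frame
#'   species/gene_id).
#' @export
compute_support <- function(forest, tree, pairs = NULL,
                            outgroup_evidence = c("hog", "pairs")) {
  outgroup_evidence <- match.arg(outgroup_evidence)
  if (outgroup_evidence == "pairs" && is.null(pairs))
    stop_config("outgroup_evidence = 'pairs' requires the ortholog pairs")
  cons_ids <- forest$by_node[[as.character(tree$consensus_node)]]
  if (is.null(cons_ids) && length(forest$hogs) > 0)
    stop_data("HOG forest has no groups at the consensus node")
  records <- list()
  for (id in cons_ids) {
    h <- forest$hogs[[id]]
    mem_sources <- unique(h$members$species)
    if (!all(mem_sources %in% tree$sources))
      stop_data("HOG ", id, " at the consensus node contains non-source species")
    src_bits <- setNames(tree$sources %in% mem_sources, tree$sources)
    out_bits <- setNames(rep(FALSE, length(tree$outgroups)), tree$outgroups)
    if (outgroup_evidence == "hog") {
      p <- h$parent
      while (!is.na(p) && !is.null(forest$hogs[[p]])) {
        anc <- forest$hogs[[p]]
        out_bits[intersect(unique(anc$members$species), tree$outgroups)] <- TRUE
        p <- anc$parent
      }
    } else {
      for (k in seq_len(nrow(h$members))) {
        hit_a <- pairs$species_a == h$members$species[k] &
          pairs$gene_a == h$members$gene_id[k]
        hit_b <- pairs$species_b == h$members$species[k] &
          pairs$gene_b == h$members$gene_id[k]
        out_bits[intersect(c(pairs$species_b[hit_a], pairs$species_a[hit_b]),
                           tree$outgroups)] <- TRUE
      }
    }
    records[[length(records) + 1L]] <- structure(
      list(hog_id = id, sources = src_bits, outgroups = out_bits,
           members = h$members), class = "support_record")
  }
  records
}

#' Apply the retention rule
#'
#' A candidate gene is retained iff it is supported by at least two distinct
#' sources, or by one source plus at least one outgroup ortholog. Order is
#' preserved. Two genes of the *same* source in one HOG do not count as two
#' sources.
#'
#' @param records list of `support_record`s from [compute_support()].
#' @return The retained subset, same order.
#' @export
retain_genes <- function(records) {
  Filter(function(r) {
    ns <- sum(r$sources)
    ns >= 2 || (ns >= 1 && any(r$outgroups))
  }, records)
}

# longest-isoform CDS length (nt) of a gene model
gene_cds_length <- function(gene) {
  max(vapply(gene$transcripts, `[[`, 0L, "cds_length"))
}

#' Select the representative gene model of a retained HOG
#'
#' Default: the member gene whose longest isoform has the greatest CDS length
#' (nucleotides). With `priority`, the member from the highest-ranking source
#' present in the HOG (longest CDS within that source); if no listed source
#' is present, falls back to longest CDS over all members. Ties go to the
#' source earliest in `source_order`, then to the smallest gene id.
#'
#' @param record a retained `support_record`.
#' @param annotations named list `source -> annotation_set`.
#' @param priority optional ordered character vector of source names.
#' @param source_order declared source order for tie-breaks (defaults to
#'   `names(annotations)`).
#' @return List with `gene` (the `gene_model`) and `source`.
#' @export
select_representative <- function(record, annotations, priority = NULL,
                                  source_order = names(annotations)) {
  if (!is.null(priority)) {
    unknown <- setdiff(priority, names(annotations))
    if (length(unknown))
      stop_config("priority list names unknown source(s): ",
                  paste(unknown, collapse = ", "))
  }
  mem <- record$members
  cand <- mem
  if (!is.null(priority)) {
    present <- priority[priority %in% mem$species]
    if (length(present))
      cand <- mem[mem$species == present[1], , drop = FALSE]
  }
  lens <- vapply(seq_len(nrow(cand)), function(k) {
    g <- annotations[[cand$species[k]]]$genes[[cand$gene_id[k]]]
    if (is.null(g))
      stop_data("HOG member gene '", cand$gene_id[k], "' not found in source '",
                cand$species[k], "'")
    gene_cds_length(g)
  }, 0L)
  ord <- order(-lens, match(cand$species, source_order), cand$gene_id)
  sel <- cand[ord[1], ]
  list(gene = annotations[[sel$species]]$genes[[sel$gene_id]],
       source = sel$species)
}

support_label <- function(record) {
  lab <- paste(names(record$sources)[record$sources], collapse = "+")
  if (any(record$outgroups)) lab <- paste0(lab, "+outgroups")
  lab
}

#' Assemble the consensus annotation
#'
#' Copies each retained HOG's representative gene with *all* of its isoforms
#' and original coordinates, attaching provenance (source, support record).
#'
#' @param retained retained `support_record`s ([retain_genes()]).
#' @param annotations named list `source -> annotation_set`.
#' @param priority optional priority source order (see
#'   [select_representative()]).
#' @param metadata free-form run metadata list stored on the object.
#' @return Object of class `consensus_annotation`: list with `genes` (each a
#'   list `hog_id`/`gene`/`source`/`support`) and `metadata`.
#' @export
assemble_consensus <- function(retained, annotations, priority = NULL,
                               metadata = list()) {
  genes <- lapply(retained, function(r) {
    rep <- select_representative(r, annotations, priority = priority)
    list(hog_id = r$hog_id, gene = rep$gene, source = rep$source, support = r)
  })
  metadata$sources <- names(annotations)
  metadata$priority <- priority
  structure(list(genes = genes, metadata = metadata),
            class = "consensus_annotation")
}

#' @export
print.consensus_annotation <- function(x, ...) {
  cat("consensus_annotation: ", length(x$genes), " genes from sources {",
      paste(x$metadata$sources, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Write the summary and detailed consensus reports
#'
#' `<prefix>_report.txt` summarizes the total number of retained genes, the
#' counts per support combination, and how often each source supplied the
#' representative model. `<prefix>_detailed_report.txt` is a TSV with one row
#' per consensus gene and one 0/1 column per source and per outgroup species
#' (sources in declared order, then outgroups in tree order).
#'
#' @param consensus a `consensus_annotation`.
#' @param out_prefix output path prefix.
#' @param tree the `species_tree` (defines outgroup column order).
#' @return Invisibly, the two file paths.
#' @export
write_reports <- function(consensus, out_prefix, tree) {
  genes <- consensus$genes
  sources <- consensus$metadata$sources
  outgroups <- tree$outgroups

  # stable order: same as the GFF3 writer (contig, start, gene id)
  if (length(genes)) {
    reps <- lapply(genes, `[[`, "gene")
    genes <- genes[order(vapply(reps, `[[`, "", "contig"),
                         vapply(reps, `[[`, 0L, "start"),
                         vapply(reps, `[[`, "", "gene_id"))]
  }

  labels <- vapply(genes, function(g) support_label(g$support), "")
  rep_src <- vapply(genes, `[[`, "", "source")
  n_src <- vapply(genes, function(g) sum(g$support$sources), 0)
  n_out <- vapply(genes, function(g) sum(g$support$outgroups), 0)

  summary_path <- paste0(out_prefix, "_report.txt")
  lines <- c(
    "Consensus annotation report",
    sprintf("Retained genes: %d", length(genes)),
    sprintf("Supported by multiple sources: %d", sum(n_src >= 2)),
    sprintf("Single source with outgroup support: %d",
            sum(n_src == 1 & n_out >= 1)),
    "",
    "Support combinations:")
  if (length(genes)) {
    tab <- table(labels)
    lines <- c(lines, sprintf("  %s: %d", names(tab), as.integer(tab)))
  }
  lines <- c(lines, "", "Representative models per source:",
             sprintf("  %s: %d", sources,
                     vapply(sources, function(s) sum(rep_src == s), 0)))
  writeLines(lines, summary_path)

  detail_path <- paste0(out_prefix, "_detailed_report.txt")
  bits <- lapply(genes, function(g)
    as.integer(c(g$support$sources[sources], g$support$outgroups[outgroups])))
  df <- data.frame(
    gene_id = vapply(genes, function(g) g$gene$gene_id, ""),
    hog_id = vapply(genes, `[[`, "", "hog_id"),
    representative_source = rep_src,
    members = vapply(genes, function(g)
      paste(paste0(g$support$members$species, ":", g$support$members$gene_id),
            collapse = ","), ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  mat <- if (length(bits)) do.call(rbind, bits) else
    matrix(integer(0), ncol = length(sources) + length(outgroups))
  colnames(mat) <- c(sources, outgroups)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  write.table(df, detail_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(summary = summary_path, detailed = detail_path))
}
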