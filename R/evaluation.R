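# Sensitivity/precision evaluation of a query annotation against a
# reference, with GffCompare-style matching rules at the exon, locus and
# transcript levels. CDS segments stand in for exons throughout (the
# pipeline models coding structure only).

flatten_transcripts <- function(annotation) {
  out <- list()
  for (g in annotation$genes) for (t in g$transcripts) {
    out[[length(out) + 1L]] <- list(
      gene_id = g$gene_id, transcript_id = t$transcript_id,
      contig = t$segments$contig[1], strand = t$segments$strand[1],
      starts = t$segments$start, ends = t$segments$end)
  }
  out
}

chain_signature <- function(t) {
  paste0(t$contig, t$strand, "|", paste(t$starts, t$ends, sep = "-",
                                        collapse = ","))
}

#' Transcript-level match test
#'
#' Multi-exon transcripts match iff their intron chains are identical and
#' each outer terminal boundary differs by at most `tolerance` bases (applied
#' per end independently). Two single-exon transcripts match iff the query
#' overlaps at least `min_overlap` of the reference exon length. A single-
#' exon transcript never matches a multi-exon one, and transcripts on
#' different contigs or strands never match.
#'
#' @param query,ref `transcript_model` objects.
#' @param tolerance terminal boundary tolerance in bases (default 100).
#' @param min_overlap single-exon overlap fraction of the reference (0.8).
#' @return `TRUE` or `FALSE`.
#' @export
transcript_match <- function(query, ref, tolerance = 100, min_overlap = 0.8) {
  q <- if (inherits(query, "transcript_model"))
    list(contig = query$segments$contig[1], strand = query$segments$strand[1],
         starts = query$segments$start, ends = query$segments$end) else query
  r <- if (inherits(ref, "transcript_model"))
    list(contig = ref$segments$contig[1], strand = ref$segments$strand[1],
         starts = ref$segments$start, ends = ref$segments$end) else ref
  if (q$contig != r$contig || q$strand != r$strand) return(FALSE)
  nq <- length(q$starts); nr <- length(r$starts)
  if (nq > 1 && nr > 1) {
    # intron chain: (end_i, start_{i+1}) pairs must be identical
    if (nq != nr) return(FALSE)
    if (!identical(q$ends[-nq], r$ends[-nr]) ||
        !identical(q$starts[-1], r$starts[-1])) return(FALSE)
    abs(q$starts[1] - r$starts[1]) <= tolerance &&
      abs(q$ends[nq] - r$ends[nr]) <= tolerance
  } else if (nq == 1 && nr == 1) {
    ov <- min(q$ends, r$ends) - max(q$starts, r$starts)
    ov >= min_overlap * (r$ends - r$starts)
  } else FALSE
}

# single-linkage clustering of [start, end) spans; returns cluster ids
cluster_spans <- function(start, end) {
  n <- length(start)
  if (n == 0) return(integer(0))
  ord <- order(start, end)
  cl <- integer(n); cur <- 0L; maxend <- -Inf
  for (k in ord) {
    if (start[k] >= maxend) { cur <- cur + 1L; maxend <- end[k] }
    else maxend <- max(maxend, end[k])
    cl[k] <- cur
  }
  cl
}

level_stats <- function(level, tp, fn, fp) {
  data.frame(level = level, tp = tp, fn = fn, fp = fp,
             sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
             precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 100,
             stringsAsFactors = FALSE)
}

#' Evaluate a query annotation against a reference
#'
#' Duplicate query transcripts (identical exon chains) are discarded first.
#' Exon level counts distinct `(contig, strand, start, end)` exon intervals;
#' a TP is an exact boundary match. Transcript level uses
#' [transcript_match()]; TP = reference transcripts with at least one
#' matching query transcript, FP = query transcripts matching none. Locus
#' level clusters overlapping same-strand reference (and query) genes into
#' loci; a reference locus is a TP iff one of its transcripts is matched, and
#' a query locus counts as FP iff none of its transcripts matches anything.
#'
#' @param query,ref `annotation_set` objects; `ref` must be non-empty.
#' @param tolerance,min_overlap see [transcript_match()].
#' @return data.frame with one row per level (`exon`, `locus`, `transcript`)
#'   and columns `tp`, `fn`, `fp`, `sensitivity`, `precision` (percent).
#' @export
evaluate_annotation <- function(query, ref, tolerance = 100, min_overlap = 0.8) {
  if (length(ref$genes) == 0)
    stop_data("empty reference annotation: sensitivity undefined")
  qt <- flatten_transcripts(query)
  rt <- flatten_transcripts(ref)
  qt <- qt[!duplicated(vapply(qt, chain_signature, ""))]  # the "-D" rule

  # ---- exon level
  exon_keys <- function(ts) unique(unlist(lapply(ts, function(t)
    paste0(t$contig, t$strand, ":", t$starts, "-", t$ends))))
  qe <- exon_keys(qt); re <- exon_keys(rt)
  ex <- level_stats("exon", length(intersect(qe, re)),
                    length(setdiff(re, qe)), length(setdiff(qe, re)))

  # ---- transcript level (candidate pairs share contig+strand)
  key <- function(ts) vapply(ts, function(t) paste0(t$contig, t$strand), "")
  qkey <- key(qt); rkey <- key(rt)
  q_matched <- logical(length(qt)); r_matched <- logical(length(rt))
  for (i in seq_along(rt)) {
    for (j in which(qkey == rkey[i])) {
      if (transcript_match(qt[[j]], rt[[i]], tolerance, min_overlap)) {
        r_matched[i] <- TRUE; q_matched[j] <- TRUE
      }
    }
  }
  tr <- level_stats("transcript", sum(r_matched), sum(!r_matched),
                    sum(!q_matched))

  # ---- locus level
  gene_loci <- function(ts, matched) {
    if (length(ts) == 0) return(logical(0))
    genes <- unique(data.frame(
      gene_id = vapply(ts, `[[`, "", "gene_id"),
      key = vapply(ts, function(t) paste0(t$contig, t$strand), ""),
      stringsAsFactors = FALSE))
    genes$start <- vapply(genes$gene_id, function(g)
      min(unlist(lapply(ts[vapply(ts, `[[`, "", "gene_id") == g],
                        `[[`, "starts"))), 0L)
    genes$end <- vapply(genes$gene_id, function(g)
      max(unlist(lapply(ts[vapply(ts, `[[`, "", "gene_id") == g],
                        `[[`, "ends"))), 0L)
    genes$locus <- NA_integer_
    off <- 0L
    for (k in unique(genes$key)) {
      sel <- genes$key == k
      genes$locus[sel] <- off + cluster_spans(genes$start[sel], genes$end[sel])
      off <- max(genes$locus[sel])
    }
    gmatch <- tapply(matched, vapply(ts, `[[`, "", "gene_id"), any)
    locus_matched <- tapply(as.logical(gmatch[genes$gene_id]), genes$locus, any)
    locus_matched
  }
  rl <- gene_loci(rt, r_matched)
  ql <- gene_loci(qt, q_matched)
  lo <- level_stats("locus", sum(rl), sum(!rl), sum(!ql))

  rbind(ex, lo, tr)
}

#' Evaluate two GFF3 files
#'
#' Convenience wrapper: parses both files (with optional feature maps) and
#' runs [evaluate_annotation()], optionally writing the stats as a TSV.
#'
#' @param query_path,ref_path GFF3 files.
#' @param out optional output TSV path.
#' @param query_feature_map,ref_feature_map feature maps for [parse_gff3()].
#' @return The stats data.frame.
#' @export
evaluate_files <- function(query_path, ref_path, out = NULL,
                           query_feature_map = default_feature_map(),
                           ref_feature_map = default_feature_map()) {
  stats <- evaluate_annotation(
    parse_gff3(query_path, query_feature_map, source_name = "query"),
    parse_gff3(ref_path, ref_feature_map, source_name = "ref"))
  if (!is.null(out))
    write.table(stats, out, sep = "\t", quote = FALSE, row.names = FALSE)
  stats
}
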