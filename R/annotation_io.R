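# Annotation I/O: GFF3 parsing with a feature-type map, CDS translation,
# proteome + splice-group extraction, and GFF3/FASTA writers.
#
# Internal coordinates are 0-based half-open; GFF3 I/O is the single
# conversion point to/from the 1-based inclusive convention.

# ---- constructors -----------------------------------------------------------

#' Create a transcript model
#'
#' A transcript is an ordered chain of CDS segments on one contig and strand.
#' Segments are given as a data.frame with columns `contig`, `start`, `end`
#' (0-based half-open), `strand` (`+`/`-`) and `phase` (0/1/2), and are sorted
#' by `start` on construction.
#'
#' @param transcript_id,parent_gene_id identifiers.
#' @param segments data.frame of CDS segments (see above).
#' @return An object of class `transcript_model`.
#' @export
new_transcript_model <- function(transcript_id, parent_gene_id, segments) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (length(unique(segments$contig)) != 1L || length(unique(segments$strand)) != 1L)
    stop_data("transcript '", transcript_id, "': CDS segments span multiple contigs or strands")
  if (any(segments$start >= segments$end))
    stop_data("transcript '", transcript_id, "': segment with start >= end")
  if (nrow(segments) > 1 && any(segments$start[-1] < segments$end[-nrow(segments)]))
    stop_data("transcript '", transcript_id, "': overlapping CDS segments")
  structure(list(
    transcript_id = transcript_id,
    parent_gene_id = parent_gene_id,
    segments = segments,
    cds_length = sum(segments$end - segments$start)
  ), class = "transcript_model")
}

#' Create a gene model
#'
#' @param gene_id identifier, unique within one annotation set.
#' @param source_name the annotation source (pseudo-species) label.
#' @param transcripts list of [new_transcript_model()] objects (>= 1).
#' @return An object of class `gene_model` with a genomic `span`.
#' @export
new_gene_model <- function(gene_id, source_name, transcripts) {
  stopifnot(length(transcripts) >= 1)
  tids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(tids))
    stop_data("gene '", gene_id, "': duplicated transcript ids")
  names(transcripts) <- tids
  contigs <- unique(vapply(transcripts, function(t) t$segments$contig[1], ""))
  strands <- unique(vapply(transcripts, function(t) t$segments$strand[1], ""))
  if (length(contigs) != 1L)
    stop_data("gene '", gene_id, "': transcripts on multiple contigs")
  structure(list(
    gene_id = gene_id,
    source_name = source_name,
    transcripts = transcripts,
    contig = contigs,
    strand = if (length(strands) == 1L) strands else "+",
    start = min(vapply(transcripts, function(t) min(t$segments$start), 0L)),
    end = max(vapply(transcripts, function(t) max(t$segments$end), 0L))
  ), class = "gene_model")
}

#' Create an annotation set
#'
#' All gene models from one annotation source; the source name doubles as the
#' pseudo-species label in the orthology step and must be unique per run.
#'
#' @param source_name source label.
#' @param genes list of [new_gene_model()] objects.
#' @param origin_path provenance string (input file path, or `""`).
#' @return An object of class `annotation_set`.
#' @export
new_annotation_set <- function(source_name, genes, origin_path = "") {
  gids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(gids))
    stop_data("source '", source_name, "': duplicated gene ids: ",
              paste(unique(gids[duplicated(gids)]), collapse = ", "))
  names(genes) <- gids
  structure(list(source_name = source_name, genes = genes,
                 origin_path = origin_path),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  nt <- sum(vapply(x$genes, function(g) length(g$transcripts), 0L))
  cat("annotation_set '", x$source_name, "': ", length(x$genes),
      " genes, ", nt, " transcripts\n", sep = "")
  invisible(x)
}

# ---- feature-type map -------------------------------------------------------

#' Default feature-type map
#'
#' Maps the standard GFF3 feature names to their role. Annotation tools often
#' deviate from these names; supply a custom map (see [read_feature_map()])
#' to interpret them. Matching is case-insensitive.
#'
#' @return Named character vector `source_feature -> role`, roles in
#'   `{gene, transcript, cds}`.
#' @export
default_feature_map <- function() {
  c(gene = "gene", mrna = "transcript", transcript = "transcript", cds = "cds")
}

#' Read a feature-type map from a two-column TSV
#'
#' Each line is `source_feature<TAB>role` with role one of `gene`,
#' `transcript`, `cds`. All three roles must be reachable and no feature name
#' may map to two roles.
#'
#' @param path TSV file path.
#' @return Named character vector usable as `feature_map` in [parse_gff3()].
#' @export
read_feature_map <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_data("feature map '", path, "': expected 2 columns")
  nm <- tolower(trimws(tab[[1]])); role <- tolower(trimws(tab[[2]]))
  bad <- setdiff(unique(role), c("gene", "transcript", "cds"))
  if (length(bad))
    stop_data("feature map '", path, "': unknown role(s): ", paste(bad, collapse = ", "))
  map <- setNames(role, nm)
  validate_feature_map(map)
  map
}

validate_feature_map <- function(map) {
  names(map) <- tolower(names(map))
  if (anyDuplicated(names(map))) {
    dups <- unique(names(map)[duplicated(names(map))])
    conflicting <- vapply(dups, function(d) length(unique(map[names(map) == d])) > 1, TRUE)
    if (any(conflicting))
      stop_data("feature map: name(s) mapped to two roles: ",
                paste(dups[conflicting], collapse = ", "))
    map <- map[!duplicated(names(map))]
  }
  missing <- setdiff(c("gene", "transcript", "cds"), unique(unname(map)))
  if (length(missing))
    stop_data("feature map: no feature name maps to role(s): ",
              paste(missing, collapse = ", "))
  map
}

# ---- GFF3 parsing -----------------------------------------------------------

parse_gff3_attributes <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) >= 2) paste(p[-1], collapse = "=") else "")
  setNames(lapply(vals, function(v) utils::URLdecode(v)),
           vapply(kv, function(p) trimws(p[1]), ""))
}

#' Parse a GFF3 annotation
#'
#' Builds an [new_annotation_set()] from GFF3 text or a file, interpreting
#' feature types through a feature-type map so that nonstandard names (e.g.
#' `locus`/`mRNA_region`/`coding`) can be read without reformatting the file.
#' Coordinates are converted from GFF3 1-based inclusive to internal 0-based
#' half-open. Rows whose (case-insensitively matched) type is absent from the
#' map are skipped and counted in `attr(x, "skipped_types")`. Transcripts
#' without a gene parent get a synthetic gene (`gene:<transcript_id>`);
#' a missing CDS `phase` is treated as 0.
#'
#' @param path_or_text GFF3 file path, or GFF3 text (anything containing a
#'   newline is treated as text).
#' @param feature_map named character vector `feature name -> role`
#'   (default [default_feature_map()]).
#' @param source_name source label; defaults to the file base name.
#' @return An `annotation_set`. Attributes: `skipped_types` (named counts of
#'   unmapped row types), `n_missing_phase`.
#' @export
parse_gff3 <- function(path_or_text, feature_map = default_feature_map(),
                       source_name = NULL) {
  feature_map <- validate_feature_map(feature_map)
  is_text <- grepl("\n", path_or_text) || grepl("^##gff", path_or_text)
  if (is_text) {
    lines <- strsplit(path_or_text, "\n", fixed = TRUE)[[1]]
    origin <- ""
    if (is.null(source_name)) source_name <- "annotation"
  } else {
    if (!file.exists(path_or_text))
      stop_config("GFF3 file not found: ", path_or_text)
    lines <- readLines(path_or_text, warn = FALSE)
    origin <- path_or_text
    if (is.null(source_name))
      source_name <- sub("\\.(gff3?|gff)$", "", basename(path_or_text),
                         ignore.case = TRUE)
  }

  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- head(lines, fasta_at[1] - 1L)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lnos <- which(keep)

  gene_rows <- list(); tx_rows <- list(); cds_rows <- list()
  skipped <- integer(0)
  n_missing_phase <- 0L

  for (i in lnos) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop_data("GFF3 line ", i, ": expected 9 tab-separated columns")
    role <- feature_map[tolower(f[3])]
    if (is.na(role)) {
      nm <- tolower(f[3])
      skipped[nm] <- sum(skipped[nm], 1L, na.rm = TRUE)
      next
    }
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop_data("GFF3 line ", i, ": non-integer coordinate")
    if (start > end)
      stop_data("GFF3 line ", i, ": start > end (", start, " > ", end, ")")
    attrs <- parse_gff3_attributes(if (length(f) >= 9) f[9] else ".")
    row <- list(contig = f[1], start = start - 1L, end = end,
                strand = if (f[7] %in% c("+", "-")) f[7] else "+",
                phase = f[8], id = attrs$ID %||% NA_character_,
                parents = if (is.null(attrs$Parent)) character(0) else
                  strsplit(attrs$Parent, ",", fixed = TRUE)[[1]],
                line = i)
    if (role == "gene") gene_rows[[length(gene_rows) + 1L]] <- row
    else if (role == "transcript") tx_rows[[length(tx_rows) + 1L]] <- row
    else cds_rows[[length(cds_rows) + 1L]] <- row
  }

  gene_ids <- vapply(gene_rows, function(r) r$id %||% NA_character_, "")
  if (anyNA(gene_ids))
    stop_data("GFF3 line ", gene_rows[[which(is.na(gene_ids))[1]]]$line,
              ": gene row without ID attribute")
  if (anyDuplicated(gene_ids))
    stop_data("duplicate gene ID(s) in '", source_name, "': ",
              paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))

  # transcript table; synthesize genes for orphan transcripts
  tx_ids <- vapply(tx_rows, function(r) {
    r$id %||% stop_data("GFF3 line ", r$line, ": transcript row without ID attribute")
  }, "")
  if (anyDuplicated(tx_ids))
    stop_data("duplicate transcript ID(s) in '", source_name, "': ",
              paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))
  tx_parent <- vapply(seq_along(tx_rows), function(k) {
    p <- tx_rows[[k]]$parents
    if (length(p) == 0) paste0("gene:", tx_ids[k]) else p[1]
  }, "")
  synth <- setdiff(unique(tx_parent), gene_ids)
  all_gene_ids <- c(gene_ids, synth)

  # group CDS segments by parent transcript
  seg_by_tx <- new.env(parent = emptyenv())
  for (r in cds_rows) {
    if (length(r$parents) == 0)
      stop_data("GFF3 line ", r$line, ": CDS row without Parent attribute")
    ph <- suppressWarnings(as.integer(r$phase))
    if (is.na(ph)) { ph <- 0L; n_missing_phase <- n_missing_phase + 1L }
    for (p in r$parents) {
      if (!p %in% tx_ids)
        stop_data("GFF3 line ", r$line, ": CDS Parent '", p,
                  "' does not name a known transcript")
      seg_by_tx[[p]] <- rbind(seg_by_tx[[p]],
        data.frame(contig = r$contig, start = r$start, end = r$end,
                   strand = r$strand, phase = ph, stringsAsFactors = FALSE))
    }
  }
  if (n_missing_phase > 0)
    warning(n_missing_phase, " CDS row(s) without phase in '", source_name,
            "'; treated as phase 0", call. = FALSE)

  tx_models <- list()
  for (k in seq_along(tx_ids)) {
    segs <- seg_by_tx[[tx_ids[k]]]
    if (is.null(segs)) next  # transcript without CDS: cannot code, skip
    tx_models[[tx_ids[k]]] <- new_transcript_model(tx_ids[k], tx_parent[k], segs)
  }

  genes <- list()
  for (gid in all_gene_ids) {
    tx <- tx_models[vapply(tx_models, `[[`, "", "parent_gene_id") == gid]
    if (length(tx) == 0) next  # gene without coding transcript
    genes[[gid]] <- new_gene_model(gid, source_name, unname(tx))
  }

  out <- new_annotation_set(source_name, genes, origin_path = origin)
  attr(out, "skipped_types") <- skipped
  attr(out, "n_missing_phase") <- n_missing_phase
  out
}

# ---- genome FASTA -----------------------------------------------------------

#' Read a genome assembly FASTA
#'
#' Sequences are uppercased and any non-ACGT letter is replaced by `N`.
#' Contig ids are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_config("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(names(seqs)))
    stop_data("genome FASTA '", path, "': duplicated contig ids")
  if (any(!nzchar(seqs)))
    stop_data("genome FASTA '", path, "': empty sequence(s)")
  gsub("[^ACGT]", "N", seqs)
}

# ---- translation ------------------------------------------------------------

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(x))))
}

genetic_code <- function() {
  gc <- .consanno_env$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE  # standard code (table 1)
    .consanno_env$genetic_code <- gc
  }
  gc
}

#' Translate a CDS segment chain
#'
#' Concatenates the segments in genomic order, reverse-complements on the
#' minus strand, trims `phase` bases off the 5' end of the first
#' codon-relevant segment (genomically first on `+`, genomically last on `-`)
#' and translates with the standard genetic code. A trailing stop codon is
#' removed; any codon containing `N` translates to `X`. An in-frame internal
#' stop is retained as `*` in the returned string so the caller can flag and
#' exclude the record.
#'
#' @param segments data.frame of CDS segments (`contig`, `start`, `end`,
#'   `strand`, `phase`; 0-based half-open).
#' @param genome named character vector from [read_genome_fasta()].
#' @return Amino-acid string, or `NA_character_` (with a warning) if the
#'   spliced CDS is shorter than one codon after phase trimming.
#' @export
translate_cds <- function(segments, genome) {
  segments <- segments[order(segments$start), , drop = FALSE]
  contig <- segments$contig[1]
  if (!contig %in% names(genome))
    stop_data("translate_cds: unknown contig '", contig, "'")
  if (max(segments$end) > nchar(genome[[contig]]))
    stop_data("translate_cds: segment beyond end of contig '", contig, "'")
  chunks <- substring(genome[[contig]], segments$start + 1L, segments$end)
  strand <- segments$strand[1]
  if (strand == "-") {
    dna <- reverse_complement(paste(chunks, collapse = ""))
    phase <- segments$phase[nrow(segments)]
  } else {
    dna <- paste(chunks, collapse = "")
    phase <- segments$phase[1]
  }
  if (phase > 0) dna <- substring(dna, phase + 1L)
  n_codon <- nchar(dna) %/% 3L
  if (n_codon < 1L) {
    warning("spliced CDS shorter than one codon; skipped", call. = FALSE)
    return(NA_character_)
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(dna, starts, starts + 2L)
  aa <- genetic_code()[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
  if (aa[n_codon] == "*") aa <- aa[-n_codon]
  paste(aa, collapse = "")
}

# ---- proteome extraction ----------------------------------------------------

#' Extract the proteome and splice groups of an annotation set
#'
#' Translates every transcript. Protein ids are namespaced
#' `<source>|<gene>|<transcript>` so that they are globally unique across
#' pseudo-species. Isoforms whose translation contains an internal stop are
#' excluded (not truncated) and counted; a gene whose every isoform fails is
#' dropped entirely, since it could never enter the consensus.
#'
#' @param annotation an `annotation_set`.
#' @param genome named character vector from [read_genome_fasta()].
#' @return List with elements `proteins` (data.frame: `protein_id`,
#'   `source_name`, `gene_id`, `transcript_id`, `sequence`), `splice_groups`
#'   (named list, one entry per gene with >= 2 surviving isoforms, each a
#'   character vector of protein ids), `n_internal_stop`, `dropped_genes`.
#' @export
extract_proteome <- function(annotation, genome) {
  src <- annotation$source_name
  recs <- list(); splice <- list()
  n_stop <- 0L; dropped <- character(0)
  for (g in annotation$genes) {
    ids <- character(0)
    for (t in g$transcripts) {
      aa <- suppressWarnings(translate_cds(t$segments, genome))
      if (is.na(aa) || !nzchar(aa)) next
      if (grepl("*", aa, fixed = TRUE)) { n_stop <- n_stop + 1L; next }
      pid <- paste(src, g$gene_id, t$transcript_id, sep = "|")
      recs[[pid]] <- data.frame(protein_id = pid, source_name = src,
                                gene_id = g$gene_id,
                                transcript_id = t$transcript_id,
                                sequence = aa, stringsAsFactors = FALSE)
      ids <- c(ids, pid)
    }
    if (length(ids) == 0) {
      dropped <- c(dropped, g$gene_id)
      next
    }
    if (length(ids) >= 2) splice[[g$gene_id]] <- ids
  }
  if (length(dropped))
    warning("source '", src, "': ", length(dropped),
            " gene(s) with no translatable isoform dropped", call. = FALSE)
  proteins <- if (length(recs)) do.call(rbind, unname(recs)) else
    data.frame(protein_id = character(0), source_name = character(0),
               gene_id = character(0), transcript_id = character(0),
               sequence = character(0), stringsAsFactors = FALSE)
  rownames(proteins) <- NULL
  list(proteins = proteins, splice_groups = splice,
       n_internal_stop = n_stop, dropped_genes = dropped)
}

#' Write protein records as FASTA
#'
#' @param proteins data.frame as returned in `extract_proteome()$proteins`,
#'   or any data.frame with `protein_id` and `sequence` columns.
#' @param path output file.
#' @export
write_proteome_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$protein_id))
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Write a splice file (one gene per line, isoform ids joined by "; ")
#'
#' @param splice_groups named list of character vectors of protein ids.
#' @param path output file.
#' @export
write_splice_file <- function(splice_groups, path) {
  writeLines(vapply(splice_groups, paste, "", collapse = "; "), path)
  invisible(path)
}

#' Read a splice file written by [write_splice_file()]
#' @param path splice file.
#' @return Unnamed list of character vectors of protein ids.
#' @export
read_splice_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(l) strsplit(l, ";\\s*")[[1]])
}

# ---- GFF3 writing -----------------------------------------------------------

gff3_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x, fixed = TRUE), fixed = TRUE)

format_gene_rows <- function(g, gene_attrs, id_prefix = "") {
  gid <- paste0(id_prefix, g$gene_id)
  rows <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                  g$contig, g$source_name, g$start + 1L, g$end, g$strand,
                  paste0("ID=", gff3_escape(gid), gene_attrs))
  for (t in g$transcripts[order(names(g$transcripts))]) {
    tid <- paste0(id_prefix, t$transcript_id)
    segs <- t$segments
    rows <- c(rows,
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$contig, g$source_name, min(segs$start) + 1L, max(segs$end),
              g$strand, gff3_escape(tid), gff3_escape(gid)),
      sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
              segs$contig, g$source_name, segs$start + 1L, segs$end,
              segs$strand, segs$phase, gff3_escape(tid), gff3_escape(tid)))
  }
  rows
}

#' Write an annotation set as GFF3
#'
#' Genes are ordered by contig, start and id; output is deterministic.
#' Round trip: `parse_gff3(write_annotation_gff3(x))` reproduces the contigs,
#' strands, segment coordinates and gene/transcript hierarchy of `x`.
#'
#' @param annotation an `annotation_set`.
#' @param path output file, or `NULL` to return the text.
#' @return The GFF3 text, invisibly when `path` is given.
#' @export
write_annotation_gff3 <- function(annotation, path = NULL) {
  genes <- annotation$genes
  if (length(genes)) {
    ord <- order(vapply(genes, `[[`, "", "contig"),
                 vapply(genes, `[[`, 0L, "start"),
                 vapply(genes, `[[`, "", "gene_id"))
    genes <- genes[ord]
  }
  lines <- c("##gff-version 3",
             unlist(lapply(genes, format_gene_rows, gene_attrs = "")))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(lines, path)
  invisible(txt)
}

#' Write a consensus annotation as GFF3
#'
#' Each gene row carries provenance attributes `source_annotation=` (which
#' source supplied the representative model) and `support=` (the support
#' combination, e.g. `src1+src2` or `src3+outgroups`). Gene and transcript
#' ids are namespaced `<source>:<id>` to stay unique across sources.
#'
#' @param consensus a `consensus_annotation` (see [assemble_consensus()]).
#' @param genome_ids character vector of valid contig ids.
#' @param path output file, or `NULL` to return the text.
#' @return GFF3 text, invisibly when `path` is given.
#' @export
write_gff3 <- function(consensus, genome_ids, path = NULL) {
  stopifnot(inherits(consensus, "consensus_annotation"))
  cgs <- consensus$genes
  if (length(cgs)) {
    reps <- lapply(cgs, `[[`, "gene")
    bad <- setdiff(unique(vapply(reps, `[[`, "", "contig")), genome_ids)
    if (length(bad))
      stop_data("consensus references unknown contig(s): ",
                paste(bad, collapse = ", "))
    ord <- order(vapply(reps, `[[`, "", "contig"),
                 vapply(reps, `[[`, 0L, "start"),
                 vapply(reps, `[[`, "", "gene_id"))
    cgs <- cgs[ord]
  }
  body <- unlist(lapply(cgs, function(cg) {
    attrs <- paste0(";source_annotation=", gff3_escape(cg$source),
                    ";support=", gff3_escape(support_label(cg$support)))
    format_gene_rows(cg$gene, attrs, id_prefix = paste0(cg$source, ":"))
  }))
  lines <- c("##gff-version 3", body)
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(lines, path)
  invisible(txt)
}

# ---- structural comparison --------------------------------------------------

annotation_signature <- function(annotation) {
  sigs <- lapply(annotation$genes, function(g) {
    chains <- sort(vapply(g$transcripts, function(t) {
      paste0(t$segments$start, "-", t$segments$end, "(", t$segments$phase, ")",
             collapse = ",")
    }, ""))
    paste0(g$contig, g$strand, "|", paste(chains, collapse = ";"))
  })
  sort(unlist(sigs, use.names = FALSE))
}

#' Structural equality of two annotation sets
#'
#' Compares contigs, strands, CDS segment coordinates and phases, and the
#' grouping of transcripts into genes — ignoring identifiers and ordering.
#'
#' @param a,b `annotation_set` objects.
#' @return `TRUE` or `FALSE`.
#' @export
annotation_identical <- function(a, b) {
  identical(annotation_signature(a), annotation_signature(b))
}
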