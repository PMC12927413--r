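# Synthetic genome + annotation simulator with known ground truth.
#
# The generator writes real coding genes into a random background contig:
# every truth gene starts with ATG, ends with a stop codon and contains no
# in-frame internal stop; all CDS chunks are codon-aligned (phase 0).
# "Decoy" open reading frames — random proteins unrelated to the truth genes
# and to the outgroups — are placed in intergenic space at construction time
# so that corrupted source annotations can include false genes that are
# still real sequences on the shared genome.

#' Simulation configuration
#'
#' @param n_genes number of truth genes.
#' @param contig_length contig length in nt (default `6000 * n_genes`, enough
#'   for genes, introns, decoys and intergenic gaps).
#' @param isoform_rate fraction of genes with a second isoform (an internal
#'   CDS segment skipped, frame preserved).
#' @param drop_rate,false_rate,boundary_jitter_nt per-source corruption
#'   defaults used by [derive_source_annotation()].
#' @param outgroup_divergence per-residue substitution probability for
#'   [derive_outgroup_proteome()].
#' @param n_decoys size of the shared decoy ORF pool (default `n_genes`).
#' @param seed RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200, contig_length = 6000 * n_genes,
                              isoform_rate = 0.2, drop_rate = 0.2,
                              false_rate = 0.1, boundary_jitter_nt = 0,
                              outgroup_divergence = 0.1,
                              n_decoys = n_genes, seed = 1) {
  rates <- c(isoform_rate = isoform_rate, drop_rate = drop_rate,
             false_rate = false_rate, outgroup_divergence = outgroup_divergence)
  if (any(rates < 0 | rates > 1))
    stop_config("rates must lie in [0, 1]: ",
                paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  structure(list(n_genes = n_genes, contig_length = contig_length,
                 isoform_rate = isoform_rate, drop_rate = drop_rate,
                 false_rate = false_rate,
                 boundary_jitter_nt = boundary_jitter_nt,
                 outgroup_divergence = outgroup_divergence,
                 n_decoys = n_decoys, seed = seed),
            class = "simulation_config")
}

synonymous_codons <- function() {
  sc <- .consanno_env$syn_codons
  if (is.null(sc)) {
    gc <- genetic_code()
    sc <- split(names(gc), unname(gc))
    .consanno_env$syn_codons <- sc
  }
  sc
}

random_protein <- function(len) {
  paste(c("M", sample(setdiff(aa_alphabet(), c("X", "M")), len - 1,
                      replace = TRUE)), collapse = "")
}

back_translate <- function(protein) {
  sc <- synonymous_codons()
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(sc[res], function(x) x[sample.int(length(x), 1)], "")
  paste0(paste(codons, collapse = ""),
         sc[["*"]][sample.int(3, 1)])  # terminal stop
}

# split a CDS of `n_nt` nucleotides into k codon-aligned chunks, each >= 6 nt
split_codon_chunks <- function(n_nt, k) {
  n_codons <- n_nt %/% 3L
  if (k == 1 || n_codons < 2 * k) return(as.integer(n_nt))
  cuts <- sort(sample(seq(2L, n_codons - 2L), k - 1L))
  as.integer(diff(c(0L, cuts, n_codons)) * 3L)
}

#' Simulate a genome with a truth annotation
#'
#' Generates `n_genes` non-overlapping genes on one contig (`chr1`), with
#' random strands, codon-aligned multi-segment CDS, ATG starts, terminal
#' stops and no internal stops, plus a pool of decoy ORFs for use as false
#' predictions. Deterministic per seed.
#'
#' @param config a [simulation_config()].
#' @return Object of class `truth_set`: `genome` (named character vector),
#'   `truth` (`annotation_set`, source `"truth"`), `decoys`
#'   (`annotation_set`), `truth_proteins` / `decoy_proteins` (named
#'   character vectors, gene id -> protein), `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  has_isoform <- stats::runif(n) < config$isoform_rate

  units <- list()
  for (i in seq_len(n)) {
    len_aa <- sample(60:300, 1)
    prot <- random_protein(len_aa)
    cds <- back_translate(prot)
    k <- if (has_isoform[i]) sample(3:4, 1) else sample(1:4, 1)
    chunks <- split_codon_chunks(nchar(cds), k)
    units[[length(units) + 1L]] <- list(
      kind = "gene", gene_id = sprintf("tg%04d", i), protein = prot,
      cds = cds, chunks = chunks, isoform = has_isoform[i],
      strand = sample(c("+", "-"), 1))
  }
  for (i in seq_len(config$n_decoys)) {
    len_aa <- sample(60:300, 1)
    prot <- random_protein(len_aa)
    units[[length(units) + 1L]] <- list(
      kind = "decoy", gene_id = sprintf("fg%04d", i), protein = prot,
      cds = back_translate(prot), chunks = NULL, isoform = FALSE,
      strand = sample(c("+", "-"), 1))
  }
  units <- units[sample.int(length(units))]  # interleave genes and decoys

  contig <- sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE)
  cursor <- 0L
  truth_genes <- list(); decoy_genes <- list()
  truth_prot <- character(0); decoy_prot <- character(0)

  place_unit <- function(u, cursor) {
    chunks <- u$chunks %||% nchar(u$cds)
    k <- length(chunks)
    introns <- if (k > 1) sample(30:200, k - 1, replace = TRUE) else integer(0)
    gap <- sample(200:800, 1)
    start <- cursor + gap
    # genomic segment j holds transcript chunk j on '+', chunk k+1-j on '-'
    seg_len <- if (u$strand == "+") chunks else rev(chunks)
    segs <- data.frame(contig = "chr1", start = integer(k), end = integer(k),
                       strand = u$strand, phase = 0L, stringsAsFactors = FALSE)
    pos <- as.integer(start)
    for (j in seq_len(k)) {
      segs$start[j] <- pos; segs$end[j] <- pos + seg_len[j]
      pos <- segs$end[j] + if (j < k) introns[j] else 0L
    }
    if (pos > config$contig_length)
      stop_config("contig too short (", config$contig_length,
                  " nt) for the requested genes")
    # write CDS chunks into the contig; on '-' the transcript reads the
    # segments right-to-left, reverse-complemented
    offs <- cumsum(c(0L, chunks))
    for (j in seq_len(k)) {
      jj <- if (u$strand == "+") j else k + 1L - j
      chunk <- substring(u$cds, offs[j] + 1L, offs[j + 1L])
      piece <- if (u$strand == "+") chunk else reverse_complement(chunk)
      contig[(segs$start[jj] + 1L):segs$end[jj]] <<-
        strsplit(piece, "", fixed = TRUE)[[1]]
    }
    list(segs = segs, cursor = pos)
  }

  for (u in units) {
    placed <- place_unit(u, cursor)
    cursor <- placed$cursor
    segs <- placed$segs
    tid1 <- paste0(u$gene_id, "_t1")
    txs <- list(new_transcript_model(tid1, u$gene_id, segs))
    if (u$isoform && nrow(segs) >= 3) {
      drop_j <- sample(2:(nrow(segs) - 1L), 1)
      txs <- c(txs, list(new_transcript_model(
        paste0(u$gene_id, "_t2"), u$gene_id, segs[-drop_j, , drop = FALSE])))
    }
    gm <- new_gene_model(u$gene_id, if (u$kind == "gene") "truth" else "decoys",
                         txs)
    if (u$kind == "gene") {
      truth_genes[[u$gene_id]] <- gm
      truth_prot[u$gene_id] <- u$protein
    } else {
      decoy_genes[[u$gene_id]] <- gm
      decoy_prot[u$gene_id] <- u$protein
    }
  }

  genome <- setNames(paste(contig, collapse = ""), "chr1")
  structure(list(
    genome = genome,
    truth = new_annotation_set("truth", truth_genes),
    decoys = new_annotation_set("decoys", decoy_genes),
    truth_proteins = truth_prot[sort(names(truth_prot))],
    decoy_proteins = decoy_prot[sort(names(decoy_prot))],
    config = config
  ), class = "truth_set")
}

# trim a gene's terminal CDS boundaries in frame (trim-only jitter: the 5'
# trim removes whole codons incl. the start codon, the 3' trim removes the
# stop; either way the model still translates without internal stops)
jitter_gene <- function(gene, jitter_nt) {
  if (jitter_nt < 3) return(gene)
  max_codons <- jitter_nt %/% 3L
  t5 <- 3L * sample.int(max_codons + 1L, 1, replace = TRUE) - 3L
  t3 <- 3L * sample.int(max_codons + 1L, 1, replace = TRUE) - 3L
  gene$transcripts <- lapply(gene$transcripts, function(t) {
    segs <- t$segments
    k <- nrow(segs)
    if (segs$strand[1] == "+") {
      a5 <- min(t5, segs$end[1] - segs$start[1] - 3L)
      a3 <- min(t3, segs$end[k] - segs$start[k] - 3L)
      segs$start[1] <- segs$start[1] + max(a5, 0L)
      segs$end[k] <- segs$end[k] - max(a3, 0L)
    } else {
      a5 <- min(t5, segs$end[k] - segs$start[k] - 3L)
      a3 <- min(t3, segs$end[1] - segs$start[1] - 3L)
      segs$end[k] <- segs$end[k] - max(a5, 0L)
      segs$start[1] <- segs$start[1] + max(a3, 0L)
    }
    new_transcript_model(t$transcript_id, t$parent_gene_id, segs)
  })
  gene$start <- min(vapply(gene$transcripts, function(t) min(t$segments$start), 0L))
  gene$end <- max(vapply(gene$transcripts, function(t) max(t$segments$end), 0L))
  gene
}

#' Derive a corrupted source annotation from the truth
#'
#' Drops `floor(drop_rate * n)` random truth genes, adds
#' `floor(false_rate * n)` false genes drawn from the decoy pool, and jitters
#' terminal CDS boundaries by at most `boundary_jitter_nt` (frame-preserving,
#' trim-only; internal splice boundaries are never moved). Gene labels are
#' recorded in `attr(, "labels")`.
#'
#' @param truth_set a [simulate_truth()] result.
#' @param name source name (pseudo-species label).
#' @param drop_rate,false_rate,boundary_jitter_nt corruption parameters
#'   (default: the truth set's config).
#' @param seed RNG seed for this source.
#' @param decoy_ids decoy genes to use as false predictions; defaults to a
#'   random sample. Use [derive_sources()] to get disjoint decoys per source.
#' @return An `annotation_set` with attributes `labels` (data.frame
#'   `gene_id`/`label`, labels in `{true_kept, false}`) and `dropped`
#'   (character vector of dropped truth gene ids).
#' @export
derive_source_annotation <- function(truth_set, name,
                                     drop_rate = truth_set$config$drop_rate,
                                     false_rate = truth_set$config$false_rate,
                                     boundary_jitter_nt =
                                       truth_set$config$boundary_jitter_nt,
                                     seed = truth_set$config$seed + 1,
                                     decoy_ids = NULL) {
  if (drop_rate < 0 || drop_rate > 1 || false_rate < 0 || false_rate > 1)
    stop_config("drop_rate and false_rate must lie in [0, 1]")
  set.seed(seed)
  n <- length(truth_set$truth$genes)
  n_drop <- floor(drop_rate * n)
  n_false <- floor(false_rate * n)
  ids <- names(truth_set$truth$genes)
  dropped <- if (n_drop > 0) sort(sample(ids, n_drop)) else character(0)
  kept <- setdiff(ids, dropped)
  if (is.null(decoy_ids)) {
    pool <- names(truth_set$decoys$genes)
    if (n_false > length(pool))
      stop_config("decoy pool too small: need ", n_false, ", have ", length(pool))
    decoy_ids <- if (n_false > 0) sort(sample(pool, n_false)) else character(0)
  } else decoy_ids <- head(decoy_ids, n_false)

  genes <- list()
  for (g in kept) {
    gm <- truth_set$truth$genes[[g]]
    gm$source_name <- name
    genes[[g]] <- jitter_gene(gm, boundary_jitter_nt)
  }
  for (g in decoy_ids) {
    gm <- truth_set$decoys$genes[[g]]
    gm$source_name <- name
    genes[[g]] <- gm
  }
  out <- new_annotation_set(name, genes)
  attr(out, "labels") <- data.frame(
    gene_id = c(kept, decoy_ids),
    label = c(rep("true_kept", length(kept)), rep("false", length(decoy_ids))),
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Derive several source annotations with disjoint false genes
#'
#' Partitions the decoy pool so that no false gene is shared between two
#' sources (a shared false gene would legitimately pass the two-source
#' retention rule and is not what "independent false predictions" means).
#'
#' @param truth_set a [simulate_truth()] result.
#' @param source_names character vector of source names.
#' @param drop_rate,false_rate,boundary_jitter_nt,seed see
#'   [derive_source_annotation()].
#' @return Named list of `annotation_set`s.
#' @export
derive_sources <- function(truth_set, source_names,
                           drop_rate = truth_set$config$drop_rate,
                           false_rate = truth_set$config$false_rate,
                           boundary_jitter_nt =
                             truth_set$config$boundary_jitter_nt,
                           seed = truth_set$config$seed + 1) {
  n <- length(truth_set$truth$genes)
  n_false <- floor(false_rate * n)
  set.seed(seed)
  pool <- names(truth_set$decoys$genes)
  if (n_false * length(source_names) > length(pool))
    stop_config("decoy pool too small for ", length(source_names),
                " sources with ", n_false, " false genes each")
  shuffled <- sample(pool)
  out <- list()
  for (i in seq_along(source_names)) {
    take <- shuffled[seq_len(n_false) + (i - 1L) * n_false]
    out[[source_names[i]]] <- derive_source_annotation(
      truth_set, source_names[i], drop_rate, false_rate, boundary_jitter_nt,
      seed = seed + i, decoy_ids = sort(take))
  }
  out
}

#' Derive a diverged outgroup proteome
#'
#' One protein per truth gene (from the full-length isoform); each residue is
#' substituted independently with probability `divergence`, uniformly over
#' the 19 other residues. The truth-gene to outgroup-protein map is returned
#' alongside.
#'
#' @param truth_set a [simulate_truth()] result.
#' @param divergence per-residue substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param name outgroup species name (protein ids are `<name>_<gene>`).
#' @return List with `proteins` (data.frame usable in [protein_database()])
#'   and `map` (data.frame `truth_gene` / `outgroup_protein`).
#' @export
derive_outgroup_proteome <- function(truth_set,
                                     divergence =
                                       truth_set$config$outgroup_divergence,
                                     seed = truth_set$config$seed + 100,
                                     name = "outgroup") {
  set.seed(seed)
  aa20 <- setdiff(aa_alphabet(), "X")
  seqs <- vapply(truth_set$truth_proteins, function(p) {
    res <- strsplit(p, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(res)) < divergence)
    for (k in hit)
      res[k] <- sample(setdiff(aa20, res[k]), 1)
    paste(res, collapse = "")
  }, "")
  ids <- paste0(name, "_", names(seqs))
  list(proteins = data.frame(protein_id = ids, gene_id = ids,
                             sequence = unname(seqs),
                             stringsAsFactors = FALSE),
       map = data.frame(truth_gene = names(seqs), outgroup_protein = ids,
                        stringsAsFactors = FALSE),
       splice_groups = list())
}

#' The canonical six-prediction demonstration fixture
#'
#' Three source annotations over six genes: genes 1-4 are each predicted by
#' at least two sources, gene 5 by a single source but with an ortholog in
#' the outgroup species, and gene 6 by a single source with no ortholog
#' anywhere. The expected consensus is therefore genes 1-5 (four retained as
#' multi-source, one as single-source-plus-outgroup) and gene 6 is dropped.
#'
#' @param seed RNG seed.
#' @return List with `genome`, `sources` (named list of `annotation_set`s),
#'   `outgroups` (named list of proteome entries), `tree` (Newick text),
#'   `expected_consensus` / `expected_dropped` (gene ids), `truth_set`.
#' @export
figure_fixture <- function(seed = 42) {
  cfg <- simulation_config(n_genes = 6, contig_length = 80000,
                           isoform_rate = 0, n_decoys = 0, seed = seed)
  ts <- simulate_truth(cfg)
  ids <- sort(names(ts$truth$genes))  # tg0001..tg0006
  pick <- function(name, idx) {
    genes <- ts$truth$genes[ids[idx]]
    genes <- lapply(genes, function(g) { g$source_name <- name; g })
    new_annotation_set(name, genes)
  }
  sources <- list(src1 = pick("src1", c(1, 2, 3, 5)),
                  src2 = pick("src2", c(1, 2, 4, 6)),
                  src3 = pick("src3", c(2, 3, 4)))
  og <- derive_outgroup_proteome(ts, divergence = 0.05, seed = seed + 7,
                                 name = "outA")
  keep <- og$map$truth_gene %in% ids[c(1, 2, 3, 5)]
  og$proteins <- og$proteins[keep, , drop = FALSE]
  og$map <- og$map[keep, , drop = FALSE]
  list(genome = ts$genome, sources = sources,
       outgroups = list(outA = og),
       tree = "((src1,src2,src3)consensus,outA)root;",
       expected_consensus = ids[1:5], expected_dropped = ids[6],
       truth_set = ts)
}

#' Write a simulated world to a directory
#'
#' Writes `genome.fasta`, `truth.gff3`, one GFF3 per source, one protein
#' FASTA per outgroup, and `truth_tables.tsv` (per-source gene labels).
#'
#' @param truth_set a [simulate_truth()] result.
#' @param sources named list from [derive_sources()].
#' @param outgroups named list from [derive_outgroup_proteome()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(truth_set, sources, outgroups, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dna <- Biostrings::DNAStringSet(truth_set$genome)
  Biostrings::writeXStringSet(dna, file.path(out_dir, "genome.fasta"))
  write_annotation_gff3(truth_set$truth, file.path(out_dir, "truth.gff3"))
  for (nm in names(sources))
    write_annotation_gff3(sources[[nm]], file.path(out_dir, paste0(nm, ".gff3")))
  for (nm in names(outgroups))
    write_proteome_fasta(outgroups[[nm]]$proteins,
                         file.path(out_dir, paste0(nm, ".faa")))
  tabs <- do.call(rbind, lapply(names(sources), function(nm) {
    lb <- attr(sources[[nm]], "labels")
    lb$source <- nm
    lb
  }))
  write.table(tabs, file.path(out_dir, "truth_tables.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
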