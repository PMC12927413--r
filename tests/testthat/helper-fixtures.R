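# Small in-code fixtures shared across test files.

# three genes on two contigs; g2 has two mRNAs (isoforms)
three_gene_gff3 <- function() {
  paste(
    "##gff-version 3",
    "chr1\ttest\tgene\t11\t100\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t11\t100\t.\t+\t.\tID=g1t1;Parent=g1",
    "chr1\ttest\tCDS\t11\t40\t.\t+\t0\tID=c1;Parent=g1t1",
    "chr1\ttest\tCDS\t61\t100\t.\t+\t0\tID=c1;Parent=g1t1",
    "chr1\ttest\tgene\t201\t400\t.\t-\t.\tID=g2",
    "chr1\ttest\tmRNA\t201\t400\t.\t-\t.\tID=g2t1;Parent=g2",
    "chr1\ttest\tCDS\t201\t260\t.\t-\t0\tID=c2;Parent=g2t1",
    "chr1\ttest\tCDS\t301\t400\t.\t-\t1\tID=c2;Parent=g2t1",
    "chr1\ttest\tmRNA\t201\t400\t.\t-\t.\tID=g2t2;Parent=g2",
    "chr1\ttest\tCDS\t301\t400\t.\t-\t1\tID=c3;Parent=g2t2",
    "chr2\ttest\tgene\t51\t80\t.\t+\t.\tID=g3",
    "chr2\ttest\tmRNA\t51\t80\t.\t+\t.\tID=g3t1;Parent=g3",
    "chr2\ttest\tCDS\t51\t80\t.\t+\t0\tID=c4;Parent=g3t1",
    sep = "\n")
}

# one-transcript annotation_set built directly from segment coordinates
toy_annotation <- function(source, genes) {
  # genes: list of list(id, contig, strand, segs = list(c(start, end)), tx2)
  gm <- lapply(genes, function(g) {
    segs <- do.call(rbind, lapply(g$segs, function(se)
      data.frame(contig = g$contig, start = se[1], end = se[2],
                 strand = g$strand, phase = 0L)))
    txs <- list(new_transcript_model(paste0(g$id, "_t1"), g$id, segs))
    if (!is.null(g$tx2)) {
      segs2 <- do.call(rbind, lapply(g$tx2, function(se)
        data.frame(contig = g$contig, start = se[1], end = se[2],
                   strand = g$strand, phase = 0L)))
      txs <- c(txs, list(new_transcript_model(paste0(g$id, "_t2"), g$id, segs2)))
    }
    new_gene_model(g$id, source, txs)
  })
  new_annotation_set(source, gm)
}

# deterministic small truth world for structural tests
small_truth <- function(seed = 5, n = 12, isoform_rate = 0.3) {
  simulate_truth(simulation_config(n_genes = n, contig_length = 8000 * n,
                                   isoform_rate = isoform_rate,
                                   n_decoys = n, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built hog_forest over an arbitrary species_tree
hand_forest <- function(hogs_spec, tree) {
  # hogs_spec: list of list(id, node, members = data.frame, children, parent)
  hogs <- lapply(hogs_spec, function(h) {
    h$children <- h$children %||% character(0)
    h$parent <- h$parent %||% NA_character_
    h
  })
  consanno:::new_hog_forest(hogs, tree)
}

# minimal orthoXML builder
orthoxml_text <- function(species_genes, groups_xml) {
  # species_genes: named list species -> data.frame(id, protId)
  sp <- paste(vapply(names(species_genes), function(nm) {
    g <- species_genes[[nm]]
    paste0('<species name="', nm, '" NCBITaxId="0"><database name="db" version="1"><genes>',
           paste(sprintf('<gene id="%s" protId="%s"/>', g$id, g$protId),
                 collapse = ""),
           "</genes></database></species>")
  }, ""), collapse = "\n")
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="test" originVersion="1">\n',
         sp, "\n<groups>\n", groups_xml, "\n</groups>\n</orthoXML>\n")
}
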