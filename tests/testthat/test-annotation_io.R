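test_that("parse_gff3 handles empty input and custom feature-type maps", {
  expect_length(parse_gff3("##gff-version 3\n")$genes, 0)

  # nonstandard feature names, resolved through the map (case-insensitive)
  txt <- paste(
    "##gff-version 3",
    "c1\tx\tlocus\t1\t60\t.\t+\t.\tID=gA",
    "c1\tx\tmRNA_region\t1\t60\t.\t+\t.\tID=tA;Parent=gA",
    "c1\tx\tcoding\t1\t30\t.\t+\t0\tID=cA;Parent=tA",
    "c1\tx\tCODING\t41\t60\t.\t+\t0\tID=cA;Parent=tA",
    "c1\tx\tignored_thing\t1\t60\t.\t+\t.\tID=zz",
    sep = "\n")
  map <- c(locus = "gene", mRNA_region = "transcript", coding = "cds")
  ann <- parse_gff3(txt, map)
  expect_length(ann$genes, 1)
  tx <- ann$genes$gA$transcripts
  expect_length(tx, 1)
  expect_equal(nrow(tx$tA$segments), 2)
  expect_equal(tx$tA$cds_length, 50L)
  expect_equal(attr(ann, "skipped_types"), c(ignored_thing = 1L))
})

test_that("parse_gff3 reads the 3-gene fixture with correct hierarchy", {
  ann <- parse_gff3(three_gene_gff3())
  expect_length(ann$genes, 3)
  iso <- vapply(ann$genes, function(g) length(g$transcripts), 0L)
  expect_equal(iso[c("g1", "g2", "g3")], c(g1 = 1L, g2 = 2L, g3 = 1L))
  # GFF3 1-based inclusive -> internal 0-based half-open
  expect_equal(ann$genes$g1$transcripts$g1t1$segments$start, c(10L, 60L))
  expect_equal(ann$genes$g1$transcripts$g1t1$segments$end, c(40L, 100L))
  expect_equal(ann$genes$g2$strand, "-")
})

test_that("parse_gff3 rejects malformed and inconsistent input", {
  bad_coord <- "##gff-version 3\nc1\tx\tgene\t50\t10\t.\t+\t.\tID=g1\n"
  expect_error(parse_gff3(bad_coord), "line 2.*start > end",
               class = "consanno_data_error")
  bad_int <- "##gff-version 3\nc1\tx\tgene\tten\t20\t.\t+\t.\tID=g1\n"
  expect_error(parse_gff3(bad_int), "line 2.*non-integer",
               class = "consanno_data_error")
  orphan_cds <- paste(
    "##gff-version 3",
    "c1\tx\tgene\t1\t60\t.\t+\t.\tID=g1",
    "c1\tx\tmRNA\t1\t60\t.\t+\t.\tID=t1;Parent=g1",
    "c1\tx\tCDS\t1\t30\t.\t+\t0\tID=c;Parent=tX", sep = "\n")
  expect_error(parse_gff3(orphan_cds), "tX", class = "consanno_data_error")
  dup <- paste(
    "##gff-version 3",
    "c1\tx\tgene\t1\t60\t.\t+\t.\tID=g1",
    "c1\tx\tgene\t100\t160\t.\t+\t.\tID=g1", sep = "\n")
  expect_error(parse_gff3(dup), "duplicate gene", class = "consanno_data_error")
})

test_that("two-level GFF3 gets synthetic genes; missing phase warns", {
  txt <- paste(
    "##gff-version 3",
    "c1\tx\tmRNA\t1\t30\t.\t+\t.\tID=t1",
    "c1\tx\tCDS\t1\t30\t.\t+\t.\tID=c;Parent=t1", sep = "\n")
  expect_warning(ann <- parse_gff3(txt), "phase")
  expect_named(ann$genes, "gene:t1")
  expect_equal(ann$genes[["gene:t1"]]$transcripts$t1$segments$phase, 0L)
})

test_that("feature map validation enforces roles and uniqueness", {
  expect_error(consanno:::validate_feature_map(c(gene = "gene", mrna = "transcript")),
               "cds", class = "consanno_data_error")
  expect_error(
    consanno:::validate_feature_map(
      c(gene = "gene", gene = "cds", mrna = "transcript", cds = "cds")),
    "two roles", class = "consanno_data_error")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("locus\tgene\nmRNA_region\ttranscript\ncoding\tcds", tf)
  map <- read_feature_map(tf)
  expect_equal(unname(map[c("locus", "mrna_region", "coding")]),
               c("gene", "transcript", "cds"))
})

test_that("translate_cds follows strand, phase, fuzzy and stop rules", {
  expect_equal(translate_cds(
    data.frame(contig = "c", start = 0L, end = 9L, strand = "+", phase = 0L),
    c(c = "ATGAAATAA")), "MK")
  expect_equal(translate_cds(
    data.frame(contig = "c", start = 0L, end = 9L, strand = "-", phase = 0L),
    c(c = "TCAGGCCAT")), "MA")
  # spliced: "ATGG" + "AAAAA" reads ATG GAA AAA
  segs <- data.frame(contig = "c", start = c(0L, 7L), end = c(4L, 12L),
                     strand = "+", phase = 0L)
  g <- c(c = "ATGGCCCAAAAA")
  expect_equal(translate_cds(segs, g), oracle_translate(segs, g))
  expect_equal(translate_cds(segs, g), "MEK")
  # phase trimming on '+': phase 1 drops the first base
  expect_equal(translate_cds(
    data.frame(contig = "c", start = 0L, end = 7L, strand = "+", phase = 1L),
    c(c = "GATGAAAT")), "MK")
  # phase on '-': trimming applies to the transcription-first (rightmost) segment
  expect_equal(translate_cds(
    data.frame(contig = "c", start = 0L, end = 7L, strand = "-", phase = 1L),
    c(c = "TTTCATCA")), "MK")
  # codon containing N -> X; internal stop kept as '*' for the caller
  expect_equal(translate_cds(
    data.frame(contig = "c", start = 0L, end = 9L, strand = "+", phase = 0L),
    c(c = "ATGANAAAA")), "MXK")
  expect_equal(translate_cds(
    data.frame(contig = "c", start = 0L, end = 9L, strand = "+", phase = 0L),
    c(c = "ATGTAAAAA")), "M*K")
  expect_warning(short <- translate_cds(
    data.frame(contig = "c", start = 0L, end = 2L, strand = "+", phase = 1L),
    c(c = "ATG")), "shorter")
  expect_true(is.na(short))
})

test_that("translate_cds agrees with the naive oracle on random transcripts", {
  set.seed(421)
  for (k in 1:60) {
    cs <- random_transcript_case()
    expect_identical(
      suppressWarnings(translate_cds(cs$segments, cs$genome)),
      suppressWarnings({
        o <- oracle_translate(cs$segments, cs$genome)
        if (nchar(o) == 0) NA_character_ else o
      }),
      info = paste("case", k))
  }
})

test_that("extract_proteome builds records and splice groups, excludes stops", {
  # gene 'a' with 2 clean isoforms, gene 'b' with one clean + one internal
  # stop, gene 'c' whose only isoform has an internal stop
  genome <- c(c1 = paste0(
    "ATGAAACCCGGGTAA",      # a: 0..15  (MKPG)
    "ATGTAACCCGGGTAA",      # b-bad uses 15..30 (M*PG); b-good skips stop codon
    "ATGTGATAA"))           # c: 30..39 (M*)
  a <- new_gene_model("a", "s", list(
    new_transcript_model("a_t1", "a", data.frame(
      contig = "c1", start = 0L, end = 15L, strand = "+", phase = 0L)),
    new_transcript_model("a_t2", "a", data.frame(
      contig = "c1", start = c(0L, 9L), end = c(6L, 15L), strand = "+", phase = 0L))))
  b <- new_gene_model("b", "s", list(
    new_transcript_model("b_bad", "b", data.frame(
      contig = "c1", start = 15L, end = 30L, strand = "+", phase = 0L)),
    new_transcript_model("b_good", "b", data.frame(
      contig = "c1", start = c(15L, 21L), end = c(18L, 30L), strand = "+", phase = 0L))))
  cc <- new_gene_model("c", "s", list(
    new_transcript_model("c_t1", "c", data.frame(
      contig = "c1", start = 30L, end = 39L, strand = "+", phase = 0L))))
  ann <- new_annotation_set("s", list(a, b, cc))
  expect_warning(ex <- extract_proteome(ann, genome), "dropped")
  expect_equal(sort(ex$proteins$transcript_id), c("a_t1", "a_t2", "b_good"))
  expect_named(ex$splice_groups, "a")
  expect_length(ex$splice_groups$a, 2)
  expect_equal(ex$n_internal_stop, 2L)
  expect_equal(ex$dropped_genes, "c")
  # protein ids are namespaced source|gene|transcript
  expect_true(all(grepl("^s\\|", ex$proteins$protein_id)))
  # conservation: isoforms == records + internal-stop exclusions (c dropped
  # contributes its failed isoform to the exclusion count)
  n_iso <- sum(vapply(ann$genes, function(g) length(g$transcripts), 0L))
  expect_equal(n_iso, nrow(ex$proteins) + ex$n_internal_stop)
})

test_that("GFF3 writing is 1-based, deterministic, and round-trips", {
  # empty consensus -> header only
  empty <- structure(list(genes = list(), metadata = list(sources = character(0))),
                     class = "consensus_annotation")
  expect_equal(write_gff3(empty, "c1"), "##gff-version 3\n")

  # internal (4,10),(14,20) -> GFF3 rows "5 10" and "15 20"
  ann <- toy_annotation("s", list(list(id = "g", contig = "c1", strand = "+",
                                       segs = list(c(4L, 10L), c(14L, 20L)))))
  txt <- write_annotation_gff3(ann)
  cds <- grep("\tCDS\t", strsplit(txt, "\n")[[1]], value = TRUE)
  expect_equal(vapply(strsplit(cds, "\t"), function(f) paste(f[4], f[5]), ""),
               c("5 10", "15 20"))

  # round-trip of the 3-gene fixture
  ann3 <- parse_gff3(three_gene_gff3())
  back <- parse_gff3(write_annotation_gff3(ann3), source_name = ann3$source_name)
  expect_true(annotation_identical(ann3, back))

  # unknown contig in a consensus is refused
  cg <- list(hog_id = "H1", gene = ann$genes$g, source = "s",
             support = structure(list(hog_id = "H1",
                                      sources = c(s = TRUE, s2 = FALSE),
                                      outgroups = logical(0),
                                      members = data.frame(species = "s",
                                                           gene_id = "g")),
                                 class = "support_record"))
  cons <- structure(list(genes = list(cg), metadata = list(sources = c("s", "s2"))),
                    class = "consensus_annotation")
  expect_error(write_gff3(cons, "other_contig"), "unknown contig",
               class = "consanno_data_error")
  # provenance attributes on gene rows
  out <- write_gff3(cons, "c1")
  expect_match(out, "source_annotation=s;support=s")
})

test_that("splice file round-trips", {
  groups <- list(g1 = c("s|g1|t1", "s|g1|t2"), g2 = c("s|g2|t1", "s|g2|t2", "s|g2|t3"))
  tf <- withr::local_tempfile()
  write_splice_file(groups, tf)
  expect_equal(readLines(tf)[1], "s|g1|t1; s|g1|t2")
  expect_equal(read_splice_file(tf), unname(groups))
})

test_that("structural round-trip holds for random synthetic annotations", {
  for (seed in c(31, 32, 33)) {
    ts <- small_truth(seed = seed)
    for (ann in list(ts$truth,
                     derive_source_annotation(ts, "sA", 0.25, 0.2, 9, seed = seed + 50))) {
      back <- parse_gff3(write_annotation_gff3(ann), source_name = ann$source_name)
      expect_true(annotation_identical(ann, back), info = paste("seed", seed))
    }
  }
})
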