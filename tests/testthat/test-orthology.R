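test_that("smith_waterman_score matches its documented examples", {
  expect_equal(smith_waterman_score("MKV", "MKV"), 14L)  # 5 + 5 + 4
  expect_equal(smith_waterman_score("MKV", ""), 0L)
  expect_equal(smith_waterman_score("AAAMKVAAA", "MKV"), 14L)  # local ignores flanks
  expect_equal(smith_waterman_score("XXXX", "MKVA"), 0L)       # X scores 0
})

test_that("smith_waterman_score equals the brute-force DP and is symmetric", {
  set.seed(201)
  ab20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (k in 1:40) {
    a <- paste(sample(ab20, sample(1:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(ab20, sample(1:30, 1), replace = TRUE), collapse = "")
    s <- smith_waterman_score(a, b)
    expect_identical(s, oracle_sw(a, b), info = paste(a, b))
    expect_identical(s, smith_waterman_score(b, a))
  }
  # gapped case exercised explicitly (vertical + horizontal gap states)
  a <- "MKVAAAAAWCD"; b <- "MKVWCD"
  expect_identical(smith_waterman_score(a, b), oracle_sw(a, b))
})

test_that("select_main_isoform prefers summed homolog score, then length, then id", {
  prot <- data.frame(protein_id = c("p|g|tA", "p|g|tB"),
                     transcript_id = c("tA", "tB"),
                     sequence = c(strrep("A", 90), strrep("A", 120)),
                     stringsAsFactors = FALSE)
  hits <- data.frame(query_id = c("p|g|tA", "p|g|tA", "p|g|tB"),
                     score = c(20, 10, 20), stringsAsFactors = FALSE)
  expect_equal(select_main_isoform(prot, hits)$transcript_id, "tA")  # 30 > 20
  no_hits <- hits[0, ]
  expect_equal(select_main_isoform(prot, no_hits)$transcript_id, "tB")  # longest
  tie <- data.frame(query_id = c("p|g|tA", "p|g|tB"), score = c(25, 25))
  expect_equal(select_main_isoform(prot, tie)$transcript_id, "tA")  # lexicographic
  expect_error(select_main_isoform(prot[0, ], hits), class = "consanno_data_error")
})

make_db <- function(...) {
  sp <- list(...)
  protein_database(lapply(sp, function(seqs) list(
    proteins = data.frame(protein_id = paste0(names(seqs), "_p"),
                          gene_id = names(seqs), sequence = unname(seqs),
                          stringsAsFactors = FALSE),
    splice_groups = list())))
}

test_that("infer_ortholog_pairs finds reciprocal best hits with thresholds", {
  p <- "MKVLIDAWCGHERTYPQNSFMKVLIDAWCG"  # 30 aa, self-score far above 100
  db <- make_db(sp1 = c(gA = p), sp2 = c(gB = p))
  pairs <- infer_ortholog_pairs(db)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gene_a, "gA")
  expect_equal(pairs$gene_b, "gB")

  # best score below min_score: no pair (spec case at min_score = 40)
  weak <- make_db(sp1 = c(gA = "MKV"), sp2 = c(gB = "MKV"))  # score 14
  expect_equal(nrow(infer_ortholog_pairs(weak, engine_options(min_score = 40))), 0)

  # 2x2: A1~B1, A2~B2, cross-similarity lower -> exactly the two pairs,
  # verified against exhaustive oracle scoring
  a1 <- "MKVLIDAWCGHERTYPQNSFAAAAAAAAAA"; a2 <- "WWCCHHRRKKEEDDNNQQSSTTYYFFPPGG"
  b1 <- sub("^MKV", "MRV", a1); b2 <- sub("GG$", "GA", a2)
  db2 <- make_db(sp1 = c(g1 = a1, g2 = a2), sp2 = c(h1 = b1, h2 = b2))
  pairs2 <- infer_ortholog_pairs(db2)
  expect_setequal(paste(pairs2$gene_a, pairs2$gene_b),
                  c("g1 h1", "g2 h2"))
  sc <- outer(c(g1 = a1, g2 = a2), c(h1 = b1, h2 = b2),
              Vectorize(function(x, y) oracle_sw(x, y)))
  expect_true(sc["g1", "h1"] == max(sc[, "h1"]) && sc["g1", "h1"] == max(sc["g1", ]))
  expect_true(sc["g2", "h2"] == max(sc[, "h2"]) && sc["g2", "h2"] == max(sc["g2", ]))

  # symmetry: species order does not change the unordered pair set
  db2r <- protein_database(rev(db2$species))
  pairs2r <- infer_ortholog_pairs(db2r)
  expect_setequal(paste(pairs2$gene_a, pairs2$gene_b),
                  paste(pairs2r$gene_a, pairs2r$gene_b))
})

test_that("main-isoform selection feeds gene-level RBH", {
  # gene gA has a short and a long isoform; the short one matches sp2,
  # so it must be chosen as main despite being shorter
  short <- "MKVLIDAWCGHERTYPQNSF"
  long <- paste0("M", strrep("G", 39))
  db <- protein_database(list(
    sp1 = list(proteins = data.frame(
      protein_id = c("sp1|gA|t1", "sp1|gA|t2"),
      gene_id = "gA", transcript_id = c("t1", "t2"),
      sequence = c(long, paste0(short, short)), stringsAsFactors = FALSE),
      splice_groups = list(gA = c("sp1|gA|t1", "sp1|gA|t2"))),
    sp2 = list(proteins = data.frame(
      protein_id = "sp2|gB|t1", gene_id = "gB", transcript_id = "t1",
      sequence = paste0(short, short), stringsAsFactors = FALSE),
      splice_groups = list())))
  pairs <- infer_ortholog_pairs(db)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$protein_a, "sp1|gA|t2")
})

test_that("build_hogs groups by connected components along the tree", {
  tree <- read_species_tree("((s1,s2,s3)consensus,outA)root;", c("s1", "s2", "s3"))
  mkpairs <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(species_a = r[1], gene_a = r[2], protein_a = r[2],
                 species_b = r[3], gene_b = r[4], protein_b = r[4],
                 score = 500, stringsAsFactors = FALSE)))
  }
  db <- protein_database(list(
    s1 = list(proteins = data.frame(protein_id = "g1", gene_id = "g1",
                                    sequence = "M"), splice_groups = list()),
    s2 = list(proteins = data.frame(protein_id = "g1p", gene_id = "g1p",
                                    sequence = "M"), splice_groups = list()),
    s3 = list(proteins = data.frame(protein_id = "g5", gene_id = "g5",
                                    sequence = "M"), splice_groups = list()),
    outA = list(proteins = data.frame(protein_id = "h", gene_id = "h",
                                      sequence = "M"), splice_groups = list())))

  # one cross-source pair -> a 2-member HOG at the consensus node
  f1 <- build_hogs(mkpairs(c("s1", "g1", "s2", "g1p")), tree, db)
  cons <- f1$by_node[[as.character(tree$consensus_node)]]
  sizes <- vapply(cons, function(id) nrow(f1$hogs[[id]]$members), 0L)
  expect_setequal(sizes, c(2L, 1L))  # {g1, g1p} and singleton g5

  # source-outgroup pair: singleton at the consensus node, co-members at root
  f2 <- build_hogs(mkpairs(c("s3", "g5", "outA", "h")), tree, db)
  cons2 <- f2$by_node[[as.character(tree$consensus_node)]]
  g5_hog <- Filter(function(id) "g5" %in% f2$hogs[[id]]$members$gene_id, cons2)
  expect_length(g5_hog, 1)
  expect_equal(nrow(f2$hogs[[g5_hog[[1]]]]$members), 1)
  root_hog <- f2$hogs[[f2$hogs[[g5_hog[[1]]]]$parent]]
  expect_setequal(root_hog$members$gene_id, c("g5", "h"))

  # no pairs: every gene is its own HOG at every ancestral node
  f3 <- build_hogs(mkpairs(c("s1", "g1", "s2", "g1p"))[0, ], tree, db)
  for (n in as.character(c(tree$consensus_node, ape::Ntip(tree$phylo) + 1L))) {
    sizes <- vapply(f3$by_node[[n]], function(id) nrow(f3$hogs[[id]]$members), 0L)
    expect_true(all(sizes == 1L))
  }

  expect_error(build_hogs(mkpairs(c("s1", "g1", "nope", "x")), tree, db),
               "unknown species", class = "consanno_data_error")
})

test_that("HOG forests satisfy nesting and partition invariants", {
  set.seed(77)
  ts <- small_truth(seed = 7, n = 15)
  srcs <- derive_sources(ts, c("s1", "s2"), drop_rate = 0.2, false_rate = 0.2,
                         boundary_jitter_nt = 0, seed = 70)
  og <- derive_outgroup_proteome(ts, 0.1, seed = 71, name = "outA")
  tree <- read_species_tree("((s1,s2)consensus,outA)root;", c("s1", "s2"))
  db <- consanno:::build_database(srcs, ts$genome, list(outA = og))
  forest <- build_hogs(infer_ortholog_pairs(db), tree, db)

  keyed <- function(m) paste(m$species, m$gene_id)
  for (h in forest$hogs) {
    # members drawn only from species under the attached node
    under <- tree$phylo$tip.label[intersect(
      consanno:::subtree_nodes(tree, h$node), seq_len(ape::Ntip(tree$phylo)))]
    expect_true(all(h$members$species %in% under))
    # nesting: child members are subsets of parent members
    if (!is.na(h$parent))
      expect_true(all(keyed(h$members) %in% keyed(forest$hogs[[h$parent]]$members)))
  }
  # partition at each node
  for (n in names(forest$by_node)) {
    all_members <- unlist(lapply(forest$by_node[[n]],
                                 function(id) keyed(forest$hogs[[id]]$members)))
    expect_false(anyDuplicated(all_members) > 0)
  }
})

test_that("zero-divergence copies give one gene per source per HOG", {
  ts <- small_truth(seed = 9, n = 10, isoform_rate = 0)
  srcs <- derive_sources(ts, c("s1", "s2", "s3"), drop_rate = 0,
                         false_rate = 0, boundary_jitter_nt = 0, seed = 90)
  tree <- read_species_tree("(s1,s2,s3)consensus;", c("s1", "s2", "s3"))
  db <- consanno:::build_database(srcs, ts$genome, list())
  forest <- build_hogs(infer_ortholog_pairs(db), tree, db)
  cons <- forest$by_node[[as.character(tree$consensus_node)]]
  expect_length(cons, 10)
  for (id in cons) {
    m <- forest$hogs[[id]]$members
    expect_equal(sort(m$species), c("s1", "s2", "s3"))
    expect_equal(length(unique(m$gene_id)), 1)
  }
})

test_that("read_orthoxml parses flat and nested groups and validates ids", {
  tree <- read_species_tree("((s1,s2)consensus,outA)root;", c("s1", "s2"))
  sg <- list(s1 = data.frame(id = "1", protId = "s1|gA|t1"),
             s2 = data.frame(id = "2", protId = "s2|gB|t1"))

  flat <- orthoxml_text(sg, '<orthologGroup id="og1">
    <geneRef id="1"/><geneRef id="2"/></orthologGroup>')
  tf <- withr::local_tempfile(fileext = ".orthoxml"); writeLines(flat, tf)
  forest <- read_orthoxml(tf, tree)
  cons <- forest$by_node[[as.character(tree$consensus_node)]]
  expect_length(cons, 1)
  expect_setequal(forest$hogs[[cons[[1]]]]$members$gene_id, c("gA", "gB"))

  # nested: root group of 6 with two consensus-level subgroups of 3
  sg6 <- list(s1 = data.frame(id = c("1", "4"), protId = c("s1|a1|t", "s1|a2|t")),
              s2 = data.frame(id = c("2", "5"), protId = c("s2|b1|t", "s2|b2|t")),
              outA = data.frame(id = c("3", "6"), protId = c("o1", "o2")))
  nested <- orthoxml_text(sg6, paste0(
    '<orthologGroup id="root1">',
    '<property name="TaxRange" value="root"/>',
    '<paralogGroup>',
    '<orthologGroup><geneRef id="1"/><geneRef id="2"/></orthologGroup>',
    '<orthologGroup><geneRef id="4"/><geneRef id="5"/></orthologGroup>',
    '</paralogGroup>',
    '<geneRef id="3"/><geneRef id="6"/>',
    '</orthologGroup>'))
  tf2 <- withr::local_tempfile(fileext = ".orthoxml"); writeLines(nested, tf2)
  f2 <- read_orthoxml(tf2, tree)
  cons2 <- f2$by_node[[as.character(tree$consensus_node)]]
  expect_length(cons2, 2)
  mem <- lapply(cons2, function(id) sort(f2$hogs[[id]]$members$gene_id))
  expect_setequal(vapply(mem, paste, "", collapse = "+"), c("a1+b1", "a2+b2"))
  # both consensus HOGs chain up to an ancestor containing the outgroup
  for (id in cons2) {
    anc <- f2$hogs[[id]]
    seen <- character(0)
    while (!is.na(anc$parent)) { anc <- f2$hogs[[anc$parent]]
      seen <- c(seen, anc$members$species) }
    expect_true("outA" %in% seen)
  }

  # undeclared geneRef id is an error naming the id
  bad <- orthoxml_text(sg, '<orthologGroup><geneRef id="999"/><geneRef id="1"/></orthologGroup>')
  tf3 <- withr::local_tempfile(fileext = ".orthoxml"); writeLines(bad, tf3)
  expect_error(read_orthoxml(tf3, tree), "999", class = "consanno_data_error")

  # species missing from the tree is an error listing the name
  sgx <- c(sg, list(mystery = data.frame(id = "7", protId = "m1")))
  unk <- orthoxml_text(sgx, '<orthologGroup><geneRef id="1"/><geneRef id="7"/></orthologGroup>')
  tf4 <- withr::local_tempfile(fileext = ".orthoxml"); writeLines(unk, tf4)
  expect_error(read_orthoxml(tf4, tree), "mystery", class = "consanno_data_error")
})

test_that("species tree validation enforces the consensus node contract", {
  expect_error(read_species_tree("((s1,s2)x,outA)r;", c("s1", "s3")),
               "absent", class = "consanno_config_error")
  expect_error(read_species_tree("((s1,outA)x,(s2)y)r;", c("s1", "s2")),
               "no internal node", class = "consanno_config_error")
  expect_error(read_species_tree("((s1,s2)c,outA)r;", "s1"),
               class = "consanno_config_error")
  tr <- read_species_tree("((s1,s2,s3)consensus,outA,outB)root;",
                          c("s1", "s2", "s3"))
  expect_setequal(tr$outgroups, c("outA", "outB"))
  expect_setequal(tr$tips[[tr$consensus_node]], c("s1", "s2", "s3"))
})
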