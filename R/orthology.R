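# Orthology engine over {annotation sources as pseudo-species} + outgroups.
#
# The built-in engine is a deliberately simple stand-in for full orthology
# inference: Smith-Waterman local alignment (BLOSUM62, affine gaps), strict
# reciprocal best hits per species pair, then bottom-up grouping of genes
# into hierarchical orthologous groups (HOGs) along the species tree
# (connected components of the RBH graph at each internal node). Full-fidelity
# interop with external orthology tools is provided via orthoXML import.

# ---- species tree -----------------------------------------------------------

node_children_list <- function(phy) {
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n_nodes)
  for (k in seq_len(nrow(phy$edge)))
    ch[[phy$edge[k, 1]]] <- c(ch[[phy$edge[k, 1]]], phy$edge[k, 2])
  ch
}

node_tips <- function(phy) {
  ntip <- ape::Ntip(phy)
  ch <- node_children_list(phy)
  tips <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- phy$tip.label[i]
  for (n in unique(ape::reorder.phylo(phy, "postorder")$edge[, 1]))
    tips[[n]] <- unlist(lapply(ch[[n]], function(c) tips[[c]]))
  tips
}

#' Read and validate the species tree
#'
#' The tree (Newick) must contain one internal node — the *consensus node* —
#' whose descendant leaves are exactly the declared annotation sources; every
#' other leaf is an outgroup species. When all leaves are sources the root is
#' the consensus node and no outgroup evidence is available.
#'
#' @param newick Newick text (anything containing `(`) or a file path.
#' @param sources character vector of source annotation names (>= 2).
#' @return An object of class `species_tree`: list with `phylo`, `sources`,
#'   `outgroups`, `consensus_node` (ape node number), `children`, `tips`
#'   (per-node descendant leaf labels).
#' @export
read_species_tree <- function(newick, sources) {
  if (length(sources) < 2)
    stop_config("at least two annotation sources are required")
  phy <- if (grepl("(", newick, fixed = TRUE)) ape::read.tree(text = newick)
         else ape::read.tree(newick)
  if (is.null(phy)) stop_config("could not parse Newick species tree")
  if (anyDuplicated(phy$tip.label))
    stop_config("species tree has duplicated leaf labels")
  missing <- setdiff(sources, phy$tip.label)
  if (length(missing))
    stop_config("source(s) absent from the species tree: ",
                paste(missing, collapse = ", "))
  tips <- node_tips(phy)
  ntip <- ape::Ntip(phy)
  internal <- ntip + seq_len(phy$Nnode)
  hit <- internal[vapply(internal, function(n)
    setequal(tips[[n]], sources), TRUE)]
  if (length(hit) == 0)
    stop_config("no internal node has exactly the sources {",
                paste(sources, collapse = ", "), "} as descendant leaves")
  structure(list(
    phylo = phy, sources = sources,
    outgroups = setdiff(phy$tip.label, sources),
    consensus_node = min(hit),  # lowest such node if nested identical sets
    children = node_children_list(phy),
    tips = tips
  ), class = "species_tree")
}

# node numbers (incl. leaves) in the subtree rooted at `node`
subtree_nodes <- function(tree, node) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    out <- c(out, n)
    stack <- c(stack, tree$children[[n]])
  }
  out
}

species_lca <- function(tree, species) {
  idx <- match(species, tree$phylo$tip.label)
  if (anyNA(idx))
    stop_data("species absent from tree: ",
              paste(species[is.na(idx)], collapse = ", "))
  if (length(unique(idx)) == 1L) return(idx[1])
  ape::getMRCA(tree$phylo, unique(idx))
}

# ---- alignment --------------------------------------------------------------

aa_alphabet <- function() c("A","R","N","D","C","Q","E","G","H","I","L","K",
                            "M","F","P","S","T","W","Y","V","X")

substitution_matrix <- function() {
  m <- .consanno_env$blosum62
  if (is.null(m)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- aa_alphabet()
    m <- e$BLOSUM62[ab, ab]
    m["X", ] <- 0L; m[, "X"] <- 0L  # X is scored 0 against everything
    storage.mode(m) <- "integer"
    .consanno_env$blosum62 <- m
  }
  m
}

encode_protein <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
  codes[is.na(codes)] <- length(aa_alphabet())  # unknown letters score as X
  as.integer(codes)
}

#' Smith-Waterman local alignment score
#'
#' Maximal local alignment score under BLOSUM62 with affine gap penalties;
#' a gap of length L costs `gap_open + L * gap_extend`. `X` (and any letter
#' outside the 20-residue alphabet) scores 0 against everything. The score is
#' symmetric and never negative; an empty sequence scores 0.
#'
#' @param a,b amino-acid strings.
#' @param gap_open,gap_extend gap penalties (positive; defaults 11 and 1).
#' @return Integer score.
#' @export
smith_waterman_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  r <- sw_align_ints(encode_protein(a), encode_protein(b),
                     substitution_matrix(), as.integer(gap_open),
                     as.integer(gap_extend))
  as.integer(r$score)
}

# ---- protein database -------------------------------------------------------

#' Build the per-species protein database
#'
#' One entry per leaf of the species tree: annotation sources contribute the
#' proteomes extracted from their GFF3 models, outgroups contribute plain
#' protein FASTA proteomes.
#'
#' @param species named list; each element a list with `proteins` (data.frame
#'   with `protein_id`, `gene_id`, `sequence`) and optional `splice_groups`.
#' @return An object of class `protein_database`.
#' @export
protein_database <- function(species) {
  stopifnot(length(names(species)) == length(species))
  for (nm in names(species)) {
    p <- species[[nm]]$proteins
    if (!is.data.frame(p) || !all(c("protein_id", "gene_id", "sequence") %in% names(p)))
      stop_config("species '", nm, "': proteins must be a data.frame with ",
                  "protein_id, gene_id, sequence")
  }
  structure(list(species = species), class = "protein_database")
}

#' Read an outgroup proteome FASTA into database form
#'
#' Each record is one gene (gene id = protein id = first header token).
#'
#' @param path FASTA file of protein sequences.
#' @param name species name.
#' @return List suitable as one entry of [protein_database()].
#' @export
read_outgroup_proteome <- function(path, name) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1)
  list(proteins = data.frame(protein_id = ids, gene_id = ids,
                             sequence = as.character(ss),
                             stringsAsFactors = FALSE),
       splice_groups = list())
}

#' Engine options
#'
#' @param min_score minimum alignment score for a hit to count. The default
#'   (100) is set so that chance local alignments are negligible at this
#'   pipeline's scale: by Karlin-Altschul statistics for gapped BLOSUM62
#'   (lambda ~ 0.267, K ~ 0.041), the expected number of chance hits of
#'   score >= S across N ~ 1e6 comparisons of ~300-residue proteins is
#'   K * m * n * N * exp(-lambda * S), which drops below 0.1 near S = 100,
#'   while genuine orthologs of >= 60 residues at <= 30% divergence score
#'   far above it.
#' @param min_cov minimum aligned fraction of the shorter sequence (0.5).
#' @param tolerance slack (score units) below the best hit still accepted as
#'   reciprocal; 0 means strict mutual best.
#' @param gap_open,gap_extend affine gap penalties.
#' @param outgroup_evidence `"hog"` (outgroup support = co-membership in an
#'   ancestral HOG, the default) or `"pairs"` (a direct ortholog pair).
#' @return List of options.
#' @export
engine_options <- function(min_score = 100, min_cov = 0.5, tolerance = 0,
                           gap_open = 11, gap_extend = 1,
                           outgroup_evidence = c("hog", "pairs")) {
  list(min_score = min_score, min_cov = min_cov, tolerance = tolerance,
       gap_open = gap_open, gap_extend = gap_extend,
       outgroup_evidence = match.arg(outgroup_evidence))
}

# encoded main-isoform table for one species: provisional main = longest
# isoform, ties broken by lexicographically smallest transcript/protein id
provisional_mains <- function(proteins) {
  ord <- order(proteins$gene_id, -nchar(proteins$sequence), proteins$protein_id)
  p <- proteins[ord, , drop = FALSE]
  p[!duplicated(p$gene_id), , drop = FALSE]
}

#' Select the main isoform of a gene
#'
#' The main isoform is the one most similar to the gene's detected homologues:
#' it maximizes the summed score of its alignment hits against proteins of
#' other species/sources. With no hits the longest isoform is used; ties are
#' broken by the lexicographically smallest transcript id.
#'
#' @param proteins data.frame of the gene's isoform records (`protein_id`,
#'   `transcript_id`, `sequence`).
#' @param hits data.frame of alignment hits with columns `query_id`, `score`
#'   (already filtered to hits passing the engine thresholds).
#' @return The selected row of `proteins`.
#' @export
select_main_isoform <- function(proteins, hits) {
  if (nrow(proteins) == 0)
    stop_data("select_main_isoform: gene has no translatable isoform")
  sums <- vapply(proteins$protein_id, function(pid)
    sum(hits$score[hits$query_id == pid]), 0)
  tid <- if ("transcript_id" %in% names(proteins)) proteins$transcript_id
         else proteins$protein_id
  if (all(sums == 0)) {
    ord <- order(-nchar(proteins$sequence), tid)
  } else {
    ord <- order(-sums, tid)
  }
  proteins[ord[1], , drop = FALSE]
}

# all-vs-all scores with engine thresholds applied: entries below min_score,
# or whose alignment covers less than min_cov of the shorter sequence, are 0.
# Coverage needs the aligned span, so it is only computed (by realignment)
# for the entries that already pass min_score.
score_cov_filtered <- function(encA, encB, opts) {
  sub <- substitution_matrix()
  s <- sw_score_only_matrix(encA, encB, sub, as.integer(opts$gap_open),
                            as.integer(opts$gap_extend))
  s[s < opts$min_score] <- 0
  cand <- which(s > 0, arr.ind = TRUE)
  if (nrow(cand)) {
    cov <- sw_cov_pairs(encA, encB, cand[, 1], cand[, 2], sub,
                        as.integer(opts$gap_open), as.integer(opts$gap_extend))
    s[cand[cov < opts$min_cov, , drop = FALSE]] <- 0
  }
  s
}

# choose main isoforms for every gene of every species: provisional mains
# (longest) serve as alignment targets; only multi-isoform genes need scoring
resolve_main_isoforms <- function(db, opts) {
  sp <- names(db$species)
  prov <- lapply(db$species, function(s) provisional_mains(s$proteins))
  enc_prov <- lapply(prov, function(p) lapply(p$sequence, encode_protein))
  mains <- list()
  for (nm in sp) {
    proteins <- db$species[[nm]]$proteins
    multi_genes <- unique(proteins$gene_id[duplicated(proteins$gene_id)])
    if (length(multi_genes) == 0) { mains[[nm]] <- prov[[nm]]; next }
    iso <- proteins[proteins$gene_id %in% multi_genes, , drop = FALSE]
    enc_iso <- lapply(iso$sequence, encode_protein)
    sums <- numeric(nrow(iso))
    for (other in setdiff(sp, nm)) {
      if (length(enc_prov[[other]]) == 0) next
      s <- score_cov_filtered(enc_iso, enc_prov[[other]], opts)
      sums <- sums + rowSums(s)
    }
    chosen <- vapply(multi_genes, function(g) {
      k <- which(iso$gene_id == g)
      sel <- if (all(sums[k] == 0))
        k[order(-nchar(iso$sequence[k]), iso$transcript_id[k])][1]
      else k[order(-sums[k], iso$transcript_id[k])][1]
      iso$protein_id[sel]
    }, "")
    m <- prov[[nm]]
    repl <- match(multi_genes, m$gene_id)
    m[repl, ] <- proteins[match(chosen, proteins$protein_id), names(m)]
    m <- m[order(m$gene_id), , drop = FALSE]
    mains[[nm]] <- m
  }
  mains
}

#' Infer ortholog pairs by reciprocal best hits
#'
#' For each species pair, genes are represented by their main isoform (see
#' [select_main_isoform()]); all-vs-all Smith-Waterman scores are computed and
#' an unordered pair is emitted iff each member scores within `tolerance` of
#' the other's best hit and the hit passes `min_score` and `min_cov`.
#'
#' @param db a [protein_database()] (>= 2 species).
#' @param opts [engine_options()].
#' @return data.frame with columns `species_a`, `gene_a`, `protein_a`,
#'   `species_b`, `gene_b`, `protein_b`, `score`. The per-species main-isoform
#'   tables are attached as `attr(, "mains")`.
#' @export
infer_ortholog_pairs <- function(db, opts = engine_options()) {
  sp <- sort(names(db$species))
  if (length(sp) < 2) stop_config("ortholog inference needs >= 2 species")
  mains <- resolve_main_isoforms(db, opts)
  enc <- lapply(mains, function(m) lapply(m$sequence, encode_protein))
  out <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (j <= i) next
    A <- mains[[sp[i]]]; B <- mains[[sp[j]]]
    if (nrow(A) == 0 || nrow(B) == 0) next
    s <- score_cov_filtered(enc[[sp[i]]], enc[[sp[j]]], opts)
    if (all(s == 0)) next
    best_a <- apply(s, 1, max)  # best hit of each A gene in B
    best_b <- apply(s, 2, max)
    hit <- which(s > 0 &
                   s >= matrix(best_a - opts$tolerance, nrow(s), ncol(s)) &
                   s >= matrix(best_b - opts$tolerance, nrow(s), ncol(s), byrow = TRUE),
                 arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      species_a = sp[i], gene_a = A$gene_id[hit[, 1]],
      protein_a = A$protein_id[hit[, 1]],
      species_b = sp[j], gene_b = B$gene_id[hit[, 2]],
      protein_b = B$protein_id[hit[, 2]],
      score = s[hit], stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(species_a = character(0), gene_a = character(0),
               protein_a = character(0), species_b = character(0),
               gene_b = character(0), protein_b = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$species_a, pairs$gene_a,
                       pairs$species_b, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "mains") <- mains
  pairs
}

# ---- HOG forest -------------------------------------------------------------

new_hog_forest <- function(hogs, tree) {
  by_node <- split(vapply(hogs, `[[`, "", "id"),
                   vapply(hogs, `[[`, 0L, "node"))
  structure(list(hogs = setNames(hogs, vapply(hogs, `[[`, "", "id")),
                 by_node = by_node, tree = tree),
            class = "hog_forest")
}

#' @export
print.hog_forest <- function(x, ...) {
  cat("hog_forest: ", length(x$hogs), " HOGs over ",
      length(x$tree$phylo$tip.label), " species\n", sep = "")
  invisible(x)
}

#' Build hierarchical orthologous groups bottom-up on the species tree
#'
#' At each leaf every gene is a singleton HOG. Ascending the tree in
#' post-order, the HOGs of a node's child subtrees become vertices of a graph
#' whose edges are the ortholog pairs whose two species have that node as
#' their most recent common ancestor; connected components become the HOGs of
#' the node. Every gene therefore belongs to exactly one HOG at every
#' ancestral node (possibly a singleton).
#'
#' @param pairs data.frame from [infer_ortholog_pairs()] (or equivalent with
#'   `species_a`, `gene_a`, `species_b`, `gene_b`).
#' @param tree a [read_species_tree()] object.
#' @param db optional [protein_database()] used to enumerate genes; when
#'   absent, genes are taken from `pairs` only.
#' @return An object of class `hog_forest`.
#' @export
build_hogs <- function(pairs, tree, db = NULL) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  bad <- setdiff(unique(c(pairs$species_a, pairs$species_b)), phy$tip.label)
  if (length(bad))
    stop_data("ortholog pair references unknown species: ",
              paste(bad, collapse = ", "))

  # gene inventory per species
  genes_of <- setNames(vector("list", ntip), phy$tip.label)
  if (!is.null(db)) {
    for (nm in names(db$species))
      genes_of[[nm]] <- sort(unique(db$species[[nm]]$proteins$gene_id))
  }
  for (k in seq_len(nrow(pairs))) {
    genes_of[[pairs$species_a[k]]] <-
      union(genes_of[[pairs$species_a[k]]], pairs$gene_a[k])
    genes_of[[pairs$species_b[k]]] <-
      union(genes_of[[pairs$species_b[k]]], pairs$gene_b[k])
  }

  # LCA node of each pair's two species
  if (nrow(pairs)) {
    la <- match(pairs$species_a, phy$tip.label)
    lb <- match(pairs$species_b, phy$tip.label)
    pair_lca <- vapply(seq_len(nrow(pairs)), function(k) {
      if (la[k] == lb[k]) la[k] else ape::getMRCA(phy, c(la[k], lb[k]))
    }, 0L)
  } else pair_lca <- integer(0)

  hogs <- list(); counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("HOG%06d", counter) }
  cur <- new.env(parent = emptyenv())  # gene key -> current top HOG id
  gkey <- function(sp, g) paste0(sp, "\r", g)

  # leaf singletons
  for (li in seq_len(ntip)) {
    sp <- phy$tip.label[li]
    for (g in sort(genes_of[[sp]])) {
      id <- new_id()
      hogs[[id]] <- list(id = id, node = li,
                         members = data.frame(species = sp, gene_id = g,
                                              stringsAsFactors = FALSE),
                         children = character(0), parent = NA_character_)
      cur[[gkey(sp, g)]] <- id
    }
  }

  post <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1])
  for (n in c(post, if (!(ntip + 1L) %in% post) ntip + 1L)) {
    # vertices: current top HOGs of all genes under n
    under <- intersect(subtree_nodes(tree, n), seq_len(ntip))
    vs <- sort(unique(unlist(lapply(phy$tip.label[under], function(sp)
      vapply(genes_of[[sp]], function(g) cur[[gkey(sp, g)]], "")))))
    if (length(vs) == 0) next
    ek <- which(pair_lca == n)
    edges <- if (length(ek)) cbind(
      vapply(ek, function(k) cur[[gkey(pairs$species_a[k], pairs$gene_a[k])]], ""),
      vapply(ek, function(k) cur[[gkey(pairs$species_b[k], pairs$gene_b[k])]], ""))
      else matrix(character(0), ncol = 2)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
      directed = FALSE, vertices = data.frame(name = vs))
    comp <- igraph::components(g)$membership
    for (cid in sort(unique(comp))) {
      child_ids <- sort(names(comp)[comp == cid])
      id <- new_id()
      members <- do.call(rbind, lapply(child_ids, function(h) hogs[[h]]$members))
      members <- members[order(members$species, members$gene_id), , drop = FALSE]
      rownames(members) <- NULL
      hogs[[id]] <- list(id = id, node = n, members = members,
                         children = child_ids, parent = NA_character_)
      for (h in child_ids) hogs[[h]]$parent <- id
      for (k in seq_len(nrow(members)))
        cur[[gkey(members$species[k], members$gene_id[k])]] <- id
    }
  }
  new_hog_forest(hogs, tree)
}

# ---- orthoXML import --------------------------------------------------------

#' Read a HOG forest from an orthoXML file
#'
#' Supports nested `orthologGroup`/`paralogGroup` elements. A group's
#' taxonomic level is taken from its `TaxRange` property when that names a
#' node label of the species tree, else inferred as the most recent common
#' ancestor of its member species. Candidate consensus genes are obtained by
#' slicing the group hierarchy at the consensus node: an `orthologGroup`
#' whose level lies at or below the consensus node yields one candidate gene
#' (all its source-gene members), and source genes hanging above it yield
#' singleton candidates.
#'
#' @param path orthoXML file.
#' @param tree a [read_species_tree()] object; every species in the file must
#'   be a tree leaf.
#' @return A `hog_forest` whose consensus-node HOGs are the sliced candidates.
#' @export
read_orthoxml <- function(path, tree) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//species")
  gene_tab <- list()
  for (sn in sp_nodes) {
    sp <- xml2::xml_attr(sn, "name")
    for (gn in xml2::xml_find_all(sn, ".//gene")) {
      gid <- xml2::xml_attr(gn, "id")
      prot <- xml2::xml_attr(gn, "protId")
      gene <- xml2::xml_attr(gn, "geneId")
      if (is.na(gene)) {
        parts <- strsplit(prot %||% gid, "|", fixed = TRUE)[[1]]
        gene <- if (length(parts) == 3) parts[2] else (prot %||% gid)
      }
      gene_tab[[gid]] <- list(species = sp, gene_id = gene,
                              protein_id = prot %||% gid)
    }
  }
  file_species <- unique(vapply(gene_tab, `[[`, "", "species"))
  bad <- setdiff(file_species, tree$phylo$tip.label)
  if (length(bad))
    stop_data("orthoXML species absent from the tree: ",
              paste(bad, collapse = ", "))

  node_labels <- tree$phylo$node.label
  label_to_node <- if (!is.null(node_labels))
    setNames(ape::Ntip(tree$phylo) + seq_along(node_labels), node_labels)
    else setNames(integer(0), character(0))

  resolve_gene <- function(id) {
    g <- gene_tab[[id]]
    if (is.null(g)) stop_data("orthoXML geneRef with undeclared id: ", id)
    g
  }

  # recursive parse into plain lists
  parse_group <- function(node) {
    kind <- xml2::xml_name(node)
    kids <- xml2::xml_children(node)
    members <- list(); subgroups <- list()
    taxrange <- NA_character_
    for (k in kids) {
      nm <- xml2::xml_name(k)
      if (nm == "geneRef") {
        members[[length(members) + 1L]] <- resolve_gene(xml2::xml_attr(k, "id"))
      } else if (nm %in% c("orthologGroup", "paralogGroup")) {
        subgroups[[length(subgroups) + 1L]] <- parse_group(k)
      } else if (nm == "property" &&
                 xml2::xml_attr(k, "name") %in% c("TaxRange", "taxRange")) {
        taxrange <- xml2::xml_attr(k, "value")
      }
    }
    all_members <- c(members, unlist(lapply(subgroups, `[[`, "all_members"),
                                     recursive = FALSE))
    if (length(all_members) == 0)
      stop_data("orthoXML group without any gene member")
    sp <- unique(vapply(all_members, `[[`, "", "species"))
    level <- if (!is.na(taxrange) && taxrange %in% names(label_to_node))
      label_to_node[[taxrange]] else species_lca(tree, sp)
    list(kind = kind, direct = members, subgroups = subgroups,
         all_members = all_members, level = level)
  }

  roots <- lapply(xml2::xml_find_all(doc, ".//groups/*"), parse_group)

  cons_sub <- subtree_nodes(tree, tree$consensus_node)
  hogs <- list(); counter <- 0L
  new_id <- function() { counter <<- counter + 1L; sprintf("XHOG%06d", counter) }
  members_df <- function(ms) {
    df <- do.call(rbind, lapply(ms, function(m)
      data.frame(species = m$species, gene_id = m$gene_id,
                 stringsAsFactors = FALSE)))
    df <- unique(df[order(df$species, df$gene_id), , drop = FALSE])
    rownames(df) <- NULL
    df
  }

  # walk a root group: materialize above-consensus groups as ancestor HOGs,
  # and slice out consensus-level candidate HOGs
  walk <- function(grp, parent_id) {
    if (grp$kind == "orthologGroup" && grp$level %in% cons_sub) {
      src_members <- Filter(function(m) m$species %in% tree$sources,
                            grp$all_members)
      if (length(src_members)) {
        id <- new_id()
        hogs[[id]] <<- list(id = id, node = tree$consensus_node,
                            members = members_df(src_members),
                            children = character(0), parent = parent_id)
      }
      return(invisible(NULL))
    }
    # group above the consensus node (or a paralog group): ancestor HOG.
    # A paralog group whose level falls inside the consensus subtree is
    # structural only — parking it at node 0 keeps it off the candidate
    # list while preserving the parent chain for outgroup evidence.
    id <- new_id()
    anc_node <- if (grp$level %in% cons_sub) 0L else grp$level
    hogs[[id]] <<- list(id = id, node = anc_node,
                        members = members_df(grp$all_members),
                        children = character(0), parent = parent_id)
    for (m in grp$direct) {
      if (m$species %in% tree$sources) {  # implicit singleton at consensus
        sid <- new_id()
        hogs[[sid]] <<- list(id = sid, node = tree$consensus_node,
                             members = members_df(list(m)),
                             children = character(0), parent = id)
      }
    }
    for (sg in grp$subgroups) walk(sg, id)
    invisible(NULL)
  }
  for (r in roots) walk(r, NA_character_)

  # fix child links
  for (id in names(hogs)) {
    p <- hogs[[id]]$parent
    if (!is.na(p)) hogs[[p]]$children <- c(hogs[[p]]$children, id)
  }
  new_hog_forest(unname(hogs), tree)
}
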