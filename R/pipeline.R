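# Pipeline orchestration: prepare -> infer (or import orthoXML) ->
# extract consensus -> report, plus a small command-line front end.

#' Run configuration
#'
#' @param genome path to the genome FASTA.
#' @param sources named list: `source_name -> list(path =, feature_map =)`
#'   where `feature_map` is optional (path to a TSV or a named vector);
#'   a bare character path is also accepted. At least two sources.
#' @param tree Newick text or path to the species tree; the sources must be
#'   the leaves under one internal (consensus) node.
#' @param outgroup_proteomes named list `species -> FASTA path` for the
#'   built-in engine (may be empty).
#' @param orthoxml optional path to a precomputed HOG forest (orthoXML);
#'   when given, the built-in engine is skipped.
#' @param priority optional ordered character vector of source names.
#' @param engine [engine_options()].
#' @param out_prefix output path prefix for the GFF3/FASTA/report files;
#'   `NULL` suppresses file output.
#' @return List of class `run_config`.
#' @export
run_config <- function(genome, sources, tree, outgroup_proteomes = list(),
                       orthoxml = NULL, priority = NULL,
                       engine = engine_options(), out_prefix = NULL) {
  if (length(sources) < 2)
    stop_config("at least two source annotations are required")
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop_config("sources must be a named list")
  sources <- lapply(sources, function(s)
    if (is.character(s)) list(path = s, feature_map = NULL) else s)
  structure(list(genome = genome, sources = sources, tree = tree,
                 outgroup_proteomes = outgroup_proteomes,
                 orthoxml = orthoxml, priority = priority, engine = engine,
                 out_prefix = out_prefix),
            class = "run_config")
}

load_source_annotations <- function(config) {
  anns <- list()
  for (nm in names(config$sources)) {
    s <- config$sources[[nm]]
    fm <- s$feature_map
    fm <- if (is.null(fm)) default_feature_map()
          else if (is.character(fm) && length(fm) == 1 && file.exists(fm))
            read_feature_map(fm)
          else fm
    anns[[nm]] <- parse_gff3(s$path, feature_map = fm, source_name = nm)
  }
  anns
}

build_database <- function(annotations, genome, outgroup_proteomes) {
  species <- list()
  log <- list()
  for (nm in names(annotations)) {
    ex <- extract_proteome(annotations[[nm]], genome)
    species[[nm]] <- list(proteins = ex$proteins,
                          splice_groups = ex$splice_groups)
    log[[nm]] <- list(n_internal_stop = ex$n_internal_stop,
                      dropped_genes = ex$dropped_genes)
  }
  for (nm in names(outgroup_proteomes)) {
    og <- outgroup_proteomes[[nm]]
    species[[nm]] <- if (is.character(og)) read_outgroup_proteome(og, nm)
                     else og[c("proteins", "splice_groups")]
  }
  db <- protein_database(species)
  attr(db, "log") <- log
  db
}

#' Run the full consensus pipeline
#'
#' Parses the sources, extracts proteomes, infers HOGs with the built-in
#' engine (or imports them from orthoXML), computes support at the consensus
#' node, applies the retention rule and writes the consensus GFF3, protein
#' FASTA and the two reports when `out_prefix` is set.
#'
#' Inputs may also be given in-memory: `genome` as a named character vector,
#' `sources` as `annotation_set` objects (wrapped as
#' `list(annotation = <set>)`), outgroups as protein data.frame entries.
#'
#' @param config a [run_config()].
#' @return A `consensus_annotation`; `attr(, "files")` lists written outputs,
#'   `attr(, "support")` holds all (pre-retention) support records.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genome <- if (is.character(config$genome) && length(config$genome) == 1 &&
                file.exists(config$genome)) read_genome_fasta(config$genome)
            else config$genome

  annotations <- list()
  for (nm in names(config$sources)) {
    s <- config$sources[[nm]]
    annotations[[nm]] <- if (!is.null(s$annotation)) s$annotation
  }
  if (any(vapply(annotations, is.null, TRUE)) || length(annotations) == 0)
    annotations <- load_source_annotations(config)

  tree <- read_species_tree(config$tree, names(annotations))
  bad <- setdiff(names(config$outgroup_proteomes), tree$outgroups)
  if (length(bad))
    stop_config("outgroup proteome(s) not in the tree: ",
                paste(bad, collapse = ", "))

  db <- build_database(annotations, genome, config$outgroup_proteomes)

  if (!is.null(config$orthoxml)) {
    forest <- read_orthoxml(config$orthoxml, tree)
    pairs <- NULL
    evidence <- "hog"  # pairwise orthologs unavailable from a HOG file
  } else {
    pairs <- infer_ortholog_pairs(db, config$engine)
    forest <- build_hogs(pairs, tree, db)
    evidence <- config$engine$outgroup_evidence
  }

  support <- compute_support(forest, tree, pairs = pairs,
                             outgroup_evidence = evidence)
  retained <- retain_genes(support)
  consensus <- assemble_consensus(retained, annotations,
                                  priority = config$priority,
                                  metadata = list(tree = config$tree,
                                                  engine = config$engine))
  attr(consensus, "support") <- support

  if (!is.null(config$out_prefix)) {
    files <- c(gff3 = paste0(config$out_prefix, ".gff3"),
               faa = paste0(config$out_prefix, ".faa"))
    write_gff3(consensus, names(genome), files[["gff3"]])
    prot <- consensus_proteins(consensus, genome)
    write_proteome_fasta(prot, files[["faa"]])
    files <- c(files, write_reports(consensus, config$out_prefix, tree))
    attr(consensus, "files") <- files
  }
  consensus
}

# all isoform proteins of the consensus genes
consensus_proteins <- function(consensus, genome) {
  recs <- list()
  for (cg in consensus$genes) {
    for (t in cg$gene$transcripts) {
      aa <- suppressWarnings(translate_cds(t$segments, genome))
      if (is.na(aa) || grepl("*", aa, fixed = TRUE)) next
      pid <- paste(cg$source, cg$gene$gene_id, t$transcript_id, sep = "|")
      recs[[pid]] <- data.frame(protein_id = pid, sequence = aa,
                                stringsAsFactors = FALSE)
    }
  }
  if (length(recs)) do.call(rbind, unname(recs)) else
    data.frame(protein_id = character(0), sequence = character(0))
}

#' Prepare the orthology database folder
#'
#' Writes the per-source protein FASTA files, splice files and the species
#' tree into `out_dir/DB` — the input layout expected by external orthology
#' tools — so that users can run an external HOG inference and feed the
#' resulting orthoXML back via `run_config(orthoxml =)`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
prepare_data <- function(config, out_dir) {
  genome <- if (is.character(config$genome) && length(config$genome) == 1 &&
                file.exists(config$genome)) read_genome_fasta(config$genome)
            else config$genome
  annotations <- load_source_annotations(config)
  tree <- read_species_tree(config$tree, names(annotations))
  db_dir <- file.path(out_dir, "DB")
  dir.create(db_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(annotations)) {
    ex <- extract_proteome(annotations[[nm]], genome)
    fa <- file.path(db_dir, paste0(nm, ".fa"))
    write_proteome_fasta(ex$proteins, fa)
    paths <- c(paths, fa)
    if (length(ex$splice_groups)) {
      sp <- file.path(db_dir, paste0(nm, ".splice"))
      write_splice_file(ex$splice_groups, sp)
      paths <- c(paths, sp)
    }
  }
  tree_file <- file.path(out_dir, "species_tree.nwk")
  tree_text <- if (grepl("(", config$tree, fixed = TRUE)) config$tree
               else readLines(config$tree, warn = FALSE)[1]
  writeLines(tree_text, tree_file)
  invisible(c(paths, tree_file))
}

# ---- command line front end -------------------------------------------------

read_run_config_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  srcs <- cfg$sources
  if (is.data.frame(srcs))
    srcs <- setNames(lapply(seq_len(nrow(srcs)), function(i)
      list(path = srcs$path[i], feature_map = srcs$feature_map[i])), srcs$name)
  run_config(genome = cfg$genome, sources = srcs, tree = cfg$tree,
             outgroup_proteomes = as.list(cfg$outgroup_proteomes %||% list()),
             orthoxml = cfg$orthoxml, priority = cfg$priority,
             engine = do.call(engine_options, as.list(cfg$engine %||% list())),
             out_prefix = cfg$out_prefix)
}

parse_source_flag <- function(x) {
  # name=path[:featuremap]
  eq <- regexpr("=", x, fixed = TRUE)
  if (eq < 0) stop_config("--source must be name=path[:featuremap], got: ", x)
  nm <- substr(x, 1, eq - 1)
  rest <- strsplit(substr(x, eq + 1, nchar(x)), ":", fixed = TRUE)[[1]]
  setNames(list(list(path = rest[1],
                     feature_map = if (length(rest) > 1) rest[2])), nm)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `prepare-data` (write the orthology DB
#' folder), `evaluate` (`--query`, `--ref`), `simulate` (`--config`,
#' `--out`). See `inst/cli/consanno.R` for the launcher script.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code: 0 ok, 2 configuration error, 3 data error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0)
      stop_config("usage: consanno <run|prepare-data|evaluate|simulate> ...")
    cmd <- args[1]; rest <- args[-1]
    flags <- list(); sources <- list()
    i <- 1
    while (i <= length(rest)) {
      a <- rest[i]
      if (a == "--source") { sources <- c(sources, parse_source_flag(rest[i + 1])); i <- i + 2 }
      else if (startsWith(a, "--")) { flags[[substring(a, 3)]] <- rest[i + 1]; i <- i + 2 }
      else stop_config("unexpected argument: ", a)
    }
    if (cmd %in% c("run", "prepare-data")) {
      cfg <- if (!is.null(flags$config)) read_run_config_json(flags$config)
      else run_config(
        genome = flags$genome %||% stop_config("--genome is required"),
        sources = sources, tree = flags$tree %||% stop_config("--tree is required"),
        outgroup_proteomes = if (is.null(flags$outgroups)) list() else {
          p <- strsplit(flags$outgroups, ",", fixed = TRUE)[[1]]
          setNames(as.list(p), sub("\\.[^.]*$", "", basename(p)))
        },
        orthoxml = flags$orthoxml,
        priority = if (!is.null(flags$priority))
          strsplit(flags$priority, ",", fixed = TRUE)[[1]],
        out_prefix = flags$out)
      if (cmd == "run") {
        cons <- run_pipeline(cfg)
        message("consensus: ", length(cons$genes), " genes retained")
      } else {
        prepare_data(cfg, flags$out %||% ".")
      }
    } else if (cmd == "evaluate") {
      stats <- evaluate_files(
        flags$query %||% stop_config("--query is required"),
        flags$ref %||% stop_config("--ref is required"),
        out = flags$out)
      if (is.null(flags$out))
        write.table(stats, stdout(), sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else if (cmd == "simulate") {
      cfg <- if (!is.null(flags$config))
        do.call(simulation_config,
                jsonlite::read_json(flags$config, simplifyVector = TRUE))
      else simulation_config(
        n_genes = as.integer(flags$n_genes %||% 50),
        seed = as.integer(flags$seed %||% 1))
      ts <- simulate_truth(cfg)
      sources <- derive_sources(ts, paste0("src", 1:3))
      og <- list(out1 = derive_outgroup_proteome(ts, name = "out1"))
      write_simulation(ts, sources, og, flags$out %||% "sim_out")
    } else stop_config("unknown subcommand: ", cmd)
    0L
  },
  consanno_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  consanno_data_error = function(e) { message("data error: ", conditionMessage(e)); 3L })
  invisible(code)
}
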