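# Independent oracles, implemented apart from the package code paths.

# brute-force affine-gap local alignment DP (full matrices, no rolling rows);
# gap of length L costs open + L * ext, matching the documented convention
oracle_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      ab <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
      mm <- e$BLOSUM62[ab, ab]
      mm["X", ] <- 0; mm[, "X"] <- 0
      m <<- mm
    }
    m
  }
})

oracle_sw <- function(a, b, open = 11, ext = 1) {
  M <- oracle_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  A[!A %in% rownames(M)] <- "X"; B[!B %in% rownames(M)] <- "X"
  n <- length(A); m <- length(B)
  if (n == 0 || m == 0) return(0L)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - (open + ext), E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - (open + ext), F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + M[A[i], B[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  as.integer(best)
}

# naive splice-then-translate oracle: builds the mRNA with string ops and a
# plain codon loop (no shared helpers with translate_cds)
oracle_translate <- function(segments, genome) {
  segments <- segments[order(segments$start), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(segments)), function(k)
    substr(genome[[segments$contig[k]]], segments$start[k] + 1L,
           segments$end[k]), "")
  mrna <- paste(seqs, collapse = "")
  if (segments$strand[1] == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    mrna <- paste(rev(comp[strsplit(mrna, "")[[1]]]), collapse = "")
    ph <- segments$phase[nrow(segments)]
  } else ph <- segments$phase[1]
  mrna <- substr(mrna, ph + 1L, nchar(mrna))
  if (nchar(mrna) < 3L) return("")
  code <- Biostrings::GENETIC_CODE
  out <- character(0)
  for (p in seq(1L, nchar(mrna) - 2L, by = 3L)) {
    cod <- substr(mrna, p, p + 2L)
    out <- c(out, if (cod %in% names(code)) code[[cod]] else "X")
  }
  if (length(out) && out[length(out)] == "*") out <- out[-length(out)]
  paste(out, collapse = "")
}

# random single/two-segment transcripts on a random genome, for the
# translation round-trip property
random_transcript_case <- function() {
  glen <- sample(60:200, 1)
  genome <- setNames(paste(sample(c("A", "C", "G", "T", "N"), glen,
                                  replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                           collapse = ""), "c1")
  strand <- sample(c("+", "-"), 1)
  nseg <- sample(1:2, 1)
  if (nseg == 1) {
    s <- sample.int(glen - 10L, 1) - 1L
    e <- s + sample(3:min(30L, glen - s), 1)
    segs <- data.frame(contig = "c1", start = s, end = e, strand = strand,
                       phase = sample(0:2, 1))
  } else {
    s1 <- sample.int(glen - 40L, 1) - 1L
    e1 <- s1 + sample(3:12, 1)
    s2 <- e1 + sample(2:10, 1)
    e2 <- min(s2 + sample(3:15, 1), glen)
    segs <- data.frame(contig = "c1", start = c(s1, s2), end = c(e1, e2),
                       strand = strand, phase = c(sample(0:2, 1), 0L))
  }
  list(segments = segs, genome = genome)
}

# GffCompare-style evaluation oracle: naive all-pairs matching, written
# directly from the matching rules
oracle_evaluate <- function(query, ref, tol = 100, min_ov = 0.8) {
  flat <- function(ann) {
    out <- list()
    for (g in ann$genes) for (t in g$transcripts)
      out[[length(out) + 1L]] <- list(gene = g$gene_id,
                                      contig = t$segments$contig[1],
                                      strand = t$segments$strand[1],
                                      s = t$segments$start, e = t$segments$end)
    out
  }
  qs <- flat(query); rs <- flat(ref)
  sig <- vapply(qs, function(t) paste(t$contig, t$strand,
                                      paste(t$s, t$e, collapse = " ")), "")
  qs <- qs[!duplicated(sig)]
  m <- function(q, r) {
    if (q$contig != r$contig || q$strand != r$strand) return(FALSE)
    nq <- length(q$s); nr <- length(r$s)
    if (nq > 1 && nr > 1) {
      nq == nr && all(q$e[-nq] == r$e[-nr]) && all(q$s[-1] == r$s[-1]) &&
        abs(q$s[1] - r$s[1]) <= tol && abs(q$e[nq] - r$e[nr]) <= tol
    } else if (nq == 1 && nr == 1) {
      min(q$e, r$e) - max(q$s, r$s) >= min_ov * (r$e - r$s)
    } else FALSE
  }
  M <- matrix(FALSE, length(qs), length(rs))
  for (i in seq_along(qs)) for (j in seq_along(rs)) M[i, j] <- m(qs[[i]], rs[[j]])
  exons <- function(ts) unique(unlist(lapply(ts, function(t)
    paste(t$contig, t$strand, t$s, t$e))))
  qe <- exons(qs); re <- exons(rs)
  loci <- function(ts, matched) {
    gm <- tapply(matched, vapply(ts, `[[`, "", "gene"), any)
    spans <- do.call(rbind, lapply(ts, function(t) data.frame(
      gene = t$gene, key = paste(t$contig, t$strand),
      s = min(t$s), e = max(t$e), stringsAsFactors = FALSE)))
    spans <- do.call(rbind, lapply(split(spans, spans$gene), function(d)
      data.frame(gene = d$gene[1], key = d$key[1], s = min(d$s), e = max(d$e))))
    hit <- logical(0)
    for (k in unique(spans$key)) {
      d <- spans[spans$key == k, ]
      d <- d[order(d$s, d$e), ]
      cl <- integer(nrow(d)); cur <- 0; mx <- -Inf
      for (i in seq_len(nrow(d))) {
        if (d$s[i] >= mx) { cur <- cur + 1; mx <- d$e[i] } else mx <- max(mx, d$e[i])
        cl[i] <- cur
      }
      hit <- c(hit, tapply(as.logical(gm[d$gene]), cl, any))
    }
    hit
  }
  r_matched <- apply(M, 2, any); q_matched <- apply(M, 1, any)
  list(
    exon = c(tp = length(intersect(qe, re)), fn = length(setdiff(re, qe)),
             fp = length(setdiff(qe, re))),
    locus = c(tp = sum(loci(rs, r_matched)), fn = sum(!loci(rs, r_matched)),
              fp = sum(!loci(qs, q_matched))),
    transcript = c(tp = sum(r_matched), fn = sum(!r_matched),
                   fp = sum(!q_matched)))
}
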