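#' Beta-barrel porin query templates
#'
#' Loads the packaged set of nine beta-barrel query templates used to scan
#' OPX gene neighborhoods: MXAN_7418/3226/1916, the PgaA, GfcD, YjbH and
#' BcsC barrel modules, AlgE, and Wzi without its plug domain. Each query
#' carries its full-length sequence and the coordinates of the porin-module
#' subsequence (`module_start`-`module_end`, 1-based inclusive).
#'
#' The packaged sequences are deterministic *synthetic stand-ins* (the real
#' proteins are not redistributable here); the module coordinates are the
#' published ones. Supply your own FASTA and sidecar TSV to use real
#' templates.
#'
#' @param fasta path to a protein FASTA of full-length query sequences.
#' @param modules path to a TSV with columns `name`, `module_start`,
#'   `module_end`.
#' @return data.frame with columns `name`, `full_sequence`, `module_start`,
#'   `module_end`.
#' @export
barrel_queries <- function(fasta = system.file("extdata",
                             "barrel_queries_synthetic.fasta",
                             package = "opxtools"),
                           modules = system.file("extdata",
                             "barrel_query_modules.tsv",
                             package = "opxtools")) {
  seqs <- Biostrings::readAAStringSet(fasta)
  mod <- read.delim(modules, stringsAsFactors = FALSE)
  nm <- sub("\\s.*", "", names(seqs))
  if (!all(mod$name %in% nm))
    stop("module table names missing from FASTA: ",
         paste(setdiff(mod$name, nm), collapse = ", "))
  out <- data.frame(name = mod$name,
                    full_sequence = as.character(seqs[match(mod$name, nm)]),
                    module_start = as.integer(mod$module_start),
                    module_end = as.integer(mod$module_end),
                    stringsAsFactors = FALSE)
  bad <- out$module_start > out$module_end |
    out$module_end > nchar(out$full_sequence)
  if (any(bad))
    stop("invalid module coordinates for: ",
         paste(out$name[bad], collapse = ", "))
  out
}

# Gapped Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1,
# the standard protein-search statistics. E = K * m * n * exp(-lambda * S)
# with S the raw local-alignment score and m*n the per-pair search space.
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Match a candidate protein against the beta-barrel query set
#'
#' Aligns the candidate locally (Smith-Waterman, BLOSUM62, gap open 11 /
#' extend 1) against every query's full-length sequence and keeps the
#' best-scoring alignment whose Karlin-Altschul E-value passes `e_max`.
#' The match is typed by query coverage: `full_length` when the alignment
#' covers at least `full_cov` of the full-length query, else `module_only`
#' when it covers at least `module_cov` of the porin-module subsequence.
#' Queries that are nearly all porin module (the MXAN templates) rarely
#' yield `module_only` calls, since even a module-only homologue covers
#' most of the full-length sequence.
#'
#' @param candidate_seq amino-acid sequence (non-empty string).
#' @param queries query set from [barrel_queries()].
#' @param e_max E-value threshold (default 1e-5).
#' @param full_cov minimum full-length query coverage for a `full_length`
#'   call (default 0.80).
#' @param module_cov minimum module coverage for a `module_only` call
#'   (default 0.50).
#' @param search_space optional fixed m*n search-space constant; default
#'   `nchar(candidate) * nchar(query)` per pair.
#' @return `NULL` if nothing passes, else a list with `query`,
#'   `match_type`, `score`, `e_value`, `coverage_full`, `coverage_module`.
#' @export
match_barrel <- function(candidate_seq, queries = barrel_queries(),
                         e_max = 1e-5, full_cov = 0.80, module_cov = 0.50,
                         search_space = NULL) {
  if (!is.character(candidate_seq) || length(candidate_seq) != 1L ||
      !nzchar(candidate_seq))
    stop("candidate_seq must be a non-empty amino-acid string")
  best <- NULL
  m <- nchar(candidate_seq)
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(candidate_seq),
      subject = Biostrings::AAString(q$full_sequence),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    s <- Biostrings::score(al)
    mn <- if (is.null(search_space)) m * nchar(q$full_sequence)
          else search_space
    e_value <- KA_K * mn * exp(-KA_LAMBDA * s)
    if (e_value > e_max) next
    if (is.null(best) || s > best$score) {
      qs <- Biostrings::start(Biostrings::subject(al))
      qe <- Biostrings::end(Biostrings::subject(al))
      cov_full <- (qe - qs + 1) / nchar(q$full_sequence)
      mod_len <- q$module_end - q$module_start + 1
      ov <- min(qe, q$module_end) - max(qs, q$module_start) + 1
      cov_mod <- max(ov, 0) / mod_len
      best <- list(query = q$name, score = s, e_value = e_value,
                   coverage_full = cov_full, coverage_module = cov_mod)
    }
  }
  if (is.null(best)) return(NULL)
  best$match_type <- if (best$coverage_full >= full_cov) "full_length"
    else if (best$coverage_module >= module_cov) "module_only"
    else return(NULL)
  best[c("query", "match_type", "score", "e_value",
         "coverage_full", "coverage_module")]
}

#' Genes in the neighborhood of an anchor gene
#'
#' Returns the genes whose index lies within `window` positions of the
#' anchor on the same replicon, excluding the anchor itself; the window is
#' truncated at replicon ends and never crosses replicon boundaries.
#'
#' @param genes gene table for one replicon (see [gen_genome()]).
#' @param anchor_index 0-based gene index of the anchor.
#' @param window half-width of the neighborhood in genes (default 10).
#' @return subset of `genes`.
#' @export
neighborhood <- function(genes, anchor_index, window = 10L) {
  if (!anchor_index %in% genes$gene_index)
    stop("anchor gene index ", anchor_index, " not found")
  keep <- genes$gene_index >= anchor_index - window &
    genes$gene_index <= anchor_index + window &
    genes$gene_index != anchor_index
  genes[keep, , drop = FALSE]
}

#' Pair OPX genes with syntenic beta-barrel homologues
#'
#' For every classified OPX gene, scans the +/- `window` gene neighborhood
#' for proteins matching a beta-barrel query ([match_barrel()]). Each
#' barrel-matched neighbor yields one synteny hit per OPX anchor (a barrel
#' flanked by two OPX genes is reported twice), carrying its single best
#' query and match type.
#'
#' @param genes gene table, possibly spanning several replicons
#'   (`genome_id` column separates them).
#' @param sequences `AAStringSet` of protein sequences keyed by
#'   `protein_id`.
#' @param classifications data.frame with `protein_id` and `class`
#'   (only non-`NOT_OPX` rows anchor a scan).
#' @param queries query set from [barrel_queries()].
#' @param window neighborhood half-width in genes (default 10).
#' @inheritParams match_barrel
#' @return data.frame of synteny hits: `genome_id`, `opx_protein_id`,
#'   `opx_class`, `barrel_protein_id`, `gene_offset` (signed, in
#'   \[-window, window\] minus 0), `query`, `match_type`, `e_value`,
#'   `coverage_full`, `coverage_module`.
#' @export
pair_opx_barrels <- function(genes, sequences, classifications,
                             queries = barrel_queries(), window = 10L,
                             e_max = 1e-5, full_cov = 0.80,
                             module_cov = 0.50) {
  hits <- list()
  match_cache <- new.env(parent = emptyenv())
  cached_match <- function(pid) {
    if (!is.null(got <- get0(pid, envir = match_cache))) return(got$m)
    if (!pid %in% names(sequences)) { m <- NULL } else {
      m <- match_barrel(as.character(sequences[[pid]]), queries,
                        e_max = e_max, full_cov = full_cov,
                        module_cov = module_cov)
    }
    assign(pid, list(m = m), envir = match_cache)
    m
  }
  opx <- classifications[classifications$class != "NOT_OPX", , drop = FALSE]
  for (gid in unique(genes$genome_id)) {
    g <- genes[genes$genome_id == gid, , drop = FALSE]
    anchors <- g[g$protein_id %in% opx$protein_id, , drop = FALSE]
    for (i in seq_len(nrow(anchors))) {
      a <- anchors[i, ]
      cls <- opx$class[match(a$protein_id, opx$protein_id)]
      nb <- neighborhood(g, a$gene_index, window)
      for (j in seq_len(nrow(nb))) {
        m <- cached_match(nb$protein_id[[j]])
        if (is.null(m)) next
        hits[[length(hits) + 1L]] <- data.frame(
          genome_id = gid, opx_protein_id = a$protein_id,
          opx_class = cls, barrel_protein_id = nb$protein_id[[j]],
          gene_offset = nb$gene_index[[j]] - a$gene_index,
          query = m$query, match_type = m$match_type,
          e_value = m$e_value, coverage_full = m$coverage_full,
          coverage_module = m$coverage_module, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(genome_id = character(), opx_protein_id = character(),
                      opx_class = character(), barrel_protein_id = character(),
                      gene_offset = integer(), query = character(),
                      match_type = character(), e_value = numeric(),
                      coverage_full = numeric(), coverage_module = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Cross-tabulate synteny hits by query and OPX class
#'
#' Builds the Table-1-style cross-tab: one row per query template and match
#' type, with the total count and per-OPX-class counts. Zero cells are kept
#' as 0 internally; [format_synteny_table()] renders them as em dashes for
#' reporting.
#'
#' @param hits synteny hits from [pair_opx_barrels()].
#' @param query_names row universe of query templates (defaults to the
#'   queries present in `hits`).
#' @return data.frame with columns `query`, `match_type`, `total` and one
#'   column per OPX class; `total` equals the row sum over class columns.
#' @export
tabulate_synteny <- function(hits, query_names = NULL) {
  classes <- setdiff(OPX_CLASSES, "NOT_OPX")
  if (is.null(query_names)) query_names <- unique(hits$query)
  grid <- expand.grid(query = query_names,
                      match_type = c("full_length", "module_only"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$query, query_names), grid$match_type), ]
  counts <- matrix(0L, nrow(grid), length(classes),
                   dimnames = list(NULL, classes))
  if (nrow(hits)) {
    for (i in seq_len(nrow(grid))) {
      sub <- hits[hits$query == grid$query[i] &
                    hits$match_type == grid$match_type[i], , drop = FALSE]
      tab <- table(factor(sub$opx_class, levels = classes))
      counts[i, ] <- as.integer(tab)
    }
  }
  out <- cbind(grid, total = rowSums(counts), as.data.frame(counts))
  rownames(out) <- NULL
  out
}

#' @rdname tabulate_synteny
#' @param tab a cross-tab from [tabulate_synteny()].
#' @return `format_synteny_table`: the same table with zero counts rendered
#'   as `"-"` (character columns).
#' @export
format_synteny_table <- function(tab) {
  numcols <- vapply(tab, is.numeric, logical(1))
  for (cn in names(tab)[numcols]) {
    tab[[cn]] <- ifelse(tab[[cn]] == 0, "−", as.character(tab[[cn]]))
  }
  tab
}

#' Intergenic distance between two genes
#'
#' The number of base pairs strictly between the two genes:
#' `(later start) - (earlier end) - 1`. Overlapping genes give a negative
#' value (the overlap length, negated, minus adjacency).
#'
#' @param a,b single-row gene records (same `genome_id`).
#' @return integer gap in bp.
#' @export
intergenic_distance <- function(a, b) {
  if (a$genome_id != b$genome_id)
    stop("genes are on different replicons")
  if (a$start_bp > b$start_bp) { tmp <- a; a <- b; b <- tmp }
  as.integer(b$start_bp - a$end_bp - 1L)
}

#' Read and write gene tables as GFF3
#'
#' Gene-order tables are exchanged as GFF3 CDS features whose attributes
#' carry `locus_tag`, `protein_id` and the 0-based `gene_index`; the
#' replicon (`genome_id`) maps to the GFF3 seqid. I/O goes through
#' rtracklayer.
#'
#' @param genes gene table (see [gen_genome()]).
#' @param path GFF3 file path.
#' @return `read_genes_gff3`: a gene table data.frame sorted by replicon
#'   and gene index.
#' @export
write_genes_gff3 <- function(genes, path) {
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$genome_id,
    ranges = IRanges::IRanges(genes$start_bp, genes$end_bp),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$source <- "opxtools"
  gr$phase <- 0L
  gr$ID <- genes$locus_tag
  gr$locus_tag <- genes$locus_tag
  gr$protein_id <- genes$protein_id
  gr$gene_index <- genes$gene_index
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_gene_records())
  out <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene_index = as.integer(gr$gene_index),
    locus_tag = as.character(gr$locus_tag),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = as.character(gr$protein_id),
    stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$gene_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a Table-1-style synteny report
#'
#' @param tab cross-tab from [tabulate_synteny()].
#' @param path output TSV path.
#' @param dash render zero cells as dashes (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_synteny_table <- function(tab, path, dash = TRUE) {
  if (dash) tab <- format_synteny_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
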