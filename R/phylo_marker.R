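#' Extract Poly_export marker sequences
#'
#' The Poly_export domain is conserved across all OPX classes and serves as
#' the phylogenetic marker. For each protein with a resolved architecture,
#' the subsequence of its N-terminal-most Poly_export span is extracted
#' (when a protein carries several Poly_export hits, only the most
#' N-terminal one is used). Proteins without a Poly_export domain are
#' excluded; proteins lacking a sequence are skipped with a warning.
#'
#' @param architectures named list of `opx_architecture` objects (see
#'   [resolve_architectures()]).
#' @param sequences `AAStringSet` keyed by protein id.
#' @return data.frame of marker records: `protein_id`, `marker_start`,
#'   `marker_end` (1-based inclusive), `marker_seq`.
#' @export
extract_marker_sequences <- function(architectures, sequences) {
  rows <- list()
  skipped <- character()
  for (arch in architectures) {
    pe <- arch$domains[arch$domains$domain_name == "Poly_export", ,
                       drop = FALSE]
    if (nrow(pe) == 0L) next
    pe <- pe[which.min(pe$start), ]
    pid <- arch$protein_id
    if (!pid %in% names(sequences)) {
      skipped <- c(skipped, pid)
      next
    }
    seq <- as.character(sequences[[pid]])
    if (pe$end > nchar(seq))
      stop("Poly_export coordinates exceed sequence length for protein ", pid)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = pid, marker_start = pe$start, marker_end = pe$end,
      marker_seq = substr(seq, pe$start, pe$end), stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("no sequence available for ", length(skipped), " protein(s): ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), marker_start = integer(),
                      marker_end = integer(), marker_seq = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Write marker sequences as FASTA
#'
#' @param markers marker records from [extract_marker_sequences()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(markers, path) {
  set <- Biostrings::AAStringSet(setNames(markers$marker_seq,
                                          markers$protein_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Build tree-annotation layers for OPX markers
#'
#' Assembles the four annotation rings drawn around the marker phylogeny:
#' the OPX class, the phylum-level taxonomy, whether a beta-barrel
#' homologue is encoded nearby (true iff the protein anchors at least one
#' synteny hit), and the protein length.
#'
#' @param classified data.frame from [classify_proteins()]; must carry
#'   `protein_id`, `class`, `length_aa`.
#' @param synteny_hits data.frame from [pair_opx_barrels()] (may be empty).
#' @param taxonomy data.frame with `protein_id` and `taxonomy_phylum`;
#'   every classified protein must be present.
#' @return data.frame of annotations: `leaf_id`, `ring1_class`,
#'   `ring2_phylum`, `ring3_barrel_nearby`, `ring4_length`.
#' @export
build_annotations <- function(classified, synteny_hits = NULL,
                              taxonomy = NULL) {
  if (is.null(taxonomy)) {
    if (!"taxonomy_phylum" %in% names(classified))
      stop("taxonomy must be supplied (or present in 'classified')")
    taxonomy <- classified[c("protein_id", "taxonomy_phylum")]
  }
  missing <- setdiff(classified$protein_id, taxonomy$protein_id)
  if (length(missing))
    stop("no taxonomy for protein(s): ", paste(head(missing, 5),
                                               collapse = ", "))
  barrel_anchors <- if (is.null(synteny_hits) || nrow(synteny_hits) == 0L)
    character() else unique(synteny_hits$opx_protein_id)
  data.frame(
    leaf_id = classified$protein_id,
    ring1_class = classified$class,
    ring2_phylum = taxonomy$taxonomy_phylum[
      match(classified$protein_id, taxonomy$protein_id)],
    ring3_barrel_nearby = classified$protein_id %in% barrel_anchors,
    ring4_length = classified$length_aa,
    stringsAsFactors = FALSE)
}

#' Write and re-read ring-annotation files
#'
#' Each ring is written as its own two-column TSV (`leaf_id`, value) under
#' `dir`; [read_ring_files()] joins them back into the annotation table.
#'
#' @param annotations data.frame from [build_annotations()].
#' @param dir output directory (created if needed).
#' @return `write_ring_files`: the four file paths, invisibly;
#'   `read_ring_files`: the reassembled annotation data.frame.
#' @export
write_ring_files <- function(annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rings <- c("ring1_class", "ring2_phylum", "ring3_barrel_nearby",
             "ring4_length")
  paths <- file.path(dir, paste0(rings, ".tsv"))
  for (i in seq_along(rings)) {
    write.table(annotations[c("leaf_id", rings[[i]])], paths[[i]],
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_ring_files
#' @export
read_ring_files <- function(dir) {
  rings <- c("ring1_class", "ring2_phylum", "ring3_barrel_nearby",
             "ring4_length")
  tabs <- lapply(rings, function(r) {
    read.delim(file.path(dir, paste0(r, ".tsv")), stringsAsFactors = FALSE)
  })
  out <- tabs[[1]]
  for (i in 2:4) out <- merge(out, tabs[[i]], by = "leaf_id", sort = FALSE)
  out
}

#' Join annotations onto a phylogenetic tree
#'
#' Reads a newick tree (via ape) and joins the annotation rings to its
#' leaves. Leaves with no annotation are reported in the `unmatched`
#' attribute rather than silently dropped.
#'
#' @param newick path to a newick file, or a newick string.
#' @param annotations data.frame from [build_annotations()].
#' @return data.frame of annotated leaves (one row per matched leaf, in
#'   tree tip order) with attribute `unmatched` listing leaf names absent
#'   from the annotations.
#' @export
attach_to_tree <- function(newick, annotations) {
  tree <- tryCatch({
    if (length(newick) == 1L && file.exists(newick)) ape::read.tree(newick)
    else ape::read.tree(text = newick)
  }, error = function(e) stop("malformed newick input: ",
                              conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick input")
  tips <- tree$tip.label
  tips <- tips[!is.na(tips) & nzchar(tips)]
  matched <- tips[tips %in% annotations$leaf_id]
  unmatched <- setdiff(tips, annotations$leaf_id)
  out <- annotations[match(matched, annotations$leaf_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Align markers and infer a tree with external tools
#'
#' Multiple-sequence alignment and maximum-likelihood tree inference are
#' not implemented here; they are delegated to external command-line tools
#' (an aligner such as MAFFT or MUSCLE, and FastTree) when those are
#' available on the PATH. The function writes the marker FASTA, runs
#' `aligner_cmd` then `tree_cmd`, and returns the newick path. Tests and
#' the packaged examples use a pre-computed fixture tree instead, so the
#' external tools are never required.
#'
#' @param markers marker records from [extract_marker_sequences()].
#' @param out_dir working directory for intermediate files.
#' @param aligner_cmd command template for the aligner; `%in%`/`%out%` are
#'   substituted with file paths.
#' @param tree_cmd command template for tree inference.
#' @return path to the newick file.
#' @export
infer_marker_tree <- function(markers, out_dir = tempdir(),
                              aligner_cmd = "mafft --retree 2 %in% > %out%",
                              tree_cmd = "fasttree %in% > %out%") {
  fasta <- file.path(out_dir, "markers.fasta")
  aln <- file.path(out_dir, "markers.aln")
  nwk <- file.path(out_dir, "markers.nwk")
  write_marker_fasta(markers, fasta)
  run <- function(tpl, infile, outfile) {
    cmd <- gsub("%out%", shQuote(outfile),
                gsub("%in%", shQuote(infile), tpl, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0) stop("external command failed: ", cmd)
  }
  run(aligner_cmd, fasta, aln)
  run(tree_cmd, aln, nwk)
  nwk
}
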