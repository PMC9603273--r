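#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with validation:
#' the profile-search E-value cutoff, the synteny window, the barrel
#' coverage thresholds, the trace resampling step, the hydrophobic
#' fraction, a global seed, and input/output paths. Configurations
#' serialize to JSON and round-trip exactly.
#'
#' @param e_value_cutoff per-domain E-value cutoff (default 1e-5).
#' @param synteny_window gene-neighborhood half width (default 10).
#' @param full_coverage,module_coverage barrel match-type thresholds
#'   (defaults 0.80 / 0.50).
#' @param resample_step trace sampling step in nm (default 0.1).
#' @param hydrophobic_fraction OM hydrophobic fraction (default 0.40).
#' @param seed integer seed driving all randomness.
#' @param input_dir,out_dir paths for pipeline inputs/outputs.
#' @return object of class `opx_config`.
#' @export
opx_config <- function(e_value_cutoff = 1e-5, synteny_window = 10L,
                       full_coverage = 0.80, module_coverage = 0.50,
                       resample_step = 0.1, hydrophobic_fraction = 0.40,
                       seed = 1L, input_dir = NULL, out_dir = tempdir()) {
  if (e_value_cutoff <= 0) stop("e_value_cutoff must be > 0")
  if (synteny_window < 0) stop("synteny_window must be >= 0")
  if (full_coverage <= 0 || full_coverage > 1 ||
      module_coverage <= 0 || module_coverage > 1)
    stop("coverage thresholds must be in (0, 1]")
  if (resample_step <= 0) stop("resample_step must be > 0")
  if (hydrophobic_fraction <= 0 || hydrophobic_fraction > 1)
    stop("hydrophobic_fraction must be in (0, 1]")
  structure(list(e_value_cutoff = e_value_cutoff,
                 synteny_window = as.integer(synteny_window),
                 full_coverage = full_coverage,
                 module_coverage = module_coverage,
                 resample_step = resample_step,
                 hydrophobic_fraction = hydrophobic_fraction,
                 seed = as.integer(seed),
                 input_dir = input_dir, out_dir = out_dir),
            class = "opx_config")
}

#' @rdname opx_config
#' @param config an `opx_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname opx_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(opx_config, x)
}

#' Run the classification stage
#'
#' Reads a domain table (domtblout dialect), fold-region TSV and optional
#' protein-record TSV from `config$input_dir` (files `domain_hits.domtbl`,
#' `fold_regions.tsv`, `proteins.tsv`), classifies every protein, and
#' writes `classification.tsv` plus `class_summary.tsv` to
#' `config$out_dir`.
#'
#' @param config an [opx_config()]; `input_dir` must exist.
#' @return the classification data.frame, invisibly.
#' @export
run_classify <- function(config) {
  ind <- config$input_dir
  if (is.null(ind) || !dir.exists(ind))
    stop("input_dir does not exist: ", if (is.null(ind)) "NULL" else ind)
  dom_path <- file.path(ind, "domain_hits.domtbl")
  fold_path <- file.path(ind, "fold_regions.tsv")
  if (!file.exists(dom_path))
    stop("missing input: ", dom_path)
  hits <- read_domtbl(dom_path, e_max = config$e_value_cutoff)
  regions <- if (file.exists(fold_path)) read_fold_regions(fold_path)
             else empty_fold_regions()
  prot_path <- file.path(ind, "proteins.tsv")
  proteins <- if (file.exists(prot_path))
    read.delim(prot_path, stringsAsFactors = FALSE) else NULL
  classified <- classify_proteins(hits, regions, proteins,
                                  e_max = config$e_value_cutoff)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  write_classification(classified,
                       file.path(config$out_dir, "classification.tsv"),
                       file.path(config$out_dir, "class_summary.tsv"))
  message(sprintf("classify: %d proteins read, %d hits kept, classes: %s",
                  nrow(classified), sum(hits$e_value <= config$e_value_cutoff),
                  paste(names(table(classified$class)),
                        table(classified$class), sep = "=", collapse = " ")))
  invisible(classified)
}

#' Run the full pipeline on a seeded synthetic study
#'
#' End-to-end demonstration and integration entry point: generates a
#' synthetic study from `config$seed` (planted proteome, one genome with a
#' planted OPX/barrel adjacency, three membrane trace pairs, correlated
#' thickness/length pairs), then runs every stage - classification,
#' synteny, marker extraction, ring annotations, envelope geometry and
#' correlation - writing all artifacts plus a checksum manifest to
#' `config$out_dir`. All randomness derives from `config$seed`, so reruns
#' are byte-identical.
#'
#' @param config an [opx_config()].
#' @param n_proteins number of planted proteins (default 60).
#' @return named list of output file paths (the manifest contents),
#'   invisibly.
#' @export
run_all <- function(config, n_proteins = 60L) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- config$seed

  # stage 1: synthetic proteome -> classification
  mix <- c(CLASS1 = 0.381, CLASS2A = 0.026, CLASS2B = 0.109, CLASS3 = 0.484)
  specs <- random_protein_specs(n_proteins, mix, seed = seed)
  tabs <- gen_domain_tables(specs, seed = seed + 1L)
  classified <- classify_proteins(tabs$domain_hits, tabs$fold_regions,
                                  tabs$proteins,
                                  e_max = config$e_value_cutoff)
  class_path <- file.path(out, "classification.tsv")
  summary_path <- file.path(out, "class_summary.tsv")
  write_classification(classified, class_path, summary_path)
  message("classify: ", nrow(classified), " proteins")

  # stage 2: synthetic genome -> synteny table
  queries <- barrel_queries()
  pairs <- data.frame(opx_index = c(10L, 20L), barrel_index = c(11L, 22L),
                      query = c("MXAN_7418", "PgaA_bb"),
                      match_type = c("full_length", "module_only"),
                      opx_class = c("CLASS3", "CLASS1"),
                      stringsAsFactors = FALSE)
  genome <- gen_genome("syng1", 30L, pairs, seed = seed + 2L,
                       queries = queries)
  syn_hits <- pair_opx_barrels(genome$genes, genome$sequences,
                               genome$classifications, queries,
                               window = config$synteny_window,
                               e_max = config$e_value_cutoff,
                               full_cov = config$full_coverage,
                               module_cov = config$module_coverage)
  syn_path <- file.path(out, "synteny_table.tsv")
  write_synteny_table(tabulate_synteny(syn_hits, queries$name), syn_path)
  message("synteny: ", nrow(syn_hits), " hits")

  # stage 3: marker FASTA + ring annotations
  archs <- resolve_architectures(tabs$domain_hits,
                                 e_max = config$e_value_cutoff)
  marker_seqs <- synth_protein_sequences(tabs$proteins, seed = seed + 3L)
  markers <- extract_marker_sequences(archs, marker_seqs)
  marker_path <- file.path(out, "markers.fasta")
  write_marker_fasta(markers, marker_path)
  ann <- build_annotations(classified, syn_hits)
  ring_dir <- file.path(out, "rings")
  write_ring_files(ann, ring_dir)
  message("markers: ", nrow(markers), " Poly_export sequences")

  # stage 4: envelope geometry + correlation
  tomo <- lapply(1:3, function(i)
    gen_membrane_pair(327, 100, noise_sd = 10, curvature_amplitude = 20,
                      seed = seed + 3L + i,
                      tomogram_id = paste0("tomo", i)))
  profiles <- lapply(tomo, function(tp)
    distance_profile(tp$om, tp$im, step = config$resample_step))
  envelope <- thickness_summary(profiles, rep("Myxococcus-like", 3))
  env_path <- file.path(out, "envelope_summary.tsv")
  write.table(envelope, env_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cp <- gen_correlated_pairs(0.15, 92, seed = seed + 7L)
  corr <- correlate_thickness(cp)
  corr_path <- file.path(out, "correlation.tsv")
  write.table(data.frame(subset = corr$subset, pearson_r = corr$pearson_r,
                         spearman_rho = corr$spearman_rho,
                         n_pairs = corr$n_pairs),
              corr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("envelope: grand mean %.1f A; correlation r = %.3f",
                  envelope$grand_mean_A[[1]], corr$pearson_r))

  files <- c(classification = class_path, class_summary = summary_path,
             synteny_table = syn_path, markers = marker_path,
             envelope_summary = env_path, correlation = corr_path)
  manifest <- data.frame(artifact = names(files), file = basename(files),
                         md5 = unname(md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(as.list(files))
}

# Deterministic per-protein sequences consistent with planted architectures:
# random residues of the recorded length (markers are substrings of these).
synth_protein_sequences <- function(proteins, seed = 1L) {
  with_seed(seed, {
    seqs <- vapply(proteins$length_aa, random_aa, character(1))
    Biostrings::AAStringSet(setNames(seqs, proteins$protein_id))
  })
}
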