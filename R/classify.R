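#' Reference coordinates of the Wza_C segment on the 2J58 template
#'
#' The OM-spanning amphipathic helix of Wza (PDB 2J58) occupies template
#' residues 326-359 (34 aa). Fold-recognition homology covering at least 10
#' of those 34 template positions counts as a true Wza_C segment.
#'
#' @return list with `template_start`, `template_end`, `min_covered_aa`,
#'   `segment_length`.
#' @export
wza_c_segment_ref <- function() {
  list(template_start = 326L, template_end = 359L,
       min_covered_aa = 10L, segment_length = 34L)
}

# Template span of the Poly_export domain on 2J58, used by the OPX
# membership gate when a protein has fold-level but no sequence-level
# Poly_export evidence. Configurable via classify_opx().
POLYEXPORT_2J58_SPAN <- c(28L, 97L)

#' Detect a Wza_C segment from fold-homology regions
#'
#' A protein carries a true Wza_C segment when the union of its 2J58
#' homology regions covers at least `min_covered_aa` template positions
#' within the Wza_C segment interval (template aa 326-359). Coverage is
#' counted as template positions covered by aligned regions, with
#' overlapping regions merged so no position is counted twice.
#'
#' @param regions data.frame of fold homology regions for one protein
#'   (see [read_fold_regions()]).
#' @param segment reference segment coordinates, see [wza_c_segment_ref()].
#' @return `TRUE` or `FALSE`; empty input gives `FALSE`.
#' @examples
#' r <- data.frame(protein_id = "p", template = "WZA_2J58",
#'                 q_start = 300, q_end = 340, t_start = 326, t_end = 340,
#'                 probability = 98)
#' detect_wza_c_segment(r)   # 15 positions covered -> TRUE
#' @export
detect_wza_c_segment <- function(regions, segment = wza_c_segment_ref()) {
  if (is.null(regions) || nrow(regions) == 0L) return(FALSE)
  reg <- regions[regions$template == "WZA_2J58", , drop = FALSE]
  if (nrow(reg) == 0L) return(FALSE)
  lo <- pmax(reg$t_start, segment$template_start)
  hi <- pmin(reg$t_end, segment$template_end)
  keep <- lo <= hi
  if (!any(keep)) return(FALSE)
  covered <- unique(unlist(mapply(seq, lo[keep], hi[keep], SIMPLIFY = FALSE)))
  length(covered) >= segment$min_covered_aa
}

#' Assign an OPX class from architecture and fold evidence
#'
#' Implements the class decision rules for outer-membrane polysaccharide
#' export (OPX) proteins:
#'
#' * Membership gate: a protein is an OPX candidate only with Poly_export
#'   evidence - a Poly_export domain hit in its architecture, or a 2J58
#'   homology region overlapping the template's Poly_export span.
#' * GfcC evidence (sequence- and fold-level merged): a GfcC (PF06251)
#'   domain hit, or a 3P42 homology region covering at least `gfcc_min_aa`
#'   residues of the query.
#' * Wza_C evidence: a qualifying Wza_C segment (see
#'   [detect_wza_c_segment()]) or a Wza_C (PF18412) domain hit.
#'
#' With GfcC evidence the protein is Class 2, subdivided by whether the
#' GfcC evidence precedes the Poly_export domain (query-coordinate
#' midpoints) and whether a Wza_C segment is present: 2A (GfcC after, no
#' Wza_C), 2B (GfcC after, Wza_C), 2C (GfcC before, no Wza_C), 2D (GfcC
#' before, Wza_C). Without GfcC evidence, a Wza_C segment gives Class 1
#' (Wza-like), otherwise Class 3 (truncated, Poly_export-SLBB only).
#' Proteins failing the gate - including stand-alone GfcC homologues with
#' no Poly_export evidence - return `NOT_OPX`.
#'
#' @param arch an `opx_architecture` (see [resolve_architecture()]).
#' @param regions fold homology regions for the same protein (may be empty).
#' @param gfcc_min_aa minimum query residues a 3P42 region must span to
#'   count as GfcC evidence (default 30).
#' @param polyexport_span template interval of the Poly_export domain on
#'   2J58, used by the membership gate.
#' @return one of `"CLASS1"`, `"CLASS2A"`, `"CLASS2B"`, `"CLASS2C"`,
#'   `"CLASS2D"`, `"CLASS3"`, `"NOT_OPX"`.
#' @export
classify_opx <- function(arch, regions = empty_fold_regions(),
                         gfcc_min_aa = 30L,
                         polyexport_span = POLYEXPORT_2J58_SPAN) {
  stopifnot(inherits(arch, "opx_architecture"))
  if (is.null(regions)) regions <- empty_fold_regions()
  if (nrow(regions) > 0L) {
    rpid <- unique(regions$protein_id)
    if (!is.na(arch$protein_id) && length(rpid) &&
        !all(rpid == arch$protein_id))
      stop("classify_opx: architecture and regions refer to different proteins")
  }
  dom <- arch$domains
  pe_dom <- dom[dom$domain_name == "Poly_export", , drop = FALSE]
  wza_regions <- regions[regions$template == "WZA_2J58", , drop = FALSE]

  # membership gate: Poly_export evidence at sequence or fold level
  pe_fold <- wza_regions[pmax(wza_regions$t_start, polyexport_span[1]) <=
                           pmin(wza_regions$t_end, polyexport_span[2]), ,
                         drop = FALSE]
  if (nrow(pe_dom) == 0L && nrow(pe_fold) == 0L) return("NOT_OPX")

  # query-coordinate midpoint of the (N-terminal-most) Poly_export evidence
  pe_mid <- if (nrow(pe_dom)) min((pe_dom$start + pe_dom$end) / 2)
            else min((pe_fold$q_start + pe_fold$q_end) / 2)

  # GfcC evidence and its query midpoint
  gf_dom <- dom[dom$domain_name == "GfcC", , drop = FALSE]
  gf_fold <- regions[regions$template == "GFCC_3P42" &
                       (regions$q_end - regions$q_start + 1L) >= gfcc_min_aa, ,
                     drop = FALSE]
  has_gfcc <- nrow(gf_dom) > 0L || nrow(gf_fold) > 0L
  has_wza <- detect_wza_c_segment(regions) || any(dom$domain_name == "Wza_C")

  if (!has_gfcc) return(if (has_wza) "CLASS1" else "CLASS3")

  gf_mid <- if (nrow(gf_dom)) min((gf_dom$start + gf_dom$end) / 2)
            else min((gf_fold$q_start + gf_fold$q_end) / 2)
  gfcc_before <- gf_mid < pe_mid
  if (gfcc_before) {
    if (has_wza) "CLASS2D" else "CLASS2C"
  } else {
    if (has_wza) "CLASS2B" else "CLASS2A"
  }
}

#' Classify every protein in a hit table
#'
#' Convenience wrapper: filters hits at the E-value cutoff, resolves one
#' architecture per protein, and classifies each against its fold-homology
#' regions. Proteins present only in `regions` (fold evidence without any
#' domain hit) are classified from an empty architecture.
#'
#' @param hits data.frame of domain hits (many proteins).
#' @param regions data.frame of fold homology regions (many proteins).
#' @param proteins optional data.frame of protein records
#'   (`protein_id`, `length_aa`, `signal_label`, ...); when given, its
#'   columns are carried into the result.
#' @inheritParams classify_opx
#' @inheritParams resolve_architectures
#' @return data.frame with one row per protein: `protein_id`, `class`,
#'   `slbb_count`, `has_wza_c`, plus any protein-record columns.
#' @export
classify_proteins <- function(hits, regions = empty_fold_regions(),
                              proteins = NULL, e_max = 1e-5,
                              gfcc_min_aa = 30L) {
  archs <- resolve_architectures(hits, e_max = e_max)
  ids <- union(names(archs), unique(regions$protein_id))
  if (!is.null(proteins)) ids <- union(ids, proteins$protein_id)
  ids <- sort(ids)
  rows <- lapply(ids, function(pid) {
    arch <- archs[[pid]]
    if (is.null(arch)) arch <- resolve_architecture(empty_domain_hits())
    reg <- regions[regions$protein_id == pid, , drop = FALSE]
    if (nrow(reg) > 0L && is.na(arch$protein_id)) arch$protein_id <- pid
    data.frame(protein_id = pid,
               class = classify_opx(arch, reg, gfcc_min_aa = gfcc_min_aa),
               slbb_count = arch$slbb_count,
               has_wza_c = detect_wza_c_segment(reg) ||
                 any(arch$domains$domain_name == "Wza_C"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(protein_id = character(),
                                      class = character(),
                                      slbb_count = integer(),
                                      has_wza_c = logical(),
                                      stringsAsFactors = FALSE)
  if (!is.null(proteins)) {
    extra <- proteins[match(out$protein_id, proteins$protein_id),
                      setdiff(names(proteins), "protein_id"), drop = FALSE]
    out <- cbind(out, extra)
    rownames(out) <- NULL
  }
  out
}

#' Summarize OPX classes
#'
#' Per-class counts, proportions of all OPX hits (denominator excludes
#' `NOT_OPX`), median protein length (lower median for even counts) and
#' lipoprotein (SPII signal) fraction.
#'
#' @param classified data.frame with columns `class`, and optionally
#'   `length_aa` and `signal_label` (as produced by [classify_proteins()]
#'   with protein records).
#' @return an object of class `opx_class_summary`: a data.frame with one
#'   row per OPX class plus attributes `n_total` and `n_opx`.
#' @export
summarize_classes <- function(classified) {
  opx_levels <- setdiff(OPX_CLASSES, "NOT_OPX")
  n_opx <- sum(classified$class %in% opx_levels)
  rows <- lapply(opx_levels, function(cl) {
    sub <- classified[classified$class == cl, , drop = FALSE]
    med <- if ("length_aa" %in% names(sub) && nrow(sub))
      lower_median(sub$length_aa) else NA_real_
    spii <- if ("signal_label" %in% names(sub) && nrow(sub))
      mean(sub$signal_label == "SPII") else NA_real_
    data.frame(class = cl, count = nrow(sub),
               proportion = if (n_opx > 0) nrow(sub) / n_opx else 0,
               median_length_aa = med, spii_fraction = spii,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_total = nrow(classified), n_opx = n_opx,
            class = c("opx_class_summary", "data.frame"))
}

#' @export
print.opx_class_summary <- function(x, ...) {
  cat("OPX classification summary:", attr(x, "n_opx"), "OPX proteins of",
      attr(x, "n_total"), "classified\n")
  y <- as.data.frame(x)
  y$proportion <- sprintf("%.1f%%", 100 * y$proportion)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write classification results
#'
#' Writes the per-protein classification TSV (`protein_id`, `genome_id`,
#' `class`, `slbb_count`, `has_wza_c`, `length_aa`, `signal_label`, when
#' available) and, optionally, the class-summary TSV.
#'
#' @param classified data.frame from [classify_proteins()].
#' @param path output TSV for per-protein rows.
#' @param summary_path optional output TSV for [summarize_classes()] rows.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classified, path, summary_path = NULL) {
  preferred <- c("protein_id", "genome_id", "class", "slbb_count",
                 "has_wza_c", "length_aa", "signal_label")
  cols <- c(intersect(preferred, names(classified)),
            setdiff(names(classified), preferred))
  write.table(classified[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- summarize_classes(classified)
    write.table(as.data.frame(s), summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
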