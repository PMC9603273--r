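#' Read a HMMER3 per-domain table (domtblout dialect)
#'
#' Parses the whitespace-delimited per-domain tabular output written by
#' `hmmscan --domtblout`. In that orientation the *target* is the profile
#' (Pfam domain) and the *query* is the protein. Only the fields the
#' downstream architecture logic needs are retained: target (domain) name,
#' query (protein) name, the per-domain independent E-value (i-Evalue), the
#' per-domain bit score and the alignment coordinates on the protein.
#'
#' Rows above the E-value cutoff are *retained* but flagged in the
#' `above_cutoff` column, so that filtering stays a separate, explicit step
#' ([filter_hits()]). The cutoff is applied to the per-domain i-Evalue, not
#' the full-sequence E-value.
#'
#' @param path path to a domtblout file; `#` comment lines are skipped.
#' @param e_max E-value threshold used only to set the `above_cutoff` flag
#'   (default `1e-5`).
#' @return a data.frame of domain hits with columns `protein_id`,
#'   `domain_name` (one of Poly_export, SLBB, Wza_C, GfcC, other),
#'   `ali_start`, `ali_end` (1-based inclusive aa coordinates), `e_value`,
#'   `bit_score`, `above_cutoff`.
#' @examples
#' hits <- read_domtbl(system.file("extdata", "example_domtbl.txt",
#'                                 package = "opxtools"))
#' @export
read_domtbl <- function(path, e_max = 1e-5) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) return(empty_domain_hits())
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[[i]]
    f <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout row at line ", ln, ": expected >= 22 fields, got ",
           length(f))
    ali_start <- suppressWarnings(as.integer(f[[18]]))
    ali_end <- suppressWarnings(as.integer(f[[19]]))
    e_value <- suppressWarnings(as.numeric(f[[13]]))
    bit_score <- suppressWarnings(as.numeric(f[[14]]))
    if (anyNA(c(ali_start, ali_end, e_value, bit_score)))
      stop("malformed domtblout row at line ", ln, ": non-numeric coordinate or score")
    if (ali_start > ali_end)
      stop("malformed domtblout row at line ", ln, ": ali_start > ali_end")
    if (e_value < 0)
      stop("malformed domtblout row at line ", ln, ": negative E-value")
    dom <- f[[1]]
    if (!dom %in% OPX_DOMAINS) dom <- "other"
    out[[i]] <- data.frame(
      protein_id = f[[4]], domain_name = dom,
      ali_start = ali_start, ali_end = ali_end,
      e_value = e_value, bit_score = bit_score,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  hits$above_cutoff <- hits$e_value > e_max
  rownames(hits) <- NULL
  hits
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             ali_start = integer(), ali_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             above_cutoff = logical(), stringsAsFactors = FALSE)
}

#' Write domain hits as a HMMER3 domtblout-dialect table
#'
#' Emits the 23-column whitespace-delimited per-domain layout of
#' `hmmscan --domtblout` (unused columns carry placeholder values), so that
#' [read_domtbl()] round-trips the hit list exactly.
#'
#' @param hits data.frame as returned by [read_domtbl()] (the
#'   `above_cutoff` column is ignored; it is recomputed on read).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_domtbl <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits) == 0L) return(invisible(path))
  acc <- PFAM_ACCESSIONS[hits$domain_name]
  acc[is.na(acc)] <- "-"
  span <- hits$ali_end - hits$ali_start + 1L
  lines <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.3g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    hits$domain_name, acc, span, hits$protein_id, "-", hits$ali_end,
    hits$e_value, hits$bit_score, 0, 1L, 1L, hits$e_value, hits$e_value,
    hits$bit_score, 0, 1L, span, hits$ali_start, hits$ali_end,
    hits$ali_start, hits$ali_end, 0.95, "-")
  writeLines(lines, con)
  invisible(path)
}

#' Filter domain hits by E-value
#'
#' Retains hits whose per-domain E-value passes the profile-search cutoff,
#' preserving input order.
#'
#' @param hits data.frame of domain hits.
#' @param e_max maximum E-value retained (default `1e-5`).
#' @return the subset of `hits` with `e_value <= e_max`.
#' @export
filter_hits <- function(hits, e_max = 1e-5) {
  hits[hits$e_value <= e_max, , drop = FALSE]
}

#' Read / write fold-recognition homology regions
#'
#' Fold-recognition reports are consumed pre-parsed as TSV with columns
#' `protein_id`, `template` (`WZA_2J58`, `GFCC_3P42` or `other`), `q_start`,
#' `q_end`, `t_start`, `t_end` (1-based inclusive on query and template) and
#' `probability` (percent). Coordinates are validated on read.
#'
#' @param path TSV file path.
#' @return data.frame of fold homology regions.
#' @export
read_fold_regions <- function(path) {
  reg <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(reg) == 0L) return(empty_fold_regions())
  needed <- c("protein_id", "template", "q_start", "q_end",
              "t_start", "t_end", "probability")
  missing <- setdiff(needed, names(reg))
  if (length(missing))
    stop("fold-region table missing columns: ", paste(missing, collapse = ", "))
  bad <- which(reg$q_start > reg$q_end | reg$t_start > reg$t_end)
  if (length(bad))
    stop("fold-region row ", bad[[1]], ": start > end")
  if (any(reg$probability < 0 | reg$probability > 100))
    stop("fold-region probability outside [0, 100]")
  reg$template[!reg$template %in% FOLD_TEMPLATES] <- "other"
  reg[needed]
}

empty_fold_regions <- function() {
  data.frame(protein_id = character(), template = character(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             probability = numeric(), stringsAsFactors = FALSE)
}

#' @rdname read_fold_regions
#' @param regions data.frame of fold homology regions.
#' @export
write_fold_regions <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble the ordered domain architecture of one protein
#'
#' Sorts the (cutoff-passing) domain hits of a single protein by alignment
#' start and resolves overlap conflicts. Two hits conflict when their
#' overlap exceeds 50% of the shorter hit's span; the hit with the higher
#' bit score wins, ties broken by lower E-value, then lower start. The
#' resolution is greedy in that priority order, which makes it deterministic,
#' idempotent and insensitive to input row order.
#'
#' `slbb_count` is the number of resolved, non-overlapping SLBB hits
#' (observed 1-14 times in OPX proteins). Hits named `other` are retained in
#' the architecture but ignored by classification.
#'
#' @param hits data.frame of domain hits, all sharing one `protein_id`.
#' @param max_overlap overlap fraction (of the shorter span) above which two
#'   hits conflict (default 0.5).
#' @return an object of class `opx_architecture`: a list with
#'   `protein_id`, `domains` (data.frame sorted by `start`, non-overlapping
#'   beyond `max_overlap`), `slbb_count`, and `gfcc_before_polyexport`
#'   (midpoint comparison when both domains are present at sequence level).
#' @export
resolve_architecture <- function(hits, max_overlap = 0.5) {
  pid <- unique(hits$protein_id)
  if (length(pid) > 1L)
    stop("resolve_architecture: hits span multiple proteins: ",
         paste(pid, collapse = ", "))
  if (nrow(hits) == 0L) {
    return(structure(list(protein_id = if (length(pid)) pid else NA_character_,
                          domains = data.frame(domain_name = character(),
                                               start = integer(), end = integer(),
                                               e_value = numeric(),
                                               bit_score = numeric(),
                                               stringsAsFactors = FALSE),
                          slbb_count = 0L,
                          gfcc_before_polyexport = FALSE),
                     class = "opx_architecture"))
  }
  ord <- order(-hits$bit_score, hits$e_value, hits$ali_start)
  cand <- hits[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (j in kept) {
      ov <- min(cand$ali_end[i], cand$ali_end[j]) -
        max(cand$ali_start[i], cand$ali_start[j]) + 1L
      shorter <- min(cand$ali_end[i] - cand$ali_start[i],
                     cand$ali_end[j] - cand$ali_start[j]) + 1L
      if (ov > max_overlap * shorter) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  res <- cand[kept, , drop = FALSE]
  res <- res[order(res$ali_start, res$ali_end), , drop = FALSE]
  domains <- data.frame(domain_name = res$domain_name,
                        start = res$ali_start, end = res$ali_end,
                        e_value = res$e_value, bit_score = res$bit_score,
                        stringsAsFactors = FALSE)
  rownames(domains) <- NULL
  gfcc_before <- FALSE
  gf <- domains[domains$domain_name == "GfcC", , drop = FALSE]
  pe <- domains[domains$domain_name == "Poly_export", , drop = FALSE]
  if (nrow(gf) && nrow(pe)) {
    gfcc_before <- min((gf$start + gf$end) / 2) < min((pe$start + pe$end) / 2)
  }
  structure(list(protein_id = pid,
                 domains = domains,
                 slbb_count = sum(domains$domain_name == "SLBB"),
                 gfcc_before_polyexport = gfcc_before),
            class = "opx_architecture")
}

#' @export
print.opx_architecture <- function(x, ...) {
  cat("Domain architecture of", x$protein_id, "\n")
  if (nrow(x$domains) == 0L) {
    cat("  (no domains)\n")
  } else {
    cat(" ", paste(sprintf("%s[%d-%d]", x$domains$domain_name,
                           x$domains$start, x$domains$end),
                   collapse = " - "), "\n")
  }
  cat("  SLBB repeats:", x$slbb_count, "\n")
  invisible(x)
}

#' Resolve architectures for a full hit table
#'
#' Splits a multi-protein hit table by `protein_id`, drops hits above the
#' E-value cutoff, and resolves each protein's architecture.
#'
#' @param hits data.frame of domain hits (possibly many proteins).
#' @param e_max per-domain E-value cutoff applied before resolution.
#' @inheritParams resolve_architecture
#' @return named list of `opx_architecture`, one per protein present.
#' @export
resolve_architectures <- function(hits, e_max = 1e-5, max_overlap = 0.5) {
  hits <- filter_hits(hits, e_max)
  if (nrow(hits) == 0L) return(structure(list(), names = character()))
  split_hits <- split(hits, hits$protein_id)
  lapply(split_hits, resolve_architecture, max_overlap = max_overlap)
}
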