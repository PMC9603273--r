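#' Planted protein specification
#'
#' Describes one synthetic protein whose domain-search and fold-recognition
#' evidence will be generated so that classification recovers
#' `planted_class`. SLBB repeat counts follow the 1-14 range observed in
#' real OPX architectures.
#'
#' @param protein_id,genome_id identifiers.
#' @param planted_class one of the OPX classes (or `NOT_OPX`).
#' @param slbb_count number of SLBB repeats, 1-14.
#' @param length_aa protein length; must leave room for the planted domain
#'   spans (see [plan_opx_layout()]); `NA` picks the minimum plus a margin.
#' @param signal_label `"SPI"`, `"SPII"` or `"none"`.
#' @return a list of class `planted_protein_spec`.
#' @export
planted_protein_spec <- function(protein_id, planted_class, slbb_count = 2L,
                                 length_aa = NA_integer_,
                                 signal_label = "SPII",
                                 genome_id = "synth_g1") {
  if (!planted_class %in% OPX_CLASSES)
    stop("unknown class: ", planted_class)
  if (slbb_count < 1L || slbb_count > 14L)
    stop("slbb_count must be within 1-14")
  if (!signal_label %in% c("SPI", "SPII", "none"))
    stop("signal_label must be SPI, SPII or none")
  layout <- plan_opx_layout(planted_class, slbb_count)
  if (is.na(length_aa)) length_aa <- layout$min_length + 20L
  if (length_aa < layout$min_length)
    stop("contradictory spec for ", protein_id, ": length_aa = ", length_aa,
         " leaves no room for the planted ", planted_class,
         " architecture (needs >= ", layout$min_length, " aa)")
  structure(list(protein_id = protein_id, planted_class = planted_class,
                 slbb_count = as.integer(slbb_count),
                 length_aa = as.integer(length_aa),
                 signal_label = signal_label, genome_id = genome_id),
            class = "planted_protein_spec")
}

#' Plan the domain layout of a synthetic OPX architecture
#'
#' Lays domains head-to-tail with short linkers: an optional N-terminal GfcC
#' (Class 2C/2D), the Poly_export domain (91 aa), `slbb_count` SLBB repeats
#' (50 aa each), an optional C-terminal GfcC (Class 2A/2B), and a Wza_C
#' segment slot (Class 1/2B/2D). `NOT_OPX` plants SLBB repeats only.
#'
#' @param class OPX class to plant.
#' @param slbb_count number of SLBB repeats.
#' @return list with `domains` (data.frame `domain_name`, `start`, `end`)
#'   and `min_length` (smallest protein length that fits the layout).
#' @export
plan_opx_layout <- function(class, slbb_count) {
  cursor <- 25L
  doms <- list()
  add <- function(name, span) {
    doms[[length(doms) + 1L]] <<- data.frame(
      domain_name = name, start = cursor, end = cursor + span - 1L,
      stringsAsFactors = FALSE)
    cursor <<- cursor + span + 10L
  }
  if (class %in% c("CLASS2C", "CLASS2D")) add("GfcC", 151L)
  if (class != "NOT_OPX") add("Poly_export", 91L)
  for (i in seq_len(slbb_count)) add("SLBB", 50L)
  if (class %in% c("CLASS2A", "CLASS2B")) add("GfcC", 151L)
  has_wza <- class %in% c("CLASS1", "CLASS2B", "CLASS2D")
  if (has_wza) add("Wza_C", 35L)
  domains <- do.call(rbind, doms)
  list(domains = domains, min_length = cursor - 10L + 4L, has_wza = has_wza)
}

#' Generate planted domain-hit and fold-region tables
#'
#' Emits, for each planted protein, the sequence-level domain hits and
#' fold-recognition homology regions that make [classify_proteins()] recover
#' the planted class:
#'
#' * domain hits for every laid-out domain, with E-values drawn log-uniform
#'   in \[1e-50, 1e-6\] (all below the 1e-5 cutoff);
#' * a 2J58 homology region over the Poly_export span (fold-level
#'   confirmation of the membership gate);
#' * for Wza_C-bearing classes, a 2J58 region covering the full template
#'   segment aa 326-359 near the protein C terminus;
#' * for Class 2, a 3P42 region over the GfcC span;
#' * decoy hits above the cutoff (E-value log-uniform in \[1e-4, 1e-2\]) at
#'   rate `decoy_rate` per protein, to exercise E-value filtering.
#'
#' Generation is deterministic given `seed`.
#'
#' @param specs list of [planted_protein_spec()] objects (may be empty).
#' @param seed integer seed.
#' @param decoy_rate per-protein probability of one above-cutoff decoy hit.
#' @return list with `domain_hits`, `fold_regions` and `proteins`
#'   data.frames (see [read_domtbl()], [read_fold_regions()]).
#' @export
gen_domain_tables <- function(specs, seed = 1L, decoy_rate = 0.1) {
  stopifnot(is.list(specs))
  if (length(specs) == 0L)
    return(list(domain_hits = empty_domain_hits(),
                fold_regions = empty_fold_regions(),
                proteins = empty_protein_records()))
  with_seed(seed, {
    phyla <- c("Proteobacteria", "Myxococcota", "Bacteroidota",
               "Firmicutes", "Actinomycetota")
    hit_rows <- list(); fold_rows <- list(); prot_rows <- list()
    gene_counter <- new.env(parent = emptyenv())
    for (sp in specs) {
      if (!inherits(sp, "planted_protein_spec"))
        stop("specs must be planted_protein_spec objects")
      layout <- plan_opx_layout(sp$planted_class, sp$slbb_count)
      L <- sp$length_aa
      doms <- layout$domains
      n <- nrow(doms)
      ev <- 10^runif(n, -50, -6)
      doms$e_value <- ev
      doms$bit_score <- round(10 + 1.8 * -log10(ev) + runif(n, 0, 4), 1)
      doms$protein_id <- sp$protein_id
      hit_rows[[length(hit_rows) + 1L]] <-
        doms[c("protein_id", "domain_name", "start", "end",
               "e_value", "bit_score")]
      if (runif(1) < decoy_rate) {
        st <- sample.int(max(L - 45L, 1L), 1L)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          protein_id = sp$protein_id,
          domain_name = sample(OPX_DOMAINS, 1L),
          start = st, end = min(st + 39L, L),
          e_value = 10^runif(1, -4, -2),
          bit_score = round(runif(1, 5, 15), 1),
          stringsAsFactors = FALSE)
      }
      if (sp$planted_class != "NOT_OPX") {
        pe <- doms[doms$domain_name == "Poly_export", ][1, ]
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          protein_id = sp$protein_id, template = "WZA_2J58",
          q_start = pe$start, q_end = pe$end,
          t_start = 28L, t_end = 118L,
          probability = round(runif(1, 95, 99.9), 1),
          stringsAsFactors = FALSE)
        if (layout$has_wza) {
          fold_rows[[length(fold_rows) + 1L]] <- data.frame(
            protein_id = sp$protein_id, template = "WZA_2J58",
            q_start = L - 44L, q_end = L - 10L,
            t_start = 325L, t_end = 359L,
            probability = round(runif(1, 90, 99.9), 1),
            stringsAsFactors = FALSE)
        }
        gf <- doms[doms$domain_name == "GfcC", , drop = FALSE]
        if (nrow(gf)) {
          fold_rows[[length(fold_rows) + 1L]] <- data.frame(
            protein_id = sp$protein_id, template = "GFCC_3P42",
            q_start = gf$start[1], q_end = gf$end[1],
            t_start = 10L, t_end = 160L,
            probability = round(runif(1, 90, 99.9), 1),
            stringsAsFactors = FALSE)
        }
      }
      gidx <- get0(sp$genome_id, envir = gene_counter, ifnotfound = 0L)
      assign(sp$genome_id, gidx + 1L, envir = gene_counter)
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        protein_id = sp$protein_id, genome_id = sp$genome_id,
        length_aa = L, signal_label = sp$signal_label,
        taxonomy_phylum = sample(phyla, 1L),
        gene_index = gidx, strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, hit_rows)
    names(hits)[names(hits) == "start"] <- "ali_start"
    names(hits)[names(hits) == "end"] <- "ali_end"
    hits$above_cutoff <- hits$e_value > 1e-5
    rownames(hits) <- NULL
    folds <- if (length(fold_rows)) do.call(rbind, fold_rows)
             else empty_fold_regions()
    rownames(folds) <- NULL
    prots <- do.call(rbind, prot_rows)
    rownames(prots) <- NULL
    list(domain_hits = hits, fold_regions = folds, proteins = prots)
  })
}

empty_protein_records <- function() {
  data.frame(protein_id = character(), genome_id = character(),
             length_aa = integer(), signal_label = character(),
             taxonomy_phylum = character(), gene_index = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Random planted protein specs at given class proportions
#'
#' Draws `n` specs with classes sampled at `class_mix` proportions and SLBB
#' counts uniform in 1-6, for round-trip and recovery experiments.
#'
#' @param n number of proteins.
#' @param class_mix named numeric vector of class proportions (normalized
#'   internally), e.g. `c(CLASS1 = 0.381, CLASS2A = 0.026, CLASS2B = 0.109,
#'   CLASS3 = 0.484)`.
#' @param seed integer seed.
#' @param genome_id genome identifier stamped on every spec.
#' @return list of [planted_protein_spec()].
#' @export
random_protein_specs <- function(n, class_mix, seed = 1L,
                                 genome_id = "synth_g1") {
  stopifnot(n >= 0, all(class_mix >= 0), sum(class_mix) > 0)
  with_seed(seed, {
    classes <- sample(names(class_mix), n, replace = TRUE,
                      prob = class_mix / sum(class_mix))
    lapply(seq_len(n), function(i) {
      planted_protein_spec(
        protein_id = sprintf("synp%05d", i),
        planted_class = classes[[i]],
        slbb_count = sample.int(6L, 1L),
        signal_label = sample(c("SPI", "SPII", "none"), 1L,
                              prob = c(0.25, 0.6, 0.15)),
        genome_id = genome_id)
    })
  })
}

#' Generate a synthetic genome with planted OPX / beta-barrel adjacencies
#'
#' Builds a gene-order table and protein sequences for one replicon.
#' Planted barrel genes carry the named query template's sequence
#' (full-length, or the porin-module subsequence for `module_only`);
#' planted OPX genes are marked in the returned classification table;
#' filler genes carry uniform-random sequences that are *verified at
#' generation time* to fall below the [match_barrel()] threshold, so the
#' planted truth has no false positives by construction.
#'
#' @param genome_id replicon identifier.
#' @param n_genes number of genes on the replicon.
#' @param planted_pairs data.frame with columns `opx_index`, `barrel_index`
#'   (0-based gene indices), `query` (a [barrel_queries()] name),
#'   `match_type` (`"full_length"` or `"module_only"`), and optionally
#'   `opx_class` (default `"CLASS3"`).
#' @param seed integer seed.
#' @param queries barrel query set, see [barrel_queries()].
#' @return list with `genes` (data.frame: `genome_id`, `gene_index`,
#'   `locus_tag`, `start_bp`, `end_bp`, `strand`, `protein_id`),
#'   `sequences` (`AAStringSet` keyed by protein_id), `classifications`
#'   (data.frame for the planted OPX genes) and `truth` (the planted pairs
#'   with protein ids and signed gene offsets).
#' @export
gen_genome <- function(genome_id, n_genes, planted_pairs = NULL,
                       seed = 1L, queries = barrel_queries()) {
  if (n_genes == 0L)
    return(list(genes = empty_gene_records(),
                sequences = Biostrings::AAStringSet(),
                classifications = data.frame(protein_id = character(),
                                             class = character(),
                                             stringsAsFactors = FALSE),
                truth = NULL))
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(opx_index = integer(), barrel_index = integer(),
                                query = character(), match_type = character(),
                                stringsAsFactors = FALSE)
  idx <- c(planted_pairs$opx_index, planted_pairs$barrel_index)
  if (any(idx < 0L | idx >= n_genes))
    stop("planted gene index outside [0, n_genes)")
  if (anyDuplicated(idx))
    stop("duplicate gene index among planted OPX/barrel genes")
  if (!all(planted_pairs$query %in% queries$name))
    stop("unknown barrel query in planted_pairs")
  if (!all(planted_pairs$match_type %in% c("full_length", "module_only")))
    stop("match_type must be full_length or module_only")
  if (is.null(planted_pairs$opx_class))
    planted_pairs$opx_class <- rep("CLASS3", nrow(planted_pairs))
  with_seed(seed, {
    seqs <- character(n_genes)
    role <- rep("filler", n_genes)
    role[planted_pairs$opx_index + 1L] <- "opx"
    role[planted_pairs$barrel_index + 1L] <- "barrel"
    for (i in seq_len(n_genes)) {
      if (role[[i]] == "barrel") {
        k <- which(planted_pairs$barrel_index == i - 1L)[[1]]
        q <- queries[queries$name == planted_pairs$query[[k]], ]
        seqs[[i]] <- if (planted_pairs$match_type[[k]] == "full_length")
          q$full_sequence else substr(q$full_sequence, q$module_start,
                                      q$module_end)
      } else if (role[[i]] == "opx") {
        seqs[[i]] <- random_aa(sample(250:400, 1L))
      } else {
        for (try in 1:20) {
          s <- random_aa(sample(150:400, 1L))
          if (is.null(match_barrel(s, queries))) break
          s <- NULL
        }
        if (is.null(s))
          stop("could not generate a filler sequence below the match threshold")
        seqs[[i]] <- s
      }
    }
    aa_len <- nchar(seqs)
    gaps <- sample(3:200, n_genes, replace = TRUE)
    nt_len <- 3L * aa_len + 3L
    start_bp <- cumsum(c(1L, head(nt_len + gaps, -1L)))
    protein_id <- sprintf("%s_p%04d", genome_id, seq_len(n_genes) - 1L)
    genes <- data.frame(
      genome_id = genome_id, gene_index = seq_len(n_genes) - 1L,
      locus_tag = sprintf("%s_%04d", genome_id, seq_len(n_genes)),
      start_bp = start_bp, end_bp = start_bp + nt_len - 1L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      protein_id = protein_id, stringsAsFactors = FALSE)
    sequences <- Biostrings::AAStringSet(setNames(seqs, protein_id))
    classifications <- data.frame(
      protein_id = protein_id[planted_pairs$opx_index + 1L],
      class = planted_pairs$opx_class, stringsAsFactors = FALSE)
    truth <- planted_pairs
    truth$opx_protein_id <- protein_id[planted_pairs$opx_index + 1L]
    truth$barrel_protein_id <- protein_id[planted_pairs$barrel_index + 1L]
    truth$gene_offset <- planted_pairs$barrel_index - planted_pairs$opx_index
    list(genes = genes, sequences = sequences,
         classifications = classifications, truth = truth)
  })
}

empty_gene_records <- function() {
  data.frame(genome_id = character(), gene_index = integer(),
             locus_tag = character(), start_bp = integer(),
             end_bp = integer(), strand = character(),
             protein_id = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic inner/outer membrane trace pair
#'
#' Emulates membrane model points traced on a tomographic slice: a smooth
#' backbone (optionally curved as a gentle sinusoid) defines the outer
#' membrane, and the inner membrane is its normal offset at the true gap.
#' Tracing noise is applied to the *outer* (source) trace as independent
#' Gaussian displacements along the local normal at each model point, while
#' the target stays smooth; measuring from the noisy trace to the smooth one
#' keeps each sampled distance equal to gap + noise with no nearest-point
#' bias, so the mean of the distance profile recovers `true_gap` within
#' about `3 * noise_sd / sqrt(n_points)` where `n_points` is the number of
#' outer-membrane model points (default spacing 1 nm, ~101 points over a
#' 100-nm stretch).
#'
#' @param true_gap true intermembrane distance in Angstrom (> 0).
#' @param trace_length_nm traced membrane stretch in nm (~100 nm typical).
#' @param noise_sd tracing noise standard deviation in Angstrom (>= 0).
#' @param curvature_amplitude amplitude of the sinusoidal backbone in
#'   Angstrom (0 = straight membranes).
#' @param seed integer seed.
#' @param tomogram_id identifier stamped on both traces.
#' @param point_spacing_nm spacing of outer-membrane model points in nm.
#' @return list with `om` and `im` [membrane_trace()] objects.
#' @export
gen_membrane_pair <- function(true_gap, trace_length_nm, noise_sd = 0,
                              curvature_amplitude = 0, seed = 1L,
                              tomogram_id = "synthetic_tomo",
                              point_spacing_nm = 1) {
  if (true_gap <= 0) stop("true_gap must be > 0")
  if (trace_length_nm <= 0) stop("trace_length_nm must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (curvature_amplitude < 0) stop("curvature_amplitude must be >= 0")
  gap_nm <- true_gap / 10
  amp_nm <- curvature_amplitude / 10
  wavelength <- max(trace_length_nm, 40)
  if (amp_nm > 0) {
    # the inner membrane is the normal offset of the backbone; the offset
    # must stay below the minimum radius of curvature or the membranes
    # would locally collide
    r_min <- wavelength^2 / (4 * pi^2 * amp_nm)
    if (gap_nm >= r_min)
      stop("curvature_amplitude too strong for this gap: ",
           "offset exceeds the backbone's radius of curvature")
  }
  backbone <- function(x) {
    y <- amp_nm * sin(2 * pi * x / wavelength)
    dy <- amp_nm * (2 * pi / wavelength) * cos(2 * pi * x / wavelength)
    nrm <- sqrt(1 + dy^2)
    list(x = x, y = y, nx = -dy / nrm, ny = 1 / nrm)
  }
  with_seed(seed, {
    x_om <- seq(0, trace_length_nm, by = point_spacing_nm)
    if (length(x_om) < 2L || x_om[length(x_om)] < trace_length_nm)
      x_om <- unique(c(x_om, trace_length_nm))
    b <- backbone(x_om)
    e <- rnorm(length(x_om), 0, noise_sd / 10)
    om <- cbind(b$x + e * b$nx, b$y + e * b$ny)
    x_im <- seq(0, trace_length_nm, by = min(point_spacing_nm, 0.25))
    if (x_im[length(x_im)] < trace_length_nm)
      x_im <- c(x_im, trace_length_nm)
    bi <- backbone(x_im)
    im <- cbind(bi$x - gap_nm * bi$nx, bi$y - gap_nm * bi$ny)
    list(om = membrane_trace(tomogram_id, "OM", om),
         im = membrane_trace(tomogram_id, "IM", im))
  })
}

#' Generate thickness/length pairs with a planted correlation
#'
#' Draws bivariate-normal (thickness, OPX length) pairs with Pearson
#' correlation `r_target`. Lengths are rounded to whole amino acids except
#' when `|r_target| == 1`, where the exact linear relation is preserved.
#' The sample correlation recovers `r_target` within about `2 / sqrt(n)`.
#'
#' @param r_target target Pearson correlation in \[-1, 1\].
#' @param n number of pairs (>= 2).
#' @param seed integer seed.
#' @param thickness_mean,thickness_sd periplasm thickness distribution in
#'   Angstrom (defaults emulate the ~327 +/- 28 A Myxococcus measurement).
#' @param length_mean,length_sd OPX protein length distribution in aa.
#' @return data.frame with columns `thickness_A` and `length_aa`.
#' @export
gen_correlated_pairs <- function(r_target, n, seed = 1L,
                                 thickness_mean = 327, thickness_sd = 28.4,
                                 length_mean = 450, length_sd = 120) {
  if (abs(r_target) > 1) stop("|r_target| must be <= 1")
  if (n < 2L) stop("n must be >= 2")
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    y <- r_target * z1 + sqrt(1 - r_target^2) * z2
    len <- length_mean + length_sd * y
    if (abs(r_target) < 1) len <- round(len)
    data.frame(thickness_A = thickness_mean + thickness_sd * z1,
               length_aa = len)
  })
}
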