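#' Membrane polyline trace
#'
#' An ordered polyline of model points traced along one membrane (inner or
#' outer) on a tomographic slice, in nm plane coordinates.
#'
#' @param tomogram_id tomogram identifier.
#' @param membrane `"IM"` or `"OM"`.
#' @param points two-column matrix (or data.frame) of (x, y) in nm, at
#'   least 2 rows, consecutive points distinct.
#' @return object of class `membrane_trace`.
#' @export
membrane_trace <- function(tomogram_id, membrane, points) {
  membrane <- match.arg(membrane, c("IM", "OM"))
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("points must be a numeric 2-column matrix")
  if (nrow(points) < 2L)
    stop("a membrane trace needs at least 2 points")
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive trace points must be distinct")
  structure(list(tomogram_id = tomogram_id, membrane = membrane,
                 points = unname(points)),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("membrane_trace: %s %s, %d points, arc length %.1f nm\n",
              x$tomogram_id, x$membrane, nrow(x$points), trace_length(x)))
  invisible(x)
}

#' Total arc length of a trace, in nm
#' @param trace a [membrane_trace()].
#' @export
trace_length <- function(trace) {
  sum(sqrt(rowSums(diff(trace$points)^2)))
}

#' Read / write membrane traces
#'
#' Trace TSV format: columns `tomogram_id`, `membrane` (IM/OM), `x_nm`,
#' `y_nm`, `point_order`. One trace per (tomogram, membrane).
#'
#' @param traces list of [membrane_trace()] objects.
#' @param path TSV path.
#' @return `read_traces`: a named list of `membrane_trace` (names
#'   `tomogram.membrane`).
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(tomogram_id = tr$tomogram_id, membrane = tr$membrane,
               x_nm = tr$points[, 1], y_nm = tr$points[, 2],
               point_order = seq_len(nrow(tr$points)),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  key <- paste(df$tomogram_id, df$membrane, sep = ".")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$point_order), ]
    membrane_trace(d$tomogram_id[[1]], d$membrane[[1]],
                   cbind(d$x_nm, d$y_nm))
  })
  out
}

#' Resample a trace at fixed arc-length steps
#'
#' Places points at arc-length positions 0, `step`, 2 `step`, ... along the
#' polyline by linear interpolation within segments; the final trace end is
#' always included. A step larger than the total length therefore yields
#' just the two end points.
#'
#' @param trace a [membrane_trace()].
#' @param step arc-length step in nm (default 0.1 nm).
#' @return matrix of resampled (x, y) points in nm.
#' @export
resample_trace <- function(trace, step = 0.1) {
  if (step <= 0) stop("step must be > 0")
  pts <- trace$points
  seg_len <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  pos <- seq(0, total, by = step)
  if (total - pos[length(pos)] > 1e-9) pos <- c(pos, total)
  idx <- findInterval(pos, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg_len))
  frac <- (pos - cum[idx]) / seg_len[idx]
  out <- cbind(pts[idx, 1] + frac * (pts[idx + 1, 1] - pts[idx, 1]),
               pts[idx, 2] + frac * (pts[idx + 1, 2] - pts[idx, 2]))
  attr(out, "positions") <- pos
  out
}

# minimum distance (nm) from each query point to a polyline,
# by orthogonal projection onto each segment (clamped to the segment)
min_dist_to_polyline <- function(qpts, polyline) {
  n_seg <- nrow(polyline) - 1L
  best <- rep(Inf, nrow(qpts))
  for (j in seq_len(n_seg)) {
    p <- polyline[j, ]
    d <- polyline[j + 1L, ] - p
    len2 <- sum(d^2)
    t <- ((qpts[, 1] - p[1]) * d[1] + (qpts[, 2] - p[2]) * d[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- qpts[, 1] - (p[1] + t * d[1])
    dy <- qpts[, 2] - (p[2] + t * d[2])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

min_dist_to_points <- function(qpts, polyline) {
  best <- rep(Inf, nrow(qpts))
  for (j in seq_len(nrow(polyline))) {
    dx <- qpts[, 1] - polyline[j, 1]
    dy <- qpts[, 2] - polyline[j, 2]
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' Intermembrane distance profile between two traces
#'
#' Resamples the source trace every `step` nm of arc length and, at each
#' sample, measures the minimum Euclidean distance to the target trace.
#' The default `"segment"` mode projects onto the target polyline's
#' segments (point-to-segment distance); `"point"` mode uses the target
#' model points only, for comparison with coarser measurement scripts.
#' Distances are reported in Angstrom (1 nm = 10 A).
#'
#' @param source,target [membrane_trace()] objects from the same tomogram
#'   (conventionally source = OM).
#' @param step sampling step along the source trace in nm (default 0.1).
#' @param mode `"segment"` (default) or `"point"`.
#' @return object of class `periplasm_profile`: list with `tomogram_id`,
#'   `sample_positions` (arc-length nm), `distances` (A), `mean` (A),
#'   `sem` (A; sd of distances over sqrt(n)).
#' @export
distance_profile <- function(source, target, step = 0.1,
                             mode = c("segment", "point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(source, "membrane_trace"),
            inherits(target, "membrane_trace"))
  if (source$tomogram_id != target$tomogram_id)
    stop("source and target traces come from different tomograms")
  qpts <- resample_trace(source, step)
  d_nm <- if (mode == "segment") min_dist_to_polyline(qpts, target$points)
          else min_dist_to_points(qpts, target$points)
  d_A <- 10 * d_nm
  structure(list(tomogram_id = source$tomogram_id,
                 sample_positions = attr(qpts, "positions"),
                 distances = d_A,
                 mean = mean(d_A),
                 sem = stats::sd(d_A) / sqrt(length(d_A))),
            class = "periplasm_profile")
}

#' @export
print.periplasm_profile <- function(x, ...) {
  cat(sprintf("periplasm_profile: %s, %d samples, mean %.1f A (SEM %.2f)\n",
              x$tomogram_id, length(x$distances), x$mean, x$sem))
  invisible(x)
}

#' Per-species envelope thickness summary
#'
#' Aggregates per-tomogram profile means into a per-species grand mean with
#' its standard error (sd of the per-tomogram means over sqrt(n); each
#' species is conventionally measured via 3 tomograms). A species with a
#' single tomogram gets SEM 0 and is flagged.
#'
#' @param profiles list of `periplasm_profile` objects.
#' @param species character vector, one species name per profile.
#' @return data.frame with one row per species: `species`, `n_tomograms`,
#'   `grand_mean_A`, `sem_A`, `single_tomogram` flag.
#' @export
thickness_summary <- function(profiles, species) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  if (length(profiles) != length(species))
    stop("profiles and species must have equal length")
  means <- vapply(profiles, function(p) p$mean, numeric(1))
  rows <- lapply(split(means, species), function(m) {
    data.frame(n_tomograms = length(m), grand_mean_A = mean(m),
               sem_A = if (length(m) > 1L) sd(m) / sqrt(length(m)) else 0,
               single_tomogram = length(m) == 1L)
  })
  out <- cbind(species = names(rows), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Correlate periplasm thickness with OPX protein length
#'
#' Pearson product-moment and Spearman rank correlation (average ranks for
#' ties) between per-organism periplasm thickness and OPX protein length,
#' optionally restricted to one OPX class.
#'
#' @param pairs data.frame with columns `thickness_A` and `length_aa`, and
#'   optionally `class`.
#' @param subset `"all"` (default) or an OPX class name to filter on the
#'   `class` column.
#' @return object of class `opx_correlation`: list with `subset`,
#'   `pearson_r`, `spearman_rho`, `n_pairs`.
#' @export
correlate_thickness <- function(pairs, subset = "all") {
  if (subset != "all") {
    if (!"class" %in% names(pairs))
      stop("subset filtering needs a 'class' column")
    pairs <- pairs[pairs$class == subset, , drop = FALSE]
  }
  if (nrow(pairs) < 2L)
    stop("need at least 2 pairs after filtering")
  x <- pairs$thickness_A
  y <- pairs$length_aa
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: constant column")
  structure(list(subset = subset,
                 pearson_r = cor(x, y, method = "pearson"),
                 spearman_rho = cor(x, y, method = "spearman"),
                 n_pairs = nrow(pairs)),
            class = "opx_correlation")
}

#' @export
print.opx_correlation <- function(x, ...) {
  cat(sprintf(
    "thickness-length correlation (%s): Pearson %.4f, Spearman %.4f, n = %d\n",
    x$subset, x$pearson_r, x$spearman_rho, x$n_pairs))
  invisible(x)
}

#' Hydrophobic thickness of the outer membrane
#'
#' The hydrophobic core of an asymmetric OM bilayer is approximately 40% of
#' its total solvated thickness; e.g. a 69.8 A membrane has a hydrophobic
#' thickness of about 28 A.
#'
#' @param total_om_thickness total solvated OM thickness in Angstrom (>= 0).
#' @param fraction hydrophobic fraction, in (0, 1\] (default 0.40).
#' @return the hydrophobic thickness in Angstrom, with attribute
#'   `reported` carrying the nearest-integer value used in reports.
#' @examples
#' hydrophobic_thickness(69.8)   # 27.92, reported ~28 A
#' @export
hydrophobic_thickness <- function(total_om_thickness, fraction = 0.40) {
  if (total_om_thickness < 0) stop("total_om_thickness must be >= 0")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  out <- total_om_thickness * fraction
  attr(out, "reported") <- round(out)
  out
}
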