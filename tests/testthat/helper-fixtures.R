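# shared fixture builders; everything is generated in code

make_hit <- function(protein_id = "p", domain = "Poly_export",
                     start = 30L, end = 120L, e = 1e-20, bits = 80) {
  data.frame(protein_id = protein_id, domain_name = domain,
             ali_start = start, ali_end = end, e_value = e,
             bit_score = bits, stringsAsFactors = FALSE)
}

make_region <- function(protein_id = "p", template = "WZA_2J58",
                        q_start = 30L, q_end = 120L,
                        t_start = 28L, t_end = 118L, prob = 98) {
  data.frame(protein_id = protein_id, template = template,
             q_start = q_start, q_end = q_end,
             t_start = t_start, t_end = t_end,
             probability = prob, stringsAsFactors = FALSE)
}

# architecture + regions for the exemplar OPX proteins
exemplar_evidence <- function(kind) {
  switch(kind,
    wza_ec = list(  # Poly_export + 2x SLBB + Wza_C segment
      hits = rbind(make_hit("p", "Poly_export", 30, 120),
                   make_hit("p", "SLBB", 130, 180),
                   make_hit("p", "SLBB", 190, 240)),
      regions = rbind(make_region("p"),
                      make_region("p", q_start = 300, q_end = 340,
                                  t_start = 326, t_end = 359))),
    kpsd_ec = list(  # Poly_export + SLBB + GfcC (after) + Wza_C segment
      hits = rbind(make_hit("p", "Poly_export", 30, 120),
                   make_hit("p", "SLBB", 130, 180),
                   make_hit("p", "GfcC", 200, 350)),
      regions = rbind(make_region("p"),
                      make_region("p", q_start = 400, q_end = 440,
                                  t_start = 326, t_end = 359))),
    wzax = list(  # Poly_export + SLBB only
      hits = rbind(make_hit("p", "Poly_export", 30, 120),
                   make_hit("p", "SLBB", 130, 180)),
      regions = make_region("p")),
    gfcc_first = list(  # GfcC preceding Poly_export, no Wza_C
      hits = rbind(make_hit("p", "GfcC", 25, 175),
                   make_hit("p", "Poly_export", 190, 280),
                   make_hit("p", "SLBB", 290, 340)),
      regions = make_region("p", q_start = 190, q_end = 280)),
    slbb_only = list(
      hits = make_hit("p", "SLBB", 30, 80),
      regions = empty_fold_regions_fixture()))
}

empty_hits_df <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             ali_start = integer(), ali_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

empty_fold_regions_fixture <- function() {
  data.frame(protein_id = character(), template = character(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             probability = numeric(), stringsAsFactors = FALSE)
}

classify_evidence <- function(kind) {
  ev <- exemplar_evidence(kind)
  classify_opx(resolve_architecture(ev$hits), ev$regions)
}

# random jagged polyline for geometry oracle tests
random_polyline <- function(n_pts, scale = 5, origin = c(0, 0)) {
  steps <- cbind(abs(rnorm(n_pts - 1, 1, 0.4)) + 0.05,
                 rnorm(n_pts - 1, 0, 0.3)) * scale / n_pts
  pts <- apply(steps, 2, cumsum, simplify = FALSE)
  rbind(origin, sweep(cbind(pts[[1]], pts[[2]]), 2, origin, "+"))
}

# brute-force nearest-distance oracle: densely sample the target polyline
# (keeping its vertices, where nearest-point error would otherwise be
# first-order in the sampling step) and take the minimum point-to-point
# distance (in Angstrom)
brute_force_profile <- function(source, target, step = 0.1,
                                dense_step = 5e-4) {
  q <- resample_trace(source, step)
  tpts <- rbind(resample_trace(target, dense_step), target$points)
  vapply(seq_len(nrow(q)), function(i) {
    10 * sqrt(min((tpts[, 1] - q[i, 1])^2 + (tpts[, 2] - q[i, 2])^2))
  }, numeric(1))
}
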