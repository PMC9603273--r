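queries <- barrel_queries()

test_that("neighborhood windows truncate at replicon ends and exclude the anchor", {
  g <- gen_genome("g1", 30, seed = 1)$genes
  nb <- neighborhood(g, 15L, 10L)
  expect_equal(nrow(nb), 20L)
  expect_false(15L %in% nb$gene_index)
  expect_equal(range(nb$gene_index), c(5L, 25L))
  nb_edge <- neighborhood(g, 3L, 10L)
  expect_equal(nrow(nb_edge), 13L)
  expect_equal(range(nb_edge$gene_index), c(0L, 13L))
  expect_equal(nrow(neighborhood(g, 15L, 0L)), 0L)
  expect_error(neighborhood(g, 99L), "not found")
})

test_that("barrel matching types self-, module- and random sequences correctly", {
  full <- queries$full_sequence[queries$name == "PgaA_bb"]
  qrow <- queries[queries$name == "PgaA_bb", ]
  m_full <- match_barrel(full, queries)
  expect_equal(m_full$query, "PgaA_bb")
  expect_equal(m_full$match_type, "full_length")
  mod <- substr(full, qrow$module_start, qrow$module_end)
  m_mod <- match_barrel(mod, queries)
  expect_equal(m_mod$query, "PgaA_bb")
  expect_equal(m_mod$match_type, "module_only")
  set.seed(9)
  for (i in 1:5) {
    rnd <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                          "P","Q","R","S","T","V","W","Y"), 300, TRUE),
                 collapse = "")
    expect_null(match_barrel(rnd, queries))
  }
  expect_error(match_barrel(""), "non-empty")
})

test_that("planted pairs inside the window are recovered exactly; outside are not", {
  pairs <- data.frame(opx_index = 15L, barrel_index = 16L,
                      query = "MXAN_7418", match_type = "full_length")
  g <- gen_genome("g1", 30, pairs, seed = 4, queries = queries)
  hits <- pair_opx_barrels(g$genes, g$sequences, g$classifications, queries)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene_offset, 1L)
  expect_equal(hits$query, "MXAN_7418")
  expect_equal(hits$match_type, "full_length")
  # pair outside the +/-10 window yields nothing
  far <- data.frame(opx_index = 2L, barrel_index = 14L,
                    query = "MXAN_7418", match_type = "full_length")
  g2 <- gen_genome("g2", 30, far, seed = 4, queries = queries)
  hits2 <- pair_opx_barrels(g2$genes, g2$sequences, g2$classifications,
                            queries)
  expect_equal(nrow(hits2), 0L)
})

test_that("a barrel flanked by two OPX genes is reported once per anchor", {
  pairs <- data.frame(opx_index = c(10L, 14L), barrel_index = c(12L, 13L),
                      query = c("MXAN_7418", "MXAN_7418"),
                      match_type = "full_length")
  g <- gen_genome("g1", 25, pairs, seed = 6, queries = queries)
  hits <- pair_opx_barrels(g$genes, g$sequences, g$classifications, queries)
  # both barrels lie within +/-10 of both anchors: 2 anchors x 2 barrels
  expect_equal(nrow(hits), 4L)
  expect_equal(sum(hits$opx_protein_id == g$truth$opx_protein_id[1]), 2L)
  expect_true(all(abs(hits$gene_offset) <= 10L))
})

test_that("pairing is invariant under reversing gene order", {
  pairs <- data.frame(opx_index = 8L, barrel_index = 5L,
                      query = "AlgE", match_type = "full_length")
  g <- gen_genome("g1", 20, pairs, seed = 8, queries = queries)
  hits <- pair_opx_barrels(g$genes, g$sequences, g$classifications, queries)
  rev_genes <- g$genes
  rev_genes$gene_index <- max(rev_genes$gene_index) - rev_genes$gene_index
  rev_hits <- pair_opx_barrels(rev_genes, g$sequences, g$classifications,
                               queries)
  expect_equal(nrow(hits), 1L)
  expect_equal(rev_hits$gene_offset, -hits$gene_offset)
  expect_equal(rev_hits$barrel_protein_id, hits$barrel_protein_id)
})

test_that("cross-tab totals equal the sum of class columns", {
  set.seed(10)
  hits <- data.frame(
    genome_id = "g", opx_protein_id = sprintf("o%d", 1:10),
    opx_class = sample(c("CLASS1", "CLASS2B", "CLASS3"), 10, TRUE),
    barrel_protein_id = sprintf("b%d", 1:10),
    gene_offset = sample(c(-3:-1, 1:3), 10, TRUE),
    query = sample(c("MXAN_7418", "Wzi_bb"), 10, TRUE),
    match_type = sample(c("full_length", "module_only"), 10, TRUE),
    e_value = 1e-30, coverage_full = 1, coverage_module = 1,
    stringsAsFactors = FALSE)
  tab <- tabulate_synteny(hits)
  class_cols <- setdiff(names(tab), c("query", "match_type", "total"))
  expect_equal(tab$total, rowSums(tab[class_cols]))
  expect_equal(sum(tab$total), 10)
  # empty input gives an all-zero table over the requested queries
  tab0 <- tabulate_synteny(hits[0, ], query_names = queries$name)
  expect_equal(sum(tab0$total), 0)
  expect_equal(nrow(tab0), 2L * nrow(queries))
  # zero cells render as dashes in the formatted report
  fmt <- format_synteny_table(tab0)
  expect_true(all(fmt$total == "−"))
})

test_that("intergenic distances follow the gap definition", {
  mk <- function(s, e, g = "g1") data.frame(genome_id = g, start_bp = s,
                                            end_bp = e)
  expect_equal(intergenic_distance(mk(100, 200), mk(204, 300)), 3L)
  expect_equal(intergenic_distance(mk(100, 200), mk(201, 300)), 0L)
  expect_equal(intergenic_distance(mk(100, 200), mk(150, 300)), -51L)
  # order of arguments does not matter
  expect_equal(intergenic_distance(mk(204, 300), mk(100, 200)), 3L)
  expect_error(intergenic_distance(mk(1, 2), mk(4, 5, g = "g2")),
               "different replicons")
})

test_that("gene tables round-trip through GFF3 and sequences through FASTA", {
  g <- gen_genome("g1", 8, seed = 2)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genes_gff3(g$genes, gff)
  back <- read_genes_gff3(gff)
  cols <- c("genome_id", "gene_index", "locus_tag", "start_bp", "end_bp",
            "strand", "protein_id")
  expect_equal(back[cols], g$genes[cols])
  fa <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(g$sequences, fa)
  seqs <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(seqs), as.character(g$sequences))
})
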