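test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_genomes = 8, seed = 7)
  b1 <- generate_genomes(cfg)
  b2 <- generate_genomes(cfg)
  expect_identical(b1, b2)
  b3 <- generate_genomes(generator_config(n_genomes = 8, seed = 8))
  expect_false(identical(b1$genomes$genes, b3$genomes$genes))
})

test_that("forced planting puts the requested system in every genome", {
  cfg <- generator_config(n_genomes = 10, system_mix = c(RNF = 1),
                          decoy_anchor_rate = 0, decoy_key_rate = 0,
                          multiflav_rate = 0, orphan_apbe_only_rate = 0,
                          orphan_apbe_duf_rate = 0, seed = 3)
  b <- generate_genomes(cfg)
  expect_setequal(b$truth$systems$genome_id, b$truth$genomes$genome_id)
  expect_true(all(b$truth$systems$system == "RNF"))
})

test_that("every template is classified as exactly its own system", {
  for (sys in c("RNF", "NOS", "PCE", "EET", "NQR", "NAPH_LIKE",
                "MSRQ_LIKE", "PEPSY", "DSBD", "NQR_RNF_LIKE")) {
    mix <- stats::setNames(1, sys)
    b <- generate_genomes(generator_config(
      n_genomes = 4, system_mix = mix, decoy_anchor_rate = 0,
      decoy_key_rate = 0, multiflav_rate = 0,
      orphan_apbe_only_rate = 0, orphan_apbe_duf_rate = 0,
      background_annotation_rate = 0, subthreshold_rate = 0,
      seed = 11))
    g <- b$genomes
    cl <- filter_extracytosolic(
      build_clusters(g$genes, detect_anchors(g$genes, g$domains)),
      g$localization)
    asn <- classify_clusters(cl, g$genes, g$domains, g$localization)
    expect_equal(nrow(cl), 4, info = sys)
    for (s in asn$systems) expect_equal(s, sys, info = sys)
  }
})

test_that("decoys are rejected by the filter and the window rule", {
  cfg <- generator_config(n_genomes = 15, system_mix = numeric(0),
                          decoy_anchor_rate = 1, decoy_key_rate = 1,
                          multiflav_rate = 0, orphan_apbe_only_rate = 0,
                          orphan_apbe_duf_rate = 0, seed = 5)
  b <- generate_genomes(cfg)
  g <- b$genomes
  raw <- build_clusters(g$genes, detect_anchors(g$genes, g$domains))
  filtered <- filter_extracytosolic(raw, g$localization)
  # type (a): anchors exist but every cluster dies at the filter
  expect_gt(nrow(raw), 0)
  expect_equal(nrow(filtered), 0)
  # type (b): lone key genes never formed a cluster at all
  lone <- b$truth$decoys$protein_id[b$truth$decoys$type == "decoy_key"]
  expect_gt(length(lone), 0)
  in_any <- vapply(lone, function(p) {
    any(vapply(raw$members, function(m) p %in% m, logical(1)))
  }, logical(1))
  expect_false(any(in_any))
})

test_that("sub-threshold hits never create anchors", {
  cfg <- generator_config(n_genomes = 10, system_mix = numeric(0),
                          decoy_anchor_rate = 0, decoy_key_rate = 0,
                          multiflav_rate = 0, orphan_apbe_only_rate = 0,
                          orphan_apbe_duf_rate = 0,
                          subthreshold_rate = 0.5,
                          background_annotation_rate = 0, seed = 13)
  b <- generate_genomes(cfg)
  g <- b$genomes
  expect_gt(nrow(g$domains), 0)          # decoy hits were planted
  expect_true(all(g$domains$evalue > 0.001))
  expect_equal(nrow(detect_anchors(g$genes, g$domains)), 0)
})

test_that("planted motifs and multi-flavinylated domain counts are exact truth", {
  b <- generate_genomes(generator_config(n_genomes = 25, seed = 19,
                                         multiflav_rate = 0.6))
  g <- b$genomes
  found <- scan_flavinylation_motifs(g$sequences)
  tru <- b$truth$motifs
  expect_identical(
    found[order(found$protein_id, found$position),
          c("protein_id", "position")],
    tibble::as_tibble(tru[order(tru$protein_id, tru$position),
                          c("protein_id", "position")]))
  mf <- find_multiflavinylated(g$domains, g$localization)
  tm <- b$truth$multiflav
  expect_setequal(mf$protein_id, tm$protein_id)
  expect_equal(mf$fmn_domain_count[match(tm$protein_id, mf$protein_id)],
               tm$n_domains)
})

test_that("fixture files round-trip through the package readers", {
  b <- generate_genomes(generator_config(n_genomes = 5, seed = 23))
  dir <- withr::local_tempdir()
  paths <- emit_fixture_files(b, dir)
  genes <- read_gene_table(paths[["genes"]])
  expect_identical(
    as.data.frame(genes), as.data.frame(
      b$genomes$genes[order(b$genomes$genes$genome_id,
                            b$genomes$genes$contig_id,
                            b$genomes$genes$gene_index), ]))
  seqs <- read_protein_fasta(paths[["proteins"]])
  expect_setequal(seqs$protein_id, b$genomes$sequences$protein_id)
  dom <- read_annotation_tsv(paths[["annotations"]])
  expect_equal(nrow(dom), nrow(b$genomes$domains))
  loc <- read_localization_tsv(paths[["localization"]])
  expect_equal(nrow(loc), nrow(b$genomes$localization))
  tax <- read_taxonomy(paths[["taxonomy"]])
  expect_setequal(tax$genome_id, unique(b$genomes$genes$genome_id))
  # truth ledger references only emitted identifiers
  expect_true(all(b$truth$systems$anchor_protein %in%
                    b$genomes$genes$protein_id))
  expect_true(all(b$truth$multiflav$protein_id %in%
                    b$genomes$genes$protein_id))
})

test_that("infeasible generator configurations error before generation", {
  expect_error(generator_config(genes_per_contig = c(2, 4)),
               "template")
  expect_error(generator_config(system_mix = c(RNF = 1.5)), "\\[0, 1\\]")
  expect_error(generator_config(system_mix = c(BOGUS = 0.5)), "unknown")
  expect_error(generator_config(n_genomes = 0), "at least one")
})
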