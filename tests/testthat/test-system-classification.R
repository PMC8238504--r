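# builds one extracytosolic cluster: an FMN-binding anchor with a signal
# peptide at index 5 of an 11-gene contig, plus caller-supplied extra hits
# on the other genes
mini_locus <- function(extra_hits = NULL, loc_overrides = NULL,
                       tm_overrides = NULL) {
  genes <- make_genes(n = 11)
  p <- genes$protein_id
  domains <- dplyr::bind_rows(hit(p[6], "PF04205"), extra_hits)
  localization <- all_other_loc(genes, except = p[6])
  if (!is.null(loc_overrides)) {
    localization$call[match(names(loc_overrides),
                            localization$protein_id)] <-
      unname(loc_overrides)
  }
  if (!is.null(tm_overrides)) {
    localization$tm_helix_count[match(names(tm_overrides),
                                      localization$protein_id)] <-
      as.integer(unname(tm_overrides))
  }
  clusters <- filter_extracytosolic(
    build_clusters(genes, detect_anchors(genes, domains)), localization)
  list(genes = genes, p = p, domains = domains,
       localization = localization, clusters = clusters)
}

classify_locus <- function(l) {
  classify_clusters(l$clusters, l$genes, l$domains, l$localization)
}

test_that("each key-gene rule assigns exactly its system", {
  single_key <- list(
    RNF = hit("x", "K03616"), NOS = hit("x", "K00376"),
    PCE = hit("x", "PF13486"), NQR = hit("x", "K00351"),
    NAPH_LIKE = hit("x", "PF12801"), MSRQ_LIKE = hit("x", "PF01794"),
    PEPSY = hit("x", "PF03929"), DSBD = hit("x", "PF02683")
  )
  for (sys in names(single_key)) {
    l <- mini_locus({
      h <- single_key[[sys]]
      h$protein_id <- "G1_c1_p2"
      h
    })
    asn <- classify_locus(l)
    expect_equal(asn$systems[[1]], sys, info = sys)
  }
  # NapH-like via the KO accession too
  l <- mini_locus(hit("G1_c1_p2", "K19339"))
  expect_equal(classify_locus(l)$systems[[1]], "NAPH_LIKE")
  # PepSY via its second family
  l <- mini_locus(hit("G1_c1_p2", "PF16357"))
  expect_equal(classify_locus(l)$systems[[1]], "PEPSY")
})

test_that("EET requires a transmembrane helix on the key gene", {
  l0 <- mini_locus(hit("G1_c1_p2", "K03885"))
  expect_equal(classify_locus(l0)$systems[[1]], character(0))
  l1 <- mini_locus(hit("G1_c1_p2", "K03885"),
                   tm_overrides = c(G1_c1_p2 = 1))
  expect_equal(classify_locus(l1)$systems[[1]], "EET")
})

test_that("multi-label assignment records genuine rule co-occurrence", {
  l <- mini_locus(dplyr::bind_rows(hit("G1_c1_p2", "PF03929"),
                                   hit("G1_c1_p3", "PF01794")))
  expect_setequal(classify_locus(l)$systems[[1]],
                  c("PEPSY", "MSRQ_LIKE"))
})

test_that("key genes failing the E-value cutoff assign nothing", {
  l <- mini_locus(hit("G1_c1_p2", "K03616", evalue = 0.01))
  expect_equal(classify_locus(l)$systems[[1]], character(0))
})

test_that("NQR/RNF-like architecture check enforces order and N-terminal start", {
  ok <- dplyr::bind_rows(
    hit("q", "PF03116", ali_from = 20, ali_to = 350),
    hit("q", "PF00175", ali_from = 400, ali_to = 580))
  expect_true(check_nqr_rnf_like(ok, 600))

  only_n <- hit("q", "PF03116", ali_from = 20, ali_to = 350)
  expect_false(check_nqr_rnf_like(only_n, 600))

  reversed <- dplyr::bind_rows(
    hit("q", "PF00175", ali_from = 10, ali_to = 150),
    hit("q", "PF03116", ali_from = 300, ali_to = 550))
  expect_false(check_nqr_rnf_like(reversed, 600))

  # PF03116 starting beyond the protein midpoint is not "N-terminal"
  late <- dplyr::bind_rows(
    hit("q", "PF03116", ali_from = 320, ali_to = 400),
    hit("q", "PF00175", ali_from = 420, ali_to = 580))
  expect_false(check_nqr_rnf_like(late, 600))

  no_coords <- dplyr::bind_rows(hit("q", "PF03116"), hit("q", "PF00175"))
  expect_warning(res <- check_nqr_rnf_like(no_coords, 600),
                 "coordinates")
  expect_false(res)

  # and end-to-end through the classifier
  l <- mini_locus(dplyr::bind_rows(
    hit("G1_c1_p2", "PF03116", ali_from = 20, ali_to = 350),
    hit("G1_c1_p2", "PF00175", ali_from = 400, ali_to = 580)))
  expect_equal(classify_locus(l)$systems[[1]], "NQR_RNF_LIKE")
})

test_that("adding annotations never removes a system label", {
  base <- mini_locus(hit("G1_c1_p2", "K03616"))
  extra <- mini_locus(dplyr::bind_rows(
    hit("G1_c1_p2", "K03616"), hit("G1_c1_p3", "PF01794"),
    hit("G1_c1_p4", "PF02683")))
  before <- classify_locus(base)$systems[[1]]
  after <- classify_locus(extra)$systems[[1]]
  expect_true(all(before %in% after))
})

test_that("NapH-like FMN partition is recorded per cluster", {
  fused <- mini_locus(hit("G1_c1_p5", "PF12801"))  # the anchor gene itself
  expect_equal(classify_locus(fused)$naph_fmn_mode, "fused")
  separate <- mini_locus(hit("G1_c1_p2", "PF12801"))
  expect_equal(classify_locus(separate)$naph_fmn_mode, "separate")
  none <- mini_locus(hit("G1_c1_p2", "K03616"))
  expect_true(is.na(classify_locus(none)$naph_fmn_mode))
})

test_that("tidy and glance summarize assignment objects", {
  l <- mini_locus(dplyr::bind_rows(hit("G1_c1_p2", "PF03929"),
                                   hit("G1_c1_p3", "PF01794")))
  asn <- classify_locus(l)
  long <- tidy(asn)
  expect_setequal(long$system, c("PEPSY", "MSRQ_LIKE"))
  g <- glance(asn)
  expect_equal(g$n_clusters, 1L)
  expect_equal(g$n_assignments, 2L)
})

test_that("accessory features are annotated with carriers and fusion flags", {
  l <- mini_locus(dplyr::bind_rows(
    hit("G1_c1_p2", "PF01794"),            # MsrQ-like key gene ...
    hit("G1_c1_p2", "PF00175"),            # ... with fused NAD-binding
    hit("G1_c1_p3", "PF01988")             # VIT1 elsewhere in cluster
  ))
  asn <- classify_locus(l)
  acc <- annotate_accessories(l$clusters, asn, l$domains)
  nad <- acc[acc$feature == "NAD_BINDING", ]
  expect_equal(nad$carrier, "G1_c1_p2")
  expect_true(nad$fused)
  vit <- acc[acc$feature == "VIT1", ]
  expect_equal(vit$carrier, "G1_c1_p3")
  expect_false(vit$fused)
})

test_that("orphan-ApbE detection distinguishes the two substrate sets", {
  # genome A: secreted ApbE only -> orphan under both definitions
  # genome B: secreted ApbE + secreted DUF2271 -> orphan only under FMN-only
  # genome C: secreted ApbE + secreted FMN protein -> not orphan
  # genome D: no ApbE -> not orphan
  genes <- dplyr::bind_rows(
    make_genes("GA", n = 3), make_genes("GB", n = 3),
    make_genes("GC", n = 3), make_genes("GD", n = 3))
  pid <- function(g, i) sprintf("%s_c1_p%d", g, i)
  domains <- dplyr::bind_rows(
    hit(pid("GA", 0), "PF02424"),
    hit(pid("GB", 0), "PF02424"), hit(pid("GB", 1), "PF10029"),
    hit(pid("GC", 0), "PF02424"), hit(pid("GC", 1), "PF04205"),
    hit(pid("GD", 0), "PF00005"))
  localization <- all_other_loc(genes, except = c(
    pid("GA", 0), pid("GB", 0), pid("GB", 1), pid("GC", 0), pid("GC", 1)))
  orph <- find_orphan_apbe(genes, domains, localization)
  expect_equal(orph$orphan_fmn_only,
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(orph$orphan_extended,
               c(TRUE, FALSE, FALSE, FALSE))

  # a cytosolic ApbE does not make an orphan
  loc2 <- all_other_loc(genes)
  expect_false(any(find_orphan_apbe(genes, domains, loc2)$orphan_fmn_only))
})

test_that("multi-flavinylated proteins are counted by passing PF04205 hits", {
  domains <- dplyr::bind_rows(
    hit("m3", "PF04205", 1e-9), hit("m3", "PF04205", 1e-8),
    hit("m3", "PF04205", 1e-7),
    hit("m1", "PF04205", 1e-9),
    hit("m2", "PF04205", 1e-9), hit("m2", "PF04205", 0.5))
  mf <- find_multiflavinylated(domains)
  expect_equal(mf$protein_id, "m3")
  expect_equal(mf$fmn_domain_count, 3L)

  # localization filter removes cytosolic candidates
  locs <- loc(c("m3"), call = "OTHER")
  expect_equal(nrow(find_multiflavinylated(domains, locs)), 0)
})

test_that("fumarate-reductase-like co-occurrence uses the ±2 gene window", {
  genes <- make_genes(n = 9)
  p <- genes$protein_id
  domains <- dplyr::bind_rows(
    hit(p[5], "PF00890"),                  # frd at index 4
    hit(p[5], "PF04205"),                  # fused FMN
    hit(p[7], "PF04205"),                  # index 6: distance 2 -> nearby
    hit(p[8], "PF14537")                   # index 7: distance 3 -> not
  )
  frd <- analyze_frd(genes, domains)
  expect_equal(nrow(frd), 1)
  expect_true(frd$fmn_fused)
  expect_true(frd$fmn_nearby)
  expect_false(frd$cytochrome_fused)
  expect_false(frd$cytochrome_nearby)

  # cytochrome moved to distance 2 flips the flag
  domains2 <- dplyr::bind_rows(hit(p[5], "PF00890"),
                               hit(p[3], "PF14537"))
  expect_true(analyze_frd(genes, domains2)$cytochrome_nearby)
})

test_that("P19 cluster typing follows FMN/thioredoxin content", {
  genes <- make_genes(n = 11)
  p <- genes$protein_id
  flav <- dplyr::bind_rows(hit(p[6], "PF10634"), hit(p[7], "PF03239"),
                           hit(p[8], "PF04205"))
  r <- detect_p19_clusters(genes, flav)
  expect_true(r$ftr1)
  expect_equal(r$p19_type, "flavinylation")

  trx <- dplyr::bind_rows(hit(p[6], "PF10634"), hit(p[7], "PF03239"),
                          hit(p[8], "PF13899"))
  expect_equal(detect_p19_clusters(genes, trx)$p19_type, "thioredoxin")

  alone <- hit(p[6], "PF10634")
  r3 <- detect_p19_clusters(genes, alone)
  expect_false(any(r3$ftr1, r3$fmn_binding, r3$thioredoxin_like))
  expect_equal(r3$p19_type, "none")
})

test_that("DsbD-independent DUF3570 loci require the full cassette minus DsbD", {
  genes <- make_genes(n = 11)
  p <- genes$protein_id
  cassette <- dplyr::bind_rows(
    hit(p[4], "PF02424"), hit(p[5], "PF12094"),
    hit(p[6], "PF13899"), hit(p[7], "PF14086"))
  mk <- function(domains) {
    filter_extracytosolic(
      build_clusters(genes, detect_anchors(genes, domains)),
      all_other_loc(genes, except = p[4], except_call = "LIPO"))
  }
  cl <- mk(cassette)
  expect_true(detect_dsbd_independent_duf3570(cl, cassette)$dsbd_independent)

  with_dsbd <- dplyr::bind_rows(cassette, hit(p[8], "PF02683"))
  expect_false(
    detect_dsbd_independent_duf3570(mk(with_dsbd),
                                    with_dsbd)$dsbd_independent)

  partial <- cassette[-3, ]  # drop the thioredoxin-like gene
  expect_false(
    detect_dsbd_independent_duf3570(mk(partial), partial)$dsbd_independent)
})
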