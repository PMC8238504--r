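# a syntactically faithful domtblout data line (23 fields incl. description)
domt_line <- function(target, qname, qacc, evalue, score, ali_from, ali_to) {
  paste(target, "-", 500, qname, qacc, 120, evalue, score, "0.1",
        1, 1, evalue, evalue, score, "0.1", 1, 120, ali_from, ali_to,
        ali_from, ali_to, "0.95", "some description", sep = "  ")
}

tbl_line <- function(target, qname, qacc, evalue, score) {
  paste(target, "-", qname, qacc, evalue, score, "0.1",
        evalue, score, "0.1", "1.1", 1, 1, 0, 0, 0, 1, 1,
        "description here", sep = "  ")
}

test_that("HMMER tabular dialects parse with correct field mapping", {
  tf <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c(
    "# comment line",
    domt_line("prot1", "FMN_bind", "PF04205.18", "1e-10", "55.2", 10, 80),
    domt_line("prot1", "FMN_bind", "PF04205.18", "2e-07", "30.1", 150, 220),
    domt_line("prot2", "ApbE", "PF02424.5", "3e-20", "99.9", 5, 300)
  ), tf)
  hits <- parse_hmmsearch_tbl(tf, "pfam", "domtblout")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$evalue[1], 1e-10)
  expect_equal(hits$accession, c("PF04205", "PF04205", "PF02424"))
  expect_equal(hits$ali_from, c(10L, 150L, 5L))
  expect_true(all(hits$namespace == "pfam"))

  tf2 <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("#", tbl_line("prot1", "K00001", "-", "5e-09", "40.0")),
             tf2)
  khits <- parse_hmmsearch_tbl(tf2, "kofam", "tblout")
  expect_equal(khits$accession, "K00001")
  expect_equal(khits$evalue, 5e-09)
  expect_true(is.na(khits$ali_from))

  # comment-only file -> empty collection
  writeLines(c("# only", "# comments"), tf)
  expect_equal(nrow(parse_hmmsearch_tbl(tf, "pfam")), 0)

  # malformed numeric field -> parse error
  writeLines(domt_line("p", "q", "PF1.1", "inf", "bad", 1, 2), tf)
  expect_error(parse_hmmsearch_tbl(tf, "pfam", "domtblout"), "malformed")

  writeLines("too few fields here", tf)
  expect_error(parse_hmmsearch_tbl(tf, "pfam", "domtblout"), "malformed")
})

test_that("best-KO assignment minimizes E-value with documented tie-breaks", {
  hits <- dplyr::bind_rows(
    hit("p1", "K00001", 1e-5),
    hit("p1", "K00002", 1e-8),
    hit("p2", "K00009", 0.01),                      # fails cutoff
    hit("p3", "K00005", 1e-6, bitscore = 50),
    hit("p3", "K00004", 1e-6, bitscore = 60),       # wins on score
    hit("p4", "K00007", 1e-6, bitscore = 60),
    hit("p4", "K00006", 1e-6, bitscore = 60)        # wins lexically
  )
  best <- assign_best_ko(hits)
  expect_equal(best$accession[best$protein_id == "p1"], "K00002")
  expect_false("p2" %in% best$protein_id)
  expect_equal(best$accession[best$protein_id == "p3"], "K00004")
  expect_equal(best$accession[best$protein_id == "p4"], "K00006")
  # reported E-value is the protein's minimum passing E-value
  expect_equal(best$evalue[best$protein_id == "p1"], 1e-8)
})

test_that("best-KO assignment matches a brute-force oracle on random tables", {
  withr::with_seed(402, {
    hits <- tibble::tibble(
      protein_id = sample(sprintf("p%03d", 1:1000), 5000, replace = TRUE),
      namespace = "kofam",
      accession = sample(sprintf("K%05d", 1:40), 5000, replace = TRUE),
      evalue = 10^stats::runif(5000, -15, 0.5),
      bitscore = round(stats::runif(5000, 10, 500), 3),
      ali_from = NA_integer_, ali_to = NA_integer_
    )
  })
  got <- assign_best_ko(hits)
  want <- oracle_best_ko(hits)
  expect_equal(got[order(got$protein_id), c("protein_id", "accession")],
               want, ignore_attr = TRUE)
})

test_that("Pfam collection keeps multiplicity and applies the cutoff", {
  hits <- dplyr::bind_rows(
    hit("p1", "PF04205", 1e-9),
    hit("p1", "PF04205", 1e-7),
    hit("p2", "PF04205", 0.5),
    hit("p3", "PF02424", 1e-5),
    hit("p3", "PF04205", 1e-5)
  )
  pf <- collect_pfam_domains(hits)
  expect_equal(sum(pf$protein_id == "p1" & pf$accession == "PF04205"), 2)
  expect_false("p2" %in% pf$protein_id)
  expect_setequal(pf$accession[pf$protein_id == "p3"],
                  c("PF02424", "PF04205"))
})

test_that("tightening the E-value cutoff never adds annotations", {
  withr::with_seed(77, {
    hits <- tibble::tibble(
      protein_id = sample(sprintf("p%02d", 1:50), 400, replace = TRUE),
      namespace = sample(c("pfam", "kofam"), 400, replace = TRUE),
      accession = sample(c(sprintf("PF%05d", 1:8),
                           sprintf("K%05d", 1:8)), 400, replace = TRUE),
      evalue = 10^stats::runif(400, -12, 0.5),
      bitscore = stats::runif(400, 10, 200),
      ali_from = NA_integer_, ali_to = NA_integer_
    )
  })
  key <- function(df) paste(df$protein_id, df$accession)
  for (cuts in list(c(0.01, 0.001), c(0.001, 1e-6), c(1e-4, 1e-8))) {
    loose <- annotation_config(cuts[1]); tight <- annotation_config(cuts[2])
    expect_true(all(key(collect_pfam_domains(hits, tight)) %in%
                      key(collect_pfam_domains(hits, loose))))
    expect_true(all(assign_best_ko(hits, tight)$protein_id %in%
                      assign_best_ko(hits, loose)$protein_id))
  }
})

test_that("localization predictor tokens map to the four calls", {
  tf <- withr::local_tempfile()
  writeLines(c("# SignalP-5.0", "p1\tSP(Sec/SPI)\t0.99",
               "p2\tLIPO(Sec/SPII)\t0.88", "p3\tTAT(Tat/SPI)\t0.91",
               "p4\tOTHER\t0.99"), tf)
  tm <- withr::local_tempfile()
  writeLines(c("p1\tlen=200\tExpAA=60\tFirst60=1\tPredHel=3\tTopology=i",
               "p4\tlen=99\tExpAA=0\tFirst60=0\tPredHel=0\tTopology=o"),
             tm)
  calls <- parse_localization(tf, tm)
  expect_equal(calls$call, c("SP", "LIPO", "TAT", "OTHER"))
  expect_equal(calls$tm_helix_count[calls$protein_id == "p1"], 3L)
  # absent from the TM file -> defaults to 0
  expect_equal(calls$tm_helix_count[calls$protein_id == "p2"], 0L)

  writeLines("p1\tWEIRD(?)\t0.5", tf)
  expect_error(parse_localization(tf), "unknown localization")
})
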