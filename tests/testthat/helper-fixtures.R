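# In-code fixtures and independent brute-force oracles.

make_genes <- function(genome_id = "G1", contig_id = "c1", n = 12,
                       prefix = "p") {
  tibble::tibble(
    genome_id = genome_id,
    contig_id = contig_id,
    gene_index = seq_len(n) - 1L,
    strand = rep(c("+", "-"), length.out = n),
    protein_id = paste0(genome_id, "_", contig_id, "_", prefix,
                        seq_len(n) - 1L),
    length_aa = 100L + 10L * (seq_len(n) - 1L)
  )
}

hit <- function(protein_id, accession, evalue = 1e-10,
                namespace = if (grepl("^PF", accession)) "pfam"
                            else "kofam",
                bitscore = 100, ali_from = NA_integer_,
                ali_to = NA_integer_) {
  tibble::tibble(protein_id = protein_id, namespace = namespace,
                 accession = accession, evalue = evalue,
                 bitscore = bitscore,
                 ali_from = as.integer(ali_from),
                 ali_to = as.integer(ali_to))
}

loc <- function(protein_id, call = "OTHER", tm = 0L) {
  tibble::tibble(protein_id = protein_id, call = call,
                 tm_helix_count = as.integer(tm))
}

all_other_loc <- function(genes, except = character(0),
                          except_call = "SP") {
  tibble::tibble(
    protein_id = genes$protein_id,
    call = ifelse(genes$protein_id %in% except, except_call, "OTHER"),
    tm_helix_count = 0L
  )
}

# ---- brute-force oracles -------------------------------------------------

# every 4-residue window tested against the closed motif pattern
oracle_scan_motifs <- function(seq, pattern = "^[ST]GA[ST]$") {
  n <- nchar(seq)
  if (n < 4) return(integer(0))
  starts <- seq_len(n - 3L)
  windows <- substring(seq, starts, starts + 3L)
  starts[grepl(pattern, windows)]
}

# independent reimplementation of anchor mining + extracytosolic filter:
# test every gene for the anchor predicate, expand windows naively, merge
# clusters that share members by repeated sweeps, then filter. Returns a
# sorted character vector of clusters, each "member1,member2,...".
oracle_mine <- function(genes, domains, localization, cutoff = 0.001,
                        window = 5L, merge = TRUE) {
  anchor_accs <- c("PF02424", "PF04205", "PF12094", "PF10029")
  is_anchor <- vapply(genes$protein_id, function(p) {
    any(domains$namespace == "pfam" & domains$protein_id == p &
          domains$accession %in% anchor_accs & domains$evalue <= cutoff)
  }, logical(1))
  ec <- localization$protein_id[localization$call %in%
                                  c("SP", "TAT", "LIPO")]
  out <- character(0)
  for (g in unique(genes$genome_id)) {
    for (ct in unique(genes$contig_id[genes$genome_id == g])) {
      sub <- genes[genes$genome_id == g & genes$contig_id == ct, ]
      sub <- sub[order(sub$gene_index), ]
      a_idx <- sub$gene_index[is_anchor[match(sub$protein_id,
                                              genes$protein_id)]]
      if (length(a_idx) == 0) next
      windows <- lapply(a_idx, function(i) {
        sub$gene_index[sub$gene_index >= i - window &
                         sub$gene_index <= i + window]
      })
      if (merge) {
        changed <- TRUE
        while (changed && length(windows) > 1) {
          changed <- FALSE
          for (i in seq_along(windows)) {
            for (j in seq_along(windows)) {
              if (i < j && length(intersect(windows[[i]],
                                            windows[[j]])) > 0) {
                windows[[i]] <- sort(union(windows[[i]], windows[[j]]))
                windows[[j]] <- NULL
                changed <- TRUE
                break
              }
            }
            if (changed) break
          }
        }
      }
      for (w in windows) {
        members <- sub$protein_id[match(sort(w), sub$gene_index)]
        # anchor-role genes anywhere in the merged window
        m_anchor_all <- intersect(members, genes$protein_id[is_anchor])
        if (any(m_anchor_all %in% ec)) {
          out <- c(out, paste(members, collapse = ","))
        }
      }
    }
  }
  sort(unique(out))
}

# best KO per protein by explicit sort-and-pick
oracle_best_ko <- function(hits, cutoff = 0.001) {
  hits <- hits[hits$namespace == "kofam" & hits$evalue <= cutoff, ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(protein_id = character(),
                          accession = character()))
  }
  res <- lapply(split(hits, hits$protein_id), function(h) {
    h <- h[order(h$evalue, -h$bitscore, h$accession), ]
    h[1, c("protein_id", "accession")]
  })
  out <- dplyr::bind_rows(res)
  out[order(out$protein_id), ]
}

AA_COLS <- function() c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# random annotated genome for oracle-equivalence tests: anchors and junk
# annotations scattered with a mix of passing and failing E-values
random_genome <- function(genome_id, max_genes = 200) {
  n_contig <- sample(1:3, 1)
  genes <- dplyr::bind_rows(lapply(seq_len(n_contig), function(ci) {
    make_genes(genome_id, sprintf("c%d", ci),
               n = sample(5:ceiling(max_genes / n_contig), 1))
  }))
  accs <- c("PF02424", "PF04205", "PF12094", "PF10029", "PF00005",
            "K03616")
  n_hits <- sample(0:25, 1)
  hits <- if (n_hits > 0) {
    tibble::tibble(
      protein_id = sample(genes$protein_id, n_hits, replace = TRUE),
      namespace = NA_character_,
      accession = sample(accs, n_hits, replace = TRUE),
      evalue = 10^stats::runif(n_hits, -12, 0.5),
      bitscore = stats::runif(n_hits, 20, 300),
      ali_from = NA_integer_, ali_to = NA_integer_
    ) |>
      dplyr::mutate(namespace = ifelse(grepl("^PF", accession),
                                       "pfam", "kofam"))
  } else {
    tibble::tibble(protein_id = character(), namespace = character(),
                   accession = character(), evalue = double(),
                   bitscore = double(), ali_from = integer(),
                   ali_to = integer())
  }
  localization <- tibble::tibble(
    protein_id = genes$protein_id,
    call = sample(c("SP", "TAT", "LIPO", "OTHER"), nrow(genes),
                  replace = TRUE, prob = c(0.1, 0.05, 0.1, 0.75)),
    tm_helix_count = sample(0:3, nrow(genes), replace = TRUE)
  )
  list(genes = genes, domains = hits, localization = localization)
}

cluster_member_strings <- function(clusters) {
  sort(vapply(clusters$members, paste, character(1), collapse = ","))
}
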