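#' Synthetic-genome generator configuration
#'
#' The generator emulates annotated prokaryotic genomes at the granularity
#' the mining pipeline consumes: contigs of ordered genes carrying Pfam/KO
#' labels with E-values, localization calls, and protein sequences where
#' the analysis needs them (motif substrates, multi-flavinylated proteins).
#' Planted features come with a ground-truth ledger for end-to-end
#' validation.
#'
#' @param n_genomes Number of genomes.
#' @param contigs_per_genome Integer range (length-2) of contigs per genome.
#' @param genes_per_contig Integer range for filler segments and
#'   feature-free contigs.
#' @param system_mix Named numeric vector: per-genome planting probability
#'   for each of the ten systems.
#' @param decoy_anchor_rate Probability a genome carries a type-(a) decoy:
#'   an anchor gene whose anchor-role genes are all cytosolic (must be
#'   removed by the extracytosolic filter).
#' @param decoy_key_rate Probability of a type-(b) decoy: a key gene with
#'   no anchor within the mining window (must yield no cluster).
#' @param background_annotation_rate Per-filler-gene probability of a
#'   random non-rule annotation.
#' @param subthreshold_rate Per-filler-gene probability of an anchor-family
#'   hit with E-value in \[0.01, 1\] — above the 0.001 cutoff, so it must
#'   never create an anchor.
#' @param multiflav_rate Probability a genome carries a multi-flavinylated
#'   protein.
#' @param fmn_domain_count_range Range of FMN-binding domain copies on a
#'   multi-flavinylated protein (observed ceiling: 13).
#' @param orphan_apbe_only_rate,orphan_apbe_duf_rate Probabilities that a
#'   genome is an orphan-ApbE genome: extracytosolic ApbE with no substrate
#'   at all, or with a DUF2271 substrate but no FMN-binding protein.
#' @param n_phyla,genera_per_phylum Shape of the synthetic taxonomy
#'   (genomes assigned round-robin).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genomes = 50L,
                             contigs_per_genome = c(1L, 3L),
                             genes_per_contig = c(15L, 30L),
                             system_mix = stats::setNames(
                               rep(0.2, length(SYSTEM_LABELS)),
                               SYSTEM_LABELS),
                             decoy_anchor_rate = 0.2,
                             decoy_key_rate = 0.2,
                             background_annotation_rate = 0.1,
                             subthreshold_rate = 0.05,
                             multiflav_rate = 0.25,
                             fmn_domain_count_range = c(2L, 13L),
                             orphan_apbe_only_rate = 0.05,
                             orphan_apbe_duf_rate = 0.05,
                             n_phyla = 4L,
                             genera_per_phylum = 3L,
                             seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    contigs_per_genome = as.integer(contigs_per_genome),
    genes_per_contig = as.integer(genes_per_contig),
    system_mix = system_mix,
    decoy_anchor_rate = decoy_anchor_rate,
    decoy_key_rate = decoy_key_rate,
    background_annotation_rate = background_annotation_rate,
    subthreshold_rate = subthreshold_rate,
    multiflav_rate = multiflav_rate,
    fmn_domain_count_range = as.integer(fmn_domain_count_range),
    orphan_apbe_only_rate = orphan_apbe_only_rate,
    orphan_apbe_duf_rate = orphan_apbe_duf_rate,
    n_phyla = as.integer(n_phyla),
    genera_per_phylum = as.integer(genera_per_phylum),
    seed = as.integer(seed)
  )
  probs <- c(cfg$system_mix, cfg$decoy_anchor_rate, cfg$decoy_key_rate,
             cfg$background_annotation_rate, cfg$subthreshold_rate,
             cfg$multiflav_rate, cfg$orphan_apbe_only_rate,
             cfg$orphan_apbe_duf_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all rates/probabilities must lie in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(names(cfg$system_mix), SYSTEM_LABELS)
  if (length(unknown) > 0) {
    stop("system_mix names unknown system(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (rng in list(cfg$contigs_per_genome, cfg$genes_per_contig,
                   cfg$fmn_domain_count_range)) {
    if (length(rng) != 2 || any(is.na(rng)) || rng[1] > rng[2]) {
      stop("ranges must be increasing length-2 integer vectors",
           call. = FALSE)
    }
  }
  max_span <- 6L  # largest template (DsbD cassette)
  if (cfg$genes_per_contig[2] < max_span) {
    stop("genes_per_contig too small for the largest system template (",
         max_span, " genes)", call. = FALSE)
  }
  if (cfg$n_genomes < 1 || cfg$contigs_per_genome[1] < 1) {
    stop("need at least one genome and one contig", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# E-values for planted (passing) annotations: log-uniform in [1e-30, 1e-4].
plant_evalue <- function(n = 1) 10^stats::runif(n, -30, -4)
# Sub-threshold decoy E-values: [0.01, 1], exercising the 0.001 cutoff.
decoy_evalue <- function(n = 1) stats::runif(n, 0.01, 1)

BACKGROUND_POOL <- list(
  pfam = c("PF00001", "PF00005", "PF00072", "PF00106", "PF00440",
           "PF01370", "PF02518", "PF07690"),
  kofam = c("K00001", "K00002", "K00100", "K02014")
)

# One gene specification inside a feature block. pfams may repeat
# (multiplicity = repeated hits); coords is an optional list parallel to
# pfams of c(from, to).
gspec <- function(pfams = character(), ko = NA_character_, loc = "OTHER",
                  tm = 0L, length_aa = NULL, sequence = NA_character_,
                  coords = NULL, tag = NA_character_,
                  motif_positions = NULL) {
  length_aa <- length_aa %||% sample(120:600, 1)
  if (!is.na(sequence)) length_aa <- nchar(sequence)
  tibble::tibble(
    pfams = list(pfams), ko = ko, loc = loc, tm = as.integer(tm),
    length_aa = as.integer(length_aa), sequence = sequence,
    coords = list(coords), tag = tag,
    motif_positions = list(as.integer(motif_positions))
  )
}

filler_genes <- function(n, cfg) {
  if (n <= 0) return(NULL)
  purrr::map_dfr(seq_len(n), function(i) {
    r <- stats::runif(1)
    if (r < cfg$subthreshold_rate) {
      # anchor-family hit that fails the cutoff; give it a signal peptide
      # so only the E-value rule can reject it
      g <- gspec(pfams = FMN_PFAM, loc = "SP", tag = "subthreshold")
    } else if (r < cfg$subthreshold_rate + cfg$background_annotation_rate) {
      if (stats::runif(1) < 0.7) {
        g <- gspec(pfams = sample(BACKGROUND_POOL$pfam, 1),
                   tag = "background")
      } else {
        g <- gspec(ko = sample(BACKGROUND_POOL$kofam, 1),
                   tag = "background")
      }
    } else {
      g <- gspec(tag = "filler")
    }
    g
  })
}

# Feature blocks. Each returns list(genes = tibble of gspecs,
# meta = list(...)). Relative gene positions are row numbers - 1.
template_block <- function(system, cfg) {
  fmn_anchor <- gspec(pfams = FMN_PFAM, loc = "SP", tag = "anchor_fmn")
  apbe <- gspec(pfams = APBE_PFAM, loc = "OTHER", tag = "apbe")
  meta <- list(system = system, naph_mode = NA_character_,
               ec_apbe = FALSE, ec_fmn = TRUE, ec_duf = FALSE)
  genes <- switch(
    system,
    RNF = dplyr::bind_rows(fmn_anchor, apbe,
                           gspec(ko = "K03616", tag = "key")),
    NOS = dplyr::bind_rows(fmn_anchor, apbe,
                           gspec(ko = "K00376", tag = "key")),
    PCE = dplyr::bind_rows(fmn_anchor, apbe,
                           gspec(pfams = "PF13486", tag = "key")),
    EET = dplyr::bind_rows(fmn_anchor, apbe,
                           gspec(ko = "K03885", tm = sample(1:3, 1),
                                 tag = "key")),
    NQR = dplyr::bind_rows(fmn_anchor, apbe,
                           gspec(ko = "K00351", tag = "key")),
    NAPH_LIKE = {
      use_pfam_key <- stats::runif(1) < 0.5
      fused <- stats::runif(1) < 0.75
      meta$naph_mode <- if (fused) "fused" else "separate"
      if (fused) {
        key <- if (use_pfam_key) {
          gspec(pfams = c("PF12801", FMN_PFAM), loc = "SP",
                tm = sample(2:6, 1), tag = "key_anchor")
        } else {
          gspec(pfams = FMN_PFAM, ko = "K19339", loc = "SP",
                tm = sample(2:6, 1), tag = "key_anchor")
        }
        dplyr::bind_rows(key, apbe)
      } else {
        key <- if (use_pfam_key) {
          gspec(pfams = "PF12801", tm = sample(2:6, 1), tag = "key")
        } else {
          gspec(ko = "K19339", tm = sample(2:6, 1), tag = "key")
        }
        dplyr::bind_rows(fmn_anchor, apbe, key)
      }
    },
    MSRQ_LIKE = {
      msrq <- if (stats::runif(1) < 0.5) {
        gspec(pfams = c("PF01794", "PF00175"), tm = 6L, tag = "key")
      } else {
        gspec(pfams = "PF01794", tm = 6L, tag = "key")
      }
      dplyr::bind_rows(fmn_anchor, apbe, msrq)
    },
    PEPSY = {
      key <- gspec(pfams = sample(c("PF03929", "PF16357"), 1), tm = 3L,
                   tag = "key")
      rows <- dplyr::bind_rows(fmn_anchor, apbe, key)
      if (stats::runif(1) < 0.5) {
        s <- make_motif_sequence(1, sample(120:160, 1))
        meta$ec_duf <- TRUE
        rows <- dplyr::bind_rows(rows,
          gspec(pfams = "PF10029", loc = "SP", sequence = s$sequence,
                tag = "duf2271", motif_positions = s$positions))
      }
      rows
    },
    DSBD = {
      s <- make_motif_sequence(2, sample(380:450, 1))
      meta$ec_apbe <- TRUE
      meta$ec_fmn <- FALSE
      meta$ec_duf <- TRUE
      dplyr::bind_rows(
        gspec(pfams = APBE_PFAM, loc = "LIPO", tag = "apbe_anchor"),
        gspec(pfams = "PF12094", loc = "SP", sequence = s$sequence,
              tag = "duf3570", motif_positions = s$positions),
        gspec(pfams = "PF13899", loc = "SP", tag = "thioredoxin"),
        gspec(pfams = "PF14086", loc = "SP", tag = "duf4266"),
        gspec(pfams = "PF02683", tm = 8L, tag = "key")
      )
    },
    NQR_RNF_LIKE = {
      len <- sample(400:700, 1)
      n_from <- sample(seq(ceiling(0.05 * len), floor(0.45 * len) - 60), 1)
      c_from <- sample(seq(ceiling(0.55 * len), floor(0.95 * len) - 60), 1)
      key <- gspec(
        pfams = c("PF03116", "PF00175"), tm = sample(6:10, 1),
        length_aa = len,
        coords = list(c(n_from, n_from + 60L), c(c_from, c_from + 60L)),
        tag = "key")
      dplyr::bind_rows(fmn_anchor, apbe, key)
    },
    stop("no template for system ", system)
  )
  # motif truth for substrate sequences planted above
  motif_rows <- which(!is.na(genes$sequence))
  list(genes = genes, meta = meta, kind = "system",
       motif_rows = motif_rows)
}

multiflav_block <- function(cfg) {
  k <- sample(seq(cfg$fmn_domain_count_range[1],
                  cfg$fmn_domain_count_range[2]), 1)
  len <- max(120L, k * 110L)
  s <- make_motif_sequence(k, len)
  slab <- len %/% k
  coords <- lapply(seq_len(k) - 1L,
                   function(i) c(i * slab + 1L,
                                 min((i + 1L) * slab, len)))
  genes <- dplyr::bind_rows(
    gspec(pfams = rep(FMN_PFAM, k), loc = "SP", sequence = s$sequence,
          coords = coords, tag = "multiflav",
          motif_positions = s$positions),
    gspec(pfams = APBE_PFAM, loc = "OTHER", tag = "apbe")
  )
  list(genes = genes, kind = "multiflav", n_domains = k,
       meta = list(ec_fmn = TRUE, ec_apbe = FALSE, ec_duf = FALSE))
}

orphan_block <- function(type) {
  if (type == "orphan_apbe_only") {
    genes <- gspec(pfams = APBE_PFAM, loc = "SP", tag = "apbe_anchor")
    meta <- list(ec_apbe = TRUE, ec_fmn = FALSE, ec_duf = FALSE)
  } else {
    s <- make_motif_sequence(1, sample(120:160, 1))
    genes <- dplyr::bind_rows(
      gspec(pfams = APBE_PFAM, loc = "SP", tag = "apbe_anchor"),
      gspec(pfams = "PF10029", loc = "SP", sequence = s$sequence,
            tag = "duf2271", motif_positions = s$positions)
    )
    meta <- list(ec_apbe = TRUE, ec_fmn = FALSE, ec_duf = TRUE)
  }
  list(genes = genes, kind = type, meta = meta)
}

decoy_block <- function(type) {
  if (type == "decoy_anchor") {
    # anchor family genes, all cytosolic: the extracytosolic filter must
    # drop the cluster even though a key gene sits in the window
    genes <- dplyr::bind_rows(
      gspec(pfams = FMN_PFAM, loc = "OTHER", tag = "decoy_anchor"),
      gspec(ko = "K00376", tag = "decoy_key_in_window")
    )
  } else {
    # key gene with no anchor anywhere near: must produce no cluster
    genes <- gspec(ko = "K03616", tag = "decoy_lone_key")
  }
  list(genes = genes, kind = type, meta = list(ec_apbe = FALSE,
                                               ec_fmn = FALSE,
                                               ec_duf = FALSE))
}

#' Generate a synthetic motif-bearing protein sequence
#'
#' Plants `n_sites` non-overlapping `[ST]GA[ST]` windows at random
#' positions. Flanking residues are drawn from an alphabet excluding S, T
#' and G, which guarantees no accidental motif can form anywhere —
#' including across the junction of a planted site and its flank.
#'
#' @param n_sites Number of motif sites to plant (0 allowed).
#' @param length Total sequence length; must be at least `4 * n_sites`.
#' @param seed Optional seed for standalone use; inside
#'   [generate_genomes()] the enclosing stream is used.
#' @return List with `sequence` and integer `positions` (1-based motif
#'   starts).
#' @export
make_motif_sequence <- function(n_sites, length, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, make_motif_sequence(n_sites, length)))
  }
  n_sites <- as.integer(n_sites)
  length <- as.integer(length)
  if (4L * n_sites > length) {
    stop("cannot pack ", n_sites, " motif sites into ", length,
         " residues", call. = FALSE)
  }
  flank_alphabet <- setdiff(AA_ALPHABET, c("S", "T", "G"))
  chars <- sample(flank_alphabet, length, replace = TRUE)
  positions <- integer(0)
  if (n_sites > 0) {
    slack <- sort(sample(0:(length - 4L * n_sites), n_sites,
                         replace = TRUE))
    positions <- slack + 4L * (seq_len(n_sites) - 1L) + 1L
    for (p in positions) {
      chars[p:(p + 3L)] <- c(sample(c("S", "T"), 1), "G", "A",
                             sample(c("S", "T"), 1))
    }
  }
  list(sequence = paste(chars, collapse = ""), positions = positions)
}

#' Generate synthetic annotated genomes with ground truth
#'
#' Builds `n_genomes` genomes by concatenating planted feature blocks
#' (system templates, multi-flavinylated proteins, orphan-ApbE cassettes,
#' decoys) separated by filler segments long enough that distinct features
#' never share a mining window, then assembling gene tables, annotation
#' hits, localization calls, sequences and a round-robin taxonomy. Every
#' planted system template satisfies exactly its classification rule and
#' the extracytosolic filter; decoys are constructed to be rejected.
#'
#' @param config A [generator_config()].
#' @return List with `genomes` (an [annotated_genomes()] bundle) and
#'   `truth` (list of tibbles: `genomes`, `systems`, `motifs`,
#'   `multiflav`, `decoys`).
#' @export
generate_genomes <- function(config = generator_config()) {
  withr::with_seed(config$seed, generate_genomes_impl(config))
}

generate_genomes_impl <- function(cfg) {
  # separator long enough that anchors of adjacent blocks are > 11 genes
  # apart: no window sharing, no accidental cluster merging
  SEP <- 12L
  phyla <- sprintf("Phylum%02d", seq_len(cfg$n_phyla))
  genera <- sprintf("Genus%02d",
                    seq_len(cfg$n_phyla * cfg$genera_per_phylum))

  all_genes <- list(); all_domains <- list(); all_loc <- list()
  all_seqs <- list(); all_tax <- list()
  truth_genomes <- list(); truth_systems <- list()
  truth_motifs <- list(); truth_multiflav <- list()
  truth_decoys <- list()

  for (gi in seq_len(cfg$n_genomes)) {
    genome_id <- sprintf("G%04d", gi)
    r <- stats::runif(1)
    gtype <- if (r < cfg$orphan_apbe_only_rate) {
      "orphan_apbe_only"
    } else if (r < cfg$orphan_apbe_only_rate + cfg$orphan_apbe_duf_rate) {
      "orphan_apbe_duf"
    } else {
      "normal"
    }
    blocks <- list()
    if (gtype == "normal") {
      for (sys in names(cfg$system_mix)) {
        if (stats::runif(1) < cfg$system_mix[[sys]]) {
          blocks <- c(blocks, list(template_block(sys, cfg)))
        }
      }
      if (stats::runif(1) < cfg$multiflav_rate) {
        blocks <- c(blocks, list(multiflav_block(cfg)))
      }
      if (stats::runif(1) < cfg$decoy_anchor_rate) {
        blocks <- c(blocks, list(decoy_block("decoy_anchor")))
      }
      if (stats::runif(1) < cfg$decoy_key_rate) {
        blocks <- c(blocks, list(decoy_block("decoy_key")))
      }
      if (length(blocks) > 1) blocks <- sample(blocks)
    } else {
      blocks <- list(orphan_block(gtype))
    }

    n_contigs <- sample(seq(cfg$contigs_per_genome[1],
                            cfg$contigs_per_genome[2]), 1)
    contig_of_block <- if (length(blocks) > 0) {
      sort(rep_len(seq_len(n_contigs), length(blocks)))
    } else {
      integer(0)
    }

    ec_apbe <- FALSE; ec_fmn <- FALSE; ec_duf <- FALSE
    for (ci in seq_len(n_contigs)) {
      contig_id <- sprintf("c%02d", ci)
      my_blocks <- blocks[contig_of_block == ci]
      specs <- filler_genes(sample(3:6, 1), cfg)
      block_start <- integer(length(my_blocks))
      for (bi in seq_along(my_blocks)) {
        if (bi > 1) specs <- dplyr::bind_rows(specs, filler_genes(SEP, cfg))
        block_start[bi] <- if (is.null(specs)) 0L else nrow(specs)
        specs <- dplyr::bind_rows(specs, my_blocks[[bi]]$genes)
      }
      n_tail <- if (length(my_blocks) > 0) {
        sample(3:6, 1)
      } else {
        sample(seq(cfg$genes_per_contig[1], cfg$genes_per_contig[2]), 1)
      }
      specs <- dplyr::bind_rows(specs, filler_genes(n_tail, cfg))
      n <- nrow(specs)
      idx <- seq_len(n) - 1L
      protein_id <- sprintf("%s_%s_p%03d", genome_id, contig_id, idx)

      all_genes[[length(all_genes) + 1]] <- tibble::tibble(
        genome_id = genome_id, contig_id = contig_id, gene_index = idx,
        strand = sample(c("+", "-"), n, replace = TRUE),
        protein_id = protein_id, length_aa = specs$length_aa
      )
      all_loc[[length(all_loc) + 1]] <- tibble::tibble(
        protein_id = protein_id, call = specs$loc,
        tm_helix_count = specs$tm
      )
      seq_rows <- which(!is.na(specs$sequence))
      if (length(seq_rows) > 0) {
        all_seqs[[length(all_seqs) + 1]] <- tibble::tibble(
          protein_id = protein_id[seq_rows],
          sequence = specs$sequence[seq_rows]
        )
        for (sr in seq_rows) {
          pos <- specs$motif_positions[[sr]]
          if (length(pos) > 0) {
            truth_motifs[[length(truth_motifs) + 1]] <- tibble::tibble(
              genome_id = genome_id, protein_id = protein_id[sr],
              position = pos, tag = specs$tag[sr]
            )
          }
        }
      }
      # domain hits
      for (ri in seq_len(n)) {
        pf <- specs$pfams[[ri]]
        sub <- identical(specs$tag[ri], "subthreshold")
        if (length(pf) > 0) {
          co <- specs$coords[[ri]]
          all_domains[[length(all_domains) + 1]] <- tibble::tibble(
            protein_id = protein_id[ri], namespace = "pfam",
            accession = pf,
            evalue = if (sub) decoy_evalue(length(pf))
                     else plant_evalue(length(pf)),
            bitscore = round(stats::runif(length(pf), 50, 500), 1),
            ali_from = if (is.null(co)) NA_integer_
                       else vapply(co, function(x) as.integer(x[1]),
                                   integer(1)),
            ali_to = if (is.null(co)) NA_integer_
                     else vapply(co, function(x) as.integer(x[2]),
                                 integer(1))
          )
        }
        if (!is.na(specs$ko[ri])) {
          all_domains[[length(all_domains) + 1]] <- tibble::tibble(
            protein_id = protein_id[ri], namespace = "kofam",
            accession = specs$ko[ri], evalue = plant_evalue(1),
            bitscore = round(stats::runif(1, 50, 500), 1),
            ali_from = NA_integer_, ali_to = NA_integer_
          )
        }
      }
      # truth records for the blocks on this contig
      for (bi in seq_along(my_blocks)) {
        blk <- my_blocks[[bi]]
        s0 <- block_start[bi]
        span <- s0:(s0 + nrow(blk$genes) - 1L)
        blk_pids <- protein_id[span + 1L]
        ec_apbe <- ec_apbe || isTRUE(blk$meta$ec_apbe)
        ec_fmn <- ec_fmn || isTRUE(blk$meta$ec_fmn)
        ec_duf <- ec_duf || isTRUE(blk$meta$ec_duf)
        if (blk$kind == "system") {
          anchor_tags <- c("anchor_fmn", "key_anchor", "apbe_anchor")
          truth_systems[[length(truth_systems) + 1]] <- tibble::tibble(
            genome_id = genome_id, contig_id = contig_id,
            system = blk$meta$system,
            start_index = min(span), end_index = max(span),
            anchor_protein = blk_pids[blk$genes$tag %in% anchor_tags][1],
            naph_fmn_mode = blk$meta$naph_mode
          )
        } else if (blk$kind == "multiflav") {
          truth_multiflav[[length(truth_multiflav) + 1]] <- tibble::tibble(
            genome_id = genome_id,
            protein_id = blk_pids[blk$genes$tag == "multiflav"],
            n_domains = blk$n_domains
          )
        } else if (blk$kind %in% c("decoy_anchor", "decoy_key")) {
          truth_decoys[[length(truth_decoys) + 1]] <- tibble::tibble(
            genome_id = genome_id, type = blk$kind,
            protein_id = blk_pids[1]
          )
        }
      }
    }
    phylum <- phyla[(gi - 1L) %% cfg$n_phyla + 1L]
    genus <- genera[(gi - 1L) %% length(genera) + 1L]
    all_tax[[length(all_tax) + 1]] <- tibble::tibble(
      genome_id = genome_id,
      lineage = sprintf(
        "d__Bacteria;p__%s;c__ClassA;o__OrderA;f__FamilyA;g__%s;s__%s sp%04d",
        phylum, genus, genus, gi)
    )
    truth_genomes[[length(truth_genomes) + 1]] <- tibble::tibble(
      genome_id = genome_id, type = gtype,
      ec_apbe = ec_apbe, ec_fmn = ec_fmn, ec_duf = ec_duf,
      orphan_fmn_only = ec_apbe && !ec_fmn,
      orphan_extended = ec_apbe && !ec_fmn && !ec_duf
    )
  }

  genes <- dplyr::bind_rows(all_genes)
  domains <- dplyr::bind_rows(all_domains)
  if (nrow(domains) == 0) domains <- empty_hits()
  localization <- dplyr::bind_rows(all_loc)
  sequences <- if (length(all_seqs) > 0) {
    dplyr::bind_rows(all_seqs)
  } else {
    tibble::tibble(protein_id = character(), sequence = character())
  }
  taxonomy <- parse_lineage(dplyr::bind_rows(all_tax))

  truth <- list(
    genomes = dplyr::bind_rows(truth_genomes),
    systems = dplyr::bind_rows(truth_systems) %||%
      tibble::tibble(),
    motifs = dplyr::bind_rows(truth_motifs),
    multiflav = dplyr::bind_rows(truth_multiflav),
    decoys = dplyr::bind_rows(truth_decoys)
  )
  if (nrow(truth$systems) == 0) {
    truth$systems <- tibble::tibble(
      genome_id = character(), contig_id = character(),
      system = character(), start_index = integer(),
      end_index = integer(), anchor_protein = character(),
      naph_fmn_mode = character())
  }
  if (nrow(truth$motifs) == 0) {
    truth$motifs <- tibble::tibble(genome_id = character(),
                                   protein_id = character(),
                                   position = integer(), tag = character())
  }
  if (nrow(truth$multiflav) == 0) {
    truth$multiflav <- tibble::tibble(genome_id = character(),
                                      protein_id = character(),
                                      n_domains = integer())
  }
  if (nrow(truth$decoys) == 0) {
    truth$decoys <- tibble::tibble(genome_id = character(),
                                   type = character(),
                                   protein_id = character())
  }

  list(
    genomes = annotated_genomes(genes, domains = domains,
                                localization = localization,
                                sequences = sequences,
                                taxonomy = taxonomy),
    truth = truth
  )
}

#' Write a synthetic bundle to fixture files
#'
#' Emits the pipeline's input dialects — gene table TSV, protein FASTA,
#' annotation TSV, localization TSV, taxonomy TSV — plus the truth-ledger
#' TSVs, all parseable by the package readers.
#'
#' @param bundle Output of [generate_genomes()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixture_files <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- bundle$genomes
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    proteins = file.path(dir, "proteins.faa"),
    annotations = file.path(dir, "annotations.tsv"),
    localization = file.path(dir, "localization.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv")
  )
  write_gene_table(g$genes, paths[["genes"]])
  write_protein_fasta(g$sequences, paths[["proteins"]])
  write_annotation_tsv(g$domains, paths[["annotations"]])
  write_localization_tsv(g$localization, paths[["localization"]])
  write_taxonomy(g$taxonomy, paths[["taxonomy"]])
  for (nm in names(bundle$truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    readr::write_tsv(bundle$truth[[nm]], p)
    paths[[paste0("truth_", nm)]] <- p
  }
  invisible(paths)
}

#' Score recovered systems against the planted truth
#'
#' Cluster level: a planted system is recovered when a detected cluster on
#' the same contig overlaps its gene span and carries its label; an
#' assigned (cluster, system) pair is correct when such a planted span
#' exists. Genome level: planted and detected (genome, system) pairs are
#' compared as sets.
#'
#' @param clusters Filtered cluster tibble.
#' @param assignments `flav_assignments` for `clusters`.
#' @param truth Truth ledger from [generate_genomes()].
#' @return One-row tibble: `cluster_recall`, `cluster_precision`,
#'   `genome_recall`, `genome_precision`, `n_planted`, `n_assigned`.
#' @export
evaluate_recovery <- function(clusters, assignments, truth) {
  planted <- truth$systems
  assigned <- tidy(assignments) %>%
    dplyr::inner_join(
      clusters[, c("cluster_id", "genome_id", "contig_id",
                   "start_index", "end_index")],
      by = "cluster_id")
  overlaps <- function(g, c, s, e, sys) {
    any(planted$genome_id == g & planted$contig_id == c &
          planted$system == sys & planted$start_index <= e &
          planted$end_index >= s)
  }
  recovered <- purrr::pmap_lgl(
    list(planted$genome_id, planted$contig_id, planted$system,
         planted$start_index, planted$end_index),
    function(g, c, sys, s, e) {
      any(assigned$genome_id == g & assigned$contig_id == c &
            assigned$system == sys & assigned$start_index <= e &
            assigned$end_index >= s)
    })
  correct <- purrr::pmap_lgl(
    list(assigned$genome_id, assigned$contig_id, assigned$start_index,
         assigned$end_index, assigned$system),
    overlaps)
  planted_gs <- unique(paste(planted$genome_id, planted$system))
  assigned_gs <- unique(paste(assigned$genome_id, assigned$system))
  tibble::tibble(
    cluster_recall = if (nrow(planted) == 0) 1 else mean(recovered),
    cluster_precision = if (nrow(assigned) == 0) 1 else mean(correct),
    genome_recall = if (length(planted_gs) == 0) 1 else
      mean(planted_gs %in% assigned_gs),
    genome_precision = if (length(assigned_gs) == 0) 1 else
      mean(assigned_gs %in% planted_gs),
    n_planted = nrow(planted),
    n_assigned = nrow(assigned)
  )
}
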