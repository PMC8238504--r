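#' Load the system rule table
#'
#' The rule table maps each of the ten electron-transfer systems to the
#' key-gene condition that assigns a flavinylation-associated cluster to it,
#' plus the accessory-feature accessions annotated on assigned clusters. It
#' ships as an editable YAML file so refined per-system definitions can be
#' dropped in without code changes.
#'
#' @param path Path to a rules YAML; `NULL` loads the packaged default.
#' @return A list of class `system_rules` with elements `systems` (named
#'   list of predicates) and `accessories` (named accession vector).
#' @export
read_system_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "system_rules.yaml",
                                package = "flavimine")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$systems) || length(raw$systems) == 0) {
    stop("rule table defines no systems", call. = FALSE)
  }
  check_acc <- function(acc, where) {
    ns <- sub(":.*$", "", acc)
    bad <- setdiff(ns, c("pfam", "kofam"))
    if (length(bad) > 0) {
      stop("rule table (", where, ") references unknown namespace '",
           bad[1], "'", call. = FALSE)
    }
  }
  for (sys in names(raw$systems)) {
    rule <- raw$systems[[sys]]
    if (!is.null(rule$key_any)) check_acc(unlist(rule$key_any), sys)
    if (!is.null(rule$architecture)) {
      check_acc(unlist(rule$architecture), sys)
    }
    if (is.null(rule$key_any) && is.null(rule$architecture)) {
      stop("rule for ", sys, " has neither key_any nor architecture",
           call. = FALSE)
    }
  }
  acc <- unlist(raw$accessories %||% list())
  if (length(acc) > 0) check_acc(acc, "accessories")
  structure(list(systems = raw$systems, accessories = acc),
            class = "system_rules")
}

# Per-protein label table used by the classifier: passing Pfam accessions
# (all of them) plus the best-KO label, each namespace-qualified.
protein_labels <- function(domains, cfg) {
  pf <- collect_pfam_domains(domains, cfg) %>%
    dplyr::transmute(.data$protein_id,
                     label = paste0("pfam:", .data$accession))
  ko <- assign_best_ko(domains, cfg) %>%
    dplyr::transmute(.data$protein_id,
                     label = paste0("kofam:", .data$accession))
  dplyr::bind_rows(pf, ko) %>% dplyr::distinct()
}

#' Test the NQR/RNF-like single-protein domain architecture
#'
#' True iff one protein carries an NqrB/RnfD-homologous membrane domain
#' (PF03116) that starts in the N-terminal half of the protein and precedes
#' an NqrF-like NAD-binding domain (PF00175).
#'
#' @param hits Passing Pfam hits for one protein (`accession`, `ali_from`,
#'   `ali_to`).
#' @param protein_length Protein length in residues.
#' @return Logical. Missing alignment coordinates make the test
#'   indeterminate: it returns `FALSE` with a warning.
#' @export
check_nqr_rnf_like <- function(hits, protein_length) {
  n_hits <- hits[hits$accession == "PF03116", , drop = FALSE]
  c_hits <- hits[hits$accession == "PF00175", , drop = FALSE]
  if (nrow(n_hits) == 0 || nrow(c_hits) == 0) {
    return(FALSE)
  }
  if (anyNA(n_hits$ali_from) || anyNA(c_hits$ali_from)) {
    warning("missing alignment coordinates; NQR/RNF-like architecture ",
            "indeterminate, reported FALSE", call. = FALSE)
    return(FALSE)
  }
  any(vapply(n_hits$ali_from, function(nf) {
    nf <= protein_length / 2 && any(c_hits$ali_from > nf)
  }, logical(1)))
}

#' Assign gene clusters to electron-transfer systems
#'
#' Matches every cluster independently against each rule in the table;
#' multi-label assignment is deliberate (PepSY-like and MsrQ-like genes
#' genuinely co-occur in some clusters). Clusters matching no rule get an
#' empty system set. KO labels use the best-hit-per-protein convention;
#' Pfam labels use all passing hits.
#'
#' For NapH-like assignments the FMN partition is recorded:
#' `"fused"` when the NapH-like gene itself carries an FMN-binding domain,
#' `"separate"` when another cluster member does, `"none"` otherwise.
#'
#' @param clusters Filtered cluster tibble (see [filter_extracytosolic()]).
#' @param genes Gene tibble (protein lengths for architecture checks).
#' @param domains Domain-hit tibble.
#' @param localization Localization tibble (TM-helix counts).
#' @param rules A [read_system_rules()] table.
#' @param cfg An [annotation_config()].
#' @return A `flav_assignments` tibble: `cluster_id`, `systems` (list of
#'   character vectors), `n_systems`, `naph_fmn_mode`.
#' @export
classify_clusters <- function(clusters, genes, domains, localization,
                              rules = read_system_rules(),
                              cfg = annotation_config()) {
  labels <- protein_labels(domains, cfg)
  tm <- localization %>%
    dplyr::select("protein_id", "tm_helix_count")
  pf_coords <- collect_pfam_domains(domains, cfg)
  lengths_tab <- genes %>% dplyr::select("protein_id", "length_aa")

  assign_one <- function(member_ids) {
    mem_labels <- labels[labels$protein_id %in% member_ids, , drop = FALSE]
    systems <- character(0)
    for (sys in names(rules$systems)) {
      rule <- rules$systems[[sys]]
      hit <- FALSE
      if (!is.null(rule$key_any)) {
        carriers <- unique(
          mem_labels$protein_id[mem_labels$label %in% unlist(rule$key_any)]
        )
        if (length(carriers) > 0) {
          if (isTRUE(rule$tm_required)) {
            tmc <- tm$tm_helix_count[match(carriers, tm$protein_id)]
            hit <- any(!is.na(tmc) & tmc >= 1L)
          } else {
            hit <- TRUE
          }
        }
      }
      if (!hit && !is.null(rule$architecture)) {
        n_acc <- sub("^[a-z]+:", "", rule$architecture$n_term)
        c_acc <- sub("^[a-z]+:", "", rule$architecture$c_term)
        cand <- pf_coords[pf_coords$protein_id %in% member_ids &
                            pf_coords$accession %in% c(n_acc, c_acc), ,
                          drop = FALSE]
        for (p in unique(cand$protein_id)) {
          plen <- lengths_tab$length_aa[match(p, lengths_tab$protein_id)]
          ph <- cand[cand$protein_id == p, , drop = FALSE]
          # architecture check is written against PF03116/PF00175; map the
          # configured accessions onto those slots
          ph2 <- ph
          ph2$accession[ph$accession == n_acc] <- "PF03116"
          ph2$accession[ph$accession == c_acc] <- "PF00175"
          if (isTRUE(check_nqr_rnf_like(ph2, plen))) {
            hit <- TRUE
            break
          }
        }
      }
      if (hit) systems <- c(systems, sys)
    }
    systems
  }

  naph_mode_one <- function(member_ids, systems) {
    if (!"NAPH_LIKE" %in% systems) return(NA_character_)
    naph_keys <- unlist(rules$systems$NAPH_LIKE$key_any)
    mem_labels <- labels[labels$protein_id %in% member_ids, , drop = FALSE]
    naph_carriers <- unique(
      mem_labels$protein_id[mem_labels$label %in% naph_keys]
    )
    fmn_carriers <- unique(
      mem_labels$protein_id[mem_labels$label == paste0("pfam:", FMN_PFAM)]
    )
    if (any(naph_carriers %in% fmn_carriers)) "fused"
    else if (length(fmn_carriers) > 0) "separate"
    else "none"
  }

  systems <- purrr::map(clusters$members, assign_one)
  out <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    systems = systems,
    n_systems = lengths(systems),
    naph_fmn_mode = purrr::map2_chr(clusters$members, systems,
                                    naph_mode_one)
  )
  class(out) <- c("flav_assignments", class(out))
  attr(out, "rules") <- rules
  out
}

#' @export
#' @rdname classify_clusters
#' @param x A `flav_assignments` object.
#' @param ... Unused.
tidy.flav_assignments <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::select("cluster_id", "systems") %>%
    tidyr::unnest_longer("systems", values_to = "system",
                         keep_empty = FALSE)
}

#' @export
#' @rdname classify_clusters
glance.flav_assignments <- function(x, ...) {
  long <- tidy(x)
  tibble::tibble(
    n_clusters = nrow(x),
    n_classified = sum(x$n_systems > 0),
    n_unclassified = sum(x$n_systems == 0),
    n_assignments = nrow(long),
    n_systems_seen = dplyr::n_distinct(long$system)
  )
}

#' Annotate accessory features on assigned clusters
#'
#' For every cluster and every accessory accession in the rule table,
#' records each carrier protein and whether the feature is fused to a core
#' (key) gene of one of the cluster's assigned systems or encoded elsewhere
#' in the cluster.
#'
#' @inheritParams classify_clusters
#' @param assignments Output of [classify_clusters()].
#' @return Long tibble `cluster_id`, `feature`, `carrier`, `fused`.
#' @export
annotate_accessories <- function(clusters, assignments, domains,
                                 rules = read_system_rules(),
                                 cfg = annotation_config()) {
  if (length(rules$accessories) == 0 || nrow(clusters) == 0) {
    return(tibble::tibble(cluster_id = character(), feature = character(),
                          carrier = character(), fused = logical()))
  }
  labels <- protein_labels(domains, cfg)
  acc_tab <- tibble::tibble(feature = names(rules$accessories),
                            label = unname(rules$accessories))
  key_labels_for <- function(systems) {
    unlist(lapply(systems, function(sys) {
      rule <- rules$systems[[sys]]
      c(unlist(rule$key_any), unlist(rule$architecture))
    }))
  }
  purrr::pmap_dfr(
    list(clusters$cluster_id, clusters$members,
         assignments$systems[match(clusters$cluster_id,
                                   assignments$cluster_id)]),
    function(cid, member_ids, systems) {
      mem_labels <- labels[labels$protein_id %in% member_ids, ,
                           drop = FALSE]
      found <- mem_labels %>% dplyr::inner_join(acc_tab, by = "label")
      if (nrow(found) == 0) return(NULL)
      keys <- key_labels_for(systems %||% character(0))
      key_carriers <- unique(
        mem_labels$protein_id[mem_labels$label %in% keys]
      )
      tibble::tibble(
        cluster_id = cid,
        feature = found$feature,
        carrier = found$protein_id,
        fused = found$protein_id %in% key_carriers
      )
    }
  )
}

#' Detect orphan-ApbE genomes
#'
#' A genome is an orphan-ApbE genome when it encodes at least one
#' extracytosolic ApbE (PF02424 with a signal peptide or lipoprotein
#' signal) but no extracytosolic protein carrying a recognized flavinylation
#' substrate. Both substrate definitions are evaluated: FMN-binding only
#' (PF04205), and the extended set that adds the DUF2271 (PF10029) and
#' DUF3570 (PF12094) substrates — the extension that resolves most orphans.
#'
#' @param genes Gene tibble (supplies the genome of each protein).
#' @param domains Domain-hit tibble.
#' @param localization Localization tibble.
#' @param cfg An [annotation_config()].
#' @return Tibble `genome_id`, `has_ec_apbe`, `orphan_fmn_only`,
#'   `orphan_extended`, one row per genome in `genes`.
#' @export
find_orphan_apbe <- function(genes, domains, localization,
                             cfg = annotation_config()) {
  ec_ids <- localization$protein_id[localization$call %in%
                                      EXTRACYTOSOLIC_CALLS]
  pf <- collect_pfam_domains(domains, cfg) %>%
    dplyr::filter(.data$protein_id %in% ec_ids) %>%
    dplyr::inner_join(genes[, c("protein_id", "genome_id")],
                      by = "protein_id")
  per_genome <- pf %>%
    dplyr::group_by(.data$genome_id) %>%
    dplyr::summarise(
      has_ec_apbe = any(.data$accession == APBE_PFAM),
      has_ec_fmn  = any(.data$accession == FMN_PFAM),
      has_ec_duf  = any(.data$accession %in%
                          ANCHOR_PFAMS[c("DUF3570", "DUF2271")]),
      .groups = "drop"
    )
  genes %>%
    dplyr::distinct(.data$genome_id) %>%
    dplyr::left_join(per_genome, by = "genome_id") %>%
    dplyr::mutate(
      dplyr::across(c("has_ec_apbe", "has_ec_fmn", "has_ec_duf"),
                    ~ dplyr::coalesce(.x, FALSE)),
      orphan_fmn_only = .data$has_ec_apbe & !.data$has_ec_fmn,
      orphan_extended = .data$has_ec_apbe & !.data$has_ec_fmn &
        !.data$has_ec_duf
    ) %>%
    dplyr::select("genome_id", "has_ec_apbe", "orphan_fmn_only",
                  "orphan_extended")
}

#' Find multi-flavinylated proteins
#'
#' Proteins carrying more than one passing FMN-binding (PF04205) domain
#' hit; up to 13 have been observed on a single protein. When a
#' localization table is supplied only extracytosolic proteins are
#' reported.
#'
#' @param domains Domain-hit tibble.
#' @param localization Optional localization tibble; restricts the result
#'   to proteins with SP/TAT/LIPO calls.
#' @param cfg An [annotation_config()].
#' @return Tibble `protein_id`, `fmn_domain_count`, sorted by descending
#'   count.
#' @export
find_multiflavinylated <- function(domains, localization = NULL,
                                   cfg = annotation_config()) {
  counts <- collect_pfam_domains(domains, cfg) %>%
    dplyr::filter(.data$accession == FMN_PFAM) %>%
    dplyr::count(.data$protein_id, name = "fmn_domain_count") %>%
    dplyr::filter(.data$fmn_domain_count > 1L)
  if (!is.null(localization)) {
    ec_ids <- localization$protein_id[localization$call %in%
                                        EXTRACYTOSOLIC_CALLS]
    counts <- dplyr::filter(counts, .data$protein_id %in% ec_ids)
  }
  dplyr::arrange(counts, dplyr::desc(.data$fmn_domain_count),
                 .data$protein_id)
}

#' Fumarate-reductase-like FMN / cytochrome co-occurrence analysis
#'
#' For every protein with a passing hit to the fumarate-reductase
#' superfamily (PF00890), tests whether an FMN-binding domain (PF04205) or
#' a multi-heme cytochrome c domain (PF14537) is fused on the same protein
#' or encoded nearby (within `frd_window` genes, default +/-2, on the same
#' contig; the protein itself does not count as "nearby").
#'
#' @param genes Gene tibble.
#' @param domains Domain-hit tibble.
#' @param cfg A [mining_config()] (supplies `frd_window`).
#' @param annot_cfg An [annotation_config()].
#' @return Tibble with one row per PF00890 protein: `protein_id`,
#'   `genome_id`, `contig_id`, `gene_index`, `fmn_fused`, `fmn_nearby`,
#'   `cytochrome_fused`, `cytochrome_nearby`.
#' @export
analyze_frd <- function(genes, domains, cfg = mining_config(),
                        annot_cfg = annotation_config()) {
  pf <- collect_pfam_domains(domains, annot_cfg)
  frd_ids <- unique(pf$protein_id[pf$accession == "PF00890"])
  fmn_ids <- unique(pf$protein_id[pf$accession == FMN_PFAM])
  cyt_ids <- unique(pf$protein_id[pf$accession == "PF14537"])
  frd_genes <- genes[genes$protein_id %in% frd_ids, , drop = FALSE]
  if (nrow(frd_genes) == 0) {
    return(tibble::tibble(
      protein_id = character(), genome_id = character(),
      contig_id = character(), gene_index = integer(),
      fmn_fused = logical(), fmn_nearby = logical(),
      cytochrome_fused = logical(), cytochrome_nearby = logical()
    ))
  }
  nearby <- function(g, c, i, p, ids) {
    nb <- genes[genes$genome_id == g & genes$contig_id == c &
                  abs(genes$gene_index - i) <= cfg$frd_window &
                  genes$protein_id != p, , drop = FALSE]
    any(nb$protein_id %in% ids)
  }
  frd_genes %>%
    dplyr::mutate(
      fmn_fused = .data$protein_id %in% fmn_ids,
      fmn_nearby = purrr::pmap_lgl(
        list(.data$genome_id, .data$contig_id, .data$gene_index,
             .data$protein_id),
        nearby, ids = fmn_ids),
      cytochrome_fused = .data$protein_id %in% cyt_ids,
      cytochrome_nearby = purrr::pmap_lgl(
        list(.data$genome_id, .data$contig_id, .data$gene_index,
             .data$protein_id),
        nearby, ids = cyt_ids)
    ) %>%
    dplyr::select("protein_id", "genome_id", "contig_id", "gene_index",
                  "fmn_fused", "fmn_nearby", "cytochrome_fused",
                  "cytochrome_nearby")
}

#' Characterize P19 iron-assimilation gene clusters
#'
#' For every gene with a passing P19 hit (PF10634), inspects its
#' neighborhood (within `window` genes on the same contig) for the FTR1
#' iron permease (PF03239), an FMN-binding gene (PF04205) and a
#' thioredoxin-like gene (PF13899). Flavinylation-type clusters carry the
#' FMN-binding gene (the Gram-positive pattern); thioredoxin-type clusters
#' carry the thioredoxin-like gene instead (Gram-negative pattern).
#'
#' @inheritParams analyze_frd
#' @return Tibble per P19 gene: `protein_id`, `genome_id`, `contig_id`,
#'   `gene_index`, `ftr1`, `fmn_binding`, `thioredoxin_like`, `p19_type`
#'   (`"flavinylation"`, `"thioredoxin"`, `"both"` or `"none"`).
#' @export
detect_p19_clusters <- function(genes, domains, cfg = mining_config(),
                                annot_cfg = annotation_config()) {
  pf <- collect_pfam_domains(domains, annot_cfg)
  acc_ids <- function(acc) unique(pf$protein_id[pf$accession == acc])
  p19_genes <- genes[genes$protein_id %in% acc_ids("PF10634"), ,
                     drop = FALSE]
  if (nrow(p19_genes) == 0) {
    return(tibble::tibble(
      protein_id = character(), genome_id = character(),
      contig_id = character(), gene_index = integer(), ftr1 = logical(),
      fmn_binding = logical(), thioredoxin_like = logical(),
      p19_type = character()
    ))
  }
  ftr1_ids <- acc_ids("PF03239")
  fmn_ids <- acc_ids(FMN_PFAM)
  trx_ids <- acc_ids("PF13899")
  in_window <- function(g, c, i, ids) {
    nb <- genes[genes$genome_id == g & genes$contig_id == c &
                  abs(genes$gene_index - i) <= cfg$window, , drop = FALSE]
    any(nb$protein_id %in% ids)
  }
  row_keys <- list(p19_genes$genome_id, p19_genes$contig_id,
                   p19_genes$gene_index)
  p19_genes %>%
    dplyr::mutate(
      ftr1 = purrr::pmap_lgl(row_keys, in_window, ids = ftr1_ids),
      fmn_binding = purrr::pmap_lgl(row_keys, in_window, ids = fmn_ids),
      thioredoxin_like = purrr::pmap_lgl(row_keys, in_window,
                                         ids = trx_ids)
    ) %>%
    dplyr::mutate(p19_type = dplyr::case_when(
      .data$fmn_binding & .data$thioredoxin_like ~ "both",
      .data$fmn_binding ~ "flavinylation",
      .data$thioredoxin_like ~ "thioredoxin",
      TRUE ~ "none"
    )) %>%
    dplyr::select("protein_id", "genome_id", "contig_id", "gene_index",
                  "ftr1", "fmn_binding", "thioredoxin_like", "p19_type")
}

#' Detect DsbD-independent DUF3570 loci
#'
#' Flags clusters that carry the full hybrid thioredoxin/flavinylation
#' cassette — ApbE (PF02424), DUF3570 (PF12094), a thioredoxin-like protein
#' (PF13899) and DUF4266 (PF14086) — without a colocalized DsbD (PF02683).
#' Such loci presumably receive electrons from a DsbD encoded elsewhere.
#'
#' @param clusters Cluster tibble.
#' @param domains Domain-hit tibble.
#' @param cfg An [annotation_config()].
#' @return Tibble `cluster_id`, `dsbd_independent` (logical).
#' @export
detect_dsbd_independent_duf3570 <- function(clusters, domains,
                                            cfg = annotation_config()) {
  pf <- collect_pfam_domains(domains, cfg)
  acc_ids <- function(acc) unique(pf$protein_id[pf$accession == acc])
  need <- list(apbe = acc_ids(APBE_PFAM), duf3570 = acc_ids("PF12094"),
               trx = acc_ids("PF13899"), duf4266 = acc_ids("PF14086"))
  dsbd_ids <- acc_ids("PF02683")
  tibble::tibble(
    cluster_id = clusters$cluster_id,
    dsbd_independent = purrr::map_lgl(clusters$members, function(m) {
      all(vapply(need, function(ids) any(m %in% ids), logical(1))) &&
        !any(m %in% dsbd_ids)
    })
  )
}

#' Write an assignment table TSV
#' @param assignments A `flav_assignments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment_tsv <- function(assignments, path) {
  flat <- tibble::as_tibble(assignments) %>%
    dplyr::mutate(systems = purrr::map_chr(
      .data$systems, ~ paste(sort(.x), collapse = ",")
    ))
  readr::write_tsv(flat, path)
  invisible(path)
}
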