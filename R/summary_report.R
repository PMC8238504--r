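#' Summarize flavinylation status per genome
#'
#' One row per genome. `has_flavinylation_component` is true iff the genome
#' encodes at least one extracytosolic (signal peptide or lipoprotein
#' signal) protein with an FMN-binding (PF04205) or ApbE (PF02424) domain —
#' the genome-level unit behind "possesses extracytosolic flavinylation
#' components". System presence deduplicates multiple clusters of one
#' system: a genome either has an NQR system or it does not. Cluster-level
#' counts live in the assignment table.
#'
#' @param genes Gene tibble.
#' @param domains Domain-hit tibble.
#' @param localization Localization tibble.
#' @param clusters Filtered cluster tibble.
#' @param assignments `flav_assignments` for `clusters`.
#' @param cfg An [annotation_config()].
#' @return Tibble `genome_id`, `has_flavinylation_component`,
#'   `systems_present` (list of sorted character vectors), `n_systems`,
#'   `n_clusters`, `n_extracytosolic_fmn_genes`, `n_apbe_genes`,
#'   `orphan_fmn_only`, `orphan_extended`, `n_multiflavinylated`.
#' @export
summarize_genomes <- function(genes, domains, localization, clusters,
                              assignments, cfg = annotation_config()) {
  genomes <- dplyr::distinct(genes, .data$genome_id)
  if (nrow(genomes) == 0) {
    return(tibble::tibble(
      genome_id = character(), has_flavinylation_component = logical(),
      systems_present = list(), n_systems = integer(),
      n_clusters = integer(), n_extracytosolic_fmn_genes = integer(),
      n_apbe_genes = integer(), orphan_fmn_only = logical(),
      orphan_extended = logical(), n_multiflavinylated = integer()
    ))
  }
  ec_ids <- localization$protein_id[localization$call %in%
                                      EXTRACYTOSOLIC_CALLS]
  pf <- collect_pfam_domains(domains, cfg) %>%
    dplyr::inner_join(genes[, c("protein_id", "genome_id")],
                      by = "protein_id")
  comp <- pf %>%
    dplyr::group_by(.data$genome_id) %>%
    dplyr::summarise(
      has_flavinylation_component = any(
        .data$accession %in% c(FMN_PFAM, APBE_PFAM) &
          .data$protein_id %in% ec_ids),
      n_extracytosolic_fmn_genes = dplyr::n_distinct(
        .data$protein_id[.data$accession == FMN_PFAM &
                           .data$protein_id %in% ec_ids]),
      n_apbe_genes = dplyr::n_distinct(
        .data$protein_id[.data$accession == APBE_PFAM]),
      .groups = "drop"
    )
  sys_per_genome <- tidy(assignments) %>%
    dplyr::inner_join(clusters[, c("cluster_id", "genome_id")],
                      by = "cluster_id") %>%
    dplyr::group_by(.data$genome_id) %>%
    dplyr::summarise(systems_present = list(sort(unique(.data$system))),
                     .groups = "drop")
  clusters_per_genome <- clusters %>%
    dplyr::count(.data$genome_id, name = "n_clusters")
  orphan <- find_orphan_apbe(genes, domains, localization, cfg)
  multiflav <- find_multiflavinylated(domains, localization, cfg) %>%
    dplyr::inner_join(genes[, c("protein_id", "genome_id")],
                      by = "protein_id") %>%
    dplyr::count(.data$genome_id, name = "n_multiflavinylated")
  genomes %>%
    dplyr::left_join(comp, by = "genome_id") %>%
    dplyr::left_join(sys_per_genome, by = "genome_id") %>%
    dplyr::left_join(clusters_per_genome, by = "genome_id") %>%
    dplyr::left_join(orphan[, c("genome_id", "orphan_fmn_only",
                                "orphan_extended")], by = "genome_id") %>%
    dplyr::left_join(multiflav, by = "genome_id") %>%
    dplyr::mutate(
      has_flavinylation_component =
        dplyr::coalesce(.data$has_flavinylation_component, FALSE),
      systems_present = purrr::map(.data$systems_present,
                                   ~ .x %||% character(0)),
      n_systems = lengths(.data$systems_present),
      dplyr::across(c("n_clusters", "n_extracytosolic_fmn_genes",
                      "n_apbe_genes", "n_multiflavinylated"),
                    ~ dplyr::coalesce(.x, 0L)),
      dplyr::across(c("orphan_fmn_only", "orphan_extended"),
                    ~ dplyr::coalesce(.x, FALSE))
    ) %>%
    dplyr::select("genome_id", "has_flavinylation_component",
                  "systems_present", "n_systems", "n_clusters",
                  "n_extracytosolic_fmn_genes", "n_apbe_genes",
                  "orphan_fmn_only", "orphan_extended",
                  "n_multiflavinylated")
}

#' Summarize system presence per genus or phylum
#'
#' At genus rank, presence is any-semantics: a system (or the flavinylation
#' machinery itself) is marked present when at least one genome of the
#' genus carries it. At phylum rank, genome counts are reported, as in
#' per-phylum pie charts. Genomes missing from the taxonomy are grouped
#' under `"unclassified"`.
#'
#' @param genome_summaries Output of [summarize_genomes()].
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param rank `"genus"` or `"phylum"`.
#' @return Long tibble `taxon`, `n_genomes`, `feature`, `n_present` and —
#'   at genus rank — `present` (logical). Features are the system labels
#'   plus `"flavinylation"`.
#' @export
summarize_by_taxon <- function(genome_summaries, taxonomy,
                               rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  tax <- taxonomy %>%
    dplyr::select("genome_id", taxon = dplyr::all_of(rank))
  joined <- genome_summaries %>%
    dplyr::left_join(tax, by = "genome_id") %>%
    dplyr::mutate(taxon = dplyr::coalesce(.data$taxon, "unclassified"))
  long <- joined %>%
    dplyr::select("genome_id", "taxon", "has_flavinylation_component",
                  "systems_present") %>%
    tidyr::unnest_longer("systems_present", values_to = "system",
                         keep_empty = TRUE) %>%
    tidyr::pivot_longer(
      cols = "has_flavinylation_component", names_to = NULL,
      values_to = "flav") %>%
    dplyr::distinct()
  features <- c("flavinylation", SYSTEM_LABELS)
  per_taxon <- joined %>%
    dplyr::group_by(.data$taxon) %>%
    dplyr::summarise(n_genomes = dplyr::n_distinct(.data$genome_id),
                     .groups = "drop")
  counts <- purrr::map_dfr(features, function(f) {
    carriers <- if (f == "flavinylation") {
      joined$genome_id[joined$has_flavinylation_component]
    } else {
      long$genome_id[!is.na(long$system) & long$system == f]
    }
    joined %>%
      dplyr::distinct(.data$genome_id, .data$taxon) %>%
      dplyr::group_by(.data$taxon) %>%
      dplyr::summarise(
        n_present = dplyr::n_distinct(
          .data$genome_id[.data$genome_id %in% carriers]),
        .groups = "drop") %>%
      dplyr::mutate(feature = f)
  })
  out <- per_taxon %>%
    dplyr::inner_join(counts, by = "taxon") %>%
    dplyr::select("taxon", "n_genomes", "feature", "n_present") %>%
    dplyr::arrange(.data$taxon, .data$feature)
  if (rank == "genus") {
    out <- dplyr::mutate(out, present = .data$n_present > 0L)
  }
  out
}

#' Cross-tabulate label co-occurrence
#'
#' Counts, for every pair of labels, the number of units (clusters or
#' genomes) carrying both. The diagonal counts units carrying each label at
#' all.
#'
#' @param labels Long tibble with a unit-id column and a label column.
#' @param unit Name of the unit-id column (default `"cluster_id"`).
#' @param label Name of the label column (default `"system"`).
#' @return Tibble with `row_label`, one column per label, cell = number of
#'   units with both labels.
#' @export
crosstab <- function(labels, unit = "cluster_id", label = "system") {
  lab <- labels %>%
    dplyr::select(unit = dplyr::all_of(unit),
                  label = dplyr::all_of(label)) %>%
    dplyr::distinct()
  all_labels <- sort(unique(lab$label))
  if (length(all_labels) == 0) {
    return(tibble::tibble(row_label = character()))
  }
  sets <- split(lab$unit, lab$label)
  mat <- vapply(all_labels, function(a) {
    vapply(all_labels, function(b) {
      length(intersect(sets[[a]], sets[[b]]))
    }, integer(1))
  }, integer(length(all_labels)))
  out <- tibble::as_tibble(t(mat))
  # t() so rows follow all_labels order with columns named by label
  names(out) <- all_labels
  dplyr::bind_cols(tibble::tibble(row_label = all_labels), out)
}

#' Write an iTOL-compatible presence/absence annotation file
#'
#' Emits an iTOL `DATASET_BINARY` block keyed by genome id, one field per
#' feature (flavinylation machinery plus the ten systems), for decorating
#' an external species tree.
#'
#' @param genome_summaries Output of [summarize_genomes()].
#' @param path Output path.
#' @param dataset_label Label shown in iTOL.
#' @return `path`, invisibly.
#' @export
write_itol_presence <- function(genome_summaries, path,
                                dataset_label = "flavinylation") {
  features <- c("flavinylation", SYSTEM_LABELS)
  header <- c(
    "DATASET_BINARY",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", dataset_label),
    "COLOR\t#d62728",
    paste0("FIELD_SHAPES\t", paste(rep("2", length(features)),
                                   collapse = "\t")),
    paste0("FIELD_LABELS\t", paste(features, collapse = "\t")),
    "DATA"
  )
  rows <- vapply(seq_len(nrow(genome_summaries)), function(i) {
    g <- genome_summaries[i, ]
    vals <- c(
      as.integer(g$has_flavinylation_component),
      as.integer(SYSTEM_LABELS %in% g$systems_present[[1]])
    )
    paste(c(g$genome_id, vals), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write the genome-summary TSV
#' @param genome_summaries Output of [summarize_genomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_summary_tsv <- function(genome_summaries, path) {
  flat <- genome_summaries %>%
    dplyr::mutate(systems_present = purrr::map_chr(
      .data$systems_present, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}
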