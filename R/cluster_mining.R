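#' Neighborhood-mining configuration
#'
#' @param window Number of genes collected on each side of an anchor
#'   (default 5: the five genes downstream and upstream).
#' @param frd_window Window used for fumarate-reductase-like co-occurrence
#'   (default 2).
#' @param merge_overlapping Merge anchor windows on one contig that share at
#'   least one gene into a single cluster (default `TRUE`), so adjacent
#'   anchors of one system are counted as one locus.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(window = 5L, frd_window = 2L,
                          merge_overlapping = TRUE) {
  window <- as.integer(window)
  frd_window <- as.integer(frd_window)
  stopifnot(window >= 0L, frd_window >= 0L, window >= frd_window,
            is.logical(merge_overlapping))
  structure(list(window = window, frd_window = frd_window,
                 merge_overlapping = merge_overlapping),
            class = "mining_config")
}

#' Detect flavinylation anchor genes
#'
#' A gene is an anchor iff its protein carries at least one passing hit to
#' one of the four anchor families: ApbE (PF02424), FMN-binding (PF04205),
#' DUF3570 (PF12094) or DUF2271 (PF10029). A gene may carry several roles
#' (e.g. a fused ApbE–DUF2271 protein).
#'
#' @param genes Gene tibble.
#' @param domains Domain-hit tibble.
#' @param cfg An [annotation_config()] supplying the E-value cutoff.
#' @return Tibble `genome_id`, `contig_id`, `gene_index`, `protein_id`,
#'   `roles` (a `+`-joined string of anchor roles, in fixed role order).
#' @export
detect_anchors <- function(genes, domains, cfg = annotation_config()) {
  role_tab <- tibble::tibble(accession = unname(ANCHOR_PFAMS),
                             role = names(ANCHOR_PFAMS))
  hit <- domains %>%
    dplyr::filter(.data$namespace == "pfam",
                  .data$evalue <= cfg$evalue_cutoff,
                  .data$accession %in% ANCHOR_PFAMS) %>%
    dplyr::inner_join(role_tab, by = "accession")
  keys <- annotation_join_keys(genes, hit)
  genes %>%
    dplyr::inner_join(dplyr::distinct(hit, dplyr::pick(dplyr::all_of(
      c(keys, "role")))), by = keys) %>%
    dplyr::mutate(role = factor(.data$role, levels = names(ANCHOR_PFAMS))) %>%
    dplyr::group_by(.data$genome_id, .data$contig_id, .data$gene_index,
                    .data$protein_id) %>%
    dplyr::summarise(
      roles = paste(sort(unique(.data$role)), collapse = "+"),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$gene_index)
}

#' Build anchored gene clusters
#'
#' Collects, for every anchor, the genes within `window` positions on the
#' same contig (truncated silently at contig ends — draft assemblies make
#' truncated windows first-class), and, when `merge_overlapping` is set,
#' unions windows on one contig that share at least one gene into a single
#' cluster carrying all of their anchors.
#'
#' Cluster ids are deterministic:
#' `genome_id|contig_id|<leftmost member index>`.
#'
#' @param genes Gene tibble.
#' @param anchors Output of [detect_anchors()].
#' @param cfg A [mining_config()].
#' @return Tibble with one row per cluster: `cluster_id`, `genome_id`,
#'   `contig_id`, `start_index`, `end_index`, `n_genes`, `anchors` (list of
#'   tibbles `protein_id`, `gene_index`, `roles`), `members` (list of
#'   member `protein_id` character vectors in gene order).
#' @export
build_clusters <- function(genes, anchors, cfg = mining_config()) {
  if (nrow(anchors) == 0) {
    return(empty_clusters())
  }
  contig_span <- genes %>%
    dplyr::group_by(.data$genome_id, .data$contig_id) %>%
    dplyr::summarise(min_idx = min(.data$gene_index),
                     max_idx = max(.data$gene_index), .groups = "drop")
  win <- anchors %>%
    dplyr::inner_join(contig_span, by = c("genome_id", "contig_id")) %>%
    dplyr::mutate(
      w_start = pmax(.data$gene_index - cfg$window, .data$min_idx),
      w_end   = pmin(.data$gene_index + cfg$window, .data$max_idx)
    ) %>%
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$w_start,
                   .data$gene_index)

  clusters <- win %>%
    dplyr::group_by(.data$genome_id, .data$contig_id) %>%
    dplyr::group_modify(function(d, key) {
      if (cfg$merge_overlapping) {
        # windows sorted by start; a window overlaps the open interval when
        # its start is <= current end (shares >= 1 gene)
        grp <- integer(nrow(d))
        g <- 0L
        cur_end <- -Inf
        for (i in seq_len(nrow(d))) {
          if (d$w_start[i] > cur_end) {
            g <- g + 1L
            cur_end <- d$w_end[i]
          } else {
            cur_end <- max(cur_end, d$w_end[i])
          }
          grp[i] <- g
        }
      } else {
        grp <- seq_len(nrow(d))
      }
      d %>%
        dplyr::mutate(.grp = grp) %>%
        dplyr::group_by(.data$.grp) %>%
        dplyr::summarise(
          start_index = min(.data$w_start),
          end_index   = max(.data$w_end),
          anchors = list(tibble::tibble(
            protein_id = protein_id,
            gene_index = gene_index,
            roles      = roles
          )),
          .groups = "drop"
        ) %>%
        dplyr::select(-".grp")
    }) %>%
    dplyr::ungroup()

  member_ids <- purrr::pmap(
    list(clusters$genome_id, clusters$contig_id,
         clusters$start_index, clusters$end_index),
    function(g, c, s, e) {
      rows <- genes[genes$genome_id == g & genes$contig_id == c &
                      genes$gene_index >= s & genes$gene_index <= e, ]
      rows$protein_id[order(rows$gene_index)]
    }
  )
  clusters %>%
    dplyr::mutate(
      cluster_id = paste(.data$genome_id, .data$contig_id,
                         .data$start_index, sep = "|"),
      n_genes = .data$end_index - .data$start_index + 1L,
      members = member_ids
    ) %>%
    dplyr::select("cluster_id", "genome_id", "contig_id", "start_index",
                  "end_index", "n_genes", "anchors", "members") %>%
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$start_index)
}

empty_clusters <- function() {
  tibble::tibble(
    cluster_id = character(), genome_id = character(),
    contig_id = character(), start_index = integer(),
    end_index = integer(), n_genes = integer(),
    anchors = list(), members = list()
  )
}

#' Apply the extracytosolic filter to gene clusters
#'
#' A cluster is retained iff at least one of its anchor-role genes — not an
#' arbitrary member — has a predicted signal peptide (Sec or Tat) or
#' lipoprotein signal. Retained clusters are the "flavinylation-associated
#' gene clusters" all downstream analyses operate on.
#'
#' @param clusters Output of [build_clusters()].
#' @param localization Localization tibble.
#' @param keep_all If `TRUE`, return all clusters with an `extracytosolic`
#'   flag instead of dropping the cytosolic ones.
#' @return The cluster tibble with an `extracytosolic` logical column,
#'   restricted to `extracytosolic == TRUE` unless `keep_all`.
#' @export
filter_extracytosolic <- function(clusters, localization, keep_all = FALSE) {
  ec_ids <- localization$protein_id[localization$call %in%
                                      EXTRACYTOSOLIC_CALLS]
  out <- clusters %>%
    dplyr::mutate(extracytosolic = purrr::map_lgl(
      .data$anchors, ~ any(.x$protein_id %in% ec_ids)
    ))
  if (keep_all) out else dplyr::filter(out, .data$extracytosolic)
}

#' Flatten clusters to the cluster-output TSV dialect
#'
#' @param clusters Cluster tibble (list columns allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  flat <- clusters %>%
    dplyr::mutate(
      members = purrr::map_chr(.data$members, paste, collapse = ","),
      anchor_roles = purrr::map_chr(
        .data$anchors,
        ~ paste(paste0(.x$protein_id, ":", .x$roles), collapse = ",")
      )
    ) %>%
    dplyr::select(-"anchors")
  readr::write_tsv(flat, path)
  invisible(path)
}
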