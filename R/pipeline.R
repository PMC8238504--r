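#' Pipeline configuration
#'
#' Collects input paths, stage toggles and the analysis configurations for
#' an end-to-end run: ingest -> mine -> classify -> motif -> summarize.
#'
#' @param gene_table Path to the gene-table TSV.
#' @param annotations Path to the pre-joined annotation TSV.
#' @param localization Path to the localization TSV.
#' @param proteins Optional protein FASTA (needed by the motif stage).
#' @param taxonomy Optional taxonomy TSV (needed for taxon summaries).
#' @param rules Optional rules YAML path; `NULL` uses the packaged table.
#' @param out_dir Output directory.
#' @param annotation_cfg An [annotation_config()].
#' @param mining_cfg A [mining_config()].
#' @param stages Named logical vector toggling `mine`, `classify`,
#'   `motif`, `summarize`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_table, annotations, localization,
                            proteins = NULL, taxonomy = NULL,
                            rules = NULL, out_dir = "flavimine_out",
                            annotation_cfg = annotation_config(),
                            mining_cfg = mining_config(),
                            stages = c(mine = TRUE, classify = TRUE,
                                       motif = TRUE, summarize = TRUE)) {
  structure(
    list(gene_table = gene_table, annotations = annotations,
         localization = localization, proteins = proteins,
         taxonomy = taxonomy, rules = rules, out_dir = out_dir,
         annotation_cfg = annotation_cfg, mining_cfg = mining_cfg,
         stages = stages),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Never mutates anything; reports problems as a tibble so callers can
#' decide what is fatal.
#'
#' @param config A [pipeline_config()].
#' @return Tibble `severity` (`"error"`/`"warning"`), `problem`. Zero rows
#'   means the configuration is clean.
#' @export
validate_config <- function(config) {
  problems <- list()
  note <- function(severity, problem) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      severity = severity, problem = problem)
  }
  for (field in c("gene_table", "annotations", "localization")) {
    p <- config[[field]]
    if (is.null(p)) {
      note("error", paste0("missing required input path: ", field))
    } else if (!file.exists(p)) {
      note("error", paste0(field, " file not found: ", p))
    }
  }
  for (field in c("proteins", "taxonomy")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      note("error", paste0(field, " file not found: ", p))
    }
  }
  if (!is.null(config$rules) && !file.exists(config$rules)) {
    note("error", paste0("rules file not found: ", config$rules))
  }
  rules <- tryCatch(read_system_rules(config$rules),
                    error = function(e) {
                      note("error", conditionMessage(e))
                      NULL
                    })
  if (!is.null(rules) && !is.null(config$annotations) &&
      file.exists(config$annotations)) {
    hits <- tryCatch(read_annotation_tsv(config$annotations),
                     error = function(e) NULL)
    if (!is.null(hits)) {
      used_ns <- unique(sub(":.*$", "", unlist(
        lapply(rules$systems, function(r) c(unlist(r$key_any),
                                            unlist(r$architecture))))))
      absent <- setdiff(used_ns, unique(hits$namespace))
      for (ns in absent) {
        note("warning", paste0("rule table references namespace '", ns,
                               "' absent from the annotations"))
      }
    }
  }
  if (config$mining_cfg$window < config$mining_cfg$frd_window) {
    note("error", "mining window smaller than frd_window")
  }
  if (length(problems) == 0) {
    tibble::tibble(severity = character(), problem = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Run the full mining pipeline
#'
#' Stages run in dependency order; each stage writes its TSV output under
#' `out_dir` and records the file's checksum in a JSON manifest. Outputs
#' are pure functions of (inputs, config): an identical rerun reproduces
#' identical files and checksums.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (also written to `out_dir/manifest.json`):
#'   list with `config_hash`, `completed` stages, `outputs`
#'   (path + md5 per stage file).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  fatal <- problems[problems$severity == "error", , drop = FALSE]
  if (nrow(fatal) > 0) {
    stop("invalid pipeline config:\n  ",
         paste(fatal$problem, collapse = "\n  "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    completed = character(0),
    outputs = list()
  )
  emit <- function(stage, file, writer) {
    path <- file.path(config$out_dir, file)
    writer(path)
    manifest$outputs[[file]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
    manifest$completed <<- union(manifest$completed, stage)
  }
  finish <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$failed <<- list(stage = stage,
                               message = conditionMessage(e))
      finish()
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ingest
  genes <- domains <- localization <- sequences <- taxonomy <- NULL
  run_stage("ingest", function() {
    genes <<- read_gene_table(config$gene_table)
    domains <<- read_annotation_tsv(config$annotations)
    localization <<- read_localization_tsv(config$localization)
    sequences <<- if (!is.null(config$proteins)) {
      read_protein_fasta(config$proteins)
    }
    taxonomy <<- if (!is.null(config$taxonomy)) {
      read_taxonomy(config$taxonomy)
    }
    invisible(NULL)
  })
  manifest$completed <- union(manifest$completed, "ingest")

  clusters <- assignments <- NULL
  if (isTRUE(config$stages[["mine"]])) {
    run_stage("mine", function() {
      anchors <- detect_anchors(genes, domains, config$annotation_cfg)
      raw <- build_clusters(genes, anchors, config$mining_cfg)
      clusters <<- filter_extracytosolic(raw, localization)
      emit("mine", "clusters.tsv",
           function(p) write_cluster_tsv(clusters, p))
    })
  }
  if (isTRUE(config$stages[["classify"]]) && !is.null(clusters)) {
    run_stage("classify", function() {
      rules <- read_system_rules(config$rules)
      assignments <<- classify_clusters(clusters, genes, domains,
                                        localization, rules,
                                        config$annotation_cfg)
      accessories <- annotate_accessories(clusters, assignments, domains,
                                          rules, config$annotation_cfg)
      emit("classify", "assignments.tsv",
           function(p) write_assignment_tsv(assignments, p))
      emit("classify", "accessories.tsv",
           function(p) readr::write_tsv(accessories, p))
    })
  }
  if (isTRUE(config$stages[["motif"]]) && !is.null(sequences)) {
    run_stage("motif", function() {
      sites <- scan_flavinylation_motifs(sequences)
      emit("motif", "motif_sites.tsv",
           function(p) write_motif_tsv(sites, p))
    })
  }
  if (isTRUE(config$stages[["summarize"]]) && !is.null(assignments)) {
    run_stage("summarize", function() {
      gs <- summarize_genomes(genes, domains, localization, clusters,
                              assignments, config$annotation_cfg)
      emit("summarize", "genome_summary.tsv",
           function(p) write_genome_summary_tsv(gs, p))
      if (!is.null(taxonomy)) {
        emit("summarize", "genus_summary.tsv", function(p)
          readr::write_tsv(summarize_by_taxon(gs, taxonomy, "genus"), p))
        emit("summarize", "phylum_summary.tsv", function(p)
          readr::write_tsv(summarize_by_taxon(gs, taxonomy, "phylum"), p))
        emit("summarize", "itol_presence.txt",
             function(p) write_itol_presence(gs, p))
      }
    })
  }
  finish()
}
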