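#' Read a gene table
#'
#' Reads the tab-separated per-genome gene table that defines gene order.
#' Gene order (the `gene_index` rank along a contig), not nucleotide
#' coordinates, is what neighborhood mining uses: the five genes up- and
#' downstream of an anchor are the genes at index distance 1..5.
#'
#' @param path Path to a TSV file with header columns `genome_id`,
#'   `contig_id`, `gene_index`, `strand`, `protein_id`, `length_aa`.
#' @return A tibble of genes, sorted by genome, contig and `gene_index`,
#'   with `gene_index` validated to be unique and contiguous (0-based)
#'   within each contig and `protein_id` unique within each genome.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("genome_id\tcontig_id\tgene_index\tstrand\tprotein_id\tlength_aa",
#'              "G1\tc1\t0\t+\tp1\t100",
#'              "G1\tc1\t1\t-\tp2\t230"), tf)
#' read_gene_table(tf)
read_gene_table <- function(path) {
  required <- c("genome_id", "contig_id", "gene_index", "strand",
                "protein_id", "length_aa")
  genes <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_idx <- which(is.na(suppressWarnings(as.integer(genes$gene_index))) |
                     !grepl("^\\s*[0-9]+\\s*$", genes$gene_index))
  if (length(bad_idx) > 0) {
    stop("non-integer gene_index at data line(s): ",
         paste(utils::head(bad_idx, 5), collapse = ", "), call. = FALSE)
  }
  genes <- genes %>%
    dplyr::mutate(
      gene_index = as.integer(.data$gene_index),
      length_aa  = as.integer(.data$length_aa)
    ) %>%
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$gene_index)
  validate_genes(genes)
  genes
}

#' Write a gene table
#'
#' Emits the same TSV dialect [read_gene_table()] consumes, with rows in
#' canonical order, so read -> write round-trips byte-identically for
#' canonicalized input.
#'
#' @param genes A gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  genes %>%
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$gene_index) %>%
    dplyr::select("genome_id", "contig_id", "gene_index", "strand",
                  "protein_id", "length_aa") %>%
    readr::write_tsv(path)
  invisible(path)
}

validate_genes <- function(genes) {
  dup <- genes %>%
    dplyr::count(.data$genome_id, .data$contig_id, .data$gene_index) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate gene_index within a contig: ",
         paste(dup$contig_id[1], dup$gene_index[1]), call. = FALSE)
  }
  gaps <- genes %>%
    dplyr::group_by(.data$genome_id, .data$contig_id) %>%
    dplyr::summarise(
      ok = identical(sort(.data$gene_index), seq(0L, dplyr::n() - 1L)),
      .groups = "drop"
    ) %>%
    dplyr::filter(!.data$ok)
  if (nrow(gaps) > 0) {
    stop("gene_index not contiguous from 0 on contig ", gaps$contig_id[1],
         " of genome ", gaps$genome_id[1], call. = FALSE)
  }
  dup_p <- genes %>%
    dplyr::count(.data$genome_id, .data$protein_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup_p) > 0) {
    stop("protein_id not unique within genome ", dup_p$genome_id[1], ": ",
         dup_p$protein_id[1], call. = FALSE)
  }
  invisible(genes)
}

#' Read protein sequences from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased and a single trailing stop (`*`) is stripped.
#' Characters outside the 20 amino acids and `X` trigger a warning but are
#' retained.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  odd <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X]"), seqs)
  if (any(odd)) {
    warning("non-amino-acid characters (other than X) in: ",
            paste(utils::head(ids[odd], 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(protein_id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Tibble with `protein_id`, `sequence` columns (or a named
#'   character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(protein_id = names(sequences),
                                sequence = unname(sequences))
  }
  set <- Biostrings::BStringSet(sequences$sequence)
  names(set) <- sequences$protein_id
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a GTDB-style taxonomy table
#'
#' @param path TSV (no header) or headered file with two columns: genome id
#'   and a semicolon-delimited 7-rank lineage with `d__`/`p__`/.../`s__`
#'   prefixes.
#' @return A tibble `genome_id`, `lineage`, `domain`, `phylum`, `genus`.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(
    path,
    col_names = c("genome_id", "lineage"),
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(tx) > 0 && tx$genome_id[1] == "genome_id") {
    tx <- tx[-1, , drop = FALSE]
  }
  if (nrow(tx) == 0) {
    return(tibble::tibble(genome_id = character(), lineage = character(),
                          domain = character(), phylum = character(),
                          genus = character()))
  }
  parse_lineage(tx)
}

RANK_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

parse_lineage <- function(tx) {
  fields <- strsplit(tx$lineage, ";", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- n_fields != 7L
  if (any(bad)) {
    stop("lineage does not have 7 ranks for genome(s): ",
         paste(utils::head(tx$genome_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  for (i in seq_along(RANK_PREFIXES)) {
    if (!all(startsWith(mat[, i], RANK_PREFIXES[i]))) {
      off <- which(!startsWith(mat[, i], RANK_PREFIXES[i]))[1]
      stop("lineage rank ", i, " missing '", RANK_PREFIXES[i],
           "' prefix for genome ", tx$genome_id[off], call. = FALSE)
    }
  }
  tibble::tibble(
    genome_id = tx$genome_id,
    lineage   = tx$lineage,
    domain    = substring(mat[, 1], 4L),
    phylum    = substring(mat[, 2], 4L),
    genus     = substring(mat[, 6], 4L)
  )
}

#' Write a taxonomy table
#' @param taxonomy Tibble with `genome_id` and `lineage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy[, c("genome_id", "lineage")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Bundle per-genome tables into an annotated-genome collection
#'
#' Cross-validates the component tables: every annotation and localization
#' call must resolve to a gene, and where a sequence is present its length
#' must match the gene's `length_aa`.
#'
#' @param genes Gene tibble (see [read_gene_table()]).
#' @param domains Domain-hit tibble (see [read_annotation_tsv()]); optional.
#' @param localization Localization tibble (see [parse_localization()]);
#'   optional.
#' @param sequences Tibble `protein_id`, `sequence`; optional.
#' @param taxonomy Taxonomy tibble; optional.
#' @return An object of class `annotated_genomes`: a named list of the five
#'   tibbles.
#' @export
annotated_genomes <- function(genes, domains = NULL, localization = NULL,
                              sequences = NULL, taxonomy = NULL) {
  validate_genes(genes)
  empty_domains <- tibble::tibble(
    protein_id = character(), namespace = character(),
    accession = character(), evalue = double(), bitscore = double(),
    ali_from = integer(), ali_to = integer()
  )
  empty_loc <- tibble::tibble(protein_id = character(), call = character(),
                              tm_helix_count = integer())
  domains <- domains %||% empty_domains
  localization <- localization %||% empty_loc
  sequences <- sequences %||% tibble::tibble(protein_id = character(),
                                             sequence = character())
  known <- unique(genes$protein_id)
  for (nm in c("domains", "localization")) {
    tab <- get(nm)
    orphan <- setdiff(unique(tab$protein_id), known)
    if (length(orphan) > 0) {
      stop(nm, " reference unknown protein_id(s): ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(sequences) > 0) {
    chk <- sequences %>%
      dplyr::inner_join(genes, by = "protein_id") %>%
      dplyr::filter(nchar(.data$sequence) != .data$length_aa)
    if (nrow(chk) > 0) {
      stop("sequence length disagrees with length_aa for: ",
           paste(utils::head(chk$protein_id, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(genes = genes, domains = domains, localization = localization,
         sequences = sequences, taxonomy = taxonomy),
    class = "annotated_genomes"
  )
}

#' @export
print.annotated_genomes <- function(x, ...) {
  cat("<annotated_genomes>\n")
  cat("  genomes:  ", dplyr::n_distinct(x$genes$genome_id), "\n")
  cat("  contigs:  ",
      nrow(dplyr::distinct(x$genes, .data$genome_id, .data$contig_id)), "\n")
  cat("  genes:    ", nrow(x$genes), "\n")
  cat("  domain hits:", nrow(x$domains), "\n")
  cat("  sequences:", nrow(x$sequences), "\n")
  invisible(x)
}
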