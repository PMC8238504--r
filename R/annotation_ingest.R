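#' Annotation thresholding configuration
#'
#' The functional-annotation convention applied throughout: a protein is
#' labeled with the accession of its best profile-HMM match, and a hit only
#' counts when its full-sequence E-value passes the cutoff (default 0.001).
#'
#' @param evalue_cutoff Positive full-sequence E-value cutoff. Default 0.001.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(evalue_cutoff = 0.001) {
  stopifnot(is.numeric(evalue_cutoff), length(evalue_cutoff) == 1,
            evalue_cutoff > 0)
  structure(list(evalue_cutoff = evalue_cutoff), class = "annotation_config")
}

#' Parse HMMER3 tabular output
#'
#' Supports both the per-sequence (`tblout`) and per-domain (`domtblout`)
#' whitespace-delimited dialects. `#` lines are comments. Fields are mapped
#' so that `evalue` is always the full-sequence E-value and `bitscore` the
#' full-sequence score; for `domtblout` the alignment coordinates
#' (`ali_from`/`ali_to`, 1-based inclusive) are retained.
#'
#' @param path Path to a HMMER3 tabular file.
#' @param namespace Either `"pfam"` or `"kofam"`; recorded on every hit. For
#'   Pfam files the query accession (e.g. `PF02424.20`) is truncated to the
#'   versionless accession; for KOfam the query name (the KO) is used.
#' @param format `"tblout"` or `"domtblout"`.
#' @return A tibble of domain hits: `protein_id`, `namespace`, `accession`,
#'   `evalue`, `bitscore`, `ali_from`, `ali_to`.
#' @export
parse_hmmsearch_tbl <- function(path, namespace = c("pfam", "kofam"),
                                format = c("domtblout", "tblout")) {
  namespace <- match.arg(namespace)
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(empty_hits())
  }
  idx <- which(keep)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  min_fields <- if (format == "domtblout") 22L else 18L
  n_tok <- lengths(toks)
  if (any(n_tok < min_fields)) {
    bad <- idx[n_tok < min_fields][1]
    stop("malformed ", format, " line ", bad, " in ", path, call. = FALSE)
  }
  num <- function(v, what, col) {
    out <- suppressWarnings(as.numeric(v))
    if (any(!is.finite(out))) {
      bad <- idx[!is.finite(out)][1]
      stop("malformed ", what, " field at line ", bad, " in ", path,
           call. = FALSE)
    }
    out
  }
  target  <- vapply(toks, `[[`, "", 1L)
  qname   <- vapply(toks, `[[`, "", if (format == "domtblout") 4L else 3L)
  qacc    <- vapply(toks, `[[`, "", if (format == "domtblout") 5L else 4L)
  if (format == "domtblout") {
    evalue   <- num(vapply(toks, `[[`, "", 7L), "E-value")
    bitscore <- num(vapply(toks, `[[`, "", 8L), "score")
    ali_from <- as.integer(num(vapply(toks, `[[`, "", 18L), "ali_from"))
    ali_to   <- as.integer(num(vapply(toks, `[[`, "", 19L), "ali_to"))
  } else {
    evalue   <- num(vapply(toks, `[[`, "", 5L), "E-value")
    bitscore <- num(vapply(toks, `[[`, "", 6L), "score")
    ali_from <- rep(NA_integer_, length(target))
    ali_to   <- rep(NA_integer_, length(target))
  }
  accession <- if (namespace == "pfam") {
    acc <- ifelse(qacc == "-", qname, qacc)
    sub("\\.\\d+$", "", acc)
  } else {
    qname
  }
  tibble::tibble(
    protein_id = target, namespace = namespace, accession = accession,
    evalue = evalue, bitscore = bitscore,
    ali_from = ali_from, ali_to = ali_to
  )
}

empty_hits <- function() {
  tibble::tibble(
    protein_id = character(), namespace = character(),
    accession = character(), evalue = double(), bitscore = double(),
    ali_from = integer(), ali_to = integer()
  )
}

#' Read / write the pre-joined annotation interchange TSV
#'
#' The internal interchange format used by the pipeline and the synthetic
#' generator: one row per hit with columns `protein_id`, `namespace`,
#' `accession`, `evalue`, `bitscore`, `ali_from`, `ali_to` (optionally
#' preceded by `genome_id`).
#'
#' @param path Path to the TSV.
#' @return A domain-hit tibble.
#' @export
read_annotation_tsv <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(),
    evalue = readr::col_double(),
    bitscore = readr::col_double(),
    ali_from = readr::col_integer(),
    ali_to = readr::col_integer()
  ))
  required <- c("protein_id", "namespace", "accession", "evalue", "bitscore")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0) {
    stop("annotation TSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(hits$evalue) & hits$evalue <= 0)) {
    stop("annotation TSV contains non-positive E-values", call. = FALSE)
  }
  hits
}

#' @rdname read_annotation_tsv
#' @param hits A domain-hit tibble.
#' @export
write_annotation_tsv <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' Assign each protein its best KO ortholog label
#'
#' Among a protein's KOfam hits that pass the E-value cutoff, the single
#' best hit's accession is kept. "Best" is deterministic: minimal E-value,
#' ties broken by maximal bitscore, then lexicographically smallest
#' accession. Proteins with no passing hit are absent from the result.
#'
#' @param hits Domain-hit tibble (only `namespace == "kofam"` rows are
#'   considered).
#' @param cfg An [annotation_config()].
#' @return Tibble `protein_id`, `accession`, `evalue`, `bitscore`, one row
#'   per protein.
#' @export
assign_best_ko <- function(hits, cfg = annotation_config()) {
  hits %>%
    dplyr::filter(.data$namespace == "kofam",
                  .data$evalue <= cfg$evalue_cutoff) %>%
    dplyr::arrange(.data$protein_id, .data$evalue,
                   dplyr::desc(.data$bitscore), .data$accession) %>%
    dplyr::distinct(.data$protein_id, .keep_all = TRUE) %>%
    dplyr::select("protein_id", "accession", "evalue", "bitscore")
}

#' Collect passing Pfam domain hits per protein
#'
#' Keeps every Pfam hit whose full-sequence E-value passes the cutoff,
#' preserving multiplicity: one protein may legitimately carry several hits
#' to the same family (e.g. multiple FMN-binding domains).
#'
#' @inheritParams assign_best_ko
#' @return Tibble of passing hits (`protein_id`, `accession`, `evalue`,
#'   `bitscore`, `ali_from`, `ali_to`).
#' @export
collect_pfam_domains <- function(hits, cfg = annotation_config()) {
  hits %>%
    dplyr::filter(.data$namespace == "pfam",
                  .data$evalue <= cfg$evalue_cutoff) %>%
    dplyr::select("protein_id", "accession", "evalue", "bitscore",
                  "ali_from", "ali_to")
}

#' Filter a mixed domain-hit table to passing hits
#'
#' @inheritParams assign_best_ko
#' @return The hits with `evalue <= cfg$evalue_cutoff`, all namespaces.
#' @export
passing_hits <- function(hits, cfg = annotation_config()) {
  dplyr::filter(hits, .data$evalue <= cfg$evalue_cutoff)
}

SIGNALP_TOKENS <- c(
  "SP(Sec/SPI)"   = "SP",
  "LIPO(Sec/SPII)" = "LIPO",
  "TAT(Tat/SPI)"  = "TAT",
  "OTHER"         = "OTHER",
  # already-normalized tokens pass through
  "SP" = "SP", "LIPO" = "LIPO", "TAT" = "TAT"
)

#' Parse localization predictor summaries
#'
#' Maps a SignalP-5 style summary (columns: protein id, prediction token)
#' to the four calls used downstream — `SP` (Sec signal peptide), `TAT`
#' (Tat signal peptide), `LIPO` (lipoprotein signal) and `OTHER` — and, when
#' a TMHMM short-format file is supplied, attaches the predicted
#' transmembrane-helix count (`PredHel=N`; proteins absent from the file get
#' 0).
#'
#' @param path SignalP summary TSV (comment lines starting with `#`
#'   ignored).
#' @param tm_path Optional TMHMM short-format file.
#' @return Tibble `protein_id`, `call`, `tm_helix_count`.
#' @export
parse_localization <- function(path, tm_path = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    calls <- tibble::tibble(protein_id = character(), call = character())
  } else {
    toks <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(toks, `[[`, "", 1L)
    raw <- vapply(toks, `[[`, "", 2L)
    mapped <- unname(SIGNALP_TOKENS[raw])
    if (any(is.na(mapped))) {
      stop("unknown localization prediction token: ",
           raw[is.na(mapped)][1], call. = FALSE)
    }
    calls <- tibble::tibble(protein_id = ids, call = mapped)
  }
  if (anyDuplicated(calls$protein_id)) {
    stop("multiple localization calls for protein ",
         calls$protein_id[duplicated(calls$protein_id)][1], call. = FALSE)
  }
  tm <- if (is.null(tm_path)) {
    tibble::tibble(protein_id = character(), tm_helix_count = integer())
  } else {
    parse_tmhmm_short(tm_path)
  }
  calls %>%
    dplyr::left_join(tm, by = "protein_id") %>%
    dplyr::mutate(tm_helix_count =
                    dplyr::coalesce(.data$tm_helix_count, 0L))
}

# TMHMM "short" one-line-per-protein format: id <tab> len=... <tab> ...
# <tab> PredHel=N <tab> Topology=...
parse_tmhmm_short <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(),
                          tm_helix_count = integer()))
  }
  ids <- sub("\\s.*$", "", trimws(lines))
  m <- regmatches(lines, regexpr("PredHel=\\d+", lines))
  if (length(m) != length(lines)) {
    stop("TMHMM line without PredHel= field in ", path, call. = FALSE)
  }
  tibble::tibble(
    protein_id = ids,
    tm_helix_count = as.integer(sub("PredHel=", "", m))
  )
}

#' Read / write localization TSV (internal interchange)
#' @param path Path to TSV with columns `protein_id`, `call`,
#'   `tm_helix_count` (optionally `genome_id`).
#' @return A localization tibble.
#' @export
read_localization_tsv <- function(path) {
  loc <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(),
    tm_helix_count = readr::col_integer()
  ))
  bad <- setdiff(unique(loc$call), c(EXTRACYTOSOLIC_CALLS, "OTHER"))
  if (length(bad) > 0) {
    stop("unknown localization call: ", bad[1], call. = FALSE)
  }
  loc
}

#' @rdname read_localization_tsv
#' @param localization A localization tibble.
#' @export
write_localization_tsv <- function(localization, path) {
  readr::write_tsv(localization, path)
  invisible(path)
}
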