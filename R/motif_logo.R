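#' Scan a protein sequence for flavinylation motifs
#'
#' Finds every occurrence of the ApbE flavinylation motif `[ST]GA[ST]` —
#' the sequence context whose serine/threonine hydroxyl receives the FMN
#' phosphoester. Overlapping occurrences are all reported (two motifs may
#' share a serine), in ascending position order.
#'
#' @param sequences A tibble with `protein_id` and `sequence` columns, or a
#'   (optionally named) character vector of uppercase sequences.
#' @param pattern Motif regex over single positions; the default is the
#'   strict `[ST]GA[ST]` pattern. Must match fixed-width windows of
#'   `motif_width` characters.
#' @param motif_width Width of the motif window (default 4).
#' @return Tibble `protein_id`, `position` (1-based motif start),
#'   `matched` (the matched residues).
#' @export
#' @examples
#' scan_flavinylation_motifs(c(p1 = "MSTGASK"))
scan_flavinylation_motifs <- function(sequences,
                                      pattern = "[ST]GA[ST]",
                                      motif_width = 4L) {
  sequences <- as_sequence_tbl(sequences)
  if (nrow(sequences) == 0) {
    return(tibble::tibble(protein_id = character(), position = integer(),
                          matched = character()))
  }
  # lookahead capture reports overlapping matches
  rx <- paste0("(?=(", pattern, "))")
  hits <- purrr::map2_dfr(
    sequences$protein_id, sequences$sequence,
    function(id, seq) {
      m <- gregexpr(rx, seq, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      pos <- as.integer(m)
      tibble::tibble(
        protein_id = id,
        position = pos,
        matched = substring(seq, pos, pos + motif_width - 1L)
      )
    }
  )
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(protein_id = character(),
                           position = integer(), matched = character())
  }
  hits
}

as_sequence_tbl <- function(sequences) {
  if (is.character(sequences)) {
    ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
    sequences <- tibble::tibble(protein_id = ids,
                                sequence = unname(sequences))
  }
  sequences
}

#' Count flavinylation-motif sites per protein
#'
#' @inheritParams scan_flavinylation_motifs
#' @return Tibble `protein_id`, `n_sites`, one row per input sequence
#'   (zero counts included).
#' @export
count_motifs <- function(sequences, pattern = "[ST]GA[ST]",
                         motif_width = 4L) {
  sequences <- as_sequence_tbl(sequences)
  sites <- scan_flavinylation_motifs(sequences, pattern, motif_width)
  sequences %>%
    dplyr::select("protein_id") %>%
    dplyr::left_join(dplyr::count(sites, .data$protein_id,
                                  name = "n_sites"),
                     by = "protein_id") %>%
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
}

#' Compute a sequence-logo matrix from an alignment
#'
#' Per alignment column: amino-acid frequencies over non-gap residues, the
#' number of non-gap residues (`n_effective`), and the information content
#' in bits, `info_bits = log2(20) - H`, where `H` is the Shannon entropy of
#' the frequency vector (`0 * log 0 = 0`). All-gap columns get
#' `n_effective = 0` and `info_bits = 0`. No small-sample correction is
#' applied.
#'
#' @param alignment Equal-length gapped sequences: a tibble with
#'   `protein_id`/`sequence`, a character vector, or an
#'   `Biostrings::AAStringSet`. Gap characters are `-` and `.`.
#' @return A tibble with one row per alignment column: `position`, the 20
#'   amino-acid frequency columns (A..Y), `n_effective`, `info_bits`.
#' @export
build_logo <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  alignment <- as_sequence_tbl(alignment)
  seqs <- toupper(alignment$sequence)
  if (length(seqs) < 1) stop("alignment needs at least one sequence",
                             call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  ncol_aln <- widths[1]
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                nrow = length(seqs), ncol = ncol_aln, byrow = TRUE)
  mat[mat == "."] <- "-"
  purrr::map_dfr(seq_len(ncol_aln), function(j) {
    col <- mat[, j]
    res <- col[col != "-" & col %in% AA_ALPHABET]
    n_eff <- length(res)
    freqs <- stats::setNames(rep(0, 20), AA_ALPHABET)
    info <- 0
    if (n_eff > 0) {
      tab <- table(factor(res, levels = AA_ALPHABET))
      freqs[] <- as.numeric(tab) / n_eff
      p <- freqs[freqs > 0]
      info <- log2(20) + sum(p * log2(p))
    }
    out <- tibble::as_tibble(as.list(freqs))
    out$position <- j
    out$n_effective <- n_eff
    out$info_bits <- info
    dplyr::relocate(out, "position")
  })
}

#' Map alignment columns to residue numbers of a reference row
#'
#' @param alignment Alignment as in [build_logo()].
#' @param reference_id `protein_id` of the reference row.
#' @return Tibble `column`, `ref_position` (`NA` where the reference has a
#'   gap).
#' @export
map_alignment_position_to_reference <- function(alignment, reference_id) {
  alignment <- as_sequence_tbl(alignment)
  i <- match(reference_id, alignment$protein_id)
  if (is.na(i)) {
    stop("reference row '", reference_id, "' not found in alignment",
         call. = FALSE)
  }
  chars <- strsplit(toupper(alignment$sequence[i]), "", fixed = TRUE)[[1]]
  is_res <- chars != "-" & chars != "."
  if (!any(is_res)) {
    stop("reference row '", reference_id, "' is all gaps", call. = FALSE)
  }
  tibble::tibble(
    column = seq_along(chars),
    ref_position = ifelse(is_res, cumsum(is_res), NA_integer_)
  )
}

#' Read an aligned FASTA file
#' @param path Path to aligned FASTA.
#' @return Tibble `protein_id`, `sequence` (rows validated equal length).
#' @export
read_alignment_fasta <- function(path) {
  aln <- read_protein_fasta(path)
  if (nrow(aln) > 0 && length(unique(nchar(aln$sequence))) != 1) {
    stop("aligned FASTA rows have unequal lengths", call. = FALSE)
  }
  aln
}

#' Plot a sequence logo
#'
#' Letter height is the residue's share of the column's information
#' content (frequency x info_bits), the conventional bits-scaled logo.
#'
#' @param logo A logo matrix from [build_logo()].
#' @param min_freq Residues below this frequency are not drawn.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo, min_freq = 0.01) {
  long <- logo %>%
    tidyr::pivot_longer(dplyr::all_of(AA_ALPHABET),
                        names_to = "residue", values_to = "frequency") %>%
    dplyr::filter(.data$frequency >= min_freq) %>%
    dplyr::mutate(bits = .data$frequency * .data$info_bits) %>%
    dplyr::arrange(.data$position, .data$bits) %>%
    dplyr::group_by(.data$position) %>%
    dplyr::mutate(ymax = cumsum(.data$bits),
                  ymin = .data$ymax - .data$bits,
                  ymid = (.data$ymin + .data$ymax) / 2) %>%
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$bits,
                                    colour = .data$residue),
                       show.legend = FALSE, fontface = "bold") +
    ggplot2::scale_size(range = c(1, 8)) +
    ggplot2::scale_x_continuous(breaks = unique(long$position)) +
    ggplot2::labs(x = "alignment position", y = "bits") +
    ggplot2::theme_minimal()
}

#' Write motif sites / logo matrix TSVs
#' @param sites Motif-site tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_motif_tsv
#' @param logo Logo matrix tibble.
#' @export
write_logo_tsv <- function(logo, path) {
  readr::write_tsv(logo, path)
  invisible(path)
}
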