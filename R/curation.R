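#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps via
#' `Biostrings::pairwiseAlignment`) between two protein sequences; identity
#' is the number of identical aligned positions divided by the full
#' alignment length, gap columns included (configurable to the shorter
#' sequence length).
#'
#' @param seq_a,seq_b amino-acid sequences (standard 20-letter alphabet).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param denominator `"alignment"` (default, full alignment length) or
#'   `"shorter"` (length of the shorter sequence).
#' @return identity fraction in `[0, 1]`.
#' @examples
#' nw_identity("HEAGAWGHEE", "HEAGAWGHEE")
#' @export
nw_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                        denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  for (s in c(seq_a, seq_b)) {
    bad <- setdiff(strsplit(toupper(s), "")[[1]],
                   strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    if (length(bad) > 0) {
      stop("invalid amino-acid character(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(a == b & a != "-")
  len <- switch(denominator,
                alignment = length(a),
                shorter = min(nchar(seq_a), nchar(seq_b)))
  ident / len
}

blosum62 <- function() {
  if (is.null(.aarsfp_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aarsfp_cache$blosum62 <- e$BLOSUM62
  }
  .aarsfp_cache$blosum62
}

#' Single-linkage identity clustering
#'
#' Clusters sequences as the connected components of the graph whose edges
#' join pairs with identity at or above the threshold (single-linkage
#' chaining: A-B and B-C above threshold place A, B, C in one cluster even
#' if A-C is below it). Used to pick non-redundant representative chains at
#' the 95% identity level.
#'
#' @param identities symmetric matrix of pairwise identities with unit
#'   diagonal.
#' @param threshold clustering cutoff.
#' @return integer cluster assignment (1-based, in order of first
#'   appearance), named after the matrix rows.
#' @export
single_linkage_clusters <- function(identities,
                                    threshold =
                                      analysis_config()$identity_threshold) {
  m <- as.matrix(identities)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9) {
    stop("identity matrix must be square and symmetric", call. = FALSE)
  }
  n <- nrow(m)
  assignment <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assignment[i])) next
    nxt <- nxt + 1L
    frontier <- i
    assignment[i] <- nxt
    while (length(frontier) > 0) {
      nbrs <- which(m[frontier[1], ] >= threshold & is.na(assignment))
      assignment[nbrs] <- nxt
      frontier <- c(frontier[-1], nbrs)
    }
  }
  names(assignment) <- rownames(m)
  assignment
}

#' Select a cluster representative
#'
#' Deterministic ordered-criteria choice: wild-type structures first, then
#' ascending resolution, then lexicographically smallest identifier.
#'
#' @param members data frame with columns `id`, `wild_type` (logical),
#'   `resolution` (A; `NA` sorts last).
#' @return the chosen `id`.
#' @export
select_representative <- function(members) {
  stopifnot(nrow(members) >= 1)
  ord <- order(!members$wild_type,
               ifelse(is.na(members$resolution), Inf, members$resolution),
               members$id)
  members$id[ord[1]]
}

#' Map author residue numbers to unified MSA columns
#'
#' Given a structure's row in its aaRS's multiple sequence alignment, maps
#' residue *k* (author numbering) to the alignment column holding the k-th
#' non-gap character of that row. The structure's gapless sequence must
#' equal its alignment row with gaps removed.
#'
#' @param aligned_row the structure's gapped alignment row (string, `-` for
#'   gaps).
#' @param sequence the structure's gapless sequence.
#' @param author_numbers integer residue numbers, one per sequence position.
#' @return a `renumber_map` tibble: `author_number`, `msa_position`, both
#'   strictly increasing.
#' @examples
#' msa_renumber("-AC-D", "ACD", c(10L, 11L, 12L))
#' @export
msa_renumber <- function(aligned_row, sequence, author_numbers) {
  row_chars <- strsplit(aligned_row, "")[[1]]
  degapped <- row_chars[row_chars != "-"]
  seq_chars <- strsplit(sequence, "")[[1]]
  if (length(seq_chars) != length(author_numbers)) {
    stop("sequence length and author_numbers length differ", call. = FALSE)
  }
  if (length(degapped) != length(seq_chars) ||
      any(degapped != seq_chars)) {
    k <- if (length(degapped) != length(seq_chars)) {
      min(length(degapped), length(seq_chars)) + 1L
    } else {
      which(degapped != seq_chars)[1]
    }
    stop("structure sequence disagrees with alignment row at position ", k,
         call. = FALSE)
  }
  out <- tibble::tibble(author_number = as.integer(author_numbers),
                        msa_position = which(row_chars != "-"))
  class(out) <- c("renumber_map", class(out))
  out
}

#' Invert a renumber map
#'
#' @param map a `renumber_map`.
#' @return tibble `msa_position`, `author_number`.
#' @export
invert_renumber_map <- function(map) {
  tibble::tibble(msa_position = map$msa_position,
                 author_number = map$author_number)
}

#' Write renumbering tables in the deposited layout
#'
#' Rows are unified MSA positions, one column per structure holding its
#' author residue number (empty where the structure has a gap).
#'
#' @param maps named list of `renumber_map`s (names: structure ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_renumber_table <- function(maps, path) {
  width <- max(vapply(maps, function(m) max(m$msa_position), integer(1)))
  out <- tibble::tibble(msa_position = seq_len(width))
  for (id in names(maps)) {
    col <- rep(NA_integer_, width)
    col[maps[[id]]$msa_position] <- maps[[id]]$author_number
    out[[id]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
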