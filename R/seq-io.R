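#' Sequence validation helpers
#'
#' Sequences are plain upper-case character strings over the alphabet
#' `A`, `C`, `G`, `T`, `N`.  `N` is an unknown base: it never counts as a
#' match anywhere in the package, not even against another `N`.
#'
#' @param x Character vector of sequences.
#' @param arg Name used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
check_dna <- function(x, arg = "sequence") {
  if (!is.character(x)) {
    abort(sprintf("`%s` must be a character vector of DNA sequences.", arg))
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains characters outside {A,C,G,T,N} (first offender: element %d).",
      arg, which(bad)[1]
    ))
  }
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed.  Vectorised; `N` complements to `N`.
#' Applying the function twice returns the input (involution).
#'
#' @param x Character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(x) {
  check_dna(x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

parse_fasta_header <- function(headers) {
  # Header convention: "id|subgenome|class"; missing fields default to
  # subgenome "none" and class "other".
  parts <- stringr::str_split(headers, stringr::fixed("|"))
  tibble(
    id = purrr::map_chr(parts, 1),
    subgenome = purrr::map_chr(parts, function(p) if (length(p) >= 2) p[[2]] else "none"),
    annotation_class = purrr::map_chr(parts, function(p) if (length(p) >= 3) p[[3]] else "other")
  )
}

#' Read transcripts from a FASTA file
#'
#' Reads a (possibly empty) FASTA file into a transcript table.  The header
#' convention `id|subgenome|class` is parsed into the `subgenome`
#' (`"S"`, `"T"` or `"none"`) and `annotation_class` columns; a bare header
#' defaults to subgenome `"none"` and class `"other"`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `subgenome`, `annotation_class`,
#'   `length_nt` and `sequence`.
#' @seealso [write_transcript_fasta()]
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("Malformed FASTA file %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0) {
    return(tibble(
      id = character(), subgenome = character(), annotation_class = character(),
      length_nt = integer(), sequence = character()
    ))
  }
  seqs <- toupper(as.character(set))
  hdr <- parse_fasta_header(names(set))
  if (anyDuplicated(hdr$id)) {
    abort(sprintf(
      "Duplicate transcript id in %s: %s", path, hdr$id[duplicated(hdr$id)][1]
    ))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf(
      "Record '%s' in %s contains non-{A,C,G,T,N} characters.",
      hdr$id[which(bad)[1]], path
    ))
  }
  dplyr::mutate(hdr,
    length_nt = unname(nchar(seqs)),
    sequence = unname(seqs)
  )
}

#' Write transcripts to a FASTA file
#'
#' Writes `id|subgenome|class` headers and wraps sequence lines at 60
#' columns, so that a write/read cycle preserves ids, annotations and
#' sequences exactly.
#'
#' @param transcripts Data frame with at least `id` and `sequence` columns;
#'   `subgenome` and `annotation_class` default to `"none"` / `"other"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  stopifnot(is.data.frame(transcripts))
  if (nrow(transcripts) > 0) check_dna(transcripts$sequence)
  subgenome <- transcripts[["subgenome"]] %||% rep("none", nrow(transcripts))
  cls <- transcripts[["annotation_class"]] %||% rep("other", nrow(transcripts))
  set <- Biostrings::DNAStringSet(transcripts[["sequence"]] %||% character())
  names(set) <- paste(transcripts$id, subgenome, cls, sep = "|")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
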