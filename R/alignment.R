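#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (equal-length, gapped) FASTA file.
#' @return Named character vector of aligned sequences (uppercase,
#'   gaps as `-`).
#' @export
read_alignment_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  out <- toupper(unlist(seqs))
  if (length(unique(nchar(out))) != 1L)
    stop("sequences are not aligned: lengths differ")
  out
}

#' Scan alignment columns for a residue motif
#'
#' Maps residue positions of a reference sequence (in its own ungapped
#' numbering) to alignment columns, then reports, for every sequence,
#' the residues found at those columns and whether they match a motif
#' pattern (all-Asp "DDDD" by default, or a variant such as "DEDD").
#'
#' @param alignment Named character vector of aligned sequences (or a
#'   path to an aligned FASTA file).
#' @param reference_id Name of the reference sequence in the alignment.
#' @param reference_positions Integer residue numbers in the reference's
#'   ungapped numbering (optionally offset; see `numbering_offset`).
#' @param pattern Single-letter residue pattern of the same length as
#'   `reference_positions`; default all `"D"`.
#' @param numbering_offset Added to `reference_positions` to convert an
#'   author numbering into 1-based ungapped positions (default 0, i.e.
#'   positions are already 1-based indices into the ungapped reference).
#' @return data.frame with one row per sequence: `id`, `residues`
#'   (residues at the mapped columns, collapsed), `present` (logical,
#'   pattern match).
#' @export
alignment_motif_scan <- function(alignment, reference_id,
                                 reference_positions, pattern = NULL,
                                 numbering_offset = 0L) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- read_alignment_fasta(alignment)
  if (is.null(names(alignment)) || !reference_id %in% names(alignment))
    stop("reference sequence '", reference_id, "' not found in the alignment")
  pos <- as.integer(reference_positions) + as.integer(numbering_offset)
  if (is.null(pattern)) pattern <- strrep("D", length(pos))
  pat <- strsplit(toupper(pattern), "")[[1L]]
  if (length(pat) != length(pos))
    stop("'pattern' length must equal the number of reference positions")

  ref <- strsplit(toupper(alignment[[reference_id]]), "")[[1L]]
  ungapped <- cumsum(ref != "-")
  cols <- vapply(pos, function(p) {
    hit <- which(ungapped == p & ref != "-")
    if (length(hit) == 0L)
      stop("reference position ", p, " is beyond the ungapped reference length")
    hit[1L]
  }, integer(1L))

  ids <- names(alignment)
  residues <- vapply(ids, function(id) {
    s <- strsplit(toupper(alignment[[id]]), "")[[1L]]
    paste(s[cols], collapse = "")
  }, character(1L))
  data.frame(id = ids,
             residues = unname(residues),
             present = unname(residues == paste(pat, collapse = "")),
             row.names = NULL)
}
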