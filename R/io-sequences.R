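# FASTA reading/writing. Thin validated wrappers over Biostrings so the rest
# of the package can assume unique ids and a clean DNA alphabet.

#' Read a FASTA file
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet] (or
#' [Biostrings::BStringSet] for non-DNA records). Wrapped lines are
#' concatenated; record order is preserved; duplicate ids and empty files are
#' rejected.
#'
#' @param path path to a FASTA file.
#' @param type `"DNA"` (validated against the ACGTN alphabet) or `"auto"`.
#' @return a named `XStringSet`; names are the full header lines.
#' @export
readFasta <- function(path, type = c("DNA", "auto")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for id(s): ", paste(ids[Biostrings::width(seqs) == 0L],
                                             collapse = ", "))
  chars <- as.character(seqs)
  isDna <- !grepl("[^ACGTNacgtn]", chars)
  if (type == "DNA" || all(isDna)) {
    if (!all(isDna))
      stop("non-DNA characters in record(s): ",
           paste(ids[!isDna], collapse = ", "))
    out <- Biostrings::DNAStringSet(toupper(chars))
    names(out) <- names(seqs)
    return(out)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a named `XStringSet` or named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}
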