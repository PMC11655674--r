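# FASTA I/O. Parsing is delegated to Biostrings; validation (alphabet,
# duplicate ids, case) follows this package's contracts.

#' Read a multi-record FASTA file
#'
#' Sequences are upper-cased; record ids are the first whitespace-delimited
#' token of each header. Duplicate ids are an error. By default the DNA
#' alphabet is restricted to A/C/G/T/N and anything else (e.g. `U`) is an
#' error; with `map_invalid_to_n = TRUE` invalid characters are mapped to N.
#'
#' @param path Path to a FASTA file (any line wrapping).
#' @param alphabet `"dna"` or `"protein"` (20 amino acids plus X).
#' @param map_invalid_to_n For DNA only: map invalid characters to N instead
#'   of erroring.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein"),
                       map_invalid_to_n = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  ok_chars <- if (alphabet == "dna") "ACGTN" else "ARNDCQEGHILKMFPSTWYVX"
  bad <- grepl(sprintf("[^%s]", ok_chars), seqs)
  if (any(bad)) {
    if (alphabet == "dna" && map_invalid_to_n) {
      seqs <- gsub(sprintf("[^%s]", ok_chars), "N", seqs)
    } else {
      stop(sprintf("record '%s' contains characters outside the %s alphabet",
                   ids[which(bad)[1]], alphabet))
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}
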