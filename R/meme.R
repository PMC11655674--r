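# MEME minimal text format: the de-facto interchange format for PWMs.

#' Write a PWM (or motif model) in MEME minimal format
#'
#' @param x A `pwm` or `motif_model` object.
#' @param path Output path.
#' @param name Motif name.
#' @param nsites Optional site count for the header.
#' @param evalue Optional E-value for the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(x, path, name = "motif_1", nsites = NULL,
                       evalue = NULL) {
  if (inherits(x, "motif_model")) {
    if (is.null(nsites)) nsites <- x$occupancy[1]
    if (is.null(evalue)) evalue <- x$evalue_approx
    x <- x$pwm
  }
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies"), con)
  writeLines(paste(sprintf("%s %.6f", .DNA, x$background), collapse = " "),
             con)
  writeLines(c("", paste("MOTIF", name)), con)
  hdr <- sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %s",
                 x$width,
                 if (is.null(nsites)) 20L else as.integer(round(nsites)),
                 if (is.null(evalue) || is.na(evalue)) "0" else
                   format(evalue, digits = 3))
  writeLines(hdr, con)
  for (i in seq_len(x$width))
    writeLines(paste(sprintf("%.6f", x$freq[, i]), collapse = " "), con)
  invisible(path)
}

#' Read the first motif from a MEME minimal format file
#'
#' @param path Path to a MEME text file.
#' @return A `pwm` object; the header's `nsites` and `E` are attached as
#'   attributes `nsites` and `evalue` when present.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg[names(vals)] <- vals
  }
  hd <- grep("^letter-probability matrix", lines)
  if (!length(hd)) stop("no letter-probability matrix in ", path)
  hdr <- lines[hd[1]]
  getnum <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\s*[0-9.eE+-]+"), hdr))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0(key, "=\\s*"), "", m))
  }
  w <- as.integer(getnum("w"))
  rows <- lines[(hd[1] + 1L):(hd[1] + w)]
  f <- t(vapply(strsplit(trimws(rows), "\\s+"),
                function(x) as.numeric(x[1:4]), numeric(4)))
  f <- sweep(f, 1, rowSums(f), "/")  # renormalize printed rounding
  pwm <- new_pwm(t(f), bg[.DNA])
  attr(pwm, "nsites") <- getnum("nsites")
  attr(pwm, "evalue") <- getnum("E")
  pwm
}
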