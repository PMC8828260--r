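#' Genome sequence container
#'
#' Bundles one or more chromosome sequences with a genome label
#' (conventionally `"human"` or `"mouse"`). Sequences are stored as
#' uppercase character strings over the alphabet `A,C,G,T,N`.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences. Names are chromosome identifiers and must be
#'   unique.
#' @param label Genome label, e.g. `"human"` or `"mouse"`.
#' @return An object of class `genome_seq`: a list with elements `label`
#'   and `seqs` (named character vector).
#' @examples
#' g <- genome_seq(c(chr1 = "ACGTACGTACGTACGT"), "human")
#' genome_lengths(g)
#' @export
genome_seq <- function(seqs, label) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || length(seqs) == 0) {
    stop("`seqs` must be a nonempty named character vector or DNAStringSet")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
    stop("chromosome names must be present and unique within a genome")
  }
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) stop("chromosome sequences must be nonempty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("chromosome(s) ", paste(names(seqs)[bad], collapse = ", "),
         " contain characters outside {A,C,G,T,N}")
  }
  structure(list(label = as.character(label), seqs = seqs),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq>", x$label, "-", length(x$seqs), "sequence(s),",
      sum(nchar(x$seqs)), "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A [genome_seq()] object.
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome$seqs, nchar, integer(1))
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param label Genome label to attach.
#' @return A [genome_seq()] object.
#' @export
read_genome_fasta <- function(path, label) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  genome_seq(ss, label)
}

#' Write a genome to a FASTA file
#' @param genome A [genome_seq()] object.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seqs)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
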