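# Small in-code fixtures shared across test files.

# plant `piece` into `text` at 0-based position `at` (forward strand)
plant_seq <- function(text, at, piece) {
  paste0(substring(text, 1, at), piece,
         substring(text, at + nchar(piece) + 1))
}

toy_genome <- function(len = 2000, label = "toy", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome_seq(c(chr1 = random_dna_str(len)), label)
}

# minimal align_summary builder for partition tests
mk_align <- function(label, read_id, mapped, unique) {
  structure(list(genome_label = label,
                 reads = data.frame(read_id = read_id, mapped = mapped,
                                    unique = unique,
                                    stringsAsFactors = FALSE),
                 hits = NULL),
            class = "align_summary")
}

# write a small SAM file; records = list of character vectors
# c(qname, flag, rname, pos, mapq, cigar)
write_test_sam <- function(path, sq_len = 1000, records) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:chr1\tLN:", sq_len))
  for (r in records) {
    lines <- c(lines, paste(r[1], r[2], r[3], r[4], r[5], r[6], "*", "0",
                            "0", "ACGTACGTAC", "IIIIIIIIII", sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# expression table helper
mk_expr <- function(values, scheme = "FPKM") {
  counts <- values
  tot <- stats::setNames(rep(1e6, ncol(values)), colnames(values))
  expr_table(counts, tot, values = values, scheme = scheme)
}

mutate_positions <- function(seq, n) {
  ch <- strsplit(seq, NULL)[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
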