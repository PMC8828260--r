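#' Mapper configuration
#'
#' Mirrors the two alignment regimes used for mature-miRNA placement:
#' up to `max_diff` differences including gaps (edit distance), and up to
#' `max_mismatch` substitutions with no gaps. All qualifying hits are
#' reported; there is no hit cap.
#'
#' @param max_diff Maximum differences (substitutions + indels) in `diff`
#'   mode. Default 2.
#' @param max_mismatch Maximum substitutions in gap-free `mismatch` mode.
#'   Default 3.
#' @return A list of class `mapper_config`.
#' @export
mapper_config <- function(max_diff = 2L, max_mismatch = 3L) {
  max_diff <- as.integer(max_diff)
  max_mismatch <- as.integer(max_mismatch)
  if (max_diff < 0 || max_mismatch < 0) stop("mapper thresholds must be >= 0")
  structure(list(max_diff = max_diff, max_mismatch = max_mismatch,
                 gaps_allowed_in_mismatch_mode = FALSE,
                 report_all_hits = TRUE),
            class = "mapper_config")
}

empty_hits <- function() {
  data.frame(query_id = character(), genome_label = character(),
              chrom = character(), start = integer(), end = integer(),
              strand = character(), n_diff = integer(), mode = character(),
              stringsAsFactors = FALSE)
}

validate_queries <- function(queries, k) {
  if (length(queries) == 0) stop("no query sequences supplied")
  if (is.null(names(queries)) || any(names(queries) == "")) {
    stop("queries must be named (names are query ids)")
  }
  queries <- toupper(queries)
  bad <- grepl("[^ACGTN]", queries)
  if (any(bad)) {
    stop("query sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(utils::head(names(queries)[bad], 5), collapse = ", "))
  }
  if (any(nchar(queries) < 10)) {
    stop("query sequences must be at least 10 nt long")
  }
  if (k < 0) stop("k must be >= 0")
  if (any(k > nchar(queries))) stop("k exceeds the length of a query")
  queries
}

#' Map query sequences exhaustively against a genome
#'
#' Finds every placement of each query on both strands of every chromosome
#' whose difference count is at most `k`. `mode = "mismatch"` counts
#' substitutions only at equal window length; `mode = "diff"` counts
#' unit-cost edit operations (substitution, insertion, deletion). One hit is
#' reported per qualifying window start; in `diff` mode the reported end is
#' the smallest end achieving the minimal distance for that start. The
#' search is exhaustive: candidate generation uses exact pigeonhole seeding,
#' which cannot drop a qualifying hit. `N` bases never match anything.
#'
#' Minus-strand hits are reported in forward-genome coordinates: a hit with
#' `strand == "-"` means the reverse complement of the query matches the
#' forward genome over `[start, end)`.
#'
#' @param queries Named character vector of query sequences (names are query
#'   ids). [map_query()] is the single-query convenience wrapper.
#' @param genome A [genome_seq()] object.
#' @param mode `"diff"` (edit distance) or `"mismatch"` (substitutions only).
#' @param k Maximum allowed differences for this mode.
#' @return A data frame of hits with columns `query_id`, `genome_label`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `n_diff`, `mode`.
#' @examples
#' g <- genome_seq(c(chr1 = paste(rep("ACGT", 20), collapse = "")), "toy")
#' map_queries(c(q1 = "ACGTACGTACGT"), g, "mismatch", 0)[1:3, ]
#' @export
map_queries <- function(queries, genome, mode = c("diff", "mismatch"), k) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "genome_seq"))
  queries <- validate_queries(queries, k)
  # identical sequences are mapped once and the hits replicated
  uq <- unique(unname(queries))
  out <- vector("list", length(genome$seqs))
  for (ci in seq_along(genome$seqs)) {
    chrom <- names(genome$seqs)[ci]
    res <- cpp_map_batch(uq, genome$seqs[[ci]], as.integer(k), mode == "diff")
    if (nrow(res) == 0) next
    out[[ci]] <- data.frame(seq_idx = res$qidx, chrom = chrom,
                            start = res$start, end = res$end,
                            strand = ifelse(res$minus == 1L, "-", "+"),
                            n_diff = res$n_diff, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) return(empty_hits())
  # expand unique-sequence hits back to every query id carrying that sequence
  idx_of_query <- match(unname(queries), uq)
  expand <- split(seq_along(queries), idx_of_query)
  reps <- lengths(expand)[as.character(out$seq_idx)]
  rows <- rep(seq_len(nrow(out)), reps)
  qpos <- unlist(expand[as.character(out$seq_idx)], use.names = FALSE)
  hits <- data.frame(query_id = names(queries)[qpos],
                     genome_label = genome$label,
                     chrom = out$chrom[rows], start = out$start[rows],
                     end = out$end[rows], strand = out$strand[rows],
                     n_diff = out$n_diff[rows], mode = mode,
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$query_id, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' @rdname map_queries
#' @param query A single query sequence.
#' @param query_id Identifier for the single query.
#' @export
map_query <- function(query, genome, mode = c("diff", "mismatch"), k,
                      query_id = "query") {
  map_queries(stats::setNames(query, query_id), genome, mode, k)
}

#' Merge hits from the two mapping regimes
#'
#' Deduplicates the union of a `diff`-mode and a `mismatch`-mode hit set,
#' keyed by (query_id, genome_label, chrom, start, end, strand). When the
#' same placement is found in both modes the record with the smaller
#' `n_diff` is kept; ties keep the `diff`-mode record.
#'
#' @param hits_diff,hits_mm Hit data frames as returned by [map_queries()].
#' @return A deduplicated hit data frame.
#' @export
union_hits <- function(hits_diff, hits_mm) {
  all <- rbind(hits_diff, hits_mm)
  if (nrow(all) == 0) return(empty_hits())
  # order so that the preferred record (smaller n_diff, then diff mode)
  # comes first within each key, then drop duplicates
  pref <- order(all$query_id, all$genome_label, all$chrom, all$start,
                all$end, all$strand, all$n_diff, all$mode != "diff")
  all <- all[pref, ]
  key <- paste(all$query_id, all$genome_label, all$chrom, all$start,
               all$end, all$strand, sep = "\r")
  out <- all[!duplicated(key), ]
  rownames(out) <- NULL
  out
}

#' Collapse per-start hits into placements and build an alignment summary
#'
#' The exhaustive mapper reports one hit per qualifying start, so a single
#' genomic placement of a read typically yields a small cloud of overlapping
#' hits (starts within `k` of each other in `diff` mode). For per-read
#' uniqueness decisions these are collapsed: hits of the same read on the
#' same chromosome and strand whose intervals overlap are merged into one
#' placement carrying the minimum `n_diff`. A read is `unique` iff it has
#' exactly one placement.
#'
#' @param hits Hit data frame from [map_queries()] / [union_hits()].
#' @param read_ids Character vector of all read ids in the sample, including
#'   reads with no hits (needed so unmapped reads are represented).
#' @param genome_label Genome label for the summary (defaults to the label
#'   found in `hits`).
#' @return An object of class `align_summary`: list with `genome_label`,
#'   `reads` (data frame `read_id`, `mapped`, `unique`) and `hits` (collapsed
#'   placements).
#' @export
hits_to_align_summary <- function(hits, read_ids, genome_label = NULL) {
  if (is.null(genome_label)) {
    genome_label <- if (nrow(hits) > 0) hits$genome_label[1] else "genome"
  }
  if (nrow(hits) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = paste(hits$query_id, hits$chrom, hits$strand, sep = "\r"),
      ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end))
    red <- GenomicRanges::reduce(gr)
    keyparts <- strsplit(as.character(GenomicRanges::seqnames(red)), "\r",
                         fixed = TRUE)
    # minimum n_diff among constituent hits of each placement
    ov <- GenomicRanges::findOverlaps(gr, red)
    min_nd <- tapply(hits$n_diff[S4Vectors::queryHits(ov)],
                     S4Vectors::subjectHits(ov), min)
    placements <- data.frame(
      read_id = vapply(keyparts, `[`, character(1), 1L),
      chrom = vapply(keyparts, `[`, character(1), 2L),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red),
      strand = vapply(keyparts, `[`, character(1), 3L),
      n_diff = as.integer(min_nd[as.character(seq_along(red))]),
      stringsAsFactors = FALSE)
  } else {
    placements <- data.frame(read_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             strand = character(), n_diff = integer(),
                             stringsAsFactors = FALSE)
  }
  n_place <- table(placements$read_id)
  np <- as.integer(n_place[read_ids])
  np[is.na(np)] <- 0L
  reads <- data.frame(read_id = read_ids, mapped = np > 0L,
                      unique = np == 1L, stringsAsFactors = FALSE)
  structure(list(genome_label = genome_label, reads = reads,
                 hits = placements),
            class = "align_summary")
}

#' @export
print.align_summary <- function(x, ...) {
  cat("<align_summary>", x$genome_label, "-", nrow(x$reads), "reads;",
      sum(x$reads$mapped), "mapped,", sum(x$reads$unique), "unique\n")
  invisible(x)
}

#' Map reads with the built-in mapper and summarise per read
#'
#' Convenience wrapper: maps all reads against one genome and collapses the
#' result into an [hits_to_align_summary()] alignment summary.
#'
#' @param reads Named character vector of read sequences, or a data frame
#'   with columns `read_id` and `sequence`.
#' @param genome A [genome_seq()] object.
#' @inheritParams map_queries
#' @return An `align_summary` object.
#' @export
align_with_builtin <- function(reads, genome, mode = "diff", k = 2L) {
  if (is.data.frame(reads)) {
    reads <- stats::setNames(reads$sequence, reads$read_id)
  }
  hits <- map_queries(reads, genome, mode, k)
  hits_to_align_summary(hits, names(reads), genome$label)
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Load a SAM/BAM file into a per-read alignment summary
#'
#' Ingests alignments produced by an external aligner for real-scale runs.
#' SAM input is converted to BAM in a temporary directory via Rsamtools.
#' Coordinates are converted from 1-based SAM to 0-based half-open. A read
#' is `unique` iff it has exactly one alignment record (no secondary or
#' supplementary records) with mapping quality at least `mapq_floor`.
#'
#' @param path Path to a SAM or BAM file (SAM must carry `@SQ` header lines).
#' @param genome_label Genome label to attach to the summary.
#' @param mapq_floor Minimum MAPQ for a unique call (default 1).
#' @return An `align_summary` object. Hit `n_diff` is taken from the `NM`
#'   tag where present (`NA` otherwise).
#' @export
load_sam <- function(path, genome_label, mapq_floor = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to parse SAM file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand"),
    tag = "NM")
  x <- tryCatch(Rsamtools::scanBam(bam, param = p)[[1]],
                error = function(e) stop("failed to parse '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  width <- cigar_ref_width(x$cigar)
  hits <- data.frame(read_id = x$qname, chrom = as.character(x$rname),
                     start = x$pos - 1L, end = x$pos - 1L + width,
                     strand = as.character(x$strand), n_diff = nm,
                     secondary = secondary | supplementary,
                     mapq = x$mapq, stringsAsFactors = FALSE)[mapped, ,
                                                             drop = FALSE]
  read_ids <- unique(x$qname)
  n_rec <- table(hits$read_id)
  nr <- as.integer(n_rec[read_ids])
  nr[is.na(nr)] <- 0L
  has_sec <- tapply(hits$secondary, hits$read_id, any)
  mq_ok <- tapply(hits$mapq, hits$read_id, function(v) all(v >= mapq_floor,
                                                          na.rm = TRUE))
  sec <- unname(has_sec[read_ids]) %in% TRUE
  mq <- unname(mq_ok[read_ids]) %in% TRUE
  uniq <- nr == 1L & !sec & mq
  reads <- data.frame(read_id = read_ids, mapped = nr > 0L, unique = uniq,
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  hits$secondary <- NULL
  hits$mapq <- NULL
  rownames(hits) <- NULL
  structure(list(genome_label = genome_label, reads = reads, hits = hits),
            class = "align_summary")
}

#' Write hits as BED6 (plus an extended TSV)
#'
#' BED columns are `chrom, start, end, query_id, n_diff, strand` (0-based
#' half-open, native to the package's internal coordinates).
#'
#' @param hits Hit data frame from [map_queries()].
#' @param path Output BED path.
#' @param tsv_path Optional path for an extended TSV that adds the
#'   `genome_label` and `mode` columns.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, tsv_path = NULL) {
  bed <- hits[, c("chrom", "start", "end", "query_id", "n_diff", "strand")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
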