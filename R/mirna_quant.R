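#' Read small-RNA reads from a FASTQ file
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return Data frame with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss), stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' Qualities are constant `I` (Phred 40); the simulator models substitution
#' errors directly rather than through quality strings.
#'
#' @param reads Data frame with `read_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

# leftmost adapter occurrence: position p (1-based) where the adapter's
# prefix matches read[p..] with mismatch rate <= max_error_rate, requiring
# at least min_overlap aligned bases. Returns 0 when absent. Vectorized
# over reads for each candidate offset.
find_adapter3 <- function(seqs, adapter, min_overlap, max_error_rate) {
  la <- nchar(adapter)
  n <- length(seqs)
  found <- integer(n)  # 0 = not found
  if (la == 0 || n == 0) return(found)
  maxlen <- max(nchar(seqs))
  for (p in seq_len(maxlen)) {
    todo <- found == 0L & nchar(seqs) >= p + min_overlap - 1L
    if (!any(todo)) break
    ov <- pmin(nchar(seqs) - p + 1L, la)
    nmm <- integer(n)
    for (j in seq_len(min(la, maxlen))) {
      act <- todo & ov >= j
      if (!any(act)) break
      rc <- substring(seqs[act], p + j - 1L, p + j - 1L)
      nmm[act] <- nmm[act] + (rc != substring(adapter, j, j))
    }
    hit <- todo & ov >= min_overlap & nmm <= floor(max_error_rate * ov)
    found[hit] <- p
  }
  found
}

#' Trim adapters and filter small-RNA reads by length
#'
#' The 3' adapter is removed at its first (leftmost) occurrence: the
#' earliest read position where a prefix of the adapter matches the read
#' suffix with at most `max_error_rate` mismatches over at least
#' `min_overlap` bases. A 5' adapter is removed symmetrically (latest
#' occurrence of an adapter suffix at the read start). Reads whose trimmed
#' insert falls outside `[min_len, max_len]` are dropped; the dropped-read
#' counts are attached as the `"dropped"` attribute and reported via
#' `message()`.
#'
#' @param reads Data frame (`read_id`, `sequence`) or named character
#'   vector; empty `adapter5`/`adapter3` means that end is pre-trimmed.
#' @param adapter3,adapter5 Adapter sequences (may be `""`).
#' @param min_len,max_len Retained insert length bounds (defaults 18, 30).
#' @param min_overlap Minimum adapter overlap (default 3).
#' @param max_error_rate Allowed adapter mismatch rate (default 0.1).
#' @return Data frame (`read_id`, `sequence`) of retained trimmed reads.
#' @export
trim_and_filter <- function(reads, adapter3 = "", adapter5 = "",
                            min_len = 18L, max_len = 30L,
                            min_overlap = 3L, max_error_rate = 0.1) {
  if (!is.data.frame(reads)) {
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  seqs <- toupper(reads$sequence)
  if (nzchar(adapter3)) {
    pos <- find_adapter3(seqs, toupper(adapter3), min_overlap,
                         max_error_rate)
    seqs <- ifelse(pos > 0L, substring(seqs, 1L, pos - 1L), seqs)
  }
  if (nzchar(adapter5)) {
    # search on reversed strings so the "latest suffix at the start"
    # becomes "earliest prefix at the end" of the reversal
    rs <- rev_str(seqs)
    ra <- rev_str(toupper(adapter5))
    pos <- find_adapter3(rs, ra, min_overlap, max_error_rate)
    rs <- ifelse(pos > 0L, substring(rs, 1L, pos - 1L), rs)
    seqs <- rev_str(rs)
  }
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  dropped <- c(too_short = sum(len < min_len), too_long = sum(len > max_len))
  message("trim_and_filter: retained ", sum(keep), "/", length(keep),
          " reads (", dropped[["too_short"]], " too short, ",
          dropped[["too_long"]], " too long)")
  out <- data.frame(read_id = reads$read_id[keep], sequence = seqs[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

rev_str <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Assign small-RNA reads to miRNA clusters
#'
#' Reads are mapped to both genomes in edit-distance mode with at most `k`
#' differences (the quantification regime uses only this setting). A read
#' with at least one hit overlapping a cluster interval is assigned to the
#' cluster with the largest overlap fraction (shorter-interval denominator);
#' reads overlapping no cluster are unassigned, and exact ties between
#' clusters are left unassigned and logged. Each read counts at most once.
#'
#' @param reads Data frame (`read_id`, `sequence`).
#' @param cluster_set A [build_clusters()] result.
#' @param genomes List of [genome_seq()] objects the clusters were built on.
#' @param k Maximum edit distance for read mapping (default 2).
#' @param min_read_overlap Minimum overlap fraction between a read placement
#'   and a cluster interval (strict `>`; default 0.9).
#' @return List: `counts` (named integer per cluster_id), `n_input`,
#'   `n_mapped` (reads with at least one genome hit), `n_assigned`,
#'   `n_tied`, and `assignment` (read-level data frame).
#' @export
assign_reads <- function(reads, cluster_set, genomes, k = 2L,
                         min_read_overlap = 0.9) {
  stopifnot(inherits(cluster_set, "mirna_cluster_set"))
  queries <- stats::setNames(reads$sequence, reads$read_id)
  hits <- do.call(rbind, lapply(genomes, function(g) {
    map_queries(queries, g, "diff", k)
  }))
  rownames(hits) <- NULL
  counts <- stats::setNames(integer(nrow(cluster_set$clusters)),
                            cluster_set$clusters$cluster_id)
  mapped_ids <- unique(hits$query_id)
  iv <- cluster_set$intervals
  best <- NULL
  if (nrow(hits) > 0 && nrow(iv) > 0) {
    hkey <- paste(hits$genome_label, hits$chrom, hits$strand, sep = "\r")
    ikey <- paste(iv$genome_label, iv$chrom, iv$strand, sep = "\r")
    hgr <- GenomicRanges::GRanges(
      seqnames = hkey, ranges = IRanges::IRanges(hits$start + 1L,
                                                 hits$end))
    igr <- GenomicRanges::GRanges(
      seqnames = ikey, ranges = IRanges::IRanges(iv$start + 1L, iv$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(hgr, igr))
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      frac <- overlap_fraction(hits$start[qh], hits$end[qh],
                               iv$start[sh], iv$end[sh])
      good <- frac > min_read_overlap
      if (any(good)) {
        cand <- data.frame(read_id = hits$query_id[qh[good]],
                           cluster_id = iv$cluster_id[sh[good]],
                           frac = frac[good], stringsAsFactors = FALSE)
        # best overlap per read x cluster, then best cluster per read
        agg <- stats::aggregate(frac ~ read_id + cluster_id, data = cand,
                                FUN = max)
        best <- do.call(rbind, lapply(split(agg, agg$read_id), function(d) {
          mx <- max(d$frac)
          top <- d[d$frac == mx, , drop = FALSE]
          data.frame(read_id = d$read_id[1],
                     cluster_id = if (nrow(top) == 1) top$cluster_id
                                  else NA_character_,
                     frac = mx, tied = nrow(top) > 1,
                     stringsAsFactors = FALSE)
        }))
      }
    }
  }
  n_tied <- 0L
  if (!is.null(best)) {
    n_tied <- sum(best$tied)
    tab <- table(best$cluster_id[!best$tied])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (n_tied > 0) {
    message("assign_reads: ", n_tied,
            " read(s) tied between clusters, left unassigned")
  }
  list(counts = counts,
       n_input = nrow(reads),
       n_mapped = length(mapped_ids),
       n_assigned = sum(counts),
       n_tied = n_tied,
       assignment = best)
}

#' Cluster-level count table with RPM normalization
#'
#' @param count_list Named list of [assign_reads()] results (names are
#'   sample ids), or a counts matrix.
#' @param mapped_reads Named vector of per-sample denominators when a plain
#'   matrix is given.
#' @param assigned_reads Optional named vector of per-sample assigned-read
#'   totals (taken from the `assign_reads` results otherwise).
#' @return Object of class `cluster_counts`: list with `counts` matrix
#'   (clusters x samples), `mapped_reads`, `assigned_reads`.
#' @export
cluster_count_table <- function(count_list, mapped_reads = NULL,
                                assigned_reads = NULL) {
  if (is.list(count_list) && !is.data.frame(count_list) &&
      !is.matrix(count_list)) {
    counts <- do.call(cbind, lapply(count_list, `[[`, "counts"))
    colnames(counts) <- names(count_list)
    mapped_reads <- vapply(count_list, `[[`, numeric(1), "n_mapped")
    assigned_reads <- vapply(count_list, `[[`, numeric(1), "n_assigned")
  } else {
    counts <- as.matrix(count_list)
    if (is.null(mapped_reads)) stop("mapped_reads required with a matrix")
    mapped_reads <- mapped_reads[colnames(counts)]
    if (is.null(assigned_reads)) assigned_reads <- colSums(counts)
  }
  if (any(colSums(counts) > mapped_reads)) {
    stop("assigned counts exceed the mapped-read denominator")
  }
  structure(list(counts = counts, mapped_reads = mapped_reads,
                 assigned_reads = assigned_reads),
            class = "cluster_counts")
}

#' @export
print.cluster_counts <- function(x, ...) {
  cat("<cluster_counts>", nrow(x$counts), "clusters x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' RPM-normalize a cluster count table
#'
#' `RPM = count * 1e6 / denominator`. The default denominator is the number
#' of mapped reads in the sample (reads with at least one genome hit after
#' QC); `"assigned_reads"` rescales by the constant per-sample factor
#' mapped/assigned.
#'
#' @param tab A [cluster_count_table()].
#' @param denominator_policy `"mapped_reads"` (default) or
#'   `"assigned_reads"`.
#' @return Numeric RPM matrix (clusters x samples).
#' @export
normalize_rpm <- function(tab,
                          denominator_policy = c("mapped_reads",
                                                 "assigned_reads")) {
  denominator_policy <- match.arg(denominator_policy)
  stopifnot(inherits(tab, "cluster_counts"))
  den <- if (denominator_policy == "mapped_reads") tab$mapped_reads
         else tab$assigned_reads
  if (any(den <= 0)) stop("zero denominator for sample(s): ",
                          paste(colnames(tab$counts)[den <= 0],
                                collapse = ", "))
  sweep(tab$counts, 2, den, "/") * 1e6
}

aggregate_rpm <- function(rpm, samples, aggregate) {
  fun <- switch(aggregate, mean = mean, max = max, min = min)
  apply(rpm[, samples, drop = FALSE], 1, fun)
}

#' Identify feeder-specific marker miRNA clusters
#'
#' A Type-B or conserved cluster is a marker iff its feeder RPM exceeds
#' `min_feeder_rpm` (default 10) AND its RPM in clean feeder-free hESC
#' samples is below `max_clean_rpm` (default 1). Type-A mouse clusters only
#' need feeder RPM above `typeA_min_rpm` (default 1), because Type-A
#' sequences cannot arise from human reads at all. Replicates are collapsed
#' with `aggregate` (default mean).
#'
#' @param rpm RPM matrix from [normalize_rpm()].
#' @param feeder_samples,clean_samples Column names of feeder and clean
#'   feeder-free hESC samples.
#' @param cluster_set The clusters the rows refer to.
#' @param min_feeder_rpm,max_clean_rpm,typeA_min_rpm Threshold parameters.
#' @param aggregate `"mean"` (default), `"max"` or `"min"`.
#' @return Data frame (`cluster_id`, `name`, `type`, `feeder_rpm`,
#'   `clean_rpm`, `rule`) of class `marker_set`.
#' @export
identify_marker_mirnas <- function(rpm, feeder_samples, clean_samples,
                                   cluster_set, min_feeder_rpm = 10,
                                   max_clean_rpm = 1, typeA_min_rpm = 1,
                                   aggregate = c("mean", "max", "min")) {
  aggregate <- match.arg(aggregate)
  if (length(feeder_samples) == 0) stop("no feeder samples given")
  if (length(clean_samples) == 0) stop("no clean hESC samples given")
  cl <- cluster_set$clusters
  fr <- aggregate_rpm(rpm, feeder_samples, aggregate)[cl$cluster_id]
  cr <- aggregate_rpm(rpm, clean_samples, aggregate)[cl$cluster_id]
  is_typeA <- cl$type == "typeA_mouse"
  is_bc <- cl$type %in% c("typeB_mouse", "conserved")
  sel_a <- is_typeA & fr > typeA_min_rpm
  sel_bc <- is_bc & fr > min_feeder_rpm & cr < max_clean_rpm
  sel <- sel_a | sel_bc
  out <- data.frame(cluster_id = cl$cluster_id[sel], name = cl$name[sel],
                    type = cl$type[sel], feeder_rpm = fr[sel],
                    clean_rpm = cr[sel],
                    rule = ifelse(sel_a[sel], "typeA_feeder_rpm",
                                  "feeder_high_clean_low"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("marker_set", class(out))
  out
}

#' Conserved clusters potentially influenced by feeder reads
#'
#' Conserved clusters (only) whose feeder-system RPM shows at least a
#' `fold`-fold increase over the feeder-free RPM, with pseudocount `eps`:
#' `(feeder + eps) / (clean + eps) >= fold`.
#'
#' @inheritParams identify_marker_mirnas
#' @param fold Minimum fold increase (default 10).
#' @param eps Pseudocount (default 0.1).
#' @return Data frame (`cluster_id`, `name`, `feeder_rpm`, `clean_rpm`,
#'   `fold`).
#' @export
identify_influenced_mirnas <- function(rpm, feeder_samples, clean_samples,
                                       cluster_set, fold = 10, eps = 0.1,
                                       aggregate = c("mean", "max",
                                                     "min")) {
  aggregate <- match.arg(aggregate)
  cl <- cluster_set$clusters
  cons <- cl[cl$type == "conserved", , drop = FALSE]
  fr <- aggregate_rpm(rpm, feeder_samples, aggregate)[cons$cluster_id]
  cr <- aggregate_rpm(rpm, clean_samples, aggregate)[cons$cluster_id]
  ratio <- (fr + eps) / (cr + eps)
  sel <- ratio >= fold
  out <- data.frame(cluster_id = cons$cluster_id[sel],
                    name = cons$name[sel], feeder_rpm = fr[sel],
                    clean_rpm = cr[sel], fold = ratio[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold), ]
  rownames(out) <- NULL
  out
}

#' Assess feeder contamination of one sample from marker evidence
#'
#' Reports, per marker class, the number of markers detected with at least
#' one read and the summed marker RPM. The contamination flag is raised if
#' any Type-A marker is detected (a single Type-A read is species-proof) or
#' if the summed Type-B/conserved marker RPM exceeds `rpm_threshold`.
#'
#' @param counts Named integer vector: cluster counts for the sample.
#' @param rpm Named numeric vector: cluster RPM for the sample.
#' @param markers A [identify_marker_mirnas()] result.
#' @param rpm_threshold Flag threshold on summed non-Type-A marker RPM
#'   (default 1).
#' @return List of class `contamination_report`: per-class detection counts
#'   and summed RPM, plus `flag`.
#' @export
assess_contamination <- function(counts, rpm, markers, rpm_threshold = 1) {
  if (nrow(markers) == 0) stop("marker set is empty")
  per_class <- lapply(split(markers$cluster_id, markers$type), function(cid) {
    list(n_markers = length(cid),
         n_detected = sum(counts[cid] > 0, na.rm = TRUE),
         sum_rpm = sum(rpm[cid], na.rm = TRUE))
  })
  typeA_cid <- markers$cluster_id[markers$type == "typeA_mouse"]
  other_cid <- markers$cluster_id[markers$type != "typeA_mouse"]
  typeA_detected <- sum(counts[typeA_cid] > 0, na.rm = TRUE)
  other_rpm <- sum(rpm[other_cid], na.rm = TRUE)
  structure(list(per_class = per_class,
                 typeA_detected = typeA_detected,
                 non_typeA_marker_rpm = other_rpm,
                 total_marker_rpm = sum(rpm[markers$cluster_id],
                                        na.rm = TRUE),
                 flag = typeA_detected > 0 || other_rpm > rpm_threshold),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("<contamination_report> flag:", x$flag, "\n")
  cat("  Type-A markers detected:", x$typeA_detected, "\n")
  cat("  non-Type-A marker RPM:",
      format(x$non_typeA_marker_rpm, digits = 4), "\n")
  invisible(x)
}
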