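#' Partition reads by species of origin
#'
#' Implements mutually exclusive dual-genome assignment: a read is
#' target-specific iff it is uniquely mapped in the target genome and
#' unmapped in the other genome (and symmetrically). Reads mapped in both
#' genomes are ambiguous, even when unique in only one. Reads mapped
#' non-uniquely in exactly one genome cannot be called confidently either
#' and are also labelled ambiguous. Reads mapped in neither genome are
#' unmapped.
#'
#' @param align_target `align_summary` for the target species genome
#'   (e.g. human for hPSC samples).
#' @param align_contaminant `align_summary` for the putative contaminant
#'   genome (e.g. mouse feeder cells).
#' @return Object of class `species_partition`: list with `labels`
#'   (data frame `read_id`, `label`), `counts` (named vector over the four
#'   labels), and the two genome labels. Label names are
#'   `<genome_label>_specific`, `ambiguous`, `unmapped`.
#' @examples
#' a <- structure(list(genome_label = "human",
#'   reads = data.frame(read_id = "r1", mapped = TRUE, unique = TRUE)),
#'   class = "align_summary")
#' b <- structure(list(genome_label = "mouse",
#'   reads = data.frame(read_id = "r1", mapped = FALSE, unique = FALSE)),
#'   class = "align_summary")
#' partition_reads(a, b)$counts
#' @export
partition_reads <- function(align_target, align_contaminant) {
  ta <- align_target$reads
  co <- align_contaminant$reads
  ids <- union(ta$read_id, co$read_id)
  if (length(ids) == 0) stop("empty read universe")
  it <- match(ids, ta$read_id)
  ic <- match(ids, co$read_id)
  t_mapped <- !is.na(it) & ta$mapped[it]
  t_unique <- !is.na(it) & ta$unique[it]
  c_mapped <- !is.na(ic) & co$mapped[ic]
  c_unique <- !is.na(ic) & co$unique[ic]
  lab_t <- paste0(align_target$genome_label, "_specific")
  lab_c <- paste0(align_contaminant$genome_label, "_specific")
  label <- ifelse(t_unique & !c_mapped, lab_t,
           ifelse(c_unique & !t_mapped, lab_c,
           ifelse(!t_mapped & !c_mapped, "unmapped", "ambiguous")))
  counts <- c(sum(label == lab_t), sum(label == lab_c),
              sum(label == "ambiguous"), sum(label == "unmapped"))
  names(counts) <- c(lab_t, lab_c, "ambiguous", "unmapped")
  stopifnot(sum(counts) == length(ids))
  structure(list(labels = data.frame(read_id = ids, label = label,
                                     stringsAsFactors = FALSE),
                 counts = counts,
                 target = align_target$genome_label,
                 contaminant = align_contaminant$genome_label),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("<species_partition>", sum(x$counts), "reads\n")
  print(x$counts)
  r <- tryCatch(mixing_ratio(x), error = function(e) NA_real_)
  cat("mixing ratio:", format(r, digits = 4), "\n")
  invisible(x)
}

#' Mixing ratio of contaminant-derived reads
#'
#' Contaminant-specific read count divided by the sum of contaminant- and
#' target-specific read counts. Ambiguous and unmapped reads are excluded
#' from both the numerator and the denominator.
#'
#' @param partition A [partition_reads()] result.
#' @return A fraction in `[0, 1]`.
#' @export
mixing_ratio <- function(partition) {
  stopifnot(inherits(partition, "species_partition"))
  nt <- partition$counts[[paste0(partition$target, "_specific")]]
  nc <- partition$counts[[paste0(partition$contaminant, "_specific")]]
  if (nt + nc == 0) {
    stop("mixing ratio undefined: no species-specific reads in either genome")
  }
  nc / (nc + nt)
}

#' Gene models from a GTF file or data frame
#'
#' Parses exon features keyed by the `gene_id` attribute and reduces them to
#' a non-overlapping exon union per gene. Coordinates in the returned object
#' are 0-based half-open.
#'
#' @param x Path to a GTF file, or a data frame with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open exon intervals).
#' @param genome_label Genome the models belong to.
#' @return Object of class `gene_models`: list with `genome_label`, `exons`
#'   (data frame of unioned exon intervals), and `lengths_kb` (named vector
#'   of exonic lengths in kilobases).
#' @export
gene_models <- function(x, genome_label) {
  if (is.character(x) && length(x) == 1) {
    gr <- rtracklayer::import(x)
    gr <- gr[gr$type == "exon"]
    df <- data.frame(gene_id = gr$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand, gene_id = df$gene_id)
  byg <- GenomicRanges::split(gr, gr$gene_id)
  red <- GenomicRanges::reduce(byg)
  flat <- unlist(red)
  exons <- data.frame(gene_id = names(flat),
                      chrom = as.character(GenomicRanges::seqnames(flat)),
                      strand = as.character(GenomicRanges::strand(flat)),
                      start = GenomicRanges::start(flat) - 1L,
                      end = GenomicRanges::end(flat),
                      stringsAsFactors = FALSE)
  rownames(exons) <- NULL
  lens <- vapply(red, function(g) sum(GenomicRanges::width(g)), numeric(1))
  if (any(lens < 1)) stop("gene(s) with empty exon union")
  structure(list(genome_label = genome_label, exons = exons,
                 lengths_kb = lens / 1000),
            class = "gene_models")
}

#' Count reads per gene (exon-union overlap counter)
#'
#' A read increments gene `g` iff any of its placements overlaps the exon
#' union of `g` by at least one base. Reads whose placements overlap exons
#' of more than one gene are discarded as ambiguous; each read is counted at
#' most once.
#'
#' @param hits Placement data frame (`read_id`, `chrom`, `start`, `end`,
#'   `strand`), typically the `hits` element of an `align_summary`
#'   restricted to a species-specific read set.
#' @param models A [gene_models()] object.
#' @param stranded Count only same-strand overlaps? Default `FALSE`
#'   (unstranded libraries).
#' @return Named integer vector of counts over all genes in `models`.
#' @export
count_reads_per_gene <- function(hits, models, stranded = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  genes <- sort(unique(models$exons$gene_id))
  counts <- stats::setNames(integer(length(genes)), genes)
  if (nrow(hits) == 0) return(counts)
  rgr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = if (stranded) hits$strand else "*")
  egr <- GenomicRanges::GRanges(
    seqnames = models$exons$chrom,
    ranges = IRanges::IRanges(start = models$exons$start + 1L,
                              end = models$exons$end),
    strand = if (stranded) models$exons$strand else "*")
  ov <- GenomicRanges::findOverlaps(rgr, egr,
                                    ignore.strand = !stranded)
  if (length(ov) == 0) return(counts)
  pairs <- unique(data.frame(
    read = hits$read_id[S4Vectors::queryHits(ov)],
    gene = models$exons$gene_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  ngene <- table(pairs$read)
  keep <- pairs[ngene[pairs$read] == 1L, , drop = FALSE]
  tab <- table(keep$gene)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Expression table container
#'
#' Genes-by-samples matrix of raw counts with per-sample mapped-read totals
#' and optional per-gene exonic lengths (for FPKM).
#'
#' @param counts Numeric matrix, rows = gene ids, columns = sample ids.
#' @param mapped_totals Named numeric vector of per-sample mapped-read
#'   totals.
#' @param lengths_kb Optional named numeric vector of exonic lengths (kb).
#' @param values Optional pre-normalized value matrix.
#' @param scheme One of `"count"`, `"RPM"`, `"FPKM"`.
#' @return Object of class `expr_table`.
#' @export
expr_table <- function(counts, mapped_totals, lengths_kb = NULL,
                       values = NULL, scheme = "count") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (!all(colnames(counts) %in% names(mapped_totals))) {
    stop("mapped_totals missing for some samples")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts,
                 mapped_totals = mapped_totals[colnames(counts)],
                 lengths_kb = lengths_kb,
                 values = if (is.null(values)) counts else values,
                 scheme = scheme),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("<expr_table>", nrow(x$counts), "features x", ncol(x$counts),
      "samples;", x$scheme, "\n")
  invisible(x)
}

#' Normalize an expression table to RPM or FPKM
#'
#' `RPM = count * 1e6 / mapped_total`;
#' `FPKM = count * 1e9 / (mapped_total * exonic_length_in_bases)`.
#' Per-sample mapped-read totals are used as denominators.
#'
#' @param table An [expr_table()].
#' @param scheme `"RPM"` or `"FPKM"`.
#' @return An [expr_table()] whose `values` hold the normalized matrix.
#' @export
normalize_expr <- function(table, scheme = c("RPM", "FPKM")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "expr_table"))
  tot <- table$mapped_totals
  if (any(tot <= 0)) stop("per-sample mapped totals must be > 0")
  rpm <- sweep(table$counts, 2, tot, "/") * 1e6
  if (scheme == "RPM") {
    vals <- rpm
  } else {
    if (is.null(table$lengths_kb)) {
      stop("FPKM requires per-gene exonic lengths")
    }
    len <- table$lengths_kb[rownames(table$counts)]
    if (anyNA(len)) stop("missing exonic length for some genes")
    vals <- rpm / len
  }
  expr_table(table$counts, table$mapped_totals, table$lengths_kb,
             values = vals, scheme = scheme)
}

#' Cell-type marker genes by fold-change against all other cell types
#'
#' A gene is a marker of the target cell type iff
#' `(target + eps) / (other + eps) > fold` for every non-target column
#' (strict inequality; default 20-fold).
#'
#' @param expr An [expr_table()] with one column per cell type (normalized
#'   values are used).
#' @param target Column name of the target cell type.
#' @param fold Fold-change threshold (must be > 1). Default 20.
#' @param eps Pseudocount added to both sides (default 0.1).
#' @return Character vector of marker gene ids.
#' @export
find_marker_genes <- function(expr, target, fold = 20, eps = 0.1) {
  stopifnot(inherits(expr, "expr_table"))
  if (fold <= 1) stop("fold must be > 1")
  v <- expr$values
  if (!target %in% colnames(v)) stop("unknown target column: ", target)
  if (ncol(v) < 2) stop("need at least one non-target cell type column")
  others <- setdiff(colnames(v), target)
  ok <- rep(TRUE, nrow(v))
  for (o in others) {
    ok <- ok & ((v[, target] + eps) / (v[, o] + eps) > fold)
  }
  rownames(v)[ok]
}

#' Misalignment-influenced genes
#'
#' Compares the apparent ("false") expression of target-genome genes driven
#' by contaminant reads against their expression in clean samples. A gene is
#' potentially influenced iff
#' `(false + eps) / (clean + eps) >= fold` (at least `fold`-fold increase;
#' default 2). The returned fold values allow deriving stricter subsets
#' (e.g. a >= 5-fold set).
#'
#' @param false_expr,clean_expr [expr_table()] objects normalized on the
#'   same gene universe (single-column, or multi-column averaged by
#'   `aggregate`).
#' @param fold Minimum fold increase (default 2).
#' @param eps Pseudocount (default 0.1).
#' @param aggregate Function collapsing replicate columns (default
#'   `rowMeans` behaviour via `mean`).
#' @return Data frame (`gene_id`, `false_value`, `clean_value`, `fold`)
#'   sorted by decreasing fold.
#' @export
find_influenced_genes <- function(false_expr, clean_expr, fold = 2,
                                  eps = 0.1, aggregate = mean) {
  stopifnot(inherits(false_expr, "expr_table"),
            inherits(clean_expr, "expr_table"))
  if (!identical(sort(rownames(false_expr$values)),
                 sort(rownames(clean_expr$values)))) {
    stop("gene universes of the two tables differ")
  }
  genes <- rownames(false_expr$values)
  fv <- apply(false_expr$values, 1, aggregate)
  cv <- apply(clean_expr$values[genes, , drop = FALSE], 1, aggregate)
  ratio <- (fv + eps) / (cv + eps)
  sel <- ratio >= fold
  out <- data.frame(gene_id = genes[sel], false_value = fv[sel],
                    clean_value = cv[sel], fold = ratio[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold), ]
  rownames(out) <- NULL
  out
}

#' Genes expressed above an FPKM floor in at least one sample
#'
#' @param expr An FPKM-normalized [expr_table()].
#' @param min_fpkm Inclusive threshold (default 1).
#' @return Character vector of gene ids with `FPKM >= min_fpkm` in at least
#'   one sample.
#' @export
select_expressed_genes <- function(expr, min_fpkm = 1) {
  stopifnot(inherits(expr, "expr_table"))
  if (!identical(expr$scheme, "FPKM")) {
    stop("select_expressed_genes expects an FPKM-normalized table")
  }
  keep <- apply(expr$values, 1, function(v) any(v >= min_fpkm))
  rownames(expr$values)[keep]
}

#' Pearson correlation matrix of an expression table
#'
#' Plain matrix export used for sample-similarity reporting (heatmap
#' rendering is out of scope).
#'
#' @param expr An [expr_table()].
#' @return Sample-by-sample Pearson correlation matrix.
#' @export
expr_correlation <- function(expr) {
  stopifnot(inherits(expr, "expr_table"))
  stats::cor(expr$values, method = "pearson")
}
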