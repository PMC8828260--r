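#' Read mature miRNAs from a FASTA file (miRBase dialect)
#'
#' `U` is normalized to `T`; the header up to the first whitespace is the
#' miRNA name. Species is inferred from the standard name prefix
#' (`hsa-` = human, `mmu-` = mouse) unless given explicitly.
#'
#' @param path FASTA path.
#' @param species Optional named character vector mapping miRNA name to
#'   species, or a single species for all records.
#' @return Data frame with columns `name`, `species`, `sequence`.
#' @export
read_mirna_fasta <- function(path, species = NULL) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- chartr("Uu", "Tt", as.character(ss))
  mirna_set(nm, toupper(seqs), species)
}

#' Assemble a mature miRNA set
#'
#' @param name Character vector of miRNA names (unique).
#' @param sequence DNA/RNA sequences (U normalized to T).
#' @param species Species per miRNA (`"human"`/`"mouse"`); inferred from
#'   `hsa-`/`mmu-` prefixes when `NULL`.
#' @return Data frame (`name`, `species`, `sequence`).
#' @export
mirna_set <- function(name, sequence, species = NULL) {
  if (anyDuplicated(name)) stop("miRNA names must be unique")
  sequence <- toupper(chartr("Uu", "Tt", sequence))
  if (is.null(species)) {
    species <- ifelse(startsWith(name, "hsa-"), "human",
               ifelse(startsWith(name, "mmu-"), "mouse", NA_character_))
    if (anyNA(species)) {
      stop("cannot infer species from name prefix for: ",
           paste(utils::head(name[is.na(species)], 5), collapse = ", "),
           "; pass `species` explicitly")
    }
  } else if (length(species) == 1) {
    species <- rep(species, length(name))
  } else if (!is.null(names(species))) {
    species <- unname(species[name])
  }
  data.frame(name = name, species = species, sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Locate mature miRNAs on both genomes
#'
#' Each miRNA is mapped against every supplied genome in both regimes —
#' edit distance at most `max_diff` (gaps allowed) and substitution count at
#' most `max_mismatch` (gap-free) — and the two hit sets are merged with
#' [union_hits()].
#'
#' @param mirnas Data frame from [mirna_set()] / [read_mirna_fasta()].
#' @param genomes List of [genome_seq()] objects (typically human + mouse).
#' @param cfg A [mapper_config()].
#' @return Locus data frame: `mirna_name`, `genome_label`, `chrom`, `start`,
#'   `end`, `strand`, `n_diff`, `mode`.
#' @export
locate_mirnas <- function(mirnas, genomes, cfg = mapper_config()) {
  stopifnot(is.data.frame(mirnas), length(genomes) >= 1)
  queries <- stats::setNames(mirnas$sequence, mirnas$name)
  out <- lapply(genomes, function(g) {
    hd <- map_queries(queries, g, "diff", cfg$max_diff)
    hm <- map_queries(queries, g, "mismatch", cfg$max_mismatch)
    union_hits(hd, hm)
  })
  loci <- do.call(rbind, out)
  rownames(loci) <- NULL
  names(loci)[names(loci) == "query_id"] <- "mirna_name"
  loci
}

#' Fraction of the shorter (or either) interval covered by an overlap
#'
#' Intervals are 0-based half-open; comparisons across chromosomes or
#' strands are the caller's responsibility (such pairs should be treated as
#' overlap 0).
#'
#' @param start1,end1,start2,end2 Interval coordinates (vectorized).
#' @param denominator `"shorter"` (default; overlap / min length) or
#'   `"reciprocal"` (overlap / max length, i.e. both intervals must be
#'   covered to the threshold).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(start1, end1, start2, end2,
                             denominator = c("shorter", "reciprocal")) {
  denominator <- match.arg(denominator)
  inter <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  len1 <- end1 - start1
  len2 <- end2 - start2
  den <- if (denominator == "shorter") pmin(len1, len2) else pmax(len1, len2)
  ifelse(den > 0, inter / den, 0)
}

#' Build cross-species miRNA clusters by locus overlap
#'
#' Two miRNAs are linked iff any pair of their loci (on either genome) lies
#' on the same chromosome and strand and overlaps by more than
#' `min_overlap` of the shorter interval. Clusters are the connected
#' components of this graph (single linkage, so transitive chains merge).
#' Every input miRNA belongs to exactly one cluster; miRNAs with no
#' overlapping partner form singleton clusters.
#'
#' @param mirnas Data frame from [mirna_set()].
#' @param loci Locus data frame from [locate_mirnas()].
#' @param min_overlap Overlap fraction threshold (strict `>`; default 0.9).
#' @param denominator Overlap denominator policy, see [overlap_fraction()].
#' @return Object of class `mirna_cluster_set`: list with
#'   * `clusters`: data frame `cluster_id`, `name`, `type`, `n_mouse`,
#'     `n_human`, plus list-columns `members_mouse`, `members_human`;
#'   * `loci`: the input loci annotated with `cluster_id`;
#'   * `intervals`: reduced per-cluster genomic intervals used for read
#'     assignment.
#' @export
build_clusters <- function(mirnas, loci, min_overlap = 0.9,
                           denominator = c("shorter", "reciprocal")) {
  denominator <- match.arg(denominator)
  nodes <- mirnas$name
  edges <- NULL
  if (nrow(loci) > 0) {
    grp <- paste(loci$genome_label, loci$chrom, loci$strand, sep = "\r")
    by_grp <- split(seq_len(nrow(loci)), grp)
    edge_list <- lapply(by_grp, function(ix) {
      if (length(ix) < 2) return(NULL)
      ir <- IRanges::IRanges(start = loci$start[ix] + 1L,
                             end = loci$end[ix])
      ov <- IRanges::findOverlaps(ir, ir)
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      keep <- qh < sh
      qh <- qh[keep]; sh <- sh[keep]
      if (length(qh) == 0) return(NULL)
      frac <- overlap_fraction(loci$start[ix][qh], loci$end[ix][qh],
                               loci$start[ix][sh], loci$end[ix][sh],
                               denominator)
      good <- frac > min_overlap
      if (!any(good)) return(NULL)
      cbind(loci$mirna_name[ix][qh[good]], loci$mirna_name[ix][sh[good]])
    })
    edges <- do.call(rbind, edge_list)
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(nodes)
  if (!is.null(edges)) {
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(g, t(edges))
    }
  }
  comp <- igraph::components(g)$membership
  finalize_clusters(mirnas, loci, split(names(comp), comp))
}

# Shared tail of build_clusters / read_based_clusters: classify, name and
# order a list of member sets.
finalize_clusters <- function(mirnas, loci, member_sets,
                              cross_mappable = NULL, n_reads = NULL) {
  species <- stats::setNames(mirnas$species, mirnas$name)
  rows <- lapply(member_sets, function(members) {
    mm <- sort(members[species[members] == "mouse"])
    mh <- sort(members[species[members] == "human"])
    locus_genomes <- if (is.null(cross_mappable)) {
      unique(loci$genome_label[loci$mirna_name %in% members])
    } else {
      own <- unique(species[members])
      other <- setdiff(c("human", "mouse"), own)
      c(own, other[isTRUE(any(cross_mappable[members], na.rm = TRUE))])
    }
    type <- classify_cluster(mm, mh, locus_genomes)
    list(name = name_cluster(mm, mh), type = type,
         members_mouse = mm, members_human = mh)
  })
  nm <- vapply(rows, `[[`, character(1), "name")
  ord <- order(nm)
  rows <- rows[ord]
  member_sets <- member_sets[ord]
  clusters <- data.frame(
    cluster_id = sprintf("cl%04d", seq_along(rows)),
    name = vapply(rows, `[[`, character(1), "name"),
    type = vapply(rows, `[[`, character(1), "type"),
    n_mouse = vapply(rows, function(r) length(r$members_mouse), integer(1)),
    n_human = vapply(rows, function(r) length(r$members_human), integer(1)),
    stringsAsFactors = FALSE)
  clusters$members_mouse <- I(lapply(rows, `[[`, "members_mouse"))
  clusters$members_human <- I(lapply(rows, `[[`, "members_human"))
  if (!is.null(n_reads)) clusters$n_reads <- n_reads[ord]
  mir2cl <- stats::setNames(
    rep(clusters$cluster_id, lengths(member_sets)),
    unlist(member_sets, use.names = FALSE))
  loci$cluster_id <- unname(mir2cl[loci$mirna_name])
  intervals <- cluster_intervals(loci)
  structure(list(clusters = clusters, loci = loci, intervals = intervals),
            class = "mirna_cluster_set")
}

cluster_intervals <- function(loci) {
  loci <- loci[!is.na(loci$cluster_id), , drop = FALSE]
  if (nrow(loci) == 0) {
    return(data.frame(cluster_id = character(), genome_label = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(loci$cluster_id, loci$genome_label, loci$chrom, loci$strand,
               sep = "\r")
  gr <- GenomicRanges::GRanges(
    seqnames = key,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  red <- GenomicRanges::reduce(gr)
  parts <- strsplit(as.character(GenomicRanges::seqnames(red)), "\r",
                    fixed = TRUE)
  out <- data.frame(
    cluster_id = vapply(parts, `[`, character(1), 1L),
    genome_label = vapply(parts, `[`, character(1), 2L),
    chrom = vapply(parts, `[`, character(1), 3L),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = vapply(parts, `[`, character(1), 4L),
    stringsAsFactors = FALSE)
  out[order(out$cluster_id, out$genome_label, out$chrom, out$start), ]
}

#' @export
print.mirna_cluster_set <- function(x, ...) {
  cat("<mirna_cluster_set>", nrow(x$clusters), "clusters\n")
  print(table(x$clusters$type))
  invisible(x)
}

#' Classify a miRNA cluster
#'
#' A cluster with annotated members of both species is `conserved`. A
#' single-species cluster is Type-B if the union of its members' loci
#' includes the other species' genome (its sequences align there but
#' overlap no annotated miRNA — otherwise it would be conserved), and
#' Type-A if it has no loci on the other genome at all.
#'
#' @param members_mouse,members_human Character vectors of member names.
#' @param locus_genomes Genome labels (`"human"`/`"mouse"`) on which the
#'   cluster's members have qualifying loci.
#' @return One of `"conserved"`, `"typeA_mouse"`, `"typeB_mouse"`,
#'   `"typeA_human"`, `"typeB_human"`.
#' @export
classify_cluster <- function(members_mouse, members_human, locus_genomes) {
  has_m <- length(members_mouse) > 0
  has_h <- length(members_human) > 0
  if (!has_m && !has_h) stop("cluster with no members")
  if (has_m && has_h) return("conserved")
  if (has_m) {
    if ("human" %in% locus_genomes) "typeB_mouse" else "typeA_mouse"
  } else {
    if ("mouse" %in% locus_genomes) "typeB_human" else "typeA_human"
  }
}

#' Canonical cluster name
#'
#' `<mouse members joined by '/'>__<human members joined by '/'>`, each side
#' `NA` when empty, members sorted lexicographically — e.g.
#' `mmu-miR-a/mmu-miR-b__hsa-miR-c` for a conserved cluster or
#' `mmu-miR-a__NA` for a mouse-specific one.
#'
#' @param members_mouse,members_human Character vectors of member names.
#' @return The canonical cluster name string.
#' @export
name_cluster <- function(members_mouse, members_human) {
  side <- function(m) if (length(m) == 0) "NA" else
    paste(sort(m), collapse = "/")
  paste0(side(members_mouse), "__", side(members_human))
}

#' Refine clusters by shared-read evidence
#'
#' Builds the bipartite read-to-miRNA graph and takes its connected
#' components, projected to miRNA sets: if read M maps to miR-A and miR-B
#' while read N maps to miR-B and miR-C, then A, B and C join one cluster
#' (together with any cross-species miRNAs the same reads hit). Type-A/B
#' status of single-species components is decided by the cross-genome
#' mappability of the member sequences.
#'
#' @param read_to_mirna Named list: read id -> character vector of miRNA
#'   names the read maps to (both species mixed).
#' @param mirnas Data frame from [mirna_set()].
#' @param cross_mappable Named logical per miRNA: does its sequence align to
#'   the other species' genome under the mapper thresholds?
#' @return A `mirna_cluster_set`; the cluster table carries `n_reads`.
#' @export
read_based_clusters <- function(read_to_mirna, mirnas, cross_mappable) {
  touched <- unique(unlist(read_to_mirna, use.names = FALSE))
  stopifnot(all(touched %in% mirnas$name))
  reads <- rep(names(read_to_mirna), lengths(read_to_mirna))
  mirs <- unlist(read_to_mirna, use.names = FALSE)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(paste0("r\r", unique(reads)),
                       paste0("m\r", mirnas$name)))
  if (length(reads) > 0) {
    g <- igraph::add_edges(
      g, rbind(paste0("r\r", reads), paste0("m\r", mirs)))
  }
  comp <- igraph::components(g)$membership
  is_mir <- startsWith(names(comp), "m\r")
  mir_comp <- comp[is_mir]
  names(mir_comp) <- sub("^m\r", "", names(mir_comp))
  sets <- split(names(mir_comp), mir_comp)
  read_comp <- comp[!is_mir]
  nr <- table(read_comp)
  n_reads <- as.integer(nr[names(sets)])
  n_reads[is.na(n_reads)] <- 0L
  loci <- data.frame(mirna_name = character(), genome_label = character(),
                     chrom = character(), start = integer(), end = integer(),
                     strand = character(), n_diff = integer(),
                     mode = character(), stringsAsFactors = FALSE)
  finalize_clusters(mirnas, loci, sets, cross_mappable = cross_mappable,
                    n_reads = n_reads)
}

#' Type-A counts under a sweep of allowed mismatches
#'
#' Re-runs gap-free mapping and clustering at each allowed-mismatch value
#' and counts Type-A clusters per species. Raising the allowed mismatches
#' can only shrink the Type-A set: placements found at `k` are still found
#' at `k + 1`.
#'
#' @param mirnas Data frame from [mirna_set()].
#' @param genomes List of [genome_seq()] objects.
#' @param k_values Integer vector of allowed mismatches (default `0:3`).
#' @param min_overlap Cluster merge threshold.
#' @return Data frame with columns `k`, `typeA_mouse`, `typeA_human`,
#'   `n_clusters`.
#' @export
sweep_typeA_counts <- function(mirnas, genomes, k_values = 0:3,
                               min_overlap = 0.9) {
  queries <- stats::setNames(mirnas$sequence, mirnas$name)
  res <- lapply(k_values, function(k) {
    loci <- do.call(rbind, lapply(genomes, function(g) {
      map_queries(queries, g, "mismatch", k)
    }))
    names(loci)[names(loci) == "query_id"] <- "mirna_name"
    cs <- build_clusters(mirnas, loci, min_overlap)
    data.frame(k = k,
               typeA_mouse = sum(cs$clusters$type == "typeA_mouse"),
               typeA_human = sum(cs$clusters$type == "typeA_human"),
               n_clusters = nrow(cs$clusters))
  })
  do.call(rbind, res)
}

#' Write a cluster table as TSV (plus per-genome BED of cluster intervals)
#'
#' @param cluster_set A `mirna_cluster_set`.
#' @param path Output TSV path.
#' @param bed_dir Optional directory for per-genome BED files of reduced
#'   cluster intervals.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cluster_set, path, bed_dir = NULL) {
  cl <- cluster_set$clusters
  out <- data.frame(cluster_id = cl$cluster_id, name = cl$name,
                    type = cl$type, n_mouse = cl$n_mouse,
                    n_human = cl$n_human,
                    members_mouse = vapply(cl$members_mouse, paste,
                                           character(1), collapse = ","),
                    members_human = vapply(cl$members_human, paste,
                                           character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_dir)) {
    iv <- cluster_set$intervals
    for (gl in unique(iv$genome_label)) {
      sub <- iv[iv$genome_label == gl, ]
      bed <- data.frame(sub$chrom, sub$start, sub$end, sub$cluster_id, 0L,
                        sub$strand)
      utils::write.table(bed, file.path(bed_dir,
                                        paste0("clusters_", gl, ".bed")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}
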