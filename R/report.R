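#' Order-statistic summary of per-sample values by group
#'
#' Exact median / min / max per group; the median of an even-sized group is
#' the mean of the central pair. Values are stored as fractions; percent
#' formatting is left to the presentation layer.
#'
#' @param values Numeric vector (e.g. per-sample mixing ratios or marker
#'   RPM sums).
#' @param groups Grouping vector of the same length.
#' @return Data frame with columns `group`, `n`, `median`, `min`, `max`.
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (length(values) == 0) stop("no values to summarize")
  if (anyNA(values)) stop("values contain NA")
  sp <- split(values, groups)
  out <- data.frame(
    group = names(sp),
    n = lengths(sp),
    median = vapply(sp, stats::median, numeric(1)),
    min = vapply(sp, min, numeric(1)),
    max = vapply(sp, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

write_atomic <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

default_thresholds <- function() {
  list(min_overlap = 0.9, k_read = 2L, min_feeder_rpm = 10,
       max_clean_rpm = 1, typeA_min_rpm = 1, influenced_fold = 10,
       eps = 0.1, rpm_flag_threshold = 1, mrna_k = 2L)
}

#' Run the end-to-end synthetic contamination pipeline
#'
#' Orchestrates: fixture generation, hit discovery and clustering
#' (miRNA mode) or dual-genome partitioning (mRNA mode), per-sample
#' quantification, marker calling and contamination assessment, group
#' summaries, and report/manifest output. All outputs are written
#' atomically; the JSON report is a pure function of the written tables.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `seed`: integer;
#'   * `mode`: `"mirna"` or `"mrna"`;
#'   * `sim`: named list of [sim_config()] overrides;
#'   * `samples`: data frame (or list of lists) with columns `sample_id`,
#'     `condition` (one of `feeder`, `feeder_free_hESC`, `query`), `phi`,
#'     `n_reads` and optional `group`;
#'   * `thresholds`: named list overriding the defaults (fold/RPM/overlap
#'     parameters).
#' @param out_dir Output directory.
#' @return The report list, invisibly. Side effects: TSV tables,
#'   `report.json`, `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is required")
  mode <- match.arg(config$mode %||% "mirna", c("mirna", "mrna"))
  samples <- config$samples
  if (!is.data.frame(samples)) {
    samples <- do.call(rbind, lapply(samples, function(s)
      as.data.frame(s, stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("sample_id", "condition", "phi", "n_reads") %in%
                  names(samples)))
  if (is.null(samples$group)) samples$group <- samples$condition
  th <- utils::modifyList(default_thresholds(), config$thresholds %||%
                            list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- do.call(sim_config, c(list(seed = config$seed),
                               config$sim %||% list()))
  fixture <- generate_genomes_and_annotation(cfg)

  report <- list(mode = mode, seed = config$seed)
  if (mode == "mirna") {
    loci <- locate_mirnas(fixture$mirnas, fixture$genomes)
    clusters <- build_clusters(fixture$mirnas, loci,
                               min_overlap = th$min_overlap)
    write_atomic(function(p) write_cluster_table(clusters, p),
                 file.path(out_dir, "clusters.tsv"))
    results <- lapply(seq_len(nrow(samples)), function(i) {
      sim <- simulate_small_reads(fixture, samples$n_reads[i],
                                  phi = samples$phi[i],
                                  seed = cfg$seed + i)
      assign_reads(sim$reads, clusters, fixture$genomes, k = th$k_read,
                   min_read_overlap = th$min_overlap)
    })
    names(results) <- samples$sample_id
    tab <- cluster_count_table(results)
    rpm <- normalize_rpm(tab)
    write_atomic(function(p) utils::write.table(
      data.frame(cluster_id = rownames(tab$counts), tab$counts,
                 check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out_dir, "counts.tsv"))
    write_atomic(function(p) utils::write.table(
      data.frame(cluster_id = rownames(rpm), rpm, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out_dir, "rpm.tsv"))
    feeder <- samples$sample_id[samples$condition == "feeder"]
    clean <- samples$sample_id[samples$condition == "feeder_free_hESC"]
    markers <- identify_marker_mirnas(rpm, feeder, clean, clusters,
                                      min_feeder_rpm = th$min_feeder_rpm,
                                      max_clean_rpm = th$max_clean_rpm,
                                      typeA_min_rpm = th$typeA_min_rpm)
    influenced <- identify_influenced_mirnas(rpm, feeder, clean, clusters,
                                             fold = th$influenced_fold,
                                             eps = th$eps)
    write_atomic(function(p) utils::write.table(
      as.data.frame(markers), p, sep = "\t", quote = FALSE,
      row.names = FALSE), file.path(out_dir, "markers.tsv"))
    write_atomic(function(p) utils::write.table(
      influenced, p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out_dir, "influenced.tsv"))
    qidx <- which(samples$condition == "query")
    per_sample <- lapply(qidx, function(i) {
      sid <- samples$sample_id[i]
      a <- assess_contamination(results[[sid]]$counts, rpm[, sid],
                                markers, th$rpm_flag_threshold)
      list(sample_id = sid, group = samples$group[i],
           phi = samples$phi[i], flag = a$flag,
           typeA_detected = a$typeA_detected,
           marker_rpm = a$total_marker_rpm)
    })
    report$n_clusters <- nrow(clusters$clusters)
    report$cluster_types <- as.list(table(clusters$clusters$type))
    report$n_markers <- nrow(markers)
    report$n_influenced <- nrow(influenced)
    report$samples <- per_sample
    if (length(per_sample) > 0) {
      report$groups <- summarize_groups(
        vapply(per_sample, `[[`, numeric(1), "marker_rpm"),
        vapply(per_sample, `[[`, character(1), "group"))
    }
  } else {
    rows <- lapply(seq_len(nrow(samples)), function(i) {
      sim <- simulate_mrna_reads(fixture, samples$n_reads[i],
                                 phi = samples$phi[i], seed = cfg$seed + i)
      ah <- align_with_builtin(sim$reads, fixture$genomes$human,
                               "diff", th$mrna_k)
      am <- align_with_builtin(sim$reads, fixture$genomes$mouse,
                               "diff", th$mrna_k)
      part <- partition_reads(ah, am)
      c(list(sample_id = samples$sample_id[i],
             group = samples$group[i], phi = samples$phi[i],
             mixing_ratio = mixing_ratio(part)),
        as.list(part$counts))
    })
    ptab <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    write_atomic(function(p) utils::write.table(
      ptab, p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(out_dir, "partition.tsv"))
    report$samples <- rows
    report$groups <- summarize_groups(ptab$mixing_ratio, ptab$group)
  }

  manifest <- list(tool = "feederscan",
                   version = as.character(utils::packageVersion("feederscan")),
                   seed = config$seed, mode = mode,
                   sim_config = unclass(cfg), thresholds = th,
                   samples = samples)
  write_atomic(function(p) jsonlite::write_json(
    report, p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(out_dir, "report.json"))
  write_atomic(function(p) jsonlite::write_json(
    manifest, p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(out_dir, "manifest.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
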