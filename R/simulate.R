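#' Simulation configuration
#'
#' Defines the synthetic two-species study conditions: genome sizes, the
#' number of planted conserved / Type-A / Type-B miRNA loci, divergence of
#' conserved copies, gene models, read parameters, and the contamination
#' fraction. Locus abundances follow a log-uniform model over `[1, 100]`.
#'
#' @param seed Integer seed; a fixed seed makes all generated files
#'   byte-identical across runs.
#' @param genome_size Genome size per species in bp (default 200000).
#' @param n_conserved Number of conserved miRNA locus pairs (default 10).
#' @param n_typeA,n_typeB Species-specific loci per species (default 5 + 5).
#' @param conserved_divergence Substitutions separating the two copies of a
#'   conserved locus; recycled over conserved loci (default 1, range 0-3).
#' @param n_genes Genes per species (default 20).
#' @param mirna_len Mature miRNA length (default 22).
#' @param read_length mRNA-Seq read length (default 75).
#' @param mrna_error_rate,small_error_rate Per-base substitution error rates
#'   (default 0.005).
#' @param phi Contamination fraction: probability a read originates from the
#'   mouse (feeder) genome (default 0.05).
#' @param end_trim_max Maximum random 3' trimming of small reads, modelling
#'   isomiR length variation (default 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_size = 200000L, n_conserved = 10L,
                       n_typeA = 5L, n_typeB = 5L, conserved_divergence = 1L,
                       n_genes = 20L, mirna_len = 22L, read_length = 75L,
                       mrna_error_rate = 0.005, small_error_rate = 0.005,
                       phi = 0.05, end_trim_max = 2L) {
  stopifnot(genome_size >= 20000, n_conserved >= 0, n_typeA >= 0,
            n_typeB >= 0, n_genes >= 0, phi >= 0, phi <= 1,
            all(conserved_divergence >= 0), all(conserved_divergence <= 3))
  structure(list(seed = as.integer(seed),
                 genome_size = as.integer(genome_size),
                 n_conserved = as.integer(n_conserved),
                 n_typeA = as.integer(n_typeA),
                 n_typeB = as.integer(n_typeB),
                 conserved_divergence = as.integer(conserved_divergence),
                 n_genes = as.integer(n_genes),
                 mirna_len = as.integer(mirna_len),
                 read_length = as.integer(read_length),
                 mrna_error_rate = mrna_error_rate,
                 small_error_rate = small_error_rate,
                 phi = phi,
                 end_trim_max = as.integer(end_trim_max)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_subs <- function(seq, n_subs) {
  if (n_subs == 0) return(seq)
  ch <- strsplit(seq, NULL)[[1]]
  pos <- sample(length(ch), n_subs)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

replace_at <- function(genome_str, start0, piece) {
  paste0(substring(genome_str, 1, start0),
         piece,
         substring(genome_str, start0 + nchar(piece) + 1))
}

#' Generate two synthetic genomes with planted miRNA loci and gene models
#'
#' Backgrounds are independent uniform-random DNA, so the two genomes are
#' effectively fully divergent except where sequence is planted:
#'
#' * conserved pairs: a mouse copy and a human copy separated by
#'   `conserved_divergence` substitutions, each annotated in its species;
#' * Type-B loci: an identical copy planted in both genomes, annotated as a
#'   miRNA in one species only;
#' * Type-A loci: planted in one genome and verified unmappable in the
#'   other under the pipeline's mapper thresholds (violating sequences are
#'   regenerated, so Type-A status is enforced, not assumed).
#'
#' Genes are non-overlapping multi-exon intervals in a genome region
#' disjoint from the miRNA slots. Per-locus abundances (log-uniform over
#' `[1, 100]`) are drawn here so that all samples simulated from the
#' fixture share one expression profile per species.
#'
#' @param cfg A [sim_config()].
#' @param mapper_cfg [mapper_config()] thresholds used for the Type-A
#'   unmappability check.
#' @param max_retries Retries for the Type-A check before giving up.
#' @return Object of class `sim_fixture`: list with `genomes` (human and
#'   mouse [genome_seq()]), `mirnas`, `mirna_loci` (planted truth),
#'   `genes` (per-species [gene_models()]), `abundances`,
#'   `gene_abundances`, and `cfg`.
#' @export
generate_genomes_and_annotation <- function(cfg,
                                            mapper_cfg = mapper_config(),
                                            max_retries = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$genome_size
  mlen <- cfg$mirna_len
  species <- c("human", "mouse")
  prefix <- c(human = "hsa", mouse = "mmu")

  divs <- rep(cfg$conserved_divergence, length.out = cfg$n_conserved)
  # draw planted sequences
  cons_base <- replicate(cfg$n_conserved, random_dna(mlen))
  cons_var <- list(mouse = cons_base,
                   human = vapply(seq_len(cfg$n_conserved), function(i) {
                     mutate_subs(cons_base[i], divs[i])
                   }, character(1)))
  typeA <- lapply(stats::setNames(species, species), function(s)
    as.character(replicate(cfg$n_typeA, random_dna(mlen))))
  typeB <- lapply(stats::setNames(species, species), function(s)
    as.character(replicate(cfg$n_typeB, random_dna(mlen))))

  # slot layout: miRNA plants live in the upper 45% of each genome,
  # genes in the lower 45%; the two never interact
  n_slots <- cfg$n_conserved + cfg$n_typeA + 2L * cfg$n_typeB
  slot_starts <- function() {
    lo <- floor(0.55 * S)
    span <- S - lo - mlen - 10L
    as.integer(lo + round(seq_len(n_slots) * span / (n_slots + 1)))
  }
  genomes_str <- list(human = random_dna(S), mouse = random_dna(S))
  slots <- list(human = slot_starts(), mouse = slot_starts())
  strands <- list(human = sample(c("+", "-"), n_slots, replace = TRUE),
                  mouse = sample(c("+", "-"), n_slots, replace = TRUE))

  # plant order within each genome: conserved variant, own Type-A,
  # own Type-B, cross-species Type-B copies
  plant_plan <- function(s) {
    other <- setdiff(species, s)
    data.frame(
      seq_role = c(rep("conserved", cfg$n_conserved),
                   rep("typeA", cfg$n_typeA),
                   rep("typeB", cfg$n_typeB),
                   rep("typeB_copy", cfg$n_typeB)),
      idx = c(seq_len(cfg$n_conserved), seq_len(cfg$n_typeA),
              seq_len(cfg$n_typeB), seq_len(cfg$n_typeB)),
      owner = c(rep(s, cfg$n_conserved + cfg$n_typeA + cfg$n_typeB),
                rep(other, cfg$n_typeB)),
      stringsAsFactors = FALSE)
  }
  get_seq <- function(plan_row, s) {
    switch(plan_row$seq_role,
           conserved = cons_var[[s]][plan_row$idx],
           typeA = typeA[[s]][plan_row$idx],
           typeB = typeB[[plan_row$owner]][plan_row$idx],
           typeB_copy = typeB[[plan_row$owner]][plan_row$idx])
  }
  plant_all <- function() {
    for (s in species) {
      plan <- plant_plan(s)
      for (i in seq_len(nrow(plan))) {
        piece <- get_seq(plan[i, ], s)
        if (strands[[s]][i] == "-") piece <- revcomp(piece)
        genomes_str[[s]] <<- replace_at(genomes_str[[s]], slots[[s]][i],
                                        piece)
      }
    }
  }
  plant_all()

  # enforce Type-A unmappability in the other genome under both regimes
  if (cfg$n_typeA > 0) {
    for (iter in seq_len(max_retries)) {
      bad <- FALSE
      for (s in species) {
        other <- setdiff(species, s)
        g_other <- genome_seq(c(chr1 = genomes_str[[other]]), other)
        qs <- stats::setNames(typeA[[s]], paste0("a", seq_along(typeA[[s]])))
        h <- union_hits(
          map_queries(qs, g_other, "diff", mapper_cfg$max_diff),
          map_queries(qs, g_other, "mismatch", mapper_cfg$max_mismatch))
        if (nrow(h) > 0) {
          bad <- TRUE
          viol <- unique(as.integer(sub("^a", "", h$query_id)))
          for (v in viol) typeA[[s]][v] <- random_dna(mlen)
        }
      }
      if (!bad) break
      plant_all()
      if (iter == max_retries) {
        stop("could not satisfy Type-A unmappability after ", max_retries,
             " retries")
      }
    }
  }

  # annotation tables
  mk_names <- function(s) {
    c(sprintf("%s-miR-simC%d", prefix[[s]], seq_len(cfg$n_conserved)),
      sprintf("%s-miR-simA%d", prefix[[s]], seq_len(cfg$n_typeA)),
      sprintf("%s-miR-simB%d", prefix[[s]], seq_len(cfg$n_typeB)))
  }
  mirnas <- do.call(rbind, lapply(species, function(s) {
    data.frame(name = mk_names(s), species = s,
               sequence = c(cons_var[[s]], typeA[[s]], typeB[[s]]),
               stringsAsFactors = FALSE)
  }))
  rownames(mirnas) <- NULL

  loci <- do.call(rbind, lapply(species, function(s) {
    plan <- plant_plan(s)
    other <- setdiff(species, s)
    owner_prefix <- prefix[plan$owner]
    nm <- ifelse(plan$seq_role == "conserved",
                 sprintf("%s-miR-simC%d", prefix[[s]], plan$idx),
          ifelse(plan$seq_role == "typeA",
                 sprintf("%s-miR-simA%d", prefix[[s]], plan$idx),
                 sprintf("%s-miR-simB%d", owner_prefix, plan$idx)))
    data.frame(mirna_name = nm, genome_label = s, chrom = "chr1",
               start = slots[[s]], end = slots[[s]] + cfg$mirna_len,
               strand = strands[[s]],
               planted_type = sub("_copy$", "", plan$seq_role),
               annotated = plan$seq_role != "typeB_copy",
               divergence = ifelse(plan$seq_role == "conserved",
                                   divs[plan$idx], 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL

  # gene models: non-overlapping multi-exon genes in [1000, 0.45 * S)
  genes <- lapply(stats::setNames(species, species), function(s) {
    if (cfg$n_genes == 0) return(NULL)
    pos <- 1000L
    rows <- list()
    for (gi in seq_len(cfg$n_genes)) {
      n_ex <- sample(2:3, 1)
      gene_id <- sprintf("%s_gene%03d", prefix[[s]], gi)
      strand <- sample(c("+", "-"), 1)
      for (e in seq_len(n_ex)) {
        elen <- sample(150:400, 1)
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gene_id, chrom = "chr1", strand = strand,
          start = pos, end = pos + elen, stringsAsFactors = FALSE)
        pos <- pos + elen + sample(100:300, 1)
      }
      pos <- pos + sample(200:800, 1)
    }
    df <- do.call(rbind, rows)
    if (max(df$end) >= floor(0.45 * S)) {
      stop("gene region overflow; increase genome_size or reduce n_genes")
    }
    gene_models(df, s)
  })

  abundances <- stats::setNames(10 ^ runif(nrow(mirnas), 0, 2),
                                mirnas$name)
  gene_ids <- unlist(lapply(genes, function(g)
    if (is.null(g)) character() else unique(g$exons$gene_id)),
    use.names = FALSE)
  gene_abundances <- stats::setNames(10 ^ runif(length(gene_ids), 0, 2),
                                     gene_ids)

  structure(list(
    genomes = list(human = genome_seq(c(chr1 = genomes_str$human), "human"),
                   mouse = genome_seq(c(chr1 = genomes_str$mouse), "mouse")),
    mirnas = mirnas, mirna_loci = loci, genes = genes,
    abundances = abundances, gene_abundances = gene_abundances,
    cfg = cfg), class = "sim_fixture")
}

#' @export
print.sim_fixture <- function(x, ...) {
  cat("<sim_fixture>", x$cfg$genome_size, "bp/genome;",
      nrow(x$mirnas), "annotated miRNAs;",
      sum(x$mirna_loci$planted_type == "conserved" & x$mirna_loci$annotated),
      "conserved loci\n")
  invisible(x)
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(seqs[i], NULL)[[1]]
    pos <- sample(lens[i], n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate small-RNA reads from a synthetic fixture
#'
#' Each read's species of origin is Bernoulli(`phi`) (mouse with
#' probability `phi`); its source miRNA is drawn from that species'
#' annotated miRNAs with probability proportional to the fixture's
#' abundances. Reads are the mature sequence with random 3' trimming of up
#' to `end_trim_max` nt (isomiR length variation), substitution errors at
#' `error_rate`, and optional adapters.
#'
#' @param fixture A [generate_genomes_and_annotation()] result.
#' @param n_reads Number of reads.
#' @param phi Contamination fraction (default from the fixture config).
#' @param error_rate Per-base substitution rate (default from config).
#' @param adapter3,adapter5 Adapters to append/prepend (default none).
#' @param seed RNG seed for this sample (default the fixture seed).
#' @param read_prefix Prefix for read ids.
#' @return List with `reads` (data frame `read_id`, `sequence`) and `truth`
#'   (`read_id`, `species`, `source`).
#' @export
simulate_small_reads <- function(fixture, n_reads, phi = NULL,
                                 error_rate = NULL, adapter3 = "",
                                 adapter5 = "", seed = NULL,
                                 read_prefix = "sr") {
  stopifnot(inherits(fixture, "sim_fixture"))
  cfg <- fixture$cfg
  if (is.null(phi)) phi <- cfg$phi
  if (is.null(error_rate)) error_rate <- cfg$small_error_rate
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  mir <- fixture$mirnas
  is_mouse <- stats::runif(n_reads) < phi
  src <- character(n_reads)
  for (s in c("human", "mouse")) {
    pick <- if (s == "mouse") is_mouse else !is_mouse
    if (!any(pick)) next
    pool <- mir$name[mir$species == s]
    w <- fixture$abundances[pool]
    src[pick] <- sample(pool, sum(pick), replace = TRUE, prob = w / sum(w))
  }
  seqs <- mir$sequence[match(src, mir$name)]
  t3 <- sample(0:cfg$end_trim_max, n_reads, replace = TRUE)
  seqs <- substring(seqs, 1L, nchar(seqs) - t3)
  seqs <- inject_errors(seqs, error_rate)
  if (nzchar(adapter3)) seqs <- paste0(seqs, adapter3)
  if (nzchar(adapter5)) seqs <- paste0(adapter5, seqs)
  ids <- sprintf("%s%07d", read_prefix, seq_len(n_reads))
  list(reads = data.frame(read_id = ids, sequence = seqs,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids,
                          species = ifelse(is_mouse, "mouse", "human"),
                          source = src, stringsAsFactors = FALSE))
}

#' Simulate mRNA-Seq reads from a synthetic fixture
#'
#' Each read's species is Bernoulli(`phi`); a gene is drawn with
#' probability proportional to the fixture's gene abundances; the read is a
#' `read_length`-mer sampled uniformly among positions fully inside one of
#' the gene's exons, from a random strand, with substitution errors.
#'
#' @inheritParams simulate_small_reads
#' @param read_length Read length (default from config).
#' @return List with `reads` and `truth` (`read_id`, `species`, `source`).
#' @export
simulate_mrna_reads <- function(fixture, n_reads, phi = NULL,
                                error_rate = NULL, read_length = NULL,
                                seed = NULL, read_prefix = "mr") {
  stopifnot(inherits(fixture, "sim_fixture"))
  cfg <- fixture$cfg
  if (is.null(phi)) phi <- cfg$phi
  if (is.null(error_rate)) error_rate <- cfg$mrna_error_rate
  if (is.null(read_length)) read_length <- cfg$read_length
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(fixture$genes$human)) {
    stop("fixture has no gene models (n_genes = 0)")
  }
  set.seed(seed)
  is_mouse <- stats::runif(n_reads) < phi
  src <- character(n_reads)
  starts <- integer(n_reads)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  for (s in c("human", "mouse")) {
    pick <- which(if (s == "mouse") is_mouse else !is_mouse)
    if (length(pick) == 0) next
    ex <- fixture$genes[[s]]$exons
    ex <- ex[ex$end - ex$start >= read_length, , drop = FALSE]
    gene_ids <- unique(ex$gene_id)
    w <- fixture$gene_abundances[gene_ids]
    gsel <- sample(gene_ids, length(pick), replace = TRUE,
                   prob = w / sum(w))
    src[pick] <- gsel
    # choose an exon of the gene weighted by eligible start positions,
    # then a uniform start within it
    for (g in unique(gsel)) {
      ridx <- pick[gsel == g]
      exg <- ex[ex$gene_id == g, , drop = FALSE]
      npos <- exg$end - exg$start - read_length + 1L
      esel <- sample.int(nrow(exg), length(ridx), replace = TRUE,
                         prob = npos)
      starts[ridx] <- exg$start[esel] +
        floor(stats::runif(length(ridx)) * npos[esel])
    }
  }
  seqs <- character(n_reads)
  for (s in c("human", "mouse")) {
    pick <- which(if (s == "mouse") is_mouse else !is_mouse)
    if (length(pick) == 0) next
    gstr <- fixture$genomes[[s]]$seqs[["chr1"]]
    seqs[pick] <- substring(gstr, starts[pick] + 1L,
                            starts[pick] + read_length)
  }
  neg <- strands == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  seqs <- inject_errors(seqs, error_rate)
  ids <- sprintf("%s%07d", read_prefix, seq_len(n_reads))
  list(reads = data.frame(read_id = ids, sequence = seqs,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids,
                          species = ifelse(is_mouse, "mouse", "human"),
                          source = src, start = starts,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic fixture to disk
#'
#' Emits the two genome FASTAs, the mature-miRNA FASTA, per-species gene
#' GTFs and the planted-locus / abundance truth TSVs, all as deterministic
#' plain text.
#'
#' @param fixture A `sim_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(fixture$genomes)) {
    write_genome_fasta(fixture$genomes[[s]],
                       file.path(dir, paste0("genome_", s, ".fa")))
  }
  con <- file(file.path(dir, "mirnas.fa"), "w")
  writeLines(paste0(">", fixture$mirnas$name, "\n", fixture$mirnas$sequence),
             con)
  close(con)
  for (s in names(fixture$genes)) {
    if (is.null(fixture$genes[[s]])) next
    ex <- fixture$genes[[s]]$exons
    gtf <- sprintf(
      "%s\tfeederscan_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
      ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$gene_id)
    writeLines(gtf, file.path(dir, paste0("genes_", s, ".gtf")))
  }
  utils::write.table(fixture$mirna_loci, file.path(dir, "mirna_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- data.frame(name = names(fixture$abundances),
                   abundance = unname(fixture$abundances))
  utils::write.table(ab, file.path(dir, "abundances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
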