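# A tiny hand-built two-genome world used by several tests:
#   - mmu-miR-x / hsa-miR-y: same locus on the human genome (conserved)
#   - mmu-miR-b: planted in both genomes, annotated in mouse only (Type-B)
#   - mmu-miR-a: planted in the mouse genome only (Type-A)
tiny_world <- function(seed = 51, div = 1) {
  set.seed(seed)
  hseq <- random_dna_str(6000)
  mseq <- random_dna_str(6000)
  cons <- random_dna_str(22)
  cons_m <- mutate_positions(cons, div)
  typeb <- random_dna_str(22)
  typea <- random_dna_str(22)
  hseq <- plant_seq(hseq, 1000, cons)
  hseq <- plant_seq(hseq, 3000, typeb)
  mseq <- plant_seq(mseq, 1500, cons_m)
  mseq <- plant_seq(mseq, 3500, typeb)
  mseq <- plant_seq(mseq, 5000, typea)
  list(genomes = list(human = genome_seq(c(chr1 = hseq), "human"),
                      mouse = genome_seq(c(chr1 = mseq), "mouse")),
       mirnas = mirna_set(
         c("hsa-miR-y", "mmu-miR-x", "mmu-miR-b", "mmu-miR-a"),
         c(cons, cons_m, typeb, typea)))
}

test_that("locate_mirnas merges both regimes against both genomes", {
  w <- tiny_world()
  loci <- locate_mirnas(w$mirnas, w$genomes)
  by_mir <- split(loci$genome_label, loci$mirna_name)
  expect_setequal(unique(by_mir[["mmu-miR-a"]]), "mouse")
  expect_setequal(unique(by_mir[["mmu-miR-b"]]), c("human", "mouse"))
  expect_setequal(unique(by_mir[["mmu-miR-x"]]), c("human", "mouse"))
  # conserved copy is found at the planted human position
  hx <- loci[loci$mirna_name == "mmu-miR-x" &
               loci$genome_label == "human", ]
  expect_true(any(hx$start >= 998 & hx$start <= 1002))
})

test_that("a 3-substitution placement is contributed by mismatch mode only", {
  w <- tiny_world(seed = 52, div = 3)
  qs <- stats::setNames(w$mirnas$sequence, w$mirnas$name)
  hd <- map_queries(qs, w$genomes$human, "diff", 2)
  hm <- map_queries(qs, w$genomes$human, "mismatch", 3)
  at_cons <- function(h) any(h$query_id == "mmu-miR-x" & h$start >= 995 &
                               h$start <= 1005)
  expect_false(at_cons(hd))
  expect_true(at_cons(hm))
  loci <- locate_mirnas(w$mirnas, w$genomes)
  expect_true(at_cons(stats::setNames(loci,
                                      sub("mirna_name", "query_id",
                                          names(loci)))))
})

test_that("overlap_fraction handles identity, disjoint and partial cases", {
  expect_equal(overlap_fraction(0, 22, 0, 22), 1.0)
  expect_equal(overlap_fraction(0, 22, 100, 122), 0.0)
  expect_equal(overlap_fraction(0, 22, 2, 24), 20 / 22)
  # shorter-interval denominator vs reciprocal
  expect_equal(overlap_fraction(0, 10, 0, 100), 1.0)
  expect_equal(overlap_fraction(0, 10, 0, 100, denominator = "reciprocal"),
               0.1)
  expect_equal(overlap_fraction(c(0, 5), c(10, 15), c(5, 5), c(15, 15)),
               c(0.5, 1))
})

test_that("clusters are single-linkage components over >90% locus overlap", {
  mirs <- mirna_set(c("mmu-miR-A", "mmu-miR-B", "hsa-miR-C"),
                    c(strrep("A", 22), strrep("C", 22), strrep("G", 22)))
  loc <- function(nm, gl, s, e, strand = "+") {
    data.frame(mirna_name = nm, genome_label = gl, chrom = "chr1",
               start = s, end = e, strand = strand, n_diff = 0L,
               mode = "diff", stringsAsFactors = FALSE)
  }
  # chain: A-B overlap 95%, B-C overlap 95%, A-C overlap ~0
  loci <- rbind(loc("mmu-miR-A", "human", 0, 22),
                loc("mmu-miR-B", "human", 1, 23),
                loc("hsa-miR-C", "human", 2, 24))
  cs <- build_clusters(mirs, loci)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$type, "conserved")
  expect_equal(cs$clusters$name,
               "mmu-miR-A/mmu-miR-B__hsa-miR-C")
  # no overlap -> singletons; opposite strands never merge
  loci2 <- rbind(loc("mmu-miR-A", "human", 0, 22),
                 loc("mmu-miR-B", "human", 100, 122),
                 loc("hsa-miR-C", "human", 100, 122, strand = "-"))
  cs2 <- build_clusters(mirs, loci2)
  expect_equal(nrow(cs2$clusters), 3L)
  # exactly-90% overlap does not merge (strict >)
  loci3 <- rbind(loc("mmu-miR-A", "human", 0, 20),
                 loc("mmu-miR-B", "human", 2, 22))
  cs3 <- build_clusters(mirs[1:2, ], loci3)
  expect_equal(nrow(cs3$clusters), 2L)
})

test_that("classification distinguishes conserved, Type-A and Type-B", {
  expect_equal(classify_cluster("mmu-miR-1", "hsa-miR-2", c("human",
                                                            "mouse")),
               "conserved")
  expect_equal(classify_cluster("mmu-miR-1", character(), "mouse"),
               "typeA_mouse")
  expect_equal(classify_cluster("mmu-miR-1", character(),
                                c("mouse", "human")), "typeB_mouse")
  expect_equal(classify_cluster(character(), "hsa-miR-1", "human"),
               "typeA_human")
  expect_equal(classify_cluster(character(), "hsa-miR-1",
                                c("human", "mouse")), "typeB_human")
  expect_error(classify_cluster(character(), character(), character()),
               "no members")
})

test_that("cluster names join sorted members with NA for empty sides", {
  expect_equal(name_cluster(c("mmu-miR-B", "mmu-miR-A"),
                            c("hsa-miR-D", "hsa-miR-C")),
               "mmu-miR-A/mmu-miR-B__hsa-miR-C/hsa-miR-D")
  expect_equal(name_cluster("mmu-miR-A", character()), "mmu-miR-A__NA")
  expect_equal(name_cluster(character(), "hsa-miR-X"), "NA__hsa-miR-X")
})

test_that("tiny world recovers every planted cluster type", {
  w <- tiny_world()
  loci <- locate_mirnas(w$mirnas, w$genomes)
  cs <- build_clusters(w$mirnas, loci)
  expect_equal(nrow(cs$clusters), 3L)
  types <- stats::setNames(cs$clusters$type, cs$clusters$name)
  expect_equal(types[["mmu-miR-x__hsa-miR-y"]], "conserved")
  expect_equal(types[["mmu-miR-b__NA"]], "typeB_mouse")
  expect_equal(types[["mmu-miR-a__NA"]], "typeA_mouse")
})

test_that("clustering is a partition, idempotent and order-invariant", {
  fx <- generate_genomes_and_annotation(
    sim_config(seed = 53, genome_size = 50000, n_genes = 0,
               n_conserved = 4, n_typeA = 2, n_typeB = 2))
  loci <- locate_mirnas(fx$mirnas, fx$genomes)
  cs <- build_clusters(fx$mirnas, loci)
  members <- c(unlist(cs$clusters$members_mouse),
               unlist(cs$clusters$members_human))
  expect_setequal(members, fx$mirnas$name)
  expect_equal(anyDuplicated(members), 0L)
  # permuting input rows changes nothing
  set.seed(54)
  perm_m <- fx$mirnas[sample(nrow(fx$mirnas)), ]
  perm_l <- loci[sample(nrow(loci)), ]
  cs2 <- build_clusters(perm_m, perm_l)
  expect_equal(cs$clusters$name, cs2$clusters$name)
  expect_equal(cs$clusters$type, cs2$clusters$type)
})

test_that("lowering the overlap threshold never increases cluster count", {
  fx <- generate_genomes_and_annotation(
    sim_config(seed = 55, genome_size = 50000, n_genes = 0))
  loci <- locate_mirnas(fx$mirnas, fx$genomes)
  prev <- Inf
  for (mo in c(0.95, 0.9, 0.5, 0.1)) {
    n <- nrow(build_clusters(fx$mirnas, loci, min_overlap = mo)$clusters)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("connected components match a union-find oracle", {
  set.seed(56)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    nms <- c(sprintf("mmu-miR-t%02d", seq_len(ceiling(n / 2))),
             sprintf("hsa-miR-t%02d", seq_len(floor(n / 2))))
    mirs <- mirna_set(nms, replicate(n, random_dna_str(22)))
    # random loci on a short axis so random overlaps arise
    loci <- data.frame(mirna_name = nms, genome_label = "human",
                       chrom = "chr1",
                       start = sample(0:60, n, replace = TRUE),
                       strand = "+", n_diff = 0L, mode = "diff",
                       stringsAsFactors = FALSE)
    loci$end <- loci$start + 22L
    cs <- build_clusters(mirs, loci, min_overlap = 0.9)
    # oracle: union-find over all >90% overlapping pairs
    edges <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      f <- overlap_fraction(loci$start[i], loci$end[i],
                            loci$start[j], loci$end[j])
      if (f > 0.9) edges <- rbind(edges, c(nms[i], nms[j]))
    }
    want <- canon_partition(oracle_components(nms, edges))
    got <- canon_partition(lapply(seq_len(nrow(cs$clusters)), function(i) {
      c(cs$clusters$members_mouse[[i]], cs$clusters$members_human[[i]])
    }))
    expect_equal(got, want)
  }
})

test_that("read-based refinement follows the shared-read example", {
  mirs <- mirna_set(
    c("mmu-miR-A", "mmu-miR-B", "mmu-miR-C", "hsa-miR-D", "hsa-miR-E"),
    replicate(5, random_dna_str(22)))
  cross <- stats::setNames(rep(TRUE, 5), mirs$name)
  r2m <- list(M = c("mmu-miR-A", "mmu-miR-B", "hsa-miR-D", "hsa-miR-E"),
              N = c("mmu-miR-B", "mmu-miR-C", "hsa-miR-D", "hsa-miR-E"))
  cs <- read_based_clusters(r2m, mirs, cross)
  cl <- cs$clusters[cs$clusters$n_reads > 0, ]
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$name,
               "mmu-miR-A/mmu-miR-B/mmu-miR-C__hsa-miR-D/hsa-miR-E")
  expect_equal(cl$type, "conserved")
  expect_equal(cl$n_reads, 2L)
  # disjoint reads give separate clusters; cross-mappability decides A vs B
  mirs2 <- mirna_set(c("mmu-miR-p", "mmu-miR-q"),
                     replicate(2, random_dna_str(22)))
  cs2 <- read_based_clusters(list(r1 = "mmu-miR-p", r2 = "mmu-miR-q"),
                             mirs2,
                             c("mmu-miR-p" = TRUE, "mmu-miR-q" = FALSE))
  tp <- stats::setNames(cs2$clusters$type, cs2$clusters$name)
  expect_equal(tp[["mmu-miR-p__NA"]], "typeB_mouse")
  expect_equal(tp[["mmu-miR-q__NA"]], "typeA_mouse")
})

test_that("read-based components match the union-find oracle on random graphs", {
  set.seed(57)
  for (rep in 1:10) {
    nm <- sprintf("mmu-miR-r%02d", 1:8)
    mirs <- mirna_set(nm, replicate(8, random_dna_str(22)))
    nreads <- sample(3:10, 1)
    r2m <- lapply(seq_len(nreads), function(i) {
      sample(nm, sample(1:3, 1))
    })
    names(r2m) <- paste0("read", seq_len(nreads))
    cs <- read_based_clusters(r2m, mirs,
                              stats::setNames(rep(FALSE, 8), nm))
    # oracle: union miRNAs co-hit by a read
    edges <- NULL
    for (ms in r2m) {
      if (length(ms) > 1) {
        edges <- rbind(edges, cbind(ms[-length(ms)], ms[-1]))
      }
    }
    want <- canon_partition(oracle_components(nm, edges))
    got <- canon_partition(lapply(seq_len(nrow(cs$clusters)), function(i) {
      c(cs$clusters$members_mouse[[i]], cs$clusters$members_human[[i]])
    }))
    expect_equal(got, want)
  }
})

test_that("raising allowed mismatches monotonically shrinks the Type-A set", {
  fx <- generate_genomes_and_annotation(
    sim_config(seed = 58, genome_size = 60000, n_genes = 0,
               n_conserved = 8, conserved_divergence = c(0, 1, 2, 3)))
  sw <- sweep_typeA_counts(fx$mirnas, fx$genomes, k_values = 0:3)
  expect_true(all(diff(sw$typeA_mouse) <= 0))
  expect_true(all(diff(sw$typeA_human) <= 0))
  # expected from planted truth: conserved pairs with divergence > k are
  # still unmappable cross-genome, so they count as Type-A at that k
  divs <- rep(c(0, 1, 2, 3), length.out = 8)
  for (i in seq_len(nrow(sw))) {
    k <- sw$k[i]
    expected <- fx$cfg$n_typeA + sum(divs > k)
    expect_equal(sw$typeA_mouse[i], expected)
    expect_equal(sw$typeA_human[i], expected)
  }
})
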