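quant_fixture <- function(seed = 61) {
  fx <- generate_genomes_and_annotation(
    sim_config(seed = seed, genome_size = 60000, n_genes = 0))
  loci <- locate_mirnas(fx$mirnas, fx$genomes)
  list(fx = fx, cs = build_clusters(fx$mirnas, loci))
}

test_that("adapter trimming recovers inserts and filters by length", {
  a3 <- "TGGAATTCTCGGGTGCCAAGG"
  a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  set.seed(62)
  ins <- random_dna_str(22)
  r <- suppressMessages(trim_and_filter(
    c(x1 = paste0(ins, a3)), adapter3 = a3))
  expect_equal(r$sequence, ins)
  # 5' + insert + 3'
  r2 <- suppressMessages(trim_and_filter(
    c(x2 = paste0(a5, ins, a3)), adapter3 = a3, adapter5 = a5))
  expect_equal(r2$sequence, ins)
  # partial 3' adapter at the read end still trims
  r3 <- suppressMessages(trim_and_filter(
    c(x3 = paste0(ins, substring(a3, 1, 6))), adapter3 = a3))
  expect_equal(r3$sequence, ins)
  # one mismatch in a 21-nt adapter is within the 10% error rate
  a3m <- paste0("A", substring(a3, 2))
  r4 <- suppressMessages(trim_and_filter(
    c(x4 = paste0(ins, a3m)), adapter3 = a3))
  expect_equal(r4$sequence, ins)
  # short inserts are dropped and counted
  short <- paste0(random_dna_str(12), a3)
  r5 <- suppressMessages(trim_and_filter(
    c(x5 = short, x6 = paste0(ins, a3)), adapter3 = a3))
  expect_equal(r5$read_id, "x6")
  expect_equal(attr(r5, "dropped")[["too_short"]], 1L)
  # overlong untrimmed reads are dropped too
  r6 <- suppressMessages(trim_and_filter(
    stats::setNames(random_dna_str(40), "x7")))
  expect_equal(nrow(r6), 0L)
  expect_equal(attr(r6, "dropped")[["too_long"]], 1L)
})

test_that("simulated adapters are removed from every error-free read", {
  q <- quant_fixture()
  a3 <- "TGGAATTCTCGGGTGCCAAGG"
  sim <- simulate_small_reads(q$fx, 300, phi = 0.5, error_rate = 0,
                              adapter3 = a3, seed = 63)
  tr <- suppressMessages(trim_and_filter(sim$reads, adapter3 = a3))
  expect_equal(nrow(tr), 300L)
  src_seq <- q$fx$mirnas$sequence[match(sim$truth$source,
                                        q$fx$mirnas$name)]
  expect_true(all(vapply(seq_len(300), function(i) {
    startsWith(src_seq[i], tr$sequence[i])
  }, logical(1))))
})

test_that("reads are assigned to the unique overlapping cluster", {
  q <- quant_fixture()
  mir <- q$fx$mirnas
  # one read per annotated miRNA, error-free
  reads <- data.frame(read_id = paste0("p", seq_len(nrow(mir))),
                      sequence = mir$sequence, stringsAsFactors = FALSE)
  res <- assign_reads(reads, q$cs, q$fx$genomes)
  expect_equal(res$n_mapped, nrow(mir))
  expect_equal(res$n_assigned, nrow(mir))
  # every cluster receives exactly its members' reads
  expect_equal(unname(res$counts[q$cs$clusters$cluster_id]),
               q$cs$clusters$n_mouse + q$cs$clusters$n_human)
  # a foreign sequence maps nowhere
  set.seed(64)
  res2 <- assign_reads(data.frame(read_id = "z",
                                  sequence = random_dna_str(22)),
                       q$cs, q$fx$genomes)
  expect_equal(res2$n_assigned, 0L)
})

test_that("per-cluster counts track a known abundance vector", {
  q <- quant_fixture()
  n <- 8000
  sim <- simulate_small_reads(q$fx, n, phi = 0, error_rate = 0, seed = 65)
  res <- assign_reads(sim$reads, q$cs, q$fx$genomes)
  expect_equal(res$n_assigned + res$n_tied, n)
  # expected multinomial proportions from the fixture abundances,
  # mapped through each source miRNA's cluster
  mir2cl <- stats::setNames(q$cs$loci$cluster_id, q$cs$loci$mirna_name)
  truth_cl <- mir2cl[sim$truth$source]
  ab <- q$fx$abundances
  hum <- q$fx$mirnas$name[q$fx$mirnas$species == "human"]
  p_mir <- ab[hum] / sum(ab[hum])
  p_cl <- tapply(p_mir, mir2cl[hum], sum)
  for (cl in names(p_cl)) {
    expe <- n * p_cl[[cl]]
    sd3 <- 3 * sqrt(n * p_cl[[cl]] * (1 - p_cl[[cl]]))
    expect_lt(abs(res$counts[[cl]] - expe), sd3 + 1)
  }
  # counts equal truth exactly for error-free reads
  tt <- table(truth_cl)
  expect_equal(res$counts[names(tt)], as.integer(tt), ignore_attr = TRUE)
})

test_that("isomiR-trimmed reads still meet the >90% overlap rule", {
  q <- quant_fixture()
  mir <- q$fx$mirnas[1, ]
  trimmed <- substring(mir$sequence, 1, 20)  # 20/22 = 0.909 > 0.9
  res <- assign_reads(data.frame(read_id = "t", sequence = trimmed),
                      q$cs, q$fx$genomes)
  cl <- q$cs$loci$cluster_id[q$cs$loci$mirna_name == mir$name][1]
  expect_equal(res$counts[[cl]], 1L)
})

test_that("RPM normalization and the denominator policy behave linearly", {
  counts <- matrix(c(10, 0, 5, 0), nrow = 2,
                   dimnames = list(c("cl1", "cl2"), c("s1", "s2")))
  tab <- cluster_count_table(counts, mapped_reads = c(s1 = 1e6, s2 = 100))
  rpm <- normalize_rpm(tab)
  expect_equal(rpm["cl1", "s1"], 10)
  expect_equal(rpm[, "s2"], c(cl1 = 5e4, cl2 = 0))
  # all-zero column stays zero
  z <- cluster_count_table(matrix(0, 2, 1,
                                  dimnames = list(c("a", "b"), "s")),
                           mapped_reads = c(s = 10))
  expect_true(all(normalize_rpm(z) == 0))
  expect_error(normalize_rpm(cluster_count_table(
    matrix(0, 1, 1, dimnames = list("a", "s")), mapped_reads = c(s = 0))),
    "denominator")
  # switching policy rescales every cluster by mapped/assigned
  tab2 <- cluster_count_table(counts, mapped_reads = c(s1 = 100, s2 = 50))
  r_m <- normalize_rpm(tab2, "mapped_reads")
  r_a <- normalize_rpm(tab2, "assigned_reads")
  fac <- tab2$mapped_reads / tab2$assigned_reads
  expect_equal(r_a, sweep(r_m, 2, fac, "*"))
})

test_that("RPM is invariant under read duplication", {
  q <- quant_fixture()
  sim <- simulate_small_reads(q$fx, 500, phi = 0.3, error_rate = 0,
                              seed = 66)
  dup <- sim$reads[rep(seq_len(500), 2), ]
  dup$read_id <- paste0("d", seq_len(1000))
  r1 <- assign_reads(sim$reads, q$cs, q$fx$genomes)
  r2 <- assign_reads(dup, q$cs, q$fx$genomes)
  t1 <- cluster_count_table(list(s = r1))
  t2 <- cluster_count_table(list(s = r2))
  expect_equal(normalize_rpm(t1), normalize_rpm(t2))
})

test_that("marker thresholds match an exhaustive truth table", {
  q <- quant_fixture()
  cl <- q$cs$clusters
  set.seed(67)
  for (rep in 1:5) {
    rpm <- matrix(stats::rexp(nrow(cl) * 2, 1 / 8), ncol = 2,
                  dimnames = list(cl$cluster_id, c("feeder", "clean")))
    mk <- identify_marker_mirnas(rpm, "feeder", "clean", q$cs)
    brute <- (cl$type == "typeA_mouse" & rpm[, "feeder"] > 1) |
      (cl$type %in% c("typeB_mouse", "conserved") &
         rpm[, "feeder"] > 10 & rpm[, "clean"] < 1)
    expect_setequal(mk$cluster_id, cl$cluster_id[brute])
  }
  # boundary rules: > 10 and < 1 are strict, and Type-A ignores clean RPM
  rpm <- matrix(0, nrow(cl), 2,
                dimnames = list(cl$cluster_id, c("feeder", "clean")))
  bid <- cl$cluster_id[cl$type == "typeB_mouse"][1]
  aid <- cl$cluster_id[cl$type == "typeA_mouse"][1]
  rpm[bid, ] <- c(15, 0.5)
  rpm[aid, ] <- c(1.5, 50)
  mk <- identify_marker_mirnas(rpm, "feeder", "clean", q$cs)
  expect_setequal(mk$cluster_id, c(bid, aid))
  rpm[bid, "clean"] <- 2
  mk2 <- identify_marker_mirnas(rpm, "feeder", "clean", q$cs)
  expect_setequal(mk2$cluster_id, aid)
  rpm[bid, ] <- c(10, 0.5)  # exactly 10 fails the strict >
  expect_false(bid %in%
    identify_marker_mirnas(rpm, "feeder", "clean", q$cs)$cluster_id)
  expect_error(identify_marker_mirnas(rpm, character(), "clean", q$cs),
               "feeder")
})

test_that("influenced clusters are conserved-only, ten-fold with pseudocount", {
  q <- quant_fixture()
  cl <- q$cs$clusters
  rpm <- matrix(0, nrow(cl), 2,
                dimnames = list(cl$cluster_id, c("feeder", "clean")))
  cons <- cl$cluster_id[cl$type == "conserved"]
  rpm[cons[1], ] <- c(100, 5)   # 20-fold
  rpm[cons[2], ] <- c(15, 5)    # 3-fold
  tb <- cl$cluster_id[cl$type == "typeB_mouse"][1]
  rpm[tb, ] <- c(1000, 0)       # huge fold but not conserved
  out <- identify_influenced_mirnas(rpm, "feeder", "clean", q$cs)
  expect_equal(out$cluster_id, cons[1])
  # brute force on random tables
  set.seed(68)
  for (rep in 1:5) {
    rr <- matrix(stats::rexp(nrow(cl) * 2, 1 / 5), ncol = 2,
                 dimnames = list(cl$cluster_id, c("feeder", "clean")))
    got <- identify_influenced_mirnas(rr, "feeder", "clean", q$cs)
    brute <- cl$cluster_id[cl$type == "conserved" &
      (rr[, "feeder"] + 0.1) / (rr[, "clean"] + 0.1) >= 10]
    expect_setequal(got$cluster_id, brute)
  }
  # influenced set is disjoint from non-conserved markers by construction
  expect_true(all(out$cluster_id %in% cons))
})

test_that("contamination assessment flags Type-A detection and marker RPM", {
  q <- quant_fixture()
  cl <- q$cs$clusters
  rpm_ref <- matrix(0, nrow(cl), 2,
                    dimnames = list(cl$cluster_id, c("feeder", "clean")))
  aid <- cl$cluster_id[cl$type == "typeA_mouse"]
  bid <- cl$cluster_id[cl$type == "typeB_mouse"]
  rpm_ref[aid, "feeder"] <- 50
  rpm_ref[bid, "feeder"] <- 50
  mk <- identify_marker_mirnas(rpm_ref, "feeder", "clean", q$cs)
  zero <- stats::setNames(rep(0, nrow(cl)), cl$cluster_id)
  a0 <- assess_contamination(zero, zero, mk)
  expect_false(a0$flag)
  expect_equal(a0$typeA_detected, 0)
  # one read on one Type-A marker is enough
  one <- zero
  one[aid[1]] <- 1
  a1 <- assess_contamination(one, zero, mk)
  expect_true(a1$flag)
  expect_error(assess_contamination(zero, zero, mk[0, ]), "empty")
})

test_that("marker RPM rises monotonically with the planted mixing fraction", {
  q <- quant_fixture()
  feeder <- simulate_small_reads(q$fx, 3000, phi = 1, error_rate = 0,
                                 seed = 70)
  clean <- simulate_small_reads(q$fx, 3000, phi = 0, error_rate = 0,
                                seed = 71)
  res <- list(feeder = assign_reads(feeder$reads, q$cs, q$fx$genomes),
              clean = assign_reads(clean$reads, q$cs, q$fx$genomes))
  for (i in seq_along(c(0, 0.01, 0.1))) {
    phi <- c(0, 0.01, 0.1)[i]
    sim <- simulate_small_reads(q$fx, 3000, phi = phi, error_rate = 0,
                                seed = 72 + i)
    res[[paste0("q", i)]] <- assign_reads(sim$reads, q$cs, q$fx$genomes)
  }
  tab <- cluster_count_table(res)
  rpm <- normalize_rpm(tab)
  mk <- identify_marker_mirnas(rpm, "feeder", "clean", q$cs)
  sums <- vapply(paste0("q", 1:3), function(s) {
    assess_contamination(res[[s]]$counts, rpm[, s], mk)$total_marker_rpm
  }, numeric(1))
  expect_true(all(diff(sums) > 0))
  expect_equal(sums[[1]], 0)  # error-free reads at phi = 0
})
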