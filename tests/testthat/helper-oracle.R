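# Independent reference implementations used to check the package's
# algorithms. They are deliberately written with different formulations
# than the package code (vectorised full-DP scans, plain union-find,
# brute-force row filters).

oracle_chars <- function(x) strsplit(x, NULL)[[1]]

oracle_is_base <- function(ch) ch %in% c("A", "C", "G", "T")

# Gap-free scan: substitution count of the query against every window of
# its own length; N (either side) never matches.
oracle_scan_mismatch <- function(query, text, k) {
  m <- nchar(query)
  L <- nchar(text)
  empty <- data.frame(start = integer(), end = integer(),
                      n_diff = integer())
  if (L < m) return(empty)
  qc <- oracle_chars(query)
  tc <- oracle_chars(text)
  nmm <- integer(L - m + 1)
  for (i in seq_len(m)) {
    win <- tc[i:(L - m + i)]
    nmm <- nmm + (win != qc[i] | !oracle_is_base(win) |
                    !oracle_is_base(qc[i]))
  }
  s <- which(nmm <= k) - 1L
  data.frame(start = s, end = s + m, n_diff = nmm[s + 1L])
}

# Edit-distance scan: for every window start, a banded Wagner-Fischer DP
# vectorised across all starts simultaneously. Reports, per qualifying
# start, the minimal distance and the smallest end achieving it (same hit
# definition as the package mapper, derived independently).
oracle_scan_diff <- function(query, text, k) {
  m <- nchar(query)
  L <- nchar(text)
  empty <- data.frame(start = integer(), end = integer(),
                      n_diff = integer())
  min_w <- max(1L, m - k)
  n_start <- L - min_w + 1L
  if (n_start < 1) return(empty)
  qc <- oracle_chars(query)
  tc <- c(oracle_chars(text), rep("#", m + k + 1L))  # sentinel padding
  INF <- m + k + 10
  s0 <- seq_len(n_start) - 1L          # 0-based starts
  ds <- -k:k
  # B[[di]] = D[i][i + d] for every start; row 0: D[0][j] = j
  B <- lapply(ds, function(d) {
    v <- rep(INF, n_start)
    ok <- d >= 0 & (s0 + d) <= L
    v[ok] <- d
    v
  })
  names(B) <- as.character(ds)
  for (i in seq_len(m)) {
    Bn <- lapply(ds, function(d) rep(INF, n_start))
    names(Bn) <- as.character(ds)
    for (d in ds) {
      j <- i + d
      if (j < 0) next
      valid <- (s0 + j) <= L
      v <- rep(INF, n_start)
      if (j >= 1) {
        tch <- tc[s0 + i + d]            # text char at window offset j-1
        sub <- (tch != qc[i]) | !oracle_is_base(tch) |
          !oracle_is_base(qc[i])
        diag <- B[[as.character(d)]] + as.integer(sub)
        v <- pmin(v, diag)
      }
      if ((d + 1) <= k) v <- pmin(v, B[[as.character(d + 1)]] + 1L)
      if ((d - 1) >= -k) v <- pmin(v, Bn[[as.character(d - 1)]] + 1L)
      v[!valid] <- INF
      Bn[[as.character(d)]] <- v
    }
    B <- Bn
  }
  best <- rep(INF, n_start)
  best_d <- rep(NA_integer_, n_start)
  for (d in ds) {                        # ascending d: smallest end wins
    j <- m + d
    if (j < 1) next
    v <- B[[as.character(d)]]
    v[(s0 + j) > L] <- INF
    upd <- v < best
    best[upd] <- v[upd]
    best_d[upd] <- d
  }
  hit <- best <= k
  data.frame(start = s0[hit], end = s0[hit] + m + best_d[hit],
             n_diff = best[hit])
}

# Both strands of one chromosome, matching the package hit layout.
oracle_map <- function(query, text, mode, k) {
  one <- function(q, strand) {
    df <- if (mode == "diff") oracle_scan_diff(q, text, k)
          else oracle_scan_mismatch(q, text, k)
    if (nrow(df) == 0) return(NULL)
    df$strand <- strand
    df
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  out <- rbind(one(query, "+"), one(rc, "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      n_diff = integer(), strand = character())
  }
  out[order(out$start, out$strand, out$end), c("start", "end", "strand",
                                               "n_diff")]
}

# plain union-find over labelled nodes
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1])
      rb <- find(edges[i, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

# canonical form for comparing partitions regardless of order
canon_partition <- function(sets) {
  sorted <- lapply(sets, sort)
  keys <- vapply(sorted, paste, character(1), collapse = "|")
  sort(keys)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
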