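# Independent re-implementations used as oracles. These deliberately avoid
# the package's own code paths (bisection instead of uniroot, transitive
# closure instead of chain scanning, exhaustive scans instead of arithmetic).

# Lea-Coulson median equation solved by plain bisection.
oracle_lc_m <- function(r, lo = 1e-6, hi = 1e6, iters = 200) {
  f <- function(m) r / m - log(m) - 1.24
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Largest k with two-sided exact binomial coverage >= level, by full search.
oracle_median_k <- function(n, level = 0.95) {
  best <- NA_integer_
  for (k in seq_len(floor(n / 2))) {
    cov <- 1 - 2 * sum(stats::dbinom(0:(k - 1), n, 0.5))
    if (cov >= level) best <- k
  }
  best
}

# Cluster elements by transitive closure of "pairwise gap <= window".
oracle_clusters <- function(ann, window_bp) {
  n <- nrow(ann)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || ann$chrom[i] != ann$chrom[j]) next
    gap <- max(ann$start[i], ann$start[j]) - min(ann$end[i], ann$end[j])
    if (gap <= window_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  out <- lapply(comp, function(idx) {
    data.frame(chrom = ann$chrom[idx[1]], start = min(ann$start[idx]),
               end = max(ann$end[idx]), n_elements = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive microhomology scan: try every overlap length and keep the ones
# whose merged sequence reproduces the fusion exactly.
oracle_microhomology <- function(donor_retained, acceptor_retained, fused) {
  hits <- list()
  for (k in 0:min(nchar(donor_retained), nchar(acceptor_retained))) {
    if (k > 0 &&
        substring(donor_retained, nchar(donor_retained) - k + 1) !=
        substring(acceptor_retained, 1, k)) next
    merged <- paste0(donor_retained, substring(acceptor_retained, k + 1))
    if (merged == fused) {
      hits[[length(hits) + 1L]] <- list(
        k = k,
        sequence = if (k) substring(acceptor_retained, 1, k) else "")
    }
  }
  hits
}

# Brute-force SNP attribution: per diagnostic position assign the parent,
# then scan linearly for parent switches and report flanking-SNP intervals.
oracle_attribution_intervals <- function(junction, a, b) {
  jc <- strsplit(junction, "")[[1]]
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  pos <- which(ac != bc)
  lab <- ifelse(jc[pos] == ac[pos], "A", ifelse(jc[pos] == bc[pos], "B", "N"))
  keep <- lab != "N"
  pos <- pos[keep]; lab <- lab[keep]
  lower <- integer(); upper <- integer()
  if (length(pos) > 1) {
    for (i in seq_len(length(pos) - 1)) {
      if (lab[i] != lab[i + 1]) {
        lower <- c(lower, pos[i]); upper <- c(upper, pos[i + 1])
      }
    }
  }
  data.frame(lower = lower, upper = upper)
}

# Shared small genome for tests.
test_genome <- function() fixture_genome()
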