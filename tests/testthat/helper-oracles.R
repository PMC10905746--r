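# Independent oracles and fixture builders used across the suite.
# All oracles are deliberately naive (quadratic scans, direct definitions)
# and share no code with the implementation paths they check.

random_interval_set <- function(n, chroms = c("chr1", "chr2"),
                                max_pos = 10000, max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  as_interval_set(data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    id = sprintf("iv%03d", seq_len(n)),
    stringsAsFactors = FALSE
  ))
}

# all-pairs overlap scan (half-open)
brute_intersect <- function(a, b) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pairwise sweep merge by repeated fusion until fixpoint
brute_merge <- function(x, max_gap = 0) {
  rows <- split(x[, c("chrom", "start", "end")], seq_len(nrow(x)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      if (is.null(rows[[i]])) next
      for (j in seq_along(rows)) {
        if (i == j || is.null(rows[[j]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= max_gap) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  out <- do.call(rbind, rows)
  as_interval_set(out)
}

# exhaustive closest-gene scan
brute_closest <- function(peaks, genes) {
  t(vapply(seq_len(nrow(peaks)), function(i) {
    gi <- which(genes$chrom == peaks$chrom[i])
    if (!length(gi)) return(c(NA_character_, NA_character_))
    d <- pmax(0, pmax(genes$start[gi] - peaks$end[i],
                      peaks$start[i] - genes$end[gi]))
    o <- order(d, genes$start[gi], genes$gene_id[gi])[1]
    c(genes$gene_id[gi][o], as.character(d[o]))
  }, character(2)))
}

# Benjamini-Hochberg by its definition: q_i = min over j with p_(j) >= p_(i)
# of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(1, adj)
  q
}

# pooled-variance two-sample t by the textbook formula
t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# two-sided Fisher p by direct enumeration of all tables with the margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# per-base signal summation oracle for weighted region counts
per_base_count <- function(track, chrom, start, end) {
  v <- track$counts[[chrom]]
  bs <- track$bin_size
  bases <- start:(end - 1)
  bin <- floor(bases / bs) + 1
  ok <- bin <= length(v)
  sum(v[bin[ok]] / bs)
}

# a small gene set for interval tests
toy_genes <- function() {
  gene_model(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(2000, 10000, 5000),
    end = c(3000, 20000, 9000),
    strand = c("+", "-", "+"),
    gene_id = c("gA", "gB", "gC")
  )
}

# default bundle shared by the heavier end-to-end tests (built once)
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- simulate_bundle(generator_config(seed))
  .bundle_cache[[key]]
}
.results_cache <- new.env(parent = emptyenv())
default_results <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.results_cache[[key]]))
    .results_cache[[key]] <- run_pipeline(default_bundle(seed),
                                          pipeline_config())
  .results_cache[[key]]
}
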