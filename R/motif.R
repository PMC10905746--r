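#' Position weight matrices
#'
#' A PWM stores per-position base probabilities over A/C/G/T, a background
#' composition, and a log-odds bit-score threshold. A pseudocount (default
#' 0.001 per cell) is added and rows renormalized at construction, so
#' degenerate consensus columns stay finite. The default threshold is 80%
#' of the maximum achievable score.
#'
#' @param probs numeric matrix, width x 4, columns A, C, G, T; each row
#'   must sum to 1 (before pseudocounts).
#' @param background base frequencies (length 4, sums to 1).
#' @param pseudocount added to every cell before renormalization.
#' @param threshold bit-score hit threshold; `NULL` means
#'   `0.8 * max_score`.
#' @return An object of class `pwm` with elements `probs`, `background`,
#'   `logodds` (width x 5; the 5th column scores `N` as background, i.e.
#'   0 bits), `max_score`, `threshold`, `width`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 0.001,
                threshold = NULL) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, all(probs >= 0),
            all(abs(rowSums(probs) - 1) < 1e-9),
            length(background) == 4, abs(sum(background) - 1) < 1e-9)
  colnames(probs) <- c("A", "C", "G", "T")
  p <- probs + pseudocount
  p <- p / rowSums(p)
  lo <- log2(sweep(p, 2, background, `/`))
  lo <- cbind(lo, N = 0)
  max_score <- sum(apply(lo[, 1:4, drop = FALSE], 1, max))
  if (is.null(threshold)) threshold <- 0.8 * max_score
  structure(list(probs = p, background = background, logodds = lo,
                 max_score = max_score, threshold = threshold,
                 width = nrow(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, max score %.2f bits, threshold %.2f bits\n",
              x$width, x$max_score, x$threshold))
  invisible(x)
}

#' Build a PWM from a consensus string
#'
#' Each consensus base gets probability 1 before the constructor's
#' pseudocount; useful as an illustrative matrix when the exact matrix a
#' study used is not published.
#'
#' @param consensus string over A/C/G/T.
#' @param ... passed to [pwm()].
#' @return A `pwm`.
#' @export
consensus_pwm <- function(consensus, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  m <- matrix(0, length(bases), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 1
  pwm(m, ...)
}

#' Read and write PWM text files
#'
#' Plain-text matrix: four whitespace-separated probability columns
#' (A C G T), one row per motif position, `#` comments allowed. Files
#' written by `write_pwm` already carry the constructor's pseudocount, so
#' re-read them with `pseudocount = 0` for an exact round trip.
#'
#' @param path file path.
#' @param ... passed to [pwm()] on read (background, pseudocount,
#'   threshold, ...).
#' @return `read_pwm` returns a `pwm`.
#' @export
read_pwm <- function(path, ...) {
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  pwm(m / rowSums(m), ...)
}

#' @rdname read_pwm
#' @param x a `pwm` to write (probabilities after pseudocount).
#' @export
write_pwm <- function(x, path) {
  utils::write.table(format(x$probs, digits = 6), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x character vector of sequences over A/C/G/T/N.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

score_offsets <- function(codes, lo, width) {
  L <- length(codes)
  if (L < width) return(numeric(0))
  npos <- L - width + 1
  sc <- numeric(npos)
  for (j in seq_len(width)) {
    sc <- sc + lo[j, codes[j:(npos + j - 1)]]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands in log2-odds bits (`N` bases score
#' 0, i.e. as background) and reports hits at or above the threshold. A
#' reverse-strand hit at offset `i` means the motif matches the reverse
#' complement of `substring(seq, i, i + width - 1)`.
#'
#' @param sequence a single DNA string over A/C/G/T/N.
#' @param motif a `pwm`.
#' @return Data frame: `offset` (1-based), `strand`, `score`; empty when
#'   the sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, motif) {
  stopifnot(inherits(motif, "pwm"), length(sequence) == 1)
  codes <- match(strsplit(toupper(sequence), "")[[1]],
                 c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) stop("scan_pwm: sequence must be over A/C/G/T/N")
  w <- motif$width
  fwd <- score_offsets(codes, motif$logodds, w)
  lo_rc <- motif$logodds[rev(seq_len(w)), c(4:1, 5), drop = FALSE]
  rev_ <- score_offsets(codes, lo_rc, w)
  hits_f <- which(fwd >= motif$threshold)
  hits_r <- which(rev_ >= motif$threshold)
  out <- data.frame(
    offset = c(hits_f, hits_r),
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    score = c(fwd[hits_f], rev_[hits_r]),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Motif enrichment in bound versus background regions
#'
#' A region contains the motif if it has at least one hit. Containment is
#' crossed with set membership in a 2x2 Fisher exact test (hypergeometric
#' enumeration via [fisher_exact_2x2()]), the presence/absence convention of
#' the usual known-motif enrichment tools.
#'
#' @param bound_seqs,background_seqs non-empty character vectors of region
#'   sequences.
#' @param motif a `pwm`.
#' @return List: `frac_bound`, `frac_background`, `odds_ratio`, `p_value`,
#'   `table`, and the per-region `contains_bound` / `contains_background`
#'   flags.
#' @export
motif_enrichment <- function(bound_seqs, background_seqs, motif) {
  if (length(bound_seqs) == 0 || length(background_seqs) == 0)
    stop("motif_enrichment: both sequence sets must be non-empty")
  has <- function(seqs) vapply(seqs, function(s) nrow(scan_pwm(s, motif)) > 0,
                               logical(1), USE.NAMES = FALSE)
  hb <- has(bound_seqs)
  hg <- has(background_seqs)
  ft <- fisher_exact_2x2(sum(hb), sum(!hb), sum(hg), sum(!hg))
  list(frac_bound = mean(hb), frac_background = mean(hg),
       odds_ratio = ft$odds_ratio, p_value = ft$p_value, table = ft$table,
       contains_bound = hb, contains_background = hg)
}

#' Read and write region FASTA files
#'
#' Thin wrappers over Biostrings; sequences are returned as a named
#' character vector (names are region labels such as `chr1:1000-2000`).
#'
#' @param path file path.
#' @return `read_region_fasta` returns a named character vector.
#' @export
read_region_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_region_fasta
#' @param seqs named character vector of sequences.
#' @export
write_region_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
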