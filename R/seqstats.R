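# Per-sequence statistics underlying the feature encoding: base counts,
# Shannon entropy, topological entropy, and Chargaff second-parity scores.

#' Count nucleotides in a sequence
#'
#' Tallies A, C, G and T (case-insensitive; `U` is folded to `T` so
#' RNA-spelled sequences score identically to their DNA spelling). Every
#' other letter — IUPAC ambiguity codes, gaps, anything else — is counted in
#' `other` and excluded from all downstream frequency, entropy and parity
#' computations.
#'
#' @param seq A single nucleotide string; may be empty.
#' @return An object of class `nucleotide_counts`: a list with integer
#'   fields `a`, `c`, `g`, `t`, `other` and `length`
#'   (`a + c + g + t + other == length`).
#' @examples
#' count_bases("ATGC")
#' count_bases("atgnu")  # U -> T, N -> other
#' @export
count_bases <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  if (n == 0L) {
    return(new_nucleotide_counts(0L, 0L, 0L, 0L, 0L))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  tab <- tabulate(factor(chars, levels = c("A", "C", "G", "T")), nbins = 4L)
  new_nucleotide_counts(tab[1L], tab[2L], tab[3L], tab[4L],
                        n - sum(tab))
}

new_nucleotide_counts <- function(a, c, g, t, other) {
  structure(
    list(a = as.integer(a), c = as.integer(c), g = as.integer(g),
         t = as.integer(t), other = as.integer(other),
         length = as.integer(a + c + g + t + other)),
    class = "nucleotide_counts"
  )
}

#' @export
print.nucleotide_counts <- function(x, ...) {
  cat(sprintf("nucleotide counts: A=%d C=%d G=%d T=%d other=%d (length %d)\n",
              x$a, x$c, x$g, x$t, x$other, x$length))
  invisible(x)
}

# Accept either a counts object or a raw sequence string.
as_counts <- function(x) {
  if (inherits(x, "nucleotide_counts")) x else count_bases(x)
}

acgt_total <- function(cnt) cnt$a + cnt$c + cnt$g + cnt$t

#' Shannon entropy of nucleotide composition
#'
#' Computes \eqn{-\sum_i p_i \log_2 p_i} over the four base frequencies
#' (non-ACGT letters are excluded from the distribution), with the
#' convention \eqn{0 \log 0 = 0}. The maximum for DNA is 2 bits
#' (equifrequent bases, e.g. "ATGC"); a homopolymer such as "AAAA" scores 0.
#'
#' @param x A `nucleotide_counts` object or a nucleotide string.
#' @return Entropy in bits, in `[0, 2]`.
#' @examples
#' shannon_entropy("ATGC")  # 2
#' shannon_entropy("AAAA")  # 0
#' @export
shannon_entropy <- function(x) {
  cnt <- as_counts(x)
  tot <- acgt_total(cnt)
  if (tot == 0L) {
    stop("Shannon entropy is undefined for a sequence with no A/C/G/T content")
  }
  p <- c(cnt$a, cnt$c, cnt$g, cnt$t) / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Topological entropy of a DNA sequence
#'
#' A length-normalized subword-complexity measure. The word length `n` is
#' the largest integer with \eqn{4^n + n - 1 \le L}; the number of distinct
#' n-mers \eqn{c_n} is counted within the prefix window of exactly
#' \eqn{4^n + n - 1} letters, and the score is \eqn{\log_4(c_n) / n}, which
#' lies in `[0, 1]` (0 for a homopolymer, 1 for a maximally diverse
#' sequence). n-mers containing a non-ACGT letter are skipped.
#'
#' @param seq A nucleotide string of length at least 4.
#' @return Normalized topological entropy in `[0, 1]`; `NA` if no valid
#'   n-mer exists in the window (all windows hit ambiguity codes).
#' @examples
#' topological_entropy("AAAAA")   # 0
#' topological_entropy("ATGCA")   # 1
#' topological_entropy("ATATAT")  # 0.5
#' @export
topological_entropy <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("U", "T", toupper(seq))
  len <- nchar(s)
  if (len < 4L) {
    stop("topological entropy requires a sequence of length >= 4")
  }
  n <- 1L
  while (4^(n + 1L) + n <= len) n <- n + 1L
  window <- 4L^n + n - 1L
  starts <- seq_len(window - n + 1L)
  kmers <- substring(s, starts, starts + n - 1L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) {
    warning("no ambiguity-free n-mer in the topological-entropy window")
    return(NA_real_)
  }
  c_n <- length(unique(kmers))
  log(c_n, base = 4) / n
}

#' Chargaff second-parity-rule scores
#'
#' Chargaff's second parity rule (CSPR) states that within a single strand
#' A ≈ T and C ≈ G; deviation indicates a non-random evolutionary pressure
#' on the sequence. Two conformity statistics are provided:
#'
#' * `chargaff_ct()` — length-normalized conformity,
#'   \eqn{1 - (|A-T| + |C-G|) / (A+C+G+T)}: 1 means the rule holds exactly,
#'   0 is the maximal violation.
#' * `chargaff_pf()` — unnormalized deviation, \eqn{|A-T| + |C-G|}: the
#'   scale is inverted relative to `ct`, with 0 meaning perfect parity and
#'   no upper bound.
#'
#' Both statistics are invariant under reverse complementation. The default
#' formulas can be swapped: pass any `function(counts) -> numeric` as
#' `method` to score with an alternative parity statistic under the same
#' input checks.
#'
#' @param x A `nucleotide_counts` object or a nucleotide string.
#' @param method Either `"abs_diff"` (the built-in formula) or a function
#'   taking a `nucleotide_counts` object and returning a numeric score.
#' @return `chargaff_ct`: a score in `[0, 1]`. `chargaff_pf`: a
#'   non-negative count-scale score.
#' @examples
#' chargaff_ct("ATGC")  # 1: perfect parity
#' chargaff_pf("ATGC")  # 0
#' chargaff_ct("AAAA")  # 0: maximal violation
#' @export
chargaff_ct <- function(x, method = "abs_diff") {
  cnt <- as_counts(x)
  tot <- acgt_total(cnt)
  if (tot == 0L) {
    stop("Chargaff score is undefined for a sequence with no A/C/G/T content")
  }
  if (is.function(method)) {
    return(method(cnt))
  }
  method <- match.arg(method, "abs_diff")
  1 - (abs(cnt$a - cnt$t) + abs(cnt$c - cnt$g)) / tot
}

#' @rdname chargaff_ct
#' @export
chargaff_pf <- function(x, method = "abs_diff") {
  cnt <- as_counts(x)
  if (acgt_total(cnt) == 0L) {
    stop("Chargaff score is undefined for a sequence with no A/C/G/T content")
  }
  if (is.function(method)) {
    return(method(cnt))
  }
  method <- match.arg(method, "abs_diff")
  abs(cnt$a - cnt$t) + abs(cnt$c - cnt$g)
}

#' All per-sequence scores at once
#'
#' Convenience wrapper computing the four scores the feature encoding uses.
#'
#' @param seq A nucleotide string.
#' @return A list with elements `shannon` (bits, `[0, 2]`), `topological`
#'   (`[0, 1]`; `NA` when the sequence is shorter than 4), `chargaff_ct`
#'   (`[0, 1]`) and `chargaff_pf` (`>= 0`).
#' @export
sequence_scores <- function(seq) {
  cnt <- count_bases(seq)
  list(
    shannon = shannon_entropy(cnt),
    topological = if (nchar(seq) >= 4L) topological_entropy(seq) else NA_real_,
    chargaff_ct = chargaff_ct(cnt),
    chargaff_pf = chargaff_pf(cnt)
  )
}
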