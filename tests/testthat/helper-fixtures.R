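# Shared fixtures and independent oracles.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_base <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Hand-built annotated genome (bypasses both the generator and the parser).
toy_genome <- function(id = "toy", replicons = c(chr = "ATGC"),
                       elements = NULL, label = "unknown") {
  if (is.null(elements)) {
    elements <- data.frame(replicon = character(), element_class = character(),
                           start = integer(), end = integer(),
                           strand = character(), sequence = character(),
                           stringsAsFactors = FALSE)
  }
  probioscreen:::new_annotated_genome(id, replicons, elements, label)
}

# Independent topological-entropy oracle: word length chosen by direct
# enumeration, distinct n-mers counted through Biostrings.
topo_oracle <- function(seq) {
  L <- nchar(seq)
  n <- max(which(vapply(1:12, function(k) 4^k + k - 1 <= L, logical(1))))
  w <- 4^n + n - 1
  prefix <- Biostrings::DNAString(substr(seq, 1, w))
  c_n <- sum(Biostrings::oligonucleotideFrequency(prefix, width = n) > 0)
  log(c_n, base = 4) / n
}

# Brute-force Mann-Whitney AUC: enumerate every positive-negative pair.
auc_oracle <- function(scores, truth, positive = "probiotic") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Standard Cohen's kappa via observed/expected agreement.
kappa_oracle <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  (po - pe) / (1 - pe)
}

# Fast small cohort for pipeline unit tests (not the reference conditions;
# scaled down for speed).
small_cohort_spec <- function(seed, n_pos = 12, n_neg = 10,
                              n_test_pos = 2, n_test_neg = 1) {
  cohort_spec(
    n_positive = n_pos, n_negative = n_neg,
    n_test_positive = n_test_pos, n_test_negative = n_test_neg,
    genome_length = c(positive = 15000, negative = 20000),
    n_cds = c(positive = 12, negative = 18),
    n_trna = c(10L, 15L), n_rrna = c(1L, 2L), n_ncrna = c(1L, 3L),
    seed = seed)
}

small_feature_table <- function(seed, ...) {
  coh <- generate_cohort(small_cohort_spec(seed, ...))
  tab <- suppressMessages(build_dataset(
    coh$genomes, stats::setNames(coh$labels$outcome, coh$labels$organism_id)))
  attr(tab, "roles") <- coh$labels$role
  tab
}

trio_features <- c("tRNA_shannon_score", "tRNA_chargaff_score_ct",
                   "tRNA_chargaff_score_pf")
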