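# The 61-feature encoding of an annotated genome and cohort assembly.
#
# The catalog is data-driven: inst/extdata/feature_catalog.csv lists every
# feature (name, block, quantity) so the schema can be corrected without a
# code change. Blocks: the whole genome plus one block per element class
# (CDS, rRNA, tRNA, ncRNA); each block carries base counts and the
# information-theoretic / Chargaff-parity scores of the block's sequence
# (element blocks are scored on the concatenation of all their elements —
# the "total tRNA sequence" convention). Note: the upstream data dictionary
# glosses bp_cdsG as CDS "Cytosines"; it is of course the Guanine count
# (the symbol is authoritative).

.catalog_env <- new.env(parent = emptyenv())

#' The canonical 61-feature catalog
#'
#' @return A `data.frame` with columns `name` (canonical feature/column
#'   name, e.g. `tRNA_shannon_score`), `block` (`genome`, `cds`, `rRNA`,
#'   `tRNA`, `ncRNA`) and `quantity` (which statistic the feature is).
#' @export
feature_catalog <- function() {
  if (is.null(.catalog_env$catalog)) {
    path <- system.file("extdata", "feature_catalog.csv",
                        package = "probioscreen", mustWork = TRUE)
    .catalog_env$catalog <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .catalog_env$catalog
}

block_features <- function(seq, prefix, n_elements, with_freq = TRUE,
                           with_topo = FALSE) {
  cnt <- count_bases(seq)
  bp <- c(cnt$a, cnt$c, cnt$g, cnt$t)
  out <- list()
  if (!is.na(n_elements)) out[[sprintf("n_%s_total", prefix)]] <- n_elements
  out[[if (prefix == "gen") "bp_genome_total"
       else sprintf("bp_%s_total", prefix)]] <- cnt$length
  for (i in 1:4) out[[paste0("bp_", prefix, c("A", "C", "G", "T")[i])]] <- bp[i]
  if (with_freq) {
    fr <- if (cnt$length > 0L) bp / cnt$length else rep(NA_real_, 4L)
    for (i in 1:4) out[[paste0("fr_", prefix, c("A", "C", "G", "T")[i])]] <- fr[i]
  }
  score_prefix <- if (prefix == "gen") "genomic" else prefix
  if (acgt_total(cnt) > 0L) {
    out[[sprintf("%s_shannon_score", score_prefix)]] <- shannon_entropy(cnt)
    if (with_topo) {
      out[["genomic_topological_score"]] <-
        if (nchar(seq) >= 4L) topological_entropy(seq) else NA_real_
    }
    out[[sprintf("%s_chargaff_score_ct", score_prefix)]] <- chargaff_ct(cnt)
    out[[sprintf("%s_chargaff_score_pf", score_prefix)]] <- chargaff_pf(cnt)
  } else {
    out[[sprintf("%s_shannon_score", score_prefix)]] <- NA_real_
    if (with_topo) out[["genomic_topological_score"]] <- NA_real_
    out[[sprintf("%s_chargaff_score_ct", score_prefix)]] <- NA_real_
    out[[sprintf("%s_chargaff_score_pf", score_prefix)]] <- NA_real_
  }
  out
}

#' Encode an annotated genome as the 61-feature vector
#'
#' Computes the whole-genome block (on the concatenation of all replicons
#' in file order) and one block per element class (on the concatenation of
#' that class's strand-correct element sequences). An absent element class
#' yields zero counts and missing (`NA`) scores; the modeling pipeline
#' median-imputes those within cross-validation folds.
#'
#' @param genome An `annotated_genome` from [read_genbank()] or the
#'   synthetic cohort generator.
#' @return A one-row `data.frame` with the 61 catalog columns in canonical
#'   order.
#' @export
encode_features <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  genome_seq <- paste(genome$replicons, collapse = "")
  if (nchar(genome_seq) == 0L) stop("genome ", genome$organism_id,
                                    " has an empty sequence")
  vals <- block_features(genome_seq, "gen", NA, with_freq = TRUE,
                         with_topo = TRUE)
  specs <- list(CDS = c("cds", TRUE), rRNA = c("rRNA", TRUE),
                tRNA = c("tRNA", TRUE), ncRNA = c("ncRNA", FALSE))
  for (cls in names(specs)) {
    prefix <- specs[[cls]][1L]
    with_freq <- as.logical(specs[[cls]][2L])
    n_el <- sum(genome$elements$element_class == cls)
    vals <- c(vals, block_features(concatenate_class(genome, cls), prefix,
                                   n_el, with_freq = with_freq))
  }
  catalog <- feature_catalog()
  missing <- setdiff(catalog$name, names(vals))
  if (length(missing)) stop("internal: encoder missed features ",
                            paste(missing, collapse = ", "))
  as.data.frame(vals[catalog$name])
}

#' Assemble a labeled feature table from a genome cohort
#'
#' Encodes every genome and joins the outcome labels. Labels may cover only
#' part of the cohort (the rest get `"unknown"`, the held-out-test role).
#'
#' @param genomes A list of `annotated_genome` objects with unique
#'   `organism_id`s.
#' @param labels Either `NULL`, a named character vector
#'   (`organism_id -> outcome`), or a `data.frame` with columns
#'   `organism_id` and `outcome`. Outcomes must be `"probiotic"`,
#'   `"non-probiotic"` or `"unknown"`. A label whose id matches no genome
#'   is an error.
#' @return A `data.frame`: `organism_id`, the 61 features, `outcome`.
#' @export
build_dataset <- function(genomes, labels = NULL) {
  ids <- vapply(genomes, function(g) g$organism_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated organism id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  catalog <- feature_catalog()
  if (length(genomes) == 0L) {
    out <- cbind(data.frame(organism_id = character()),
                 as.data.frame(stats::setNames(
                   rep(list(numeric()), nrow(catalog)), catalog$name)),
                 data.frame(outcome = character()))
    return(out)
  }
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$outcome, labels$organism_id)
  }
  if (!is.null(labels)) {
    orphan <- setdiff(names(labels), ids)
    if (length(orphan)) stop("label(s) with no matching genome: ",
                             paste(orphan, collapse = ", "))
    bad <- setdiff(labels, c("probiotic", "non-probiotic", "unknown"))
    if (length(bad)) stop("invalid outcome value(s): ",
                          paste(bad, collapse = ", "))
  }
  rows <- lapply(genomes, encode_features)
  tab <- do.call(rbind, rows)
  tab <- cbind(data.frame(organism_id = ids, stringsAsFactors = FALSE), tab)
  tab$outcome <- if (is.null(labels)) "unknown"
                 else unname(ifelse(is.na(labels[ids]), "unknown", labels[ids]))
  rownames(tab) <- NULL
  n_lab <- table(factor(tab$outcome,
                        levels = c("probiotic", "non-probiotic", "unknown")))
  message(sprintf("cohort: %d probiotic, %d non-probiotic, %d unknown",
                  n_lab[1L], n_lab[2L], n_lab[3L]))
  tab
}

# Split a feature table into the labeled (training) and unlabeled rows.
#' Partition a feature table by label availability
#'
#' @param table A feature table from [build_dataset()].
#' @return A list with elements `train` (rows with a known outcome) and
#'   `test` (rows labeled `"unknown"`).
#' @export
partition_dataset <- function(table) {
  known <- table$outcome %in% c("probiotic", "non-probiotic")
  list(train = table[known, , drop = FALSE],
       test = table[!known, , drop = FALSE])
}
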