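# GenBank flat-file ingestion and feature-table CSV round-trip.
#
# The reader is a purpose-built minimal parser for annotated bacterial
# genomes: it extracts the ORIGIN sequence of every record (replicon) and
# the CDS / rRNA / tRNA / ncRNA features with their locations, handling
# complement(), join() and partial-boundary (< >) markers. Qualifiers are
# not interpreted. Internally coordinates are 0-based half-open; GenBank's
# 1-based inclusive spans are converted on read.

ELEMENT_CLASSES <- c("CDS", "rRNA", "tRNA", "ncRNA")

new_annotated_genome <- function(organism_id, replicons, elements,
                                 label = "unknown") {
  structure(
    list(organism_id = organism_id, replicons = replicons,
         elements = elements, label = label),
    class = "annotated_genome"
  )
}

empty_elements <- function() {
  data.frame(replicon = character(), element_class = character(),
             start = integer(), end = integer(), strand = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated genome '%s' (%s)\n", x$organism_id, x$label))
  cat(sprintf("  %d replicon(s), total %d bp\n",
              length(x$replicons), sum(nchar(x$replicons))))
  tab <- table(factor(x$elements$element_class, levels = ELEMENT_CLASSES))
  cat("  elements:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

# Parse a GenBank location string into spans (1-based inclusive) + strand.
# Handles: "a..b", "complement(a..b)", "join(a..b,c..d)",
# "complement(join(...))", single-base "a", and '<'/'>' partial markers.
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "order(")) {
    loc <- sub("^order\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- t(vapply(parts, function(p) {
    ab <- strsplit(p, "..", fixed = TRUE)[[1L]]
    ab <- suppressWarnings(as.integer(ab))
    if (anyNA(ab)) stop("unparseable GenBank location part: ", p)
    if (length(ab) == 1L) ab <- c(ab, ab)
    ab
  }, integer(2)))
  dimnames(spans) <- NULL
  list(strand = strand, spans = spans)
}

# Split a flat file into records on the '//' terminator.
split_gb_records <- function(lines) {
  term <- grep("^//", lines)
  if (length(term) == 0L) term <- length(lines)
  starts <- c(1L, head(term, -1L) + 1L)
  Map(function(s, e) lines[s:e], starts, term)
}

parse_gb_record <- function(lines, path) {
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  name <- if (length(locus_line)) strsplit(trimws(locus_line[1L]),
                                           "[[:space:]]+")[[1L]][2L]
          else NA_character_
  feat_at <- grep("^FEATURES", lines)
  orig_at <- grep("^ORIGIN", lines)
  if (length(orig_at) == 0L) {
    stop("GenBank record ", name %||% "?", " in ", path, " has no ORIGIN block")
  }
  seq_lines <- lines[(orig_at[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- list()
  if (length(feat_at)) {
    flines <- lines[(feat_at[1L] + 1L):(orig_at[1L] - 1L)]
    key <- NA_character_; loc <- NULL
    flush <- function() {
      if (!is.na(key)) features[[length(features) + 1L]] <<-
          list(key = key, location = loc)
    }
    for (ln in flines) {
      if (grepl("^ {5}[^ ]", ln)) {          # new feature key
        flush()
        key <- trimws(substr(ln, 6L, 20L))
        loc <- trimws(substr(ln, 21L, nchar(ln)))
      } else if (!is.na(key)) {
        cont <- trimws(ln)
        if (!startsWith(cont, "/")) loc <- paste0(loc, cont)  # wrapped location
        # qualifier lines are ignored
      }
    }
    flush()
  }
  list(name = name, sequence = sequence, features = features)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Read an annotated genome from a GenBank flat file
#'
#' Parses a (possibly multi-record) GenBank flat file into a single
#' `annotated_genome`: one replicon per record plus every CDS, rRNA, tRNA
#' and ncRNA feature with its strand-correct sequence. Minus-strand and
#' `complement(join(...))` features are reverse-complemented; compound
#' locations are concatenated in annotation order before complementing.
#' Partial features (with `<`/`>` boundary markers) are included as-is.
#'
#' mRNA features are an annotation-quality criterion, not a scored element
#' class, so they are skipped unless `include_mrna = TRUE` (they are then
#' carried with class `"mRNA"` but ignored by [encode_features()]).
#'
#' @param path Path to a GenBank flat file.
#' @param organism_id Identifier for the genome; defaults to the file name
#'   without extension.
#' @param include_mrna Parse mRNA features as well? Default `FALSE`.
#' @param ncrna_keys GenBank feature keys mapped to the ncRNA class;
#'   default `"ncRNA"` only (the narrowest reading; add e.g. `"tmRNA"`,
#'   `"misc_RNA"` to widen).
#' @return An `annotated_genome` object.
#' @export
read_genbank <- function(path, organism_id = NULL, include_mrna = FALSE,
                         ncrna_keys = "ncRNA") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- split_gb_records(lines)
  records <- Filter(function(r) any(grepl("^LOCUS", r)), records)
  if (length(records) == 0L) stop("no GenBank record found in ", path)
  parsed <- lapply(records, parse_gb_record, path = path)

  keys <- ELEMENT_CLASSES
  if (include_mrna) keys <- c(keys, "mRNA")

  replicons <- character(0)
  rows <- list()
  for (rec in parsed) {
    rep_name <- rec$name %||% sprintf("replicon%d", length(replicons) + 1L)
    replicons[rep_name] <- rec$sequence
    for (ft in rec$features) {
      cls <- ft$key
      if (cls %in% ncrna_keys) cls <- "ncRNA"
      if (!cls %in% keys) next
      pl <- tryCatch(parse_gb_location(ft$location), error = function(e) {
        stop("record ", rep_name, " in ", path, ": ", conditionMessage(e))
      })
      if (any(pl$spans < 1L) || any(pl$spans[, 2L] > nchar(rec$sequence))) {
        stop("record ", rep_name, " in ", path,
             ": feature coordinates outside the replicon: ", ft$location)
      }
      pieces <- substring(rec$sequence, pl$spans[, 1L], pl$spans[, 2L])
      s <- paste(pieces, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        replicon = rep_name, element_class = cls,
        start = min(pl$spans[, 1L]) - 1L, end = max(pl$spans[, 2L]),
        strand = pl$strand, sequence = s, stringsAsFactors = FALSE)
    }
  }
  elements <- if (length(rows)) do.call(rbind, rows) else empty_elements()
  minus <- elements$strand == "-"
  elements$sequence[minus] <- revcomp(elements$sequence[minus])
  if (nrow(elements) == 0L) {
    warning("genome in ", path, " has no CDS/rRNA/tRNA/ncRNA annotation")
  }
  new_annotated_genome(
    organism_id = organism_id %||% tools::file_path_sans_ext(basename(path)),
    replicons = replicons, elements = elements)
}

# Vectorized reverse complement via Biostrings (DNA alphabet; GenBank ORIGIN
# is DNA). One DNAStringSet call amortizes S4 dispatch over many elements.
revcomp <- function(s) {
  if (length(s) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)),
               use.names = FALSE)
}

#' Concatenate all element sequences of one class
#'
#' Element-class scores are computed on the concatenation of all
#' strand-correct element sequences of that class, in file order — the
#' "total tRNA sequence" convention.
#'
#' @param genome An `annotated_genome`.
#' @param element_class One of `"CDS"`, `"rRNA"`, `"tRNA"`, `"ncRNA"`.
#' @return A single nucleotide string; `""` when the class is absent.
#' @export
concatenate_class <- function(genome, element_class) {
  element_class <- match.arg(element_class, ELEMENT_CLASSES)
  sel <- genome$elements$element_class == element_class
  paste(genome$elements$sequence[sel], collapse = "")
}

#' Write / read the labeled feature table as CSV
#'
#' The on-disk format is one row per organism: `organism_id`, the 61
#' catalog features in canonical order, and `outcome`
#' (`probiotic` / `non-probiotic` / `unknown`). The round trip is lossless
#' to at least 12 significant digits.
#'
#' @param table A feature table as returned by [build_dataset()].
#' @param path CSV file path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   returns the feature table (a `data.frame`). A file without an
#'   `outcome` column is accepted (labels set to `"unknown"`, with a
#'   message); an unrecognized column is an error naming it.
#' @export
write_feature_csv <- function(table, path) {
  catalog <- feature_catalog()
  cols <- c("organism_id", catalog$name, "outcome")
  missing <- setdiff(cols, names(table))
  if (length(missing)) stop("feature table lacks columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(format(table[, cols], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  catalog <- feature_catalog()
  known <- c("organism_id", catalog$name, "outcome")
  extra <- setdiff(names(tab), known)
  if (length(extra)) stop("unrecognized feature column(s): ",
                          paste(extra, collapse = ", "))
  missing <- setdiff(catalog$name, names(tab))
  if (length(missing)) stop("feature CSV lacks catalog column(s): ",
                            paste(missing, collapse = ", "))
  if (!"outcome" %in% names(tab)) {
    message("no 'outcome' column in ", path, "; labels set to 'unknown'")
    tab$outcome <- "unknown"
  }
  if (!"organism_id" %in% names(tab)) {
    tab$organism_id <- sprintf("organism%03d", seq_len(nrow(tab)))
  }
  for (nm in catalog$name) tab[[nm]] <- as.numeric(tab[[nm]])
  tab[, c("organism_id", catalog$name, "outcome")]
}
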