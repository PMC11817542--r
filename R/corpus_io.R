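#' Corpora of labeled short-text documents
#'
#' A corpus is a plain `data.frame` with one row per document and the columns
#' `id`, `text`, `raw_label`, `label`, and `source`. `raw_label` preserves the
#' label string found in the source dataset verbatim; `label` is the canonical
#' class used by the models and is always one of `"trustworthy"`,
#' `"misinformation"`, or `"unlabeled"`. `as_corpus()` fills in missing
#' optional columns and checks the corpus invariants (non-empty, unique ids;
#' canonical labels).
#'
#' @param x A data.frame with at least `id` and `text` columns.
#' @return A validated corpus data.frame with the five canonical columns.
#' @export
as_corpus <- function(x) {
  if (!is.data.frame(x)) stop("a corpus must be a data.frame")
  if (!all(c("id", "text") %in% names(x))) {
    stop("a corpus needs at least 'id' and 'text' columns")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$raw_label)) x$raw_label <- rep("", nrow(x))
  if (is.null(x$label)) x$label <- rep("unlabeled", nrow(x))
  if (is.null(x$source)) x$source <- rep("", nrow(x))
  canon <- c("id", "text", "raw_label", "label", "source")
  x <- x[, c(canon, setdiff(names(x), canon)), drop = FALSE]
  for (col in canon) x[[col]] <- as.character(x[[col]])
  x$label[is.na(x$label) | x$label == ""] <- "unlabeled"
  x$raw_label[is.na(x$raw_label)] <- ""
  x$source[is.na(x$source)] <- ""
  validate_corpus(x)
  x
}

validate_corpus <- function(corpus) {
  bad <- which(is.na(corpus$id) | corpus$id == "")
  if (length(bad)) {
    stop("empty document id at record ", bad[1])
  }
  dup <- which(duplicated(corpus$id))
  if (length(dup)) {
    stop("duplicate id '", corpus$id[dup[1]], "' at record ", dup[1])
  }
  bad_lab <- which(!corpus$label %in% .canonical_labels)
  if (length(bad_lab)) {
    stop("non-canonical label '", corpus$label[bad_lab[1]],
         "' at record ", bad_lab[1],
         " (expected trustworthy/misinformation/unlabeled)")
  }
  invisible(corpus)
}

#' Read a corpus from CSV or JSON-lines
#'
#' Reads one document per record. Raw labels are preserved verbatim and the
#' canonical `label` column is initialized to `"unlabeled"` unless the file
#' already carries canonical labels (e.g. a file previously written by
#' [write_corpus()]). Duplicate or missing ids are rejected with the
#' offending line identified; a malformed JSON-lines record raises an error
#' naming its line number.
#'
#' @param path Path to the file.
#' @param format `"csv"` (comma-separated, quoted fields, UTF-8, with a
#'   header row) or `"jsonl"` (one JSON object per line).
#' @return A corpus data.frame (possibly with zero rows for an empty file).
#' @export
read_corpus <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    return(as_corpus(data.frame(id = character(), text = character(),
                                stringsAsFactors = FALSE)))
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = character(), encoding = "UTF-8")
    if (!all(c("id", "text") %in% names(df))) {
      stop("CSV header must include 'id' and 'text' columns: ", path)
    }
    # header occupies line 1, so record i sits on file line i + 1
    line_of <- function(i) i + 1L
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(as_corpus(data.frame(id = character(), text = character(),
                                  stringsAsFactors = FALSE)))
    }
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop("malformed JSON record at line ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      if (is.null(rec$id) || is.null(rec$text)) {
        stop("record at line ", i, " lacks an 'id' or 'text' field")
      }
      recs[[i]] <- data.frame(
        id = as.character(rec$id), text = as.character(rec$text),
        raw_label = if (is.null(rec$raw_label)) "" else as.character(rec$raw_label),
        label = if (is.null(rec$label)) "unlabeled" else as.character(rec$label),
        source = if (is.null(rec$source)) "" else as.character(rec$source),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
    line_of <- function(i) i
  }
  bad <- which(is.na(df$id) | df$id == "")
  if (length(bad)) stop("empty id at line ", line_of(bad[1]), " of ", path)
  dup <- which(duplicated(df$id))
  if (length(dup)) {
    stop("duplicate id '", df$id[dup[1]], "' at line ", line_of(dup[1]),
         " of ", path)
  }
  as_corpus(df)
}

#' Write a corpus to CSV or JSON-lines
#'
#' Inverse of [read_corpus()]: a write followed by a read reproduces `id`,
#' `text`, `raw_label`, `label` and `source` exactly.
#'
#' @param corpus A corpus data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  corpus <- as_corpus(corpus)
  if (format == "csv") {
    utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      as.character(jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                                    auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

# case-insensitive, whitespace-normalized key used for label matching
.label_key <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Source-label to canonical-label mapping
#'
#' A label map holds two disjoint sets of source-label strings: those that
#' count as trustworthy information and those that count as misinformation.
#' Matching is case-insensitive after trimming and collapsing whitespace
#' (fact-checking datasets mix capitalizations of the same verdict).
#' Source labels in neither set map to `"unlabeled"`; they are retained in
#' the corpus but excluded from supervised use.
#'
#' @param trustworthy Character vector of source labels mapped to the
#'   trustworthy class.
#' @param misinformation Character vector of source labels mapped to the
#'   misinformation class.
#' @return An object of class `label_map`.
#' @export
label_map <- function(trustworthy = character(), misinformation = character()) {
  t_keys <- unique(.label_key(trustworthy))
  m_keys <- unique(.label_key(misinformation))
  clash <- intersect(t_keys, m_keys)
  if (length(clash)) {
    stop("label map sets are not disjoint: ", paste(clash, collapse = ", "))
  }
  structure(list(trustworthy_set = t_keys, misinformation_set = m_keys),
            class = "label_map")
}

#' Read a label map from a YAML or JSON config file
#'
#' The file must define `trustworthy_set` and `misinformation_set` arrays.
#' Per-dataset maps for seven public COVID-19 fact-checking datasets ship
#' with the package under `system.file("extdata", "labelmaps", package =
#' "misinfonet")` as editable config data.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  label_map(trustworthy = unlist(cfg$trustworthy_set),
            misinformation = unlist(cfg$misinformation_set))
}

#' Map raw source labels to canonical class labels
#'
#' Applies a [label_map()] to a corpus: documents whose `raw_label` matches
#' the trustworthy set become `"trustworthy"`, matches of the misinformation
#' set become `"misinformation"`, and everything else becomes `"unlabeled"`.
#' Unknown raw labels are not an error. The operation reads only `raw_label`,
#' so it is idempotent.
#'
#' @param corpus A corpus data.frame.
#' @param map A [label_map()].
#' @return The corpus with its `label` column rewritten.
#' @export
normalize_labels <- function(corpus, map) {
  corpus <- as_corpus(corpus)
  stopifnot(inherits(map, "label_map"))
  keys <- .label_key(corpus$raw_label)
  lab <- rep("unlabeled", nrow(corpus))
  lab[keys %in% map$trustworthy_set] <- "trustworthy"
  lab[keys %in% map$misinformation_set] <- "misinformation"
  corpus$label <- lab
  corpus
}

#' Merge corpora from several sources
#'
#' Concatenates corpora after prefixing each document id with its source tag
#' (`"<source>:<id>"`), so ids from different datasets cannot collide; a
#' collision that survives prefixing is an error. The returned corpus carries
#' a `"summary"` attribute with per-source and per-label document counts
#' (also available via [corpus_summary()]).
#'
#' @param corpora A named list of corpus data.frames; names are used as
#'   source tags (falling back to each corpus's own `source` column).
#' @param prefix_ids Prefix ids with the source tag (default `TRUE`).
#' @return A single corpus data.frame.
#' @export
merge_corpora <- function(corpora, prefix_ids = TRUE) {
  stopifnot(is.list(corpora), length(corpora) >= 1)
  tags <- names(corpora)
  pieces <- vector("list", length(corpora))
  for (i in seq_along(corpora)) {
    cp <- as_corpus(corpora[[i]])
    tag <- if (!is.null(tags) && nzchar(tags[i])) tags[i] else cp$source[1]
    if (is.na(tag) || !nzchar(tag)) tag <- paste0("source", i)
    cp$source <- tag
    if (prefix_ids) cp$id <- paste0(tag, ":", cp$id)
    pieces[[i]] <- cp
  }
  merged <- do.call(rbind, pieces)
  dup <- which(duplicated(merged$id))
  if (length(dup)) {
    stop("id collision across sources after prefixing: '",
         merged$id[dup[1]], "'")
  }
  merged <- as_corpus(merged)
  attr(merged, "summary") <- corpus_summary(merged)
  merged
}

#' Per-source and per-label document counts
#'
#' @param corpus A corpus data.frame.
#' @return A list with `n_documents`, a `by_label` named count vector, and a
#'   `by_source_label` contingency table.
#' @export
corpus_summary <- function(corpus) {
  corpus <- as_corpus(corpus)
  lab <- factor(corpus$label, levels = .canonical_labels)
  list(n_documents = nrow(corpus),
       by_label = table(label = lab),
       by_source_label = table(source = corpus$source, label = lab))
}
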