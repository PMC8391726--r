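# Corpus and results readers/writers. The corpus interchange format is
# line-delimited JSON (one narrative per line, UTF-8) with an optional
# per-sentence annotation block, so any external parser can feed the
# pipeline without the core depending on it.

.record_to_json <- function(doc) {
  rec <- list(doc_id = doc$doc_id, text = doc$text)
  if (!is.null(doc$k10_items)) rec$k10_items <- as.integer(doc$k10_items)
  if (!is.null(doc$age_group) && !is.na(doc$age_group)) rec$age_group <- doc$age_group
  if (!is.null(doc$gender) && !is.na(doc$gender)) rec$gender <- doc$gender
  if (!is.null(doc$annotations)) {
    rec$annotations <- lapply(doc$annotations, function(a) {
      list(
        surface = as.character(a$surface), pos = as.character(a$pos),
        chunk_index = as.integer(a$chunk_index),
        chunk_heads = as.integer(a$chunk_heads)
      )
    })
  }
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
}

#' Write a corpus to line-delimited JSON
#'
#' One record per line with fields `doc_id`, `text`, optional `k10_items`,
#' `age_group`, `gender`, and an optional `annotations` array (one block per
#' sentence: `surface`, `pos`, `chunk_index`, `chunk_heads`; chunk indices
#' 0-based, head `-1` marks the root chunk). Files written here read back
#' identically with [read_corpus()].
#'
#' @param documents List of document records (e.g.
#'   `generate_corpus()$documents`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(documents, path) {
  if (!length(documents)) stop("no documents to write", call. = FALSE)
  lines <- vapply(documents, function(d) as.character(.record_to_json(d)), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

.parse_record <- function(line, lineno) {
  rec <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) {
      stop("line ", lineno, ": malformed JSON record (", conditionMessage(e), ")",
        call. = FALSE
      )
    }
  )
  if (is.null(rec$doc_id) || is.null(rec$text) || !nzchar(trimws(rec$text))) {
    stop("line ", lineno, ": record needs non-empty 'doc_id' and 'text'",
      call. = FALSE
    )
  }
  if (!is.null(rec$k10_items)) {
    it <- unlist(rec$k10_items)
    if (length(it) != 10L || any(it != round(it)) || any(it < 1 | it > 5)) {
      stop("line ", lineno, ": k10_items must be 10 integers in 1..5",
        call. = FALSE
      )
    }
    rec$k10_items <- as.integer(it)
  }
  if (!is.null(rec$annotations)) {
    rec$annotations <- lapply(seq_along(rec$annotations), function(s) {
      a <- rec$annotations[[s]]
      need <- c("surface", "pos", "chunk_index", "chunk_heads")
      if (!all(need %in% names(a))) {
        stop("line ", lineno, ": annotation block ", s,
          " lacks required fields",
          call. = FALSE
        )
      }
      list(
        surface = as.character(unlist(a$surface)),
        pos = as.character(unlist(a$pos)),
        chunk_index = as.integer(unlist(a$chunk_index)),
        chunk_heads = as.integer(unlist(a$chunk_heads))
      )
    })
  }
  if (is.null(rec$age_group)) rec$age_group <- NA_character_
  if (is.null(rec$gender)) rec$gender <- NA_character_
  rec[c("doc_id", "text", "k10_items", "age_group", "gender", "annotations")]
}

#' Read a line-delimited JSON corpus
#'
#' Malformed lines are rejected with their line number, never silently
#' repaired; duplicate `doc_id`s are an error. Records come back in file
#' order.
#'
#' @param path Path to a file written by [write_corpus()] or produced by an
#'   external annotator in the same layout.
#' @return A list of document records.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("corpus file is empty: ", path, call. = FALSE)
  docs <- lapply(seq_along(lines), function(i) .parse_record(lines[i], i))
  ids <- vapply(docs, `[[`, "", "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  docs
}

#' Write a comparison table to CSV
#'
#' Writes the cohort report with floats rounded to three decimals (the
#' conventional presentation) and a companion `*_full.csv` with full double
#' precision. Run metadata (test variant, cutoff, emotion mode, truncation
#' limit, seed) is recorded as `#`-prefixed header comment lines so every
#' output is reproducible from its header.
#'
#' @param table A `comparison_table` from [compare_groups()].
#' @param path Output CSV path; the full-precision companion gets a
#'   `_full.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!inherits(table, "comparison_table") || nrow(table) == 0L) {
    stop("`table` must be a non-empty comparison_table", call. = FALSE)
  }
  md <- attr(table, "metadata")
  header <- vapply(names(md), function(k) {
    paste0("# ", k, "=", paste(format(md[[k]]), collapse = ","))
  }, "")
  df <- as.data.frame(table)
  rounded <- df
  for (k in names(df)) {
    if (is.numeric(df[[k]]) && !k %in% c("n_high", "n_low")) {
      rounded[[k]] <- round(df[[k]], 3)
    }
  }
  write_one <- function(d, p) {
    con <- file(p, open = "wb")
    on.exit(close(con))
    writeLines(header, con, useBytes = TRUE)
    utils::write.table(d, con,
      sep = ",", row.names = FALSE, quote = FALSE,
      fileEncoding = ""
    )
  }
  write_one(rounded, path)
  write_one(df, sub("\\.csv$", "_full.csv", path))
  invisible(path)
}
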