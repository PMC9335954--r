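#' @name exports
#' @title Render a saved record for clinical notes and pipelines
#'
#' @description
#' A saved phenotype record is dual-purpose: it must drop into a clinical
#' note as a formatted table, and it must feed downstream bioinformatics
#' pipelines in easily parsed formats.  `to_rtf_table()`, `to_tsv_table()`
#' and `to_markdown_table()` render the record as tables (one header row plus
#' one row per annotation); `to_phenopacket()` emits a minimal
#' Phenopacket-style JSON document.
#'
#' The RTF output is a minimal valid RTF 1.x document: it begins with
#' `{\rtf1\ansi`, ends with `}`, and contains exactly
#' `annotation count + 1` `\row` tokens.  Backslashes and braces in user text
#' are emitted as RTF hex escapes (`\'5c`, `\'7b`, `\'7d`) so user content can
#' neither unbalance the braces nor forge control words.
#'
#' @param record A `phenotype_record`.
#' @return For the table renderers, a `rendered_table` list with fields
#'   `format`, `content` and `row_count` (data rows, excluding the header).
#'   For `to_phenopacket()`, a JSON string.
NULL

table_cells <- function(record) {
  items <- record$annotations
  data.frame(
    id = items$term_id,
    name = items$term_name,
    negated = ifelse(items$negated, "Yes", ""),
    comment = ifelse(is.na(items$comment), "", items$comment),
    added = items$added_at,
    stringsAsFactors = FALSE
  )
}

TABLE_HEADER <- c("HPO ID", "Term Name", "Negated", "Comment", "Date Added")

rtf_escape <- function(x) {
  x <- gsub("\\", "\\'5c", x, fixed = TRUE)
  x <- gsub("{", "\\'7b", x, fixed = TRUE)
  gsub("}", "\\'7d", x, fixed = TRUE)
}

#' @rdname exports
#' @export
to_rtf_table <- function(record) {
  stopifnot(inherits(record, "phenotype_record"))
  cells <- table_cells(record)
  widths <- cumsum(c(1800L, 3600L, 1000L, 2600L, 1800L))
  cellx <- paste0("\\cellx", widths, collapse = "")
  row_rtf <- function(vals) {
    paste0("\\trowd", cellx, " ",
           paste0(rtf_escape(vals), "\\cell", collapse = " "),
           "\\row")
  }
  body <- vapply(seq_len(nrow(cells)), function(i) row_rtf(unlist(cells[i, ])),
                 character(1))
  content <- paste(c("{\\rtf1\\ansi\\deff0", row_rtf(TABLE_HEADER), body, "}"),
                   collapse = "\n")
  structure(list(format = "rtf", content = content, row_count = nrow(cells)),
            class = "rendered_table")
}

#' @rdname exports
#' @export
to_tsv_table <- function(record) {
  stopifnot(inherits(record, "phenotype_record"))
  items <- record$annotations
  clean <- function(x) {
    x <- ifelse(is.na(x), "", x)
    gsub("[\t\r\n]+", " ", x)
  }
  header <- paste(c("term_id", "term_name", "negated", "comment", "added_at"),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(items)), function(i) {
    paste(c(items$term_id[i], clean(items$term_name[i]),
            if (items$negated[i]) "true" else "false",
            clean(items$comment[i]), items$added_at[i]),
          collapse = "\t")
  }, character(1))
  structure(list(format = "tsv",
                 content = paste(c(header, rows), collapse = "\n"),
                 row_count = nrow(items)),
            class = "rendered_table")
}

#' @rdname exports
#' @export
to_markdown_table <- function(record) {
  stopifnot(inherits(record, "phenotype_record"))
  cells <- table_cells(record)
  clean <- function(x) gsub("[\r\n|]+", " ", x)
  line <- function(vals) paste0("| ", paste(clean(vals), collapse = " | "), " |")
  content <- paste(c(line(TABLE_HEADER),
                     paste0("|", paste(rep(" --- |", length(TABLE_HEADER)), collapse = "")),
                     vapply(seq_len(nrow(cells)),
                            function(i) line(unlist(cells[i, ])), character(1))),
                   collapse = "\n")
  structure(list(format = "markdown", content = content, row_count = nrow(cells)),
            class = "rendered_table")
}

#' @rdname exports
#' @export
to_phenopacket <- function(record) {
  stopifnot(inherits(record, "phenotype_record"))
  items <- record$annotations
  features <- lapply(seq_len(nrow(items)), function(i) {
    list(type = list(id = items$term_id[i], label = items$term_name[i]),
         excluded = items$negated[i])
  })
  packet <- list(
    id = record$patient_id,
    phenotypicFeatures = features,
    metaData = list(
      created = record$saved_at,
      resources = list(list(id = "hp", version = record$ontology_version))
    )
  )
  as.character(jsonlite::toJSON(packet, auto_unbox = TRUE, pretty = TRUE, digits = NA))
}

#' Expand a note-template token into a rendered table
#'
#' Emulates SmartLink-style expansion: every occurrence of `token` in the
#' note text is replaced by the record rendered in the requested format.
#' Rendered content is never rescanned, so expansion cannot recurse even if
#' the record's comments contain the token; text without the token is
#' returned unchanged.
#'
#' @param note_text Note text (single string).
#' @param record A `phenotype_record`.
#' @param token Non-empty token to expand (default `".chophpo"`).
#' @param format One of `"rtf"`, `"tsv"`, `"markdown"`.
#' @return The expanded note text.
#' @export
expand_note_token <- function(note_text, record, token = ".chophpo",
                              format = c("rtf", "tsv", "markdown")) {
  stopifnot(is.character(note_text), length(note_text) == 1,
            is.character(token), nzchar(token))
  format <- match.arg(format)
  rendered <- switch(format,
                     rtf = to_rtf_table(record)$content,
                     tsv = to_tsv_table(record)$content,
                     markdown = to_markdown_table(record)$content)
  hits <- gregexpr(token, note_text, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(note_text)
  n <- nchar(token)
  pieces <- character(0)
  last <- 1L
  for (h in hits) {
    pieces <- c(pieces, substr(note_text, last, h - 1L), rendered)
    last <- h + n
  }
  pieces <- c(pieces, substring(note_text, last))
  paste(pieces, collapse = "")
}

#' @export
print.rendered_table <- function(x, ...) {
  cat(sprintf("<rendered_table> format %s, %d data row(s)\n", x$format, x$row_count))
  invisible(x)
}
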