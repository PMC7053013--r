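# Corpus I/O: one JSON record {"id","title","abstract"} per line.

#' Read a JSONL corpus of titled abstracts
#'
#' @param path JSONL file; each line an object with `id`, `title`,
#'   `abstract`.
#' @return Data frame with character columns `id`, `title`, `abstract`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0L, "corpus file is empty", "litqa_parse_error")
  recs <- lapply(lines, jsonlite::fromJSON)
  ids <- vapply(recs, function(r) as.character(r$id), "")
  assert_that(!anyDuplicated(ids), "duplicate document ids in corpus",
              "litqa_parse_error")
  data.frame(id = ids,
             title = vapply(recs, function(r) as.character(r$title %||% ""), ""),
             abstract = vapply(recs, function(r) as.character(r$abstract %||% ""), ""),
             stringsAsFactors = FALSE)
}

#' Write a corpus data frame as JSONL
#' @param corpus Data frame with `id`, `title`, `abstract`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i)
    jsonlite::toJSON(list(id = corpus$id[i], title = corpus$title[i],
                          abstract = corpus$abstract[i]), auto_unbox = TRUE),
    "")
  writeLines(lines, path)
  invisible(path)
}
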