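`%||%` <- function(x, y) if (is.null(x)) y else x

litqa_error <- function(msg, class) {
  stop(structure(class = c(class, "litqa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg, class = "litqa_input_error") {
  if (!isTRUE(cond)) litqa_error(msg, class)
  invisible(TRUE)
}

#' Default stop-word list
#'
#' Returns the packaged English stop-word list used when scoring sentences
#' and selecting candidate terms. High-frequency function words otherwise
#' dominate max-cosine matches in embedding space.
#'
#' @return Character vector of lowercased stop words.
#' @export
litqa_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "litqa")
  readLines(path, warn = FALSE)
}

# split a (possibly multi-word) surface into lowercased tokens
surface_tokens <- function(surface) {
  strsplit(tolower(trimws(surface)), "[ ]+")[[1]]
}

is_number_like <- function(x) grepl("^[0-9]+([.,][0-9]+)*$", x)
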