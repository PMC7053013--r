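# Word/phrase embedding store. Vectors are consumed, never trained here:
# the on-disk format is GloVe text (surface followed by D floats per
# line); multi-token surfaces use underscores on disk and spaces in
# memory.

#' Load GloVe-format text embeddings
#'
#' Each line is `surface v1 ... vD` with a constant dimension D inferred
#' from the first line. Underscore-joined surfaces are stored
#' space-joined.
#'
#' @param path Embedding file path.
#' @return A `litqa_embeddings` store.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0L, "embedding file is empty",
              "litqa_parse_error")
  parts <- strsplit(lines, " ", fixed = TRUE)
  dim <- length(parts[[1L]]) - 1L
  assert_that(dim >= 1L, "embedding file has no vector components",
              "litqa_parse_error")
  bad <- which(vapply(parts, length, 1L) != dim + 1L)
  assert_that(!length(bad),
              paste0("inconsistent embedding dimension at line ", bad[1L]),
              "litqa_parse_error")
  surfaces <- gsub("_", " ", vapply(parts, `[[`, "", 1L), fixed = TRUE)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  if (dim == 1L) mat <- matrix(mat, ncol = 1L)
  rownames(mat) <- tolower(surfaces)
  new_embeddings(mat)
}

new_embeddings <- function(mat) {
  structure(list(matrix = mat, dimension = ncol(mat)),
            class = "litqa_embeddings")
}

#' @export
print.litqa_embeddings <- function(x, ...) {
  cat("<litqa_embeddings> ", nrow(x$matrix), " vectors, dimension ",
      x$dimension, "\n", sep = "")
  invisible(x)
}

#' Write embeddings in GloVe text format
#' @param embeddings A `litqa_embeddings` store.
#' @param path Output path (spaces in surfaces become underscores).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  mat <- embeddings$matrix
  surf <- gsub(" ", "_", rownames(mat), fixed = TRUE)
  lines <- vapply(seq_len(nrow(mat)), function(i)
    paste(surf[i], paste(format(mat[i, ], digits = 9, trim = TRUE,
                                scientific = FALSE), collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Look up an embedding vector
#'
#' @param embeddings A `litqa_embeddings` store.
#' @param surface Surface string (case-insensitive; phrases space-joined).
#' @return Numeric vector, or `NULL` when the surface is absent — an
#'   absent surface is distinguishable from a stored zero vector.
#' @export
embedding_vector <- function(embeddings, surface) {
  key <- tolower(surface)
  mat <- embeddings$matrix
  i <- match(key, rownames(mat))
  if (is.na(i)) NULL else mat[i, ]
}

#' Does the store contain a surface?
#' @inheritParams embedding_vector
#' @return Logical scalar.
#' @export
has_embedding <- function(embeddings, surface) {
  tolower(surface) %in% rownames(embeddings$matrix)
}

# vector for a (possibly multi-token) surface: exact entry when present,
# else the mean of the constituent token vectors, else NULL
phrase_vector <- function(embeddings, surface) {
  v <- embedding_vector(embeddings, surface)
  if (!is.null(v)) return(v)
  toks <- surface_tokens(surface)
  if (length(toks) < 2L) return(NULL)
  vs <- lapply(toks, embedding_vector, embeddings = embeddings)
  vs <- vs[!vapply(vs, is.null, TRUE)]
  if (!length(vs)) return(NULL)
  Reduce(`+`, vs) / length(vs)
}

#' Cosine similarity between two vectors
#'
#' Standard cosine; a zero vector yields 0 (with a warning) rather than
#' an error, so degenerate embeddings cannot abort ranking.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Value in \[-1, 1\].
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0))
#' @export
cosine_similarity <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("cosine of zero vector defined as 0")
    return(0)
  }
  max(min(sum(a * b) / (na * nb), 1), -1)
}
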