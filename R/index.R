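# Reference search backend: an in-memory inverted index with token
# positions (needed for phrase contiguity). The backend contract is a
# list with an `evaluate` function so an external search engine adapter
# can be slotted in; every query semantics test runs against this
# reference implementation.

#' Build an in-memory inverted index over a corpus
#'
#' Indexes the lowercased token stream of title + abstract per document,
#' keeping token positions so phrase disjuncts match only contiguous
#' runs.
#'
#' @param corpus Data frame with `id`, `title`, `abstract`.
#' @return A `litqa_index`.
#' @export
build_index <- function(corpus) {
  assert_that(nrow(corpus) > 0L, "corpus must be non-empty")
  doc_tokens <- lapply(seq_len(nrow(corpus)), function(i)
    tolower(tokenize_text(paste(corpus$title[i], corpus$abstract[i]))$surface))
  postings <- new.env(parent = emptyenv())
  for (d in seq_along(doc_tokens)) {
    toks <- doc_tokens[[d]]
    if (!length(toks)) next
    by_tok <- split(seq_along(toks), toks)
    for (tok in names(by_tok)) {
      cur <- if (exists(tok, envir = postings, inherits = FALSE))
        get(tok, envir = postings) else list()
      cur[[as.character(d)]] <- by_tok[[tok]]
      assign(tok, cur, envir = postings)
    }
  }
  structure(list(postings = postings, doc_ids = corpus$id,
                 doc_tokens = doc_tokens, n_docs = nrow(corpus)),
            class = "litqa_index")
}

#' @export
print.litqa_index <- function(x, ...) {
  cat("<litqa_index> ", x$n_docs, " documents, ",
      length(ls(x$postings)), " distinct tokens\n", sep = "")
  invisible(x)
}

# documents (integer positions) containing a surface; phrases must be
# contiguous token runs
docs_with_surface <- function(index, surface) {
  toks <- surface_tokens(surface)
  if (!length(toks)) return(integer())
  get_post <- function(tok)
    if (exists(tok, envir = index$postings, inherits = FALSE))
      get(tok, envir = index$postings) else list()
  first <- get_post(toks[1L])
  if (!length(first)) return(integer())
  if (length(toks) == 1L) return(sort(as.integer(names(first))))
  rest <- lapply(toks[-1L], get_post)
  hits <- integer()
  for (d in names(first)) {
    pos <- first[[d]]
    ok <- FALSE
    for (p in pos) {
      match_all <- TRUE
      for (k in seq_along(rest)) {
        if (!(d %in% names(rest[[k]])) || !((p + k) %in% rest[[k]][[d]])) {
          match_all <- FALSE
          break
        }
      }
      if (match_all) { ok <- TRUE; break }
    }
    if (ok) hits <- c(hits, as.integer(d))
  }
  sort(hits)
}

#' Evaluate a conjunction-of-disjunctions keyword query
#'
#' A document matches when every active search construct has at least
#' one disjunct present in its title+abstract token stream (phrase
#' disjuncts as contiguous runs). Returned ids are ordered by a simple
#' relevance score (sum over constructs of the best matching disjunct
#' weight), document order breaking ties; `total_hits` is always exact
#' even when ids are capped.
#'
#' @param query A `litqa_query` (see [build_query()]).
#' @param index A `litqa_index`.
#' @param max_ids Cap on the number of returned ids (default 1000).
#' @return List with `ids` (character) and `total_hits` (integer).
#' @export
evaluate_boolean <- function(query, index, max_ids = 1000L) {
  assert_that(inherits(query, "litqa_query"), "query must be a litqa_query")
  active <- query$constructs
  assert_that(length(active) > 0L, "query has no active constructs",
              "litqa_empty_query")
  doc_sets <- list()
  score <- numeric(index$n_docs)
  matched <- rep(TRUE, index$n_docs)
  for (cons in active) {
    cons_docs <- integer()
    best <- numeric(index$n_docs)
    for (i in seq_along(cons$disjuncts)) {
      d <- docs_with_surface(index, cons$disjuncts[i])
      cons_docs <- union(cons_docs, d)
      best[d] <- pmax(best[d], cons$disjunct_weights[i])
    }
    m <- rep(FALSE, index$n_docs)
    m[cons_docs] <- TRUE
    matched <- matched & m
    score <- score + best
  }
  hits <- which(matched)
  total <- length(hits)
  if (total) {
    ord <- hits[order(-score[hits], hits)]
    ids <- index$doc_ids[utils::head(ord, max_ids)]
  } else ids <- character()
  list(ids = ids, total_hits = total)
}

# backend contract used by iterative_retrieve: the reference index is
# wrapped so an adapter exposing $evaluate(query, max_ids) can replace it
as_backend <- function(index) {
  if (inherits(index, "litqa_index"))
    list(evaluate = function(query, max_ids) evaluate_boolean(query, index, max_ids))
  else index
}
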