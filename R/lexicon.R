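# Phrase vocabulary with document frequencies and IDF weights.
#
# Multi-word phrases (2-4 tokens) are mined by collocation hypothesis
# testing (Dunning's log-likelihood ratio): an n-gram is kept as a phrase
# only when its components co-occur far more often than chance predicts.
# Document frequencies are then counted for every word and phrase, and
# idf = ln(N_docs / doc_frequency) is the term weight used throughout
# query construction and answer ranking.

# Dunning log-likelihood ratio for a bigram (a, b):
# 2 * [ logL(k11, c1, p1) + logL(k21, n - c1, p2)
#       - logL(k11, c1, p) - logL(k21, n - c1, p) ]
# with k11 = count(ab), c1 = count(a), k21 = count(b) - count(ab),
# n = total bigram positions.
.ll_term <- function(k, n, p) {
  # k*log(p) + (n-k)*log(1-p), guarding the 0*log(0) limits
  t1 <- if (k > 0) k * log(p) else 0
  t2 <- if (n - k > 0) (n - k) * log1p(-min(p, 1 - 1e-12)) else 0
  t1 + t2
}

llr_bigram <- function(k_ab, k_a, k_b, n) {
  if (k_ab == 0L) return(0)
  p <- k_b / n
  p1 <- k_ab / k_a
  p2 <- (k_b - k_ab) / (n - k_a)
  if (p2 <= 0) p2 <- 1e-12
  ll <- .ll_term(k_ab, k_a, p1) + .ll_term(k_b - k_ab, n - k_a, p2) -
    .ll_term(k_ab, k_a, p) - .ll_term(k_b - k_ab, n - k_a, p)
  s <- 2 * ll
  if (p1 < p) 0 else max(s, 0)    # one-sided: only over-represented pairs
}

count_ngrams <- function(token_lists, n) {
  grams <- unlist(lapply(token_lists, function(toks) {
    L <- length(toks)
    if (L < n) return(character())
    vapply(seq_len(L - n + 1L), function(i)
      paste(toks[i:(i + n - 1L)], collapse = " "), "")
  }))
  if (!length(grams)) return(integer())
  table(grams)
}

#' Mine multi-word phrases by collocation hypothesis testing
#'
#' Scores every 2-gram by Dunning's log-likelihood ratio; longer phrases
#' (3- and 4-grams) are admitted when each adjacent pair inside them
#' passes the test and the full n-gram meets the count floor. Only
#' n-grams whose statistic reaches `threshold` and whose corpus count is
#' at least `min_count` are returned.
#'
#' @param tokenized_corpus List of lowercased token vectors (one per
#'   document).
#' @param min_count Minimum corpus occurrence count for a phrase
#'   (default 5).
#' @param threshold Minimum log-likelihood-ratio statistic (default
#'   10.83, the chi-square 1-df critical value at p = 0.001).
#' @return Character vector of phrase surfaces (space-joined tokens).
#' @export
mine_phrases <- function(tokenized_corpus, min_count = 5L, threshold = 10.83) {
  assert_that(length(tokenized_corpus) > 0L, "corpus must be non-empty")
  assert_that(min_count >= 1L, "min_count must be >= 1")
  token_lists <- lapply(tokenized_corpus, tolower)
  uni <- count_ngrams(token_lists, 1L)
  bi <- count_ngrams(token_lists, 2L)
  n_positions <- sum(vapply(token_lists, function(t) max(length(t) - 1L, 0L), 1L))
  if (!length(bi) || n_positions == 0L) return(character())
  bi <- bi[bi >= min_count]
  if (!length(bi)) return(character())
  parts <- strsplit(names(bi), " ", fixed = TRUE)
  score <- vapply(seq_along(bi), function(i) {
    a <- parts[[i]][1L]; b <- parts[[i]][2L]
    llr_bigram(as.integer(bi[i]), as.integer(uni[a]), as.integer(uni[b]),
               n_positions)
  }, 0)
  good_bi <- names(bi)[score >= threshold]
  out <- good_bi
  # extend to 3- and 4-grams whose internal bigrams all pass
  prev <- good_bi
  for (n in 3:4) {
    if (!length(prev)) break
    grams <- count_ngrams(token_lists, n)
    grams <- grams[grams >= min_count]
    if (!length(grams)) { prev <- character(); next }
    keep <- vapply(names(grams), function(g) {
      toks <- strsplit(g, " ", fixed = TRUE)[[1]]
      pairs <- vapply(seq_len(n - 1L), function(i)
        paste(toks[i], toks[i + 1L]), "")
      all(pairs %in% good_bi)
    }, TRUE)
    prev <- names(grams)[keep]
    out <- c(out, prev)
  }
  sort(unique(out))
}

#' Build the vocabulary with document frequencies and IDF weights
#'
#' Counts, for every surface in `vocabulary`, the number of distinct
#' corpus documents whose title+abstract token stream contains it
#' (phrases matched as contiguous token runs) and derives
#' `idf = ln(N_docs / doc_frequency)`. Surfaces occurring in no document
#' are omitted.
#'
#' @param corpus A corpus data frame (columns `id`, `title`, `abstract`),
#'   e.g. from [read_corpus_jsonl()].
#' @param vocabulary Character vector of word and phrase surfaces.
#' @return A `litqa_lexicon`: lookup environment plus `n_docs` and
#'   `max_idf`.
#' @export
build_document_frequencies <- function(corpus, vocabulary) {
  assert_that(length(vocabulary) > 0L, "vocabulary must be non-empty")
  vocabulary <- unique(tolower(vocabulary))
  n_docs <- nrow(corpus)
  doc_tokens <- lapply(seq_len(n_docs), function(i)
    tolower(tokenize_text(paste(corpus$title[i], corpus$abstract[i]))$surface))
  vocab_parts <- strsplit(vocabulary, " ", fixed = TRUE)
  lens <- lengths(vocab_parts)
  assert_that(all(lens >= 1L & lens <= 4L),
              "vocabulary surfaces must be 1-4 tokens")
  df <- integer(length(vocabulary))
  for (toks in doc_tokens) {
    toks_set <- unique(toks)
    for (v in seq_along(vocabulary)) {
      hit <- if (lens[v] == 1L) vocabulary[v] %in% toks_set
             else phrase_in_tokens(vocab_parts[[v]], toks)
      if (hit) df[v] <- df[v] + 1L
    }
  }
  keep <- df > 0L
  new_lexicon(vocabulary[keep], df[keep], n_docs)
}

new_lexicon <- function(surfaces, doc_frequency, n_docs) {
  idf <- log(n_docs / doc_frequency)
  env <- new.env(parent = emptyenv(), size = max(length(surfaces), 1L))
  for (i in seq_along(surfaces))
    assign(surfaces[i], c(df = doc_frequency[i], idf = idf[i]), envir = env)
  structure(list(env = env, n_docs = n_docs,
                 max_idf = if (length(idf)) max(idf) else 0),
            class = "litqa_lexicon")
}

#' @export
print.litqa_lexicon <- function(x, ...) {
  cat("<litqa_lexicon> ", length(ls(x$env)), " surfaces over ", x$n_docs,
      " documents (max idf ", format(x$max_idf, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Is a surface in the vocabulary?
#' @param lexicon A `litqa_lexicon`.
#' @param surface Surface string.
#' @return Logical scalar.
#' @export
in_vocabulary <- function(lexicon, surface) {
  exists(tolower(surface), envir = lexicon$env, inherits = FALSE)
}

#' IDF weight of a surface
#'
#' Out-of-vocabulary surfaces receive the maximum observed corpus IDF by
#' default (treating an unseen term as maximally rare), or 0 with
#' `oov = "zero"`.
#'
#' @param lexicon A `litqa_lexicon`.
#' @param surface Surface string.
#' @param oov Out-of-vocabulary policy, `"max"` or `"zero"`.
#' @return Non-negative IDF weight.
#' @export
idf_weight <- function(lexicon, surface, oov = c("max", "zero")) {
  oov <- match.arg(oov)
  key <- tolower(surface)
  if (exists(key, envir = lexicon$env, inherits = FALSE))
    return(unname(get(key, envir = lexicon$env)[["idf"]]))
  if (oov == "max") lexicon$max_idf else 0
}

#' Document frequency of a surface (0 when absent)
#' @inheritParams idf_weight
#' @return Integer count.
#' @export
doc_frequency <- function(lexicon, surface) {
  key <- tolower(surface)
  if (exists(key, envir = lexicon$env, inherits = FALSE))
    return(unname(get(key, envir = lexicon$env)[["df"]]))
  0L
}

#' Write / read a lexicon as TSV (surface, doc_frequency, idf)
#' @param lexicon A `litqa_lexicon`.
#' @param path File path.
#' @return `read_lexicon_tsv` returns a `litqa_lexicon`; the writer
#'   returns `path` invisibly.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  surfaces <- sort(ls(lexicon$env))
  rows <- vapply(surfaces, function(s) {
    v <- get(s, envir = lexicon$env)
    paste(s, v[["df"]], format(v[["idf"]], digits = 17), sep = "\t")
  }, "")
  writeLines(c(paste0("#n_docs\t", lexicon$n_docs), rows), path)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_docs <- as.integer(sub("^#n_docs\t", "", lines[1L]))
  lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  new_lexicon(vapply(parts, `[[`, "", 1L),
              as.integer(vapply(parts, `[[`, "", 2L)), n_docs)
}

#' All vocabulary surfaces
#' @param lexicon A `litqa_lexicon`.
#' @return Character vector.
#' @export
lexicon_surfaces <- function(lexicon) sort(ls(lexicon$env))
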