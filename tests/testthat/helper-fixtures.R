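# Shared fixture builders and independent oracles. Oracles are written
# as plain brute-force enumerations so they stay independent of the
# implementation paths they check.

# lexicon with exact IDF weights: df = n * exp(-w) inverts idf = ln(n/df)
toy_lexicon <- function(weights, n_docs = 100) {
  litqa:::new_lexicon(names(weights), n_docs * exp(-unname(weights)), n_docs)
}

# orthonormal embeddings: one basis direction per surface
toy_embeddings <- function(surfaces, dim = length(surfaces)) {
  m <- diag(1, dim)[seq_along(surfaces), , drop = FALSE]
  rownames(m) <- surfaces
  litqa:::new_embeddings(m)
}

embeddings_from_matrix <- function(m) litqa:::new_embeddings(m)

toy_corpus <- function(abstracts, titles = NULL, ids = NULL) {
  n <- length(abstracts)
  data.frame(id = ids %||% sprintf("d%02d", seq_len(n)),
             title = titles %||% rep("", n),
             abstract = abstracts, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- brute-force boolean retrieval oracle -----------------------------

oracle_phrase_present <- function(doc_tokens, phrase_tokens) {
  np <- length(phrase_tokens); nt <- length(doc_tokens)
  if (np > nt) return(FALSE)
  for (s in seq_len(nt - np + 1L)) {
    if (all(doc_tokens[s:(s + np - 1L)] == phrase_tokens)) return(TRUE)
  }
  FALSE
}

# query_groups: list of character vectors (disjunct surfaces)
oracle_boolean_scan <- function(corpus, query_groups) {
  hits <- character()
  for (i in seq_len(nrow(corpus))) {
    toks <- tolower(litqa:::tokenize_text(
      paste(corpus$title[i], corpus$abstract[i]))$surface)
    ok <- all(vapply(query_groups, function(group) {
      any(vapply(group, function(surf) {
        pt <- strsplit(tolower(surf), " +")[[1]]
        oracle_phrase_present(toks, pt)
      }, TRUE))
    }, TRUE))
    if (ok) hits <- c(hits, corpus$id[i])
  }
  hits
}

# ---- exhaustive-transport wRWMD oracle --------------------------------

# enumerates every assignment of each question term to an answer term
# (the transport plan of the relaxation with the answer-side constraint
# dropped is concentrated on one answer term per question term) and
# maximises total weighted cosine
oracle_wrwmd <- function(q_weights, a_surfaces, emb_matrix) {
  q_weights <- unlist(q_weights)
  qs <- names(q_weights)
  cosv <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  na <- length(a_surfaces)
  grid <- do.call(expand.grid, rep(list(seq_len(na)), length(qs)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    tot <- 0
    for (i in seq_along(qs)) {
      tot <- tot + q_weights[[i]] *
        cosv(emb_matrix[qs[i], ], emb_matrix[a_surfaces[grid[r, i]], ])
    }
    best <- max(best, tot)
  }
  best / sum(q_weights)
}

# ---- independent relaxation-policy simulator --------------------------

# groups: list of lists with fields surfaces, weights (parallel),
# kind, protected. Returns the expected drop sequence (surfaces) until
# the scan oracle finds a hit or nothing remains.
oracle_relaxation <- function(corpus, groups) {
  drops <- character()
  repeat {
    active <- Filter(function(g) length(g$surfaces) > 0L, groups)
    if (length(active)) {
      ids <- oracle_boolean_scan(corpus,
                                 lapply(active, function(g) g$surfaces))
      if (length(ids)) return(list(drops = drops, exhausted = FALSE))
    }
    # candidate table
    tab <- do.call(rbind, lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      if (!length(g$surfaces)) return(NULL)
      data.frame(i = i, verb = g$kind == "verb", prot = g$protected,
                 size = length(g$surfaces), maxw = max(g$weights),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(tab) || sum(tab$size) <= 1L)
      return(list(drops = drops, exhausted = TRUE))
    choose_from <- function(sub) {
      if (!nrow(sub)) return(NA_integer_)
      sub$i[order(sub$maxw, sub$i)][1L]
    }
    target <- choose_from(tab[tab$verb & !tab$prot, ])
    if (is.na(target)) target <- choose_from(tab[!tab$verb & !tab$prot & tab$size > 1L, ])
    if (is.na(target)) target <- choose_from(tab[!tab$verb & !tab$prot & tab$size == 1L, ])
    if (is.na(target)) target <- choose_from(tab[tab$prot & tab$size > 1L, ])
    if (is.na(target)) target <- choose_from(tab[tab$prot & tab$size == 1L, ])
    if (is.na(target)) return(list(drops = drops, exhausted = TRUE))
    g <- groups[[target]]
    ord <- order(-g$weights, g$surfaces)      # weight-descending, lex tie
    victim <- ord[length(ord)]
    drops <- c(drops, g$surfaces[victim])
    groups[[target]]$surfaces <- g$surfaces[-victim]
    groups[[target]]$weights <- g$weights[-victim]
  }
}

# build a litqa_query from the same abstract groups
query_from_groups <- function(groups, lexicon) {
  constructs <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    new_search_construct(g$surfaces, g$kind, lexicon,
                         protected = g$protected, position = i)
  })
  with_query_lexicon(litqa:::new_keyword_query(constructs), lexicon)
}

# random engineered relaxation cases over a small corpus
random_relaxation_case <- function(seed) {
  set.seed(seed)
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta")
  n_docs <- sample(4:8, 1)
  corpus <- toy_corpus(vapply(seq_len(n_docs), function(i)
    paste(sample(vocab, sample(2:4, 1)), collapse = " "), ""))
  weights <- stats::setNames(round(stats::runif(length(vocab), 0.1, 3), 3),
                             vocab)
  lexicon <- toy_lexicon(weights, n_docs = 50)
  n_groups <- sample(2:4, 1)
  kinds <- sample(c("verb", "np", "word"), n_groups, replace = TRUE)
  groups <- lapply(seq_len(n_groups), function(i) {
    surfs <- sample(c(vocab, "omega", "sigma"), sample(1:3, 1))
    list(surfaces = surfs,
         weights = vapply(surfs, function(s)
           litqa:::disjunct_weight(lexicon, s), 0),
         kind = kinds[i],
         protected = stats::runif(1) < 0.25)
  })
  # guarantee at least one unprotected group so relaxation can proceed
  groups[[1L]]$protected <- FALSE
  list(corpus = corpus, lexicon = lexicon, groups = groups)
}

# ---- separable reranker fixture ---------------------------------------

# judged runs where every correct answer carries a planted token
make_separable_runs <- function(n_questions, pool = 10, seed = 2) {
  set.seed(seed)
  fillers <- paste0("w", 1:30)
  mk_sent <- function(pos) paste(c(if (pos) "zorbix",
                                   sample(fillers, 5)), collapse = " ")
  lapply(seq_len(n_questions), function(i) {
    cands <- c(vapply(1:(pool - 1), function(j) mk_sent(FALSE), ""),
               mk_sent(TRUE))
    ord <- sample(pool)
    list(question = paste("which agent binds",
                          paste(sample(fillers, 3), collapse = " ")),
         candidates = cands[ord],
         first_correct_rank = which(ord == pool))
  })
}

separable_embeddings <- function() toy_embeddings(c("zorbix", paste0("w", 1:30)))

# ---- misc -------------------------------------------------------------

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
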