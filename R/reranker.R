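# Supervised answer-candidate reranking as sentence-pair classification.
# Training pairs come from judged baseline rankings: per question one
# positive (the annotated first correct answer) and the remaining pool
# members as negatives. The classifier backend is pluggable; the
# packaged backend is a deterministic bag-of-embeddings logistic
# classifier (features: mean question vector, mean sentence vector,
# their absolute difference and product, plus lexical-overlap summary),
# trained by full-batch gradient descent under a fixed seed.

#' Reranker configuration
#'
#' @param max_sequence_length Token cap per sentence (default 64).
#' @param batch_size Training batch size (default 16).
#' @param epochs Training epochs (default 3).
#' @param candidate_pool Ranked-candidate pool size per question
#'   (default 100).
#' @param seed Integer seed.
#' @return A `litqa_reranker_config`.
#' @export
reranker_config <- function(max_sequence_length = 64L, batch_size = 16L,
                            epochs = 3L, candidate_pool = 100L, seed = 42L) {
  cfg <- list(max_sequence_length = as.integer(max_sequence_length),
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              candidate_pool = as.integer(candidate_pool),
              seed = as.integer(seed))
  assert_that(all(unlist(cfg) > 0L), "all reranker config values must be positive")
  structure(cfg, class = "litqa_reranker_config")
}

#' Build sentence-pair training examples from judged rankings
#'
#' @param judged_runs List of per-question records, each with `question`
#'   (string), `candidates` (character vector of ranked sentences, at
#'   most the pool size) and `first_correct_rank` (1-based rank or NA).
#'   Questions with no correct answer in the pool contribute nothing.
#' @param candidate_pool Pool cap (default 100).
#' @return Data frame with `question`, `sentence`, `label`.
#' @export
build_training_pairs <- function(judged_runs, candidate_pool = 100L) {
  rows <- list()
  for (run in judged_runs) {
    r <- run$first_correct_rank
    cands <- utils::head(run$candidates, candidate_pool)
    if (is.null(r) || is.na(r) || r > length(cands)) next
    lab <- integer(length(cands))
    lab[r] <- 1L
    rows[[length(rows) + 1L]] <- data.frame(
      question = run$question, sentence = cands, label = lab,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(question = character(), sentence = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pair_features <- function(question, sentence, embeddings, stops) {
  featurize <- function(text) {
    toks <- unique(tolower(tokenize_text(text)$surface))
    toks <- toks[grepl("[a-z0-9]", toks) & !(toks %in% stops)]
    vs <- lapply(toks, embedding_vector, embeddings = embeddings)
    vs <- vs[!vapply(vs, is.null, TRUE)]
    v <- if (length(vs)) Reduce(`+`, vs) / length(vs)
         else numeric(embeddings$dimension)
    list(vec = v, toks = toks)
  }
  q <- featurize(question); s <- featurize(sentence)
  overlap <- if (length(q$toks)) length(intersect(q$toks, s$toks)) / length(q$toks) else 0
  c(q$vec, s$vec, abs(q$vec - s$vec), q$vec * s$vec,
    overlap, cosine_zero_safe(q$vec, s$vec))
}

cosine_zero_safe <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
}

# deterministic full-batch logistic regression with L2 penalty
fit_logistic <- function(X, y, epochs, lr = 0.5, l2 = 1e-4) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  w <- numeric(ncol(Xs)); b <- 0
  n <- nrow(Xs)
  for (it in seq_len(epochs * 100L)) {
    p <- 1 / (1 + exp(-(Xs %*% w + b)))
    gw <- as.numeric(t(Xs) %*% (p - y)) / n + l2 * w
    gb <- mean(p - y)
    w <- w - lr * gw
    b <- b - lr * gb
  }
  list(w = w, b = b, mu = mu, sd = sdv)
}

#' Fine-tune the sentence-pair reranking classifier
#'
#' @param pairs Data frame from [build_training_pairs()].
#' @param config A [reranker_config()].
#' @param embeddings A `litqa_embeddings` (used by the packaged
#'   backend).
#' @param backend Optional custom backend: a function
#'   `(pairs, config) -> scorer`, where `scorer(question, sentence)`
#'   returns a probability. Defaults to the packaged bag-of-embeddings
#'   logistic classifier.
#' @return A scorer function `(question, sentence) -> probability`.
#' @export
fine_tune <- function(pairs, config = reranker_config(), embeddings = NULL,
                      backend = NULL) {
  assert_that(nrow(pairs) > 0L, "no training pairs")
  assert_that(any(pairs$label == 1L) && any(pairs$label == 0L),
              "training data must contain both classes",
              "litqa_degenerate_data")
  if (!is.null(backend)) return(backend(pairs, config))
  assert_that(!is.null(embeddings),
              "the packaged backend requires embeddings")
  stops <- litqa_stopwords()
  set.seed(config$seed)
  X <- t(vapply(seq_len(nrow(pairs)), function(i)
    pair_features(pairs$question[i], pairs$sentence[i], embeddings, stops),
    numeric(4L * embeddings$dimension + 2L)))
  fit <- fit_logistic(X, pairs$label, epochs = config$epochs)
  function(question, sentence) {
    x <- pair_features(question, sentence, embeddings, stops)
    xs <- (x - fit$mu) / fit$sd
    as.numeric(1 / (1 + exp(-(sum(xs * fit$w) + fit$b))))
  }
}

#' Rerank candidates by classifier probability
#'
#' Sorts candidates by `rerank_prob` descending; the incoming (wRWMD)
#' order is the stable tie-break, so a constant scorer preserves the
#' input ranking.
#'
#' @param candidates A `litqa_candidates` data frame.
#' @param scorer Scorer function from [fine_tune()].
#' @param question Question string (defaults to attribute lookup is not
#'   attempted; pass explicitly).
#' @return Candidates with `rerank_prob` filled, reordered.
#' @export
rerank <- function(candidates, scorer, question) {
  if (!nrow(candidates)) return(candidates)
  probs <- vapply(candidates$sentence, function(s) scorer(question, s), 0,
                  USE.NAMES = FALSE)
  candidates$rerank_prob <- probs
  ord <- order(-probs, seq_len(nrow(candidates)))
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
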