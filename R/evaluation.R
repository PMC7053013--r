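# Evaluation: mean reciprocal rank and Precision@1 over judged
# rankings, plus a heuristic aligner that matches system output against
# gold answer strings (human judging remains authoritative; the aligner
# exists for regression testing).

#' Mean reciprocal rank
#'
#' `MRR = (1/N) * sum_i 1/rank(Q_i)`; questions with no correct answer
#' (rank `NA`) contribute 0.
#'
#' @param judged Data frame with a `rank` column (1-based or `NA`), or a
#'   numeric vector of ranks.
#' @return Value in \[0, 1\].
#' @examples
#' mrr(c(1, 2, NA))
#' @export
mrr <- function(judged) {
  ranks <- if (is.data.frame(judged)) judged$rank else judged
  assert_that(length(ranks) >= 1L, "judged set is empty")
  assert_that(all(is.na(ranks) | ranks >= 1), "ranks must be >= 1")
  mean(ifelse(is.na(ranks), 0, 1 / ranks))
}

#' Precision at rank 1
#'
#' Fraction of questions whose first returned candidate is correct.
#'
#' @inheritParams mrr
#' @return Value in \[0, 1\]; never exceeds [mrr()] on the same set.
#' @export
precision_at_1 <- function(judged) {
  ranks <- if (is.data.frame(judged)) judged$rank else judged
  assert_that(length(ranks) >= 1L, "judged set is empty")
  mean(!is.na(ranks) & ranks == 1)
}

# gold string present in a candidate at token boundaries,
# case-insensitive
contains_gold <- function(sentence, gold) {
  toks <- tolower(tokenize_text(sentence)$surface)
  any(vapply(gold, function(g)
    phrase_in_tokens(surface_tokens(g), toks), TRUE))
}

#' Align a ranked candidate list against gold answer strings
#'
#' Returns the rank of the first candidate within the window containing
#' any gold string (case-insensitive, matched at token boundaries). For
#' list questions a candidate containing at least one list item counts
#' as correct. The result is flagged heuristic: human judging remains
#' authoritative.
#'
#' @param ranked_answers Character vector of candidate sentences in rank
#'   order.
#' @param gold Character vector of exact/ideal answer strings (list
#'   items allowed).
#' @param window How many leading candidates to examine (default 200).
#' @return List with `rank` (integer or `NA`) and `heuristic = TRUE`.
#' @export
align_gold <- function(ranked_answers, gold, window = 200L) {
  gold <- gold[nzchar(trimws(gold))]
  assert_that(length(gold) >= 1L, "gold strings must be non-empty")
  pool <- utils::head(ranked_answers, window)
  for (r in seq_along(pool)) {
    if (contains_gold(pool[r], gold)) return(list(rank = r, heuristic = TRUE))
  }
  list(rank = NA_integer_, heuristic = TRUE)
}

#' Read a BioASQ-style question/gold JSON file
#'
#' Expects `{"questions": [{"body", "type", "exact_answer",
#' "ideal_answer"}, ...]}`; answer fields may be strings or (nested)
#' arrays.
#'
#' @param path JSON file path.
#' @return List of question records with `body`, `type`, `gold`
#'   (character vector of acceptable answer strings).
#' @export
read_bioasq_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  assert_that(!is.null(obj$questions), "no 'questions' field in gold file",
              "litqa_parse_error")
  lapply(obj$questions, function(q) {
    gold <- unique(unlist(c(q$exact_answer, q$ideal_answer)))
    list(body = q$body, type = q$type %||% "factoid",
         gold = as.character(gold))
  })
}

#' Read keyword-annotation training data
#'
#' Loader for deposited keyword-selection annotations: JSONL with one
#' object `{"question": ..., "keyword_labels": [0/1, ...]}` per line
#' (labels aligned with the annotation's own whitespace tokenization,
#' which is authoritative).
#'
#' @param path JSONL file path.
#' @return List of records with `tokens` and `labels`.
#' @export
read_keyword_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    toks <- strsplit(trimws(obj$question), "[[:space:]]+")[[1]]
    labels <- as.integer(obj$keyword_labels)
    assert_that(length(labels) == length(toks),
                "keyword_labels length must match question tokens",
                "litqa_parse_error")
    list(tokens = toks, labels = labels)
  })
}

#' Build an evaluation report
#'
#' @param judged Data frame with columns `question_id`, `rank`, and
#'   optionally `heuristic`.
#' @return A `litqa_eval_report` list: `n_questions`, `mrr`,
#'   `precision_at_1`, `n_unanswered`, `heuristic`.
#' @export
eval_report <- function(judged) {
  structure(list(n_questions = nrow(judged),
                 mrr = mrr(judged),
                 precision_at_1 = precision_at_1(judged),
                 n_unanswered = sum(is.na(judged$rank)),
                 heuristic = isTRUE(any(judged$heuristic))),
            class = "litqa_eval_report")
}

#' @export
print.litqa_eval_report <- function(x, ...) {
  cat("<litqa_eval_report> N=", x$n_questions,
      " MRR=", format(x$mrr, digits = 4),
      " P@1=", format(x$precision_at_1, digits = 4),
      " unanswered=", x$n_unanswered,
      if (x$heuristic) " (heuristic judgments)", "\n", sep = "")
  invisible(x)
}
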