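# Boolean search constructs and greedy iterative query relaxation.
#
# A search construct is an OR-group of surface variants of one question
# term (an NP with its number variants and acronyms, a verb with its
# conjugations and nominalizations, a subphrase, or an individual NP
# word). Constructs are conjoined (AND) into the keyword query. The
# query starts maximally specific and is relaxed greedily: the
# lowest-weight disjunct is dropped from one construct per iteration —
# verb constructs first, then the unprotected construct whose maximum
# element weight is least — until the backend returns documents.
# Constructs protected as recognized entities (usually the question
# focus) are only touched as a last resort.

# weight of one disjunct for sorting and for the construct weight
# formula: in-vocabulary surfaces use their IDF; out-of-vocabulary
# multi-token surfaces use the minimum IDF over their tokens
disjunct_weight <- function(lexicon, surface) {
  if (in_vocabulary(lexicon, surface))
    return(idf_weight(lexicon, surface))
  toks <- surface_tokens(surface)
  if (length(toks) >= 2L)
    return(min(vapply(toks, function(t) idf_weight(lexicon, t, oov = "max"), 0)))
  idf_weight(lexicon, surface, oov = "max")
}

#' Weight of a disjunctional search construct
#'
#' Averages the contribution of each disjunct over the construct size:
#' in-vocabulary disjuncts contribute their IDF weight, out-of-vocabulary
#' disjuncts the minimum IDF over their constituent tokens.
#'
#' @param construct A `litqa_construct` (see [new_search_construct()]).
#' @param lexicon A `litqa_lexicon`.
#' @return Non-negative real weight.
#' @export
construct_weight <- function(construct, lexicon) {
  st <- construct$disjuncts
  assert_that(length(st) >= 1L, "construct has no disjuncts",
              "litqa_empty_construct")
  contrib <- vapply(st, function(s) {
    if (in_vocabulary(lexicon, s)) idf_weight(lexicon, s)
    else {
      toks <- surface_tokens(s)
      min(vapply(toks, function(t) idf_weight(lexicon, t, oov = "max"), 0))
    }
  }, 0)
  sum(contrib) / length(st)
}

#' Create a search construct
#'
#' Disjuncts are weighted by [construct_weight()]'s per-disjunct rule and
#' sorted descending by weight (ties broken lexicographically for
#' determinism).
#'
#' @param disjuncts Character vector of term/phrase surfaces.
#' @param kind One of `"verb"`, `"np"`, `"entity"`, `"word"`,
#'   `"subphrase"`.
#' @param lexicon A `litqa_lexicon`.
#' @param protected Logical: entity-focus constructs are dropped last.
#' @param position Original question-order index (tie-break).
#' @return A `litqa_construct`.
#' @export
new_search_construct <- function(disjuncts, kind, lexicon,
                                 protected = FALSE, position = 0L) {
  disjuncts <- unique(tolower(disjuncts))
  assert_that(length(disjuncts) >= 1L, "construct has no disjuncts",
              "litqa_empty_construct")
  wts <- vapply(disjuncts, disjunct_weight, 0, lexicon = lexicon)
  ord <- order(-wts, disjuncts)
  cons <- structure(list(disjuncts = unname(disjuncts[ord]),
                         disjunct_weights = unname(wts[ord]),
                         kind = kind, protected = protected,
                         position = as.integer(position), weight = NA_real_),
                    class = "litqa_construct")
  cons$weight <- construct_weight(cons, lexicon)
  cons
}

# remove the lowest-weight disjunct; returns NULL when emptied
drop_lowest_disjunct <- function(construct, lexicon) {
  n <- length(construct$disjuncts)
  dropped <- construct$disjuncts[n]
  if (n == 1L) return(list(construct = NULL, dropped = dropped))
  construct$disjuncts <- construct$disjuncts[-n]
  construct$disjunct_weights <- construct$disjunct_weights[-n]
  construct$weight <- construct_weight(construct, lexicon)
  list(construct = construct, dropped = dropped)
}

#' Build the conjunctive keyword query for an analyzed question
#'
#' One OR-construct per noun phrase (disjuncts: the NP, its number
#' variants, its acronym expansions), one per verb (infinitive,
#' conjugations, nominalizations), plus constructs for
#' vocabulary-validated subphrases and individual NP words. Constructs
#' whose primary surface matches a recognized entity in the question are
#' flagged protected.
#'
#' @param question A `litqa_question` from [analyze_question()], or a
#'   candidate-term data frame.
#' @param lexicon A `litqa_lexicon`.
#' @param entities Optional entity-mention data frame (defaults to the
#'   question's own).
#' @return A `litqa_query`.
#' @export
build_query <- function(question, lexicon, entities = NULL) {
  if (inherits(question, "litqa_question")) {
    candidates <- question$candidates
    entities <- entities %||% question$entities
  } else {
    candidates <- question
  }
  assert_that(nrow(candidates) > 0L, "no candidate terms to build a query from")
  ent_surfaces <- if (!is.null(entities) && nrow(entities)) entities$surface
                  else character()
  kinds_main <- c("verb", "np", "entity", "np_word", "subphrase")
  main <- candidates[candidates$kind %in% kinds_main, , drop = FALSE]
  expansions <- candidates[candidates$kind == "expansion", , drop = FALSE]
  constructs <- list()
  pos <- 0L
  for (i in seq_len(nrow(main))) {
    surf <- main$surface[i]
    kind <- switch(main$kind[i], verb = "verb", np = "np", entity = "entity",
                   np_word = "word", subphrase = "subphrase")
    disj <- c(surf, expansions$surface[!is.na(expansions$variant_of) &
                                         expansions$variant_of == surf])
    pos <- pos + 1L
    constructs[[pos]] <- new_search_construct(
      disj, kind, lexicon,
      protected = surf %in% ent_surfaces || main$kind[i] == "entity",
      position = pos)
  }
  # dedupe constructs with identical disjunct sets (keep first/protected)
  keys <- vapply(constructs, function(cs) paste(sort(cs$disjuncts), collapse = "|"), "")
  keep <- !duplicated(keys)
  for (k in which(duplicated(keys))) {
    orig <- which(keys == keys[k])[1L]
    if (constructs[[k]]$protected) constructs[[orig]]$protected <- TRUE
  }
  constructs <- constructs[keep]
  with_query_lexicon(new_keyword_query(constructs), lexicon)
}

new_keyword_query <- function(constructs) {
  structure(list(constructs = constructs, iteration = 0L,
                 history = data.frame(surface = character(),
                                      construct = integer(),
                                      stringsAsFactors = FALSE)),
            class = "litqa_query")
}

#' @export
print.litqa_query <- function(x, ...) {
  cat("<litqa_query> iteration ", x$iteration, ":\n", sep = "")
  for (cs in x$constructs) {
    cat(if (cs$protected) "  *[" else "   [",
        paste(cs$disjuncts, collapse = " OR "), "] <", cs$kind, ", w=",
        format(cs$weight, digits = 3), ">\n", sep = "")
  }
  invisible(x)
}

# choose the construct index to relax next, or NA when nothing may be
# dropped without emptying the query
select_drop_target <- function(constructs) {
  if (length(constructs) == 0L) return(NA_integer_)
  kind <- vapply(constructs, `[[`, "", "kind")
  prot <- vapply(constructs, `[[`, TRUE, "protected")
  size <- vapply(constructs, function(cs) length(cs$disjuncts), 1L)
  maxw <- vapply(constructs, function(cs) max(cs$disjunct_weights), 0)
  posn <- vapply(constructs, `[[`, 1L, "position")
  pick <- function(idx) {
    if (!length(idx)) return(NA_integer_)
    idx[order(maxw[idx], posn[idx])][1L]
  }
  # never drop the final remaining disjunct of the whole query
  total_disjuncts <- sum(size)
  would_empty <- function(idx) total_disjuncts == 1L
  groups <- list(
    which(kind == "verb" & !prot),                  # verbs always first
    which(kind != "verb" & !prot & size > 1L),      # unprotected OR-groups
    which(kind != "verb" & !prot & size == 1L),     # unprotected singletons
    which(prot & size > 1L),                        # protected, reluctantly
    which(prot & size == 1L)                        # last resort
  )
  for (g in groups) {
    cand <- pick(g)
    if (!is.na(cand) && !would_empty(cand)) return(cand)
  }
  NA_integer_
}

#' Iteratively relax a keyword query until documents are returned
#'
#' Evaluates the query; while no documents match, drops the
#' lowest-weight disjunct from one construct per iteration following the
#' relaxation policy (verb constructs first; then unprotected constructs
#' in ascending least-maximum-weight order; a construct emptied of
#' disjuncts leaves the conjunction; protected entity constructs are
#' touched only when every other construct is exhausted to singletons).
#' An initial query already matching more than `max_hits` documents is
#' accepted with its id list truncated.
#'
#' @param query A `litqa_query`.
#' @param index A `litqa_index` or backend handle with an `evaluate`
#'   function.
#' @param max_hits Result-size cap (default 1000).
#' @return List with `result` (`ids`, `total_hits`), `query` (final
#'   state, `iteration` counter and drop `history`), and `exhausted`
#'   (logical).
#' @export
iterative_retrieve <- function(query, index, max_hits = 1000L) {
  assert_that(length(query$constructs) > 0L, "query has no constructs",
              "litqa_empty_query")
  backend <- as_backend(index)
  repeat {
    res <- backend$evaluate(query, max_hits)
    if (res$total_hits >= 1L) {
      res$ids <- utils::head(res$ids, max_hits)
      return(list(result = res, query = query, exhausted = FALSE))
    }
    target <- select_drop_target(query$constructs)
    if (is.na(target)) {
      return(list(result = list(ids = character(), total_hits = 0L),
                  query = query, exhausted = TRUE))
    }
    dropped <- drop_lowest_disjunct(query$constructs[[target]],
                                    lexicon = query_lexicon(query))
    query$history <- rbind(query$history,
                           data.frame(surface = dropped$dropped,
                                      construct = target,
                                      stringsAsFactors = FALSE))
    query$iteration <- query$iteration + 1L
    if (is.null(dropped$construct)) {
      query$constructs[[target]] <- NULL
    } else {
      query$constructs[[target]] <- dropped$construct
    }
  }
}

# construct weights are recomputed on mutation; the lexicon used to
# build the query is cached on it for that purpose
query_lexicon <- function(query) {
  attr(query, "lexicon") %||% new_lexicon(character(), integer(), 1L)
}

#' Attach the lexicon used for weight recomputation during relaxation
#' @param query A `litqa_query`.
#' @param lexicon A `litqa_lexicon`.
#' @return The query with the lexicon attached.
#' @export
with_query_lexicon <- function(query, lexicon) {
  attr(query, "lexicon") <- lexicon
  query
}
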