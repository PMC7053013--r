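# Deterministic rule-based linguistic annotation: tokenisation, sentence
# segmentation, POS tagging (closed-class lexicon + suffix heuristics),
# rule-based lemmatisation and base noun-phrase chunking. The annotator is
# pluggable so an industrial parser can be substituted; the built-in
# fallback is fully deterministic, which the test-suite relies on.

TOKEN_PATTERN <- "[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]"

# closed-class lexicons -------------------------------------------------

.determiners <- c("the", "a", "an", "this", "that", "these", "those", "each",
                  "every", "any", "some", "no", "both", "all", "another")
.wh_words <- c("what", "which", "who", "whom", "whose", "where", "when",
               "why", "how")
.copulas <- c("is", "are", "was", "were", "be", "been", "being", "am")
.auxiliaries <- c("do", "does", "did", "have", "has", "had", "can", "could",
                  "will", "would", "shall", "should", "may", "might", "must")
.prepositions <- c("of", "in", "on", "for", "with", "to", "from", "by", "at",
                   "as", "into", "after", "before", "between", "during",
                   "against", "about", "over", "under", "through", "within",
                   "among", "upon", "via")
.pronouns <- c("it", "its", "they", "them", "their", "he", "she", "his",
               "her", "we", "you", "i", "our", "your", "us", "me", "itself",
               "themselves")
.conjunctions <- c("and", "or", "but", "nor")
.adverbs <- c("very", "not", "also", "usually", "commonly", "currently",
              "often", "mainly", "mostly", "highly", "only", "still", "well")
.degree_words <- c("most", "more", "least", "less")
.comparatives <- c("better", "worse", "greater", "higher", "lower", "larger",
                   "smaller", "fewer")
.superlatives <- c("best", "worst", "greatest", "highest", "lowest",
                   "largest", "smallest")
.adjectives <- c("abundant", "common", "human", "effective", "major",
                 "important", "new", "different", "specific", "abnormal",
                 "chronic", "rare", "genetic", "cellular", "molecular",
                 "clinical", "normal", "severe", "acute", "responsible",
                 "main", "primary", "possible", "several",
                 "novel", "key", "essential", "similar", "various")
.verb_lexicon <- c("cause", "treat", "induce", "inhibit", "diagnose",
                   "affect", "regulate", "encode", "activate", "express",
                   "bind", "associate", "relate", "involve", "use", "play",
                   "produce", "prevent", "target", "block", "stimulate",
                   "suppress", "mediate", "trigger", "lead", "result",
                   "occur", "report", "characterize", "require", "reduce",
                   "increase", "decrease", "contain", "interact", "control",
                   "recommend", "develop", "find", "show", "know", "define")
.abbreviations <- c("e.g", "i.e", "etc", "vs", "fig", "dr", "al", "st",
                    "ca", "approx", "no")
.word_cardinals <- c("one", "two", "three", "four", "five", "six", "seven",
                     "eight", "nine", "ten", "hundred", "thousand")

copula_or_aux <- function(surface) tolower(surface) %in% c(.copulas, .auxiliaries)

# tokenisation ----------------------------------------------------------

tokenize_text <- function(text) {
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(surface = substring(text, starts, starts + lens - 1L),
             char_start = starts, char_end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

# sentence segmentation: break after .!? followed by whitespace and an
# upper-case/digit start, unless the period terminates a known abbreviation
# or a single initial.
sentence_breaks <- function(text) {
  n <- nchar(text)
  breaks <- integer()
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(".", "!", "?")) {
      j <- i
      while (j < n && substr(text, j + 1L, j + 1L) %in% c(".", "!", "?", "\"", "'", ")"))
        j <- j + 1L
      rest <- substr(text, j + 1L, n)
      if (grepl("^[[:space:]]+[\"'(]?[A-Z0-9]", rest)) {
        prev <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, 1L, i - 1L))
        prev <- tolower(sub("\\.$", "", prev))
        if (!(prev %in% .abbreviations) && nchar(prev) != 1L)
          breaks <- c(breaks, j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  breaks
}

# POS tagging -----------------------------------------------------------

tag_token <- function(surface) {
  lw <- tolower(surface)
  if (grepl("^[^A-Za-z0-9]", surface)) return("PUNCT")
  if (is_number_like(surface) || lw %in% .word_cardinals) return("CD")
  if (lw %in% .determiners) return("DT")
  if (lw %in% c("what", "which")) return("WDT")
  if (lw %in% c("who", "whom", "whose")) return("WP")
  if (lw %in% c("where", "when", "why", "how")) return("WRB")
  if (lw %in% .copulas) return("VBZ")       # finer copula tense unused
  if (lw %in% .auxiliaries) return("MD")
  if (lw %in% .prepositions) return("IN")
  if (lw %in% .pronouns) return("PRP")
  if (lw %in% .conjunctions) return("CC")
  if (lw %in% .degree_words) return("RBS")
  if (lw %in% .comparatives) return("JJR")
  if (lw %in% .superlatives) return("JJS")
  if (lw %in% .adverbs) return("RB")
  if (lw %in% .adjectives) return("JJ")
  if (lw %in% .verb_lexicon) return("VB")
  if (grepl("s$", lw) && !grepl("ss$", lw) &&
      verb_base(lw) %in% .verb_lexicon)
    return("VBZ")
  if (grepl("ly$", lw) && nchar(lw) > 3L) return("RB")
  if (grepl("ing$", lw) && nchar(lw) > 5L &&
      verb_base(lw) %in% .verb_lexicon) return("VBG")
  if (grepl("ed$", lw) && nchar(lw) > 4L &&
      verb_base(lw) %in% c(.verb_lexicon, "report")) return("VBN")
  if (grepl("ed$", lw) && nchar(lw) > 5L) return("VBN")
  if (grepl("(s)$", lw) && !grepl("(ss|us|is|ics)$", lw)) return("NNS")
  "NN"
}

# strip -ing / -ed / -s to a base verb form (rule-based)
verb_base <- function(lw) {
  if (grepl("ying$", lw)) return(sub("ying$", "y", lw))
  if (grepl("ing$", lw)) {
    stem <- sub("ing$", "", lw)
    if (nchar(stem) > 2L && substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1L, nchar(stem) - 1L))
      return(substr(stem, 1L, nchar(stem) - 1L))
    if (grepl("[^aeiou][aeiou][^aeiouwxy]$", stem)) return(paste0(stem, "e"))
    if (grepl("(at|os|ir|uc|ag|ul|in|id)$", stem)) return(paste0(stem, "e"))
    return(stem)
  }
  if (grepl("ied$", lw)) return(sub("ied$", "y", lw))
  if (grepl("ed$", lw)) {
    stem <- sub("d$", "", lw)                       # induced -> induce
    if (sub("e$", "", stem) %in% .verb_lexicon || grepl("[^aeiou](at|os|uc|ag|ul|in|id|et)e$", stem))
      return(stem)
    stem2 <- sub("ed$", "", lw)
    if (nchar(stem2) > 2L && substr(stem2, nchar(stem2), nchar(stem2)) ==
        substr(stem2, nchar(stem2) - 1L, nchar(stem2) - 1L))
      return(substr(stem2, 1L, nchar(stem2) - 1L))
    if (stem2 %in% .verb_lexicon) return(stem2)
    if (grepl("[^aeiou][aeiou][^aeiouwxy]$", stem2)) return(paste0(stem2, "e"))
    return(stem2)
  }
  if (grepl("ies$", lw)) return(sub("ies$", "y", lw))
  if (grepl("(ch|sh|x|z|ss|o)es$", lw)) return(sub("es$", "", lw))
  if (grepl("s$", lw) && !grepl("ss$", lw)) return(sub("s$", "", lw))
  lw
}

lemma_of <- function(surface, pos) {
  lw <- tolower(surface)
  if (pos %in% c("VB", "VBZ", "VBD", "VBN", "VBG")) {
    if (lw %in% .copulas) return("be")
    return(verb_base(lw))
  }
  if (pos == "NNS") return(singularize(lw))
  lw
}

# noun-phrase chunking --------------------------------------------------

NP_TAGS <- c("JJ", "JJR", "JJS", "NN", "NNS")

# base NPs match (RBS? JJ*)* (NN|NNS)+: adjectives attach only before a
# noun head, so a predicative adjective after a noun is excluded
chunk_noun_phrases <- function(tokens, sent_id) {
  idx <- which(tokens$sentence == sent_id)
  if (!length(idx)) return(NULL)
  pos <- tokens$pos[idx]
  n <- length(idx)
  out <- list()
  i <- 1L
  while (i <= n) {
    start <- i
    # optional degree word opening an adjective run
    if (pos[i] == "RBS" && i < n && pos[i + 1L] %in% c("JJ", "JJR", "JJS"))
      i <- i + 1L
    while (i <= n && pos[i] %in% c("JJ", "JJR", "JJS")) i <- i + 1L
    if (i <= n && pos[i] %in% c("NN", "NNS")) {
      while (i <= n && pos[i] %in% c("NN", "NNS")) i <- i + 1L
      out[[length(out) + 1L]] <- c(idx[start], idx[i - 1L])
    } else {
      i <- max(i, start + 1L)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# public API ------------------------------------------------------------

#' Built-in deterministic annotator
#'
#' The default annotator handle: a regex tokenizer, a closed-class
#' lexicon plus suffix-rule POS tagger, a rule-based lemmatizer, and a
#' chunk-rule base noun-phrase finder. Identical input always yields an
#' identical annotation. A custom annotator may be supplied to
#' [annotate()] as a list with an `annotate` function obeying the same
#' contract.
#'
#' @return An annotator handle.
#' @export
default_annotator <- function() {
  structure(list(annotate = builtin_annotate, name = "builtin"),
            class = "litqa_annotator")
}

builtin_annotate <- function(text) {
  toks <- tokenize_text(text)
  brks <- sentence_breaks(text)
  sent_of_char <- function(pos) sum(brks < pos) + 1L
  toks$sentence <- if (nrow(toks)) vapply(toks$char_start, sent_of_char, 1L) else integer()
  toks$pos <- if (nrow(toks)) vapply(toks$surface, tag_token, "") else character()
  toks$lemma <- if (nrow(toks)) mapply(lemma_of, toks$surface, toks$pos, USE.NAMES = FALSE) else character()
  n_sent <- if (nrow(toks)) max(toks$sentence) else 0L
  nps <- NULL
  for (s in seq_len(n_sent)) nps <- rbind(nps, chunk_noun_phrases(toks, s))
  sentences <- if (n_sent) data.frame(
    sentence = seq_len(n_sent),
    start_token = vapply(seq_len(n_sent), function(s) min(which(toks$sentence == s)), 1L),
    end_token = vapply(seq_len(n_sent), function(s) max(which(toks$sentence == s)), 1L)
  ) else data.frame(sentence = integer(), start_token = integer(), end_token = integer())
  structure(list(
    text = text, tokens = toks, sentences = sentences,
    noun_phrases = if (is.null(nps)) data.frame(start_token = integer(), end_token = integer())
                   else data.frame(start_token = nps[, 1L], end_token = nps[, 2L])
  ), class = "litqa_annotation")
}

#' Annotate text with tokens, POS tags, lemmas and noun phrases
#'
#' @param text Non-empty character scalar.
#' @param annotator Annotator handle; defaults to [default_annotator()].
#' @return A `litqa_annotation`: the raw text, a token table (surface,
#'   lemma, POS, character offsets, sentence id), sentence token ranges,
#'   and base noun-phrase token ranges.
#' @examples
#' ann <- annotate("Is miR-21 related to carcinogenesis?")
#' ann$tokens$surface
#' @export
annotate <- function(text, annotator = default_annotator()) {
  assert_that(is.character(text) && length(text) == 1L && nzchar(trimws(text)),
              "text must be a non-empty string")
  res <- tryCatch(annotator$annotate(text), error = function(e)
    litqa_error(paste0("annotator failed: ", conditionMessage(e)),
                "litqa_annotator_error"))
  assert_that(inherits(res, "litqa_annotation"),
              "annotator returned an invalid result", "litqa_annotator_error")
  res
}

#' @export
print.litqa_annotation <- function(x, ...) {
  cat("<litqa_annotation> ", nrow(x$sentences), " sentence(s), ",
      nrow(x$tokens), " token(s), ", nrow(x$noun_phrases), " NP(s)\n", sep = "")
  invisible(x)
}

np_surface <- function(start_token, end_token, ann) {
  paste(ann$tokens$surface[start_token:end_token], collapse = " ")
}

# surfaces of all base NPs, in question order
np_surfaces <- function(ann) {
  if (!nrow(ann$noun_phrases)) return(character())
  mapply(np_surface, ann$noun_phrases$start_token, ann$noun_phrases$end_token,
         MoreArgs = list(ann = ann), USE.NAMES = FALSE)
}
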