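# Morphology utilities: number inflection for nouns and noun phrases,
# rule-based verb conjugation, nominalization lookup, acronym resolution.

.irregular_plurals <- c(
  bacterium = "bacteria", datum = "data", criterion = "criteria",
  analysis = "analyses", diagnosis = "diagnoses", hypothesis = "hypotheses",
  phenomenon = "phenomena", genus = "genera", nucleus = "nuclei",
  fungus = "fungi", stimulus = "stimuli", focus = "foci",
  mouse = "mice", man = "men", woman = "women", child = "children",
  foot = "feet", tooth = "teeth", vertebra = "vertebrae", larva = "larvae"
)

.irregular_verbs <- list(
  be =   c("be", "is", "are", "was", "were", "been", "being"),
  have = c("have", "has", "had", "having"),
  do =   c("do", "does", "did", "done", "doing"),
  find = c("find", "finds", "found", "finding"),
  lead = c("lead", "leads", "led", "leading"),
  show = c("show", "shows", "showed", "shown", "showing"),
  know = c("know", "knows", "knew", "known", "knowing"),
  bind = c("bind", "binds", "bound", "binding"),
  give = c("give", "gives", "gave", "given", "giving")
)

pluralize <- function(word) {
  lw <- tolower(word)
  if (lw %in% names(.irregular_plurals)) return(unname(.irregular_plurals[lw]))
  if (lw %in% .irregular_plurals) return(lw)
  if (grepl("is$", lw)) return(sub("is$", "es", lw))    # craniosynostosis
  if (grepl("[^aeiou]y$", lw)) return(sub("y$", "ies", lw))
  if (grepl("(s|x|z|ch|sh)$", lw)) return(paste0(lw, "es"))
  paste0(lw, "s")
}

singularize <- function(word) {
  lw <- tolower(word)
  hit <- names(.irregular_plurals)[.irregular_plurals == lw]
  if (length(hit)) return(hit[1L])
  if (lw %in% names(.irregular_plurals)) return(lw)
  if (grepl("ses$", lw) && nchar(lw) > 4L) {
    greek <- sub("es$", "is", lw)                        # craniosynostoses
    if (grepl("(osis|ysis|asis|esis)$", greek)) return(greek)
    stem <- sub("es$", "", lw)
    if (grepl("s$", stem)) return(stem)                  # viruses -> virus
    return(sub("s$", "", lw))                            # causes -> cause
  }
  if (grepl("(xes|zes|ches|shes)$", lw) && nchar(lw) > 4L)
    return(sub("es$", "", lw))
  if (grepl("ies$", lw) && nchar(lw) > 4L) return(sub("ies$", "y", lw))
  if (grepl("ss$", lw) || grepl("us$", lw) || grepl("is$", lw)) return(lw)
  if (grepl("s$", lw)) return(sub("s$", "", lw))
  lw
}

#' Singular and plural variants of a noun or noun phrase
#'
#' For a multi-token noun phrase the head (final) token is inflected.
#' The operation is idempotent: applying it to any of its outputs yields
#' the same two-element set.
#'
#' @param surface A noun or noun-phrase surface string.
#' @return Character vector with the singular and plural variants
#'   (deduplicated, lowercased).
#' @examples
#' morph_variants("gene")
#' morph_variants("craniosynostosis")
#' @export
morph_variants <- function(surface) {
  toks <- surface_tokens(surface)
  assert_that(length(toks) >= 1L, "surface must contain at least one token")
  head_tok <- toks[length(toks)]
  sing <- singularize(head_tok)
  plur <- pluralize(sing)
  rebuild <- function(h) paste(c(toks[-length(toks)], h), collapse = " ")
  unique(c(rebuild(sing), rebuild(plur)))
}

#' Conjugated forms of a verb lemma
#'
#' Rule-based conjugator returning at least the infinitive, third-person
#' singular, past and gerund forms (irregular verbs from a small table).
#'
#' @param lemma Verb lemma (infinitive form).
#' @return Character vector of surface forms including the lemma.
#' @examples
#' verb_forms("diagnose")
#' @export
verb_forms <- function(lemma) {
  lw <- tolower(trimws(lemma))
  if (lw %in% names(.irregular_verbs)) return(unique(.irregular_verbs[[lw]]))
  third <- if (grepl("[^aeiou]y$", lw)) sub("y$", "ies", lw)
           else if (grepl("(s|x|z|ch|sh|o)$", lw)) paste0(lw, "es")
           else paste0(lw, "s")
  if (grepl("e$", lw)) {
    past <- paste0(lw, "d")
    ger <- paste0(sub("e$", "", lw), "ing")
  } else if (grepl("[^aeiou]y$", lw)) {
    past <- sub("y$", "ied", lw)
    ger <- paste0(lw, "ing")
  } else if (grepl("[^aeiou][aeiou][^aeiouwxy]$", lw) && nchar(lw) <= 5L) {
    last <- substr(lw, nchar(lw), nchar(lw))
    past <- paste0(lw, last, "ed")
    ger <- paste0(lw, last, "ing")
  } else {
    past <- paste0(lw, "ed")
    ger <- paste0(lw, "ing")
  }
  unique(c(lw, third, past, ger))
}

#' Load a nominalization lexicon
#'
#' Reads a two-column TSV (verb lemma, nominal surface); multiple rows per
#' verb accumulate. The packaged default lexicon maps common scientific
#' verbs to their event/result nominals.
#'
#' @param path TSV path; defaults to the packaged lexicon.
#' @return A named list mapping verb lemma to character vector of nominals.
#' @export
load_nominalizations <- function(path = NULL) {
  path <- path %||% system.file("extdata", "nominalizations.tsv", package = "litqa")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  assert_that(!length(bad), paste0("malformed nominalization line ", bad[1L]))
  verbs <- tolower(vapply(parts, `[[`, "", 1L))
  noms <- tolower(vapply(parts, `[[`, "", 2L))
  split(noms, verbs)
}

#' Nominal forms of a verb lemma
#'
#' @param lemma Verb lemma.
#' @param lexicon A nominalization lexicon from [load_nominalizations()].
#' @return Character vector of nominal surfaces (possibly empty).
#' @examples
#' nominalizations("induce", load_nominalizations())
#' @export
nominalizations <- function(lemma, lexicon = load_nominalizations()) {
  unique(lexicon[[tolower(trimws(lemma))]] %||% character())
}

#' Load an acronym table
#'
#' @param path TSV path with lines `acronym<TAB>expansion`.
#' @return Named character vector (names = acronyms, lowercase values).
#' @export
load_acronym_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  assert_that(!length(bad), paste0("malformed acronym line ", bad[1L]))
  stats::setNames(tolower(vapply(parts, `[[`, "", 2L)),
                  vapply(parts, `[[`, "", 1L))
}

acronym_like <- function(surface) {
  grepl("^[A-Z][A-Za-z0-9-]*$", surface) && grepl("[A-Z].*[A-Z0-9]", surface) &&
    nchar(gsub("[^A-Z0-9]", "", surface)) >= 2L && nchar(surface) <= 10L
}

#' Resolve acronyms in an annotated question
#'
#' Detects (i) parenthetical definitions, e.g. a long form directly
#' followed by `(ACRONYM)`, and (ii) acronym/expansion pairs via a lookup
#' table applied in both directions (acronym token present, or an NP that
#' is the expansion of a table acronym).
#'
#' @param question A `litqa_annotation`.
#' @param table Optional named character vector (acronym -> expansion).
#' @return Named character vector mapping acronym to expansion.
#' @export
resolve_acronyms <- function(question, table = NULL) {
  toks <- question$tokens
  out <- character()
  # (i) parenthetical: LONG FORM ( ACR ) — allow a multi-token acronym span
  opens <- which(toks$surface == "(")
  for (o in opens) {
    close <- which(toks$surface == ")" & seq_len(nrow(toks)) > o)
    if (!length(close)) next
    close <- close[1L]
    inner_idx <- (o + 1L):(close - 1L)
    if (!length(inner_idx) || length(inner_idx) > 3L) next
    inner <- paste(toks$surface[inner_idx], collapse = " ")
    if (!acronym_like(toks$surface[inner_idx][1L])) next
    k <- nchar(gsub("[^A-Za-z0-9]", "", inner))
    pre_idx <- which(seq_len(nrow(toks)) < o & toks$pos != "PUNCT")
    if (!length(pre_idx)) next
    window <- max(2L, min(k + 2L, length(pre_idx)))
    for (w in window:2L) {
      cand_idx <- pre_idx[(length(pre_idx) - w + 1L):length(pre_idx)]
      words <- toks$surface[cand_idx]
      first_letter <- tolower(substr(gsub("[^A-Za-z0-9]", "", inner), 1L, 1L))
      if (tolower(substr(words[1L], 1L, 1L)) == first_letter) {
        out[inner] <- paste(words, collapse = " ")
        break
      }
    }
  }
  # (ii) table lookups, both directions
  if (!is.null(table) && length(table)) {
    for (acr in names(table)) {
      acr_toks <- surface_tokens(acr)
      if (phrase_in_tokens(acr_toks, tolower(toks$surface)))
        out[acr] <- unname(table[[acr]])
    }
    text_l <- tolower(question$text)
    for (acr in names(table)) {
      if (grepl(table[[acr]], text_l, fixed = TRUE)) out[acr] <- unname(table[[acr]])
    }
  }
  out
}

# is `phrase` (token vector) a contiguous run inside `tokens`?
phrase_in_tokens <- function(phrase, tokens) {
  np <- length(phrase); nt <- length(tokens)
  if (np == 0L || np > nt) return(FALSE)
  if (np == 1L) return(phrase %in% tokens)
  starts <- which(tokens == phrase[1L])
  for (s in starts) {
    if (s + np - 1L <= nt && all(tokens[s:(s + np - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

# NP normalization: drop leading articles, pronouns, possessives, degree
# words with their adjective, comparatives/superlatives and gerund modifiers.
normalize_np <- function(surface) {
  toks <- strsplit(trimws(surface), "[ ]+")[[1]]
  toks <- toks[!grepl("^'s?$", toks)]
  repeat {
    if (length(toks) <= 1L) break
    t1 <- tolower(toks[1L])
    if (t1 %in% c(.determiners, .pronouns)) { toks <- toks[-1L]; next }
    if (t1 %in% .degree_words) {
      toks <- toks[-1L]
      if (length(toks) > 1L && tag_token(toks[1L]) %in% c("JJ", "JJR", "JJS", "NN"))
        toks <- toks[-1L]                 # "most abundant X" -> "X"
      next
    }
    if (tag_token(toks[1L]) %in% c("JJR", "JJS")) { toks <- toks[-1L]; next }
    if (grepl("ing$", t1) && verb_base(t1) %in% .verb_lexicon && length(toks) > 1L) {
      toks <- toks[-1L]; next             # gerund modifier
    }
    break
  }
  toks <- gsub("'s$", "", toks)
  paste(toks, collapse = " ")
}
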