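# Lookup-based named entity recognition over the nine entity types used
# for question-focus filtering and exact-answer extraction.

#' The nine recognized entity types
#' @return Character vector of type names.
#' @export
entity_types <- function() {
  c("gene", "protein", "enzyme", "disease", "drug", "molecular entity",
    "organism", "anatomical entity", "cellular component")
}

#' Load gazetteer TSV files
#'
#' Each line is `surface<TAB>type`; surfaces are lowercased on load and
#' must map to one of the nine recognized types.
#'
#' @param paths Character vector of TSV file paths.
#' @return A `litqa_gazetteer`.
#' @export
load_gazetteer <- function(paths) {
  surfaces <- character(); types <- character()
  for (path in paths) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) next
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    assert_that(!length(bad),
                paste0("malformed gazetteer line ", bad[1L], " in ", path),
                "litqa_parse_error")
    ty <- tolower(trimws(vapply(parts, `[[`, "", 2L)))
    unknown <- setdiff(unique(ty), entity_types())
    assert_that(!length(unknown),
                paste0("unknown entity type '", unknown[1L], "' in ", path),
                "litqa_parse_error")
    surfaces <- c(surfaces, tolower(trimws(vapply(parts, `[[`, "", 1L))))
    types <- c(types, ty)
  }
  keep <- !duplicated(paste(surfaces, types))
  surfaces <- surfaces[keep]; types <- types[keep]
  n_tokens <- lengths(strsplit(surfaces, " ", fixed = TRUE))
  structure(list(surfaces = surfaces, types = types, n_tokens = n_tokens,
                 max_tokens = if (length(n_tokens)) max(n_tokens) else 0L),
            class = "litqa_gazetteer")
}

#' Build a gazetteer from vectors (used by fixture generation)
#' @param surfaces Character vector of entity surfaces.
#' @param types Parallel character vector of entity types.
#' @return A `litqa_gazetteer`.
#' @export
gazetteer_from_vectors <- function(surfaces, types) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(paste(surfaces, types, sep = "\t"), tmp)
  load_gazetteer(tmp)
}

#' @export
print.litqa_gazetteer <- function(x, ...) {
  cat("<litqa_gazetteer> ", length(x$surfaces), " surfaces, types: ",
      paste(sort(unique(x$types)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Entity type of a surface, or NA
#' @param gazetteer A `litqa_gazetteer`.
#' @param surface Surface string (case-insensitive).
#' @return Type name or `NA_character_`.
#' @export
gazetteer_type <- function(gazetteer, surface) {
  i <- match(tolower(trimws(surface)), gazetteer$surfaces)
  if (is.na(i)) NA_character_ else gazetteer$types[i]
}

#' Tag entity mentions in annotated text
#'
#' Greedy longest-match, left to right, over lowercased token n-grams;
#' returned mentions never overlap and are sorted by position.
#'
#' @param text A `litqa_annotation`.
#' @param gazetteer A `litqa_gazetteer`.
#' @return Data frame with `surface`, `type`, `start_token`, `end_token`,
#'   `sentence`.
#' @export
tag_entities <- function(text, gazetteer) {
  toks <- tolower(text$tokens$surface)
  sent <- text$tokens$sentence
  n <- length(toks)
  out <- list()
  if (!length(gazetteer$surfaces) || n == 0L) {
    return(data.frame(surface = character(), type = character(),
                      start_token = integer(), end_token = integer(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (k in min(gazetteer$max_tokens, n - i + 1L):1) {
      if (k < 1L) break
      span <- i:(i + k - 1L)
      if (length(unique(sent[span])) > 1L) next   # mention within one sentence
      cand <- paste(toks[span], collapse = " ")
      j <- match(cand, gazetteer$surfaces)
      if (!is.na(j)) {
        out[[length(out) + 1L]] <- data.frame(
          surface = cand, type = gazetteer$types[j],
          start_token = i, end_token = i + k - 1L, sentence = sent[i],
          stringsAsFactors = FALSE)
        matched <- k
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  if (!length(out)) {
    return(data.frame(surface = character(), type = character(),
                      start_token = integer(), end_token = integer(),
                      sentence = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
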