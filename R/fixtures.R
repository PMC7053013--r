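# Seeded synthetic fixture generation. The generator emulates the
# pipeline's real inputs — a titled-abstract corpus, GloVe-format
# embeddings, gazetteer TSVs and a BioASQ-style gold file — with
# controlled term co-occurrence so each planted answer sentence is
# uniquely optimal under wRWMD: every content word receives its own
# orthonormal embedding direction, except that entities share the
# latent direction of their type trigger word ("drug" ~ each drug), so
# planted similarities are exact (cosine 0 or 1) by construction.

#' Fixture specification
#'
#' @param n_docs Number of corpus documents (default 50).
#' @param n_qa Number of planted question/answer pairs (default 5).
#' @param embedding_dim Embedding dimension (default 100; must be at
#'   least the number of latent concepts).
#' @param n_filler_words Size of the filler vocabulary (default 30).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `litqa_fixture_spec`.
#' @export
fixture_spec <- function(n_docs = 50L, n_qa = 5L, embedding_dim = 100L,
                         n_filler_words = 30L, seed = 1L) {
  assert_that(n_docs >= 1L, "n_docs must be positive")
  assert_that(n_qa >= 1L && n_qa <= n_docs, "need 1 <= n_qa <= n_docs")
  structure(list(n_docs = as.integer(n_docs), n_qa = as.integer(n_qa),
                 embedding_dim = as.integer(embedding_dim),
                 n_filler_words = as.integer(n_filler_words),
                 seed = as.integer(seed)),
            class = "litqa_fixture_spec")
}

# the five planted QA shapes, cycled when n_qa > 5
qa_shapes <- function() {
  list(
    list(focus_type = "drug", verb = "inhibits",
         q = "Which drug inhibits %s?",
         a = "%s inhibits %s in patients.",
         ans_prefix = "vexorab", obj_prefix = "migratosis",
         obj_type = "disease"),
    list(focus_type = "gene", verb = "causes",
         q = "Which gene causes %s?",
         a = "%s causes %s.",
         ans_prefix = "brcx", obj_prefix = "osteolipidosis",
         obj_type = "disease"),
    list(focus_type = "protein", verb = "binds",
         q = "Which protein binds %s?",
         a = "%s binds %s strongly.",
         ans_prefix = "lhcoprotein", obj_prefix = "glucorin",
         obj_type = "molecular entity"),
    list(focus_type = "disease", verb = "caused",
         q = "Which disease is caused by %s?",
         a = "%s is caused by %s.",
         ans_prefix = "morbusosis", obj_prefix = "xylophilus",
         obj_type = "organism"),
    list(focus_type = "organism", verb = "produces",
         q = "Which organism produces %s?",
         a = "%s produces %s.",
         ans_prefix = "streptomima", obj_prefix = "auxotoxin",
         obj_type = "molecular entity")
  )
}

#' Generate a complete synthetic fixture
#'
#' Produces a corpus, embeddings, gazetteer and gold set in memory and,
#' when `dir` is given, writes them as corpus.jsonl, embeddings.txt,
#' gazetteer.tsv and gold.json. The same seed yields identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory (created if missing).
#' @return List with `corpus` (data frame), `embeddings`, `gazetteer`,
#'   `gold` (list of question records with `body`, `type`, `gold`,
#'   `focus_type`), and `paths` when written.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  assert_that(inherits(spec, "litqa_fixture_spec"),
              "spec must be a litqa_fixture_spec")
  set.seed(spec$seed)
  shapes <- qa_shapes()
  fillers <- paste0("filler", seq_len(spec$n_filler_words))
  qa <- vector("list", spec$n_qa)
  gaz_surfaces <- character(); gaz_types <- character()
  for (k in seq_len(spec$n_qa)) {
    sh <- shapes[[((k - 1L) %% length(shapes)) + 1L]]
    ans <- paste0(sh$ans_prefix, k)
    obj <- paste0(sh$obj_prefix, k)
    qa[[k]] <- list(
      body = sprintf(sh$q, obj),
      answer = ans,
      sentence = sprintf(sh$a, paste0(toupper(substr(ans, 1, 1)),
                                      substr(ans, 2, nchar(ans))), obj),
      focus_type = sh$focus_type, obj = obj, obj_type = sh$obj_type)
    gaz_surfaces <- c(gaz_surfaces, ans, obj)
    gaz_types <- c(gaz_types, sh$focus_type, sh$obj_type)
  }
  # distractor entities: never co-occur with any question's object term
  for (ty in c("drug", "gene", "protein", "disease", "organism")) {
    gaz_surfaces <- c(gaz_surfaces, paste0("other", ty, 1:2))
    gaz_types <- c(gaz_types, rep(ty, 2L))
  }
  gazetteer <- gazetteer_from_vectors(gaz_surfaces, gaz_types)
  # corpus: planted docs first, then filler docs
  docs <- vector("list", spec$n_docs)
  for (k in seq_len(spec$n_qa)) {
    filler_sent <- paste0(paste(sample(fillers, 6L), collapse = " "), ".")
    docs[[k]] <- list(id = sprintf("qa-%02d", k),
                      title = sprintf("Report %d.", k),
                      abstract = paste(qa[[k]]$sentence,
                                       capitalize(filler_sent)))
  }
  distractors <- paste0("other", c("drug", "gene", "protein", "disease",
                                   "organism"))
  for (j in (spec$n_qa + 1L):spec$n_docs) {
    s1 <- paste(sample(fillers, 7L), collapse = " ")
    ent <- paste0(sample(distractors, 1L), sample(1:2, 1L))
    s2 <- paste(ent, paste(sample(fillers, 5L), collapse = " "))
    docs[[j]] <- list(id = sprintf("doc-%02d", j),
                      title = sprintf("Study %d.", j),
                      abstract = paste0(capitalize(s1), ". ",
                                        capitalize(s2), "."))
  }
  corpus <- data.frame(
    id = vapply(docs, `[[`, "", "id"),
    title = vapply(docs, `[[`, "", "title"),
    abstract = vapply(docs, `[[`, "", "abstract"),
    stringsAsFactors = FALSE)
  # embeddings: one orthonormal direction per concept; entities share
  # the direction of their type trigger word
  type_triggers <- c(drug = "drug", gene = "gene", protein = "protein",
                     disease = "disease", organism = "organism",
                     `molecular entity` = "molecule",
                     enzyme = "enzyme", `anatomical entity` = "organ",
                     `cellular component` = "organelle")
  corpus_words <- unique(unlist(lapply(seq_len(nrow(corpus)), function(i)
    tolower(tokenize_text(paste(corpus$title[i], corpus$abstract[i]))$surface))))
  question_words <- unique(unlist(lapply(qa, function(x)
    tolower(tokenize_text(x$body)$surface))))
  all_words <- unique(c(corpus_words, question_words, unname(type_triggers),
                        gaz_surfaces))
  all_words <- all_words[grepl("[a-z]", all_words)]
  concept_of <- stats::setNames(all_words, all_words)
  for (i in seq_along(gaz_surfaces))
    concept_of[gaz_surfaces[i]] <- type_triggers[[gaz_types[i]]]
  concepts <- unique(concept_of)
  assert_that(length(concepts) <= spec$embedding_dim,
              "embedding_dim too small for the concept vocabulary")
  basis <- diag(1, spec$embedding_dim)[seq_along(concepts), , drop = FALSE]
  rownames(basis) <- concepts
  emb_mat <- basis[concept_of[all_words], , drop = FALSE]
  rownames(emb_mat) <- all_words
  embeddings <- new_embeddings(emb_mat)
  gold <- lapply(qa, function(x)
    list(body = x$body, type = "factoid", gold = x$answer,
         focus_type = x$focus_type))
  out <- list(corpus = corpus, embeddings = embeddings,
              gazetteer = gazetteer, gold = gold, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(corpus = file.path(dir, "corpus.jsonl"),
                  embeddings = file.path(dir, "embeddings.txt"),
                  gazetteer = file.path(dir, "gazetteer.tsv"),
                  gold = file.path(dir, "gold.json"))
    write_corpus_jsonl(corpus, paths$corpus)
    write_embeddings(embeddings, paths$embeddings)
    writeLines(paste(gaz_surfaces, gaz_types, sep = "\t"), paths$gazetteer)
    jsonlite::write_json(
      list(questions = lapply(gold, function(g)
        list(body = g$body, type = g$type,
             exact_answer = list(g$gold)))),
      paths$gold, auto_unbox = TRUE)
    out$paths <- paths
  }
  out
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate the planted-rule keyword-selection dataset
#'
#' Synthetic questions are token sequences mixing a designated content
#' lexicon (labelled keywords) with function words (not keywords);
#' every token carries its own orthonormal embedding direction, so the
#' planted rule "content-lexicon tokens are keywords" is recoverable
#' from the embeddings alone.
#'
#' @param n_questions Number of questions (default 500).
#' @param n_content Content-lexicon size (default 40).
#' @param n_function Function-word vocabulary size (default 40).
#' @param min_len,max_len Question length range (defaults 5 and 23).
#' @param embedding_dim Embedding dimension (default 100).
#' @param seed Integer seed.
#' @return List with `encoded` (list for [train_selector()]) and
#'   `embeddings`.
#' @export
generate_selector_data <- function(n_questions = 500L, n_content = 40L,
                                   n_function = 40L, min_len = 5L,
                                   max_len = 23L, embedding_dim = 100L,
                                   seed = 1L) {
  set.seed(seed)
  content <- paste0("term", seq_len(n_content))
  funcs <- paste0("func", seq_len(n_function))
  vocab <- c(content, funcs)
  assert_that(length(vocab) <= embedding_dim,
              "embedding_dim too small for the vocabulary")
  emb_mat <- diag(1, embedding_dim)[seq_along(vocab), , drop = FALSE]
  rownames(emb_mat) <- vocab
  embeddings <- new_embeddings(emb_mat)
  encoded <- lapply(seq_len(n_questions), function(i) {
    len <- sample(min_len:max_len, 1L)
    is_content <- stats::rbinom(len, 1L, 0.5)
    toks <- ifelse(is_content == 1L, sample(content, len, replace = TRUE),
                   sample(funcs, len, replace = TRUE))
    encode_question(toks, embeddings, labels = is_content)
  })
  list(encoded = encoded, embeddings = embeddings)
}
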