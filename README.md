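# litqa

Question answering over corpora of titled abstracts, for text-mining
researchers and engineers who need an end-to-end, retrieval-first QA
baseline that runs entirely offline. Given a question, litqa builds a
weighted boolean keyword query, relaxes it iteratively against an
inverted index until documents come back, ranks the retrieved
sentences by embedding similarity, filters them by the question's
expected entity type, and — for factoid questions — extracts exact
answer phrases. A trainable sentence-pair reranker and a
sequence-labelling keyword selector are optional supervised add-ons.

## The core score

Candidate sentences are ranked by the IDF-weighted relaxed word
mover's distance between the question Q and sentence A over unique
terms:

    wRWMD(Q, A) = Σ_{i∈I_Q} w_i · max_{j∈I_A} cossim(v_i, v_j)
                  ─────────────────────────────────────────────
                            Σ_{k∈I_Q} w_k

where `v` are word/phrase embedding vectors and `w_i = ln(N/df_i)` is
the corpus IDF of term i. This is the closed-form optimum of the
word-mover transportation problem with the answer-side constraint
dropped: each question term ships its mass to its most similar answer
term. Queries are conjunctions of OR-groups ("search constructs")
weighted by

    w_cons = (1/|ST|) [ Σ_{i∈V} w_i + Σ_{i∉V} min_j w_ij ]

(in-vocabulary disjuncts contribute their IDF, out-of-vocabulary
phrases the minimum IDF over their tokens), and relaxation drops the
lowest-weight disjunct of one group per iteration — verbs first,
then least-max-weight groups, recognized entities last.

## A worked example

Everything below runs on a generated fixture — a 50-document corpus
with five planted question/answer pairs, orthonormal "GloVe" vectors
and a nine-type gazetteer:

```r
library(litqa)

fx <- generate_fixture(fixture_spec(seed = 7))
pl <- litqa_pipeline(fx$corpus, fx$embeddings, fx$gazetteer)

ans <- answer_question(pl, "Which drug inhibits migratosis1?")
ans
#> <litqa_answer> top candidates:
#>   1. [1.000] Vexorab1 inhibits migratosis1 in patients.

ans$exact_answers[1, ]
#>     phrase sentence_rank   path score
#> 1 vexorab1             1 entity    NA

run_eval(pl, fx$gold)$report
#> <litqa_eval_report> N=5 MRR=1 P@1=1 unanswered=0 (heuristic judgments)
```

The top candidate scores wRWMD = 1.0 because the planted sentence
contains every question term (or an entity sharing its type's latent
embedding direction); the exact answer comes from the entity path: the
focus "drug" maps to the drug entity type and `vexorab1` is the first
drug mention in the top sentences. The evaluation report aggregates
the per-question rank of the first correct answer into MRR and
Precision@1.

A thin CLI wrapping the same functions ships in `inst/cli/litqa`
(`fixtures`, `ask`, `eval`).

## Package tour

| Area | Entry points |
| --- | --- |
| Vocabulary & embeddings | `mine_phrases`, `build_document_frequencies`, `load_embeddings`, `cosine_similarity` |
| Annotation & morphology | `annotate`, `morph_variants`, `verb_forms`, `nominalizations`, `resolve_acronyms` |
| Question analysis | `analyze_question`, `detect_focus`, `detect_question_type`, `enumerate_subphrases` |
| Entities | `load_gazetteer`, `tag_entities` |
| Retrieval | `build_index`, `build_query`, `construct_weight`, `evaluate_boolean`, `iterative_retrieve` |
| Ranking | `rank_candidates`, `wrwmd_similarity`, `filter_by_focus_type`, `match_definition_patterns` |
| Reranker | `build_training_pairs`, `fine_tune`, `rerank` |
| Keyword selector | `encode_question`, `train_selector`, `select_keywords`, `force_include` |
| Exact answers | `harvest_candidates`, `filter_candidates`, `score_and_rank` |
| Evaluation | `mrr`, `precision_at_1`, `align_gold`, `read_bioasq_json` |
| Pipeline & fixtures | `litqa_pipeline`, `answer_question`, `run_eval`, `generate_fixture` |

The methods vignette (`vignettes/litqa-methods.Rmd`) documents the
model, the relaxation policy, parameter defaults, what the synthetic
fixtures do and do not demonstrate, and the open design decisions.
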