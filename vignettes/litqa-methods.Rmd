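---
title: "Methods: question answering over titled abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: question answering over titled abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litqa)
```

## The problem

Given a corpus of titled abstracts (the shape of a bibliographic
database), litqa answers natural-language questions by returning the
sentences most likely to contain the answer, and, for factoid
questions, a ranked list of exact answer phrases. The design is
retrieval-first: no gold passages are assumed, and everything except
the two optional supervised components (the keyword selector and the
sentence-pair reranker) is unsupervised.

The pipeline is: question analysis → weighted candidate search terms →
conjunction-of-disjunctions boolean query → greedy iterative relaxation
against an inverted index → sentence segmentation → similarity ranking →
focus-entity-type filtering (or definition-pattern promotion) →
optional supervised reranking → exact-answer extraction.

## Vocabulary and term weights

The unit of retrieval and scoring is the *term*: a word or a 2–4-token
phrase. Phrases are mined by collocation hypothesis testing with
Dunning's log-likelihood ratio; an n-gram qualifies when each adjacent
pair inside it is over-represented relative to independence and the
n-gram itself clears a count floor. Defaults are `min_count = 5`
(echoing the frequency floor used to admit terms to the embedding
vocabulary) and `threshold = 10.83`, the 1-df chi-square critical value
at p = 0.001 — a standard, conservative setting for sparse counts. The
test statistic is one-sided: under-represented pairs score zero.

Every term carries an IDF weight `idf = ln(N_docs / doc_frequency)`
with document frequencies counted at the document level (a term twice
in one abstract counts once). The log-ratio form is the conventional
choice; no additional normalization is applied because the ranking
formula below normalizes by the sum of question-term weights anyway.
An out-of-vocabulary term receives the maximum observed corpus IDF:
rare biomedical surface forms (gene symbols, drug names) are exactly
the terms one must not discard, so the rarest-possible assumption is
the safe direction.

## Question analysis

A deterministic rule-based annotator (regex tokenizer, closed-class
lexicon plus suffix-rule POS tagger, rule lemmatizer, base-NP chunker)
provides tokens, sentences, POS tags, lemmas and noun phrases. The
annotator is an injected interface, so a heavier parser can be
substituted; the built-in fallback keeps the package dependency-light
and its determinism is what the test-suite relies on. Base
(non-recursive) NPs are emitted; the pipeline only consumes NP chunks
and the copula/wh structure, so full constituency parsing would add
nothing it uses.

The wh-word is located first. The focus phrase — the NP naming the
expected answer type — is taken as the first NP after the wh-word, or
after the copula/auxiliary when one immediately follows the wh-word.
For a prepositional attachment with "of"/"in", one attachment decision
is made: a relational head noun (mechanism, role, function, cause, …)
or a vocabulary phrase absorbs the post-preposition NP into the focus
("mechanism of action"); otherwise the post-preposition NP becomes the
focus and the preceding NP a modifier. Precedence is wh-adjacent >
post-copula > post-preposition. Questions shaped "what/which is/are
NP (of NP)*" with no further predicate are definition questions;
questions with a focus are factoid-like ("focus"); the rest (yes/no
questions in particular) are "other".

The focus maps to one of nine entity types (gene, protein, enzyme,
disease, drug, molecular entity, organism, anatomical entity, cellular
component) through a configurable head-noun trigger table
("genes" → gene, "drug" → drug, …), falling back to gazetteer lookup
of the whole phrase.

Candidate search terms are then generated: non-copula verbs (lemma
plus conjugations and nominalizations from a packaged verb→nominal
lexicon), normalized NPs (articles, pronouns, possessives, degree
words and gerund modifiers stripped) with singular/plural variants and
resolved acronym expansions, each NP's individual words, and
vocabulary-validated subphrases obtained by dropping tokens from
either end of an NP. Slash words contribute each side separately.
Every candidate is weighted by its IDF; identical surfaces are
deduplicated keeping the maximum weight.

## Boolean retrieval and query relaxation

Each candidate becomes a *search construct*: an OR-group of its
surface variants. Constructs are conjoined into the keyword query. The
weight of a construct averages its disjunct contributions — IDF for
in-vocabulary disjuncts, the minimum token IDF for out-of-vocabulary
phrases — and disjuncts are kept sorted descending by weight.

A document matches when every construct has at least one disjunct
present in its title+abstract token stream, phrases as contiguous
runs. The reference backend is an in-memory inverted index with token
positions; the backend is a narrow interface (`evaluate(query,
max_ids)`), so an external search engine can be slotted in.

The query starts maximally specific and is relaxed greedily until at
least one document matches: per iteration, the lowest-weight disjunct
of one construct is dropped. Verb constructs are always dropped first;
then unprotected multi-disjunct constructs in ascending order of their
maximum element weight; then unprotected singletons (removing the
construct from the conjunction); constructs protected as recognized
entities — usually the question focus — are touched only as a last
resort, and the final remaining disjunct of a query is never dropped
(the query instead reports exhaustion). Ties in construct weight break
by question order and ties in disjunct weight lexicographically, so
relaxation is fully deterministic. A query whose initial form already
exceeds the result cap (default 1000) is accepted with the id list
truncated: the most specific available query is the best one.

Dropping a disjunct narrows an OR-group, so the result set provably
grows only when an emptied group leaves the conjunction; termination
is guaranteed by the finite disjunct count, and the drop policy is
cross-checked in the tests against an independent simulator.

## Answer ranking

Retrieved documents are segmented into sentences (the title is
sentence 0) and each sentence A is scored against the question Q by
the IDF-weighted relaxed word mover's distance over unique terms:

$$
\mathrm{wRWMD}(Q,A) \;=\;
\frac{\sum_{i \in I_Q} w_i \cdot \max_{j \in I_A}
\mathrm{cossim}(v_i, v_j)}{\sum_{k \in I_Q} w_k}
$$

This is the closed-form optimum of the word-mover transportation
problem when the answer-side capacity constraint is dropped: each
question term ships all its mass to its most similar answer term. The
value is a similarity in [−1, 1]; ranking by it descending is
identical to ranking by the corresponding distance 1 − S ascending,
and the package uses the similarity convention throughout. The
equivalence with the exhaustive-transport optimum is asserted in the
acceptance tests to 1e−9.

Numerical and degenerate-input choices: terms are deduplicated on both
sides; stop-words are removed from both index sets before scoring
(they otherwise dominate max-cosine matches); detected vocabulary
phrases replace their constituent words; a question term with no
embedding scores 1 on exact surface occurrence in the answer and 0
otherwise (rare-term signal preserved); an empty answer sentence
scores 0; a zero embedding vector has cosine 0 by definition (with a
warning) rather than raising.

Factoid candidates are then filtered to sentences carrying at least
one entity mention of the focus type (gazetteer lookup, greedy
longest-match). When the filter would empty the list the unfiltered
ranking is returned with a warning — an empty answer helps nobody, and
the fallback is visible in the logs. Definition questions skip the
filter; instead, sentences matching definitional patterns for the
focus ("X is a …", "X, a …", "X is defined as …", "X refers to …") are
promoted above non-matching ones, each group keeping its wRWMD order.

## Supervised components

**Reranker.** Answer reranking is cast as sentence-pair
classification. Training pairs come from judged rankings: per question
one positive (the annotated first correct answer) and the remaining
pool members (default pool 100) as negatives — a deliberately noisy
labelling, since correct answers below the first occurrence become
negatives. The packaged backend is a deterministic bag-of-embeddings
logistic classifier (mean question vector, mean sentence vector, their
absolute difference and product, lexical overlap, cosine; full-batch
gradient descent under a fixed seed). The backend is pluggable: any
function mapping (question, sentence) to a probability can replace
it, and the architecture of the scorer is deliberately not part of the
contract — reranking itself only sorts by probability with the
incoming wRWMD order as the stable tie-break. Configuration defaults
(sequence cap 64, batch 16, 3 epochs, pool 100) are kept even though
the lightweight backend ignores the sequence cap.

**Keyword selector.** A sequence-labelling classifier marks which
question tokens are keywords; selected keywords are force-included in
the initial query by protecting their constructs. Questions are
encoded as fixed 40-position sequences of embedding vectors (zero
padding, truncation beyond 40; the cap reflects a maximum observed
question length of 23 tokens plus headroom), with POS tags encoded
over a fixed inventory. Six architectures are implemented from
scratch in vectorised base R with hand-written backward passes and
Adam: a dense layer over the flattened sequence, an LSTM, a 1-d
convolution (kernel 3), and multi-input variants that pass one-hot POS
tags through an 8-unit rectifier layer before concatenation
(dense–dense, LSTM–dense, stacked LSTM–LSTM). Dropout (default 0.2)
applies to the encoder output during training. Training runs 8-fold
cross-validation — every example held out exactly once — and reports
token-level precision/recall/F1 with padding positions excluded, then
fits a final model on all data. Everything is seeded: identical seeds
give identical fold metrics.

## Synthetic fixtures: what they emulate and what they do not

All tests run offline on generated data. The fixture generator emits
the pipeline's real input formats — a JSONL corpus, GloVe-format text
embeddings, gazetteer TSVs, a BioASQ-style gold JSON — with controlled
term co-occurrence: five planted question/answer shapes (one per focus
type among drug, gene, protein, disease, organism) in a 50-document
corpus whose remaining documents are filler with distractor entities.
Embeddings give every content word its own orthonormal direction,
except that entities share the latent direction of their type trigger
word, so planted similarities are exact (cosine 0 or 1) and each
planted answer sentence is uniquely optimal under wRWMD by
construction. The keyword-selector dataset plants the rule
"content-lexicon tokens are keywords" over 500 questions of 5–23
tokens with the same orthonormal-embedding device.

These constructions make recovery provable, which is the point: they
test the machinery, not the linguistics. Real abstracts have graded
similarities, ambiguous focus phrases, imperfect gazetteers and noisy
judgments; passing on the fixtures says the formulas, policies and
plumbing are implemented as specified, not that the system attains any
particular accuracy on real literature. Quantities that depend on a
real corpus, human judgment or deposited annotations are out of reach
of the fixtures by design; loaders for externally supplied gold files
and keyword annotations (`read_bioasq_json()`,
`read_keyword_annotations()`) provide the offline reproduction path
for users who have those downloads.

Problem sizes used by the test-suite and the acceptance script — a
50-document corpus with 5 planted pairs, 500 selector questions with
8-fold cross-validation, 100-document retrieval oracles, 1000-pair
wRWMD oracle sweeps — were chosen as the smallest sizes at which every
property is exercised with comfortable statistical margin.

## Design choices made where the design was open

- **Collocation test**: Dunning's LLR with `min_count = 5`; the exact
  test used to build any particular reference vocabulary is rarely
  reported, and LLR is the standard choice that is well-calibrated for
  sparse counts.
- **Distance vs similarity**: the wRWMD formula is a similarity; the
  package ranks by it descending and documents 1 − S as the distance —
  the two orderings are identical.
- **Entity matching on surfaces, not lemmas**: gazetteer surfaces are
  matched literally (case-insensitive); biomedical entity surfaces are
  mostly invariant and lemma-matching would add failure modes.
- **NP granularity**: base NPs, not maximal NPs; downstream only needs
  heads and spans.
- **Exact-answer filtering**: the generic-type-word stoplist (seeded
  with the nine type names) and the ≥ 0.8 cosine-to-question filter
  apply to the NP path only; entity-path candidates pass through in
  first-occurrence order, unscored, since the entity type already
  certifies them. Phrase vectors fall back to the mean of token
  vectors when the phrase itself is not in the embedding vocabulary;
  with no vectors at all the score is 0.
- **Subphrase ranks**: subphrases inherit their parent NP's sentence
  rank; score ties break by sentence rank then surface.

## Known limitations

The rule-based annotator covers question-shaped and abstract-shaped
English; it is not a general parser, and its verb detection leans on a
domain verb lexicon plus suffix heuristics. Coordination handling is
limited to what base-NP chunking yields. The gold aligner is
heuristic (token-boundary containment of a gold string) and is
flagged as such in every report; it exists for regression testing, not
as a replacement for human judgment. The reranker's packaged backend
is a linear model over embedding summaries — sufficient for the
contract and for separable data, and replaceable where more capacity
is needed.

## A worked example

```{r example}
fx <- generate_fixture(fixture_spec(seed = 7))
pl <- litqa_pipeline(fx$corpus, fx$embeddings, fx$gazetteer)
ans <- answer_question(pl, fx$gold[[1]]$body)
ans$candidates[1, c("sentence", "wrwmd_score")]
ans$exact_answers[1, ]
run_eval(pl, fx$gold)$report
```
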