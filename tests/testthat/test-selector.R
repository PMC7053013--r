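small_selector_data <- function(n = 48, seed = 5) {
  generate_selector_data(n_questions = n, n_content = 10, n_function = 10,
                         min_len = 4, max_len = 10, embedding_dim = 20,
                         seed = seed)
}

fast_config <- function(arch = "lstm", seed = 3) {
  selector_config(arch, seed = seed, epochs = 30, hidden = 8, filters = 8,
                  batch_size = 16, lr = 0.02)
}

test_that("question encoding pads, truncates and flags prediction-only input", {
  emb <- toy_embeddings(c("alpha", "beta"), dim = 4)
  enc <- encode_question(rep(c("alpha", "beta"), 10), emb,
                         labels = rep(c(1, 0), 10))
  expect_equal(dim(enc$X), c(40, 4))
  expect_equal(enc$true_length, 20)
  expect_true(all(enc$X[21:40, ] == 0))
  expect_true(all(enc$labels[21:40] == 0))
  # truncation of a 45-token question
  enc2 <- encode_question(rep("alpha", 45), emb)
  expect_equal(enc2$true_length, 40)
  expect_true(enc2$prediction_only)
  # OOV tokens map to zero vectors
  enc3 <- encode_question(c("alpha", "unknowntoken"), emb)
  expect_true(all(enc3$X[2, ] == 0))
})

test_that("fold metrics exclude padding and match hand-computed confusion counts", {
  prob <- rbind(c(0.9, 0.2, 0.8, 0.7), c(0.1, 0.6, 0.3, 0.9))
  Y <- rbind(c(1, 0, 0, 1), c(0, 1, 0, 1))
  mask <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0))   # only 5 live positions
  m <- litqa:::token_metrics(prob, Y, mask, 0.5)
  # live predictions: (1,0,1) vs (1,0,0) and (0,1) vs (0,1):
  # tp=2 fp=1 fn=0
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["f1"]), 2 * (2 / 3) / (2 / 3 + 1))
})

test_that("cross-validation partitions the data and is seed-deterministic", {
  sd <- small_selector_data()
  cfg <- fast_config()
  set.seed(cfg$seed)
  fold_of <- sample(rep(seq_len(cfg$folds), length.out = length(sd$encoded)))
  expect_equal(sort(unique(fold_of)), 1:8)
  expect_equal(length(fold_of), length(sd$encoded))
  sel1 <- train_selector(sd$encoded, cfg)
  sel2 <- train_selector(sd$encoded, cfg)
  expect_equal(sel1$fold_metrics, sel2$fold_metrics)
  expect_equal(sel1$mean, sel2$mean)
})

test_that("degenerate labels and undersized data are rejected", {
  emb <- toy_embeddings(c("alpha", "beta"), dim = 4)
  allzero <- lapply(1:16, function(i)
    encode_question(c("alpha", "beta"), emb, labels = c(0, 0)))
  expect_error(train_selector(allzero, fast_config()),
               class = "litqa_degenerate_data")
  few <- lapply(1:5, function(i)
    encode_question(c("alpha", "beta"), emb, labels = c(1, 0)))
  expect_error(train_selector(few, fast_config()), "folds")
})

test_that("keyword selection respects the threshold and positional semantics", {
  sd <- small_selector_data()
  sel <- train_selector(sd$encoded, fast_config())
  # a rule-conforming question: content tokens selected, function tokens not
  q <- c("term1", "func2", "term3", "func4", "term5")
  got <- select_keywords(q, sel, sd$embeddings)
  expect_setequal(got, c("term1", "term3", "term5"))
  # impossible threshold selects nothing
  expect_length(select_keywords(q, sel, sd$embeddings, threshold = 1.01), 0)
  # duplicated token above threshold is returned once per position
  got2 <- select_keywords(c("term1", "func2", "term1"), sel, sd$embeddings)
  expect_equal(got2, c("term1", "term1"))
})

test_that("force-included keywords protect their constructs", {
  lex <- toy_lexicon(c(alpha = 1, beta = 2, gamma = 3))
  q <- litqa:::new_keyword_query(list(
    new_search_construct(c("alpha", "beta"), "np", lex, position = 1),
    new_search_construct("gamma", "word", lex, position = 2)))
  out <- force_include(q, "gamma")
  expect_false(out$constructs[[1]]$protected)
  expect_true(out$constructs[[2]]$protected)
  # unknown keyword changes nothing
  out2 <- force_include(q, "nothere")
  expect_false(any(vapply(out2$constructs, `[[`, TRUE, "protected")))
  # all selected: relaxation still proceeds under the base policy
  out3 <- force_include(q, c("alpha", "gamma"))
  expect_true(all(vapply(out3$constructs, `[[`, TRUE, "protected")))
  corpus <- toy_corpus("gamma only here")
  ret <- iterative_retrieve(with_query_lexicon(out3, lex),
                            build_index(corpus))
  expect_false(ret$exhausted)
  expect_equal(ret$result$total_hits, 1)
})
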