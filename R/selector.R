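# Supervised keyword selection: a sequence-labelling classifier over
# fixed-length (40-position) questions marks which tokens are keywords;
# selected keywords are then force-included in the initial boolean
# query. Six architectures are supported: a dense layer over the
# flattened embedding sequence, an LSTM, a 1-d convolutional encoder,
# and multi-input variants that add a POS-tag branch encoded by a small
# rectifier layer before the sigmoid outputs.

SELECTOR_POS_TAGS <- c("NN", "NNS", "JJ", "JJR", "JJS", "RB", "RBS", "VB",
                       "VBZ", "VBD", "VBN", "VBG", "MD", "DT", "PDT", "IN",
                       "CC", "PRP", "WDT", "WP", "WRB", "CD", "PUNCT",
                       "OTHER")

pos_code <- function(tags) {
  i <- match(tags, SELECTOR_POS_TAGS)
  i[is.na(i)] <- match("OTHER", SELECTOR_POS_TAGS)
  i
}

#' Selector configuration
#'
#' @param architecture One of `"dense"`, `"lstm"`, `"conv1d"`,
#'   `"dense_dense"`, `"lstm_dense"`, `"lstm_lstm"`.
#' @param dropout Dropout probability on the encoder output
#'   (default 0.2).
#' @param threshold Keyword decision threshold on the sigmoid output
#'   (default 0.5).
#' @param seed Integer seed controlling fold assignment, initialisation
#'   and dropout.
#' @param folds Cross-validation folds (default 8).
#' @param epochs Training epochs (default 20).
#' @param hidden LSTM hidden units (default 24).
#' @param filters Convolution filters (default 24).
#' @param pos_units POS-branch rectifier units (default 8).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate (default 0.01).
#' @param max_len Fixed sequence length (default 40).
#' @return A `litqa_selector_config`.
#' @export
selector_config <- function(architecture = c("lstm", "dense", "conv1d",
                                             "dense_dense", "lstm_dense",
                                             "lstm_lstm"),
                            dropout = 0.2, threshold = 0.5, seed = 1L,
                            folds = 8L, epochs = 20L, hidden = 24L,
                            filters = 24L, pos_units = 8L, batch_size = 64L,
                            lr = 0.01, max_len = 40L) {
  architecture <- match.arg(architecture)
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(architecture = architecture, dropout = dropout,
                 threshold = threshold, seed = as.integer(seed),
                 folds = as.integer(folds), epochs = as.integer(epochs),
                 hidden = as.integer(hidden), filters = as.integer(filters),
                 pos_units = as.integer(pos_units),
                 batch_size = as.integer(batch_size), lr = lr,
                 max_len = as.integer(max_len)),
            class = "litqa_selector_config")
}

#' Encode a question for the keyword selector
#'
#' Looks up the embedding vector for each token (out-of-vocabulary
#' tokens map to zero vectors), zero-pads or truncates to `max_len`
#' positions and encodes POS tags over a fixed inventory. When `labels`
#' is supplied its tokenization is authoritative; otherwise the encoding
#' is marked prediction-only with all labels zero.
#'
#' @param q A `litqa_annotation`, a character scalar question, or a
#'   character vector of tokens.
#' @param embeddings A `litqa_embeddings`.
#' @param labels Optional 0/1 vector, one per token.
#' @param max_len Fixed length (default 40).
#' @param annotator Annotator used when `q` is a raw string.
#' @return List with `X` (max_len x D matrix), `pos` (integer codes),
#'   `labels`, `true_length`, `tokens`, `prediction_only`.
#' @export
encode_question <- function(q, embeddings, labels = NULL, max_len = 40L,
                            annotator = default_annotator()) {
  if (inherits(q, "litqa_annotation")) {
    tokens <- q$tokens$surface
    tags <- q$tokens$pos
  } else if (is.character(q) && length(q) == 1L && grepl("[[:space:]]", q)) {
    ann <- annotate(q, annotator)
    tokens <- ann$tokens$surface
    tags <- ann$tokens$pos
  } else {
    tokens <- as.character(q)
    tags <- vapply(tokens, tag_token, "")
  }
  n <- length(tokens)
  true_len <- min(n, max_len)
  tokens <- tokens[seq_len(true_len)]
  tags <- tags[seq_len(true_len)]
  D <- embeddings$dimension
  X <- matrix(0, max_len, D)
  for (i in seq_len(true_len)) {
    v <- embedding_vector(embeddings, tokens[i])
    if (!is.null(v)) X[i, ] <- v
  }
  pos <- rep(match("OTHER", SELECTOR_POS_TAGS), max_len)
  pos[seq_len(true_len)] <- pos_code(tags)
  lab <- integer(max_len)
  prediction_only <- is.null(labels)
  if (!prediction_only) {
    labels <- as.integer(labels)
    lab[seq_len(true_len)] <- labels[seq_len(true_len)]
  }
  list(X = X, pos = pos, labels = lab, true_length = true_len,
       tokens = tokens, prediction_only = prediction_only)
}

stack_encoded <- function(encoded, max_len) {
  n <- length(encoded)
  D <- ncol(encoded[[1L]]$X)
  X <- array(0, c(n, max_len, D))
  POS <- matrix(match("OTHER", SELECTOR_POS_TAGS), n, max_len)
  Y <- matrix(0, n, max_len)
  len <- integer(n)
  for (i in seq_len(n)) {
    X[i, , ] <- encoded[[i]]$X
    POS[i, ] <- encoded[[i]]$pos
    Y[i, ] <- encoded[[i]]$labels
    len[i] <- encoded[[i]]$true_length
  }
  mask <- outer(len, seq_len(max_len), `>=`) * 1
  list(X = X, POS = POS, Y = Y, len = len, mask = mask)
}

# ---- architectures ----------------------------------------------------

selector_init_params <- function(cfg, D) {
  T_ <- cfg$max_len; h <- cfg$hidden; nP <- length(SELECTOR_POS_TAGS)
  pu <- cfg$pos_units
  switch(cfg$architecture,
    dense = list(out = list(W = rand_mat(T_ * D, T_, 0.05),
                            b = matrix(0, 1L, T_))),
    lstm = list(enc = lstm_init(D, h), out = td_dense_init(h, 1L)),
    conv1d = list(enc = conv1d_init(D, cfg$filters),
                  out = td_dense_init(cfg$filters, 1L)),
    dense_dense = list(pos = td_dense_init(nP, pu),
                       out = list(W = rand_mat(T_ * (D + pu), T_, 0.05),
                                  b = matrix(0, 1L, T_))),
    lstm_dense = list(enc = lstm_init(D, h), pos = td_dense_init(nP, pu),
                      out = td_dense_init(h + pu, 1L)),
    lstm_lstm = list(pos = td_dense_init(nP, pu),
                     enc = lstm_init(D + pu, h),
                     enc2 = lstm_init(h, h),
                     out = td_dense_init(h, 1L)))
}

selector_forward <- function(params, cfg, Xl, Pl, train = FALSE) {
  T_ <- cfg$max_len; h <- cfg$hidden
  n <- nrow(Xl[[1L]])
  drop_p <- if (train) cfg$dropout else 0
  cache <- list()
  td_logits <- function(Hl, outp) {
    fw <- td_dense_forward(outp, Hl)
    list(logits = do.call(cbind, lapply(fw$Z, as.numeric)), fwd = fw)
  }
  apply_dropout <- function(Hl) {
    if (drop_p <= 0) return(list(H = Hl, masks = NULL))
    masks <- lapply(Hl, function(hm) dropout_mask(nrow(hm), ncol(hm), drop_p))
    list(H = Map(`*`, Hl, masks), masks = masks)
  }
  if (cfg$architecture == "dense") {
    Xf <- do.call(cbind, Xl)
    dm <- if (drop_p > 0) dropout_mask(nrow(Xf), ncol(Xf), drop_p) else NULL
    Xfd <- if (is.null(dm)) Xf else Xf * dm
    logits <- Xfd %*% params$out$W +
      matrix(params$out$b, n, T_, byrow = TRUE)
    cache <- list(Xf = Xfd, dm = dm)
  } else if (cfg$architecture == "lstm") {
    fw <- lstm_forward(params$enc, Xl, h)
    dr <- apply_dropout(fw$H)
    tl <- td_logits(dr$H, params$out)
    logits <- tl$logits
    cache <- list(enc = fw, dr = dr, out = tl$fwd)
  } else if (cfg$architecture == "conv1d") {
    fw <- conv1d_forward(params$enc, Xl)
    dr <- apply_dropout(fw$Z)
    tl <- td_logits(dr$H, params$out)
    logits <- tl$logits
    cache <- list(enc = fw, dr = dr, out = tl$fwd)
  } else if (cfg$architecture == "dense_dense") {
    pf <- td_dense_forward(params$pos, Pl, relu = TRUE)
    Cl <- Map(cbind, Xl, pf$Z)
    Xf <- do.call(cbind, Cl)
    dm <- if (drop_p > 0) dropout_mask(nrow(Xf), ncol(Xf), drop_p) else NULL
    Xfd <- if (is.null(dm)) Xf else Xf * dm
    logits <- Xfd %*% params$out$W +
      matrix(params$out$b, n, T_, byrow = TRUE)
    cache <- list(pos = pf, Xf = Xfd, dm = dm, dcol = ncol(Xl[[1L]]))
  } else if (cfg$architecture == "lstm_dense") {
    fw <- lstm_forward(params$enc, Xl, h)
    pf <- td_dense_forward(params$pos, Pl, relu = TRUE)
    Cl <- Map(cbind, fw$H, pf$Z)
    dr <- apply_dropout(Cl)
    tl <- td_logits(dr$H, params$out)
    logits <- tl$logits
    cache <- list(enc = fw, pos = pf, dr = dr, out = tl$fwd)
  } else {                                     # lstm_lstm
    pf <- td_dense_forward(params$pos, Pl, relu = TRUE)
    Cl <- Map(cbind, Xl, pf$Z)
    fw1 <- lstm_forward(params$enc, Cl, h)
    fw2 <- lstm_forward(params$enc2, fw1$H, h)
    dr <- apply_dropout(fw2$H)
    tl <- td_logits(dr$H, params$out)
    logits <- tl$logits
    cache <- list(pos = pf, enc = fw1, enc2 = fw2, dr = dr, out = tl$fwd,
                  dcol = ncol(Xl[[1L]]))
  }
  list(prob = sigmoid(logits), cache = cache)
}

selector_backward <- function(params, cfg, fwdres, G) {
  # G: (n x T) gradient of loss wrt logits
  T_ <- cfg$max_len; h <- cfg$hidden
  cc <- fwdres$cache
  Gl <- lapply(seq_len(T_), function(t) G[, t, drop = FALSE])
  redrop <- function(dHl, masks) {
    if (is.null(masks)) dHl else Map(`*`, dHl, masks)
  }
  if (cfg$architecture == "dense") {
    dW <- crossprod(cc$Xf, G)
    db <- colSums(G)
    return(list(out = list(W = dW, b = db)))
  }
  if (cfg$architecture %in% c("lstm", "conv1d")) {
    ob <- td_dense_backward(params$out, cc$out, Gl)
    dH <- redrop(ob$dX, cc$dr$masks)
    if (cfg$architecture == "lstm") {
      eb <- lstm_backward(params$enc, cc$enc, dH, h)
      return(list(enc = eb$grads, out = ob$grads))
    }
    eb <- conv1d_backward(params$enc, cc$enc, dH)
    return(list(enc = eb$grads, out = ob$grads))
  }
  if (cfg$architecture == "dense_dense") {
    dW <- crossprod(cc$Xf, G)
    db <- colSums(G)
    dXf <- tcrossprod(G, params$out$W)
    if (!is.null(cc$dm)) dXf <- dXf * cc$dm
    width <- cc$dcol + cfg$pos_units
    dEl <- lapply(seq_len(T_), function(t) {
      cols <- ((t - 1L) * width + cc$dcol + 1L):(t * width)
      dXf[, cols, drop = FALSE]
    })
    pb <- td_dense_backward(params$pos, cc$pos, dEl)
    return(list(pos = pb$grads, out = list(W = dW, b = db)))
  }
  if (cfg$architecture == "lstm_dense") {
    ob <- td_dense_backward(params$out, cc$out, Gl)
    dC <- redrop(ob$dX, cc$dr$masks)
    dH <- lapply(dC, function(m) m[, seq_len(h), drop = FALSE])
    dE <- lapply(dC, function(m) m[, (h + 1L):ncol(m), drop = FALSE])
    eb <- lstm_backward(params$enc, cc$enc, dH, h)
    pb <- td_dense_backward(params$pos, cc$pos, dE)
    return(list(enc = eb$grads, pos = pb$grads, out = ob$grads))
  }
  # lstm_lstm
  ob <- td_dense_backward(params$out, cc$out, Gl)
  dH2 <- redrop(ob$dX, cc$dr$masks)
  eb2 <- lstm_backward(params$enc2, cc$enc2, dH2, h)
  eb1 <- lstm_backward(params$enc, cc$enc, eb2$dX, h)
  dC <- eb1$dX
  dE <- lapply(dC, function(m) m[, (cc$dcol + 1L):ncol(m), drop = FALSE])
  pb <- td_dense_backward(params$pos, cc$pos, dE)
  list(pos = pb$grads, enc = eb1$grads, enc2 = eb2$grads, out = ob$grads)
}

train_selector_model <- function(stacked, cfg, idx) {
  D <- dim(stacked$X)[3L]
  params <- selector_init_params(cfg, D)
  state <- adam_init(params)
  n <- length(idx)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- idx[sample.int(n)]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (b in batches) {
      Xl <- array_to_list(stacked$X, b)
      Pl <- pos_onehot_list(stacked$POS, b, length(SELECTOR_POS_TAGS))
      fw <- selector_forward(params, cfg, Xl, Pl, train = TRUE)
      M <- stacked$mask[b, , drop = FALSE]
      G <- (fw$prob - stacked$Y[b, , drop = FALSE]) * M / max(sum(M), 1)
      grads <- selector_backward(params, cfg, fw, G)
      step <- step + 1L
      upd <- adam_step(params, grads, state, cfg$lr, step)
      params <- upd$params; state <- upd$state
    }
  }
  params
}

selector_predict <- function(params, cfg, stacked, idx) {
  Xl <- array_to_list(stacked$X, idx)
  Pl <- pos_onehot_list(stacked$POS, idx, length(SELECTOR_POS_TAGS))
  selector_forward(params, cfg, Xl, Pl, train = FALSE)$prob
}

token_metrics <- function(prob, Y, mask, threshold) {
  pred <- (prob >= threshold) & (mask > 0)
  truth <- (Y == 1) & (mask > 0)
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Train the keyword selector with cross-validation
#'
#' Trains the configured architecture in k-fold cross-validation (each
#' example held out exactly once) and reports per-fold token-level
#' precision, recall and F1 with padding positions excluded, then fits a
#' final model on all data.
#'
#' @param data List of encoded questions from [encode_question()] (with
#'   labels).
#' @param config A [selector_config()].
#' @return A `litqa_selector`: `params`, `config`, `fold_metrics` data
#'   frame, and `mean`/`sd` summaries.
#' @export
train_selector <- function(data, config = selector_config()) {
  assert_that(length(data) >= config$folds,
              "need at least as many examples as folds")
  stacked <- stack_encoded(data, config$max_len)
  assert_that(sum(stacked$Y * stacked$mask) > 0 &&
                sum((1 - stacked$Y) * stacked$mask) > 0,
              "labels are degenerate (single class)",
              "litqa_degenerate_data")
  n <- length(data)
  set.seed(config$seed)
  fold_of <- sample(rep(seq_len(config$folds), length.out = n))
  metrics <- matrix(0, config$folds, 3L,
                    dimnames = list(NULL, c("precision", "recall", "f1")))
  for (k in seq_len(config$folds)) {
    test_idx <- which(fold_of == k)
    train_idx <- which(fold_of != k)
    set.seed(config$seed * 1000L + k)
    params_k <- train_selector_model(stacked, config, train_idx)
    prob <- selector_predict(params_k, config, stacked, test_idx)
    metrics[k, ] <- token_metrics(prob, stacked$Y[test_idx, , drop = FALSE],
                                  stacked$mask[test_idx, , drop = FALSE],
                                  config$threshold)
  }
  set.seed(config$seed * 1000L)
  params <- train_selector_model(stacked, config, seq_len(n))
  structure(list(params = params, config = config,
                 fold_metrics = as.data.frame(metrics),
                 mean = colMeans(metrics),
                 sd = apply(metrics, 2, stats::sd)),
            class = "litqa_selector")
}

#' @export
print.litqa_selector <- function(x, ...) {
  cat("<litqa_selector> ", x$config$architecture, ", ", x$config$folds,
      "-fold CV: F1 ", format(x$mean[["f1"]], digits = 3), " (sd ",
      format(x$sd[["f1"]], digits = 2), ")\n", sep = "")
  invisible(x)
}

#' Select keywords from a question with a trained selector
#'
#' @param q Question (annotation, string, or token vector).
#' @param selector A `litqa_selector`.
#' @param embeddings The embeddings used at training time.
#' @param threshold Decision threshold (defaults to the config value).
#' @return Character vector of keyword tokens at unpadded positions, in
#'   question order (one entry per selected position).
#' @export
select_keywords <- function(q, selector, embeddings,
                            threshold = selector$config$threshold) {
  enc <- encode_question(q, embeddings, max_len = selector$config$max_len)
  stacked <- stack_encoded(list(enc), selector$config$max_len)
  prob <- selector_predict(selector$params, selector$config, stacked, 1L)
  sel <- which(prob[1L, ] >= threshold & stacked$mask[1L, ] > 0)
  enc$tokens[sel]
}

#' Force selected keywords into the initial query
#'
#' Marks every construct containing a selected keyword (as one of its
#' disjunct tokens) protected, so the relaxation process drops it only
#' as a last resort.
#'
#' @param query A `litqa_query`.
#' @param keywords Character vector of keyword surfaces.
#' @return The modified query.
#' @export
force_include <- function(query, keywords) {
  if (!length(keywords)) return(query)
  kw <- tolower(keywords)
  query$constructs <- lapply(query$constructs, function(cs) {
    toks <- unlist(lapply(cs$disjuncts, surface_tokens))
    if (any(kw %in% toks) || any(kw %in% cs$disjuncts)) cs$protected <- TRUE
    cs
  })
  query
}
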