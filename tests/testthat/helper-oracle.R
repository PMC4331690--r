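# Brute-force linear-chain CRF oracle: enumerates every tag path of a toy
# instance and computes the partition function, per-position marginals, the
# (lexicographically smallest) argmax path and per-path probabilities
# directly from the definition. Independent of the package's forward,
# backward and Viterbi code.

oracle_crf <- function(weights, feats, n_feat, n_tags) {
  n_pos <- length(feats)
  state_w <- matrix(weights[seq_len(n_feat * n_tags)], nrow = n_tags) # [y, f]
  trans_w <- matrix(weights[n_feat * n_tags + seq_len(n_tags^2)],
    nrow = n_tags, byrow = TRUE
  ) # [y_prev, y_cur]
  psi <- vapply(seq_len(n_pos), function(t) {
    v <- numeric(n_tags)
    for (f in feats[[t]]) v <- v + state_w[, f + 1L]
    v
  }, numeric(n_tags))
  psi <- matrix(psi, nrow = n_tags)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n_tags)), n_pos)))
  scores <- apply(paths, 1, function(p) {
    s <- sum(psi[cbind(p, seq_len(n_pos))])
    if (n_pos > 1) s <- s + sum(trans_w[cbind(p[-n_pos], p[-1])])
    s
  })
  m <- max(scores)
  logz <- m + log(sum(exp(scores - m)))
  probs <- exp(scores - logz)
  marg <- matrix(0, n_pos, n_tags)
  for (t in seq_len(n_pos)) {
    for (y in seq_len(n_tags)) marg[t, y] <- sum(probs[paths[, t] == y])
  }
  best <- which(scores == max(scores))
  bp <- paths[best, , drop = FALSE]
  ord <- do.call(order, as.data.frame(bp))
  list(
    logz = logz, marginals = marg, viterbi = bp[ord[1], ] - 1L,
    paths = paths, scores = scores, probs = probs
  )
}

# Random toy instance within the enumeration-tractable regime.
random_crf_instance <- function(max_pos = 4L, max_tags = 5L) {
  n_pos <- sample.int(max_pos, 1)
  n_tags <- sample(2:max_tags, 1)
  n_feat <- sample(2:5, 1)
  feats <- lapply(seq_len(n_pos), function(t) {
    k <- sample(0:n_feat, 1)
    if (k == 0L) integer(0) else sort(sample.int(n_feat, k) - 1L)
  })
  weights <- stats::rnorm(n_feat * n_tags + n_tags^2)
  list(feats = feats, weights = weights, n_feat = n_feat, n_tags = n_tags)
}

# Wrap raw weights in a model object so the exported R interface can be
# driven with hand-set parameters.
toy_model <- function(weights, n_feat, n_tags) {
  structure(
    list(
      weights = weights,
      feature_names = paste0("f", seq_len(n_feat)),
      tags = paste0("t", seq_len(n_tags)),
      sigma2 = 1, nll = NA_real_, iterations = 0L, convergence = 0L,
      trace = NULL, scheme = NULL, tokenizer = NULL, feature_cfg = NULL,
      iob12e_two_token = "B1E"
    ),
    class = "chemner_crf"
  )
}

# Feature-name sequences for toy_model(): 0-based index vectors -> names.
toy_features <- function(feats) {
  lapply(feats, function(f) paste0("f", f + 1L))
}

# Random non-overlapping mention ranges over n_tokens, for round-trip tests.
random_ranges <- function(n_tokens) {
  first <- integer(0)
  last <- integer(0)
  i <- 1L
  while (i <= n_tokens) {
    if (stats::runif(1) < 0.35) {
      len <- sample.int(min(4L, n_tokens - i + 1L), 1)
      first <- c(first, i)
      last <- c(last, i + len - 1L)
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(
    first = first, last = last,
    category = sample(chem_categories, length(first), replace = TRUE)
  )
}
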