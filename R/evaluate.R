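# Entity-level evaluation: mention-recognition (CEM) and document-indexing
# (CDI) matching, micro and macro precision/recall/F, and a resampled
# paired significance test between two system configurations.

.counts <- function(tp, fp, fn) {
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Match CEM predictions against gold mentions
#'
#' A prediction is a true positive iff its `(doc_id, section, start, end)`
#' exactly equals a gold mention's; matching is one-to-one and, for the
#' overall score, category-blind. Duplicate predictions of an identical
#' span count once; the surplus is a false positive.
#'
#' @param gold,pred Mention tibbles.
#' @return A one-row tibble with `tp`, `fp`, `fn`.
#' @export
match_cem <- function(gold, pred) {
  key <- function(m) paste(m$doc_id, m$section, m$start, m$end, sep = "\r")
  gold_keys <- unique(key(gold))
  pred_keys <- key(pred)
  tp <- length(intersect(unique(pred_keys), gold_keys))
  .counts(tp, length(pred_keys) - tp, length(gold_keys) - tp)
}

#' Match CDI predictions against gold entity sets
#'
#' Per-document set intersection on exact entity strings (no case folding).
#'
#' @param gold A mention tibble (its per-document unique texts form the gold
#'   sets) or any tibble with `doc_id` and `text` columns.
#' @param pred A CDI record tibble (`doc_id`, `text`, ...), e.g. from
#'   [cem_to_cdi()]; duplicate `(doc_id, text)` pairs are a validation
#'   error.
#' @return A one-row tibble with `tp`, `fp`, `fn`.
#' @export
match_cdi <- function(gold, pred) {
  if (any(duplicated(pred[, c("doc_id", "text")]))) {
    stop("duplicate (doc_id, text) in CDI predictions")
  }
  key <- function(m) paste(m$doc_id, m$text, sep = "\r")
  gold_keys <- unique(key(gold))
  pred_keys <- key(pred)
  tp <- length(intersect(pred_keys, gold_keys))
  .counts(tp, length(pred_keys) - tp, length(gold_keys) - tp)
}

.safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Micro-averaged precision, recall and F1 from pooled counts
#'
#' `R = TP / (TP + FN)`, `P = TP / (TP + FP)`,
#' `F1 = 2 P R / (P + R)`; any 0/0 is defined as 0.
#'
#' @param counts A tibble with `tp`, `fp`, `fn` (one or more rows; rows are
#'   scored independently).
#' @return `counts` with added `precision`, `recall`, `f1` columns.
#' @export
micro_scores <- function(counts) {
  p <- .safe_ratio(counts$tp, counts$tp + counts$fp)
  r <- .safe_ratio(counts$tp, counts$tp + counts$fn)
  dplyr::mutate(counts,
    precision = p, recall = r,
    f1 = .safe_ratio(2 * p * r, p + r)
  )
}

#' Category-pivoted and macro-averaged CEM scores
#'
#' The gold annotations are split by their seven categories; predictions of
#' each category are scored against the gold mentions of that category
#' (exact spans, as in [match_cem()]). The macro scores are the unweighted
#' means of the seven per-category precisions and recalls; macro-F is by
#' default the harmonic mean of macro-P and macro-R (`macro_f = "pr"`), or
#' the mean of the per-category F1 values (`macro_f = "mean_f"`).
#'
#' Categories empty in both gold and predictions contribute (0, 0, 0) under
#' the 0/0 rule and are flagged in the `empty` column.
#'
#' @param gold,pred Mention tibbles with a `category` column.
#' @param macro_f `"pr"` (default) or `"mean_f"`.
#' @return A tibble of class `chemner_eval` with one row per category plus a
#'   `"MACRO"` row: `category`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `empty`.
#' @export
category_scores <- function(gold, pred, macro_f = c("pr", "mean_f")) {
  macro_f <- match.arg(macro_f)
  rows <- purrr::map(chem_categories, function(cat) {
    g <- gold[gold$category == cat, ]
    p <- pred[pred$category == cat, ]
    sc <- micro_scores(match_cem(g, p))
    dplyr::mutate(sc,
      category = cat,
      empty = nrow(g) == 0L && nrow(p) == 0L, .before = 1
    )
  })
  per_cat <- dplyr::bind_rows(rows)
  macro_p <- mean(per_cat$precision)
  macro_r <- mean(per_cat$recall)
  macro_f1 <- if (macro_f == "pr") {
    .safe_ratio(2 * macro_p * macro_r, macro_p + macro_r)
  } else {
    mean(per_cat$f1)
  }
  macro <- tibble::tibble(
    category = "MACRO", empty = any(per_cat$empty),
    tp = sum(per_cat$tp), fp = sum(per_cat$fp), fn = sum(per_cat$fn),
    precision = macro_p, recall = macro_r, f1 = macro_f1
  )
  out <- dplyr::bind_rows(
    per_cat[, names(macro)],
    macro
  )
  class(out) <- c("chemner_eval", class(out))
  out
}

#' Evaluate CEM predictions
#'
#' @param gold,pred Mention tibbles.
#' @param by_category If `TRUE`, return the category-pivoted table of
#'   [category_scores()]; otherwise the overall (category-blind) micro
#'   scores.
#' @param ... Passed to [category_scores()].
#' @return A tibble of scores.
#' @export
evaluate_cem <- function(gold, pred, by_category = FALSE, ...) {
  if (by_category) {
    return(category_scores(gold, pred, ...))
  }
  micro_scores(match_cem(gold, pred))
}

#' Evaluate CDI predictions
#'
#' @param gold A gold mention tibble (unique texts per document are the gold
#'   index sets).
#' @param pred A CDI record tibble.
#' @return A one-row tibble of micro scores.
#' @export
evaluate_cdi <- function(gold, pred) {
  micro_scores(match_cdi(gold, pred))
}

#' Corrupt gold mentions (for constructed system degradations)
#'
#' Randomly corrupts a fraction of the mentions: half of the selected
#' mentions are dropped, the other half get a boundary shifted by one
#' character (kept consistent with the section text). Useful for building a
#' deliberately degraded training signal when validating the significance
#' test.
#'
#' @param mentions A mention tibble.
#' @param documents The corpus the mentions refer to.
#' @param rate Fraction of mentions to corrupt, in `[0, 1]`.
#' @return A corrupted mention tibble (possibly fewer rows).
#' @export
corrupt_mentions <- function(mentions, documents, rate = 0.2) {
  n <- nrow(mentions)
  if (n == 0L || rate <= 0) {
    return(mentions)
  }
  hit <- sample.int(n, size = round(rate * n))
  drop <- hit[seq_len(floor(length(hit) / 2))]
  shift <- setdiff(hit, drop)
  sec_len <- nchar(.section_text(documents, mentions$doc_id, mentions$section))
  for (i in shift) {
    if (mentions$end[i] < sec_len[i]) {
      mentions$end[i] <- mentions$end[i] + 1L
    } else if (mentions$start[i] > 0L) {
      mentions$start[i] <- mentions$start[i] - 1L
    } else {
      drop <- c(drop, i)
      next
    }
    sec <- .section_text(documents, mentions$doc_id[i], mentions$section[i])
    mentions$text[i] <- substr(sec, mentions$start[i] + 1L, mentions$end[i])
  }
  if (length(drop) > 0L) mentions <- mentions[-drop, ]
  mentions
}

#' Build a trainable recognizer "system" for comparisons
#'
#' Returns a function `(train_docs, train_mentions, dev_docs) -> predicted
#' mentions` wrapping [chemner_fit()] and [predict.chemner_crf()], suitable
#' for [paired_resample_test()].
#'
#' @param scheme,tokenizer,config,sigma2,maxit Passed to [chemner_fit()].
#' @param threshold Confidence threshold at prediction time.
#' @param corrupt Fraction of the training mentions corrupted with
#'   [corrupt_mentions()] before fitting (0 = none).
#' @return A system function.
#' @export
crf_system <- function(scheme = "IOBES", tokenizer = "fine",
                       config = feature_config(), threshold = 0.5,
                       sigma2 = 1, maxit = 100L, corrupt = 0) {
  force(scheme)
  force(tokenizer)
  function(train_docs, train_mentions, dev_docs) {
    if (corrupt > 0) {
      train_mentions <- corrupt_mentions(train_mentions, train_docs,
        rate = corrupt
      )
    }
    fit <- chemner_fit(train_docs, train_mentions,
      scheme = scheme,
      tokenizer = tokenizer, config = config, sigma2 = sigma2, maxit = maxit
    )
    predict(fit, dev_docs, threshold = threshold)
  }
}

# Bootstrap-resample documents (with replacement) together with their
# mentions; resampled copies get fresh unique doc ids.
.resample_corpus <- function(documents, mentions, n) {
  idx <- sample.int(nrow(documents), size = n, replace = TRUE)
  docs <- documents[idx, ]
  new_ids <- paste0(docs$doc_id, "#", seq_len(n))
  m_by <- split(mentions, mentions$doc_id)
  ms <- purrr::map(seq_len(n), function(k) {
    m <- m_by[[docs$doc_id[k]]]
    if (is.null(m)) {
      return(NULL)
    }
    m$doc_id <- new_ids[k]
    m
  })
  docs$doc_id <- new_ids
  list(documents = docs, mentions = dplyr::bind_rows(ms))
}

#' Resampled paired significance test between two systems
#'
#' Draws `n_resamples` bootstrap training and development sets (sampled with
#' replacement at the configured sizes) from the given corpus, trains both
#' systems on each training set, scores both on the matching development set
#' (CEM micro-F), and applies a two-sided paired t-test to the F-score
#' pairs.
#'
#' @param system_a,system_b System functions, see [crf_system()].
#' @param documents,mentions The corpus to resample from.
#' @param n_train,n_dev Sizes of each resampled training and development
#'   set; default to a 2:1 split of the corpus.
#' @param n_resamples Number of resamples (at least 2; default 30).
#' @param seed Optional seed fixing all resampling randomness.
#' @return A one-row tibble: `mean_f_a`, `mean_f_b`, `delta_f`
#'   (`mean(F_a - F_b)`), `t`, `p_value`, `n_resamples`. If the paired
#'   differences have zero variance (e.g. two identical deterministic
#'   systems), `t` is `NA` and `p_value` is 1.
#' @export
paired_resample_test <- function(system_a, system_b, documents, mentions,
                                 n_train = NULL, n_dev = NULL,
                                 n_resamples = 30L, seed = NULL) {
  if (n_resamples < 2L) {
    stop("n_resamples must be at least 2")
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n_train <- n_train %||% floor(2 * nrow(documents) / 3)
  n_dev <- n_dev %||% (nrow(documents) - n_train)
  f_a <- numeric(n_resamples)
  f_b <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    train <- .resample_corpus(documents, mentions, n_train)
    dev <- .resample_corpus(documents, mentions, n_dev)
    pred_a <- system_a(train$documents, train$mentions, dev$documents)
    pred_b <- system_b(train$documents, train$mentions, dev$documents)
    f_a[r] <- micro_scores(match_cem(dev$mentions, pred_a))$f1
    f_b[r] <- micro_scores(match_cem(dev$mentions, pred_b))$f1
  }
  d <- f_a - f_b
  if (stats::sd(d) == 0) {
    t_stat <- NA_real_
    p <- 1
  } else {
    tt <- stats::t.test(f_a, f_b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(
    mean_f_a = mean(f_a), mean_f_b = mean(f_b), delta_f = mean(d),
    t = t_stat, p_value = p, n_resamples = as.integer(n_resamples)
  )
}

#' Plot a category-pivoted evaluation report
#'
#' Dodged bars of precision, recall and F1 per category (macro row
#' included).
#'
#' @param object A `chemner_eval` from [category_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemner_eval
#' @export
autoplot.chemner_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("category", "precision", "recall", "f1")],
    cols = c("precision", "recall", "f1"),
    names_to = "measure", values_to = "score"
  )
  long$measure <- factor(long$measure, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$category, y = .data$score, fill = .data$measure)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the training objective trace of a fitted CRF
#'
#' Penalized negative log-likelihood at each objective evaluation during
#' L-BFGS training.
#'
#' @param object A `chemner_crf` with a training trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemner_crf
#' @export
autoplot.chemner_crf <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("model carries no training trace (was it deserialized?)")
  }
  df <- tibble::tibble(
    evaluation = seq_along(object$trace),
    nll = object$trace
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$evaluation, y = .data$nll)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "objective evaluation", y = "penalized NLL") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
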