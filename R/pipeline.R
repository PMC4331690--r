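# End-to-end pipeline: fit a CRF recognizer on an annotated corpus and
# predict mentions with entity-level confidence.

.sentence_groups <- function(tokens) {
  tokens |>
    dplyr::group_by(.data$doc_id, .data$section, .data$sentence) |>
    dplyr::group_split()
}

.mention_key <- function(doc_id, section) paste(doc_id, section, sep = "\r")

#' Fit a chemical mention recognizer
#'
#' Tokenizes the corpus, extracts features, projects the gold mentions onto
#' token ranges, encodes them under the chosen tag scheme, and trains a
#' linear-chain CRF.
#'
#' @param documents Document tibble (`doc_id`, `title`, `abstract`).
#' @param mentions Gold mention tibble (see [read_annotations()]).
#' @param scheme Tag scheme, one of [tag_schemes] (default `"IOBES"`).
#' @param tokenizer `"fine"` (default) or `"coarse"`.
#' @param config Feature configuration, see [feature_config()].
#' @param token_annotations Optional POS/chunk sidecar (see [attach_pos()]);
#'   when supplied, syntax features are extracted.
#' @param policy Misalignment policy for [align_mentions()].
#' @param iob12e_two_token See [encode_tags()].
#' @param sigma2,maxit,pgtol Passed to [crf_train()].
#' @return A `chemner_crf` carrying the scheme, tokenizer and feature
#'   configuration it was trained with.
#' @export
chemner_fit <- function(documents, mentions,
                        scheme = "IOBES",
                        tokenizer = c("fine", "coarse"),
                        config = feature_config(),
                        token_annotations = NULL,
                        policy = c("expand", "drop"),
                        iob12e_two_token = c("B1E", "B1B2"),
                        sigma2 = 1, maxit = 200L, pgtol = 1e-4) {
  scheme <- match.arg(scheme, tag_schemes)
  tokenizer <- match.arg(tokenizer)
  policy <- match.arg(policy)
  iob12e_two_token <- match.arg(iob12e_two_token)
  tokens <- tokenize_corpus(documents, tokenizer = tokenizer)
  if (!is.null(token_annotations)) {
    tokens <- attach_pos(tokens, token_annotations)
  }
  tokens <- extract_features(tokens, config = config)
  groups <- .sentence_groups(tokens)
  m_by <- split(mentions, .mention_key(mentions$doc_id, mentions$section))
  x <- vector("list", length(groups))
  y <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    ms <- m_by[[.mention_key(g$doc_id[1], g$section[1])]]
    sent_lo <- min(g$start)
    sent_hi <- max(g$end)
    if (is.null(ms)) {
      ms <- mentions[0, ]
    } else {
      ms <- ms[ms$start < sent_hi & ms$end > sent_lo, ]
    }
    ranges <- align_mentions(g[, c("start", "end")], ms, policy = policy)
    x[[k]] <- g$features
    y[[k]] <- encode_tags(nrow(g), ranges, scheme,
      iob12e_two_token = iob12e_two_token
    )
  }
  model <- crf_train(x, y,
    tags = tag_inventory(scheme), sigma2 = sigma2,
    maxit = maxit, pgtol = pgtol
  )
  model$scheme <- scheme
  model$tokenizer <- tokenizer
  model$feature_cfg <- config
  model$iob12e_two_token <- iob12e_two_token
  model
}

#' Predict chemical mentions in documents
#'
#' Tokenizes with the model's tokenizer, extracts its features, decodes each
#' sentence with Viterbi, repairs ill-formed tag runs into mention spans,
#' scores each mention with an entity-level confidence, and keeps mentions
#' with confidence at or above the threshold.
#'
#' @param object A fitted `chemner_crf` from [chemner_fit()].
#' @param documents Document tibble to annotate.
#' @param threshold Confidence threshold in `[0, 1]`; default 0.5.
#' @param token_annotations Optional POS/chunk sidecar.
#' @param confidence `"marginal"` (product of per-token tag marginals,
#'   default) or `"exact"` (constrained-path probability).
#' @param ... Unused.
#' @return A mention tibble with columns `doc_id`, `section`, `start`,
#'   `end`, `text`, `category`, `confidence`.
#' @export
predict.chemner_crf <- function(object, documents, threshold = 0.5,
                                token_annotations = NULL,
                                confidence = c("marginal", "exact"), ...) {
  confidence <- match.arg(confidence)
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.null(object$scheme)) {
    stop("model was trained with crf_train() directly; use chemner_fit() ",
      "models for document prediction")
  }
  tokens <- tokenize_corpus(documents, tokenizer = object$tokenizer)
  empty <- tibble::tibble(
    doc_id = character(), section = character(), start = integer(),
    end = integer(), text = character(), category = character(),
    confidence = numeric()
  )
  if (nrow(tokens) == 0L) {
    return(empty)
  }
  if (!is.null(token_annotations)) {
    tokens <- attach_pos(tokens, token_annotations)
  }
  tokens <- extract_features(tokens, config = object$feature_cfg %||% feature_config())
  groups <- .sentence_groups(tokens)
  # index the whole corpus against the model vocabulary in one pass
  xi_all <- .index_sequences(
    lapply(groups, function(g) g$features),
    object$feature_names
  )
  nf <- length(object$feature_names)
  nt <- length(object$tags)
  out <- purrr::map(seq_along(groups), function(k) {
    g <- groups[[k]]
    xi <- xi_all[[k]]
    path <- crf_viterbi_cpp(object$weights, xi, nf, nt)
    tags <- object$tags[path + 1L]
    ranges <- decode_tags(tags)
    if (nrow(ranges) == 0L) {
      return(NULL)
    }
    conf <- if (confidence == "marginal") {
      marg <- crf_marginals_cpp(object$weights, xi, nf, nt)
      vapply(seq_len(nrow(ranges)), function(i) {
        span <- ranges$first[i]:ranges$last[i]
        prod(marg[cbind(span, path[span] + 1L)])
      }, numeric(1))
    } else {
      logz <- crf_constrained_logz_cpp(
        object$weights, xi,
        rep(-1L, length(xi)), nf, nt
      )
      vapply(seq_len(nrow(ranges)), function(i) {
        constraint <- rep(-1L, length(xi))
        span <- ranges$first[i]:ranges$last[i]
        constraint[span] <- path[span]
        exp(crf_constrained_logz_cpp(object$weights, xi, constraint, nf, nt) - logz)
      }, numeric(1))
    }
    sec_text <- .section_text(documents, g$doc_id[1], g$section[1])
    m <- mentions_from_ranges(g, ranges, sec_text,
      doc_id = g$doc_id[1], section = g$section[1]
    )
    m$confidence <- conf
    m[conf >= threshold, ]
  })
  out <- dplyr::bind_rows(c(list(empty), out))
  dplyr::arrange(out, .data$doc_id, .data$section, .data$start)
}
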