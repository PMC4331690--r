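# Linear-chain CRF: training by L2-regularized maximum conditional
# likelihood (quasi-Newton, L-BFGS-B), Viterbi decoding, forward-backward
# marginals, and entity-level confidence.

# Map feature-name sequences to 0-based integer index sequences; unseen
# features (at prediction time) are dropped. One match() call for the whole
# input, so the feature-name hash table is built once.
.index_sequences <- function(x, feature_names) {
  n_tok_per_seq <- lengths(x)
  if (sum(n_tok_per_seq) == 0L) {
    return(lapply(x, function(s) list()))
  }
  per_tok_len <- lengths(unlist(x, recursive = FALSE, use.names = FALSE))
  idx <- match(unlist(x, use.names = FALSE), feature_names) - 1L
  tok_id <- rep.int(seq_along(per_tok_len), per_tok_len)
  by_tok <- split(idx, factor(tok_id, levels = seq_along(per_tok_len)))
  by_tok <- lapply(by_tok, function(v) as.integer(v[!is.na(v)]))
  seq_id <- rep.int(seq_along(x), n_tok_per_seq)
  unname(lapply(
    split(by_tok, factor(seq_id, levels = seq_along(x))),
    unname
  ))
}

#' Train a linear-chain CRF
#'
#' Maximizes the L2-regularized conditional log-likelihood
#' \deqn{\sum_s \log p_\lambda(y^{(s)} \mid x^{(s)}) - \frac{1}{2\sigma^2}\lVert\lambda\rVert^2}
#' with L-BFGS-B. Observation features are conjoined with the current tag
#' only; tag-pair transition indicators complete the first-order chain.
#' Training is deterministic for fixed data and data order.
#'
#' @param x List of sequences; each sequence is a list of character vectors
#'   of active feature names, one per token (see [token_features()]).
#' @param y List of character vectors of gold tags, parallel to `x`.
#' @param tags The full tag inventory, e.g. [tag_inventory()]. Defaults to
#'   the sorted set of tags observed in `y`.
#' @param sigma2 Gaussian prior variance of the L2 penalty (default 1).
#' @param maxit Maximum L-BFGS iterations (default 200).
#' @param pgtol Projected-gradient tolerance (default 1e-4).
#' @return An object of class `chemner_crf`: weights, feature and tag index
#'   maps, hyperparameters and optimizer metadata. The objective trace (the
#'   penalized negative log-likelihood at every function evaluation) is kept
#'   in `$trace`.
#' @export
crf_train <- function(x, y, tags = NULL, sigma2 = 1, maxit = 200L,
                      pgtol = 1e-4) {
  if (length(x) == 0L) {
    stop("empty training set")
  }
  stopifnot(length(x) == length(y))
  if (is.null(tags)) {
    tags <- sort(unique(unlist(y)), method = "radix")
  }
  bad <- setdiff(unique(unlist(y)), tags)
  if (length(bad) > 0L) {
    stop("tag outside inventory: ", bad[1L])
  }
  feature_names <- sort(unique(unlist(x, use.names = FALSE)), method = "radix")
  n_feat <- length(feature_names)
  n_tags <- length(tags)
  xi <- .index_sequences(x, feature_names)
  yi <- lapply(y, function(t) as.integer(match(t, tags) - 1L))
  npar <- n_feat * n_tags + n_tags * n_tags
  cache <- new.env(parent = emptyenv())
  cache$trace <- numeric(0)
  eval_obj <- function(p) {
    r <- crf_nll_grad_cpp(p, xi, yi, n_feat, n_tags, 1 / sigma2)
    cache$p <- p
    cache$g <- r$grad
    cache$trace <- c(cache$trace, r$nll)
    r$nll
  }
  eval_grad <- function(p) {
    if (is.null(cache$p) || !identical(p, cache$p)) {
      eval_obj(p)
    }
    cache$g
  }
  opt <- stats::optim(
    par = rep(0, npar), fn = eval_obj, gr = eval_grad,
    method = "L-BFGS-B",
    control = list(maxit = as.integer(maxit), pgtol = pgtol, factr = 1e7)
  )
  structure(
    list(
      weights = opt$par,
      feature_names = feature_names,
      tags = tags,
      sigma2 = sigma2,
      nll = opt$value,
      iterations = unname(opt$counts["function"]),
      convergence = opt$convergence,
      trace = cache$trace,
      scheme = NULL,
      tokenizer = NULL,
      feature_cfg = NULL,
      iob12e_two_token = "B1E"
    ),
    class = "chemner_crf"
  )
}

#' @export
print.chemner_crf <- function(x, ...) {
  cat(
    "Linear-chain CRF:", length(x$feature_names), "features x",
    length(x$tags), "tags;",
    length(x$weights), "weights\n"
  )
  if (!is.null(x$scheme)) {
    cat("scheme:", x$scheme, " tokenizer:", x$tokenizer, "\n")
  }
  cat(
    "penalized NLL:", format(x$nll), " function evaluations:",
    x$iterations, "\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted CRF into a weight table
#'
#' @param x A `chemner_crf`.
#' @param ... Unused.
#' @return A tibble with columns `feature` (a feature name, or
#'   `"trans:<from>"` for transition rows), `tag` and `weight`, one row per
#'   parameter.
#' @method tidy chemner_crf
#' @export
tidy.chemner_crf <- function(x, ...) {
  n_feat <- length(x$feature_names)
  n_tags <- length(x$tags)
  state <- tibble::tibble(
    feature = rep(x$feature_names, each = n_tags),
    tag = rep(x$tags, times = n_feat),
    weight = x$weights[seq_len(n_feat * n_tags)]
  )
  trans <- tibble::tibble(
    feature = rep(paste0("trans:", x$tags), each = n_tags),
    tag = rep(x$tags, times = n_tags),
    weight = x$weights[n_feat * n_tags + seq_len(n_tags * n_tags)]
  )
  dplyr::bind_rows(state, trans)
}

#' One-row summary of a fitted CRF
#'
#' @param x A `chemner_crf`.
#' @param ... Unused.
#' @return A one-row tibble: number of features, tags and parameters, the
#'   penalized negative log-likelihood, function evaluations and optimizer
#'   convergence code.
#' @method glance chemner_crf
#' @export
glance.chemner_crf <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_tags = length(x$tags),
    n_parameters = length(x$weights),
    nll = x$nll,
    iterations = x$iterations,
    convergence = x$convergence
  )
}

#' Viterbi decoding
#'
#' Returns an argmax tag path of \eqn{p(Y \mid W)}; ties are broken by
#' lexicographic tag order.
#'
#' @param model A `chemner_crf`.
#' @param x_seq One sequence: a list of character vectors of feature names.
#' @return Character vector of tags, one per position.
#' @export
crf_viterbi <- function(model, x_seq) {
  if (length(x_seq) == 0L) {
    return(character(0))
  }
  xi <- .index_sequences(list(x_seq), model$feature_names)[[1]]
  path <- crf_viterbi_cpp(
    model$weights, xi, length(model$feature_names),
    length(model$tags)
  )
  model$tags[path + 1L]
}

#' Forward-backward posterior marginals
#'
#' @param model A `chemner_crf`.
#' @param x_seq One sequence (list of feature-name vectors).
#' @return A numeric matrix (positions x tags, columns named by tag) of
#'   posterior tag probabilities; each row sums to 1.
#' @export
crf_marginals <- function(model, x_seq) {
  xi <- .index_sequences(list(x_seq), model$feature_names)[[1]]
  m <- crf_marginals_cpp(
    model$weights, xi, length(model$feature_names),
    length(model$tags)
  )
  colnames(m) <- model$tags
  m
}

#' Conditional log-probability of a full or partial tag assignment
#'
#' @param model A `chemner_crf`.
#' @param x_seq One sequence (list of feature-name vectors).
#' @param tags Character vector, one entry per position; `NA` marks a free
#'   position. Fully specified, this is the log-probability of that path.
#' @return `log p(constraint | x)`.
#' @export
crf_logprob <- function(model, x_seq, tags) {
  stopifnot(length(tags) == length(x_seq))
  xi <- .index_sequences(list(x_seq), model$feature_names)[[1]]
  constraint <- as.integer(ifelse(is.na(tags), -1L, match(tags, model$tags) - 1L))
  if (any(constraint < -1L | is.na(constraint))) {
    stop("constraint tag outside the model inventory")
  }
  nf <- length(model$feature_names)
  nt <- length(model$tags)
  logzc <- crf_constrained_logz_cpp(model$weights, xi, constraint, nf, nt)
  logz <- crf_constrained_logz_cpp(
    model$weights, xi,
    rep(-1L, length(x_seq)), nf, nt
  )
  logzc - logz
}

#' Entity-level confidence
#'
#' Confidence of a decoded mention spanning tokens `first..last` of a
#' sequence. The default (`"marginal"`) is the product of the per-position
#' posterior marginals of the decoded tags over the mention's tokens; the
#' `"exact"` mode computes the exact probability mass of all paths agreeing
#' with the decoded tags on those positions (constrained forward).
#'
#' @param model A `chemner_crf`.
#' @param x_seq One sequence (list of feature-name vectors).
#' @param first,last 1-based token range of the mention.
#' @param tags The decoded tag sequence for the whole sentence.
#' @param mode `"marginal"` (default) or `"exact"`.
#' @param marginals Optional precomputed [crf_marginals()] matrix, to avoid
#'   recomputation when scoring several mentions of one sentence.
#' @return A probability in `[0, 1]`.
#' @export
entity_confidence <- function(model, x_seq, first, last, tags,
                              mode = c("marginal", "exact"),
                              marginals = NULL) {
  mode <- match.arg(mode)
  stopifnot(first >= 1L, last <= length(x_seq), first <= last)
  if (mode == "marginal") {
    if (is.null(marginals)) {
      marginals <- crf_marginals(model, x_seq)
    }
    idx <- cbind(first:last, match(tags[first:last], model$tags))
    return(prod(marginals[idx]))
  }
  constraint <- rep(NA_character_, length(x_seq))
  constraint[first:last] <- tags[first:last]
  exp(crf_logprob(model, x_seq, constraint))
}

#' Serialize a CRF model to a versioned flat file
#'
#' JSON with the weights stored as full-precision (`%.17g`) strings, so a
#' write/read round trip reproduces the model exactly.
#'
#' @param model A `chemner_crf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
crf_write <- function(model, path) {
  obj <- list(
    format = "chemner_crf",
    version = 1L,
    tags = model$tags,
    feature_names = model$feature_names,
    sigma2 = sprintf("%.17g", model$sigma2),
    nll = sprintf("%.17g", model$nll),
    iterations = model$iterations,
    convergence = model$convergence,
    scheme = model$scheme,
    tokenizer = model$tokenizer,
    iob12e_two_token = model$iob12e_two_token,
    feature_cfg = if (!is.null(model$feature_cfg)) unclass(model$feature_cfg),
    weights = sprintf("%.17g", model$weights)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized CRF model
#'
#' @param path Path written by [crf_write()].
#' @return A `chemner_crf`.
#' @export
crf_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "chemner_crf") || !identical(obj$version, 1L)) {
    stop("not a chemner CRF model file (or unsupported version): ", path)
  }
  cfg <- obj$feature_cfg
  if (!is.null(cfg)) {
    cfg <- do.call(feature_config, cfg[setdiff(names(cfg), character(0))])
  }
  structure(
    list(
      weights = as.numeric(obj$weights),
      feature_names = obj$feature_names,
      tags = obj$tags,
      sigma2 = as.numeric(obj$sigma2),
      nll = as.numeric(obj$nll),
      iterations = obj$iterations,
      convergence = obj$convergence,
      trace = NULL,
      scheme = obj$scheme,
      tokenizer = obj$tokenizer,
      feature_cfg = cfg,
      iob12e_two_token = obj$iob12e_two_token %||% "B1E"
    ),
    class = "chemner_crf"
  )
}
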