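# Per-token feature extraction: word/context, affix, orthographic,
# word-shape and syntax (POS/chunk) features feeding the CRF.

#' Feature extraction configuration
#'
#' @param word,affix,ortho,shape,syntax,bias Logical toggles per feature
#'   family.
#' @param word_window Number of neighbouring words on each side used for
#'   word/context features (default 2, a window of five words).
#' @param pos_window Number of neighbouring POS tags on each side (default
#'   2, a window of five).
#' @param strict_az Keep the orthographic patterns exactly as designed,
#'   including the `[A-z]` ranges (which also admit `[ \ ] ^ _` and the
#'   backtick). Set to `FALSE` to substitute `[A-Za-z]`.
#' @param shape_digit Symbol digits map to in word shapes; `"0"` by default,
#'   `"1"` reproduces the digit-normalized variant.
#' @return A named list of class `chemner_feature_config`.
#' @export
feature_config <- function(word = TRUE, affix = TRUE, ortho = TRUE,
                           shape = TRUE, syntax = TRUE, bias = TRUE,
                           word_window = 2L, pos_window = 2L,
                           strict_az = TRUE, shape_digit = "0") {
  stopifnot(word_window >= 0L, pos_window >= 0L, nchar(shape_digit) == 1L)
  structure(
    list(
      word = word, affix = affix, ortho = ortho, shape = shape,
      syntax = syntax, bias = bias,
      word_window = as.integer(word_window),
      pos_window = as.integer(pos_window),
      strict_az = strict_az, shape_digit = shape_digit
    ),
    class = "chemner_feature_config"
  )
}

#' Normalize a word by collapsing digit runs
#'
#' Every maximal run of digits is replaced by `"1"`, so e.g. numbered
#' homologues ("cyclooxygenase-2", "cyclooxygenase-12") share one surface
#' form and the feature vocabulary stays small. Idempotent.
#'
#' @param x Character vector of token texts.
#' @return Character vector of the same length.
#' @examples
#' normalize_word("cyclooxygenase-2") # "cyclooxygenase-1"
#' normalize_word("CHEBI:28262") # "CHEBI:1"
#' @export
normalize_word <- function(x) {
  gsub("[0-9]+", "1", x)
}

#' The orthographic pattern table
#'
#' Eighteen named regular expressions capturing writing styles typical of
#' chemical names (functional-group locants, capitalization mixes,
#' alphanumeric mixes, Roman numerals, dashes, punctuation, quotes). The
#' `HASDASH`, `INITDASH` and `ENDDASH` patterns are unanchored substring
#' searches; all others are anchored as written.
#'
#' @param strict_az See [feature_config()].
#' @return A tibble with columns `name` and `pattern`.
#' @export
ortho_patterns <- function(strict_az = TRUE) {
  pat <- c(
    FG = "^\\d(,\\d)*\\-?\\w+",
    INITCAPS = "^[A-Z].+",
    CAPWORD = "^[A-Z][a-z]+$",
    ALLCAPS = "^[A-Z]+$",
    CAPSMIX = "^[A-z]*([A-Z][a-z]|[a-z][A-Z])[A-z]*$",
    ALPHANUMMIX = "^[A-z0-9]*([0-9][A-z]|[A-z][0-9])[A-z0-9]*$",
    ALPHANUM = "^[A-z]+[0-9]+$",
    UPPERCHAR = "^[A-Z]$",
    LOWERCHAR = "^[a-z]$",
    SHORTNUM = "^[0-9]?$",
    INTEGER = "^-?[0-9]+$",
    REAL = "^-?[0-9]\\.[0-9]+$",
    ROMAN = "^[IVX]+$",
    HASDASH = "-",
    INITDASH = "^-",
    ENDDASH = "-$",
    PUNCTUATION = "^[,.;:?!]$",
    QUOTE = "^[\"`']$"
  )
  if (!strict_az) {
    pat <- gsub("A-z", "A-Za-z", pat, fixed = TRUE)
  }
  tibble::tibble(name = names(pat), pattern = unname(pat))
}

#' Orthographic features of tokens
#'
#' @param x Character vector of token texts (raw, not normalized: digits
#'   matter for these patterns).
#' @param strict_az See [feature_config()].
#' @return A list (one element per token) of character vectors naming the
#'   matched patterns, prefixed `"ortho:"`; binary features, present iff the
#'   pattern matches.
#' @examples
#' ortho_features("2,4-dinitrophenyl") # includes "ortho:FG"
#' @export
ortho_features <- function(x, strict_az = TRUE) {
  pats <- ortho_patterns(strict_az)
  m <- vapply(
    pats$pattern,
    function(p) stringr::str_detect(x, p),
    logical(length(x)),
    USE.NAMES = FALSE
  )
  if (length(x) == 1L) m <- matrix(m, nrow = 1L)
  names_v <- paste0("ortho:", pats$name)
  lapply(seq_along(x), function(i) names_v[m[i, ]])
}

#' Word shape of tokens
#'
#' Maps every uppercase A-Z to `"A"`, lowercase a-z to `"a"`, digit to
#' `shape_digit`, and everything else (punctuation, Greek letters, ...) to
#' `"_"`. The collapsed shape additionally reduces runs of identical
#' characters to a single character, so e.g. `"Aaaaa_A"` contracts to
#' `"Aa_A"`.
#'
#' @param x Character vector of token texts.
#' @param shape_digit See [feature_config()].
#' @return A tibble with character columns `raw` and `collapsed`.
#' @examples
#' word_shape("Na(2)CO(3)")
#' @export
word_shape <- function(x, shape_digit = "0") {
  raw <- gsub("[A-Z]", "A", x)
  raw <- gsub("[a-z]", "a", raw)
  raw <- gsub("[0-9]", shape_digit, raw)
  keep <- paste0("Aa", shape_digit)
  raw <- gsub(paste0("[^", keep, "]"), "_", raw)
  collapsed <- gsub("(.)\\1+", "\\1", raw)
  tibble::tibble(raw = raw, collapsed = collapsed)
}

#' Affix features of a token
#'
#' Prefixes and suffixes of 3 to 5 characters (only those not exceeding the
#' token length), computed on the digit-normalized form.
#'
#' @param x Character vector of token texts.
#' @return A list (one element per token) of character vectors like
#'   `"pre3=hyd"`, `"suf4=ogen"`.
#' @examples
#' affix_features("hydrogen")
#' @export
affix_features <- function(x) {
  norm <- normalize_word(x)
  lapply(norm, function(w) {
    nc <- nchar(w)
    lens <- 3:5
    lens <- lens[lens <= nc]
    if (length(lens) == 0L) {
      return(character(0))
    }
    c(
      paste0("pre", lens, "=", substr(rep(w, length(lens)), 1L, lens)),
      paste0("suf", lens, "=", substr(rep(w, length(lens)), nc - lens + 1L, nc))
    )
  })
}

# Windowed access with boundary sentinels: k ranges over -w..w.
.window <- function(padded, n, k, w) {
  padded[seq_len(n) + k + w]
}

#' Per-token feature vectors for one sentence
#'
#' Assembles all enabled feature families for every token of a sentence:
#' digit-normalized unigrams in a +-`word_window` context with contiguous
#' bigram and trigram conjunctions, affixes, orthographic pattern matches,
#' raw and collapsed word shapes, POS identity features in a
#' +-`pos_window` context plus the current chunk tag (when annotations are
#' supplied), and a bias feature. Out-of-range context positions emit the
#' boundary sentinels `__BOS__`/`__EOS__`. Deterministic: identical input
#' yields identical output.
#'
#' @param texts Character vector of the sentence's token texts.
#' @param pos,chunk Optional character vectors of POS and chunk tags, same
#'   length as `texts`.
#' @param config A [feature_config()].
#' @return A list of character vectors, one per token.
#' @export
token_features <- function(texts, pos = NULL, chunk = NULL,
                           config = feature_config()) {
  n <- length(texts)
  if (n == 0L) {
    return(list())
  }
  if (!is.null(pos) && length(pos) != n) {
    stop("POS annotation length does not match token count")
  }
  if (!is.null(chunk) && length(chunk) != n) {
    stop("chunk annotation length does not match token count")
  }
  fixed <- list() # character vectors of length n, one feature per position
  ragged <- list() # lists of length n, several features per position
  if (config$word) {
    w <- config$word_window
    norm <- normalize_word(texts)
    padded <- c(rep("__BOS__", w), norm, rep("__EOS__", w))
    for (k in -w:w) {
      fixed <- c(fixed, list(paste0("w[", k, "]=", .window(padded, n, k, w))))
    }
    if (w >= 1L) {
      for (a in -w:(w - 1L)) {
        fixed <- c(fixed, list(paste0(
          "w[", a, ",", a + 1L, "]=",
          .window(padded, n, a, w), "_", .window(padded, n, a + 1L, w)
        )))
      }
    }
    if (w >= 1L) {
      for (a in -w:(w - 2L)) {
        if (a + 2L > w) break
        fixed <- c(fixed, list(paste0(
          "w[", a, ",", a + 2L, "]=",
          .window(padded, n, a, w), "_",
          .window(padded, n, a + 1L, w), "_",
          .window(padded, n, a + 2L, w)
        )))
      }
    }
  }
  if (config$shape) {
    sh <- word_shape(texts, shape_digit = config$shape_digit)
    fixed <- c(fixed, list(
      paste0("rawshape=", sh$raw),
      paste0("shape=", sh$collapsed)
    ))
  }
  if (config$bias) {
    fixed <- c(fixed, list(rep("bias", n)))
  }
  if (config$syntax && !is.null(pos)) {
    w <- config$pos_window
    padded <- c(rep("__BOS__", w), pos, rep("__EOS__", w))
    for (k in -w:w) {
      fixed <- c(fixed, list(paste0("pos[", k, "]=", .window(padded, n, k, w))))
    }
  }
  if (config$syntax && !is.null(chunk)) {
    fixed <- c(fixed, list(paste0("chunk=", chunk)))
  }
  if (config$affix) {
    ragged <- c(ragged, list(affix_features(texts)))
  }
  if (config$ortho) {
    ragged <- c(ragged, list(ortho_features(texts, strict_az = config$strict_az)))
  }
  fixed_mat <- matrix(unlist(fixed, use.names = FALSE), nrow = n)
  if (length(ragged) == 0L) {
    return(lapply(seq_len(n), function(i) fixed_mat[i, ]))
  }
  lapply(seq_len(n), function(i) {
    c(
      fixed_mat[i, ],
      unlist(lapply(ragged, `[[`, i), use.names = FALSE)
    )
  })
}

#' Extract features for a tokenized corpus
#'
#' Adds a `features` list-column to a token tibble (one character vector per
#' token), processing each sentence independently. If the tibble carries
#' `pos`/`chunk` columns they feed the syntax features.
#'
#' @param tokens A token tibble from [tokenize_corpus()], optionally with
#'   `pos` and `chunk` columns (see [attach_pos()]).
#' @param config A [feature_config()].
#' @return `tokens` with an added `features` list-column.
#' @export
extract_features <- function(tokens, config = feature_config()) {
  has_pos <- "pos" %in% names(tokens)
  has_chunk <- "chunk" %in% names(tokens)
  tokens |>
    dplyr::group_by(.data$doc_id, .data$section, .data$sentence) |>
    dplyr::mutate(features = token_features(
      .data$text,
      pos = if (has_pos) .data$pos else NULL,
      chunk = if (has_chunk) .data$chunk else NULL,
      config = config
    )) |>
    dplyr::ungroup()
}

#' Attach POS/chunk annotations to tokens by span overlap
#'
#' Joins a token-annotation sidecar (as produced by [generate_corpus()] or
#' an external tagger) onto a token tibble: each token receives the POS and
#' chunk tag of the annotation span that covers it. Tokens covered by no
#' annotation get `NA`.
#'
#' @param tokens A token tibble from [tokenize_corpus()].
#' @param annotations A tibble with columns `doc_id`, `section`, `start`,
#'   `end`, `pos`, `chunk` (0-based half-open spans).
#' @return `tokens` with added `pos` and `chunk` columns.
#' @export
attach_pos <- function(tokens, annotations) {
  key <- function(d, s) paste(d, s, sep = "\r")
  ann_by <- split(
    annotations[, c("start", "end", "pos", "chunk")],
    key(annotations$doc_id, annotations$section)
  )
  tokens |>
    dplyr::group_by(.data$doc_id, .data$section) |>
    dplyr::group_modify(function(df, g) {
      ann <- ann_by[[key(g$doc_id, g$section)]]
      if (is.null(ann)) {
        df$pos <- NA_character_
        df$chunk <- NA_character_
        return(df)
      }
      idx <- vapply(seq_len(nrow(df)), function(i) {
        j <- which(ann$start <= df$start[i] & ann$end >= df$end[i])
        if (length(j) == 0L) NA_integer_ else j[1L]
      }, integer(1))
      df$pos <- ann$pos[idx]
      df$chunk <- ann$chunk[idx]
      df
    }) |>
    dplyr::ungroup()
}
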