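# Sentence splitting and offset-preserving tokenization.
#
# All character offsets in this package are 0-based, half-open [start, end),
# so a token's text always equals substr(section_text, start + 1, end).

#' Default abbreviation guard list for the sentence splitter
#'
#' Words (without their trailing period) after which a period is never
#' treated as a sentence boundary. A single capital letter followed by a
#' period (an initial) is always guarded, independently of this list.
#'
#' @param path Optional path to a plain-text file with one abbreviation per
#'   line; entries are added to the built-in list.
#' @return Character vector of guard words.
#' @export
sentence_guards <- function(path = NULL) {
  guards <- c(
    "e.g", "i.e", "etc", "cf", "vs", "viz", "ca", "approx",
    "Fig", "Figs", "Eq", "Eqs", "Ref", "Refs", "No", "Nos",
    "Dr", "Prof", "Mr", "Mrs", "Ms", "St", "al", "Inc", "Ltd", "Co"
  )
  if (!is.null(path)) {
    extra <- readLines(path, warn = FALSE)
    extra <- trimws(extra)
    guards <- unique(c(guards, extra[nzchar(extra)]))
  }
  guards
}

#' Split text into sentence spans
#'
#' Rule-based sentence boundary detection: a boundary is placed after one of
#' `.`, `!`, `?` when it is followed by whitespace and an uppercase letter or
#' digit, unless the period terminates a guarded abbreviation or a single
#' capital initial. Spans are trimmed of surrounding whitespace, so together
#' they tile the non-whitespace content of the input.
#'
#' @param text A single character string.
#' @param guards Abbreviation guard list, see [sentence_guards()].
#' @return A tibble with integer columns `start`, `end`: 0-based, half-open
#'   character spans of the sentences, in order.
#' @examples
#' split_sentences("A is b. C is d.")
#' split_sentences("pH 7.4 buffer was used.") # one sentence
#' @export
split_sentences <- function(text, guards = sentence_guards()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- tibble::tibble(start = integer(), end = integer())
  if (!stringr::str_detect(text, "\\S")) {
    return(empty)
  }
  cand <- stringr::str_locate_all(text, "[.!?](?=\\s+[\\p{Lu}0-9])")[[1]][, 1]
  is_boundary <- vapply(cand, function(i) {
    if (substr(text, i, i) != ".") {
      return(TRUE)
    }
    prefix <- substr(text, 1L, i - 1L)
    word <- stringr::str_extract(prefix, "[\\p{L}\\p{Nd}.]+$")
    if (is.na(word)) {
      return(TRUE)
    }
    word <- sub("\\.+$", "", word)
    !(word %in% guards || stringr::str_detect(word, "^\\p{Lu}$"))
  }, logical(1))
  ends <- cand[is_boundary] # sentence ends at this 1-based position, inclusive
  seg_start <- c(1L, as.integer(ends) + 1L)
  seg_end <- c(as.integer(ends), stringr::str_length(text))
  spans <- purrr::map2(seg_start, seg_end, function(s, e) {
    if (s > e) {
      return(NULL)
    }
    seg <- substr(text, s, e)
    m <- stringr::str_locate(seg, "\\S")[1, 1]
    if (is.na(m)) {
      return(NULL)
    }
    last <- stringr::str_locate_all(seg, "\\S")[[1]]
    last <- last[nrow(last), 1]
    c(s + m - 1L, s + last - 1L)
  })
  spans <- purrr::compact(spans)
  if (length(spans) == 0L) {
    return(empty)
  }
  tibble::tibble(
    start = vapply(spans, function(x) as.integer(x[1] - 1L), integer(1)),
    end = vapply(spans, function(x) as.integer(x[2]), integer(1))
  )
}

# Character sets used by the coarse tokenizer.
.openers <- c("(", "[", "{", "\"", "'", "`")
.closers <- c(")", "]", "}", "\"", "'", "`", ",", ";", ":", "!", "?")

.digits <- as.character(0:9)

# Fast tibble constructor for the hot tokenization path.
.tok_tibble <- function(text, start, end) {
  tibble::new_tibble(
    list(text = text, start = as.integer(start), end = as.integer(end)),
    nrow = length(text)
  )
}

# Split one whitespace-delimited chunk into coarse tokens.
# Returns a two-column matrix of local 1-based inclusive (start, end) spans.
.coarse_split_chunk <- function(chars, is_last) {
  n <- length(chars)
  lo <- 1L
  hi <- n
  while (hi > lo && chars[lo] %in% .openers) lo <- lo + 1L
  while (hi > lo &&
    (chars[hi] %in% .closers || (chars[hi] == "." && is_last))) {
    hi <- hi - 1L
  }
  lead <- if (lo > 1L) seq_len(lo - 1L) else integer(0)
  trail <- if (hi < n) (hi + 1L):n else integer(0)
  # internal commas: detach unless flanked by digits on both sides (1,000)
  cuts <- integer(0) # comma positions that become standalone tokens
  if (any(chars[lo:hi] == ",")) {
    for (i in which(chars == ",")) {
      if (i >= lo && i <= hi &&
        !(i > lo && i < hi && chars[i - 1L] %in% .digits &&
          chars[i + 1L] %in% .digits)) {
        cuts <- c(cuts, i)
      }
    }
  }
  seg_bounds <- sort(unique(c(lo - 1L, cuts - 1L, cuts, hi)))
  starts <- seg_bounds[-length(seg_bounds)] + 1L
  ends <- seg_bounds[-1L]
  keep <- starts <= ends
  starts <- starts[keep]
  ends <- ends[keep]
  # contractions and genitives: won't -> wo n't, X's -> X 's
  if (any(chars[lo:hi] == "'")) {
    new_s <- integer(0)
    new_e <- integer(0)
    for (k in seq_along(starts)) {
      s <- starts[k]
      e <- ends[k]
      str <- paste(chars[s:e], collapse = "")
      cut <- NA_integer_
      if (grepl("[a-z]n't$", str, ignore.case = TRUE)) {
        cut <- e - 3L
      } else {
        m <- regexpr("'(s|re|ll|ve|d|m)$", str, ignore.case = TRUE)
        if (m > 1L) cut <- s + m - 2L
      }
      if (!is.na(cut) && cut >= s) {
        new_s <- c(new_s, s, cut + 1L)
        new_e <- c(new_e, cut, e)
      } else {
        new_s <- c(new_s, s)
        new_e <- c(new_e, e)
      }
    }
    starts <- new_s
    ends <- new_e
  }
  cbind(c(lead, starts, trail), c(lead, ends, trail))
}

#' Coarse (Penn-Treebank-style) tokenization
#'
#' Whitespace-delimited segmentation with punctuation detachment: opening
#' quotes and brackets are split off the front of a chunk, closing quotes,
#' brackets and clause punctuation off its end, a sentence-final period is
#' detached, commas are detached unless flanked by digits on both sides
#' (as in "1,000"), and verb contractions and Saxon genitives are split into
#' their morphemes ("won't" becomes "wo" + "n't"). Punctuation internal to a
#' chunk is otherwise kept, so chemical names such as "benzo(a)pyrene" and
#' "2,4-dinitrophenyl" survive as single tokens.
#'
#' @param text A single sentence as a character string.
#' @param base_offset Integer added to all offsets, so tokens can be indexed
#'   into the enclosing section when `text` is a sentence extracted from it.
#' @return A tibble with columns `text`, `start`, `end` (0-based half-open
#'   offsets). Tokens are non-empty, non-overlapping and sorted by `start`.
#' @examples
#' tokenize_coarse("10, 12-pentacosadiynoic acid")$text
#' tokenize_coarse("N-cinnamoylated chloroquine")$text
#' @export
tokenize_coarse <- function(text, base_offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chunks <- stringr::str_locate_all(text, "\\S+")[[1]]
  n_chunks <- nrow(chunks)
  if (n_chunks == 0L) {
    return(.tok_tibble(character(0), integer(0), integer(0)))
  }
  all_chars <- strsplit(text, "", fixed = TRUE)[[1]]
  starts <- vector("list", n_chunks)
  ends <- vector("list", n_chunks)
  for (j in seq_len(n_chunks)) {
    s <- chunks[j, 1]
    spans <- .coarse_split_chunk(all_chars[s:chunks[j, 2]],
      is_last = j == n_chunks
    )
    starts[[j]] <- s + spans[, 1] - 2L # 0-based
    ends[[j]] <- s + spans[, 2] - 1L
  }
  starts <- unlist(starts)
  ends <- unlist(ends)
  .tok_tibble(
    substring(text, starts + 1L, ends),
    base_offset + starts,
    base_offset + ends
  )
}

# Zero-width boundary pattern implementing the fine-grained splits:
# around any symbol (non-letter, non-digit), between letters and digits in
# both directions, and at lowercase-to-uppercase transitions.
.fine_boundary <- paste(
  "(?<=[^\\p{L}\\p{Nd}])",
  "(?=[^\\p{L}\\p{Nd}])",
  "(?<=\\p{L})(?=\\p{Nd})",
  "(?<=\\p{Nd})(?=\\p{L})",
  "(?<=\\p{Ll})(?=\\p{Lu})",
  sep = "|"
)

#' Fine-grained tokenization
#'
#' Applies [tokenize_coarse()] and then splits each token further: every
#' symbol (any character that is neither a Unicode letter nor a digit)
#' becomes a standalone token, and splits are inserted between letters and
#' digits (both directions) and where a lowercase letter is followed by an
#' uppercase one. Symbols are kept, so the segmentation is lossless and
#' offsets remain valid.
#'
#' @inheritParams tokenize_coarse
#' @return A tibble with columns `text`, `start`, `end`, as in
#'   [tokenize_coarse()].
#' @examples
#' nrow(tokenize_fine("α-phenyl-N-tert-butyl nitrone")) # 10
#' tokenize_fine("alcohols/esters")$text
#' @export
tokenize_fine <- function(text, base_offset = 0L) {
  coarse <- tokenize_coarse(text, base_offset = base_offset)
  if (nrow(coarse) == 0L) {
    return(coarse)
  }
  pieces <- stringr::str_split(coarse$text, .fine_boundary)
  n_per <- lengths(pieces)
  flat <- unlist(pieces, use.names = FALSE)
  origin <- rep.int(coarse$start, n_per)
  keep <- nzchar(flat)
  flat <- flat[keep]
  origin <- origin[keep]
  tok_of <- rep.int(seq_along(n_per), n_per)[keep]
  lens <- nchar(flat)
  # cumulative offset within each coarse token
  ends_global <- stats::ave(lens, tok_of, FUN = cumsum)
  .tok_tibble(flat, origin + ends_global - lens, origin + ends_global)
}

#' Tokenize a corpus of documents
#'
#' Runs sentence splitting and tokenization over the title and abstract of
#' each document, preserving character offsets into each section.
#'
#' @param documents A tibble of documents as returned by [read_abstracts()]
#'   or [generate_corpus()]: columns `doc_id`, `title`, `abstract`.
#' @param tokenizer `"fine"` (default) or `"coarse"`.
#' @param guards Abbreviation guard list for [split_sentences()].
#' @return A tibble with one row per token: `doc_id`, `section` (`"T"` or
#'   `"A"`), `sentence` (1-based index within the section), `token`
#'   (1-based index within the sentence), `start`, `end`, `text`.
#' @export
tokenize_corpus <- function(documents,
                            tokenizer = c("fine", "coarse"),
                            guards = sentence_guards()) {
  tokenizer <- match.arg(tokenizer)
  tok_fun <- if (tokenizer == "fine") tokenize_fine else tokenize_coarse
  section_tokens <- function(doc_id, section, text) {
    sents <- split_sentences(text, guards = guards)
    if (nrow(sents) == 0L) {
      return(NULL)
    }
    purrr::map(seq_len(nrow(sents)), function(i) {
      s <- sents$start[i]
      e <- sents$end[i]
      toks <- tok_fun(substr(text, s + 1L, e), base_offset = s)
      if (nrow(toks) == 0L) {
        return(NULL)
      }
      tibble::tibble(
        doc_id = doc_id, section = section, sentence = i,
        token = seq_len(nrow(toks)),
        start = toks$start, end = toks$end, text = toks$text
      )
    })
  }
  rows <- purrr::pmap(
    list(documents$doc_id, documents$title, documents$abstract),
    function(id, title, abstract) {
      c(
        section_tokens(id, "T", title),
        section_tokens(id, "A", abstract)
      )
    }
  )
  dplyr::bind_rows(purrr::list_flatten(rows))
}
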