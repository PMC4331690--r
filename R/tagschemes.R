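# Conversion between character-span mentions and per-token tag sequences
# under the IOB, IOBE, IOBES and IOB12E schemes, including repair-based
# decoding of ill-formed model output.

#' The seven chemical mention categories
#'
#' Category labels used for chemical mentions: systematic (IUPAC-style)
#' names, database identifiers, molecular formulas, trivial/brand names,
#' chemical families, discontinuous multi-chemical mentions, and
#' abbreviations.
#'
#' @format Character vector of length 7.
#' @export
chem_categories <- c(
  "SYSTEMATIC", "IDENTIFIER", "FORMULA", "TRIVIAL",
  "FAMILY", "MULTIPLE", "ABBREVIATION"
)

#' Supported tag scheme names
#' @export
tag_schemes <- c("IOB", "IOBE", "IOBES", "IOB12E")

.scheme_prefixes <- list(
  IOB = c("B", "I"),
  IOBE = c("B", "I", "E"),
  IOBES = c("B", "I", "E", "S"),
  IOB12E = c("B1", "B2", "I", "E")
)

#' Tag inventory of a scheme
#'
#' The full tag set of a scheme: one tag per (positional prefix, category)
#' pair plus the outside tag `"O"`, sorted lexicographically. The sorted
#' order is the tie-breaking order used by Viterbi decoding.
#'
#' @param scheme One of `"IOB"`, `"IOBE"`, `"IOBES"`, `"IOB12E"`.
#' @return Character vector of tags (length `|prefixes| * 7 + 1`).
#' @examples
#' length(tag_inventory("IOBES")) # 4 * 7 + 1
#' @export
tag_inventory <- function(scheme) {
  scheme <- match.arg(scheme, tag_schemes)
  prefixes <- .scheme_prefixes[[scheme]]
  tags <- c("O", as.vector(outer(prefixes, chem_categories, paste, sep = "-")))
  sort(tags, method = "radix")
}

#' Project character-span mentions onto token index ranges
#'
#' Maps each mention to the minimal contiguous range of tokens covering its
#' character span. Mentions whose boundaries cut through a token (possible
#' under coarse tokenization) are flagged with a warning and either expanded
#' to the covering tokens or dropped, per `policy`.
#'
#' @param tokens Tokens of one sentence: a tibble with columns `start`,
#'   `end` (0-based half-open), sorted by `start`.
#' @param mentions Mentions falling inside the sentence: a tibble with
#'   columns `start`, `end`, `category`.
#' @param policy `"expand"` (default) or `"drop"` for boundary-crossing
#'   mentions.
#' @return A tibble with columns `first`, `last` (1-based token indices,
#'   inclusive) and `category`, sorted by `first`.
#' @export
align_mentions <- function(tokens, mentions, policy = c("expand", "drop")) {
  policy <- match.arg(policy)
  out <- tibble::tibble(
    first = integer(), last = integer(), category = character()
  )
  if (nrow(mentions) == 0L) {
    return(out)
  }
  rows <- purrr::pmap(
    list(mentions$start, mentions$end, mentions$category),
    function(ms, me, cat) {
      idx <- which(tokens$start < me & tokens$end > ms)
      if (length(idx) == 0L) {
        warning("mention [", ms, ",", me, ") covers no token; dropped",
          call. = FALSE
        )
        return(NULL)
      }
      first <- min(idx)
      last <- max(idx)
      if (tokens$start[first] != ms || tokens$end[last] != me) {
        warning(
          "mention [", ms, ",", me, ") crosses token boundaries; ",
          if (policy == "expand") "expanded to covering tokens" else "dropped",
          call. = FALSE
        )
        if (policy == "drop") {
          return(NULL)
        }
      }
      tibble::tibble(first = first, last = last, category = cat)
    }
  )
  out <- dplyr::arrange(dplyr::bind_rows(c(list(out), rows)), .data$first)
  if (nrow(out) > 1L &&
    any(out$first[-1L] <= out$last[-nrow(out)])) {
    stop("overlapping mentions after alignment; corpus must be non-overlapping")
  }
  out
}

#' Encode aligned mention ranges as a tag sequence
#'
#' @param n_tokens Number of tokens in the sentence.
#' @param ranges Aligned mention ranges, as returned by [align_mentions()]:
#'   non-overlapping, sorted tibble with `first`, `last`, `category`.
#' @param scheme Tag scheme name, see [tag_schemes].
#' @param iob12e_two_token How a two-token entity is tagged under IOB12E:
#'   `"B1E"` (default; the terminator stays explicit) or `"B1B2"`.
#' @return Character vector of `n_tokens` tags from the scheme's inventory.
#' @examples
#' encode_tags(6, tibble::tibble(
#'   first = c(1L, 5L), last = c(3L, 5L),
#'   category = c("FAMILY", "ABBREVIATION")
#' ), "IOBES")
#' @export
encode_tags <- function(n_tokens, ranges, scheme,
                        iob12e_two_token = c("B1E", "B1B2")) {
  scheme <- match.arg(scheme, tag_schemes)
  iob12e_two_token <- match.arg(iob12e_two_token)
  if (nrow(ranges) > 1L) {
    o <- order(ranges$first)
    ranges <- ranges[o, ]
    if (any(ranges$first[-1L] <= ranges$last[-nrow(ranges)])) {
      stop("overlapping mention ranges cannot be encoded")
    }
  }
  tags <- rep("O", n_tokens)
  for (k in seq_len(nrow(ranges))) {
    f <- ranges$first[k]
    l <- ranges$last[k]
    cat <- ranges$category[k]
    len <- l - f + 1L
    prefixes <- switch(scheme,
      IOB = c("B", rep("I", len - 1L)),
      IOBE = if (len == 1L) "B" else c("B", rep("I", len - 2L), "E"),
      IOBES = if (len == 1L) {
        "S"
      } else {
        c("B", rep("I", len - 2L), "E")
      },
      IOB12E = if (len == 1L) {
        "B1"
      } else if (len == 2L) {
        if (iob12e_two_token == "B1E") c("B1", "E") else c("B1", "B2")
      } else {
        c("B1", "B2", rep("I", len - 3L), "E")
      }
    )
    tags[f:l] <- paste(prefixes, cat, sep = "-")
  }
  tags
}

#' Decode a tag sequence to mention token ranges, repairing ill-formed runs
#'
#' Total function over arbitrary tag sequences (anything a model could
#' emit). Repair rules: an inside/end/second-begin tag without a matching
#' open entity of the same category opens a new one; a category change or an
#' outside tag closes the open entity; `S` is always a singleton; `E` closes
#' the entity at its position. Decoded ranges never overlap.
#'
#' @param tags Character vector of tags (`"O"` or `prefix-CATEGORY`).
#' @return A tibble with columns `first`, `last`, `category`.
#' @examples
#' decode_tags(c("B-FAMILY", "I-FAMILY", "E-FAMILY", "O", "S-ABBREVIATION", "O"))
#' decode_tags(c("O", "I-TRIVIAL", "O")) # repaired to a singleton
#' @export
decode_tags <- function(tags) {
  n <- length(tags)
  firsts <- integer(0)
  lasts <- integer(0)
  cats <- character(0)
  open_first <- NA_integer_
  open_cat <- NA_character_
  close_entity <- function(last) {
    if (!is.na(open_first)) {
      firsts <<- c(firsts, open_first)
      lasts <<- c(lasts, last)
      cats <<- c(cats, open_cat)
      open_first <<- NA_integer_
      open_cat <<- NA_character_
    }
  }
  for (i in seq_len(n)) {
    tag <- tags[i]
    if (is.na(tag) || tag == "O" || !stringr::str_detect(tag, "-")) {
      close_entity(i - 1L)
      next
    }
    prefix <- sub("-.*$", "", tag)
    cat <- sub("^[^-]*-", "", tag)
    if (prefix %in% c("B", "B1", "S")) {
      close_entity(i - 1L)
      open_first <- i
      open_cat <- cat
      if (prefix == "S") close_entity(i)
    } else if (prefix %in% c("I", "B2", "E")) {
      if (is.na(open_first) || open_cat != cat) {
        close_entity(i - 1L)
        open_first <- i
        open_cat <- cat
      }
      if (prefix == "E") close_entity(i)
    } else {
      # unknown prefix: treat as outside
      close_entity(i - 1L)
    }
  }
  close_entity(n)
  tibble::tibble(first = firsts, last = lasts, category = cats)
}

#' Recover character-span mentions from decoded token ranges
#'
#' @param tokens Tokens of one sentence (tibble with `start`, `end`).
#' @param ranges Decoded ranges from [decode_tags()].
#' @param section_text Full text of the section the tokens index into; used
#'   to recover the exact surface string (including internal whitespace).
#' @param doc_id,section Identifiers copied onto the output rows.
#' @return A mention tibble: `doc_id`, `section`, `start`, `end`, `text`,
#'   `category`.
#' @export
mentions_from_ranges <- function(tokens, ranges, section_text,
                                 doc_id = NA_character_, section = NA_character_) {
  start <- tokens$start[ranges$first]
  end <- tokens$end[ranges$last]
  tibble::tibble(
    doc_id = doc_id,
    section = section,
    start = as.integer(start),
    end = as.integer(end),
    text = substr(rep(section_text, length(start)), start + 1L, end),
    category = ranges$category
  )
}
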