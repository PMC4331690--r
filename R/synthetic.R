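# Seedable generator of synthetic annotated corpora in the abstracts +
# annotations format, with known gold offsets, controllable category and
# entity-length mixes, and template-derived POS/chunk annotations.
#
# "Entity length" throughout is the number of fine-grained tokens of the
# mention surface; every name constructor below builds a surface with an
# exact, known fine-token count.

.sys_stems <- c(
  "meth", "eth", "prop", "but", "pent", "hex", "benz", "phen", "chlor",
  "brom", "fluor", "nitr", "sulf", "carb", "oxo", "hydrox", "cycl",
  "acet", "tolu", "pyr"
)
.sys_suffixes <- c(
  "ane", "ene", "ol", "al", "one", "ide", "ate", "ine", "yl", "oxide",
  "amine", "onic"
)
.sys_multipliers <- c("di", "tri", "tetra", "penta")
.trivial_words <- c(
  "aspirin", "ibuprofen", "paracetamol", "caffeine", "morphine", "codeine",
  "nicotine", "taurine", "retinol", "thymol", "menthol", "urea",
  "cholesterol", "dopamine", "serotonin", "melatonin", "quinine",
  "atropine", "naproxen", "warfarin", "glucose", "sucrose", "fructose",
  "Tylenol", "Advil", "Prozac"
)
.trivial_acids <- c(
  "valproic", "folic", "citric", "acetic", "ascorbic", "lactic",
  "salicylic", "benzoic", "oleic", "palmitic"
)
.family_nouns <- c(
  "alcohols", "esters", "ketones", "phenols", "alkaloids", "flavonoids",
  "terpenes", "steroids", "opioids", "sulfonamides", "hydrocarbons",
  "amines", "ethers", "aldehydes", "carbohydrates", "quinolones"
)
.family_adjectives <- c(
  "aromatic", "polycyclic", "halogenated", "cyclic", "saturated",
  "volatile", "fatty", "aliphatic", "heterocyclic", "polyunsaturated"
)
.id_prefixes <- c("CHEBI", "CID", "CAS", "CHEMBL", "DB")
.elements_two <- c("Na", "Cl", "Ca", "Fe", "Mg", "Br", "Si", "Zn", "Cu", "Mn")
.elements_one <- c("H", "C", "N", "O", "S", "P", "K")

.pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

# A single all-lowercase systematic word (one fine token).
.sys_word <- function() {
  parts <- c(
    if (stats::runif(1) < 0.4) .pick(.sys_multipliers),
    .pick(.sys_stems, sample(1:2, 1)),
    .pick(.sys_suffixes)
  )
  paste0(parts, collapse = "")
}

# A systematic word with n_sep internal separators (2 * n_sep + 1 fine
# tokens): a sequence of morphemes (digit locants, single capitals, or
# lowercase syllables) ending in a lowercase word, joined by "-", with ","
# between consecutive digit locants.
.sys_hyphen_word <- function(n_sep, locant_start = TRUE) {
  if (n_sep == 0L) {
    return(.sys_word())
  }
  kinds <- character(n_sep)
  if (locant_start) {
    n_loc <- sample.int(n_sep, 1)
    kinds[seq_len(n_loc)] <- "digit"
    if (n_loc < n_sep) {
      kinds[(n_loc + 1):n_sep] <- .pick(c("syl", "cap", "syl"), n_sep - n_loc)
    }
  } else {
    kinds <- .pick(c("syl", "cap", "digit"), n_sep)
  }
  morphs <- vapply(kinds, function(k) {
    switch(k,
      digit = as.character(sample.int(12, 1)),
      cap = .pick(c("N", "O", "S")),
      syl = paste0(.pick(.sys_multipliers), .pick(.sys_stems))
    )
  }, character(1))
  morphs <- c(morphs, .sys_word())
  seps <- vapply(seq_len(n_sep), function(j) {
    if (kinds[j] == "digit" && j < n_sep && kinds[j + 1] == "digit") "," else "-"
  }, character(1))
  paste0(paste0(morphs[seq_len(n_sep)], seps, collapse = ""), morphs[n_sep + 1])
}

# Decompose a fine-token length into odd per-word lengths (words are
# separated by spaces; a word with h separators has 2h + 1 fine tokens).
.odd_parts <- function(len, prefer_large = TRUE) {
  parts <- integer(0)
  rem <- len
  while (rem > 0L) {
    cand <- seq(1L, min(rem, 7L), by = 2L)
    p <- if (rem %% 2L == 0L) {
      # an even remainder needs at least two words
      cand <- cand[cand < rem]
      .pick(cand)
    } else if (prefer_large && stats::runif(1) < 0.7) {
      max(cand)
    } else {
      .pick(cand)
    }
    parts <- c(parts, p)
    rem <- rem - p
  }
  parts
}

.name_systematic <- function(len) {
  parts <- .odd_parts(len)
  words <- vapply(seq_along(parts), function(i) {
    n_sep <- (parts[i] - 1L) %/% 2L
    .sys_hyphen_word(n_sep, locant_start = i == 1L && stats::runif(1) < 0.85)
  }, character(1))
  paste(words, collapse = " ")
}

.name_formula <- function(len) {
  groups <- vapply(seq_len(len), function(i) {
    if (i %% 2L == 1L) {
      if (stats::runif(1) < 0.5) {
        .pick(.elements_two)
      } else {
        paste0(.pick(.elements_one, sample(1:2, 1)), collapse = "")
      }
    } else {
      as.character(sample.int(20, 1))
    }
  }, character(1))
  paste0(groups, collapse = "")
}

.name_identifier <- function(len) {
  digits <- paste0(sample(0:9, sample(4:6, 1), replace = TRUE), collapse = "")
  if (len == 3L) {
    paste0(.pick(.id_prefixes), ":", digits)
  } else {
    paste0(paste0(.pick(LETTERS, 3), collapse = ""), digits)
  }
}

.name_abbreviation <- function() {
  paste0(.pick(LETTERS, sample(2:6, 1)), collapse = "")
}

.name_trivial <- function(len) {
  if (len == 1L) {
    .pick(.trivial_words)
  } else {
    paste(.pick(.trivial_acids), "acid")
  }
}

.name_family <- function(len) {
  words <- c(.pick(.family_adjectives, len - 1L), .pick(.family_nouns))
  paste(words, collapse = " ")
}

.name_multiple <- function(len) {
  k <- (len + 1L) %/% 2L
  frags <- .pick(c(.family_nouns, .trivial_words[1:15]), k)
  paste0(frags, collapse = "/")
}

# Feasible fine-token lengths per category (lengths 1..8).
.feasible_lengths <- list(
  SYSTEMATIC = 1:8,
  IDENTIFIER = 2:3,
  FORMULA = 2:8,
  TRIVIAL = 1:2,
  FAMILY = 1:3,
  MULTIPLE = c(3L, 5L, 7L),
  ABBREVIATION = 1L
)

# Category-conditional default length profiles used when make_name() is
# called without a target length. Systematic names default to locant-rich
# multi-token surfaces, as systematic nomenclature usually is.
.default_length_profile <- list(
  SYSTEMATIC = c(0.20, 0.05, 0.35, 0.10, 0.20, 0, 0.10, 0),
  IDENTIFIER = c(0, 0.4, 0.6, 0, 0, 0, 0, 0),
  FORMULA = c(0, 0.35, 0.15, 0.30, 0.10, 0.10, 0, 0),
  TRIVIAL = c(0.8, 0.2, 0, 0, 0, 0, 0, 0),
  FAMILY = c(0.45, 0.35, 0.20, 0, 0, 0, 0, 0),
  MULTIPLE = c(0, 0, 0.7, 0, 0.25, 0, 0.05, 0),
  ABBREVIATION = c(1, 0, 0, 0, 0, 0, 0, 0)
)

#' Generate one chemical-like surface string
#'
#' Draws a category-appropriate surface form: systematic names from a
#' morpheme grammar (digit locant lists such as "2,4-", multipliers,
#' stems and suffixes), formulas from an element-symbol + count grammar,
#' identifiers as a database prefix plus digits, abbreviations as short
#' uppercase strings, trivial and family names from word lists, and
#' "multiple" mentions as slash-conjoined fragments. Uses R's RNG; fix
#' `set.seed()` for reproducible sequences.
#'
#' @param category One of [chem_categories].
#' @param length Target length of the surface in fine-grained tokens; must
#'   be feasible for the category (see the error message otherwise). When
#'   `NULL`, drawn from a category-typical profile.
#' @return A single string whose [tokenize_fine()] token count equals
#'   `length`.
#' @export
make_name <- function(category, length = NULL) {
  category <- match.arg(category, chem_categories)
  feas <- .feasible_lengths[[category]]
  if (is.null(length)) {
    prof <- .default_length_profile[[category]]
    length <- sample.int(8L, 1L, prob = prof)
  }
  length <- as.integer(length)
  if (!(length %in% feas)) {
    stop(
      "category ", category, " cannot realize an entity of length ", length,
      " (feasible: ", paste(feas, collapse = ", "), ")"
    )
  }
  switch(category,
    SYSTEMATIC = .name_systematic(length),
    IDENTIFIER = .name_identifier(length),
    FORMULA = .name_formula(length),
    TRIVIAL = .name_trivial(length),
    FAMILY = .name_family(length),
    MULTIPLE = .name_multiple(length),
    ABBREVIATION = .name_abbreviation()
  )
}

# Iterative proportional fitting of the category x length joint to the
# configured marginals under the feasibility mask.
.ipf_joint <- function(category_mix, length_dist, iterations = 300L) {
  k <- length(length_dist)
  mask <- matrix(0, nrow = 7, ncol = k,
    dimnames = list(chem_categories, NULL))
  for (cat in chem_categories) {
    feas <- .feasible_lengths[[cat]]
    mask[cat, feas[feas <= k]] <- 1
  }
  joint <- outer(category_mix, length_dist) * mask
  for (i in seq_len(iterations)) {
    rs <- rowSums(joint)
    joint <- joint * ifelse(rs > 0, category_mix / rs, 0)
    cs <- colSums(joint)
    joint <- t(t(joint) * ifelse(cs > 0, length_dist / cs, 0))
  }
  joint / sum(joint)
}

.default_templates <- function() {
  tpl <- function(words, pos, chunk) list(words = words, pos = pos, chunk = chunk)
  list(
    tpl(
      c("Effects", "of", "<E1>", "on", "<F1>", "in", "rats", "."),
      c("NNS", "IN", "ENT", "IN", "NN", "IN", "NNS", "."),
      c("B-NP", "B-PP", "B-NP", "B-PP", "B-NP", "B-PP", "B-NP", "O")
    ),
    tpl(
      c("The", "compound", "<E1>", "inhibited", "<F1>", "activity", "."),
      c("DT", "NN", "ENT", "VBD", "NN", "NN", "."),
      c("B-NP", "I-NP", "I-NP", "B-VP", "B-NP", "I-NP", "O")
    ),
    tpl(
      c("Treatment", "with", "<E1>", "and", "<E2>", "reduced", "<F1>", "levels", "."),
      c("NN", "IN", "ENT", "CC", "ENT", "VBD", "NN", "NNS", "."),
      c("B-NP", "B-PP", "B-NP", "O", "B-NP", "B-VP", "B-NP", "I-NP", "O")
    ),
    tpl(
      c("We", "measured", "the", "concentration", "of", "<E1>", "in", "<F1>", "samples", "."),
      c("PRP", "VBD", "DT", "NN", "IN", "ENT", "IN", "NN", "NNS", "."),
      c("B-NP", "B-VP", "B-NP", "I-NP", "B-PP", "B-NP", "B-PP", "B-NP", "I-NP", "O")
    ),
    tpl(
      c("Exposure", "to", "<E1>", "increased", "<F1>", "expression", "."),
      c("NN", "TO", "ENT", "VBD", "NN", "NN", "."),
      c("B-NP", "B-PP", "B-NP", "B-VP", "B-NP", "I-NP", "O")
    ),
    tpl(
      c("<E1>", "was", "synthesized", "from", "<E2>", "under", "mild", "conditions", "."),
      c("ENT", "VBD", "VBN", "IN", "ENT", "IN", "JJ", "NNS", "."),
      c("B-NP", "B-VP", "I-VP", "B-PP", "B-NP", "B-PP", "B-NP", "I-NP", "O")
    ),
    tpl(
      c("The", "role", "of", "<E1>", "in", "<F1>", "metabolism", "was", "examined", "."),
      c("DT", "NN", "IN", "ENT", "IN", "NN", "NN", "VBD", "VBN", "."),
      c("B-NP", "I-NP", "B-PP", "B-NP", "B-PP", "B-NP", "I-NP", "B-VP", "I-VP", "O")
    ),
    tpl(
      c("Administration", "of", "<E1>", "improved", "<F1>", "function", "in", "mice", "."),
      c("NN", "IN", "ENT", "VBD", "NN", "NN", "IN", "NNS", "."),
      c("B-NP", "B-PP", "B-NP", "B-VP", "B-NP", "I-NP", "B-PP", "B-NP", "O")
    ),
    tpl(
      c("Binding", "of", "<E1>", "to", "<F1>", "receptors", "was", "observed", "."),
      c("NN", "IN", "ENT", "TO", "NN", "NNS", "VBD", "VBN", "."),
      c("B-NP", "B-PP", "B-NP", "B-PP", "B-NP", "I-NP", "B-VP", "I-VP", "O")
    ),
    tpl(
      c("Samples", "were", "analyzed", "for", "<E1>", "and", "<E2>", "by", "chromatography", "."),
      c("NNS", "VBD", "VBN", "IN", "ENT", "CC", "ENT", "IN", "NN", "."),
      c("B-NP", "B-VP", "I-VP", "B-PP", "B-NP", "O", "B-NP", "B-PP", "B-NP", "O")
    )
  )
}

.filler_nouns <- c(
  "enzyme", "plasma", "serum", "tissue", "liver", "kidney", "neuron",
  "muscle", "tumor", "membrane", "cortex", "mucosa"
)

#' Synthetic corpus generator configuration
#'
#' @param n_docs Number of documents (at least 1).
#' @param seed Optional integer seed; when given, [generate_corpus()] is
#'   byte-reproducible.
#' @param category_mix Named probabilities over the seven categories
#'   (must sum to 1).
#' @param length_dist Probabilities over entity lengths 1..8 in fine-grained
#'   tokens (must sum to 1). The default follows the heavily
#'   single-token-skewed length profile typical of chemical corpora
#'   (about 70.9% single-token, 9.2% two-token, 6.2% three-token, 4.4%
#'   four-token, the rest longer).
#' @param mentions_per_doc Integer range (min, max) of gold mentions per
#'   document.
#' @param sentences_per_abstract Integer range (min, max) of abstract
#'   sentences.
#' @param ambiguity Probability that a non-entity filler slot is filled with
#'   an entity-like surface without a gold annotation (default 0.05).
#' @param templates Sentence templates; each a list with `words`, `pos`,
#'   `chunk` vectors of equal length, where `<E1>`, `<E2>` mark entity slots
#'   and `<F1>` a filler slot. Every template must contain at least one
#'   entity slot.
#' @return A validated configuration list of class `chemner_gen_config`.
#' @export
generator_config <- function(n_docs = 100L,
                             seed = NULL,
                             category_mix = c(
                               SYSTEMATIC = 0.28, TRIVIAL = 0.26,
                               ABBREVIATION = 0.15, FAMILY = 0.15,
                               FORMULA = 0.10, IDENTIFIER = 0.03,
                               MULTIPLE = 0.03
                             ),
                             length_dist = c(
                               0.709, 0.092, 0.062, 0.044,
                               0.050, 0.025, 0.012, 0.006
                             ),
                             mentions_per_doc = c(2L, 6L),
                             sentences_per_abstract = c(2L, 4L),
                             ambiguity = 0.05,
                             templates = .default_templates()) {
  if (n_docs < 1L) stop("n_docs must be at least 1")
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1")
  }
  if (!all(chem_categories %in% names(category_mix))) {
    stop("category_mix must name all seven categories")
  }
  if (abs(sum(length_dist) - 1) > 1e-9) {
    stop("length_dist must sum to 1")
  }
  ok <- vapply(templates, function(t) {
    length(t$words) == length(t$pos) &&
      length(t$words) == length(t$chunk) &&
      any(grepl("^<E[0-9]+>$", t$words))
  }, logical(1))
  if (!all(ok)) {
    stop("template ", which(!ok)[1L], " lacks an entity slot or has ",
      "mismatched word/pos/chunk lengths")
  }
  structure(
    list(
      n_docs = as.integer(n_docs), seed = seed,
      category_mix = category_mix[chem_categories],
      length_dist = length_dist,
      mentions_per_doc = as.integer(mentions_per_doc),
      sentences_per_abstract = as.integer(sentences_per_abstract),
      ambiguity = ambiguity, templates = templates
    ),
    class = "chemner_gen_config"
  )
}

# Render one template instance. fill_entities: how many entity slots get a
# gold mention. Returns the sentence text plus relative-offset mention and
# token-annotation rows.
.render_sentence <- function(template, fill_entities, joint, ambiguity) {
  words <- template$words
  n <- length(words)
  e_slots <- which(grepl("^<E[0-9]+>$", words))
  f_slots <- which(grepl("^<F[0-9]+>$", words))
  filled <- if (fill_entities > 0L) {
    sort(.pick(e_slots, min(fill_entities, length(e_slots))))
  } else {
    integer(0)
  }
  filled <- unique(filled)
  draw_entity <- function() {
    cell <- sample.int(length(joint), 1L, prob = as.vector(joint))
    cat <- chem_categories[(cell - 1L) %% 7L + 1L]
    len <- (cell - 1L) %/% 7L + 1L
    list(category = cat, text = make_name(cat, len))
  }
  surface <- character(n)
  mention_at <- vector("list", n)
  for (i in seq_len(n)) {
    if (i %in% filled) {
      ent <- draw_entity()
      surface[i] <- ent$text
      mention_at[[i]] <- ent$category
    } else if (i %in% c(e_slots, f_slots)) {
      if (stats::runif(1) < ambiguity) {
        surface[i] <- draw_entity()$text # ambiguous: entity-like, no gold
      } else {
        surface[i] <- .pick(.filler_nouns)
      }
    } else {
      surface[i] <- words[i]
    }
  }
  # join with spaces, attaching "." and "," to the preceding word
  text <- ""
  starts <- integer(n)
  for (i in seq_len(n)) {
    sep <- if (i == 1L || surface[i] %in% c(".", ",")) "" else " "
    starts[i] <- nchar(text) + nchar(sep)
    text <- paste0(text, sep, surface[i])
  }
  ends <- starts + nchar(surface)
  is_mention <- !vapply(mention_at, is.null, logical(1))
  mentions <- tibble::tibble(
    start = starts[is_mention], end = ends[is_mention],
    text = surface[is_mention],
    category = unlist(mention_at[is_mention]) %||% character(0)
  )
  ann <- tibble::tibble(
    start = starts, end = ends,
    pos = ifelse(template$pos == "ENT", "NN", template$pos),
    chunk = template$chunk
  )
  list(text = text, mentions = mentions, annotations = ann, n_filled = length(filled))
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents from sentence templates with chemical-like names spliced
#' into entity slots. Gold mention offsets are exact against the produced
#' text; the joint distribution of mention categories and fine-token lengths
#' is fitted to the configured marginals (iterative proportional fitting
#' over the category/length feasibility mask), so for large corpora the
#' realized category and length mixes track the configured ones closely.
#' POS and chunk tags are emitted per template word as a token-annotation
#' sidecar.
#'
#' @param config A [generator_config()].
#' @return A list with tibbles `documents` (`doc_id`, `title`, `abstract`),
#'   `mentions` (gold, validated), and `token_annotations` (`doc_id`,
#'   `section`, `start`, `end`, `pos`, `chunk`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "chemner_gen_config"))
  if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  joint <- .ipf_joint(config$category_mix, config$length_dist)
  templates <- config$templates
  one_slot <- templates[vapply(
    templates,
    function(t) sum(grepl("^<E[0-9]+>$", t$words)) == 1L, logical(1)
  )]
  docs <- vector("list", config$n_docs)
  mens <- vector("list", config$n_docs)
  anns <- vector("list", config$n_docs)
  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("SD%05d", d)
    m_total <- .pick(seq(config$mentions_per_doc[1], config$mentions_per_doc[2]))
    # title: one 1-slot sentence, carrying a mention with probability 0.7
    title_fill <- as.integer(m_total > 0L && stats::runif(1) < 0.7)
    title <- .render_sentence(
      .pick(one_slot)[[1]], title_fill, joint,
      config$ambiguity
    )
    remaining <- m_total - nrow(title$mentions)
    n_sent <- .pick(
      seq(config$sentences_per_abstract[1], config$sentences_per_abstract[2])
    )
    sents <- list()
    while (length(sents) < n_sent || remaining > 0L) {
      tpl <- .pick(templates)[[1]]
      want <- min(remaining, sum(grepl("^<E[0-9]+>$", tpl$words)))
      s <- .render_sentence(tpl, want, joint, config$ambiguity)
      remaining <- remaining - nrow(s$mentions)
      sents <- c(sents, list(s))
    }
    # assemble the abstract, shifting offsets
    offset <- 0L
    abs_text <- character(length(sents))
    for (k in seq_along(sents)) {
      if (k > 1L) offset <- offset + 1L # joining space
      sents[[k]]$mentions$start <- sents[[k]]$mentions$start + offset
      sents[[k]]$mentions$end <- sents[[k]]$mentions$end + offset
      sents[[k]]$annotations$start <- sents[[k]]$annotations$start + offset
      sents[[k]]$annotations$end <- sents[[k]]$annotations$end + offset
      abs_text[k] <- sents[[k]]$text
      offset <- offset + nchar(sents[[k]]$text)
    }
    abstract <- paste(abs_text, collapse = " ")
    docs[[d]] <- tibble::tibble(
      doc_id = doc_id, title = title$text,
      abstract = abstract
    )
    doc_mentions <- dplyr::bind_rows(
      dplyr::mutate(title$mentions, section = "T"),
      dplyr::mutate(
        dplyr::bind_rows(purrr::map(sents, "mentions")),
        section = "A"
      )
    )
    doc_mentions$doc_id <- rep(doc_id, nrow(doc_mentions))
    mens[[d]] <- doc_mentions[, c(
      "doc_id", "section", "start", "end",
      "text", "category"
    )]
    doc_ann <- dplyr::bind_rows(
      dplyr::mutate(title$annotations, section = "T"),
      dplyr::mutate(
        dplyr::bind_rows(purrr::map(sents, "annotations")),
        section = "A"
      )
    )
    doc_ann$doc_id <- rep(doc_id, nrow(doc_ann))
    anns[[d]] <- doc_ann[, c("doc_id", "section", "start", "end", "pos", "chunk")]
  }
  documents <- dplyr::bind_rows(docs)
  mentions <- dplyr::bind_rows(mens)
  validate_mentions(mentions, documents)
  list(
    documents = documents,
    mentions = mentions,
    token_annotations = dplyr::bind_rows(anns)
  )
}
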