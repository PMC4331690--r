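# Word, affix, orthographic, word-shape and syntax features.

test_that("digit-run normalization matches the homologue-collapsing rule", {
  expect_equal(normalize_word("cyclooxygenase-2"), "cyclooxygenase-1")
  expect_equal(normalize_word("abc"), "abc")
  expect_equal(normalize_word("CHEBI:28262"), "CHEBI:1")
  expect_equal(normalize_word("a12b345"), "a1b1")
  # idempotent
  x <- c("cyclooxygenase-2", "H2SO4", "10,12-diynoic")
  expect_equal(normalize_word(normalize_word(x)), normalize_word(x))
})

test_that("the orthographic pattern table has exactly 18 compiling patterns", {
  pats <- ortho_patterns()
  expect_equal(nrow(pats), 18L)
  expect_setequal(pats$name, c(
    "FG", "INITCAPS", "CAPWORD", "ALLCAPS", "CAPSMIX", "ALPHANUMMIX",
    "ALPHANUM", "UPPERCHAR", "LOWERCHAR", "SHORTNUM", "INTEGER", "REAL",
    "ROMAN", "HASDASH", "INITDASH", "ENDDASH", "PUNCTUATION", "QUOTE"
  ))
  for (p in pats$pattern) {
    expect_no_error(stringr::str_detect("x", p))
  }
  # the relaxed variant swaps the A-z ranges for A-Za-z
  relaxed <- ortho_patterns(strict_az = FALSE)
  expect_false(any(grepl("A-z]", relaxed$pattern, fixed = TRUE)))
})

test_that("orthographic features fire on the expected surface styles", {
  expect_true("ortho:FG" %in% ortho_features("2,4-dinitrophenyl")[[1]])
  tylenol <- ortho_features("Tylenol")[[1]]
  expect_true(all(c("ortho:CAPWORD", "ortho:INITCAPS") %in% tylenol))
  expect_false("ortho:ALLCAPS" %in% tylenol)
  xiv <- ortho_features("XIV")[[1]]
  expect_true(all(c("ortho:ROMAN", "ortho:ALLCAPS") %in% xiv))
  expect_true(all(c("ortho:HASDASH", "ortho:ENDDASH") %in%
    ortho_features("octadecanol-")[[1]]))
  expect_true("ortho:ALPHANUMMIX" %in% ortho_features("ICI204636")[[1]])
  expect_true("ortho:QUOTE" %in% ortho_features("\"")[[1]])
})

test_that("word shapes map case, digits and other characters as specified", {
  sh <- word_shape("Aaaaa_A")
  expect_equal(sh$collapsed, "Aa_A")
  sh <- word_shape(c("Na(2)CO(3)", "As(2)O(3)"))
  expect_equal(sh$raw, c("Aa_0_AA_0_", "Aa_0_A_0_"))
  expect_equal(sh$collapsed, c("Aa_0_A_0_", "Aa_0_A_0_"))
  # the alternate digit symbol reproduces the digit-normalized rendering
  expect_equal(word_shape("Na(2)CO(3)", shape_digit = "1")$raw, "Aa_1_AA_1_")
  # Greek letters and punctuation are non-English -> "_"
  expect_equal(word_shape("α-ol")$raw, "__aa")
  expect_equal(word_shape("")$raw, "")
  expect_equal(word_shape("")$collapsed, "")
})

test_that("collapsed shapes never contain equal adjacent characters", {
  set.seed(404)
  pool <- c(letters, LETTERS, 0:9, "α", "-", "(", ")")
  for (i in 1:200) {
    w <- paste(sample(pool, sample(1:12, 1), replace = TRUE), collapse = "")
    coll <- word_shape(w)$collapsed
    cs <- strsplit(coll, "")[[1]]
    if (length(cs) > 1) expect_true(all(cs[-1] != cs[-length(cs)]))
  }
})

test_that("affixes cover lengths three to five capped at the token length", {
  a <- affix_features("hydrogen")[[1]]
  expect_setequal(a, c(
    "pre3=hyd", "pre4=hydr", "pre5=hydro",
    "suf3=gen", "suf4=ogen", "suf5=rogen"
  ))
  expect_length(affix_features("ab")[[1]], 0L)
  expect_setequal(
    affix_features("abcd")[[1]],
    c("pre3=abc", "pre4=abcd", "suf3=bcd", "suf4=abcd")
  )
  # computed on the digit-normalized form
  expect_true("suf3=e-1" %in% affix_features("cyclooxygenase-22")[[1]])
})

test_that("word context features carry sentinels and n-gram conjunctions", {
  f <- token_features(c("nitric", "oxide", "synthase"),
    config = feature_config(affix = FALSE, ortho = FALSE, shape = FALSE)
  )
  expect_true("w[-1]=__BOS__" %in% f[[1]])
  expect_true("w[-2]=__BOS__" %in% f[[1]])
  expect_true("w[0,1]=oxide_synthase" %in% f[[2]])
  expect_true("w[-1,1]=nitric_oxide_synthase" %in% f[[2]])
  expect_true("w[2]=__EOS__" %in% f[[2]])
  single <- token_features("alone",
    config = feature_config(affix = FALSE, ortho = FALSE, shape = FALSE)
  )[[1]]
  non_sentinel <- grep("^w\\[0\\]=", single, value = TRUE)
  expect_equal(non_sentinel, "w[0]=alone")
})

test_that("syntax features use the POS window and current chunk", {
  f <- token_features(
    c("the", "polyhedral", "silsesquioxane"),
    pos = c("DT", "JJ", "NN"),
    chunk = c("B-NP", "I-NP", "I-NP"),
    config = feature_config()
  )
  expect_true("chunk=I-NP" %in% f[[2]])
  expect_true("pos[-1]=JJ" %in% f[[3]])
  expect_true("pos[1]=__EOS__" %in% f[[3]])
  expect_true("pos[2]=__EOS__" %in% f[[3]])
  # absent annotations: the family is simply omitted
  f2 <- token_features(c("a", "b"), config = feature_config())
  expect_length(grep("^pos\\[", unlist(f2)), 0L)
  expect_error(
    token_features(c("a", "b"), pos = "DT"),
    "length"
  )
})

test_that("feature extraction is deterministic, local and toggle-aware", {
  sent <- c("Mercury", "induces", "cyclooxygenase-2", "expression", ".")
  f1 <- token_features(sent)
  expect_identical(f1, token_features(sent))
  # locality: editing a token beyond the +-2 window leaves a vector unchanged
  sent2 <- sent
  sent2[5] <- "XYZ"
  expect_identical(token_features(sent2)[[1]], f1[[1]])
  expect_identical(token_features(sent2)[[2]], f1[[2]])
  # toggles remove whole families
  no_ortho <- token_features(sent, config = feature_config(ortho = FALSE))
  expect_length(grep("^ortho:", unlist(no_ortho)), 0L)
  no_shape <- token_features(sent, config = feature_config(shape = FALSE))
  expect_length(grep("shape=", unlist(no_shape)), 0L)
  # every token carries its own surface feature
  expect_true(all(vapply(
    seq_along(sent),
    function(i) paste0("w[0]=", normalize_word(sent[i])) %in% f1[[i]],
    logical(1)
  )))
})

test_that("extract_features adds one feature vector per token", {
  docs <- tibble::tibble(
    doc_id = "D1", title = "Aspirin study",
    abstract = "Aspirin reduces fever."
  )
  toks <- extract_features(tokenize_corpus(docs))
  expect_true("features" %in% names(toks))
  expect_equal(nrow(toks), length(toks$features))
  expect_true(all(lengths(toks$features) > 0))
})

test_that("attach_pos joins sidecar annotations by covering span", {
  docs <- tibble::tibble(
    doc_id = "D1", title = "Aspirin study",
    abstract = "It reduces fever."
  )
  ann <- tibble::tibble(
    doc_id = "D1", section = c("T", "T"),
    start = c(0L, 8L), end = c(7L, 13L),
    pos = c("NN", "NN"), chunk = c("B-NP", "I-NP")
  )
  toks <- attach_pos(tokenize_corpus(docs), ann)
  title_toks <- toks[toks$section == "T", ]
  expect_equal(title_toks$pos, c("NN", "NN"))
  expect_equal(title_toks$chunk, c("B-NP", "I-NP"))
  # uncovered tokens get NA
  expect_true(all(is.na(toks$pos[toks$section == "A"])))
})
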