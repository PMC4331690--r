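# CEM/CDI matching, micro and macro scores, and the resampled paired test.

mk_mentions <- function(doc_id, section, start, end,
                        category = "TRIVIAL", text = "x") {
  tibble::tibble(
    doc_id = doc_id, section = section, start = start, end = end,
    text = text, category = category
  )
}

test_that("CEM matching requires exact spans and counts one-to-one", {
  gold <- mk_mentions("D1", "A", 0L, 7L)
  expect_equal(match_cem(gold, gold), tibble::tibble(tp = 1L, fp = 0L, fn = 0L))
  off <- mk_mentions("D1", "A", 1L, 7L)
  expect_equal(match_cem(gold, off), tibble::tibble(tp = 0L, fp = 1L, fn = 1L))

  gold4 <- mk_mentions("D1", "A", c(0L, 10L, 20L, 30L), c(7L, 17L, 27L, 37L))
  pred4 <- mk_mentions("D1", "A", c(0L, 10L, 20L, 40L), c(7L, 17L, 27L, 47L))
  counts <- match_cem(gold4, pred4)
  expect_equal(counts, tibble::tibble(tp = 3L, fp = 1L, fn = 1L))
  sc <- micro_scores(counts)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 0.75)
  expect_equal(sc$f1, 0.75)

  # duplicated identical spans: one TP, surplus FP
  dup <- gold[c(1, 1), ]
  expect_equal(match_cem(gold, dup), tibble::tibble(tp = 1L, fp = 1L, fn = 0L))

  # matching is category-blind for the overall score
  recat <- gold
  recat$category <- "FORMULA"
  expect_equal(match_cem(gold, recat)$tp, 1L)
})

test_that("CEM matching is symmetric: FP(g,p) equals FN(p,g)", {
  set.seed(321)
  for (i in 1:30) {
    g <- mk_mentions("D1", "A",
      start = sample(seq(0, 90, 10), 5), end = sample(seq(95, 185, 10), 5)
    )
    p <- mk_mentions("D1", "A",
      start = sample(seq(0, 90, 10), 5), end = sample(seq(95, 185, 10), 5)
    )
    expect_equal(match_cem(g, p)$fp, match_cem(p, g)$fn)
    expect_equal(match_cem(g, p)$fn, match_cem(p, g)$fp)
  }
})

test_that("CDI matching intersects per-document entity strings exactly", {
  gold <- tibble::tibble(
    doc_id = "D1",
    text = c("aspirin", "ibuprofen")
  )
  pred <- tibble::tibble(doc_id = "D1", text = "aspirin", rank = 1L, confidence = 0.9)
  expect_equal(match_cdi(gold, pred), tibble::tibble(tp = 1L, fp = 0L, fn = 1L))
  # case mismatch is a non-match
  cased <- pred
  cased$text <- "Aspirin"
  expect_equal(match_cdi(gold, cased)$tp, 0L)
  expect_equal(match_cdi(gold, pred[0, ]), tibble::tibble(tp = 0L, fp = 0L, fn = 2L))
  expect_error(match_cdi(gold, pred[c(1, 1), ]), "duplicate")
})

test_that("micro scores implement the printed formulas with 0/0 = 0", {
  expect_equal(
    micro_scores(tibble::tibble(tp = 0L, fp = 0L, fn = 0L))[, 4:6],
    tibble::tibble(precision = 0, recall = 0, f1 = 0)
  )
  expect_equal(
    micro_scores(tibble::tibble(tp = 1L, fp = 0L, fn = 0L))[, 4:6],
    tibble::tibble(precision = 1, recall = 1, f1 = 1)
  )
  # harmonic-mean identity wherever P + R > 0
  set.seed(432)
  for (i in 1:50) {
    sc <- micro_scores(tibble::tibble(
      tp = sample(0:20, 1), fp = sample(0:20, 1), fn = sample(0:20, 1)
    ))
    if (sc$precision + sc$recall > 0) {
      expect_equal(
        sc$f1,
        2 * sc$precision * sc$recall / (sc$precision + sc$recall)
      )
    }
  }
})

test_that("category scores pivot the gold and macro-average over 7 categories", {
  gold <- dplyr::bind_rows(lapply(chem_categories, function(cat) {
    mk_mentions("D1", "A", 0L, 7L, category = cat)
  }))
  gold$start <- seq(0L, by = 10L, length.out = 7L)
  gold$end <- gold$start + 7L
  perfect <- category_scores(gold, gold)
  expect_equal(nrow(perfect), 8L)
  expect_equal(perfect$f1[perfect$category == "MACRO"], 1)
  expect_true(all(perfect$precision[perfect$category != "MACRO"] == 1))

  # hand-built two-category corpus: TRIVIAL P=R=1; FORMULA P=1/2, R=1/3
  gold2 <- dplyr::bind_rows(
    mk_mentions("D1", "A", 0L, 7L, category = "TRIVIAL"),
    mk_mentions("D1", "A", c(10L, 20L, 30L), c(17L, 27L, 37L), category = "FORMULA")
  )
  pred2 <- dplyr::bind_rows(
    mk_mentions("D1", "A", 0L, 7L, category = "TRIVIAL"),
    mk_mentions("D1", "A", c(10L, 40L), c(17L, 47L), category = "FORMULA")
  )
  sc <- category_scores(gold2, pred2)
  expect_equal(sc$precision[sc$category == "FORMULA"], 1 / 2)
  expect_equal(sc$recall[sc$category == "FORMULA"], 1 / 3)
  macro <- sc[sc$category == "MACRO", ]
  expect_equal(macro$precision, (1 + 1 / 2 + 0 * 5) / 7)
  expect_equal(macro$recall, (1 + 1 / 3 + 0 * 5) / 7)
  expect_equal(
    macro$f1,
    2 * macro$precision * macro$recall / (macro$precision + macro$recall)
  )
  # empty categories are flagged
  expect_true(all(sc$empty[!sc$category %in% c("TRIVIAL", "FORMULA", "MACRO")]))
  # alternative macro-F: mean of the per-category F1
  sc2 <- category_scores(gold2, pred2, macro_f = "mean_f")
  expect_equal(
    sc2$f1[sc2$category == "MACRO"],
    mean(sc2$f1[sc2$category != "MACRO"])
  )
})

test_that("per-category true positives sum to the overall count", {
  set.seed(543)
  gold <- mk_mentions("D1", "A",
    start = seq(0L, 90L, 10L), end = seq(7L, 97L, 10L),
    category = sample(chem_categories, 10, replace = TRUE)
  )
  pred <- gold[sample(10, 6), ]
  sc <- category_scores(gold, pred)
  expect_equal(
    sum(sc$tp[sc$category != "MACRO"]),
    match_cem(gold, pred)$tp
  )
})

test_that("scores are invariant to input ordering", {
  set.seed(654)
  gold <- mk_mentions("D1", "A", seq(0L, 40L, 10L), seq(7L, 47L, 10L),
    category = sample(chem_categories, 5, replace = TRUE)
  )
  pred <- gold[c(3, 1, 5), ]
  shuffled <- pred[sample(3), ]
  expect_equal(match_cem(gold, pred), match_cem(gold[sample(5), ], shuffled))
  expect_equal(
    as.data.frame(category_scores(gold, pred)),
    as.data.frame(category_scores(gold[sample(5), ], shuffled))
  )
})

test_that("the paired resample test handles the null and degenerate cases", {
  corpus <- generate_corpus(generator_config(n_docs = 12L, seed = 9L))
  silent <- function(train_docs, train_mentions, dev_docs) {
    train_mentions[0, ]
  }
  res <- paired_resample_test(silent, silent, corpus$documents,
    corpus$mentions,
    n_train = 6L, n_dev = 4L, n_resamples = 5L, seed = 1L
  )
  expect_equal(res$delta_f, 0)
  expect_equal(res$p_value, 1)
  expect_error(
    paired_resample_test(silent, silent, corpus$documents,
      corpus$mentions,
      n_resamples = 1L
    ),
    "at least 2"
  )
})

test_that("mention corruption preserves validity and respects the rate", {
  corpus <- generate_corpus(generator_config(n_docs = 20L, seed = 3L))
  set.seed(77)
  out <- corrupt_mentions(corpus$mentions, corpus$documents, rate = 0.2)
  # corrupted mentions still point at real text
  expect_no_error(validate_mentions(out, corpus$documents))
  n <- nrow(corpus$mentions)
  changed <- n - nrow(dplyr::inner_join(
    out, corpus$mentions,
    by = c("doc_id", "section", "start", "end", "text", "category")
  ))
  expect_gt(changed + (n - nrow(out)), 0)
  expect_lt(nrow(out), n + 1) # never grows
  expect_identical(
    corrupt_mentions(corpus$mentions, corpus$documents, rate = 0),
    corpus$mentions
  )
})

test_that("evaluation reports can be plotted", {
  gold <- mk_mentions("D1", "A", 0L, 7L)
  p <- autoplot(category_scores(gold, gold))
  expect_s3_class(p, "ggplot")
})
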