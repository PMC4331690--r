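# CRF engine: training, decoding, marginals, confidence, serialization.
# The independent oracle is exhaustive path enumeration (helper-oracle.R).

test_that("a separable one-token problem is learned", {
  x <- list(list("f1"), list("f2"))
  y <- list("YES", "NO")
  fit <- crf_train(x, y)
  m1 <- crf_marginals(fit, list("f1"))
  expect_gt(m1[1, "YES"], 0.5)
  m2 <- crf_marginals(fit, list("f2"))
  expect_gt(m2[1, "NO"], 0.5)
})

test_that("training rejects empty data and tags outside the inventory", {
  expect_error(crf_train(list(), list()), "empty")
  expect_error(
    crf_train(list(list("f1")), list("B-XYZ"), tags = tag_inventory("IOB")),
    "outside inventory"
  )
})

test_that("training is deterministic for fixed data", {
  x <- list(list(c("a", "b"), "c"), list("a", c("b", "c")))
  y <- list(c("T1", "T2"), c("T2", "T1"))
  f1 <- crf_train(x, y)
  f2 <- crf_train(x, y)
  expect_identical(f1$weights, f2$weights)
})

test_that("duplicating the training data matches rescaling the prior", {
  x <- list(list(c("a", "b"), "c"), list("b", c("a", "c")))
  y <- list(c("T1", "T2"), c("T2", "T1"))
  dup <- crf_train(c(x, x), c(y, y), sigma2 = 1, pgtol = 1e-7)
  single <- crf_train(x, y, sigma2 = 2, pgtol = 1e-7)
  # optima of 2*LL - |w|^2/2 and of LL - |w|^2/4 coincide
  expect_equal(dup$weights, single$weights, tolerance = 1e-4)
})

test_that("Viterbi agrees with exhaustive enumeration on toy instances", {
  set.seed(505)
  for (i in 1:60) {
    inst <- random_crf_instance()
    o <- oracle_crf(inst$weights, inst$feats, inst$n_feat, inst$n_tags)
    model <- toy_model(inst$weights, inst$n_feat, inst$n_tags)
    path <- crf_viterbi(model, toy_features(inst$feats))
    expect_equal(match(path, model$tags) - 1L, unname(o$viterbi))
  }
})

test_that("zero weights give the lexicographically first path and uniform marginals", {
  n_feat <- 3L
  n_tags <- 4L
  model <- toy_model(rep(0, n_feat * n_tags + n_tags^2), n_feat, n_tags)
  feats <- toy_features(list(0L, c(1L, 2L), integer(0)))
  expect_equal(crf_viterbi(model, feats), rep("t1", 3))
  m <- crf_marginals(model, feats)
  expect_equal(unname(m), matrix(1 / n_tags, 3, n_tags))
})

test_that("marginals match enumeration and rows sum to one", {
  set.seed(606)
  for (i in 1:60) {
    inst <- random_crf_instance()
    o <- oracle_crf(inst$weights, inst$feats, inst$n_feat, inst$n_tags)
    model <- toy_model(inst$weights, inst$n_feat, inst$n_tags)
    m <- crf_marginals(model, toy_features(inst$feats))
    expect_equal(unname(m), o$marginals, tolerance = 1e-9)
    expect_equal(rowSums(m), rep(1, length(inst$feats)), tolerance = 1e-9)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("path log-probabilities normalize correctly (partition function)", {
  set.seed(707)
  for (i in 1:20) {
    inst <- random_crf_instance(max_pos = 3L, max_tags = 4L)
    o <- oracle_crf(inst$weights, inst$feats, inst$n_feat, inst$n_tags)
    model <- toy_model(inst$weights, inst$n_feat, inst$n_tags)
    feats <- toy_features(inst$feats)
    total <- 0
    for (r in seq_len(nrow(o$paths))) {
      tags <- model$tags[o$paths[r, ]]
      lp <- crf_logprob(model, feats, tags)
      expect_equal(lp, o$scores[r] - o$logz, tolerance = 1e-8)
      total <- total + exp(lp)
    }
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("the Viterbi path scores at least as high as random paths", {
  set.seed(808)
  inst <- random_crf_instance(max_pos = 4L, max_tags = 5L)
  model <- toy_model(inst$weights, inst$n_feat, inst$n_tags)
  feats <- toy_features(inst$feats)
  best <- crf_logprob(model, feats, crf_viterbi(model, feats))
  for (i in 1:1000) {
    rnd <- sample(model$tags, length(feats), replace = TRUE)
    expect_gte(best, crf_logprob(model, feats, rnd))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(909)
  for (i in 1:5) {
    inst <- random_crf_instance(max_pos = 3L, max_tags = 3L)
    y <- lapply(
      seq_along(inst$feats),
      function(t) sample.int(inst$n_tags, 1) - 1L
    )
    yi <- list(as.integer(unlist(y)))
    xi <- list(inst$feats)
    par <- inst$weights
    g <- chemner:::crf_nll_grad_cpp(
      par, xi, yi, inst$n_feat,
      inst$n_tags, 1
    )$grad
    eps <- 1e-6
    for (j in seq_along(par)) {
      up <- par
      up[j] <- up[j] + eps
      dn <- par
      dn[j] <- dn[j] - eps
      fd <- (chemner:::crf_nll_grad_cpp(up, xi, yi, inst$n_feat, inst$n_tags, 1)$nll -
        chemner:::crf_nll_grad_cpp(dn, xi, yi, inst$n_feat, inst$n_tags, 1)$nll) /
        (2 * eps)
      expect_equal(g[j], fd, tolerance = 1e-5)
    }
  }
})

test_that("the training objective is non-increasing in the iteration budget", {
  set.seed(111)
  x <- lapply(1:6, function(i) {
    lapply(1:4, function(t) sample(c("a", "b", "c", "d"), 2))
  })
  y <- lapply(1:6, function(i) sample(c("T1", "T2"), 4, replace = TRUE))
  vals <- vapply(1:10, function(k) {
    crf_train(x, y, tags = c("T1", "T2"), maxit = k)$nll
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
})

test_that("entity confidence follows the product-of-marginals rule", {
  model <- toy_model(rep(0, 3 * 2 + 4), 3L, 2L)
  x_seq <- toy_features(list(0L, 1L))
  marg <- matrix(c(0.8, 0.2, 0.5, 0.5), nrow = 2, byrow = TRUE,
    dimnames = list(NULL, c("t1", "t2")))
  expect_equal(
    entity_confidence(model, x_seq,
      first = 1, last = 1,
      tags = c("t1", "t1"), marginals = marg
    ),
    0.8
  )
  expect_equal(
    entity_confidence(model, x_seq,
      first = 1, last = 2,
      tags = c("t1", "t1"), marginals = marg
    ),
    0.8 * 0.5
  )
})

test_that("exact entity confidence equals the enumerated constrained mass", {
  set.seed(212)
  for (i in 1:20) {
    inst <- random_crf_instance(max_pos = 4L, max_tags = 4L)
    n_pos <- length(inst$feats)
    model <- toy_model(inst$weights, inst$n_feat, inst$n_tags)
    feats <- toy_features(inst$feats)
    o <- oracle_crf(inst$weights, inst$feats, inst$n_feat, inst$n_tags)
    path <- crf_viterbi(model, feats)
    first <- sample.int(n_pos, 1)
    last <- first + sample.int(n_pos - first + 1L, 1) - 1L
    exact <- entity_confidence(model, feats, first, last, path, mode = "exact")
    pidx <- match(path, model$tags)
    keep <- rep(TRUE, nrow(o$paths))
    for (t in first:last) keep <- keep & o$paths[, t] == pidx[t]
    expect_equal(exact, sum(o$probs[keep]), tolerance = 1e-8)
    # the marginal-product approximation is also a probability
    approx <- entity_confidence(model, feats, first, last, path)
    expect_true(approx >= 0 && approx <= 1)
  }
})

test_that("serialization round-trips the model exactly", {
  x <- list(list(c("a", "b"), "c"), list("a", c("b", "c")))
  y <- list(c("T1", "T2"), c("T2", "T1"))
  fit <- crf_train(x, y)
  p <- withr::local_tempfile(fileext = ".json")
  crf_write(fit, p)
  back <- crf_read(p)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$feature_names, fit$feature_names)
  expect_identical(back$tags, fit$tags)
  expect_equal(back$sigma2, fit$sigma2)
  seq <- list("a", "b")
  expect_identical(crf_viterbi(back, seq), crf_viterbi(fit, seq))
  expect_error(crf_read(write_lines_tmp("{\"format\": \"other\"}")), "model file")
})

test_that("tidy and glance summarize the fitted weights", {
  x <- list(list("a", "b"))
  y <- list(c("T1", "T2"))
  fit <- crf_train(x, y)
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$weights))
  expect_setequal(names(td), c("feature", "tag", "weight"))
  gl <- glance(fit)
  expect_equal(gl$n_parameters, length(fit$weights))
  expect_equal(gl$n_tags, 2L)
})
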