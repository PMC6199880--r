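test_that("ngram similarity matches the brute-force Dice oracle", {
  expect_equal(ngram_similarity("myocardium", "myocardium"), 1)
  expect_equal(ngram_similarity("abc", "xyz"), 0)
  # frozen from oracle_ngram("myocardium", "myocardial"): 16 shared of 24
  expect_equal(oracle_ngram("myocardium", "myocardial"), 2 / 3)
  expect_equal(ngram_similarity("myocardium", "myocardial"), 2 / 3)
  set.seed(401)
  words <- replicate(20, paste(sample(letters[1:6], sample(1:8, 1),
                                      replace = TRUE), collapse = ""))
  for (k in 1:40) {
    w <- sample(words, 2)
    expect_equal(ngram_similarity(w[1], w[2]), oracle_ngram(w[1], w[2]),
                 info = paste(w, collapse = " / "))
    expect_equal(ngram_similarity(w[1], w[2]), ngram_similarity(w[2], w[1]))
  }
})

test_that("word similarity prefers synonymy over n-grams", {
  syn <- synonym_provider(data.frame(a = "myocardium", b = "cardiac"))
  expect_equal(word_similarity("myocardium", "cardiac", syn), 1)
  expect_equal(word_similarity("cardiac", "myocardium", syn), 1)  # symmetric
  empty <- synonym_provider()
  expect_equal(word_similarity("heart", "heart", empty), 1)
  expect_equal(word_similarity("abc", "xyz", empty), 0)
  expect_true(is_synonym(syn, "anything", "anything"))  # reflexive
})

test_that("synonym provider loads the tab-separated dictionary", {
  syn <- synonym_provider(extdata("cardiac-synonyms.tsv"))
  expect_true(is_synonym(syn, "myocardium", "cardiac"))
  expect_false(is_synonym(syn, "myocardium", "valve"))
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_silent(empty <- synonym_provider(f))
  expect_false(is_synonym(empty, "a", "b"))
})

test_that("profile intersection equals the exhaustive pairing oracle", {
  params <- ccoem_params()
  syn <- synonym_provider(data.frame(a = "cardiac", b = "myocardium"))
  p1 <- c("cardiac", "muscle", "tissue")
  p2 <- c("myocardium", "wall")
  expect_equal(profile_intersection_size(p1, p2, syn, params), 1L)
  expect_equal(oracle_intersection(p1, p2, syn, params), 1L)
  ident <- c("alpha", "beta", "gamma", "delta")
  expect_equal(profile_intersection_size(ident, ident, syn, params), 4L)
  expect_equal(profile_intersection_size(c("aaa", "bbb"), c("ccc", "ddd"),
                                         syn, params), 0L)
  # randomized agreement with the oracle on small multisets
  set.seed(402)
  vocab <- c("kora", "kore", "lumi", "lumo", "zeta", "zetu", "cardiac",
             "myocardium")
  for (k in 1:30) {
    t1 <- sample(vocab, sample(1:4, 1), replace = TRUE)
    t2 <- sample(vocab, sample(1:4, 1), replace = TRUE)
    expect_equal(profile_intersection_size(t1, t2, syn, params),
                 oracle_intersection(t1, t2, syn, params),
                 info = paste(paste(t1, collapse = "+"),
                              paste(t2, collapse = "+"), sep = " vs "))
    expect_lte(profile_intersection_size(t1, t2, syn, params),
               min(length(t1), length(t2)))
  }
})

test_that("profile similarity applies the delta gate exactly", {
  params <- ccoem_params(delta = 0.06)
  empty <- synonym_provider()
  ident <- c("alpha", "beta", "gamma", "delta")
  expect_equal(profile_similarity(ident, ident, empty, params), 1)
  # |p1|=4, |p2|=5, I=2: s1=0.5, s2=0.4, gap 0.1 > 0.06 -> gated to 0
  p1 <- c("alpha", "beta", "qqq", "www")
  p2 <- c("alpha", "beta", "xxx", "yyy", "zzz")
  expect_equal(profile_intersection_size(p1, p2, empty, params), 2L)
  expect_equal(profile_similarity(p1, p2, empty, params), 0)
  # |p1|=|p2|=4, I=3 -> (0.75+0.75)/2
  p3 <- c("alpha", "beta", "gamma", "qqq")
  p4 <- c("alpha", "beta", "gamma", "zzz")
  expect_equal(profile_similarity(p3, p4, empty, params), 0.75)
  expect_error(profile_similarity(character(), p4, empty, params),
               "empty profile")
})

test_that("profile similarity is symmetric and respects the gate bound", {
  params <- ccoem_params()
  syn <- synonym_provider(data.frame(a = c("kora", "lumi"),
                                     b = c("kore", "lumo")))
  set.seed(403)
  vocab <- c("kora", "kore", "lumi", "lumo", "zeta", "pira", "piru", "nolo")
  for (k in 1:40) {
    t1 <- sample(vocab, sample(2:5, 1), replace = TRUE)
    t2 <- sample(vocab, sample(2:5, 1), replace = TRUE)
    s12 <- profile_similarity(t1, t2, syn, params)
    expect_equal(s12, profile_similarity(t2, t1, syn, params))
    if (s12 > 0) {
      I <- profile_intersection_size(t1, t2, syn, params)
      s1 <- I / length(t1); s2 <- I / length(t2)
      expect_lte(abs(s1 - s2), params$delta)
      expect_equal(s12, (s1 + s2) / 2)
    }
  }
})

test_that("growing the synonym dictionary never lowers similarity", {
  # property exercised where word similarities are effectively binary
  # (the greedy pairing can in principle lose on adversarial near-ties;
  # see the methods vignette)
  params <- ccoem_params()
  set.seed(404)
  vocab <- paste0(rep(c("taf", "bem", "ruk", "zol"), each = 2), 1:2)
  pairs <- data.frame(a = c("taf1", "bem1"), b = c("ruk2", "zol2"))
  small <- synonym_provider(pairs[1, ])
  large <- synonym_provider(pairs)
  for (k in 1:30) {
    t1 <- sample(vocab, sample(2:4, 1), replace = TRUE)
    t2 <- sample(vocab, sample(2:4, 1), replace = TRUE)
    expect_gte(profile_similarity(t1, t2, large, params),
               profile_similarity(t1, t2, small, params))
  }
})

test_that("the similarity matrix equals the double loop and transposes", {
  pair <- generate_pair(8, synonym_rename_fraction = 0.25, seed = 21)
  params <- ccoem_params()
  m <- similarity_matrix(pair$o1, pair$o2, pair$synonyms, params)
  p1 <- build_profiles(pair$o1); p2 <- build_profiles(pair$o2)
  for (i in seq_along(p1)) {
    for (j in seq_along(p2)) {
      expect_equal(m[i, j],
                   profile_similarity(p1[[i]], p2[[j]], pair$synonyms,
                                      params),
                   info = paste(i, j))
    }
  }
  mt <- similarity_matrix(pair$o2, pair$o1, pair$synonyms, params)
  expect_equal(unclass(m), t(unclass(mt)), ignore_attr = TRUE)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("matching an ontology against itself yields a unit diagonal", {
  o <- tiny_ontology()
  m <- similarity_matrix(o, o, synonym_provider())
  expect_equal(unname(diag(m)), rep(1, 3))
})
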