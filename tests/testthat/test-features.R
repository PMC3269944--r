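# Tokenizer and the five feature families; vocabulary fitting and vectorization.

test_that("tokenizer lowercases, keeps hyphen/digit tokens, splits sentences", {
  expect_equal(tokenize_sentences("A binds B."), list(c("a", "binds", "b")))
  expect_equal(tokenize_sentences("MEK-1 interacts"), list(c("mek-1", "interacts")))
  expect_equal(tokenize_sentences(""), list())
  two <- tokenize_sentences("A binds B. Cells were used.")
  expect_length(two, 2)
  expect_equal(two[[2]], c("cells", "were", "used"))
  # title and abstract never share a sentence
  doc <- tokenize_document("Short title", "p53 is active.")
  expect_equal(doc[[1]], c("short", "title"))
  expect_equal(doc[[2]], c("p53", "is", "active"))
})

test_that("word n-grams respect enabled orders and sentence boundaries", {
  cfg <- feature_config(use_trigram = FALSE, min_doc_freq = 1)
  f <- word_ngram_features(list(c("a", "binds", "b")), cfg)
  expect_setequal(f, c("W1|a", "W1|binds", "W1|b", "W2|a_binds", "W2|binds_b"))
  cfg3 <- feature_config(use_trigram = TRUE, min_doc_freq = 1)
  f3 <- word_ngram_features(list(c("a", "binds", "b")), cfg3)
  expect_true("W3|a_binds_b" %in% f3)
  # no bigram across a sentence boundary
  fb <- word_ngram_features(list(c("a", "binds", "b"), "c"), cfg)
  expect_false("W2|b_c" %in% fb)
})

test_that("substring features use k-windows with whole-token fallback", {
  expect_equal(substring_features("kinase", 6), "S|kinase")
  expect_setequal(substring_features("kinases", 6), c("S|kinase", "S|inases"))
  expect_equal(substring_features("p53", 6), "S|p53")
})

test_that("mesh features emit unigram and bigram subphrases per descriptor", {
  expect_setequal(
    mesh_features("Protein Binding"),
    c("M1|protein", "M1|binding", "M2|protein_binding")
  )
  expect_equal(mesh_features("Mice"), "M1|mice")
  expect_equal(mesh_features(character(0)), character(0))
  # qualifiers after "/" are separate descriptors: no bigram across the slash
  f <- mesh_features("Proteins/metabolism")
  expect_setequal(f, c("M1|proteins", "M1|metabolism"))
})

test_that("dependency features stem and anonymize per configuration", {
  parses <- tibble::tibble(
    sentence_index = 0L, relation = "dobj", head = "binds", dependent = "MEK1"
  )
  mentions <- tibble::tibble(sentence_index = 0L, text = "MEK1")
  stem_on <- feature_config(stem_dependency = TRUE, min_doc_freq = 1)
  expect_equal(
    dependency_features(parses, mentions, stem_on),
    "D|dobj(bind,PTNWORD)"
  )
  plain <- feature_config(stem_dependency = FALSE, min_doc_freq = 1)
  parses2 <- tibble::tibble(
    sentence_index = 0L, relation = "dobj", head = "binds", dependent = "lamp"
  )
  expect_equal(dependency_features(parses2, NULL, plain), "D|dobj(binds,lamp)")
  no_anon <- feature_config(
    stem_dependency = TRUE, anonymize_genes = FALSE, min_doc_freq = 1
  )
  parses3 <- tibble::tibble(
    sentence_index = 0L, relation = "dobj", head = "binds", dependent = "lamp"
  )
  expect_equal(dependency_features(parses3, mentions, no_anon), "D|dobj(bind,lamp)")
})

test_that("head words inside mentions are never anonymized", {
  parses <- tibble::tibble(
    sentence_index = 0L, relation = "subj", head = "MEK1", dependent = "RAF2"
  )
  mentions <- tibble::tibble(sentence_index = c(0L, 0L), text = c("MEK1", "RAF2"))
  cfg <- feature_config(min_doc_freq = 1)
  expect_equal(dependency_features(parses, mentions, cfg), "D|subj(mek1,PTNWORD)")
})

test_that("vocabulary cut removes features below the document frequency", {
  sets <- list(
    c("W1|a", "W1|b"), c("W1|a", "W1|c"), c("W1|a", "W1|b"),
    c("W1|a", "W1|b"), c("W1|a", "W1|b")
  )
  # hand-tabulated DF: a=5, b=4, c=1
  v4 <- fit_vocabulary(sets, min_doc_freq = 4)
  expect_setequal(v4$feature, c("W1|a", "W1|b"))
  expect_equal(v4$index, seq_len(nrow(v4)))
  expect_equal(v4$doc_freq[v4$feature == "W1|a"], 5L)
  v1 <- fit_vocabulary(sets, min_doc_freq = 1)
  expect_setequal(v1$feature, c("W1|a", "W1|b", "W1|c"))
  # a feature in 3 docs is removed at min_doc_freq = 4
  sets3 <- c(sets, list(c("W1|d"), c("W1|d"), c("W1|d")))
  expect_false("W1|d" %in% fit_vocabulary(sets3, 4)$feature)
  expect_error(fit_vocabulary(list("W1|x"), 4), "survive")
})

test_that("vocabulary size is non-increasing in min_doc_freq", {
  syn <- synthetic_corpus(n_docs = 30, seed = 3)
  feats <- corpus_features(
    syn$documents, syn$parses, syn$mentions,
    feature_config(min_doc_freq = 1)
  )
  sizes <- vapply(1:6, function(k) nrow(fit_vocabulary(feats, k)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("vectorization is idempotent, order-independent, and drops unknowns", {
  vocab <- fit_vocabulary(list(c("W1|a", "W1|b")), 1)
  expect_equal(vectorize(c("W1|b", "W1|a", "W1|b"), vocab)[[1]],
               vectorize(c("W1|a", "W1|b"), vocab)[[1]])
  expect_equal(vectorize("W1|zzz", vocab)[[1]], integer(0))
  expect_equal(vectorize(c("W1|a", "W1|a"), vocab)[[1]],
               vectorize("W1|a", vocab)[[1]])
})

test_that("unigram-only pipeline reduces to bag-of-words presence", {
  syn <- synthetic_corpus(n_docs = 20, seed = 8)
  cfg <- feature_config(
    use_bigram = FALSE, use_substrings = FALSE, use_mesh = FALSE,
    use_dependency = FALSE, anonymize_genes = FALSE, min_doc_freq = 1
  )
  feats <- corpus_features(syn$documents, config = cfg)
  for (i in seq_len(nrow(syn$documents))) {
    bow <- unique(unlist(tokenize_document(
      syn$documents$title[i], syn$documents$abstract[i]
    )))
    expect_setequal(feats[[i]], paste0("W1|", bow))
  }
})

test_that("documents differing only in gene surfaces give identical dependency features", {
  cfg <- feature_config(min_doc_freq = 1)
  p1 <- tibble::tibble(
    sentence_index = 0L, relation = c("subj", "obj"),
    head = c("binds", "binds"), dependent = c("Abc1", "Def2")
  )
  m1 <- tibble::tibble(sentence_index = c(0L, 0L), text = c("Abc1", "Def2"))
  p2 <- tibble::tibble(
    sentence_index = 0L, relation = c("subj", "obj"),
    head = c("binds", "binds"), dependent = c("Xyz9", "Qrs8")
  )
  m2 <- tibble::tibble(sentence_index = c(0L, 0L), text = c("Xyz9", "Qrs8"))
  expect_equal(
    dependency_features(p1, m1, cfg),
    dependency_features(p2, m2, cfg)
  )
})

test_that("anonymization collapses multi-word mentions to one n-gram token", {
  sentences <- list(c("insulin", "receptor", "binds", "irs-1"))
  mentions <- tibble::tibble(
    sentence_index = c(0L, 0L), start = c(0L, 3L), end = c(2L, 4L)
  )
  out <- anonymize_tokens(sentences, mentions, "ptnword")
  expect_equal(out[[1]], c("ptnword", "binds", "ptnword"))
})

test_that("vocabulary sidecar round-trips", {
  v <- fit_vocabulary(list(c("W1|a", "D|subj(x,y)"), c("W1|a")), 1)
  path <- withr::local_tempfile()
  write_vocabulary(v, path)
  expect_equal(read_vocabulary(path), v)
})
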