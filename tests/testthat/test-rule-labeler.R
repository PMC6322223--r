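test_that("sentence splitting covers the text and honors the delimiter set", {
  s <- split_sentences("Indications: femur fx. Cannulated screw fixation.")
  expect_equal(nrow(s), 2)
  expect_equal(nrow(split_sentences("No smoking after age 40")), 1)
  expect_equal(nrow(split_sentences("a; b. c")), 3)
  expect_equal(nrow(split_sentences("")), 0)

  # spans are ordered, non-overlapping, and reconstruct the text with the
  # delimiters put back
  txt <- "one two; three. four!\nfive? six"
  sp <- split_sentences(txt)
  expect_true(all(diff(sp$start) > 0))
  expect_true(all(sp$end >= sp$start))
  rebuilt <- strsplit(txt, "")[[1]]
  covered <- unlist(mapply(seq, sp$start, sp$end, SIMPLIFY = FALSE))
  expect_false(any(duplicated(covered)))
  expect_identical(paste(rebuilt[covered], collapse = ""),
                   paste(sp$text, collapse = ""))
  expect_true(all(grepl("^[.!?;\n]$", rebuilt[-covered])))
})

test_that("built-in rule sets load with the transcribed structure", {
  rs <- load_builtin("mayo_smoking")
  expect_equal(nrow(rs$rules), 17)   # 11 smoker + 6 non-smoker patterns
  expect_equal(sum(rs$rules$category == "smoker"), 11)
  expect_equal(sum(rs$rules$category == "non-smoker"), 6)
  expect_equal(rs$default, "non-smoker")
  expect_equal(rs$precedence, c("non-smoker", "smoker"))

  hf <- load_builtin("hip_fracture")
  expect_true(hf$cooccurrence)
  expect_equal(hf$scope, "sentence")
  expect_equal(hf$default, "no-fracture")

  i2 <- load_builtin("i2b2_smoking")
  expect_equal(i2$default, "unknown")
  expect_equal(i2$precedence, c("past smoker", "current smoker", "non-smoker"))

  expect_error(load_builtin("nope"), "mayo_smoking.*hip_fracture.*i2b2_smoking")
})

test_that("rule sets label the printed example snippets correctly", {
  mayo <- load_builtin("mayo_smoking")
  expect_equal(apply_ruleset("No smoking after age XXX", mayo)$category,
               "non-smoker")
  expect_equal(apply_ruleset("He smokes two packs daily.", mayo)$category,
               "smoker")
  default_case <- apply_ruleset("Patient enjoys gardening.", mayo)
  expect_equal(default_case$category, "non-smoker")
  expect_equal(nrow(default_case$evidence), 0)

  hf <- load_builtin("hip_fracture")
  expect_equal(apply_ruleset("Fx Vertebra Cervical Closed", hf)$category,
               "fracture")
  expect_equal(apply_ruleset(
    "R hip inj/marc/steroid; fx femur neck nos closed, pain hip", hf)$category,
    "fracture")
  expect_equal(apply_ruleset(
    "Indications: femur fx. Cannulated screw fixation of the right femoral neck.",
    hf)$category, "no-fracture")

  i2 <- load_builtin("i2b2_smoking")
  expect_equal(apply_ruleset("She quit smoking in 1990.", i2)$category,
               "past smoker")
  expect_equal(apply_ruleset("He is a current smoker.", i2)$category,
               "current smoker")
  expect_equal(apply_ruleset("Vitals stable.", i2)$category, "unknown")
})

test_that("word boundaries keep smoker patterns out of 'nonsmoker'", {
  mayo <- load_builtin("mayo_smoking")
  hits <- rule_matches("nonsmoker", mayo)
  expect_false(any(hits$category == "smoker"))
  expect_true(any(hits$category == "non-smoker"))
})

test_that("non-smoker precedence wins whenever both categories match", {
  mayo <- load_builtin("mayo_smoking")
  both <- c("No smoking after age XXX", "denies smoking and tobacco",
            "never smoked cigarettes", "negative tobacco use, quit smoking")
  for (txt in both) {
    hits <- rule_matches(txt, mayo)
    expect_true(any(hits$category == "smoker"), info = txt)
    expect_true(any(hits$category == "non-smoker"), info = txt)
    expect_equal(apply_ruleset(txt, mayo)$category, "non-smoker", info = txt)
  }
})

test_that("co-occurrence labels are order-invariant and monotone", {
  hf <- load_builtin("hip_fracture")
  sents <- c("femur fx noted", "the femoral neck appears intact",
             "degenerative changes elsewhere")
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  labs <- vapply(perms, function(p)
    apply_ruleset(paste(sents[p], collapse = ". "), hf)$category, character(1))
  expect_equal(unique(labs), "no-fracture")   # permuting sentences never flips

  # moving the modifier into the keyword's sentence can only create a fracture
  joined <- "the femoral neck appears intact with fx. degenerative changes elsewhere"
  expect_equal(apply_ruleset(joined, hf)$category, "fracture")
})

test_that("labeling a corpus is deterministic and order-preserving", {
  b <- generate_corpus(generator_config("smoking_binary", n = 30,
                                        p_miss = 0.2, seed = 7))
  mayo <- load_builtin("mayo_smoking")
  l1 <- label_corpus(b$corpus, mayo)
  l2 <- label_corpus(b$corpus, mayo)
  expect_identical(l1$weak_label, l2$weak_label)
  expect_identical(l1$id, b$corpus$id)
  expect_equal(nrow(label_corpus(b$corpus[0, ], mayo)), 0)
})

test_that("the engine agrees with a brute-force (pattern, sentence) oracle", {
  tasks <- list(c("smoking_binary", "mayo_smoking"),
                c("fracture_binary", "hip_fracture"),
                c("smoking_multiclass", "i2b2_smoking"))
  for (tk in tasks) {
    b <- generate_corpus(generator_config(tk[1], n = 50, p_miss = 0.3,
                                          p_cross = 0.4, seed = 9))
    rs <- load_builtin(tk[2])
    engine <- label_corpus(b$corpus, rs)$weak_label
    oracle <- vapply(b$corpus$text, brute_label, character(1), rs = rs,
                     USE.NAMES = FALSE)
    expect_identical(engine, oracle)
  }
})

test_that("evidence is empty exactly when the default fired with no match", {
  b <- generate_corpus(generator_config("smoking_binary", n = 60,
                                        p_miss = 0.2, seed = 21))
  mayo <- load_builtin("mayo_smoking")
  lab <- label_corpus(b$corpus, mayo)
  for (i in seq_len(nrow(lab))) {
    ev <- lab$evidence[[i]]
    if (nrow(ev) == 0) {
      expect_equal(lab$weak_label[i], mayo$default)
      expect_equal(nrow(rule_matches(lab$text[i], mayo)), 0)
    } else {
      expect_true(all(ev$category == lab$weak_label[i]))
      expect_identical(ev$match,
                       substring(lab$text[i], ev$start, ev$end))
    }
  }
})

test_that("rule-set configs round-trip through JSON", {
  rs <- load_builtin("hip_fracture")
  f <- withr::local_tempfile(fileext = ".json")
  write_ruleset(rs, f)
  back <- read_ruleset(f)
  expect_equal(back$rules$pattern, rs$rules$pattern)
  expect_equal(back$precedence, rs$precedence)
  expect_equal(back$cooccurrence, rs$cooccurrence)
  expect_identical(apply_ruleset("femoral neck fx", back)$category, "fracture")
})

test_that("rule-set validation rejects broken specifications", {
  expect_error(ruleset("x", labels = "one", default = "one",
                       rules = data.frame(category = "one", pattern = "a")),
               "at least 2")
  expect_error(ruleset("x", labels = c("a", "b"), default = "c",
                       rules = data.frame(category = "a", pattern = "p")),
               "default")
  expect_error(ruleset("x", labels = c("a", "b"), default = "b",
                       rules = data.frame(category = "a", pattern = "p",
                                          accuracy = 0.3)),
               "accuracy")
})
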