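test_that("bag-of-word window features count and read off correctly", {
  # single token: 5 unigrams (4 boundary), 4 bigrams, 3 trigrams
  f <- bow_features("only", 1, c(-2L, 2L))
  expect_length(f, 12)
  expect_length(grep("^bow:uni", f), 5)
  expect_length(grep("^bow:bi", f), 4)
  expect_length(grep("^bow:tri", f), 3)
  expect_equal(sum(grepl("=<s>$", grep("^bow:uni", f, value = TRUE))), 4)

  f2 <- bow_features(c("a", "b", "c"), 2)
  expect_true("bow:uni[-1]=a" %in% f2)
  expect_true("bow:bi[0,1]=b_c" %in% f2)
  expect_true("bow:tri[-1,0,1]=a_b_c" %in% f2)

  expect_length(bow_features(c("a", "b"), 1, c(0L, 0L)), 1)
  # lowercasing
  expect_true("bow:uni[0]=nacl" %in% bow_features("NaCl", 1))
})

test_that("every orthographic pattern fires on a positive and not a negative", {
  cases <- list(
    ALLCAPS     = c("ABC", "Abc"),
    INITCAP     = c("Abc", "abc"),
    HASCAP      = c("aBc", "abc"),
    SINGLECAP   = c("A", "AB"),
    PUNCTATION  = c(";", "x"),
    INITDIGIT   = c("2x", "x2"),
    SINGLEDIGIT = c("7", "77"),
    ALPHANUM    = c("C6", "CC"),
    MANY_NUM    = c("1,2", "12"),
    REAL_NUM    = c("7.4", "74"),
    INDASH      = c("a-b", "ab"),
    HASDIGIT    = c("x2", "xx"),
    IS_DASH     = c("--", "-x"),
    ROMAN       = c("IV", "IVy"),
    END_PUNC    = c("?", "x?"),
    CAPSMIX     = c("NaCl", "NACL")
  )
  for (nm in names(cases)) {
    expect_true(paste0("ortho:", nm) %in% orthographic_features(cases[[nm]][1]),
                info = paste(nm, "positive"))
    expect_false(paste0("ortho:", nm) %in% orthographic_features(cases[[nm]][2]),
                 info = paste(nm, "negative"))
  }
  expect_setequal(orthographic_features("1,2"),
                  c("ortho:MANY_NUM", "ortho:HASDIGIT", "ortho:INITDIGIT"))
  expect_true(all(c("ortho:ROMAN", "ortho:ALLCAPS") %in%
                    orthographic_features("IV")))
  expect_setequal(orthographic_features("ABC"),
                  c("ortho:ALLCAPS", "ortho:INITCAP", "ortho:HASCAP"))
})

test_that("morphological features emit guarded affixes and shapes", {
  f <- morphological_features("cysteine")
  expect_true(all(c("morph:prefix2=cy", "morph:prefix5=cyste",
                    "morph:suffix5=teine", "morph:shape=aaaaaaaa",
                    "morph:cshape=a") %in% f))
  f2 <- morphological_features("Ab1")
  expect_true(all(c("morph:shape=Aa0", "morph:cshape=Aa0") %in% f2))
  f3 <- morphological_features("ol")
  expect_setequal(grep("prefix|suffix", f3, value = TRUE),
                  c("morph:prefix2=ol", "morph:suffix2=ol"))
})

test_that("POS and structure features behave positionally", {
  f <- pos_features(c("DT", "NN", "VB"), 2)
  expect_true("pos:uni[1]=VB" %in% f)
  expect_true("pos:uni[-1]=DT" %in% f)
  same <- pos_features(rep("NN", 3), 2)
  expect_true(all(c("pos:uni[-1]=NN", "pos:uni[1]=NN") %in% same))
  expect_equal(structure_feature("anything", "TITLE"), "struct:in_title")
  expect_length(structure_feature("anything", "ABSTRACT"), 0)
})

test_that("domain features look up affixes, elements and user lexicons", {
  expect_setequal(domain_features("methane"),
                  c("domain:prefix=meth", "domain:suffix=ane"))
  expect_equal(domain_features("Fe"), "domain:element")
  expect_equal(domain_features("iron"), "domain:element")
  expect_length(domain_features("the"), 0)
  expect_true("domain:lex=drugs" %in%
                domain_features("imatinib", list(drugs = c("imatinib", "aspirin"))))
  expect_equal(nrow(chemical_elements()), 118)
})

test_that("word-representation features emit path prefixes and UNK markers", {
  fmap <- wr_feature_map("brown", c(water = "0110", acid = "011010110101"))
  expect_equal(wr_features("water", list(fmap)), "wr:brown:p4=0110")
  expect_setequal(wr_features("acid", list(fmap)),
                  c("wr:brown:p4=0110", "wr:brown:p6=011010",
                    "wr:brown:p10=0110101101"))
  expect_equal(wr_features("unknown", list(fmap)), "wr:brown:UNK")
  cmap <- wr_feature_map("ri", c(water = "3"))
  expect_equal(wr_features("Water", list(cmap)), "wr:ri:c=3")  # lowercased lookup
  expect_length(wr_features("x", list()), 0)
})

test_that("extraction is pure, namespaced, and respects family toggles", {
  toks <- tokenize("Aspirin reduced methane levels.", section = "TITLE")
  base <- feature_config()
  f1 <- extract_features(toks, base)
  f2 <- extract_features(toks, base)
  expect_identical(f1, f2)
  expect_true(all(vapply(f1, function(x) "struct:in_title" %in% x, logical(1))))
  # disabling a family removes exactly its namespace
  no_dom <- feature_config(families = setdiff(base$families, "domain"))
  f3 <- extract_features(toks, no_dom)
  for (i in seq_along(f1)) {
    expect_setequal(setdiff(f1[[i]], f3[[i]]),
                    grep("^domain:", f1[[i]], value = TRUE))
  }
  # enabling WR adds only wr:* features
  fmap <- wr_feature_map("brown", c(aspirin = "0011", methane = "0010"))
  with_wr <- feature_config(families = c(base$families, "wr"),
                            wr_models = list(fmap))
  f4 <- extract_features(toks, with_wr)
  for (i in seq_along(f1)) {
    expect_true(all(startsWith(setdiff(f4[[i]], f1[[i]]), "wr:")))
  }
  # all families off -> empty vectors
  f5 <- extract_features(toks, feature_config(families = character(0)))
  expect_true(all(lengths(f5) == 0))
})

test_that("the baseline feature set spans exactly the six baseline families", {
  toks <- tokenize("NaCl dissolved quickly.", section = "ABSTRACT")
  f <- extract_features(toks, feature_config())
  fams <- unique(sub(":.*$", "", unlist(f)))
  expect_setequal(fams, c("bow", "ortho", "morph", "pos", "domain"))
  # struct absent because this is an abstract; wr absent because not enabled
})
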