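test_that("PKS reduction subtypes follow the domain rule table", {
  expect_equal(classify_pks_subtype(c("KS", "AT", "DH", "CMeT", "ER", "KR",
                                      "ACP")), "hrPKS")
  expect_equal(classify_pks_subtype(c("SAT", "KS", "AT", "PT", "ACP", "TE")),
               "nrPKS")
  expect_equal(classify_pks_subtype(c("KS", "AT", "KR", "ACP")), "prPKS")
  expect_equal(classify_pks_subtype(c("KS", "AT")), "truncated_PKS")
  expect_equal(classify_pks_subtype(c("KS", "AT", "DH", "ACP")), "prPKS")
  expect_error(classify_pks_subtype(c("C", "A", "T")), "not a PKS")
})

test_that("disintegrated PKS detection needs complementary partial genes nearby", {
  # the split hrPKS: KS-AT-DH-CMeT-ER + KR-ACP within 10 kb
  split_close <- toy_locus(list(c("KS", "AT", "DH", "CMeT", "ER"),
                                c("KR", "ACP")))
  expect_true(detect_disintegrated(split_close))
  # two complete PKS genes are collaborative, not disintegrated
  two_complete <- toy_locus(list(c("KS", "AT", "ACP"), c("KS", "AT", "ACP")))
  expect_false(detect_disintegrated(two_complete))
  # complementary genes 50 kb apart exceed the gap rule
  split_far <- toy_locus(list(c("KS", "AT", "DH", "CMeT", "ER"),
                              c("KR", "ACP")), gene_gap_bp = 50000L)
  expect_false(detect_disintegrated(split_far))
})


test_that("every crafted fixture maps to its intended class", {
  for (fx in class_fixtures()) {
    got <- classify_locus(fx$l)
    expect_equal(got$class, fx$cls,
                 info = paste(fx$cls, "<-",
                              paste(unlist(lapply(fx$l$genes$gene_id,
                                bgcfam:::gene_domain_string, locus = fx$l)),
                                collapse = "-")))
  }
})

test_that("classification totality: randomized inputs get exactly one class", {
  set.seed(99)
  core_classes_pool <- c("typeI_PKS", "typeIII_PKS", "NRPS_family", "terpene",
                         "alkyl_citrate", "alkaloid_DMAT", "RiPP_precursor")
  for (rep in 1:60) {
    n_genes <- sample(1:4, 1)
    strings <- lapply(seq_len(n_genes), function(i)
      sample(domain_vocab(), sample(0:7, 1), replace = TRUE))
    l <- toy_locus(strings,
                   core_classes = stats::setNames(
                     sample(core_classes_pool, 1), "g001"))
    got <- classify_locus(l)
    expect_true(got$class %in% bgc_classes())
    expect_length(got$class, 1L)
    # permuting gene discovery order never changes the class (order of
    # genes along the contig is what matters, and stays fixed)
    l2 <- l
    perm <- sample(n_genes)
    l2$genes <- l2$genes[perm, ]
    l2$domain_hits <- l2$domain_hits[l2$genes$gene_id]
    l2$genes <- l2$genes[order(l2$genes$start), ]
    got2 <- classify_locus(l2)
    expect_equal(got2$class, got$class)
  }
})

test_that("class counts exclude primary metabolism and unclustered A-T-R", {
  fx <- class_fixtures()
  loci <- lapply(seq_along(fx), function(i) {
    l <- classify_locus(fx[[i]]$l)
    l$bgc_id <- paste0("L", i)
    l
  })
  m <- class_count_table(loci, species = "toy")
  expect_false("excluded_primary_metabolism" %in% colnames(m))
  n_counted <- sum(vapply(loci, function(l) isTRUE(l$counted), TRUE))
  expect_equal(sum(m), n_counted)
  expect_equal(sum(m), length(fx) - 2L)  # the two excluded fixtures
  expect_equal(m["toy", "meroterpenoid"], 2L)
  # empty cohort -> all-zero matrix
  expect_equal(sum(class_count_table(list(), species = c("a", "b"))), 0L)
  # a single-gene A-T-R locus is assembled but not counted
  atr <- classify_locus(toy_locus(list(c("A", "T", "R")),
                                  core_classes = c(g001 = "NRPS_family")))
  expect_equal(atr$class, "NRPS_like_ATR")
  expect_false(atr$counted)
})
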