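test_that("self-comparison yields one perfect link per gene", {
  l <- toy_locus(list(c("KS", "AT", "ACP"), "TC", "CS"))
  links <- compare_bgcs(l, l)
  expect_equal(nrow(links), nrow(l$genes))
  expect_true(all(links$identity_pct == 100))
  expect_identical(links$gene1, links$gene2)
})

test_that("links are order-independent and respect the identity floor", {
  a <- toy_locus(list(c("KS", "AT"), "TC", "DMAT"), identity = 0.8, seed = 4L)
  b <- toy_locus(list(c("KS", "AT"), "TC", "DMAT"), identity = 0.8, seed = 9L)
  b_rev <- b
  b_rev$genes <- b_rev$genes[rev(seq_len(nrow(b_rev$genes))), ]
  b_rev$genes <- b_rev$genes[order(b_rev$genes$start), ]
  l1 <- compare_bgcs(a, b)
  l2 <- compare_bgcs(a, b_rev)
  expect_identical(l1[order(l1$gene1), c("gene1", "gene2")],
                   l2[order(l2$gene1), c("gene1", "gene2")])
  # disjoint random loci produce no links
  set.seed(12)
  r1 <- toy_locus(list(character(), character()), seed = 21L)
  r2 <- toy_locus(list(character(), character()), seed = 22L)
  expect_equal(nrow(compare_bgcs(r1, r2)), 0L)
})

test_that("homology groups are single-linkage and input-order invariant", {
  copies <- lapply(1:3, function(i) {
    l <- toy_locus(list(c("KS", "AT"), "TC", "CS"), identity = 0.9,
                   seed = 40L + 0L)  # same seed: identical loci
    l$bgc_id <- paste0("B", i)
    l
  })
  hg <- homology_groups(copies)
  expect_equal(nrow(hg), 9L)
  expect_equal(length(unique(hg$group)), 3L)  # one group per gene position
  expect_true(all(table(hg$group) == 3L))
  # order invariance (up to group relabelling)
  hg2 <- homology_groups(rev(copies))
  key1 <- unname(split(paste(hg$bgc_id, hg$gene_id), hg$group))
  key2 <- unname(split(paste(hg2$bgc_id, hg2$gene_id), hg2$group))
  expect_setequal(lapply(key1, sort), lapply(key2, sort))
  # unrelated loci -> all singleton groups
  set.seed(6)
  u1 <- toy_locus(list(character()), seed = 61L); u1$bgc_id <- "U1"
  u2 <- toy_locus(list(character()), seed = 62L); u2$bgc_id <- "U2"
  hg3 <- homology_groups(list(u1, u2))
  expect_equal(length(unique(hg3$group)), 2L)
})

test_that("a family member lost in one locus shrinks only its group", {
  full <- toy_locus(list(c("KS", "AT"), "TC", "CS"), identity = 0.9,
                    seed = 50L)
  full$bgc_id <- "full1"
  full2 <- toy_locus(list(c("KS", "AT"), "TC", "CS"), identity = 0.9,
                     seed = 50L)
  full2$bgc_id <- "full2"
  lost <- toy_locus(list(c("KS", "AT"), "CS"), identity = 0.9, seed = 50L)
  lost$bgc_id <- "lost"
  hg <- homology_groups(list(full, full2, lost))
  sizes <- sort(as.integer(table(hg$group)), decreasing = TRUE)
  expect_identical(sizes, c(3L, 3L, 2L))
})

test_that("co-localised search finds planted clusters within gene gaps", {
  fdb <- fix_fdb()
  set.seed(9)
  queries <- stats::setNames(
    vapply(1:3, function(i) random_peptide(200), ""), c("qA", "qB", "qC"))
  filler <- vapply(1:12, function(i) random_peptide(150), "")
  # cluster: homologs of all three queries with one intervening filler
  cluster <- vapply(queries, mutate_to_identity, "", 0.75, seed = 3L)
  g <- toy_genome(c(filler[1:4], cluster[1], filler[5], cluster[2],
                    cluster[3], filler[6:9]), "coloc")
  hits <- find_colocalized(queries, list(g), min_queries = 3L,
                           max_gap_genes = 2L)
  expect_length(hits, 1L)
  expect_setequal(hits[[1]]$matched_queries, names(queries))
  expect_identical(hits[[1]]$gene_ids, c("g005", "g007", "g008"))
  # scattered homologs beyond the gap yield no window
  g2 <- toy_genome(c(cluster[1], filler[1:5], cluster[2], filler[6:10],
                     cluster[3]), "scatter")
  expect_length(find_colocalized(queries, list(g2), min_queries = 3L,
                                 max_gap_genes = 2L), 0L)
  expect_error(find_colocalized(queries, list(g), min_queries = 5L),
               "min_queries")
  expect_error(find_colocalized(queries[1], list(g)), "two queries")
})
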