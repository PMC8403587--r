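test_that("Jaccard index follows set arithmetic on domain types", {
  a <- toy_locus(list(c("KS", "AT", "ACP")))
  b <- toy_locus(list(c("KS", "AT", "KR", "ACP")))
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, b), 3 / 4)
  expect_equal(jaccard_index(toy_locus(list("TC")), toy_locus(list("CS"))), 0)
  # both empty -> 0 by convention
  e <- toy_locus(list(character()))
  expect_equal(jaccard_index(e, e), 0)
})

test_that("DSI matches the weighted copy-pairing formula by hand", {
  # two KS copies at exactly 80% and 60% identity, nothing else:
  # mutate fixed blocks of a shared base so local identity is exact
  set.seed(8)
  base <- random_peptide(100)
  swap_block <- function(p, idx) {
    letters <- strsplit(p, "")[[1]]
    # substitute with a mildly penalised residue so the full-length
    # alignment stays optimal and identity is exactly the block fraction
    letters[idx] <- ifelse(letters[idx] == "A", "G", "A")
    paste(letters, collapse = "")
  }
  c80 <- swap_block(base, 41:60)   # 80% identical
  c60 <- swap_block(base, 31:70)   # 60% identical
  inv <- function(seqs) list(multiset = rep("KS", length(seqs)),
                             sequence = rep("KS", length(seqs)),
                             copies = data.frame(domain = "KS",
                                                 gene_id = "g", seq = seqs))
  A <- inv(c(base, base)); B <- inv(c(c80, c60))
  # greedy pairing: base-c80 (0.8) then base-c60 (0.6); all copies weight 1
  # DSI = (2*0.8 + 2*0.6) / 4
  expect_equal(dsi(A, B), (2 * 0.8 + 2 * 0.6) / 4, tolerance = 1e-6)
  # identical inventories -> 1; disjoint types -> 0
  expect_equal(dsi(A, A), 1)
  B2 <- list(multiset = "TC", sequence = "TC",
             copies = data.frame(domain = "TC", gene_id = "g", seq = base))
  expect_equal(dsi(A, B2), 0)
  # anchor weighting shifts the same identities toward the anchor copy
  Aa <- list(multiset = c("KS", "TC"), sequence = c("KS", "TC"),
             copies = data.frame(domain = c("KS", "TC"), gene_id = "g",
                                 seq = c(base, base)))
  Bb <- list(multiset = c("KS", "TC"), sequence = c("KS", "TC"),
             copies = data.frame(domain = c("KS", "TC"), gene_id = "g",
                                 seq = c(c60, c80)))
  # weights: KS 1, TC 2 -> DSI = (2*1*0.6 + 2*2*0.8)/(2*1 + 2*2)
  expect_equal(dsi(Aa, Bb), (2 * 0.6 + 4 * 0.8) / 6, tolerance = 1e-6)
})

test_that("adjacency index is the Jaccard of ordered adjacent pairs", {
  a <- toy_locus(list(c("KS", "AT", "ACP", "TE")))
  expect_equal(adjacency_index(a, a), 1)
  # same multiset, no shared adjacencies
  b <- toy_locus(list(c("TE", "ACP", "AT", "KS")))
  expect_equal(adjacency_index(a, b), 0)
  # a single-domain locus against a multi-domain locus shares no pairs
  expect_equal(adjacency_index(toy_locus(list("TC")), a), 0)
  # degenerate pair of single-domain loci: type-set fallback, so a locus is
  # never at positive distance from itself
  expect_equal(adjacency_index(toy_locus(list("TC")), toy_locus(list("CS"))),
               0)
  expect_equal(adjacency_index(toy_locus(list("TC")), toy_locus(list("TC"))),
               1)
})

test_that("the weighted distance obeys its axioms on random loci", {
  set.seed(31)
  for (i in 1:25) {
    dsA <- sample(domain_vocab(), sample(1:5, 1))
    dsB <- sample(domain_vocab(), sample(1:5, 1))
    A <- toy_locus(list(dsA), identity = 0.9, seed = i)
    B <- toy_locus(list(dsB), identity = 0.9, seed = i + 500L)
    pd <- pair_distance(A, B)
    pd_rev <- pair_distance(B, A)
    expect_gte(pd$distance, 0); expect_lte(pd$distance, 1)
    expect_true(all(c(pd$ji, pd$dsi, pd$ai) >= 0 &
                      c(pd$ji, pd$dsi, pd$ai) <= 1))
    expect_equal(pd$distance, pd_rev$distance, tolerance = 1e-9)
    expect_equal(pair_distance(A, A)$distance, 0)
  }
  # fully disjoint loci are maximally distant
  expect_equal(pair_distance(toy_locus(list(c("KS", "AT"))),
                             toy_locus(list(c("CS", "TC"))))$distance, 1)
  # permuting the index weights changes the value (weights matter)
  A <- toy_locus(list(c("KS", "AT", "ACP"))); B <- toy_locus(list(c("KS", "AT")))
  expect_false(isTRUE(all.equal(
    pair_distance(A, B, weights = c(0.2, 0.75, 0.05))$distance,
    pair_distance(A, B, weights = c(0.75, 0.2, 0.05))$distance)))
})

test_that("DSI falls and distance rises along a divergence ladder", {
  base <- toy_locus(list(c("KS", "AT", "KR", "ACP")), identity = 1,
                    seed = 77L)
  idents <- c(0.95, 0.85, 0.75, 0.65, 0.5)
  dsis <- numeric(); dists <- numeric()
  for (k in seq_along(idents)) {
    other <- toy_locus(list(c("KS", "AT", "KR", "ACP")),
                       identity = idents[k], seed = 77L)
    pd <- pair_distance(base, other)
    dsis <- c(dsis, pd$dsi); dists <- c(dists, pd$distance)
  }
  expect_true(all(diff(dsis) <= 1e-9))
  expect_true(all(diff(dists) >= -1e-9))
})

test_that("GCF components match brute-force closure; cutoffs nest", {
  set.seed(55)
  mk_fake_loci <- function(n) lapply(seq_len(n), function(i) {
    l <- toy_locus(list("TC"), bgc_id = sprintf("B%02d", i),
                   species_id = sample(c("s1", "s2", "s3"), 1))
    l$bgc_id <- sprintf("B%02d", i)
    l
  })
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    loci <- mk_fake_loci(n)
    ids <- vapply(loci, `[[`, "", "bgc_id")
    pairs <- t(combn(ids, 2))
    distances <- data.frame(bgc1 = pairs[, 1], bgc2 = pairs[, 2],
                            ji = 0, dsi = 0, ai = 0,
                            distance = round(runif(nrow(pairs)), 2))
    parts <- list()
    for (cf in c(0.3, 0.4, 0.5, 0.6)) {
      nw <- build_network(loci, cutoff = cf, distances = distances)
      # every BGC in exactly one GCF
      expect_setequal(nw$membership$bgc_id, ids)
      expect_false(anyDuplicated(nw$membership$bgc_id) > 0)
      # oracle: transitive closure over kept edges
      kept <- distances[distances$distance < cf, ]
      oracle <- oracle_components(ids, kept)
      got <- nw$membership$gcf_id[match(ids, nw$membership$bgc_id)]
      expect_equal(adjusted_rand_index(got, oracle), 1)
      parts[[sprintf("%.1f", cf)]] <- got
    }
    # nestedness: raising the cutoff only merges, never splits
    for (k in 1:3) {
      lo <- parts[[k]]; hi <- parts[[k + 1]]
      same_lo <- outer(lo, lo, "==")
      same_hi <- outer(hi, hi, "==")
      expect_true(all(same_hi[same_lo]))
    }
  }
})

test_that("singletons are kept and reference-only subnetworks are pruned", {
  l1 <- toy_locus(list(c("KS", "AT", "ACP")), identity = 0.95, seed = 1L)
  l1$bgc_id <- "mine1"
  l2 <- toy_locus(list(c("KS", "AT", "ACP")), identity = 0.95, seed = 1L)
  l2$bgc_id <- "ref_sibling"; l2$is_reference <- TRUE
  r1 <- toy_locus(list(c("C", "A", "T")), identity = 0.95, seed = 2L,
                  is_reference = TRUE)
  r1$bgc_id <- "ref1"
  r2 <- toy_locus(list(c("C", "A", "T")), identity = 0.95, seed = 2L,
                  is_reference = TRUE)
  r2$bgc_id <- "ref2"
  lone <- toy_locus(list("DMAT"), seed = 3L); lone$bgc_id <- "lone"
  nw <- build_network(list(l1, l2, r1, r2, lone), cutoff = 0.4)
  expect_length(nw$gcfs, 3L)
  pruned <- prune_reference_only(nw$gcfs)
  expect_length(pruned, 2L)
  members <- lapply(pruned, `[[`, "members")
  # the mixed component is retained intact, the singleton kept
  expect_true(any(vapply(members, function(m)
    setequal(m, c("mine1", "ref_sibling")), TRUE)))
  expect_true(any(vapply(members, identical, TRUE, "lone")))
  # no references at all -> pruning is the identity
  nw2 <- build_network(list(l1, lone), cutoff = 0.4)
  expect_identical(prune_reference_only(nw2$gcfs), nw2$gcfs)
})

test_that("conserved-family counting requires every species", {
  g <- function(sp) structure(list(gcf_id = "x", members = "m",
                                   species = sp), class = "gcf")
  expect_equal(conserved_gcfs(list(), c("a", "b")), 0)
  expect_equal(conserved_gcfs(list(g(c("a", "b")), g("a"), g(c("a", "b"))),
                              c("a", "b")), 2)
})
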