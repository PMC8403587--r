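test_that("protein generation is seeded and validated", {
  expect_identical(make_protein(50L, 1L), make_protein(50L, 1L))
  expect_false(make_protein(50L, 1L) == make_protein(50L, 2L))
  expect_error(make_protein(0L, 1L), ">= 1")
})

test_that("mutation hits the exact conserved-position count", {
  p <- make_protein(100L, 10L)
  expect_identical(mutate_to_identity(p, 1.0, 3L), p)
  m <- mutate_to_identity(p, 0.7, 3L)
  expect_equal(nchar(m), 100L)
  same <- sum(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
  expect_equal(same, 70L)
  # identity floor enforced
  expect_error(mutate_to_identity(p, 0.05, 3L), "0.2")
  # ceiling rule on awkward lengths
  p2 <- make_protein(7L, 11L)
  m2 <- mutate_to_identity(p2, 0.5, 4L)
  expect_equal(sum(strsplit(p2, "")[[1]] == strsplit(m2, "")[[1]]),
               ceiling(0.5 * 7))
})

test_that("planted families reproduce their variants' signatures", {
  panel <- fix_panel(); fdb <- fix_fdb(); templates <- fix_templates()
  spec <- family_spec(
    "famX", "collaborative_PKS",
    genes = list(
      list(name = "pks1", kind = "domains", role = "core",
           domains = c("KS", "AT", "DH", "ER", "KR", "ACP")),
      list(name = "pks2", kind = "domains", role = "core",
           domains = c("SAT", "KS", "AT", "PT", "ACP")),
      list(name = "t1", kind = "function", ref = "tail_p450",
           role = "tailoring")),
    species = c("spA", "spB", "spC"), identity = 1.0,
    rearrange_in = "spC")
  fam <- plant_family(spec, 77L, panel, fdb, templates)
  # identity 1.0, no variants: members A and B are identical
  pa <- vapply(fam$spA$genes, `[[`, "", "protein")
  pb <- vapply(fam$spB$genes, `[[`, "", "protein")
  expect_identical(pa, pb)
  # the rearranged sibling has the same proteins in a different order
  pc <- vapply(fam$spC$genes, `[[`, "", "protein")
  expect_setequal(pc, pa)
  expect_false(identical(pc, pa))
  # gene-order shuffle lowers the adjacency index against the sibling
  mk_locus <- function(member, id) {
    doms <- lapply(member$genes, `[[`, "domains")
    l <- toy_locus(doms, bgc_id = id)
    for (k in seq_along(member$genes)) {
      gid <- l$genes$gene_id[k]
      dh <- l$domain_hits[[gid]]
      if (nrow(dh)) {
        lens <- nchar(panel[dh$domain])
        ends <- cumsum(lens); starts <- ends - lens + 1L
        dh$seq <- substring(member$genes[[k]]$protein, starts, ends)
        l$domain_hits[[gid]] <- dh
      }
      l$genes$protein[k] <- member$genes[[k]]$protein
    }
    l
  }
  ai_sib <- adjacency_index(mk_locus(fam$spA, "A"), mk_locus(fam$spC, "C"))
  expect_lt(ai_sib, 1)
  # disintegration produces a locus the detector recognises
  spec2 <- family_spec(
    "famY", "hrPKS",
    genes = list(list(name = "pks", kind = "domains", role = "core",
                      domains = c("KS", "AT", "DH", "CMeT", "ER", "KR",
                                  "ACP"))),
    species = "spA", identity = 0.9,
    disintegrate_in = list(species = "spA", gene = "pks", split_after = 5L))
  fam2 <- plant_family(spec2, 78L, panel, fdb, templates)
  expect_length(fam2$spA$genes, 2L)
  expect_identical(fam2$spA$genes[[1]]$domains,
                   c("KS", "AT", "DH", "CMeT", "ER"))
  expect_identical(fam2$spA$genes[[2]]$domains, c("KR", "ACP"))
})

test_that("cohorts are deterministic and filler is template-clean", {
  fams <- list(family_spec(
    "f1", "terpene_mono_sesqui",
    genes = list(list(name = "tc", kind = "domains", domains = "TC",
                      role = "core")),
    species = "sp01", identity = 0.9))
  co1 <- make_cohort(n_species = 1L, families = fams, seed = 9L,
                     panel = fix_panel(), fdb = fix_fdb(),
                     templates = fix_templates())
  co2 <- make_cohort(n_species = 1L, families = fams, seed = 9L,
                     panel = fix_panel(), fdb = fix_fdb(),
                     templates = fix_templates())
  expect_identical(co1$genomes$sp01$genes, co2$genomes$sp01$genes)
  expect_identical(co1$genomes$sp01$contigs, co2$genomes$sp01$contigs)
  expect_identical(co1$truth, co2$truth)
  # cohort with no families: pure filler, the pipeline finds nothing
  co0 <- make_cohort(n_species = 1L, families = list(), seed = 10L,
                     panel = fix_panel(), fdb = fix_fdb(),
                     templates = fix_templates())
  expect_equal(nrow(scan_cores(co0$genomes$sp01, fix_templates())), 0L)
  roles <- call_gene_roles(co0$genomes$sp01, fix_fdb())
  expect_true(all(roles == "unrelated"))
})

test_that("the default design plants the documented study conditions", {
  spec <- default_cohort_spec()
  expect_equal(spec$n_species, 8L)
  ids <- vapply(spec$families, `[[`, "", "family_id")
  multi <- vapply(spec$families, function(f) length(f$species) > 1L, TRUE)
  excl <- vapply(spec$families, function(f)
    f$class == "excluded_primary_metabolism", TRUE)
  expect_equal(sum(multi & !excl), 6L)     # six multi-species families
  expect_equal(sum(!multi & !excl), 10L)   # ten private singletons
  expect_true(any(vapply(spec$families, function(f)
    !is.null(f$rearrange_in), TRUE)))
  expect_true(any(vapply(spec$families, function(f)
    !is.null(f$truncate_in), TRUE)))
  expect_true(any(vapply(spec$families, function(f)
    !is.null(f$disintegrate_in), TRUE)))
  idents <- vapply(spec$families[multi & !excl], `[[`, 0, "identity")
  expect_true(all(idents >= 0.70 & idents <= 0.90))
  expect_gte(spec$filler_per_contig, 4L)
})
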