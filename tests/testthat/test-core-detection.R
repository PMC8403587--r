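test_that("template scanning detects planted cores and nothing else", {
  templates <- fix_templates()
  set.seed(7)
  # filler drawn as the generator draws it: random proteins rejection-
  # sampled against the template library (E <= 0.1 is permissive by design,
  # so unfiltered random sequences would produce the expected ~0.1 chance
  # hits per search)
  scheme <- scoring_scheme()
  filler <- character()
  while (length(filler) < 10L) {
    p <- random_peptide(300)
    if (!bgcfam:::hits_templates(p, templates, scheme, db_len_floor = 1e3))
      filler <- c(filler, p)
  }
  pks_template <- templates$protein[templates$accession == "APH07629"]
  planted <- mutate_to_identity(pks_template, 0.65, 99L)
  g <- toy_genome(c(filler[1:5], planted, filler[6:10]), "scan")
  hits <- scan_cores(g, templates)
  expect_equal(hits$gene_id, "g006")
  expect_equal(hits$target_class, "typeI_PKS")
  # a genome of random filler alone yields no hits
  expect_equal(nrow(scan_cores(toy_genome(filler), templates)), 0L)
  # the template itself is found with full identity
  g2 <- toy_genome(c(filler[1:3], pks_template), "self")
  h2 <- scan_cores(g2, templates)
  expect_equal(h2$gene_id, "g004")
  r <- local_align(pks_template, g2$genes$protein[4])
  expect_equal(r$identity_pct, 100)
})

test_that("core scanning is invariant to template order", {
  templates <- fix_templates()
  co <- make_cohort(n_species = 1L, seed = 5L, families = list(
    family_spec("f", "hrPKS", genes = list(
      list(name = "pks", kind = "domains", role = "core",
           domains = c("KS", "AT", "DH", "ER", "KR", "ACP"))),
      species = "sp01", identity = 0.8)),
    panel = fix_panel(), fdb = fix_fdb(), templates = templates)
  g <- co$genomes$sp01
  h1 <- scan_cores(g, templates)
  set.seed(1)
  h2 <- scan_cores(g, templates[sample(nrow(templates)), ])
  expect_identical(h1, h2)
})

test_that("domain strings are recovered from concatenated references", {
  panel <- fix_panel()
  gene <- paste0(panel[["KS"]], panel[["AT"]], panel[["ACP"]])
  hits <- assign_domains(gene, panel, gene_id = "g1")
  expect_identical(hits$domain, c("KS", "AT", "ACP"))
  expect_true(all(diff(hits$start) > 0))
  expect_true(all(hits$end[-nrow(hits)] < hits$start[-1]))  # non-nested
  # a random protein has no domains
  set.seed(3)
  expect_equal(nrow(assign_domains(random_peptide(300), panel)), 0L)
  # repeated domains are each recovered (re-fit after masking)
  gene2 <- paste0(panel[["C"]], panel[["A"]], panel[["T"]],
                  panel[["C"]], panel[["A"]], panel[["T"]])
  expect_identical(assign_domains(gene2, panel)$domain,
                   c("C", "A", "T", "C", "A", "T"))
})

test_that("a supplied domain table takes precedence over the matcher", {
  panel <- fix_panel()
  gene <- paste0(panel[["KS"]], panel[["AT"]])
  f <- tempfile()
  writeLines(c("gene_id\tdomain\tstart\tend\tscore",
               "g9\tTC\t1\t100\t55"), f)
  tab <- read_domain_table(f)
  hits <- assign_domains(gene, panel, gene_id = "g9", table = tab)
  expect_identical(hits$domain, "TC")
  expect_identical(hits$seq, substr(gene, 1, 100))
})

test_that("domain inventories respect coordinate order and strand", {
  l <- toy_locus(list(c("KS", "AT"), c("C", "A", "T")),
                 strand = c("+", "-"))
  inv <- domain_inventory(l)
  # minus-strand gene contributes its N->C string reversed (genomic order)
  expect_identical(inv$sequence, c("KS", "AT", "T", "A", "C"))
  expect_setequal(inv$multiset, c("KS", "AT", "C", "A", "T"))
  # single gene, plus strand
  l2 <- toy_locus(list(c("KS", "AT", "ACP")))
  expect_identical(domain_inventory(l2)$sequence, c("KS", "AT", "ACP"))
  # empty locus inventory
  l3 <- toy_locus(list(character()))
  expect_length(domain_inventory(l3)$multiset, 0L)
})
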