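test_that("GenBank reading handles trivial and malformed records", {
  f <- tempfile()
  writeLines("nothing here", f)
  expect_error(read_genbank(f), "no records")
  # single 9-nt CDS translates with the standard code, stop trimmed
  writeLines(c(
    "LOCUS       tiny 9 bp    DNA     linear   PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    '                     /locus_tag="t1"',
    "ORIGIN",
    "        1 atggcataa",
    "//"), f)
  g <- read_genbank(f)
  expect_equal(nrow(g$genes), 1L)
  expect_equal(g$genes$protein, "MA")
})

test_that("internal stop codons become X with a warning", {
  f <- tempfile()
  writeLines(c(
    "LOCUS       s 12 bp    DNA     linear   PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..12",
    "ORIGIN",
    "        1 atgtaagcat aa",
    "//"), f)
  expect_warning(g <- read_genbank(f), "internal stop")
  expect_equal(g$genes$protein, "MXA")
})

test_that("GFF3+FASTA reading matches the coordinate and strand contract", {
  gff <- tempfile(fileext = ".gff3"); fna <- tempfile(fileext = ".fna")
  # minus-strand CDS: protein equals translation of the reverse complement
  nt <- paste0("GGGG", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGGCACGGTAA"))),
    "GG")
  writeLines(c(">c1", nt), fna)
  writeLines(c("##gff-version 3",
               paste("c1", "x", "CDS", "5", "16", ".", "-", "0",
                     "ID=m1", sep = "\t")), gff)
  g <- read_gff_fasta(gff, fna)
  expect_equal(g$genes$protein, "MAR")
  expect_equal(g$genes$strand, "-")
  # zero CDS -> empty genome
  writeLines("##gff-version 3", gff)
  expect_equal(nrow(read_gff_fasta(gff, fna)$genes), 0L)
  # absent contig errors
  writeLines(c("##gff-version 3",
               paste("cX", "x", "CDS", "1", "6", ".", "+", "0",
                     "ID=m2", sep = "\t")), gff)
  expect_error(read_gff_fasta(gff, fna), "absent contig")
})

test_that("generator output round-trips through both readers exactly", {
  fam <- family_spec("f1", "terpene_mono_sesqui",
                     genes = list(list(name = "tc", kind = "domains",
                                       domains = "TC", role = "core")),
                     species = "sp01", identity = 0.9)
  co <- make_cohort(n_species = 1L, families = list(fam), seed = 3L,
                    panel = fix_panel(), fdb = fix_fdb(),
                    templates = fix_templates())
  g <- co$genomes$sp01
  td <- tempfile(); dir.create(td)
  write_cohort(co, td)
  g_gbk <- read_genbank(file.path(td, "sp01.gbk"))
  g_gff <- read_gff_fasta(file.path(td, "sp01.gff3"),
                          file.path(td, "sp01.fna"))
  for (g2 in list(g_gbk, g_gff)) {
    expect_equal(nrow(g2$genes), nrow(g$genes))
    expect_identical(g2$genes$protein, g$genes$protein)
    expect_identical(g2$genes$start, g$genes$start)
    expect_identical(g2$genes$end, g$genes$end)
    expect_identical(g2$genes$strand, g$genes$strand)
    # ordering invariant after any read path
    expect_true(all(diff(order(g2$genes$contig_id, g2$genes$start)) == 1L))
  }
})

test_that("domain tables are validated and sorted", {
  f <- tempfile()
  writeLines("gene_id\tdomain\tstart\tend\tscore", f)
  expect_equal(nrow(read_domain_table(f)), 0L)
  writeLines(c("gene_id\tdomain\tstart\tend\tscore",
               "g1\tKS\t400\t200\t10"), f)
  expect_error(read_domain_table(f), "end < start")
  writeLines(c("gene_id\tdomain\tstart\tend\tscore",
               "g1\tNOTADOMAIN\t1\t50\t10"), f)
  expect_error(read_domain_table(f), "vocabulary")
  writeLines(c("gene_id\tdomain\tstart\tend\tscore",
               "g1\tAT\t300\t500\t10", "g1\tKS\t1\t280\t12"), f)
  tab <- read_domain_table(f)
  expect_identical(tab$domain, c("KS", "AT"))
})

test_that("BGC GFF3 output round-trips loci", {
  f <- tempfile(fileext = ".gff3")
  write_bgc_gff(list(), f)
  expect_identical(readLines(f), "##gff-version 3")
  l <- toy_locus(list(c("KS", "AT", "ACP"), "TC", character(), "CS", "DMAT"),
                 core_classes = c(g001 = "typeI_PKS"))
  write_bgc_gff(list(l), f)
  lines <- readLines(f)
  expect_equal(length(lines), 1L + 1L + 5L)  # header + cluster + 5 genes
  genome <- new_genome("toy", l$genes)
  back <- read_bgc_gff(f, genome)
  expect_length(back, 1L)
  expect_identical(back[[1]]$genes$gene_id, l$genes$gene_id)
  expect_identical(back[[1]]$core_gene_ids, l$core_gene_ids)
  expect_identical(back[[1]]$genes$protein, l$genes$protein)
})
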