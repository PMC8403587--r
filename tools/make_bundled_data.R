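# Regenerates the synthetic bundled reference data under inst/extdata:
# the per-domain reference panel, the 17-entry core-template library (with
# its Table-2-style manifest), and the labelled function database.
# All sequences are deterministic synthetic stand-ins; this script asserts
# the cross-hit cleanliness the pipeline relies on.
# Run from the package root:  Rscript tools/make_bundled_data.R

suppressMessages(devtools::load_all(".", quiet = TRUE))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

# ---- domain reference panel --------------------------------------------
panel_len <- c(
  SAT = 240L, KS = 300L, AT = 250L, PT = 220L, ACP = 80L, CMeT = 200L,
  DH = 180L, ER = 250L, KR = 220L, TE = 200L, R = 250L,
  C = 300L, A = 400L, T = 80L, E = 250L,
  GGPPS = 250L, TC = 250L, CS = 300L, FAS_alpha = 500L, FAS_beta = 450L,
  PTase = 250L, LSS = 400L, SHC = 400L, DMAT = 300L, GT = 250L, CDPS = 200L)
stopifnot(setequal(names(panel_len), domain_vocab()))
panel <- vapply(names(panel_len), function(d)
  make_protein(panel_len[[d]], derive_seed(20240101L, paste("panel", d))), "")
write_fasta(as.list(panel), "inst/extdata/domain_panel_synthetic.faa")
write.table(
  data.frame(domain = names(panel_len), length = unname(panel_len),
             description = "synthetic reference segment"),
  "inst/extdata/domain_panel_manifest.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

# ---- core template library ---------------------------------------------
cat_panel <- function(...) paste(panel[c(...)], collapse = "")
mut <- function(p, id, lbl) mutate_to_identity(p, id, derive_seed(20240102L, lbl))
templates <- list(
  list("APH07629", "orsellinic acid synthase PKS1", "Agaricomycetes sp.",
       "typeI_PKS", cat_panel("SAT", "KS", "AT", "PT", "ACP", "TE")),
  list("XP_960427", "chalcone synthase", "Neurospora crassa",
       "typeIII_PKS", make_protein(380L, derive_seed(20240102L, "chs"))),
  list("S3DQP3", "A1 domain of nonribosomal peptide synthetase GloA",
       "Glarea lozoyensis", "NRPS_family", panel[["A"]]),
  list("AHY23922", "1,8-cineole synthase", "Hypoxylon sp.", "terpene",
       mut(panel[["TC"]], 0.75, "cin")),
  list("AWM95795", "humulene synthase Asr6", "Sarocladium sp.", "terpene",
       mut(panel[["TC"]], 0.75, "hum")),
  list("Q6WP50", "presilphiperfolan-8-beta-ol synthase Bot2",
       "Botrytis cinerea", "terpene", mut(panel[["TC"]], 0.75, "bot")),
  list("QOE88883", "brasilane synthase BraA", "Annulohypoxylon truncatum",
       "terpene", mut(panel[["TC"]], 0.75, "bra")),
  list("C9K2Q3", "fusicoccadiene synthase", "Alternaria brassicicola",
       "terpene", paste0(mut(panel[["TC"]], 0.8, "fusT"),
                         mut(panel[["GGPPS"]], 0.8, "fusG"))),
  list("A0A1B4XBG5", "cycloaraneosene synthase SdnA", "Sordaria araneosa",
       "terpene", paste0(mut(panel[["TC"]], 0.8, "sdnT"),
                         mut(panel[["GGPPS"]], 0.8, "sdnG"))),
  list("B2DBF1", "copalyl diphosphate synthase", "Diaporthe amygdali",
       "terpene", paste0(mut(panel[["TC"]], 0.8, "cpsT"),
                         mut(panel[["GGPPS"]], 0.8, "cpsG"))),
  list("P38604", "lanosterol synthase Erg7", "Saccharomyces cerevisiae",
       "terpene", panel[["LSS"]]),
  list("FernS", "fernane-type triterpene synthase (synthetic)", "synthetic",
       "terpene", panel[["SHC"]]),
  list("QOV03404", "citrate synthase SpoE", "Hypomontagnella monticulosa",
       "alkyl_citrate", panel[["CS"]]),
  list("D4D449", "tryptophan dimethylallyltransferase",
       "Trichophyton verrucosum", "alkaloid_DMAT", panel[["DMAT"]]),
  list("AMR44282", "phomopsin precursor PhomA", "Diaporthe leptostromiformis",
       "RiPP_precursor", make_protein(64L, derive_seed(20240102L, "phomA"))),
  list("OphMA", "omphalotin precursor OphMA", "Omphalotus olearius",
       "RiPP_precursor", make_protein(70L, derive_seed(20240102L, "ophMA"))),
  list("ACB30126", "epichloecyclin precursor GigA", "Epichloe festucae",
       "RiPP_precursor", make_protein(58L, derive_seed(20240102L, "gigA"))))
stopifnot(length(templates) == 17L)
tman <- do.call(rbind, lapply(templates, function(t) data.frame(
  accession = t[[1]], name = t[[2]], organism = t[[3]], target_class = t[[4]])))
tseq <- setNames(lapply(templates, `[[`, 5L), tman$accession)
write_fasta(tseq, "inst/extdata/core_templates_synthetic.faa")
write.table(tman, "inst/extdata/core_templates_manifest.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# ---- function database --------------------------------------------------
fdb_spec <- list(
  # core-adjacent standalone enzymes share the panel sequences so that
  # panel-derived accessory core genes are recognised as BGC-related
  list("core_PTase", "core", "UbiA-type prenyltransferase", panel[["PTase"]]),
  list("core_GGPPS", "core", "geranylgeranyl pyrophosphate synthase",
       panel[["GGPPS"]]),
  list("core_FASalpha", "core", "fatty acid synthase alpha subunit",
       panel[["FAS_alpha"]]),
  list("core_FASbeta", "core", "fatty acid synthase beta subunit",
       panel[["FAS_beta"]]),
  list("tail_p450", "tailoring", "cytochrome P450 monooxygenase", 320L),
  list("tail_fmo", "tailoring", "FAD-dependent monooxygenase", 300L),
  list("tail_omt", "tailoring", "O-methyltransferase", 260L),
  list("tail_gt", "tailoring", "glycosyltransferase", 280L),
  list("reg_zn2cys6", "regulatory", "Zn2Cys6 transcription factor", 280L),
  list("trans_mfs", "transport", "MFS transporter", 300L),
  list("trans_abc", "transport", "ABC transporter", 350L),
  list("res_pump", "resistance", "multidrug efflux pump", 310L),
  list("hk_actin", "housekeeping", "actin", 280L),
  list("hk_tubulin", "housekeeping", "beta-tubulin", 300L),
  list("hk_gapdh", "housekeeping", "glyceraldehyde-3-phosphate dehydrogenase",
       260L),
  list("hk_rpl", "housekeeping", "60S ribosomal protein", 220L),
  list("hk_hsp70", "housekeeping", "heat shock protein 70", 320L))
fdb_rows <- do.call(rbind, lapply(fdb_spec, function(x) data.frame(
  id = x[[1]], label = x[[2]], description = x[[3]])))
# random entries are rejection-sampled so that no non-core reference (nor
# anything derived from one) can chance-hit the template library
scheme <- scoring_scheme()
tpl_df <- data.frame(accession = tman$accession,
                     protein = unlist(tseq), stringsAsFactors = FALSE)
clean_protein <- function(len, label) {
  for (attempt in 0:50) {
    p <- make_protein(len, derive_seed(20240103L, paste(label, attempt)))
    if (!bgcfam:::hits_templates(p, tpl_df, scheme)) return(p)
  }
  stop("could not draw a template-clean reference for ", label)
}
fdb_seqs <- setNames(lapply(fdb_spec, function(x)
  if (is.character(x[[4]])) x[[4]] else clean_protein(x[[4]], x[[1]])),
  fdb_rows$id)
write_fasta(fdb_seqs, "inst/extdata/function_db_synthetic.faa")
write.table(fdb_rows, "inst/extdata/function_db_manifest.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# ---- cleanliness assertions --------------------------------------------
self <- vapply(panel, function(p) sum(scheme$matrix[cbind(
  strsplit(p, "")[[1]], strsplit(p, "")[[1]])]), 0)
# no panel reference reaches 30% of another's self-score (domain matcher
# cannot confuse labels)
for (a in names(panel)) for (b in names(panel)) {
  if (a == b) next
  sc <- local_scores(panel[[a]], panel[[b]], scheme)
  stopifnot(sc < 0.3 * self[[a]], sc < 0.3 * self[[b]])
}
# no non-core function-db entry produces a template hit at the core
# threshold (conservative small database length)
for (i in seq_len(nrow(fdb_rows))) {
  if (fdb_rows$label[i] == "core") next
  stopifnot(!bgcfam:::hits_templates(fdb_seqs[[i]], core_templates(),
                                     scheme))
}
cat("bundled data written and verified\n")
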