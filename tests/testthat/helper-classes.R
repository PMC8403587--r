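# one crafted fixture per class (plus exclusion variants)
class_fixtures <- function() list(
  list(cls = "hrPKS",
       l = toy_locus(list(c("KS", "AT", "DH", "CMeT", "ER", "KR", "ACP")))),
  list(cls = "nrPKS", l = toy_locus(list(c("SAT", "KS", "AT", "PT", "ACP",
                                           "TE")))),
  list(cls = "prPKS", l = toy_locus(list(c("KS", "AT", "KR", "ACP")))),
  list(cls = "truncated_PKS", l = toy_locus(list(c("KS", "AT")))),
  list(cls = "disintegrated_PKS",
       l = toy_locus(list(c("KS", "AT", "DH", "CMeT", "ER"),
                          c("KR", "ACP")))),
  list(cls = "collaborative_PKS",
       l = toy_locus(list(c("KS", "AT", "DH", "ER", "KR", "ACP"),
                          c("SAT", "KS", "AT", "PT", "ACP")))),
  list(cls = "typeIII_PKS",
       l = toy_locus(list(character()),
                     core_classes = c(g001 = "typeIII_PKS"))),
  list(cls = "meroterpenoid",
       l = toy_locus(list(c("SAT", "KS", "AT", "PT", "ACP", "TE"),
                          "PTase"))),
  list(cls = "meroterpenoid",
       l = toy_locus(list(c("KS", "AT", "DH", "ER", "KR", "ACP"), "TC"))),
  list(cls = "alkyl_citrate",
       l = toy_locus(list("CS", "FAS_alpha", "FAS_beta"),
                     core_classes = c(g001 = "alkyl_citrate"))),
  list(cls = "alkyl_citrate",
       l = toy_locus(list("CS", c("KS", "AT", "DH", "ER", "KR", "ACP")),
                     core_classes = c(g001 = "alkyl_citrate"))),
  list(cls = "PKS_NRPS",
       l = toy_locus(list(c("KS", "AT", "ACP", "C", "A", "T")))),
  list(cls = "NRPS_PKS",
       l = toy_locus(list(c("C", "A", "T", "KS", "AT", "ACP")))),
  list(cls = "NRPS",
       l = toy_locus(list(c("C", "A", "T", "C", "A", "T", "TE")),
                     core_classes = c(g001 = "NRPS_family"))),
  list(cls = "NRPS_like_ATTE",
       l = toy_locus(list(c("A", "T", "TE")),
                     core_classes = c(g001 = "NRPS_family"))),
  list(cls = "NRPS_like_ATR",
       l = toy_locus(list(c("A", "T", "R"), character()),
                     core_classes = c(g001 = "NRPS_family"))),
  list(cls = "excluded_primary_metabolism",
       l = toy_locus(list(c("A", "T", "R", "R")),
                     core_classes = c(g001 = "NRPS_family"))),
  list(cls = "excluded_primary_metabolism",
       l = toy_locus(list("LSS"), core_classes = c(g001 = "terpene"))),
  list(cls = "labdane_diterpene",
       l = toy_locus(list(c("TC", "GGPPS")),
                     core_classes = c(g001 = "terpene"))),
  list(cls = "diterpene_GGPPS",
       l = toy_locus(list("TC", "GGPPS"),
                     core_classes = c(g001 = "terpene"))),
  list(cls = "triterpene",
       l = toy_locus(list("SHC", character()),
                     core_classes = c(g001 = "terpene"))),
  list(cls = "triterpene",
       l = toy_locus(list("LSS", character()),
                     core_classes = c(g001 = "terpene"))),
  list(cls = "DMAT_alkaloid",
       l = toy_locus(list("DMAT", character()),
                     core_classes = c(g001 = "alkaloid_DMAT"))),
  list(cls = "terpene_mono_sesqui",
       l = toy_locus(list("TC", character()),
                     core_classes = c(g001 = "terpene"))),
  list(cls = "RiPP",
       l = toy_locus(list(character(), character()),
                     core_classes = c(g001 = "RiPP_precursor"))))
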