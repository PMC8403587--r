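# Biosynthetic class taxonomy: one class per locus, assigned by precedence
# rules over per-gene domain strings, locus gene content, and genome context.

#' The biosynthetic class vocabulary
#'
#' @return Character vector of all assignable classes.
#' @export
bgc_classes <- function() BGC_CLASSES

BGC_CLASSES <- c(
  "nrPKS", "hrPKS", "prPKS", "typeIII_PKS", "collaborative_PKS",
  "truncated_PKS", "disintegrated_PKS", "meroterpenoid", "alkyl_citrate",
  "PKS_NRPS", "NRPS_PKS", "NRPS", "NRPS_like_ATTE", "NRPS_like_ATR",
  "terpene_mono_sesqui", "diterpene_GGPPS", "labdane_diterpene", "triterpene",
  "DMAT_alkaloid", "RiPP", "excluded_primary_metabolism")

# PKS domain labels considered when judging completeness of split genes.
PKS_DOMAINS <- c("SAT", "KS", "AT", "PT", "ACP", "CMeT", "DH", "ER", "KR",
                 "TE", "R")

# Minimal definitions (consequential, documented in the vignette):
# a gene is a PKS iff its domain string contains KS and (AT or ACP);
# an NRPS module is an ordered C..A..T triple.
is_pks_string <- function(ds) "KS" %in% ds && ("AT" %in% ds || "ACP" %in% ds)

has_cat_module <- function(ds) {
  ci <- which(ds == "C")
  for (i in ci) {
    ai <- which(ds == "A" & seq_along(ds) > i)
    if (length(ai) && any(ds == "T" & seq_along(ds) > min(ai))) return(TRUE)
  }
  FALSE
}

# Number of complete C..A..T modules (greedy left-to-right).
count_cat_modules <- function(ds) {
  n <- 0L; i <- 1L
  while (i <= length(ds)) {
    ci <- which(ds == "C" & seq_along(ds) >= i)
    if (!length(ci)) break
    ai <- which(ds == "A" & seq_along(ds) > ci[1])
    if (!length(ai)) break
    ti <- which(ds == "T" & seq_along(ds) > ai[1])
    if (!length(ti)) break
    n <- n + 1L; i <- ti[1] + 1L
  }
  n
}

#' Classify a PKS domain string into its reduction subtype
#'
#' \itemize{
#'   \item \code{hrPKS}: KS, AT, DH, ER and KR all present (fully reducing
#'     loop);
#'   \item \code{truncated_PKS}: any of the essential KS / AT / ACP missing;
#'   \item \code{prPKS}: KR present without ER (or any incomplete reducing
#'     set);
#'   \item \code{nrPKS}: no reductive domain (KR, DH, ER); SAT/PT are
#'     supportive but not required.
#' }
#'
#' @param ds Character vector domain string (N to C) of a PKS gene.
#' @return One of \code{"nrPKS"}, \code{"hrPKS"}, \code{"prPKS"},
#'   \code{"truncated_PKS"}.
#' @export
classify_pks_subtype <- function(ds) {
  if (!is_pks_string(ds))
    stop("not a PKS domain string (needs KS and AT or ACP): ",
         paste(ds, collapse = "-"))
  reducing <- c("KR", "DH", "ER")
  if (all(c("KS", "AT", "DH", "ER", "KR") %in% ds)) return("hrPKS")
  if (!all(c("KS", "AT", "ACP") %in% ds)) return("truncated_PKS")
  if (!any(reducing %in% ds)) return("nrPKS")
  "prPKS"    # some reductive domains but not the full hr loop
}

#' Detect a disintegrated PKS within a locus
#'
#' TRUE iff two genes of the locus, each carrying only a partial PKS domain
#' set, lie within \code{max_gap_kb} of each other and together carry a
#' complete highly-reducing (KS, AT, DH, ER, KR, ACP) or non-reducing
#' (KS, AT, ACP) domain complement.
#'
#' @param locus A domain-annotated locus.
#' @param max_gap_kb Maximum nucleotide gap between the two genes, in kb.
#' @return Logical.
#' @export
detect_disintegrated <- function(locus, max_gap_kb = 10) {
  g <- locus$genes
  ds <- lapply(g$gene_id, function(id) gene_domain_string(locus, id))
  pks_content <- lapply(ds, intersect, x = PKS_DOMAINS)
  hr <- c("KS", "AT", "DH", "ER", "KR", "ACP"); nr <- c("KS", "AT", "ACP")
  complete <- function(s) all(hr %in% s) || all(nr %in% s)
  cand <- which(vapply(pks_content, length, 0L) > 0L)
  for (a in cand) for (b in cand) {
    if (b <= a) next
    if (complete(pks_content[[a]]) || complete(pks_content[[b]])) next
    gap_kb <- (max(g$start[a], g$start[b]) - min(g$end[a], g$end[b])) / 1000
    if (gap_kb > max_gap_kb) next
    u <- union(pks_content[[a]], pks_content[[b]])
    if ((complete(u)) &&
        length(setdiff(pks_content[[a]], pks_content[[b]])) > 0L &&
        length(setdiff(pks_content[[b]], pks_content[[a]])) > 0L)
      return(TRUE)
  }
  FALSE
}

#' Assign the biosynthetic class of a locus
#'
#' Applies the class precedence rules: exclusions (glycine-betaine-reductase
#' A-T-R-R architecture; single-gene primary-copy lanosterol synthase) first,
#' then RiPP, the gene-content-specific composite classes (alkyl citrate,
#' meroterpenoid), single-protein PKS/NRPS hybrids, collaborative and
#' disintegrated PKS, PKS reduction subtypes, type III PKS, NRPS and
#' NRPS-like, diterpene (bifunctional labdane-type before GGPPS-coupled),
#' triterpene, DMAT alkaloid, and finally mono/sesquiterpene. The first
#' matching rule wins; a fallback on the core template's target class
#' guarantees that every locus with a core receives exactly one class.
#'
#' @param locus A domain-annotated [new_bgc_locus()] (with
#'   \code{$core_classes} from detection).
#' @param genome_context Optional list; currently unused slots reserved for
#'   genome-level copy numbers.
#' @return The locus with \code{$class}, \code{$rule} (which rule fired),
#'   \code{$counted} (FALSE for excluded loci and unclustered single-gene
#'   A-T-R NRPS-like genes, which BGC counts conventionally omit), and
#'   \code{$nrps_modules} set.
#' @export
classify_locus <- function(locus, genome_context = NULL) {
  if (!length(locus$core_gene_ids)) stop("locus has no core gene")
  if (is.null(locus$domain_hits))
    stop("locus is not domain-annotated; run annotate_locus_domains()")
  g <- locus$genes
  ds_list <- stats::setNames(
    lapply(g$gene_id, function(id) gene_domain_string(locus, id)), g$gene_id)
  D <- unlist(ds_list, use.names = FALSE)
  core_cls <- locus$core_classes %||% character()
  pks_genes <- names(ds_list)[vapply(ds_list, is_pks_string, TRUE)]
  single_gene <- nrow(g) == 1L

  set_class <- function(class, rule) {
    locus$class <- class; locus$rule <- rule
    locus$counted <- !(class == "excluded_primary_metabolism" ||
                         (class == "NRPS_like_ATR" && single_gene))
    locus$nrps_modules <- max(vapply(ds_list, count_cat_modules, 0L), 0L)
    locus
  }

  # 1. exclusions: A-T-R-R architecture anywhere; primary-copy unclustered LSS
  atrr <- vapply(ds_list, function(ds) identical(ds, c("A", "T", "R", "R")),
                 TRUE)
  if (any(atrr))
    return(set_class("excluded_primary_metabolism", "A-T-R-R"))
  if (single_gene && identical(unique(D), "LSS"))
    return(set_class("excluded_primary_metabolism", "primary_LSS"))
  # 2. RiPP precursor similarity
  if (any(core_cls == "RiPP_precursor"))
    return(set_class("RiPP", "RiPP_precursor"))
  # 3. alkyl citrate: citrate synthase + dedicated FAS pair or an hrPKS-type
  #    partner gene
  if ("CS" %in% D &&
      (all(c("FAS_alpha", "FAS_beta") %in% D) || length(pks_genes)))
    return(set_class("alkyl_citrate", "CS+FAS_or_PKS"))
  # 4. meroterpenoid: PKS plus prenyltransferase and/or terpene cyclase
  if (length(pks_genes) && any(c("PTase", "TC") %in% D))
    return(set_class("meroterpenoid", "PKS+PTase/TC"))
  # 5. single-protein hybrids; PKS-NRPS iff the PKS half is N-terminal
  for (id in names(ds_list)) {
    ds <- ds_list[[id]]
    if (all(c("KS", "AT") %in% ds) && all(c("C", "A", "T") %in% ds)) {
      pks_pos <- min(which(ds %in% c("KS", "AT")))
      nrps_pos <- min(which(ds == "C"))
      # for minus-strand genes the stored string is already N->C
      return(set_class(if (pks_pos < nrps_pos) "PKS_NRPS" else "NRPS_PKS",
                       "single-protein_hybrid"))
    }
  }
  # 6. collaborative PKS
  if (length(pks_genes) >= 2L)
    return(set_class("collaborative_PKS", ">=2_PKS_genes"))
  # 7. disintegrated PKS
  if (detect_disintegrated(locus))
    return(set_class("disintegrated_PKS", "split_domain_complement"))
  # 8. PKS reduction subtype (or a truncated core with partial domains)
  if (length(pks_genes) == 1L)
    return(set_class(classify_pks_subtype(ds_list[[pks_genes]]),
                     "PKS_subtype"))
  if (any(core_cls == "typeI_PKS") &&
      any(vapply(ds_list, function(ds) any(ds %in% PKS_DOMAINS), TRUE)))
    return(set_class("truncated_PKS", "partial_PKS_core"))
  # 9. type III PKS by template similarity (no modular domain string)
  if (any(core_cls == "typeIII_PKS"))
    return(set_class("typeIII_PKS", "typeIII_template"))
  # 10. NRPS: at least one complete C-A-T module
  if (any(vapply(ds_list, has_cat_module, TRUE)))
    return(set_class("NRPS", "C-A-T_module"))
  # 11. NRPS-like
  for (ds in ds_list) {
    if (!"C" %in% ds && all(c("A", "T") %in% ds)) {
      if ("TE" %in% ds) return(set_class("NRPS_like_ATTE", "A-T-TE"))
      if ("R" %in% ds) return(set_class("NRPS_like_ATR", "A-T-R"))
    }
  }
  # 12. bifunctional labdane-type diterpene cyclase (TC + GGPPS on one gene)
  for (ds in ds_list)
    if (all(c("TC", "GGPPS") %in% ds))
      return(set_class("labdane_diterpene", "bifunctional_TC+GGPPS"))
  # 13. GGPPS-coupled diterpene (separate genes)
  if ("TC" %in% D && "GGPPS" %in% D)
    return(set_class("diterpene_GGPPS", "TC_gene+GGPPS_gene"))
  # 14. triterpene: clustered LSS or any squalene-hopene-type cyclase
  if ("SHC" %in% D || ("LSS" %in% D && !single_gene))
    return(set_class("triterpene", "LSS_clustered_or_SHC"))
  # 15. DMAT alkaloid
  if ("DMAT" %in% D || any(core_cls == "alkaloid_DMAT"))
    return(set_class("DMAT_alkaloid", "DMAT"))
  # 16. mono/sesquiterpene cyclase
  if ("TC" %in% D || any(core_cls == "terpene"))
    return(set_class("terpene_mono_sesqui", "TC"))
  # fallback: core template class decides (guarantees totality)
  fb <- c(typeI_PKS = "truncated_PKS", typeIII_PKS = "typeIII_PKS",
          NRPS_family = "NRPS_like_ATR", terpene = "terpene_mono_sesqui",
          alkyl_citrate = "alkyl_citrate", alkaloid_DMAT = "DMAT_alkaloid",
          RiPP_precursor = "RiPP")
  set_class(unname(fb[core_cls[1]]), "core_template_fallback")
}

#' Species-by-class count matrix
#'
#' Integer counts of classified loci per species and class.
#' Excluded (primary-metabolism) loci and unclustered single-gene A-T-R
#' NRPS-like genes are not counted.
#'
#' @param loci List of classified loci (any number of species).
#' @param species Optional character vector fixing row order.
#' @return Integer matrix species x class (all classes as columns, excluded
#'   class omitted).
#' @export
class_count_table <- function(loci, species = NULL) {
  classes <- setdiff(BGC_CLASSES, "excluded_primary_metabolism")
  if (is.null(species))
    species <- sort(unique(vapply(loci, `[[`, "", "species_id")))
  m <- matrix(0L, length(species), length(classes),
              dimnames = list(species, classes))
  for (l in loci) {
    if (is.na(l$class)) stop("unclassified locus ", l$bgc_id)
    if (!isTRUE(l$counted)) next
    if (!l$species_id %in% species) next
    m[l$species_id, l$class] <- m[l$species_id, l$class] + 1L
  }
  m
}
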