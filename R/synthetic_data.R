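# Synthetic multi-species cohorts with planted, ground-truth BGCs.
#
# The generator builds protein families top-down: for each planted family a
# founder sequence per domain/gene slot is derived from the bundled reference
# panel (at a fixed founder identity), and each member species receives a
# copy mutated to the family's identity target. Core genes are concatenations
# of domain segments, so the domain matcher recovers the planned domain
# string; accessory genes derive from labelled function-database entries, so
# the border caller recovers the planned roles; filler genes derive from
# housekeeping entries and are rejection-sampled against the template
# library, so they can never extend a border or fake a core. Every draw is
# seeded, making cohorts byte-reproducible.

#' Generate a random protein sequence
#'
#' I.i.d. draws over background amino-acid frequencies; reproducible under
#' the seed.
#'
#' @param length Positive sequence length.
#' @param seed Integer seed.
#' @return Protein string.
#' @export
make_protein <- function(length, seed) {
  if (length < 1L) stop("length must be >= 1")
  with_seed(seed, paste(sample(names(AA_BACKGROUND), length, replace = TRUE,
                               prob = AA_BACKGROUND), collapse = ""))
}

#' Mutate a protein to an exact target identity
#'
#' Applies point substitutions (no indels) at randomly chosen positions until
#' the exact-position identity to the input equals
#' \code{ceiling(target * length) / length}. Replacement residues are
#' BLOSUM-biased: likelier where the substitution score is higher, as in real
#' divergent homologs. Targets below 0.2 are rejected (alignment-based
#' recovery is not meaningful below the twilight zone).
#'
#' @param p Protein string.
#' @param target_identity Number in [0.2, 1].
#' @param seed Integer seed.
#' @return Mutated protein of the same length.
#' @export
mutate_to_identity <- function(p, target_identity, seed) {
  check_protein(p)
  if (target_identity < 0.2 || target_identity > 1)
    stop("target_identity must be in [0.2, 1]")
  n <- nchar(p)
  keep <- as.integer(ceiling(target_identity * n))
  n_mut <- n - keep
  if (n_mut == 0L) return(p)
  m <- blosum62_matrix()
  with_seed(seed, {
    pos <- sample.int(n, n_mut)
    letters <- strsplit(p, "")[[1]]
    for (i in pos) {
      a <- letters[i]
      others <- setdiff(AA20, a)
      w <- exp(m[a, others] / 2) * AA_BACKGROUND[others]
      letters[i] <- sample(others, 1L, prob = w)
    }
    paste(letters, collapse = "")
  })
}

#' Specify a planted BGC family
#'
#' @param family_id Unique family identifier.
#' @param class Intended biosynthetic class of unmodified members.
#' @param genes List of gene plans; each plan is a list with \code{name},
#'   \code{kind} (\code{"domains"}: protein concatenated from domain-panel
#'   segments; \code{"function"}: derived from a function-database entry;
#'   \code{"template"}: derived from a core template), \code{role} (truth
#'   label), and \code{domains} / \code{ref} / \code{template} as
#'   appropriate.
#' @param species Character vector of member species ids.
#' @param identity Within-family protein identity target (member to family
#'   archetype), in [0.5, 1].
#' @param founder_identity Identity of the family archetype to the bundled
#'   reference it derives from (default 0.55; controls between-family
#'   divergence).
#' @param rearrange_in Species whose member has its gene order shuffled
#'   (NULL for none).
#' @param truncate_in List \code{(species, gene, drop)}: member gene losing
#'   the named domains.
#' @param disintegrate_in List \code{(species, gene, split_after)}: member
#'   core split into two adjacent genes after the given domain index.
#' @param class_overrides Named character vector species -> class for variant
#'   members whose intended class differs.
#' @return Object of class \code{"family_spec"}.
#' @export
family_spec <- function(family_id, class, genes, species, identity,
                        founder_identity = 0.55, rearrange_in = NULL,
                        truncate_in = NULL, disintegrate_in = NULL,
                        class_overrides = NULL) {
  stopifnot(identity >= 0.5, identity <= 1, length(species) >= 1L,
            class %in% BGC_CLASSES)
  has_core <- any(vapply(genes, function(g) g$role == "core", TRUE))
  if (!has_core) stop("family plan needs at least one core gene")
  structure(list(family_id = family_id, class = class, genes = genes,
                 species = species, identity = identity,
                 founder_identity = founder_identity,
                 rearrange_in = rearrange_in, truncate_in = truncate_in,
                 disintegrate_in = disintegrate_in,
                 class_overrides = class_overrides),
            class = "family_spec")
}

# Build the founder (archetype) protein pieces for one gene plan.
family_founder_gene <- function(plan, spec, seed, panel, fdb, templates) {
  fid <- spec$family_id
  if (plan$kind == "domains") {
    lapply(seq_along(plan$domains), function(k) {
      d <- plan$domains[k]
      if (!d %in% names(panel)) stop("unknown domain ", d)
      mutate_to_identity(panel[[d]], spec$founder_identity,
                         derive_seed(seed, paste(fid, plan$name, d, k)))
    })
  } else if (plan$kind == "function") {
    ref <- fdb$protein[fdb$id == plan$ref]
    if (!length(ref)) stop("unknown function-db ref ", plan$ref)
    list(mutate_to_identity(ref, max(spec$founder_identity, 0.8),
                            derive_seed(seed, paste(fid, plan$name))))
  } else if (plan$kind == "template") {
    tpl <- templates$protein[templates$accession == plan$template]
    if (!length(tpl)) stop("unknown template ", plan$template)
    list(mutate_to_identity(tpl, max(spec$founder_identity, 0.8),
                            derive_seed(seed, paste(fid, plan$name))))
  } else stop("unknown gene plan kind ", plan$kind)
}

#' Plant one family: per-species gene lists plus truth
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed.
#' @param panel,fdb,templates Bundled references (defaults used when NULL).
#' @return Named list (by species) of member descriptions; each member is a
#'   list with \code{genes} (data.frame name, protein, role, domains) and
#'   \code{class} (intended class of that member).
#' @export
plant_family <- function(spec, seed, panel = NULL, fdb = NULL,
                         templates = NULL) {
  if (is.null(panel)) panel <- domain_panel()
  if (is.null(fdb)) fdb <- function_db()
  if (is.null(templates)) templates <- core_templates()
  founders <- lapply(spec$genes, family_founder_gene, spec = spec,
                     seed = seed, panel = panel, fdb = fdb,
                     templates = templates)
  out <- list()
  for (sp in spec$species) {
    genes <- list()
    for (gi in seq_along(spec$genes)) {
      plan <- spec$genes[[gi]]
      segs <- founders[[gi]]
      doms <- if (plan$kind == "domains") plan$domains else character()
      # member-level variants
      if (!is.null(spec$truncate_in) &&
          identical(spec$truncate_in$species, sp) &&
          identical(spec$truncate_in$gene, plan$name)) {
        keep <- !doms %in% spec$truncate_in$drop
        segs <- segs[keep]; doms <- doms[keep]
      }
      # members diverge independently from the archetype; mutating each at
      # sqrt(identity) makes the *pairwise* member identity ~= the target
      mut <- function(piece, k, attempt = 0L)
        mutate_to_identity(piece, sqrt(spec$identity),
                           derive_seed(seed, paste(spec$family_id, sp,
                                                   plan$name, k, attempt)))
      pieces <- mapply(mut, segs, seq_along(segs))
      if (plan$role != "core") {
        # accessory genes must never chance-hit the template library, or a
        # spurious core would corrupt planted borders and classes; redraw
        # the member mutation until the protein is template-clean
        member <- paste(pieces, collapse = "")
        attempt <- 0L
        while (hits_templates(member, templates, default_scheme())) {
          attempt <- attempt + 1L
          if (attempt > 50L) stop("accessory rejection sampling failed")
          pieces <- mapply(mut, segs, seq_along(segs),
                           MoreArgs = list(attempt = attempt))
          member <- paste(pieces, collapse = "")
        }
      }
      if (!is.null(spec$disintegrate_in) &&
          identical(spec$disintegrate_in$species, sp) &&
          identical(spec$disintegrate_in$gene, plan$name)) {
        s <- spec$disintegrate_in$split_after
        genes[[length(genes) + 1L]] <- list(
          name = paste0(plan$name, "a"),
          protein = paste(pieces[seq_len(s)], collapse = ""),
          role = plan$role, domains = doms[seq_len(s)])
        genes[[length(genes) + 1L]] <- list(
          name = paste0(plan$name, "b"),
          protein = paste(pieces[-seq_len(s)], collapse = ""),
          role = plan$role, domains = doms[-seq_len(s)])
      } else {
        genes[[length(genes) + 1L]] <- list(
          name = plan$name, protein = paste(pieces, collapse = ""),
          role = plan$role, domains = doms)
      }
    }
    if (identical(spec$rearrange_in, sp))
      genes <- with_seed(derive_seed(seed, paste(spec$family_id, sp, "shuf")),
                         sample(genes))
    cls <- spec$class
    if (!is.null(spec$class_overrides) && sp %in% names(spec$class_overrides))
      cls <- spec$class_overrides[[sp]]
    out[[sp]] <- list(genes = genes, class = cls)
  }
  out
}

# Fixed codon per amino acid for deterministic back-translation.
CODON_OF <- c(A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "TTG", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

back_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

random_nt <- function(length, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, TRUE),
                        collapse = ""))
}

# Would this protein hit any template at E <= max_evalue under a
# conservatively small database length? Used to rejection-sample filler and
# accessory genes so planted borders and classes are unambiguous. The floor
# understates any realistic proteome size, which makes the E-value smaller
# than the pipeline will ever compute -- i.e. rejection errs on the strict
# side.
hits_templates <- function(protein, templates, scheme, max_evalue = 1e-1,
                           db_len_floor = 1e3) {
  for (ti in seq_len(nrow(templates))) {
    sc <- local_scores(protein, templates$protein[ti], scheme)
    if (sc > 0 &&
        evalue(sc, nchar(templates$protein[ti]), db_len_floor, scheme) <=
          max_evalue)
      return(TRUE)
  }
  FALSE
}

#' The default planted-cohort design
#'
#' Eight species; six multi-species families (identity targets 0.70-0.90)
#' covering hrPKS, nrPKS, NRPS, meroterpenoid, collaborative PKS and
#' A-T-TE NRPS-like chemistry, with one rearranged member, one
#' truncated-variant member and one disintegrated-variant member; ten
#' species-private singleton BGCs spanning the remaining classes; plus
#' planted primary-metabolism decoys (a glycine-betaine-reductase-like
#' A-T-R-R gene and one unclustered lanosterol synthase per genome) that the
#' classifier must exclude. Two families span all eight species (the designed
#' conserved-family count).
#'
#' @return List with \code{n_species}, \code{families},
#'   \code{filler_per_contig}.
#' @export
default_cohort_spec <- function() {
  sp <- sprintf("sp%02d", 1:8)
  dom <- function(name, domains) list(name = name, kind = "domains",
                                      domains = domains, role = "core")
  fn <- function(name, ref, role) list(name = name, kind = "function",
                                       ref = ref, role = role)
  tpl <- function(name, template) list(name = name, kind = "template",
                                       template = template, role = "core")
  families <- list(
    family_spec("fam_hr", "hrPKS",
      genes = list(dom("pks", c("KS", "AT", "DH", "CMeT", "ER", "KR", "ACP")),
                   fn("ox1", "tail_p450", "tailoring"),
                   fn("mfs", "trans_mfs", "transport")),
      species = sp, identity = 0.85,
      disintegrate_in = list(species = "sp04", gene = "pks", split_after = 5L),
      class_overrides = c(sp04 = "disintegrated_PKS")),
    family_spec("fam_nr", "nrPKS",
      genes = list(dom("pks", c("SAT", "KS", "AT", "PT", "ACP", "TE")),
                   fn("fmo", "tail_fmo", "tailoring"),
                   fn("reg", "reg_zn2cys6", "regulatory")),
      species = sp, identity = 0.80,
      truncate_in = list(species = "sp07", gene = "pks", drop = "ACP"),
      class_overrides = c(sp07 = "truncated_PKS")),
    family_spec("fam_nrps", "NRPS",
      genes = list(dom("nrps", c("C", "A", "T", "C", "A", "T", "TE")),
                   fn("abc", "trans_abc", "transport")),
      species = sp[1:5], identity = 0.90),
    family_spec("fam_mero", "meroterpenoid",
      genes = list(dom("pks", c("SAT", "KS", "AT", "PT", "ACP", "TE")),
                   dom("pt", "PTase"), dom("cyc", "TC"),
                   fn("ox1", "tail_p450", "tailoring")),
      species = sp[2:6], identity = 0.75),
    family_spec("fam_collab", "collaborative_PKS",
      genes = list(dom("pks1", c("KS", "AT", "DH", "ER", "KR", "ACP")),
                   dom("pks2", c("SAT", "KS", "AT", "PT", "ACP")),
                   fn("mt", "tail_omt", "tailoring")),
      species = sp[3:8], identity = 0.70, rearrange_in = "sp06"),
    family_spec("fam_atte", "NRPS_like_ATTE",
      genes = list(dom("atte", c("A", "T", "TE")),
                   fn("ox2", "tail_fmo", "tailoring")),
      species = sp[2:8], identity = 0.82),
    # --- species-private singleton BGCs -------------------------------
    family_spec("sing_terp", "terpene_mono_sesqui",
      genes = list(dom("tc", "TC"), fn("ox1", "tail_p450", "tailoring")),
      species = "sp01", identity = 0.9),
    family_spec("sing_dmat", "DMAT_alkaloid",
      genes = list(dom("dmat", "DMAT"), fn("ox2", "tail_fmo", "tailoring"),
                   fn("mt", "tail_omt", "tailoring")),
      species = "sp02", identity = 0.9),
    family_spec("sing_atr", "NRPS_like_ATR",
      genes = list(dom("atr", c("A", "T", "R")),
                   fn("ox1", "tail_p450", "tailoring")),
      species = "sp03", identity = 0.9),
    # the two diterpene singletons share a domain-type set; extra founder
    # divergence and opposite gene orders keep them distinct families
    family_spec("sing_labdane", "labdane_diterpene",
      genes = list(dom("cps", c("TC", "GGPPS")),
                   fn("mfs", "trans_mfs", "transport")),
      species = "sp04", identity = 0.9, founder_identity = 0.5),
    family_spec("sing_ggpps", "diterpene_GGPPS",
      genes = list(dom("ggs", "GGPPS"), dom("tc", "TC"),
                   fn("ox1", "tail_p450", "tailoring")),
      species = "sp05", identity = 0.9, founder_identity = 0.5),
    family_spec("sing_tri", "triterpene",
      genes = list(dom("shc", "SHC"), fn("ox2", "tail_fmo", "tailoring")),
      species = "sp06", identity = 0.9),
    family_spec("sing_ac", "alkyl_citrate",
      genes = list(dom("cs", "CS"), dom("fasA", "FAS_alpha"),
                   dom("fasB", "FAS_beta"),
                   fn("ox2", "tail_fmo", "tailoring")),
      species = "sp07", identity = 0.9),
    family_spec("sing_hybrid", "PKS_NRPS",
      genes = list(dom("hyb", c("KS", "AT", "ACP", "C", "A", "T")),
                   fn("reg", "reg_zn2cys6", "regulatory")),
      species = "sp08", identity = 0.9),
    family_spec("sing_t3", "typeIII_PKS",
      genes = list(tpl("chs", "XP_960427")),
      species = "sp01", identity = 0.85),
    family_spec("sing_ripp", "RiPP",
      genes = list(tpl("prec", "AMR44282"),
                   fn("ox1", "tail_p450", "tailoring"),
                   fn("mt", "tail_omt", "tailoring")),
      species = "sp02", identity = 0.85),
    # --- primary-metabolism decoys (excluded from counts) -------------
    family_spec("dec_atrr", "excluded_primary_metabolism",
      genes = list(dom("gbr", c("A", "T", "R", "R"))),
      species = "sp01", identity = 0.9),
    family_spec("dec_lss", "excluded_primary_metabolism",
      genes = list(dom("erg7", "LSS")),
      species = sp, identity = 0.9))
  list(n_species = 8L, families = families, filler_per_contig = 4L)
}

#' Generate a synthetic cohort of annotated genomes with planted BGCs
#'
#' Each species receives two contigs in which planted loci are separated (and
#' flanked) by runs of \code{filler_per_contig} housekeeping-derived filler
#' genes -- more than the three-gene border run, so planted borders are
#' unambiguous. Filler and accessory proteins are rejection-sampled against
#' the template library so they can never produce a chance core hit. Truth
#' tables (gene roles, locus extents and classes, the expected GCF partition
#' at the design cutoff, and the expected class-count matrix) are returned
#' alongside the genomes.
#'
#' @param n_species Number of species (>= max species index used by
#'   families).
#' @param families List of [family_spec()] objects.
#' @param filler_per_contig Filler genes between and around planted loci
#'   (>= 4 keeps borders deterministic).
#' @param seed Integer master seed.
#' @param panel,fdb,templates Bundled references (defaults when NULL).
#' @return List of class \code{"bgc_cohort"}: \code{genomes} (named list of
#'   [new_genome()]), \code{truth} (list: \code{gene_roles}, \code{loci},
#'   \code{gcf_partition}, \code{class_matrix}, \code{conserved_families}),
#'   and \code{spec}.
#' @export
make_cohort <- function(n_species = 8L, families = default_cohort_spec()$families,
                        filler_per_contig = 4L, seed = 1L,
                        panel = NULL, fdb = NULL, templates = NULL) {
  if (is.null(panel)) panel <- domain_panel()
  if (is.null(fdb)) fdb <- function_db()
  if (is.null(templates)) templates <- core_templates()
  scheme <- default_scheme()
  species <- sprintf("sp%02d", seq_len(n_species))
  for (f in families)
    if (!all(f$species %in% species))
      stop("family ", f$family_id, " references unknown species")
  if (filler_per_contig < 4L)
    warning("filler_per_contig < 4 can fuse adjacent planted loci")

  planted <- lapply(families, function(f)
    plant_family(f, derive_seed(seed, f$family_id), panel, fdb, templates))
  names(planted) <- vapply(families, `[[`, "", "family_id")

  hk <- fdb[fdb$label == "housekeeping", ]
  make_filler <- function(sp, k) {
    attempt <- 0L
    repeat {
      s <- derive_seed(seed, paste("filler", sp, k, attempt))
      ref <- hk$protein[[with_seed(s, sample.int(nrow(hk), 1L))]]
      p <- mutate_to_identity(ref, 0.7, derive_seed(s, "mut"))
      if (!hits_templates(p, templates, scheme)) return(p)
      attempt <- attempt + 1L
      if (attempt > 25L) stop("filler rejection sampling failed")
    }
  }

  genomes <- list(); roles_tab <- list(); loci_tab <- list()
  for (sp in species) {
    # collect this species' planted loci (deterministic family order)
    loci <- list()
    for (fid in names(planted)) {
      if (!sp %in% names(planted[[fid]])) next
      member <- planted[[fid]][[sp]]
      loci[[length(loci) + 1L]] <- c(member, list(family_id = fid))
    }
    # distribute over two contigs, round-robin
    contig_of <- rep_len(1:2, length(loci))
    gene_rows <- list(); contig_nt <- c("", "")
    gene_counter <- 0L
    emit_gene <- function(contig, protein, product, role, strand) {
      gene_counter <<- gene_counter + 1L
      gid <- sprintf("%s_g%03d", sp, gene_counter)
      cds <- back_translate(protein)
      spacer <- random_nt(with_seed(derive_seed(seed, paste(sp, gid, "sp")),
                                    sample(100:200, 1L)),
                          derive_seed(seed, paste(sp, gid, "nt")))
      start <- nchar(contig_nt[contig]) + nchar(spacer) + 1L
      placed <- if (strand == "-") revcomp(cds) else cds
      contig_nt[contig] <<- paste0(contig_nt[contig], spacer, placed)
      gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
        gene_id = gid, contig_id = sprintf("%s_c%d", sp, contig),
        start = start, end = start + nchar(cds) - 1L, strand = strand,
        protein = protein, product = product, stringsAsFactors = FALSE)
      gid
    }
    filler_counter <- 0L
    emit_fillers <- function(contig, n) {
      for (i in seq_len(n)) {
        filler_counter <<- filler_counter + 1L
        p <- make_filler(sp, filler_counter)
        strand <- with_seed(derive_seed(seed, paste(sp, "fs", filler_counter)),
                            sample(c("+", "-"), 1L))
        gid <- emit_gene(contig, p, "hypothetical protein", "unrelated", strand)
        roles_tab[[length(roles_tab) + 1L]] <<- data.frame(
          species_id = sp, gene_id = gid, role = "unrelated")
      }
    }
    for (contig in 1:2) {
      emit_fillers(contig, filler_per_contig)
      for (li in which(contig_of == contig)) {
        loc <- loci[[li]]
        member_gids <- character()
        for (gk in loc$genes) {
          # domain-bearing genes stay on +, so within-family linear domain
          # sequences (and hence AI) are invariant across members
          strand <- if (length(gk$domains)) "+" else
            with_seed(derive_seed(seed, paste(sp, loc$family_id, gk$name, "st")),
                      sample(c("+", "-"), 1L))
          gid <- emit_gene(contig, gk$protein,
                           paste(loc$family_id, gk$name), gk$role, strand)
          member_gids <- c(member_gids, gid)
          roles_tab[[length(roles_tab) + 1L]] <- data.frame(
            species_id = sp, gene_id = gid, role = gk$role)
        }
        counted <- !(loc$class == "excluded_primary_metabolism" ||
                       (loc$class == "NRPS_like_ATR" &&
                          length(loc$genes) == 1L))
        loci_tab[[length(loci_tab) + 1L]] <- data.frame(
          species_id = sp, contig_id = sprintf("%s_c%d", sp, contig),
          locus_id = paste(sp, loc$family_id, sep = "|"),
          family_id = loc$family_id, class = loc$class, counted = counted,
          first_gene = member_gids[1],
          last_gene = member_gids[length(member_gids)],
          gene_ids = paste(member_gids, collapse = ","),
          stringsAsFactors = FALSE)
        emit_fillers(contig, filler_per_contig)
      }
      # a contig with no loci still gets its filler flank only once
    }
    genes <- do.call(rbind, gene_rows)
    names(contig_nt) <- sprintf("%s_c%d", sp, 1:2)
    genomes[[sp]] <- new_genome(sp, genes, contigs = contig_nt,
                                metadata = list(synthetic = TRUE, seed = seed))
  }
  roles <- do.call(rbind, roles_tab)
  loci_df <- if (length(loci_tab)) do.call(rbind, loci_tab) else
    data.frame(species_id = character(), contig_id = character(),
               locus_id = character(), family_id = character(),
               class = character(), counted = logical(),
               first_gene = character(), last_gene = character(),
               gene_ids = character())
  counted_loci <- loci_df[loci_df$counted, , drop = FALSE]
  fam_sizes <- table(counted_loci$family_id)
  class_matrix <- {
    classes <- setdiff(BGC_CLASSES, "excluded_primary_metabolism")
    m <- matrix(0L, length(species), length(classes),
                dimnames = list(species, classes))
    for (i in seq_len(nrow(counted_loci)))
      m[counted_loci$species_id[i], counted_loci$class[i]] <-
        m[counted_loci$species_id[i], counted_loci$class[i]] + 1L
    m
  }
  conserved <- sum(vapply(split(counted_loci$species_id, counted_loci$family_id),
                          function(s) all(species %in% s), TRUE))
  structure(list(
    genomes = genomes,
    truth = list(
      gene_roles = roles, loci = loci_df,
      gcf_partition = counted_loci[, c("locus_id", "family_id")],
      class_matrix = class_matrix,
      conserved_families = conserved,
      n_singletons = sum(fam_sizes == 1L),
      design_cutoff = 0.4),
    spec = list(n_species = n_species, filler_per_contig = filler_per_contig,
                seed = seed,
                families = vapply(families, `[[`, "", "family_id"))),
    class = "bgc_cohort")
}

#' @export
print.bgc_cohort <- function(x, ...) {
  cat(sprintf("<bgc_cohort> %d species, %d planted loci (%d counted), seed %d\n",
              length(x$genomes), nrow(x$truth$loci),
              sum(x$truth$loci$counted), x$spec$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per species: GenBank (\code{.gbk}), GFF3 (\code{.gff3}) and genomic FASTA
#' (\code{.fna}); plus truth TSVs (\code{gene_roles.tsv}, \code{loci.tsv},
#' \code{gcf_truth.tsv}, \code{class_matrix.tsv}) and a \code{cohort.yaml}
#' spec summary.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(cohort$genomes)) {
    g <- cohort$genomes[[sp]]
    write_genbank(g, file.path(dir, paste0(sp, ".gbk")))
    write_gff_fasta(g, file.path(dir, paste0(sp, ".gff3")),
                    file.path(dir, paste0(sp, ".fna")))
  }
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(cohort$truth$gene_roles, "gene_roles.tsv")
  tsv(cohort$truth$loci, "loci.tsv")
  tsv(cohort$truth$gcf_partition, "gcf_truth.tsv")
  cm <- as.data.frame(cohort$truth$class_matrix)
  cm <- cbind(species_id = rownames(cm), cm)
  tsv(cm, "class_matrix.tsv")
  yaml::write_yaml(cohort$spec, file.path(dir, "cohort.yaml"))
  invisible(dir)
}
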