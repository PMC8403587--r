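# Biosynthetic core-gene detection and domain-string annotation.
#
# Core genes are found by Smith-Waterman search of every gene product against
# a bundled template library of characterised core enzymes (type I / type III
# PKS, NRPS A-domain, terpene cyclases, citrate synthase, DMAT, RiPP
# precursors), keeping the best hit per gene at E <= 1e-1. Domain strings are
# parsed with a greedy non-overlapping match against one bundled reference
# segment per domain label.

# Controlled vocabulary of biosynthetic domain labels.
DOMAIN_VOCAB <- c(
  "SAT", "KS", "AT", "PT", "ACP", "CMeT", "DH", "ER", "KR", "TE", "R",
  "C", "A", "T", "E",
  "GGPPS", "TC", "CS", "FAS_alpha", "FAS_beta", "PTase", "LSS", "SHC",
  "DMAT", "GT", "CDPS")

#' Controlled vocabulary of biosynthetic domain labels
#'
#' PKS domains (SAT, KS, AT, PT, ACP, CMeT, DH, ER, KR, TE, R), NRPS domains
#' (C, A, T, E), and standalone core/accessory enzyme types (GGPPS, terpene
#' cyclase TC, citrate synthase CS, fatty-acid synthase subunits, UbiA-type
#' prenyltransferase PTase, lanosterol synthase LSS, squalene-hopene cyclase
#' SHC, tryptophan dimethylallyltransferase DMAT, glycosyltransferase GT,
#' cyclodipeptide synthase CDPS).
#'
#' @return Character vector of valid domain names.
#' @export
domain_vocab <- function() DOMAIN_VOCAB

# Valid core-template target classes.
TARGET_CLASSES <- c("typeI_PKS", "typeIII_PKS", "NRPS_family", "terpene",
                    "alkyl_citrate", "alkaloid_DMAT", "RiPP_precursor")

# ---- bundled reference data --------------------------------------------

#' Bundled core-enzyme template library
#'
#' Seventeen template proteins spanning the searched pathway types (type I and
#' type III PKS, NRPS, mono-/sesqui-/di-/triterpene cyclases, citrate
#' synthase, tryptophan DMAT, RiPP precursor peptides), with the accession,
#' protein name, source organism, and targeted class of each. The bundled
#' sequences are deterministic synthetic stand-ins for the real accessions
#' (built from the package's domain reference panel), suitable for the
#' synthetic cohorts the package tests itself on.
#'
#' @param fasta,manifest Optional paths to an alternative template library
#'   (FASTA + TSV manifest with columns accession, name, organism,
#'   target_class).
#' @return data.frame with columns \code{accession}, \code{name},
#'   \code{organism}, \code{target_class}, \code{protein}.
#' @export
core_templates <- function(fasta = NULL, manifest = NULL) {
  if (is.null(fasta)) fasta <- bgcfam_extdata("core_templates_synthetic.faa")
  if (is.null(manifest)) manifest <- bgcfam_extdata("core_templates_manifest.tsv")
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  seqs <- read_fasta_chr(fasta)
  if (!all(man$accession %in% names(seqs)))
    stop("template manifest and FASTA disagree")
  bad <- setdiff(man$target_class, TARGET_CLASSES)
  if (length(bad)) stop("unknown target_class: ", paste(bad, collapse = ", "))
  man$protein <- unname(seqs[man$accession])
  man
}

#' Bundled per-domain reference sequence panel
#'
#' One representative sequence per [domain_vocab()] label, used by
#' [assign_domains()] to parse domain strings. Synthetic stand-ins generated
#' deterministically; see the package vignette.
#'
#' @param fasta Optional alternative panel FASTA (headers = domain labels).
#' @return Named character vector (names are domain labels).
#' @export
domain_panel <- function(fasta = NULL) {
  if (is.null(fasta)) fasta <- bgcfam_extdata("domain_panel_synthetic.faa")
  seqs <- read_fasta_chr(fasta)
  missing <- setdiff(DOMAIN_VOCAB, names(seqs))
  if (length(missing))
    stop("domain panel lacks reference(s) for: ", paste(missing, collapse = ", "))
  seqs[DOMAIN_VOCAB]
}

#' Bundled function database of labelled reference proteins
#'
#' Labelled reference proteins (core / tailoring / regulatory / transport /
#' resistance / housekeeping) used for neighbour function calls when growing
#' BGC borders; a synthetic stand-in for a curated protein database.
#'
#' @param fasta,manifest Optional alternative database (FASTA + TSV with
#'   columns id, label, description).
#' @return data.frame of class \code{"function_db"} with columns \code{id},
#'   \code{label}, \code{description}, \code{protein}.
#' @export
function_db <- function(fasta = NULL, manifest = NULL) {
  if (is.null(fasta)) fasta <- bgcfam_extdata("function_db_synthetic.faa")
  if (is.null(manifest)) manifest <- bgcfam_extdata("function_db_manifest.tsv")
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  bad <- setdiff(man$label, FUNCTION_LABELS)
  if (length(bad)) stop("unknown function label: ", paste(bad, collapse = ", "))
  seqs <- read_fasta_chr(fasta)
  if (!all(man$id %in% names(seqs))) stop("function DB manifest and FASTA disagree")
  man$protein <- unname(seqs[man$id])
  class(man) <- c("function_db", "data.frame")
  man
}

FUNCTION_LABELS <- c("core", "tailoring", "regulatory", "transport",
                     "resistance", "housekeeping")

# ---- core scanning ------------------------------------------------------

#' Scan a genome for biosynthetic core genes
#'
#' Aligns every gene product against every template; a gene with at least one
#' hit at \code{E <= max_evalue} yields exactly one core hit (the
#' highest-scoring template; ties broken by lower E-value then lexicographic
#' accession). E-values use the total proteome length as database size, so
#' the chance-hit rate matches a whole-proteome search.
#'
#' @param genome A [new_genome()] object.
#' @param templates Template library, as from [core_templates()].
#' @param max_evalue Maximum E-value (default 1e-1).
#' @param scheme A [scoring_scheme()].
#' @return data.frame with columns \code{gene_id}, \code{template_accession},
#'   \code{evalue}, \code{score}, \code{target_class}, sorted by contig and
#'   start.
#' @export
scan_cores <- function(genome, templates = core_templates(),
                       max_evalue = 1e-1, scheme = NULL) {
  stopifnot(inherits(genome, "bgc_genome"))
  if (!nrow(templates)) stop("templates must be non-empty")
  scheme <- as_scheme(scheme)
  g <- genome$genes
  empty <- data.frame(gene_id = character(), template_accession = character(),
                      evalue = numeric(), score = numeric(),
                      target_class = character())
  if (!nrow(g)) return(empty)
  db_len <- sum(nchar(g$protein))
  best <- data.frame(gene_id = g$gene_id, template_accession = NA_character_,
                     evalue = NA_real_, score = -Inf,
                     target_class = NA_character_)
  ord_t <- order(templates$accession)   # template order never matters
  for (ti in ord_t) {
    sc <- local_scores(g$protein, templates$protein[ti], scheme)
    ev <- evalue(pmax(sc, 0), nchar(templates$protein[ti]), db_len, scheme)
    hit <- which(ev <= max_evalue & sc > 0)
    for (i in hit) {
      better <- sc[i] > best$score[i] ||
        (sc[i] == best$score[i] && ev[i] < best$evalue[i]) ||
        (sc[i] == best$score[i] && ev[i] == best$evalue[i] &&
           templates$accession[ti] < best$template_accession[i])
      if (better) {
        best$template_accession[i] <- templates$accession[ti]
        best$evalue[i] <- ev[i]; best$score[i] <- sc[i]
        best$target_class[i] <- templates$target_class[ti]
      }
    }
  }
  out <- best[!is.na(best$template_accession), , drop = FALSE]
  key <- match(out$gene_id, g$gene_id)
  out <- out[order(g$contig_id[key], g$start[key]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- domain assignment --------------------------------------------------

# Self-score of a sequence: sum of diagonal substitution scores.
self_score <- function(p, scheme) {
  letters <- strsplit(p, "")[[1]]
  sum(scheme$matrix[cbind(letters, letters)])
}

#' Parse the biosynthetic domain string of one protein
#'
#' Greedy non-overlapping selection of local-alignment hits of the domain
#' reference panel against the protein: the highest-scoring candidate (at
#' score >= \code{min_score_frac} of the reference's self-alignment score) is
#' accepted, the covered interval is masked, and remaining references are
#' re-fitted to the free intervals until no candidate passes. If a
#' pre-computed domain annotation table covers the gene, the table takes
#' precedence over the built-in matcher.
#'
#' @param protein Protein sequence (or a one-row gene data.frame).
#' @param refs Reference panel from [domain_panel()].
#' @param min_score_frac Acceptance threshold as a fraction of the reference
#'   self-score (default 0.3).
#' @param gene_id Gene identifier recorded in the result.
#' @param table Optional \code{domain_annotation_table}; its rows for this
#'   gene, if any, replace the matcher's output.
#' @param scheme A [scoring_scheme()].
#' @return data.frame with columns \code{gene_id}, \code{domain},
#'   \code{start}, \code{end}, \code{score}, \code{seq}, ordered N- to
#'   C-terminal. Zero rows when no domain is recognised.
#' @export
assign_domains <- function(protein, refs = domain_panel(),
                           min_score_frac = 0.3, gene_id = "gene",
                           table = NULL, scheme = NULL) {
  if (is.data.frame(protein)) {
    gene_id <- protein$gene_id[1]
    protein <- protein$protein[1]
  }
  check_protein(protein)
  scheme <- as_scheme(scheme)
  empty <- data.frame(gene_id = character(), domain = character(),
                      start = integer(), end = integer(), score = numeric(),
                      seq = character())
  if (!is.null(table) && gene_id %in% table$gene_id) {
    rows <- table[table$gene_id == gene_id, , drop = FALSE]
    out <- data.frame(gene_id = rows$gene_id, domain = rows$domain,
                      start = as.integer(rows$start), end = as.integer(rows$end),
                      score = as.numeric(rows$score),
                      seq = substring(protein, rows$start, rows$end))
    return(out[order(out$start), , drop = FALSE])
  }
  if (length(refs) == 0L) stop("domain reference panel is empty")
  thr <- vapply(refs, function(r) min_score_frac * self_score(r, scheme), 0)
  # prefilter on the whole protein: references that cannot pass anywhere
  pre <- local_scores(refs, protein, scheme)
  cand_refs <- names(refs)[pre >= thr]
  if (!length(cand_refs)) return(empty)
  free <- list(c(1L, nchar(protein)))
  hits <- empty
  # best hit of one reference over the free intervals
  best_in_free <- function(d) {
    bst <- NULL
    for (iv in free) {
      if (iv[2] - iv[1] + 1L < 15L) next
      seg <- substr(protein, iv[1], iv[2])
      r <- local_align(refs[[d]], seg, scheme)
      if (r$score >= thr[[d]] &&
          (is.null(bst) || r$score > bst$score)) {
        bst <- list(score = r$score,
                    start = iv[1] + r$subject_range[1] - 1L,
                    end = iv[1] + r$subject_range[2] - 1L)
      }
    }
    bst
  }
  pending <- cand_refs
  cache <- stats::setNames(vector("list", length(pending)), pending)
  for (d in pending) cache[[d]] <- best_in_free(d)
  repeat {
    ok <- !vapply(cache, is.null, TRUE)
    if (!any(ok)) break
    scores <- vapply(cache[ok], `[[`, 0, "score")
    d <- names(scores)[order(-scores, names(scores))][1]
    h <- cache[[d]]
    hits <- rbind(hits, data.frame(
      gene_id = gene_id, domain = d, start = h$start, end = h$end,
      score = h$score, seq = substr(protein, h$start, h$end)))
    # carve the accepted interval out of the free set
    newfree <- list()
    for (iv in free) {
      if (h$end < iv[1] || h$start > iv[2]) { newfree <- c(newfree, list(iv)); next }
      if (h$start > iv[1]) newfree <- c(newfree, list(c(iv[1], h$start - 1L)))
      if (h$end < iv[2]) newfree <- c(newfree, list(c(h$end + 1L, iv[2])))
    }
    free <- newfree
    # re-fit every pending reference (the accepted one may occur again)
    for (dd in names(cache)) cache[[dd]] <- best_in_free(dd)
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Domain inventory of a BGC locus
#'
#' Collects all member-gene domain hits into (i) the multiset of domain
#' labels and (ii) the linear domain sequence of the locus: genes
#' left-to-right by coordinate, domains N- to C-terminal within each gene,
#' with minus-strand genes reversed gene-wise so the sequence reads in
#' genomic orientation.
#'
#' @param locus A domain-annotated BGC locus (see [annotate_locus_domains()]).
#' @return List with \code{multiset} (character vector, one entry per domain
#'   copy), \code{sequence} (linear domain-label sequence), and \code{copies}
#'   (data.frame with per-copy \code{domain}, \code{gene_id}, \code{seq}).
#' @export
domain_inventory <- function(locus) {
  stopifnot(inherits(locus, "bgc_locus"))
  if (is.null(locus$domain_hits))
    stop("locus genes are not domain-annotated; run annotate_locus_domains()")
  g <- locus$genes
  copies <- list()
  for (i in seq_len(nrow(g))) {
    dh <- locus$domain_hits[[g$gene_id[i]]]
    if (is.null(dh) || !nrow(dh)) next
    dh <- dh[order(dh$start), , drop = FALSE]        # N -> C
    if (g$strand[i] == "-") dh <- dh[rev(seq_len(nrow(dh))), , drop = FALSE]
    copies[[length(copies) + 1L]] <- dh
  }
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(gene_id = character(), domain = character(), start = integer(),
               end = integer(), score = numeric(), seq = character())
  rownames(copies) <- NULL
  list(multiset = copies$domain, sequence = copies$domain,
       copies = copies[, c("domain", "gene_id", "seq")])
}
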