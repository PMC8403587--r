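# BGC locus assembly: neighbour function calls and the
# three-consecutive-unrelated-genes border rule.

#' Construct a BGC locus object
#'
#' @param bgc_id Locus identifier.
#' @param species_id,contig_id Provenance.
#' @param genes Contiguous, start-ordered data.frame of member genes
#'   (same columns as \code{genome$genes}).
#' @param core_gene_ids Non-empty character vector of core gene ids.
#' @param gene_roles Named list/vector mapping gene_id to a function label
#'   (\code{core}, \code{tailoring}, \code{regulatory}, \code{transport},
#'   \code{resistance}) or \code{"unrelated"}.
#' @param class Biosynthetic class (NA until classified).
#' @param is_reference TRUE for characterised reference BGCs mixed into
#'   networks.
#' @param core_classes Named vector mapping core gene ids to their template
#'   target class.
#' @return Object of class \code{"bgc_locus"}.
#' @export
new_bgc_locus <- function(bgc_id, species_id, contig_id, genes, core_gene_ids,
                          gene_roles, class = NA_character_,
                          is_reference = FALSE, core_classes = NULL) {
  stopifnot(nrow(genes) >= 1L, length(core_gene_ids) >= 1L)
  if (!all(core_gene_ids %in% genes$gene_id))
    stop("core gene(s) not among locus genes")
  genes <- genes[order(genes$start, genes$end, genes$gene_id), ]
  rownames(genes) <- NULL
  structure(list(bgc_id = bgc_id, species_id = species_id,
                 contig_id = contig_id, genes = genes,
                 core_gene_ids = core_gene_ids,
                 gene_roles = as.list(gene_roles),
                 class = class, is_reference = is_reference,
                 core_classes = core_classes,
                 collaborative_candidate = FALSE,
                 domain_hits = NULL, counted = TRUE),
            class = "bgc_locus")
}

#' @export
print.bgc_locus <- function(x, ...) {
  cat(sprintf("<bgc_locus> %s [%s %s:%d-%d] %d genes, %d core(s), class %s\n",
              x$bgc_id, x$species_id, x$contig_id, min(x$genes$start),
              max(x$genes$end), nrow(x$genes), length(x$core_gene_ids),
              if (is.na(x$class)) "unassigned" else x$class))
  invisible(x)
}

#' Predict the function label of one gene by homology
#'
#' Best-hit search against the labelled function database: the gene takes the
#' label of its best hit at \code{E <= max_evalue}; genes with no hit, or
#' whose best hit is a housekeeping protein, are \code{"unrelated"} (they do
#' not extend BGC borders).
#'
#' @param gene One-row gene data.frame or a protein string.
#' @param db A [function_db()].
#' @param max_evalue Maximum E-value (default 1e-5, stricter than core
#'   detection: one spurious call extends a border by up to three genes).
#' @param scheme A [scoring_scheme()].
#' @return A single label.
#' @export
call_gene_role <- function(gene, db, max_evalue = 1e-5, scheme = NULL) {
  p <- if (is.data.frame(gene)) gene$protein[1] else gene
  if (!nrow(db)) stop("function database is empty")
  hit <- best_hit(p, stats::setNames(db$protein, db$id), scheme, max_evalue)
  if (is.null(hit)) return("unrelated")
  lab <- db$label[db$id == hit$id]
  if (lab == "housekeeping") "unrelated" else lab
}

#' Function labels for every gene of a genome
#'
#' Vectorised equivalent of [call_gene_role()] (one alignment pass per
#' database entry). Genes listed in \code{core_gene_ids} are labelled
#' \code{"core"} regardless of the database.
#'
#' @inheritParams call_gene_role
#' @param genome A [new_genome()] object.
#' @param core_gene_ids Optional ids of detected core genes.
#' @return Named character vector gene_id -> label.
#' @export
call_gene_roles <- function(genome, db, max_evalue = 1e-5,
                            core_gene_ids = character(), scheme = NULL) {
  scheme <- as_scheme(scheme)
  g <- genome$genes
  if (!nrow(g)) return(stats::setNames(character(), character()))
  n_db <- sum(nchar(db$protein))
  best_sc <- rep(-Inf, nrow(g)); best_ev <- rep(Inf, nrow(g))
  best_id <- rep(NA_character_, nrow(g))
  for (k in order(db$id)) {
    sc <- local_scores(g$protein, db$protein[k], scheme)
    ev <- evalue(pmax(sc, 0), nchar(g$protein), n_db, scheme)
    upd <- which(sc > 0 & ev <= max_evalue &
                   (sc > best_sc |
                      (sc == best_sc & ev < best_ev) |
                      (sc == best_sc & ev == best_ev & db$id[k] < best_id)))
    best_sc[upd] <- sc[upd]; best_ev[upd] <- ev[upd]; best_id[upd] <- db$id[k]
  }
  labels <- ifelse(is.na(best_id), "unrelated",
                   db$label[match(best_id, db$id)])
  labels[labels == "housekeeping"] <- "unrelated"
  labels[g$gene_id %in% core_gene_ids] <- "core"
  stats::setNames(labels, g$gene_id)
}

#' Grow a BGC locus around a core gene
#'
#' Walks outward from the core gene in each direction independently and stops
#' as soon as a run of three consecutive \code{"unrelated"} genes is seen
#' (a contig end terminates a walk early); the locus is then trimmed back to
#' the outermost related gene on each side. A core gene whose neighbours are
#' all unrelated yields a single-gene locus. "Consecutive" counts genes only,
#' regardless of strand or intergenic distance.
#'
#' @param genome A [new_genome()] object.
#' @param core A core gene id, or one row of [scan_cores()] output.
#' @param roles Named character vector from [call_gene_roles()]; if NULL it
#'   is computed from \code{db}.
#' @param db A [function_db()] (only needed when \code{roles} is NULL).
#' @param max_evalue Neighbour-call threshold (default 1e-5).
#' @param border_run Number of consecutive unrelated genes that closes a
#'   border (default 3).
#' @param bgc_id Identifier for the new locus.
#' @param scheme A [scoring_scheme()].
#' @return A [new_bgc_locus()] object.
#' @export
extend_locus <- function(genome, core, roles = NULL, db = NULL,
                         max_evalue = 1e-5, border_run = 3L,
                         bgc_id = NULL, scheme = NULL) {
  core_row <- NULL
  if (is.data.frame(core)) { core_row <- core[1, ]; core <- core_row$gene_id }
  g <- genome$genes
  ci <- match(core, g$gene_id)
  if (is.na(ci)) stop("core gene ", core, " not in genome")
  contig <- g$contig_id[ci]
  idx <- which(g$contig_id == contig)          # already start-ordered
  pos <- match(ci, idx)
  if (is.null(roles))
    roles <- call_gene_roles(genome, db, max_evalue,
                             core_gene_ids = core, scheme = scheme)
  related <- function(i) {
    r <- roles[[g$gene_id[idx[i]]]]
    !is.null(r) && r != "unrelated"
  }
  walk <- function(step) {
    i <- pos; run <- 0L; last_related <- pos
    repeat {
      i <- i + step
      if (i < 1L || i > length(idx)) break
      if (related(i)) { run <- 0L; last_related <- i }
      else { run <- run + 1L; if (run >= border_run) break }
    }
    last_related
  }
  lo <- walk(-1L); hi <- walk(+1L)
  genes <- g[idx[lo:hi], , drop = FALSE]
  if (is.null(bgc_id))
    bgc_id <- sprintf("%s|%s|%s", genome$species_id, contig, core)
  core_classes <- NULL
  if (!is.null(core_row))
    core_classes <- stats::setNames(core_row$target_class, core)
  new_bgc_locus(bgc_id, genome$species_id, contig, genes,
                core_gene_ids = core,
                gene_roles = roles[genes$gene_id],
                core_classes = core_classes)
}

#' Merge BGC loci that share genes
#'
#' Loci from one genome sharing at least one gene are merged (union of genes
#' and cores); merged loci carrying two or more type I PKS core genes are
#' flagged as collaborative candidates (the flag records that such a locus
#' may also be two adjacent independent pathways).
#'
#' @param loci List of [new_bgc_locus()] objects from one genome.
#' @return List of loci, merged, ordered by contig and start.
#' @export
merge_overlapping <- function(loci) {
  if (length(loci) <= 1L) return(annotate_collab(loci))
  ids <- lapply(loci, function(l) paste(l$contig_id, l$genes$gene_id))
  parent <- seq_along(loci)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(loci)) for (j in seq_len(i - 1L)) {
    if (length(intersect(ids[[i]], ids[[j]]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  groups <- split(seq_along(loci), vapply(seq_along(loci), find, 0L))
  out <- lapply(groups, function(members) {
    if (length(members) == 1L) return(loci[[members]])
    base <- loci[[members[1L]]]
    genes <- unique(do.call(rbind, lapply(loci[members], `[[`, "genes")))
    roles <- do.call(c, lapply(loci[members], `[[`, "gene_roles"))
    roles <- roles[!duplicated(names(roles))]
    cores <- sort(unique(unlist(lapply(loci[members], `[[`, "core_gene_ids"))))
    cls <- do.call(c, lapply(loci[members], `[[`, "core_classes"))
    cls <- cls[!duplicated(names(cls))]
    new_bgc_locus(base$bgc_id, base$species_id, base$contig_id, genes,
                  core_gene_ids = cores, gene_roles = roles,
                  is_reference = base$is_reference, core_classes = cls)
  })
  ord <- order(vapply(out, `[[`, "", "contig_id"),
               vapply(out, function(l) min(l$genes$start), 0L))
  annotate_collab(unname(out[ord]))
}

annotate_collab <- function(loci) {
  lapply(loci, function(l) {
    if (!is.null(l$core_classes))
      l$collaborative_candidate <- sum(l$core_classes == "typeI_PKS") >= 2L
    l
  })
}

#' Annotate every gene of a locus with its domain string
#'
#' Runs [assign_domains()] on each member gene (a supplied domain annotation
#' table takes precedence per gene) and stores the hits on the locus.
#'
#' @param locus A [new_bgc_locus()] object.
#' @param refs Panel from [domain_panel()].
#' @param table Optional \code{domain_annotation_table}.
#' @param min_score_frac Matcher threshold (default 0.3).
#' @param scheme A [scoring_scheme()].
#' @return The locus with \code{$domain_hits} set (named list per gene).
#' @export
annotate_locus_domains <- function(locus, refs = domain_panel(), table = NULL,
                                   min_score_frac = 0.3, scheme = NULL) {
  hits <- lapply(seq_len(nrow(locus$genes)), function(i)
    assign_domains(locus$genes$protein[i], refs, min_score_frac,
                   gene_id = locus$genes$gene_id[i], table = table,
                   scheme = scheme))
  locus$domain_hits <- stats::setNames(hits, locus$genes$gene_id)
  locus
}

# Domain string (character vector, N->C) of one gene of an annotated locus.
gene_domain_string <- function(locus, gene_id) {
  dh <- locus$domain_hits[[gene_id]]
  if (is.null(dh) || !nrow(dh)) character() else dh$domain[order(dh$start)]
}
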