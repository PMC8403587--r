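# Cluster-to-cluster comparison: best-link-per-gene synteny links, homology
# groups across multiple BGCs, and co-localised homolog search across
# genomes.

#' Best-link synteny comparison of two BGCs
#'
#' All-vs-all protein alignment between the genes of the two loci; for every
#' gene of \code{b1} the single best link into \code{b2} is kept, ranked by
#' similarity percentage (positives), ties broken by raw score then partner
#' gene order. Links below \code{min_identity} percent identity are dropped,
#' as are alignments covering less than \code{min_coverage} percent of either
#' protein (synteny links relate whole genes; without the coverage floor the
#' short high-identity islands that any two random proteins share would
#' count as links).
#' Reciprocal consistency is not required: two genes of b1 may link to the
#' same gene of b2.
#'
#' @param b1,b2 Non-empty [new_bgc_locus()] objects.
#' @param min_identity Identity floor in percent (default 30).
#' @param min_coverage Minimum percent of the better-covered protein spanned
#'   by the alignment (default 50).
#' @param scheme A [scoring_scheme()].
#' @return data.frame with columns \code{gene1}, \code{gene2},
#'   \code{identity_pct}, \code{similarity_pct}, \code{score}.
#' @export
compare_bgcs <- function(b1, b2, min_identity = 30, min_coverage = 50,
                         scheme = NULL) {
  stopifnot(nrow(b1$genes) >= 1L, nrow(b2$genes) >= 1L)
  scheme <- as_scheme(scheme)
  out <- list()
  for (i in seq_len(nrow(b1$genes))) {
    best <- NULL
    for (j in seq_len(nrow(b2$genes))) {
      r <- local_align(b1$genes$protein[i], b2$genes$protein[j], scheme)
      if (r$identity_pct < min_identity) next
      if (max(r$query_cov, r$subject_cov) < min_coverage) next
      if (is.null(best) || r$similarity_pct > best$r$similarity_pct ||
          (r$similarity_pct == best$r$similarity_pct &&
             r$score > best$r$score))
        best <- list(j = j, r = r)
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(
        gene1 = b1$genes$gene_id[i], gene2 = b2$genes$gene_id[best$j],
        identity_pct = best$r$identity_pct,
        similarity_pct = best$r$similarity_pct, score = best$r$score)
  }
  if (!length(out))
    return(data.frame(gene1 = character(), gene2 = character(),
                      identity_pct = numeric(), similarity_pct = numeric(),
                      score = numeric()))
  do.call(rbind, out)
}

#' Homology groups across multiple BGCs
#'
#' Single-linkage grouping of genes over the pairwise best links of every
#' locus pair (both directions). Group ids are stable: numbered by the first
#' occurrence of a member gene in input order.
#'
#' @param loci List of [new_bgc_locus()] objects.
#' @param min_identity,min_coverage Link floors passed to [compare_bgcs()].
#' @param scheme A [scoring_scheme()].
#' @return data.frame with columns \code{bgc_id}, \code{gene_id},
#'   \code{group}.
#' @export
homology_groups <- function(loci, min_identity = 30, min_coverage = 50,
                            scheme = NULL) {
  ids <- vapply(loci, `[[`, "", "bgc_id")
  nodes <- do.call(rbind, lapply(loci, function(l)
    data.frame(bgc_id = l$bgc_id, gene_id = l$genes$gene_id)))
  node_key <- paste(nodes$bgc_id, nodes$gene_id, sep = "::")
  edges <- list()
  for (i in seq_along(loci)) for (j in seq_along(loci)) {
    if (j <= i) next
    l12 <- compare_bgcs(loci[[i]], loci[[j]], min_identity, min_coverage,
                        scheme)
    if (nrow(l12))
      edges[[length(edges) + 1L]] <- data.frame(
        from = paste(ids[i], l12$gene1, sep = "::"),
        to = paste(ids[j], l12$gene2, sep = "::"))
    l21 <- compare_bgcs(loci[[j]], loci[[i]], min_identity, min_coverage,
                        scheme)
    if (nrow(l21))
      edges[[length(edges) + 1L]] <- data.frame(
        from = paste(ids[j], l21$gene1, sep = "::"),
        to = paste(ids[i], l21$gene2, sep = "::"))
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = node_key))
  comp <- igraph::components(g)$membership[node_key]
  # renumber components by first occurrence
  group <- match(comp, unique(comp))
  data.frame(bgc_id = nodes$bgc_id, gene_id = nodes$gene_id, group = group)
}

#' Co-localised homolog search across genomes
#'
#' Finds windows of genes in which at least \code{min_queries} distinct query
#' proteins have homologs (E-value at most \code{max_evalue}, computed
#' against the genome's proteome length), allowing at most
#' \code{max_gap_genes} consecutive non-hit genes inside a window. Only
#' maximal windows are reported; windows on one contig never overlap.
#'
#' @param queries Named character vector of at least two query proteins.
#' @param genomes List of [new_genome()] objects.
#' @param min_queries Minimum number of distinct matched queries per window.
#' @param max_gap_genes Maximum run of intervening non-hit genes.
#' @param max_evalue E-value threshold (default 1e-1).
#' @param scheme A [scoring_scheme()].
#' @return List of hits; each has \code{species_id}, \code{contig_id},
#'   \code{gene_ids} (hit genes only), \code{span} (first..last hit gene
#'   coordinates), \code{matched_queries}, and \code{identities} (per hit
#'   gene, identity of its best query match).
#' @export
find_colocalized <- function(queries, genomes, min_queries = 2L,
                             max_gap_genes = 2L, max_evalue = 1e-1,
                             scheme = NULL) {
  if (length(queries) < 2L) stop("need at least two queries")
  if (min_queries > length(queries))
    stop("min_queries exceeds the number of queries")
  if (is.null(names(queries))) names(queries) <- sprintf("q%02d", seq_along(queries))
  scheme <- as_scheme(scheme)
  hits <- list()
  for (genome in genomes) {
    g <- genome$genes
    if (!nrow(g)) next
    db_len <- sum(nchar(g$protein))
    # per gene: best matching query (if any) and its identity
    match_q <- rep(NA_character_, nrow(g)); match_id <- rep(NA_real_, nrow(g))
    best_sc <- rep(-Inf, nrow(g))
    for (qn in names(queries)) {
      sc <- local_scores(g$protein, queries[[qn]], scheme)
      ev <- evalue(pmax(sc, 0), nchar(g$protein), db_len, scheme)
      upd <- which(sc > 0 & ev <= max_evalue & sc > best_sc)
      if (length(upd)) {
        best_sc[upd] <- sc[upd]; match_q[upd] <- qn
        for (i in upd)
          match_id[i] <- local_align(queries[[qn]], g$protein[i],
                                     scheme)$identity_pct
      }
    }
    for (contig in unique(g$contig_id)) {
      idx <- which(g$contig_id == contig)
      hit_pos <- idx[!is.na(match_q[idx])]
      if (!length(hit_pos)) next
      # split hit genes into windows at gaps > max_gap_genes non-hit genes
      pos_in_contig <- match(hit_pos, idx)
      breaks <- which(diff(pos_in_contig) - 1L > max_gap_genes)
      starts <- c(1L, breaks + 1L); ends <- c(breaks, length(hit_pos))
      for (w in seq_along(starts)) {
        members <- hit_pos[starts[w]:ends[w]]
        qs <- unique(match_q[members])
        if (length(qs) < min_queries) next
        hits[[length(hits) + 1L]] <- list(
          species_id = genome$species_id, contig_id = contig,
          gene_ids = g$gene_id[members],
          span = c(min(g$start[members]), max(g$end[members])),
          matched_queries = sort(qs),
          identities = stats::setNames(match_id[members], g$gene_id[members]))
      }
    }
  }
  hits
}
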