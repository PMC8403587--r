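# Gene-cluster-family networking: pairwise BGC similarity distances from
# domain inventories (Jaccard / domain-sequence-identity / adjacency indices,
# combined 0.2/0.75/0.05), cutoff networks, and connected subnetworks as
# GCFs.

#' Default anchor domain set
#'
#' Domain types given extra weight in the DSI: citrate synthase, terpene
#' cyclase, UbiA-type prenyltransferase and tryptophan DMAT (the package's
#' vocabulary translation of the Pfam anchors Citrate_synt, Terpene_syn_C_2,
#' UbiA and Trp_DMAT).
#'
#' @return Character vector of anchor domain labels.
#' @export
anchor_domains <- function() c("CS", "TC", "PTase", "DMAT")

as_inventory <- function(x) {
  if (inherits(x, "bgc_locus")) domain_inventory(x)
  else if (is.list(x) && all(c("multiset", "sequence", "copies") %in% names(x))) x
  else stop("expected a bgc_locus or a domain_inventory() result")
}

#' Jaccard index of two domain inventories
#'
#' Jaccard similarity of the *sets* of domain types (copy numbers ignored).
#' Two empty inventories give 0 by convention, so domainless loci never bind
#' families together.
#'
#' @param A,B Loci or [domain_inventory()] results.
#' @return Number in [0, 1].
#' @export
jaccard_index <- function(A, B) {
  a <- unique(as_inventory(A)$multiset); b <- unique(as_inventory(B)$multiset)
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

#' Domain sequence identity of two domain inventories
#'
#' For each domain type shared by both BGCs, copies are paired greedily by
#' descending pairwise local-alignment identity; every paired copy
#' contributes its pair identity, every unpaired copy contributes 0, and the
#' DSI is the weighted mean over all copies in both BGCs, with anchor types
#' weighted by \code{anchor_weight}.
#'
#' @param A,B Loci or [domain_inventory()] results (copies must carry their
#'   amino-acid subsequences).
#' @param anchors Anchor domain set, default [anchor_domains()].
#' @param anchor_weight Multiplicative weight of anchor copies (default 2).
#' @param scheme A [scoring_scheme()].
#' @return Number in [0, 1].
#' @export
dsi <- function(A, B, anchors = anchor_domains(), anchor_weight = 2.0,
                scheme = NULL) {
  a <- as_inventory(A)$copies; b <- as_inventory(B)$copies
  if ((nrow(a) && any(!nzchar(a$seq))) || (nrow(b) && any(!nzchar(b$seq))))
    stop("domain copies are missing their subsequences")
  if (!nrow(a) && !nrow(b)) return(0)
  w <- function(type) ifelse(type %in% anchors, anchor_weight, 1)
  total_w <- sum(w(a$domain)) + sum(w(b$domain))
  if (total_w == 0) return(0)
  num <- 0
  for (type in intersect(unique(a$domain), unique(b$domain))) {
    ia <- which(a$domain == type); ib <- which(b$domain == type)
    id <- matrix(0, length(ia), length(ib))
    for (i in seq_along(ia)) for (j in seq_along(ib))
      id[i, j] <- local_align(a$seq[ia[i]], b$seq[ib[j]],
                              scheme)$identity_pct / 100
    for (k in seq_len(min(length(ia), length(ib)))) {
      m <- arrayInd(which.max(id), dim(id))
      # each paired copy (one in A, one in B) contributes the pair identity
      num <- num + 2 * w(type) * id[m[1], m[2]]
      id[m[1], ] <- -1; id[, m[2]] <- -1
    }
  }
  min(1, num / total_w)
}

#' Adjacency index of two domain inventories
#'
#' Jaccard similarity of the sets of adjacent ordered domain-type pairs along
#' each BGC's linear domain sequence. When both loci carry fewer than two
#' domains there are no adjacencies to compare, and the index degrades to the
#' Jaccard of the domain-type sets (so a locus is never at positive distance
#' from itself); a single-domain locus compared with a multi-domain locus has
#' no shared pairs and gives 0.
#'
#' @param A,B Loci or [domain_inventory()] results.
#' @return Number in [0, 1].
#' @export
adjacency_index <- function(A, B) {
  sa <- as_inventory(A)$sequence; sb <- as_inventory(B)$sequence
  if (length(sa) < 2L && length(sb) < 2L) {
    u <- union(sa, sb)
    if (!length(u)) return(0)
    return(length(intersect(sa, sb)) / length(u))
  }
  pairs <- function(s) {
    if (length(s) < 2L) return(character())
    unique(paste(s[-length(s)], s[-1L], sep = ">"))
  }
  pa <- pairs(sa); pb <- pairs(sb)
  u <- union(pa, pb)
  if (!length(u)) return(0)
  length(intersect(pa, pb)) / length(u)
}

#' Weighted similarity distance between two BGCs
#'
#' \deqn{d = 1 - (w_J \cdot JI + w_D \cdot DSI + w_A \cdot AI)}
#' with default weights 0.2 / 0.75 / 0.05 ("mix"-class weighting); 0 means
#' complete similarity, 1 not similar at all. Clamped to [0, 1].
#'
#' @param A,B Loci or [domain_inventory()] results.
#' @param weights Numeric length-3 vector (JI, DSI, AI weights).
#' @param anchors,anchor_weight,scheme Passed to [dsi()].
#' @return List of class \code{"pair_distance"} with \code{ji}, \code{dsi},
#'   \code{ai}, \code{distance}.
#' @export
pair_distance <- function(A, B, weights = c(0.2, 0.75, 0.05),
                          anchors = anchor_domains(), anchor_weight = 2.0,
                          scheme = NULL) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) <= 1 + 1e-9)
  ji <- jaccard_index(A, B)
  ds <- dsi(A, B, anchors, anchor_weight, scheme)
  ai <- adjacency_index(A, B)
  d <- 1 - (weights[1] * ji + weights[2] * ds + weights[3] * ai)
  structure(list(ji = ji, dsi = ds, ai = ai,
                 distance = min(1, max(0, d))),
            class = "pair_distance")
}

#' All pairwise BGC distances
#'
#' Computes the full edge table once so that networks at several cutoffs can
#' be derived without re-aligning.
#'
#' @param loci Named list (or list with bgc_ids) of domain-annotated loci.
#' @inheritParams pair_distance
#' @return data.frame with columns \code{bgc1}, \code{bgc2}, \code{ji},
#'   \code{dsi}, \code{ai}, \code{distance} for every unordered pair.
#' @export
pair_distance_table <- function(loci, weights = c(0.2, 0.75, 0.05),
                                anchors = anchor_domains(),
                                anchor_weight = 2.0, scheme = NULL) {
  ids <- vapply(loci, `[[`, "", "bgc_id")
  inv <- lapply(loci, domain_inventory)
  n <- length(loci)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    pd <- pair_distance(inv[[i]], inv[[j]], weights, anchors, anchor_weight,
                        scheme)
    k <- k + 1L
    rows[[k]] <- data.frame(bgc1 = ids[i], bgc2 = ids[j], ji = pd$ji,
                            dsi = pd$dsi, ai = pd$ai, distance = pd$distance)
  }
  if (!k) return(data.frame(bgc1 = character(), bgc2 = character(),
                            ji = numeric(), dsi = numeric(), ai = numeric(),
                            distance = numeric()))
  do.call(rbind, rows)
}

#' Build the cutoff network and emit GCFs
#'
#' Keeps an edge for every pair with distance strictly below the cutoff and
#' returns the connected components as gene cluster families; isolated BGCs
#' become singleton GCFs. All classes are mixed in one network.
#'
#' @param loci List of domain-annotated loci.
#' @param cutoff Distance cutoff (the study grid is 0.3, 0.4, 0.5, 0.6).
#' @param distances Optional precomputed [pair_distance_table()].
#' @param ... Passed to [pair_distance_table()] when distances are computed
#'   here.
#' @return List with \code{edges} (kept edges), \code{gcfs} (list of GCF
#'   objects: \code{gcf_id}, \code{members}, \code{cutoff},
#'   \code{is_singleton}, \code{species}, \code{is_reference_only}), and
#'   \code{membership} (data.frame bgc_id -> gcf_id).
#' @export
build_network <- function(loci, cutoff = 0.4, distances = NULL, ...) {
  if (!length(loci)) stop("need at least one BGC")
  ids <- vapply(loci, `[[`, "", "bgc_id")
  if (anyDuplicated(ids)) stop("duplicate bgc_ids")
  if (is.null(distances)) distances <- pair_distance_table(loci, ...)
  edges <- distances[distances$distance < cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("bgc1", "bgc2")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  species_of <- stats::setNames(vapply(loci, `[[`, "", "species_id"), ids)
  ref_of <- stats::setNames(
    vapply(loci, function(l) isTRUE(l$is_reference), TRUE), ids)
  members_by_comp <- split(names(comp$membership), comp$membership)
  # stable ids: order components by first member occurrence in input order
  first_idx <- vapply(members_by_comp,
                      function(m) min(match(m, ids)), 0L)
  members_by_comp <- members_by_comp[order(first_idx)]
  gcfs <- lapply(seq_along(members_by_comp), function(k) {
    m <- members_by_comp[[k]]
    structure(list(
      gcf_id = sprintf("GCF_%03d", k), members = sort(m), cutoff = cutoff,
      is_singleton = length(m) == 1L,
      species = sort(unique(unname(species_of[m][!ref_of[m]]))),
      is_reference_only = all(ref_of[m])), class = "gcf")
  })
  membership <- data.frame(
    bgc_id = unlist(lapply(gcfs, `[[`, "members")),
    gcf_id = rep(vapply(gcfs, `[[`, "", "gcf_id"),
                 vapply(gcfs, function(x) length(x$members), 0L)))
  list(edges = edges, gcfs = gcfs, membership = membership)
}

#' @export
print.gcf <- function(x, ...) {
  cat(sprintf("<gcf> %s (cutoff %.2f): %d member(s), %d species%s\n",
              x$gcf_id, x$cutoff, length(x$members), length(x$species),
              if (x$is_singleton) ", singleton" else ""))
  invisible(x)
}

#' Prune reference-only GCFs
#'
#' Removes subnetworks whose members are all characterised reference BGCs;
#' mixed subnetworks are retained intact.
#'
#' @param gcfs List of GCF objects from [build_network()].
#' @return Filtered list.
#' @export
prune_reference_only <- function(gcfs) {
  Filter(function(g) !isTRUE(g$is_reference_only), gcfs)
}

#' Count GCFs conserved across a species universe
#'
#' @param gcfs List of GCF objects.
#' @param species_universe Character vector of species that must all be
#'   represented in a GCF for it to count as conserved.
#' @return Integer count.
#' @export
conserved_gcfs <- function(gcfs, species_universe) {
  sum(vapply(gcfs, function(g) all(species_universe %in% g$species), TRUE))
}
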