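# Pipeline orchestration and study-level summary reporting:
# detect -> assemble -> classify -> network -> report.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: core-search
#' E-value 1e-1, neighbour-call E-value 1e-5, distance cutoff grid
#' {0.3, 0.4, 0.5, 0.6} with default 0.4, index weights 0.2/0.75/0.05
#' (JI/DSI/AI), anchor weight 2.0, domain-matcher threshold 0.3.
#'
#' @param core_max_evalue,neighbour_max_evalue E-value thresholds.
#' @param cutoffs Distance cutoffs for which GCF tables are produced.
#' @param default_cutoff Cutoff used for the presence matrix and summary.
#' @param weights Length-3 JI/DSI/AI weights (must sum to <= 1).
#' @param anchors,anchor_weight DSI anchor domains and their weight.
#' @param min_score_frac Domain-matcher acceptance threshold.
#' @param min_identity Synteny link identity floor (percent).
#' @param border_run Unrelated-gene run closing a BGC border.
#' @param out_dir Output directory, or NULL for in-memory results only.
#' @param seed Integer seed recorded with the run.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(core_max_evalue = 1e-1,
                            neighbour_max_evalue = 1e-5,
                            cutoffs = c(0.3, 0.4, 0.5, 0.6),
                            default_cutoff = 0.4,
                            weights = c(0.2, 0.75, 0.05),
                            anchors = anchor_domains(), anchor_weight = 2.0,
                            min_score_frac = 0.3, min_identity = 30,
                            border_run = 3L, out_dir = NULL, seed = 1L) {
  stopifnot(sum(weights) <= 1 + 1e-9, all(cutoffs > 0), all(cutoffs < 1),
            default_cutoff %in% cutoffs)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full mining pipeline
#'
#' For every genome: scan for core genes, call neighbour roles, grow and
#' merge BGC loci, annotate domain strings, classify. Then, on all counted
#' loci (plus any supplied reference BGCs), compute the pairwise distance
#' table once, build GCF networks at every configured cutoff, prune
#' reference-only subnetworks, and derive the presence matrix and summary
#' statistics at the default cutoff. Deterministic given (genomes, config);
#' when \code{config$out_dir} is set, all tables are also written to disk
#' with stable formatting, so reruns are byte-identical.
#'
#' @param genomes A [make_cohort()] result, a list of [new_genome()] objects,
#'   or a directory of \code{.gbk} files.
#' @param config A [pipeline_config()].
#' @param references Optional list of domain-annotated reference loci
#'   (\code{is_reference = TRUE}) to mix into the network.
#' @param domain_table Optional \code{domain_annotation_table} taking
#'   precedence over the built-in domain matcher.
#' @return List of class \code{"bgc_results"}: \code{loci}, \code{loci_table},
#'   \code{class_matrix}, \code{distances}, \code{networks} (per cutoff),
#'   \code{gcfs} (default cutoff, pruned), \code{presence},
#'   \code{summary}, \code{config}.
#' @export
run_pipeline <- function(genomes, config = pipeline_config(),
                         references = NULL, domain_table = NULL) {
  if (inherits(genomes, "bgc_cohort")) genomes <- genomes$genomes
  if (is.character(genomes) && length(genomes) == 1L && dir.exists(genomes)) {
    paths <- sort(list.files(genomes, pattern = "\\.gbk$", full.names = TRUE))
    if (!length(paths)) stop("no .gbk files in ", genomes)
    genomes <- lapply(paths, read_genbank)
    names(genomes) <- vapply(genomes, `[[`, "", "species_id")
  }
  stopifnot(all(vapply(genomes, inherits, TRUE, "bgc_genome")))
  templates <- core_templates()
  fdb <- function_db()
  panel <- domain_panel()
  species <- vapply(genomes, `[[`, "", "species_id")

  all_loci <- list()
  for (genome in genomes) {
    cores <- scan_cores(genome, templates, config$core_max_evalue)
    if (!nrow(cores)) next
    roles <- call_gene_roles(genome, fdb, config$neighbour_max_evalue,
                             core_gene_ids = cores$gene_id)
    loci <- lapply(seq_len(nrow(cores)), function(i)
      extend_locus(genome, cores[i, ], roles = roles,
                   border_run = config$border_run))
    loci <- merge_overlapping(loci)
    loci <- lapply(seq_along(loci), function(i) {
      l <- loci[[i]]
      l$bgc_id <- sprintf("%s|BGC%02d", genome$species_id, i)
      l$core_classes <- stats::setNames(
        cores$target_class[match(l$core_gene_ids, cores$gene_id)],
        l$core_gene_ids)
      l <- annotate_locus_domains(l, panel, table = domain_table,
                                  min_score_frac = config$min_score_frac)
      classify_locus(l)
    })
    all_loci <- c(all_loci, loci)
  }

  class_matrix <- class_count_table(all_loci, species = unname(species))
  counted <- Filter(function(l) isTRUE(l$counted), all_loci)
  net_loci <- c(counted, references %||% list())
  networks <- list(); distances <- NULL
  if (length(net_loci)) {
    distances <- pair_distance_table(net_loci, weights = config$weights,
                                     anchors = config$anchors,
                                     anchor_weight = config$anchor_weight)
    for (cf in sort(config$cutoffs)) {
      nw <- build_network(net_loci, cutoff = cf, distances = distances)
      nw$gcfs <- prune_reference_only(nw$gcfs)
      networks[[sprintf("%.1f", cf)]] <- nw
    }
  }
  gcfs <- networks[[sprintf("%.1f", config$default_cutoff)]]$gcfs %||% list()
  pres <- presence_matrix(gcfs, unname(species))
  res <- structure(list(
    loci = all_loci, loci_table = loci_summary_table(all_loci),
    class_matrix = class_matrix, distances = distances,
    networks = networks, gcfs = gcfs, presence = pres,
    summary = summary_stats(all_loci, gcfs, unname(species)),
    config = config), class = "bgc_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

loci_summary_table <- function(loci) {
  if (!length(loci))
    return(data.frame(bgc_id = character(), species_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      core_genes = character(), class = character(),
                      counted = logical(), rule = character()))
  do.call(rbind, lapply(loci, function(l) data.frame(
    bgc_id = l$bgc_id, species_id = l$species_id, contig_id = l$contig_id,
    start = min(l$genes$start), end = max(l$genes$end),
    n_genes = nrow(l$genes),
    core_genes = paste(sort(l$core_gene_ids), collapse = ","),
    class = l$class, counted = isTRUE(l$counted),
    rule = l$rule %||% NA_character_)))
}

#' @export
print.bgc_results <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<bgc_results> %d BGCs across %d species (mean %.1f/species)\n",
    "  %d GCFs at cutoff %.1f (%d singletons, %d conserved, %d with >= 4 members)\n"),
    s$total_bgcs, s$n_species, s$mean_bgcs_per_species, s$n_gcfs,
    x$config$default_cutoff, s$n_singletons, s$n_conserved,
    s$n_gcfs_ge4))
  invisible(x)
}

#' Family presence/absence matrix
#'
#' @param gcfs List of GCF objects (default-cutoff families).
#' @param species Character vector of cohort species (column order).
#' @return Logical matrix families x species.
#' @export
presence_matrix <- function(gcfs, species) {
  m <- matrix(FALSE, length(gcfs), length(species),
              dimnames = list(vapply(gcfs, `[[`, "", "gcf_id"), species))
  for (g in gcfs) m[g$gcf_id, intersect(g$species, species)] <- TRUE
  m
}

#' Summary statistics of a mining run
#'
#' Totals in the style of the study-level reporting: number of (counted)
#' BGCs, mean per species, number of GCFs and singleton GCFs, GCFs conserved
#' across all species, GCFs with at least four members.
#'
#' @param loci Classified loci list.
#' @param gcfs GCF list at the reporting cutoff.
#' @param species Cohort species ids.
#' @return Named list of totals.
#' @export
summary_stats <- function(loci, gcfs, species) {
  counted <- Filter(function(l) isTRUE(l$counted), loci)
  n_members <- vapply(gcfs, function(g) length(g$members), 0L)
  list(total_bgcs = length(counted),
       n_species = length(species),
       mean_bgcs_per_species =
         if (length(species)) length(counted) / length(species) else 0,
       n_gcfs = length(gcfs),
       n_singletons = sum(n_members == 1L),
       n_conserved = conserved_gcfs(gcfs, species),
       n_gcfs_ge4 = sum(n_members >= 4L))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 means identical partitions.
#'
#' @param a,b Equal-length label vectors.
#' @return Number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab))); sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Stable-format writers: fixed column order, fixed numeric formatting, no
# timestamps, so identical runs produce byte-identical files.
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    df
  }
  tsv <- function(x, f) utils::write.table(
    fmt(x), file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(res$loci_table, "loci.tsv")
  cm <- as.data.frame(res$class_matrix)
  tsv(cbind(species_id = rownames(res$class_matrix), cm), "class_table.tsv")
  if (!is.null(res$distances)) tsv(res$distances, "edges.tsv")
  for (cf in names(res$networks)) {
    nw <- res$networks[[cf]]
    memb <- nw$membership
    keep_ids <- unlist(lapply(nw$gcfs, `[[`, "members"))
    memb <- memb[memb$bgc_id %in% keep_ids, ]
    tsv(memb, sprintf("gcf_%s.tsv", cf))
    graphml <- file.path(dir, sprintf("network_%s.graphml", cf))
    g <- igraph::graph_from_data_frame(
      nw$edges[, c("bgc1", "bgc2", "distance")], directed = FALSE,
      vertices = data.frame(name = sort(unique(memb$bgc_id))))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  pres <- as.data.frame(res$presence)
  tsv(cbind(gcf_id = rownames(res$presence), pres), "presence_matrix.tsv")
  jsonlite::write_json(res$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rule_trace <- lapply(res$loci, function(l)
    list(bgc_id = l$bgc_id, class = l$class, rule = l$rule,
         counted = isTRUE(l$counted)))
  jsonlite::write_json(rule_trace, file.path(dir, "rule_trace.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_bgc_gff(res$loci, file.path(dir, "loci.gff3"))
  cfg <- res$config; cfg$out_dir <- NULL
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)],
                   file.path(dir, "parameters.yaml"))
  invisible(dir)
}
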