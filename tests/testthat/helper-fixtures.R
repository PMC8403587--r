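# Shared fixtures, all built in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fix_panel <- function() cached("panel", domain_panel())
fix_fdb <- function() cached("fdb", function_db())
fix_templates <- function() cached("templates", core_templates())

# A bare genome whose genes carry the given proteins (one contig, plus
# strand, consecutive coordinates).
toy_genome <- function(proteins, species_id = "toy", strand = NULL) {
  n <- length(proteins)
  if (is.null(strand)) strand <- rep("+", n)
  width <- nchar(proteins) * 3L + 3L
  start <- cumsum(c(1L, head(width + 200L, -1L)))
  new_genome(species_id, data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), contig_id = "c1",
    start = start, end = start + width - 1L, strand = strand,
    protein = proteins, product = ""))
}

# A locus whose genes have prescribed domain strings. Domain-hit
# subsequences are the panel references themselves (identity-1 copies), or
# per-gene mutated copies when `identity` is given.
toy_locus <- function(domain_strings, bgc_id = "L1", species_id = "toy",
                      core_classes = c(g001 = "typeI_PKS"),
                      strand = NULL, identity = NULL, seed = 1L,
                      gene_gap_bp = 200L, is_reference = FALSE) {
  panel <- fix_panel()
  n <- length(domain_strings)
  proteins <- vapply(seq_len(n), function(i) {
    ds <- domain_strings[[i]]
    if (!length(ds)) return(make_protein(120L, bgcfam:::derive_seed(
      seed, paste("toy-gene", i))))
    paste(vapply(seq_along(ds), function(k) {
      p <- panel[[ds[k]]]
      if (is.null(identity)) p
      else mutate_to_identity(p, identity, seed + i * 100L + k)
    }, ""), collapse = "")
  }, "")
  width <- nchar(proteins) * 3L + 3L
  start <- cumsum(c(1L, head(width + gene_gap_bp, -1L)))
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), contig_id = "c1",
    start = start, end = start + width - 1L,
    strand = if (is.null(strand)) rep("+", n) else strand,
    protein = proteins, product = "")
  l <- new_bgc_locus(bgc_id, species_id, "c1", genes,
                     core_gene_ids = names(core_classes),
                     gene_roles = stats::setNames(
                       rep("core", n), genes$gene_id),
                     is_reference = is_reference,
                     core_classes = core_classes)
  # attach exact domain hits (construction truth, no alignment needed)
  l$domain_hits <- stats::setNames(lapply(seq_len(n), function(i) {
    ds <- domain_strings[[i]]
    if (!length(ds))
      return(data.frame(gene_id = character(), domain = character(),
                        start = integer(), end = integer(),
                        score = numeric(), seq = character()))
    lens <- nchar(panel[ds])
    ends <- cumsum(lens); starts <- ends - lens + 1L
    segs <- substring(proteins[i], starts, ends)
    data.frame(gene_id = genes$gene_id[i], domain = ds,
               start = starts, end = ends, score = lens * 5,
               seq = segs)
  }), genes$gene_id)
  l
}

# The study-condition cohort and its pipeline run, computed once and shared
# by the end-to-end tests (generation + full pipeline take minutes).
acceptance_cohort <- function() cached("cohort", make_cohort(seed = 20240115L))

acceptance_run <- function() cached("run", {
  out <- file.path(tempdir(), "bgcfam_run_a")
  run_pipeline(acceptance_cohort(), pipeline_config(out_dir = out))
})

# Recovered loci joined to truth by (species, first gene, last gene).
acceptance_matches <- function() cached("matches", {
  co <- acceptance_cohort(); res <- acceptance_run()
  rec <- do.call(rbind, lapply(res$loci, function(l) data.frame(
    bgc_id = l$bgc_id, species_id = l$species_id,
    first_gene = l$genes$gene_id[1],
    last_gene = l$genes$gene_id[nrow(l$genes)],
    class_found = l$class, counted_found = isTRUE(l$counted))))
  merge(rec, co$truth$loci, by = c("species_id", "first_gene", "last_gene"))
})
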