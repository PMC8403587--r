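# Annotated-genome I/O and the coordinate model used throughout the package.
#
# Coordinates are 1-based inclusive nucleotide positions (GenBank convention;
# GFF3 needs no conversion). Genes are kept ordered by (contig, start, end,
# gene_id); strand is retained for reporting and adjacency display only --
# proteins are always compared strand-agnostically.

#' Construct a genome object
#'
#' @param species_id Species/strain identifier.
#' @param genes data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{protein}, \code{product}.
#' @param contigs Optional named character vector of contig nucleotide
#'   sequences (required for writing GenBank/FASTA).
#' @param metadata Free-form list (species metadata).
#' @return Object of class \code{"bgc_genome"}.
#' @export
new_genome <- function(species_id, genes, contigs = NULL, metadata = list()) {
  req <- c("gene_id", "contig_id", "start", "end", "strand", "protein", "product")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "))
  genes <- genes[, req]
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id within genome: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(!genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(nchar(genes$protein) < 1L)) stop("empty protein sequence")
  genes <- genes[order(genes$contig_id, genes$start, genes$end, genes$gene_id), ]
  rownames(genes) <- NULL
  structure(list(species_id = species_id, genes = genes,
                 contigs = contigs, metadata = metadata),
            class = "bgc_genome")
}

#' @export
print.bgc_genome <- function(x, ...) {
  cat(sprintf("<bgc_genome> %s: %d genes on %d contig(s)\n",
              x$species_id, nrow(x$genes), length(unique(x$genes$contig_id))))
  invisible(x)
}

# ---- translation helpers -----------------------------------------------

# Translate a joined CDS nucleotide string with the standard code; internal
# stops become X (with a warning naming the gene), a single trailing stop is
# trimmed.
translate_cds <- function(nt, gene_id = "?") {
  nt <- toupper(nt)
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) stop("CDS shorter than one codon for gene ", gene_id)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE)) {
    warning("internal stop codon(s) in CDS of gene ", gene_id,
            "; replaced with X", call. = FALSE)
    aa <- gsub("*", "X", aa, fixed = TRUE)
  }
  if (!nzchar(aa)) stop("CDS of gene ", gene_id, " translates to nothing")
  aa
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# ---- GenBank flat file --------------------------------------------------

# Parse a GenBank location string into a data.frame of spans plus a strand.
# Handles N..M, single positions, join(...), complement(...), partial
# markers < and >.
parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("complement|join", loc))
    stop("unsupported nested location: ", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- lapply(parts, function(p) {
    xs <- strsplit(p, "..", fixed = TRUE)[[1]]
    if (length(xs) == 1L) xs <- c(xs, xs)
    as.integer(xs)
  })
  if (any(vapply(spans, anyNA, TRUE))) stop("malformed location: ", loc)
  list(spans = do.call(rbind, spans), strand = strand)
}

#' Read an annotated genome from a GenBank flat file
#'
#' One gene per CDS feature; multi-exon CDS are joined in feature order.
#' Proteins come from the \code{/translation} qualifier when present,
#' otherwise from standard-code translation of the joined CDS. CDS whose
#' translation contains internal stops are kept with \code{X} at the stop
#' positions (with a warning).
#'
#' @param path GenBank flat file (possibly multi-record; one record per
#'   contig).
#' @param species_id Species identifier; default: file name without extension.
#' @return A [new_genome()] object.
#' @export
read_genbank <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^LOCUS", lines)))
    stop("no records in GenBank file ", path)
  if (is.null(species_id))
    species_id <- tools::file_path_sans_ext(basename(path))
  rec_starts <- grep("^LOCUS", lines)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  genes <- list(); contigs <- character()
  auto <- 0L
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    contig_id <- strsplit(trimws(sub("^LOCUS\\s+", "", rec[1])), "\\s+")[[1]][1]
    # ORIGIN block -> contig sequence
    oi <- grep("^ORIGIN", rec)
    seq_nt <- ""
    if (length(oi)) {
      stop_i <- grep("^//", rec)
      stop_i <- if (length(stop_i)) stop_i[stop_i > oi[1]][1] else length(rec) + 1L
      if (is.na(stop_i)) stop_i <- length(rec) + 1L
      body <- rec[(oi[1] + 1L):(stop_i - 1L)]
      seq_nt <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    contigs[contig_id] <- seq_nt
    # FEATURES block
    fi <- grep("^FEATURES", rec)
    if (!length(fi)) next
    fend <- if (length(oi)) oi[1] - 1L else length(rec)
    feat <- rec[(fi[1] + 1L):fend]
    # feature lines start at column 6; continuation/qualifiers at column 22
    starts <- grep("^     \\S", feat)
    if (!length(starts)) next
    ends <- c(starts[-1] - 1L, length(feat))
    for (k in seq_along(starts)) {
      block <- feat[starts[k]:ends[k]]
      key <- sub("^\\s*(\\S+).*$", "\\1", block[1])
      if (key != "CDS") next
      # location may continue over lines until the first qualifier
      qstart <- grep("^\\s+/", block)
      loc_end <- if (length(qstart)) qstart[1] - 1L else length(block)
      loc <- paste(trimws(sub("^\\s*CDS\\s*", "", block[1])),
                   paste(trimws(block[seq_len(loc_end)[-1]]), collapse = ""),
                   sep = "")
      loc <- gsub("\\s", "", loc)
      pl <- tryCatch(parse_gb_location(loc),
                     error = function(e) stop("malformed record near line ",
                                              rec_starts[r] + fi[1] + starts[k] - 1L,
                                              ": ", conditionMessage(e), call. = FALSE))
      quals <- parse_gb_qualifiers(block[seq(loc_end + 1L, length.out = length(block) - loc_end)])
      gid <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
        quals[["protein_id"]] %||% {
          auto <- auto + 1L; sprintf("%s_cds%03d", contig_id, auto)
        }
      prot <- quals[["translation"]]
      if (is.null(prot)) {
        if (!nzchar(seq_nt))
          stop("CDS ", gid, " has no /translation and record has no sequence")
        spans <- pl$spans
        pieces <- substring(seq_nt, spans[, 1], spans[, 2])
        nt <- paste(pieces, collapse = "")
        if (pl$strand == "-") nt <- revcomp(nt)
        prot <- translate_cds(nt, gid)
      } else {
        prot <- gsub("\\s", "", prot)
        if (grepl("*", prot, fixed = TRUE)) {
          warning("internal stop in /translation of ", gid,
                  "; replaced with X", call. = FALSE)
          prot <- gsub("*", "X", prot, fixed = TRUE)
        }
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, contig_id = contig_id,
        start = min(pl$spans[, 1]), end = max(pl$spans[, 2]),
        strand = pl$strand, protein = prot,
        product = quals[["product"]] %||% "",
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               protein = character(), product = character())
  new_genome(species_id, genes,
             contigs = if (any(nzchar(contigs))) contigs else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_gb_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  # stitch continuation lines onto the preceding qualifier
  is_q <- grepl("^/", txt)
  grp <- cumsum(is_q)
  txt <- txt[grp > 0]; grp <- grp[grp > 0]
  merged <- vapply(split(txt, grp), paste, "", collapse = "")
  out <- list()
  for (q in merged) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)(=(".*"|\\S+))?$', q))[[1]]
    if (length(m) < 2L) next
    val <- m[4]
    val <- gsub('^"|"$', "", val)
    out[[m[2]]] <- val
  }
  out
}

# ---- GFF3 + FASTA -------------------------------------------------------

#' Read an annotated genome from GFF3 + genomic FASTA
#'
#' CDS features are grouped into genes by their \code{ID} (falling back to
#' \code{Parent}); multi-exon CDS are joined in transcription order with the
#' first segment's phase respected. Same gene contract as [read_genbank()].
#'
#' @param gff GFF3 file with CDS features.
#' @param fasta Genomic FASTA whose ids match the GFF seqids.
#' @param species_id Species identifier; default: GFF file name.
#' @return A [new_genome()] object.
#' @export
read_gff_fasta <- function(gff, fasta, species_id = NULL) {
  if (is.null(species_id))
    species_id <- tools::file_path_sans_ext(basename(gff))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  empty <- data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      protein = character(), product = character())
  if (!length(gr))
    return(new_genome(species_id, empty, contigs = as.character(seqs)))
  ids <- as.character(gr$ID)
  if (all(is.na(ids)) && !is.null(gr$Parent))
    ids <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  if (anyNA(ids)) ids[is.na(ids)] <- sprintf("cds%04d", which(is.na(ids)))
  genes <- list()
  for (gid in unique(ids)) {
    part <- gr[ids == gid]
    contig <- as.character(GenomicRanges::seqnames(part))[1]
    if (!contig %in% names(seqs))
      stop("CDS ", gid, " references absent contig ", contig)
    st <- GenomicRanges::start(part); en <- GenomicRanges::end(part)
    if (any(en > nchar(as.character(seqs[[contig]]))) || any(st < 1L))
      stop("CDS ", gid, " has out-of-bounds coordinates on ", contig)
    strand <- as.character(GenomicRanges::strand(part))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    ord <- if (strand == "+") order(st) else order(-en)
    nt <- paste(substring(as.character(seqs[[contig]]), st[ord], en[ord]),
                collapse = "")
    if (strand == "-") nt <- revcomp(nt)
    ph <- suppressWarnings(as.integer(as.character(part$phase[ord][1])))
    if (!is.na(ph) && ph > 0L) nt <- substr(nt, ph + 1L, nchar(nt))
    prot <- translate_cds(nt, gid)
    prod <- ""
    if (!is.null(part$product)) {
      pv <- as.character(part$product)[1]
      if (!is.na(pv)) prod <- pv
    }
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = gid, contig_id = contig, start = min(st), end = max(en),
      strand = strand, protein = prot, product = prod,
      stringsAsFactors = FALSE)
  }
  new_genome(species_id, do.call(rbind, genes), contigs = as.character(seqs))
}

# ---- domain annotation table -------------------------------------------

#' Read a per-gene domain annotation table
#'
#' TSV with header \code{gene_id, domain, start, end, score} giving
#' pre-computed biosynthetic domain hits (e.g. from an external annotator);
#' rows are validated against the controlled domain vocabulary
#' ([domain_vocab()]) and sorted by (gene_id, start).
#'
#' @param path TSV file.
#' @return data.frame of class \code{"domain_annotation_table"}.
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "domain", "start", "end", "score")
  if (!all(req %in% names(tab)))
    stop("domain table must have columns: ", paste(req, collapse = ", "))
  tab <- tab[, req]
  if (nrow(tab)) {
    bad <- setdiff(unique(tab$domain), domain_vocab())
    if (length(bad))
      stop("unknown domain name(s): ", paste(bad, collapse = ", "),
           "; vocabulary: ", paste(domain_vocab(), collapse = ", "))
    if (any(tab$end < tab$start)) stop("domain row with end < start")
    if (any(tab$start < 1L)) stop("domain row with start < 1")
    tab <- tab[order(tab$gene_id, tab$start), ]
    rownames(tab) <- NULL
  }
  class(tab) <- c("domain_annotation_table", "data.frame")
  tab
}

# ---- BGC GFF3 output ----------------------------------------------------

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write BGC loci as GFF3
#'
#' One \code{biosynthetic_gene_cluster} feature per locus plus one child
#' \code{gene} feature per member gene (1-based inclusive coordinates).
#'
#' @param loci List of BGC loci (see [extend_locus()]).
#' @param path Output file.
#' @export
write_bgc_gff <- function(loci, path) {
  out <- "##gff-version 3"
  for (l in loci) {
    g <- l$genes
    attrs <- sprintf(
      "ID=%s;species=%s;class=%s;core_genes=%s;is_reference=%s",
      gff_escape(l$bgc_id), gff_escape(l$species_id),
      gff_escape(if (is.null(l$class) || is.na(l$class)) "unclassified" else l$class),
      gff_escape(paste(sort(l$core_gene_ids), collapse = ",")),
      tolower(isTRUE(l$is_reference)))
    out <- c(out, paste(l$contig_id, "bgcfam", "biosynthetic_gene_cluster",
                        min(g$start), max(g$end), ".", ".", ".", attrs,
                        sep = "\t"))
    for (i in seq_len(nrow(g))) {
      ga <- sprintf("ID=%s;Parent=%s;role=%s;product=%s",
                    gff_escape(g$gene_id[i]), gff_escape(l$bgc_id),
                    gff_escape(l$gene_roles[[g$gene_id[i]]] %||% "unrelated"),
                    gff_escape(g$product[i]))
      out <- c(out, paste(l$contig_id, "bgcfam", "gene", g$start[i], g$end[i],
                          ".", g$strand[i], ".", ga, sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read BGC loci back from a GFF3 written by [write_bgc_gff()]
#'
#' Requires the genome the loci were called on, to restore protein sequences.
#'
#' @param path GFF3 file.
#' @param genome The [new_genome()] object the loci belong to.
#' @return List of BGC loci.
#' @export
read_bgc_gff <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(list())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attrs <- lapply(f[, 9], function(a) {
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) gsub("%3B", ";", gsub("%2C", ",",
      gsub("%3D", "=", gsub("%25", "%", x[2], fixed = TRUE), fixed = TRUE),
      fixed = TRUE), fixed = TRUE), ""), vapply(kv, `[`, "", 1))
  })
  is_bgc <- f[, 3] == "biosynthetic_gene_cluster"
  loci <- list()
  for (i in which(is_bgc)) {
    a <- attrs[[i]]
    bgc_id <- a[["ID"]]
    kid <- which(!is_bgc & vapply(attrs, function(x)
      identical(unname(x["Parent"]), bgc_id), TRUE))
    gene_ids <- vapply(attrs[kid], function(x) unname(x["ID"]), "")
    roles <- stats::setNames(
      vapply(attrs[kid], function(x) unname(x["role"]), ""), gene_ids)
    g <- genome$genes[match(gene_ids, genome$genes$gene_id), ]
    if (anyNA(g$gene_id))
      stop("locus ", bgc_id, " references genes absent from the genome")
    g <- g[order(g$start), ]; rownames(g) <- NULL
    cls <- a[["class"]]
    loci[[length(loci) + 1L]] <- new_bgc_locus(
      bgc_id = bgc_id, species_id = a[["species"]],
      contig_id = f[i, 1], genes = g,
      core_gene_ids = strsplit(a[["core_genes"]], ",", fixed = TRUE)[[1]],
      gene_roles = as.list(roles),
      class = if (identical(cls, "unclassified")) NA_character_ else cls,
      is_reference = identical(a[["is_reference"]], "true"))
  }
  loci
}

# ---- genome writers (used by the synthetic cohort generator) ------------

format_gb_seq <- function(nt) {
  n <- nchar(nt)
  out <- character()
  for (pos in seq(1L, n, by = 60L)) {
    chunk <- substring(nt, pos, min(pos + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", pos, paste(tolower(groups), collapse = " ")))
  }
  out
}

wrap_qualifier <- function(text, width = 58L) {
  starts <- seq(1L, nchar(text), by = width)
  paste0("                     ",
         substring(text, starts, pmin(starts + width - 1L, nchar(text))))
}

#' Write a genome as a GenBank flat file
#'
#' One record per contig, CDS features with \code{/locus_tag},
#' \code{/product} and \code{/translation}, and the contig sequence in the
#' ORIGIN block. Requires contig sequences on the genome object.
#'
#' @param genome A [new_genome()] object with contig sequences.
#' @param path Output file.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$contigs)) stop("genome has no contig sequences")
  out <- character()
  for (contig in names(genome$contigs)) {
    nt <- genome$contigs[[contig]]
    out <- c(out, sprintf(
      "LOCUS       %s %d bp    DNA     linear   PLN 01-JAN-2024",
      contig, nchar(nt)),
      sprintf("DEFINITION  %s synthetic contig.", genome$species_id),
      sprintf("SOURCE      %s", genome$species_id),
      "FEATURES             Location/Qualifiers")
    g <- genome$genes[genome$genes$contig_id == contig, ]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i], g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      tr <- paste0('/translation="', g$protein[i], '"')
      out <- c(out,
        sprintf("     CDS             %s", loc),
        sprintf('                     /locus_tag="%s"', g$gene_id[i]),
        if (nzchar(g$product[i]))
          sprintf('                     /product="%s"', g$product[i]),
        wrap_qualifier(tr))
    }
    out <- c(out, "ORIGIN", format_gb_seq(nt), "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a genome as GFF3 + genomic FASTA
#'
#' @param genome A [new_genome()] object with contig sequences.
#' @param gff,fasta Output paths.
#' @export
write_gff_fasta <- function(genome, gff, fasta) {
  if (is.null(genome$contigs)) stop("genome has no contig sequences")
  out <- "##gff-version 3"
  for (contig in names(genome$contigs))
    out <- c(out, sprintf("##sequence-region %s 1 %d", contig,
                          nchar(genome$contigs[[contig]])))
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf("ID=%s;product=%s", gff_escape(g$gene_id[i]),
                     gff_escape(g$product[i]))
    out <- c(out, paste(g$contig_id[i], "bgcfam", "CDS", g$start[i], g$end[i],
                        ".", g$strand[i], "0", attrs, sep = "\t"))
  }
  writeLines(out, gff)
  write_fasta(as.list(genome$contigs) |> stats::setNames(names(genome$contigs)),
              fasta)
  invisible(gff)
}
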