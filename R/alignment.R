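# Protein local alignment and similarity statistics.
#
# All similarity decisions in the pipeline (core-gene detection, neighbour
# function calls, DSI, synteny links) run through this module: Smith-Waterman
# local alignment under BLOSUM62 with affine gap cost 11/1, and a
# Karlin-Altschul E-value on the raw score.

# Published Karlin-Altschul parameters for gapped BLOSUM62 with gap cost 11/1.
KA_CALIBRATION <- list(lambda = 0.267, K = 0.041)

#' Scoring scheme for protein local alignment
#'
#' Bundles a substitution matrix with affine gap penalties. The default is
#' BLOSUM62 with gap open 11 and gap extension 1, i.e. a gap of length L costs
#' \code{11 + L}. The unknown residue \code{X} scores 0 against everything.
#'
#' @param matrix Square integer substitution matrix with amino-acid dimnames,
#'   or \code{NULL} for BLOSUM62.
#' @param gap_open Positive gap opening penalty.
#' @param gap_extend Positive per-residue gap extension penalty.
#' @param lambda,K Karlin-Altschul calibration constants used by
#'   [evalue()]. Defaults are the published gapped-BLOSUM62 pair.
#' @return An object of class \code{"scoring_scheme"}.
#' @export
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["W", "W"]
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = KA_CALIBRATION$lambda,
                           K = KA_CALIBRATION$K) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            identical(rownames(matrix), colnames(matrix)))
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (gap_extend < 1L || gap_open < gap_extend)
    stop("require gap_open >= gap_extend >= 1")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

# BLOSUM62 restricted to the 20 amino acids plus X, with X scoring 0
# against everything (including itself).
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format used by NCBI BLAST
#' (comment lines starting with \code{#}, a header row of residue letters,
#' then one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(0L, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, "", 1L), header))
  for (i in seq_along(rows)) m[i, ] <- as.integer(rows[[i]][-1])
  m
}

default_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- scoring_scheme()
    cache
  }
})

as_scheme <- function(scheme) {
  if (is.null(scheme)) default_scheme()
  else if (inherits(scheme, "scoring_scheme")) scheme
  else stop("'scheme' must be a scoring_scheme")
}

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' \deqn{E = K m n e^{-\lambda S}}
#' where \eqn{m} is the query length and \eqn{n} the total residue count of
#' the searched database (one subject sequence, or a whole proteome).
#'
#' @param score Raw Smith-Waterman score (non-negative).
#' @param query_len,db_len Query length and total database length in residues.
#' @param scheme A [scoring_scheme()] carrying the calibration constants.
#' @return Expected number of chance hits with at least this score.
#' @export
evalue <- function(score, query_len, db_len, scheme = NULL) {
  scheme <- as_scheme(scheme)
  if (any(score < 0)) stop("score must be >= 0")
  scheme$K * as.numeric(query_len) * as.numeric(db_len) *
    exp(-scheme$lambda * as.numeric(score))
}

# Vectorised local-alignment scores of many queries against one subject.
# Used internally wherever only scores are needed (detection, role calls).
local_scores <- function(queries, subject, scheme = NULL) {
  scheme <- as_scheme(scheme)
  q <- Biostrings::AAStringSet(queries)
  as.numeric(Biostrings::pairwiseAlignment(
    q, Biostrings::AAString(subject), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE))
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under affine gaps (a gap of length L costs
#' \code{gap_open + L * gap_extend}, the BLAST convention for "11 1").
#' Identity and similarity are computed over the aligned columns of the
#' optimal traceback, gaps included in the denominator; a column is "similar"
#' when its residues are identical or have a positive substitution score.
#'
#' @param a,b Non-empty protein strings over the 20 amino acids plus X.
#' @param scheme A [scoring_scheme()]; default BLOSUM62 11/1.
#' @param db_len Database length used for the E-value; defaults to
#'   \code{nchar(b)} (single-subject search).
#' @return An object of class \code{"alignment_result"}: a list with
#'   \code{score}, \code{aln_len}, \code{identity_pct}, \code{similarity_pct},
#'   \code{evalue}, \code{query_cov}, \code{subject_cov},
#'   \code{query_range}, \code{subject_range}, and the aligned strings.
#' @export
#' @examples
#' r <- local_align("MKWVTFISLL", "MKWVTFISLL")
#' r$identity_pct  # 100
local_align <- function(a, b, scheme = NULL, db_len = nchar(b)) {
  check_protein(a, "a"); check_protein(b, "b")
  scheme <- as_scheme(scheme)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(
      score = 0, aln_len = 0L, identity_pct = 0, similarity_pct = 0,
      evalue = evalue(0, nchar(a), db_len, scheme),
      query_cov = 0, subject_cov = 0,
      query_range = c(NA_integer_, NA_integer_),
      subject_range = c(NA_integer_, NA_integer_),
      aligned_query = "", aligned_subject = ""),
      class = "alignment_result"))
  }
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(pat, "")[[1]]; sc2 <- strsplit(sub, "")[[1]]
  aln_len <- length(pc)
  nongap <- pc != "-" & sc2 != "-"
  ident <- nongap & pc == sc2
  pos <- ident
  if (any(nongap & !ident)) {
    idx <- which(nongap & !ident)
    pos[idx] <- scheme$matrix[cbind(pc[idx], sc2[idx])] > 0
  }
  qr <- c(Biostrings::start(Biostrings::pattern(pa)),
          Biostrings::end(Biostrings::pattern(pa)))
  sr <- c(Biostrings::start(Biostrings::subject(pa)),
          Biostrings::end(Biostrings::subject(pa)))
  structure(list(
    score = sc, aln_len = aln_len,
    identity_pct = 100 * sum(ident) / aln_len,
    similarity_pct = 100 * sum(pos) / aln_len,
    evalue = evalue(sc, nchar(a), db_len, scheme),
    query_cov = 100 * (qr[2] - qr[1] + 1L) / nchar(a),
    subject_cov = 100 * (sr[2] - sr[1] + 1L) / nchar(b),
    query_range = as.integer(qr), subject_range = as.integer(sr),
    aligned_query = pat, aligned_subject = sub),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "local alignment: score %.0f, length %d, identity %.1f%%, similarity %.1f%%, E = %.3g\n",
    x$score, x$aln_len, x$identity_pct, x$similarity_pct, x$evalue))
  invisible(x)
}

#' Best database hit for a query protein
#'
#' Aligns the query against every database entry and returns the
#' highest-scoring hit whose E-value (computed against the total database
#' length, BLAST-style) does not exceed \code{max_evalue}. Ties are broken by
#' lower E-value, then lexicographic id.
#'
#' @param query Protein string.
#' @param db Named character vector of protein sequences (names are ids).
#' @param scheme A [scoring_scheme()].
#' @param max_evalue Maximum E-value for a reportable hit.
#' @return \code{NULL} if no hit passes, otherwise a list with \code{id} and
#'   \code{result} (an \code{alignment_result} whose E-value uses the full
#'   database length).
#' @export
best_hit <- function(query, db, scheme = NULL, max_evalue = 1e-1) {
  check_protein(query, "query")
  if (length(db) == 0L) return(NULL)
  if (is.null(names(db)) || anyNA(names(db)) || any(!nzchar(names(db))))
    stop("db must be a named vector of proteins")
  scheme <- as_scheme(scheme)
  n_db <- sum(nchar(db))
  sc <- local_scores(db, query, scheme)   # symmetric: score(a,b)=score(b,a)
  ev <- evalue(pmax(sc, 0), nchar(query), n_db, scheme)
  keep <- which(ev <= max_evalue & sc > 0)
  if (!length(keep)) return(NULL)
  ord <- keep[order(-sc[keep], ev[keep], names(db)[keep])]
  i <- ord[1L]
  res <- local_align(query, db[[i]], scheme, db_len = n_db)
  list(id = names(db)[i], result = res)
}
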