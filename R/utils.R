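# Internal helpers shared across modules.

# The 20 proteinogenic amino acids; X is the only additional symbol the
# package accepts in protein sequences.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Background amino-acid frequencies (Robinson & Robinson-style composition,
# normalised); used by the synthetic sequence generator and BLOSUM-biased
# mutation.
AA_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.065)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded generation never disturbs
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a parent seed and a label, staying inside the
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

check_protein <- function(p, what = "protein") {
  if (!is.character(p) || length(p) != 1L || is.na(p) || nchar(p) < 1L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  bad <- setdiff(unique(strsplit(p, "")[[1]]), c(AA20, "X"))
  if (length(bad))
    stop(what, " contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

# Stable file path to bundled reference data.
bgcfam_extdata <- function(...) {
  system.file("extdata", ..., package = "bgcfam", mustWork = TRUE)
}

# Simple FASTA writer for plain character vectors (names become headers).
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_fasta_chr <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
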