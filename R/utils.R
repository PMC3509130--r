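# Internal helpers shared across modules.

# The 20 standard residues; X marks ambiguity.
AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# Approximate natural amino-acid frequencies (Swiss-Prot order as above),
# used by the synthetic sequence generator.
AA_FREQS <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
              Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
              L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
              S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686)

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed; stays below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483629)
}

valid_sequence <- function(x) {
  nzchar(x) & !grepl(paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]"), x)
}

check_sequences <- function(x, what = "sequence") {
  bad <- !valid_sequence(x)
  if (any(bad)) {
    stop(sprintf("invalid %s (empty or non-standard residues): %s",
                 what, paste(head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves after K/R, suppressed before P, and enumerates peptides with up to
#' `max_mc` missed cleavages. Protein termini count as valid boundaries;
#' flanking residues are recorded (`"-"` for a terminus).
#'
#' @param sequence amino-acid string.
#' @param max_mc maximum internal missed cleavages (default 4).
#' @param min_len minimum peptide length retained (default 6).
#' @return data.frame with columns `peptide`, `start`, `end`, `prev_aa`,
#'   `next_aa`, `n_mc`.
#' @examples
#' digest_protein("MAAAGGGKEEEFFFRHHHIIIK", max_mc = 1)
#' @export
digest_protein <- function(sequence, max_mc = 4, min_len = 6) {
  check_sequences(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  k <- length(starts)
  idx <- which(outer(seq_len(k), seq_len(k), function(i, j) j >= i & j - i <= max_mc),
               arr.ind = TRUE)
  s <- starts[idx[, 1]]
  e <- ends[idx[, 2]]
  mc <- idx[, 2] - idx[, 1]
  keep <- (e - s + 1L) >= min_len
  s <- s[keep]; e <- e[keep]; mc <- mc[keep]
  data.frame(
    peptide = substring(sequence, s, e),
    start = s, end = e,
    prev_aa = ifelse(s == 1L, "-", aa[pmax(s - 1L, 1L)]),
    next_aa = ifelse(e == n, "-", aa[pmin(e + 1L, n)]),
    n_mc = mc,
    stringsAsFactors = FALSE
  )
}

#' Count internal missed tryptic cleavage sites in a peptide
#'
#' An internal K/R not followed by P (the C-terminal residue is the peptide
#' boundary, not a missed site).
#'
#' @param peptide amino-acid string(s).
#' @return integer vector.
#' @export
count_missed_cleavages <- function(peptide) {
  vapply(strsplit(peptide, "", fixed = TRUE), function(aa) {
    n <- length(aa)
    if (n < 2L) return(0L)
    sum(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  }, integer(1))
}

# Deterministic TSV writer (fixed quoting/eol so outputs are byte-stable).
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", quote = "", ...)
}
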