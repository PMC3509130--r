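# Readers/writers for the package's external formats: FASTA, PSM tables,
# run metadata, cluster tables and module definitions. All tab-delimited
# files carry a header row and are written deterministically.

#' Write protein sequences to FASTA
#'
#' @param proteins data.frame with `id`, `sequence` (or a named character
#'   vector).
#' @param path output file.
#' @export
write_fasta <- function(proteins, path) {
  if (is.data.frame(proteins)) {
    seqs <- setNames(proteins$sequence, proteins$id)
  } else seqs <- proteins
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a protein FASTA into a data.frame
#'
#' @param path FASTA file.
#' @return data.frame with `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read / write PSM tables
#'
#' Tab-delimited with header: spectrum_id, run_id, sample_id, peptide,
#' prev_aa, next_aa, charge, xcorr, deltcn, ppm_error, protein_ids
#' (semicolon-separated), is_decoy.
#'
#' @param path file path.
#' @return data.frame in the PSM schema.
#' @export
read_psm_table <- function(path) {
  psms <- read_tsv(path, colClasses = c(peptide = "character",
                                        prev_aa = "character",
                                        next_aa = "character"))
  needed <- c("spectrum_id", "run_id", "sample_id", "peptide", "prev_aa",
              "next_aa", "charge", "xcorr", "deltcn", "ppm_error",
              "protein_ids", "is_decoy")
  miss <- setdiff(needed, names(psms))
  if (length(miss))
    stop("PSM table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms
}

#' @rdname read_psm_table
#' @param psms data.frame in the PSM schema.
#' @export
write_psm_table <- function(psms, path) write_tsv(psms, path)

#' Read run metadata
#'
#' Tab-delimited: run_id, sample_id, pair_id (optional), group, n_i
#' (optional).
#' @param path file path.
#' @export
read_run_metadata <- function(path) read_tsv(path)

#' Read KO-to-module definitions
#'
#' Tab-delimited with columns module_id, ko_id.
#' @param path file path.
#' @export
read_module_defs <- function(path) {
  defs <- read_tsv(path)
  stopifnot(all(c("module_id", "ko_id") %in% names(defs)))
  defs
}

# Wide count matrix <-> TSV with a feature_id first column.
write_count_matrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_count_matrix <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  m
}
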