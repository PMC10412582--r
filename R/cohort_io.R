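# Readers and writers for the pipeline's tabular inputs: expression TSV,
# MAF-style mutation tables, clinical tables and GMT genesets.

#' Standard MAF variant-classification vocabulary
#'
#' @return Character vector of the recognised Variant_Classification strings.
#' @export
maf_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site", "Silent",
    "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
    "Targeted_Region")
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated table with genes as rows (first column gene ids) and
#' a header row of sample ids.  Unless `already_log_transformed` is TRUE the
#' values are interpreted as TPM and transformed to log2(TPM + 0.001), the
#' storage scale used throughout the package.  Duplicate gene rows are
#' resolved by keeping the first occurrence; duplicate sample ids and
#' non-numeric or missing cells are errors.
#'
#' @param path Path to the TSV file.
#' @param already_log_transformed Set TRUE when the file already holds
#'   log2(TPM + 0.001) values; they are then passed through unchanged.
#' @return Numeric matrix (genes x samples) on the log2(TPM + 0.001) scale.
#' @export
read_expression <- function(path, already_log_transformed = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression file needs a gene column and >=1 sample")
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  gene_ids <- raw[[1L]]
  vals <- as.matrix(raw[-1L])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  keep <- !duplicated(gene_ids)
  num <- num[keep, , drop = FALSE]
  dimnames(num) <- list(gene_ids[keep], sample_ids)
  if (!already_log_transformed) {
    if (any(num < 0)) stop("negative TPM value in expression file")
    num <- log2(num + TPM_PSEUDOCOUNT)
  }
  num
}

#' Keep one sample per patient by highest median expression
#'
#' Among a patient's samples the one with the highest median stored expression
#' is kept; ties are broken in favour of the sample appearing first in the
#' matrix (file order).  Samples without an entry in `patient_map` are kept
#' as their own patient.
#'
#' @param mat Expression matrix (genes x samples).
#' @param patient_map Named character vector mapping sample id -> patient id.
#' @return The matrix restricted to the selected samples (original column
#'   order preserved).
#' @export
dedup_samples <- function(mat, patient_map) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) == 0L) stop("empty expression matrix")
  ids <- colnames(mat)
  patient <- ifelse(ids %in% names(patient_map), patient_map[ids], ids)
  med <- apply(mat, 2L, stats::median)
  keep <- logical(ncol(mat))
  for (p in unique(patient)) {
    idx <- which(patient == p)
    keep[idx[which.max(med[idx])]] <- TRUE  # which.max: first wins on ties
  }
  mat[, keep, drop = FALSE]
}

#' Read genesets from a GMT file
#'
#' Each line holds the set name, a description and one gene per remaining
#' field.  Duplicate members within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (geneset name -> member genes).
#' @export
read_genesets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("malformed GMT line %d: no gene members", i))
    sets[[fields[1L]]] <- members
  }
  sets
}

#' Write genesets to a GMT file
#'
#' @param genesets Named list of character vectors.
#' @param path Output path.
#' @export
write_genesets <- function(genesets, path) {
  stopifnot(is.list(genesets), length(names(genesets)) == length(genesets))
  lines <- vapply(names(genesets), function(nm) {
    paste(c(nm, "na", genesets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Read a MAF-style somatic mutation table
#'
#' Requires the columns `Tumor_Sample_Barcode`, `Hugo_Symbol` and
#' `Variant_Classification`; other columns are preserved.  Classification
#' strings outside the standard MAF vocabulary are kept but flagged in the
#' logical column `known_class` (with a warning naming each unknown string
#' once).
#'
#' @param path Path to the tab-separated file; lines starting with `#` are
#'   skipped.
#' @return Data frame of mutation records.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MAF file missing required column(s): ", paste(miss, collapse = ", "))
  df$known_class <- df$Variant_Classification %in% maf_classes()
  if (!all(df$known_class)) {
    unk <- unique(df$Variant_Classification[!df$known_class])
    warning("unknown Variant_Classification string(s): ",
            paste(unk, collapse = ", "))
  }
  df
}

#' Read a clinical / annotation table
#'
#' One row per sample.  Survival-time columns (any of `ttp_days`, `os_days`,
#' `treatment_duration_days`) must be nonnegative and event indicators
#' (`ttp_event`, `os_event`, `progressed`) binary.  Optional genomic-score
#' columns (`mantis`, `hrd_score`, `msisensor`, `hrdetect`) may contain NA.
#'
#' @param path Path to the tab-separated file with header.
#' @return Data frame, one validated row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in clinical table")
  for (col in intersect(c("ttp_days", "os_days", "treatment_duration_days"),
                        names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0))
      stop(sprintf("negative survival/duration time in column '%s'", col))
  }
  for (col in intersect(c("ttp_event", "os_event", "progressed"), names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & !v %in% c(0, 1)))
      stop(sprintf("event column '%s' must be binary 0/1", col))
  }
  df
}

#' Write an expression matrix as a TPM TSV
#'
#' Inverts the storage transform (TPM = 2^value - 0.001) so the written file
#' is on the TPM scale expected by [read_expression()] with
#' `already_log_transformed = FALSE`.
#'
#' @param mat Matrix on the log2(TPM + 0.001) scale.
#' @param path Output path.
#' @param scale `"tpm"` (default) or `"log"` to write stored values as-is.
#' @export
write_expression <- function(mat, path, scale = c("tpm", "log")) {
  scale <- match.arg(scale)
  out <- if (scale == "tpm") pmax(2^mat - TPM_PSEUDOCOUNT, 0) else mat
  df <- data.frame(gene_id = rownames(mat), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a tidy table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
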