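# Tumor mutational burden, protein-truncating classification, DNA-repair
# pathway mutation rates, and KRAS status from MAF-style records.

#' Non-silent MAF classes counted for TMB by default
#'
#' The default counted set excludes Silent, UTR/flank, intronic, intergenic
#' and RNA records; it is configuration, not a claim of bit-equivalence with
#' any particular variant-calling pipeline, and is recorded on the result.
#'
#' @return Character vector of Variant_Classification strings.
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' The six protein-truncating MAF classes
#' @return Character vector.
#' @export
truncating_classes <- function() {
  c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonsense_Mutation",
    "Splice_Site", "Translation_Start_Site", "Nonstop_Mutation")
}

#' DNA repair and fidelity pathway gene sets
#'
#' Mismatch repair (MMR), homologous recombination (HR) and DNA
#' replication/proofreading genes considered in the pathway mutation-rate
#' analyses; membership is fixed.
#'
#' @return Named list of character vectors `mmr`, `hr`, `replication`.
#' @export
pathway_genes <- function() {
  list(mmr = c("MLH1", "MSH2", "MSH6", "PMS2"),
       hr = c("BRCA1", "BRCA2", "PALB2"),
       replication = c("POLE", "POLD1"))
}

#' Per-sample tumor mutational burden
#'
#' TMB is the number of counted mutations divided by the exome capture size
#' in megabases (default 35.8 Mb).  Samples listed in `samples` but absent
#' from the mutation table receive a count of zero.  A sample is TMB-high
#' when its burden is at least 10 mutations per megabase (inclusive
#' boundary).
#'
#' @param maf Mutation table with columns `Tumor_Sample_Barcode` and
#'   `Variant_Classification` (e.g. from [read_maf()]).
#' @param samples Optional character vector of all cohort sample ids;
#'   defaults to the samples present in `maf`.
#' @param capture_size_mb Capture size in megabases; must be positive.
#' @param counted_classes Variant classes counted; default the non-silent
#'   set of [nonsilent_classes()].
#' @param tmb_hi_cutoff Mutations/Mb at or above which a sample is `hi`.
#' @return Data frame with columns `sample_id`, `counted_mutations`, `tmb`
#'   and `tmb_class` (factor hi/lo); `capture_size_mb` and the counted class
#'   set are attached as attributes.
#' @export
compute_tmb <- function(maf, samples = NULL, capture_size_mb = 35.8,
                        counted_classes = nonsilent_classes(),
                        tmb_hi_cutoff = 10) {
  if (!is.numeric(capture_size_mb) || capture_size_mb <= 0)
    stop("capture_size_mb must be positive")
  stopifnot(all(c("Tumor_Sample_Barcode", "Variant_Classification") %in%
                  names(maf)))
  if (is.null(samples)) samples <- unique(maf$Tumor_Sample_Barcode)
  counted <- maf[maf$Variant_Classification %in% counted_classes, ]
  n <- table(factor(counted$Tumor_Sample_Barcode, levels = samples))
  tmb <- as.numeric(n) / capture_size_mb
  out <- data.frame(
    sample_id = samples,
    counted_mutations = as.integer(n),
    tmb = tmb,
    tmb_class = factor(ifelse(tmb >= tmb_hi_cutoff, "hi", "lo"),
                       levels = c("hi", "lo")),
    stringsAsFactors = FALSE
  )
  attr(out, "capture_size_mb") <- capture_size_mb
  attr(out, "counted_classes") <- counted_classes
  out
}

.truncating_warned <- new.env(parent = emptyenv())

#' Is a variant classification protein-truncating?
#'
#' TRUE exactly for frameshift deletions/insertions, nonsense, splice-site,
#' translation-start-site and nonstop mutations.  Strings outside the
#' standard MAF vocabulary are never truncating and trigger a warning once
#' per distinct string per session.
#'
#' @param variant_classification Character vector of MAF classification
#'   strings.
#' @return Logical vector.
#' @export
is_protein_truncating <- function(variant_classification) {
  unknown <- setdiff(unique(variant_classification), maf_classes())
  new_unknown <- setdiff(unknown, ls(.truncating_warned))
  if (length(new_unknown)) {
    for (u in new_unknown) assign(u, TRUE, envir = .truncating_warned)
    warning("unknown Variant_Classification string(s) treated as non-truncating: ",
            paste(new_unknown, collapse = ", "))
  }
  variant_classification %in% truncating_classes()
}

#' Per-group mutation rates in a gene set
#'
#' For each group, reports the count rate (mutation records in the gene set
#' divided by patients in the group) and the patient fraction (patients with
#' at least one such mutation divided by patients in the group), both overall
#' and restricted to protein-truncating records.
#'
#' @param maf Mutation table.
#' @param groups Named vector mapping sample id -> group label; its names
#'   define the cohort (denominators).
#' @param genes Character vector of gene symbols (may be empty).
#' @return Data frame, one row per group: `group`, `n_patients`,
#'   `count_rate`, `patient_fraction`, `truncating_count_rate`,
#'   `truncating_patient_fraction`.
#' @export
pathway_mutation_rates <- function(maf, groups, genes) {
  stopifnot(!is.null(names(groups)))
  glev <- unique(as.character(groups))
  hits <- maf[maf$Hugo_Symbol %in% genes &
                maf$Tumor_Sample_Barcode %in% names(groups), ]
  trunc_hits <- hits[is_protein_truncating(hits$Variant_Classification), ]
  one_group <- function(g) {
    ids <- names(groups)[groups == g]
    h <- hits[hits$Tumor_Sample_Barcode %in% ids, ]
    th <- trunc_hits[trunc_hits$Tumor_Sample_Barcode %in% ids, ]
    data.frame(group = g, n_patients = length(ids),
               count_rate = nrow(h) / length(ids),
               patient_fraction = length(unique(h$Tumor_Sample_Barcode)) /
                 length(ids),
               truncating_count_rate = nrow(th) / length(ids),
               truncating_patient_fraction =
                 length(unique(th$Tumor_Sample_Barcode)) / length(ids),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(glev, one_group))
}

#' KRAS mutation status per sample
#'
#' A sample is `mutated` when it carries at least one KRAS record of a
#' non-silent class, otherwise `wt`.  When tumor types are supplied the
#' per-type prevalence (fraction mutated) is attached.
#'
#' @param maf Mutation table.
#' @param samples Character vector of cohort sample ids.
#' @param tumor_type Optional vector of tumor types aligned with `samples`.
#' @return Data frame with `sample_id`, `kras` (factor wt/mutated) and, when
#'   types are given, a `"prevalence"` attribute (named fraction per type).
#' @export
kras_status <- function(maf, samples, tumor_type = NULL) {
  hits <- maf[maf$Hugo_Symbol == "KRAS" &
                maf$Variant_Classification %in% nonsilent_classes(), ]
  mutated <- samples %in% hits$Tumor_Sample_Barcode
  out <- data.frame(sample_id = samples,
                    kras = factor(ifelse(mutated, "mutated", "wt"),
                                  levels = c("wt", "mutated")),
                    stringsAsFactors = FALSE)
  if (!is.null(tumor_type)) {
    out$tumor_type <- rep_len(tumor_type, length(samples))
    attr(out, "prevalence") <-
      tapply(mutated, out$tumor_type, mean)
  }
  out
}
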