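read_extdata_tsv <- function(file, ...) {
  path <- system.file("extdata", file, package = "tyGCR", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

#' Published fluctuation-assay survey rates
#'
#' The bundled GCR-rate survey table: per genotype, the rates in the -Ty
#' and +Ty912 assays with their fold changes over wild type, censoring
#' flags for "<" upper bounds, and the IA-IIIB mutation class.
#'
#' @return A `data.frame` with columns `grouping`, `genotype`,
#'   `rate_minusTy`, `censored_minusTy`, `fold_minusTy`, `rate_plusTy912`,
#'   `censored_plusTy912`, `fold_plusTy912`, `mutation_class`.
#' @examples
#' rates <- ty_survey_rates()
#' wt <- rates[rates$genotype == "wild_type", ]
#' fold_change(wt$rate_plusTy912, wt$rate_minusTy)$rounded  # 380
#' @export
ty_survey_rates <- function() {
  read_extdata_tsv("published_gcr_rates.tsv")
}

#' Published GCR class counts
#'
#' The bundled per-genotype Class I-V event counts from the aCGH survey;
#' the `all_genotypes` row totals the 88 +Ty912 isolates.
#'
#' @return A `data.frame` with columns `genotype`, `assay`, and `class_I`
#'   through `class_V`.
#' @export
ty_survey_class_counts <- function() {
  read_extdata_tsv("gcr_class_counts.tsv")
}

#' Published rearranged chromosome V size accounting
#'
#' Observed rearranged ChrV sizes alongside the deleted and duplicated
#' region sizes from aCGH, the inputs to [predict_chromosome_size()].
#'
#' @return A `data.frame` with columns `isolate`, `observed_kb`,
#'   `deleted_kb`, `duplicated_kb`, `duplicated_region`.
#' @export
ty_survey_size_accounting <- function() {
  read_extdata_tsv("chrV_size_accounting.tsv")
}

#' Published junction breakpoint intervals
#'
#' The sequenced Ty fusion junctions with their SNP-derived crossover
#' intervals in assay-element coordinates.
#'
#' @return A `data.frame` with columns `isolate`, `ectopic_ty`,
#'   `breakpoint_intervals`, `recombination`, `method`.
#' @export
ty_survey_junctions <- function() {
  read_extdata_tsv("junction_breakpoints.tsv")
}
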