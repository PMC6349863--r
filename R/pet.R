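# Amyloid PET summary: global cortical uptake ratio over cerebellum and the
# positivity call.

#' Global PET uptake ratio
#'
#' Mean uptake over the composite cortical regions divided by the reference
#' (cerebellar) uptake.
#'
#' @param uptake_row One row of a regional uptake table (data.frame or named
#'   vector/list with one value per region).
#' @param composite_regions Region labels entering the composite mean.
#' @param reference_region Reference region label (default cerebellum).
#' @return The global uptake ratio (positive real).
#' @export
compute_global_pet_ratio <- function(uptake_row,
                                     composite_regions = c("frontal", "parietal",
                                                           "temporal",
                                                           "posterior_cingulate"),
                                     reference_region = "cerebellum") {
  vals <- as.list(uptake_row)
  miss <- setdiff(c(composite_regions, reference_region), names(vals))
  if (length(miss) > 0) {
    data_error(sprintf("uptake table missing region(s): %s",
                       paste(miss, collapse = ", ")))
  }
  ref <- as.numeric(vals[[reference_region]])
  if (!is.finite(ref) || ref <= 0) {
    data_error("reference-region uptake must be positive")
  }
  mean(vapply(composite_regions, function(r) as.numeric(vals[[r]]), numeric(1))) / ref
}

#' Amyloid positivity from the global uptake ratio
#'
#' Positive if the ratio is strictly greater than the threshold (1.5); a
#' ratio of exactly 1.5 is negative.
#'
#' @param ratio Global uptake ratio.
#' @param threshold Positivity cutoff.
#' @return Logical.
#' @export
classify_amyloid <- function(ratio, threshold = 1.5) {
  if (any(!is.finite(ratio))) data_error("uptake ratio must be finite")
  ratio > threshold
}

#' Amyloid positivity for every subject of a PET table
#'
#' @param pet_table Output of [generate_pet_table()] or a compatible table.
#' @param ... Passed to [compute_global_pet_ratio()] / [classify_amyloid()].
#' @return data.frame with `subject_id`, `ratio`, `positive`.
#' @export
classify_pet_table <- function(pet_table, ...) {
  ratios <- vapply(seq_len(nrow(pet_table)), function(i) {
    compute_global_pet_ratio(pet_table[i, setdiff(names(pet_table), "subject_id")])
  }, numeric(1))
  data.frame(subject_id = pet_table$subject_id, ratio = ratios,
             positive = classify_amyloid(ratios, ...),
             stringsAsFactors = FALSE)
}
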