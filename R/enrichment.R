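#' Build a target panel table
#'
#' @param target Target names.
#' @param class `"CC"` or `"CXnC"` for chemokine targets (`NA` for the
#'   control).
#' @param type Optional chemokine type: inflammatory (`"I"`), dual (`"D"`)
#'   or homeostatic (`"H"`); carried into reports, never used in ranking.
#' @param is_control Logical; at most one control (a C5A-like non-chemokine
#'   used to flag non-specific binders) per panel.
#' @return Tibble with the panel columns.
#' @export
target_panel <- function(target, class = NA_character_, type = NA_character_,
                         is_control = FALSE) {
  panel <- tibble(target = target,
                  class = rep_len(class, length(target)),
                  type = rep_len(type, length(target)),
                  is_control = rep_len(is_control, length(target)))
  if (sum(panel$is_control) > 1L) abort("at most one control target allowed")
  bad <- !panel$is_control & !panel$class %in% c("CC", "CXnC")
  if (any(bad)) {
    abort(paste0("class must be CC or CXnC for non-control target(s): ",
                 paste(panel$target[bad], collapse = ", ")))
  }
  panel
}

#' Convert variant counts to frequencies
#'
#' Two dialects are supported:
#'
#' * `"add_one"` adds one pseudocount to every member of the designed library
#'   (observed or not) and normalises, so frequencies always sum to one over
#'   the full library and no division by zero can occur.
#' * `"impute_min"` normalises raw counts over observed variants and assigns
#'   each unobserved library member the lowest observed proportion of that
#'   sample, flagging it as imputed. The minimum is per sample, not global.
#'
#' @param counts Count tibble (`sample_id`, `peptide`, `count`), one sample.
#' @param library Character vector: the designed library (must contain every
#'   counted peptide).
#' @param mode `"add_one"` (default) or `"impute_min"`.
#' @return Tibble `sample_id`, `peptide`, `count`, `freq`, `imputed`, covering
#'   the whole library, with a `mode` attribute.
#' @export
compute_frequencies <- function(counts, library,
                                mode = c("add_one", "impute_min")) {
  mode <- match.arg(mode)
  stopifnot(length(library) > 0L, !anyDuplicated(library))
  if (!all(counts$peptide %in% library)) {
    abort("counted peptides outside the designed library")
  }
  if (length(unique(counts$sample_id)) > 1L) {
    abort("compute_frequencies expects a single sample")
  }
  sid <- if (nrow(counts)) counts$sample_id[[1]] else "sample"
  full <- left_join(tibble(peptide = library), counts, by = "peptide")
  full <- mutate(full,
                 sample_id = sid,
                 count = dplyr::coalesce(.data$count, 0L))
  if (mode == "add_one") {
    full <- mutate(full,
                   freq = (.data$count + 1) / sum(.data$count + 1),
                   imputed = FALSE)
  } else {
    tot <- sum(full$count)
    if (tot == 0L) abort("impute_min undefined for all-zero counts")
    obs <- full$count > 0L
    fmin <- min(full$count[obs] / tot)
    full <- mutate(full,
                   freq = ifelse(.data$count > 0L, .data$count / tot, fmin),
                   imputed = .data$count == 0L)
  }
  out <- select(full, "sample_id", "peptide", "count", "freq", "imputed")
  attr(out, "mode") <- mode
  out
}

#' Compute log2 enrichment from input and output frequency tables
#'
#' Enrichment of a variant is the ratio of its output to input frequency,
#' expressed as `log2E = log2(out_freq / in_freq)`; positive values indicate
#' enrichment during selection, which correlates with binding affinity.
#' The output table may hold several selection samples (one per target);
#' enrichment is computed per target against the common input.
#'
#' @param input_ft Frequency table of the input (pre-selection) library.
#' @param output_ft Frequency table(s) of the selected population; the
#'   `sample_id` becomes the `target` column.
#' @return Tibble `variant`, `target`, `log2E`, `input_imputed`,
#'   `output_imputed`.
#' @export
compute_log2E <- function(input_ft, output_ft) {
  if (!identical(attr(input_ft, "mode"), attr(output_ft, "mode"))) {
    abort("input and output frequency tables use different imputation modes")
  }
  out_tbl <- select(output_ft, target = "sample_id", variant = "peptide",
                    out_freq = "freq", output_imputed = "imputed")
  in_tbl <- select(input_ft, variant = "peptide", in_freq = "freq",
                   input_imputed = "imputed")
  per_target <- split(out_tbl, out_tbl$target)
  for (tb in per_target) {
    if (!setequal(tb$variant, in_tbl$variant)) {
      abort("input and output tables cover different libraries; impute first")
    }
  }
  joined <- inner_join(out_tbl, in_tbl, by = "variant")
  transmute_cols <- mutate(joined,
                           log2E = log2(.data$out_freq / .data$in_freq))
  select(transmute_cols, "variant", "target", "log2E",
         "input_imputed", "output_imputed")
}

#' Add delta-log2E relative to the parental peptide
#'
#' `delta_log2E(v, t) = log2E(v, t) - log2E(parent, t)`: the parent row is 0
#' for every target by construction.
#'
#' @param tbl Enrichment tibble from [compute_log2E()].
#' @param parent Parental peptide sequence (must be present for every target).
#' @return `tbl` with a `delta_log2E` column.
#' @export
compute_delta <- function(tbl, parent) {
  parent_rows <- filter(tbl, .data$variant == parent)
  missing <- setdiff(unique(tbl$target), parent_rows$target)
  if (length(missing)) {
    abort(paste0("parent peptide missing for target(s): ",
                 paste(missing, collapse = ", ")))
  }
  ref <- select(parent_rows, "target", parent_log2E = "log2E")
  joined <- left_join(tbl, ref, by = "target")
  joined <- mutate(joined, delta_log2E = .data$log2E - .data$parent_log2E)
  select(joined, -"parent_log2E")
}

#' Exclude non-specific (control-binding) variants
#'
#' Variants enriched on the control target (`log2E > 0`, strict) are removed
#' from all non-control rows; the control's own rows are retained untouched.
#' Applied after delta computation and before any ranking.
#'
#' @param tbl Enrichment tibble (with or without `delta_log2E`).
#' @param panel A [target_panel()] containing the control.
#' @return Filtered tibble; removed variants in the `excluded_variants`
#'   attribute. If the panel has no control the table is returned unchanged
#'   with a warning.
#' @export
exclude_control_binders <- function(tbl, panel) {
  ctrl <- panel$target[panel$is_control]
  if (length(ctrl) == 0L) {
    warn("panel has no control target; no variants excluded")
    attr(tbl, "excluded_variants") <- character()
    return(tbl)
  }
  ctrl_rows <- filter(tbl, .data$target == ctrl)
  if (nrow(ctrl_rows) == 0L) {
    abort("control target has no enrichment rows")
  }
  bad <- unique(ctrl_rows$variant[ctrl_rows$log2E > 0])
  out <- filter(tbl, .data$target == ctrl | !.data$variant %in% bad)
  attr(out, "excluded_variants") <- bad
  out
}
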