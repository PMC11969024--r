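#' Selection thresholds and pool sizes for improving mutations
#'
#' Defaults mirror the published two-pronged strategy: a peak delta-log2E
#' threshold of 5 (captures binding-diversity gains on at least one target),
#' a mean delta-log2E threshold of 0.55 (captures overall affinity gains),
#' and per-class pool sizes of 10 (CC) and 12 (CXnC).
#'
#' @param peak_threshold,mean_threshold Retention thresholds on peak and mean
#'   delta-log2E.
#' @param top_n_cc,top_n_cxnc Pool sizes after ranking.
#' @param combine `"or"` (default: keep a candidate if either threshold
#'   passes) or `"and"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(peak_threshold = 5, mean_threshold = 0.55,
                             top_n_cc = 10L, top_n_cxnc = 12L,
                             combine = c("or", "and")) {
  combine <- match.arg(combine)
  stopifnot(is.finite(peak_threshold), is.finite(mean_threshold),
            top_n_cc >= 1L, top_n_cxnc >= 1L)
  structure(list(peak_threshold = peak_threshold,
                 mean_threshold = mean_threshold,
                 top_n_cc = as.integer(top_n_cc),
                 top_n_cxnc = as.integer(top_n_cxnc),
                 combine = combine),
            class = "selection_config")
}

scope_targets <- function(panel, scope) {
  panel <- filter(panel, !.data$is_control)
  switch(scope,
         ALL = panel$target,
         CC = panel$target[panel$class == "CC"],
         CXnC = panel$target[panel$class == "CXnC"],
         abort("scope must be ALL, CC or CXnC"))
}

#' Summarise per-mutation effects over a target scope
#'
#' Every non-parent variant in the table must be a single mutant of the
#' parent. For each mutation, `mean_delta` is the arithmetic mean and
#' `peak_delta` the maximum of delta-log2E over the in-scope targets.
#'
#' @param tbl Control-excluded enrichment tibble with `delta_log2E`.
#' @param panel A [target_panel()].
#' @param parent Parental peptide sequence.
#' @param scope `"ALL"`, `"CC"` or `"CXnC"`.
#' @return Tibble `mutation`, `position`, `from_aa`, `to_aa`, `scope`,
#'   `mean_delta`, `peak_delta`, `n_targets`.
#' @export
summarize_mutation_effects <- function(tbl, panel, parent,
                                       scope = c("ALL", "CC", "CXnC")) {
  scope <- match.arg(scope)
  targets <- scope_targets(panel, scope)
  tbl <- filter(tbl, .data$target %in% targets, .data$variant != parent)
  if (nrow(tbl) == 0L) abort("no in-scope enrichment rows")
  variants <- unique(tbl$variant)
  mut_map <- map(variants, mutations_from_parent, parent = parent)
  n_mut <- vapply(mut_map, nrow, integer(1))
  if (any(n_mut != 1L)) {
    abort(paste0("variant(s) not single mutants of the parent: ",
                 paste(variants[n_mut != 1L], collapse = ", ")))
  }
  muts <- bind_rows(mut_map)
  muts$variant <- variants
  eff <- summarise(group_by(tbl, .data$variant),
                   mean_delta = mean(.data$delta_log2E),
                   peak_delta = max(.data$delta_log2E),
                   n_targets = dplyr::n(), .groups = "drop")
  out <- inner_join(muts, eff, by = "variant")
  out <- mutate(out, scope = scope)
  arrange(select(out, "mutation", "position", "from_aa", "to_aa", "scope",
                 "mean_delta", "peak_delta", "n_targets"),
          desc(.data$mean_delta), desc(.data$peak_delta))
}

best_per_position <- function(effects) {
  by_mean <- slice(group_by(effects, .data$position),
                   which.max(.data$mean_delta))
  by_peak <- slice(group_by(effects, .data$position),
                   which.max(.data$peak_delta))
  distinct(bind_rows(ungroup(by_mean), ungroup(by_peak)))
}

#' Select improving mutations per chemokine class
#'
#' For each class scope the best mutation per position is kept (one by mean
#' delta-log2E, one by peak; often the same), candidates failing both
#' thresholds are dropped, the survivors are ranked by mean then peak
#' (descending, position and replacement residue as deterministic
#' tie-breaks), and the list truncated to the class pool size. The two class
#' pools are then united; a mutation can belong to both.
#'
#' @param effects_cc,effects_cxnc Output of [summarize_mutation_effects()]
#'   with scopes `"CC"` and `"CXnC"`.
#' @param config A [selection_config()].
#' @return Long tibble with one row per (mutation, pool): columns `pool`,
#'   `mutation`, `position`, `from_aa`, `to_aa`, `mean_delta`, `peak_delta`,
#'   `rank`.
#' @export
select_improving_mutations <- function(effects_cc, effects_cxnc,
                                       config = selection_config()) {
  one_pool <- function(effects, label, top_n) {
    cand <- best_per_position(effects)
    keep <- if (config$combine == "or") {
      cand$peak_delta >= config$peak_threshold |
        cand$mean_delta >= config$mean_threshold
    } else {
      cand$peak_delta >= config$peak_threshold &
        cand$mean_delta >= config$mean_threshold
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- arrange(cand, desc(.data$mean_delta), desc(.data$peak_delta),
                    .data$position, .data$to_aa)
    if (nrow(cand) < top_n) {
      warn(paste0("pool ", label, ": only ", nrow(cand),
                  " candidates pass thresholds (requested ", top_n, ")"))
    }
    cand <- head(cand, top_n)
    mutate(cand, pool = label, rank = row_number())
  }
  out <- bind_rows(
    one_pool(effects_cc, "CC", config$top_n_cc),
    one_pool(effects_cxnc, "CXnC", config$top_n_cxnc)
  )
  select(out, "pool", "mutation", "position", "from_aa", "to_aa",
         "mean_delta", "peak_delta", "rank")
}

#' Rank combinatorial mutants by median delta-log2E
#'
#' The median (rather than mean + peak) is used to find variants with the
#' broadest binding across the panel. Group membership:
#' * `cm_max` / `cm_min`: highest / lowest `group_size` variants by median
#'   over all non-control targets;
#' * `cm_max_cc` / `cm_max_cxnc`: highest `group_size` by the class medians.
#'
#' Ties break by (median, mean, sequence); for `cm_min` the ordering is
#' ascending. Medians over an even number of targets are the midpoint of the
#' central pair.
#'
#' @param tbl Control-excluded enrichment tibble with `delta_log2E` over the
#'   combinatorial library.
#' @param panel A [target_panel()].
#' @param group_size Members per CM group (default 5).
#' @return Tibble, one row per variant: medians and means per scope plus
#'   logical group-membership columns.
#' @export
rank_combinatorial <- function(tbl, panel, group_size = 5L) {
  scope_stats <- function(scope) {
    targets <- scope_targets(panel, scope)
    sub <- filter(tbl, .data$target %in% targets)
    summarise(group_by(sub, .data$variant),
              median_delta = stats::median(.data$delta_log2E),
              mean_delta = mean(.data$delta_log2E), .groups = "drop")
  }
  all_s <- scope_stats("ALL")
  if (nrow(all_s) < group_size) {
    abort("library smaller than the requested group size")
  }
  cc_s <- rename(scope_stats("CC"), median_cc = "median_delta",
                 mean_cc = "mean_delta")
  cx_s <- rename(scope_stats("CXnC"), median_cxnc = "median_delta",
                 mean_cxnc = "mean_delta")
  out <- left_join(left_join(rename(all_s, median_all = "median_delta",
                                    mean_all = "mean_delta"),
                             cc_s, by = "variant"),
                   cx_s, by = "variant")
  top_set <- function(med, mea, decreasing) {
    # sequence tie-break stays ascending lexicographic in both directions
    ord <- order(if (decreasing) -med else med,
                 if (decreasing) -mea else mea,
                 out$variant)
    out$variant[ord[seq_len(group_size)]]
  }
  out <- mutate(out,
                cm_max = .data$variant %in%
                  top_set(out$median_all, out$mean_all, TRUE),
                cm_min = .data$variant %in%
                  top_set(out$median_all, out$mean_all, FALSE),
                cm_max_cc = .data$variant %in%
                  top_set(out$median_cc, out$mean_cc, TRUE),
                cm_max_cxnc = .data$variant %in%
                  top_set(out$median_cxnc, out$mean_cxnc, TRUE))
  arrange(out, desc(.data$median_all), desc(.data$mean_all), .data$variant)
}
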