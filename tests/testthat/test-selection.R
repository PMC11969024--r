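make_single_mutants <- function(muts) {
  vapply(muts, function(m) apply_mutations(fx_parent, m), character(1))
}

test_that("mutation effects are per-scope means and maxima of delta-log2E", {
  panel <- fx_panel(1, 0)
  one <- tibble(variant = c(fx_parent, make_single_mutants("Y5W")),
                target = "CCL1", log2E = c(0, 2), delta_log2E = c(0, 2))
  eff <- summarize_mutation_effects(one, panel, fx_parent, scope = "CC")
  expect_equal(eff$mean_delta, 2)
  expect_equal(eff$peak_delta, 2)

  panel2 <- fx_panel(2, 0)
  two <- tibble(variant = rep(make_single_mutants("T6D"), 2),
                target = c("CCL1", "CCL2"), log2E = c(1, 3),
                delta_log2E = c(1, 3))
  eff2 <- summarize_mutation_effects(two, panel2, fx_parent, scope = "CC")
  expect_equal(eff2$mean_delta, 2)
  expect_equal(eff2$peak_delta, 3)

  expect_error(
    summarize_mutation_effects(
      tibble(variant = apply_mutations(fx_parent, c("Y5W", "T6D")),
             target = "CCL1", delta_log2E = 1),
      panel, fx_parent, scope = "CC"),
    "single mutants")
})

test_that("effects match a per-row mean/max oracle on a 10 x 6 table", {
  muts <- c("E1A", "E2G", "D3N", "D4E", "Y5W", "T6D", "A7D", "Q8R", "A9V",
            "P10S")
  vars <- make_single_mutants(muts)
  panel <- fx_panel(3, 3)
  tbl <- fx_enrichment(vars, scope_targets <- panel$target[!panel$is_control],
                       seed = 11)
  eff <- summarize_mutation_effects(tbl, panel, fx_parent, scope = "ALL")
  for (i in seq_along(muts)) {
    rows <- tbl$delta_log2E[tbl$variant == vars[i]]
    expect_equal(eff$mean_delta[eff$mutation == muts[i]], mean(rows))
    expect_equal(eff$peak_delta[eff$mutation == muts[i]], max(rows))
  }
  expect_true(all(eff$peak_delta >= eff$mean_delta))
  expect_equal(unique(eff$n_targets), 6L)
})

fx_effects <- function(muts, means, peaks, scope) {
  info <- parse_mutations(muts)
  tibble(mutation = muts, position = info$position, from_aa = info$from_aa,
         to_aa = info$to_aa, scope = scope, mean_delta = means,
         peak_delta = peaks, n_targets = 6L)
}

test_that("improving-mutation selection applies thresholds and pool sizes", {
  single <- fx_effects("T6D", 2, 8, "CC")
  sel <- suppressWarnings(
    select_improving_mutations(single, fx_effects("Y5W", 1, 6, "CXnC"),
                               selection_config()))
  expect_setequal(sel$mutation, c("T6D", "Y5W"))

  # below both default thresholds -> excluded
  weak <- fx_effects(c("T6D", "A7D"), c(0.5, 2), c(4.9, 7), "CC")
  expect_warning(select_improving_mutations(
    weak, fx_effects("Y5W", 1, 6, "CXnC"),
    selection_config(top_n_cc = 2L, top_n_cxnc = 1L)), "only")
  sel2 <- suppressWarnings(
    select_improving_mutations(weak, fx_effects("Y5W", 1, 6, "CXnC")))
  expect_false("T6D" %in% sel2$mutation)

  # mean >= 0.55 OR peak >= 5 keeps either prong
  either <- fx_effects(c("T6D", "A7D"), c(0.6, 0.1), c(1, 6), "CC")
  sel3 <- suppressWarnings(
    select_improving_mutations(either, fx_effects("Y5W", 1, 6, "CXnC")))
  expect_setequal(sel3$mutation[sel3$pool == "CC"], c("T6D", "A7D"))
})

test_that("class pools of 10 and 12 with 6 shared unite to 16 mutations", {
  parent_aa <- strsplit(fx_parent, "")[[1]]
  mk <- function(pos, to) paste0(parent_aa[pos], pos, to)
  shared <- mk(1:6, c("K", "K", "K", "K", "W", "D"))
  cc_only <- mk(7:10, c("D", "R", "V", "S"))
  cx_only <- mk(7:12, c("E", "H", "I", "T", "M", "N"))
  cc <- fx_effects(c(shared, cc_only), means = seq(10, 1), peaks = 12, "CC")
  cx <- fx_effects(c(shared, cx_only), means = seq(12, 1), peaks = 12, "CXnC")
  sel <- select_improving_mutations(cc, cx, selection_config())
  expect_equal(sum(sel$pool == "CC"), 10L)
  expect_equal(sum(sel$pool == "CXnC"), 12L)
  expect_equal(length(unique(sel$mutation)), 16L)   # 10 + 12 - 6 shared
  expect_equal(length(unique(parse_mutations(unique(sel$mutation))$position)),
               12L)
})

test_that("combinatorial ranking uses scope medians with stated tie-breaks", {
  panel <- fx_panel(2, 1)
  v <- apply_mutations(fx_parent, c("Y5W", "T6D"))
  tbl <- tibble(variant = rep(c(fx_parent, v), each = 3),
                target = rep(c("CCL1", "CCL2", "CXCL1"), 2),
                delta_log2E = c(0, 0, 0, 0, 1, 2))
  rk <- rank_combinatorial(tbl, panel, group_size = 1L)
  expect_equal(rk$median_all[rk$variant == v], 1)
  expect_equal(rk$median_all[rk$variant == fx_parent], 0)
  expect_true(rk$cm_max[rk$variant == v])
  expect_true(rk$cm_min[rk$variant == fx_parent])
})

test_that("CM groups equal a full-sort oracle on a 30-variant table", {
  vars <- random_peptides(30, seed = 12)
  panel <- fx_panel(3, 3)
  tbl <- fx_enrichment(vars, panel$target[!panel$is_control], seed = 13)
  rk <- rank_combinatorial(tbl, panel, group_size = 5L)

  med <- sapply(rk$variant, function(v) {
    median(tbl$delta_log2E[tbl$variant == v])
  })
  oracle_max <- names(sort(med, decreasing = TRUE))[1:5]
  oracle_min <- names(sort(med))[1:5]
  expect_setequal(rk$variant[rk$cm_max], oracle_max)
  expect_setequal(rk$variant[rk$cm_min], oracle_min)
  expect_length(intersect(rk$variant[rk$cm_max], rk$variant[rk$cm_min]), 0)

  med_cc <- sapply(rk$variant, function(v) {
    median(tbl$delta_log2E[tbl$variant == v &
                             tbl$target %in% c("CCL1", "CCL2", "CCL3")])
  })
  expect_setequal(rk$variant[rk$cm_max_cc],
                  names(sort(med_cc, decreasing = TRUE))[1:5])

  expect_error(rank_combinatorial(tbl, panel, group_size = 50L), "smaller")
})

test_that("selection and ranking are shift- and permutation-invariant", {
  vars <- random_peptides(12, seed = 14)
  panel <- fx_panel(3, 3)
  tbl <- fx_enrichment(vars, panel$target[!panel$is_control], seed = 15)
  rk1 <- rank_combinatorial(tbl, panel)
  shifted <- mutate(tbl, delta_log2E = delta_log2E + 7)
  rk2 <- rank_combinatorial(shifted, panel)
  expect_equal(rk2$median_all, rk1$median_all + 7)
  expect_equal(rk1$variant[rk1$cm_max], rk2$variant[rk2$cm_max])

  set.seed(16)
  shuffled <- tbl[sample(nrow(tbl)), ]
  rk3 <- rank_combinatorial(shuffled, panel)
  expect_equal(rk3, rk1)
})
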