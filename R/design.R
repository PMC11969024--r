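#' Escherichia coli codon-usage table
#'
#' Relative codon usage (fraction within each amino acid) for E. coli K-12,
#' the expression host of the display system. Bundled as the default for
#' [reverse_translate()]; any table with columns `codon`, `aa`, `fraction`
#' can be substituted.
#'
#' @return Tibble `codon`, `aa` (one-letter), `fraction`.
#' @export
ecoli_codon_table <- function() {
  raw <- c(
    "GCG A 0.36", "GCC A 0.27", "GCA A 0.21", "GCT A 0.16",
    "CGC R 0.40", "CGT R 0.38", "CGG R 0.10", "CGA R 0.06",
    "AGA R 0.04", "AGG R 0.02",
    "AAC N 0.55", "AAT N 0.45",
    "GAT D 0.63", "GAC D 0.37",
    "TGC C 0.55", "TGT C 0.45",
    "CAG Q 0.65", "CAA Q 0.35",
    "GAA E 0.68", "GAG E 0.32",
    "GGC G 0.40", "GGT G 0.34", "GGG G 0.15", "GGA G 0.11",
    "CAT H 0.57", "CAC H 0.43",
    "ATT I 0.51", "ATC I 0.42", "ATA I 0.07",
    "CTG L 0.50", "TTA L 0.13", "TTG L 0.13", "CTT L 0.10",
    "CTC L 0.10", "CTA L 0.04",
    "AAA K 0.76", "AAG K 0.24",
    "ATG M 1.00",
    "TTT F 0.57", "TTC F 0.43",
    "CCG P 0.52", "CCA P 0.19", "CCT P 0.16", "CCC P 0.13",
    "AGC S 0.28", "TCT S 0.15", "TCC S 0.15", "TCG S 0.15",
    "AGT S 0.15", "TCA S 0.12",
    "ACC T 0.44", "ACG T 0.27", "ACT T 0.17", "ACA T 0.12",
    "TGG W 1.00",
    "TAT Y 0.57", "TAC Y 0.43",
    "GTG V 0.37", "GTT V 0.26", "GTC V 0.22", "GTA V 0.15"
  )
  parts <- strsplit(raw, " ")
  tibble(codon = map_chr(parts, 1L),
         aa = map_chr(parts, 2L),
         fraction = as.numeric(map_chr(parts, 3L)))
}

#' Synthetic parent hexadecapeptide for simulations and fixtures
#'
#' A 16-mer used as the default simulation parent. It is synthetic: the
#' residues at positions 8 and 14 are placeholders (Q, G), and the sequence
#' is chosen only so that the canonical mutation labels used throughout the
#' documentation (Y5W, T6D, T6W, A7D, L11I, ...) are consistent with it.
#' Real reproduction runs must supply the true parent sequence.
#'
#' @return A 16-character amino-acid string.
#' @export
synthetic_parent <- function() "EEDDYTAQAPLTCGFT"

#' Codon-selection model for reverse translation
#'
#' @param table Codon-usage tibble (`codon`, `aa`, `fraction`); defaults to
#'   [ecoli_codon_table()].
#' @param mode `"most_frequent"` (deterministic) or `"weighted"` (sample
#'   codons proportionally to usage; reproducible under `seed`).
#' @param gc_bias If `TRUE`, choice is restricted to the two highest-GC
#'   codons of each amino acid before applying `mode`.
#' @param seed Optional integer seed for `"weighted"` mode.
#' @return A list of class `codon_model`.
#' @export
codon_model <- function(table = ecoli_codon_table(),
                        mode = c("most_frequent", "weighted"),
                        gc_bias = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("codon", "aa", "fraction") %in% names(table)),
            all(table$fraction >= 0))
  ok <- summarise(group_by(as_tibble(table), .data$aa),
                  any_pos = any(.data$fraction > 0), .groups = "drop")
  if (!all(ok$any_pos)) abort("every amino acid needs a positive-weight codon")
  if (gc_bias) {
    gc <- function(codon) {
      vapply(strsplit(codon, ""), function(b) sum(b %in% c("G", "C")),
             numeric(1))
    }
    table <- mutate(as_tibble(table), .gc = gc(.data$codon))
    table <- slice(arrange(group_by(table, .data$aa),
                           desc(.data$.gc), desc(.data$fraction)),
                   seq_len(min(2L, dplyr::n())))
    table <- select(ungroup(table), -".gc")
  }
  structure(list(table = as_tibble(table), mode = mode,
                 gc_bias = gc_bias, seed = seed),
            class = "codon_model")
}

#' Oligonucleotide cloning arms
#'
#' Defaults are the arms used for the 81-mer mutant oligonucleotides
#' (`5'` arm + 48-nt insert + `3'` arm = 18 + 48 + 15 nt).
#'
#' @param arm5,arm3 Arm sequences.
#' @return Named list with `arm5` and `arm3`.
#' @export
oligo_arms <- function(arm5 = "GCAGCCTCTTCATCTGGC", arm3 = "GGTGGAGGATCCGGA") {
  stopifnot(grepl("^[ACGT]+$", arm5), grepl("^[ACGT]+$", arm3))
  list(arm5 = arm5, arm3 = arm3)
}

#' Reverse-translate peptides into oligonucleotide designs
#'
#' Each peptide is encoded codon-by-codon under the given [codon_model()] and
#' flanked by the cloning arms. `translate(insert_nt)` always equals the
#' peptide; `most_frequent` mode is deterministic and `weighted` mode is
#' reproducible under the model seed.
#'
#' @param peptides Data frame with a `peptide` column, or character vector.
#' @param model A [codon_model()].
#' @param arms An [oligo_arms()] list.
#' @return Tibble `peptide`, `insert_nt`, `full_oligo`.
#' @export
reverse_translate <- function(peptides, model = codon_model(),
                              arms = oligo_arms()) {
  pep <- if (is.data.frame(peptides)) peptides$peptide else peptides
  stopifnot(is.character(pep), length(pep) > 0L)
  tab <- model$table[model$table$fraction > 0, ]
  by_aa <- split(tab, tab$aa)
  residues <- unique(unlist(strsplit(pep, "")))
  missing <- setdiff(residues, names(by_aa))
  if (length(missing)) {
    abort(paste0("residue(s) absent from codon table: ",
                 paste(missing, collapse = ", ")))
  }
  if (model$mode == "weighted" && !is.null(model$seed)) set.seed(model$seed)
  encode <- function(p) {
    aa <- strsplit(p, "")[[1]]
    codons <- vapply(aa, function(a) {
      rows <- by_aa[[a]]
      if (model$mode == "most_frequent") {
        rows$codon[which.max(rows$fraction)]
      } else {
        sample(rows$codon, 1L, prob = rows$fraction)
      }
    }, character(1))
    paste(codons, collapse = "")
  }
  insert_nt <- vapply(pep, encode, character(1), USE.NAMES = FALSE)
  tibble(peptide = pep, insert_nt = insert_nt,
         full_oligo = paste0(arms$arm5, insert_nt, arms$arm3))
}

#' Build the NNK single-mutant (saturation) library of a parent peptide
#'
#' The NNK degenerate codon encodes all 20 canonical amino acids, so the
#' designed library is every single-position substitution plus the parent:
#' `L * 19 + 1` unique peptides for a parent of length `L` with no repeated
#' substitutions-to-self.
#'
#' @param parent Parent peptide.
#' @return Tibble `peptide`, `mutation` (`NA` for the parent), `provenance`.
#' @export
build_nnk_library <- function(parent) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  stopifnot(all(strsplit(parent, "")[[1]] %in% aa20))
  p <- strsplit(parent, "")[[1]]
  rows <- purrr::map(seq_along(p), function(i) {
    to <- setdiff(aa20, p[i])
    tibble(peptide = vapply(to, function(a) {
      q <- p; q[i] <- a; paste(q, collapse = "")
    }, character(1)),
    mutation = paste0(p[i], i, to))
  })
  out <- bind_rows(rows)
  out <- mutate(out, provenance = "single")
  bind_rows(tibble(peptide = parent, mutation = NA_character_,
                   provenance = "parent"),
            distinct(out, .data$peptide, .keep_all = TRUE))
}

#' Scramble a peptide sequence
#'
#' Returns a seeded random permutation of the parent with identical residue
#' composition, guaranteed to differ from the parent (re-drawn on collision).
#'
#' @param parent Peptide of length >= 2 with at least two distinct residues.
#' @param seed Integer seed.
#' @return Scrambled peptide string.
#' @export
scramble <- function(parent, seed = 1L) {
  aa <- strsplit(parent, "")[[1]]
  stopifnot(length(aa) >= 2L)
  if (length(unique(aa)) == 1L) {
    abort("cannot scramble a homopolymer: no distinct permutation exists")
  }
  set.seed(seed)
  repeat {
    s <- paste(sample(aa), collapse = "")
    if (s != parent) return(s)
  }
}

#' Enumerate all combinatorial mutants from per-class mutation pools
#'
#' For each pool, every subset of size >= 2 whose mutations sit at pairwise
#' distinct positions is applied to the parent (subsets containing two
#' alternative substitutions at one position are excluded at enumeration
#' time, since simultaneous substitutions at one site are undefined). Pool
#' outputs are united and deduplicated by sequence (first provenance kept,
#' pool origins united), then all single mutants of the pooled mutations,
#' the parent and the scrambled parent are appended.
#'
#' @param pools Tibble with columns `pool` (e.g. `"CC"`, `"CXnC"`) and
#'   `mutation` (labels such as `"T6D"`), or the output of
#'   [select_improving_mutations()].
#' @param parent Parent peptide.
#' @param scrambled Scrambled-parent sequence (must differ from `parent`).
#' @return Tibble `peptide`, `mutations` (`+`-joined, position-sorted),
#'   `n_mutations`, `provenance` (`combo`/`single`/`parent`/`scrambled`),
#'   `pools` (`;`-joined origins). Sequences are pairwise distinct.
#' @export
enumerate_combinations <- function(pools, parent, scrambled) {
  stopifnot(all(c("pool", "mutation") %in% names(pools)), nrow(pools) > 0L)
  if (identical(scrambled, parent)) {
    abort("scrambled sequence equals the parent")
  }
  pools <- distinct(as_tibble(pools), .data$pool, .data$mutation)

  combos_one_pool <- function(label, mutations) {
    info <- parse_mutations(mutations)
    k_max <- length(unique(info$position))
    subs <- list()
    for (k in seq(2L, max(2L, k_max))) {
      if (k > length(mutations)) break
      cc <- utils::combn(seq_along(mutations), k, simplify = FALSE)
      keep <- cc[vapply(cc, function(idx) {
        !anyDuplicated(info$position[idx])
      }, logical(1))]
      subs <- c(subs, keep)
    }
    if (length(subs) == 0L) {
      return(tibble(peptide = character(), mutations = character(),
                    n_mutations = integer(), pools = character()))
    }
    tibble(
      peptide = map_chr(subs, function(idx) {
        apply_mutations(parent, info[idx, ])
      }),
      mutations = map_chr(subs, function(idx) format_mutations(info[idx, ])),
      n_mutations = lengths(subs),
      pools = label
    )
  }

  combo_tbl <- bind_rows(lapply(split(pools, pools$pool), function(p) {
    combos_one_pool(p$pool[[1]], p$mutation)
  }))
  # dedupe by sequence, uniting pool origins
  if (nrow(combo_tbl)) {
    combo_tbl <- summarise(
      group_by(combo_tbl, .data$peptide),
      mutations = .data$mutations[[1]],
      n_mutations = .data$n_mutations[[1]],
      pools = paste(sort(unique(.data$pools)), collapse = ";"),
      .groups = "drop")
    combo_tbl <- mutate(combo_tbl, provenance = "combo")
  }

  singles_info <- parse_mutations(unique(pools$mutation))
  singles_pools <- summarise(group_by(pools, .data$mutation),
                             pools = paste(sort(unique(.data$pool)),
                                           collapse = ";"),
                             .groups = "drop")
  singles <- tibble(
    peptide = map_chr(seq_len(nrow(singles_info)), function(i) {
      apply_mutations(parent, singles_info[i, ])
    }),
    mutations = singles_info$mutation,
    n_mutations = 1L,
    provenance = "single"
  )
  singles <- left_join(singles,
                       rename(singles_pools, mutations = "mutation"),
                       by = "mutations")

  out <- bind_rows(
    combo_tbl,
    singles,
    tibble(peptide = parent, mutations = "", n_mutations = 0L,
           provenance = "parent", pools = NA_character_),
    tibble(peptide = scrambled, mutations = NA_character_,
           n_mutations = NA_integer_, provenance = "scrambled",
           pools = NA_character_)
  )
  out <- distinct(out, .data$peptide, .keep_all = TRUE)
  select(out, "peptide", "mutations", "n_mutations", "provenance", "pools")
}
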