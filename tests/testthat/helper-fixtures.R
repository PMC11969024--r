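suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

fx_parent <- synthetic_parent()

fx_panel <- function(n_cc = 3L, n_cxnc = 3L, control = TRUE) {
  target_panel(
    target = c(paste0("CCL", seq_len(n_cc)), paste0("CXCL", seq_len(n_cxnc)),
               if (control) "C5A"),
    class = c(rep("CC", n_cc), rep("CXnC", n_cxnc), if (control) NA),
    is_control = c(rep(FALSE, n_cc + n_cxnc), if (control) TRUE)
  )
}

# random enrichment table over given variants/targets, parent delta = 0
fx_enrichment <- function(variants, targets, seed = 1L, parent = fx_parent) {
  set.seed(seed)
  tbl <- tidyr::crossing(variant = unique(c(parent, variants)),
                         target = targets)
  tbl <- mutate(tbl, log2E = round(rnorm(dplyr::n(), 0, 2), 3),
                input_imputed = FALSE, output_imputed = FALSE)
  compute_delta(tbl, parent)
}

random_peptides <- function(n, len = 16L, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}

# atom-tibble constructor for hand-built geometries
fx_atoms <- function(chain, res_id, res_name, atom, element, x, y, z) {
  m <- tibble(chain = chain, res_id = as.integer(res_id),
              res_name = res_name, atom = atom, element = element,
              x = x, y = y, z = z)
  attr(m, "model_id") <- "fixture"
  m
}

# write a minimal single-sample FASTQ by hand
fx_write_fastq <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

fx_amplicon <- function(insert, scaffold = amplicon_scaffold()) {
  paste0(scaffold$fwd_demux, scaffold$fwd_const, insert,
         scaffold$rev_const,
         as.character(Biostrings::reverseComplement(
           Biostrings::DNAString(scaffold$rev_demux))))
}

fx_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate an insert -> peptide with internal-codon semantics (oracle use)
fx_translate <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

# counts -> delta-log2E table for one target (used across test files)
sim_enrichment <- function(counts, library, parent, target,
                           mode = "add_one") {
  inft <- compute_frequencies(counts[counts$sample_id == "input", ],
                              library, mode)
  outft <- compute_frequencies(counts[counts$sample_id == target, ],
                               library, mode)
  compute_delta(compute_log2E(inft, outft), parent)
}

fx_pair <- function(insert, read_id = "r1", scaffold = amplicon_scaffold()) {
  amp <- fx_amplicon(insert, scaffold)
  tibble(read_id = read_id, fwd_seq = amp, rev_seq = fx_revcomp(amp),
         fwd_qual = strrep("I", nchar(amp)),
         rev_qual = strrep("I", nchar(amp)))
}
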