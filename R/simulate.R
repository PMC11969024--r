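#' Latent per-variant selection weights from mutation effects
#'
#' The simulator's ground truth: each variant's binding weight on a target
#' is `2^(sum of additive per-mutation log2 effects + pairwise epistasis
#' terms)`, so the parent (no mutations) has weight 1 and a variant carrying
#' one mutation of effect `+2` binds 4-fold better than the parent.
#'
#' @param library Tibble with `peptide` and `mutations` (`+`-joined labels;
#'   `""` or `NA` for parent/scrambled).
#' @param effects Tibble `mutation`, `target`, `effect` (additive log2).
#' @param targets Character vector of targets to cover (defaults to those in
#'   `effects`).
#' @param epistasis Optional tibble `mutation_1`, `mutation_2`, `target`,
#'   `effect` for pairwise (e.g. antagonistic, negative) interaction terms.
#' @return Tibble `peptide`, `target`, `weight` (strictly positive).
#' @export
affinity_weights <- function(library, effects, targets = NULL,
                             epistasis = NULL) {
  targets <- targets %||% unique(effects$target)
  mut_col <- if ("mutations" %in% names(library)) library$mutations else
    library$mutation
  mut_list <- strsplit(ifelse(is.na(mut_col), "", mut_col),
                       "+", fixed = TRUE)
  grid <- tidyr::crossing(peptide = library$peptide, target = targets)
  names(mut_list) <- library$peptide
  w <- map_dbl(seq_len(nrow(grid)), function(r) {
    muts <- mut_list[[grid$peptide[r]]]
    tg <- grid$target[r]
    eff <- sum(effects$effect[effects$target == tg &
                                effects$mutation %in% muts])
    if (!is.null(epistasis) && length(muts) > 1L) {
      ep <- epistasis[epistasis$target == tg &
                        epistasis$mutation_1 %in% muts &
                        epistasis$mutation_2 %in% muts, ]
      eff <- eff + sum(ep$effect)
    }
    2^eff
  })
  mutate(grid, weight = w)
}

#' Simulate phage-display selection rounds
#'
#' Selection is modelled as weight-proportional retention: after each round
#' a variant's proportion is `p_i w_i / sum_j p_j w_j`, so after `rounds`
#' rounds the expected delta-log2E of a variant against the parent is
#' `rounds * log2(w_variant / w_parent)`. Sequencing of the input and of
#' each selected population draws counts multinomially at the configured
#' depth.
#'
#' @param library Tibble with `peptide` and optionally `freq` (initial
#'   frequencies; uniform if absent).
#' @param weights Tibble `peptide`, `target`, `weight` from
#'   [affinity_weights()] (or constructed directly).
#' @param rounds Selection rounds (default 3).
#' @param depth Sequencing depth per sample.
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `peptide`, `count` with the input sample
#'   labelled `"input"` and one sample per target.
#' @export
simulate_selection <- function(library, weights, rounds = 3L, depth = 1e5,
                               seed = 1L) {
  stopifnot(rounds >= 1L, depth >= 1L)
  set.seed(seed)
  pep <- library$peptide
  p0 <- if ("freq" %in% names(library)) library$freq else
    rep(1 / length(pep), length(pep))
  stopifnot(abs(sum(p0) - 1) < 1e-6)
  if (!all(pep %in% unique(weights$peptide))) {
    abort("weights must cover every library peptide")
  }
  draw <- function(p, sid) {
    tibble(sample_id = sid, peptide = pep,
           count = as.integer(rmultinom(1L, size = depth, prob = p)))
  }
  out <- list(draw(p0, "input"))
  for (tg in unique(weights$target)) {
    wt <- weights[weights$target == tg, ]
    w <- wt$weight[match(pep, wt$peptide)]
    p <- p0
    for (r in seq_len(rounds)) p <- p * w / sum(p * w)
    out[[length(out) + 1L]] <- draw(p, tg)
  }
  filter(bind_rows(out), .data$count > 0L)
}

random_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L),
                        character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Synthesize paired amplicon FASTQ files from variant counts
#'
#' Emits one read pair per count. The forward read is the full amplicon
#' (forward demux + forward constant + insert + reverse constant + reverse
#' complement of the reverse demux); the reverse read is its reverse
#' complement. Substitution errors are injected independently per mate at
#' the given per-base rate; output is byte-identical under a fixed seed.
#'
#' @param counts Tibble `peptide`, `count`.
#' @param oligos Tibble `peptide`, `insert_nt` (from [reverse_translate()]);
#'   every counted peptide needs an oligo.
#' @param fwd_path,rev_path Output FASTQ paths (`.gz` supported).
#' @param scaffold An [amplicon_scaffold()].
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return Invisibly, a tibble with the two paths and the read count.
#' @export
synthesize_reads <- function(counts, oligos, fwd_path, rev_path,
                             scaffold = amplicon_scaffold(),
                             error_rate = 0, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  missing <- setdiff(counts$peptide, oligos$peptide)
  if (length(missing)) {
    abort(paste0("no oligo for peptide(s): ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  set.seed(seed)
  inserts <- oligos$insert_nt[match(counts$peptide, oligos$peptide)]
  amplicon <- paste0(scaffold$fwd_demux, scaffold$fwd_const,
                     rep(inserts, counts$count), scaffold$rev_const,
                     revcomp(scaffold$rev_demux))
  n <- length(amplicon)
  fwd <- random_errors(amplicon, error_rate)
  rev <- random_errors(revcomp(amplicon), error_rate)
  ids <- sprintf("read%07d", seq_len(n))
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))),
      compress = grepl("\\.gz$", path))
  }
  write_one(fwd, fwd_path)
  write_one(rev, rev_path)
  invisible(tibble(fwd_path = fwd_path, rev_path = rev_path, n_reads = n))
}

#' Simulate chemotaxis dose-response data
#'
#' Mean responses follow the 3-parameter log-logistic curve at the true
#' parameters; replicate noise is Gaussian (`sd` in response units) or
#' negative binomial (for migrated-cell counts, with `dispersion` the NB
#' size parameter's inverse).
#'
#' @param doses Molar doses (> 0).
#' @param b,c,d,e True curve parameters (see [fit_ll3()]).
#' @param replicates Replicates per dose (default 3).
#' @param noise `"gaussian"` or `"nb"`.
#' @param sd Gaussian noise standard deviation.
#' @param dispersion NB dispersion (> 0).
#' @param seed Integer seed.
#' @return Tibble `dose`, `replicate`, `response`.
#' @export
simulate_chemotaxis <- function(doses, b = -1, c = 0, d = 100, e,
                                replicates = 3L,
                                noise = c("gaussian", "nb"),
                                sd = 5, dispersion = 0.05, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(doses > 0), replicates >= 1L, dispersion > 0)
  set.seed(seed)
  grid <- tidyr::crossing(dose = doses, replicate = seq_len(replicates))
  mu <- ll3_curve(grid$dose, b, c, d, e)
  resp <- if (noise == "gaussian") {
    if (sd > 0) mu + rnorm(nrow(grid), 0, sd) else mu
  } else {
    rnbinom(nrow(grid), mu = pmax(mu, 1e-9), size = 1 / dispersion)
  }
  mutate(grid, response = resp)
}

#' Simulate chemokine expression (TPM) tables
#'
#' Emulates mean tissue expression profiles used for pool design:
#' `"uniform"` gives every chemokine the same TPM, `"sparse"` concentrates
#' most expression on one dominant chemokine, `"lognormal"` draws from a
#' log-normal with the given log-scale mean and sd.
#'
#' @param chemokines Character vector.
#' @param profile `"lognormal"`, `"uniform"` or `"sparse"`.
#' @param meanlog,sdlog Log-normal parameters.
#' @param seed Integer seed.
#' @return Tibble `chemokine`, `tpm`.
#' @export
simulate_tpm <- function(chemokines, profile = c("lognormal", "uniform",
                                                 "sparse"),
                         meanlog = log(50), sdlog = 1, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(length(chemokines) > 0L)
  set.seed(seed)
  n <- length(chemokines)
  tpm <- switch(profile,
                uniform = rep(100, n),
                lognormal = rlnorm(n, meanlog, sdlog),
                sparse = {
                  v <- rlnorm(n, meanlog - 2, 0.25)
                  dom <- sample.int(n, 1L)
                  v[dom] <- sum(v) * 20
                  v
                })
  tibble(chemokine = chemokines, tpm = tpm)
}

# --- toy complex fixtures --------------------------------------------------

#' Write a structure tibble to PDB or mmCIF
#'
#' Minimal standard-conformant writers used for synthetic fixtures; files
#' round-trip through [read_structure()].
#'
#' @param model Structure tibble (`chain`, `res_id`, `res_name`, `atom`,
#'   `element`, `x`, `y`, `z`).
#' @param path Output path; format from extension unless given.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  m <- as_tibble(model)
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m)),
      ifelse(nchar(m$atom) < 4L, paste0(" ", m$atom), m$atom),
      m$res_name, m$chain, m$res_id, m$x, m$y, m$z, 1, 0, m$element)
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_synthetic", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    ent <- as.integer(factor(m$chain))
    rows <- sprintf(
      "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      seq_len(nrow(m)), m$element, m$atom, m$res_name, m$chain, ent,
      m$res_id, m$x, m$y, m$z, m$res_id, m$res_name, m$chain, m$atom)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Build toy chemokine / partner / peptide complex models
#'
#' Constructs a synthetic chemokine-like chain (A) laid out on a line with
#' one residue every 8 Angstrom, a partner chain (B) placed
#' `contact_distance` away from the first `n_site` chemokine residues, and a
#' peptide chain (C) placed symmetrically against the first `n_blocked` of
#' them. Under the 5 Angstrom rule the chemokine:partner binding site is
#' exactly the first `n_site` residues and exactly `n_blocked` of them are
#' also within reach of the peptide, so [occlusion()] on the emitted site
#' (A+B) and probe (A+C) models must report `n_site` / `n_blocked`. Both
#' mmCIF and PDB encodings are written; they parse to identical models.
#' Geometry is verified against a brute-force distance check before writing;
#' an infeasible prescription errors.
#'
#' @param n_site Binding-site residues (>= 1).
#' @param n_blocked Blocked residues (0..n_site).
#' @param n_extra Additional non-site chemokine residues.
#' @param dir Output directory.
#' @param contact_distance Heavy-atom contact distance used in construction
#'   (must be below the 5 Angstrom site cutoff).
#' @return Tibble `model` (`"site"`/`"probe"`), `format`, `path`.
#' @export
make_toy_complex <- function(n_site = 7L, n_blocked = 3L, n_extra = 2L,
                             dir = tempdir(), contact_distance = 4) {
  stopifnot(n_site >= 1L, n_blocked >= 0L, n_extra >= 0L)
  if (n_blocked > n_site) {
    abort("infeasible prescription: n_blocked exceeds n_site")
  }
  if (contact_distance >= 5 || contact_distance <= 0) {
    abort("contact_distance must lie in (0, 5) for the 5 Angstrom rule")
  }
  res_row <- function(chain, i, x, y) {
    tibble(chain = chain, res_id = i, res_name = "GLY",
           atom = c("N", "CA"), element = c("N", "C"),
           x = x, y = y, z = c(0, 1.3))
  }
  spacing <- 8
  chem <- bind_rows(lapply(seq_len(n_site + n_extra), function(i) {
    res_row("A", i, spacing * i, 0)
  }))
  partner <- bind_rows(lapply(seq_len(n_site), function(i) {
    res_row("B", i, spacing * i, contact_distance)
  }))
  peptide <- if (n_blocked > 0L) {
    bind_rows(lapply(seq_len(n_blocked), function(i) {
      res_row("C", i, spacing * i, -contact_distance)
    }))
  } else {
    # place the peptide far from every chemokine residue
    res_row("C", 1L, -10 * spacing, -50)
  }
  site_model <- bind_rows(chem, partner)
  probe_model <- bind_rows(chem, peptide)
  attr(site_model, "model_id") <- "toy_site"
  attr(probe_model, "model_id") <- "toy_probe"

  # brute-force feasibility check of the realized contact counts
  realized_site <- nrow(contact_residues(site_model, "A", "B"))
  occ <- occlusion(site_model, probe_model, "A", "B", "C")
  if (realized_site != n_site || occ$blocked != n_blocked) {
    abort("internal geometry error: realized contacts differ from prescription")
  }

  out <- tidyr::crossing(model = c("site", "probe"),
                         format = c("cif", "pdb"))
  out <- mutate(out, path = file.path(
    dir, paste0("toy_", .data$model, ".", .data$format)))
  for (r in seq_len(nrow(out))) {
    write_structure(if (out$model[r] == "site") site_model else probe_model,
                    out$path[r], out$format[r])
  }
  out
}
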