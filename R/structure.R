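#' Distance and interaction-typing rules for contact analysis
#'
#' The 5 Angstrom site cutoff is residue-level (any heavy-atom pair);
#' per-class atom-pair cutoffs are separate and deliberately simple,
#' documented constants:
#' hydrophobic = apolar carbon pair <= 4.5; hydrogen = donor-acceptor
#' <= 3.5; ionic = opposite formal charges <= 4.0; polar = uncharged polar
#' pair <= 3.5; carbonyl = carbonyl carbon to carbonyl oxygen <= 3.6;
#' aromatic = aromatic-carbon pair <= 4.0 (no ring-centroid geometry);
#' vdw = sum of van der Waals radii + 0.5. Formal charges follow residue
#' templates at physiological pH (Asp/Glu negative, Lys/Arg positive, His
#' neutral).
#'
#' @param site_cutoff Residue-level contact cutoff (Angstrom).
#' @param hydrophobic,hydrogen,ionic,polar,carbonyl,aromatic Class cutoffs.
#' @param vdw_slack Slack added to the sum of vdW radii.
#' @return A list of class `contact_rules`.
#' @export
contact_rules <- function(site_cutoff = 5.0, hydrophobic = 4.5,
                          hydrogen = 3.5, ionic = 4.0, polar = 3.5,
                          carbonyl = 3.6, aromatic = 4.0, vdw_slack = 0.5) {
  vals <- c(site_cutoff, hydrophobic, hydrogen, ionic, polar, carbonyl,
            aromatic, vdw_slack)
  stopifnot(all(vals > 0))
  structure(list(site_cutoff = site_cutoff, hydrophobic = hydrophobic,
                 hydrogen = hydrogen, ionic = ionic, polar = polar,
                 carbonyl = carbonyl, aromatic = aromatic,
                 vdw_slack = vdw_slack),
            class = "contact_rules")
}

#' Read a complex model from PDB or mmCIF
#'
#' Uses [bio3d::read.pdb()] / [bio3d::read.cif()]. Hydrogens are dropped on
#' load; alternate locations are resolved to the highest-occupancy copy of
#' each atom. Both encodings of the same model yield identical tables.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return Tibble `chain`, `res_id`, `res_name`, `atom`, `element`, `x`,
#'   `y`, `z` with a `model_id` attribute.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  s <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
    ),
    error = function(e) abort(paste0("cannot parse structure '", path, "': ",
                                     conditionMessage(e)))
  )
  a <- as_tibble(s$atom)
  a <- filter(a, .data$type %in% c("ATOM", "HETATM"))
  elem <- ifelse(!is.na(a$elesy) & nzchar(a$elesy),
                 toupper(a$elesy),
                 toupper(substr(gsub("[0-9]", "", a$elety), 1L, 1L)))
  a <- mutate(a, element = elem,
              o = ifelse(is.na(.data$o), 1, .data$o))
  a <- filter(a, .data$element != "H")
  # altloc: keep the highest-occupancy copy of each atom
  a <- arrange(a, .data$chain, .data$resno, .data$elety, desc(.data$o))
  a <- distinct(a, .data$chain, .data$resno, .data$elety, .keep_all = TRUE)
  if (nrow(a) == 0L || all(is.na(a$chain))) {
    abort(paste0("no chains found in '", path, "'"))
  }
  out <- select(a, chain = "chain", res_id = "resno", res_name = "resid",
                atom = "elety", element = "element",
                x = "x", y = "y", z = "z")
  out <- arrange(out, .data$chain, .data$res_id, .data$atom)
  if (any(!is.finite(c(out$x, out$y, out$z)))) {
    abort("non-finite coordinates in structure")
  }
  attr(out, "model_id") <- sub("\\.(pdb|cif)$", "",
                               basename(path), ignore.case = TRUE)
  out
}

# --- residue-template atom typing -----------------------------------------

AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
CHARGE_POS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
CHARGE_NEG <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SIDE_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG"
)
SIDE_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  MET = "SD", CYS = "SG"
)
CARBONYL_C <- list(ASN = "CG", GLN = "CD")
CARBONYL_O <- list(ASN = "OD1", GLN = "OE1")
# side-chain carbons bonded to N/O (treated as polar-adjacent, not apolar)
POLARIZED_C <- list(ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD",
                    ARG = "CZ")
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

in_template <- function(tpl, res_name, atom) {
  hits <- tpl[res_name]
  mapply(function(atoms, a) !is.null(atoms) && a %in% atoms,
         hits, atom, USE.NAMES = FALSE)
}

# Per-atom property flags; unknown residues are typed by element only.
atom_properties <- function(model) {
  res <- model$res_name
  atm <- model$atom
  el <- model$element
  known <- res %in% STANDARD_AA3
  if (any(!known)) {
    inform(paste0("unknown residue name(s) typed by element only: ",
                  paste(unique(res[!known]), collapse = ", ")))
  }
  charge <- numeric(nrow(model))
  charge[known & in_template(CHARGE_POS, res, atm)] <- 1
  charge[known & in_template(CHARGE_NEG, res, atm)] <- -1
  donor <- (known & ((atm == "N" & res != "PRO") |
                       in_template(SIDE_DONORS, res, atm))) |
    (!known & el == "N")
  acceptor <- (known & (atm %in% c("O", "OXT") |
                          in_template(SIDE_ACCEPTORS, res, atm))) |
    (!known & el == "O")
  aromatic <- known & in_template(AROMATIC_ATOMS, res, atm)
  carbonyl_c <- known & (atm == "C" | in_template(CARBONYL_C, res, atm))
  carbonyl_o <- known & (atm == "O" | in_template(CARBONYL_O, res, atm))
  polar <- el %in% c("N", "O") & charge == 0
  apolar_c <- el == "C" &
    ((known & !atm %in% c("C", "CA") &
        !in_template(POLARIZED_C, res, atm)) | !known)
  radius <- unname(VDW_RADII[el])
  radius[is.na(radius)] <- 1.70
  tibble(charge = charge, donor = donor, acceptor = acceptor,
         aromatic = aromatic, carbonyl_c = carbonyl_c,
         carbonyl_o = carbonyl_o, polar = polar, apolar_c = apolar_c,
         radius = radius)
}

cross_dist <- function(A, B) {
  # Euclidean distance matrix between two coordinate matrices (n x 3, m x 3)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

chain_atoms <- function(model, chain) {
  filter(as_tibble(model), .data$chain == !!chain)
}

#' Inter-chain contact residues at the site cutoff
#'
#' A residue of `chain_a` is a binding-site residue if any of its heavy
#' atoms lies within `rules$site_cutoff` (default 5 Angstrom) of any heavy
#' atom of `chain_b`. Symmetric under chain swap at the residue-pair level.
#'
#' @param model Structure tibble from [read_structure()].
#' @param chain_a,chain_b Chain identifiers.
#' @param rules A [contact_rules()].
#' @return Tibble `chain`, `res_id`, `res_name`, `min_dist` for the
#'   contacting residues of `chain_a`.
#' @export
contact_residues <- function(model, chain_a, chain_b,
                             rules = contact_rules()) {
  A <- chain_atoms(model, chain_a)
  B <- chain_atoms(model, chain_b)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    warn("empty chain; returning no contacts")
    return(tibble(chain = character(), res_id = integer(),
                  res_name = character(), min_dist = numeric()))
  }
  D <- cross_dist(as.matrix(A[, c("x", "y", "z")]),
                  as.matrix(B[, c("x", "y", "z")]))
  A <- mutate(A, min_dist = apply(D, 1, min))
  res <- summarise(group_by(A, .data$chain, .data$res_id, .data$res_name),
                   min_dist = min(.data$min_dist), .groups = "drop")
  res <- filter(res, .data$min_dist <= rules$site_cutoff)
  arrange(res, .data$res_id)
}

#' Classify inter-chain residue contacts into bond classes
#'
#' Every inter-chain atom pair of a contacting residue pair is tested
#' against the per-class geometric criteria of [contact_rules()]; a residue
#' pair's classes are the union over its atom pairs (possibly none:
#' proximity without a typed interaction). Ring-centroid (pi) geometry is
#' intentionally not modelled; the aromatic class uses plain aromatic-atom
#' distances.
#'
#' @inheritParams contact_residues
#' @return Tibble, one row per contacting residue pair: residue identities
#'   on both chains, `min_dist`, logical class columns (`hydrophobic`,
#'   `hydrogen`, `ionic`, `polar`, `carbonyl`, `aromatic`, `vdw`) and
#'   `model` id.
#' @export
classify_contacts <- function(model, chain_a, chain_b,
                              rules = contact_rules()) {
  A <- chain_atoms(model, chain_a)
  B <- chain_atoms(model, chain_b)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    warn("empty chain; returning no contacts")
    return(tibble())
  }
  pa <- atom_properties(A)
  pb <- atom_properties(B)
  D <- cross_dist(as.matrix(A[, c("x", "y", "z")]),
                  as.matrix(B[, c("x", "y", "z")]))

  idx <- which(D <= max(rules$site_cutoff), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble())
  }
  i <- idx[, 1]; j <- idx[, 2]
  d <- D[idx]
  pair <- tibble(
    res_a = A$res_id[i], name_a = A$res_name[i],
    res_b = B$res_id[j], name_b = B$res_name[j],
    d = d,
    hydrophobic = pa$apolar_c[i] & pb$apolar_c[j] & d <= rules$hydrophobic,
    hydrogen = ((pa$donor[i] & pb$acceptor[j]) |
                  (pa$acceptor[i] & pb$donor[j])) & d <= rules$hydrogen,
    ionic = pa$charge[i] * pb$charge[j] < 0 & d <= rules$ionic,
    polar = pa$polar[i] & pb$polar[j] & d <= rules$polar,
    carbonyl = ((pa$carbonyl_c[i] & pb$carbonyl_o[j]) |
                  (pa$carbonyl_o[i] & pb$carbonyl_c[j])) &
      d <= rules$carbonyl,
    aromatic = pa$aromatic[i] & pb$aromatic[j] &
      A$element[i] == "C" & B$element[j] == "C" & d <= rules$aromatic,
    vdw = d <= pa$radius[i] + pb$radius[j] + rules$vdw_slack
  )
  out <- summarise(
    group_by(pair, .data$res_a, .data$name_a, .data$res_b, .data$name_b),
    min_dist = min(.data$d),
    across(c("hydrophobic", "hydrogen", "ionic", "polar",
             "carbonyl", "aromatic", "vdw"), any),
    .groups = "drop")
  out <- filter(out, .data$min_dist <= rules$site_cutoff)
  out <- mutate(out, chain_a = chain_a, chain_b = chain_b,
                model = attr(model, "model_id") %||% NA_character_)
  arrange(select(out, "model", "chain_a", "res_a", "name_a",
                 "chain_b", "res_b", "name_b", "min_dist",
                 "hydrophobic", "hydrogen", "ionic", "polar",
                 "carbonyl", "aromatic", "vdw"),
          .data$res_a, .data$res_b)
}

BOND_CLASSES <- c("hydrophobic", "hydrogen", "ionic", "polar",
                  "carbonyl", "aromatic", "vdw")

#' Count classified bonds per class
#'
#' Counts residue-pair interactions per bond class, plus an `all` total (the
#' number of residue pairs carrying at least one typed interaction), grouped
#' by model or by peptide residue (`res_a`).
#'
#' @param pairs Output of [classify_contacts()] (rows from one or more
#'   models may be bound together).
#' @param by `"model"` or `"peptide_residue"`.
#' @return Long tibble with grouping columns, `class` and `n`.
#' @export
summarize_bonds <- function(pairs, by = c("model", "peptide_residue")) {
  by <- match.arg(by)
  key <- if (by == "model") "model" else c("model", "chain_a", "res_a")
  if (nrow(pairs) == 0L) {
    return(tibble(model = character(), class = character(), n = integer()))
  }
  long <- tidyr::pivot_longer(pairs, cols = dplyr::all_of(BOND_CLASSES),
                              names_to = "class", values_to = "hit")
  per_class <- summarise(group_by(long, across(dplyr::all_of(c(key, "class")))),
                         n = sum(.data$hit), .groups = "drop")
  all_cnt <- summarise(group_by(pairs, across(dplyr::all_of(key))),
                       n = sum(rowSums(
                         as.matrix(pick(dplyr::all_of(BOND_CLASSES)))) > 0),
                       .groups = "drop")
  all_cnt <- mutate(all_cnt, class = "all")
  arrange(bind_rows(all_cnt, per_class),
          across(dplyr::all_of(key)), .data$class)
}

#' Binding-site occlusion by a bound peptide
#'
#' The binding site is the set of chemokine residues within the site cutoff
#' of the partner (receptor or dimer mate) in `site_model`; a site residue
#' is "blocked" if it is also within the cutoff of the peptide in
#' `probe_model`. Residue numbering of the chemokine chain must agree
#' between the two models (checked on shared residues; mismatches are an
#' error listing the offending residues).
#'
#' @param site_model Structure with the chemokine and its partner.
#' @param probe_model Structure with the same chemokine and the peptide.
#' @param chemokine_chain,partner_chain,peptide_chain Chain ids. By default
#'   the peptide chain is auto-detected as the shortest chain of
#'   `probe_model`.
#' @param rules A [contact_rules()].
#' @return One-row tibble `total`, `blocked` plus list columns
#'   `site_residues`, `blocked_residues`.
#' @export
occlusion <- function(site_model, probe_model, chemokine_chain,
                      partner_chain, peptide_chain = NULL,
                      rules = contact_rules()) {
  if (is.null(peptide_chain)) {
    sizes <- count(distinct(as_tibble(probe_model),
                            .data$chain, .data$res_id), .data$chain)
    sizes <- filter(sizes, .data$chain != chemokine_chain)
    peptide_chain <- sizes$chain[which.min(sizes$n)]
  }
  a <- distinct(chain_atoms(site_model, chemokine_chain),
                .data$res_id, .data$res_name)
  b <- distinct(chain_atoms(probe_model, chemokine_chain),
                .data$res_id, .data$res_name)
  shared <- inner_join(a, b, by = "res_id", suffix = c("_site", "_probe"))
  bad <- filter(shared, .data$res_name_site != .data$res_name_probe)
  if (nrow(bad)) {
    abort(paste0("chemokine residue numbering disagrees between models at: ",
                 paste(bad$res_id, collapse = ", ")))
  }
  site <- contact_residues(site_model, chemokine_chain, partner_chain, rules)
  probe <- contact_residues(probe_model, chemokine_chain, peptide_chain, rules)
  blocked <- intersect(site$res_id, probe$res_id)
  tibble(chemokine_chain = chemokine_chain,
         partner_chain = partner_chain,
         peptide_chain = peptide_chain,
         total = nrow(site),
         blocked = length(blocked),
         site_residues = list(site$res_id),
         blocked_residues = list(blocked))
}

#' Build the complex-modelling task manifest
#'
#' Crosses every chemokine with every peptide and appends any supplied
#' chemokine:receptor and chemokine:dimer pair tasks; duplicates are dropped
#' with a warning. 46 chemokines by 3 peptides gives 138 peptide tasks.
#'
#' @param chemokines,peptides Character vectors.
#' @param receptor_pairs,dimer_pairs Optional tibbles with columns
#'   `chemokine` and `partner`.
#' @return Tibble `task_type`, `chemokine`, `partner`.
#' @export
build_model_manifest <- function(chemokines, peptides,
                                 receptor_pairs = NULL, dimer_pairs = NULL) {
  stopifnot(length(chemokines) > 0L, length(peptides) > 0L)
  tasks <- tidyr::crossing(chemokine = chemokines, partner = peptides)
  tasks <- mutate(tasks, task_type = "peptide")
  add_pairs <- function(tbl, type) {
    if (is.null(tbl)) return(NULL)
    mutate(select(as_tibble(tbl), "chemokine", "partner"), task_type = type)
  }
  out <- bind_rows(tasks,
                   add_pairs(receptor_pairs, "receptor"),
                   add_pairs(dimer_pairs, "dimer"))
  n0 <- nrow(out)
  out <- distinct(out, .data$task_type, .data$chemokine, .data$partner)
  if (nrow(out) < n0) warn("duplicate task(s) removed from manifest")
  select(out, "task_type", "chemokine", "partner")
}
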