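test_that("structures round-trip through PDB and mmCIF identically", {
  tc <- make_toy_complex(5, 2, n_extra = 1, dir = tempdir())
  cif <- read_structure(tc$path[tc$model == "site" & tc$format == "cif"])
  pdb <- read_structure(tc$path[tc$model == "site" & tc$format == "pdb"])
  expect_equal(nrow(cif), (5 + 1 + 5) * 2)  # two heavy atoms per residue
  expect_equal(as.data.frame(cif), as.data.frame(pdb), tolerance = 1e-6)
  expect_error(read_structure(tempfile(fileext = ".cif")), "cannot parse")
})

test_that("a residue is a contact iff any heavy-atom pair is within 5 A", {
  near <- fx_atoms(c("A", "B"), c(1, 1), "GLY", "CA", "C",
                   x = c(0, 4.9), y = 0, z = 0)
  out <- contact_residues(near, "A", "B")
  expect_equal(out$res_id, 1L)
  expect_equal(out$min_dist, 4.9)
  rev_side <- contact_residues(near, "B", "A")
  expect_equal(rev_side$res_id, 1L)

  far <- fx_atoms(c("A", "B"), c(1, 1), "GLY", "CA", "C",
                  x = c(0, 5.1), y = 0, z = 0)
  expect_equal(nrow(contact_residues(far, "A", "B")), 0L)

  expect_warning(empty <- contact_residues(near, "A", "Z"), "empty chain")
  expect_equal(nrow(empty), 0L)
})

test_that("contact sets equal an all-pairs brute-force oracle", {
  set.seed(25)
  rand_chain <- function(chain, n) {
    bind_rows(lapply(seq_len(n), function(i) {
      ctr <- runif(3, 0, 25)
      k <- sample(2:4, 1)
      fx_atoms(chain, i, "GLY", paste0("C", seq_len(k)), "C",
               x = ctr[1] + rnorm(k), y = ctr[2] + rnorm(k),
               z = ctr[3] + rnorm(k))
    }))
  }
  model <- bind_rows(rand_chain("A", 30), rand_chain("B", 30))
  attr(model, "model_id") <- "random"
  got <- contact_residues(model, "A", "B")

  A <- model[model$chain == "A", ]
  B <- model[model$chain == "B", ]
  oracle <- list()
  for (r in unique(A$res_id)) {
    a <- A[A$res_id == r, ]
    dmin <- Inf
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(B))) {
        dmin <- min(dmin, sqrt((a$x[i] - B$x[j])^2 + (a$y[i] - B$y[j])^2 +
                                 (a$z[i] - B$z[j])^2))
      }
    }
    if (dmin <= 5) oracle[[length(oracle) + 1L]] <- list(r = r, d = dmin)
  }
  expect_equal(got$res_id, vapply(oracle, `[[`, numeric(1), "r"))
  expect_equal(got$min_dist, vapply(oracle, `[[`, numeric(1), "d"),
               tolerance = 1e-9)

  # symmetry: a residue pair contacts iff its mirror does
  ab <- classify_contacts(model, "A", "B")
  ba <- classify_contacts(model, "B", "A")
  expect_setequal(paste(ab$res_a, ab$res_b), paste(ba$res_b, ba$res_a))
})

test_that("bond classes follow the documented geometric rules", {
  # apolar side-chain carbons 4.0 A apart -> hydrophobic
  hydro <- bind_rows(
    fx_atoms("A", 1, "LEU", "CD1", "C", 0, 0, 0),
    fx_atoms("B", 1, "ALA", "CB", "C", 4, 0, 0))
  ph <- classify_contacts(hydro, "A", "B")
  expect_true(ph$hydrophobic)
  expect_false(ph$hydrogen)

  # backbone amide N to carbonyl O at 3.0 A -> hydrogen bond
  hb <- bind_rows(
    fx_atoms("A", 1, "GLY", "N", "N", 0, 0, 0),
    fx_atoms("B", 1, "GLY", "O", "O", 3, 0, 0))
  pb <- classify_contacts(hb, "A", "B")
  expect_true(pb$hydrogen)
  expect_true(pb$polar)   # uncharged N/O pair within the polar cutoff too
  expect_false(pb$hydrophobic)

  # Lys NZ / Glu OE1: ionic at 3.5 A, not at 4.5 A
  mk_salt <- function(d) bind_rows(
    fx_atoms("A", 1, "LYS", "NZ", "N", 0, 0, 0),
    fx_atoms("B", 1, "GLU", "OE1", "O", d, 0, 0))
  expect_true(classify_contacts(mk_salt(3.5), "A", "B")$ionic)
  expect_false(classify_contacts(mk_salt(4.5), "A", "B")$ionic)

  # aromatic ring carbons within 4 A
  aro <- bind_rows(
    fx_atoms("A", 1, "PHE", "CZ", "C", 0, 0, 0),
    fx_atoms("B", 1, "TYR", "CE1", "C", 3.8, 0, 0))
  expect_true(classify_contacts(aro, "A", "B")$aromatic)

  # every classified pair is also a site contact
  all_pairs <- classify_contacts(mk_salt(3.5), "A", "B")
  expect_true(all(all_pairs$min_dist <= 5))
})

test_that("unknown residues fall back to element-only typing", {
  odd <- bind_rows(
    fx_atoms("A", 1, "XYZ", "C1", "C", 0, 0, 0),
    fx_atoms("B", 1, "ALA", "CB", "C", 4, 0, 0))
  expect_message(p <- classify_contacts(odd, "A", "B"), "unknown residue")
  expect_true(p$hydrophobic)
})

test_that("bond summaries count residue-pair interactions per class", {
  expect_equal(nrow(summarize_bonds(tibble())), 0L)

  pairs <- bind_rows(
    tibble(model = "m1", chain_a = "C", res_a = 1:3, name_a = "LEU",
           chain_b = "A", res_b = 1:3, name_b = "ALA", min_dist = 4,
           hydrophobic = TRUE, hydrogen = FALSE, ionic = FALSE,
           polar = FALSE, carbonyl = FALSE, aromatic = FALSE, vdw = FALSE),
    tibble(model = "m1", chain_a = "C", res_a = 4, name_a = "GLY",
           chain_b = "A", res_b = 4, name_b = "GLY", min_dist = 3,
           hydrophobic = FALSE, hydrogen = TRUE, ionic = FALSE,
           polar = FALSE, carbonyl = FALSE, aromatic = FALSE, vdw = FALSE))
  s <- summarize_bonds(pairs, by = "model")
  expect_equal(s$n[s$class == "all"], 4L)
  expect_equal(s$n[s$class == "hydrophobic"], 3L)
  expect_equal(s$n[s$class == "hydrogen"], 1L)

  # group-by oracle across two models
  pairs2 <- bind_rows(pairs, mutate(pairs, model = "m2"))
  s2 <- summarize_bonds(pairs2, by = "model")
  expect_equal(s2$n[s2$class == "hydrophobic"], c(3L, 3L))
  per_res <- summarize_bonds(pairs, by = "peptide_residue")
  expect_equal(sum(per_res$n[per_res$class == "all"]), 4L)
})

test_that("occlusion reports blocked site residues per prescription", {
  tc <- make_toy_complex(7, 3, dir = tempdir())
  site <- read_structure(tc$path[tc$model == "site" & tc$format == "cif"])
  probe <- read_structure(tc$path[tc$model == "probe" & tc$format == "cif"])
  occ <- occlusion(site, probe, "A", "B", "C")
  expect_equal(occ$total, 7L)
  expect_equal(occ$blocked, 3L)
  expect_true(all(occ$blocked_residues[[1]] %in% occ$site_residues[[1]]))

  # full overlap and opposite-face placements
  tc_full <- make_toy_complex(4, 4, dir = tempdir())
  s2 <- read_structure(tc_full$path[tc_full$model == "site" &
                                      tc_full$format == "pdb"])
  p2 <- read_structure(tc_full$path[tc_full$model == "probe" &
                                      tc_full$format == "pdb"])
  occ2 <- occlusion(s2, p2, "A", "B", "C")
  expect_equal(occ2$blocked, occ2$total)

  tc_none <- make_toy_complex(4, 0, dir = tempdir())
  s3 <- read_structure(tc_none$path[tc_none$model == "site" &
                                      tc_none$format == "cif"])
  p3 <- read_structure(tc_none$path[tc_none$model == "probe" &
                                      tc_none$format == "cif"])
  expect_equal(occlusion(s3, p3, "A", "B", "C")$blocked, 0L)

  # peptide chain auto-detection picks the shortest chain
  expect_equal(occlusion(site, probe, "A", "B")$blocked, 3L)

  # numbering mismatch is an error naming residues
  probe_bad <- mutate(probe,
                      res_name = ifelse(chain == "A" & res_id == 2,
                                        "ALA", res_name))
  attr(probe_bad, "model_id") <- "bad"
  expect_error(occlusion(site, probe_bad, "A", "B", "C"), "2")

  expect_error(make_toy_complex(3, 5), "infeasible")
})

test_that("the model manifest crosses chemokines with peptides", {
  m <- build_model_manifest(paste0("CK", 1:4), c("P1", "P2"))
  expect_equal(nrow(m), 8L)
  expect_equal(nrow(build_model_manifest("CK1", "P1")), 1L)
  expect_warning(
    dup <- build_model_manifest(
      "CK1", "P1",
      receptor_pairs = tibble(chemokine = c("CK1", "CK1"),
                              partner = c("R1", "R1"))),
    "duplicate")
  expect_equal(nrow(dup), 2L)
})
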