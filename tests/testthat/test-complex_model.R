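test_that("a minimal tripeptide + ethanol complex parses with r = 3", {
  pdb <- write_gly_chain_pdb(withr::local_tempfile(fileext = ".pdb"), n = 3)
  sdf <- write_ethanol_sdf(withr::local_tempfile(fileext = ".sdf"))
  model <- parse_complex(pdb, sdf)
  expect_s3_class(model, "ttmd_complex")
  expect_equal(model$r, 3)
  expect_equal(model$residue_order, paste0("A|", 1:3, "||GLY"))
  expect_equal(sum(!model$ligand$is_h), 3)
  # the hydroxyl hydrogen is bonded to the oxygen
  expect_equal(model$ligand$heavy[model$ligand$is_h], 3L)
})

test_that("two 10-residue chains give r = 20 in file order", {
  pdb <- write_gly_chain_pdb(withr::local_tempfile(fileext = ".pdb"),
                             n = 10, chains = c("A", "B"))
  sdf <- write_ethanol_sdf(withr::local_tempfile(fileext = ".sdf"))
  model <- parse_complex(pdb, sdf)
  expect_equal(model$r, 20)
  expect_equal(model$residue_order,
               c(paste0("A|", 1:10, "||GLY"), paste0("B|", 1:10, "||GLY")))
})

test_that("parse errors on missing files and degenerate inputs", {
  sdf <- write_ethanol_sdf(withr::local_tempfile(fileext = ".sdf"))
  expect_error(parse_complex("nope.pdb", sdf), "not found")
  pdb <- write_gly_chain_pdb(withr::local_tempfile(fileext = ".pdb"))
  expect_error(parse_complex(pdb, "nope.sdf"), "not found")
  # duplicate serials
  dup <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
               pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 0, 0),
               pdb_atom_line(2, "C", "GLY", "A", 1, 2, 0, 0),
               "END"), dup)
  suppressWarnings(expect_error(parse_complex(dup, sdf), "duplicate atom serials"))
  # ligand with no heavy atoms
  hsdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("h", "  ttmd", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), hsdf)
  expect_error(parse_complex(pdb, hsdf), "heavy atoms")
})

test_that("alternate locations keep the highest-occupancy copy", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(3, "CA", "GLY", "A", 1, 9.0, 0, 0, occ = 0.6, alt = "B"),
    pdb_atom_line(4, "C", "GLY", "A", 1, 2, 0, 0),
    pdb_atom_line(5, "O", "GLY", "A", 1, 2.5, 1, 0),
    "END"), pdb)
  sdf <- write_ethanol_sdf(withr::local_tempfile(fileext = ".sdf"))
  model <- parse_complex(pdb, sdf)
  ca <- model$protein[model$protein$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9.0)
})

test_that("perception applies the residue rule table", {
  fx <- make_fixture_complex(synthetic_ligand_spec(
    classes = "saltbridge_protein_positive", characteristic_temperatures = 400,
    seed = 2), n_residues = 3)
  p <- fx$model$protein
  nz <- p[p$name == "NZ", ]
  expect_equal(nz$charge_class, "cationic")
  expect_true(nz$is_hbond_donor_heavy)
  # backbone donors and acceptors on the plain glycines
  gly <- p[p$resname == "GLY", ]
  expect_true(all(gly$is_hbond_donor_heavy[gly$name == "N"]))
  expect_true(all(gly$is_hbond_acceptor[gly$name == "O"]))
  expect_false(any(gly$charge_class != "neutral"))
})

test_that("benzene ligand gives one aromatic ring of 6 hydrophobic carbons", {
  pdb <- write_gly_chain_pdb(withr::local_tempfile(fileext = ".pdb"))
  sdf <- write_benzene_sdf(withr::local_tempfile(fileext = ".sdf"))
  model <- perceive_features(parse_complex(pdb, sdf))
  lrings <- Filter(function(r) r$side == "ligand", model$rings)
  expect_length(lrings, 1)
  expect_length(lrings[[1]]$serials, 6)
  expect_true(all(model$ligand$is_hydrophobic))
})

test_that("glycine-only peptide has no rings and no charged sidechains", {
  pdb <- write_gly_chain_pdb(withr::local_tempfile(fileext = ".pdb"), n = 5)
  sdf <- write_ethanol_sdf(withr::local_tempfile(fileext = ".sdf"))
  model <- perceive_features(parse_complex(pdb, sdf))
  expect_length(Filter(function(r) r$side == "protein", model$rings), 0)
  expect_true(all(model$protein$charge_class == "neutral"))
})

test_that("fixture complexes round-trip through PDB/SDF with identical features", {
  for (seed in c(1, 9)) {
    fx <- make_fixture_complex(synthetic_ligand_spec(
      classes = c("hydrophobic", "aromatic_face_to_face", "hbond_protein_donor",
                  "saltbridge_protein_negative", "metal_ionic"),
      characteristic_temperatures = rep(400, 5), seed = seed))
    dir <- withr::local_tempdir()
    paths <- write_fixture_files(fx, dir)
    model2 <- perceive_features(parse_complex(paths["protein"], paths["ligand"]))
    expect_identical(model2$residue_order, fx$model$residue_order)
    expect_equal(nrow(model2$protein), nrow(fx$model$protein))
    expect_equal(nrow(model2$ligand), nrow(fx$model$ligand))
    for (col in c("charge_class", "is_hydrophobic", "is_hbond_donor_heavy",
                  "is_hbond_acceptor", "is_metal"))
      expect_identical(model2$protein[[col]], fx$model$protein[[col]])
    for (col in c("charge_class", "is_hydrophobic", "is_hbond_donor_heavy",
                  "is_hbond_acceptor"))
      expect_identical(model2$ligand[[col]], fx$model$ligand[[col]])
    d1 <- detect_interactions(fx$model)
    d2 <- detect_interactions(model2)
    expect_identical(d2[order(d2$residue, d2$class), ],
                     d1[order(d1$residue, d1$class), ],
                     ignore_attr = TRUE)
  }
})

test_that("feature perception is independent of atom order within residues", {
  fx <- make_fixture_complex(synthetic_ligand_spec(
    classes = "saltbridge_protein_positive", characteristic_temperatures = 400,
    seed = 4), n_residues = 2)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(fx, dir)
  # shuffle the LYS sidechain atom records in the PDB
  lines <- readLines(paths["protein"])
  side <- grep("(NZ|CE|CD|CG|CB|HZ)", lines)
  shuffled <- lines
  shuffled[side] <- lines[rev(side)]
  p2 <- file.path(dir, "shuffled.pdb")
  writeLines(shuffled, p2)
  m1 <- perceive_features(parse_complex(paths["protein"], paths["ligand"]))
  m2 <- perceive_features(parse_complex(p2, paths["ligand"]))
  expect_identical(m1$residue_order, m2$residue_order)
  by_serial <- function(m) m$protein[order(m$protein$serial),
                                     c("name", "charge_class", "is_hbond_donor_heavy")]
  o1 <- by_serial(m1); o2 <- by_serial(m2)
  expect_identical(o1[order(o1$name), ], o2[order(o2$name), ], ignore_attr = TRUE)
  d1 <- detect_interactions(m1); d2 <- detect_interactions(m2)
  expect_identical(d1[order(d1$class), ], d2[order(d2$class), ], ignore_attr = TRUE)
})

test_that("perceived ring normals are unit vectors with centroids near members", {
  fx <- make_fixture_complex(synthetic_ligand_spec(
    classes = c("aromatic_face_to_face", "aromatic_edge_to_face"),
    characteristic_temperatures = c(400, 400), seed = 5))
  fr <- fx$reference_frame
  for (rg in fx$model$rings) {
    xyz <- if (rg$side == "protein") fr$protein_xyz[rg$rows, ]
           else fr$ligand_xyz[rg$rows, ]
    g <- ring_geometry(xyz)
    expect_equal(sqrt(sum(g$normal^2)), 1, tolerance = 1e-6)
    expect_true(all(pair_dist(rbind(g$centroid), xyz) <= 3))
  }
})

test_that("trajectories round-trip through DCD with ascending times", {
  fx <- make_fixture_complex(demo_spec(seed = 6))
  be <- synth_backend(fx)
  res <- be(list(), 320, 0.5, 100, 42)
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(res$frames, dcd)
  frames <- load_trajectory(fx$model, dcd, 320)
  expect_length(frames, 5)
  expect_false(is.unsorted(vapply(frames, `[[`, 0, "time")))
  expect_equal(frames[[3]]$ligand_xyz, res$frames[[3]]$ligand_xyz, tolerance = 1e-5)
  expect_equal(frames[[1]]$temperature, 320)
  # atom-count mismatch must error
  fx2 <- make_fixture_complex(synthetic_ligand_spec(
    classes = "metal_ionic", characteristic_temperatures = 400, seed = 1))
  expect_error(load_trajectory(fx2$model, dcd, 320), "atom-count mismatch")
})
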