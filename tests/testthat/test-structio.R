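# Structure reading, secondary structure, accessibility, annotations.

test_that("PDB round trip and cross-format mmCIF agreement", {
  cx <- toy_complex(seed = 3)
  pdb <- tempfile(fileext = ".pdb")
  cif <- tempfile(fileext = ".cif")
  write_structure_pdb(cx$structure, pdb)
  write_mmcif_fixture(cx$structure, cif)
  s_pdb <- read_structure(pdb, id = "toy")
  s_cif <- read_structure(cif, id = "toy")

  expect_equal(length(unique(s_pdb$residues$chain)), 2)
  expect_equal(nrow(s_pdb$residues), nrow(cx$structure$residues))
  expect_equal(nrow(s_pdb$atoms), nrow(cx$structure$atoms))
  expect_identical(s_pdb$residues$aa, cx$structure$residues$aa)
  expect_false(any(s_pdb$residues$incomplete))
  # seq_index strictly increasing per chain
  for (ch in unique(s_pdb$residues$chain)) {
    si <- s_pdb$residues$seq_index[s_pdb$residues$chain == ch]
    expect_true(all(diff(si) > 0))
  }
  # same model in both formats parses to identical contents
  expect_identical(s_pdb$residues$aa, s_cif$residues$aa)
  expect_equal(s_pdb$atoms[, c("chain", "seq_index", "elety")],
               s_cif$atoms[, c("chain", "seq_index", "elety")])
  expect_equal(as.matrix(s_pdb$atoms[, c("x", "y", "z")]),
               as.matrix(s_cif$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3)
})

test_that("degenerate structure files raise parse errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), f)
  expect_error(read_structure(f), "ATOM|parse")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("internal assigner labels ideal geometries correctly and is idempotent", {
  helix <- toy_complex(peptide_kind = "helix", peptide_len = 8, seed = 5)
  st <- assign_secondary_structure(helix$structure)
  hss <- st$residues$ss[st$residues$chain == "B"]
  expect_true(all(hss == "H"))

  strand <- toy_complex(peptide_kind = "strand", peptide_len = 8, seed = 5)
  st2 <- assign_secondary_structure(strand$structure)
  sss <- st2$residues$ss[st2$residues$chain == "B"]
  expect_true(all(sss %in% c("E", "-")))
  expect_false(any(sss %in% c("H", "G", "I")))

  # idempotent: re-running changes nothing
  expect_identical(assign_secondary_structure(st)$residues, st$residues)
})

test_that("DSSP file parsing is a column identity and mismatches error", {
  df <- data.frame(resno = 1:6, chain = "A",
                   aa = c("A", "L", "G", "K", "S", "T"),
                   ss = c("H", "H", "H", "T", "-", "E"),
                   acc = c(10, 55, 3, 120, 80, 40))
  f <- write_dssp_fixture(df, tempfile(fileext = ".dssp"))
  parsed <- parse_dssp(f)
  expect_identical(parsed$ss, df$ss)
  expect_equal(parsed$acc, df$acc)
  expect_equal(parsed$resno, df$resno)

  st <- make_line_chain(6)
  st2 <- assign_secondary_structure(st, dssp_path = f)
  expect_identical(st2$residues$ss, df$ss)

  st7 <- make_line_chain(7)
  expect_error(assign_secondary_structure(st7, dssp_path = f), "unmatched")
})

test_that("accessibility: exposed, buried and convergent", {
  # single isolated glycine-like residue is exposed
  g <- dmiminer:::backbone_atoms(matrix(0, 1, 3))
  a1 <- sasa_atoms(as.matrix(g[, c("x", "y", "z")]),
                   dmiminer:::vdw_radius(g$element))
  expect_gt(sum(a1), 50)

  # residue caged inside a dense synthetic shell is buried (<= 1 A^2)
  shell <- dmiminer:::fibonacci_sphere(300) * 4.0
  xyz <- rbind(c(0, 0, 0), shell)
  a2 <- sasa_atoms(xyz, rep(1.7, nrow(xyz)))
  expect_lte(a2[1], 1)

  # doubling the sphere-point count changes per-residue values < 2%
  cx <- toy_complex(seed = 3)
  at <- cx$structure$atoms[cx$structure$atoms$chain == "B", ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- dmiminer:::vdw_radius(at$element)
  s960 <- tapply(sasa_atoms(xyz, rad, n_points = 960), at$seq_index, sum)
  s1920 <- tapply(sasa_atoms(xyz, rad, n_points = 1920), at$seq_index, sum)
  expect_true(all(abs(s960 - s1920) / pmax(s1920, 1) < 0.02))
})

test_that("accessibility is invariant under rigid motion", {
  cx <- toy_complex(seed = 4)
  st <- compute_accessibility(cx$structure, n_points = 240)
  set.seed(42)
  rot <- random_rotation(); shift <- rnorm(3, sd = 20)
  st2 <- cx$structure
  st2$atoms[, c("x", "y", "z")] <-
    rigid_motion(st2$atoms[, c("x", "y", "z")], rot, shift)
  st2 <- compute_accessibility(st2, n_points = 240)
  expect_equal(st2$residues$acc, st$residues$acc, tolerance = 1e-6)
})

test_that("annotation tables are validated", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("structure\tchain\tfamily\tstart\tend\tkind",
               "s1\tA\tSH3\t1\t60\tsequence",
               "s1\tA\tCATHX\t1\t70\tstructure",
               "s1\tB\tPDZ\t10\t90\tsequence"), f)
  ann <- load_annotations(f)
  expect_equal(nrow(ann), 3)

  writeLines(c("structure\tchain\tfamily\tstart\tend\tkind",
               "s1\tA\tSH3\t60\t1\tsequence"), f)
  expect_error(load_annotations(f), "row")

  writeLines(c("structure\tchain\tfamily\tstart\tend\tkind",
               "s1\tA\tSH3\t1\t60\tmystery"), f)
  expect_error(load_annotations(f), "kind")
})

test_that("profile maps load and must be injective", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("family\tstructure\tchain\tseq_index\tcolumn",
               paste("SH3", "s1", "A", 10:60, 1:51, sep = "\t")), f)
  pm <- load_profile_map(f)
  expect_equal(nrow(pm), 51)
  expect_equal(pm$column[pm$seq_index == 10], 1)

  writeLines(c("family\tstructure\tchain\tseq_index\tcolumn",
               "SH3\ts1\tA\t10\t1", "SH3\ts1\tA\t11\t1"), f)
  expect_error(load_profile_map(f), "injective")
})
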