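test_that("a single ATOM record round-trips through the parser", {
  line <- "ATOM      1  CA  GLY A   1      11.104  13.207  10.000  1.00  5.00           C"
  m <- parse_structure(c(line, "END"), format = "pdb")
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$resseq, 1L)
  expect_equal(m$atoms$atom, "CA")
  expect_equal(c(m$atoms$x, m$atoms$y, m$atoms$z), c(11.104, 13.207, 10.0))
  expect_false(m$atoms$het)
})

test_that("generated fixtures survive a write/parse round trip at PDB precision", {
  fix <- make_toy_hydrolase(seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fix$model, path)
  m2 <- parse_structure(path)
  expect_equal(nrow(m2$atoms), nrow(fix$model$atoms))
  expect_identical(m2$atoms$atom, fix$model$atoms$atom)
  expect_identical(m2$atoms$chain, fix$model$atoms$chain)
  expect_identical(m2$atoms$resname, fix$model$atoms$resname)
  expect_lt(max(abs(model_coords(m2) - model_coords(fix$model))), 1e-3)
})

test_that("mmCIF atom_site input parses to the same model as PDB", {
  fix <- make_toy_hydrolase(seed = 3)
  a <- fix$model$atoms
  cif <- c(
    "data_toy", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "Cartn_x", "Cartn_y",
             "Cartn_z", "occupancy", "B_iso_or_equiv", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_ins_code", "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s . %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s ? 1",
            ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
            a$atom, a$resname, a$x, a$y, a$z, a$occ, a$b, a$resseq,
            a$resname, a$chain, a$atom))
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, path)
  m <- parse_structure(path)
  expect_identical(m$source_format, "mmcif")
  expect_equal(nrow(m$atoms), nrow(a))
  expect_identical(m$atoms$atom, a$atom)
  expect_lt(max(abs(model_coords(m) - round(model_coords(fix$model), 3))),
            1e-9)
})

test_that("altloc resolution keeps highest occupancy, ties to smallest id, deterministically", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA CSER A   2       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BSER A   2       2.000   0.000   0.000  0.50  0.00           C",
    "END")
  m1 <- parse_structure(lines, format = "pdb")
  expect_equal(nrow(m1$atoms), 2L)
  # residue 1: occupancy winner B; residue 2: tie -> lexicographic B < C
  expect_equal(m1$atoms$x[m1$atoms$resseq == 1L], 1.0)
  expect_equal(m1$atoms$altloc[m1$atoms$resseq == 2L], "B")
  m2 <- parse_structure(lines, format = "pdb")
  expect_identical(m1$atoms, m2$atoms)
  rep <- attr(m1, "altloc_report")
  expect_equal(nrow(rep), 2L)
})

test_that("selection order follows the specification, not the file", {
  fix <- make_toy_hydrolase(seed = 1)
  sel <- atom_selection(c("D", "A", "B"), c(11, 4, 7),
                        c("CA", "N", "CA"))
  xyz <- select_atoms(fix$model, sel)
  expect_equal(rownames(xyz), c("D/11/CA", "A/4/N", "B/7/CA"))
  # empty selection
  empty <- select_atoms(fix$model, atom_selection(character(0), integer(0),
                                                  character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("the donor backbone N resolves once per chain on the tetramer fixture", {
  fix <- make_toy_hydrolase(seed = 1, n_chains = 4)
  for (ch in model_chains(fix$model)) {
    xyz <- select_atoms(fix$model, atom_selection(ch, 4, "N"))
    expect_equal(nrow(xyz), 1L)
  }
})

test_that("strict mode lists every unresolved atom; lenient mode drops them", {
  fix <- make_toy_hydrolase(seed = 1)
  sel <- atom_selection(c("A", "A", "A"), c(4, 4, 7), c("N", "CB", "OG"))
  # Gly 4 has no CB
  err <- expect_error(select_atoms(fix$model, sel), "missing atoms")
  expect_match(conditionMessage(err), "A/4/CB")
  xyz <- select_atoms(fix$model, sel, strict = FALSE)
  expect_equal(nrow(xyz), 2L)
  expect_equal(nrow(attr(xyz, "dropped")), 1L)
})

test_that("multi-model PDB files yield model 1, or a frame list on request", {
  fix <- make_toy_hydrolase(seed = 1, n_chains = 1)
  shifted <- transform_model(fix$model, rigid_transform(diag(3), c(5, 0, 0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(list(fix$model, shifted), path)
  one <- parse_structure(path)
  expect_s3_class(one, "StructureModel")
  expect_lt(max(abs(model_coords(one) - round(model_coords(fix$model), 3))),
            1e-9)
  many <- parse_structure(path, ensemble = TRUE)
  expect_length(many, 2L)
  expect_lt(max(abs(model_coords(many[[2]]) -
                      round(model_coords(shifted), 3))), 1e-9)
})

test_that("waters and hydrogens are kept but flagged", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   GLY A   1       1.000   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 100       5.000   0.000   0.000  1.00  0.00           O",
    "END")
  m <- parse_structure(lines, format = "pdb")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(sum(m$atoms$hydrogen), 1L)
  expect_equal(sum(m$atoms$water), 1L)
  # excluded from the heavy-atom coordinate view
  expect_equal(nrow(model_coords(m)), 1L)
})

test_that("malformed and unreadable inputs fail with context", {
  expect_error(parse_structure("/no/such/file.pdb"), "cannot read")
  bad <- c("ATOM      1  CA  GLY A   1      xx.xxx   0.000   0.000  1.00  0.00           C",
           "END")
  expect_error(parse_structure(bad, format = "pdb"), "malformed")
  expect_error(parse_structure("just some text", format = "auto"),
               "cannot determine format|no ATOM")
})
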