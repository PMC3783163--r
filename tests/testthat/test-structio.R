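test_that("structures round-trip through PDB and mmCIF at 3 decimals", {
  duplex <- build_ideal_bdna("GTACAAGCTT")
  model <- duplex$structure
  for (dialect in c("pdb", "mmcif")) {
    path <- tempfile(fileext = if (dialect == "pdb") ".pdb" else ".cif")
    write_structure(model, path, dialect)
    back <- read_structure(path, dialect)
    expect_equal(nrow(back$atoms), nrow(model$atoms))
    expect_identical(back$atoms$atom_name, model$atoms$atom_name)
    expect_identical(back$atoms$residue_number, model$atoms$residue_number)
    expect_identical(back$atoms$residue_name, model$atoms$residue_name)
    expect_identical(back$atoms$chain_id, model$atoms$chain_id)
    expect_lt(max(abs(coords(back) - round(coords(model), 3))), 5e-4)
    unlink(path)
  }
})

test_that("reader and writer reject what the dialect cannot express", {
  # zero ATOM records
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TEST", "END"), empty)
  expect_error(read_structure(empty, "pdb"))
  expect_error(read_structure(tempfile(), "pdb"), "no such file")
  unlink(empty)

  one_atom <- data.frame(atom_name = "CA", element = "C",
                         residue_name = "ALA", residue_number = 1L,
                         chain_id = "AB", x = 0, y = 0, z = 0,
                         is_hetero = FALSE, stringsAsFactors = FALSE)
  m <- structure_model(one_atom, c(AB = "other"))
  expect_error(write_structure(m, tempfile(fileext = ".pdb"), "pdb"),
               "chain ids longer than 1")
  # the same model is representable in mmCIF
  p <- tempfile(fileext = ".cif")
  write_structure(m, p, "mmcif")
  expect_identical(read_structure(p, "mmcif")$atoms$chain_id, "AB")
  unlink(p)

  big <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                    residue_number = seq_len(100000L), chain_id = "A",
                    x = 0, y = 0, z = 0, is_hetero = FALSE,
                    stringsAsFactors = FALSE)
  mbig <- structure_model(big, c(A = "other"))
  expect_error(write_structure(mbig, tempfile(fileext = ".pdb"), "pdb"),
               "serial limit")
})

test_that("chain roles are inferred from residue chemistry", {
  duplex <- build_ideal_bdna("ACGTACGT")
  prot <- data.frame(atom_name = "CA", element = "C", residue_name = "ALA",
                     residue_number = 1:3, chain_id = "A",
                     x = 1:3, y = 0, z = 0, is_hetero = FALSE,
                     stringsAsFactors = FALSE)
  zn <- data.frame(atom_name = "ZN", element = "ZN", residue_name = "ZN",
                   residue_number = 1L, chain_id = "Z", x = 0, y = 0, z = 9,
                   is_hetero = TRUE, stringsAsFactors = FALSE)
  atoms <- rbind(prot, duplex$structure$atoms, zn)
  roles <- infer_chain_roles(atoms)
  expect_identical(unname(roles[c("A", "T", "B", "Z")]),
                   c("integrase", "dna_top", "dna_bottom", "other"))
})

test_that("the LI domain scheme annotates a complete CTD chain", {
  model <- full_ctd_chain()
  ann <- annotate_domains(model, "A")
  expect_identical(ann$CC$range, c(342L, 416L))
  expect_identical(range(ann$CC$residues_present), c(342L, 416L))
  expect_identical(ann$ZD_anchor$range[1], 338L)
  expect_identical(ann$CC_tip$range[1], 374L)
  expect_identical(ann$ZD$metadata$zinc_cysteines, c(274L, 277L, 302L, 314L))
  # the CC insertion is carved out of the ZD span
  expect_false(any(ann$CC$residues_present %in% ann$ZD$residues_present))
  # sibling ranges partition the chain: no residue claimed twice
  sib <- c("alphaE", "RD", "RD_ZD_linker", "ZD", "CC")
  claimed <- unlist(lapply(ann[sib], `[[`, "residues_present"))
  expect_identical(anyDuplicated(claimed), 0L)
  expect_setequal(claimed, 133:452)
})

test_that("annotation tolerates gaps but rejects missing anchors", {
  model <- full_ctd_chain()
  # disordered CC gap: warning listing missing residues, annotation kept
  gappy <- model
  gappy$atoms <- gappy$atoms[!gappy$atoms$residue_number %in% 380:400, ]
  expect_warning(ann <- annotate_domains(gappy, "A"), "absent")
  expect_true(all(380:400 %in% ann$CC$residues_missing))
  # missing anchor residue is fatal
  noanchor <- model
  noanchor$atoms <- noanchor$atoms[noanchor$atoms$residue_number != 338, ]
  expect_error(annotate_domains(noanchor, "A", warn_missing = FALSE),
               "ZD_anchor")
  # empty range is an error
  bad <- li_domain_scheme()
  bad$RD$range <- c(200L, 150L)
  expect_error(annotate_domains(model, "A", bad), "range")
  # non-integrase chain rejected
  duplex <- build_ideal_bdna("ACGTAC")
  expect_error(annotate_domains(duplex$structure, "T"), "not an integrase")
})

test_that("YAML scheme matches the built-in one", {
  path <- system.file("extdata", "li_domains.yaml", package = "attarch")
  sc <- read_domain_scheme(path)
  ref <- li_domain_scheme()
  for (nm in names(ref)) expect_identical(sc[[nm]]$range, ref[[nm]]$range)
})

test_that("solvent fraction follows the Matthews relation", {
  # crystal bookkeeping from the published cell: I23, a = 290.8 A, four
  # CTD (320 residues) + 26-bp duplex complexes per asymmetric unit
  cell <- c(290.8, 290.8, 290.8, 90, 90, 90)
  contents <- cell_contents(
    proteins = list(list(residues = 320, copies = 4)),
    dnas = list(list(bp = 26, copies = 4)), zinc_ions = 6)
  sf <- solvent_fraction(cell, "I23", contents)
  expect_equal(sf, 0.74, tolerance = 0.02)
  # hand evaluation of the relation: Vm = 2.40 -> 1 - 1.23/2.40
  vm <- matthews_vm(cell, "I23", contents)
  expect_equal(sf, 1 - 1.23 / vm, tolerance = 1e-12)
  prot <- function(n) cell_contents(proteins = list(list(residues = n)))
  # choose a cell so that Vm = 2.40 exactly for a 100-residue protein in P1
  a <- (2.40 * 100 * 110)^(1 / 3)
  expect_equal(solvent_fraction(c(a, a, a, 90, 90, 90), "P1", prot(100)),
               1 - 1.23 / 2.40, tolerance = 1e-9)
  # empty contents -> pure solvent
  expect_equal(solvent_fraction(cell, "I23", cell_contents()), 1.0)
  # monotonically decreasing in macromolecular mass at fixed cell
  fracs <- vapply(c(100, 500, 1000, 2000), function(n)
    solvent_fraction(cell, "I23", prot(n)), numeric(1))
  expect_true(all(diff(fracs) < 0))
  expect_error(solvent_fraction(cell, "X999", contents), "space group")
  expect_error(solvent_fraction(c(0, 0, 0, 90, 90, 90), "I23", contents),
               "volume")
})
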