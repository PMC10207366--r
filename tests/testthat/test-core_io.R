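test_that("SDF write/read round-trip preserves ids, order, elements and coordinates", {
  gen <- smallSynthetic(n = 40, seed = 5)
  ds <- gen$dataset
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeStructuresSDF(ds, sdf)
  back <- readAlignedStructures(sdf, format = "sdf")
  expect_length(back, 40)
  expect_identical(vapply(back, `[[`, "", "mol_id"), molIds(ds))
  at <- atomTable(ds)
  for (i in c(1, 17, 40)) {
    orig <- at[at$mol_id == molIds(ds)[i], ]
    expect_identical(back[[i]]$atoms$element, orig$element)
    expect_lt(max(abs(as.matrix(back[[i]]$atoms[, c("x", "y", "z")]) -
                        as.matrix(orig[, c("x", "y", "z")]))), 1e-4 + 1e-12)
  }
})

test_that("SDF reader preserves molecule order and rejects bad input", {
  atoms <- rbind(toyAtom("a", 1, 0, 0, 0), toyAtom("a", 2, 1.5, 0, 0),
                 toyAtom("b", 1, 1, 0, 0), toyAtom("b", 2, 1, 1.5, 0),
                 toyAtom("c", 1, 2, 0, 0), toyAtom("c", 2, 2, 0, 1.5))
  ds <- toyDataset(atoms)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeStructuresSDF(ds, sdf)
  expect_identical(vapply(readAlignedStructures(sdf), `[[`, "", "mol_id"),
                   c("a", "b", "c"))
  empty <- withr::local_tempfile(fileext = ".sdf")
  file.create(empty)
  expect_error(readAlignedStructures(empty), "empty")
  expect_error(readAlignedStructures("no_such_file.sdf"), "not found")
})

test_that("MOL2 reader parses TRIPOS atom blocks and flags malformed rows", {
  mol2 <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "lig1", " 2 1 0 0 0", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1  0.0000  0.0000  0.0000 C.3  1 LIG 0.0",
    "  2 N1  1.5000  0.0000  0.0000 N.am 1 LIG 0.0",
    "@<TRIPOS>BOND", "  1 1 2 1",
    "@<TRIPOS>MOLECULE", "lig2", " 1 0 0 0 0", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 O1  -1.2500  2.0000  0.5000 O.3  1 LIG 0.0"), mol2)
  mols <- readAlignedStructures(mol2, format = "mol2")
  expect_length(mols, 2)
  expect_identical(mols[[1]]$mol_id, "lig1")
  expect_identical(mols[[1]]$atoms$element, c("C", "N"))
  expect_equal(mols[[2]]$atoms$x, -1.25)
  bad <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "oops", "1", "@<TRIPOS>ATOM",
               "  1 C1 nonsense"), bad)
  expect_error(readAlignedStructures(bad, format = "mol2"),
               "molecule index 1")
})

test_that("descriptor table reader enforces the fixed header and 1-based keys", {
  gen <- smallSynthetic(n = 4, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorTable(atomTable(gen$dataset), csv)
  d <- readDescriptorTable(csv)
  expect_identical(nrow(d), nrow(atomTable(gen$dataset)))

  d0 <- utils::read.csv(csv)
  d0$atom_index[1] <- 0L
  utils::write.csv(d0, csv, row.names = FALSE)
  expect_error(readDescriptorTable(csv), "1-based")

  d1 <- utils::read.csv(csv)
  d1$atom_index[1] <- d1$atom_index[2]
  utils::write.csv(d1, csv, row.names = FALSE)
  expect_error(readDescriptorTable(csv), "duplicate")

  d2 <- utils::read.csv(csv)[, -3]
  utils::write.csv(d2, csv, row.names = FALSE)
  expect_error(readDescriptorTable(csv), "logp")
})

test_that("full dataset round-trip through disk preserves descriptors and activities", {
  gen <- smallSynthetic(n = 40, noiseSD = 0.2, seed = 9)
  ds <- gen$dataset
  dir <- withr::local_tempdir()
  writeDatasetFiles(ds, dir)
  back <- assembleDataset(
    readAlignedStructures(file.path(dir, "structures.sdf")),
    readDescriptorTable(file.path(dir, "descriptors.csv")),
    readActivityTable(file.path(dir, "activities.csv")))
  expect_identical(molIds(back), molIds(ds))
  expect_identical(nrow(atomTable(back)), nrow(atomTable(ds)))
  expect_identical(atomTable(back)$element, atomTable(ds)$element)
  num <- c("logp", "hbd", "hba", "q_gast", "q_esp", "r_vdw", "lj_eps",
           "lj_rstar")
  expect_lt(max(abs(as.matrix(atomTable(back)[num]) -
                      as.matrix(atomTable(ds)[num]))), 1e-6)
  expect_lt(max(abs(unname(activities(back)) - unname(activities(ds)))),
            1e-6)
  expect_true(all(sampleLabels(back) == "train"))
})

test_that("assembleDataset labels candidates, flags orphans and missing descriptors", {
  atoms <- rbind(toyAtom("m1", 1, 0, 0, 0), toyAtom("m2", 1, 1, 1, 1),
                 toyAtom("m3", 1, 2, 2, 2))
  structures <- lapply(c("m1", "m2", "m3"), function(id) {
    a <- atoms[atoms$mol_id == id, ]
    list(mol_id = id, atoms = a[, c("atom_index", "element", "x", "y", "z")])
  })
  desc <- atoms[, c("mol_id", "atom_index", "logp", "hbd", "hba",
                    "q_gast", "q_esp", "r_vdw", "lj_eps", "lj_rstar")]
  acts <- data.frame(mol_id = c("m1", "m2"), activity = c(7.1, 8.2))
  ds <- assembleDataset(structures, desc, acts)
  expect_identical(unname(sampleLabels(ds)),
                   c("train", "train", "candidate"))
  expect_equal(unname(activities(ds))[1:2], c(7.1, 8.2))

  # orphan descriptor row -> warning, not error
  desc_extra <- rbind(desc, transform(desc[1, ], atom_index = 99))
  expect_warning(assembleDataset(structures, desc_extra, acts), "orphan")

  # missing descriptor row -> error naming the atom
  expect_error(assembleDataset(structures, desc[-2, ], acts),
               "\\(m2, 1\\)")
})

test_that("assembleDataset is order-independent in its input rows", {
  gen <- smallSynthetic(n = 6, seed = 4)
  dir <- withr::local_tempdir()
  writeDatasetFiles(gen$dataset, dir)
  desc <- readDescriptorTable(file.path(dir, "descriptors.csv"))
  acts <- readActivityTable(file.path(dir, "activities.csv"))
  strs <- readAlignedStructures(file.path(dir, "structures.sdf"))
  a <- assembleDataset(strs, desc, acts)
  b <- assembleDataset(strs, desc[rev(seq_len(nrow(desc))), ],
                       acts[sample(nrow(acts)), ])
  expect_equal(atomTable(a), atomTable(b))
  expect_equal(sampleTable(a), sampleTable(b))
})

test_that("activity tables convert ic50_nM and reject duplicates", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mol_id,ic50_nM", "a,20", "b,0.4"), csv)
  acts <- readActivityTable(csv)
  expect_equal(acts$activity, 9 - log10(c(20, 0.4)))
  writeLines(c("mol_id,pic50", "a,7", "a,8"), csv)
  expect_error(readActivityTable(csv), "duplicated")
  writeLines(c("mol_id,foo", "a,7"), csv)
  expect_error(readActivityTable(csv), "pic50 or ic50_nM")
})

test_that("packaged external-validation fixture matches its published range", {
  d <- loadVS1Predictions()
  expect_identical(nrow(d), 46L)
  expect_equal(min(d$experimental), 5.8)
  expect_equal(max(d$experimental), 9.4)
  expect_equal(unlist(d[d$mol_id == "VS1_mol1",
                        c("experimental", "qg_lj", "qe_r3", "logp",
                          "logp_hb")], use.names = FALSE),
               c(6.0, 7.5, 9.3, 6.4, 6.5))
})

test_that("QSARDataset validity rejects inconsistent containers", {
  atoms <- rbind(toyAtom("m1", 1, 0, 0, 0), toyAtom("m1", 2, 1, 0, 0))
  ds <- toyDataset(atoms, activities = 7)
  expect_s4_class(ds, "QSARDataset")
  bad <- atoms
  bad$x[1] <- NaN
  expect_error(toyDataset(bad, activities = 7), "non-finite")
  bad2 <- atoms
  bad2$atom_index[2] <- 1
  expect_error(toyDataset(bad2, activities = 7), "duplicated")
  bad3 <- atoms
  bad3$logp[1] <- NA
  expect_error(toyDataset(bad3, activities = 7), "descriptor")
})
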