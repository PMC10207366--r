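test_that("grid construction matches the padded-box definition", {
  ds <- toyDataset(toyAtom("m", 1, 0, 0, 0), activities = 7)
  g <- buildGrid(ds, spacing = 1, padding = 4)
  expect_equal(g@origin, c(-4, -4, -4))
  expect_identical(g@dims, c(9L, 9L, 9L))
  expect_identical(nGridPoints(g), 729)
  # defaults
  expect_equal(formals(buildGrid)$spacing, 1.0)
  expect_equal(formals(buildGrid)$padding, 4.0)
  expect_error(buildGrid(ds, spacing = 0), "positive")
  expect_error(buildGrid(ds, padding = -1), "positive")
})

test_that("grid dims for two disjoint molecules match brute-force lattice enumeration", {
  atoms <- rbind(toyAtom("m1", 1, 0.3, 0.2, 0.1),
                 toyAtom("m1", 2, 2.8, 1.4, 0.9),
                 toyAtom("m2", 1, 7.1, 6.6, 5.2),
                 toyAtom("m2", 2, 8.4, 9.0, 6.3))
  ds <- toyDataset(atoms, activities = c(7, 8))
  sp <- 0.7; pad <- 3.1
  g <- buildGrid(ds, sp, pad)
  lo <- c(0.3, 0.2, 0.1) - pad
  hi <- c(8.4, 9.0, 6.3) + pad
  # oracle: count lattice planes from lo until the box is covered
  oracle <- vapply(1:3, function(k) {
    n <- 1L
    while (lo[k] + (n - 1L) * sp < hi[k] - 1e-9) n <- n + 1L
    n
  }, 1L)
  expect_identical(g@dims, oracle)
  expect_equal(g@origin, lo)
  # every atom at least `pad` inside the box
  up <- g@origin + (g@dims - 1L) * sp
  expect_true(all(atoms$x >= g@origin[1] + pad - 1e-9 &
                    atoms$x <= up[1] - pad + 1e-9))
})

test_that("grid point enumeration is x fastest, then y, then z", {
  g <- new("GridSpec", origin = c(0, 0, 0), spacing = 1,
           dims = c(2L, 3L, 2L))
  pts <- gridPoints(g)
  expect_identical(nrow(pts), 12L)
  expect_equal(unname(pts[1:3, 1]), c(0, 1, 0))   # x cycles first
  expect_equal(unname(pts[c(1, 3), 2]), c(0, 1))  # then y
  expect_equal(unname(pts[7, 3]), 1)              # z slowest
})

test_that("exponential projection matches its closed form", {
  # atom on a grid point: exp(0) = 1
  ds <- toyDataset(toyAtom("m", 1, 0, 0, 0, logp = 2), activities = 7)
  g <- new("GridSpec", origin = c(0, 0, 0), spacing = 1, dims = c(1L, 1L, 1L))
  expect_equal(projectExponential(ds, "m", g, "LOGP"), 2.0, tolerance = 0)

  # single atom, single points at 1 A and 2 A, alpha 0.3
  g2 <- new("GridSpec", origin = c(1, 0, 0), spacing = 1,
            dims = c(2L, 1L, 1L))
  f <- projectExponential(ds, "m", g2, "LOGP", alpha = 0.3)
  expect_equal(f / 2, c(exp(-0.3), exp(-0.6)), tolerance = 1e-12)
  expect_equal(sum(f / 2), 1.289630, tolerance = 1e-6)

  # zero weights -> identically zero field
  ds0 <- toyDataset(rbind(toyAtom("m", 1, 0.2, 0.4, 0.1),
                          toyAtom("m", 2, 1, 1, 1)), activities = 7)
  expect_true(all(projectExponential(ds0, "m", g2, "LOGP") == 0))

  # R3 weighting uses the cubed vdW radius
  dsr <- toyDataset(toyAtom("m", 1, 0, 0, 0, r_vdw = 1.5), activities = 7)
  expect_equal(projectExponential(dsr, "m", g, "R3"), 1.5^3)
})

test_that("exponential field is linear in the weights and decays monotonically", {
  a1 <- toyAtom("m", 1, 1.1, 2.2, 0.4, logp = 0.7)
  a2 <- toyAtom("m", 2, 3.0, 1.5, 2.2, logp = -1.2)
  ds <- toyDataset(rbind(a1, a2), activities = 7)
  dsx2 <- toyDataset(transform(rbind(a1, a2), logp = 2 * logp),
                     activities = 7)
  g <- buildGrid(ds, 1.5, 4)
  expect_equal(projectExponential(dsx2, "m", g, "LOGP"),
               2 * projectExponential(ds, "m", g, "LOGP"),
               tolerance = 1e-12)
  # single-atom field strictly decreases with distance
  ds1 <- toyDataset(toyAtom("m", 1, 0, 0, 0, logp = 1), activities = 7)
  gl <- new("GridSpec", origin = c(0.5, 0, 0), spacing = 0.5,
            dims = c(12L, 1L, 1L))
  f <- projectExponential(ds1, "m", gl, "LOGP")
  expect_true(all(diff(f) < 0))
})

test_that("fields are equivariant under joint translation of molecules and grid", {
  gen <- smallSynthetic(n = 3, seed = 8)
  ds <- gen$dataset
  shift <- c(2.13, -1.07, 0.55)
  at2 <- atomTable(ds)
  at2$x <- at2$x + shift[1]; at2$y <- at2$y + shift[2]
  at2$z <- at2$z + shift[3]
  ds2 <- methods::new("QSARDataset", atoms = at2, samples = sampleTable(ds),
                      frameNote = "shifted")
  g <- buildGrid(ds, 1, 4)
  g2 <- new("GridSpec", origin = g@origin + shift, spacing = g@spacing,
            dims = g@dims)
  cfg <- fieldConfig()
  for (f in c("LOGP", "QE", "R3")) {
    expect_lt(max(abs(projectExponential(ds, molIds(ds)[1], g, f) -
                        projectExponential(ds2, molIds(ds)[1], g2, f))),
              1e-10)
  }
  p1 <- projectProbeEnergies(ds, molIds(ds)[2], g, cfg)
  p2 <- projectProbeEnergies(ds2, molIds(ds)[2], g2, cfg)
  expect_lt(max(abs(p1$coulomb - p2$coulomb)), 1e-10)
  expect_lt(max(abs(p1$lj - p2$lj)), 1e-10)
})

test_that("probe energies follow the Coulomb closed form and the clamp contract", {
  # q = +1 e at 2 A from the probe, distance-dependent dielectric:
  # 332.0636 / (2*2) = 83.0159 kcal/mol, clamped to +10
  ds <- toyDataset(toyAtom("m", 1, 0, 0, 0, q_gast = 1), activities = 7)
  g <- new("GridSpec", origin = c(2, 0, 0), spacing = 1, dims = c(1L, 1L, 1L))
  cfg <- fieldConfig()
  pe <- projectProbeEnergies(ds, "m", g, cfg)
  expect_equal(pe$coulomb, 10)
  cfg100 <- fieldConfig(energyCutoff = 100)
  expect_equal(projectProbeEnergies(ds, "m", g, cfg100)$coulomb,
               332.0636 / 4, tolerance = 1e-10)

  # zero charges -> identically zero Coulomb row
  ds0 <- toyDataset(toyAtom("m", 1, 0.5, 0.5, 0.5), activities = 7)
  gbig <- buildGrid(ds0, 1, 4)
  expect_true(all(projectProbeEnergies(ds0, "m", gbig, cfg)$coulomb == 0))

  # grid point coincident with an atom: finite, equal to the clamp bound
  gat <- new("GridSpec", origin = c(0.5, 0.5, 0.5), spacing = 1,
             dims = c(1L, 1L, 1L))
  pe2 <- projectProbeEnergies(ds0, "m", gat, cfg)
  expect_true(is.finite(pe2$lj) && pe2$lj == 10)

  # no row ever exceeds the clamp bound in magnitude
  gen <- smallSynthetic(n = 4, seed = 12)
  gg <- buildGrid(gen$dataset, 1, 4)
  for (id in molIds(gen$dataset)) {
    pe3 <- projectProbeEnergies(gen$dataset, id, gg, cfg)
    expect_lte(max(abs(pe3$coulomb)), 10)
    expect_lte(max(abs(pe3$lj)), 10)
  }
})

test_that("recipes assemble the documented blocks, stacked per molecule", {
  gen <- smallSynthetic(n = 2, seed = 3)
  ds <- gen$dataset
  g <- buildGrid(ds, 1.5, 4)
  cfg <- fieldConfig()
  expect_named(assembleFieldBlocks(ds, "LOGP", g, cfg), "LOGP")
  expect_named(assembleFieldBlocks(ds, "LOGP_HB", g, cfg),
               c("LOGP", "HBD", "HBA"))
  expect_named(assembleFieldBlocks(ds, "QG_LJ", g, cfg),
               c("QG_COULOMB", "LJ"))
  blocks <- assembleFieldBlocks(ds, "QE_R3", g, cfg)
  # stacking oracle: block rows equal per-molecule projection calls
  for (i in 1:2) {
    expect_equal(blocks$QE@values[i, ],
                 projectExponential(ds, molIds(ds)[i], g, "QE"),
                 tolerance = 1e-12)
    expect_equal(blocks$R3@values[i, ],
                 projectExponential(ds, molIds(ds)[i], g, "R3"),
                 tolerance = 1e-12)
  }
  expect_error(assembleFieldBlocks(ds, "BOGUS", g, cfg), "unknown recipe")
})

test_that("variance filter masks constant columns and matches a recount", {
  set.seed(42)
  vals <- matrix(rnorm(8 * 50), 8, 50)
  vals[, 1:5] <- 3.3   # constant columns
  rownames(vals) <- paste0("m", 1:8)
  b <- new("FieldBlock", name = "LOGP", values = vals,
           mask = rep(TRUE, 50))
  f0 <- filterColumns(list(LOGP = b), 0)
  expect_identical(which(!f0$LOGP@mask), 1:5)
  thr <- stats::median(apply(vals, 2, sd))
  fm <- filterColumns(list(LOGP = b), thr)
  expect_identical(sum(fm$LOGP@mask),
                   sum(apply(vals, 2, sd) > thr))
  allconst <- new("FieldBlock", name = "LOGP",
                  values = matrix(1, 4, 3), mask = rep(TRUE, 3))
  expect_error(filterColumns(list(LOGP = allconst), 0), "every design column")
})
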