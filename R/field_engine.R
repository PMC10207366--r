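#' Projection and probe-energy configuration
#'
#' Constructor for [FieldConfig-class].  Defaults follow common molecular
#' field practice: attenuation factor 0.3 with a linear distance argument
#' in the exponential, a +1 e sp3-carbon probe with a distance-dependent
#' dielectric (epsilon = r) for the Coulomb field, and a symmetric clamp of
#' projected probe energies at +/- 10 kcal/mol.
#'
#' @param alpha attenuation factor (> 0); default 0.3.
#' @param decayPower 1 for `exp(-alpha * r)` (default) or 2 for
#'   `exp(-alpha * r^2)`.
#' @param dielectricMode `"distance_dependent"` (epsilon = r) or
#'   `"constant"`.
#' @param dielectric relative permittivity for constant mode; default 1.
#' @param probeCharge probe charge, e; default +1.
#' @param probeEps,probeRstar probe Lennard-Jones parameters; defaults read
#'   from the packaged `probe_params.csv` (sp3 carbon).
#' @param energyCutoff clamp bound for probe energies, kcal/mol; default 10.
#' @param minColumnSD variance-filter threshold; default 0 (drop only
#'   strictly constant columns).
#' @return a [FieldConfig-class] object.
#' @export
fieldConfig <- function(alpha = 0.3, decayPower = 1,
                        dielectricMode = c("distance_dependent", "constant"),
                        dielectric = 1,
                        probeCharge = 1,
                        probeEps = NULL, probeRstar = NULL,
                        energyCutoff = 10, minColumnSD = 0) {
  dielectricMode <- match.arg(dielectricMode)
  if (is.null(probeEps) || is.null(probeRstar)) {
    pf <- utils::read.csv(system.file("extdata", "probe_params.csv",
                                      package = "fieldpharm"),
                          stringsAsFactors = FALSE)
    row <- pf[pf$probe == "C.3", , drop = FALSE]
    if (is.null(probeEps)) probeEps <- row$lj_eps
    if (is.null(probeRstar)) probeRstar <- row$lj_rstar
  }
  new("FieldConfig", alpha = alpha, decayPower = decayPower,
      dielectricMode = dielectricMode, dielectric = dielectric,
      probeCharge = probeCharge, probeEps = probeEps,
      probeRstar = probeRstar, energyCutoff = energyCutoff,
      minColumnSD = minColumnSD)
}

#' Build the common lattice around an aligned dataset
#'
#' The axis-aligned union bounding box of all atoms of all molecules is
#' expanded by `padding` on every face and discretized at `spacing`, with
#' both boundary planes included.  The grid origin is the padded box corner
#' (no snapping to integer coordinates), and the upper face is extended to
#' the next lattice plane when the padded extent is not a multiple of the
#' spacing, so the padding is a guaranteed minimum.
#'
#' @param dataset a [QSARDataset-class] (or any data.frame with x/y/z
#'   columns).
#' @param spacing lattice spacing, Angstrom; default 1.0.
#' @param padding minimum extension beyond every atom, Angstrom; default 4.0.
#' @return a [GridSpec-class].
#' @examples
#' # a single atom at the origin with the defaults gives the box [-4, 4]^3:
#' # 9 planes per axis, 729 lattice points
#' @export
buildGrid <- function(dataset, spacing = 1.0, padding = 4.0) {
  if (spacing <= 0) stop("spacing must be positive")
  if (padding <= 0) stop("padding must be positive")
  at <- if (is(dataset, "QSARDataset")) atomTable(dataset) else dataset
  if (nrow(at) == 0) stop("dataset has no atoms")
  lo <- c(min(at$x), min(at$y), min(at$z)) - padding
  hi <- c(max(at$x), max(at$y), max(at$z)) + padding
  ext <- hi - lo
  dims <- as.integer(ceiling(ext / spacing - 1e-9)) + 1L
  new("GridSpec", origin = lo, spacing = spacing, dims = dims)
}

#' Lattice point coordinates
#'
#' @param grid a [GridSpec-class].
#' @return an `n_points x 3` matrix of coordinates (Angstrom), enumerated
#'   x fastest, then y, then z.
#' @export
gridPoints <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid@origin[k] + (seq_len(grid@dims[k]) - 1L) * grid@spacing)
  n <- prod(grid@dims)
  cbind(x = rep(ax[[1]], times = n / grid@dims[1]),
        y = rep(rep(ax[[2]], each = grid@dims[1]),
                times = grid@dims[3]),
        z = rep(ax[[3]], each = grid@dims[1] * grid@dims[2]))
}

## Atom-to-point Euclidean distance matrix (atoms x points), floored at
## `floor` to keep probe energies finite at coincident points.
.distMatrix <- function(axyz, pts, floor = 0) {
  d2 <- outer(rowSums(axyz^2), rowSums(pts^2), "+") -
    2 * axyz %*% t(pts)
  d <- sqrt(pmax(d2, 0))
  if (floor > 0) d[d < floor] <- floor
  d
}

.moleculeAtoms <- function(dataset, mol_id) {
  at <- atomTable(dataset)
  a <- at[at$mol_id == mol_id, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown mol_id: ", mol_id)
  a[order(a$atom_index), , drop = FALSE]
}

.expWeights <- function(atoms, weightKind) {
  switch(weightKind,
         LOGP = atoms$logp,
         HBD = atoms$hbd,
         HBA = atoms$hba,
         QE = atoms$q_esp,
         R3 = atoms$r_vdw^3,
         stop("unknown weight kind '", weightKind, "'"))
}

## Exponential projection at arbitrary points; the workhorse behind
## projectExponential() and the generator's probe-point ground truth.
.projectExpAt <- function(atoms, pts, weightKind, alpha, decayPower = 1) {
  w <- .expWeights(atoms, weightKind)
  r <- .distMatrix(as.matrix(atoms[, c("x", "y", "z")]), pts)
  if (decayPower == 2) r <- r^2
  as.vector(crossprod(exp(-alpha * r), w))
}

#' Exponential-decay projection of a per-atom descriptor
#'
#' Projects atomic weights onto the lattice as
#' `F_q = sum_i w_i * exp(-alpha * r_iq)`, where `r_iq` is the Euclidean
#' distance between atom `i` and grid point `q` (Angstrom) and `w_i` is the
#' descriptor selected by `weightKind`: the atomic log P contribution
#' (`LOGP`), hydrogen-bond donor/acceptor value (`HBD`/`HBA`), ESP partial
#' charge (`QE`) or the cubed van der Waals radius (`R3`).  No distance
#' cutoff is applied; the exponential makes far contributions negligible.
#'
#' @param dataset a [QSARDataset-class].
#' @param mol_id molecule to project.
#' @param grid a [GridSpec-class].
#' @param weightKind one of `"LOGP"`, `"HBD"`, `"HBA"`, `"QE"`, `"R3"`.
#' @param alpha attenuation factor; default 0.3.
#' @param decayPower distance exponent inside the exponential; default 1.
#' @return numeric field row of length `nGridPoints(grid)`.
#' @export
projectExponential <- function(dataset, mol_id, grid,
                               weightKind = c("LOGP", "HBD", "HBA",
                                              "QE", "R3"),
                               alpha = 0.3, decayPower = 1) {
  weightKind <- match.arg(weightKind)
  a <- .moleculeAtoms(dataset, mol_id)
  .projectExpAt(a, gridPoints(grid), weightKind, alpha, decayPower)
}

#' CoMFA-style probe interaction energies on the lattice
#'
#' Computes, for one molecule, the Coulomb and Lennard-Jones interaction
#' energies of a probe atom placed at every lattice point.  Coulomb:
#' `E_q = sum_i k * q_i * q_probe / (eps(r) * r_iq)` with
#' `k = 332.0636 kcal A / (mol e^2)` and `eps(r) = r_iq` in
#' distance-dependent mode (the CoMFA default).  Lennard-Jones 6-12 with
#' arithmetic/geometric combining rules `rstar_ij = rstar_i + rstar_probe`
#' and `eps_ij = sqrt(eps_i * eps_probe)`.  Each projected value is
#' independently clamped to `[-cutoff, +cutoff]`; lattice points that fall
#' inside an atom therefore yield the finite clamp bound, never infinity.
#'
#' @param dataset a [QSARDataset-class].
#' @param mol_id molecule to project.
#' @param grid a [GridSpec-class].
#' @param config a [FieldConfig-class]; supplies charges mode, probe
#'   parameters and the energy cutoff.
#' @return list with numeric rows `coulomb` and `lj`, each of length
#'   `nGridPoints(grid)`, kcal/mol.
#' @export
projectProbeEnergies <- function(dataset, mol_id, grid,
                                 config = fieldConfig()) {
  a <- .moleculeAtoms(dataset, mol_id)
  pts <- gridPoints(grid)
  r <- .distMatrix(as.matrix(a[, c("x", "y", "z")]), pts, floor = 1e-6)
  k <- 332.0636
  eps_r <- if (config@dielectricMode == "distance_dependent") r
           else config@dielectric
  coul <- as.vector(crossprod(1 / (eps_r * r),
                              k * a$q_gast * config@probeCharge))
  rstar <- a$lj_rstar + config@probeRstar
  epsij <- sqrt(a$lj_eps * config@probeEps)
  s6 <- (rstar / r)^6
  lj <- as.vector(crossprod(s6 * (s6 - 2), epsij))
  cut <- config@energyCutoff
  list(coulomb = pmin(pmax(coul, -cut), cut),
       lj = pmin(pmax(lj, -cut), cut))
}

#' Assemble the field blocks of a projection recipe
#'
#' Projects every molecule of the dataset onto the grid for each field of
#' the recipe: `QG_LJ` gives the Coulomb (Gasteiger) and Lennard-Jones
#' probe-energy blocks; `QE_R3`, `LOGP` and `LOGP_HB` give exponential
#' projections of the corresponding atomic descriptors.  Rows follow
#' dataset molecule order.
#'
#' @param dataset a [QSARDataset-class].
#' @param recipe one of `"QG_LJ"`, `"QE_R3"`, `"LOGP"`, `"LOGP_HB"`.
#' @param grid a [GridSpec-class].
#' @param config a [FieldConfig-class].
#' @return named list of [FieldBlock-class] objects, in recipe order, with
#'   all columns initially retained.
#' @export
assembleFieldBlocks <- function(dataset, recipe, grid,
                                config = fieldConfig()) {
  fields <- recipeFields(recipe)
  ids <- molIds(dataset)
  np <- nGridPoints(grid)
  pts <- gridPoints(grid)
  rows <- lapply(ids, function(id) {
    a <- .moleculeAtoms(dataset, id)
    out <- list()
    if (any(c("QG_COULOMB", "LJ") %in% fields)) {
      pe <- projectProbeEnergies(dataset, id, grid, config)
      out$QG_COULOMB <- pe$coulomb
      out$LJ <- pe$lj
    }
    for (f in setdiff(fields, c("QG_COULOMB", "LJ")))
      out[[f]] <- .projectExpAt(a, pts, f, config@alpha, config@decayPower)
    out
  })
  blocks <- lapply(fields, function(f) {
    vals <- do.call(rbind, lapply(rows, `[[`, f))
    rownames(vals) <- ids
    new("FieldBlock", name = f, values = vals, mask = rep(TRUE, np))
  })
  names(blocks) <- fields
  blocks
}

#' Variance-filter design columns
#'
#' Masks out lattice columns whose across-molecule standard deviation is
#' `<= minColumnSD`; constant columns carry no information and break
#' centering-only PLS.  The mask is stored per block for prediction-time
#' reuse, so new poses are reduced to exactly the training design columns.
#'
#' @param blocks named list of [FieldBlock-class] objects.
#' @param minColumnSD threshold (>= 0); default 0.
#' @return the blocks with their `mask` slots set.
#' @export
filterColumns <- function(blocks, minColumnSD = 0) {
  if (minColumnSD < 0) stop("minColumnSD must be >= 0")
  out <- lapply(blocks, function(b) {
    sds <- apply(b@values, 2, stats::sd)
    b@mask <- sds > minColumnSD
    b
  })
  if (sum(vapply(out, function(b) sum(b@mask), 0L)) == 0L)
    stop("variance filter removed every design column")
  out
}

## Stack the retained columns of the blocks into the PLS design matrix.
## Returns the matrix plus the field name owning each column.
.designMatrix <- function(blocks) {
  X <- do.call(cbind, lapply(blocks, function(b)
    b@values[, b@mask, drop = FALSE]))
  idx <- unlist(lapply(blocks, function(b) rep(b@name, sum(b@mask))),
                use.names = FALSE)
  list(X = X, blockIndex = idx)
}
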