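#' Configuration of the synthetic aligned-ligand generator
#'
#' Defines the study conditions the generator emulates: a set of aligned
#' pseudo-ligands sharing a rigid common scaffold (so fields vary smoothly
#' across the set, as in a congeneric inhibitor series), with per-atom
#' descriptors drawn from fixed distributions and activities produced by a
#' known linear field-to-activity model plus Gaussian noise.
#'
#' Descriptor distributions: atomic log P contributions Normal(0, 0.5);
#' H-bond donor/acceptor indicators Bernoulli(0.15) on scaffold atoms and
#' Bernoulli(`variablePolarProb`, default 0.04) on the per-molecule
#' variable atoms -- in a congeneric inhibitor series the hydrogen-bonding
#' atoms concentrate in the conserved anchor moiety while variable
#' decorations are predominantly apolar; Gasteiger and ESP charges
#' Normal(0, 0.2) e; van der Waals radii Uniform(1.2, 2.0) Angstrom (also
#' used as the Lennard-Jones minimum-energy radius); LJ well depths
#' Uniform(0.05, 0.2) kcal/mol.
#'
#' @param nMolecules number of molecules; default 60.
#' @param atomsPerMolecule integer range of total atoms per molecule
#'   (scaffold included); default c(12, 20).
#' @param boxExtent side of the cubic region containing all atoms,
#'   Angstrom; default 8 (a drug-like ligand footprint).
#' @param nScaffold atoms shared (coordinates and descriptors) by every
#'   molecule, two of them pinned at opposite box corners so the lattice is
#'   identical across seeds; default 6.
#' @param nSites number of fixed attachment sites from which each
#'   molecule's variable atoms are drawn, mirroring the fixed R-group
#'   positions of a congeneric series; default 16.
#' @param trueRecipe field recipe generating the activities; default
#'   `"LOGP"`.
#' @param nProbes number of lattice probe points whose field values define
#'   the true activity; default 4 (a binding site with a few interaction
#'   hotspots: two hydrophobic subpockets plus secondary contact points).
#' @param activityMean,activitySD location/scale the noiseless activities
#'   are standardized to (pIC50 units); defaults 7 and 1.5, a realistic
#'   potency spread for an inhibitor series.
#' @param noiseSD Gaussian noise added to the activities; default 0.1.
#' @param variablePolarProb probability that a variable (non-scaffold)
#'   atom carries an H-bond donor or acceptor flag; default 0.04.
#' @param alpha,spacing,padding projection and lattice parameters used for
#'   the ground truth; defaults 0.3 / 1.0 / 4.0.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a named list of class `generatorConfig`.
#' @export
generatorConfig <- function(nMolecules = 60, atomsPerMolecule = c(12, 20),
                            boxExtent = 8, nScaffold = 6, nSites = 16,
                            trueRecipe = "LOGP", nProbes = 4,
                            activityMean = 7, activitySD = 1.5,
                            noiseSD = 0.1, alpha = 0.3, spacing = 1.0,
                            padding = 4.0, variablePolarProb = 0.04,
                            seed = 1) {
  if (nMolecules < 1) stop("nMolecules must be >= 1")
  if (any(atomsPerMolecule < nScaffold + 1))
    stop("atomsPerMolecule must exceed the scaffold size")
  if (max(atomsPerMolecule) - nScaffold > nSites)
    stop("atomsPerMolecule exceeds nScaffold + nSites")
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  recipeFields(trueRecipe)
  structure(list(nMolecules = nMolecules,
                 atomsPerMolecule = atomsPerMolecule,
                 boxExtent = boxExtent, nScaffold = nScaffold,
                 nSites = nSites,
                 trueRecipe = toupper(trueRecipe), nProbes = nProbes,
                 activityMean = activityMean, activitySD = activitySD,
                 noiseSD = noiseSD, alpha = alpha, spacing = spacing,
                 padding = padding, variablePolarProb = variablePolarProb,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

.drawDescriptors <- function(n, polarProb = 0.15) {
  hbd <- as.numeric(stats::runif(n) < polarProb)
  hba <- as.numeric(stats::runif(n) < polarProb)
  r <- stats::runif(n, 1.2, 2.0)
  data.frame(element = ifelse(hbd > 0, "N", ifelse(hba > 0, "O", "C")),
             logp = stats::rnorm(n, 0, 0.5),
             hbd = hbd, hba = hba,
             q_gast = stats::rnorm(n, 0, 0.2),
             q_esp = stats::rnorm(n, 0, 0.2),
             r_vdw = r,
             lj_eps = stats::runif(n, 0.05, 0.2),
             lj_rstar = r,
             stringsAsFactors = FALSE)
}

#' Generate an aligned pseudo-ligand dataset with known ground truth
#'
#' Molecules are clustered point sets in one frame: a rigid scaffold of
#' `nScaffold` atoms common to every molecule (two pinned at opposite
#' corners of the box, fixing the lattice) plus per-molecule variable
#' atoms placed on a subset of `nSites` fixed attachment sites with
#' freshly drawn descriptors -- the geometry of a congeneric series, where
#' substituents change but attachment positions do not.  The true activity
#' of molecule `i` is a linear
#' functional of its projected field values at `nProbes` fixed lattice
#' points -- so the PLS model class contains the truth and parameter
#' recovery is a fair test -- standardized to `activityMean` /
#' `activitySD`, plus Normal(0, `noiseSD`) noise.
#'
#' All randomness flows from `config$seed`; the global RNG state is left
#' untouched.
#'
#' @param config a [generatorConfig()].
#' @return list with `dataset` (a [QSARDataset-class], all molecules
#'   labelled `train`) and `truth`: `probePoints` (coordinates),
#'   `coefficients` (per field x probe), `intercept`, `noiseless`
#'   activities, `grid`, and the generating `config`.
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)
  ext <- config$boxExtent
  ns <- config$nScaffold
  scaffold <- cbind(.drawDescriptors(ns),
                    x = stats::runif(ns, 0, ext),
                    y = stats::runif(ns, 0, ext),
                    z = stats::runif(ns, 0, ext))
  ## two anchors pin the union bounding box (and hence the lattice)
  scaffold[1, c("x", "y", "z")] <- 0
  scaffold[2, c("x", "y", "z")] <- ext
  sites <- cbind(x = stats::runif(config$nSites, 0, ext),
                 y = stats::runif(config$nSites, 0, ext),
                 z = stats::runif(config$nSites, 0, ext))
  nm <- config$nMolecules
  ids <- sprintf("SYN_mol%03d", seq_len(nm))
  atoms <- do.call(rbind, lapply(seq_len(nm), function(i) {
    ntot <- sample(seq(config$atomsPerMolecule[1],
                       config$atomsPerMolecule[2]), 1)
    nv <- ntot - ns
    at <- sort(sample(config$nSites, nv))
    var <- cbind(.drawDescriptors(nv, config$variablePolarProb),
                 x = sites[at, "x"], y = sites[at, "y"],
                 z = sites[at, "z"])
    mol <- rbind(scaffold, var)
    cbind(data.frame(mol_id = ids[i], atom_index = seq_len(ntot),
                     stringsAsFactors = FALSE),
          mol[, c("element", "x", "y", "z", "logp", "hbd", "hba",
                  "q_gast", "q_esp", "r_vdw", "lj_eps", "lj_rstar")])
  }))
  rownames(atoms) <- NULL
  samples <- data.frame(mol_id = ids, activity = NA_real_, label = "train",
                        group = "", stringsAsFactors = FALSE)
  ds <- new("QSARDataset", atoms = atoms, samples = samples,
            frameNote = sprintf("synthetic generator seed %d", config$seed))
  ## ground truth: linear functional of field values at fixed lattice points
  grid <- buildGrid(ds, config$spacing, config$padding)
  pts <- gridPoints(grid)
  probeIdx <- sample(nrow(pts), config$nProbes)
  probePts <- pts[probeIdx, , drop = FALSE]
  fields <- recipeFields(config$trueRecipe)
  beta <- matrix(stats::rnorm(length(fields) * config$nProbes), ncol =
                   config$nProbes,
                 dimnames = list(fields, NULL))
  raw <- vapply(ids, function(id) {
    a <- .moleculeAtoms(ds, id)
    sum(vapply(fields, function(f)
      sum(beta[f, ] * .projectExpAt(a, probePts, f, config$alpha)),
      0))
  }, 0)
  sdr <- stats::sd(raw)
  scale <- if (nm > 1 && sdr > 0) config$activitySD / sdr else 1
  noiseless <- config$activityMean + scale * (raw - mean(raw))
  ds@samples$activity <-
    unname(noiseless + stats::rnorm(nm, 0, config$noiseSD))
  truth <- list(probePoints = probePts, probeIndex = probeIdx,
                coefficients = beta * scale,
                intercept = config$activityMean - scale * mean(raw),
                noiseless = unname(noiseless), grid = grid,
                config = config)
  list(dataset = ds, truth = truth)
}

#' Write a dataset as SDF + descriptor CSV + activity CSV
#'
#' The on-disk form of a [QSARDataset-class]: aligned structures
#' (`structures.sdf`), the per-atom descriptor sidecar
#' (`descriptors.csv`) and the activity table (`activities.csv`), readable
#' back with [readAlignedStructures()], [readDescriptorTable()],
#' [readActivityTable()] and [assembleDataset()].
#'
#' @param dataset a [QSARDataset-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeDatasetFiles <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("structures.sdf", "descriptors.csv",
                            "activities.csv"))
  writeStructuresSDF(dataset, paths[1])
  writeDescriptorTable(atomTable(dataset), paths[2])
  writeActivityTable(sampleTable(dataset), paths[3])
  invisible(paths)
}

#' External-validation activity table (46 compounds, four models)
#'
#' Packaged transcription of the published external-validation series:
#' experimental pIC50 for 46 compounds (four series of urea/amide inhibitors,
#' pIC50 range 5.8 to 9.4) together with the predictions of the four
#' pharmacophore models (QG+LJ, QE+R3, log P, log P + HB).
#'
#' @return data.frame with columns `mol_id`, `experimental`, `qg_lj`,
#'   `qe_r3`, `logp`, `logp_hb`.
#' @export
loadVS1Predictions <- function() {
  d <- utils::read.csv(system.file("extdata",
                                   "vs1_external_predictions.csv",
                                   package = "fieldpharm"),
                       stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 46)
  d
}

#' Prospective-study activity table (18 purchased compounds)
#'
#' Packaged transcription of the prospective screening results: measured
#' pIC50 against human, mouse and rat soluble epoxide hydrolase for the
#' nine compounds selected by each of the log P + HB and QE + R3
#' pharmacophores.
#'
#' @return data.frame with columns `mol_id`, `selecting_model`
#'   (`logp_hb` / `qe_r3`), `hsEH`, `msEH`, `rsEH`.
#' @export
loadProspectiveHits <- function() {
  d <- utils::read.csv(system.file("extdata", "prospective_hits.csv",
                                   package = "fieldpharm"),
                       stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 18)
  d
}
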