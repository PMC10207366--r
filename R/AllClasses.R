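#' @import methods
NULL

## Column layout of the per-atom table carried by a QSARDataset. The first
## six columns identify and place the atom; the remainder is the descriptor
## vector every projection recipe draws its weights from.
.ATOM_COLS <- c("mol_id", "atom_index", "element", "x", "y", "z",
                "logp", "hbd", "hba", "q_gast", "q_esp",
                "r_vdw", "lj_eps", "lj_rstar")
.DESC_COLS <- c("logp", "hbd", "hba", "q_gast", "q_esp",
                "r_vdw", "lj_eps", "lj_rstar")
.MOL_LABELS <- c("train", "test", "active", "decoy", "candidate")

#' QSARDataset: aligned molecules with per-atom descriptors and activities
#'
#' Container for a set of small molecules that share one 3D reference frame
#' (for example, docked or template-superposed ligand poses).  Atoms are held
#' column-wise in a single data frame, one row per atom, carrying coordinates
#' in Angstrom and the full per-atom descriptor vector: atomic log P
#' contribution, hydrogen-bond donor/acceptor values, Gasteiger and
#' ESP-derived partial charges (e), van der Waals radius (Angstrom) and
#' Lennard-Jones well depth (kcal/mol) / minimum-energy radius (Angstrom).
#' Sample-level data (activity as pIC50, set label, group) live in a second
#' data frame keyed by `mol_id`.
#'
#' @slot atoms data.frame with one row per atom; columns `mol_id`,
#'   `atom_index` (1-based, file order), `element`, `x`, `y`, `z`, `logp`,
#'   `hbd`, `hba`, `q_gast`, `q_esp`, `r_vdw`, `lj_eps`, `lj_rstar`.
#' @slot samples data.frame with one row per molecule; columns `mol_id`,
#'   `activity` (pIC50, NA for unlabelled screening candidates), `label`
#'   (one of train/test/active/decoy/candidate) and `group`.
#' @slot frameNote free-text provenance of the common alignment frame.
#'
#' @seealso [assembleDataset()], [generateDataset()]
#' @export
setClass("QSARDataset",
         representation(atoms = "data.frame",
                        samples = "data.frame",
                        frameNote = "character"))

setValidity("QSARDataset", function(object) {
  a <- object@atoms
  s <- object@samples
  msg <- character()
  if (!all(.ATOM_COLS %in% names(a)))
    msg <- c(msg, paste("atoms lacks columns:",
                        paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  if (!all(c("mol_id", "activity", "label", "group") %in% names(s)))
    msg <- c(msg, "samples lacks mol_id/activity/label/group")
  if (length(msg)) return(msg)
  if (nrow(s) < 1) msg <- c(msg, "dataset must contain at least one molecule")
  if (anyDuplicated(s$mol_id)) msg <- c(msg, "duplicated mol_id in samples")
  if (!all(a$mol_id %in% s$mol_id))
    msg <- c(msg, "atoms reference unknown mol_id")
  if (!all(s$mol_id %in% a$mol_id))
    msg <- c(msg, "molecule without atoms")
  if (!all(s$label %in% .MOL_LABELS))
    msg <- c(msg, paste("label must be one of",
                        paste(.MOL_LABELS, collapse = "/")))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) msg <- c(msg, "non-finite atom coordinates")
  if (any(a$atom_index < 1L)) msg <- c(msg, "atom_index must be 1-based")
  desc <- as.matrix(a[, .DESC_COLS])
  if (anyNA(desc)) msg <- c(msg, "incomplete descriptor vector")
  if (any(a$r_vdw <= 0, na.rm = TRUE)) msg <- c(msg, "vdw radius must be > 0")
  dup <- duplicated(a[, c("mol_id", "atom_index")])
  if (any(dup)) msg <- c(msg, "duplicated (mol_id, atom_index)")
  if (length(msg)) msg else TRUE
})

#' GridSpec: the regular lattice shared by all field projections
#'
#' An axis-aligned box discretized at fixed spacing.  Grid points are
#' enumerated x fastest, then y, then z, so point q = 1 sits at the origin
#' corner.
#'
#' @slot origin numeric(3), Angstrom; the corner of the padded box.
#' @slot spacing numeric(1), Angstrom between adjacent lattice planes.
#' @slot dims integer(3), number of lattice planes per axis.
#' @seealso [buildGrid()], [gridPoints()]
#' @export
setClass("GridSpec",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@origin) != 3 || !all(is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite coordinates")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive value")
  if (length(object@dims) != 3 || any(object@dims < 1))
    msg <- c(msg, "dims must be 3 positive integers")
  if (length(msg)) msg else TRUE
})

#' FieldConfig: projection and probe-energy parameters
#'
#' @slot alpha attenuation factor of the exponential projection (1/Angstrom
#'   implied); default 0.3.
#' @slot decayPower exponent applied to the atom-gridpoint distance inside
#'   the exponential (1 = exp(-alpha * r), the default; 2 = exp(-alpha * r^2)).
#' @slot dielectricMode "distance_dependent" (epsilon = r, the CoMFA default)
#'   or "constant" (epsilon = `dielectric`).
#' @slot dielectric relative permittivity used in constant mode.
#' @slot probeCharge probe point charge, e; default +1.
#' @slot probeEps,probeRstar Lennard-Jones parameters of the probe atom
#'   (kcal/mol, Angstrom); defaults are the packaged sp3-carbon values.
#' @slot energyCutoff symmetric clamp for projected probe energies, kcal/mol;
#'   default 10.
#' @slot minColumnSD variance-filter threshold for design columns; default 0.
#' @seealso [fieldConfig()]
#' @export
setClass("FieldConfig",
         representation(alpha = "numeric", decayPower = "numeric",
                        dielectricMode = "character", dielectric = "numeric",
                        probeCharge = "numeric", probeEps = "numeric",
                        probeRstar = "numeric", energyCutoff = "numeric",
                        minColumnSD = "numeric"))

setValidity("FieldConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (!object@decayPower %in% c(1, 2))
    msg <- c(msg, "decayPower must be 1 or 2")
  if (!object@dielectricMode %in% c("distance_dependent", "constant"))
    msg <- c(msg, "dielectricMode must be distance_dependent or constant")
  if (object@energyCutoff <= 0) msg <- c(msg, "energyCutoff must be > 0")
  if (object@minColumnSD < 0) msg <- c(msg, "minColumnSD must be >= 0")
  if (length(msg)) msg else TRUE
})

.FIELD_NAMES <- c("LOGP", "HBD", "HBA", "QE", "R3", "QG_COULOMB", "LJ")
.RECIPES <- list(QG_LJ = c("QG_COULOMB", "LJ"),
                 QE_R3 = c("QE", "R3"),
                 LOGP = "LOGP",
                 LOGP_HB = c("LOGP", "HBD", "HBA"))

#' FieldBlock: projected field values for one descriptor kind
#'
#' @slot name one of LOGP, HBD, HBA, QE, R3, QG_COULOMB, LJ.
#' @slot values n_molecules x n_points matrix, rows in dataset order
#'   (rownames are mol ids).
#' @slot mask logical per column; TRUE where the column survived variance
#'   filtering and enters the PLS design.
#' @seealso [assembleFieldBlocks()], [filterColumns()]
#' @export
setClass("FieldBlock",
         representation(name = "character", values = "matrix",
                        mask = "logical"))

setValidity("FieldBlock", function(object) {
  msg <- character()
  if (!object@name %in% .FIELD_NAMES)
    msg <- c(msg, paste("unknown field name", object@name))
  if (!all(is.finite(object@values))) msg <- c(msg, "non-finite field values")
  if (length(object@mask) != ncol(object@values))
    msg <- c(msg, "mask length != number of grid points")
  if (length(msg)) msg else TRUE
})

#' PLSModel: a fitted partial least-squares regression
#'
#' Single-response PLS fitted by NIPALS with column centering only (no
#' autoscaling).  The coefficient vector is expressed in original column
#' units, so predictions are `yCenter + (x - xCenter) %*% coefficients`.
#'
#' @slot nComponents number of latent components (Nc).
#' @slot coefficients numeric, one per retained design column.
#' @slot xCenter per-column training means.
#' @slot xSD per-column training standard deviations (used for the
#'   stdev-times-coefficient field contributions and contour maps).
#' @slot yCenter mean training activity.
#' @slot blockIndex character, field name owning each retained column.
#' @slot stats list of model statistics: `q2`, `spress`, `r2_fit`, `m`, `n`,
#'   `c`, `r2_origin`, `field_pct`, `loo_predictions`, `fitted`.
#' @seealso [fitPLS()], [looCV()], [selectComponents()]
#' @export
setClass("PLSModel",
         representation(nComponents = "integer", coefficients = "numeric",
                        xCenter = "numeric", xSD = "numeric",
                        yCenter = "numeric", blockIndex = "character",
                        stats = "list"))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  p <- length(object@coefficients)
  if (length(object@xCenter) != p || length(object@xSD) != p ||
      length(object@blockIndex) != p)
    msg <- c(msg, "coefficient/center/sd/blockIndex lengths differ")
  if (length(msg)) msg else TRUE
})

#' PharmacophoreModel: a trained field pharmacophore
#'
#' Bundles everything needed to re-project and score new aligned poses
#' identically to training: the recipe, the lattice, the projection
#' configuration, the per-block column masks and the fitted PLS model.
#'
#' @slot recipe one of QG_LJ, QE_R3, LOGP, LOGP_HB.
#' @slot grid the training [GridSpec-class].
#' @slot config the [FieldConfig-class] used at training time.
#' @slot masks named list of logical column masks, one per field block.
#' @slot pls the fitted [PLSModel-class].
#' @slot scanTable per-component LOO scan statistics (data.frame).
#' @slot provenance list: training mol ids, timestamps, dataset fingerprint.
#' @seealso [trainPharmacophore()], [scoreMolecules()], [coefficientMap()]
#' @export
setClass("PharmacophoreModel",
         representation(recipe = "character", grid = "GridSpec",
                        config = "FieldConfig", masks = "list",
                        pls = "PLSModel", scanTable = "data.frame",
                        provenance = "list"))

setValidity("PharmacophoreModel", function(object) {
  msg <- character()
  if (!object@recipe %in% names(.RECIPES))
    msg <- c(msg, paste("unknown recipe", object@recipe))
  else if (!identical(names(object@masks), unname(.RECIPES[[object@recipe]])))
    msg <- c(msg, "masks do not match the recipe's field blocks")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn QSARDataset-class number of molecules
#' @param object,x a QSARDataset
#' @export
setGeneric("nMolecules", function(object) standardGeneric("nMolecules"))
#' @export
setMethod("nMolecules", "QSARDataset", function(object) nrow(object@samples))

#' @describeIn QSARDataset-class molecule identifiers, in dataset order
#' @export
setGeneric("molIds", function(object) standardGeneric("molIds"))
#' @export
setMethod("molIds", "QSARDataset", function(object) object@samples$mol_id)

#' @describeIn QSARDataset-class named pIC50 vector (NA for candidates)
#' @export
setGeneric("activities", function(object) standardGeneric("activities"))
#' @export
setMethod("activities", "QSARDataset", function(object)
  stats::setNames(object@samples$activity, object@samples$mol_id))

#' @describeIn QSARDataset-class set labels (train/test/active/decoy/candidate)
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))
#' @export
setMethod("sampleLabels", "QSARDataset", function(object)
  stats::setNames(object@samples$label, object@samples$mol_id))

#' @describeIn QSARDataset-class the per-atom table (all molecules)
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))
#' @export
setMethod("atomTable", "QSARDataset", function(object) object@atoms)

#' @describeIn QSARDataset-class the per-molecule sample table
#' @export
setGeneric("sampleTable", function(object) standardGeneric("sampleTable"))
#' @export
setMethod("sampleTable", "QSARDataset", function(object) object@samples)

#' @describeIn QSARDataset-class subset by molecule index or id
#' @param i molecule indices, logical mask or mol_id character vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "QSARDataset", function(x, i, j, ..., drop = FALSE) {
  ids <- if (is.character(i)) i else x@samples$mol_id[i]
  if (!all(ids %in% x@samples$mol_id)) stop("unknown mol_id in subset")
  s <- x@samples[match(ids, x@samples$mol_id), , drop = FALSE]
  a <- x@atoms[x@atoms$mol_id %in% ids, , drop = FALSE]
  a <- a[order(match(a$mol_id, ids), a$atom_index), , drop = FALSE]
  rownames(s) <- rownames(a) <- NULL
  new("QSARDataset", atoms = a, samples = s, frameNote = x@frameNote)
})

setMethod("show", "QSARDataset", function(object) {
  lab <- table(object@samples$label)
  cat("QSARDataset with", nrow(object@samples), "molecules,",
      nrow(object@atoms), "atoms\n")
  cat("  labels:", paste(names(lab), lab, sep = ":", collapse = " "), "\n")
  act <- object@samples$activity
  if (any(!is.na(act)))
    cat(sprintf("  pIC50 range: %.2f .. %.2f\n",
                min(act, na.rm = TRUE), max(act, na.rm = TRUE)))
  if (nzchar(object@frameNote)) cat("  frame:", object@frameNote, "\n")
})

#' @describeIn GridSpec-class total number of lattice points
#' @param object a GridSpec
#' @export
setGeneric("nGridPoints", function(object) standardGeneric("nGridPoints"))
#' @export
setMethod("nGridPoints", "GridSpec", function(object) prod(object@dims))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d points (%d total), spacing %.3f A\n",
              object@dims[1], object@dims[2], object@dims[3],
              prod(object@dims), object@spacing))
  up <- object@origin + (object@dims - 1L) * object@spacing
  cat(sprintf("  box [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] A\n",
              object@origin[1], up[1], object@origin[2], up[2],
              object@origin[3], up[3]))
})

setMethod("show", "FieldBlock", function(object) {
  cat(sprintf("FieldBlock %s: %d molecules x %d points (%d retained)\n",
              object@name, nrow(object@values), ncol(object@values),
              sum(object@mask)))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: Nc = %d, %d design columns\n",
              object@nComponents, length(object@coefficients)))
  s <- object@stats
  if (!is.null(s$q2))
    cat(sprintf("  q2 = %.3f  Spress = %.3f  r2(fit) = %.3f\n",
                s$q2, s$spress, s$r2_fit))
  if (!is.null(s$field_pct)) {
    cat("  field %:",
        paste(sprintf("%s: %.0f", names(s$field_pct), s$field_pct),
              collapse = "  "), "\n")
  }
})

setMethod("show", "PharmacophoreModel", function(object) {
  cat("PharmacophoreModel, recipe", object@recipe, "\n")
  show(object@grid)
  show(object@pls)
})

#' Recipe field names
#'
#' Field blocks entering the design for a projection recipe: `QG_LJ` combines
#' Coulomb (Gasteiger charges) and Lennard-Jones probe energies; `QE_R3`
#' combines exponential projections of ESP charges and cubed van der Waals
#' radii; `LOGP` uses atomic log P contributions alone; `LOGP_HB` adds the
#' hydrogen-bond donor and acceptor fields.
#'
#' @param recipe recipe name (case-insensitive).
#' @return character vector of field block names.
#' @export
recipeFields <- function(recipe) {
  recipe <- toupper(recipe)
  if (!recipe %in% names(.RECIPES))
    stop("unknown recipe '", recipe, "'; expected one of ",
         paste(names(.RECIPES), collapse = ", "))
  .RECIPES[[recipe]]
}
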