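#' Read aligned 3D structures from SDF or MOL2
#'
#' Reads all molecules of a multi-record SDF (V2000, via ChemmineR) or a
#' multi-record MOL2 file.  Molecules must already sit in one common
#' reference frame (docked poses or template-superposed ligands); no
#' alignment is performed here.  Hydrogens are retained as present in the
#' file and atom indices follow the file's atom-block order (1-based).
#'
#' @param path file path.
#' @param format `"sdf"` or `"mol2"`; defaults to the file extension.
#' @return a list with one element per molecule, each a list with `mol_id`
#'   (the record title, or `mol<i>` when blank) and `atoms`, a data.frame
#'   with columns `atom_index`, `element`, `x`, `y`, `z` (Angstrom).
#' @examples
#' sdf <- system.file("extdata", "example_probe.sdf", package = "fieldpharm")
#' if (nzchar(sdf)) str(readAlignedStructures(sdf), max.level = 2)
#' @export
readAlignedStructures <- function(path,
                                  format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mol2") "mol2" else "sdf"
  }
  if (file.info(path)$size == 0) stop("empty structure file: ", path)
  out <- switch(format,
                sdf = .readSDFStructures(path),
                mol2 = .readMOL2Structures(path))
  if (length(out) == 0) stop("no molecules parsed from ", path)
  out
}

.readSDFStructures <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok))
    stop("unparsable SDF record at molecule index ",
         paste(which(!ok), collapse = ", "), " in ", path)
  lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) < 1) stop("molecule index ", i, " has no atoms")
    elem <- sub("_.*$", "", rownames(ab))
    id <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(id) || is.na(id) || !nzchar(trimws(id)))
      id <- paste0("mol", i)
    list(mol_id = trimws(id),
         atoms = data.frame(atom_index = seq_len(nrow(ab)),
                            element = elem,
                            x = unname(ab[, 1]), y = unname(ab[, 2]),
                            z = unname(ab[, 3])))
  })
}

## Minimal TRIPOS MOL2 reader: MOLECULE record name + ATOM block
## (atom_id atom_name x y z atom_type ...); element taken as the SYBYL
## type's prefix before any dot.
.readMOL2Structures <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("no @<TRIPOS>MOLECULE record in ", path)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    rec <- lines[bounds[i]:(bounds[i + 1] - 1L)]
    id <- trimws(rec[2])
    if (!nzchar(id)) id <- paste0("mol", i)
    at <- grep("^@<TRIPOS>ATOM", rec)
    if (length(at) != 1) stop("molecule index ", i, " lacks an ATOM block")
    sec <- rec[(at + 1L):length(rec)]
    nxt <- grep("^@<TRIPOS>", sec)
    if (length(nxt)) sec <- sec[seq_len(nxt[1] - 1L)]
    sec <- sec[nzchar(trimws(sec))]
    if (length(sec) == 0) stop("molecule index ", i, " has no atoms")
    fields <- strsplit(trimws(sec), "[[:space:]]+")
    bad <- which(vapply(fields, length, 1L) < 6L)
    if (length(bad))
      stop("unparsable ATOM row in molecule index ", i,
           " (row ", bad[1], ")")
    xyz <- t(vapply(fields, function(f) as.numeric(f[3:5]), numeric(3)))
    if (!all(is.finite(xyz)))
      stop("non-numeric coordinates in molecule index ", i)
    list(mol_id = id,
         atoms = data.frame(
           atom_index = seq_along(fields),
           element = vapply(fields, function(f) sub("\\..*$", "", f[6]), ""),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  })
}

#' Write aligned structures as an SDF V2000 file
#'
#' Emits one V2000 record per molecule with the `mol_id` as the title line
#' and coordinates at the standard 4-decimal fixed-width precision.  The
#' field projections are bond-agnostic, so atoms are joined by a simple
#' single-bond chain purely to keep the records valid for standard SDF
#' tooling.  The counterpart reader is [readAlignedStructures()].
#'
#' @param structures a list as returned by [readAlignedStructures()], or a
#'   [QSARDataset-class] (whose coordinates and elements are exported).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeStructuresSDF <- function(structures, path) {
  if (is(structures, "QSARDataset")) {
    at <- atomTable(structures)
    structures <- lapply(molIds(structures), function(id) {
      a <- at[at$mol_id == id, , drop = FALSE]
      list(mol_id = id, atoms = a[order(a$atom_index), , drop = FALSE])
    })
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in structures) {
    a <- mol$atoms
    n <- nrow(a)
    writeLines(c(mol$mol_id, "  fieldpharm", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n, max(n - 1L, 0L)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (n > 1)
      writeLines(sprintf("%3d%3d  1  0  0  0  0",
                         seq_len(n - 1L), seq_len(n - 1L) + 1L), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

.DESC_HEADER <- c("mol_id", "atom_index", "logp", "hbd", "hba",
                  "q_gast", "q_esp", "r_vdw", "lj_eps", "lj_rstar")

#' Read a per-atom descriptor table
#'
#' The sidecar CSV carries the per-atom descriptor vector that has no
#' portable SDF encoding: atomic log P contribution, H-bond donor/acceptor
#' values, Gasteiger and ESP charges (e), van der Waals radius and
#' Lennard-Jones parameters.  Header names are fixed; each (mol_id,
#' atom_index) pair must be unique and atom indices are 1-based, matching
#' the structure file's atom-block order.
#'
#' @param path CSV path with columns `mol_id`, `atom_index`, `logp`, `hbd`,
#'   `hba`, `q_gast`, `q_esp`, `r_vdw`, `lj_eps`, `lj_rstar`.
#' @return data.frame keyed by (`mol_id`, `atom_index`), numeric descriptor
#'   columns.
#' @export
readDescriptorTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DESC_HEADER, names(d))
  if (length(missing))
    stop("descriptor table lacks column(s): ",
         paste(missing, collapse = ", "))
  d <- d[, .DESC_HEADER]
  if (any(d$atom_index < 1))
    stop("atom_index must be 1-based (found ", min(d$atom_index), ")")
  key <- paste(d$mol_id, d$atom_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate descriptor key (", dup$mol_id, ", ", dup$atom_index, ")")
  }
  num <- setdiff(.DESC_HEADER, c("mol_id", "atom_index"))
  d[num] <- lapply(d[num], as.numeric)
  d
}

#' Write a per-atom descriptor table
#' @param atoms data.frame holding the descriptor columns (e.g. from
#'   [atomTable()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeDescriptorTable <- function(atoms, path) {
  utils::write.csv(atoms[, .DESC_HEADER], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an activity table
#'
#' Activities are pIC50 (`-log10` of the molar IC50) in a `pic50` column;
#' an `ic50_nM` column is accepted instead and converted via
#' `pIC50 = 9 - log10(ic50_nM)`.  pKi values, where that is what a source
#' reports, go in the same column without distinction.  Optional `label`
#' (train/test/active/decoy/candidate) and `group` columns are carried
#' through.
#'
#' @param path CSV path with `mol_id` plus `pic50` or `ic50_nM`.
#' @return data.frame with columns `mol_id`, `activity`, `label`, `group`.
#' @export
readActivityTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mol_id" %in% names(d)) stop("activity table lacks column: mol_id")
  if ("pic50" %in% names(d)) {
    act <- as.numeric(d$pic50)
  } else if ("ic50_nM" %in% names(d)) {
    act <- 9 - log10(as.numeric(d$ic50_nM))
  } else {
    stop("activity table needs a pic50 or ic50_nM column")
  }
  if (anyDuplicated(d$mol_id)) stop("duplicated mol_id in activity table")
  data.frame(mol_id = d$mol_id,
             activity = act,
             label = if ("label" %in% names(d)) d$label else NA_character_,
             group = if ("group" %in% names(d)) d$group else "",
             stringsAsFactors = FALSE)
}

#' Write an activity table
#' @param samples data.frame with `mol_id`, `activity` and optionally
#'   `label`, `group` (e.g. from [sampleTable()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeActivityTable <- function(samples, path) {
  out <- data.frame(mol_id = samples$mol_id, pic50 = samples$activity)
  if ("label" %in% names(samples)) out$label <- samples$label
  if ("group" %in% names(samples)) out$group <- samples$group
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a validated QSAR dataset
#'
#' Joins aligned structures with their per-atom descriptors and (optionally)
#' activities into a [QSARDataset-class].  Every structure atom must have a
#' descriptor row; descriptor rows with no matching atom raise a warning.
#' Molecules without an activity are labelled `candidate` (screening poses);
#' molecules with one default to `train` unless the activity table supplies
#' a label.
#'
#' @param structures list from [readAlignedStructures()].
#' @param descriptors data.frame from [readDescriptorTable()].
#' @param activities optional data.frame from [readActivityTable()].
#' @param frameNote free-text provenance of the common alignment frame.
#' @return a [QSARDataset-class].
#' @export
assembleDataset <- function(structures, descriptors, activities = NULL,
                            frameNote = "") {
  ids <- vapply(structures, `[[`, "", "mol_id")
  if (anyDuplicated(ids))
    stop("duplicated mol_id among structures: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dkey <- paste(descriptors$mol_id, descriptors$atom_index, sep = "\r")
  atoms <- do.call(rbind, lapply(structures, function(mol) {
    a <- mol$atoms
    idx <- match(paste(mol$mol_id, a$atom_index, sep = "\r"), dkey)
    if (anyNA(idx)) {
      miss <- a$atom_index[which(is.na(idx))[1]]
      stop("no descriptor row for (", mol$mol_id, ", ", miss, ")")
    }
    cbind(data.frame(mol_id = mol$mol_id, atom_index = a$atom_index,
                     element = a$element, x = a$x, y = a$y, z = a$z,
                     stringsAsFactors = FALSE),
          descriptors[idx, setdiff(.DESC_HEADER, c("mol_id", "atom_index")),
                      drop = FALSE])
  }))
  rownames(atoms) <- NULL
  used <- dkey %in% paste(atoms$mol_id, atoms$atom_index, sep = "\r")
  if (any(!used))
    warning(sum(!used), " orphan descriptor row(s) with no matching atom")
  samples <- data.frame(mol_id = ids, activity = NA_real_,
                        label = "candidate", group = "",
                        stringsAsFactors = FALSE)
  if (!is.null(activities)) {
    idx <- match(samples$mol_id, activities$mol_id)
    hit <- !is.na(idx)
    samples$activity[hit] <- activities$activity[idx[hit]]
    samples$label[hit & !is.na(samples$activity)] <- "train"
    if ("label" %in% names(activities)) {
      lab <- activities$label[idx[hit]]
      keep <- !is.na(lab) & nzchar(lab)
      samples$label[hit][keep] <- lab[keep]
    }
    if ("group" %in% names(activities)) {
      grp <- activities$group[idx[hit]]
      samples$group[hit][!is.na(grp)] <- grp[!is.na(grp)]
    }
  }
  new("QSARDataset", atoms = atoms, samples = samples,
      frameNote = frameNote)
}
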