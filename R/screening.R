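#' Filter a SMILES library for the urea moiety
#'
#' Keeps molecules containing the urea substructure N-C(=O)-N with
#' trivalent neutral nitrogens (SMARTS `[NX3][CX3](=O)[NX3]`), the key
#' anchoring feature for the catalytic triad of the target; carbamates and
#' plain amides are excluded.  Set `disubstituted = TRUE` for the stricter
#' 1,3-disubstituted pattern.  Unparsable SMILES are dropped with a logged
#' count, never an error; an empty input yields an empty result.
#'
#' @param smiles character vector of SMILES strings (names preserved).
#' @param disubstituted require carbon substituents on both nitrogens.
#' @return the kept subset of `smiles`, in input order.
#' @examples
#' filterUrea(c(dmu = "CNC(=O)NC", carbamate = "COC(=O)NC"))
#' @export
filterUrea <- function(smiles, disubstituted = FALSE) {
  if (length(smiles) == 0) return(smiles)
  pattern <- if (disubstituted)
    "[#6][NX3H1][CX3](=O)[NX3H1][#6]" else "[NX3][CX3](=O)[NX3]"
  hits <- vapply(smiles, function(s) {
    tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      n <- ChemmineOB::smartsSearch_OB(mol, pattern, uniqueMatches = TRUE)
      if (length(n) == 0 || is.na(n)) NA_real_ else as.numeric(n)
    }, error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(hits))
    message(sum(is.na(hits)), " unparsable SMILES dropped")
  smiles[!is.na(hits) & hits > 0]
}

#' Build a docked pose set
#'
#' One screening molecule with its docked poses across several receptor
#' targets; lower docking score = better pose.
#'
#' @param mol_id molecule identifier.
#' @param target_ids character vector of target identifiers, in declared
#'   priority order (used to break score ties).
#' @param scores docking scores, one per target (lower = better).
#' @param poses optional list of pose structures (as the elements of
#'   [readAlignedStructures()]), one per target.
#' @return a `dockedPoseSet` list.
#' @export
dockedPoseSet <- function(mol_id, target_ids, scores, poses = NULL) {
  if (length(target_ids) < 1) stop("at least one target entry required")
  if (length(scores) != length(target_ids))
    stop("scores and target_ids lengths differ")
  structure(list(mol_id = mol_id, target_ids = target_ids,
                 scores = scores, poses = poses),
            class = "dockedPoseSet")
}

#' Select the best docked pose across targets
#'
#' Returns the entry with the minimum (most negative) docking score; ties
#' go to the first target in declared order.
#'
#' @param poseSet a [dockedPoseSet()].
#' @return list with `target_id`, `score`, `pose` (NULL when no pose
#'   structures were attached).
#' @export
selectBestPose <- function(poseSet) {
  i <- which.min(poseSet$scores)   # first minimum wins ties
  list(target_id = poseSet$target_ids[i],
       score = poseSet$scores[i],
       pose = if (is.null(poseSet$poses)) NULL else poseSet$poses[[i]])
}

#' Read a pose manifest
#'
#' CSV with columns `mol_id`, `target_id`, `score`; one row per docked
#' pose.  Rows are grouped into [dockedPoseSet()]s in first-appearance
#' order, target order within a molecule following row order.
#'
#' @param path CSV path.
#' @return list of `dockedPoseSet`s.
#' @export
readPoseManifest <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mol_id", "target_id", "score")
  if (!all(need %in% names(d)))
    stop("pose manifest lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  ids <- unique(d$mol_id)
  lapply(ids, function(id) {
    rows <- d[d$mol_id == id, , drop = FALSE]
    dockedPoseSet(id, rows$target_id, rows$score)
  })
}

#' Pharmacophore reranking of docking candidates
#'
#' The prospective-screening step: take the `topIn` pose sets by best
#' docking score, select each molecule's best pose across targets, score
#' the poses with the trained pharmacophore, and return the `topOut`
#' molecules by predicted pIC50 with full score provenance.  With fewer
#' than `topOut` candidates all are returned with a warning.  Ties in
#' predicted pIC50 keep docking order (stable sort), so the result is a
#' deterministic function of the input.
#'
#' @param model a [PharmacophoreModel-class].
#' @param poseSets list of [dockedPoseSet()]s whose poses carry structures,
#'   or -- when `dataset` is given -- score-only sets whose best poses are
#'   looked up in `dataset` by mol_id.
#' @param dataset optional [QSARDataset-class] holding the aligned pose of
#'   every candidate (descriptors included).
#' @param topIn number of best-docked molecules to rerank; default 100.
#' @param topOut number of molecules to report; default 9.
#' @return data.frame with `mol_id`, `target_id`, `dock_score`,
#'   `predicted_pIC50`, `rank`.
#' @export
rerankCandidates <- function(model, poseSets, dataset = NULL,
                             topIn = 100, topOut = 9) {
  if (length(poseSets) == 0) stop("no candidates to rerank")
  best <- lapply(poseSets, selectBestPose)
  ids <- vapply(poseSets, `[[`, "", "mol_id")
  scores <- vapply(best, `[[`, 0, "score")
  keep <- order(scores)[seq_len(min(topIn, length(poseSets)))]
  keep <- sort(keep)                      # preserve input order downstream
  ids <- ids[keep]
  best <- best[keep]
  scores <- scores[keep]
  if (is.null(dataset)) stop("a candidate pose dataset is required")
  sub <- dataset[ids]
  preds <- scoreMolecules(model, sub, sort = FALSE)
  stopifnot(identical(preds$mol_id, ids))
  if (length(ids) < topOut)
    warning("only ", length(ids), " candidates available (topOut = ",
            topOut, ")")
  ord <- order(-preds$predicted)[seq_len(min(topOut, length(ids)))]
  out <- data.frame(
    mol_id = ids[ord],
    target_id = vapply(best[ord], `[[`, "", "target_id"),
    dock_score = scores[ord],
    predicted_pIC50 = preds$predicted[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
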