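#' Train a field pharmacophore
#'
#' Full training pipeline for one recipe: build the common lattice around
#' the training molecules, project the recipe's field blocks, variance-filter
#' the columns, scan component counts under leave-one-out cross-validation,
#' and fit the final PLS model at the best `Nc` (highest q2, ties broken by
#' lower Spress then smaller `Nc`).  The resulting model carries the grid,
#' configuration and column masks so that new poses are re-projected
#' identically at prediction time.
#'
#' @param dataset a [QSARDataset-class]; all molecules must carry an
#'   activity.  At least 6 training molecules are required for the
#'   cross-validation to have meaningful degrees of freedom.
#' @param recipe one of `"QG_LJ"`, `"QE_R3"`, `"LOGP"`, `"LOGP_HB"`.
#' @param config a [FieldConfig-class].
#' @param spacing,padding lattice parameters, Angstrom; defaults 1.0 / 4.0.
#' @param nMax largest component count scanned; default 10.
#' @return a [PharmacophoreModel-class].  The embedded [PLSModel-class]
#'   `stats` list holds `q2`, `spress`, `r2_fit`, the LOO predictions and
#'   the regression diagnostics of cross-validated vs experimental
#'   activities (`m`, `n`, `c`, `r2_origin`).
#' @export
trainPharmacophore <- function(dataset, recipe, config = fieldConfig(),
                               spacing = 1.0, padding = 4.0, nMax = 10) {
  recipe <- toupper(recipe)
  y <- unname(activities(dataset))
  if (anyNA(y))
    stop("all molecules must have activities for training (",
         sum(is.na(y)), " missing)")
  if (nMolecules(dataset) < 6)
    stop("need at least 6 training molecules, got ", nMolecules(dataset))
  grid <- buildGrid(dataset, spacing, padding)
  blocks <- assembleFieldBlocks(dataset, recipe, grid, config)
  blocks <- filterColumns(blocks, config@minColumnSD)
  des <- .designMatrix(blocks)
  sel <- selectComponents(des$X, y, nMax)
  model <- fitPLS(des$X, y, sel$bestNc, blockIndex = des$blockIndex)
  cv <- looCV(des$X, y, sel$bestNc)
  reg <- regressionValidation(y, cv$loo_predictions,
                              orientation = "pred_on_obs")
  model@stats <- c(model@stats,
                   list(q2 = cv$q2, spress = cv$spress,
                        loo_predictions = cv$loo_predictions,
                        m = reg$m, n = reg$n, c = reg$c,
                        r2_origin = reg$r2_origin))
  new("PharmacophoreModel", recipe = recipe, grid = grid, config = config,
      masks = lapply(blocks, slot, "mask"), pls = model,
      scanTable = sel$scan,
      provenance = list(mol_ids = molIds(dataset),
                        n_train = nMolecules(dataset),
                        trained = format(Sys.time(), tz = "UTC"),
                        activity_mean = mean(y)))
}

## Project a dataset with a trained model's grid/config and reduce to the
## stored training columns.
.modelDesign <- function(model, dataset) {
  blocks <- assembleFieldBlocks(dataset, model@recipe, model@grid,
                                model@config)
  X <- do.call(cbind, lapply(names(blocks), function(f)
    blocks[[f]]@values[, model@masks[[f]], drop = FALSE]))
  X
}

#' Score aligned candidate poses with a trained pharmacophore
#'
#' Re-projects each candidate pose onto the model's stored lattice with the
#' stored configuration, applies the training column masks, and predicts
#' pIC50 with the embedded PLS model.  Poses reaching outside the lattice
#' box are scored anyway -- the exponential fields extend beyond the box --
#' but a warning is logged.  Ties keep input order (stable sort).
#'
#' @param model a [PharmacophoreModel-class].
#' @param dataset a [QSARDataset-class] of aligned candidate poses (in the
#'   model's frame, with complete descriptors).
#' @param sort sort rows by descending prediction (default TRUE).
#' @return data.frame with `mol_id` and `predicted` (pIC50).
#' @export
scoreMolecules <- function(model, dataset, sort = TRUE) {
  at <- atomTable(dataset)
  up <- model@grid@origin + (model@grid@dims - 1L) * model@grid@spacing
  outside <- at$x < model@grid@origin[1] | at$x > up[1] |
    at$y < model@grid@origin[2] | at$y > up[2] |
    at$z < model@grid@origin[3] | at$z > up[3]
  if (any(outside))
    warning(length(unique(at$mol_id[outside])),
            " molecule(s) have atoms outside the grid box; scored anyway")
  X <- .modelDesign(model, dataset)
  pred <- predict(model@pls, X)
  out <- data.frame(mol_id = molIds(dataset), predicted = unname(pred),
                    stringsAsFactors = FALSE)
  if (sort) out <- out[order(-out$predicted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coefficient contour map for one field
#'
#' Returns the `b_j * s_j` (coefficient times training column standard
#' deviation) volumetric map of one field block -- the usual display
#' quantity behind grid-field QSAR isocontour plots.  Masked-out columns
#' map to 0.  Positive values mark lattice regions where more of the
#' field's property in a ligand increases predicted pIC50 (for the LOGP
#' field: apolar-favoured regions).
#'
#' @param model a [PharmacophoreModel-class].
#' @param fieldName a field of the model's recipe.
#' @return list with `grid` (the [GridSpec-class]) and `values`, a numeric
#'   vector over all lattice points in x-fastest order.
#' @seealso [exportCube()], [exportOpenDX()]
#' @export
coefficientMap <- function(model, fieldName) {
  fieldName <- toupper(fieldName)
  fields <- recipeFields(model@recipe)
  if (!fieldName %in% fields)
    stop("field ", fieldName, " not in recipe ", model@recipe)
  vals <- numeric(nGridPoints(model@grid))
  own <- model@pls@blockIndex == fieldName
  vals[which(model@masks[[fieldName]])] <-
    model@pls@coefficients[own] * model@pls@xSD[own]
  list(grid = model@grid, values = vals)
}

.BOHR <- 1 / 0.529177210903

#' Export a volumetric map as a Gaussian cube file
#'
#' Standard cube layout: two comment lines, origin/axis records in Bohr,
#' one placeholder atom, then values with z fastest (the cube convention;
#' the in-memory x-fastest order is transposed on write and restored by
#' [readCube()]).
#'
#' @param map list with `grid` and `values` as from [coefficientMap()].
#' @param path output path.
#' @param comment first comment line.
#' @return invisibly, `path`.
#' @export
exportCube <- function(map, path, comment = "fieldpharm coefficient map") {
  g <- map$grid
  d <- g@dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "b*sd values, x fastest in memory"), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 1L,
                     g@origin[1] * .BOHR, g@origin[2] * .BOHR,
                     g@origin[3] * .BOHR), con)
  step <- g@spacing * .BOHR
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", d[1], step, 0, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", d[2], 0, step, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", d[3], 0, 0, step), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 6L, 0, 0, 0, 0), con)
  arr <- array(map$values, dim = d)      # x fastest in memory
  vals <- as.vector(aperm(arr, c(3, 2, 1)))  # cube wants z fastest
  lines <- tapply(sprintf("%16.8e", vals),
                  (seq_along(vals) - 1L) %/% 6L, paste, collapse = " ")
  writeLines(unname(lines), con)
  invisible(path)
}

#' Read a Gaussian cube file written by [exportCube()]
#' @param path cube file path.
#' @return list with `grid` and `values` (x-fastest order).
#' @export
readCube <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(trimws(lines[3:6]), "[[:space:]]+")
  natoms <- as.integer(hd[[1]][1])
  origin <- as.numeric(hd[[1]][2:4]) / .BOHR
  dims <- vapply(hd[2:4], function(f) as.integer(f[1]), 1L)
  spacing <- as.numeric(hd[[2]][2]) / .BOHR
  body <- lines[(6 + natoms + 1):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "[[:space:]]+")))
  arr <- array(vals, dim = rev(dims))     # read back z fastest
  grid <- new("GridSpec", origin = origin, spacing = spacing, dims = dims)
  list(grid = grid, values = as.vector(aperm(arr, c(3, 2, 1))))
}

#' Export a volumetric map in OpenDX format
#'
#' @inheritParams exportCube
#' @return invisibly, `path`.
#' @export
exportOpenDX <- function(map, path) {
  g <- map$grid
  d <- g@dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[3], d[2], d[1]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f",
                     g@origin[1], g@origin[2], g@origin[3]), con)
  writeLines(sprintf("delta %.6f 0.000000 0.000000", g@spacing), con)
  writeLines(sprintf("delta 0.000000 %.6f 0.000000", g@spacing), con)
  writeLines(sprintf("delta 0.000000 0.000000 %.6f", g@spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[3], d[2], d[1]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(d)), con)
  arr <- array(map$values, dim = d)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  lines <- tapply(sprintf("%.8e", vals),
                  (seq_along(vals) - 1L) %/% 3L, paste, collapse = " ")
  writeLines(unname(lines), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Serialize a trained pharmacophore to JSON
#'
#' The model file is plain JSON (grid, configuration, masks, centers,
#' coefficients, statistics, provenance) at full double precision, so a
#' reloaded model scores any dataset identically.
#'
#' @param model a [PharmacophoreModel-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePharmacophore <- function(model, path) {
  cfg <- model@config
  obj <- list(
    format = "fieldpharm-model",
    version = 1L,
    recipe = model@recipe,
    grid = list(origin = model@grid@origin, spacing = model@grid@spacing,
                dims = model@grid@dims),
    config = list(alpha = cfg@alpha, decayPower = cfg@decayPower,
                  dielectricMode = cfg@dielectricMode,
                  dielectric = cfg@dielectric,
                  probeCharge = cfg@probeCharge, probeEps = cfg@probeEps,
                  probeRstar = cfg@probeRstar,
                  energyCutoff = cfg@energyCutoff,
                  minColumnSD = cfg@minColumnSD),
    masks = lapply(model@masks, which),
    pls = list(nComponents = model@pls@nComponents,
               coefficients = model@pls@coefficients,
               xCenter = model@pls@xCenter, xSD = model@pls@xSD,
               yCenter = model@pls@yCenter,
               blockIndex = model@pls@blockIndex,
               stats = model@pls@stats[c("q2", "spress", "r2_fit", "m",
                                         "n", "c", "r2_origin",
                                         "field_pct")]),
    scan = model@scanTable,
    provenance = model@provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a pharmacophore model written by [writePharmacophore()]
#' @param path JSON model path.
#' @return a [PharmacophoreModel-class].
#' @export
readPharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fieldpharm-model"))
    stop(path, " is not a fieldpharm model file")
  grid <- new("GridSpec", origin = obj$grid$origin,
              spacing = obj$grid$spacing,
              dims = as.integer(obj$grid$dims))
  cfg <- new("FieldConfig", alpha = obj$config$alpha,
             decayPower = obj$config$decayPower,
             dielectricMode = obj$config$dielectricMode,
             dielectric = obj$config$dielectric,
             probeCharge = obj$config$probeCharge,
             probeEps = obj$config$probeEps,
             probeRstar = obj$config$probeRstar,
             energyCutoff = obj$config$energyCutoff,
             minColumnSD = obj$config$minColumnSD)
  np <- prod(grid@dims)
  masks <- lapply(obj$masks, function(idx) {
    m <- rep(FALSE, np)
    m[idx] <- TRUE
    m
  })
  stats <- obj$pls$stats
  stats$field_pct <- unlist(stats$field_pct)
  pls <- new("PLSModel", nComponents = as.integer(obj$pls$nComponents),
             coefficients = obj$pls$coefficients,
             xCenter = obj$pls$xCenter, xSD = obj$pls$xSD,
             yCenter = obj$pls$yCenter, blockIndex = obj$pls$blockIndex,
             stats = stats)
  new("PharmacophoreModel", recipe = obj$recipe, grid = grid, config = cfg,
      masks = masks, pls = pls,
      scanTable = as.data.frame(obj$scan),
      provenance = as.list(obj$provenance))
}
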