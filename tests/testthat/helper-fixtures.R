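# In-code fixtures shared across test files.

# A hand-built atom row with full descriptor vector; defaults give an
# apolar carbon of vdW radius 1.7 A.
toyAtom <- function(mol_id, atom_index, x, y, z, element = "C",
                    logp = 0, hbd = 0, hba = 0, q_gast = 0, q_esp = 0,
                    r_vdw = 1.7, lj_eps = 0.107, lj_rstar = 1.7) {
  data.frame(mol_id = mol_id, atom_index = atom_index, element = element,
             x = x, y = y, z = z, logp = logp, hbd = hbd, hba = hba,
             q_gast = q_gast, q_esp = q_esp, r_vdw = r_vdw,
             lj_eps = lj_eps, lj_rstar = lj_rstar,
             stringsAsFactors = FALSE)
}

# Assemble a QSARDataset directly from atom rows + activities.
toyDataset <- function(atoms, activities = NULL, label = "train") {
  ids <- unique(atoms$mol_id)
  act <- if (is.null(activities)) rep(NA_real_, length(ids)) else activities
  samples <- data.frame(mol_id = ids, activity = act,
                        label = ifelse(is.na(act), "candidate", label),
                        group = "", stringsAsFactors = FALSE)
  methods::new("QSARDataset", atoms = atoms, samples = samples,
               frameNote = "toy")
}

# Small, fast synthetic dataset for property checks.
smallSynthetic <- function(n = 16, noiseSD = 0, seed = 1, ...) {
  generateDataset(generatorConfig(
    nMolecules = n, atomsPerMolecule = c(8, 12), boxExtent = 5,
    nScaffold = 4, nSites = 10, noiseSD = noiseSD, seed = seed, ...))
}

# Independent PLS oracle: fitted values for `a` components equal the
# least-squares projection of centered y onto the order-a Krylov space
# span{S b0, S^2 b0, ...} with S = Xc'Xc, b0 = Xc'yc (PLS = conjugate
# gradients on the normal equations).
krylovPLSFitted <- function(X, y, a) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  v <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), a)
  for (k in seq_len(a)) {
    K[, k] <- v
    v <- crossprod(Xc, Xc %*% v)
  }
  Tb <- Xc %*% K
  mean(y) + Tb %*% qr.coef(qr(Tb), yc)
}
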