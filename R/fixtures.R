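#' @include AllClasses.R StructureModel-methods.R motif-scaffold.R active-site.R
NULL

## All generators are pure functions of (parameters, seed): they restore the
## caller's RNG state on exit.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Generate a toy scaffold with a planted catalytic triad
#'
#' Builds an ideal-geometry alpha-helical backbone (N, CA, C, O plus an
#' outward-pointing CB pseudo-atom per residue) and plants Ser/His/Asp
#' side-chain pseudo-atoms (OG, NE2/ND1, OD1/OD2) so that the triad
#' hydrogen-bond distances hit `triadTargets` exactly. Optionally converts
#' stretches of residues to an exposed hydrophobic type to plant surface
#' patches. Deterministic under `seed`.
#'
#' @param nResidues chain length (>= 20).
#' @param triadTargets numeric `(serHis, hisAsp)` target distances in
#'   Angstrom, each in (2.4, 6).
#' @param triadResidues indices of the Ser/His/Asp residues (default 10,
#'   12, 14).
#' @param plantedPatch `NULL`, or a list (or list of lists) with `start`,
#'   `size` and optional `resname` (default `"LEU"`).
#' @param bfactor per-residue confidence written to all atoms (default 90).
#' @param provenance provenance tag (default `"synthetic"`).
#' @param seed RNG seed.
#' @return a [StructureModel-class]; the triad assignment is attached as
#'   attribute `"triad"`.
#' @export
makeToyScaffold <- function(nResidues = 60L, triadTargets = c(3.0, 2.8),
                            triadResidues = c(10L, 12L, 14L),
                            plantedPatch = NULL, bfactor = 90,
                            provenance = "synthetic", seed = 1L) {
  if (nResidues < 20L) stop("nResidues must be >= 20", call. = FALSE)
  if (any(triadTargets <= 2.4) || any(triadTargets >= 6.0))
    stop("triad targets must lie in (2.4, 6.0) A", call. = FALSE)
  if (any(triadResidues > nResidues))
    stop("triad residues beyond chain length", call. = FALSE)
  .withSeed(seed, {
    omega <- 100 * pi / 180   # helical twist per residue
    rise <- 1.5               # A per residue
    rCA <- 2.3
    pos <- function(u, radius = rCA)
      c(radius * cos(omega * u), radius * sin(omega * u), rise * u)
    radial <- function(u) .unit(c(cos(omega * u), sin(omega * u), 0))
    atoms <- list()
    resnames <- rep(c("SER", "THR", "ASN", "GLN"), length.out = nResidues)
    resnames[triadResidues] <- c("SER", "HIS", "ASP")
    if (!is.null(plantedPatch)) {
      if (!is.null(plantedPatch$start)) plantedPatch <- list(plantedPatch)
      for (pp in plantedPatch) {
        rn <- if (is.null(pp$resname)) "LEU" else pp$resname
        idx <- seq(pp$start, length.out = pp$size)
        if (any(idx %in% triadResidues) || any(idx > nResidues))
          stop("planted patch overlaps triad or chain end", call. = FALSE)
        resnames[idx] <- rn
      }
    }
    add <- function(i, name, element, xyz) {
      atoms[[length(atoms) + 1L]] <<- data.frame(
        name = name, element = element, x = xyz[1], y = xyz[2], z = xyz[3],
        bfactor = bfactor, chain = "A", resnum = i, resname = resnames[i],
        stringsAsFactors = FALSE)
    }
    ## small seeded jitter makes scaffolds differ across seeds without
    ## disturbing the planted triad distances (placed afterwards, exactly)
    jitter <- matrix(stats::rnorm(3L * nResidues, sd = 0.02), ncol = 3)
    for (i in seq_len(nResidues)) {
      add(i, "N", "N", pos(i - 0.35, 1.8) + jitter[i, ])
      add(i, "CA", "C", pos(i) + jitter[i, ])
      add(i, "C", "C", pos(i + 0.35, 1.9) + jitter[i, ])
      add(i, "O", "O", pos(i + 0.45, 3.0) + jitter[i, ])
      if (resnames[i] != "GLY")
        add(i, "CB", "C", pos(i, rCA + 1.53) + jitter[i, ])
    }
    ## triad pseudo-atoms outside the helix surface, exact target distances
    iS <- triadResidues[1]; iH <- triadResidues[2]; iD <- triadResidues[3]
    caS <- pos(iS) + jitter[iS, ]
    u <- radial(iS)
    axis <- c(0, 0, 1)
    tang <- .unit(.cross3(u, axis))
    og <- caS + 1.4 * u
    v1 <- .unit(u + 0.3 * tang + 0.1 * stats::rnorm(3))
    ne2 <- og + triadTargets[1] * v1
    w <- .unit(u - 0.5 * tang + 0.2 * axis + 0.1 * stats::rnorm(3))
    nd1 <- ne2 + 2.2 * w
    od1 <- nd1 + triadTargets[2] * v1
    od2 <- nd1 + (triadTargets[2] + 0.4) * .unit(v1 + 0.5 * axis)
    add(iS, "OG", "O", og)
    add(iH, "NE2", "N", ne2)
    add(iH, "ND1", "N", nd1)
    add(iD, "OD1", "O", od1)
    add(iD, "OD2", "O", od2)
    model <- StructureModel(do.call(rbind, atoms), provenance = provenance)
    attr(model, "triad") <- TriadAssignment(serResnum = iS, hisResnum = iH,
                                            aspResnum = iD)
    model
  })
}

## 3-vector cross product
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Perturb a model to an exact post-superposition RMSD
#'
#' Adds a random per-atom displacement field scaled (by 1-D root finding)
#' so that the RMSD of the measured atom set against the original model,
#' after optimal superposition, equals `targetRmsd` to within 1e-3 A.
#'
#' @param model a [StructureModel-class].
#' @param targetRmsd Angstrom (>= 0; 0 returns the model unchanged).
#' @param seed RNG seed.
#' @param measure atom set the RMSD is targeted on: `"backbone"`
#'   (N, CA, C, O) or `"ca"`.
#' @return perturbed [StructureModel-class].
#' @export
perturbToRmsd <- function(model, targetRmsd, seed = 1L,
                          measure = c("backbone", "ca")) {
  measure <- match.arg(measure)
  if (targetRmsd < 0) stop("targetRmsd must be >= 0", call. = FALSE)
  if (targetRmsd == 0) return(model)
  atoms <- if (measure == "backbone") c("N", "CA", "C", "O") else "CA"
  .withSeed(seed, {
    a <- model@atoms
    D <- matrix(stats::rnorm(3L * nrow(a)), ncol = 3)
    sel <- !a$het & a$name %in% atoms
    ref <- as.matrix(a[sel, c("x", "y", "z")])
    rmsdAt <- function(s) {
      moved <- ref + s * D[sel, , drop = FALSE]
      kabschSuperpose(ref, moved)$rmsd
    }
    hi <- targetRmsd / sqrt(mean(rowSums(D[sel, , drop = FALSE]^2)))
    while (rmsdAt(hi) < targetRmsd) hi <- hi * 2
    s <- stats::uniroot(function(s) rmsdAt(s) - targetRmsd,
                        lower = 0, upper = hi, tol = 1e-9)$root
    m <- model
    xyz <- as.matrix(a[, c("x", "y", "z")]) + s * D
    m@atoms$x <- xyz[, 1]; m@atoms$y <- xyz[, 2]; m@atoms$z <- xyz[, 3]
    m
  })
}

#' Generate a drifting trajectory with a known RMSD schedule
#'
#' Frame `i` is the input model perturbed so its Calpha RMSD against frame 1
#' (after superposition) equals `rmsdSchedule[i]` within 1e-3 A.
#'
#' @param model reference [StructureModel-class] (frame 1).
#' @param rmsdSchedule Angstrom per frame; must start at 0.
#' @param seed RNG seed.
#' @return list of [StructureModel-class] frames.
#' @export
makeDriftTrajectory <- function(model, rmsdSchedule, seed = 1L) {
  if (length(rmsdSchedule) < 1L || rmsdSchedule[1] != 0)
    stop("rmsdSchedule must start at 0", call. = FALSE)
  lapply(seq_along(rmsdSchedule), function(i) {
    if (rmsdSchedule[i] == 0) model
    else perturbToRmsd(model, rmsdSchedule[i], seed = seed + i,
                       measure = "ca")
  })
}

#' Place a minimal ester ligand at a prescribed attack distance
#'
#' Builds a 6-atom ester fragment (carbonyl C, carbonyl O, bridging ester O
#' and three carbons -- the smallest unit exercising ester auto-annotation)
#' and positions it so the carbonyl carbon sits exactly `d` Angstrom from
#' the serine nucleophile oxygen, clash-free against the protein (no
#' heavy-atom pair under 2.4 A, the measured OG-C contact excepted for
#' d < 2.4). Placement directions are retried deterministically under
#' `seed`; fails after 1000 attempts.
#'
#' @param model a [StructureModel-class].
#' @param triad a [TriadAssignment-class].
#' @param d target attack distance, Angstrom (> 1.5).
#' @param seed RNG seed.
#' @param bindingEnergy optional energy annotation, kcal/mol.
#' @return a [LigandPose-class] with one auto-annotated ester group.
#' @export
makePoseAtDistance <- function(model, triad, d, seed = 1L,
                               bindingEnergy = NA_real_) {
  if (d <= 1.5) stop("d must be > 1.5 A", call. = FALSE)
  og <- .serOG(model, triad)
  prot <- model@atoms[!model@atoms$het, c("x", "y", "z")]
  prot <- as.matrix(prot)
  centroid <- colMeans(prot)
  .withSeed(seed, {
    for (attempt in seq_len(1000L)) {
      u <- .unit(.unit(og - centroid) + 0.3 * attempt / 1000 *
                   stats::rnorm(3))
      c1 <- og + d * u
      a <- .unit(.cross3(u, stats::rnorm(3)))
      b <- .unit(u + 0.8 * a)
      o1 <- c1 + 1.23 * a
      o2 <- c1 + 1.34 * b
      c2 <- o2 + 1.43 * .unit(u + 0.2 * a)
      c3 <- c2 + 1.52 * u
      c4 <- c1 + 1.50 * .unit(u - 0.8 * a)
      lig <- rbind(c1, o1, o2, c2, c3, c4)
      dmat <- sqrt(pmax(outer(rowSums(lig^2), rep(1, nrow(prot))) +
                          outer(rep(1, nrow(lig)), rowSums(prot^2)) -
                          2 * lig %*% t(prot), 0))
      ## exempt the engineered OG-carbonyl contact itself
      ogIdx <- which(apply(prot, 1, function(p) all(abs(p - og) < 1e-9)))
      if (length(ogIdx)) dmat[1, ogIdx] <- Inf
      if (min(dmat) >= 2.4) {
        atoms <- data.frame(
          label = c("C1", "O1", "O2", "C2", "C3", "C4"),
          element = c("C", "O", "O", "C", "C", "C"),
          x = lig[, 1], y = lig[, 2], z = lig[, 3],
          stringsAsFactors = FALSE)
        return(LigandPose(atoms, bindingEnergy = bindingEnergy))
      }
    }
    stop("ligand placement infeasible after 1000 attempts", call. = FALSE)
  })
}

#' Generate synthetic Michaelis-Menten rate data
#'
#' Rates follow `vmax * S / (km + S)` with multiplicative Gaussian noise;
#' the generating parameters are recorded in the dataset's `truth` slot.
#' Negative noisy rates are clipped at zero.
#'
#' @param vmax maximum rate, uM/min.
#' @param km half-saturation load, g/L.
#' @param substrateGrid substrate loads, g/L.
#' @param noiseSdFrac multiplicative noise SD (0 = exact curve).
#' @param seed RNG seed.
#' @return a [KineticsDataset-class].
#' @export
makeMmDataset <- function(vmax, km, substrateGrid = seq(0.1, 5, length.out = 8),
                          noiseSdFrac = 0, seed = 1L) {
  if (vmax <= 0 || km <= 0) stop("vmax and km must be positive", call. = FALSE)
  .withSeed(seed, {
    v <- vmax * substrateGrid / (km + substrateGrid)
    if (noiseSdFrac > 0)
      v <- pmax(0, v * (1 + stats::rnorm(length(v), 0, noiseSdFrac)))
    KineticsDataset(substrateGrid, v, truth = c(vmax = vmax, km = km))
  })
}

#' Generate a planted-failure candidate batch
#'
#' Builds a deterministic candidate set in which a prescribed number of
#' candidates fail each screening stage (low pLDDT, excessive motif RMSD,
#' out-of-window docking energy, unstable trajectory, pathological
#' sequence); the remainder pass everything. Used to verify screen
#' bookkeeping exactly.
#'
#' @param n total candidates.
#' @param nLowPlddt,nHighRmsd,nBadEnergy,nUnstable,nPathological planted
#'   failure counts (must sum to <= n).
#' @param seed RNG seed.
#' @return list of [CandidateRecord-class].
#' @export
makeCandidateBatch <- function(n = 20L, nLowPlddt = 5L, nHighRmsd = 4L,
                               nBadEnergy = 3L, nUnstable = 2L,
                               nPathological = 0L, seed = 1L) {
  stopifnot(nLowPlddt + nHighRmsd + nBadEnergy + nUnstable + nPathological <= n)
  .withSeed(seed, {
    kinds <- c(rep("low_plddt", nLowPlddt), rep("high_rmsd", nHighRmsd),
               rep("bad_energy", nBadEnergy), rep("unstable", nUnstable),
               rep("pathological", nPathological))
    kinds <- c(kinds, rep("pass", n - length(kinds)))
    kinds <- sample(kinds)
    cleanSeq <- function()
      paste(sample(c("G", "S", "T", "N", "Q", "D", "E", "K", "R", "P"),
                   60, replace = TRUE), collapse = "")
    lapply(seq_len(n), function(i) {
      scores <- c(mean_plddt = stats::runif(1, 75, 95),
                  ptm = stats::runif(1, 0.75, 0.95),
                  motif_rmsd = stats::runif(1, 0.5, 2.2),
                  binding_energy = stats::runif(1, -3.5, -0.5),
                  attack_distance = stats::runif(1, 2.8, 3.8),
                  n_donors = 2,
                  traj_max_rmsd = stats::runif(1, 1, 4.5))
      sq <- cleanSeq()
      switch(kinds[i],
             low_plddt = scores[["mean_plddt"]] <- stats::runif(1, 40, 65),
             high_rmsd = scores[["motif_rmsd"]] <- stats::runif(1, 2.6, 6),
             bad_energy = scores[["binding_energy"]] <-
               sample(c(stats::runif(1, -8, -4.5), stats::runif(1, 0.5, 2)), 1),
             unstable = scores[["traj_max_rmsd"]] <- stats::runif(1, 5.5, 9),
             pathological = sq <- paste0(substr(sq, 1, 30), "LLLLLLL",
                                         substr(sq, 31, 60)),
             pass = NULL)
      cand <- CandidateRecord(sprintf("cand%02d", i), scores = scores,
                              sequence = sq)
      attr(cand, "planted") <- kinds[i]
      cand
    })
  })
}
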