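#' @include AllClasses.R StructureModel-methods.R motif-scaffold.R
NULL

#' Trajectory Calpha-RMSD time course
#'
#' Per-frame RMSD of Calpha atoms against a reference frame, optionally
#' after optimal (Kabsch) superposition of each frame onto the reference.
#' Frame times are taken from `times` when supplied, otherwise frames are
#' assumed uniformly spaced over `duration` ns (default spacing 1 ns).
#'
#' @param frames list of [StructureModel-class] sharing residue count and
#'   order (e.g. a multi-model PDB trajectory from [readStructure()]).
#' @param referenceIndex reference frame (default 1).
#' @param superpose superpose each frame before measuring (default TRUE).
#' @param times optional time stamps, ns.
#' @param duration optional total duration, ns (frames spread uniformly from 0).
#' @return a [TrajectorySeries-class].
#' @export
caRmsdTimecourse <- function(frames, referenceIndex = 1L, superpose = TRUE,
                             times = NULL, duration = NULL) {
  n <- length(frames)
  if (n == 0L) stop("no frames", call. = FALSE)
  ca <- lapply(frames, .namedAtomCoords, atomName = "CA")
  sizes <- vapply(ca, nrow, 0L)
  if (length(unique(sizes)) != 1L)
    stop("inconsistent frame topology: Calpha counts differ", call. = FALSE)
  ref <- ca[[referenceIndex]]
  rmsd <- vapply(ca, function(x) {
    if (superpose) kabschSuperpose(ref, x)$rmsd
    else sqrt(mean(rowSums((x - ref)^2)))
  }, 0)
  rmsd[referenceIndex] <- 0
  if (is.null(times)) {
    times <- if (is.null(duration)) seq(0, n - 1L)
             else seq(0, duration, length.out = n)
  }
  new("TrajectorySeries", times = as.numeric(times), rmsd = as.numeric(rmsd),
      referenceIndex = as.integer(referenceIndex))
}

setMethod("show", "TrajectorySeries", function(object) {
  cat(sprintf("TrajectorySeries: %d frames over %.1f ns, max RMSD %.2f A\n",
              length(object@times), max(object@times), max(object@rmsd)))
  invisible(object)
})

#' Trajectory stability gate
#'
#' A design fails if its Calpha RMSD strictly exceeds `maxRmsd` at any time
#' at or before `horizon` (defaults 5 A within 20 ns). Excursions after the
#' horizon are ignored.
#'
#' @param series a [TrajectorySeries-class].
#' @param maxRmsd Angstrom.
#' @param horizon ns.
#' @return list with `pass`, `max_rmsd_in_horizon`, and `first_exceed_time`
#'   (NA when passing).
#' @export
stabilityFilter <- function(series, maxRmsd = 5, horizon = 20) {
  inh <- series@times <= horizon
  if (!any(inh))
    return(list(pass = TRUE, max_rmsd_in_horizon = NA_real_,
                first_exceed_time = NA_real_))
  r <- series@rmsd[inh]
  t <- series@times[inh]
  bad <- which(r > maxRmsd)
  list(pass = length(bad) == 0L,
       max_rmsd_in_horizon = max(r),
       first_exceed_time = if (length(bad)) t[bad[1]] else NA_real_)
}

## ---------------------------------------------------------------------------
## SASA
## ---------------------------------------------------------------------------

## Deterministic quasi-uniform sphere points (golden-spiral lattice).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-sampling SASA: each atom's solvent-accessible sphere
#' (van der Waals radius + probe) is sampled with a deterministic
#' golden-spiral lattice and points occluded by any neighbouring atom's
#' accessible sphere are removed. Per-residue areas are atom sums; relative
#' exposure divides by a fixed per-residue-type theoretical maximum (Tien et
#' al.-style table), so values can slightly exceed 1 for unusually extended
#' residues.
#'
#' @param model a [StructureModel-class] (HETATM atoms are ignored).
#' @param probeRadius probe radius, Angstrom (default 1.4, water).
#' @param nPoints sample points per atom (default 960).
#' @return a [SASAResult-class].
#' @export
shrakeRupleySasa <- function(model, probeRadius = 1.4, nPoints = 960L) {
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(.VDW_RADII))
  if (length(unknown))
    stop(sprintf("no van der Waals radius for element(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  radii <- .VDW_RADII[el] + probeRadius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .spherePoints(nPoints)
  ## neighbour lists from pairwise distances
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= radii[j]^2
    }
    area[i] <- 4 * pi * radii[i]^2 * sum(acc) / nPoints
  }
  key <- .resKey(a$chain, a$resnum, a$icode)
  rt <- residueTable(model)
  rkey <- .resKey(rt$chain, rt$resnum, rt$icode)
  resArea <- vapply(rkey, function(k) sum(area[key == k]), 0)
  rel <- resArea / .MAX_SASA[rt$resname]
  per <- data.frame(chain = rt$chain, resnum = rt$resnum, icode = rt$icode,
                    resname = rt$resname, area = as.numeric(resArea),
                    rel_exposure = as.numeric(rel), stringsAsFactors = FALSE)
  new("SASAResult", perResidue = per, atomArea = area,
      total = sum(area), probeRadius = probeRadius,
      nPoints = as.integer(nPoints))
}

setMethod("show", "SASAResult", function(object) {
  cat(sprintf("SASAResult: total %.1f A^2 over %d residues (probe %.1f A, %d points)\n",
              object@total, nrow(object@perResidue), object@probeRadius,
              object@nPoints))
  invisible(object)
})

#' Surface hydrophobic patch detection
#'
#' Exposed hydrophobic residues (resname in `hydrophobicSet`, relative
#' exposure >= `exposureMin`) are clustered by single linkage on
#' Cbeta-Cbeta distance (Calpha for glycine) at cutoff `linkDist`. Patches
#' are returned sorted by total area descending; membership is a partition.
#' Large exposed patches mark likely misfolding/aggregation hot spots and
#' feed the redesign mask.
#'
#' @param model a [StructureModel-class].
#' @param sasa matching [SASAResult-class].
#' @param hydrophobicSet three-letter residue names treated as hydrophobic.
#' @param exposureMin relative-exposure threshold (default 0.25).
#' @param linkDist linkage cutoff, Angstrom (default 8).
#' @return list of patches, each a list with `members` (data.frame),
#'   `total_area` and `centroid`.
#' @export
hydrophobicPatches <- function(model, sasa,
                               hydrophobicSet = .HYDROPHOBIC_THREE,
                               exposureMin = 0.25, linkDist = 8) {
  per <- sasa@perResidue
  sel <- which(per$resname %in% hydrophobicSet &
                 !is.na(per$rel_exposure) & per$rel_exposure >= exposureMin)
  if (length(sel) == 0L) return(list())
  coords <- t(vapply(sel, function(i) {
    atom <- if (per$resname[i] == "GLY") "CA" else "CB"
    co <- try(atomCoords(model, per$chain[i], per$resnum[i], per$icode[i],
                         atom), silent = TRUE)
    if (inherits(co, "try-error"))
      co <- atomCoords(model, per$chain[i], per$resnum[i], per$icode[i], "CA")
    co[1, ]
  }, numeric(3)))
  cl <- if (length(sel) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(coords), method = "single")
    stats::cutree(hc, h = linkDist)
  }
  patches <- lapply(unique(cl), function(g) {
    ix <- sel[cl == g]
    members <- per[ix, , drop = FALSE]
    rownames(members) <- NULL
    list(members = members,
         total_area = sum(members$area),
         centroid = colMeans(coords[cl == g, , drop = FALSE]))
  })
  patches[order(vapply(patches, function(p) p$total_area, 0),
                decreasing = TRUE)]
}

#' Write a SASA/patch report
#'
#' TSV with one row per residue: area, relative exposure and patch id (NA
#' for residues outside every patch).
#'
#' @param sasa a [SASAResult-class].
#' @param patches output of [hydrophobicPatches()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSasaReport <- function(sasa, patches, path) {
  per <- sasa@perResidue
  per$patch_id <- NA_integer_
  for (pi in seq_along(patches)) {
    m <- patches[[pi]]$members
    idx <- match(.resKey(m$chain, m$resnum, m$icode),
                 .resKey(per$chain, per$resnum, per$icode))
    per$patch_id[idx] <- pi
  }
  utils::write.table(per, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
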