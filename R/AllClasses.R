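#' @import methods
#' @include constants.R
NULL

## ---------------------------------------------------------------------------
## StructureModel
## ---------------------------------------------------------------------------

#' Parsed atomic model
#'
#' An atomic protein model: a flat atom table grouped implicitly into residues
#' by `(chain, resnum, icode)`, plus a model index (for multi-model files) and
#' a provenance tag. For predicted models the B-factor column carries the
#' per-residue pLDDT confidence score in \[0, 100\].
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`, `x`, `y`,
#'   `z`, `occupancy`, `bfactor`, `chain`, `resnum`, `icode`, `resname`,
#'   `het` (logical, HETATM origin).
#' @slot modelIndex integer model number (>= 1).
#' @slot provenance one of `"predicted"`, `"experimental"`, `"synthetic"`.
#'
#' @seealso [readStructure()], [makeToyScaffold()]
#' @export
setClass("StructureModel",
  representation(
    atoms = "data.frame",
    modelIndex = "integer",
    provenance = "character"
  ),
  prototype(modelIndex = 1L, provenance = "experimental")
)

.ATOM_COLS <- c("serial", "name", "element", "x", "y", "z",
                "occupancy", "bfactor", "chain", "resnum", "icode",
                "resname", "het")

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character()
  if (!all(.ATOM_COLS %in% names(a)))
    msgs <- c(msgs, paste("atom table must have columns:",
                          paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  else {
    if (nrow(a) == 0L) msgs <- c(msgs, "structure has zero atoms")
    if (nrow(a) > 0L && !all(is.finite(c(a$x, a$y, a$z))))
      msgs <- c(msgs, "atom coordinates must be finite")
    if (nrow(a) > 0L && any(!nzchar(a$name)))
      msgs <- c(msgs, "atom names must be non-empty")
  }
  if (length(object@provenance) != 1L ||
      !object@provenance %in% c("predicted", "experimental", "synthetic"))
    msgs <- c(msgs, "provenance must be one of predicted/experimental/synthetic")
  if (length(msgs) == 0L && !is.logical(a$het))
    msgs <- c(msgs, "het column must be logical")
  if (length(msgs) == 0L && identical(object@provenance, "predicted")) {
    rt <- unique(a[!a$het, c("chain", "resnum", "icode")])
    ca <- a[!a$het & a$name == "CA", , drop = FALSE]
    key <- function(d) paste(d$chain, d$resnum, d$icode)
    if (!all(key(rt) %in% key(ca)))
      msgs <- c(msgs, "predicted models require a CA atom in every residue")
    else if (any(ca$bfactor < 0 | ca$bfactor > 100))
      msgs <- c(msgs, "predicted-model CA B-factors (pLDDT) must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ProteinSequence
## ---------------------------------------------------------------------------

#' Protein sequence with structural numbering
#'
#' One-letter amino-acid string plus an invertible mapping from string
#' position (1-based) to the author `(chain, resnum, icode)` of the source
#' structure. Non-standard residues are encoded as `"X"`.
#'
#' @slot letters single character string.
#' @slot numbering data.frame with columns `chain`, `resnum`, `icode`, one
#'   row per letter.
#' @export
setClass("ProteinSequence",
  representation(letters = "character", numbering = "data.frame")
)

setValidity("ProteinSequence", function(object) {
  msgs <- character()
  if (length(object@letters) != 1L)
    return("letters must be a single string")
  n <- nchar(object@letters)
  if (!all(c("chain", "resnum", "icode") %in% names(object@numbering)))
    msgs <- c(msgs, "numbering needs chain/resnum/icode columns")
  else if (nrow(object@numbering) != n)
    msgs <- c(msgs, "numbering must have one row per letter")
  bad <- setdiff(strsplit(object@letters, "")[[1]], c(.STANDARD_AA1, "X"))
  if (length(bad))
    msgs <- c(msgs, paste("invalid letters:", paste(unique(bad), collapse = "")))
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## MotifSpec
## ---------------------------------------------------------------------------

#' Retained catalytic-motif specification
#'
#' The template segments retained around a Ser-His-Asp catalytic triad, the
#' triad role assignments, and the backbone atom set used for motif-fidelity
#' RMSD.
#'
#' @slot segments data.frame with columns `chain`, `start`, `end` (author
#'   numbering, inclusive), sorted and non-overlapping.
#' @slot catalytic data.frame with columns `role` (`nucleophile`, `base`,
#'   `acid`), `chain`, `resnum`; each role exactly once, each residue inside
#'   a segment.
#' @slot backboneAtoms ordered atom names used for fidelity (default
#'   N, CA, C, O).
#' @export
setClass("MotifSpec",
  representation(
    segments = "data.frame",
    catalytic = "data.frame",
    backboneAtoms = "character"
  ),
  prototype(backboneAtoms = c("N", "CA", "C", "O"))
)

setValidity("MotifSpec", function(object) {
  s <- object@segments
  k <- object@catalytic
  msgs <- character()
  if (!all(c("chain", "start", "end") %in% names(s)))
    return("segments needs chain/start/end columns")
  if (nrow(s) == 0L) msgs <- c(msgs, "at least one segment required")
  if (any(s$end < s$start)) msgs <- c(msgs, "segment end < start")
  if (nrow(s) > 1L) {
    for (ch in unique(s$chain)) {
      ss <- s[s$chain == ch, , drop = FALSE]
      if (is.unsorted(ss$start, strictly = TRUE))
        msgs <- c(msgs, "segments must be sorted by start within chain")
      if (any(ss$start[-1] <= ss$end[-nrow(ss)]))
        msgs <- c(msgs, "segments must not overlap")
    }
  }
  if (!all(c("role", "chain", "resnum") %in% names(k)))
    return(c(msgs, "catalytic needs role/chain/resnum columns"))
  if (!identical(sort(k$role), sort(c("nucleophile", "base", "acid"))))
    msgs <- c(msgs, "roles nucleophile/base/acid must each appear exactly once")
  for (i in seq_len(nrow(k))) {
    inside <- any(s$chain == k$chain[i] & s$start <= k$resnum[i] &
                    s$end >= k$resnum[i])
    if (!inside)
      msgs <- c(msgs, sprintf("catalytic residue %s%d outside all segments",
                              k$chain[i], k$resnum[i]))
  }
  if (length(object@backboneAtoms) < 1L)
    msgs <- c(msgs, "backboneAtoms must be non-empty")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## TriadAssignment
## ---------------------------------------------------------------------------

#' Catalytic triad atom assignment
#'
#' Names the Ser/His/Asp residues of a serine-hydrolase triad and the atoms
#' used for geometry checks. The canonical arrangement is assumed: His NE2
#' faces the Ser nucleophile, His ND1 hydrogen-bonds the Asp carboxylate.
#'
#' @slot ser,his,asp lists with elements `chain`, `resnum` (and for ser an
#'   `atom`, default `"OG"`).
#' @export
setClass("TriadAssignment",
  representation(ser = "list", his = "list", asp = "list")
)

setValidity("TriadAssignment", function(object) {
  need <- function(x) is.list(x) && all(c("chain", "resnum") %in% names(x))
  if (!need(object@ser) || !need(object@his) || !need(object@asp))
    return("ser/his/asp must be lists with chain and resnum")
  ids <- vapply(list(object@ser, object@his, object@asp),
                function(x) paste(x$chain, x$resnum), "")
  if (anyDuplicated(ids)) return("triad residues must be distinct")
  TRUE
})

## ---------------------------------------------------------------------------
## LigandPose
## ---------------------------------------------------------------------------

#' Docked substrate-analog pose
#'
#' Ligand atoms with annotated ester groups (the hydrolyzable C(=O)-O units)
#' and an optional docking binding energy.
#'
#' @slot atoms data.frame with columns `label`, `element`, `x`, `y`, `z`.
#' @slot esterGroups data.frame with integer columns `carbonylC`,
#'   `carbonylO`, `esterO` (row indices into `atoms`).
#' @slot bindingEnergy kcal/mol, `NA` if absent.
#' @export
setClass("LigandPose",
  representation(
    atoms = "data.frame",
    esterGroups = "data.frame",
    bindingEnergy = "numeric"
  ),
  prototype(bindingEnergy = NA_real_)
)

setValidity("LigandPose", function(object) {
  a <- object@atoms
  g <- object@esterGroups
  msgs <- character()
  if (!all(c("label", "element", "x", "y", "z") %in% names(a)))
    return("atoms needs label/element/x/y/z columns")
  if (nrow(g)) {
    if (!all(c("carbonylC", "carbonylO", "esterO") %in% names(g)))
      return("esterGroups needs carbonylC/carbonylO/esterO columns")
    idx <- unlist(g[, c("carbonylC", "carbonylO", "esterO")])
    if (any(idx < 1L | idx > nrow(a)))
      msgs <- c(msgs, "ester-group index out of range")
    else {
      for (i in seq_len(nrow(g))) {
        d <- sqrt(sum((as.numeric(a[g$carbonylC[i], c("x", "y", "z")]) -
                         as.numeric(a[g$carbonylO[i], c("x", "y", "z")]))^2))
        if (d >= 1.6)
          msgs <- c(msgs, sprintf("ester group %d: carbonyl C-O distance %.2f >= 1.6 A", i, d))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## TrajectorySeries
## ---------------------------------------------------------------------------

#' Time course of trajectory Calpha RMSD
#'
#' @slot times ns, strictly increasing.
#' @slot rmsd Angstrom, same length; zero at the reference frame.
#' @slot referenceIndex frame used as reference.
#' @export
setClass("TrajectorySeries",
  representation(times = "numeric", rmsd = "numeric", referenceIndex = "integer")
)

setValidity("TrajectorySeries", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@rmsd))
    return("times and rmsd must have equal length")
  if (length(object@times) == 0L) msgs <- c(msgs, "series must be non-empty")
  if (is.unsorted(object@times, strictly = TRUE))
    msgs <- c(msgs, "times must be strictly increasing")
  ri <- object@referenceIndex
  if (ri < 1L || ri > length(object@rmsd))
    msgs <- c(msgs, "referenceIndex out of range")
  else if (abs(object@rmsd[ri]) > 1e-8)
    msgs <- c(msgs, "rmsd at the reference frame must be 0")
  if (any(object@rmsd < 0)) msgs <- c(msgs, "rmsd must be non-negative")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## SASAResult
## ---------------------------------------------------------------------------

#' Solvent-accessible surface area result
#'
#' @slot perResidue data.frame with `chain`, `resnum`, `icode`, `resname`,
#'   `area` (Angstrom^2) and `rel_exposure` (observed / theoretical max; NA
#'   for residue types without a reference value).
#' @slot atomArea per-atom areas in atom-table order.
#' @slot total total SASA, Angstrom^2.
#' @slot probeRadius,nPoints parameters used.
#' @export
setClass("SASAResult",
  representation(
    perResidue = "data.frame",
    atomArea = "numeric",
    total = "numeric",
    probeRadius = "numeric",
    nPoints = "integer"
  )
)

setValidity("SASAResult", function(object) {
  msgs <- character()
  if (any(object@perResidue$area < 0)) msgs <- c(msgs, "areas must be non-negative")
  if (abs(sum(object@perResidue$area) - object@total) > 1e-6 * max(1, object@total))
    msgs <- c(msgs, "total must equal the per-residue sum")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## RedesignMask
## ---------------------------------------------------------------------------

#' Redesign mask for iterative re-inpainting
#'
#' @slot keep logical, one per sequence position; `FALSE` marks positions to
#'   redesign.
#' @slot contig contig string alternating kept stretches and fixed-length
#'   redesign gaps.
#' @slot protected positions inside motif segments, never redesigned.
#' @slot conflicts positions where a requested redesign was overridden by
#'   protection.
#' @export
setClass("RedesignMask",
  representation(
    keep = "logical",
    contig = "character",
    protected = "integer",
    conflicts = "integer"
  )
)

setValidity("RedesignMask", function(object) {
  if (length(object@protected) &&
      any(!object@keep[object@protected]))
    return("protected positions must have keep = TRUE")
  TRUE
})

## ---------------------------------------------------------------------------
## Kinetics
## ---------------------------------------------------------------------------

#' Michaelis-Menten kinetics dataset
#'
#' Substrate loads in g/L (PET is polymeric, so molarity is undefined) and
#' initial rates in uM/min.
#'
#' @slot substrate g/L, non-negative ascending.
#' @slot rate uM/min, non-negative, same length.
#' @slot truth optional named numeric (`vmax`, `km`) recording generator
#'   ground truth for synthetic data.
#' @export
setClass("KineticsDataset",
  representation(substrate = "numeric", rate = "numeric", truth = "numeric"),
  prototype(truth = numeric())
)

setValidity("KineticsDataset", function(object) {
  msgs <- character()
  if (length(object@substrate) != length(object@rate))
    return("substrate and rate must have equal length")
  if (length(object@substrate) < 4L)
    msgs <- c(msgs, "at least 4 points required")
  if (any(object@substrate < 0) || any(object@rate < 0))
    msgs <- c(msgs, "substrate and rate must be non-negative")
  if (is.unsorted(object@substrate))
    msgs <- c(msgs, "substrate must be ascending")
  if (length(msgs)) msgs else TRUE
})

#' Michaelis-Menten fit
#'
#' @slot vmax maximum rate, uM/min.
#' @slot km half-saturation load, g/L.
#' @slot seVmax,seKm standard errors from the Jacobian at the optimum.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot message fitter diagnostics.
#' @export
setClass("MMFit",
  representation(
    vmax = "numeric", km = "numeric",
    seVmax = "numeric", seKm = "numeric",
    rss = "numeric", converged = "logical", message = "character"
  ),
  prototype(message = "")
)

setValidity("MMFit", function(object) {
  if (isTRUE(object@converged) && (object@vmax <= 0 || object@km <= 0))
    return("converged fits must have vmax > 0 and km > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Screening
## ---------------------------------------------------------------------------

#' Screening thresholds
#'
#' All thresholds of the multi-criteria design screen: prediction-confidence
#' gates, motif-fidelity cut, docking-energy window, active-site geometry,
#' trajectory stability, and sequence/surface pathology parameters.
#'
#' @slot plddtMin mean pLDDT must exceed this (strict; default 70).
#' @slot ptmMin pTM must exceed this (strict; default 0.7).
#' @slot motifRmsdMax motif RMSD must not exceed this (inclusive; default 2.5 A).
#' @slot energyWindow inclusive docking-energy window, kcal/mol (default -4..0).
#' @slot attackDistMax nucleophilic attack distance must be below this
#'   (strict; default 4 A).
#' @slot minOxyanionDonors minimum backbone-N oxyanion donors (default 2).
#' @slot oxyanionMaxDist donor N to carbonyl O cutoff (default 3.5 A).
#' @slot trajRmsdMax,trajHorizon stability gate: fail if Calpha RMSD exceeds
#'   `trajRmsdMax` (strict) at any time <= `trajHorizon` ns (defaults 5 A, 20 ns).
#' @slot minRun minimum run length flagged as SAAR/CHAA (default 5).
#' @slot hydrophobicSet one-letter hydrophobic alphabet.
#' @slot exposureMin relative-exposure threshold for surface residues (default 0.25).
#' @slot linkDist single-linkage cutoff for hydrophobic patches (default 8 A).
#' @slot flank redesign-mask flank, residues (default 2).
#' @slot exhaustive score all stages even after a failure (default FALSE).
#' @slot templateLength,templateMw template size for reduction metrics (NA ok).
#' @export
setClass("ScreenConfig",
  representation(
    plddtMin = "numeric", ptmMin = "numeric", motifRmsdMax = "numeric",
    energyWindow = "numeric", attackDistMax = "numeric",
    minOxyanionDonors = "numeric", oxyanionMaxDist = "numeric",
    trajRmsdMax = "numeric", trajHorizon = "numeric",
    minRun = "numeric", hydrophobicSet = "character",
    exposureMin = "numeric", linkDist = "numeric", flank = "numeric",
    exhaustive = "logical", templateLength = "numeric", templateMw = "numeric"
  ),
  prototype(
    plddtMin = 70, ptmMin = 0.7, motifRmsdMax = 2.5,
    energyWindow = c(-4, 0), attackDistMax = 4,
    minOxyanionDonors = 2, oxyanionMaxDist = 3.5,
    trajRmsdMax = 5, trajHorizon = 20,
    minRun = 5, hydrophobicSet = .HYDROPHOBIC_ONE,
    exposureMin = 0.25, linkDist = 8, flank = 2,
    exhaustive = FALSE, templateLength = NA_real_, templateMw = NA_real_
  )
)

setValidity("ScreenConfig", function(object) {
  msgs <- character()
  pos <- c(plddtMin = object@plddtMin, ptmMin = object@ptmMin,
           motifRmsdMax = object@motifRmsdMax,
           attackDistMax = object@attackDistMax,
           minOxyanionDonors = object@minOxyanionDonors,
           oxyanionMaxDist = object@oxyanionMaxDist,
           trajRmsdMax = object@trajRmsdMax, trajHorizon = object@trajHorizon,
           minRun = object@minRun, exposureMin = object@exposureMin,
           linkDist = object@linkDist)
  if (any(pos <= 0))
    msgs <- c(msgs, paste("thresholds must be positive:",
                          paste(names(pos)[pos <= 0], collapse = ", ")))
  if (length(object@energyWindow) != 2L ||
      object@energyWindow[1] >= object@energyWindow[2])
    msgs <- c(msgs, "energyWindow must be (low, high) with low < high")
  if (object@flank < 0) msgs <- c(msgs, "flank must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' One design candidate and its screening state
#'
#' @slot id candidate identifier.
#' @slot sequence one-letter sequence (NA if unknown).
#' @slot structurePath path to the candidate structure (NA if not on disk).
#' @slot scores named numeric: any of `mean_plddt`, `ptm`, `motif_rmsd`,
#'   `binding_energy`, `attack_distance`, `n_donors`, `traj_max_rmsd`.
#' @slot decisions named list of per-criterion pass/fail with reasons.
#' @slot stage one of generated, static_pass, docked_pass, stable_pass,
#'   pathology_flagged, accepted, errored.
#' @export
setClass("CandidateRecord",
  representation(
    id = "character", sequence = "character", structurePath = "character",
    scores = "numeric", decisions = "list", stage = "character"
  ),
  prototype(sequence = NA_character_, structurePath = NA_character_,
            scores = numeric(), decisions = list(), stage = "generated")
)

.STAGES <- c("generated", "static_pass", "docked_pass", "stable_pass",
             "pathology_flagged", "accepted", "errored")

setValidity("CandidateRecord", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "id must be a non-empty string")
  if (!object@stage %in% .STAGES)
    msgs <- c(msgs, paste("stage must be one of", paste(.STAGES, collapse = "/")))
  if (length(msgs)) msgs else TRUE
})

#' Screening report
#'
#' @slot table one row per candidate: scores, per-criterion pass flags,
#'   terminal stage and failure reasons.
#' @slot summary named integer stage counts.
#' @slot config the `ScreenConfig` used.
#' @export
setClass("ScreenReport",
  representation(table = "data.frame", summary = "integer", config = "ScreenConfig")
)
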