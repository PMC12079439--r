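#' @include AllClasses.R StructureModel-methods.R
NULL

#' Construct a TriadAssignment
#'
#' @param serChain,serResnum the nucleophilic serine.
#' @param hisChain,hisResnum the general-base histidine.
#' @param aspChain,aspResnum the acid aspartate.
#' @param serAtom nucleophile atom name (default `"OG"`).
#' @return a [TriadAssignment-class].
#' @export
TriadAssignment <- function(serChain = "A", serResnum,
                            hisChain = "A", hisResnum,
                            aspChain = "A", aspResnum,
                            serAtom = "OG") {
  new("TriadAssignment",
      ser = list(chain = serChain, resnum = serResnum, atom = serAtom),
      his = list(chain = hisChain, resnum = hisResnum),
      asp = list(chain = aspChain, resnum = aspResnum))
}

setMethod("show", "TriadAssignment", function(object) {
  cat(sprintf("TriadAssignment: Ser %s%d (%s) / His %s%d / Asp %s%d\n",
              object@ser$chain, object@ser$resnum, object@ser$atom,
              object@his$chain, object@his$resnum,
              object@asp$chain, object@asp$resnum))
  invisible(object)
})

#' Construct a LigandPose
#'
#' @param atoms data.frame with `label`, `element`, `x`, `y`, `z`.
#' @param esterGroups data.frame of atom indices (`carbonylC`, `carbonylO`,
#'   `esterO`); if `NULL`, groups are auto-annotated from heavy-atom
#'   connectivity (C bonded to a terminal O and a bridging O).
#' @param bindingEnergy docking energy, kcal/mol (NA if unknown).
#' @return a [LigandPose-class].
#' @export
LigandPose <- function(atoms, esterGroups = NULL, bindingEnergy = NA_real_) {
  if (is.null(esterGroups)) esterGroups <- annotateEsterGroups(atoms)
  new("LigandPose", atoms = as.data.frame(atoms),
      esterGroups = as.data.frame(esterGroups),
      bindingEnergy = as.numeric(bindingEnergy))
}

setMethod("show", "LigandPose", function(object) {
  cat(sprintf("LigandPose: %d atoms, %d ester group(s), binding energy %s kcal/mol\n",
              nrow(object@atoms), nrow(object@esterGroups),
              ifelse(is.na(object@bindingEnergy), "NA",
                     format(object@bindingEnergy))))
  invisible(object)
})

#' Auto-annotate ester groups from connectivity
#'
#' Detects the C(=O)-O pattern by distance-based heavy-atom connectivity
#' (bond cutoff 1.6 A): a carbon bonded to two oxygens, one of which bridges
#' to a further carbon (the ester oxygen) while the other is terminal (the
#' carbonyl oxygen).
#'
#' @param atoms ligand atom data.frame (`label`, `element`, `x`, `y`, `z`).
#' @param bondCutoff bond distance cutoff, Angstrom.
#' @return data.frame with `carbonylC`, `carbonylO`, `esterO` indices (zero
#'   rows, with a warning, if no ester pattern exists).
#' @export
annotateEsterGroups <- function(atoms, bondCutoff = 1.6) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  bonded <- d > 0 & d < bondCutoff
  el <- toupper(atoms$element)
  groups <- list()
  for (ci in which(el == "C")) {
    ox <- which(bonded[ci, ] & el == "O")
    if (length(ox) < 2L) next
    ## bridging oxygen: bonded to a second carbon besides ci
    bridges <- vapply(ox, function(oi)
      any(bonded[oi, ] & el == "C" & seq_len(n) != ci), logical(1))
    if (!any(bridges) || all(bridges)) next
    esterO <- ox[bridges][1]
    carbonylO <- ox[!bridges][which.min(d[ci, ox[!bridges]])]
    groups[[length(groups) + 1L]] <- data.frame(
      carbonylC = ci, carbonylO = carbonylO, esterO = esterO)
  }
  if (length(groups) == 0L) {
    warning("no ester C(=O)-O pattern found; ester annotation is empty")
    return(data.frame(carbonylC = integer(), carbonylO = integer(),
                      esterO = integer()))
  }
  do.call(rbind, groups)
}

.serOG <- function(model, triad) {
  atomCoords(model, triad@ser$chain, triad@ser$resnum,
             atoms = triad@ser$atom)[1, ]
}

#' Nucleophilic attack distance
#'
#' Minimum distance from the serine nucleophile oxygen (Ser O-gamma) to any
#' annotated ester carbonyl carbon of the pose. The mechanism criterion
#' passes when the distance is strictly below the configured maximum
#' (default 4 A).
#'
#' @param model a [StructureModel-class].
#' @param triad a [TriadAssignment-class].
#' @param pose a [LigandPose-class] with at least one ester group.
#' @return distance in Angstrom.
#' @export
attackDistance <- function(model, triad, pose) {
  if (nrow(pose@esterGroups) == 0L)
    stop("pose has no annotated ester groups", call. = FALSE)
  og <- .serOG(model, triad)
  cc <- as.matrix(pose@atoms[pose@esterGroups$carbonylC, c("x", "y", "z"),
                             drop = FALSE])
  min(sqrt(rowSums(sweep(cc, 2, og)^2)))
}

#' Oxyanion-hole donor search
#'
#' Finds backbone amide nitrogens positioned to stabilize the oxyanion
#' formed at the ester carbonyl oxygen during nucleophilic attack. All
#' residues whose backbone N lies within `maxNODist` of the carbonyl O are
#' returned sorted by distance; prolines are excluded (no amide H). The
#' criterion passes when at least `minDonors` donors are found (default 2,
#' matching the canonical two-NH oxyanion hole).
#'
#' @param model a [StructureModel-class].
#' @param pose a [LigandPose-class].
#' @param groupIndex which ester group's carbonyl O to probe.
#' @param maxNODist donor N - carbonyl O cutoff, Angstrom (default 3.5).
#' @param minDonors donors required to pass (default 2).
#' @param excludeProline drop proline backbone N (default TRUE).
#' @return list with `donors` (data.frame `chain`, `resnum`, `icode`,
#'   `resname`, `distance`) and `pass`.
#' @export
findOxyanionDonors <- function(model, pose, groupIndex = 1L,
                               maxNODist = 3.5, minDonors = 2L,
                               excludeProline = TRUE) {
  if (groupIndex < 1L || groupIndex > nrow(pose@esterGroups))
    stop(sprintf("invalid ester group index %d", groupIndex), call. = FALSE)
  oc <- as.numeric(pose@atoms[pose@esterGroups$carbonylO[groupIndex],
                              c("x", "y", "z")])
  a <- model@atoms[!model@atoms$het & model@atoms$name == "N", , drop = FALSE]
  if (excludeProline) a <- a[a$resname != "PRO", , drop = FALSE]
  d <- sqrt((a$x - oc[1])^2 + (a$y - oc[2])^2 + (a$z - oc[3])^2)
  keep <- d <= maxNODist
  donors <- data.frame(chain = a$chain[keep], resnum = a$resnum[keep],
                       icode = a$icode[keep], resname = a$resname[keep],
                       distance = d[keep], stringsAsFactors = FALSE)
  donors <- donors[order(donors$distance), , drop = FALSE]
  rownames(donors) <- NULL
  list(donors = donors, pass = nrow(donors) >= minDonors)
}

#' Catalytic-triad hydrogen-bond geometry
#'
#' Heavy-atom distances of the serine-hydrolase charge-relay system: Ser
#' O-gamma to His NE2, and His ND1 to the nearer Asp carboxylate oxygen
#' (min over OD1/OD2). Each contact is flagged hydrogen-bonded at <= `hbondMax`
#' (default 3.5 A). Hydrogens are never required.
#'
#' @param model a [StructureModel-class].
#' @param triad a [TriadAssignment-class].
#' @param hbondMax H-bond heavy-atom cutoff, Angstrom.
#' @return list with `ser_og_his_ne2`, `his_nd1_asp_o` (Angstrom) and
#'   `hbonded` (named logical).
#' @export
triadGeometry <- function(model, triad, hbondMax = 3.5) {
  og <- .serOG(model, triad)
  his <- atomCoords(model, triad@his$chain, triad@his$resnum,
                    atoms = c("NE2", "ND1"))
  asp <- atomCoords(model, triad@asp$chain, triad@asp$resnum,
                    atoms = c("OD1", "OD2"))
  d1 <- sqrt(sum((og - his["NE2", ])^2))
  d2 <- min(sqrt(sum((his["ND1", ] - asp["OD1", ])^2)),
            sqrt(sum((his["ND1", ] - asp["OD2", ])^2)))
  list(ser_og_his_ne2 = d1, his_nd1_asp_o = d2,
       hbonded = c(ser_his = d1 <= hbondMax, his_asp = d2 <= hbondMax))
}

#' Docking-energy window filter
#'
#' Keeps poses whose binding energy falls inside the screening window
#' (inclusive at both ends; default -4 to 0 kcal/mol, bracketing the
#' template's computed binding energy of about -2.8 kcal/mol).
#'
#' @param energy binding energy, kcal/mol.
#' @param window numeric `(low, high)`.
#' @return logical.
#' @export
energyWindowFilter <- function(energy, window = c(-4, 0)) {
  if (window[1] >= window[2]) stop("window low must be < high", call. = FALSE)
  energy >= window[1] & energy <= window[2]
}

#' Full active-site audit
#'
#' Runs the attack-distance, oxyanion-donor, triad-geometry and
#' energy-window checks against one pose and reports distances plus
#' per-criterion pass flags. Flags are pure functions of the stored
#' distances and the configuration.
#'
#' @param model a [StructureModel-class].
#' @param triad a [TriadAssignment-class].
#' @param pose a [LigandPose-class].
#' @param config a [ScreenConfig-class].
#' @return list with `attack_distance`, `donors`, `triad`, `binding_energy`
#'   and `pass` (named logical vector).
#' @export
auditActiveSite <- function(model, triad, pose, config = ScreenConfig()) {
  ad <- attackDistance(model, triad, pose)
  don <- findOxyanionDonors(model, pose, 1L,
                            maxNODist = config@oxyanionMaxDist,
                            minDonors = config@minOxyanionDonors)
  tg <- triadGeometry(model, triad)
  epass <- if (is.na(pose@bindingEnergy)) NA else
    energyWindowFilter(pose@bindingEnergy, config@energyWindow)
  list(
    attack_distance = ad,
    donors = don$donors,
    triad = tg,
    binding_energy = pose@bindingEnergy,
    pass = c(attack = ad < config@attackDistMax,
             oxyanion = don$pass,
             triad = all(tg$hbonded),
             energy = epass)
  )
}

#' Read a docking pose table
#'
#' Reads a TSV with columns `pose_id`, `energy_kcal_mol`, `ligand_pdb_path`
#' (paths resolved relative to the table's directory), loads each ligand's
#' HETATM coordinates, auto-annotates ester groups, and returns poses
#' ordered by energy ascending.
#'
#' @param path pose table path.
#' @return named list of [LigandPose-class], ordered by energy.
#' @export
parsePoseTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pose_id", "energy_kcal_mol", "ligand_pdb_path")
  if (!all(need %in% names(tab)))
    stop(sprintf("pose table must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  dir <- dirname(path)
  tab <- tab[order(tab$energy_kcal_mol), , drop = FALSE]
  poses <- lapply(seq_len(nrow(tab)), function(i) {
    lp <- tab$ligand_pdb_path[i]
    if (!file.exists(lp)) lp <- file.path(dir, lp)
    if (!file.exists(lp))
      stop(sprintf("missing ligand coordinates for pose '%s': %s",
                   tab$pose_id[i], tab$ligand_pdb_path[i]), call. = FALSE)
    mod <- readStructure(lp)[[1]]
    a <- atomTable(mod)  # ligands may use ATOM or HETATM records
    atoms <- data.frame(label = a$name, element = a$element,
                        x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    LigandPose(atoms, bindingEnergy = tab$energy_kcal_mol[i])
  })
  names(poses) <- tab$pose_id
  poses
}
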