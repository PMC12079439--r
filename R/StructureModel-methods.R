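#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a StructureModel from an atom table
#'
#' Low-level constructor; most users obtain models from [readStructure()] or
#' [makeToyScaffold()].
#'
#' @param atoms atom data.frame (see [StructureModel-class]). Missing
#'   `occupancy`, `icode`, `het`, `serial` columns are filled with defaults.
#' @param modelIndex model number, >= 1.
#' @param provenance `"predicted"`, `"experimental"` or `"synthetic"`.
#' @return a validated [StructureModel-class] object.
#' @export
StructureModel <- function(atoms, modelIndex = 1L, provenance = "experimental") {
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- .guessElement(atoms$name)
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, modelIndex = as.integer(modelIndex),
      provenance = provenance)
}

.guessElement <- function(name) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  out <- substr(stripped, 1L, 1L)
  out[stripped %in% c("CL", "BR", "SE")] <- stripped[stripped %in% c("CL", "BR", "SE")]
  out
}

.resKey <- function(chain, resnum, icode) paste(chain, resnum, icode, sep = "|")

#' @rdname StructureModel-class
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel-class
#' @export
setMethod("residueTable", "StructureModel", function(x) {
  a <- x@atoms[!x@atoms$het, , drop = FALSE]
  key <- .resKey(a$chain, a$resnum, a$icode)
  first <- !duplicated(key)
  out <- a[first, c("chain", "resnum", "icode", "resname")]
  rownames(out) <- NULL
  out
})

#' @rdname StructureModel-class
#' @export
setMethod("nResidues", "StructureModel", function(x) nrow(residueTable(x)))

#' @rdname StructureModel-class
#' @export
setMethod("provenance", "StructureModel", function(x) x@provenance)

setMethod("show", "StructureModel", function(object) {
  rt <- residueTable(object)
  cat(sprintf("StructureModel (%s), model %d: %d residues, %d atoms",
              object@provenance, object@modelIndex, nrow(rt),
              nrow(object@atoms)))
  chains <- unique(rt$chain)
  cat(sprintf(" | chains: %s\n", paste(chains, collapse = ", ")))
  invisible(object)
})

#' Look up atom coordinates
#'
#' Returns the coordinates of named atoms of one residue, in the order
#' requested.
#'
#' @param model a [StructureModel-class].
#' @param chain,resnum,icode residue identifier (author numbering).
#' @param atoms character vector of atom names.
#' @return numeric matrix with one row per requested atom.
#' @export
atomCoords <- function(model, chain, resnum, icode = "", atoms) {
  a <- model@atoms
  sel <- a$chain == chain & a$resnum == resnum & a$icode == icode
  out <- matrix(NA_real_, length(atoms), 3,
                dimnames = list(atoms, c("x", "y", "z")))
  for (i in seq_along(atoms)) {
    hit <- which(sel & a$name == atoms[i])
    if (length(hit) == 0L)
      stop(sprintf("atom %s missing in residue %s%s%s", atoms[i], chain,
                   resnum, icode), call. = FALSE)
    out[i, ] <- as.numeric(a[hit[1], c("x", "y", "z")])
  }
  out
}

## Coordinates of one named atom per residue of the (non-het) model, in
## residue order; errors listing residues where the atom is absent.
.namedAtomCoords <- function(model, atomName) {
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  rt <- residueTable(model)
  key <- .resKey(a$chain, a$resnum, a$icode)
  sel <- a$name == atomName
  akey <- key[sel]
  idx <- match(.resKey(rt$chain, rt$resnum, rt$icode), akey)
  if (anyNA(idx)) {
    miss <- rt[is.na(idx), ]
    stop(sprintf("residues missing %s atom: %s", atomName,
                 paste(paste0(miss$chain, miss$resnum), collapse = ", ")),
         call. = FALSE)
  }
  coords <- as.matrix(a[sel, c("x", "y", "z")])[idx, , drop = FALSE]
  rownames(coords) <- NULL
  coords
}

## Apply a rigid motion (rotation matrix R, translation t) to all atoms.
.transformModel <- function(model, R, t) {
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  m <- model
  m@atoms$x <- xyz[, 1]; m@atoms$y <- xyz[, 2]; m@atoms$z <- xyz[, 3]
  m
}
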