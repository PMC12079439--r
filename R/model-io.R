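#' @include AllClasses.R StructureModel-methods.R
NULL

## ---------------------------------------------------------------------------
## PDB reading (bio3d backend) and writing
## ---------------------------------------------------------------------------

## Pre-scan a PDB file for malformed coordinate records so parse failures can
## name the offending line (the backend reader does not).
.scanPdbLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0L)
    stop(sprintf("empty structure: no ATOM records in '%s'", path),
         call. = FALSE)
  for (i in atom_idx) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok)
      stop(sprintf("malformed ATOM line %d in '%s'", i, path), call. = FALSE)
  }
  invisible(length(atom_idx))
}

## Altloc policy: keep the highest-occupancy conformer per (residue, atom
## name); ties resolved by first occurrence.
.resolveAltloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
    ix[which.max(atoms$occupancy[ix])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a PDB structure
#'
#' Parses a (possibly multi-model) PDB file into one [StructureModel-class]
#' per `MODEL` block (a single implicit model if the file has none). The
#' B-factor column is preserved verbatim; for predicted models it carries
#' per-residue pLDDT. Alternate locations keep the highest-occupancy
#' conformer. Only the PDB dialect with `ATOM`/`HETATM`/`MODEL`/`ENDMDL`
#' records is supported; mmCIF is out of scope.
#'
#' @param path PDB file path.
#' @param provenance provenance tag for the returned models:
#'   `"experimental"` (default), `"predicted"` or `"synthetic"`.
#' @param includeHet keep HETATM records (default TRUE; they are flagged in
#'   the atom table and excluded from residue-level operations).
#' @return list of [StructureModel-class], one per model.
#' @examples
#' tf <- tempfile(fileext = ".pdb")
#' writeStructure(makeToyScaffold(nResidues = 24), tf)
#' mod <- readStructure(tf)[[1]]
#' nResidues(mod)
#' @export
readStructure <- function(path, provenance = "experimental", includeHet = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  .scanPdbLines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     .guessElement(trimws(at$elety)), toupper(trimws(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    resnum = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = trimws(at$resid),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (!includeHet) atoms <- atoms[!atoms$het, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop(sprintf("empty structure: no residues in '%s'", path), call. = FALSE)
  atoms <- .resolveAltloc(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz)
  lapply(seq_len(nmod), function(m) {
    a <- atoms
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    ## read.pdb's xyz covers all atoms pre-altloc-filtering; map via serial
    keep_idx <- match(atoms$serial, at$eleno)
    a$x <- co[keep_idx, 1]; a$y <- co[keep_idx, 2]; a$z <- co[keep_idx, 3]
    StructureModel(a, modelIndex = m, provenance = provenance)
  })
}

.fmtAtomName <- function(name) {
  ifelse(nchar(name) < 4L, sprintf(" %-3s", name), sprintf("%-4s", name))
}

.pdbAtomLines <- function(atoms) {
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, atoms$serial %% 100000L, .fmtAtomName(atoms$name), " ",
          substr(atoms$resname, 1, 3), substr(atoms$chain, 1, 1),
          atoms$resnum %% 10000L, ifelse(nzchar(atoms$icode), atoms$icode, " "),
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$bfactor,
          sprintf("%2s", atoms$element))
}

#' Write one or more models to a PDB file
#'
#' Multi-model input produces `MODEL`/`ENDMDL` blocks; chains are terminated
#' with `TER`. Coordinates are written at the PDB precision of 0.001 A and
#' B-factors at 0.01.
#'
#' @param models a [StructureModel-class] or a list of them (e.g. trajectory
#'   frames).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(models, path) {
  if (is(models, "StructureModel")) models <- list(models)
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    atoms <- models[[m]]@atoms
    for (ch in unique(atoms$chain)) {
      sub <- atoms[atoms$chain == ch, , drop = FALSE]
      writeLines(.pdbAtomLines(sub), con)
      if (!all(sub$het)) writeLines("TER", con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Sequences
## ---------------------------------------------------------------------------

#' Construct a ProteinSequence
#'
#' @param letters one-letter string (standard amino acids plus `"X"`).
#' @param numbering optional data.frame (`chain`, `resnum`, `icode`); default
#'   chain "A", residues numbered 1..n.
#' @return a [ProteinSequence-class].
#' @export
ProteinSequence <- function(letters, numbering = NULL) {
  n <- nchar(letters)
  if (is.null(numbering))
    numbering <- data.frame(chain = rep("A", n), resnum = seq_len(n),
                            icode = rep("", n), stringsAsFactors = FALSE)
  new("ProteinSequence", letters = toupper(letters), numbering = numbering)
}

#' @rdname ProteinSequence-class
#' @export
setMethod("seqLetters", "ProteinSequence", function(x) x@letters)

#' @rdname ProteinSequence-class
#' @export
setMethod("seqNumbering", "ProteinSequence", function(x) x@numbering)

setMethod("show", "ProteinSequence", function(object) {
  n <- nchar(object@letters)
  head <- if (n > 40) paste0(substr(object@letters, 1, 40), "...") else object@letters
  cat(sprintf("ProteinSequence: %d aa | %s\n", n, head))
  invisible(object)
})

setMethod("length", "ProteinSequence", function(x) nchar(x@letters))

## Accept either a ProteinSequence or a plain string in sequence utilities.
.asLetters <- function(seq) {
  if (is(seq, "ProteinSequence")) seqLetters(seq) else toupper(as.character(seq))
}

#' Extract the one-letter sequence of a chain
#'
#' One letter per residue in author order; non-standard residues map to
#' `"X"`. The returned numbering makes the mapping to `(chain, resnum,
#' icode)` invertible.
#'
#' @param model a [StructureModel-class].
#' @param chain chain identifier.
#' @return a [ProteinSequence-class].
#' @export
extractSequence <- function(model, chain = "A") {
  rt <- residueTable(model)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0L)
    stop(sprintf("chain '%s' not found", chain), call. = FALSE)
  letters <- .AA_THREE_TO_ONE[rt$resname]
  letters[is.na(letters)] <- "X"
  ProteinSequence(paste(letters, collapse = ""),
                  rt[, c("chain", "resnum", "icode")])
}

#' Mean pLDDT of a predicted model
#'
#' Model-level prediction confidence: the arithmetic mean of the Calpha
#' B-factors (per-residue pLDDT) over all residues. The quality gate used in
#' screening is strict (`mean pLDDT > 70` passes).
#'
#' @param model a [StructureModel-class] with provenance `"predicted"`
#'   (enforced).
#' @return numeric in \[0, 100\].
#' @export
meanPlddt <- function(model) {
  if (!identical(provenance(model), "predicted"))
    stop("meanPlddt requires a model with provenance 'predicted'", call. = FALSE)
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  ca <- a[a$name == "CA", , drop = FALSE]
  rt <- residueTable(model)
  missing <- setdiff(.resKey(rt$chain, rt$resnum, rt$icode),
                     .resKey(ca$chain, ca$resnum, ca$icode))
  if (length(missing))
    stop(sprintf("residues missing CA: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  mean(ca$bfactor)
}

#' Theoretical average molecular mass of a sequence
#'
#' Sum of standard average residue masses plus one water (18.02 Da).
#' Undefined for sequences containing `"X"`.
#'
#' @param seq a [ProteinSequence-class] or plain string.
#' @return mass in Da.
#' @examples
#' sequenceMass("G")  # 75.07
#' @export
sequenceMass <- function(seq) {
  letters <- strsplit(.asLetters(seq), "")[[1]]
  if (length(letters) == 0L) stop("empty sequence", call. = FALSE)
  if (any(letters == "X"))
    stop("mass undefined: sequence contains 'X' residues", call. = FALSE)
  bad <- setdiff(letters, names(.RESIDUE_MASS))
  if (length(bad))
    stop(sprintf("unknown letters: %s", paste(unique(bad), collapse = "")),
         call. = FALSE)
  sum(.RESIDUE_MASS[letters]) + .WATER_MASS
}

## ---------------------------------------------------------------------------
## FASTA
## ---------------------------------------------------------------------------

#' Read/write protein FASTA
#'
#' Thin wrappers over Biostrings returning/accepting named character vectors.
#'
#' @param path FASTA file.
#' @return `readFastaSequences`: named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname readFastaSequences
#' @param seqs named character vector (or list) of sequences.
#' @export
writeFastaSequences <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
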