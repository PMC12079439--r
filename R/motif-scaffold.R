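#' @include AllClasses.R StructureModel-methods.R
NULL

#' Construct a MotifSpec
#'
#' Defines the template segments retained around the catalytic triad. For a
#' cutinase-like template the triad is Ser (nucleophile), His (base), Asp
#' (acid), e.g. S165/H242/D210.
#'
#' @param segments data.frame with `chain`, `start`, `end` (author
#'   numbering, inclusive).
#' @param catalytic data.frame with `role` (`nucleophile`/`base`/`acid`),
#'   `chain`, `resnum`.
#' @param backboneAtoms atom names used for motif-fidelity RMSD; default full
#'   backbone `N, CA, C, O`.
#' @return a [MotifSpec-class].
#' @export
MotifSpec <- function(segments, catalytic,
                      backboneAtoms = c("N", "CA", "C", "O")) {
  segments <- segments[order(segments$chain, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  new("MotifSpec", segments = as.data.frame(segments),
      catalytic = as.data.frame(catalytic), backboneAtoms = backboneAtoms)
}

setMethod("show", "MotifSpec", function(object) {
  s <- object@segments
  cat(sprintf("MotifSpec: %d segments (%d residues), backbone atoms %s\n",
              nrow(s), sum(s$end - s$start + 1L),
              paste(object@backboneAtoms, collapse = ",")))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s%d-%d\n", s$chain[i], s$start[i], s$end[i]))
  invisible(object)
})

## Expand a segment table to one row per residue, in segment order.
.segmentResidues <- function(segments) {
  do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    data.frame(chain = segments$chain[i],
               resnum = seq(segments$start[i], segments$end[i]),
               stringsAsFactors = FALSE)
  }))
}

#' Motif residue count and retained percentage
#'
#' @param spec a [MotifSpec-class].
#' @param templateLength template length in residues.
#' @return list with `retained_count` and `retained_percent` (rounded to the
#'   nearest integer).
#' @examples
#' ## three segments totalling 44 residues on a 258-residue template -> 17%
#' @export
specSummary <- function(spec, templateLength) {
  if (templateLength <= 0) stop("templateLength must be positive", call. = FALSE)
  count <- sum(spec@segments$end - spec@segments$start + 1L)
  if (count > templateLength)
    stop("retained count exceeds template length", call. = FALSE)
  list(retained_count = as.integer(count),
       retained_percent = as.integer(.roundHalfAway(100 * count / templateLength)))
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Extract motif backbone coordinates
#'
#' One row per backbone atom per motif residue, ordered by (segment, residue,
#' backbone-atom order).
#'
#' @param model a [StructureModel-class].
#' @param spec a [MotifSpec-class].
#' @param residues optional residue table (`chain`, `resnum`) overriding the
#'   spec segments (used for correspondences onto a design).
#' @return numeric matrix (n_residues * n_atoms) x 3 with a `residues`
#'   attribute.
#' @export
extractMotif <- function(model, spec, residues = NULL) {
  if (is.null(residues)) residues <- .segmentResidues(spec@segments)
  .collectCoords(model, residues, spec@backboneAtoms)
}

## Gather named atoms of listed residues as a stacked coordinate matrix.
.collectCoords <- function(model, residues, atoms) {
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  rows <- vector("list", nrow(residues))
  missing <- character()
  for (i in seq_len(nrow(residues))) {
    sel <- a$chain == residues$chain[i] & a$resnum == residues$resnum[i]
    m <- matrix(NA_real_, length(atoms), 3)
    for (j in seq_along(atoms)) {
      hit <- which(sel & a$name == atoms[j])
      if (length(hit) == 0L) {
        missing <- c(missing, sprintf("%s%d:%s", residues$chain[i],
                                      residues$resnum[i], atoms[j]))
      } else {
        m[j, ] <- as.numeric(a[hit[1], c("x", "y", "z")])
      }
    }
    rows[[i]] <- m
  }
  if (length(missing))
    stop(sprintf("motif extraction failed; missing atoms: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, rows)
  colnames(out) <- c("x", "y", "z")
  attr(out, "residues") <- residues
  out
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares superposition of coordinate set `B` onto `A` via singular
#' value decomposition, constrained to a proper rotation. Applying the
#' returned transform to `B` (`B %*% t(rotation)` + `translation`) minimizes
#' the RMSD to `A`.
#'
#' @param A,B n x 3 matrices with rows in correspondence, n >= 3.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom).
#' @export
kabschSuperpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size", call. = FALSE)
  if (nrow(A) < 3L) stop("at least 3 points required", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2L || qr(Bc)$rank < 2L)
    stop("degenerate point set (collinear)", call. = FALSE)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - Brot)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% t(R)), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param X n x 3 matrix.
#' @param sup result of [kabschSuperpose()].
#' @return transformed n x 3 matrix.
#' @export
applySuperposition <- function(X, sup) {
  sweep(as.matrix(X) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Build a template-design motif correspondence
#'
#' Pairs each motif residue of the template spec with the residue occupying
#' the same position in the design's kept segments (exact-length positional
#' mapping).
#'
#' @param spec a [MotifSpec-class] (template side).
#' @param designSegments data.frame with `chain`, `start`, `end` giving the
#'   kept segments in design numbering, same segment lengths as the spec.
#' @return data.frame with `t_chain`, `t_resnum`, `d_chain`, `d_resnum`.
#' @export
motifCorrespondence <- function(spec, designSegments) {
  ts <- spec@segments
  ds <- designSegments
  if (nrow(ts) != nrow(ds))
    stop("segment counts differ between template and design", call. = FALSE)
  tlen <- ts$end - ts$start + 1L
  dlen <- ds$end - ds$start + 1L
  if (!all(tlen == dlen))
    stop("segment lengths differ between template and design", call. = FALSE)
  tr <- .segmentResidues(ts)
  dr <- .segmentResidues(ds)
  data.frame(t_chain = tr$chain, t_resnum = tr$resnum,
             d_chain = dr$chain, d_resnum = dr$resnum,
             stringsAsFactors = FALSE)
}

#' Motif-fidelity RMSD between template and design
#'
#' Backbone RMSD of the retained motif residues after optimal rigid-body
#' superposition. Designs with motif RMSD above the screening threshold
#' (default 2.5 A) fail motif recapitulation.
#'
#' @param template,design [StructureModel-class] objects.
#' @param spec a [MotifSpec-class] (template numbering).
#' @param correspondence optional data.frame from [motifCorrespondence()];
#'   by default design residues are assumed to share the template numbering.
#' @return RMSD in Angstrom.
#' @export
motifRmsd <- function(template, design, spec, correspondence = NULL) {
  tres <- .segmentResidues(spec@segments)
  if (is.null(correspondence)) {
    dres <- tres
  } else {
    ord <- match(paste(tres$chain, tres$resnum),
                 paste(correspondence$t_chain, correspondence$t_resnum))
    if (anyNA(ord))
      stop("correspondence does not cover all motif residues", call. = FALSE)
    dres <- data.frame(chain = correspondence$d_chain[ord],
                       resnum = correspondence$d_resnum[ord],
                       stringsAsFactors = FALSE)
  }
  A <- extractMotif(template, spec, tres)
  B <- extractMotif(design, spec, dres)
  kabschSuperpose(A, B)$rmsd
}

#' Contig string for inpainting
#'
#' Emits the alternating kept-segment / gap-length specification used to ask
#' an inpainting model for designs of a bounded total length. Kept segments
#' are written as `"<chain><start>-<end>"`; gaps as `"<min>-<max>"` (or a
#' single number when fixed). Gap budgets are distributed as evenly as
#' possible over the slots before, between and after the kept segments so
#' that the minimal (maximal) gap choices sum to the target minimum
#' (maximum).
#'
#' @param spec a [MotifSpec-class].
#' @param templateLength template length (residues).
#' @param targetLength numeric `(min, max)` total design length; `max` must
#'   be below `templateLength` and `min` at least the retained count.
#' @return contig string, e.g. `"24-36/A150-175/24-35/A205-215/24-35/A239-245/24-35"`.
#' @export
contigString <- function(spec, templateLength, targetLength) {
  s <- spec@segments
  retained <- sum(s$end - s$start + 1L)
  tmin <- targetLength[1]; tmax <- targetLength[2]
  if (tmin > tmax) stop("targetLength min > max", call. = FALSE)
  if (tmax >= templateLength)
    stop("target length must be shorter than the template", call. = FALSE)
  if (tmin < retained)
    stop(sprintf("infeasible budget: target min %d < retained %d",
                 tmin, retained), call. = FALSE)
  nslots <- nrow(s) + 1L
  distribute <- function(total) {
    base <- total %/% nslots
    extra <- total %% nslots
    base + as.integer(seq_len(nslots) <= extra)
  }
  gmin <- distribute(as.integer(tmin - retained))
  gmax <- distribute(as.integer(tmax - retained))
  tokens <- character()
  for (i in seq_len(nslots)) {
    if (gmax[i] > 0)
      tokens <- c(tokens,
                  if (gmin[i] == gmax[i]) as.character(gmin[i])
                  else sprintf("%d-%d", gmin[i], gmax[i]))
    if (i <= nrow(s))
      tokens <- c(tokens, sprintf("%s%d-%d", s$chain[i], s$start[i], s$end[i]))
  }
  paste(tokens, collapse = "/")
}

#' Parse a contig string
#'
#' Inverse of [contigString()]: recovers kept segments and gap ranges and the
#' total length bounds they imply.
#'
#' @param text contig string.
#' @return list with `segments` (data.frame `chain`, `start`, `end`), `gaps`
#'   (data.frame `min`, `max`), `min_total`, `max_total`.
#' @export
parseContigString <- function(text) {
  tokens <- strsplit(text, "/", fixed = TRUE)[[1]]
  segs <- list(); gaps <- list()
  for (tok in tokens) {
    if (grepl("^[A-Za-z]", tok)) {
      m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)-([0-9]+)$", tok))[[1]]
      if (length(m) == 0L) stop(sprintf("bad segment token '%s'", tok), call. = FALSE)
      segs[[length(segs) + 1L]] <- data.frame(
        chain = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
        stringsAsFactors = FALSE)
    } else {
      m <- regmatches(tok, regexec("^([0-9]+)(-([0-9]+))?$", tok))[[1]]
      if (length(m) == 0L) stop(sprintf("bad gap token '%s'", tok), call. = FALSE)
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
      gaps[[length(gaps) + 1L]] <- data.frame(min = lo, max = hi)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chain = character(), start = integer(), end = integer())
  gapdf <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(min = integer(), max = integer())
  retained <- sum(segments$end - segments$start + 1L)
  list(segments = segments, gaps = gapdf,
       min_total = retained + sum(gapdf$min),
       max_total = retained + sum(gapdf$max))
}

#' Static structural quality gate
#'
#' The first screening stage: a candidate passes iff mean pLDDT strictly
#' exceeds `plddtMin`, pTM strictly exceeds `ptmMin`, and motif RMSD is at
#' most `motifRmsdMax` (a design exactly at the RMSD threshold passes; the
#' screen discards only designs *larger* than it).
#'
#' @param candidate a [CandidateRecord-class] carrying scores `mean_plddt`,
#'   `ptm`, `motif_rmsd`.
#' @param config a [ScreenConfig-class].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing).
#' @export
staticQualityFilter <- function(candidate, config = ScreenConfig()) {
  sc <- candidate@scores
  need <- c("mean_plddt", "ptm", "motif_rmsd")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop(sprintf("incomplete candidate '%s': missing %s", candidate@id,
                 paste(miss, collapse = ", ")), call. = FALSE)
  reasons <- character()
  if (!(sc[["mean_plddt"]] > config@plddtMin)) reasons <- c(reasons, "plddt")
  if (!(sc[["ptm"]] > config@ptmMin)) reasons <- c(reasons, "ptm")
  if (!(sc[["motif_rmsd"]] <= config@motifRmsdMax)) reasons <- c(reasons, "motif_rmsd")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
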