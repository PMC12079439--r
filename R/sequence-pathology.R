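#' @include AllClasses.R model-io.R
NULL

.runsFromFlags <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Detect single-amino-acid repeats (SAAR)
#'
#' Maximal homopolymeric runs (e.g. `LLLLLLL`, `GGGGGGGG`) of length at
#' least `minRun`. Such repeats are a known artifact of structure-based
#' sequence generators and correlate with poor expressibility. Positions are
#' 1-based inclusive.
#'
#' @param seq a [ProteinSequence-class] or plain string.
#' @param minRun minimum run length (default 5; >= 2 required).
#' @return data.frame with `kind` (`"SAAR"`), `start`, `end`, `length`,
#'   `subsequence`.
#' @export
findSaar <- function(seq, minRun = 5L) {
  if (minRun < 2L) stop("minRun must be >= 2", call. = FALSE)
  letters <- strsplit(.asLetters(seq), "")[[1]]
  if (length(letters) == 0L) return(.emptyRuns())
  r <- rle(letters)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= minRun
  .runAnnotation("SAAR", starts[keep], ends[keep], letters)
}

#' Detect consecutive hydrophobic amino acid (CHAA) runs
#'
#' Maximal runs of letters from the hydrophobic alphabet (e.g. `LVVLV`) of
#' length at least `minRun`. A run that is itself a homopolymer of length
#' >= `minRun` is reported by [findSaar()] instead and omitted here, so the
#' two detectors never double-report a span.
#'
#' @param seq a [ProteinSequence-class] or plain string.
#' @param hydrophobicSet one-letter hydrophobic alphabet (default
#'   A, V, L, I, M, F, W).
#' @param minRun minimum run length (default 5; >= 2 required).
#' @return data.frame as in [findSaar()] with `kind` `"CHAA"`.
#' @export
findChaa <- function(seq, hydrophobicSet = .HYDROPHOBIC_ONE, minRun = 5L) {
  if (minRun < 2L) stop("minRun must be >= 2", call. = FALSE)
  letters <- strsplit(.asLetters(seq), "")[[1]]
  if (length(letters) == 0L) return(.emptyRuns())
  runs <- .runsFromFlags(letters %in% hydrophobicSet)
  runs <- runs[runs$length >= minRun, , drop = FALSE]
  if (nrow(runs)) {
    homopolymer <- vapply(seq_len(nrow(runs)), function(i) {
      length(unique(letters[runs$start[i]:runs$end[i]])) == 1L
    }, logical(1))
    runs <- runs[!homopolymer, , drop = FALSE]
  }
  .runAnnotation("CHAA", runs$start, runs$end, letters)
}

.runAnnotation <- function(kind, starts, ends, letters) {
  if (length(starts) == 0L) return(.emptyRuns())
  data.frame(
    kind = kind, start = as.integer(starts), end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    subsequence = vapply(seq_along(starts), function(i)
      paste(letters[starts[i]:ends[i]], collapse = ""), ""),
    stringsAsFactors = FALSE)
}

.emptyRuns <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             length = integer(), subsequence = character(),
             stringsAsFactors = FALSE)
}

#' Detect all sequence pathologies
#'
#' Convenience wrapper returning SAAR and CHAA annotations in one table,
#' sorted by start.
#'
#' @inheritParams findChaa
#' @return data.frame of run annotations.
#' @export
findPathologies <- function(seq, hydrophobicSet = .HYDROPHOBIC_ONE,
                            minRun = 5L) {
  out <- rbind(findSaar(seq, minRun), findChaa(seq, hydrophobicSet, minRun))
  out[order(out$start), , drop = FALSE]
}

#' Hydrophobic fraction of a sequence
#'
#' @inheritParams findChaa
#' @return fraction of letters in `hydrophobicSet`.
#' @export
hydrophobicFraction <- function(seq, hydrophobicSet = .HYDROPHOBIC_ONE) {
  letters <- strsplit(.asLetters(seq), "")[[1]]
  if (length(letters) == 0L) stop("empty sequence", call. = FALSE)
  mean(letters %in% hydrophobicSet)
}

#' Build a redesign mask for iterative re-inpainting
#'
#' Marks pathological spans (sequence runs, surface-patch positions) for
#' redesign, extends each by a flank, and protects motif positions, which
#' are never redesigned. The companion contig string alternates kept
#' stretches (`"A<start>-<end>"`) with fixed-length redesign gaps
#' (`"<len>-<len>"`), so re-inpainting rebuilds exactly the replaced length.
#' All positions are 1-based.
#'
#' @param length sequence length.
#' @param runs run annotations from [findPathologies()] (or an empty
#'   data.frame).
#' @param patchPositions integer positions inside surface hydrophobic
#'   patches.
#' @param protected integer positions inside motif segments.
#' @param flank residues added on both sides of each redesigned span
#'   (default 2).
#' @return a [RedesignMask-class]; redesign/protection conflicts are
#'   resolved in favour of protection and recorded in `@conflicts` with a
#'   warning.
#' @export
redesignMask <- function(length, runs = .emptyRuns(),
                         patchPositions = integer(), protected = integer(),
                         flank = 2L) {
  length <- as.integer(length)
  bad <- c(patchPositions, protected)
  if (any(bad < 1L | bad > length))
    stop("positions out of range", call. = FALSE)
  keep <- rep(TRUE, length)
  mark <- function(lo, hi) {
    lo <- max(1L, lo - flank); hi <- min(length, hi + flank)
    keep[lo:hi] <<- FALSE
  }
  for (i in seq_len(nrow(runs))) mark(runs$start[i], runs$end[i])
  for (p in patchPositions) mark(p, p)
  conflicts <- intersect(which(!keep), as.integer(protected))
  if (length(conflicts)) {
    keep[conflicts] <- TRUE
    warning(sprintf("redesign overridden by motif protection at %d position(s): %s",
                    length(conflicts),
                    paste(utils::head(conflicts, 10), collapse = ", ")))
  }
  new("RedesignMask", keep = keep, contig = .maskContig(keep),
      protected = as.integer(sort(unique(protected))),
      conflicts = as.integer(conflicts))
}

## Contig for a mask: kept stretches as segments, redesigned stretches as
## fixed-length gaps.
.maskContig <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tokens <- vapply(seq_along(r$values), function(i) {
    if (r$values[i]) sprintf("A%d-%d", starts[i], ends[i])
    else sprintf("%d-%d", r$lengths[i], r$lengths[i])
  }, "")
  paste(tokens, collapse = "/")
}

setMethod("show", "RedesignMask", function(object) {
  cat(sprintf("RedesignMask: %d positions, %d to redesign, %d protected\n",
              length(object@keep), sum(!object@keep),
              length(object@protected)))
  cat("  contig:", object@contig, "\n")
  invisible(object)
})

#' Write run annotations to TSV
#'
#' @param runs data.frame of run annotations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunsTable <- function(runs, path) {
  utils::write.table(runs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
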