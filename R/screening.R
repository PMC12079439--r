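#' @include AllClasses.R motif-scaffold.R active-site.R stability-surface.R sequence-pathology.R
NULL

#' Construct a ScreenConfig
#'
#' All defaults reproduce the published screening thresholds: mean pLDDT
#' > 70, pTM > 0.7, motif RMSD <= 2.5 A, docking energy in \[-4, 0\]
#' kcal/mol, attack distance < 4 A, >= 2 oxyanion donors, trajectory
#' Calpha RMSD <= 5 A within 20 ns.
#'
#' @param ... slot overrides, e.g. `plddtMin = 80`, `exhaustive = TRUE`.
#' @return a [ScreenConfig-class].
#' @export
ScreenConfig <- function(...) {
  new("ScreenConfig", ...)
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig:\n")
  cat(sprintf("  static   : pLDDT > %g, pTM > %g, motif RMSD <= %g A\n",
              object@plddtMin, object@ptmMin, object@motifRmsdMax))
  cat(sprintf("  docking  : energy in [%g, %g] kcal/mol, attack < %g A, donors >= %g\n",
              object@energyWindow[1], object@energyWindow[2],
              object@attackDistMax, object@minOxyanionDonors))
  cat(sprintf("  stability: RMSD <= %g A within %g ns\n",
              object@trajRmsdMax, object@trajHorizon))
  cat(sprintf("  pathology: min run %g, flank %g, exposure >= %g, link %g A\n",
              object@minRun, object@flank, object@exposureMin, object@linkDist))
  invisible(object)
})

#' Read/write a ScreenConfig as YAML
#'
#' @param path YAML file.
#' @return `readScreenConfig`: a [ScreenConfig-class].
#' @export
readScreenConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- slotNames("ScreenConfig")
  y <- y[names(y) %in% known]
  if (!is.null(y$energyWindow)) y$energyWindow <- as.numeric(unlist(y$energyWindow))
  do.call(ScreenConfig, y)
}

#' @rdname readScreenConfig
#' @param config a [ScreenConfig-class].
#' @export
writeScreenConfig <- function(config, path) {
  vals <- lapply(slotNames("ScreenConfig"), function(s) slot(config, s))
  names(vals) <- slotNames("ScreenConfig")
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Construct a CandidateRecord
#'
#' @param id candidate identifier.
#' @param scores named numeric scores (see [CandidateRecord-class]).
#' @param sequence optional one-letter sequence.
#' @param structurePath optional structure file path.
#' @return a [CandidateRecord-class].
#' @export
CandidateRecord <- function(id, scores = numeric(), sequence = NA_character_,
                            structurePath = NA_character_) {
  new("CandidateRecord", id = as.character(id), scores = scores,
      sequence = sequence, structurePath = structurePath)
}

setMethod("show", "CandidateRecord", function(object) {
  cat(sprintf("CandidateRecord '%s' [%s]", object@id, object@stage))
  if (length(object@scores))
    cat(": ", paste(sprintf("%s=%.3g", names(object@scores), object@scores),
                    collapse = ", "))
  cat("\n")
  invisible(object)
})

.SCORE_COLS <- c("mean_plddt", "ptm", "motif_rmsd", "binding_energy",
                 "attack_distance", "n_donors", "traj_max_rmsd")

## Evaluate one candidate through the staged screen; returns a one-row
## data.frame plus the terminal stage.
.screenOne <- function(cand, config, exhaustive) {
  sc <- cand@scores
  get <- function(k) if (k %in% names(sc)) sc[[k]] else NA_real_
  row <- as.list(setNames(vapply(.SCORE_COLS, get, 0), .SCORE_COLS))
  reasons <- character()
  stage <- "generated"
  failed <- FALSE

  ## stage 1: static structural quality
  static <- tryCatch(staticQualityFilter(cand, config), error = function(e) e)
  if (inherits(static, "error")) {
    return(c(row, list(pass_static = NA, pass_docking = NA, pass_stability = NA,
                       pathology_clean = NA, stage = "errored",
                       reasons = conditionMessage(static))))
  }
  row$pass_static <- static$pass
  if (static$pass) stage <- "static_pass"
  else { reasons <- c(reasons, static$reasons); failed <- TRUE }

  ## stage 2: docking energy + active-site geometry
  row$pass_docking <- NA
  if (!failed || exhaustive) {
    checks <- logical(0)
    if (!is.na(row$binding_energy))
      checks["energy"] <- energyWindowFilter(row$binding_energy,
                                             config@energyWindow)
    if (!is.na(row$attack_distance))
      checks["attack"] <- row$attack_distance < config@attackDistMax
    if (!is.na(row$n_donors))
      checks["oxyanion"] <- row$n_donors >= config@minOxyanionDonors
    row$pass_docking <- length(checks) == 0L || all(checks)
    bad <- names(checks)[!checks]
    if (!failed) {
      if (row$pass_docking) stage <- "docked_pass"
      else { reasons <- c(reasons, bad); failed <- TRUE }
    }
  }

  ## stage 3: trajectory stability
  row$pass_stability <- NA
  if (!failed || exhaustive) {
    if (!is.na(row$traj_max_rmsd))
      row$pass_stability <- !(row$traj_max_rmsd > config@trajRmsdMax)
    else row$pass_stability <- TRUE
    if (!failed) {
      if (row$pass_stability) stage <- "stable_pass"
      else { reasons <- c(reasons, "stability"); failed <- TRUE }
    }
  }

  ## stage 4: sequence pathology
  row$pathology_clean <- NA
  if (!failed || exhaustive) {
    clean <- TRUE
    if (!is.na(cand@sequence) && nzchar(cand@sequence)) {
      runs <- findPathologies(cand@sequence,
                              hydrophobicSet = config@hydrophobicSet,
                              minRun = config@minRun)
      clean <- nrow(runs) == 0L
    }
    row$pathology_clean <- clean
    if (!failed) {
      stage <- if (clean) "accepted" else "pathology_flagged"
      if (!clean) reasons <- c(reasons, "pathology")
    }
  }

  c(row, list(stage = stage, reasons = paste(reasons, collapse = ";")))
}

#' Run the multi-criteria design screen
#'
#' Applies the staged screen to a candidate set in the fixed published
#' order: static structural quality (pLDDT/pTM/motif RMSD), docking energy
#' and active-site geometry, trajectory stability, then sequence pathology.
#' By default a candidate stops at its first failed stage; with
#' `config@exhaustive = TRUE` later criteria are still evaluated for
#' diagnostics. A candidate whose scores are incomplete for stage 1 is
#' recorded as an errored row; the batch never aborts. Criteria absent from
#' a candidate's scores (e.g. no trajectory) are treated as not assessed and
#' do not fail the candidate.
#'
#' @param candidates list of [CandidateRecord-class].
#' @param config a [ScreenConfig-class].
#' @return a [ScreenReport-class].
#' @export
runScreen <- function(candidates, config = ScreenConfig()) {
  if (length(candidates) == 0L) {
    tab <- data.frame(id = character(), stringsAsFactors = FALSE)
    summ <- setNames(integer(7L), c("input", "static_pass", "docked_pass",
                                    "stable_pass", "pathology_flagged",
                                    "accepted", "errored"))
    return(new("ScreenReport", table = tab, summary = summ, config = config))
  }
  rows <- lapply(candidates, function(cand) {
    out <- .screenOne(cand, config, config@exhaustive)
    cbind(data.frame(id = cand@id, stringsAsFactors = FALSE),
          as.data.frame(out, stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ## stage counts are cumulative: a candidate whose terminal stage is
  ## 'accepted' (or 'pathology_flagged') also passed every earlier gate
  reached <- function(stg) {
    ord <- match(tab$stage, .STAGES)
    sum(ord >= match(stg, .STAGES) & tab$stage != "errored")
  }
  summ <- c(
    input = nrow(tab),
    static_pass = reached("static_pass"),
    docked_pass = reached("docked_pass"),
    stable_pass = reached("stable_pass"),
    pathology_flagged = sum(tab$stage == "pathology_flagged"),
    accepted = sum(tab$stage == "accepted"),
    errored = sum(tab$stage == "errored")
  )
  new("ScreenReport", table = tab,
      summary = setNames(as.integer(summ), names(summ)), config = config)
}

setMethod("show", "ScreenReport", function(object) {
  s <- object@summary
  cat(sprintf("ScreenReport: %d candidates | static %d, docked %d, stable %d, accepted %d",
              s[["input"]], s[["static_pass"]], s[["docked_pass"]],
              s[["stable_pass"]], s[["accepted"]]))
  if (s[["pathology_flagged"]] > 0)
    cat(sprintf(", pathology-flagged %d", s[["pathology_flagged"]]))
  if (s[["errored"]] > 0) cat(sprintf(", errored %d", s[["errored"]]))
  cat("\n")
  invisible(object)
})

#' Size reduction of a design relative to the template
#'
#' Percent reductions in length and molecular weight, rounded half away
#' from zero to integers. A design larger than the template yields a
#' negative (unrounded-sign-preserving) reduction and a warning.
#'
#' @param templateLength,designLength residue counts (either may be NA).
#' @param templateMw,designMw molecular weights, kDa (either may be NA).
#' @return list with `len_reduction_pct`, `mw_reduction_pct` (NA where
#'   inputs are missing).
#' @export
sizeMetrics <- function(templateLength = NA, templateMw = NA,
                        designLength = NA, designMw = NA) {
  reduce <- function(tpl, des, what) {
    if (is.na(tpl) || is.na(des)) return(NA_real_)
    if (tpl <= 0 || des <= 0) stop("sizes must be positive", call. = FALSE)
    raw <- 100 * (tpl - des) / tpl
    if (raw < 0) {
      warning(sprintf("design %s exceeds template; negative reduction %.2f%%",
                      what, raw))
      return(raw)
    }
    as.numeric(.roundHalfAway(raw))
  }
  list(len_reduction_pct = reduce(templateLength, designLength, "length"),
       mw_reduction_pct = reduce(templateMw, designMw, "Mw"))
}

#' Full-chain backbone RMSD between two models
#'
#' Backbone (N, CA, C, O) RMSD after optimal superposition over all shared
#' residues, used to check that fixed-backbone sequence redesign preserved
#' the fold (acceptance gate <= 1.0 A).
#'
#' @param before,after [StructureModel-class] objects with equal residue
#'   counts and ordering.
#' @param atoms backbone atom set.
#' @return RMSD in Angstrom.
#' @export
compareBackbones <- function(before, after, atoms = c("N", "CA", "C", "O")) {
  rb <- residueTable(before); ra <- residueTable(after)
  if (nrow(rb) != nrow(ra))
    stop("topology mismatch: residue counts differ", call. = FALSE)
  A <- .collectCoords(before, rb[, c("chain", "resnum")], atoms)
  B <- .collectCoords(after, ra[, c("chain", "resnum")], atoms)
  kabschSuperpose(A, B)$rmsd
}

#' Rank screened candidates
#'
#' Accepted candidates first; within each group ordered by motif RMSD
#' ascending, then binding energy ascending, then mean pLDDT descending,
#' with a deterministic lexicographic tie-break on id.
#'
#' @param report a [ScreenReport-class].
#' @return character vector of candidate ids.
#' @export
rankCandidates <- function(report) {
  tab <- report@table
  if (nrow(tab) == 0L) return(character())
  accepted <- tab$stage == "accepted"
  num <- function(x) ifelse(is.na(x), Inf, x)
  ord <- order(!accepted, num(tab$motif_rmsd), num(tab$binding_energy),
               -ifelse(is.na(tab$mean_plddt), -Inf, tab$mean_plddt),
               tab$id, method = "radix")
  tab$id[ord]
}

#' Write a screen report as TSV + JSON twin
#'
#' The TSV holds the per-candidate table; the JSON twin adds the stage
#' summary and every threshold of the config for provenance.
#'
#' @param report a [ScreenReport-class].
#' @param prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @return paths, invisibly.
#' @export
writeScreenReport <- function(report, prefix) {
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  utils::write.table(report@table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- lapply(slotNames("ScreenConfig"),
                function(s) slot(report@config, s))
  names(cfg) <- slotNames("ScreenConfig")
  jsonlite::write_json(list(summary = as.list(report@summary), config = cfg,
                            table = report@table),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
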