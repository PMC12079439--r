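test_that("planted-failure batches produce exact stage counts", {
  batch <- makeCandidateBatch(n = 20, nLowPlddt = 5, nHighRmsd = 4,
                              nBadEnergy = 3, nUnstable = 2, seed = 42)
  report <- runScreen(batch)
  s <- report@summary
  expect_equal(s[["input"]], 20L)
  expect_equal(s[["static_pass"]], 11L)   # 20 - 5 low-pLDDT - 4 high-RMSD
  expect_equal(s[["docked_pass"]], 8L)    # - 3 out-of-window energies
  expect_equal(s[["stable_pass"]], 6L)    # - 2 unstable trajectories
  expect_equal(s[["accepted"]], 6L)
  expect_equal(s[["errored"]], 0L)
  ## each planted failure lands at the stage its defect targets
  planted <- vapply(batch, function(c) attr(c, "planted"), "")
  tab <- report@table
  expect_true(all(tab$stage[planted == "low_plddt"] == "generated"))
  expect_true(all(tab$stage[planted == "high_rmsd"] == "generated"))
  expect_true(all(tab$stage[planted == "bad_energy"] == "static_pass"))
  expect_true(all(tab$stage[planted == "unstable"] == "docked_pass"))
  expect_true(all(tab$stage[planted == "pass"] == "accepted"))
})

test_that("summary counts equal column-wise tallies of the table", {
  batch <- makeCandidateBatch(n = 30, nLowPlddt = 6, nHighRmsd = 5,
                              nBadEnergy = 4, nUnstable = 3,
                              nPathological = 2, seed = 7)
  report <- runScreen(batch)
  tab <- report@table
  s <- report@summary
  later <- c("static_pass", "docked_pass", "stable_pass",
             "pathology_flagged", "accepted")
  expect_equal(s[["static_pass"]], sum(tab$stage %in% later))
  expect_equal(s[["docked_pass"]],
               sum(tab$stage %in% later[-1]))
  expect_equal(s[["stable_pass"]],
               sum(tab$stage %in% c("stable_pass", "pathology_flagged",
                                    "accepted")))
  expect_equal(s[["pathology_flagged"]], sum(tab$stage == "pathology_flagged"))
  expect_equal(s[["pathology_flagged"]], 2L)
  expect_equal(s[["accepted"]], sum(tab$stage == "accepted"))
  ## ledger completeness: every candidate exactly once, with a terminal stage
  expect_setequal(tab$id, vapply(batch, function(c) c@id, ""))
  expect_equal(anyDuplicated(tab$id), 0L)
  expect_true(all(tab$stage %in% c("generated", "static_pass", "docked_pass",
                                   "stable_pass", "pathology_flagged",
                                   "accepted", "errored")))
})

test_that("all-pass batches keep every candidate at every stage; empty input is fine", {
  batch <- makeCandidateBatch(n = 12, nLowPlddt = 0, nHighRmsd = 0,
                              nBadEnergy = 0, nUnstable = 0, seed = 3)
  s <- runScreen(batch)@summary
  expect_equal(unname(s[c("input", "static_pass", "docked_pass",
                          "stable_pass", "accepted")]),
               rep(12L, 5))
  empty <- runScreen(list())
  expect_equal(nrow(empty@table), 0L)
  expect_equal(empty@summary[["input"]], 0L)
})

test_that("tightening any threshold never increases acceptances", {
  batch <- makeCandidateBatch(n = 25, nLowPlddt = 4, nHighRmsd = 3,
                              nBadEnergy = 3, nUnstable = 2, seed = 13)
  base <- runScreen(batch)@summary[["accepted"]]
  tighter <- list(
    ScreenConfig(plddtMin = 85),
    ScreenConfig(ptmMin = 0.85),
    ScreenConfig(motifRmsdMax = 1.5),
    ScreenConfig(energyWindow = c(-3, -1)),
    ScreenConfig(attackDistMax = 3.2),
    ScreenConfig(trajRmsdMax = 3)
  )
  for (cfg in tighter)
    expect_lte(runScreen(batch, cfg)@summary[["accepted"]], base)
})

test_that("screening is deterministic and robust to errored candidates", {
  batch <- makeCandidateBatch(n = 15, seed = 5)
  r1 <- runScreen(batch)
  r2 <- runScreen(batch)
  expect_identical(r1@table, r2@table)
  expect_identical(r1@summary, r2@summary)
  ## a candidate without stage-1 scores becomes an errored row, not an abort
  broken <- c(batch, list(CandidateRecord("broken", scores = c(ptm = 0.9))))
  r3 <- runScreen(broken)
  expect_equal(r3@summary[["errored"]], 1L)
  expect_equal(r3@summary[["input"]], 16L)
  expect_match(r3@table$reasons[r3@table$id == "broken"], "incomplete")
})

test_that("exhaustive mode scores later stages even after a failure", {
  cand <- CandidateRecord("x", scores = c(
    mean_plddt = 50, ptm = 0.9, motif_rmsd = 1, binding_energy = -2,
    attack_distance = 3, n_donors = 2, traj_max_rmsd = 2))
  shortCircuit <- runScreen(list(cand))@table
  expect_true(is.na(shortCircuit$pass_docking))
  exhaustive <- runScreen(list(cand), ScreenConfig(exhaustive = TRUE))@table
  expect_true(exhaustive$pass_docking)
  expect_true(exhaustive$pass_stability)
  expect_equal(exhaustive$stage, "generated")  # still fails at stage 1
})

test_that("sizeMetrics rounds percent reductions half away from zero", {
  ## 258 -> 140 residues: 46% shorter
  expect_equal(sizeMetrics(templateLength = 258, designLength = 140
                           )$len_reduction_pct, 46)
  ## 27.78 -> 18.34 kDa: 34% lighter
  expect_equal(sizeMetrics(templateMw = 27.78, designMw = 18.34
                           )$mw_reduction_pct, 34)
  ## identical sizes
  m <- sizeMetrics(100, 20, 100, 20)
  expect_equal(m$len_reduction_pct, 0)
  expect_equal(m$mw_reduction_pct, 0)
  ## a design larger than the template: warned, sign preserved, unrounded
  expect_warning(r <- sizeMetrics(templateLength = 100, designLength = 103),
                 "negative")
  expect_equal(r$len_reduction_pct, -3)
  expect_true(is.na(sizeMetrics(templateLength = 258)$mw_reduction_pct))
})

test_that("compareBackbones matches an all-residue motif RMSD and gates at 1 A", {
  m <- makeToyScaffold(nResidues = 35, seed = 17)
  expect_equal(compareBackbones(m, m), 0, tolerance = 1e-10)
  near <- perturbToRmsd(m, 0.8, seed = 2)
  far <- perturbToRmsd(m, 1.3, seed = 2)
  expect_equal(compareBackbones(m, near), 0.8, tolerance = 1e-3)
  expect_equal(compareBackbones(m, far), 1.3, tolerance = 1e-3)
  expect_true(compareBackbones(m, near) <= 1.0)
  expect_false(compareBackbones(m, far) <= 1.0)
  ## internal consistency with motifRmsd over an all-residue spec
  all_spec <- MotifSpec(data.frame(chain = "A", start = 1, end = 35),
                        data.frame(role = c("nucleophile", "base", "acid"),
                                   chain = "A", resnum = c(10, 12, 14)))
  expect_equal(compareBackbones(m, far), motifRmsd(m, far, all_spec),
               tolerance = 1e-8)
  short <- makeToyScaffold(nResidues = 30, seed = 17)
  expect_error(compareBackbones(m, short), "mismatch")
})

test_that("rankCandidates orders accepted designs by fidelity, energy, confidence", {
  mk <- function(id, rmsd, energy, plddt) {
    c <- CandidateRecord(id, scores = c(mean_plddt = plddt, ptm = 0.9,
                                        motif_rmsd = rmsd,
                                        binding_energy = energy,
                                        attack_distance = 3, n_donors = 2,
                                        traj_max_rmsd = 2))
    c
  }
  r <- runScreen(list(mk("b", 2.0, -2, 80), mk("a", 1.2, -2, 80)))
  expect_equal(rankCandidates(r), c("a", "b"))
  ## full tie -> lexicographic id
  r2 <- runScreen(list(mk("z", 1, -2, 80), mk("y", 1, -2, 80)))
  expect_equal(rankCandidates(r2), c("y", "z"))
  ## failed candidates sort after accepted ones
  r3 <- runScreen(list(mk("fail", 9, -2, 80), mk("ok", 2, -2, 80)))
  expect_equal(rankCandidates(r3), c("ok", "fail"))
  ## 50 random candidates equal a brute-force sort oracle
  set.seed(29)
  cands <- lapply(1:50, function(i)
    mk(sprintf("c%02d", i), runif(1, 0.5, 2.4), runif(1, -3.9, -0.1),
       runif(1, 71, 99)))
  rep <- runScreen(cands)
  tab <- rep@table
  oracle <- tab$id[order(tab$stage != "accepted", tab$motif_rmsd,
                         tab$binding_energy, -tab$mean_plddt, tab$id)]
  expect_equal(rankCandidates(rep), oracle)
})

test_that("screen configs round-trip through YAML and reports through TSV/JSON", {
  cfg <- ScreenConfig(plddtMin = 75, energyWindow = c(-5, -1),
                      exhaustive = TRUE)
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeScreenConfig(cfg, tf)
  back <- readScreenConfig(tf)
  expect_equal(back@plddtMin, 75)
  expect_equal(back@energyWindow, c(-5, -1))
  expect_true(back@exhaustive)
  expect_equal(back@motifRmsdMax, 2.5)
  report <- runScreen(makeCandidateBatch(n = 8, nLowPlddt = 2, nHighRmsd = 1,
                                         nBadEnergy = 1, nUnstable = 0,
                                         seed = 2))
  prefix <- file.path(withr::local_tempdir(), "report")
  writeScreenReport(report, prefix)
  tsv <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(nrow(tsv), 8L)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$summary$input, 8L)
  expect_equal(js$config$motifRmsdMax, 2.5)
})
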