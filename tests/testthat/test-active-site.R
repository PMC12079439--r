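test_that("attackDistance measures the Ser OG to carbonyl-carbon minimum", {
  m <- makeToyScaffold(nResidues = 30, seed = 1)
  triad <- attr(m, "triad")
  pose <- makePoseAtDistance(m, triad, 3.0, seed = 2)
  expect_equal(attackDistance(m, triad, pose), 3.0, tolerance = 1e-6)
  ## exactly 4.0 A fails the strict "< 4" criterion; built with the Ser OG
  ## at the origin so the distance is exactly representable
  atoms <- rbind(
    toyAtoms("CA", "C", cbind(-1.4, 0, 0), resnum = 1, resname = "SER"),
    toyAtoms("OG", "O", cbind(0, 0, 0), resnum = 1, resname = "SER"))
  tiny <- StructureModel(atoms)
  tinyTriad <- TriadAssignment(serResnum = 1, hisResnum = 2, aspResnum = 3)
  poseAt <- function(d) LigandPose(
    data.frame(label = c("C1", "O1", "O2", "C2"),
               element = c("C", "O", "O", "C"),
               x = c(d, d, d + 1.1, d + 2.4), y = c(0, 1.23, -0.76, -0.9),
               z = 0),
    esterGroups = data.frame(carbonylC = 1, carbonylO = 2, esterO = 3))
  cfg <- ScreenConfig()
  expect_false(attackDistance(tiny, tinyTriad, poseAt(4.0)) < cfg@attackDistMax)
  expect_true(attackDistance(tiny, tinyTriad, poseAt(3.99)) < cfg@attackDistMax)
  ## the generated fixture hits the advertised distance
  pose4 <- makePoseAtDistance(m, triad, 4.0, seed = 3)
  expect_equal(attackDistance(m, triad, pose4), 4.0, tolerance = 1e-6)
})

test_that("attackDistance minimizes over all ester groups", {
  m <- makeToyScaffold(nResidues = 30, seed = 5)
  triad <- attr(m, "triad")
  og <- atomCoords(m, "A", 10, atoms = "OG")[1, ]
  ## hand-built pose with three ester groups at 6.1 / 3.4 / 5.0 A
  mkGroup <- function(d, dir) {
    c1 <- og + d * dir
    rbind(c1, c1 + c(0, 0, 1.23), c1 + c(0, 1.34, 0))
  }
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0.6, 0.8, 0))
  ds <- c(6.1, 3.4, 5.0)
  xyz <- do.call(rbind, Map(mkGroup, ds, dirs))
  atoms <- data.frame(label = paste0("X", 1:9),
                      element = rep(c("C", "O", "O"), 3),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  pose <- LigandPose(atoms, esterGroups = data.frame(
    carbonylC = c(1, 4, 7), carbonylO = c(2, 5, 8), esterO = c(3, 6, 9)))
  ## brute-force oracle: min over all annotated carbonyl carbons
  oracle <- min(vapply(c(1, 4, 7), function(i)
    sqrt(sum((as.numeric(atoms[i, c("x", "y", "z")]) - og)^2)), 0))
  expect_equal(attackDistance(m, triad, pose), oracle, tolerance = 1e-9)
  expect_equal(oracle, 3.4, tolerance = 1e-9)
  ## no ester groups -> error
  empty <- new("LigandPose", atoms = atoms,
               esterGroups = data.frame(carbonylC = integer(),
                                        carbonylO = integer(),
                                        esterO = integer()),
               bindingEnergy = NA_real_)
  expect_error(attackDistance(m, triad, empty), "ester")
})

test_that("oxyanion donors are backbone N within the cutoff, sorted by distance", {
  ## bespoke model: carbonyl O at origin, backbone N at prescribed radii
  mkModel <- function(dists, resnames = NULL) {
    n <- length(dists)
    if (is.null(resnames)) resnames <- rep("ALA", n)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      ang <- 2 * pi * i / n
      rbind(toyAtoms("N", "N", cbind(dists[i] * cos(ang),
                                     dists[i] * sin(ang), 0),
                     resnum = i, resname = resnames[i]),
            toyAtoms("CA", "C", cbind((dists[i] + 1.5) * cos(ang),
                                      (dists[i] + 1.5) * sin(ang), 0),
                     resnum = i, resname = resnames[i]))
    }))
    StructureModel(atoms)
  }
  poseAtoms <- data.frame(label = c("C1", "O1", "O2", "C2"),
                          element = c("C", "O", "O", "C"),
                          x = c(1.3, 0, 2.2, 3.3), y = c(0, 0, 1, 1.5),
                          z = c(0, 0, 0, 0))
  pose <- LigandPose(poseAtoms)  # carbonyl O is atom 2, at the origin
  expect_equal(pose@esterGroups$carbonylO, 2L)

  two <- findOxyanionDonors(mkModel(c(2.9, 2.9, 6)), pose)
  expect_true(two$pass)
  expect_equal(nrow(two$donors), 2L)
  expect_equal(two$donors$distance, c(2.9, 2.9), tolerance = 1e-6)

  none <- findOxyanionDonors(mkModel(c(3.6, 4.0)), pose)
  expect_false(none$pass)
  expect_equal(nrow(none$donors), 0L)

  ## five candidate N at mixed distances match an exhaustive scan
  dists <- c(2.5, 3.1, 3.49, 3.51, 5.0)
  got <- findOxyanionDonors(mkModel(dists), pose)
  expect_equal(got$donors$distance, sort(dists[dists <= 3.5]), tolerance = 1e-6)
  ## prolines are excluded: their backbone N has no amide H
  gotP <- findOxyanionDonors(mkModel(c(2.5, 2.6), c("PRO", "ALA")), pose)
  expect_equal(nrow(gotP$donors), 1L)
  expect_false(gotP$pass)
  expect_error(findOxyanionDonors(mkModel(c(2.9)), pose, groupIndex = 9L),
               "invalid")
})

test_that("triadGeometry reproduces planted distances and flags broken H-bonds", {
  m <- makeToyScaffold(nResidues = 30, triadTargets = c(3.0, 2.8), seed = 6)
  g <- triadGeometry(m, attr(m, "triad"))
  expect_equal(g$ser_og_his_ne2, 3.0, tolerance = 1e-6)
  expect_equal(g$his_nd1_asp_o, 2.8, tolerance = 1e-6)
  expect_true(all(g$hbonded))
  ## Asp rotated away: distance above the 3.5 A H-bond cutoff
  far <- makeToyScaffold(nResidues = 30, triadTargets = c(3.0, 5.5), seed = 6)
  gf <- triadGeometry(far, attr(far, "triad"))
  expect_equal(gf$his_nd1_asp_o, 5.5, tolerance = 1e-6)
  expect_false(gf$hbonded[["his_asp"]])
  ## random toy triads agree with direct coordinate arithmetic
  for (seed in 1:20) {
    t1 <- runif(1, 2.5, 3.4); t2 <- runif(1, 2.5, 3.4)
    mm <- makeToyScaffold(nResidues = 25, triadTargets = c(t1, t2), seed = seed)
    tri <- attr(mm, "triad")
    gg <- triadGeometry(mm, tri)
    og <- atomCoords(mm, "A", tri@ser$resnum, atoms = "OG")[1, ]
    ne2 <- atomCoords(mm, "A", tri@his$resnum, atoms = "NE2")[1, ]
    nd1 <- atomCoords(mm, "A", tri@his$resnum, atoms = "ND1")[1, ]
    od <- atomCoords(mm, "A", tri@asp$resnum, atoms = c("OD1", "OD2"))
    expect_equal(gg$ser_og_his_ne2, sqrt(sum((og - ne2)^2)), tolerance = 1e-10)
    expect_equal(gg$his_nd1_asp_o,
                 min(sqrt(sum((nd1 - od[1, ])^2)), sqrt(sum((nd1 - od[2, ])^2))),
                 tolerance = 1e-10)
  }
  ## a missing atom is named
  noOG <- m
  noOG@atoms <- noOG@atoms[noOG@atoms$name != "OG", ]
  expect_error(triadGeometry(noOG, attr(m, "triad")), "OG")
})

test_that("the docking-energy window is inclusive at both ends", {
  expect_true(energyWindowFilter(-2.78))   # the template's computed energy
  expect_false(energyWindowFilter(-4.5))
  expect_false(energyWindowFilter(0.5))
  expect_true(energyWindowFilter(-4))
  expect_true(energyWindowFilter(0))
  expect_error(energyWindowFilter(-1, c(0, -4)), "low")
})

test_that("active-site distances are invariant under joint rigid motions", {
  m <- makeToyScaffold(nResidues = 30, seed = 9)
  triad <- attr(m, "triad")
  pose <- makePoseAtDistance(m, triad, 3.2, seed = 10)
  a0 <- auditActiveSite(m, triad, pose)
  set.seed(77)
  R <- randomRotation(); tr <- rnorm(3, sd = 20)
  m2 <- ScaffoldScreen:::.transformModel(m, R, tr)
  p2 <- pose
  xyz <- as.matrix(pose@atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, tr, "+")
  p2@atoms$x <- xyz[, 1]; p2@atoms$y <- xyz[, 2]; p2@atoms$z <- xyz[, 3]
  a1 <- auditActiveSite(m2, triad, p2)
  expect_equal(a1$attack_distance, a0$attack_distance, tolerance = 1e-8)
  expect_equal(a1$triad$ser_og_his_ne2, a0$triad$ser_og_his_ne2, tolerance = 1e-8)
  expect_equal(nrow(a1$donors), nrow(a0$donors))
})

test_that("pose tables parse, sort by energy, and auto-annotate esters", {
  m <- makeToyScaffold(nResidues = 30, seed = 11)
  triad <- attr(m, "triad")
  dir <- withr::local_tempdir()
  energies <- c(-0.5, -3.1, -2.0)
  for (i in 1:3) {
    pose <- makePoseAtDistance(m, triad, 3 + 0.2 * i, seed = 20 + i)
    la <- pose@atoms
    lig <- StructureModel(data.frame(name = la$label, element = la$element,
                                     x = la$x, y = la$y, z = la$z,
                                     bfactor = 0, chain = "A", resnum = 1,
                                     resname = "LIG", het = TRUE))
    writeStructure(lig, file.path(dir, sprintf("pose%d.pdb", i)))
  }
  tab <- data.frame(pose_id = paste0("p", 1:3), energy_kcal_mol = energies,
                    ligand_pdb_path = sprintf("pose%d.pdb", 1:3))
  tabPath <- file.path(dir, "poses.tsv")
  write.table(tab, tabPath, sep = "\t", quote = FALSE, row.names = FALSE)
  poses <- parsePoseTable(tabPath)
  expect_length(poses, 3)
  expect_equal(names(poses), c("p2", "p3", "p1"))  # energy ascending
  expect_equal(vapply(poses, function(p) p@bindingEnergy, 0),
               sort(energies), ignore_attr = TRUE)
  expect_true(all(vapply(poses, function(p) nrow(p@esterGroups), 0L) == 1L))
  ## ester indices match a hand annotation of the 6-atom fragment:
  ## C1 (carbonyl C) - O1 (carbonyl O) - O2 (ester O, bridging to C2)
  p <- poses[[1]]
  lab <- p@atoms$label
  expect_equal(lab[p@esterGroups$carbonylC], "C1")
  expect_equal(lab[p@esterGroups$carbonylO], "O1")
  expect_equal(lab[p@esterGroups$esterO], "O2")
})

test_that("a carbonyl-free ligand yields an empty annotation with a warning", {
  atoms <- data.frame(label = c("C1", "C2", "C3"), element = "C",
                      x = c(0, 1.5, 3), y = 0, z = 0)
  expect_warning(pose <- LigandPose(atoms), "no ester")
  expect_equal(nrow(pose@esterGroups), 0L)
  m <- makeToyScaffold(nResidues = 30, seed = 12)
  expect_error(attackDistance(m, attr(m, "triad"), pose), "ester")
})

test_that("adding an ester group never increases the attack distance", {
  m <- makeToyScaffold(nResidues = 30, seed = 13)
  triad <- attr(m, "triad")
  og <- atomCoords(m, "A", 10, atoms = "OG")[1, ]
  mkAtoms <- function(d, off) {
    c1 <- og + d * c(1, 0, 0) + off
    data.frame(label = c("C", "O", "O"), element = c("C", "O", "O"),
               x = c(c1[1], c1[1], c1[1]), y = c(c1[2], c1[2], c1[2] + 1.34),
               z = c(c1[3], c1[3] + 1.23, c1[3]))
  }
  a1 <- mkAtoms(5.0, c(0, 0, 0))
  a2 <- mkAtoms(3.1, c(0, 0, 4))
  poseOne <- LigandPose(a1, esterGroups = data.frame(carbonylC = 1,
                                                     carbonylO = 2, esterO = 3))
  poseTwo <- LigandPose(rbind(a1, a2),
                        esterGroups = data.frame(carbonylC = c(1, 4),
                                                 carbonylO = c(2, 5),
                                                 esterO = c(3, 6)))
  expect_lte(attackDistance(m, triad, poseTwo),
             attackDistance(m, triad, poseOne))
})
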