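## Independent oracles used across the suite. None of these call the
## package's own superposition/scan/cluster code paths.

## Random proper rotation via QR decomposition of a Gaussian matrix.
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.eulerRot <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## Numeric-minimization superposition oracle: minimizes RMSD over Euler
## angles + translation with several starts; independent of the SVD path.
oracleSuperposeRmsd <- function(A, B, nStarts = 6L) {
  A <- as.matrix(A); B <- as.matrix(B)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  f <- function(par) {
    R <- .eulerRot(par[1], par[2], par[3])
    moved <- sweep(Bc %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((Ac - moved)^2)))
  }
  best <- Inf
  starts <- c(list(rep(0, 6)),
              lapply(seq_len(nStarts - 1L), function(i)
                c(runif(3, -pi, pi), rnorm(3, 0, 0.5))))
  for (p0 in starts) {
    o <- optim(p0, f, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
    o <- optim(o$par, f, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
    best <- min(best, o$value)
  }
  best
}

## Exhaustive O(n^2) maximal-run scan. pred maps a letter to TRUE/FALSE.
bruteForceRuns <- function(letters, pred, minRun) {
  n <- length(letters)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (pred(letters[i])) {
      j <- i
      while (j < n && pred(letters[j + 1L])) j <- j + 1L
      if (j - i + 1L >= minRun)
        out[[length(out) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, out)
}

## Connected components of the "distance <= h" graph == single-linkage
## clusters cut at h.
bruteForceSingleLinkage <- function(coords, h) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(d[v, ] <= h & comp == 0L))
    }
  }
  comp
}

## Accessible area of two overlapping equal spheres of radius R at centre
## distance d: each loses a cap of height R - d/2.
twoSphereArea <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

## Plain RMSD between two coordinate sets (no superposition).
plainRmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

## Small helpers to build bespoke structures in tests.
toyAtoms <- function(name, element, xyz, chain = "A", resnum = 1L,
                     resname = "GLY", bfactor = 0) {
  data.frame(name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             bfactor = bfactor, chain = chain, resnum = resnum,
             resname = resname, stringsAsFactors = FALSE)
}

lccLikeMotifSpec <- function() {
  MotifSpec(
    segments = data.frame(chain = "A", start = c(150, 205, 239),
                          end = c(175, 215, 245)),
    catalytic = data.frame(role = c("nucleophile", "base", "acid"),
                           chain = "A", resnum = c(165, 210, 242))
  )
}
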