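## Shared fixtures (built once per test run) and independent oracles.

vlen <- function(v) sqrt(sum(v * v))

## Lazily built standard models; the cache lives for the whole run.
g4Fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    m <- switch(name,
      left1b = buildG4(g4BuildSpec(n_tetrads = 2, blocks = 2,
                                   twist = -27)),
      left2b = buildG4(g4BuildSpec()),
      left_bulged = buildG4(g4BuildSpec(n_tetrads = 2, blocks = 2,
                                        twist = -27,
                                        bulges = list(c(2, 1)))),
      right = buildG4(g4BuildSpec(n_tetrads = 3, blocks = 3,
                                  twist = 30)),
      left2b_2bulge = buildG4(g4BuildSpec(bulges = list(c(2, 3),
                                                        c(3, 3)))),
      left2b_3bulge = buildG4(g4BuildSpec(bulges = list(c(2, 3), c(3, 3),
                                                        c(4, 3)))),
      stop("unknown fixture ", name))
    assign(name, m, envir = cache)
    m
  }
})

## cached annotation of a fixture
g4Annotation <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    a <- annotateG4(g4Fixture(name))
    assign(name, a, envir = cache)
    a
  }
})

## ------------------------------------------------------------------
## Independent oracles

## dihedral via projection onto the plane perpendicular to the central
## bond (no cross-product atan2 path shared with the implementation)
oracleDihedral <- function(p1, p2, p3, p4) {
  b <- (p3 - p2) / vlen(p3 - p2)
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  u <- u / vlen(u); v <- v / vlen(v)
  ang <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  s <- det(cbind(u, v, b))
  if (s < 0) ang <- -ang
  ang %% 360
}

## quaternion-eigenvalue RMSD (Horn closed form)
oracleRmsd <- function(A, B) {
  ca <- sweep(A, 2, colMeans(A)); cb <- sweep(B, 2, colMeans(B))
  M <- t(cb) %*% ca
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ca^2) + sum(cb^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

## resultant-vector circular mean (independent formulation via complex sum)
oracleCircMean <- function(theta) {
  z <- sum(exp(1i * theta * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

## von Mises sampler (Best & Fisher rejection method)
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f) * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

## random proper rotation (deterministic under the caller's seed)
randomRotation <- function() {
  q <- rnorm(4); q <- q / vlen(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y+w*z),   2*(x*z-w*y),
           2*(x*y-w*z),   1-2*(x^2+z^2), 2*(y*z+w*x),
           2*(x*z+w*y),   2*(y*z-w*x),   1-2*(x^2+y^2)), 3, 3)
}

## apply a rigid motion to a model
rigidMove <- function(model, R = NULL, t = c(5, -3, 2)) {
  a <- atomTable(model)
  xyz <- cbind(a$x, a$y, a$z)
  if (!is.null(R)) xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, -t)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  StructureModel(a, modelIndex(model), sourceId(model))
}

## a deliberately non-quadruplex arrangement: the four tetrad guanines
## pulled 10+ Angstrom apart
spreadGuanines <- function() {
  m <- buildTetrad(g4BuildSpec())
  a <- atomTable(m)
  for (i in 1:4) {
    sel <- a$resno == i
    a$x[sel] <- a$x[sel] + 15 * i
  }
  StructureModel(a, sourceId = "spread")
}

## minimal hand-written two-model PDB fixture
writeTwoModelPdb <- function(path) {
  lines <- c("MODEL        1",
    "ATOM      1  P    DG A   1       1.000   2.000   3.000  1.00 10.00           P",
    "ATOM      2  C1'  DG A   1       2.000   2.500   3.100  1.00 10.00           C",
    "ATOM      3  N9   DG A   1       3.000   2.600   3.200  1.00 10.00           N",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  P    DG A   1       1.100   2.100   3.100  1.00 10.00           P",
    "ATOM      2  C1'  DG A   1       2.100   2.600   3.200  1.00 10.00           C",
    "ATOM      3  N9   DG A   1       3.100   2.700   3.300  1.00 10.00           N",
    "ENDMDL", "END")
  writeLines(lines, path)
  path
}
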