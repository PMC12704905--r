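## Concentric four-sphere (brain / CSF / skull / scalp) quasi-static forward
## solution for a current dipole inside the innermost sphere.
##
## Per spherical-harmonic degree n the radial part in shell s is
## A_s r^n + B_s r^-(n+1); in the innermost shell the singular part is the
## known infinite-medium dipole expansion. The seven remaining coefficients
## (B_1 regular at the origin is absent, i.e. A1, A2, B2, A3, B3, A4, B4)
## follow from potential and radial-current continuity at the three
## interfaces plus a zero-current condition at the scalp surface. Radii are
## scaled by the outer radius for numerical balance.

## Coefficients for one degree n, unit source strength (S = 1, i.e. a term
## r~^-(n+1) in shell 1). Per-shell scaled basis keeps every matrix entry
## O(n) regardless of degree: in shell s spanning [Rin_s, Rout_s] the basis
## is u = (r~/Rout_s)^n and w = (Rin_s/r~)^(n+1) (no w in shell 1), so the
## solve stays well conditioned at high orders. Returns the 7-vector
## (a1, a2, b2, a3, b3, a4, b4).
.fs_coeffs <- function(n, rt, sig) {
  Rout <- c(rt, 1)                 # outer scaled radius per shell
  Rin <- c(0, rt)                  # inner scaled radius per shell
  M <- matrix(0, 7, 7)
  rhs <- numeric(7)
  aidx <- c(1L, 2L, 4L, 6L); bidx <- c(NA, 3L, 5L, 7L)
  for (j in 1:3) {
    t <- rt[j]
    rowc <- 2L * j - 1L; rowf <- 2L * j
    wj <- (Rin[j] / Rout[j])^(n + 1)       # w_j at its outer edge
    uj1 <- (Rout[j] / Rout[j + 1L])^n      # u_{j+1} at its inner edge
    ## continuity of potential at t
    M[rowc, aidx[j]] <- 1
    if (!is.na(bidx[j])) M[rowc, bidx[j]] <- wj
    M[rowc, aidx[j + 1L]] <- -uj1
    M[rowc, bidx[j + 1L]] <- -1
    ## continuity of sigma * r * dPhi/dr at t
    M[rowf, aidx[j]] <- sig[j] * n
    if (!is.na(bidx[j])) M[rowf, bidx[j]] <- -sig[j] * (n + 1) * wj
    M[rowf, aidx[j + 1L]] <- -sig[j + 1L] * n * uj1
    M[rowf, bidx[j + 1L]] <- sig[j + 1L] * (n + 1)
    if (j == 1L) {
      src <- t^(-(n + 1))                  # bounded: t < 1 but b~ < t scales S
      rhs[rowc] <- -src
      rhs[rowf] <- sig[1L] * (n + 1) * src
    }
  }
  ## insulating outside: dPhi/dr = 0 at the scalp surface (r~ = 1)
  M[7, 6] <- n
  M[7, 7] <- -(n + 1) * Rin[4]^(n + 1)
  solve(M, rhs)
}

## evaluate the degree-n unit-source radial function at scaled radius rto
## (vector); callers scale by the actual source strength
.fs_eval <- function(n, co, rt, rto) {
  Rout <- c(rt, 1)
  Rin <- c(0, rt)
  shell <- pmin(findInterval(rto, rt) + 1L, 4L)   # rto <= rt[1] -> shell 1
  a <- c(co[1], co[2], co[4], co[6])[shell]
  b <- c(0, co[3], co[5], co[7])[shell]
  val <- a * (rto / Rout[shell])^n +
    b * ifelse(shell == 1L, 0, (Rin[shell] / rto)^(n + 1))
  s1 <- shell == 1L
  val[s1] <- val[s1] + rto[s1]^(-(n + 1))
  val
}

## core: potential (mV) at obs points (rows, mm) from one complex dipole
## 3-vector (nA um) at position rdip (mm)
.fs_potential <- function(p, rdip, radii, sigmas, obs, order) {
  r4 <- radii[4]
  rt <- radii[1:3] / r4
  b <- sqrt(sum(rdip^2)) / r4
  if (b >= rt[1]) stop("dipole must lie strictly inside the brain sphere")
  if (is.vector(obs)) obs <- matrix(obs, ncol = 3L)
  robs <- sqrt(rowSums(obs^2)) / r4
  if (any(robs > 1 + 1e-9)) stop("observation point outside the scalp")
  robs <- pmin(robs, 1)

  ## local frame
  if (b < 1e-12) {
    ## central dipole: superpose three axis-aligned radial configurations
    tot <- rep(0 + 0i, nrow(obs))
    for (k in 1:3) {
      if (p[k] == 0) next
      zhat <- c(0, 0, 0); zhat[k] <- 1
      costh <- (obs %*% zhat) / pmax(robs * r4, 1e-300)
      costh <- pmin(pmax(as.numeric(costh), -1), 1)
      co <- .fs_coeffs(1L, rt, sigmas)        # S = n b^(n-1) = 1 at n = 1
      f <- .fs_eval(1L, co, rt, robs)
      Pl <- costh
      tot <- tot + p[k] * f * Pl
    }
    return(tot * 1e-6 / (4 * pi * sigmas[1] * r4^2))
  }

  zhat <- rdip / (b * r4)
  ## orthonormal tangential axes
  seed <- if (abs(zhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  xhat <- seed - sum(seed * zhat) * zhat
  xhat <- xhat / sqrt(sum(xhat^2))
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  pr <- sum(p * zhat)          # complex radial component
  ptx <- sum(p * xhat)
  pty <- sum(p * yhat)

  oz <- as.numeric(obs %*% zhat) / r4
  ox <- as.numeric(obs %*% xhat) / r4
  oy <- as.numeric(obs %*% yhat) / r4
  costh <- pmin(pmax(oz / pmax(robs, 1e-300), -1), 1)
  rho <- sqrt(pmax(robs^2 - oz^2, 0))
  cosphi <- ifelse(rho > 1e-300, ox / (rho + (rho <= 1e-300)), 0)
  sinphi <- ifelse(rho > 1e-300, oy / (rho + (rho <= 1e-300)), 0)

  tot <- rep(0 + 0i, nrow(obs))
  needTan <- (Mod(ptx) + Mod(pty)) > 0
  Pn <- .legendre_table(order, costh, needTan)
  for (n in seq_len(order)) {
    Srad <- n * b^(n - 1)
    Stan <- b^(n - 1)
    co <- .fs_coeffs(n, rt, sigmas)      # linear in S: solve once for S = 1
    fr <- .fs_eval(n, co, rt, robs)
    if (pr != 0)
      tot <- tot + pr * Srad * fr * Pn$P[, n]
    if (needTan) {
      tanAmp <- ptx * cosphi + pty * sinphi
      tot <- tot - tanAmp * Stan * fr * Pn$P1[, n]
    }
  }
  tot * 1e-6 / (4 * pi * sigmas[1] * r4^2)
}

## P_n(costh) and P_n^1(costh) for n = 1..order (Condon-Shortley phase),
## columns indexed by n
.legendre_table <- function(order, x, withP1) {
  np <- length(x)
  P <- matrix(0, np, order)
  P1 <- if (withP1) matrix(0, np, order) else NULL
  Pm1 <- rep(1, np); P0 <- x
  P[, 1] <- x
  if (withP1) {
    s <- -sqrt(pmax(1 - x^2, 0))      # P_1^1 with CS phase
    Q0 <- s; Qm1 <- rep(0, np)
    P1[, 1] <- Q0
  }
  for (n in 2:max(2, order)) {
    if (n > order) break
    Pn <- ((2 * n - 1) * x * P0 - (n - 1) * Pm1) / n
    P[, n] <- Pn
    Pm1 <- P0; P0 <- Pn
    if (withP1) {
      Qn <- ((2 * n - 1) * x * Q0 - n * Qm1) / (n - 1)
      P1[, n] <- Qn
      Qm1 <- Q0; Q0 <- Qn
    }
  }
  list(P = P, P1 = P1)
}

#' Scalp potential of a dipole in a four-sphere head model
#'
#' Quasi-static series solution for a current dipole inside the innermost
#' sphere of a concentric four-shell (brain / CSF / skull / scalp) volume
#' conductor with an insulating exterior; a download-free head model used as
#' a physically consistent stand-in for detailed lead fields.
#'
#' @param p a [DipoleMoment-class], or a (possibly complex) 3-vector in
#'   nA um.
#' @param dipolePos dipole position, mm from the centre (strictly inside the
#'   brain sphere).
#' @param obs observation points (rows) on or inside the scalp, mm.
#' @param model a four-sphere [VolumeConductor-class] (see
#'   [fourSphereModel()]).
#' @param order truncation order of the Legendre series.
#' @return potential in mV: a vector (3-vector `p`) or an observation x
#'   frequency matrix ([DipoleMoment-class] input).
#' @export
fourSphereVe <- function(p, dipolePos, obs, model = fourSphereModel(),
                         order = 100L) {
  stopifnot(is(model, "VolumeConductor"), model@kind == "four_sphere")
  if (is(p, "DipoleMoment")) {
    if (is.vector(obs)) obs <- matrix(obs, ncol = 3L)
    out <- sapply(seq_along(p@frequencies), function(k)
      .fs_potential(p@p[, k], dipolePos, model@radii, model@sigmas, obs, order))
    return(matrix(out, nrow = nrow(obs)))
  }
  .fs_potential(as.complex(p), dipolePos, model@radii, model@sigmas, obs, order)
}
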