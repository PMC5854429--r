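#' Bead-on-spool nucleosome mimic specification
#'
#' A coarse stand-in for the nucleosome with two DNA arms, each a chain of
#' beads wrapped around a cylindrical core.  Selected bonds carry discrete
#' binding sites (the toy analog of the distinct histone-DNA binding
#' domains): a bond is "bound" while its bond vector stays within a capture
#' radius of its wrapped reference orientation, and releasing a site costs a
#' configurable energy.  The two arms are mirror images (pseudo-symmetric
#' construction), and the scalar reaction coordinate is the distance between
#' the two terminal beads (the end-to-end distance analog).
#'
#' Every potential term acts on one bond vector at a time, so the unbiased
#' Boltzmann ensemble factorizes exactly over bonds and the free energy of
#' every site-occupancy state is exactly computable by quadrature plus
#' enumeration ([spool_occupancy_profile()]) — the mimic is a
#' parameter-recovery benchmark with a known answer.  A site bond has two
#' states: \emph{bound}, trapped softly at its wrapped reference bond
#' vector with energy \eqn{-\epsilon_m}, and \emph{released}, a longer bond
#' that straightens along the arm's exit axis under a tension field (the
#' toy analog of a stiff DNA tangent extending when a histone contact
#' breaks).  Releasing a site therefore lengthens the end-to-end distance
#' by several Angstrom, which is what lets a bias along d drive unwrapping
#' exactly as in the full system.  Non-site bonds sit in isotropic traps at
#' their wrapped orientations, so the rest of the arm carries the wrapped
#' geometry along rigidly.
#'
#' @param n_beads Beads per arm.
#' @param sites Bond indices (1 = innermost bond, counted from the core
#'   anchor) carrying binding sites; default every second bond from 3.
#' @param epsilon Site binding energies, kcal/mol: scalar, per-site vector
#'   (recycled to both arms), or a \code{length(sites) x 2} matrix for
#'   per-arm values.
#' @param bond_length Bond rest length \eqn{b_0} of the wrapped state, A
#'   (the chord between consecutive reference beads).
#' @param bond_k Stiffness of the isotropic trap holding non-site bonds at
#'   their wrapped reference orientations, kcal/mol/A^2.
#' @param bound_k Stiffness of the (soft) bound-state trap of a site bond
#'   around its reference bond vector, kcal/mol/A^2.
#' @param free_length Rest length of a released site bond, A (longer than
#'   the wrapped chord: the released segment straightens and extends).
#' @param free_k Radial stiffness of a released site bond, kcal/mol/A^2.
#' @param capture \code{c(r_in, r_out)}: the smooth capture switch on the
#'   displacement u of a site bond vector from its reference is 1 below
#'   \code{r_in} and 0 above \code{r_out} (A); "bound" means u below the
#'   midpoint \code{r_mid}.
#' @param core_radius Radius of the wrapped reference circle, A.
#' @param z_offset Out-of-plane offset of each arm (+/-), A, giving the
#'   two wraps of the spool distinct planes.
#' @param phi0 Angle of the core attachment points, degrees.
#' @param tension Alignment energy h of a released site bond, kcal/mol: it
#'   pays \eqn{h (1 - (b \cdot \hat e)/b_f)} for bending away from its
#'   arm's exit axis — the straightening of a released stiff DNA tangent,
#'   zero in the fully extended aligned state.  Being a per-bond term it
#'   preserves the exact bond factorization of the ensemble.
#' @param pinned_arm Optional arm index (1 or 2) whose beads are frozen at
#'   the reference (used for the one-end-unwrapping asymmetry checks).
#' @param mass Mass per degree of freedom (internal units).
#' @return An object of class \code{spool_spec}.
#' @export
spool_spec <- function(n_beads = 10L, sites = seq(3L, n_beads, by = 2L),
                       epsilon = 1.0, bond_length = 4.0, bond_k = 10.0,
                       bound_k = 0.2, free_length = 7.0, free_k = 4.0,
                       capture = c(3.0, 6.0), core_radius = 10.0,
                       z_offset = 1.5, phi0 = 90, tension = 3.0,
                       pinned_arm = NULL, mass = 1) {
  n_beads <- as.integer(n_beads)
  sites <- as.integer(sites)
  stopifnot(n_beads >= 2L, all(sites >= 2L), all(sites <= n_beads),
            !anyDuplicated(sites), length(capture) == 2L,
            capture[1] < capture[2], bond_k > 0, bond_length > 0,
            2 * core_radius > bond_length)
  M <- length(sites)
  eps <- if (is.matrix(epsilon)) {
    stopifnot(nrow(epsilon) == M, ncol(epsilon) == 2L)
    epsilon
  } else {
    matrix(rep_len(epsilon, M), nrow = M, ncol = 2L)
  }
  structure(list(n_beads = n_beads, sites = sites, epsilon = eps,
                 bond_length = bond_length, bond_k = bond_k,
                 bound_k = bound_k, free_length = free_length,
                 free_k = free_k, capture = capture, r_mid = mean(capture),
                 core_radius = core_radius, z_offset = z_offset,
                 phi0 = phi0, tension = tension, pinned_arm = pinned_arm,
                 mass = mass),
            class = "spool_spec")
}

#' @export
print.spool_spec <- function(x, ...) {
  cat("<spool_spec> 2 arms x", x$n_beads, "beads,", length(x$sites),
      "sites/arm at bonds", paste(x$sites, collapse = ","),
      "; eps =", paste(unique(as.vector(x$epsilon)), collapse = "/"),
      "kcal/mol\n")
  invisible(x)
}

# Smooth capture switch: 1 below r_in, 0 above r_out, cubic shoulder between.
.switch_S <- function(u, r_in, r_out) {
  t <- pmin(pmax((u - r_in) / (r_out - r_in), 0), 1)
  1 - 3 * t^2 + 2 * t^3
}
.switch_dS <- function(u, r_in, r_out) {
  t <- (u - r_in) / (r_out - r_in)
  ds <- numeric(length(u))
  ins <- t > 0 & t < 1
  ds[ins] <- (-6 * t[ins] + 6 * t[ins]^2) / (r_out - r_in)
  ds
}

#' Reference (fully wrapped) geometry of the spool mimic
#'
#' Beads of each arm sit on a circle of the core radius at equal angular
#' increments (chord = bond rest length), arm 1 at +z offset and arm 2 its
#' mirror image through y -> -y, z -> -z.
#'
#' @param spec A [spool_spec()].
#' @return A list with \code{arm1}, \code{arm2} (n_beads x 3 matrices,
#'   innermost bead first), \code{anchor1}, \code{anchor2} (fixed core
#'   attachment points), \code{bond_ref1}, \code{bond_ref2} (3 x n_beads
#'   reference bond vectors) and \code{core_center}.
#' @export
spool_reference <- function(spec) {
  stopifnot(inherits(spec, "spool_spec"))
  R <- spec$core_radius
  dphi <- 2 * asin(spec$bond_length / (2 * R))
  phi0 <- spec$phi0 * pi / 180
  ang1 <- phi0 + (0:spec$n_beads) * dphi      # element 1 = anchor
  a1 <- cbind(R * cos(ang1), R * sin(ang1), spec$z_offset)
  a2 <- a1
  a2[, 2] <- -a2[, 2]
  a2[, 3] <- -a2[, 3]
  arm1 <- a1[-1L, , drop = FALSE]
  arm2 <- a2[-1L, , drop = FALSE]
  # exit axis along the wrapped end-to-end vector: released segments
  # straighten in the direction that extends d
  axis <- arm1[nrow(arm1), ] - arm2[nrow(arm2), ]
  axis <- axis / sqrt(sum(axis^2))
  list(arm1 = arm1, arm2 = arm2,
       anchor1 = a1[1L, ], anchor2 = a2[1L, ],
       bond_ref1 = t(diff(a1)), bond_ref2 = t(diff(a2)),
       pull_axis1 = axis, pull_axis2 = -axis,
       core_center = c(0, 0, 0))
}

# Internal: everything the vectorized force/aux kernels need, precomputed.
.spool_ctx <- function(spec) {
  ref <- spool_reference(spec)
  B <- spec$n_beads
  list(ref = ref, B = B, n_dof = 6L * B,
       anchors = list(ref$anchor1, ref$anchor2),
       bond_ref = list(ref$bond_ref1, ref$bond_ref2),
       pull_axis = list(ref$pull_axis1, ref$pull_axis2),
       end_rows = list(seq.int(3L * (B - 1L) + 1L, 3L * B),
                       seq.int(3L * (2L * B - 1L) + 1L, 6L * B)))
}

# Per-arm bond vectors for stacked coordinates.
# Pos: 3 x (B*W) matrix of one arm's bead positions (bead fastest).
.arm_bonds <- function(Pos, anchor, B, W) {
  Prev <- Pos
  if (B > 1L) {
    keep <- as.vector(outer(seq_len(B - 1L), (seq_len(W) - 1L) * B, `+`))
    Prev[, keep + 1L] <- Pos[, keep]
  }
  first <- (seq_len(W) - 1L) * B + 1L
  Prev[, first] <- anchor
  Pos - Prev
}

#' Build the simulation system for a spool mimic
#'
#' @param spec A [spool_spec()].
#' @return An [md_system()] whose auxiliary observables are the per-arm
#'   unwrapped-site counts (\code{unwrapped_end1}, \code{unwrapped_end2}).
#' @export
spool_system <- function(spec) {
  stopifnot(inherits(spec, "spool_spec"))
  ctx <- .spool_ctx(spec)
  B <- ctx$B
  b0 <- spec$bond_length
  kb <- spec$bond_k
  r_in <- spec$capture[1]; r_out <- spec$capture[2]; r_mid <- spec$r_mid
  js <- spec$sites
  ns <- length(js)

  kb_ns <- spec$bond_k
  k_b <- spec$bound_k
  b_f <- spec$free_length
  k_f <- spec$free_k
  h <- spec$tension
  is_site <- seq_len(B) %in% js

  arm_force <- function(Pos, arm, W) {
    BV <- .arm_bonds(Pos, ctx$anchors[[arm]], B, W)
    Dref <- BV - ctx$bond_ref[[arm]][, rep(seq_len(B), W), drop = FALSE]
    e <- numeric(B * W)
    Fj <- matrix(0, 3L, B * W)     # dV/db per bond (force on bead j is -Fj)
    # non-site bonds: isotropic trap at the wrapped reference orientation
    nscol <- as.vector(outer(which(!is_site), (seq_len(W) - 1L) * B, `+`))
    e[nscol] <- kb_ns * colSums(Dref[, nscol, drop = FALSE]^2)
    Fj[, nscol] <- 2 * kb_ns * Dref[, nscol, drop = FALSE]
    # site bonds: soft bound trap vs released long aligned bond
    scol <- as.vector(outer(js, (seq_len(W) - 1L) * B, `+`))
    b <- BV[, scol, drop = FALSE]
    Dlt <- Dref[, scol, drop = FALSE]
    u <- sqrt(colSums(Dlt^2))
    r <- sqrt(colSums(b^2))
    eps <- rep(spec$epsilon[, arm], W)
    ax <- ctx$pull_axis[[arm]]
    proj <- colSums(b * ax) / b_f
    S <- .switch_S(u, r_in, r_out)
    dS <- .switch_dS(u, r_in, r_out)
    e_bound <- k_b * u^2 - eps
    e_free <- k_f * (r - b_f)^2 + h * (1 - proj)
    e[scol] <- S * e_bound + (1 - S) * e_free
    uhat <- Dlt / rep(pmax(u, 1e-12), each = 3L)
    rhat <- b / rep(pmax(r, 1e-12), each = 3L)
    Fj[, scol] <- uhat * rep(dS * (e_bound - e_free) + S * 2 * k_b * u,
                             each = 3L) +
      rhat * rep((1 - S) * 2 * k_f * (r - b_f), each = 3L) -
      ax %o% ((1 - S) * h / b_f)
    # accumulate: force on bead j is -Fj, reaction +Fj on bead j-1
    Farm <- -Fj
    if (B > 1L) {
      cur <- as.vector(outer(2:B, (seq_len(W) - 1L) * B, `+`))
      Farm[, cur - 1L] <- Farm[, cur - 1L] + Fj[, cur]
    }
    list(E = colSums(matrix(e, B, W)), Farm = Farm)
  }

  force <- function(X) {
    W <- ncol(X)
    f1 <- arm_force(matrix(X[seq_len(3L * B), , drop = FALSE], 3L), 1L, W)
    f2 <- arm_force(matrix(X[3L * B + seq_len(3L * B), , drop = FALSE], 3L), 2L, W)
    Ftot <- rbind(matrix(f1$Farm, 3L * B, W), matrix(f2$Farm, 3L * B, W))
    list(E = f1$E + f2$E, F = Ftot)
  }

  rc <- function(X) {
    W <- ncol(X)
    e1 <- X[ctx$end_rows[[1]], , drop = FALSE]
    e2 <- X[ctx$end_rows[[2]], , drop = FALSE]
    v <- e1 - e2
    d <- sqrt(colSums(v^2))
    unit <- v / rep(pmax(d, 1e-12), each = 3L)
    grad <- matrix(0, nrow(X), W)
    grad[ctx$end_rows[[1]], ] <- unit
    grad[ctx$end_rows[[2]], ] <- -unit
    list(d = d, grad = grad)
  }

  aux <- function(X) {
    W <- ncol(X)
    out <- matrix(0, 2L, W,
                  dimnames = list(c("unwrapped_end1", "unwrapped_end2"), NULL))
    for (arm in 1:2) {
      Pos <- matrix(X[(arm - 1L) * 3L * B + seq_len(3L * B), , drop = FALSE], 3L)
      BV <- .arm_bonds(Pos, ctx$anchors[[arm]], B, W)
      scol <- as.vector(outer(js, (seq_len(W) - 1L) * B, `+`))
      Dlt <- BV[, scol, drop = FALSE] -
        ctx$bond_ref[[arm]][, rep(js, W), drop = FALSE]
      u <- sqrt(colSums(Dlt^2))
      out[arm, ] <- colSums(matrix(u > r_mid, ns, W))
    }
    out
  }

  x_ref <- c(t(ctx$ref$arm1), t(ctx$ref$arm2))
  init <- function(n) matrix(rep(x_ref, n), ncol = n)

  free <- rep(TRUE, ctx$n_dof)
  if (!is.null(spec$pinned_arm)) {
    rows <- (spec$pinned_arm - 1L) * 3L * B + seq_len(3L * B)
    free[rows] <- FALSE
  }
  md_system("spool", ctx$n_dof, force, rc, aux = aux, init = init,
            mass = spec$mass, free = free, spec = spec)
}

#' Extract a coordinate frame from a flattened spool state
#'
#' @param x Flattened coordinates (one column of the ensemble matrix).
#' @param spec The [spool_spec()].
#' @return A \code{2*n_beads x 3} matrix of bead coordinates; rows are arm 1
#'   innermost-to-outermost then arm 2, with rownames \code{a1_b1}, ...
#' @export
spool_frame <- function(x, spec) {
  B <- spec$n_beads
  m <- matrix(x, ncol = 3L, byrow = TRUE)
  rownames(m) <- c(paste0("a1_b", seq_len(B)), paste0("a2_b", seq_len(B)))
  m
}

#' Reference structure of the mimic for the unwrapping metrics
#'
#' @param spec A [spool_spec()].
#' @return A [reference_structure()] whose units are the beads, with per-end
#'   orderings outermost-first as the unwrapping counter expects.
#' @export
spool_reference_structure <- function(spec) {
  ref <- spool_reference(spec)
  coords <- rbind(ref$arm1, ref$arm2)
  rownames(coords) <- c(paste0("a1_b", seq_len(spec$n_beads)),
                        paste0("a2_b", seq_len(spec$n_beads)))
  reference_structure(
    coords = coords,
    core_center = ref$core_center,
    end1 = rev(paste0("a1_b", seq_len(spec$n_beads))),
    end2 = rev(paste0("a2_b", seq_len(spec$n_beads))))
}

# ---- exact site statistics ------------------------------------------------

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch).
.gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Exact per-site binding statistics by quadrature
#'
#' Every term of a site bond's potential depends only on that bond vector,
#' so its partition function reduces to a two-dimensional integral over
#' bond length r and displacement-from-reference u,
#' \deqn{Z = \frac{2\pi}{b_0}\int r \int_{|r-b_0|}^{r+b_0} u\,
#'   e^{-\beta V(r, u)}\, e^{c_1(r,u) \cos\theta}
#'   I_0\!\big(c_2(r,u) \sin\theta\big)\, du\, dr,}
#' where \eqn{\theta(r, u)} is the angle to the reference bond orientation,
#' \eqn{\alpha} the angle between the reference orientation and the arm's
#' exit axis, \eqn{c_1 = \beta (1-S) h r \cos\alpha / b_f},
#' \eqn{c_2 = \beta (1-S) h r \sin\alpha / b_f}, and the Bessel factor is
#' the exact azimuthal integral of the tension field acting on the
#' released state.  Split at the capture midpoint into bound
#' (\eqn{u \le r_{mid}}) and released parts, this gives the per-site
#' statistics to quadrature precision — the exact oracle behind the
#' occupancy enumeration.
#'
#' @param spec A [spool_spec()].
#' @param temperature Temperature, K.
#' @return A data.frame, one row per (site, arm): columns \code{site},
#'   \code{arm}, \code{epsilon}, \code{Z_bound}, \code{Z_free},
#'   \code{p_bound}, and \code{dF_release} (free-energy cost of releasing
#'   the site, kcal/mol).
#' @export
spool_site_stats <- function(spec, temperature = 300) {
  stopifnot(inherits(spec, "spool_spec"))
  beta <- 1 / kBT(temperature)
  b0 <- spec$bond_length
  k_b <- spec$bound_k; b_f <- spec$free_length; k_f <- spec$free_k
  h <- spec$tension
  r_in <- spec$capture[1]; r_out <- spec$capture[2]; r_mid <- spec$r_mid
  ref <- spool_reference(spec)
  bond_ref <- list(ref$bond_ref1, ref$bond_ref2)
  axes <- list(ref$pull_axis1, ref$pull_axis2)
  # cached unit-interval Gauss-Legendre rules, rescaled per sub-interval
  gl_u <- .gauss_legendre(32L, 0, 1)
  gl_seg <- .gauss_legendre(16L, 0, 1)
  r_hi <- b_f + 10 * sqrt(1 / (2 * beta * k_f))
  r_brk <- seq(1e-3, r_hi, length.out = 41L)   # composite outer rule
  r_nodes <- as.vector(vapply(seq_len(40L), function(s) {
    r_brk[s] + (r_brk[s + 1L] - r_brk[s]) * gl_seg$x
  }, numeric(16L)))
  r_wts <- as.vector(vapply(seq_len(40L), function(s) {
    (r_brk[s + 1L] - r_brk[s]) * gl_seg$w
  }, numeric(16L)))

  inner <- function(r, eps, cos_a, sin_a, lo_u, hi_u) {
    if (hi_u <= lo_u + 1e-14) return(0)
    brk <- sort(unique(pmin(pmax(c(lo_u, r_in, r_out, hi_u), lo_u), hi_u)))
    tot <- 0
    for (k in seq_len(length(brk) - 1L)) {
      w_seg <- brk[k + 1L] - brk[k]
      if (w_seg < 1e-14) next
      u <- brk[k] + w_seg * gl_u$x
      S <- .switch_S(u, r_in, r_out)
      ct <- (r^2 + b0^2 - u^2) / (2 * r * b0)
      st <- sqrt(pmax(1 - ct^2, 0))
      lf <- -beta * (S * (k_b * u^2 - eps) +
                       (1 - S) * (k_f * (r - b_f)^2 + h)) +
        beta * (1 - S) * h * r * cos_a * ct / b_f
      f <- u * exp(lf) * besselI(beta * (1 - S) * h * r * sin_a * st / b_f, 0)
      tot <- tot + w_seg * sum(gl_u$w * f)
    }
    tot
  }
  one <- function(eps, cos_a) {
    sin_a <- sqrt(max(1 - cos_a^2, 0))
    zb <- zf <- 0
    for (i in seq_along(r_nodes)) {
      r <- r_nodes[i]
      wr <- r_wts[i] * r
      lo_u <- abs(r - b0); hi_u <- r + b0
      zb <- zb + wr * inner(r, eps, cos_a, sin_a, lo_u, min(r_mid, hi_u))
      zf <- zf + wr * inner(r, eps, cos_a, sin_a, max(r_mid, lo_u), hi_u)
    }
    c(Z_bound = 2 * pi / b0 * zb, Z_free = 2 * pi / b0 * zf)
  }
  rows <- expand.grid(si = seq_along(spec$sites), arm = 1:2)
  z <- vapply(seq_len(nrow(rows)), function(i) {
    si <- rows$si[i]; arm <- rows$arm[i]
    br <- bond_ref[[arm]][, spec$sites[si]]
    cos_a <- sum(br * axes[[arm]]) / sqrt(sum(br^2))
    one(spec$epsilon[si, arm], cos_a)
  }, numeric(2L))
  data.frame(site = spec$sites[rows$si],
             arm = rows$arm,
             epsilon = spec$epsilon[cbind(rows$si, rows$arm)],
             Z_bound = z[1L, ], Z_free = z[2L, ],
             p_bound = z[1L, ] / (z[1L, ] + z[2L, ]),
             dF_release = -log(z[2L, ] / z[1L, ]) / beta)
}

#' Exact free-energy profile over the total unwrapped-site count
#'
#' Enumerates all site-occupancy states (2^(2M) for M sites per arm; sites
#' of a pinned arm are held bound) with weights given by the exact per-site
#' partition functions, and returns the free energy as a function of the
#' total number of released sites.  This is the enumeration oracle the full
#' sampling + WHAM + reweighting pipeline is tested against.
#'
#' @param spec A [spool_spec()].
#' @param temperature Temperature, K.
#' @return A \code{fe_profile} over coordinate \code{unwrapped_total}
#'   (integer bin centers 0..n_sites), min-anchored.
#' @export
spool_occupancy_profile <- function(spec, temperature = 300) {
  st <- spool_site_stats(spec, temperature)
  if (!is.null(spec$pinned_arm)) st <- st[st$arm != spec$pinned_arm, ]
  n <- nrow(st)
  # convolution of independent two-state sites == full 2^n enumeration
  pvec <- c(1)   # pvec[r+1] = unnormalized weight of r released sites
  for (i in seq_len(n)) {
    w0 <- st$Z_bound[i]; w1 <- st$Z_free[i]
    pvec <- c(pvec * w0, 0) + c(0, pvec * w1)
  }
  P <- pvec / sum(pvec)
  F <- -kBT(temperature) * log(P)
  F <- F - min(F)
  fe_profile("unwrapped_total", 0:n, F = F, P = P, temperature = temperature)
}

#' Metropolis sampling of the reduced site-occupancy model
#'
#' Single-flip Metropolis Monte Carlo on the occupancy vector of the reduced
#' (site-occupancy-only) model, whose stationary distribution is the product
#' of the exact per-site weights.  Used to check the enumeration oracle by
#' long-run sampling.
#'
#' @param spec A [spool_spec()].
#' @param n_sweeps Number of MC sweeps (one attempted flip per site each).
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @return Integer vector of total released-site counts, one per sweep.
#' @export
spool_occupancy_mc <- function(spec, n_sweeps = 2000L, temperature = 300,
                               seed = 1L) {
  st <- spool_site_stats(spec, temperature)
  if (!is.null(spec$pinned_arm)) st <- st[st$arm != spec$pinned_arm, ]
  set.seed(seed)
  n <- nrow(st)
  ratio_release <- st$Z_free / st$Z_bound
  s <- rep(0L, n)
  out <- integer(n_sweeps)
  for (sw in seq_len(n_sweeps)) {
    for (i in sample.int(n)) {
      a <- if (s[i] == 0L) ratio_release[i] else 1 / ratio_release[i]
      if (a >= 1 || stats::runif(1L) < a) s[i] <- 1L - s[i]
    }
    out[sw] <- sum(s)
  }
  out
}

#' Shorten the spool arms between stages
#'
#' Removes the outermost beads of each arm (the toy analog of deleting
#' base pairs from each DNA end between unwrapping stages); sites on removed
#' bonds disappear.
#'
#' @param spec A [spool_spec()].
#' @param drop_beads Number of outermost beads to remove per arm.
#' @return The shortened [spool_spec()].
#' @export
spool_shorten <- function(spec, drop_beads) {
  stopifnot(inherits(spec, "spool_spec"), drop_beads >= 1,
            spec$n_beads - drop_beads >= 2)
  newB <- spec$n_beads - as.integer(drop_beads)
  keep <- spec$sites <= newB
  spool_spec(n_beads = newB, sites = spec$sites[keep],
             epsilon = spec$epsilon[keep, , drop = FALSE],
             bond_length = spec$bond_length, bond_k = spec$bond_k,
             bound_k = spec$bound_k, free_length = spec$free_length,
             free_k = spec$free_k, capture = spec$capture,
             core_radius = spec$core_radius, z_offset = spec$z_offset,
             phi0 = spec$phi0, tension = spec$tension,
             pinned_arm = spec$pinned_arm, mass = spec$mass)
}

#' Map a spool state onto shortened arms
#'
#' @param x Flattened coordinates of the original system (one walker), or a
#'   matrix with one walker per column.
#' @param spec Original [spool_spec()].
#' @param drop_beads Beads removed per arm (outermost).
#' @return Flattened coordinates for the shortened system (same shape
#'   convention as the input).
#' @export
spool_drop_beads <- function(x, spec, drop_beads) {
  B <- spec$n_beads
  newB <- B - as.integer(drop_beads)
  rows <- c(outer(seq_len(3L), (seq_len(newB) - 1L) * 3L, `+`))
  keep <- c(rows, 3L * B + rows)
  if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep]
}
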