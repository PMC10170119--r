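#' Two-component template for segment embeddings
#'
#' The slow/fast template used by [embed_target_ode()]:
#' `u_t = d_u Lap u - lambda1 u + f(u, v; x) + zeta(x)` (slow, Neumann in y),
#' `v_t = D_v Lap v - lambda2 v + u` (fast, Dirichlet in y by default).
#' The fast component relaxes on the time scale `1/lambda2` and mediates the
#' long-range inter-segment coupling with screening length
#' `1/beta = sqrt(D_v / lambda2)`.
#'
#' @param epsilon Segment width; the slow diffusion is `d_u = epsilon^2`.
#' @param lambda1,lambda2 Degradation rates of the slow and fast component.
#' @param D_v Fast diffusion coefficient.
#' @param bc_v y-boundary tag pair for the fast component.
#' @return An [rd_system_spec()] skeleton (reaction and sources are filled in
#'   by the embedding).
#' @export
embedding_template <- function(epsilon = 0.1, lambda1 = 5, lambda2 = 80,
                               D_v = 20, bc_v = c("neumann0", "neumann0")) {
  rd_system_spec(2, D = c(epsilon^2, D_v), lambdas = c(lambda1, lambda2),
                 reaction = reaction_zero(2),
                 bc = list(c("neumann0", "neumann0"), bc_v))
}

#' Embed a target vector field into a two-component reaction-diffusion system
#'
#' Constructs spatially varying reaction coefficients and gradient sources for
#' the slow/fast template so that the Galerkin projection of the slow
#' component onto the segment basis obeys (up to a measured defect) the
#' prescribed amplitude dynamics
#' `dX_i/dt = c0_i + (L X)_i + X_i (B X)_i`.
#'
#' The construction: the fast component `v` is a linear, rapidly relaxing
#' readout of the slow field (`v ~ (lambda2 - D_v Lap)^{-1} u`), so its value
#' near segment `i` carries a fixed linear combination of all amplitudes with
#' exponentially decaying weights. Per-segment reaction channels
#' `a(x) u + b(x) v + d(x) u v + e(x) u^2 + zeta(x)` are then calibrated
#' against the exact discrete projection integrals (including a first-order
#' correction for the finite relaxation lag of `v`). Couplings the channels
#' cannot represent remain in the reported defect, which must stay below
#' `defect_tol` of the vector-field norm on the working box.
#'
#' @param target An [amplitude_system_quadratic()]-family system (cubic
#'   coefficients must be zero) with `n_vars == length(basis$centers)`,
#'   expressed in basis (left-to-right center) order.
#' @param basis A [build_segment_basis()] on the grid to be used.
#' @param template An [embedding_template()] / two-component
#'   [rd_system_spec()]; its u-boundary must be Neumann (the segment ansatz
#'   is y-constant).
#' @param working_box Optional `n x 2` matrix of amplitude bounds; default is
#'   the bounding box of a reference orbit of the target, padded 10% and
#'   clipped to `|X_i| <= 30`.
#' @param defect_tol Maximum admissible relative defect (default 0.1).
#' @param n_defect Number of working-box sample points for the defect scan.
#' @param force_cap Pointwise bound on the reaction forcing delivered by the
#'   fast-field channels; the ridge strength of the calibration fit is chosen
#'   as the smallest that respects it (large coefficient fields destabilize
#'   off-manifold grid modes even when their projection is correct).
#' @param b_cap Magnitude cap on the linear fast-field coefficient `b(x,y)`,
#'   bounding the u -> v -> u slaving feedback loop.
#' @param newton_linear Number of Newton passes matching the slow invariant
#'   subspace of the exact discrete linearization (corrects systematic
#'   linear drift the static channel algebra cannot see).
#' @param empirical_passes Number of empirical flow-matching passes: the PDE
#'   flow is probed at working-box states over short horizons and the
#'   residual drift, fitted as a quadratic in the amplitudes, is
#'   pre-compensated in the calibration targets.
#' @return An object of class `rd_embedding`: the filled-in `spec`, the
#'   `basis`, the calibrated `reduced` amplitude system (the exact projected
#'   dynamics in the channel algebra), the `defect` report, calibration
#'   matrices, and the fast-component response fields needed to build slaved
#'   initial states.
#' @export
embed_target_ode <- function(target, basis, template = embedding_template(),
                             working_box = NULL, defect_tol = 0.1,
                             n_defect = 24L, force_cap = 3000, b_cap = 12000,
                             newton_linear = 2L, empirical_passes = 0L) {
  stopifnot(inherits(target, "amplitude_system"),
            inherits(basis, "segment_basis"),
            inherits(template, "rd_system_spec"), template$m == 2L)
  if (target$family != "quadratic_cubic" || any(target$params$cub != 0)) {
    stop("embedding supports constant + linear + bilinear targets only")
  }
  n <- target$n_vars
  if (n != length(basis$centers)) {
    stop("target dimension must equal the number of basis segments")
  }
  if (!all(template$bc[[1]] == "neumann0")) {
    stop("embedding requires Neumann y-boundaries for the slow component")
  }
  g <- basis$grid
  D_v <- template$D[2]
  lambda1 <- template$lambdas[1]; lambda2 <- template$lambdas[2]
  bc_v <- template$bc[[2]]
  c0 <- target$params$c0; L <- target$params$L; B <- target$params$B
  # harmonic confinement: with d_u = lambda1 eps^2 / 8 the activation
  # profile A0(x) = lambda1 + d_u/eps^2 - d_u dx^2/eps^4 (truncated where it
  # turns negative) touches zero exactly at |dx| = 3 eps, the Gaussian psi is
  # an exact eigenmode of d_u Lap - lambda1 + A0, and in-window excited
  # modes are damped by the well's level spacing 2 d_u / eps^2 = lambda1/4
  d_u <- lambda1 * basis$epsilon^2 / 8

  # the fast-equation source gain carries y-harmonics so that v holds a
  # y-flat mode (slow x-decay) plus cos(m pi y / Ly) modes (faster x-decay);
  # the mode mix gives the readings distance discrimination along x
  cg_f <- matrix(rep(1 + cos(pi * g$y / g$Ly) + 0.8 * cos(2 * pi * g$y / g$Ly),
                     g$nx), g$ny, g$nx)

  # --- fast-component response fields:
  #     G_j = (lambda2 - D_v Lap)^{-1} (cg psi_j),
  #     G2_j = (lambda2 - D_v Lap)^{-1} G_j (relaxation-lag correction)
  Gfull <- vector("list", n)
  G2full <- vector("list", n)
  for (j in seq_len(n)) {
    srcj <- cg_f * matrix(basis$profiles[, j], g$ny, g$nx, byrow = TRUE)
    Gfull[[j]] <- solve_screened_poisson(-srcj, D_v, sqrt(lambda2), g, bc_v)
    G2full[[j]] <- solve_screened_poisson(-Gfull[[j]], D_v, sqrt(lambda2), g,
                                          bc_v)
  }

  # --- dynamical importance weights from a reference orbit of the target:
  # a residual coupling (reader ip, monomial) perturbs trajectories in
  # proportion to the monomial's typical size over the orbit relative to the
  # size of dX_ip/dt; |dX_ip/dt| is taken at a low quantile because residuals
  # hurt most in slow phases (e.g. the reinjection phase of a Roessler-like
  # flow)
  ref0 <- integrate_amplitudes(target, rep(0.1, n), t_end = 300, dt = 0.01,
                               save_every = 10L)
  post <- ref0$X[ref0$times > 50, , drop = FALSE]
  Xrms <- pmax(sqrt(colMeans(post^2)), 0.01)
  Xbox <- pmax(apply(abs(post), 2, max), Xrms)   # orbit extremes
  Fabs <- abs(t(apply(post, 1, target$vfield)))
  Flow <- pmax(apply(Fabs, 2, stats::quantile, probs = 0.2),
               0.05 * apply(Fabs, 2, max), 1e-6)

  # --- channel shapes
  #
  # Reaction channels and their hazards:
  #   a(x) u        local linear (sets diagonal rates; windows W)
  #   b(x,y) v      linear fast-field readout; no du-feedback, safe
  #   d(x,y) u v    product channel; carries a pointwise growth rate d*v for
  #                 off-manifold modes, so its magnitude is capped by the
  #                 slow-component damping lambda1 (the template compensates
  #                 a large lambda1 on-manifold through the a-channel)
  #   h(x,y) v^2    quadratic fast-field readout; no du-feedback, safe, but
  #                 weakly read, so reserved for fine corrections
  #   e(x) u^2      self-square mop-up (kept small by construction)
  # x-shapes: even psi-width and 2.5 eps profiles, odd 2 eps and 4 eps
  # profiles. Odd profiles null the segment's own fast-field reading and its
  # relaxation lag. y-shapes: cos(m pi y / Ly), m = 0..4, which weight the
  # y-harmonics of v and discriminate same-side sources at different
  # distances (the second space dimension is essential here). All shapes
  # have unit peak so coefficient norms track pointwise magnitudes.
  P <- basis$profiles                       # nx x n
  eps <- basis$epsilon
  W <- vapply(basis$centers, function(cc) {
    periodized_gaussian(g$x, cc, 3 * eps, g$Lx)
  }, numeric(g$nx))                         # even window fields, peak 1
  odd_profile <- function(cc, width) {
    dxp <- (g$x - cc + g$Lx / 2) %% g$Lx - g$Lx / 2   # wrapped displacement
    o <- (dxp / eps) * exp(-dxp^2 / (2 * width^2))
    o / max(abs(o))
  }
  even_profile <- function(cc, width) {
    periodized_gaussian(g$x, cc, width, g$Lx)
  }
  Pn <- sweep(P, 2, apply(abs(P), 2, max), "/")       # peak-1 even profiles
  hx <- g$hx
  wy <- y_weights(g)
  sys_y <- lapply(0:4, function(m) cos(m * pi * g$y / g$Ly))
  names(sys_y) <- paste0("mode", 0:4)
  yread <- function(F2, sy) as.numeric(crossprod(wy * sys_y[[sy]], F2))
  xshapes <- function(i) {
    cc <- basis$centers[i]
    list(Pn[, i], even_profile(cc, 2.5 * eps),
         odd_profile(cc, 2 * eps), odd_profile(cc, 4 * eps))
  }
  oshapes <- function(i) {
    cc <- basis$centers[i]
    list(odd_profile(cc, 2 * eps), odd_profile(cc, 4 * eps))
  }

  Pw   <- colSums(W * P^2) * hx                       # u-channel gain
  lapP <- (P[c(g$nx, 1:(g$nx - 1)), ] + P[c(2:g$nx, 1), ] - 2 * P) / hx^2
  Dlt  <- d_u * colSums(P * lapP) * hx                # discrete d_u <psi, psi''>
  A0 <- numeric(g$nx)                                 # confinement field
  for (cc in basis$centers) {
    dxp <- (g$x - cc + g$Lx / 2) %% g$Lx - g$Lx / 2
    A0 <- A0 + pmax(0, lambda1 + d_u / eps^2 - d_u * dxp^2 / eps^4)
  }
  A0proj <- as.numeric(crossprod(P^2, A0)) * hx       # reader projections

  # pair bookkeeping for bilinear monomials X_j X_m, j <= m
  npair <- n * (n + 1) / 2
  pair_idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  pair_of <- matrix(0L, n, n)
  for (pidx in seq_len(npair)) {
    pair_of[pair_idx[pidx, 1], pair_idx[pidx, 2]] <- pidx
    pair_of[pair_idx[pidx, 2], pair_idx[pidx, 1]] <- pidx
  }
  # lag fields of the linear and constant drift
  H <- lapply(seq_len(n), function(m) {
    Reduce(`+`, Map(function(G2k, Lkm) G2k * Lkm, G2full, L[, m]))
  })
  H0 <- Reduce(`+`, Map(function(G2k, ck) G2k * ck, G2full, c0))
  triples <- which(B != 0, arr.ind = TRUE)            # cubic-lag generators

  # --- v-linear channels
  vmeta <- list()
  for (i in seq_len(n)) {
    for (xv in xshapes(i)) {
      for (sy in paste0("mode", 0:2)) {
        vmeta[[length(vmeta) + 1L]] <- list(xv = xv, sy = sy)
      }
    }
  }
  ncv <- length(vmeta)
  RV <- R2V <- array(0, c(ncv, n, n))       # channel, reader, amplitude
  for (ch in seq_len(ncv)) {
    cm <- vmeta[[ch]]
    for (j in seq_len(n)) {
      RV[ch, , j]  <- crossprod(P * cm$xv, yread(Gfull[[j]], cm$sy)) * hx
      R2V[ch, , j] <- crossprod(P * cm$xv, yread(G2full[[j]], cm$sy)) * hx
    }
  }
  RtV <- RV
  for (ch in seq_len(ncv)) RtV[ch, , ] <- RV[ch, , ] - R2V[ch, , ] %*% L

  # --- bilinear channels: u*v (odd shapes only) and v^2
  # u*v channels use odd x-shapes only: an odd coefficient times the (even,
  # self-dominated) fast field has zero mean against any in-window mode, so
  # its pointwise hazard enters the well modes only at second order
  umeta <- list()
  for (i in seq_len(n)) {
    for (xv in oshapes(i)) {
      for (sy in paste0("mode", 0:2)) {
        umeta[[length(umeta) + 1L]] <- list(xv = xv, sy = sy)
      }
    }
  }
  ncu <- length(umeta)
  RU <- RU2 <- array(0, c(max(ncu, 1), n, n))
  for (ch in seq_len(ncu)) {
    cm <- umeta[[ch]]
    for (j in seq_len(n)) {
      RU[ch, , j]  <- crossprod(P^2 * cm$xv, yread(Gfull[[j]], cm$sy)) * hx
      RU2[ch, , j] <- crossprod(P^2 * cm$xv, yread(G2full[[j]], cm$sy)) * hx
    }
  }
  qmeta <- list()
  for (i in seq_len(n)) {
    for (xv in xshapes(i)) {
      for (sy in paste0("mode", 0:4)) {
        qmeta[[length(qmeta) + 1L]] <- list(xv = xv, sy = sy)
      }
    }
  }
  ncq <- length(qmeta)
  ntr <- n * max(nrow(triples), 0)
  # deliveries in pair basis, linear side-effects, and cubic-lag penalties
  pair_deliver_uv <- function(Rm, R2m) {
    # u*v channel read by reader ip delivers X_ip X_j with the
    # lag-compensated reading (R - R2 L); returns (reader, pair) matrix
    D <- matrix(0, n, npair)
    Rt <- Rm - R2m %*% L
    for (ip in seq_len(n)) {
      for (j in seq_len(n)) {
        D[ip, pair_of[ip, j]] <- D[ip, pair_of[ip, j]] + Rt[ip, j]
      }
    }
    D
  }
  QDu  <- array(0, c(max(ncu, 1), n, npair))
  LDu  <- matrix(0, max(ncu, 1), n)         # linear side (lag of c0): X_ip
  QD3u <- array(0, c(max(ncu, 1), n, max(ntr, 1)))
  for (ch in seq_len(ncu)) {
    QDu[ch, , ] <- pair_deliver_uv(RU[ch, , ], RU2[ch, , ])
    LDu[ch, ] <- -as.numeric(RU2[ch, , ] %*% c0)
    if (ntr > 0) {
      tr <- 0L
      for (j in seq_len(n)) {
        for (r in seq_len(nrow(triples))) {
          tr <- tr + 1L
          # cubic from u*v lag: X_ip * X_k (B X)_k -> only j == ip terms
          # matter per reader; delivery = -RU2[ch, ip, k] B[k, m] for the
          # monomial X_ip X_k X_m; store per reader at slot (j == reader)
          k <- triples[r, 1]; m <- triples[r, 2]
          QD3u[ch, j, tr] <- -RU2[ch, j, k] * B[k, m]
        }
      }
    }
  }
  QDq  <- array(0, c(ncq, n, npair))
  LDq  <- array(0, c(ncq, n, n))
  QD3q <- array(0, c(ncq, n, max(ntr, 1)))
  tr_scale <- numeric(max(ntr, 1))
  for (ch in seq_len(ncq)) {
    cm <- qmeta[[ch]]
    xw <- P * cm$xv
    for (pidx in seq_len(npair)) {
      j <- pair_idx[pidx, 1]; m <- pair_idx[pidx, 2]
      F2 <- if (j == m) {
        Gfull[[j]] * Gfull[[j]] - 2 * Gfull[[j]] * H[[j]]
      } else {
        2 * Gfull[[j]] * Gfull[[m]] -
          2 * (Gfull[[j]] * H[[m]] + Gfull[[m]] * H[[j]])
      }
      QDq[ch, , pidx] <- crossprod(xw, yread(F2, cm$sy)) * hx
    }
    for (j in seq_len(n)) {
      LDq[ch, , j] <- crossprod(xw, yread(-2 * Gfull[[j]] * H0, cm$sy)) * hx
    }
    if (ntr > 0) {
      tr <- 0L
      for (j in seq_len(n)) {
        for (r in seq_len(nrow(triples))) {
          tr <- tr + 1L
          k <- triples[r, 1]; m <- triples[r, 2]
          F2 <- -2 * Gfull[[j]] * G2full[[k]] * B[k, m]
          QD3q[ch, , tr] <- crossprod(xw, yread(F2, cm$sy)) * hx
          tr_scale[tr] <- Xbox[j] * Xbox[k] * Xbox[m]
        }
      }
    }
  }

  # --- pointwise hazard/forcing models
  vscale_fields <- Reduce(`+`, Map(function(Gj, s) abs(Gj) * s, Gfull,
                                   pmax(2 * Xrms, 4 * Xrms)))
  field_of <- function(th, meta) {
    f <- matrix(0, g$ny, g$nx)
    for (ch in seq_along(th)) {
      if (th[ch] != 0) {
        f <- f + th[ch] * outer(sys_y[[meta[[ch]]$sy]], meta[[ch]]$xv)
      }
    }
    f
  }
  # the v-linear channel is safe as direct forcing but closes a feedback
  # loop u -> v -> u through the fast-field slaving; capping the coefficient
  # magnitude keeps the loop rate below the y-mode damping of the well
  force_v <- function(th) max(abs(field_of(th, vmeta))) * force_cap / b_cap
  force_uq <- function(th) {
    thu <- th[seq_len(ncu)]
    thq <- th[ncu + seq_len(ncq)]
    rate <- max(abs(field_of(thu, umeta)) * vscale_fields)     # d*v hazard
    forc <- max(abs(field_of(thq, qmeta)) * vscale_fields^2)   # h*v^2 forcing
    max(rate / (0.15 * lambda1), forc / force_cap) * force_cap
  }

  # weighted ridge fit: minimize |W (M theta - t)|^2 + mu |theta|^2, with mu
  # the smallest value whose solution respects the pointwise caps
  ridge_fit <- function(M, t, w, force_of) {
    Mw <- M * w
    tw <- t * w
    MtM <- crossprod(Mw)
    Mtt <- crossprod(Mw, tw)
    base <- mean(diag(MtM))
    th <- NULL
    for (mu in base * 10^seq(-14, 2, by = 0.5)) {
      th2 <- tryCatch(as.numeric(solve(MtM + diag(mu, ncol(M)), Mtt)),
                      error = function(e) NULL)
      if (is.null(th2)) next
      th <- th2
      if (force_of(th) <= force_cap) return(th)
    }
    th
  }
  offmask <- row(L) != col(L)

  # --- diagonal-channel cross-window systems
  Pu <- t(P^2) %*% W * hx            # a-channel: reader ip, window i
  Ce <- t(P^3) %*% W * hx            # u^2-channel
  Gm <- crossprod(P) * hx            # zeta (psi-shaped source) Gram
  row_field <- function(shape, coefs) {
    matrix(rep(as.numeric(shape %*% coefs), each = g$ny), g$ny, g$nx)
  }
  A0_f <- matrix(rep(A0, each = g$ny), g$ny, g$nx)
  wl <- outer(1 / Flow, Xrms)
  wq <- matrix(0, n, npair)
  for (ip in seq_len(n)) {
    for (pidx in seq_len(npair)) {
      j <- pair_idx[pidx, 1]; m <- pair_idx[pidx, 2]
      wq[ip, pidx] <- Xbox[j] * Xbox[m] / Flow[ip]
    }
  }

  # alternating global calibration for given linear fit targets Lfit (two
  # passes; the cross-corrections between the stages are small). Lag
  # compensation always uses the true drift L.
  calibrate <- function(Lfit, Bfit_pair = NULL, c0fit = c0) {
    if (is.null(Bfit_pair)) {
      Bfit_pair <- matrix(0, n, npair)
      for (ip in seq_len(n)) {
        for (k in seq_len(n)) {
          if (B[ip, k] != 0) {
            Bfit_pair[ip, pair_of[ip, k]] <- Bfit_pair[ip, pair_of[ip, k]] +
              B[ip, k]
          }
        }
      }
    }
    th_v <- numeric(ncv); th_u <- numeric(max(ncu, 1)); th_q <- numeric(ncq)
    for (pass in 1:2) {
      # linear stage: match off-diagonal Lfit net of the bilinear channels'
      # linear side-effects
      Ltar <- Lfit
      for (ip in seq_len(n)) {
        for (j in seq_len(n)) {
          Ltar[ip, j] <- Lfit[ip, j] - sum(th_q * LDq[, ip, j])
        }
      }
      Mv <- apply(RtV, 1, function(Rch) Rch[offmask])   # neq x ncv
      th_v <- if (any(Ltar[offmask] != 0)) {
        ridge_fit(Mv, Ltar[offmask], wl[offmask], force_v)
      } else numeric(ncv)
      # bilinear stage: targets = B (pair basis) + cancellation of the
      # v-linear channels' lag bilinears, with cubic-lag penalty rows
      Tq <- Bfit_pair
      for (ip in seq_len(n)) {
        lagread <- vapply(seq_len(n), function(j) sum(th_v * R2V[, ip, j]), 0)
        for (k in seq_len(n)) {
          for (m in seq_len(n)) {
            if (B[k, m] == 0) next
            Tq[ip, pair_of[k, m]] <- Tq[ip, pair_of[k, m]] +
              lagread[k] * B[k, m]
          }
        }
      }
      if (any(Tq != 0)) {
        Mu <- apply(QDu, 1, function(Qch) Qch[seq_along(Qch)])
        Mq <- apply(QDq, 1, function(Qch) Qch[seq_along(Qch)])
        Mpair <- cbind(Mu, Mq)              # (n*npair) x (ncu + ncq)
        tfit <- as.numeric(Tq)
        wfit <- as.numeric(wq)
        if (ntr > 0) {
          M3u <- apply(QD3u, 1, function(Qch) Qch[seq_along(Qch)])
          M3q <- apply(QD3q, 1, function(Qch) Qch[seq_along(Qch)])
          Mpair <- rbind(Mpair, cbind(M3u, M3q))
          tfit <- c(tfit, numeric(n * ntr))
          wfit <- c(wfit, as.numeric(outer(1 / Flow, rep(1, ntr)) *
                                       matrix(tr_scale, n, ntr,
                                              byrow = TRUE)))
        }
        thb <- ridge_fit(Mpair, tfit, wfit, force_uq)
        th_u <- thb[seq_len(ncu)]
        th_q <- thb[ncu + seq_len(ncq)]
      }
    }
    # summed channel deliveries per reader
    chanL <- matrix(0, n, n)
    chanQ <- matrix(0, n, npair)
    for (ip in seq_len(n)) {
      for (j in seq_len(n)) {
        chanL[ip, j] <- sum(th_v * RtV[, ip, j]) + sum(th_q * LDq[, ip, j])
      }
      chanL[ip, ip] <- chanL[ip, ip] + sum(th_u * LDu[, ip])
      for (pidx in seq_len(npair)) {
        chanQ[ip, pidx] <- sum(th_u * QDu[, ip, pidx]) +
          sum(th_q * QDq[, ip, pidx])
      }
    }
    lagv_c0 <- vapply(seq_len(n), function(ip) {
      sum(vapply(seq_len(n), function(j) sum(th_v * R2V[, ip, j]) * c0[j], 0))
    }, 0)
    # diagonal channels solved exactly through the cross-window systems
    alpha <- as.numeric(solve(Pu, diag(Lfit) + lambda1 - Dlt - A0proj -
                                diag(chanL)))
    selfsq <- vapply(seq_len(n), function(ip) chanQ[ip, pair_of[ip, ip]], 0)
    sq_tar <- vapply(seq_len(n), function(ip) Bfit_pair[ip, pair_of[ip, ip]],
                     0)
    e2 <- as.numeric(solve(Ce, sq_tar - selfsq))
    gam <- as.numeric(solve(Gm, c0fit + lagv_c0))
    b_f <- field_of(th_v, vmeta)
    d_f <- field_of(th_u, umeta)
    h_f <- field_of(th_q, qmeta)
    a_f <- row_field(W, alpha) + A0_f
    e_f <- row_field(W, e2)
    zeta <- row_field(P, gam)
    spec <- rd_system_spec(2, D = c(d_u, D_v), lambdas = template$lambdas,
                           reaction = reaction_fields(a_f, b_f, d = d_f,
                                                      e = e_f, h = h_f,
                                                      cg = cg_f),
                           sources = list(zeta, NULL), bc = template$bc,
                           noise_amplitude = template$noise_amplitude)
    list(th_v = th_v, th_u = th_u, th_q = th_q, alpha = alpha, e2 = e2,
         gam = gam, chanL = chanL, chanQ = chanQ, lagv_c0 = lagv_c0,
         a_f = a_f, b_f = b_f, spec = spec)
  }

  # observed linear slow dynamics of the full discretized system: block
  # inverse iteration on the sparse linearization about the origin (only the
  # a, b and cg channels act there), read through the Gram projection
  observed_linear <- function(cal) {
    npt <- g$ny * g$nx
    Lap1 <- laplacian_matrix(g, template$bc[[1]][1], template$bc[[1]][2])
    Lap2 <- laplacian_matrix(g, bc_v[1], bc_v[2])
    Tuu <- d_u * Lap1 - Matrix::Diagonal(npt, lambda1) +
      Matrix::Diagonal(npt, as.vector(cal$a_f))
    Tuv <- Matrix::Diagonal(npt, as.vector(cal$b_f))
    Tvu <- Matrix::Diagonal(npt, as.vector(cg_f))
    Tvv <- D_v * Lap2 - Matrix::Diagonal(npt, lambda2)
    TT <- rbind(cbind(Tuu, Tuv), cbind(Tvu, Tvv))
    V <- vapply(seq_len(n), function(j) {
      c(rep(basis$profiles[, j], each = g$ny), as.vector(Gfull[[j]]))
    }, numeric(2 * npt))
    for (it in 1:2) {
      V <- as.matrix(Matrix::solve(TT, V))
      V <- qr.Q(qr(V))
    }
    TV <- as.matrix(TT %*% V)
    Ltrue <- solve(crossprod(V), crossprod(V, TV))
    Rm <- vapply(seq_len(n), function(j) {
      project_to_amplitudes(matrix(V[seq_len(npt), j], g$ny, g$nx), basis)
    }, numeric(n))
    Rm %*% Ltrue %*% solve(Rm)
  }

  # Newton refinement of the linear targets: correct for everything the
  # static channel algebra does not see (y-mode contamination of the slow
  # field, slaving feedback, shape drift) by matching the slow invariant
  # subspace of the exact discrete linearization
  Lfit <- L
  cal <- calibrate(Lfit)
  best <- list(err = Inf, Lfit = Lfit, cal = cal)
  for (it in seq_len(newton_linear)) {
    L_obs <- tryCatch(observed_linear(cal), error = function(e) NULL)
    if (is.null(L_obs)) break
    err <- max(abs(L_obs - L))
    if (err < best$err) best <- list(err = err, Lfit = Lfit, cal = cal)
    # damped update: weakly read couplings respond with gain below one, and
    # an undamped iteration can drift on them
    Lfit <- Lfit + 0.6 * (L - L_obs)
    cal <- calibrate(Lfit)
  }
  if (newton_linear > 0) {
    L_obs <- tryCatch(observed_linear(cal), error = function(e) NULL)
    if (!is.null(L_obs) && max(abs(L_obs - L)) > best$err) {
      Lfit <- best$Lfit
      cal <- best$cal
    }
  }

  # --- empirical flow matching: probe the actual PDE flow at working-box
  # states over short horizons, fit the residual drift to a quadratic model
  # in the amplitudes, and pre-compensate the calibration targets. This
  # catches second-order dynamic effects (y-mode contamination interacting
  # with the nonlinear channels) that no static projection sees.
  c0fit <- c0
  Bfit_pair <- NULL
  emp_log <- list()
  if (empirical_passes > 0 && n <= 6) {
    # probe along the reference orbit: these are the states that matter and
    # the states where the construction is dynamically well behaved (box
    # corners can sit outside its stability envelope); failed probes are
    # skipped
    nprobe <- 4L * (1L + n + npair)
    probe_states <- post[round(seq(1, nrow(post), length.out = nprobe)), ,
                         drop = FALSE]
    dt_probe <- rd_stable_dt(cal$spec, g)
    n_settle <- max(2L, ceiling(3 / lambda2 / dt_probe))
    n_meas <- max(10L, ceiling(0.03 / dt_probe))
    for (it in seq_len(empirical_passes)) {
      resid <- matrix(0, nprobe, n)
      Xmid <- matrix(0, nprobe, n)
      ok <- logical(nprobe)
      for (sid in seq_len(nprobe)) {
        st <- embedded_initial_state_cal(probe_states[sid, ], basis, Gfull)
        tr <- tryCatch(
          simulate_rd(cal$spec, g, st, t_end = (n_settle + n_meas) * dt_probe,
                      dt = dt_probe, save_every = n_settle),
          error = function(e) NULL)
        if (is.null(tr) || length(tr$times) < 3) next
        t1 <- tr$times[2]; t2 <- tr$times[length(tr$times)]
        X1 <- project_to_amplitudes(tr$states[[2]]$values[[1]], basis)
        X2 <- project_to_amplitudes(
          tr$states[[length(tr$times)]]$values[[1]], basis)
        # evolve the target from X1 over the same window; the residual is
        # the drift rate of the PDE flow relative to the target flow
        refp <- integrate_amplitudes(target, X1, t_end = t2 - t1,
                                     dt = (t2 - t1) / 50)
        resid[sid, ] <- (X2 - refp$X[nrow(refp$X), ]) / (t2 - t1)
        Xmid[sid, ] <- X1
        ok[sid] <- TRUE
      }
      emp_log[[length(emp_log) + 1L]] <- list(pass = it, n_ok = sum(ok),
        resid_rms = sqrt(mean(resid[ok, ]^2)))
      if (sum(ok) < 1 + n + npair) break
      MM <- cbind(1, Xmid[ok, , drop = FALSE],
                  t(apply(Xmid[ok, , drop = FALSE], 1, function(X) {
                    vapply(seq_len(npair), function(pidx) {
                      X[pair_idx[pidx, 1]] * X[pair_idx[pidx, 2]]
                    }, 0)
                  })))
      # orbit-sampled monomials are collinear (the attractor is a thin
      # set), so fit only the well-determined directions of the drift and
      # damp the update
      sv <- svd(MM)
      keep <- sv$d > 0.05 * sv$d[1]
      fit <- 0.7 * sv$v[, keep, drop = FALSE] %*%
        (crossprod(sv$u[, keep, drop = FALSE], resid[ok, , drop = FALSE]) /
           sv$d[keep])
      c0fit <- c0fit - fit[1, ]
      Lfit <- Lfit - t(fit[1 + seq_len(n), , drop = FALSE])
      dQ <- t(fit[1 + n + seq_len(npair), , drop = FALSE])
      if (is.null(Bfit_pair)) {
        Bfit_pair <- matrix(0, n, npair)
        for (ip in seq_len(n)) {
          for (k in seq_len(n)) {
            if (B[ip, k] != 0) {
              Bfit_pair[ip, pair_of[ip, k]] <-
                Bfit_pair[ip, pair_of[ip, k]] + B[ip, k]
            }
          }
        }
      }
      Bfit_pair <- Bfit_pair - dQ
      cal <- calibrate(Lfit, Bfit_pair, c0fit)
    }
  }
  th_v <- cal$th_v; th_u <- cal$th_u; th_q <- cal$th_q
  alpha <- cal$alpha; e2 <- cal$e2; gam <- cal$gam
  chanL <- cal$chanL; chanQ <- cal$chanQ; lagv_c0 <- cal$lagv_c0
  spec <- cal$spec

  # --- exact projected dynamics in the channel algebra (reduced model)
  L_red <- diag(-lambda1 + Dlt + A0proj + as.numeric(Pu %*% alpha), n) +
    chanL
  c0_red <- as.numeric(Gm %*% gam) - lagv_c0
  Qred <- chanQ
  for (ip in seq_len(n)) {
    Qred[ip, pair_of[ip, ip]] <- Qred[ip, pair_of[ip, ip]] +
      as.numeric(Ce %*% e2)[ip]
  }
  vf_red <- local({
    L_c <- L_red; c_c <- c0_red; Q_c <- Qred; pi_c <- pair_idx
    function(X) {
      qv <- vapply(seq_len(nrow(pi_c)), function(pidx) {
        X[pi_c[pidx, 1]] * X[pi_c[pidx, 2]]
      }, 0)
      as.numeric(c_c + L_c %*% X + Q_c %*% qv)
    }
  })
  reduced <- amplitude_system(vf_red, n)

  # --- working box and defect scan
  if (is.null(working_box)) {
    lo <- apply(post, 2, min); hi <- apply(post, 2, max)
    pad <- pmax(0.1 * (hi - lo), 0.1 * max(hi - lo))
    working_box <- cbind(pmax(lo - pad, -30), pmin(hi + pad, 30))
  }
  # residual of the realized linear dynamics after the Newton correction,
  # measured on the exact discrete linearization
  L_obs_final <- tryCatch(observed_linear(cal), error = function(e) NULL)
  Ldyn_res <- if (is.null(L_obs_final)) matrix(0, n, n) else L_obs_final - L
  # diagnostic model of the *realized* slow dynamics: the measured linear
  # part plus the target nonlinearity offset by the bilinear/constant fit
  # residuals (quadratic_cubic family, usable for Lyapunov work)
  Bfit0 <- if (is.null(Bfit_pair)) {
    tmp <- matrix(0, n, npair)
    for (ip in seq_len(n)) {
      for (k in seq_len(n)) {
        if (B[ip, k] != 0) {
          tmp[ip, pair_of[ip, k]] <- tmp[ip, pair_of[ip, k]] + B[ip, k]
        }
      }
    }
    tmp
  } else Bfit_pair
  B_real <- matrix(0, n, n)
  for (ip in seq_len(n)) {
    for (k in seq_len(n)) {
      B_real[ip, k] <- B[ip, k] +
        Qred[ip, pair_of[ip, k]] - Bfit0[ip, pair_of[ip, k]]
    }
  }
  c0_real <- c0 + (c0_red - c0fit)
  L_real <- if (is.null(L_obs_final)) L else L_obs_final
  reduced_quad <- amplitude_system_quadratic(c0_real, L_real, B_real)
  shifts <- list(SL = Lfit - L,
                 Sc = c0fit - c0,
                 SB = if (is.null(Bfit_pair)) matrix(0, n, npair) else {
                   B0 <- matrix(0, n, npair)
                   for (ip in seq_len(n)) {
                     for (k in seq_len(n)) {
                       if (B[ip, k] != 0) {
                         B0[ip, pair_of[ip, k]] <- B0[ip, pair_of[ip, k]] +
                           B[ip, k]
                       }
                     }
                   }
                   Bfit_pair - B0
                 },
                 pair_idx = pair_idx, Ldyn = Ldyn_res)
  defect <- embedding_defect(spec, basis, target, Gfull, G2full, working_box,
                             n_defect, shifts)
  if (defect$rel > defect_tol) {
    stop(sprintf(paste0("embedding defect %.1f%% exceeds tolerance %.1f%%; ",
                        "worst row %d (relative %.1f%%)"),
                 100 * defect$rel, 100 * defect_tol,
                 which.max(defect$per_row), 100 * max(defect$per_row)))
  }
  structure(list(spec = spec, basis = basis, target = target,
                 reduced = reduced, reduced_quad = reduced_quad,
                 defect = defect,
                 working_box = working_box,
                 emp_log = emp_log,
                 calib = list(alpha = alpha, th_v = th_v, th_u = th_u,
                              th_q = th_q, e2 = e2, gamma = gam, P = Pw,
                              Delta = Dlt, chanL = chanL, chanQ = chanQ,
                              pair_idx = pair_idx),
                 Gfull = Gfull, G2full = G2full,
                 lambda1 = lambda1, lambda2 = lambda2, d_u = d_u, D_v = D_v),
            class = "rd_embedding")
}

#' @exportS3Method base::print
print.rd_embedding <- function(x, ...) {
  cat(sprintf(paste0("<rd_embedding> n=%d segments, defect %.2f%% ",
                     "(tol box [%s])\n"),
              x$target$n_vars, 100 * x$defect$rel,
              paste(sprintf("%.3g..%.3g", x$working_box[, 1],
                            x$working_box[, 2]), collapse = ", ")))
  invisible(x)
}

# defect of the Galerkin projection of the slow-component right-hand side on
# the slaved manifold, relative to the target field, over the working box
embedding_defect <- function(spec, basis, target, Gfull, G2full, box,
                             n_defect, shifts = NULL) {
  g <- basis$grid
  n <- target$n_vars
  Lh <- laplacian_matrix(g, spec$bc[[1]][1], spec$bc[[1]][2])
  X_s <- matrix(g$x, g$ny, g$nx, byrow = TRUE)
  Y_s <- matrix(g$y, g$ny, g$nx)
  zeta <- resolve_source(spec$sources[[1]], g)
  # deterministic Kronecker low-discrepancy samples in the box
  irr <- (sqrt(c(2, 3, 5, 7, 11, 13)) %% 1)[seq_len(n)]
  err2 <- tgt2 <- 0
  per_row_err <- per_row_ref <- numeric(n)
  defects <- matrix(0, n_defect, n)
  for (s in seq_len(n_defect)) {
    frac <- (s * irr) %% 1
    X <- box[, 1] + frac * (box[, 2] - box[, 1])
    FX <- target$vfield(X)
    uprof <- amplitudes_to_field(X, basis)
    u <- matrix(rep(uprof, each = g$ny), g$ny, g$nx)
    v <- Reduce(`+`, Map(function(Gj, Xj) Gj * Xj, Gfull, X)) -
      Reduce(`+`, Map(function(G2j, Fj) G2j * Fj, G2full, FX))
    reac <- spec$reaction$fn(list(u, v), X_s, Y_s, 0)[[1]]
    rhs <- spec$D[1] * matrix(as.numeric(Lh %*% as.vector(u)), g$ny, g$nx) -
      spec$lambdas[1] * u + reac + zeta
    proj <- project_to_amplitudes(rhs, basis)
    # the calibration may deliberately pre-distort its static targets (the
    # Newton / flow-matching corrections); the honest defect is the fit
    # residual against those targets plus the *measured* residual of the
    # realized linear dynamics against the true target
    FX_cal <- FX
    dyn <- 0
    if (!is.null(shifts)) {
      qv <- vapply(seq_len(nrow(shifts$pair_idx)), function(pidx) {
        X[shifts$pair_idx[pidx, 1]] * X[shifts$pair_idx[pidx, 2]]
      }, 0)
      FX_cal <- FX + as.numeric(shifts$SL %*% X) + shifts$Sc +
        as.numeric(shifts$SB %*% qv)
      dyn <- as.numeric(shifts$Ldyn %*% X)
    }
    d <- (proj - FX_cal) + dyn
    defects[s, ] <- d
    err2 <- err2 + sum(d^2); tgt2 <- tgt2 + sum(FX^2)
    per_row_err <- per_row_err + d^2
    per_row_ref <- per_row_ref + FX^2
  }
  list(rel = sqrt(err2 / tgt2),
       per_row = sqrt(per_row_err / pmax(per_row_ref, 1e-12)),
       samples = defects)
}

#' Field state on the slaved manifold for given amplitudes
#'
#' Builds `u = sum X_i psi_i` (y-constant) and the quasi-statically slaved
#' fast component `v = sum X_i G_i`, so that an embedded simulation can start
#' without a fast initial transient.
#'
#' @param embedding An [embed_target_ode()] result.
#' @param X0 Amplitude vector.
#' @return A [field_state()] at `t = 0`.
#' @export
embedded_initial_state <- function(embedding, X0) {
  g <- embedding$basis$grid
  uprof <- amplitudes_to_field(X0, embedding$basis)
  u <- matrix(rep(uprof, each = g$ny), g$ny, g$nx)
  v <- Reduce(`+`, Map(function(Gj, Xj) Gj * Xj, embedding$Gfull, X0))
  field_state(0, list(u, v), g)
}

#' Simulate an embedded system and project to amplitude trajectories
#'
#' Runs the full two-component PDE from the slaved state for `X0` and returns
#' the amplitude trajectory obtained by projecting each snapshot of the slow
#' component onto the segment basis.
#'
#' @param embedding An [embed_target_ode()] result.
#' @param X0 Initial amplitudes.
#' @param t_end,dt,save_every,seed Passed to [simulate_rd()]; `dt` defaults
#'   to the stability bound.
#' @return List with `times`, `X` (projected amplitude matrix), and the full
#'   `trajectory` record.
#' @export
simulate_embedded <- function(embedding, X0, t_end, dt = NULL,
                              save_every = NULL, seed = NULL) {
  g <- embedding$basis$grid
  if (is.null(dt)) dt <- rd_stable_dt(embedding$spec, g)
  if (is.null(save_every)) {
    save_every <- max(1L, round(0.05 / dt))
  }
  init <- embedded_initial_state(embedding, X0)
  tr <- simulate_rd(embedding$spec, g, init, t_end = t_end, dt = dt,
                    save_every = save_every, seed = seed)
  Xs <- t(vapply(tr$states, function(st) {
    project_to_amplitudes(st$values[[1]], embedding$basis)
  }, numeric(embedding$target$n_vars)))
  colnames(Xs) <- paste0("X", seq_len(embedding$target$n_vars))
  list(times = tr$times, X = Xs, trajectory = tr)
}

# slaved field state used by the calibration probes (quasi-static v)
embedded_initial_state_cal <- function(X0, basis, Gfull) {
  g <- basis$grid
  uprof <- amplitudes_to_field(X0, basis)
  u <- matrix(rep(uprof, each = g$ny), g$ny, g$nx)
  v <- Reduce(`+`, Map(function(Gj, Xj) Gj * Xj, Gfull, X0))
  field_state(0, list(u, v), g)
}
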