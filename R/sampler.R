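# Blocked Metropolis-within-Gibbs sampler for the multilevel growth model.
#
# Sampled quantities (all on the transformed scale):
#   theta  (n x 19)  person-level parameters, centred parameterization
#   beta0  (19)      baseline means            -> exact conjugate Gibbs
#   g      (G x 19)  group offsets (row 1 = 0) -> exact conjugate Gibbs
#   Sigma  (4)       per-family person-offset covariances -> conjugate
#                    inverse-Wishart Gibbs
#   sigma_eta/mu     measurement SDs           -> random-walk MH on log scale
#
# theta moves by adaptive random-walk Metropolis, vectorised across persons
# (person blocks are conditionally independent): a 5-(or 4-)dimensional
# block proposal per parameter family shaped by the current Sigma, a
# per-coordinate sweep, and full 19-dimensional proposals shaped by a
# per-person empirical covariance learned during warmup (these follow
# likelihood ridges that cross families, e.g. log H - log K trade-offs).
# Additional translation moves shift a baseline mean or group offset
# together with the corresponding coordinate of every affected person's
# theta (leaving the person offsets unchanged), which lets the population
# level traverse its posterior directly instead of through the random walk
# of individual thetas.  Per-record component-trajectory caches make moves
# that touch a single growth process cheap.  Proposal scales adapt during
# warmup (Robbins-Monro) and are frozen afterwards.

# recompute the natural-scale matrices of one family from proposed columns
.family_natural <- function(f, thcols) {
  switch(f,
    H = exp(thcols),
    K = exp(thcols),
    q = stats::plogis(thcols),
    i = {
      E <- exp(thcols)
      cbind(0, E[, 1], E[, 1] + E[, 2], E[, 1] + E[, 2] + E[, 3],
            E[, 1] + E[, 2] + E[, 3] + E[, 4])
    })
}

.chol_mvn_draw <- function(A, bvec) {
  # one draw from MVN with precision A and potential vector bvec
  U <- chol(A)
  m <- backsolve(U, forwardsolve(t(U), bvec))
  as.vector(m + backsolve(U, stats::rnorm(length(bvec))))
}

# Per-person ridge-penalized mode search used to initialize the chains near
# the dominant posterior mode (the composite model's timing parameters give
# the person-level posterior well-separated local modes; random-walk chains
# started far away may not cross between them within a short warmup).
.map_init <- function(model, sigma = c(0.05, 0.10), ridge_var = 0.05,
                      maxit = 60) {
  obs <- model$obs
  m0 <- unname(model$priors$means0)
  th <- matrix(m0, obs$n_person, N_TRANSFORMED, byrow = TRUE)
  for (p in seq_len(obs$n_person)) {
    sel <- obs$pid == p
    tt <- obs$t[sel]
    lh <- obs$lh[sel]
    lw <- obs$lw[sel]
    hs <- obs$hs[sel]
    ws <- obs$ws[sel]
    fn <- function(v) {
      nat <- .transformed_to_natural(v)
      h <- m <- 0
      for (x in 1:5) {
        hx <- .vb_height(nat$H[1, x], nat$K[1, x], nat$q[1, x],
                         nat$i[1, x], tt)
        h <- h + hx
        m <- m + pi * hx^(1 + 2 * nat$q[1, x])
      }
      r <- sum((v - m0)^2) / (2 * ridge_var)
      if (any(hs))
        r <- r + sum((lh[hs] - log(EGG_HEIGHT_CM + h[hs]))^2) / (2 * sigma[1]^2)
      if (any(ws))
        r <- r + sum((lw[ws] - log(EGG_WEIGHT_G + m[ws]))^2) / (2 * sigma[2]^2)
      if (!is.finite(r)) r <- 1e10
      r
    }
    o <- try(stats::optim(m0, fn, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-8)),
             silent = TRUE)
    if (!inherits(o, "try-error") && all(is.finite(o$par)))
      th[p, ] <- o$par
  }
  th
}

.run_chain <- function(model, iter, warmup, seed, fix_sigma = NULL,
                       likelihood_weight = 1, scalar_updates = TRUE,
                       init_theta = NULL, sweeps = 1, init_jitter = 0.05,
                       progress = FALSE) {
  set.seed(seed)
  obs <- model$obs
  pr <- model$priors
  n <- obs$n_person
  G <- obs$n_group
  pid <- obs$pid
  pgroup <- obs$person_group
  nrec <- length(obs$t)
  fams <- names(.family_cols)
  col_family <- rep(fams, lengths(.family_cols))
  # growth processes affected by a change to transformed column c:
  # H/K/q columns touch their own process; an initiation increment d_x
  # cascades into every later process
  col_comps <- c(as.list(1:5), as.list(1:5), as.list(1:5),
                 lapply(2:5, function(x) x:5))
  fam_comps <- list(H = 1:5, K = 1:5, q = 1:5, i = 2:5)
  m0 <- unname(pr$means0)
  wgt <- likelihood_weight
  group_members <- split(seq_len(n), pgroup)
  group_rec <- lapply(seq_len(G), function(k) pgroup[pid] == k)

  # --- state ---
  th <- if (is.null(init_theta))
    matrix(m0, n, N_TRANSFORMED, byrow = TRUE) else init_theta
  th <- th + matrix(stats::rnorm(n * N_TRANSFORMED, 0, init_jitter),
                    n, N_TRANSFORMED)
  ref_rows <- which(pgroup == 1L)
  b0 <- colMeans(th[ref_rows, , drop = FALSE]) +
    stats::rnorm(N_TRANSFORMED, 0, 0.02)
  g <- matrix(0, G, N_TRANSFORMED)
  if (G > 1)
    for (k in 2:G)
      g[k, ] <- colMeans(th[pgroup == k, , drop = FALSE]) - b0
  Sig <- lapply(.family_cols, function(cols) diag(pr$cov_scale, length(cols)))
  Siginv <- lapply(Sig, function(S) chol2inv(chol(S)))
  sig <- if (!is.null(fix_sigma)) unname(fix_sigma)
         else c(pr$sigma_eta_scale, pr$sigma_mu_scale)
  nat <- .transformed_to_natural(th)

  # --- per-record component caches ---
  HX <- matrix(0, nrec, 5)
  MX <- matrix(0, nrec, 5)
  eval_comps <- function(natl, cset) {
    out_h <- matrix(0, nrec, length(cset))
    out_m <- matrix(0, nrec, length(cset))
    for (jj in seq_along(cset)) {
      x <- cset[jj]
      qx <- natl$q[pid, x]
      hx <- .vb_height(natl$H[pid, x], natl$K[pid, x], qx,
                       natl$i[pid, x], obs$t)
      out_h[, jj] <- hx
      out_m[, jj] <- pi * hx^(1 + 2 * qx)
    }
    list(h = out_h, m = out_m)
  }
  full <- eval_comps(nat, 1:5)
  HX[] <- full$h
  MX[] <- full$m
  mu_h <- log(EGG_HEIGHT_CM + rowSums(HX))
  mu_w <- log(EGG_WEIGHT_G + rowSums(MX))

  person_ll <- function(muh, muw, s1, s2) {
    if (wgt == 0) return(numeric(n))
    llrec <- numeric(nrec)
    llrec[obs$hs] <- -log(s1) - 0.918938533204673 -
      0.5 * ((obs$lh[obs$hs] - muh[obs$hs]) / s1)^2
    llrec[obs$ws] <- llrec[obs$ws] - log(s2) - 0.918938533204673 -
      0.5 * ((obs$lw[obs$ws] - muw[obs$ws]) / s2)^2
    # overflowing trajectories (possible under extreme proposals) must be
    # rejected, not propagated as NaN
    llrec[is.na(llrec)] <- -Inf
    as.vector(rowsum(llrec * wgt, pid))
  }
  llp <- person_ll(mu_h, mu_w, sig[1], sig[2])

  # --- adaptation state ---
  s_block <- matrix(0.6, n, length(fams))
  s_sc <- matrix(0.1, n, N_TRANSFORMED)
  s_joint <- rep(1, n)
  s_tb0 <- rep(0.05, N_TRANSFORMED)
  s_tg <- matrix(0.05, G, N_TRANSFORMED)
  s_thk <- matrix(0.1, G + 1, 5)
  s_sig <- c(0.3, 0.3)
  acc_tally <- c(block = 0, scalar = 0, joint = 0, translate = 0)
  acc_n <- c(block = 0, scalar = 0, joint = 0, translate = 0)

  cov_n <- 0L
  cov_mean <- matrix(0, n, N_TRANSFORMED)
  cov_M2 <- array(0, c(n, N_TRANSFORMED, N_TRANSFORMED))
  R_joint <- NULL
  accum_cov <- function() {
    cov_n <<- cov_n + 1L
    d1 <- th - cov_mean
    cov_mean <<- cov_mean + d1 / cov_n
    d2 <- th - cov_mean
    for (j in seq_len(N_TRANSFORMED))
      cov_M2[, j, ] <<- cov_M2[, j, ] + d1[, j] * d2
  }
  refresh_joint_chol <- function() {
    if (cov_n < 50L) return(invisible())
    sc <- 2.38^2 / N_TRANSFORMED
    R_joint <<- lapply(seq_len(n), function(p)
      chol(sc * (cov_M2[p, , ] / (cov_n - 1L)) + diag(1e-8, N_TRANSFORMED)))
    invisible()
  }

  # per-person MH acceptance of a proposal touching components `cset` of
  # family `f` (dq = prior quadratic-form difference per person)
  commit_person <- function(thp_cols, cols, f, cset, natp, tally) {
    ev <- eval_comps(natp, cset)
    HXp <- HX
    MXp <- MX
    HXp[, cset] <- ev$h
    MXp[, cset] <- ev$m
    muh_p <- log(EGG_HEIGHT_CM + rowSums(HXp))
    muw_p <- log(EGG_WEIGHT_G + rowSums(MXp))
    llpp <- person_ll(muh_p, muw_p, sig[1], sig[2])
    lvl <- matrix(b0[cols], n, length(cols), byrow = TRUE) +
      g[pgroup, cols, drop = FALSE]
    dev0 <- th[, cols, drop = FALSE] - lvl
    dev1 <- thp_cols - lvl
    dq <- rowSums((dev1 %*% Siginv[[f]]) * dev1) -
      rowSums((dev0 %*% Siginv[[f]]) * dev0)
    acc <- log(stats::runif(n)) < (llpp - llp - 0.5 * dq)
    if (any(acc)) {
      th[acc, cols] <<- thp_cols[acc, , drop = FALSE]
      key <- if (f == "i") "i" else f
      nat[[key]][acc, ] <<- natp[[key]][acc, , drop = FALSE]
      mask <- acc[pid]
      HX[mask, cset] <<- HXp[mask, cset]
      MX[mask, cset] <<- MXp[mask, cset]
      mu_h[mask] <<- muh_p[mask]
      mu_w[mask] <<- muw_p[mask]
      llp[acc] <<- llpp[acc]
    }
    acc_tally[tally] <<- acc_tally[tally] + mean(acc)
    acc_n[tally] <<- acc_n[tally] + 1
    acc
  }

  # full 19-dimensional per-person move with learned proposal covariance
  try_joint_move <- function(gam) {
    eps <- matrix(stats::rnorm(n * N_TRANSFORMED), n, N_TRANSFORMED)
    for (p in seq_len(n))
      eps[p, ] <- (eps[p, , drop = FALSE] %*% R_joint[[p]]) * s_joint[p]
    thp <- th + eps
    natp <- .transformed_to_natural(thp)
    ev <- eval_comps(natp, 1:5)
    muh_p <- log(EGG_HEIGHT_CM + rowSums(ev$h))
    muw_p <- log(EGG_WEIGHT_G + rowSums(ev$m))
    llpp <- person_ll(muh_p, muw_p, sig[1], sig[2])
    dq <- 0
    for (f in fams) {
      cols <- .family_cols[[f]]
      lvl <- matrix(b0[cols], n, length(cols), byrow = TRUE) +
        g[pgroup, cols, drop = FALSE]
      dev0 <- th[, cols, drop = FALSE] - lvl
      dev1 <- thp[, cols, drop = FALSE] - lvl
      dq <- dq + rowSums((dev1 %*% Siginv[[f]]) * dev1) -
        rowSums((dev0 %*% Siginv[[f]]) * dev0)
    }
    acc <- log(stats::runif(n)) < (llpp - llp - 0.5 * dq)
    if (any(acc)) {
      th[acc, ] <<- thp[acc, , drop = FALSE]
      for (key in c("H", "K", "q", "i"))
        nat[[key]][acc, ] <<- natp[[key]][acc, , drop = FALSE]
      mask <- acc[pid]
      HX[mask, ] <<- ev$h[mask, ]
      MX[mask, ] <<- ev$m[mask, ]
      mu_h[mask] <<- muh_p[mask]
      mu_w[mask] <<- muw_p[mask]
      llp[acc] <<- llpp[acc]
    }
    if (!is.null(gam))
      s_joint <<- pmin(10, pmax(1e-3, s_joint * exp(gam * (acc - 0.234))))
    else {
      acc_tally["joint"] <<- acc_tally["joint"] + mean(acc)
      acc_n["joint"] <<- acc_n["joint"] + 1
    }
    invisible(acc)
  }

  # translation move: shift a population-level coordinate and the same
  # coordinate of every affected person's theta together (offsets unchanged)
  try_translate <- function(cc, k, gam) {
    # k = 0 -> baseline mean (all persons); k >= 2 -> group offset k
    f <- col_family[cc]
    cols <- .family_cols[[f]]
    cset <- col_comps[[cc]]
    rows <- if (k == 0L) seq_len(n) else group_members[[k]]
    dlt <- stats::rnorm(1) * (if (k == 0L) s_tb0[cc] else s_tg[k, cc])
    thp_cols <- th[, cols, drop = FALSE]
    thp_cols[rows, match(cc, cols)] <- thp_cols[rows, match(cc, cols)] + dlt
    natp <- nat
    natp[[if (f == "i") "i" else f]] <- .family_natural(f, thp_cols)
    ev <- eval_comps(natp, cset)
    HXp <- HX
    MXp <- MX
    HXp[, cset] <- ev$h
    MXp[, cset] <- ev$m
    muh_p <- log(EGG_HEIGHT_CM + rowSums(HXp))
    muw_p <- log(EGG_WEIGHT_G + rowSums(MXp))
    llpp <- person_ll(muh_p, muw_p, sig[1], sig[2])
    dll <- sum(llpp[rows]) - sum(llp[rows])
    dprior <- if (k == 0L)
      stats::dnorm(b0[cc] + dlt, m0[cc], pr$tau0[cc], log = TRUE) -
        stats::dnorm(b0[cc], m0[cc], pr$tau0[cc], log = TRUE)
    else
      stats::dnorm(g[k, cc] + dlt, 0, pr$tau_group, log = TRUE) -
        stats::dnorm(g[k, cc], 0, pr$tau_group, log = TRUE)
    ok <- log(stats::runif(1)) < (dll + dprior)
    if (ok) {
      if (k == 0L) b0[cc] <<- b0[cc] + dlt else g[k, cc] <<- g[k, cc] + dlt
      th[rows, cc] <<- th[rows, cc] + dlt
      key <- if (f == "i") "i" else f
      nat[[key]][rows, ] <<- natp[[key]][rows, , drop = FALSE]
      mask <- if (k == 0L) rep(TRUE, nrec) else group_rec[[k]]
      HX[mask, cset] <<- HXp[mask, cset]
      MX[mask, cset] <<- MXp[mask, cset]
      mu_h[mask] <<- muh_p[mask]
      mu_w[mask] <<- muw_p[mask]
      llp[rows] <<- llpp[rows]
    }
    if (!is.null(gam)) {
      if (k == 0L)
        s_tb0[cc] <<- min(2, max(1e-4, s_tb0[cc] * exp(gam * (ok - 0.44))))
      else
        s_tg[k, cc] <<- min(2, max(1e-4, s_tg[k, cc] * exp(gam * (ok - 0.44))))
    } else {
      acc_tally["translate"] <<- acc_tally["translate"] + ok
      acc_n["translate"] <<- acc_n["translate"] + 1
    }
    invisible(ok)
  }

  # paired metabolic translation: move log H_x and log K_x of a population
  # level together (same delta), for the baseline (k = 0) or a group offset.
  # Raising both leaves the process asymptote (2H/K)^(1/q) unchanged while
  # changing its rate, i.e. this proposal walks along the level-preserving
  # valley of the H-K attribution posterior that per-coordinate moves cross
  # only slowly.
  try_translate_hk <- function(x, k, gam) {
    cH <- x
    cK <- 5L + x
    rows <- if (k == 0L) seq_len(n) else group_members[[k]]
    dlt <- stats::rnorm(1) * s_thk[k + 1L, x]
    thp_H <- th[, 1:5, drop = FALSE]
    thp_K <- th[, 6:10, drop = FALSE]
    thp_H[rows, x] <- thp_H[rows, x] + dlt
    thp_K[rows, x] <- thp_K[rows, x] + dlt
    natp <- nat
    natp$H <- exp(thp_H)
    natp$K <- exp(thp_K)
    ev <- eval_comps(natp, x)
    HXp <- HX
    MXp <- MX
    HXp[, x] <- ev$h
    MXp[, x] <- ev$m
    muh_p <- log(EGG_HEIGHT_CM + rowSums(HXp))
    muw_p <- log(EGG_WEIGHT_G + rowSums(MXp))
    llpp <- person_ll(muh_p, muw_p, sig[1], sig[2])
    dll <- sum(llpp[rows]) - sum(llp[rows])
    dprior <- if (k == 0L)
      sum(stats::dnorm(c(b0[cH], b0[cK]) + dlt, m0[c(cH, cK)],
                       pr$tau0[c(cH, cK)], log = TRUE)) -
        sum(stats::dnorm(c(b0[cH], b0[cK]), m0[c(cH, cK)],
                         pr$tau0[c(cH, cK)], log = TRUE))
    else
      sum(stats::dnorm(c(g[k, cH], g[k, cK]) + dlt, 0, pr$tau_group,
                       log = TRUE)) -
        sum(stats::dnorm(c(g[k, cH], g[k, cK]), 0, pr$tau_group, log = TRUE))
    ok <- log(stats::runif(1)) < (dll + dprior)
    if (ok) {
      if (k == 0L) {
        b0[c(cH, cK)] <<- b0[c(cH, cK)] + dlt
      } else {
        g[k, c(cH, cK)] <<- g[k, c(cH, cK)] + dlt
      }
      th[rows, c(cH, cK)] <<- th[rows, c(cH, cK)] + dlt
      nat$H[rows, ] <<- natp$H[rows, , drop = FALSE]
      nat$K[rows, ] <<- natp$K[rows, , drop = FALSE]
      mask <- if (k == 0L) rep(TRUE, nrec) else group_rec[[k]]
      HX[mask, x] <<- HXp[mask, x]
      MX[mask, x] <<- MXp[mask, x]
      mu_h[mask] <<- muh_p[mask]
      mu_w[mask] <<- muw_p[mask]
      llp[rows] <<- llpp[rows]
    }
    if (!is.null(gam))
      s_thk[k + 1L, x] <<- min(2, max(1e-4,
                                      s_thk[k + 1L, x] * exp(gam * (ok - 0.44))))
    else {
      acc_tally["translate"] <<- acc_tally["translate"] + ok
      acc_n["translate"] <<- acc_n["translate"] + 1
    }
    invisible(ok)
  }

  upd_sigma <- function(gam) {
    for (mod in 1:2) {
      ssel <- if (mod == 1) obs$hs else obs$ws
      y <- if (mod == 1) obs$lh[ssel] else obs$lw[ssel]
      mm <- if (mod == 1) mu_h[ssel] else mu_w[ssel]
      SSR <- sum((y - mm)^2)
      nobs <- length(y)
      scale <- if (mod == 1) pr$sigma_eta_scale else pr$sigma_mu_scale
      lp <- function(ls) {
        s2 <- exp(2 * ls)
        wgt * (-nobs * ls - SSR / (2 * s2)) - 0.5 * s2 / scale^2 + ls
      }
      ls0 <- log(sig[mod])
      lsp <- ls0 + stats::rnorm(1) * s_sig[mod]
      ok <- log(stats::runif(1)) < (lp(lsp) - lp(ls0))
      if (ok) sig[mod] <<- exp(lsp)
      if (!is.null(gam))
        s_sig[mod] <<- min(5, max(1e-3, s_sig[mod] * exp(gam * (ok - 0.44))))
    }
    llp <<- person_ll(mu_h, mu_w, sig[1], sig[2])
  }

  # --- storage ---
  beta0_d <- matrix(NA_real_, iter, N_TRANSFORMED)
  g_d <- array(NA_real_, c(iter, G, N_TRANSFORMED))
  theta_d <- array(NA_real_, c(iter, n, N_TRANSFORMED))
  Sigma_d <- lapply(.family_cols, function(cols)
    array(NA_real_, c(iter, length(cols), length(cols))))
  sigma_d <- matrix(NA_real_, iter, 2)
  lp_d <- numeric(iter)

  total <- warmup + iter
  for (it in seq_len(total)) {
    adapting <- it <= warmup
    gam <- if (adapting) min(0.5, 1 / sqrt(it)) else NULL

    for (sw in seq_len(sweeps)) {
      # person-level family-block moves
      for (fi in seq_along(fams)) {
        f <- fams[fi]
        cols <- .family_cols[[f]]
        d <- length(cols)
        R <- chol(Sig[[f]])
        eps <- (matrix(stats::rnorm(n * d), n, d) %*% R) * s_block[, fi]
        thp_cols <- th[, cols, drop = FALSE] + eps
        natp <- nat
        natp[[if (f == "i") "i" else f]] <- .family_natural(f, thp_cols)
        acc <- commit_person(thp_cols, cols, f, fam_comps[[f]], natp, "block")
        if (adapting)
          s_block[, fi] <- pmin(10, pmax(1e-3, s_block[, fi] *
                                           exp(gam * (acc - 0.234))))
      }

      # full-vector moves with learned covariance
      if (!is.null(R_joint))
        for (rep in 1:3) try_joint_move(gam)

      # per-coordinate sweep (cheap: only the affected processes are
      # re-evaluated)
      if (scalar_updates) {
        for (cc in seq_len(N_TRANSFORMED)) {
          f <- col_family[cc]
          cols <- .family_cols[[f]]
          thp_cols <- th[, cols, drop = FALSE]
          j <- match(cc, cols)
          thp_cols[, j] <- thp_cols[, j] + stats::rnorm(n) * s_sc[, cc]
          natp <- nat
          natp[[if (f == "i") "i" else f]] <- .family_natural(f, thp_cols)
          acc <- commit_person(thp_cols, cols, f, col_comps[[cc]], natp,
                               "scalar")
          if (adapting)
            s_sc[, cc] <- pmin(10, pmax(1e-4, s_sc[, cc] *
                                          exp(gam * (acc - 0.44))))
        }
      }

      # population-level translation moves
      for (cc in seq_len(N_TRANSFORMED)) {
        try_translate(cc, 0L, gam)
        if (G > 1) for (k in 2:G) try_translate(cc, k, gam)
      }
      # paired metabolic (H, K) valley moves per process
      for (x in 1:5) {
        try_translate_hk(x, 0L, gam)
        if (G > 1) for (k in 2:G) try_translate_hk(x, k, gam)
      }
    }

    # learn per-person proposal covariances
    if (adapting && it > min(25L, warmup %/% 4)) accum_cov()
    if (adapting && it %% 25L == 0L) refresh_joint_chol()

    # conjugate population-level updates
    for (fi in seq_along(fams)) {
      f <- fams[fi]
      cols <- .family_cols[[f]]
      d <- length(cols)
      resid <- th[, cols, drop = FALSE] - g[pgroup, cols, drop = FALSE]
      A <- n * Siginv[[f]]
      diag(A) <- diag(A) + 1 / pr$tau0[cols]^2
      bvec <- Siginv[[f]] %*% colSums(resid) + m0[cols] / pr$tau0[cols]^2
      b0[cols] <- .chol_mvn_draw(A, bvec)
      if (G > 1) {
        for (k in 2:G) {
          pk <- group_members[[k]]
          residk <- th[pk, cols, drop = FALSE] -
            matrix(b0[cols], length(pk), d, byrow = TRUE)
          Ak <- length(pk) * Siginv[[f]]
          diag(Ak) <- diag(Ak) + 1 / pr$tau_group^2
          g[k, cols] <- .chol_mvn_draw(Ak, Siginv[[f]] %*% colSums(residk))
        }
      }
      U <- th[, cols, drop = FALSE] -
        matrix(b0[cols], n, d, byrow = TRUE) - g[pgroup, cols, drop = FALSE]
      S <- diag(pr$cov_scale, d) + crossprod(U)
      dfw <- d + pr$cov_df_extra + n
      W <- stats::rWishart(1, dfw, chol2inv(chol(S)))[, , 1]
      Siginv[[f]] <- W
      Sig[[f]] <- chol2inv(chol(W))
    }

    if (is.null(fix_sigma)) upd_sigma(gam)

    if (!adapting) {
      s <- it - warmup
      beta0_d[s, ] <- b0
      g_d[s, , ] <- g
      theta_d[s, , ] <- th
      for (fi in seq_along(fams)) Sigma_d[[fi]][s, , ] <- Sig[[fi]]
      sigma_d[s, ] <- sig
      lp_d[s] <- sum(llp)
    }
    if (progress && it %% 100 == 0)
      message(sprintf("  iteration %d / %d", it, total))
  }

  list(beta0 = beta0_d, g = g_d, theta = theta_d, Sigma = Sigma_d,
       sigma = sigma_d, lp = lp_d,
       accept = as.list(acc_tally / pmax(1, acc_n)))
}

#' Fit the multilevel growth model by MCMC
#'
#' Runs the package's blocked Metropolis-within-Gibbs sampler: adaptive
#' vectorised random-walk updates for person-level transformed parameters
#' (family blocks, per-coordinate sweeps and full-vector proposals with
#' per-person covariances learned during warmup), population-level
#' translation moves, exact conjugate Gibbs updates for baseline means,
#' group offsets and person-offset covariances, and random-walk updates for
#' the log measurement SDs.  Every stored draw respects the model
#' constraints by construction (positivity of H and K, q in (0,1), ordered
#' initiation ages).
#'
#' @param model A `cg_model` from [build_model()].
#' @param chains Number of chains (run sequentially).
#' @param iter Post-warmup draws per chain.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param seed Integer seed; chain c uses `seed + 1000 * (c - 1)`.
#' @param fix_sigma Optional length-2 vector `c(sigma_eta, sigma_mu)` to fix
#'   the measurement SDs instead of sampling them.
#' @param likelihood_weight Multiplier on the measurement log likelihood;
#'   0 gives a prior-only run.
#' @param scalar_updates Also perform the per-coordinate sweep each
#'   iteration (default TRUE).
#' @param map_init Initialize person parameters by a per-person
#'   ridge-penalized mode search before sampling (default TRUE); chains are
#'   jittered around the common initialization.
#' @param sweeps Person-level/translation update sweeps per stored
#'   iteration (default 2; raise for harder posteriors, lower for quick
#'   smoke runs).
#' @param init_jitter SD of the per-chain Gaussian jitter applied to the
#'   initial person parameters (transformed scale).
#' @param progress Print progress messages.
#' @return A `cg_fit` object holding draw arrays (`beta0`, `g`, `theta`,
#'   `Sigma`, `sigma`), the chain index of each draw, sampler acceptance
#'   rates and split-R-hat / effective-sample-size diagnostics for all
#'   population-level parameters.
#' @export
fit_growth <- function(model, chains = 2, iter = 500, warmup = 500, seed = 1,
                       fix_sigma = NULL, likelihood_weight = 1,
                       scalar_updates = TRUE, map_init = TRUE, sweeps = 2,
                       init_jitter = 0.05, progress = FALSE) {
  stopifnot(inherits(model, "cg_model"), chains >= 1, iter >= 1, warmup >= 0)
  init_theta <- if (map_init && likelihood_weight > 0) {
    if (progress) message("initializing at per-person penalized modes")
    .map_init(model)
  } else NULL
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (progress) message("chain ", ch)
    res[[ch]] <- .run_chain(model, iter, warmup,
                            seed = seed + 1000L * (ch - 1L),
                            fix_sigma = fix_sigma,
                            likelihood_weight = likelihood_weight,
                            scalar_updates = scalar_updates,
                            init_theta = init_theta, sweeps = sweeps,
                            init_jitter = init_jitter, progress = progress)
  }
  fams <- names(.family_cols)
  G <- model$obs$n_group
  S <- chains * iter
  comb <- function(get) do.call(rbind, lapply(res, get))
  abind1 <- function(arrs) {
    out <- array(NA_real_, c(S, dim(arrs[[1]])[-1]))
    at <- 0
    for (a in arrs) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  fit <- structure(list(
    beta0 = comb(function(r) r$beta0),
    g = abind1(lapply(res, function(r) r$g)),
    theta = abind1(lapply(res, function(r) r$theta)),
    Sigma = stats::setNames(lapply(seq_along(fams), function(fi)
      abind1(lapply(res, function(r) r$Sigma[[fi]]))), fams),
    sigma = comb(function(r) r$sigma),
    lp = unlist(lapply(res, function(r) r$lp)),
    chain = rep(seq_len(chains), each = iter),
    chains = chains, iter = iter, warmup = warmup, seed = seed,
    model = model,
    accept = lapply(res, function(r) r$accept)),
    class = "cg_fit")
  colnames(fit$beta0) <- transformed_names()
  dimnames(fit$g)[[2]] <- model$groups
  dimnames(fit$g)[[3]] <- transformed_names()
  fit$diagnostics <- .fit_diagnostics(fit)
  fit
}

#' @export
print.cg_fit <- function(x, ...) {
  cat(sprintf(
    "multilevel growth model fit: %d persons, %d group(s), %d chains x %d draws\n",
    dim(x$theta)[2], dim(x$g)[2], x$chains, x$iter))
  d <- x$diagnostics
  cat(sprintf("  max split-R-hat %.3f, min bulk ESS %.0f\n",
              max(d$rhat, na.rm = TRUE), min(d$ess, na.rm = TRUE)))
  cat(sprintf("  sigma_eta %.4f, sigma_mu %.4f (posterior means)\n",
              mean(x$sigma[, 1]), mean(x$sigma[, 2])))
  invisible(x)
}

# split-half R-hat (classic formula on split chains)
.split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  nn <- min(lengths(halves))
  if (nn < 2) return(NA_real_)
  halves <- lapply(halves, function(v) v[seq_len(nn)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt((nn - 1) / nn + B / (W * nn))
}

# effective sample size via initial positive autocorrelation sums, per chain
.ess_basic <- function(x, chain) {
  per <- vapply(split(x, chain), function(v) {
    nn <- length(v)
    if (stats::var(v) == 0) return(nn)
    a <- stats::acf(v, lag.max = min(100, nn - 2), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq_along(a)) {
      if (a[k] < 0) break
      s <- s + a[k]
    }
    nn / (1 + 2 * s)
  }, numeric(1))
  sum(per)
}

.fit_diagnostics <- function(fit) {
  pars <- list()
  for (j in seq_len(ncol(fit$beta0)))
    pars[[paste0("beta0[", colnames(fit$beta0)[j], "]")]] <- fit$beta0[, j]
  gn <- dimnames(fit$g)[[2]]
  if (dim(fit$g)[2] > 1)
    for (k in 2:dim(fit$g)[2])
      for (j in seq_len(dim(fit$g)[3]))
        pars[[paste0("g[", gn[k], "][", transformed_names()[j], "]")]] <-
          fit$g[, k, j]
  pars[["sigma_eta"]] <- fit$sigma[, 1]
  pars[["sigma_mu"]] <- fit$sigma[, 2]
  data.frame(
    parameter = names(pars),
    rhat = vapply(pars, .split_rhat, numeric(1), chain = fit$chain),
    ess = vapply(pars, .ess_basic, numeric(1), chain = fit$chain),
    row.names = NULL)
}
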