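# Candidate set membership, the transition operator, the fixed point, lineage
# shares and the martingale property.

test_that("in_Z accepts uniform candidates and rejects violations", {
  f <- random_Z(hd_chain, 1, seed = 1)[[1]]
  expect_true(in_Z(f, hd_chain))
  f_neg <- f; f_neg[1, 1] <- -0.1
  expect_false(in_Z(f_neg, hd_chain))
  f_sum <- f; f_sum[1, ] <- f_sum[1, ] * 2
  expect_false(in_Z(f_sum, hd_chain))
  # nonzero value on an empty class
  ch <- demographic_chain(make_age_density())
  f2 <- random_Z(ch, 1, seed = 1)[[1]]
  empty <- which(rvprice:::state_counts(ch) == 0, arr.ind = TRUE)[1, ]
  f3 <- f2; f3[empty[1], empty[2]] <- 0.5
  expect_false(in_Z(f3, ch))
})

test_that("Z is T-invariant and T is linear (property over random candidates)", {
  fs <- random_Z(hd_chain, 100, seed = 3)
  for (f in fs[1:10]) expect_true(in_Z(apply_T(f, hd_chain), hd_chain))
  for (f in fs[11:100]) {
    Tf <- apply_T(f, hd_chain)
    ok <- in_Z(Tf, hd_chain)
    if (!isTRUE(ok)) fail(paste("Tf left Z:", attr(ok, "witnesses")))
  }
  succeed()
  f <- fs[[1]]; g <- fs[[2]]; a <- 0.3
  lhs <- apply_T(a * f + (1 - a) * g, hd_chain)
  rhs <- a * apply_T(f, hd_chain) + (1 - a) * apply_T(g, hd_chain)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("apply_T matches an independent enumeration oracle", {
  # oracle: raw double sum over kernel outcomes and next environments,
  # recomputing u and next states directly from the kernel output
  m <- hd_model
  f <- random_Z(hd_chain, 1, seed = 5)[[1]]
  Tf <- apply_T(f, hd_chain)
  for (key in hd_chain$states$key) {
    st <- parse_state_key(key)
    pop <- rvprice:::demographic_population(m, st$tally)
    outs <- m$kernel(st$env, pop, m)
    for (x in m$classes) {
      nx <- sum(pop$class == x)
      if (nx == 0) next
      acc <- 0
      for (o in outs) for (e2 in m$env_states) {
        tab <- numeric(0); csum_x <- stats::setNames(rep(0, 2), m$classes)
        for (i in seq_along(o$shares)) {
          s <- o$shares[[i]]
          L <- m$ploidy[[pop$class[i]]]
          for (k in seq_along(s)) {
            nm <- names(s)[k]
            tab[nm] <- (if (nm %in% names(tab)) tab[[nm]] else 0) + L * s[k]
            if (pop$class[i] == x)
              csum_x[[cg_class(nm)]] <- csum_x[[cg_class(nm)]] + s[k]
          }
        }
        dt <- demographic_tally(stats::setNames(as.integer(round(tab)), names(tab)))
        u_x <- csum_x / nx
        inner <- sum(f[state_key(e2, dt), m$classes] * m$ploidy[m$classes] * u_x)
        acc <- acc + o$prob * m$Pi[st$env, e2] * inner
      }
      expect_equal(Tf[key, x], acc, tolerance = 1e-12)
    }
  }
})

test_that("clonal reproductive value is 1/N everywhere and uniform f is fixed", {
  m <- make_clonal(N = 4)
  ch <- demographic_chain(m)
  phi <- solve_rv(m, ch, probe_starts = 2)
  expect_equal(as.numeric(phi$values), rep(1 / 4, nrow(phi$values)),
               tolerance = 1e-12)
  f <- matrix(1 / 4, nrow(phi$values), 1,
              dimnames = dimnames(phi$values))
  expect_equal(apply_T(f, ch), f, tolerance = 1e-15)
})

test_that("power iteration agrees with the direct constrained linear solve", {
  p1 <- solve_rv(hd_model, hd_chain, method = "power", probe_starts = 0)
  p2 <- solve_rv(hd_model, hd_chain, method = "direct", probe_starts = 0)
  expect_lt(max(abs(p1$values - p2$values)), 1e-10)
  expect_lt(p1$residual, 1e-12)
  expect_lt(p2$residual, 1e-10)
})

test_that("solved reproductive value sums to one over every state", {
  N <- rvprice:::state_counts(hd_chain)
  L <- hd_model$ploidy[colnames(N)]
  sums <- rowSums(hd_phi$values * sweep(N, 2, L, "*"))
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("lineage matrices satisfy the recursion and path-sum product form", {
  traj <- simulate_neutral(hd_model, 6, seed = 2, chain = hd_full)
  classes <- hd_model$classes
  expect_equal(lineage_matrix(traj, 2, 2), diag(2),
               ignore_attr = TRUE)
  # one step: the L_y-weighted realized u matrix
  L <- hd_model$ploidy[classes]
  U0 <- traj$records[[1]]$U
  expect_equal(lineage_matrix(traj, 0, 1), L * U0, ignore_attr = TRUE)
  # two steps: explicit path sum over intermediate classes
  U1 <- traj$records[[2]]$U
  C2 <- lineage_matrix(traj, 0, 2)
  for (x in classes) for (z in classes) {
    # path sum: over intermediate class y, (L_x u^x_y) * (L_y u^y_z)
    ps <- sum(vapply(classes, function(y)
      L[[x]] * U0[x, y] * L[[y]] * U1[y, z], 0))
    expect_equal(C2[x, z], ps, tolerance = 1e-12)
  }
  expect_error(lineage_matrix(traj, 0, 10), "outside trajectory")
})

test_that("descendant reproductive value starts at phi and totals one", {
  traj <- simulate_neutral(hd_model, 4, seed = 9, chain = hd_full)
  r0 <- traj$records[[1]]
  R0 <- descendant_rv(traj, hd_phi, 0)
  d0 <- demographic_tally(r0$tally)
  phi_x <- vapply(hd_model$classes, function(x)
    hd_model$ploidy[[x]] * rv_at(hd_phi, x, r0$env, d0), 0)
  expect_equal(R0, as.numeric(phi_x), tolerance = 1e-12)
  expect_equal(sum(d0[hd_model$classes] * R0), 1, tolerance = 1e-12)
  # t = 3: recompute directly from raw realized shares
  R3 <- descendant_rv(traj, hd_phi, 3)
  C <- diag(2); dimnames(C) <- list(hd_model$classes, hd_model$classes)
  L <- hd_model$ploidy[hd_model$classes]
  for (k in 0:2) C <- C %*% (L * traj$records[[k + 1]]$U)
  r3 <- traj$records[[4]]
  dkey <- state_key(r3$env, demographic_tally(r3$tally))
  v <- L * hd_phi$values[dkey, hd_model$classes]
  expect_equal(R3, as.numeric(C %*% v), tolerance = 1e-12)
})

test_that("martingale residual vanishes exactly by full history enumeration", {
  # clonal: residual exactly zero
  m <- make_clonal(N = 2)
  ch <- demographic_chain(m)
  phi <- solve_rv(m, ch, probe_starts = 0)
  expect_equal(as.numeric(verify_martingale(m, phi, 0, 0, chain = ch)), 0)
  # two-class fixture, horizons within 3 years
  for (tl in list(c(0, 0), c(0, 1), c(1, 1))) {
    res <- verify_martingale(hd_model, hd_phi, tl[1], tl[2], chain = hd_chain)
    expect_lt(as.numeric(res), 1e-10)
  }
  # age fixture, horizon 3
  ma <- make_age_density()
  cha <- demographic_chain(ma)
  phia <- solve_rv(ma, cha, probe_starts = 0)
  expect_lt(as.numeric(verify_martingale(ma, phia, 0, 2, chain = cha)), 1e-10)
})

test_that("Monte Carlo martingale residual is within 3 standard errors of 0", {
  # the age fixture from a mixed-age state has genuinely stochastic R
  ma <- make_age_density()
  cha <- demographic_chain(ma)
  phia <- solve_rv(ma, cha, probe_starts = 0)
  res <- verify_martingale(ma, phia, 0, 1, mode = "mc", chain = cha,
                           start = "e1::A=1,J=1", reps = 4000, seed = 13)
  expect_gt(max(res$se), 1e-6)   # non-degenerate: R really varies
  expect_true(all(abs(res$z) <= 3))
  expect_true(all(res$ci[, "lower"] <= 0 & 0 <= res$ci[, "upper"]))
  # the haplodiploid fixture conserves class totals realization-wise, so its
  # martingale is exact along every path
  degen <- verify_martingale(hd_model, hd_phi, 0, 1, mode = "mc",
                             chain = hd_chain, reps = 500, seed = 13)
  expect_true(all(degen$z == 0))
})

test_that("unreachable states are refused by the reproductive-value lookup", {
  expect_error(rv_at(hd_phi, "F", "e1", c(F = 5, M = 5)), "not in the")
})
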