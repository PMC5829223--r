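# Weighted population statistics, p-scores, delta-star and breeding values.

test_that("weighted moments reduce to ordinary moments and match longhand", {
  f <- c(1, 4, 2, 8); g <- c(0, 1, 1, 0); w <- rep(1, 4)
  expect_equal(weighted_ave(w, f), mean(f))
  expect_equal(weighted_cov(w, f, g), mean(f * g) - mean(f) * mean(g))
  expect_equal(weighted_var(w, rep(3, 4)), 0)
  # longhand weighted covariance
  w2 <- c(0.1, 0.2, 0.3, 0.4)
  mu_f <- sum(w2 * f) / sum(w2); mu_g <- sum(w2 * g) / sum(w2)
  expect_equal(weighted_cov(w2, f, g),
               sum(w2 * (f - mu_f) * (g - mu_g)) / sum(w2))
  expect_equal(weighted_cov(w2, f, f), weighted_var(w2, f))
  expect_error(weighted_ave(c(0, 0), f[1:2]), "positive total")
  expect_error(weighted_ave(c(-1, 2), f[1:2]), "nonnegative")
})

test_that("p-scores follow allele dosages and class means", {
  pop <- population_state(c("F", "F", "M"), c("ab", "aa", "b"))
  ps <- pscore(c(a = 1), pop, hd_model)
  expect_equal(ps$p, c(1 / 2, 1, 0))  # heterozygote dosage 1/2
  expect_equal(as.numeric(ps$class_means[c("F", "M")]), c(3 / 4, 0))
  # multi-allele weighted sum against hand dosage arithmetic
  ps2 <- pscore(c(a = 2, b = -1), pop, hd_model)
  expect_equal(ps2$p, c(2 * 0.5 - 1 * 0.5, 2, -1))
  expect_error(pscore(c(zz = 1), pop, hd_model), "unknown allele")
  # reproductive-value-weighted mean equals sum p_i phi_i
  d <- demographic_tally(pop)
  phi_i <- rvprice:::individual_rv(hd_phi, hd_model, "e1", pop)
  expect_equal(weighted_ave(phi_i, ps$p) * sum(phi_i), sum(ps$p * phi_i))
})

test_that("delta-star is zero under exact self-replication", {
  m <- make_clonal(N = 3)
  ch <- demographic_chain(m)
  phi <- solve_rv(m, ch, probe_starts = 0)
  pop <- rvprice:::canonical_population(m, m$initial$tally)
  ent <- enumerate_year(m, "e1", pop)[[1]]
  expect_equal(delta_star(c(k0 = 1), m, "e1", pop, phi, ent), 0,
               tolerance = 1e-12)
})

test_that("delta-star matches the two-genotype doubling oracle", {
  # clonal base model; in the Taylor year phenotype "a1" doubles and the
  # background dies (kernel consults phenotype only)
  m <- make_clonal(N = 2)
  m$genotypes <- c("g0", "g1")
  m$dosage <- matrix(c(1, 0, 0, 1), 2, 2,
                     dimnames = list(c("g0", "g1"), c("k0", "k1")))
  m$alleles <- c("k0", "k1"); m$loci <- list(locus1 = c("k0", "k1"))
  m$initial$tally <- c(`A|g0` = 1L, `A|g1` = 1L)
  m$bound <- 2
  m$kernel <- function(e, pop, model) {
    shares <- lapply(seq_len(nrow(pop)), function(i) {
      n_off <- if (pop$phenotype[i] == "a1") 2 else
        if (all(pop$phenotype == "a0")) 1 else 0
      if (n_off == 0) stats::setNames(numeric(0), character(0))
      else stats::setNames(n_off, cg_key(pop$class[i], pop$genotype[i]))
    })
    list(list(prob = 1, shares = shares))
  }
  ch <- demographic_chain(m)
  phi <- solve_rv(m, ch, probe_starts = 0)   # 1/2 everywhere
  h <- phenotype_map(c(`A|g1` = "a1"), "a0")
  pop <- apply_phenotypes(rvprice:::canonical_population(m, m$initial$tally),
                          h, m)
  ent <- enumerate_year(m, "e1", pop)[[1]]
  # hand oracle: weighted mean moves from (p_g0 + p_g1)/2 to p-score of g1
  lam <- c(k1 = 1)
  expect_equal(delta_star(lam, m, "e1", pop, phi, ent), 1 - 1 / 2,
               tolerance = 1e-12)
  # linearity in lambda
  lam_a <- c(k0 = 0.7, k1 = -0.2); lam_b <- c(k0 = -1, k1 = 3)
  d_ab <- delta_star(c(k0 = 0.7 - 1, k1 = -0.2 + 3), m, "e1", pop, phi, ent)
  expect_equal(d_ab,
               delta_star(lam_a, m, "e1", pop, phi, ent) +
                 delta_star(lam_b, m, "e1", pop, phi, ent),
               tolerance = 1e-12)
})

test_that("breeding values satisfy projection and normal-equation identities", {
  pop <- rvprice:::canonical_population(
    hd_model, c(`F|aa` = 1L, `F|ab` = 1L, `M|b` = 1L))
  w <- rvprice:::individual_rv(hd_phi, hd_model, "e1", pop)
  # a target already a p-score is reproduced exactly
  ps <- pscore(c(a = 2, b = -1), pop, hd_model)
  bv <- breeding_values(ps$p, pop, hd_model, w)
  expect_equal(bv$beta, ps$p, tolerance = 1e-10)
  # a target phi-orthogonal to all dosage columns projects to zero
  X <- hd_model$dosage[pop$genotype, , drop = FALSE]
  t0 <- c(1, -1, 0.5)
  t_orth <- t0 - X %*% solve(t(X) %*% (w * X), t(X) %*% (w * t0))
  bv0 <- breeding_values(as.numeric(t_orth), pop, hd_model, w)
  expect_lt(max(abs(bv0$beta)), 1e-10)
  # normal equations: centred target => ave_phi beta = 0 and
  # ave_phi(beta * target) = ave_phi(beta^2)
  tc <- t0 - sum(w * t0) / sum(w)
  bvc <- breeding_values(tc, pop, hd_model, w)
  expect_lt(abs(sum(w * bvc$beta) / sum(w)), 1e-10)
  expect_equal(sum(w * bvc$beta * tc), sum(w * bvc$beta^2), tolerance = 1e-10)
})

test_that("breeding values match an independent pseudoinverse oracle", {
  skip_if_not_installed("MASS")
  pop <- rvprice:::canonical_population(
    hd_model, c(`F|ab` = 2L, `M|a` = 1L))
  w <- rvprice:::individual_rv(hd_phi, hd_model, "e2", pop)
  targ <- c(0.3, -0.1, 0.6)
  bv <- breeding_values(targ, pop, hd_model, w)
  X <- hd_model$dosage[pop$genotype, , drop = FALSE]
  A <- sqrt(w) * X
  lam_or <- as.numeric(MASS::ginv(A) %*% (sqrt(w) * targ))
  expect_equal(as.numeric(X %*% lam_or), bv$beta, tolerance = 1e-9)
})
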