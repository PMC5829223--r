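# The Taylor year: Williams' reproductive value, fitness conventions, and
# exact expected fitness.

test_that("Williams' reproductive value reproduces the age-class example", {
  # age-10 diploid, survival 0.9 into class 11, three diploid offspring in
  # class 0 (expectation form): W = 0.9 v11 + (3/2) v0
  shares <- c(`11` = 0.9 * (1 / 2), `0` = 3 * (1 / 4))
  expect_equal(williams_rv(2, shares, c(`11` = 1, `0` = 0)), 0.9)
  expect_equal(williams_rv(2, shares, c(`11` = 0, `0` = 1)), 1.5)
  expect_equal(williams_rv(2, numeric(0), c(`11` = 1, `0` = 1)), 0)
})

test_that("Williams' value has no tendency to increase with ploidy", {
  v <- c(A = 0.4, B = 0.1)
  s <- c(`A|g` = 0.5, `B|g` = 0.25)
  expect_equal(williams_rv(2, s, v), williams_rv(4, s / 2, v))
})

test_that("fitness follows Fisher's relative definition with flagged edge cases", {
  expect_equal(fitness(0.3, 0.3)$value, 0)
  expect_equal(fitness(0.6, 0.3)$value, 1)
  f <- fitness(0.3, 0)
  expect_true(is.infinite(f$value) && f$flag)
  f0 <- fitness(0, 0)
  expect_true(f0$value == 0 && f0$flag)
  expect_error(fitness(-1, 0.5), "nonnegative")
})

test_that("realized Williams' value matches a term-by-term hand sum", {
  set.seed(21)
  pop <- apply_phenotypes(
    rvprice:::canonical_population(hd_model, c(`F|ab` = 1L, `M|a` = 1L)),
    h_haplodiploid_selective(), hd_model)
  realized <- realize_year(hd_model, "e1", pop)
  recs <- fitness_records(hd_model, "e1", pop, hd_phi, realized)
  for (i in seq_len(nrow(pop))) {
    s <- realized$shares[[i]]
    hand <- 0
    for (k in seq_along(s)) {
      cls <- cg_class(names(s)[k])
      hand <- hand + s[[k]] * hd_model$ploidy[[cls]] *
        rv_at(hd_phi, cls, realized$e_next, realized$d_next)
    }
    hand <- hd_model$ploidy[[pop$class[i]]] * hand
    expect_equal(recs$W[i], hand, tolerance = 1e-12)
  }
})

test_that("the phi-weighted mean of realized fitness is zero in every realization", {
  h <- h_haplodiploid_selective()
  for (key in hd_full$states$key[c(1, 9, 17, 30)]) {
    st <- parse_state_key(key)
    pop <- apply_phenotypes(rvprice:::canonical_population(hd_model, st$tally),
                            h, hd_model)
    for (ent in enumerate_year(hd_model, st$env, pop)) {
      recs <- fitness_records(hd_model, st$env, pop, hd_phi, ent)
      expect_lt(abs(attr(recs, "ave_phi_fitness")), 1e-10)
    }
  }
})

test_that("expected fitness vanishes under the background phenotype", {
  for (key in hd_full$states$key) {
    st <- parse_state_key(key)
    pop <- apply_phenotypes(rvprice:::canonical_population(hd_model, st$tally),
                            background_map(hd_model), hd_model)
    ef <- expected_fitness(hd_model, st$env, pop, hd_phi)
    expect_lt(max(abs(ef$expected_fitness)), 1e-10)
  }
})

test_that("selective expected fitness matches a brute-force oracle", {
  h <- h_haplodiploid_selective()
  st <- list(env = "e2", tally = c(`F|aa` = 1L, `F|ab` = 1L, `M|b` = 1L))
  pop <- apply_phenotypes(rvprice:::canonical_population(hd_model, st$tally),
                          h, hd_model)
  ef <- expected_fitness(hd_model, st$env, pop, hd_phi)
  # oracle: raw kernel enumeration with explicit next-state reconstruction
  outs <- hd_model$kernel(st$env, pop, hd_model)
  phi_i <- rvprice:::individual_rv(hd_phi, hd_model, st$env, pop)
  for (i in seq_len(nrow(pop))) {
    acc <- 0
    for (o in outs) for (e2 in hd_model$env_states) {
      tab <- numeric(0)
      for (j in seq_along(o$shares)) {
        s <- o$shares[[j]]
        L <- hd_model$ploidy[[pop$class[j]]]
        for (k in seq_along(s))
          tab[names(s)[k]] <- (if (names(s)[k] %in% names(tab))
            tab[[names(s)[k]]] else 0) + L * s[k]
      }
      dt <- demographic_tally(stats::setNames(as.integer(round(tab)), names(tab)))
      s <- o$shares[[i]]
      W <- 0
      for (k in seq_along(s)) {
        cls <- cg_class(names(s)[k])
        W <- W + s[[k]] * hd_model$ploidy[[cls]] *
          rv_at(hd_phi, cls, e2, dt)
      }
      W <- hd_model$ploidy[[pop$class[i]]] * W
      acc <- acc + o$prob * hd_model$Pi[st$env, e2] * W
    }
    expect_equal(ef$numerator[i], acc - phi_i[i], tolerance = 1e-12)
    expect_equal(ef$expected_fitness[i], (acc - phi_i[i]) / phi_i[i],
                 tolerance = 1e-12)
  }
  # selection is actually present at this state
  expect_gt(max(abs(ef$expected_fitness)), 1e-6)
})

test_that("Taylor initialization is seed-reproducible and h-validated", {
  h <- h_haplodiploid_selective()
  a <- initialize_taylor(hd_model, hd_D, h, seed = 5)
  b <- initialize_taylor(hd_model, hd_D, h, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$population$phenotype %in% hd_model$phenotypes))
  # phenotype depends only on own class and genotype
  expect_equal(a$population$phenotype,
               h(a$population$class, a$population$genotype))
  h_bad <- function(class, genotype) rep("nope", length(class))
  expect_error(initialize_taylor(hd_model, hd_D, h_bad, seed = 5),
               "undefined|out of range")
})

test_that("background map makes the Taylor year match the neutral step", {
  st <- hd_model$initial
  pop0 <- rvprice:::canonical_population(hd_model, st$tally)
  pop_h <- apply_phenotypes(pop0, background_map(hd_model), hd_model)
  ents0 <- enumerate_year(hd_model, st$env, pop0)
  ents1 <- enumerate_year(hd_model, st$env, pop_h)
  expect_equal(vapply(ents0, function(x) x$prob, 0),
               vapply(ents1, function(x) x$prob, 0))
  expect_equal(lapply(ents0, function(x) x$tab),
               lapply(ents1, function(x) x$tab))
})
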