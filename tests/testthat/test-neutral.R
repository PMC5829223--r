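# The neutral process: one-year step distributions, exact chains, the
# ergodic distribution, and simulation.

test_that("clonal step distribution reduces to the environment chain", {
  sk <- step_kernel(clonal3, "e1", c(A = 3))
  expect_equal(sum(sk$prob), 1)
  expect_equal(sort(sk$env), sort(clonal3$env_states))
  for (i in seq_len(nrow(sk)))
    expect_equal(sk$prob[i], clonal3$Pi["e1", sk$env[i]])
  expect_true(all(sk$tally_key == "A=3"))
})

test_that("two-class step distribution matches a brute-force kernel oracle", {
  # oracle: call the raw kernel and hand-tabulate next demographic states
  m <- hd_model
  pop <- rvprice:::demographic_population(m, c(F = 1, M = 1))
  outs <- m$kernel("e1", pop, m)
  oracle <- new.env()
  for (o in outs) {
    tab <- numeric(0)
    for (i in seq_along(o$shares)) {
      s <- o$shares[[i]]
      L <- m$ploidy[[pop$class[i]]]
      for (k in seq_along(s)) {
        nm <- names(s)[k]
        tab[nm] <- (if (nm %in% names(tab)) tab[[nm]] else 0) + L * s[k]
      }
    }
    dt <- demographic_tally(stats::setNames(as.integer(round(tab)), names(tab)))
    for (e2 in m$env_states) {
      key <- state_key(e2, dt)
      prev <- if (is.null(oracle[[key]])) 0 else oracle[[key]]
      oracle[[key]] <- prev + o$prob * m$Pi["e1", e2]
    }
  }
  sk <- step_kernel(m, "e1", c(F = 1, M = 1))
  expect_equal(sum(sk$prob), 1)
  for (i in seq_len(nrow(sk)))
    expect_equal(sk$prob[i], oracle[[sk$key[i]]], tolerance = 1e-12)
})

test_that("demographic chain rows equal step_kernel outputs", {
  ch <- hd_chain
  for (key in ch$states$key) {
    st <- parse_state_key(key)
    sk <- step_kernel(hd_model, st$env, st$tally)
    row <- ch$P[key, ]
    for (i in seq_len(nrow(sk)))
      expect_equal(row[[sk$key[i]]], sk$prob[i], tolerance = 1e-12)
    expect_equal(sum(row), 1, tolerance = 1e-12)
  }
})

test_that("genotype dynamics never alter the demographic chain", {
  # project the full chain onto demographic states and compare
  full <- hd_full
  proj_key <- vapply(full$states$key, function(k) {
    st <- parse_state_key(k)
    state_key(st$env, demographic_tally(st$tally))
  }, "")
  D <- hd_D
  # stationary of the projected full chain vs stationary of demographic chain
  d_from_full <- tapply(D$prob, proj_key, sum)
  d_direct <- ergodic_distribution(hd_chain)$prob
  expect_equal(sort(names(d_from_full)), sort(names(d_direct)))
  expect_equal(as.numeric(d_from_full[names(d_direct)]),
               as.numeric(d_direct), tolerance = 1e-10)
})

test_that("ergodic distribution matches the two-state closed form", {
  Pi <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE,
               dimnames = list(c("e1", "e2"), c("e1", "e2")))
  m <- make_clonal(N = 2, Pi = Pi)
  d <- ergodic_distribution(demographic_chain(m))
  # closed form for a 2-state chain with off-diagonals p, q: (q, p)/(p+q)
  expect_equal(as.numeric(d$prob[["e1::A=2"]]), 0.4 / 0.7, tolerance = 1e-12)
  expect_equal(as.numeric(d$prob[["e2::A=2"]]), 0.3 / 0.7, tolerance = 1e-12)
  # doubly stochastic: uniform
  m2 <- make_clonal(N = 2, Pi = matrix(0.5, 2, 2, dimnames = dimnames(Pi)))
  d2 <- ergodic_distribution(demographic_chain(m2))
  expect_equal(as.numeric(d2$prob), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("ergodic distribution is a fixed point of the step kernel", {
  D <- hd_D
  expect_lt(max(abs(as.numeric(D$prob %*% hd_full$P) - D$prob)), 1e-12)
})

test_that("non-ergodic chains are rejected with diagnostics", {
  # deterministic alternation between environments -> period 2
  Pi <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("e1", "e2"), c("e1", "e2")))
  m <- make_clonal(N = 2, Pi = Pi)
  expect_error(ergodic_distribution(demographic_chain(m)), "periodic")
})

test_that("simulation is seed-reproducible and mutation follows reproduction", {
  t1 <- simulate_neutral(hd_model, 50, seed = 7, chain = hd_full)
  t2 <- simulate_neutral(hd_model, 50, seed = 7, chain = hd_full)
  expect_identical(trajectory_table(t1), trajectory_table(t2))
  t3 <- simulate_neutral(hd_model, 50, seed = 8, chain = hd_full)
  expect_false(identical(trajectory_table(t1), trajectory_table(t3)))
  # mutation happens after reproduction: the recorded pre-mutation tally has
  # the same demographic projection as the next year's (post-mutation) state
  for (t in 1:49) {
    r <- t1$records[[t]]
    expect_equal(demographic_tally(r$pre_mutation),
                 demographic_tally(t1$records[[t + 1]]$tally))
  }
})

test_that("long-run state frequencies converge to the exact stationary", {
  years <- 20000
  traj <- simulate_neutral(hd_model, years, seed = 11, chain = hd_full)
  keys <- vapply(traj$records[-1], function(r) r$key, "")
  emp <- table(factor(keys, levels = names(hd_D$prob))) / years
  # 3 iid standard errors inflated x3 for autocorrelation
  tol <- 9 * sqrt(pmax(hd_D$prob * (1 - hd_D$prob), 1e-6) / years)
  expect_true(all(abs(as.numeric(emp) - hd_D$prob) < pmax(tol, 0.01)))
})
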