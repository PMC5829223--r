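# The neutral (background-phenotype) process as an exact Markov chain on small
# state spaces, in two modes: demographic (class tallies only; enough for the
# transition operator and reproductive value) and full (class x genotype
# tallies including mutation; needed for the ergodic distribution that seeds
# the Taylor year).

#' One-year step distribution of the neutral process
#'
#' Enumerates the finite kernel support and the environment transition at a
#' demographic or full state, under the uniform background phenotype.
#'
#' @param model a validated reproduction model.
#' @param e current environment.
#' @param tally current state tally: class counts (`mode = "demographic"`,
#'   genotype dynamics ignored, justified by genotype-through-phenotype) or
#'   `"class|genotype"` counts (`mode = "full"`, mutation included).
#' @param mode `"demographic"` or `"full"`.
#' @return A data frame with columns `env`, `key` (state key), `tally_key` and
#'   `prob`, summing to one.
#' @export
step_kernel <- function(model, e, tally, mode = c("demographic", "full")) {
  mode <- match.arg(mode)
  tally <- canon_tally(tally)
  if (mode == "demographic") {
    pop <- demographic_population(model, tally)
    ents <- enum_transitions(model, e, pop)
    keys <- vapply(ents, function(x) state_key(x$e_next, x$d_next), "")
    envs <- vapply(ents, function(x) x$e_next, "")
    tks <- vapply(ents, function(x) tally_key(x$d_next), "")
    probs <- vapply(ents, function(x) x$prob, 0)
  } else {
    pop <- canonical_population(model, tally)
    ents <- enum_transitions(model, e, pop)
    keys <- character(0); envs <- character(0); tks <- character(0); probs <- numeric(0)
    for (ent in ents) {
      for (m in enum_mutation(model, ent$tab)) {
        keys <- c(keys, state_key(ent$e_next, m$tally))
        envs <- c(envs, ent$e_next)
        tks <- c(tks, tally_key(m$tally))
        probs <- c(probs, ent$prob * m$prob)
      }
    }
  }
  agg <- tapply(probs, keys, sum)
  i <- match(names(agg), keys)
  data.frame(env = envs[i], key = names(agg), tally_key = tks[i],
             prob = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname cg_key
#' @param tk,key key strings.
#' @export
parse_tally_key <- function(tk) {
  if (tk == "") return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(strsplit(tk, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.integer(p[[2]]), 0L),
                  vapply(parts, function(p) p[[1]], ""))
}

#' @rdname cg_key
#' @export
parse_state_key <- function(key) {
  sp <- regmatches(key, regexpr("::", key, fixed = TRUE), invert = TRUE)[[1]]
  list(env = sp[[1]], tally = parse_tally_key(sp[[2]]))
}

#' Exact demographic chain of the neutral process
#'
#' Builds the reachable closure of (environment, class tally) states from the
#' model's seed state and the per-state move tables (outcome probability,
#' realized class-mean offspring matrix u, next state) needed by the transition
#' operator and the martingale checks, plus the row-stochastic transition
#' matrix.
#'
#' @param model a reproduction model.
#' @param state_cap maximum number of reachable states before erroring (larger
#'   instances should use the Monte Carlo modes).
#' @return An object of class `demographic_chain` with elements `states` (data
#'   frame `key`, `env`, `tally_key`), `moves` (per-state list of entries with
#'   `prob`, `e_next`, `key_next`, `U`) and `P`.
#' @export
demographic_chain <- function(model, state_cap = 500) {
  seed <- state_key(model$initial$env, demographic_tally(model$initial$tally))
  frontier <- seed
  seen <- character(0)
  moves <- list()
  while (length(frontier)) {
    key <- frontier[[1]]; frontier <- frontier[-1]
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(seen) > state_cap)
      stop("demographic chain exceeds state_cap = ", state_cap,
           "; consider Monte Carlo mode")
    st <- parse_state_key(key)
    pop <- demographic_population(model, st$tally)
    ents <- enum_transitions(model, st$env, pop)
    # aggregate outcomes with identical (e', next tally, U)
    mv <- list()
    for (ent in ents) {
      k2 <- state_key(ent$e_next, ent$d_next)
      mk <- paste(k2, paste(signif(ent$U, 12), collapse = ","), sep = "#")
      if (is.null(mv[[mk]]))
        mv[[mk]] <- list(prob = 0, e_next = ent$e_next, key_next = k2, U = ent$U)
      mv[[mk]]$prob <- mv[[mk]]$prob + ent$prob
      if (!(k2 %in% c(seen, frontier))) frontier <- c(frontier, k2)
    }
    moves[[key]] <- unname(mv)
  }
  keys <- sort(seen)
  P <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  for (key in keys) for (mv in moves[[key]])
    P[key, mv$key_next] <- P[key, mv$key_next] + mv$prob
  states <- data.frame(
    key = keys,
    env = vapply(keys, function(k) parse_state_key(k)$env, ""),
    tally_key = vapply(keys, function(k) tally_key(parse_state_key(k)$tally), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = model, states = states, moves = moves, P = P,
                 mode = "demographic"),
            class = "demographic_chain")
}

#' Exact full (genotype-inclusive) chain of the neutral process
#'
#' Like [demographic_chain()] but on (environment, class x genotype tally)
#' states, with reproduction followed by mutation. Mutation keeps the genotype
#' structure irreducible, so this chain carries the ergodic distribution used
#' to seed the Taylor year.
#'
#' @inheritParams demographic_chain
#' @return An object of class `ensemble_chain` with `states`, `P`, and
#'   per-state reproduction entries `trans` (before mutation) for simulation.
#' @export
ensemble_chain <- function(model, state_cap = 2000) {
  seed <- state_key(model$initial$env, model$initial$tally)
  frontier <- seed
  seen <- character(0)
  trans <- list()
  P_rows <- list()
  while (length(frontier)) {
    key <- frontier[[1]]; frontier <- frontier[-1]
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(seen) > state_cap)
      stop("full chain exceeds state_cap = ", state_cap,
           "; consider Monte Carlo mode")
    st <- parse_state_key(key)
    pop <- canonical_population(model, st$tally)
    ents <- enum_transitions(model, st$env, pop)
    row <- numeric(0)
    for (ent in ents) {
      for (m in enum_mutation(model, ent$tab)) {
        k2 <- state_key(ent$e_next, m$tally)
        row[k2] <- (if (k2 %in% names(row)) row[[k2]] else 0) + ent$prob * m$prob
        if (!(k2 %in% c(seen, frontier))) frontier <- c(frontier, k2)
      }
    }
    trans[[key]] <- ents
    P_rows[[key]] <- row
  }
  keys <- sort(seen)
  P <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  for (key in keys) P[key, names(P_rows[[key]])] <- P_rows[[key]]
  states <- data.frame(
    key = keys,
    env = vapply(keys, function(k) parse_state_key(k)$env, ""),
    tally_key = vapply(keys, function(k) tally_key(parse_state_key(k)$tally), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = model, states = states, P = P, trans = trans,
                 mode = "full"),
            class = "ensemble_chain")
}

# Strongly connected components via boolean transitive closure; state spaces
# here are small (hundreds at most), so O(n^3) is fine and hard to get wrong.
scc_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n))
    reach <- reach | (outer(reach[, k], reach[k, ], "&"))
  mutual <- reach & t(reach)
  comp <- integer(n); cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    comp[mutual[v, ]] <- cid
  }
  comp
}

chain_period <- function(adj, members) {
  # gcd over edges within the recurrent class of (level[u] + 1 - level[v])
  lev <- rep(NA_integer_, nrow(adj))
  start <- members[[1]]
  lev[start] <- 0L
  q <- c(start)
  while (length(q)) {
    u <- q[[1]]; q <- q[-1]
    for (v in intersect(which(adj[u, ]), members))
      if (is.na(lev[v])) { lev[v] <- lev[u] + 1L; q <- c(q, v) }
  }
  g <- 0L
  for (u in members) for (v in intersect(which(adj[u, ]), members)) {
    d <- abs(lev[u] + 1L - lev[v])
    g <- if (g == 0L) d else .gcd_vec(g, d)
  }
  if (g == 0L) 1L else g
}

#' Stationary (ergodic) distribution of an exact chain
#'
#' Solves for the unique stationary distribution of the chain's transition
#' matrix. Instances with multiple recurrent classes or a periodic recurrent
#' class are rejected with diagnostics, since the theory assumes the neutral
#' process tends to an ergodic distribution.
#'
#' @param chain a [demographic_chain()] or [ensemble_chain()].
#' @param tol residual tolerance for the balance equations.
#' @return An object of class `ergodic_distribution`: list with `states`,
#'   `prob` (named numeric summing to one) and `chain`.
#' @export
ergodic_distribution <- function(chain, tol = 1e-12) {
  P <- chain$P
  n <- nrow(P)
  adj <- P > 0
  comp <- scc_components(adj)
  recurrent <- integer(0)
  for (cid in unique(comp)) {
    inside <- comp == cid
    if (!any(adj[inside, !inside, drop = FALSE])) recurrent <- c(recurrent, cid)
  }
  if (length(recurrent) != 1)
    stop("chain has ", length(recurrent), " recurrent classes; ",
         "the neutral process is assumed ergodic (components: ",
         paste(unique(comp), collapse = ","), ")")
  members <- which(comp == recurrent)
  per <- chain_period(adj, members)
  if (per != 1)
    stop("recurrent class is periodic with period ", per,
         "; the neutral process is assumed ergodic")
  if (n <= 2000) {
    A <- rbind(t(P) - diag(n), rep(1, n))
    b <- c(rep(0, n), 1)
    pi_hat <- qr.solve(A, b)
  } else {
    pi_hat <- rep(1 / n, n)
    for (it in seq_len(100000)) {
      nxt <- as.numeric(pi_hat %*% P)
      if (max(abs(nxt - pi_hat)) < tol) { pi_hat <- nxt; break }
      pi_hat <- nxt
    }
  }
  pi_hat[abs(pi_hat) < 1e-15] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  resid <- max(abs(as.numeric(pi_hat %*% P) - pi_hat))
  if (resid > max(tol, 1e-10))
    stop("stationary solve residual ", format(resid), " exceeds tolerance")
  structure(list(states = chain$states, prob = stats::setNames(pi_hat, rownames(P)),
                 chain = chain, residual = resid),
            class = "ergodic_distribution")
}

#' @export
print.ergodic_distribution <- function(x, ...) {
  cat("<ergodic_distribution> over", length(x$prob), "states; residual",
      format(x$residual), "\n")
  invisible(x)
}

#' Simulate the neutral process
#'
#' Iterates the neutral recursion (reproduction at the background phenotype,
#' then mutation) for a number of years, recording for each year the
#' environment, state, realized class-mean offspring matrix and pre-/post-
#' mutation genotype tallies. Per-year RNG substreams are derived from the
#' root seed so trajectories are reproducible and extendable.
#'
#' @param model a reproduction model.
#' @param years number of years to simulate.
#' @param seed integer root seed.
#' @param chain optionally a prebuilt [ensemble_chain()] (reused across calls
#'   for speed).
#' @return An object of class `trajectory`: a list with `records` (one per
#'   year `0..years`, each with `env`, `key`, `tally`, and for all but the
#'   last year `U`, `pre_mutation` tally and `outcome` index) and `model`.
#' @export
simulate_neutral <- function(model, years, seed, chain = NULL) {
  years <- as.integer(years)
  if (is.null(chain)) chain <- ensemble_chain(model)
  set.seed(seed)
  year_seeds <- sample.int(.Machine$integer.max - 1L, years)
  key <- state_key(model$initial$env, model$initial$tally)
  records <- vector("list", years + 1)
  for (t in seq_len(years)) {
    set.seed(year_seeds[[t]])
    st <- parse_state_key(key)
    ents <- chain$trans[[key]]
    probs <- vapply(ents, function(x) x$prob, 0)
    j <- sample.int(length(ents), 1L, prob = probs)
    ent <- ents[[j]]
    # mutation: independent per individual of the pre-mutation population
    pre <- ent$tab
    slots <- rep(names(pre), pre)
    post <- stats::setNames(integer(0), character(0))
    for (slot in slots) {
      d <- mutation_dist(model, cg_genotype(slot), cg_class(slot))
      g2 <- names(d)[sample.int(length(d), 1L, prob = d)]
      nm <- cg_key(cg_class(slot), g2)
      post[nm] <- (if (nm %in% names(post)) post[[nm]] else 0L) + 1L
    }
    post <- canon_tally(post)
    records[[t]] <- list(year = t - 1L, env = st$env, key = key,
                         tally = st$tally, U = ent$U,
                         pre_mutation = pre, outcome = j)
    key <- state_key(ent$e_next, post)
  }
  st <- parse_state_key(key)
  records[[years + 1]] <- list(year = years, env = st$env, key = key,
                               tally = st$tally)
  structure(list(records = records, model = model, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$records) - 1, "years of the neutral process\n")
  invisible(x)
}

#' Export a trajectory as a data frame
#'
#' @param trajectory a [simulate_neutral()] trajectory.
#' @return Data frame with one row per year: `year`, `env`, `tally_key`, and
#'   `pre_mutation_key` where available.
#' @export
trajectory_table <- function(trajectory) {
  recs <- trajectory$records
  data.frame(
    year = vapply(recs, function(r) r$year, 0L),
    env = vapply(recs, function(r) r$env, ""),
    tally_key = vapply(recs, function(r) tally_key(r$tally), ""),
    pre_mutation_key = vapply(recs, function(r)
      if (is.null(r$pre_mutation)) NA_character_ else tally_key(r$pre_mutation), ""),
    stringsAsFactors = FALSE)
}
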