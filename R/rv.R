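# Reproductive value: the candidate set Z, the transition operator T, its
# fixed point phi*, lineage shares, and the martingale property.
#
# A candidate reproductive-value function assigns a nonnegative per-haploid-set
# value to each (class, environment, class tally), vanishing on empty classes,
# with ploidy-weighted population sum 1 at every state. It is represented as a
# matrix over the reachable states of a demographic chain (rows = state keys,
# columns = classes); keying by tally rather than by ordered class arrays
# builds in the permutation clause.

rv_function <- function(values, chain, residual = NA_real_, iterations = NA_integer_,
                        method = NA_character_, diagnostics = list()) {
  structure(list(values = values, chain = chain, residual = residual,
                 iterations = iterations, method = method,
                 diagnostics = diagnostics),
            class = "rv_function")
}

#' @export
print.rv_function <- function(x, ...) {
  cat("<rv_function> per-haploid-set reproductive value on",
      nrow(x$values), "states x", ncol(x$values), "classes\n")
  if (!is.na(x$residual))
    cat("  fixed-point residual:", format(x$residual),
        " method:", x$method, "\n")
  invisible(x)
}

state_counts <- function(chain) {
  # matrix states x classes of class counts n(x, state)
  keys <- chain$states$key
  classes <- chain$model$classes
  N <- matrix(0L, length(keys), length(classes), dimnames = list(keys, classes))
  for (k in keys) {
    tal <- parse_state_key(k)$tally
    # demographic chains key by class; full chains by class|genotype
    d <- if (all(names(tal) %in% classes)) tal else demographic_tally(tal)
    N[k, names(d)] <- d
  }
  N
}

#' Per-haploid-set reproductive value at a state
#'
#' @param phi an `rv_function` (e.g. from [solve_rv()]).
#' @param class class identifier.
#' @param e environment.
#' @param tally demographic class tally (or a key produced by the chain).
#' @return Numeric scalar phi*(class, e, tally).
#' @export
rv_at <- function(phi, class, e, tally) {
  key <- if (is.character(tally) && length(tally) == 1 && grepl("=", tally))
    paste0(e, "::", tally) else state_key(e, tally)
  if (!(key %in% rownames(phi$values)))
    stop("state ", key, " is not in the reproductive-value domain ",
         "(unreachable under the neutral process)")
  phi$values[key, class]
}

# Individual reproductive values phi_i = L_{x_i} phi*(x_i, e, tally(pop)).
individual_rv <- function(phi, model, e, pop) {
  d <- demographic_tally(pop)
  vapply(seq_len(nrow(pop)), function(i)
    model$ploidy[[pop$class[i]]] * rv_at(phi, pop$class[i], e, d), 0)
}

# Per-individual class RV vector at an explicit (e', next tally) pair, as a
# named vector over classes: phi(y', e', x') = L_y * phi*.
class_rv <- function(phi, model, e, d_tally) {
  key <- state_key(e, d_tally)
  model$ploidy * phi$values[key, model$classes]
}

#' Class mean offspring array for a realized outcome
#'
#' For each parental class x, the genotype-summed per-haploid-set shares of
#' its members, averaged over the n(x) members (zero row when the class is
#' empty).
#'
#' @param outcome one enumerated outcome entry (from the chain moves or
#'   [step_kernel()] internals) carrying the per-individual class-summed share
#'   matrix, or a kernel outcome's share list.
#' @param population the parental population state.
#' @param model the reproduction model.
#' @return Matrix parent class x offspring class.
#' @export
class_mean_offspring <- function(outcome, population, model) {
  if (!is.null(outcome$U)) return(outcome$U)
  shares <- if (!is.null(outcome$shares)) outcome$shares else outcome
  classes <- model$classes
  csum <- matrix(0, nrow(population), length(classes),
                 dimnames = list(NULL, classes))
  for (i in seq_along(shares)) {
    s <- shares[[i]]
    if (!length(s)) next
    cls <- cg_class(names(s))
    for (k in seq_along(s)) csum[i, cls[k]] <- csum[i, cls[k]] + s[k]
  }
  U <- matrix(0, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (x in classes) {
    nx <- sum(population$class == x)
    if (nx > 0) U[x, ] <- colSums(csum[population$class == x, , drop = FALSE]) / nx
  }
  U
}

#' Membership in the candidate set of reproductive values
#'
#' Checks the defining constraints: nonnegativity, zero on empty classes, and
#' ploidy-weighted population sum equal to one at every state. (Dependence on
#' the class array only through its tally holds by construction, since
#' candidate functions are keyed by tallies.)
#'
#' @param f a matrix states x classes (or an `rv_function`).
#' @param chain the demographic chain whose states index `f`.
#' @param tol numeric tolerance.
#' @return Logical, with attribute `"witnesses"` describing any violations.
#' @export
in_Z <- function(f, chain, tol = 1e-9) {
  V <- if (inherits(f, "rv_function")) f$values else f
  model <- chain$model
  N <- state_counts(chain)
  wit <- character(0)
  if (any(V < -tol))
    wit <- c(wit, paste("negative value at",
                        rownames(V)[which(apply(V < -tol, 1, any))[1]]))
  empty_bad <- N == 0 & abs(V) > tol
  if (any(empty_bad))
    wit <- c(wit, paste("nonzero value on empty class at",
                        rownames(V)[which(apply(empty_bad, 1, any))[1]]))
  sums <- rowSums(V * sweep(N, 2, model$ploidy[colnames(N)], "*"))
  bad <- abs(sums - 1) > tol
  if (any(bad))
    wit <- c(wit, paste("ploidy-weighted sum", format(sums[bad][1]),
                        "at", names(sums)[bad][1]))
  structure(length(wit) == 0, witnesses = wit)
}

#' Random candidate reproductive-value functions
#'
#' Draws functions uniformly-at-random on occupied (state, class) entries and
#' rescales each state to satisfy the ploidy-weighted sum-to-one constraint.
#' Used by the invariance and linearity property checks.
#'
#' @param chain a demographic chain.
#' @param n how many functions.
#' @param seed RNG seed.
#' @return List of matrices.
#' @export
random_Z <- function(chain, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- chain$model
  N <- state_counts(chain)
  lapply(seq_len(n), function(j) {
    V <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(N))
    for (k in seq_len(nrow(N))) {
      occ <- N[k, ] > 0
      v <- stats::runif(sum(occ))
      w <- N[k, occ] * model$ploidy[colnames(N)[occ]]
      V[k, occ] <- v / sum(w * v)
    }
    V
  })
}

#' Apply the transition operator T
#'
#' Maps a candidate descendant reproductive-value function f to the implied
#' parental one: (Tf)(x, e, tally) is the expectation, over kernel outcomes
#' and the next environment, of the ploidy-weighted average of f over the
#' offspring of class-x parents, sum_{y'} f(y', e', tally') L_{y'} u^x_{y'}.
#' Computed by exhaustive enumeration via the chain's move tables.
#'
#' @param f matrix states x classes (or `rv_function`).
#' @param chain a [demographic_chain()].
#' @return Matrix of the same shape.
#' @export
apply_T <- function(f, chain) {
  V <- if (inherits(f, "rv_function")) f$values else f
  model <- chain$model
  classes <- model$classes
  L <- model$ploidy[classes]
  out <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  for (key in chain$states$key) {
    occ <- state_counts_row(chain, key)
    for (mv in chain$moves[[key]]) {
      fnext <- V[mv$key_next, classes] * L   # L_{y'} f(y', e', x')
      contrib <- as.numeric(mv$U %*% fnext)  # per parent class x
      out[key, ] <- out[key, ] + mv$prob * contrib
    }
    out[key, occ == 0] <- 0
  }
  out
}

state_counts_row <- function(chain, key) {
  tal <- parse_state_key(key)$tally
  classes <- chain$model$classes
  d <- if (all(names(tal) %in% classes)) tal else demographic_tally(tal)
  out <- stats::setNames(rep(0L, length(classes)), classes)
  out[names(d)] <- d
  out
}

#' Solve for reproductive value as the fixed point of T
#'
#' Finds phi* in the candidate set with T phi* = phi*. Because T is linear,
#' two independent algorithms are offered and cross-checked: power iteration
#' from a uniform candidate, and a direct linear solve of the stacked system
#' (T - I) phi = 0 subject to one ploidy-weighted sum-to-one constraint per
#' state. A multistart probe re-solves from random candidates to flag
#' non-uniqueness (existence and uniqueness are not guaranteed in general).
#'
#' @param model a reproduction model.
#' @param chain optionally a prebuilt [demographic_chain()].
#' @param tol sup-norm residual tolerance for the fixed point.
#' @param max_iter maximum power iterations.
#' @param method `"both"` (default; cross-validates), `"direct"` or `"power"`.
#' @param probe_starts number of random starting points for the uniqueness
#'   probe (0 disables).
#' @param seed RNG seed for the probe.
#' @return An `rv_function` with residual and diagnostics.
#' @export
solve_rv <- function(model, chain = NULL, tol = 1e-12, max_iter = 10000,
                     method = c("both", "direct", "power"),
                     probe_starts = 5, seed = 1) {
  method <- match.arg(method)
  if (is.null(chain)) chain <- demographic_chain(model)
  classes <- model$classes
  L <- model$ploidy[classes]
  keys <- chain$states$key
  N <- state_counts(chain)
  # index of occupied (state, class) entries
  ent <- which(N > 0, arr.ind = TRUE)
  ent_id <- paste(keys[ent[, 1]], classes[ent[, 2]])
  m <- nrow(ent)
  # linear map M with (T f)_occupied = M f_occupied
  M <- matrix(0, m, m, dimnames = list(ent_id, ent_id))
  for (r in seq_len(m)) {
    key <- keys[ent[r, 1]]; x <- classes[ent[r, 2]]
    for (mv in chain$moves[[key]]) {
      for (y in classes) {
        if (mv$U[x, y] == 0) next
        cid <- paste(mv$key_next, y)
        M[r, cid] <- M[r, cid] + mv$prob * L[[y]] * mv$U[x, y]
      }
    }
  }
  unpack <- function(v) {
    V <- matrix(0, length(keys), length(classes),
                dimnames = list(keys, classes))
    V[cbind(ent[, 1], ent[, 2])] <- v
    V
  }
  # constraints: per state, sum_x n_x L_x phi*(x) = 1
  C <- matrix(0, length(keys), m, dimnames = list(keys, ent_id))
  for (r in seq_len(m))
    C[ent[r, 1], r] <- N[ent[r, 1], ent[r, 2]] * L[[classes[ent[r, 2]]]]
  uniform_start <- {
    v <- numeric(m)
    for (r in seq_len(m)) v[r] <- 1 / sum(N[ent[r, 1], ] * L)
    v
  }
  power_solve <- function(v0) {
    v <- v0
    for (it in seq_len(max_iter)) {
      nxt <- as.numeric(M %*% v)
      if (max(abs(nxt - v)) < tol) return(list(v = nxt, iter = it))
      v <- nxt
    }
    stop("power iteration did not converge in ", max_iter,
         " iterations; the fixed point may not exist or not be unique")
  }
  diagnostics <- list()
  sol_direct <- sol_power <- NULL
  if (method %in% c("both", "direct")) {
    A <- rbind(M - diag(m), C)
    b <- c(rep(0, m), rep(1, nrow(C)))
    v <- qr.solve(A, b)
    sol_direct <- v
  }
  if (method %in% c("both", "power")) {
    ps <- power_solve(uniform_start)
    sol_power <- ps$v
    diagnostics$power_iterations <- ps$iter
  }
  if (method == "both") {
    diagnostics$method_disagreement <- max(abs(sol_direct - sol_power))
    if (diagnostics$method_disagreement > 1e-8)
      warning("direct and power solutions differ by ",
              format(diagnostics$method_disagreement),
              "; the fixed point may be non-unique")
  }
  v <- if (!is.null(sol_direct)) sol_direct else sol_power
  resid <- max(abs(as.numeric(M %*% v) - v))
  if (resid > max(tol, 1e-10) || any(v < -1e-9))
    stop("no valid fixed point found (residual ", format(resid), ")")
  if (probe_starts > 0) {
    set.seed(seed)
    dists <- replicate(probe_starts, {
      v0 <- numeric(m)
      for (k in seq_along(keys)) {
        rows <- which(ent[, 1] == k)
        u <- stats::runif(length(rows))
        w <- N[cbind(ent[rows, 1], ent[rows, 2])] * L[classes[ent[rows, 2]]]
        v0[rows] <- u / sum(w * u)
      }
      max(abs(power_solve(v0)$v - v))
    })
    diagnostics$multistart_max_distance <- max(dists)
    if (max(dists) > 1e-8)
      warning("multistart probe found distinct fixed points (max distance ",
              format(max(dists)), ")")
  }
  phi <- rv_function(unpack(pmax(v, 0)), chain, residual = resid,
                     iterations = diagnostics$power_iterations %||% NA_integer_,
                     method = method, diagnostics = diagnostics)
  stopifnot(isTRUE(in_Z(phi$values, chain, tol = 1e-8)))
  phi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lineage share matrices along a trajectory
#'
#' The expected number-equivalent of descendants: c^{k,k} is the identity and
#' c^{k,l+1}_{x,z} = sum_y L_y u^{y,(l)}_z c^{k,l}_{x,y}, with u the realized
#' class-mean offspring arrays recorded in the trajectory.
#'
#' @param trajectory a [simulate_neutral()] trajectory.
#' @param from_year,to_year year indices within the trajectory (0-based).
#' @return Matrix ancestor class x descendant class, c^{from,to}.
#' @export
lineage_matrix <- function(trajectory, from_year, to_year) {
  recs <- trajectory$records
  max_year <- recs[[length(recs)]]$year
  if (from_year < 0 || to_year > max_year || from_year > to_year)
    stop("year range [", from_year, ",", to_year, "] outside trajectory 0..",
         max_year)
  model <- trajectory$model
  classes <- model$classes
  L <- model$ploidy[classes]
  C <- diag(length(classes))
  dimnames(C) <- list(classes, classes)
  if (to_year > from_year)
    for (k in seq(from_year, to_year - 1)) {
      U <- recs[[k + 1]]$U
      C <- C %*% (L * U)   # rows of U scaled by L_y
    }
  C
}

#' Reproductive value descended from each ancestor class
#'
#' R^{(t)}_x = sum_z c^{0,t}_{x,z} L_z phi*(z, e^{(t)}, x^{(t)}): the share of
#' year-t reproductive value tracing back to one individual of class x in year
#' 0, in expectation over Mendelian segregation.
#'
#' @param trajectory a neutral trajectory.
#' @param phi a solved `rv_function`.
#' @param t year index.
#' @return Named numeric vector over ancestor classes.
#' @export
descendant_rv <- function(trajectory, phi, t) {
  model <- trajectory$model
  C <- lineage_matrix(trajectory, 0, t)
  rec <- trajectory$records[[t + 1]]
  d <- demographic_tally(rec$tally)
  v <- class_rv(phi, model, rec$env, d)   # L_z phi*(z, e, x) per class
  as.numeric(C %*% v[model$classes])
}

# Enumerate all depth-`horizon` histories of the demographic chain from a
# state, tracking the running lineage matrix and R-vector at each depth.
enumerate_histories <- function(chain, phi, start_key, horizon, path_cap = 2e5) {
  model <- chain$model
  classes <- model$classes
  L <- model$ploidy[classes]
  Rvec <- function(key, C) {
    st <- parse_state_key(key)
    as.numeric(C %*% (L * phi$values[key, classes]))
  }
  paths <- list(list(key = start_key, prob = 1,
                     C = diag(length(classes)),
                     R = list(Rvec(start_key, diag(length(classes)))),
                     prefix = ""))
  for (d in seq_len(horizon)) {
    nxt <- list()
    for (p in paths) {
      for (j in seq_along(chain$moves[[p$key]])) {
        mv <- chain$moves[[p$key]][[j]]
        C2 <- p$C %*% (L * mv$U)
        q <- p
        q$key <- mv$key_next
        q$prob <- p$prob * mv$prob
        q$C <- C2
        q$R <- c(p$R, list(Rvec(mv$key_next, C2)))
        q$prefix <- paste0(p$prefix, "/", j)
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    paths <- nxt
    if (length(paths) > path_cap)
      stop("history enumeration exceeds ", path_cap,
           " paths; use mode = 'mc'")
  }
  paths
}

#' Verify the martingale property of lineage reproductive value
#'
#' In the neutral process the descendant reproductive value R^{(t)}_x is a
#' martingale: E[R^{(t+l+1)} - R^{(t+l)} | history to year t] = 0. Exact mode
#' enumerates every history and returns the maximum conditional-expectation
#' residual over histories and ancestor classes; Monte Carlo mode simulates
#' paths and returns the standardized residual with a normal confidence
#' interval.
#'
#' @param model a reproduction model.
#' @param phi solved `rv_function`.
#' @param t conditioning year.
#' @param l lag (the identity is checked between years t+l and t+l+1).
#' @param mode `"exact"` or `"mc"`.
#' @param chain optional prebuilt demographic chain.
#' @param start state key to start from (default the model's seed state).
#' @param reps Monte Carlo replications.
#' @param seed RNG seed for Monte Carlo mode.
#' @return For exact mode, the max residual (numeric) with attribute
#'   `"by_class"`; for MC mode a list with `estimate`, `se`, `z`, `ci`.
#' @export
verify_martingale <- function(model, phi, t = 0, l = 0,
                              mode = c("exact", "mc"), chain = NULL,
                              start = NULL, reps = 1e4, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(chain)) chain <- phi$chain
  if (is.null(start))
    start <- state_key(model$initial$env, demographic_tally(model$initial$tally))
  classes <- model$classes
  L <- model$ploidy[classes]
  if (mode == "exact") {
    paths <- enumerate_histories(chain, phi, start, t + l + 1)
    prefix_at_t <- vapply(paths, function(p)
      paste(strsplit(p$prefix, "/")[[1]][seq_len(t + 1)], collapse = "/"), "")
    groups <- split(seq_along(paths), prefix_at_t)
    worst <- 0
    by_class <- stats::setNames(rep(0, length(classes)), classes)
    for (g in groups) {
      pg <- sum(vapply(paths[g], function(p) p$prob, 0))
      diff <- rep(0, length(classes))
      for (i in g) {
        p <- paths[[i]]
        diff <- diff + (p$prob / pg) * (p$R[[t + l + 2]] - p$R[[t + l + 1]])
      }
      by_class <- pmax(by_class, abs(diff))
      worst <- max(worst, max(abs(diff)))
    }
    structure(worst, by_class = by_class)
  } else {
    set.seed(seed)
    diffs <- matrix(0, reps, length(classes))
    for (r in seq_len(reps)) {
      key <- start
      C <- diag(length(classes))
      Rprev <- Rcur <- NULL
      for (d in seq_len(t + l + 1)) {
        mvs <- chain$moves[[key]]
        probs <- vapply(mvs, function(m) m$prob, 0)
        mv <- mvs[[sample.int(length(mvs), 1L, prob = probs)]]
        C <- C %*% (L * mv$U)
        key <- mv$key_next
        if (d == t + l) Rprev <- as.numeric(C %*% (L * phi$values[key, classes]))
        if (d == t + l + 1) Rcur <- as.numeric(C %*% (L * phi$values[key, classes]))
      }
      if (t + l == 0) {
        st0 <- parse_state_key(start)
        Rprev <- L * phi$values[start, classes]
      }
      diffs[r, ] <- Rcur - Rprev
    }
    est <- colMeans(diffs)
    sds <- apply(diffs, 2, stats::sd)
    # degenerate martingales (R constant along every path, e.g. a single
    # ancestor class owning the whole gene pool) leave only rounding noise
    degen <- sds < 1e-10
    est[degen] <- 0
    se <- sds / sqrt(reps)
    z <- ifelse(se > 1e-12, est / se, 0)
    list(estimate = stats::setNames(est, classes),
         se = stats::setNames(se, classes),
         z = stats::setNames(z, classes),
         ci = cbind(lower = est - 3 * se, upper = est + 3 * se))
  }
}
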