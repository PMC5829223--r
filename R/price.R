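# Reproductive-value-weighted population statistics, p-scores, breeding
# values, and the verification suite for the Price equations and both
# fundamental-theorem decompositions.

#' Weighted population mean, covariance, variance
#'
#' Population (statistical) moments with arbitrary nonnegative weights h:
#' ave_h f = sum h_i f_i / sum h_i and cov_h(f,g) = ave_h(fg) - ave_h f
#' ave_h g. With reproductive-value weights the total weight is 1.
#'
#' @param weights nonnegative weights with positive total.
#' @param f,g numeric vectors.
#' @return Numeric scalar.
#' @export
weighted_ave <- function(weights, f) {
  tw <- sum(weights)
  if (any(weights < 0) || tw <= 0) stop("weights must be nonnegative with positive total")
  sum(weights * f) / tw
}

#' @rdname weighted_ave
#' @export
weighted_cov <- function(weights, f, g) {
  weighted_ave(weights, f * g) - weighted_ave(weights, f) * weighted_ave(weights, g)
}

#' @rdname weighted_ave
#' @export
weighted_var <- function(weights, f) weighted_cov(weights, f, f)

#' Evaluate a p-score on a population
#'
#' A p-score is a linear combination of allele frequencies: p_i = sum_k
#' lambda_k g_i^k with g_i^k the dosage of allele k in individual i. Class
#' means pi_x are unweighted sample means over class members (0 for empty
#' classes).
#'
#' @param lambda named numeric vector of allelic weights over (a subset of)
#'   the model's allele set.
#' @param population a population state.
#' @param model the reproduction model (for the dosage table).
#' @return List with `p` (per-individual values), `class_means`, and `lambda`
#'   expanded to the full allele set.
#' @export
pscore <- function(lambda, population, model) {
  bad <- setdiff(names(lambda), model$alleles)
  if (length(bad)) stop("unknown allele in p-score weights: ", bad[[1]])
  lam <- stats::setNames(rep(0, length(model$alleles)), model$alleles)
  lam[names(lambda)] <- lambda
  p <- as.numeric(model$dosage[population$genotype, , drop = FALSE] %*% lam)
  cm <- vapply(model$classes, function(x) {
    sel <- population$class == x
    if (any(sel)) mean(p[sel]) else 0
  }, 0)
  list(p = p, class_means = cm, lambda = lam)
}

#' Realized pre-mutation change in a weighted mean p-score
#'
#' Delta* ave_phi p for one realized (outcome, next environment) pair: the
#' reproductive-value-weighted mean p-score of next year's pre-mutation
#' population minus this year's. Offspring p-values are taken in expectation
#' over fair meiosis, i.e. the next-year term is sum_{y'} phi(y', e', x')
#' sum_i p_i L_i w^i_{y',+}. The supplied transition must be pre-mutation;
#' mutation is excluded from Delta* by construction.
#'
#' @param lambda allelic weights (or a precomputed [pscore()]).
#' @param model reproduction model.
#' @param e,population year-0 environment and population (phenotypes applied).
#' @param phi solved `rv_function`.
#' @param realized one realized transition entry (see [fitness_records()]).
#' @return Numeric scalar.
#' @export
delta_star <- function(lambda, model, e, population, phi, realized) {
  ps <- if (is.list(lambda) && !is.null(lambda$p)) lambda
        else pscore(lambda, population, model)
  L <- model$ploidy[population$class]
  phi_i <- individual_rv(phi, model, e, population)
  v <- class_rv(phi, model, realized$e_next, realized$d_next)
  nxt <- sum(ps$p * L * as.numeric(realized$csum %*% v[model$classes]))
  nxt - sum(ps$p * phi_i)
}

#' Breeding values by reproductive-value-weighted least squares
#'
#' Projects per-individual targets (typically expected fitnesses) onto the
#' span of allele-dosage columns under phi weights: lambda minimizes
#' ave_phi (target - sum_k lambda_k dosage_ik)^2. Rank-deficient designs are
#' resolved by the minimum-norm solution; the fitted p-score beta (which is
#' unique) is the meaningful output. Because every locus's dosages sum to one,
#' constants lie in the design span, so the normal equations force
#' ave_phi beta = ave_phi target and ave_phi(beta * target) = ave_phi(beta^2).
#'
#' @param targets per-individual numeric targets.
#' @param population population state (or a matrix of dosage rows).
#' @param model reproduction model.
#' @param weights nonnegative weights (reproductive values phi_i).
#' @return List with `lambda`, `beta` (fitted values), `rank`, `rss`.
#' @export
breeding_values <- function(targets, population, model, weights) {
  X <- if (is.matrix(population)) population
       else model$dosage[population$genotype, , drop = FALSE]
  stopifnot(length(targets) == nrow(X), length(weights) == nrow(X))
  sw <- sqrt(weights)
  A <- sw * X
  b <- sw * targets
  sv <- svd(A)
  pos <- sv$d > max(sv$d[1], 1e-30) * 1e-12
  dinv <- ifelse(pos, 1 / sv$d, 0)
  lambda <- as.numeric(sv$v %*% (dinv * (t(sv$u) %*% b)))
  names(lambda) <- colnames(X)
  beta <- as.numeric(X %*% lambda)
  list(lambda = lambda, beta = beta, rank = sum(pos),
       rss = sum(weights * (targets - beta)^2))
}

verification_report <- function(identity, lhs, rhs, mode = "exact",
                                extra = list()) {
  structure(c(list(identity = identity, lhs = lhs, rhs = rhs,
                   residual = abs(lhs - rhs), mode = mode), extra),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<verification_report> ", x$identity, " [", x$mode, "]\n",
      "  LHS ", format(x$lhs, digits = 15),
      "  RHS ", format(x$rhs, digits = 15),
      "  residual ", format(x$residual), "\n", sep = "")
  invisible(x)
}

# Conditional one-year quantities at a full initial state: expected
# delta-star for a p-score, and per-individual expected-fitness numerators.
# Everything is accumulated in numerator form (finite even when phi_i = 0).
conditional_year <- function(model, h, e, gt_tally, phi, lambda = NULL) {
  pop <- apply_phenotypes(canonical_population(model, gt_tally), h, model)
  ents <- enum_transitions(model, e, pop)
  L <- model$ploidy[pop$class]
  phi_i <- individual_rv(phi, model, e, pop)
  num <- rep(0, nrow(pop))      # E[L_i sum phi w^i] - phi_i
  for (ent in ents) {
    v <- class_rv(phi, model, ent$e_next, ent$d_next)
    num <- num + ent$prob * (L * as.numeric(ent$csum %*% v[model$classes]))
  }
  num <- num - phi_i
  out <- list(population = pop, phi_i = phi_i, numerator = num, ents = ents,
              L = L)
  if (!is.null(lambda)) {
    ps <- pscore(lambda, pop, model)
    out$p <- ps$p
    # E[Delta* ave_phi p | e, x, g] = sum_i p_i * numerator_i (exactly)
    out$expected_delta <- sum(ps$p * num)
    # cov_phi(p, E[F]) in numerator form; sum_i phi_i = 1, ave_phi E[F] = sum num
    out$cov_p_EF <- sum(ps$p * num) - sum(ps$p * phi_i) * sum(num)
  }
  out
}

#' Verify the conditional Price equation
#'
#' Checks E[Delta* ave_phi p | e, x, g] = cov_phi(p, E[F | e, x, g]) for the
#' Taylor year at a given initial state, by exhaustive enumeration of the
#' kernel support and next environments (exact mode) or by sampling realized
#' transitions (Monte Carlo mode, which estimates the left side and compares
#' it with the exact right side).
#'
#' @param model a reproduction model.
#' @param h a [phenotype_map()] for the Taylor year.
#' @param state list with `env` and `tally` (genotype-level); defaults to the
#'   model's seed state.
#' @param phi solved `rv_function`.
#' @param lambda allelic weights of the p-score.
#' @param mode `"exact"` or `"mc"`.
#' @param reps Monte Carlo replications.
#' @param seed RNG seed for Monte Carlo mode.
#' @return A `verification_report`.
#' @export
verify_price_conditional <- function(model, h, state = NULL, phi, lambda,
                                     mode = c("exact", "mc"), reps = 1e4,
                                     seed = 1) {
  mode <- match.arg(mode)
  if (is.null(state)) state <- model$initial
  cy <- conditional_year(model, h, state$env, state$tally, phi, lambda)
  if (mode == "exact")
    return(verification_report("price_conditional", cy$expected_delta,
                               cy$cov_p_EF))
  set.seed(seed)
  probs <- vapply(cy$ents, function(x) x$prob, 0)
  ps <- list(p = cy$p)
  vals <- vapply(cy$ents, function(ent)
    delta_star(ps, model, state$env, cy$population, phi, ent), 0)
  idx <- sample.int(length(vals), reps, replace = TRUE, prob = probs)
  est <- mean(vals[idx]); se <- stats::sd(vals[idx]) / sqrt(reps)
  verification_report("price_conditional", est, cy$cov_p_EF, mode = "mc",
                      extra = list(se = se,
                                   ci = c(est - 3 * se, est + 3 * se)))
}

#' Verify the ensemble Price equation
#'
#' Checks E[Delta* ave_phi p] = E[cov_phi(p, E[F | e, x, a])] with the outer
#' expectation over the ergodic distribution of the neutral process, by
#' summing the conditional quantities over the distribution's support.
#'
#' @inheritParams verify_price_conditional
#' @param D an [ergodic_distribution()] over the full chain.
#' @return A `verification_report`.
#' @export
verify_price_ensemble <- function(model, h, D, phi, lambda) {
  lhs <- 0; rhs <- 0
  for (k in names(D$prob)) {
    pk <- D$prob[[k]]
    if (pk == 0) next
    st <- parse_state_key(k)
    cy <- conditional_year(model, h, st$env, st$tally, phi, lambda)
    lhs <- lhs + pk * cy$expected_delta
    rhs <- rhs + pk * cy$cov_p_EF
  }
  verification_report("price_ensemble", lhs, rhs)
}

#' Verify the conditional fundamental theorem
#'
#' With breeding values beta of conditional expected fitness (the phi-weighted
#' least-squares projection of E[F | e, x, a] onto allele dosages) taken as
#' the p-score, checks E[Delta* ave_phi beta | e, x, a] = var_phi beta.
#'
#' @inheritParams verify_price_conditional
#' @return A `verification_report` with the breeding-value diagnostics
#'   attached.
#' @export
verify_ftns_conditional <- function(model, h, state = NULL, phi) {
  if (is.null(state)) state <- model$initial
  cy <- conditional_year(model, h, state$env, state$tally, phi)
  if (any(cy$phi_i == 0))
    warning("zero reproductive value in the initial state; breeding values ",
            "use ratio-form expected fitness and may be unstable")
  EF <- cy$numerator / cy$phi_i
  bv <- breeding_values(EF, cy$population, model, cy$phi_i)
  ps <- list(p = bv$beta)
  lhs <- sum(bv$beta * cy$numerator)   # E[Delta* ave_phi beta | state]
  rhs <- weighted_var(cy$phi_i, bv$beta)
  verification_report("ftns_conditional", lhs, rhs,
                      extra = list(breeding = bv,
                                   ave_phi_beta = sum(cy$phi_i * bv$beta)))
}

#' Verify the ensemble fundamental theorem
#'
#' Ensemble breeding values minimize the D-weighted phi-weighted squared error
#' of conditional expected fitness over all states in the ergodic support;
#' with that p-score, checks the decomposition
#' E[Delta* ave_phi p] = E[var_phi p] + V[ave_phi p].
#'
#' @inheritParams verify_price_ensemble
#' @return A `verification_report`; the two right-hand summands are reported
#'   separately in `E_var` and `V_ave`.
#' @export
verify_ftns_ensemble <- function(model, h, D, phi) {
  sup <- names(D$prob)[D$prob > 0]
  cys <- list()
  Xs <- list(); ys <- list(); ws <- list()
  for (k in sup) {
    st <- parse_state_key(k)
    cy <- conditional_year(model, h, st$env, st$tally, phi)
    cys[[k]] <- cy
    EF <- cy$numerator / cy$phi_i
    Xs[[k]] <- model$dosage[cy$population$genotype, , drop = FALSE]
    ys[[k]] <- EF
    ws[[k]] <- D$prob[[k]] * cy$phi_i
  }
  bv <- breeding_values(unlist(ys), do.call(rbind, Xs), model, unlist(ws))
  lhs <- 0; E_var <- 0; E_ave <- 0; E_ave2 <- 0
  for (k in sup) {
    pk <- D$prob[[k]]
    cy <- cys[[k]]
    beta <- as.numeric(model$dosage[cy$population$genotype, , drop = FALSE] %*%
                         bv$lambda)
    lhs <- lhs + pk * sum(beta * cy$numerator)
    av <- sum(cy$phi_i * beta)
    E_var <- E_var + pk * weighted_var(cy$phi_i, beta)
    E_ave <- E_ave + pk * av
    E_ave2 <- E_ave2 + pk * av^2
  }
  V_ave <- E_ave2 - E_ave^2
  verification_report("ftns_ensemble", lhs, E_var + V_ave,
                      extra = list(E_var = E_var, V_ave = V_ave,
                                   E_ave = E_ave, lambda = bv$lambda))
}

#' Neutrality check: all selection quantities vanish under the background map
#'
#' With h mapping everything to the background phenotype, both sides of the
#' conditional and ensemble Price equations and both fundamental-theorem
#' sides must be zero: phenotypically neutral genetic variability implies no
#' selection.
#'
#' @param model a reproduction model.
#' @param phi solved `rv_function`.
#' @param D ergodic distribution over the full chain.
#' @param lambda allelic weights to test with.
#' @return Named numeric vector of the absolute values of all computed sides.
#' @export
verify_neutrality <- function(model, phi, D, lambda) {
  h0 <- background_map(model)
  pc <- verify_price_conditional(model, h0, NULL, phi, lambda)
  pe <- verify_price_ensemble(model, h0, D, phi, lambda)
  fc <- verify_ftns_conditional(model, h0, NULL, phi)
  fe <- verify_ftns_ensemble(model, h0, D, phi)
  abs(c(price_conditional_lhs = pc$lhs, price_conditional_rhs = pc$rhs,
        price_ensemble_lhs = pe$lhs, price_ensemble_rhs = pe$rhs,
        ftns_conditional_lhs = fc$lhs, ftns_conditional_rhs = fc$rhs,
        ftns_ensemble_lhs = fe$lhs, ftns_ensemble_rhs = fe$rhs))
}
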