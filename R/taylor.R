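# The Taylor year: a single selective year started from the ergodic
# distribution of the neutral process, in which an arbitrary class-and-
# genotype-to-phenotype map h is switched on. Williams' reproductive value,
# realized and expected fitness are computed against the reproductive values
# phi solved in the neutral process.

#' Apply a phenotype map to a population
#'
#' @param population a population state.
#' @param h a [phenotype_map()].
#' @param model the model (for validating the produced phenotypes).
#' @return The population with phenotypes set to `h(class, genotype)`.
#' @export
apply_phenotypes <- function(population, h, model) {
  ph <- h(population$class, population$genotype)
  if (any(is.na(ph)) || !all(ph %in% model$phenotypes))
    stop("phenotype map is undefined or out of range on a drawn (class, genotype)")
  population$phenotype <- ph
  population
}

#' Draw the Taylor-year initial conditions
#'
#' Samples the year-0 state (environment, classes, genotypes) from the ergodic
#' distribution of the neutral process, then assigns year-0 phenotypes by the
#' map h; all later years revert to the background phenotype.
#'
#' @param model a reproduction model.
#' @param D an [ergodic_distribution()] over the full (genotype-inclusive)
#'   chain.
#' @param h a [phenotype_map()].
#' @param seed RNG seed.
#' @return List with `env`, `population` (phenotypes applied), and `key`.
#' @export
initialize_taylor <- function(model, D, h, seed) {
  stopifnot(inherits(D, "ergodic_distribution"))
  set.seed(seed)
  key <- names(D$prob)[sample.int(length(D$prob), 1L, prob = D$prob)]
  st <- parse_state_key(key)
  pop <- canonical_population(model, st$tally)
  pop <- apply_phenotypes(pop, h, model)
  list(env = st$env, population = pop, key = key)
}

#' Williams' reproductive value of an individual
#'
#' The sum, over an individual's offspring and surviving self, of its share of
#' their reproductive value: W_i = L_i * sum_{y'} phi(y', e', x') w^i_{y',+},
#' where w is the realized (or expectation-form) offspring array per parental
#' haploid set and phi(y', ...) = L_{y'} phi* is the individual reproductive
#' value of a class-y' member of next year's population.
#'
#' @param ploidy the parent's ploidy L_i.
#' @param shares named numeric vector of the parent's per-haploid-set shares,
#'   keyed `"class|genotype"` or by class alone.
#' @param phi_next named numeric vector: individual reproductive value of each
#'   offspring class next year (i.e. `L_y * phi*(y, e', tally')`), or an
#'   `rv_function` together with `e_next`/`tally_next`.
#' @param e_next,tally_next next year's environment and class tally (used when
#'   `phi_next` is an `rv_function`).
#' @param model model, required when `phi_next` is an `rv_function`.
#' @return Numeric W_i.
#' @examples
#' # an age-10 diploid with survival probability 0.9 into age class "11" and 3
#' # diploid offspring in class "0": W = 0.9 v11 + (3/2) v0
#' williams_rv(2, c(`11` = 0.9 / 2, `0` = 3 / 4), c(`11` = 1, `0` = 0))  # 0.9
#' williams_rv(2, c(`11` = 0.9 / 2, `0` = 3 / 4), c(`11` = 0, `0` = 1))  # 1.5
#' @export
williams_rv <- function(ploidy, shares, phi_next, e_next = NULL,
                        tally_next = NULL, model = NULL) {
  if (inherits(phi_next, "rv_function")) {
    stopifnot(!is.null(e_next), !is.null(tally_next), !is.null(model))
    phi_next <- class_rv(phi_next, model, e_next, tally_next)
  }
  if (!length(shares)) return(0)
  cls <- cg_class(names(shares))
  bad <- setdiff(cls, names(phi_next))
  if (length(bad)) stop("no reproductive value supplied for class ", bad[[1]])
  ploidy * sum(shares * phi_next[cls])
}

#' Fisherian fitness from Williams' reproductive value
#'
#' F = (W - phi_i) / phi_i: the proportional change in the individual's
#' expected contribution to the asymptotic gene pool from one year's new
#' information. Zero for an individual performing exactly as expected for its
#' class; one for an individual performing twice as well. When phi_i = 0 but
#' W > 0 the ratio is infinite (flagged); phi_i = 0 with W = 0 returns 0 with
#' a flag (a convention -- the quantity is undefined).
#'
#' @param W Williams' reproductive value (nonnegative).
#' @param phi_i the class-predicted individual reproductive value.
#' @return List with `value` and logical `flag` (TRUE when phi_i = 0).
#' @export
fitness <- function(W, phi_i) {
  if (W < 0 || phi_i < 0) stop("fitness() requires nonnegative W and phi")
  if (phi_i > 0) return(list(value = (W - phi_i) / phi_i, flag = FALSE))
  if (W > 0) list(value = Inf, flag = TRUE) else list(value = 0, flag = TRUE)
}

#' Exact expected fitness of every individual
#'
#' Enumerates the kernel outcome support and next environments at the year-0
#' population (phenotypes applied) and returns, per individual, the
#' expectation of the fitness numerator L_i sum_{y'} phi(y',e',x') w^i_{y',+}
#' minus phi_i, together with the ratio-form expected fitness. With the
#' background phenotype everywhere the expectations are all zero (to numerical
#' tolerance), by the fixed-point property.
#'
#' @param model a reproduction model.
#' @param e year-0 environment.
#' @param population year-0 population with phenotypes applied.
#' @param phi a solved `rv_function`.
#' @return Data frame per individual: `phi`, `numerator` (E of the fitness
#'   numerator), `expected_fitness`, `flag`.
#' @export
expected_fitness <- function(model, e, population, phi) {
  ents <- enum_transitions(model, e, population)
  L <- model$ploidy[population$class]
  phi_i <- individual_rv(phi, model, e, population)
  num <- rep(0, nrow(population))
  for (ent in ents) {
    v <- class_rv(phi, model, ent$e_next, ent$d_next)  # L_y phi* per class
    num <- num + ent$prob * (L * as.numeric(ent$csum %*% v[model$classes]))
  }
  num <- num - phi_i
  flag <- phi_i == 0
  ef <- ifelse(flag, ifelse(num > 1e-12, Inf, 0), num / pmax(phi_i, 1e-300))
  data.frame(phi = phi_i, numerator = num, expected_fitness = ef,
             flag = flag)
}

#' Fitness records for one realized transition
#'
#' Realizes (or accepts) one (kernel outcome, next environment) draw at the
#' year-0 population and tabulates per individual: class-predicted reproductive
#' value phi_i, Williams' reproductive value W_i, realized fitness F_i,
#' expected fitness and flags. The reproductive-value-weighted mean of F
#' (accumulated in numerator form) is returned as an attribute and is zero in
#' every realization.
#'
#' @param model a reproduction model.
#' @param e year-0 environment.
#' @param population year-0 population with phenotypes applied.
#' @param phi a solved `rv_function`.
#' @param realized an entry from the internal enumeration (with `e_next`,
#'   `csum`, `d_next`); if `NULL`, one is drawn using the current RNG state.
#' @return Data frame with one row per individual and attribute
#'   `"ave_phi_fitness"` (the phi-weighted mean of realized fitness).
#' @export
fitness_records <- function(model, e, population, phi, realized = NULL) {
  if (is.null(realized)) realized <- realize_year(model, e, population)
  L <- model$ploidy[population$class]
  phi_i <- individual_rv(phi, model, e, population)
  v <- class_rv(phi, model, realized$e_next, realized$d_next)
  W <- L * as.numeric(realized$csum %*% v[model$classes])
  numerator <- W - phi_i
  flag <- phi_i == 0
  Fi <- ifelse(flag, ifelse(W > 1e-12, Inf, 0), numerator / pmax(phi_i, 1e-300))
  ef <- expected_fitness(model, e, population, phi)
  out <- data.frame(
    individual = seq_len(nrow(population)),
    class = population$class, genotype = population$genotype,
    phenotype = population$phenotype,
    phi = phi_i, W = W, fitness = Fi, numerator = numerator,
    expected_fitness = ef$expected_fitness, flag = flag | ef$flag)
  attr(out, "ave_phi_fitness") <- sum(numerator)  # = sum_i phi_i F_i exactly
  attr(out, "e_next") <- realized$e_next
  attr(out, "tally_next") <- realized$d_next
  out
}
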