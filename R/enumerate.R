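# One-year exhaustive enumeration: the workhorse behind the transition
# operator, expected fitness, the Price checks and the exact chains.

# Normalise kernel output and attach derived per-outcome quantities:
#   csum  - matrix individuals x classes of genotype-summed shares w^i_{y',+}
#   tab   - named integer next-year (class, genotype) counts (sum_i L_i w^i)
#   U     - class mean offspring matrix (parent class x offspring class)
# Each entry of the returned list is one (kernel outcome, next environment)
# pair with joint probability prob = P(outcome) * Pi(e, e').
enum_transitions <- function(model, e, pop, envs = TRUE) {
  outs <- model$kernel(e, pop, model)
  p_tot <- sum(vapply(outs, function(o) o$prob, 0))
  if (abs(p_tot - 1) > 1e-9)
    stop("kernel outcome probabilities sum to ", format(p_tot), ", not 1")
  L <- model$ploidy[pop$class]
  classes <- model$classes
  n_by_class <- table(factor(pop$class, levels = classes))
  base <- lapply(outs, function(o) {
    shares <- o$shares
    if (length(shares) != nrow(pop))
      stop("kernel outcome has ", length(shares), " share arrays for ",
           nrow(pop), " individuals")
    csum <- matrix(0, nrow(pop), length(classes),
                   dimnames = list(NULL, classes))
    tab <- numeric(0)
    for (i in seq_along(shares)) {
      s <- shares[[i]]
      if (!length(s)) next
      if (any(s < 0) || any(s > model$bound + 1e-12))
        stop("share outside [0, bound] in kernel outcome")
      cls <- cg_class(names(s))
      for (k in seq_along(s)) {
        csum[i, cls[k]] <- csum[i, cls[k]] + s[k]
        nm <- names(s)[k]
        tab[nm] <- (if (nm %in% names(tab)) tab[[nm]] else 0) + L[i] * s[k]
      }
    }
    if (any(abs(tab - round(tab)) > 1e-9))
      stop("ploidy-weighted offspring counts are not integers")
    tab <- canon_tally(stats::setNames(as.integer(round(tab)), names(tab)))
    if (!length(tab))
      stop("kernel outcome implies an empty next-year population")
    U <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
    for (x in classes) {
      nx <- n_by_class[[x]]
      if (nx > 0)
        U[x, ] <- colSums(csum[pop$class == x, , drop = FALSE]) / nx
    }
    list(prob = o$prob, shares = shares, csum = csum, tab = tab,
         d_next = demographic_tally(tab), U = U)
  })
  if (!isTRUE(envs)) return(base)
  res <- list()
  Pi_row <- model$Pi[e, ]
  for (b in base) for (e2 in model$env_states) {
    if (Pi_row[[e2]] == 0) next
    ent <- b
    ent$prob <- b$prob * Pi_row[[e2]]
    ent$e_next <- e2
    res[[length(res) + 1L]] <- ent
  }
  res
}

# Enumerate the mutation step applied to a pre-mutation (class, genotype)
# tally: mutation acts independently on each individual. Returns a list of
# (prob, tally) pairs, deduplicated by resulting tally.
enum_mutation <- function(model, gt_tally) {
  if (is.null(model$mutation))
    return(list(list(prob = 1, tally = canon_tally(gt_tally))))
  slots <- rep(names(gt_tally), gt_tally)
  acc <- list(list(prob = 1, tally = stats::setNames(integer(0), character(0))))
  for (slot in slots) {
    cls <- cg_class(slot); g <- cg_genotype(slot)
    d <- mutation_dist(model, g, cls)
    nxt <- list()
    for (a in acc) for (j in seq_along(d)) {
      t2 <- a$tally
      nm <- cg_key(cls, names(d)[j])
      t2[nm] <- (if (nm %in% names(t2)) t2[[nm]] else 0L) + 1L
      key <- tally_key(t2)
      if (is.null(nxt[[key]])) nxt[[key]] <- list(prob = 0, tally = canon_tally(t2))
      nxt[[key]]$prob <- nxt[[key]]$prob + a$prob * d[[j]]
    }
    acc <- unname(nxt)
  }
  acc
}

#' Enumerate or realize one year of the process
#'
#' `enumerate_year` lists every (kernel outcome, next environment) pair at a
#' population, with joint probabilities and derived quantities: per-individual
#' genotype-summed shares (`csum`), the next-year count table (`tab`), the
#' demographic projection (`d_next`), the class-mean offspring matrix (`U`)
#' and the next environment (`e_next`). `realize_year` samples one such pair
#' using the current RNG state.
#'
#' @param model a reproduction model.
#' @param e current environment.
#' @param population a population state with phenotypes set (use the
#'   background for the neutral process).
#' @return A list of transition entries, or a single entry.
#' @export
enumerate_year <- function(model, e, population) {
  enum_transitions(model, e, population)
}

#' @rdname enumerate_year
#' @export
realize_year <- function(model, e, population) {
  ents <- enum_transitions(model, e, population)
  probs <- vapply(ents, function(x) x$prob, 0)
  ents[[sample.int(length(ents), 1L, prob = probs)]]
}

#' Build a kernel outcome from offspring descriptors
#'
#' Helper for writing fixture kernels: given the parental population and a list
#' of offspring, each described by its class, genotype and the haploid sets
#' contributed by each parent (`sets`, a named-by-index integer vector; a
#' surviving self is an offspring whose sets all come from itself), computes
#' the per-parent share arrays using the coreplicon share rules. The
#' contributed sets of each offspring must total its class ploidy, so the
#' ploidy-weighted parental shares of every offspring sum to 1 by construction.
#'
#' @param pop parental population state.
#' @param model reproduction model (for ploidies).
#' @param offspring list of lists with elements `class`, `genotype`, `sets`.
#' @param prob outcome probability.
#' @return An outcome suitable for inclusion in a kernel's return list.
#' @export
offspring_outcome <- function(pop, model, offspring, prob) {
  shares <- rep(list(stats::setNames(numeric(0), character(0))), nrow(pop))
  for (off in offspring) {
    L_off <- model$ploidy[[off$class]]
    sets <- off$sets
    if (sum(sets) != L_off)
      stop("offspring sets (", sum(sets), ") != class ploidy (", L_off, ")")
    for (j in seq_along(sets)) {
      if (sets[j] == 0) next
      i <- as.integer(names(sets)[j])
      L_par <- model$ploidy[[pop$class[i]]]
      nm <- cg_key(off$class, off$genotype)
      s <- shares[[i]]
      s[nm] <- (if (nm %in% names(s)) s[[nm]] else 0) + sets[j] / (L_off * L_par)
      shares[[i]] <- s
    }
  }
  list(prob = prob, shares = shares)
}
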