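# Core domain types: class space, environment chain, genotype space,
# population states, tallies, and the reproduction model wrapping the
# finite-support stochastic kernel w.

#' State and tally keys
#'
#' Tallies are named integer vectors keyed `"class|genotype"` (full) or by
#' class (demographic); states pair an environment with a tally and are keyed
#' `"env::tallykey"`. These helpers build and parse the canonical keys used
#' throughout chain states, reproductive-value tables and reports.
#'
#' @param class,genotype character vectors.
#' @return `cg_key` a `"class|genotype"` key; `canon_tally` the tally with
#'   zero entries dropped and names sorted; `tally_key`/`state_key` strings;
#'   `parse_tally_key`/`parse_state_key` the inverse parses.
#' @export
cg_key <- function(class, genotype) paste(class, genotype, sep = "|")

cg_class <- function(keys) sub("\\|.*$", "", keys)

cg_genotype <- function(keys) sub("^[^|]*\\|", "", keys)

#' @rdname cg_key
#' @param x a named count vector.
#' @export
canon_tally <- function(x) {
  x <- x[x != 0]
  if (!length(x)) return(stats::setNames(integer(0), character(0)))
  x[order(names(x))]
}

#' @rdname cg_key
#' @param tally a named count vector.
#' @export
tally_key <- function(tally) {
  tally <- canon_tally(tally)
  paste(names(tally), tally, sep = "=", collapse = ",")
}

#' @rdname cg_key
#' @param e environment identifier.
#' @export
state_key <- function(e, tally) paste0(e, "::", tally_key(tally))

#' Construct a population state
#'
#' A population in a given year is a list of individuals, each with a class,
#' a genotype, and (during the Taylor year) a phenotype.
#'
#' @param class character vector of class identifiers.
#' @param genotype character vector of genotype identifiers, same length.
#' @param phenotype character vector of phenotypes, or `NULL` (filled with the
#'   model background when the population enters the neutral process).
#' @return A data frame with columns `class`, `genotype`, `phenotype`.
#' @export
population_state <- function(class, genotype, phenotype = NULL) {
  stopifnot(length(class) == length(genotype), length(class) >= 1)
  if (is.null(phenotype)) phenotype <- rep(NA_character_, length(class))
  stopifnot(length(phenotype) == length(class))
  data.frame(class = as.character(class), genotype = as.character(genotype),
             phenotype = as.character(phenotype), stringsAsFactors = FALSE)
}

#' Tabulate a population by class and genotype
#'
#' Returns the permutation-invariant (class, genotype) count table of a
#' population; the demographic projection is obtained with
#' [demographic_tally()].
#'
#' @param population a population state (see [population_state()]).
#' @return A named integer vector keyed `"class|genotype"`, sorted by key.
#' @export
tally <- function(population) {
  if (is.null(population) || nrow(population) == 0)
    stop("empty population: the model conditions on non-extinction")
  k <- cg_key(population$class, population$genotype)
  tab <- table(k)
  canon_tally(stats::setNames(as.integer(tab), names(tab)))
}

#' Demographic (class-only) projection of a tally or population
#'
#' @param x a population state or a `"class|genotype"`-keyed tally.
#' @return A named integer vector of class counts.
#' @export
demographic_tally <- function(x) {
  if (is.data.frame(x)) x <- tally(x)
  cls <- cg_class(names(x))
  out <- tapply(as.numeric(x), cls, sum)
  canon_tally(stats::setNames(as.integer(out), names(out)))
}

#' Convert a tabulated offspring array to an individual-indexed population
#'
#' The ploidy-weighted sum of parental offspring arrays describes next year's
#' population as a (class, genotype) count table; this converts it back to an
#' individual list. The ordering is canonical (sorted by class then genotype),
#' which is benign under the permutation assumption on the kernel but makes
#' results reproducible.
#'
#' @param tabulated named nonnegative vector keyed `"class|genotype"`; entries
#'   must be whole numbers (they are ploidy-weighted sums of shares).
#' @param phenotype phenotype to assign to every individual (default `NA`).
#' @param tol tolerance for the whole-number check.
#' @return A population state.
#' @export
extract_population <- function(tabulated, phenotype = NA_character_, tol = 1e-9) {
  tabulated <- tabulated[tabulated != 0]
  if (!length(tabulated) || sum(tabulated) < 1)
    stop("extract: empty next-year population (extinction is excluded by assumption)")
  if (any(abs(tabulated - round(tabulated)) > tol))
    stop("extract: non-integer ploidy-weighted offspring count; model mis-specified")
  n <- round(tabulated)
  keys <- rep(names(n), n)
  keys <- keys[order(cg_class(keys), cg_genotype(keys))]
  population_state(cg_class(keys), cg_genotype(keys),
                   rep(phenotype, length(keys)))
}

#' Construct a reproduction model
#'
#' Bundles the full specification of a finite instance: the class space with
#' per-class ploidies, the finite Markov environment chain, the genotype space
#' with per-locus allele dosages, the phenotype set with its designated
#' background, the stochastic reproduction kernel with finite outcome support,
#' the mutation kernel, and a uniform bound on shares. All loci are assumed to
#' belong to a single coreplicon, fixed by the model.
#'
#' The kernel is a function `kernel(e, population, model)` returning a list of
#' outcomes, each a list with elements `prob` (numeric) and `shares` (a list,
#' one element per individual in population order, each a named numeric vector
#' keyed `"class|genotype"` giving that parent's per-haploid-set share of each
#' kind of next-year individual). Outcome probabilities must sum to one and,
#' for every outcome, the ploidy-weighted column sums must be nonnegative
#' integers with at least one individual.
#'
#' @param classes character vector of class identifiers.
#' @param ploidy named positive integer vector over `classes`.
#' @param env_states character vector of environment identifiers.
#' @param Pi row-stochastic environment transition matrix with dimnames
#'   `env_states`.
#' @param genotypes character vector of genotype identifiers.
#' @param loci named list partitioning the allele set into loci; each element
#'   is a character vector of allele names.
#' @param dosage numeric matrix `genotypes x alleles`; within each locus the
#'   rows must sum to one (allele fractions).
#' @param phenotypes character vector of phenotype identifiers.
#' @param background the background phenotype, an element of `phenotypes`.
#' @param kernel the reproduction kernel function (see Details).
#' @param mutation either `NULL` (no mutation) or a data frame with columns
#'   `class`, `from`, `to`, `prob` giving the per-individual genotype mutation
#'   distributions; rows for a `(class, from)` pair must sum to one.
#' @param bound uniform upper bound on individual shares.
#' @param initial list with elements `env` and `tally` (a
#'   `"class|genotype"`-keyed count vector): the seed state from which
#'   reachable state spaces are enumerated.
#' @param class_genotype named character vector giving one representative
#'   genotype per class, used when enumerating the demographic (class-only)
#'   chain; legitimate because class-summed offspring distributions do not
#'   depend on genotypes (checked by [validate_model()]).
#' @param coreplicon one of `"autosome"`, `"X"`, `"Y"`, `"mitochondrial"`,
#'   `"custom"`; informational, since a model fixes exactly one coreplicon.
#' @param name optional model name.
#' @param kernel_spec optional serialisable description of the kernel (used by
#'   [write_model()]).
#' @return An object of class `reproduction_model`.
#' @export
reproduction_model <- function(classes, ploidy, env_states, Pi,
                               genotypes, loci, dosage,
                               phenotypes, background,
                               kernel, mutation = NULL, bound = 1,
                               initial, class_genotype,
                               coreplicon = "autosome",
                               name = "model", kernel_spec = NULL) {
  stopifnot(!anyDuplicated(classes), !anyDuplicated(env_states),
            !anyDuplicated(genotypes))
  ploidy <- ploidy[classes]
  if (any(is.na(ploidy)) || any(ploidy < 1) || any(ploidy != round(ploidy)))
    stop("ploidy must be a positive integer for every class")
  Pi <- as.matrix(Pi)
  if (is.null(dimnames(Pi))) dimnames(Pi) <- list(env_states, env_states)
  if (any(Pi < 0) || any(abs(rowSums(Pi) - 1) > 1e-10))
    stop("environment transition matrix must be row-stochastic")
  alleles <- unlist(loci, use.names = FALSE)
  stopifnot(!anyDuplicated(alleles))
  dosage <- as.matrix(dosage)[genotypes, alleles, drop = FALSE]
  for (loc in loci) {
    s <- rowSums(dosage[, loc, drop = FALSE])
    if (any(abs(s - 1) > 1e-10))
      stop("dosages within locus {", paste(loc, collapse = ","),
           "} must sum to 1 for every genotype")
  }
  stopifnot(background %in% phenotypes)
  if (!is.null(mutation)) {
    stopifnot(all(c("class", "from", "to", "prob") %in% names(mutation)))
    agg <- tapply(mutation$prob, paste(mutation$class, mutation$from), sum)
    if (any(abs(agg - 1) > 1e-10))
      stop("mutation distributions must sum to 1 for each (class, genotype)")
  }
  stopifnot(is.function(kernel), bound > 0)
  stopifnot(is.list(initial), all(c("env", "tally") %in% names(initial)))
  stopifnot(initial$env %in% env_states)
  model <- structure(list(
    name = name, classes = classes, ploidy = ploidy,
    env_states = env_states, Pi = Pi,
    genotypes = genotypes, loci = loci, alleles = alleles, dosage = dosage,
    phenotypes = phenotypes, background = background,
    kernel = kernel, mutation = mutation, bound = bound,
    initial = list(env = initial$env, tally = canon_tally(initial$tally)),
    class_genotype = class_genotype[classes],
    coreplicon = coreplicon, kernel_spec = kernel_spec
  ), class = "reproduction_model")
  model
}

#' @export
print.reproduction_model <- function(x, ...) {
  cat("<reproduction_model> ", x$name, "\n", sep = "")
  cat("  classes:     ", paste0(x$classes, " (L=", x$ploidy, ")", collapse = ", "), "\n")
  cat("  environments:", paste(x$env_states, collapse = ", "), "\n")
  cat("  genotypes:   ", paste(x$genotypes, collapse = ", "), "\n")
  cat("  phenotypes:  ", paste(x$phenotypes, collapse = ", "),
      " (background ", x$background, ")\n", sep = "")
  cat("  coreplicon:  ", x$coreplicon, "\n")
  invisible(x)
}

#' Phenotype maps for the Taylor year
#'
#' Builds the genotype-and-class-to-phenotype map `h` applied in year 0 of the
#' Taylor switch process. Each individual's phenotype depends only on its own
#' class and genotype.
#'
#' @param assignments named character vector mapping `"class|genotype"` keys to
#'   phenotypes; pairs not listed receive the background.
#' @param background the background phenotype.
#' @return A function `h(class, genotype)` (vectorised).
#' @export
phenotype_map <- function(assignments = character(), background) {
  force(assignments); force(background)
  h <- function(class, genotype) {
    k <- cg_key(class, genotype)
    out <- unname(assignments[k])
    out[is.na(out)] <- background
    out
  }
  attr(h, "assignments") <- assignments
  attr(h, "background") <- background
  h
}

#' @rdname phenotype_map
#' @param model a reproduction model.
#' @export
background_map <- function(model) phenotype_map(character(), model$background)

# Canonical population at a genotype-level state: extract + background phenotype.
canonical_population <- function(model, gt_tally) {
  extract_population(gt_tally, phenotype = model$background)
}

# Representative population for a demographic (class-only) tally, using the
# model's per-class representative genotypes. Only valid for class-summed
# quantities, by the genotype-through-phenotype assumption.
demographic_population <- function(model, d_tally) {
  d_tally <- canon_tally(d_tally)
  gt <- stats::setNames(as.integer(d_tally),
                        cg_key(names(d_tally), model$class_genotype[names(d_tally)]))
  canonical_population(model, gt)
}

mutation_dist <- function(model, genotype, class) {
  if (is.null(model$mutation))
    return(stats::setNames(1, genotype))
  m <- model$mutation
  sel <- m$class == class & m$from == genotype
  if (!any(sel)) return(stats::setNames(1, genotype))
  stats::setNames(m$prob[sel], m$to[sel])
}
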