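# Built-in fixtures with known answers. Sizes are kept small enough that
# every theorem can be verified by full enumeration: at most a handful of
# individuals, two environments, a few genotypes.

.env2 <- function(Pi = NULL) {
  if (is.null(Pi))
    Pi <- matrix(c(3/4, 1/4, 1/4, 3/4), 2, 2, byrow = TRUE,
                 dimnames = list(c("e1", "e2"), c("e1", "e2")))
  Pi
}

#' Clonal fixture: exact survival of N haploid individuals
#'
#' One haploid class whose members each survive exactly (share 1 to their own
#' class and genotype), under an arbitrary environment chain. Reproductive
#' value is 1/N at every state, all fitnesses are zero in every realization,
#' and the demographic chain is isomorphic to the environment chain.
#'
#' @param N population size.
#' @param Pi environment transition matrix (default a symmetric 2-state
#'   chain).
#' @return A validated-by-construction [reproduction_model()].
#' @export
make_clonal <- function(N = 3, Pi = NULL) {
  stopifnot(N >= 1)
  Pi <- .env2(Pi)
  envs <- rownames(Pi)
  kern <- function(e, pop, model) {
    shares <- lapply(seq_len(nrow(pop)), function(i)
      stats::setNames(1, cg_key(pop$class[i], pop$genotype[i])))
    list(list(prob = 1, shares = shares))
  }
  reproduction_model(
    classes = "A", ploidy = c(A = 1), env_states = envs, Pi = Pi,
    genotypes = "g0", loci = list(locus1 = "k0"),
    dosage = matrix(1, 1, 1, dimnames = list("g0", "k0")),
    phenotypes = c("a0", "a1"), background = "a0",
    kernel = kern, mutation = NULL, bound = 1,
    initial = list(env = envs[[1]],
                   tally = stats::setNames(as.integer(N), cg_key("A", "g0"))),
    class_genotype = c(A = "g0"),
    name = "clonal",
    kernel_spec = list(type = "builtin", name = "clonal",
                       params = list(N = N)))
}

#' Haplodiploid two-class fixture
#'
#' Females are diploid (L = 2), males haploid (L = 1), with one biallelic
#' locus (female genotypes aa/ab/bb, male genotypes a/b). A mated pair
#' produces one son (from the mother alone) and one or two daughters (from
#' both parents); the two-daughter family is more likely in the good
#' environment, so the class distribution genuinely fluctuates between one
#' and two females. When two females are present, one is chosen as the mother
#' -- uniformly in the background, with phenotype `"aS"` favoured by
#' `sel_weight` in the Taylor year -- and the phenotype can also raise the
#' two-daughter probability. Recurrent mutation at rate `mu` per allele keeps
#' the genotype chain irreducible. All kernel probabilities are dyadic
#' rationals by default, so enumeration identities hold to machine exactness.
#'
#' @param p_big named probability of the two-daughter family per environment
#'   (background mother).
#' @param p_big_sel the same for a mother with phenotype `"aS"`.
#' @param sel_weight mother-choice weight for phenotype `"aS"`.
#' @param mu per-allele mutation probability.
#' @param Pi environment transition matrix.
#' @return A [reproduction_model()].
#' @export
make_haplodiploid <- function(p_big = c(e1 = 1/2, e2 = 1/4),
                              p_big_sel = c(e1 = 3/4, e2 = 1/2),
                              sel_weight = 2, mu = 1/16, Pi = NULL) {
  Pi <- .env2(Pi)
  envs <- rownames(Pi)
  stopifnot(all(envs %in% names(p_big)), all(envs %in% names(p_big_sel)))
  gametes <- function(g) {
    al <- strsplit(g, "")[[1]]
    tab <- table(al) / length(al)
    stats::setNames(as.numeric(tab), names(tab))
  }
  kern <- function(e, pop, model) {
    fem <- which(pop$class == "F"); mal <- which(pop$class == "M")
    if (!length(fem) || !length(mal))
      stop("haplodiploid kernel needs at least one female and one male")
    # mother choice: weights by phenotype only (permutation-equivariant)
    wgt <- ifelse(pop$phenotype[fem] == "aS", sel_weight, 1)
    mother_p <- wgt / sum(wgt)
    father_p <- rep(1 / length(mal), length(mal))
    outs <- list()
    for (mi in seq_along(fem)) for (fi in seq_along(mal)) {
      m <- fem[mi]; f <- mal[fi]
      base_p <- mother_p[mi] * father_p[fi]
      if (base_p == 0) next
      pb <- if (length(fem) == 1) {
        if (pop$phenotype[m] == "aS") p_big_sel[[e]] else p_big[[e]]
      } else 0   # with two females, always the small family
      mg <- gametes(pop$genotype[m])
      pat <- pop$genotype[f]    # haploid father: his single allele
      for (fam in if (pb > 0) c(2L, 1L) else 1L) {
        p_fam <- if (pb > 0) (if (fam == 2L) pb else 1 - pb) else 1
        # enumerate meiosis: maternal allele of each daughter and of the son
        combos <- expand.grid(rep(list(names(mg)), fam + 1L),
                              stringsAsFactors = FALSE)
        for (r in seq_len(nrow(combos))) {
          als <- as.character(combos[r, ])
          p_mei <- prod(vapply(als, function(a) mg[[a]], 0))
          offs <- list()
          for (d in seq_len(fam)) {
            dg <- paste(sort(c(als[d], pat)), collapse = "")
            offs[[length(offs) + 1L]] <- list(
              class = "F", genotype = dg,
              sets = stats::setNames(c(1L, 1L), c(m, f)))
          }
          offs[[length(offs) + 1L]] <- list(
            class = "M", genotype = als[fam + 1L],
            sets = stats::setNames(1L, m))
          outs[[length(outs) + 1L]] <-
            offspring_outcome(pop, model, offs, base_p * p_fam * p_mei)
        }
      }
    }
    outs
  }
  mut <- rbind(
    data.frame(class = "M", from = "a", to = c("a", "b"),
               prob = c(1 - mu, mu)),
    data.frame(class = "M", from = "b", to = c("b", "a"),
               prob = c(1 - mu, mu)),
    data.frame(class = "F", from = "aa", to = c("aa", "ab", "bb"),
               prob = c((1 - mu)^2, 2 * mu * (1 - mu), mu^2)),
    data.frame(class = "F", from = "bb", to = c("bb", "ab", "aa"),
               prob = c((1 - mu)^2, 2 * mu * (1 - mu), mu^2)),
    data.frame(class = "F", from = "ab",
               to = c("ab", "aa", "bb"),
               prob = c((1 - mu)^2 + mu^2, mu * (1 - mu), mu * (1 - mu))))
  dosage <- rbind(aa = c(1, 0), ab = c(1/2, 1/2), bb = c(0, 1),
                  a = c(1, 0), b = c(0, 1))
  colnames(dosage) <- c("a", "b")
  reproduction_model(
    classes = c("F", "M"), ploidy = c(F = 2, M = 1),
    env_states = envs, Pi = Pi,
    genotypes = c("aa", "ab", "bb", "a", "b"),
    loci = list(locus1 = c("a", "b")), dosage = dosage,
    phenotypes = c("a0", "aS"), background = "a0",
    kernel = kern, mutation = mut, bound = 1,
    initial = list(env = envs[[1]],
                   tally = c(`F|ab` = 1L, `M|a` = 1L)),
    class_genotype = c(F = "ab", M = "a"),
    name = "haplodiploid",
    kernel_spec = list(type = "builtin", name = "haplodiploid",
                       params = list(p_big = as.list(p_big),
                                     p_big_sel = as.list(p_big_sel),
                                     sel_weight = sel_weight, mu = mu)))
}

#' Selective phenotype map for the haplodiploid fixture
#'
#' Females homozygous for allele a express phenotype `"aS"`; everyone else
#' keeps the background.
#' @return A [phenotype_map()].
#' @export
h_haplodiploid_selective <- function() phenotype_map(c(`F|aa` = "aS"), "a0")

#' Age-structured fixture with density dependence
#'
#' Two haploid age classes: juveniles (`J`) mature deterministically into the
#' adult class (survival counted as a self-offspring into the next age
#' class); adults produce clonal juveniles (one in the good environment, none
#' in the bad one) and survive as adults only at low density (total
#' population size 1). The class distribution therefore fluctuates with both
#' environment and density, while the population can never die out. Genotype
#' turnover is by mutation alone.
#'
#' @param mu mutation (allele flip) probability.
#' @param Pi environment transition matrix.
#' @return A [reproduction_model()].
#' @export
make_age_density <- function(mu = 1/8, Pi = NULL) {
  Pi <- .env2(Pi)
  envs <- rownames(Pi)
  kern <- function(e, pop, model) {
    N <- nrow(pop)
    k <- if (e == envs[[1]]) 1L else 0L   # fecundity per adult
    survive <- N <= 1                     # density-dependent adult survival
    offs <- list()
    for (i in seq_len(N)) {
      if (pop$class[i] == "J") {
        offs[[length(offs) + 1L]] <- list(class = "A",
                                          genotype = pop$genotype[i],
                                          sets = stats::setNames(1L, i))
      } else {
        if (survive)
          offs[[length(offs) + 1L]] <- list(class = "A",
                                            genotype = pop$genotype[i],
                                            sets = stats::setNames(1L, i))
        for (j in seq_len(k))
          offs[[length(offs) + 1L]] <- list(class = "J",
                                            genotype = pop$genotype[i],
                                            sets = stats::setNames(1L, i))
      }
    }
    list(offspring_outcome(pop, model, offs, 1))
  }
  mut <- rbind(
    data.frame(class = rep(c("J", "A"), each = 2),
               from = rep(c("a", "b"), 2),
               to = rep(c("b", "a"), 2), prob = mu),
    data.frame(class = rep(c("J", "A"), each = 2),
               from = rep(c("a", "b"), 2),
               to = rep(c("a", "b"), 2), prob = 1 - mu))
  dosage <- rbind(a = c(1, 0), b = c(0, 1))
  colnames(dosage) <- c("a", "b")
  reproduction_model(
    classes = c("J", "A"), ploidy = c(J = 1, A = 1),
    env_states = envs, Pi = Pi,
    genotypes = c("a", "b"), loci = list(locus1 = c("a", "b")),
    dosage = dosage,
    phenotypes = c("a0", "aS"), background = "a0",
    kernel = kern, mutation = mut, bound = 2,
    initial = list(env = envs[[1]], tally = c(`A|a` = 1L)),
    class_genotype = c(J = "a", A = "a"),
    name = "age_density",
    kernel_spec = list(type = "builtin", name = "age_density",
                       params = list(mu = mu)))
}

#' Bet-hedging fixture: risky versus safe phenotypes in a fluctuating
#' environment
#'
#' A constant-size haploid population of N individuals competing for N slots:
#' each slot is filled independently by parent i with probability proportional
#' to a performance score s_i that depends on environment and phenotype. The
#' background phenotype scores 1 everywhere; the risky phenotype `"aR"`
#' scores `s_risky[e]` (high in the good environment, low in the bad one).
#' Offspring inherit the parent's genotype clonally; mutation flips alleles.
#'
#' @param N population size.
#' @param s_risky named performance of the risky phenotype per environment.
#' @param mu mutation probability.
#' @param Pi environment transition matrix.
#' @return A [reproduction_model()].
#' @export
make_bethedge <- function(N = 2, s_risky = c(e1 = 2, e2 = 1/2), mu = 1/8,
                          Pi = NULL) {
  Pi <- .env2(Pi)
  envs <- rownames(Pi)
  stopifnot(all(envs %in% names(s_risky)))
  kern <- function(e, pop, model) {
    n <- nrow(pop)
    s <- ifelse(pop$phenotype == "aR", s_risky[[e]], 1)
    pr <- s / sum(s)
    combos <- expand.grid(rep(list(seq_len(n)), n))
    outs <- list()
    for (r in seq_len(nrow(combos))) {
      winners <- as.integer(combos[r, ])
      p <- prod(pr[winners])
      offs <- lapply(winners, function(i)
        list(class = "A", genotype = pop$genotype[i],
             sets = stats::setNames(1L, i)))
      outs[[length(outs) + 1L]] <- offspring_outcome(pop, model, offs, p)
    }
    outs
  }
  mut <- rbind(
    data.frame(class = "A", from = c("r", "c"), to = c("c", "r"), prob = mu),
    data.frame(class = "A", from = c("r", "c"), to = c("r", "c"), prob = 1 - mu))
  dosage <- rbind(r = c(1, 0), c = c(0, 1))
  colnames(dosage) <- c("R", "C")
  reproduction_model(
    classes = "A", ploidy = c(A = 1), env_states = envs, Pi = Pi,
    genotypes = c("r", "c"), loci = list(locus1 = c("R", "C")),
    dosage = dosage,
    phenotypes = c("a0", "aR"), background = "a0",
    kernel = kern, mutation = mut, bound = N,
    initial = list(env = envs[[1]],
                   tally = stats::setNames(c(1L, as.integer(N - 1)),
                                           c("A|r", "A|c"))[c(TRUE, N > 1)]),
    class_genotype = c(A = "r"),
    name = "bethedge",
    kernel_spec = list(type = "builtin", name = "bethedge",
                       params = list(N = N, s_risky = as.list(s_risky),
                                     mu = mu)))
}

#' Phenotype map giving the risky phenotype to genotype r
#' @return A [phenotype_map()].
#' @export
h_bethedge_risky <- function() phenotype_map(c(`A|r` = "aR"), "a0")

#' Catalogue of built-in fixtures
#'
#' @return Data frame naming each fixture constructor and its documented
#'   expected properties.
#' @export
fixture_catalog <- function() {
  data.frame(
    fixture = c("clonal", "haplodiploid", "age_density", "bethedge"),
    constructor = c("make_clonal", "make_haplodiploid", "make_age_density",
                    "make_bethedge"),
    property = c(
      "phi* = 1/N everywhere; all fitnesses 0; chain = environment chain",
      "fluctuating class tally; dyadic kernel; full identity suite",
      "density-dependent age structure; survival as self-offspring",
      "constant size; risky/safe phenotypes with env-dependent payoffs"),
    stringsAsFactors = FALSE)
}
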