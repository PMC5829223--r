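# Transmission-share accounting. Offspring counts are measured per parental
# haploid set and weighted by the parent's genetic contribution, so the rules
# depend on the ploidies of parent and offspring at the coreplicon under
# study. All arithmetic here is exact rational.

#' Per-haploid-set share of one offspring
#'
#' When a parent contributes one haploid set to an offspring, its share is
#' 1/(offspring ploidy) (the part of the offspring belonging to this parent)
#' times 1/(parent ploidy) (shares are measured per parental haploid set).
#' Survival to the next year is counted as an offspring all of whose genes come
#' from the individual itself, giving share 1/(parent ploidy).
#'
#' @param parent_ploidy,offspring_ploidy positive integers.
#' @param contribution `"haploid_set"` for one contributed gamete, or `"self"`
#'   for a whole surviving self.
#' @return A [rational()] scalar.
#' @examples
#' gamete_share(2, 2, "haploid_set")  # 1/4
#' gamete_share(2, 2, "self")         # 1/2
#' gamete_share(1, 2, "haploid_set")  # 1/2
#' @export
gamete_share <- function(parent_ploidy, offspring_ploidy,
                         contribution = c("haploid_set", "self")) {
  contribution <- match.arg(contribution)
  stopifnot(parent_ploidy >= 1, offspring_ploidy >= 1)
  if (contribution == "haploid_set")
    rational(1, offspring_ploidy * parent_ploidy)
  else
    rational(1, parent_ploidy)
}

#' Specify a family for coreplicon share accounting
#'
#' A family lists parents with their per-coreplicon ploidies and offspring with
#' the number of haploid sets contributed by each parent at each coreplicon.
#' Ploidy 0 at a coreplicon means the individual carries no copies there (for
#' example a mother at the Y): such parents have all shares zero and such
#' offspring are skipped.
#'
#' @param parents named list: each element a named numeric vector of ploidies
#'   per coreplicon (e.g. `c(autosome = 2, X = 2, Y = 0)`).
#' @param offspring list of offspring; each a list with elements `class`,
#'   `genotype`, and `gametes`, the latter a named list per coreplicon of named
#'   integer vectors (parent label -> haploid sets contributed).
#' @param coreplicons character vector of the coreplicons covered.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(parents, offspring, coreplicons) {
  stopifnot(length(names(parents)) == length(parents))
  structure(list(parents = parents, offspring = offspring,
                 coreplicons = coreplicons), class = "family_spec")
}

#' Tabulate per-parent offspring arrays for one coreplicon
#'
#' Sums [gamete_share()] over a family's offspring, tabulated by offspring
#' (class, genotype), for the chosen coreplicon. The ploidy-weighted parental
#' shares of each whole offspring sum to exactly 1 (rational arithmetic).
#'
#' @param family a [family_spec()].
#' @param coreplicon which coreplicon to account at.
#' @param offspring_ploidy named integer vector: offspring-class ploidy at this
#'   coreplicon.
#' @return A named list per parent label; each element a list with parallel
#'   vectors `key` (`"class|genotype"`) and `share` (a [rational()] vector).
#' @export
family_shares <- function(family, coreplicon, offspring_ploidy) {
  stopifnot(inherits(family, "family_spec"), coreplicon %in% family$coreplicons)
  labels <- names(family$parents)
  acc <- lapply(labels, function(l) list(key = character(0), share = rational(numeric(0))))
  names(acc) <- labels
  add <- function(lab, key, sh) {
    a <- acc[[lab]]
    i <- match(key, a$key)
    if (is.na(i)) {
      a$key <- c(a$key, key)
      a$share <- rational(c(a$share$num, sh$num), c(a$share$den, sh$den))
    } else {
      s <- a$share[i] + sh
      a$share$num[i] <- s$num; a$share$den[i] <- s$den
    }
    acc[[lab]] <<- a
  }
  for (off in family$offspring) {
    L_off <- offspring_ploidy[[off$class]]
    if (is.null(L_off) || L_off == 0) next  # offspring carries no copies here
    g <- off$gametes[[coreplicon]]
    if (sum(g) != L_off)
      stop("offspring of class ", off$class, ": ", sum(g),
           " contributed haploid sets but ploidy ", L_off, " at ", coreplicon)
    for (lab in names(g)) {
      if (g[[lab]] == 0) next
      L_par <- family$parents[[lab]][[coreplicon]]
      if (L_par == 0)
        stop("parent ", lab, " contributes at ", coreplicon,
             " but has ploidy 0 there")
      add(lab, cg_key(off$class, off$genotype),
          rational(g[[lab]], 1) * gamete_share(L_par, L_off))
    }
  }
  # conservation: sum over parents of L_parent * share(offspring) = 1 each
  acc
}

#' The diploid XY mated pair with two daughters and one son
#'
#' The standard worked family for coreplicon accounting: a mother and father
#' under XY sex determination with two daughters and one son, a single
#' genotype, and per-coreplicon ploidies (autosomes 2/2, X 2/1, Y 0/1,
#' mitochondria 1/0 treated as haploid maternal).
#'
#' @return A [family_spec()].
#' @export
make_xy_family <- function() {
  parents <- list(
    mother = c(autosome = 2, X = 2, Y = 0, mitochondrial = 1),
    father = c(autosome = 2, X = 1, Y = 1, mitochondrial = 0)
  )
  daughter <- function() list(
    class = "female", genotype = "g",
    gametes = list(
      autosome = c(mother = 1, father = 1),
      X = c(mother = 1, father = 1),
      Y = c(mother = 0, father = 0),
      mitochondrial = c(mother = 1, father = 0)
    ))
  son <- list(
    class = "male", genotype = "g",
    gametes = list(
      autosome = c(mother = 1, father = 1),
      X = c(mother = 1, father = 0),
      Y = c(mother = 0, father = 1),
      mitochondrial = c(mother = 1, father = 0)
    ))
  family_spec(parents = parents,
              offspring = list(daughter(), daughter(), son),
              coreplicons = c("autosome", "X", "Y", "mitochondrial"))
}

#' Offspring-class ploidies for the XY family, per coreplicon
#'
#' @param coreplicon coreplicon name.
#' @return Named integer vector over classes `female`, `male`.
#' @export
xy_offspring_ploidy <- function(coreplicon = c("autosome", "X", "Y", "mitochondrial")) {
  coreplicon <- match.arg(coreplicon)
  switch(coreplicon,
    autosome = c(female = 2, male = 2),
    X = c(female = 2, male = 1),
    Y = c(female = 0, male = 1),
    mitochondrial = c(female = 1, male = 1))
}

# Look up a parent's tabulated share for one (class, genotype), as rational.
share_of <- function(shares, parent, class, genotype = "g") {
  a <- shares[[parent]]
  i <- match(cg_key(class, genotype), a$key)
  if (is.na(i)) rational(0) else a$share[i]
}
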