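# Shared fixtures, built once per test run. All are small enough for full
# enumeration; the haplodiploid model is the main two-class workhorse.

hd_model <- make_haplodiploid()
hd_chain <- demographic_chain(hd_model)
hd_phi <- solve_rv(hd_model, hd_chain, probe_starts = 0)
hd_full <- ensemble_chain(hd_model)
hd_D <- ergodic_distribution(hd_full)

clonal3 <- make_clonal(N = 3)

# A broken model for negative tests: the class of an individual's offspring
# depends directly on its genotype at fixed phenotype, violating
# genotype-through-phenotype while keeping the population bounded.
make_broken_gtp <- function() {
  Pi <- matrix(c(3/4, 1/4, 1/4, 3/4), 2, 2, byrow = TRUE,
               dimnames = list(c("e1", "e2"), c("e1", "e2")))
  kern <- function(e, pop, model) {
    shares <- lapply(seq_len(nrow(pop)), function(i) {
      cls <- if (pop$genotype[i] == "g0") "A" else "B"   # genotype-driven!
      stats::setNames(1, cg_key(cls, pop$genotype[i]))
    })
    list(list(prob = 1, shares = shares))
  }
  reproduction_model(
    classes = c("A", "B"), ploidy = c(A = 1, B = 1),
    env_states = rownames(Pi), Pi = Pi,
    genotypes = c("g0", "g1"), loci = list(locus1 = c("k0", "k1")),
    dosage = matrix(c(1, 0, 0, 1), 2, 2,
                    dimnames = list(c("g0", "g1"), c("k0", "k1"))),
    phenotypes = "a0", background = "a0",
    kernel = kern,
    mutation = {
      mg <- expand.grid(class = c("A", "B"), from = c("g0", "g1"),
                        to = c("g0", "g1"), stringsAsFactors = FALSE)
      mg$prob <- 1/2
      mg
    },
    bound = 1,
    initial = list(env = "e1", tally = c(`A|g0` = 1L, `B|g1` = 1L)),
    class_genotype = c(A = "g0", B = "g1"),
    name = "broken_gtp")
}
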