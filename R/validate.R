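# Structural validation of a reproduction model against the assumptions the
# theory rests on: permutation equivariance, genotype-through-phenotype,
# uniform boundedness, whole-individual offspring counts, and no reachable
# route to extinction. Failures are reported with witnesses, not raised.

outcome_signature <- function(ents, field = c("csum", "shares")) {
  # canonical multiset of (prob, serialized field), aggregated
  field <- match.arg(field)
  ser <- function(e) {
    if (field == "csum") return(paste(signif(as.numeric(e$csum), 10),
                                      collapse = ","))
    paste(vapply(e$shares, function(s) {
      s <- s[order(names(s))]
      paste(names(s), signif(s, 10), sep = ":", collapse = ",")
    }, ""), collapse = "|")
  }
  keys <- vapply(ents, ser, "")
  agg <- tapply(vapply(ents, function(e) e$prob, 0), keys, sum)
  paste(sort(paste(names(agg), signif(agg, 10), sep = "@")), collapse = ";")
}

#' Validate a reproduction model's structural assumptions
#'
#' Runs four checks on the reachable states of the model: (a) permutation
#' equivariance -- permuting the population permutes the outcome share arrays
#' identically in distribution; (b) genotype-through-phenotype -- genotype
#' arrays with identical class and phenotype arrays induce the same
#' distribution of genotype-summed offspring; (c) uniform boundedness of
#' shares and whole-number ploidy-weighted offspring counts; (d) no reachable
#' outcome leaves an empty (or inevitably doomed) next-year population,
#' checked by enumerating the demographic chain and confirming every state
#' has valid outcomes.
#'
#' @param model a [reproduction_model()].
#' @param n_perm number of random permutations to test per state.
#' @param seed RNG seed for the permutation draws.
#' @param state_cap cap on the enumerated state space.
#' @return An object of class `model_validation`: data frame of checks with
#'   pass/fail and a witness message.
#' @export
validate_model <- function(model, n_perm = 3, seed = 1, state_cap = 2000) {
  set.seed(seed)
  checks <- list()
  note <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  full <- tryCatch(ensemble_chain(model, state_cap = state_cap),
                   error = function(e) e)
  if (inherits(full, "error")) {
    note("reachability", FALSE, conditionMessage(full))
    out <- do.call(rbind, checks)
    class(out) <- c("model_validation", class(out))
    return(out)
  }
  note("reachability", TRUE,
       paste(nrow(full$states), "reachable full states"))

  pops <- lapply(full$states$key, function(k)
    canonical_population(model, parse_state_key(k)$tally))
  multi <- which(vapply(pops, nrow, 0L) >= 2)

  # (a) permutation equivariance
  perm_ok <- TRUE; perm_wit <- ""
  for (idx in utils::head(multi, 3)) {
    pop <- pops[[idx]]
    e <- parse_state_key(full$states$key[[idx]])$env
    ref <- enum_transitions(model, e, pop, envs = FALSE)
    for (r in seq_len(n_perm)) {
      sig <- sample(nrow(pop))
      pop2 <- pop[sig, , drop = FALSE]
      ents2 <- enum_transitions(model, e, pop2, envs = FALSE)
      # un-permute the per-individual share arrays
      for (j in seq_along(ents2))
        ents2[[j]]$shares <- ents2[[j]]$shares[order(sig)]
      if (outcome_signature(ref, "shares") != outcome_signature(ents2, "shares")) {
        perm_ok <- FALSE
        perm_wit <- paste("state", full$states$key[[idx]],
                          "permutation", paste(sig, collapse = ""))
        break
      }
    }
    if (!perm_ok) break
  }
  note("permutation_equivariance", perm_ok, perm_wit)

  # (b) genotype-through-phenotype: swap genotypes within classes, compare
  # the distribution of class-summed shares
  gtp_ok <- TRUE; gtp_wit <- ""
  class_genotypes <- lapply(stats::setNames(model$classes, model$classes),
                            function(x) {
    gs <- unique(unlist(lapply(pops, function(p) p$genotype[p$class == x])))
    gs[!is.na(gs)]
  })
  for (idx in utils::head(seq_along(pops), 6)) {
    pop <- pops[[idx]]
    e <- parse_state_key(full$states$key[[idx]])$env
    ref <- outcome_signature(enum_transitions(model, e, pop, envs = FALSE))
    for (r in seq_len(2)) {
      pop2 <- pop
      pop2$genotype <- vapply(pop$class, function(x) {
        gs <- class_genotypes[[x]]
        gs[[sample.int(length(gs), 1L)]]
      }, "")
      sig2 <- outcome_signature(enum_transitions(model, e, pop2, envs = FALSE))
      if (sig2 != ref) {
        gtp_ok <- FALSE
        gtp_wit <- paste("state", full$states$key[[idx]],
                         "genotypes", paste(pop2$genotype, collapse = ","))
        break
      }
    }
    if (!gtp_ok) break
  }
  note("genotype_through_phenotype", gtp_ok, gtp_wit)

  # (c) boundedness + integer offspring: enum_transitions errors on violation
  bound_ok <- TRUE; bound_wit <- ""
  for (idx in seq_along(pops)) {
    e <- parse_state_key(full$states$key[[idx]])$env
    res <- tryCatch({enum_transitions(model, e, pops[[idx]]); TRUE},
                    error = function(err) conditionMessage(err))
    if (!isTRUE(res)) { bound_ok <- FALSE; bound_wit <- res; break }
  }
  note("bounded_integer_offspring", bound_ok, bound_wit)

  # (d) no extinction: every reachable state has outcomes with non-empty
  # next populations (enum_transitions raises otherwise), and the chain has
  # no absorbing failure state by construction of the closure above.
  note("no_extinction", bound_ok,
       if (bound_ok) "all reachable outcomes yield non-empty populations"
       else bound_wit)

  out <- do.call(rbind, checks)
  class(out) <- c("model_validation", class(out))
  out
}

#' @export
print.model_validation <- function(x, ...) {
  cat("<model_validation>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s %s\n", if (x$pass[i]) "ok" else "FAIL",
                x$check[i], if (nzchar(x$detail[i])) paste0("- ", x$detail[i]) else ""))
  invisible(x)
}

#' @export
all_pass <- function(validation) all(validation$pass)
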