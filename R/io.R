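# Model specification files (YAML). Probabilities and shares may be decimals
# or "p/q" rational strings; rational strings are preserved verbatim on a
# round trip. Two kernel dialects are supported:
#   - builtin: a named fixture constructor plus its parameters;
#   - table:   explicit outcome tables for clonal-transmission kernels, keyed
#              by (environment, demographic tally pattern); each outcome lists
#              offspring as (class, parent slot in canonical population order),
#              with the offspring's genotype inherited from the parent.
# Arbitrary Mendelian kernels are R functions and are expressed as builtins.

.spec_keys <- c("name", "classes", "environments", "genotypes", "phenotypes",
                "kernel", "mutation", "bound", "initial", "coreplicon",
                "class_genotype")

num_of <- function(x) {
  if (is.character(x)) as.numeric(as.numeric.rational(parse_rational(x)))
  else as.numeric(x)
}

#' Read a model specification file
#'
#' @param path path to a YAML model specification.
#' @return A [reproduction_model()].
#' @export
read_model <- function(path) {
  spec <- yaml::read_yaml(path)
  unknown <- setdiff(names(spec), .spec_keys)
  if (length(unknown))
    stop("unknown key in model specification: ", unknown[[1]])
  model_from_spec(spec)
}

model_from_spec <- function(spec) {
  kern <- spec$kernel
  if (identical(kern$type, "builtin")) {
    ctor <- switch(kern$name,
                   clonal = make_clonal,
                   haplodiploid = make_haplodiploid,
                   age_density = make_age_density,
                   bethedge = make_bethedge,
                   stop("unknown builtin kernel: ", kern$name))
    params <- kern$params
    # named numeric lists (e.g. per-environment probabilities) arrive as lists
    params <- lapply(params, function(p) {
      if (is.list(p)) unlist(lapply(p, num_of))
      else if (is.character(p)) num_of(p)
      else p
    })
    m <- do.call(ctor, params)
    # keep the file's own kernel description (preserves rational strings)
    m$kernel_spec <- kern
    return(m)
  }
  if (!identical(kern$type, "table"))
    stop("kernel type must be 'builtin' or 'table'")
  classes <- vapply(spec$classes, function(x) x$id, "")
  ploidy <- stats::setNames(vapply(spec$classes, function(x) as.integer(x$ploidy), 0L),
                            classes)
  envs <- vapply(spec$environments$states, identity, "")
  Pi <- do.call(rbind, lapply(spec$environments$transition,
                              function(row) vapply(row, num_of, 0)))
  dimnames(Pi) <- list(envs, envs)
  genotypes <- vapply(spec$genotypes, function(g) g$id, "")
  loci <- list()
  dosage_rows <- list()
  for (g in spec$genotypes) {
    for (loc in names(g$dosage)) {
      al <- names(g$dosage[[loc]])
      loci[[loc]] <- union(loci[[loc]] %||% character(0), al)
    }
  }
  alleles <- unlist(loci, use.names = FALSE)
  dosage <- matrix(0, length(genotypes), length(alleles),
                   dimnames = list(genotypes, alleles))
  for (g in spec$genotypes)
    for (loc in names(g$dosage))
      for (al in names(g$dosage[[loc]]))
        dosage[g$id, al] <- num_of(g$dosage[[loc]][[al]])
  entries <- lapply(spec$kernel$entries, function(en) {
    list(env = en$env,
         tally = stats::setNames(vapply(en$tally, as.integer, 0L),
                                 names(en$tally)),
         outcomes = lapply(en$outcomes, function(o)
           list(prob = num_of(o$prob),
                offspring = lapply(o$offspring, function(x)
                  list(class = x$class, parent = as.integer(x$parent))))))
  })
  kern_fn <- function(e, pop, model) {
    d <- demographic_tally(pop)
    hit <- NULL
    for (en in entries)
      if (en$env == e && identical(canon_tally(en$tally), d)) { hit <- en; break }
    if (is.null(hit))
      stop("table kernel has no entry for (", e, ", ", tally_key(d), ")")
    lapply(hit$outcomes, function(o) {
      offs <- lapply(o$offspring, function(x) {
        i <- x$parent
        list(class = x$class, genotype = pop$genotype[i],
             sets = stats::setNames(model$ploidy[[x$class]], i))
      })
      offspring_outcome(pop, model, offs, o$prob)
    })
  }
  mutation <- if (is.null(spec$mutation)) NULL else
    do.call(rbind, lapply(spec$mutation, function(m)
      data.frame(class = m$class, from = m$from, to = m$to,
                 prob = num_of(m$prob), stringsAsFactors = FALSE)))
  reproduction_model(
    classes = classes, ploidy = ploidy, env_states = envs, Pi = Pi,
    genotypes = genotypes, loci = loci, dosage = dosage,
    phenotypes = vapply(spec$phenotypes$ids, identity, ""),
    background = spec$phenotypes$background,
    kernel = kern_fn, mutation = mutation, bound = num_of(spec$bound),
    initial = list(env = spec$initial$env,
                   tally = stats::setNames(
                     vapply(spec$initial$tally, as.integer, 0L),
                     names(spec$initial$tally))),
    class_genotype = stats::setNames(
      vapply(spec$class_genotype, identity, ""), names(spec$class_genotype)),
    coreplicon = spec$coreplicon %||% "autosome",
    name = spec$name %||% "model",
    kernel_spec = spec$kernel)
}

#' Write a model specification file
#'
#' Only models carrying a serialisable kernel description (builtin fixtures or
#' table kernels) can be written; `read_model(write_model(m))` reproduces the
#' model.
#'
#' @param model a reproduction model with a `kernel_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (is.null(model$kernel_spec))
    stop("model has no serialisable kernel description (kernel_spec)")
  spec <- list(
    name = model$name,
    classes = lapply(model$classes, function(x)
      list(id = x, ploidy = as.integer(model$ploidy[[x]]))),
    environments = list(
      states = as.list(model$env_states),
      transition = lapply(model$env_states, function(e)
        as.list(model$Pi[e, ]))),
    genotypes = lapply(model$genotypes, function(g) {
      dl <- lapply(model$loci, function(al)
        as.list(stats::setNames(as.numeric(model$dosage[g, al]), al)))
      list(id = g, dosage = dl)
    }),
    phenotypes = list(ids = as.list(model$phenotypes),
                      background = model$background),
    kernel = model$kernel_spec,
    mutation = if (is.null(model$mutation)) NULL else
      lapply(seq_len(nrow(model$mutation)), function(i)
        as.list(model$mutation[i, ])),
    bound = model$bound,
    initial = list(env = model$initial$env,
                   tally = as.list(model$initial$tally)),
    coreplicon = model$coreplicon,
    class_genotype = as.list(model$class_genotype))
  yaml::write_yaml(spec, path)
  invisible(path)
}
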