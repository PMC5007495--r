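#' Genetic-programming classifier configuration
#'
#' Symbolic one-vs-rest discriminants over the feature set, evolved by a
#' generational GP with tournament parent selection and an
#' offspring-selection acceptance rule: an offspring enters the next
#' generation only if its fitness strictly exceeds
#' `comparison_factor` times the better parent's fitness, until
#' `success_ratio` of the generation is filled or the per-generation
#' effort budget (`max_effort_factor * population_size` evaluations) is
#' exhausted, at which point evolution stops (selection pressure
#' exceeded) and the best individual so far is returned.
#'
#' @param population_size individuals per generation (>= 10).
#' @param max_tree_depth maximum expression depth (>= 2).
#' @param max_generations generation budget.
#' @param success_ratio fraction of the next generation that must come
#'   from accepted offspring.
#' @param comparison_factor weight of the parent fitness in the
#'   acceptance threshold.
#' @param tournament_size parent tournament size.
#' @param mutation_prob per-offspring subtree mutation probability.
#' @param max_effort_factor per-generation evaluation budget in units of
#'   `population_size`.
#' @param const_range ephemeral constants are drawn uniformly from
#'   `[-const_range, const_range]` (features are z-scored).
#' @return object of class `rhd_gp_config`.
#' @export
gp_config <- function(population_size = 100, max_tree_depth = 7,
                      max_generations = 50, success_ratio = 1,
                      comparison_factor = 1, tournament_size = 3,
                      mutation_prob = 0.15, max_effort_factor = 20,
                      const_range = 3) {
  stopifnot(population_size >= 10, max_tree_depth >= 2,
            max_generations >= 1, tournament_size >= 1)
  structure(as.list(environment()), class = "rhd_gp_config")
}

# ---- expression trees -------------------------------------------------
# A tree is a nested list: list("op", name, left, right),
# list("var", j) or list("const", v). Function set: +, -, *, protected
# division. Trees are compiled to R calls and evaluated vectorised.

gp_ops <- c("+", "-", "*", "pdiv")

pdiv <- function(a, b) {
  r <- a / b
  r[!is.finite(r)] <- 1
  r
}

random_tree <- function(depth, d, cfg, full = FALSE) {
  if (depth <= 1 || (!full && runif(1) < 0.3)) {
    if (runif(1) < 0.7) list("var", sample.int(d, 1))
    else list("const", runif(1, -cfg$const_range, cfg$const_range))
  } else {
    op <- gp_ops[sample.int(4, 1)]
    list("op", op, random_tree(depth - 1, d, cfg, full),
         random_tree(depth - 1, d, cfg, full))
  }
}

tree_depth <- function(t) {
  if (t[[1]] != "op") 1L else 1L + max(tree_depth(t[[3]]), tree_depth(t[[4]]))
}

tree_size <- function(t) {
  if (t[[1]] != "op") 1L else 1L + tree_size(t[[3]]) + tree_size(t[[4]])
}

# preorder node access (1 = root)
tree_get <- function(t, idx) {
  if (idx == 1) return(t)
  idx <- idx - 1
  sl <- tree_size(t[[3]])
  if (idx <= sl) tree_get(t[[3]], idx) else tree_get(t[[4]], idx - sl)
}

tree_set <- function(t, idx, sub) {
  if (idx == 1) return(sub)
  idx <- idx - 1
  sl <- tree_size(t[[3]])
  if (idx <= sl) t[[3]] <- tree_set(t[[3]], idx, sub)
  else t[[4]] <- tree_set(t[[4]], idx - sl, sub)
  t
}

tree_to_call <- function(t) {
  switch(t[[1]],
    var = as.name(paste0("x", t[[2]])),
    const = t[[2]],
    op = as.call(list(as.name(t[[2]]), tree_to_call(t[[3]]),
                      tree_to_call(t[[4]]))))
}

eval_tree <- function(expr, env, n) {
  v <- eval(expr, env)
  if (length(v) == 1) v <- rep(v, n)
  v[!is.finite(v)] <- 0
  v
}

gp_env <- function(X) {
  env <- new.env(parent = baseenv())
  for (j in seq_len(ncol(X))) assign(paste0("x", j), X[, j], envir = env)
  assign("pdiv", pdiv, envir = env)
  env
}

gp_crossover <- function(p1, p2) {
  i <- sample.int(tree_size(p1), 1)
  j <- sample.int(tree_size(p2), 1)
  tree_set(p1, i, tree_get(p2, j))
}

gp_mutate <- function(t, d, cfg) {
  i <- sample.int(tree_size(t), 1)
  node <- tree_get(t, i)
  if (node[[1]] == "const" && runif(1) < 0.5)
    tree_set(t, i, list("const", node[[2]] + rnorm(1, 0, 0.5)))
  else tree_set(t, i, random_tree(2, d, cfg))
}

# ---- evolution --------------------------------------------------------

evolve_gp_binary <- function(X, yk, cfg) {
  n <- nrow(X); d <- ncol(X)
  env <- gp_env(X)
  fitness <- function(t) {
    v <- eval_tree(tree_to_call(t), env, n)
    mean((v > 0) == yk)
  }
  depths <- rep(2:4, length.out = cfg$population_size)
  pop <- lapply(seq_len(cfg$population_size), function(i)
    random_tree(depths[i], d, cfg, full = i %% 2 == 0))
  fit <- vapply(pop, fitness, numeric(1))
  for (gen in seq_len(cfg$max_generations)) {
    best <- which.max(fit)
    if (fit[best] >= 1) break
    target <- ceiling(cfg$success_ratio * (cfg$population_size - 1))
    newpop <- list(pop[[best]]); newfit <- fit[best]   # elite
    effort <- 0; cap <- cfg$max_effort_factor * cfg$population_size
    tournament <- function() {
      cand <- sample.int(cfg$population_size, cfg$tournament_size)
      cand[which.max(fit[cand])]
    }
    while (length(newpop) < cfg$population_size && effort < cap) {
      i1 <- tournament(); i2 <- tournament()
      child <- gp_crossover(pop[[i1]], pop[[i2]])
      if (runif(1) < cfg$mutation_prob) child <- gp_mutate(child, d, cfg)
      if (tree_depth(child) > cfg$max_tree_depth) child <- pop[[i1]]
      fc <- fitness(child)
      effort <- effort + 1
      accepted <- fc > cfg$comparison_factor * max(fit[i1], fit[i2])
      filled <- length(newpop) - 1
      if (accepted || filled >= target) {
        newpop[[length(newpop) + 1]] <- child
        newfit <- c(newfit, fc)
      }
    }
    stagnated <- length(newpop) < cfg$population_size
    if (stagnated) {   # fill from best parents, then stop (max pressure)
      ord <- order(-fit)
      need <- cfg$population_size - length(newpop)
      for (i in seq_len(need)) {
        newpop[[length(newpop) + 1]] <- pop[[ord[i]]]
        newfit <- c(newfit, fit[ord[i]])
      }
    }
    pop <- newpop; fit <- newfit
    if (stagnated) break
  }
  best <- which.max(fit)
  list(tree = pop[[best]], fitness = fit[best])
}

#' Evolve a genetic-programming classifier
#'
#' One binary discriminant tree per class (one-vs-rest); prediction is
#' the arg-max of the per-class outputs. Deterministic for a fixed RNG
#' state.
#'
#' @param X z-scored feature matrix.
#' @param y integer class indices `1..K`.
#' @param K number of classes.
#' @param cfg [gp_config()].
#' @return model list (class trees, fitnesses) usable by the ensemble.
#' @export
evolve_gp_classifier <- function(X, y, K, cfg = gp_config()) {
  stopifnot(length(unique(y)) >= 1, nrow(X) == length(y))
  fits <- lapply(seq_len(K), function(k)
    evolve_gp_binary(X, y == k, cfg))
  trees <- lapply(fits, `[[`, "tree")
  # per-tree output scale on the training data: the one-vs-rest
  # discriminants are on arbitrary scales, so prediction compares
  # z-normalised outputs instead of raw ones
  env <- gp_env(X)
  n <- nrow(X)
  scale <- t(vapply(trees, function(t) {
    v <- eval_tree(tree_to_call(t), env, n)
    c(mean(v), max(sd(v), 1e-8))
  }, numeric(2)))
  list(alg = "GP", trees = trees, score_scale = scale,
       train_fitness = vapply(fits, `[[`, numeric(1), "fitness"), K = K)
}

gp_scores <- function(model, X) {
  env <- gp_env(X)
  n <- nrow(X)
  s <- vapply(model$trees, function(t) eval_tree(tree_to_call(t), env, n),
              numeric(n))
  if (is.null(dim(s))) s <- matrix(s, nrow = n)
  sweep(sweep(s, 2, model$score_scale[, 1]), 2, model$score_scale[, 2], "/")
}
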