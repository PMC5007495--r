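# Internal classifier layer behind the voting ensemble. All algorithms
# consume z-scored feature matrices and integer class indices 1..K and
# return class indices; ties are broken by the supplied priority order.

argmax_prio <- function(scores, prio) {
  # scores: n x K; prio: class indices, highest priority first
  apply(scores, 1, function(s) {
    cand <- which(s == max(s))
    cand[which.min(match(cand, prio))]
  })
}

fit_model <- function(alg, X, y, K, cfg) {
  switch(alg,
    RF = list(alg = "RF",
              forest = forest_fit_cpp(X, as.integer(y - 1), K,
                                      as.integer(cfg$rf_ntree),
                                      max(1L, as.integer(floor(sqrt(ncol(X))))),
                                      as.integer(cfg$rf_maxdepth), 1L),
              K = K),
    SVM = fit_svm_rbf(X, y, K, C = cfg$svm_C),
    KNN = list(alg = "KNN", X = X, y = y, K = K, k = cfg$knn_k),
    GP = evolve_gp_classifier(X, y, K, cfg$gp),
    stop("unknown algorithm: ", alg))
}

predict_model <- function(model, X, prio) {
  scores <- switch(model$alg,
    RF = forest_votes_cpp(model$forest, X, model$K),
    SVM = predict_svm_scores(model, X),
    KNN = knn_scores(model, X),
    GP = gp_scores(model, X))
  argmax_prio(scores, prio)
}

# ---- RBF-kernel SVM (one-vs-rest, dual coordinate ascent) -------------
# The bias is absorbed by augmenting the kernel with +1, which removes
# the equality constraint and makes box-constrained coordinate ascent
# exact and deterministic.

rbf_gram <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(D2, 0))
}

fit_svm_rbf <- function(X, y, K, C = 1, max_passes = 80, tol = 1e-3) {
  n <- nrow(X); gamma <- 1 / ncol(X)
  Kt <- rbf_gram(X, X, gamma) + 1
  alphas <- matrix(0, n, K)
  for (k in seq_len(K)) {
    yk <- ifelse(y == k, 1, -1)
    a <- numeric(n); f <- numeric(n)
    for (pass in seq_len(max_passes)) {
      delta_max <- 0
      for (i in seq_len(n)) {
        d <- (1 - yk[i] * f[i]) / Kt[i, i]
        ai <- min(max(a[i] + d, 0), C)
        d <- ai - a[i]
        if (d != 0) {
          f <- f + d * yk[i] * Kt[, i]
          a[i] <- ai
          delta_max <- max(delta_max, abs(d))
        }
      }
      if (delta_max < tol) break
    }
    alphas[, k] <- a * yk
  }
  list(alg = "SVM", X = X, alphas = alphas, gamma = gamma, K = K)
}

predict_svm_scores <- function(model, X) {
  G <- rbf_gram(X, model$X, model$gamma) + 1
  G %*% model$alphas
}

# ---- k-nearest neighbours --------------------------------------------

knn_scores <- function(model, X) {
  an <- rowSums(X^2); bn <- rowSums(model$X^2)
  D2 <- outer(an, bn, "+") - 2 * X %*% t(model$X)
  k <- min(model$k, nrow(model$X))
  scores <- matrix(0, nrow(X), model$K)
  for (i in seq_len(nrow(X))) {
    nb <- order(D2[i, ])[seq_len(k)]
    tab <- tabulate(model$y[nb], nbins = model$K)
    scores[i, ] <- tab
  }
  scores
}

# ---- feature scaling --------------------------------------------------

zscore_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  list(mu = mu, s = s)
}

zscore_apply <- function(X, zs) sweep(sweep(X, 2, zs$mu), 2, zs$s, "/")
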