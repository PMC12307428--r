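# Internal learner implementations backing the classifier catalog.
# Each .fit_* returns a model list with a $predict(newX) closure producing
# integer class indices into $levels. The environment ships no tree/SVM/NN
# packages, so these are self-contained; hyperparameters follow widely used
# GUI presets and live in .variant_presets().

# ---- decision tree (CART, gini) ----------------------------------------

# exact split scan over (a subset of) features; returns NULL if no gain
.best_split <- function(X, yint, K, mtry = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  cols <- if (is.null(mtry) || mtry >= p) seq_len(p)
          else sort(sample.int(p, mtry))
  counts <- tabulate(yint, K)
  g_parent <- 1 - sum((counts / n)^2)
  best <- NULL
  best_score <- g_parent - 1e-12
  for (j in cols) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]
    ys <- yint[o]
    valid <- which(xs[-n] < xs[-1L])
    if (!length(valid)) next
    cum <- vapply(seq_len(K), function(c) cumsum(ys == c), numeric(n))
    i <- valid
    nl <- i
    nr <- n - i
    gl <- 1 - rowSums((cum[i, , drop = FALSE] / nl)^2)
    gr <- 1 - rowSums((sweep(-cum[i, , drop = FALSE], 2, counts, "+") / nr)^2)
    score <- (nl * gl + nr * gr) / n
    m <- which.min(score)
    if (score[m] < best_score) {
      best_score <- score[m]
      best <- list(feature = j,
                   threshold = (xs[i[m]] + xs[i[m] + 1L]) / 2,
                   score = score[m])
    }
  }
  best
}

.tree_fit <- function(X, y, max_splits = 20L, min_leaf = 1L, mtry = NULL) {
  levels_y <- levels(y)
  yint <- as.integer(y)
  K <- length(levels_y)
  nodes <- list()
  splits_left <- max_splits
  grow <- function(idx) {
    id <- length(nodes) + 1L
    counts <- tabulate(yint[idx], K)
    node <- list(pred = which.max(counts), leaf = TRUE)
    nodes[[id]] <<- node
    pure <- sum(counts > 0) <= 1L
    if (!pure && splits_left > 0L && length(idx) >= 2L * min_leaf) {
      sp <- .best_split(X[idx, , drop = FALSE], yint[idx], K, mtry)
      if (!is.null(sp)) {
        left <- idx[X[idx, sp$feature] <= sp$threshold]
        right <- setdiff(idx, left)
        if (length(left) >= min_leaf && length(right) >= min_leaf) {
          splits_left <<- splits_left - 1L
          node$leaf <- FALSE
          node$feature <- sp$feature
          node$threshold <- sp$threshold
          nodes[[id]] <<- node
          node$left <- grow(left)
          node$right <- grow(right)
          nodes[[id]] <<- node
        }
      }
    }
    id
  }
  grow(seq_len(nrow(X)))
  tree <- list(nodes = nodes, levels = levels_y)
  tree$predict <- function(newX) .tree_predict(tree, newX)
  tree
}

.tree_predict <- function(tree, newX) {
  n <- nrow(newX)
  out <- integer(n)
  for (r in seq_len(n)) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$leaf) { out[r] <- nd$pred; break }
      id <- if (newX[r, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }
  out
}

# ---- naive Bayes --------------------------------------------------------

.nb_fit <- function(X, y, kernel = FALSE) {
  levels_y <- levels(y)
  K <- length(levels_y)
  classes <- lapply(seq_len(K), function(c) X[as.integer(y) == c, , drop = FALSE])
  priors <- vapply(classes, nrow, integer(1)) / nrow(X)
  if (!kernel) {
    mu <- t(vapply(classes, colMeans, numeric(ncol(X))))
    vr <- t(vapply(classes, function(M) {
      v <- apply(M, 2, var)
      pmax(v, 1e-9 * max(1, mean(v)))
    }, numeric(ncol(X))))
    predict_fun <- function(newX) {
      ll <- vapply(seq_len(K), function(c) {
        rowSums(-0.5 * (sweep(newX, 2, mu[c, ])^2) / rep(vr[c, ], each = nrow(newX)) -
                  0.5 * rep(log(2 * pi * vr[c, ]), each = nrow(newX)))
      }, numeric(nrow(newX)))
      max.col(ll + rep(log(priors), each = nrow(newX)), ties.method = "first")
    }
  } else {
    bw <- lapply(classes, function(M) {
      apply(M, 2, function(v) {
        h <- tryCatch(bw.nrd0(v), error = function(e) 0)
        if (!is.finite(h) || h <= 0) max(sd(v), 1e-3) else h
      })
    })
    predict_fun <- function(newX) {
      n <- nrow(newX)
      ll <- matrix(0, n, K)
      for (c in seq_len(K)) {
        M <- classes[[c]]
        h <- bw[[c]]
        for (j in seq_len(ncol(newX))) {
          d <- outer(newX[, j], M[, j], "-") / h[j]
          dens <- rowMeans(dnorm(d)) / h[j]
          ll[, c] <- ll[, c] + log(pmax(dens, 1e-300))
        }
      }
      max.col(ll + rep(log(priors), each = n), ties.method = "first")
    }
  }
  list(levels = levels_y, predict = predict_fun)
}

# ---- least-squares kernel SVM (one-vs-rest) -----------------------------

.kernel_matrix <- function(A, B, kernel, scale, degree) {
  switch(kernel,
         linear = A %*% t(B),
         poly = (1 + (A %*% t(B)) / scale^2)^degree,
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
           exp(-pmax(d2, 0) / (2 * scale^2))
         },
         stop("unknown kernel: ", kernel))
}

.lssvm_fit <- function(X, y, kernel = "linear", scale = NULL, degree = 1,
                       lambda = 1) {
  levels_y <- levels(y)
  K <- length(levels_y)
  if (is.null(scale)) scale <- sqrt(ncol(X))
  Km <- .kernel_matrix(X, X, kernel, scale, degree)
  Y <- vapply(seq_len(K), function(c) ifelse(as.integer(y) == c, 1, -1),
              numeric(nrow(X)))
  A <- solve(Km + diag(lambda, nrow(X)), Y)
  list(levels = levels_y, predict = function(newX) {
    scores <- .kernel_matrix(newX, X, kernel, scale, degree) %*% A
    max.col(scores, ties.method = "first")
  })
}

# ---- k-nearest neighbours ----------------------------------------------

.knn_fit <- function(X, y, k = 10L, metric = c("euclidean", "minkowski3",
                                               "cosine")) {
  metric <- match.arg(metric)
  levels_y <- levels(y)
  K <- length(levels_y)
  yint <- as.integer(y)
  k <- min(k, nrow(X))
  Xn <- if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2)); X / ifelse(nrm > 0, nrm, 1)
  } else X
  list(levels = levels_y, predict = function(newX) {
    n <- nrow(newX)
    out <- integer(n)
    if (metric == "cosine") {
      nrm <- sqrt(rowSums(newX^2))
      S <- (newX / ifelse(nrm > 0, nrm, 1)) %*% t(Xn)   # similarity
      for (r in seq_len(n)) {
        nb <- yint[order(-S[r, ])[seq_len(k)]]
        out[r] <- which.max(tabulate(nb, K))
      }
    } else {
      pw <- if (metric == "minkowski3") 3 else 2
      for (r in seq_len(n)) {
        d <- rowSums(abs(Xn - rep(newX[r, ], each = nrow(Xn)))^pw)
        nb <- yint[order(d)[seq_len(k)]]
        out[r] <- which.max(tabulate(nb, K))
      }
    }
    out
  })
}

# ---- ensembles ----------------------------------------------------------

.vote <- function(pred_matrix, K) {
  # pred_matrix: n x B integer predictions; deterministic ties (lowest class)
  apply(pred_matrix, 1, function(v) which.max(tabulate(v, K)))
}

.bag_fit <- function(X, y, B = 30L, max_splits = 30L) {
  levels_y <- levels(y)
  K <- length(levels_y)
  mtry <- max(2L, ceiling(sqrt(ncol(X))))
  members <- lapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(X), replace = TRUE)
    .tree_fit(X[idx, , drop = FALSE], y[idx], max_splits = max_splits,
              mtry = mtry)
  })
  list(levels = levels_y, predict = function(newX) {
    P <- vapply(members, function(m) .tree_predict(m, newX),
                integer(nrow(newX)))
    .vote(matrix(P, nrow = nrow(newX)), K)
  })
}

# SAMME boosting over shallow trees; weighted fitting is approximated by
# weighted resampling each round (deterministic under the ambient seed)
.boost_fit <- function(X, y, B = 30L, max_splits = 10L, rus = FALSE) {
  levels_y <- levels(y)
  K <- length(levels_y)
  yint <- as.integer(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  members <- list()
  alphas <- numeric(0)
  for (b in seq_len(B)) {
    pool <- seq_len(n)
    wts <- w
    if (rus) {
      # random undersampling: equalize class counts before resampling
      m <- min(tabulate(yint, K))
      pool <- unlist(lapply(seq_len(K), function(c) {
        idx <- which(yint == c)
        if (length(idx) > m) sample(idx, m) else idx
      }))
      wts <- w[pool]
    }
    idx <- sample(pool, size = length(pool), replace = TRUE,
                  prob = wts / sum(wts))
    fit <- .tree_fit(X[idx, , drop = FALSE], y[idx], max_splits = max_splits)
    pred <- .tree_predict(fit, X)
    err <- sum(w * (pred != yint)) / sum(w)
    if (err >= 1 - 1 / K) next            # weaker than chance: discard round
    err <- max(err, 1e-10)
    a <- log((1 - err) / err) + log(K - 1)
    members[[length(members) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(a * (pred != yint))
    w <- w / sum(w)
  }
  if (!length(members)) {                 # fall back to a single tree
    members <- list(.tree_fit(X, y, max_splits = max_splits))
    alphas <- 1
  }
  list(levels = levels_y, predict = function(newX) {
    scores <- matrix(0, nrow(newX), K)
    for (b in seq_along(members)) {
      p <- .tree_predict(members[[b]], newX)
      scores[cbind(seq_len(nrow(newX)), p)] <-
        scores[cbind(seq_len(nrow(newX)), p)] + alphas[b]
    }
    max.col(scores, ties.method = "first")
  })
}

.subspace_fit <- function(X, y, base = c("discriminant", "knn"), B = 30L) {
  base <- match.arg(base)
  levels_y <- levels(y)
  K <- length(levels_y)
  d <- max(2L, floor(ncol(X) / 2))
  members <- list()
  for (b in seq_len(B)) {
    feats <- sort(sample.int(ncol(X), min(d, ncol(X))))
    Xs <- X[, feats, drop = FALSE]
    fit <- if (base == "discriminant") {
      tryCatch(suppressWarnings(MASS::lda(Xs, grouping = y)),
               error = function(e) NULL)
    } else {
      .knn_fit(Xs, y, k = 1L, metric = "euclidean")
    }
    if (!is.null(fit)) members[[length(members) + 1L]] <- list(feats = feats,
                                                               fit = fit)
  }
  if (!length(members)) stop("no subspace learner could be fitted")
  list(levels = levels_y, predict = function(newX) {
    P <- vapply(members, function(m) {
      Xs <- newX[, m$feats, drop = FALSE]
      if (inherits(m$fit, "lda")) {
        as.integer(predict(m$fit, Xs)$class)
      } else m$fit$predict(Xs)
    }, integer(nrow(newX)))
    .vote(matrix(P, nrow = nrow(newX)), K)
  })
}

# ---- multilayer perceptron ---------------------------------------------

# fully connected ReLU net with softmax output, Adam, full-batch training
.mlp_fit <- function(X, y, hidden = c(10L), epochs = 200L, lr = 0.01,
                     l2 = 1e-4) {
  levels_y <- levels(y)
  K <- length(levels_y)
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, K)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l) {
    matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1L])
  })
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
  Yoh <- matrix(0, n, K)
  Yoh[cbind(seq_len(n), as.integer(y))] <- 1
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  forward <- function(A0) {
    acts <- vector("list", L + 1L)
    acts[[1L]] <- A0
    for (l in seq_len(L)) {
      Z <- acts[[l]] %*% W[[l]] + rep(b[[l]], each = nrow(A0))
      acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
    }
    acts
  }
  for (t in seq_len(epochs)) {
    acts <- forward(X)
    Z <- acts[[L + 1L]]
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    delta <- (P - Yoh) / n
    for (l in rev(seq_len(L))) {
      gW <- t(acts[[l]]) %*% delta + l2 * W[[l]]
      gb <- colSums(delta)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
        (sqrt(vW[[l]] / (1 - b2^t)) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
        (sqrt(vb[[l]] / (1 - b2^t)) + eps)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(levels = levels_y, predict = function(newX) {
    acts <- forward(newX)
    max.col(acts[[L + 1L]], ties.method = "first")
  })
}

# ---- random-Fourier-feature kernel approximation ------------------------

.rff_fit <- function(X, y, variant = c("svm", "logistic"), m = 256L,
                     lambda = 1) {
  variant <- match.arg(variant)
  levels_y <- levels(y)
  K <- length(levels_y)
  p <- ncol(X)
  s <- sqrt(p)
  W <- matrix(rnorm(p * m, sd = 1 / s), p, m)
  bph <- runif(m, 0, 2 * pi)
  phi <- function(A) sqrt(2 / m) * cos(A %*% W + rep(bph, each = nrow(A)))
  Z <- phi(X)
  if (variant == "svm") {
    Y <- vapply(seq_len(K), function(c) ifelse(as.integer(y) == c, 1, -1),
                numeric(nrow(X)))
    beta <- solve(crossprod(Z) + diag(lambda, m), crossprod(Z, Y))
    pred <- function(newX) max.col(phi(newX) %*% beta, ties.method = "first")
  } else {
    # softmax regression on the random features (a linear net, reusing Adam)
    fit <- .mlp_fit(Z, y, hidden = integer(0), epochs = 300L, lr = 0.05,
                    l2 = lambda / nrow(X))
    pred <- function(newX) fit$predict(phi(newX))
  }
  list(levels = levels_y, predict = pred)
}

# ---- discriminant analysis ---------------------------------------------

.da_fit <- function(X, y, quadratic = FALSE) {
  levels_y <- levels(y)
  fit <- if (quadratic) MASS::qda(X, grouping = y)
         else suppressWarnings(MASS::lda(X, grouping = y))
  list(levels = levels_y, predict = function(newX) {
    as.integer(predict(fit, newX)$class)
  })
}
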