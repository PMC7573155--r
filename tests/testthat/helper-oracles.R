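# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths.

# KMO/MSA via explicit residual regressions: the partial correlation of items
# i and j given all others is the correlation of the residuals of each
# regressed on the remaining items.
oracle_kmo <- function(R) {
  p <- nrow(R)
  A <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others)) {
        # regression coefficients from the correlation matrix
        Roo <- R[others, others, drop = FALSE]
        bi <- solve(Roo, R[others, i])
        bj <- solve(Roo, R[others, j])
        num <- R[i, j] - sum(bi * R[others, j])
        den <- sqrt((1 - sum(bi * R[others, i])) * (1 - sum(bj * R[others, j])))
        A[i, j] <- A[j, i] <- num / den
      } else {
        A[i, j] <- A[j, i] <- R[i, j]
      }
    }
  }
  R0 <- R; diag(R0) <- 0
  kmo <- sum(R0^2) / (sum(R0^2) + sum(A^2))
  msa <- rowSums(R0^2) / (rowSums(R0^2) + rowSums(A^2))
  list(kmo = kmo, msa = msa, anti_image = A)
}

# Connected components by transitive closure of the adjacency matrix.
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- (adj != 0) | diag(n) > 0
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  memb <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(memb[v])) {
      cid <- cid + 1
      memb[which(reach[v, ])] <- cid
    }
  }
  has_edge <- rowSums(adj != 0) > 0
  comps <- list()
  for (c0 in unique(memb[has_edge])) {
    nodes <- sort(which(memb == c0 & has_edge))
    idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
    keep <- idx[, 1] %in% nodes
    comps[[length(comps) + 1]] <- list(nodes = nodes,
                                       edges = idx[keep, , drop = FALSE])
  }
  comps
}

# AUC by explicit pair counting (ties one half).
oracle_auc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  pos <- score[outcome]; neg <- score[!outcome]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Per-edge t by explicit normal equations.
oracle_edge_t <- function(y, X, interest) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  beta[interest] / sqrt(s2 * solve(XtX)[interest, interest])
}

# Tucker congruence between matched columns after sign/permutation
# alignment by greedy best match.
aligned_congruence <- function(true_lambda, est_lambda) {
  congr <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- ncol(true_lambda)
  avail <- seq_len(ncol(est_lambda))
  out <- numeric(k)
  for (f in seq_len(k)) {
    cc <- vapply(avail, function(j) abs(congr(true_lambda[, f],
                                              est_lambda[, j])), 0)
    best <- which.max(cc)
    out[f] <- cc[best]
    avail <- avail[-best]
  }
  out
}

# Small helper: a null study (no planted effect) with standard-normal
# score changes.
null_study <- function(n_subjects = 30, n_nodes = 46, seed = 1) {
  spec <- synth_spec(n_subjects = n_subjects, n_nodes = n_nodes, seed = seed)
  set.seed(seed + 10000)
  gen_connectivity_study(spec, rnorm(n_subjects), keep_matrices = FALSE)
}

# A study with a planted predictive path component.
planted_study <- function(n_subjects = 40, n_nodes = 60, rho = 0.6,
                          n_planted = 10, seed = 1) {
  spec <- synth_spec(n_subjects = n_subjects, n_nodes = n_nodes,
                     planted_edges = planted_path_edges(n_planted),
                     effect_rho = rho, seed = seed)
  set.seed(seed + 20000)
  gen_connectivity_study(spec, rnorm(n_subjects), keep_matrices = FALSE)
}
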