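# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# ARI by exhaustive enumeration of entity pairs
ari_pair_oracle <- function(p1, p2) {
  n <- length(p1)
  s11 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- p1[i] == p1[j]
    b <- p2[i] == p2[j]
    if (a && b) s11 <- s11 + 1
    else if (a) s10 <- s10 + 1
    else if (b) s01 <- s01 + 1
  }
  np <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- (s11 + s10 + s11 + s01) / 2
  if (abs(max_idx - exp_idx) < 1e-12) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# cophenetic matrix by walking the merge list for the first common cluster
coph_oracle <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1)
  getm <- function(idx) if (idx < 0) -idx else members[[idx]]
  D <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  for (i in seq_len(n - 1)) {
    a <- getm(hc$merge[i, 1]); b <- getm(hc$merge[i, 2])
    for (x in a) for (y in b) D[x, y] <- D[y, x] <- hc$height[i]
    members[[i]] <- c(a, b)
  }
  D
}

# all-pairs shortest paths by repeated relaxation (Bellman-Ford style)
sp_oracle <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  repeat {
    Dnew <- D
    for (i in seq_len(n)) for (j in seq_len(n))
      Dnew[i, j] <- min(D[i, j], min(D[i, ] + W[, j]))
    if (identical(Dnew, D)) break
    D <- Dnew
  }
  D
}

# complete-linkage merge heights by naive agglomeration
complete_heights_oracle <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- list(h = Inf, a = NA, b = NA)
    for (a in seq_len(length(clusters) - 1)) for (b in seq(a + 1, length(clusters))) {
      h <- max(D[clusters[[a]], clusters[[b]]])
      if (h < best$h) best <- list(h = h, a = a, b = b)
    }
    heights <- c(heights, best$h)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  heights
}

# ward.D2 merge heights by replaying the Lance-Williams recurrence on
# squared distances and reporting square roots
ward2_heights_oracle <- function(D) {
  S <- D^2
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- list(s = Inf, i = NA, j = NA)
    k <- length(active)
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      if (S[active[a], active[b]] < best$s)
        best <- list(s = S[active[a], active[b]], i = active[a], j = active[b])
    }
    i <- best$i; j <- best$j
    heights <- c(heights, sqrt(best$s))
    for (c_ in setdiff(active, c(i, j))) {
      S[i, c_] <- S[c_, i] <-
        ((sizes[i] + sizes[c_]) * S[i, c_] + (sizes[j] + sizes[c_]) * S[j, c_] -
           sizes[c_] * S[i, j]) / (sizes[i] + sizes[j] + sizes[c_])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# mean silhouette width computed from first principles
sil_mean_oracle <- function(D, cl) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# dominant singular value by power iteration on X'X
sigma1_oracle <- function(X, iters = 1000) {
  v <- rep(1, ncol(X)) + stats::runif(ncol(X), 0, 0.1)
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- crossprod(X, X %*% v)
    v <- w / sqrt(sum(w^2))
  }
  sqrt(sum((X %*% v)^2))
}
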