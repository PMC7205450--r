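# Independent brute-force implementation of the density-peak rule.
densitypeak_oracle <- function(emb, n_centers, dc_quantile = 0.02) {
  n <- nrow(emb)
  d <- as.matrix(dist(emb))
  d_c <- quantile(d[upper.tri(d)], dc_quantile)
  rho <- numeric(n)
  for (i in 1:n) for (j in 1:n)
    if (j != i) rho[i] <- rho[i] + exp(-(d[i, j] / d_c)^2)
  ord <- order(-rho)
  delta <- numeric(n)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (r == 1) delta[i] <- max(d[i, ]) else
      delta[i] <- min(d[i, ord[1:(r - 1)]])
  }
  centers <- order(-(rho * delta))[seq_len(n_centers)]
  lab <- rep(NA_integer_, n)
  lab[centers] <- seq_along(centers) - 1L
  for (r in seq_len(n)) {
    i <- ord[r]
    if (!is.na(lab[i])) next
    higher <- ord[1:(r - 1)]
    lab[i] <- lab[higher[which.min(d[i, higher])]]
  }
  lab
}


# Exhaustive MST oracle via Prufer sequences (all labeled trees).
mst_oracle_weight <- function(cent) {
  k <- nrow(cent)
  d <- as.matrix(dist(cent))
  if (k == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(1:k), k - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pruefer <- seqs[r, ]
    degree <- rep(1, k)
    for (v in pruefer) degree[v] <- degree[v] + 1
    w <- 0
    deg <- degree
    avail <- 1:k
    pr <- pruefer
    for (v in pr) {
      leaf <- min(avail[deg[avail] == 1])
      w <- w + d[leaf, v]
      deg[leaf] <- 0
      deg[v] <- deg[v] - 1
      avail <- avail[avail != leaf]
    }
    last <- avail[deg[avail] > 0]
    w <- w + d[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

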