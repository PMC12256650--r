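# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, hand
# arithmetic.

# Minimal number of loss events for one ancestrally-present binary character
# under single-gain irreversibility, by exhaustive enumeration of internal
# node states (unknown tip states are free and enumerated too). On fully
# observed characters this is the exact minimum the implementation must hit;
# with unknowns the implementation's conservative rule (unknowns neither
# rescue presence nor generate events) may legitimately exceed it.
oracle_min_losses <- function(tree, tip_states) {
  n_tip <- tree$n_tip
  n_all <- n_tip + tree$n_node
  edges <- tree$phy$edge
  tips <- tree$labels[seq_len(n_tip)]
  st0 <- rep(NA_integer_, n_all)
  st0[seq_len(n_tip)] <- tip_states[tips]
  internals <- (n_tip + 1L):n_all
  unknown <- which(is.na(st0[seq_len(n_tip)]))
  kI <- length(internals); kU <- length(unknown)
  best <- Inf
  for (mask in 0:(2^kI - 1L)) {
    sI <- bitwAnd(bitwShiftR(mask, seq_len(kI) - 1L), 1L)
    for (umask in 0:(max(2^kU - 1L, 0L))) {
      st <- st0
      st[internals] <- sI
      if (kU) st[unknown] <- bitwAnd(bitwShiftR(umask, seq_len(kU) - 1L), 1L)
      if (st[tree$root] != 1L) next
      ok <- TRUE; losses <- 0L
      for (i in seq_len(nrow(edges))) {
        p <- st[edges[i, 1L]]; ch <- st[edges[i, 2L]]
        if (p == 0L && ch == 1L) { ok <- FALSE; break }
        if (p == 1L && ch == 0L) losses <- losses + 1L
      }
      if (ok && losses < best) best <- losses
    }
  }
  best
}

# Closed-form simple-regression coefficients from the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# First-order partial correlation from the definitional formula on
# externally computed average ranks.
oracle_partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  rxy <- pearson(rx, ry); rxz <- pearson(rx, rz); ryz <- pearson(ry, rz)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Exact upper-tail hypergeometric probability by combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Step-up BH by direct sorting arithmetic (independent of bh_adjust's
# cummin formulation); stats::p.adjust is the second reference.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Random rooted binary tree with unique tip labels, as a phylo_tree.
random_tree <- function(n_tips) {
  phy <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  as_phylo_tree(phy)
}
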