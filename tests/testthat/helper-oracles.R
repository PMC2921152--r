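# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms from the package code paths.

# Benjamini-Hochberg step-up by the direct definition:
# q_(i) = min_{j >= i} p_(j) * m / j, clipped to 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- min(running, 1)
  }
  q
}

# HMM likelihood by explicit depth-first enumeration of all state paths.
# emis: 4 x (W+1) emission probabilities (col 1 = background state).
hmm_paths_loglik <- function(codes, emis, tau) {
  W <- ncol(emis) - 1L
  L <- length(codes)
  total <- 0
  rec <- function(pos, state, w) {
    w <- w * emis[codes[pos] + 1L, state + 1L]
    if (w == 0) return(invisible(NULL))
    if (pos == L) {
      total <<- total + w
      return(invisible(NULL))
    }
    if (state == 0L) {
      rec(pos + 1L, 0L, w * (1 - tau))
      rec(pos + 1L, 1L, w * tau)
    } else if (state < W) {
      rec(pos + 1L, state + 1L, w)
    } else {
      rec(pos + 1L, 0L, w)
    }
  }
  rec(1L, 0L, 1 - tau)
  rec(1L, 1L, tau)
  log(total)
}

# Enumerate all valid site-placement sets for sequences of length L and a
# motif of width W under the single-motif HMM topology: site starts are
# strictly increasing with gaps >= W + 1 (a background symbol must separate
# sites); a truncated site (start > L - W + 1) can only be last.
enumerate_site_sets <- function(L, W) {
  sets <- list(integer(0))
  grow <- function(prefix, min_start) {
    for (s in seq(min_start, L)) {
      newset <- c(prefix, s)
      sets[[length(sets) + 1L]] <<- newset
      if (s + W + 1L <= L) grow(newset, s + W + 1L)
    }
  }
  grow(integer(0), 1L)
  sets
}

# state vector (0 = B, 1..W = match) for a site-placement set
site_set_states <- function(S, L, W) {
  st <- integer(L)
  for (s in S) {
    span <- s:min(s + W - 1L, L)
    st[span] <- seq_along(span)
  }
  st
}

# transition weight for a placement set: product over transitions
# (including the virtual initial background state before position 1)
site_set_transweight <- function(S, L, W, tau) {
  st <- c(0L, site_set_states(S, L, W))  # prepend virtual B
  w <- 1
  for (i in seq_len(L)) {
    from <- st[i]
    to <- st[i + 1L]
    if (from == 0L) {
      w <- w * if (to == 1L) tau else (1 - tau)
    }
    # match-state transitions (Mi -> Mi+1, MW -> B) have probability 1
  }
  w
}

# Vectorised placement-enumeration likelihood for a matrix of sequences
# (rows = sequences, columns = positions, values = base codes 0..3).
# Returns log-likelihood per sequence.
hmm_placement_loglik_matrix <- function(code_mat, emis, tau) {
  L <- ncol(code_mat)
  W <- ncol(emis) - 1L
  sets <- enumerate_site_sets(L, W)
  log_emis <- log(emis)
  acc <- matrix(-Inf, nrow = nrow(code_mat), ncol = length(sets))
  for (k in seq_along(sets)) {
    S <- sets[[k]]
    st <- site_set_states(S, L, W)
    lw <- log(site_set_transweight(S, L, W, tau))
    ll <- rep(lw, nrow(code_mat))
    for (j in seq_len(L)) {
      ll <- ll + log_emis[code_mat[, j] + 1L, st[j] + 1L]
    }
    acc[, k] <- ll
  }
  mx <- apply(acc, 1L, max)
  out <- mx + log(rowSums(exp(acc - mx)))
  out[is.nan(out)] <- -Inf
  out
}

# Exact null score distribution by enumeration of all 4^W windows, using
# the same integer score discretisation as the scanner.
enum_null_distribution <- function(si, bg) {
  W <- ncol(si)
  grid <- as.matrix(expand.grid(rep(list(0:3), W)))
  score <- numeric(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (j in seq_len(W)) {
    score <- score + si[grid[, j] + 1L, j]
    prob <- prob * bg[grid[, j] + 1L]
  }
  floor_sent <- ldbscreen:::NEG_SENTINEL
  score[score < floor_sent / 2] <- floor_sent
  agg <- rowsum(prob, score)
  data.frame(score = as.numeric(rownames(agg)), prob = as.numeric(agg))
}

# Upper-tail hypergeometric probability by enumeration of all C(N, n)
# target subsets of a population with K marked items.
hypergeom_subset_oracle <- function(k, n, K, N) {
  marked <- seq_len(K)
  subsets <- combn(N, n)
  mean(colSums(matrix(subsets %in% marked, nrow = n)) >= k)
}

# Two-sided permutation p-value for the rank-sum comparison of two ordinal
# count vectors.
perm_ranksum_p <- function(test_counts, control_counts, B = 10000,
                           seed = 1) {
  x <- rep(seq_along(test_counts), test_counts)
  y <- rep(seq_along(control_counts), control_counts)
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(n)]) - n * (length(pooled) + 1) / 2)
  withr::with_seed(seed, {
    stats <- replicate(B, {
      idx <- sample.int(length(pooled), n)
      abs(sum(r[idx]) - n * (length(pooled) + 1) / 2)
    })
  })
  mean(stats >= obs - 1e-9)
}

# small default severity scheme used across tests
CONTROL_PROBS6 <- c(50, 30, 10, 5, 3, 2) / 100
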