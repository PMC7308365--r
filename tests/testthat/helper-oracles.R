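# Independent oracles used across the test files. None of these call the
# package's simulation or cluster code paths.

# Exact master equation of the model on a 3x3 torus. State = base-3 integer
# with digit 0 = destroyed, 1 = vacant, 2 = NC (occupied). Rates are written
# straight from the reaction scheme; finite-time distributions come from
# uniformization with sparse matrix-vector products.
master_equation_3x3 <- function(delta, e, cons, alpha, t, p0_index) {
  n_states <- 3^9
  pow3 <- 3^(0:8)
  D <- sapply(0:8, function(i) (0:(n_states - 1)) %/% pow3[i + 1] %% 3)
  nb <- sapply(0:8, function(i) { # 4 torus neighbors, sites 0..8 column-major
    r <- i %% 3
    cc <- i %/% 3
    c(
      ((r + 1) %% 3) + 3 * cc, ((r + 2) %% 3) + 3 * cc,
      r + 3 * ((cc + 1) %% 3), r + 3 * ((cc + 2) %% 3)
    ) + 1
  })
  beta <- (1 - cons)^alpha
  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(from, to, rate) {
    k <- rate > 0
    ii <<- c(ii, from[k])
    jj <<- c(jj, to[k])
    xx <<- c(xx, rate[k])
  }
  s_all <- seq_len(n_states)
  for (i in 1:9) {
    di <- D[, i]
    n_nc <- rowSums(D[, nb[, i], drop = FALSE] == 2)
    sel <- di == 2
    add(s_all[sel], s_all[sel] - pow3[i], rep(delta, sum(sel))) # NC -> vacant
    add(s_all[sel], s_all[sel] - 2 * pow3[i], rep(e, sum(sel))) # NC -> destroyed
    sel <- di == 1
    add(s_all[sel], s_all[sel] - pow3[i], rep(e, sum(sel))) # vacant -> destroyed
    add(s_all[sel], s_all[sel] + pow3[i], beta * n_nc[sel] / 4) # colonization
    sel <- di == 0
    add(s_all[sel], s_all[sel] + pow3[i], cons * n_nc[sel] / 4) # construction
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_states, n_states))
  out_rate <- Matrix::rowSums(Q)
  lam <- max(out_rate) * 1.05 + 1e-9
  P <- Q / lam
  Matrix::diag(P) <- Matrix::diag(P) + 1 - out_rate / lam
  p <- numeric(n_states)
  p[p0_index] <- 1
  nmax <- max(20, ceiling(lam * t + 8 * sqrt(lam * t) + 20))
  w <- dpois(0:nmax, lam * t)
  res <- w[1] * p
  for (k in seq_len(nmax)) {
    p <- as.numeric(p %*% P)
    res <- res + w[k + 1] * p
  }
  list(p = res, n_occ = rowSums(D == 2))
}

# All-NC initial state index (1-based) for the 3x3 master equation.
me_all_nc_index <- function() 3^9

# Brute-force flood fill (4-connectivity) in plain R; wrap optional.
flood_fill_clusters <- function(grid, codes, wrap = TRUE) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  target <- matrix(grid %in% codes, nr, nc)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  sizes <- integer(0)
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!target[r0, c0] || labels[r0, c0] != 0L) next
      lab <- lab + 1L
      queue <- list(c(r0, c0))
      labels[r0, c0] <- lab
      size <- 0L
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        size <- size + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- cur[1] + d[1]
          cc <- cur[2] + d[2]
          if (wrap) {
            rr <- ((rr - 1) %% nr) + 1
            cc <- ((cc - 1) %% nc) + 1
          } else if (rr < 1 || rr > nr || cc < 1 || cc > nc) {
            next
          }
          if (target[rr, cc] && labels[rr, cc] == 0L) {
            labels[rr, cc] <- lab
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
      sizes <- c(sizes, size)
    }
  }
  list(sizes = sizes, labels = labels)
}

# Uniform random landscape over all four states.
.as_random_grid <- function(L) {
  m <- matrix(sample(c(-1L, 0L, 1L, 2L), L * L, replace = TRUE), L, L)
  class(m) <- c("landscape", "matrix", "array")
  m
}

# Shared values computed once per test session (the acceptance file reuses the
# contact-process critical point across blocks).
.acceptance_cache <- new.env(parent = emptyenv())
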