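# Independent brute-force oracles used to validate the scanners and the
# phylogenetic machinery. These deliberately use different algorithms from
# the implementation (per-substring tests, per-position extension, dense
# linear algebra, numerical quadrature).

ORACLE_BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) {
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}

seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], ORACLE_BASES)
}

zstep_ok <- function(a, b, allow_at = FALSE) {
  if (is.na(a) || is.na(b)) return(FALSE)
  pur <- c(TRUE, FALSE, TRUE, FALSE)
  if (pur[[a]] == pur[[b]]) return(FALSE)
  if (!allow_at && ((a == 1L && b == 4L) || (a == 4L && b == 1L)))
    return(FALSE)
  TRUE
}

oracle_is_primitive <- function(unit) {
  u <- length(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && identical(unit, rep_len(unit[seq_len(d)], u)))
      return(FALSE)
  }
  TRUE
}

# Every-substring brute force (small sequences only).
oracle_zdna_small <- function(seq, params) {
  code <- seq_codes(seq)
  n <- length(code)
  valid <- function(i, j) {
    if (j <= i) return(FALSE)
    for (t in i:(j - 1L))
      if (!zstep_ok(code[[t]], code[[t + 1L]],
                    params$zdna_allow_at_steps)) return(FALSE)
    TRUE
  }
  out <- list()
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (j - i + 1L < params$zdna_min_len) next
    if (!valid(i, j)) next
    if (i > 1L && valid(i - 1L, j)) next
    if (j < n && valid(i, j + 1L)) next
    out[[length(out) + 1L]] <- c(i, j)
  }
  do.call(rbind, out)
}

# Per-position extension brute force (long sequences).
oracle_zdna_extend <- function(seq, params) {
  code <- seq_codes(seq)
  n <- length(code)
  out <- list()
  if (n >= 2L) {
    step <- vapply(seq_len(n - 1L), function(t)
      zstep_ok(code[[t]], code[[t + 1L]], params$zdna_allow_at_steps),
      logical(1))
    i <- 1L
    while (i < n) {
      if (step[[i]]) {
        j <- i
        while (j < n - 1L && step[[j + 1L]]) j <- j + 1L
        if (j + 2L - i >= params$zdna_min_len)
          out[[length(out) + 1L]] <- c(i, j + 1L)
        i <- j + 2L
      } else i <- i + 1L
    }
  }
  do.call(rbind, out)
}

oracle_str_extend <- function(seq, params) {
  code <- seq_codes(seq)
  n <- length(code)
  out <- list()
  for (u in params$str_unit_min:params$str_unit_max) {
    if (n < u + 1L) next
    i <- 1L
    while (i <= n - u) {
      ok <- !is.na(code[[i]]) && !is.na(code[[i + u]]) &&
        code[[i]] == code[[i + u]]
      if (ok) {
        j <- i
        while (j < n - u && !is.na(code[[j + 1L]]) &&
               !is.na(code[[j + 1L + u]]) &&
               code[[j + 1L]] == code[[j + 1L + u]]) j <- j + 1L
        len <- j + u - i + 1L
        if (len >= params$str_min_len &&
            len %/% u >= params$str_min_copies &&
            oracle_is_primitive(code[i:(i + u - 1L)]))
          out[[length(out) + 1L]] <- c(i, j + u, u)
        i <- j + 2L
      } else i <- i + 1L
    }
  }
  m <- do.call(rbind, out)
  if (!is.null(m)) m <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
  m
}

# ---- exhaustive (vectorized) oracles over every sequence of length k ----

all_seq_matrix <- function(k) {
  m <- as.matrix(expand.grid(rep(list(1:4), k)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

codes_to_string <- function(v) paste(ORACLE_BASES[v], collapse = "")

# Run a scanner over every row of M at once by concatenating rows with an
# N separator (N terminates every tract), then map hits back per row.
scan_batch <- function(M, scanner, params) {
  k <- ncol(M)
  s <- paste(c(ORACLE_BASES, "N")[as.vector(t(cbind(M, 5L)))],
             collapse = "")
  hits <- scanner(s, "concat", params)
  if (nrow(hits) == 0L)
    return(data.frame(idx = integer(0), start = integer(0),
                      stop = integer(0), u = integer(0)))
  idx <- (hits$start - 1L) %/% (k + 1L) + 1L
  off <- (idx - 1L) * (k + 1L)
  data.frame(idx = idx, start = hits$start - off, stop = hits$stop - off,
             u = ifelse(hits$motif_class == "STR", nchar(hits$unit), 0L))
}

# Exhaustive Z-DNA oracle: tests every substring of every row of M.
oracle_zdna_batch <- function(M, params) {
  k <- ncol(M); nr <- nrow(M)
  empty <- data.frame(idx = integer(0), start = integer(0),
                      stop = integer(0), u = integer(0))
  if (k < 2L) return(empty)
  inv <- matrix(0L, nr, k - 1L)
  for (i in seq_len(k - 1L)) {
    pa <- M[, i] == 1L | M[, i] == 3L
    pb <- M[, i + 1L] == 1L | M[, i + 1L] == 3L
    ok <- xor(pa, pb)
    if (!params$zdna_allow_at_steps)
      ok <- ok & !((M[, i] == 1L & M[, i + 1L] == 4L) |
                   (M[, i] == 4L & M[, i + 1L] == 1L))
    inv[, i] <- 1L - as.integer(ok)
  }
  cum <- inv
  if (k - 1L >= 2L) for (t in 2:(k - 1L)) cum[, t] <- cum[, t - 1L] + inv[, t]
  n_inv <- function(i, j) {            # invalid steps among i..j-1
    lo <- if (i >= 2L) cum[, i - 1L] else 0L
    cum[, j - 1L] - lo
  }
  out <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (j - i + 1L < params$zdna_min_len) next
    sel <- n_inv(i, j) == 0L
    if (i > 1L) sel <- sel & inv[, i - 1L] == 1L
    if (j < k) sel <- sel & inv[, j] == 1L
    w <- which(sel)
    if (length(w) > 0L)
      out[[length(out) + 1L]] <- data.frame(idx = w, start = i, stop = j,
                                            u = 0L)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# Exhaustive STR oracle.
oracle_str_batch <- function(M, params) {
  k <- ncol(M); nr <- nrow(M)
  empty <- data.frame(idx = integer(0), start = integer(0),
                      stop = integer(0), u = integer(0))
  u_max <- min(params$str_unit_max, k - 1L)
  if (u_max < params$str_unit_min) return(empty)
  out <- list()
  for (u in params$str_unit_min:u_max) {
    L <- k - u
    mm <- matrix(0L, nr, L)
    for (i in seq_len(L)) mm[, i] <- as.integer(M[, i] == M[, i + u])
    cum <- mm
    if (L >= 2L) for (t in 2:L) cum[, t] <- cum[, t - 1L] + mm[, t]
    for (i in seq_len(L)) for (j in i:L) {
      len <- j + u - i + 1L
      if (len < params$str_min_len ||
          len %/% u < params$str_min_copies) next
      lo <- if (i >= 2L) cum[, i - 1L] else 0L
      sel <- (cum[, j] - lo) == (j - i + 1L)
      if (i > 1L) sel <- sel & mm[, i - 1L] == 0L
      if (j < L) sel <- sel & mm[, j + 1L] == 0L
      for (d in seq_len(u - 1L)) {     # unit primitivity
        if (u %% d != 0L) next
        per_d <- rep(TRUE, nr)
        for (t in i:(i + u - 1L - d)) per_d <- per_d & (M[, t] == M[, t + d])
        sel <- sel & !per_d
      }
      w <- which(sel)
      if (length(w) > 0L)
        out[[length(out) + 1L]] <- data.frame(idx = w, start = i,
                                              stop = j + u, u = u)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

hit_set_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$idx, df$start, df$stop, df$u))
}

# ---- phylogenetics oracles ----

# Dense-GLS conditional-mean oracle for BM ancestral states, built from
# the joint tips+nodes covariance via ape's mrca/depth utilities.
anc_oracle_dense <- function(tree, x) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  dep <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  S <- matrix(dep[mr], nn, nn)
  tips <- seq_len(n); nodes <- (n + 1L):nn
  x <- x[tree$tip.label]
  Sxx <- S[tips, tips]
  Sinv <- solve(Sxx)
  ones <- rep(1, n)
  mu <- drop(crossprod(ones, Sinv %*% x)) /
    drop(crossprod(ones, Sinv %*% ones))
  est <- mu + drop(S[nodes, tips, drop = FALSE] %*% (Sinv %*% (x - mu)))
  names(est) <- as.character(nodes)
  est
}

mvn_loglik_oracle <- function(x, mu, Sigma) {
  n <- length(x)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld +
            drop(crossprod(x - mu, solve(Sigma, x - mu))))
}

# Upper tail of the studentized range distribution (df = Inf) by
# quadrature: P(Q_{k,Inf} >= q) = 1 - k Int phi(z) [Phi(z)-Phi(z-q)]^(k-1).
sr_tail_oracle <- function(q, k) {
  f <- function(z) stats::dnorm(z) *
    (stats::pnorm(z) - stats::pnorm(z - q))^(k - 1)
  1 - k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
}

# A random tree with branch lengths (mix of shapes for oracle sweeps).
rand_test_tree <- function(n, ultrametric = FALSE) {
  if (ultrametric) ape::rcoal(n) else ape::rtree(n)
}
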