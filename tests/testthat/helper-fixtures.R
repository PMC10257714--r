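## Shared fixtures: small networks and profiles built in code.

mk_net <- function(w, kind = "pcn", normalize = TRUE) {
  if (is.null(rownames(w))) rownames(w) <- sprintf("G%02d", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- sprintf("K%05d", seq_len(ncol(w)))
  TaxonFunctionNetwork(w, kind, normalize = normalize)
}

mk_profile <- function(p, taxa = NULL) {
  if (is.null(names(p)))
    names(p) <- if (is.null(taxa)) sprintf("G%02d", seq_along(p)) else taxa
  AbundanceProfile(p)
}

## staircase presence matrix: row i has 1s in columns 1..(n - i + 1)
staircase <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) w[i, seq_len(n - i + 1L)] <- 1
  w
}

random_network <- function(S, F_, seed, kind = "pcn", density = 0.6) {
  set.seed(seed)
  w <- matrix(stats::runif(S * F_) * (stats::runif(S * F_) < density), S, F_)
  empty <- rowSums(w) == 0
  w[empty, 1L] <- 1  # no all-zero taxon rows
  mk_net(w, kind)
}

## independent brute-force oracles (plain double loops, no shared code path)
oracle_jaccard <- function(w) {
  S <- nrow(w)
  d <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) next
    num <- 0; den <- 0
    for (a in seq_len(ncol(w))) {
      num <- num + min(w[i, a], w[j, a])
      den <- den + max(w[i, a], w[j, a])
    }
    d[i, j] <- 1 - num / den
  }
  d
}

oracle_metrics <- function(w, p) {
  d <- oracle_jaccard(w)
  S <- length(p)
  td <- 1 - sum(p * p)
  fd <- 0; fr <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i == j) next
    fd <- fd + d[i, j] * p[i] * p[j]
    fr <- fr + (1 - d[i, j]) * p[i] * p[j]
  }
  list(td = td, fd = fd, fr = fr, nfr = if (td > 0) fr / td else 0)
}

oracle_nodf <- function(b) {
  pair_sum <- function(m) {
    fills <- rowSums(m)
    tot <- 0; n <- 0L
    for (u in seq_len(nrow(m) - 1L)) for (v in seq.int(u + 1L, nrow(m))) {
      n <- n + 1L
      fu <- fills[u]; fv <- fills[v]
      if (fu == fv || min(fu, fv) == 0) next
      lo <- if (fu > fv) v else u
      hi <- if (fu > fv) u else v
      tot <- tot + sum(m[lo, ] & m[hi, ]) / unname(fills[lo])
    }
    c(tot, n)
  }
  r <- pair_sum(b); cl <- pair_sum(t(b))
  unname((r[1] + cl[1]) / (r[2] + cl[2]))
}
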