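# Independent oracles used by the property tests. These deliberately use
# naive exhaustive formulations, not the package's algorithms.

ref_fixture <- function() dd_example_reference()

random_junctions <- function(n, max_len = 30) {
  lens <- sample(0:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Brute-force junction decomposition: maximize the D1 prefix length p, then
# the D2 suffix length s over every feasible (p, s) pair and allele.
oracle_decompose <- function(junction, d1_coding, d2_codings) {
  L <- nchar(junction)
  best_p <- 0L
  for (p in seq_len(min(L, nchar(d1_coding)))) {
    if (substr(junction, 1, p) == substr(d1_coding, 1, p)) best_p <- p
  }
  best <- list(s = 0L, allele = names(d2_codings)[1])
  for (al in names(d2_codings)) {
    cod <- d2_codings[[al]]
    for (s in seq_len(min(L - best_p, nchar(cod)))) {
      if (substr(junction, L - s + 1, L) ==
        substr(cod, nchar(cod) - s + 1, nchar(cod)) && s > best$s) {
        best <- list(s = s, allele = al)
      }
    }
  }
  list(
    d1_match = best_p,
    insert_seq = substr(junction, best_p + 1, L - best$s),
    d2_match = best$s,
    d2_allele = best$allele
  )
}

# Mann-Whitney by direct pair counting and full enumeration of group labels.
oracle_mwu <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
  list(u = u_obs, p = p)
}

# Bayes posterior P(short | length) under the true generative law of the
# standard simulation (equal pathway priors), computed by direct convolution
# rather than any fitting.
bayes_short_posterior <- function(len) {
  kmax <- max(len, 200)
  ks <- 0:kmax
  # short: zero-inflated shifted geometric
  q <- 1 / 9.677
  d_short <- ifelse(ks == 0, 0.38, 0.62 * q * (1 - q)^(pmax(ks, 1) - 1))
  # long: (12 - min(G1, 12)) + Poisson(6) + (16 - min(G2, 16)), G geometric(1/6)
  p_keep <- function(len_gene) {
    g <- stats::dgeom(0:(len_gene - 1), 1 / 6)
    kept <- c(1 - sum(g), rev(g)) # retained length 0..len_gene
    kept
  }
  conv <- function(a, b) {
    out <- rep(0, length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      idx <- (i - 1) + seq_along(b)
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  d1k <- p_keep(12)
  d2k <- p_keep(16)
  pois <- stats::dpois(ks, 6)
  d_long <- conv(conv(d1k, d2k), pois)[seq_along(ks)]
  num <- 0.5 * d_short[len + 1]
  den <- num + 0.5 * d_long[len + 1]
  num / den
}

# Probability that a fully random window of length w contains at least one of
# m distinct k-mers, treating windows as independent. This is the quick
# approximation (it ignores motif overlap) and is used only as an upper
# bound; see exact_motif_hit_prob for the exact value.
analytic_motif_fp <- function(w, m, k) {
  n_windows <- max(w - k + 1, 0)
  p <- m / 4^k
  1 - (1 - p)^n_windows
}

# Exact probability that a uniform random string of length w contains at
# least one motif, via a prefix-automaton dynamic programme (handles the
# strong overlap between the motifs, which are shifted windows of the same
# coding region).
exact_motif_hit_prob <- function(motifs, w) {
  motifs <- toupper(motifs)
  if (w < min(nchar(motifs))) {
    return(0)
  }
  prefixes <- unique(c("", unlist(lapply(
    motifs,
    function(m) substring(m, 1, seq_len(nchar(m) - 1))
  ))))
  bases <- c("A", "C", "G", "T")
  n <- length(prefixes)
  trans <- matrix(0L, n, 4)
  hit <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) {
    for (b in 1:4) {
      t <- paste0(prefixes[i], bases[b])
      if (any(vapply(motifs, function(m) endsWith(t, m), logical(1)))) {
        hit[i, b] <- TRUE
        next
      }
      sfx <- substring(t, seq_len(nchar(t) + 1)) # suffixes, longest first
      sfx <- sfx[sfx %in% prefixes]
      trans[i, b] <- match(sfx[1], prefixes)
    }
  }
  p <- numeric(n)
  p[match("", prefixes)] <- 1
  p_hit <- 0
  for (step in seq_len(w)) {
    pn <- numeric(n)
    for (b in 1:4) {
      contrib <- p * 0.25
      p_hit <- p_hit + sum(contrib[hit[, b]])
      for (i in which(!hit[, b])) {
        pn[trans[i, b]] <- pn[trans[i, b]] + contrib[i]
      }
    }
    p <- pn
  }
  p_hit
}
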