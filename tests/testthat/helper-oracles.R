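# Independent reference implementations, written straight from the defining
# equations with naive loops. They deliberately share no code with the
# package internals they check.

# z-scored property matrix -> mean squared property difference of two residues
oracle_theta <- function(a, b, H) {
  aa <- aa_alphabet()
  s <- 0
  for (j in seq_len(nrow(H))) {
    s <- s + (H[j, match(a, aa)] - H[j, match(b, aa)])^2
  }
  s / nrow(H)
}

# full PseAAC vector from the equations: composition f_u, correlation
# factors theta_k, then x_u = f_u / D resp. omega * theta_k / D
oracle_pseaac <- function(residues, lambda, omega, H) {
  aa <- aa_alphabet()
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  f <- numeric(20)
  for (ch in chars) f[match(ch, aa)] <- f[match(ch, aa)] + 1
  f <- f / L
  theta <- numeric(lambda)
  if (lambda > 0) {
    for (k in seq_len(lambda)) {
      acc <- 0
      for (i in seq_len(L - k)) {
        acc <- acc + oracle_theta(chars[i], chars[i + k], H)
      }
      theta[k] <- acc / (L - k)
    }
  }
  D <- sum(f) + omega * sum(theta)
  c(f / D, omega * theta / D)
}

# AUC as the explicit pairwise Mann-Whitney probability, ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

random_protein <- function(L) {
  paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
}
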