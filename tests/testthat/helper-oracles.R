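# Independent oracles, kept free of the code paths they check:
#  - least squares via explicit normal equations,
#  - Cook's distance via its direct leverage/residual formula,
#  - exact Wilcoxon p by full enumeration of group assignments.

normal_eq_coef <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

cooks_direct <- function(X, y) {
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  h <- diag(H)
  e <- y - H %*% y
  p <- ncol(X)
  s2 <- sum(e^2) / (nrow(X) - p)
  as.numeric(e^2 / (p * s2) * h / (1 - h)^2)
}

wilcox_exact_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)])
  combs <- utils::combn(n, length(a))
  all_w <- apply(combs, 2, function(i) sum(rank(seq_len(n))[i]))
  mu <- length(a) * (n + 1) / 2
  p <- mean(abs(all_w - mu) >= abs(w_obs - mu))
  min(1, p)
}

mk_pca_data <- function(n = 40, seed = 5, sites = "A") {
  set.seed(seed)
  data.frame(tree_id = sprintf("T%02d", 1:n),
             site = rep(sites, length.out = n),
             position = rep(c("edge", "interior"), length.out = n),
             rp_cm = runif(n, 12, 30),
             pca_pct = rnorm(n, 0, 15), stringsAsFactors = FALSE)
}
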