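# Independent brute-force oracles used to cross-check the fast paths.

# AUC: all presence/absence pairs, ties half credit
auc_oracle <- function(scores, labels) {
  p <- scores[labels == 1]; a <- scores[labels == 0]
  tot <- 0
  for (x in p) for (y in a)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(p) * length(a))
}

# TSS: explicit scan of every unique-score threshold (predict 1 iff >= t)
tss_oracle <- function(scores, labels) {
  best <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    if (sens + spec - 1 > best) {
      best <- sens + spec - 1
      best_t <- t
    }
  }
  list(tss = best, threshold = best_t)
}

# ordinary kriging by directly assembling and solving the (n+1) system
ok_oracle <- function(x, y, z, x0, y0, model, nugget, psill, range) {
  n <- length(z)
  gam <- function(h) ifelse(h > 0, nugget + switch(model,
    exponential = psill * (1 - exp(-h / range)),
    gaussian    = psill * (1 - exp(-(h / range)^2)),
    spherical   = ifelse(h < range,
                         psill * (1.5 * h / range - 0.5 * (h / range)^3),
                         psill)), 0)
  A <- matrix(0, n + 1, n + 1)
  for (i in 1:n) for (j in 1:n)
    A[i, j] <- gam(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  A[n + 1, 1:n] <- 1; A[1:n, n + 1] <- 1
  b <- c(gam(sqrt((x - x0)^2 + (y - y0)^2)), 1)
  w <- solve(A, b)[1:n]
  sum(w * z)
}

# VIF by regressing each variable on all the others
vif_oracle <- function(X) {
  vapply(seq_along(X), function(i) {
    r2 <- summary(stats::lm(X[[i]] ~ ., data = X[-i]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}
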