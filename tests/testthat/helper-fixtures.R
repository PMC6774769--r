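# Shared fixtures, all generated in code.

# well-separated two-component ground truth in an abstract chrominance plane
twoClusterTruth <- function() {
  gmmParams(c(0.5, 0.5), rbind(c(0, 0), c(5, 5)), diag(2), space = "lab")
}

# best assignment of fitted components to truth components (small J only)
matchComponents <- function(fit, truth) {
  J <- length(truth@priors)
  perms <- if (J == 2) list(1:2, 2:1) else
    asplit(as.matrix(expand.grid(rep(list(seq_len(J)), J))), 1)
  best <- NULL; bestCost <- Inf
  for (p in perms) {
    p <- as.integer(p)
    if (anyDuplicated(p)) next
    cost <- sum((fit@means[p, , drop = FALSE] - truth@means)^2)
    if (cost < bestCost) { bestCost <- cost; best <- p }
  }
  best
}

# hand-assembled GNG state for single-step tests
newGNGForTest <- function(positions, cfg, edges = matrix(integer(0), 0, 2),
                          ages = integer(0), errors = NULL) {
  new("GNG", positions = positions,
      errors = if (is.null(errors)) rep(0, nrow(positions)) else errors,
      colours = matrix(numeric(0), 0, 3),
      edges = matrix(as.integer(edges), ncol = 2), ages = as.integer(ages),
      nSignals = 0, config = unclass(cfg))
}

# uniform unit-square sample cloud
unitSquareCloud <- function(n = 4000, seed = 1) {
  set.seed(seed)
  cbind(runif(n), runif(n))
}

# filled disc mask
discMask <- function(h, w, cy, cx, r) {
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

# random blobby mask for metric property tests
randomMask <- function(h, w) {
  matrix(runif(h * w) < runif(1, 0.2, 0.8), h, w)
}
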