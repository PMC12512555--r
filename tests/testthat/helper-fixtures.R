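# Shared in-code fixtures for the suite.

# small log2-space matrix with named genes/samples
make_log2_matrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, space = "log2")
}

# random log2 cohort for property tests: iid normal noise around a baseline
random_log2_cohort <- function(n_genes, n1, n2, seed, mean = 5, sd = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_genes * (n1 + n2), mean, sd), n_genes)
  m <- make_log2_matrix(x)
  list(m = m, groups = rep(c("tumor", "normal"), c(n1, n2)))
}

# minimal splice-event table built from explicit per-group count vectors
make_event_table <- function(inc1, skip1, inc2, skip2, n_events = 1,
                             event_class = "SE", inc_len = 1, skip_len = 1,
                             tpm = NULL) {
  R <- length(inc1)
  samples <- c(sprintf("A%d", seq_len(R)), sprintf("B%d", seq_len(R)))
  inc <- matrix(as.integer(rep(c(inc1, inc2), each = n_events)),
                n_events, 2 * R, byrow = FALSE)
  skip <- matrix(as.integer(rep(c(skip1, skip2), each = n_events)),
                 n_events, 2 * R, byrow = FALSE)
  dimnames(inc) <- dimnames(skip) <- list(sprintf("ev%d", seq_len(n_events)),
                                          samples)
  events <- data.frame(event_id = rownames(inc),
                       gene_id = sprintf("gene%d", seq_len(n_events)),
                       event_class = rep_len(event_class, n_events),
                       inclusion_len = as.integer(inc_len),
                       skipping_len = as.integer(skip_len))
  splice_event_table(events, inc, skip, tpm)
}

event_groups_for <- function(tab) {
  samples <- colnames(tab$inc)
  stats::setNames(ifelse(grepl("^A", samples), "g1", "g2"), samples)
}

# brute-force BH step-up, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# brute-force two-sided exact Wilcoxon rank-sum p by full enumeration
wilcox_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  combs <- utils::combn(length(pooled), length(a))
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# grid-search binomial-pooling LRT oracle (rho = 0): maximize the binomial
# log-likelihood over a fine mean grid for null and per-group alternatives
binom_lrt_grid_oracle <- function(k, n, g, grid = seq(1e-4, 1 - 1e-4,
                                                      length.out = 20001)) {
  ll <- function(kk, nn, mu) sum(lchoose(nn, kk) + kk * log(mu) +
                                   (nn - kk) * log(1 - mu))
  best <- function(kk, nn) max(vapply(grid, function(mu) ll(kk, nn, mu),
                                      numeric(1)))
  2 * (best(k[g == 1], n[g == 1]) + best(k[g == 2], n[g == 2]) -
         best(k, n))
}
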