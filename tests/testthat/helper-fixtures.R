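# Fixtures built in code at test time.

# Tab-separated PhosphoSitePlus-style kinase-substrate table.
write_psp_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                              banner = TRUE) {
  header <- paste("KINASE", "SUBSTRATE", "SUB_ORG", "SUB_MOD_RSD", sep = "\t")
  lines <- c(if (banner) c("Kinase-substrate dataset", ""), header,
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Two tight, well-separated profile groups (for clustering geometry tests).
two_blob_matrix <- function(n_per = 20, sep = 10, sd = 0.05, seed = 42) {
  set.seed(seed)
  base1 <- c(0, 1, 2, 3)
  base2 <- base1 + sep * c(1, -1, 1, -1)
  m <- rbind(
    matrix(rep(base1, each = n_per), ncol = 4) + rnorm(n_per * 4, sd = sd),
    matrix(rep(base2, each = n_per), ncol = 4) + rnorm(n_per * 4, sd = sd))
  rownames(m) <- sprintf("site%02d", seq_len(nrow(m)))
  m
}

# A 30-site, 3-cluster toy with 3 matched kinase sets.
toy_cluster_model <- function(assignment) {
  k <- max(assignment)
  n <- length(assignment)
  names(assignment) <- sprintf("s%02d", seq_len(n))
  membership <- matrix(0, n, k)
  membership[cbind(seq_len(n), assignment)] <- 1
  structure(list(k = k, centers = matrix(0, k, 2),
                 membership = membership, cluster = assignment,
                 size = tabulate(assignment, k), objective = 0,
                 method = "kmeans", fuzzifier = NA_real_,
                 iter = 1L, seed = 1L),
            class = "clue_clustering")
}

# Independent oracle for the one-sided Fisher p-value: direct summation of
# the hypergeometric probability formula via log-gamma binomials, never
# touching phyper.
fisher_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b
  n <- a + c
  avals <- a:min(K, n)
  avals <- avals[avals >= max(0, K + n - N)]
  if (length(avals) == 0) return(1)
  logp <- lchoose(K, avals) + lchoose(N - K, n - avals) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

# Closed-form chi-squared upper tail for even degrees of freedom 2k:
# P(chi2_{2k} > x) = exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i / i!
chisq_tail_even_df <- function(x, k) {
  h <- x / 2
  terms <- c(1, if (k > 1) cumprod(h / seq_len(k - 1)))
  exp(-h) * sum(terms)
}
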