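# shared fixtures and small oracles, all built in code at test time

base_of <- function(col) sub("__.*$", "", col)

# a minimal schema with one feature of each data type
tiny_schema <- function() {
  data.frame(
    name = c("flag", "terms", "level"),
    data_type = c("binary", "categorical", "continuous"),
    category = c("evolutionary property", "functional annotation", "expression")
  )
}

tiny_genes <- function() {
  data.frame(
    gene = paste0("g", 1:10),
    flag = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1),
    terms = c("a;b", "b;c", "a;b;c", "", "c", "a", "a;c", "b", "c;d", "d"),
    level = c(10, 9, 3, 3, 0, 5, 7, 2, 8, 1)
  )
}

tiny_pairs <- function() {
  data.frame(pair_id = paste0("p", 1:5),
             gene_a = paste0("g", c(1, 3, 5, 7, 9)),
             gene_b = paste0("g", c(2, 4, 6, 8, 10)))
}

# trio table covering a handful of known label cells
make_trios <- function(sm_a, sm_b, dm, n = length(dm)) {
  data.frame(
    pair_id = sprintf("t%03d", seq_len(n)),
    gene_a = sprintf("ga%03d", seq_len(n)),
    gene_b = sprintf("gb%03d", seq_len(n)),
    sm_a_class = rep_len(sm_a, n), sm_b_class = rep_len(sm_b, n),
    dm_class = rep_len(dm, n)
  )
}

# all 125 phenotype-class combinations as a trio table
all_class_trios <- function() {
  cls <- phenotype_classes()
  g <- expand.grid(sm_a = cls, sm_b = cls, dm = cls, stringsAsFactors = FALSE)
  make_trios(g$sm_a, g$sm_b, g$dm, n = nrow(g))
}

# linearly separable two-class feature matrix
separable_data <- function(n_per_class = 40, p = 5, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- paste0("i", seq_len(2 * n_per_class))
  list(x = x, y = rep(c(FALSE, TRUE), each = n_per_class))
}

# independent two-sided Fisher p oracle: full hypergeometric enumeration,
# summing P(k) <= P(observed) with the canonical 1e-7 relative tolerance
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b      # margin of row 1
  n2 <- c + d
  k <- a + c      # margin of column 1
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force BH step-up oracle: q_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# exact rank-sum p oracle by enumeration of all C(n1+n2, n1) assignments
wilcoxon_exact_oracle <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(all_v), nx)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- nx * (length(all_v) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
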