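# Independent enumeration oracles used to validate the simulation and the
# paternity-index arithmetic. These work by brute-force summation over all
# founder genotypes and transmission choices at a single small locus and
# never call the package's own kernels.

# joint genotype distribution of two pedigree members at one locus:
# enumerate ordered founder genotypes (Hardy-Weinberg) and per-child
# transmission choices. `children` must be listed in dependency order.
enumerate_pair_dist <- function(p, founders, children, pair) {
  K <- length(p)
  cols <- list()
  for (f in founders) {
    cols[[paste0(f, "_1")]] <- seq_len(K)
    cols[[paste0(f, "_2")]] <- seq_len(K)
  }
  for (ch in names(children)) {
    cols[[paste0(ch, "_t1")]] <- 1:2
    cols[[paste0(ch, "_t2")]] <- 1:2
  }
  g <- do.call(expand.grid, cols)
  n <- nrow(g)
  prob <- rep(0.25^length(children), n)
  geno <- list()
  for (f in founders) {
    geno[[f]] <- cbind(g[[paste0(f, "_1")]], g[[paste0(f, "_2")]])
    prob <- prob * p[geno[[f]][, 1]] * p[geno[[f]][, 2]]
  }
  for (ch in names(children)) {
    pr <- children[[ch]]
    g1 <- geno[[pr[1]]]
    g2 <- geno[[pr[2]]]
    geno[[ch]] <- cbind(g1[cbind(seq_len(n), g[[paste0(ch, "_t1")]])],
                        g2[cbind(seq_len(n), g[[paste0(ch, "_t2")]])])
  }
  list(a = geno[[pair[1]]], b = geno[[pair[2]]], prob = prob)
}

# P(two members share >= 1 allele) = per-locus duo non-exclusion probability
oracle_share_prob <- function(p, founders, children, pair) {
  d <- enumerate_pair_dist(p, founders, children, pair)
  share <- d$a[, 1] == d$b[, 1] | d$a[, 1] == d$b[, 2] |
           d$a[, 2] == d$b[, 1] | d$a[, 2] == d$b[, 2]
  sum(d$prob[share])
}

# minimal pedigrees realizing each alleged-father pair (duo evaluation)
ORACLE_PEDIGREES <- list(
  sibling      = list(founders = c("E", "F"), children = list(B = c("E", "F"), C = c("E", "F")),
                      pair = c("C", "B")),
  grandparent  = list(founders = c("I", "J", "F"), children = list(E = c("I", "J"), B = c("E", "F")),
                      pair = c("I", "B")),
  uncle        = list(founders = c("I", "J", "F"),
                      children = list(E = c("I", "J"), K = c("I", "J"), B = c("E", "F")),
                      pair = c("K", "B")),
  half_sibling = list(founders = c("E", "S", "J2"),
                      children = list(W = c("E", "S"), M = c("E", "J2")),
                      pair = c("W", "M")),
  cousin       = list(founders = c("I", "J", "N", "F"),
                      children = list(D = c("I", "J"), E = c("I", "J"),
                                      R = c("N", "D"), B = c("E", "F")),
                      pair = c("R", "B")),
  random_man   = list(founders = c("E", "F", "X"), children = list(B = c("E", "F")),
                      pair = c("X", "B"))
)

# duo paternity index by direct enumeration of untyped-mother genotypes
oracle_duo_pi <- function(f, ch, p) {
  K <- length(p)
  num <- 0
  for (m1 in seq_len(K)) for (m2 in seq_len(K)) {
    pm <- p[m1] * p[m2]
    for (fi in 1:2) for (mi in 1:2) {
      if (all(sort(c(f[fi], c(m1, m2)[mi])) == sort(ch))) num <- num + pm * 0.25
    }
  }
  den <- if (ch[1] == ch[2]) p[ch[1]]^2 else 2 * p[ch[1]] * p[ch[2]]
  num / den
}

# trio paternity-index numerator and denominator by direct enumeration
oracle_trio_num_den <- function(f, m, ch, p) {
  num <- 0
  for (fi in 1:2) for (mi in 1:2) {
    if (all(sort(c(f[fi], m[mi])) == sort(ch))) num <- num + 0.25
  }
  den <- 0
  for (mi in 1:2) for (a in seq_along(p)) {
    if (all(sort(c(m[mi], a)) == sort(ch))) den <- den + 0.5 * p[a]
  }
  c(num = num, den = den)
}

# all ordered genotypes at a K-allele locus
ordered_genotypes <- function(K) {
  as.matrix(expand.grid(a = seq_len(K), b = seq_len(K)))
}

# a one-locus freq_set wrapper for small oracle loci
one_locus_set <- function(p) {
  freq_set(list(list(locus = "L1", alleles = paste0("a", seq_along(p)), freqs = p)))
}
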