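# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# One-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(m+n, m) assignments of the case labels to the pooled values.
# p = fraction of assignments whose case rank-sum is >= (alternative
# "greater") the observed one; with the opposite inequality for "less".
enum_mwu_p <- function(x, y, alternative = c("greater", "less",
                                             "two.sided")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  switch(alternative,
         greater = mean(sums >= obs),
         less = mean(sums <= obs),
         two.sided = min(1, 2 * min(mean(sums >= obs), mean(sums <= obs))))
}

# Two-sided Fisher probability-mass rule by direct hypergeometric
# enumeration over every table with the observed margins.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Spearman p-value by enumeration over all n! permutations (no ties).
enum_spearman_p <- function(x, y) {
  n <- length(x)
  rho_of <- function(a, b) cor(rank(a), rank(b))
  obs <- abs(rho_of(x, y))
  perms <- combinat_permutations(n)
  rhos <- apply(perms, 1, function(p) rho_of(x, y[p]))
  mean(abs(rhos) >= obs - 1e-12)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# small well-formed fixtures -------------------------------------------

make_profile <- function(n_kos = 6, n_samples = 8, seed = 42,
                         strata = FALSE, n_genera = 3) {
  set.seed(seed)
  kos <- sprintf("K%05d", seq_len(n_kos))
  samples <- sprintf("S%02d", seq_len(n_samples))
  if (!strata) {
    comm <- matrix(round(rexp(n_kos * n_samples, 1 / 50), 4),
                   n_kos, dimnames = list(kos, samples))
    return(ko_profile(comm))
  }
  genera <- paste0("Genus", LETTERS[seq_len(n_genera)])
  st <- matrix(round(rexp(n_kos * n_genera * n_samples, 1 / 20), 4),
               n_kos * n_genera,
               dimnames = list(paste0(rep(kos, each = n_genera), "|g__",
                                      genera), samples))
  comm <- rowsum(st, rep(kos, each = n_genera))[kos, , drop = FALSE]
  # leave an unclassified remainder on the first KO
  comm[1, ] <- comm[1, ] * 1.25
  ko_profile(comm, st)
}

make_design <- function(n_case = 4, n_control = 4) {
  cohort_design(sprintf("S%02d", seq_len(n_case + n_control)),
                rep(c("case", "control"), c(n_case, n_control)))
}

make_panel <- function(n_samples = 8, seed = 7, compartment = "plasma") {
  set.seed(seed)
  aa <- c("Ala", "Arg", "His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr",
          "Trp", "Tyr", "Val")
  m <- matrix(round(rexp(n_samples * length(aa), 1 / 100), 3), n_samples,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)), aa))
  metabolite_panel(m, compartment)
}
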