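# Shared oracles and fixture builders, independent of the code paths they check.

# Best-match intersection-over-union of each truth object against a predicted
# label image.
per_object_iou <- function(truth_labels, pred_labels) {
  K <- max(truth_labels)
  vapply(seq_len(K), function(k) {
    tk <- truth_labels == k
    cand <- unique(pred_labels[tk])
    cand <- cand[cand > 0L]
    if (!length(cand)) return(0)
    max(vapply(cand, function(j) {
      pj <- pred_labels == j
      sum(tk & pj) / sum(tk | pj)
    }, numeric(1L)))
  }, numeric(1L))
}

# Brute-force per-pixel compartment sums for one nucleus (explicit loop).
loop_sums <- function(img, nuc_labels, no_labels, no_parent, k) {
  i_nuc <- 0; i_no <- 0
  for (r in seq_len(nrow(img))) for (c2 in seq_len(ncol(img))) {
    if (nuc_labels[r, c2] == k) {
      i_nuc <- i_nuc + img[r, c2]
      l <- no_labels[r, c2]
      if (l > 0 && no_parent[l] == k) i_no <- i_no + img[r, c2]
    }
  }
  c(nucleus = i_nuc, nucleolar = i_no, nucleoplasm = i_nuc - i_no)
}

# Exact hypergeometric upper tail by explicit summation of the count
# distribution with choose() -- independent of phyper.
hyper_upper_oracle <- function(k_obs, K, N, n) {
  ks <- k_obs:min(K, n)
  ks <- ks[(n - ks) <= (N - K)]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Full subset-enumeration upper tail (only for tiny libraries).
hyper_enum_oracle <- function(k_obs, K, N, n) {
  if (n == 0L) return(if (k_obs <= 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  in_class <- subsets <= K   # first K library members are the class
  mean(colSums(in_class) >= k_obs)
}

# A tiny field with hand-placed masks: square nucleus with a square nucleolus.
toy_cell <- function(side = 12L, nucleolus = 3:4, value_fun = NULL) {
  dimm <- c(side + 4L, side + 4L)
  nuc <- matrix(0L, dimm[1L], dimm[2L])
  nuc[3:(side + 2L), 3:(side + 2L)] <- 1L
  no <- matrix(0L, dimm[1L], dimm[2L])
  no[nucleolus + 2L, nucleolus + 2L] <- 1L
  list(nuclei = label_mask(nuc), nucleoli = label_mask(no, parent = 1L),
       dim = dimm)
}

# Planted phosphosite table with known pass/fail reasons.
make_phospho_table <- function(n = 50L, seed = 11L) {
  set.seed(seed)
  d <- data.frame(
    protein_id = sprintf("P%03d", seq_len(n)),
    site = sprintf("S%d", sample(10:999, n)),
    untreated_1 = sample(0:10, n, replace = TRUE),
    untreated_2 = sample(0:10, n, replace = TRUE),
    treated_flavo = sample(0:8, n, replace = TRUE),
    treated_azd = sample(0:8, n, replace = TRUE),
    logfc_flavo = round(stats::rnorm(n, 0, 1.2), 3),
    logfc_azd = round(stats::rnorm(n, 0, 1.2), 3),
    fdr_flavo = signif(stats::runif(n)^3, 3),
    fdr_azd = signif(stats::runif(n)^3, 3),
    is_nucleolar = sample(c(TRUE, FALSE), n, replace = TRUE))
  # plant unambiguous cases
  d$untreated_1[1] <- 1; d$untreated_2[1] <- 7          # count rule fails
  d$untreated_1[2] <- 2; d$untreated_2[2] <- 2          # count rule passes
  d$fdr_flavo[3] <- 1e-6; d$logfc_flavo[3] <- -2        # abundance drop
  d$fdr_azd[4] <- 1e-6; d$logfc_azd[4] <- 2             # significant increase: keep
  d
}
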