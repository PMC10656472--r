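# Shared fixtures and brute-force oracles. Everything is generated in code;
# the small atlas is built once per test run.

fixture_env <- new.env(parent = emptyenv())

small_atlas <- function(shape = c(32L, 32L, 32L), seed = 11L) {
  key <- paste(c(shape, seed), collapse = "_")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_atlas(shape, seed = seed)
  }
  fixture_env[[key]]
}

# uniformly random (non-anatomical) label volume; exercises code paths only
random_label_volume <- function(shape = c(12L, 12L, 12L), scheme = scheme_seven(),
                                p_lesion = 0.2) {
  codes <- c(0L, scheme$codes)
  prob <- c(1 - p_lesion, rep(p_lesion / length(scheme$codes), length(scheme$codes)))
  g <- array(sample(codes, prod(shape), replace = TRUE, prob = prob), shape)
  label_volume(g, scheme = scheme)
}

# brute-force per-voxel Dice oracle on two binary masks
oracle_dice <- function(a, b) {
  ia <- which(a != 0)
  ib <- which(b != 0)
  if (length(ia) + length(ib) == 0L) return(NA_real_)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# exhaustive sign-flip null for the Wilcoxon signed-rank statistic
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- signs %*% r
  min(1, 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs)))
}

# exhaustive rank-assignment null for the Mann-Whitney U statistic (no ties)
oracle_mann_whitney_p <- function(a, b) {
  m <- length(a)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(a, b)
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), m)
  u_null <- apply(combos, 2L, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

# brute-force pairwise AUC oracle
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
}
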