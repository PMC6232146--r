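test_that("RDMs are symmetric, zero-diagonal, rank-scaled to [0,1]", {
  set.seed(1)
  pats <- matrix(rnorm(33 * 60), 33, 60)
  r <- compute_rdm(pats)
  expect_equal(unclass(r), t(unclass(r)))
  expect_equal(diag(r), rep(0, 33), ignore_attr = TRUE)
  off <- r[lower.tri(r)]
  expect_length(off, 528)
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
  # two identical patterns land at scaled distance 0
  pats2 <- pats
  pats2[5, ] <- pats2[9, ]
  r2 <- compute_rdm(pats2)
  expect_equal(unname(unclass(r2)[9, 5]), 0)
})

test_that("RDMs are invariant to per-condition positive affine rescaling", {
  set.seed(2)
  pats <- matrix(rnorm(12 * 40), 12, 40)
  gains <- runif(12, 0.2, 5)
  offs <- rnorm(12, 0, 3)
  r1 <- compute_rdm(pats)
  r2 <- compute_rdm(pats * gains + offs)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-12)
})

test_that("degenerate patterns are rejected with the condition named", {
  pats <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), NULL))
  pats["g3", ] <- 2
  expect_error(compute_rdm(pats), "g3")
  expect_error(compute_rdm(pats[1:2, ]), "at least 3")
})

test_that("RDM machinery matches the brute-force oracle to 1e-12", {
  set.seed(3)
  for (rep in 1:10) {
    a <- matrix(rnorm(6 * 25), 6, 25)
    b <- matrix(rnorm(6 * 25), 6, 25)
    ra <- compute_rdm(a); rb <- compute_rdm(b)
    expect_equal(unclass(ra), oracle_rdm(a), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(compare_rdms(ra, rb),
                 oracle_rdm_distance(unclass(ra), unclass(rb)),
                 tolerance = 1e-12)
    # ranking first changes nothing: Spearman sees only the order
    expect_equal(compare_rdms(ra, rb),
                 oracle_rdm_distance(attr(ra, "raw"), attr(rb, "raw")),
                 tolerance = 1e-12)
  }
})

test_that("categorical models are binary with the scheme's block structure", {
  tax <- default_taxonomy()
  one <- tax; one$grasp_type <- "power"
  expect_equal(unclass(categorical_rdm(one, "grasp_type")),
               matrix(0, 33, 33), ignore_attr = TRUE)
  solo <- tax; solo$object_shape <- as.character(1:33)
  expect_error(validate_taxonomy(solo), "at most")
  rs <- categorical_rdm(tax, "object_shape")
  expect_setequal(unique(as.vector(rs)), c(0, 1))
  # within-category zeros partition the conditions into 7 blocks
  g <- apply(unclass(rs) == 0, 1, which)
  blocks <- unique(lapply(g, sort))
  expect_length(blocks, 7)
  small <- tax[1:6, ]; small$thumb_position[3] <- NA
  expect_error(categorical_rdm(small, "thumb_position"), "missing")
  expect_error(categorical_rdm(tax, "grip_force"), "not present")
})

test_that("RDM distances span [0,2] with the expected anchors", {
  set.seed(4)
  r <- compute_rdm(matrix(rnorm(10 * 30), 10, 30))
  expect_equal(compare_rdms(r, r), 0)
  rev <- unclass(r)
  rev[lower.tri(rev)] <- 1 - rev[lower.tri(rev)]
  rev <- rev * 0
  rev[lower.tri(rev)] <- 1 - unclass(r)[lower.tri(r)]
  rev <- rev + t(rev)
  rownames(rev) <- colnames(rev) <- rownames(r)
  expect_equal(compare_rdms(r, rev), 2)
  # independent random RDMs sit at distance ~1
  set.seed(5)
  d <- replicate(60, {
    compare_rdms(compute_rdm(matrix(rnorm(10 * 30), 10, 30)),
                 compute_rdm(matrix(rnorm(10 * 30), 10, 30)))
  })
  expect_lt(abs(mean(d) - 1), 3 * sd(d) / sqrt(length(d)))
  r2 <- compute_rdm(matrix(rnorm(8 * 30), 8, 30))
  expect_error(compare_rdms(r, r2), "sizes")
  r3 <- compute_rdm(matrix(rnorm(10 * 30), 10, 30,
                           dimnames = list(letters[1:10], NULL)))
  expect_error(compare_rdms(r3, r), "ordering mismatch")
})

test_that("condition relabeling permutes RDMs and preserves distances", {
  set.seed(6)
  pats <- matrix(rnorm(9 * 40), 9, 40, dimnames = list(1:9, NULL))
  other <- matrix(rnorm(9 * 40), 9, 40, dimnames = list(1:9, NULL))
  perm <- sample(9)
  r <- compute_rdm(pats)
  rp <- compute_rdm(pats[perm, ])
  expect_equal(unclass(rp), unclass(r)[perm, perm], ignore_attr = TRUE)
  o <- compute_rdm(other)
  op <- compute_rdm(other[perm, ])
  expect_equal(compare_rdms(r, o), compare_rdms(rp, op), tolerance = 1e-12)
})

test_that("searchlight maps locate the argmin and demand completeness", {
  set.seed(7)
  refs <- list()
  base <- matrix(rnorm(6 * 30), 6, 30)
  cand <- compute_rdm(base)
  for (ci in 1:4) for (fi in 1:3) {
    noise <- if (ci == 2 && fi == 3) 0.1 else 5
    refs[[grasprsa:::cell_name(ci, fi)]] <-
      compute_rdm(base + noise * matrix(rnorm(180), 6, 30))
  }
  m <- searchlight_rsa(refs, cand, n_channel_nb = 4, n_freq_nb = 3)
  expect_equal(unname(m$argmin), c(2, 3))
  expect_true(all(m$distances >= 0 & m$distances <= 2))
  # candidate identical to every reference -> all-zero map
  refs0 <- refs
  for (k in names(refs0)) refs0[[k]] <- cand
  m0 <- searchlight_rsa(refs0, cand, 4, 3)
  expect_equal(max(abs(m0$distances)), 0)
  expect_error(searchlight_rsa(refs[-3], cand, 4, 3), "missing cell")
})

test_that("bootstrap percentile CIs behave at the edges", {
  set.seed(8)
  pat <- matrix(rnorm(6 * 20), 6, 20)
  cand <- compute_rdm(matrix(rnorm(6 * 20), 6, 20))
  same <- list(lapply(1:5, function(s) pat))
  b <- bootstrap_effect(same, cand, n_iter = 50, seed = 1)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$ci_low, b$observed)
  varied <- list(lapply(1:5, function(s) pat + 0.3 * matrix(rnorm(120), 6, 20)))
  b1 <- bootstrap_effect(varied, cand, n_iter = 1, seed = 2)
  expect_equal(b1$ci_low, b1$ci_high)
  expect_equal(b1$ci_low, b1$replicates[1])
  expect_error(bootstrap_effect(varied, cand, n_iter = 0), "n_iter")
  expect_error(bootstrap_effect(list(list(pat)), cand, n_iter = 5),
               "2 subjects")
  b2a <- bootstrap_effect(varied, cand, n_iter = 30, seed = 9)
  b2b <- bootstrap_effect(varied, cand, n_iter = 30, seed = 9)
  expect_identical(b2a$replicates, b2b$replicates)
})

test_that("the second-level RDM relates representations by rank correlation", {
  set.seed(9)
  r1 <- compute_rdm(matrix(rnorm(8 * 30), 8, 30))
  r2 <- compute_rdm(matrix(rnorm(8 * 30), 8, 30))
  s <- second_level_rdm(list(a = r1, b = r2, dup = r1))
  expect_equal(s, t(s))
  expect_equal(diag(s), rep(0, 3), ignore_attr = TRUE)
  expect_equal(s["a", "dup"], 0)
  expect_equal(s["a", "b"], compare_rdms(r1, r2))
  expect_error(second_level_rdm(list(r1)), "at least 2")
  r3 <- compute_rdm(matrix(rnorm(5 * 30), 5, 30))
  expect_error(second_level_rdm(list(r1, r3)), "heterogeneous")
})

test_that("a rank-shifted counterpart lands at its constructed distance", {
  # 33 conditions -> 528 ranks; cyclically shifting the rank sequence by s
  # gives Spearman rho = 1 - 6*s*(n-s)/(n^2-1) exactly, so shifting by 33
  # constructs a pair correlating at rho ~ 0.648 on ranks, distance ~ 0.35
  n <- 528
  v1 <- seq_len(n) / n
  s <- 33
  v2 <- v1[((seq_len(n) - 1 + s) %% n) + 1]
  m1 <- matrix(0, 33, 33); m1[lower.tri(m1)] <- v1; m1 <- m1 + t(m1)
  m2 <- matrix(0, 33, 33); m2[lower.tri(m2)] <- v2; m2 <- m2 + t(m2)
  rho <- 1 - 6 * s * (n - s) / (n^2 - 1)
  got <- compare_rdms(m1, m2)
  expect_equal(got, 1 - rho, tolerance = 1e-12)
  expect_lt(abs(got - 0.36), 0.02)
})
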