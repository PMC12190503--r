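# Gaussian MMI-PhiID core: lattice structure, mutual information,
# decomposition, and the pairwise synergy estimator.

test_that("the atom lattice has the documented structure", {
  lat <- phiid_lattice()
  expect_equal(nrow(lat), 16L)
  expect_equal(sum(lat$eval == "mi"), 9L)
  expect_equal(sum(lat$eval == "red_forward"), 3L)
  expect_equal(sum(lat$eval == "red_backward"), 3L)
  expect_equal(sum(lat$eval == "double_red"), 1L)
})

test_that("lagged covariance estimation z-scores and aligns the series", {
  set.seed(41)
  m <- estimate_lagged_covariance(rnorm(20000), rnorm(20000), tau = 1)
  expect_equal(diag(m$cov), rep(1, 4), tolerance = 0.03)
  off <- m$cov[upper.tri(m$cov)]
  expect_lt(max(abs(off)), 0.05)
  expect_equal(m$n_obs, 19999L)
})

test_that("degenerate and malformed series are handled per contract", {
  set.seed(42)
  x <- rnorm(100)
  # an exact copy still yields a model (ridge prevents singularity) with
  # cross-correlation entries ~ 1
  m <- estimate_lagged_covariance(x, x, tau = 1)
  expect_equal(m$cov[1, 2], 1, tolerance = 0.05)
  expect_equal(m$cov[3, 4], 1, tolerance = 0.05)
  expect_error(estimate_lagged_covariance(x, rnorm(99)), "same length")
  expect_error(estimate_lagged_covariance(rnorm(10), rnorm(10), tau = 1),
               "too short")
  expect_error(estimate_lagged_covariance(rep(1, 100), x), "constant")
  expect_error(estimate_lagged_covariance(c(x[-1], NA), x), "non-finite")
})

test_that("gaussian_mi matches the bivariate closed form", {
  S <- diag(4)
  expect_equal(gaussian_mi(lagged_gaussian_model(S), 1, 3), 0)
  S[1, 3] <- S[3, 1] <- 0.5
  got <- gaussian_mi(lagged_gaussian_model(S), 1, 3)
  expect_equal(got, -0.5 * log2(1 - 0.25), tolerance = 1e-12)
  expect_equal(round(got, 4), 0.2075)
})

test_that("gaussian_mi agrees with an independent determinant routine", {
  set.seed(7)
  for (rep in 1:20) {
    S <- rand_pd4()
    m <- lagged_gaussian_model(S)
    expect_equal(gaussian_mi(m, c(1, 2), c(3, 4)),
                 oracle_mi(S, c(1, 2), c(3, 4)), tolerance = 1e-9)
    expect_equal(gaussian_mi(m, 1, c(3, 4)), oracle_mi(S, 1, c(3, 4)),
                 tolerance = 1e-9)
    # symmetry in the two arguments
    expect_equal(gaussian_mi(m, c(3, 4), c(1, 2)),
                 gaussian_mi(m, c(1, 2), c(3, 4)), tolerance = 1e-12)
  }
})

test_that("gaussian_mi rejects invalid variable sets", {
  m <- lagged_gaussian_model(diag(4))
  expect_error(gaussian_mi(m, c(1, 2), c(2, 3)), "disjoint")
  expect_error(gaussian_mi(m, integer(0), 3), "non-empty")
  expect_error(gaussian_mi(m, 1, 5), "1:4")
})

test_that("mmi_redundancy is the minimum", {
  expect_equal(mmi_redundancy(c(0.3, 0.1, 0.7, 0.2)), 0.1)
  expect_equal(mmi_redundancy(c(0.4, 0.4)), 0.4)
  expect_equal(mmi_redundancy(c(0, 0, 0, 0)), 0)
  expect_error(mmi_redundancy(numeric(0)), "non-empty")
})

test_that("independent white channels carry no information atoms", {
  d <- phiid_decompose(lagged_gaussian_model(diag(4)))
  expect_equal(d$atoms$i_partial, rep(0, 16), tolerance = 1e-12)
  expect_equal(d$tdmi, 0, tolerance = 1e-12)
})

test_that("two independent AR(1) channels decompose as the lattice oracle says", {
  # Analytic stationary covariance of two uncoupled AR(1) channels with
  # coefficient 0.8: unit variances, lag-1 autocorrelation 0.8, no cross
  # terms. Expected atoms frozen from the independent zeta-solve oracle:
  # the unique->unique atoms carry each channel's own-lag information
  # m = -log2(1 - 0.64)/2 = 0.73697 bits; because MMI counts equal-strength
  # sources as redundant, red->syn and syn->red also equal m, the mixed
  # unique->syn / syn->unique atoms equal -m, and syn->syn = TDMI = 2m.
  S <- diag(4)
  S[1, 3] <- S[3, 1] <- 0.8
  S[2, 4] <- S[4, 2] <- 0.8
  m <- -0.5 * log2(1 - 0.8^2)
  want <- c(0, 0, 0, m,          # red -> red, un1, un2, syn
            0, m, 0, -m,         # un1 -> ...
            0, 0, m, -m,         # un2 -> ...
            m, -m, -m, 2 * m)    # syn -> ...
  orc <- oracle_phiid(S)
  expect_equal(orc$ipart, want, tolerance = 1e-12)
  d <- phiid_decompose(lagged_gaussian_model(S))
  expect_equal(d$atoms$i_partial, want, tolerance = 1e-9)
  expect_equal(round(phiid_atom(d, "un1", "un1"), 3), 0.737)
  expect_equal(round(phiid_atom(d, "un2", "un2"), 3), 0.737)
})

test_that("the production solver equals the brute-force lattice oracle", {
  set.seed(11)
  for (rep in 1:40) {
    S <- rand_pd4()
    d <- phiid_decompose(lagged_gaussian_model(S))
    orc <- oracle_phiid(S)
    expect_equal(d$atoms$i_cap, orc$icap, tolerance = 1e-9)
    expect_equal(d$atoms$i_partial, orc$ipart, tolerance = 1e-9)
  }
})

test_that("decomposition invariants hold on random covariances", {
  set.seed(12)
  leq <- matrix(FALSE, 4, 4,
                dimnames = list(c("red", "un1", "un2", "syn"),
                                c("red", "un1", "un2", "syn")))
  leq["red", ] <- TRUE; leq["un1", c("un1", "syn")] <- TRUE
  leq["un2", c("un2", "syn")] <- TRUE; leq["syn", "syn"] <- TRUE
  for (rep in 1:25) {
    S <- rand_pd4()
    d <- phiid_decompose(lagged_gaussian_model(S))
    a <- d$atoms
    # conservation: atoms sum to the time-delayed mutual information
    tdmi <- oracle_mi(S, c(1, 2), c(3, 4))
    expect_equal(sum(a$i_partial), tdmi, tolerance = 1e-9)
    expect_equal(d$tdmi, tdmi, tolerance = 1e-9)
    # cumulative consistency: every i_cap is the sum of its down-set atoms
    for (k in seq_len(16)) {
      ds <- leq[a$source, a$source[k]] & leq[a$target, a$target[k]]
      expect_equal(sum(a$i_partial[ds]), a$i_cap[k], tolerance = 1e-9)
    }
    # forward marginalization: row sums reproduce the forward MMI-PID
    red_f <- min(oracle_mi(S, 1, c(3, 4)), oracle_mi(S, 2, c(3, 4)))
    fwd <- c(red = red_f,
             un1 = oracle_mi(S, 1, c(3, 4)) - red_f,
             un2 = oracle_mi(S, 2, c(3, 4)) - red_f,
             syn = tdmi - oracle_mi(S, 1, c(3, 4)) -
               oracle_mi(S, 2, c(3, 4)) + red_f)
    for (s in names(fwd)) {
      expect_equal(sum(a$i_partial[a$source == s]), unname(fwd[s]),
                   tolerance = 1e-9)
    }
    # double redundancy never exceeds any pairwise lagged MI
    rr <- a$i_cap[a$source == "red" & a$target == "red"]
    for (i in 1:2) for (j in 3:4) {
      expect_lte(rr, oracle_mi(S, i, j) + 1e-12)
    }
  }
})

test_that("swapping the two regions permutes un1 and un2 and fixes red/syn", {
  set.seed(13)
  swap1 <- c(red = "red", un1 = "un2", un2 = "un1", syn = "syn")
  for (rep in 1:10) {
    S <- rand_pd4()
    perm <- c(2, 1, 4, 3)
    d1 <- phiid_decompose(lagged_gaussian_model(S))
    d2 <- phiid_decompose(lagged_gaussian_model(S[perm, perm]))
    for (k in seq_len(16)) {
      s <- swap1[[d1$atoms$source[k]]]
      t <- swap1[[d1$atoms$target[k]]]
      expect_lt(abs(d1$atoms$i_partial[k] -
                      d2$atoms$i_partial[d2$atoms$source == s &
                                           d2$atoms$target == t]),
                1e-12)
    }
  }
})

test_that("synergy of independent noise is near zero and swap-symmetric", {
  set.seed(14)
  x <- rnorm(20000); y <- rnorm(20000)
  expect_lt(abs(synergy(x, y, tau = 1)), 0.02)
  set.seed(15)
  a <- rnorm(300); b <- as.vector(stats::filter(rnorm(300), 0.5, "recursive"))
  expect_lt(abs(synergy(a, b) - synergy(b, a)), 1e-12)
})

test_that("cross-coupled VAR pair matches the lattice oracle analytically", {
  model <- var_model(matrix(c(0.2, 0.5, 0.5, 0.2), 2, 2))
  m <- lagged_pair_model(model, 1, 2, tau = 1)
  d <- phiid_decompose(m)
  orc <- oracle_phiid(m$cov)
  expect_equal(d$atoms$i_partial, orc$ipart, tolerance = 1e-9)
  expect_gt(phiid_atom(d, "syn", "syn"), 0)
})
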