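# NRD / energy AUC, class histograms, stratified subsampling, MDPA, Bayes
# components and line ranking.

planck_energy <- function(nm) 6.62607015e-34 * 2.99792458e8 / (nm * 1e-9)

test_that("NRD is the relative drop of the salt mean and is scale invariant", {
  bands <- c(500, 600, 700)
  C <- matrix(c(0.5, 0.5, 0.2, 0.2, 0.4, 0.4), 3, 2, byrow = TRUE)
  S <- matrix(c(0.4, 0.4, 0.2, 0.2, 0.5, 0.5), 3, 2, byrow = TRUE)
  cv <- nrd_curve(C, S, bands)
  expect_equal(cv$nrd, c((0.5 - 0.4) / 0.5, 0, (0.4 - 0.5) / 0.4))
  expect_equal(nrd_curve(C, C, bands)$nrd, rep(0, 3))
  expect_equal(nrd_curve(3 * C, 3 * S, bands)$nrd, cv$nrd)
  # zero control mean flags the band as undefined
  C0 <- C; C0[2, ] <- 0
  expect_true(is.na(nrd_curve(C0, S, bands)$nrd[2]))
  expect_error(nrd_curve(C[, 0], S, bands), "nonempty")
})

test_that("energy-axis AUC matches direct Planck arithmetic", {
  # unit curve on two bands: area is the photon-energy gap
  cv <- structure(list(nrd = c(1, 1), band_centers = c(500, 600)),
                  class = "nrd_curve")
  expect_equal(auc_energy(cv), planck_energy(500) - planck_energy(600),
               tolerance = 1e-12)
  expect_equal(auc_energy(cv), 6.623e-20, tolerance = 1e-3)
  # zero curve, linearity, NA exclusion
  cv0 <- structure(list(nrd = c(0, 0, 0), band_centers = c(500, 600, 700)),
                   class = "nrd_curve")
  expect_equal(auc_energy(cv0), 0)
  cv2 <- structure(list(nrd = c(0.3, 0.7, 0.2), band_centers = c(500, 600, 700)),
                   class = "nrd_curve")
  expect_equal(auc_energy(structure(list(nrd = 2 * cv2$nrd,
                                         band_centers = cv2$band_centers),
                                    class = "nrd_curve")),
               2 * auc_energy(cv2), tolerance = 1e-12)
  cv_na <- structure(list(nrd = c(0.3, NA, 0.2), band_centers = c(500, 600, 700)),
                     class = "nrd_curve")
  expect_equal(auc_energy(cv_na),
               0.5 * (0.3 + 0.2) * (planck_energy(500) - planck_energy(700)),
               tolerance = 1e-12)
  expect_error(auc_energy(structure(list(nrd = 1, band_centers = 500),
                                    class = "nrd_curve")), "two defined bands")
})

test_that("histograms tile [0,1] with a closed last bin", {
  f <- field_of(c(0.005, 0.5, 1, 1, 0.9999), c("control", "control", "salt", "salt", "salt"))
  h <- class_histograms(f, b = 100)
  expect_equal(sum(h$control$counts), 2)
  expect_equal(sum(h$salt$counts), 3)
  expect_equal(h$control$counts[1], 1)        # 0.005 -> bin 1
  expect_equal(h$control$counts[51], 1)       # 0.5 -> bin [0.50, 0.51)
  expect_equal(h$salt$counts[100], 3)         # both 1.0 and 0.9999 -> last bin
  expect_equal(h$salt$mean, mean(c(1, 1, 0.9999)))
  expect_error(class_histograms(field_of(numeric(0), character(0))), "empty")
})

test_that("stratified subsampling preserves proportions exactly", {
  v <- c(rep(0.05, 100), rep(0.55, 300))
  h <- structure(list(counts = tabulate(pmin(floor(v * 10), 9) + 1, 10),
                      b = 10L, n = 400L, mean = mean(v), sd = sd(v), values = v),
                 class = "class_histogram")
  sub <- stratified_subsample(h, 200, seed = 5)
  expect_equal(sub$n, 200)
  expect_equal(sub$counts[c(1, 6)], c(50, 150))   # exact proportions
  # determinism under the seed
  sub2 <- stratified_subsample(h, 200, seed = 5)
  expect_identical(sub$values, sub2$values)
  # ratio 1 is the identity
  expect_equal(stratified_subsample(h, 400, seed = 1)$counts, h$counts)
  # largest-remainder top-up keeps the exact total for awkward ratios
  sub3 <- stratified_subsample(h, 133, seed = 2)
  expect_equal(sub3$n, 133)
  expect_equal(sum(sub3$counts), 133)
  expect_error(stratified_subsample(h, 0), "positive")
  expect_error(stratified_subsample(h, 500), "exceeds")
})

# independent 1-D minimal pair-assignment oracle: expand histograms to sorted
# sample positions and match in sorted order (optimal for an ordinal metric)
transport_oracle <- function(hc, hs) {
  a <- sort(rep(seq_along(hc), hc))
  b <- sort(rep(seq_along(hs), hs))
  sum(abs(a - b))
}

test_that("MDPA equals the minimal transport distance", {
  expect_equal(mdpa(c(2, 0, 1), c(1, 1, 1)) * 3, 1)
  expect_equal(mdpa(c(3, 0, 0), c(0, 0, 3)) * 3, 6)
  expect_equal(mdpa(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(77)
  for (k in 1:50) {
    b <- sample(2:8, 1); n <- sample(1:12, 1)
    hc <- tabulate(sample(b, n, replace = TRUE), b)
    hs <- tabulate(sample(b, n, replace = TRUE), b)
    expect_equal(mdpa(hc, hs) * n, transport_oracle(hc, hs))
  }
  expect_error(mdpa(c(1, 2), c(1, 1)), "equal totals")
  expect_error(mdpa(c(1, 2), c(1, 1, 1)), "bin counts")
})

test_that("sorted matching is itself the assignment optimum (tiny n)", {
  # exhaustive permutation search certifies the oracle on every pair of
  # 3-bin histograms with up to 4 samples
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  comps <- function(n, b) {
    if (b == 1) return(list(n))
    out <- list()
    for (k in 0:n) for (rest in comps(n - k, b - 1)) out <- c(out, list(c(k, rest)))
    out
  }
  for (n in 2:4) {
    hset <- comps(n, 3)
    for (hc in hset) for (hs in hset) {
      a <- rep(1:3, hc); b <- rep(1:3, hs)
      best <- min(vapply(perms(b), function(p) sum(abs(a - p)), numeric(1)))
      expect_equal(transport_oracle(hc, hs), best)
    }
  }
})

test_that("MDPA is a metric but is not shuffling invariant", {
  set.seed(31)
  for (k in 1:40) {
    b <- 10; n <- 30
    h1 <- tabulate(sample(b, n, replace = TRUE), b)
    h2 <- tabulate(sample(b, n, replace = TRUE), b)
    h3 <- tabulate(sample(b, n, replace = TRUE), b)
    expect_equal(mdpa(h1, h2), mdpa(h2, h1))
    expect_lte(mdpa(h1, h3), mdpa(h1, h2) + mdpa(h2, h3) + 1e-12)
    expect_equal(mdpa(h1, h1), 0)
  }
  # permuting bins changes the ordinal distance (unlike Euclidean)
  h1 <- c(3, 0, 0); h2 <- c(0, 0, 3)
  expect_false(isTRUE(all.equal(mdpa(h1, h2), mdpa(h1, rev(h2)))))
})

test_that("Bayes components combine by Bayes' rule", {
  f <- field_of(c(0.2, 0.6, 0.7, 0.4, 0.8, 0.9, 0.3, 0.55),
                rep(c("control", "salt"), each = 4))
  b <- bayes_table(f, split = 0.5)
  expect_equal(b$cc_salt, 0.75)
  expect_equal(b$cc_control, 0.5)
  expect_equal(b$evidence, 0.625)
  expect_equal(b$posterior, 0.75 / 1.25)
  # uninformative observation returns the prior
  b2 <- bayes_table(cc_salt = 0.4, cc_control = 0.4)
  expect_equal(b2$posterior, 0.5)
  # perfectly separating observation
  b3 <- bayes_table(cc_salt = 0.3, cc_control = 0)
  expect_equal(b3$posterior, 1)
  # no pixel above the split -> flagged undefined
  b4 <- bayes_table(cc_salt = 0, cc_control = 0)
  expect_true(b4$undefined && is.na(b4$posterior))
  expect_error(bayes_table(field_of(c(0.1, 0.2, 0.3), c("control", "salt", "salt"))),
               "balanced")
})

test_that("posterior from evidence equals posterior from both conditionals", {
  set.seed(55)
  for (k in 1:50) {
    cs <- runif(1); cc <- runif(1)
    ev <- 0.5 * cs + 0.5 * cc
    p1 <- bayes_table(cc_salt = cs, cc_control = cc)$posterior
    p2 <- bayes_table(cc_salt = cs, evidence = ev)$posterior
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("binned posterior is the per-bin salt fraction with complement", {
  f <- field_of(c(0.05, 0.08, 0.95, 0.92, 0.97, 0.5, 0.55),
                c("control", "control", "salt", "salt", "control", "control", "salt"))
  pc <- binned_posterior(f, nbins = 10)
  expect_equal(pc$posterior_salt[1], 0)              # only control in bin 1
  expect_equal(pc$posterior_salt[10], 2 / 3)         # 2 salt, 1 control
  expect_equal(pc$posterior_salt[6], 0.5)
  expect_true(all(is.na(pc$posterior_salt[pc$n == 0])))
  ok <- pc$n > 0
  expect_equal(pc$posterior_salt[ok] + pc$posterior_control[ok], rep(1, sum(ok)))
})

test_that("identically distributed classes give posterior near one half", {
  set.seed(99)
  s <- runif(2000)
  f <- field_of(s, rep(c("control", "salt"), 1000))
  pc <- binned_posterior(f, nbins = 10)
  expect_true(all(abs(pc$posterior_salt - 0.5) < 0.12))
})

test_that("line ranking is ascending, tie-flagged and monotone invariant", {
  st <- c(B = 0.6333, A = 0.5021, C = 0.5760)
  rk <- rank_lines(st)
  expect_equal(rk$line, c("A", "C", "B"))
  expect_equal(rk$rank, 1:3)
  expect_false(any(rk$tied))
  # monotone transform preserves the ordering
  rk2 <- rank_lines(exp(10 * st))
  expect_equal(rk2$line, rk$line)
  # ties flagged and broken by name
  rk3 <- rank_lines(c(B = 1, A = 1, C = 2))
  expect_equal(rk3$line, c("A", "B", "C"))
  expect_true(all(rk3$tied[1:2]))
  expect_error(rank_lines(c(A = 1)), "two lines")
})
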