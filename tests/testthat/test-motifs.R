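# Frequency-domain motif quadratures checked against independent
# time-domain oracles (helper-oracles.R), plus structural properties.

kp0 <- table1_kp()
sp0 <- table1_sp(1)
sp0$A_plus <- balanced_potentiation(sp0, 150)

test_that("pair coefficients match the time-domain oracle", {
  for (ab in list(c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(0, 2), c(0, 3))) {
    q <- motif_pair(ab[1], ab[2], kp0, sp0)
    o <- oracle_pair(ab[1], ab[2], kp0, sp0)
    expect_lt(abs(q - o) / abs(o), 1e-5,
              label = sprintf("pair(%d,%d) relative error", ab[1], ab[2]))
  }
  # feedforward pair coefficients vanish by support disjointness
  expect_identical(motif_pair(1, 0, kp0, sp0), 0)
  expect_identical(motif_pair(3, 0, kp0, sp0), 0)
})

test_that("triplet cross-covariance coefficients match the oracle", {
  for (ab in list(c(1, 0), c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(0, 3))) {
    q <- motif_triplet_ab(ab[1], ab[2], kp0, sp0)
    o <- oracle_trip_ab(ab[1], ab[2], kp0, sp0)
    expect_lt(abs(q - o) / abs(o), 1e-5,
              label = sprintf("trip(%d,%d) relative error", ab[1], ab[2]))
  }
  expect_gt(motif_triplet_ab(1, 0, kp0, sp0), 0) # drives feedforward growth
  expect_identical(motif_triplet_ab(1, 1, kp0, table1_sp(1, A_plus = 0)), 0)
})

test_that("gamma-path coefficients match the oracle and are eta-invariant", {
  for (ag in list(c(1, 1), c(2, 0), c(2, 1), c(3, 0), c(1, 2))) {
    q <- motif_triplet_ag(ag[1], ag[2], kp0, sp0)
    o <- oracle_trip_ag(ag[1], ag[2], kp0, sp0)
    expect_lt(abs(q - o) / abs(o), 1e-5,
              label = sprintf("ag(%d,%d) relative error", ag[1], ag[2]))
    expect_gt(q, 0)
    sp13 <- sp0; sp13$eta_minus <- 13
    expect_identical(motif_triplet_ag(ag[1], ag[2], kp0, sp13), q)
  }
  # pure delayed paths vanish by support
  expect_equal(motif_triplet_ag(0, 2, kp0, sp0), 0, tolerance = 1e-12)
  expect_equal(motif_triplet_ag(0, 3, kp0, sp0), 0, tolerance = 1e-12)
})

test_that("straight third-cumulant coefficients match the oracle", {
  for (st in list(c(1, 0, 1), c(1, 1, 1))) {
    q <- motif_triplet_straight(st[1], st[2], st[3], kp0, sp0)
    o <- oracle_trip_straight(st[1], st[2], st[3], kp0, sp0)
    expect_lt(abs(q - o) / abs(o), 1e-5,
              label = sprintf("straight(%d,%d,%d) relative error",
                              st[1], st[2], st[3]))
  }
  expect_identical(
    motif_triplet_straight(1, 1, 1, kp0, table1_sp(1, A_plus = 0)), 0)
})

test_that("symmetry structure of the pair family", {
  # (1,1) self-symmetric trivially; (2,1) and (1,2) genuinely differ
  expect_false(isTRUE(all.equal(motif_pair(2, 1, kp0, sp0),
                                motif_pair(1, 2, kp0, sp0))))
})

test_that("branched motifs: exponent identity, zeta validation, decay", {
  b <- motif_triplet_branched(1, 1, 1, 1, "alpha", kp0, sp0)
  s <- motif_triplet_straight(2, 1, 1, kp0, sp0)
  expect_equal(b, s, tolerance = 1e-10)
  expect_error(motif_triplet_branched(1, 1, 1, 0, "alpha", kp0, sp0),
               "zeta")
  # total order 4 is much weaker than order 2
  expect_lt(abs(motif_triplet_branched(1, 1, 1, 1, "gamma", kp0, sp0)),
            abs(motif_triplet_straight(1, 0, 1, kp0, sp0)))
})

test_that("quadratures are real: imaginary parts integrate away", {
  im_line <- stats::integrate(function(w)
    Im(epsc_ft(w, kp0) * epsc_ft(-w, kp0)^2 * stdp_pair_ft(-w, sp0)),
    -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-14)$value / (2 * pi)
  expect_lt(abs(im_line), 1e-10)
})

test_that("balance condition sets the potentiation rate", {
  sp <- table1_sp(1)
  expect_equal(balanced_potentiation(sp, 150), 1.1731e-3, tolerance = 1e-4)
  expect_equal(balanced_potentiation(sp, 300),
               balanced_potentiation(sp, 150) / 2)
  expect_error(balanced_potentiation(sp, -1), "positive")
  ms <- motif_set(table1_kp(), sp, 150)
  expect_identical(ms$M0, 0)
  # explicit A_plus reproduces the balanced zero-order motif
  sp$A_plus <- balanced_potentiation(sp, 150)
  ms2 <- motif_set(table1_kp(), sp, 150, balance = FALSE)
  expect_equal(ms2$M0, 0, tolerance = 1e-15)
})

test_that("grouped coefficients combine pair and triplet parts", {
  ms <- motif_set(kp0, table1_sp(7), 150)
  sp7 <- table1_sp(7); sp7$A_plus <- ms$A_plus
  expect_equal(ms$M12, motif_pair(1, 2, kp0, sp7) +
                 150 * motif_triplet_ab(1, 2, kp0, sp7), tolerance = 1e-12)
  expect_equal(ms$M10, 150 * motif_triplet_ab(1, 0, kp0, sp7),
               tolerance = 1e-12)
  expect_equal(ms$Mtrip_a2g1_plus_a1g2,
               motif_triplet_ag(2, 1, kp0, sp7) +
                 motif_triplet_ag(1, 2, kp0, sp7), tolerance = 1e-12)
})

test_that("reciprocal coefficient sign change under depression modulation", {
  f01 <- function(eta) motif_set(kp0, table1_sp(eta), 150)$M01
  expect_lt(f01(1), 0)
  expect_gt(f01(13), 0)
  cr <- find_crossing(f01, 1, 13)
  expect_gt(cr, 4); expect_lt(cr, 7)
  # feedforward coefficient stays positive across the sweep
  for (eta in c(1, 5, 9, 13))
    expect_gt(motif_set(kp0, table1_sp(eta), 150)$M10, 0)
})

test_that("find_crossing locates roots and validates brackets", {
  expect_equal(find_crossing(function(x) x - 2, 0, 5), 2, tolerance = 1e-3)
  expect_error(find_crossing(function(x) x + 10, 0, 5), "sign change")
})

test_that("motif set round-trips through the flat text serialization", {
  ms <- motif_set(kp0, table1_sp(3), 150)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_motif_set(ms, path)
  back <- read_motif_set(path)
  expect_equal(back[["M11"]], ms$M11, tolerance = 1e-15)
  expect_equal(unname(back[tidy(ms)$coefficient]), tidy(ms)$value,
               tolerance = 1e-15)
})

test_that("motif profile tabulates coefficients over a parameter grid", {
  pr <- motif_profile("eta_minus", c(1, 13), kp0, table1_sp(1), 150)
  expect_s3_class(pr, "motif_profile")
  expect_equal(nrow(pr), 2 * 16)
  m01 <- pr[pr$coefficient == "M01", ]
  expect_lt(m01$value[m01$value_of_param == 1], 0)
  expect_gt(m01$value[m01$value_of_param == 13], 0)
  p <- autoplot(pr)
  expect_s3_class(p, "ggplot")
})
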