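test_that("threshold roots match an independent polynomial-root oracle", {
  g <- ref_game()
  # oracle: Gamma(x) b - c = 0 is the degree-5 polynomial
  # -10 x^5 + 30 x^4 - 30 x^3 + 10 x^2 - 0.1, solved by polyroot
  pr <- polyroot(c(-0.1, 0, 10, -30, 30, -10))
  real_roots <- sort(Re(pr[abs(Im(pr)) < 1e-9 & Re(pr) > 0 & Re(pr) < 1]))
  roots <- find_threshold_roots(g)
  expect_length(roots, 2)
  expect_equal(roots, real_roots, tolerance = 1e-10)
  expect_lt(abs(gamma_kernel(roots[1], g) - 0.1), 1e-12)
  expect_lt(abs(gamma_kernel(roots[2], g) - 0.1), 1e-12)
  expect_true(roots[1] < 0.4 && roots[2] > 0.4)  # straddle the kernel mode
})

test_that("threshold roots degenerate correctly at tangency and vanish above the peak", {
  # cost exactly at the kernel peak: double root at the mode
  g_tan <- crsd_game(6, 3, 1, 0.3456)
  expect_equal(find_threshold_roots(g_tan), 0.4, tolerance = 1e-12)
  # cost above the peak: no roots
  expect_length(find_threshold_roots(crsd_game(6, 3, 1, 0.5)), 0)
})

test_that("fixed-point catalogue has the regime-dependent count", {
  expect_identical(nrow(enumerate_fixed_points(linear_system(2))), 7L)
  expect_identical(nrow(enumerate_fixed_points(sigmoid_system(0.5))), 7L)
  expect_identical(nrow(enumerate_fixed_points(linear_system(4))), 6L)
  expect_identical(nrow(enumerate_fixed_points(sigmoid_system(0.8))), 6L)
  # cost above the kernel peak: only the four corners remain
  g_hi <- crsd_game(6, 3, 1, 0.5)
  expect_identical(nrow(enumerate_fixed_points(crsd_system(g_hi, linear_feedback(2), 0.1))), 4L)
})

test_that("every catalogued point annihilates the vector field", {
  set.seed(99)
  for (i in 1:50) {
    g <- random_game(12)
    sys <- if (i %% 2) crsd_system(g, linear_feedback(stats::runif(1, 0.1, 5)), 0.1)
           else crsd_system(g, exponential_feedback(stats::runif(1, 0.05, 0.95), 10), 0.1)
    fp <- enumerate_fixed_points(sys)
    for (j in seq_len(nrow(fp)))
      expect_lt(sqrt(sum(system_rhs(fp$x[j], fp$r[j], sys)^2)), 1e-10)
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(7)
  for (i in 1:30) {
    g <- random_game(15)
    sys <- if (i %% 2) crsd_system(g, linear_feedback(stats::runif(1, 0.2, 4)), stats::runif(1, 0.05, 1))
           else crsd_system(g, exponential_feedback(stats::runif(1, 0.1, 0.9), stats::runif(1, 1, 20)),
                            stats::runif(1, 0.05, 1))
    x <- stats::runif(1, 0.05, 0.95); r <- stats::runif(1, 0.05, 0.95)
    J <- system_jacobian(sys, c(x, r))
    h <- 1e-6
    num <- cbind((riskcoev:::rhs_raw(x + h, r, sys) - riskcoev:::rhs_raw(x - h, r, sys)) / (2 * h),
                 (riskcoev:::rhs_raw(x, r + h, sys) - riskcoev:::rhs_raw(x, r - h, sys)) / (2 * h))
    expect_equal(unname(J), num, tolerance = 1e-6)
  }
})

test_that("interior fixed points have a zero risk-diagonal Jacobian entry", {
  for (sys in list(linear_system(2), sigmoid_system(0.5))) {
    fp <- enumerate_fixed_points(sys)
    ip <- fp[fp$kind == "interior", ]
    expect_identical(nrow(ip), 1L)
    J <- system_jacobian(sys, c(ip$x, ip$r))
    expect_lt(abs(J[2, 2]), 1e-13)
  }
})

test_that("stability labels reproduce the regime catalogue at the reference game", {
  # bistable interior regime (u = 2): exactly (0,1) and (2/3, r*) stable
  ss <- stable_set_of(linear_system(2))
  expect_identical(nrow(ss), 2L)
  expect_equal(ss$x[order(ss$x)], c(0, 2 / 3), tolerance = 1e-12)
  expect_equal(ss$r[order(ss$x)], c(1, 0.1 / gamma_kernel(2 / 3, ref_game())),
               tolerance = 1e-12)
  # weak feedback (u = 0.5): tragedy of the commons only
  ss2 <- stable_set_of(linear_system(0.5))
  expect_identical(nrow(ss2), 1L)
  expect_equal(c(ss2$x, ss2$r), c(0, 1))
  fp <- enumerate_fixed_points(linear_system(0.5))
  expect_identical(fp$stability[fp$kind == "interior"], "unstable")
  # no interior point (u = 4): (0,1) and the high-cooperation boundary point
  ss3 <- stable_set_of(linear_system(4))
  expect_identical(nrow(ss3), 2L)
  x2 <- find_threshold_roots(ref_game())[2]
  expect_equal(sort(ss3$x), sort(c(0, x2)), tolerance = 1e-10)
  expect_lt(x2, 4 / 5)  # stability condition x2* < u/(1+u)
  # sigmoid family: same structure at T = 0.5 and T = 0.8
  ss4 <- stable_set_of(sigmoid_system(0.5))
  expect_equal(sort(ss4$x), c(0, 0.5), tolerance = 1e-12)
  ss5 <- stable_set_of(sigmoid_system(0.8))
  expect_equal(sort(ss5$x), sort(c(0, x2)), tolerance = 1e-10)
})

test_that("the tragedy point (0,1) is present and stable in every sampled regime", {
  set.seed(2026)
  for (i in 1:500) {
    g <- random_game(15)
    sys <- if (i %% 2) crsd_system(g, linear_feedback(stats::runif(1, 0.05, 8)),
                                   sample(c(0.01, 0.1, 1), 1))
           else crsd_system(g, exponential_feedback(stats::runif(1, 0.02, 0.98),
                                                    stats::runif(1, 0.5, 40)),
                            sample(c(0.01, 0.1, 1), 1))
    fp <- enumerate_fixed_points(sys)
    i01 <- which(fp$x == 0 & fp$r == 1)
    expect_length(i01, 1)
    expect_identical(fp$stability[i01], "stable")
    # count matches the regime table
    n <- nrow(fp)
    expect_true(n %in% c(4L, 5L, 6L, 7L))
    has_interior <- any(fp$kind == "interior")
    has_roots <- any(fp$kind == "boundary_root")
    if (has_interior) expect_identical(n, 7L)
    else if (has_roots) expect_true(n %in% c(5L, 6L))
    else expect_identical(n, 4L)
  }
})

test_that("stability labels are invariant to the strategy-update speed", {
  for (u in c(0.5, 2, 4)) {
    labs <- lapply(c(0.01, 0.1, 1), function(e) {
      fp <- enumerate_fixed_points(linear_system(u, eps = e))
      fp$stability[order(fp$x, fp$r)]
    })
    expect_identical(labs[[1]], labs[[2]])
    expect_identical(labs[[2]], labs[[3]])
  }
})

test_that("degenerate coincidences are labelled, not forced", {
  # interior point exactly at the Hopf threshold: purely imaginary pair
  expect_identical(classify_stability(linear_system(2 / 3), c(0.4, 0.1 / 0.3456)),
                   "center_hopf")
  # boundary root coinciding with the kernel balance point: one zero eigenvalue
  x2 <- find_threshold_roots(ref_game())[2]
  u_deg <- x2 / (1 - x2)
  fp <- enumerate_fixed_points(linear_system(u_deg))
  lab <- fp$stability[fp$kind == "boundary_root" & abs(fp$x - x2) < 1e-9]
  expect_identical(lab, "marginal_degenerate")
})

test_that("region classifier covers the four regimes of the parameter plane", {
  g <- ref_game()
  expect_identical(classify_region(g, linear_feedback(2))$label, "bistable_interior")
  expect_identical(classify_region(g, linear_feedback(0.5))$label, "defection_only")
  expect_identical(classify_region(g, linear_feedback(2 / 3))$label, "hopf_line")
  expect_identical(classify_region(g, linear_feedback(4))$label, "bistable_boundary")
  expect_identical(classify_region(g, exponential_feedback(0.5, 10))$label, "bistable_interior")
  expect_identical(classify_region(g, exponential_feedback(0.2, 10))$label, "defection_only")
  expect_identical(classify_region(g, exponential_feedback(0.8, 10))$label, "bistable_boundary")
  # the tragedy point is in every stable set; defection_only has nothing else
  for (fb in list(linear_feedback(2), linear_feedback(0.5), linear_feedback(4),
                  exponential_feedback(0.5, 10), exponential_feedback(0.8, 10))) {
    reg <- classify_region(g, fb)
    expect_true(any(reg$stable_set$x == 0 & reg$stable_set$r == 1))
    if (reg$label == "defection_only") expect_identical(nrow(reg$stable_set), 1L)
  }
})

test_that("region labels agree with the analytic stable sets", {
  set.seed(11)
  for (i in 1:60) {
    g <- random_game(12)
    fb <- if (i %% 2) linear_feedback(stats::runif(1, 0.1, 6))
          else exponential_feedback(stats::runif(1, 0.05, 0.95), 10)
    reg <- classify_region(g, fb)
    ss <- stable_set_of(crsd_system(g, fb, 0.1))
    if (reg$label != "hopf_line") {
      expect_identical(nrow(reg$stable_set), nrow(ss))
      expect_equal(sort(reg$stable_set$x), sort(ss$x), tolerance = 1e-9)
    }
  }
})

test_that("region sweep partitions the plane deterministically", {
  sw <- region_sweep(6, 3, 1, "linear",
                     param_vals = c(seq(0.1, 5, length.out = 12), 2 / 3),
                     cb_vals = seq(0.02, 0.4, length.out = 8))
  expect_identical(nrow(sw), 13L * 8L)
  expect_setequal(unique(sw$label),
                  c("bistable_interior", "hopf_line", "defection_only",
                    "bistable_boundary"))
  sw2 <- region_sweep(6, 3, 1, "linear",
                      param_vals = c(seq(0.1, 5, length.out = 12), 2 / 3),
                      cb_vals = seq(0.02, 0.4, length.out = 8))
  expect_identical(sw, sw2)
})
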