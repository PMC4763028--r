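test_that("the objective reduces to hand arithmetic on tiny instances", {
  A <- diag(3)
  ddc <- fake_ddc(A)
  ph <- fake_phantom(3)
  obj <- plan_objective(50, target_constraints = list())
  ev <- evaluate_objective(c(48, 50, 52), ddc, obj, ph)
  expect_equal(ev$value, 4 + 0 + 4)
  # exact prescription everywhere scores zero
  expect_equal(evaluate_objective(c(50, 50, 50), ddc, obj, ph)$value, 0)
})

test_that("the penalty factor scales only the constraint terms", {
  set.seed(3)
  A <- diag(6)
  ddc <- fake_ddc(A)
  ph <- fake_phantom(3, n_oar = 3)
  obj <- plan_objective(
    50, target_constraints = list(),
    oar_constraints = list(dv_constraint("OAR", 10, 20, "upper")))
  x <- c(48, 50, 53, 30, 25, 5)  # OAR doses 30, 25, 5
  e1 <- evaluate_objective(x, ddc, obj, ph, r = 1)
  e2 <- evaluate_objective(x, ddc, obj, ph, r = 2)
  expect_equal(unname(e1$terms["target"]), unname(e2$terms["target"]))
  expect_gt(e1$terms[["oar_penalty"]], 0)
  expect_equal(e2$terms[["oar_penalty"]], 2 * e1$terms[["oar_penalty"]])
  expect_equal(e2$value - e1$value, e1$terms[["oar_penalty"]])
})

test_that("violation flags implement the DVH gating convention", {
  # upper (10 Gy, 30%): 5 of 10 voxels exceed 10; hottest 30% are allowed
  d <- c(2, 4, 6, 8, 9, 11, 12, 13, 14, 15)
  fl <- violation_flags(d, dv_constraint("PTV", 10, 30, "upper"))
  expect_true(all(which(fl) %in% which(d > 10)))
  expect_false(fl[d == 15] || fl[d == 14])   # allowed hottest fraction
  expect_true(fl[d == 11] && fl[d == 12])    # flagged excess
  # lower (10 Gy, 30%): coldest 30% may stay below
  fl2 <- violation_flags(d, dv_constraint("PTV", 10, 30, "lower"))
  expect_true(all(which(fl2) %in% which(d < 10)))
  expect_false(fl2[d == 2])
  expect_true(fl2[d == 9] && fl2[d == 8])
  # satisfied constraint flags nothing
  expect_false(any(violation_flags(d, dv_constraint("PTV", 16, 5, "upper"))))
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(21)
  A <- matrix(runif(20 * 5), 20, 5)
  ddc <- fake_ddc(A)
  ph <- fake_phantom(12, n_oar = 8)
  obj <- plan_objective(
    30,
    target_constraints = list(dv_constraint("PTV", 29, 10, "lower"),
                              dv_constraint("PTV", 31, 10, "upper")),
    oar_constraints = list(dv_constraint("OAR", 5, 25, "upper",
                                         weight = 0.7)))
  for (rep in 1:5) {
    x <- runif(5, 0.5, 2)
    ev <- evaluate_objective(x, ddc, obj, ph, r = 2)
    g <- objective_gradient(x, ddc, obj, ph, r = 2)
    # flags held fixed in the finite-difference functional too
    f_fixed <- function(xx) {
      d <- as.numeric(A %*% xx)
      val <- sum((d[1:12] - 30)^2)
      for (k in 1:2) {
        cn <- obj$target_constraints[[k]]
        fl <- ev$flags[[paste0("target_", k)]]
        val <- val + 2 * cn$weight * sum((d[1:12][fl] - cn$threshold)^2)
      }
      cn <- obj$oar_constraints[[1]]
      fl <- ev$flags[["OAR_1"]]
      val + 2 * 0.7 * sum((d[13:20][fl] - cn$threshold)^2)
    }
    fd <- fd_gradient(f_fixed, x)
    expect_equal(g, fd, tolerance = 1e-5)
  }
  # zero gradient at the exact-prescription point
  obj0 <- plan_objective(30, target_constraints = list())
  ph0 <- fake_phantom(5)
  x_star <- rep(30, 5)
  expect_equal(objective_gradient(x_star, fake_ddc(diag(5)), obj0, ph0),
               rep(0, 5))
})

test_that("constraint weights scale the penalty gradient linearly", {
  set.seed(5)
  A <- matrix(runif(10 * 4), 10, 4)
  ddc <- fake_ddc(A)
  ph <- fake_phantom(6, n_oar = 4)
  mk <- function(w) plan_objective(
    20, target_constraints = list(),
    oar_constraints = list(dv_constraint("OAR", 1, 10, "upper", weight = w)))
  x <- runif(4, 1, 3)
  g1 <- objective_gradient(x, ddc, mk(1), ph)
  g3 <- objective_gradient(x, ddc, mk(3), ph)
  g0 <- objective_gradient(x, ddc, mk(0), ph)
  expect_equal(g3 - g0, 3 * (g1 - g0), tolerance = 1e-9)
})

test_that("aperture initialization projects the target", {
  ph <- make_selector_phantom(6, 4, 12, spacing = 0.25)
  grid <- beamlet_grid(ph, beam_ray(0, ph$isocenter))
  x <- ciao_init(grid, ph)
  expect_true(all(x %in% c(0, 1)))
  # disc area of a 4 cm sphere projection: pi * 2^2 = 12.6 beamlets of 1 cm2
  expect_gte(sum(x), 9)
  expect_lte(sum(x), 17)
  # aperture beamlets are the ones nearest the field center
  r2 <- rowSums(grid$centers^2)
  expect_true(max(r2[x == 1]) < min(c(r2[x == 0], Inf)) + 2.1)
  # a beam that misses the target yields an all-zero aperture with a warning
  off <- beam_ray(0, ph$isocenter + c(30, 0, 0))
  grid_off <- structure(list(centers = matrix(c(0, 0), 1, 2),
                             e1 = grid$e1, e2 = grid$e2, ray = off, size = 1),
                        class = "beamlet_grid")
  expect_warning(x_off <- ciao_init(grid_off, ph), "aperture|PTV")
  expect_true(all(x_off == 0))
})

test_that("descent is monotone, nonnegative and stops at an optimum", {
  set.seed(9)
  A <- matrix(runif(40 * 8, 0, 1), 40, 8)
  ddc <- fake_ddc(A)
  ph <- fake_phantom(40)
  obj <- plan_objective(25, target_constraints = list(),
                        r_interval = 1e9)  # fixed r
  init <- rep(1, 8)
  fit <- optimize_weights(ddc, obj, ph, init)
  h <- fit$state$history
  expect_true(all(diff(h$objective) <= 1e-9))
  expect_true(all(fit$weights >= 0))
  expect_true(fit$state$stop_reason %in% c("converged", "max_iter"))
  # matches an independent bound-constrained quadratic solver within 1%
  f_qp <- function(x) sum((A %*% x - 25)^2)
  g_qp <- function(x) as.numeric(2 * crossprod(A, A %*% x - 25))
  o <- optim(init * 25 / mean(A %*% init), f_qp, g_qp, method = "L-BFGS-B",
             lower = 0, control = list(maxit = 5000, factr = 1e3))
  expect_lt(abs(fit$state$objective - o$value) / o$value, 0.01)
})

test_that("an already-optimal start terminates immediately and unchanged", {
  ddc <- fake_ddc(diag(4))
  ph <- fake_phantom(4)
  obj <- plan_objective(10, target_constraints = list())
  fit <- optimize_weights(ddc, obj, ph, rep(10, 4), scale_init = FALSE)
  expect_equal(fit$weights, rep(10, 4))
  expect_equal(fit$state$stop_reason, "converged")
  expect_lte(fit$state$iterations, optimizer_controls()$tol_window + 1)
})

test_that("an upper dose-volume constraint spares the critical structure", {
  set.seed(13)
  # target and OAR voxels coupled through shared beamlets
  A <- rbind(matrix(runif(30 * 6, 0.5, 1), 30, 6),
             matrix(runif(10 * 6, 0.1, 0.8), 10, 6))
  ddc <- fake_ddc(A)
  ph <- fake_phantom(30, n_oar = 10)
  base <- plan_objective(20, target_constraints = list())
  con <- plan_objective(
    20, target_constraints = list(),
    oar_constraints = list(dv_constraint("OAR", 5, 10, "upper", weight = 5)))
  f_free <- optimize_weights(ddc, base, ph, rep(1, 6))
  f_con <- optimize_weights(ddc, con, ph, rep(1, 6))
  oar_mean <- function(x) mean(as.numeric(A[31:40, ] %*% x))
  expect_lt(oar_mean(f_con$weights), oar_mean(f_free$weights))
  # escalating r tightens (never loosens) the residual violation
  con_fast <- plan_objective(
    20, target_constraints = list(),
    oar_constraints = list(dv_constraint("OAR", 5, 10, "upper", weight = 5)),
    r0 = 1, r_growth = 4, r_interval = 10)
  f_fast <- optimize_weights(ddc, con_fast, ph, rep(1, 6))
  over <- function(x) {
    d <- sort(as.numeric(A[31:40, ] %*% x), decreasing = TRUE)[-1]
    sum(pmax(d - 5, 0))
  }
  expect_lte(over(f_fast$weights), over(f_free$weights))
})

test_that("a missing structure in the objective is a configuration error", {
  ddc <- fake_ddc(diag(3))
  ph <- fake_phantom(3)
  obj <- plan_objective(
    10, target_constraints = list(),
    oar_constraints = list(dv_constraint("SPLEEN", 5, 10, "upper")))
  expect_error(evaluate_objective(rep(1, 3), ddc, obj, ph),
               class = "emxrt_config")
})
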