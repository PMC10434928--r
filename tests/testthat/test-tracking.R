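# Tracking stage: treadmill conversion, problem construction, transcription
# and the collocation solver (validated against a closed-form toy; the
# full walking recovery runs in the acceptance suite).

test_that("treadmill-to-overground conversion", {
  q <- matrix(0, 2, 3, dimnames = list(c("pelvis_tx", "knee_r"), NULL))
  tt <- c(0, 0.5, 1)
  out <- treadmill_to_overground(q, tt, 1.25)
  expect_equal(out["pelvis_tx", ], c(0, 0.625, 1.25))
  expect_equal(out["knee_r", ], c(0, 0, 0))
  expect_identical(treadmill_to_overground(q, tt, 0), q)
  # average fore-aft speed increases by the belt speed
  expect_equal(mean(diff(out["pelvis_tx", ]) / diff(tt)), 1.25)
  expect_error(treadmill_to_overground(q[2, , drop = FALSE], tt, 1.25))
})

test_that("tracking problem construction and invariants", {
  m <- fix_model()
  ref <- fix_reference()
  ocp <- build_tracking_problem(m, ref)
  # periodicity constraint count = number of states + controls
  expect_equal(ocp$n_periodicity, ocp$nx + ocp$nu)
  # subtalar and MTP carry zero tracking weight
  zero <- grepl("^(subtalar|mtp)", m$coord_names)
  expect_true(all(ocp$wq[zero] == 0))
  expect_true(all(ocp$wq[!zero] > 0))
  # at least one tracking weight must be positive
  w0 <- tracking_weights()
  w0$q <- w0$u <- w0$grf <- w0$torso <- w0$calcn <- 0
  expect_error(build_tracking_problem(m, ref, w0), "tracking weight")
})

test_that("Hermite-Simpson transcription: mesh count and analytic toy", {
  m <- fix_model()
  ocp <- build_tracking_problem(m, fix_reference())
  nlp <- transcribe_hermite_simpson(ocp, 0.01)
  expect_equal(nlp$N, 110)  # 1.1 s at 10 ms
  expect_equal(nlp$nn, 221)

  # double integrator, minimum effort, rest-to-rest transfer: analytic
  # solution x1 = 3 t^2 - 2 t^3, u = 6 - 12 t on [0, 1]
  N <- 10; h <- 0.1
  sw <- rep(0, 2 * N + 1)
  sw[seq(1, 2 * N + 1, 2)] <- 2 * h / 6
  sw[1] <- sw[2 * N + 1] <- h / 6
  sw[seq(2, 2 * N, 2)] <- 4 * h / 6
  sw <- sqrt(sw)
  toy <- list(nx = 2L, nu = 1L, T = 1,
              f_batch = function(times, X, U)
                list(F = rbind(X[2, ], U[1, ]), grf = NULL),
              node_resid = function(times, X, U, be)
                matrix(0.01 * sw * U[1, ], 1),
              global_resid = function(X, U, rho)
                rho * c(X[, 1] - c(0, 0), X[, ncol(X)] - c(1, 0)))
  nlp2 <- transcribe_hermite_simpson(toy, h)
  sol <- solve_tracking(nlp2, list(X = matrix(0, 2, nlp2$nn),
                                   U = matrix(0, 1, nlp2$nn)),
                        rho0 = 1e5, max_iter = 60, convergence_tol = 1e-10)
  tt <- nlp2$times
  expect_lt(max(abs(sol$X[1, ] - (3 * tt^2 - 2 * tt^3))), 1e-6)
  expect_lt(max(abs(sol$U[1, ] - (6 - 12 * tt))), 1e-5)
  # tolerance contract on the solved toy: defects and boundary constraints
  expect_lte(sol$max_violation, 1e-4)
  # objective history is monotone after the first iterate
  expect_true(all(diff(sol$objective_history) <= 1e-9))
})

test_that("initial guess interpolates the observations at the nodes", {
  m <- fix_model()
  ref <- fix_reference()
  ocp <- build_tracking_problem(m, ref)
  nlp <- transcribe_hermite_simpson(ocp, 0.1)
  g <- tracking_initial_guess(ocp, nlp)
  expect_equal(dim(g$X), c(ocp$nx, nlp$nn))
  expect_equal(dim(g$U), c(ocp$nu, nlp$nn))
  expect_equal(unname(g$X[1:23, 1]), unname(ref$q[, 1]), tolerance = 1e-9)
  # dynamics at the guess are consistent with the reference accelerations
  be <- exowalk:::.walk_batch(m, nlp$times, g$X, g$U)
  udot_ref <- exowalk:::.obs_at(ref, "udot", nlp$times)
  expect_lt(max(abs(be$F[24:46, ] - udot_ref)), 1e-6)
})
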