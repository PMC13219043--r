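#' Parameters for the sparse point-to-plane refinement
#'
#' Defaults follow the method's published operating point: sparsity exponent
#' `p = 0.5` (the `0 < p < 1` Lp norm that down-weights outlier residuals),
#' ADMM penalty `mu = 1.0` held fixed, correspondence gate `d_max = 5.0` mm,
#' at most `k_max = 100` outer iterations, and pose-increment stopping
#' thresholds of 0.01 mm / 0.01 degrees with an objective-change threshold of
#' `1e-6`. `inner_iters`, `lm_damping` and `step_cap` are solver safeguards:
#' the number of ADMM passes per correspondence update, the Tikhonov damping
#' on the normal equations, and the per-step cap on the incremental rotation
#' angle (radians) protecting the small-angle linearization.
#'
#' @param p sparsity exponent, `0 < p < 1`.
#' @param mu ADMM penalty parameter (> 0).
#' @param d_max correspondence distance gate (mm).
#' @param k_max maximum outer iterations.
#' @param trans_tol translation-increment stop threshold (mm).
#' @param rot_tol rotation-increment stop threshold (degrees).
#' @param obj_tol objective-change stop threshold.
#' @param inner_iters ADMM passes per correspondence update.
#' @param lm_damping Tikhonov damping added to the normal equations.
#' @param step_cap maximum incremental rotation per linearized solve (radians).
#' @return A validated `sparse_icp_params` list.
#' @export
sparse_icp_params <- function(p = 0.5, mu = 1.0, d_max = 5.0, k_max = 100L,
                              trans_tol = 0.01, rot_tol = 0.01, obj_tol = 1e-6,
                              inner_iters = 5L, lm_damping = 1e-9,
                              step_cap = 0.1) {
  par <- list(p = p, mu = mu, d_max = d_max, k_max = as.integer(k_max),
              trans_tol = trans_tol, rot_tol = rot_tol, obj_tol = obj_tol,
              inner_iters = as.integer(inner_iters), lm_damping = lm_damping,
              step_cap = step_cap)
  validate_icp_params(par)
  structure(par, class = "sparse_icp_params")
}

validate_icp_params <- function(par) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(par$p) && par$p > 0 && par$p < 1,
      sprintf("p must satisfy 0 < p < 1 (got %s)", format(par$p)))
  chk(is.numeric(par$mu) && par$mu > 0, "mu must be > 0")
  chk(par$d_max > 0, "d_max must be > 0")
  chk(par$k_max >= 1L, "k_max must be >= 1")
  chk(par$trans_tol > 0 && par$rot_tol > 0 && par$obj_tol > 0,
      "stopping tolerances must be > 0")
  chk(par$inner_iters >= 1L, "inner_iters must be >= 1")
  chk(par$lm_damping >= 0, "lm_damping must be >= 0")
  chk(par$step_cap > 0, "step_cap must be > 0")
  invisible(TRUE)
}

#' Proximal operator of the Lp penalty (threshold iteration)
#'
#' The scalar minimiser of `f(z) = |z|^p + (mu/2) (z - e)^2` for `0 < p < 1`.
#' Below a hard threshold on `|e|` the minimiser is exactly 0 (the sparse
#' branch); above it, a fixed-point "threshold iteration"
#' `z <- |e| - (p/mu) z^(p-1)` converges to the attractive stationary point,
#' which is then kept only if it beats `f(0)`. An exact tie at the threshold
#' resolves to 0, the sparser solution. Vectorised over `e_tilde`.
#'
#' @param e_tilde shifted residuals `n.(Rx + t - y) + lambda/mu` (mm).
#' @param mu ADMM penalty (> 0).
#' @param p sparsity exponent in (0, 1).
#' @return The elementwise minimisers, same length as `e_tilde`;
#'   `sign(z) == sign(e_tilde)` or 0, and `|z| <= |e_tilde|`.
#' @export
prox_lp <- function(e_tilde, mu = 1.0, p = 0.5) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must satisfy 0 < p < 1", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("mu must be > 0", call. = FALSE)
  }
  e <- as.numeric(e_tilde)
  a <- abs(e)
  z <- numeric(length(e))

  # inflection of g(z) = z^p + (mu/2)(z-a)^2 on z > 0: below z_inf the
  # stationary equation has no root, so the minimiser is 0
  z_inf <- (p * (1 - p) / mu)^(1 / (2 - p))
  # a root exists only if g'(z_inf) <= 0
  gp_inf <- p * z_inf^(p - 1) + mu * (z_inf - a)
  cand <- which(gp_inf <= 0 & a > 0)
  if (length(cand)) {
    ac <- a[cand]
    zc <- ac # start at the quadratic minimiser; iteration descends to the root
    for (it in 1:100) {
      znew <- ac - (p / mu) * zc^(p - 1)
      if (max(abs(znew - zc)) < 1e-14) {
        zc <- znew
        break
      }
      zc <- znew
    }
    f0 <- (mu / 2) * ac^2
    fz <- zc^p + (mu / 2) * (zc - ac)^2
    win <- fz < f0 # tie -> 0
    z[cand[win]] <- sign(e[cand[win]]) * zc[win]
  }
  z
}

#' Sparse registration objective
#'
#' `E = sum over kept pairs of |n_i . (R x_i + t - y_i)|^p`, the Lp
#' point-to-plane loss the refinement minimises.
#'
#' @param corrs a `correspondence_set` from [find_correspondences()].
#' @param transform a [rigid_transform()] applied to the stored source points.
#' @param p sparsity exponent.
#' @return The scalar objective value.
#' @export
objective_value <- function(corrs, transform, p = 0.5) {
  kp <- kept_pairs(corrs)
  if (nrow(kp$source) == 0L) {
    stop("objective_value: no kept correspondences", call. = FALSE)
  }
  x <- transform_points(transform, kp$source)
  r <- rowSums(kp$normal * (x - kp$target))
  sum(abs(r)^p)
}

#' Linearized point-to-plane system
#'
#' Small-angle linearization of the pose step: with residual model
#' `r_i = n_i.(x_i - y_i) + n_i.t + n_i.(w x x_i) - z_i`, the unknown
#' `xi = [w, dt]` satisfies the stacked system with rows
#' `A_i = [(x_i x n_i)^T, n_i^T]` and `b_i = z_i - n_i.(x_i - y_i)`, the
#' source points `x_i` being expressed in the current pose.
#'
#' @param corrs a `correspondence_set` (kept pairs are used).
#' @param z auxiliary residual targets, one per kept pair (use zeros for the
#'   plain quadratic point-to-plane step).
#' @return List `A` (N x 6), `b` (length N) of class `linearized_system`.
#' @export
build_linear_system <- function(corrs, z) {
  kp <- kept_pairs(corrs)
  n <- nrow(kp$source)
  if (n == 0L) stop("build_linear_system: no kept correspondences", call. = FALSE)
  z <- as.numeric(z)
  if (length(z) != n) stop("z must match the kept-pair count", call. = FALSE)
  x <- kp$source
  nn <- kp$normal
  cross_xn <- cbind(
    x[, 2] * nn[, 3] - x[, 3] * nn[, 2],
    x[, 3] * nn[, 1] - x[, 1] * nn[, 3],
    x[, 1] * nn[, 2] - x[, 2] * nn[, 1]
  )
  A <- cbind(cross_xn, nn)
  b <- z - rowSums(nn * (x - kp$target))
  structure(list(A = A, b = b), class = "linearized_system")
}

#' Solve the normal equations for a pose increment
#'
#' Damped least squares `(A^T A + damping I) xi = A^T b`; the incremental
#' rotation magnitude is capped at `step_cap` by rescaling the whole step so
#' the small-angle model stays valid.
#'
#' @param system a `linearized_system`.
#' @param lm_damping Tikhonov damping (>= 0).
#' @param step_cap cap on `|w|` in radians.
#' @return A `rotation_increment` list: `omega` (radians), `dt` (mm).
#' @export
solve_increment <- function(system, lm_damping = 1e-9, step_cap = 0.1) {
  stopifnot(inherits(system, "linearized_system"))
  A <- system$A
  b <- system$b
  AtA <- crossprod(A) + lm_damping * diag(6)
  ev <- eigen(AtA, symmetric = TRUE, only.values = TRUE)$values
  if (ev[6] <= 0 || ev[1] / ev[6] > 1e12) {
    stop(sprintf(
      "degenerate geometry: normal equations condition %.3g exceeds 1e12 (surface under-constrains the pose)",
      ev[1] / max(ev[6], .Machine$double.xmin)), call. = FALSE)
  }
  xi <- solve(AtA, crossprod(A, b))
  omega <- xi[1:3]
  dt <- xi[4:6]
  wn <- sqrt(sum(omega^2))
  if (wn > step_cap) {
    s <- step_cap / wn
    omega <- omega * s
    dt <- dt * s
  }
  structure(list(omega = as.numeric(omega), dt = as.numeric(dt)),
            class = "rotation_increment")
}

#' One block of ADMM passes over fixed correspondences
#'
#' With the correspondence set frozen, cycles `inner_iters` times through:
#' (a) the elementwise proximal update of the auxiliary residuals
#' `z_i <- prox(|.|^p)(n_i.(R x_i + t - y_i) + lambda_i / mu)`; (b) the
#' linearized pose solve driving residuals toward `z`, composed exactly as
#' `R <- exp([w]x) R`, `t <- exp([w]x) t + dt`; (c) the dual ascent
#' `lambda_i <- lambda_i + mu (n_i.(R x_i + t - y_i) - z_i)`.
#'
#' @param corrs a `correspondence_set` (kept pairs drive the solve).
#' @param state list with numeric `z` and `lambda`, one entry per kept pair.
#' @param params a [sparse_icp_params()] object.
#' @return List `increment` (the accumulated [rigid_transform()] over the
#'   block, acting on the current-pose source points) and updated `state`.
#' @export
admm_inner_loop <- function(corrs, state, params) {
  kp <- kept_pairs(corrs)
  n <- nrow(kp$source)
  if (n == 0L) stop("admm_inner_loop: no kept correspondences", call. = FALSE)
  z <- state$z
  lambda <- state$lambda
  stopifnot(length(z) == n, length(lambda) == n)
  Rd <- diag(3)
  td <- c(0, 0, 0)
  x0 <- kp$source
  y <- kp$target
  nn <- kp$normal
  for (j in seq_len(params$inner_iters)) {
    x_cur <- sweep(x0 %*% t(Rd), 2L, td, "+")
    r <- rowSums(nn * (x_cur - y))
    z <- prox_lp(r + lambda / params$mu, params$mu, params$p)
    sys <- build_linear_system(
      structure(list(source = x_cur, target = y, normal = nn,
                     kept = rep(TRUE, n), source_index = kp$source_index,
                     target_index = kp$target_index, dist = numeric(n),
                     d_max = params$d_max),
                class = "correspondence_set"), z)
    inc <- solve_increment(sys, params$lm_damping, params$step_cap)
    Rw <- exp_so3(inc$omega)
    Rd <- Rw %*% Rd
    td <- as.numeric(Rw %*% td) + inc$dt
    x_new <- sweep(x0 %*% t(Rd), 2L, td, "+")
    delta <- rowSums(nn * (x_new - y)) - z
    lambda <- lambda + params$mu * delta
  }
  list(increment = rigid_transform(orthonormalize_rotation(Rd), td),
       state = list(z = z, lambda = lambda))
}

# Shared outer loop for the three fine-registration variants.
# method: "sparse_p2pl", "p2pl", "p2pt"
icp_outer_loop <- function(source, target, init, params, method) {
  stopifnot(inherits(source, "point_cloud"), inherits(init, "rigid_transform"))
  index <- if (inherits(target, "spatial_index")) target else build_spatial_index(target)
  if (is.null(index$cloud$normals)) {
    stop("target cloud lacks normals: run estimate_normals() first", call. = FALSE)
  }
  n_src <- n_points(source)
  pose <- init
  # warm-started duals keyed by source point; reset when the match changes
  z_all <- numeric(n_src)
  lam_all <- numeric(n_src)
  prev_match <- rep(NA_integer_, n_src)
  prev_E <- NA_real_
  prev_kept_sig <- ""
  trace <- vector("list", params$k_max)
  termination <- "max_iters"

  for (k in seq_len(params$k_max)) {
    moved <- point_cloud(transform_points(pose, source$points))
    corrs <- find_correspondences(moved, index, params$d_max)
    n_kept <- sum(corrs$kept)
    if (n_kept == 0L) {
      stop(paste0(
        "lost registration: every correspondence exceeded d_max = ",
        format(params$d_max),
        " mm; increase d_max or improve the initial alignment"), call. = FALSE)
    }
    kept_idx <- corrs$source_index[corrs$kept]
    match_now <- corrs$target_index

    if (method == "p2pt") {
      kp <- kept_pairs(corrs)
      fit <- kabsch_align(kp$source, kp$target)
      increment <- fit$transform
      inner_used <- 1L
    } else {
      if (method == "sparse_p2pl") {
        changed <- is.na(prev_match) | match_now != prev_match | !corrs$kept
        z_all[changed] <- 0
        lam_all[changed] <- 0
        state <- list(z = z_all[kept_idx], lambda = lam_all[kept_idx])
        res <- admm_inner_loop(corrs, state, params)
        z_all[kept_idx] <- res$state$z
        lam_all[kept_idx] <- res$state$lambda
        increment <- res$increment
      } else { # plain point-to-plane: quadratic loss, z == 0, no duals
        res <- p2pl_inner_loop(corrs, params)
        increment <- res$increment
      }
      inner_used <- if (method == "p2pl") 1L else params$inner_iters
    }

    pose <- compose(increment, pose)
    dt_norm <- sqrt(sum(increment$t^2))
    dtheta_deg <- rotation_angle(increment$R) * 180 / pi

    E <- switch(method,
      sparse_p2pl = objective_value(corrs, increment, params$p),
      p2pl = {
        kp <- kept_pairs(corrs)
        x <- transform_points(increment, kp$source)
        sum(rowSums(kp$normal * (x - kp$target))^2)
      },
      p2pt = {
        kp <- kept_pairs(corrs)
        x <- transform_points(increment, kp$source)
        mean(rowSums((x - kp$target)^2))
      })

    trace[[k]] <- data.frame(iter = k, objective = E, kept = n_kept,
                             dt_norm = dt_norm, dtheta_deg = dtheta_deg,
                             inner_iters = inner_used)

    kept_sig <- paste(kept_idx, match_now[kept_idx], collapse = ";")
    if (dt_norm < params$trans_tol && dtheta_deg < params$rot_tol) {
      termination <- "pose_tol"
      break
    }
    # objective change is only comparable on an unchanged support
    if (!is.na(prev_E) && kept_sig == prev_kept_sig &&
        abs(E - prev_E) < params$obj_tol) {
      termination <- "obj_tol"
      break
    }
    prev_E <- E
    prev_kept_sig <- kept_sig
    prev_match <- match_now
  }

  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  structure(list(
    transform = pose, # total: fine o init
    fine = compose(pose, invert(init)),
    init = init,
    trace = trace,
    termination = termination,
    method = method,
    params = params
  ), class = "icp_result")
}

# One damped least-squares pass for the plain point-to-plane step (quadratic
# loss): the same linearized system with z = 0. Classic point-to-plane ICP
# relinearizes after every correspondence update, so a single solve per outer
# iteration; several passes on a stale correspondence set overshoot.
p2pl_inner_loop <- function(corrs, params) {
  n <- sum(corrs$kept)
  sys <- build_linear_system(corrs, numeric(n))
  inc <- solve_increment(sys, params$lm_damping, params$step_cap)
  list(increment = rigid_transform(exp_so3(inc$omega), inc$dt))
}

#' @export
print.icp_result <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<icp_result> method %s: %d outer iterations, stopped on %s\n",
              x$method, nrow(x$trace), x$termination))
  cat(sprintf("  final objective %.6g, kept %d pairs, last step %.4g mm / %.4g deg\n",
              last$objective, last$kept, last$dt_norm, last$dtheta_deg))
  print(x$transform)
  invisible(x)
}

#' Sparse point-to-plane ICP registration
#'
#' The fine-registration stage: alternates gated nearest-neighbour
#' correspondence search against the dense target with ADMM minimisation of
#' the Lp point-to-plane objective
#' `sum_i |n_i . (R x_i + t - y_i)|^p` over rigid poses. The
#' sparsity-inducing norm (`0 < p < 1`) drives outlier residuals — e.g. probe
#' points held off the bone by cartilage — toward auxiliary values that the
#' pose solve then ignores, making the refinement robust at ~30 sample
#' points. Stops on the iteration cap, on a pose increment below
#' `(trans_tol, rot_tol)`, or on an objective change below `obj_tol` over an
#' unchanged correspondence support.
#'
#' @param source sparse probe `point_cloud` in the patient/tracker frame.
#' @param target dense `point_cloud` with normals (CT frame), or a
#'   `spatial_index` built over one.
#' @param init initial [rigid_transform()], typically the coarse solution.
#' @param params a [sparse_icp_params()] object.
#' @return An `icp_result`: `transform` (total source-to-target map, the fine
#'   stage composed onto `init`), `fine` (the refinement alone), `trace`
#'   (per-iteration objective, kept-pair count and pose increments), and
#'   `termination` (one of `"max_iters"`, `"pose_tol"`, `"obj_tol"`).
#' @export
sparse_icp_register <- function(source, target, init = identity_transform(),
                                params = sparse_icp_params()) {
  validate_icp_params(params)
  icp_outer_loop(source, target, init, params, "sparse_p2pl")
}

#' Plain point-to-plane ICP (ablation baseline)
#'
#' Identical to [sparse_icp_register()] with the sparse machinery disabled:
#' each correspondence update is followed by damped Gauss-Newton passes on
#' the quadratic point-to-plane loss.
#'
#' @inheritParams sparse_icp_register
#' @return An `icp_result`; the trace objective is the quadratic loss
#'   `sum (n.r)^2`.
#' @export
icp_point_to_plane <- function(source, target, init = identity_transform(),
                               params = sparse_icp_params()) {
  validate_icp_params(params)
  icp_outer_loop(source, target, init, params, "p2pl")
}

#' Classic point-to-point ICP (ablation baseline)
#'
#' Nearest-neighbour correspondences with the same distance gating, followed
#' by the closed-form SVD (Kabsch) update on the matched pairs each
#' iteration; same stopping rules.
#'
#' @inheritParams sparse_icp_register
#' @return An `icp_result`; the trace objective is the mean squared
#'   point-to-point distance.
#' @export
icp_point_to_point <- function(source, target, init = identity_transform(),
                               params = sparse_icp_params()) {
  validate_icp_params(params)
  icp_outer_loop(source, target, init, params, "p2pt")
}
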